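#' Load a STRING-dialect weighted edge list
#'
#' Reads a tab-separated file with columns `protein1`, `protein2`,
#' `combined_score` (confidence on the 0-1000 scale), drops self-loops and
#' edges below the confidence threshold, canonicalizes node order
#' (min, max) and deduplicates, keeping the highest score of duplicated
#' edges. Malformed rows raise an error naming the offending line.
#'
#' @param path Path to the TSV file (a header line is expected).
#' @param score_threshold Minimum combined score retained (default 700, the
#'   conventional high-confidence cutoff for STRING-style scores).
#' @return Tibble with columns `protein1`, `protein2`, `combined_score`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein1\tprotein2\tcombined_score",
#'              "A\tB\t900", "B\tA\t900", "B\tC\t650"), f)
#' load_string_edges(f)
#' @export
load_string_edges <- function(path, score_threshold = 700) {
  # parse issues surface via readr::problems() and become errors below
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    protein1 = readr::col_character(),
    protein2 = readr::col_character(),
    combined_score = readr::col_double())))
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(raw))) {
    abort(sprintf("edge file must have columns %s", paste(need, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  bad <- which(is.na(raw$protein1) | is.na(raw$protein2) |
                 is.na(raw$combined_score))
  if (nrow(probs) > 0 || length(bad)) {
    # readr reports the file line directly; the NA fallback adds the header
    line <- if (nrow(probs) > 0) probs$row[1] else bad[1] + 1L
    abort(sprintf("malformed edge row at line %d of %s", line, path))
  }
  canonicalize_edges(raw, score_threshold)
}

# Shared by the loader and the pipeline (which already holds a tibble).
canonicalize_edges <- function(edges, score_threshold = 0) {
  edges <- tibble::as_tibble(edges)
  edges <- dplyr::mutate(edges,
                         a = pmin(.data$protein1, .data$protein2),
                         b = pmax(.data$protein1, .data$protein2))
  edges <- dplyr::filter(edges, .data$a != .data$b,
                         .data$combined_score >= score_threshold)
  edges <- dplyr::arrange(edges, .data$a, .data$b,
                          dplyr::desc(.data$combined_score))
  edges <- dplyr::distinct(edges, .data$a, .data$b, .keep_all = TRUE)
  tibble::tibble(protein1 = edges$a, protein2 = edges$b,
                 combined_score = edges$combined_score)
}

#' Extract the positives-anchored module from projected burden hits
#'
#' Three deterministic steps: (1) induce the subgraph on the significant
#' genes (plus, with `include_all_positives = TRUE`, every training positive
#' present in the edge list); (2) keep only nodes that are training
#' positives or adjacent to one within that subgraph; (3) return the union
#' of connected components containing at least one training positive.
#'
#' @param edges Canonical edge tibble from [load_string_edges()] or
#'   [simulate_network()].
#' @param significant_genes Genes projected onto the network (burden hits).
#' @param training_positives Anchor gene set.
#' @param include_all_positives If TRUE, training positives join the
#'   projected node set even when not burden-significant; by default only
#'   significant positives anchor the module.
#' @return An object of class `gene_module`: list with `nodes` (tibble:
#'   gene, is_training_positive) and `edges` (tibble). Empty inputs give an
#'   empty module.
#' @examples
#' edges <- tibble::tibble(protein1 = c("A", "B", "D"),
#'                         protein2 = c("B", "C", "E"),
#'                         combined_score = 900)
#' extract_module(edges, c("A", "B", "C", "D", "E"), "A")$nodes
#' @export
extract_module <- function(edges, significant_genes, training_positives,
                           include_all_positives = FALSE) {
  edges <- tibble::as_tibble(edges)
  node_set <- unique(significant_genes)
  if (include_all_positives) {
    in_graph <- unique(c(edges$protein1, edges$protein2))
    node_set <- unique(c(node_set, intersect(training_positives, in_graph)))
  }

  sub <- dplyr::filter(edges, .data$protein1 %in% node_set,
                       .data$protein2 %in% node_set)
  nodes <- unique(c(node_set[node_set %in% c(sub$protein1, sub$protein2)],
                    intersect(node_set, training_positives)))
  if (length(nodes) == 0 || length(intersect(nodes, training_positives)) == 0) {
    return(empty_module())
  }

  g <- igraph::graph_from_data_frame(
    sub[, c("protein1", "protein2")], directed = FALSE,
    vertices = data.frame(name = nodes))
  anchors <- intersect(nodes, training_positives)
  neighbour_idx <- unlist(lapply(igraph::adjacent_vertices(g, anchors), as.integer))
  keep <- intersect(nodes, unique(c(anchors, igraph::V(g)$name[neighbour_idx])))
  g2 <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(g2)
  anchored <- unique(comp$membership[intersect(keep, anchors)])
  members <- names(comp$membership)[comp$membership %in% anchored]
  members <- c_sort(members)

  mod_edges <- dplyr::filter(sub, .data$protein1 %in% members,
                             .data$protein2 %in% members)
  structure(list(
    nodes = tibble::tibble(gene = members,
                           is_training_positive = members %in% training_positives),
    edges = mod_edges),
    class = "gene_module")
}

empty_module <- function() {
  structure(list(
    nodes = tibble::tibble(gene = character(),
                           is_training_positive = logical()),
    edges = tibble::tibble(protein1 = character(), protein2 = character(),
                           combined_score = double())),
    class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %d genes (%d training positives), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_training_positive), nrow(x$edges)))
  invisible(x)
}

#' Annotate a module with evidence scores and group membership
#'
#' Joins combined evidence scores onto the module's node table; module genes
#' without a score receive 0 and are flagged. When the per-group significant
#' gene sets are supplied, each node is labelled restricted/binge/both.
#'
#' @param module A [extract_module()] result.
#' @param evidence Tibble from [combine_evidence()].
#' @param groups Optional named list of per-group significant gene vectors
#'   (e.g. the `significant` element of a `burden_scan`).
#' @return The module with its `nodes` table gaining `combined_score`,
#'   `score_missing` and (when `groups` is given) `group` columns.
#' @examples
#' edges <- tibble::tibble(protein1 = "A", protein2 = "B",
#'                         combined_score = 900)
#' m <- extract_module(edges, c("A", "B"), "A")
#' ev <- tibble::tibble(gene = "A", combined_score = 0.9)
#' annotate_module(m, ev)$nodes
#' @export
annotate_module <- function(module, evidence, groups = NULL) {
  stopifnot(inherits(module, "gene_module"))
  ev <- dplyr::select(tibble::as_tibble(evidence), "gene", "combined_score")
  nodes <- dplyr::left_join(module$nodes, ev, by = "gene")
  nodes <- dplyr::mutate(nodes,
                         score_missing = is.na(.data$combined_score),
                         combined_score = dplyr::coalesce(.data$combined_score, 0))
  if (!is.null(groups)) {
    grp_names <- setdiff(names(groups), "union")
    membership <- vapply(nodes$gene, function(g) {
      hit <- grp_names[vapply(grp_names, function(nm) g %in% groups[[nm]], logical(1))]
      if (length(hit) == 0) "none"
      else if (length(hit) == length(grp_names) && length(grp_names) > 1) "both"
      else paste(hit, collapse = "/")
    }, character(1))
    nodes$group <- unname(membership)
  }
  module$nodes <- nodes
  module
}

#' @rdname extract_module
#' @param object A `gene_module` (annotated or not).
#' @param seed Seed for the deterministic force-directed layout.
#' @param ... Unused.
#' @method autoplot gene_module
#' @export
autoplot.gene_module <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty module"))
  }
  g <- igraph::graph_from_data_frame(
    object$edges[, c("protein1", "protein2")], directed = FALSE,
    vertices = data.frame(name = object$nodes$gene))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes,
                         x = xy[, 1], y = xy[, 2],
                         score = if ("combined_score" %in% names(object$nodes))
                           .data$combined_score else 0)
  seg <- dplyr::left_join(object$edges,
                          dplyr::select(nodes, gene, x1 = "x", y1 = "y"),
                          by = c(protein1 = "gene"))
  seg <- dplyr::left_join(seg,
                          dplyr::select(nodes, gene, x2 = "x", y2 = "y"),
                          by = c(protein2 = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$score,
                                     shape = .data$is_training_positive),
                        size = 4, colour = "black") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 22),
                                name = "training positive") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1), name = "evidence") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
                       vjust = -1.2, size = 3) +
    ggplot2::theme_void()
}

#' Write a module as GraphML
#'
#' @param module A `gene_module`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_module_graphml <- function(module, path) {
  stopifnot(inherits(module, "gene_module"))
  g <- igraph::graph_from_data_frame(
    module$edges, directed = FALSE,
    vertices = as.data.frame(module$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
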