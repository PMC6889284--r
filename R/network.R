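#' Build the bipartite students-by-responses incidence matrix
#'
#' Rows are students, columns are (question, option) pairs; entry 1 marks
#' that the student chose that option on that question. A missing response
#' contributes an all-zero block, so row sums equal the number of answered
#' questions.
#'
#' @param responses Response tibble (see [as_responses()]).
#' @return A binary integer matrix with student IDs as row names and
#'   `"question::option"` labels as column names, column order grouped by
#'   question in encounter order.
#' @export
build_bipartite <- function(responses) {
  responses <- as_responses(responses)
  students <- unique(responses$student_id)
  questions <- unique(responses$question_id)
  answered <- dplyr::filter(responses, !is.na(.data$choice))
  cols <- dplyr::distinct(answered, .data$question_id, .data$choice)
  cols <- dplyr::arrange(cols, match(.data$question_id, questions), .data$choice)
  col_labels <- paste0(cols$question_id, "::", cols$choice)
  m <- matrix(0L, nrow = length(students), ncol = length(col_labels),
              dimnames = list(students, col_labels))
  if (nrow(answered) > 0L) {
    idx <- cbind(match(answered$student_id, students),
                 match(paste0(answered$question_id, "::", answered$choice),
                       col_labels))
    m[idx] <- 1L
  }
  m
}

new_agreement_network <- function(edges, nodes, n_questions) {
  structure(list(edges = edges, nodes = nodes, n_questions = n_questions),
            class = "agreement_network")
}

#' Project responses onto the weighted student agreement network
#'
#' Computes `A = M M^T` for the bipartite incidence `M`: the weight of edge
#' (i, j) counts the questions on which students i and j chose the same
#' option (both must have answered). Weights range from 0 to the number of
#' questions; zero-agreement pairs are non-edges, not zero-weight edges.
#'
#' @param x Response tibble, or a binary incidence matrix from
#'   [build_bipartite()].
#' @param n_questions Number of questions (inferred from a response tibble;
#'   required only to annotate the weight bound when `x` is a matrix and
#'   column names lack `"question::option"` structure).
#' @return An `agreement_network`: list with `edges` (tibble `from`, `to`,
#'   `weight`, each undirected edge once with `from` before `to` in node
#'   order), `nodes` (all student IDs, isolates included), `n_questions`.
#' @export
project_agreement <- function(x, n_questions = NULL) {
  if (is.data.frame(x)) {
    x <- as_responses(x)
    n_questions <- length(unique(x$question_id))
    m <- build_bipartite(x)
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(n_questions)) {
      qs <- sub("::.*$", "", colnames(m))
      n_questions <- if (length(qs) > 0 && !any(is.na(qs))) length(unique(qs)) else ncol(m)
    }
  } else {
    stop("x must be a response data frame or incidence matrix", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("need at least 2 students to build a network", call. = FALSE)
  a <- tcrossprod(m)
  diag(a) <- 0L
  nodes <- rownames(m)
  ut <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = nodes[ut[, 1]],
    to = nodes[ut[, 2]],
    weight = as.numeric(a[ut])
  )
  edges <- dplyr::arrange(edges, match(.data$from, nodes), match(.data$to, nodes))
  new_agreement_network(edges, nodes, n_questions)
}

#' @export
print.agreement_network <- function(x, ...) {
  cat("<agreement_network> ", length(x$nodes), " students, ",
      nrow(x$edges), " edges, weights in [0, ", x$n_questions, "]\n", sep = "")
  invisible(x)
}

#' Per-endpoint empirical edge significance
#'
#' Locally adaptive nonparametric significance: each node ranks its incident
#' edges by fractional weight (edge weight divided by node strength), and an
#' edge's p-value at that endpoint is the fraction of the node's incident
#' edges with strictly greater fractional weight — i.e. `1 - F̂(p_ij)` under
#' the less-than-or-equal empirical CDF convention, so a node's maximal
#' (and tied-maximal) edges get p-value 0. Scale-invariant by construction.
#'
#' @param network An `agreement_network`.
#' @return The edge tibble with `p_from` and `p_to` columns appended
#'   (significance at the `from` and `to` endpoints respectively).
#' @export
edge_significance <- function(network) {
  stopifnot(inherits(network, "agreement_network"))
  edges <- network$edges
  if (nrow(edges) == 0L || all(edges$weight <= 0)) {
    stop("network has no positive-weight edge", call. = FALSE)
  }
  directed <- dplyr::bind_rows(
    dplyr::transmute(edges, node = .data$from, other = .data$to,
                     weight = .data$weight, eid = dplyr::row_number()),
    dplyr::transmute(edges, node = .data$to, other = .data$from,
                     weight = .data$weight, eid = dplyr::row_number())
  )
  directed <- dplyr::mutate(
    dplyr::group_by(directed, .data$node),
    frac = .data$weight / sum(.data$weight),
    p_at = (dplyr::n() - rank(.data$frac, ties.method = "max")) / dplyr::n()
  )
  directed <- dplyr::ungroup(directed)
  p_from <- directed$p_at[seq_len(nrow(edges))]
  p_to <- directed$p_at[nrow(edges) + seq_len(nrow(edges))]
  dplyr::mutate(edges, p_from = p_from, p_to = p_to)
}

new_backbone_graph <- function(edges, nodes, n_questions, alpha, rule) {
  structure(list(edges = edges, nodes = nodes, n_questions = n_questions,
                 alpha = alpha, rule = rule),
            class = "backbone_graph")
}

#' Extract the nonparametric backbone of an agreement network
#'
#' Retains the edges that are locally significant per
#' [edge_significance()]: under the default `"either"` rule an edge
#' survives if it is significant at `alpha` from at least one endpoint's
#' perspective; under `"both"` it must be significant from both. All nodes
#' are retained (isolates are allowed) and weights are never modified.
#'
#' @param network An `agreement_network`.
#' @param alpha Significance level in (0, 1); default 0.01.
#' @param rule `"either"` (default) or `"both"` endpoint-combination rule.
#' @return A `backbone_graph`: list with `edges` (tibble `from`, `to`,
#'   `weight`, `p_from`, `p_to`, `retained`), `nodes`, `n_questions`,
#'   `alpha`, `rule`.
#' @export
lans_backbone <- function(network, alpha = 0.01, rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(alpha > 0, alpha < 1)
  edges <- edge_significance(network)
  edges$retained <- if (rule == "either") {
    edges$p_from < alpha | edges$p_to < alpha
  } else {
    edges$p_from < alpha & edges$p_to < alpha
  }
  new_backbone_graph(edges, network$nodes, network$n_questions, alpha, rule)
}

#' @export
print.backbone_graph <- function(x, ...) {
  cat("<backbone_graph> ", length(x$nodes), " students, ",
      sum(x$edges$retained), "/", nrow(x$edges),
      " edges retained (alpha = ", x$alpha, ", rule = ", x$rule, ")\n", sep = "")
  invisible(x)
}

retained_edges <- function(g) {
  if (inherits(g, "backbone_graph")) {
    g$edges[g$edges$retained, c("from", "to", "weight")]
  } else if (inherits(g, "agreement_network")) {
    g$edges[c("from", "to", "weight")]
  } else {
    stop("expected an agreement_network or backbone_graph", call. = FALSE)
  }
}

#' Write a network edge list (and node list) to CSV, optionally GraphML
#'
#' The node list is written separately so isolated students survive
#' serialization.
#'
#' @param g A `backbone_graph` or `agreement_network`.
#' @param path Edge-list CSV path; the node list goes to
#'   `<path-sans-ext>_nodes.csv`, GraphML (if requested) to
#'   `<path-sans-ext>.graphml`.
#' @param graphml Also write GraphML (requires the igraph package).
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, graphml = FALSE) {
  edges <- if (inherits(g, "backbone_graph")) g$edges else
    dplyr::mutate(edge_significance(g), retained = NA)
  readr::write_csv(
    dplyr::rename(edges, source = "from", target = "to",
                  pvalue_src = "p_from", pvalue_tgt = "p_to"),
    path, progress = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  readr::write_csv(tibble::tibble(student_id = g$nodes),
                   paste0(stem, "_nodes.csv"), progress = FALSE)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("GraphML output requires the igraph package", call. = FALSE)
    }
    ig <- igraph::graph_from_data_frame(retained_edges(g), directed = FALSE,
                                        vertices = tibble::tibble(name = g$nodes))
    igraph::write_graph(ig, paste0(stem, ".graphml"), format = "graphml")
  }
  invisible(path)
}
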