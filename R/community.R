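#' Random-walker visit rates on an undirected weighted graph
#'
#' For an undirected graph the stationary distribution of the weighted
#' random walk is strength-proportional: `p[a] = strength(a) / (2 W)` with
#' `W` the total edge weight. Isolated nodes get visit rate 0.
#'
#' @param g A `backbone_graph` (retained edges are used) or
#'   `agreement_network`.
#' @return Tibble with columns `student_id`, `strength`, `visit_rate`
#'   (summing to 1), one row per node including isolates.
#' @export
node_visit_rates <- function(g) {
  edges <- retained_edges(g)
  if (nrow(edges) == 0L || all(edges$weight <= 0)) {
    stop("graph has no positive-weight edge; no walk is defined", call. = FALSE)
  }
  strength <- tapply(
    c(edges$weight, edges$weight),
    factor(c(edges$from, edges$to), levels = g$nodes),
    sum, default = 0
  )
  strength <- as.numeric(strength)
  tibble::tibble(
    student_id = g$nodes,
    strength = strength,
    visit_rate = strength / sum(strength)
  )
}

as_assignment <- function(partition, nodes, isolated = NULL) {
  if (is.data.frame(partition)) {
    stopifnot(all(c("student_id", "community") %in% names(partition)))
    assign <- partition$community[match(nodes, partition$student_id)]
  } else {
    assign <- partition[nodes]
  }
  miss <- is.na(assign)
  if (any(miss)) {
    # isolated nodes may be left out of the partition: they become singletons
    if (is.null(isolated) || !all(nodes[miss] %in% isolated)) {
      stop("partition does not cover every non-isolated node", call. = FALSE)
    }
    assign <- as.character(assign)
    assign[miss] <- paste0(".isolate.", seq_len(sum(miss)))
  }
  as.integer(factor(assign, levels = unique(assign)))
}

#' Two-level map-equation codelength of a partition
#'
#' Computes `L = q H(Q) + sum_c p_c H(P_c)` in bits: the expected per-step
#' description length of a random walk under a two-level (index plus
#' per-community) codebook. `q_c` is the community's relative exit weight
#' (cut to the rest over `2W`), `q = sum q_c`, `H(Q)` the entropy of the
#' normalized exit weights, `p_c = q_c + sum of member visit rates`, and
#' `H(P_c)` the entropy of the normalized vector of the exit weight and the
#' member visit rates; `0 log 0 = 0` throughout. For a single community
#' covering the whole graph, `L` equals the entropy of the visit rates.
#'
#' @param g A `backbone_graph` or `agreement_network`.
#' @param partition Tibble with `student_id`, `community` columns, or a
#'   named vector mapping node to community label. Must cover all
#'   non-isolated nodes; communities made only of isolated nodes contribute
#'   zero.
#' @return Codelength in bits (non-negative scalar).
#' @export
map_equation <- function(g, partition) {
  edges <- retained_edges(g)
  vr <- node_visit_rates(g)
  assign <- as_assignment(partition, g$nodes,
                          isolated = vr$student_id[vr$strength == 0])
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  two_w <- 2 * sum(edges$weight)
  ci <- assign[match(edges$from, g$nodes)]
  cj <- assign[match(edges$to, g$nodes)]
  ncomm <- max(assign)
  cut <- numeric(ncomm)
  ext <- ci != cj
  if (any(ext)) {
    cut_tab <- tapply(c(edges$weight[ext], edges$weight[ext]),
                      factor(c(ci[ext], cj[ext]), levels = seq_len(ncomm)),
                      sum, default = 0)
    cut <- as.numeric(cut_tab)
  }
  q_c <- cut / two_w
  p_c <- as.numeric(tapply(vr$visit_rate, factor(assign, levels = seq_len(ncomm)),
                           sum, default = 0))
  q <- sum(q_c)
  index_term <- if (q > 0) -sum(plogp(q_c / q)) * q else 0
  module_terms <- vapply(seq_len(ncomm), function(c) {
    tot <- q_c[c] + p_c[c]
    if (tot <= 0) return(0)
    inner <- c(q_c[c], vr$visit_rate[assign == c])
    tot * (-sum(plogp(inner / tot)))
  }, numeric(1))
  index_term + sum(module_terms)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (s(c)/(2W))^2 ]` with `w_in(c)` the total
#' within-community edge weight, `s(c)` the summed node strength, and `W`
#' the total edge weight. Reported for map-equation partitions as a
#' descriptive statistic; it is never optimized here.
#'
#' @inheritParams map_equation
#' @return Modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(g, partition) {
  edges <- retained_edges(g)
  vr <- node_visit_rates(g)
  assign <- as_assignment(partition, g$nodes,
                          isolated = vr$student_id[vr$strength == 0])
  w_tot <- sum(edges$weight)
  ci <- assign[match(edges$from, g$nodes)]
  cj <- assign[match(edges$to, g$nodes)]
  ncomm <- max(assign)
  w_in <- as.numeric(tapply(edges$weight[ci == cj],
                            factor(ci[ci == cj], levels = seq_len(ncomm)),
                            sum, default = 0))
  s_c <- as.numeric(tapply(vr$strength, factor(assign, levels = seq_len(ncomm)),
                           sum, default = 0))
  sum(w_in / w_tot - (s_c / (2 * w_tot))^2)
}

#' Detect student communities by map-equation minimization
#'
#' Greedy two-phase search (local node moves that decrease the two-level
#' codelength, then community aggregation, repeated to convergence),
#' restarted `n_trials` times with seeded shuffled node orders; the trial
#' with minimal codelength wins and ties keep the first-found partition.
#' Isolated nodes become singleton communities. Deterministic given the
#' graph, `n_trials` and `seed`.
#'
#' @param g A `backbone_graph` (retained edges are used) or
#'   `agreement_network`.
#' @param n_trials Number of seeded restarts (default 100).
#' @param seed RNG seed (default 42).
#' @param tolerance Minimum codelength improvement (bits) to accept a move.
#' @return A `student_partition`: tibble with columns `student_id`,
#'   `community` (integer labels, 1-based, ordered by decreasing community
#'   size), `community_size`, carrying attributes `map_score` (bits),
#'   `modularity` , `n_trials`, `seed`.
#' @export
detect_communities <- function(g, n_trials = 100, seed = 42, tolerance = 1e-10) {
  stopifnot(n_trials >= 1)
  edges <- retained_edges(g)
  if (nrow(edges) == 0L) stop("graph has no edges", call. = FALSE)
  nodes <- g$nodes
  connected <- union(edges$from, edges$to)
  sub_nodes <- nodes[nodes %in% connected]
  idx <- match(edges$from, sub_nodes) - 1L
  jdx <- match(edges$to, sub_nodes) - 1L
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  res <- .mapeq_detect(length(sub_nodes), idx, jdx, as.numeric(edges$weight),
                       as.integer(n_trials), tolerance)
  assign <- integer(length(nodes))
  assign[match(sub_nodes, nodes)] <- res$assign + 1L
  n_sub <- max(res$assign) + 1L
  iso <- assign == 0L
  assign[iso] <- n_sub + seq_len(sum(iso))
  sizes <- table(assign)
  # relabel by decreasing size, ties by first appearance
  ord <- order(-as.numeric(sizes), match(names(sizes), unique(as.character(assign))))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes)[ord])] <- seq_along(ord)
  community <- relabel[assign]
  out <- tibble::tibble(
    student_id = nodes,
    community = community,
    community_size = as.integer(table(community)[as.character(community)])
  )
  structure(out,
            class = c("student_partition", class(out)),
            map_score = res$L,
            modularity = modularity_q(g, out),
            n_trials = n_trials,
            seed = seed)
}

#' @export
print.student_partition <- function(x, ...) {
  cat("<student_partition> ", nrow(x), " students in ",
      length(unique(x$community)), " communities; L = ",
      format(attr(x, "map_score"), digits = 6), " bits, Q = ",
      format(attr(x, "modularity"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Select normative groups (communities of at least `min_size` members)
#'
#' @param partition A `student_partition` or tibble with `student_id`,
#'   `community`.
#' @param min_size Minimum community size (default 10, inclusive).
#' @return Integer vector of community labels with size >= `min_size`,
#'   ordered by decreasing size then label; may be empty.
#' @export
select_normative_groups <- function(partition, min_size = 10) {
  sizes <- table(partition$community)
  keep <- sizes[as.numeric(sizes) >= min_size]
  if (length(keep) == 0L) return(integer(0))
  labs <- as.integer(names(keep))
  labs[order(-as.numeric(keep), labs)]
}

#' Compare two partitions by adjusted Rand index and NMI
#'
#' ARI is the pair-counting Rand index corrected for chance under the
#' permutation model; NMI is mutual information normalized by the mean of
#' the two marginal entropies. Both are invariant to label permutation.
#' When the ARI correction denominator is zero (e.g., both partitions
#' trivial), ARI is 1 if the partitions are identical up to relabeling and
#' 0 otherwise; NMI of two identical one-block partitions is defined as 1.
#'
#' @param p1,p2 `student_partition`s, tibbles with `student_id` and
#'   `community`, or equal-length label vectors over the same node set.
#' @return Tibble with columns `ari`, `nmi`, `n`.
#' @export
compare_partitions <- function(p1, p2) {
  lab <- function(p, ids = NULL) {
    if (is.data.frame(p)) {
      if (!is.null(ids)) p$community[match(ids, p$student_id)] else p$community
    } else p
  }
  if (is.data.frame(p1) && is.data.frame(p2)) {
    ids <- p1$student_id
    if (!setequal(ids, p2$student_id)) {
      stop("partitions cover different node sets", call. = FALSE)
    }
    a <- lab(p1, ids); b <- lab(p2, ids)
  } else {
    a <- lab(p1); b <- lab(p2)
    if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  }
  n <- length(a)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  max_idx <- (ai + bj) / 2
  ari <- if (max_idx == expected) {
    if (nij == max_idx) 1 else 0
  } else {
    (nij - expected) / (max_idx - expected)
  }
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  hx <- -sum(plogp(px)); hy <- -sum(plogp(py))
  mi <- sum(ifelse(pxy > 0, pxy * log(pxy / outer(px, py)), 0))
  nmi <- if (hx + hy == 0) 1 else 2 * mi / (hx + hy)
  tibble::tibble(ari = ari, nmi = nmi, n = n)
}
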