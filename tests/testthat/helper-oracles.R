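# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths: plain loops and
# literal formula transcriptions only.

# Pairwise agreement counting by nested loops over students and questions.
brute_agreement <- function(responses) {
  students <- unique(responses$student_id)
  questions <- unique(responses$question_id)
  n <- length(students)
  choice <- matrix(NA_character_, n, length(questions),
                   dimnames = list(students, questions))
  for (k in seq_len(nrow(responses))) {
    choice[responses$student_id[k], responses$question_id[k]] <-
      responses$choice[k]
  }
  w <- matrix(0, n, n, dimnames = list(students, students))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      for (q in seq_along(questions)) {
        if (!is.na(choice[i, q]) && !is.na(choice[j, q]) &&
            choice[i, q] == choice[j, q]) {
          w[i, j] <- w[i, j] + 1
        }
      }
    }
  }
  w
}

# Per-endpoint empirical-CDF edge significance, evaluated literally.
brute_p_at <- function(edges, node) {
  inc <- edges[edges$from == node | edges$to == node, ]
  strength <- sum(inc$weight)
  vapply(seq_len(nrow(inc)), function(k) {
    f <- inc$weight[k] / strength
    sum(inc$weight / strength > f) / nrow(inc)
  }, numeric(1))
}

brute_backbone <- function(edges, alpha, rule = "either") {
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    pf <- brute_p_at(edges, edges$from[k])
    inc_f <- which(edges$from == edges$from[k] | edges$to == edges$from[k])
    p_from <- pf[which(inc_f == k)]
    pt <- brute_p_at(edges, edges$to[k])
    inc_t <- which(edges$from == edges$to[k] | edges$to == edges$to[k])
    p_to <- pt[which(inc_t == k)]
    keep[k] <- if (rule == "either") {
      p_from < alpha || p_to < alpha
    } else {
      p_from < alpha && p_to < alpha
    }
  }
  keep
}

# Literal transcription of the two-level map equation: L = q H(Q) +
# sum_c p_c^circ H(P_c), all terms spelled out with explicit entropies.
literal_map_equation <- function(edges, nodes, assign) {
  strength <- sapply(nodes, function(v) {
    sum(edges$weight[edges$from == v]) + sum(edges$weight[edges$to == v])
  })
  two_w <- sum(strength)
  p <- strength / two_w
  ent <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0) return(0)
    -sum(x * log2(x))
  }
  comms <- unique(assign)
  q_c <- sapply(comms, function(cc) {
    members <- nodes[assign == cc]
    cut_w <- sum(edges$weight[xor(edges$from %in% members,
                                  edges$to %in% members)])
    cut_w / two_w
  })
  q <- sum(q_c)
  index <- if (q > 0) q * ent(q_c / q) else 0
  mods <- 0
  for (k in seq_along(comms)) {
    members <- nodes[assign == comms[k]]
    p_circ <- q_c[k] + sum(p[members])
    if (p_circ <= 0) next
    inner <- c(q_c[k], p[members]) / p_circ
    mods <- mods + p_circ * ent(inner)
  }
  index + mods
}

# Literal weighted Newman-Girvan modularity.
literal_modularity <- function(edges, nodes, assign) {
  w_tot <- sum(edges$weight)
  strength <- sapply(nodes, function(v) {
    sum(edges$weight[edges$from == v]) + sum(edges$weight[edges$to == v])
  })
  total <- 0
  for (cc in unique(assign)) {
    members <- nodes[assign == cc]
    w_in <- sum(edges$weight[edges$from %in% members & edges$to %in% members])
    s_c <- sum(strength[members])
    total <- total + w_in / w_tot - (s_c / (2 * w_tot))^2
  }
  total
}

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rec(c(prefix, v), max(maxv, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# Random connected-ish weighted graph as an agreement_network-shaped object.
random_network <- function(n, p_edge = 0.5, max_w = 9, seed = 1) {
  withr::local_seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1)] <- TRUE
  edges <- tibble::tibble(
    from = pairs[1, keep],
    to = pairs[2, keep],
    weight = sample.int(max_w, sum(keep), replace = TRUE)
  )
  structure(list(edges = edges, nodes = nodes, n_questions = max_w),
            class = "agreement_network")
}

# Random response tibble with optional missingness.
random_responses <- function(n_students, n_questions, n_options,
                             p_missing = 0, seed = 1) {
  withr::local_seed(seed)
  grid <- expand.grid(
    student_id = sprintf("s%02d", seq_len(n_students)),
    question_id = sprintf("q%d", seq_len(n_questions)),
    stringsAsFactors = FALSE
  )
  grid$choice <- sample(LETTERS[seq_len(n_options)], nrow(grid), replace = TRUE)
  if (p_missing > 0) {
    grid$choice[stats::runif(nrow(grid)) < p_missing] <- NA_character_
  }
  tibble::as_tibble(grid)
}

# Tiny fixed network: weight-5 star edge plus three weight-1 spokes at "a".
star_network <- function() {
  structure(list(
    edges = tibble::tibble(
      from = c("a", "a", "a", "a"),
      to = c("b", "c", "d", "e"),
      weight = c(5, 1, 1, 1)
    ),
    nodes = c("a", "b", "c", "d", "e"),
    n_questions = 9
  ), class = "agreement_network")
}
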