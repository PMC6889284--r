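ring4 <- function() {
  structure(list(
    edges = tibble::tibble(
      from = c("a", "b", "c", "d"),
      to = c("b", "c", "d", "a"),
      weight = 1
    ),
    nodes = letters[1:4], n_questions = 9
  ), class = "agreement_network")
}

two_triangles <- function() {
  # two unit-weight triangles joined by one unit edge
  structure(list(
    edges = tibble::tibble(
      from = c("a", "b", "a", "d", "e", "d", "c"),
      to = c("b", "c", "c", "e", "f", "f", "d"),
      weight = 1
    ),
    nodes = letters[1:6], n_questions = 9
  ), class = "agreement_network")
}

test_that("visit rates are strength-proportional and sum to one", {
  vr <- node_visit_rates(ring4())
  expect_equal(vr$visit_rate, rep(0.25, 4))

  # star: center strength 3, leaves 1, W = 3 -> (1/2, 1/6, 1/6, 1/6)
  st <- structure(list(
    edges = tibble::tibble(from = "a", to = c("b", "c", "d"), weight = 1),
    nodes = letters[1:4], n_questions = 9
  ), class = "agreement_network")
  expect_equal(node_visit_rates(st)$visit_rate, c(1/2, 1/6, 1/6, 1/6))

  for (i in 1:10) {
    net <- random_network(sample(3:10, 1), seed = 40 + i)
    expect_equal(sum(node_visit_rates(net)$visit_rate), 1)
  }
})

test_that("one-module codelength equals the visit-rate entropy exactly", {
  g <- ring4()
  one <- tibble::tibble(student_id = g$nodes, community = 1)
  expect_equal(map_equation(g, one), 2)

  for (i in 1:20) {
    net <- random_network(sample(3:10, 1), seed = 70 + i)
    vr <- node_visit_rates(net)
    p <- vr$visit_rate[vr$visit_rate > 0]
    h <- -sum(p * log2(p))
    one <- tibble::tibble(student_id = net$nodes, community = 1)
    expect_equal(map_equation(net, one), h, tolerance = 1e-12)
  }
})

test_that("codelength matches an independent literal evaluator; good splits win", {
  g <- two_triangles()
  split2 <- tibble::tibble(student_id = g$nodes,
                           community = c(1, 1, 1, 2, 2, 2))
  one <- tibble::tibble(student_id = g$nodes, community = 1)
  l2 <- map_equation(g, split2)
  l1 <- map_equation(g, one)
  expect_equal(l2, literal_map_equation(g$edges, g$nodes, split2$community),
               tolerance = 1e-12)
  expect_equal(l1, literal_map_equation(g$edges, g$nodes, one$community),
               tolerance = 1e-12)
  expect_lt(l2, l1)

  # random graphs, random partitions
  for (i in 1:25) {
    net <- random_network(sample(4:9, 1), seed = 90 + i)
    assign <- sample(1:3, length(net$nodes), replace = TRUE)
    part <- tibble::tibble(student_id = net$nodes, community = assign)
    expect_equal(map_equation(net, part),
                 literal_map_equation(net$edges, net$nodes, assign),
                 tolerance = 1e-12)
  }
})

test_that("modularity matches closed forms and the literal formula", {
  g <- two_triangles()
  one <- tibble::tibble(student_id = g$nodes, community = 1)
  expect_equal(modularity_q(g, one), 0)

  # two disjoint equal cliques split at the components: Q = 1/2
  cliq <- structure(list(
    edges = tibble::tibble(
      from = c("a", "a", "b", "d", "d", "e"),
      to = c("b", "c", "c", "e", "f", "f"),
      weight = 2
    ),
    nodes = letters[1:6], n_questions = 9
  ), class = "agreement_network")
  split <- tibble::tibble(student_id = cliq$nodes,
                          community = c(1, 1, 1, 2, 2, 2))
  expect_equal(modularity_q(cliq, split), 0.5)

  for (i in 1:25) {
    net <- random_network(sample(4:9, 1), seed = 120 + i)
    assign <- sample(1:3, length(net$nodes), replace = TRUE)
    part <- tibble::tibble(student_id = net$nodes, community = assign)
    expect_equal(modularity_q(net, part),
                 literal_modularity(net$edges, net$nodes, assign),
                 tolerance = 1e-12)
  }
})

test_that("modularity agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (i in 1:20) {
    net <- random_network(sample(4:10, 1), seed = 150 + i)
    assign <- sample(1:3, length(net$nodes), replace = TRUE)
    part <- tibble::tibble(student_id = net$nodes, community = assign)
    ig <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                        vertices = net$nodes)
    q_ig <- igraph::modularity(ig, membership = assign,
                               weights = net$edges$weight)
    expect_equal(modularity_q(net, part), q_ig, tolerance = 1e-10)
  }
})

test_that("scores are invariant under relabeling and node reordering", {
  net <- random_network(8, seed = 77)
  assign <- sample(1:3, 8, replace = TRUE)
  part <- tibble::tibble(student_id = net$nodes, community = assign)
  relab <- tibble::tibble(student_id = rev(net$nodes),
                          community = rev(10 - assign))
  expect_equal(map_equation(net, part), map_equation(net, relab))
  expect_equal(modularity_q(net, part), modularity_q(net, relab))
})

test_that("detection separates disconnected cliques and is deterministic", {
  cliq <- structure(list(
    edges = tibble::tibble(
      from = c("a", "a", "a", "b", "b", "c", "e", "e", "e", "f", "f", "g"),
      to = c("b", "c", "d", "c", "d", "d", "f", "g", "h", "g", "h", "h"),
      weight = 1
    ),
    nodes = letters[1:8], n_questions = 9
  ), class = "agreement_network")
  p1 <- detect_communities(cliq, n_trials = 10, seed = 1)
  expect_equal(length(unique(p1$community)), 2L)
  expect_equal(length(unique(p1$community[1:4])), 1L)
  expect_equal(length(unique(p1$community[5:8])), 1L)

  p2 <- detect_communities(cliq, n_trials = 10, seed = 1)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  expect_equal(attr(p1, "map_score"), attr(p2, "map_score"))
})

test_that("detection attains the exhaustive-enumeration optimum on small graphs", {
  for (i in 1:20) {
    n <- sample(4:7, 1)
    net <- random_network(n, p_edge = 0.7, seed = 200 + i)
    pt <- detect_communities(net, n_trials = 30, seed = i)
    best <- Inf
    for (assign in all_partitions(n)) {
      best <- min(best, literal_map_equation(net$edges, net$nodes, assign))
    }
    expect_equal(attr(pt, "map_score"), best, tolerance = 1e-9)
  }
})

test_that("reported codelength and modularity match the standalone scorers", {
  net <- random_network(12, p_edge = 0.5, seed = 321)
  pt <- detect_communities(net, n_trials = 20, seed = 5)
  expect_equal(attr(pt, "map_score"), map_equation(net, pt), tolerance = 1e-10)
  expect_equal(attr(pt, "modularity"), modularity_q(net, pt))
})

test_that("isolated students become singleton communities", {
  r <- tibble::tibble(
    student_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    question_id = rep(c("q1", "q2"), 4),
    choice = c("A", "B", "A", "B", "C", "D", "D", "C")
  )
  net <- project_agreement(r)  # s3, s4 differ from everyone
  pt <- detect_communities(net, n_trials = 5, seed = 2)
  expect_equal(nrow(pt), 4L)
  expect_equal(pt$community_size[pt$student_id %in% c("s3", "s4")], c(1L, 1L))
})

test_that("normative-group selection is a size filter with stable ordering", {
  part <- tibble::tibble(
    student_id = sprintf("s%02d", 1:69),
    community = rep(1:6, c(24, 17, 10, 13, 3, 2))
  )
  expect_equal(select_normative_groups(part, 10), c(1L, 2L, 4L, 3L))

  singles <- tibble::tibble(student_id = c("a", "b"), community = 1:2)
  expect_equal(select_normative_groups(singles, 10), integer(0))

  exact <- tibble::tibble(student_id = sprintf("s%d", 1:10), community = 1)
  expect_equal(select_normative_groups(exact, 10), 1L)
})

test_that("partition comparison follows the contingency-table formulas", {
  p <- tibble::tibble(student_id = letters[1:6], community = c(1, 1, 2, 2, 3, 3))
  expect_equal(compare_partitions(p, p)$ari, 1)
  expect_equal(compare_partitions(p, p)$nmi, 1)

  # all singletons vs one block on n = 4: ARI = 0 by the adjusted formula
  s4 <- tibble::tibble(student_id = letters[1:4], community = 1:4)
  b4 <- tibble::tibble(student_id = letters[1:4], community = rep(1, 4))
  expect_equal(compare_partitions(s4, b4)$ari, 0)

  # label permutation leaves both scores unchanged
  q <- p
  q$community <- c(7, 7, 5, 5, 1, 1)
  expect_equal(compare_partitions(p, q), compare_partitions(p, p))
})

test_that("ARI agrees with mclust's reference implementation", {
  skip_if_not_installed("mclust")
  withr::local_seed(9)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(compare_partitions(a, b)$ari,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
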