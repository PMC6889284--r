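test_that("bipartite incidence encodes choices and missing cells", {
  r1 <- tibble::tibble(student_id = "s1", question_id = "q1", choice = "A")
  m1 <- build_bipartite(r1)
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(unname(m1[1, 1]), 1L)

  r2 <- tibble::tibble(
    student_id = c("s1", "s1"),
    question_id = c("q1", "q2"),
    choice = c("A", NA)
  )
  expect_equal(sum(build_bipartite(r2)[1, ]), 1L)

  # 3x2 toy matrix, verified cell by cell against a nested-loop construction
  r3 <- tibble::tibble(
    student_id = rep(c("s1", "s2", "s3"), each = 2),
    question_id = rep(c("q1", "q2"), 3),
    choice = c("A", "B", "A", "C", "D", "B")
  )
  m3 <- build_bipartite(r3)
  for (s in c("s1", "s2", "s3")) {
    for (col in colnames(m3)) {
      q <- sub("::.*", "", col)
      opt <- sub(".*::", "", col)
      chosen <- r3$choice[r3$student_id == s & r3$question_id == q]
      expect_identical(m3[s, col], as.integer(identical(chosen, opt)))
    }
  }
  expect_equal(unname(rowSums(m3)), c(2L, 2L, 2L))
})

test_that("agreement projection matches brute-force pairwise counting", {
  r <- tibble::tibble(
    student_id = rep(c("s1", "s2", "s3"), each = 2),
    question_id = rep(c("q1", "q2"), 3),
    choice = c("A", "B", "A", "C", "D", "B")
  )
  net <- project_agreement(r)
  w <- function(a, b) {
    e <- net$edges[(net$edges$from == a & net$edges$to == b) |
                     (net$edges$from == b & net$edges$to == a), ]
    if (nrow(e) == 0) 0 else e$weight
  }
  expect_equal(w("s1", "s2"), 1)
  expect_equal(w("s1", "s3"), 1)
  expect_equal(w("s2", "s3"), 0)
  expect_equal(net$n_questions, 2L)
})

test_that("identical answers give the complete graph at the weight ceiling; loners are isolates", {
  r <- tibble::tibble(
    student_id = rep(sprintf("s%d", 1:4), each = 3),
    question_id = rep(sprintf("q%d", 1:3), 4),
    choice = rep(c("A", "B", "C"), 4)
  )
  net <- project_agreement(r)
  expect_equal(nrow(net$edges), choose(4, 2))
  expect_true(all(net$edges$weight == 3))

  # s3 shares nothing: isolated node, still listed
  r$choice[r$student_id == "s3"] <- c("D", "D", "D")
  net2 <- project_agreement(r)
  expect_false("s3" %in% c(net2$edges$from, net2$edges$to))
  expect_true("s3" %in% net2$nodes)

  expect_error(project_agreement(r[r$student_id == "s1", ]), "at least 2")
})

test_that("projection equals the nested-loop oracle on random response matrices", {
  for (i in 1:200) {
    ns <- sample(2:12, 1)
    nq <- sample(1:9, 1)
    no <- sample(2:5, 1)
    r <- random_responses(ns, nq, no, p_missing = 0.15, seed = 10000 + i)
    net <- project_agreement(r)
    w_oracle <- brute_agreement(r)
    students <- net$nodes
    w_pkg <- matrix(0, length(students), length(students),
                    dimnames = list(students, students))
    for (k in seq_len(nrow(net$edges))) {
      w_pkg[net$edges$from[k], net$edges$to[k]] <- net$edges$weight[k]
      w_pkg[net$edges$to[k], net$edges$from[k]] <- net$edges$weight[k]
    }
    expect_identical(w_pkg, w_oracle[students, students])
    expect_true(all(net$edges$weight <= nq))
  }
})

test_that("weight hits the number of questions exactly when responses are identical", {
  for (i in 1:25) {
    r <- random_responses(5, 9, 4, p_missing = 0.1, seed = 300 + i)
    net <- project_agreement(r)
    expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 9))
    wide <- tidyr::pivot_wider(r, names_from = "question_id",
                               values_from = "choice")
    for (k in seq_len(nrow(net$edges))) {
      ident <- identical(
        unlist(wide[wide$student_id == net$edges$from[k], -1]),
        unlist(wide[wide$student_id == net$edges$to[k], -1])
      )
      no_missing <- !anyNA(wide[wide$student_id == net$edges$from[k], -1])
      expect_equal(net$edges$weight[k] == 9, ident && no_missing)
    }
  }
})

test_that("edge significance follows the per-node empirical CDF with ties at zero", {
  # node with incident weights [5,1,1,1]: p-values 0, .25, .25, .25 at hub
  st <- star_network()
  e <- edge_significance(st)
  expect_equal(e$p_from, c(0, 0.25, 0.25, 0.25))
  # each leaf has a single incident edge: p = 0
  expect_equal(e$p_to, rep(0, 4))

  # all-equal incident weights saturate to p = 0 everywhere
  eq <- st
  eq$edges$weight <- rep(2, 4)
  e_eq <- edge_significance(eq)
  expect_true(all(e_eq$p_from == 0) && all(e_eq$p_to == 0))

  # scale invariance of fractional weights
  sc <- st
  sc$edges$weight <- sc$edges$weight * 10
  e_sc <- edge_significance(sc)
  expect_equal(e_sc$p_from, e$p_from)
  expect_equal(e_sc$p_to, e$p_to)
})

test_that("endpoint rules behave as stated on the star example", {
  st <- star_network()
  # leaves have p = 0, so either-endpoint keeps all four edges at alpha = .01
  bb_either <- lans_backbone(st, alpha = 0.01, rule = "either")
  expect_true(all(bb_either$edges$retained))
  # both-endpoints keeps only the weight-5 edge
  bb_both <- lans_backbone(st, alpha = 0.01, rule = "both")
  expect_equal(bb_both$edges$retained, c(TRUE, FALSE, FALSE, FALSE))

  # complete equal-weight graph: every p-value 0, backbone = graph
  cg <- structure(list(
    edges = tibble::tibble(
      from = utils::combn(letters[1:4], 2)[1, ],
      to = utils::combn(letters[1:4], 2)[2, ],
      weight = 3
    ),
    nodes = letters[1:4], n_questions = 9
  ), class = "agreement_network")
  expect_true(all(lans_backbone(cg, alpha = 0.001)$edges$retained))
})

test_that("backbone matches the brute-force evaluator and is monotone in alpha", {
  for (i in 1:100) {
    net <- random_network(sample(4:15, 1), p_edge = 0.6, seed = 600 + i)
    alpha <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
    for (rule in c("either", "both")) {
      bb <- lans_backbone(net, alpha = alpha, rule = rule)
      expect_equal(bb$edges$retained, brute_backbone(net$edges, alpha, rule))
    }
    # nesting: retained(alpha1) subset of retained(alpha2) for alpha1 <= alpha2
    r1 <- lans_backbone(net, alpha = 0.05)$edges$retained
    r2 <- lans_backbone(net, alpha = 0.3)$edges$retained
    expect_true(all(!r1 | r2))
    # sparsification never creates edges and never modifies weights
    expect_equal(bb$edges$weight, net$edges$weight)
    expect_equal(bb$edges[c("from", "to")], net$edges[c("from", "to")])
  }
})

test_that("network serialization keeps isolates and round-trips edges", {
  r <- tibble::tibble(
    student_id = rep(c("s1", "s2", "s3"), each = 2),
    question_id = rep(c("q1", "q2"), 3),
    choice = c("A", "B", "A", "B", "C", "D")
  )
  bb <- lans_backbone(project_agreement(r))
  td <- withr::local_tempdir()
  path <- file.path(td, "edges.csv")
  write_network(bb, path)
  edges <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(edges, c("source", "target", "weight",
                        "pvalue_src", "pvalue_tgt", "retained"))
  nodes <- readr::read_csv(file.path(td, "edges_nodes.csv"),
                           show_col_types = FALSE)
  expect_true("s3" %in% nodes$student_id)
})
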