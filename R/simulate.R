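#' Simulation configuration with planted group structure
#'
#' Describes a synthetic cohort: groups of students with a shared
#' probability of answering correctly and a shared preference over
#' conceptual modules for their incorrect answers. The default population
#' emulates the in-scanner study scale this package targets: 107 students
#' answering 9 four-option questions, organized as 13 planted groups —
#' three target normative groups of 24, 17 and 10 students with accuracy
#' rates 0.77, 0.73 and 0.53 and distinct dominant-module sets (one
#' coherent, one two-module, one fragmented five-module profile), a fourth
#' normative group of 12 with inflated head motion, and nine small
#' background groups (4–6 students, accuracy 0.50) each organized around
#' its own module pair. Mean planted accuracy is ~0.61. Head motion
#' defaults to ~0.15 mm mean framewise displacement (SD 0.05, 3 runs per
#' student) with the motion-inflated group at +0.2 mm.
#'
#' @param groups Tibble with columns `group`, `size`, `p_correct`,
#'   `modules` (list column of preferred module IDs), `concentration`
#'   (total weight on the preferred modules; the remainder is spread
#'   uniformly over the others), `n_hard` (number of hard questions, see
#'   below; `NA` for uniform difficulty), `fd_mean`, `fd_sd`.
#' @param n_questions,n_options,n_modules Assessment geometry.
#' @param difficulty_ratio Odds ratio of the per-question error rate on a
#'   group's hard questions versus its easy ones (default 40; 1 gives
#'   uniform difficulty). A group's hard questions are the first `n_hard`
#'   questions covered by its dominant modules: students holding a
#'   misconception consistently miss the questions probing it, so errors
#'   concentrate there. Per-question error rates are scaled so the group
#'   mean accuracy equals `p_correct` exactly in expectation.
#' @param runs_per_student Motion runs per student.
#' @return A `sim_config` list.
#' @export
sim_config <- function(groups = default_groups(),
                       n_questions = 9, n_options = 4, n_modules = 9,
                       difficulty_ratio = 40, runs_per_student = 3) {
  stopifnot(is.data.frame(groups),
            all(c("group", "size", "p_correct", "modules", "concentration",
                  "fd_mean", "fd_sd") %in% names(groups)),
            all(groups$size >= 1),
            all(groups$p_correct >= 0 & groups$p_correct <= 1),
            n_options >= 2, difficulty_ratio >= 1)
  groups <- tibble::as_tibble(groups)
  if (!"n_hard" %in% names(groups)) groups$n_hard <- NA_integer_
  structure(list(groups = groups,
                 n_questions = n_questions, n_options = n_options,
                 n_modules = n_modules, difficulty_ratio = difficulty_ratio,
                 runs_per_student = runs_per_student),
            class = "sim_config")
}

#' Default planted population
#'
#' @return The default `groups` tibble used by [sim_config()]; see that
#'   help page for the rationale.
#' @export
default_groups <- function() {
  small_sizes <- c(6L, 6L, 6L, 6L, 5L, 5L, 5L, 5L)
  # background groups carry one signature module each (m2..m9, avoiding m1,
  # Group A's module, so their wrong answers do not collide with the
  # coherent group's)
  small_mods <- as.list(paste0("m", 2:9))
  tibble::tibble(
    group = c("A", "B", "C", "D", paste0("bg", 1:8)),
    size = c(24L, 17L, 10L, 12L, small_sizes),
    p_correct = c(0.77, 0.73, 0.53, 0.60, rep(0.50, 8)),
    modules = c(
      list("m1"),
      list(c("m3", "m9")),
      list(c("m2", "m5", "m8")),
      list(c("m4", "m6")),
      small_mods
    ),
    concentration = 0.9,
    n_hard = c(2L, 2L, 4L, 3L, rep(4L, 8)),
    fd_mean = c(0.15, 0.15, 0.15, 0.35, rep(0.15, 8)),
    fd_sd = 0.05
  )
}

#' Simulate an answer key and conceptual-module catalog
#'
#' Draws one correct option per question, then partitions the incorrect
#' (question, option) pairs among `n_modules` modules so that every module
#' appears on at least two distinct questions (modules are cross-question
#' constructs). With the default geometry (9 questions x 4 options, 9
#' modules) each module receives 3 pairs on 3 distinct questions.
#' Deterministic per seed.
#'
#' @param config A `sim_config`.
#' @param seed Integer RNG seed.
#' @return List with `key` (answer-key tibble) and `catalog` (validated
#'   catalog tibble).
#' @export
simulate_catalog <- function(config, seed = 1) {
  nq <- config$n_questions; no <- config$n_options; nm <- config$n_modules
  total_pairs <- nq * (no - 1)
  if (nm > total_pairs / 2) {
    stop("infeasible: ", nm, " modules need at least 2 pairs each but only ",
         total_pairs, " incorrect pairs exist", call. = FALSE)
  }
  withr::local_seed(seed)
  questions <- sprintf("q%d", seq_len(nq))
  options <- LETTERS[seq_len(no)]
  key <- tibble::tibble(
    question_id = questions,
    correct = sample(options, nq, replace = TRUE)
  )
  # per-question stacks of shuffled incorrect options
  slots <- purrr::map(seq_len(nq), function(q) {
    sample(setdiff(options, key$correct[q]))
  })
  remaining <- vapply(slots, length, integer(1))
  quota <- rep(total_pairs %/% nm, nm)
  extra <- total_pairs %% nm
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  assign_rows <- list()
  for (m in sample(seq_len(nm))) {
    used_q <- integer(0)
    for (k in seq_len(quota[m])) {
      # pick the eligible question with most remaining slots (seeded tie-break)
      elig <- setdiff(which(remaining > 0), used_q)
      if (length(elig) == 0L) stop("catalog allocation failed", call. = FALSE)
      elig <- elig[sample.int(length(elig))]
      q <- elig[which.max(remaining[elig])]
      opt <- slots[[q]][remaining[q]]
      remaining[q] <- remaining[q] - 1L
      used_q <- c(used_q, q)
      assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
        module_id = sprintf("m%d", m),
        question_id = questions[q],
        option = opt
      )
    }
  }
  catalog <- dplyr::bind_rows(assign_rows)
  catalog <- dplyr::arrange(catalog,
                            as.integer(sub("m", "", .data$module_id)),
                            match(.data$question_id, questions))
  catalog$module_name <- catalog$module_id
  list(key = key, catalog = validate_catalog(catalog, key))
}

# Assign each group its hard-question set: n_hard questions drawn from the
# coverage of its dominant modules. Larger groups choose first; later groups
# prefer questions whose (question, option) claims are least contested, so
# groups sharing a module end up missing different questions where possible.
# Deterministic given (groups, catalog).
allocate_hard_questions <- function(grp, catalog, questions) {
  claims <- stats::setNames(
    rep(0L, nrow(catalog)),
    paste(catalog$question_id, catalog$option, sep = "\r")
  )
  ext_claims <- stats::setNames(rep(0L, length(questions)), questions)
  out <- stats::setNames(vector("list", nrow(grp)), grp$group)
  for (gi in order(-grp$size, seq_len(nrow(grp)))) {
    n_hard <- grp$n_hard[gi]
    empty <- tibble::tibble(question_id = character(0),
                            option = character(0), module_id = character(0))
    if (is.na(n_hard)) { out[[grp$group[gi]]] <- empty; next }
    cov <- catalog[catalog$module_id %in% grp$modules[[gi]], ]
    if (nrow(cov) == 0L) { out[[grp$group[gi]]] <- empty; next }
    picked <- character(0)
    picked_rows <- list()
    mod_use <- stats::setNames(rep(0L, length(grp$modules[[gi]])),
                               grp$modules[[gi]])
    # iterate: unclaimed module questions first, then uncontested questions
    # outside the coverage, then contested module questions; round-robin
    # across the group's modules, question order as the final tie-break
    for (k in seq_len(min(n_hard, length(questions)))) {
      cand <- cov[!(cov$question_id %in% picked), ]
      rest <- setdiff(questions, union(picked, cand$question_id))
      cand_score <- if (nrow(cand) > 0L) {
        as.numeric(claims[paste(cand$question_id, cand$option, sep = "\r")])
      } else numeric(0)
      rest_score <- vapply(rest, function(q) {
        ks <- paste(q, catalog$option[catalog$question_id == q], sep = "\r")
        0.75 + 0.5 * sum(claims[ks]) + ext_claims[q]
      }, numeric(1))
      pool <- tibble::tibble(
        question_id = c(cand$question_id, rest),
        option = c(cand$option, rep(NA_character_, length(rest))),
        module_id = c(cand$module_id, rep(NA_character_, length(rest))),
        score = c(cand_score, unname(rest_score)),
        use = c(if (nrow(cand) > 0L) mod_use[cand$module_id] else integer(0),
                rep(length(questions), length(rest)))
      )
      if (nrow(pool) == 0L) break
      best <- pool[order(pool$score, pool$use,
                         match(pool$question_id, questions)), ][1, ]
      picked <- c(picked, best$question_id)
      picked_rows[[k]] <- best[c("question_id", "option", "module_id")]
      if (!is.na(best$option)) {
        kk <- paste(best$question_id, best$option, sep = "\r")
        claims[kk] <- claims[kk] + 1L
        mod_use[best$module_id] <- mod_use[best$module_id] + 1L
      } else {
        ext_claims[best$question_id] <- ext_claims[best$question_id] + 1L
      }
    }
    out[[grp$group[gi]]] <- dplyr::bind_rows(picked_rows)
  }
  out
}

#' Simulate student responses with planted group structure
#'
#' Per student and question: answer correctly with probability
#' `1 - e[group, question]`, where the per-question error rates average to
#' `1 - p_correct` for the group and are concentrated (by
#' `difficulty_ratio`) on the group's hard questions — the ones its
#' dominant modules cover. An incorrect answer draws a module from the
#' group's weight vector restricted to the modules present on that
#' question (renormalized), then an option uniformly within that module's
#' options on the question. If no module covers the question the incorrect
#' option is uniform with attribution `"unaffiliated"`. Group similarity
#' is induced solely through shared correct answers and shared module
#' preferences — no copying between students. Deterministic per seed.
#'
#' @param config A `sim_config`.
#' @param key,catalog From [simulate_catalog()] (or user-supplied).
#' @param seed Integer RNG seed.
#' @return List with `responses` (response tibble), `truth` (list:
#'   `groups` tibble `student_id`/`group`, `attribution` tibble per
#'   response, `config` echo).
#' @export
simulate_responses <- function(config, key, catalog, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed + 1L)
  questions <- key$question_id
  module_ids <- sprintf("m%d", seq_len(config$n_modules))
  # options per (question, module)
  mod_opts <- purrr::map(questions, function(q) {
    sub <- catalog[catalog$question_id == q, ]
    split(sub$option, factor(sub$module_id, levels = module_ids))
  })
  names(mod_opts) <- questions
  all_opts <- LETTERS[seq_len(config$n_options)]

  grp <- config$groups
  students <- sprintf("s%03d", seq_len(sum(grp$size)))
  group_of <- rep(grp$group, grp$size)

  weight_vec <- function(gi) {
    mods <- grp$modules[[gi]]
    conc <- grp$concentration[gi]
    w <- stats::setNames(rep(0, length(module_ids)), module_ids)
    mods <- intersect(mods, module_ids)
    others <- setdiff(module_ids, mods)
    if (length(mods) > 0) w[mods] <- conc / length(mods)
    if (length(others) > 0) w[others] <- (1 - conc) / length(others)
    w / sum(w)
  }
  weights <- purrr::map(seq_len(nrow(grp)), weight_vec)
  names(weights) <- grp$group

  # per-group per-question error rates: mean 1 - p_correct, concentrated on
  # n_hard questions covered by the group's dominant modules; hard-question
  # sets are allocated collision-aware so that two groups sharing a module
  # overlap on as few (question, option) hard claims as possible
  ratio <- config$difficulty_ratio %||% 1
  hard_sets <- allocate_hard_questions(grp, catalog, questions)
  err_rates <- purrr::map(seq_len(nrow(grp)), function(gi) {
    e_bar <- 1 - grp$p_correct[gi]
    nq <- length(questions)
    n_hard <- grp$n_hard[gi]
    if (is.na(n_hard) || ratio == 1 || e_bar == 0) {
      return(stats::setNames(rep(e_bar, nq), questions))
    }
    hard <- hard_sets[[grp$group[gi]]]$question_id
    if (length(hard) == 0L) {
      return(stats::setNames(rep(e_bar, nq), questions))
    }
    nh <- length(hard)
    e_hard <- e_bar * nq / (nh + (nq - nh) / ratio)
    if (e_hard > 0.97) e_hard <- 0.97
    e_easy <- if (nq > nh) (e_bar * nq - nh * e_hard) / (nq - nh) else e_hard
    e <- stats::setNames(rep(e_easy, nq), questions)
    e[hard] <- e_hard
    pmin(pmax(e, 0), 1)
  })
  names(err_rates) <- grp$group

  # per-group, per-hard-question claimed module: the misconception the group
  # expresses on that question, receiving the concentration mass outright
  claimed <- purrr::map(seq_len(nrow(grp)), function(gi) {
    hs <- hard_sets[[grp$group[gi]]]
    hs <- hs[!is.na(hs$module_id), ]
    stats::setNames(as.list(hs$module_id), hs$question_id)
  })
  names(claimed) <- grp$group
  conc_of <- stats::setNames(grp$concentration, grp$group)

  rows <- vector("list", length(students) * length(questions))
  k <- 0L
  for (si in seq_along(students)) {
    g <- group_of[si]
    w <- weights[[g]]
    e_q <- err_rates[[g]]
    for (q in questions) {
      k <- k + 1L
      correct_opt <- key$correct[key$question_id == q]
      if (stats::runif(1) >= e_q[[q]]) {
        rows[[k]] <- list(student_id = students[si], question_id = q,
                          choice = correct_opt, outcome = "correct")
      } else {
        present <- names(mod_opts[[q]])[lengths(mod_opts[[q]]) > 0]
        wq <- w[present]
        cm <- claimed[[g]][[q]]
        if (!is.null(cm) && cm %in% present) {
          # the group's misconception on this question is the claimed module:
          # all dominant-module mass moves there, background mass unchanged
          wq[names(wq) %in% grp$modules[[match(g, grp$group)]]] <- 0
          wq[cm] <- conc_of[[g]]
        }
        if (length(present) == 0L || sum(wq) <= 0) {
          opt <- sample(setdiff(all_opts, correct_opt), 1)
          rows[[k]] <- list(student_id = students[si], question_id = q,
                            choice = opt, outcome = "unaffiliated")
        } else {
          m <- sample(present, 1, prob = wq / sum(wq))
          opts <- mod_opts[[q]][[m]]
          opt <- opts[sample.int(length(opts), 1)]
          rows[[k]] <- list(student_id = students[si], question_id = q,
                            choice = opt, outcome = m)
        }
      }
    }
  }
  attribution <- dplyr::bind_rows(rows)
  responses <- as_responses(attribution[c("student_id", "question_id", "choice")])
  truth <- list(
    groups = tibble::tibble(student_id = students, group = group_of),
    attribution = tibble::as_tibble(attribution),
    config = config
  )
  list(responses = responses, truth = truth)
}

#' Simulate per-run head motion
#'
#' Framewise displacement per run is Normal(group mean, group sd) truncated
#' at zero (negative draws are redrawn). Deterministic per seed.
#'
#' @param config A `sim_config`.
#' @param truth Planted truth from [simulate_responses()].
#' @param seed Integer RNG seed.
#' @return Motion tibble (`student_id`, `run_id`, `mean_fd_mm`).
#' @export
simulate_motion <- function(config, truth, seed = 1) {
  withr::local_seed(seed + 2L)
  grp <- config$groups
  g_of <- truth$groups
  rows <- purrr::map_dfr(seq_len(nrow(g_of)), function(i) {
    g <- grp[grp$group == g_of$group[i], ]
    fd <- stats::rnorm(config$runs_per_student, g$fd_mean, g$fd_sd)
    while (any(fd < 0)) {
      fd[fd < 0] <- stats::rnorm(sum(fd < 0), g$fd_mean, g$fd_sd)
    }
    tibble::tibble(
      student_id = g_of$student_id[i],
      run_id = sprintf("r%d", seq_len(config$runs_per_student)),
      mean_fd_mm = fd
    )
  })
  validate_motion(rows)
}

#' Score recovery of the planted structure
#'
#' @param truth Planted truth from [simulate_responses()].
#' @param partition Inferred `student_partition`.
#' @param profiles Optional `group_profiles` for the inferred normative
#'   groups; if given, each planted normative group is matched to the
#'   inferred community with maximal member overlap and the profile's share
#'   vector is compared to the planted module weights by cosine similarity.
#' @param key,catalog Needed with `profiles` to score accuracy errors.
#' @return List with `scores` (one-row tibble: `ari`, `nmi`) and, when
#'   profiles are supplied, `matches` (tibble per planted normative group:
#'   matched community, overlap, planted vs recovered accuracy and its
#'   binomial SE, cosine similarity of module profiles).
#' @export
recovery_report <- function(truth, partition, profiles = NULL,
                            key = NULL, catalog = NULL) {
  planted <- truth$groups
  stopifnot(setequal(planted$student_id, partition$student_id))
  scores <- compare_partitions(
    tibble::tibble(student_id = planted$student_id, community = planted$group),
    partition
  )[c("ari", "nmi")]
  out <- list(scores = scores)
  if (!is.null(profiles)) {
    cfg <- truth$config
    norm_groups <- cfg$groups[cfg$groups$size >= 10, ]
    matches <- purrr::map_dfr(norm_groups$group, function(g) {
      members <- planted$student_id[planted$group == g]
      comm <- partition$community[match(members, partition$student_id)]
      best <- as.integer(names(which.max(table(comm))))
      overlap <- mean(comm == best)
      grow <- profiles$groups[profiles$groups$group_id == best, ]
      prow <- profiles$profiles[profiles$profiles$group_id == best, ]
      p_planted <- norm_groups$p_correct[norm_groups$group == g]
      n_resp <- length(members) * cfg$n_questions
      cosine <- NA_real_
      if (nrow(prow) > 0) {
        w <- stats::setNames(rep(0, nrow(prow)), prow$module_id)
        mods <- intersect(norm_groups$modules[[match(g, norm_groups$group)]],
                          names(w))
        conc <- norm_groups$concentration[norm_groups$group == g]
        if (length(mods) > 0) w[mods] <- conc / length(mods)
        others <- setdiff(names(w), mods)
        if (length(others) > 0) w[others] <- (1 - conc) / length(others)
        s <- prow$share[match(names(w), prow$module_id)]
        if (sum(s) > 0 && sum(w) > 0) {
          cosine <- sum(s * w) / sqrt(sum(s^2) * sum(w^2))
        }
      }
      tibble::tibble(
        group = g,
        matched_community = best,
        member_overlap = overlap,
        planted_accuracy = p_planted,
        recovered_accuracy = if (nrow(grow) > 0) grow$accuracy else NA_real_,
        accuracy_se = sqrt(p_planted * (1 - p_planted) / n_resp),
        profile_cosine = cosine
      )
    })
    out$matches <- matches
  }
  out
}
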