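#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition via [stats::aov()],
#' returned tidily. The all-identical-observations case is reported as
#' `f = 0, p = 1` (no between-group signal), and zero within-group variance
#' with unequal means as `p = 0` with a `degenerate` flag.
#'
#' @param data Data frame with one value per row.
#' @param value,group Column names (strings) of the numeric response and the
#'   grouping label.
#' @return One-row tibble: `f`, `df_between`, `df_within`, `p_value`,
#'   `degenerate`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  gl <- factor(data[[group]])
  if (nlevels(gl) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(v) <= nlevels(gl)) stop("need total n > number of groups", call. = FALSE)
  df_b <- nlevels(gl) - 1L
  df_w <- length(v) - nlevels(gl)
  ssb <- sum(tapply(v, gl, function(x) length(x) * (mean(x) - mean(v))^2))
  ssw <- sum(tapply(v, gl, function(x) sum((x - mean(x))^2)))
  if (ssw == 0 && ssb == 0) {
    return(tibble::tibble(f = 0, df_between = df_b, df_within = df_w,
                          p_value = 1, degenerate = FALSE))
  }
  if (ssw == 0) {
    return(tibble::tibble(f = Inf, df_between = df_b, df_within = df_w,
                          p_value = 0, degenerate = TRUE))
  }
  fit <- stats::anova(stats::aov(v ~ gl))
  tibble::tibble(
    f = fit$`F value`[1],
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    p_value = fit$`Pr(>F)`[1],
    degenerate = FALSE
  )
}

#' Tukey honest significant difference comparisons
#'
#' Tukey-Kramer pairwise comparisons from the one-way ANOVA decomposition:
#' for groups i, j the studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt((MSW / 2) (1/n_i + 1/n_j))` with the
#' adjusted p from the studentized range distribution on (k, df_within).
#' For two balanced groups, `q = sqrt(2) |t|`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Tibble, one row per group pair: `group_a`, `group_b`,
#'   `mean_diff` (a - b), `q`, `p_adj`, `significant`; plus attribute
#'   `greater_than_all`: group labels whose mean is significantly greater
#'   than every other group's.
#' @export
tukey_hsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  v <- data[[value]]
  gl <- factor(data[[group]])
  k <- nlevels(gl)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_g <- tapply(v, gl, length)
  m_g <- tapply(v, gl, mean)
  df_w <- length(v) - k
  msw <- sum(tapply(v, gl, function(x) sum((x - mean(x))^2))) / df_w
  pairs <- utils::combn(levels(gl), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- m_g[[a]] - m_g[[b]]
    se <- sqrt((msw / 2) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    }
    tibble::tibble(group_a = a, group_b = b, mean_diff = unname(diff),
                   q = unname(q), p_adj = p, significant = p < alpha)
  })
  greater <- purrr::keep(levels(gl), function(g) {
    rows <- out[out$group_a == g | out$group_b == g, ]
    all(rows$significant) &&
      all(ifelse(rows$group_a == g, rows$mean_diff > 0, rows$mean_diff < 0))
  })
  structure(out, greater_than_all = unlist(greater) %||% character(0))
}

#' Screen normative groups for head-motion confounds
#'
#' Runs a one-way ANOVA of per-run framewise displacement across the given
#' groups; while the omnibus test is significant, excludes every group that
#' Tukey HSD flags as having significantly greater FD than each remaining
#' group, then re-tests, stopping when the omnibus test is non-significant
#' or two groups remain. A single pass equals the iterated rule when only
#' one group is motion-inflated.
#'
#' @param partition `student_partition` (or tibble with `student_id`,
#'   `community`).
#' @param motion Motion tibble (`student_id`, `run_id`, `mean_fd_mm`).
#' @param groups Community labels to screen; defaults to normative groups
#'   (size >= `min_size`).
#' @param alpha Significance level for both the omnibus and post hoc tests.
#' @param min_size Normative-group threshold used when `groups` is `NULL`.
#' @return A list with `retained` (community labels), `excluded`, and
#'   `report` (tibble audit trail: one row per iteration with `f`,
#'   `p_value`, groups tested and excluded).
#' @export
screen_groups_motion <- function(partition, motion, groups = NULL,
                                 alpha = 0.05, min_size = 10) {
  motion <- validate_motion(motion)
  if (is.null(groups)) groups <- select_normative_groups(partition, min_size)
  if (length(groups) < 2L) {
    return(list(retained = groups, excluded = integer(0),
                report = tibble::tibble()))
  }
  fd <- dplyr::inner_join(
    motion,
    partition[partition$community %in% groups, c("student_id", "community")],
    by = "student_id"
  )
  no_rows <- setdiff(groups, unique(fd$community))
  if (length(no_rows) > 0L) {
    stop("group(s) with no motion rows: ", paste(no_rows, collapse = ", "),
         call. = FALSE)
  }
  current <- groups
  excluded <- c()
  report <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sub <- fd[fd$community %in% current, ]
    aov_res <- one_way_anova(sub, "mean_fd_mm", "community")
    drop <- integer(0)
    if (aov_res$p_value < alpha && length(current) > 2L) {
      tk <- tukey_hsd(sub, "mean_fd_mm", "community", alpha = alpha)
      drop <- as.integer(attr(tk, "greater_than_all"))
    }
    report[[iter]] <- tibble::tibble(
      iteration = iter,
      groups_tested = paste(current, collapse = ","),
      f = aov_res$f, df_between = aov_res$df_between,
      df_within = aov_res$df_within, p_value = aov_res$p_value,
      excluded = paste(drop, collapse = ",")
    )
    if (length(drop) == 0L) break
    excluded <- c(excluded, drop)
    current <- setdiff(current, drop)
    if (length(current) <= 2L) break
  }
  list(retained = current, excluded = as.integer(excluded),
       report = dplyr::bind_rows(report))
}
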