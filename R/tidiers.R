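#' Tidy an agreement network or backbone into its edge table
#'
#' @param x An `agreement_network` or `backbone_graph`.
#' @param ... Unused.
#' @return The edge tibble (with significance columns for a backbone).
#' @export
tidy.agreement_network <- function(x, ...) x$edges

#' @rdname tidy.agreement_network
#' @export
tidy.backbone_graph <- function(x, ...) x$edges

#' One-row summaries of network objects
#'
#' @param x An `agreement_network`, `backbone_graph`, `student_partition`
#'   or `group_profiles` object.
#' @param ... Unused.
#' @return A one-row tibble of summary statistics.
#' @export
glance.agreement_network <- function(x, ...) {
  tibble::tibble(
    n_students = length(x$nodes),
    n_edges = nrow(x$edges),
    n_questions = x$n_questions,
    mean_weight = mean(x$edges$weight),
    max_weight = max(x$edges$weight)
  )
}

#' @rdname glance.agreement_network
#' @export
glance.backbone_graph <- function(x, ...) {
  tibble::tibble(
    n_students = length(x$nodes),
    n_edges = nrow(x$edges),
    n_retained = sum(x$edges$retained),
    alpha = x$alpha,
    rule = x$rule
  )
}

#' @rdname glance.agreement_network
#' @export
glance.student_partition <- function(x, ...) {
  tibble::tibble(
    n_students = nrow(x),
    n_communities = length(unique(x$community)),
    map_score_bits = attr(x, "map_score"),
    modularity_q = attr(x, "modularity"),
    n_trials = attr(x, "n_trials"),
    seed = attr(x, "seed")
  )
}

#' @rdname glance.agreement_network
#' @export
glance.group_profiles <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    mean_accuracy = mean(x$groups$accuracy),
    total_incorrect = sum(x$groups$n_incorrect)
  )
}

#' Tidy a partition into its assignment table
#'
#' @param x A `student_partition`.
#' @param ... Unused.
#' @return Tibble with `student_id`, `community`, `community_size`.
#' @export
tidy.student_partition <- function(x, ...) tibble::as_tibble(x)

#' Tidy group profiles into the long per-(group, module) table
#'
#' @param x A `group_profiles` object.
#' @param ... Unused.
#' @return Tibble with one row per group x module.
#' @export
tidy.group_profiles <- function(x, ...) x$profiles

#' Heat map of responses ordered by community
#'
#' Students (rows) are sorted by community then ID; tiles are colored by
#' chosen option, with community boundaries drawn as horizontal lines —
#' groups of similarly-answering students appear as horizontal bands of
#' matching color.
#'
#' @param object A `student_partition`.
#' @param responses The response tibble that the partition was derived
#'   from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.student_partition <- function(object, responses, ...) {
  responses <- as_responses(responses)
  ord <- order(object$community, object$student_id)
  lev <- object$student_id[ord]
  df <- dplyr::mutate(
    responses,
    student = factor(.data$student_id, levels = rev(lev)),
    question = factor(.data$question_id, levels = unique(.data$question_id))
  )
  boundaries <- cumsum(rev(as.numeric(table(object$community[ord])))) + 0.5
  ggplot2::ggplot(df, ggplot2::aes(x = .data$question, y = .data$student,
                                   fill = .data$choice)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = utils::head(boundaries, -1),
                        linewidth = 0.4) +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey90") +
    ggplot2::labs(x = "Question", y = "Student", fill = "Choice") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Bar chart of per-group module overlap profiles
#'
#' @param object A `group_profiles` object.
#' @param metric `"scaled_overlap"` (incorrect responses per student,
#'   default) or `"share"` (fraction of the group's incorrect responses).
#' @param ... Unused.
#' @return A ggplot object, one facet per group.
#' @export
autoplot.group_profiles <- function(object,
                                    metric = c("scaled_overlap", "share"),
                                    ...) {
  metric <- match.arg(metric)
  df <- dplyr::mutate(
    object$profiles,
    module = factor(.data$module_id, levels = unique(.data$module_id))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group_id, ncol = 1) +
    ggplot2::labs(x = "Conceptual module",
                  y = if (metric == "scaled_overlap") {
                    "Incorrect responses per student"
                  } else {
                    "Share of group's incorrect responses"
                  }) +
    ggplot2::theme_minimal()
}
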