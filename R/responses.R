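#' Read a multiple-choice response table
#'
#' Reads student responses from CSV in either long format (columns
#' `student_id`, `question_id`, `choice`) or wide format (one `student_id`
#' column plus one column per question). Long CSV is the canonical
#' interchange format; wide is supported read-only because it cannot
#' distinguish a skipped question from an absent one unambiguously.
#'
#' @param path Path to a CSV file with a header row.
#' @param format `"long"` (default) or `"wide"`.
#' @param valid_options Optional character vector (or named list keyed by
#'   question) of permitted option labels; any other non-missing choice is a
#'   hard error naming the offending cell. Labels are otherwise opaque
#'   strings and per-question option sets may differ in size.
#' @return A validated response tibble with columns `student_id`,
#'   `question_id`, `choice` (character; `NA` marks a missing response),
#'   containing one row for every student x question combination.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("student_id,question_id,choice",
#'              "s1,q1,A", "s1,q2,B", "s2,q1,A", "s2,q2,C"), tf)
#' read_responses(tf)
#' @export
read_responses <- function(path, format = c("long", "wide"), valid_options = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (format == "wide") {
    if (!"student_id" %in% names(raw)) {
      stop("wide response file must have a 'student_id' column", call. = FALSE)
    }
    raw <- tidyr::pivot_longer(raw, -"student_id",
                               names_to = "question_id", values_to = "choice")
  } else {
    need <- c("student_id", "question_id", "choice")
    if (!all(need %in% names(raw))) {
      stop("long response file must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    raw <- raw[need]
  }
  as_responses(raw, valid_options = valid_options)
}

#' Validate and canonicalize a response table
#'
#' Coerces a long data frame of responses into the canonical form used
#' throughout the package: character IDs, one row per student x question
#' pair (the grid is completed, absent pairs become `NA`), original
#' student/question encounter order preserved as factor-free ordering
#' metadata via row order.
#'
#' @param data Data frame with columns `student_id`, `question_id`, `choice`.
#' @param valid_options Optional permitted option labels; either a character
#'   vector applying to every question or a named list keyed by question ID.
#' @return A tibble with columns `student_id`, `question_id`, `choice`.
#' @export
as_responses <- function(data, valid_options = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("student_id", "question_id", "choice")
  if (!all(need %in% names(data))) {
    stop("responses need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data <- dplyr::mutate(
    tibble::as_tibble(data[need]),
    dplyr::across(dplyr::everything(), as.character)
  )
  dup <- dplyr::filter(
    dplyr::add_count(data, .data$student_id, .data$question_id), .data$n > 1L
  )
  if (nrow(dup) > 0L) {
    ex <- dplyr::distinct(dup, .data$student_id, .data$question_id)[1, ]
    stop("duplicate (student, question) rows, e.g. (",
         ex$student_id, ", ", ex$question_id, ")", call. = FALSE)
  }
  students <- unique(data$student_id)
  questions <- unique(data$question_id)
  out <- tidyr::complete(
    data,
    student_id = students,
    question_id = questions
  )
  out <- dplyr::arrange(out,
                        match(.data$student_id, students),
                        match(.data$question_id, questions))
  out$choice[!is.na(out$choice) & out$choice == ""] <- NA_character_
  if (!is.null(valid_options)) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      ch <- out$choice[i]
      if (is.na(ch)) return(TRUE)
      opts <- if (is.list(valid_options)) {
        valid_options[[out$question_id[i]]]
      } else {
        valid_options
      }
      is.null(opts) || ch %in% opts
    }, logical(1))
    if (!all(ok)) {
      bad <- out[!ok, ][1, ]
      stop("unknown option label '", bad$choice, "' at (student ",
           bad$student_id, ", question ", bad$question_id, ")", call. = FALSE)
    }
  }
  out
}

#' Write responses to long CSV
#'
#' @param responses Response tibble (see [as_responses()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  responses <- as_responses(responses)
  readr::write_csv(responses, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read an answer key
#'
#' @param path CSV with columns `question_id`, `correct`.
#' @return Tibble with columns `question_id`, `correct`.
#' @export
read_answer_key <- function(path) {
  key <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("question_id", "correct") %in% names(key))) {
    stop("answer key must have columns question_id, correct", call. = FALSE)
  }
  if (anyDuplicated(key$question_id)) {
    stop("answer key has duplicated question_id", call. = FALSE)
  }
  tibble::as_tibble(key[c("question_id", "correct")])
}

#' Read a head-motion table
#'
#' @param path CSV with columns `student_id`, `run_id`, `mean_fd_mm`.
#' @return Tibble with those columns; `mean_fd_mm` numeric, non-negative.
#' @export
read_motion <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    student_id = readr::col_character(),
    run_id = readr::col_character(),
    mean_fd_mm = readr::col_double()
  ), progress = FALSE)
  validate_motion(m)
}

validate_motion <- function(m) {
  need <- c("student_id", "run_id", "mean_fd_mm")
  if (!all(need %in% names(m))) {
    stop("motion table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m <- tibble::as_tibble(m[need])
  if (any(is.na(m$mean_fd_mm)) || any(m$mean_fd_mm < 0)) {
    stop("mean_fd_mm must be non-negative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(m[c("student_id", "run_id")])) {
    stop("duplicate (student_id, run_id) rows in motion table", call. = FALSE)
  }
  m
}

check_key_covers <- function(responses, key) {
  missing_q <- setdiff(unique(responses$question_id), key$question_id)
  if (length(missing_q) > 0L) {
    stop("answer key is missing question(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Score per-student accuracy and per-question miss rates
#'
#' Missing responses are excluded from both numerator and denominator and
#' reported separately; a student who answered nothing gets `NA` accuracy
#' and is flagged (`undefined = TRUE`) so callers can exclude them from
#' means.
#'
#' @param responses Response tibble (see [as_responses()]).
#' @param key Answer key tibble (`question_id`, `correct`).
#' @return A list with components `students` (tibble: `student_id`,
#'   `n_answered`, `n_correct`, `n_missing`, `accuracy`, `undefined`) and
#'   `questions` (tibble: `question_id`, `n_answered`, `n_incorrect`,
#'   `n_missing`, `miss_rate`).
#' @export
score_accuracy <- function(responses, key) {
  responses <- as_responses(responses)
  check_key_covers(responses, key)
  scored <- dplyr::mutate(
    dplyr::left_join(responses, key, by = "question_id"),
    answered = !is.na(.data$choice),
    correct = .data$answered & .data$choice == .data$correct
  )
  students <- dplyr::summarise(
    dplyr::group_by(scored, .data$student_id),
    n_answered = sum(.data$answered),
    n_correct = sum(.data$correct),
    n_missing = sum(!.data$answered),
    .groups = "drop"
  )
  students <- dplyr::mutate(
    students,
    accuracy = ifelse(.data$n_answered > 0, .data$n_correct / .data$n_answered, NA_real_),
    undefined = .data$n_answered == 0L
  )
  questions <- dplyr::summarise(
    dplyr::group_by(scored, .data$question_id),
    n_answered = sum(.data$answered),
    n_incorrect = sum(.data$answered & !.data$correct),
    n_missing = sum(!.data$answered),
    .groups = "drop"
  )
  questions <- dplyr::mutate(
    questions,
    miss_rate = ifelse(.data$n_answered > 0,
                       .data$n_incorrect / .data$n_answered, NA_real_)
  )
  list(students = students, questions = questions)
}

#' Compare paired behavioral measures between two conditions
#'
#' Runs a paired two-sided t-test per measure (e.g., accuracy and response
#' time on assessment vs. control items), aligned by student.
#'
#' @param data Long tibble with columns `student_id`, `condition`, and one
#'   or more numeric measure columns.
#' @param measures Character vector of measure column names; defaults to all
#'   numeric columns other than the identifiers.
#' @param conditions Length-2 character vector naming the two condition
#'   levels to compare (difference is `conditions[1] - conditions[2]`);
#'   defaults to the two levels present.
#' @return Tibble with one row per measure: condition means, `t`, `df`,
#'   `p_value`, and a `degenerate` flag (zero-variance differences, where
#'   the t statistic is infinite and p collapses to 0).
#' @export
summarize_behavior <- function(data, measures = NULL, conditions = NULL) {
  stopifnot(is.data.frame(data),
            all(c("student_id", "condition") %in% names(data)))
  if (is.null(conditions)) {
    conditions <- unique(as.character(data$condition))
  }
  if (length(conditions) != 2L) {
    stop("exactly two conditions are required", call. = FALSE)
  }
  if (is.null(measures)) {
    measures <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c("student_id", "condition"))
  }
  purrr::map_dfr(measures, function(m) {
    wide <- tidyr::pivot_wider(data[c("student_id", "condition", m)],
                               names_from = "condition",
                               values_from = dplyr::all_of(m))
    wide <- wide[stats::complete.cases(wide[conditions]), ]
    n <- nrow(wide)
    if (n < 2L) stop("paired comparison needs at least 2 students", call. = FALSE)
    d <- wide[[conditions[1]]] - wide[[conditions[2]]]
    degenerate <- stats::sd(d) == 0 && mean(d) != 0
    if (all(d == 0)) {
      t_stat <- 0; p <- 1
    } else if (degenerate) {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    } else {
      tt <- stats::t.test(d)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble::tibble(
      measure = m,
      mean_a = mean(wide[[conditions[1]]]),
      mean_b = mean(wide[[conditions[2]]]),
      mean_diff = mean(d),
      n = n, t = t_stat, df = n - 1L, p_value = p,
      degenerate = degenerate
    )
  })
}
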