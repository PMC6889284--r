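#' Read a conceptual-module catalog
#'
#' A catalog maps module IDs (e.g., `m1` "impetus force") to sets of
#' (question, incorrect option) pairs. JSON schema:
#' `{"modules": {"m1": {"name": "...", "items": [{"question": "...",
#' "option": "..."}]}}}`. Pairs that equal the keyed correct answer are
#' rejected, as are pairs claimed by more than one module; pairs belonging
#' to no module ("unaffiliated distractors") are permitted.
#'
#' @param path Path to the catalog JSON file.
#' @param key Answer key tibble (`question_id`, `correct`).
#' @return Tibble with columns `module_id`, `module_name`, `question_id`,
#'   `option`.
#' @export
read_module_catalog <- function(path, key) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$modules)) stop("catalog JSON must have a 'modules' object", call. = FALSE)
  cat_tbl <- purrr::imap_dfr(raw$modules, function(mod, id) {
    items <- purrr::map_dfr(mod$items, tibble::as_tibble)
    tibble::tibble(
      module_id = id,
      module_name = mod$name %||% id,
      question_id = as.character(items$question),
      option = as.character(items$option)
    )
  })
  validate_catalog(cat_tbl, key)
}

#' Validate a module catalog against an answer key
#'
#' @param catalog Tibble with columns `module_id`, `question_id`, `option`
#'   (and optionally `module_name`).
#' @param key Answer key tibble.
#' @return The validated catalog tibble (with `module_name` filled in).
#' @export
validate_catalog <- function(catalog, key) {
  need <- c("module_id", "question_id", "option")
  if (!all(need %in% names(catalog))) {
    stop("catalog needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  catalog <- tibble::as_tibble(catalog)
  if (!"module_name" %in% names(catalog)) catalog$module_name <- catalog$module_id
  joined <- dplyr::left_join(catalog, key, by = "question_id")
  if (any(is.na(joined$correct))) {
    bad <- joined$question_id[is.na(joined$correct)][1]
    stop("catalog references question not in key: ", bad, call. = FALSE)
  }
  hit <- joined$option == joined$correct
  if (any(hit)) {
    bad <- joined[hit, ][1, ]
    stop("catalog pair (", bad$question_id, ", ", bad$option,
         ") is the correct answer, not a distractor", call. = FALSE)
  }
  dup <- dplyr::filter(
    dplyr::add_count(catalog, .data$question_id, .data$option), .data$n > 1L
  )
  if (nrow(dup) > 0L) {
    stop("pair (", dup$question_id[1], ", ", dup$option[1],
         ") claimed by multiple modules: ",
         paste(unique(dup$module_id[dup$question_id == dup$question_id[1] &
                                      dup$option == dup$option[1]]),
               collapse = ", "), call. = FALSE)
  }
  catalog[c("module_id", "module_name", "question_id", "option")]
}

#' Write a module catalog to JSON
#'
#' @param catalog Validated catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_catalog <- function(catalog, path) {
  mods <- split(catalog, factor(catalog$module_id, levels = unique(catalog$module_id)))
  obj <- list(modules = purrr::map(mods, function(m) {
    list(name = m$module_name[1],
         items = purrr::map2(m$question_id, m$option,
                             ~list(question = .x, option = .y)))
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Scaled overlap profile of one student group
#'
#' Counts the group's incorrect responses falling in each conceptual
#' module. Two normalizations are reported, because "scaled by group size"
#' admits both readings and they answer different questions:
#' `scaled_overlap` (responses per student, `raw / group size`) compares
#' absolute module usage across groups of different sizes, while `share`
#' (`raw / total incorrect responses of the group`) describes the
#' composition of the group's errors. Shares sum to at most 1; the
#' remainder is incorrect responses on unaffiliated distractors.
#'
#' @param responses Response tibble.
#' @param key Answer key tibble.
#' @param catalog Validated module catalog tibble.
#' @param students Character vector of student IDs forming the group.
#' @param group_id Optional label recorded in the output.
#' @return A list with `profile` (tibble: one row per catalog module with
#'   `raw`, `scaled_overlap`, `share`) and `summary` (tibble: `group_id`,
#'   `size`, `accuracy`, `n_incorrect`, `n_unaffiliated`).
#' @export
overlap_profile <- function(responses, key, catalog, students, group_id = NA) {
  responses <- as_responses(responses)
  stopifnot(length(students) > 0)
  if (!all(students %in% responses$student_id)) {
    stop("group contains students absent from the responses", call. = FALSE)
  }
  sub <- dplyr::filter(responses, .data$student_id %in% students)
  scored <- score_accuracy(sub, key)
  wrong <- dplyr::filter(
    dplyr::left_join(sub, key, by = "question_id"),
    !is.na(.data$choice), .data$choice != .data$correct
  )
  wrong <- dplyr::left_join(
    wrong, catalog[c("module_id", "question_id", "option")],
    by = c("question_id" = "question_id", "choice" = "option")
  )
  modules <- unique(catalog$module_id)
  raw <- as.integer(table(factor(wrong$module_id, levels = modules)))
  n_incorrect <- nrow(wrong)
  size <- length(students)
  profile <- tibble::tibble(
    group_id = group_id,
    module_id = modules,
    raw = raw,
    scaled_overlap = raw / size,
    share = if (n_incorrect > 0) raw / n_incorrect else rep(0, length(raw))
  )
  acc <- scored$students$accuracy[!scored$students$undefined]
  summary <- tibble::tibble(
    group_id = group_id,
    size = size,
    accuracy = if (length(acc) > 0) mean(acc) else NA_real_,
    n_incorrect = n_incorrect,
    n_unaffiliated = sum(is.na(wrong$module_id))
  )
  list(profile = profile, summary = summary)
}

#' Overlap profiles for every normative group of a partition
#'
#' @param responses Response tibble.
#' @param key Answer key tibble.
#' @param catalog Validated module catalog tibble.
#' @param partition `student_partition` (or tibble with `student_id`,
#'   `community`).
#' @param min_size Minimum community size for a group to be profiled
#'   (default 10); use 1 to profile everything.
#' @param groups Optional explicit community labels (overrides `min_size`).
#' @return A `group_profiles` object: list with `profiles` (tibble, one row
#'   per group x module) and `groups` (tibble, one row per group with size,
#'   accuracy, incorrect counts).
#' @export
group_profiles <- function(responses, key, catalog, partition,
                           min_size = 10, groups = NULL) {
  if (is.null(groups)) groups <- select_normative_groups(partition, min_size)
  res <- purrr::map(groups, function(gid) {
    members <- partition$student_id[partition$community == gid]
    overlap_profile(responses, key, catalog, members, group_id = gid)
  })
  structure(
    list(
      profiles = purrr::map_dfr(res, "profile"),
      groups = purrr::map_dfr(res, "summary")
    ),
    class = "group_profiles"
  )
}

#' @export
print.group_profiles <- function(x, ...) {
  cat("<group_profiles> ", nrow(x$groups), " group(s)\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Classify a group's error profile as concentrated or fragmented
#'
#' A module is "dominant" when its share of the group's module-affiliated
#' incorrect responses exceeds `dominance_threshold`. A profile with at
#' least one dominant module is classed `concentrated`; otherwise
#' `fragmented`. The normalized entropy of the (renormalized, nonzero)
#' share vector is reported as a continuous fragmentation index: 0 for a
#' point mass, 1 for shares uniform over the modules actually used.
#'
#' @param profile Tibble with `module_id` and `share` columns (one group),
#'   e.g. one group's rows from [group_profiles()].
#' @param dominance_threshold Share above which a module is dominant
#'   (default 0.5).
#' @return Tibble with `dominant_modules` (list column), `n_dominant`,
#'   `coherence` (`"concentrated"`/`"fragmented"`), `fragmentation_index`.
#' @export
classify_profile <- function(profile, dominance_threshold = 0.5) {
  stopifnot(all(c("module_id", "share") %in% names(profile)))
  share <- profile$share
  dominant <- profile$module_id[share > dominance_threshold]
  nz <- share[share > 0]
  frag <- if (length(nz) <= 1L) 0 else {
    p <- nz / sum(nz)
    -sum(p * log2(p)) / log2(length(nz))
  }
  tibble::tibble(
    dominant_modules = list(dominant),
    n_dominant = length(dominant),
    coherence = if (length(dominant) > 0) "concentrated" else "fragmented",
    fragmentation_index = frag
  )
}
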