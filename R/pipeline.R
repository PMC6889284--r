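#' Validate a bundle of input files without running the analysis
#'
#' Runs every format validator (responses, answer key, catalog, motion)
#' and cross-checks (key coverage, catalog consistency) and collects hard
#' errors instead of stopping at the first.
#'
#' @param responses,answer_key,module_catalog,motion File paths; `NULL`
#'   entries are skipped.
#' @return Tibble with columns `input`, `error` (empty when everything is
#'   valid).
#' @export
validate_inputs <- function(responses = NULL, answer_key = NULL,
                            module_catalog = NULL, motion = NULL) {
  errs <- list()
  note <- function(input, expr) {
    tryCatch({ expr; NULL },
             error = function(e) {
               errs[[length(errs) + 1L]] <<- tibble::tibble(
                 input = input, error = conditionMessage(e))
             })
  }
  resp <- key <- NULL
  if (!is.null(responses)) note("responses", resp <- read_responses(responses))
  if (!is.null(answer_key)) note("answer_key", key <- read_answer_key(answer_key))
  if (!is.null(resp) && !is.null(key)) {
    note("answer_key", check_key_covers(resp, key))
  }
  if (!is.null(module_catalog)) {
    if (is.null(key)) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        input = "module_catalog", error = "cannot validate catalog without an answer key")
    } else {
      note("module_catalog", read_module_catalog(module_catalog, key))
    }
  }
  if (!is.null(motion)) note("motion", read_motion(motion))
  if (length(errs) == 0L) {
    tibble::tibble(input = character(0), error = character(0))
  } else {
    dplyr::bind_rows(errs)
  }
}

#' Run the full response-profiling pipeline
#'
#' Orchestrates: (1) simulate or load inputs, (2) agreement-network
#' projection, (3) backbone extraction, (4) map-equation community
#' detection, (5) motion screening of normative groups (optional), (6)
#' per-group conceptual-module profiles. Writes every stage output plus a
#' machine-readable manifest to `out_dir`; re-running with the same inputs
#' and seed reproduces byte-identical CSV/JSON outputs.
#'
#' @param responses,answer_key,module_catalog,motion Input file paths;
#'   leave `NULL` (with `simulate = TRUE`) to generate them.
#' @param simulate Generate inputs from `sim` instead of reading files.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param alpha Backbone significance level (default 0.01).
#' @param rule Backbone endpoint rule (`"either"` or `"both"`).
#' @param min_group_size Normative-group size threshold (default 10).
#' @param n_trials Community-detection restarts (default 100).
#' @param screen_motion Run the motion-screening stage when motion data is
#'   available.
#' @param seed Seed for simulation and community detection.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return A list of stage results: `responses`, `key`, `catalog`,
#'   `motion`, `truth` (when simulated), `network`, `backbone`,
#'   `partition`, `normative_groups`, `screen`, `profiles`, and `manifest`.
#' @export
run_pipeline <- function(responses = NULL, answer_key = NULL,
                         module_catalog = NULL, motion = NULL,
                         simulate = is.null(responses),
                         sim = sim_config(),
                         alpha = 0.01, rule = "either",
                         min_group_size = 10, n_trials = 100,
                         screen_motion = TRUE, seed = 42,
                         out_dir = NULL) {
  t0 <- Sys.time()
  stages <- list()
  mark <- function(name, n) {
    stages[[name]] <<- tibble::tibble(
      stage = name, records = n,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  if (simulate) {
    kc <- simulate_catalog(sim, seed = seed)
    key <- kc$key
    catalog <- kc$catalog
    simr <- simulate_responses(sim, key, catalog, seed = seed)
    resp <- simr$responses
    truth <- simr$truth
    mot <- simulate_motion(sim, truth, seed = seed)
  } else {
    if (is.null(responses) || is.null(answer_key)) {
      stop("responses and answer_key paths are required when simulate = FALSE",
           call. = FALSE)
    }
    resp <- read_responses(responses)
    key <- read_answer_key(answer_key)
    check_key_covers(resp, key)
    catalog <- if (!is.null(module_catalog)) {
      read_module_catalog(module_catalog, key)
    } else NULL
    mot <- if (!is.null(motion)) read_motion(motion) else NULL
    truth <- NULL
  }
  mark("inputs", nrow(resp))

  network <- project_agreement(resp)
  mark("network", nrow(network$edges))

  backbone <- lans_backbone(network, alpha = alpha, rule = rule)
  mark("backbone", sum(backbone$edges$retained))

  partition <- detect_communities(backbone, n_trials = n_trials, seed = seed)
  mark("communities", length(unique(partition$community)))

  normative <- select_normative_groups(partition, min_group_size)
  screen <- NULL
  retained_groups <- normative
  if (screen_motion && !is.null(mot) && length(normative) >= 2L) {
    screen <- screen_groups_motion(partition, mot, groups = normative)
    retained_groups <- screen$retained
  }
  mark("screening", length(retained_groups))

  profiles <- NULL
  if (!is.null(catalog)) {
    if (length(retained_groups) == 0L) {
      warning("no community reached min_group_size = ", min_group_size,
              "; profiles table is empty", call. = FALSE)
      profiles <- structure(
        list(profiles = tibble::tibble(), groups = tibble::tibble()),
        class = "group_profiles")
    } else {
      profiles <- group_profiles(resp, key, catalog, partition,
                                 groups = retained_groups)
    }
  }
  mark("profiles", if (is.null(profiles)) 0L else nrow(profiles$profiles))

  result <- list(responses = resp, key = key, catalog = catalog, motion = mot,
                 truth = truth, network = network, backbone = backbone,
                 partition = partition, normative_groups = normative,
                 screen = screen, profiles = profiles)

  manifest <- list(
    config = list(alpha = alpha, rule = rule, min_group_size = min_group_size,
                  n_trials = n_trials, seed = seed, simulate = simulate),
    versions = list(respnet = as.character(utils::packageVersion("respnet")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    stages = dplyr::bind_rows(stages)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_responses(resp, p("responses.csv"))
    readr::write_csv(key, p("answer_key.csv"), progress = FALSE)
    if (!is.null(catalog)) write_module_catalog(catalog, p("module_catalog.json"))
    if (!is.null(mot)) readr::write_csv(mot, p("motion.csv"), progress = FALSE)
    if (!is.null(truth)) {
      readr::write_csv(truth$groups, p("truth_groups.csv"), progress = FALSE)
    }
    write_network(backbone, p("network_edges.csv"))
    readr::write_csv(tibble::as_tibble(partition), p("partition.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(n_communities = length(unique(partition$community)),
           map_score_bits = attr(partition, "map_score"),
           modularity_q = attr(partition, "modularity"),
           n_trials = n_trials, seed = seed),
      p("summary.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(screen)) {
      readr::write_csv(screen$report, p("motion_screening.csv"), progress = FALSE)
    }
    if (!is.null(profiles) && nrow(profiles$profiles) > 0) {
      readr::write_csv(profiles$profiles, p("profiles.csv"), progress = FALSE)
      jsonlite::write_json(profiles$groups, p("groups.json"), digits = NA)
    }
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  result$manifest <- manifest
  result
}
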