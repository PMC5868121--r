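#' Pipeline configuration
#'
#' Assembles and validates the nested configuration driving
#' [run_pipeline()]: cohort, paradigm, denoising, connectivity and
#' decoding settings plus the master seed. Any field can be overridden;
#' validation runs before any stage executes.
#'
#' @param cohort Named list overriding [cohort_spec()] arguments
#'   (`paradigm` is supplied separately).
#' @param paradigm Named list overriding [paradigm_spec()] arguments.
#' @param denoise Named list overriding [denoise_spec()] arguments.
#' @param decoding Named list overriding [decoding_spec()] arguments
#'   (the decoding seed is derived from the master seed).
#' @param fc Named list: `hemodynamic_shift_s` (default 4),
#'   `positive_q` (FDR level of the positive-edge masks, default 0.01),
#'   `conditions` (analyzed conditions, default static + dynamic).
#' @param seed Master seed.
#' @param write_cohort Also write the simulated cohort as TSV tables.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), paradigm = list(),
                            denoise = list(), decoding = list(),
                            fc = list(), seed = 1,
                            write_cohort = FALSE) {
  pspec <- do.call(paradigm_spec, paradigm)
  cspec <- do.call(cohort_spec, c(cohort, list(paradigm = pspec)))
  dspec <- do.call(denoise_spec, denoise)
  decoding$seed <- NULL
  dec <- do.call(decoding_spec, c(decoding, list(seed = 0L)))
  fc_defaults <- list(hemodynamic_shift_s = 4, positive_q = 0.01,
                      conditions = c("static", "dynamic"))
  fc <- utils::modifyList(fc_defaults, fc)
  nyquist <- 1 / (2 * pspec$tr_s)
  if (dspec$band_hz[2] >= nyquist) {
    stop(sprintf("band high edge %.3g Hz is not below Nyquist %.3g Hz",
                 dspec$band_hz[2], nyquist))
  }
  if (!all(fc$conditions %in% pspec$conditions)) {
    stop("analyzed conditions must be a subset of the paradigm conditions")
  }
  if (fc$positive_q <= 0 || fc$positive_q >= 1) stop("positive_q in (0,1)")
  structure(list(cohort = cspec, denoise = dspec, decoding = dec,
                 fc = fc, seed = as.integer(seed),
                 write_cohort = isTRUE(write_cohort)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] argument structure
#' (`cohort:`, `paradigm:`, `denoise:`, `decoding:`, `fc:`, `seed:`).
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @keywords internal
#' @noRd
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) the cohort, denoise, compute condition-specific
#' connectivity, group edge statistics and pooled positive-edge feature
#' sets, decode each condition with the permutation test, summarize
#' behavior, and write every result as plain-text tables and JSON under
#' `out_dir`. A manifest records the configuration hash and seed;
#' re-running with an unchanged configuration over an intact output
#' directory skips recomputation.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param cohort Optional pre-built cohort (e.g. from [read_cohort()]);
#'   `NULL` simulates one from the config.
#' @return A `pipeline_result` list: `decoding` (per condition),
#'   `group_stats`, `pooled`, `behavior_tests`, `manifest_path`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  hash <- config_hash(config)
  if (file.exists(manifest_path)) {
    old <- try(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
               silent = TRUE)
    if (!inherits(old, "try-error") && identical(old$config_hash, hash) &&
        all(file.exists(file.path(out_dir, old$outputs)))) {
      message("configuration unchanged and outputs present; skipping")
      return(invisible(structure(list(out_dir = out_dir,
                                      manifest_path = manifest_path,
                                      skipped = TRUE),
                                 class = "pipeline_result")))
    }
  }
  pd <- config$cohort$paradigm
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(rel) outputs <<- c(outputs, rel)

  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(config$cohort, config$seed))
    if (config$write_cohort) {
      stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))
      emit(file.path("cohort", "manifest.json"))
    }
  }

  fc_tbl <- stage("connectivity", cohort_fc(
    cohort, denoise_spec = config$denoise,
    expressions = pd$expressions,
    conditions = config$fc$conditions,
    tr_s = pd$tr_s,
    hemodynamic_shift_s = config$fc$hemodynamic_shift_s,
    discard_initial_volumes = pd$discard_initial_volumes))

  stats <- stage("groupfc", group_edge_stats(fc_tbl))
  readr::write_tsv(stats, file.path(out_dir, "group_edge_stats.tsv"),
                   progress = FALSE)
  emit("group_edge_stats.tsv")
  pooled <- stage("groupfc",
                  pooled_feature_sets(stats, config$fc$positive_q))
  pooled_tbl <- tibble::tibble(
    condition = names(pooled),
    n_features = vapply(pooled, attr, numeric(1), "n_features")
  )
  readr::write_tsv(pooled_tbl, file.path(out_dir, "pooled_features.tsv"),
                   progress = FALSE)
  emit("pooled_features.tsv")

  n_rois <- config$cohort$n_rois
  atlas <- atlas_table(n_rois)
  decoding <- list()
  for (cond in config$fc$conditions) {
    dec_spec <- config$decoding
    dec_spec$seed <- derive_seed(config$seed, "decode", cond)
    samples <- stage("fcmvpa", edge_samples(fc_tbl, cond))
    res <- stage("fcmvpa",
                 permutation_test(samples, dec_spec, pooled[[cond]]))
    net <- consensus_network(res, atlas)
    decoding[[cond]] <- res
    json <- list(
      condition = cond,
      accuracy = res$accuracy,
      p_value = res$p_value,
      n_permutations = length(res$permutation_null),
      n_folds = length(res$selected_features),
      n_predictions = nrow(res$predictions),
      n_pooled_features = attr(pooled[[cond]], "n_features"),
      n_consensus_edges = nrow(net$edges),
      fallback_folds = res$fallback_folds,
      permutation_null = res$permutation_null
    )
    jsonlite::write_json(json,
                         file.path(out_dir,
                                   sprintf("decoding_%s.json", cond)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(sprintf("decoding_%s.json", cond))
    readr::write_tsv(
      tibble::as_tibble(as.data.frame(res$confusion)),
      file.path(out_dir, sprintf("confusion_%s.tsv", cond)),
      progress = FALSE)
    emit(sprintf("confusion_%s.tsv", cond))
    readr::write_tsv(net$edges,
                     file.path(out_dir, sprintf("consensus_%s.tsv", cond)),
                     progress = FALSE)
    emit(sprintf("consensus_%s.tsv", cond))
    readr::write_tsv(net$node_degrees,
                     file.path(out_dir,
                               sprintf("node_degree_%s.tsv", cond)),
                     progress = FALSE)
    emit(sprintf("node_degree_%s.tsv", cond))
  }

  behavior_tbl <- dplyr::bind_rows(lapply(cohort$subjects, `[[`,
                                          "behavior"))
  behav_summary <- stage("behavior", summarize_behavior(
    behavior_tbl, expressions = pd$expressions,
    conditions = unique(behavior_tbl$condition)))
  readr::write_tsv(behav_summary,
                   file.path(out_dir, "behavior_summary.tsv"),
                   progress = FALSE)
  emit("behavior_summary.tsv")
  behavior_tests <- stage("behavior",
                          compare_conditions_behavior(behavior_tbl))
  jsonlite::write_json(behavior_tests,
                       file.path(out_dir, "behavior_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("behavior_tests.json")

  manifest <- list(config_hash = hash, seed = config$seed,
                   n_subjects = config$cohort$n_subjects,
                   n_rois = n_rois,
                   conditions = config$fc$conditions,
                   outputs = outputs,
                   package_version = as.character(
                     utils::packageVersion("fcdecoder")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(list(decoding = decoding, group_stats = stats,
                           pooled = pooled,
                           behavior_tests = behavior_tests,
                           manifest_path = manifest_path,
                           out_dir = out_dir, skipped = FALSE),
                      class = "pipeline_result"))
}

#' Validate an on-disk cohort directory
#'
#' Checks the cohort manifest, per-run table shapes (volumes x regions
#' against the schedule arithmetic), missing values and behavioral ranges.
#' Problems are reported, not thrown.
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @return Tibble of issues (`file`, `issue`); zero rows when clean.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(file = file,
                                                    issue = issue)
  }
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    note("manifest.json", "missing cohort manifest")
    return(dplyr::bind_rows(issues))
  }
  man <- try(jsonlite::read_json(man_path, simplifyVector = TRUE),
             silent = TRUE)
  if (inherits(man, "try-error")) {
    note("manifest.json", "unparseable manifest")
    return(dplyr::bind_rows(issues))
  }
  for (id in man$subjects) {
    sdir <- file.path(dir, id)
    for (k in seq_len(man$n_runs)) {
      tag <- sprintf("run-%d", k)
      ev_path <- file.path(sdir, paste0(tag, "_events.tsv"))
      ts_path <- file.path(sdir, paste0(tag, "_roi_timeseries.tsv"))
      if (!file.exists(ev_path)) {
        note(ev_path, "missing events file")
        next
      }
      if (!file.exists(ts_path)) {
        note(ts_path, "missing timeseries file")
        next
      }
      sched <- try(read_events(ev_path, tr_s = man$tr_s), silent = TRUE)
      if (inherits(sched, "try-error")) {
        note(ev_path, "unreadable events file")
        next
      }
      expected_T <- as.integer(round(schedule_duration(sched) / man$tr_s)) -
        man$discard_initial_volumes
      y <- try(read_matrix_tsv(ts_path), silent = TRUE)
      if (inherits(y, "try-error")) {
        note(ts_path, "unreadable timeseries file")
        next
      }
      if (nrow(y) != expected_T) {
        note(ts_path, sprintf("expected %d volumes, found %d",
                              expected_T, nrow(y)))
      }
      if (ncol(y) != man$n_rois) {
        note(ts_path, sprintf("expected %d ROI columns, found %d",
                              man$n_rois, ncol(y)))
      }
      if (anyNA(y)) note(ts_path, "missing values in timeseries")
    }
    bpath <- file.path(sdir, "behavior.tsv")
    if (!file.exists(bpath)) {
      note(bpath, "missing behavior table")
    } else {
      b <- try(readr::read_tsv(bpath, show_col_types = FALSE,
                               progress = FALSE), silent = TRUE)
      if (inherits(b, "try-error")) {
        note(bpath, "unreadable behavior table")
      } else {
        if (any(b$intensity < 1 | b$intensity > 9)) {
          note(bpath, "intensity outside 1..9")
        }
        if (any(b$rt_ms < 0)) note(bpath, "negative reaction time")
        bad <- setdiff(unique(b$expression), man$expressions)
        if (length(bad)) {
          note(bpath, paste("unknown expression labels:",
                            paste(bad, collapse = ", ")))
        }
      }
    }
  }
  out <- dplyr::bind_rows(issues)
  if (nrow(out) == 0) {
    tibble::tibble(file = character(), issue = character())
  } else {
    out
  }
}
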