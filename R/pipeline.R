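# Event-table I/O, pipeline configuration, and end-to-end orchestration.

#' Read a BIDS-style events table
#'
#' Tab-separated with required columns `onset`, `duration`, `stimulus_id`,
#' `genre`; onsets in seconds from run start (0-based). A header-only file
#' yields an empty table.
#'
#' @param path TSV path.
#' @return typed data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("onset", "duration", "stimulus_id", "genre")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("events file lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric %s in events row %d", col, bad[1L]))
    if (length(v) && anyNA(v)) stop("missing ", col, " in events file")
    df[[col]] <- v
  }
  if (nrow(df) > 0L && any(df$onset < 0)) stop("negative onset in events file")
  df[, required]
}

#' @rdname read_events
#' @param events data.frame to write.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1L,
    out = "musemap-results",
    simulate = list(shape = c(16L, 16L, 12L), snr = 4, n_runs = 8L,
                    volumes_per_run = 153L, tr = 2, signal_free = FALSE),
    features = list(min_variance = 0.95, kinds = FEATURE_KINDS),
    glm = list(hrf = list()),
    decode = list(enabled = TRUE, k = 500L, selection_runs = c(1L, 4L),
                  targets = c("song", "genre")),
    searchlight = list(enabled = TRUE, kinds = "melody_rel", radius = 3,
                       scatter_step = 3L, repetitions = 10L, lambda = 1),
    group_stats = list(enabled = FALSE, n_subjects = 4L, n_null = 20L,
                       null_repetitions = 2L, n_bootstrap = 10000L,
                       voxel_p = 0.001, cluster_p = 0.05, connectivity = 6L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Starts from the package defaults and overlays the user's values; unknown
#' keys at any level are rejected (they usually indicate typos).
#'
#' @param config path to a JSON file, or a named list of overrides, or NULL
#'   for the defaults.
#' @return validated config list.
#' @export
pipeline_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_checked <- function(base, user, path = "") {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_checked(base[[nm]], as.list(user[[nm]]),
                                    paste0(path, nm, "."))
      } else base[[nm]] <- user[[nm]]
    }
    base
  }
  merge_checked(base, as.list(config))
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> features -> GLM -> decode and/or searchlight (+ optional
#' group statistics over several simulated subjects), writing results and a
#' provenance record to `config$out`.
#'
#' @param config see [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list of stage results (also serialized to the output
#'   directory).
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- pipeline_config(config)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  regions <- if (isTRUE(cfg$simulate$signal_free)) list() else NULL

  say("[simulate] %s grid, snr=%s", paste(cfg$simulate$shape, collapse = "x"),
      cfg$simulate$snr)
  subj <- simulate_subject(rng_seed = cfg$seed,
                           shape = unlist(cfg$simulate$shape),
                           snr = cfg$simulate$snr, regions = regions,
                           n_runs = cfg$simulate$n_runs,
                           volumes_per_run = cfg$simulate$volumes_per_run,
                           tr = cfg$simulate$tr,
                           min_variance = cfg$features$min_variance)
  say("[glm] fitting betas")
  bp <- fit_betas(subj$session, hrf_params = cfg$glm$hrf)
  results <- list(config = cfg)

  if (isTRUE(cfg$decode$enabled)) {
    results$decode <- lapply(stats::setNames(cfg$decode$targets,
                                             cfg$decode$targets),
                             function(tg) {
      say("[decode] target=%s", tg)
      dec <- run_decoding(bp, tg, k = cfg$decode$k,
                          selection_runs = unlist(cfg$decode$selection_runs))
      utils::write.csv(dec$confusion$counts,
                       file.path(out, paste0("confusion_", tg, ".csv")))
      res <- list(accuracy = dec$accuracy, per_fold = dec$per_fold)
      if (tg == "genre") {
        behav <- generate_behavioral_confusions(derive_seed(cfg$seed, 17L))
        utils::write.csv(behav, file.path(out, "confusion_behavioral.csv"))
        res$behavioral_spearman <- confusion_spearman(dec$confusion, behav)
      }
      res
    })
  }

  if (isTRUE(cfg$searchlight$enabled)) {
    results$searchlight <- lapply(
      stats::setNames(cfg$searchlight$kinds, cfg$searchlight$kinds),
      function(kd) {
        say("[searchlight] kind=%s", kd)
        sl <- run_searchlight(bp, subj$features[[kd]],
                              radius = cfg$searchlight$radius,
                              scatter_step = cfg$searchlight$scatter_step,
                              repetitions = cfg$searchlight$repetitions,
                              rng_seed = derive_seed(cfg$seed, 7L),
                              lambda = cfg$searchlight$lambda)
        vol <- fill_searchlight_map(sl)$volume
        vol[is.nan(vol)] <- 0
        write_nifti(vol, file.path(out, paste0("accuracy_", kd, ".nii.gz")),
                    affine = subj$brain$affine, dtype = "float32")
        list(n_tests = sl$n_tests, n_centers = nrow(sl$centers),
             mean_accuracy = mean(sl$center_values))
      })
  }

  summary <- list(
    provenance = list(seed = cfg$seed, package_version =
                        as.character(utils::packageVersion("musemap")),
                      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    config = cfg,
    decode = results$decode,
    searchlight = results$searchlight)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("[done] results in %s", out)
  invisible(results)
}
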