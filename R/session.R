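# Synthetic ground-truth brains and fMRI sessions.
#
# The forward model plants feature-encoding regions in a small voxel grid:
# within a region, each voxel's response amplitude to a stimulus is a fixed
# linear readout (row of W) of that stimulus's reduced feature vector. Voxel
# time series are the HRF-convolved event regressors scaled by these
# amplitudes, plus white Gaussian noise. Everything needed to verify recovery
# (labels, weights, SNR) is retained in the object.

#' Construct a ground-truth brain with planted encoding regions
#'
#' The default layout plants three full-plane slabs, two voxels thick, one
#' per feature kind, in a 24^3 grid -- small enough for minutes-scale
#' end-to-end runs while leaving a majority of background voxels.
#'
#' @param shape 3-vector of voxel counts.
#' @param feature_dims named integer vector: reduced-vector length per
#'   feature kind (e.g. `c(melody_abs = 480, ...)`). Kinds absent from
#'   `regions` may be omitted.
#' @param regions list of region descriptors: `list(name=, kind=, slices=)`
#'   where `slices` are z-indices of a full-plane slab, or `voxels=` a
#'   logical array / integer vector of array indices. `kind` must be one of
#'   `"melody_abs"`, `"melody_rel"`, `"chroma"`, `"none"`. `NULL` gives the
#'   default three-slab layout.
#' @param snr per-voxel signal-to-noise ratio (signal sd / noise sd) for
#'   planted regions; `Inf` means noise-free. Default 1.
#' @param weight_scale standard deviation of the Gaussian readout weights.
#' @param affine voxel-to-mm map (default 2 mm isotropic).
#' @param rng_seed seed for the weight draws.
#' @return `ground_truth_brain` object: list with `shape`, `affine`,
#'   `region_labels` (integer array, 0 = background), `region_encoding`
#'   (per region: `kind`, `W` voxels x components, `snr`, `voxels`).
#' @export
ground_truth_brain <- function(shape = c(24, 24, 24), feature_dims,
                               regions = NULL, snr = 1, weight_scale = 1,
                               affine = diag(c(2, 2, 2, 1)), rng_seed = 1L) {
  if (is.null(regions)) {
    zs <- round(shape[3L] * c(0.2, 0.5, 0.8))
    regions <- list(
      list(name = "slab_melody_abs", kind = "melody_abs", slices = zs[1L] + 0:1),
      list(name = "slab_melody_rel", kind = "melody_rel", slices = zs[2L] + 0:1),
      list(name = "slab_chroma",     kind = "chroma",     slices = zs[3L] + 0:1))
  }
  labels <- array(0L, dim = shape)
  encoding <- list()
  with_seed(rng_seed, {
    for (i in seq_along(regions)) {
      rg <- regions[[i]]
      if (!rg$kind %in% c(FEATURE_KINDS, "none"))
        stop("unknown feature kind: ", rg$kind)
      if (!is.null(rg$voxels)) {
        vox <- if (is.logical(rg$voxels)) which(rg$voxels) else as.integer(rg$voxels)
      } else {
        m <- array(FALSE, dim = shape); m[, , rg$slices] <- TRUE
        vox <- which(m)
      }
      if (any(labels[vox] != 0L)) stop("regions must be disjoint")
      labels[vox] <- i
      d <- if (rg$kind == "none") 0L else feature_dims[[rg$kind]]
      W <- if (d > 0L)
        matrix(stats::rnorm(length(vox) * d, 0, weight_scale), length(vox), d)
      else matrix(0, length(vox), 0L)
      encoding[[rg$name %||% paste0("region", i)]] <-
        list(kind = rg$kind, W = W, snr = rg$snr %||% snr, voxels = vox)
    }
  })
  structure(list(shape = shape, affine = affine, region_labels = labels,
                 region_encoding = encoding),
            class = "ground_truth_brain")
}

# Sample inter-trial gap sequences from {4, 6, 8} s by rejection until the
# trial train fits in the run.
sample_gaps <- function(n_gaps, budget, gaps = c(4, 6, 8), max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    g <- sample(gaps, n_gaps, replace = TRUE)
    if (sum(g) <= budget) return(g)
  }
  stop("could not fit trials in run: increase run length")
}

#' Generate a synthetic fMRI session
#'
#' Per run, all stimuli are presented once in random order with inter-trial
#' delays drawn from {4, 6, 8} s. Event boxcars are convolved with the same
#' double-gamma HRF used by the GLM stage; each in-region voxel's time series
#' is the regressor set times its amplitude vector `W %*% feature_vector`,
#' plus white Gaussian noise with sd = signal sd / SNR. Background voxels are
#' pure unit-variance noise.
#'
#' @param brain a `ground_truth_brain`.
#' @param stimuli data.frame from [stimulus_specs()].
#' @param feature_vectors named list: per feature kind used by the brain, a
#'   stimuli x components matrix (rownames = stimulus ids), e.g. the
#'   `vectors` field of [fit_reduce()].
#' @param rng_seed integer seed.
#' @param n_runs number of runs (default 8).
#' @param volumes_per_run volumes per run (default 153).
#' @param tr repetition time in seconds (default 2).
#' @param first_onset onset of the first trial in each run (s).
#' @param hrf_params HRF overrides (shared with the GLM stage).
#' @param epi_format `"array"` (4D volumes, the on-disk layout) or
#'   `"matrix"` (T x voxels; avoids large copies in simulation-heavy tests).
#' @return `synthetic_session`: list with `epi` (list of 4D arrays), `events`
#'   (list of data.frames: onset, duration, stimulus_id, genre), `brain`,
#'   `tr`, `n_runs`, `volumes_per_run`, `stimuli`.
#' @export
generate_session <- function(brain, stimuli, feature_vectors, rng_seed = 1L,
                             n_runs = 8L, volumes_per_run = 153L, tr = 2,
                             first_onset = 4, hrf_params = list(),
                             epi_format = c("array", "matrix")) {
  epi_format <- match.arg(epi_format)
  shape <- brain$shape
  n_vox <- prod(shape)
  n_stim <- nrow(stimuli)
  run_dur <- volumes_per_run * tr
  for (rg in brain$region_encoding) {
    if (rg$kind == "none") next
    fv <- feature_vectors[[rg$kind]]
    if (is.null(fv)) stop("missing feature vectors for kind ", rg$kind)
    if (ncol(rg$W) != ncol(fv))
      stop("W column count does not match feature dimensionality for kind ",
           rg$kind)
  }
  # amplitude map: voxels x stimuli (zero outside planted regions)
  A <- matrix(0, n_vox, n_stim)
  snr_vox <- rep(NA_real_, n_vox)
  for (rg in brain$region_encoding) {
    if (rg$kind == "none" || ncol(rg$W) == 0L) { snr_vox[rg$voxels] <- rg$snr; next }
    fv <- feature_vectors[[rg$kind]][stimuli$stimulus_id, , drop = FALSE]
    A[rg$voxels, ] <- rg$W %*% t(fv)
    snr_vox[rg$voxels] <- rg$snr
  }
  with_seed(rng_seed, {
    events <- vector("list", n_runs)
    designs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      ord <- sample.int(n_stim)
      budget <- run_dur - first_onset - sum(stimuli$duration)
      g <- sample_gaps(n_stim - 1L, budget)
      onsets <- first_onset + cumsum(c(0, stimuli$duration[ord][-n_stim] + g))
      ev <- data.frame(onset = onsets, duration = stimuli$duration[ord],
                       stimulus_id = stimuli$stimulus_id[ord],
                       genre = stimuli$genre[ord])
      events[[r]] <- ev
      D <- convolved_regressors(ev, volumes_per_run, tr, hrf_params)
      designs[[r]] <- D[, stimuli$stimulus_id, drop = FALSE]
    }
    # per-voxel signal sd over the concatenated noiseless series
    sig <- lapply(designs, function(D) D %*% t(A))      # T x V each
    ssum <- Reduce(`+`, lapply(sig, colSums))
    ssum2 <- Reduce(`+`, lapply(sig, function(x) colSums(x^2)))
    n_t <- n_runs * volumes_per_run
    sig_sd <- sqrt(pmax(ssum2 / n_t - (ssum / n_t)^2, 0))
    noise_sd <- rep(1, n_vox)
    planted <- which(!is.na(snr_vox))
    noise_sd[planted] <- ifelse(is.infinite(snr_vox[planted]), 0,
                                sig_sd[planted] / snr_vox[planted])
    # a planted voxel with no signal (e.g. all-zero weights) stays pure noise
    noise_sd[planted][sig_sd[planted] == 0 & !is.infinite(snr_vox[planted])] <- 1
    epi <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      noise <- matrix(stats::rnorm(volumes_per_run * n_vox), volumes_per_run,
                      n_vox)
      Y <- sig[[r]] + sweep(noise, 2L, noise_sd, "*")
      epi[[r]] <- if (epi_format == "array")
        array(t(Y), dim = c(shape, volumes_per_run)) else Y
    }
    structure(list(epi = epi, events = events, brain = brain, tr = tr,
                   n_runs = n_runs, volumes_per_run = volumes_per_run,
                   stimuli = stimuli),
              class = "synthetic_session")
  })
}

#' Simulate a complete synthetic subject
#'
#' Convenience wrapper: stimulus specs, melodies, the three feature sets,
#' ground-truth reduction (fitted on the full stimulus set -- this is the
#' generator side, not the analysis side), brain, and session.
#'
#' @param rng_seed integer seed.
#' @param shape grid shape.
#' @param snr planted-region SNR (`0` or empty `regions` gives a signal-free
#'   subject).
#' @param regions region layout passed to [ground_truth_brain()]; `NULL` =
#'   default three slabs, `list()` = no planted regions (pure noise brain).
#' @param n_runs,volumes_per_run,tr session geometry.
#' @param min_variance SVD retention for the ground-truth feature vectors.
#' @param epi_format see [generate_session()].
#' @return list with `stimuli`, `features` (per kind), `reduced` (per kind),
#'   `brain`, `session`.
#' @export
simulate_subject <- function(rng_seed = 1L, shape = c(24, 24, 24), snr = 1,
                             regions = NULL, n_runs = 8L,
                             volumes_per_run = 153L, tr = 2,
                             min_variance = 0.95,
                             epi_format = c("array", "matrix")) {
  specs <- stimulus_specs()
  features <- lapply(stats::setNames(FEATURE_KINDS, FEATURE_KINDS),
                     function(kd) build_stimulus_features(specs, kd,
                                                          derive_seed(rng_seed, 1L)))
  reduced <- lapply(features, fit_reduce, train_ids = specs$stimulus_id,
                    min_variance = min_variance)
  fdims <- vapply(reduced, function(r) ncol(r$vectors), 0L)
  brain <- ground_truth_brain(shape = shape, feature_dims = fdims,
                              regions = regions, snr = snr,
                              rng_seed = derive_seed(rng_seed, 2L))
  session <- generate_session(brain, specs,
                              lapply(reduced, function(r) r$vectors),
                              rng_seed = derive_seed(rng_seed, 3L),
                              n_runs = n_runs,
                              volumes_per_run = volumes_per_run, tr = tr,
                              epi_format = match.arg(epi_format))
  list(stimuli = specs, features = features, reduced = reduced, brain = brain,
       session = session)
}

#' Write a synthetic session to disk
#'
#' One NIfTI per run, BIDS-style `events.tsv` per run, region-label NIfTI,
#' and a JSON manifest of the stimulus specs and provenance.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, prefix = "sub-01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(session$n_runs)) {
    write_nifti(session$epi[[r]],
                file.path(dir, sprintf("%s_run-%02d_bold.nii.gz", prefix, r)),
                affine = session$brain$affine, dtype = "float32")
    write_events(session$events[[r]],
                 file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, r)))
  }
  write_nifti(session$brain$region_labels + 0L,
              file.path(dir, paste0(prefix, "_regions.nii.gz")),
              affine = session$brain$affine, dtype = "int16")
  jsonlite::write_json(
    list(stimuli = session$stimuli, tr = session$tr,
         volumes_per_run = session$volumes_per_run, n_runs = session$n_runs),
    file.path(dir, paste0(prefix, "_manifest.json")),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
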