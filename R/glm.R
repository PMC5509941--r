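# Per-voxel GLM: double-gamma HRF, event-related design matrices, OLS beta
# estimation, and fold-safe z-scoring of beta patterns.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak_delay) - ratio * g(t; under_delay)` with gamma densities
#' parameterized by delay (shape * dispersion) and dispersion (scale). The
#' defaults are the field-standard canonical values: response peak around
#' 5-6 s, undershoot around 16 s, undershoot ratio 1/6.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,peak_disp response gamma delay / dispersion (6, 1).
#' @param under_delay,under_disp undershoot gamma delay / dispersion (16, 1).
#' @param ratio undershoot amplitude ratio (1/6).
#' @return HRF values at `t`.
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, peak_disp = 1,
                             under_delay = 16, under_disp = 1, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp, scale = under_disp)
}

default_hrf_params <- function() {
  list(peak_delay = 6, peak_disp = 1, under_delay = 16, under_disp = 1,
       ratio = 1 / 6)
}

# Convolve per-condition boxcars with the HRF on a fine grid (dt seconds) and
# sample at volume acquisition times. Shared between design construction and
# the synthetic forward model, so analysis and simulation use the same kernel.
convolved_regressors <- function(events, volumes, tr, hrf_params = list(),
                                 dt = 0.1, hrf_span = 32) {
  hp <- utils::modifyList(default_hrf_params(), hrf_params)
  conds <- unique(events$stimulus_id)
  t_hi <- seq(0, volumes * tr - dt, by = dt)
  hrf <- do.call(double_gamma_hrf, c(list(t = seq(0, hrf_span, by = dt)), hp)) * dt
  vol_idx <- round((seq_len(volumes) - 1L) * tr / dt) + 1L
  X <- matrix(0, volumes, length(conds), dimnames = list(NULL, conds))
  for (j in seq_along(conds)) {
    ev <- events[events$stimulus_id == conds[j], , drop = FALSE]
    ends <- ev$onset + ev$duration
    if (nrow(ev) > 1L) {
      ev <- ev[order(ev$onset), ]
      if (any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)]))
        stop("overlapping events for condition ", conds[j])
    }
    if (any(ends > volumes * tr + 1e-9))
      stop("event exceeds run bounds for condition ", conds[j])
    box <- numeric(length(t_hi))
    for (i in seq_len(nrow(ev)))
      box[t_hi >= ev$onset[i] - 1e-9 & t_hi < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(t_hi)]
    X[, j] <- conv[vol_idx]
  }
  X
}

#' Build an event-related design matrix for one run
#'
#' One regressor per stimulus condition: a boxcar spanning the event (a 6 s
#' stimulus at TR 2 s covers 3 TRs) convolved with the double-gamma HRF,
#' sampled at volume times. Constant and linear-trend nuisance columns are
#' appended.
#'
#' @param events data.frame with columns `onset` (s), `duration` (s),
#'   `stimulus_id` (and optionally more).
#' @param volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param hrf_params named list overriding [double_gamma_hrf()] defaults.
#' @return `design_matrix` object: list with `values` (volumes x
#'   (conditions + 2)), `condition_ids`, `tr`.
#' @export
build_design <- function(events, volumes, tr, hrf_params = list()) {
  required <- c("onset", "duration", "stimulus_id")
  if (!all(required %in% names(events))) stop("events lacks required columns")
  if (nrow(events) > 0L && any(events$onset < 0)) stop("negative event onset")
  if (nrow(events) > 0L) {
    Xc <- convolved_regressors(events, volumes, tr, hrf_params)
  } else {
    Xc <- matrix(0, volumes, 0L)
  }
  nuis <- cbind(constant = 1, trend = seq_len(volumes) - (volumes + 1) / 2)
  structure(list(values = cbind(Xc, nuis), condition_ids = colnames(Xc),
                 tr = tr), class = "design_matrix")
}

#' Fit the per-voxel GLM for one run
#'
#' Ordinary least squares per voxel; nuisance betas are discarded. A
#' rank-deficient design is reported as an error, not silently regularized.
#'
#' @param epi 4D array (X, Y, Z, T) or T x V matrix of voxel time series.
#' @param design a `design_matrix`.
#' @param mask logical 3D array (required when `epi` is 4D).
#' @return conditions x voxels matrix of betas (rownames = condition ids).
#' @export
fit_glm <- function(epi, design, mask = NULL) {
  X <- design$values
  if (is.array(epi) && length(dim(epi)) == 4L) {
    if (is.null(mask)) stop("mask required for 4D input")
    sp <- dim(epi)[1:3]
    Y <- t(matrix(epi, prod(sp), dim(epi)[4L])[which(mask), , drop = FALSE])
  } else {
    Y <- as.matrix(epi)
    if (!is.null(mask) && ncol(Y) == length(mask) && !all(mask))
      Y <- Y[, which(mask), drop = FALSE]
  }
  if (nrow(Y) != nrow(X)) stop("design rows must equal volume count")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  coefs <- qr.coef(qx, Y)
  n_cond <- length(design$condition_ids)
  out <- coefs[seq_len(n_cond), , drop = FALSE]
  rownames(out) <- design$condition_ids
  out
}

#' Estimate beta patterns for a whole session
#'
#' Runs [build_design()] and [fit_glm()] per run and assembles the
#' stimulus x run x voxel beta array within the mask.
#'
#' @param session a `synthetic_session` (or any list with `epi` runs, `events`
#'   tables, `volumes_per_run`, `tr`).
#' @param mask logical 3D array; default: all voxels.
#' @param hrf_params HRF overrides.
#' @param subject_id stored in the result.
#' @return `beta_patterns` object: list with `betas` (stimulus x run x voxel),
#'   `mask`, `stimulus_ids`, `genres`, `subject_id`, `zscored`.
#' @export
fit_betas <- function(session, mask = NULL, hrf_params = list(),
                      subject_id = "sub-01") {
  n_runs <- length(session$epi)
  if (is.null(mask)) {
    shape <- if (length(dim(session$epi[[1L]])) == 4L)
      dim(session$epi[[1L]])[1:3] else session$brain$shape
    mask <- array(TRUE, dim = shape)
  }
  stim_ids <- sort(unique(session$events[[1L]]$stimulus_id))
  V <- sum(mask)
  betas <- array(NA_real_, c(length(stim_ids), n_runs, V))
  for (r in seq_len(n_runs)) {
    des <- build_design(session$events[[r]], session$volumes_per_run,
                        session$tr, hrf_params)
    b <- fit_glm(session$epi[[r]], des, mask)
    betas[, r, ] <- b[stim_ids, , drop = FALSE]
  }
  genres <- NULL
  if (!is.null(session$events[[1L]]$genre)) {
    ev1 <- session$events[[1L]]
    genres <- ev1$genre[match(stim_ids, ev1$stimulus_id)]
  }
  structure(list(betas = betas, mask = mask, stimulus_ids = stim_ids,
                 genres = genres, subject_id = subject_id, zscored = FALSE),
            class = "beta_patterns")
}

#' Z-score beta patterns using training-fold statistics only
#'
#' Per voxel, mean and standard deviation are estimated on the training cells
#' (a stimulus x run logical selector) and applied to all cells, so held-out
#' cells never influence the normalization. With `by_run = TRUE` statistics
#' are computed per run across the training stimuli of that run (removing
#' run-level offsets), the variant used by the searchlight stage.
#'
#' @param bp a `beta_patterns`.
#' @param train_cells logical stimulus x run matrix selecting training cells.
#' @param by_run compute statistics per run rather than pooled.
#' @return `beta_patterns` with `zscored = TRUE` and attribute
#'   `zero_variance_voxels` flagging voxels whose training sd was floored.
#' @export
zscore_within_fold <- function(bp, train_cells = NULL, by_run = FALSE) {
  b <- bp$betas
  d <- dim(b)
  if (is.null(train_cells)) train_cells <- matrix(TRUE, d[1L], d[2L])
  if (!any(train_cells)) stop("no training cells selected")
  floor_sd <- sqrt(.Machine$double.eps)
  flagged <- logical(d[3L])
  col_sd <- function(x) {   # vectorized column sd (n-1 denominator)
    n <- nrow(x)
    m <- colMeans(x)
    sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1L))
  }
  if (by_run) {
    for (r in seq_len(d[2L])) {
      sel <- which(train_cells[, r])
      if (length(sel) < 2L) stop("need >= 2 training stimuli per run")
      xr <- b[, r, , drop = FALSE][, 1L, ]
      m <- colMeans(xr[sel, , drop = FALSE])
      s <- col_sd(xr[sel, , drop = FALSE])
      flagged <- flagged | (s < floor_sd)
      s <- pmax(s, floor_sd)
      b[, r, ] <- t((t(xr) - m) / s)
    }
  } else {
    flat <- matrix(b, d[1L] * d[2L], d[3L])
    sel <- which(as.vector(train_cells))
    if (length(sel) < 2L) stop("need >= 2 training cells")
    m <- colMeans(flat[sel, , drop = FALSE])
    s <- col_sd(flat[sel, , drop = FALSE])
    flagged <- s < floor_sd
    s <- pmax(s, floor_sd)
    flat <- t((t(flat) - m) / s)
    b <- array(flat, d)
  }
  out <- bp
  out$betas <- b
  out$zscored <- TRUE
  attr(out, "zero_variance_voxels") <- which(flagged)
  out
}
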