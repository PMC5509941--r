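# Spherical-searchlight stimulus encoding: ridge regression from reduced
# music features to multivoxel patterns, scored by correlation-error
# probability, over scattered sphere centers.

# Integer displacement table for a sphere of the given voxel radius.
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

#' Enumerate scattered searchlight spheres within a mask
#'
#' Centers lie on a cubic lattice of spacing `scatter_step` with a uniformly
#' random offset in `{0..step-1}^3` (seeded), intersected with the mask;
#' members are the in-mask voxels within Euclidean voxel distance `radius`
#' of the center. Scattering by 3 voxels visits 1/27 of the centers a dense
#' searchlight would.
#'
#' @param mask logical 3D array.
#' @param radius sphere radius in voxels (default 3: max 123 members).
#' @param scatter_step center lattice spacing (default 3; 1 = every voxel).
#' @param rng_seed seed for the lattice offset.
#' @param offset explicit 3-vector lattice offset in `0..step-1` (overrides
#'   the seeded draw; used to reuse one scatter across true and null maps).
#' @return list of spheres (`center` voxel coordinate, `center_voxel` and
#'   `members` as indices into `which(mask)`), with attributes `offset`,
#'   `radius`, `scatter_step`.
#' @export
enumerate_spheres <- function(mask, radius = 3, scatter_step = 3L,
                              rng_seed = 1L, offset = NULL) {
  if (!any(mask)) stop("mask is empty")
  dims <- dim(mask)
  if (is.null(offset)) {
    offset <- with_seed(rng_seed, sample.int(scatter_step, 3L, replace = TRUE) - 1L)
  }
  offset <- as.integer(offset) %% as.integer(scatter_step)
  vox_index <- array(0L, dims)
  vox_index[mask] <- seq_len(sum(mask))
  coords <- which(mask, arr.ind = TRUE)
  on_lattice <- (coords[, 1L] - 1L - offset[1L]) %% scatter_step == 0L &
    (coords[, 2L] - 1L - offset[2L]) %% scatter_step == 0L &
    (coords[, 3L] - 1L - offset[3L]) %% scatter_step == 0L
  centers <- coords[on_lattice, , drop = FALSE]
  offs <- sphere_offsets(radius)
  spheres <- lapply(seq_len(nrow(centers)), function(i) {
    cc <- centers[i, ]
    pts <- sweep(offs, 2L, cc, "+")
    ok <- pts[, 1L] >= 1L & pts[, 1L] <= dims[1L] &
      pts[, 2L] >= 1L & pts[, 2L] <= dims[2L] &
      pts[, 3L] >= 1L & pts[, 3L] <= dims[3L]
    pts <- pts[ok, , drop = FALSE]
    idx <- vox_index[cbind(pts[, 1L], pts[, 2L], pts[, 3L])]
    list(center = unname(cc), center_voxel = vox_index[cc[1L], cc[2L], cc[3L]],
         members = idx[idx > 0L])
  })
  structure(spheres, offset = offset, radius = radius,
            scatter_step = scatter_step)
}

#' Ridge regression: fit on training items, predict test patterns
#'
#' Per-voxel ridge solution with one shared penalty; the intercept is left
#' unpenalized (fitted via centering), so as `lambda` grows predictions
#' shrink to the training mean pattern. Uses the dual (kernel) form when
#' features outnumber training samples.
#'
#' @param x_train,x_test feature matrices (items x features).
#' @param y_train training patterns (items x voxels).
#' @param lambda ridge penalty (> 0).
#' @return predicted patterns, `nrow(x_test)` x voxels.
#' @export
fit_predict_ridge <- function(x_train, y_train, x_test, lambda = 1) {
  if (lambda <= 0) stop("lambda must be positive")
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  x_test <- as.matrix(x_test)
  mx <- colMeans(x_train); my <- colMeans(y_train)
  Xc <- sweep(x_train, 2L, mx); Yc <- sweep(y_train, 2L, my)
  Xt <- sweep(x_test, 2L, mx)
  n <- nrow(Xc); p <- ncol(Xc)
  if (p <= n) {
    B <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, Yc))
    pred <- Xt %*% B
  } else {
    # dual form via the test-train hat matrix: cheaper when voxels are many
    H <- t(solve(tcrossprod(Xc) + diag(lambda, n), tcrossprod(Xc, Xt)))
    pred <- H %*% Yc
  }
  sweep(pred, 2L, my, "+")
}

#' Correlation-error probability of a prediction
#'
#' Pearson correlation between predicted and observed pattern across a
#' sphere's voxels; `p` is the two-sided probability of `|r|` under the null
#' (t distribution, n - 2 df); the score is `1 - p`, in [0, 1], with perfect
#' predictions scoring 1. A constant vector scores 0 (flagged).
#'
#' @param predicted,observed numeric vectors of equal length n >= 3.
#' @return score in [0, 1]; attribute `degenerate` is TRUE when either
#'   vector was constant.
#' @export
correlation_error_probability <- function(predicted, observed) {
  n <- length(predicted)
  if (length(observed) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 voxels")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(structure(0, degenerate = TRUE))
  r <- stats::cor(predicted, observed)
  1 - cor_pvalue(r, n)
}

# Two-sided p of a Pearson correlation under the null (t with n-2 df).
cor_pvalue <- function(r, n) {
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-tstat, n - 2)
}

# Row-wise correlation-error probability between two item x voxel matrices
# (each row = one test pattern over a sphere's members).
rowwise_cep <- function(P, O) {
  m <- ncol(P)
  pm <- rowMeans(P); om <- rowMeans(O)
  vp <- rowMeans(P^2) - pm^2; vo <- rowMeans(O^2) - om^2
  cv <- rowMeans(P * O) - pm * om
  ok <- vp > 1e-24 & vo > 1e-24
  r <- numeric(nrow(P))
  r[ok] <- cv[ok] / sqrt(vp[ok] * vo[ok])
  score <- numeric(nrow(P))
  score[ok] <- 1 - cor_pvalue(pmin(pmax(r[ok], -1), 1), m)
  score          # degenerate rows score 0
}

#' Run the searchlight stimulus-encoding analysis for one subject
#'
#' Per repetition, one randomly-selected stimulus per genre is held out (all
#' runs). The SVD feature reduction is refit on the training stimuli only,
#' betas are z-scored per run with training-stimulus statistics, and a ridge
#' model maps feature vectors to voxel patterns. Each held-out
#' (stimulus, run) pattern is scored in every sphere by correlation-error
#' probability. With defaults (8 runs, 10 repetitions) each sphere is scored
#' on 5 x 8 x 10 = 400 tests, averaged into a single accuracy.
#'
#' @param bp a `beta_patterns` (raw; z-scoring happens per fold inside).
#' @param features named list of `feature_matrix` objects (one per stimulus).
#' @param mask logical 3D array; must match `bp$mask`.
#' @param radius sphere radius in voxels (default 3).
#' @param scatter_step center lattice spacing (default 3).
#' @param repetitions cross-validation repetitions (default 10).
#' @param rng_seed seed for held-out draws (and the scatter offset unless
#'   `offset` is given).
#' @param lambda ridge penalty on z-scored data (default 1).
#' @param min_variance SVD retention refit per fold (default 0.95).
#' @param offset explicit scatter offset (see [enumerate_spheres()]).
#' @param min_sphere spheres with fewer members are skipped (default 10).
#' @param feature_perm optional permutation of stimulus indices: stimulus s
#'   is paired with the features of stimulus `feature_perm[s]`
#'   (randomized-target null models; identity = true model).
#' @param spheres optional precomputed sphere set from [enumerate_spheres()]
#'   (reused across subjects/null models to skip re-enumeration).
#' @return `searchlight_map`: list with `volume` (accuracy, NaN where
#'   uncomputed), `center_values`, `centers`, `mask`, `offset`,
#'   `scatter_step`, `radius`, `n_tests`, `lambda`.
#' @export
run_searchlight <- function(bp, features, mask = bp$mask, radius = 3,
                            scatter_step = 3L, repetitions = 10L,
                            rng_seed = 1L, lambda = 1, min_variance = 0.95,
                            offset = NULL, min_sphere = 10L,
                            feature_perm = NULL, spheres = NULL) {
  perms <- list(feature_perm %||% seq_len(dim(bp$betas)[1L]))
  eng <- searchlight_engine(bp, features, perms, mask, radius, scatter_step,
                            repetitions, rng_seed, lambda, min_variance,
                            offset, min_sphere, spheres)
  center_values <- eng$values[1L, ]
  vol <- array(NaN, dim = dim(mask))
  vol[eng$centers] <- center_values
  structure(list(volume = vol, center_values = center_values,
                 centers = eng$centers, mask = mask, offset = eng$offset,
                 scatter_step = scatter_step, radius = radius,
                 n_tests = eng$n_tests, lambda = lambda),
            class = "searchlight_map")
}

# Shared engine: evaluates one or more stimulus-to-feature permutations over
# identical cross-validation draws, z-scored data, and sphere geometry, so
# randomized-target null models cost only an extra ridge solve + scoring pass
# per fold. Returns per-permutation center values.
searchlight_engine <- function(bp, features, perms, mask = bp$mask,
                               radius = 3, scatter_step = 3L,
                               repetitions = 10L, rng_seed = 1L, lambda = 1,
                               min_variance = 0.95, offset = NULL,
                               min_sphere = 10L, spheres = NULL) {
  d <- dim(bp$betas)
  n_stim <- d[1L]; n_runs <- d[2L]; V <- d[3L]
  stim_ids <- bp$stimulus_ids
  genres <- bp$genres
  if (is.null(genres)) stop("beta patterns lack genre labels")
  if (sum(mask) != V) stop("mask voxel count does not match betas")
  if (is.null(spheres))
    spheres <- enumerate_spheres(mask, radius, scatter_step,
                                 rng_seed = derive_seed(rng_seed, 99L),
                                 offset = offset)
  keep <- vapply(spheres, function(s) length(s$members) >= min_sphere, TRUE)
  if (!all(keep)) spheres <- structure(spheres[keep],
                                       offset = attr(spheres, "offset"))
  if (length(spheres) == 0L) stop("no spheres of sufficient size in mask")
  members <- lapply(spheres, `[[`, "members")
  flat <- matrix(bp$betas, n_stim * n_runs, V)
  flat2 <- flat^2
  run_of_cell <- rep(seq_len(n_runs), each = n_stim)
  cell_stim <- rep(seq_len(n_stim), times = n_runs)
  by_genre <- split(seq_len(n_stim), genres)
  acc <- matrix(0, length(perms), length(spheres))
  n_scored <- 0L
  floor_sd <- sqrt(.Machine$double.eps)
  with_seed(rng_seed, {
    for (rep_i in seq_len(repetitions)) {
      held <- vapply(by_genre, function(ix) ix[sample.int(length(ix), 1L)], 0L)
      train_s <- setdiff(seq_len(n_stim), held)
      tr <- which(cell_stim %in% train_s); te <- which(cell_stim %in% held)
      # per-run z-scoring with training-stimulus statistics
      n_tr_run <- length(train_s)
      Mr <- rowsum(flat[tr, , drop = FALSE], run_of_cell[tr]) / n_tr_run
      S2 <- (rowsum(flat2[tr, , drop = FALSE], run_of_cell[tr]) -
               n_tr_run * Mr^2) / (n_tr_run - 1L)
      Sr <- sqrt(pmax(S2, 0)); Sr[Sr < floor_sd] <- floor_sd
      Ytr <- (flat[tr, , drop = FALSE] - Mr[run_of_cell[tr], , drop = FALSE]) /
        Sr[run_of_cell[tr], , drop = FALSE]
      Yte <- (flat[te, , drop = FALSE] - Mr[run_of_cell[te], , drop = FALSE]) /
        Sr[run_of_cell[te], , drop = FALSE]
      # hoist the voxel-pattern centering out of the permutation loop: the
      # ridge targets do not depend on the stimulus-to-feature assignment
      my <- colMeans(Ytr)
      Ytr_c <- Ytr - rep(my, each = nrow(Ytr))
      my_row <- rep(my, each = length(te))
      for (pi in seq_along(perms)) {
        feats <- features[stim_ids][perms[[pi]]]
        names(feats) <- stim_ids
        red <- fit_reduce(feats, train_ids = stim_ids[train_s],
                          min_variance = min_variance)
        vec <- red$vectors[stim_ids, , drop = FALSE]
        Xtr <- vec[cell_stim[tr], , drop = FALSE]
        Xte <- vec[cell_stim[te], , drop = FALSE]
        mx <- colMeans(Xtr)
        Xc <- Xtr - rep(mx, each = nrow(Xtr))
        Xt <- Xte - rep(mx, each = nrow(Xte))
        H <- t(solve(tcrossprod(Xc) + diag(lambda, nrow(Xc)),
                     tcrossprod(Xc, Xt)))
        P <- H %*% Ytr_c + my_row
        acc[pi, ] <- acc[pi, ] + sphere_score_sums(P, Yte, members)
      }
      n_scored <- n_scored + length(te)
    }
  })
  list(values = acc / n_scored,
       centers = t(vapply(spheres, function(s) s$center, integer(3L))),
       offset = attr(spheres, "offset"), n_tests = n_scored)
}

#' Fill a scattered searchlight map by nearest computed center
#'
#' Every in-mask voxel is assigned the accuracy of its nearest computed
#' center (squared-distance ties broken by lowest center index), producing a
#' complete volume for group-level thresholding and clustering.
#'
#' @param slmap a `searchlight_map` (or compatible list).
#' @return list with `fill_index` (per in-mask voxel, index of the assigned
#'   center) and `volume` (filled accuracy volume, NaN outside the mask).
#' @export
fill_searchlight_map <- function(slmap) {
  mask <- slmap$mask
  coords <- which(mask, arr.ind = TRUE)
  centers <- slmap$centers
  if (nrow(centers) == nrow(coords)) {
    # exhaustive searchlight: every in-mask voxel is its own center
    fill_index <- seq_len(nrow(centers))
  } else {
    # nearest center; squared distances are integers, ties exact.
    # chunked to bound the distance-matrix memory.
    fill_index <- integer(nrow(coords))
    chunk <- max(1L, floor(4e6 / nrow(centers)))
    for (lo in seq(1L, nrow(coords), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(coords))
      cc <- coords[lo:hi, , drop = FALSE]
      d2 <- outer(cc[, 1L], centers[, 1L], "-")^2 +
        outer(cc[, 2L], centers[, 2L], "-")^2 +
        outer(cc[, 3L], centers[, 3L], "-")^2
      fill_index[lo:hi] <- max.col(-d2, ties.method = "first")
    }
  }
  vol <- array(NaN, dim = dim(mask))
  vol[mask] <- slmap$center_values[fill_index]
  list(fill_index = fill_index, volume = vol)
}
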