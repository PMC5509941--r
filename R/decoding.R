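# Multivoxel decoding of song identity and genre: ANOVA feature selection on
# reserved runs, norm-scaled linear SVMs, leakage-safe cross-validation, and
# confusion-matrix comparison with behavior.

#' ANOVA-based voxel selection on reserved runs
#'
#' One-way ANOVA F score per voxel with the individual stimulus (25-level)
#' factor, computed on the selection runs only; the `k` voxels with the
#' highest F are returned, ties broken by voxel index. Using runs that never
#' enter the cross-validation folds avoids selection circularity.
#'
#' @param bp a `beta_patterns` (not z-scored; selection is scale-invariant).
#' @param selection_runs run indices reserved for selection (default 1 and 4).
#' @param k number of voxels to keep (default 5000). If `k` exceeds the voxel
#'   count, all voxels are kept with a warning.
#' @return sorted integer vector of selected voxel indices (into the voxel
#'   axis of `bp$betas`), with attribute `f_scores`.
#' @export
select_voxels_anova <- function(bp, selection_runs = c(1L, 4L), k = 5000L) {
  d <- dim(bp$betas)
  if (length(selection_runs) < 2L)
    stop("need at least 2 selection runs (>= 2 observations per stimulus)")
  if (any(selection_runs > d[2L])) stop("selection run out of range")
  X <- matrix(bp$betas[, selection_runs, ], d[1L] * length(selection_runs),
              d[3L])
  a <- d[1L]                       # factor levels (stimuli)
  ng <- length(selection_runs)     # observations per level
  N <- a * ng
  lev <- rep(seq_len(a), times = ng)
  gm <- rowsum(X, lev) / ng                       # level means, a x V
  grand <- colMeans(X)
  ssb <- ng * colSums(sweep(gm, 2L, grand)^2)
  ssw <- colSums(X^2) - ng * colSums(gm^2)
  f <- (ssb / (a - 1)) / pmax(ssw / (N - a), .Machine$double.eps)
  if (k >= d[3L]) {
    if (k > d[3L]) warning("k exceeds voxel count; keeping all voxels")
    sel <- seq_len(d[3L])
  } else {
    sel <- sort(order(-f, seq_along(f))[seq_len(k)])
  }
  attr(sel, "f_scores") <- f
  sel
}

#' Train a multiclass linear SVM with norm-scaled C
#'
#' One-vs-one linear SVMs (dual coordinate descent, deterministic). The
#' margin parameter is scaled by the norm of the data:
#' `C = C0 / mean(l2 norm of training patterns)`.
#'
#' @param X training patterns (samples x features).
#' @param y training labels (factor or character).
#' @param C margin parameter; `NULL` (default) applies the norm-scaling rule.
#' @param C0 numerator of the scaling rule (default 1).
#' @param multiclass `"one_vs_one"` (default) or `"one_vs_rest"`.
#' @return `linear_svm` object.
#' @export
train_svm <- function(X, y, C = NULL, C0 = 1, multiclass = c("one_vs_one", "one_vs_rest")) {
  multiclass <- match.arg(multiclass)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes")
  X <- as.matrix(X)
  if (is.null(C)) {
    mean_norm <- mean(sqrt(rowSums(X^2)))
    if (mean_norm <= 0) mean_norm <- 1
    C <- C0 / mean_norm
  }
  Xb <- cbind(X, 1)   # bias as an appended constant feature
  fits <- list()
  if (multiclass == "one_vs_one") {
    for (i in seq_len(length(classes) - 1L)) for (j in (i + 1L):length(classes)) {
      sel <- y %in% classes[c(i, j)]
      yy <- ifelse(y[sel] == classes[i], 1, -1)
      w <- svm_dcd_fit(Xb[sel, , drop = FALSE], yy, C)
      fits[[paste(i, j, sep = ":")]] <- list(i = i, j = j, w = w)
    }
  } else {
    for (i in seq_along(classes)) {
      yy <- ifelse(y == classes[i], 1, -1)
      fits[[as.character(i)]] <- list(i = i, w = svm_dcd_fit(Xb, yy, C))
    }
  }
  structure(list(fits = fits, classes = classes, C = C,
                 multiclass = multiclass, p = ncol(X)),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  X <- cbind(as.matrix(newdata), 1)
  L <- length(object$classes)
  score <- matrix(0, nrow(X), L)
  if (object$multiclass == "one_vs_one") {
    votes <- matrix(0, nrow(X), L)
    for (f in object$fits) {
      dec <- as.vector(X %*% f$w)
      votes[, f$i] <- votes[, f$i] + (dec > 0)
      votes[, f$j] <- votes[, f$j] + (dec <= 0)
      score[, f$i] <- score[, f$i] + dec
      score[, f$j] <- score[, f$j] - dec
    }
    # ties in the vote broken by summed decision values, then class order
    pick <- apply(votes + 1e-9 * pmin(pmax(score, -1e6), 1e6), 1L, which.max)
  } else {
    for (f in object$fits) score[, f$i] <- as.vector(X %*% f$w)
    pick <- apply(score, 1L, which.max)
  }
  factor(object$classes[pick], levels = object$classes)
}

#' Build a cross-validation scheme over beta-pattern cells
#'
#' Song decoding is cross-validated by run (leave one run out); genre
#' decoding by stimulus (each fold holds out all runs of exactly one stimulus
#' per genre; five folds, each stimulus held out exactly once). Runs reserved
#' for feature selection never appear in train or test cells.
#'
#' @param kind `"leave_run_out"` or `"leave_stimulus_per_genre_out"`.
#' @param stimulus_ids character vector of stimulus ids (cell rows).
#' @param genres genre per stimulus (required for the genre scheme).
#' @param n_runs total number of runs.
#' @param feature_selection_runs runs reserved for selection (default 1, 4).
#' @return `cv_scheme` object: list with `kind`, `folds` (each a list of
#'   `train`, `test` logical stimulus x run matrices), `cv_runs`,
#'   `feature_selection_runs`.
#' @export
make_cv_scheme <- function(kind = c("leave_run_out", "leave_stimulus_per_genre_out"),
                           stimulus_ids, genres = NULL, n_runs = 8L,
                           feature_selection_runs = c(1L, 4L)) {
  kind <- match.arg(kind)
  cv_runs <- setdiff(seq_len(n_runs), feature_selection_runs)
  n_stim <- length(stimulus_ids)
  cell <- function() matrix(FALSE, n_stim, length(cv_runs),
                            dimnames = list(stimulus_ids, cv_runs))
  folds <- list()
  if (kind == "leave_run_out") {
    for (r in seq_along(cv_runs)) {
      test <- cell(); test[, r] <- TRUE
      train <- cell(); train[, -r] <- TRUE
      folds[[length(folds) + 1L]] <- list(train = train, test = test)
    }
  } else {
    if (is.null(genres)) stop("genres required for the genre scheme")
    by_genre <- split(seq_len(n_stim), genres)
    n_fold <- unique(lengths(by_genre))
    if (length(n_fold) != 1L) stop("genres must be balanced")
    for (f in seq_len(n_fold)) {
      held <- vapply(by_genre, `[`, 0L, f)
      test <- cell(); test[held, ] <- TRUE
      train <- cell(); train[-held, ] <- TRUE
      folds[[length(folds) + 1L]] <- list(train = train, test = test)
    }
  }
  structure(list(kind = kind, folds = folds, cv_runs = cv_runs,
                 feature_selection_runs = feature_selection_runs),
            class = "cv_scheme")
}

#' Run within-subject decoding
#'
#' Full Analysis-1 pipeline for one subject: ANOVA voxel selection on the
#' reserved runs, then per fold z-scoring with training statistics, SVM
#' fitting, and prediction of the held-out cells. Accuracy is the pooled
#' fraction correct; confusion counts are accumulated over folds.
#'
#' @param bp a `beta_patterns` (raw, not z-scored).
#' @param target `"song"` (25-way, leave-run-out) or `"genre"` (5-way,
#'   leave-one-stimulus-per-genre-out).
#' @param k number of voxels retained by ANOVA selection.
#' @param selection_runs runs reserved for voxel selection.
#' @param scheme optional pre-built `cv_scheme` (defaults to the target's
#'   canonical scheme).
#' @param ... passed to [train_svm()].
#' @return list with `accuracy`, `confusion` (a `confusion_matrix`),
#'   `per_fold` accuracies, `selected_voxels`, `scheme`.
#' @export
run_decoding <- function(bp, target = c("song", "genre"), k = 5000L,
                         selection_runs = c(1L, 4L), scheme = NULL, ...) {
  target <- match.arg(target)
  d <- dim(bp$betas)
  sel <- select_voxels_anova(bp, selection_runs, k)
  if (is.null(scheme)) {
    scheme <- make_cv_scheme(
      if (target == "song") "leave_run_out" else "leave_stimulus_per_genre_out",
      bp$stimulus_ids, bp$genres, n_runs = d[2L],
      feature_selection_runs = selection_runs)
  }
  labels_of <- function(stim_idx) {
    if (target == "song") bp$stimulus_ids[stim_idx] else bp$genres[stim_idx]
  }
  lev <- if (target == "song") bp$stimulus_ids else sort(unique(bp$genres))
  counts <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold <- numeric(0)
  cv_runs <- scheme$cv_runs
  full_cells <- function(cells_cv) {
    m <- matrix(FALSE, d[1L], d[2L]); m[, cv_runs] <- cells_cv; m
  }
  for (fold in scheme$folds) {
    train_cells <- full_cells(fold$train)
    test_cells <- full_cells(fold$test)
    if (!any(test_cells) || !any(train_cells)) stop("empty fold")
    bz <- zscore_within_fold(bp, train_cells)
    flat <- matrix(bz$betas, d[1L] * d[2L], d[3L])[, sel, drop = FALSE]
    stim_of_cell <- rep(seq_len(d[1L]), times = d[2L])
    tr <- which(as.vector(train_cells)); te <- which(as.vector(test_cells))
    fit <- train_svm(flat[tr, , drop = FALSE],
                     factor(labels_of(stim_of_cell[tr]), levels = lev), ...)
    pred <- predict(fit, flat[te, , drop = FALSE])
    truth <- factor(labels_of(stim_of_cell[te]), levels = lev)
    per_fold <- c(per_fold, mean(pred == truth))
    counts <- counts + unclass(table(truth, pred))
  }
  cm <- structure(list(counts = counts, labels = lev, normalized = FALSE),
                  class = "confusion_matrix")
  acc <- sum(diag(counts)) / sum(counts)
  list(accuracy = acc, confusion = cm, per_fold = per_fold,
       selected_voxels = sel, scheme = scheme)
}

#' Group mean and standard error of per-subject accuracies
#'
#' @param accuracies numeric vector, one accuracy per subject (n >= 2).
#' @return list with `mean` and `se` (= sd / sqrt(n)).
#' @export
group_summary <- function(accuracies) {
  n <- length(accuracies)
  if (n < 2L) stop("need at least 2 subjects")
  list(mean = mean(accuracies), se = stats::sd(accuracies) / sqrt(n))
}

#' Spearman correlation of confusion matrices above the diagonal
#'
#' Rank correlation between the strictly-upper-triangle entries of two
#' equally-shaped confusion matrices (L(L-1)/2 values), removing the positive
#' bias the shared diagonal structure would induce. Two-sided p.
#'
#' @param neural,behavioral `confusion_matrix` objects or plain matrices of
#'   the same shape (L >= 3).
#' @return list with `rho` and `p` (`rho = NA` with a message if either
#'   triangle is constant).
#' @export
confusion_spearman <- function(neural, behavioral) {
  m1 <- if (inherits(neural, "confusion_matrix")) neural$counts else neural
  m2 <- if (inherits(behavioral, "confusion_matrix")) behavioral$counts else behavioral
  if (!all(dim(m1) == dim(m2))) stop("confusion matrices differ in shape")
  if (nrow(m1) < 3L) stop("need at least 3 labels")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, note = "constant upper triangle"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Chance-level calibration of the decoders on signal-free data
#'
#' Simulates signal-free subjects (all encoding weights absent: every voxel
#' is pure noise), runs the full decoding pipeline (GLM, ANOVA selection on
#' the reserved runs, fold-wise z-scoring, SVM, cross-validation), and
#' returns the per-seed cross-validated accuracies. With no
#' stimulus-related signal the song decoder should average 1/25 and the
#' genre decoder 1/5.
#'
#' @param n_seeds number of independent subjects to simulate.
#' @param rng_seed base seed; subject s uses `derive_seed(rng_seed, s)`.
#' @param shape grid of the simulated brain (small by default: the
#'   calibration needs voxels, not anatomy).
#' @param k ANOVA-selected voxel count.
#' @param targets decoding targets to calibrate.
#' @return data.frame with columns `seed`, `song`, `genre` (accuracies; only
#'   requested targets filled).
#' @export
chance_calibration <- function(n_seeds = 50L, rng_seed = 1L,
                               shape = c(10L, 10L, 4L), k = 150L,
                               targets = c("song", "genre")) {
  out <- data.frame(seed = seq_len(n_seeds), song = NA_real_,
                    genre = NA_real_)
  for (s in seq_len(n_seeds)) {
    subj <- simulate_subject(rng_seed = derive_seed(rng_seed, s),
                             shape = shape, regions = list(),
                             epi_format = "matrix")
    bp <- fit_betas(subj$session)
    for (tg in targets)
      out[[tg]][s] <- run_decoding(bp, tg, k = k)$accuracy
  }
  out
}
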