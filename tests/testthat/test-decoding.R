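# ANOVA voxel selection, norm-scaled linear SVMs, cross-validation schemes,
# decoding, and confusion-matrix comparison.

test_that("ANOVA F scores match a brute-force oracle on a 5-voxel toy", {
  set.seed(12)
  n_stim <- 6; n_sel <- 2; V <- 5
  betas <- array(rnorm(n_stim * 4 * V), c(n_stim, 4, V))
  bp <- structure(list(betas = betas, stimulus_ids = paste0("s", 1:n_stim),
                       genres = rep(c("a", "b"), 3),
                       mask = array(TRUE, c(V, 1, 1)), zscored = FALSE),
                  class = "beta_patterns")
  sel <- select_voxels_anova(bp, selection_runs = c(1, 2), k = V)
  f <- attr(sel, "f_scores")
  # oracle: stats::anova on lm, per voxel
  for (v in 1:V) {
    y <- as.vector(betas[, 1:2, v])
    g <- factor(rep(1:n_stim, 2))
    f_ref <- stats::anova(stats::lm(y ~ g))$`F value`[1]
    expect_equal(f[v], f_ref, tolerance = 1e-10)
  }
})

test_that("ANOVA selection keeps top-k and finds planted voxels", {
  set.seed(13)
  n_stim <- 25; V <- 60
  betas <- array(rnorm(n_stim * 8 * V, sd = 1), c(n_stim, 8, V))
  effect <- rnorm(n_stim, sd = 8)
  betas[, , 42] <- betas[, , 42] + effect     # strong stimulus effect
  bp <- structure(list(betas = betas, stimulus_ids = paste0("s", 1:n_stim),
                       genres = rep(letters[1:5], each = 5),
                       mask = array(TRUE, c(V, 1, 1)), zscored = FALSE),
                  class = "beta_patterns")
  expect_equal(select_voxels_anova(bp, k = 1)[1], 42L)
  expect_equal(as.integer(select_voxels_anova(bp, k = V)), seq_len(V))
  expect_warning(select_voxels_anova(bp, k = V + 10), "keeping all")
  expect_error(select_voxels_anova(bp, selection_runs = 1), "2 selection runs")
})

test_that("linear SVM separates separable data deterministically", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40, mean = 2), 20), matrix(rnorm(40, mean = -2), 20))
  y <- rep(c("p", "q"), each = 20)
  fit <- train_svm(X, y)
  expect_equal(mean(predict(fit, X) == y), 1)
  fit2 <- train_svm(X, y)
  expect_identical(fit$fits, fit2$fits)
  expect_error(train_svm(X, rep("p", 40)), "2 classes")
  # norm-scaling rule: scaling patterns by c rescales C by 1/c
  f1 <- train_svm(X, y)
  f3 <- train_svm(3 * X, y)
  expect_equal(f3$C, f1$C / 3, tolerance = 1e-12)
})

test_that("multiclass SVM handles >2 classes with one-vs-one voting", {
  set.seed(15)
  centers <- matrix(c(0, 0, 4, 0, 0, 4), 3, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(30, sd = 0.5), 15), 2, centers[k, ], "+")))
  y <- rep(c("a", "b", "c"), each = 15)
  fit <- train_svm(X, y)
  expect_equal(length(fit$fits), 3L)   # 3 choose 2
  expect_gte(mean(predict(fit, X) == y), 0.95)
  fit_ovr <- train_svm(X, y, multiclass = "one_vs_rest")
  expect_gte(mean(predict(fit_ovr, X) == y), 0.9)
})

test_that("cross-validation schemes are leakage-safe by construction", {
  ids <- fx_specs()$stimulus_id
  genres <- fx_specs()$genre
  sc <- make_cv_scheme("leave_run_out", ids, genres, n_runs = 8)
  expect_equal(length(sc$folds), 6L)
  expect_equal(sc$cv_runs, c(2, 3, 5, 6, 7, 8))
  for (f in sc$folds) {
    expect_false(any(f$train & f$test))
    # selection runs never appear: fold matrices only span cv runs
    expect_equal(colnames(f$train), as.character(c(2, 3, 5, 6, 7, 8)))
  }
  sg <- make_cv_scheme("leave_stimulus_per_genre_out", ids, genres, n_runs = 8)
  expect_equal(length(sg$folds), 5L)
  held_all <- c()
  for (f in sg$folds) {
    held <- rownames(f$test)[rowSums(f$test) > 0]
    expect_equal(length(held), 5L)                       # one per genre
    expect_setequal(genres[match(held, ids)], unique(genres))
    expect_true(all(rowSums(f$test)[held] == 6))         # all cv runs held out
    expect_false(any(f$train & f$test))
    held_all <- c(held_all, held)
  }
  expect_setequal(held_all, ids)                         # each held exactly once
  expect_equal(anyDuplicated(held_all), 0L)
})

test_that("high-SNR decoding recovers song identity well above chance", {
  bp <- fx_signal_betas()
  dec <- run_decoding(bp, "song", k = 200)
  expect_gt(dec$accuracy, 3 / 25)   # > 3x chance
  expect_equal(sum(dec$confusion$counts), 25 * 6)
  expect_equal(unname(rowSums(dec$confusion$counts)), rep(6L, 25))
  # genre targets generalization to novel stimuli; the forward model carries
  # genre structure only through feature-vector similarity, so only the
  # bookkeeping contract is asserted here (chance calibration is tested in
  # the acceptance suite)
  dg <- run_decoding(bp, "genre", k = 200)
  expect_true(dg$accuracy >= 0 && dg$accuracy <= 1)
  expect_equal(unname(rowSums(dg$confusion$counts)), rep(5L * 6L, 5))
})

test_that("decoding on label-permuted betas is at chance", {
  bp <- fx_signal_betas()
  set.seed(99)
  bp_perm <- bp
  # permute stimulus labels independently per run: destroys the association
  for (r in seq_len(dim(bp$betas)[2]))
    bp_perm$betas[, r, ] <- bp$betas[sample(25), r, ]
  dec <- run_decoding(bp_perm, "song", k = 200)
  # binomial null: 150 tests at p = 0.04
  expect_lt(abs(dec$accuracy - 0.04), 3 * sqrt(0.04 * 0.96 / 150) + 1e-9)
})

test_that("group summary and confusion Spearman match hand computations", {
  expect_equal(group_summary(c(0.2, 0.4)), list(mean = 0.3, se = 0.1))
  expect_equal(group_summary(rep(0.5, 4))$se, 0)
  expect_equal(group_summary(c(0.1, 0.3, 0.5)),
               group_summary(c(0.5, 0.1, 0.3)))
  expect_error(group_summary(0.5), "at least 2")

  cm <- generate_behavioral_confusions(3L)
  self <- confusion_spearman(cm, cm)
  expect_equal(self$rho, 1)
  # 10 strictly-upper-triangle entries enter the correlation
  expect_equal(sum(upper.tri(cm)), 10L)
  set.seed(16)
  other <- matrix(runif(25), 5, 5)
  cs <- confusion_spearman(cm, other)
  expect_equal(cs$rho, spearman_oracle(cm[upper.tri(cm)], other[upper.tri(other)]),
               tolerance = 1e-12)
  const <- matrix(1, 5, 5)
  expect_true(is.na(confusion_spearman(const, other)$rho))
  expect_error(confusion_spearman(cm[1:2, 1:2], other[1:2, 1:2]), "3 labels")
})
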