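# Sphere geometry, ridge encoding, correlation-error probability, and the
# searchlight map machinery.

test_that("sphere membership counts match the radius geometry", {
  mask <- array(TRUE, c(15, 15, 15))
  for (cfg in list(list(r = 1, n = 7L), list(r = 2, n = 33L),
                   list(r = 3, n = 123L))) {
    sp <- enumerate_spheres(mask, radius = cfg$r, scatter_step = 5,
                            rng_seed = 1, offset = c(2, 2, 2))
    expect_equal(max(vapply(sp, function(s) length(s$members), 0L)), cfg$n)
  }
})

test_that("sphere membership equals a brute-force distance oracle on random masks", {
  set.seed(17)
  mask <- array(runif(10 * 9 * 8) > 0.3, c(10, 9, 8))
  sp <- enumerate_spheres(mask, radius = 2, scatter_step = 2, rng_seed = 3)
  vox <- which(mask)
  for (s in sp[seq(1, length(sp), length.out = 12)]) {
    oracle <- brute_sphere_members(mask, s$center, 2)
    expect_equal(sort(s$members), oracle)
    expect_true(s$center_voxel %in% s$members)
  }
  # membership offsets are reflection-symmetric
  offs <- sphere_offsets(3)
  expect_true(all(duplicated(rbind(offs, -offs))[nrow(offs) + seq_len(nrow(offs))]))
})

test_that("scattering by 3 visits 1/27 of the centers of a dense searchlight", {
  mask <- array(TRUE, c(9, 9, 9))
  dense <- enumerate_spheres(mask, radius = 1, scatter_step = 1)
  scat <- enumerate_spheres(mask, radius = 1, scatter_step = 3, rng_seed = 5)
  expect_equal(length(dense) / length(scat), 27)
  # offsets are reproducible and within range
  s1 <- enumerate_spheres(mask, 1, 3, rng_seed = 8)
  s2 <- enumerate_spheres(mask, 1, 3, rng_seed = 8)
  expect_identical(attr(s1, "offset"), attr(s2, "offset"))
  expect_true(all(attr(s1, "offset") %in% 0:2))
})

test_that("ridge matches OLS as lambda -> 0 and the intercept as lambda -> Inf", {
  set.seed(18)
  X <- matrix(rnorm(40 * 5), 40)
  B <- matrix(rnorm(5 * 3), 5)
  Y <- X %*% B + 2
  Xt <- matrix(rnorm(6 * 5), 6)
  ols <- cbind(1, Xt) %*% solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), Y))
  expect_equal(fit_predict_ridge(X, Y, Xt, 1e-10), ols, tolerance = 1e-8)
  big <- fit_predict_ridge(X, Y, Xt, 1e12)
  expect_equal(big, matrix(colMeans(Y), 6, 3, byrow = TRUE), tolerance = 1e-6)
  expect_error(fit_predict_ridge(X, Y, Xt, 0), "positive")
})

test_that("ridge agrees with the closed form on a 3x2 toy", {
  X <- matrix(c(1, 0, 2, 1, 1, 3), 3, 2)
  Y <- matrix(c(1, 2, 4), 3, 1)
  Xt <- matrix(c(1, 2), 1, 2)
  lam <- 0.5
  Xc <- sweep(X, 2, colMeans(X)); Yc <- Y - mean(Y)
  beta <- solve(t(Xc) %*% Xc + lam * diag(2)) %*% t(Xc) %*% Yc
  ref <- (Xt - colMeans(X)) %*% beta + mean(Y)
  expect_equal(fit_predict_ridge(X, Y, Xt, lam), ref, tolerance = 1e-12)
})

test_that("correlation-error probability behaves at its limits and under the null", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expect_gt(correlation_error_probability(x, x), 1 - 1e-10)
  expect_equal(correlation_error_probability(rep(1, 8), x), 0, ignore_attr = TRUE)
  expect_true(attr(correlation_error_probability(rep(1, 8), x), "degenerate"))
  expect_error(correlation_error_probability(x[1:2], x[1:2]), "at least 3")
  # p-values uniform under independence: mean score ~ 0.5
  set.seed(19)
  sc <- vapply(1:800, function(i)
    correlation_error_probability(rnorm(20), rnorm(20)), 0)
  expect_lt(abs(mean(sc) - 0.5), 3 * sd(sc) / sqrt(800))
  expect_gt(stats::ks.test(sc, "punif")$p.value, 0.001)
})

test_that("the analytic p matches a permutation oracle on n = 20 toys", {
  set.seed(20)
  n_perm <- 2000
  for (i in 1:4) {
    a <- rnorm(20); b <- rnorm(20) + 0.3 * a
    r_obs <- abs(cor(a, b))
    perm_p <- (sum(vapply(seq_len(n_perm), function(j)
      abs(cor(a, sample(b))) >= r_obs, TRUE)) + 1) / (n_perm + 1)
    analytic_p <- 1 - correlation_error_probability(a, b)
    expect_lt(abs(analytic_p - perm_p),
              3 * sqrt(perm_p * (1 - perm_p) / n_perm) + 0.01)
  }
})

test_that("searchlight bookkeeping: 400 tests, lattice centers, NaN elsewhere", {
  bp <- fx_signal_betas()
  subj <- fx_signal_subject()
  sl <- run_searchlight(bp, subj$features$melody_abs, repetitions = 10,
                        rng_seed = 31, offset = c(0, 0, 0))
  expect_equal(sl$n_tests, 400L)     # 5 stimuli x 8 runs x 10 repetitions
  expect_true(all(sl$center_values >= 0 & sl$center_values <= 1))
  expect_equal(sum(!is.nan(sl$volume)), nrow(sl$centers))
  expect_true(all((sl$centers - 1) %% 3 == 0))
})

test_that("searchlight engine equals a plain-function reference implementation", {
  subj <- fx_signal_subject()
  bp <- fx_signal_betas()
  feats <- subj$features$melody_rel
  sl <- run_searchlight(bp, feats, repetitions = 2, rng_seed = 41,
                        offset = c(1, 1, 1))
  d <- dim(bp$betas)
  sp <- enumerate_spheres(bp$mask, 3, 3, offset = c(1, 1, 1))
  sp <- sp[vapply(sp, function(s) length(s$members) >= 10, TRUE)]
  by_genre <- split(seq_len(d[1]), bp$genres)
  acc <- numeric(length(sp)); n_sc <- 0
  set.seed(41)
  for (r in 1:2) {
    held <- vapply(by_genre, function(ix) ix[sample.int(length(ix), 1L)], 0L)
    train_s <- setdiff(seq_len(d[1]), held)
    red <- fit_reduce(feats, bp$stimulus_ids[train_s])
    vec <- red$vectors[bp$stimulus_ids, ]
    tc <- matrix(FALSE, d[1], d[2]); tc[train_s, ] <- TRUE
    bz <- zscore_within_fold(bp, tc, by_run = TRUE)
    flat <- matrix(bz$betas, d[1] * d[2], d[3])
    cs <- rep(seq_len(d[1]), times = d[2])
    tr <- which(cs %in% train_s); te <- which(cs %in% held)
    P <- fit_predict_ridge(vec[cs[tr], ], flat[tr, ], vec[cs[te], ], 1)
    for (si in seq_along(sp)) {
      m <- sp[[si]]$members
      acc[si] <- acc[si] + sum(vapply(seq_along(te), function(i)
        as.numeric(correlation_error_probability(P[i, m], flat[te[i], m])), 0))
    }
    n_sc <- n_sc + length(te)
  }
  expect_equal(sl$center_values, acc / n_sc, tolerance = 1e-12)
})

test_that("planted regions score high, background near one half", {
  subj <- fx_signal_subject()
  bp <- fx_signal_betas()
  sl <- run_searchlight(bp, subj$features$melody_rel, repetitions = 5,
                        rng_seed = 51, offset = c(0, 0, 0))
  lab <- subj$brain$region_labels[sl$centers]
  kind_of <- vapply(subj$brain$region_encoding, function(r) r$kind, "")
  own <- which(kind_of == "melody_rel")
  in_region <- mean(sl$center_values[lab == own])
  background <- mean(sl$center_values[lab == 0])
  expect_gt(in_region, 0.65)
  expect_gt(in_region, background + 0.1)
  expect_lt(background, 0.62)
})

test_that("feature-specific recovery: matching maps beat mismatched maps in-region", {
  # single planted melody_rel region; paired comparison over seeds
  specs <- stimulus_specs()
  wins <- vapply(1:5, function(s) {
    feats <- lapply(stats::setNames(c("melody_rel", "chroma"),
                                    c("melody_rel", "chroma")),
                    function(kd) build_stimulus_features(specs, kd, derive_seed(400L, s)))
    red <- lapply(feats, fit_reduce, train_ids = specs$stimulus_id)
    brain <- ground_truth_brain(
      shape = c(8, 8, 6),
      feature_dims = vapply(red, function(r) ncol(r$vectors), 0L),
      regions = list(list(name = "rel", kind = "melody_rel", slices = 3:4)),
      snr = 3, rng_seed = derive_seed(401L, s))
    sess <- generate_session(brain, specs, lapply(red, function(r) r$vectors),
                             rng_seed = derive_seed(402L, s),
                             epi_format = "matrix")
    bp <- fit_betas(sess)
    in_region <- function(sl) {
      lab <- brain$region_labels[sl$centers]
      mean(sl$center_values[lab == 1])
    }
    m_rel <- run_searchlight(bp, feats$melody_rel, repetitions = 3,
                             rng_seed = s, offset = c(0, 0, 0))
    m_chr <- run_searchlight(bp, feats$chroma, repetitions = 3,
                             rng_seed = s, offset = c(0, 0, 0))
    in_region(m_rel) > in_region(m_chr)
  }, TRUE)
  expect_true(all(wins))
})
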