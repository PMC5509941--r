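# Null maps, subject-wise bootstrap, thresholding, clustering, FWE records.

mk_slmap <- function(mask, centers, values, step = 1L) {
  vol <- array(NaN, dim(mask)); vol[centers] <- values
  structure(list(volume = vol, center_values = values, centers = centers,
                 mask = mask, offset = c(0, 0, 0), scatter_step = step,
                 radius = 3, n_tests = 0L, lambda = 1),
            class = "searchlight_map")
}

test_that("identity permutation reproduces the true searchlight map", {
  bp <- fx_signal_betas()
  feats <- fx_signal_subject()$features$melody_abs
  sl <- run_searchlight(bp, feats, repetitions = 2, rng_seed = 61,
                        offset = c(0, 0, 0))
  sl_id <- run_searchlight(bp, feats, repetitions = 2, rng_seed = 61,
                           offset = c(0, 0, 0), feature_perm = 1:25)
  expect_identical(sl$center_values, sl_id$center_values)
})

test_that("null maps share geometry with the true map and are deterministic", {
  bp <- fx_signal_betas()
  feats <- fx_signal_subject()$features$melody_rel
  nl1 <- make_null_maps(bp, feats, n_null = 3, rng_seed = 71,
                        repetitions = 1, offset = c(0, 0, 0))
  nl2 <- make_null_maps(bp, feats, n_null = 3, rng_seed = 71,
                        repetitions = 1, offset = c(0, 0, 0))
  expect_identical(nl1$maps, nl2$maps)
  expect_equal(nrow(nl1$maps), 3L)
  sl <- run_searchlight(bp, feats, repetitions = 1, rng_seed = 61,
                        offset = c(0, 0, 0))
  expect_identical(nl1$centers, sl$centers)
  # permuting the assignment destroys the planted signal (melody_rel slab
  # is region 2 and contains scatter-lattice planes at this grid size)
  lab <- fx_signal_subject()$brain$region_labels[sl$centers]
  expect_lt(mean(nl1$maps[, lab == 2]), mean(sl$center_values[lab == 2]))
})

test_that("bootstrap group nulls average subject draws", {
  set.seed(23)
  centers <- which(array(TRUE, c(4, 4, 2)), arr.ind = TRUE)
  nC <- nrow(centers)
  mk_nulls <- function(m) structure(list(maps = m, centers = centers,
                                         n_null = nrow(m)),
                                    class = "null_map_set")
  # identical maps -> degenerate null
  m0 <- matrix(rep(runif(nC), each = 5), 5, nC)
  bn0 <- bootstrap_group_null(list(mk_nulls(m0), mk_nulls(m0)), 1000, 1)
  expect_equal(max(apply(bn0$boot, 2, sd)), 0)
  expect_equal(bn0$boot[1, ], m0[1, ], ignore_attr = TRUE)
  # per-voxel null mean ~ mean of subject null means
  ms <- lapply(1:3, function(s) matrix(rnorm(8 * nC, mean = s), 8, nC))
  bn <- bootstrap_group_null(lapply(ms, mk_nulls), 4000, 2)
  ref <- Reduce(`+`, lapply(ms, colMeans)) / 3
  expect_equal(colMeans(bn$boot), ref, tolerance = 0.05, ignore_attr = TRUE)
  # determinism + subject count guard
  bn2 <- bootstrap_group_null(lapply(ms, mk_nulls), 4000, 2)
  expect_identical(bn$boot, bn2$boot)
  expect_error(bootstrap_group_null(list(mk_nulls(m0)), 1000, 1), "2 subjects")
  expect_warning(bootstrap_group_null(list(mk_nulls(m0), mk_nulls(m0)), 500, 1),
                 "unstable")
})

test_that("thresholding and clustering separate planted slabs", {
  mask <- array(TRUE, c(8, 8, 8))
  centers <- which(mask, arr.ind = TRUE)
  vals <- rep(0.3, nrow(centers))
  vals[centers[, 3] %in% 2] <- 0.99       # slab 1
  vals[centers[, 3] %in% 6:7] <- 0.99     # slab 2, separated by > 1 voxel
  slm <- mk_slmap(mask, centers, vals)
  thr <- rep(0.9, nrow(centers))
  cl <- threshold_and_cluster(vals, NULL, slm, thresholds = thr)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(lengths(cl$clusters), c(64L, 128L))
  # empty suprathreshold set
  cl0 <- threshold_and_cluster(rep(0, nrow(centers)), NULL, slm,
                               thresholds = thr)
  expect_equal(length(cl0$clusters), 0L)
})

test_that("connected components respect the chosen connectivity", {
  dims <- c(5, 5, 5)
  # two voxels touching only at a corner
  idx <- c(1L, 1L + 1L + 5L + 25L)
  expect_equal(length(connected_components(idx, dims, 6L)), 2L)
  expect_equal(length(connected_components(idx, dims, 26L)), 1L)
  # face neighbors merge
  idx2 <- c(1L, 2L)
  expect_equal(length(connected_components(idx2, dims, 6L)), 1L)
})

test_that("cluster records carry the empirical-p convention and geometry", {
  mask <- array(TRUE, c(7, 7, 7))
  centers <- which(mask, arr.ind = TRUE)
  vals <- rep(0.2, nrow(centers))
  cube <- centers[, 1] %in% 3:5 & centers[, 2] %in% 3:5 & centers[, 3] %in% 3:5
  vals[cube] <- 0.95
  slm <- mk_slmap(mask, centers, vals)
  nulls <- lapply(1:2, function(s)
    structure(list(maps = matrix(stats::runif(6 * nrow(centers), 0, 0.5),
                                 6, nrow(centers)),
                   centers = centers, n_null = 6), class = "null_map_set"))
  bn <- bootstrap_group_null(nulls, 1999, 5)
  cl <- threshold_and_cluster(vals, bn, slm, voxel_p = 0.01)
  tab <- cluster_fwe(cl, vals, bn, slm, cluster_p = 0.05, affine = diag(4))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$voxels, 27L)
  # observed cluster larger than every null maximum: p = 1/(B+1)
  expect_equal(tab$p_cluster, 1 / (1999 + 1))
  # center of mass of a symmetric cube is its geometric center (0-based mm)
  expect_equal(c(tab$x, tab$y, tab$z), c(3, 3, 3))
  expect_equal(c(tab$com_i, tab$com_j, tab$com_k), c(4, 4, 4))
})

test_that("C++ null-max fast path equals the R clustering path", {
  set.seed(27)
  mask <- array(TRUE, c(6, 6, 6))
  centers <- which(mask, arr.ind = TRUE)
  nC <- nrow(centers)
  boot <- matrix(runif(300 * nC), 300, nC)
  thr <- rep(0.93, nC)
  slm <- mk_slmap(mask, centers, runif(nC))
  fill <- fill_searchlight_map(slm)
  fast <- boot_null_max_cluster(boot, thr, centers, dim(mask),
                                tabulate(fill$fill_index, nC), 1L)
  slow <- integer(300)
  for (b in 1:300) {
    supra <- which(boot[b, ] > thr)
    if (length(supra))
      slow[b] <- max(lengths(connected_components(which(mask)[supra], dim(mask))))
  }
  expect_equal(as.integer(fast), slow)
  # scattered lattice variant
  maskS <- array(TRUE, c(9, 9, 9))
  spS <- enumerate_spheres(maskS, 1, 3, offset = c(0, 0, 0), rng_seed = 1)
  centS <- t(vapply(spS, function(s) s$center, integer(3)))
  slmS <- mk_slmap(maskS, centS, runif(nrow(centS)), step = 3L)
  fillS <- fill_searchlight_map(slmS)
  bootS <- matrix(runif(300 * nrow(centS)), 300)
  thrS <- rep(0.8, nrow(centS))
  fastS <- boot_null_max_cluster(bootS, thrS, centS, dim(maskS),
                                 tabulate(fillS$fill_index, nrow(centS)), 3L)
  slowS <- integer(300)
  mask_vox <- which(maskS)
  for (b in 1:300) {
    supra <- which(bootS[b, ] > thrS)
    if (length(supra)) {
      vox <- mask_vox[fillS$fill_index %in% supra]
      slowS[b] <- max(lengths(connected_components(vox, dim(maskS))))
    }
  }
  expect_equal(as.integer(fastS), slowS)
})

test_that("fill assigns every mask voxel its nearest center", {
  mask <- array(TRUE, c(7, 6, 5))
  sp <- enumerate_spheres(mask, 1, 3, rng_seed = 12)
  cent <- t(vapply(sp, function(s) s$center, integer(3)))
  slm <- mk_slmap(mask, cent, seq_len(nrow(cent)) / nrow(cent), step = 3L)
  fill <- fill_searchlight_map(slm)
  coords <- which(mask, arr.ind = TRUE)
  for (i in seq(1, nrow(coords), by = 17)) {
    d2 <- colSums((t(cent) - coords[i, ])^2)
    expect_equal(d2[fill$fill_index[i]], min(d2))
  }
})
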