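# Melody grids, transposition, frame resampling, chromagrams, and SVD
# feature reduction.

mk_melody <- function(events, n_slots = 48L, key_pc = 0L, tempo = 120,
                      duration = 6) {
  structure(list(events = events, key_pc = key_pc, mode = "major",
                 tempo = tempo, meter = 4L, n_slots = n_slots,
                 duration = duration, stimulus_id = "t"),
            class = "melody_transcription")
}

test_that("transcription_to_grid matches the slot-level definition", {
  empty <- mk_melody(data.frame(pitch_class = integer(0), onset = integer(0),
                                duration = integer(0)))
  expect_equal(sum(transcription_to_grid(empty)), 0)

  one_c <- mk_melody(data.frame(pitch_class = 0L, onset = 0L, duration = 4L))
  g <- transcription_to_grid(one_c)
  expect_equal(which(g[, 1] == 1), 1:4)
  expect_equal(sum(g), 4)

  # sum equals total sounding slot count
  set.seed(4)
  onsets <- cumsum(c(0, sample(3:5, 9, replace = TRUE)))
  ev <- data.frame(pitch_class = sample(0:11, 10, replace = TRUE),
                   onset = onsets, duration = 3L)
  expect_equal(sum(transcription_to_grid(mk_melody(ev))), 30)

  overlap <- mk_melody(data.frame(pitch_class = c(0L, 2L), onset = c(0L, 1L),
                                  duration = c(4L, 2L)))
  expect_error(transcription_to_grid(overlap), "monophonic")
})

test_that("transpose_to_c rotates the tonic to C and is invertible", {
  g <- matrix(0L, 4, 12)
  expect_identical(transpose_to_c(g, 0), g)
  g[2, 3] <- 1L   # pitch class 2 (D)
  gt <- transpose_to_c(g, 2)
  expect_equal(unname(gt[2, 1]), 1L)
  expect_equal(sum(gt), 1)
  set.seed(8)
  for (k in sample(0:11, 6)) {
    r <- matrix(rbinom(8 * 12, 1, 0.3), 8, 12)
    back <- transpose_to_c(transpose_to_c(r, k), (12 - k) %% 12)
    expect_equal(unname(back), unname(r))
  }
})

test_that("resample_to_frames uses the nearest slot at frame centers", {
  g48 <- matrix(rbinom(48 * 12, 1, 0.2), 48, 12)
  f <- resample_to_frames(g48, tempo = 120, duration = 6)
  expect_equal(dim(f), c(60L, 12L))
  # at 150 bpm one 16th note lasts exactly 0.1 s: frame i == slot i
  g60 <- matrix(rbinom(60 * 12, 1, 0.2), 60, 12)
  expect_equal(unname(resample_to_frames(g60, 150, 6)), unname(g60))
  expect_equal(sum(resample_to_frames(matrix(0, 48, 12), 120, 6)), 0)
  # no new pitch classes appear
  sounded <- which(colSums(g48) > 0)
  expect_true(all(which(colSums(f) > 0) %in% sounded))
})

test_that("chromagram synthesis honors contracts and RMS equalization", {
  specs <- fx_specs()
  mel <- generate_melody(specs[3, ], 5L)
  # degenerate config: support equals the melody indicator support
  ch0 <- synthesize_chromagram(mel, specs[3, ], 5L, chords = FALSE,
                               bass = FALSE, env_depth = 0, noise_sd = 0,
                               ramp_s = 0)
  mf <- melody_features(mel, "melody_abs")
  expect_equal(unname(ch0 > 0), unname(mf == 1))
  # shape/nonnegativity and cross-stimulus energy equalization
  rms <- vapply(seq_len(nrow(specs)), function(i) {
    m <- generate_melody(specs[i, ], derive_seed(50L, i))
    ch <- synthesize_chromagram(m, specs[i, ], derive_seed(51L, i))
    expect_equal(dim(unclass(ch)), c(60L, 12L))
    expect_true(all(ch >= 0))
    sqrt(mean(ch^2))
  }, 0)
  expect_true(max(rms) - min(rms) < 1e-6)
  expect_error(synthesize_chromagram(mk_melody(
    data.frame(pitch_class = integer(0), onset = integer(0),
               duration = integer(0))), specs[1, ]), "no events")
})

test_that("audio chromagram folds spectra onto the right pitch classes", {
  sr <- 22050
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  a440 <- sin(2 * pi * 440 * t)
  ch <- audio_to_chromagram(a440, sr = sr)
  expect_true(all(apply(unclass(ch), 1, which.max) == 10L))  # pc 9 = A
  expect_equal(sum(audio_to_chromagram(numeric(sr), sr = sr)), 0)
  triad <- sin(2 * pi * 261.63 * t) + sin(2 * pi * 329.63 * t) +
    sin(2 * pi * 392 * t)
  cht <- colSums(audio_to_chromagram(triad, sr = sr))
  expect_setequal(order(cht, decreasing = TRUE)[1:3], c(1L, 5L, 8L)) # C E G
  # transposition by k semitones rotates the chromagram columns
  shift <- 3
  f0 <- c(261.63, 329.63, 392)
  up <- rowSums(vapply(f0 * 2^(shift / 12),
                       function(f) sin(2 * pi * f * t), t))
  chu <- colSums(audio_to_chromagram(up, sr = sr))
  expect_setequal(order(chu, decreasing = TRUE)[1:3], ((c(0, 4, 7) + shift) %% 12) + 1)
  expect_error(audio_to_chromagram(numeric(10), sr = sr), "shorter")
})

test_that("fit_reduce retains minimal k for the variance target", {
  specs <- fx_specs()
  feats <- fx_features("melody_rel")
  # rank-1 features (varying energy along one direction) -> k = 1
  rank1 <- lapply(seq_along(feats), function(i)
    feature_matrix(outer(seq_len(60) * i / 60, c(2, rep(0, 11))), "chroma",
                   names(feats)[i]))
  names(rank1) <- names(feats)
  expect_equal(fit_reduce(rank1, names(rank1)[1:5])$k, 1L)
  # full-rank features with min_variance = 1 -> k = 12
  set.seed(2)
  fr <- lapply(feats, function(f)
    feature_matrix(matrix(runif(60 * 12), 60), "chroma", attr(f, "stimulus_id")))
  expect_equal(fit_reduce(fr, names(fr), min_variance = 1)$k, 12L)
  # criterion check: retained components explain >= 95% of pooled variance
  red <- fit_reduce(feats, specs$stimulus_id)
  pooled <- do.call(rbind, lapply(feats, unclass))
  pc <- sweep(pooled, 2, red$center)
  recon <- pc %*% red$basis %*% t(red$basis)
  expect_gte(1 - sum((pc - recon)^2) / sum(pc^2), 0.95 - 1e-12)
  expect_equal(red$variance_explained >= 0.95, TRUE)
  # k is minimal
  frac <- cumsum(red$singular_values^2) / sum(red$singular_values^2)
  if (red$k > 1) expect_lt(frac[red$k - 1], 0.95)
  expect_error(fit_reduce(rank1, character(0)), "nonempty")
  zeros <- lapply(feats, function(f)
    feature_matrix(matrix(0, 60, 12), "chroma", attr(f, "stimulus_id")))
  expect_error(fit_reduce(zeros, names(zeros)[1:3]), "degenerate")
})

test_that("fit_reduce never reads test stimuli during basis fitting", {
  feats <- fx_features("melody_abs")
  train <- names(feats)[1:15]
  red1 <- fit_reduce(feats, train)
  mutated <- feats
  for (nm in setdiff(names(feats), train))
    mutated[[nm]] <- feature_matrix(matrix(runif(60 * 12), 60), "chroma", nm)
  red2 <- fit_reduce(mutated, train)
  expect_identical(red1$basis, red2$basis)
  expect_identical(red1$center, red2$center)
  expect_identical(red1$vectors[train, ], red2$vectors[train, ])
})

test_that("feature vectors stack frame projections in temporal order", {
  feats <- fx_features("melody_abs")
  red <- fit_reduce(feats, names(feats))
  f1 <- feats[[1]]
  proj <- sweep(unclass(f1), 2, red$center) %*% red$basis
  expect_equal(red$vectors[1, ], as.vector(t(proj)), ignore_attr = TRUE)
  expect_equal(ncol(red$vectors), 60L * red$k)
})
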