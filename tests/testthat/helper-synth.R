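# Shared fixtures, built in code and cached for the duration of the test run.
# Everything here is deterministic given the seeds baked into the builders.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 25-stimulus design and per-kind feature sets (one melody seed stream).
fx_specs <- function() fixture("specs", function() stimulus_specs())

fx_features <- function(kind) {
  fixture(paste0("features_", kind), function()
    build_stimulus_features(fx_specs(), kind, rng_seed = 101L))
}

# Small high-SNR subject: 10 x 10 x 12 grid, default three-slab brain
# (slabs at z = 2:3, 6:7, 10:11, leaving background planes between them).
fx_signal_subject <- function() {
  fixture("signal_subject", function()
    simulate_subject(rng_seed = 11L, shape = c(10L, 10L, 12L), snr = 4,
                     epi_format = "matrix"))
}

fx_signal_betas <- function() {
  fixture("signal_betas", function() fit_betas(fx_signal_subject()$session))
}

# Small signal-free subject (pure-noise brain).
fx_null_subject <- function() {
  fixture("null_subject", function()
    simulate_subject(rng_seed = 21L, shape = c(10L, 10L, 4L), regions = list(),
                     epi_format = "matrix"))
}

fx_null_betas <- function() {
  fixture("null_betas", function() fit_betas(fx_null_subject()$session))
}

# Independent brute-force sphere membership for the geometry oracle.
brute_sphere_members <- function(mask, center, radius) {
  coords <- which(mask, arr.ind = TRUE)
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  sort(which(d2 <= radius^2))
}

# Rank-based Spearman oracle: Pearson correlation of midranks.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}
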