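# Stimulus feature construction: schematic melody matrices (absolute and
# relative pitch), acoustic chromagrams, and SVD reduction to model-ready
# stacked vectors.
#
# All three representations share one container: a frames x 12 matrix at
# 0.1 s frame spacing (60 rows for a 6 s stimulus), columns C..B.

FEATURE_KINDS <- c("melody_abs", "melody_rel", "chroma")

#' Construct a feature matrix object
#'
#' @param values frames x 12 numeric matrix.
#' @param kind one of `"melody_abs"`, `"melody_rel"`, `"chroma"`.
#' @param stimulus_id identifier.
#' @return `feature_matrix` object (a matrix with attributes).
#' @export
feature_matrix <- function(values, kind, stimulus_id = NA_character_) {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (!is.matrix(values) || ncol(values) != 12L)
    stop("feature matrix must have 12 columns")
  if (any(!is.finite(values)) || any(values < 0))
    stop("feature matrix entries must be finite and nonnegative")
  if (startsWith(kind, "melody") &&
      (!all(values %in% c(0, 1)) || any(rowSums(values) > 1)))
    stop("melody feature matrices must be binary with row sums in {0, 1}")
  colnames(values) <- PITCH_CLASSES
  structure(values, kind = kind, stimulus_id = stimulus_id,
            class = c("feature_matrix", "matrix", "array"))
}

#' Rasterize a melody transcription to the 16th-note grid
#'
#' @param melody a `melody_transcription`.
#' @return binary `n_slots` x 12 matrix; slot s, column p is 1 iff an event
#'   with pitch class p sounds during slot s. Rests are all-zero rows.
#' @export
transcription_to_grid <- function(melody) {
  ev <- melody$events
  g <- matrix(0L, nrow = melody$n_slots, ncol = 12L,
              dimnames = list(NULL, PITCH_CLASSES))
  if (nrow(ev) == 0L) return(g)
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)]))
    stop("overlapping events: melody is not monophonic")
  if (any(ev$pitch_class < 0 | ev$pitch_class > 11))
    stop("pitch_class out of range 0-11")
  for (i in seq_len(nrow(ev))) {
    slots <- (ev$onset[i] + 1L):min(ev$onset[i] + ev$duration[i], melody$n_slots)
    g[slots, ev$pitch_class[i] + 1L] <- 1L
  }
  g
}

#' Transpose a pitch-class grid to the key of C
#'
#' Circularly rotates the 12 pitch-class columns by `-key` so the tonic maps
#' to column 1 (C). With `key = 0` this is the identity.
#'
#' @param grid slots x 12 matrix.
#' @param key tonic pitch class 0-11.
#' @return rotated matrix of the same shape.
#' @export
transpose_to_c <- function(grid, key) {
  if (ncol(grid) != 12L) stop("grid must have 12 columns")
  key <- as.integer(key) %% 12L
  if (key == 0L) return(grid)
  out <- grid[, ((seq_len(12L) - 1L + key) %% 12L) + 1L, drop = FALSE]
  colnames(out) <- PITCH_CLASSES
  out
}

#' Resample a metrical grid to regular 0.1 s frames
#'
#' Converts a tempo-normalized 16th-note slot matrix to an absolute time
#' scale. Each frame takes the value of the slot active at the frame center
#' (nearest-slot rule: preserves binarity, no interpolation artifacts).
#'
#' @param grid slots x 12 matrix.
#' @param tempo bpm.
#' @param duration stimulus duration in seconds.
#' @param frame frame length in seconds (default 0.1).
#' @return `round(duration/frame)` x 12 matrix.
#' @export
resample_to_frames <- function(grid, tempo, duration, frame = 0.1) {
  stopifnot_scalar_pos(tempo, "tempo")
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(frame, "frame")
  n_frames <- round(duration / frame)
  slot_dur <- 60 / tempo / 4
  centers <- (seq_len(n_frames) - 0.5) * frame
  idx <- pmin(floor(centers / slot_dur) + 1L, nrow(grid))
  out <- grid[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a schematic melody feature matrix for a stimulus
#'
#' Convenience wrapper: grid rasterization, optional transposition to C
#' (relative pitch), and resampling to 0.1 s frames.
#'
#' @param melody a `melody_transcription`.
#' @param kind `"melody_abs"` or `"melody_rel"`.
#' @param frame frame length in seconds.
#' @return a `feature_matrix`.
#' @export
melody_features <- function(melody, kind = c("melody_abs", "melody_rel"),
                            frame = 0.1) {
  kind <- match.arg(kind)
  g <- transcription_to_grid(melody)
  if (kind == "melody_rel") g <- transpose_to_c(g, melody$key_pc)
  vals <- resample_to_frames(g, melody$tempo, melody$duration, frame)
  feature_matrix(vals, kind, melody$stimulus_id)
}

#' Synthesize a polyphonic chromagram from a melody
#'
#' Emulates what an audio chromagram extractor would return for a produced
#' recording of the melody: melody indicator energy plus triad chord and bass
#' energy on a simple seeded I-IV-V progression, a multiplicative amplitude
#' envelope (loudness dynamics), additive noise, a 50 ms quarter-sine
#' onset/offset ramp, and RMS equalization so total energy is identical
#' across stimuli.
#'
#' @param melody a `melody_transcription` (must have at least one event).
#' @param spec the matching stimulus spec row.
#' @param rng_seed integer seed.
#' @param chords,bass logical: add triad / bass-note energy.
#' @param chord_gain,bass_gain energy of chord and bass pitch classes.
#' @param env_depth amplitude-modulation depth in [0, 1) (0 = flat envelope).
#' @param noise_sd additive noise scale (half-normal), 0 disables.
#' @param ramp_s onset/offset ramp length in seconds.
#' @param rms_target target root-mean-square value after equalization
#'   (set to NA to skip equalization).
#' @param frame frame length in seconds.
#' @return a `feature_matrix` of kind `"chroma"`.
#' @export
synthesize_chromagram <- function(melody, spec, rng_seed = 1L, chords = TRUE,
                                  bass = TRUE, chord_gain = 0.5, bass_gain = 0.8,
                                  env_depth = 0.3, noise_sd = 0.05,
                                  ramp_s = 0.05, rms_target = 1, frame = 0.1) {
  if (nrow(melody$events) == 0L) stop("melody has no events")
  spec <- as.list(spec)
  mel <- resample_to_frames(transcription_to_grid(melody), melody$tempo,
                            melody$duration, frame)
  n_frames <- nrow(mel)
  X <- mel * 1.0
  scale <- scale_for(melody$key_pc, melody$mode)
  with_seed(rng_seed, {
    if (chords || bass) {
      # one chord per beat, drawn from a seeded I-IV-V progression
      beat_dur <- 60 / melody$tempo
      beat_of_frame <- floor(((seq_len(n_frames) - 0.5) * frame) / beat_dur)
      n_beats <- max(beat_of_frame) + 1L
      roots <- sample(c(1L, 4L, 5L), n_beats, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25))
      for (b in seq_len(n_beats)) {
        rows <- which(beat_of_frame == b - 1L)
        triad_deg <- ((roots[b] - 1L + c(0L, 2L, 4L)) %% 7L) + 1L
        pcs <- scale[triad_deg] + 1L
        if (chords) X[rows, pcs] <- X[rows, pcs] + chord_gain
        if (bass) X[rows, pcs[1L]] <- X[rows, pcs[1L]] + bass_gain
      }
    }
    if (env_depth > 0) {
      f_env <- stats::runif(1, 0.5, 2)
      phase <- stats::runif(1, 0, 2 * pi)
      env <- 1 + env_depth * sin(2 * pi * f_env * (seq_len(n_frames) - 0.5) * frame + phase)
      X <- X * env
    }
    if (noise_sd > 0)
      X <- X + abs(matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X)))
  })
  X <- X * quarter_sine_ramp(n_frames, frame, ramp_s)
  if (!is.na(rms_target)) {
    rms <- sqrt(mean(X^2))
    if (rms <= 0) stop("degenerate all-zero chromagram; cannot equalize RMS")
    X <- X * (rms_target / rms)
  }
  feature_matrix(X, "chroma", melody$stimulus_id)
}

# Per-frame attenuation factors for a quarter-sine amplitude ramp of length
# ramp_s applied at both ends of the clip (frame-averaged).
quarter_sine_ramp <- function(n_frames, frame, ramp_s) {
  if (ramp_s <= 0) return(rep(1, n_frames))
  ramp_fun <- function(t) ifelse(t < ramp_s, sin(pi * t / (2 * ramp_s)), 1)
  fac <- vapply(seq_len(n_frames), function(i) {
    ts <- seq((i - 1) * frame, i * frame, length.out = 33L)
    mean(ramp_fun(ts))
  }, 0)
  fac * rev(fac)
}

#' Compute a chromagram from audio
#'
#' Magnitude-spectrum energy per 0.1 s frame folded onto the 12
#' equal-temperament pitch classes (A4 = 440 Hz reference), accumulated
#' across octaves. Stereo input is averaged to mono.
#'
#' @param audio numeric vector (mono) or 2-column matrix (stereo), waveform.
#' @param sr sample rate in Hz (default 44100).
#' @param frame frame length in seconds (default 0.1).
#' @param window FFT window length in samples (default 8192).
#' @param fmin,fmax frequency band folded onto pitch classes.
#' @return frames x 12 nonnegative matrix (class `feature_matrix`, kind
#'   `"chroma"`).
#' @export
audio_to_chromagram <- function(audio, sr = 44100, frame = 0.1, window = 8192L,
                                fmin = 55, fmax = 5000) {
  if (is.matrix(audio)) audio <- rowMeans(audio)
  hop <- round(sr * frame)
  if (length(audio) < hop) stop("audio shorter than one frame")
  n_frames <- floor(length(audio) / hop)
  window <- min(window, 2^floor(log2(length(audio))))
  half <- window %/% 2L
  freqs <- (seq_len(half) - 1L) * sr / window
  band <- which(freqs >= fmin & freqs <= fmax)
  pc_of_bin <- (9L + round(12 * log2(freqs[band] / 440))) %% 12L + 1L
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  out <- matrix(0, n_frames, 12L)
  for (i in seq_len(n_frames)) {
    center <- (i - 0.5) * hop
    lo <- round(center - half) + 1L
    seg <- numeric(window)
    src <- max(1L, lo):min(length(audio), lo + window - 1L)
    seg[src - lo + 1L] <- audio[src]
    mag2 <- Mod(stats::fft(seg * hann)[seq_len(half)])^2
    out[i, ] <- vapply(1:12, function(p) sum(mag2[band[pc_of_bin == p]]), 0)
  }
  feature_matrix(out, "chroma")
}

#' Fit an SVD reduction on training stimuli and project all stimuli
#'
#' Pools the frame rows of the training stimuli, mean-centers them with the
#' training mean, and computes the singular-value decomposition. The smallest
#' number of components whose cumulative squared-singular-value fraction
#' reaches `min_variance` is retained. Every stimulus (train and test) is
#' projected frame-wise and its 60 projected observation vectors are stacked
#' in temporal order into a single vector of length `60 * k`. Test stimuli
#' are never read during basis fitting.
#'
#' @param features named list of `feature_matrix` objects (one per stimulus,
#'   same kind).
#' @param train_ids character vector of stimulus ids to fit the basis on.
#' @param min_variance minimum fraction of variance retained (default 0.95).
#' @return `reduced_feature_set` object: list with `basis` (12 x k), `center`
#'   (length-12 training mean), `k`, `variance_explained`, `singular_values`,
#'   `vectors` (stimuli x 60k matrix, rownames = stimulus ids), `fitted_on`,
#'   `kind`.
#' @export
fit_reduce <- function(features, train_ids, min_variance = 0.95) {
  if (length(train_ids) == 0L) stop("train_ids must be nonempty")
  if (is.null(names(features))) stop("features must be a named list")
  if (!all(train_ids %in% names(features)))
    stop("train_ids not all present in features")
  if (min_variance <= 0 || min_variance > 1)
    stop("min_variance must be in (0, 1]")
  pooled <- do.call(rbind, lapply(features[train_ids], unclass))
  center <- colMeans(pooled)
  pc <- sweep(pooled, 2L, center)
  sv <- svd(pc)
  tot <- sum(sv$d^2)
  if (tot <= 0) stop("degenerate training features: no variance")
  cumfrac <- cumsum(sv$d^2) / tot
  k <- which(cumfrac >= min_variance - 1e-12)[1L]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # fix sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  vectors <- t(vapply(features, function(f) {
    proj <- sweep(unclass(f), 2L, center) %*% V
    as.vector(t(proj))          # frame-major: 60 observation vectors stacked
  }, numeric(nrow(features[[1L]]) * k)))
  rownames(vectors) <- names(features)
  structure(list(basis = V, center = center, k = k,
                 variance_explained = cumfrac[k], singular_values = sv$d,
                 vectors = vectors, fitted_on = train_ids,
                 kind = attr(features[[1L]], "kind")),
            class = "reduced_feature_set")
}

#' Build all feature matrices for a stimulus set
#'
#' @param specs data.frame from [stimulus_specs()].
#' @param kind feature kind to build.
#' @param rng_seed base seed; melodies and chromagrams derive per-stimulus
#'   seeds from it.
#' @param ... passed to [synthesize_chromagram()] for `kind = "chroma"`.
#' @return named list of `feature_matrix` objects (names = stimulus ids).
#' @export
build_stimulus_features <- function(specs, kind = FEATURE_KINDS, rng_seed = 1L, ...) {
  kind <- match.arg(kind)
  out <- lapply(seq_len(nrow(specs)), function(i) {
    mel <- generate_melody(specs[i, ], derive_seed(rng_seed, i))
    if (kind == "chroma")
      synthesize_chromagram(mel, specs[i, ], derive_seed(rng_seed, 1000L + i), ...)
    else melody_features(mel, kind)
  })
  names(out) <- specs$stimulus_id
  out
}
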