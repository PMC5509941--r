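# Stimulus set specification and symbolic melody generation.
#
# The synthetic stimulus set mirrors the design of the music-listening
# experiment the pipeline targets: 25 six-second clips, five per genre, each
# with a musical key (tonic pitch class + mode) and a tempo. Melodies are
# monophonic pitch-class event lists on a 16th-note metrical grid.

GENRES <- c("Ambient", "Country", "HeavyMetal", "RocknRoll", "Symphonic")

PITCH_CLASSES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

# Keys of the 25 clips (tonic pitch class 0-11 and mode), five per genre.
DEFAULT_KEYS <- data.frame(
  genre = rep(GENRES, each = 5),
  key_pc = c(5, 0, 0, 0, 11,     # Ambient: F C C Cm B
             0, 9, 2, 7, 2,      # Country: C A D G D
             1, 6, 4, 7, 4,      # HeavyMetal: Db F# E G Em
             3, 5, 5, 9, 4,      # RocknRoll: Eb F F A E
             5, 10, 2, 5, 5),    # Symphonic: F Bbm D F F
  mode = c("major", "major", "major", "minor", "major",
           "major", "major", "major", "major", "major",
           "major", "major", "major", "major", "minor",
           "major", "major", "major", "major", "major",
           "major", "minor", "major", "major", "major"),
  stringsAsFactors = FALSE
)

# Genre-typical tempos (bpm). All are multiples of 2.5 so that a 6 s clip
# spans an integer number of 16th-note slots (duration * tempo / 15).
DEFAULT_TEMPOS <- c(Ambient = 70, Country = 100, HeavyMetal = 140,
                    RocknRoll = 160, Symphonic = 90)

# Per-genre melody-generator configuration: probability that a free grid slot
# starts a note, the note-duration distribution (in 16th-note slots), the
# scale-degree weighting (degrees 1..7), and the random-walk step scale.
MELODY_GENRE_PARAMS <- list(
  Ambient    = list(density = 0.30, durs = c(2, 4, 8), dur_w = c(2, 4, 4),
                    degree_w = c(5, 1, 3, 1, 4, 2, 1), walk_sd = 0.8),
  Country    = list(density = 0.55, durs = c(1, 2, 4), dur_w = c(3, 4, 2),
                    degree_w = c(5, 2, 4, 1, 4, 3, 1), walk_sd = 1.2),
  HeavyMetal = list(density = 0.80, durs = c(1, 2), dur_w = c(6, 3),
                    degree_w = c(6, 3, 1, 4, 4, 1, 3), walk_sd = 1.8),
  RocknRoll  = list(density = 0.70, durs = c(1, 2), dur_w = c(5, 4),
                    degree_w = c(5, 1, 4, 2, 4, 3, 2), walk_sd = 1.5),
  Symphonic  = list(density = 0.45, durs = c(1, 2, 4), dur_w = c(3, 4, 3),
                    degree_w = c(4, 3, 3, 3, 4, 2, 2), walk_sd = 1.0)
)

SCALE_MAJOR <- c(0, 2, 4, 5, 7, 9, 11)
SCALE_MINOR <- c(0, 2, 3, 5, 7, 8, 10)

#' Build the default stimulus set specification
#'
#' Returns the 25-stimulus design: five stimuli in each of five genres, each
#' with key (tonic pitch class, mode), genre-typical tempo, and duration.
#'
#' @param duration clip duration in seconds (default 6).
#' @param tempos named vector of per-genre tempos in bpm.
#' @param keys data frame with columns `genre`, `key_pc`, `mode` (25 rows).
#' @return data.frame with columns `stimulus_id`, `genre`, `key_pc`, `mode`,
#'   `tempo`, `duration`.
#' @export
stimulus_specs <- function(duration = 6, tempos = DEFAULT_TEMPOS,
                           keys = DEFAULT_KEYS) {
  stopifnot_scalar_pos(duration, "duration")
  if (any(tempos <= 0)) stop("tempo must be positive")
  df <- keys
  df$stimulus_id <- paste0(df$genre, sprintf("%03d", stats::ave(
    seq_len(nrow(df)), df$genre, FUN = seq_along)))
  df$tempo <- unname(tempos[df$genre])
  df$duration <- duration
  df[, c("stimulus_id", "genre", "key_pc", "mode", "tempo", "duration")]
}

#' Number of 16th-note grid slots spanned by a stimulus
#'
#' One 16th note lasts `60 / tempo / 4` seconds, so a clip of `duration`
#' seconds spans `duration * tempo / 15` slots.
#'
#' @param tempo beats per minute.
#' @param duration seconds.
#' @return integer slot count.
#' @export
n_grid_slots <- function(tempo, duration) {
  stopifnot_scalar_pos(tempo, "tempo")
  stopifnot_scalar_pos(duration, "duration")
  round(duration * tempo / 15)
}

scale_for <- function(key_pc, mode) {
  base <- if (identical(mode, "minor")) SCALE_MINOR else SCALE_MAJOR
  (key_pc + base) %% 12
}

#' Generate a monophonic melody for a stimulus
#'
#' A bounded random walk on scale degrees fills a 16th-note grid spanning the
#' stimulus duration. Genre controls note density, duration distribution, and
#' the scale-degree distribution, so that melodies within a genre are
#' statistically more alike than melodies across genres.
#'
#' @param spec one row of [stimulus_specs()] (data.frame or list with fields
#'   `stimulus_id`, `genre`, `key_pc`, `mode`, `tempo`, `duration`).
#' @param rng_seed integer seed; identical seeds give identical melodies.
#' @return object of class `melody_transcription`: list with `events`
#'   (data.frame `pitch_class`, `onset`, `duration` in slot units), `key_pc`,
#'   `mode`, `tempo`, `meter`, `n_slots`, `duration`, `stimulus_id`.
#' @export
generate_melody <- function(spec, rng_seed = 1L) {
  spec <- as.list(spec)
  params <- MELODY_GENRE_PARAMS[[spec$genre]]
  if (is.null(params)) stop("unknown genre: ", spec$genre)
  n_slots <- n_grid_slots(spec$tempo, spec$duration)
  scale <- scale_for(spec$key_pc, spec$mode)
  with_seed(rng_seed, {
    deg <- sample.int(7L, 1L, prob = params$degree_w)
    ev_pc <- integer(0); ev_on <- integer(0); ev_du <- integer(0)
    t <- 0L
    while (t < n_slots) {
      if (stats::runif(1) < params$density) {
        dur <- sample(rep(params$durs, 2L), 1L, prob = rep(params$dur_w, 2L))
        dur <- min(dur, n_slots - t)
        # mostly walk; occasionally jump to a degree drawn from the genre's
        # scale-degree distribution
        if (stats::runif(1) < 0.3) {
          deg <- sample.int(7L, 1L, prob = params$degree_w)
        } else {
          step <- round(stats::rnorm(1, 0, params$walk_sd))
          deg <- ((deg - 1L + max(-3L, min(3L, step))) %% 7L) + 1L
        }
        ev_pc <- c(ev_pc, scale[deg]); ev_on <- c(ev_on, t); ev_du <- c(ev_du, dur)
        t <- t + dur
      } else {
        t <- t + 1L
      }
    }
    structure(list(
      events = data.frame(pitch_class = ev_pc, onset = ev_on, duration = ev_du),
      key_pc = spec$key_pc, mode = spec$mode, tempo = spec$tempo, meter = 4L,
      n_slots = n_slots, duration = spec$duration,
      stimulus_id = spec$stimulus_id %||% NA_character_),
      class = "melody_transcription")
  })
}

#' Generate a synthetic behavioral genre-confusion matrix
#'
#' Row-stochastic 5x5 matrix (true genre x assigned genre) with configurable
#' diagonal mass. The default off-diagonal structure elevates the
#' Ambient-Symphonic and Country-RocknRoll confusions, with milder
#' Country-HeavyMetal and HeavyMetal-RocknRoll confusion, the pattern typical
#' of human genre-assignment behavior on such stimulus sets.
#'
#' @param rng_seed integer seed for the (small) multiplicative jitter.
#' @param diag_mass probability mass on the diagonal (default 0.864, matching
#'   typical behavioral accuracy on this kind of task).
#' @param pair_weights named vector of extra off-diagonal weights, names of
#'   the form `"GenreA:GenreB"` (applied symmetrically; baseline weight 1).
#' @param jitter_sd standard deviation of log-normal jitter on off-diagonal
#'   weights (0 = fully deterministic).
#' @return 5x5 row-stochastic matrix with genre dimnames.
#' @export
generate_behavioral_confusions <- function(rng_seed = 1L, diag_mass = 0.864,
                                           pair_weights = c("Ambient:Symphonic" = 4,
                                                            "Country:RocknRoll" = 3,
                                                            "Country:HeavyMetal" = 1.5,
                                                            "HeavyMetal:RocknRoll" = 1.5),
                                           jitter_sd = 0.02) {
  if (diag_mass < 0 || diag_mass > 1) stop("diag_mass must be in [0, 1]")
  L <- length(GENRES)
  W <- matrix(1, L, L, dimnames = list(GENRES, GENRES))
  for (nm in names(pair_weights)) {
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    W[ab[1], ab[2]] <- W[ab[2], ab[1]] <- pair_weights[[nm]]
  }
  diag(W) <- 0
  with_seed(rng_seed, {
    if (jitter_sd > 0)
      W <- W * exp(matrix(stats::rnorm(L * L, 0, jitter_sd), L, L))
  })
  diag(W) <- 0
  off <- W / rowSums(W) * (1 - diag_mass)
  cm <- off
  diag(cm) <- diag_mass
  cm
}
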