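# Minimal ABC-notation subset for melody transcriptions: header fields
# X/T/M/L/Q/K, pitch letters with accidentals and octave marks, rests, and
# integer duration multipliers on a 16th-note grid. Chords, ties, beams,
# ornaments and full ABC syntax are out of scope.

NOTE_PC <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

# sharps (+n) / flats (-n) in the key signature, by tonic pitch class & mode
key_signature_accidentals <- function(key_pc, mode) {
  # position on the circle of fifths relative to C (major) / A (minor)
  ref <- if (identical(mode, "minor")) 9L else 0L
  n_sharps <- ((key_pc - ref) * 7) %% 12      # fifths from reference
  if (n_sharps > 6) n_sharps <- n_sharps - 12 # prefer flats past 6 sharps
  sharp_order <- c("F", "C", "G", "D", "A", "E", "B")
  flat_order <- rev(sharp_order)
  acc <- stats::setNames(integer(7), names(NOTE_PC))
  if (n_sharps > 0) acc[sharp_order[seq_len(n_sharps)]] <- 1L
  if (n_sharps < 0) acc[flat_order[seq_len(-n_sharps)]] <- -1L
  acc
}

parse_abc_key <- function(s) {
  m <- regmatches(s, regexec("^([A-Ga-g])([#b]?)\\s*(m|min|minor|maj|major)?$",
                             trimws(s)))[[1]]
  if (length(m) == 0L) stop("unparseable ABC key: ", s)
  pc <- NOTE_PC[toupper(m[2])]
  if (m[3] == "#") pc <- pc + 1L
  if (m[3] == "b") pc <- pc - 1L
  mode <- if (m[4] %in% c("m", "min", "minor")) "minor" else "major"
  list(key_pc = as.integer(pc %% 12L), mode = mode)
}

#' Read a melody transcription in the supported ABC subset
#'
#' Header fields: `X:` (id), `T:` (title), `M:` (meter), `L:` (unit note
#' length, e.g. `1/16`), `Q:` (tempo, `1/4=120`), `K:` (key, e.g. `C`,
#' `Bb`, `Em`). The body holds pitch letters (case/`,`/`'` set octave,
#' which is ignored: only pitch class is kept), `^`/`_`/`=` accidentals,
#' `z` rests, and integer duration multipliers in units of `L`. Key
#' signature accidentals are applied to unmarked notes. Bar lines and
#' whitespace are ignored.
#'
#' @param path text file path (or a character vector of lines via `lines`).
#' @param lines optional character vector overriding `path`.
#' @param duration total duration in seconds; default from the note content.
#' @return a `melody_transcription`.
#' @export
read_abc <- function(path, lines = NULL, duration = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  hdr <- function(tag) {
    h <- grep(paste0("^", tag, ":"), lines, value = TRUE)
    if (length(h)) trimws(sub(paste0("^", tag, ":"), "", h[1])) else NULL
  }
  key <- parse_abc_key(hdr("K") %||% "C")
  unit <- hdr("L") %||% "1/16"
  um <- as.integer(strsplit(unit, "/", fixed = TRUE)[[1]])
  slots_per_unit <- (16L / um[2]) * um[1]
  if (slots_per_unit != round(slots_per_unit))
    stop("unit note length must map to whole 16th-note slots")
  tempo_s <- hdr("Q") %||% "1/4=120"
  tempo <- as.numeric(sub("^.*=", "", tempo_s))
  meter_s <- hdr("M") %||% "4/4"
  meter <- as.integer(strsplit(meter_s, "/", fixed = TRUE)[[1]][1])
  sig <- key_signature_accidentals(key$key_pc, key$mode)

  body <- paste(lines[!grepl("^[A-Za-z]:", lines)], collapse = " ")
  body <- gsub("[|[:space:]]", "", body)
  toks <- regmatches(body, gregexpr("([\\^_=]*[A-Ga-gz][,']*[0-9]*)", body))[[1]]
  ev_pc <- integer(0); ev_on <- integer(0); ev_du <- integer(0)
  t <- 0L
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([\\^_=]*)([A-Ga-gz])[,']*([0-9]*)$", tok))[[1]]
    mult <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    dur <- as.integer(mult * slots_per_unit)
    if (m[3] %in% c("z", "Z")) { t <- t + dur; next }
    letter <- toupper(m[3])
    pc <- NOTE_PC[letter]
    acc <- m[2]
    if (acc == "") pc <- pc + sig[letter]
    else pc <- pc + sum(strsplit(acc, "")[[1]] == "^") -
      sum(strsplit(acc, "")[[1]] == "_")
    ev_pc <- c(ev_pc, as.integer(pc %% 12L))
    ev_on <- c(ev_on, t); ev_du <- c(ev_du, dur)
    t <- t + dur
  }
  slot_dur <- 60 / tempo / 4
  duration <- duration %||% (t * slot_dur)
  structure(list(events = data.frame(pitch_class = ev_pc, onset = ev_on,
                                     duration = ev_du),
                 key_pc = key$key_pc, mode = key$mode, tempo = tempo,
                 meter = meter, n_slots = max(t, round(duration / slot_dur)),
                 duration = duration,
                 stimulus_id = hdr("T") %||% hdr("X") %||% NA_character_),
            class = "melody_transcription")
}

#' Write a melody transcription in the supported ABC subset
#'
#' Inverse of [read_abc()] up to enharmonic spelling: every pitch is written
#' as a natural or sharped letter with an explicit accidental mark, so the
#' round trip reproduces pitch classes exactly.
#'
#' @param melody a `melody_transcription`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abc <- function(melody, path) {
  pc_name <- c("C", "^C", "D", "^D", "E", "F", "^F", "G", "^G", "A", "^A", "B")
  key_name <- c("C", "C#", "D", "Eb", "E", "F", "F#", "G", "Ab", "A", "Bb", "B")
  ev <- melody$events[order(melody$events$onset), , drop = FALSE]
  toks <- character(0)
  t <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$onset[i] > t) toks <- c(toks, paste0("z", ev$onset[i] - t))
    # naturals get an explicit "=" so key-signature accidentals never apply
    nm <- pc_name[ev$pitch_class[i] + 1L]
    if (!startsWith(nm, "^")) nm <- paste0("=", nm)
    toks <- c(toks, paste0(nm, ev$duration[i]))
    t <- ev$onset[i] + ev$duration[i]
  }
  if (melody$n_slots > t) toks <- c(toks, paste0("z", melody$n_slots - t))
  key <- paste0(key_name[melody$key_pc + 1L],
                if (identical(melody$mode, "minor")) "m" else "")
  writeLines(c("X:1",
               paste0("T:", melody$stimulus_id %||% "melody"),
               paste0("M:", melody$meter, "/4"),
               "L:1/16",
               paste0("Q:1/4=", format(melody$tempo)),
               paste0("K:", key),
               paste(toks, collapse = " ")), path)
  invisible(path)
}
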