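#' Quantise a load score to a multiple of the detuning quantum
#'
#' Rounds to the nearest multiple of `quantum` (default 5), so that small
#' loads produce no audible detuning at all. Exact half-quantum ties round
#' away from zero.
#'
#' @param score Nonnegative load score(s).
#' @param quantum Positive integer step.
#' @return Integer multiples of `quantum`.
#' @export
quantize_load <- function(score, quantum = 5L) {
  if (any(is.na(score)) || any(score < 0)) stop("load scores must be nonnegative")
  if (length(quantum) != 1L || is.na(quantum) || quantum <= 0) {
    stop("quantum must be a positive integer")
  }
  as.integer(quantum) * as.integer(floor(score / quantum + 0.5))
}

#' Map a load score to a MIDI pitch-bend value
#'
#' The score is quantised with [quantize_load()] and scaled by a negative
#' constant (default -20), giving downward-only detuning: the larger the
#' load, the flatter the note. Values below the 14-bit floor are clamped to
#' -8192 with a warning (full two-semitone downward bend at the default
#' bend range).
#'
#' @param score Nonnegative load score(s).
#' @param quantum Positive integer rounding step (default 5). `quantum = 1`
#'   scales the raw score without quantisation.
#' @param scale Negative integer multiplier (default -20).
#' @return Integer pitch-bend value(s) in `[-8192, 0]`.
#' @export
load_to_pitchbend <- function(score, quantum = 5L, scale = -20L) {
  if (length(scale) != 1L || is.na(scale) || scale >= 0) {
    stop("scale must be a negative integer")
  }
  bend <- as.integer(scale) * quantize_load(score, quantum)
  clamped <- bend < -8192L
  if (any(clamped)) {
    warning(sum(clamped), " pitch-bend value(s) clamped to -8192")
    bend[clamped] <- -8192L
  }
  bend
}

#' Detune a melody according to a per-scaffold load profile
#'
#' Walks the note onsets of a monophonic single-channel melody and, after an
#' undetuned reference prefix, inserts one pitch-bend event immediately
#' before each onset (zero tick delta between bend and onset), with the bend
#' value mapped from the corresponding scaffold's load by
#' [load_to_pitchbend()]. Onset `skip_prefix + i` receives `scores[i]`; the
#' first `skip_prefix` onsets give the listener an in-tune frame of
#' reference. All original events keep their order, timing, pitch and
#' velocity; because pitch-bend is channel-wide, a polyphonic overlap is an
#' error rather than a misrendered chord.
#'
#' @param track A `melody_track`.
#' @param scores Nonnegative load scores in scaffold order (lexicographic);
#'   there must be at least `skip_prefix + length(scores)` onsets, and
#'   trailing onsets beyond the scores are left untouched.
#' @param quantum,scale Passed to [load_to_pitchbend()].
#' @param skip_prefix Number of leading onsets left undetuned (default 4).
#' @param emit_rpn Also emit the RPN 0 (pitch-bend sensitivity) setup
#'   messages declaring the assumed +/-2 semitone bend range, for synths
#'   that do not default to it.
#' @return A new `melody_track` with the bends inserted.
#' @export
detune_melody <- function(track, scores, quantum = 5L, scale = -20L,
                          skip_prefix = 4L, emit_rpn = FALSE) {
  stopifnot(inherits(track, "melody_track"))
  if (length(skip_prefix) != 1L || is.na(skip_prefix) || skip_prefix < 0) {
    stop("skip_prefix must be a nonnegative integer")
  }
  onsets <- which(track$type == "note_on")
  needed <- skip_prefix + length(scores)
  if (length(onsets) < needed) {
    stop(
      "insufficient notes: melody has ", length(onsets),
      " onsets but skip_prefix + |scores| = ", needed
    )
  }
  check_monophonic(track)
  bends <- load_to_pitchbend(scores, quantum = quantum, scale = scale)
  channel <- track$channel[!is.na(track$channel)][1]
  if (is.na(channel)) channel <- 0L

  events <- tibble::as_tibble(track)
  if (length(scores)) {
    targets <- onsets[skip_prefix + seq_along(scores)]
    bend_rows <- events[targets, ]
    bend_rows$type <- "pitch_bend"
    bend_rows$channel <- channel
    bend_rows$p1 <- NA_integer_
    bend_rows$p2 <- NA_integer_
    bend_rows$value <- as.integer(bends)
    bend_rows$meta_type <- NA_integer_
    bend_rows$data <- vector("list", nrow(bend_rows))
    # bend takes the onset's delta; the onset follows at zero delta
    events$delta[targets] <- 0L
    idx <- order(c(seq_len(nrow(events)), targets - 0.5))
    events <- rbind(events, bend_rows)[idx, ]
  }
  if (emit_rpn) {
    rpn <- tibble::tibble(
      delta = 0L, type = "control_change", channel = channel,
      p1 = c(101L, 100L, 6L, 38L), p2 = c(0L, 0L, 2L, 0L),
      value = NA_integer_, meta_type = NA_integer_,
      data = vector("list", 4)
    )
    events <- rbind(rpn, events)
  }
  new_melody_track(events, ticks_per_beat = attr(track, "ticks_per_beat"))
}

check_monophonic <- function(track) {
  sounding <- integer(0)
  for (i in seq_len(nrow(track))) {
    type <- track$type[i]
    if (type == "note_on") {
      if (length(sounding)) {
        stop(
          "polyphonic overlap: note ", track$p1[i],
          " starts while note ", sounding[1], " is sounding"
        )
      }
      sounding <- c(sounding, track$p1[i])
    } else if (type == "note_off") {
      sounding <- setdiff(sounding, track$p1[i])
    }
  }
  invisible(TRUE)
}

#' Remove all pitch-bend events from a melody track
#'
#' The tick delay of each removed bend is folded into the following event,
#' so note timing is preserved; stripping a detuned melody recovers the
#' original event sequence.
#'
#' @param track A `melody_track`.
#' @return A `melody_track` without pitch-bend events.
#' @export
strip_pitchbend <- function(track) {
  stopifnot(inherits(track, "melody_track"))
  events <- tibble::as_tibble(track)
  keep <- events$type != "pitch_bend"
  # push each dropped delta onto the next surviving event
  carry <- 0L
  delta <- events$delta
  for (i in seq_len(nrow(events))) {
    if (!keep[i]) {
      carry <- carry + delta[i]
    } else {
      delta[i] <- delta[i] + carry
      carry <- 0L
    }
  }
  events$delta <- delta
  new_melody_track(events[keep, ], ticks_per_beat = attr(track, "ticks_per_beat"))
}

#' Extract one cross's load profile from a cross-load table
#'
#' Selects the rows of a long per-cross per-scaffold table (see
#' [read_cross_loads()]) belonging to one cross and returns its scores in
#' lexicographic scaffold order, ready for [detune_melody()].
#'
#' @param cross_loads Tibble with `cross_id`, `scaffold`, `realised_load`.
#' @param cross_id The cross to extract, e.g. `"PP2xPP6"`.
#' @return Named numeric vector of scores (names = scaffolds).
#' @export
profile_scores <- function(cross_loads, cross_id) {
  rows <- cross_loads[cross_loads$cross_id == cross_id, ]
  if (!nrow(rows)) stop("no rows for cross ", cross_id)
  rows <- rows[order(rows$scaffold, method = "radix"), ]
  stats::setNames(rows$realised_load, rows$scaffold)
}

#' Sonify one cross end to end
#'
#' Convenience wrapper: read the melody, pick the cross's per-scaffold
#' profile, detune and write the result.
#'
#' @param melody_path Input Standard MIDI File.
#' @param cross_loads Cross-load table (tibble or CSV path).
#' @param cross_id Cross to sonify.
#' @param out_path Output `.mid` path.
#' @param ... Passed to [detune_melody()].
#' @return The detuned `melody_track`, invisibly.
#' @export
sonify_cross <- function(melody_path, cross_loads, cross_id, out_path, ...) {
  if (is.character(cross_loads)) cross_loads <- read_cross_loads(cross_loads)
  track <- read_melody(melody_path)
  detuned <- detune_melody(track, profile_scores(cross_loads, cross_id), ...)
  write_melody(detuned, out_path)
  invisible(detuned)
}
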