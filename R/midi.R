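#' @title Melody tracks and Standard MIDI File I/O
#' @description
#' A `melody_track` holds the timed events of a monophonic single-channel
#' melody as a tibble with one row per MIDI event and an attribute
#' `ticks_per_beat`. Columns:
#'
#' * `delta` — integer tick delay since the previous event
#' * `type` — `"note_on"`, `"note_off"`, `"pitch_bend"`, `"control_change"`,
#'   `"program_change"`, `"channel_pressure"`, `"poly_pressure"`, `"meta"`,
#'   `"sysex"`
#' * `channel` — 0-based channel for channel events, `NA` otherwise
#' * `p1`, `p2` — data bytes (note and velocity for note events)
#' * `value` — signed 14-bit pitch-bend value in `[-8192, 8191]`
#' * `meta_type` — meta-event type byte (`0x51` = set tempo), or the sysex
#'   status byte
#' * `data` — list column of raw payloads for meta/sysex events
#'
#' Two SMF dialects are normalised on read: running status is expanded, and
#' `note_on` with velocity 0 (the conventional note release) is stored as
#' `note_off`. Note onsets are therefore exactly the `note_on` rows.
#' @name melody_track
NULL

CHANNEL_EVENT_TYPES <- c(
  "note_off", "note_on", "poly_pressure", "control_change",
  "program_change", "channel_pressure", "pitch_bend"
)

#' Construct a melody track from an event table
#'
#' @param events Data frame of events (see [melody_track]); missing optional
#'   columns are filled with `NA`.
#' @param ticks_per_beat Positive integer SMF time division.
#' @return A `melody_track`.
#' @export
new_melody_track <- function(events, ticks_per_beat = 480L) {
  events <- tibble::as_tibble(events)
  for (col in c("channel", "p1", "p2", "value", "meta_type")) {
    if (!col %in% names(events)) events[[col]] <- NA_integer_
  }
  if (!"data" %in% names(events)) events$data <- vector("list", nrow(events))
  stopifnot(
    all(c("delta", "type") %in% names(events)),
    is.numeric(ticks_per_beat), ticks_per_beat > 0
  )
  events$delta <- as.integer(events$delta)
  if (any(events$delta < 0)) stop("negative delta time")
  bad <- setdiff(events$type, c(CHANNEL_EVENT_TYPES, "meta", "sysex"))
  if (length(bad)) stop("unknown event type: ", paste(bad, collapse = ", "))
  events <- events[c(
    "delta", "type", "channel", "p1", "p2", "value", "meta_type", "data"
  )]
  structure(events,
    ticks_per_beat = as.integer(ticks_per_beat),
    class = c("melody_track", class(events))
  )
}

#' @export
print.melody_track <- function(x, ...) {
  cat(
    "<melody_track>", nrow(x), "events,", count_onsets(x), "note onsets,",
    attr(x, "ticks_per_beat"), "ticks/beat\n"
  )
  invisible(x)
}

#' Count note onsets in a melody track
#'
#' Onsets are `note_on` events; after read normalisation these always have
#' velocity > 0 (velocity-0 releases are stored as `note_off`).
#'
#' @param track A `melody_track`.
#' @return Integer count.
#' @export
count_onsets <- function(track) {
  sum(track$type == "note_on")
}

# ---- variable-length quantities ------------------------------------------

decode_varlen <- function(bytes, pos) {
  val <- 0L
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128L + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

encode_varlen <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0L)
  out <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    out <- c(as.raw(128L + x %% 128L), out)
    x <- x %/% 128L
  }
  out
}

uint <- function(bytes, pos, n) {
  sum(as.integer(bytes[pos:(pos + n - 1L)]) * 256^((n - 1L):0))
}

# ---- reading --------------------------------------------------------------

#' Read a monophonic melody from a Standard MIDI File
#'
#' Accepts format 0, or format 1 files in which exactly one track carries
#' channel (note) events; meta events of the other format-1 tracks (tempo,
#' time signature, ...) are merged in at their absolute times. All channel
#' events must sit on a single channel. Running status and
#' `note_on`-velocity-0 releases are normalised (see [melody_track]). The
#' end-of-track meta is stripped on read and regenerated on write, so the
#' round trip is lossless at the event level.
#'
#' @param path Path to a `.mid` file.
#' @return A `melody_track`.
#' @export
read_melody <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14L || rawToChar(bytes[1:4]) != "MThd") {
    stop("not a Standard MIDI File (missing MThd header): ", path)
  }
  if (uint(bytes, 5L, 4L) != 6L) stop("unexpected MThd length")
  format <- uint(bytes, 9L, 2L)
  ntrk <- uint(bytes, 11L, 2L)
  division <- uint(bytes, 13L, 2L)
  if (division >= 32768L) {
    stop("unsupported format: SMPTE time division")
  }
  if (!format %in% c(0L, 1L)) {
    stop("unsupported format: SMF format ", format)
  }
  pos <- 15L
  tracks <- vector("list", ntrk)
  for (t in seq_len(ntrk)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop("corrupt file: expected MTrk chunk")
    }
    len <- uint(bytes, pos + 4L, 4L)
    tracks[[t]] <- parse_track(bytes, pos + 8L, len)
    pos <- pos + 8L + len
  }
  has_channel <- vapply(
    tracks, function(ev) any(ev$type %in% CHANNEL_EVENT_TYPES), logical(1)
  )
  if (sum(has_channel) > 1L) {
    stop(
      "unsupported format: ", sum(has_channel),
      " tracks carry channel events; a single melody track is required"
    )
  }
  events <- if (ntrk == 1L) {
    tracks[[1L]]
  } else {
    merge_tracks(tracks)
  }
  chans <- unique(events$channel[!is.na(events$channel)])
  if (length(chans) > 1L) {
    stop(
      "unsupported format: events on ", length(chans),
      " channels; a single-channel melody is required"
    )
  }
  new_melody_track(events, ticks_per_beat = division)
}

parse_track <- function(bytes, start, len) {
  end <- start + len
  pos <- start
  running <- NA_integer_
  rows <- list()
  i <- 0L
  while (pos < end) {
    dv <- decode_varlen(bytes, pos)
    delta <- dv$value
    pos <- dv$pos
    b <- as.integer(bytes[pos])
    if (b >= 128L) {
      status <- b
      pos <- pos + 1L
    } else {
      if (is.na(running)) stop("corrupt file: data byte without running status")
      status <- running
    }
    i <- i + 1L
    if (status == 255L) { # meta
      meta_type <- as.integer(bytes[pos])
      lv <- decode_varlen(bytes, pos + 1L)
      payload <- if (lv$value > 0L) bytes[lv$pos:(lv$pos + lv$value - 1L)] else raw(0)
      pos <- lv$pos + lv$value
      running <- NA_integer_
      if (meta_type == 47L) { # end of track: stripped, regenerated on write
        i <- i - 1L
        break
      }
      rows[[i]] <- list(
        delta = delta, type = "meta", channel = NA_integer_,
        p1 = NA_integer_, p2 = NA_integer_, value = NA_integer_,
        meta_type = meta_type, data = list(payload)
      )
    } else if (status %in% c(240L, 247L)) { # sysex
      lv <- decode_varlen(bytes, pos)
      payload <- if (lv$value > 0L) bytes[lv$pos:(lv$pos + lv$value - 1L)] else raw(0)
      pos <- lv$pos + lv$value
      running <- NA_integer_
      rows[[i]] <- list(
        delta = delta, type = "sysex", channel = NA_integer_,
        p1 = NA_integer_, p2 = NA_integer_, value = NA_integer_,
        meta_type = status, data = list(payload)
      )
    } else if (status >= 128L) {
      running <- status
      kind <- status %/% 16L
      channel <- status %% 16L
      nbytes <- if (kind %in% c(12L, 13L)) 1L else 2L
      d1 <- as.integer(bytes[pos])
      d2 <- if (nbytes == 2L) as.integer(bytes[pos + 1L]) else NA_integer_
      pos <- pos + nbytes
      type <- switch(as.character(kind),
        "8" = "note_off", "9" = "note_on", "10" = "poly_pressure",
        "11" = "control_change", "12" = "program_change",
        "13" = "channel_pressure", "14" = "pitch_bend"
      )
      value <- NA_integer_
      if (type == "pitch_bend") {
        value <- d1 + 128L * d2 - 8192L
        d1 <- NA_integer_
        d2 <- NA_integer_
      }
      if (type == "note_on" && !is.na(d2) && d2 == 0L) type <- "note_off"
      rows[[i]] <- list(
        delta = delta, type = type, channel = channel,
        p1 = d1, p2 = d2, value = value,
        meta_type = NA_integer_, data = list(NULL)
      )
    } else {
      stop("corrupt file: unexpected status byte ", status)
    }
  }
  rows_to_events(rows[seq_len(i)])
}

rows_to_events <- function(rows) {
  tibble::tibble(
    delta = vapply(rows, function(r) as.integer(r$delta), integer(1)),
    type = vapply(rows, function(r) r$type, character(1)),
    channel = vapply(rows, function(r) r$channel, integer(1)),
    p1 = vapply(rows, function(r) r$p1, integer(1)),
    p2 = vapply(rows, function(r) r$p2, integer(1)),
    value = vapply(rows, function(r) r$value, integer(1)),
    meta_type = vapply(rows, function(r) r$meta_type, integer(1)),
    data = lapply(rows, function(r) r$data[[1]])
  )
}

# Flatten a multi-track format-1 file: absolute-time merge, meta events
# before channel events at equal times, original order otherwise.
merge_tracks <- function(tracks) {
  pieces <- lapply(seq_along(tracks), function(t) {
    ev <- tracks[[t]]
    ev$.abs <- cumsum(ev$delta)
    ev$.trk <- t
    ev$.seq <- seq_len(nrow(ev))
    ev
  })
  all_ev <- do.call(rbind, pieces)
  ord <- order(all_ev$.abs, all_ev$.trk, all_ev$.seq)
  all_ev <- all_ev[ord, ]
  all_ev$delta <- as.integer(c(all_ev$.abs[1], diff(all_ev$.abs)))
  all_ev[setdiff(names(all_ev), c(".abs", ".trk", ".seq"))]
}

# ---- writing --------------------------------------------------------------

#' Write a melody track as a format-0 Standard MIDI File
#'
#' Events are written without running status; `note_off` events with
#' velocity 0 are emitted as `note_on` velocity 0 (the dialect of most
#' sequencer exports); an end-of-track meta is appended.
#'
#' @param track A `melody_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melody <- function(track, path) {
  stopifnot(inherits(track, "melody_track"))
  body <- lapply(seq_len(nrow(track)), function(i) {
    ev <- track[i, ]
    c(encode_varlen(ev$delta), encode_event(ev))
  })
  body <- c(body, list(c(as.raw(0L), as.raw(c(255L, 47L, 0L)))))
  body <- do.call(c, body)
  tpb <- attr(track, "ticks_per_beat")
  header <- c(
    charToRaw("MThd"), uint_bytes(6L, 4L),
    uint_bytes(0L, 2L), uint_bytes(1L, 2L), uint_bytes(tpb, 2L),
    charToRaw("MTrk"), uint_bytes(length(body), 4L)
  )
  writeBin(c(header, body), path)
  invisible(path)
}

uint_bytes <- function(x, n) {
  as.raw((x %/% 256^((n - 1L):0)) %% 256L)
}

encode_event <- function(ev) {
  type <- ev$type
  if (type == "meta") {
    payload <- ev$data[[1]]
    if (is.null(payload)) payload <- raw(0)
    return(c(
      as.raw(255L), as.raw(ev$meta_type),
      encode_varlen(length(payload)), payload
    ))
  }
  if (type == "sysex") {
    payload <- ev$data[[1]]
    if (is.null(payload)) payload <- raw(0)
    return(c(as.raw(ev$meta_type), encode_varlen(length(payload)), payload))
  }
  ch <- ev$channel
  if (is.na(ch)) stop("channel event without channel")
  if (type == "pitch_bend") {
    v <- ev$value + 8192L
    if (v < 0L || v > 16383L) stop("pitch-bend value out of 14-bit range")
    return(as.raw(c(224L + ch, v %% 128L, v %/% 128L)))
  }
  if (type == "note_off" && !is.na(ev$p2) && ev$p2 == 0L) {
    return(as.raw(c(144L + ch, ev$p1, 0L)))
  }
  status <- switch(type,
    note_off = 128L, note_on = 144L, poly_pressure = 160L,
    control_change = 176L, program_change = 192L, channel_pressure = 208L
  ) + ch
  if (type %in% c("program_change", "channel_pressure")) {
    as.raw(c(status, ev$p1))
  } else {
    as.raw(c(status, ev$p1, ev$p2))
  }
}
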