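#' Generate a synthetic founder population
#'
#' Emulates the structure of the study system: a handful of genome-sequenced
#' founders genotyped at several hundred deleterious SNPs spread over the 100
#' largest scaffolds of a draft genome, each SNP weighted by a CADD-like
#' impact score. Deleterious-allele frequencies are drawn from
#' `Beta(af_shape1, af_shape2)` (right-skewed: most harmful alleles are
#' rare), founder genotypes from Hardy-Weinberg proportions at those
#' frequencies, and impact scores from `Gamma(impact_shape, impact_scale)`.
#' The default Gamma parameters were calibrated once so that the maximum
#' expected per-scaffold offspring load over all virtual crosses of the
#' default population falls within the (0, 376] range the method targets.
#'
#' Everything is deterministic for a given seed and the global RNG state is
#' left untouched.
#'
#' @param n_individuals Number of founders (default 6; ids `"PP1"`, ...).
#' @param n_scaffolds Number of scaffolds (default 100; names
#'   `"scaffold_001"`, ... sort lexicographically).
#' @param n_variants Number of deleterious SNPs (default 658).
#' @param af_shape1,af_shape2 Beta parameters of the deleterious-allele
#'   frequency distribution (default 0.5 and 2).
#' @param impact_shape,impact_scale Gamma parameters of the impact-score
#'   distribution.
#' @param seed Integer seed.
#' @param check_load_range If `TRUE`, verify that the maximum expected
#'   per-scaffold offspring load over all crosses does not exceed
#'   `max_load`, and error with a parameter suggestion if it does.
#' @param max_load Calibration ceiling (default 376).
#' @return A `load_population`.
#' @export
generate_population <- function(n_individuals = 6L, n_scaffolds = 100L,
                                n_variants = 658L,
                                af_shape1 = 0.5, af_shape2 = 2,
                                impact_shape = 2, impact_scale = 20,
                                seed = 1L,
                                check_load_range = FALSE, max_load = 376) {
  stopifnot(n_individuals >= 1L, n_scaffolds >= 1L, n_variants >= 0L)
  scaffolds <- sprintf("scaffold_%0*d", max(3L, nchar(n_scaffolds)),
    seq_len(n_scaffolds))
  ids <- sprintf("PP%d", seq_len(n_individuals))
  pop <- withr::with_seed(seed, {
    # every scaffold carries at least one SNP (one melody note per
    # scaffold), the rest are spread uniformly
    scaffold <- if (n_variants >= n_scaffolds) {
      c(scaffolds, sample(scaffolds, n_variants - n_scaffolds, replace = TRUE))
    } else {
      sample(scaffolds, n_variants)
    }
    scaffold <- sort(scaffold, method = "radix")
    # unique (scaffold, position) pairs: sample positions without
    # replacement within each scaffold
    position <- unlist(lapply(split(seq_along(scaffold), scaffold), function(i) {
      sort(sample.int(1e6L, length(i)))
    }), use.names = FALSE)
    freq <- stats::rbeta(n_variants, af_shape1, af_shape2)
    impact <- stats::rgamma(n_variants, shape = impact_shape,
      scale = impact_scale)
    variants <- tibble::tibble(
      variant_id = sprintf("v%04d", seq_len(n_variants)),
      scaffold = scaffold,
      position = as.integer(position),
      impact_score = impact,
      sex_linked = FALSE
    )
    geno <- matrix(
      stats::rbinom(n_variants * n_individuals, 2L, rep(freq, n_individuals)),
      nrow = n_variants, ncol = n_individuals,
      dimnames = list(variants$variant_id, ids)
    )
    load_population(variants, geno)
  })
  if (check_load_range && n_variants > 0L) {
    loads <- cross_all(pop)
    worst <- max(loads$realised_load)
    if (worst > max_load) {
      stop(
        "infeasible calibration: maximum expected per-scaffold offspring ",
        "load ", format(worst, digits = 5), " exceeds ", max_load,
        "; reduce impact_scale or n_variants per scaffold"
      )
    }
  }
  pop
}

# Pitch classes of A harmonic minor around A4, the register of the melody
# the method was designed around.
MELODY_SCALE <- c(57L, 59L, 60L, 62L, 64L, 65L, 68L, 69L, 71L, 72L, 74L, 76L)

#' Generate a synthetic monophonic melody
#'
#' Stands in for a transcribed familiar melody: a seeded random walk over an
#' A-minor scale, one note at a time (strictly monophonic, single channel),
#' with a tempo meta event up front. The default length of 104 onsets leaves
#' 100 notes for detuning after the 4-note reference prefix.
#'
#' @param n_notes Number of note onsets (>= 5 so at least one note can be
#'   detuned after the reference prefix).
#' @param tempo_bpm Tempo in beats per minute.
#' @param ticks_per_beat SMF time division.
#' @param channel MIDI channel (0-based).
#' @param seed Integer seed.
#' @return A `melody_track`.
#' @export
generate_melody <- function(n_notes = 104L, tempo_bpm = 110,
                            ticks_per_beat = 480L, channel = 0L,
                            seed = 1L) {
  if (n_notes < 5L) stop("n_notes must be at least 5")
  notes <- withr::with_seed(seed, {
    idx <- numeric(n_notes)
    idx[1] <- 8L # A4
    for (i in seq_len(n_notes - 1L)) {
      step <- sample(c(-2L, -1L, -1L, 0L, 1L, 1L, 2L), 1L)
      idx[i + 1L] <- min(max(idx[i] + step, 1L), length(MELODY_SCALE))
    }
    MELODY_SCALE[idx]
  })
  dur <- as.integer(ticks_per_beat / 2L) # straight eighth notes
  tempo_us <- as.integer(round(6e7 / tempo_bpm))
  tempo_bytes <- as.raw((tempo_us %/% 256^(2:0)) %% 256L)
  events <- tibble::tibble(
    delta = c(0L, rep(c(0L, dur), n_notes)),
    type = c("meta", rep(c("note_on", "note_off"), n_notes)),
    channel = c(NA_integer_, rep(as.integer(channel), 2L * n_notes)),
    p1 = c(NA_integer_, rep(notes, each = 2L)),
    p2 = c(NA_integer_, rep(c(80L, 0L), n_notes)),
    value = NA_integer_,
    meta_type = c(0x51L, rep(NA_integer_, 2L * n_notes)),
    data = c(list(tempo_bytes), vector("list", 2L * n_notes))
  )
  new_melody_track(events, ticks_per_beat = ticks_per_beat)
}

#' Generate synthetic survey responses
#'
#' Each respondent answers the most-optimal question correctly with
#' probability `p_most` and the least-optimal question with probability
#' `p_least`, independently; a wrong answer is uniform over the wrong
#' options. If the two draws land on the same offspring, the wrong member of
#' the colliding pair is resampled among its remaining wrong options, which
#' keeps both marginal correctness probabilities exact while guaranteeing
#' distinct answers; this resolution needs at least three options unless
#' both probabilities are 1.
#'
#' @param options Labels of the presented offspring (length >= 2).
#' @param truth_most,truth_least True extreme labels (distinct, within
#'   `options`).
#' @param n Number of respondents.
#' @param p_most,p_least Per-question success probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble `respondent_id`, `most_optimal`, `least_optimal`.
#' @export
generate_responses <- function(options, truth_most, truth_least, n,
                               p_most, p_least, seed = 1L) {
  stopifnot(
    length(options) >= 2L, truth_most %in% options, truth_least %in% options,
    truth_most != truth_least, n >= 0L,
    p_most >= 0, p_most <= 1, p_least >= 0, p_least <= 1
  )
  if (length(options) < 3L && (p_most < 1 || p_least < 1)) {
    stop("collision resolution needs at least three options")
  }
  pick <- function(correct, truth) {
    if (correct) return(truth)
    wrong <- setdiff(options, truth)
    wrong[sample.int(length(wrong), 1L)]
  }
  withr::with_seed(seed, {
    most <- character(n)
    least <- character(n)
    for (i in seq_len(n)) {
      most[i] <- pick(stats::runif(1) < p_most, truth_most)
      least[i] <- pick(stats::runif(1) < p_least, truth_least)
      if (least[i] == most[i]) {
        # a collision always involves at least one wrong answer; resample
        # that answer within its wrong set so correctness marginals hold
        if (most[i] != truth_most) {
          wrong <- setdiff(options, c(truth_most, least[i]))
          most[i] <- wrong[sample.int(length(wrong), 1L)]
        } else {
          wrong <- setdiff(options, c(truth_least, most[i]))
          least[i] <- wrong[sample.int(length(wrong), 1L)]
        }
      }
    }
    tibble::tibble(
      respondent_id = sprintf("R%03d", seq_len(n)),
      most_optimal = most,
      least_optimal = least
    )
  })
}
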