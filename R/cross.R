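#' Mendelian transmission probability of a diploid genotype
#'
#' The probability that a parent transmits the deleterious allele to a
#' gamete under Mendelian segregation: 0 for non-carriers, 1/2 for
#' heterozygotes, 1 for homozygotes. `NA` dosages return `NA`.
#'
#' @param dosage Integer dosage(s) in `{0, 1, 2}`.
#' @return Numeric vector of probabilities.
#' @export
transmission_prob <- function(dosage) {
  dosage <- as.integer(dosage)
  if (any(!dosage %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosage must be 0, 1 or 2")
  }
  dosage / 2
}

#' Enumerate all virtual crosses of a founder set
#'
#' All ordered parent pairs including selfing: `n` founders give `n^2`
#' crosses (six founders give the 36 crosses of the deposited data layout).
#' Ids are taken in lexicographic order; the outer loop runs over parent A,
#' the inner over parent B, so the order is stable.
#'
#' @param ids Character vector of individual ids, or a `load_population`.
#' @return Tibble with columns `cross_id` (e.g. `"PP2xPP6"`), `parent_a`,
#'   `parent_b`.
#' @export
enumerate_crosses <- function(ids) {
  if (inherits(ids, "load_population")) ids <- individual_ids(ids)
  ids <- as.character(ids)
  if (!length(ids)) stop("no individuals to cross")
  ids <- sort(unique(ids), method = "radix")
  grid <- expand.grid(parent_b = ids, parent_a = ids,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    cross_id = paste0(grid$parent_a, "x", grid$parent_b),
    parent_a = grid$parent_a,
    parent_b = grid$parent_b
  )
}

#' Expected realised load of a virtual cross's offspring
#'
#' Under Mendelian segregation each parent transmits its deleterious allele
#' with probability `p = dosage / 2`, independently across variants (linkage
#' is ignored). The expected realised contribution of a variant with score
#' `s` is `s * (pA*pB + h*(pA*(1-pB) + pB*(1-pA)))`: the first term is the
#' probability of a homozygous offspring, the second the partially dominant
#' heterozygote. Selfing (`parent_a == parent_b`) uses the same parent's
#' transmission probability twice, so its expectation reduces to
#' `sum(s * p^2)` at `h = 0`. A parent's missing genotype makes the variant
#' contribute 0 (with a warning).
#'
#' Sex-linked variants are scored as autosomal unless `sex_linked_mode =
#' TRUE`, in which case offspring sex is treated as a 50/50 mixture: a
#' heterogametic offspring is hemizygous and expresses the score with the
#' transmission probability of the homogametic parent, while a homogametic
#' offspring is scored diploid. This mode requires both parents' sexes to be
#' known and exactly one parent to be homogametic.
#'
#' @param pop A `load_population`.
#' @param parent_a,parent_b Individual ids; equal ids mean selfing.
#' @param h Dominance coefficient in `[0, 1]`.
#' @param sex_linked_mode Enable hemizygous expectation for sex-linked
#'   variants (default `FALSE`).
#' @return A list of class `cross_result`: `cross_id`, `parent_a`,
#'   `parent_b`, `profile` (per-scaffold tibble, lexicographic order) and
#'   `total` (sum over scaffolds).
#' @export
expected_offspring_profile <- function(pop, parent_a, parent_b, h = 0,
                                       sex_linked_mode = FALSE) {
  stopifnot(inherits(pop, "load_population"))
  check_dominance(h)
  for (p in c(parent_a, parent_b)) {
    if (!p %in% colnames(pop$genotypes)) stop("unknown parent id: ", p)
  }
  ga <- pop$genotypes[, parent_a]
  gb <- pop$genotypes[, parent_b]
  if (anyNA(ga) || anyNA(gb)) {
    warning("missing parental genotypes contribute 0 to the expected load")
  }
  pa <- transmission_prob(ifelse(is.na(ga), 0L, ga))
  pb <- transmission_prob(ifelse(is.na(gb), 0L, gb))
  s <- pop$variants$impact_score
  contrib <- s * (pa * pb + h * (pa * (1 - pb) + pb * (1 - pa)))
  if (sex_linked_mode && any(pop$variants$sex_linked)) {
    sexes <- pop$sex[c(parent_a, parent_b)]
    if (any(sexes == "unknown")) {
      stop("sex_linked_mode requires known parent sexes")
    }
    if (sum(sexes == "homogametic") != 1L) {
      stop("sex_linked_mode requires exactly one homogametic parent")
    }
    p_hom <- if (sexes[[1]] == "homogametic") pa else pb
    sl <- pop$variants$sex_linked
    diploid <- contrib
    contrib[sl] <- 0.5 * s[sl] * p_hom[sl] + 0.5 * diploid[sl]
  }
  profile <- scaffold_profile(contrib, pop$variants$scaffold)
  structure(
    list(
      cross_id = paste0(parent_a, "x", parent_b),
      parent_a = parent_a, parent_b = parent_b,
      profile = profile, total = sum(profile$score)
    ),
    class = "cross_result"
  )
}

#' @export
print.cross_result <- function(x, ...) {
  cat(
    "<cross_result>", x$cross_id, "- expected realised load",
    format(x$total, digits = 6), "over", nrow(x$profile), "scaffolds\n"
  )
  invisible(x)
}

#' Expected per-scaffold realised load for every cross
#'
#' Runs [expected_offspring_profile()] over all ordered parent pairs
#' (including selfing) and stacks the per-scaffold profiles into the long
#' table written as `cross_loads.csv` — the same shape as the deposited
#' per-cross per-scaffold score tables, so such files can be fed to the
#' sonifier directly.
#'
#' @inheritParams expected_offspring_profile
#' @return Tibble with columns `cross_id`, `scaffold`, `realised_load`.
#' @export
cross_all <- function(pop, h = 0, sex_linked_mode = FALSE) {
  crosses <- enumerate_crosses(pop)
  out <- lapply(seq_len(nrow(crosses)), function(i) {
    res <- expected_offspring_profile(
      pop, crosses$parent_a[i], crosses$parent_b[i],
      h = h, sex_linked_mode = sex_linked_mode
    )
    tibble::tibble(
      cross_id = res$cross_id,
      scaffold = res$profile$scaffold,
      realised_load = res$profile$score
    )
  })
  do.call(rbind, out)
}

#' Total expected realised load per cross
#'
#' @param cross_loads A long table as produced by [cross_all()] or
#'   [read_cross_loads()].
#' @return Tibble with columns `cross_id` and `total`, in first-appearance
#'   order of `cross_id`.
#' @export
cross_totals <- function(cross_loads) {
  stopifnot(all(c("cross_id", "realised_load") %in% names(cross_loads)))
  ids <- unique(cross_loads$cross_id)
  tot <- tapply(cross_loads$realised_load,
    factor(cross_loads$cross_id, levels = ids), sum)
  tibble::tibble(cross_id = ids, total = as.numeric(tot))
}

#' Sample one virtual offspring under Mendelian segregation
#'
#' Each parent independently transmits its deleterious allele with
#' probability `dosage / 2` at every variant; the offspring dosage is the sum
#' of the two Bernoulli draws. Deterministic for a given seed; the global RNG
#' state is left untouched. Used for validating the expectation engine and
#' for pedagogy — the expectation is the primary output.
#'
#' @inheritParams expected_offspring_profile
#' @param seed Integer seed for the draw.
#' @return Named integer vector of offspring dosages (one per variant).
#' @export
sample_offspring <- function(pop, parent_a, parent_b, seed) {
  stopifnot(inherits(pop, "load_population"))
  for (p in c(parent_a, parent_b)) {
    if (!p %in% colnames(pop$genotypes)) stop("unknown parent id: ", p)
  }
  ga <- pop$genotypes[, parent_a]
  gb <- pop$genotypes[, parent_b]
  pa <- transmission_prob(ifelse(is.na(ga), 0L, ga))
  pb <- transmission_prob(ifelse(is.na(gb), 0L, gb))
  n <- length(pa)
  withr::with_seed(seed, {
    d <- stats::rbinom(n, 1L, pa) + stats::rbinom(n, 1L, pb)
  })
  stats::setNames(as.integer(d), pop$variants$variant_id)
}

#' Shared genetic load of two prospective parents
#'
#' Sum of impact scores over the variants at which both individuals carry at
#' least one copy of the deleterious allele. Offspring of parents with a high
#' shared load are likely to inherit homozygous harmful variants and suffer
#' inbreeding depression; `shared_load(x, x)` is the individual's own carried
#' load. Missing genotypes count as non-carrying.
#'
#' @param pop A `load_population`.
#' @param a,b Individual ids.
#' @return A single nonnegative number.
#' @export
shared_load <- function(pop, a, b) {
  stopifnot(inherits(pop, "load_population"))
  for (p in c(a, b)) {
    if (!p %in% colnames(pop$genotypes)) stop("unknown individual: ", p)
  }
  ga <- pop$genotypes[, a]
  gb <- pop$genotypes[, b]
  carrier <- !is.na(ga) & ga >= 1L & !is.na(gb) & gb >= 1L
  sum(pop$variants$impact_score[carrier])
}

#' Pairwise shared-load matrix of a population
#'
#' @param pop A `load_population`.
#' @return Symmetric numeric matrix over all individuals (lexicographic id
#'   order); the diagonal holds each individual's own carried load.
#' @export
shared_load_matrix <- function(pop) {
  ids <- sort(individual_ids(pop), method = "radix")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      m[i, j] <- m[j, i] <- shared_load(pop, ids[i], ids[j])
    }
  }
  m
}

#' Write / read the per-cross per-scaffold load table
#'
#' `cross_loads.csv` has columns `cross_id`, `scaffold`, `realised_load`.
#' On read, rows are re-sorted lexicographically by scaffold within each
#' cross so downstream note mapping is deterministic.
#'
#' @param cross_loads Tibble from [cross_all()].
#' @param path Output/input CSV path.
#' @return `write_cross_loads()` returns `path` invisibly;
#'   `read_cross_loads()` returns the tibble.
#' @export
write_cross_loads <- function(cross_loads, path) {
  utils::write.csv(cross_loads, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cross_loads
#' @export
read_cross_loads <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cross_id", "scaffold", "realised_load")
  if (!all(need %in% names(tab))) {
    stop("cross-load table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(tab$realised_load)) || any(tab$realised_load < 0)) {
    stop("realised_load must be nonnegative")
  }
  tab <- tab[order(tab$cross_id, tab$scaffold, method = "radix"), ]
  tibble::as_tibble(tab[need])
}

#' Write the shared-load matrix as CSV
#'
#' Square matrix with individual ids as header row and first column.
#'
#' @param m Matrix from [shared_load_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shared_load_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}
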