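#' Realised-load contribution of one genotype
#'
#' The realised load is the component of the genetic load that reduces fitness
#' in the current generation: homozygous harmful variants express their full
#' impact score, heterozygous variants express a fraction `h` of it (the
#' dominance coefficient; `h = 0` is fully recessive), and hemizygous harmful
#' variants in the heterogametic sex (females, in birds) express the full
#' score from a single copy.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param impact_score Nonnegative impact score(s) of the variant(s).
#' @param dosage Deleterious-allele dosage, 0/1/2 (0/1 at hemizygous sites).
#'   `NA` contributes 0.
#' @param h Dominance coefficient in `[0, 1]`; default 0 (fully recessive).
#' @param sex_linked Logical: is the site on the sex chromosome?
#' @param carrier_sex `"homogametic"`, `"heterogametic"` or `"unknown"`.
#'   Hemizygous scoring applies only when `sex_linked` is `TRUE` and the
#'   carrier is heterogametic; an unknown-sex carrier is scored as diploid.
#' @return Numeric vector of nonnegative contributions.
#' @export
realised_contribution <- function(impact_score, dosage, h = 0,
                                  sex_linked = FALSE,
                                  carrier_sex = "homogametic") {
  check_dominance(h)
  n <- max(length(impact_score), length(dosage), length(sex_linked),
    length(carrier_sex))
  impact_score <- rep_len(impact_score, n)
  dosage <- rep_len(as.integer(dosage), n)
  sex_linked <- rep_len(sex_linked, n)
  carrier_sex <- rep_len(carrier_sex, n)
  if (any(impact_score < 0, na.rm = TRUE)) stop("impact_score must be >= 0")
  if (any(!dosage %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosage must be 0, 1, 2 or NA")
  }
  hemi <- sex_linked & carrier_sex == "heterogametic"
  if (any(hemi & !is.na(dosage) & dosage == 2L)) {
    stop("invalid genotype: dosage 2 at a hemizygous site")
  }
  d <- ifelse(is.na(dosage), 0L, dosage)
  expr <- ifelse(hemi, as.numeric(d >= 1L),
    ifelse(d == 2L, 1, ifelse(d == 1L, h, 0))
  )
  impact_score * expr
}

#' Masked-load contribution of one genotype
#'
#' The masked load sits in heterozygotes whose harmful allele is (partially)
#' recessive: a fraction `1 - h` of the impact score is hidden from selection
#' in the carrier but can be converted to realised load in inbred offspring.
#' Homozygotes and non-carriers mask nothing. Diploid sites only.
#'
#' @inheritParams realised_contribution
#' @return Numeric vector of nonnegative contributions.
#' @export
masked_contribution <- function(impact_score, dosage, h = 0) {
  check_dominance(h)
  n <- max(length(impact_score), length(dosage))
  impact_score <- rep_len(impact_score, n)
  dosage <- rep_len(as.integer(dosage), n)
  if (any(impact_score < 0, na.rm = TRUE)) stop("impact_score must be >= 0")
  if (any(!dosage %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("dosage must be 0, 1, 2 or NA")
  }
  d <- ifelse(is.na(dosage), 0L, dosage)
  impact_score * (1 - h) * (d == 1L)
}

check_dominance <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h > 1) {
    stop("dominance coefficient h must be a single value in [0, 1]")
  }
  invisible(h)
}

#' Per-scaffold load profile of one individual
#'
#' Sums the chosen load component over the variants of each scaffold,
#' weighting each variant by its impact score. Scaffolds are always reported
#' in lexicographic order of their names (the ordering used for sonification,
#' stable across outputs), and scaffolds with no contributing variants appear
#' with score 0. Missing genotypes contribute 0 with a warning; an individual
#' with no called genotype at all is an error.
#'
#' @param pop A `load_population`.
#' @param individual Individual id (a column of the genotype matrix).
#' @param h Dominance coefficient in `[0, 1]`.
#' @param component `"realised"` or `"masked"`.
#' @return A tibble with columns `scaffold` and `score` (one row per
#'   scaffold, lexicographic order, `score >= 0`).
#' @export
per_scaffold_load <- function(pop, individual, h = 0,
                              component = c("realised", "masked")) {
  stopifnot(inherits(pop, "load_population"))
  component <- match.arg(component)
  if (nrow(pop$variants) == 0L) stop("variant table is empty")
  if (!individual %in% colnames(pop$genotypes)) {
    stop("unknown individual: ", individual)
  }
  g <- pop$genotypes[, individual]
  if (all(is.na(g))) {
    stop("all genotypes missing for individual ", individual)
  }
  if (anyNA(g)) {
    warning(
      sum(is.na(g)), " missing genotype(s) for ", individual,
      " contribute 0 to the load"
    )
  }
  contrib <- if (component == "realised") {
    realised_contribution(
      pop$variants$impact_score, g, h,
      sex_linked = pop$variants$sex_linked,
      carrier_sex = pop$sex[[individual]]
    )
  } else {
    masked_contribution(pop$variants$impact_score, g, h)
  }
  scaffold_profile(contrib, pop$variants$scaffold)
}

# Sum per-variant contributions into the lexicographically ordered
# per-scaffold profile; `universe` defaults to the scaffolds present.
scaffold_profile <- function(contrib, scaffold, universe = NULL) {
  if (is.null(universe)) universe <- unique(scaffold)
  universe <- sort(universe, method = "radix")
  f <- factor(scaffold, levels = universe)
  score <- as.numeric(tapply(contrib, f, sum, default = 0))
  tibble::tibble(scaffold = universe, score = score)
}
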