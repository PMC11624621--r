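# Small in-code fixtures and independent oracles shared across test files.

# A hand-built three-founder population: two scaffolds, five variants,
# genotypes chosen so every dosage combination of interest occurs.
tiny_population <- function(sex = NULL) {
  variants <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    scaffold = c("scafA", "scafA", "scafB", "scafB", "scafB"),
    position = c(100L, 200L, 50L, 150L, 250L),
    impact_score = c(5, 7, 10, 3, 4),
    sex_linked = FALSE
  )
  geno <- matrix(
    c(
      2L, 1L, 0L, 1L, 1L, # I1
      0L, 1L, 2L, 0L, 1L, # I2
      0L, 0L, 0L, 2L, 0L # I3
    ),
    nrow = 5, ncol = 3,
    dimnames = list(variants$variant_id, c("I1", "I2", "I3"))
  )
  load_population(variants, geno, sex = sex)
}

# Definitional realised contribution, written from the dominance model
# itself (not via the package), for oracle use.
def_realised <- function(s, d, h) {
  s * ifelse(d == 2, 1, ifelse(d == 1, h, 0))
}

# Brute-force expectation oracle: per locus, enumerate the four equiprobable
# gamete pairs from the parents' explicit allele pairs and average the
# definitional realised contribution of the resulting offspring dosage.
brute_force_cross_total <- function(pop, a, b, h = 0) {
  alleles <- function(d) if (d == 0L) c(0L, 0L) else if (d == 1L) c(0L, 1L) else c(1L, 1L)
  ga <- pop$genotypes[, a]
  gb <- pop$genotypes[, b]
  s <- pop$variants$impact_score
  per_variant <- vapply(seq_along(s), function(v) {
    aa <- alleles(ga[v])
    ab <- alleles(gb[v])
    mean(outer(aa, ab, function(x, y) def_realised(s[v], x + y, h)))
  }, numeric(1))
  tapply(per_variant, factor(pop$variants$scaffold), sum)
}

# Brute-force binomial upper tail by direct pmf summation.
brute_force_binom_upper <- function(x, n, p) {
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# A random small population for property-style loops.
random_population <- function(n_ind, n_var, seed) {
  withr::with_seed(seed, {
    scaf <- sort(sample(c("s1", "s2", "s3"), n_var, replace = TRUE))
    variants <- tibble::tibble(
      variant_id = sprintf("v%d", seq_len(n_var)),
      scaffold = scaf,
      position = seq_len(n_var) * 10L,
      impact_score = round(stats::runif(n_var, 0, 30), 2),
      sex_linked = FALSE
    )
    geno <- matrix(
      sample(0:2, n_var * n_ind, replace = TRUE),
      nrow = n_var,
      dimnames = list(variants$variant_id, sprintf("X%d", seq_len(n_ind)))
    )
    load_population(variants, geno)
  })
}

# The survey response table implied by the published Table 1 margins:
# most-optimal counts A=25, B=0, C=73; least-optimal A=11, B=85, C=2;
# 62 respondents correct on both (most = C and least = B).
table1_responses <- function() {
  cell <- function(m, l, k) {
    if (k == 0) return(NULL)
    tibble::tibble(most_optimal = rep(m, k), least_optimal = rep(l, k))
  }
  out <- do.call(rbind, list(
    cell("C", "B", 62L),
    cell("C", "A", 11L),
    cell("A", "B", 23L),
    cell("A", "C", 2L)
  ))
  out$respondent_id <- sprintf("R%02d", seq_len(nrow(out)))
  out
}
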