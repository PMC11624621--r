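test_that("transmission probability is dosage / 2", {
  expect_equal(transmission_prob(0), 0)
  expect_equal(transmission_prob(1), 0.5)
  expect_equal(transmission_prob(2), 1)
  expect_equal(transmission_prob(c(0, 1, 2)), c(0, 0.5, 1))
  expect_error(transmission_prob(3), "dosage")
  expect_error(transmission_prob(-1), "dosage")
})

test_that("cross enumeration yields all ordered pairs including selfing", {
  crosses6 <- enumerate_crosses(sprintf("PP%d", 1:6))
  expect_equal(nrow(crosses6), 36L)
  expect_true("PP2xPP6" %in% crosses6$cross_id)
  expect_equal(nrow(enumerate_crosses("solo")), 1L)
  crosses3 <- enumerate_crosses(c("b", "a", "c"))
  expect_equal(nrow(crosses3), 9L)
  expect_equal(sum(crosses3$parent_a == crosses3$parent_b), 3L)
  # stable order: lexicographic ids, outer loop parent A
  expect_equal(
    crosses3$cross_id,
    c("axa", "axb", "axc", "bxa", "bxb", "bxc", "cxa", "cxb", "cxc")
  )
  expect_error(enumerate_crosses(character(0)), "no individuals")
})

test_that("expected offspring load matches hand-computable cases", {
  one_var <- function(ga, gb, score = 4) {
    variants <- tibble::tibble(
      variant_id = "v1", scaffold = "s", position = 1L,
      impact_score = score, sex_linked = FALSE
    )
    load_population(variants, matrix(c(ga, gb), 1, 2,
      dimnames = list("v1", c("A", "B"))))
  }
  # het x het: offspring homozygous with probability 1/4
  expect_equal(expected_offspring_profile(one_var(1L, 1L), "A", "B")$total, 1)
  # hom x hom: offspring necessarily homozygous
  expect_equal(expected_offspring_profile(one_var(2L, 2L), "A", "B")$total, 4)
  # het x non-carrier: homozygote impossible
  expect_equal(expected_offspring_profile(one_var(1L, 0L), "A", "B")$total, 0)
  # partial dominance adds the heterozygous fraction
  # P(hom)=1/4, P(het)=1/2 -> 4 * (0.25 + 0.5 h)
  expect_equal(
    expected_offspring_profile(one_var(1L, 1L), "A", "B", h = 0.5)$total,
    4 * 0.5
  )
  expect_error(
    expected_offspring_profile(one_var(1L, 1L), "A", "Z"),
    "unknown parent"
  )
})

test_that("expectation engine agrees with gamete-pair enumeration oracle", {
  for (seed in 1:8) {
    pop <- random_population(n_ind = 4, n_var = 20, seed = seed)
    h <- c(0, 0, 0.25, 0.5, 1, 0.1, 0.9, 0.33)[seed]
    ids <- individual_ids(pop)
    pairs <- list(c(1, 2), c(3, 3), c(2, 4))
    for (p in pairs) {
      res <- expected_offspring_profile(pop, ids[p[1]], ids[p[2]], h = h)
      oracle <- brute_force_cross_total(pop, ids[p[1]], ids[p[2]], h = h)
      expect_equal(res$profile$score, as.numeric(oracle), tolerance = 1e-12)
      expect_equal(res$total, sum(oracle), tolerance = 1e-12)
    }
  }
})

test_that("expected profiles are symmetric in the parents", {
  pop <- random_population(n_ind = 5, n_var = 18, seed = 42)
  ids <- individual_ids(pop)
  for (h in c(0, 0.3)) {
    ab <- expected_offspring_profile(pop, ids[1], ids[4], h = h)
    ba <- expected_offspring_profile(pop, ids[4], ids[1], h = h)
    expect_equal(ab$profile$score, ba$profile$score)
  }
})

test_that("selfing expectation equals the closed form sum of s * p^2 at h = 0", {
  pop <- random_population(n_ind = 3, n_var = 20, seed = 11)
  for (id in individual_ids(pop)) {
    res <- expected_offspring_profile(pop, id, id, h = 0)
    p <- pop$genotypes[, id] / 2
    expect_equal(res$total, sum(pop$variants$impact_score * p^2))
  }
})

test_that("cross result total equals the sum of its profile", {
  pop <- tiny_population()
  res <- expected_offspring_profile(pop, "I1", "I2", h = 0.2)
  expect_equal(res$total, sum(res$profile$score))
  expect_equal(res$profile$scaffold, sort(res$profile$scaffold, method = "radix"))
})

test_that("offspring sampling is seeded, Mendelian and consistent with expectation", {
  pop <- random_population(n_ind = 3, n_var = 20, seed = 5)
  ids <- individual_ids(pop)
  # determinism
  expect_identical(
    sample_offspring(pop, ids[1], ids[2], seed = 99),
    sample_offspring(pop, ids[1], ids[2], seed = 99)
  )
  # double homozygote parents always transmit
  hom <- pop$variants$variant_id[pop$genotypes[, ids[1]] == 2L &
    pop$genotypes[, ids[2]] == 2L]
  off <- sample_offspring(pop, ids[1], ids[2], seed = 1)
  expect_true(all(off[hom] == 2L))
  # selfing a heterozygote: dosage-2 fraction ~ 1/4 within 3 SE at N = 10000
  one <- load_population(
    tibble::tibble(variant_id = "v1", scaffold = "s", position = 1L,
      impact_score = 1, sex_linked = FALSE),
    matrix(1L, 1, 1, dimnames = list("v1", "X"))
  )
  n <- 10000L
  d2 <- vapply(seq_len(n), function(i) {
    sample_offspring(one, "X", "X", seed = 1000L + i)[[1]] == 2L
  }, logical(1))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(d2) - 0.25), 3 * se)
})

test_that("Monte-Carlo mean load converges to the expectation", {
  pop <- random_population(n_ind = 3, n_var = 15, seed = 21)
  ids <- individual_ids(pop)
  expected <- expected_offspring_profile(pop, ids[1], ids[2], h = 0)$total
  n <- 10000L
  s <- pop$variants$impact_score
  totals <- vapply(seq_len(n), function(i) {
    d <- sample_offspring(pop, ids[1], ids[2], seed = 20000L + i)
    sum(s[d == 2L])
  }, numeric(1))
  se <- stats::sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("shared load sums scores over jointly carried variants", {
  pop <- tiny_population()
  # I1 carries v1,v2,v4,v5; I2 carries v2,v3,v5 -> shared v2 (7) + v5 (4)
  expect_equal(shared_load(pop, "I1", "I2"), 11)
  expect_equal(shared_load(pop, "I2", "I1"), 11)
  # disjoint carriers share nothing: I2 (v2,v3,v5) vs I3 (v4)
  expect_equal(shared_load(pop, "I2", "I3"), 0)
  # self-shared load is the individual's own carried load
  expect_equal(shared_load(pop, "I1", "I1"), 5 + 7 + 3 + 4)
  # het in one parent, hom in the other still counts the full score
  expect_equal(shared_load(pop, "I1", "I3"), 3) # v4: dos 1 vs dos 2
  m <- shared_load_matrix(pop)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), c(19, 21, 3))
})

test_that("cross tables round-trip through CSV and preserve totals", {
  pop <- tiny_population()
  loads <- cross_all(pop, h = 0.1)
  expect_equal(nrow(loads), 9L * 2L) # 9 crosses x 2 scaffolds
  f <- withr::local_tempfile(fileext = ".csv")
  write_cross_loads(loads, f)
  back <- read_cross_loads(f)
  expect_equal(back$realised_load, loads$realised_load, tolerance = 1e-8)
  tot <- cross_totals(back)
  res <- expected_offspring_profile(pop, "I1", "I2", h = 0.1)
  expect_equal(tot$total[tot$cross_id == "I1xI2"], res$total, tolerance = 1e-8)
  mf <- withr::local_tempfile(fileext = ".csv")
  write_shared_load_matrix(shared_load_matrix(pop), mf)
  m2 <- as.matrix(utils::read.csv(mf, row.names = 1))
  expect_equal(unname(m2), unname(shared_load_matrix(pop)))
})

test_that("sex-linked expectation mode mixes offspring sexes 50/50", {
  variants <- tibble::tibble(
    variant_id = c("a1", "z1"), scaffold = c("s1", "s2"),
    position = c(1L, 1L), impact_score = c(6, 10),
    sex_linked = c(FALSE, TRUE)
  )
  geno <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
    dimnames = list(c("a1", "z1"), c("M", "F")))
  pop <- load_population(variants, geno,
    sex = c(M = "homogametic", F = "heterogametic"))
  res <- expected_offspring_profile(pop, "M", "F", sex_linked_mode = TRUE)
  # autosomal: 6 * 0.25; sex-linked: 0.5 * 10 * pM + 0.5 * 10 * pM * pF
  expect_equal(res$profile$score, c(6 * 0.25, 0.5 * 10 * 0.5 + 0.5 * 10 * 0.25))
  expect_error(
    expected_offspring_profile(
      load_population(variants, geno), "M", "F", sex_linked_mode = TRUE
    ),
    "known parent sexes"
  )
})
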