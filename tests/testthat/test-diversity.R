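geno_from_counts <- function(pairs, pop = NULL) {
  # pairs: list of c(a1, a2) per individual at one locus
  a1 <- matrix(vapply(pairs, `[`, 0L, 1L), ncol = 1)
  a2 <- matrix(vapply(pairs, `[`, 0L, 2L), ncol = 1)
  n <- nrow(a1)
  if (is.null(pop)) pop <- rep("P1", n)
  genotypes(paste0("s", seq_len(n)), pop, "L1", a1, a2)
}

test_that("observed heterozygosity is a direct count", {
  gm <- geno_from_counts(list(c(1L, 2L), c(1L, 1L), c(2L, 3L),
                              c(3L, 3L), c(1L, 3L)))
  expect_equal(observed_heterozygosity(gm, "P1", "L1"), 3 / 5)
  all_het <- geno_from_counts(list(c(1L, 2L), c(2L, 3L)))
  expect_equal(observed_heterozygosity(all_het, "P1", "L1"), 1)
  all_hom <- geno_from_counts(list(c(1L, 1L), c(2L, 2L)))
  expect_equal(observed_heterozygosity(all_hom, "P1", "L1"), 0)
})

test_that("unbiased expected heterozygosity matches the closed form", {
  # n = 5 genotypes, allele counts {6, 4}: (10/9) * (1 - .36 - .16)
  gm <- geno_from_counts(list(c(1L, 1L), c(1L, 1L), c(1L, 2L),
                              c(2L, 2L), c(1L, 2L)))
  expect_equal(expected_heterozygosity(gm, "P1", "L1"),
               (10 / 9) * (1 - 0.36 - 0.16))
  mono <- geno_from_counts(list(c(1L, 1L), c(1L, 1L)))
  expect_equal(expected_heterozygosity(mono, "P1", "L1"), 0)
})

test_that("unbiased gene diversity equals exhaustive pair counting", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    copies <- sample.int(4, 2 * n, replace = TRUE)
    gm <- geno_from_counts(split(copies, rep(seq_len(n), each = 2)) |>
                             lapply(as.integer))
    expect_equal(expected_heterozygosity(gm, "P1", "L1"),
                 oracle_exp_het(copies), tolerance = 1e-12)
  }
})

test_that("allelic richness matches subset enumeration and edge cases", {
  # copies {A,A,A,B}, g = 2 -> 1.5
  gm <- geno_from_counts(list(c(1L, 1L), c(1L, 2L)))
  expect_equal(allelic_richness(gm, "P1", "L1", 2), 1.5)
  # g = N_c recovers the observed allele count
  expect_equal(allelic_richness(gm, "P1", "L1", 4), 2)
  mono <- geno_from_counts(list(c(7L, 7L), c(7L, 7L)))
  for (g in 1:4) expect_equal(allelic_richness(mono, "P1", "L1", g), 1)
  expect_error(allelic_richness(gm, "P1", "L1", 5), "exceeds")
})

test_that("Weir-Cockerham components equal the independent transcription", {
  set.seed(71)
  for (rep in 1:50) {
    gm <- random_genotypes(sample(6:20, 1), sample(1:4, 1),
                           npop = sample(2:4, 1), n_alleles = 3, miss = 0.1)
    for (l in seq_along(gm$loci)) {
      got <- wc_components(gm, l)
      o <- oracle_wc(gm$a1[, l], gm$a2[, l], gm$pop)
      if (anyNA(o)) {
        expect_false(attr(got, "informative"))
      } else {
        expect_equal(as.numeric(got), as.numeric(o), tolerance = 1e-12)
      }
    }
  }
})

test_that("the spec'd two-population table matches the oracle exactly", {
  # pop1 {AA:2, Aa:2, aa:1}, pop2 {AA:1, Aa:1, aa:3}
  gm <- geno_from_counts(list(c(1L, 1L), c(1L, 1L), c(1L, 2L), c(1L, 2L),
                              c(2L, 2L),
                              c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 2L),
                              c(2L, 2L)),
                         pop = rep(c("P1", "P2"), each = 5))
  got <- wc_components(gm, "L1")
  o <- oracle_wc(gm$a1[, 1], gm$a2[, 1], gm$pop)
  expect_equal(as.numeric(got), as.numeric(o), tolerance = 1e-12)
})

test_that("theta is 1 under complete fixation and ~0 under panmixia", {
  fix <- geno_from_counts(list(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 2L)),
                          pop = c("A", "A", "B", "B"))
  expect_equal(pairwise_theta(fix, "A", "B"), 1)
  # random halves of one panmictic pool centre on zero
  set.seed(81)
  scn <- panmictic_scenario()
  th <- replicate(20, {
    d <- simulate_dataset(scn, c(Ne = 2000), c(A = 60), n_loci = 5,
                          mu_mean = 5e-4)
    gm <- genotypes(d$ids, rep(c("X", "Y"), 30), d$loci, d$a1, d$a2)
    pairwise_theta(gm, "X", "Y")
  })
  expect_lt(abs(mean(th)), 0.02)
})

test_that("multilocus estimators are ratio-of-sums and locus-order invariant", {
  set.seed(91)
  gm <- random_genotypes(16, 4, npop = 2, n_alleles = 3, miss = 0.1)
  th <- pairwise_theta(gm, "P1", "P2")
  comp <- vapply(seq_len(4), function(l) wc_components(gm, l), numeric(3))
  inf <- vapply(seq_len(4), function(l)
    attr(wc_components(gm, l), "informative"), logical(1))
  expect_equal(th, sum(comp[1, inf]) / sum(comp[, inf]), tolerance = 1e-12)
  # permute loci: unchanged
  gmp <- genotypes(gm$ids, gm$pop, gm$loci[4:1], gm$a1[, 4:1], gm$a2[, 4:1])
  expect_equal(pairwise_theta(gmp, "P1", "P2"), th, tolerance = 1e-12)
  # appending an uninformative (monomorphic) locus changes nothing
  gm5 <- genotypes(gm$ids, gm$pop, c(gm$loci, "L5"),
                   cbind(gm$a1, 9L), cbind(gm$a2, 9L))
  expect_equal(pairwise_theta(gm5, "P1", "P2"), th, tolerance = 1e-12)
})

test_that("multilocus f matches the single-population oracle and signs", {
  set.seed(101)
  for (rep in 1:20) {
    gm <- random_genotypes(10, 3, npop = 1, n_alleles = 3, miss = 0.1)
    o <- vapply(1:3, function(l)
      oracle_fis_components(gm$a1[, l], gm$a2[, l]), numeric(2))
    keep <- !apply(o, 2, anyNA)
    if (!any(keep)) next
    f_oracle <- 1 - sum(o[2, keep]) / sum(colSums(o[, keep, drop = FALSE]))
    expect_equal(multilocus_fis(gm, "P1"), f_oracle, tolerance = 1e-12)
  }
  # no heterozygotes but 2 alleles -> f = 1; all heterozygotes -> f < 0
  hom <- geno_from_counts(list(c(1L, 1L), c(2L, 2L), c(1L, 1L)))
  expect_equal(multilocus_fis(hom, "P1"), 1)
  het <- geno_from_counts(list(c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  expect_lt(multilocus_fis(het, "P1"), 0)
})

test_that("permutation p-values: bounds, determinism, one-sidedness", {
  fix <- geno_from_counts(rep(list(c(1L, 1L)), 6), pop = rep(c("A", "B"), 3))
  fix$a1[fix$pop == "B", 1] <- 2L; fix$a2[fix$pop == "B", 1] <- 2L
  gm <- genotypes(fix$ids, fix$pop, "L1", fix$a1, fix$a2)
  pt <- permutation_test(gm, c("A", "B"), "genotypes", B = 99, seed = 1)
  # observed theta = 1 beats every permutation that mixes the groups
  expect_equal(pt$observed, 1)
  expect_lt(pt$p_value, 0.12)
  pt2 <- permutation_test(gm, c("A", "B"), "genotypes", B = 99, seed = 1)
  expect_identical(pt$p_value, pt2$p_value)
  # p never reports zero
  expect_gte(pt$p_value, 1 / 100)
})

test_that("adjusted nominal levels reproduce the printed thresholds", {
  expect_equal(adjusted_nominal_level(0.05, 1), 0.05)
  expect_equal(signif(adjusted_nominal_level(0.05, choose(12, 2)), 3),
               0.000758)
  expect_equal(round(adjusted_nominal_level(0.05, 22), 4), 0.0023)
})

test_that("diversity table and theta matrix have the reported shapes", {
  set.seed(111)
  gm <- random_genotypes(24, 3, npop = 3, n_alleles = 4, miss = 0.05)
  dt <- diversity_table(gm, B = 100, seed = 1)
  expect_s3_class(dt, "diversity_table")
  expect_equal(nrow(dt), 3L)
  expect_true(all(dt$H_exp >= 0 & dt$H_exp <= 1))
  expect_true(all(dt$H_obs >= 0 & dt$H_obs <= 1))
  expect_true(all(dt$F_IS >= -1 & dt$F_IS <= 1))
  expect_true(all(dt$allelic_richness >= 1))
  fm <- fst_matrix(gm, B = 100, seed = 2)
  expect_s3_class(fm, "fst_matrix")
  expect_equal(diag(fm$theta), rep(0, 3), ignore_attr = TRUE)
  expect_equal(fm$theta, t(fm$theta))
  expect_equal(fm$adjusted_level, 0.05 / 3)
  expect_equal(fm$significant, !is.na(fm$p_value) & fm$p_value < 0.05 / 3)
  # identical seed reproduces identical matrices
  fm2 <- fst_matrix(gm, B = 100, seed = 2)
  expect_identical(fm$p_value, fm2$p_value)
})
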