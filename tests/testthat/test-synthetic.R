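test_that("the study-shaped bundle reproduces the sampling design", {
  b <- make_study_like(seed = 5, scale = 1, clone_pairs = 0, n_loci = 4)
  expect_equal(length(b$clean$ids), 331L)
  expect_equal(nlevels(b$clean$pop), 12L)
  expect_setequal(levels(b$clean$pop), meadow_design()$meadow)
  expect_equal(as.integer(table(b$clean$pop)[meadow_design()$meadow]),
               meadow_design()$n)
  # identical seed reproduces the bundle
  b2 <- make_study_like(seed = 5, scale = 1, clone_pairs = 0, n_loci = 4)
  expect_identical(b$clean$a1, b2$clean$a1)
})

test_that("scaled bundles give pairwise theta in the study's range", {
  set.seed(55)
  th <- c()
  for (s in 1:3) {
    b <- make_study_like(seed = s, scale = 0.3, clone_pairs = 0,
                         n_loci = 10)
    pooled <- pool_populations(b$clean, deme_pooling_map(), drop = "CYP")
    st <- summary_stats(pooled)
    th <- c(th, st[grep("^fst_", names(st))])
  }
  expect_gt(mean(th > 0.01 & th < 0.35), 0.8)
})

test_that("clone injection is recovered exactly by the clonality module", {
  b <- make_study_like(seed = 6, scale = 0.25, clone_pairs = 3,
                       n_loci = 10)
  expect_equal(nrow(b$clone_ledger), 3L)
  part <- collapse_mll(identify_mlg(b$corrupted), b$corrupted, 2L)
  n <- length(b$corrupted$ids)
  expect_equal(max(part$mll_of), n - 3L)
  # the collapsed pairs are exactly the injected ones
  mll <- part$mll_of[part$mlg_of]
  dup <- names(which(table(mll) == 2))
  joined <- vapply(dup, function(k)
    paste(sort(b$corrupted$ids[mll == as.integer(k)]), collapse = "+"), "")
  truth <- apply(b$clone_ledger[, c("original", "copy")], 1, function(r)
    paste(sort(r), collapse = "+"))
  expect_setequal(unname(joined), unname(truth))
})

test_that("zero clone pairs leave every MLG unique", {
  b <- make_study_like(seed = 7, scale = 0.15, clone_pairs = 0, n_loci = 8)
  p <- identify_mlg(b$corrupted)
  expect_equal(max(p$mlg_of), length(b$corrupted$ids))
})

test_that("null-allele injection: ledger, missing rate, heterozygote deficit", {
  b <- make_study_like(seed = 8, scale = 0.3, clone_pairs = 0,
                       null_freq = 0.2, n_loci = 12)
  clean <- b$clean; cor <- b$corrupted
  # ledger exactly describes the clean->corrupted difference
  changed <- which((is.na(cor$a1) & !is.na(clean$a1)) |
                     (!is.na(cor$a1) & !is.na(clean$a1) &
                        (cor$a1 != clean$a1 | cor$a2 != clean$a2)))
  expect_equal(length(changed), nrow(b$null_ledger))
  # missing rate ~ freq^2
  extra_missing <- mean(is.na(cor$a1) & !is.na(clean$a1))
  expect_equal(extra_missing, 0.04, tolerance = 0.35)
  # induced heterozygote deficit: F_IS flips positive
  pooled_cor <- pool_populations(cor, deme_pooling_map(), drop = "CYP")
  pooled_cln <- pool_populations(clean, deme_pooling_map(), drop = "CYP")
  f_cor <- vapply(levels(pooled_cor$pop), function(p)
    multilocus_fis(pooled_cor, p), numeric(1))
  f_cln <- vapply(levels(pooled_cln$pop), function(p)
    multilocus_fis(pooled_cln, p), numeric(1))
  expect_true(all(f_cor > f_cln))
  expect_gt(mean(f_cor), 0.1)
  expect_lt(abs(mean(f_cln)), 0.06)
})

test_that("injections never touch missing calls and freq 0 is the identity", {
  set.seed(9)
  gm <- random_genotypes(20, 5, npop = 2, miss = 0.2)
  same <- inject_null_alleles(gm, 0)
  expect_identical(same$a1, gm$a1)
  cl <- inject_clones(gm, 2, max_distance = 1, seed = 1)
  led <- attr(cl, "clone_ledger")
  for (r in seq_len(nrow(led))) {
    i <- match(led$original[r], gm$ids); j <- match(led$copy[r], gm$ids)
    # the copy's missing pattern equals the original's (edits skip missing)
    expect_equal(is.na(cl$a1[j, ]), is.na(gm$a1[i, ]), ignore_attr = TRUE)
  }
})

test_that("truth bundles round-trip through genepop + JSON ledger", {
  b <- make_study_like(seed = 10, scale = 0.1, clone_pairs = 1, n_loci = 5)
  dir <- withr::local_tempdir()
  paths <- write_truth_bundle(b, dir)
  back <- read_genepop(file.path(dir, "synthetic_genotypes.gen"))
  expect_equal(length(back$ids), length(b$corrupted$ids))
  led <- jsonlite::read_json(file.path(dir, "truth_ledger.json"))
  expect_equal(led$scenario, "scenario13")
  expect_equal(length(led$clone_pairs), 1L)
  expect_true(!is.null(led$clone_pairs[[1]]$original))
})
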