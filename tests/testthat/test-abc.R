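# a small shared reference table, built once per test run
local_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      scns <- list(scenario13 = scenario13(),
                   alternative = scenario_alternative())
      ref <<- build_reference_table(scns, c(N = 8, NE = 8, NW = 8, CW = 8),
                                    n_per_scenario = 400, n_loci = 6,
                                    seed = 900)
    }
    ref
  }
})

test_that("the summary panel has 2K + choose(K,2) ordered entries", {
  set.seed(22)
  scn <- scenario13()
  par <- c(Ne1 = 2000, Ne2 = 2000, Ne3 = 2000, Ne4 = 2000, Na = 500,
           t0 = 50, t2 = 300, t3 = 2000)
  d <- simulate_dataset(scn, par, c(N = 6, NE = 6, NW = 6, CW = 6),
                        n_loci = 4)
  st <- summary_stats(d)
  expect_length(st, 4 + 4 + 6)
  expect_named(st, c(paste0("nal_", c("N", "NE", "NW", "CW")),
                     paste0("het_", c("N", "NE", "NW", "CW")),
                     "fst_N_NE", "fst_N_NW", "fst_CW_N", "fst_NE_NW",
                     "fst_CW_NE", "fst_CW_NW"))
  # recomputation is idempotent
  expect_identical(st, summary_stats(d))
})

test_that("statistically identical demes give near-zero theta entries", {
  scn <- panmictic_scenario()
  set.seed(23)
  d <- simulate_dataset(scn, c(Ne = 2000), c(A = 40), n_loci = 8,
                        mu_mean = 5e-4)
  gm <- genotypes(d$ids, rep(c("X", "Y"), each = 20), d$loci, d$a1, d$a2)
  st <- summary_stats(gm)
  expect_lt(abs(st[["fst_X_Y"]]), 0.05)
})

test_that("reference tables are seed-deterministic and batch-resumable", {
  scns <- list(scenario13 = scenario13(),
               alternative = scenario_alternative())
  sizes <- c(N = 4, NE = 4, NW = 4, CW = 4)
  one <- build_reference_table(scns, sizes, n_per_scenario = 6, n_loci = 3,
                               seed = 31)
  expect_equal(nrow(one$stats), 12L)
  expect_equal(as.integer(table(one$scenario)), c(6L, 6L))
  # regenerate in two batches: identical
  b1 <- build_reference_table(scns, sizes, 6, n_loci = 3, seed = 31,
                              rows = 1:5)
  b2 <- build_reference_table(scns, sizes, 6, n_loci = 3, seed = 31,
                              rows = 6:12)
  merged <- b1$stats
  merged[6:12, ] <- b2$stats[6:12, ]
  expect_identical(merged, one$stats)
  # parameters respect scenario priors
  expect_true(all(one$params[, "t2"] < one$params[, "t3"]))
})

test_that("rejection keeps the closest rows and honours trivial cases", {
  ref <- local_ref()
  obs <- ref$stats[7, ]
  ret <- abc_rejection(ref, obs, 0.01)
  expect_equal(ret$index[1], 7L)
  expect_equal(ret$distance[1], 0)
  all_ret <- abc_rejection(ref, obs, 1)
  expect_equal(length(all_ret$index), nrow(ref$stats))
})

test_that("distances are invariant to rescaling a raw statistic", {
  ref <- local_ref()
  obs <- summary_stats_from_row <- ref$stats[11, ] * 1.01
  ret1 <- abc_rejection(ref, obs, 0.05)
  ref2 <- ref
  ref2$stats[, "het_N"] <- 2 * ref2$stats[, "het_N"]
  obs2 <- obs; obs2["het_N"] <- 2 * obs2["het_N"]
  ret2 <- abc_rejection(ref2, obs2, 0.05)
  expect_equal(ret1$index, ret2$index)
  expect_equal(ret1$distance, ret2$distance, tolerance = 1e-12)
})

test_that("direct scenario posterior is a frequency that sums to one", {
  ref <- local_ref()
  obs <- ref$stats[3, ]
  ret <- abc_rejection(ref, obs, 0.1)
  p <- model_posterior_direct(ret, 40)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # single-scenario retained set gives probability one
  sub <- ret
  keep <- sub$scenario == "scenario13"
  sub$index <- sub$index[keep]; sub$distance <- sub$distance[keep]
  sub$dev <- sub$dev[keep, , drop = FALSE]
  sub$scenario <- sub$scenario[keep]
  expect_equal(unname(model_posterior_direct(sub)["scenario13"]), 1)
})

test_that("logistic scenario posterior: separable case, degenerate case", {
  ref <- local_ref()
  ret <- abc_rejection(ref, ref$stats[3, ], 0.25)
  # perfectly separable synthetic deviations
  sep <- ret
  n <- length(sep$index)
  half <- rep(c(0, 4), length.out = n)
  sep$dev <- cbind(sep$dev[, 1:3, drop = FALSE], sepstat = half)
  sep$scenario <- factor(ifelse(half == 0, "scenario13", "alternative"),
                         levels = levels(ret$scenario))
  p <- suppressWarnings(model_posterior_logistic(sep, decay = 1e-6))
  expect_gt(p[["scenario13"]], 0.95)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # all-one-scenario: degenerate direct estimate with a warning
  one <- ret
  keep <- one$scenario == "alternative"
  one$index <- one$index[keep]; one$distance <- one$distance[keep]
  one$dev <- one$dev[keep, , drop = FALSE]
  one$scenario <- one$scenario[keep]
  expect_warning(pl <- model_posterior_logistic(one), "one scenario")
  expect_equal(unname(pl[["alternative"]]), 1)
})

test_that("logistic estimate is invariant to a constant added statistic", {
  ref <- local_ref()
  ret <- abc_rejection(ref, ref$stats[9, ], 0.25)
  p0 <- suppressWarnings(model_posterior_logistic(ret))
  ret2 <- ret
  ret2$dev <- cbind(ret$dev, const = 0)
  p1 <- suppressWarnings(model_posterior_logistic(ret2))
  expect_equal(p0, p1, tolerance = 1e-6)
})

test_that("direct and logistic estimates agree on well-mixed cases", {
  # observed at the centre of the simulated cloud, where the scenario
  # composition is locally balanced
  ref <- local_ref()
  centre <- apply(ref$stats, 2, stats::median, na.rm = TRUE)
  for (rf in c(0.1, 0.25)) {
    ret <- abc_rejection(ref, centre, rf)
    pd <- model_posterior_direct(ret, length(ret$index))
    pl <- suppressWarnings(model_posterior_logistic(ret))
    expect_lt(max(abs(pd - pl[names(pd)])), 0.15)
  }
})

test_that("parameter posteriors order their quantiles and stay in bounds", {
  ref <- local_ref()
  obs <- ref$stats[5, ]
  ret <- abc_rejection(ref, obs, 0.5)
  post <- parameter_posterior(ret, "scenario13")
  expect_true(all(post$q2.5 <= post$median & post$median <= post$q97.5))
  s13 <- ref$scenarios$scenario13
  for (pn in names(s13$priors)) {
    expect_gte(post[pn, "q2.5"], s13$priors[[pn]]$lower)
    expect_lte(post[pn, "q97.5"], s13$priors[[pn]]$upper)
  }
  expect_error(parameter_posterior(ret, "scenario13", min_rows = 1e6),
               "retained rows")
})

test_that("zero-deviation retained rows make the adjustment an identity", {
  ref <- local_ref()
  ret <- abc_rejection(ref, ref$stats[5, ], 0.5)
  sel <- ret$scenario == "scenario13"
  ret$dev[] <- 0
  post <- parameter_posterior(ret, "scenario13")
  draws <- attr(post, "draws")
  raw <- ret$ref$params[ret$index[sel], colnames(draws)]
  expect_equal(unname(draws), unname(raw), tolerance = 1e-6)
})

test_that("posterior predictive checks are seeded and return tails in [0,1]", {
  ref <- local_ref()
  obs <- ref$stats[5, ]
  ret <- abc_rejection(ref, obs, 0.5)
  post <- parameter_posterior(ret, "scenario13")
  pp1 <- posterior_predictive_check(post, obs, ret, n_rep = 8, seed = 42)
  pp2 <- posterior_predictive_check(post, obs, ret, n_rep = 8, seed = 42)
  expect_identical(pp1, pp2)
  expect_true(all(pp1 >= 0 & pp1 <= 1))
  expect_named(pp1, names(obs))
})
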