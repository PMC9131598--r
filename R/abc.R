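# ABC over divergence scenarios: summary statistics, reference-table
# simulation, rejection, scenario choice (direct + multinomial logistic),
# Beaumont-style local-linear parameter posteriors, and posterior
# predictive checks.

summary_stat_names <- function(demes) {
  K <- length(demes)
  pairs <- utils::combn(K, 2)
  # pair names use sorted deme labels so vectors computed under different
  # deme orderings align by name (theta is symmetric)
  pn <- apply(pairs, 2L, function(pr)
    paste0("fst_", paste(sort(demes[pr]), collapse = "_")))
  c(paste0("nal_", demes), paste0("het_", demes), pn)
}

#' Summary statistics of a genotype data set
#'
#' The ABC summary panel: per deme the mean number of alleles per locus and
#' mean unbiased gene diversity (expected heterozygosity), and multilocus
#' Weir-Cockerham theta for every deme pair. For `K` demes the vector has
#' `2K + choose(K,2)` entries in a fixed order. Theta entries undefined for
#' lack of polymorphism are returned `NA` (imputed as 0 and masked during
#' rejection).
#'
#' @param gm a [genotypes] object pooled to the ABC demes.
#' @return named numeric vector.
#' @export
summary_stats <- function(gm) {
  demes <- levels(gm$pop)
  K <- length(demes)
  if (K < 2L) stop("need >= 2 demes")
  L <- length(gm$loci)
  nal <- het <- numeric(K)
  for (p in seq_len(K)) {
    ix <- pop_index(gm, demes[p])
    nav <- hev <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      al <- c(gm$a1[ix, l], gm$a2[ix, l]); al <- al[!is.na(al)]
      nav[l] <- length(unique(al))
      if (length(al) >= 2L) {
        pa <- tabulate(factor(al)) / length(al)
        hev[l] <- (length(al) / (length(al) - 1)) * (1 - sum(pa^2))
      } else hev[l] <- 0
    }
    nal[p] <- mean(nav); het[p] <- mean(hev, na.rm = TRUE)
  }
  pairs <- utils::combn(K, 2)
  th <- apply(pairs, 2L, function(pr)
    tryCatch(pairwise_theta(gm, demes[pr[1]], demes[pr[2]]),
             error = function(e) NA_real_))
  stats::setNames(c(nal, het, th), summary_stat_names(demes))
}

#' Build an ABC reference table
#'
#' For each scenario, draws `n_per_scenario` parameter vectors from the
#' priors and simulates a data set and its summary-statistic vector for
#' each. Row `i` of the table is generated under its own seed derived from
#' `seed`, so the table can be built in batches (any subset of `rows`) and
#' is bit-identical to a one-shot run.
#'
#' @param scenarios named list of [scenario] objects (all over the same
#'   demes).
#' @param sizes named integer vector of diploid sample sizes per deme.
#' @param n_per_scenario rows simulated per scenario.
#' @param n_loci loci per simulated data set.
#' @param mu_prior length-2 range of the log-uniform prior on the mean
#'   mutation rate.
#' @param P_prior length-2 range of the uniform prior on the GSM parameter.
#' @param ladder allele-state ladder bounds.
#' @param seed integer seed (keep below 2^31 minus the row count).
#' @param rows optional integer subset of row indices to (re)generate.
#' @return object of class `abc_reftable`: `stats` matrix, `params` matrix,
#'   `scenario` factor, and the generating settings.
#' @export
build_reference_table <- function(scenarios, sizes, n_per_scenario,
                                  n_loci = 18L, mu_prior = c(1e-4, 1e-3),
                                  P_prior = c(0, 0.3), ladder = c(1, 200),
                                  seed = 1L, rows = NULL) {
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  nS <- length(scenarios)
  ntot <- nS * n_per_scenario
  demes <- scenarios[[1]]$demes
  pnames <- unique(unlist(lapply(scenarios, function(s) names(s$priors))))
  pnames <- c(pnames, "mu_mean", "P")
  snames <- summary_stat_names(demes)
  stats_m <- matrix(NA_real_, ntot, length(snames),
                    dimnames = list(NULL, snames))
  params_m <- matrix(NA_real_, ntot, length(pnames),
                     dimnames = list(NULL, pnames))
  scen_id <- factor(rep(names(scenarios), each = n_per_scenario),
                    levels = names(scenarios))
  if (is.null(rows)) rows <- seq_len(ntot)
  for (i in rows) {
    set.seed(seed + i)
    s <- scenarios[[as.integer(scen_id[i])]]
    par <- sample_priors(s, 1L)[1L, ]
    mu <- exp(stats::runif(1, log(mu_prior[1]), log(mu_prior[2])))
    P <- stats::runif(1, P_prior[1], P_prior[2])
    stats_m[i, ] <- simulate_stats(s, par, sizes, n_loci, mu, P, ladder)
    params_m[i, names(par)] <- par
    params_m[i, "mu_mean"] <- mu
    params_m[i, "P"] <- P
  }
  structure(list(stats = stats_m, params = params_m, scenario = scen_id,
                 scenarios = scenarios, sizes = sizes, n_loci = n_loci,
                 mu_prior = mu_prior, P_prior = P_prior, ladder = ladder,
                 seed = seed),
            class = "abc_reftable")
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("ABC reference table: ", nrow(x$stats), " rows (",
      paste0(levels(x$scenario), ": ", as.integer(table(x$scenario)),
             collapse = ", "), "), ",
      ncol(x$stats), " summary statistics\n", sep = "")
  invisible(x)
}

#' Save / load a reference table (TSV with a JSON header line)
#' @param ref an `abc_reftable`.
#' @param path file path.
#' @return `path` invisibly / an `abc_reftable`.
#' @export
write_reference_table <- function(ref, path) {
  hdr <- jsonlite::toJSON(list(
    scenarios = levels(ref$scenario), stat_names = colnames(ref$stats),
    param_names = colnames(ref$params), sizes = as.list(ref$sizes),
    n_loci = ref$n_loci, seed = ref$seed), auto_unbox = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  d <- data.frame(scenario = as.character(ref$scenario), ref$params,
                  ref$stats, check.names = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# standardize stats by median absolute deviation over the table; constant
# or undefined columns are masked out of the distance
standardize_stats <- function(ref_stats, observed) {
  obs <- observed[colnames(ref_stats)]
  X <- ref_stats
  X[is.na(X)] <- 0
  obs[is.na(obs)] <- 0
  s <- apply(X, 2L, stats::mad)
  mask <- is.finite(s) & s > 0
  list(X = sweep(X[, mask, drop = FALSE], 2L, s[mask], "/"),
       obs = obs[mask] / s[mask], mask = mask)
}

#' ABC rejection step
#'
#' Euclidean distance between observed and simulated summary statistics,
#' each standardized by its median absolute deviation across the table;
#' keeps the `ceiling(retain_fraction x rows)` closest simulations.
#'
#' @param ref an `abc_reftable`.
#' @param observed named summary-statistic vector (from [summary_stats]).
#' @param retain_fraction fraction of rows retained (default 0.01).
#' @return object of class `abc_retained`: row indices, distances,
#'   standardized deviations `dev` (retained rows minus observed), the
#'   scenario of each retained row, and the parent table.
#' @export
abc_rejection <- function(ref, observed, retain_fraction = 0.01) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  z <- standardize_stats(ref$stats, observed)
  dev <- sweep(z$X, 2L, z$obs, "-")
  d <- sqrt(rowSums(dev^2))
  keep <- order(d)[seq_len(ceiling(retain_fraction * nrow(ref$stats)))]
  structure(list(index = keep, distance = d[keep],
                 dev = dev[keep, , drop = FALSE],
                 scenario = ref$scenario[keep], ref = ref,
                 observed = observed, retain_fraction = retain_fraction),
            class = "abc_retained")
}

#' @export
print.abc_retained <- function(x, ...) {
  cat("ABC rejection: retained ", length(x$index), " of ",
      nrow(x$ref$stats), " rows (",
      paste0(levels(x$scenario), ": ", as.integer(table(x$scenario)),
             collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Scenario posterior probabilities, direct estimate
#'
#' Scenario frequencies among the `n_delta` closest retained simulations.
#'
#' @param retained an `abc_retained`.
#' @param n_delta number of closest rows used (default 500, capped at the
#'   retained count).
#' @return named probability vector summing to 1.
#' @export
model_posterior_direct <- function(retained, n_delta = 500L) {
  n <- min(n_delta, length(retained$index))
  top <- order(retained$distance)[seq_len(n)]
  p <- table(retained$scenario[top]) / n
  stats::setNames(as.numeric(p), names(p))
}

epanechnikov_weights <- function(d) {
  dmax <- max(d) * (1 + 1e-9)
  if (dmax <= 0) return(rep(1, length(d)))
  1 - (d / dmax)^2
}

#' Scenario posterior probabilities, logistic estimate
#'
#' Weighted multinomial logistic regression of scenario identity on the
#' standardized deviations of the retained statistics from the observed
#' vector, evaluated at zero deviation (the observed point). Epanechnikov
#' weights on distance; a small ridge penalty (weight decay) guards against
#' separation. With a single scenario among the retained rows the
#' degenerate direct estimate is returned with a warning.
#'
#' @param retained an `abc_retained`.
#' @param decay ridge penalty for the multinomial fit.
#' @return named probability vector summing to 1 (attribute `method`).
#' @export
model_posterior_logistic <- function(retained, decay = 0.5) {
  scen <- droplevels(retained$scenario)
  all_lev <- levels(retained$scenario)
  if (nlevels(scen) < 2L) {
    warning("all retained simulations from one scenario; ",
            "returning the degenerate direct estimate")
    p <- model_posterior_direct(retained, n_delta = length(retained$index))
    return(structure(p, method = "direct-degenerate"))
  }
  dat <- data.frame(scen = scen, retained$dev, check.names = FALSE)
  w <- epanechnikov_weights(retained$distance)
  fit <- nnet::multinom(scen ~ ., data = dat, weights = w, decay = decay,
                        trace = FALSE, maxit = 500, MaxNWts = 5000)
  nd <- as.data.frame(matrix(0, 1, ncol(retained$dev),
                             dimnames = list(NULL, colnames(retained$dev))),
                      check.names = FALSE)
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) {
    if (length(pr) == 1L)  # binomial case: P(second level)
      pr <- c(1 - pr, pr)
    names(pr) <- levels(scen)
  }
  out <- stats::setNames(rep(0, length(all_lev)), all_lev)
  out[names(pr)] <- as.numeric(pr)
  structure(out / sum(out), method = "logistic")
}

# map parameters to the real line over their prior bounds (log scale for
# log-uniform / truncated-log-normal priors) and back
param_transform <- function(x, pr) {
  lo <- pr$lower; hi <- pr$upper
  if (pr$shape == "uniform") {
    u <- (x - lo) / (hi - lo)
  } else {
    u <- (log(x) - log(lo)) / (log(hi) - log(lo))
  }
  u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
  log(u / (1 - u))
}

param_backtransform <- function(z, pr) {
  u <- 1 / (1 + exp(-z))
  if (pr$shape == "uniform") pr$lower + u * (pr$upper - pr$lower)
  else exp(log(pr$lower) + u * (log(pr$upper) - log(pr$lower)))
}

wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

wmode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  # bw.nrd0 ignores weights; select bandwidth on the unweighted sample
  d <- stats::density(x, bw = stats::bw.nrd0(x), weights = w / sum(w),
                      n = 512)
  d$x[which.max(d$y)]
}

#' Local-linear regression parameter posterior
#'
#' Beaumont-style adjustment for one scenario's parameters: retained draws
#' are logit-mapped onto their prior bounds (log scale for log-uniform
#' priors), regressed on the standardized statistic deviations with
#' Epanechnikov weights, adjusted to zero deviation
#' (\eqn{\theta_i^* = \theta_i - (s_i - s_{obs})^T \hat\beta}), and
#' back-transformed. Mode from a weighted kernel density; median and 95%
#' interval from weighted quantiles. A rank-deficient regression falls back
#' to unadjusted weighted quantiles with attribute `adjusted = FALSE`.
#'
#' @param retained an `abc_retained`.
#' @param scenario scenario name whose retained rows are used (default: the
#'   scenario with most retained rows).
#' @param min_rows minimum retained rows required (default 50).
#' @return object of class `abc_posterior`: data.frame of per-parameter
#'   `mode`, `median`, `q2.5`, `q97.5` (rows named by parameter), with the
#'   adjusted draws and weights as attributes.
#' @export
parameter_posterior <- function(retained, scenario = NULL, min_rows = 50L) {
  if (is.null(scenario))
    scenario <- names(which.max(table(retained$scenario)))
  sel <- which(as.character(retained$scenario) == scenario)
  if (length(sel) < min_rows)
    stop("only ", length(sel), " retained rows for scenario '", scenario,
         "' (need >= ", min_rows, ")")
  scn <- retained$ref$scenarios[[scenario]]
  priors <- scn$priors
  priors$mu_mean <- prior_spec("mu_mean", "log-uniform",
                               retained$ref$mu_prior[1],
                               retained$ref$mu_prior[2])
  if (diff(retained$ref$P_prior) > 0 && retained$ref$P_prior[1] >= 0) {
    plo <- max(retained$ref$P_prior[1], 1e-6)
    priors$P <- prior_spec("P", "uniform", plo, retained$ref$P_prior[2])
  }
  pnames <- intersect(colnames(retained$ref$params), names(priors))
  X <- retained$dev[sel, , drop = FALSE]
  w <- epanechnikov_weights(retained$distance[sel])
  adjusted <- TRUE
  draws <- matrix(NA_real_, length(sel), length(pnames),
                  dimnames = list(NULL, pnames))
  for (pn in pnames) {
    th <- retained$ref$params[retained$index[sel], pn]
    pr <- priors[[pn]]
    z <- param_transform(th, pr)
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), z, w),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      adjusted <- FALSE
      zadj <- z
    } else {
      beta <- fit$coefficients[-1]
      zadj <- z - drop(X %*% beta)
    }
    draws[, pn] <- param_backtransform(zadj, pr)
  }
  tab <- data.frame(
    mode = vapply(pnames, function(pn) wmode(draws[, pn], w), numeric(1)),
    median = vapply(pnames, function(pn)
      wquantile(draws[, pn], w, 0.5), numeric(1)),
    q2.5 = vapply(pnames, function(pn)
      wquantile(draws[, pn], w, 0.025), numeric(1)),
    q97.5 = vapply(pnames, function(pn)
      wquantile(draws[, pn], w, 0.975), numeric(1)),
    row.names = pnames)
  structure(tab, class = c("abc_posterior", "data.frame"),
            scenario = scenario, draws = draws, weights = w,
            adjusted = adjusted)
}

#' @export
print.abc_posterior <- function(x, digits = 3, ...) {
  cat("ABC parameter posterior (scenario '", attr(x, "scenario"), "', ",
      nrow(attr(x, "draws")), " retained draws",
      if (!attr(x, "adjusted")) ", unadjusted" else "", ")\n", sep = "")
  print.data.frame(x, digits = digits)
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates `n_rep` data sets from parameter draws resampled (by weight)
#' from the adjusted posterior and returns, per summary statistic, the
#' two-sided tail probability of the observed value:
#' `min(p, 1 - p) * 2` capped at 1, where `p` is the fraction of simulated
#' values at or below the observed one.
#'
#' @param posterior an `abc_posterior`.
#' @param observed the observed summary-statistic vector.
#' @param n_rep number of posterior predictive replicates.
#' @param retained the `abc_retained` the posterior came from (supplies the
#'   simulation settings).
#' @param seed optional integer seed.
#' @return named vector of tail probabilities (one per statistic).
#' @export
posterior_predictive_check <- function(posterior, observed, retained,
                                       n_rep = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- attr(posterior, "draws")
  w <- attr(posterior, "weights")
  if (nrow(draws) == 1L)
    warning("degenerate posterior: a single draw")
  ref <- retained$ref
  scn <- ref$scenarios[[attr(posterior, "scenario")]]
  sims <- matrix(NA_real_, n_rep, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (r in seq_len(n_rep)) {
    i <- sample.int(nrow(draws), 1L, prob = w)
    par <- draws[i, names(scn$priors)]
    # honour the order constraints; a violating adjusted draw is re-sampled
    tries <- 0L
    while (tries < 100L) {
      okc <- TRUE
      for (cs in scn$constraints) {
        ab <- trimws(strsplit(cs, "<")[[1]])
        if (!(par[ab[1]] < par[ab[2]])) okc <- FALSE
      }
      if (okc) break
      i <- sample.int(nrow(draws), 1L, prob = w)
      par <- draws[i, names(scn$priors)]
      tries <- tries + 1L
    }
    mu <- if ("mu_mean" %in% colnames(draws)) draws[i, "mu_mean"] else
      mean(ref$mu_prior)
    P <- if ("P" %in% colnames(draws)) draws[i, "P"] else mean(ref$P_prior)
    sims[r, ] <- simulate_stats(scn, par, ref$sizes, ref$n_loci, mu, P,
                                ref$ladder)
  }
  obs <- observed
  obs[is.na(obs)] <- 0
  sims[is.na(sims)] <- 0
  p_le <- colMeans(sims <= rep(obs, each = n_rep))
  p_ge <- 1 - p_le + colMeans(sims == rep(obs, each = n_rep))
  stats::setNames(pmin(1, 2 * pmin(p_le, p_ge)), names(observed))
}

#' One-call ABC scenario choice and parameter estimation
#'
#' Convenience wrapper: rejection, direct and logistic scenario posteriors,
#' and the parameter posterior for the best-supported scenario.
#'
#' @param ref an `abc_reftable`.
#' @param observed observed summary-statistic vector.
#' @param retain_fraction rejection retain fraction.
#' @param n_delta rows for the direct estimate.
#' @return list with `retained`, `direct`, `logistic`, `best`, `posterior`.
#' @export
abc_analysis <- function(ref, observed, retain_fraction = 0.01,
                         n_delta = 500L) {
  ret <- abc_rejection(ref, observed, retain_fraction)
  direct <- model_posterior_direct(ret, n_delta)
  logistic <- tryCatch(model_posterior_logistic(ret),
                       warning = function(w) {
                         suppressWarnings(model_posterior_logistic(ret))
                       })
  best <- names(which.max(logistic))
  post <- tryCatch(parameter_posterior(ret, best), error = function(e) NULL)
  list(retained = ret, direct = direct, logistic = logistic, best = best,
       posterior = post)
}
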