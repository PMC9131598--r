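# Coalescent simulation of diploid microsatellite genotypes under a
# divergence scenario, with a generalized stepwise mutation model (GSM).

#' Simulate a coalescent genealogy under a scenario
#'
#' Continuous-time Kingman coalescent within each deme (pair-coalescence
#' rate \eqn{k(k-1)/(4N_e)} per generation for diploid \eqn{N_e}); at MERGE
#' times lineages move between demes, at SIZE_CHANGE times the deme's size
#' switches. Returns an ultrametric genealogy with node times in
#' generations.
#'
#' @param scn a [scenario] object.
#' @param params named numeric parameter vector (satisfying the scenario's
#'   constraints), e.g. one row of [sample_priors].
#' @param sizes named integer vector: diploid individuals sampled per deme
#'   (gene copies simulated = 2x).
#' @param seed optional integer seed.
#' @return object of class `genealogy`: `parent` and `node_time` vectors
#'   over `2n-1` nodes (tips first, in deme-block order), `n_tips`, and the
#'   deme of each tip.
#' @export
simulate_genealogy <- function(scn, params, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sizes[scn$demes]
  if (anyNA(sizes)) stop("sizes must cover every sampled deme")
  ev <- resolve_events(scn, params)
  ne <- unname(params[scn$sizes[scn$demes]])
  di <- function(d) match(d, scn$demes) - 1L
  g <- .sim_genealogy_cpp(
    as.integer(2L * sizes), as.numeric(ne),
    as.numeric(ev$t),
    as.integer(ifelse(ev$type == "merge", 0L, 1L)),
    as.integer(di(ev$deme)),
    as.integer(ifelse(ev$type == "merge", di(ev$target), 0L)),
    as.numeric(ifelse(ev$type == "merge", 0, unname(params[ev$size]))))
  g$tip_deme <- rep(scn$demes, times = 2L * sizes)
  class(g) <- "genealogy"
  g
}

#' Total branch length and TMRCA of a genealogy
#' @param g a `genealogy`.
#' @return named numeric `c(tmrca, total_length)` in generations.
#' @export
genealogy_summary <- function(g) {
  nn <- length(g$parent)
  len <- g$node_time[g$parent[-nn] + 1L] - g$node_time[-nn]
  c(tmrca = g$node_time[nn], total_length = sum(len))
}

#' Drop stepwise mutations on a genealogy
#'
#' Mutation counts per branch are Poisson with mean `mu x length`; each
#' mutation steps the repeat number by \eqn{\pm k} with
#' \eqn{k \sim} geometric(`P`) (`P = 0` is the strict stepwise model),
#' symmetric in direction, reflected at the ladder bounds. The ancestral
#' state is the ladder midpoint (or `ancestral` if given).
#'
#' @param g a `genealogy` from [simulate_genealogy].
#' @param mu mutation rate per locus per generation.
#' @param P geometric parameter of the GSM in `[0, 1)`.
#' @param ladder length-2 numeric: allele-state bounds; may be infinite for
#'   an unbounded ladder.
#' @param ancestral ancestral repeat number (default ladder midpoint, or 0
#'   on an unbounded ladder).
#' @param seed optional integer seed.
#' @return integer vector of repeat numbers, one per tip.
#' @export
mutate_gsm <- function(g, mu, P = 0, ladder = c(1, 200), ancestral = NULL,
                       seed = NULL) {
  stopifnot(mu >= 0, P >= 0, P < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ancestral)) {
    ancestral <- if (all(is.finite(ladder))) floor(mean(ladder)) else 0
  }
  if (all(is.finite(ladder)) && ladder[2] - ladder[1] < 1)
    stop("ladder must hold >= 2 states")
  .mutate_gsm_cpp(g$parent, g$node_time, g$n_tips, mu, P,
                  ladder[1], ladder[2], ancestral)
}

#' Simulate a diploid microsatellite data set under a scenario
#'
#' Per locus: a genealogy of `2 x sum(sizes)` gene copies is drawn under
#' the scenario, mutated under the GSM, and gene copies are paired into
#' diploid individuals within demes (random union of gametes). Per-locus
#' mutation rates are drawn from a Gamma with shape 2 around `mu_mean`
#' (locus heterogeneity), unless `mu_locus` is supplied.
#'
#' @param scn a [scenario] object.
#' @param params named numeric parameter vector.
#' @param sizes named integer vector of diploid sample sizes per deme.
#' @param n_loci number of loci.
#' @param mu_mean mean mutation rate per locus per generation.
#' @param P GSM geometric parameter.
#' @param ladder allele-state ladder bounds (finite for genepop output).
#' @param mu_locus optional numeric vector of per-locus rates (overrides
#'   the Gamma draw).
#' @param seed optional integer seed.
#' @return a [genotypes] object (alleles are repeat numbers on the ladder),
#'   with attributes `params`, `mu_locus`, `P`.
#' @export
simulate_dataset <- function(scn, params, sizes, n_loci = 18L,
                             mu_mean = 5e-4, P = 0.22,
                             ladder = c(1, 200), mu_locus = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sizes[scn$demes]
  n <- sum(sizes)
  if (is.null(mu_locus))
    mu_locus <- stats::rgamma(n_loci, shape = 2, rate = 2 / mu_mean)
  a1 <- matrix(NA_integer_, n, n_loci)
  a2 <- matrix(NA_integer_, n, n_loci)
  for (l in seq_len(n_loci)) {
    g <- simulate_genealogy(scn, params, sizes)
    st <- mutate_gsm(g, mu_locus[l], P, ladder)
    a1[, l] <- st[seq(1L, 2L * n, by = 2L)]
    a2[, l] <- st[seq(2L, 2L * n, by = 2L)]
  }
  ids <- sprintf("sim%04d", seq_len(n))
  pop <- factor(rep(scn$demes, times = sizes), levels = scn$demes)
  gm <- genotypes(ids, pop, sprintf("L%02d", seq_len(n_loci)), a1, a2)
  attr(gm, "params") <- params
  attr(gm, "mu_locus") <- mu_locus
  attr(gm, "P") <- P
  gm
}

# Fast internal path used by the ABC reference-table builder: simulate and
# summarize without building a genotypes object. Returns the summary-stat
# vector matching summary_stats() ordering for the scenario's deme order.
simulate_stats <- function(scn, params, sizes, n_loci, mu_mean, P,
                           ladder = c(1, 200), mu_locus = NULL) {
  sizes <- sizes[scn$demes]
  n <- sum(sizes)
  if (is.null(mu_locus))
    mu_locus <- stats::rgamma(n_loci, shape = 2, rate = 2 / mu_mean)
  states <- matrix(NA_integer_, 2L * n, n_loci)
  for (l in seq_len(n_loci)) {
    g <- simulate_genealogy(scn, params, sizes)
    states[, l] <- mutate_gsm(g, mu_locus[l], P, ladder)
  }
  ind_pop <- rep(seq_along(sizes) - 1L, times = sizes)
  st <- .summary_stats_cpp(states, ind_pop, length(sizes))
  names(st) <- summary_stat_names(scn$demes)
  st
}
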