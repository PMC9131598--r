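# Per-population diversity and F-statistics.
#
# All multilocus Weir-Cockerham estimators are ratios of summed variance
# components over informative loci (never means of per-locus ratios), and
# missing data are handled by pairwise per-locus deletion: a genotype
# missing at a locus contributes nothing to that locus anywhere.

pop_index <- function(gm, pop) {
  if (is.character(pop)) {
    ix <- which(as.character(gm$pop) == pop)
    if (!length(ix)) stop("unknown population: ", pop)
    ix
  } else which(as.integer(gm$pop) == pop)
}

locus_index <- function(gm, locus) {
  if (is.character(locus)) {
    l <- match(locus, gm$loci)
    if (is.na(l)) stop("unknown locus: ", locus)
    l
  } else as.integer(locus)
}

#' Observed heterozygosity at one locus in one population
#'
#' @param gm a [genotypes] object.
#' @param pop population label or index.
#' @param locus locus name or index.
#' @return heterozygote proportion among non-missing genotypes.
#' @export
observed_heterozygosity <- function(gm, pop, locus) {
  ix <- pop_index(gm, pop); l <- locus_index(gm, locus)
  x1 <- gm$a1[ix, l]; x2 <- gm$a2[ix, l]
  ok <- !is.na(x1)
  if (!any(ok)) stop("no non-missing genotype at locus ", locus)
  mean(x1[ok] != x2[ok])
}

#' Unbiased expected heterozygosity (Nei gene diversity)
#'
#' Small-sample-corrected gene diversity
#' \eqn{\hat{H} = \frac{2n}{2n-1}\left(1 - \sum_a \hat{p}_a^2\right)} with
#' `n` the number of non-missing genotypes.
#'
#' @inheritParams observed_heterozygosity
#' @return gene diversity in `[0, 1]`.
#' @export
expected_heterozygosity <- function(gm, pop, locus) {
  ix <- pop_index(gm, pop); l <- locus_index(gm, locus)
  al <- c(gm$a1[ix, l], gm$a2[ix, l])
  al <- al[!is.na(al)]
  n2 <- length(al)
  if (n2 < 4L) stop("need >= 2 non-missing genotypes")
  p <- tabulate(factor(al)) / n2
  (n2 / (n2 - 1)) * (1 - sum(p^2))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (hypergeometric expectation):
#' \eqn{\sum_a \left[1 - \binom{N_c-N_a}{g} / \binom{N_c}{g}\right]}.
#'
#' @inheritParams observed_heterozygosity
#' @param g rarefaction size in gene copies; must not exceed the non-missing
#'   gene-copy count.
#' @return expected allele count (>= 1 whenever data exist).
#' @export
allelic_richness <- function(gm, pop, locus, g) {
  ix <- pop_index(gm, pop); l <- locus_index(gm, locus)
  al <- c(gm$a1[ix, l], gm$a2[ix, l])
  al <- al[!is.na(al)]
  nc <- length(al)
  if (g > nc) stop("rarefaction size g = ", g, " exceeds ", nc, " gene copies")
  if (g < 1L) stop("g must be >= 1")
  cnt <- tabulate(factor(al))
  sum(1 - exp(lchoose(nc - cnt, g) - lchoose(nc, g)))
}

# Per-locus data for a set of populations, as a list of n x 2 matrices.
loci_geno_list <- function(gm, ix) {
  lapply(seq_along(gm$loci), function(l)
    cbind(gm$a1[ix, l], gm$a2[ix, l]))
}

#' Weir-Cockerham variance components at one locus
#'
#' Components `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals) of the 1984 estimator, with the
#' standard unequal-sample-size weights, computed per allele and summed over
#' alleles. A locus monomorphic across the included populations, or with
#' fewer than two populations carrying data, is uninformative and returns
#' `NA` components with attribute `informative = FALSE`.
#'
#' @param gm a [genotypes] object.
#' @param locus locus name or index.
#' @param pops populations to include (default all).
#' @return named numeric `c(a, b, c)` with attribute `informative`.
#' @export
wc_components <- function(gm, locus, pops = levels(gm$pop)) {
  l <- locus_index(gm, locus)
  ix <- which(as.character(gm$pop) %in% pops)
  pf <- factor(as.character(gm$pop)[ix], levels = pops)
  x1 <- gm$a1[ix, l]; x2 <- gm$a2[ix, l]
  ok <- !is.na(x1)
  uninf <- structure(c(a = NA_real_, b = NA_real_, c = NA_real_),
                     informative = FALSE)
  if (!any(ok)) return(uninf)
  pf <- pf[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2L) return(uninf)
  nvec <- tabulate(pf, nbins = length(pops))
  use <- nvec >= 1L
  r <- sum(use)
  if (r < 2L) return(uninf)
  nvec <- nvec[use]
  nbar <- mean(nvec)
  if (nbar <= 1) return(uninf)
  nsum <- sum(nvec)
  nc <- (nsum - sum(nvec^2) / nsum) / (r - 1)

  # allele counts and heterozygote-carrier counts per pop x allele
  pl <- levels(pf)[use]
  cnt <- matrix(0, r, length(alleles))
  hcnt <- matrix(0, r, length(alleles))
  pi_ix <- match(as.character(pf), pl)
  for (k in seq_along(alleles)) {
    a <- alleles[k]
    cnt[, k] <- vapply(seq_len(r), function(p)
      sum((x1 == a)[pi_ix == p]) + sum((x2 == a)[pi_ix == p]), numeric(1))
    hcnt[, k] <- vapply(seq_len(r), function(p)
      sum((x1 != x2 & (x1 == a | x2 == a))[pi_ix == p]), numeric(1))
  }
  pmat <- cnt / (2 * nvec)
  hmat <- hcnt / nvec
  pbar <- colSums(nvec * pmat) / nsum
  hbar <- colSums(nvec * hmat) / nsum
  s2 <- colSums(nvec * (pmat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  pq <- pbar * (1 - pbar)
  a_ <- (nbar / nc) * (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b_ <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  structure(c(a = sum(a_), b = sum(b_), c = sum(c_)), informative = TRUE)
}

#' Multilocus Weir-Cockerham f (F_IS) for one population
#'
#' Within-population inbreeding estimator
#' \eqn{\hat{f} = 1 - \sum_l c_l / \sum_l (b_l + c_l)} over informative loci
#' (a ratio of sums, not a mean of ratios); positive under heterozygote
#' deficit.
#'
#' @param gm a [genotypes] object.
#' @param pop population label or index.
#' @return f in `[-1, 1]` (not truncated).
#' @export
multilocus_fis <- function(gm, pop) {
  ix <- pop_index(gm, pop)
  f <- .fis_multilocus_cpp(loci_geno_list(gm, ix))
  if (is.na(f)) stop("no informative locus in population")
  f
}

#' Multilocus pairwise theta (F_ST) between two populations
#'
#' Weir-Cockerham \eqn{\hat\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)} over
#' informative loci.
#'
#' @param gm a [genotypes] object.
#' @param popA,popB population labels or indices.
#' @return theta (not truncated; may be slightly negative).
#' @export
pairwise_theta <- function(gm, popA, popB) {
  ixA <- pop_index(gm, popA); ixB <- pop_index(gm, popB)
  ix <- c(ixA, ixB)
  pop01 <- c(rep(0L, length(ixA)), rep(1L, length(ixB)))
  th <- .theta_multilocus_cpp(loci_geno_list(gm, ix), pop01, 2L)
  if (is.na(th)) stop("no informative locus for this population pair")
  th
}

#' Bonferroni-adjusted nominal significance level
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests.
#' @return adjusted per-test nominal level `alpha / n_tests`.
#' @export
adjusted_nominal_level <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Permutation test for F_IS or pairwise theta
#'
#' One-sided permutation p-value `(#\{perm >= observed\} + 1) / (B + 1)`
#' (excess structure / heterozygote deficit). Scheme `"alleles"` permutes
#' gene copies among individuals within the population (for F_IS); scheme
#' `"genotypes"` permutes whole genotypes between the two populations (for
#' theta). The seed fully determines the permutation stream.
#'
#' @param gm a [genotypes] object.
#' @param pops one population (F_IS) or two (theta).
#' @param scheme `"alleles"` or `"genotypes"`.
#' @param B number of permutations.
#' @param seed optional integer seed.
#' @return list with `observed`, `p_value`, `B`.
#' @export
permutation_test <- function(gm, pops, scheme = c("alleles", "genotypes"),
                             B = 10000L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "alleles") {
    stopifnot(length(pops) == 1L)
    ix <- pop_index(gm, pops)
    gl <- loci_geno_list(gm, ix)
    obs <- .fis_multilocus_cpp(gl)
    perm <- .fis_perm_cpp(gl, as.integer(B))
  } else {
    stopifnot(length(pops) == 2L)
    ixA <- pop_index(gm, pops[1]); ixB <- pop_index(gm, pops[2])
    ix <- c(ixA, ixB)
    pop01 <- c(rep(0L, length(ixA)), rep(1L, length(ixB)))
    gl <- loci_geno_list(gm, ix)
    obs <- .theta_multilocus_cpp(gl, pop01, 2L)
    perm <- .theta_perm_cpp(gl, pop01, 2L, as.integer(B))
  }
  if (is.na(obs)) stop("observed statistic undefined (no informative locus)")
  p <- (sum(perm >= obs, na.rm = TRUE) + 1) / (B + 1)
  list(observed = obs, p_value = p, B = B)
}

#' Per-population diversity table
#'
#' One row per population: unbiased expected heterozygosity and observed
#' heterozygosity (unweighted means over loci), rarefied allelic richness,
#' mean observed allele count, multilocus Weir-Cockerham F_IS with its
#' permutation p-value, and a significance flag at the Bonferroni-adjusted
#' nominal level.
#'
#' @param gm a [genotypes] object.
#' @param B permutations for the F_IS test.
#' @param alpha family-wise level for the adjusted flag.
#' @param n_tests divisor for the adjusted nominal level (default: number of
#'   populations).
#' @param g rarefaction size per locus; default is the smallest per-population
#'   non-missing gene-copy count at that locus across populations.
#' @param seed optional integer seed for the permutation streams.
#' @return data.frame of class `diversity_table` with attribute
#'   `adjusted_level`.
#' @export
diversity_table <- function(gm, B = 10000L, alpha = 0.05,
                            n_tests = nlevels(gm$pop), g = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(gm$pop)
  L <- length(gm$loci)
  gvec <- g
  if (is.null(gvec)) {
    gvec <- vapply(seq_len(L), function(l) {
      counts <- vapply(pops, function(p)
        2L * sum(!is.na(gm$a1[pop_index(gm, p), l])), integer(1))
      max(2L, min(counts))
    }, integer(1))
  } else gvec <- rep_len(as.integer(g), L)
  alev <- adjusted_nominal_level(alpha, n_tests)

  rows <- lapply(pops, function(p) {
    hexp <- hobs <- ar <- nal <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      ix <- pop_index(gm, p)
      al <- c(gm$a1[ix, l], gm$a2[ix, l]); al <- al[!is.na(al)]
      if (length(al) >= 4L) {
        hexp[l] <- expected_heterozygosity(gm, p, l)
        hobs[l] <- observed_heterozygosity(gm, p, l)
        nal[l] <- length(unique(al))
        if (gvec[l] <= length(al)) ar[l] <- allelic_richness(gm, p, l, gvec[l])
      }
    }
    pt <- permutation_test(gm, p, "alleles", B = B)
    data.frame(pop = p, N = length(pop_index(gm, p)),
               H_exp = mean(hexp, na.rm = TRUE),
               H_obs = mean(hobs, na.rm = TRUE),
               allelic_richness = mean(ar, na.rm = TRUE),
               n_alleles = mean(nal, na.rm = TRUE),
               F_IS = pt$observed, p_FIS = pt$p_value,
               significant = pt$p_value < alev)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "adjusted_level") <- alev
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
print.diversity_table <- function(x, digits = 3, ...) {
  cat("Per-population diversity (adjusted nominal level ",
      format(attr(x, "adjusted_level"), digits = 3), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pairwise theta matrix with permutation significance
#'
#' Lower-triangular multilocus Weir-Cockerham theta for every population
#' pair, permutation p-values, and the significance mask at the
#' Bonferroni-adjusted nominal level for the
#' `choose(n_pops, 2)` tests.
#'
#' @inheritParams diversity_table
#' @return object of class `fst_matrix`: list with `theta`, `p_value`,
#'   `significant` matrices and `adjusted_level`.
#' @export
fst_matrix <- function(gm, B = 10000L, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(gm$pop)
  K <- length(pops)
  if (K < 2L) stop("need >= 2 populations")
  th <- pmat <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(th) <- 0
  n_tests <- K * (K - 1) / 2
  alev <- adjusted_nominal_level(alpha, n_tests)
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    pt <- permutation_test(gm, c(pops[i], pops[j]), "genotypes", B = B)
    th[j, i] <- th[i, j] <- pt$observed
    pmat[j, i] <- pmat[i, j] <- pt$p_value
  }
  structure(list(theta = th, p_value = pmat,
                 significant = !is.na(pmat) & pmat < alev,
                 adjusted_level = alev, B = B, alpha = alpha),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Weir-Cockerham theta (lower triangle; * p < ",
      format(x$adjusted_level, digits = 3), ", B = ", x$B, ")\n", sep = "")
  K <- nrow(x$theta)
  disp <- matrix("", K, K, dimnames = dimnames(x$theta))
  for (i in seq_len(K)) for (j in seq_len(i)) {
    disp[i, j] <- formatC(x$theta[i, j], digits = digits, format = "f")
    if (i != j && isTRUE(x$significant[i, j]))
      disp[i, j] <- paste0(disp[i, j], "*")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write Table-1 / Table-2 shaped TSV outputs
#' @param x a `diversity_table` or `fst_matrix`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_stats_tsv <- function(x, path) {
  if (inherits(x, "diversity_table")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "fst_matrix")) {
    K <- nrow(x$theta)
    low <- x$theta; low[upper.tri(low)] <- NA
    d <- data.frame(pop = rownames(low), low, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else stop("unsupported object")
  invisible(path)
}
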