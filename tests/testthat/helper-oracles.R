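# Independent oracles and fixture generators for the test suite.
# The oracles are deliberately written as plain scalar loops, independent of
# the package's vectorized / compiled implementations.

# Weir & Cockerham (1984) variance components (a, b, c) at one locus,
# summed over alleles; scalar transcription with the unequal-sample-size
# weights. Returns NA triple for uninformative loci.
oracle_wc <- function(a1, a2, pop) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  pop <- factor(as.character(pop[ok]))
  pops <- levels(pop)
  r <- length(pops)
  alleles <- sort(unique(c(a1, a2)))
  if (r < 2 || length(alleles) < 2) return(c(a = NA, b = NA, c = NA))
  n <- numeric(r)
  for (k in 1:r) n[k] <- sum(pop == pops[k])
  nbar <- sum(n) / r
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- numeric(r); h_i <- numeric(r)
    for (k in 1:r) {
      sel <- which(pop == pops[k])
      cnt <- 0; het <- 0
      for (i in sel) {
        cnt <- cnt + (a1[i] == al) + (a2[i] == al)
        if (a1[i] != a2[i] && (a1[i] == al || a2[i] == al)) het <- het + 1
      }
      p_i[k] <- cnt / (2 * n[k])
      h_i[k] <- het / n[k]
    }
    pbar <- 0; hbar <- 0
    for (k in 1:r) { pbar <- pbar + n[k] * p_i[k]; hbar <- hbar + n[k] * h_i[k] }
    pbar <- pbar / (r * nbar); hbar <- hbar / (r * nbar)
    s2 <- 0
    for (k in 1:r) s2 <- s2 + n[k] * (p_i[k] - pbar)^2
    s2 <- s2 / ((r - 1) * nbar)
    A <- A + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(a = A, b = B, c = C)
}

# single-population within/among-individual components (b, c) at one locus
oracle_fis_components <- function(a1, a2) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  if (n < 2 || length(alleles) < 2) return(c(b = NA, c = NA))
  B <- C <- 0
  for (al in alleles) {
    cnt <- 0; het <- 0
    for (i in 1:n) {
      cnt <- cnt + (a1[i] == al) + (a2[i] == al)
      if (a1[i] != a2[i] && (a1[i] == al || a2[i] == al)) het <- het + 1
    }
    p <- cnt / (2 * n); h <- het / n
    B <- B + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    C <- C + h / 2
  }
  c(b = B, c = C)
}

# multiset-intersection allele distance between two samples, brute force
oracle_distance <- function(gm, i, j) {
  d <- 0; skipped <- 0
  for (l in seq_along(gm$loci)) {
    x <- c(gm$a1[i, l], gm$a2[i, l]); y <- c(gm$a1[j, l], gm$a2[j, l])
    if (anyNA(x) || anyNA(y)) { skipped <- skipped + 1; next }
    inter <- 0
    yy <- y
    for (v in x) {
      hit <- match(v, yy)
      if (!is.na(hit)) { inter <- inter + 1; yy <- yy[-hit] }
    }
    d <- d + 2 - inter
  }
  structure(d, skipped = skipped)
}

# unbiased gene diversity by exhaustive gene-copy pair counting
oracle_exp_het <- function(copies) {
  n <- length(copies)
  same <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (copies[i] == copies[j]) same <- same + 1
  }
  1 - same / tot
}

# rarefied allelic richness by exhaustive subset enumeration
oracle_richness <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# random genotype fixture; every population non-empty
random_genotypes <- function(n, L, npop = 2, n_alleles = 4, miss = 0.1,
                             base = 100L) {
  npop <- min(npop, n)
  pop <- sample(paste0("P", seq_len(npop)), n, replace = TRUE)
  pop[seq_len(npop)] <- paste0("P", seq_len(npop))
  a1 <- matrix(sample(base + seq_len(n_alleles) - 1L, n * L, TRUE), n, L)
  a2 <- matrix(sample(base + seq_len(n_alleles) - 1L, n * L, TRUE), n, L)
  if (miss > 0) {
    m <- matrix(stats::runif(n * L) < miss, n, L)
    a1[m] <- NA; a2[m] <- NA
  }
  genotypes(paste0("s", seq_len(n)), pop, paste0("L", seq_len(L)), a1, a2)
}

# brute-force O(N^2) exact-match MLG partition
oracle_mlg <- function(gm) {
  n <- length(gm$ids)
  grp <- integer(n); nxt <- 0L
  for (i in seq_len(n)) {
    found <- FALSE
    if (i > 1) for (j in 1:(i - 1)) {
      if (all((is.na(gm$a1[i, ]) & is.na(gm$a1[j, ])) |
              (!is.na(gm$a1[i, ]) & !is.na(gm$a1[j, ]) &
                 gm$a1[i, ] == gm$a1[j, ] & gm$a2[i, ] == gm$a2[j, ]))) {
        grp[i] <- grp[j]; found <- TRUE; break
      }
    }
    if (!found) { nxt <- nxt + 1L; grp[i] <- nxt }
  }
  grp
}

# a tiny panmictic one-deme scenario for null simulations
panmictic_scenario <- function(ne_upper = 1e7) {
  scenario("panmictic", "A", c(A = "Ne"), data.frame(),
           list(prior_spec("Ne", "log-uniform", 10, ne_upper)))
}

# two demes merging at time t_split (sizes NeA, NeB, ancestral NeAnc)
split_scenario <- function() {
  scenario("split", c("A", "B"), c(A = "NeA", B = "NeB"),
           data.frame(time = c("tsplit", "tsplit"),
                      type = c("merge", "size_change"),
                      deme = c("B", "A"), target = c("A", NA),
                      size = c(NA, "NeAnc")),
           list(prior_spec("NeA", "log-uniform", 10, 1e7),
                prior_spec("NeB", "log-uniform", 10, 1e7),
                prior_spec("NeAnc", "log-uniform", 10, 1e7),
                prior_spec("tsplit", "log-uniform", 10, 2e6)))
}
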