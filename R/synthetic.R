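# Study-shaped synthetic genotype data with known truth: a divergence-
# scenario simulation dressed with meadow labels, injected clone pairs and
# null alleles, each injection recorded in a machine-readable ledger.

#' Meadow sampling design emulated by the generator
#'
#' Twelve meadow labels with their sample sizes and the regional deme each
#' belongs to (NE: Lemnos, Imeros; N: Fanari, Vrasidas, Nea Karvali; NW:
#' Viamyl, Ag. Triada, Chalkidiki; CW: eastern/western Pagasitikos,
#' Maliakos). The small south-eastern sample (CYP) is drawn from the NE
#' deme's gene pool, the genetically closest cluster.
#'
#' @return data.frame with columns `meadow`, `n`, `deme`.
#' @export
meadow_design <- function() {
  data.frame(
    meadow = c("LEM", "IME", "FAN", "VRA", "NKA", "VIA", "AGT", "CHA",
               "EPA", "WPA", "MAG", "CYP"),
    n = c(8L, 32L, 34L, 34L, 22L, 23L, 38L, 9L, 47L, 36L, 37L, 11L),
    deme = c("NE", "NE", "N", "N", "N", "NW", "NW", "NW",
             "CW", "CW", "CW", "NE"),
    stringsAsFactors = FALSE)
}

#' Pooling map from meadows to regional demes
#' @param drop labels excluded from the map (default the small CYP sample,
#'   which gets a drop-list entry instead).
#' @return named character vector usable with [pool_populations].
#' @export
deme_pooling_map <- function(drop = "CYP") {
  d <- meadow_design()
  d <- d[!(d$meadow %in% drop), ]
  stats::setNames(d$deme, d$meadow)
}

#' Inject null alleles
#'
#' Each gene copy independently becomes null with its locus frequency; a
#' null/null genotype becomes missing, a null/visible genotype an apparent
#' homozygote for the visible allele. On Hardy-Weinberg data this produces
#' the classic heterozygote deficit (positive F_IS) and a per-locus missing
#' rate near `freq^2`.
#'
#' @param gm a [genotypes] object.
#' @param freq_per_locus null-allele frequency, recycled over loci; each in
#'   `[0, 0.5]`.
#' @param seed optional integer seed.
#' @return a [genotypes] object with attribute `null_ledger`: data.frame of
#'   every altered call (`sample`, `locus`, `change` of `"homozygote"` or
#'   `"missing"`).
#' @export
inject_null_alleles <- function(gm, freq_per_locus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freq <- rep_len(freq_per_locus, length(gm$loci))
  if (any(freq < 0 | freq > 0.5)) stop("null frequencies must be in [0, 0.5]")
  a1 <- gm$a1; a2 <- gm$a2
  led <- list()
  for (l in seq_along(gm$loci)) {
    if (freq[l] <= 0) next
    ok <- which(!is.na(a1[, l]))
    n1 <- stats::runif(length(ok)) < freq[l]
    n2 <- stats::runif(length(ok)) < freq[l]
    both <- ok[n1 & n2]; one <- ok[xor(n1, n2)]
    first_null <- n1[xor(n1, n2)]
    if (length(both)) {
      a1[both, l] <- NA_integer_; a2[both, l] <- NA_integer_
      led[[length(led) + 1L]] <- data.frame(
        sample = gm$ids[both], locus = gm$loci[l], change = "missing")
    }
    if (length(one)) {
      vis <- ifelse(first_null, a2[one, l], a1[one, l])
      het <- a1[one, l] != a2[one, l]  # homozygotes are visibly unchanged
      a1[one, l] <- vis; a2[one, l] <- vis
      if (any(het))
        led[[length(led) + 1L]] <- data.frame(
          sample = gm$ids[one[het]], locus = gm$loci[l],
          change = "homozygote")
    }
  }
  out <- genotypes(gm$ids, gm$pop, gm$loci, a1, a2)
  attr(out, "null_ledger") <- if (length(led)) do.call(rbind, led) else
    data.frame(sample = character(0), locus = character(0),
               change = character(0))
  out
}

#' Inject clonal replicates
#'
#' Overwrites `n_pairs` samples with near-copies of a same-population
#' partner: for each pair `(i, j)` sample `j`'s genotype becomes sample
#' `i`'s with at most `max_distance` single-allele stepwise edits (never on
#' missing calls), emulating ramets of one genet separated by somatic
#' mutation or scoring slips. The total sample count is unchanged and the
#' number of multilocus lineages drops by exactly `n_pairs` (when all other
#' genotypes are distinct).
#'
#' @param gm a [genotypes] object.
#' @param n_pairs number of clone pairs to create (`<= N/2`).
#' @param max_distance maximum allele edits within a pair.
#' @param seed optional integer seed.
#' @return a [genotypes] object with attribute `clone_ledger`: data.frame
#'   of `original`, `copy`, `edits`.
#' @export
inject_clones <- function(gm, n_pairs, max_distance = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$ids)
  if (n_pairs > n %/% 2L) stop("n_pairs exceeds N/2")
  a1 <- gm$a1; a2 <- gm$a2
  led <- data.frame(original = character(0), copy = character(0),
                    edits = integer(0))
  if (n_pairs >= 1L) {
    used <- integer(0)
    for (k in seq_len(n_pairs)) {
      avail <- setdiff(seq_len(n), used)
      # pick a population with at least two unused members
      repeat {
        i <- sample(avail, 1L)
        mates <- setdiff(avail[gm$pop[avail] == gm$pop[i]], i)
        if (length(mates)) break
      }
      j <- if (length(mates) == 1L) mates else sample(mates, 1L)
      a1[j, ] <- a1[i, ]; a2[j, ] <- a2[i, ]
      d <- if (max_distance >= 1L) sample.int(max_distance + 1L, 1L) - 1L else 0L
      slots <- which(!is.na(a1[j, ]))
      d <- min(d, length(slots))
      if (d > 0L) for (l in sample(slots, d)) {
        step <- sample(c(-1L, 1L), 1L)
        a2[j, l] <- max(1L, a2[j, l] + step)
        if (a2[j, l] < a1[j, l]) { tmp <- a1[j, l]; a1[j, l] <- a2[j, l]; a2[j, l] <- tmp }
      }
      led <- rbind(led, data.frame(original = gm$ids[i], copy = gm$ids[j],
                                   edits = d))
      used <- c(used, i, j)
    }
  }
  out <- genotypes(gm$ids, gm$pop, gm$loci, a1, a2)
  attr(out, "clone_ledger") <- led
  out
}

#' Generate a study-shaped data set with known truth
#'
#' Simulates the shipped divergence scenario at fixed "truth" parameters
#' chosen so pairwise theta between demes falls in roughly 0.02-0.30, dresses
#' the four simulated demes with the twelve meadow labels of
#' [meadow_design] at their sample sizes scaled by `scale`, then injects
#' `clone_pairs` clonal replicates and (optionally) null alleles.
#'
#' @param seed integer seed; fully determines the bundle.
#' @param scale sampling-fraction in `(0, 1]` applied to the meadow sizes.
#' @param clone_pairs number of injected clone pairs (default 3).
#' @param null_freq per-locus null-allele frequency (default 0, clean data);
#'   use ~0.1-0.2 to emulate the observed heterozygote deficits.
#' @param n_loci number of loci (default 18).
#' @param params optional named truth parameter vector overriding the
#'   default.
#' @return object of class `truth_bundle`: list with `clean` and
#'   `corrupted` [genotypes] (meadow labels), `scenario`, `params`,
#'   `clone_ledger`, `null_ledger`, `scale`.
#' @export
make_study_like <- function(seed = 1L, scale = 1, clone_pairs = 3L,
                            null_freq = 0, n_loci = 18L, params = NULL) {
  stopifnot(scale > 0, scale <= 1)
  set.seed(seed)
  scn <- scenario13()
  if (is.null(params))
    params <- c(Ne1 = 5000, Ne2 = 5000, Ne3 = 5000, Ne4 = 5000, Na = 1000,
                t0 = 100, t2 = 600, t3 = 3000)
  des <- meadow_design()
  des$n_scaled <- pmax(2L, as.integer(round(des$n * scale)))
  sizes <- vapply(scn$demes, function(d) sum(des$n_scaled[des$deme == d]),
                  integer(1))
  gm <- simulate_dataset(scn, params, sizes, n_loci = n_loci,
                         mu_mean = 5e-4, P = 0.22)
  # re-label simulated individuals with meadow labels nested in their deme
  meadow <- character(length(gm$ids))
  for (d in scn$demes) {
    ix <- which(as.character(gm$pop) == d)
    meadow[ix] <- rep(des$meadow[des$deme == d],
                      times = des$n_scaled[des$deme == d])
  }
  clean <- genotypes(sprintf("%s_%03d", meadow, seq_along(meadow)),
                     factor(meadow, levels = des$meadow),
                     gm$loci, gm$a1, gm$a2)
  # nulls first, clones second: ramet pairs then differ by exactly the
  # controlled edits, as scoring slips on a shared (corrupted) genotype
  cor1 <- inject_null_alleles(clean, null_freq)
  cor2 <- inject_clones(cor1, clone_pairs, max_distance = 1L)
  structure(list(clean = clean, corrupted = cor2, scenario = scn,
                 params = params,
                 clone_ledger = attr(cor2, "clone_ledger"),
                 null_ledger = attr(cor1, "null_ledger"),
                 scale = scale, seed = seed),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("truth_bundle: ", length(x$corrupted$ids), " samples, ",
      length(x$corrupted$loci), " loci (scale ", x$scale, ")\n", sep = "")
  cat("  injected clone pairs: ", nrow(x$clone_ledger),
      "; null-allele edits: ", nrow(x$null_ledger), "\n", sep = "")
  invisible(x)
}

#' Write a truth bundle to disk
#'
#' Emits the corrupted data as genepop plus a JSON truth ledger (scenario
#' name, parameters, clone pairs, null-allele edits).
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "synthetic_genotypes.gen")
  write_genepop(bundle$corrupted, gp, title = "synthetic study-like data")
  led <- file.path(dir, "truth_ledger.json")
  jsonlite::write_json(list(
    scenario = bundle$scenario$name,
    params = as.list(bundle$params),
    seed = bundle$seed, scale = bundle$scale,
    clone_pairs = bundle$clone_ledger,
    null_edits = bundle$null_ledger), led, auto_unbox = TRUE, digits = NA)
  invisible(c(gp, led))
}
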