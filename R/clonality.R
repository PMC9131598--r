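#' Allele-difference distance between two multilocus genotypes
#'
#' Counts, summed over loci typed in both samples, the number of allele
#' copies not shared between the two calls (per locus: ploidy minus the size
#' of the multiset intersection). A shared heterozygote scores 0, `Aa` vs
#' `AA` scores 1, `AA` vs `BB` scores 2. Loci missing in either genotype are
#' skipped; the number skipped is reported in attribute `skipped`.
#'
#' @param gm a [genotypes] object.
#' @param i,j sample indices (or ids).
#' @return non-negative integer with attribute `skipped`.
#' @export
allele_distance <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$ids)
  if (is.character(j)) j <- match(j, gm$ids)
  x1 <- gm$a1[i, ]; x2 <- gm$a2[i, ]
  y1 <- gm$a1[j, ]; y2 <- gm$a2[j, ]
  miss <- is.na(x1) | is.na(y1)
  if (all(miss)) stop("no locus typed in both genotypes")
  x1 <- x1[!miss]; x2 <- x2[!miss]; y1 <- y1[!miss]; y2 <- y2[!miss]
  # calls are canonicalized a1 <= a2, so multiset overlap per locus is
  # 2 if identical pairs, else 1 if any cross-match, else 0
  same <- (x1 == y1) & (x2 == y2)
  shared1 <- !same & ((x1 == y1) | (x1 == y2) | (x2 == y1) | (x2 == y2))
  d <- sum(2L * (!same & !shared1) + 1L * shared1)
  structure(as.integer(d), skipped = sum(miss))
}

#' Identify multilocus genotypes (MLGs)
#'
#' Partitions samples into exact-match multilocus genotypes. By default a
#' missing call only matches a missing call; with `missing_matches = TRUE`
#' missing calls act as wildcards and samples compatible through a chain of
#' wildcard matches are joined (single linkage).
#'
#' @param gm a [genotypes] object.
#' @param missing_matches logical; treat missing calls as wildcards.
#' @return an object of class `mll_partition` with threshold 0 (the MLL
#'   partition equals the MLG partition).
#' @export
identify_mlg <- function(gm, missing_matches = FALSE) {
  n <- length(gm$ids)
  if (!missing_matches) {
    key <- apply(cbind(gm$a1, gm$a2), 1L, paste, collapse = "/")
    mlg <- match(key, unique(key))
  } else {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      xi1 <- gm$a1[i, ]; xi2 <- gm$a2[i, ]
      xj1 <- gm$a1[j, ]; xj2 <- gm$a2[j, ]
      m <- is.na(xi1) | is.na(xj1)
      if (all(m) || (all(xi1[!m] == xj1[!m]) && all(xi2[!m] == xj2[!m]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    mlg <- match(root, unique(root))
  }
  new_mll_partition(gm, mlg, seq_len(max(mlg)), 0L)
}

new_mll_partition <- function(gm, mlg_of, mll_of, threshold) {
  structure(list(ids = gm$ids, pop = gm$pop,
                 mlg_of = as.integer(mlg_of), mll_of = as.integer(mll_of),
                 threshold = as.integer(threshold)),
            class = "mll_partition")
}

#' Collapse MLGs into multilocus lineages (MLLs)
#'
#' Joins MLGs whose pairwise [allele_distance] is at most `threshold` by
#' single linkage (connected components of the threshold graph). Genotypes
#' separated by a few stepwise mutations or scoring errors thereby collapse
#' into one lineage; `threshold = 0` leaves the MLG partition unchanged.
#'
#' @param part an `mll_partition` from [identify_mlg].
#' @param gm the [genotypes] object the partition was built from.
#' @param threshold maximum allele differences joining two MLGs.
#' @return an updated `mll_partition`.
#' @export
collapse_mll <- function(part, gm, threshold = 2L) {
  stopifnot(inherits(part, "mll_partition"), threshold >= 0L)
  K <- max(part$mlg_of)
  if (threshold == 0L || K == 1L)
    return(new_mll_partition(gm, part$mlg_of, seq_len(K), threshold))
  rep_ix <- match(seq_len(K), part$mlg_of)  # first member of each MLG
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K)) {
    d <- tryCatch(allele_distance(gm, rep_ix[i], rep_ix[j]),
                  error = function(e) NA_integer_)
    if (!is.na(d) && d <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(K), find, integer(1))
  mll_of <- match(root, unique(root[order(rep_ix)]))
  new_mll_partition(gm, part$mlg_of, mll_of, threshold)
}

#' @export
print.mll_partition <- function(x, ...) {
  cat("mll_partition: ", length(x$ids), " samples, ",
      max(x$mlg_of), " MLGs, ", max(x$mll_of[x$mlg_of]), " MLLs",
      " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Per-population clonality summary
#'
#' @param part an `mll_partition`.
#' @return data.frame with per-population sample, MLG and MLL counts (an
#'   MLG/MLL is counted in every population where it has a member).
#' @export
mll_summary <- function(part) {
  mll_sample <- part$mll_of[part$mlg_of]
  pops <- levels(part$pop)
  out <- data.frame(
    pop = pops,
    N = as.integer(table(part$pop)[pops]),
    MLG = vapply(pops, function(p)
      length(unique(part$mlg_of[part$pop == p])), integer(1)),
    MLL = vapply(pops, function(p)
      length(unique(mll_sample[part$pop == p])), integer(1)))
  rownames(out) <- NULL
  out
}

#' Membership listing of each multilocus lineage
#' @param part an `mll_partition`.
#' @return data.frame of sample id, MLG index and MLL index.
#' @export
mll_members <- function(part) {
  data.frame(sample = part$ids, pop = as.character(part$pop),
             mlg = part$mlg_of, mll = part$mll_of[part$mlg_of])
}

#' Keep one representative per multilocus lineage
#'
#' The genet-level reduction used for ABC: for each MLL the lowest-sorted
#' sample id is retained.
#'
#' @param gm a [genotypes] object.
#' @param part an `mll_partition` for `gm`.
#' @return a [genotypes] object with one sample per MLL.
#' @export
representatives <- function(gm, part) {
  mll <- part$mll_of[part$mlg_of]
  keep <- vapply(sort(unique(mll)), function(k) {
    ix <- which(mll == k)
    ix[order(gm$ids[ix])][1L]
  }, integer(1))
  subset_samples(gm, sort(keep))
}
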