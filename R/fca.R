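# Factorial correspondence analysis of individuals coded by allele counts
# (GENETIX-style 0/1/2 coding), with population centroids.

#' Allele-count coding of genotypes
#'
#' Codes each individual by the number of copies (0, 1 or 2) it carries of
#' every allele observed at every locus. Columns are named `locus.allele`.
#' A locus missing in an individual contributes zeros across that locus's
#' columns; the missingness pattern is recorded in attribute `mask`.
#'
#' @param gm a [genotypes] object.
#' @return integer matrix, individuals x alleles, with attribute `mask`.
#' @export
allele_count_table <- function(gm) {
  n <- length(gm$ids); L <- length(gm$loci)
  cols <- list(); mask_cols <- list()
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(gm$a1[, l], gm$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) next
    m <- matrix(0L, n, length(alleles),
                dimnames = list(gm$ids,
                                paste0(gm$loci[l], ".", alleles)))
    for (k in seq_along(alleles)) {
      m[, k] <- (gm$a1[, l] %in% alleles[k]) + (gm$a2[, l] %in% alleles[k])
    }
    miss <- is.na(gm$a1[, l])
    m[miss, ] <- 0L
    cols[[length(cols) + 1L]] <- m
    mask_cols[[length(mask_cols) + 1L]] <-
      matrix(miss, n, length(alleles))
  }
  out <- do.call(cbind, cols)
  attr(out, "mask") <- do.call(cbind, mask_cols)
  out
}

#' Factorial correspondence analysis
#'
#' Standard correspondence analysis of a non-negative table: relative
#' frequencies, row/column masses, the Pearson-residual (standardized)
#' matrix, its singular value decomposition, and principal coordinates,
#' with axes sorted by eigenvalue. Axis signs are canonicalized by forcing
#' the largest-magnitude column loading on each axis to be positive.
#'
#' @param x a non-negative matrix (e.g. from [allele_count_table]) or a
#'   [genotypes] object (coded automatically).
#' @param k number of retained axes (default 3).
#' @return object of class `fca`: row (individual) principal coordinates,
#'   column standard coordinates, eigenvalues, percent inertia, masses.
#' @export
fca <- function(x, k = 3L) {
  if (inherits(x, "genotypes")) {
    gm <- x
    x <- allele_count_table(gm)
    pop <- gm$pop
  } else pop <- NULL
  if (any(x < 0)) stop("table must be non-negative")
  gt <- sum(x)
  if (gt <= 0) stop("table has zero grand total")
  P <- x / gt
  r <- rowSums(P); cmass <- colSums(P)
  keep_col <- cmass > 0
  P <- P[, keep_col, drop = FALSE]; cmass <- cmass[keep_col]
  zrow <- r <= 0
  E <- outer(r, cmass)
  S <- (P - E) / sqrt(E)
  S[zrow, ] <- 0
  inertia_total <- sum(S^2)
  if (inertia_total < 1e-12) stop("constant table: zero inertia")
  sv <- svd(S)
  pos <- sv$d > 1e-10
  d <- sv$d[pos]
  k <- min(k, sum(pos))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # principal row coordinates, standard column coordinates
  row_coord <- sweep(U, 1, ifelse(zrow, 1, sqrt(r)), "/") *
    rep(d[seq_len(k)], each = nrow(U))
  col_coord <- sweep(V, 1, sqrt(cmass), "/")
  row_coord[zrow, ] <- NA_real_
  for (ax in seq_len(k)) {
    j <- which.max(abs(col_coord[, ax]))
    if (col_coord[j, ax] < 0) {
      col_coord[, ax] <- -col_coord[, ax]
      row_coord[, ax] <- -row_coord[, ax]
    }
  }
  eig <- d^2
  dimnames(row_coord) <- list(rownames(x), paste0("Axis", seq_len(k)))
  dimnames(col_coord) <- list(colnames(P), paste0("Axis", seq_len(k)))
  structure(list(row_coord = row_coord, col_coord = col_coord,
                 eigenvalues = eig,
                 percent_inertia = 100 * eig / inertia_total,
                 total_inertia = inertia_total,
                 row_mass = r, pop = pop, k = k),
            class = "fca")
}

#' @export
print.fca <- function(x, ...) {
  cat("Factorial correspondence analysis: ", nrow(x$row_coord),
      " individuals, ", nrow(x$col_coord), " allele columns\n", sep = "")
  k <- x$k
  cat("  inertia on retained axes: ",
      paste0(sprintf("%.1f%%", x$percent_inertia[seq_len(k)]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Population centroids in ordination space
#'
#' Mass-weighted mean of member-individual coordinates per population.
#'
#' @param res an `fca` object.
#' @param pop population labels (default: carried from the genotypes).
#' @return matrix, populations x axes.
#' @export
population_centroids <- function(res, pop = res$pop) {
  if (is.null(pop)) stop("population labels required")
  pop <- factor(pop)
  k <- ncol(res$row_coord)
  out <- matrix(NA_real_, nlevels(pop), k,
                dimnames = list(levels(pop), colnames(res$row_coord)))
  for (p in levels(pop)) {
    ix <- which(pop == p & !is.na(res$row_coord[, 1]))
    w <- res$row_mass[ix]
    out[p, ] <- colSums(res$row_coord[ix, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' @export
plot.fca <- function(x, axes = c(1, 2), ...) {
  pop <- x$pop
  cols <- if (is.null(pop)) "grey30" else as.integer(factor(pop))
  graphics::plot(x$row_coord[, axes[1]], x$row_coord[, axes[2]],
                 col = cols, pch = 16, cex = 0.7,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                x$percent_inertia[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                x$percent_inertia[axes[2]]), ...)
  if (!is.null(pop)) {
    cen <- population_centroids(x)
    graphics::points(cen[, axes[1]], cen[, axes[2]], pch = 8, cex = 1.4,
                     col = seq_len(nrow(cen)))
    graphics::text(cen[, axes[1]], cen[, axes[2]], rownames(cen), pos = 3)
  }
  invisible(x)
}
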