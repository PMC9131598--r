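#' Diploid microsatellite genotype matrix
#'
#' Container for diploid codominant genotypes: `n` samples typed at `L`
#' microsatellite loci, each call an unordered pair of positive integer
#' allele sizes (or repeat numbers) or missing. Population labels partition
#' the samples.
#'
#' Calls are stored in two `n x L` integer matrices `a1`, `a2`, canonicalized
#' so `a1 <= a2`; a missing call has `NA` in both. Unordered-pair semantics
#' therefore hold under ordinary equality everywhere downstream.
#'
#' @param ids character vector of unique sample identifiers.
#' @param pop factor (or coercible) of population labels, one per sample.
#' @param loci character vector of locus names.
#' @param a1,a2 integer `n x L` matrices of allele sizes; `NA` for missing.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(ids, pop, loci, a1, a2) {
  ids <- as.character(ids)
  pop <- if (is.factor(pop)) factor(pop, levels = unique(as.character(pop))) else factor(pop, levels = unique(pop))
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids); L <- length(loci)
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(pop) != n) stop("pop labels must match number of samples")
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be n x L")
  if (L < 1L) stop("at least one locus required")
  if (n < 1L) stop("at least one sample required")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  if (any(a1[!miss] < 1L) || any(a2[!miss] < 1L))
    stop("allele sizes must be positive integers")
  swap <- !miss & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  if (any(tabulate(pop, nbins = nlevels(pop)) == 0L))
    stop("empty population level(s): ",
         paste(levels(pop)[tabulate(pop, nbins = nlevels(pop)) == 0L], collapse = ", "))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, pop = pop, loci = loci, a1 = a1, a2 = a2),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes: ", length(x$ids), " samples x ", length(x$loci),
      " loci, ", nlevels(x$pop), " populations\n", sep = "")
  tab <- table(x$pop)
  cat("  populations:",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotypes <- function(object, ...) {
  nal <- vapply(seq_along(object$loci), function(l) {
    length(unique(c(object$a1[, l], object$a2[, l])[!is.na(c(object$a1[, l], object$a2[, l]))]))
  }, integer(1))
  out <- data.frame(locus = object$loci, n_alleles = nal,
                    missing = colMeans(is.na(object$a1)))
  rownames(out) <- NULL
  out
}

#' Number of samples and loci
#' @param gm a `genotypes` object.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$ids)

#' @rdname n_samples
#' @export
n_loci <- function(gm) length(gm$loci)

#' Subset a genotypes object by sample
#' @param gm a `genotypes` object.
#' @param i integer or logical index over samples.
#' @return a `genotypes` object.
#' @export
subset_samples <- function(gm, i) {
  genotypes(gm$ids[i], factor(as.character(gm$pop[i])), gm$loci,
            gm$a1[i, , drop = FALSE], gm$a2[i, , drop = FALSE])
}

#' Read a genepop file
#'
#' Parses the genepop dialect: a title line, locus names (one per line or
#' comma-separated on one line), `Pop` separators, then per-sample lines
#' `id , a1a2 a1a2 ...` with 2- or 3-digit allele encoding. `00` / `000`
#' encodes a missing allele; a call with any missing allele is treated as a
#' missing genotype. The encoding width is auto-detected per file and
#' recorded in attribute `digits`.
#'
#' @param path path to a genepop file.
#' @return a [genotypes] object with populations in file order (labelled by
#'   the first sample id of each `Pop` block) and attribute `digits`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("genepop file too short: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  if (first_pop < 3L) stop("zero loci declared in ", path)
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("zero loci declared in ", path)
  L <- length(loci)

  blocks <- split(seq_along(lines)[-(1:first_pop)][!is_pop[-(1:first_pop)]],
                  cumsum(is_pop)[-(1:first_pop)][!is_pop[-(1:first_pop)]])
  blocks <- lapply(blocks, function(ix) ix[nzchar(trimws(lines[ix]))])
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0L]
  if (length(blocks) == 0L) stop("zero populations in ", path)

  all_tok <- character(0)
  ids <- character(0); popl <- character(0); rows <- list()
  for (b in seq_along(blocks)) {
    for (ln in blocks[[b]]) {
      txt <- lines[ln]
      comma <- regexpr(",", txt, fixed = TRUE)
      if (comma < 0) stop("parse error at line ", ln,
                          ": expected 'id , genotypes'")
      id <- trimws(substr(txt, 1L, comma - 1L))
      gts <- strsplit(trimws(substr(txt, comma + 1L, nchar(txt))),
                      "[ \t]+")[[1]]
      gts <- gts[nzchar(gts)]
      if (length(gts) != L)
        stop("parse error at line ", ln, ": ", length(gts),
             " genotype fields for ", L, " loci")
      ids <- c(ids, id); popl <- c(popl, sprintf("pop%02d", b))
      rows[[length(rows) + 1L]] <- gts
      all_tok <- c(all_tok, gts)
    }
  }
  widths <- unique(nchar(all_tok))
  digits <- if (any(widths == 6L)) 3L else if (all(widths == 4L)) 2L else
    stop("cannot detect allele encoding width (token widths: ",
         paste(widths, collapse = ","), ")")
  if (!all(widths %in% c(2L * digits)))
    stop("inconsistent genotype token widths in ", path)

  n <- length(ids)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- rows[[i]]
    x1 <- as.integer(substr(g, 1L, digits))
    x2 <- as.integer(substr(g, digits + 1L, 2L * digits))
    keep <- !is.na(x1) & !is.na(x2) & x1 > 0L & x2 > 0L
    a1[i, keep] <- x1[keep]; a2[i, keep] <- x2[keep]
  }
  # label each population by its first sample id (common genepop convention)
  pop_sizes <- vapply(blocks, length, integer(1))
  first_ids <- ids[cumsum(c(1L, pop_sizes[-length(pop_sizes)]))]
  lab <- make.unique(first_ids)
  popl <- rep(lab, pop_sizes)
  gm <- genotypes(ids, factor(popl, levels = lab), loci, a1, a2)
  attr(gm, "digits") <- digits
  gm
}

#' Write a genepop file
#'
#' Emits 3-digit allele encoding, one `Pop` block per population in level
#' order. Allele sizes above 999 cannot be represented and raise an error.
#'
#' @param gm a [genotypes] object.
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, title = "msatABC genepop export") {
  stopifnot(inherits(gm, "genotypes"))
  mx <- suppressWarnings(max(c(gm$a1, gm$a2), na.rm = TRUE))
  if (is.finite(mx) && mx > 999L)
    stop("allele size ", mx, " exceeds the 3-digit genepop encoding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$loci, con)
  for (p in levels(gm$pop)) {
    writeLines("Pop", con)
    ix <- which(gm$pop == p)
    for (i in ix) {
      g1 <- gm$a1[i, ]; g2 <- gm$a2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      writeLines(paste0(gm$ids[i], " , ",
                        paste0(sprintf("%03d", g1), sprintf("%03d", g2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write the long TSV sidecar format
#'
#' One row per sample x locus: columns `sample`, `pop`, `locus`, `allele1`,
#' `allele2` (`NA` for missing calls).
#'
#' @param path file path.
#' @return `read_genotypes_tsv` returns a [genotypes] object;
#'   `write_genotypes_tsv` returns `path` invisibly.
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "pop", "locus", "allele1", "allele2")
  if (!all(need %in% names(d))) stop("TSV must have columns: ",
                                     paste(need, collapse = ", "))
  ids <- unique(d$sample); loci <- unique(d$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(d$sample, ids), match(d$locus, loci))] <- as.integer(d$allele1)
  a2[cbind(match(d$sample, ids), match(d$locus, loci))] <- as.integer(d$allele2)
  pop <- d$pop[match(ids, d$sample)]
  genotypes(ids, factor(pop, levels = unique(pop)), loci, a1, a2)
}

#' @rdname read_genotypes_tsv
#' @param gm a [genotypes] object.
#' @export
write_genotypes_tsv <- function(gm, path) {
  n <- length(gm$ids); L <- length(gm$loci)
  d <- data.frame(sample = rep(gm$ids, each = L),
                  pop = rep(as.character(gm$pop), each = L),
                  locus = rep(gm$loci, times = n),
                  allele1 = as.vector(t(gm$a1)),
                  allele2 = as.vector(t(gm$a2)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool populations into groups
#'
#' Relabels populations according to a label-to-group mapping, e.g. pooling
#' meadows into the regional demes used as ABC populations. Every input
#' label must be covered by the mapping or listed in `drop`; dropped
#' populations are removed from the output.
#'
#' @param gm a [genotypes] object.
#' @param mapping named character vector: `names(mapping)` are input
#'   population labels, values are group labels.
#' @param drop character vector of labels to exclude (e.g. a small sample
#'   left out of downstream analysis).
#' @return a [genotypes] object with group labels (in first-appearance order
#'   of the mapping values).
#' @export
pool_populations <- function(gm, mapping, drop = character(0)) {
  stopifnot(inherits(gm, "genotypes"))
  labs <- levels(gm$pop)
  unknown <- setdiff(labs, c(names(mapping), drop))
  if (length(unknown))
    stop("mapping omits population(s) with no drop-list entry: ",
         paste(unknown, collapse = ", "))
  keep <- !(as.character(gm$pop) %in% drop)
  if (!any(keep)) stop("all populations dropped")
  newpop <- unname(mapping[as.character(gm$pop)[keep]])
  genotypes(gm$ids[keep], factor(newpop, levels = unique(unname(mapping))),
            gm$loci, gm$a1[keep, , drop = FALSE], gm$a2[keep, , drop = FALSE])
}
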