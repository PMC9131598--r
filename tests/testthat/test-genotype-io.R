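test_that("a minimal genepop file parses: codes, missing convention, shape", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy data", "LocA", "LocB", "Pop",
               "i1 , 001002 003003",
               "i2 , 000000 003004",
               "Pop",
               "j1 , 002002 004004",
               "j2 , 001001 003003"), f)
  gm <- read_genepop(f)
  expect_s3_class(gm, "genotypes")
  expect_equal(length(gm$loci), 2L)
  expect_equal(nlevels(gm$pop), 2L)
  expect_equal(attr(gm, "digits"), 3L)
  expect_equal(unname(c(gm$a1["i1", "LocA"], gm$a2["i1", "LocA"])), c(1L, 2L))
  # "000000" marks only that call missing
  expect_true(is.na(gm$a1["i2", "LocA"]))
  expect_equal(unname(gm$a1["i2", "LocB"]), 3L)
})

test_that("2-digit encoding and comma-separated locus headers are accepted", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "LocA, LocB", "POP",
               "a , 0102 0303", "b , 0201 0000"), f)
  gm <- read_genepop(f)
  expect_equal(attr(gm, "digits"), 2L)
  expect_equal(length(gm$loci), 2L)
  # unordered-pair semantics: (1,2) == (2,1)
  expect_equal(unname(gm$a1[, "LocA"]), c(1L, 1L))
  expect_equal(unname(gm$a2[, "LocA"]), c(2L, 2L))
  expect_true(is.na(gm$a1["b", "LocB"]))
})

test_that("malformed files raise errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "L2", "Pop", "x , 001001"), f)
  expect_error(read_genepop(f), "line 5")
  writeLines(c("t", "Pop", "x , 001001"), f)
  expect_error(read_genepop(f), "zero loci")
  writeLines(c("t", "L1", "Pop", "x , 001001", "x , 002002"), f)
  expect_error(read_genepop(f), "duplicate")
})

test_that("write/read round-trip is lossless over randomized matrices", {
  set.seed(11)
  for (rep in 1:100) {
    gm <- random_genotypes(n = sample(2:12, 1), L = sample(1:5, 1),
                           npop = sample(1:3, 1), miss = 0.15)
    f <- tempfile(fileext = ".gen")
    write_genepop(gm, f)
    back <- read_genepop(f)
    # the writer groups samples into Pop blocks: match rows by id
    ix <- match(gm$ids, back$ids)
    expect_false(anyNA(ix))
    expect_equal(unname(back$a1[ix, , drop = FALSE]), unname(gm$a1))
    expect_equal(unname(back$a2[ix, , drop = FALSE]), unname(gm$a2))
    # population partition is preserved (labels are file-derived)
    expect_equal(unname(table(as.integer(back$pop)[ix],
                              as.integer(gm$pop)) > 0) |> rowSums(),
                 rep(1, nlevels(gm$pop)), ignore_attr = TRUE)
    unlink(f)
  }
})

test_that("write_genepop rejects alleles overflowing 3 digits", {
  gm <- genotypes("s1", "A", "L1", matrix(1000L), matrix(1000L))
  expect_error(write_genepop(gm, tempfile()), "3-digit")
})

test_that("single-pop single-locus matrix emits exactly one Pop block", {
  gm <- genotypes(c("a", "b"), c("P", "P"), "L1",
                  matrix(c(1L, 2L)), matrix(c(1L, 3L)))
  f <- withr::local_tempfile()
  write_genepop(gm, f)
  expect_equal(sum(toupper(trimws(readLines(f))) == "POP"), 1L)
})

test_that("unused population levels cannot survive construction", {
  gm <- genotypes("s1", factor("A", levels = c("A", "B")), "L1",
                  matrix(1L), matrix(1L))
  expect_equal(nlevels(gm$pop), 1L)
  expect_error(genotypes(character(0), factor(character(0)), "L1",
                         matrix(integer(0), 0, 1), matrix(integer(0), 0, 1)),
               "at least one sample")
})

test_that("TSV sidecar round-trips", {
  set.seed(3)
  gm <- random_genotypes(8, 3, npop = 2, miss = 0.2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gm, f)
  back <- read_genotypes_tsv(f)
  expect_equal(unname(back$a1), unname(gm$a1))
  expect_equal(as.character(back$pop), as.character(gm$pop))
})

test_that("pooling meadows into regional demes reproduces the study sizes", {
  des <- meadow_design()
  n <- sum(des$n)
  expect_equal(n, 331L)  # per-site counts; the loader never hard-codes this
  pop <- rep(des$meadow, des$n)
  gm <- genotypes(sprintf("s%03d", seq_len(n)), pop, "L1",
                  matrix(1L, n, 1), matrix(2L, n, 1))
  mapping <- c(FAN = "N", VRA = "N", NKA = "N", LEM = "NE", IME = "NE",
               VIA = "NW", AGT = "NW", CHA = "NW",
               EPA = "CW", WPA = "CW", MAG = "CW")
  pooled <- pool_populations(gm, mapping, drop = "CYP")
  sizes <- table(pooled$pop)
  expect_equal(unname(sizes["N"]), 34 + 34 + 22, ignore_attr = TRUE)  # = 90
  expect_equal(unname(sizes["NE"]), 8 + 32, ignore_attr = TRUE)
  expect_equal(unname(sizes["NW"]), 23 + 38 + 9, ignore_attr = TRUE)
  expect_equal(unname(sizes["CW"]), 47 + 36 + 37, ignore_attr = TRUE)
  expect_equal(sum(sizes), n - 11L)  # dropped population removed
})

test_that("identity pooling leaves the matrix unchanged; gaps error", {
  set.seed(5)
  gm <- random_genotypes(6, 2, npop = 2)
  idm <- stats::setNames(levels(gm$pop), levels(gm$pop))
  same <- pool_populations(gm, idm)
  expect_equal(same$a1, gm$a1)
  expect_equal(as.character(same$pop), as.character(gm$pop))
  expect_error(pool_populations(gm, idm[-1]), "omits")
})
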