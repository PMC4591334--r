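test_that("count tables round-trip through TSV bit-identically", {
  m <- matrix(c(0L, 5L, 12L, 3L, 999L, 1L), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("A1", "B1")))
  cd <- data.frame(sample_id = c("A1", "B1"), group = c("AD", "control"),
                   mappable_reads = c(2e6, 3e6))
  x <- MirCountSet(m, sampleData = cd, locus = c("L1", "L1", "L2"))
  tmp <- tempfile(fileext = ".tsv"); stmp <- tempfile(fileext = ".tsv")
  writeCountTable(x, tmp, comment = "toy")
  writeSampleTable(colData(x), stmp)
  y <- readCountTable(tmp, stmp)
  expect_identical(assay(y), assay(x))
  expect_identical(locusAssignments(y), locusAssignments(x))
  expect_equal(mappableReads(y), mappableReads(x))
})

test_that("a simulated cohort round-trips through the writers", {
  sim <- smallCohort(seed = 2L)
  tmp <- tempfile(fileext = ".tsv"); stmp <- tempfile(fileext = ".tsv")
  writeCountTable(sim$counts, tmp)
  writeSampleTable(colData(sim$counts), stmp)
  y <- readCountTable(tmp, stmp)
  expect_identical(assay(y), assay(sim$counts))
  expect_identical(rowData(y)$sequence, rowData(sim$counts)$sequence)
})

test_that("malformed count files are rejected with the offending row", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tlocus\ts1\ts2",
               "a\tL1\t1\t2",
               "b\tL1\t3.5\t0"), tmp)
  expect_error(readCountTable(tmp), "row\\(s\\): 2")
  writeLines(c("seq_id\tlocus\ts1",
               "a\tL1\t1",
               "a\tL2\t2"), tmp)
  expect_error(readCountTable(tmp), "duplicate")
  writeLines(c("seq_id\ts1", "a\t1"), tmp)
  expect_error(readCountTable(tmp), "locus")
})

test_that("sample tables enforce their required columns", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "a\tAD"), tmp)
  expect_error(readSampleTable(tmp), "mappable_reads")
  writeLines(c("sample_id\tgroup\tmappable_reads",
               "a\tAD\t100", "b\tAD\t100"), tmp)
  expect_error(readSampleTable(tmp), "two classes")
})

test_that("expression matrices preserve level and normalization on re-read", {
  m <- matrix(c(1.5, 0, 2.25, 4), 2, 2,
              dimnames = list(c("L1", "L2"), c("a", "b")))
  x <- toyLocusSet(m, c("AD", "control"))
  tmp <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(x, tmp)
  y <- readExpressionMatrix(tmp)
  expect_equal(assay(y), assay(x))
  expect_equal(normMethod(y), "cpm_mappable")
  expect_equal(exprLevel(y), "locus")
})

test_that("filterMinTotal keeps sequences at or above the threshold", {
  m <- matrix(c(499L, 0L, 250L, 250L, 501L, 0L), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  x <- MirCountSet(m, locus = c("L1", "L2", "L3"))
  f <- filterMinTotal(x, 500)
  expect_identical(rownames(f), c("b", "c"))  # 500 kept, 499 dropped
  empty <- filterMinTotal(x[0, ], 500)
  expect_equal(nrow(empty), 0L)
  expect_error(
    filterMinTotal(normalizeCpmMappable(
      MirCountSet(m, locus = c("L1", "L2", "L3"),
                  sampleData = data.frame(sample_id = c("s1", "s2"),
                                          mappable_reads = c(1e6, 1e6))))),
    "raw")
})

test_that("filterMinTotal matches a brute-force row-sum check", {
  set.seed(10)
  m <- matrix(rpois(300, 30), 30, 10,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("c%02d", 1:10)))
  x <- MirCountSet(m, locus = sprintf("L%02d", 1:30))
  for (thr in c(0, 250, 300, 1000)) {
    keep <- vapply(seq_len(nrow(m)), function(i) sum(m[i, ]) >= thr,
                   logical(1))
    expect_identical(rownames(filterMinTotal(x, thr)), rownames(m)[keep])
  }
})

test_that("CPM-mappable normalization follows its definition", {
  m <- matrix(c(7L, 0L, 14L, 3L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cd <- data.frame(sample_id = c("s1", "s2"), group = c("AD", "control"),
                   mappable_reads = c(14e6, 7e6))
  x <- MirCountSet(m, sampleData = cd, locus = c("L1", "L2"))
  n1 <- normalizeCpmMappable(x)
  expect_equal(assay(n1)["a", "s1"], 0.5)
  expect_equal(assay(n1)["b", "s2"], 3 * 1e6 / 7e6)
  # doubling mappable reads halves every value
  cd2 <- cd; cd2$mappable_reads <- cd$mappable_reads * 2
  n2 <- normalizeCpmMappable(MirCountSet(m, cd2, locus = c("L1", "L2")))
  expect_equal(assay(n2), assay(n1) / 2)
  # zeros and positives preserved
  expect_identical(assay(n1) == 0, m == 0)
  cdBad <- cd[, c("sample_id", "group")]
  expect_error(
    normalizeCpmMappable(MirCountSet(m, cdBad, locus = c("L1", "L2"))),
    "mappable_reads")
})

test_that("normalization reduces spike-in variability across samples", {
  sim <- smallCohort(seed = 12L, nPerGroup = 15L)
  raw <- sumByLocus(sim$counts)
  nrm <- sumByLocus(normalizeCpmMappable(sim$counts))
  spike <- "ath-miR-159a"
  cvOf <- function(v) sd(v) / mean(v)
  expect_lt(cvOf(assay(nrm)[spike, ]), cvOf(assay(raw)[spike, ]))
})

test_that("spike/reference geometric-mean normalization is exact on a toy", {
  m <- matrix(c(10L, 20L,   # target locus
                4L, 16L,    # spike
                9L, 25L),   # reference
              3, 2, byrow = TRUE,
              dimnames = list(c("t", "sp", "rf"), c("s1", "s2")))
  x <- MirCountSet(m, locus = c("L1", "SPIKE", "REF"))
  y <- normalizeSpikeGeomean(x, spikeId = "SPIKE", referenceId = "REF",
                             scale = 1)
  expect_equal(assay(y)["t", "s1"], 10 / 6)     # sqrt(4*9) = 6
  expect_equal(assay(y)["t", "s2"], 20 / 20)    # sqrt(16*25) = 20
  # the spike row itself becomes sqrt(spike/reference) * scale
  expect_equal(assay(y)["sp", "s1"], sqrt(4 / 9))
  # default scale: mean of per-sample geometric means
  y2 <- normalizeSpikeGeomean(x, spikeId = "SPIKE", referenceId = "REF")
  expect_equal(assay(y2), assay(y) * mean(c(6, 20)))
  m0 <- m; m0["sp", 2] <- 0L
  expect_error(
    normalizeSpikeGeomean(MirCountSet(m0, locus = c("L1", "SPIKE", "REF")),
                          "SPIKE", "REF"),
    "s2")
})

test_that("sumByLocus adds sequence variants and keeps single sequences", {
  m <- rbind(a = c(1.5, 2), b = c(2.5, 3), c = c(2.5, 2))
  colnames(m) <- c("s1", "s2")
  x <- MirCountSet(m, locus = c("L1", "L1", "L2"),
                   normalization = "cpm_mappable")
  y <- sumByLocus(x)
  expect_equal(assay(y)["L1", ], c(s1 = 4.0, s2 = 5.0))
  expect_equal(assay(y)["L2", ], c(s1 = 2.5, s2 = 2.0))
  expect_equal(exprLevel(y), "locus")
  expect_equal(normMethod(y), "cpm_mappable")
})

test_that("multinomial variant split re-sums to the locus totals", {
  sim <- smallCohort(seed = 13L)
  locRaw <- sumByLocus(sim$counts)
  # summing after normalization equals normalizing the locus sums (linearity)
  a <- assay(sumByLocus(normalizeCpmMappable(sim$counts)))
  b <- assay(normalizeCpmMappable(locRaw))
  expect_equal(a, b)
})

test_that("low-expression filter applies the control-mean threshold exactly", {
  m <- matrix(c(3.59, 3.59, 3.60, 3.60, 10, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("lo", "at", "hi"), c("c1", "c2")))
  x <- toyLocusSet(m, c("control", "control"))
  expect_identical(rownames(filterLowExpression(x, 3.6)), c("at", "hi"))
  expect_identical(rownames(filterLowExpression(x, 0)), rownames(m))
  expect_error(filterLowExpression(toyLocusSet(m, c("AD", "AD"))),
               "control")
})

test_that("quantile mode matches a sort-based oracle", {
  set.seed(99)
  m <- matrix(runif(200, 0, 50), 20, 10,
              dimnames = list(sprintf("L%02d", 1:20), sprintf("s%02d", 1:10)))
  x <- toyLocusSet(m, rep(c("AD", "control"), each = 5))
  for (q in c(0.1, 0.25, 0.5)) {
    got <- rownames(filterLowExpression(x, q = q))
    means <- rowMeans(m[, 6:10])
    dropN <- floor(q * 20)
    keep <- sort(setdiff(rownames(m), rownames(m)[order(means)][seq_len(dropN)]))
    expect_setequal(got, keep)
  }
})
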