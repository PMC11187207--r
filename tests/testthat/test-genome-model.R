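test_that("partitionGenome tiles with a ceiling bin count and exact coverage", {
  gb <- partitionGenome(c(chr1 = 1.2e6), binSize = 5e5)
  br <- binRanges(gb)
  expect_equal(length(br), 3L)
  expect_equal(start(br), c(1L, 500001L, 1000001L))
  expect_equal(end(br), c(500000L, 1000000L, 1200000L))

  gb2 <- partitionGenome(c(a = 1e6, b = 1e6), binSize = 1e5)
  expect_equal(nBins(gb2), 20L)
  expect_equal(as.integer(table(as.character(seqnames(binRanges(gb2))))),
               c(10L, 10L))

  # tiling conservation: per-chromosome bin widths sum to the length
  for (gb in list(tinyBins(), partitionGenome(c(x = 777777), 1e5))) {
    w <- tapply(width(binRanges(gb)),
                as.character(seqnames(binRanges(gb))), sum)
    expect_equal(as.numeric(w[names(chromLengths(gb))]),
                 unname(as.numeric(chromLengths(gb))))
  }

  # short terminal bins are masked by default, configurable
  expect_equal(sum(binMask(tinyBins())), 1L)
  expect_equal(sum(binMask(partitionGenome(c(chrB = 5.5e5), 1e5,
                                           maskShortLast = FALSE))), 0L)

  expect_error(partitionGenome(c(chr1 = 1e6), 0), "invalid")
  expect_error(partitionGenome(c(chr1 = -5), 1e5), "invalid")
})

test_that("readIntervalTrack parses BED and bedGraph with line-level errors", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t450\tgeneA\t7"), bed)
  gr <- readIntervalTrack(bed)
  expect_equal(start(gr), c(101L, 301L))
  expect_equal(end(gr), c(200L, 450L))
  expect_equal(mcols(gr)$name[2L], "geneA")

  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t100\t0.5", bg)
  expect_equal(mcols(readIntervalTrack(bg))$score, 0.5)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(readIntervalTrack(bad), "line 2")
  writeLines(c("chr1\tx\t200"), bad)
  expect_error(readIntervalTrack(bad), "line 1")

  # 1-based closed input converts at the boundary
  writeLines("chr1\t101\t200", bad)
  gr1 <- readIntervalTrack(bad, oneBased = TRUE)
  expect_equal(c(start(gr1), end(gr1)), c(101L, 200L))
})

test_that("binTrack implements midpoint counts, coverage and weighted scores", {
  gb <- tinyBins()
  inside <- GRanges("chrA", IRanges(120001, 130000))
  cnt <- binTrack(inside, gb, "count")
  expect_equal(cnt[2L], 1)
  expect_equal(sum(cnt), 1)

  # a gene spanning a bin edge is counted once, in its midpoint bin
  spanning <- GRanges("chrA", IRanges(160001, 260000))  # midpoint 210 kb
  cntSpan <- binTrack(spanning, gb, "count")
  expect_equal(which(cntSpan == 1), 3L)
  expect_equal(sum(cntSpan), 1)

  cov <- binTrack(GRanges("chrA", IRanges(140001, 240000)), gb,
                  "coverage_fraction")
  expect_equal(cov[2L], 0.6)
  expect_equal(cov[3L], 0.4)
  expect_true(all(cov >= 0 & cov <= 1))

  # summed overlapped bp equals total interval bp (with multiplicity)
  set.seed(3)
  st <- sort(sample(1:9e5, 20))
  trk <- GRanges("chrA", IRanges(st, st + sample(1000:50000, 20)))
  trk <- trk[end(trk) <= 1e6]
  covAll <- binTrack(trk, gb, "coverage_fraction")
  expect_equal(sum(covAll * width(binRanges(gb))), sum(width(trk)))

  empty <- GRanges()
  expect_equal(binTrack(empty, gb, "count"), numeric(nBins(gb)))
  expect_true(all(is.na(binTrack(empty, gb, "mean_score"))))
  expect_error(binTrack(inside, gb, "mean_score"), "score")

  scored <- GRanges("chrA", IRanges(c(1, 50001), c(50000, 100000)),
                    score = c(1, 3))
  expect_equal(binTrack(scored, gb, "mean_score")[1L], 2)

  expect_error(binTrack(GRanges("chrZ", IRanges(1, 10)), gb), "chrZ")
})

test_that("writeBedGraph round-trips values and omits masked bins", {
  gb <- tinyBins()
  set.seed(42)
  vals <- round(runif(nBins(gb)), 6)
  path <- tempfile(fileext = ".bedgraph")
  writeBedGraph(vals, gb, path)
  expect_equal(length(readLines(path)), sum(!binMask(gb)))

  back <- binTrack(readIntervalTrack(path), gb, "mean_score")
  keep <- !binMask(gb)
  expect_equal(back[keep], vals[keep], tolerance = 1e-8)
  expect_true(all(is.na(back[!keep])))

  expect_error(writeBedGraph(vals[-1], gb, path), "invalid")
})

test_that("count tables round-trip through TSV", {
  gb <- tinyBins()
  m <- matrix(rpois(nBins(gb) * 3L, 50), ncol = 3L,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  path <- tempfile(fileext = ".tsv")
  writeCountsTSV(m, gb, path)
  back <- readCountsTSV(path)
  expect_equal(back$counts, m)
  expect_equal(nBins(back$bins), nBins(gb))
  expect_equal(chromLengths(back$bins), chromLengths(gb))
})

test_that("chromosome aliases translate names at the reading boundary", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100", "chr2\t0\t100"), bed)
  gr <- readIntervalTrack(bed, chromAliases = c("1" = "chr1"))
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr2"))
})
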