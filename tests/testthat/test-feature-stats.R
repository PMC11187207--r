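test_that("sampleRandomRegions matches lengths and avoids the mask", {
  gb <- tinyBins()
  lens <- c(5e4, 1e5, 2.5e5, 5e4)
  r1 <- sampleRandomRegions(lens, gb, seed = 4)
  expect_equal(width(r1), as.integer(lens))
  expect_identical(as.data.frame(r1),
                   as.data.frame(sampleRandomRegions(lens, gb, seed = 4)))

  # never touches masked territory (the short chrB tail)
  many <- sampleRandomRegions(rep(1e5, 200), gb, seed = 8)
  masked <- binRanges(gb)[binMask(gb)]
  expect_equal(sum(countOverlaps(many, masked)), 0L)

  allMasked <- gb
  binMask(allMasked) <- rep(TRUE, nBins(gb))
  expect_error(sampleRandomRegions(1e5, allMasked, seed = 1),
               "fully masked")
  expect_error(sampleRandomRegions(1e7, gb, seed = 1), "sampling failure")

  sets <- sampleRandomRegions(c(1e5, 1e5), gb, nSets = 3, seed = 2)
  expect_length(sets, 3L)
})

test_that("valueAtSites averages unmasked bins under the site", {
  gb <- tinyBins()
  vals <- seq_len(nBins(gb))
  onebin <- GRanges("chrA", IRanges(150001, 160000))
  expect_equal(valueAtSites(onebin, vals, gb), 2)

  twobin <- GRanges("chrA", IRanges(150001, 250000))  # bins 2 and 3
  expect_equal(valueAtSites(twobin, vals, gb), 2.5)

  maskedSite <- GRanges("chrB", IRanges(500001, 540000))  # masked tail bin
  expect_true(is.na(valueAtSites(maskedSite, vals, gb)))

  # window extension pulls in flanking bins
  expect_equal(valueAtSites(onebin, vals, gb, windowBins = 1L), 2)
})

test_that("laminaOE compares site overlap against genomic coverage", {
  gb <- partitionGenome(c(chr1 = 1e6), 1e5)
  lad <- GRanges("chr1", IRanges(1, 5e5))  # coverage 0.5
  sites <- GRanges("chr1", IRanges(c(1e4, 2e5, 4e5), c(1.1e4, 2.1e5, 4.1e5)))
  res <- laminaOE(sites, lad, gb)
  expect_equal(res$oe, 2)
  expect_equal(res$expected, 0.5)

  outside <- GRanges("chr1", IRanges(c(6e5, 8e5), c(6.1e5, 8.1e5)))
  expect_equal(laminaOE(outside, lad, gb)$oe, 0)

  expect_error(laminaOE(sites, GRanges(), gb), "zero expected")
})

test_that("compartment labels follow the eigenvector sign convention", {
  gb <- partitionGenome(c(chr1 = 3e5), 1e5)
  eig <- c(0.8, -0.3, 0)
  sites <- GRanges("chr1", IRanges(c(1, 100001, 200001),
                                   c(100000, 200000, 300000)))
  res <- compartmentAtSites(sites, eig, gb)
  expect_equal(as.character(res$label), c("A", "B", "unassigned"))
  expect_equal(res$value, eig)
})

test_that("deriveRegionSets extracts long genes and long intergenic gaps", {
  gb <- partitionGenome(c(chr1 = 5e6, chr2 = 2e6), 1e5)
  genes <- GRanges("chr1", IRanges(c(1e5, 1000100, 3e6),
                                   c(7e5, 1000200, 3.2e6)))
  rs <- deriveRegionSets(genes, gb)
  expect_equal(width(rs$longGenes), 600001L)  # only the 600 kb gene

  # adjacent genes 100 bp apart leave no intergenic interval between them;
  # a gene-free 2 Mb chromosome is one long intergenic interval
  ig <- rs$longIntergenic
  expect_true(any(as.character(seqnames(ig)) == "chr2" & width(ig) == 2e6))
  expect_false(any(start(ig) > 7e5 & end(ig) < 1000100))
  expect_true(all(width(ig) > 1e6))

  expect_warning(rs0 <- deriveRegionSets(GRanges(), gb), "empty gene track")
  expect_equal(length(rs0$longGenes), 0L)
})

test_that("mannWhitney exact branch equals enumeration, ties included", {
  res <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$method, "exact")

  same <- mannWhitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)

  # oracle: independent enumeration over all group assignments
  enumP <- function(a, b) {
    pool <- c(a, b)
    n1 <- length(a)
    r <- rank(pool)
    mu <- n1 * length(b) / 2
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(combn(length(pool), n1), 2, function(ix) {
      sum(rank(pool)[ix]) - n1 * (n1 + 1) / 2
    })
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
  }
  set.seed(17)
  for (i in 1:40) {
    a <- sample(1:6, sample(2:6, 1), replace = TRUE)
    b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_equal(mannWhitney(a, b)$p, enumP(a, b))
  }

  # against the standard implementation when ties are absent
  set.seed(18)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    expect_equal(mannWhitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(mannWhitney(a, b)$U,
                 unname(wilcox.test(a, b, exact = TRUE)$statistic))
  }

  # large shifted samples are overwhelmingly significant
  set.seed(19)
  shifted <- mannWhitney(rnorm(50) + 5, rnorm(50))
  expect_equal(shifted$method, "normal")
  expect_lt(shifted$p, 1e-6)

  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("oneWayANOVA matches direct sums of squares", {
  # equal group means with internal variance: F = 0, p = 1
  res0 <- oneWayANOVA(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # two groups: F equals the square of the pooled-variance t statistic
  a <- c(1.1, 2.3, 0.7, 1.9)
  b <- c(2.2, 3.1, 2.9)
  res <- oneWayANOVA(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
  expect_equal(res$p, tt$p.value)

  # hand-computed sums of squares for {1,2,3} vs {7,8,9}
  g <- list(c(1, 2, 3), c(7, 8, 9))
  ssb <- 3 * (2 - 5)^2 + 3 * (8 - 5)^2
  ssw <- 2 + 2
  fHand <- (ssb / 1) / (ssw / 4)
  expect_equal(oneWayANOVA(g)$F, fHand)

  expect_error(oneWayANOVA(list(c(1, 1), c(1, 1))), "undefined F")
  expect_error(oneWayANOVA(list(1:3)), "2 groups")
})

test_that("testEnrichment assembles a coherent result object", {
  gb <- deskBins()
  truth <- makeRTTruth(gb, coupling = 3, seed = 22)
  geneDensity <- binTrack(geneAnnotation(truth), genomeBins(truth), "count")
  # sites deliberately placed in the earliest (gene-rich) decile
  early <- which(rtProgram(truth) < 0.1)
  br <- binRanges(genomeBins(truth))[early[1:100]]
  res <- testEnrichment(br, geneDensity, genomeBins(truth),
                        statistic = "gene_density", nNull = 360, seed = 2)
  expect_s4_class(res, "EnrichmentResult")
  expect_equal(res@nNull, 360L)
  expect_lt(res@pValue, 0.05)  # early bins are gene-dense by construction
  expect_gt(mean(res@siteValues), mean(res@nullValues))
  df <- as.data.frame(res)
  expect_equal(df$n_sites, 100L)
})
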