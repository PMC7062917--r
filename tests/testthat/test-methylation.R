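test_that("context classification follows the downstream-two-base rule", {
  g <- GenomeSequence(c(Chr1 = "ACGT"))
  r <- classifyContext(g, "Chr1", 2, "+")
  expect_equal(r$context, "CG")
  expect_equal(r$trinucleotide, "CGT")

  g2 <- GenomeSequence(c(Chr1 = "TTGAA"))
  r2 <- classifyContext(g2, "Chr1", 3, "-")
  expect_equal(r2$context, "CHH")
  expect_equal(r2$trinucleotide, "CAA")

  g3 <- GenomeSequence(c(Chr1 = "ACAGT"))
  r3 <- classifyContext(g3, "Chr1", 2, "+")
  expect_equal(r3$context, "CHG")
  expect_equal(r3$trinucleotide, "CAG")

  ## non-cytosine is an error; chromosome edge / N is undefined (NA)
  expect_error(classifyContext(g, "Chr1", 1, "+"), "not a cytosine")
  edge <- classifyContext(GenomeSequence(c(Chr1 = "AACG")), "Chr1", 3, "+")
  expect_true(is.na(edge$context))
  nn <- classifyContext(GenomeSequence(c(Chr1 = "ACNGT")), "Chr1", 2, "+")
  expect_true(is.na(nn$context))
})

test_that("cytosine enumeration agrees with the brute-force scanner", {
  withr::local_seed(42)
  for (i in 1:5) {
    s <- randomSeq(3000, withN = TRUE)
    g <- GenomeSequence(c(ChrT = s))
    got <- cytosineSites(g)
    gdf <- data.frame(pos = GenomicRanges::start(got),
                      strand = as.character(GenomicRanges::strand(got)),
                      context = as.character(S4Vectors::mcols(got)$context),
                      tri = S4Vectors::mcols(got)$tri)
    gdf <- gdf[order(gdf$pos, gdf$strand), ]
    rownames(gdf) <- NULL
    expect_equal(gdf, contextOracle(s))
  }
})

test_that("site-level ML and the non-conversion correction are exact", {
  expect_equal(siteML(3, 7), 0.3)
  expect_equal(siteML(0, 10), 0)
  expect_equal(siteML(10, 0), 1)
  expect_true(is.na(siteML(0, 0)))
  expect_error(siteML(-1, 5), "non-negative")

  expect_equal(correctML(0.3, 0.005), (0.3 - 0.005) / 0.995)
  expect_equal(correctML(0.004, 0.005), 0)      # clamped at 0
  expect_equal(correctML(0.42, 0), 0.42)        # identity at r = 0
  expect_error(correctML(0.5, 1), "in \\[0,1\\)")
})

test_that("non-conversion estimation pools reads over the control", {
  g <- GenomeSequence(c(Chr1 = "ACGTACGT", lambda = "AACGTACGTT"),
                      controlChrom = "lambda")
  m <- makeMethylome(chrom = c("Chr1", "lambda", "lambda"),
                     pos = c(2L, 3L, 7L), strand = "+",
                     M = c(5L, 1L, 1L), U = c(5L, 199L, 199L),
                     context = c("CG", "CG", "CG"))
  m <- estimateNonconversion(m, g)
  expect_equal(nonconversionRate(m), 2 / 400)   # pooled, Chr1 excluded

  z <- makeMethylome("lambda", 3L, "+", 0L, 100L, "CG")
  expect_equal(nonconversionRate(estimateNonconversion(z, g)), 0)

  nocov <- makeMethylome("Chr1", 2L, "+", 3L, 7L, "CG")
  expect_error(estimateNonconversion(nocov, g), "control")
})

test_that("methylated-site calls use the exact binomial tail against r", {
  m <- makeMethylome(chrom = "Chr1", pos = c(10L, 20L, 30L, 40L),
                     strand = "+", M = c(5L, 0L, 2L, 1L),
                     U = c(0L, 10L, 8L, 1L), context = rep("CG", 4),
                     sampleId = "t")
  nonconversionRate(m) <- 0.005
  calls <- callMethylatedSites(m, minCoverage = 5L, alpha = 0.05)
  ## (5,5): p = 0.005^5
  expect_equal(calls[pos == 10, p], 0.005^5, tolerance = 1e-12)
  expect_true(calls[pos == 10, methylated])
  ## (0,10): p = 1
  expect_equal(calls[pos == 20, p], 1)
  expect_false(calls[pos == 20, methylated])
  ## (2,10): brute-force binomial tail
  oracle <- sum(dbinom(2:10, 10, 0.005))
  expect_equal(calls[pos == 30, p], oracle, tolerance = 1e-12)
  ## coverage 2 < 5: not testable
  expect_false(calls[pos == 40, testable])
  expect_true(is.na(calls[pos == 40, p]))
})

test_that("sliding windows tile from position 1 and truncate at the end", {
  m1 <- makeMethylome("Chr1", 1500L, "+", 4L, 6L, "CG",
                      seqlens = c(Chr1 = 3000L))
  w <- slidingWindowML(m1, 3000L, 600L, context = "CG")
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 1L)
  expect_equal(w$end, 3000L)
  expect_equal(w$ml, 0.4)
  expect_equal(w$n_sites, 1L)

  m2 <- makeMethylome("Chr1", c(100L, 3500L), "+", c(1L, 1L), c(1L, 3L),
                      c("CG", "CG"), seqlens = c(Chr1 = 3600L))
  w2 <- slidingWindowML(m2, 3000L, 600L, context = "CG")
  expect_equal(w2$start, c(1L, 601L))
  expect_equal(w2$end, c(3000L, 3600L))
  ## first window holds only the first site, second only the second
  expect_equal(w2$ml, c(0.5, 0.25))
})

test_that("pooled window ML is the coverage-weighted mean of site MLs", {
  cfg <- smallConfig(seed = 9L)
  g <- simulateGenome(cfg)
  m <- simulateCounts(simulateTrueMethylome(g, cfg), cfg, "w")
  w <- slidingWindowML(m, 3000L, 3000L, context = "CG")
  st <- methSites(m)
  keep <- as.character(S4Vectors::mcols(st)$context) == "CG" &
    (S4Vectors::mcols(st)$M + S4Vectors::mcols(st)$U) > 0
  st <- st[keep]
  withr::local_seed(1)
  for (i in sample(nrow(w), 5)) {
    sel <- as.character(GenomicRanges::seqnames(st)) == w$chrom[i] &
      GenomicRanges::start(st) >= w$start[i] &
      GenomicRanges::start(st) <= w$end[i]
    M <- S4Vectors::mcols(st)$M[sel]; U <- S4Vectors::mcols(st)$U[sel]
    cov <- M + U
    expect_equal(w$ml[i], sum(cov * (M / cov)) / sum(cov))
  }
})

test_that("bin profile equals sliding windows with window = step = bin", {
  cfg <- smallConfig(seed = 10L)
  g <- simulateGenome(cfg)
  m <- simulateCounts(simulateTrueMethylome(g, cfg), cfg, "b")
  expect_equal(binProfile(m, 10000L),
               slidingWindowML(m, 10000L, 10000L))
  empty <- makeMethylome("Chr1", 5L, "+", 0L, 0L, "CG",
                         seqlens = c(Chr1 = 100L))
  expect_equal(nrow(binProfile(empty, 10L)), 0L)
})

test_that("context proportions share one testable denominator and add up", {
  n <- 100L
  m <- makeMethylome(chrom = "Chr1", pos = seq(10L, by = 10L, length.out = n),
                     strand = "+",
                     M = c(rep(50L, 40), rep(0L, 60)),
                     U = c(rep(0L, 40), rep(50L, 60)),
                     context = c(rep("CG", 40), rep("CHG", 30),
                                 rep("CHH", 30)))
  nonconversionRate(m) <- 0.004
  calls <- callMethylatedSites(m)
  pr <- contextProportions(calls, by = "genome")
  expect_equal(pr$pct_mCG, 40)
  expect_equal(pr$pct_mCHG, 0)
  expect_equal(pr$pct_total_mCX, 40)
  expect_equal(pr$share_mCG, 1)
  ## additivity holds on simulated data too
  cfg <- smallConfig(seed = 13L)
  g <- simulateGenome(cfg)
  ms <- estimateNonconversion(
    simulateCounts(simulateTrueMethylome(g, cfg), cfg, "pp"), g)
  pr2 <- contextProportions(callMethylatedSites(ms), by = "both",
                            excludeChrom = "lambda")
  expect_equal(pr2$pct_total_mCX,
               pr2$pct_mCG + pr2$pct_mCHG + pr2$pct_mCHH, tolerance = 1e-9)
  withShare <- pr2[pr2$pct_total_mCX > 0, ]
  expect_equal(withShare$share_mCG + withShare$share_mCHG +
                 withShare$share_mCHH, rep(1, nrow(withShare)))
})

test_that("raw ML reflects the error model and correction inverts it", {
  cfg <- SimulationConfig(seed = 21L, chromLengths = 60000L,
                          lambdaLength = 20000L, levelDispersion = Inf,
                          baseLevels = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
                          nonconversionRate = 0.01, coverageMean = 30)
  g <- simulateGenome(cfg)
  m <- estimateNonconversion(
    simulateCounts(simulateTrueMethylome(g, cfg), cfg, "corr"), g)
  st <- methSites(m)
  off <- as.character(GenomicRanges::seqnames(st)) != "lambda"
  M <- sum(S4Vectors::mcols(st)$M[off])
  Tot <- sum(S4Vectors::mcols(st)$M[off] + S4Vectors::mcols(st)$U[off])
  mlRaw <- M / Tot
  q <- 0.3 + 0.7 * 0.01
  se <- sqrt(q * (1 - q) / Tot)
  expect_lt(abs(mlRaw - q), 4 * se)
  expect_lt(abs(correctML(mlRaw, nonconversionRate(m)) - 0.3), 0.002)
})
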