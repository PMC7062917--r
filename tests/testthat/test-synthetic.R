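test_that("genome simulation is deterministic and respects its knobs", {
  cfg <- SimulationConfig(seed = 11L, chromLengths = 1000L,
                          lambdaLength = 500L)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(genomeSeq(g1)), as.character(genomeSeq(g2)))
  expect_equal(chromNames(g1), c("Chr1", "lambda"))
  expect_equal(unname(chromLengths(g1)), c(1000L, 500L))
  expect_equal(controlChrom(g1), "lambda")

  gcfg <- SimulationConfig(seed = 11L, chromLengths = 2000L,
                           gcFraction = 0, lambdaLength = 100L)
  g3 <- simulateGenome(gcfg)
  expect_false(grepl("[CG]", as.character(genomeSeq(g3)[["Chr1"]])))
})

test_that("true methylome respects context means and the control chromosome", {
  cfg <- SimulationConfig(seed = 5L, chromLengths = 10000L,
                          lambdaLength = 2000L)
  g <- simulateGenome(cfg)
  tr <- simulateTrueMethylome(g, cfg)
  sites <- truthSites(tr)
  p <- S4Vectors::mcols(sites)$p
  ctx <- as.character(S4Vectors::mcols(sites)$context)
  onLambda <- as.character(GenomicRanges::seqnames(sites)) == "lambda"
  expect_true(all(p[onLambda] == 0))
  ## default context means are ordered CG > CHH in the realised truth
  expect_gt(mean(p[ctx == "CG" & !onLambda]),
            mean(p[ctx == "CHH" & !onLambda]))

  zcfg <- SimulationConfig(seed = 5L, chromLengths = 10000L,
                           lambdaLength = 2000L,
                           baseLevels = c(CG = 0, CHG = 0, CHH = 0))
  expect_true(all(S4Vectors::mcols(truthSites(
    simulateTrueMethylome(g, zcfg)))$p == 0))
})

test_that("planted regions shift only their context, clamped to [0,1]", {
  cfg <- SimulationConfig(seed = 6L, chromLengths = 30000L,
                          lambdaLength = 2000L,
                          baseLevels = c(CG = 0.9, CHG = 0.1, CHH = 0.04),
                          levelDispersion = Inf)
  g <- simulateGenome(cfg)
  tr <- simulateTrueMethylome(g, cfg)

  ## delta = 0 leaves the truth unchanged
  same <- plantDMRs(tr, cfg, regions = data.frame(
    chrom = "Chr1", start = 1000L, end = 3000L, context = "CG", delta = 0))
  expect_equal(S4Vectors::mcols(truthSites(same))$p,
               S4Vectors::mcols(truthSites(tr))$p)

  ## +0.4 on p = 0.9 clamps at 1; CHH sites inside untouched
  up <- plantDMRs(tr, cfg, regions = data.frame(
    chrom = "Chr1", start = 1000L, end = 3000L, context = "CG",
    delta = 0.4))
  s <- truthSites(up)
  inreg <- as.character(GenomicRanges::seqnames(s)) == "Chr1" &
    GenomicRanges::start(s) >= 1000 & GenomicRanges::start(s) <= 3000
  ctx <- as.character(S4Vectors::mcols(s)$context)
  expect_true(all(S4Vectors::mcols(s)$p[inreg & ctx == "CG"] == 1))
  expect_equal(S4Vectors::mcols(s)$p[inreg & ctx == "CHH"],
               S4Vectors::mcols(truthSites(tr))$p[inreg & ctx == "CHH"])

  expect_error(plantDMRs(tr, cfg, regions = data.frame(
    chrom = c("Chr1", "Chr1"), start = c(1000L, 2000L),
    end = c(2500L, 3500L), context = "CG", delta = 0.4)), "overlap")
  expect_error(plantDMRs(tr, cfg, regions = data.frame(
    chrom = "lambda", start = 10L, end = 50L, context = "CG",
    delta = 0.4)), "control")
})

test_that("read-count simulation follows the non-conversion error model", {
  cfg <- SimulationConfig(seed = 8L, chromLengths = 20000L,
                          lambdaLength = 2000L, levelDispersion = Inf,
                          nonconversionRate = 0)
  g <- simulateGenome(cfg)

  ## p = 0 and r = 0: no methylated read anywhere
  z <- SimulationConfig(seed = 8L, chromLengths = 20000L,
                        lambdaLength = 2000L,
                        baseLevels = c(CG = 0, CHG = 0, CHH = 0),
                        nonconversionRate = 0)
  m0 <- simulateCounts(simulateTrueMethylome(g, z), z, "a")
  expect_true(all(S4Vectors::mcols(methSites(m0))$M == 0L))

  ## p = 1: every read methylated
  o <- SimulationConfig(seed = 8L, chromLengths = 20000L,
                        lambdaLength = 2000L, levelDispersion = Inf,
                        baseLevels = c(CG = 1, CHG = 1, CHH = 1),
                        nonconversionRate = 0)
  truth1 <- simulateTrueMethylome(g, o)
  m1 <- simulateCounts(truth1, o, "b")
  s <- methSites(m1)
  off <- as.character(GenomicRanges::seqnames(s)) != "lambda"
  expect_true(all(S4Vectors::mcols(s)$U[off] == 0L))

  ## pooled lambda rate estimates r: 0.006 within 0.002 at 50x over >= 5000
  ## control sites (law of large numbers)
  rcfg <- SimulationConfig(seed = 8L, chromLengths = 1000L,
                           lambdaLength = 11000L, coverageMean = 50,
                           nonconversionRate = 0.006)
  gl <- simulateGenome(rcfg)
  ml <- simulateCounts(simulateTrueMethylome(gl, rcfg), rcfg, "c")
  sl <- methSites(ml)
  on <- as.character(GenomicRanges::seqnames(sl)) == "lambda"
  expect_gte(sum(on), 5000)
  pooled <- sum(S4Vectors::mcols(sl)$M[on]) /
    sum(S4Vectors::mcols(sl)$M[on] + S4Vectors::mcols(sl)$U[on])
  expect_lt(abs(pooled - 0.006), 0.002)

  ## deterministic given (seed, sample id); different ids differ
  ma <- simulateCounts(truth1, o, "x")
  mb <- simulateCounts(truth1, o, "x")
  expect_identical(S4Vectors::mcols(methSites(ma))$M,
                   S4Vectors::mcols(methSites(mb))$M)
})

test_that("dose-response simulation matches the median-effect curve", {
  expect_equal(simulateDoseResponse(2, 10, 10)$fa, 0.5)
  expect_equal(simulateDoseResponse(1, 10, 30)$fa, 0.75)
  ## steep slope below Dm pushes fa towards 0
  expect_lt(simulateDoseResponse(50, 10, 8)$fa, 1e-4)
  expect_error(simulateDoseResponse(1, 10, c(5, -1)), "positive")
  ## reproducible under a seed
  a <- simulateDoseResponse(1.8, 10, c(2, 4, 8), cv = 0.1, seed = 3L)
  b <- simulateDoseResponse(1.8, 10, c(2, 4, 8), cv = 0.1, seed = 3L)
  expect_equal(a, b)
})

test_that("context ordering of realised mean ML holds at default settings", {
  cfg <- SimulationConfig(seed = 12L, chromLengths = 100000L,
                          lambdaLength = 5000L)
  g <- simulateGenome(cfg)
  m <- simulateCounts(simulateTrueMethylome(g, cfg), cfg, "ord")
  st <- methSites(m)
  off <- as.character(GenomicRanges::seqnames(st)) != "lambda"
  mlOf <- function(cc) {
    sel <- off & as.character(S4Vectors::mcols(st)$context) == cc
    sum(S4Vectors::mcols(st)$M[sel]) /
      sum(S4Vectors::mcols(st)$M[sel] + S4Vectors::mcols(st)$U[sel])
  }
  expect_gt(mlOf("CG"), mlOf("CHG"))
  expect_gt(mlOf("CHG"), mlOf("CHH"))
})
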