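test_that("two-sided Fisher p matches known values and fisher.test", {
  expect_equal(fisherExact2x2(3, 0, 0, 3), 0.1)          # 2/20
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)
  expect_equal(fisherExact2x2(0, 0, 0, 0), 1)
  withr::local_seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("window scan pools shared covered cytosines per window", {
  ## 1100-bp chromosome: windows [1,1000] and [101,1100]
  t1 <- makeMethylome("Chr1", c(50L, 500L, 1050L), "+",
                      c(8L, 6L, 9L), c(2L, 4L, 1L), rep("CG", 3),
                      seqlens = c(Chr1 = 1100L), sampleId = "t")
  c1 <- makeMethylome("Chr1", c(50L, 500L, 1050L), "+",
                      c(1L, 1L, 1L), c(9L, 9L, 9L), rep("CG", 3),
                      seqlens = c(Chr1 = 1100L), sampleId = "c")
  w <- windowScan(t1, c1, DmrParams(), "CG")
  expect_equal(w$start, c(1L, 101L))
  expect_equal(w$end, c(1000L, 1100L))
  expect_equal(w$n_cytosines, c(2L, 2L))
  expect_equal(w$M_t, c(14, 15))

  ## a site under coverage 5 in either sample is excluded from both
  c2 <- makeMethylome("Chr1", c(50L, 500L, 1050L), "+",
                      c(1L, 1L, 1L), c(9L, 2L, 9L), rep("CG", 3),
                      seqlens = c(Chr1 = 1100L), sampleId = "c")
  w2 <- windowScan(t1, c2, DmrParams(), "CG")
  expect_equal(w2$n_cytosines, c(1L, 1L))

  ## no shared covered sites anywhere -> empty
  t3 <- makeMethylome("Chr1", 10L, "+", 8L, 2L, "CG",
                      seqlens = c(Chr1 = 1100L))
  c3 <- makeMethylome("Chr1", 20L, "+", 8L, 2L, "CG",
                      seqlens = c(Chr1 = 1100L))
  expect_equal(nrow(windowScan(t3, c3, DmrParams(), "CG")), 0L)
})

test_that("window statistics and the filter cascade behave as specified", {
  t1 <- makeMethylome("Chr1", seq(10L, 300L, by = 20L), "+",
                      rep(8L, 15), rep(2L, 15), rep("CG", 15),
                      seqlens = c(Chr1 = 1000L), sampleId = "t")
  c1 <- makeMethylome("Chr1", seq(10L, 300L, by = 20L), "+",
                      rep(2L, 15), rep(8L, 15), rep("CG", 15),
                      seqlens = c(Chr1 = 1000L), sampleId = "c")
  w <- testWindows(windowScan(t1, c1, DmrParams(), "CG"), DmrParams())
  expect_equal(w$ml_treat, rep(0.8, nrow(w)))
  expect_equal(w$diff, rep(0.6, nrow(w)))
  expect_equal(w$fold_change, rep(4, nrow(w)))
  ## identical samples: diff 0, cannot pass the pre-filter
  w0 <- testWindows(windowScan(t1, t1, DmrParams(), "CG"), DmrParams())
  expect_true(all(w0$diff == 0))
  expect_equal(nrow(callDMRs(t1, t1, DmrParams(), "CG")), 0L)
})

test_that("DMRs merge same-sign overlapping windows and recompute stats", {
  ## strong signal confined to [1001, 2100]: several overlapping windows
  ## pass and must merge into one hyper DMR spanning the signal
  pos <- seq(1001L, 2100L, by = 50L)
  n <- length(pos)
  t1 <- makeMethylome("Chr1", pos, "+", rep(15L, n), rep(5L, n),
                      rep("CG", n), seqlens = c(Chr1 = 4000L),
                      sampleId = "t")
  c1 <- makeMethylome("Chr1", pos, "+", rep(4L, n), rep(16L, n),
                      rep("CG", n), seqlens = c(Chr1 = 4000L),
                      sampleId = "c")
  dmrs <- callDMRs(t1, c1, DmrParams(), "CG")
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$status, "hyper")
  expect_lte(dmrs$start, 1001L)
  expect_gte(dmrs$end, 2100L)
  ## merged stats recomputed from all shared sites in the span
  expect_equal(dmrs$ml_treat, 0.75)
  expect_equal(dmrs$ml_ctrl, 0.2)
  expect_equal(dmrs$n_cytosines, n)
  expect_equal(dmrs$p, fisherExact2x2(15 * n, 5 * n, 4 * n, 16 * n))

  ## hypo direction is symmetric
  dmrs2 <- callDMRs(c1, t1, DmrParams(), "CG")
  expect_equal(dmrs2$status, "hypo")
  expect_equal(dmrs2$diff, -dmrs$diff)
})

test_that("planted regions are recovered on a seeded synthetic genome", {
  cfg <- SimulationConfig(seed = 31L, chromLengths = 200000L,
                          lambdaLength = 20000L, dmrCount = 1L)
  g <- simulateGenome(cfg)
  truth <- simulateTrueMethylome(g, cfg)
  planted <- plantDMRs(truth, cfg, regions = data.frame(
    chrom = "Chr1", start = 90001L, end = 92000L, context = "CG",
    delta = 0.4))
  treat <- simulateCounts(planted, cfg, "t")
  ctrl <- simulateCounts(truth, cfg, "c")
  dmrs <- callDMRs(treat, ctrl, DmrParams(), "CG")
  ev <- evaluateDmrRecovery(dmrs, plantedRegions(planted))
  expect_gte(ev$sensitivity, 1)
  expect_equal(ev$fdp, 0)
  expect_true(all(dmrs$status == "hyper"))
})

test_that("DMR annotation records overlapped element types and genes", {
  g <- GenomeSequence(c(Chr1 = strrep("A", 20000)))
  gm <- makeModels("Chr1", 5001L, 8000L, "+", c(5001L, 6001L),
                   c(5800L, 8000L))
  el <- deriveElements(gm, g)
  base <- data.table::data.table(
    context = "CG", status = "hyper", ml_treat = 0.6, ml_ctrl = 0.2,
    diff = 0.4, fold_change = 3, n_cytosines = 12L, p = 1e-4, q = 1e-3)
  dmrs <- data.table::data.table(
    chrom = "Chr1", start = c(3500L, 5700L, 15000L),
    end = c(4200L, 6100L, 15500L), base)
  ann <- annotateDMRs(dmrs, el)
  expect_equal(ann$element_hits[1], "promoter")
  expect_equal(ann$gene_ids[1], "g1")
  expect_equal(ann$element_hits[2], "exon/intron")  # spans the boundary
  expect_equal(ann$element_hits[3], "")             # intergenic
  expect_equal(ann$gene_ids[3], "")
})

test_that("DMG ratios classify hyper, hypo and unchanged", {
  pos <- seq(5001L, 5800L, by = 40L)
  n <- length(pos)
  mk <- function(M, U, id) makeMethylome("Chr1", pos, "+", rep(M, n),
                                         rep(U, n), rep("CG", n),
                                         seqlens = c(Chr1 = 20000L),
                                         sampleId = id)
  g <- GenomeSequence(c(Chr1 = strrep("A", 20000)))
  gm <- makeModels("Chr1", 5001L, 8000L, "+", 5001L, 8000L)
  el <- deriveElements(gm, g)
  dmr <- data.table::data.table(
    chrom = "Chr1", start = 5001L, end = 5800L, context = "CG",
    status = "hyper", ml_treat = 0.6, ml_ctrl = 0.2, diff = 0.4,
    fold_change = 3, n_cytosines = n, p = 1e-6, q = 1e-5)
  ann <- annotateDMRs(dmr, el)

  hyper <- collectDMGs(ann, mk(6L, 4L, "t"), mk(3L, 7L, "c"))
  expect_equal(hyper$methylation_ratio, 2)
  expect_equal(hyper$ratio_status, "hyper")

  hypo <- collectDMGs(ann, mk(3L, 7L, "t"), mk(6L, 4L, "c"))
  expect_equal(hypo$methylation_ratio, 0.5)
  expect_equal(hypo$ratio_status, "hypo")

  flat <- collectDMGs(ann, mk(5L, 5L, "t"), mk(5L, 5L, "c"))
  expect_equal(flat$methylation_ratio, 1)
  expect_equal(flat$ratio_status, "unchanged")

  ## the 1.5-fold rule is a closed boundary for hyper
  edge <- collectDMGs(ann, mk(15L, 5L, "t"), mk(10L, 10L, "c"))
  expect_equal(edge$methylation_ratio, 1.5)
  expect_equal(edge$ratio_status, "hyper")

  ## intergenic DMRs never produce a DMG
  interg <- data.table::copy(ann)[, `:=`(gene_ids = "", element_hits = "")]
  expect_equal(nrow(collectDMGs(interg, mk(6L, 4L, "t"), mk(3L, 7L, "c"))),
               0L)
})

test_that("venn overlap counts every exclusive region", {
  v <- vennOverlap(list(A = c("g1", "g2"), B = c("g1", "g2"),
                        C = c("g1", "g2")))
  expect_equal(v[v$region == "A&B&C", ]$count, 2L)
  expect_equal(sum(v$count), 2L)

  v2 <- vennOverlap(list(A = c("a", "b"), B = c("c"), C = c("d")))
  expect_equal(v2[v2$region == "A", ]$count, 2L)
  expect_true(all(v2[grepl("&", v2$region), ]$count == 0L))

  v3 <- vennOverlap(list(A = c("g1", "g2"), B = c("g2", "g3"),
                         C = character()))
  expect_equal(v3[v3$region == "A&B", ]$count, 1L)
  expect_equal(v3[v3$region == "A", ]$count, 1L)
  expect_equal(v3[v3$region == "B", ]$count, 1L)

  expect_error(vennOverlap(list(A = "g")), "2 or 3")
  expect_error(vennOverlap(list(A = "g", B = "h", C = "i", D = "j")),
               "2 or 3")
})

test_that("Pearson-distance clustering pairs correlated genes first", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1), g4 = c(9, 7, 5, 3))
  cl <- clusterDMGs(m)
  h <- cl$hclust
  ## first two merges are the perfectly correlated pairs at distance 0
  expect_equal(sort(h$height)[1:2], c(0, 0))
  pair1 <- sort(h$labels[-h$merge[1, ]])
  pair2 <- sort(h$labels[-h$merge[2, ]])
  expect_equal(sort(c(paste(pair1, collapse = ""),
                      paste(pair2, collapse = ""))), c("g1g2", "g3g4"))
  ## g1 vs g3 are anti-correlated: distance 2 at the top merge
  expect_equal(max(h$height), 2)
  expect_match(cl$newick, "^\\(")

  expect_error(clusterDMGs(rbind(g1 = c(1, NA), g2 = c(1, 2))), "missing")
  expect_warning(clusterDMGs(rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3),
                                   g3 = c(3, 2, 1))), "constant")
})

test_that("raising thresholds never adds DMRs or DMGs", {
  cfg <- SimulationConfig(seed = 32L, chromLengths = 150000L,
                          lambdaLength = 10000L, dmrCount = 5L,
                          dmrDelta = 0.25)
  g <- simulateGenome(cfg)
  truth <- simulateTrueMethylome(g, cfg)
  planted <- plantDMRs(truth, cfg)
  treat <- simulateCounts(planted, cfg, "t")
  ctrl <- simulateCounts(truth, cfg, "c")
  gm <- simulateGeneModels(g)
  el <- deriveElements(gm, g)
  nOf <- function(params) {
    dmrs <- annotateDMRs(callDMRs(treat, ctrl, params, "CG"), el)
    c(nrow(dmrs), nrow(collectDMGs(dmrs, treat, ctrl, params)))
  }
  base <- nOf(DmrParams())
  expect_true(all(nOf(DmrParams(minDiff = 0.2)) <= base))
  expect_true(all(nOf(DmrParams(minFoldChange = 4)) <= base))
  expect_true(all(nOf(DmrParams(minCytosines = 20L)) <= base))
})

test_that("null window p-values are conservative for discrete tables", {
  cfg <- SimulationConfig(seed = 33L, chromLengths = 300000L,
                          lambdaLength = 10000L)
  g <- simulateGenome(cfg)
  truth <- simulateTrueMethylome(g, cfg)
  treat <- simulateCounts(truth, cfg, "null_a")
  ctrl <- simulateCounts(truth, cfg, "null_b")
  w <- testWindows(windowScan(treat, ctrl, DmrParams(), "CG"), DmrParams())
  n <- nrow(w)
  expect_gt(n, 1000)
  frac <- mean(w$p < 0.05)
  ## windows overlap, so these are not n independent tests; the binomial
  ## SE bound is still a sound upper envelope because Fisher is
  ## conservative on discrete tables
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
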