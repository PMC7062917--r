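## Seeded synthetic-data generator.
##
## Produces every input the pipeline consumes: a toy multi-chromosome
## genome plus an unmethylated lambda control chromosome, gene models,
## context-dependent true methylomes with planted differential regions,
## binomially sampled read counts with a non-conversion error process, and
## median-effect dose-response tables. The whole dataset is a pure function
## of a SimulationConfig; per-sample random streams are derived by hashing
## (seed, sample_id) so samples are independent yet reproducible.

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Polynomial string hash folded with the master seed, kept below 2^31 so
#' it is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param id Character label (sample name, stage name, ...).
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (x in utf8ToInt(as.character(id)))
    h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

#' SimulationConfig: all knobs of the synthetic dataset
#'
#' Defaults emulate a plant-like methylome: CG methylation highest, CHG
#' intermediate, CHH low (mean true levels 0.24 / 0.10 / 0.04), site-level
#' variability from a Beta distribution, ~30x Poisson coverage, and a
#' non-conversion rate of 0.004 (conversion efficiency 99.6%). Planted
#' differential regions default to twenty 2-kb CG regions shifted by +0.4.
#'
#' @slot seed Master seed.
#' @slot chromLengths Integer vector of test-chromosome lengths (bp).
#' @slot gcFraction GC content of simulated chromosomes.
#' @slot baseLevels Named numeric: mean true methylation per context.
#' @slot levelDispersion Beta concentration; `Inf` gives every site exactly
#'   the context mean.
#' @slot coverageMean Expected reads per site (Poisson).
#' @slot nonconversionRate Fraction of unmethylated molecules reading as
#'   methylated.
#' @slot dmrCount,dmrLength,dmrDelta,dmrContext Planted-region spec.
#' @slot lambdaLength,lambdaName Length and name of the unmethylated
#'   spike-in control chromosome (default: the 48,502-bp lambda genome).
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", chromLengths = "integer",
            gcFraction = "numeric", baseLevels = "numeric",
            levelDispersion = "numeric", coverageMean = "numeric",
            nonconversionRate = "numeric", dmrCount = "integer",
            dmrLength = "integer", dmrDelta = "numeric",
            dmrContext = "character", lambdaLength = "integer",
            lambdaName = "character"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@chromLengths < 1L)) msg <- c(msg, "zero-length chromosome")
  if (object@coverageMean <= 0) msg <- c(msg, "coverageMean must be > 0")
  r <- object@nonconversionRate
  if (r < 0 || r >= 1) msg <- c(msg, "nonconversionRate must be in [0,1)")
  if (!all(VALID_CONTEXTS %in% names(object@baseLevels)))
    msg <- c(msg, "baseLevels must name CG, CHG and CHH")
  if (any(object@baseLevels < 0 | object@baseLevels > 1))
    msg <- c(msg, "baseLevels must be in [0,1]")
  if (!object@dmrContext %in% VALID_CONTEXTS)
    msg <- c(msg, "dmrContext must be CG, CHG or CHH")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#' @param seed,chromLengths,gcFraction,baseLevels,levelDispersion,coverageMean,nonconversionRate,dmrCount,dmrLength,dmrDelta,dmrContext,lambdaLength,lambdaName
#'   See [SimulationConfig-class].
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(seed = 1, chromLengths = c(2e5, 1e5))
#' @export
SimulationConfig <- function(seed = 1L,
                             chromLengths = c(300000L, 200000L),
                             gcFraction = 0.36,
                             baseLevels = c(CG = 0.24, CHG = 0.10,
                                            CHH = 0.04),
                             levelDispersion = 20,
                             coverageMean = 30,
                             nonconversionRate = 0.004,
                             dmrCount = 20L, dmrLength = 2000L,
                             dmrDelta = 0.4, dmrContext = "CG",
                             lambdaLength = 48502L,
                             lambdaName = "lambda") {
  new("SimulationConfig", seed = as.integer(seed),
      chromLengths = as.integer(chromLengths),
      gcFraction = as.numeric(gcFraction),
      baseLevels = baseLevels[VALID_CONTEXTS],
      levelDispersion = as.numeric(levelDispersion),
      coverageMean = as.numeric(coverageMean),
      nonconversionRate = as.numeric(nonconversionRate),
      dmrCount = as.integer(dmrCount), dmrLength = as.integer(dmrLength),
      dmrDelta = as.numeric(dmrDelta), dmrContext = as.character(dmrContext),
      lambdaLength = as.integer(lambdaLength),
      lambdaName = as.character(lambdaName))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: seed %d; %d chromosome(s) (%s bp) + %s (%d bp)\n",
    "  GC %.2f; base levels CG/CHG/CHH = %.2f/%.2f/%.2f; coverage %gx; r = %g\n",
    "  planted: %d x %d bp %s regions, delta %+.2f\n"),
    object@seed, length(object@chromLengths),
    paste(object@chromLengths, collapse = ","), object@lambdaName,
    object@lambdaLength, object@gcFraction, object@baseLevels[["CG"]],
    object@baseLevels[["CHG"]], object@baseLevels[["CHH"]],
    object@coverageMean, object@nonconversionRate, object@dmrCount,
    object@dmrLength, object@dmrContext, object@dmrDelta))
})

#' TrueMethylome: per-site ground-truth methylation probabilities
#'
#' The unobservable truth the read-count simulation draws from: every
#' classifiable cytosine of the genome carries a true methylation
#' probability (fixed to 0 on the control chromosome), plus the list of
#' planted differential regions when the object is a treatment arm.
#'
#' @slot sites Width-1 stranded `GRanges` with mcols `context`, `tri`, `p`.
#' @slot planted `data.frame` of planted regions (chrom, start, end,
#'   context, delta); zero rows for a control-arm truth.
#' @export
setClass("TrueMethylome",
  slots = c(sites = "GRanges", planted = "data.frame"))

setMethod("show", "TrueMethylome", function(object) {
  cat("TrueMethylome over", length(object@sites), "cytosines;",
      nrow(object@planted), "planted region(s)\n")
})

#' @describeIn TrueMethylome-class site-level `GRanges` with true `p`
#' @param x A `TrueMethylome`.
#' @export
truthSites <- function(x) x@sites

#' @describeIn TrueMethylome-class planted differential regions
#' @export
plantedRegions <- function(x) x@planted

#' Simulate a toy genome with a lambda control chromosome
#'
#' Chromosomes `Chr1..ChrN` of the configured lengths with i.i.d. bases at
#' the configured GC fraction, plus a final unmethylated control chromosome
#' (GC 0.5). Deterministic given the config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A [GenomeSequence-class] with `controlChrom` set.
#' @export
simulateGenome <- function(config) {
  validObject(config)
  old <- .Random.seed_exists()
  set.seed(deriveSeed(config@seed, "genome"))
  gc <- config@gcFraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(config@chromLengths, function(L)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""))
  names(seqs) <- paste0("Chr", seq_along(seqs))
  lam <- paste(sample(c("A", "C", "G", "T"), config@lambdaLength,
                      replace = TRUE), collapse = "")
  seqs[[config@lambdaName]] <- lam
  .restore_seed(old)
  GenomeSequence(unlist(seqs), controlChrom = config@lambdaName)
}

## internal: save/restore the global RNG state so simulators are pure
## functions of their seeds without clobbering the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Simulate the true methylome of a genome
#'
#' Each cytosine's true methylation probability is drawn from a Beta
#' distribution with the context-specific mean and concentration
#' `levelDispersion` (a `levelDispersion` of `Inf`, or a mean of exactly 0
#' or 1, gives the mean itself). Every site on the control chromosome is
#' fixed at 0.
#'
#' @param genome A [GenomeSequence-class] with a control chromosome.
#' @param config A [SimulationConfig-class].
#' @return A control-arm [TrueMethylome-class].
#' @export
simulateTrueMethylome <- function(genome, config) {
  stopifnot(!is.na(controlChrom(genome)))
  sites <- cytosineSites(genome)
  ctx <- as.character(mcols(sites)$context)
  mu <- unname(config@baseLevels[ctx])
  old <- .Random.seed_exists()
  set.seed(deriveSeed(config@seed, "truth"))
  conc <- config@levelDispersion
  if (is.finite(conc)) {
    p <- numeric(length(mu))
    draw <- mu > 0 & mu < 1
    p[draw] <- stats::rbeta(sum(draw), mu[draw] * conc,
                            (1 - mu[draw]) * conc)
    p[!draw] <- mu[!draw]
  } else {
    p <- mu
  }
  .restore_seed(old)
  p[as.character(seqnames(sites)) == controlChrom(genome)] <- 0
  mcols(sites)$p <- p
  new("TrueMethylome", sites = sites,
      planted = data.frame(chrom = character(), start = integer(),
                           end = integer(), context = character(),
                           delta = numeric()))
}

## internal: default placement of planted regions — evenly spaced across
## the non-control chromosomes, proportional to chromosome length
.defaultRegions <- function(truth, config, controlName) {
  chroms <- setdiff(unique(as.character(seqnames(truth@sites))), controlName)
  lens <- vapply(chroms, function(ch)
    max(end(truth@sites[seqnames(truth@sites) == ch])), numeric(1))
  total <- sum(lens)
  nper <- diff(round(config@dmrCount * c(0, cumsum(lens)) / total))
  regs <- list()
  for (i in seq_along(chroms)) {
    k <- nper[i]
    if (k == 0L) next
    gap <- floor(lens[i] / k)
    if (gap < config@dmrLength + 1000L)
      stop("chromosome ", chroms[i], " too short for ", k,
           " planted regions of ", config@dmrLength, " bp")
    starts <- floor(gap * (seq_len(k) - 1L) + gap / 4)  + 1L
    regs[[i]] <- data.table(chrom = chroms[i], start = as.integer(starts),
                            end = as.integer(starts + config@dmrLength - 1L),
                            context = config@dmrContext,
                            delta = config@dmrDelta)
  }
  as.data.frame(rbindlist(regs))
}

#' Plant differential regions into a true methylome
#'
#' Returns a treatment-arm copy whose true probability inside each region
#' is shifted by the region's `delta` (clamped to `[0,1]`) for sites of the
#' region's context only; the regions are recorded as ground truth on the
#' returned object. With `regions = NULL` the config's planted-region spec
#' is realised at evenly spaced positions on the non-control chromosomes.
#'
#' @param truth A control-arm [TrueMethylome-class].
#' @param config A [SimulationConfig-class].
#' @param regions Optional `data.frame(chrom, start, end, context, delta)`;
#'   regions must be non-overlapping and lie on non-control chromosomes.
#' @param controlName Control chromosome name (default from config).
#' @return A treatment-arm [TrueMethylome-class].
#' @export
plantDMRs <- function(truth, config, regions = NULL,
                      controlName = config@lambdaName) {
  if (is.null(regions)) regions <- .defaultRegions(truth, config, controlName)
  regions <- as.data.frame(regions)
  if (nrow(regions) > 0L) {
    gr <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
      stop("planted regions overlap")
    if (controlName %in% regions$chrom)
      stop("cannot plant regions on the control chromosome")
    sl <- seqlengths(truth@sites)
    if (any(regions$end > sl[regions$chrom], na.rm = TRUE))
      stop("planted region extends past chromosome end")
  }
  sites <- truth@sites
  p <- mcols(sites)$p
  for (i in seq_len(nrow(regions))) {
    inreg <- as.character(seqnames(sites)) == regions$chrom[i] &
      start(sites) >= regions$start[i] & start(sites) <= regions$end[i] &
      as.character(mcols(sites)$context) == regions$context[i]
    p[inreg] <- pmin(1, pmax(0, p[inreg] + regions$delta[i]))
  }
  mcols(sites)$p <- p
  new("TrueMethylome", sites = sites, planted = regions)
}

#' Simulate per-cytosine read counts from a true methylome
#'
#' Per site: coverage ~ Poisson(`coverageMean`); methylated count ~
#' Binomial(coverage, q) with `q = p + (1 - p) r` — unmethylated molecules
#' escape conversion with probability `r` and read as methylated, while
#' conversion of methylated cytosines is assumed perfect. Deterministic
#' given the config seed and `sampleId`.
#'
#' @param truth A [TrueMethylome-class].
#' @param config A [SimulationConfig-class].
#' @param sampleId Sample label; also salts the random stream.
#' @return A [SampleMethylome-class] including zero-coverage sites.
#' @export
simulateCounts <- function(truth, config, sampleId) {
  sites <- truth@sites
  p <- mcols(sites)$p
  r <- config@nonconversionRate
  q <- p + (1 - p) * r
  old <- .Random.seed_exists()
  set.seed(deriveSeed(config@seed, paste0("counts:", sampleId)))
  cov <- stats::rpois(length(p), config@coverageMean)
  M <- stats::rbinom(length(p), cov, q)
  .restore_seed(old)
  out <- granges(sites)
  mcols(out)$M <- as.integer(M)
  mcols(out)$U <- as.integer(cov - M)
  mcols(out)$context <- mcols(sites)$context
  mcols(out)$tri <- mcols(sites)$tri
  SampleMethylome(out, sampleId)
}

#' Simulate a median-effect dose-response table
#'
#' `Fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)` multiplied by lognormal noise with
#' coefficient of variation `cv`, clamped into (0, 1).
#'
#' @param m Sigmoidicity slope (> 0).
#' @param Dm Median-effect dose in uM (> 0).
#' @param doses Positive dose vector (uM).
#' @param cv Noise coefficient of variation (0 = noise free).
#' @param seed Optional integer seed.
#' @return `data.table(dose, fa)`.
#' @examples
#' simulateDoseResponse(1, 10, c(2.5, 5, 10, 20, 40))
#' @export
simulateDoseResponse <- function(m, Dm, doses, cv = 0, seed = NULL) {
  stopifnot(m > 0, Dm > 0)
  if (any(doses <= 0)) stop("doses must be positive")
  fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  if (cv > 0) {
    old <- .Random.seed_exists()
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + cv^2))
    fa <- fa * stats::rlnorm(length(fa), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    if (!is.null(seed)) .restore_seed(old)
  }
  data.table(dose = as.numeric(doses),
             fa = pmin(1 - 1e-9, pmax(1e-9, fa)))
}

#' Simulate a combination observation with a chosen true combination index
#'
#' Given the true single-agent median-effect parameters, finds the affected
#' fraction at which the fixed dose pair `(d1, d2)` yields combination
#' index `ciTrue`, i.e. solves `d1/Dx1(fa) + d2/Dx2(fa) = ciTrue` for `fa`.
#' Used by the generator to plant synergy (`ciTrue < 1`), additivity or
#' antagonism into combination dose tables.
#'
#' @param fit1,fit2 [MedianEffectFit-class] objects (the true parameters).
#' @param d1,d2 Combination doses (uM).
#' @param ciTrue Target combination index (> 0).
#' @param cv Lognormal noise coefficient applied to the resulting `fa`.
#' @param seed Optional seed for the noise.
#' @return The simulated affected fraction (scalar).
#' @export
simulateComboResponse <- function(fit1, fit2, d1, d2, ciTrue, cv = 0,
                                  seed = NULL) {
  stopifnot(ciTrue > 0, d1 > 0, d2 > 0)
  f <- function(fa) d1 / doseForFa(fit1, fa) + d2 / doseForFa(fit2, fa) -
    ciTrue
  fa <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  if (cv > 0) {
    old <- .Random.seed_exists()
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + cv^2))
    fa <- fa * stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (!is.null(seed)) .restore_seed(old)
  }
  min(1 - 1e-9, max(1e-9, fa))
}

#' Simulate simple gene models along a genome
#'
#' Deterministic layout: one gene every `spacing` bp (leaving room for the
#' 2-kb promoter), alternating strands, three exons separated by two
#' introns, and 150-bp UTRs at the transcript ends. Used by the bundle
#' generator; real annotations are read with [readGeneModels()].
#'
#' @param genome A [GenomeSequence-class].
#' @param spacing Distance between gene starts (>= gene span + 2 kb).
#' @param span Genomic span of each gene (bp).
#' @return A [GeneModelSet-class].
#' @export
simulateGeneModels <- function(genome, spacing = 6000L, span = 3000L) {
  stopifnot(spacing >= span + 2000L)
  chroms <- setdiff(chromNames(genome), controlChrom(genome))
  lens <- chromLengths(genome)[chroms]
  genesL <- list(); exonsL <- list(); u5L <- list(); u3L <- list()
  for (ch in chroms) {
    n <- max(0L, floor((lens[[ch]] - 2000L - span) / spacing))
    for (i in seq_len(n)) {
      s <- 2001L + (i - 1L) * spacing
      e <- s + span - 1L
      strand <- if (i %% 2L == 1L) "+" else "-"
      gid <- sprintf("G%s_%04d", sub("^Chr", "", ch), i)
      genesL[[gid]] <- GRanges(ch, IRanges(s, e), strand = strand)
      ## exon layout relative to the span (thirds with two introns)
      exonsL[[gid]] <- GRanges(ch, IRanges(
        start = s + c(0L, 1000L, 2400L),
        end = s + c(599L, 1799L, span - 1L)))
      if (strand == "+") {
        u5L[[gid]] <- GRanges(ch, IRanges(s, s + 149L))
        u3L[[gid]] <- GRanges(ch, IRanges(e - 149L, e))
      } else {
        u5L[[gid]] <- GRanges(ch, IRanges(e - 149L, e))
        u3L[[gid]] <- GRanges(ch, IRanges(s, s + 149L))
      }
    }
  }
  if (length(genesL) == 0L) stop("genome too short to place any gene")
  gn <- suppressWarnings(unlist(GenomicRanges::GRangesList(genesL)))
  gids <- names(gn)
  names(gn) <- NULL
  out <- granges(gn)
  mcols(out)$gene_id <- gids
  mcols(out)$tss <- ifelse(as.character(strand(gn)) == "-", end(gn),
                           start(gn))
  new("GeneModelSet", genes = out,
      exons = GenomicRanges::GRangesList(stats::setNames(exonsL, gids)),
      utr5 = GenomicRanges::GRangesList(stats::setNames(u5L, gids)),
      utr3 = GenomicRanges::GRangesList(stats::setNames(u3L, gids)))
}

#' Simulate a term-to-gene map with one planted enriched term
#'
#' Random terms of 8-40 genes over the given universe, plus a term
#' `TERM_PLANTED` holding the supplied target genes (the genes carrying
#' planted differential regions) so over-representation is recoverable.
#'
#' @param geneIds Background gene universe.
#' @param targetGenes Genes to concentrate in the planted term.
#' @param nTerms Number of random terms.
#' @param seed Integer seed.
#' @return List with `map` (`data.table(term_id, gene_id)`) and
#'   `descriptions` (`data.table(term_id, description)`).
#' @export
simulateTermMap <- function(geneIds, targetGenes = character(),
                            nTerms = 15L, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(deriveSeed(seed, "terms"))
  rows <- list()
  lo <- min(8L, length(geneIds))
  hi <- min(40L, length(geneIds))
  for (i in seq_len(nTerms)) {
    k <- sample(seq.int(lo, hi), 1L)
    rows[[i]] <- data.table(term_id = sprintf("TERM%03d", i),
                            gene_id = sample(geneIds, k))
  }
  .restore_seed(old)
  targetGenes <- intersect(targetGenes, geneIds)
  if (length(targetGenes))
    rows[[nTerms + 1L]] <- data.table(term_id = "TERM_PLANTED",
                                      gene_id = targetGenes)
  map <- rbindlist(rows)
  desc <- data.table(term_id = unique(map$term_id))
  desc[, description := ifelse(term_id == "TERM_PLANTED",
                               "planted differential-gene term",
                               paste("synthetic term", term_id))]
  list(map = map[], descriptions = desc[])
}
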