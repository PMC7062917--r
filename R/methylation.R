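## Methylation-level estimation and genome-wide summaries.
##
## The per-site methylation level (ML) is the fraction of reads supporting
## methylation, mC/(mC+C). Because a fraction r of unmethylated cytosines
## escapes bisulfite conversion and reads as methylated, the apparent level
## at a site with true level p has expectation q = p + (1-p) r; the
## correction inverts that relation. r is estimated by pooling all reads on
## the unmethylated lambda spike-in chromosome.

## internal: site-level data.table view of a SampleMethylome
.siteTable <- function(methylome) {
  gr <- methSites(methylome)
  data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
             strand = as.character(strand(gr)),
             M = as.integer(mcols(gr)$M), U = as.integer(mcols(gr)$U),
             context = as.character(mcols(gr)$context))
}

## internal: chromosome lengths for a methylome (seqlengths, else max pos)
.chromLens <- function(methylome) {
  gr <- methSites(methylome)
  sl <- seqlengths(gr)
  if (all(!is.na(sl))) return(sl)
  tapply(end(gr), as.character(seqnames(gr)), max)
}

## internal: 1-anchored window starts covering a chromosome of length L.
## Windows start at 1, 1+step, ...; the first window whose end reaches the
## chromosome end is the last one and is truncated there.
.windowStarts <- function(L, window, step) {
  n <- ceiling(max(0L, L - window) / step) + 1L
  seq.int(1L, by = step, length.out = n)
}

#' Per-site methylation level
#'
#' `ML = mC / (mC + C)`: the fraction of reads supporting methylation.
#' Sites with zero coverage have no defined level and must be treated as
#' missing, never as 0.
#'
#' @param countMeth,countUnmeth Non-negative read counts (vectorised).
#' @return Numeric vector of fractions; `NA` where coverage is zero.
#' @examples
#' siteML(3, 7)  # 0.3
#' @export
siteML <- function(countMeth, countUnmeth) {
  if (any(countMeth < 0) || any(countUnmeth < 0))
    stop("read counts must be non-negative")
  cov <- countMeth + countUnmeth
  ifelse(cov > 0, countMeth / cov, NA_real_)
}

#' Estimate the bisulfite non-conversion rate from the spike-in control
#'
#' Pools methylated and unmethylated read counts over every covered site of
#' the unmethylated control chromosome: `r = sum(mC) / sum(mC + C)`. Because
#' the control is fully unmethylated, any methylated call there is a
#' conversion failure.
#'
#' @param methylome A [SampleMethylome-class].
#' @param genome The companion [GenomeSequence-class]; its `controlChrom`
#'   must be set.
#' @return The input methylome with `nonconversionRate` filled in.
#' @export
estimateNonconversion <- function(methylome, genome) {
  stopifnot(is(methylome, "SampleMethylome"), is(genome, "GenomeSequence"))
  ctrl <- controlChrom(genome)
  if (is.na(ctrl))
    stop("genome has no control chromosome; supply the rate explicitly ",
         "with nonconversionRate(x) <- r")
  gr <- methSites(methylome)
  on <- as.character(seqnames(gr)) == ctrl
  M <- sum(as.numeric(mcols(gr)$M[on]))
  U <- sum(as.numeric(mcols(gr)$U[on]))
  if (M + U == 0)
    stop("no covered sites on control chromosome '", ctrl,
         "'; supply the non-conversion rate explicitly")
  nonconversionRate(methylome) <- M / (M + U)
  methylome
}

#' Correct a methylation level for bisulfite non-conversion
#'
#' Inverts the error model `ml_raw = p + (1 - p) r` (a fraction `r` of
#' unmethylated molecules reads as methylated):
#' `ml_corrected = max(0, (ml_raw - r) / (1 - r))`.
#'
#' @param mlRaw Raw level(s) in `[0,1]`.
#' @param r Non-conversion rate in `[0,1)`.
#' @return Corrected level(s), clamped at 0.
#' @examples
#' correctML(0.3, 0.005)
#' @export
correctML <- function(mlRaw, r) {
  if (any(r >= 1) || any(r < 0)) stop("non-conversion rate must be in [0,1)")
  if (any(mlRaw < 0 | mlRaw > 1, na.rm = TRUE))
    stop("mlRaw must be in [0,1]")
  pmax(0, (mlRaw - r) / (1 - r))
}

#' Call methylated cytosines against the non-conversion background
#'
#' For every site with coverage of at least `minCoverage`, tests the
#' one-sided exact binomial null that all methylated reads are conversion
#' failures: `p = P[X >= M | X ~ Binomial(coverage, r)]`. p-values are
#' BH-adjusted within each context stratum and a site is called methylated
#' when its adjusted p falls below `alpha`. Sites below the coverage
#' threshold are not testable and are excluded from downstream numerators
#' and denominators alike.
#'
#' @param methylome A [SampleMethylome-class]; its `nonconversionRate` must
#'   be set (see [estimateNonconversion()]) unless `r` is supplied.
#' @param r Optional explicit non-conversion rate overriding the stored one.
#' @param minCoverage Minimum coverage for a site to be testable (default 5).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return A `data.table` with one row per site: `chrom, pos, strand,
#'   context, M, U, testable, p, q, methylated`.
#' @export
callMethylatedSites <- function(methylome, r = NULL, minCoverage = 5L,
                                alpha = 0.05) {
  if (is.null(r)) r <- nonconversionRate(methylome)
  if (is.na(r))
    stop("non-conversion rate unset; run estimateNonconversion() first")
  dt <- .siteTable(methylome)
  dt[, cov := M + U]
  dt[, testable := cov >= minCoverage]
  dt[, p := NA_real_]
  dt[testable == TRUE,
     p := stats::pbinom(M - 1L, cov, r, lower.tail = FALSE)]
  dt[, q := NA_real_]
  dt[testable == TRUE, q := stats::p.adjust(p, method = "BH"), by = context]
  dt[, methylated := testable & !is.na(q) & q < alpha]
  dt[, cov := NULL]
  dt[]
}

## internal: pool site counts into 1-anchored windows; shared core of
## slidingWindowML / binProfile. `sites` is a data.table with chrom, pos,
## M, U (covered sites only).
.poolWindows <- function(sites, chromLens, window, step) {
  out <- vector("list", length(chromLens))
  for (i in seq_along(chromLens)) {
    chrom <- names(chromLens)[i]
    L <- chromLens[[i]]
    ss <- sites[chrom, on = "chrom", nomatch = NULL]
    if (nrow(ss) == 0L) next
    starts <- .windowStarts(L, window, step)
    ends <- pmin(starts + window - 1L, L)
    hits <- findOverlaps(IRanges(ss$pos, width = 1L), IRanges(starts, ends))
    if (length(hits) == 0L) next
    h <- data.table(win = S4Vectors::subjectHits(hits),
                    M = ss$M[S4Vectors::queryHits(hits)],
                    U = ss$U[S4Vectors::queryHits(hits)])
    agg <- h[, .(n_sites = .N, sum_meth = sum(as.numeric(M)),
                 sum_unmeth = sum(as.numeric(U))), by = win]
    agg[, `:=`(chrom = chrom, start = starts[win], end = ends[win])]
    out[[i]] <- agg[, .(chrom, start, end, n_sites, sum_meth, sum_unmeth)]
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      sum_meth = numeric(), sum_unmeth = numeric(),
                      ml = numeric()))
  res[, ml := sum_meth / (sum_meth + sum_unmeth)]
  res[]
}

#' Sliding-window pooled methylation levels
#'
#' Tiles every chromosome with windows anchored at position 1 and stepped
#' by `step`; the last window is truncated at the chromosome end. Read
#' counts of all covered sites of the requested context (both strands) are
#' pooled per window; windows containing no covered site are omitted.
#'
#' @param methylome A [SampleMethylome-class].
#' @param window,step Window and step size in bp (defaults 3000/600).
#' @param context `"CG"`, `"CHG"`, `"CHH"`, or `"combined"` to pool all
#'   three contexts.
#' @param chromLens Optional named chromosome lengths; defaults to the
#'   methylome's `seqlengths` (or the max covered position per chromosome).
#' @return `data.table` with `chrom, start, end, n_sites, sum_meth,
#'   sum_unmeth, ml` (1-based inclusive coordinates).
#' @export
slidingWindowML <- function(methylome, window = 3000L, step = 600L,
                            context = "combined", chromLens = NULL) {
  stopifnot(window >= step, step >= 1L)
  context <- match.arg(context, c(VALID_CONTEXTS, "combined"))
  if (is.null(chromLens)) chromLens <- .chromLens(methylome)
  dt <- .siteTable(methylome)
  if (context != "combined") dt <- dt[context, on = "context", nomatch = NULL]
  dt <- dt[M + U > 0L]
  .poolWindows(dt, chromLens, as.integer(window), as.integer(step))
}

#' Fixed-bin methylation profile
#'
#' Non-overlapping tiling bins (default 10 kb): equivalent to
#' [slidingWindowML()] with `window = step = bin`. The per-bin pooled
#' levels are the input for genome-wide violin/density displays.
#'
#' @inheritParams slidingWindowML
#' @param bin Bin width in bp.
#' @return Same shape as [slidingWindowML()].
#' @export
binProfile <- function(methylome, bin = 10000L, context = "combined",
                       chromLens = NULL) {
  slidingWindowML(methylome, window = bin, step = bin, context = context,
                  chromLens = chromLens)
}

#' Genome and per-chromosome methylated-context proportions
#'
#' For each scope (whole genome and/or each chromosome) reports, per
#' context `c`: `pct_mC(c) = 100 * called-methylated sites of context c /
#' testable cytosines of all contexts in scope`, so the three context
#' percentages add up to the total methylated-cytosine percentage. Also
#' reports the composition of the methylated sites themselves
#' (`share_mCG/mCHG/mCHH`, summing to 1 for scopes with at least one call).
#'
#' @param calls Output of [callMethylatedSites()].
#' @param by `"genome"`, `"chromosome"`, or `"both"`.
#' @param excludeChrom Chromosomes to drop first (the spike-in control is
#'   the usual candidate).
#' @return `data.table` with one row per scope.
#' @export
contextProportions <- function(calls, by = c("both", "genome", "chromosome"),
                               excludeChrom = NULL) {
  by <- match.arg(by)
  dt <- calls[testable == TRUE]
  if (!is.null(excludeChrom)) dt <- dt[!chrom %in% excludeChrom]
  if (nrow(dt) == 0L) stop("no testable cytosines in scope")
  summarise <- function(d, scope) {
    N <- nrow(d)
    k <- vapply(VALID_CONTEXTS,
                function(cc) sum(d$methylated & d$context == cc), numeric(1))
    tot <- sum(k)
    data.table(scope = scope,
               n_testable = N,
               pct_mCG = 100 * k[["CG"]] / N,
               pct_mCHG = 100 * k[["CHG"]] / N,
               pct_mCHH = 100 * k[["CHH"]] / N,
               pct_total_mCX = 100 * tot / N,
               share_mCG = if (tot > 0) k[["CG"]] / tot else 0,
               share_mCHG = if (tot > 0) k[["CHG"]] / tot else 0,
               share_mCHH = if (tot > 0) k[["CHH"]] / tot else 0)
  }
  out <- list()
  if (by %in% c("both", "genome")) out$genome <- summarise(dt, "genome")
  if (by %in% c("both", "chromosome"))
    out$chrom <- rbindlist(lapply(split(dt, dt$chrom),
                                  function(d) summarise(d, d$chrom[1L])))
  rbindlist(out)
}
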