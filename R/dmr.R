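## Sliding-window DMR detection.
##
## Treatment and control are compared in 1000-bp windows stepped by 100 bp.
## Only cytosines of the tested context covered by at least 5 reads in BOTH
## samples enter a window; read counts are pooled per window and sample.
## The filter cascade: |diff| > 0.1, symmetric fold change > 2, strictly
## more than 10 shared cytosines; then a two-sided Fisher's exact test on
## the pooled 2x2 table (p < 0.05); then Benjamini-Hochberg FDR (< 0.05)
## across all windows that passed the pre-filter. Surviving windows that
## overlap or are book-ended and share the sign of the difference are
## merged, and all statistics (including the Fisher p) are recomputed on
## each merged interval.

#' Two-sided Fisher's exact test for 2x2 tables, vectorised
#'
#' Point-probability ordering: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 absorbs floating-point ties, as in
#' [stats::fisher.test()]).
#'
#' @param a,b,c,d Vectors of cell counts: table rows are `(a, b)` and
#'   `(c, d)`.
#' @return Vector of two-sided p-values.
#' @examples
#' fisherExact2x2(3, 0, 0, 3)  # 0.1
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  p <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; c1 <- a[i] + c[i]
    if (r1 + r2 == 0L) { p[i] <- 1; next }
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    dk <- stats::dhyper(x, c1, r1 + r2 - c1, r1)
    d0 <- stats::dhyper(a[i], c1, r1 + r2 - c1, r1)
    p[i] <- min(1, sum(dk[dk <= d0 * (1 + 1e-7)]))
  }
  p
}

## internal: pool shared covered sites of one context into windows for one
## treatment/control pair. Returns per-window counts for both samples.
.scanTable <- function(treat, ctrl, params, context, chromLens) {
  tt <- .siteTable(treat)
  ct <- .siteTable(ctrl)
  tt <- tt[context, on = "context", nomatch = NULL]
  ct <- ct[context, on = "context", nomatch = NULL]
  mc <- params@minSiteCoverage
  tt <- tt[M + U >= mc]
  ct <- ct[M + U >= mc]
  shared <- merge(tt, ct, by = c("chrom", "pos", "strand"),
                  suffixes = c("_t", "_c"))
  list(shared = shared, chromLens = chromLens)
}

#' Scan paired methylomes into sliding-window count tables
#'
#' For every window (anchored at position 1, stepped by `stepBp`, last
#' window truncated at the chromosome end) pools the methylated and
#' unmethylated read counts over the shared covered cytosines of the
#' requested context — sites covered by at least `minSiteCoverage` reads in
#' both samples. Windows containing no shared site are omitted.
#'
#' @param treat,ctrl [SampleMethylome-class] objects on the same genome.
#' @param params A [DmrParams-class].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param chromLens Optional named chromosome lengths (defaults to the
#'   treatment methylome's `seqlengths`).
#' @return `data.table` with one row per non-empty window: `chrom, start,
#'   end, context, n_cytosines, M_t, U_t, M_c, U_c`.
#' @export
windowScan <- function(treat, ctrl, params = DmrParams(), context = "CG",
                       chromLens = NULL) {
  context <- match.arg(context, VALID_CONTEXTS)
  if (is.null(chromLens)) chromLens <- .chromLens(treat)
  sc <- .scanTable(treat, ctrl, params, context, chromLens)
  shared <- sc$shared
  out <- vector("list", length(chromLens))
  for (i in seq_along(chromLens)) {
    ch <- names(chromLens)[i]
    L <- chromLens[[i]]
    ss <- shared[ch, on = "chrom", nomatch = NULL]
    if (nrow(ss) == 0L) next
    starts <- .windowStarts(L, params@windowBp, params@stepBp)
    ends <- pmin(starts + params@windowBp - 1L, L)
    hits <- findOverlaps(IRanges(ss$pos, width = 1L), IRanges(starts, ends))
    if (length(hits) == 0L) next
    h <- data.table(win = S4Vectors::subjectHits(hits),
                    M_t = ss$M_t[S4Vectors::queryHits(hits)],
                    U_t = ss$U_t[S4Vectors::queryHits(hits)],
                    M_c = ss$M_c[S4Vectors::queryHits(hits)],
                    U_c = ss$U_c[S4Vectors::queryHits(hits)])
    agg <- h[, .(n_cytosines = .N, M_t = sum(as.numeric(M_t)),
                 U_t = sum(as.numeric(U_t)), M_c = sum(as.numeric(M_c)),
                 U_c = sum(as.numeric(U_c))), by = win]
    agg[, `:=`(chrom = ch, start = starts[win], end = ends[win])]
    out[[i]] <- agg[, .(chrom, start, end, n_cytosines, M_t, U_t, M_c, U_c)]
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_cytosines = integer(),
                      M_t = numeric(), U_t = numeric(), M_c = numeric(),
                      U_c = numeric())
  res[, context := context]
  res[]
}

#' Add effect sizes and Fisher p-values to window count tables
#'
#' `diff = ml_treat - ml_ctrl`; the fold change is symmetric,
#' `max(ml)/max(min(ml), eps)` with `eps = params@foldEps`, so it applies
#' to hyper- and hypomethylation alike and is finite when one level is 0.
#' The p-value is the two-sided Fisher's exact probability of the pooled
#' table `[[M_t, U_t], [M_c, U_c]]`.
#'
#' @param windows Output of [windowScan()].
#' @param params A [DmrParams-class].
#' @param computeP Compute Fisher p for every window (set `FALSE` to defer
#'   until after the pre-filter, as [callDMRs()] does).
#' @return The windows with `ml_treat, ml_ctrl, diff, fold_change` and
#'   (optionally) `p` added. Windows with zero pooled coverage in either
#'   sample are dropped.
#' @export
testWindows <- function(windows, params = DmrParams(), computeP = TRUE) {
  w <- as.data.table(windows)
  w <- w[M_t + U_t > 0 & M_c + U_c > 0]
  w[, ml_treat := M_t / (M_t + U_t)]
  w[, ml_ctrl := M_c / (M_c + U_c)]
  w[, diff := ml_treat - ml_ctrl]
  eps <- params@foldEps
  w[, fold_change := pmax(ml_treat, ml_ctrl) /
      pmax(pmin(ml_treat, ml_ctrl), eps)]
  if (computeP && nrow(w) > 0L)
    w[, p := fisherExact2x2(M_t, U_t, M_c, U_c)]
  else if (computeP)
    w[, p := numeric()]
  w[]
}

#' Call DMRs from tested windows
#'
#' The full cascade: (1) pre-filter `|diff| > minDiff`, `fold_change >
#' minFoldChange`, `n_cytosines > minCytosines`; (2) Fisher `p <
#' pThreshold`; (3) BH adjustment across all windows passing (1), keep `q <
#' fdrThreshold`; (4) merge overlapping or book-ended surviving windows
#' with the same sign of `diff` into maximal runs; (5) recompute pooled
#' statistics and the Fisher p on each merged interval from the shared
#' covered sites, classify hyper/hypo by the sign of the merged difference,
#' and BH-adjust the merged p-values.
#'
#' @param treat,ctrl The [SampleMethylome-class] pair the windows came from
#'   (needed to recompute merged-interval statistics).
#' @param params A [DmrParams-class].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param chromLens Optional named chromosome lengths.
#' @param windows Optional precomputed [windowScan()] output for this
#'   contrast and context.
#' @return `data.table` of DMRs: `chrom, start, end, context, status,
#'   ml_treat, ml_ctrl, diff, fold_change, n_cytosines, p, q`.
#' @export
callDMRs <- function(treat, ctrl, params = DmrParams(), context = "CG",
                     chromLens = NULL, windows = NULL) {
  context <- match.arg(context, VALID_CONTEXTS)
  if (is.null(chromLens)) chromLens <- .chromLens(treat)
  if (is.null(windows))
    windows <- windowScan(treat, ctrl, params, context, chromLens)
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      status = character(), ml_treat = numeric(),
                      ml_ctrl = numeric(), diff = numeric(),
                      fold_change = numeric(), n_cytosines = integer(),
                      p = numeric(), q = numeric())
  if (nrow(windows) == 0L) return(empty)
  w <- testWindows(windows, params, computeP = FALSE)
  ## (1) effect-size / support pre-filter
  w <- w[abs(diff) > params@minDiff & fold_change > params@minFoldChange &
           n_cytosines > params@minCytosines]
  if (nrow(w) == 0L) return(empty)
  ## (2)+(3) Fisher p, then BH across all pre-filter survivors
  w[, p := fisherExact2x2(M_t, U_t, M_c, U_c)]
  w[, q := stats::p.adjust(p, method = "BH")]
  w <- w[p < params@pThreshold & q < params@fdrThreshold]
  if (nrow(w) == 0L) return(empty)
  ## (4) merge same-sign overlapping/book-ended windows
  w[, sign_ := sign(diff)]
  gr <- GRanges(w$chrom, IRanges(w$start, w$end))
  mcols(gr)$sign_ <- w$sign_
  merged <- list()
  for (s in unique(w$sign_)) {
    red <- GenomicRanges::reduce(gr[mcols(gr)$sign_ == s],
                                 min.gapwidth = 1L)
    if (length(red))
      merged[[as.character(s)]] <- data.table(
        chrom = as.character(seqnames(red)), start = start(red),
        end = end(red), sign_ = s)
  }
  m <- rbindlist(merged)
  setorder(m, chrom, start, end)
  ## (5) recompute pooled statistics on each merged interval
  sc <- .scanTable(treat, ctrl, params, context, chromLens)
  shared <- sc$shared
  res <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    ss <- shared[chrom == m$chrom[i] & pos >= m$start[i] & pos <= m$end[i]]
    Mt <- sum(as.numeric(ss$M_t)); Ut <- sum(as.numeric(ss$U_t))
    Mc <- sum(as.numeric(ss$M_c)); Uc <- sum(as.numeric(ss$U_c))
    mlT <- Mt / (Mt + Ut); mlC <- Mc / (Mc + Uc)
    res[[i]] <- data.table(
      chrom = m$chrom[i], start = m$start[i], end = m$end[i],
      context = context,
      status = if (m$sign_[i] > 0) "hyper" else "hypo",
      ml_treat = mlT, ml_ctrl = mlC, diff = mlT - mlC,
      fold_change = pmax(mlT, mlC) / pmax(pmin(mlT, mlC), params@foldEps),
      n_cytosines = nrow(ss),
      p = fisherExact2x2(Mt, Ut, Mc, Uc))
  }
  dmrs <- rbindlist(res)
  dmrs[, q := stats::p.adjust(p, method = "BH")]
  setorder(dmrs, chrom, start, end)
  dmrs[]
}

#' Annotate DMRs with overlapping elements and genes
#'
#' A DMR records every element type it overlaps by at least 1 bp and every
#' owning gene; a DMR overlapping nothing is intergenic (empty hits).
#' Element types are reported in fixed promoter/utr5/exon/intron/utr3
#' order, joined by `/`; gene ids are sorted and joined by `,`.
#'
#' @param dmrs Output of [callDMRs()].
#' @param elements `GRanges` from [deriveElements()].
#' @return The DMRs with `element_hits` and `gene_ids` columns added.
#' @export
annotateDMRs <- function(dmrs, elements) {
  dmrs <- as.data.table(dmrs)
  dmrs[, element_hits := ""]
  dmrs[, gene_ids := ""]
  if (nrow(dmrs) == 0L) return(dmrs[])
  gr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  hits <- findOverlaps(gr, elements, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    h <- data.table(dmr = S4Vectors::queryHits(hits),
                    type = mcols(elements)$element_type[
                      S4Vectors::subjectHits(hits)],
                    gene = mcols(elements)$gene_id[
                      S4Vectors::subjectHits(hits)])
    ann <- h[, .(
      element_hits = paste(intersect(ELEMENT_TYPES, unique(type)),
                           collapse = "/"),
      gene_ids = paste(sort(unique(gene)), collapse = ",")), by = dmr]
    dmrs[ann$dmr, `:=`(element_hits = ann$element_hits,
                       gene_ids = ann$gene_ids)]
  }
  dmrs[]
}

#' Collapse annotated DMRs into differentially methylated genes
#'
#' One DMG per gene owning at least one DMR. The gene's methylation ratio
#' is the treatment/control ratio of pooled methylation levels over the
#' distinct shared covered cytosines (per DMR context) of the union of the
#' gene's DMR intervals, with an epsilon floor on the denominator. Status:
#' hyper when the ratio is at least `ratioCut`, hypo when at most
#' `1/ratioCut`, otherwise unchanged.
#'
#' @param dmrs Annotated DMRs (see [annotateDMRs()]).
#' @param treat,ctrl The [SampleMethylome-class] pair.
#' @param params A [DmrParams-class] (for the shared-site coverage policy
#'   and epsilon floor).
#' @param ratioCut Hyper/hypo ratio threshold (default 1.5).
#' @return `data.table(gene_id, n_dmrs, regions, ml_treat, ml_ctrl,
#'   methylation_ratio, ratio_status)`.
#' @export
collectDMGs <- function(dmrs, treat, ctrl, params = DmrParams(),
                        ratioCut = 1.5) {
  dmrs <- as.data.table(dmrs)
  empty <- data.table(gene_id = character(), n_dmrs = integer(),
                      regions = character(), ml_treat = numeric(),
                      ml_ctrl = numeric(), methylation_ratio = numeric(),
                      ratio_status = character())
  genic <- dmrs[gene_ids != ""]
  if (nrow(genic) == 0L) return(empty)
  long <- genic[, .(gene_id = strsplit(gene_ids, ",", fixed = TRUE)[[1L]]),
                by = .(chrom, start, end, context, element_hits)]
  tt <- .siteTable(treat); ct <- .siteTable(ctrl)
  mc <- params@minSiteCoverage
  tt <- tt[M + U >= mc]; ct <- ct[M + U >= mc]
  shared <- merge(tt, ct, by = c("chrom", "pos", "strand", "context"),
                  suffixes = c("_t", "_c"))
  out <- list()
  for (g in sort(unique(long$gene_id))) {
    regs <- long[gene_id == g]
    keys <- list()
    for (i in seq_len(nrow(regs))) {
      sel <- shared[chrom == regs$chrom[i] & pos >= regs$start[i] &
                      pos <= regs$end[i] & context == regs$context[i]]
      keys[[i]] <- sel
    }
    sel <- unique(rbindlist(keys))
    Mt <- sum(as.numeric(sel$M_t)); Ut <- sum(as.numeric(sel$U_t))
    Mc <- sum(as.numeric(sel$M_c)); Uc <- sum(as.numeric(sel$U_c))
    mlT <- if (Mt + Ut > 0) Mt / (Mt + Ut) else NA_real_
    mlC <- if (Mc + Uc > 0) Mc / (Mc + Uc) else NA_real_
    ratio <- if (is.na(mlT) || is.na(mlC)) NA_real_
             else mlT / max(mlC, params@foldEps)
    status <- if (is.na(ratio)) "degenerate"
              else if (ratio >= ratioCut) "hyper"
              else if (ratio <= 1 / ratioCut) "hypo"
              else "unchanged"
    out[[g]] <- data.table(
      gene_id = g, n_dmrs = nrow(regs),
      regions = paste(sort(unique(unlist(
        strsplit(regs$element_hits, "/", fixed = TRUE)))), collapse = "/"),
      ml_treat = mlT, ml_ctrl = mlC, methylation_ratio = ratio,
      ratio_status = status)
  }
  rbindlist(out)[]
}

#' Venn-region counts of 2-3 named gene sets
#'
#' @param dmgSets Named list of 2 or 3 character vectors of gene ids.
#' @return `data.table(region, count)` with one row per exclusive Venn
#'   region (membership pattern over the named sets).
#' @examples
#' vennOverlap(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
vennOverlap <- function(dmgSets) {
  n <- length(dmgSets)
  if (n < 2L || n > 3L) stop("vennOverlap needs 2 or 3 sets")
  if (is.null(names(dmgSets)) || any(!nzchar(names(dmgSets))))
    stop("sets must be named")
  sets <- lapply(dmgSets, unique)
  all_ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_ %in% s, logical(length(all_)))
  if (length(all_) == 1L) memb <- matrix(memb, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))[-2^n, , drop = FALSE]
  names(patterns) <- names(sets)
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, , drop = TRUE])
    cnt <- if (length(all_) == 0L) 0L
           else sum(apply(memb, 1L, function(r) all(r == pat)))
    data.table(region = paste(names(sets)[pat], collapse = "&"),
               count = as.integer(cnt))
  })
  res <- rbindlist(out)
  setorder(res, region)
  res[]
}

#' Cluster DMGs by Pearson-correlation distance
#'
#' Agglomerative (average-linkage) clustering of the gene-by-sample matrix
#' of pooled DMR methylation levels under the distance `d = 1 - Pearson r`.
#' Rows are sorted by gene id first so leaf order is deterministic;
#' constant rows (undefined correlation) are dropped with a warning.
#'
#' @param mlMatrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @return List with `hclust` (the tree), `order` (leaf labels in plotting
#'   order) and `newick` (the dendrogram serialised as a Newick string).
#' @export
clusterDMGs <- function(mlMatrix) {
  m <- as.matrix(mlMatrix)
  if (anyNA(m))
    stop("methylation matrix contains missing values; impute or drop first")
  if (ncol(m) < 2L) stop("need >= 2 samples")
  m <- m[order(rownames(m)), , drop = FALSE]
  constant <- apply(m, 1L, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant row(s) dropped before clustering")
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 non-constant genes")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Score recovered DMRs against planted truth
#'
#' A planted region counts as recovered when called DMRs of its context
#' overlap at least `minFrac` of its length; a called DMR counts as a false
#' discovery when it overlaps no planted region at all.
#'
#' @param dmrs `data.table` from [callDMRs()].
#' @param planted `data.frame(chrom, start, end, context, delta)`.
#' @param minFrac Minimum recovered fraction of a planted region.
#' @return List with `sensitivity`, `fdp`, `n_called`, `n_planted`.
#' @export
evaluateDmrRecovery <- function(dmrs, planted, minFrac = 0.5) {
  planted <- as.data.frame(planted)
  nP <- nrow(planted)
  if (nrow(dmrs) == 0L)
    return(list(sensitivity = 0, fdp = 0, n_called = 0L, n_planted = nP))
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  pgr <- GRanges(planted$chrom, IRanges(planted$start, planted$end))
  cov <- GenomicRanges::coverage(dgr)
  recovered <- vapply(seq_len(nP), function(i) {
    if (!planted$chrom[i] %in% names(cov)) return(FALSE)
    v <- cov[[planted$chrom[i]]]
    if (length(v) < planted$start[i]) return(FALSE)
    w <- sum(S4Vectors::window(v, planted$start[i],
                               min(length(v), planted$end[i])) > 0)
    w >= minFrac * (planted$end[i] - planted$start[i] + 1L)
  }, logical(1))
  falsePos <- GenomicRanges::countOverlaps(dgr, pgr) == 0L
  list(sensitivity = mean(recovered),
       fdp = mean(falsePos),
       n_called = nrow(dmrs), n_planted = nP)
}
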