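## Independent oracles and small fixture builders used across the suite.

## --- brute-force two-sided Fisher p for one 2x2 table -------------------
## Enumerates every table with the observed margins, computing each point
## probability from binomial coefficients, and sums those not exceeding the
## observed table's probability (relative tolerance 1e-7 for float ties).
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p0 <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

## --- brute-force cytosine context scanner -------------------------------
## Classifies every position of both strands of a plain character sequence
## through a precomputed 64-entry trinucleotide lookup table.
.oracleTriTable <- local({
  bases <- c("A", "C", "G", "T")
  tris <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                          paste0))
  tris <- tris[substring(tris, 1, 1) == "C"]
  ctx <- ifelse(substring(tris, 2, 2) == "G", "CG",
                ifelse(substring(tris, 3, 3) == "G", "CHG", "CHH"))
  stats::setNames(ctx, tris)
})

.oracleRevcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), character(1)))
}

## returns data.frame(pos, strand, context, tri) of all classifiable sites
contextOracle <- function(seqstr) {
  n <- nchar(seqstr)
  ch <- strsplit(seqstr, "")[[1]]
  out <- list()
  plus <- which(ch == "C")
  plus <- plus[plus + 2 <= n]
  if (length(plus)) {
    tri <- substring(seqstr, plus, plus + 2)
    ok <- !grepl("N", tri, fixed = TRUE)
    out$p <- data.frame(pos = plus[ok], strand = "+",
                        context = unname(.oracleTriTable[tri[ok]]),
                        tri = tri[ok])
  }
  minus <- which(ch == "G")
  minus <- minus[minus - 2 >= 1]
  if (length(minus)) {
    tri <- .oracleRevcomp(substring(seqstr, minus - 2, minus))
    ok <- !grepl("N", tri, fixed = TRUE)
    out$m <- data.frame(pos = minus[ok], strand = "-",
                        context = unname(.oracleTriTable[tri[ok]]),
                        tri = tri[ok])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(pos = integer(), strand = character(),
                      context = character(), tri = character()))
  res <- res[order(res$pos, res$strand), ]
  rownames(res) <- NULL
  res
}

## --- fixture builders ----------------------------------------------------

## a methylome built directly from a site table
makeMethylome <- function(chrom, pos, strand, M, U, context, tri = NULL,
                          sampleId = "s", seqlens = NULL) {
  if (is.null(tri))
    tri <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")[context]
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand)
  if (!is.null(seqlens))
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  S4Vectors::mcols(gr)$M <- as.integer(M)
  S4Vectors::mcols(gr)$U <- as.integer(U)
  S4Vectors::mcols(gr)$context <- factor(context, c("CG", "CHG", "CHH"))
  S4Vectors::mcols(gr)$tri <- unname(tri)
  SampleMethylome(gr, sampleId)
}

## a quick small simulation config for unit tests
smallConfig <- function(seed = 1L, ...) {
  SimulationConfig(seed = seed, chromLengths = c(40000L, 30000L),
                   lambdaLength = 20000L, dmrCount = 6L, ...)
}

## random DNA string with optional N runs
randomSeq <- function(n, withN = FALSE) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (withN && n > 50) {
    k <- sample(1:3, 1)
    for (i in seq_len(k)) {
      s <- sample(1:(n - 10), 1)
      b[s:(s + sample(1:8, 1))] <- "N"
    }
  }
  paste(b, collapse = "")
}

## simple single-gene GeneModelSet builder
makeModels <- function(chrom, start, end, strand, exonStarts, exonEnds,
                       gid = "g1") {
  gn <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gn)$gene_id <- gid
  S4Vectors::mcols(gn)$tss <- if (strand == "+") start else end
  ex <- GenomicRanges::GRanges(chrom, IRanges::IRanges(exonStarts, exonEnds))
  e <- GenomicRanges::GRangesList(stats::setNames(list(ex), gid))
  u <- GenomicRanges::GRangesList(stats::setNames(
    list(GenomicRanges::GRanges()), gid))
  new("GeneModelSet", genes = gn, exons = e, utr5 = u, utr3 = u)
}

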