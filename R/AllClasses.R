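#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom data.table data.table as.data.table setkey setorder := fwrite rbindlist
NULL

## quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "M", "U", "chrom", "pos", "context", "tri",
  "win", "n_sites", "sum_meth", "sum_unmeth", "ml", "cov", "covered",
  "M_t", "U_t", "M_c", "U_c", "n_cytosines", "p", "q",
  "fold_change", "ml_treat", "ml_ctrl", "bin", "meth", "unmeth",
  "element_type", "gene_id", "testable", "methylated", "term_id",
  "sample_id", "sign_", "i.meth", "i.unmeth", "gene_ids", "dmr", "type",
  "gene", "region", "agent", "dose_uM", "fresh_weight_mg", "K", "k", "N",
  "n", "description", "pair", "agent1", "agent2", "dose1_uM", "dose2_uM",
  "w", "delta", "ci_true", "i"
))

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' GenomeSequence: a reference genome with an optional unmethylated control
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] that additionally names
#' the spike-in control chromosome (an unmethylated lambda phage genome is
#' the convention in WGBS libraries) used to estimate the bisulfite
#' non-conversion rate.
#'
#' @slot seq A `DNAStringSet`, one entry per chromosome, uppercase A/C/G/T/N.
#' @slot controlChrom Name of the unmethylated control chromosome, or
#'   `NA_character_` when the genome has none.
#'
#' @export
setClass("GenomeSequence",
  slots = c(seq = "DNAStringSet", controlChrom = "character"))

setValidity("GenomeSequence", function(object) {
  msg <- character()
  nm <- names(object@seq)
  if (length(object@seq) == 0L) msg <- c(msg, "genome has no chromosomes")
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    msg <- c(msg, "every chromosome needs a name")
  if (anyDuplicated(nm)) msg <- c(msg, "duplicate chromosome names")
  if (any(Biostrings::width(object@seq) < 1L))
    msg <- c(msg, "every chromosome must have length >= 1")
  if (length(object@controlChrom) != 1L)
    msg <- c(msg, "controlChrom must be a single string (or NA)")
  else if (!is.na(object@controlChrom) && !object@controlChrom %in% nm)
    msg <- c(msg, sprintf("control chromosome '%s' not in genome",
                          object@controlChrom))
  bad <- grepl("[^ACGTN]", as.character(object@seq))
  if (any(bad))
    msg <- c(msg, sprintf("chromosome '%s' contains letters outside A,C,G,T,N",
                          nm[which(bad)[1L]]))
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSequence
#'
#' @param seq A named `DNAStringSet` or named character vector of sequences.
#' @param controlChrom Optional name of the unmethylated spike-in chromosome.
#' @return A [GenomeSequence-class] object.
#' @examples
#' g <- GenomeSequence(c(Chr1 = "ACGTACGT", lambda = "AAAA"),
#'                     controlChrom = "lambda")
#' chromNames(g)
#' @export
GenomeSequence <- function(seq, controlChrom = NA_character_) {
  if (is.character(seq)) seq <- DNAStringSet(toupper(seq))
  new("GenomeSequence", seq = seq,
      controlChrom = as.character(controlChrom))
}

#' @describeIn GenomeSequence-class chromosome names, in genome order
#' @param x,object A `GenomeSequence`.
#' @export
chromNames <- function(x) names(x@seq)

#' @describeIn GenomeSequence-class named vector of chromosome lengths (bp)
#' @export
chromLengths <- function(x) {
  stats::setNames(Biostrings::width(x@seq), names(x@seq))
}

#' @describeIn GenomeSequence-class the underlying `DNAStringSet`
#' @export
genomeSeq <- function(x) x@seq

#' @describeIn GenomeSequence-class name of the control chromosome (or NA)
#' @export
controlChrom <- function(x) x@controlChrom

setMethod("show", "GenomeSequence", function(object) {
  cat("GenomeSequence with", length(object@seq), "chromosome(s),",
      sum(Biostrings::width(object@seq)), "bp total\n")
  if (!is.na(object@controlChrom))
    cat("  control chromosome:", object@controlChrom, "\n")
})

#' SampleMethylome: per-cytosine methylation counts for one sample
#'
#' Holds one sample's per-cytosine read counts as a stranded `GRanges`
#' (width-1 sites) with metadata columns `M` (reads supporting methylation),
#' `U` (reads supporting non-methylation), `context` (CG/CHG/CHH) and `tri`
#' (the trinucleotide 5'->3' on the cytosine's strand), plus the sample's
#' bisulfite non-conversion rate once estimated.
#'
#' @slot sites A `GRanges` of width-1 cytosine positions.
#' @slot sampleId Sample label, e.g. "DMSO" or "AZD".
#' @slot nonconversionRate Fraction of unmethylated cytosines escaping
#'   conversion, in `[0,1]`, or `NA` before estimation.
#'
#' @export
setClass("SampleMethylome",
  slots = c(sites = "GRanges", sampleId = "character",
            nonconversionRate = "numeric"))

setValidity("SampleMethylome", function(object) {
  msg <- character()
  gr <- object@sites
  mc <- mcols(gr)
  need <- c("M", "U", "context", "tri")
  if (!all(need %in% names(mc)))
    return(sprintf("sites must carry metadata columns %s",
                   paste(need, collapse = ", ")))
  if (any(IRanges::width(gr) != 1L)) msg <- c(msg, "all sites must be width 1")
  if (any(mc$M < 0L) || any(mc$U < 0L)) msg <- c(msg, "negative read counts")
  if (!all(as.character(mc$context) %in% VALID_CONTEXTS))
    msg <- c(msg, "context must be one of CG, CHG, CHH")
  if (any(as.character(strand(gr)) == "*"))
    msg <- c(msg, "sites must be stranded (+ or -)")
  key <- paste(as.character(seqnames(gr)), start(gr), as.character(strand(gr)))
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (chrom, pos, strand) site keys")
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single string")
  r <- object@nonconversionRate
  if (length(r) != 1L || (!is.na(r) && (r < 0 || r > 1)))
    msg <- c(msg, "nonconversionRate must be one value in [0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleMethylome
#'
#' @param sites `GRanges` of width-1 cytosine sites with metadata columns
#'   `M`, `U`, `context`, `tri`.
#' @param sampleId Sample label.
#' @param nonconversionRate Known non-conversion rate, or `NA` (default) to
#'   estimate later with [estimateNonconversion()].
#' @return A [SampleMethylome-class].
#' @export
SampleMethylome <- function(sites, sampleId,
                            nonconversionRate = NA_real_) {
  new("SampleMethylome", sites = sites, sampleId = as.character(sampleId),
      nonconversionRate = as.numeric(nonconversionRate))
}

#' @describeIn SampleMethylome-class the site-level `GRanges`
#' @param x,object A `SampleMethylome`.
#' @export
methSites <- function(x) x@sites

#' @describeIn SampleMethylome-class the sample label
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn SampleMethylome-class the stored non-conversion rate (NA if unset)
#' @export
nonconversionRate <- function(x) x@nonconversionRate

#' @describeIn SampleMethylome-class set the non-conversion rate
#' @param value New rate in `[0,1]`.
#' @export
`nonconversionRate<-` <- function(x, value) {
  x@nonconversionRate <- as.numeric(value)
  validObject(x)
  x
}

setMethod("show", "SampleMethylome", function(object) {
  gr <- object@sites
  cov <- mcols(gr)$M + mcols(gr)$U
  cat("SampleMethylome '", object@sampleId, "': ", length(gr),
      " cytosine sites (", sum(cov > 0L), " covered)\n", sep = "")
  tab <- table(factor(as.character(mcols(gr)$context), VALID_CONTEXTS))
  cat("  contexts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (!is.na(object@nonconversionRate))
    cat("  non-conversion rate:",
        format(object@nonconversionRate, digits = 4), "\n")
})

#' GeneModelSet: gene models with derived transcript structure
#'
#' One record per gene, collapsed to the transcript with the longest genomic
#' span when a gene has several. Exons, 5'UTRs and 3'UTRs are kept per gene;
#' introns and strand-aware promoters are derived by [deriveElements()].
#'
#' @slot genes `GRanges` of gene spans with mcols `gene_id` and `tss`
#'   (transcription start site: span start on `+`, span end on `-`).
#' @slot exons,utr5,utr3 `GRangesList` keyed by `gene_id`.
#'
#' @export
setClass("GeneModelSet",
  slots = c(genes = "GRanges", exons = "GRangesList",
            utr5 = "GRangesList", utr3 = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  ids <- mcols(object@genes)$gene_id
  if (is.null(ids)) return("genes must carry a gene_id column")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate gene_id")
  if (!identical(names(object@exons), ids))
    msg <- c(msg, "exons must be named by gene_id in gene order")
  for (i in seq_along(ids)) {
    g <- object@genes[i]
    ex <- object@exons[[i]]
    if (length(ex) == 0L) { msg <- c(msg, "gene without exons"); break }
    if (any(start(ex) < start(g)) || any(end(ex) > end(g))) {
      msg <- c(msg, sprintf("exon outside gene span for %s", ids[i]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class gene spans as `GRanges`
#' @param x,object A `GeneModelSet`.
#' @export
genes <- function(x) x@genes

#' @describeIn GeneModelSet-class gene identifiers
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' @describeIn GeneModelSet-class per-gene exon `GRangesList`
#' @export
geneExons <- function(x) x@exons

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "gene(s) on",
      length(unique(as.character(seqnames(object@genes)))),
      "chromosome(s)\n")
})

#' DmrParams: thresholds of the sliding-window DMR filter cascade
#'
#' Defaults follow the standard plant WGBS sliding-window procedure:
#' 1000-bp windows stepped by 100 bp, per-cytosine coverage of at least 5
#' reads in both samples, absolute methylation difference > 0.1, symmetric
#' fold change > 2, strictly more than 10 shared covered cytosines per
#' window, Fisher's exact p < 0.05 and Benjamini-Hochberg FDR < 0.05.
#'
#' @slot windowBp,stepBp Window and step size in bp.
#' @slot minSiteCoverage Minimum per-cytosine coverage required in both
#'   samples for a site to enter a window.
#' @slot minDiff Minimum absolute pooled methylation-level difference.
#' @slot minFoldChange Minimum symmetric fold change between the two
#'   pooled methylation levels (`max/min` with an epsilon floor).
#' @slot minCytosines Window must contain strictly more shared covered
#'   cytosines than this.
#' @slot pThreshold,fdrThreshold Fisher p and BH q cutoffs.
#' @slot foldEps Epsilon floor applied to the smaller methylation level in
#'   the fold-change ratio so fully unmethylated windows stay comparable.
#' @export
setClass("DmrParams",
  slots = c(windowBp = "integer", stepBp = "integer",
            minSiteCoverage = "integer", minDiff = "numeric",
            minFoldChange = "numeric", minCytosines = "integer",
            pThreshold = "numeric", fdrThreshold = "numeric",
            foldEps = "numeric"))

setValidity("DmrParams", function(object) {
  msg <- character()
  if (object@windowBp < object@stepBp)
    msg <- c(msg, "window must be >= step")
  if (object@stepBp < 1L) msg <- c(msg, "step must be >= 1")
  for (s in c("minSiteCoverage", "minDiff", "minFoldChange", "minCytosines",
              "pThreshold", "fdrThreshold", "foldEps"))
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("%s must be positive", s))
  if (length(msg)) msg else TRUE
})

#' Construct DmrParams
#' @param windowBp,stepBp,minSiteCoverage,minDiff,minFoldChange,minCytosines,pThreshold,fdrThreshold,foldEps
#'   See [DmrParams-class].
#' @return A `DmrParams` object.
#' @examples
#' DmrParams()              # standard defaults
#' DmrParams(minDiff = 0.2) # stricter effect size
#' @export
DmrParams <- function(windowBp = 1000L, stepBp = 100L, minSiteCoverage = 5L,
                      minDiff = 0.1, minFoldChange = 2, minCytosines = 10L,
                      pThreshold = 0.05, fdrThreshold = 0.05,
                      foldEps = 0.01) {
  new("DmrParams", windowBp = as.integer(windowBp),
      stepBp = as.integer(stepBp),
      minSiteCoverage = as.integer(minSiteCoverage),
      minDiff = as.numeric(minDiff),
      minFoldChange = as.numeric(minFoldChange),
      minCytosines = as.integer(minCytosines),
      pThreshold = as.numeric(pThreshold),
      fdrThreshold = as.numeric(fdrThreshold),
      foldEps = as.numeric(foldEps))
}

setMethod("show", "DmrParams", function(object) {
  cat(sprintf(paste0(
    "DmrParams: window %d bp / step %d bp; site coverage >= %d;\n",
    "  |diff| > %g; fold change > %g; cytosines > %d; p < %g; FDR < %g\n"),
    object@windowBp, object@stepBp, object@minSiteCoverage, object@minDiff,
    object@minFoldChange, object@minCytosines, object@pThreshold,
    object@fdrThreshold))
})

#' MedianEffectFit: parameters of a fitted median-effect dose-response
#'
#' The median-effect model `fa/(1-fa) = (D/Dm)^m` linearises to
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)`; the fit is ordinary least
#' squares on that line. `Dm` is the median-effect dose (the GI50 when `fa`
#' measures growth inhibition), `m` the sigmoidicity slope.
#'
#' @slot agent Agent label.
#' @slot m Slope (dimensionless).
#' @slot Dm Median-effect dose, same unit as the input doses (uM here).
#' @slot r2 R-squared of the log-linear fit.
#' @slot n Number of dose points used.
#' @export
setClass("MedianEffectFit",
  slots = c(agent = "character", m = "numeric", Dm = "numeric",
            r2 = "numeric", n = "integer"))

setValidity("MedianEffectFit", function(object) {
  if (object@Dm <= 0) "Dm must be positive"
  else if (object@m <= 0) "slope m must be positive"
  else TRUE
})

setMethod("show", "MedianEffectFit", function(object) {
  cat(sprintf("MedianEffectFit [%s]: m = %.4g, Dm = %.4g uM, r2 = %.4f (n = %d)\n",
              object@agent, object@m, object@Dm, object@r2, object@n))
})
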