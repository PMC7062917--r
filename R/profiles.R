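## Functional-element metaprofiles.
##
## Gene models yield five element classes: promoter (the 2 kb immediately
## upstream of the TSS, strand-aware), 5'UTR, exon, intron and 3'UTR. Each
## element is split into 20 equal-length bins traversed 5'->3' in gene
## orientation, read counts of covered sites are pooled per bin across all
## elements of a class, and the per-bin pooled methylation level is the
## metaprofile.

ELEMENT_TYPES <- c("promoter", "utr5", "exon", "intron", "utr3")

#' Derive functional-element intervals from gene models
#'
#' Promoter: `[TSS-2000, TSS-1]` on `+` genes, `[TSS+1, TSS+2000]` on `-`
#' genes, truncated at the chromosome bounds (omitted with a warning when
#' fully off-chromosome). Introns are the gaps between consecutive exons;
#' UTRs are passed through from the models.
#'
#' @param models A [GeneModelSet-class].
#' @param genome The companion [GenomeSequence-class] (for chromosome
#'   bounds).
#' @param promoterBp Promoter length upstream of the TSS (default 2000).
#' @return `GRanges` with mcols `gene_id` and `element_type`, strand taken
#'   from the gene.
#' @export
deriveElements <- function(models, genome, promoterBp = 2000L) {
  gn <- genes(models)
  lens <- chromLengths(genome)
  out <- list()
  for (i in seq_along(gn)) {
    gid <- mcols(gn)$gene_id[i]
    ch <- as.character(seqnames(gn))[i]
    st <- as.character(strand(gn))[i]
    tss <- mcols(gn)$tss[i]
    L <- lens[[ch]]
    if (st == "+") {
      ps <- tss - promoterBp; pe <- tss - 1L
    } else {
      ps <- tss + 1L; pe <- tss + promoterBp
    }
    ps2 <- max(1L, ps); pe2 <- min(L, pe)
    if (ps2 > pe2) {
      warning("promoter of ", gid, " fully off-chromosome; omitted")
      prom <- NULL
    } else {
      prom <- GRanges(ch, IRanges(ps2, pe2), strand = st)
    }
    ex <- sort(models@exons[[i]])
    nex <- length(ex)
    introns <- NULL
    if (nex > 1L) {
      is_ <- end(ex)[-nex] + 1L
      ie_ <- start(ex)[-1L] - 1L
      keep <- ie_ >= is_
      if (any(keep))
        introns <- GRanges(ch, IRanges(is_[keep], ie_[keep]))
    }
    mk <- function(gr, type) {
      if (is.null(gr) || length(gr) == 0L) return(NULL)
      gr <- GRanges(as.character(seqnames(gr)),
                    IRanges(start(gr), end(gr)), strand = st)
      mcols(gr)$gene_id <- gid
      mcols(gr)$element_type <- type
      gr
    }
    parts <- Filter(Negate(is.null), list(
      mk(prom, "promoter"), mk(models@utr5[[i]], "utr5"),
      mk(granges(ex), "exon"), mk(introns, "intron"),
      mk(models@utr3[[i]], "utr3")))
    out[[gid]] <- if (length(parts))
      suppressWarnings(do.call(c, parts)) else NULL
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- suppressWarnings(unname(do.call(c, unname(out))))
  seqlengths(res) <- lens[seqlevels(res)]
  res
}

## internal: assign an offset (0-based distance from the element's 5' end)
## to bin 1..nBins using floor boundaries b_k = floor(k*L/n): 1-based bin k
## covers offsets [b_{k-1}, b_k). The largest k with b_{k-1} <= off is
## floor((n*(off+1) - 1)/L) + 1 (exact integer arithmetic; ties from
## zero-width bins of short elements land in the last such bin).
## Vectorised over matched off/L pairs.
.binOf <- function(off, L, nBins) {
  as.integer(floor((as.numeric(nBins) * (off + 1) - 1) / L)) + 1L
}

#' Pooled metaprofile over a functional-element class
#'
#' Splits every element of the requested type into `nBins` equal-length
#' bins (floor boundaries), walks bins 5'->3' in gene orientation (elements
#' on `-` genes are traversed from their genomic end), pools methylated and
#' unmethylated read counts of covered sites of the requested context per
#' bin across all elements, and reports the pooled level per bin. Sites are
#' assigned by position only, both strands pooled; each site inside an
#' element lands in exactly one bin of that element.
#'
#' @param methylome A [SampleMethylome-class].
#' @param elements `GRanges` from [deriveElements()].
#' @param elementType One of `r toString(ELEMENT_TYPES)`.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"combined"`.
#' @param nBins Number of bins (default 20).
#' @return `data.table(bin, meth, unmeth, ml)` with `nBins` rows; `ml` is
#'   `NA` for bins with no pooled reads.
#' @export
metaProfile <- function(methylome, elements, elementType,
                        context = "combined", nBins = 20L) {
  if (nBins < 1L) stop("nBins must be >= 1")
  elementType <- match.arg(elementType, ELEMENT_TYPES)
  context <- match.arg(context, c(VALID_CONTEXTS, "combined"))
  el <- elements[mcols(elements)$element_type == elementType]
  if (length(el) == 0L) stop("no elements of type ", elementType)
  dt <- .siteTable(methylome)
  if (context != "combined") dt <- dt[context, on = "context", nomatch = NULL]
  dt <- dt[M + U > 0L]
  acc <- data.table(bin = seq_len(nBins), meth = 0, unmeth = 0)
  if (nrow(dt) > 0L) {
    siteGr <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L))
    hits <- findOverlaps(siteGr, el, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      L <- IRanges::width(el)[si]
      minus <- as.character(strand(el))[si] == "-"
      off <- ifelse(minus, end(el)[si] - dt$pos[qi],
                    dt$pos[qi] - start(el)[si])
      h <- data.table(bin = .binOf(off, L, nBins),
                      M = dt$M[qi], U = dt$U[qi])
      agg <- h[, .(meth = sum(as.numeric(M)), unmeth = sum(as.numeric(U))),
               by = bin]
      acc[agg, `:=`(meth = i.meth, unmeth = i.unmeth), on = "bin"]
    }
  }
  acc[, ml := ifelse(meth + unmeth > 0, meth / (meth + unmeth), NA_real_)]
  acc[]
}
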