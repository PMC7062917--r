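## Cytosine context calling.
##
## A cytosine's context is read 5'->3' on its own strand from the two bases
## immediately downstream: second base G -> CG; otherwise third base G ->
## CHG; otherwise CHH (H = A, T or C). Sites with fewer than two downstream
## bases (chromosome edge) or with an N among them have undefined context
## and are excluded from all analyses.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.contextFromDownstream <- function(b1, b2) {
  ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
}

#' Classify the sequence context of cytosines
#'
#' Vectorised over `pos`. For a plus-strand cytosine the trinucleotide is
#' the reference bases at `pos, pos+1, pos+2`; for a minus-strand cytosine
#' (a `G` on the reference) it is the reverse complement of the bases at
#' `pos-2, pos-1, pos`, so that it always reads 5'->3' on the cytosine's
#' own strand.
#'
#' @param genome A [GenomeSequence-class].
#' @param chrom Chromosome name (single value).
#' @param pos Integer vector of 1-based positions.
#' @param strand `"+"` or `"-"` (single value or vector matching `pos`).
#' @return A `data.frame` with columns `context` and `trinucleotide`;
#'   both are `NA` where the context is undefined (chromosome edge or a
#'   downstream `N`).
#' @examples
#' g <- GenomeSequence(c(Chr1 = "ACGT"))
#' classifyContext(g, "Chr1", 2, "+")   # CG, trinucleotide CGT
#' @export
classifyContext <- function(genome, chrom, pos, strand) {
  stopifnot(is(genome, "GenomeSequence"), length(chrom) == 1L)
  if (!chrom %in% chromNames(genome))
    stop(sprintf("unknown chromosome '%s'", chrom))
  s <- as.character(genomeSeq(genome)[[chrom]])
  n <- nchar(s)
  pos <- as.integer(pos)
  strand <- rep_len(as.character(strand), length(pos))
  if (any(pos < 1L | pos > n)) stop("position outside chromosome")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  base <- substring(s, pos, pos)
  okbase <- ifelse(strand == "+", base == "C", base == "G")
  if (!all(okbase))
    stop(sprintf("position %d is not a cytosine on strand %s",
                 pos[!okbase][1L], strand[!okbase][1L]))
  context <- tri <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  if (any(plus)) {
    p <- pos[plus]
    b1 <- ifelse(p + 1L <= n, substring(s, p + 1L, p + 1L), "N")
    b2 <- ifelse(p + 2L <= n, substring(s, p + 2L, p + 2L), "N")
    ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
    context[plus][ok] <- .contextFromDownstream(b1[ok], b2[ok])
    tri[plus][ok] <- paste0("C", b1[ok], b2[ok])
  }
  if (any(!plus)) {
    p <- pos[!plus]
    ## downstream on the minus strand runs towards lower reference coords
    d1 <- ifelse(p - 1L >= 1L, substring(s, p - 1L, p - 1L), "N")
    d2 <- ifelse(p - 2L >= 1L, substring(s, p - 2L, p - 2L), "N")
    b1 <- unname(.COMPLEMENT[d1])
    b2 <- unname(.COMPLEMENT[d2])
    ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
    context[!plus][ok] <- .contextFromDownstream(b1[ok], b2[ok])
    tri[!plus][ok] <- paste0("C", b1[ok], b2[ok])
  }
  data.frame(context = context, trinucleotide = tri,
             stringsAsFactors = FALSE)
}

#' Enumerate every classifiable cytosine of a genome
#'
#' Scans both strands of every chromosome and returns all cytosines whose
#' context is defined (two non-N downstream bases on their own strand).
#'
#' @param genome A [GenomeSequence-class].
#' @return A stranded width-1 `GRanges` with mcols `context` and `tri`,
#'   carrying the genome's `seqlengths`, sorted by chromosome, position,
#'   strand.
#' @export
cytosineSites <- function(genome) {
  stopifnot(is(genome, "GenomeSequence"))
  res <- vector("list", length(chromNames(genome)))
  for (i in seq_along(chromNames(genome))) {
    chrom <- chromNames(genome)[i]
    s <- as.character(genomeSeq(genome)[[chrom]])
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(b)
    out <- list()
    pc <- which(b == "C")
    if (length(pc)) {
      b1 <- ifelse(pc + 1L <= n, b[pmin(pc + 1L, n)], "N")
      b2 <- ifelse(pc + 2L <= n, b[pmin(pc + 2L, n)], "N")
      ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
      if (any(ok))
        out$plus <- data.table(pos = pc[ok], strand = "+",
                               context = .contextFromDownstream(b1[ok], b2[ok]),
                               tri = paste0("C", b1[ok], b2[ok]))
    }
    pg <- which(b == "G")
    if (length(pg)) {
      d1 <- ifelse(pg - 1L >= 1L, b[pmax(pg - 1L, 1L)], "N")
      d2 <- ifelse(pg - 2L >= 1L, b[pmax(pg - 2L, 1L)], "N")
      b1 <- unname(.COMPLEMENT[d1])
      b2 <- unname(.COMPLEMENT[d2])
      ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
      if (any(ok))
        out$minus <- data.table(pos = pg[ok], strand = "-",
                                context = .contextFromDownstream(b1[ok], b2[ok]),
                                tri = paste0("C", b1[ok], b2[ok]))
    }
    if (length(out)) {
      dt <- rbindlist(out)
      dt[, chrom := chrom]
      res[[i]] <- dt
    }
  }
  dt <- rbindlist(res)
  if (nrow(dt) > 0L)
    dt[, chrom := factor(chrom, levels = chromNames(genome))]
  if (nrow(dt) == 0L) {
    gr <- GRanges(seqinfo = Seqinfo(chromNames(genome),
                                    unname(chromLengths(genome))))
    mcols(gr)$context <- factor(character(), VALID_CONTEXTS)
    mcols(gr)$tri <- character()
    return(gr)
  }
  setorder(dt, chrom, pos, strand)
  gr <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L), strand = dt$strand,
                seqinfo = Seqinfo(chromNames(genome),
                                  unname(chromLengths(genome))))
  mcols(gr)$context <- factor(dt$context, VALID_CONTEXTS)
  mcols(gr)$tri <- dt$tri
  gr
}
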