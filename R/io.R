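## Readers and writers for the standard formats the pipeline touches:
## FASTA genome, GFF3 gene models, per-cytosine CX report (7-column TSV),
## and BED6 + TSV DMR outputs. All in-memory coordinates are 1-based
## inclusive; BED output alone is 0-based half-open. Every TSV written by
## the package carries a single header line beginning "#".

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @param controlChrom Optional name of the unmethylated spike-in
#'   chromosome; must be present in the file.
#' @return A [GenomeSequence-class] with uppercased sequences.
#' @export
readGenomeFasta <- function(path, controlChrom = NA_character_) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name: ",
         names(seqs)[duplicated(names(seqs))][1L])
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record: ",
         names(seqs)[Biostrings::width(seqs) == 0L][1L])
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  if (!is.na(controlChrom) && !controlChrom %in% names(seqs))
    stop(sprintf("control chromosome '%s' not found in %s",
                 controlChrom, path))
  GenomeSequence(seqs, controlChrom = controlChrom)
}

#' Write a GenomeSequence to FASTA
#' @param genome A [GenomeSequence-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genomeSeq(genome), path, width = 70L)
  invisible(path)
}

#' Read a per-cytosine CX report
#'
#' Seven tab-separated columns: chrom, pos (1-based), strand (+/-), count
#' of methylated reads, count of unmethylated reads, context (CG/CHG/CHH),
#' trinucleotide. Lines beginning `#` are treated as headers and skipped.
#' The context column must be consistent with the trinucleotide (second
#' base G -> CG; else third base G -> CHG; else CHH).
#'
#' @param path Input TSV.
#' @param sampleId Sample label; defaults to the file name stem.
#' @param genome Optional [GenomeSequence-class]; when supplied, chromosome
#'   names are validated against it and `seqlengths` are attached.
#' @return A [SampleMethylome-class].
#' @export
readCXReport <- function(path, sampleId = NULL, genome = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.(CX_report\\.)?(tsv|txt)(\\.gz)?$", "",
                    basename(path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  fail <- function(i, why)
    stop(sprintf("%s: parse error at line %d: %s", path, lineno[i], why),
         call. = FALSE)
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr)$M <- integer(); mcols(gr)$U <- integer()
    mcols(gr)$context <- factor(character(), VALID_CONTEXTS)
    mcols(gr)$tri <- character()
    return(SampleMethylome(gr, sampleId))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L))
    fail(which(nf != 7L)[1L],
         sprintf("expected 7 tab-separated fields, found %d",
                 nf[which(nf != 7L)[1L]]))
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  bad <- which(is.na(pos) | pos < 1L | m[, 2L] != as.character(pos))
  if (length(bad)) fail(bad[1L], sprintf("bad position '%s'", m[bad[1L], 2L]))
  if (any(!m[, 3L] %in% c("+", "-")))
    fail(which(!m[, 3L] %in% c("+", "-"))[1L], "strand must be + or -")
  cm <- suppressWarnings(as.integer(m[, 4L]))
  cu <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(cm) | cm < 0L | m[, 4L] != as.character(cm))
  if (length(bad))
    fail(bad[1L], sprintf("non-integer methylated count '%s'", m[bad[1L], 4L]))
  bad <- which(is.na(cu) | cu < 0L | m[, 5L] != as.character(cu))
  if (length(bad))
    fail(bad[1L], sprintf("non-integer unmethylated count '%s'", m[bad[1L], 5L]))
  if (any(!m[, 6L] %in% VALID_CONTEXTS))
    fail(which(!m[, 6L] %in% VALID_CONTEXTS)[1L],
         "context must be CG, CHG or CHH")
  tri <- m[, 7L]
  bad <- which(nchar(tri) != 3L | substring(tri, 1L, 1L) != "C")
  if (length(bad))
    fail(bad[1L], sprintf("bad trinucleotide '%s'", tri[bad[1L]]))
  expctx <- .contextFromDownstream(substring(tri, 2L, 2L),
                                   substring(tri, 3L, 3L))
  bad <- which(expctx != m[, 6L])
  if (length(bad))
    fail(bad[1L], sprintf("context '%s' inconsistent with trinucleotide '%s'",
                          m[bad[1L], 6L], tri[bad[1L]]))
  key <- paste(m[, 1L], pos, m[, 3L])
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate site key at line %d",
                 path, lineno[which(duplicated(key))[1L]]), call. = FALSE)
  si <- NULL
  if (!is.null(genome)) {
    unknown <- setdiff(unique(m[, 1L]), chromNames(genome))
    if (length(unknown))
      stop(path, ": chromosome not in genome: ", unknown[1L], call. = FALSE)
    si <- Seqinfo(chromNames(genome), unname(chromLengths(genome)))
  }
  gr <- if (is.null(si)) {
    GRanges(m[, 1L], IRanges(pos, width = 1L), strand = m[, 3L])
  } else {
    GRanges(m[, 1L], IRanges(pos, width = 1L), strand = m[, 3L],
            seqinfo = si)
  }
  mcols(gr)$M <- cm
  mcols(gr)$U <- cu
  mcols(gr)$context <- factor(m[, 6L], VALID_CONTEXTS)
  mcols(gr)$tri <- tri
  SampleMethylome(gr, sampleId)
}

#' Write a SampleMethylome as a CX report
#'
#' Emits the 7-column format accepted by [readCXReport()], sorted by
#' chromosome, position, strand; a write-then-read round trip reproduces
#' the identical keyed site collection.
#'
#' @param methylome A [SampleMethylome-class].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeCXReport <- function(methylome, path) {
  dt <- .siteTable(methylome)
  gr <- methSites(methylome)
  dt[, tri := mcols(gr)$tri]
  setorder(dt, chrom, pos, strand)
  header <- "#chrom\tpos\tstrand\tcount_meth\tcount_unmeth\tcontext\ttrinucleotide"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dt) > 0L)
    writeLines(paste(dt$chrom, dt$pos, dt$strand, dt$M, dt$U, dt$context,
                     dt$tri, sep = "\t"), con)
  invisible(path)
}

## internal: choose the transcript with the longest genomic span; ties go
## to the lexicographically smallest transcript ID so results are stable.
.pickTranscript <- function(tx) {
  spans <- end(tx) - start(tx)
  ord <- order(-spans, mcols(tx)$ID)
  tx[ord[1L]]
}

#' Read gene models from GFF3
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon`, `five_prime_UTR` and
#' `three_prime_UTR` features. When a gene has several transcripts, the one
#' with the longest genomic span is used (ties broken by transcript ID).
#' Exons parented directly on a gene are accepted for annotation styles
#' without transcript features. Genes without exons are skipped with a
#' warning; an exon outside its gene span is an error.
#'
#' @param path GFF3 file.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(mcols(gff)$type)
  ids <- as.character(mcols(gff)$ID)
  parent <- mcols(gff)$Parent
  parent1 <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  gn <- gff[type == "gene"]
  if (length(gn) == 0L) stop(path, ": no gene features")
  gids <- as.character(mcols(gn)$ID)
  keep <- rep(TRUE, length(gn))
  exons <- utr5s <- utr3s <- vector("list", length(gn))
  tx <- gff[type %in% c("mRNA", "transcript")]
  ex <- gff[type == "exon"]
  u5 <- gff[type == "five_prime_UTR"]
  u3 <- gff[type == "three_prime_UTR"]
  exParent <- parent1[type == "exon"]
  u5Parent <- parent1[type == "five_prime_UTR"]
  u3Parent <- parent1[type == "three_prime_UTR"]
  txParent <- parent1[type %in% c("mRNA", "transcript")]
  for (i in seq_along(gn)) {
    gid <- gids[i]
    mytx <- tx[!is.na(txParent) & txParent == gid]
    if (length(mytx) > 0L) {
      chosen <- .pickTranscript(mytx)
      tid <- as.character(mcols(chosen)$ID)
      myex <- ex[!is.na(exParent) & exParent == tid]
      myu5 <- u5[!is.na(u5Parent) & u5Parent == tid]
      myu3 <- u3[!is.na(u3Parent) & u3Parent == tid]
    } else {
      myex <- ex[!is.na(exParent) & exParent == gid]
      myu5 <- u5[!is.na(u5Parent) & u5Parent == gid]
      myu3 <- u3[!is.na(u3Parent) & u3Parent == gid]
    }
    if (length(myex) == 0L) {
      warning("gene ", gid, " has no exons; skipped")
      keep[i] <- FALSE
      next
    }
    if (any(start(myex) < start(gn[i])) || any(end(myex) > end(gn[i])))
      stop("exon outside gene span for ", gid)
    exons[[i]] <- sort(granges(myex))
    utr5s[[i]] <- sort(granges(myu5))
    utr3s[[i]] <- sort(granges(myu3))
  }
  gn <- gn[keep]
  gids <- gids[keep]
  exons <- exons[keep]; utr5s <- utr5s[keep]; utr3s <- utr3s[keep]
  tssv <- ifelse(as.character(strand(gn)) == "-", end(gn), start(gn))
  out <- granges(gn)
  mcols(out)$gene_id <- gids
  mcols(out)$tss <- tssv
  names(exons) <- names(utr5s) <- names(utr3s) <- gids
  new("GeneModelSet", genes = out,
      exons = GenomicRanges::GRangesList(exons),
      utr5 = GenomicRanges::GRangesList(utr5s),
      utr3 = GenomicRanges::GRangesList(utr3s))
}

#' Write a GeneModelSet as GFF3
#'
#' One gene + one mRNA per gene model, with exon and UTR children. Used by
#' the synthetic-data generator to emit its gene models.
#'
#' @param models A [GeneModelSet-class].
#' @param path Output GFF3.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  gn <- genes(models)
  rows <- c("##gff-version 3")
  for (i in seq_along(gn)) {
    gid <- mcols(gn)$gene_id[i]
    ch <- as.character(seqnames(gn))[i]
    st <- as.character(strand(gn))[i]
    line <- function(type, s, e, attrs)
      sprintf("%s\tmethylscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
              ch, type, s, e, st, attrs)
    rows <- c(rows,
              line("gene", start(gn)[i], end(gn)[i], sprintf("ID=%s", gid)),
              line("mRNA", start(gn)[i], end(gn)[i],
                   sprintf("ID=%s.1;Parent=%s", gid, gid)))
    ex <- models@exons[[i]]
    for (j in seq_along(ex))
      rows <- c(rows, line("exon", start(ex)[j], end(ex)[j],
                           sprintf("ID=%s.1.exon%d;Parent=%s.1", gid, j, gid)))
    u5 <- models@utr5[[i]]
    for (j in seq_along(u5))
      rows <- c(rows, line("five_prime_UTR", start(u5)[j], end(u5)[j],
                           sprintf("ID=%s.1.utr5.%d;Parent=%s.1", gid, j, gid)))
    u3 <- models@utr3[[i]]
    for (j in seq_along(u3))
      rows <- c(rows, line("three_prime_UTR", start(u3)[j], end(u3)[j],
                           sprintf("ID=%s.1.utr3.%d;Parent=%s.1", gid, j, gid)))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Write DMR calls as BED6 and TSV
#'
#' The BED file uses 0-based half-open intervals (`bed_start = start - 1`,
#' `bed_end = end`), name `context:status`, score `-10 log10(q)` rounded
#' and capped at 1000, strand `"."`. The TSV carries every DMR field with a
#' `#`-prefixed header. Output is sorted and formatted deterministically:
#' repeated runs on identical input are byte-identical.
#'
#' @param dmrs `data.table` of DMRs from [callDMRs()] (possibly annotated).
#' @param pathPrefix Output prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
writeDmrOutputs <- function(dmrs, pathPrefix) {
  dmrs <- as.data.table(dmrs)
  bedPath <- paste0(pathPrefix, ".bed")
  tsvPath <- paste0(pathPrefix, ".tsv")
  if (nrow(dmrs) > 0L) {
    setorder(dmrs, chrom, start, end, context)
    score <- ifelse(dmrs$q <= 0, 1000L,
                    pmin(1000L, as.integer(round(-10 * log10(dmrs$q)))))
    bed <- paste(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                 paste0(dmrs$context, ":", dmrs$status), score, ".",
                 sep = "\t")
    writeLines(bed, bedPath)
  } else {
    writeLines(character(), bedPath)
  }
  num <- function(x) sprintf("%.6g", x)
  cols <- c("chrom", "start", "end", "context", "status", "ml_treat",
            "ml_ctrl", "diff", "fold_change", "n_cytosines", "p", "q",
            "element_hits", "gene_ids")
  present <- intersect(cols, names(dmrs))
  header <- paste0("#", paste(present, collapse = "\t"))
  con <- file(tsvPath, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dmrs) > 0L) {
    body <- do.call(paste, c(lapply(present, function(cn) {
      v <- dmrs[[cn]]
      if (is.double(v)) num(v) else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(c(bed = bedPath, tsv = tsvPath))
}

#' Write any table as a deterministic #-headed TSV
#'
#' @param dt A data.frame/data.table.
#' @param path Output file.
#' @param digits Significant digits used to format double columns.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(dt, path, digits = 6L) {
  dt <- as.data.table(dt)
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dt) > 0L) {
    body <- do.call(paste, c(lapply(names(dt), function(cn) {
      v <- dt[[cn]]
      if (is.double(v)) sprintf(paste0("%.", digits, "g"), v)
      else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a #-headed TSV written by the package
#' @param path Input file.
#' @return A `data.table` (all columns as read by [data.table::fread()]).
#' @export
readTsv <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L)
    return(as.data.table(stats::setNames(
      replicate(length(cols), character(), simplify = FALSE), cols)))
  dt <- data.table::fread(text = lines[-1L], sep = "\t", header = FALSE)
  data.table::setnames(dt, cols)
  dt[]
}
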