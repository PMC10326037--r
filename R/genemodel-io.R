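## Readers/writers for transcript models (GFF3, BED12) and reference
## FASTA. Parsing is delegated to rtracklayer / Biostrings; these
## functions only translate between those containers and TranscriptModel.

## genomic ranges (one per exon chunk) covering transcript coords t1..t2
.txSpanToGenomic <- function(tm, t1, t2) {
  ends <- .txExonEnds(tm)
  starts <- c(0L, ends) + 1L
  ord <- .txOrder(tm)
  out <- IRanges()
  for (i in seq_along(ends)) {
    a <- max(t1, starts[i]); b <- min(t2, ends[i])
    if (a > b) next
    gx <- tm@exons[ord[i]]
    if (tm@strand == "+") {
      out <- c(out, IRanges(start(gx) + (a - starts[i]),
                            start(gx) + (b - starts[i])))
    } else {
      out <- c(out, IRanges(end(gx) - (b - starts[i]),
                            end(gx) - (a - starts[i])))
    }
  }
  out[order(start(out))]
}

#' Write a transcript model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with `ID`/`Parent`
#' attributes, the dialect [readTranscriptGFF3()] consumes.
#'
#' @param tm a [TranscriptModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTranscriptGFF3 <- function(tm, path) {
  gid <- if (is.na(tm@geneName)) paste0(tm@transcriptId, ".gene")
         else tm@geneName
  span <- IRanges(min(start(tm@exons)), max(end(tm@exons)))
  cdsg <- .txSpanToGenomic(tm, tm@cdsStartC, tm@cdsEndC)
  feats <- c("gene", "mRNA", rep("exon", length(tm@exons)),
             rep("CDS", length(cdsg)))
  r <- c(span, span, as(tm@exons, "IRanges"), cdsg)
  gr <- GRanges(tm@chrom, r, strand = tm@strand)
  mcols(gr)$source <- "pseudoexon"
  mcols(gr)$type <- feats
  mcols(gr)$ID <- c(gid, tm@transcriptId,
                    paste0(tm@transcriptId, ".exon", seq_along(tm@exons)),
                    paste0(tm@transcriptId, ".cds", seq_along(cdsg)))
  mcols(gr)$Parent <- c(NA_character_, gid,
                        rep(tm@transcriptId, length(tm@exons) + length(cdsg)))
  ## CDS phase: bases of the piece-initial codon already used upstream
  cdsWidths <- width(cdsg)
  txOrd <- if (tm@strand == "+") seq_along(cdsg) else rev(seq_along(cdsg))
  phase <- integer(length(cdsg))
  before <- 0L
  for (i in txOrd) {
    phase[i] <- (3L - before %% 3L) %% 3L
    before <- before + cdsWidths[i]
  }
  mcols(gr)$phase <- c(rep(NA_integer_, 2L + length(tm@exons)), phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a transcript model from GFF3
#'
#' Expects gene/mRNA/exon/CDS features linked by `ID`/`Parent`.
#'
#' @param path GFF3 file.
#' @param transcriptId mRNA `ID` to extract; default the first mRNA.
#' @param refseq optional reference sequence to attach (DNAStringSet,
#'   DNAString or character).
#' @return A [TranscriptModel-class].
#' @export
readTranscriptGFF3 <- function(path, transcriptId = NULL, refseq = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript feature in ", path)
  ids <- as.character(mrna$ID)
  if (is.null(transcriptId)) transcriptId <- ids[1L]
  m <- mrna[match(transcriptId, ids)]
  if (length(m) == 0L || is.na(ids[1L]))
    stop("transcript '", transcriptId, "' not found in ", path)
  parentOf <- function(x) vapply(x$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  ex <- gr[type == "exon"][parentOf(gr[type == "exon"]) == transcriptId]
  cds <- gr[type == "CDS"][parentOf(gr[type == "CDS"]) == transcriptId]
  if (length(ex) == 0L) stop("no exons for transcript '", transcriptId, "'")
  strand <- as.character(GenomicRanges::strand(m))
  gene <- parentOf(m)
  tm <- transcriptModel(transcriptId,
                        as.character(seqnames(m)), strand,
                        IRanges(start(ex), end(ex)),
                        geneName = gene)
  if (length(cds) > 0L) {
    g5 <- if (strand == "+") min(start(cds)) else max(end(cds))
    g3 <- if (strand == "+") max(end(cds)) else min(start(cds))
    tm@cdsStartC <- .g2t(tm, g5)
    tm@cdsEndC <- .g2t(tm, g3)
    validObject(tm)
  }
  if (!is.null(refseq)) tm <- attachSequence(tm, refseq)
  tm
}

#' Write a transcript model as BED12
#'
#' One BED12 line: exon blocks, CDS as the thick range.
#'
#' @param tm a [TranscriptModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTranscriptBED12 <- function(tm, path) {
  lo <- min(start(tm@exons))
  span <- IRanges(lo, max(end(tm@exons)))
  cdsg <- .txSpanToGenomic(tm, tm@cdsStartC, tm@cdsEndC)
  gr <- GRanges(tm@chrom, span, strand = tm@strand)
  mcols(gr)$name <- tm@transcriptId
  mcols(gr)$score <- 0L
  mcols(gr)$thick <- IRanges(min(start(cdsg)), max(end(cdsg)))
  mcols(gr)$blocks <- IRanges::IRangesList(
    IRanges(start(tm@exons) - lo + 1L, end(tm@exons) - lo + 1L))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a transcript model from BED12
#'
#' @param path BED12 file (one transcript per line).
#' @param name transcript name to extract; default the first line.
#' @param refseq optional reference sequence to attach.
#' @return A [TranscriptModel-class].
#' @export
readTranscriptBED12 <- function(path, name = NULL, refseq = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("no records in ", path)
  if (!is.null(name)) {
    gr <- gr[gr$name == name]
    if (length(gr) == 0L) stop("transcript '", name, "' not found in ", path)
  }
  gr <- gr[1L]
  blocks <- gr$blocks[[1L]]                       # relative to line start
  exons <- IRanges(start(gr) + start(blocks) - 1L,
                   start(gr) + end(blocks) - 1L)
  strand <- as.character(GenomicRanges::strand(gr))
  tm <- transcriptModel(gr$name, as.character(seqnames(gr)), strand, exons)
  th <- gr$thick
  if (length(th) == 1L && width(th) > 0L) {
    g5 <- if (strand == "+") start(th) else end(th)
    g3 <- if (strand == "+") end(th) else start(th)
    tm@cdsStartC <- .g2t(tm, g5)
    tm@cdsEndC <- .g2t(tm, g3)
    validObject(tm)
  }
  if (!is.null(refseq)) tm <- attachSequence(tm, refseq)
  tm
}

#' Read a reference FASTA (multi-record, wrapped lines)
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
readReferenceFasta <- function(path) {
  s <- readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))         # drop description
  s
}

#' Write a reference FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
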