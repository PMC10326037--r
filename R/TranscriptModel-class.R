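#' TranscriptModel: exon/CDS structure of one transcript on a genome
#'
#' Holds the exon intervals (1-based, inclusive, genomic order), strand,
#' CDS bounds in transcript coordinates, and optionally the reference
#' chromosome sequence. On strand `-` the transcript-order exons are the
#' reverse of the genomic order; all transcript-sense operations
#' ([cToG()], [gToC()], [extractSequence()]) account for this.
#'
#' @slot transcriptId character, e.g. `"SYNAPC.t1"`.
#' @slot geneName character, gene symbol (may be `NA`).
#' @slot chrom character, chromosome/sequence name.
#' @slot strand character, `"+"` or `"-"`.
#' @slot exons an [IRanges::IRanges] of exon intervals, sorted by
#'   genomic start, non-overlapping.
#' @slot cdsStartC,cdsEndC integer transcript coordinates (1-based,
#'   along the spliced transcript) of the first and last CDS base.
#' @slot refseq the chromosome sequence as a
#'   [Biostrings::DNAString] or `NULL` when no sequence is attached.
#'
#' @name TranscriptModel-class
#' @aliases TranscriptModel
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneName     = "character",
    chrom        = "character",
    strand       = "character",
    exons        = "IRanges",
    cdsStartC    = "integer",
    cdsEndC      = "integer",
    refseq       = "ANY"
  )
)

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return("exons must be non-empty")
  if (is.unsorted(start(ex))) return("exons must be sorted by genomic start")
  if (any(start(ex) > end(ex))) return("each exon must have start <= end")
  if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
    return("exons must be non-overlapping and separated by introns")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  tl <- sum(width(ex))
  if (object@cdsStartC < 1L || object@cdsEndC > tl ||
      object@cdsStartC > object@cdsEndC)
    return("CDS bounds must lie within the spliced transcript length")
  if (!is.null(object@refseq)) {
    if (!is(object@refseq, "DNAString"))
      return("refseq must be a DNAString or NULL")
    if (end(ex)[length(ex)] > length(object@refseq))
      return("exons extend beyond the attached reference sequence")
  }
  TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons an [IRanges::IRanges] (or a 2-column matrix of
#'   start/end) of exon intervals in genomic order.
#' @param cdsStartC,cdsEndC CDS bounds in transcript coordinates;
#'   default the whole transcript.
#' @param refseq optional chromosome [Biostrings::DNAString] (a
#'   character string is accepted).
#' @param geneName optional gene symbol.
#' @return A [TranscriptModel-class].
#' @examples
#' tm <- transcriptModel("TOYG1", "chrT", "+",
#'   IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
#' cdsLength(tm)
#' @export
transcriptModel <- function(transcriptId, chrom, strand, exons,
                            cdsStartC = 1L, cdsEndC = NULL,
                            refseq = NULL, geneName = NA_character_) {
  if (is.matrix(exons)) exons <- IRanges(exons[, 1L], exons[, 2L])
  exons <- exons[order(start(exons))]
  if (is.null(cdsEndC)) cdsEndC <- sum(width(exons))
  if (is.character(refseq)) refseq <- DNAString(refseq)
  new("TranscriptModel",
      transcriptId = transcriptId, geneName = geneName, chrom = chrom,
      strand = strand, exons = exons,
      cdsStartC = as.integer(cdsStartC), cdsEndC = as.integer(cdsEndC),
      refseq = refseq)
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId,
      if (!is.na(object@geneName)) paste0(" (", object@geneName, ")"),
      "\n  ", object@chrom, ":", min(start(object@exons)), "-",
      max(end(object@exons)), " (", object@strand, "), ",
      length(object@exons), " exons, transcript length ",
      sum(width(object@exons)), " nt, CDS c.1..", cdsLength(object),
      " at transcript ", object@cdsStartC, "..", object@cdsEndC,
      if (is.null(object@refseq)) "\n  no reference sequence attached"
      else paste0("\n  reference sequence: ", length(object@refseq), " nt"),
      "\n", sep = "")
})

#' @describeIn transcriptModel Exon intervals in genomic order.
#' @param tm a [TranscriptModel-class].
#' @export
exonRanges <- function(tm) tm@exons

#' @describeIn transcriptModel Spliced transcript length in nt.
#' @export
transcriptLength <- function(tm) sum(width(tm@exons))

#' @describeIn transcriptModel CDS length in nt.
#' @export
cdsLength <- function(tm) tm@cdsEndC - tm@cdsStartC + 1L

#' @describeIn transcriptModel Number of exons.
#' @export
exonCount <- function(tm) length(tm@exons)

#' @describeIn transcriptModel Attach a reference sequence.
#' @param refseq chromosome sequence ([Biostrings::DNAString],
#'   [Biostrings::DNAStringSet] keyed by chromosome, or character).
#' @export
attachSequence <- function(tm, refseq) {
  if (is(refseq, "DNAStringSet")) {
    if (!tm@chrom %in% names(refseq))
      stop("chromosome '", tm@chrom, "' not found in the sequence set")
    refseq <- refseq[[tm@chrom]]
  }
  if (is.character(refseq)) refseq <- DNAString(refseq)
  tm@refseq <- refseq
  validObject(tm)
  tm
}

## ---- internal transcript-order geometry -------------------------------

## exon index vector in transcript order (1 = 5'-most exon of the mRNA)
.txOrder <- function(tm) {
  if (tm@strand == "+") seq_along(tm@exons) else rev(seq_along(tm@exons))
}

## cumulative transcript coordinates of exon ends, transcript order
.txExonEnds <- function(tm) cumsum(width(tm@exons)[.txOrder(tm)])

## intron length (genomic gap) between transcript-order exons i and i+1
.intronLengths <- function(tm) {
  gaps <- start(tm@exons)[-1L] - end(tm@exons)[-length(tm@exons)] - 1L
  if (tm@strand == "+") gaps else rev(gaps)
}

## transcript coordinate -> genomic position (exonic only)
.t2g <- function(tm, t) {
  ends <- .txExonEnds(tm)
  if (t < 1L || t > ends[length(ends)])
    stop("transcript coordinate ", t, " outside the transcript")
  i <- which(t <= ends)[1L]                      # transcript-order exon
  within <- t - c(0L, ends)[i]                   # 1-based within exon
  gx <- tm@exons[.txOrder(tm)[i]]
  if (tm@strand == "+") start(gx) + within - 1L else end(gx) - within + 1L
}

## genomic position -> transcript coordinate, or NA when intronic
.g2t <- function(tm, g) {
  hit <- which(g >= start(tm@exons) & g <= end(tm@exons))
  if (length(hit) == 0L) return(NA_integer_)
  ends <- .txExonEnds(tm)
  i <- match(hit, .txOrder(tm))                  # transcript-order index
  gx <- tm@exons[hit]
  within <- if (tm@strand == "+") g - start(gx) + 1L else end(gx) - g + 1L
  c(0L, ends)[i] + within
}

## ---- coordinate conversion --------------------------------------------

#' Convert a coding position to a genomic position
#'
#' Strand-aware HGVS arithmetic: offset 0 returns the genomic base
#' carrying CDS base `base`; `+k` walks k bases 3'-ward (transcript
#' sense) of the exon-final base; `-k` walks k bases 5'-ward of the
#' exon-initial base. Offsets that walk past the intron into the next
#' exon, and bases beyond the CDS length, are errors, never clamped.
#'
#' @param tm a [TranscriptModel-class].
#' @param p a [CodingPosition-class].
#' @return 1-based genomic position (integer).
#' @examples
#' tm <- transcriptModel("TOYG1", "chrT", "+",
#'   IRanges::IRanges(c(101, 301, 501), c(200, 400, 600)))
#' cToG(tm, parseCpos("c.100+50"))  # 250
#' @seealso [gToC()] for the inverse.
#' @export
cToG <- function(tm, p) {
  stopifnot(is(tm, "TranscriptModel"), is(p, "CodingPosition"))
  if (p@base > cdsLength(tm))
    stop("c.", p@base, " beyond CDS length ", cdsLength(tm))
  t <- tm@cdsStartC + p@base - 1L
  if (p@offset == 0L) return(.t2g(tm, t))
  ends <- .txExonEnds(tm)
  i <- which(t <= ends)[1L]
  starts <- c(0L, ends) + 1L
  introns <- .intronLengths(tm)
  ord <- .txOrder(tm)
  if (p@offset > 0L) {
    if (t != ends[i])
      stop("offset +", p@offset, " must anchor the final base of an exon; ",
           formatCpos(p), " does not")
    if (i >= length(ends))
      stop("no intron downstream of the terminal exon")
    if (p@offset > introns[i])
      stop("offset +", p@offset, " walks past intron ", i,
           " (length ", introns[i], ") into the next exon")
    gx <- tm@exons[ord[i]]
    if (tm@strand == "+") end(gx) + p@offset else start(gx) - p@offset
  } else {
    k <- -p@offset
    if (t != starts[i])
      stop("offset ", p@offset, " must anchor the first base of an exon; ",
           formatCpos(p), " does not")
    if (i < 2L)
      stop("no intron upstream of the first exon")
    if (k > introns[i - 1L])
      stop("offset ", p@offset, " walks past intron ", i - 1L,
           " (length ", introns[i - 1L], ") into the previous exon")
    gx <- tm@exons[ord[i]]
    if (tm@strand == "+") start(gx) - k else end(gx) + k
  }
}

#' Convert a genomic position to a coding position
#'
#' Exonic positions get offset 0. Intronic positions are assigned to
#' the nearer exon boundary: `+d` from the upstream (transcript sense)
#' exon up to and including the midpoint, `-d` beyond. For even-length
#' introns the two central bases take `+` and `-` respectively. Inverse
#' of [cToG()] over its whole range.
#'
#' @param tm a [TranscriptModel-class].
#' @param g 1-based genomic position within the transcript span.
#' @return A [CodingPosition-class].
#' @export
gToC <- function(tm, g) {
  stopifnot(is(tm, "TranscriptModel"), length(g) == 1L, !is.na(g))
  g <- as.integer(g)
  if (g < min(start(tm@exons)) || g > max(end(tm@exons)))
    stop("g.", g, " outside the transcript genomic span")
  t <- .g2t(tm, g)
  ends <- .txExonEnds(tm)
  if (!is.na(t)) {
    base <- t - tm@cdsStartC + 1L
    if (base < 1L || base > cdsLength(tm))
      stop("g.", g, " maps to a UTR position (unsupported)")
    return(codingPosition(base))
  }
  loc <- locateInIntron(tm, g)
  L <- .intronLengths(tm)[loc$intron]
  d <- loc$offset
  if (2L * d <= L + 1L) {
    codingPosition(loc$anchorBase, d)
  } else {
    nextFirst <- ends[loc$intron] + 1L - tm@cdsStartC + 1L
    codingPosition(nextFirst, -(L - d + 1L))
  }
}

#' Locate a genomic position inside an intron
#'
#' Returns the transcript-order intron index, the distance from the
#' upstream (transcript sense) exon boundary, and the CDS base of that
#' exon's final base (the anchor for `+` offsets). Unlike [gToC()] this
#' always reports the donor-side offset, regardless of the intron
#' midpoint; the pipeline uses it so a variant deep in a long intron
#' keeps its donor-anchored name.
#'
#' @param tm a [TranscriptModel-class].
#' @param g genomic position; must be intronic.
#' @return list with `intron`, `offset`, `anchorBase`.
#' @export
locateInIntron <- function(tm, g) {
  stopifnot(is(tm, "TranscriptModel"))
  g <- as.integer(g)
  if (!is.na(.g2t(tm, g))) stop("g.", g, " is exonic, not intronic")
  if (g < min(start(tm@exons)) || g > max(end(tm@exons)))
    stop("g.", g, " outside the transcript genomic span")
  ord <- .txOrder(tm)
  ends <- .txExonEnds(tm)
  gaps <- .intronLengths(tm)
  for (i in seq_len(length(ord) - 1L)) {
    up <- tm@exons[ord[i]]
    d <- if (tm@strand == "+") g - end(up) else start(up) - g
    if (d >= 1L && d <= gaps[i]) {
      return(list(intron = i, offset = d,
                  anchorBase = ends[i] - tm@cdsStartC + 1L))
    }
  }
  stop("g.", g, " not located in any intron")     # unreachable
}

#' Extract transcript-sense sequence between two coding positions
#'
#' The span is taken along the transcript-plus-intron order (contiguous
#' on the genome within the gene); on strand `-` the returned sequence
#' is the reverse complement of the plus-strand slice. Length always
#' equals the inclusive coordinate span.
#'
#' @param tm a [TranscriptModel-class] with a reference sequence.
#' @param from,to [CodingPosition-class] bounds, `from` not after `to`
#'   in transcript order.
#' @return A [Biostrings::DNAString].
#' @export
extractSequence <- function(tm, from, to) {
  if (is.null(tm@refseq))
    stop("no reference sequence attached to ", tm@transcriptId)
  gf <- cToG(tm, from)
  gt <- cToG(tm, to)
  if (tm@strand == "+") {
    if (gf > gt) stop("'from' follows 'to' in transcript order")
    subseq(tm@refseq, gf, gt)
  } else {
    if (gf < gt) stop("'from' follows 'to' in transcript order")
    reverseComplement(subseq(tm@refseq, gt, gf))
  }
}

#' Spliced CDS sequence of a transcript
#'
#' @param tm a [TranscriptModel-class] with a reference sequence.
#' @return A [Biostrings::DNAString] of length [cdsLength()].
#' @export
getCdsSequence <- function(tm) {
  if (is.null(tm@refseq))
    stop("no reference sequence attached to ", tm@transcriptId)
  pieces <- lapply(seq_along(tm@exons), function(i)
    subseq(tm@refseq, start(tm@exons)[i], end(tm@exons)[i]))
  spliced <- do.call(xscat, pieces)               # genomic left-to-right
  if (tm@strand == "-") spliced <- reverseComplement(spliced)
  subseq(spliced, tm@cdsStartC, tm@cdsEndC)
}

#' Transcript-sense sequence of one intron
#'
#' @param tm a [TranscriptModel-class] with a reference sequence.
#' @param intron transcript-order intron index (1 = between exon 1 and
#'   exon 2 of the mRNA).
#' @return A [Biostrings::DNAString].
#' @export
intronSequence <- function(tm, intron) {
  if (is.null(tm@refseq))
    stop("no reference sequence attached to ", tm@transcriptId)
  n <- length(tm@exons)
  stopifnot(intron >= 1L, intron <= n - 1L)
  ord <- .txOrder(tm)
  up <- tm@exons[ord[intron]]
  dn <- tm@exons[ord[intron + 1L]]
  if (tm@strand == "+") {
    subseq(tm@refseq, end(up) + 1L, start(dn) - 1L)
  } else {
    reverseComplement(subseq(tm@refseq, end(dn) + 1L, start(up) - 1L))
  }
}
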