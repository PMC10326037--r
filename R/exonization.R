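#' PseudoexonEvent: an intronic segment exonized between two exons
#'
#' Describes the inclusion of an intronic segment (pseudoexon) into the
#' mature transcript after activation of a cryptic acceptor (intronic
#' AG ending 1 nt before the first exonized base) and a cryptic donor
#' (intronic GT beginning 1 nt after the last exonized base). All
#' boundary positions are donor-side-anchored [CodingPosition-class]s
#' sharing the variant's intron: the base is the last CDS base of the
#' upstream exon and offsets count into the intron.
#'
#' @slot variant the intronic variant position.
#' @slot refAllele,altAllele transcript-sense variant alleles (may be
#'   `NA`).
#' @slot acceptorFirstBase first exonized base.
#' @slot donorLastBase last exonized base.
#' @slot insertedLength pseudoexon length in bp (inclusive span).
#' @slot insertedSequence transcript-sense pseudoexon sequence, or `NA`.
#' @slot insertionSite the flanking exonic CDS bases (anchor,
#'   anchor + 1).
#' @slot hgvsR HGVS RNA-level description, e.g.
#'   `"r.531_532ins531+1422_531+1477"`.
#' @slot frameRemainder `insertedLength mod 3`; non-zero means
#'   out-of-frame.
#' @slot proteinConsequence HGVS p. string once annotated, else `NA`.
#' @slot ptcTranscriptPos transcript coordinate (mutant transcript) of
#'   the first base of the premature termination codon, or `NA`.
#' @slot nmdPredicted 50-nt-rule prediction once annotated, else `NA`.
#'
#' @name PseudoexonEvent-class
#' @aliases PseudoexonEvent
#' @exportClass PseudoexonEvent
setClass("PseudoexonEvent",
  representation(
    variant = "CodingPosition",
    refAllele = "character", altAllele = "character",
    acceptorFirstBase = "CodingPosition",
    donorLastBase = "CodingPosition",
    insertedLength = "integer",
    insertedSequence = "character",
    insertionSite = "integer",
    hgvsR = "character",
    frameRemainder = "integer",
    proteinConsequence = "character",
    ptcTranscriptPos = "integer",
    nmdPredicted = "logical"))

setValidity("PseudoexonEvent", function(object) {
  a <- object@acceptorFirstBase; d <- object@donorLastBase
  if (a@base != d@base)
    return("acceptor and donor must share the same intron anchor base")
  if (a@offset < 1L || d@offset < 1L)
    return("pseudoexon boundaries must be intronic (offset >= 1)")
  if (a@offset > d@offset)
    return("acceptor must not lie downstream of the donor")
  if (object@insertedLength != d@offset - a@offset + 1L)
    return("insertedLength must equal the inclusive boundary span")
  if (object@frameRemainder != object@insertedLength %% 3L)
    return("frameRemainder must equal insertedLength mod 3")
  if (!is.na(object@insertedSequence) &&
      nchar(object@insertedSequence) != object@insertedLength)
    return("insertedSequence length must equal insertedLength")
  if (!identical(object@insertionSite,
                 c(a@base, a@base + 1L)))
    return("insertionSite must be the anchor base and its successor")
  TRUE
})

setMethod("show", "PseudoexonEvent", function(object) {
  cat("PseudoexonEvent ", object@hgvsR, "\n",
      "  ", object@insertedLength, " bp inserted between c.",
      object@insertionSite[1], " and c.", object@insertionSite[2],
      "; frame remainder ", object@frameRemainder,
      if (object@frameRemainder != 0L) " (out-of-frame)" else " (in-frame)",
      "\n", sep = "")
  if (!is.na(object@proteinConsequence))
    cat("  protein: ", object@proteinConsequence, "\n", sep = "")
  if (!is.na(object@nmdPredicted))
    cat("  NMD predicted: ", object@nmdPredicted, "\n", sep = "")
})

#' Define a pseudoexon from its activated splice boundaries
#'
#' The inserted length is the inclusive span between the first and last
#' exonized bases; the insertion site is the pair of exonic CDS bases
#' flanking the host intron; the frame remainder is length mod 3.
#'
#' @param variant intronic variant position ([CodingPosition-class] or
#'   HGVS string).
#' @param acceptorFirstBase,donorLastBase pseudoexon boundaries
#'   ([CodingPosition-class] or HGVS strings), in the variant's intron.
#' @param refAllele,altAllele optional transcript-sense alleles.
#' @param tm optional [TranscriptModel-class] with reference sequence;
#'   when given, the inserted sequence is extracted.
#' @return A [PseudoexonEvent-class].
#' @examples
#' definePseudoexon("c.531+1482", "c.531+1422", "c.531+1477")
#' @export
definePseudoexon <- function(variant, acceptorFirstBase, donorLastBase,
                             refAllele = NA_character_,
                             altAllele = NA_character_, tm = NULL) {
  asCpos <- function(x) if (is.character(x)) parseCpos(x) else x
  variant <- asCpos(variant)
  a <- asCpos(acceptorFirstBase)
  d <- asCpos(donorLastBase)
  if (a@base != d@base || variant@base != a@base)
    stop("variant, acceptor and donor must share one intron ",
         "(anchor bases ", variant@base, ", ", a@base, ", ", d@base, ")")
  if (a@offset < 1L || d@offset < 1L || variant@offset < 1L)
    stop("all three positions must be intronic (+offsets)")
  if (a@offset > d@offset)
    stop("inverted boundaries: acceptor +", a@offset,
         " lies downstream of donor +", d@offset)
  len <- d@offset - a@offset + 1L
  seqc <- NA_character_
  if (!is.null(tm) && !is.null(tm@refseq))
    seqc <- as.character(extractSequence(tm, a, d))
  ev <- new("PseudoexonEvent",
            variant = variant, refAllele = refAllele,
            altAllele = altAllele,
            acceptorFirstBase = a, donorLastBase = d,
            insertedLength = len, insertedSequence = seqc,
            insertionSite = c(a@base, a@base + 1L),
            hgvsR = "", frameRemainder = len %% 3L,
            proteinConsequence = NA_character_,
            ptcTranscriptPos = NA_integer_, nmdPredicted = NA)
  ev@hgvsR <- formatHgvsR(ev)
  ev
}

#' Distance from the variant to the new exon/intron boundary
#'
#' `variant offset - donor last-base offset`; positive when the variant
#' lies downstream (3'-ward) of the last exonized base, as in a variant
#' whose activated donor sits a few nucleotides upstream of it.
#'
#' @param variant,donorLastBase [CodingPosition-class]s (or HGVS
#'   strings) sharing an intron anchor.
#' @return Signed integer distance in nt.
#' @examples
#' variantToDonorDistance("c.531+1482", "c.531+1477")  # 5
#' @export
variantToDonorDistance <- function(variant, donorLastBase) {
  asCpos <- function(x) if (is.character(x)) parseCpos(x) else x
  v <- asCpos(variant); d <- asCpos(donorLastBase)
  if (v@base != d@base)
    stop("variant and donor anchor different introns (bases ",
         v@base, " vs ", d@base, ")")
  v@offset - d@offset
}

#' Format the HGVS r. description of a pseudoexon insertion
#'
#' `r.<a>_<a+1>ins<acceptor>_<donor>` with intronic offsets and no
#' whitespace.
#'
#' @param event a [PseudoexonEvent-class].
#' @return Character HGVS r. string.
#' @export
formatHgvsR <- function(event) {
  stopifnot(is(event, "PseudoexonEvent"))
  paste0("r.", event@insertionSite[1], "_", event@insertionSite[2],
         "ins", formatCpos(event@acceptorFirstBase, prefix = ""),
         "_", formatCpos(event@donorLastBase, prefix = ""))
}

#' Parse an HGVS r. pseudoexon-insertion description
#'
#' Inverse of [formatHgvsR()] over its range; whitespace is tolerated.
#'
#' @param text e.g. `"r.531_532ins531+1422_531+1477"`.
#' @return list with `insertionSite` (integer pair) and
#'   [CodingPosition-class]s `acceptorFirstBase`, `donorLastBase`.
#' @export
parseHgvsR <- function(text) {
  s <- gsub("[[:space:]]+", "", text)
  m <- regmatches(s, regexec(
    "^r\\.([0-9]+)_([0-9]+)ins([0-9+-]+)_([0-9+-]+)$", s))[[1L]]
  if (length(m) == 0L)
    stop("malformed r. insertion description: '", text, "'")
  site <- as.integer(m[2:3])
  if (site[2L] != site[1L] + 1L)
    stop("insertion site must be two consecutive bases: '", text, "'")
  list(insertionSite = site,
       acceptorFirstBase = parseCpos(paste0("c.", m[4])),
       donorLastBase = parseCpos(paste0("c.", m[5])))
}

#' Scan an intron for cryptic acceptor/donor pairs
#'
#' Donors are GT dinucleotides immediately 3' of a candidate last
#' exonized base within `window` nt of the predicted donor-gain
#' position; acceptors are AG dinucleotides immediately 5' of a
#' candidate first exonized base, upstream of the donor within
#' `window`. Pairs shorter than `minLength` are discarded. Pairs are
#' ranked by `|length - window/2|` ascending; on ties the acceptor
#' nearest the donor (shorter pseudoexon) comes first.
#'
#' @param intronSeq intron sequence in transcript sense
#'   ([Biostrings::DNAString] or character).
#' @param variantOffset 1-based intron offset of the predicted
#'   donor-gain position (typically the variant's offset).
#' @param window maximum search distance in nt (default 300).
#' @param minLength minimum pseudoexon length in nt (default 20).
#' @return data.frame with columns `acceptorFirst`, `donorLast`,
#'   `length`, ranked best first; zero rows when no donor GT (or no
#'   compatible acceptor AG) lies in the window.
#' @export
scanCrypticSites <- function(intronSeq, variantOffset, window = 300L,
                             minLength = 20L) {
  s <- toupper(as.character(intronSeq))
  L <- nchar(s)
  chars <- strsplit(s, "")[[1L]]
  di <- paste0(chars[-L], chars[-1L])             # dinucleotide starts
  gtStart <- which(di == "GT")
  agStart <- which(di == "AG")
  donors <- gtStart - 1L                          # last exonized base
  donors <- donors[donors >= 1L &
                   abs(donors - variantOffset) <= window]
  if (length(donors) == 0L) {
    message("no cryptic donor GT within ", window, " nt of offset ",
            variantOffset)
    return(data.frame(acceptorFirst = integer(), donorLast = integer(),
                      length = integer()))
  }
  acceptors <- agStart + 2L                       # first exonized base
  grid <- expand.grid(acceptorFirst = acceptors, donorLast = donors)
  grid$length <- grid$donorLast - grid$acceptorFirst + 1L
  grid <- grid[grid$length >= minLength & grid$length <= window, ,
               drop = FALSE]
  if (nrow(grid) == 0L) {
    message("no acceptor AG compatible with a donor GT in the window")
    return(data.frame(acceptorFirst = integer(), donorLast = integer(),
                      length = integer()))
  }
  grid <- grid[order(abs(grid$length - window / 2), grid$length), ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid[, c("acceptorFirst", "donorLast", "length")]
}

## 1->3 letter amino-acid code, stop rendered "*"
.aa3 <- function(aa) {
  code <- Biostrings::AMINO_ACID_CODE
  vapply(strsplit(aa, "")[[1L]], function(a)
    if (a == "*") "*" else unname(code[a]), character(1))
}

.translateCds <- function(dna) {
  n <- floor(length(dna) / 3L) * 3L
  as.character(suppressWarnings(
    translate(subseq(dna, 1L, n), if.fuzzy.codon = "X")))
}

#' Protein consequence of a pseudoexon insertion
#'
#' Splices the inserted sequence into the reference CDS between the
#' insertion-site bases, translates from codon 1 and reports the first
#' altered residue. Out-of-frame events yield
#' `p.(<Ref><codon><New>fs<k>*)` where `k` is the 1-based position of
#' the new stop counting the first altered residue as 1 (standard HGVS
#' fs semantics); in-frame insertions between codons yield
#' `p.(<Ref><i>_<Ref><i+1>ins<peptide>)`, or `p.(=)` when the protein
#' is unchanged. A shifted frame that reaches the transcript end
#' without a stop is reported as `noStop = TRUE`, not an error.
#'
#' @param tm a [TranscriptModel-class] with reference sequence.
#' @param event a [PseudoexonEvent-class] with an inserted sequence (it
#'   is extracted from `tm` if absent).
#' @return list with `consequence` (HGVS p. string),
#'   `firstAffectedCodon`, `ptcTranscriptPos` (mutant-transcript
#'   coordinate of the stop codon's first base, `NA` if none) and
#'   `noStop`.
#' @export
proteinConsequence <- function(tm, event) {
  stopifnot(is(tm, "TranscriptModel"), is(event, "PseudoexonEvent"))
  ins <- event@insertedSequence
  if (is.na(ins))
    ins <- as.character(extractSequence(tm, event@acceptorFirstBase,
                                        event@donorLastBase))
  cds <- getCdsSequence(tm)
  anchor <- event@insertionSite[1L]
  mut <- xscat(subseq(cds, 1L, anchor), DNAString(ins),
               subseq(cds, anchor + 1L, length(cds)))
  refP <- .translateCds(cds)
  mutP <- .translateCds(mut)
  refAA <- strsplit(refP, "")[[1L]]
  mutAA <- strsplit(mutP, "")[[1L]]
  ## truncate at the first stop (the reference stop ends refAA)
  cutAt <- function(x) {
    st <- which(x == "*")
    if (length(st)) x[seq_len(st[1L])] else x
  }
  refAA <- cutAt(refAA); mutAA <- cutAt(mutAA)
  n <- min(length(refAA), length(mutAA))
  diffIdx <- which(refAA[seq_len(n)] != mutAA[seq_len(n)])
  i <- if (length(diffIdx)) diffIdx[1L] else n + 1L
  ref3 <- function(k) .aa3(refAA[k])
  mut3 <- function(k) .aa3(mutAA[k])
  ptcPos <- NA_integer_
  noStop <- FALSE
  if (event@frameRemainder != 0L) {
    stopIdx <- which(mutAA == "*")
    if (length(stopIdx) == 0L) {
      noStop <- TRUE
      cons <- paste0("p.(", ref3(i), i, mut3(i), "fs*?)")
    } else {
      stopIdx <- stopIdx[1L]
      ptcPos <- tm@cdsStartC - 1L + (stopIdx - 1L) * 3L + 1L
      if (i > length(mutAA) || mutAA[i] == "*") {
        ## first altered codon is itself the stop
        i <- min(i, stopIdx)
        cons <- paste0("p.(", ref3(i), i, "*)")
      } else {
        k <- stopIdx - i + 1L
        cons <- paste0("p.(", ref3(i), i, mut3(i), "fs", k, "*)")
      }
    }
  } else {
    m <- event@insertedLength %/% 3L
    if (identical(refAA, mutAA) || m == 0L) {
      cons <- "p.(=)"
    } else {
      ## a non-identical in-frame insertion must differ at some j <= n
      j <- diffIdx[1L]
      if (mutAA[j] == "*") {
        ## the inserted segment itself introduces a stop
        ptcPos <- tm@cdsStartC - 1L + (j - 1L) * 3L + 1L
        cons <- paste0("p.(", ref3(j), j, "*)")
      } else {
        pep <- paste(vapply(seq(j, min(j + m - 1L, length(mutAA))),
                            function(k) mut3(k), character(1)),
                     collapse = "")
        left <- if (j > 1L) paste0(ref3(j - 1L), j - 1L) else "?0"
        cons <- paste0("p.(", left, "_", ref3(j), j, "ins", pep, ")")
        inWin <- mutAA[seq(j, min(j + m - 1L, length(mutAA)))]
        if (any(inWin == "*")) {
          stopIdx <- which(mutAA == "*")[1L]
          ptcPos <- tm@cdsStartC - 1L + (stopIdx - 1L) * 3L + 1L
        }
      }
    }
  }
  list(consequence = cons, firstAffectedCodon = as.integer(min(i, n + 1L)),
       ptcTranscriptPos = ptcPos, noStop = noStop)
}

#' Exon-exon junction positions of the mutant (pseudoexon) transcript
#'
#' Transcript coordinates (mutant transcript) of the last base of each
#' exon except the final one, with the pseudoexon included as its own
#' exon after the anchor exon.
#'
#' @param tm a [TranscriptModel-class].
#' @param event a [PseudoexonEvent-class]; its anchor base must be the
#'   final CDS base of an exon.
#' @return Increasing integer vector of junction positions.
#' @export
pseudoexonJunctions <- function(tm, event) {
  ends <- .txExonEnds(tm)
  anchorT <- tm@cdsStartC + event@insertionSite[1L] - 1L
  i <- match(anchorT, ends)
  if (is.na(i))
    stop("insertion anchor c.", event@insertionSite[1L],
         " is not the final base of an exon")
  len <- event@insertedLength
  newEnds <- c(ends[seq_len(i)], anchorT + len,
               if (i < length(ends)) ends[seq(i + 1L, length(ends))] + len)
  newEnds[-length(newEnds)]
}

#' Predict nonsense-mediated decay by the 50-nt rule
#'
#' `TRUE` iff the premature termination codon lies at least
#' `threshold` nt (default 50) upstream of the last exon-exon junction
#' of the mutant transcript.
#'
#' @param ptcTranscriptPos mutant-transcript coordinate of the PTC
#'   (first base of the stop codon).
#' @param junctions mutant-transcript junction positions (must include
#'   the pseudoexon's new junctions); see [pseudoexonJunctions()].
#' @param threshold rule distance in nt.
#' @return logical.
#' @export
nmdPredict <- function(ptcTranscriptPos, junctions, threshold = 50L) {
  if (length(junctions) == 0L)
    stop("junction list must not be empty")
  stopifnot(length(ptcTranscriptPos) == 1L, !is.na(ptcTranscriptPos))
  max(junctions) - ptcTranscriptPos >= threshold
}

#' Write pseudoexon events as JSON lines (plus optional BED)
#'
#' One JSON object per event with all descriptive fields; when a
#' transcript model is given, a BED line with the pseudoexon's genomic
#' interval is written alongside.
#'
#' @param events list of [PseudoexonEvent-class].
#' @param path output JSON-lines path.
#' @param tm optional [TranscriptModel-class] for the BED companion
#'   (`paste0(path, ".bed")`).
#' @return `path`, invisibly.
#' @export
writeEventJson <- function(events, path, tm = NULL) {
  if (is(events, "PseudoexonEvent")) events <- list(events)
  lines <- vapply(events, function(e) {
    jsonlite::toJSON(list(
      variant = formatCpos(e@variant), ref = e@refAllele,
      alt = e@altAllele,
      acceptorFirstBase = formatCpos(e@acceptorFirstBase),
      donorLastBase = formatCpos(e@donorLastBase),
      insertedLength = e@insertedLength,
      insertedSequence = e@insertedSequence,
      insertionSite = e@insertionSite, hgvsR = e@hgvsR,
      frameRemainder = e@frameRemainder,
      proteinConsequence = e@proteinConsequence,
      ptcTranscriptPos = e@ptcTranscriptPos,
      nmdPredicted = e@nmdPredicted), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(tm)) {
    bed <- vapply(events, function(e) {
      g1 <- cToG(tm, e@acceptorFirstBase)
      g2 <- cToG(tm, e@donorLastBase)
      lo <- min(g1, g2); hi <- max(g1, g2)
      paste(tm@chrom, lo - 1L, hi, paste0("pseudoexon_", e@hgvsR), 0,
            tm@strand, sep = "\t")
    }, character(1))
    writeLines(bed, paste0(path, ".bed"))
  }
  invisible(path)
}
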