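#' PeakSet: allele-assigned electropherogram peak quantities at a locus
#'
#' Peak areas (or heights; the two are accepted interchangeably) in
#' arbitrary fluorescence units for the alleles of one marker on one
#' template (cDNA or gDNA). Heteroduplex bands are not allele-assigned
#' and never enter a PeakSet.
#'
#' @slot locus marker identifier.
#' @slot template `"cDNA"` or `"gDNA"`.
#' @slot areas named non-negative numeric vector, one entry per allele.
#'
#' @name PeakSet-class
#' @aliases PeakSet
#' @exportClass PeakSet
setClass("PeakSet",
  representation(locus = "character", template = "character",
                 areas = "numeric"))

setValidity("PeakSet", function(object) {
  if (!object@template %in% c("cDNA", "gDNA"))
    return("template must be 'cDNA' or 'gDNA'")
  if (length(object@areas) < 2L)
    return("an informative locus needs >= 2 allele peaks")
  if (is.null(names(object@areas)) || any(!nzchar(names(object@areas))))
    return("areas must be named by allele")
  if (any(!is.finite(object@areas)) || any(object@areas < 0))
    return("areas must be finite and non-negative")
  TRUE
})

#' Construct a PeakSet
#'
#' @param locus marker identifier.
#' @param template `"cDNA"` or `"gDNA"`.
#' @param areas named numeric vector of allele peak areas/heights.
#' @return A [PeakSet-class].
#' @examples
#' peakSet("rsX", "cDNA", c(T = 1200, C = 640))
#' @export
peakSet <- function(locus, template, areas) {
  new("PeakSet", locus = locus, template = template,
      areas = setNames(as.numeric(areas), names(areas)))
}

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet ", object@locus, " [", object@template, "]: ",
      paste(names(object@areas), signif(object@areas, 4), sep = "=",
            collapse = ", "), "\n", sep = "")
})

#' Allelic-imbalance ratio from cDNA and gDNA peaks
#'
#' The gDNA-normalized ratio of ratios
#' `(alt/ref)_cDNA / (alt/ref)_gDNA`. 1.0 means balanced expression of
#' the two alleles; values below 1 mean the alt-bearing transcript is
#' depleted (e.g. degraded by NMD). The gDNA ratio corrects for
#' locus-specific amplification and dye effects.
#'
#' @param cdna,gdna [PeakSet-class]s for the same locus, templates
#'   `"cDNA"` and `"gDNA"`; both alleles must have area > 0 in gDNA.
#' @param refAllele,altAllele allele names; default the first and
#'   second allele of the cDNA set.
#' @return Non-negative ratio; 0 (with a warning) when the cDNA alt
#'   peak is absent.
#' @examples
#' allelicImbalance(peakSet("m", "cDNA", c(A = 10, G = 5)),
#'                  peakSet("m", "gDNA", c(A = 10, G = 10)))  # 0.5
#' @export
allelicImbalance <- function(cdna, gdna,
                             refAllele = names(cdna@areas)[1L],
                             altAllele = names(cdna@areas)[2L]) {
  stopifnot(is(cdna, "PeakSet"), is(gdna, "PeakSet"))
  if (cdna@locus != gdna@locus)
    stop("peak sets describe different loci: ", cdna@locus, " vs ",
         gdna@locus)
  if (cdna@template != "cDNA" || gdna@template != "gDNA")
    stop("expected a cDNA and a gDNA peak set, in that order")
  pick <- function(ps, allele) {
    if (!allele %in% names(ps@areas))
      stop("allele '", allele, "' absent from the ", ps@template,
           " peak set at ", ps@locus)
    unname(ps@areas[allele])
  }
  gr <- pick(gdna, refAllele); ga <- pick(gdna, altAllele)
  if (gr <= 0 || ga <= 0)
    stop("gDNA areas must be positive for both alleles at ", gdna@locus)
  cr <- pick(cdna, refAllele); ca <- pick(cdna, altAllele)
  if (cr <= 0)
    stop("undefined ratio: cDNA reference peak is zero at ", cdna@locus)
  if (ca == 0) {
    warning("cDNA alt peak is zero at ", cdna@locus,
            "; ratio reported as 0 (complete allele loss)")
    return(0)
  }
  (ca / cr) / (ga / gr)
}

#' Classify an allelic-imbalance ratio
#'
#' Imbalanced iff `ratio < threshold` or `ratio > 1/threshold`
#' (strict). The default threshold 0.8 calls a transcript reduced "by
#' about half" (ratios near 0.5) imbalanced with margin.
#'
#' @param ratio non-negative ratio from [allelicImbalance()].
#' @param threshold lower bound for balance, in (0, 1].
#' @return `"balanced"` or `"imbalanced"`.
#' @export
classifyImbalance <- function(ratio, threshold = 0.8) {
  stopifnot(ratio >= 0, threshold > 0, threshold <= 1)
  if (ratio < threshold || ratio > 1 / threshold) "imbalanced"
  else "balanced"
}

#' Completeness-of-aberrant-splicing test from tagging SNPs
#'
#' Interprets tagging observations from an RT-PCR amplicon selective
#' for the wild-type (normal-length) transcript. If every
#' gDNA-heterozygous marker shows exactly one allele in that amplicon
#' (and, when the expected wild-type-haplotype alleles are supplied,
#' the observed allele agrees with them), the aberrant splicing is
#' complete: the normal transcript comes from one allele only. Any het
#' marker showing both alleles means incomplete; no het markers means
#' uninformative.
#'
#' @param observations data.frame with columns `marker`,
#'   `gdnaGenotype` (`"het"`, `"hom_ref"`, `"hom_alt"`) and `observed`
#'   (alleles seen in the wild-type-selective amplicon; character,
#'   comma-separated for several, or a list column).
#' @param phase optional named character vector mapping marker to the
#'   allele expected on the wild-type haplotype; enables the phase
#'   agreement check.
#' @return `"complete"`, `"incomplete"` or `"uninformative"`.
#' @export
completenessTest <- function(observations, phase = NULL) {
  stopifnot(all(c("marker", "gdnaGenotype", "observed") %in%
                names(observations)))
  obsList <- if (is.list(observations$observed)) observations$observed
             else strsplit(as.character(observations$observed), ",[ ]*")
  if (any(lengths(obsList) == 0L))
    stop("each observation must list at least one observed allele")
  het <- observations$gdnaGenotype == "het"
  if (!any(het)) return("uninformative")
  hetObs <- obsList[het]
  if (any(lengths(hetObs) > 1L)) return("incomplete")
  if (!is.null(phase)) {
    markers <- observations$marker[het]
    expected <- phase[markers]
    seen <- vapply(hetObs, `[[`, character(1), 1L)
    if (any(!is.na(expected) & expected != seen)) return("incomplete")
  }
  "complete"
}

#' Predicted RT-PCR amplicon lengths per transcript isoform
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer in each spliced transcript sequence and reports the spanned
#' length. Transcripts in which a primer does not map yield `NA`
#' (no product) - the basis of isoform-selective amplification. When
#' both primers flank a pseudoexon insertion, the aberrant-minus-normal
#' length difference equals the pseudoexon length.
#'
#' @param transcripts a named [Biostrings::DNAStringSet] (or named
#'   character vector) of spliced transcript sequences.
#' @param forwardPrimer,reversePrimer primer sequences, 5'->3'; the
#'   reverse primer is given on the opposite strand as usual.
#' @return Named integer vector of product lengths, `NA` = no product.
#' @export
predictAmpliconLengths <- function(transcripts, forwardPrimer,
                                   reversePrimer) {
  if (is.character(transcripts)) transcripts <- DNAStringSet(transcripts)
  fwd <- DNAString(as.character(forwardPrimer))
  rev <- reverseComplement(DNAString(as.character(reversePrimer)))
  vapply(seq_along(transcripts), function(i) {
    s <- transcripts[[i]]
    mf <- matchPattern(fwd, s)
    mr <- matchPattern(rev, s)
    if (length(mf) == 0L || length(mr) == 0L) return(NA_integer_)
    len <- end(mr)[length(mr)] - start(mf)[1L] + 1L
    if (len < length(fwd)) NA_integer_ else as.integer(len)
  }, integer(1), USE.NAMES = FALSE) |>
    setNames(names(transcripts))
}

#' Read a tab-separated peak table
#'
#' Columns: `locus`, `template`, `allele`, `area` (an optional
#' `replicate` column is preserved).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPeakTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "template", "allele", "area")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' Write a peak table as TSV
#'
#' @param d data.frame with `locus`, `template`, `allele`, `area`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a PeakSet from peak-table rows
#'
#' @param d a peak table (see [readPeakTable()]).
#' @param locus,template the subset to extract.
#' @return A [PeakSet-class].
#' @export
peakSetFromTable <- function(d, locus, template) {
  sub <- d[d$locus == locus & d$template == template, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no rows for locus '", locus, "' template '", template, "'")
  peakSet(locus, template, setNames(sub$area, sub$allele))
}

#' Read tagging observations from TSV
#'
#' Columns: `marker`, `gdnaGenotype`, `observed` (comma-separated
#' allele set).
#'
#' @param path TSV file.
#' @return data.frame suitable for [completenessTest()].
#' @export
readTaggingTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "gdnaGenotype", "observed")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("tagging table lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' Write tagging observations as TSV
#'
#' @param d data.frame with `marker`, `gdnaGenotype`, `observed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaggingTable <- function(d, path) {
  if (is.list(d$observed))
    d$observed <- vapply(d$observed, paste, character(1), collapse = ",")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
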