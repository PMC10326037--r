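#' Default point weights for the ACMG criteria used here
#'
#' The evidence scheme is deliberately small: exactly the five criteria
#' with integer weights PVS1 = 8 and PM2 = PP1 = PP3 = PP4 = 1, summed
#' against a pathogenicity threshold of 10. Criteria outside this set
#' carry no invented default weight and must be given one explicitly.
#'
#' @return Named integer vector of weights.
#' @export
acmgDefaultWeights <- function() {
  c(PVS1 = 8L, PM2 = 1L, PP1 = 1L, PP3 = 1L, PP4 = 1L)
}

#' AcmgEvidence: asserted criteria with point weights
#'
#' @slot criteria named integer vector mapping each asserted criterion
#'   code to its positive weight.
#' @slot threshold total score at or above which pathogenicity is
#'   asserted (default 10).
#' @slot notEvaluable criterion codes that could not be evaluated for
#'   lack of upstream results (informational).
#'
#' @name AcmgEvidence-class
#' @aliases AcmgEvidence
#' @exportClass AcmgEvidence
setClass("AcmgEvidence",
  representation(criteria = "integer", threshold = "integer",
                 notEvaluable = "character"))

setValidity("AcmgEvidence", function(object) {
  cr <- object@criteria
  if (length(cr) > 0L) {
    if (is.null(names(cr)) || any(!nzchar(names(cr))))
      return("criteria must be named by code")
    if (anyDuplicated(names(cr)))
      return("criterion codes must be unique")
    if (any(is.na(cr)) || any(cr <= 0L))
      return("weights must be positive integers")
  }
  if (object@threshold < 1L) return("threshold must be positive")
  TRUE
})

#' Assemble ACMG evidence
#'
#' @param criteria character vector of asserted criterion codes.
#' @param weights named integer vector of weights; any asserted
#'   criterion without a weight is an error - no silent defaults.
#' @param threshold pathogenicity threshold (default 10).
#' @param notEvaluable codes recorded as not evaluable.
#' @return An [AcmgEvidence-class].
#' @examples
#' ev <- acmgEvidence(c("PVS1", "PM2", "PP1", "PP3", "PP4"))
#' totalScore(ev)       # 12
#' classifyEvidence(ev) # "pathogenic"
#' @export
acmgEvidence <- function(criteria = character(),
                         weights = acmgDefaultWeights(),
                         threshold = 10L,
                         notEvaluable = character()) {
  criteria <- unique(as.character(criteria))
  unknown <- setdiff(criteria, names(weights))
  if (length(unknown))
    stop("no weight defined for criterion: ",
         paste(unknown, collapse = ", "))
  new("AcmgEvidence",
      criteria = setNames(as.integer(weights[criteria]), criteria),
      threshold = as.integer(threshold),
      notEvaluable = as.character(notEvaluable))
}

setMethod("show", "AcmgEvidence", function(object) {
  cat("AcmgEvidence: ",
      if (length(object@criteria) == 0L) "(none)" else
        paste(names(object@criteria), " (+", object@criteria, ")",
              sep = "", collapse = ", "),
      "\n  total ", totalScore(object), " vs threshold >= ",
      object@threshold, " -> ", classifyEvidence(object), "\n", sep = "")
  if (length(object@notEvaluable))
    cat("  not evaluable: ", paste(object@notEvaluable, collapse = ", "),
        "\n", sep = "")
})

#' Summed evidence score
#'
#' @param evidence an [AcmgEvidence-class].
#' @return Integer sum of the asserted criteria's weights.
#' @export
totalScore <- function(evidence) {
  stopifnot(is(evidence, "AcmgEvidence"))
  sum(evidence@criteria)
}

#' Classify summed evidence
#'
#' `"pathogenic"` iff the total score reaches the threshold
#' (inclusive); everything below is reported as `"not_demonstrated"` -
#' this scheme has no benign-side evidence and therefore no
#' intermediate classes.
#'
#' @param evidence an [AcmgEvidence-class].
#' @return `"pathogenic"` or `"not_demonstrated"`.
#' @export
classifyEvidence <- function(evidence) {
  stopifnot(is(evidence, "AcmgEvidence"))
  if (totalScore(evidence) >= evidence@threshold) "pathogenic"
  else "not_demonstrated"
}

#' Assert criteria automatically from pipeline results
#'
#' Rule table: PM2 when the population AF is absent or 0 (novel
#' variant); PP3 when the maximum splice delta score exceeds the gate;
#' PVS1 when the pseudoexon is out-of-frame AND the aberrant splicing
#' is complete AND NMD is predicted (the loss-of-function argument
#' requires all three); PP1 (co-segregation) and PP4 (specific
#' phenotype) only from explicit user flags, never automatically.
#' Inputs that are missing (`NA`/`NULL`) leave the affected criterion
#' unasserted and record it as not evaluable.
#'
#' @param populationAf population allele frequency (`NA` = absent).
#' @param spliceScoreMax maximum splice delta score (`NA` = unscored).
#' @param frameRemainder pseudoexon length mod 3, or `NA`.
#' @param completeness `"complete"`, `"incomplete"`,
#'   `"uninformative"` or `NA`.
#' @param nmdPredicted logical or `NA`.
#' @param segregation user flag: variant co-segregates with disease.
#' @param phenotypeMatch user flag: phenotype specific for the gene.
#' @param spliceGate splice-score gate for PP3 (default 0.2).
#' @param weights,threshold see [acmgEvidence()].
#' @return An [AcmgEvidence-class].
#' @export
autoAssert <- function(populationAf = NA_real_,
                       spliceScoreMax = NA_real_,
                       frameRemainder = NA_integer_,
                       completeness = NA_character_,
                       nmdPredicted = NA,
                       segregation = FALSE, phenotypeMatch = FALSE,
                       spliceGate = 0.2,
                       weights = acmgDefaultWeights(),
                       threshold = 10L) {
  asserted <- character()
  notEval <- character()
  if (is.null(populationAf) || is.na(populationAf) || populationAf == 0)
    asserted <- c(asserted, "PM2")
  if (is.null(spliceScoreMax) || is.na(spliceScoreMax)) {
    notEval <- c(notEval, "PP3")
  } else if (spliceScoreMax > spliceGate) {
    asserted <- c(asserted, "PP3")
  }
  frameKnown <- !is.null(frameRemainder) && !is.na(frameRemainder)
  if (frameKnown && frameRemainder == 0L) {
    ## in-frame: PVS1 withheld on the merits, evaluable
  } else if (!frameKnown || is.null(completeness) || is.na(completeness) ||
             is.null(nmdPredicted) || is.na(nmdPredicted)) {
    notEval <- c(notEval, "PVS1")
  } else if (frameRemainder != 0L && completeness == "complete" &&
             isTRUE(nmdPredicted)) {
    asserted <- c(asserted, "PVS1")
  }
  if (isTRUE(segregation)) asserted <- c(asserted, "PP1")
  if (isTRUE(phenotypeMatch)) asserted <- c(asserted, "PP4")
  acmgEvidence(asserted, weights = weights, threshold = threshold,
               notEvaluable = notEval)
}

#' Serialize evidence to JSON
#'
#' `{"criteria": {...}, "total": n, "class": "...", "not_evaluable":
#' [...]}`, the interchange form.
#'
#' @param evidence an [AcmgEvidence-class].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
evidenceToJson <- function(evidence, path = NULL) {
  x <- list(criteria = as.list(evidence@criteria),
            total = totalScore(evidence),
            class = classifyEvidence(evidence),
            not_evaluable = evidence@notEvaluable)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read evidence from JSON
#'
#' @param path file or JSON string from [evidenceToJson()].
#' @param threshold pathogenicity threshold to apply.
#' @return An [AcmgEvidence-class].
#' @export
evidenceFromJson <- function(path, threshold = 10L) {
  x <- jsonlite::fromJSON(path)
  w <- unlist(x$criteria)
  acmgEvidence(names(w), weights = setNames(as.integer(w), names(w)),
               threshold = threshold,
               notEvaluable = as.character(x$not_evaluable %||% character()))
}
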