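#' FilterConfig: thresholds for carrier-aware variant prioritization
#'
#' Defaults follow conventional germline short-variant heuristics
#' (depth >= 20, alt reads >= 5, heterozygous allele fraction in
#' 0.2..0.8), a rare-variant gate of population AF < 0.01 and a splice
#' delta-score gate of > 0.2. All are overridable; none is hidden.
#'
#' @slot minDp minimum position depth in the affected sample.
#' @slot minAdAlt minimum alt allele depth in the affected sample.
#' @slot vfRange closed interval for the affected-sample variant allele
#'   fraction.
#' @slot genePanel non-empty character vector of panel gene symbols
#'   (case-sensitive exact match).
#' @slot maxAf population-frequency cut-off; variants kept when
#'   AF < maxAf (strict); missing AF counts as novel (AF 0).
#' @slot spliceScoreMin splice gate; kept when max delta > this
#'   (strict); unscored variants dropped.
#'
#' @name FilterConfig-class
#' @aliases FilterConfig
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(minDp = "integer", minAdAlt = "integer",
                 vfRange = "numeric", genePanel = "character",
                 maxAf = "numeric", spliceScoreMin = "numeric"))

setValidity("FilterConfig", function(object) {
  if (object@minDp < 0L || object@minAdAlt < 0L)
    return("thresholds must be non-negative")
  if (length(object@vfRange) != 2L || any(object@vfRange < 0) ||
      any(object@vfRange > 1) || object@vfRange[1] > object@vfRange[2])
    return("vfRange must be an interval within [0, 1]")
  if (length(object@genePanel) == 0L)
    return("genePanel must be non-empty")
  if (object@maxAf <= 0 || object@maxAf > 1)
    return("maxAf must be in (0, 1]")
  if (object@spliceScoreMin < 0 || object@spliceScoreMin > 1)
    return("spliceScoreMin must be in [0, 1]")
  TRUE
})

#' Construct a FilterConfig
#'
#' @param genePanel character vector of panel gene symbols (required).
#' @param minDp,minAdAlt,vfRange,maxAf,spliceScoreMin see
#'   [FilterConfig-class].
#' @return A [FilterConfig-class].
#' @examples
#' filterConfig(genePanel = c("APC", "MUTYH"))
#' @export
filterConfig <- function(genePanel, minDp = 20L, minAdAlt = 5L,
                         vfRange = c(0.2, 0.8), maxAf = 0.01,
                         spliceScoreMin = 0.2) {
  new("FilterConfig", minDp = as.integer(minDp),
      minAdAlt = as.integer(minAdAlt), vfRange = as.numeric(vfRange),
      genePanel = as.character(genePanel), maxAf = maxAf,
      spliceScoreMin = spliceScoreMin)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: DP >= ", object@minDp, ", alt AD >= ",
      object@minAdAlt, ", VF in [", object@vfRange[1], ", ",
      object@vfRange[2], "], panel {",
      paste(object@genePanel, collapse = ", "), "}, AF < ",
      object@maxAf, ", splice delta > ", object@spliceScoreMin,
      "\n", sep = "")
})

.checkVariantTable <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "af", "spliceMax",
            "gtAffected", "gtUnaffected", "dp", "adRef", "adAlt", "vf")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(variants)
}

#' Quality gate on the affected sample
#'
#' Keeps variants with depth, alt allele depth and variant allele
#' fraction inside the configured bounds; a missing value fails the
#' gate.
#'
#' @param variants a variant table as returned by [readDuoVcf()].
#' @param cfg a [FilterConfig-class].
#' @return The surviving rows of `variants`.
#' @export
filterQuality <- function(variants, cfg) {
  .checkVariantTable(variants)
  keep <- !is.na(variants$dp) & variants$dp >= cfg@minDp &
    !is.na(variants$adAlt) & variants$adAlt >= cfg@minAdAlt &
    !is.na(variants$vf) & variants$vf >= cfg@vfRange[1] &
    variants$vf <= cfg@vfRange[2]
  variants[keep, , drop = FALSE]
}

#' Gene-panel restriction
#'
#' Case-sensitive exact match of the gene annotation against the panel;
#' unannotated variants are dropped. An empty panel is a configuration
#' error, not an empty result.
#'
#' @param variants a variant table.
#' @param genePanel character vector of gene symbols.
#' @return The surviving rows of `variants`.
#' @export
filterPanel <- function(variants, genePanel) {
  .checkVariantTable(variants)
  if (length(genePanel) == 0L) stop("gene panel must not be empty")
  keep <- !is.na(variants$gene) & variants$gene %in% genePanel
  variants[keep, , drop = FALSE]
}

#' Population-frequency filter
#'
#' Keeps variants with population AF strictly below `maxAf`. Variants
#' without an AF annotation are treated as novel (AF 0) and kept.
#'
#' @param variants a variant table.
#' @param maxAf frequency cut-off in (0, 1].
#' @return The surviving rows of `variants`.
#' @export
filterFrequency <- function(variants, maxAf = 0.01) {
  .checkVariantTable(variants)
  stopifnot(maxAf > 0, maxAf <= 1)
  keep <- is.na(variants$af) | variants$af < maxAf
  variants[keep, , drop = FALSE]
}

#' Affected-only (duo) filter
#'
#' Keeps variants carried by the affected sample (het or hom alt) and
#' absent (hom ref) in the unaffected relative. A missing unaffected
#' genotype cannot discriminate; such variants are dropped and counted
#' in the `"indeterminate"` attribute of the result.
#'
#' @param variants a variant table.
#' @return Surviving rows, with `attr(, "indeterminate")` holding the
#'   number of rows dropped for a missing unaffected genotype.
#' @export
filterDuo <- function(variants) {
  .checkVariantTable(variants)
  carrier <- variants$gtAffected %in% c("het", "hom_alt")
  indet <- carrier & variants$gtUnaffected == "missing"
  keep <- carrier & variants$gtUnaffected == "hom_ref"
  out <- variants[keep, , drop = FALSE]
  attr(out, "indeterminate") <- sum(indet)
  out
}

#' Splice delta-score gate
#'
#' Keeps variants whose maximum splice delta score is strictly greater
#' than `spliceScoreMin`; unscored variants are dropped.
#'
#' @param variants a variant table.
#' @param spliceScoreMin gate value (default 0.2).
#' @return The surviving rows of `variants`.
#' @export
filterSpliceScore <- function(variants, spliceScoreMin = 0.2) {
  .checkVariantTable(variants)
  keep <- !is.na(variants$spliceMax) & variants$spliceMax > spliceScoreMin
  variants[keep, , drop = FALSE]
}

#' PrioritizationReport: per-stage funnel counts plus final candidates
#'
#' @slot stages data.frame with columns `stage` and `surviving`
#'   (non-increasing).
#' @slot candidates the final variant table, sorted by descending
#'   maximum splice delta score.
#' @slot indeterminate number of variants dropped at the duo stage for
#'   a missing unaffected genotype.
#'
#' @name PrioritizationReport-class
#' @aliases PrioritizationReport
#' @exportClass PrioritizationReport
setClass("PrioritizationReport",
  representation(stages = "data.frame", candidates = "data.frame",
                 indeterminate = "integer"))

setMethod("show", "PrioritizationReport", function(object) {
  cat("PrioritizationReport\n")
  for (i in seq_len(nrow(object@stages)))
    cat(sprintf("  %-10s %6d\n", object@stages$stage[i],
                object@stages$surviving[i]))
  if (object@indeterminate > 0L)
    cat("  (", object@indeterminate,
        " carrier variant(s) indeterminate: unaffected genotype missing)\n",
        sep = "")
  cat("  final candidates: ", nrow(object@candidates), "\n", sep = "")
})

#' @describeIn runPrioritization Stage/survivor funnel as a data.frame.
#' @param report a [PrioritizationReport-class].
#' @export
stageCounts <- function(report) report@stages

#' @describeIn runPrioritization Final candidate table.
#' @export
candidates <- function(report) report@candidates

#' Run the full prioritization funnel
#'
#' Applies quality, gene-panel, population-frequency, duo and
#' splice-score filters in that order and records each stage's survivor
#' count. The filters are independent predicates, so the final set does
#' not depend on their order; only the per-stage counts do.
#'
#' @param variants a variant table from [readDuoVcf()].
#' @param cfg a [FilterConfig-class].
#' @return A [PrioritizationReport-class]; candidates are sorted by
#'   descending maximum splice delta score.
#' @export
runPrioritization <- function(variants, cfg) {
  stopifnot(is(cfg, "FilterConfig"))
  .checkVariantTable(variants)
  stages <- data.frame(stage = "input", surviving = nrow(variants))
  v <- filterQuality(variants, cfg)
  stages <- rbind(stages, data.frame(stage = "quality", surviving = nrow(v)))
  v <- filterPanel(v, cfg@genePanel)
  stages <- rbind(stages, data.frame(stage = "panel", surviving = nrow(v)))
  v <- filterFrequency(v, cfg@maxAf)
  stages <- rbind(stages, data.frame(stage = "frequency", surviving = nrow(v)))
  v <- filterDuo(v)
  indet <- attr(v, "indeterminate")
  stages <- rbind(stages, data.frame(stage = "duo", surviving = nrow(v)))
  v <- filterSpliceScore(v, cfg@spliceScoreMin)
  stages <- rbind(stages, data.frame(stage = "splice", surviving = nrow(v)))
  v <- v[order(-v$spliceMax), , drop = FALSE]
  rownames(v) <- NULL
  new("PrioritizationReport", stages = stages, candidates = v,
      indeterminate = as.integer(indet))
}

#' Write the stage-count funnel as a tab-separated report
#'
#' @param report a [PrioritizationReport-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeStageReport <- function(report, path) {
  write.table(report@stages, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
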