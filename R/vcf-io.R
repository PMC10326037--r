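## VCF input for the duo pipeline. Parsing is delegated to
## VariantAnnotation::readVcf; this layer splits multi-allelic records
## into one row per alt allele (re-pairing AD and re-reading GT against
## that alt) and flattens the annotations the filters consume.

## classify a GT string ("0/1", "1|1", "./.") relative to alt index k
.classifyGt <- function(gt, k, where) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (length(alleles) == 0L || any(!grepl("^[0-9.]+$", alleles)))
    stop("malformed GT '", gt, "' at ", where)
  if (any(alleles == ".")) return("missing")
  hits <- sum(alleles == as.character(k))
  if (hits == 2L) "hom_alt" else if (hits == 1L) "het" else "hom_ref"
}

## max splice delta score from pipe-delimited annotation entries
## (ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|POS..); entries matching the alt
## allele are preferred, otherwise all entries are pooled
.spliceMax <- function(entries, alt) {
  if (length(entries) == 0L) return(NA_real_)
  parse1 <- function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1L]]
    if (length(f) < 6L) return(c(allele = NA, max = NA_real_))
    ds <- suppressWarnings(as.numeric(f[3:6]))
    c(allele = f[1L], max = suppressWarnings(max(ds, na.rm = TRUE)))
  }
  parsed <- lapply(entries, parse1)
  alleles <- vapply(parsed, function(p) as.character(p[["allele"]]),
                    character(1))
  vals <- vapply(parsed, function(p) as.numeric(p[["max"]]), numeric(1))
  matched <- vals[!is.na(alleles) & alleles == alt]
  pool <- if (length(matched)) matched else vals
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) NA_real_ else max(pool)
}

#' Read an annotated duo VCF into a per-alt variant table
#'
#' Reads a VCF v4.2 subset (FORMAT `GT:DP:AD`; INFO keys for gene,
#' population AF and splice delta scores) with
#' [VariantAnnotation::readVcf()], splits multi-allelic records into
#' one row per alt allele (AD re-paired, genotypes re-read against that
#' alt), and binds the affected/unaffected genotypes plus the
#' affected-sample quality metrics the prioritization filters use. The
#' variant allele fraction `vf` is derived as alt AD / DP.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param affected,unaffected sample names in the VCF header.
#' @param spliceKey,geneKey,afKey INFO keys for the splice delta
#'   annotation, gene symbol and population allele frequency.
#' @return A data.frame with one row per (record, alt) and columns
#'   `chrom, pos, id, ref, alt, gene, af, spliceMax, gtAffected,
#'   gtUnaffected, dp, adRef, adAlt, vf, srcRow, altIndex`. The
#'   underlying `VCF` object is kept in `attr(, "vcf")` for
#'   [writeFilteredVcf()].
#' @export
readDuoVcf <- function(path, affected, unaffected,
                       spliceKey = "SPLICEAI", geneKey = "GENE",
                       afKey = "AF") {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(v)
  miss <- setdiff(c(affected, unaffected), samples)
  if (length(miss))
    stop("sample(s) not in VCF header: ", paste(miss, collapse = ", "))
  g <- VariantAnnotation::geno(v)
  if (!"GT" %in% names(g)) stop("VCF lacks FORMAT/GT: ", path)
  gt <- g$GT
  dp <- if ("DP" %in% names(g)) g$DP else
    matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ad <- if ("AD" %in% names(g)) g$AD else NULL
  inf <- VariantAnnotation::info(v)
  rr <- SummarizedExperiment::rowRanges(v)
  alts <- VariantAnnotation::alt(v)
  geneV <- if (geneKey %in% colnames(inf)) inf[[geneKey]] else NULL
  afV <- if (afKey %in% colnames(inf)) inf[[afKey]] else NULL
  spliceV <- if (spliceKey %in% colnames(inf)) inf[[spliceKey]] else NULL

  adAt <- function(r, sample, slot) {
    if (is.null(ad)) return(NA_integer_)
    x <- if (is.array(ad) && length(dim(ad)) == 3L) ad[r, sample, ]
         else ad[[r, sample]]
    x <- suppressWarnings(as.integer(x))
    if (slot > length(x)) NA_integer_ else x[slot]
  }

  nAlt <- lengths(alts)
  rIdx <- rep(seq_len(nrow(v)), nAlt)
  kIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
  n <- length(rIdx)
  if (n == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), gene = character(),
                      af = numeric(), spliceMax = numeric(),
                      gtAffected = character(), gtUnaffected = character(),
                      dp = integer(), adRef = integer(), adAlt = integer(),
                      vf = numeric(), srcRow = integer(),
                      altIndex = integer(), stringsAsFactors = FALSE)
    attr(out, "vcf") <- v
    return(out)
  }
  altChr <- unlist(lapply(seq_len(nrow(v)), function(r)
    as.character(alts[[r]])), use.names = FALSE)
  chromV <- as.character(seqnames(rr))
  where <- paste0(chromV[rIdx], ":", start(rr)[rIdx],
                  " (record ", rIdx, ")")
  afList <- if (is.null(afV)) NULL else as.list(afV)
  splList <- if (is.null(spliceV)) NULL else as.list(spliceV)
  dpA <- suppressWarnings(as.integer(dp[, affected]))[rIdx]
  adRef <- vapply(seq_len(n), function(j)
    adAt(rIdx[j], affected, 1L), integer(1))
  adAlt <- vapply(seq_len(n), function(j)
    adAt(rIdx[j], affected, kIdx[j] + 1L), integer(1))
  out <- data.frame(
    chrom = chromV[rIdx],
    pos = start(rr)[rIdx],
    id = if (is.null(names(rr))) NA_character_ else names(rr)[rIdx],
    ref = as.character(VariantAnnotation::ref(v))[rIdx],
    alt = altChr,
    gene = if (is.null(geneV)) NA_character_ else
      as.character(geneV)[rIdx],
    af = if (is.null(afList)) NA_real_ else vapply(seq_len(n),
      function(j) {
        x <- suppressWarnings(as.numeric(afList[[rIdx[j]]]))
        if (kIdx[j] > length(x)) NA_real_ else x[kIdx[j]]
      }, numeric(1)),
    spliceMax = if (is.null(splList)) NA_real_ else vapply(seq_len(n),
      function(j) .spliceMax(splList[[rIdx[j]]], altChr[j]), numeric(1)),
    gtAffected = vapply(seq_len(n), function(j)
      .classifyGt(gt[rIdx[j], affected], kIdx[j], where[j]), character(1)),
    gtUnaffected = vapply(seq_len(n), function(j)
      .classifyGt(gt[rIdx[j], unaffected], kIdx[j], where[j]),
      character(1)),
    dp = dpA,
    adRef = adRef,
    adAlt = adAlt,
    vf = ifelse(!is.na(adAlt) & !is.na(dpA) & dpA > 0, adAlt / dpA,
                NA_real_),
    srcRow = rIdx,
    altIndex = kIdx,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "vcf") <- v
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

#' Write the VCF records behind a filtered variant table
#'
#' Emits, via [VariantAnnotation::writeVcf()], the original VCF records
#' whose alt allele survived filtering (a record is written once even
#' if several of its alts survived).
#'
#' @param variants a filtered variant table (rows of a table from
#'   [readDuoVcf()]).
#' @param source the original table from [readDuoVcf()] (its `"vcf"`
#'   attribute is used), a `VCF` object, or the original VCF path.
#' @param path output VCF path (".vcf" for plain text).
#' @return The path written, invisibly.
#' @export
writeFilteredVcf <- function(variants, source, path) {
  v <- if (is(source, "VCF")) source
       else if (is.data.frame(source)) attr(source, "vcf")
       else VariantAnnotation::readVcf(source, genome = "unknown")
  if (is.null(v)) stop("no VCF object available from 'source'")
  rows <- sort(unique(variants$srcRow))
  VariantAnnotation::writeVcf(v[rows], path)
  invisible(path)
}
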