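#' Pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end workflow in one
#' validated list; nothing is hidden in function bodies. Unknown keys
#' are rejected so a typo cannot silently fall back to a default.
#'
#' @param affected,unaffected VCF sample names.
#' @param genePanel gene panel for prioritization.
#' @param minDp,minAdAlt,vfRange,maxAf,spliceScoreMin see
#'   [filterConfig()].
#' @param spliceKey INFO key carrying splice delta scores.
#' @param scanWindow,minPseudoexonLength cryptic-site scan parameters
#'   (nt).
#' @param nmdThreshold 50-nt-rule distance (nt).
#' @param imbalanceThreshold balance bound for [classifyImbalance()].
#' @param acmgWeights,acmgThreshold see [acmgEvidence()].
#' @param seed seed for the simulate stage.
#' @return A validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(affected = "AFFECTED",
                           unaffected = "UNAFFECTED",
                           genePanel = "SYNAPC",
                           minDp = 20L, minAdAlt = 5L,
                           vfRange = c(0.2, 0.8), maxAf = 0.01,
                           spliceScoreMin = 0.2,
                           spliceKey = "SPLICEAI",
                           scanWindow = 300L,
                           minPseudoexonLength = 20L,
                           nmdThreshold = 50L,
                           imbalanceThreshold = 0.8,
                           acmgWeights = acmgDefaultWeights(),
                           acmgThreshold = 10L,
                           seed = 1L) {
  cfg <- list(affected = affected, unaffected = unaffected,
              genePanel = genePanel, minDp = as.integer(minDp),
              minAdAlt = as.integer(minAdAlt), vfRange = vfRange,
              maxAf = maxAf, spliceScoreMin = spliceScoreMin,
              spliceKey = spliceKey, scanWindow = as.integer(scanWindow),
              minPseudoexonLength = as.integer(minPseudoexonLength),
              nmdThreshold = as.integer(nmdThreshold),
              imbalanceThreshold = imbalanceThreshold,
              acmgWeights = acmgWeights,
              acmgThreshold = as.integer(acmgThreshold),
              seed = as.integer(seed))
  ## validate the filter subset eagerly
  invisible(filterConfig(cfg$genePanel, cfg$minDp, cfg$minAdAlt,
                         cfg$vfRange, cfg$maxAf, cfg$spliceScoreMin))
  stopifnot(cfg$nmdThreshold > 0L, cfg$imbalanceThreshold > 0,
            cfg$imbalanceThreshold <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys, optionally grouped in sections (sections are flattened);
#' unknown keys are a validation error.
#'
#' @param path YAML file.
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (k in names(raw)) {
    if (is.list(raw[[k]]) && !is.null(names(raw[[k]])))
      flat <- c(flat, raw[[k]])
    else flat[[k]] <- raw[[k]]
  }
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(flat$acmgWeights))
    flat$acmgWeights <- unlist(flat$acmgWeights)
  do.call(pipelineConfig, flat)
}

#' @describeIn pipelineConfig Print every effective setting as YAML.
#' @param cfg a `"PipelineConfig"`.
#' @export
showConfig <- function(cfg = pipelineConfig()) {
  x <- unclass(cfg)
  x$acmgWeights <- as.list(x$acmgWeights)
  cat(yaml::as.yaml(x))
  invisible(cfg)
}

## transcript-sense alleles for a genomic ref/alt pair
.txAlleles <- function(strand, ref, alt) {
  if (strand == "+") return(c(ref = ref, alt = alt))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  c(ref = unname(comp[ref]), alt = unname(comp[alt]))
}

#' Run the full synthetic end-to-end workflow
#'
#' Mirrors the study's order: generate the scenario, genotype
#' (duo VCF), prioritize, derive the pseudoexon from the top candidate
#' by scanning its intron for the activated cryptic sites, infer the
#' protein consequence and NMD fate, interpret the RNA assays, and
#' classify by the point-based ACMG scheme. Co-segregation (PP1) and
#' phenotype specificity (PP4) remain user flags, as in any real
#' curation.
#'
#' @param spec a [scenarioSpec()]; the generator side of the run.
#' @param segregation,phenotypeMatch user-asserted PP1/PP4 flags.
#' @param cfg a `"PipelineConfig"`; the gene panel defaults to the
#'   scenario's gene.
#' @return A list report: variant identifiers, prioritization funnel,
#'   pseudoexon HGVS r./p. strings, frame and NMD calls, imbalance
#'   ratios and classification, completeness, amplicon-length
#'   difference, ACMG criteria, total score and class.
#' @export
runPipeline <- function(spec = scenarioSpec(),
                        segregation = FALSE, phenotypeMatch = FALSE,
                        cfg = NULL) {
  if (is.null(cfg))
    cfg <- pipelineConfig(genePanel = spec$geneName, seed = spec$seed)
  gene <- makeGene(spec)
  tm <- gene$tm
  vcfPath <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcfPath), add = TRUE)
  planted <- plantVariantAndDuoVcf(spec, gene, vcfPath,
                                   cfg$affected, cfg$unaffected)
  vars <- readDuoVcf(vcfPath, cfg$affected, cfg$unaffected,
                     spliceKey = cfg$spliceKey)
  fcfg <- filterConfig(cfg$genePanel, cfg$minDp, cfg$minAdAlt,
                       cfg$vfRange, cfg$maxAf, cfg$spliceScoreMin)
  prior <- runPrioritization(vars, fcfg)
  cand <- candidates(prior)
  if (nrow(cand) == 0L)
    stop("prioritization produced no candidate variant")
  top <- cand[1L, ]

  loc <- locateInIntron(tm, top$pos)
  iseq <- intronSequence(tm, loc$intron)
  pairs <- scanCrypticSites(iseq, loc$offset, cfg$scanWindow,
                            cfg$minPseudoexonLength)
  if (nrow(pairs) == 0L)
    stop("no cryptic acceptor/donor pair found near the candidate")
  alleles <- .txAlleles(tm@strand, top$ref, top$alt)
  event <- definePseudoexon(
    codingPosition(loc$anchorBase, loc$offset),
    codingPosition(loc$anchorBase, pairs$acceptorFirst[1L]),
    codingPosition(loc$anchorBase, pairs$donorLast[1L]),
    refAllele = alleles[["ref"]], altAllele = alleles[["alt"]],
    tm = tm)
  pc <- proteinConsequence(tm, event)
  junctions <- pseudoexonJunctions(tm, event)
  nmd <- if (!is.na(pc$ptcTranscriptPos))
    nmdPredict(pc$ptcTranscriptPos, junctions, cfg$nmdThreshold)
  else FALSE
  event@proteinConsequence <- pc$consequence
  event@ptcTranscriptPos <- pc$ptcTranscriptPos
  event@nmdPredicted <- nmd

  assays <- simulateAssays(spec)
  peaks1 <- assays$peaks[assays$peaks$replicate == 1L, , drop = FALSE]
  loci <- unique(peaks1$locus)
  ratios <- vapply(loci, function(l) {
    suppressWarnings(allelicImbalance(
      peakSetFromTable(peaks1, l, "cDNA"),
      peakSetFromTable(peaks1, l, "gDNA"),
      refAllele = peaks1$allele[peaks1$locus == l &
                                peaks1$role == "ref"][1L],
      altAllele = peaks1$allele[peaks1$locus == l &
                                peaks1$role == "alt"][1L]))
  }, numeric(1))
  imbalanceClass <- vapply(ratios, classifyImbalance, character(1),
                           threshold = cfg$imbalanceThreshold)
  completeness <- completenessTest(assays$tagging)

  ## selective RT-PCR: flanking primers, normal vs aberrant transcript
  cds <- getCdsSequence(tm)
  anchor <- event@insertionSite[1L]
  fwd <- as.character(subseq(cds, anchor - 59L, anchor - 40L))
  rev <- as.character(reverseComplement(subseq(cds, anchor + 40L,
                                               anchor + 59L)))
  mut <- xscat(subseq(cds, 1L, anchor),
               DNAString(event@insertedSequence),
               subseq(cds, anchor + 1L, length(cds)))
  amplicons <- predictAmpliconLengths(
    DNAStringSet(c(normal = as.character(cds),
                   aberrant = as.character(mut))), fwd, rev)

  ev <- autoAssert(populationAf = top$af, spliceScoreMax = top$spliceMax,
                   frameRemainder = event@frameRemainder,
                   completeness = completeness, nmdPredicted = nmd,
                   segregation = segregation,
                   phenotypeMatch = phenotypeMatch,
                   spliceGate = cfg$spliceScoreMin,
                   weights = cfg$acmgWeights,
                   threshold = cfg$acmgThreshold)

  list(
    nVcfRecords = planted$nRecords,
    stages = stageCounts(prior),
    nCandidates = nrow(cand),
    variant = list(chrom = top$chrom, pos = top$pos, ref = top$ref,
                   alt = top$alt,
                   hgvsC = formatCpos(event@variant),
                   spliceScoreMax = top$spliceMax,
                   populationAf = top$af),
    pseudoexon = list(hgvsR = event@hgvsR,
                      insertedLength = event@insertedLength,
                      frameRemainder = event@frameRemainder,
                      acceptor = formatCpos(event@acceptorFirstBase),
                      donor = formatCpos(event@donorLastBase),
                      variantToDonor = variantToDonorDistance(
                        event@variant, event@donorLastBase)),
    protein = list(consequence = pc$consequence,
                   firstAffectedCodon = pc$firstAffectedCodon,
                   ptcTranscriptPos = pc$ptcTranscriptPos,
                   nmdPredicted = nmd),
    assays = list(imbalanceRatios = as.list(ratios),
                  imbalanceClass = as.list(imbalanceClass),
                  completeness = completeness,
                  ampliconLengths = as.list(amplicons),
                  ampliconDelta = unname(amplicons["aberrant"] -
                                         amplicons["normal"])),
    acmg = list(criteria = as.list(ev@criteria),
                notEvaluable = ev@notEvaluable,
                total = totalScore(ev),
                class = classifyEvidence(ev)),
    event = event)
}

#' Write a pipeline report as JSON
#'
#' @param report list from [runPipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writePipelineReport <- function(report, path) {
  report$event <- NULL                            # S4, not for JSON
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE), path)
  invisible(path)
}
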