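## Deterministic, seeded generators emulating the study design: a
## multi-exon gene with a deep-intronic variant that activates a
## cryptic AG...GT pseudoexon, a duo VCF where only the planted variant
## survives every filter, and electropherogram peak areas under a
## configurable NMD-degradation efficiency.

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Specify a synthetic pseudoexon scenario
#'
#' A pure description: every generator is a deterministic function of
#' the returned spec. Defaults reproduce the study conditions - an
#' 8-exon gene whose fifth exon ends at CDS base 531, a 56-bp
#' pseudoexon at intron offsets +1422..+1477 whose cryptic donor GT
#' starts 5 nt upstream of the planted A>G variant at +1482, NMD
#' efficiency 0.5 ("reduced by about half"), 500 background duo
#' variants, 5% multiplicative peak noise and a planted splice delta
#' score of 0.93.
#'
#' @param seed integer RNG seed.
#' @param nExons number of exons (> `targetIntron`).
#' @param exonLengthRange,intronLengthRange sampling ranges (nt) for
#'   exons after the anchor and for non-target introns.
#' @param targetIntron transcript-order index of the intron hosting the
#'   pseudoexon.
#' @param anchorBase CDS base ending the anchor exon (the `+` offset
#'   anchor).
#' @param pseudoexonLength planted pseudoexon length (bp); defaults to
#'   57 (in-frame) when `inFrame = TRUE`, else 56.
#' @param acceptorOffset intron offset of the first exonized base.
#' @param variantToDonorDistance nt from the last exonized base to the
#'   variant (>= 3 so the variant clears the donor GT).
#' @param targetIntronLength length of the host intron (nt).
#' @param nmdEfficiency fraction of variant-allele transcripts degraded
#'   (0..1).
#' @param nBackgroundVariants background duo variants to plant.
#' @param commonAfRange,rareAfMax background population-AF parameters:
#'   range for the common (filtered-out) class, maximum for the rare
#'   class.
#' @param peakNoiseCV coefficient of variation of the multiplicative
#'   log-normal peak noise.
#' @param spliceScore splice delta score planted on the variant.
#' @param scanWindow donor search window used for scrubbing spurious
#'   splice dinucleotides around the planted sites.
#' @param geneName,transcriptId,chromName,strand,flank cosmetics of the
#'   synthetic gene; both strands are supported.
#' @param inFrame negative-scenario flag: plant an in-frame (57 bp)
#'   pseudoexon to exercise PVS1 withholding.
#' @return A validated list of class `"ScenarioSpec"`.
#' @export
scenarioSpec <- function(seed = 1L, nExons = 8L,
                         exonLengthRange = c(90L, 200L),
                         intronLengthRange = c(300L, 800L),
                         targetIntron = 5L, anchorBase = 531L,
                         pseudoexonLength = NULL,
                         acceptorOffset = 1422L,
                         variantToDonorDistance = 5L,
                         targetIntronLength = 3200L,
                         nmdEfficiency = 0.5,
                         nBackgroundVariants = 500L,
                         commonAfRange = c(0.01, 0.5),
                         rareAfMax = 0.005,
                         peakNoiseCV = 0.05,
                         spliceScore = 0.93,
                         scanWindow = 300L,
                         geneName = "SYNAPC",
                         transcriptId = NULL,
                         chromName = "chrS", strand = "+",
                         flank = 300L, inFrame = FALSE) {
  if (is.null(pseudoexonLength))
    pseudoexonLength <- if (inFrame) 57L else 56L
  if (is.null(transcriptId)) transcriptId <- paste0(geneName, ".t1")
  spec <- list(seed = as.integer(seed), nExons = as.integer(nExons),
               exonLengthRange = as.integer(exonLengthRange),
               intronLengthRange = as.integer(intronLengthRange),
               targetIntron = as.integer(targetIntron),
               anchorBase = as.integer(anchorBase),
               pseudoexonLength = as.integer(pseudoexonLength),
               acceptorOffset = as.integer(acceptorOffset),
               variantToDonorDistance = as.integer(variantToDonorDistance),
               targetIntronLength = as.integer(targetIntronLength),
               nmdEfficiency = nmdEfficiency,
               nBackgroundVariants = as.integer(nBackgroundVariants),
               commonAfRange = commonAfRange, rareAfMax = rareAfMax,
               peakNoiseCV = peakNoiseCV, spliceScore = spliceScore,
               scanWindow = as.integer(scanWindow),
               geneName = geneName, transcriptId = transcriptId,
               chromName = chromName, strand = strand,
               flank = as.integer(flank), inFrame = isTRUE(inFrame))
  class(spec) <- "ScenarioSpec"
  validateScenarioSpec(spec)
  spec
}

#' Validate a scenario spec
#'
#' @param spec a `"ScenarioSpec"`.
#' @return `spec`, invisibly; errors on an infeasible specification.
#' @export
validateScenarioSpec <- function(spec) {
  with(spec, {
    stopifnot(nExons > targetIntron, targetIntron >= 1L,
              strand %in% c("+", "-"),
              nmdEfficiency >= 0, nmdEfficiency <= 1,
              peakNoiseCV >= 0, pseudoexonLength >= 6L,
              variantToDonorDistance >= 3L,
              acceptorOffset >= 3L, flank >= 10L,
              all(exonLengthRange > 0L), all(intronLengthRange > 0L),
              nBackgroundVariants >= 0L)
    if (anchorBase < 60L * targetIntron)
      stop("infeasible spec: anchorBase ", anchorBase,
           " too small to split across ", targetIntron,
           " exons of >= 60 nt")
    donorLast <- acceptorOffset + pseudoexonLength - 1L
    vo <- donorLast + variantToDonorDistance
    if (vo + 10L > targetIntronLength)
      stop("infeasible spec: target intron (", targetIntronLength,
           " nt) too short for the pseudoexon, donor and margins (needs > ",
           vo + 10L, " nt)")
    if (pseudoexonLength > scanWindow)
      stop("infeasible spec: pseudoexon longer than the donor search window")
  })
  invisible(spec)
}

## intron offsets of the planted donor's last exonized base and variant
.donorLastOffset <- function(spec)
  spec$acceptorOffset + spec$pseudoexonLength - 1L
.variantOffset <- function(spec)
  .donorLastOffset(spec) + spec$variantToDonorDistance

.randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

## remove AG/GT dinucleotides in chars[lo..hi] (second base -> C);
## a single left-to-right pass cannot create new sites
.scrubSpliceDinucs <- function(chars, lo, hi, protect = integer()) {
  for (i in seq(max(1L, lo), min(length(chars) - 1L, hi))) {
    if ((i + 1L) %in% protect || i %in% protect) next
    if ((chars[i] == "A" && chars[i + 1L] == "G") ||
        (chars[i] == "G" && chars[i + 1L] == "T"))
      chars[i + 1L] <- "C"
  }
  chars
}

## pseudoexon sequence: G-free (so it can contain no AG/GT), Ile codon
## first, a TAA planted at shifted-frame codon 14 for out-of-frame
## events, no earlier TAA
.makePseudoexonSeq <- function(spec) {
  P <- spec$pseudoexonLength
  chars <- sample(c("A", "C", "T"), P, TRUE)
  atBoundary <- spec$anchorBase %% 3L == 0L
  if (atBoundary) {
    nCod <- P %/% 3L
    codonAt <- function(j) paste(chars[(3L * j - 2L):(3L * j)],
                                 collapse = "")
    setCodon <- function(chars, j, s) {
      chars[(3L * j - 2L):(3L * j)] <- strsplit(s, "")[[1L]]
      chars
    }
    if (nCod >= 1L) chars <- setCodon(chars, 1L, "ATC")   # Ile
    outOfFrame <- P %% 3L != 0L
    stopAt <- if (outOfFrame && nCod >= 2L) min(14L, nCod) else 0L
    for (j in seq_len(nCod)) {
      if (j == stopAt) {
        chars <- setCodon(chars, j, "TAA")
      } else if (j > 1L && codonAt(j) == "TAA") {
        chars[3L * j] <- "C"                              # TAA -> TAC
      }
    }
  }
  chars
}

#' Generate the synthetic gene of a scenario
#'
#' Builds a chromosome (flank + gene + flank) whose CDS starts with ATG,
#' ends with a single stop and is free of internal stops; the target
#' intron carries canonical GT..AG termini, a planted cryptic acceptor
#' AG and donor GT delimiting the pseudoexon, the variant reference
#' base A at its offset, and no spurious AG/GT dinucleotide anywhere in
#' the donor/acceptor search window. Repeated calls with the same spec
#' return identical sequences.
#'
#' @param spec a [scenarioSpec()].
#' @return list with `tm` (a [TranscriptModel-class] with attached
#'   chromosome sequence) and `manifest` (the planted truth: variant
#'   coordinates and alleles, pseudoexon boundaries and sequence,
#'   splice score, NMD efficiency).
#' @export
makeGene <- function(spec) {
  validateScenarioSpec(spec)
  set.seed(spec$seed)
  tI <- spec$targetIntron
  ## exon widths: the first tI exons partition anchorBase (each >= 60)
  wAnchor <- rep(60L, tI)
  extra <- spec$anchorBase - 60L * tI
  if (extra > 0L) {
    add <- tabulate(sample(seq_len(tI), extra, TRUE), nbins = tI)
    wAnchor <- wAnchor + add
  }
  nAfter <- spec$nExons - tI
  wAfter <- sample(seq(spec$exonLengthRange[1L], spec$exonLengthRange[2L]),
                   nAfter, TRUE)
  total <- spec$anchorBase + sum(wAfter)
  wAfter[nAfter] <- wAfter[nAfter] + (3L - total %% 3L) %% 3L
  widths <- c(wAnchor, wAfter)
  total <- sum(widths)
  nCodons <- total %/% 3L

  codons <- sample(.SENSE_CODONS, nCodons, TRUE)
  codons[1L] <- "ATG"
  codons[nCodons] <- "TAA"
  if (nCodons - 1L >= 178L) codons[178L] <- "TTT"         # Phe
  cdsSeq <- strsplit(paste(codons, collapse = ""), "")[[1L]]

  intronLens <- vapply(seq_len(spec$nExons - 1L), function(i)
    if (i == tI) spec$targetIntronLength
    else sample(seq(spec$intronLengthRange[1L],
                    spec$intronLengthRange[2L]), 1L), integer(1))
  introns <- lapply(intronLens, function(L) {
    x <- sample(c("A", "C", "G", "T"), L, TRUE)
    x[1:2] <- c("G", "T"); x[(L - 1L):L] <- c("A", "G")   # canonical ends
    x
  })

  ## plant the pseudoexon machinery in the target intron
  donorLast <- .donorLastOffset(spec)
  vo <- .variantOffset(spec)
  ti <- introns[[tI]]
  win <- spec$scanWindow
  ti <- .scrubSpliceDinucs(ti, donorLast - win - 2L, vo + win + 2L)
  pe <- .makePseudoexonSeq(spec)
  ti[spec$acceptorOffset:donorLast] <- pe
  ti[(spec$acceptorOffset - 2L):(spec$acceptorOffset - 1L)] <- c("A", "G")
  ti[(donorLast + 1L):(donorLast + 2L)] <- c("G", "T")
  ti[vo] <- "A"
  if (ti[vo + 1L] == "G") ti[vo + 1L] <- "C"
  introns[[tI]] <- ti

  ## assemble the gene region (transcript sense) and exon offsets
  exonSeqs <- split(cdsSeq, factor(rep(seq_along(widths), widths),
                                   levels = seq_along(widths)))
  regionParts <- character(0)
  exonStartOff <- integer(spec$nExons)
  intronStartOff <- integer(spec$nExons - 1L)
  off <- 0L
  for (i in seq_len(spec$nExons)) {
    exonStartOff[i] <- off + 1L
    regionParts <- c(regionParts, paste(exonSeqs[[i]], collapse = ""))
    off <- off + widths[i]
    if (i < spec$nExons) {
      intronStartOff[i] <- off + 1L
      regionParts <- c(regionParts, paste(introns[[i]], collapse = ""))
      off <- off + intronLens[i]
    }
  }
  region <- paste(regionParts, collapse = "")
  GL <- nchar(region)
  flank1 <- .randNt(spec$flank); flank2 <- .randNt(spec$flank)
  chromSeq <- if (spec$strand == "+")
    paste0(flank1, region, flank2)
  else
    paste0(flank1, as.character(reverseComplement(DNAString(region))),
           flank2)

  toGenomic <- function(o)                       # region offset -> genomic
    if (spec$strand == "+") spec$flank + o else spec$flank + GL - o + 1L
  exIR <- if (spec$strand == "+") {
    IRanges(spec$flank + exonStartOff,
            spec$flank + exonStartOff + widths - 1L)
  } else {
    IRanges(spec$flank + GL - (exonStartOff + widths - 1L) + 1L,
            spec$flank + GL - exonStartOff + 1L)
  }
  tm <- transcriptModel(spec$transcriptId, spec$chromName, spec$strand,
                        exIR, 1L, total, refseq = chromSeq,
                        geneName = spec$geneName)
  ## self-check: the model must read back exactly the CDS we wrote
  stopifnot(identical(as.character(getCdsSequence(tm)),
                      paste(codons, collapse = "")))

  gVar <- toGenomic(intronStartOff[tI] + vo - 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  refG <- if (spec$strand == "+") "A" else unname(comp["A"])
  altG <- if (spec$strand == "+") "G" else unname(comp["G"])
  manifest <- list(
    geneName = spec$geneName, transcriptId = spec$transcriptId,
    chrom = spec$chromName, strand = spec$strand,
    chromLength = nchar(chromSeq),
    variantC = paste0("c.", spec$anchorBase, "+", vo),
    variantG = gVar, refTx = "A", altTx = "G",
    refG = refG, altG = altG,
    acceptorC = paste0("c.", spec$anchorBase, "+", spec$acceptorOffset),
    donorC = paste0("c.", spec$anchorBase, "+", donorLast),
    acceptorOffset = spec$acceptorOffset, donorLastOffset = donorLast,
    variantOffset = vo, targetIntron = tI,
    anchorBase = spec$anchorBase,
    pseudoexonLength = spec$pseudoexonLength,
    pseudoexonSequence = paste(pe, collapse = ""),
    frameRemainder = spec$pseudoexonLength %% 3L,
    spliceScore = spec$spliceScore,
    nmdEfficiency = spec$nmdEfficiency)
  ## coordinate self-consistency with the HGVS arithmetic
  stopifnot(cToG(tm, parseCpos(manifest$variantC)) == gVar)
  list(tm = tm, manifest = manifest)
}

.BACKGROUND_CATEGORIES <- c("low_dp", "bad_vf", "off_panel", "common",
                            "shared", "unaff_missing", "low_splice")

#' Plant the variant in a two-sample duo VCF
#'
#' Writes a VCF v4.2 file with the affected and unaffected samples: the
#' planted variant (het in affected, hom ref in unaffected, no
#' population AF, splice delta score from the spec) among background
#' variants drawn over seven deliberate rejection categories (low
#' depth, bad allele fraction, off-panel gene, common AF, shared
#' genotype, missing unaffected genotype, sub-gate splice score), so
#' that exactly the planted variant survives the full filter chain and
#' every filter's rejection path is exercised. Byte-identical under a
#' fixed spec.
#'
#' @param spec a [scenarioSpec()].
#' @param gene output of [makeGene()] for the same spec.
#' @param path output VCF path.
#' @param affected,unaffected sample column names.
#' @return Invisibly, a list with `path`, `nRecords` and `plantedKey`
#'   (`chrom:pos_ref/alt`).
#' @export
plantVariantAndDuoVcf <- function(spec, gene, path,
                                  affected = "AFFECTED",
                                  unaffected = "UNAFFECTED") {
  set.seed(spec$seed)
  m <- gene$manifest
  chrom <- gene$tm@refseq
  n <- spec$nBackgroundVariants
  spliceStr <- function(alt, dsAG, dsAL, dsDG, dsDL)
    paste(alt, m$geneName, dsAG, dsAL, dsDG, dsDL,
          2, -41, -spec$variantToDonorDistance, -47, sep = "|")

  recs <- data.frame(pos = m$variantG, ref = m$refG, alt = m$altG,
                     gene = m$geneName, af = NA_real_,
                     splice = spliceStr(m$altG, 0.02, 0.01,
                                        m$spliceScore, 0.03),
                     gtA = "0/1", dpA = 40L, adA = "20,20",
                     gtU = "0/0", dpU = 40L, adU = "40,0",
                     stringsAsFactors = FALSE)
  if (n > 0L) {
    pool <- setdiff(seq_len(length(chrom)), m$variantG)
    pos <- sort(sample(pool, n))
    category <- sample(.BACKGROUND_CATEGORIES, n, TRUE)
    chromChars <- strsplit(as.character(chrom), "")[[1L]]
    ref <- chromChars[pos]
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
      USE.NAMES = FALSE)
    gene_ <- rep(m$geneName, n)
    af <- ifelse(runif(n) < 0.5, NA_real_,
                 round(runif(n, 0, spec$rareAfMax), 4))
    splice <- rep(NA_character_, n)
    dp <- sample(30:60, n, TRUE)
    vf <- runif(n, 0.4, 0.6)
    gtA <- rep("0/1", n)
    gtU <- rep("0/0", n)

    i <- category == "low_dp"
    dp[i] <- sample(3:15, sum(i), TRUE)
    i <- category == "bad_vf"
    vf[i] <- runif(sum(i), 0.02, 0.15)
    i <- category == "off_panel"
    gene_[i] <- sample(c("BGGENE1", "BGGENE2", NA_character_), sum(i),
                       TRUE)
    i <- category == "common"
    af[i] <- round(runif(sum(i), spec$commonAfRange[1L],
                         spec$commonAfRange[2L]), 4)
    i <- category == "shared"
    gtU[i] <- sample(c("0/1", "1/1"), sum(i), TRUE)
    gtU[category == "unaff_missing"] <- "./."
    i <- category == "low_splice"
    if (any(i)) {
      ds <- sample(c(0, 0.05, 0.1, 0.2), sum(i), TRUE)
      splice[i] <- mapply(function(a, d)
        spliceStr(a, d, 0, round(d / 2, 3), 0), alt[i], ds)
    }

    adAlt <- as.integer(round(dp * vf))
    adRef <- dp - adAlt
    dpU <- sample(30:60, n, TRUE)
    adU <- ifelse(gtU == "0/0", paste0(dpU, ",0"),
           ifelse(gtU == "./.", ".,.",
                  paste0(floor(dpU / 2), ",", dpU - floor(dpU / 2))))
    bg <- data.frame(pos = pos, ref = ref, alt = alt, gene = gene_,
                     af = af, splice = splice, gtA = gtA, dpA = dp,
                     adA = paste0(adRef, ",", adAlt), gtU = gtU,
                     dpU = dpU, adU = adU, stringsAsFactors = FALSE)
    recs <- rbind(recs, bg)
    recs <- recs[order(recs$pos), , drop = FALSE]
  }

  info <- vapply(seq_len(nrow(recs)), function(i) {
    parts <- character(0)
    if (!is.na(recs$gene[i]))
      parts <- c(parts, paste0("GENE=", recs$gene[i]))
    if (!is.na(recs$af[i]))
      parts <- c(parts, paste0("AF=", format(recs$af[i], scientific = FALSE)))
    if (!is.na(recs$splice[i]))
      parts <- c(parts, paste0("SPLICEAI=", recs$splice[i]))
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }, character(1))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pseudoexon-synthetic",
    paste0("##contig=<ID=", m$chrom, ",length=", m$chromLength, ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=AF,Number=A,Type=Float,",
           "Description=\"Population allele frequency\">"),
    paste0("##INFO=<ID=SPLICEAI,Number=.,Type=String,Description=",
           "\"Splice delta scores: ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|",
           "DP_AG|DP_AL|DP_DG|DP_DL\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allele depths (ref,alt)\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", affected, unaffected, sep = "\t"))
  body <- paste(m$chrom, recs$pos, ".", recs$ref, recs$alt, 50, "PASS",
                info, "GT:DP:AD",
                paste0(recs$gtA, ":", recs$dpA, ":", recs$adA),
                paste0(recs$gtU, ":", recs$dpU, ":", recs$adU),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(list(path = path, nRecords = nrow(recs),
                 plantedKey = paste0(m$chrom, ":", m$variantG, "_",
                                     m$refG, "/", m$altG)))
}

## mean-1 multiplicative log-normal noise at coefficient of variation cv
.lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate electropherogram peak areas under NMD degradation
#'
#' Two heterozygous tagging markers; the cDNA alt-allele area is scaled
#' by `1 - nmdEfficiency` (the variant-bearing transcript fraction that
#' survives decay) and all areas carry multiplicative log-normal noise
#' with the spec's CV; gDNA areas are balanced. The closed-form
#' expectation of the [allelicImbalance()] ratio is `1 - nmdEfficiency`.
#'
#' @param spec a [scenarioSpec()].
#' @param replicates number of independent replicate assays.
#' @return data.frame with columns `replicate, locus, template, allele,
#'   role, area` (`role` marks ref/alt).
#' @export
simulatePeakAreas <- function(spec, replicates = 1L) {
  set.seed(spec$seed)
  markers <- data.frame(locus = c("tagSNP1", "tagSNP2"),
                        ref = c("T", "G"), alt = c("C", "A"),
                        stringsAsFactors = FALSE)
  base <- 10000
  e <- spec$nmdEfficiency
  rows <- list()
  for (r in seq_len(replicates)) {
    for (k in seq_len(nrow(markers))) {
      noise <- .lnNoise(4L, spec$peakNoiseCV)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, locus = markers$locus[k],
        template = c("cDNA", "cDNA", "gDNA", "gDNA"),
        allele = c(markers$ref[k], markers$alt[k],
                   markers$ref[k], markers$alt[k]),
        role = c("ref", "alt", "ref", "alt"),
        area = c(base * noise[1L], base * (1 - e) * noise[2L],
                 base * noise[3L], base * noise[4L]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate tagging-SNP observations of the wild-type-selective amplicon
#'
#' Consistent with complete aberrant splicing: both markers are
#' gDNA-heterozygous and the normal-length amplicon shows only the
#' allele of the non-variant haplotype (the reference allele here).
#'
#' @param spec a [scenarioSpec()].
#' @return data.frame with `marker`, `gdnaGenotype`, `observed`.
#' @export
simulateTaggingObservations <- function(spec) {
  data.frame(marker = c("tagSNP1", "tagSNP2"),
             gdnaGenotype = "het",
             observed = c("T", "G"),
             stringsAsFactors = FALSE)
}

#' Simulate all RNA assays of a scenario
#'
#' @param spec a [scenarioSpec()].
#' @param replicates replicate peak assays.
#' @return list with `peaks` ([simulatePeakAreas()]) and `tagging`
#'   ([simulateTaggingObservations()]).
#' @export
simulateAssays <- function(spec, replicates = 1L) {
  list(peaks = simulatePeakAreas(spec, replicates),
       tagging = simulateTaggingObservations(spec))
}

#' Write a complete scenario to disk
#'
#' Emits reference FASTA, GFF3 gene model, duo VCF, peak and tagging
#' TSV tables, and a manifest JSON recording the planted truth.
#'
#' @param spec a [scenarioSpec()].
#' @param dir output directory (created if needed).
#' @param affected,unaffected VCF sample names.
#' @return Invisibly, a named list of the paths written.
#' @export
writeScenario <- function(spec, dir, affected = "AFFECTED",
                          unaffected = "UNAFFECTED") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene <- makeGene(spec)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "gene.gff3"),
    vcf = file.path(dir, "duo.vcf"),
    peaks = file.path(dir, "peaks.tsv"),
    tagging = file.path(dir, "tagging.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeReferenceFasta(setNames(DNAStringSet(as.character(gene$tm@refseq)),
                               spec$chromName), paths$fasta)
  writeTranscriptGFF3(gene$tm, paths$gff3)
  plantVariantAndDuoVcf(spec, gene, paths$vcf, affected, unaffected)
  assays <- simulateAssays(spec)
  writePeakTable(assays$peaks, paths$peaks)
  writeTaggingTable(assays$tagging, paths$tagging)
  writeLines(jsonlite::toJSON(gene$manifest, auto_unbox = TRUE,
                              digits = NA), paths$manifest)
  invisible(paths)
}
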