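cdnaOf <- function(refA, altA) peakSet("m1", "cDNA", c(T = refA, C = altA))
gdnaOf <- function(refA, altA) peakSet("m1", "gDNA", c(T = refA, C = altA))

test_that("imbalance ratio is the gDNA-normalized ratio of ratios", {
  expect_equal(allelicImbalance(cdnaOf(10, 10), gdnaOf(10, 10)), 1.0)
  expect_equal(allelicImbalance(cdnaOf(10, 5), gdnaOf(10, 10)), 0.5)
  ## gDNA normalization corrects locus-specific amplification bias
  expect_equal(allelicImbalance(cdnaOf(20, 6), gdnaOf(20, 12)), 0.5)
})

test_that("imbalance is scale-invariant in either peak set", {
  set.seed(51)
  for (i in 1:20) {
    a <- runif(4, 1, 1000)
    base <- allelicImbalance(cdnaOf(a[1], a[2]), gdnaOf(a[3], a[4]))
    k <- runif(2, 0.01, 100)
    expect_equal(allelicImbalance(cdnaOf(k[1] * a[1], k[1] * a[2]),
                                  gdnaOf(k[2] * a[3], k[2] * a[4])),
                 base)
  }
})

test_that("degenerate peak inputs follow the error contract", {
  expect_error(allelicImbalance(cdnaOf(10, 5), gdnaOf(0, 10)),
               "gDNA areas must be positive")
  expect_error(allelicImbalance(cdnaOf(0, 5), gdnaOf(10, 10)),
               "undefined ratio")
  expect_warning(r <- allelicImbalance(cdnaOf(10, 0), gdnaOf(10, 10)),
                 "complete allele loss")
  expect_equal(r, 0)
  expect_error(allelicImbalance(cdnaOf(10, 5),
                                peakSet("other", "gDNA",
                                        c(T = 10, C = 10))),
               "different loci")
  expect_error(allelicImbalance(gdnaOf(10, 5), gdnaOf(10, 10)),
               "cDNA and a gDNA")
})

test_that("imbalance classification uses a strict two-sided bound", {
  expect_equal(classifyImbalance(0.57), "imbalanced")
  expect_equal(classifyImbalance(0.56), "imbalanced")
  expect_equal(classifyImbalance(1.0), "balanced")
  expect_equal(classifyImbalance(0.79, threshold = 0.8), "imbalanced")
  expect_equal(classifyImbalance(0.8, threshold = 0.8), "balanced")
  expect_equal(classifyImbalance(1.24, threshold = 0.8), "balanced")
  expect_equal(classifyImbalance(1.26, threshold = 0.8), "imbalanced")
})

tagObs <- function(gt, obs)
  data.frame(marker = paste0("rs", seq_along(gt)), gdnaGenotype = gt,
             observed = obs, stringsAsFactors = FALSE)

test_that("completeness verdicts follow the tagging-SNP logic", {
  expect_equal(completenessTest(tagObs(c("het", "het"), c("T", "G"))),
               "complete")
  expect_equal(completenessTest(tagObs(c("het", "het"), c("T,C", "G"))),
               "incomplete")
  expect_equal(completenessTest(tagObs(c("hom_ref", "hom_alt"),
                                       c("T", "A"))),
               "uninformative")
  ## hom markers showing both alleles do not matter
  expect_equal(completenessTest(tagObs(c("hom_ref", "het"), c("T,C", "G"))),
               "complete")
})

test_that("completeness is invariant to marker order and relabelling", {
  obs <- tagObs(c("het", "hom_ref", "het"), c("T", "A", "G"))
  perm <- obs[c(3, 1, 2), ]
  expect_equal(completenessTest(perm), completenessTest(obs))
  ## relabel ref/alt with consistent phase map: verdict unchanged
  phase <- c(rs1 = "T", rs3 = "G")
  expect_equal(completenessTest(obs, phase), "complete")
  swapped <- obs
  swapped$observed[1] <- "C"
  phaseSwapped <- c(rs1 = "C", rs3 = "G")
  expect_equal(completenessTest(swapped, phaseSwapped), "complete")
  ## but an observed allele off the expected haplotype is incomplete
  expect_equal(completenessTest(swapped, phase), "incomplete")
})

test_that("amplicon prediction is selective and shifts by the insert", {
  gene <- makeGene(scenarioSpec(seed = 52))
  m <- gene$manifest
  cds <- as.character(getCdsSequence(gene$tm))
  anchor <- m$anchorBase
  mutant <- paste0(substr(cds, 1, anchor), m$pseudoexonSequence,
                   substr(cds, anchor + 1, nchar(cds)))
  fwd <- substr(cds, anchor - 59, anchor - 40)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(cds, anchor + 40, anchor + 59))))
  lens <- predictAmpliconLengths(c(normal = cds, aberrant = mutant),
                                 fwd, rev)
  expect_equal(unname(lens["aberrant"] - lens["normal"]),
               m$pseudoexonLength)
  ## a primer inside the pseudoexon amplifies only the aberrant isoform
  fwdIns <- substr(m$pseudoexonSequence, 11, 30)
  lens2 <- predictAmpliconLengths(c(normal = cds, aberrant = mutant),
                                  fwdIns, rev)
  expect_true(is.na(lens2["normal"]))
  expect_false(is.na(lens2["aberrant"]))
  ## identical transcripts, identical lengths
  lens3 <- predictAmpliconLengths(c(a = cds, b = cds), fwd, rev)
  expect_equal(unname(lens3["a"]), unname(lens3["b"]))
})

test_that("peak and tagging tables round-trip through TSV", {
  spec <- scenarioSpec(seed = 53)
  assays <- simulateAssays(spec)
  p <- withr::local_tempfile(fileext = ".tsv")
  t <- withr::local_tempfile(fileext = ".tsv")
  writePeakTable(assays$peaks, p)
  writeTaggingTable(assays$tagging, t)
  peaks <- readPeakTable(p)
  expect_equal(peaks$area, assays$peaks$area, tolerance = 1e-12)
  expect_equal(peaks$locus, assays$peaks$locus)
  tags <- readTaggingTable(t)
  expect_equal(tags$marker, assays$tagging$marker)
  expect_equal(completenessTest(tags), "complete")
  ps <- peakSetFromTable(peaks, "tagSNP1", "cDNA")
  expect_s4_class(ps, "PeakSet")
  expect_error(peakSetFromTable(peaks, "nope", "cDNA"), "no rows")
})
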