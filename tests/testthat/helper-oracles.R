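## Shared fixtures and independent oracles. The oracles deliberately
## re-derive expectations by enumeration / naive translation, never by
## calling the code paths they check.

## -- toy gene: 3 exons on +, CDS = whole transcript ---------------------
toyGene <- function(strand = "+", seed = 99L) {
  set.seed(seed)
  chrom <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
  transcriptModel("TOYG1", "chrT", strand,
                  IRanges::IRanges(c(101L, 301L, 501L),
                                   c(200L, 400L, 600L)),
                  refseq = chrom, geneName = "TOY")
}

## random transcript model with mixed odd/even intron lengths
randomTm <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  widths <- sample(30:80, n, TRUE)
  gaps <- sample(20:61, n - 1, TRUE)
  starts <- integer(n)
  starts[1] <- 50L
  for (i in seq_len(n - 1))
    starts[i + 1] <- starts[i] + widths[i] + gaps[i]
  ends <- starts + widths - 1L
  chromLen <- ends[n] + 50L
  chrom <- paste(sample(c("A", "C", "G", "T"), chromLen, TRUE),
                 collapse = "")
  transcriptModel(paste0("RND", seed), "chrR",
                  sample(c("+", "-"), 1),
                  IRanges::IRanges(starts, ends), refseq = chrom)
}

## -- exhaustive coordinate enumeration oracle ---------------------------
## Walks the gene in transcript sense using only exon coordinates and
## strand, labelling every genomic position with its canonical
## CodingPosition (base, offset). CDS is assumed to span the whole
## transcript (true for all fixtures here).
enumeratePositions <- function(tm) {
  ex <- exonRanges(tm)
  n <- length(ex)
  ord <- if (tm@strand == "+") seq_len(n) else rev(seq_len(n))
  rows <- list()
  t <- 0L
  for (i in seq_len(n)) {
    gx <- ex[ord[i]]
    gpos <- if (tm@strand == "+")
      seq(IRanges::start(gx), IRanges::end(gx))
    else seq(IRanges::end(gx), IRanges::start(gx))
    for (g in gpos) {
      t <- t + 1L
      rows[[length(rows) + 1L]] <- c(g = g, base = t, offset = 0L)
    }
    if (i < n) {
      nx <- ex[ord[i + 1L]]
      L <- if (tm@strand == "+")
        IRanges::start(nx) - IRanges::end(gx) - 1L
      else IRanges::start(gx) - IRanges::end(nx) - 1L
      for (d in seq_len(L)) {
        g <- if (tm@strand == "+") IRanges::end(gx) + d
             else IRanges::start(gx) - d
        lab <- if (2L * d <= L + 1L) c(base = t, offset = d)
               else c(base = t + 1L, offset = -(L - d + 1L))
        rows[[length(rows) + 1L]] <- c(g = g, lab)
      }
    }
  }
  as.data.frame(do.call(rbind, rows))
}

## -- naive translation oracle -------------------------------------------
## Codon-by-codon walk over a character CDS using the standard genetic
## code table; stops at the first stop codon.
naiveTranslate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  aa <- character(0)
  for (j in seq_len(n)) {
    codon <- substr(cds, 3L * j - 2L, 3L * j)
    a <- unname(gc[codon])
    if (is.na(a)) a <- "X"
    aa <- c(aa, a)
    if (a == "*") break
  }
  aa
}

aa3 <- function(a) {
  if (a == "*") return("*")
  unname(Biostrings::AMINO_ACID_CODE[a])
}

## independent protein-consequence oracle: splices the insert into the
## CDS by plain string surgery and derives the HGVS p. description from
## the two naive translations
oracleConsequence <- function(cds, insert, anchor) {
  mutant <- paste0(substr(cds, 1L, anchor), insert,
                   substr(cds, anchor + 1L, nchar(cds)))
  refAA <- naiveTranslate(cds)
  mutAA <- naiveTranslate(mutant)
  n <- min(length(refAA), length(mutAA))
  d <- which(refAA[seq_len(n)] != mutAA[seq_len(n)])
  i <- if (length(d)) d[1L] else n + 1L
  if (nchar(insert) %% 3L != 0L) {
    stopIdx <- if (mutAA[length(mutAA)] == "*") length(mutAA) else NA
    if (is.na(stopIdx))
      return(list(text = paste0("p.(", aa3(refAA[i]), i, aa3(mutAA[i]),
                                "fs*?)"), ptc = NA))
    if (i >= stopIdx) {
      i <- stopIdx
      return(list(text = paste0("p.(", aa3(refAA[i]), i, "*)"),
                  ptc = (stopIdx - 1L) * 3L + 1L))
    }
    k <- stopIdx - i + 1L
    list(text = paste0("p.(", aa3(refAA[i]), i, aa3(mutAA[i]),
                       "fs", k, "*)"),
         ptc = (stopIdx - 1L) * 3L + 1L)
  } else {
    m <- nchar(insert) %/% 3L
    if (identical(refAA, mutAA) || m == 0L)
      return(list(text = "p.(=)", ptc = NA))
    if (mutAA[i] == "*")
      return(list(text = paste0("p.(", aa3(refAA[i]), i, "*)"),
                  ptc = (i - 1L) * 3L + 1L))
    pep <- paste(vapply(seq(i, min(i + m - 1L, length(mutAA))),
                        function(k) aa3(mutAA[k]), character(1)),
                 collapse = "")
    list(text = paste0("p.(", aa3(refAA[i - 1L]), i - 1L, "_",
                       aa3(refAA[i]), i, "ins", pep, ")"), ptc = NA)
  }
}

## -- random variant table for filter tests ------------------------------
randomVariantTable <- function(n, seed) {
  set.seed(seed)
  gts <- c("hom_ref", "het", "hom_alt", "missing")
  dp <- sample(c(NA, 2:80), n, TRUE)
  vf <- round(runif(n), 3)
  adAlt <- ifelse(is.na(dp), NA, as.integer(round(dp * vf)))
  data.frame(
    chrom = "chrS",
    pos = sample(1:100000, n),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    gene = sample(c("APC", "MUTYH", "OTHER", NA), n, TRUE),
    af = sample(c(NA, 0, 0.001, 0.009, 0.01, 0.02, 0.3), n, TRUE),
    spliceMax = sample(c(NA, 0, 0.1, 0.2, 0.21, 0.5, 0.93), n, TRUE),
    gtAffected = sample(gts, n, TRUE, prob = c(0.1, 0.5, 0.2, 0.2)),
    gtUnaffected = sample(gts, n, TRUE),
    dp = dp,
    adRef = ifelse(is.na(dp), NA, dp - adAlt),
    adAlt = adAlt,
    vf = ifelse(is.na(dp), NA, vf),
    stringsAsFactors = FALSE)
}

## key identifying a variant row across filter permutations
variantKey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
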