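test_that("coding-position strings parse and format canonically", {
  p <- parseCpos("c.531+1482")
  expect_s4_class(p, "CodingPosition")
  expect_equal(p@base, 531L)
  expect_equal(p@offset, 1482L)
  expect_equal(formatCpos(p), "c.531+1482")

  expect_equal(parseCpos("c.532")@offset, 0L)
  expect_equal(parseCpos("c.101-50")@offset, -50L)
  ## published spacing is tolerated, output is canonical
  expect_equal(formatCpos(parseCpos("c.531 + 1482")), "c.531+1482")

  for (s in c("c.10", "c.10+3", "c.10-3", "c.531+1482"))
    expect_equal(formatCpos(parseCpos(s)), s)
})

test_that("malformed coding positions error, naming the offending token", {
  expect_error(parseCpos("g.100"), "malformed")
  expect_error(parseCpos("c.12++3"), "malformed")
  expect_error(parseCpos("c.0"), "invalid base '0'")
  expect_error(parseCpos("c.5+0"), "invalid offset '0'")
})

test_that("toy-gene conversions match the worked coordinates", {
  tm <- toyGene()
  expect_equal(cToG(tm, parseCpos("c.1")), 101L)
  expect_equal(cToG(tm, parseCpos("c.100+1")), 201L)
  expect_equal(cToG(tm, parseCpos("c.100+50")), 250L)
  expect_equal(formatCpos(gToC(tm, 250)), "c.100+50")
  expect_equal(formatCpos(gToC(tm, 301)), "c.101")
})

test_that("conversion errors are raised, never clamped", {
  tm <- toyGene()
  expect_error(cToG(tm, parseCpos("c.301")), "beyond CDS length")
  ## intron 1 is 100 nt: +101 would land on the next exon
  expect_error(cToG(tm, parseCpos("c.100+101")), "walks past intron")
  expect_error(cToG(tm, parseCpos("c.99+5")), "final base of an exon")
  expect_error(cToG(tm, parseCpos("c.102-5")), "first base of an exon")
  expect_error(gToC(tm, 50), "outside the transcript")
  expect_error(gToC(tm, 1000), "outside the transcript")
})

test_that("cToG and gToC invert each other over exhaustive enumerations", {
  models <- c(list(toyGene("+"), toyGene("-")),
              lapply(1:4, randomTm))
  for (tm in models) {
    tab <- enumeratePositions(tm)
    for (r in seq_len(nrow(tab))) {
      p <- codingPosition(tab$base[r], tab$offset[r])
      expect_equal(cToG(tm, p), tab$g[r])
      q <- gToC(tm, tab$g[r])
      expect_equal(q@base, tab$base[r])
      expect_equal(q@offset, tab$offset[r])
    }
  }
})

test_that("intron midpoint assignment balances + and - offsets", {
  for (tm in lapply(5:8, randomTm)) {
    tab <- enumeratePositions(tm)
    intr <- tab[tab$offset != 0L, ]
    ## group intron positions by their flanking exon pair
    grp <- cumsum(c(TRUE, diff(which(tab$offset != 0L)) > 1L))
    for (g in unique(grp)) {
      off <- intr$offset[grp == g]
      expect_lte(abs(sum(off > 0) - sum(off < 0)), 1L)
    }
  }
})

test_that("codonIndex follows ceiling arithmetic and rejects introns", {
  expect_equal(codonIndex(parseCpos("c.532")), 178L)
  expect_equal(codonIndex(parseCpos("c.1")), 1L)
  expect_equal(codonIndex(parseCpos("c.531")), 177L)
  expect_error(codonIndex(parseCpos("c.531+1482")), "intronic")
  idx <- vapply(1:300, function(b) codonIndex(codingPosition(b)),
                integer(1))
  expect_true(all(diff(idx) >= 0L))
  expect_equal(idx[3 * (1:100)], 1:100)
})

test_that("sequence extraction spans are exact on both strands", {
  tmP <- toyGene("+")
  first <- as.character(extractSequence(tmP, parseCpos("c.1"),
                                        parseCpos("c.3")))
  expect_equal(first,
               as.character(Biostrings::subseq(tmP@refseq, 101, 103)))

  ## inclusive span length, random bounds, both strands
  for (tm in list(tmP, toyGene("-"))) {
    for (i in 1:20) {
      set.seed(i)
      b <- sort(sample(1:300, 2))
      s <- extractSequence(tm, codingPosition(b[1]), codingPosition(b[2]))
      g1 <- cToG(tm, codingPosition(b[1]))
      g2 <- cToG(tm, codingPosition(b[2]))
      expect_equal(length(s), abs(g2 - g1) + 1L)
    }
  }

  ## minus-strand extraction is the reverse complement of the + slice
  tmM <- toyGene("-")
  g1 <- cToG(tmM, parseCpos("c.100+10"))
  g2 <- cToG(tmM, parseCpos("c.100+30"))
  s <- extractSequence(tmM, parseCpos("c.100+10"), parseCpos("c.100+30"))
  plus <- Biostrings::subseq(tmM@refseq, min(g1, g2), max(g1, g2))
  expect_equal(as.character(s),
               as.character(Biostrings::reverseComplement(plus)))

  expect_error(extractSequence(toyGene("+"), parseCpos("c.50"),
                               parseCpos("c.10")), "follows")
  tmNoSeq <- transcriptModel("X", "chrT", "+",
                             IRanges::IRanges(101, 200))
  expect_error(extractSequence(tmNoSeq, parseCpos("c.1"),
                               parseCpos("c.3")), "no reference sequence")
})

test_that("locateInIntron reports donor-side offsets past the midpoint", {
  tm <- toyGene()
  ## g.290 is 90 nt into the 100-nt intron 1: canonical name is -11
  expect_equal(formatCpos(gToC(tm, 290)), "c.101-11")
  loc <- locateInIntron(tm, 290)
  expect_equal(loc$intron, 1L)
  expect_equal(loc$offset, 90L)
  expect_equal(loc$anchorBase, 100L)
  expect_error(locateInIntron(tm, 150), "exonic")
})
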