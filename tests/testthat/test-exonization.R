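paperEvent <- function(tm = NULL)
  definePseudoexon("c.531+1482", "c.531+1422", "c.531+1477", tm = tm)

test_that("pseudoexon definition reproduces the 56-bp worked example", {
  ev <- paperEvent()
  expect_equal(ev@insertedLength, 56L)
  expect_equal(ev@insertionSite, c(531L, 532L))
  expect_equal(ev@frameRemainder, 2L)
  expect_equal(ev@hgvsR, "r.531_532ins531+1422_531+1477")
})

test_that("degenerate and invalid boundary pairs behave as specified", {
  ev <- definePseudoexon("c.99+15", "c.99+10", "c.99+10")
  expect_equal(ev@insertedLength, 1L)
  expect_equal(ev@hgvsR, "r.99_100ins99+10_99+10")
  expect_error(definePseudoexon("c.531+1482", "c.530+10", "c.531+20"),
               "share one intron")
  expect_error(definePseudoexon("c.531+1482", "c.531+100", "c.531+50"),
               "inverted")
  expect_error(definePseudoexon("c.531", "c.531+10", "c.531+20"),
               "intronic")
})

test_that("inserted length matches an exhaustive base-counting oracle", {
  set.seed(41)
  for (i in 1:50) {
    off <- sort(sample(1:2000, 2))
    ev <- definePseudoexon(codingPosition(300, off[2] + 5),
                           codingPosition(300, off[1]),
                           codingPosition(300, off[2]))
    ## oracle: count the inclusive span position by position
    expect_equal(ev@insertedLength, length(seq(off[1], off[2])))
    expect_equal(ev@frameRemainder, ev@insertedLength %% 3L)
  }
})

test_that("variant-to-donor distance matches the worked 5-nt example", {
  expect_equal(variantToDonorDistance("c.531+1482", "c.531+1477"), 5L)
  expect_equal(variantToDonorDistance("c.531+1477", "c.531+1477"), 0L)
  expect_error(variantToDonorDistance("c.530+5", "c.531+2"), "different")
})

test_that("negative donor distances agree with genomic arithmetic", {
  tm <- toyGene()
  v <- parseCpos("c.100+20")
  d <- parseCpos("c.100+35")
  expect_equal(variantToDonorDistance(v, d), -15L)
  ## oracle: recompute from genomic coordinates (transcript sense, +)
  expect_equal(variantToDonorDistance(v, d), cToG(tm, v) - cToG(tm, d))
})

test_that("r. formatting and parsing are mutually inverse", {
  ev <- paperEvent()
  parsed <- parseHgvsR(formatHgvsR(ev))
  expect_equal(parsed$insertionSite, ev@insertionSite)
  expect_equal(formatCpos(parsed$acceptorFirstBase), "c.531+1422")
  expect_equal(formatCpos(parsed$donorLastBase), "c.531+1477")
  ## whitespace-normalized published form parses too
  p2 <- parseHgvsR("r.531_532ins531 + 1422_531 + 1477")
  expect_equal(formatCpos(p2$donorLastBase), "c.531+1477")
  expect_error(parseHgvsR("r.531_533ins1_2"), "consecutive")
  expect_error(parseHgvsR("r.banana"), "malformed")
})

test_that("cryptic-site scan finds exactly the planted AG...GT pair", {
  bg <- rep("C", 500)
  bg[100:101] <- c("A", "G")          # acceptor AG -> first base 102
  bg[160:161] <- c("G", "T")          # donor GT -> last base 159
  s <- paste(bg, collapse = "")
  hits <- scanCrypticSites(s, variantOffset = 164)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$acceptorFirst, 102L)
  expect_equal(hits$donorLast, 159L)
  expect_equal(hits$length, 58L)
})

test_that("scan returns empty (with a message) when no pair exists", {
  expect_message(h1 <- scanCrypticSites(strrep("C", 400), 200), "no cryptic")
  expect_equal(nrow(h1), 0L)
  ## donor GT present but no upstream AG in the window
  bg <- rep("C", 400); bg[200:201] <- c("G", "T")
  expect_message(h2 <- scanCrypticSites(paste(bg, collapse = ""), 204),
                 "no acceptor")
  expect_equal(nrow(h2), 0L)
})

test_that("competing pairs are ranked like an enumeration oracle", {
  bg <- rep("C", 600)
  bg[80:81] <- c("A", "G")            # acceptorFirst 82
  bg[200:201] <- c("A", "G")          # acceptorFirst 202
  bg[320:321] <- c("G", "T")          # donorLast 319
  bg[360:361] <- c("G", "T")          # donorLast 359
  s <- paste(bg, collapse = "")
  hits <- scanCrypticSites(s, variantOffset = 330, window = 300,
                           minLength = 20)
  ## oracle: enumerate all AG x GT pairs and rank by the same rule
  acc <- c(82L, 202L); don <- c(319L, 359L)
  grid <- expand.grid(acceptorFirst = acc, donorLast = don)
  grid$length <- grid$donorLast - grid$acceptorFirst + 1L
  grid <- grid[grid$length >= 20 & grid$length <= 300, ]
  grid <- grid[order(abs(grid$length - 150), grid$length), ]
  expect_equal(hits$acceptorFirst, grid$acceptorFirst)
  expect_equal(hits$donorLast, grid$donorLast)
  ## ranking self-consistency: no GT inside the top span would produce
  ## a better-ranked pair with the same acceptor
  top <- hits[1L, ]
  gtLast <- c(319L, 359L)
  inside <- gtLast[gtLast > top$acceptorFirst & gtLast < top$donorLast]
  for (g in inside) {
    altLen <- g - top$acceptorFirst + 1L
    if (altLen >= 20 && altLen <= 300)
      expect_gte(abs(altLen - 150), abs(top$length - 150))
  }
})

test_that("protein consequence reproduces the frameshift worked example", {
  gene <- makeGene(scenarioSpec(seed = 42))
  ev <- paperEvent(gene$tm)
  expect_equal(nchar(ev@insertedSequence), 56L)
  pc <- proteinConsequence(gene$tm, ev)
  expect_equal(pc$firstAffectedCodon, 178L)
  expect_match(pc$consequence, "^p\\.\\(Phe178")
  expect_match(pc$consequence, "fs14\\*\\)$")
  expect_false(pc$noStop)
})

test_that("protein consequence equals the naive translation oracle", {
  set.seed(43)
  for (i in 1:25) {
    spec <- scenarioSpec(
      seed = 4300 + i,
      nExons = sample(6:9, 1),
      anchorBase = sample(seq(420, 630, by = 3), 1) +
        sample(0:2, 1, prob = c(0.6, 0.2, 0.2)),
      pseudoexonLength = sample(20:80, 1),
      acceptorOffset = sample(800:1600, 1))
    gene <- makeGene(spec)
    m <- gene$manifest
    ev <- definePseudoexon(parseCpos(m$variantC), parseCpos(m$acceptorC),
                           parseCpos(m$donorC), tm = gene$tm)
    pc <- proteinConsequence(gene$tm, ev)
    orc <- oracleConsequence(as.character(getCdsSequence(gene$tm)),
                             ev@insertedSequence, m$anchorBase)
    expect_equal(pc$consequence, orc$text)
    if (!is.na(orc$ptc)) expect_equal(pc$ptcTranscriptPos, orc$ptc)
  }
})

test_that("in-frame insertions leave the downstream protein unchanged", {
  gene <- makeGene(scenarioSpec(seed = 44, inFrame = TRUE))
  m <- gene$manifest
  ev <- definePseudoexon(parseCpos(m$variantC), parseCpos(m$acceptorC),
                         parseCpos(m$donorC), tm = gene$tm)
  expect_equal(ev@frameRemainder, 0L)
  pc <- proteinConsequence(gene$tm, ev)
  expect_match(pc$consequence, "ins")
  expect_true(is.na(pc$ptcTranscriptPos))
  ## reference residues after the insertion are conserved
  cds <- as.character(getCdsSequence(gene$tm))
  refAA <- naiveTranslate(cds)
  mutAA <- naiveTranslate(paste0(substr(cds, 1, m$anchorBase),
                                 ev@insertedSequence,
                                 substr(cds, m$anchorBase + 1, nchar(cds))))
  m3 <- nchar(ev@insertedSequence) / 3
  expect_equal(mutAA[(m$anchorBase / 3 + m3 + 1):length(mutAA)],
               refAA[(m$anchorBase / 3 + 1):length(refAA)])
})

test_that("the 50-nt NMD rule is applied to the last junction", {
  expect_true(nmdPredict(100, c(250, 400)))
  expect_false(nmdPredict(390, c(250, 400)))
  expect_true(nmdPredict(350, c(250, 400)))    # exactly 50 nt: >=
  expect_false(nmdPredict(351, c(250, 400)))
  expect_error(nmdPredict(100, integer()), "empty")
  ## threshold is configurable
  expect_true(nmdPredict(390, c(250, 400), threshold = 5))
  expect_false(nmdPredict(390, c(250, 400), threshold = 20))
})

test_that("mutant-transcript junctions shift by the inserted length", {
  gene <- makeGene(scenarioSpec(seed = 45))
  tm <- gene$tm
  ev <- paperEvent(tm)
  ends <- cumsum(IRanges::width(exonRanges(tm))[
    if (tm@strand == "+") seq_len(exonCount(tm))
    else rev(seq_len(exonCount(tm)))])
  junc <- pseudoexonJunctions(tm, ev)
  i <- match(531L, ends)
  expect_equal(junc[seq_len(i)], ends[seq_len(i)])
  expect_equal(junc[i + 1L], 531L + 56L)
  expect_equal(junc[-seq_len(i + 1L)],
               ends[seq(i + 1L, length(ends) - 1L)] + 56L)
  ## a paper-like gene: PTC deep in the pseudoexon, many downstream
  ## junctions -> NMD predicted
  pc <- proteinConsequence(tm, ev)
  expect_true(nmdPredict(pc$ptcTranscriptPos, junc))
})

test_that("event JSON-lines and BED outputs carry the genomic interval", {
  gene <- makeGene(scenarioSpec(seed = 46))
  ev <- paperEvent(gene$tm)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeEventJson(ev, path, tm = gene$tm)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$insertedLength, 56L)
  expect_equal(rec$hgvsR, ev@hgvsR)
  bed <- read.delim(paste0(path, ".bed"), header = FALSE)
  expect_equal(bed$V3 - bed$V2, 56L)           # BED half-open width
  g1 <- cToG(gene$tm, ev@acceptorFirstBase)
  g2 <- cToG(gene$tm, ev@donorLastBase)
  expect_equal(bed$V2, min(g1, g2) - 1L)
})
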