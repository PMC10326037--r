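cfgDefault <- filterConfig(genePanel = c("APC", "MUTYH"))

oneVariant <- function(...) {
  v <- data.frame(chrom = "chrS", pos = 100L, ref = "A", alt = "G",
                  gene = "APC", af = NA_real_, spliceMax = 0.93,
                  gtAffected = "het", gtUnaffected = "hom_ref",
                  dp = 40L, adRef = 18L, adAlt = 22L, vf = 0.55,
                  stringsAsFactors = FALSE)
  args <- list(...)
  for (k in names(args)) v[[k]] <- args[[k]]
  v
}

test_that("quality gate applies DP, alt AD and VF bounds", {
  expect_equal(nrow(filterQuality(oneVariant(), cfgDefault)), 1L)
  expect_equal(nrow(filterQuality(oneVariant(dp = 4L), cfgDefault)), 0L)
  expect_equal(nrow(filterQuality(oneVariant(adAlt = 4L), cfgDefault)), 0L)
  expect_equal(nrow(filterQuality(oneVariant(vf = 0.9), cfgDefault)), 0L)
  expect_equal(nrow(filterQuality(oneVariant(dp = NA), cfgDefault)), 0L)
})

test_that("quality survivors equal an independent predicate recheck", {
  v <- randomVariantTable(200, seed = 21)
  got <- variantKey(filterQuality(v, cfgDefault))
  keep <- !is.na(v$dp) & v$dp >= 20 &
    !is.na(v$adAlt) & v$adAlt >= 5 &
    !is.na(v$vf) & v$vf >= 0.2 & v$vf <= 0.8
  expect_setequal(got, variantKey(v[keep, ]))
})

test_that("panel filter is exact, case-sensitive, and rejects empty panels", {
  expect_equal(nrow(filterPanel(oneVariant(), c("APC", "MUTYH"))), 1L)
  expect_equal(nrow(filterPanel(oneVariant(gene = "apc"), "APC")), 0L)
  expect_equal(nrow(filterPanel(oneVariant(gene = NA), "APC")), 0L)
  expect_error(filterPanel(oneVariant(), character()), "empty")
  expect_error(filterConfig(genePanel = character()), "non-empty")
})

test_that("frequency filter is strict and treats missing AF as novel", {
  expect_equal(nrow(filterFrequency(oneVariant(af = 0.009), 0.01)), 1L)
  expect_equal(nrow(filterFrequency(oneVariant(af = 0.01), 0.01)), 0L)
  expect_equal(nrow(filterFrequency(oneVariant(af = NA), 0.01)), 1L)
  expect_equal(nrow(filterFrequency(oneVariant(af = 0), 0.01)), 1L)
})

test_that("duo filter keeps affected-only carriers and flags missing", {
  expect_equal(nrow(filterDuo(oneVariant())), 1L)
  expect_equal(nrow(filterDuo(oneVariant(gtAffected = "hom_alt"))), 1L)
  expect_equal(nrow(filterDuo(oneVariant(gtUnaffected = "het"))), 0L)
  miss <- filterDuo(oneVariant(gtUnaffected = "missing"))
  expect_equal(nrow(miss), 0L)
  expect_equal(attr(miss, "indeterminate"), 1L)
})

test_that("duo accounting: kept + dropped + indeterminate covers the input", {
  v <- randomVariantTable(200, seed = 22)
  out <- filterDuo(v)
  carrier <- v$gtAffected %in% c("het", "hom_alt")
  oracleKept <- sum(carrier & v$gtUnaffected == "hom_ref")
  oracleIndet <- sum(carrier & v$gtUnaffected == "missing")
  expect_equal(nrow(out), oracleKept)
  expect_equal(attr(out, "indeterminate"), oracleIndet)
  expect_lte(nrow(out) + attr(out, "indeterminate"), nrow(v))
})

test_that("splice gate is strict and drops unscored variants", {
  expect_equal(nrow(filterSpliceScore(oneVariant(spliceMax = 0.93))), 1L)
  expect_equal(nrow(filterSpliceScore(oneVariant(spliceMax = 0.2))), 0L)
  expect_equal(nrow(filterSpliceScore(oneVariant(spliceMax = NA))), 0L)
})

test_that("funnel counts are non-increasing and subsets nest", {
  v <- randomVariantTable(300, seed = 23)
  rep <- runPrioritization(v, cfgDefault)
  counts <- stageCounts(rep)$surviving
  expect_equal(counts[1], 300)
  expect_true(all(diff(counts) <= 0))
  expect_true(all(variantKey(candidates(rep)) %in% variantKey(v)))
})

test_that("empty input yields an all-zero funnel", {
  v <- randomVariantTable(5, seed = 1)[0, ]
  rep <- runPrioritization(v, cfgDefault)
  expect_true(all(stageCounts(rep)$surviving == 0))
  expect_equal(nrow(candidates(rep)), 0L)
})

test_that("vacuous gates pass everything that reaches them", {
  cfg <- filterConfig(genePanel = c("APC", "MUTYH", "OTHER"),
                      maxAf = 1.0, spliceScoreMin = 0)
  v <- randomVariantTable(150, seed = 24)
  v$af[!is.na(v$af) & v$af >= 1] <- 0.999
  rep <- runPrioritization(v, cfg)
  st <- stageCounts(rep)
  expect_equal(st$surviving[st$stage == "frequency"],
               st$surviving[st$stage == "panel"])
  ## splice gate at 0 still drops unscored and zero-scored variants
  afterDuo <- st$surviving[st$stage == "duo"]
  expect_lte(st$surviving[st$stage == "splice"], afterDuo)
})

test_that("the final candidate set is invariant to filter order", {
  v <- randomVariantTable(250, seed = 25)
  cfg <- cfgDefault
  filters <- list(
    quality = function(x) filterQuality(x, cfg),
    panel = function(x) filterPanel(x, cfg@genePanel),
    frequency = function(x) filterFrequency(x, cfg@maxAf),
    duo = function(x) filterDuo(x),
    splice = function(x) filterSpliceScore(x, cfg@spliceScoreMin))
  ref <- NULL
  set.seed(26)
  orders <- c(list(names(filters)),
              lapply(1:5, function(i) sample(names(filters))))
  for (ord in orders) {
    out <- v
    for (f in ord) out <- filters[[f]](out)
    keys <- sort(variantKey(out))
    if (is.null(ref)) ref <- keys else expect_equal(keys, ref)
  }
  expect_setequal(variantKey(runPrioritization(v, cfg)@candidates), ref)
})
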