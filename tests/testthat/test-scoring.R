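test_that("builtin schemes encode the published genotype-score maps", {
  lit <- builtinScheme("literature")
  expect_equal(schemeComponents(lit)$COMT$map, c(AA = 2L, AG = 1L, GG = 0L))
  expect_equal(schemeComponents(lit)$rs405509$map, c(GG = 2L, GT = 1L, TT = 0L))
  expect_equal(schemeComponents(lit)$APOE_e$map, c(`e4-` = 2L, `e4+` = 0L))
  expect_equal(schemeNormaliser(lit), 100 / 14)
  dl <- builtinScheme("data_led")
  expect_equal(schemeComponents(dl)$COMT$map, c(GG = 2L, AG = 1L, AA = 0L))
  expect_equal(schemeComponents(dl)$rs405509$map, c(TT = 2L, GT = 1L, GG = 0L))
  expect_equal(schemeComponents(dl)$NOS3$map, c(TT = 2L, CT = 1L, CC = 0L))
  ## the two schemes differ in exactly the re-scored components
  nms <- names(schemeComponents(lit))
  differing <- nms[vapply(nms, function(nm) {
    a <- schemeComponents(lit)[[nm]]$map; b <- schemeComponents(dl)[[nm]]$map
    !identical(a[sort(names(a))], b[sort(names(b))])
  }, TRUE)]
  expect_setequal(differing, c("rs405509", "COMT"))
  flip <- builtinScheme("literature_nos3_flipped")
  expect_equal(schemeComponents(flip)$NOS3$map, c(CC = 2L, CT = 1L, TT = 0L))
  expect_error(builtinScheme("nope"), "literature")
})

test_that("scheme files round-trip through YAML", {
  sch <- builtinScheme("data_led")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeScheme(sch, f)
  back <- readScheme(f)
  expect_equal(schemeComponents(back), schemeComponents(sch))
  expect_equal(schemeNormaliser(back), schemeNormaliser(sch))
})

test_that("TGS arithmetic matches the published scale anchors", {
  s <- scoreCohort(toyCohort(), builtinScheme("literature"))
  expect_equal(s$tgs[1], 100)           # perfect profile
  expect_equal(s$tgs[2], 0)             # worst profile
  expect_equal(round(s$tgs[3], 1), 92.9) # component sum 13
  expect_equal(round(s$tgs[4], 1), 21.4) # component sum 3
  expect_true(all(s$complete))
  ## tgs equals normaliser * component sum
  comps <- names(schemeComponents(builtinScheme("literature")))
  expect_equal(s$tgs, rowSums(s[, comps]) * 100 / 14)
})

test_that("every TGS is one of the 15 multiples of 100/14", {
  coh <- simulateCohort(simulationSpec(seed = 21))
  s <- scoreCohort(coh)
  k <- s$tgs / (100 / 14)
  expect_equal(k, round(k))
  expect_true(all(k >= 0 & k <= 14))
  expect_lte(length(unique(s$tgs)), 15)
})

test_that("raising any component score never lowers the TGS", {
  sch <- builtinScheme("literature")
  coh <- simulateCohort(simulationSpec(groupSizes = c(athlete = 50), seed = 5))
  s <- scoreCohort(coh, sch)
  ## flip each individual's COMT call to the top-scoring genotype
  calls <- genotypeCalls(coh)
  calls[, "COMT"] <- "AA"
  s2 <- scoreCohort(genotypeCohort(calls, groupLabels(coh)), sch)
  expect_true(all(s2$tgs >= s$tgs))
})

test_that("missing components follow the complete-case policy by default", {
  coh <- toyCohort()
  calls <- genotypeCalls(coh)
  calls[1, "COMT"] <- NA
  calls[2, "rs7412"] <- NA  # breaks the APOE component
  coh2 <- genotypeCohort(calls, groupLabels(coh))
  s <- scoreCohort(coh2)
  expect_false(s$complete[1])
  expect_false(s$complete[2])
  expect_true(all(is.na(s$tgs[1:2])))
  expect_false(any(is.na(s$tgs[3:4])))
  ## imputation fills with the group-expected component score instead
  si <- scoreCohort(coh2, missing = "impute")
  expect_false(any(is.na(si$tgs)))
})

test_that("distribution summaries use the bias-corrected kurtosis", {
  ## degenerate: constant sample has SD 0 and undefined kurtosis
  s <- summarizeTgs(rep(50, 10))
  expect_equal(s$sd, 0)
  expect_true(is.na(s$kurtosis))
  ## large normal sample: excess kurtosis near 0
  set.seed(31)
  s <- summarizeTgs(stats::rnorm(20000))
  expect_lt(abs(s$kurtosis), 0.1)
  ## the closed-form kurtosis standard error at n = 1000
  n <- 1000
  seSkew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  expect_equal(summarizeTgs(stats::rnorm(n))$se_kurtosis,
               2 * seSkew * sqrt((n^2 - 1) / ((n - 3) * (n + 5))))
})

test_that("quartile membership is computed on the pooled distribution", {
  ## pooled scores 1..8: Q1 = 2.75, Q3 = 6.25 by linear interpolation,
  ## so bottom = {1,2}, top = {7,8}
  m <- quartileMembership(1:4, 5:8)
  expect_equal(unname(m), rbind(c(0L, 2L), c(2L, 0L)))
  ## two identical groups split evenly; chi-square is 0
  m <- quartileMembership(rep(1:8, 4), rep(1:8, 4))
  expect_equal(m[1, ], m[2, ])
  expect_equal(chi2Contingency(m)$chi2, 0)
  ## complete separation: group A owns the whole top quartile
  m <- quartileMembership(101:108, 1:8, labels = c("A", "B"))
  expect_equal(unname(m["A", ]), c(4L, 0L))
  expect_equal(unname(m["B", ]), c(0L, 4L))
})

test_that("expected TGS from full enumeration matches component marginals", {
  ft <- rugbyFrequencies()
  for (nm in c("literature", "data_led")) {
    sch <- builtinScheme(nm)
    en <- enumerateTgs(sch, ft, "athlete")
    ## independent additive components: mean = normaliser * sum of marginals
    marg <- sum(vapply(schemeComponents(sch), function(cmp) {
      fr <- locusFrequencies(ft, "athlete", cmp$source)
      sum(cmp$map[names(fr)] * fr)
    }, 0))
    expect_equal(en$mean, marg * 100 / 14)
    expect_equal(sum(en$distribution$prob), 1)
  }
  ## the data-led athlete expectation sits near 59.7 on the 0-100 scale
  expect_equal(enumerateTgs(builtinScheme("data_led"), ft, "athlete")$mean,
               59.7, tolerance = 0.002)
})

test_that("simulated cohort means converge to the enumerated expectation", {
  ft <- rugbyFrequencies()
  expected <- enumerateTgs(builtinScheme("data_led"), ft, "athlete")$mean
  spec <- simulationSpec(groupSizes = c(athlete = 20000), seed = 61)
  s <- scoreCohort(simulateCohort(spec), builtinScheme("data_led"))
  sem <- stats::sd(s$tgs) / sqrt(length(s$tgs))
  expect_lt(abs(mean(s$tgs) - expected), 4 * sem)
})
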