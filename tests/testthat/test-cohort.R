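test_that("genotype tables round-trip through the TSV dialect", {
  coh <- toyCohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(coh, f)
  back <- readGenotypeTable(f)
  expect_identical(genotypeCalls(back), genotypeCalls(coh))
  expect_identical(groupLabels(back), groupLabels(coh))
  expect_identical(sampleIDs(back), sampleIDs(coh))
  ## writing again reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("genotypes are unordered allele pairs, canonicalised on input", {
  expect_identical(canonicalGenotype(c("GA", "AG", "TC", NA)),
                   c("AG", "AG", "CT", NA))
  calls <- genotypeCalls(toyCohort())
  calls[1, "COMT"] <- "GA"
  calls2 <- calls; calls2[1, "COMT"] <- "AG"
  c1 <- genotypeCohort(calls, group = rep("g", 4))
  c2 <- genotypeCohort(calls2, group = rep("g", 4))
  expect_identical(genotypeCalls(c1), genotypeCalls(c2))
})

test_that("invalid input is rejected with informative errors", {
  coh <- toyCohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  ## a disallowed allele symbol names the locus and sample
  calls <- genotypeCalls(coh)
  calls[2, "COMT"] <- "AC"
  expect_error(genotypeCohort(calls, group = rep("g", 4), sample_id = paste0("S", 1:4)),
               "COMT.*S2|S2.*COMT")
  ## a missing required column is named
  df <- data.frame(sample_id = sampleIDs(coh), group = groupLabels(coh),
                   genotypeCalls(coh), check.names = FALSE)
  df$COMT <- NULL
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeTable(f), "COMT")
})

test_that("APOE diplotypes derive correctly from rs429358 + rs7412", {
  ## all unambiguous combinations, enumerated by hand from the haplotype map
  ## e2=(T,T), e3=(T,C), e4=(C,C) over (rs429358, rs7412)
  cases <- list(
    list("TT", "CC", "e3/e3", FALSE), list("TT", "CT", "e2/e3", FALSE),
    list("TT", "TT", "e2/e2", FALSE), list("CT", "CC", "e3/e4", TRUE),
    list("CC", "CC", "e4/e4", TRUE))
  for (cs in cases) {
    d <- deriveApoe(cs[[1]], cs[[2]])
    expect_identical(d$diplotype, cs[[3]])
    expect_identical(d$e4_carrier, cs[[4]])
  }
  ## symmetric under within-SNP allele order
  expect_identical(deriveApoe("TC", "CT")$diplotype,
                   deriveApoe("CT", "TC")$diplotype)
  ## double heterozygote: two resolutions exist ({e2,e4} and {e1,e3});
  ## the convention excludes the rare e1 haplotype
  expect_identical(deriveApoe("CT", "CT")$diplotype, "e2/e4")
  expect_true(is.na(deriveApoe("CT", "CT", ambiguous = "exclude")$diplotype))
  ## combinations forcing an e1 haplotype in every resolution are unresolvable
  for (g in list(c("CC", "TT"), c("CC", "CT"), c("CT", "TT"))) {
    d <- deriveApoe(g[1], g[2])
    expect_false(d$resolvable)
    expect_true(is.na(d$diplotype))
  }
})

test_that("genotype frequencies are per-locus complete-call proportions", {
  calls <- matrix("AA", 10, 8, dimnames = list(NULL, defaultPanel()@loci$name))
  calls[, "rs429358"] <- "TT"; calls[, "rs7412"] <- "CC"
  calls[, "rs405509"] <- "GG"; calls[, "BDNF_AS"] <- "CC"
  calls[, "MAPT"] <- "CC"; calls[, "NOS3"] <- "CC"
  coh <- genotypeCohort(calls, group = rep("g", 10))
  ft <- genotypeFrequencies(coh)
  expect_equal(locusFrequencies(ft, "g", "COMT"),
               c(AA = 1, AG = 0, GG = 0))
  ## arithmetic: counts {AA:2, AG:5, GG:3} -> 0.2/0.5/0.3, sums to 1
  calls[, "COMT"] <- rep(c("AA", "AG", "GG"), c(2, 5, 3))
  ## missing calls drop out of that locus only
  calls[1, "MAPT"] <- NA
  coh <- genotypeCohort(calls, group = rep("g", 10))
  ft <- genotypeFrequencies(coh)
  expect_equal(locusFrequencies(ft, "g", "COMT"),
               c(AA = 0.2, AG = 0.5, GG = 0.3))
  expect_equal(sum(ft@counts$g$MAPT), 9)
  for (loc in defaultPanel()@loci$name)
    expect_equal(sum(locusFrequencies(ft, "g", loc)), 1)
})

test_that("simulated frequencies converge to the generator parameters", {
  spec <- simulationSpec(groupSizes = c(nonathlete = 100000), seed = 404)
  coh <- simulateCohort(spec)
  ft <- genotypeFrequencies(coh)
  expect_equal(unname(locusFrequencies(ft, "nonathlete", "COMT")["AA"]),
               0.302, tolerance = 0.005 / 0.302)
  ## every locus matches its published frequency parameters within binomial error
  ref <- rugbyFrequencies()
  for (loc in c("ANKK1", "rs405509", "BDNF_AS", "COMT", "MAPT", "NOS3", "APOE_e"))
    expect_equal(locusFrequencies(ft, "nonathlete", loc),
                 locusFrequencies(ref, "nonathlete", loc), tolerance = 0.02)
})

test_that("Hardy-Weinberg chi-square matches hand-computed oracles", {
  ## exact HWE proportions: chi2 = 0, p = 1
  h <- hweTest(c(25, 50, 25))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  ## no heterozygotes at p = q = 0.5: expected 25/50/25, chi2 = 25+50+25
  h <- hweTest(c(50, 0, 50))
  expect_equal(h$chi2, 100)
  ## monomorphic locus: not applicable, not p = 1
  h <- hweTest(c(100, 0, 0))
  expect_false(h$applicable)
  expect_true(is.na(h$p))
  ## chi2 >= 0 always, and matches the textbook formula on random counts
  set.seed(9)
  for (i in 1:50) {
    cnt <- stats::rmultinom(1, 200, c(.3, .5, .2))[, 1]
    h <- hweTest(cnt)
    p <- (2 * cnt[1] + cnt[2]) / 400
    ex <- 200 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    expect_equal(h$chi2, sum((cnt - ex)^2 / ex))
    expect_gte(h$chi2, 0)
  }
})

test_that("HWE test holds its nominal type-I error under the null", {
  set.seed(123)
  p <- 0.6
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  rej <- mean(replicate(1000, {
    hweTest(stats::rmultinom(1, 300, probs)[, 1])$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("cohorts drawn in HWE mode pass HWE QC", {
  spec <- simulationSpec(groupSizes = c(athlete = 2000), mode = "hwe", seed = 77)
  hw <- hweTable(simulateCohort(spec))
  expect_true(all(hw$applicable))
  expect_gt(min(hw$p), 0.001)
})
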