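test_that("cell labelling follows the case:control ratio threshold", {
  lab <- labelCells(c(a = 10, b = 5, c = 0, d = 3),
                    c(a = 5, b = 10, c = 0, d = 0), threshold = 1)
  expect_equal(lab$label, c("high", "low", "empty", "high"))
  ## ratio ties label high
  expect_equal(labelCells(4, 4, threshold = 1)$label, "high")
  expect_error(labelCells(1, 1, threshold = 0), "threshold")
})

test_that("majority labelling maximises training balanced accuracy", {
  ## balanced toy data on a 4-cell table: compare against every one of the
  ## 2^4 possible labelings by brute force
  cellOf <- rep(c("a", "b", "c", "d"), each = 10)
  isCase <- c(rep(c(TRUE, FALSE), c(7, 3)), rep(c(TRUE, FALSE), c(4, 6)),
              rep(c(TRUE, FALSE), c(6, 4)), rep(c(TRUE, FALSE), c(2, 8)))
  ba <- function(highSet) {
    pred <- cellOf %in% highSet
    (mean(pred[isCase]) + mean(!pred[!isCase])) / 2
  }
  cells <- c("a", "b", "c", "d")
  allBa <- vapply(0:15, function(m) ba(cells[bitwAnd(m, 2^(0:3)) > 0]), 0)
  counts <- table(factor(cellOf, cells), isCase)
  majority <- labelCells(counts[, "TRUE"], counts[, "FALSE"], threshold = 1)
  expect_equal(ba(majority$cell[majority$label == "high"]), max(allBa))
})

test_that("with folds = 1 the search equals brute-force enumeration", {
  set.seed(40)
  n <- 50
  attrs <- data.frame(A = sample(c("x", "y", "z"), n, TRUE),
                      B = sample(c("x", "y"), n, TRUE),
                      C = sample(c("x", "y", "z"), n, TRUE),
                      D = sample(c("x", "y"), n, TRUE),
                      E = sample(c("x", "y", "z"), n, TRUE))
  isCase <- sample(c(TRUE, FALSE), n, TRUE)
  ## independent oracle: whole-sample balanced accuracy of every pair,
  ## majority-style labelling recomputed from scratch
  thr <- sum(isCase) / sum(!isCase)
  oracle <- function(cb) {
    key <- do.call(paste, c(attrs[cb], sep = ":"))
    high <- names(which(tapply(isCase, key, sum) /
                          pmax(1e-9, tapply(!isCase, key, sum)) >= thr))
    pred <- key %in% high
    (mean(pred[isCase]) + mean(!pred[!isCase])) / 2
  }
  pairs <- utils::combn(names(attrs), 2, simplify = FALSE)
  best <- pairs[[which.max(vapply(pairs, oracle, 0))]]
  res <- mdrSearch(attrs, isCase, kRange = 2, folds = 1, seed = 1)
  expect_setequal(mdrCombination(res), best)
  expect_equal(res@trainingBA, max(vapply(pairs, oracle, 0)))
  expect_gte(res@trainingBA, 0.5)  # majority labelling can't do worse
})

test_that("the search is invariant to attribute order and category names", {
  coh <- simulateCohort(xorPlantSpec(n = 400, nLoci = 4, seed = 9))
  attrs <- mdrAttributes(coh)
  isCase <- groupLabels(coh) == "case"
  r1 <- mdrSearch(attrs, isCase, kRange = 2, folds = 5, seed = 2)
  r2 <- mdrSearch(attrs[, rev(names(attrs))], isCase, kRange = 2, folds = 5, seed = 2)
  expect_setequal(mdrCombination(r1), mdrCombination(r2))
  expect_equal(mdrTestingBA(r1), mdrTestingBA(r2))
  ## renaming genotype categories changes nothing
  attrs3 <- as.data.frame(lapply(attrs, function(a)
    c(AA = "g0", AB = "g1", BB = "g2")[a]), stringsAsFactors = FALSE)
  r3 <- mdrSearch(attrs3, isCase, kRange = 2, folds = 5, seed = 2)
  expect_setequal(mdrCombination(r3), mdrCombination(r1))
  expect_equal(mdrTestingBA(r3), mdrTestingBA(r1))
})

test_that("a fixed seed reproduces the whole selection path", {
  coh <- simulateCohort(xorPlantSpec(n = 300, nLoci = 5, seed = 14))
  r1 <- mdrSearch(coh, caseGroups = "case", kRange = 1:2, folds = 10, seed = 7)
  r2 <- mdrSearch(coh, caseGroups = "case", kRange = 1:2, folds = 10, seed = 7)
  expect_identical(r1@perFold, r2@perFold)
  expect_identical(mdrPerSize(r1), mdrPerSize(r2))
})

test_that("a planted zero-marginal XOR interaction is recovered", {
  coh <- simulateCohort(xorPlantSpec(n = 800, nLoci = 6, seed = 2))
  ## single-locus chi-squares show no marginal signal at the planted pair
  isCase <- groupLabels(coh) == "case"
  for (loc in c("L1", "L2")) {
    tab <- table(genotypeCalls(coh)[, loc], isCase)
    expect_gt(chi2Contingency(tab)$p, 0.01)
  }
  res <- mdrSearch(coh, caseGroups = "case", kRange = 2, folds = 10, seed = 2)
  expect_setequal(mdrCombination(res), c("L1", "L2"))
  expect_gte(mdrCvc(res), 8L)
  expect_gt(mdrTestingBA(res), 0.6)
})

test_that("null labels give chance-level testing accuracy", {
  spec <- simulationSpec(groupSizes = c(all = 1000),
                         freqTable = uniformFreqTable(6, sizes = 1000),
                         panel = syntheticPanel(6), seed = 10)
  coh <- simulateCohort(spec)
  set.seed(99)
  isCase <- sample(c(TRUE, FALSE), length(coh), replace = TRUE)
  res <- mdrSearch(mdrAttributes(coh), isCase, kRange = 2, folds = 10, seed = 4)
  expect_lt(abs(mdrTestingBA(res) - 0.5), 0.05)
})

test_that("single binary attribute with complete separation scores 1.0", {
  attrs <- data.frame(A = rep(c("p", "q"), each = 20))
  isCase <- rep(c(TRUE, FALSE), each = 20)
  res <- mdrSearch(attrs, isCase, kRange = 1, folds = 5, seed = 1)
  expect_equal(mdrTestingBA(res), 1)
  expect_equal(mdrCvc(res), 5L)
})

test_that("single-level attributes are dropped with a warning", {
  attrs <- data.frame(A = rep(c("p", "q"), 20), B = "const")
  isCase <- rep(c(TRUE, FALSE), 20)
  expect_warning(res <- mdrSearch(attrs, isCase, kRange = 1, folds = 2, seed = 1),
                 "single-level")
  expect_equal(mdrCombination(res), "A")
})

test_that("carrier-combination frequencies count carriers at every locus", {
  ## 4-individual toy: only the GG/CT individual carries G at COMT and C at MAPT
  calls <- genotypeCalls(toyCohort())[c(1, 1, 1, 1), ]
  calls[, "COMT"] <- c("AA", "AG", "GG", "AA")
  calls[, "MAPT"] <- c("CC", "TT", "CT", "TT")
  coh <- genotypeCohort(calls, group = rep("g", 4), sample_id = paste0("I", 1:4))
  cf <- carrierCombinationFrequency(coh, c(COMT = "G", MAPT = "C"))
  expect_equal(cf$carriers, 1L)
  expect_equal(cf$proportion, 0.25)
  ## all carriers when every genotype holds the allele
  calls[, "COMT"] <- "GG"; calls[, "MAPT"] <- "CC"
  coh <- genotypeCohort(calls, group = rep("g", 4), sample_id = paste0("I", 1:4))
  expect_equal(carrierCombinationFrequency(coh, c(COMT = "G", MAPT = "C"))$proportion, 1)
  ## allele-level counting uses a 2N denominator
  cf2 <- carrierCombinationFrequency(coh, c(COMT = "G", MAPT = "C"), mode = "allele")
  expect_equal(cf2$n, 8L)
  expect_equal(cf2$proportion, 1)
  expect_error(carrierCombinationFrequency(coh, c(COMT = "C")), "allele")
})

test_that("carrier frequency converges to the product of marginals", {
  coh <- simulateCohort(simulationSpec(groupSizes = c(nonathlete = 100000),
                                       seed = 55))
  cf <- carrierCombinationFrequency(coh, c(COMT = "G", MAPT = "C"))
  ## independence across loci: P(G carrier) * P(C carrier) from the
  ## generator's own parameters
  expect_equal(cf$proportion, (1 - 0.302) * (0.047 + 0.314), tolerance = 0.02)
})
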