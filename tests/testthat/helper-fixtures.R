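## Shared in-code fixtures.

## a tiny hand-written cohort on the default 8-locus panel
toyCohort <- function() {
  calls <- rbind(
    ## perfect literature profile: all component scores 2
    c("GG", "TT", "CC", "GG", "CC", "AA", "CC", "TT"),
    ## worst profile: all component scores 0 (rs429358 CC -> e4/e4)
    c("AA", "CC", "CC", "TT", "TT", "GG", "TT", "CC"),
    ## sum 13: ANKK1 heterozygous, rest preferable
    c("AG", "TT", "CC", "GG", "CC", "AA", "CC", "TT"),
    ## sum 3: ANKK1 het, rs405509 het, BDNF het, rest 0
    c("AG", "CC", "CC", "GT", "CT", "GG", "TT", "CC"))
  colnames(calls) <- defaultPanel()@loci$name
  genotypeCohort(calls, group = c("athlete", "athlete", "nonathlete", "nonathlete"))
}

## uniform-frequency table for n generic A/B loci (HWE at allele freq 0.5)
uniformFreqTable <- function(nLoci, groups = "all", sizes = 100) {
  fr <- stats::setNames(rep(list(stats::setNames(c(.25, .5, .25),
                                                 c("AA", "AB", "BB"))), nLoci),
                        paste0("L", seq_len(nLoci)))
  frequencyTable(stats::setNames(rep(list(fr), length(groups)), groups),
                 stats::setNames(rep_len(sizes, length(groups)), groups))
}

## spec with a planted XOR interaction on L1 x L2 among nLoci generic loci
xorPlantSpec <- function(n = 800, nLoci = 6, seed = 1, pHigh = 0.9, pLow = 0.1) {
  simulationSpec(groupSizes = c(all = n),
                 freqTable = uniformFreqTable(nLoci, sizes = n),
                 panel = syntheticPanel(nLoci),
                 plant = penetrancePlant(c("L1", "L2"),
                                         xorPenetrance(pHigh = pHigh, pLow = pLow)),
                 seed = seed)
}
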