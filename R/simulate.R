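## Seeded synthetic-cohort generator.
##
## Loci are drawn independently (linkage equilibrium: the study panel's loci
## lie on different chromosomes) from per-group genotype frequencies. The
## APOE pair rs429358/rs7412 is drawn as an epsilon diplotype matching the
## group's epsilon4-carrier frequency and back-converted to SNP genotypes,
## so the derived attribute reproduces the target e4+/e4- rates exactly in
## expectation.

#' Construct a simulation specification
#'
#' Defaults reproduce the study conditions: 635 elite rugby athletes and 722
#' non-athletes drawn from the published genotype frequency table
#' ([rugbyFrequencies()]) under linkage equilibrium, no missingness, no
#' planted effect.
#'
#' @param groupSizes named group sizes.
#' @param freqTable a [CohortFrequencyTable-class] of category probabilities.
#' @param panel the [GenotypePanel-class] to simulate.
#' @param freqGroup named map simulated group -> frequency group, for groups
#'   (e.g. positional subgroups) that share a frequency table entry;
#'   identity where omitted.
#' @param mode `"genotype"` (draw the printed category frequencies, default)
#'   or `"hwe"` (draw Hardy-Weinberg proportions at the implied allele
#'   frequencies).
#' @param missingness per-locus completely-at-random missing-call rate.
#' @param plant optional [PenetrancePlant-class]; when present,
#'   [simulateCohort()] relabels the cohort case/control via [plantLabels()].
#' @param seed integer seed or NULL.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(groupSizes = c(athlete = 635, nonathlete = 722),
                           freqTable = rugbyFrequencies(),
                           panel = defaultPanel(),
                           freqGroup = character(0),
                           mode = c("genotype", "hwe"),
                           missingness = 0, plant = NULL, seed = NULL) {
  mode <- match.arg(mode)
  new("SimulationSpec", panel = panel, groupSizes = groupSizes,
      freqTable = freqTable, freqGroup = freqGroup, mode = mode,
      missingness = missingness, plant = plant, seed = seed)
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "), "\n")
  cat("  mode:", object@mode, "| missingness:", object@missingness,
      "| plant:", if (is.null(object@plant)) "none" else
        paste(object@plant@loci, collapse = " x "),
      "| seed:", if (is.null(object@seed)) "none" else object@seed, "\n")
})

## HWE-mode conversion: genotype category probabilities -> HWE proportions
## at the implied allele frequency (categories in hom1/het/hom2 order)
.hweProbs <- function(fr) {
  p <- fr[1] + fr[2] / 2
  stats::setNames(c(p^2, 2 * p * (1 - p), (1 - p)^2), names(fr))
}

## epsilon allele frequencies whose HWE diplotypes hit the target e4+ rate:
## f(e4) from 1-(1-f4)^2 = P(e4+), e2:e3 kept at the reference ratio
.epsAlleleFreqs <- function(e4plus, base = c(e2 = 0.08, e3 = 0.77, e4 = 0.15)) {
  f4 <- 1 - sqrt(1 - e4plus)
  rest <- base[c("e2", "e3")] / sum(base[c("e2", "e3")]) * (1 - f4)
  c(rest, e4 = unname(f4))
}

#' Simulate a case-control genotype cohort
#'
#' Draws every panel locus independently from the spec's per-group category
#' probabilities (`"genotype"` mode) or from Hardy-Weinberg proportions at
#' the implied allele frequencies (`"hwe"` mode). If the panel contains the
#' APOE pair and the frequency table an `"APOE_e"` entry, the two SNPs are
#' generated through an epsilon diplotype draw (alleles e2/e3/e4 in HWE,
#' e4 frequency calibrated to the target e4+ rate, e2:e3 at the reference
#' European ratio) and back-converted via e2 = (T,T), e3 = (T,C),
#' e4 = (C,C) over (rs429358, rs7412). Missingness is applied per call,
#' completely at random. A planted penetrance effect, when present,
#' relabels individuals case/control afterwards.
#'
#' Reproducible: the spec seed (or the `seed` argument) fully determines the
#' cohort.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed overrides the spec seed when non-NULL.
#' @return a [GenotypeCohort-class].
#' @export
#' @examples
#' coh <- simulateCohort(simulationSpec(seed = 7))
#' table(groupLabels(coh))
simulateCohort <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec@seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  pl <- spec@panel@loci
  hasApoePair <- all(c("rs429358", "rs7412") %in% pl$name)
  groups <- names(spec@groupSizes)
  blocks <- lapply(groups, function(g) {
    fgName <- if (g %in% names(spec@freqGroup)) spec@freqGroup[[g]] else g
    fg <- spec@freqTable@freq[[fgName]]
    if (is.null(fg)) stop("frequency table has no group '", fgName, "'")
    n <- spec@groupSizes[[g]]
    m <- matrix(NA_character_, n, nrow(pl), dimnames = list(NULL, pl$name))
    useEps <- hasApoePair && "APOE_e" %in% names(fg)
    for (j in seq_len(nrow(pl))) {
      loc <- pl$name[j]
      if (useEps && loc %in% c("rs429358", "rs7412")) next
      fr <- fg[[loc]]
      if (is.null(fr)) stop("frequency table group '", fgName,
                            "' lacks panel locus '", loc, "'")
      cats <- validGenotypes(pl$allele1[j], pl$allele2[j])
      if (!setequal(names(fr), cats))
        stop("categories for ", loc, " must be ", paste(cats, collapse = "/"))
      fr <- fr[cats]
      if (spec@mode == "hwe") fr <- .hweProbs(fr)
      m[, loc] <- sample(cats, n, replace = TRUE, prob = fr)
    }
    if (useEps) {
      eps <- .epsAlleleFreqs(fg[["APOE_e"]][["e4+"]])
      h1 <- sample(names(eps), n, replace = TRUE, prob = eps)
      h2 <- sample(names(eps), n, replace = TRUE, prob = eps)
      a112 <- function(h) ifelse(h == "e4", "C", "T")
      a158 <- function(h) ifelse(h == "e2", "T", "C")
      m[, "rs429358"] <- canonicalGenotype(paste0(a112(h1), a112(h2)))
      m[, "rs7412"] <- canonicalGenotype(paste0(a158(h1), a158(h2)))
    }
    m
  })
  calls <- do.call(rbind, blocks)
  group <- rep(groups, spec@groupSizes[groups])
  if (spec@missingness > 0) {
    drop <- matrix(stats::runif(length(calls)) < spec@missingness,
                   nrow(calls), ncol(calls))
    calls[drop] <- NA_character_
  }
  ids <- sprintf("%s_%04d", group, unlist(lapply(spec@groupSizes[groups], seq_len)))
  cohort <- genotypeCohort(calls, group = group, panel = spec@panel,
                           sample_id = ids)
  if (!is.null(spec@plant)) cohort <- plantLabels(cohort, spec@plant)
  cohort
}

#' Build a penetrance plant
#'
#' @param loci the two target locus names.
#' @param penetrance matrix of case probabilities, dimnames = genotype
#'   categories of the two loci.
#' @return a [PenetrancePlant-class].
#' @export
penetrancePlant <- function(loci, penetrance) {
  new("PenetrancePlant", loci = loci, penetrance = penetrance)
}

#' XOR-style two-locus penetrance table
#'
#' Case probability `pHigh` when exactly one of the two loci is
#' heterozygous, `pLow` otherwise. When both loci have heterozygote
#' frequency 1/2 (allele frequency 0.5 under HWE) every single-locus
#' marginal penetrance equals `(pHigh + pLow) / 2`: a pure interaction with
#' zero marginal effects, invisible to single-locus tests but recoverable by
#' a genuine interaction search.
#'
#' @param categories1,categories2 the 3 genotype categories of each locus
#'   (hom/het/hom order).
#' @param pHigh,pLow the two case probabilities.
#' @return penetrance matrix usable in [penetrancePlant()].
#' @export
xorPenetrance <- function(categories1 = c("AA", "AB", "BB"),
                          categories2 = c("AA", "AB", "BB"),
                          pHigh = 0.9, pLow = 0.1) {
  het1 <- seq_along(categories1) == 2
  het2 <- seq_along(categories2) == 2
  m <- outer(het1, het2, function(a, b) ifelse(xor(a, b), pHigh, pLow))
  dimnames(m) <- list(categories1, categories2)
  m
}

#' Apply a planted penetrance model as case/control labels
#'
#' Each individual becomes a case with the probability in the penetrance
#' cell of its two-locus genotype; group labels are replaced by
#' `"case"`/`"control"`. Individuals missing either target call keep
#' penetrance equal to the cell-average and are labelled accordingly.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param plant a [PenetrancePlant-class].
#' @param seed optional integer seed.
#' @return the relabelled [GenotypeCohort-class].
#' @export
plantLabels <- function(cohort, plant, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  calls <- genotypeCalls(cohort)
  miss <- setdiff(plant@loci, colnames(calls))
  if (length(miss)) stop("plant loci not in panel: ", paste(miss, collapse = ", "))
  g1 <- calls[, plant@loci[1]]; g2 <- calls[, plant@loci[2]]
  p <- rep(mean(plant@penetrance), length(g1))
  ok <- !is.na(g1) & !is.na(g2)
  p[ok] <- plant@penetrance[cbind(g1[ok], g2[ok])]
  isCase <- stats::runif(length(p)) < p
  new("GenotypeCohort", calls = calls,
      group = ifelse(isCase, "case", "control"), panel = cohortPanel(cohort))
}
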