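#' @import methods
NULL

#' GenotypePanel: the locus panel under study
#'
#' Describes the candidate polymorphisms an analysis operates on: locus name,
#' dbSNP identifier and the two allele symbols, plus (optionally) the allele
#' suspected to carry risk. All cohort, scoring and simulation machinery is
#' driven by a panel, so alternative panels (e.g. synthetic loci for method
#' validation) plug in without code changes.
#'
#' @slot loci data.frame with columns `name`, `rsid`, `allele1`, `allele2`,
#'   `risk_allele`; row names equal `name`. Alleles are single characters and
#'   must differ; `risk_allele` is one of the two alleles or `"undetermined"`.
#' @seealso [defaultPanel()], [genotypePanel()]
#' @export
setClass("GenotypePanel", slots = c(loci = "data.frame"))

setValidity("GenotypePanel", function(object) {
  df <- object@loci
  need <- c("name", "rsid", "allele1", "allele2", "risk_allele")
  if (!all(need %in% colnames(df)))
    return(paste("loci must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$name)) return("duplicated locus names")
  if (any(nchar(df$allele1) != 1L) || any(nchar(df$allele2) != 1L))
    return("alleles must be single characters")
  if (any(df$allele1 == df$allele2)) return("the two alleles of a locus must differ")
  ok <- df$risk_allele == "undetermined" |
    df$risk_allele == df$allele1 | df$risk_allele == df$allele2
  if (!all(ok)) return("risk_allele must be one of the locus alleles or 'undetermined'")
  TRUE
})

#' GenotypeCohort: individual-level genotype calls plus group labels
#'
#' The central data container: one row per individual, one column per panel
#' locus, each call an unordered allele pair stored in canonical (sorted)
#' two-character form, `NA` for missing. Group labels (e.g. athlete subgroup
#' vs non-athlete, or case vs control) ride alongside.
#'
#' @slot calls character matrix (samples x loci), canonical genotypes or NA.
#' @slot group character vector of group labels, one per sample.
#' @slot panel the [GenotypePanel-class] the calls are validated against.
#' @seealso [genotypeCohort()], [readGenotypeTable()], [simulateCohort()]
#' @export
setClass("GenotypeCohort",
         slots = c(calls = "matrix", group = "character", panel = "GenotypePanel"))

setValidity("GenotypeCohort", function(object) {
  m <- object@calls
  pl <- object@panel@loci
  if (!is.character(m)) return("calls must be a character matrix")
  if (!identical(colnames(m), pl$name))
    return("calls columns must match panel loci (same names, same order)")
  if (nrow(m) != length(object@group))
    return("group must have one label per sample")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("calls must have unique sample ids as row names")
  for (j in seq_len(ncol(m))) {
    allowed <- validGenotypes(pl$allele1[j], pl$allele2[j])
    bad <- !is.na(m[, j]) & !(m[, j] %in% allowed)
    if (any(bad)) {
      i <- which(bad)[1L]
      return(sprintf("invalid genotype '%s' at locus %s (sample %s): alleles must be %s/%s",
                     m[i, j], pl$name[j], rownames(m)[i], pl$allele1[j], pl$allele2[j]))
    }
  }
  TRUE
})

#' ScoringScheme: per-locus genotype-to-score maps for an additive TGS
#'
#' An ordered set of score components. Each component draws on either a raw
#' bi-allelic locus (genotype categories scored 0/1/2 under the codominant
#' model) or the derived APOE epsilon attribute (`e4+` scored 0, `e4-` scored
#' 2, no intermediate score). The total genotype score of an individual is
#' `normaliser * sum(component scores)`, placing it on a 0-100 scale.
#'
#' @slot name scheme identifier.
#' @slot components named list; each element is `list(source=, map=)` where
#'   `source` is a panel locus name or `"APOE_e"` and `map` a named integer
#'   vector over that source's categories with values in 0..2.
#' @slot normaliser scale factor, `100 / (2 * number of components)`.
#' @seealso [builtinScheme()], [scoreCohort()]
#' @export
setClass("ScoringScheme",
         slots = c(name = "character", components = "list", normaliser = "numeric"))

setValidity("ScoringScheme", function(object) {
  comps <- object@components
  if (length(comps) < 1L) return("at least one component required")
  if (is.null(names(comps)) || anyDuplicated(names(comps)))
    return("components must be uniquely named")
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    if (!is.list(cmp) || !all(c("source", "map") %in% names(cmp)))
      return(sprintf("component %s must be list(source=, map=)", nm))
    map <- cmp$map
    if (is.null(names(map)) || !all(map %in% 0:2))
      return(sprintf("component %s: map must be named with scores in 0..2", nm))
    if (identical(cmp$source, "APOE_e")) {
      if (!setequal(names(map), c("e4+", "e4-")))
        return("APOE_e component must map exactly e4+ and e4-")
      if (!identical(unname(map[["e4+"]]), 2L) && map[["e4+"]] != 0)
        return("APOE_e component must score e4+ as 0")
      if (map[["e4-"]] != 2 || any(map == 1))
        return("APOE_e component must score e4- as 2 with no score of 1")
    }
  }
  expct <- 100 / (2 * length(comps))
  if (abs(object@normaliser - expct) > 1e-9)
    return("normaliser must equal 100 / (2 * number of components)")
  TRUE
})

#' CohortFrequencyTable: per-group, per-locus genotype frequencies
#'
#' Relative genotype-category frequencies for each group, optionally with the
#' absolute counts they were estimated from. Doubles as the parameter set of
#' the synthetic-cohort generator, where the proportions are treated as exact
#' category probabilities. The derived APOE epsilon4 carrier attribute is
#' stored under the pseudo-locus `"APOE_e"` with categories `e4+`/`e4-`.
#'
#' @slot freq named list: `freq[[group]][[locus]]` is a named numeric vector
#'   of proportions summing to 1 (tolerance 1e-9).
#' @slot counts same shape as `freq` holding integer counts, or empty list.
#' @slot groupSizes named numeric vector of group sizes.
#' @seealso [genotypeFrequencies()], [rugbyFrequencies()], [frequencyTable()]
#' @export
setClass("CohortFrequencyTable",
         slots = c(freq = "list", counts = "list", groupSizes = "numeric"))

setValidity("CohortFrequencyTable", function(object) {
  if (is.null(names(object@freq))) return("freq must be named by group")
  for (g in names(object@freq)) {
    for (loc in names(object@freq[[g]])) {
      v <- object@freq[[g]][[loc]]
      if (is.null(names(v))) return(sprintf("%s/%s: categories must be named", g, loc))
      if (any(v < 0) || any(v > 1))
        return(sprintf("%s/%s: proportions must lie in [0,1]", g, loc))
      if (abs(sum(v) - 1) > 1e-9)
        return(sprintf("%s/%s: proportions must sum to 1", g, loc))
    }
  }
  if (!all(names(object@freq) %in% names(object@groupSizes)) &&
      length(object@groupSizes) > 0)
    return("groupSizes must cover every frequency group")
  TRUE
})

#' PenetrancePlant: a planted two-locus penetrance model
#'
#' Describes a case/control labelling rule over the joint genotypes of two
#' loci: each individual becomes a case with the probability in the cell of
#' its two-locus genotype. An XOR-style table (see [xorPenetrance()]) has
#' constant single-locus marginals and therefore plants a pure interaction,
#' the worst case for marginal-effect methods and the benchmark for MDR.
#'
#' @slot loci character vector of the two target locus names.
#' @slot penetrance numeric matrix of case probabilities with dimnames equal
#'   to the genotype categories of locus 1 (rows) and locus 2 (columns).
#' @seealso [plantLabels()], [xorPenetrance()]
#' @export
setClass("PenetrancePlant", slots = c(loci = "character", penetrance = "matrix"))

setValidity("PenetrancePlant", function(object) {
  if (length(object@loci) != 2L) return("exactly two target loci required")
  p <- object@penetrance
  if (any(p < 0) || any(p > 1)) return("penetrances must lie in [0,1]")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("penetrance matrix must have genotype-category dimnames")
  TRUE
})

#' SimulationSpec: study conditions for the synthetic-cohort generator
#'
#' Bundles everything [simulateCohort()] needs: group sizes, the genotype
#' frequency table to draw from, how each simulated group maps to a frequency
#' group, the sampling mode, per-locus missingness and an optional planted
#' two-locus penetrance effect.
#'
#' @slot panel the [GenotypePanel-class] to simulate.
#' @slot groupSizes named integer-ish vector, e.g. `c(athlete=635, nonathlete=722)`.
#' @slot freqTable the [CohortFrequencyTable-class] supplying category probabilities.
#' @slot freqGroup named character vector mapping simulated group -> frequency
#'   group (identity where omitted).
#' @slot mode `"genotype"` (draw categories as printed) or `"hwe"` (draw from
#'   Hardy-Weinberg proportions at the implied allele frequencies).
#' @slot missingness per-locus missing-call probability in [0,1).
#' @slot plant a [PenetrancePlant-class] or NULL.
#' @slot seed integer seed or NULL.
#' @seealso [simulationSpec()], [simulateCohort()]
#' @export
setClass("SimulationSpec",
         slots = c(panel = "GenotypePanel", groupSizes = "numeric",
                   freqTable = "CohortFrequencyTable", freqGroup = "character",
                   mode = "character", missingness = "numeric",
                   plant = "ANY", seed = "ANY"))

setValidity("SimulationSpec", function(object) {
  if (length(object@groupSizes) < 1L || is.null(names(object@groupSizes)))
    return("groupSizes must be a named vector")
  if (any(object@groupSizes < 1)) return("group sizes must be >= 1")
  if (!object@mode %in% c("genotype", "hwe"))
    return("mode must be 'genotype' or 'hwe'")
  if (object@missingness < 0 || object@missingness >= 1)
    return("missingness must lie in [0,1)")
  if (!is.null(object@plant) && !is(object@plant, "PenetrancePlant"))
    return("plant must be a PenetrancePlant or NULL")
  TRUE
})

#' MdrResult: outcome of a multifactor dimensionality reduction search
#'
#' Holds the winning attribute combination, its cross-validation consistency
#' (number of folds in which it was selected), mean training/testing balanced
#' accuracies, the per-size leader board and the per-fold detail for the
#' winning model, plus its high/low risk cell table fitted on the full data.
#'
#' @slot combination character vector of attribute names of the final model.
#' @slot cvc integer, folds selecting the modal combination.
#' @slot folds integer, number of cross-validation folds.
#' @slot trainingBA,testingBA mean balanced accuracies of the final model.
#' @slot perSize data.frame: one row per combination size searched.
#' @slot perFold data.frame: per-fold metrics of the final model.
#' @slot cellTable data.frame: full-data case/control counts and risk labels.
#' @seealso [mdrSearch()]
#' @export
setClass("MdrResult",
         slots = c(combination = "character", cvc = "integer", folds = "integer",
                   trainingBA = "numeric", testingBA = "numeric",
                   perSize = "data.frame", perFold = "data.frame",
                   cellTable = "data.frame"))
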