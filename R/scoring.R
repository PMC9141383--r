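## The additive Total Genotype Score engine.
##
## Seven score components (six raw SNPs scored 0/1/2 under the codominant
## model + the derived APOE epsilon attribute scored 0 or 2), summed and
## scaled by 100/14 onto a 0-100 scale. 100 is the 'perfect' profile, 0 the
## worst; the attainable values are the 15 multiples of 100/14.

#' Construct a scoring scheme
#'
#' @param name scheme identifier.
#' @param components named list of `list(source=, map=)` components; `source`
#'   is a panel locus or `"APOE_e"`, `map` a named score vector (values 0..2)
#'   over the source's genotype categories.
#' @return a [ScoringScheme-class] with normaliser `100 / (2 * length(components))`.
#' @export
scoringScheme <- function(name, components) {
  components <- lapply(components, function(cmp) {
    nms <- if (identical(cmp$source, "APOE_e")) names(cmp$map) else
      canonicalGenotype(names(cmp$map))
    cmp$map <- stats::setNames(as.integer(cmp$map), nms)
    cmp
  })
  new("ScoringScheme", name = name, components = components,
      normaliser = 100 / (2 * length(components)))
}

#' Scheme accessors
#'
#' @param object a [ScoringScheme-class].
#' @return `schemeName`: the identifier; `schemeComponents`: the named list
#'   of components; `schemeNormaliser`: the scale factor (100/14 for the
#'   seven-component schemes).
#' @export
schemeName <- function(object) object@name

#' @rdname schemeName
#' @export
schemeComponents <- function(object) object@components

#' @rdname schemeName
#' @export
schemeNormaliser <- function(object) object@normaliser

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme '", object@name, "': ", length(object@components),
      " components, normaliser 100/", 2 * length(object@components), "\n", sep = "")
  for (nm in names(object@components)) {
    cmp <- object@components[[nm]]
    cat(sprintf("  %-9s (%s): %s\n", nm, cmp$source,
                paste(names(cmp$map), cmp$map, sep = "=", collapse = ", ")))
  }
})

.schemeComponent <- function(source, map) list(source = source, map = map)

#' Built-in TGS scoring schemes for the concussion panel
#'
#' Three presets over the seven components (ANKK1, APOE epsilon, rs405509,
#' BDNF-AS, COMT, MAPT, NOS3), normaliser 100/14:
#'
#' * `"literature"` - the prior-literature scheme: ANKK1 GG=2, APOE e4-=2,
#'   rs405509 GG=2, BDNF-AS CC=2, COMT AA=2, MAPT CC=2, NOS3 TT=2
#'   (heterozygotes 1, opposite homozygotes 0; APOE has no score of 1).
#' * `"data_led"` - scores chosen from genotype frequencies observed in elite
#'   rugby athletes: as `"literature"` but rs405509 TT=2/GT=1/GG=0 and COMT
#'   GG=2/GA=1/AA=0.
#' * `"literature_nos3_flipped"` - `"literature"` with NOS3 CC=2/TC=1/TT=0,
#'   the variant under which independence-based expected means reconcile
#'   with the published literature-scheme cohort means (see the vignette).
#'
#' @param name one of the preset names above.
#' @return a [ScoringScheme-class].
#' @export
#' @examples builtinScheme("data_led")
builtinScheme <- function(name = c("literature", "data_led", "literature_nos3_flipped")) {
  valid <- c("literature", "data_led", "literature_nos3_flipped")
  if (!is.character(name) || !name[1] %in% valid)
    stop("unknown scheme '", name[1], "'; valid names: ",
         paste(valid, collapse = ", "))
  name <- name[1]
  comps <- list(
    ANKK1    = .schemeComponent("ANKK1",    c(GG = 2, AG = 1, AA = 0)),
    APOE_e   = .schemeComponent("APOE_e",   c(`e4-` = 2, `e4+` = 0)),
    rs405509 = .schemeComponent("rs405509", c(GG = 2, GT = 1, TT = 0)),
    BDNF_AS  = .schemeComponent("BDNF_AS",  c(CC = 2, CT = 1, TT = 0)),
    COMT     = .schemeComponent("COMT",     c(AA = 2, AG = 1, GG = 0)),
    MAPT     = .schemeComponent("MAPT",     c(CC = 2, CT = 1, TT = 0)),
    NOS3     = .schemeComponent("NOS3",     c(TT = 2, CT = 1, CC = 0)))
  if (name == "data_led") {
    comps$rs405509$map <- c(TT = 2, GT = 1, GG = 0)
    comps$COMT$map     <- c(GG = 2, AG = 1, AA = 0)
  } else if (name == "literature_nos3_flipped") {
    comps$NOS3$map <- c(CC = 2, CT = 1, TT = 0)
  }
  scoringScheme(name, comps)
}

#' Read / write a scoring scheme as a YAML file
#'
#' @param path scheme file.
#' @return a [ScoringScheme-class] (`readScheme`) or `path` (`writeScheme`).
#' @export
readScheme <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$components))
    stop("scheme file must contain 'name' and 'components'")
  comps <- lapply(y$components, function(cmp)
    .schemeComponent(cmp$source, unlist(cmp$map)))
  scoringScheme(y$name, comps)
}

#' @rdname readScheme
#' @param scheme a [ScoringScheme-class] to write.
#' @export
writeScheme <- function(scheme, path) {
  y <- list(name = schemeName(scheme),
            components = lapply(schemeComponents(scheme), function(cmp)
              list(source = cmp$source, map = as.list(cmp$map))))
  yaml::write_yaml(y, path)
  invisible(path)
}

## per-individual component category values for one scheme component
.componentCategories <- function(cohort, source, ambiguous = "e2/e4") {
  if (identical(source, "APOE_e")) apoeCarrierStatus(cohort, ambiguous)
  else genotypeCalls(cohort)[, source]
}

#' Score a cohort under a TGS scheme
#'
#' Looks up each individual's component scores and forms
#' `tgs = normaliser * sum(scores)` at full precision (use one decimal for
#' display, matching the convention of the published range 21.4-92.9). The
#' default missing-component policy is complete-case: any missing or
#' unresolvable component leaves `complete = FALSE` and `tgs = NA`. With
#' `missing = "impute"` a missing component contributes its group-expected
#' score (from the cohort's own genotype frequencies) instead.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param scheme a [ScoringScheme-class] (default: the literature preset).
#' @param missing `"complete"` (default) or `"impute"`.
#' @param ambiguous APOE double-heterozygote policy, see [deriveApoe()].
#' @return data.frame: `sample_id`, `group`, one integer column per component
#'   (NA where missing), `tgs`, `complete`.
#' @export
#' @examples
#' coh <- simulateCohort(simulationSpec(seed = 1))
#' head(scoreCohort(coh, builtinScheme("literature")))
scoreCohort <- function(cohort, scheme = builtinScheme("literature"),
                        missing = c("complete", "impute"), ambiguous = "e2/e4") {
  missing <- match.arg(missing)
  comps <- schemeComponents(scheme)
  n <- length(cohort)
  scores <- matrix(NA_real_, n, length(comps),
                   dimnames = list(sampleIDs(cohort), names(comps)))
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    cats <- .componentCategories(cohort, cmp$source, ambiguous)
    scores[, nm] <- unname(cmp$map[cats])
  }
  complete <- !apply(is.na(scores), 1L, any)
  if (missing == "impute" && any(!complete)) {
    ft <- genotypeFrequencies(cohort)
    for (nm in names(comps)) {
      cmp <- comps[[nm]]
      idx <- which(is.na(scores[, nm]))
      for (i in idx) {
        fr <- ft@freq[[groupLabels(cohort)[i]]][[cmp$source]]
        scores[i, nm] <- sum(cmp$map[names(fr)] * fr)
      }
    }
  }
  total <- rowSums(scores)
  tgs <- schemeNormaliser(scheme) * total
  if (missing == "complete") tgs[!complete] <- NA_real_
  out <- data.frame(sample_id = sampleIDs(cohort), group = groupLabels(cohort),
                    scores, tgs = tgs, complete = complete,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## bias-corrected sample excess kurtosis (the convention of mainstream
## statistics packages) and its standard error
.kurtosisG2 <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2); m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

.seSkew <- function(n) sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))

.seKurtosis <- function(n) 2 * .seSkew(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))

#' Summarise a TGS distribution
#'
#' Mean, SD (n-1 denominator), bias-corrected excess kurtosis with its
#' standard error, and linear-interpolation quartile cut-points, over the
#' complete results. Kurtosis is undefined (NA) for n < 4 or a constant
#' sample.
#'
#' @param tgs numeric TGS vector, or the data.frame from [scoreCohort()]
#'   (its `tgs` column is used; incomplete rows are dropped).
#' @return one-row data.frame: n, mean, sd, kurtosis, se_kurtosis, q1,
#'   median, q3.
#' @export
summarizeTgs <- function(tgs) {
  if (is.data.frame(tgs)) tgs <- tgs$tgs
  x <- tgs[!is.na(tgs)]
  n <- length(x)
  if (n < 1) stop("no complete TGS values to summarise")
  kurt <- seK <- NA_real_
  if (n >= 4 && stats::sd(x) > 0) {
    kurt <- .kurtosisG2(x)
    seK <- .seKurtosis(n)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = n, mean = mean(x), sd = stats::sd(x),
             kurtosis = kurt, se_kurtosis = seK,
             q1 = q[1], median = q[2], q3 = q[3])
}

#' Top/bottom quartile membership of two groups
#'
#' Quartile cut-points are computed on the pooled complete scores of both
#' groups (linear-interpolation percentiles); the middle 50% is excluded and
#' the counts of each group in the top (>= Q3) and bottom (<= Q1) quartiles
#' are returned, ready for [chi2Contingency()].
#'
#' @param scoresA,scoresB numeric score vectors (or [scoreCohort()] frames).
#' @param labels row labels for the two groups.
#' @return 2x2 integer matrix, rows = groups, columns = `top`, `bottom`.
#' @export
quartileMembership <- function(scoresA, scoresB, labels = c("A", "B")) {
  if (is.data.frame(scoresA)) scoresA <- scoresA$tgs
  if (is.data.frame(scoresB)) scoresB <- scoresB$tgs
  scoresA <- scoresA[!is.na(scoresA)]; scoresB <- scoresB[!is.na(scoresB)]
  pooled <- c(scoresA, scoresB)
  if (length(pooled) < 8) stop("need >= 8 pooled complete scores")
  q <- stats::quantile(pooled, c(0.25, 0.75), names = FALSE)
  m <- rbind(c(sum(scoresA >= q[2]), sum(scoresA <= q[1])),
             c(sum(scoresB >= q[2]), sum(scoresB <= q[1])))
  dimnames(m) <- list(labels, c("top", "bottom"))
  m
}

#' Expected TGS distribution by full genotype-space enumeration
#'
#' Enumerates the product space of all component categories (at most
#' 3^6 x 2 = 1458 cells for the seven-component schemes), with cell
#' probabilities taken from a frequency table under linkage equilibrium, and
#' returns the exact TGS distribution and its mean. Simulated cohort means
#' converge to this value; it is the generator-side oracle for the scoring
#' engine.
#'
#' @param scheme a [ScoringScheme-class].
#' @param freqTable a [CohortFrequencyTable-class].
#' @param group frequency group to use.
#' @return list with `distribution` (data.frame: tgs, prob) and `mean`.
#' @export
#' @examples enumerateTgs(builtinScheme("data_led"), rugbyFrequencies(), "athlete")$mean
enumerateTgs <- function(scheme, freqTable, group) {
  comps <- schemeComponents(scheme)
  probs <- lapply(comps, function(cmp) {
    fr <- freqTable@freq[[group]][[cmp$source]]
    if (is.null(fr)) stop("frequency table lacks locus '", cmp$source,
                          "' for group '", group, "'")
    fr
  })
  scoreLists <- lapply(names(comps), function(nm)
    unname(comps[[nm]]$map[names(probs[[nm]])]))
  grid <- expand.grid(lapply(probs, seq_along))
  cellP <- rep(1, nrow(grid))
  cellS <- rep(0, nrow(grid))
  for (k in seq_along(probs)) {
    cellP <- cellP * unname(probs[[k]])[grid[[k]]]
    cellS <- cellS + scoreLists[[k]][grid[[k]]]
  }
  tgs <- schemeNormaliser(scheme) * cellS
  dist <- stats::aggregate(cellP, list(tgs = tgs), sum)
  names(dist)[2] <- "prob"
  list(distribution = dist, mean = sum(tgs * cellP))
}
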