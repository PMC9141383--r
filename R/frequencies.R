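## Genotype frequency tabulation, the packaged rugby frequency fixture and
## Hardy-Weinberg equilibrium QC.

#' Construct a cohort frequency table directly
#'
#' @param freq named list: `freq[[group]][[locus]]` = named proportions
#'   summing to 1. Use pseudo-locus `"APOE_e"` with categories `e4+`/`e4-`
#'   for the derived epsilon4 carrier attribute.
#' @param groupSizes named group sizes.
#' @param counts optional counts, same shape as `freq`.
#' @return a [CohortFrequencyTable-class].
#' @export
frequencyTable <- function(freq, groupSizes, counts = list()) {
  new("CohortFrequencyTable", freq = freq, counts = counts,
      groupSizes = groupSizes)
}

#' Frequency-table accessors
#'
#' @param object a [CohortFrequencyTable-class].
#' @param group group label; `locus` locus name.
#' @param locus locus name.
#' @return `freqGroups`: group names; `locusFrequencies`: named proportions.
#' @export
freqGroups <- function(object) names(object@freq)

#' @rdname freqGroups
#' @export
locusFrequencies <- function(object, group, locus) object@freq[[group]][[locus]]

setMethod("show", "CohortFrequencyTable", function(object) {
  cat("CohortFrequencyTable:", length(object@freq), "group(s) [",
      paste(names(object@freq), collapse = ", "), "]\n")
  for (g in names(object@freq))
    cat(sprintf("  %s (n=%s): %d loci\n", g,
                format(object@groupSizes[[g]]), length(object@freq[[g]])))
})

#' Tabulate genotype frequencies per group
#'
#' Per locus, proportions are computed over non-missing calls only (the
#' per-locus complete-call policy); all three genotype categories are always
#' reported, in hom/het/hom order. If the panel contains the APOE SNP pair,
#' the derived epsilon4 carrier attribute is tabulated under `"APOE_e"` over
#' records whose diplotype resolves.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param groups groups to tabulate (default: all present).
#' @return a [CohortFrequencyTable-class] with counts retained.
#' @export
genotypeFrequencies <- function(cohort, groups = unique(groupLabels(cohort))) {
  calls <- genotypeCalls(cohort)
  pl <- cohortPanel(cohort)@loci
  hasApoe <- all(c("rs429358", "rs7412") %in% pl$name)
  eps <- if (hasApoe) apoeCarrierStatus(cohort) else NULL
  freq <- list(); counts <- list(); sizes <- numeric(0)
  for (g in groups) {
    sel <- groupLabels(cohort) == g
    if (!any(sel)) stop("no records in group '", g, "'")
    fg <- list(); cg <- list()
    for (j in seq_len(nrow(pl))) {
      cats <- validGenotypes(pl$allele1[j], pl$allele2[j])
      x <- calls[sel, pl$name[j]]
      cnt <- table(factor(x, levels = cats))
      cg[[pl$name[j]]] <- as.vector(cnt)
      names(cg[[pl$name[j]]]) <- cats
      tot <- sum(cnt)
      fg[[pl$name[j]]] <- if (tot > 0) cg[[pl$name[j]]] / tot else
        stats::setNames(rep(NA_real_, 3), cats)
    }
    if (hasApoe) {
      ce <- table(factor(eps[sel], levels = c("e4+", "e4-")))
      cg[["APOE_e"]] <- stats::setNames(as.vector(ce), c("e4+", "e4-"))
      fg[["APOE_e"]] <- cg[["APOE_e"]] / sum(ce)
    }
    freq[[g]] <- fg; counts[[g]] <- cg
    sizes[g] <- sum(sel)
  }
  frequencyTable(freq, sizes, counts)
}

#' The published rugby case-control genotype frequency table
#'
#' Genotype frequencies of the eight-polymorphism concussion panel in 635
#' elite male rugby athletes and 722 non-athletes, as proportions. Ships as a
#' plain-text fixture (`inst/extdata/genotype_frequencies_rugby.tsv`) and is
#' the default parameter set of the synthetic-cohort generator. The APOE
#' entry is epsilon4 carriage (`e4+`/`e4-`) under pseudo-locus `"APOE_e"`.
#'
#' @return a [CohortFrequencyTable-class] with groups `athlete` (n = 635) and
#'   `nonathlete` (n = 722).
#' @export
rugbyFrequencies <- function() {
  path <- system.file("extdata", "genotype_frequencies_rugby.tsv",
                      package = "polyprofile", mustWork = TRUE)
  readFrequencyTable(path, groupSizes = c(athlete = 635, nonathlete = 722))
}

#' Read / write a frequency table as TSV
#'
#' Long format: columns `group`, `locus`, `genotype`, `proportion`.
#'
#' @param path TSV file.
#' @param groupSizes named group sizes (required metadata on read).
#' @return a [CohortFrequencyTable-class].
#' @export
readFrequencyTable <- function(path, groupSizes) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("group", "locus", "genotype", "proportion")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("frequency table is missing column(s): ", paste(miss, collapse = ", "))
  freq <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    freq[[g]] <- lapply(split(sub, sub$locus), function(s)
      stats::setNames(s$proportion, s$genotype))
    ## preserve file order of loci
    freq[[g]] <- freq[[g]][unique(sub$locus)]
  }
  frequencyTable(freq, groupSizes)
}

#' @rdname readFrequencyTable
#' @param object a [CohortFrequencyTable-class] to write.
#' @export
writeFrequencyTable <- function(object, path) {
  rows <- do.call(rbind, lapply(names(object@freq), function(g)
    do.call(rbind, lapply(names(object@freq[[g]]), function(loc)
      data.frame(group = g, locus = loc,
                 genotype = names(object@freq[[g]][[loc]]),
                 proportion = unname(object@freq[[g]][[loc]]),
                 stringsAsFactors = FALSE)))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hardy-Weinberg equilibrium test for one locus
#'
#' Allele frequencies are estimated from the genotype counts; expected counts
#' are n*p^2, 2npq, n*q^2 and compared by Pearson chi-square with 1 degree of
#' freedom (no continuity correction). A monomorphic locus (one allele
#' absent) leaves the test undefined and is reported as not applicable
#' rather than p = 1.
#'
#' @param counts numeric vector of length 3: counts of (hom1, het, hom2).
#' @return list with `chi2`, `df`, `p` and `applicable`.
#' @export
#' @examples hweTest(c(25, 50, 25))  # exact HWE proportions: chi2 = 0
hweTest <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be 3 non-negative genotype counts (hom1, het, hom2)")
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_, applicable = FALSE))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = unname(chi2), df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), applicable = TRUE)
}

#' Hardy-Weinberg QC table for a cohort
#'
#' Tests every bi-allelic panel locus within each group separately (the
#' derived APOE epsilon attribute is not a bi-allelic genotype and is not
#' tested).
#'
#' @param cohort a [GenotypeCohort-class].
#' @param groups groups to test (default all).
#' @return data.frame with columns group, locus, n, chi2, p, applicable.
#' @export
hweTable <- function(cohort, groups = unique(groupLabels(cohort))) {
  ft <- genotypeFrequencies(cohort, groups)
  pl <- cohortPanel(cohort)@loci
  out <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(pl$name, function(loc) {
      cnt <- ft@counts[[g]][[loc]]
      h <- hweTest(cnt)
      data.frame(group = g, locus = loc, n = sum(cnt), chi2 = h$chi2,
                 p = h$p, applicable = h$applicable, stringsAsFactors = FALSE)
    }))))
  rownames(out) <- NULL
  out
}
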