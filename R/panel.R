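## Panel construction, genotype canonicalisation and cohort accessors.

#' Canonicalise unordered genotype calls
#'
#' Genotypes are unordered allele pairs: `"GA"` and `"AG"` are the same call.
#' The canonical form sorts the two allele characters, so every downstream
#' table and map uses a single spelling.
#'
#' @param g character vector of two-character genotype strings (NA allowed).
#' @return character vector of canonical genotypes.
#' @export
#' @examples canonicalGenotype(c("GA", "AG", NA))
canonicalGenotype <- function(g) {
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g)
  if (any(ok)) {
    bad <- nchar(g[ok]) != 2L
    if (any(bad)) stop("genotypes must be two-character allele pairs: '",
                       g[ok][bad][1L], "'")
    out[ok] <- vapply(strsplit(g[ok], ""), function(a) paste(sort(a), collapse = ""), "")
  }
  out
}

## the three canonical genotype categories of a bi-allelic locus, in
## hom1 / het / hom2 order (allele1 < allele2 is not assumed)
validGenotypes <- function(a1, a2) {
  canonicalGenotype(c(paste0(a1, a1), paste0(a1, a2), paste0(a2, a2)))
}

#' Construct a genotype panel
#'
#' @param name locus names (used as column headers in genotype tables).
#' @param rsid dbSNP identifiers.
#' @param allele1,allele2 the two allele symbols per locus.
#' @param risk_allele risk allele per locus, or `"undetermined"`.
#' @return a [GenotypePanel-class].
#' @export
genotypePanel <- function(name, rsid, allele1, allele2,
                          risk_allele = rep("undetermined", length(name))) {
  df <- data.frame(name = as.character(name), rsid = as.character(rsid),
                   allele1 = as.character(allele1), allele2 = as.character(allele2),
                   risk_allele = as.character(risk_allele),
                   stringsAsFactors = FALSE)
  rownames(df) <- df$name
  new("GenotypePanel", loci = df)
}

#' The eight-polymorphism concussion candidate panel
#'
#' ANKK1 rs1800497, the three APOE polymorphisms (rs429358 and rs7412, which
#' jointly define the epsilon2/3/4 haplotypes, plus promoter rs405509),
#' BDNF-AS rs6265, COMT rs4680, MAPT rs10445337 and NOS3 rs2070744. The loci
#' lie on different chromosomes, so linkage equilibrium across the panel is a
#' reasonable modelling assumption. Risk-allele annotations follow the prior
#' TBI literature and are metadata only; several are controversial and left
#' undetermined.
#'
#' @return a [GenotypePanel-class] of 8 loci.
#' @export
defaultPanel <- function() {
  genotypePanel(
    name        = c("ANKK1", "rs429358", "rs7412", "rs405509", "BDNF_AS", "COMT", "MAPT", "NOS3"),
    rsid        = c("rs1800497", "rs429358", "rs7412", "rs405509", "rs6265", "rs4680", "rs10445337", "rs2070744"),
    allele1     = c("A", "C", "C", "G", "C", "A", "C", "C"),
    allele2     = c("G", "T", "T", "T", "T", "G", "T", "T"),
    risk_allele = c("A", "C", "undetermined", "T", "T", "undetermined", "T", "C"))
}

#' A synthetic panel of generic bi-allelic loci
#'
#' `nLoci` loci named `L1..Ln` with alleles A/B, handy for method-validation
#' simulations (e.g. planted-interaction benchmarks) that do not need the
#' study panel.
#'
#' @param nLoci number of loci.
#' @return a [GenotypePanel-class].
#' @export
syntheticPanel <- function(nLoci) {
  genotypePanel(name = paste0("L", seq_len(nLoci)),
                rsid = paste0("rsL", seq_len(nLoci)),
                allele1 = "A", allele2 = "B")
}

#' Construct a genotype cohort
#'
#' Calls are canonicalised (unordered allele pairs) and validated against the
#' panel; a call using an allele the locus does not carry is an error naming
#' the sample and locus.
#'
#' @param calls character matrix (samples x loci) of two-character genotypes,
#'   NA for missing; column names must match the panel loci.
#' @param group character vector of group labels.
#' @param panel a [GenotypePanel-class]; defaults to [defaultPanel()].
#' @param sample_id optional sample identifiers (default: existing row names
#'   or `S1..Sn`).
#' @return a [GenotypeCohort-class].
#' @export
genotypeCohort <- function(calls, group, panel = defaultPanel(), sample_id = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(sample_id)) {
    sample_id <- rownames(calls)
    if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(calls)))
  }
  rownames(calls) <- as.character(sample_id)
  want <- panel@loci$name
  miss <- setdiff(want, colnames(calls))
  if (length(miss))
    stop("missing locus column(s): ", paste(miss, collapse = ", "))
  calls <- calls[, want, drop = FALSE]
  for (j in seq_len(ncol(calls))) calls[, j] <- canonicalGenotype(calls[, j])
  new("GenotypeCohort", calls = calls, group = as.character(group), panel = panel)
}

#' @describeIn genotypeCohort number of individuals.
#' @param x a GenotypeCohort.
#' @export
setMethod("length", "GenotypeCohort", function(x) nrow(x@calls))

#' Cohort accessors
#'
#' `sampleIDs`, `groupLabels`, `genotypeCalls` and `cohortPanel` expose the
#' slots of a [GenotypeCohort-class] without touching `@`.
#'
#' @param object a GenotypeCohort.
#' @return character vector / matrix / [GenotypePanel-class] respectively.
#' @export
sampleIDs <- function(object) rownames(object@calls)

#' @rdname sampleIDs
#' @export
groupLabels <- function(object) object@group

#' @rdname sampleIDs
#' @export
genotypeCalls <- function(object) object@calls

#' @rdname sampleIDs
#' @export
cohortPanel <- function(object) object@panel

#' Subset a cohort by sample
#'
#' @param x a GenotypeCohort; `i` a logical/integer/character sample index.
#' @param i,j,...,drop standard subsetting arguments (`j` unused).
#' @export
setMethod("[", "GenotypeCohort", function(x, i, j, ..., drop = FALSE) {
  new("GenotypeCohort", calls = x@calls[i, , drop = FALSE],
      group = x@group[i], panel = x@panel)
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel with", nrow(object@loci), "loci\n")
  print(object@loci, row.names = FALSE)
})

setMethod("show", "GenotypeCohort", function(object) {
  cat("GenotypeCohort:", nrow(object@calls), "individuals x",
      ncol(object@calls), "loci\n")
  tab <- table(object@group)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(is.na(object@calls))
  if (nmiss > 0) cat("missing calls:", nmiss, "\n")
})
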