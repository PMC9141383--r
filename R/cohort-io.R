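## Genotype table I/O. Dialect: TSV with header
##   sample_id  group  <locus> ...
## genotypes as two adjacent allele characters, missing = "NA".

#' Read an individual-level genotype table
#'
#' @param path TSV file with columns `sample_id`, `group` and one column per
#'   panel locus; genotypes as two-character allele pairs, `NA` for missing.
#' @param panel the [GenotypePanel-class] to validate against.
#' @return a [GenotypeCohort-class]; genotypes are canonicalised to unordered
#'   form, and any allele symbol outside the locus's declared alleles is an
#'   error naming the sample and locus.
#' @export
readGenotypeTable <- function(path, panel = defaultPanel()) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = "NA")
  need <- c("sample_id", "group", panel@loci$name)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("genotype table is missing required column(s): ",
         paste(miss, collapse = ", "))
  genotypeCohort(as.matrix(df[, panel@loci$name, drop = FALSE]),
                 group = df$group, panel = panel, sample_id = df$sample_id)
}

#' Write a genotype cohort to the TSV dialect read by [readGenotypeTable()]
#'
#' @param cohort a [GenotypeCohort-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(cohort, path) {
  df <- data.frame(sample_id = sampleIDs(cohort), group = groupLabels(cohort),
                   genotypeCalls(cohort), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
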