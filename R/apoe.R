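## APOE epsilon diplotype derivation from rs429358 + rs7412.
##
## Haplotypes over (rs429358, rs7412): e2 = (T,T), e3 = (T,C), e4 = (C,C);
## (C,T) is the rare e1 haplotype, not scored here. Given the two unphased
## genotypes there are at most two haplotype-pair resolutions; all are
## unambiguous except the double heterozygote C/T + C/T, whose resolutions
## are {e2,e4} and {e1,e3}.

.hapEps <- c(TT = "e2", TC = "e3", CC = "e4", CT = "e1")

#' Derive APOE epsilon diplotypes from rs429358 and rs7412 genotypes
#'
#' The two C/T SNPs at codons 112 (rs429358) and 158 (rs7412) jointly define
#' the epsilon2/epsilon3/epsilon4 haplotypes; their unphased genotypes
#' resolve to one of the six diplotypes e2/e2, e2/e3, e2/e4, e3/e3, e3/e4,
#' e4/e4. The doubly heterozygous case is genuinely ambiguous between e2/e4
#' and e1/e3; by the standard convention the rare e1 haplotype is excluded
#' and e2/e4 assigned (`ambiguous = "e2/e4"`), or the record can be dropped
#' (`ambiguous = "exclude"`). Genotype combinations that force an e1
#' haplotype in every resolution (e.g. rs429358 C/C with rs7412 T/T) are
#' unresolvable and returned as NA with `resolvable = FALSE`.
#'
#' @param rs429358,rs7412 character vectors of two-character C/T genotypes
#'   (allele order irrelevant), NA for missing.
#' @param ambiguous policy for the double heterozygote: `"e2/e4"` (default)
#'   or `"exclude"`.
#' @return data.frame with columns `diplotype` (e.g. `"e3/e4"`, NA if missing
#'   or unresolved), `e4_carrier` (logical) and `resolvable` (FALSE only for
#'   e1-forced combinations).
#' @export
#' @examples
#' deriveApoe("TT", "CC")           # e3/e3
#' deriveApoe("CT", "CT")           # ambiguous; e2/e4 by convention
deriveApoe <- function(rs429358, rs7412, ambiguous = c("e2/e4", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  g1 <- canonicalGenotype(rs429358)
  g2 <- canonicalGenotype(rs7412)
  n <- max(length(g1), length(g2))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n)
  dip <- rep(NA_character_, n)
  resolvable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    a <- strsplit(g1[i], "")[[1]]
    b <- strsplit(g2[i], "")[[1]]
    if (!all(a %in% c("C", "T")) || !all(b %in% c("C", "T")))
      stop("APOE SNP genotypes must use alleles C/T (got '",
           g1[i], "', '", g2[i], "')")
    res <- unique(list(sort(c(.hapEps[paste0(a[1], b[1])], .hapEps[paste0(a[2], b[2])])),
                       sort(c(.hapEps[paste0(a[1], b[2])], .hapEps[paste0(a[2], b[1])]))))
    valid <- Filter(function(r) !"e1" %in% r, res)
    if (length(valid) == 0L) { resolvable[i] <- FALSE; next }
    if (length(res) > 1L && length(valid) == 1L && ambiguous == "exclude" &&
        g1[i] == "CT" && g2[i] == "CT") next  # drop the double heterozygote
    dip[i] <- paste(valid[[1]], collapse = "/")
  }
  data.frame(diplotype = dip,
             e4_carrier = ifelse(is.na(dip), NA, grepl("e4", dip)),
             resolvable = resolvable, stringsAsFactors = FALSE)
}

#' APOE epsilon4 carrier status for a whole cohort
#'
#' @param cohort a [GenotypeCohort-class] whose panel contains `rs429358`
#'   and `rs7412`.
#' @param ambiguous passed to [deriveApoe()].
#' @return character vector (`"e4+"`, `"e4-"` or NA) aligned with the cohort.
#' @export
apoeCarrierStatus <- function(cohort, ambiguous = "e2/e4") {
  calls <- genotypeCalls(cohort)
  if (!all(c("rs429358", "rs7412") %in% colnames(calls)))
    stop("cohort panel lacks rs429358/rs7412")
  d <- deriveApoe(calls[, "rs429358"], calls[, "rs7412"], ambiguous = ambiguous)
  ifelse(is.na(d$e4_carrier), NA_character_, ifelse(d$e4_carrier, "e4+", "e4-"))
}
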