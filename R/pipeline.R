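## End-to-end orchestration: simulate or read -> HWE QC -> TGS under each
## scheme -> group comparisons (t-test, quartile chi-square, ROC/AUC) ->
## MDR epistasis search -> allele-combination carrier analysis, emitted as a
## reproducible report bundle.

.defaultComparisons <- function() list(
  list(name = "All Rugby Athletes", case = c("RU_forward", "RU_back", "RL")),
  list(name = "RU Athletes",        case = c("RU_forward", "RU_back")),
  list(name = "RL Athletes",        case = "RL"),
  list(name = "RU Forwards",        case = "RU_forward"),
  list(name = "RU Backs",           case = "RU_back"))

#' Default simulation spec of the rugby study layout
#'
#' 722 non-athletes plus 635 athletes split into rugby union forwards (304),
#' union backs (230) and league athletes (101); all athlete subgroups draw
#' from the published all-athlete frequencies (per-position frequencies are
#' not published).
#'
#' @param seed integer seed.
#' @return a [SimulationSpec-class].
#' @export
rugbyStudySpec <- function(seed = NULL) {
  simulationSpec(
    groupSizes = c(RU_forward = 304, RU_back = 230, RL = 101, nonathlete = 722),
    freqGroup = c(RU_forward = "athlete", RU_back = "athlete", RL = "athlete"),
    seed = seed)
}

#' Run the full polygenic-profile analysis pipeline
#'
#' Workflow: obtain a cohort (simulate from `spec` unless `cohort` is
#' given) -> Hardy-Weinberg QC per group -> TGS under each scheme with
#' per-comparison summaries (mean, SD, kurtosis and SE, independent t-test
#' vs the control group, top-vs-bottom-quartile chi-square, ROC AUC with CI)
#' -> TGS frequency-distribution histogram data -> MDR search (cases = all
#' athlete groups) -> allele-combination carrier frequencies with odds
#' ratios vs the control group. Everything is computed first and written
#' only on success (no partial output directories), as TSV files plus a
#' structured-text summary embedding the configuration and seed.
#'
#' @param spec a [SimulationSpec-class] (default: [rugbyStudySpec()]).
#' @param cohort optional pre-built [GenotypeCohort-class]; overrides `spec`.
#' @param schemes character vector of built-in scheme names, or a list of
#'   [ScoringScheme-class] objects.
#' @param comparisons list of `list(name=, case=)` group comparisons against
#'   `controlGroup`; default: the five athlete groupings of the study layout.
#' @param controlGroup the control/reference group label.
#' @param alleles carrier-combination definition for the epistasis
#'   follow-up, named locus -> allele vector.
#' @param kRange,folds MDR search settings.
#' @param seed integer seed controlling simulation and MDR folds.
#' @param outDir output directory (created); NULL for no files.
#' @return (invisibly) a list with elements `hwe`, `tgs` (per scheme:
#'   summary table, per-individual scores, histogram data), `mdr`,
#'   `carriers`, `config`; written files when `outDir` is set.
#' @export
runPipeline <- function(spec = rugbyStudySpec(seed = seed), cohort = NULL,
                        schemes = c("literature", "data_led"),
                        comparisons = .defaultComparisons(),
                        controlGroup = "nonathlete",
                        alleles = c(COMT = "G", MAPT = "C"),
                        kRange = 2, folds = 10, seed = 1, outDir = NULL) {
  if (is.null(cohort)) cohort <- simulateCohort(spec, seed = seed)
  groups <- unique(groupLabels(cohort))
  if (!controlGroup %in% groups) stop("control group '", controlGroup,
                                      "' absent from cohort")
  for (cmp in comparisons) {
    absent <- setdiff(cmp$case, groups)
    if (length(absent) == length(cmp$case))
      stop("comparison '", cmp$name, "': no records in group(s) ",
           paste(cmp$case, collapse = ", "))
  }
  if (is.character(schemes)) schemes <- lapply(schemes, builtinScheme)
  names(schemes) <- vapply(schemes, schemeName, "")

  hwe <- hweTable(cohort)

  tgsOut <- lapply(schemes, function(sch) {
    scored <- scoreCohort(cohort, sch)
    ctrl <- scored$tgs[scored$group == controlGroup]
    rowFor <- function(name, tgs, ref = NULL) {
      s <- summarizeTgs(tgs)
      if (is.null(ref))
        return(data.frame(group = name, s, t_p = NA_real_, quartile_p = NA_real_,
                          auc = NA_real_, auc_lower = NA_real_,
                          auc_upper = NA_real_, auc_p = NA_real_))
      tt <- tTestInd(tgs, ref)
      qc <- chi2Contingency(quartileMembership(tgs, ref, c(name, "control")))
      rc <- rocAuc(tgs[!is.na(tgs)], ref[!is.na(ref)])
      data.frame(group = name, s, t_p = tt$p, quartile_p = qc$p,
                 auc = rc$auc, auc_lower = rc$lower, auc_upper = rc$upper,
                 auc_p = rc$p)
    }
    summary <- rbind(
      rowFor("Non-athletes", ctrl),
      do.call(rbind, lapply(comparisons, function(cmp)
        rowFor(cmp$name, scored$tgs[scored$group %in% cmp$case], ctrl))))
    rownames(summary) <- NULL
    ## histogram data: per-group counts over the attainable TGS values
    vals <- sort(unique(round(scored$tgs[!is.na(scored$tgs)], 1)))
    hist <- do.call(rbind, lapply(c(list(list(name = "Non-athletes",
                                              case = controlGroup)), comparisons),
                                  function(cmp) {
      x <- round(scored$tgs[scored$group %in% cmp$case], 1)
      cnt <- table(factor(x[!is.na(x)], levels = vals))
      data.frame(group = cmp$name, tgs = vals, count = as.vector(cnt),
                 stringsAsFactors = FALSE)
    }))
    list(summary = summary, scores = scored, histogram = hist)
  })

  allCase <- unique(unlist(lapply(comparisons, `[[`, "case")))
  mdr <- mdrSearch(cohort, caseGroups = allCase, kRange = kRange,
                   folds = folds, seed = seed + 1L)

  carriers <- carrierCombinationFrequency(cohort, alleles)
  ctrlRow <- carriers[carriers$group == controlGroup, ]
  orRows <- do.call(rbind, lapply(comparisons, function(cmp) {
    cf <- data.frame(group = cmp$name,
                     n = sum(carriers$n[carriers$group %in% cmp$case]),
                     carriers = sum(carriers$carriers[carriers$group %in% cmp$case]))
    cf$proportion <- cf$carriers / cf$n
    o <- oddsRatio(cf$carriers, cf$n - cf$carriers,
                   ctrlRow$carriers, ctrlRow$n - ctrlRow$carriers)
    cbind(cf, or = o$or, or_lower = o$lower, or_upper = o$upper)
  }))

  config <- list(schemes = names(schemes), controlGroup = controlGroup,
                 comparisons = vapply(comparisons, `[[`, "", "name"),
                 alleles = paste(names(alleles), alleles, sep = ":"),
                 kRange = kRange, folds = folds, seed = seed)
  res <- list(hwe = hwe, tgs = tgsOut, mdr = mdr,
              carriers = list(perGroup = carriers, comparisons = orRows),
              config = config)
  if (!is.null(outDir)) .writeReport(res, outDir)
  invisible(res)
}

.writeReport <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) utils::write.table(
    df, file.path(outDir, file), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$hwe, "hwe.tsv")
  for (nm in names(res$tgs)) {
    wt(res$tgs[[nm]]$summary, paste0("tgs_summary_", nm, ".tsv"))
    wt(res$tgs[[nm]]$scores, paste0("tgs_scores_", nm, ".tsv"))
    wt(res$tgs[[nm]]$histogram, paste0("tgs_histogram_", nm, ".tsv"))
  }
  wt(mdrPerSize(res$mdr), "mdr_models.tsv")
  wt(mdrCellTable(res$mdr), "mdr_cells.tsv")
  wt(res$carriers$perGroup, "carriers_per_group.tsv")
  wt(res$carriers$comparisons, "carriers_comparisons.tsv")
  con <- file(file.path(outDir, "summary.txt"), "w")
  on.exit(close(con))
  cat("polygenic-profile pipeline report\n", file = con)
  cat("seed:", res$config$seed, "\n", file = con)
  cat("schemes:", paste(res$config$schemes, collapse = ", "), "\n", file = con)
  cat("control group:", res$config$controlGroup, "\n", file = con)
  cat("comparisons:", paste(res$config$comparisons, collapse = "; "), "\n",
      file = con)
  cat("MDR: sizes", paste(res$config$kRange, collapse = ","), "with",
      res$config$folds, "folds; best model",
      paste(mdrCombination(res$mdr), collapse = " x "),
      sprintf("(CVC %d/%d, testing BA %.3f)\n", mdrCvc(res$mdr),
              res$mdr@folds, mdrTestingBA(res$mdr)), file = con)
  cat("carrier combination:", paste(res$config$alleles, collapse = " + "),
      "\n", file = con)
  for (nm in names(res$tgs)) {
    cat("\n[", nm, " TGS summary]\n", sep = "", file = con)
    s <- res$tgs[[nm]]$summary
    utils::write.table(format(s, digits = 4), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(outDir)
}
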