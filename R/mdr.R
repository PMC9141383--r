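## Multifactor dimensionality reduction, from scratch.
##
## Exhaustive search over attribute combinations: the multilocus cells of a
## combination are labelled high- or low-risk by their training case:control
## ratio, turning the combination into a one-dimensional classifier whose
## balanced accuracy is estimated by stratified k-fold cross-validation.
## The winning model is the combination selected most often across folds
## (cross-validation consistency, CVC), ties broken by testing accuracy.

#' MDR attribute matrix of a cohort
#'
#' By default the two APOE epsilon-defining SNPs (rs429358, rs7412) are
#' merged into the single binary epsilon4-carrier attribute, giving the same
#' seven attributes as the TGS components; `apoe = "raw"` keeps the two SNPs
#' as separate three-level attributes instead (for panels without the APOE
#' pair the distinction is moot).
#'
#' @param cohort a [GenotypeCohort-class].
#' @param apoe `"e4"` (merged, default) or `"raw"`.
#' @return data.frame of categorical attributes, one row per individual.
#' @export
mdrAttributes <- function(cohort, apoe = c("e4", "raw")) {
  apoe <- match.arg(apoe)
  df <- as.data.frame(genotypeCalls(cohort), stringsAsFactors = FALSE)
  hasPair <- all(c("rs429358", "rs7412") %in% colnames(df))
  if (apoe == "e4" && hasPair) {
    pos <- match("rs429358", colnames(df))
    eps <- apoeCarrierStatus(cohort)
    df <- df[, setdiff(colnames(df), c("rs429358", "rs7412")), drop = FALSE]
    df <- append(df, list(APOE_e = eps), after = pos - 1L)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  }
  rownames(df) <- sampleIDs(cohort)
  df
}

#' Label multilocus cells high/low risk by case:control ratio
#'
#' A cell is `high` iff its case:control ratio is at least the threshold
#' (ties labelled high; a cell with cases but no controls is high), `low`
#' otherwise, and `empty` when it holds no observations at all. At
#' prediction time empty/unseen cells are classified low under the default
#' convention.
#'
#' @param cases,controls parallel non-negative count vectors (named by cell).
#' @param threshold positive case:control ratio threshold; canonically the
#'   overall case:control ratio of the training data.
#' @return data.frame with columns `cell`, `cases`, `controls`, `label`.
#' @export
#' @examples labelCells(c(10, 5), c(5, 10), threshold = 1)
labelCells <- function(cases, controls, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (any(cases < 0) || any(controls < 0)) stop("counts must be non-negative")
  lab <- ifelse(cases + controls == 0, "empty",
                ifelse((controls > 0 & cases / controls >= threshold) |
                         (controls == 0 & cases > 0), "high", "low"))
  data.frame(cell = if (!is.null(names(cases))) names(cases) else
    as.character(seq_along(cases)),
    cases = as.vector(cases), controls = as.vector(controls),
    label = lab, stringsAsFactors = FALSE)
}

## balanced accuracy of 'predict case iff cell is high-risk'
.balancedAccuracy <- function(pred, isCase) {
  sens <- if (any(isCase)) mean(pred[isCase]) else NA_real_
  spec <- if (any(!isCase)) mean(!pred[!isCase]) else NA_real_
  (sens + spec) / 2
}

## train-cell counts and high-risk cell set for one combination key
.fitCells <- function(key, isCase) {
  kf <- factor(key)
  cases <- tapply(isCase, kf, sum)
  tot <- tapply(rep(1L, length(kf)), kf, sum)
  controls <- tot - cases
  thr <- sum(isCase) / max(1, sum(!isCase))
  high <- names(cases)[(controls > 0 & cases / controls >= thr) |
                         (controls == 0 & cases > 0)]
  list(high = high, cases = cases, controls = controls, threshold = thr)
}

#' Exhaustive MDR search with cross-validation consistency
#'
#' For every attribute combination of each size in `kRange`, and within each
#' of `folds` stratified cross-validation folds: cell case/control counts
#' are built on the training part, cells labelled high/low risk against the
#' training case:control ratio, and the combination's training balanced
#' accuracy computed; the best combination of each size in each fold is then
#' evaluated on the held-out part (testing balanced accuracy). Per size, the
#' modal selected combination's CVC is the number of folds that picked it;
#' the final model is the combination with the highest CVC, ties broken by
#' higher mean testing balanced accuracy. With `folds = 1` the search
#' reduces to maximising whole-sample balanced accuracy.
#'
#' Balanced accuracy (mean of sensitivity and specificity) is used
#' throughout, the appropriate choice for unbalanced case:control designs.
#' Records missing any attribute value are excluded; attributes with a
#' single observed level are dropped with a warning. Cells unseen in
#' training predict 'control' under the default `emptyCell = "low"`
#' convention, or are left out of the testing accuracy with `"abstain"`.
#'
#' @param x a [GenotypeCohort-class] or a data.frame of categorical
#'   attributes (rows = individuals).
#' @param isCase logical case indicator; for a cohort, derived from
#'   `caseGroups` instead.
#' @param caseGroups group labels treated as cases when `x` is a cohort.
#' @param kRange combination sizes to search (default 2).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the stratified fold shuffle.
#' @param emptyCell prediction rule for unseen cells: `"low"` or `"abstain"`.
#' @param apoe passed to [mdrAttributes()] for cohort input.
#' @return an [MdrResult-class].
#' @export
mdrSearch <- function(x, isCase = NULL, caseGroups = NULL, kRange = 2,
                      folds = 10, seed = 1, emptyCell = c("low", "abstain"),
                      apoe = "e4") {
  emptyCell <- match.arg(emptyCell)
  if (is(x, "GenotypeCohort")) {
    if (is.null(caseGroups)) stop("caseGroups required for cohort input")
    isCase <- groupLabels(x) %in% caseGroups
    x <- mdrAttributes(x, apoe)
  }
  attrs <- as.data.frame(x, stringsAsFactors = FALSE)
  isCase <- as.logical(isCase)
  keep <- stats::complete.cases(attrs) & !is.na(isCase)
  attrs <- attrs[keep, , drop = FALSE]; isCase <- isCase[keep]
  nLevels <- vapply(attrs, function(a) length(unique(a)), 0L)
  if (any(nLevels < 2)) {
    warning("dropping single-level attribute(s): ",
            paste(colnames(attrs)[nLevels < 2], collapse = ", "))
    attrs <- attrs[, nLevels >= 2, drop = FALSE]
  }
  if (sum(isCase) < 2 || sum(!isCase) < 2)
    stop("need >= 2 records per class")
  if (folds < 1) stop("folds must be >= 1")
  nm <- colnames(attrs)
  kRange <- kRange[kRange >= 1 & kRange <= length(nm)]
  if (!length(kRange)) stop("no searchable combination sizes")

  ## seeded stratified fold assignment
  set.seed(as.integer(seed))
  fold <- integer(nrow(attrs))
  fold[isCase] <- sample(rep_len(seq_len(folds), sum(isCase)))
  fold[!isCase] <- sample(rep_len(seq_len(folds), sum(!isCase)))

  combosBySize <- lapply(kRange, function(k)
    utils::combn(sort(nm), k, simplify = FALSE))
  keyFor <- function(cb) do.call(paste, c(attrs[cb], sep = ":"))

  ## evaluate one combination in one fold; returns train/test BA
  evalFold <- function(key, f) {
    tr <- if (folds == 1) rep(TRUE, length(key)) else fold != f
    te <- if (folds == 1) tr else !tr
    fit <- .fitCells(key[tr], isCase[tr])
    baTr <- .balancedAccuracy(key[tr] %in% fit$high, isCase[tr])
    predTe <- key[te] %in% fit$high
    if (emptyCell == "abstain") {
      seen <- key[te] %in% names(fit$cases)
      baTe <- .balancedAccuracy(predTe[seen], isCase[te][seen])
    } else baTe <- .balancedAccuracy(predTe, isCase[te])
    c(train = baTr, test = baTe)
  }

  perSize <- NULL
  bestDetail <- list()
  for (si in seq_along(kRange)) {
    combos <- combosBySize[[si]]
    keys <- lapply(combos, keyFor)
    sel <- character(folds); selTest <- numeric(folds)
    for (f in seq_len(folds)) {
      baTrain <- vapply(keys, function(k) evalFold(k, f)[["train"]], 0)
      best <- which.max(baTrain)  # ties: first in sorted combn order
      sel[f] <- paste(combos[[best]], collapse = "+")
      selTest[f] <- evalFold(keys[[best]], f)[["test"]]
    }
    tab <- table(sel)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {  # modal tie: higher mean testing BA, then name
      mt <- vapply(cand, function(cm) mean(selTest[sel == cm]), 0)
      cand <- cand[order(-mt, cand)]
    }
    modal <- cand[1]
    cvc <- as.integer(tab[[modal]])
    modalCombo <- strsplit(modal, "+", fixed = TRUE)[[1]]
    ## per-fold metrics of the modal combination, evaluated in every fold
    keyM <- keyFor(modalCombo)
    m <- t(vapply(seq_len(folds), function(f) evalFold(keyM, f), c(train = 0, test = 0)))
    perSize <- rbind(perSize, data.frame(
      size = kRange[si], combination = modal, cvc = cvc,
      trainingBA = mean(m[, "train"]), testingBA = mean(m[, "test"], na.rm = TRUE),
      stringsAsFactors = FALSE))
    bestDetail[[as.character(kRange[si])]] <-
      data.frame(fold = seq_len(folds), selected = sel,
                 trainingBA = m[, "train"], testingBA = m[, "test"],
                 selectedTestingBA = selTest, stringsAsFactors = FALSE)
  }
  ## final model: highest CVC, ties by testing BA
  ord <- order(-perSize$cvc, -perSize$testingBA)
  win <- perSize[ord[1], ]
  winCombo <- strsplit(win$combination, "+", fixed = TRUE)[[1]]
  fitAll <- .fitCells(keyFor(winCombo), isCase)
  cells <- labelCells(fitAll$cases, fitAll$controls, fitAll$threshold)
  new("MdrResult", combination = winCombo, cvc = as.integer(win$cvc),
      folds = as.integer(folds), trainingBA = win$trainingBA,
      testingBA = win$testingBA, perSize = perSize,
      perFold = bestDetail[[as.character(win$size)]], cellTable = cells)
}

setMethod("show", "MdrResult", function(object) {
  cat("MdrResult: best model", paste(object@combination, collapse = " x "), "\n")
  cat(sprintf("  CVC %d/%d | training BA %.3f | testing BA %.3f\n",
              object@cvc, object@folds, object@trainingBA, object@testingBA))
  cat("  per-size leader board:\n")
  print(object@perSize, row.names = FALSE)
})

#' MdrResult accessors
#'
#' @param object an [MdrResult-class].
#' @return the selected attribute combination, CVC, mean testing balanced
#'   accuracy, per-size summary or full-data cell table respectively.
#' @export
mdrCombination <- function(object) object@combination

#' @rdname mdrCombination
#' @export
mdrCvc <- function(object) object@cvc

#' @rdname mdrCombination
#' @export
mdrTestingBA <- function(object) object@testingBA

#' @rdname mdrCombination
#' @export
mdrPerSize <- function(object) object@perSize

#' @rdname mdrCombination
#' @export
mdrCellTable <- function(object) object@cellTable

#' Allele-combination carrier frequencies per group
#'
#' An individual is a combination carrier iff it carries at least one copy
#' of the listed allele at every listed locus (e.g. the COMT G + MAPT C
#' combination). Proportions are over individuals with complete calls at all
#' listed loci. `mode = "allele"` counts at chromosome level instead: the
#' number of combinations formable from the per-locus allele dosages
#' (minimum dosage across loci) over a 2N denominator - an unphased proxy
#' for haplotype-level counting.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param alleles named character vector, locus -> allele, e.g.
#'   `c(COMT = "G", MAPT = "C")`.
#' @param groups groups to tabulate (default all).
#' @param mode `"carrier"` (default) or `"allele"`.
#' @return data.frame: group, n (denominator basis), carriers, proportion.
#' @export
carrierCombinationFrequency <- function(cohort, alleles = c(COMT = "G", MAPT = "C"),
                                        groups = unique(groupLabels(cohort)),
                                        mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  calls <- genotypeCalls(cohort)
  pl <- cohortPanel(cohort)@loci
  for (loc in names(alleles)) {
    if (!loc %in% pl$name) stop("locus '", loc, "' not in panel")
    if (!alleles[[loc]] %in% c(pl[loc, "allele1"], pl[loc, "allele2"]))
      stop("allele '", alleles[[loc]], "' not valid for locus ", loc)
  }
  sub <- calls[, names(alleles), drop = FALSE]
  completeRows <- !apply(is.na(sub), 1L, any)
  dosage <- vapply(names(alleles), function(loc)
    lengths(regmatches(sub[, loc], gregexpr(alleles[[loc]], sub[, loc], fixed = TRUE))),
    integer(nrow(sub)))
  dosage[!completeRows, ] <- NA_integer_
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- groupLabels(cohort) == g & completeRows
    nInd <- sum(sel)
    if (mode == "carrier") {
      carriers <- sum(apply(dosage[sel, , drop = FALSE] >= 1, 1L, all))
      data.frame(group = g, n = nInd, carriers = carriers,
                 proportion = if (nInd > 0) carriers / nInd else NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      combs <- sum(apply(dosage[sel, , drop = FALSE], 1L, min))
      data.frame(group = g, n = 2L * nInd, carriers = combs,
                 proportion = if (nInd > 0) combs / (2 * nInd) else NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}
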