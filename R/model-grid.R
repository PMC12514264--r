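.DEFAULT_COVARIATES <- c("age_group", "female", "race", "education",
                         "bmi_class", "pack_years", "weekly_drinks",
                         "insomnia")
.DEFAULT_LINEAR_OUTCOMES <- c("pace", "clock_aa", "bioage_aa", "cognition",
                              "multimorbidity")
## one proportion (granulocytes) is the implicit reference: the six sum to 1
.DEFAULT_CELLPROP_COLS <- c("prop_nk", "prop_b", "prop_cd4", "prop_cd8",
                            "prop_mono")

.runOne <- function(tab, spec, cv = FALSE, cvK = 5L, cvSeed = 1L) {
  sub <- buildAnalysisSample(tab, spec)
  d <- standardizeVariables(sub, spec)
  res <- if (spec$family == "linear")
    fitLinearWeighted(d$y, d$X, d$weights)
  else
    fitLogisticWeighted(d$y, d$X, d$weights)
  res$focal <- res$term %in% d$focalCols
  res$n <- attr(res, "n")
  res$r.squared <- if (spec$family == "linear") attr(res, "r.squared")
                   else attr(res, "pseudo.r.squared")
  if (cv) {
    cvm <- kfoldCv(spec, tab, k = cvK, seed = cvSeed)
    res$cv.r2 <- cvm$cvR2
    res$cv.rmse <- cvm$rmse
    res$cv.mae <- cvm$mae
    res$full.r2 <- cvm$fullR2
  }
  res
}

#' Run the full association model grid
#'
#' Executes the analysis families over a scored cohort:
#' \describe{
#'   \item{\code{"scores"}}{each composite score regressed on all
#'     socio-behavioral covariates jointly plus batch dummies (the
#'     score-prediction layout).}
#'   \item{\code{"outcomes"}}{each aging outcome regressed on each score plus
#'     all covariates and batch; 6-year mortality uses weighted logistic
#'     regression, the rest weighted least squares.}
#'   \item{\code{"outcomes_pace"}}{the outcome models with the standardized
#'     pace-of-aging covariate added.}
#'   \item{\code{"outcomes_cellprops"}}{the outcome models with immune
#'     cell-type proportions added (one proportion held out as reference).}
#' }
#' Benjamini-Hochberg FDR adjustment is applied within each family: across
#' the score models term-by-term for \code{"scores"} (the models differ in
#' their dependent variable), and across scores within each outcome for the
#' outcome families.  Per-model failures are recorded and the run continues.
#'
#' @param x a [SenescenceCohort-class] (scored internally) or a data.frame
#'   already containing phenotype and score columns.
#' @param scoreNames score column names; defaults to the cohort's gene-set
#'   names.
#' @param families subset of
#'   \code{c("scores", "outcomes", "outcomes_pace", "outcomes_cellprops")}.
#' @param linearOutcomes,logisticOutcomes outcome column names by family.
#' @param covariates socio-behavioral adjustment columns.
#' @param batch include batch dummies.
#' @param weightCol survey-weight column, or NULL for unweighted fits.
#' @param excludePresumedAlive sensitivity filter for mortality models.
#' @param cellPropCols cell-type proportion columns for the adjusted family.
#' @param cv run [kfoldCv()] for every outcome-family model.
#' @param cvK,cvSeed folds and seed for cross-validation.
#' @param keepBatchTerms keep the batch-dummy rows in the output
#'   (default FALSE).
#' @return tidy data.frame, one row per model x term, with columns
#'   \code{family, outcome, score, term, focal, estimate, se, statistic,
#'   p.value, fdr.p, or, or.low, or.high, n, r.squared} (plus CV columns when
#'   requested) and an \code{attr(, "failures")} data.frame of skipped models.
#' @export
runModelGrid <- function(x, scoreNames = NULL,
                         families = c("scores", "outcomes", "outcomes_pace"),
                         linearOutcomes = .DEFAULT_LINEAR_OUTCOMES,
                         logisticOutcomes = "mortality",
                         covariates = .DEFAULT_COVARIATES,
                         batch = TRUE, weightCol = "weight",
                         excludePresumedAlive = FALSE,
                         cellPropCols = .DEFAULT_CELLPROP_COLS,
                         cv = FALSE, cvK = 5L, cvSeed = 1L,
                         keepBatchTerms = FALSE) {
  if (is(x, "SenescenceCohort")) {
    if (is.null(scoreNames)) scoreNames <- names(geneSets(x))
    sc <- scoreAll(x)
    tab <- cbind(phenotypes(x), sc[, setdiff(names(sc), "sample_id"),
                                   drop = FALSE])
  } else {
    stopifnot(is.data.frame(x))
    if (is.null(scoreNames))
      stop("scoreNames is required when x is a data.frame", call. = FALSE)
    tab <- x
  }
  families <- match.arg(families, c("scores", "outcomes", "outcomes_pace",
                                    "outcomes_cellprops"),
                        several.ok = TRUE)
  if ("bioage_aa" %in% linearOutcomes && !"bioage_aa" %in% names(tab) &&
      all(c("bioage", "age_years") %in% names(tab)))
    tab$bioage_aa <- ageAccelResiduals(tab$bioage, tab$age_years)

  rows <- list()
  failures <- list()
  addModel <- function(family, outcome, score, spec, withCv) {
    res <- tryCatch(.runOne(tab, spec, cv = withCv, cvK = cvK, cvSeed = cvSeed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <<-
        data.frame(family = family, outcome = outcome, score = score,
                   message = conditionMessage(res), stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    res$family <- family
    res$outcome <- outcome
    res$score <- score
    rows[[length(rows) + 1L]] <<- res
  }

  if ("scores" %in% families)
    for (sn in scoreNames)
      addModel("scores", sn, sn,
               modelSpec(sn, "linear", focal = covariates, covariates = character(),
                         batch = batch, weightCol = weightCol),
               withCv = FALSE)
  outcomeFamilies <- intersect(families,
                               c("outcomes", "outcomes_pace",
                                 "outcomes_cellprops"))
  for (fam in outcomeFamilies) {
    extra <- switch(fam, outcomes = character(),
                    outcomes_pace = "pace",
                    outcomes_cellprops = cellPropCols)
    outs <- c(linearOutcomes, logisticOutcomes)
    if (fam == "outcomes_pace") outs <- setdiff(outs, "pace")
    for (oc in outs)
      for (sn in scoreNames)
        addModel(fam, oc, sn,
                 modelSpec(oc,
                           if (oc %in% logisticOutcomes) "logistic" else "linear",
                           focal = sn, covariates = covariates,
                           batch = batch, weightCol = weightCol,
                           excludePresumedAlive = excludePresumedAlive &&
                             oc %in% logisticOutcomes,
                           extra = extra),
                 withCv = cv)
  }
  if (!length(rows))
    stop("every model in the grid failed", call. = FALSE)
  ## bind with union of columns (logistic adds or/or.low/or.high, cv adds more)
  allCols <- unique(unlist(lapply(rows, names)))
  res <- do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(allCols, names(r))) r[[cc]] <- NA_real_
    r[, allCols]
  }))
  lead <- c("family", "outcome", "score", "term", "focal")
  res <- res[, c(lead, setdiff(allCols, lead))]
  if (!keepBatchTerms) res <- res[!startsWith(res$term, "batch"), , drop = FALSE]

  ## family-wise BH-FDR
  res$fdr.p <- NA_real_
  sc <- res$family == "scores" & res$focal
  for (tm in unique(res$term[sc])) {
    idx <- which(sc & res$term == tm)
    res$fdr.p[idx] <- bhFdr(res$p.value[idx])
  }
  oc <- res$family != "scores" & res$focal
  for (fam in unique(res$family[oc]))
    for (out in unique(res$outcome[oc & res$family == fam])) {
      idx <- which(oc & res$family == fam & res$outcome == out)
      res$fdr.p[idx] <- bhFdr(res$p.value[idx])
    }
  rownames(res) <- NULL
  structure(res,
            failures = if (length(failures)) do.call(rbind, failures)
                       else data.frame())
}
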