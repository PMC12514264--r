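#' Specify one regression model of the association grid
#'
#' @param outcome outcome column name; \code{"mortality"} is derived from
#'   \code{vital_status} (statuses 3/4 = deceased) and \code{"bioage_aa"} from
#'   residualizing \code{bioage} on \code{age_years} when absent.
#' @param family \code{"linear"} (weighted least squares) or
#'   \code{"logistic"} (weighted maximum likelihood).
#' @param focal focal predictor column(s), reported first.
#' @param covariates adjustment covariate columns (factors expand to dummies
#'   against their first level).
#' @param batch include batch-plate dummies (default TRUE).
#' @param weightCol survey-weight column, or NULL for unweighted.
#' @param excludePresumedAlive drop vital-status-2 rows (sensitivity filter
#'   for mortality models).
#' @param extra additional continuous adjustment columns (e.g. the pace
#'   covariate, cell-type proportions).
#' @return list of class \code{"senModelSpec"}.
#' @export
modelSpec <- function(outcome, family = c("linear", "logistic"),
                      focal = character(), covariates = character(),
                      batch = TRUE, weightCol = "weight",
                      excludePresumedAlive = FALSE, extra = character()) {
  family <- match.arg(family)
  if (outcome %in% c(focal, covariates, extra))
    stop("outcome must not appear among the predictors", call. = FALSE)
  structure(list(outcome = outcome, family = family, focal = focal,
                 covariates = covariates, batch = isTRUE(batch),
                 weightCol = weightCol,
                 excludePresumedAlive = isTRUE(excludePresumedAlive),
                 extra = extra),
            class = "senModelSpec")
}

#' Build the complete-case analysis sample for one model
#'
#' Derives the outcome where needed (6-year mortality coded deceased iff
#' vital status is 3 or 4; biological-age acceleration as the residual of
#' biological on chronological age over the non-missing rows), optionally
#' drops the "presumed alive" (status 2) rows, and keeps complete cases on
#' every model variable.  Unused factor levels are dropped.
#'
#' @param table phenotype data.frame (typically with score columns merged).
#' @param spec a [modelSpec()].
#' @return filtered data.frame with attribute \code{"n"}.
#' @export
buildAnalysisSample <- function(table, spec) {
  stopifnot(inherits(spec, "senModelSpec"), is.data.frame(table))
  tab <- table
  if (spec$outcome == "mortality") {
    if (!"vital_status" %in% names(tab))
      stop("mortality models require a vital_status column", call. = FALSE)
    bad <- stats::na.omit(setdiff(unique(tab$vital_status), 1:4))
    if (length(bad))
      stop(sprintf("unknown vital-status code(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (spec$excludePresumedAlive)
      tab <- tab[is.na(tab$vital_status) | tab$vital_status != 2L, ,
                 drop = FALSE]
    tab$mortality <- ifelse(is.na(tab$vital_status), NA_integer_,
                            as.integer(tab$vital_status %in% c(3L, 4L)))
  }
  if (spec$outcome == "bioage_aa" && !"bioage_aa" %in% names(tab)) {
    if (!all(c("bioage", "age_years") %in% names(tab)))
      stop("bioage_aa requires bioage and age_years columns", call. = FALSE)
    tab$bioage_aa <- ageAccelResiduals(tab$bioage, tab$age_years)
  }
  vars <- unique(c(spec$outcome, spec$focal, spec$covariates, spec$extra,
                   if (spec$batch) "batch", spec$weightCol))
  miss <- setdiff(vars, names(tab))
  if (length(miss))
    stop(sprintf("model variables not found in table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  keep <- stats::complete.cases(tab[, vars, drop = FALSE])
  out <- droplevels(tab[keep, , drop = FALSE])
  if (nrow(out) == 0L)
    stop("analysis sample is empty after complete-case filtering",
         call. = FALSE)
  structure(out, n = nrow(out))
}

## is a column continuous (numeric, more than two distinct values)?
.isContinuous <- function(x) is.numeric(x) && length(unique(x[!is.na(x)])) > 2L

#' Standardize model variables and expand the design matrix
#'
#' Continuous predictors (and the outcome, for linear models) are z-scored on
#' the analysis sample so that coefficients are fully standardized betas
#' (logistic: odds ratio per SD of the focal predictor); 0/1 indicators are
#' left binary; factors expand to treatment dummies against their declared
#' (first) level, batch included when flagged.
#'
#' @param table analysis sample from [buildAnalysisSample()].
#' @param spec a [modelSpec()].
#' @return list with \code{y}, design matrix \code{X} (no intercept column),
#'   \code{weights}, and \code{focalCols} (column names of X belonging to the
#'   focal predictors).
#' @export
standardizeVariables <- function(table, spec) {
  stopifnot(inherits(spec, "senModelSpec"))
  preds <- unique(c(spec$focal, spec$covariates, spec$extra,
                    if (spec$batch) "batch"))
  tab <- table
  for (v in preds) {
    x <- tab[[v]]
    if (is.numeric(x)) {
      u <- unique(x)
      if (length(u) == 1L)
        stop(sprintf("zero-variance variable '%s' cannot be standardized", v),
             call. = FALSE)
      if (!all(u %in% c(0, 1))) tab[[v]] <- zstd(x, v)  # 0/1 stays binary
    }
  }
  y <- tab[[spec$outcome]]
  if (spec$family == "linear") {
    y <- zstd(y, spec$outcome)
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1)))
      stop("logistic family requires a 0/1 outcome", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("logistic outcome has a single class", call. = FALSE)
  }
  fml <- stats::as.formula(paste("~", paste(sprintf("`%s`", preds),
                                            collapse = " + ")))
  X <- stats::model.matrix(fml, data = tab)[, -1, drop = FALSE]
  colnames(X) <- gsub("`", "", colnames(X))
  focalCols <- unlist(lapply(spec$focal, function(f) {
    hit <- colnames(X)[colnames(X) == f | startsWith(colnames(X), f)]
    hit
  }))
  w <- if (!is.null(spec$weightCol)) tab[[spec$weightCol]] else NULL
  list(y = y, X = X, weights = w, focalCols = unique(focalCols))
}

.tidyFit <- function(fit, vc, terms, df = Inf) {
  est <- stats::coef(fit)[terms]
  se <- sqrt(diag(vc))[terms]
  stat <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  data.frame(term = terms, estimate = unname(est), se = unname(se),
             statistic = unname(stat), p.value = unname(p),
             conf.low = unname(est - q * se),
             conf.high = unname(est + q * se),
             stringsAsFactors = FALSE)
}

.checkRank <- function(fit, cols) {
  bad <- which(is.na(stats::coef(fit)))
  if (length(bad)) {
    aliased <- cols[bad - 1L]  # coefficient order: intercept, then X columns
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
}

#' Weighted least squares with standardized coefficients
#'
#' Fits \eqn{y = X\beta + \epsilon} by (survey-)weighted least squares.  When
#' analytic weights are supplied, heteroskedasticity-robust (HC1 sandwich)
#' standard errors are reported, approximating design-based survey variance;
#' classical standard errors otherwise.  With variables prepared by
#' [standardizeVariables()], the coefficients are the reported standardized
#' betas.
#'
#' @param y numeric outcome vector.
#' @param X design matrix (no intercept column; one is added).
#' @param weights optional positive weights.
#' @return data.frame, one row per term (intercept omitted), with columns
#'   \code{term, estimate, se, statistic, p.value, conf.low, conf.high} and
#'   attributes \code{r.squared}, \code{n}, \code{family}.
#' @export
fitLinearWeighted <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (!is.null(weights) && any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  Xmat <- X
  fit <- if (is.null(weights)) stats::lm(y ~ Xmat)
         else stats::lm(y ~ Xmat, weights = weights)
  .checkRank(fit, colnames(X))
  robust <- !is.null(weights) && stats::var(weights) > 0
  vc <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  out <- .tidyFit(fit, vc, names(stats::coef(fit))[-1], df = fit$df.residual)
  out$term <- colnames(X)
  structure(out, r.squared = summary(fit)$r.squared, n = length(y),
            family = "linear")
}

#' Weighted logistic regression with odds ratios per SD
#'
#' Fits a binomial (quasibinomial when analytic weights are supplied) GLM by
#' weighted maximum likelihood.  Robust (HC0 sandwich) standard errors are
#' used under weights.  Reports the odds ratio per unit (per SD for
#' standardized predictors) with a 95\% Wald interval.  Non-convergence and
#' (quasi-)separation abort with a diagnostic.
#'
#' @param y 0/1 outcome with both classes present.
#' @param X design matrix (no intercept column).
#' @param weights optional positive weights.
#' @return data.frame, one row per term (intercept omitted), with columns
#'   \code{term, estimate, se, statistic, p.value, or, or.low, or.high} and
#'   attributes \code{n}, \code{family}, \code{pseudo.r.squared} (McFadden).
#' @export
fitLogisticWeighted <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("logistic outcome must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("logistic outcome has a single class", call. = FALSE)
  if (!is.null(weights) && any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
  separated <- FALSE
  Xmat <- X
  fit <- withCallingHandlers(
    if (is.null(weights)) stats::glm(y ~ Xmat, family = fam)
    else stats::glm(y ~ Xmat, family = fam, weights = weights),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated)
    stop(paste("(quasi-)separation detected: fitted probabilities numerically",
               "0 or 1; the focal effect is not identifiable"), call. = FALSE)
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  .checkRank(fit, colnames(X))
  robust <- !is.null(weights) && stats::var(weights) > 0
  vc <- if (robust) sandwich::vcovHC(fit, type = "HC0") else stats::vcov(fit)
  out <- .tidyFit(fit, vc, names(stats::coef(fit))[-1], df = Inf)
  out$term <- colnames(X)
  out$or <- exp(out$estimate)
  out$or.low <- exp(out$conf.low)
  out$or.high <- exp(out$conf.high)
  nullDev <- fit$null.deviance
  structure(out, n = length(y), family = "logistic",
            pseudo.r.squared = 1 - fit$deviance / nullDev)
}

#' Age-acceleration residuals
#'
#' Residuals from the least-squares regression (with intercept) of a
#' biological-age measure on chronological age; by construction they have
#' mean zero and are in years, interpretable as acceleration (positive) or
#' deceleration (negative) relative to chronological age.  Missing inputs
#' give missing residuals; the fit uses complete pairs.
#'
#' @param bioage numeric biological-age vector.
#' @param chronage numeric chronological-age vector (non-constant).
#' @return numeric residual vector, same length as the inputs.
#' @examples
#' ageAccelResiduals(c(60, 70, 85), c(60, 70, 80))
#' @export
ageAccelResiduals <- function(bioage, chronage) {
  stopifnot(length(bioage) == length(chronage))
  ok <- !is.na(bioage) & !is.na(chronage)
  if (sum(ok) < 3L)
    stop("need at least 3 complete (bioage, age) pairs", call. = FALSE)
  if (stats::var(chronage[ok]) == 0)
    stop("chronological age is constant; residuals undefined", call. = FALSE)
  fit <- stats::lm(bioage[ok] ~ chronage[ok])
  out <- rep(NA_real_, length(bioage))
  out[ok] <- stats::residuals(fit)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, \eqn{\tilde p_{(i)} = \min_{j \ge i} (p_{(j)} m / j)} capped at
#' 1, mapped back to input order.  The adjustment is order-preserving and the
#' adjusted values never fall below the raw ones.
#'
#' @param pvalues numeric vector of finite p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)))
    stop("p-values must be finite numbers", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

## seeded fold assignment; stratified round-robin within class for logistic
.assignFolds <- function(y, k, seed, stratify) {
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k)
        stop(sprintf("cannot form %d stratified folds: class %s has only %d members",
                     k, format(cls), length(idx)), call. = FALSE)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' k-fold cross-validation of one grid model
#'
#' Seeded fold assignment (stratified on the outcome for logistic models),
#' per-fold out-of-sample \eqn{R^2 = 1 - SSE/SST} with the total sum of
#' squares taken from the held-out fold, RMSE and MAE (computed on predicted
#' probabilities against the 0/1 outcome for logistic models), their
#' averages, and the full-sample \eqn{R^2} under the same convention.
#'
#' @param spec a [modelSpec()].
#' @param table phenotype table (filtered and standardized internally).
#' @param k number of folds (>= 2, default 5).
#' @param seed integer seed for the fold assignment.
#' @return list of class \code{"CVMetrics"}: \code{k}, \code{seed},
#'   \code{cvR2}, \code{fullR2}, \code{rmse}, \code{mae}, \code{perFold}
#'   (data.frame), \code{n}.
#' @export
kfoldCv <- function(spec, table, k = 5L, seed = 1L) {
  stopifnot(inherits(spec, "senModelSpec"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  tab <- buildAnalysisSample(table, spec)
  d <- standardizeVariables(tab, spec)
  n <- length(d$y)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  w <- if (is.null(d$weights)) rep(1, n) else d$weights
  logistic <- spec$family == "logistic"
  fold <- .assignFolds(d$y, k, seed, stratify = logistic)
  X1 <- cbind(`(Intercept)` = 1, d$X)

  predictFit <- function(train, test) {
    if (logistic) {
      fit <- suppressWarnings(
        stats::glm.fit(X1[train, , drop = FALSE], d$y[train], weights = w[train],
                       family = stats::quasibinomial()))
      b <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      stats::plogis(drop(X1[test, , drop = FALSE] %*% b))
    } else {
      fit <- stats::lm.wfit(X1[train, , drop = FALSE], d$y[train], w[train])
      b <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      drop(X1[test, , drop = FALSE] %*% b)
    }
  }
  metrics <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    sse <- sum((obs - pred)^2)
    c(r2 = 1 - sse / sst, rmse = sqrt(mean((obs - pred)^2)),
      mae = mean(abs(obs - pred)))
  }
  perFold <- t(vapply(seq_len(k), function(f) {
    test <- fold == f
    metrics(d$y[test], predictFit(!test, test))
  }, c(r2 = 0, rmse = 0, mae = 0)))
  full <- metrics(d$y, predictFit(rep(TRUE, n), rep(TRUE, n)))
  structure(list(k = k, seed = seed,
                 cvR2 = mean(perFold[, "r2"]), fullR2 = unname(full["r2"]),
                 rmse = mean(perFold[, "rmse"]), mae = mean(perFold[, "mae"]),
                 perFold = data.frame(fold = seq_len(k), perFold),
                 n = n),
            class = "CVMetrics")
}

#' @export
print.CVMetrics <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d, n = %d): mean CV R2 = %.4f, full-sample R2 = %.4f\n",
              x$k, x$seed, x$n, x$cvR2, x$fullR2))
  cat(sprintf("  RMSE = %.4f, MAE = %.4f\n", x$rmse, x$mae))
  invisible(x)
}
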