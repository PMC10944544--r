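# Regression of carbon outcomes on environmental covariates plus a
# single microbiome predictor: additive models with penalized spline
# smooths for selected covariates, a parametric (linear) microbiome
# slope reported raw and standardized, variance-inflation diagnostics,
# and Pearson correlation reporting.

#' Variance inflation factors
#'
#' \eqn{VIF_k = 1/(1 - R^2_k)} where \eqn{R^2_k} regresses predictor k
#' on all other predictors. Categorical predictors are dummy-coded;
#' smooth model terms enter through their covariate's linear column.
#' Values above 5 signal problematic collinearity; perfect collinearity
#' yields `Inf`.
#'
#' @param predictors data frame of model predictors (no outcome)
#' @return named numeric vector of VIFs, one per design column
#' @export
vif <- function(predictors) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 2)
  X <- stats::model.matrix(~ ., data = predictors)[, -1, drop = FALSE]
  vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    sst <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X))
}

#' Pearson correlation with test
#'
#' Product-moment correlation over complete pairs with the usual
#' two-sided t-test.
#'
#' @param x,y numeric vectors
#' @return one-row data frame: r, p, n
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Fit one additive carbon model
#'
#' Regresses a carbon outcome on the covariate set plus exactly one
#' microbiome predictor. Selected covariates enter as penalized cubic
#' B-spline smooths (basis dimension 10, second-derivative penalty,
#' smoothing parameters chosen by GCV); the remaining covariates and
#' the microbiome predictor enter linearly, the microbiome slope being
#' the quantity of interest. The slope is reported raw and standardized
#' (\eqn{\beta \cdot sd(x)/sd(y)}). VIFs are computed on the linearised
#' design (each smooth replaced by its covariate); models with infinite
#' VIF are refused, and `vif_flag` marks max VIF > `vif_limit`.
#'
#' @param data data frame holding outcome, microbiome predictor and
#'   covariates; complete cases are used (n reported)
#' @param outcome name of the outcome column
#' @param microbiome name of the microbiome predictor column
#' @param covariates character vector of covariate column names
#' @param smooth_terms subset of `covariates` to model as smooths
#'   (default: those of MAT, MAP, N deposition and forest age present)
#' @param k spline basis dimension, default 10
#' @param vif_limit collinearity flag threshold, default 5
#' @param hard_fail error (rather than flag) when max VIF exceeds
#'   `vif_limit`, default FALSE
#' @return list of class `carbon_model`: coefficients, the raw and
#'   standardized microbiome slope with SEs and Wald z/p, VIF table,
#'   residuals, n, and the fitted `mgcv::gam` object
#' @export
fit_additive_model <- function(data, outcome, microbiome, covariates,
                               smooth_terms = NULL, k = 10,
                               vif_limit = 5, hard_fail = FALSE) {
  stopifnot(length(microbiome) == 1)
  vars <- c(outcome, microbiome, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (is.null(smooth_terms))
    smooth_terms <- intersect(c("mat", "map", "n_deposition", "age"), covariates)
  lin <- setdiff(covariates, smooth_terms)
  smooth_terms <- vapply(smooth_terms, function(v) {
    kk <- min(k, length(unique(df[[v]])) - 1)
    sprintf("s(%s, bs = 'bs', k = %d, m = c(3, 2))", v, kk)
  }, character(1))
  rhs <- paste(c(microbiome, smooth_terms, lin), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))

  numeric_preds <- vars[-1][vapply(df[vars[-1]], is.numeric, logical(1))]
  vifs <- vif(df[vars[-1]])
  if (any(!is.finite(vifs)))
    stop("perfectly collinear predictors (infinite VIF): ",
         paste(names(vifs)[!is.finite(vifs)], collapse = ", "))
  vif_flag <- max(vifs) > vif_limit
  if (vif_flag && hard_fail)
    stop(sprintf("max VIF %.2f exceeds limit %.1f", max(vifs), vif_limit))

  fit <- mgcv::gam(form, data = df, method = "GCV.Cp")
  edf <- sum(fit$edf)
  if (nrow(df) < 10 * edf)
    warning(sprintf("only %d observations for %.1f effective parameters",
                    nrow(df), edf), call. = FALSE)
  sm <- summary(fit)
  b <- sm$p.table[microbiome, ]
  sd_ratio <- stats::sd(df[[microbiome]]) / stats::sd(df[[outcome]])
  structure(list(
    outcome = outcome, microbiome = microbiome,
    n = nrow(df),
    coefficients = stats::coef(fit),
    slope = unname(b["Estimate"]),
    slope_se = unname(b["Std. Error"]),
    slope_std = unname(b["Estimate"]) * sd_ratio,
    slope_std_se = unname(b["Std. Error"]) * sd_ratio,
    z = unname(b["Estimate"] / b["Std. Error"]),
    p = unname(b["Pr(>|t|)"]),
    vif = vifs, vif_flag = vif_flag,
    residuals = stats::residuals(fit),
    gam = fit), class = "carbon_model")
}

#' @export
print.carbon_model <- function(x, ...) {
  cat(sprintf("carbon model: %s ~ %s + covariates (n = %d)\n",
              x$outcome, x$microbiome, x$n))
  cat(sprintf("  slope %.4g (SE %.3g), standardized %.4g (SE %.3g), p = %.3g\n",
              x$slope, x$slope_se, x$slope_std, x$slope_std_se, x$p))
  cat(sprintf("  max VIF %.2f%s\n", max(x$vif),
              if (x$vif_flag) " [collinearity flag]" else ""))
  invisible(x)
}
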