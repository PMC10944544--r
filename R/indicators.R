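# Indicator-species analysis against continuous carbon covariates:
# median-of-positive-ratios ("poscounts") size factors, method-of-moments
# dispersions shrunk to a parametric trend, per-OTU negative-binomial
# Wald tests of a continuous covariate, and the joint significance +
# effect-size indicator call. Runs on the NON-rarefied count table;
# sequencing depth is handled by the size factors.

#' Poscounts size factors
#'
#' Median-of-ratios normalisation tolerant of zeros: the per-OTU
#' reference is the geometric mean over samples where the OTU is
#' observed; each sample's factor is the median of its positive
#' count/reference ratios, and factors are rescaled to geometric mean 1.
#'
#' @param counts numeric matrix of raw counts, samples in rows
#' @return positive numeric vector of per-sample size factors
#' @export
size_factors_poscounts <- function(counts) {
  counts <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (any(rowSums(counts) == 0)) stop("sample with all-zero counts")
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  ref <- apply(counts, 2, function(x) exp(mean(log(x[x > 0]))))
  s <- vapply(seq_len(nrow(counts)), function(j) {
    r <- counts[j, ] / ref
    stats::median(r[counts[j, ] > 0])
  }, numeric(1))
  s <- s / exp(mean(log(s)))
  names(s) <- rownames(counts)
  s
}

#' Per-OTU dispersion with shrinkage to a parametric trend
#'
#' OTU-wise dispersions come from the method of moments on
#' size-factor-normalised counts, \eqn{\hat\alpha = \max(0,
#' (v - \mu)/\mu^2)}. A parametric mean-dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} is fitted over OTUs with positive
#' \eqn{\hat\alpha}, and the final estimate interpolates between the
#' OTU-wise value and the trend on the log scale (weight `delta`),
#' stabilising noisy per-OTU estimates. Zero OTU-wise dispersions take
#' the trend value directly. A floor keeps estimates strictly positive.
#'
#' @param counts raw count matrix, samples in rows
#' @param s size factors from [size_factors_poscounts()]
#' @param delta weight of the OTU-wise estimate in the log-scale
#'   interpolation, default 0.5
#' @param floor minimum dispersion, default 1e-8
#' @return numeric vector of per-OTU dispersions
#' @export
estimate_dispersions <- function(counts, s, delta = 0.5, floor = 1e-8) {
  counts <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples")
  q <- sweep(counts, 1, s, "/")
  mu <- colMeans(q)
  v <- apply(q, 2, stats::var)
  a_hat <- pmax(0, (v - mu) / mu^2)
  use <- a_hat > 0 & mu > 0
  if (sum(use) >= 2) {
    # trimmed refits keep the trend robust to genuinely differential
    # OTUs, whose marginal variance (and hence MoM dispersion) is
    # inflated by the covariate effect
    keep <- use
    for (it in 1:4) {
      fit <- stats::lm(a_hat[keep] ~ I(1 / mu[keep]))
      a0 <- max(unname(fit$coefficients[1]), floor)
      a1 <- max(unname(fit$coefficients[2]), 0)
      trend <- a0 + a1 / pmax(mu, floor)
      new_keep <- use & a_hat <= 2 * trend
      if (sum(new_keep) < 2 || all(new_keep == keep)) break
      keep <- new_keep
    }
  } else {
    warning("too few positive-dispersion OTUs for a trend; using global median")
    trend <- rep(max(stats::median(a_hat), floor), length(a_hat))
  }
  alpha <- ifelse(a_hat > 0,
                  exp(delta * log(a_hat) + (1 - delta) * log(trend)),
                  trend)
  stats::setNames(pmax(alpha, floor), colnames(counts))
}

# NB log-link IRLS for one OTU: log mu = log s + b0 + b1 x, dispersion
# alpha fixed. Returns coefficients and SEs from the Fisher information.
.nb_irls <- function(y, s, alpha, x, max_iter = 50, tol = 1e-8) {
  X <- cbind(1, x)
  off <- log(s)
  beta <- c(log(pmax(mean(y / s), 1e-8)), 0)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- off + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.numeric(mu / (1 + alpha * mu))
    z <- (eta - off) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, as.numeric(z), w),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    new <- fit$coefficients
    if (max(abs(new - beta)) < tol) { beta <- new; ok <- TRUE; break }
    beta <- new
  }
  if (!ok && it == max_iter) ok <- TRUE  # converged slowly; accept last
  eta <- off + X %*% beta
  mu <- pmin(exp(eta), 1e12)
  w <- as.numeric(mu / (1 + alpha * mu))
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, 2))
  list(beta = as.numeric(beta), se = se, converged = ok && all(is.finite(se)))
}

#' Negative-binomial Wald tests of a continuous covariate
#'
#' Fits, per OTU, \eqn{\log \mu_j = \log s_j + \beta_0 + \beta_1 x_j}
#' with fixed dispersion, and tests \eqn{\beta_1 = 0} with a Wald z.
#' The slope is reported in log2 units: the log2 change in expected
#' abundance per unit change of the covariate, keeping the covariate's
#' units (the covariate enters unstandardised).
#'
#' @param counts raw count matrix, samples in rows; all-zero OTUs are
#'   dropped
#' @param x continuous covariate, one value per sample, finite and
#'   non-constant
#' @param s size factors (computed if `NULL`)
#' @param dispersions per-OTU dispersions (computed if `NULL`)
#' @return data frame, one row per fitted OTU: otu_id, beta0, log2fc,
#'   se, z, p, converged
#' @export
nb_wald_continuous <- function(counts, x, s = NULL, dispersions = NULL) {
  counts <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (!all(is.finite(x))) stop("covariate must be finite")
  if (stats::sd(x) == 0) stop("covariate is constant")
  if (is.null(s)) s <- size_factors_poscounts(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, s)
  ln2 <- log(2)
  rows <- lapply(seq_len(ncol(counts)), function(k) {
    fit <- .nb_irls(counts[, k], s, dispersions[k], x)
    data.frame(otu_id = colnames(counts)[k],
               beta0 = fit$beta[1],
               log2fc = fit$beta[2] / ln2,
               se = fit$se[2] / ln2,
               z = fit$beta[2] / fit$se[2],
               p = 2 * stats::pnorm(-abs(fit$beta[2] / fit$se[2])),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Call indicator taxa
#'
#' An OTU is an indicator of the covariate when its (adjusted) p-value
#' is significant AND its |log2 fold change per unit covariate| strictly
#' exceeds the effect-size threshold, mirroring common RNA-seq practice.
#' Direction is the sign of the slope.
#'
#' @param results data frame from [nb_wald_continuous()]
#' @param alpha significance level, default 0.05
#' @param lfc_threshold effect-size threshold on |log2fc|, default 0.6
#'   (strict inequality)
#' @param adjust `"BH"` (Benjamini-Hochberg, default) or `"none"`
#' @return `results` with added columns p_adj, indicator, direction;
#'   non-converged rows are never called
#' @export
call_indicators <- function(results, alpha = 0.05, lfc_threshold = 0.6,
                            adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  results$p_adj <- if (adjust == "BH") stats::p.adjust(results$p, "BH") else results$p
  results$indicator <- results$converged &
    !is.na(results$p_adj) & results$p_adj <= alpha &
    abs(results$log2fc) > lfc_threshold
  results$direction <- ifelse(results$log2fc > 0, "positive", "negative")
  results$direction[!results$indicator] <- NA_character_
  attr(results, "adjust") <- adjust
  results
}

#' Full indicator-species analysis for one covariate
#'
#' Convenience wrapper: size factors, dispersions, per-OTU Wald tests
#' and the indicator call, on the non-rarefied table.
#'
#' @param table an [otu_table()] or count matrix (samples x rows)
#' @param x continuous covariate per sample
#' @inheritParams call_indicators
#' @return annotated results data frame (see [call_indicators()])
#' @export
indicator_analysis <- function(table, x, alpha = 0.05, lfc_threshold = 0.6,
                               adjust = "BH") {
  res <- nb_wald_continuous(table, x)
  call_indicators(res, alpha = alpha, lfc_threshold = lfc_threshold,
                  adjust = adjust)
}
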