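# Per-variant causal estimates and the pooled fixed-effects IVW model.

#' Odds ratio and confidence interval from a log-odds estimate
#'
#' @param beta Log-odds estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @param level Two-sided coverage in (0, 1); default 0.95.
#' @return Data frame with columns `or`, `ci_low`, `ci_high`.
#' @export
or_ci <- function(beta, se, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("level must be a single number strictly inside (0, 1)")
  if (any(se < 0)) stop("se must be non-negative")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(or = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

#' Per-variant Wald ratio estimate with delta-method standard error
#'
#' The causal log-odds per exposure unit for one variant is the ratio of
#' its outcome association to its exposure association,
#' `beta_iv = beta_gy / beta_gx`. The standard error is the first-order
#' delta-method approximation. `method = "both_terms"` (default) keeps both
#' variance terms,
#' `se_iv^2 = se_gy^2 / beta_gx^2 + beta_gy^2 se_gx^2 / beta_gx^4`;
#' `"first_term"` is the common simplification `se_gy / |beta_gx|`, which
#' ignores uncertainty in the exposure association. No covariance term is
#' included: in a two-sample design the two associations come from
#' non-overlapping samples.
#'
#' @param beta_gx Exposure beta(s) per coded allele, or a harmonized-pair
#'   data frame with columns `beta_gx`, `se_gx`, `beta_gy`, `se_gy`.
#' @param se_gx,beta_gy,se_gy Remaining per-variant statistics (ignored
#'   when `beta_gx` is a data frame).
#' @param method Delta-method variant, see above.
#' @return Data frame with `beta_iv`, `se_iv` and IVW `weight`
#'   (`= se_iv^-2`); carries the pairs' `rsid` when available.
#' @export
wald_ratio <- function(beta_gx, se_gx = NULL, beta_gy = NULL, se_gy = NULL,
                       method = c("both_terms", "first_term")) {
  method <- match.arg(method)
  rsid <- NULL
  if (is.data.frame(beta_gx)) {
    pairs <- beta_gx
    rsid <- pairs$rsid
    beta_gx <- pairs$beta_gx; se_gx <- pairs$se_gx
    beta_gy <- pairs$beta_gy; se_gy <- pairs$se_gy
  }
  if (any(beta_gx == 0))
    stop("beta_gx = 0: Wald ratio undefined (degenerate weak instrument)")
  if (any(se_gx <= 0) || any(se_gy <= 0)) stop("standard errors must be > 0")
  beta_iv <- beta_gy / beta_gx
  se_iv <- switch(method,
    both_terms = sqrt(se_gy^2 / beta_gx^2 +
                        beta_gy^2 * se_gx^2 / beta_gx^4),
    first_term = se_gy / abs(beta_gx))
  out <- data.frame(beta_iv = beta_iv, se_iv = se_iv, weight = se_iv^-2)
  if (!is.null(rsid)) out <- cbind(rsid = rsid, out)
  out
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-variant estimates with weights `w_i = se_i^-2`:
#' `beta = sum(w b) / sum(w)`, `se = sum(w)^-1/2`. Heterogeneity is
#' summarized by Cochran's `Q = sum(w (b_i - beta)^2)` on `k - 1` degrees
#' of freedom and `I2 = max(0, (Q - (k-1)) / Q) * 100` (0 when `k = 1`).
#'
#' @param beta Per-variant estimates (log-odds scale here).
#' @param se Their standard errors, all `> 0`.
#' @param level Confidence level for the odds-ratio interval.
#' @return A list with `k`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `z`,
#'   `pvalue`, `Q`, `df`, `Q_pvalue` (`NA` when `k = 1`), `I2`, `level`.
#' @export
ivw_meta <- function(beta, se, level = 0.95) {
  k <- length(beta)
  if (k < 1L) stop("at least one estimate is required")
  if (length(se) != k) stop("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se))) stop("estimates must be finite")
  if (any(se <= 0)) stop("all standard errors must be > 0")
  w <- se^-2
  beta_pooled <- sum(w * beta) / sum(w)
  se_pooled <- sum(w)^-0.5
  z <- beta_pooled / se_pooled
  pvalue <- 2 * stats::pnorm(-abs(z))
  Q <- sum(w * (beta - beta_pooled)^2)
  df <- k - 1L
  Q_pvalue <- if (k == 1L) NA_real_
              else stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (k == 1L || Q <= 0) 0 else max(0, (Q - df) / Q) * 100
  ci <- or_ci(beta_pooled, se_pooled, level)
  list(k = k, beta = beta_pooled, se = se_pooled,
       or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
       z = z, pvalue = pvalue,
       Q = Q, df = df, Q_pvalue = Q_pvalue, I2 = I2, level = level)
}

.extract_pairs <- function(object) {
  if (inherits(object, "mr_harmonization")) object$pairs
  else if (inherits(object, "instrument_set")) object$pairs
  else if (is.data.frame(object)) object
  else stop("cannot extract harmonized pairs from an object of class ",
            paste(class(object), collapse = "/"))
}

#' Fit a fixed-effects IVW Mendelian randomization model
#'
#' The package's central fitting function. In `mode = "causal"` the pooled
#' estimate combines the per-variant outcome log-odds directly (oriented to
#' raising-allele counts): it tests for, and gives the direction of, a
#' causal effect, but its magnitude is per raising allele, not per exposure
#' unit. In `mode = "magnitude"` each variant first contributes a Wald
#' ratio ([wald_ratio()]), so the pooled estimate is the change in outcome
#' log-odds per unit (typically SD) of the exposure.
#'
#' @param object An `mr_harmonization`, `instrument_set`, or data frame of
#'   oriented harmonized pairs.
#' @param mode `"causal"` (direct SNP-outcome pooling) or `"magnitude"`
#'   (Wald-ratio pooling).
#' @param level Confidence level (default 0.95).
#' @param delta Delta-method variant passed to [wald_ratio()].
#' @param label Optional analysis label shown by `print`.
#' @return An object of class `mr_ivw` with components `estimates` (one
#'   row per variant: `rsid`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `weight`) and `pooled` (see [ivw_meta()]). Supports `print`,
#'   `summary`, `coef`, `vcov`, `confint`, `residuals`, `weights` and
#'   `plot` (forest plot).
#' @examples
#' sim <- simulate_two_sample(sim_config(seed = 7))
#' h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
#' fit <- mr_ivw(h, mode = "magnitude")
#' fit
#' coef(fit)
#' confint(fit)
#' @export
mr_ivw <- function(object, mode = c("causal", "magnitude"), level = 0.95,
                   delta = c("both_terms", "first_term"), label = NULL) {
  mode <- match.arg(mode)
  delta <- match.arg(delta)
  pairs <- .extract_pairs(object)
  if (nrow(pairs) == 0L) stop("no harmonized pairs to analyse")
  if (mode == "magnitude") {
    w <- wald_ratio(pairs, method = delta)
    est_beta <- w$beta_iv
    est_se <- w$se_iv
  } else {
    est_beta <- pairs$beta_gy
    est_se <- pairs$se_gy
  }
  pooled <- ivw_meta(est_beta, est_se, level = level)
  ci <- or_ci(est_beta, est_se, level)
  estimates <- data.frame(rsid = pairs$rsid, beta = est_beta, se = est_se,
                          or = ci$or, ci_low = ci$ci_low,
                          ci_high = ci$ci_high, weight = est_se^-2,
                          stringsAsFactors = FALSE)
  structure(list(call = match.call(), mode = mode, delta = delta,
                 level = level, label = label,
                 estimates = estimates, pooled = pooled),
            class = "mr_ivw")
}

.fmt_or <- function(x) sprintf("%.2f", x)
.fmt_p <- function(p) format(signif(p, 3))

#' @export
print.mr_ivw <- function(x, ...) {
  unit <- if (x$mode == "magnitude") "per exposure unit (SD)"
          else "per raising allele"
  cat("Fixed-effects IVW Mendelian randomization (",
      x$mode, " mode)\n", sep = "")
  if (!is.null(x$label)) cat("Analysis:", x$label, "\n")
  p <- x$pooled
  cat(sprintf("Instruments: %d\nPooled OR %s: %s (%d%% CI %s-%s); p = %s\n",
              p$k, unit, .fmt_or(p$or), round(100 * x$level),
              .fmt_or(p$ci_low), .fmt_or(p$ci_high), .fmt_p(p$pvalue)))
  qp <- if (is.na(p$Q_pvalue)) "NA" else .fmt_p(p$Q_pvalue)
  cat(sprintf("Heterogeneity: Q = %.3f on %d df (p = %s); I2 = %.1f%%\n",
              p$Q, p$df, qp, p$I2))
  invisible(x)
}

#' @export
summary.mr_ivw <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_ivw")
}

#' @export
print.summary.mr_ivw <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-variant estimates:\n")
  est <- fit$estimates
  est$or <- .fmt_or(est$or)
  est$ci_low <- .fmt_or(est$ci_low)
  est$ci_high <- .fmt_or(est$ci_high)
  print(est, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mr_ivw <- function(object, ...) {
  stats::setNames(object$pooled$beta, "beta_ivw")
}

#' @export
vcov.mr_ivw <- function(object, ...) {
  matrix(object$pooled$se^2, 1, 1,
         dimnames = list("beta_ivw", "beta_ivw"))
}

#' @export
confint.mr_ivw <- function(object, parm, level = NULL, ...) {
  if (is.null(level)) level <- object$level
  z <- stats::qnorm((1 + level) / 2)
  p <- object$pooled
  out <- matrix(c(p$beta - z * p$se, p$beta + z * p$se), 1, 2,
                dimnames = list("beta_ivw",
                                paste0(100 * c((1 - level) / 2,
                                               (1 + level) / 2), " %")))
  out
}

#' Residuals of an IVW fit
#'
#' `type = "standardized"` (default) returns `(b_i - b_pooled) / se_i`, the
#' per-variant contribution signs of Cochran's Q; the variant with the
#' largest absolute standardized residual is the leading candidate for a
#' pleiotropic outlier. `type = "raw"` returns `b_i - b_pooled`.
#'
#' @param object An `mr_ivw` fit.
#' @param type `"standardized"` or `"raw"`.
#' @param ... Unused.
#' @return Named numeric vector (names are rsids).
#' @export
residuals.mr_ivw <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  r <- est$beta - object$pooled$beta
  if (type == "standardized") r <- r / est$se
  stats::setNames(r, est$rsid)
}

#' @export
weights.mr_ivw <- function(object, ...) {
  stats::setNames(object$estimates$weight, object$estimates$rsid)
}

#' Forest plot of an IVW fit
#'
#' Per-variant odds ratios with confidence intervals on a log-scaled axis,
#' the pooled estimate at the bottom, and a reference line at OR = 1.
#'
#' @param x An `mr_ivw` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_ivw <- function(x, ...) {
  est <- x$estimates
  p <- x$pooled
  k <- nrow(est)
  ys <- seq(k + 1, 2)
  xlim <- range(c(est$ci_low, est$ci_high, p$ci_low, p$ci_high, 1))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 1.5), log = "x",
                 xlab = "Odds ratio", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = c(ys, 1), labels = c(est$rsid, "Pooled (IVW)"),
                 las = 1, cex.axis = 0.8)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::segments(est$ci_low, ys, est$ci_high, ys)
  graphics::points(est$or, ys, pch = 15,
                   cex = 0.6 + est$weight / max(est$weight))
  graphics::segments(p$ci_low, 1, p$ci_high, 1, lwd = 2)
  graphics::points(p$or, 1, pch = 18, cex = 1.6)
  invisible(x)
}

#' Analyse a named instrument subset
#'
#' Runs the IVW model on one of the analysis subsets defined by the
#' instrument specification's `affects` classes: `"main"` (every variant
#' except the `bivariate_opposite` one), `"igf1_only"`, `"igfbp3_only"`,
#' or `"molar_ratio"` (IGF1-only variants, IGFBP3-only variants recoded to
#' their IGFBP3-lowering alleles, plus the `bivariate_opposite` variant;
#' see [code_molar_ratio()]).
#'
#' @param harmonization An `mr_harmonization` object (or harmonized-pair
#'   data frame plus `spec`).
#' @param subset One of `"main"`, `"igf1_only"`, `"igfbp3_only"`,
#'   `"molar_ratio"`.
#' @param spec Instrument specification; defaults to the one stored in
#'   `harmonization`.
#' @param mode,level,delta Passed to [mr_ivw()].
#' @return An `mr_ivw` fit labelled with the subset name.
#' @export
subset_analysis <- function(harmonization,
                            subset = c("main", "igf1_only", "igfbp3_only",
                                       "molar_ratio"),
                            spec = NULL,
                            mode = c("causal", "magnitude"),
                            level = 0.95,
                            delta = c("both_terms", "first_term")) {
  subset <- match.arg(subset)
  mode <- match.arg(mode)
  delta <- match.arg(delta)
  pairs <- .extract_pairs(harmonization)
  if (is.null(spec)) {
    if (!inherits(harmonization, "mr_harmonization"))
      stop("spec must be supplied when harmonization is a plain data frame")
    spec <- harmonization$spec
  }
  classes <- switch(subset,
    main = c("igf1_only", "igfbp3_only", "both"),
    igf1_only = "igf1_only",
    igfbp3_only = "igfbp3_only",
    molar_ratio = c("igf1_only", "igfbp3_only", "bivariate_opposite"))
  wanted <- spec$rsid[spec$affects %in% classes]
  missing <- setdiff(wanted, pairs$rsid)
  if (length(missing))
    stop("subset '", subset, "' needs instrument(s) absent from the ",
         "harmonized pairs: ", paste(missing, collapse = ", "))
  sel <- pairs[match(wanted, pairs$rsid), , drop = FALSE]
  object <- if (subset == "molar_ratio") code_molar_ratio(sel, spec) else sel
  mr_ivw(object, mode = mode, level = level, delta = delta, label = subset)
}

#' Write an IVW fit as a results table
#'
#' One row per variant (rsid, beta, SE, OR, CI bounds, weight) followed by
#' a pooled row that also carries p, Q, df, Q p-value and I-squared — the
#' data behind a forest plot. Values are written at full precision.
#'
#' @param fit An `mr_ivw` fit.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(fit, path) {
  est <- fit$estimates
  p <- fit$pooled
  pooled_row <- data.frame(rsid = "POOLED_IVW", beta = p$beta, se = p$se,
                           or = p$or, ci_low = p$ci_low, ci_high = p$ci_high,
                           weight = NA_real_, stringsAsFactors = FALSE)
  tab <- rbind(est, pooled_row)
  tab$pvalue <- c(rep(NA_real_, nrow(est)), p$pvalue)
  tab$Q <- c(rep(NA_real_, nrow(est)), p$Q)
  tab$Q_df <- c(rep(NA_integer_, nrow(est)), p$df)
  tab$Q_pvalue <- c(rep(NA_real_, nrow(est)), p$Q_pvalue)
  tab$I2 <- c(rep(NA_real_, nrow(est)), p$I2)
  for (col in setdiff(names(tab), "rsid"))
    tab[[col]] <- ifelse(is.na(tab[[col]]), "NA", sprintf("%.17g", tab[[col]]))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
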