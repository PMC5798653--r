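# Power calculation for binary-outcome Mendelian randomization designs.

#' Define a binary-outcome MR power design
#'
#' Collects the design quantities of a two-sample MR analysis with a
#' case-control outcome: total sample size `n`, case fraction `K`, the
#' proportion `r2` of exposure variance explained by the instruments, the
#' two-sided significance level and the target power. The normal
#' approximation used throughout treats the IVW estimate as Gaussian with
#' information `n * r2 * K * (1 - K)` per squared log-odds unit, so
#'
#'   power(OR) = Phi( |ln OR| * sqrt(n r2 K (1-K)) - z_{1-alpha/2} ).
#'
#' @param n Total outcome sample size (cases + controls), `>= 1`.
#' @param case_fraction Proportion of cases, strictly in (0, 1).
#' @param r2 Exposure variance explained by the instrument set, in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1); default 0.05.
#' @param power Target power, in (0, 1); default 0.80.
#' @return An object of class `mr_power_design`.
#' @examples
#' d <- mr_power_design(n = 54162, case_fraction = 0.314, r2 = 0.065)
#' min_detectable_or(d, "protective")
#' power_binary(d, 0.90)
#' @export
mr_power_design <- function(n, case_fraction, r2, alpha = 0.05,
                            power = 0.80) {
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  for (nm in c("case_fraction", "r2", "alpha", "power")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop(nm, " must lie strictly inside (0, 1)")
  }
  structure(list(n = n, case_fraction = case_fraction, r2 = r2,
                 alpha = alpha, power = power),
            class = "mr_power_design")
}

.design_info <- function(design) {
  sqrt(design$n * design$r2 * design$case_fraction *
         (1 - design$case_fraction))
}

#' Power to detect an odds ratio under a binary-outcome MR design
#'
#' @param design An [mr_power_design()] object.
#' @param or_alt Odds ratio(s) under the alternative, `> 0`.
#' @return Power value(s) in (0, 1).
#' @export
power_binary <- function(design, or_alt) {
  stopifnot(inherits(design, "mr_power_design"))
  if (any(!is.finite(or_alt)) || any(or_alt <= 0))
    stop("or_alt must be > 0")
  stats::pnorm(abs(log(or_alt)) * .design_info(design) -
                 stats::qnorm(1 - design$alpha / 2))
}

#' Minimum detectable odds ratio at the design's target power
#'
#' Solves the power approximation for the effect size:
#' `|ln OR| = (z_power + z_{1-alpha/2}) / sqrt(n r2 K (1-K))`. The
#' protective direction returns `exp(-|ln OR|)` (an OR below 1), the
#' harmful direction its reciprocal.
#'
#' @param design An [mr_power_design()] object.
#' @param direction `"protective"` or `"harmful"`.
#' @return The minimum detectable odds ratio.
#' @export
min_detectable_or <- function(design,
                              direction = c("protective", "harmful")) {
  stopifnot(inherits(design, "mr_power_design"))
  direction <- match.arg(direction)
  labs <- (stats::qnorm(design$power) +
             stats::qnorm(1 - design$alpha / 2)) / .design_info(design)
  if (direction == "protective") exp(-labs) else exp(labs)
}

#' @export
print.mr_power_design <- function(x, ...) {
  cat("Binary-outcome MR power design\n")
  cat(sprintf("  n = %s, case fraction = %.3f, instrument R2 = %.3f\n",
              format(x$n, big.mark = ","), x$case_fraction, x$r2))
  cat(sprintf("  alpha = %.3f (two-sided), target power = %.2f\n",
              x$alpha, x$power))
  cat(sprintf("  Minimum detectable OR: %.3f (protective), %.3f (harmful)\n",
              min_detectable_or(x, "protective"),
              min_detectable_or(x, "harmful")))
  grid <- c(0.80, 0.85, 0.90, 0.95, 1.05, 1.10, 1.15, 1.20)
  pw <- power_binary(x, grid)
  cat("  Power at OR grid:\n")
  for (i in seq_along(grid))
    cat(sprintf("    OR %.2f: %.3f\n", grid[i], pw[i]))
  invisible(x)
}

#' Standard deviation from an interquartile range
#'
#' For an approximately normal trait measured in a large sample the
#' standard deviation is close to IQR / 1.35 (the exact normal divisor is
#' 2 * qnorm(0.75) = 1.349); used to put exposure associations on an SD
#' scale when only quartiles are published.
#'
#' @param iqr Interquartile range, `> 0`.
#' @return The implied standard deviation.
#' @export
sd_from_iqr <- function(iqr) {
  if (any(!is.finite(iqr)) || any(iqr <= 0)) stop("iqr must be > 0")
  iqr / 1.35
}
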