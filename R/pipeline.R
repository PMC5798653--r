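# End-to-end orchestration: read -> harmonize -> analyses -> report files.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

.ANALYSES <- c("main", "igf1_only", "igfbp3_only", "molar_ratio")

#' Run the full two-sample MR pipeline from a configuration
#'
#' Reads the exposure/outcome tables and instrument specification,
#' harmonizes them, runs the requested analysis subsets, optionally adds a
#' power section, and (when `outdir` is set) writes the per-analysis
#' results tables, the harmonization audit and a plain-text summary. Any
#' stage's hard error aborts with a stage-labelled message; soft
#' exclusions (e.g. dropped palindromic variants) accumulate in the
#' report. Report files contain no timestamps, so two runs on the same
#' inputs are byte-identical.
#'
#' @param config A named list or the path to a YAML file with entries:
#'   `exposure`, `outcome`, `instruments` (paths);
#'   `exposure_dialect`/`outcome_dialect` (dialect name or mapping,
#'   default `"canonical"`); `analyses` (subset of `"main"`,
#'   `"igf1_only"`, `"igfbp3_only"`, `"molar_ratio"`; default all);
#'   `mode` (`"causal"` or `"magnitude"`); `level`;
#'   `palindrome_policy`; `power` (list with `n`, `case_fraction`, `r2`,
#'   optional `alpha`, `power`); `overlap` (list of named lists with
#'   `n_overlap`, `n_total`); `outdir` (optional output directory).
#' @return An object of class `mr_report`: list with `analyses` (named
#'   `mr_ivw` fits), `harmonization`, `power` (design or `NULL`),
#'   `overlap` (data frame or `NULL`) and `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("[config] file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (field in c("exposure", "outcome", "instruments")) {
    if (is.null(config[[field]]))
      stop("[config] missing required entry '", field, "'")
    if (!file.exists(config[[field]]))
      stop("[config] ", field, " file not found: ", config[[field]])
  }
  analyses <- config$analyses %||% .ANALYSES
  analyses <- match.arg(analyses, .ANALYSES, several.ok = TRUE)
  mode <- config$mode %||% "causal"
  level <- config$level %||% 0.95
  policy <- config$palindrome_policy %||% "drop_ambiguous"

  exposure <- .stage("read_exposure", read_association_table(
    config$exposure, dialect = config$exposure_dialect %||% "canonical",
    quiet = TRUE))
  outcome <- .stage("read_outcome", read_association_table(
    config$outcome, dialect = config$outcome_dialect %||% "canonical",
    trait = config$outcome_trait, scale = config$outcome_scale,
    quiet = TRUE))
  spec <- .stage("read_instruments", read_instrument_spec(config$instruments))

  harmonization <- .stage("harmonize",
    harmonize_pairs(exposure, outcome, spec, policy = policy))

  fits <- lapply(analyses, function(a) .stage(paste0("analysis_", a),
    subset_analysis(harmonization, subset = a, mode = mode, level = level)))
  names(fits) <- analyses

  power <- NULL
  if (!is.null(config$power)) {
    pw <- config$power
    power <- .stage("power", mr_power_design(
      n = pw$n, case_fraction = pw$case_fraction, r2 = pw$r2,
      alpha = pw$alpha %||% 0.05, power = pw$power %||% 0.80))
  }
  overlap <- NULL
  if (!is.null(config$overlap)) {
    overlap <- .stage("overlap", do.call(rbind, lapply(
      names(config$overlap), function(nm) {
        o <- config$overlap[[nm]]
        data.frame(label = nm, n_overlap = o$n_overlap, n_total = o$n_total,
                   percent = overlap_fraction(o$n_overlap, o$n_total),
                   stringsAsFactors = FALSE)
      })))
  }

  report <- structure(list(analyses = fits, harmonization = harmonization,
                           power = power, overlap = overlap,
                           outdir = config$outdir),
                      class = "mr_report")
  if (!is.null(config$outdir)) .stage("write_report",
                                      .write_report_files(report))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_report_files <- function(report) {
  dir.create(report$outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$analyses))
    write_mr_results(report$analyses[[nm]],
                     file.path(report$outdir, paste0("results_", nm, ".tsv")))
  write_harmonization_report(report$harmonization,
                             file.path(report$outdir,
                                       "harmonization_audit.tsv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(report$outdir, "summary.txt"))
  invisible(report$outdir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR analysis report\n")
  cat(strrep("=", 29), "\n\n")
  print(x$harmonization)
  for (nm in names(x$analyses)) {
    cat("\n")
    print(x$analyses[[nm]])
  }
  if (!is.null(x$power)) {
    cat("\n")
    print(x$power)
  }
  if (!is.null(x$overlap)) {
    cat("\nSample overlap between source GWAS:\n")
    for (i in seq_len(nrow(x$overlap)))
      cat(sprintf("  %s: %s of %s participants (%.1f%%)\n",
                  x$overlap$label[i],
                  format(x$overlap$n_overlap[i], big.mark = ","),
                  format(x$overlap$n_total[i], big.mark = ","),
                  x$overlap$percent[i]))
  }
  invisible(x)
}

#' Percentage overlap between two study samples
#'
#' @param n_overlap Number of shared participants, `0 <= n_overlap <=
#'   n_total`.
#' @param n_total Total participants in the reference sample, `> 0`.
#' @return Percentage, rounded to one decimal.
#' @export
overlap_fraction <- function(n_overlap, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_overlap < 0) || any(n_overlap > n_total))
    stop("n_overlap must lie in [0, n_total]")
  round(100 * n_overlap / n_total, 1)
}

#' Pool a primary estimate with replication-sample estimates
#'
#' Fixed-effects IVW pooling (via [ivw_meta()]) of one primary-sample
#' estimate for a variant with replication-sample estimates of the same
#' variant on the same allele orientation. If the replication data frame
#' carries a `same_orientation` column, any `FALSE` entry is an error —
#' replication estimates must be recoded before pooling.
#'
#' @param primary Named vector or list with `beta` and `se`.
#' @param replications Data frame with columns `beta`, `se` and optional
#'   `same_orientation` (logical). May have zero rows.
#' @param level Confidence level.
#' @return An [ivw_meta()] pooled-result list.
#' @export
replication_meta <- function(primary, replications = NULL, level = 0.95) {
  primary <- as.list(primary)
  beta <- primary$beta
  se <- primary$se
  if (!is.null(replications) && nrow(replications)) {
    if (!is.null(replications$same_orientation) &&
        !all(replications$same_orientation))
      stop("replication estimate(s) flagged with a different allele ",
           "orientation; recode before pooling")
    beta <- c(beta, replications$beta)
    se <- c(se, replications$se)
  }
  ivw_meta(beta, se, level = level)
}
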