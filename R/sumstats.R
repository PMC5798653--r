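# Reading, validating and writing GWAS summary-association tables.
# All downstream stages consume the data frames produced here.

.SNV_ALLELES <- c("A", "C", "G", "T")

.ASSOC_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "trait", "scale")

#' Column dialects for summary-statistic tables
#'
#' A dialect maps the canonical field names used throughout the package to
#' the column headers of a particular source file. `canonical_dialect()` is
#' the package's own fixed column layout; `igap_dialect()` matches the
#' header style of published Alzheimer case-control meta-analysis tables
#' (`MarkerName`, `Effect_allele`, `Non_Effect_allele`, `Beta`, `SE`,
#' `Pvalue`). Any named list with entries for at least `rsid`,
#' `effect_allele`, `other_allele`, `beta`, `se` and `pvalue` is a valid
#' dialect; `chrom`, `pos`, `eaf`, `trait` and `scale` are optional.
#'
#' @return A named list mapping canonical field names to column headers.
#' @export
canonical_dialect <- function() {
  list(rsid = "rsid", chrom = "chrom", pos = "pos",
       effect_allele = "effect_allele", other_allele = "other_allele",
       eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue",
       trait = "trait", scale = "scale")
}

#' @rdname canonical_dialect
#' @export
igap_dialect <- function() {
  list(rsid = "MarkerName", effect_allele = "Effect_allele",
       other_allele = "Non_Effect_allele", beta = "Beta", se = "SE",
       pvalue = "Pvalue")
}

.resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- switch(dialect,
                      canonical = canonical_dialect(),
                      igap = igap_dialect(),
                      stop("unknown dialect name: ", dialect))
  }
  if (!is.list(dialect)) stop("dialect must be a named list or a dialect name")
  dialect
}

#' Read a GWAS summary-association table
#'
#' Reads a tab-delimited table of per-SNP association results and validates
#' every row. Rows violating the record invariants (alleles must be two
#' distinct single bases among A/C/G/T, `se > 0`, p-value in (0, 1], finite
#' beta, effect-allele frequency in \[0, 1\] when present) are rejected and
#' reported with row numbers; no row is silently skipped.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column-name mapping: a list from [canonical_dialect()]
#'   family, the name `"canonical"` or `"igap"`, or a custom named list.
#' @param trait,scale Optional labels applied to every record when the
#'   source table has no trait/scale columns (e.g. `trait = "AD"`,
#'   `scale = "log_odds"`).
#' @param quiet Suppress the record/rejection count message.
#' @return A data frame of validated association records with columns
#'   `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `trait`, `scale`, carrying a `"rejections"`
#'   attribute (data frame with `row`, `rsid`, `reason`).
#' @seealso [write_association_table()], [validate_associations()]
#' @export
read_association_table <- function(path, dialect = canonical_dialect(),
                                   trait = NULL, scale = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  dialect <- .resolve_dialect(dialect)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col))
      stop("dialect does not map required column '", field, "'")
    if (!col %in% names(raw))
      stop("required column '", col, "' (field '", field,
           "') not present in ", path)
  }
  pull <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  records <- data.frame(
    rsid = as.character(pull("rsid")),
    chrom = as.character(pull("chrom")),
    pos = num(pull("pos")),
    effect_allele = toupper(as.character(pull("effect_allele"))),
    other_allele = toupper(as.character(pull("other_allele"))),
    eaf = num(pull("eaf")),
    beta = num(pull("beta")),
    se = num(pull("se")),
    pvalue = num(pull("pvalue")),
    trait = if (is.null(trait)) as.character(pull("trait")) else trait,
    scale = if (is.null(scale)) as.character(pull("scale")) else scale,
    stringsAsFactors = FALSE
  )
  validate_associations(records, source = path, quiet = quiet)
}

#' Validate association records
#'
#' Applies the record invariants to a data frame of association records and
#' splits it into accepted records and row-level rejections. Every input
#' row ends up in exactly one of the two: accepted records plus rejection
#' diagnostics always sum to the input row count.
#'
#' @param records Data frame with at least the columns of
#'   [read_association_table()]'s output.
#' @param source Label used in messages.
#' @param quiet Suppress the summary message.
#' @return The accepted rows, with attribute `"rejections"`.
#' @export
validate_associations <- function(records, source = "<in-memory>",
                                  quiet = FALSE) {
  n <- nrow(records)
  reason <- rep("", n)
  add <- function(reason, bad, why) {
    bad[is.na(bad)] <- FALSE
    ifelse(bad, ifelse(reason == "", why, paste(reason, why, sep = "; ")),
           reason)
  }
  bad_allele <- !(records$effect_allele %in% .SNV_ALLELES) |
    !(records$other_allele %in% .SNV_ALLELES) |
    records$effect_allele == records$other_allele
  reason <- add(reason, bad_allele | is.na(bad_allele),
                "effect_allele != other_allele, both in {A,C,G,T}")
  reason <- add(reason, is.na(records$se) | records$se <= 0, "se > 0")
  reason <- add(reason, is.na(records$pvalue) | records$pvalue <= 0 |
                  records$pvalue > 1, "pvalue in (0,1]")
  reason <- add(reason, !is.finite(records$beta), "beta finite")
  reason <- add(reason, !is.na(records$eaf) &
                  (records$eaf < 0 | records$eaf > 1), "eaf in [0,1]")
  ok <- reason == ""
  rejections <- data.frame(row = which(!ok),
                           rsid = records$rsid[!ok],
                           reason = reason[!ok],
                           stringsAsFactors = FALSE)
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  if (!quiet)
    message(source, ": ", nrow(out), " record(s) accepted, ",
            nrow(rejections), " rejected")
  out
}

#' Write association records in the canonical dialect
#'
#' Writes a tab-separated table with a fixed column order so that repeated
#' runs diff cleanly. Numeric columns are serialized with 17 significant
#' digits, which makes write-then-read an exact round trip for doubles.
#'
#' @param records Data frame of association records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(records, path) {
  out <- records[, .ASSOC_COLS, drop = FALSE]
  for (col in c("pos", "eaf", "beta", "se", "pvalue")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read or write an instrument specification
#'
#' An instrument specification names the variants used as instruments, the
#' exposure each one instruments, the allele that raises that exposure, and
#' an `affects` class describing which traits the variant determines:
#' `igf1_only`, `igfbp3_only`, `both`, or `bivariate_opposite` (a variant
#' with inverse effects on the two traits, used only in the molar-ratio
#' analysis).
#'
#' @param path Path to a tab-separated file with columns `rsid`,
#'   `exposure_trait`, `raising_allele`, `affects`.
#' @return Data frame with those four columns.
#' @export
read_instrument_spec <- function(path) {
  if (!file.exists(path)) stop("instrument spec file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("rsid", "exposure_trait", "raising_allele", "affects")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("instrument spec is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$raising_allele <- toupper(df$raising_allele)
  .check_instrument_spec(df)
  df
}

#' @rdname read_instrument_spec
#' @param spec Instrument-specification data frame.
#' @export
write_instrument_spec <- function(spec, path) {
  .check_instrument_spec(spec)
  utils::write.table(spec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.AFFECTS_CLASSES <- c("igf1_only", "igfbp3_only", "both", "bivariate_opposite")

.check_instrument_spec <- function(spec) {
  if (anyDuplicated(spec$rsid))
    stop("duplicate rsid(s) in instrument spec: ",
         paste(unique(spec$rsid[duplicated(spec$rsid)]), collapse = ", "))
  bad <- !spec$affects %in% .AFFECTS_CLASSES
  if (any(bad))
    stop("invalid affects class(es): ", paste(unique(spec$affects[bad]),
                                              collapse = ", "))
  if (!all(spec$raising_allele %in% .SNV_ALLELES))
    stop("raising_allele must be one of A, C, G, T")
  invisible(TRUE)
}

#' Select instrument records from an association table
#'
#' Returns the records matching the specification's rsids, in specification
#' order. Variants absent from the table are reported via the `"missing"`
#' attribute (and a message), never silently dropped. Two records for the
#' same rsid and trait are an ambiguity and raise an error; when a table
#' holds several traits, the specification's `exposure_trait` (or the
#' `trait` argument) disambiguates.
#'
#' @param records Association-record data frame.
#' @param spec Instrument specification (see [read_instrument_spec()]).
#' @param trait Optional trait filter applied to `records` first.
#' @param quiet Suppress the missing-rsid message.
#' @return The matching records in `spec` order, with attribute
#'   `"missing"` listing absent rsids (possibly empty).
#' @export
select_instruments <- function(records, spec, trait = NULL, quiet = FALSE) {
  if (anyDuplicated(spec$rsid)) stop("instrument spec rsids must be unique")
  recs <- as.data.frame(records)
  if (!is.null(trait)) recs <- recs[recs$trait %in% trait, , drop = FALSE]
  picked <- vector("list", nrow(spec))
  missing <- character(0)
  for (i in seq_len(nrow(spec))) {
    hit <- recs[recs$rsid == spec$rsid[i], , drop = FALSE]
    if (nrow(hit) == 0L) {
      missing <- c(missing, spec$rsid[i])
      next
    }
    if (nrow(hit) > 1L) {
      if (anyDuplicated(hit$trait))
        stop("ambiguous records: rsid ", spec$rsid[i],
             " appears more than once for the same trait")
      if (!is.null(spec$exposure_trait)) {
        hit <- hit[hit$trait == spec$exposure_trait[i], , drop = FALSE]
      }
      if (nrow(hit) != 1L)
        stop("ambiguous records for rsid ", spec$rsid[i],
             ": multiple traits and no matching exposure_trait")
    }
    picked[[i]] <- hit
  }
  out <- do.call(rbind, picked)
  if (is.null(out)) out <- recs[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  if (length(missing) && !quiet)
    message(length(missing), " instrument(s) missing from table: ",
            paste(missing, collapse = ", "))
  out
}
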