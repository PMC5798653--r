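# Allele harmonization: align exposure and outcome records to a common
# coded allele and orient effect signs to the exposure-raising allele.
# Every transformation is recorded in a flips audit string so the mapping
# from input records to stored betas is fully reproducible.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_alleles <- function(x) unname(.COMPLEMENT[x])

is_palindromic <- function(a1, a2) complement_alleles(a1) == a2

.new_pair <- function(exposure, beta_gy, se_gy, eaf_gy, flips) {
  out <- data.frame(
    rsid = exposure$rsid,
    coded_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_gx = exposure$beta,
    se_gx = exposure$se,
    eaf = exposure$eaf,
    beta_gy = beta_gy,
    se_gy = se_gy,
    eaf_gy = eaf_gy,
    exposure_trait = exposure$trait,
    orientation = NA_character_,
    flips = paste(flips, collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

.exclusion <- function(rsid, reason) {
  structure(list(rsid = rsid, reason = reason),
            class = "harmonization_exclusion")
}

#' Align outcome alleles to the exposure's coded allele
#'
#' Puts an exposure record and an outcome record for the same variant on a
#' common coded allele. If the outcome's effect/other alleles are swapped
#' relative to the exposure, the outcome beta is negated and its
#' effect-allele frequency complemented; if the alleles match only after
#' strand complementing (A<->T, C<->G), they are complemented first.
#' Palindromic variants (A/T or C/G pairs), whose strand cannot be resolved
#' from alleles alone, are handled by `policy`:
#'
#' * `"drop_ambiguous"` (default): drop the pair when either effect-allele
#'   frequency is missing or lies inside the ambiguity window
#'   (frequencies too close to 0.5 to tell strands apart); otherwise infer
#'   the strand by frequency matching, negating the outcome beta when the
#'   frequencies disagree about which allele is the minor one.
#' * `"drop_all"`: drop every palindromic pair.
#' * `"assume_forward"`: assume both sources report the same strand.
#'
#' @param exposure,outcome One-row association-record data frames for the
#'   same rsid.
#' @param policy Palindromic-variant policy (see above).
#' @param ambiguity_window Frequency interval within which a palindromic
#'   variant's strand cannot be inferred from frequency.
#' @return A one-row `harmonized_pair` data frame (unoriented; columns
#'   `beta_gx`, `se_gx`, `beta_gy`, `se_gy`, `flips`, ...), or a
#'   `harmonization_exclusion` object when the pair is dropped by policy.
#'   Irreconcilable allele sets are a hard error.
#' @export
align_alleles <- function(exposure, outcome,
                          policy = c("drop_ambiguous", "drop_all",
                                     "assume_forward"),
                          ambiguity_window = c(0.42, 0.58)) {
  policy <- match.arg(policy)
  if (exposure$rsid != outcome$rsid)
    stop("rsid mismatch: ", exposure$rsid, " vs ", outcome$rsid)
  ea <- exposure$effect_allele; oa <- exposure$other_allele
  eb <- outcome$effect_allele;  ob <- outcome$other_allele
  flips <- character(0)
  beta_gy <- outcome$beta
  eaf_gy <- outcome$eaf

  if (is_palindromic(ea, oa)) {
    if (!is_palindromic(eb, ob) || !eb %in% c(ea, oa))
      stop("alleles irreconcilable for ", exposure$rsid, ": exposure ",
           ea, "/", oa, " vs outcome ", eb, "/", ob)
    if (policy == "drop_all")
      return(.exclusion(exposure$rsid, "palindromic variant (policy drop_all)"))
    # nominal same-strand alignment first
    if (eb == oa) {
      beta_gy <- -beta_gy
      eaf_gy <- 1 - eaf_gy
      flips <- c(flips, "allele_swap")
    }
    if (policy == "drop_ambiguous") {
      ambiguous <- function(f) is.na(f) ||
        (f >= ambiguity_window[1] && f <= ambiguity_window[2])
      if (ambiguous(exposure$eaf) || ambiguous(eaf_gy))
        return(.exclusion(exposure$rsid,
                          "palindromic variant with ambiguous allele frequency"))
      if ((exposure$eaf < 0.5) != (eaf_gy < 0.5)) {
        # frequencies disagree: the sources report opposite strands
        beta_gy <- -beta_gy
        eaf_gy <- 1 - eaf_gy
        flips <- c(flips, "palindromic_strand_flip")
      }
    }
    return(.new_pair(exposure, beta_gy, outcome$se, eaf_gy, flips))
  }

  if (eb == ea && ob == oa) {
    # already aligned
  } else if (eb == oa && ob == ea) {
    beta_gy <- -beta_gy
    eaf_gy <- 1 - eaf_gy
    flips <- c(flips, "allele_swap")
  } else {
    ceb <- complement_alleles(eb); cob <- complement_alleles(ob)
    if (ceb == ea && cob == oa) {
      flips <- c(flips, "strand_complement")
    } else if (ceb == oa && cob == ea) {
      beta_gy <- -beta_gy
      eaf_gy <- 1 - eaf_gy
      flips <- c(flips, "strand_complement", "allele_swap")
    } else {
      stop("alleles irreconcilable for ", exposure$rsid, ": exposure ",
           ea, "/", oa, " vs outcome ", eb, "/", ob)
    }
  }
  .new_pair(exposure, beta_gy, outcome$se, eaf_gy, flips)
}

#' Orient a harmonized pair to the exposure-raising allele
#'
#' If the pair's coded allele is not the specified raising allele, both the
#' exposure and outcome betas are negated (log-odds are subtracted from
#' zero), the coded and other alleles are switched and the coded-allele
#' frequencies complemented. Standard errors are never touched. Orienting
#' an already-oriented pair is the identity.
#'
#' @param pair A `harmonized_pair` row from [align_alleles()].
#' @param spec Instrument-specification data frame (or one row of it)
#'   containing the pair's rsid.
#' @return The oriented pair, `orientation = "exposure_raising"`, with any
#'   sign flip appended to `flips`.
#' @export
orient_to_raising_allele <- function(pair, spec) {
  row <- spec[spec$rsid == pair$rsid, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("instrument spec must contain exactly one row for ", pair$rsid)
  raising <- row$raising_allele
  if (raising == pair$coded_allele) {
    pair$orientation <- "exposure_raising"
    return(pair)
  }
  if (raising != pair$other_allele)
    stop("raising allele ", raising, " for ", pair$rsid,
         " is neither of the pair's alleles (", pair$coded_allele, "/",
         pair$other_allele, ")")
  pair$beta_gx <- -pair$beta_gx
  pair$beta_gy <- -pair$beta_gy
  pair$other_allele <- pair$coded_allele
  pair$coded_allele <- raising
  pair$eaf <- 1 - pair$eaf
  pair$eaf_gy <- 1 - pair$eaf_gy
  pair$flips <- paste(c(if (nzchar(pair$flips)) pair$flips, "orient_sign_flip"),
                      collapse = ";")
  pair$orientation <- "exposure_raising"
  pair
}

#' Recode harmonized pairs to the molar-ratio orientation
#'
#' Builds the instrument set for the IGF1:IGFBP3 molar-ratio analysis.
#' Variants affecting only IGF1 keep their IGF1-raising orientation
#' (raising IGF1 raises the ratio); variants affecting only IGFBP3 are
#' sign-flipped so they are coded on the IGFBP3-lowering allele (lowering
#' the denominator raises the ratio); a `bivariate_opposite` variant is
#' kept coded on its higher-IGF1/lower-IGFBP3 allele, which is the raising
#' allele its specification row records. Variants of class `"both"` have
#' conflicting effects on numerator and denominator and are rejected.
#'
#' @param pairs Data frame of exposure-raising oriented harmonized pairs.
#' @param spec Instrument specification covering the pairs' rsids.
#' @return An `instrument_set`: list with `name`, `exposure` and the
#'   recoded `pairs` (orientation `"ratio_raising"`).
#' @export
code_molar_ratio <- function(pairs, spec) {
  pairs <- as.data.frame(pairs)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    row <- spec[spec$rsid == pairs$rsid[i], , drop = FALSE]
    if (nrow(row) != 1L)
      stop("instrument spec must contain exactly one row for ", pairs$rsid[i])
    cls <- row$affects
    if (cls == "both")
      stop("variant ", pairs$rsid[i], " affects both traits and cannot be ",
           "coded for the molar-ratio analysis")
    if (cls == "igfbp3_only") {
      # recode onto the IGFBP3-lowering allele
      pairs$beta_gx[i] <- -pairs$beta_gx[i]
      pairs$beta_gy[i] <- -pairs$beta_gy[i]
      tmp <- pairs$coded_allele[i]
      pairs$coded_allele[i] <- pairs$other_allele[i]
      pairs$other_allele[i] <- tmp
      pairs$eaf[i] <- 1 - pairs$eaf[i]
      pairs$eaf_gy[i] <- 1 - pairs$eaf_gy[i]
      pairs$flips[i] <- paste(c(if (nzchar(pairs$flips[i])) pairs$flips[i],
                                "ratio_recode"), collapse = ";")
    }
    keep[i] <- TRUE
  }
  pairs$orientation <- "ratio_raising"
  structure(list(name = "molar_ratio",
                 exposure = "IGF1:IGFBP3 molar ratio",
                 pairs = pairs[keep, , drop = FALSE]),
            class = "instrument_set")
}

#' Harmonize exposure and outcome tables against an instrument spec
#'
#' Runs [align_alleles()] and [orient_to_raising_allele()] for every
#' variant in the instrument specification, collecting the oriented pairs,
#' the exclusions (with reasons) and a per-variant audit of the
#' transformations applied.
#'
#' @param exposure,outcome Association-record data frames.
#' @param spec Instrument specification.
#' @param policy,ambiguity_window Passed to [align_alleles()].
#' @return An object of class `mr_harmonization`: list with `pairs`
#'   (oriented harmonized pairs), `exclusions` (rsid + reason) and `audit`
#'   (rsid, status, flips).
#' @export
harmonize_pairs <- function(exposure, outcome, spec,
                            policy = "drop_ambiguous",
                            ambiguity_window = c(0.42, 0.58)) {
  pair_rows <- vector("list", nrow(spec))
  excl <- list()
  audit <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    rsid <- spec$rsid[i]
    exp_row <- exposure[exposure$rsid == rsid &
                          exposure$trait == spec$exposure_trait[i], ,
                        drop = FALSE]
    if (nrow(exp_row) == 0L)  # fall back to rsid alone (single-trait tables)
      exp_row <- exposure[exposure$rsid == rsid, , drop = FALSE]
    out_row <- outcome[outcome$rsid == rsid, , drop = FALSE]
    status <- NULL
    if (nrow(exp_row) != 1L) {
      status <- if (nrow(exp_row) == 0L) "missing in exposure table"
                else "ambiguous in exposure table"
    } else if (nrow(out_row) != 1L) {
      status <- if (nrow(out_row) == 0L) "missing in outcome table"
                else "ambiguous in outcome table"
    }
    if (!is.null(status)) {
      excl[[length(excl) + 1L]] <- data.frame(rsid = rsid, reason = status,
                                              stringsAsFactors = FALSE)
      audit[[i]] <- data.frame(rsid = rsid, status = "excluded",
                               flips = status, stringsAsFactors = FALSE)
      next
    }
    aligned <- align_alleles(exp_row, out_row, policy = policy,
                             ambiguity_window = ambiguity_window)
    if (inherits(aligned, "harmonization_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(rsid = rsid,
                                              reason = aligned$reason,
                                              stringsAsFactors = FALSE)
      audit[[i]] <- data.frame(rsid = rsid, status = "excluded",
                               flips = aligned$reason,
                               stringsAsFactors = FALSE)
      next
    }
    oriented <- orient_to_raising_allele(aligned, spec)
    pair_rows[[i]] <- oriented
    audit[[i]] <- data.frame(rsid = rsid, status = "harmonized",
                             flips = if (nzchar(oriented$flips))
                               oriented$flips else "none",
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs)) pairs <- .new_pair(
    data.frame(rsid = character(0), effect_allele = character(0),
               other_allele = character(0), beta = numeric(0),
               se = numeric(0), eaf = numeric(0), trait = character(0),
               stringsAsFactors = FALSE),
    numeric(0), numeric(0), numeric(0), character(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 exclusions = if (length(excl)) do.call(rbind, excl)
                              else data.frame(rsid = character(0),
                                              reason = character(0)),
                 audit = do.call(rbind, audit),
                 spec = spec),
            class = "mr_harmonization")
}

#' @export
print.mr_harmonization <- function(x, ...) {
  cat("Harmonization of", nrow(x$audit), "instrument(s):",
      nrow(x$pairs), "pair(s) harmonized,",
      nrow(x$exclusions), "excluded\n")
  flips <- sum(grepl("orient_sign_flip", x$pairs$flips))
  cat("Sign-recoded to the raising allele:", flips, "beta pair(s)\n")
  if (nrow(x$exclusions)) {
    cat("Exclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  invisible(x)
}

#' Write the harmonization audit as a TSV report
#'
#' @param harmonization An `mr_harmonization` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(harmonization, path) {
  utils::write.table(harmonization$audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
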