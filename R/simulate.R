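# Generator of paired exposure/outcome GWAS summary statistics with known
# ground truth. Simulation is at the summary-statistics level: per-SNP
# standard errors come from the usual GWAS information approximations,
#   se_x = 1 / sqrt(2 p q n_exposure)                  (SD-scale trait)
#   se_y = 1 / sqrt(2 p q n_total K (1 - K))           (log-odds outcome)
# and the true exposure effect for a SNP explaining a fraction r2 of the
# exposure variance is b = sqrt(r2 / (2 p q)).

.derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

.ALLELE_PAIRS <- list(c("A", "G"), c("C", "T"), c("G", "A"),
                      c("T", "C"), c("A", "C"), c("G", "T"))

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults describe a study-shaped design: 9 independent instruments
#' jointly explaining 6.5% of the exposure variance, an exposure GWAS of
#' 30,884 individuals, and a case-control outcome GWAS of 17,008 cases and
#' 37,154 controls. `theta` is the true causal log-odds of the outcome per
#' SD of the exposure; `pleiotropy` gives per-SNP direct log-odds effects
#' on the outcome that bypass the exposure (horizontal pleiotropy).
#'
#' @param n_snps Number of instruments.
#' @param eafs Effect-allele frequencies, strictly inside (0, 1); default
#'   an even spread from 0.15 to 0.55.
#' @param r2_per_snp Per-SNP exposure variance explained; default equal
#'   shares of 0.065. Must sum to less than 1.
#' @param n_exposure Exposure-GWAS sample size.
#' @param n_cases,n_controls Outcome case-control sample sizes.
#' @param theta True causal log-odds per SD of exposure.
#' @param pleiotropy Per-SNP direct outcome log-odds effects (recycled).
#' @param n_sign_flips Number of SNPs (taken from the start of the set)
#'   whose exposure record is reported on the exposure-lowering allele, so
#'   that harmonization must sign-recode them.
#' @param n_allele_swaps Number of SNPs (taken from the end of the set)
#'   whose outcome record is reported with effect/other alleles swapped
#'   relative to the exposure record.
#' @param noise_scale Multiplier on the sampling noise only (reported
#'   standard errors are unchanged); 0 gives noiseless betas, useful for
#'   exact-identity checks.
#' @param seed Integer RNG seed; the exposure and outcome tables use
#'   seeds derived from it so their noise is independent (two-sample
#'   design).
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_snps = 9, eafs = NULL, r2_per_snp = NULL,
                       n_exposure = 30884, n_cases = 17008,
                       n_controls = 37154, theta = 0, pleiotropy = 0,
                       n_sign_flips = 0, n_allele_swaps = 0,
                       noise_scale = 1, seed = 1L) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (is.null(eafs)) eafs <- seq(0.15, 0.55, length.out = n_snps)
  if (is.null(r2_per_snp)) r2_per_snp <- rep(0.065 / n_snps, n_snps)
  pleiotropy <- rep_len(pleiotropy, n_snps)
  if (length(eafs) != n_snps || length(r2_per_snp) != n_snps)
    stop("eafs and r2_per_snp must have length n_snps")
  if (any(eafs <= 0) || any(eafs >= 1))
    stop("eafs must lie strictly inside (0, 1)")
  if (any(r2_per_snp <= 0) || sum(r2_per_snp) >= 1)
    stop("r2_per_snp must be positive and sum to less than 1")
  if (min(n_exposure, n_cases, n_controls) < 1)
    stop("all sample sizes must be >= 1")
  if (!is.finite(theta)) stop("theta must be finite")
  if (any(!is.finite(pleiotropy))) stop("pleiotropy must be finite")
  if (n_sign_flips < 0 || n_sign_flips > n_snps)
    stop("n_sign_flips must be between 0 and n_snps")
  if (n_allele_swaps < 0 || n_allele_swaps > n_snps)
    stop("n_allele_swaps must be between 0 and n_snps")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (!is.finite(seed) || abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  structure(list(n_snps = as.integer(n_snps), eafs = eafs,
                 r2_per_snp = r2_per_snp,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, theta = theta,
                 pleiotropy = pleiotropy,
                 n_sign_flips = as.integer(n_sign_flips),
                 n_allele_swaps = as.integer(n_allele_swaps),
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "sim_config")
}

.assoc_row <- function(rsid, pos, a1, a2, eaf, beta, se, trait, scale) {
  pvalue <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  data.frame(rsid = rsid, chrom = "1", pos = pos,
             effect_allele = a1, other_allele = a2, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue,
             trait = trait, scale = scale, stringsAsFactors = FALSE)
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Draws one exposure table and one outcome table of per-SNP association
#' records under the model described in [sim_config()]. The observed
#' exposure beta for SNP j is `Normal(b_j, se_xj^2)` with
#' `b_j = sqrt(r2_j / (2 p_j q_j))` (SD-units exposure); the observed
#' outcome log-odds is `Normal(theta * b_j + pleiotropy_j, se_yj^2)`.
#' Reported standard errors equal the true sampling standard deviations.
#' Allele labels are assigned so that `n_sign_flips` SNPs are reported on
#' the exposure-lowering allele and `n_allele_swaps` outcome records have
#' swapped alleles, exercising the harmonization stage downstream. Output
#' is bit-identical for identical configurations (including the seed).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `mr_simulation`: list with `exposure` and
#'   `outcome` association tables, the matching `instruments`
#'   specification, a `truth` data frame (`b`, per-SNP standard errors,
#'   `theta`, `pleiotropy`, raising alleles) and the `config`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  p <- config$eafs
  q <- 1 - p
  b <- sqrt(config$r2_per_snp / (2 * p * q))
  se_x <- 1 / sqrt(2 * p * q * config$n_exposure)
  n_total <- config$n_cases + config$n_controls
  K <- config$n_cases / n_total
  se_y <- 1 / sqrt(2 * p * q * n_total * K * (1 - K))

  set.seed(.derive_seed(config$seed, 1L))
  beta_x <- b + config$noise_scale * se_x * stats::rnorm(n)
  set.seed(.derive_seed(config$seed, 2L))
  beta_y <- config$theta * b + config$pleiotropy +
    config$noise_scale * se_y * stats::rnorm(n)

  rsid <- sprintf("rs%07d", 1000000L + seq_len(n))
  pairs <- .ALLELE_PAIRS[((seq_len(n) - 1L) %% length(.ALLELE_PAIRS)) + 1L]
  a1 <- vapply(pairs, `[`, "", 1L)  # raising allele
  a2 <- vapply(pairs, `[`, "", 2L)

  sign_flip <- seq_len(n) <= config$n_sign_flips
  swap <- seq_len(n) > n - config$n_allele_swaps

  # exposure table: flipped SNPs are reported on the lowering allele
  exposure <- .assoc_row(
    rsid, pos = 1000L * seq_len(n),
    a1 = ifelse(sign_flip, a2, a1), a2 = ifelse(sign_flip, a1, a2),
    eaf = ifelse(sign_flip, q, p),
    beta = ifelse(sign_flip, -beta_x, beta_x),
    se = se_x, trait = "exposure", scale = "sd_units")

  # outcome table: swapped SNPs are reported on the other allele
  outcome <- .assoc_row(
    rsid, pos = 1000L * seq_len(n),
    a1 = ifelse(swap, a2, a1), a2 = ifelse(swap, a1, a2),
    eaf = ifelse(swap, q, p),
    beta = ifelse(swap, -beta_y, beta_y),
    se = se_y, trait = "AD", scale = "log_odds")

  instruments <- data.frame(rsid = rsid, exposure_trait = "exposure",
                            raising_allele = a1, affects = "igf1_only",
                            stringsAsFactors = FALSE)
  truth <- data.frame(rsid = rsid, eaf = p, b = b, se_x = se_x, se_y = se_y,
                      theta = config$theta, pleiotropy = config$pleiotropy,
                      raising_allele = a1, stringsAsFactors = FALSE)
  structure(list(exposure = exposure, outcome = outcome,
                 instruments = instruments, truth = truth, config = config),
            class = "mr_simulation")
}

#' Simulate a pleiotropic-outlier (FOXO3-like) scenario
#'
#' A null causal effect (`theta = 0`) with exactly one SNP given a direct
#' (pleiotropic) effect on the outcome. The outlier's per-allele outcome
#' odds ratio defaults to 1.04, echoing the size of association a single
#' longevity-locus variant can show against an otherwise null instrument
#' set; larger values make the outlier separable by heterogeneity
#' diagnostics. The outlier SNP is renamed `rs2153960` in all tables.
#'
#' @param config A [sim_config()] object (its `theta` and `pleiotropy` are
#'   overridden).
#' @param outlier Index of the pleiotropic SNP (default 1).
#' @param outlier_or Per-allele outcome odds ratio of the outlier.
#' @return An `mr_simulation` (see [simulate_two_sample()]) with an extra
#'   `outlier` element naming the pleiotropic SNP.
#' @export
make_foxo3_scenario <- function(config, outlier = 1L, outlier_or = 1.04) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 2) stop("at least 2 SNPs are required")
  if (outlier < 1 || outlier > config$n_snps) stop("invalid outlier index")
  if (!is.finite(outlier_or) || outlier_or <= 0) stop("outlier_or must be > 0")
  config$theta <- 0
  pleio <- rep(0, config$n_snps)
  pleio[outlier] <- log(outlier_or)
  config$pleiotropy <- pleio
  sim <- simulate_two_sample(config)
  name <- "rs2153960"
  old <- sim$exposure$rsid[outlier]
  for (tab in c("exposure", "outcome", "instruments", "truth"))
    sim[[tab]]$rsid[sim[[tab]]$rsid == old] <- name
  sim$outlier <- name
  sim
}

#' Simulate the packaged IGF study fixture
#'
#' A 10-variant, study-shaped synthetic dataset: 5 variants determining
#' IGF1 only (including `rs2153960`), 2 determining IGFBP3 only, 2
#' determining both, and `rs646776` with opposite effects on the two
#' traits (entering only the molar-ratio analysis). Five of the nine main
#' variants are reported on the exposure-lowering allele and three outcome
#' records have swapped alleles, so harmonization must recode exactly 5
#' betas and repair 3 allele swaps. The causal effect is null.
#'
#' @param seed Integer RNG seed.
#' @param theta True causal log-odds per SD (default 0).
#' @return An `mr_simulation` whose `instruments` carry the IGF trait
#'   labels and affects classes.
#' @export
simulate_igf_study <- function(seed = 20180123L, theta = 0) {
  config <- sim_config(n_snps = 10, theta = theta, n_sign_flips = 5,
                       n_allele_swaps = 3, seed = seed)
  sim <- simulate_two_sample(config)
  affects <- c(rep("igf1_only", 5), rep("igfbp3_only", 2), rep("both", 2),
               "bivariate_opposite")
  traits <- ifelse(affects == "igfbp3_only", "IGFBP3", "IGF1")
  names <- sim$exposure$rsid
  names[1] <- "rs2153960"   # FOXO3 intron variant, IGF1-determining
  names[10] <- "rs646776"   # inverse effects on IGF1 and IGFBP3
  for (tab in c("exposure", "outcome", "instruments", "truth"))
    sim[[tab]]$rsid <- names
  sim$exposure$trait <- traits
  sim$instruments$exposure_trait <- traits
  sim$instruments$affects <- affects
  sim
}

#' Write a simulation to fixture files
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `instruments.tsv` and
#' `truth.tsv` (the ground-truth sidecar) in the canonical dialect.
#'
#' @param sim An `mr_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(sim$exposure, file.path(dir, "exposure.tsv"))
  write_association_table(sim$outcome, file.path(dir, "outcome.tsv"))
  write_instrument_spec(sim$instruments, file.path(dir, "instruments.tsv"))
  truth <- sim$truth
  for (col in c("eaf", "b", "se_x", "se_y", "theta", "pleiotropy"))
    truth[[col]] <- sprintf("%.17g", truth[[col]])
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
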