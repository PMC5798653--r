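# Allele alignment, raising-allele orientation and molar-ratio coding.

test_that("matching alleles pass through and swapped alleles flip the sign", {
  exp <- assoc_row("rs1", "A", "G", beta = 0.12)
  out_same <- assoc_row("rs1", "A", "G", beta = 0.03, trait = "AD")
  p <- align_alleles(exp, out_same)
  expect_equal(p$beta_gy, 0.03)
  expect_equal(p$flips, "")

  out_swap <- assoc_row("rs1", "G", "A", beta = 0.03, eaf = 0.7, trait = "AD")
  p2 <- align_alleles(exp, out_swap)
  expect_equal(p2$beta_gy, -0.03)
  expect_equal(p2$eaf_gy, 0.3)
  expect_match(p2$flips, "allele_swap")
  # SEs are never touched by any flip
  expect_equal(p2$se_gy, out_swap$se)
})

test_that("strand complements are resolved, with and without a swap", {
  exp <- assoc_row("rs1", "A", "G")
  out_comp <- assoc_row("rs1", "T", "C", beta = 0.05, trait = "AD")
  p <- align_alleles(exp, out_comp)
  expect_equal(p$beta_gy, 0.05)
  expect_match(p$flips, "strand_complement")

  out_comp_swap <- assoc_row("rs1", "C", "T", beta = 0.05, trait = "AD")
  p2 <- align_alleles(exp, out_comp_swap)
  expect_equal(p2$beta_gy, -0.05)
  expect_match(p2$flips, "strand_complement;allele_swap")
})

test_that("irreconcilable allele sets are a hard error listing both pairs", {
  exp <- assoc_row("rs1", "A", "G")
  out <- assoc_row("rs1", "A", "C", trait = "AD")
  expect_error(align_alleles(exp, out), "A/G.*A/C")
})

test_that("palindromic variants follow the configured policy", {
  exp <- assoc_row("rs1", "A", "T", eaf = 0.2)
  out_amb <- assoc_row("rs1", "A", "T", beta = 0.02, eaf = 0.50, trait = "AD")
  drop <- align_alleles(exp, out_amb, policy = "drop_ambiguous")
  expect_s3_class(drop, "harmonization_exclusion")
  expect_match(drop$reason, "ambiguous")

  # unambiguous frequencies: same minor allele, keep as is
  out_ok <- assoc_row("rs1", "A", "T", beta = 0.02, eaf = 0.22, trait = "AD")
  kept <- align_alleles(exp, out_ok, policy = "drop_ambiguous")
  expect_equal(kept$beta_gy, 0.02)
  # discordant frequencies imply opposite strands: sign flips
  out_flip <- assoc_row("rs1", "A", "T", beta = 0.02, eaf = 0.78, trait = "AD")
  flipped <- align_alleles(exp, out_flip, policy = "drop_ambiguous")
  expect_equal(flipped$beta_gy, -0.02)
  expect_match(flipped$flips, "palindromic_strand_flip")

  expect_s3_class(align_alleles(exp, out_ok, policy = "drop_all"),
                  "harmonization_exclusion")
  fwd <- align_alleles(exp, out_flip, policy = "assume_forward")
  expect_equal(fwd$beta_gy, 0.02)
})

test_that("orientation recodes betas by subtracting from zero, idempotently", {
  spec <- data.frame(rsid = "rs1", exposure_trait = "exposure",
                     raising_allele = "A", affects = "igf1_only",
                     stringsAsFactors = FALSE)
  exp <- assoc_row("rs1", "A", "G", beta = 0.12)
  out <- assoc_row("rs1", "A", "G", beta = 0.02, trait = "AD")
  pair <- align_alleles(exp, out)
  ok <- orient_to_raising_allele(pair, spec)
  expect_equal(ok$beta_gy, 0.02)          # already raising: unchanged
  expect_equal(ok$orientation, "exposure_raising")

  # coded on the lowering allele: both betas negate, alleles switch
  exp2 <- assoc_row("rs1", "G", "A", beta = -0.12, eaf = 0.7)
  out2 <- assoc_row("rs1", "G", "A", beta = 0.05, trait = "AD")
  pair2 <- align_alleles(exp2, out2)
  flipped <- orient_to_raising_allele(pair2, spec)
  expect_equal(flipped$beta_gy, 0 - 0.05)
  expect_equal(flipped$beta_gx, 0.12)
  expect_true(flipped$beta_gx >= 0)
  expect_equal(flipped$coded_allele, "A")
  expect_equal(flipped$se_gx, pair2$se_gx)
  expect_match(flipped$flips, "orient_sign_flip")
  # double orientation is the identity
  expect_identical(orient_to_raising_allele(flipped, spec), flipped)

  # zero beta survives the flip as zero
  out3 <- assoc_row("rs1", "G", "A", beta = 0, trait = "AD")
  z <- orient_to_raising_allele(align_alleles(exp2, out3), spec)
  expect_equal(z$beta_gy, 0)

  spec_bad <- transform(spec, raising_allele = "C")
  expect_error(orient_to_raising_allele(pair, spec_bad), "neither")
})

test_that("sign flips are involutions: applying the coding twice restores betas", {
  set.seed(42)
  for (i in 1:25) {
    beta_gx <- runif(1, 0.05, 0.3)
    beta_gy <- rnorm(1, 0, 0.05)
    spec <- data.frame(rsid = "rs1", exposure_trait = "exposure",
                       raising_allele = "A", affects = "igf1_only",
                       stringsAsFactors = FALSE)
    exp <- assoc_row("rs1", "G", "A", beta = -beta_gx, eaf = 0.6)
    out <- assoc_row("rs1", "A", "G", beta = beta_gy, eaf = 0.4, trait = "AD")
    oriented <- orient_to_raising_allele(align_alleles(exp, out), spec)
    # align swapped the outcome once, orientation flipped once: net identity
    expect_equal(oriented$beta_gy, beta_gy)
    expect_equal(oriented$beta_gx, beta_gx)
    # the flips audit fully determines the stored betas from the inputs
    n_flips <- sum(strsplit(oriented$flips, ";")[[1]] %in%
                     c("allele_swap", "orient_sign_flip",
                       "palindromic_strand_flip"))
    expect_equal(n_flips, 2L)
    expect_equal(oriented$beta_gy, beta_gy * (-1)^n_flips)
  }
})

test_that("molar-ratio coding keeps IGF1 variants, flips IGFBP3 variants, rejects 'both'", {
  sim <- simulate_igf_study()
  h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
  spec <- sim$instruments
  sel <- h$pairs[h$pairs$rsid %in%
                   spec$rsid[spec$affects != "both"], , drop = FALSE]
  set8 <- code_molar_ratio(sel, spec)
  expect_s3_class(set8, "instrument_set")
  expect_equal(nrow(set8$pairs), 8L)
  expect_true(all(set8$pairs$orientation == "ratio_raising"))

  igfbp3 <- spec$rsid[spec$affects == "igfbp3_only"]
  before <- h$pairs[match(igfbp3, h$pairs$rsid), ]
  after <- set8$pairs[match(igfbp3, set8$pairs$rsid), ]
  expect_equal(after$beta_gy, -before$beta_gy)  # recoded to lowering allele
  expect_equal(after$se_gy, before$se_gy)

  # the bivariate variant stays on its higher-IGF1/lower-IGFBP3 allele
  biv <- h$pairs[h$pairs$rsid == "rs646776", ]
  expect_equal(set8$pairs[set8$pairs$rsid == "rs646776", "beta_gy"],
               biv$beta_gy)

  both_pair <- h$pairs[h$pairs$rsid %in%
                         spec$rsid[spec$affects == "both"][1], , drop = FALSE]
  expect_error(code_molar_ratio(both_pair, spec), "both traits")
})

test_that("the study-shaped instrument sets have cardinalities 9/5/2/8", {
  sim <- simulate_igf_study()
  h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
  expect_equal(subset_analysis(h, "main")$pooled$k, 9L)
  expect_equal(subset_analysis(h, "igf1_only")$pooled$k, 5L)
  expect_equal(subset_analysis(h, "igfbp3_only")$pooled$k, 2L)
  expect_equal(subset_analysis(h, "molar_ratio")$pooled$k, 8L)
})

test_that("harmonize_pairs reports missing variants instead of dropping them silently", {
  sim <- simulate_two_sample(sim_config(seed = 3))
  spec <- rbind(sim$instruments,
                data.frame(rsid = "rs9999999", exposure_trait = "exposure",
                           raising_allele = "A", affects = "igf1_only"))
  h <- harmonize_pairs(sim$exposure, sim$outcome, spec)
  expect_equal(nrow(h$pairs), sim$config$n_snps)
  expect_equal(h$exclusions$rsid, "rs9999999")
  expect_match(h$exclusions$reason, "missing")
  expect_equal(nrow(h$audit), nrow(spec))
})
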