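# Shared helpers: small in-code fixtures and a one-call simulate->fit path.

assoc_row <- function(rsid = "rs1", ea = "A", oa = "G", beta = 0.1,
                      se = 0.02, eaf = 0.3, pvalue = 1e-4,
                      trait = "exposure", scale = "sd_units") {
  data.frame(rsid = rsid, chrom = "1", pos = 1000,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue,
             trait = trait, scale = scale, stringsAsFactors = FALSE)
}

# simulate, harmonize and fit in one call (the full pipeline path)
sim_fit <- function(config, mode = "magnitude") {
  sim <- simulate_two_sample(config)
  h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
  mr_ivw(h, mode = mode)
}

# weighted-least-squares oracle for fixed-effects IVW pooling
wls_oracle <- function(beta, se) {
  w <- se^-2
  fit <- stats::lm(beta ~ 1, weights = w)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se = unname(s$coefficients[1, 2] / s$sigma))
}
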