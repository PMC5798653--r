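# Wald ratios, IVW pooling, heterogeneity and the mr_ivw model object.

test_that("the Wald ratio and its delta-method SE match hand computation", {
  w <- wald_ratio(beta_gx = 0.1, se_gx = 0.02, beta_gy = 0.02, se_gy = 0.01)
  expect_equal(w$beta_iv, 0.2)
  expect_equal(w$se_iv, sqrt(0.0001 / 0.01 + (0.0004 * 0.0004) / 0.0001))
  expect_equal(w$se_iv, 0.1077033, tolerance = 1e-6)
  expect_equal(w$weight, w$se_iv^-2)

  expect_equal(wald_ratio(0.1, 0.02, 0, 0.01)$beta_iv, 0)
  expect_error(wald_ratio(0, 0.02, 0.02, 0.01), "undefined")

  w1 <- wald_ratio(0.1, 0.02, 0.02, 0.01, method = "first_term")
  expect_equal(w1$se_iv, 0.01 / 0.1)
})

test_that("the delta-method SE tracks a parametric-bootstrap SD for a strong instrument", {
  set.seed(101)
  z1 <- rnorm(2e5); z2 <- rnorm(2e5)
  beta_gx <- 0.15; se_gx <- 0.015  # F-proxy = 10
  beta_gy <- 0.03; se_gy <- 0.012
  boot_sd <- sd((beta_gy + se_gy * z1) / (beta_gx + se_gx * z2))
  w <- wald_ratio(beta_gx, se_gx, beta_gy, se_gy)
  expect_lt(abs(w$se_iv - boot_sd) / boot_sd, 0.03)
})

test_that("IVW pooling reproduces hand-worked and degenerate cases", {
  # homogeneous: pooled equals common value, no heterogeneity
  hom <- ivw_meta(rep(0.05, 4), rep(0.1, 4))
  expect_equal(hom$beta, 0.05)
  expect_equal(hom$se, 0.05)
  expect_equal(hom$Q, 0)
  expect_equal(hom$I2, 0)

  # hand-worked two-study case
  two <- ivw_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(two$beta, 0.2)
  expect_equal(two$se, 1 / sqrt(200))
  expect_equal(two$Q, 2.0)
  expect_equal(two$df, 1L)
  expect_equal(two$I2, 50)
  expect_equal(two$Q_pvalue, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(two$Q_pvalue, 0.1573, tolerance = 1e-4)

  # single study: identity, Q undefined territory handled
  one <- ivw_meta(0.04, 0.02)
  expect_equal(one$beta, 0.04)
  expect_equal(one$se, 0.02)
  expect_equal(one$Q, 0)
  expect_true(is.na(one$Q_pvalue))
  expect_equal(one$I2, 0)

  expect_error(ivw_meta(numeric(0), numeric(0)), "at least one")
  expect_error(ivw_meta(c(0.1, 0.2), c(0.1, 0)), "> 0")
})

test_that("IVW equals the weighted-least-squares oracle and metafor", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    beta <- rnorm(k, 0.05, 0.2)
    se <- runif(k, 0.02, 0.5)
    got <- ivw_meta(beta, se)
    oracle <- wls_oracle(beta, se)
    expect_equal(got$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(got$se, oracle$se, tolerance = 1e-12)
    rma <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(got$beta, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(got$se, rma$se, tolerance = 1e-10)
    expect_equal(got$Q, rma$QE, tolerance = 1e-10)
  }
})

test_that("odds-ratio intervals match the normal quantile computation", {
  z <- qnorm(0.975)
  ci <- or_ci(0, 0.1)
  expect_equal(ci$or, 1)
  expect_equal(ci$ci_low, exp(-z * 0.1))
  expect_equal(ci$ci_low, 0.8220, tolerance = 1e-4)
  expect_equal(ci$ci_high, 1.2165, tolerance = 1e-4)

  exact <- or_ci(log(2), 0)
  expect_equal(unlist(exact), c(or = 2, ci_low = 2, ci_high = 2))
  expect_equal(unlist(or_ci(0, 0)), c(or = 1, ci_low = 1, ci_high = 1))
  expect_error(or_ci(0, 0.1, level = 1.2), "level")
  expect_error(or_ci(0, -0.1), "se")
})

test_that("Wald estimates are scale-equivariant and z-statistics scale-invariant", {
  set.seed(21)
  pairs <- data.frame(rsid = sprintf("rs%d", 1:6),
                      beta_gx = runif(6, 0.05, 0.3),
                      se_gx = runif(6, 0.005, 0.02),
                      beta_gy = rnorm(6, 0, 0.03),
                      se_gy = runif(6, 0.01, 0.03))
  fit1 <- mr_ivw(pairs, mode = "magnitude")
  scaled <- transform(pairs, beta_gx = beta_gx * 3, se_gx = se_gx * 3)
  fit3 <- mr_ivw(scaled, mode = "magnitude")
  expect_equal(fit3$pooled$beta, fit1$pooled$beta / 3)
  expect_equal(fit3$pooled$se, fit1$pooled$se / 3)
  expect_equal(fit3$pooled$z, fit1$pooled$z)
  expect_equal(fit3$pooled$pvalue, fit1$pooled$pvalue)
  expect_equal(fit3$pooled$Q, fit1$pooled$Q)
})

test_that("Q is invariant under common rescaling of estimates and their SEs", {
  set.seed(22)
  beta <- rnorm(8, 0.1, 0.2); se <- runif(8, 0.05, 0.3)
  a <- ivw_meta(beta, se)
  b <- ivw_meta(beta * 2.5, se * 2.5)
  expect_equal(b$Q, a$Q)
  expect_equal(b$I2, a$I2)
  expect_equal(b$z, a$z)
})

test_that("the mr_ivw object's accessors agree with its pooled result", {
  fit <- sim_fit(sim_config(seed = 5), mode = "magnitude")
  expect_s3_class(fit, "mr_ivw")
  expect_equal(unname(coef(fit)), fit$pooled$beta)
  expect_equal(unname(vcov(fit)[1, 1]), fit$pooled$se^2)
  ci <- confint(fit)
  expect_equal(unname(exp(ci[1, ])), c(fit$pooled$ci_low, fit$pooled$ci_high))
  # inverse-variance weighted raw residuals sum to zero
  r <- residuals(fit, type = "raw")
  expect_equal(sum(weights(fit) * r), 0, tolerance = 1e-10)
  # standardized residuals reproduce Q
  expect_equal(sum(residuals(fit)^2), fit$pooled$Q)
  expect_output(print(summary(fit)), "Per-variant estimates")
})

test_that("causal mode pools outcome log-odds directly", {
  sim <- simulate_igf_study()
  h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
  fit <- subset_analysis(h, "main", mode = "causal")
  pairs <- h$pairs[match(fit$estimates$rsid, h$pairs$rsid), ]
  expect_equal(fit$estimates$beta, pairs$beta_gy)
  expect_equal(fit$estimates$se, pairs$se_gy)
  man <- ivw_meta(pairs$beta_gy, pairs$se_gy)
  expect_equal(fit$pooled$beta, man$beta)
})

test_that("subset_analysis errors list the missing instruments", {
  sim <- simulate_igf_study()
  h <- harmonize_pairs(sim$exposure, sim$outcome, sim$instruments)
  h$pairs <- h$pairs[h$pairs$rsid != "rs2153960", ]
  expect_error(subset_analysis(h, "main"), "rs2153960")
})

test_that("forest plotting runs without error", {
  fit <- sim_fit(sim_config(seed = 5), mode = "causal")
  path <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_no_error(plot(fit, main = "forest"))
})
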