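test_that("instrument screening applies all three screens and is idempotent", {
  set.seed(21)
  n <- 2000
  trait <- rnorm(n)
  outcome <- 5 + 0.3 * trait + rnorm(n)
  cands <- cbind(self = trait,                      # corr 1 with trait
                 noise = rnorm(n),                  # fails the trait screen
                 good = 0.7 * trait + rnorm(n))
  tr <- cbind(neuroticism = trait)
  # vacuous thresholds retain everything
  all_in <- select_instruments(cands, tr, outcome, r_trait_min = 0,
                               r_outcome_max = 1, alpha = 1)
  expect_setequal(all_in$per_trait$neuroticism, colnames(cands))
  # the trait itself passes the trait screen but fails the outcome screen
  scr <- select_instruments(cands, tr, outcome, r_outcome_max = 0.15)
  rep_self <- scr$report[scr$report$candidate == "self", ]
  expect_equal(rep_self$r_trait, 1)
  expect_false(rep_self$retained)
  rep_noise <- scr$report[scr$report$candidate == "noise", ]
  expect_false(rep_noise$retained)
  expect_true("good" %in% scr$per_trait$neuroticism)
  # idempotence
  scr2 <- select_instruments(cands[, scr$per_trait$neuroticism, drop = FALSE],
                             tr, outcome, r_outcome_max = 0.15)
  expect_setequal(scr2$per_trait$neuroticism, scr$per_trait$neuroticism)
  # a trait with no surviving instrument is a named error
  expect_error(select_instruments(cbind(noise = rnorm(n)), tr, outcome),
               "neuroticism")
})

test_that("first stage satisfies the OLS identities", {
  set.seed(22)
  n <- 300
  Z <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("z1", "z2")))
  C <- cbind(c1 = rnorm(n))
  trait_lin <- 1 + 2 * Z[, 1] - Z[, 2]
  fs <- suppressWarnings(first_stage(trait_lin, Z, C))  # perfect fit
  expect_lt(max(abs(fs$residuals)), 1e-10)
  trait <- trait_lin + rnorm(n)
  fs2 <- first_stage(trait, Z, C, county = rep(1:50, each = 6))
  expect_lt(max(abs(crossprod(Z, fs2$residuals))), 1e-8)
  expect_lt(max(abs(sum(fs2$residuals))), 1e-8)
  expect_gt(fs2$partial_f, 10)
})

test_that("first-stage partial F is strong on the simulated panel", {
  cfg <- recovery_config(seed = 23, n_counties = 300)
  pd <- panel_design(generate_panel(cfg))
  Z <- pd$panel[, grep("^z_neuroticism_", names(pd$panel))]
  C <- as.matrix(pd$panel[, names(cfg$gamma_true)])
  fs <- first_stage(pd$panel$neuroticism, Z, C, county = pd$panel$fips)
  expect_gt(fs$partial_f, 10)
})

test_that("Anderson statistic hits its algebraic extremes and null size", {
  set.seed(24)
  n <- 500
  x <- rnorm(n)
  # trait duplicated as the only instrument: canonical correlation 1, stat n
  out <- anderson_underid(cbind(x), cbind(x))
  expect_equal(out$stat, n)
  expect_equal(out$df, 1)
  # null: instruments unrelated to the trait -> p uniform on [0, 1]
  pvals <- replicate(500, {
    tr <- rnorm(400)
    Z <- matrix(rnorm(400 * 2), ncol = 2)
    anderson_underid(cbind(tr), Z)$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("strong instruments reject underidentification decisively", {
  cfg <- recovery_config(seed = 25, n_counties = 400)
  pd <- panel_design(generate_panel(cfg))
  Z <- as.matrix(pd$panel[, grep("^z_openness_", names(pd$panel))])
  C <- as.matrix(pd$panel[, names(cfg$gamma_true)])
  out <- anderson_underid(cbind(pd$panel$openness), Z, C)
  expect_lt(out$p, 0.001)
})

test_that("Cragg-Donald equals the first-stage partial F when just identified", {
  set.seed(26)
  n <- 400
  z <- cbind(z1 = rnorm(n))
  C <- cbind(c1 = rnorm(n))
  x <- 0.5 * z[, 1] + 0.3 * C[, 1] + rnorm(n)
  cd <- cragg_donald(cbind(x), z, C)
  fs <- first_stage(x, z, C)
  expect_equal(cd, fs$partial_f, tolerance = 1e-8)
  # zero instrument strength: statistic near zero
  cd0 <- cragg_donald(cbind(rnorm(n)), cbind(rnorm(n)), C)
  expect_lt(cd0, 4)
  # non-negative by construction, over random overidentified draws
  for (i in 1:5) {
    Z2 <- matrix(rnorm(n * 3), ncol = 3)
    x2 <- rnorm(n)
    expect_gte(cragg_donald(cbind(x2), Z2), 0)
  }
  expect_equal(stock_yogo_critical(1), 16.38)
  expect_equal(stock_yogo_critical(2), 19.93)
  expect_error(stock_yogo_critical(11), "1-10")
})

test_that("Sargan test is zero for orthogonal residuals and errors when just identified", {
  set.seed(27)
  n <- 300
  Z <- matrix(rnorm(n * 2), ncol = 2)
  C <- cbind(rnorm(n))
  y <- rnorm(n)
  e <- traitpanel:::.resid_on(y, cbind(Z, C))
  out <- sargan(drop(e), Z, C, n_endog = 1)
  expect_lt(abs(out$stat), 1e-8)
  expect_equal(out$df, 1)
  expect_error(sargan(drop(e), Z[, 1, drop = FALSE], C, n_endog = 1),
               "just-identified")
})

test_that("Sargan test has power against an invalid instrument", {
  set.seed(28)
  rej <- mean(replicate(200, {
    n <- 2000
    z1 <- rnorm(n); z2 <- rnorm(n)
    e <- rnorm(n)
    x <- 0.5 * z1 + 0.5 * z2 + rnorm(n)
    y <- 1 + 0.4 * x + e + 0.3 * z2     # z2 loads directly on the error
    ts <- two_sls(y, cbind(x = x), cbind(z1, z2))
    sargan(ts$residuals, cbind(z1, z2), n_endog = 1)$p < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("Davidson-MacKinnon test has correct null behavior and power", {
  set.seed(29)
  # null: exogenous regressor -> p uniform
  pvals <- replicate(500, {
    n <- 400
    z <- cbind(rnorm(n), rnorm(n))
    x <- 0.6 * z[, 1] + 0.6 * z[, 2] + rnorm(n)
    y <- 1 + 0.4 * x + rnorm(n)
    fs <- first_stage(x, z)
    davidson_mackinnon(y, cbind(x), C = NULL, cbind(fs$residuals))$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # power: strong confounding at n = 2000
  rej <- mean(replicate(200, {
    n <- 2000
    q <- rnorm(n)
    z <- cbind(rnorm(n), rnorm(n))
    x <- 0.6 * z[, 1] + 0.6 * z[, 2] + q + rnorm(n)
    y <- 1 + 0.4 * x + q + rnorm(n)
    fs <- first_stage(x, z)
    davidson_mackinnon(y, cbind(x), C = NULL, cbind(fs$residuals))$p < 0.05
  }))
  expect_gt(rej, 0.8)
  # degenerate: regressor inside the instrument span
  x <- rnorm(100)
  fs0 <- suppressWarnings(first_stage(x, cbind(x)))  # perfect fit
  expect_error(davidson_mackinnon(rnorm(100), cbind(x), NULL,
                                  cbind(fs0$residuals)), "degenerate")
})

test_that("2SLS equals OLS when the regressor instruments itself", {
  set.seed(30)
  n <- 200
  x <- rnorm(n)
  C <- cbind(c1 = rnorm(n))
  y <- 2 + 0.7 * x - 0.4 * C[, 1] + rnorm(n)
  ts <- two_sls(y, cbind(x = x), cbind(x = x), C)
  ols <- qr.solve(cbind(1, x, C), y)
  expect_lt(max(abs(ts$coefficients - ols)), 1e-10)
  expect_identical(ts$coefficients,
                   two_sls(y, cbind(x = x), cbind(x = x), C)$coefficients)
})

test_that("control function augmentation is harmless under exogeneity", {
  cfg <- recovery_config(seed = 31, n_counties = 200, confounder_strength = 0)
  pd <- panel_design(generate_panel(cfg))
  naive <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X,
                           pd$panel$fips, K = 8)
  R <- fs_residual_matrix(pd$panel, pd$X, names(cfg$gamma_true))
  cf <- cf_second_stage(pd$panel$lower, pd$panel$upper, pd$X, pd$panel$fips,
                        R, K = 8)
  expect_equal(cf$n_obs, naive$n_obs)     # no residual missingness here
  for (tr in BIG_FIVE) {
    expect_lt(abs(cf$coefficients[[tr]] - naive$coefficients[[tr]]),
              2 * sqrt(cf$se[[tr]]^2 + naive$se[[tr]]^2))
  }
})

test_that("control function corrects omitted-variable bias across seeds", {
  wins <- vapply(1:50, function(s) {
    cfg <- recovery_config(seed = s, n_counties = 250, confounder_strength = 2)
    pd <- panel_design(generate_panel(cfg))
    naive <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X,
                             pd$panel$fips, K = 8)
    R <- fs_residual_matrix(pd$panel, pd$X, names(cfg$gamma_true))
    cf <- cf_second_stage(pd$panel$lower, pd$panel$upper, pd$X,
                          pd$panel$fips, R, K = 8)
    abs(cf$coefficients[["neuroticism"]] - 0.25) <
      abs(naive$coefficients[["neuroticism"]] - 0.25)
  }, logical(1L))
  expect_gte(mean(wins), 0.8)
})

test_that("misaligned residuals are rejected", {
  cfg <- recovery_config(seed = 32, n_counties = 30)
  pd <- panel_design(generate_panel(cfg))
  expect_error(cf_second_stage(pd$panel$lower, pd$panel$upper, pd$X,
                               pd$panel$fips,
                               matrix(0, 10, 2)), "aligned")
})
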