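test_that("Gauss-Hermite nodes reproduce the closed forms", {
  g1 <- gh_nodes(1)
  expect_equal(g1$x, 0)
  expect_equal(g1$w, sqrt(pi))
  g2 <- gh_nodes(2)
  expect_equal(sort(g2$x), c(-1, 1) / sqrt(2))
  expect_equal(g2$w, rep(sqrt(pi) / 2, 2))
  for (K in c(2, 5, 12, 32)) {
    g <- gh_nodes(K)
    expect_lt(abs(sum(g$w) - sqrt(pi)), 1e-12)
    if (K >= 2) {
      # exact for polynomials up to degree 2K-1: integral of x^2 e^{-x^2}
      expect_equal(sum(g$w * g$x^2), sqrt(pi) / 2, tolerance = 1e-12)
    }
  }
  expect_error(gh_nodes(0), "positive")
})

test_that("county likelihood matches normal CDF and density closed forms", {
  expect_equal(county_loglik(0, 9, mu = 0, sigma_u = 0, sigma_e = 1),
               log(pnorm(9) - pnorm(0)))
  expect_equal(county_loglik(0, 0, mu = 0, sigma_u = 0, sigma_e = 1),
               dnorm(0, log = TRUE))
  expect_error(county_loglik(5, 2, mu = 0, sigma_u = 0, sigma_e = 1),
               "upper bound below")
  # zero-width interval is an exact observation even within a censored county
  expect_equal(county_loglik(c(3, 0), c(3, 9), mu = c(0, 0), sigma_u = 0,
                             sigma_e = 2),
               dnorm(3, 0, 2, log = TRUE) + log(pnorm(4.5) - pnorm(0)))
})

test_that("quadrature equals brute-force integration over the random effect", {
  set.seed(10)
  for (draw in 1:5) {
    nT <- sample(2:4, 1)
    mu <- rnorm(nT, 2, 3)
    su <- runif(1, 0.4, 2.5)
    se <- runif(1, 0.8, 3)
    lo <- ifelse(runif(nT) < 0.5, 0, round(abs(rnorm(nT, 8, 4))))
    up <- ifelse(lo == 0, 9, lo)
    gh_val <- county_loglik(lo, up, mu, su, se, K = 32)
    x <- seq(-10 * su, 10 * su, length.out = 20001)
    exact <- lo == up
    f <- vapply(x, function(u) {
      g <- ifelse(exact, dnorm(lo, mu + u, se),
                  pnorm((up - mu - u) / se) - pnorm((lo - mu - u) / se))
      prod(g) * dnorm(u, 0, su)
    }, numeric(1))
    oracle <- log(sum((f[-1] + f[-length(f)]) / 2) * (x[2] - x[1]))
    expect_lt(abs(gh_val - oracle), 1e-6)
  }
})

test_that("analytic score equals the numeric gradient", {
  cfg <- recovery_config(seed = 13, n_counties = 60)
  pd <- panel_design(generate_panel(cfg))
  exact <- pd$panel$lower == pd$panel$upper
  group <- match(pd$panel$fips, unique(pd$panel$fips))
  gh <- gh_nodes(8)
  p <- ncol(pd$X)
  # evaluate around the optimizer's operating region (perturbed midpoint-OLS
  # start); far outside it the clamped interval probabilities make the
  # objective flat and the comparison meaningless
  mid <- ifelse(is.finite(pd$panel$upper),
                (pd$panel$lower + pd$panel$upper) / 2, pd$panel$lower)
  b0 <- qr.solve(pd$X, mid)
  set.seed(14)
  for (draw in 1:3) {
    beta <- b0 + rnorm(p, 0, 0.05)
    su <- runif(1, 0.5, 3); se <- runif(1, 1, 4)
    ga <- traitpanel:::.panel_grad(beta, su, se, pd$panel$lower, pd$panel$upper,
                                   exact, pd$X, group, gh, TRUE)
    fn <- function(par) {
      traitpanel:::.panel_loglik(par[1:p], exp(par[p + 1]), exp(par[p + 2]),
                                 pd$panel$lower, pd$panel$upper, exact,
                                 pd$X, group, gh)
    }
    gn <- traitpanel:::.num_grad(fn, c(beta, log(su), log(se)))
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1)), 1e-6)
  }
})

test_that("records widened to an infinite interval contribute zero log-likelihood", {
  expect_equal(county_loglik(rep(-Inf, 3), rep(Inf, 3), mu = c(1, 2, 3),
                             sigma_u = 1.5, sigma_e = 2, K = 12), 0)
  expect_equal(county_loglik(-Inf, Inf, mu = 0, sigma_u = 0, sigma_e = 1), 0)
})

test_that("log-likelihood is affine invariant when the intercept absorbs a shift", {
  cfg <- recovery_config(seed = 15, n_counties = 80)
  pd <- panel_design(generate_panel(cfg))
  f1 <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X, pd$panel$fips,
                        K = 8)
  X2 <- pd$X
  X2[, "neuroticism"] <- X2[, "neuroticism"] + 50
  f2 <- fit_interval_re(pd$panel$lower, pd$panel$upper, X2, pd$panel$fips,
                        K = 8)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
  expect_equal(f2$coefficients[["neuroticism"]],
               f1$coefficients[["neuroticism"]], tolerance = 1e-4)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] - 50 * f1$coefficients[["neuroticism"]],
               tolerance = 1e-3)
})

test_that("doubling the quadrature order leaves the likelihood unchanged", {
  cfg <- recovery_config(seed = 16, n_counties = 150)
  pd <- panel_design(generate_panel(cfg))
  f12 <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X, pd$panel$fips,
                         K = 12)
  exact <- pd$panel$lower == pd$panel$upper
  group <- match(pd$panel$fips, unique(pd$panel$fips))
  ll24 <- traitpanel:::.panel_loglik(f12$coefficients, f12$sigma_u,
                                     f12$sigma_e, pd$panel$lower,
                                     pd$panel$upper, exact, pd$X, group,
                                     gh_nodes(24))
  expect_lt(abs(f12$loglik - ll24), 1e-4)
})

test_that("rank-deficient designs are rejected", {
  cfg <- recovery_config(seed = 17, n_counties = 30)
  pd <- panel_design(generate_panel(cfg))
  Xbad <- cbind(pd$X, dup = pd$X[, "neuroticism"])
  expect_error(fit_interval_re(pd$panel$lower, pd$panel$upper, Xbad,
                               pd$panel$fips), "rank deficient")
})

test_that("cluster bootstrap is deterministic and degenerates sensibly", {
  cfg <- recovery_config(seed = 18, n_counties = 60)
  pd <- panel_design(generate_panel(cfg))
  fit <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X, pd$panel$fips,
                         K = 8)
  # at this tiny B a couple of refits may fail to converge; the drop warning
  # is expected and must fire identically on both runs
  b1 <- suppressWarnings(cluster_bootstrap(fit, B = 8, seed = 99))
  b2 <- suppressWarnings(cluster_bootstrap(fit, B = 8, seed = 99))
  expect_identical(b1$se, b2$se)
  expect_equal(b1$se_method, "cluster_bootstrap")

  # a single county: every resample is the same block, so SEs are exactly 0
  y <- c(1.2, 2.4, 3.1, 4.9)
  X1 <- cbind(`(Intercept)` = 1, x = c(0, 1, 2, 3))
  f1 <- fit_interval_re(y, y, X1, rep("c1", 4), sigma_u = 0)
  bb <- cluster_bootstrap(f1, B = 2, seed = 1)
  expect_equal(unname(bb$se), c(0, 0))
})

test_that("bootstrap and Hessian standard errors agree at moderate size", {
  cfg <- recovery_config(seed = 19, n_counties = 200)
  pd <- panel_design(generate_panel(cfg))
  fit <- fit_interval_re(pd$panel$lower, pd$panel$upper, pd$X, pd$panel$fips,
                         K = 8)
  boot <- cluster_bootstrap(fit, B = 200, seed = 20)
  ratio <- boot$se[["neuroticism"]] / fit$se[["neuroticism"]]
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("within estimator recovers exact linear relations and drops invariants", {
  county <- rep(c("a", "b", "c"), each = 3)
  x <- c(1, 2, 3, 2, 4, 6, 0, 1, 5)
  fe_effect <- rep(c(10, -5, 2), each = 3)
  y <- 2 * x + fe_effect
  fe <- fit_fe_within(y, cbind(x = x), county)
  expect_equal(fe$coefficients[["x"]], 2, tolerance = 1e-10)

  Xti <- cbind(x = x, z = rep(c(1, 2, 3), each = 3))  # time-invariant z
  expect_warning(fe2 <- fit_fe_within(y, Xti, county), "time-invariant")
  expect_equal(fe2$dropped, "z")
  expect_equal(fe2$coefficients[["x"]], 2, tolerance = 1e-10)

  expect_error(fit_fe_within(1:3, cbind(x = 1:3), c("a", "b", "c")),
               ">= 2 exact")
})

test_that("within estimator on the exact subsample stays near the truth", {
  cfg <- recovery_config(seed = 1)
  sim <- generate_panel(cfg)
  panel <- merge(sim$outcomes, sim$latent, by = c("fips", "year"))
  ex <- panel[panel$observed_exact, ]
  X <- as.matrix(ex[, c(BIG_FIVE, names(cfg$gamma_true))])
  fe <- suppressWarnings(fit_fe_within(ex$lower, X, ex$fips))
  expect_lt(abs(fe$coefficients[["neuroticism"]] - 0.25),
            3 * fe$se[["neuroticism"]])
})
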