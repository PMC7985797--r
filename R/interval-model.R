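#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for \eqn{\int e^{-x^2} f(x) dx \approx \sum_k w_k
#' f(x_k)}; the weights sum to \eqn{\sqrt\pi}. Used to integrate the county
#' random effect out of the interval likelihood after the change of variables
#' \eqn{u = \sqrt2 \sigma_u x}.
#'
#' @param K number of nodes (>= 1).
#' @return list with `x` (abscissae) and `w` (weights).
#' @export
#' @examples
#' gh <- gh_nodes(2) # nodes +-1/sqrt(2), weights sqrt(pi)/2
gh_nodes <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) {
    stop("K must be a positive integer", call. = FALSE)
  }
  K <- as.integer(K)
  if (K == 1L) return(list(x = 0, w = sqrt(pi)))
  gh <- pracma::gaussHermite(K)
  list(x = gh$x, w = gh$w)
}

# per-observation log-contribution at a given random-effect shift:
# densities for exact records, normal CDF differences for intervals
.obs_loglik <- function(lower, upper, exact, mu_shift, sigma_e) {
  ll <- numeric(length(lower))
  if (any(exact)) {
    ll[exact] <- dnorm(lower[exact], mu_shift[exact], sigma_e, log = TRUE)
  }
  if (any(!exact)) {
    p <- pnorm((upper[!exact] - mu_shift[!exact]) / sigma_e) -
      pnorm((lower[!exact] - mu_shift[!exact]) / sigma_e)
    ll[!exact] <- log(pmax(p, 1e-300))
  }
  ll
}

.check_intervals <- function(lower, upper) {
  if (any(upper < lower, na.rm = TRUE)) {
    stop("interval upper bound below lower bound", call. = FALSE)
  }
  # zero-width intervals are exact observations
  is.finite(lower) & is.finite(upper) & lower == upper
}

#' Log-likelihood contribution of one county
#'
#' \deqn{\log \int \prod_t g_t(u) \, \phi(u; 0, \sigma_u^2) \, du}
#' evaluated by Gauss-Hermite quadrature, where \eqn{g_t} is the normal
#' density at the observed point for exact records and the CDF difference
#' \eqn{\Phi((y_2 - \mu - u)/\sigma_e) - \Phi((y_1 - \mu - u)/\sigma_e)} for
#' interval records. `sigma_u = 0` short-circuits the integral.
#'
#' @param lower,upper interval bounds for the county's records (equal for
#'   exact observations; `upper` may be `Inf`).
#' @param mu linear predictor per record.
#' @param sigma_u county random-effect SD (>= 0).
#' @param sigma_e idiosyncratic SD (> 0).
#' @param K quadrature nodes.
#' @return scalar log-likelihood.
#' @export
county_loglik <- function(lower, upper, mu, sigma_u, sigma_e, K = 12L) {
  stopifnot(sigma_e > 0, sigma_u >= 0)
  exact <- .check_intervals(lower, upper)
  if (sigma_u == 0) {
    return(sum(.obs_loglik(lower, upper, exact, mu, sigma_e)))
  }
  gh <- gh_nodes(K)
  contrib <- vapply(gh$x, function(x) {
    sum(.obs_loglik(lower, upper, exact, mu + sqrt(2) * sigma_u * x, sigma_e))
  }, numeric(1L))
  a <- log(gh$w) - 0.5 * log(pi) + contrib
  m <- max(a)
  m + log(sum(exp(a - m)))
}

# per-observation log-contribution plus derivatives wrt the linear predictor
# and sigma_e, at a given random-effect shift
.obs_derivs <- function(lower, upper, exact, mu_shift, sigma_e) {
  n <- length(lower)
  ll <- dmu <- dse <- numeric(n)
  if (any(exact)) {
    r <- (lower[exact] - mu_shift[exact]) / sigma_e
    ll[exact] <- dnorm(lower[exact], mu_shift[exact], sigma_e, log = TRUE)
    dmu[exact] <- r / sigma_e
    dse[exact] <- (r^2 - 1) / sigma_e
  }
  if (any(!exact)) {
    a <- (lower[!exact] - mu_shift[!exact]) / sigma_e
    b <- (upper[!exact] - mu_shift[!exact]) / sigma_e
    fa <- dnorm(a); fb <- dnorm(b)
    afa <- ifelse(is.finite(a), a * fa, 0)
    bfb <- ifelse(is.finite(b), b * fb, 0)
    P <- pnorm(b) - pnorm(a)
    under <- P <= 1e-300          # clamped region: objective is flat there
    P <- pmax(P, 1e-300)
    ll[!exact] <- log(P)
    dmu[!exact] <- ifelse(under, 0, (fa - fb) / (sigma_e * P))
    dse[!exact] <- ifelse(under, 0, (afa - bfb) / (sigma_e * P))
  }
  list(ll = ll, dmu = dmu, dse = dse)
}

# total panel log-likelihood, vectorized across counties via rowsum
.panel_loglik <- function(beta, sigma_u, sigma_e, lower, upper, exact,
                          X, group, gh) {
  mu <- drop(X %*% beta)
  if (sigma_u < 1e-10) {
    return(sum(.obs_loglik(lower, upper, exact, mu, sigma_e)))
  }
  K <- length(gh$x)
  L <- matrix(0, length(mu), K)
  shift <- sqrt(2) * sigma_u * gh$x
  for (k in seq_len(K)) {
    L[, k] <- .obs_loglik(lower, upper, exact, mu + shift[k], sigma_e)
  }
  S <- rowsum(L, group, reorder = FALSE)
  A <- sweep(S, 2L, log(gh$w) - 0.5 * log(pi), "+")
  sum(.row_logsumexp(A))
}

# analytic gradient of the total log-likelihood wrt (beta, log sigma_u,
# log sigma_e); the log-sigma_u entry is omitted when sigma_u is fixed.
# Node posteriors p_ik weight the per-observation score contributions.
.panel_grad <- function(beta, sigma_u, sigma_e, lower, upper, exact,
                        X, group, gh, estimate_su) {
  mu <- drop(X %*% beta)
  if (sigma_u < 1e-10) {
    d <- .obs_derivs(lower, upper, exact, mu, sigma_e)
    g_beta <- drop(crossprod(X, d$dmu))
    g_lse <- sigma_e * sum(d$dse)
    return(if (estimate_su) c(g_beta, 0, g_lse) else c(g_beta, g_lse))
  }
  K <- length(gh$x)
  n <- length(mu)
  L <- Dmu <- Dse <- matrix(0, n, K)
  shift <- sqrt(2) * sigma_u * gh$x
  for (k in seq_len(K)) {
    d <- .obs_derivs(lower, upper, exact, mu + shift[k], sigma_e)
    L[, k] <- d$ll; Dmu[, k] <- d$dmu; Dse[, k] <- d$dse
  }
  S <- rowsum(L, group, reorder = FALSE)
  A <- sweep(S, 2L, log(gh$w) - 0.5 * log(pi), "+")
  P <- exp(A - apply(A, 1L, max))
  P <- P / rowSums(P)
  Pn <- P[group, , drop = FALSE]
  WDmu <- Dmu * Pn
  g_beta <- drop(crossprod(X, rowSums(WDmu)))
  g_lse <- sigma_e * sum(Dse * Pn)
  if (!estimate_su) return(c(g_beta, g_lse))
  g_lsu <- sigma_u * sqrt(2) * sum(colSums(WDmu) * gh$x)
  c(g_beta, g_lsu, g_lse)
}

.num_grad <- function(fn, par, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    hp <- h * max(1, abs(par[i]))
    e <- replace(numeric(length(par)), i, hp)
    (fn(par + e) - fn(par - e)) / (2 * hp)
  }, numeric(1L))
}

.num_hess_from_grad <- function(gr, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    hp <- h * max(1, abs(par[i]))
    e <- replace(numeric(p), i, hp)
    H[, i] <- (gr(par + e) - gr(par - e)) / (2 * hp)
  }
  (H + t(H)) / 2
}

#' Fit the random-effects interval regression by maximum likelihood
#'
#' Maximizes the Gauss-Hermite-quadrature likelihood of the panel interval
#' model
#' \deqn{y^*_{it} = x_{it}'\beta + u_i + e_{it}, \quad
#'       u_i \sim N(0, \sigma_u^2),\; e_{it} \sim N(0, \sigma_e^2)}
#' where each outcome is known only to lie in `[lower, upper]` (equal bounds
#' for exact observations). Optimization is quasi-Newton (BFGS) over
#' `(beta, log sigma_u, log sigma_e)` — the log parameterization keeps both
#' SDs positive by construction — started from OLS on interval midpoints.
#' Standard errors come from the inverse numerical Hessian by default; see
#' [cluster_bootstrap()] for county-resampled SEs.
#'
#' @param lower,upper outcome interval bounds per county-year (`upper` may be
#'   `Inf` for right-open intervals).
#' @param X design matrix (include the intercept and any year dummies; must
#'   be full column rank).
#' @param county county identifier per row.
#' @param K Gauss-Hermite nodes (default 12; doubling K should leave the
#'   log-likelihood essentially unchanged — use that as a stability check).
#' @param sigma_u `NULL` to estimate the random-effect SD, or a fixed
#'   non-negative value (0 collapses the model to pooled interval
#'   regression, and with all-exact data to OLS).
#' @param tol relative-gradient convergence tolerance for the `converged`
#'   flag.
#' @param start optional full start vector `c(beta, log sigma_u, log
#'   sigma_e)` (the fixed-sigma_u variants drop the corresponding entry).
#' @return an object of class `interval_re_fit`: `coefficients`, `se`, `z`,
#'   `p_value`, `sigma_u`, `sigma_e` (+ their SEs), `loglik`, `aic`, `bic`,
#'   `converged`, `n_obs`, `n_counties`, `quadrature_nodes`, `se_method`,
#'   `vcov`, and the fitting data (for bootstrap refits).
#' @export
fit_interval_re <- function(lower, upper, X, county, K = 12L,
                            sigma_u = NULL, tol = 1e-6, start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(lower) == n, length(upper) == n, length(county) == n)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  exact <- .check_intervals(lower, upper)
  group <- match(county, unique(county))
  gh <- gh_nodes(K)
  p <- ncol(X)
  estimate_su <- is.null(sigma_u)

  # analytic collapse: with no censoring and no random effect the Gaussian
  # interval likelihood is maximized in closed form by OLS with the ML
  # variance, so no iterative optimization is needed
  if (!estimate_su && sigma_u == 0 && all(exact)) {
    y <- lower
    beta <- qr.solve(X, y)
    r <- y - drop(X %*% beta)
    se_ml <- sqrt(mean(r^2))
    ll <- sum(dnorm(y, drop(X %*% beta), se_ml, log = TRUE))
    vcov_b <- se_ml^2 * chol2inv(chol(crossprod(X)))
    se_beta <- sqrt(diag(vcov_b))
    names(beta) <- names(se_beta) <- colnames(X)
    k_par <- p + 1L
    z <- beta / se_beta
    fit <- list(
      coefficients = beta, se = se_beta, z = z,
      p_value = 2 * pnorm(-abs(z)),
      sigma_u = 0, sigma_e = se_ml,
      se_sigma_u = NA_real_, se_sigma_e = se_ml / sqrt(2 * n),
      loglik = ll, aic = -2 * ll + 2 * k_par,
      bic = -2 * ll + k_par * log(n),
      converged = TRUE, relgrad = 0,
      n_obs = n, n_counties = length(unique(county)),
      quadrature_nodes = K, se_method = "hessian", vcov = vcov_b,
      par = c(beta, log(se_ml)), estimate_sigma_u = FALSE, sigma_u_fixed = 0,
      data = list(lower = lower, upper = upper, X = X, county = county))
    class(fit) <- "interval_re_fit"
    return(fit)
  }

  mid <- ifelse(is.finite(upper), (lower + upper) / 2, lower)
  ols <- qr.solve(X, mid)
  s0 <- max(sd(mid - drop(X %*% ols)), 0.5)
  if (is.null(start)) {
    start <- if (estimate_su) c(ols, log(s0 / sqrt(2)), log(s0 / sqrt(2)))
             else c(ols, log(s0))
  }

  unpack <- function(par) {
    if (estimate_su) {
      list(beta = par[seq_len(p)], su = exp(par[p + 1L]), se = exp(par[p + 2L]))
    } else {
      list(beta = par[seq_len(p)], su = sigma_u, se = exp(par[p + 1L]))
    }
  }
  nll <- function(par) {
    th <- unpack(par)
    -.panel_loglik(th$beta, th$su, th$se, lower, upper, exact, X, group, gh)
  }
  ngr <- function(par) {
    th <- unpack(par)
    -.panel_grad(th$beta, th$su, th$se, lower, upper, exact, X, group, gh,
                 estimate_su)
  }
  opt <- optim(start, nll, gr = ngr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  # polish restarts refresh the BFGS curvature estimate until the relative
  # gradient criterion is met (or stops improving)
  relgrad_at <- function(par, ll) {
    g <- ngr(par)
    max(abs(g) * pmax(abs(par), 1)) / max(abs(ll), 1)
  }
  relgrad <- relgrad_at(opt$par, -opt$value)
  for (restart in 1:3) {
    if (relgrad < tol) break
    opt2 <- optim(opt$par, nll, gr = ngr, method = "BFGS",
                  control = list(maxit = 200, reltol = 1e-12))
    if (opt2$value > opt$value - 1e-12) {
      opt <- opt2
      relgrad <- relgrad_at(opt$par, -opt$value)
      break
    }
    opt <- opt2
    relgrad <- relgrad_at(opt$par, -opt$value)
  }
  par <- opt$par
  ll <- -opt$value

  # Newton polish: BFGS line searches stall once the objective is flat to
  # machine precision; a few damped Newton steps on the numerical Hessian
  # drive the gradient to the stationary point proper
  H <- .num_hess_from_grad(ngr, par)
  for (newton in 1:3) {
    if (relgrad < tol) break
    step <- tryCatch(solve(H, ngr(par)), error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (halving in 1:3) {
      cand <- par - step
      val <- nll(cand)
      if (is.finite(val) && val <= -ll + 1e-9) {
        par <- cand; ll <- -val; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    relgrad <- relgrad_at(par, ll)
  }
  if (relgrad < tol) H <- .num_hess_from_grad(ngr, par)
  converged <- opt$convergence == 0 && relgrad < tol

  th <- unpack(par)
  vcov <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  ses <- suppressWarnings(sqrt(diag(vcov)))
  se_beta <- ses[seq_len(p)]
  names(th$beta) <- names(se_beta) <- colnames(X)
  if (estimate_su) {
    se_su <- th$su * ses[p + 1L]
    se_se <- th$se * ses[p + 2L]
  } else {
    se_su <- NA_real_
    se_se <- th$se * ses[p + 1L]
  }

  k_par <- length(par)
  z <- th$beta / se_beta
  fit <- list(
    coefficients = th$beta, se = se_beta, z = z,
    p_value = 2 * pnorm(-abs(z)),
    sigma_u = th$su, sigma_e = th$se,
    se_sigma_u = se_su, se_sigma_e = se_se,
    loglik = ll, aic = -2 * ll + 2 * k_par,
    bic = -2 * ll + k_par * log(n),
    converged = converged, relgrad = relgrad,
    n_obs = n, n_counties = length(unique(county)),
    quadrature_nodes = K, se_method = "hessian", vcov = vcov,
    par = par, estimate_sigma_u = estimate_su, sigma_u_fixed = sigma_u,
    data = list(lower = lower, upper = upper, X = X, county = county))
  class(fit) <- "interval_re_fit"
  fit
}

#' @export
print.interval_re_fit <- function(x, ...) {
  cat(sprintf(
    "Random-effects interval regression (GH quadrature, K = %d)\n",
    x$quadrature_nodes))
  cat(sprintf("  n = %d observations, %d counties; logLik %.2f, AIC %.1f, BIC %.1f\n",
              x$n_obs, x$n_counties, x$loglik, x$aic, x$bic))
  cat(sprintf("  sigma_u %.4f, sigma_e %.4f, converged: %s (SEs: %s)\n",
              x$sigma_u, x$sigma_e, x$converged, x$se_method))
  tab <- data.frame(estimate = x$coefficients, se = x$se, p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Coefficient table of an interval fit
#'
#' @param fit an `interval_re_fit`.
#' @param model optional model label column.
#' @return data frame with `term`, `estimate`, `se`, `p` (and `model`).
#' @export
coef_table <- function(fit, model = NULL) {
  out <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    se = unname(fit$se), p = unname(fit$p_value),
                    stringsAsFactors = FALSE)
  if (!is.null(model)) out$model <- model
  out
}

#' County-cluster bootstrap standard errors
#'
#' Resamples counties with replacement (whole panel blocks), refits the
#' interval model on each resample (starting from the full-sample optimum),
#' and reports the standard deviation of the estimates. Non-convergent
#' refits are dropped and counted, with a warning when more than 10% drop.
#' Deterministic under `seed`.
#'
#' @param fit a converged [fit_interval_re()] result.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @return the fit with `se`, `z`, `p_value` replaced by bootstrap values,
#'   `se_method = "cluster_bootstrap"`, and a `bootstrap` element holding the
#'   estimate draws and drop count.
#' @export
cluster_bootstrap <- function(fit, B = 200L, seed = 1L) {
  stopifnot(inherits(fit, "interval_re_fit"), B >= 2)
  d <- fit$data
  ids <- unique(d$county)
  rows_by_id <- split(seq_along(d$county), match(d$county, ids))
  set.seed(seed)
  p <- length(fit$coefficients)
  draws <- matrix(NA_real_, B, p + 2L,
                  dimnames = list(NULL, c(names(fit$coefficients),
                                          "sigma_u", "sigma_e")))
  dropped <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(length(ids), replace = TRUE)
    rows <- unlist(rows_by_id[pick], use.names = FALSE)
    # resampled counties become distinct clusters even when drawn twice
    cl <- rep(seq_along(pick), times = lengths(rows_by_id[pick]))
    bf <- tryCatch(
      fit_interval_re(d$lower[rows], d$upper[rows],
                      d$X[rows, , drop = FALSE], cl,
                      K = fit$quadrature_nodes,
                      sigma_u = fit$sigma_u_fixed,
                      start = fit$par),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) {
      dropped <- dropped + 1L
      next
    }
    draws[b, ] <- c(bf$coefficients, bf$sigma_u, bf$sigma_e)
  }
  if (dropped > 0.1 * B) {
    warning(sprintf("%d of %d bootstrap refits non-convergent and dropped",
                    dropped, B))
  }
  ok <- complete.cases(draws)
  se_all <- apply(draws[ok, , drop = FALSE], 2L, sd)
  fit$se <- se_all[seq_len(p)]
  fit$z <- fit$coefficients / fit$se
  fit$p_value <- 2 * pnorm(-abs(fit$z))
  fit$se_sigma_u <- se_all[p + 1L]
  fit$se_sigma_e <- se_all[p + 2L]
  fit$se_method <- "cluster_bootstrap"
  fit$bootstrap <- list(draws = draws[ok, , drop = FALSE], B = B,
                        dropped = dropped, seed = seed)
  fit
}

#' Fixed-effects (within) estimator on exactly observed records
#'
#' Robustness fit on the subsample with exact outcomes: county-demeaned OLS.
#' Time-invariant regressors are annihilated by the within transformation and
#' dropped with a warning; counties contributing fewer than two exact records
#' are dropped.
#'
#' @param y exact outcome values.
#' @param X regressor matrix (no intercept — it is absorbed by the county
#'   effects).
#' @param county county identifier per row.
#' @return list with `coefficients`, `se` (within-df classical), `dropped`
#'   (names of annihilated columns), `n_obs`, `n_counties`.
#' @export
fit_fe_within <- function(y, X, county) {
  X <- as.matrix(X)
  tab <- table(county)
  keep_ids <- names(tab)[tab >= 2L]
  if (!length(keep_ids)) {
    stop("no county has >= 2 exact observations", call. = FALSE)
  }
  sel <- county %in% keep_ids
  y <- y[sel]; X <- X[sel, , drop = FALSE]; county <- county[sel]
  g <- match(county, unique(county))
  demean <- function(v) v - ave(v, g)
  yd <- demean(y)
  Xd <- apply(X, 2L, demean)
  sds <- apply(Xd, 2L, sd)
  dropped <- colnames(X)[sds < 1e-10]
  if (length(dropped)) {
    warning("time-invariant regressor(s) dropped by within transform: ",
            paste(dropped, collapse = ", "))
    Xd <- Xd[, sds >= 1e-10, drop = FALSE]
  }
  fit <- lm.fit(Xd, yd)
  cf <- coef(fit)
  df <- length(yd) - length(unique(g)) - ncol(Xd)
  s2 <- sum(resid(fit)^2) / df
  XtX_inv <- chol2inv(chol(crossprod(Xd)))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- names(cf)
  list(coefficients = cf, se = se, dropped = dropped,
       n_obs = length(yd), n_counties = length(unique(g)))
}

#' Build a design matrix with intercept and year dummies
#'
#' Year dummies are coded against the earliest year as reference.
#'
#' @param data data frame containing the regressor columns and a year column.
#' @param regressors character vector of regressor column names.
#' @param year name of the year column.
#' @return numeric design matrix with `(Intercept)`, the regressors, and
#'   `year_<y>` dummy columns.
#' @export
build_design <- function(data, regressors, year = "year") {
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, regressors, drop = FALSE]))
  yrs <- sort(unique(data[[year]]))
  for (y in yrs[-1L]) {
    X <- cbind(X, as.numeric(data[[year]] == y))
    colnames(X)[ncol(X)] <- paste0("year_", y)
  }
  X
}
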