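# residuals of each column of A after OLS on [1, W]
.resid_on <- function(A, W = NULL) {
  A <- as.matrix(A)
  D <- if (is.null(W)) matrix(1, nrow(A), 1L) else cbind(1, as.matrix(W))
  A - D %*% qr.solve(D, A)
}

#' Screen candidate instruments for the Big Five traits
#'
#' An instrument must (a) correlate at least moderately with its trait,
#' (b) correlate only weakly with the outcome, and (c) significantly predict
#' the trait in a first-stage regression (controlling for `C`). All three
#' statistics are reported for every candidate. Screening is idempotent:
#' re-screening a retained set changes nothing.
#'
#' @param candidates data frame or matrix of candidate instrument columns.
#' @param traits data frame or matrix of trait columns (screened per trait).
#' @param outcome numeric outcome (use midpoint coding for interval rows).
#' @param C optional control matrix for the first-stage p-value.
#' @param r_trait_min minimum |corr(candidate, trait)|.
#' @param r_outcome_max maximum |corr(candidate, outcome)|.
#' @param alpha significance level for the first-stage coefficient.
#' @return an object of class `instrument_set`: `per_trait` (named list of
#'   retained candidate names) and `report` (all statistics for every
#'   candidate x trait).
#' @export
select_instruments <- function(candidates, traits, outcome, C = NULL,
                               r_trait_min = 0.3, r_outcome_max = 0.1,
                               alpha = 0.05) {
  Zc <- as.matrix(candidates)
  Tr <- as.matrix(traits)
  if (ncol(Zc) < 1L) stop("need at least one candidate", call. = FALSE)
  rows <- list()
  per_trait <- setNames(vector("list", ncol(Tr)), colnames(Tr))
  for (tr in colnames(Tr)) {
    for (zn in colnames(Zc)) {
      z <- Zc[, zn]
      r_tr <- cor(z, Tr[, tr])
      r_out <- cor(z, outcome)
      D <- if (is.null(C)) cbind(1, z) else cbind(1, z, as.matrix(C))
      fsf <- lm.fit(D, Tr[, tr])
      dfres <- length(z) - ncol(D)
      s2 <- sum(resid(fsf)^2) / dfres
      se_z <- sqrt(s2 * chol2inv(chol(crossprod(D)))[2L, 2L])
      pval <- 2 * pt(-abs(coef(fsf)[2L] / se_z), dfres)
      keep <- abs(r_tr) >= r_trait_min && abs(r_out) <= r_outcome_max &&
        pval < alpha
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, candidate = zn, r_trait = r_tr, r_outcome = r_out,
        first_stage_p = pval, retained = keep, stringsAsFactors = FALSE)
      if (keep) per_trait[[tr]] <- c(per_trait[[tr]], zn)
    }
    if (is.null(per_trait[[tr]])) {
      stop("no candidate instrument survived screening for trait: ", tr,
           call. = FALSE)
    }
  }
  structure(list(per_trait = per_trait,
                 report = do.call(rbind, rows)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument screening:\n")
  for (tr in names(x$per_trait)) {
    cat(sprintf("  %s: %s\n", tr, paste(x$per_trait[[tr]], collapse = ", ")))
  }
  invisible(x)
}

#' First-stage regression of a trait on its instruments
#'
#' Pooled OLS of the trait on instruments and controls with county-cluster
#' robust standard errors, plus the classical partial F statistic for the
#' instrument block. The residuals feed the control-function second stage.
#'
#' @param trait numeric trait vector.
#' @param Z instrument matrix.
#' @param C optional control matrix (year dummies included here if wanted).
#' @param county optional county ids for cluster-robust standard errors.
#' @return an object of class `first_stage_fit`: `coefficients`, `se`
#'   (cluster-robust when `county` is given, classical otherwise),
#'   `residuals`, `r_squared`, `partial_f`, `partial_f_p`, `n`.
#' @export
first_stage <- function(trait, Z, C = NULL, county = NULL) {
  Z <- as.matrix(Z)
  df <- data.frame(.y = trait, Z, check.names = FALSE)
  if (!is.null(C)) df <- cbind(df, as.data.frame(as.matrix(C)))
  fml <- as.formula(paste("`.y` ~", paste(sprintf("`%s`", setdiff(names(df), ".y")),
                                          collapse = " + ")))
  fit <- lm(fml, data = df)
  if (qr(fit)$rank < length(coef(fit))) {
    stop("first-stage design is rank deficient", call. = FALSE)
  }
  vc <- if (is.null(county)) vcov(fit) else sandwich::vcovCL(fit, cluster = county)
  # classical partial F for the instrument block
  restricted <- if (is.null(C)) lm(trait ~ 1) else
    lm(trait ~ ., data = as.data.frame(as.matrix(C)))
  rss_r <- sum(resid(restricted)^2)
  rss_u <- sum(resid(fit)^2)
  kz <- ncol(Z)
  dfu <- fit$df.residual
  Fstat <- ((rss_r - rss_u) / kz) / (rss_u / dfu)
  structure(list(
    coefficients = coef(fit),
    se = sqrt(diag(vc)),
    residuals = unname(resid(fit)),
    r_squared = summary(fit)$r.squared,
    partial_f = Fstat,
    partial_f_p = pf(Fstat, kz, dfu, lower.tail = FALSE),
    n = length(trait)), class = "first_stage_fit")
}

#' Anderson canonical-correlation underidentification test
#'
#' LM statistic `n * (smallest squared canonical correlation)` between the
#' endogenous block and the instrument block after partialling out the
#' controls; chi-squared with `#instruments - #endogenous + 1` degrees of
#' freedom under the null that the model is underidentified.
#'
#' @param traits endogenous regressor matrix (n x m).
#' @param Z instrument matrix (n x kz, kz >= m).
#' @param C optional control matrix partialled from both blocks.
#' @return list with `stat`, `df`, `p`.
#' @export
anderson_underid <- function(traits, Z, C = NULL) {
  Xt <- .resid_on(traits, C)
  Zt <- .resid_on(Z, C)
  m <- ncol(Xt); kz <- ncol(Zt)
  if (kz < m) stop("need at least as many instruments as endogenous regressors",
                   call. = FALSE)
  cc <- cancor(Xt, Zt, xcenter = FALSE, ycenter = FALSE)
  r2_min <- min(cc$cor)^2
  stat <- nrow(Xt) * r2_min
  df <- kz - m + 1L
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Cragg-Donald weak-instrument statistic
#'
#' Minimum eigenvalue of the concentration matrix
#' \eqn{\Sigma^{-1/2}' \tilde X' P_{\tilde Z} \tilde X \Sigma^{-1/2} / k_z}
#' where tildes denote residuals after the controls and
#' \eqn{\Sigma = \tilde X' M_{\tilde Z} \tilde X / (n - k_z - k_c - 1)}.
#' With one endogenous regressor and one instrument it equals the
#' first-stage partial F. Compare against the Stock-Yogo critical values in
#' [stock_yogo_critical()]; the comparison is reported, never auto-failed.
#'
#' @inheritParams anderson_underid
#' @return the scalar statistic (>= 0).
#' @export
cragg_donald <- function(traits, Z, C = NULL) {
  Xt <- .resid_on(traits, C)
  Zt <- .resid_on(Z, C)
  n <- nrow(Xt); m <- ncol(Xt); kz <- ncol(Zt)
  if (kz < m) stop("order condition violated", call. = FALSE)
  kc <- if (is.null(C)) 0L else ncol(as.matrix(C))
  P <- Zt %*% qr.solve(Zt, Xt)         # projection of Xt on span(Zt)
  G <- crossprod(Xt, P)
  S <- crossprod(Xt, Xt - P) / (n - kz - kc - 1L)
  ev <- eigen(solve(S, G), only.values = TRUE)$values
  min(Re(ev)) / kz
}

#' Stock-Yogo 5% critical values (one endogenous regressor)
#'
#' Critical values for the Cragg-Donald statistic at the 5% significance
#' level for a 10% maximal 2SLS size distortion, one endogenous regressor,
#' 1-10 instruments (Stock & Yogo, 2005, Table 5.2).
#'
#' @param n_instruments number of instruments (1-10).
#' @return the critical value.
#' @export
stock_yogo_critical <- function(n_instruments) {
  tab <- c(16.38, 19.93, 22.30, 24.58, 26.87, 29.18, 31.50, 33.84, 36.19, 38.54)
  if (n_instruments < 1 || n_instruments > length(tab)) {
    stop("critical values shipped for 1-10 instruments only", call. = FALSE)
  }
  tab[n_instruments]
}

#' Sargan overidentification test
#'
#' `n * R^2` from regressing the 2SLS residuals on all instruments and
#' controls; chi-squared with `#instruments - #endogenous` degrees of
#' freedom. Requires an overidentified model.
#'
#' @param residuals 2SLS (structural) residuals.
#' @param Z instrument matrix.
#' @param C optional control matrix.
#' @param n_endog number of endogenous regressors.
#' @return list with `stat`, `df`, `p`.
#' @export
sargan <- function(residuals, Z, C = NULL, n_endog = 1L) {
  Z <- as.matrix(Z)
  df_test <- ncol(Z) - n_endog
  if (df_test < 1L) {
    stop("just-identified model: Sargan test undefined (df = 0)", call. = FALSE)
  }
  W <- if (is.null(C)) Z else cbind(Z, as.matrix(C))
  e <- .resid_on(residuals, W)
  r2 <- 1 - sum(e^2) / sum((residuals - mean(residuals))^2)
  stat <- length(residuals) * r2
  list(stat = stat, df = df_test,
       p = pchisq(stat, df_test, lower.tail = FALSE))
}

#' Davidson-MacKinnon test of endogeneity
#'
#' Artificial regression of the outcome on the endogenous regressors,
#' controls, and the first-stage residuals; joint F-test that the residual
#' coefficients are zero. Rejection indicates endogeneity (OLS and IV
#' estimates diverge).
#'
#' @param y outcome (midpoint-coded for interval rows).
#' @param endog endogenous regressor matrix.
#' @param C optional control matrix.
#' @param fs_residuals matrix of first-stage residuals, one column per
#'   endogenous regressor.
#' @return list with `stat` (F), `df1`, `df2`, `p`.
#' @export
davidson_mackinnon <- function(y, endog, C = NULL, fs_residuals) {
  R <- as.matrix(fs_residuals)
  if (any(apply(R, 2L, sd) < 1e-12)) {
    stop("degenerate first-stage residuals (endogenous regressor lies in the ",
         "instrument/control span)", call. = FALSE)
  }
  base <- if (is.null(C)) cbind(1, as.matrix(endog))
          else cbind(1, as.matrix(endog), as.matrix(C))
  full <- cbind(base, R)
  if (qr(full)$rank < ncol(full)) {
    stop("artificial regression is rank deficient", call. = FALSE)
  }
  rss_r <- sum(.resid_on(y, base[, -1L, drop = FALSE])^2)
  rss_u <- sum(.resid_on(y, full[, -1L, drop = FALSE])^2)
  q <- ncol(R)
  df2 <- length(y) - ncol(full)
  Fstat <- ((rss_r - rss_u) / q) / (rss_u / df2)
  list(stat = Fstat, df1 = q, df2 = df2,
       p = pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Textbook two-stage least squares
#'
#' Independent oracle for the control-function estimator: on linear,
#' exactly observed data the CF point estimates coincide with 2SLS.
#'
#' @param y outcome.
#' @param endog endogenous regressor matrix.
#' @param Z instrument matrix.
#' @param C optional exogenous control matrix (instruments for themselves).
#' @return list with `coefficients` (intercept, endogenous, controls),
#'   `residuals` (structural, at the original regressors), `fitted`.
#' @export
two_sls <- function(y, endog, Z, C = NULL) {
  Xe <- as.matrix(endog)
  W <- if (is.null(C)) cbind(1, as.matrix(Z)) else
    cbind(1, as.matrix(Z), as.matrix(C))
  R <- if (is.null(C)) cbind(`(Intercept)` = 1, Xe) else
    cbind(`(Intercept)` = 1, Xe, as.matrix(C))
  if (ncol(W) < ncol(R)) stop("order condition violated", call. = FALSE)
  Rhat <- W %*% qr.solve(W, R)
  beta <- drop(qr.solve(Rhat, y))
  names(beta) <- colnames(R)
  fitted <- drop(R %*% beta)
  list(coefficients = beta, residuals = y - fitted, fitted = fitted)
}

#' Control-function second stage
#'
#' Refits the random-effects interval regression on the design augmented
#' with the first-stage residuals. Rows lacking any residual are listwise
#' dropped, mirroring the reduced sample of a residual-augmented model.
#'
#' @param lower,upper outcome interval bounds.
#' @param X design matrix (intercept, traits, controls, year dummies).
#' @param county county ids.
#' @param fs_residuals matrix of first-stage residuals aligned to the rows
#'   of `X` (NA where a residual is unavailable), one column per
#'   instrumented trait.
#' @param ... passed to [fit_interval_re()] (e.g. `K`, `sigma_u`).
#' @return an `interval_re_fit` on the augmented design; residual terms are
#'   named `cf_<trait>`.
#' @export
cf_second_stage <- function(lower, upper, X, county, fs_residuals, ...) {
  R <- as.matrix(fs_residuals)
  if (nrow(R) != nrow(as.matrix(X))) {
    stop("first-stage residuals are not aligned to the panel rows", call. = FALSE)
  }
  colnames(R) <- paste0("cf_", colnames(R))
  keep <- complete.cases(R)
  fit_interval_re(lower[keep], upper[keep],
                  cbind(as.matrix(X), R)[keep, , drop = FALSE],
                  county[keep], ...)
}
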