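#' Per-year summary of interval outcomes
#'
#' Counts, totals, and mean deaths over the exactly observed (nonsuppressed)
#' county-years, the means rounded half away from zero — the arithmetic
#' behind a standard descriptive table for suppressed mortality counts.
#'
#' @param outcomes data frame with `year`, `lower`, `upper`,
#'   `observed_exact`.
#' @return data frame with `year`, `n_nonsuppressed`, `total_deaths`,
#'   `mean_deaths`.
#' @export
summarize_outcomes <- function(outcomes) {
  ex <- outcomes[outcomes$observed_exact, , drop = FALSE]
  years <- sort(unique(outcomes$year))
  out <- data.frame(year = years,
                    n_nonsuppressed = 0L, total_deaths = 0,
                    mean_deaths = NA_real_)
  for (i in seq_along(years)) {
    v <- ex$lower[ex$year == years[i]]
    out$n_nonsuppressed[i] <- length(v)
    out$total_deaths[i] <- sum(v)
    if (length(v)) out$mean_deaths[i] <- round_half_away(sum(v) / length(v))
  }
  out
}

#' Percentile units per additional death
#'
#' Interprets a trait coefficient (deaths per percentile point): the number
#' of percentile units of increase associated with one additional expected
#' death, `round(1 / coef)` half away from zero. A coefficient of 0.248
#' reads "about a 4-unit increase per additional death".
#'
#' @param coef positive trait coefficient.
#' @return integer number of percentile units.
#' @export
units_per_additional_death <- function(coef) {
  .assert_scalar_number(coef, "coef")
  if (coef <= 0) {
    stop("interpretation undefined for non-positive coefficients", call. = FALSE)
  }
  round_half_away(1 / coef)
}

#' Sample coverage as a percentage of a population
#'
#' `round(100 * users / population)` half away from zero; e.g. 18.7 million
#' sampled users against a 316 million population is a 6% coverage.
#'
#' @param users number sampled.
#' @param population reference population.
#' @return integer percentage.
#' @export
sample_coverage_pct <- function(users, population) {
  .assert_scalar_number(users, "users")
  .assert_scalar_number(population, "population")
  if (population <= 0) stop("population must be positive", call. = FALSE)
  round_half_away(100 * users / population)
}

#' Instrument diagnostic battery, one row per trait
#'
#' For each trait, instrumented separately with its own instrument block:
#' Anderson underidentification p-value, Cragg-Donald statistic with the
#' Stock-Yogo 5% critical value (reported, not auto-failed), Sargan
#' overidentification p-value, and the Davidson-MacKinnon endogeneity
#' p-value. Computed on the exactly observed rows with midpoint coding for
#' any interval rows, since the classical IV tests assume an observed
#' outcome.
#'
#' @param panel merged analysis data frame (outcome bounds, traits,
#'   covariates, instruments).
#' @param traits trait column names.
#' @param instruments named list mapping each trait to its instrument
#'   columns.
#' @param controls covariate column names.
#' @param exact_only if `TRUE` (default) restrict to `observed_exact` rows,
#'   else midpoint-code the intervals.
#' @return data frame with one diagnostic row per trait.
#' @export
iv_diagnostics <- function(panel, traits = BIG_FIVE, instruments,
                           controls = character(), exact_only = TRUE) {
  d <- if (exact_only) panel[panel$observed_exact, , drop = FALSE] else panel
  y <- ifelse(is.finite(d$upper), (d$lower + d$upper) / 2, d$lower)
  C <- if (length(controls)) as.matrix(d[, controls, drop = FALSE]) else NULL
  rows <- lapply(traits, function(tr) {
    Z <- as.matrix(d[, instruments[[tr]], drop = FALSE])
    x <- d[[tr]]
    and <- anderson_underid(cbind(x), Z, C)
    cd <- cragg_donald(cbind(x), Z, C)
    ts <- two_sls(y, cbind(x), Z, C)
    sg <- sargan(ts$residuals, Z, C, n_endog = 1L)
    fs <- first_stage(x, Z, C)
    dm <- davidson_mackinnon(y, cbind(x), C, cbind(fs$residuals))
    data.frame(trait = tr,
               anderson_p = and$p,
               cragg_donald = cd,
               stock_yogo_crit = stock_yogo_critical(ncol(Z)),
               sargan_p = sg$p,
               dm_p = dm$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the three-model sequence on a synthetic panel
#'
#' The standard comparison ladder: model 1 has controls and year dummies
#' only; model 2 adds the five trait percentiles (the main effects); model 3
#' adds the first-stage residuals of each trait on its instruments (the
#' control function). One coefficient table and an AIC/BIC comparison line
#' are produced; with real trait effects in the data, model 2's AIC should
#' beat model 1's.
#'
#' @param config a [sim_config()], or an existing [generate_panel()] result.
#' @param K Gauss-Hermite nodes.
#' @param models which of `controls_only`, `main_effects`,
#'   `main_effects_cf` to fit (in that order).
#' @param bootstrap optional number of county-cluster bootstrap resamples
#'   for the fitted models' SEs.
#' @return an object of class `model_sequence_report`: `fits` (named list),
#'   `table` (stacked coefficient tables), `comparison` (per-model logLik,
#'   AIC, BIC, n), and `diagnostics` (the per-trait IV battery, when the CF
#'   model is fitted).
#' @export
run_model_sequence <- function(config, K = 12L,
                               models = c("controls_only", "main_effects",
                                          "main_effects_cf"),
                               bootstrap = NULL) {
  sim <- if (inherits(config, "trait_panel_sim")) config else generate_panel(config)
  cfg <- sim$config
  panel <- merge(sim$outcomes, sim$latent, by = c("fips", "year"), sort = TRUE)
  controls <- names(cfg$gamma_true)
  inst_cols <- grep("^z_", names(panel), value = TRUE)
  inst_by_trait <- setNames(lapply(BIG_FIVE, function(tr) {
    grep(sprintf("^z_%s_", tr), inst_cols, value = TRUE)
  }), BIG_FIVE)

  fits <- list()
  diagnostics <- NULL
  if ("controls_only" %in% models) {
    X1 <- build_design(panel, controls)
    fits$controls_only <- fit_interval_re(panel$lower, panel$upper, X1,
                                          panel$fips, K = K)
  }
  X2 <- build_design(panel, c(BIG_FIVE, controls))
  if ("main_effects" %in% models) {
    fits$main_effects <- fit_interval_re(panel$lower, panel$upper, X2,
                                         panel$fips, K = K)
  }
  if ("main_effects_cf" %in% models) {
    yr_cols <- grep("^year_", colnames(X2), value = TRUE)
    Cfs <- as.matrix(cbind(panel[, controls, drop = FALSE],
                           X2[, yr_cols, drop = FALSE]))
    R <- sapply(BIG_FIVE, function(tr) {
      first_stage(panel[[tr]], panel[, inst_by_trait[[tr]], drop = FALSE],
                  Cfs, county = panel$fips)$residuals
    })
    fits$main_effects_cf <- cf_second_stage(panel$lower, panel$upper, X2,
                                            panel$fips, R, K = K)
    diagnostics <- iv_diagnostics(panel, BIG_FIVE, inst_by_trait, controls)
  }
  if (!is.null(bootstrap)) {
    fits <- lapply(fits, cluster_bootstrap, B = bootstrap, seed = cfg$seed)
  }
  table <- do.call(rbind, lapply(names(fits), function(nm) {
    coef_table(fits[[nm]], model = nm)
  }))
  comparison <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    bic = vapply(fits, `[[`, 0, "bic"),
    n_obs = vapply(fits, `[[`, 0L, "n_obs"),
    n_counties = vapply(fits, `[[`, 0L, "n_counties"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  rownames(comparison) <- NULL
  structure(list(fits = fits, table = table, comparison = comparison,
                 diagnostics = diagnostics, config = cfg),
            class = "model_sequence_report")
}

#' @export
print.model_sequence_report <- function(x, ...) {
  cat("Model sequence:\n")
  print(transform(x$comparison,
                  loglik = round(loglik, 1), aic = round(aic, 1),
                  bic = round(bic, 1)))
  if (nrow(x$comparison) >= 2L) {
    best <- x$comparison$model[which.min(x$comparison$aic)]
    cat(sprintf("Lowest AIC: %s\n", best))
  }
  invisible(x)
}

.log_line <- function(log_con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the full pipeline: simulate, score, components, fit, diagnostics
#'
#' End-to-end orchestration from one configuration: generates the panel,
#' polygons, and corpus; writes every exchange file; scores the corpus back
#' into trait percentiles; builds superordinate components from planted
#' facet matrices; fits the three-model sequence on the *scored* traits
#' (components and word count included as controls); and writes the
#' instrument diagnostic battery. Every stage logs row counts and elapsed
#' time; the run is deterministic under the config seed.
#'
#' @param config a [sim_config()]. Keep corpus sizes modest: the corpus has
#'   `n_counties * n_years * tweets_per_county` rows.
#' @param out_dir output directory (created if needed).
#' @param lexicon,weights lexicon and weight table; default to the shipped
#'   fixtures.
#' @param K Gauss-Hermite nodes.
#' @return the `model_sequence_report`, invisibly; files are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         lexicon = read_lexicon(system.file(
                           "extdata", "lexicon.dic", package = "traitpanel")),
                         weights = read_trait_weights(system.file(
                           "extdata", "trait_weights.csv", package = "traitpanel")),
                         K = 12L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  t0 <- Sys.time()

  sim <- generate_panel(config)
  polys <- generate_polygons(config)
  write_panel_csv(sim, file.path(out_dir, "panel.csv"))
  write_truth_config(sim, file.path(out_dir, "truth.cfg"))
  write_polygons_geojson(polys, file.path(out_dir, "counties.geojson"))
  .log_line(log_con, "simulate: %d county-years, %.1f%% suppressed (%.1fs)",
            nrow(sim$outcomes), 100 * mean(!sim$outcomes$observed_exact),
            as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  tweets <- generate_corpus(sim$latent, lexicon, config, polys)
  write_tweets_jsonl(tweets, file.path(out_dir, "tweets.jsonl"))
  scores <- score_corpus(tweets, polys, lexicon, weights)
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  .log_line(log_con, "score: %d tweets -> %d county-year documents (%.1fs)",
            nrow(tweets), nrow(scores),
            as.numeric(Sys.time() - t1, units = "secs"))

  t2 <- Sys.time()
  facets <- generate_facets(nrow(sim$latent), seed = config$seed + 2L)
  comp <- lapply(facets, pca_retain)
  comp_scores <- lapply(names(comp), function(dim) {
    s <- component_scores(comp[[dim]], facets[[dim]])
    colnames(s) <- sprintf("%s_pc%d", dim, seq_len(ncol(s)))
    s
  })
  diag_df <- data.frame(
    dimension = names(comp),
    kmo = vapply(comp, `[[`, 0, "kmo"),
    cronbach_alpha = vapply(comp, `[[`, 0, "cronbach_alpha"),
    retained = vapply(comp, `[[`, 0L, "retained"),
    variance_explained = vapply(comp, `[[`, 0, "variance_explained"))
  write.csv(diag_df, file.path(out_dir, "component_diagnostics.csv"),
            row.names = FALSE)
  .log_line(log_con, "components: retained %s (alpha), %s (beta) (%.1fs)",
            comp$alpha$retained, comp$beta$retained,
            as.numeric(Sys.time() - t2, units = "secs"))

  t3 <- Sys.time()
  panel <- merge(sim$outcomes, sim$latent[, !(names(sim$latent) %in% BIG_FIVE)],
                 by = c("fips", "year"), sort = TRUE)
  panel <- merge(panel, scores[, c("fips", "year", "word_count", BIG_FIVE)],
                 by = c("fips", "year"), sort = TRUE)
  panel <- cbind(panel, do.call(cbind, comp_scores)[seq_len(nrow(panel)), ,
                                                    drop = FALSE])
  controls <- c(names(config$gamma_true), "word_count",
                grep("_pc", names(panel), value = TRUE))
  ctrl_sd <- vapply(panel[controls], sd, numeric(1L))
  if (any(ctrl_sd < 1e-12)) {
    .log_line(log_con, "fit: dropping constant control(s): %s",
              paste(controls[ctrl_sd < 1e-12], collapse = ", "))
    controls <- controls[ctrl_sd >= 1e-12]
  }
  sim2 <- sim
  sim2$outcomes <- panel[, c("fips", "year", "lower", "upper", "observed_exact")]
  sim2$latent <- panel[, setdiff(names(panel),
                                 c("lower", "upper", "observed_exact"))]
  cfg2 <- config
  cfg2$gamma_true <- setNames(rep(NA_real_, length(controls)), controls)
  sim2$config <- cfg2
  report <- run_model_sequence(sim2, K = K)
  write.csv(report$table, file.path(out_dir, "coefficients.csv"),
            row.names = FALSE)
  if (!is.null(report$diagnostics)) {
    write.csv(report$diagnostics, file.path(out_dir, "diagnostics.csv"),
              row.names = FALSE)
  }
  summ <- lapply(report$fits, function(f) {
    list(loglik = f$loglik, aic = f$aic, bic = f$bic,
         sigma_u = f$sigma_u, sigma_e = f$sigma_e,
         n_obs = f$n_obs, n_counties = f$n_counties,
         converged = f$converged)
  })
  jsonlite::write_json(summ, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(summarize_outcomes(sim$outcomes),
            file.path(out_dir, "outcome_summary.csv"), row.names = FALSE)
  .log_line(log_con, "fit: %d models (%.1fs); total %.1fs",
            nrow(report$comparison),
            as.numeric(Sys.time() - t3, units = "secs"),
            as.numeric(Sys.time() - t0, units = "secs"))
  invisible(report)
}
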