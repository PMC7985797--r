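# shared fixtures, all built in code

toy_lexicon <- function() {
  trait_lexicon(list(posemo = c("good", "happi*"), negemo = "sad"))
}

fixture_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.dic", package = "traitpanel"))
}

fixture_weights <- function() {
  read_trait_weights(system.file("extdata", "trait_weights.csv",
                                 package = "traitpanel"))
}

# the parameter-recovery study condition: 500 counties x 3 years, ~70%
# suppressed, with the outcome scale positioned so the zero floor of
# reported counts almost never binds (latent mean ~36, threshold 44) and the
# generator therefore matches the fitted model's assumptions
recovery_config <- function(seed = 1L, n_counties = 500L,
                            suppression_threshold = 44L, intercept = -3.5,
                            ...) {
  sim_config(n_counties = n_counties, n_years = 3L, seed = seed,
             suppression_threshold = suppression_threshold,
             intercept = intercept, ...)
}

# merged panel + standard design matrix for a simulated panel
panel_design <- function(sim) {
  panel <- merge(sim$outcomes, sim$latent, by = c("fips", "year"), sort = TRUE)
  X <- build_design(panel, c(BIG_FIVE, names(sim$config$gamma_true)))
  list(panel = panel, X = X)
}

# first-stage residual matrix, one column per trait, instruments per trait
fs_residual_matrix <- function(panel, X, controls) {
  yr <- grep("^year_", colnames(X), value = TRUE)
  Cfs <- as.matrix(cbind(panel[, controls, drop = FALSE],
                         X[, yr, drop = FALSE]))
  sapply(BIG_FIVE, function(tr) {
    Z <- panel[, grep(sprintf("^z_%s_", tr), names(panel)), drop = FALSE]
    first_stage(panel[[tr]], Z, Cfs)$residuals
  })
}
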