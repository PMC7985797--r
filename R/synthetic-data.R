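#' Big Five trait names used throughout the package
#'
#' Canonical order: openness, conscientiousness, extraversion, agreeableness,
#' neuroticism.
#' @export
BIG_FIVE <- c("openness", "conscientiousness", "extraversion",
              "agreeableness", "neuroticism")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the county-year panel
#' with interval-suppressed mortality, the tiled county polygons, and the
#' geo-tagged text corpus.
#'
#' The outcome model is a Gaussian latent
#' \deqn{y^*_{it} = \alpha + X_{it}\beta + C_{it}\gamma +
#'       \lambda q_{it} + u_i + e_{it}}
#' with \eqn{X_{it}} trait percentiles (0-100), \eqn{C_{it}} covariates,
#' \eqn{q_{it}} an omitted confounder with loading \eqn{\lambda}
#' (`confounder_strength`) on both the focal trait (neuroticism) and the
#' outcome, \eqn{u_i \sim N(0,
#' \sigma_u^2)} a county random effect and \eqn{e_{it} \sim N(0, \sigma_e^2)}.
#' The reported count is `round(max(0, y*))`; counts below
#' `suppression_threshold` are released only as the censoring interval
#' `[0, suppression_threshold - 1]`, mimicking small-cell suppression in
#' mortality surveillance.
#'
#' The default `intercept` (-40.8) was calibrated once by Monte Carlo so that
#' at the default effect sizes roughly 77% of county-years are suppressed at
#' threshold 10 for a 3000-county, 3-year panel — the regime the pipeline is
#' designed for.
#'
#' @param n_counties number of counties (>= 2).
#' @param n_years number of panel years.
#' @param seed integer seed; identical configs reproduce outputs bit-for-bit.
#' @param suppression_threshold counts strictly below this are released as the
#'   interval `[0, threshold - 1]`; 0 disables suppression.
#' @param intercept latent-outcome intercept (deaths).
#' @param beta_true named 5-vector, deaths per trait-percentile point.
#' @param gamma_true named vector of covariate effects; covariates are drawn
#'   standard normal under these names.
#' @param sigma_u county random-effect SD (>= 0).
#' @param sigma_e idiosyncratic SD (> 0).
#' @param confounder_strength loading of the omitted confounder on both the
#'   latent traits and the outcome; 0 gives an exogenous design.
#' @param instrument_strength in `[0, 1]`; correlation between each instrument
#'   and the pre-confounder trait signal.
#' @param instruments_per_trait instruments generated per trait (>= 2 keeps
#'   the Sargan test overidentified).
#' @param tweets_per_county tweets per county-year in the corpus.
#' @param words_per_tweet central tokens-per-tweet; actual lengths vary
#'   uniformly within +-3 of this, floored at 3 so no tweet is
#'   length-filtered.
#' @param duplicate_author_rate fraction of tweets rewritten as exact
#'   author+text duplicates of their predecessor, to exercise deduplication.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_counties = 9, n_years = 2, seed = 1)
#' sim <- generate_panel(cfg)
#' head(sim$outcomes)
sim_config <- function(n_counties = 3000L,
                       n_years = 3L,
                       seed = 1L,
                       suppression_threshold = 10L,
                       intercept = -40.8,
                       beta_true = c(openness = 0.05, conscientiousness = 0.23,
                                     extraversion = 0.31, agreeableness = -0.05,
                                     neuroticism = 0.25),
                       gamma_true = c(health_index = 1.0, ses_index = -1.0),
                       sigma_u = 2,
                       sigma_e = 3,
                       confounder_strength = 0,
                       instrument_strength = 0.6,
                       instruments_per_trait = 2L,
                       tweets_per_county = 200L,
                       words_per_tweet = 12L,
                       duplicate_author_rate = 0) {
  if (!is.numeric(n_counties) || n_counties < 2) {
    stop("n_counties must be >= 2", call. = FALSE)
  }
  if (!is.numeric(sigma_e) || sigma_e <= 0) {
    stop("sigma_e must be > 0", call. = FALSE)
  }
  if (sigma_u < 0) stop("sigma_u must be >= 0", call. = FALSE)
  if (suppression_threshold < 0) {
    stop("suppression_threshold must be >= 0", call. = FALSE)
  }
  if (!setequal(names(beta_true), BIG_FIVE)) {
    stop("beta_true must be named by the Big Five traits", call. = FALSE)
  }
  if (instrument_strength < 0 || instrument_strength > 1) {
    stop("instrument_strength must lie in [0, 1]", call. = FALSE)
  }
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (tweets_per_county < 1 || words_per_tweet < 1) {
    stop("corpus sizes must be positive", call. = FALSE)
  }
  cfg <- list(
    n_counties = as.integer(n_counties),
    n_years = as.integer(n_years),
    seed = as.integer(seed),
    suppression_threshold = as.integer(suppression_threshold),
    intercept = intercept,
    beta_true = beta_true[BIG_FIVE],
    gamma_true = gamma_true,
    sigma_u = sigma_u,
    sigma_e = sigma_e,
    confounder_strength = confounder_strength,
    instrument_strength = instrument_strength,
    instruments_per_trait = as.integer(instruments_per_trait),
    tweets_per_county = as.integer(tweets_per_county),
    words_per_tweet = as.integer(words_per_tweet),
    duplicate_author_rate = duplicate_author_rate,
    first_year = 2014L
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:",
      sprintf("%d counties x %d years, seed %d", x$n_counties, x$n_years, x$seed),
      sprintf("suppression threshold %d, sigma_u %.3g, sigma_e %.3g",
              x$suppression_threshold, x$sigma_u, x$sigma_e),
      sprintf("confounder strength %.3g, instrument strength %.3g",
              x$confounder_strength, x$instrument_strength),
      sep = "\n  ")
  cat("\n")
  invisible(x)
}

#' Generate the latent county panel and interval-censored outcomes
#'
#' Draws the full county-year panel: latent trait percentiles, the omitted
#' confounder, covariates, linguistic-style instruments, and the mortality
#' outcome reported either exactly or as the suppression interval
#' `[0, threshold - 1]`.
#'
#' Random numbers are consumed in a fixed, documented order so seeds are
#' stable across refactors: (1) county random effects; then per year, in
#' panel order: (2) trait base signal, (3) confounder, (4) covariates,
#' (5) idiosyncratic errors, (6) instrument noise.
#'
#' Instruments are built from the *pre-confounder* trait signal,
#' `instrument_strength * signal + sqrt(1 - instrument_strength^2) * noise`,
#' so they correlate with the traits but reach the outcome only through them:
#' they remain valid even when `confounder_strength > 0`.
#'
#' @param config a [sim_config()].
#' @return a list of class `trait_panel_sim` with elements
#'   `latent` (fips, year, trait percentiles, confounder, covariates,
#'   instruments), `outcomes` (fips, year, lower, upper, observed_exact),
#'   `truth` (fips, year, true count, latent y*, plus the county effects as
#'   attribute `u`), and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_counties
  ny <- config$n_years
  fips <- sprintf("%05d", seq_len(n))
  years <- config$first_year + seq_len(ny) - 1L
  m <- config$instruments_per_trait
  inst_names <- as.vector(t(outer(BIG_FIVE, seq_len(m),
                                  function(tr, l) sprintf("z_%s_%d", tr, l))))
  cov_names <- names(config$gamma_true)

  set.seed(config$seed)
  u <- rnorm(n, 0, config$sigma_u)

  lat_rows <- vector("list", ny)
  out_rows <- vector("list", ny)
  tru_rows <- vector("list", ny)
  for (t in seq_len(ny)) {
    zbase <- matrix(rnorm(n * 5L), n, 5L, dimnames = list(NULL, BIG_FIVE))
    conf <- rnorm(n)
    xcov <- matrix(rnorm(n * length(cov_names)), n, length(cov_names),
                   dimnames = list(NULL, cov_names))
    e <- rnorm(n, 0, config$sigma_e)
    znoise <- matrix(rnorm(n * 5L * m), n, 5L * m)

    # the omitted variable is tied to the focal trait (neuroticism) and the
    # outcome; loading it on a single trait keeps the five percentiles from
    # becoming artificially collinear while still inducing endogeneity
    latent_trait <- zbase
    latent_trait[, "neuroticism"] <- latent_trait[, "neuroticism"] +
      config$confounder_strength * conf
    pct <- apply(latent_trait, 2L, percentile_transform)

    inst <- matrix(0, n, 5L * m, dimnames = list(NULL, inst_names))
    for (j in seq_len(5L)) {
      s <- (zbase[, j] - mean(zbase[, j])) / sd(zbase[, j])
      for (l in seq_len(m)) {
        col <- (j - 1L) * m + l
        inst[, col] <- config$instrument_strength * s +
          sqrt(1 - config$instrument_strength^2) * znoise[, col]
      }
    }

    ystar <- config$intercept +
      drop(pct %*% config$beta_true) +
      drop(xcov %*% config$gamma_true) +
      config$confounder_strength * conf + u + e
    count <- round(pmax(0, ystar))
    suppressed <- count < config$suppression_threshold

    lat_rows[[t]] <- data.frame(fips = fips, year = years[t], pct,
                                confounder = conf, xcov, inst,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
    out_rows[[t]] <- data.frame(
      fips = fips, year = years[t],
      lower = ifelse(suppressed, 0, count),
      upper = ifelse(suppressed, config$suppression_threshold - 1L, count),
      observed_exact = !suppressed,
      stringsAsFactors = FALSE)
    tru_rows[[t]] <- data.frame(fips = fips, year = years[t],
                                count = count, ystar = ystar,
                                stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, tru_rows)
  attr(truth, "u") <- u
  out <- list(latent = do.call(rbind, lat_rows),
              outcomes = do.call(rbind, out_rows),
              truth = truth,
              config = config)
  class(out) <- "trait_panel_sim"
  out
}

#' @export
print.trait_panel_sim <- function(x, ...) {
  supp <- mean(!x$outcomes$observed_exact)
  cat(sprintf(
    "Synthetic trait panel: %d counties x %d years (%.1f%% suppressed)\n",
    x$config$n_counties, x$config$n_years, 100 * supp))
  invisible(x)
}

#' Generate a grid of square county polygons
#'
#' Tiles a rectangle with axis-aligned unit squares, one per county, each
#' carrying its FIPS code. Cells are laid out row-major from the origin, in
#' lon/lat degrees, so the panel's geography is trivial but exercises the
#' same point-in-polygon machinery as real county shapes.
#'
#' @param config a [sim_config()], or a plain county count.
#' @return an object of class `county_polygons`: a list of features, each a
#'   list with `fips` and `ring` (closed 5x2 coordinate matrix, columns
#'   lon, lat).
#' @export
generate_polygons <- function(config) {
  n <- if (inherits(config, "sim_config")) config$n_counties else as.integer(config)
  stopifnot(n >= 1)
  ncol_grid <- ceiling(sqrt(n))
  feats <- vector("list", n)
  for (k in seq_len(n)) {
    row <- (k - 1L) %/% ncol_grid
    col <- (k - 1L) %% ncol_grid
    x0 <- col; y0 <- row
    ring <- cbind(lon = c(x0, x0 + 1, x0 + 1, x0, x0),
                  lat = c(y0, y0, y0 + 1, y0 + 1, y0))
    feats[[k]] <- list(fips = sprintf("%05d", k), ring = ring)
  }
  structure(feats, class = "county_polygons", grid_ncol = ncol_grid)
}

#' @export
print.county_polygons <- function(x, ...) {
  cat(sprintf("county_polygons: %d features\n", length(x)))
  invisible(x)
}

# neutral filler vocabulary; deliberately disjoint from the fixture lexicon,
# including its wildcard prefixes
.FILLER_WORDS <- c(
  "the", "and", "for", "with", "about", "today", "tomorrow", "morning",
  "evening", "weather", "coffee", "lunch", "dinner", "street", "river",
  "north", "south", "east", "west", "window", "garden", "music", "game",
  "travel", "photo", "update", "news", "video", "phone", "book", "paper",
  "water", "light", "road", "city", "town", "house", "door", "table")

#' Generate a geo-tagged synthetic text corpus
#'
#' Emits `tweets_per_county` messages per county-year. Each token is drawn
#' from a mixture of lexicon category word lists and neutral filler words;
#' the emission probability of the category mapped to trait *t* is affine in
#' the county's latent percentile for *t*:
#' `p = base_prob + slope * percentile / 100`. Coordinates are uniform inside
#' the county's polygon; author ids are globally unique unless the config's
#' `duplicate_author_rate` injects duplicates.
#'
#' Random numbers are consumed per county-year in `latent` row order:
#' (1) tweet lengths, (2) category labels for all tokens, (3) words within
#' category, (4) coordinates, (5) timestamps; duplicate injection (if any)
#' draws last.
#' The corpus stream is seeded with `config$seed + 1`, independent of the
#' panel stream.
#'
#' @param latent the `latent` data frame of a [generate_panel()] result.
#' @param lexicon a [trait_lexicon()].
#' @param config the [sim_config()].
#' @param polygons county polygons; defaults to [generate_polygons()] of the
#'   config.
#' @param trait_map named character vector mapping each trait to the lexicon
#'   category whose emission rate it drives.
#' @param base_prob baseline emission probability per mapped category.
#' @param slope increase in emission probability from percentile 0 to 100.
#' @return data frame with columns `author`, `ts` (POSIXct UTC), `lat`,
#'   `lon`, `text`, plus ground-truth labels `fips` and `year` (the scoring
#'   pipeline must not read these; they exist for validation).
#' @export
generate_corpus <- function(latent, lexicon, config,
                            polygons = generate_polygons(config),
                            trait_map = c(openness = "insight",
                                          conscientiousness = "achieve",
                                          extraversion = "posemo",
                                          agreeableness = "social",
                                          neuroticism = "negemo"),
                            base_prob = 0.02,
                            slope = 0.06) {
  stopifnot(inherits(config, "sim_config"), inherits(lexicon, "trait_lexicon"))
  if (length(lexicon$categories) == 0L) {
    stop("lexicon has no categories", call. = FALSE)
  }
  missing_cat <- setdiff(trait_map, names(lexicon$categories))
  if (length(missing_cat)) {
    stop("trait_map categories absent from lexicon: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  cats <- unname(trait_map[BIG_FIVE])
  # emission vocabulary: wildcard patterns emit their stem
  vocab <- lapply(lexicon$categories[cats], function(p) sub("\\*$", "", p))
  ring_by_fips <- setNames(lapply(polygons, `[[`, "ring"),
                           vapply(polygons, `[[`, "", "fips"))

  set.seed(config$seed + 1L)
  n_tw <- config$tweets_per_county
  n_wd <- config$words_per_tweet
  len_lo <- max(3L, n_wd - 3L)
  len_hi <- n_wd + 3L
  rows <- vector("list", nrow(latent))
  author_base <- 0L
  for (i in seq_len(nrow(latent))) {
    pct <- as.numeric(latent[i, BIG_FIVE])
    p <- base_prob + slope * pct / 100
    # tweet lengths vary uniformly around words_per_tweet (never below 3,
    # so none are length-filtered)
    lens <- sample(len_lo:len_hi, n_tw, replace = TRUE)
    ntok <- sum(lens)
    cat_idx <- sample.int(6L, ntok, replace = TRUE, prob = c(p, 1 - sum(p)))
    words <- character(ntok)
    for (j in seq_len(5L)) {
      sel <- cat_idx == j
      if (any(sel)) words[sel] <- sample(vocab[[j]], sum(sel), replace = TRUE)
    }
    sel <- cat_idx == 6L
    if (any(sel)) words[sel] <- sample(.FILLER_WORDS, sum(sel), replace = TRUE)
    text <- vapply(split(words, rep(seq_len(n_tw), times = lens)),
                   paste, character(1L), collapse = " ")

    ring <- ring_by_fips[[latent$fips[i]]]
    lon <- runif(n_tw, min(ring[, "lon"]), max(ring[, "lon"]))
    lat <- runif(n_tw, min(ring[, "lat"]), max(ring[, "lat"]))
    year0 <- ISOdatetime(latent$year[i], 1, 1, 0, 0, 0, tz = "UTC")
    ts <- year0 + runif(n_tw, 0, 364.99 * 86400)

    rows[[i]] <- data.frame(
      author = sprintf("u%08d", author_base + seq_len(n_tw)),
      ts = ts, lat = lat, lon = lon, text = text,
      fips = latent$fips[i], year = latent$year[i],
      stringsAsFactors = FALSE)
    author_base <- author_base + n_tw
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (config$duplicate_author_rate > 0 && nrow(out) > 1L) {
    dup <- which(runif(nrow(out) - 1L) < config$duplicate_author_rate) + 1L
    out$author[dup] <- out$author[dup - 1L]
    out$text[dup] <- out$text[dup - 1L]
  }
  out
}

#' Generate facet matrices with a planted superordinate structure
#'
#' Emulates the facet-level input of the superordinate component stage:
#' each dimension's facets load on one general factor plus sub-block factors
#' (plus noise), so a correlation-matrix PCA recovers several
#' eigenvalue-above-1 components and reliability statistics land in the
#' conventionally "satisfactory" range.
#'
#' @param n number of rows (county-years).
#' @param seed integer seed.
#' @param n_alpha,n_beta facet counts for the alpha (stability) and beta
#'   (plasticity) dimensions.
#' @param block_size facets per sub-block factor.
#' @return list with numeric matrices `alpha` and `beta`.
#' @export
generate_facets <- function(n, seed = 1L, n_alpha = 12L, n_beta = 8L,
                            block_size = 3L) {
  set.seed(seed)
  make_dim <- function(k, g_load, b_load, label) {
    g <- rnorm(n)
    nb <- ceiling(k / block_size)
    bf <- matrix(rnorm(n * nb), n, nb)
    M <- matrix(0, n, k)
    for (j in seq_len(k)) {
      b <- (j - 1L) %/% block_size + 1L
      M[, j] <- g_load * g + b_load * bf[, b] +
        sqrt(max(0, 1 - g_load^2 - b_load^2)) * rnorm(n)
    }
    colnames(M) <- sprintf("%s_f%02d", label, seq_len(k))
    M
  }
  list(alpha = make_dim(n_alpha, 0.75, 0.5, "alpha"),
       beta = make_dim(n_beta, 0.6, 0.55, "beta"))
}

# ---- writers / readers for the exchange formats -----------------------------

#' Write and read tweets as JSON-lines
#'
#' One JSON object per line with fields `author`, `ts` (ISO-8601 UTC), `lat`,
#' `lon`, `text`.
#'
#' @param tweets data frame as produced by [generate_corpus()].
#' @param path file path.
#' @return `write_tweets_jsonl` returns `path` invisibly; `read_tweets_jsonl`
#'   returns a data frame with `ts` parsed to POSIXct UTC.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  df <- data.frame(author = tweets$author,
                   ts = format(tweets$ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   lat = tweets$lat, lon = tweets$lon, text = tweets$text,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_tweets_jsonl
#' @export
read_tweets_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  df$ts <- as.POSIXct(df$ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df
}

#' Write and read county polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features, each with `properties.fips`.
#'
#' @param polygons a `county_polygons` object.
#' @param path file path.
#' @return `write_polygons_geojson` returns `path` invisibly;
#'   `read_polygons_geojson` returns a `county_polygons` object in file order.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(f) {
    list(type = "Feature",
         properties = list(fips = f$fips),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(f$ring)),
                                  function(i) as.numeric(f$ring[i, ]))))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- lapply(fc$features, function(f) {
    ring_list <- f$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(ring_list, function(xy) {
      if (length(xy) != 2L) stop("malformed polygon ring", call. = FALSE)
      as.numeric(xy)
    }))
    colnames(ring) <- c("lon", "lat")
    list(fips = f$properties$fips, ring = ring)
  })
  structure(feats, class = "county_polygons")
}

#' Write the county-year analysis panel as CSV
#'
#' Columns: `fips, year, lower, upper, observed_exact`, then covariates and
#' instruments.
#'
#' @param sim a `trait_panel_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(sim, path) {
  df <- merge(sim$outcomes, sim$latent, by = c("fips", "year"), sort = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the generator's ground-truth parameters as a flat key-value file
#'
#' @param sim a `trait_panel_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_config <- function(sim, path) {
  cfg <- sim$config
  kv <- c(
    sprintf("n_counties=%d", cfg$n_counties),
    sprintf("n_years=%d", cfg$n_years),
    sprintf("seed=%d", cfg$seed),
    sprintf("suppression_threshold=%d", cfg$suppression_threshold),
    sprintf("intercept=%.10g", cfg$intercept),
    sprintf("beta_%s=%.10g", names(cfg$beta_true), cfg$beta_true),
    sprintf("gamma_%s=%.10g", names(cfg$gamma_true), cfg$gamma_true),
    sprintf("sigma_u=%.10g", cfg$sigma_u),
    sprintf("sigma_e=%.10g", cfg$sigma_e),
    sprintf("confounder_strength=%.10g", cfg$confounder_strength),
    sprintf("instrument_strength=%.10g", cfg$instrument_strength))
  writeLines(kv, path)
  invisible(path)
}
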