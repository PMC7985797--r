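#' Construct a category lexicon
#'
#' A lexicon maps category names to pattern lists. A pattern is either an
#' exact lowercase token or a prefix wildcard with a trailing `*`
#' (`happi*` matches any token beginning "happi"). This mirrors the dialect
#' of psycholinguistic dictionaries of the Linguistic Inquiry and Word Count
#' family, so a real dictionary file drops in; the package ships a small open
#' fixture (`system.file("extdata", "lexicon.dic", package = "traitpanel")`).
#'
#' @param categories named list of character pattern vectors.
#' @return an object of class `trait_lexicon`.
#' @export
#' @examples
#' lx <- trait_lexicon(list(posemo = c("good", "happi*"), negemo = "sad"))
trait_lexicon <- function(categories) {
  if (!is.list(categories) || is.null(names(categories)) ||
      anyDuplicated(names(categories))) {
    stop("categories must be a uniquely named list", call. = FALSE)
  }
  categories <- lapply(categories, function(p) {
    p <- as.character(p)
    if (any(p != tolower(p))) stop("patterns must be lowercase", call. = FALSE)
    p
  })
  structure(list(categories = categories), class = "trait_lexicon")
}

#' @export
print.trait_lexicon <- function(x, ...) {
  cat(sprintf("trait_lexicon: %d categories, %d patterns\n",
              length(x$categories), sum(lengths(x$categories))))
  invisible(x)
}

#' Read and write the dictionary file format
#'
#' The file has a header block delimited by `%` lines listing
#' `id<TAB>category` pairs, followed by `pattern<TAB>id [id ...]` entries;
#' `*` marks a prefix wildcard.
#'
#' @param path file path.
#' @return `read_lexicon` returns a [trait_lexicon()]; `write_lexicon`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("missing % header block", call. = FALSE)
  header <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  body <- if (pct[2] < length(lines)) lines[(pct[2] + 1L):length(lines)] else character()
  hp <- strsplit(trimws(header), "[ \t]+")
  ids <- vapply(hp, `[[`, "", 1L)
  cats <- vapply(hp, `[[`, "", 2L)
  patt <- setNames(vector("list", length(cats)), cats)
  for (ln in body) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    word <- f[1]
    for (id in f[-1]) {
      cat_name <- cats[match(id, ids)]
      if (is.na(cat_name)) stop("unknown category id: ", id, call. = FALSE)
      patt[[cat_name]] <- c(patt[[cat_name]], word)
    }
  }
  trait_lexicon(patt)
}

#' @rdname read_lexicon
#' @param lexicon a [trait_lexicon()].
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "trait_lexicon"))
  cats <- names(lexicon$categories)
  ids <- as.character(seq_along(cats))
  inv <- list()
  for (k in seq_along(cats)) {
    for (w in lexicon$categories[[k]]) inv[[w]] <- c(inv[[w]], ids[k])
  }
  lines <- c("%", paste(ids, cats, sep = "\t"), "%",
             vapply(names(inv), function(w) {
               paste(w, paste(inv[[w]], collapse = " "), sep = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Trait weight table
#'
#' Per trait, an intercept plus one coefficient per lexicon category; a
#' trait's raw score is the intercept plus the dot product of coefficients
#' and category proportions. The coefficient values are a configurable input
#' (the shipped fixture is synthetic); the pipeline, not the constants, is
#' what the package provides.
#'
#' @param table data frame with columns `trait`, `category`, `weight`;
#'   rows with category `"_intercept"` set the trait intercepts.
#' @return an object of class `trait_weights`.
#' @export
trait_weights <- function(table) {
  stopifnot(all(c("trait", "category", "weight") %in% names(table)))
  traits <- unique(table$trait)
  w <- setNames(vector("list", length(traits)), traits)
  for (tr in traits) {
    sub <- table[table$trait == tr, , drop = FALSE]
    ic <- sub$weight[sub$category == "_intercept"]
    coefs <- sub[sub$category != "_intercept", , drop = FALSE]
    w[[tr]] <- list(intercept = if (length(ic)) ic[1] else 0,
                    coef = setNames(coefs$weight, coefs$category))
  }
  structure(list(traits = w), class = "trait_weights")
}

#' @rdname trait_weights
#' @param path CSV path with columns `trait,category,weight`.
#' @export
read_trait_weights <- function(path) {
  trait_weights(read.csv(path, stringsAsFactors = FALSE))
}

#' Check that every category a weight table references exists in a lexicon
#'
#' @param weights a [trait_weights()].
#' @param lexicon a [trait_lexicon()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_weights <- function(weights, lexicon) {
  refd <- unique(unlist(lapply(weights$traits, function(t) names(t$coef))))
  missing <- setdiff(refd, names(lexicon$categories))
  if (length(missing)) {
    stop("weight table references categories absent from lexicon: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Tokenize text
#'
#' Lowercases, strips apostrophes (so "don't" becomes the single token
#' "dont"), and splits on any run of non-alphanumeric characters. Stop-word
#' removal and stemming are *optional and off by default*: wildcard lexicon
#' patterns subsume most inflection, and dictionary matching conventionally
#' consumes raw tokens. Word counts for the language control variable are
#' always taken before stop-word removal.
#'
#' @param text a single character string.
#' @param stopwords optional character vector of tokens to drop.
#' @param stem if `TRUE`, apply a small rule-based suffix stripper
#'   (`ing`, `ed`, `es`, `ly`, `s`; only when at least 3 characters remain).
#' @return character vector of tokens.
#' @export
#' @examples
#' tokenize("Good, GOOD happiness!")
tokenize <- function(text, stopwords = NULL, stem = FALSE) {
  stopifnot(length(text) == 1L)
  toks <- .tokenize_all(text)[[1L]]
  if (!is.null(stopwords)) toks <- toks[!(toks %in% stopwords)]
  if (stem) toks <- .strip_suffixes(toks)
  toks
}

.tokenize_all <- function(text) {
  x <- gsub("['’]", "", tolower(text))
  out <- strsplit(x, "[^a-z0-9]+")
  lapply(out, function(t) t[nzchar(t)])
}

.strip_suffixes <- function(tokens) {
  for (sfx in c("ing", "ed", "es", "ly", "s")) {
    hit <- endsWith(tokens, sfx) & nchar(tokens) - nchar(sfx) >= 3L
    tokens[hit] <- substr(tokens[hit], 1L, nchar(tokens[hit]) - nchar(sfx))
  }
  tokens
}

#' Filter a set of tweets
#'
#' Drops (a) duplicate tweets by the same author — at most one tweet per
#' (author, whitespace/case-normalized text) pair, keeping the earliest
#' timestamp — and (b) tweets with fewer than three tokens. The same text by
#' two different authors is retained for both.
#'
#' @param tweets data frame with columns `author`, `ts`, `text` (other
#'   columns pass through).
#' @return the retained rows, original column set preserved.
#' @export
filter_tweets <- function(tweets) {
  if (nrow(tweets) == 0L) return(tweets)
  norm <- gsub("\\s+", " ", trimws(tolower(tweets$text)))
  ord <- order(tweets$ts)
  tweets <- tweets[ord, , drop = FALSE]
  norm <- norm[ord]
  keep <- !duplicated(paste(tweets$author, norm, sep = "\r"))
  tweets <- tweets[keep, , drop = FALSE]
  ntok <- lengths(.tokenize_all(tweets$text))
  out <- tweets[ntok >= 3L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign points to county polygons
#'
#' Ray-casting (even-odd) point-in-polygon test, vectorized over points.
#' Boundary points (edges and vertices) count as inside; when polygons
#' touch, the *first matching feature in file order* wins. Points outside
#' every feature get `NA`.
#'
#' @param lat,lon numeric vectors of equal length (WGS84 degrees).
#' @param polygons a `county_polygons` object.
#' @return character vector of FIPS codes (or `NA`) parallel to the inputs.
#' @export
#' @examples
#' polys <- generate_polygons(4)
#' assign_county(lat = 0.5, lon = 0.5, polys)
assign_county <- function(lat, lon, polygons) {
  stopifnot(length(lat) == length(lon))
  out <- rep(NA_character_, length(lat))
  todo <- seq_along(lat)
  for (f in polygons) {
    if (!length(todo)) break
    hit <- .point_in_ring(lon[todo], lat[todo], f$ring)
    out[todo[hit]] <- f$fips
    todo <- todo[!hit]
  }
  out
}

# even-odd crossing test plus explicit on-edge detection
.point_in_ring <- function(px, py, ring) {
  if (!is.matrix(ring) || nrow(ring) < 4L ||
      any(ring[1L, ] != ring[nrow(ring), ])) {
    stop("malformed polygon ring (must be closed with >= 4 vertices)",
         call. = FALSE)
  }
  eps <- 1e-9
  n <- length(px)
  inside <- rep(FALSE, n)
  onedge <- rep(FALSE, n)
  for (i in seq_len(nrow(ring) - 1L)) {
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
    x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onseg <- abs(cross) <= eps &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | onseg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Build a county-year document
#'
#' @param fips county FIPS code.
#' @param year calendar year.
#' @param text concatenated retained tweet text.
#' @return list of class `county_document` with `fips`, `year`, `text` and
#'   `word_count` (tokenizer output length on `text`, before any stop-word
#'   removal).
#' @export
county_document <- function(fips, year, text) {
  structure(list(fips = fips, year = year, text = text,
                 word_count = length(.tokenize_all(text)[[1L]])),
            class = "county_document")
}

#' Aggregate geo-assigned tweets into county-year documents
#'
#' Tweets are attributed to the calendar year of their timestamp in UTC and
#' concatenated per (county, year). Scoring is therefore invariant to tweet
#' order within a county-year.
#'
#' @param tweets data frame with `ts` and `text`.
#' @param fips county assignment per tweet (from [assign_county()]); `NA`
#'   rows are dropped.
#' @return list of [county_document()]s.
#' @export
aggregate_documents <- function(tweets, fips) {
  keep <- !is.na(fips)
  tweets <- tweets[keep, , drop = FALSE]
  fips <- fips[keep]
  year <- as.integer(format(tweets$ts, "%Y", tz = "UTC"))
  key <- paste(fips, year, sep = "_")
  idx <- split(seq_along(key), key)
  lapply(idx, function(i) {
    county_document(fips[i[1L]], year[i[1L]],
                    paste(tweets$text[i], collapse = " "))
  })
}

#' Score category proportions for a document
#'
#' For each lexicon category, the proportion of the document's tokens
#' matching any of the category's patterns, with the document's full token
#' count (before stop-word removal) as the denominator. A token may match
#' multiple categories.
#'
#' @param doc a [county_document()] or a character vector of tokens.
#' @param lexicon a [trait_lexicon()].
#' @param stopwords optional stop-word list removed before matching (the
#'   denominator is unaffected).
#' @param stem if `TRUE`, stem tokens before matching.
#' @return named numeric vector of per-category proportions.
#' @export
score_categories <- function(doc, lexicon, stopwords = NULL, stem = FALSE) {
  stopifnot(inherits(lexicon, "trait_lexicon"))
  if (inherits(doc, "county_document")) {
    tokens <- .tokenize_all(doc$text)[[1L]]
  } else {
    tokens <- as.character(doc)
  }
  total <- length(tokens)
  if (total == 0L) stop("document has zero tokens", call. = FALSE)
  if (!is.null(stopwords)) tokens <- tokens[!(tokens %in% stopwords)]
  if (stem) tokens <- .strip_suffixes(tokens)
  tab <- table(tokens)
  toks <- names(tab)
  cnt <- as.numeric(tab)
  vapply(lexicon$categories, function(patterns) {
    wild <- endsWith(patterns, "*")
    exact <- patterns[!wild]
    prefixes <- sub("\\*$", "", patterns[wild])
    matched <- toks %in% exact
    for (p in prefixes) matched <- matched | startsWith(toks, p)
    sum(cnt[matched]) / total
  }, numeric(1L))
}

#' Weighted-lexicon trait scores
#'
#' `raw_t = intercept_t + sum_c coef_tc * proportion_c` for each trait in
#' the weight table.
#'
#' @param props named category proportions (from [score_categories()]).
#' @param weights a [trait_weights()].
#' @return named numeric vector of raw trait scores.
#' @export
score_traits <- function(props, weights) {
  stopifnot(inherits(weights, "trait_weights"))
  vapply(weights$traits, function(w) {
    missing <- setdiff(names(w$coef), names(props))
    if (length(missing)) {
      stop("proportions missing for categories: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    w$intercept + sum(w$coef * props[names(w$coef)])
  }, numeric(1L))
}

#' Percentile transform across counties
#'
#' `100 * (average rank - 0.5) / n`, with ties receiving averaged ranks.
#' Strictly monotone in the raw score, invariant under monotone
#' transformations, and with mean exactly 50 within each year.
#'
#' @param raw numeric vector of raw scores for one year (length >= 2).
#' @return percentiles in `[0, 100]`.
#' @export
#' @examples
#' percentile_transform(c(1, 2, 3, 4))
percentile_transform <- function(raw) {
  if (length(raw) < 2L) {
    stop("need at least 2 counties to form percentiles", call. = FALSE)
  }
  100 * (rank(raw, ties.method = "average") - 0.5) / length(raw)
}

#' Score a corpus end to end
#'
#' Filter, geo-assign, aggregate by county-year, lexicon-match, weight, and
#' percentile-rank within year.
#'
#' @param tweets raw tweet data frame (`author`, `ts`, `lat`, `lon`, `text`).
#' @param polygons a `county_polygons` object.
#' @param lexicon a [trait_lexicon()].
#' @param weights a [trait_weights()].
#' @param stopwords optional stop-word list.
#' @param stem if `TRUE`, stem before matching.
#' @return data frame with `fips`, `year`, `word_count`, raw scores
#'   (`raw_<trait>`) and within-year percentiles (`<trait>`).
#' @export
score_corpus <- function(tweets, polygons, lexicon, weights,
                         stopwords = NULL, stem = FALSE) {
  validate_weights(weights, lexicon)
  tweets <- filter_tweets(tweets)
  fips <- assign_county(tweets$lat, tweets$lon, polygons)
  docs <- aggregate_documents(tweets, fips)
  if (!length(docs)) stop("no documents after filtering/assignment", call. = FALSE)
  raw <- t(vapply(docs, function(d) {
    score_traits(score_categories(d, lexicon, stopwords, stem), weights)
  }, numeric(length(names(weights$traits)))))
  out <- data.frame(
    fips = vapply(docs, `[[`, "", "fips"),
    year = vapply(docs, function(d) as.integer(d$year), integer(1L)),
    word_count = vapply(docs, function(d) as.integer(d$word_count), integer(1L)),
    stringsAsFactors = FALSE)
  colnames(raw) <- paste0("raw_", colnames(raw))
  out <- cbind(out, raw)
  for (tr in names(weights$traits)) {
    out[[tr]] <- NA_real_
    for (y in unique(out$year)) {
      sel <- out$year == y
      out[[tr]][sel] <- percentile_transform(out[[paste0("raw_", tr)]][sel])
    }
  }
  rownames(out) <- NULL
  out
}
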