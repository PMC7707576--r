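#' Read a per-language sociodemographic predictor table
#'
#' Expects a CSV with one row per language: historical population size,
#' distance (km) to the nearest landmass inhabited by a different
#' culture (0 = such a culture shares the island), and three 4-point
#' ordinal conflict scales coded 1 (conflict endemic/frequent) to 4
#' (conflict low/rare): conflict within the local community, warfare
#' between communities of the same culture (internal), and warfare with
#' other cultures (external).
#'
#' @param path CSV path.
#' @param schema named character vector mapping the canonical names
#'   `language`, `population`, `distance_km`, `conflict_within`,
#'   `warfare_internal`, `warfare_external` to file columns.
#' @return data.frame with the canonical columns, validated.
#' @export
readPredictors <- function(path, schema = NULL) {
  canonical <- c("language", "population", "distance_km", "conflict_within",
                 "warfare_internal", "warfare_external")
  if (is.null(schema)) schema <- stats::setNames(canonical, canonical)
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[canonical]), names(raw))
  if (length(missing_cols))
    stop("predictor table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(language = as.character(raw[[schema[["language"]]]]),
                    population = as.numeric(raw[[schema[["population"]]]]),
                    distance_km = as.numeric(raw[[schema[["distance_km"]]]]),
                    conflict_within = as.integer(raw[[schema[["conflict_within"]]]]),
                    warfare_internal = as.integer(raw[[schema[["warfare_internal"]]]]),
                    warfare_external = as.integer(raw[[schema[["warfare_external"]]]]),
                    stringsAsFactors = FALSE)
  .validateRawPredictors(out)
  out
}

.validateRawPredictors <- function(raw) {
  if (any(!is.finite(raw$population) | raw$population <= 0))
    stop("non-positive population size for: ",
         paste(raw$language[!is.finite(raw$population) | raw$population <= 0],
               collapse = ", "))
  if (any(!is.finite(raw$distance_km) | raw$distance_km < 0))
    stop("negative or missing distance for: ",
         paste(raw$language[!is.finite(raw$distance_km) | raw$distance_km < 0],
               collapse = ", "))
  for (v in c("conflict_within", "warfare_internal", "warfare_external")) {
    bad <- is.na(raw[[v]]) | !(raw[[v]] %in% 1:4)
    if (any(bad))
      stop(v, " outside the ordinal scale 1-4 for: ",
           paste(raw$language[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Transform and standardize the five predictors
#'
#' Population is log-transformed; distance becomes the isolation score
#' `log(distance_km + 1)` so that a shared island (0 km) maps to 0 while
#' ordering is preserved; each conflict ordinal `v` is reversed as
#' `5 - v` so that higher values mean more conflict.  Every column is
#' then z-standardized (mean 0, sd 1) over the analysis sample, so that
#' regression effect sizes are directly comparable.
#'
#' @param raw data.frame in [readPredictors()] shape.
#' @param sample optional character vector of language ids defining the
#'   analysis (and standardization) sample; default: all rows.
#' @param distance_offset_km offset added to distance before the log
#'   (default 1 km).
#' @return data.frame: `language`, `logPopulation`, `conflictWithin`,
#'   `isolation`, `warfareInternal`, `warfareExternal`, all standardized
#'   over `sample`.
#' @export
transformPredictors <- function(raw, sample = NULL, distance_offset_km = 1) {
  .validateRawPredictors(raw)
  if (is.null(sample)) sample <- raw$language
  missing_l <- setdiff(sample, raw$language)
  if (length(missing_l))
    stop("no predictor row for language(s): ",
         paste(missing_l, collapse = ", "))
  raw <- raw[match(sample, raw$language), , drop = FALSE]
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero variance after transformation; cannot standardize")
    (x - mean(x)) / s
  }
  out <- data.frame(
    language = raw$language,
    logPopulation = z(log(raw$population)),
    conflictWithin = z(5 - raw$conflict_within),
    isolation = z(log(raw$distance_km + distance_offset_km)),
    warfareInternal = z(5 - raw$warfare_internal),
    warfareExternal = z(5 - raw$warfare_external),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Names of the five standardized predictors
#' @return character vector of the five design-column names.
#' @export
predictorNames <- function() {
  c("logPopulation", "conflictWithin", "isolation",
    "warfareInternal", "warfareExternal")
}

#' Build the per-pair design table
#'
#' Joins standardized predictors to the event counts of each sister
#' pair.  Because the regression is formulated on predictor levels while
#' the response is a per-pair count, the mapping from two languages to
#' one row admits several constructions, offered as modes:
#'
#' * `"pair_mean"` (default): each predictor is the mean of the two
#'   sisters' standardized values, the response the pair-total count —
#'   the only symmetric, orientation-free level summary;
#' * `"two_row"`: one row per language with its own values and its own
#'   branch counts (`gains_a`/`losses_a` etc.);
#' * `"signed_contrast"` (experimental): within-pair differences
#'   `value(a) - value(b)`, with the pair oriented so the focal
#'   predictor's contrast is non-negative, response = count on branch a.
#'
#' @param pairs data.frame of sister pairs.
#' @param pred data.frame from [transformPredictors()].
#' @param events data.frame from [tabulateEvents()] (matched on
#'   `pair_id`).
#' @param mode one of `"pair_mean"`, `"two_row"`, `"signed_contrast"`.
#' @param focal focal predictor used to orient pairs in
#'   `"signed_contrast"` mode.
#' @return data.frame with the five predictor columns plus response
#'   columns `gains`, `losses`, `turnover` (and `language` in
#'   `"two_row"` mode); attribute `pairing_mode` records the mode.
#' @export
buildDesign <- function(pairs, pred, events, mode = c("pair_mean",
                        "two_row", "signed_contrast"),
                        focal = "isolation") {
  mode <- match.arg(mode)
  vars <- predictorNames()
  langs <- c(pairs$language_a, pairs$language_b)
  missing_l <- setdiff(langs, pred$language)
  if (length(missing_l))
    stop("language(s) missing from predictor table: ",
         paste(missing_l, collapse = ", "))
  ev <- events[match(pairs$pair_id, events$pair_id), , drop = FALSE]
  if (any(is.na(ev$pair_id)))
    stop("event row missing for pair(s): ",
         paste(pairs$pair_id[is.na(ev$pair_id)], collapse = ", "))
  va <- pred[match(pairs$language_a, pred$language), vars, drop = FALSE]
  vb <- pred[match(pairs$language_b, pred$language), vars, drop = FALSE]
  out <- switch(mode,
    pair_mean = {
      x <- (as.matrix(va) + as.matrix(vb)) / 2
      cbind(data.frame(pair_id = pairs$pair_id, stringsAsFactors = FALSE),
            as.data.frame(x),
            ev[c("gains", "losses", "turnover")])
    },
    two_row = {
      xa <- cbind(data.frame(pair_id = pairs$pair_id,
                             language = pairs$language_a,
                             stringsAsFactors = FALSE),
                  va,
                  data.frame(gains = ev$gains_a, losses = ev$losses_a,
                             turnover = ev$gains_a + ev$losses_a))
      xb <- cbind(data.frame(pair_id = pairs$pair_id,
                             language = pairs$language_b,
                             stringsAsFactors = FALSE),
                  vb,
                  data.frame(gains = ev$gains_b, losses = ev$losses_b,
                             turnover = ev$gains_b + ev$losses_b))
      rbind(xa, xb)
    },
    signed_contrast = {
      if (!focal %in% vars) stop("unknown focal predictor: ", focal)
      d <- as.matrix(va) - as.matrix(vb)
      flip <- d[, focal] < 0
      d[flip, ] <- -d[flip, , drop = FALSE]
      resp <- data.frame(gains = ifelse(flip, ev$gains_b, ev$gains_a),
                         losses = ifelse(flip, ev$losses_b, ev$losses_a))
      resp$turnover <- resp$gains + resp$losses
      cbind(data.frame(pair_id = pairs$pair_id, stringsAsFactors = FALSE),
            as.data.frame(d), resp)
    })
  rownames(out) <- NULL
  attr(out, "pairing_mode") <- mode
  out
}

#' Variance inflation factors of the design predictors
#'
#' Collinearity diagnostic: for each predictor `j`, `1 / (1 - R2_j)`
#' where `R2_j` comes from the ordinary regression of column `j` on all
#' other predictors.  All five predictors are continuous after
#' standardization, so the generalized VIF reduces to the plain VIF.
#' Values of 2 or above are flagged as collinearity concerns; a
#' perfectly collinear column yields `Inf` rather than an error.
#'
#' @param design data.frame containing the predictor columns.
#' @param vars predictor column names (default [predictorNames()],
#'   intersected with what is present).
#' @param threshold flag level (default 2).
#' @return data.frame: `predictor`, `gvif`, `flagged`.
#' @export
gvif <- function(design, vars = NULL, threshold = 2) {
  if (is.null(vars)) vars <- intersect(predictorNames(), names(design))
  if (length(vars) < 2) stop("need at least two predictors")
  X <- as.data.frame(design)[vars]
  if (nrow(X) <= length(vars))
    stop("need more rows than predictors")
  out <- data.frame(predictor = vars, gvif = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(vars)) {
    fit <- stats::lm(stats::reformulate(vars[-j], response = vars[j]),
                     data = X)
    r2 <- summary(fit)$r.squared
    out$gvif[j] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  out$flagged <- out$gvif >= threshold
  out
}

#' Pairwise Pearson correlations among predictors
#'
#' @param pred data.frame from [transformPredictors()] (or any numeric
#'   columns selected by `vars`).
#' @param vars column names; default the five standard predictors.
#' @return list with symmetric matrices `r` (Pearson coefficients,
#'   diagonal 1) and `p` (two-sided p-values from the t transform of r,
#'   diagonal `NA`), and `n` the number of rows used.
#' @export
correlationMatrix <- function(pred, vars = NULL) {
  if (is.null(vars)) vars <- intersect(predictorNames(), names(pred))
  X <- as.data.frame(pred)[vars]
  if (nrow(X) < 3) stop("need at least 3 rows")
  k <- length(vars)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(vars, vars)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(X[[i]]) == 0 || stats::sd(X[[j]]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      warning("zero-variance column: correlation undefined for ",
              vars[i], " / ", vars[j])
      next
    }
    ct <- stats::cor.test(X[[i]], X[[j]], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(X))
}

#' Pearson chi-square test of independence of two categorical variables
#'
#' Cross-tabulates the two vectors and applies the Pearson chi-square
#' test without continuity correction; degrees of freedom are
#' `(r - 1)(c - 1)`.  A warning is raised when any expected cell count
#' falls below 5 (the asymptotic p-value is then approximate), which is
#' routine when a near-continuous variable such as isolation is used at
#' its raw distinct values.
#'
#' @param a,b equal-length vectors, coerced to factors.
#' @return list: `statistic`, `df`, `p`, `expected` (matrix).
#' @export
chisqIndependence <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  tab <- table(factor(a), factor(b))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("each variable needs at least 2 observed levels (df would be 0)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected counts below 5; chi-square p-value is approximate")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}
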