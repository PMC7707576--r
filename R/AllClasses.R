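#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib lexRates, .registration = TRUE
NULL

#' CognateMatrix: cognate-coded basic-vocabulary data
#'
#' The central lexical container: for every (language, concept) cell it
#' records the set of cognate-set ids attested, together with an
#' `attested` flag that distinguishes genuine missing data (no entry was
#' ever collected for that cell) from a cell that became empty after
#' filtering (e.g. when every recorded form was a loan).  A language may
#' hold several cognate sets for one concept (synonyms).
#'
#' @slot entries data.frame with columns `language`, `concept`,
#'   `cognate_set`, `form`, `loan`; one row per unique
#'   (language, concept, cognate_set, loan) combination.
#' @slot languages character vector of language ids (ordered).
#' @slot concepts character vector of concept ids (ordered); concepts are
#'   the basic-vocabulary semantic units (210 in an ABVD-style list).
#' @slot attested logical matrix (languages x concepts); `TRUE` where the
#'   cell had at least one entry when the data were read.  Filtering
#'   never changes this flag.
#'
#' @seealso [readWordlists()], [filterLoans()], [restrictToLanguages()]
#' @exportClass CognateMatrix
setClass("CognateMatrix",
  representation(
    entries  = "data.frame",
    languages = "character",
    concepts = "character",
    attested = "matrix"
  )
)

setValidity("CognateMatrix", function(object) {
  msgs <- character(0)
  e <- object@entries
  need <- c("language", "concept", "cognate_set", "form", "loan")
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste("entries must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@languages))
      msgs <- c(msgs, "duplicated language ids")
    if (anyDuplicated(object@concepts))
      msgs <- c(msgs, "duplicated concept ids")
    if (nrow(e)) {
      if (!all(e$language %in% object@languages))
        msgs <- c(msgs, "entries reference unknown languages")
      if (!all(e$concept %in% object@concepts))
        msgs <- c(msgs, "entries reference unknown concepts")
      if (any(is.na(e$cognate_set) | e$cognate_set == ""))
        msgs <- c(msgs, "empty cognate_set id in entries")
      if (anyDuplicated(e[c("language", "concept", "cognate_set", "loan")]))
        msgs <- c(msgs, "duplicated (language, concept, cognate_set, loan) rows")
      if (!is.logical(e$loan))
        msgs <- c(msgs, "loan column must be logical")
    }
    a <- object@attested
    if (!identical(dim(a),
                   c(length(object@languages), length(object@concepts))))
      msgs <- c(msgs, "attested matrix dimensions do not match ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CognateMatrix from an entry table
#'
#' Deduplicates rows on (language, concept, cognate_set, loan); the
#' `attested` flag is set for every cell with at least one row.  Extra
#' languages/concepts with no entries may be declared so that their cells
#' are carried as unattested (missing data).
#'
#' @param entries data.frame with columns `language`, `concept`,
#'   `cognate_set`, `form` (optional, defaults to `""`), `loan`
#'   (optional, defaults to `FALSE`).
#' @param languages,concepts optional id vectors; defaults to the ids
#'   observed in `entries`, in order of first appearance.
#' @param attested optional logical matrix overriding the default
#'   attestation flags (used internally by the filtering verbs).
#' @return A [CognateMatrix-class] object.
#' @export
CognateMatrix <- function(entries, languages = NULL, concepts = NULL,
                          attested = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(entries$form)) entries$form <- rep("", nrow(entries))
  if (is.null(entries$loan)) entries$loan <- rep(FALSE, nrow(entries))
  entries$language <- as.character(entries$language)
  entries$concept <- as.character(entries$concept)
  entries$cognate_set <- as.character(entries$cognate_set)
  entries$form <- as.character(entries$form)
  entries$loan <- as.logical(entries$loan)
  if (nrow(entries) && any(is.na(entries$cognate_set) | entries$cognate_set == "")) {
    bad <- which(is.na(entries$cognate_set) | entries$cognate_set == "")
    stop("empty cognate_set id in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  entries <- entries[!duplicated(entries[c("language", "concept",
                                           "cognate_set", "loan")]), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  if (is.null(languages)) languages <- unique(entries$language)
  if (is.null(concepts)) concepts <- unique(entries$concept)
  languages <- as.character(languages)
  concepts <- as.character(concepts)
  if (is.null(attested)) {
    attested <- matrix(FALSE, length(languages), length(concepts),
                       dimnames = list(languages, concepts))
    if (nrow(entries))
      attested[cbind(entries$language, entries$concept)] <- TRUE
  } else {
    dimnames(attested) <- list(languages, concepts)
  }
  new("CognateMatrix", entries = entries[c("language", "concept",
                                           "cognate_set", "form", "loan")],
      languages = languages, concepts = concepts, attested = attested)
}

#' @describeIn CognateMatrix Language ids.
#' @param x A `CognateMatrix`.
#' @export
languageIds <- function(x) x@languages

#' @describeIn CognateMatrix Concept (semantic unit) ids.
#' @export
conceptIds <- function(x) x@concepts

#' @describeIn CognateMatrix The entry table (one row per attested
#'   cognate set in a cell).
#' @export
wordEntries <- function(x) x@entries

#' @describeIn CognateMatrix Logical attestation matrix
#'   (languages x concepts).
#' @export
attestedCells <- function(x) x@attested

#' Cognate sets present in one (language, concept) cell
#'
#' @param x A [CognateMatrix-class].
#' @param language,concept single ids.
#' @return Character vector of cognate-set ids (possibly empty).
#' @export
presenceSet <- function(x, language, concept) {
  e <- x@entries
  sort(unique(e$cognate_set[e$language == language & e$concept == concept]))
}

setMethod("show", "CognateMatrix", function(object) {
  cat("CognateMatrix:", length(object@languages), "languages x",
      length(object@concepts), "concepts\n")
  cat("  entries:   ", nrow(object@entries),
      " (", sum(object@entries$loan), " loan-flagged)\n", sep = "")
  cat("  attested cells: ", sum(object@attested), " of ",
      length(object@attested), "\n", sep = "")
})

#' PosteriorSummary: draws and diagnostics from a fitted Poisson GLM
#'
#' Holds the pooled post-warmup posterior draws of the intercept and
#' regression coefficients of a Bayesian Poisson log-linear model,
#' the pointwise log-likelihood matrix required by WAIC, and per-parameter
#' convergence diagnostics (split-Rhat, effective sample size).
#'
#' @slot draws numeric matrix (pooled post-warmup draws x parameters);
#'   column names are `alpha` and the predictor names.
#' @slot logLik numeric matrix (draws x observations) of pointwise
#'   Poisson log-likelihoods.
#' @slot summary data.frame: one row per parameter with posterior
#'   `median`, 90% HPDI bounds, `rhat`, `ess`.
#' @slot X,y the design matrix (including intercept column) and response
#'   used for the fit, kept so WAIC/Bayesian R-squared can be recomputed.
#' @slot nChains,drawsPerChain sampler layout of `draws` (row-major by
#'   chain: the first `drawsPerChain` rows are chain 1, and so on).
#' @slot response name of the response count.
#' @slot predictors names of the predictor columns (may be empty: null
#'   model).
#' @slot converged logical; `TRUE` when every parameter passed the Rhat
#'   and effective-sample-size gates.
#' @slot acceptRate mean Metropolis acceptance rate across chains.
#' @slot config the [samplerConfig()] list used.
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(
    draws = "matrix",
    logLik = "matrix",
    summary = "data.frame",
    X = "matrix",
    y = "numeric",
    nChains = "integer",
    drawsPerChain = "integer",
    response = "character",
    predictors = "character",
    converged = "logical",
    acceptRate = "numeric",
    config = "list"
  )
)

setValidity("PosteriorSummary", function(object) {
  msgs <- character(0)
  if (nrow(object@draws) != object@nChains * object@drawsPerChain)
    msgs <- c(msgs, "draw count != chains x draws-per-chain")
  if (nrow(object@logLik) && nrow(object@logLik) != nrow(object@draws))
    msgs <- c(msgs, "logLik rows != draw rows")
  s <- object@summary
  if (nrow(s) && !all(s$hpdi_lower <= s$median & s$median <= s$hpdi_upper))
    msgs <- c(msgs, "HPDI does not bracket the posterior median")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PosteriorSummary Pooled post-warmup draws
#'   (matrix, draws x parameters).
#' @param x A `PosteriorSummary`.
#' @export
posteriorDraws <- function(x) x@draws

#' @describeIn PosteriorSummary Per-parameter summary table (posterior
#'   median, 90% HPDI, Rhat, effective sample size).
#' @export
posteriorTable <- function(x) x@summary

#' @describeIn PosteriorSummary Pointwise log-likelihood matrix
#'   (draws x observations).
#' @export
pointwiseLogLik <- function(x) x@logLik

#' @describeIn PosteriorSummary `TRUE` when all convergence gates passed.
#' @export
isConverged <- function(x) x@converged

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary: Poisson GLM for '", object@response, "' (",
      length(object@y), " observations)\n", sep = "")
  cat("  ", object@nChains, " chains x ", object@drawsPerChain,
      " post-warmup draws = ", nrow(object@draws), " samples",
      if (!object@converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(format(object@summary, digits = 3))
})
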