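#' Read a pipeline run configuration
#'
#' YAML with the keys used by the `run*` stages: `paths` (`tree`,
#' `wordlists`, `predictors`, `output`), `thresholds` (`min_support`,
#' `max_divergence`), `reject` (pair ids), `pairing_mode`, `responses`,
#' `sampler` (`chains`, `iterations`, `warmup`), `seed`.  Missing keys
#' fall back to the package defaults shown by [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return named list (class `runConfig`).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaultRunConfig(), cfg)
  class(out) <- "runConfig"
  out
}

#' Default run configuration
#' @return named list with the default thresholds, pairing mode,
#'   responses, sampler settings and seed.
#' @export
defaultRunConfig <- function() {
  list(paths = list(tree = NULL, wordlists = NULL, predictors = NULL,
                    output = "."),
       thresholds = list(min_support = 0.80, max_divergence = Inf),
       reject = character(0),
       pairing_mode = "pair_mean",
       responses = c("gains", "losses", "turnover"),
       sampler = list(chains = 3L, iterations = 10000L, warmup = 2000L),
       seed = 1L)
}

.outPath <- function(cfg, name) {
  dir.create(cfg$paths$output, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$paths$output, name)
}

.stampProvenance <- function(cfg, stage) {
  info <- list(stage = stage, seed = cfg$seed,
               package_version = as.character(utils::packageVersion("lexRates")),
               r_version = R.version.string,
               config = .configForJson(cfg),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(info, .outPath(cfg, paste0(stage, "-run-info.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.configForJson <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$thresholds$max_divergence <-
    if (is.finite(cfg$thresholds$max_divergence))
      cfg$thresholds$max_divergence else "Inf"
  cfg
}

#' Stage 1: extract and filter sister pairs from the tree
#'
#' Parses the configured Newick tree, extracts cherries, applies the
#' support/divergence/reject filters and writes `pairs.csv` plus a
#' `pair-rejections.csv` log and a provenance stamp to the output
#' directory.
#'
#' @param cfg a [readRunConfig()] list.
#' @return the retained pair table, invisibly.
#' @export
runExtractPairs <- function(cfg) {
  if (is.null(cfg$paths$tree) || !file.exists(cfg$paths$tree))
    stop("tree file not found: ", cfg$paths$tree)
  tree <- parseTimeTree(cfg$paths$tree)
  pairs <- extractCherries(tree)
  max_div <- cfg$thresholds$max_divergence
  if (is.character(max_div) && max_div == "tree_depth") max_div <- tree$depth
  kept <- filterPairs(pairs, min_support = cfg$thresholds$min_support,
                      max_divergence = max_div,
                      reject = as.character(cfg$reject), quiet = TRUE)
  writePairTable(kept, .outPath(cfg, "pairs.csv"))
  utils::write.csv(attr(kept, "rejections"),
                   .outPath(cfg, "pair-rejections.csv"), row.names = FALSE)
  .stampProvenance(cfg, "extract-pairs")
  invisible(kept)
}

#' Stage 2: count gain/loss/turnover events per pair
#'
#' Reads the wordlists, removes loan entries, loads `pairs.csv` from the
#' output directory and writes `events.csv`.
#'
#' @param cfg a [readRunConfig()] list.
#' @return the event table, invisibly.
#' @export
runCount <- function(cfg) {
  if (is.null(cfg$paths$wordlists) || !file.exists(cfg$paths$wordlists))
    stop("wordlist file not found: ", cfg$paths$wordlists)
  pairs_path <- .outPath(cfg, "pairs.csv")
  if (!file.exists(pairs_path))
    stop("pairs.csv not found in output directory; run runExtractPairs first")
  pairs <- utils::read.csv(pairs_path, stringsAsFactors = FALSE)
  mat <- filterLoans(readWordlists(cfg$paths$wordlists, quiet = TRUE),
                     quiet = TRUE)
  missing_l <- setdiff(c(pairs$language_a, pairs$language_b),
                       languageIds(mat))
  if (length(missing_l))
    stop("pair language(s) absent from wordlists: ",
         paste(missing_l, collapse = ", "))
  events <- tabulateEvents(pairs, mat)
  writeEventTable(events, .outPath(cfg, "events.csv"))
  .stampProvenance(cfg, "count")
  invisible(events)
}

#' Stage 3: fit and compare the Poisson models per response
#'
#' Reads the predictor table, joins it to `pairs.csv` and `events.csv`,
#' runs the collinearity check, and for each configured response fits
#' the candidate model set, writing `model-comparison-<response>.csv`,
#' `coefficients-<response>.csv` (full-model posterior summaries) and a
#' JSON report with convergence flags and the GVIF table.
#'
#' @param cfg a [readRunConfig()] list.
#' @param allow_unconverged if `FALSE` (default) an unconverged full
#'   model raises an error.
#' @return list of per-response [compareModels()] tables, invisibly.
#' @export
runFit <- function(cfg, allow_unconverged = FALSE) {
  if (is.null(cfg$paths$predictors) || !file.exists(cfg$paths$predictors))
    stop("predictor file not found: ", cfg$paths$predictors)
  pairs <- utils::read.csv(.outPath(cfg, "pairs.csv"),
                           stringsAsFactors = FALSE)
  events <- utils::read.csv(.outPath(cfg, "events.csv"),
                            stringsAsFactors = FALSE)
  raw <- readPredictors(cfg$paths$predictors)
  sample_l <- c(pairs$language_a, pairs$language_b)
  pred <- transformPredictors(raw, sample = sample_l)
  design <- buildDesign(pairs, pred, events, mode = cfg$pairing_mode)
  # the collinearity check needs more pairs than predictors
  vif_tab <- if (nrow(design) > length(predictorNames()) + 1L)
    gvif(design) else NULL
  scfg <- samplerConfig(chains = cfg$sampler$chains,
                        iterations = cfg$sampler$iterations,
                        warmup = cfg$sampler$warmup, seed = cfg$seed)
  out <- list()
  report <- list(seed = cfg$seed, pairing_mode = cfg$pairing_mode,
                 gvif = vif_tab)
  for (resp in cfg$responses) {
    cmp <- compareModels(design, response = resp, cfg = scfg)
    out[[resp]] <- cmp$table
    utils::write.csv(cmp$table,
                     .outPath(cfg, paste0("model-comparison-", resp, ".csv")),
                     row.names = FALSE)
    full <- cmp$fits$full
    utils::write.csv(posteriorTable(full),
                     .outPath(cfg, paste0("coefficients-", resp, ".csv")),
                     row.names = FALSE)
    report[[paste0("converged_", resp)]] <- isConverged(full)
    if (!isConverged(full) && !allow_unconverged)
      stop("full model for '", resp, "' failed convergence gates; ",
           "rerun with more iterations or allow_unconverged = TRUE")
  }
  jsonlite::write_json(report, .outPath(cfg, "fit-report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .stampProvenance(cfg, "fit")
  invisible(out)
}
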