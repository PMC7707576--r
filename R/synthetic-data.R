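#' Ground-truth record for the synthetic cognate-evolution generator
#'
#' Word gains and word losses are simulated as two independent Poisson
#' log-linear processes with their own intercepts (the fitted models
#' treat the three responses separately); lexical turnover is derived as
#' their sum, so `turnover = gains + losses` holds exactly.  The default
#' intercepts give a few tens of events per pair, the order observed for
#' real sister pairs of basic-vocabulary lists, and the default
#' coefficient vector mixes strong positive, weak and negative effects
#' across the five predictors.
#'
#' @param alpha_gain,alpha_loss intercepts (log expected events).
#' @param beta_gain,beta_loss length-5 coefficient vectors on the
#'   standardized predictors, in [predictorNames()] order;
#'   `beta_loss` defaults to `beta_gain`, in which case turnover follows
#'   the same log-linear model with intercept
#'   `log(exp(alpha_gain) + exp(alpha_loss))`.
#' @param n_pairs number of sister pairs.
#' @param n_concepts basic-vocabulary size (default 210 semantic units).
#' @param n_background background languages per pair (disjoint across
#'   pairs, so loss detection is unambiguous).
#' @param pairing_mode design construction mode (see [buildDesign()]).
#' @param seed integer seed.
#' @return named list of class `simTruth`.
#' @export
simTruth <- function(alpha_gain = log(8),
                     beta_gain = c(0.5, 0.2, 0.9, -0.3, -0.5),
                     alpha_loss = log(10), beta_loss = beta_gain,
                     n_pairs = 25L, n_concepts = 210L, n_background = 4L,
                     pairing_mode = "pair_mean", seed = 1L) {
  stopifnot(length(beta_gain) == 5, length(beta_loss) == 5,
            n_pairs >= 1, n_concepts >= 1, n_background >= 1)
  # generation draws pair-level counts, so the mode must map pairs to
  # single design rows ("two_row" remains available for fitting)
  if (!pairing_mode %in% c("pair_mean", "signed_contrast"))
    stop("pairing_mode for generation must be 'pair_mean' or 'signed_contrast'")
  structure(list(alpha_gain = alpha_gain, beta_gain = beta_gain,
                 alpha_loss = alpha_loss, beta_loss = beta_loss,
                 n_pairs = as.integer(n_pairs),
                 n_concepts = as.integer(n_concepts),
                 n_background = as.integer(n_background),
                 pairing_mode = pairing_mode, seed = as.integer(seed)),
            class = "simTruth")
}

#' Simulate raw sociodemographic predictors
#'
#' Emulates the marginal distributions of the real covariates:
#' population size is log-normal with a median of about 26,500 speakers;
#' distance to the nearest differently-cultured landmass is a mixture of
#' exact zeros (a different culture on the same island) and a log-normal
#' in km whose mean is on the order of 100 km; each 4-point conflict
#' scale is categorical with most mass on the low-conflict codes.
#'
#' @param n_languages number of languages (at least 2).
#' @param seed integer seed.
#' @param language_ids optional ids (default `"L1"..."Ln"`).
#' @param p_same_island probability of a zero distance.
#' @return data.frame in [readPredictors()] shape.
#' @export
simulatePredictors <- function(n_languages, seed = 1L,
                               language_ids = NULL,
                               p_same_island = 0.15) {
  stopifnot(n_languages >= 2)
  if (is.null(language_ids))
    language_ids <- paste0("L", seq_len(n_languages))
  set.seed(seed)
  pop <- pmax(1, round(stats::rlnorm(n_languages, log(26485), 1.5)))
  zero <- stats::runif(n_languages) < p_same_island
  dist <- ifelse(zero, 0,
                 round(stats::rlnorm(n_languages, log(40), 1.5), 1))
  ord <- function() sample(1:4, n_languages, replace = TRUE,
                           prob = c(0.15, 0.25, 0.30, 0.30))
  data.frame(language = language_ids, population = pop,
             distance_km = dist, conflict_within = ord(),
             warfare_internal = ord(), warfare_external = ord(),
             stringsAsFactors = FALSE)
}

#' Simulate per-pair gain and loss counts from the log-linear model
#'
#' For each design row, `gains ~ Poisson(exp(alpha_g + x . beta_g))` and
#' `losses ~ Poisson(exp(alpha_l + x . beta_l))` independently; each
#' event is assigned to one of the two branches by a fair coin, since
#' the regression models use pair-level counts.
#'
#' @param design data.frame with `pair_id` and the five predictor
#'   columns (response columns, if present, are ignored).
#' @param truth a [simTruth()].
#' @param seed integer seed (default: `truth$seed`).
#' @return data.frame in [tabulateEvents()] shape (without
#'   `concepts_used`, which only exists once a matrix is realized; it is
#'   set to `truth$n_concepts`).
#' @export
simulatePairCounts <- function(design, truth, seed = truth$seed) {
  X <- as.matrix(as.data.frame(design)[predictorNames()])
  eta_g <- truth$alpha_gain + drop(X %*% truth$beta_gain)
  eta_l <- truth$alpha_loss + drop(X %*% truth$beta_loss)
  if (any(c(eta_g, eta_l) > 20))
    stop("linear predictor exceeds 20 (rate overflow); ",
         "use smaller intercepts or coefficients")
  set.seed(seed)
  n <- nrow(X)
  gains <- stats::rpois(n, exp(eta_g))
  losses <- stats::rpois(n, exp(eta_l))
  gains_a <- stats::rbinom(n, gains, 0.5)
  losses_a <- stats::rbinom(n, losses, 0.5)
  data.frame(pair_id = design$pair_id,
             gains_a = gains_a, gains_b = gains - gains_a,
             losses_a = losses_a, losses_b = losses - losses_a,
             gains = gains, losses = losses,
             turnover = gains + losses,
             concepts_used = truth$n_concepts,
             stringsAsFactors = FALSE)
}

#' Realize a cognate matrix that reproduces given event counts exactly
#'
#' Constructive inverse of the counting rules.  Per pair, every concept
#' receives a shared retained cognate set in both sisters (present in
#' both, hence uninformative); each gain event adds a globally unique
#' cognate set to the gaining sister only; each loss event charged to a
#' sister adds a cognate set to the *other* sister and to one of the
#' pair's background languages, so the counter classifies it as an
#' inherited word lost by that sister.  Background languages carry their
#' own private filler sets, and every cell of the matrix is attested.
#' Events are spread round-robin over concepts (several events may share
#' a concept, as synonym cells make legal); a capacity error names the
#' required vocabulary size when a pair carries more events than
#' `n_concepts * max_events_per_concept`.
#'
#' By construction, [tabulateEvents()] on the result returns `events`
#' exactly — this is the generator's defining contract and what makes
#' the counting pipeline testable end to end.
#'
#' @param events data.frame with per-pair `gains_a`, `gains_b`,
#'   `losses_a`, `losses_b` (as from [simulatePairCounts()]).
#' @param pairs data.frame with `pair_id`, `language_a`, `language_b`
#'   matching `events`.
#' @param truth a [simTruth()] (supplies `n_concepts`, `n_background`).
#' @param seed integer seed (shuffles the concept slots used by events).
#' @param max_events_per_concept cap on events sharing one concept
#'   within a pair.
#' @param loan_entries number of additional loan-flagged entries with
#'   fresh unique cognate sets scattered over the sisters; they must be
#'   removed with [filterLoans()] before counting, otherwise each would
#'   count as a spurious gain.
#' @return A [CognateMatrix-class].
#' @export
realizeCognateMatrix <- function(events, pairs, truth, seed = truth$seed,
                                 max_events_per_concept = 4L,
                                 loan_entries = 0L) {
  ev <- events[match(pairs$pair_id, events$pair_id), , drop = FALSE]
  if (any(is.na(ev$pair_id)))
    stop("events missing for pair(s): ",
         paste(pairs$pair_id[is.na(ev$pair_id)], collapse = ", "))
  n_concepts <- truth$n_concepts
  concepts <- sprintf("c%03d", seq_len(n_concepts))
  total_ev <- ev$gains_a + ev$gains_b + ev$losses_a + ev$losses_b
  over <- total_ev > n_concepts * max_events_per_concept
  if (any(over))
    stop("too many events for pair(s) ",
         paste(pairs$pair_id[over], collapse = ", "),
         "; need n_concepts >= ",
         ceiling(max(total_ev) / max_events_per_concept))
  set.seed(seed)
  parts <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$language_a[i]; b <- pairs$language_b[i]
    bg <- sprintf("BG%d_%d", i, seq_len(truth$n_background))
    # shared retained vocabulary: one common set per concept, both sisters
    shared_ids <- sprintf("P%d_%s_share", i, concepts)
    rows <- list(
      data.frame(language = rep(c(a, b), each = n_concepts),
                 concept = rep(concepts, 2),
                 cognate_set = rep(shared_ids, 2),
                 stringsAsFactors = FALSE),
      # background private fillers
      data.frame(language = rep(bg, each = n_concepts),
                 concept = rep(concepts, length(bg)),
                 cognate_set = paste0(rep(bg, each = n_concepts), "_",
                                      rep(concepts, length(bg)), "_fill"),
                 stringsAsFactors = FALSE))
    kinds <- rep(c("ga", "gb", "la", "lb"),
                 times = c(ev$gains_a[i], ev$gains_b[i],
                           ev$losses_a[i], ev$losses_b[i]))
    if (length(kinds)) {
      slot_concepts <- concepts[(sample(seq_along(kinds)) - 1L) %%
                                  n_concepts + 1L]
      uid <- sprintf("P%d_ev%04d", i, seq_along(kinds))
      holders <- lapply(seq_along(kinds), function(j) {
        switch(kinds[j],
               ga = a,                 # unique innovation in sister a
               gb = b,                 # unique innovation in sister b
               la = c(b, bg[1]),       # inherited word lost by sister a
               lb = c(a, bg[1]))       # inherited word lost by sister b
      })
      rows[[3]] <- data.frame(
        language = unlist(holders),
        concept = rep(slot_concepts, lengths(holders)),
        cognate_set = rep(uid, lengths(holders)),
        stringsAsFactors = FALSE)
    }
    parts[[i]] <- do.call(rbind, rows)
  }
  entries <- do.call(rbind, parts)
  entries$form <- paste0("w_", entries$cognate_set)
  entries$loan <- FALSE
  if (loan_entries > 0) {
    sisters <- c(pairs$language_a, pairs$language_b)
    loans <- data.frame(
      language = sample(sisters, loan_entries, replace = TRUE),
      concept = sample(concepts, loan_entries, replace = TRUE),
      cognate_set = sprintf("LOAN%04d", seq_len(loan_entries)),
      stringsAsFactors = FALSE)
    loans$form <- paste0("w_", loans$cognate_set)
    loans$loan <- TRUE
    entries <- rbind(entries, loans)
  }
  CognateMatrix(entries)
}

#' Build an ultrametric Newick tree holding the simulated sister pairs
#'
#' The pairs appear as cherries with their divergence times and support
#' values; background languages attach as successively deeper outgroup
#' tips along a ladder, with the root at `depth` years.  The result
#' parses with [parseTimeTree()] and [extractCherries()] recovers
#' exactly the simulated pairs.
#'
#' @param pairs data.frame with `language_a`, `language_b`,
#'   `divergence_time`, `support`.
#' @param background character vector of background tip labels.
#' @param depth root height in years (default 4300).
#' @param join_support label given to the ladder's internal joins.
#' @return single Newick string (terminated by `;`).
#' @export
syntheticNewick <- function(pairs, background, depth = 4300,
                            join_support = 1) {
  fmt <- function(x) sprintf("%.12g", x)
  comp <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs$divergence_time[i]
    list(txt = sprintf("(%s:%s,%s:%s)%s", pairs$language_a[i], fmt(d),
                       pairs$language_b[i], fmt(d),
                       fmt(pairs$support[i])),
         h = d)
  })
  comp <- c(comp, lapply(background, function(b) list(txt = b, h = 0)))
  if (length(comp) == 1L) return(paste0(comp[[1]]$txt, ";"))
  hmax <- max(vapply(comp, `[[`, numeric(1), "h"))
  if (depth <= hmax) stop("depth must exceed the deepest cherry")
  joins <- hmax + (depth - hmax) * seq_len(length(comp) - 1L) /
    (length(comp) - 1L)
  cur <- comp[[1]]
  for (k in 2:length(comp)) {
    H <- joins[k - 1L]
    lab <- if (k < length(comp)) fmt(join_support) else ""
    cur <- list(txt = sprintf("(%s:%s,%s:%s)%s", cur$txt, fmt(H - cur$h),
                              comp[[k]]$txt, fmt(H - comp[[k]]$h), lab),
                h = H)
  }
  paste0(cur$txt, ";")
}

#' Simulate a complete synthetic study
#'
#' Draws predictors for the sister languages, lays the pairs out on an
#' ultrametric tree, simulates gain/loss counts from the log-linear
#' truth, and realizes a cognate matrix reproducing those counts
#' exactly.  Everything downstream of this call — pair extraction,
#' counting, design construction, model fitting — can then be run
#' through the normal pipeline and compared against `truth`.
#'
#' @param truth a [simTruth()].
#' @param loan_entries passed to [realizeCognateMatrix()].
#' @return list: `truth`, `raw_predictors`, `predictors` (standardized),
#'   `pairs`, `events`, `matrix`, `design`, `newick`.
#' @export
simulateStudy <- function(truth = simTruth(), loan_entries = 0L) {
  n <- truth$n_pairs
  langs_a <- sprintf("L%02da", seq_len(n))
  langs_b <- sprintf("L%02db", seq_len(n))
  raw <- simulatePredictors(2L * n, seed = truth$seed,
                            language_ids = c(langs_a, langs_b))
  set.seed(truth$seed + 1L)
  pairs <- data.frame(
    pair_id = paste(langs_a, langs_b, sep = "--"),
    language_a = langs_a, language_b = langs_b,
    divergence_time = round(stats::runif(n, 500, 2500)),
    support = round(stats::runif(n, 0.85, 1), 3),
    stringsAsFactors = FALSE)
  pairs$pair_path_length <- 2 * pairs$divergence_time
  pairs$shared_nodes <- NA_integer_
  pred <- transformPredictors(raw)
  designX <- buildDesignX(pairs, pred, mode = truth$pairing_mode)
  events <- simulatePairCounts(designX, truth, seed = truth$seed + 2L)
  mat <- realizeCognateMatrix(events, pairs, truth,
                              seed = truth$seed + 3L,
                              loan_entries = loan_entries)
  design <- buildDesign(pairs, pred, events, mode = truth$pairing_mode)
  bg <- setdiff(languageIds(mat), c(langs_a, langs_b))
  nwk <- syntheticNewick(pairs, bg)
  list(truth = truth, raw_predictors = raw, predictors = pred,
       pairs = pairs, events = events, matrix = mat, design = design,
       newick = nwk)
}

#' Predictor-only design rows (no response attached)
#'
#' Same predictor construction as [buildDesign()] but without event
#' counts, for use when counts are yet to be simulated.
#'
#' @inheritParams buildDesign
#' @return data.frame: `pair_id` plus the five predictor columns.
#' @export
buildDesignX <- function(pairs, pred, mode = "pair_mean",
                         focal = "isolation") {
  zero <- data.frame(pair_id = pairs$pair_id,
                     gains_a = 0L, gains_b = 0L, losses_a = 0L,
                     losses_b = 0L, gains = 0L, losses = 0L,
                     turnover = 0L, concepts_used = 0L,
                     stringsAsFactors = FALSE)
  d <- buildDesign(pairs, pred, zero, mode = mode, focal = focal)
  d[setdiff(names(d), c("gains", "losses", "turnover"))]
}

#' Write a loadable synthetic fixture set
#'
#' Serializes a [simulateStudy()] result as the four plain-text inputs
#' the pipeline consumes: wordlist CSV, Newick tree, predictor CSV and a
#' JSON truth record.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtureSet <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(wordlist = file.path(dir, "wordlist.csv"),
             tree = file.path(dir, "tree.nwk"),
             predictors = file.path(dir, "predictors.csv"),
             truth = file.path(dir, "truth.json"))
  writeWordlists(sim$matrix, paths[["wordlist"]])
  writeLines(sim$newick, paths[["tree"]])
  utils::write.csv(sim$raw_predictors, paths[["predictors"]],
                   row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' End-to-end parameter recovery on synthetic data
#'
#' Runs the full pipeline on one synthetic study: simulate, recount the
#' events from the realized cognate matrix, build the design, fit the
#' Poisson model, and compare the posterior to the generating truth.
#' When gains and losses share one coefficient vector the turnover
#' response follows the same log-linear model (sum of two proportional
#' Poisson rates), with intercept
#' `log(exp(alpha_gain) + exp(alpha_loss))`.
#'
#' @param truth a [simTruth()].
#' @param cfg a [samplerConfig()].
#' @param response which count to fit (`"turnover"`, `"gains"`,
#'   `"losses"`).
#' @param models optional named model list; when given,
#'   [compareModels()] is run and its table included.
#' @return list: `fit` (the [PosteriorSummary-class]), `report`
#'   (data.frame per parameter: truth, posterior median, sd, bias,
#'   `covered` by the 90% HPDI, `excludes_zero`), `roundtrip_exact`
#'   (counts from the realized matrix equal the simulated counts),
#'   `comparison` (or `NULL`).
#' @export
endToEndRecovery <- function(truth = simTruth(), cfg = samplerConfig(),
                             response = "turnover", models = NULL) {
  sim <- simulateStudy(truth)
  counted <- tabulateEvents(sim$pairs, sim$matrix)
  cols <- c("gains_a", "gains_b", "losses_a", "losses_b",
            "gains", "losses", "turnover")
  roundtrip <- all(counted[cols] == sim$events[cols])
  design <- buildDesign(sim$pairs, sim$predictors, counted,
                        mode = truth$pairing_mode)
  fit <- fitPoissonGLM(design, response = response, cfg = cfg)
  tv <- .truthVector(truth, response)
  s <- posteriorTable(fit)
  sds <- apply(posteriorDraws(fit), 2, stats::sd)
  report <- data.frame(parameter = s$parameter, truth = tv,
                       median = s$median, sd = sds,
                       bias = s$median - tv,
                       covered = s$hpdi_lower <= tv & tv <= s$hpdi_upper,
                       excludes_zero = s$hpdi_lower > 0 | s$hpdi_upper < 0,
                       stringsAsFactors = FALSE, row.names = NULL)
  comparison <- if (!is.null(models))
    compareModels(design, response = response, cfg = cfg,
                  models = models)$table
  list(fit = fit, report = report, roundtrip_exact = roundtrip,
       comparison = comparison, design = design, sim = sim)
}

.truthVector <- function(truth, response) {
  switch(response,
    gains = c(truth$alpha_gain, truth$beta_gain),
    losses = c(truth$alpha_loss, truth$beta_loss),
    turnover = {
      if (!isTRUE(all.equal(truth$beta_gain, truth$beta_loss)))
        c(NA_real_, rep(NA_real_, 5))
      else
        c(log(exp(truth$alpha_gain) + exp(truth$alpha_loss)),
          truth$beta_gain)
    },
    stop("unknown response: ", response))
}
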