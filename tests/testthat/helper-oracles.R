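# Independent oracles and fixture builders shared across the tests.

# Literal brute-force classifier: enumerate every (concept, cognate set)
# observed anywhere in the matrix and apply the three counting rules one
# case at a time, with no set algebra.  Kept deliberately naive so it is
# an independent check on countPairEvents().
oracleCountPairEvents <- function(a, b, mat, background,
                                  concept_scoped = TRUE) {
  e <- wordEntries(mat)
  att <- attestedCells(mat)
  out <- c(gains_a = 0L, gains_b = 0L, losses_a = 0L, losses_b = 0L)
  used <- 0L
  has <- function(lang, concept, k)
    any(e$language == lang & e$concept == concept & e$cognate_set == k)
  for (concept in conceptIds(mat)) {
    if (!(att[a, concept] && att[b, concept])) next
    used <- used + 1L
    sets <- unique(e$cognate_set[e$concept == concept])
    for (k in sets) {
      inA <- has(a, concept, k)
      inB <- has(b, concept, k)
      if (inA == inB) next  # both or neither: uninformative
      inBG <- if (concept_scoped)
        any(vapply(background, function(g) has(g, concept, k), logical(1)))
      else
        any(e$language %in% background & e$cognate_set == k)
      if (inA && !inB) {
        if (inBG) out["losses_b"] <- out["losses_b"] + 1L
        else out["gains_a"] <- out["gains_a"] + 1L
      } else {
        if (inBG) out["losses_a"] <- out["losses_a"] + 1L
        else out["gains_b"] <- out["gains_b"] + 1L
      }
    }
  }
  c(out, gains = unname(out["gains_a"] + out["gains_b"]),
    losses = unname(out["losses_a"] + out["losses_b"]),
    turnover = unname(sum(out)), concepts_used = used)
}

# Small random cognate matrix: a handful of languages and concepts, a
# shared pool of cognate ids per concept (so overlap, uniqueness and
# cross-concept id reuse all occur), some cells unattested and some
# attested but empty.
randomCognateMatrix <- function(n_lang = sample(3:6, 1),
                                n_concepts = sample(2:10, 1)) {
  langs <- paste0("G", seq_len(n_lang))
  concepts <- paste0("c", seq_len(n_concepts))
  pool <- paste0("k", 1:6)
  att <- matrix(FALSE, n_lang, n_concepts,
                dimnames = list(langs, concepts))
  rows <- list()
  for (l in langs) for (cc in concepts) {
    if (stats::runif(1) < 0.85) {
      att[l, cc] <- TRUE
      ns <- sample(0:3, 1, prob = c(0.15, 0.45, 0.30, 0.10))
      if (ns > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          language = l, concept = cc,
          cognate_set = sample(pool, ns), stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows)
  else data.frame(language = character(0), concept = character(0),
                  cognate_set = character(0), stringsAsFactors = FALSE)
  CognateMatrix(entries, languages = langs, concepts = concepts,
                attested = att)
}

# 1-D grid quadrature of the intercept-only Poisson posterior under the
# Normal(0, prior_sd) prior: the independent route to the posterior the
# Metropolis sampler targets.
quadraturePosterior1D <- function(y, prior_sd = 10,
                                  grid = seq(-5, 10, length.out = 20001)) {
  ll <- vapply(grid, function(a) sum(stats::dpois(y, exp(a), log = TRUE)),
               numeric(1))
  lp <- stats::dnorm(grid, 0, prior_sd, log = TRUE) + ll
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- sum(grid * w)
  list(median = grid[which(cumsum(w) >= 0.5)[1]], mean = mu,
       sd = sqrt(sum((grid - mu)^2 * w)))
}

# 2-D grid quadrature for an intercept + one-slope Poisson model.
quadraturePosterior2D <- function(y, x, prior_sd = c(10, 2),
                                  agrid = seq(0, 4, length.out = 401),
                                  bgrid = seq(-2, 2, length.out = 401)) {
  ll <- outer(agrid, bgrid, Vectorize(function(a, b)
    sum(stats::dpois(y, exp(a + b * x), log = TRUE))))
  lp <- ll + outer(stats::dnorm(agrid, 0, prior_sd[1], log = TRUE),
                   stats::dnorm(bgrid, 0, prior_sd[2], log = TRUE), "+")
  w <- exp(lp - max(lp)); w <- w / sum(w)
  marg_b <- colSums(w)
  marg_a <- rowSums(w)
  list(median_a = agrid[which(cumsum(marg_a) >= 0.5)[1]],
       median_b = bgrid[which(cumsum(marg_b) >= 0.5)[1]])
}

# Five-row wordlist file used by the reader tests.
writeToyWordlist <- function(path, dup = FALSE, sep = ",") {
  df <- data.frame(
    language = c("A", "A", "B", "B", "B"),
    concept = c("hand", "five", "hand", "five", "five"),
    form = c("lima", "lima", "rima", "rima", "qima"),
    cognate_set = c("k1", "k2", "k1", "k2", "k9"),
    loan = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  if (dup) df <- rbind(df, df[3, ])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

# Random per-pair event tables for the realization round trip.
randomEventTable <- function(n_pairs, max_count = 15L) {
  r <- function() sample(0:max_count, n_pairs, replace = TRUE)
  ga <- r(); gb <- r(); la <- r(); lb <- r()
  data.frame(pair_id = sprintf("S%02da--S%02db", seq_len(n_pairs),
                               seq_len(n_pairs)),
             gains_a = ga, gains_b = gb, losses_a = la, losses_b = lb,
             gains = ga + gb, losses = la + lb,
             turnover = ga + gb + la + lb,
             stringsAsFactors = FALSE)
}

randomPairFrame <- function(n_pairs) {
  data.frame(pair_id = sprintf("S%02da--S%02db", seq_len(n_pairs),
                               seq_len(n_pairs)),
             language_a = sprintf("S%02da", seq_len(n_pairs)),
             language_b = sprintf("S%02db", seq_len(n_pairs)),
             stringsAsFactors = FALSE)
}
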