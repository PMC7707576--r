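#' Count word gains and losses for one sister pair
#'
#' The counting rules, applied per semantic unit (concept) attested in
#' both sisters, to every cognate set present in exactly one of the two:
#'
#' * the set also occurs, at the same concept, in at least one
#'   background language of the family: the word was inherited from the
#'   pair's common ancestor, so its absence in the other sister is a
#'   **loss** counted against the sister lacking it;
#' * the set occurs in no background language: the word is unique to one
#'   sister and represents a **gain** of a new word since the split.
#'
#' Cognate sets present in both sisters, or absent from both, carry no
#' information on gain or loss and contribute nothing.  Every qualifying
#' cognate set is one event, regardless of concept (synonym cells can
#' yield several events).  Concepts unattested in either sister are
#' skipped: a missing wordlist entry cannot be distinguished from a
#' loss.  Loan entries should be removed first ([filterLoans()]).
#'
#' @param pair one-row data.frame (or list) with `language_a`,
#'   `language_b` (and optionally `pair_id`).
#' @param matrix A [CognateMatrix-class] holding the pair and the
#'   background languages.
#' @param background character vector of background language ids; must
#'   be non-empty (losses are undetectable otherwise) and exclude both
#'   pair members.
#' @param concept_scoped if `TRUE` (default) a background occurrence
#'   only rescues a cognate set at the same concept; if `FALSE` any
#'   occurrence of the set id anywhere in the background counts
#'   (family-wide matching, for sensitivity analysis).
#' @return one-row data.frame: `pair_id`, `gains_a`, `gains_b`,
#'   `losses_a`, `losses_b`, `gains`, `losses`, `turnover`,
#'   `concepts_used`.
#' @export
countPairEvents <- function(pair, matrix, background,
                            concept_scoped = TRUE) {
  stopifnot(is(matrix, "CognateMatrix"))
  a <- as.character(pair$language_a)
  b <- as.character(pair$language_b)
  background <- as.character(background)
  if (!a %in% matrix@languages) stop("pair language not in matrix: ", a)
  if (!b %in% matrix@languages) stop("pair language not in matrix: ", b)
  if (!length(background))
    stop("background is empty: word losses cannot be detected")
  if (any(c(a, b) %in% background))
    stop("background must exclude the pair members")
  bad_bg <- setdiff(background, matrix@languages)
  if (length(bad_bg))
    stop("background language(s) not in matrix: ",
         paste(bad_bg, collapse = ", "))

  att <- matrix@attested
  shared_concepts <- matrix@concepts[att[a, ] & att[b, ]]
  e <- matrix@entries
  ea <- e[e$language == a & e$concept %in% shared_concepts, , drop = FALSE]
  eb <- e[e$language == b & e$concept %in% shared_concepts, , drop = FALSE]
  # NB: paste0() recycles zero-length inputs against the separator, so
  # empty cells must short-circuit to character(0)
  mkKey <- function(d) if (nrow(d))
    unique(paste0(d$concept, "\r", d$cognate_set)) else character(0)
  keyA <- mkKey(ea)
  keyB <- mkKey(eb)
  onlyA <- setdiff(keyA, keyB)
  onlyB <- setdiff(keyB, keyA)
  ebg <- e[e$language %in% background, , drop = FALSE]
  inBackground <- if (concept_scoped) {
    bgKeys <- mkKey(ebg)
    function(keys) keys %in% bgKeys
  } else {
    bgSets <- unique(ebg$cognate_set)
    function(keys) sub("^.*\r", "", keys) %in% bgSets
  }
  a_inherited <- inBackground(onlyA)  # in a, missing from b -> loss of b
  b_inherited <- inBackground(onlyB)  # in b, missing from a -> loss of a
  gains_a <- sum(!a_inherited)
  gains_b <- sum(!b_inherited)
  losses_b <- sum(a_inherited)
  losses_a <- sum(b_inherited)
  data.frame(
    pair_id = if (!is.null(pair$pair_id)) as.character(pair$pair_id)
              else paste(sort(c(a, b)), collapse = "--"),
    gains_a = gains_a, gains_b = gains_b,
    losses_a = losses_a, losses_b = losses_b,
    gains = gains_a + gains_b, losses = losses_a + losses_b,
    turnover = gains_a + gains_b + losses_a + losses_b,
    concepts_used = length(shared_concepts),
    stringsAsFactors = FALSE)
}

#' Tabulate gain/loss/turnover events for a set of sister pairs
#'
#' Applies [countPairEvents()] to each pair.  Under the default
#' background policy every language in the matrix other than the two
#' pair members serves as background for that pair (so other pairs'
#' languages are part of the family-wide evidence for inheritance).
#'
#' @param pairs data.frame of sister pairs ([extractCherries()] shape);
#'   pairs must be disjoint (no language in two pairs).
#' @param matrix A [CognateMatrix-class].
#' @param background optional explicit character vector of background
#'   ids used for every pair (pair members are excluded per pair
#'   automatically if present); default: all other matrix languages.
#' @param concept_scoped see [countPairEvents()].
#' @return data.frame with one [countPairEvents()] row per pair.
#' @export
tabulateEvents <- function(pairs, matrix, background = NULL,
                           concept_scoped = TRUE) {
  stopifnot(is(matrix, "CognateMatrix"))
  tips <- c(pairs$language_a, pairs$language_b)
  if (anyDuplicated(tips))
    stop("pairs are not disjoint; language(s) in more than one pair: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  empty <- data.frame(pair_id = character(0), gains_a = integer(0),
                      gains_b = integer(0), losses_a = integer(0),
                      losses_b = integer(0), gains = integer(0),
                      losses = integer(0), turnover = integer(0),
                      concepts_used = integer(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    bg <- if (is.null(background))
      setdiff(matrix@languages, c(p$language_a, p$language_b))
    else setdiff(background, c(p$language_a, p$language_b))
    countPairEvents(p, matrix, bg, concept_scoped = concept_scoped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pair-event table
#'
#' CSV with one row per pair: gains, losses, turnover and the number of
#' concepts the count was based on.
#'
#' @param events data.frame from [tabulateEvents()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
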