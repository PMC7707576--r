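makePair <- function(a = "A", b = "B")
  data.frame(pair_id = paste0(a, "--", b), language_a = a, language_b = b,
             stringsAsFactors = FALSE)

# the worked four-language example: A,B sisters; X,Y background
fourLangMatrix <- function() {
  e <- rbind(
    data.frame(language = "A", concept = "c1", cognate_set = c("k1", "k3")),
    data.frame(language = "A", concept = "c2", cognate_set = "k4"),
    data.frame(language = "B", concept = "c1", cognate_set = "k1"),
    data.frame(language = "B", concept = "c2", cognate_set = "k5"),
    data.frame(language = "X", concept = "c1", cognate_set = "k3"),
    data.frame(language = "X", concept = "c2", cognate_set = "k5"))
  att <- matrix(TRUE, 4, 2, dimnames = list(c("A", "B", "X", "Y"),
                                            c("c1", "c2")))
  CognateMatrix(e, languages = c("A", "B", "X", "Y"),
                concepts = c("c1", "c2"), attested = att)
}

test_that("gain, loss and turnover follow the classification rules", {
  ev <- countPairEvents(makePair(), fourLangMatrix(), c("X", "Y"))
  # k3: in A only among sisters, inherited (X has it) -> B lost it
  # k4: unique to A in the whole family -> gain by A
  # k5: in B only, inherited via X -> A lost it
  expect_equal(ev$gains_a, 1L)
  expect_equal(ev$gains_b, 0L)
  expect_equal(ev$losses_a, 1L)
  expect_equal(ev$losses_b, 1L)
  expect_equal(ev$gains, 1L)
  expect_equal(ev$losses, 2L)
  expect_equal(ev$turnover, 3L)
  expect_equal(ev$concepts_used, 2L)
})

test_that("shared and identical vocabularies produce no events", {
  # sisters share the set: uninformative whatever the background holds
  e <- data.frame(language = c("A", "B", "X"), concept = "five",
                  cognate_set = "lima", stringsAsFactors = FALSE)
  m <- CognateMatrix(e)
  ev <- countPairEvents(makePair(), m, "X")
  expect_equal(ev$turnover, 0L)

  set.seed(31)
  m2 <- randomCognateMatrix(n_lang = 4, n_concepts = 6)
  langs <- languageIds(m2)
  # duplicate language 1's rows as a twin: identical presence everywhere
  e2 <- wordEntries(m2)
  twin <- e2[e2$language == langs[1], ]
  twin$language <- "TWIN"
  att <- rbind(attestedCells(m2),
               TWIN = attestedCells(m2)[langs[1], ])
  m3 <- CognateMatrix(rbind(e2, twin), languages = c(langs, "TWIN"),
                      concepts = conceptIds(m2), attested = att)
  ev2 <- countPairEvents(makePair(langs[1], "TWIN"), m3, langs[-1])
  expect_equal(ev2$turnover, 0L)
})

test_that("input contracts are enforced", {
  m <- fourLangMatrix()
  expect_error(countPairEvents(makePair("A", "Z"), m, "X"), "not in matrix")
  expect_error(countPairEvents(makePair(), m, character(0)), "background")
  expect_error(countPairEvents(makePair(), m, c("A", "X")), "exclude")
})

test_that("counting matches the brute-force classifier on random matrices", {
  set.seed(101)
  for (i in 1:250) {
    m <- randomCognateMatrix()
    langs <- languageIds(m)
    bg <- langs[-(1:2)]
    if (!length(bg)) next
    scoped <- i %% 4 != 0  # exercise family-wide matching too
    got <- countPairEvents(makePair(langs[1], langs[2]), m, bg,
                           concept_scoped = scoped)
    want <- oracleCountPairEvents(langs[1], langs[2], m, bg,
                                  concept_scoped = scoped)
    expect_identical(
      unlist(got[c("gains_a", "gains_b", "losses_a", "losses_b",
                   "gains", "losses", "turnover", "concepts_used")],
             use.names = FALSE),
      unname(as.integer(want)))
  }
})

test_that("swapping the sisters mirrors per-branch counts", {
  set.seed(55)
  for (i in 1:25) {
    m <- randomCognateMatrix(n_lang = 5)
    langs <- languageIds(m)
    ab <- countPairEvents(makePair(langs[1], langs[2]), m, langs[3:5])
    ba <- countPairEvents(makePair(langs[2], langs[1]), m, langs[3:5])
    expect_equal(ab$gains_a, ba$gains_b)
    expect_equal(ab$losses_a, ba$losses_b)
    expect_equal(ab$turnover, ba$turnover)
    expect_equal(ab$gains, ba$gains)
  }
})

test_that("adding background never decreases losses nor increases gains", {
  set.seed(77)
  for (i in 1:40) {
    m <- randomCognateMatrix(n_lang = 6)
    langs <- languageIds(m)
    small <- countPairEvents(makePair(langs[1], langs[2]), m, langs[3])
    big <- countPairEvents(makePair(langs[1], langs[2]), m, langs[3:6])
    expect_gte(big$losses, small$losses)
    expect_lte(big$gains, small$gains)
    # a reclassified event stays one event: turnover is unchanged
    expect_equal(big$turnover, small$turnover)
  }
})

test_that("a cognate set present in both sisters changes no counts", {
  set.seed(91)
  tried <- 0L
  for (i in 1:20) {
    m <- randomCognateMatrix(n_lang = 4, n_concepts = 5)
    langs <- languageIds(m)
    att <- attestedCells(m)
    both <- conceptIds(m)[att[langs[1], ] & att[langs[2], ]]
    if (!length(both)) next
    tried <- tried + 1L
    base <- countPairEvents(makePair(langs[1], langs[2]), m, langs[3:4])
    extra <- data.frame(language = langs[1:2], concept = both[1],
                        cognate_set = "SHARED_NEW", form = "",
                        loan = FALSE, stringsAsFactors = FALSE)
    m2 <- CognateMatrix(rbind(wordEntries(m), extra), languages = langs,
                        concepts = conceptIds(m), attested = att)
    after <- countPairEvents(makePair(langs[1], langs[2]), m2, langs[3:4])
    expect_equal(after[c("gains", "losses", "turnover")],
                 base[c("gains", "losses", "turnover")])
  }
  expect_gt(tried, 0L)
})

test_that("tabulation maps pairs to rows and enforces disjointness", {
  ev <- tabulateEvents(makePair(), fourLangMatrix())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$turnover, 3L)  # default background = X and Y

  empty <- tabulateEvents(makePair()[0, ], fourLangMatrix())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gains", "losses", "turnover") %in% names(empty)))

  dup <- rbind(makePair("A", "B"), makePair("A", "X"))
  expect_error(tabulateEvents(dup, fourLangMatrix()), "disjoint")
})
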