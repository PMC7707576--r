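rawTable <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(language = paste0("L", seq_len(n)),
             population = round(stats::rlnorm(n, 10, 1)),
             distance_km = c(0, round(stats::rlnorm(n - 1, 3, 1), 1)),
             conflict_within = sample(1:4, n, TRUE),
             warfare_internal = sample(1:4, n, TRUE),
             warfare_external = sample(1:4, n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("predictor transforms reverse, log and standardize as specified", {
  raw <- rawTable()
  pred <- transformPredictors(raw)
  for (v in predictorNames()) {
    expect_equal(mean(pred[[v]]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(pred[[v]]), 1, tolerance = 1e-9)
  }
  # ordinal 1 (endemic conflict) must land at the high-conflict end
  i_endemic <- which(raw$conflict_within == 1)
  if (length(i_endemic))
    expect_equal(pred$conflictWithin[i_endemic],
                 rep(max(pred$conflictWithin), length(i_endemic)))
  # reversal is 5 - v: a strictly decreasing map of the ordinal
  expect_equal(stats::cor(pred$warfareExternal, raw$warfare_external), -1,
               tolerance = 1e-12)
  # a zero distance maps to log(0 + 1) = 0 before standardization:
  # it must sit at the sample minimum of isolation
  expect_equal(pred$isolation[raw$distance_km == 0],
               min(pred$isolation))
})

test_that("transform validation rejects bad raw values", {
  raw <- rawTable()
  raw$population[2] <- 0
  expect_error(transformPredictors(raw), "population")
  raw <- rawTable()
  raw$conflict_within[3] <- 5L
  expect_error(transformPredictors(raw), "ordinal")
})

test_that("standardization is invariant to rescaling log-variable units", {
  raw <- rawTable(seed = 3)
  p1 <- transformPredictors(raw)
  raw2 <- raw
  raw2$population <- raw2$population * 1000  # a positive rescaling is a
  p2 <- transformPredictors(raw2)            # shift on the log scale
  expect_equal(p1$logPopulation, p2$logPopulation, tolerance = 1e-12)
})

test_that("design construction supports the three pairing modes", {
  raw <- rawTable(n = 6, seed = 9)
  pred <- transformPredictors(raw)
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      language_a = c("L1", "L3", "L5"),
                      language_b = c("L2", "L4", "L6"),
                      stringsAsFactors = FALSE)
  ev <- data.frame(pair_id = pairs$pair_id,
                   gains_a = c(2L, 0L, 4L), gains_b = c(1L, 3L, 0L),
                   losses_a = c(0L, 2L, 1L), losses_b = c(5L, 1L, 1L))
  ev$gains <- ev$gains_a + ev$gains_b
  ev$losses <- ev$losses_a + ev$losses_b
  ev$turnover <- ev$gains + ev$losses

  d <- buildDesign(pairs, pred, ev)
  expect_equal(attr(d, "pairing_mode"), "pair_mean")
  expect_equal(nrow(d), 3L)
  expect_equal(d$logPopulation[1],
               mean(pred$logPopulation[pred$language %in% c("L1", "L2")]))
  expect_equal(d$turnover, ev$turnover)

  d2 <- buildDesign(pairs, pred, ev, mode = "two_row")
  expect_equal(nrow(d2), 6L)
  expect_equal(sum(d2$gains), sum(ev$gains))
  expect_equal(d2$losses[d2$language == "L2"], ev$losses_b[1])

  d3 <- buildDesign(pairs, pred, ev, mode = "signed_contrast")
  expect_true(all(d3$isolation >= 0))

  # two identical sisters under pair_mean keep their common value
  pred2 <- pred; pred2[pred2$language == "L2", -1] <-
    pred2[pred2$language == "L1", -1]
  d4 <- buildDesign(pairs, pred2, ev)
  expect_equal(d4$isolation[1], pred2$isolation[pred2$language == "L1"])

  expect_error(buildDesign(pairs, pred[-1, ], ev), "missing from predictor")
})

test_that("variance inflation matches closed forms and an independent route", {
  n <- 200
  # columns orthonormal AND orthogonal to the intercept (exactly mean 0),
  # so sample correlations are exact: mix two to correlation 0.6
  set.seed(42)
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 3), n, 3))))
  z <- Q[, 2:4]
  x1 <- z[, 1]
  x2 <- 0.6 * z[, 1] + sqrt(1 - 0.36) * z[, 2]
  x3 <- z[, 3]
  d <- data.frame(a = x1, b = x2, c = x3)
  g <- gvif(d, vars = c("a", "b", "c"))
  expect_equal(g$gvif[g$predictor == "a"], 1.5625, tolerance = 1e-6)
  expect_equal(g$gvif[g$predictor == "b"], 1.5625, tolerance = 1e-6)
  expect_equal(g$gvif[g$predictor == "c"], 1, tolerance = 1e-6)
  expect_false(any(g$flagged))
  expect_true(all(g$gvif >= 1))

  # orthogonal design: all factors exactly 1
  g0 <- gvif(data.frame(a = z[, 1], b = z[, 2], c = z[, 3]),
             vars = c("a", "b", "c"))
  expect_equal(g0$gvif, rep(1, 3), tolerance = 1e-9)

  # duplicated column: infinite, flagged, no crash
  gdup <- gvif(data.frame(a = x1, b = x1, c = x3), vars = c("a", "b", "c"))
  expect_true(is.infinite(gdup$gvif[1]) && gdup$flagged[1])

  # independent route: car::vif on an lm with the same predictors
  skip_if_not_installed("car")
  fit <- stats::lm(stats::rnorm(n) ~ a + b + c, data = d)
  expect_equal(g$gvif, unname(suppressWarnings(car::vif(fit))),
               tolerance = 1e-8)
})

test_that("correlation matrix agrees with the t transform of r", {
  set.seed(8)
  n <- 50
  x <- stats::rnorm(n)
  y <- 0.99 * x + sqrt(1 - 0.99^2) * stats::rnorm(n)
  d <- data.frame(x = x, y = y, w = stats::rnorm(n))
  cm <- correlationMatrix(d, vars = c("x", "y", "w"))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r, t(cm$r))
  r <- cm$r["x", "y"]
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cm$p["x", "y"], 2 * stats::pt(-abs(t_stat), n - 2),
               tolerance = 1e-12)
  expect_lt(cm$p["x", "y"], 0.05)
  # perfect anticorrelation
  cm2 <- correlationMatrix(data.frame(a = x, b = -x, c = y),
                           vars = c("a", "b", "c"))
  expect_equal(cm2$r["a", "b"], -1)
  w <- testthat::capture_warnings(
    correlationMatrix(data.frame(a = x, b = rep(1, n), c = y),
                      vars = c("a", "b", "c")))
  expect_true(all(grepl("zero-variance", w)) && length(w) >= 1)
})

test_that("chi-square independence test matches hand computation", {
  # perfectly balanced 2x2: no association at all
  a <- rep(c(0, 1), each = 10)
  b <- rep(c(0, 1, 0, 1), each = 5)
  r0 <- suppressWarnings(chisqIndependence(a, b))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 1)
  expect_equal(r0$p, 1)

  # diagonal 2x2: every expected cell is 5, sum (O-E)^2/E = 4 * 25/5
  r1 <- suppressWarnings(chisqIndependence(rep(c("u", "v"), each = 10),
                                           rep(c("u", "v"), each = 10)))
  expect_equal(r1$statistic, 20)
  expect_equal(r1$df, 1)

  # 3x3 uniform: df = (3-1)(3-1)
  g <- expand.grid(a = 1:3, b = 1:3)
  r2 <- suppressWarnings(chisqIndependence(g$a, g$b))
  expect_equal(r2$df, 4)

  # permutation invariance of the statistic
  set.seed(2)
  aa <- sample(1:3, 60, TRUE); bb <- sample(1:4, 60, TRUE)
  s1 <- suppressWarnings(chisqIndependence(aa, bb))$statistic
  relab <- c(3, 1, 2)[aa]
  s2 <- suppressWarnings(chisqIndependence(relab, bb))$statistic
  expect_equal(s1, s2)

  expect_error(chisqIndependence(rep(1, 10), rep(1, 10)), "2 observed")
})
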