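mk_fit <- function(alpha, beta, n = 517) {
  structure(list(alpha = alpha,
                 coefficients = data.frame(term = "TFR", estimate = beta,
                                           se = NA_real_, p = NA_real_),
                 n = n, spec = NULL), class = "panel_fit")
}

test_that("constant covariate series gives a constant reconstruction", {
  f <- mk_fit(2, -0.5)
  s <- data.frame(year = 1950:2010, value = 1.8)
  rec <- reconstruct(s, f, theta = 0.5, spec = list(G = 10L, W = 2L),
                     target_years = 1970:2000)
  expect_equal(length(unique(round(rec$series$value, 12))), 1)
})

test_that("a hand-computed year matches the arithmetic chain exactly", {
  f <- mk_fit(10, -6.1)
  s <- data.frame(year = 1984:1996, value = 2.0)
  rec <- reconstruct(s, f, theta = 0.34, spec = list(G = 20L, W = 5L),
                     target_years = 2010)
  # windowed TFR mean = 2.0; normalized = 10 - 6.1*2 = -2.2
  expect_equal(rec$series$normalized, -2.2, tolerance = 1e-12)
  expect_lt(abs(rec$series$value - (0.34 * (-2.2) + 1)^(1 / 0.34)), 1e-10)
})

test_that("reconstruction is monotone decreasing in TFR for beta < 0, theta > 0", {
  f <- mk_fit(10, -2)
  s <- data.frame(year = 1960:2010,
                  value = seq(4, 1.2, length.out = 51)) # declining TFR
  rec <- reconstruct(s, f, theta = 0.4, spec = list(G = 5L, W = 1L),
                     target_years = 1970:2005)
  # TFR falls over time, so the predicted metric must rise
  expect_true(all(diff(rec$series$value) > 0))
})

test_that("years without full windows are missing, and provenance reproduces output", {
  f <- mk_fit(1, -1)
  s <- data.frame(year = 1990:2010, value = runif(21, 1, 2))
  expect_warning(rec <- reconstruct(s, f, theta = 0.3,
                                    spec = list(G = 15L, W = 2L),
                                    target_years = 2000:2010),
                 "missing")
  expect_true(any(is.na(rec$series$value)))
  pr <- rec$provenance
  f2 <- mk_fit(pr$alpha, pr$beta)
  rec2 <- suppressWarnings(reconstruct(s, f2, theta = pr$theta, spec = pr$spec,
                                       target_years = 2000:2010))
  expect_identical(rec$series, rec2$series)
})
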