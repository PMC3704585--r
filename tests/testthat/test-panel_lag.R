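test_that("lag-smoothing windows follow the closed [j-G-W, j-G+W] rule", {
  w <- lag_window(2010, 20, 5)
  expect_equal(w$from, 1985)
  expect_equal(w$to, 1995)

  s <- data.frame(region = "A", year = 1980:2010, value = 1980:2010)
  # W = 0 is the point lag
  l0 <- lag_smooth(s, G = 3, W = 0, years = 2010)
  expect_equal(l0$value, 2007)
  # mean over the window
  l1 <- lag_smooth(s, G = 20, W = 5, years = 2010)
  expect_equal(l1$value, mean(1985:1995))
  # constant series stays constant
  sc <- transform(s, value = 7)
  expect_true(all(lag_smooth(sc, 4, 2)$value == 7, na.rm = TRUE))
  # incomplete window -> missing
  expect_true(is.na(lag_smooth(s, 25, 5, years = 2005)$value))
})

test_that("lag-smoothing is equivariant to time shifts of the series", {
  set.seed(30)
  s <- data.frame(region = "A", year = 1980:2010, value = rnorm(31))
  # relabelling years forward by s is the same as lagging s more
  shifted <- transform(s, year = year + 4)
  a <- lag_smooth(shifted, G = 6, W = 2, years = 2000:2005)
  b <- lag_smooth(s, G = 10, W = 2, years = 2000:2005)
  expect_equal(a$value, b$value)
})

test_that("biennial interpolation fills single-year gaps only", {
  s <- data.frame(region = "A", year = c(1986, 1988, 1990), value = c(10, 14, 20))
  out <- interpolate_biennial(s)
  expect_equal(out$value[out$year == 1987], 12)
  expect_equal(out$value[out$year == 1988], 14) # observed untouched
  expect_false(1985 %in% out$year) # no extrapolation
  g <- data.frame(region = "A", year = c(1990, 1994), value = c(1, 5))
  expect_warning(out2 <- interpolate_biennial(g), "gaps longer")
  expect_true(all(is.na(out2$value[out2$year %in% 1991:1993])))
})

test_that("panel estimator degenerates to OLS without random effects or AR noise", {
  d <- gen_ar1_panel(40, 50, alpha = 2, beta = -1.5, phi = 0,
                     sigma_nu = 0, sigma_eta = 1, seed = 44)
  f <- suppressWarnings(fit_re_ar1(d, "x"))
  o <- fit_ols(d$y, cbind(x = d$x))
  expect_lt(abs(f$coefficients$estimate - o$coefficients$estimate[2]), 1e-3)
  expect_equal(f$n, 2000)
})

test_that("region-constant shifts move only the intercept", {
  d <- gen_ar1_panel(20, 12, alpha = 1, beta = 2, phi = 0.4,
                     sigma_nu = 0.3, sigma_eta = 0.4, seed = 45)
  f1 <- suppressWarnings(fit_re_ar1(d, "x"))
  d2 <- d
  d2$y <- d2$y + 5
  f2 <- suppressWarnings(fit_re_ar1(d2, "x"))
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f2$alpha - f1$alpha, 5, tolerance = 1e-8)

  # region relabeling leaves estimates unchanged
  d3 <- d
  d3$region <- factor(d3$region,
                      labels = rev(sort(unique(d3$region)))) |> as.character()
  f3 <- suppressWarnings(fit_re_ar1(d3, "x"))
  expect_equal(f3$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f3$phi, f1$phi, tolerance = 1e-10)
})

test_that("short regions are dropped with a warning", {
  d <- gen_ar1_panel(5, 8, 0, 1, 0.3, 0.2, 0.5, seed = 46)
  d <- d[!(d$region == "r01" & d$year > 2001), ] # r01 keeps 2 years
  expect_warning(f <- fit_re_ar1(d, "x"), "r01")
  expect_equal(f$n, 4 * 8)
})

test_that("overall R2 equals the squared fixed-part correlation", {
  d <- gen_ar1_panel(15, 10, 1, -2, 0.3, 0.2, 0.4, seed = 47)
  f <- suppressWarnings(fit_re_ar1(d, "x"))
  fixed <- f$alpha + f$coefficients$estimate * d$x
  expect_equal(overall_r2(f, d, "x"), cor(fixed, d$y)^2, tolerance = 1e-12)
  expect_equal(f$overall_r2, cor(fixed, d$y)^2, tolerance = 1e-12)

  # perfect noiseless fixed part -> 1
  d0 <- d; d0$y <- 2 + 3 * d0$x
  f0 <- suppressWarnings(fit_re_ar1(d0, "x"))
  expect_equal(f0$overall_r2, 1, tolerance = 1e-9)
})

test_that("grid search reports a surface whose maximum is the returned spec", {
  sc <- scenario_config(seed = 52)
  covs <- simulate_covariates(sc)
  lp <- simulate_linear_panel(sc, covs)
  x <- covs$covariates[covs$covariates$variable == "TFR",
                       c("region", "year", "value")]
  gs <- grid_search_lag(lp$panel, x, G_range = 10:20, W_range = 1:3)
  expect_equal(unlist(gs$spec),
               unlist(gs$surface[which.max(gs$surface$r2), c("G", "W")]))
  expect_equal(gs$fit$overall_r2, max(gs$surface$r2, na.rm = TRUE))
  expect_error(grid_search_lag(lp$panel, x, W_range = 0:2), "at least 1")

  # deterministic tie-break: a time-constant covariate makes every (G, W)
  # cell identical, so the smallest G then smallest W must win
  regional <- setNames(seq_len(47) / 10, sort(unique(x$region)))
  xc <- transform(x, value = regional[region])
  gs0 <- grid_search_lag(lp$panel, xc, G_range = 3:5, W_range = 1:2)
  expect_equal(gs0$spec$G, 3)
  expect_equal(gs0$spec$W, 1)
  expect_equal(length(unique(round(gs0$surface$r2, 12))), 1)
})

test_that("wrongly lagged covariates explain less than the true lag", {
  hits <- sapply(1:20, function(s) {
    sc <- scenario_config(seed = 600 + s)
    covs <- simulate_covariates(sc)
    lp <- simulate_linear_panel(sc, covs)
    x <- covs$covariates[covs$covariates$variable == "TFR",
                         c("region", "year", "value")]
    r2_at <- function(G, W) {
      xl <- lag_smooth(x, G, W, years = 2000:2010)
      d <- merge(lp$panel, setNames(xl, c("region", "year", "x")))
      suppressWarnings(fit_re_ar1(d, "x"))$overall_r2
    }
    r2_at(15, 2) > r2_at(8, 2)
  })
  expect_gte(mean(hits), 0.9)
})
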