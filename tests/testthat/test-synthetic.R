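test_that("generators are fully deterministic under the seed", {
  sc <- scenario_config(seed = 77, n_regions = 9, case_years = 2000:2003)
  a <- simulate_covariates(sc)
  b <- simulate_covariates(sc)
  expect_identical(a, b)
  ca <- simulate_catalytic_cases(sc, a)
  cb <- simulate_catalytic_cases(sc, b)
  expect_identical(ca, cb)
  la <- simulate_linear_panel(sc, a)
  lb <- simulate_linear_panel(sc, b)
  expect_identical(la, lb)
  expect_error(scenario_config(), "seed")
})

test_that("TFR trajectories are positive and decline in the ensemble mean", {
  sc <- scenario_config(seed = 3)
  covs <- simulate_covariates(sc)
  tfr <- covs$covariates[covs$covariates$variable == "TFR", ]
  expect_true(all(tfr$value > 0))
  nat <- covs$national_tfr
  expect_lt(mean(tail(nat$value, 5)), mean(head(nat$value, 5)))
  # physician is biennial, exercising interpolation downstream
  phys <- covs$covariates[covs$covariates$variable == "physician", ]
  expect_true(all(phys$year %% 2 == 0))
})

test_that("spatial correlation parameter controls neighboring-region correlation", {
  nb_cor <- function(rho, seeds) {
    vals <- sapply(seeds, function(s) {
      sc <- scenario_config(seed = s, spatial_rho = rho, n_regions = 25)
      covs <- simulate_covariates(sc)
      U <- covs$adjacency
      t5 <- covs$covariates[covs$covariates$variable == "temperature" &
                              covs$covariates$year == 2000, ]
      v <- t5$value[match(rownames(U), t5$region)]
      idx <- which(U == 1 & upper.tri(U), arr.ind = TRUE)
      cor(v[idx[, 1]], v[idx[, 2]])
    })
    mean(vals)
  }
  expect_lt(abs(nb_cor(0, 1:40)), 0.12)
  expect_gt(nb_cor(0.8, 1:40), 0.3)
})

test_that("the linear generator is exact in the noiseless limit and matches
           its AR(1) moments", {
  sc <- scenario_config(seed = 10,
                        truth = list(alpha = 10, beta = c(TFR = -6), phi = 0,
                                     sigma_nu = 0, sigma_eta = 0,
                                     G = 15L, W = 2L))
  covs <- simulate_covariates(sc)
  lp <- simulate_linear_panel(sc, covs)
  d <- merge(lp$panel, lp$truth$design)
  expect_equal(d$y, 10 - 6 * d$TFR, tolerance = 1e-12)

  # sample within-region lag-1 autocorrelation of the AR noise tracks phi
  # (long panels, so the O(1/T) estimator bias is small)
  ac <- sapply(1:40, function(s) {
    sc <- scenario_config(seed = 900 + s, panel_years = 1982:2010,
                          truth = list(alpha = 0, beta = c(TFR = 0), phi = 0.5,
                                       sigma_nu = 0, sigma_eta = 0.5,
                                       G = 15L, W = 2L))
    lp <- simulate_linear_panel(sc)
    by_reg <- split(lp$panel$y, lp$panel$region)
    v <- sapply(by_reg, function(e) sum(e[-1] * e[-length(e)]) / sum(e[-length(e)]^2))
    mean(v)
  })
  expect_lt(abs(mean(ac) - 0.5), 0.06)
})

test_that("the catalytic generator embodies the inverse hazard/mean-age law", {
  expect_equal(mean_age_oracle(1), 1)
  expect_equal(mean_age_oracle(0.25), 4)
  expect_true(all(diff(mean_age_oracle(seq(0.2, 2, 0.1))) < 0))
  expect_error(mean_age_oracle(0), "positive")

  # hard passive-immunity suppression empties the sub-cutoff classes
  sc <- scenario_config(seed = 12, n_regions = 6, case_years = 2000:2004,
                        passive = list(cutoff_months = 6L, protect_prob = 1))
  sim <- simulate_catalytic_cases(sc)
  young <- sim$cases[sim$cases$age_class %in% c("0-2m", "3-5m"), ]
  expect_true(all(young$count == 0))

  # negative slope on the identity link must be caught before sampling
  sc_bad <- scenario_config(seed = 13, n_regions = 4,
                            foi = list(a = 0.1, b = -2, link = "identity",
                                       G = 3L, W = 2L))
  expect_error(simulate_catalytic_cases(sc_bad), "positive")
})
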