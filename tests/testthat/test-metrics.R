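fine <- fine_age_scheme()
coarse <- coarse_age_scheme()

test_that("incidence uses all-ages cases over the 0-4 population", {
  pop <- tiny_pop(20000) # 5 under-5 classes -> denominator 100,000
  cases <- tiny_cases(c("12-14m" = 50))
  expect_equal(crude_incidence(cases, pop)$value, 50)

  # cases at >= 5 years still count in the numerator
  older <- tiny_cases(c("10y+" = 10))
  pop2 <- tiny_pop(40000) # 0-4 population 200,000
  expect_equal(crude_incidence(older, pop2)$value, 5)

  zero <- tiny_cases(c("12-14m" = 0))
  expect_equal(crude_incidence(zero, pop)$value, 0)

  expect_error(crude_incidence(cases, tiny_pop(1, region = "B")),
               "region-year")
})

test_that("direct standardization matches hand-computed rates", {
  # equal age-specific rates r in every class -> 1e5 * r
  pop <- tiny_pop(10000)
  cases <- data.frame(region = "A", year = 2000L,
                      age_class = coarse$label, count = 5)
  out <- age_adjusted_incidence(cases, pop, uniform_standard())
  expect_equal(out$value, 1e5 * 5 / 10000)

  # two-class scheme, rates (1e-4, 3e-4), S = (.5, .5) -> 20 per 100,000
  s2 <- age_scheme(c("young", "old"), c(0, 60), c(60, NA), c(2.5, 7))
  c2 <- data.frame(region = "A", year = 2000L,
                   age_class = c("young", "old"), count = c(1, 3))
  p2 <- data.frame(region = "A", year = 2000L,
                   age_class = c("young", "old"), population = c(10000, 10000))
  st2 <- data.frame(age_class = c("young", "old"), proportion = c(0.5, 0.5))
  expect_equal(age_adjusted_incidence(c2, p2, st2, s2)$value, 20)

  # local structure equal to the standard -> equals the crude all-ages rate
  expect_equal(age_adjusted_incidence(cases, pop, uniform_standard())$value,
               1e5 * sum(cases$count) / sum(pop$population))
})

test_that("crude mean age is the count-weighted midpoint mean", {
  one <- tiny_cases(c("2y6m-2y11m" = 12)) # midpoint 2.75
  expect_equal(crude_mean_age(one)$value, 2.75)

  # counts 10 at midpoint 1.0 y and 30 at midpoint 3.0 y -> 2.5
  s2 <- age_scheme(c("a", "b"), c(6, 18), c(18, NA), c(1, 3))
  c2 <- data.frame(region = "A", year = 2000L, age_class = c("a", "b"),
                   count = c(10, 30))
  expect_equal(crude_mean_age(c2, s2)$value, 2.5)

  # pooling weights by counts, not by years
  c3 <- rbind(data.frame(region = "A", year = 2000L, age_class = "a", count = 10),
              data.frame(region = "A", year = 2001L, age_class = "b", count = 30))
  expect_equal(crude_mean_age(c3, s2, pool_years = TRUE)$value, 2.5)

  # zero cases -> missing, never zero
  expect_true(is.na(crude_mean_age(tiny_cases(c("0-2m" = 0)))$value))

  # bounded by midpoints; monotone when mass shifts older
  set.seed(4)
  for (i in 1:20) {
    cnt <- rpois(19, 3); names(cnt) <- fine$label
    v <- crude_mean_age(tiny_cases(cnt))$value
    if (!is.na(v)) expect_true(v >= 0.125 && v <= 10.5)
  }
})

test_that("adjusted mean age reweights counts by standard/local proportions", {
  # worked two-class example: weights (6.25, 25) -> 1.30
  s2 <- age_scheme(c("a", "b"), c(0, 12), c(12, NA), c(0.5, 1.5))
  c2 <- data.frame(region = "A", year = 2000L, age_class = c("a", "b"),
                   count = c(10, 10))
  p2 <- data.frame(region = "A", year = 2000L, age_class = c("a", "b"),
                   population = c(0.8, 0.2) * 1e5)
  st2 <- data.frame(age_class = c("a", "b"), proportion = c(0.5, 0.5))
  expect_equal(adjusted_mean_age(c2, p2, st2, s2)$value, 1.30)

  # C == S -> reduces to crude mean age (random panels)
  set.seed(9)
  for (i in 1:10) {
    cnt <- rpois(11, 5); names(cnt) <- coarse$label
    cases <- data.frame(region = "A", year = 2000L,
                        age_class = coarse$label, count = cnt)
    st <- uniform_standard()
    pop <- tiny_pop(3000)
    expect_equal(adjusted_mean_age(cases, pop, st)$value,
                 crude_mean_age(cases, coarse)$value)
  }

  # scale invariance of the population proportions
  p3 <- p2; p3$population <- p3$population * 37
  expect_equal(adjusted_mean_age(c2, p3, st2, s2)$value, 1.30)
})

test_that("three-category proportions sum to 100 and split by lower bound", {
  cases <- tiny_cases(c("3-5m" = 5, "4y-4y11m" = 5, "18-20m" = 10))
  pr <- age_category_proportions(cases)
  expect_equal(c(pr$pct_0_5m, pr$pct_6m_2y, pr$pct_3y_plus), c(25, 50, 25))

  tripled <- cases; tripled$count <- tripled$count * 3
  expect_equal(age_category_proportions(tripled)[, 3:5], pr[, 3:5])

  only_young <- tiny_cases(c("0-2m" = 7))
  pr2 <- age_category_proportions(only_young)
  expect_equal(c(pr2$pct_0_5m, pr2$pct_6m_2y, pr2$pct_3y_plus), c(100, 0, 0))

  none <- tiny_cases(c("0-2m" = 0))
  expect_true(is.na(age_category_proportions(none)$pct_0_5m))
})

test_that("age-independent rates make adjusted and crude ages agree, and the
           two incidence measures rank-correlate on near-standard structures", {
  set.seed(31)
  sc <- scenario_config(seed = 31, n_regions = 12, case_years = 2000:2005,
                        passive = list(cutoff_months = 0L, protect_prob = 0))
  sim <- simulate_catalytic_cases(sc)
  agg <- aggregate_to_coarse(sim$cases, sim$scheme)
  crude <- crude_mean_age(agg$cases, sim$coarse)
  adj <- adjusted_mean_age(agg$cases, sim$pop, sim$standard, sim$coarse)
  # pyramids vary only mildly with TFR here: agreement within MC error
  expect_lt(max(abs(crude$value - adj$value), na.rm = TRUE), 0.35)
  expect_gt(cor(crude$value, adj$value, use = "complete.obs"), 0.9)

  ci <- crude_incidence(sim$cases, sim$pop, sim$scheme, sim$coarse)
  ai <- age_adjusted_incidence(agg$cases, sim$pop, sim$standard, sim$coarse)
  expect_gt(cor(ci$value, ai$value, method = "spearman"), 0.9)
})
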