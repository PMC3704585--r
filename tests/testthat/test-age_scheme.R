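test_that("fine scheme has 19 contiguous classes with month-interval midpoints", {
  s <- fine_age_scheme()
  expect_equal(nrow(s), 19)
  expect_equal(s$lower[1], 0)
  expect_true(is.na(s$upper[19]))
  expect_equal(s$midpoint[1], 0.125) # midpoint of [0, 3) months in years
  expect_equal(s$midpoint[19], 10.5)
  expect_true(all(diff(s$midpoint) > 0))
  expect_equal(s$lower[-1], s$upper[-19])

  s15 <- fine_age_scheme(15)
  expect_equal(s15$midpoint[19], 15)
  expect_equal(s15[-19, ], s[-19, ]) # identical apart from the open midpoint
  expect_error(fine_age_scheme(9), "greater than 10")
})

test_that("scheme constructor rejects malformed class sets", {
  expect_error(age_scheme("a", 0, NA, 1), NA) # single open class is fine
  expect_error(age_scheme(c("a", "b"), c(0, 6), c(3, NA), c(0.125, 1)),
               "contiguous")
  expect_error(age_scheme(c("a", "b"), c(0, 3), c(NA, 6), c(0.2, 0.4)),
               "open")
  expect_error(age_scheme(c("a", "b"), c(0, 3), c(3, 6), c(0.2, 0.1)),
               "midpoint")
})

test_that("aggregation to 11 classes conserves counts per region-year", {
  fine <- fine_age_scheme()
  # sub-year classes collapse into <1y
  cases <- tiny_cases(c("0-2m" = 3, "3-5m" = 4, "6-8m" = 2, "9-11m" = 1))
  agg <- aggregate_to_coarse(cases, fine)
  expect_equal(nrow(agg$scheme), 11)
  expect_equal(agg$cases$count[agg$cases$age_class == "<1y"], 10)

  # totals conserved on a random multi-region panel
  set.seed(21)
  big <- expand.grid(region = c("A", "B", "C"), year = 1990:1995,
                     age_class = fine$label, stringsAsFactors = FALSE)
  big$count <- rpois(nrow(big), 7)
  agg2 <- aggregate_to_coarse(big, fine)
  tot_fine <- tapply(big$count, paste(big$region, big$year), sum)
  tot_coarse <- tapply(agg2$cases$count, paste(agg2$cases$region, agg2$cases$year), sum)
  expect_equal(tot_coarse[names(tot_fine)], tot_fine)

  # all-zero panel stays all-zero
  zero <- big; zero$count <- 0
  expect_true(all(aggregate_to_coarse(zero, fine)$cases$count == 0))

  # unknown label rejected
  bad <- rbind(big, data.frame(region = "A", year = 1990,
                               age_class = "nonsense", count = 1))
  expect_error(aggregate_to_coarse(bad, fine), "unknown age-class")
})
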