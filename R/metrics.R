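#' Surveillance metrics from age-stratified case and population panels
#'
#' @description
#' These functions compute the region-by-year epidemiological summaries
#' used throughout the package: incidence over the 0-4-year population,
#' directly age-standardized incidence, crude and demography-adjusted mean
#' patient age, and three-category age proportions. All take long-format
#' panels (`region`, `year`, `age_class`, count/population) and return a
#' metric series (`region`, `year`, `value`), with `NA` for region-years
#' where the metric is undefined (e.g. zero cases): an undefined mean age
#' is reported as missing, never as zero.
#'
#' @name surveillance-metrics
NULL

# sum over a (region, year) grouping, returning a data.frame region/year/value;
# a NA year (pooled panels) forms its own group
.by_region_year <- function(region, year, x, fun = sum) {
  ychr <- ifelse(is.na(year), ".pooled", as.character(year))
  key <- paste(region, ychr, sep = "\r")
  v <- tapply(x, key, fun)
  parts <- strsplit(names(v), "\r", fixed = TRUE)
  ys <- vapply(parts, `[[`, "", 2L)
  data.frame(region = vapply(parts, `[[`, "", 1L),
             year = ifelse(ys == ".pooled", NA_integer_,
                           as.integer(ifelse(ys == ".pooled", "0", ys))),
             value = as.vector(v),
             stringsAsFactors = FALSE)
}

.order_series <- function(df) {
  df <- df[order(df$region, df$year), ]
  rownames(df) <- NULL
  df
}

#' Incidence over the 0-4-year population
#'
#' Annual incidence per 100,000 children aged 0-4 years: cases occurring
#' at *any* age are counted in the numerator, while the denominator is the
#' population below 5 years of age.
#'
#' @param cases case panel (`region`, `year`, `age_class`, `count`) on any
#'   scheme.
#' @param pop population panel (`region`, `year`, `age_class`,
#'   `population`) keyed on `pop_scheme`; classes with an upper bound at or
#'   below 60 months form the denominator.
#' @param scheme the [age_scheme] `cases` is keyed on.
#' @param pop_scheme the [age_scheme] `pop` is keyed on (default coarse).
#' @return Metric series data frame `region`, `year`, `value` (per
#'   100,000 per year).
#' @export
crude_incidence <- function(cases, pop, scheme = fine_age_scheme(),
                            pop_scheme = coarse_age_scheme()) {
  validate_case_panel(cases, scheme)
  validate_population_panel(pop, pop_scheme)
  num <- .by_region_year(cases$region, cases$year, cases$count)
  under5 <- pop_scheme$label[!is.na(pop_scheme$upper) & pop_scheme$upper <= 60]
  p <- pop[pop$age_class %in% under5, ]
  den <- .by_region_year(p$region, p$year, p$population)
  key_n <- paste(num$region, num$year)
  key_d <- paste(den$region, den$year)
  idx <- match(key_n, key_d)
  if (anyNA(idx)) {
    bad <- key_n[is.na(idx)][1L]
    stop("no 0-4-year population for region-year: ", bad)
  }
  d <- den$value[idx]
  if (any(d <= 0)) {
    bad <- key_n[d <= 0][1L]
    stop("zero 0-4-year population for region-year: ", bad)
  }
  out <- data.frame(region = num$region, year = num$year,
                    value = 1e5 * num$value / d,
                    stringsAsFactors = FALSE)
  .order_series(out)
}

#' Directly age-standardized incidence
#'
#' Weights age-specific rates by a fixed standard structure (the direct
#' method): `1e5 * sum_k (N_k / P_k) * S_k` over the scheme's classes.
#'
#' @param cases case panel keyed on `scheme` (typically the coarse scheme,
#'   matching census population resolution).
#' @param pop population panel keyed on the same scheme; every class with
#'   cases must have positive population.
#' @param standard data frame `age_class`, `proportion` (the standard
#'   structure S_k), covering the scheme.
#' @param scheme the shared [age_scheme].
#' @return Metric series `region`, `year`, `value` (per 100,000 per year).
#' @export
age_adjusted_incidence <- function(cases, pop, standard,
                                   scheme = coarse_age_scheme()) {
  validate_case_panel(cases, scheme)
  validate_population_panel(pop, scheme)
  validate_standard(standard, scheme)
  key_c <- paste(cases$region, cases$year, cases$age_class)
  key_p <- paste(pop$region, pop$year, pop$age_class)
  idx <- match(key_c, key_p)
  if (any(is.na(idx) & cases$count > 0)) {
    bad <- key_c[is.na(idx) & cases$count > 0][1L]
    stop("no population for age class with cases: ", bad)
  }
  rate <- ifelse(is.na(idx), 0, cases$count / pop$population[idx])
  s <- standard$proportion[match(cases$age_class, standard$age_class)]
  out <- .by_region_year(cases$region, cases$year, 1e5 * rate * s)
  .order_series(out)
}

#' Crude mean patient age
#'
#' Case-weighted mean of age-class midpoints. With `pool_years = TRUE` the
#' age-stratified counts are first summed over all years per region (the
#' period-pooled variant used for cross-sectional analysis); the result
#' then carries `year = NA`.
#'
#' @inheritParams crude_incidence
#' @param pool_years pool counts over the study period per region before
#'   averaging.
#' @return Metric series `region`, `year`, `value` (years); `NA` value for
#'   groups with zero cases.
#' @export
crude_mean_age <- function(cases, scheme = fine_age_scheme(),
                           pool_years = FALSE) {
  validate_case_panel(cases, scheme)
  mid <- scheme$midpoint[match(cases$age_class, scheme$label)]
  yr <- if (pool_years) rep(NA_integer_, nrow(cases)) else cases$year
  num <- .by_region_year(cases$region, yr, mid * cases$count)
  den <- .by_region_year(cases$region, yr, cases$count)
  out <- data.frame(region = num$region, year = num$year,
                    value = ifelse(den$value > 0, num$value / den$value, NA_real_),
                    stringsAsFactors = FALSE)
  .order_series(out)
}

#' Demography-adjusted mean patient age
#'
#' Mean patient age reweighted to remove the effect of the local age
#' pyramid: class counts are scaled by `S_k / C_ijk`, the ratio of the
#' standard to the local population proportion in each class, before the
#' midpoint average. Where the local structure equals the standard, this
#' reduces to the crude mean age. With `pool_years = TRUE`, counts are
#' summed and population proportions averaged over the period per region.
#'
#' @param cases case panel keyed on `scheme` (coarse, census resolution).
#' @param pop population panel on the same scheme; proportions C_ijk are
#'   computed within the scheme's span and renormalized.
#' @inheritParams age_adjusted_incidence
#' @inheritParams crude_mean_age
#' @return Metric series `region`, `year`, `value` (years).
#' @export
adjusted_mean_age <- function(cases, pop, standard,
                              scheme = coarse_age_scheme(),
                              pool_years = FALSE) {
  validate_case_panel(cases, scheme)
  validate_population_panel(pop, scheme)
  validate_standard(standard, scheme)
  if (pool_years) {
    key <- paste(cases$region, cases$age_class, sep = "\r")
    cnt <- rowsum(cases$count, key)
    parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
    cases <- data.frame(region = vapply(parts, `[[`, "", 1L),
                        year = NA_integer_,
                        age_class = vapply(parts, `[[`, "", 2L),
                        count = as.vector(cnt), stringsAsFactors = FALSE)
    keyp <- paste(pop$region, pop$age_class, sep = "\r")
    pp <- rowsum(pop$population, keyp)
    tab <- table(keyp)
    npp <- as.vector(tab)[match(rownames(pp), names(tab))]
    partsp <- strsplit(rownames(pp), "\r", fixed = TRUE)
    pop <- data.frame(region = vapply(partsp, `[[`, "", 1L),
                      year = NA_integer_,
                      age_class = vapply(partsp, `[[`, "", 2L),
                      population = as.vector(pp) / npp,
                      stringsAsFactors = FALSE)
  }
  tot <- .by_region_year(pop$region, pop$year, pop$population)
  keyt <- paste(pop$region, pop$year)
  prop <- pop$population / tot$value[match(keyt, paste(tot$region, tot$year))]
  key_c <- paste(cases$region, cases$year, cases$age_class)
  key_p <- paste(pop$region, pop$year, pop$age_class)
  idx <- match(key_c, key_p)
  if (any(is.na(idx) & cases$count > 0)) {
    bad <- key_c[is.na(idx) & cases$count > 0][1L]
    stop("no population proportion for age class with cases: ", bad)
  }
  C <- prop[idx]
  if (any(!is.na(C) & C == 0 & cases$count > 0)) {
    bad <- key_c[!is.na(C) & C == 0 & cases$count > 0][1L]
    stop("zero population proportion for age class with cases: ", bad)
  }
  s <- standard$proportion[match(cases$age_class, standard$age_class)]
  w <- ifelse(cases$count > 0, cases$count * s / C, 0)
  mid <- scheme$midpoint[match(cases$age_class, scheme$label)]
  num <- .by_region_year(cases$region, cases$year, mid * w)
  den <- .by_region_year(cases$region, cases$year, w)
  out <- data.frame(region = num$region, year = num$year,
                    value = ifelse(den$value > 0, num$value / den$value, NA_real_),
                    stringsAsFactors = FALSE)
  .order_series(out)
}

#' Three-category age proportions
#'
#' Re-classifies fine-scheme cases into three age categories — 0-5 months,
#' 6 months-2 years, and 3 years and above — and returns the percentage of
#' cases in each per (region, year). Membership is decided by the class
#' lower bound.
#'
#' @inheritParams crude_mean_age
#' @return Data frame `region`, `year`, `pct_0_5m`, `pct_6m_2y`,
#'   `pct_3y_plus`; percentages sum to 100, `NA` when a region-year has no
#'   cases.
#' @export
age_category_proportions <- function(cases, scheme = fine_age_scheme()) {
  validate_case_panel(cases, scheme)
  lw <- scheme$lower[match(cases$age_class, scheme$label)]
  cat3 <- ifelse(lw < 6L, 1L, ifelse(lw < 36L, 2L, 3L))
  tot <- .by_region_year(cases$region, cases$year, cases$count)
  res <- tot[, c("region", "year")]
  keyt <- paste(tot$region, tot$year)
  for (i in 1:3) {
    ci <- .by_region_year(cases$region, cases$year, cases$count * (cat3 == i))
    res[[c("pct_0_5m", "pct_6m_2y", "pct_3y_plus")[i]]] <-
      ifelse(tot$value > 0,
             100 * ci$value[match(keyt, paste(ci$region, ci$year))] / tot$value,
             NA_real_)
  }
  res <- res[order(res$region, res$year), ]
  rownames(res) <- NULL
  res
}
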