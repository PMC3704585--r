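#' Scenario configuration for the synthetic surveillance generator
#'
#' Bundles every knob of the synthetic panels: the panel dimensions (47
#' regions, annual years), declining total-fertility-rate trajectories
#' with regional spread, the TFR-to-hazard link of the catalytic
#' generator, a passive-immunity switch for early infancy, spatially
#' autocorrelated covariate fields, and the ground-truth parameters of the
#' linear panel generator (including the embedded lag spec the grid search
#' is expected to recover). The seed is mandatory: every generated
#' quantity is reproducible from the configuration alone.
#'
#' @param n_regions number of regions (default 47 prefectures).
#' @param years calendar span of the covariate record.
#' @param case_years years with surveillance case data.
#' @param panel_years years of the linear-panel response.
#' @param oldest_midpoint open age-class midpoint in years.
#' @param tfr list: `start` and `end` national TFR levels (linear decline
#'   in expectation across `years`), `sd_region` regional spread,
#'   `sd_year` year-to-year noise.
#' @param spatial_rho autocorrelation of the simultaneous-autoregressive
#'   covariate fields on the region lattice (0 = independent regions).
#' @param foi list: hazard link `lambda = a + b * TFRwin` (`link =
#'   "identity"`) or `exp(a + b * TFRwin)` (`link = "log"`), with the TFR
#'   window `(G, W)` feeding the hazard. The default positive slope
#'   encodes sibling-driven transmission: more children per family, higher
#'   hazard.
#' @param passive list: `cutoff_months` and `protect_prob` — infections
#'   below the cutoff age are suppressed with this probability (maternal
#'   passive immunity; KD is rare below 6 months).
#' @param events_per_region_year expected symptomatic cases per
#'   region-year.
#' @param birth_cohort base births per region-year used to build the
#'   population pyramid (cohort sizes scale with lagged TFR so local age
#'   structure varies with fertility).
#' @param truth list of linear-panel ground truth: `alpha`, named `beta`
#'   per covariate, AR coefficient `phi`, `sigma_nu`, `sigma_eta`, and
#'   the embedded lag spec `G`, `W`.
#' @param seed integer seed (mandatory).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 47L,
                            years = 1965:2010,
                            case_years = 1979:2010,
                            panel_years = 2000:2010,
                            oldest_midpoint = 10.5,
                            tfr = list(start = 2.1, end = 1.3,
                                       sd_region = 0.15, sd_year = 0.12),
                            spatial_rho = 0.5,
                            foi = list(a = 0.05, b = 0.25,
                                       link = "identity", G = 3L, W = 2L),
                            passive = list(cutoff_months = 6L,
                                           protect_prob = 0.8),
                            events_per_region_year = 150,
                            birth_cohort = 20000,
                            truth = list(alpha = 10, beta = c(TFR = -6),
                                         phi = 0.5, sigma_nu = 0.3,
                                         sigma_eta = 0.3, G = 15L, W = 2L),
                            seed) {
  if (missing(seed)) stop("a seed is mandatory in a scenario configuration")
  stopifnot(n_regions >= 2, abs(truth$phi) < 1,
            spatial_rho >= 0, spatial_rho < 1)
  structure(list(n_regions = as.integer(n_regions), years = as.integer(years),
                 case_years = as.integer(case_years),
                 panel_years = as.integer(panel_years),
                 oldest_midpoint = oldest_midpoint, tfr = tfr,
                 spatial_rho = spatial_rho, foi = foi, passive = passive,
                 events_per_region_year = events_per_region_year,
                 birth_cohort = birth_cohort, truth = truth,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# near-square lattice edge list over n nodes
.lattice_edges <- function(n, ids) {
  ncols <- ceiling(sqrt(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% ncols; c <- (i - 1L) %% ncols
    if (c + 1L < ncols && i + 1L <= n) { from <- c(from, i); to <- c(to, i + 1L) }
    if (i + ncols <= n) { from <- c(from, i); to <- c(to, i + ncols) }
  }
  data.frame(from = ids[from], to = ids[to], stringsAsFactors = FALSE)
}

# one spatially autocorrelated field on the lattice: (I - rho Wr)^-1 e
.sar_field <- function(U, rho) {
  n <- nrow(U)
  Wr <- U / pmax(rowSums(U), 1)
  as.vector(solve(diag(n) - rho * Wr, stats::rnorm(n)))
}

#' Simulate regional covariate panels with spatial and temporal structure
#'
#' Generates a lattice adjacency over the regions and seven covariates in
#' the mold of prefecture-level surveillance work — mean temperature,
#' rainfall, physician density (emitted biennially, to exercise
#' interpolation), population density, aged-population percentage,
#' higher-education percentage, and the total fertility rate. Each
#' variable is a spatially autocorrelated regional field (simultaneous
#' autoregression on the lattice) plus a deterministic temporal trend and
#' independent year-to-year noise. TFR declines linearly in expectation
#' from `tfr$start` to `tfr$end` and stays strictly positive.
#'
#' @param config a [scenario_config()].
#' @return List: `covariates` (long data frame `region`, `year`,
#'   `variable`, `value`), `adjacency` (binary matrix), `regions`,
#'   `national_tfr` (data frame `year`, `value`, the regional mean).
#' @export
simulate_covariates <- function(config) {
  set.seed(config$seed)
  n <- config$n_regions
  ids <- sprintf("R%02d", seq_len(n))
  U <- build_adjacency(.lattice_edges(n, ids), ids)
  years <- config$years
  ny <- length(years)
  t01 <- (years - years[1]) / (years[ny] - years[1])
  vars <- list(
    temperature      = list(base = 14,  trend = 0,    sd_f = 2,    sd_t = 0.5,  min = NA),
    rainfall         = list(base = 130, trend = 0,    sd_f = 25,   sd_t = 10,   min = 5),
    physician        = list(base = 120, trend = 60,   sd_f = 15,   sd_t = 4,    min = 20),
    population_density = list(base = 300, trend = 30, sd_f = 150,  sd_t = 5,    min = 20),
    aged_population  = list(base = 8,   trend = 10,   sd_f = 1.5,  sd_t = 0.3,  min = 1),
    higher_education = list(base = 85,  trend = 8,    sd_f = 3,    sd_t = 0.6,  min = 40)
  )
  out <- vector("list", length(vars) + 1L)
  for (vi in seq_along(vars)) {
    v <- vars[[vi]]
    field <- v$sd_f * .sar_field(U, config$spatial_rho)
    val <- outer(field + v$base, v$trend * t01, `+`) +
      matrix(stats::rnorm(n * ny, sd = v$sd_t), n, ny)
    if (!is.na(v$min)) val <- pmax(val, v$min)
    df <- data.frame(region = rep(ids, ny),
                     year = rep(years, each = n),
                     variable = names(vars)[vi],
                     value = as.vector(val), stringsAsFactors = FALSE)
    if (names(vars)[vi] == "physician")  # biennial record
      df <- df[df$year %% 2L == 0L, ]
    out[[vi]] <- df
  }
  tfr_nat <- config$tfr$start + (config$tfr$end - config$tfr$start) * t01
  field <- config$tfr$sd_region * .sar_field(U, config$spatial_rho)
  tfr <- outer(field, tfr_nat, `+`) +
    matrix(stats::rnorm(n * ny, sd = config$tfr$sd_year), n, ny)
  tfr <- pmax(tfr, 0.2)
  out[[length(vars) + 1L]] <- data.frame(
    region = rep(ids, ny), year = rep(years, each = n),
    variable = "TFR", value = as.vector(tfr), stringsAsFactors = FALSE)
  cov <- do.call(rbind, out)
  rownames(cov) <- NULL
  list(covariates = cov, adjacency = U, regions = ids,
       national_tfr = data.frame(year = years, value = colMeans(tfr)))
}

#' Simulate a linear panel response with known ground truth
#'
#' Generates `Y_ij = alpha + sum_v beta_v * X_v,ij(G*, W*) + nu_i +
#' eps_ij` over `panel_years`, where each covariate enters through the
#' embedded lag spec `(G*, W*)`, `nu_i` is a region random effect, and
#' `eps` follows a stationary AR(1) with coefficient `phi`. This is the
#' validation bed for the panel estimator and the lag grid search.
#'
#' @inheritParams simulate_covariates
#' @param covariates output of [simulate_covariates()] (regenerated from
#'   `config` if omitted).
#' @return List: `panel` (data frame `region`, `year`, `y`), `truth`
#'   (generating parameters, per-region effects, the lagged design).
#' @export
simulate_linear_panel <- function(config, covariates = simulate_covariates(config)) {
  tr <- config$truth
  set.seed(config$seed + 1000003L)
  cov <- covariates$covariates
  vars <- names(tr$beta)
  xlag <- NULL
  for (v in vars) {
    s <- cov[cov$variable == v, c("region", "year", "value")]
    xs <- lag_smooth(s, tr$G, tr$W, years = config$panel_years)
    if (anyNA(xs$value))
      stop("lag window precedes the covariate record start for variable ", v)
    names(xs)[names(xs) == "value"] <- v
    xlag <- if (is.null(xlag)) xs else merge(xlag, xs, by = c("region", "year"))
  }
  xlag <- xlag[order(xlag$region, xlag$year), ]
  ids <- covariates$regions
  ny <- length(config$panel_years)
  nu <- stats::rnorm(length(ids), sd = tr$sigma_nu)
  names(nu) <- ids
  eps <- unlist(lapply(ids, function(r) {
    e <- numeric(ny)
    e[1] <- stats::rnorm(1, sd = tr$sigma_eta / sqrt(1 - tr$phi^2))
    for (t in seq_len(ny - 1L))
      e[t + 1L] <- tr$phi * e[t] + stats::rnorm(1, sd = tr$sigma_eta)
    e
  }))
  X <- as.matrix(xlag[, vars, drop = FALSE])
  y <- tr$alpha + as.vector(X %*% tr$beta) + nu[xlag$region] + eps
  panel <- data.frame(region = xlag$region, year = xlag$year, y = y,
                      stringsAsFactors = FALSE)
  list(panel = panel,
       truth = list(params = tr, nu = nu, design = xlag, seed = config$seed))
}

#' Expected mean age at first infection under a constant hazard
#'
#' Under a catalytic model with constant force of infection `lambda`, ages
#' at first infection are exponential and the mean age is `1 / lambda`.
#' This is the inverse-surrogate relation the whole analysis leans on:
#' mean patient age falls as the hazard of contracting the agent rises.
#'
#' @param lambda force of infection per year (> 0).
#' @return Mean age at first infection in years.
#' @export
mean_age_oracle <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("force of infection must be strictly positive")
  1 / lambda
}

#' Simulate case and population panels from a catalytic hazard model
#'
#' The mechanistic generator: each region-year has a force of infection
#' `lambda_ij` linked to its windowed TFR, ages at first infection are
#' exponential with rate `lambda_ij`, infections below the
#' passive-immunity cutoff are suppressed with the configured
#' probability, and surviving events are binned into the 19-class fine
#' age scheme (event counts Poisson around the configured region-year
#' intensity). A matching coarse-scheme population panel is emitted whose
#' cohort sizes scale with the region's lagged TFR, so that the local age
#' pyramid varies with fertility, plus the year-2000 national structure
#' as the standard for direct adjustment.
#'
#' @inheritParams simulate_linear_panel
#' @return List: `cases` (fine-scheme case panel), `pop` (coarse-scheme
#'   population panel), `standard` (data frame `age_class`,
#'   `proportion`), `scheme` (fine), `coarse` (coarse scheme), `truth`
#'   (per-region-year `lambda`, parameters).
#' @export
simulate_catalytic_cases <- function(config, covariates = simulate_covariates(config)) {
  set.seed(config$seed + 2000003L)
  foi <- config$foi
  scheme <- fine_age_scheme(config$oldest_midpoint)
  coarse <- coarse_age_scheme(config$oldest_midpoint)
  tfr <- covariates$covariates[covariates$covariates$variable == "TFR",
                               c("region", "year", "value")]
  win <- lag_smooth(tfr, foi$G, foi$W, years = config$case_years)
  if (anyNA(win$value))
    stop("TFR window precedes the covariate record start")
  lam <- switch(foi$link,
                identity = foi$a + foi$b * win$value,
                log = exp(foi$a + foi$b * win$value),
                stop("unknown FOI link: ", foi$link))
  if (any(lam <= 0))
    stop("force of infection must be positive everywhere; check the link")
  cutoff_y <- config$passive$cutoff_months / 12
  pprot <- config$passive$protect_prob
  nrow_w <- nrow(win)
  counts <- matrix(0L, nrow_w, nrow(scheme))
  for (i in seq_len(nrow_w)) {
    nev <- stats::rpois(1L, config$events_per_region_year)
    if (nev == 0L) next
    ages <- stats::rexp(nev, rate = lam[i])
    if (pprot > 0 && cutoff_y > 0) {
      young <- ages < cutoff_y
      drop <- young & (stats::runif(nev) < pprot)
      ages <- ages[!drop]
    }
    if (!length(ages)) next
    cls <- findInterval(pmin(ages * 12, 1e6), scheme$lower)
    tab <- tabulate(cls, nbins = nrow(scheme))
    counts[i, ] <- tab
  }
  cases <- data.frame(
    region = rep(win$region, each = nrow(scheme)),
    year = rep(win$year, each = nrow(scheme)),
    age_class = rep(scheme$label, nrow_w),
    count = as.integer(t(counts)), stringsAsFactors = FALSE)
  # population pyramid: cohort aged a in year j was born in year j - a and
  # scales with the region's TFR around that birth year
  tfr_lookup <- function(region, yr) {
    yr <- pmax(pmin(yr, max(tfr$year)), min(tfr$year))
    tfr$value[match(paste(region, yr), paste(tfr$region, tfr$year))]
  }
  grid <- unique(win[, c("region", "year")])
  pop_rows <- vector("list", nrow(coarse))
  mean_tfr <- mean(tfr$value)
  for (k in seq_len(nrow(coarse))) {
    a <- k - 1L
    width <- if (k < nrow(coarse)) 1 else 8  # open class spans ~8 cohorts
    coh <- config$birth_cohort * width *
      tfr_lookup(grid$region, grid$year - a) / mean_tfr
    pop_rows[[k]] <- data.frame(region = grid$region, year = grid$year,
                                age_class = coarse$label[k],
                                population = pmax(coh, 1),
                                stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, pop_rows)
  pop <- pop[order(pop$region, pop$year, match(pop$age_class, coarse$label)), ]
  rownames(pop) <- NULL
  std_year <- if (2000L %in% grid$year) 2000L else max(grid$year)
  ps <- pop[pop$year == std_year, ]
  tot <- tapply(ps$population, ps$age_class, sum)[coarse$label]
  standard <- data.frame(age_class = coarse$label,
                         proportion = as.vector(tot) / sum(tot),
                         stringsAsFactors = FALSE)
  truth <- list(lambda = data.frame(region = win$region, year = win$year,
                                    lambda = lam, stringsAsFactors = FALSE),
                foi = foi, passive = config$passive, seed = config$seed)
  list(cases = cases, pop = pop, standard = standard, scheme = scheme,
       coarse = coarse, truth = truth)
}
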