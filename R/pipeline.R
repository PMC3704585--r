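#' Pipeline run configuration
#'
#' Resolved settings for [run_pipeline()]: input paths (or `simulate =
#' TRUE` to generate the default synthetic scenario), stage toggles, the
#' elimination threshold, lag-search ranges, the Box-Cox search interval,
#' and the output directory. The resolved configuration is written beside
#' the outputs of every run.
#'
#' @param simulate generate panels from the synthetic scenario instead of
#'   reading files.
#' @param paths named list of input CSV paths (`cases`, `pop`,
#'   `standard`, `covariates`, `adjacency`, `national`) when `simulate =
#'   FALSE`.
#' @param outdir output directory.
#' @param seed integer seed (drives the synthetic scenario).
#' @param dependents which dependent variables to analyse; subset of
#'   `"incidence"`, `"crude_age"`, `"adjusted_age"`.
#' @param do_crosssection,do_spatial,do_timeseries,do_reconstruct stage
#'   toggles.
#' @param alpha stepwise elimination threshold.
#' @param G_range,W_range lag-search ranges.
#' @param fit_years dependent years for the time-series stage.
#' @param boxcox_interval Box-Cox power search interval.
#' @param normalize apply Box-Cox normalization of dependent variables;
#'   `FALSE` runs the non-normalized sensitivity variant.
#' @param oldest_midpoint open age-class midpoint (years).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, paths = list(),
                            outdir = tempfile("kdrun"),
                            seed = 1L,
                            dependents = c("incidence", "crude_age",
                                           "adjusted_age"),
                            do_crosssection = TRUE, do_spatial = TRUE,
                            do_timeseries = TRUE, do_reconstruct = TRUE,
                            alpha = 0.05, G_range = 0:30, W_range = 1:5,
                            fit_years = 2000:2010,
                            boxcox_interval = c(-5, 15),
                            normalize = TRUE, oldest_midpoint = 10.5) {
  dependents <- match.arg(dependents, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, length(boxcox_interval) == 2L)
  structure(list(simulate = isTRUE(simulate), paths = paths,
                 outdir = outdir, seed = as.integer(seed),
                 dependents = dependents,
                 do_crosssection = isTRUE(do_crosssection),
                 do_spatial = isTRUE(do_spatial),
                 do_timeseries = isTRUE(do_timeseries),
                 do_reconstruct = isTRUE(do_reconstruct),
                 alpha = alpha, G_range = as.integer(G_range),
                 W_range = as.integer(W_range),
                 fit_years = as.integer(fit_years),
                 boxcox_interval = as.numeric(boxcox_interval),
                 normalize = isTRUE(normalize),
                 oldest_midpoint = oldest_midpoint),
            class = "pipeline_config")
}

# period mean of each covariate per region; requires >= 50% year coverage
.period_means <- function(cov, years) {
  cov <- cov[cov$year %in% years & !is.na(cov$value), ]
  out <- lapply(split(cov, cov$variable), function(s) {
    m <- tapply(s$value, s$region, mean)
    nyr <- tapply(s$year, s$region, function(y) length(unique(y)))
    have <- length(unique(s$year))
    cover <- nyr / max(1L, have)
    m[cover < 0.5] <- NA_real_
    data.frame(region = names(m), variable = s$variable[1L],
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.cross_table <- function(fit) {
  cf <- fit$coefficients
  data.frame(variable = cf$term, coefficient = cf$estimate, se = cf$se,
             p = cf$p, r2 = fit$r2, rho = fit$rho, n = fit$n,
             stringsAsFactors = FALSE)
}

# backward elimination for the panel model: covariates enter at their
# fixed (univariate-optimal) lag specs; drop the worst p >= alpha per step
.panel_eliminate <- function(panel, covariates, alpha) {
  keep <- covariates
  repeat {
    if (!length(keep)) return(NULL)
    fit <- suppressWarnings(fit_re_ar1(panel, keep))
    cand <- fit$coefficients
    worst <- which.max(cand$p)
    if (cand$p[worst] < alpha) return(fit)
    keep <- setdiff(keep, cand$term[worst])
  }
}

#' Run the full surveillance regression pipeline
#'
#' Orchestrates the three analyses and the reconstruction on one set of
#' panels: surveillance metrics, Box-Cox normalization, cross-sectional
#' OLS with backward elimination, maximum-likelihood spatial-lag
#' regression with backward elimination, per-covariate lag/smoothing grid
#' search feeding univariate and multivariate random-effect AR(1) panel
#' regressions, and a national backcast from the univariate TFR model.
#' Writes table-shaped CSVs, the R-squared surfaces, the reconstruction
#' series, the resolved configuration, and a JSON manifest (theta values,
#' selected lag specs, seed, row counts) into `config$outdir`. Identical
#' configurations produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fine <- fine_age_scheme(config$oldest_midpoint)
  stage <- "load"
  manifest <- list(package_version = as.character(utils::packageVersion("kdpanel")),
                   seed = config$seed, theta = list(), lag_specs = list(),
                   rows = list())
  on_fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    if (config$simulate) {
      sc <- scenario_config(seed = config$seed,
                            oldest_midpoint = config$oldest_midpoint)
      covs <- simulate_covariates(sc)
      cat_sim <- simulate_catalytic_cases(sc, covs)
      cases <- cat_sim$cases; pop <- cat_sim$pop
      standard <- cat_sim$standard
      cov <- covs$covariates
      U <- covs$adjacency
      national <- covs$national_tfr
    } else {
      p <- config$paths
      cases <- read_case_panel(p$cases, fine)
      pp <- read_population_panel(p$pop, coarse_age_scheme(config$oldest_midpoint),
                                  p$standard)
      pop <- pp$pop; standard <- pp$standard
      cov <- read_covariate_panel(p$covariates)
      regions <- sort(unique(cases$region))
      U <- read_adjacency(p$adjacency, regions)
      national <- if (!is.null(p$national)) read_national_series(p$national)
    }
  }, error = on_fail)

  stage <- "metrics"
  tryCatch({
    coarse <- coarse_age_scheme(config$oldest_midpoint)
    agg <- aggregate_to_coarse(cases, fine)
    metrics <- list(
      incidence = crude_incidence(cases, pop, fine, coarse),
      crude_age = crude_mean_age(cases, fine),
      adjusted_age = adjusted_mean_age(agg$cases, pop, standard, coarse))
    # period-pooled variants for the cross-sectional analyses
    yrs <- sort(unique(cases$year))
    pooled_cases <- stats::aggregate(count ~ region + age_class, cases, sum)
    pooled_cases$year <- 0L
    pooled_cases$count <- pooled_cases$count / length(yrs)
    pooled_pop <- stats::aggregate(population ~ region + age_class, pop, mean)
    pooled_pop$year <- 0L
    pooled <- list(
      incidence = crude_incidence(pooled_cases, pooled_pop, fine, coarse),
      crude_age = crude_mean_age(cases, fine, pool_years = TRUE),
      adjusted_age = adjusted_mean_age(agg$cases, pop, standard, coarse,
                                       pool_years = TRUE))
    for (m in names(metrics)) {
      write_metric_series(metrics[[m]],
                          file.path(config$outdir, paste0("metric_", m, ".csv")))
      manifest$rows[[m]] <- nrow(metrics[[m]])
    }
    props <- age_category_proportions(cases, fine)
    utils::write.csv(props, file.path(config$outdir, "age_category_proportions.csv"),
                     row.names = FALSE, na = "")
  }, error = on_fail)

  region_order <- sort(unique(cases$region))
  if (config$do_crosssection || config$do_spatial) {
    stage <- "crosssection"
    tryCatch({
      pm <- .period_means(cov, yrs)
      vars <- sort(unique(pm$variable))
      Xw <- do.call(cbind, lapply(vars, function(v) {
        s <- pm[pm$variable == v, ]
        s$value[match(region_order, s$region)]
      }))
      colnames(Xw) <- vars
      for (m in config$dependents) {
        dep <- pooled[[m]]
        yv <- dep$value[match(region_order, dep$region)]
        ok <- !is.na(yv) & stats::complete.cases(Xw)
        yok <- yv[ok]; Xok <- Xw[ok, , drop = FALSE]
        if (config$normalize) {
          th <- bc_fit_theta(yok, config$boxcox_interval)
          manifest$theta[[paste0("cross_", m)]] <- th$theta
          yok <- bc_transform(yok, th$theta)
        }
        uni <- do.call(rbind, lapply(vars, function(v)
          .cross_table(fit_ols(yok, Xok[, v, drop = FALSE]))))
        utils::write.csv(uni, file.path(config$outdir,
                                        paste0("cross_univariate_", m, ".csv")),
                         row.names = FALSE, na = "")
        if (config$do_crosssection) {
          be <- suppressWarnings(backward_eliminate(yok, Xok, config$alpha, fit_ols))
          utils::write.csv(.cross_table(be$fit),
                           file.path(config$outdir,
                                     paste0("cross_multivariate_", m, ".csv")),
                           row.names = FALSE, na = "")
        }
        if (config$do_spatial) {
          Uok <- U[region_order, region_order][ok, ok]
          bs <- suppressWarnings(backward_eliminate(yok, Xok, config$alpha,
                                                    fit_spatial_lag, U = Uok))
          utils::write.csv(.cross_table(bs$fit),
                           file.path(config$outdir,
                                     paste0("spatial_multivariate_", m, ".csv")),
                           row.names = FALSE, na = "")
        }
      }
    }, error = on_fail)
  }

  ts_fits <- list()
  if (config$do_timeseries) {
    stage <- "timeseries"
    tryCatch({
      vars <- sort(unique(cov$variable))
      for (m in config$dependents) {
        dep <- metrics[[m]]
        dep <- dep[!is.na(dep$value), ]
        theta_m <- NA_real_
        if (config$normalize) {
          th <- bc_fit_theta(dep$value[dep$year %in% config$fit_years],
                             config$boxcox_interval)
          theta_m <- th$theta
          manifest$theta[[paste0("ts_", m)]] <- th$theta
          dep$y <- bc_transform(dep$value, th$theta)
        } else dep$y <- dep$value
        uni_rows <- list(); specs <- list(); xlags <- list()
        for (v in vars) {
          s <- cov[cov$variable == v, c("region", "year", "value")]
          if (v == "physician") s <- interpolate_biennial(s)
          gs <- grid_search_lag(dep[, c("region", "year", "y")], s,
                                config$G_range, config$W_range,
                                config$fit_years)
          utils::write.csv(gs$surface,
                           file.path(config$outdir,
                                     paste0("surface_", m, "_", v, ".csv")),
                           row.names = FALSE, na = "")
          specs[[v]] <- gs$spec
          cf <- gs$fit$coefficients
          uni_rows[[v]] <- data.frame(variable = v, G = gs$spec$G,
                                      W = gs$spec$W,
                                      coefficient = cf$estimate, p = cf$p,
                                      r2 = gs$fit$overall_r2, n = gs$fit$n,
                                      stringsAsFactors = FALSE)
          xl <- lag_smooth(s, gs$spec$G, gs$spec$W, years = config$fit_years)
          names(xl)[names(xl) == "value"] <- v
          xlags[[v]] <- xl
        }
        uni <- do.call(rbind, uni_rows)
        utils::write.csv(uni, file.path(config$outdir,
                                        paste0("ts_univariate_", m, ".csv")),
                         row.names = FALSE, na = "")
        manifest$lag_specs[[m]] <- specs
        # multivariate: covariates at their univariate-optimal specs
        mv <- dep[, c("region", "year", "y")]
        for (v in vars) {
          xl <- xlags[[v]]
          mv[[v]] <- xl[[v]][match(paste(mv$region, mv$year),
                                   paste(xl$region, xl$year))]
        }
        mv <- mv[mv$year %in% config$fit_years, ]
        mfit <- .panel_eliminate(mv, vars, config$alpha)
        if (!is.null(mfit)) {
          cf <- mfit$coefficients
          mvt <- data.frame(variable = cf$term,
                            G = vapply(cf$term, function(v) specs[[v]]$G, 0L),
                            W = vapply(cf$term, function(v) specs[[v]]$W, 0L),
                            coefficient = cf$estimate, p = cf$p,
                            r2 = mfit$overall_r2, n = mfit$n,
                            stringsAsFactors = FALSE)
          utils::write.csv(mvt, file.path(config$outdir,
                                          paste0("ts_multivariate_", m, ".csv")),
                           row.names = FALSE, na = "")
        }
        if ("TFR" %in% vars) {
          s <- cov[cov$variable == "TFR", c("region", "year", "value")]
          gs <- grid_search_lag(dep[, c("region", "year", "y")], s,
                                config$G_range, config$W_range,
                                config$fit_years)
          ts_fits[[m]] <- list(fit = gs$fit, theta = theta_m)
        }
      }
    }, error = on_fail)
  }

  if (config$do_reconstruct && length(ts_fits) && !is.null(national)) {
    stage <- "reconstruct"
    tryCatch({
      for (m in names(ts_fits)) {
        f <- ts_fits[[m]]
        span <- range(national$year)
        spec <- f$fit$spec
        target <- (span[1] + spec$G + spec$W):(span[2])
        rec <- suppressWarnings(
          reconstruct(national, f$fit,
                      theta = if (is.na(f$theta)) 1 else f$theta,
                      target_years = target))
        utils::write.csv(rec$series,
                         file.path(config$outdir, paste0("reconstruction_", m, ".csv")),
                         row.names = FALSE, na = "")
        manifest$reconstruction[[m]] <- rec$provenance
      }
    }, error = on_fail)
  }

  stage <- "manifest"
  tryCatch({
    cfg_plain <- unclass(config)
    jsonlite::write_json(cfg_plain, file.path(config$outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest$config_hash <- sum(utf8ToInt(paste(
      utils::capture.output(utils::str(cfg_plain)), collapse = "")))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }, error = on_fail)
  invisible(manifest)
}
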