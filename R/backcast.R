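#' Reconstruct a national metric trajectory from a fitted lag model
#'
#' Applies a univariate time-series model fitted on the regional panel to
#' a national covariate series (a deliberate model-transfer step, recorded
#' in the provenance): for each target year the normalized prediction is
#' `alpha + beta * mean(series over [j-G-W, j-G+W])`, which is then mapped
#' back to the original scale by the inverse Box-Cox transform. Only the
#' fixed part of the model is used — random effects and AR noise are
#' excluded — so reconstructed curves are smooth and epidemic-year spikes
#' are not reproduced. Run backwards in time this is a retrograde
#' extrapolation (backcast).
#'
#' @param series national covariate data frame `year`, `value` (e.g. the
#'   nationwide total fertility rate).
#' @param fit a univariate `panel_fit` from [fit_re_ar1()] or
#'   [grid_search_lag()].
#' @param theta Box-Cox power used to normalize the response the model
#'   was fitted on; `NA` if the model was fitted on the raw scale (no
#'   inverse transform is applied, only the floor clamp).
#' @param spec lag spec, a list with `G` and `W`; defaults to `fit$spec`.
#' @param target_years years to reconstruct. Years whose window is not
#'   fully covered by `series` are reported missing with a warning, never
#'   padded.
#' @param floor lower clamp for the inverse transform (default 0;
#'   predictions on the original scale are non-negative).
#' @return An object of class `reconstruction`: data frame `series`
#'   (`year`, `normalized`, `value`) plus a `provenance` list (lag spec,
#'   theta, coefficients, clamp events) sufficient to reproduce the
#'   output exactly.
#' @export
reconstruct <- function(series, fit, theta, spec = fit$spec, target_years,
                        floor = 0) {
  if (is.null(spec)) stop("no lag spec: supply `spec` or use a fit from grid_search_lag()")
  if (nrow(fit$coefficients) != 1L)
    stop("reconstruction requires a univariate fit")
  s <- data.frame(region = "national", year = series$year,
                  value = series$value)
  xl <- lag_smooth(s, spec$G, spec$W, years = target_years)
  if (anyNA(xl$value))
    warning(sum(is.na(xl$value)),
            " target year(s) lack full covariate windows; reported missing")
  beta <- fit$coefficients$estimate[1L]
  normalized <- fit$alpha + beta * xl$value
  clamped <- 0L
  value <- if (is.na(theta)) pmax(normalized, floor) else
    withCallingHandlers(
      bc_inverse(normalized, theta, floor = floor),
      warning = function(w) {
        clamped <<- clamped + 1L
        invokeRestart("muffleWarning")
      })
  out <- data.frame(year = xl$year, normalized = normalized, value = value)
  structure(list(
    series = out,
    provenance = list(spec = spec, theta = theta, alpha = fit$alpha,
                      beta = beta, covariate = fit$coefficients$term[1L],
                      fit_n = fit$n, floor = floor,
                      clamp_events = clamped)),
    class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf(
    "Reconstruction: %d years, G = %d, W = %d, theta = %.3g, beta = %.4g\n",
    nrow(x$series), pr$spec$G, pr$spec$W, pr$theta, pr$beta))
  if (pr$clamp_events > 0)
    cat("note:", pr$clamp_events, "prediction batch(es) clamped at", pr$floor, "\n")
  invisible(x)
}
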