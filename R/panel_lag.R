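#' Lag/smoothing window bounds
#'
#' The distributed-lag transform replaces a covariate at dependent year
#' `j` by its mean over the closed span of calendar years
#' `[j - G - W, j - G + W]`: a lag of `G` years and a smoothing radius of
#' `W` years. For example, dependent year 2010 with `G = 20`, `W = 5`
#' averages the years 1985 through 1995.
#'
#' @param j dependent calendar year(s).
#' @param G lag in whole years (>= 0).
#' @param W smoothing radius in whole years (>= 0).
#' @return Data frame with columns `year`, `from`, `to` (inclusive bounds).
#' @export
lag_window <- function(j, G, W) {
  stopifnot(G >= 0, W >= 0, G == round(G), W == round(W))
  data.frame(year = as.integer(j),
             from = as.integer(j - G - W),
             to = as.integer(j - G + W))
}

#' Lag-and-smooth a covariate panel
#'
#' Applies the `(G, W)` window of [lag_window()] per region: the value at
#' `(region, j)` is the mean of the series over `[j-G-W, j-G+W]`, and is
#' `NA` whenever any year in the window is unavailable (no padding, no
#' partial windows).
#'
#' @param series data frame `region`, `year`, `value` (a `region` column
#'   of one constant value works for a national series).
#' @inheritParams lag_window
#' @param years dependent years at which to evaluate; defaults to the
#'   years present in `series` per region.
#' @return Data frame `region`, `year`, `value` with `NA` for incomplete
#'   windows.
#' @export
lag_smooth <- function(series, G, W, years = NULL) {
  stopifnot(G >= 0, W >= 0, G == round(G), W == round(W))
  out <- lapply(split(series, series$region), function(s) {
    yrs <- if (is.null(years)) sort(unique(s$year)) else as.integer(years)
    span <- range(s$year)
    full <- span[1]:span[2]
    v <- rep(NA_real_, length(full))
    v[match(s$year, full)] <- s$value
    cs <- cumsum(ifelse(is.na(v), 0, v))
    nas <- cumsum(is.na(v))
    from <- yrs - G - W
    to <- yrs - G + W
    ok <- from >= span[1] & to <= span[2]
    i0 <- pmax(match(from, full), 1L)
    i1 <- pmin(match(to, full), length(full))
    val <- rep(NA_real_, length(yrs))
    idx <- which(ok)
    if (length(idx)) {
      a <- i0[idx]; b <- i1[idx]
      lo_n <- numeric(length(a)); lo_s <- numeric(length(a))
      lo_n[a > 1L] <- nas[a[a > 1L] - 1L]
      lo_s[a > 1L] <- cs[a[a > 1L] - 1L]
      n_na <- nas[b] - lo_n
      s_ab <- cs[b] - lo_s
      val[idx] <- ifelse(n_na == 0, s_ab / (b - a + 1L), NA_real_)
    }
    data.frame(region = s$region[1L], year = yrs, value = val,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interpolate a biennial series to annual resolution
#'
#' Fills single-year gaps between observations by the mean of the flanking
#' values (linear interpolation at the midpoint). Observed years are left
#' untouched; no extrapolation beyond the observed endpoints; gaps longer
#' than one year remain missing with a warning.
#'
#' @param series data frame `region`, `year`, `value` (or `year`, `value`
#'   for a single series).
#' @return Annual data frame over each region's observed span.
#' @export
interpolate_biennial <- function(series) {
  if (!"region" %in% names(series)) series$region <- "national"
  obs <- series[!is.na(series$value), ]
  out <- lapply(split(obs, obs$region), function(s) {
    s <- s[order(s$year), ]
    full <- s$year[1L]:s$year[nrow(s)]
    v <- rep(NA_real_, length(full))
    v[match(s$year, full)] <- s$value
    miss <- which(is.na(v))
    fill <- miss[miss > 1L & miss < length(v) & !is.na(v[miss - 1L]) &
                   !is.na(v[miss + 1L])]
    v[fill] <- (v[fill - 1L] + v[fill + 1L]) / 2
    if (anyNA(v))
      warning("region ", s$region[1L],
              ": gaps longer than one year left missing")
    data.frame(region = s$region[1L], year = full, value = v,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# core two-step FGLS for y_ij = a + x_ij b + nu_i + e_ij, e AR(1).
# region: integer codes; rows must be sorted by (region, year), complete.
# Returns minimal list; wrapped by fit_re_ar1().
.re_ar1_core <- function(y, X, region, year) {
  n <- length(y)
  p <- ncol(X)
  # consecutive-pair indicator within region
  prev <- c(NA, seq_len(n - 1L))
  consec <- c(FALSE, region[-1L] == region[-n] & diff(year) == 1L)
  # step 1: within (region-demeaned) OLS for residuals free of nu_i
  ym <- ave(y, region)
  Xm <- X
  for (k in seq_len(p)) Xm[, k] <- ave(X[, k], region)
  yw <- y - ym
  Xw <- X - Xm
  bw <- tryCatch(qr.coef(qr(Xw), yw), error = function(e) rep(0, p))
  bw[is.na(bw)] <- 0
  r <- yw - Xw %*% bw
  # step 2: pooled lag-1 autocorrelation of within residuals, with a
  # small-T bias correction (within-demeaning biases the raw estimate
  # downward by about (1 + 3 phi)/T)
  r1 <- r[consec]; r0 <- r[prev[consec]]
  denom <- sum(r0^2)
  phi_raw <- if (denom > 0) sum(r1 * r0) / denom else 0
  if (!is.finite(phi_raw) || abs(phi_raw) >= 1)
    stop("estimated serial correlation is not stationary (|phi| >= 1)")
  Tbar <- n / length(unique(region))
  phi <- (Tbar * phi_raw + 1) / (Tbar - 3)
  phi <- max(-0.98, min(0.98, phi))
  # step 3: Prais-Winsten quasi-differencing within region runs
  c0 <- rep(1, n)
  ys <- y
  Xs <- X
  first <- !consec
  sc <- sqrt(1 - phi^2)
  ys[first] <- sc * y[first]
  Xs[first, ] <- sc * X[first, , drop = FALSE]
  c0[first] <- sc
  if (any(consec)) {
    i <- which(consec)
    ys[i] <- y[i] - phi * y[i - 1L]
    Xs[i, ] <- X[i, , drop = FALSE] - phi * X[i - 1L, , drop = FALSE]
    c0[i] <- 1 - phi
  }
  Z <- cbind(c0, Xs)
  # step 4: Swamy-Arora variance components on the transformed data
  Zm <- Z
  for (k in seq_len(ncol(Z))) Zm[, k] <- ave(Z[, k], region)
  ysm <- ave(ys, region)
  Nreg <- length(unique(region))
  bww <- tryCatch(qr.coef(qr(Z - Zm), ys - ysm), error = function(e) rep(0, ncol(Z)))
  bww[is.na(bww)] <- 0
  rw <- (ys - ysm) - (Z - Zm) %*% bww
  df_w <- max(n - Nreg - p, 1L)
  s2_e <- sum(rw^2) / df_w
  # between regression on region means
  ug <- !duplicated(region)
  Ti <- as.vector(table(region)[as.character(region[ug])])
  qrB <- qr(Zm[ug, , drop = FALSE])
  bb <- tryCatch(qr.coef(qrB, ysm[ug]), error = function(e) rep(0, ncol(Z)))
  bb[is.na(bb)] <- 0
  rb <- ysm[ug] - Zm[ug, , drop = FALSE] %*% bb
  df_b <- max(Nreg - ncol(Z), 1L)
  s2_b <- sum(rb^2) / df_b
  Th <- Nreg / sum(1 / Ti) # harmonic mean of region lengths
  s2_u <- max(0, s2_b - s2_e / Th)
  # GLS by quasi-demeaning with region-specific shrinkage
  lam_i <- 1 - sqrt(s2_e / (Ti * s2_u + s2_e))
  lam <- lam_i[match(region, region[ug])]
  Zg <- Z - lam * Zm
  yg <- ys - lam * ysm
  qrG <- qr(Zg)
  coef <- qr.coef(qrG, yg)
  if (anyNA(coef)) stop("singular design in panel GLS step")
  eg <- yg - Zg %*% coef
  dfres <- n - ncol(Z)
  s2g <- sum(eg^2) / dfres
  Vg <- chol2inv(qr.R(qrG)) * s2g
  se <- sqrt(diag(Vg))
  pv <- 2 * stats::pt(abs(coef / se), df = dfres, lower.tail = FALSE)
  # overall R2: squared correlation of the fixed part with y (original scale)
  fixed <- coef[1L] + X %*% coef[-1L]
  r2 <- if (stats::sd(fixed) > 0 && stats::sd(y) > 0)
    stats::cor(as.vector(fixed), y)^2 else 0
  list(alpha = coef[1L], beta = coef[-1L], se = se, p = pv, phi = phi,
       phi_raw = phi_raw, sigma2_nu = s2_u, sigma2_eta = s2_e,
       overall_r2 = r2, n = n)
}

# drop regions whose longest run of consecutive years is < min_run
.prep_panel <- function(panel, response, covariates, min_run = 3L) {
  cols <- c("region", "year", response, covariates)
  miss <- setdiff(cols, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  d <- panel[stats::complete.cases(panel[, cols, drop = FALSE]), cols,
             drop = FALSE]
  d <- d[order(d$region, d$year), ]
  runlen <- vapply(split(d$year, d$region), function(yy) {
    if (length(yy) == 0L) return(0L)
    max(tapply(seq_along(yy), cumsum(c(TRUE, diff(yy) != 1L)), length))
  }, integer(1))
  bad <- names(runlen)[runlen < min_run]
  if (length(bad)) {
    warning("dropping regions with fewer than ", min_run,
            " consecutive years: ", paste(bad, collapse = ", "))
    d <- d[!d$region %in% bad, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no usable observations after dropping short regions")
  d
}

#' Random-effect AR(1) panel regression
#'
#' Fits `Y_ij = alpha + X_ij beta + nu_i + eps_ij`, with a region random
#' effect `nu_i` and serially correlated errors
#' `eps_ij = phi * eps_{i,j-1} + eta_ij`, by two-step feasible GLS:
#' a within-region first pass, `phi` from the pooled lag-1 autocorrelation
#' of within residuals (bias-corrected for short panels),
#' Prais-Winsten quasi-differencing within each region's runs of
#' consecutive years, and Swamy-Arora random-effects GLS on the
#' transformed data. Regions contributing fewer than 3 consecutive years
#' are dropped with a warning.
#'
#' @param panel data frame with columns `region`, `year`, the response and
#'   the covariates; incomplete rows are dropped.
#' @param covariates character vector of covariate column names.
#' @param response response column name (default `"y"`).
#' @return An object of class `panel_fit`: `alpha`, `coefficients`
#'   (data frame `term`, `estimate`, `se`, `p`), `phi`, `sigma2_nu`,
#'   `sigma2_eta`, `overall_r2`, `n`, `spec` (attached by
#'   [grid_search_lag()]).
#' @export
fit_re_ar1 <- function(panel, covariates, response = "y") {
  d <- .prep_panel(panel, response, covariates)
  X <- as.matrix(d[, covariates, drop = FALSE])
  core <- .re_ar1_core(d[[response]], X, match(d$region, unique(d$region)),
                       d$year)
  structure(list(
    alpha = unname(core$alpha),
    coefficients = data.frame(term = covariates,
                              estimate = unname(core$beta),
                              se = unname(core$se[-1L]),
                              p = unname(core$p[-1L]),
                              stringsAsFactors = FALSE),
    alpha_se = unname(core$se[1L]),
    phi = core$phi, sigma2_nu = core$sigma2_nu,
    sigma2_eta = core$sigma2_eta,
    overall_r2 = core$overall_r2, n = core$n, spec = NULL),
    class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(sprintf("RE-AR(1) panel fit: n = %d, phi = %.3f, overall R2 = %.3f\n",
              x$n, x$phi, x$overall_r2))
  if (!is.null(x$spec))
    cat(sprintf("lag spec: G = %d, W = %d\n", x$spec$G, x$spec$W))
  cat(sprintf("alpha = %.4g (se %.3g)\n", x$alpha, x$alpha_se))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Overall R-squared of a panel fit
#'
#' The squared correlation between the fixed part `alpha + X beta` and the
#' observed response over complete cases — the conventional "overall"
#' statistic for random-effects panel models. Returns 0 when either
#' vector has zero variance.
#'
#' @param fit a `panel_fit` from [fit_re_ar1()].
#' @inheritParams fit_re_ar1
#' @return A number in \[0, 1\].
#' @export
overall_r2 <- function(fit, panel, covariates = fit$coefficients$term,
                       response = "y") {
  d <- panel[stats::complete.cases(
    panel[, c("region", "year", response, covariates), drop = FALSE]), ]
  X <- as.matrix(d[, covariates, drop = FALSE])
  fixed <- fit$alpha + as.vector(X %*% fit$coefficients$estimate)
  y <- d[[response]]
  if (stats::sd(fixed) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(fixed, y)^2
}

#' Grid search over lag and smoothing radius
#'
#' For a single covariate series, fits the RE-AR(1) model at every
#' combination of lag `G` and smoothing radius `W`, restricting the
#' response to `fit_years`, and selects the combination maximizing the
#' overall R-squared. Smoothing is required (`W >= 1`): at `W = 0` the
#' R-squared-vs-G relationship is unstable. Ties are broken by the
#' smallest `G`, then the smallest `W`. Cells with too few complete cases
#' are skipped and recorded with `NA` in the surface.
#'
#' @param y_panel response panel `region`, `year`, `y` (already
#'   normalized as desired).
#' @param x_series covariate panel `region`, `year`, `value`.
#' @param G_range candidate lags (default 0:30).
#' @param W_range candidate smoothing radii (default 1:5; must be >= 1).
#' @param fit_years dependent years used for selection (default
#'   2000:2010).
#' @param min_n minimum complete cases for a cell to be fitted.
#' @return List with `spec` (list `G`, `W`), `fit` (the selected
#'   `panel_fit`, with `spec` attached), and `surface` (data frame `G`,
#'   `W`, `r2`, `n`).
#' @export
grid_search_lag <- function(y_panel, x_series, G_range = 0:30,
                            W_range = 1:5, fit_years = 2000:2010,
                            min_n = 30L) {
  if (any(W_range < 1)) stop("smoothing radius W must be at least 1")
  yd <- y_panel[!is.na(y_panel$y) & y_panel$year %in% fit_years, ]
  yd <- yd[order(yd$region, yd$year), ]
  regions <- unique(yd$region)
  # region x year value matrix over the covariate's full span, with
  # cumulative sums so any (G, W) window mean is a difference of sums
  span <- range(x_series$year)
  full <- span[1]:span[2]
  V <- matrix(NA_real_, length(regions), length(full),
              dimnames = list(regions, full))
  xs <- x_series[x_series$region %in% regions, ]
  V[cbind(match(xs$region, regions), match(xs$year, full))] <- xs$value
  CS <- t(apply(ifelse(is.na(V), 0, V), 1L, cumsum))
  CN <- t(apply(is.na(V), 1L, cumsum))
  ri <- match(yd$region, regions)
  grid <- expand.grid(W = sort(W_range), G = sort(G_range))[, c("G", "W")]
  grid <- grid[order(grid$G, grid$W), ]
  surface <- data.frame(G = grid$G, W = grid$W, r2 = NA_real_, n = NA_integer_)
  rcode <- match(yd$region, regions)
  best <- NULL; best_r2 <- -Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    G <- grid$G[i]; W <- grid$W[i]
    a <- match(yd$year - G - W, full)
    b <- match(yd$year - G + W, full)
    ok <- !is.na(a) & !is.na(b)
    xv <- rep(NA_real_, nrow(yd))
    if (any(ok)) {
      ia <- a[ok]; ib <- b[ok]; ir <- ri[ok]
      lo_s <- numeric(length(ia)); lo_n <- numeric(length(ia))
      inner <- ia > 1L
      lo_s[inner] <- CS[cbind(ir[inner], ia[inner] - 1L)]
      lo_n[inner] <- CN[cbind(ir[inner], ia[inner] - 1L)]
      s_ab <- CS[cbind(ir, ib)] - lo_s
      n_na <- CN[cbind(ir, ib)] - lo_n
      xv[ok] <- ifelse(n_na == 0, s_ab / (ib - ia + 1L), NA_real_)
    }
    use <- !is.na(xv)
    if (sum(use) < min_n) next
    core <- tryCatch(suppressWarnings(
      .re_ar1_core(yd$y[use], cbind(x = xv[use]), rcode[use], yd$year[use])),
      error = function(e) NULL)
    if (is.null(core)) next
    surface$r2[i] <- core$overall_r2
    surface$n[i] <- core$n
    if (core$overall_r2 > best_r2) { # strict: first (smallest G, W) wins ties
      best_r2 <- core$overall_r2
      best_i <- i
    }
  }
  if (is.na(best_i)) stop("no (G, W) cell had enough complete cases to fit")
  G <- grid$G[best_i]; W <- grid$W[best_i]
  xl <- lag_smooth(x_series, G, W, years = fit_years)
  xv <- xl$value[match(paste(yd$region, yd$year), paste(xl$region, xl$year))]
  d <- data.frame(region = yd$region, year = yd$year, y = yd$y, x = xv,
                  stringsAsFactors = FALSE)
  fit <- suppressWarnings(fit_re_ar1(d, "x"))
  fit$spec <- list(G = G, W = W)
  list(spec = fit$spec, fit = fit, surface = surface)
}
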