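#' Build a binary spatial adjacency matrix from an edge list
#'
#' Elements are 1 where two regions are geographically adjacent (or joined
#' by a bridge/tunnel), 0 otherwise; the matrix is symmetric with a zero
#' diagonal and is used *unstandardized* in the spatial-lag model.
#'
#' @param edges two-column data frame or matrix of region-id pairs; an
#'   optional third column may tag edges (e.g. bridge opening year) and is
#'   ignored here.
#' @param regions character vector fixing the region order of the matrix.
#' @return n x n binary matrix with `regions` as dimnames.
#' @export
build_adjacency <- function(edges, regions) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("empty edge list: the null graph is unusable")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (any(a == b)) stop("self-edges are not allowed")
  unknown <- setdiff(c(a, b), regions)
  if (length(unknown))
    stop("edge endpoints not in region list: ", paste(unknown, collapse = ", "))
  n <- length(regions)
  U <- matrix(0, n, n, dimnames = list(regions, regions))
  U[cbind(match(a, regions), match(b, regions))] <- 1
  U[cbind(match(b, regions), match(a, regions))] <- 1
  U
}

.cross_fit <- function(terms, est, se, p, rho, rho_se, rho_p, r2, n, sigma2,
                       logLik = NA_real_, intercept_only = FALSE) {
  structure(list(
    coefficients = data.frame(term = terms, estimate = est, se = se,
                              p = p, stringsAsFactors = FALSE),
    rho = rho, rho_se = rho_se, rho_p = rho_p,
    r2 = r2, n = n, sigma2 = sigma2, logLik = logLik,
    intercept_only = intercept_only), class = "cross_fit")
}

#' @export
print.cross_fit <- function(x, ...) {
  kind <- if (is.na(x$rho)) "OLS" else "spatial lag (ML)"
  cat(sprintf("Cross-sectional %s fit: n = %d, R2 = %.3f", kind, x$n, x$r2))
  if (!is.na(x$rho)) cat(sprintf(", rho = %.4g", x$rho))
  cat("\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

.check_design <- function(y, X) {
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X are not allowed")
  if (length(y) != nrow(X)) stop("y and X have different numbers of rows")
  if (length(y) <= ncol(X) + 1L)
    stop("need n > p + 1 observations")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):ncol(Xi)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  list(X = X, Xi = Xi, qr = qrX)
}

#' Ordinary least squares cross-sectional fit
#'
#' Classical linear regression of a (normalized) metric on region-level
#' covariates: least-squares coefficients, classical standard errors,
#' t-test p-values, and R-squared.
#'
#' @param y numeric response vector (one value per region).
#' @param X numeric covariate matrix (no intercept column; one is added).
#' @return A `cross_fit` object.
#' @export
fit_ols <- function(y, X) {
  y <- as.numeric(y)
  d <- .check_design(y, X)
  n <- length(y); pp <- ncol(d$Xi)
  beta <- qr.coef(d$qr, y)
  res <- y - d$Xi %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - pp)
  XtXinv <- chol2inv(qr.R(d$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - pp, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  .cross_fit(colnames(d$Xi), as.vector(beta), se, p,
             NA_real_, NA_real_, NA_real_, r2, n, sigma2)
}

# full log-likelihood of the spatial lag model at (beta, rho, log sigma2);
# omega = eigenvalues of symmetric U so log|I - rho U| = sum log(1 - rho w)
.sl_loglik <- function(par, y, Xi, U, omega) {
  p <- ncol(Xi)
  beta <- par[1:p]; rho <- par[p + 1L]; s2 <- exp(par[p + 2L])
  if (any(1 - rho * omega <= 0)) return(-Inf)
  n <- length(y)
  e <- y - rho * (U %*% y) - Xi %*% beta
  sum(log(1 - rho * omega)) - n / 2 * log(2 * pi * s2) - sum(e^2) / (2 * s2)
}

# central-difference Hessian of f at x
.num_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  hs <- pmax(abs(x), 1) * h
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- hs[i]; ej[j] <- hs[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * hs[i] * hs[j])
  }
  H
}

#' Maximum-likelihood spatial-lag regression
#'
#' Fits `Y = rho U Y + X beta + eps` with Gaussian errors by maximizing
#' the log-likelihood concentrated over `rho`, including the Jacobian term
#' `log|I - rho U|`. `rho` is restricted to `(1/omega_min, 1/omega_max)`,
#' with `omega_min < 0 < omega_max` the extreme eigenvalues of the binary
#' adjacency matrix `U` (used raw, not row-standardized). Standard errors
#' are asymptotic, from the observed information of the full likelihood;
#' p-values are two-sided normal. The reported R-squared is the squared
#' correlation between reduced-form fitted values and observations.
#'
#' @inheritParams fit_ols
#' @param U binary adjacency matrix from [build_adjacency()], rows in the
#'   same order as `y`.
#' @param rho_fixed fix `rho` at this value instead of estimating it (e.g.
#'   0 to reproduce OLS); standard errors are then conditional on `rho`.
#' @return A `cross_fit` with `rho`, `rho_se`, `rho_p` filled in.
#' @export
fit_spatial_lag <- function(y, X, U, rho_fixed = NULL) {
  y <- as.numeric(y)
  d <- .check_design(y, X)
  n <- length(y)
  if (!is.matrix(U) || nrow(U) != n || ncol(U) != n)
    stop("U must be an n x n matrix matching y")
  omega <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  wmin <- min(omega); wmax <- max(omega)
  if (wmax <= 0) stop("adjacency matrix has no positive eigenvalue")
  lo <- if (wmin < 0) 1 / wmin else -Inf
  hi <- 1 / wmax
  Xi <- d$Xi; pp <- ncol(Xi)
  Uy <- as.vector(U %*% y)
  conc <- function(rho) {
    z <- y - rho * Uy
    beta <- qr.coef(d$qr, z)
    e <- z - Xi %*% beta
    s2 <- sum(e^2) / n
    sum(log(1 - rho * omega)) - n / 2 * (log(2 * pi * s2) + 1)
  }
  if (is.null(rho_fixed)) {
    eps <- 1e-8 + 1e-6 * (hi - max(lo, -10 * hi))
    lo_s <- max(lo, -1e6) + eps
    opt <- stats::optimize(conc, c(lo_s, hi - eps), maximum = TRUE, tol = 1e-9)
    rho <- opt$maximum
    if (rho > hi - 10 * eps || rho < lo_s + 10 * eps)
      warning("rho estimate is at the boundary of the admissible interval")
  } else {
    if (rho_fixed <= lo || rho_fixed >= hi)
      stop("rho_fixed outside the admissible interval")
    rho <- rho_fixed
  }
  z <- y - rho * Uy
  beta <- as.vector(qr.coef(d$qr, z))
  e <- z - Xi %*% beta
  s2 <- sum(e^2) / n
  ll <- sum(log(1 - rho * omega)) - n / 2 * (log(2 * pi * s2) + 1)
  if (is.null(rho_fixed)) {
    par <- c(beta, rho, log(s2))
    H <- .num_hessian(function(p) .sl_loglik(p, y, Xi, U, omega), par)
    V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, pp + 2, pp + 2))
    se <- sqrt(pmax(diag(V)[1:pp], 0))
    rho_se <- sqrt(max(diag(V)[pp + 1L], 0))
  } else {
    # conditional on rho: classical OLS covariance on the filtered response
    sigma2_u <- sum(e^2) / (n - pp)
    XtXinv <- chol2inv(qr.R(d$qr))
    se <- sqrt(sigma2_u * diag(XtXinv))
    rho_se <- NA_real_
  }
  pv <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  rho_p <- if (is.na(rho_se) || rho_se == 0) NA_real_ else
    2 * stats::pnorm(abs(rho / rho_se), lower.tail = FALSE)
  fitted <- tryCatch(solve(diag(n) - rho * U, Xi %*% beta),
                     error = function(e) rep(NA_real_, n))
  r2 <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
    stats::cor(as.vector(fitted), y)^2 else 0
  .cross_fit(colnames(Xi), beta, se, pv, rho, rho_se, rho_p, r2, n, s2, ll)
}

#' Backward stepwise elimination of non-significant covariates
#'
#' Starting from the full model, repeatedly refits after removing the
#' single covariate with the largest p-value at or above `alpha`, until
#' every retained covariate is significant or none remain. The intercept
#' is never a candidate for removal.
#'
#' @inheritParams fit_ols
#' @param alpha significance threshold for retention (default 0.05).
#' @param fitter fitting function, [fit_ols] or [fit_spatial_lag].
#' @param ... further arguments passed to `fitter` (e.g. `U`).
#' @return List with `fit` (final `cross_fit`; intercept-only and flagged
#'   if everything was eliminated), `retained` (covariate names), and
#'   `trace` (data frame of elimination steps).
#' @export
backward_eliminate <- function(y, X, alpha = 0.05, fitter = fit_ols, ...) {
  stopifnot(alpha > 0, alpha < 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- colnames(X)
  trace <- data.frame(step = integer(), dropped = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(keep) == 0L) {
      fit <- fitter(y, matrix(numeric(0), nrow = length(y), ncol = 0), ...)
      fit$intercept_only <- TRUE
      warning("all covariates eliminated; returning intercept-only fit")
      return(list(fit = fit, retained = character(0), trace = trace))
    }
    fit <- tryCatch(fitter(y, X[, keep, drop = FALSE], ...),
                    error = function(e)
                      stop("fitter failed with covariates {",
                           paste(keep, collapse = ", "), "}: ",
                           conditionMessage(e)))
    cf <- fit$coefficients
    cand <- cf[cf$term %in% keep, ]
    worst <- which.max(cand$p)
    if (cand$p[worst] < alpha)
      return(list(fit = fit, retained = keep, trace = trace))
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = cand$term[worst],
                                     p = cand$p[worst]))
    keep <- setdiff(keep, cand$term[worst])
  }
}
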