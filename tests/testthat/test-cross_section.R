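test_that("adjacency construction is symmetric, binary, and strict about input", {
  U <- build_adjacency(data.frame(from = "A", to = "B"), c("A", "B", "C"))
  expect_equal(sum(U), 2)
  expect_equal(U["A", "B"], 1)
  expect_equal(U["B", "A"], 1)
  expect_true(all(diag(U) == 0))
  expect_error(build_adjacency(data.frame(from = character(), to = character()),
                               c("A", "B")), "empty")
  expect_error(build_adjacency(data.frame(from = "A", to = "A"), c("A", "B")),
               "self-edge")
  expect_error(build_adjacency(data.frame(from = "A", to = "Z"), c("A", "B")),
               "not in region list")

  # adding bridge edges changes only the named pairs
  U2 <- build_adjacency(data.frame(from = c("A", "B"), to = c("B", "C")),
                        c("A", "B", "C"))
  d <- U2 - U
  expect_equal(sum(d != 0), 2)
  expect_equal(d["B", "C"], 1)
})

test_that("OLS reproduces exact linear data and reports bookkeeping", {
  x <- 1:20
  fit <- fit_ols(2 * x + 1, cbind(x = x))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n, 20)

  # residual orthogonality to the design
  set.seed(3)
  X <- scale(matrix(rnorm(47 * 3), 47))
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(47)
  f <- fit_ols(y, X)
  res <- y - cbind(1, X) %*% f$coefficients$estimate
  expect_lt(max(abs(t(X) %*% res)), 1e-8)
  expect_equal(f$n, 47)

  expect_error(fit_ols(y, cbind(a = X[, 1], b = X[, 1])), "collinear")
})

test_that("null slopes give uniform-ish p-values and small estimates", {
  set.seed(17)
  ps <- replicate(200, {
    x <- rnorm(100); y <- rnorm(100)
    fit_ols(y, cbind(x = x))$coefficients$p[2]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.1)
})

test_that("backward elimination drops noise and keeps signal", {
  set.seed(23)
  keep_true <- logical(100); drop_noise <- logical(100)
  for (s in 1:100) {
    x <- rnorm(200)
    N <- matrix(rnorm(200 * 3), 200, 3)
    X <- cbind(signal = x, n1 = N[, 1], n2 = N[, 2], n3 = N[, 3])
    y <- 3 * x + rnorm(200)
    be <- suppressWarnings(backward_eliminate(y, X))
    keep_true[s] <- "signal" %in% be$retained
    drop_noise[s] <- !any(c("n1", "n2", "n3") %in% be$retained)
  }
  expect_gte(mean(keep_true), 0.9)
  expect_gt(mean(drop_noise), 0.7) # each noise column survives w.p. ~ alpha

  # all significant at the first fit -> unchanged
  set.seed(5)
  x1 <- rnorm(100); x2 <- rnorm(100)
  y <- 2 * x1 - 3 * x2 + rnorm(100, sd = 0.5)
  be <- backward_eliminate(y, cbind(x1 = x1, x2 = x2))
  expect_setequal(be$retained, c("x1", "x2"))
  expect_equal(nrow(be$trace), 0)

  # collinear design propagates the fitter error with context
  expect_error(backward_eliminate(y, cbind(a = x1, b = x1)), "fitter failed")

  # pure noise -> intercept-only fit, flagged
  set.seed(6)
  expect_warning(be0 <- backward_eliminate(rnorm(60), cbind(z = rnorm(60))),
                 "intercept-only")
  expect_true(be0$fit$intercept_only)
})

test_that("retained set is invariant to column order for distinct p-values", {
  set.seed(41)
  X <- matrix(rnorm(150 * 4), 150, 4)
  colnames(X) <- c("a", "b", "c", "d")
  y <- 1.5 * X[, 1] - 0.8 * X[, 3] + rnorm(150)
  r1 <- suppressWarnings(backward_eliminate(y, X))$retained
  perm <- c("d", "b", "a", "c")
  r2 <- suppressWarnings(backward_eliminate(y, X[, perm]))$retained
  expect_setequal(r1, r2)
})

test_that("spatial lag at rho = 0 coincides with OLS, and scaling U rescales rho", {
  U <- lattice47()
  set.seed(12)
  x <- rnorm(47)
  y <- 1 + 2 * x + rnorm(47)
  f0 <- fit_spatial_lag(y, cbind(x = x), U, rho_fixed = 0)
  fo <- fit_ols(y, cbind(x = x))
  expect_lt(max(abs(f0$coefficients$estimate - fo$coefficients$estimate)), 1e-6)

  set.seed(13)
  ysp <- solve(diag(47) - 0.1 * U, 1 + 2 * x + rnorm(47))
  f1 <- fit_spatial_lag(ysp, cbind(x = x), U)
  f2 <- fit_spatial_lag(ysp, cbind(x = x), 2 * U)
  expect_equal(f2$rho, f1$rho / 2, tolerance = 1e-4)

  # log-likelihood is at an interior local maximum
  omega <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  ll <- function(rho) {
    z <- ysp - rho * U %*% ysp
    b <- qr.coef(qr(cbind(1, x)), z)
    s2 <- mean((z - cbind(1, x) %*% b)^2)
    sum(log(1 - rho * omega)) - 47 / 2 * (log(2 * pi * s2) + 1)
  }
  expect_gte(ll(f1$rho), ll(f1$rho + 0.01))
  expect_gte(ll(f1$rho), ll(f1$rho - 0.01))
})

test_that("spatial autoregressive parameter is recovered without spatial signal", {
  U <- lattice47()
  set.seed(19)
  rhos <- replicate(40, {
    x <- rnorm(47)
    y <- 1 + 2 * x + rnorm(47) # rho = 0
    fit_spatial_lag(y, cbind(x = x), U)$rho
  })
  expect_lt(abs(mean(rhos)), 0.02)
})
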