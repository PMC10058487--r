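test_that("one-column proportional response is fitted exactly", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- 2 * x
  f <- fit_pls(x, y, 1)
  expect_equal(predict(f, x), y, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(drop(f$coefficients), 2, tolerance = 1e-12)
})

test_that("full-rank PLS reproduces the OLS oracle", {
  for (seed in 1:5) {
    d <- random_xy(n = 10, p = 3, noise = 0, seed = seed)
    f <- fit_pls(d$X, d$Y, 3)
    expect_equal(predict(f, d$X), ols_predict(d$X, d$Y),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # and for a multivariate response (PLS2)
  d <- random_xy(n = 20, p = 4, q = 3, noise = 0.5, seed = 9)
  f <- fit_pls(d$X, d$Y, 4)
  expect_equal(predict(f, d$X), ols_predict(d$X, d$Y),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("scores are orthogonal and training evar is monotone in ncomp", {
  d <- random_xy(n = 30, p = 6, q = 2, noise = 1, seed = 11)
  f <- fit_pls(d$X, d$Y, 5)
  G <- crossprod(f$T)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  evs <- vapply(1:5, function(a)
    explained_variance_fraction(d$Y, predict(f, d$X, ncomp = a)), 0)
  expect_true(all(diff(evs) >= -1e-12))
})

test_that("fitting is invariant to joint row permutation", {
  d <- random_xy(n = 25, p = 4, noise = 0.4, seed = 7)
  perm <- withr::with_seed(8, sample(25))
  f1 <- fit_pls(d$X, d$Y, 3)
  f2 <- fit_pls(d$X[perm, ], d$Y[perm, , drop = FALSE], 3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("a response orthogonal to X stops early with zero coefficients", {
  X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  y <- c(1, -1, -1, 1)  # orthogonal to both columns, zero mean
  f <- expect_silent(fit_pls(X, y, 2))
  expect_identical(f$n_components, 0L)
  expect_true(f$early_stop)
  expect_equal(unname(predict(f, X)), matrix(0, 4, 1), tolerance = 1e-12)
})

test_that("prediction respects centering and shape contracts", {
  d <- random_xy(n = 15, p = 3, noise = 0.2, seed = 5)
  f <- fit_pls(d$X, d$Y, 2)
  expect_equal(drop(predict(f, matrix(f$x_means, 1))), unname(f$y_means),
               tolerance = 1e-10)
  expect_equal(dim(predict(f, d$X[1, , drop = FALSE])), c(1L, 1L))
  expect_error(predict(f, d$X[, 1:2]), "columns")
})

test_that("explained-variance fraction matches its definition and edge cases", {
  d <- random_xy(n = 12, p = 2, noise = 1, seed = 3)
  expect_equal(explained_variance_fraction(d$Y, d$Y), 1)
  mu <- matrix(rep(colMeans(d$Y), each = 12), 12)
  expect_equal(explained_variance_fraction(d$Y, mu), 0)
  expect_error(explained_variance_fraction(mu, mu), "zero total variance")
  # unidimensional standardized training fit equals the squared correlation
  withr::with_seed(21, { x <- scale(rnorm(80)); y <- scale(0.7 * x + rnorm(80)) })
  f <- fit_pls(x, y, 1)
  expect_equal(explained_variance_fraction(y, predict(f, x)),
               cor(x, y)[1]^2, tolerance = 1e-10)
})

test_that("VIP matches a direct formula oracle and separates signal from noise", {
  withr::with_seed(13, {
    x1 <- rnorm(60); x2 <- rnorm(60)
    y <- x1 + rnorm(60, sd = 0.1)
  })
  f <- fit_pls(cbind(x1, x2), y, 1)
  v <- vip(f)
  expect_gt(v[["x1"]], 1)
  expect_lt(v[["x2"]], 1)
  # independent re-implementation from the stored W, T, Q
  vip_oracle <- function(m) {
    p <- nrow(m$W); a <- m$n_components
    ssy <- vapply(seq_len(a), function(j)
      sum(m$Q[, j]^2) * sum(m$T[, j]^2), 0)
    sapply(seq_len(p), function(jv) {
      num <- sum(vapply(seq_len(a), function(j)
        ssy[j] * (m$W[jv, j] / sqrt(sum(m$W[, j]^2)))^2, 0))
      sqrt(p * num / sum(ssy))
    })
  }
  d <- random_xy(n = 40, p = 7, q = 2, noise = 0.7, seed = 17)
  f2 <- fit_pls(d$X, d$Y, 3)
  expect_equal(unname(vip(f2)), vip_oracle(f2), tolerance = 1e-12)
})

test_that("VIP is invariant to positive column rescaling at fixed scaling", {
  d <- random_xy(n = 30, p = 5, noise = 0.5, seed = 19)
  X <- apply(d$X, 2, function(col) col / sd(col))
  f1 <- fit_pls(X, d$Y, 2)
  # rescale a column, re-apply unit-variance scaling: same VIP
  X2 <- X; X2[, 3] <- 5 * X2[, 3]
  X2 <- apply(X2, 2, function(col) col / sd(col))
  f2 <- fit_pls(X2, d$Y, 2)
  expect_equal(vip(f1), vip(f2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fitted values and VIP agree with mixOmics as external reference", {
  d <- random_xy(n = 30, p = 8, noise = 0.5, seed = 1)
  colnames(d$X) <- paste0("x", 1:8)
  f <- fit_pls(d$X, d$Y, 3)
  m <- mixOmics::pls(d$X, d$Y, ncomp = 3, scale = FALSE, mode = "regression")
  pm <- predict(m, d$X)$predict[, , 3]
  expect_equal(drop(predict(f, d$X)), unname(pm), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(vip(f)), unname(mixOmics::vip(m)[, 3]),
               tolerance = 1e-8)
})
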