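# Shared fixture builders. Everything is generated in code; no stored data.

# A small block with known values.
tiny_block <- function(values, ids = NULL) {
  values <- as.matrix(values)
  data_block(values,
             sample_ids = ids %||% paste0("s", seq_len(nrow(values))),
             variable_ids = paste0("v", seq_len(ncol(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random regression problem with controllable noise.
random_xy <- function(n, p, q = 1, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(p * q), p, q)
    Y <- X %*% B + matrix(rnorm(n * q, sd = noise), n, q)
    list(X = X, Y = Y)
  })
}

# OLS predictions via the normal equations on centered data: the
# independent oracle for full-rank PLS.
ols_predict <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  fit <- Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc))
  sweep(fit, 2, colMeans(as.matrix(Y)), "+")
}

# Lightweight CV settings for unit tests (the protocol defaults k = 10,
# repeats = 50 are exercised in the acceptance suite).
quick_cv <- function(seed = 1, ...) {
  cv_config(k = 5, repeats = 5, seed = seed, max_components = 4, ...)
}

# Empirical unidimensional oracle: squared correlation and squared partial
# correlation computed directly from the sample.
empirical_uni_effects <- function(a, b, cc) {
  r_ac <- stats::cor(a, cc); r_ab <- stats::cor(a, b); r_bc <- stats::cor(b, cc)
  list(global = r_ac^2,
       partial = ((r_ac - r_ab * r_bc) / sqrt((1 - r_ab^2) * (1 - r_bc^2)))^2)
}
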