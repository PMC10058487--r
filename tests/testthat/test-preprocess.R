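test_that("zero replacement substitutes a fraction of the positive minimum", {
  b <- tiny_block(cbind(c(0, 5, 10), c(3, 5, 10)))
  out <- replace_zeros(b, 0.8)
  expect_equal(out$values[, 1], c(s1 = 4, s2 = 5, s3 = 10))
  expect_equal(out$values[, 2], c(s1 = 3, s2 = 5, s3 = 10))
  expect_identical(out$provenance, "zeros_replaced")
  # the minimum is taken over strictly positive entries, not the zeros
  b2 <- tiny_block(matrix(c(0, 0, 2, 8), ncol = 1))
  expect_equal(replace_zeros(b2, 0.5)$values[, 1],
               c(s1 = 1, s2 = 1, s3 = 2, s4 = 8))
  expect_error(replace_zeros(tiny_block(matrix(c(0, 0, 0), ncol = 1))),
               "all-zero")
  expect_error(replace_zeros(tiny_block(matrix(c(-1, 2), ncol = 1))),
               "non-negative")
})

test_that("log transform is exact and rejects non-positive entries", {
  b <- tiny_block(matrix(c(1, exp(1), exp(2)), ncol = 1))
  expect_equal(unname(log_transform(b)$values[, 1]), c(0, 1, 2))
  expect_equal(unname(log_transform(tiny_block(matrix(100)), base = 10)$values),
               matrix(2))
  expect_error(log_transform(tiny_block(matrix(c(0, 1), ncol = 1))),
               "non-positive entry")
})

test_that("zero replacement then log is total on non-negative input", {
  withr::with_seed(4, {
    x <- matrix(rexp(60), 12, 5)
    x[sample(60, 8)] <- 0
  })
  out <- log_transform(replace_zeros(tiny_block(x)))
  expect_true(all(is.finite(out$values)))
  expect_identical(out$provenance, c("zeros_replaced", "log"))
})

test_that("unit-variance scaling yields unit column variances, idempotently", {
  withr::with_seed(2, b <- tiny_block(matrix(rnorm(40, sd = 7), 10, 4)))
  s1 <- scale_unit_variance(b)
  expect_equal(unname(apply(s1$values, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # columns are scaled but not centered
  expect_false(all(abs(colMeans(s1$values)) < 1e-8))
  s2 <- scale_unit_variance(s1)
  expect_equal(s2$values, s1$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(scale_unit_variance(
    tiny_block(matrix(c(0, 2), ncol = 1)))$values[, 1]),
    c(0, sqrt(2)), tolerance = 1e-12)
  expect_error(scale_unit_variance(tiny_block(matrix(c(1, 1, 1), ncol = 1))),
               "zero-variance")
})

test_that("outcome encoding maps the case label to 1 and rejects degeneracy", {
  o <- encode_outcome(c("case", "control", "case"))
  expect_equal(o$coded, c(1, 0, 1))
  o2 <- encode_outcome(c("MetS", "healthy", "MetS"), case = "MetS")
  expect_equal(o2$coded, c(1, 0, 1))
  expect_error(encode_outcome(c("case", "case")), "two distinct")
  expect_error(encode_outcome(c("a", "b", "c")), "two distinct")
  # swapping the coding flips the coded values
  sw <- encode_outcome(c("case", "control", "case"), case = "control")
  expect_equal(sw$coded, 1 - o$coded)
})

test_that("complete-case filtering removes a sample from every block", {
  withr::with_seed(3, {
    A <- matrix(rnorm(24), 8, 3)
    B <- matrix(rnorm(40), 8, 5)
  })
  A[3, 2] <- NA
  ids <- paste0("s", 1:8)
  blocks <- list(clin = data_block(A, ids, paste0("a", 1:3)),
                 met = data_block(B, ids, paste0("b", 1:5)))
  out <- encode_outcome(rep(c("case", "control"), 4), sample_ids = ids)
  cc <- complete_cases(blocks, out)
  expect_identical(cc$blocks$clin$sample_ids, ids[-3])
  expect_identical(cc$blocks$met$sample_ids, ids[-3])
  expect_identical(cc$outcome$sample_ids, ids[-3])
  expect_equal(sum(cc$counts), 7)
  # no missing values: identity
  blocks$clin <- data_block(B[, 1:3], ids, paste0("a", 1:3))
  cc2 <- complete_cases(blocks, out)
  expect_identical(cc2$blocks$met$values, blocks$met$values)
  # everything missing: error
  A_all_na <- data_block(matrix(NA_real_, 8, 2), ids, c("x1", "x2"))
  expect_error(complete_cases(list(a = A_all_na), out), "no complete samples")
})
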