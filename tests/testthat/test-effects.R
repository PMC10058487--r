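test_that("global effect saturates when the output is a column of the input", {
  withr::with_seed(41, A <- tiny_block(matrix(rnorm(200), 50, 4)))
  C <- A$values[, 1]
  est <- global_effect(A, C, quick_cv(seed = 2))
  expect_gte(est$mean_percent, 99)
  expect_s3_class(est, "effect_estimate")
  expect_identical(est$kind, "global")
})

test_that("residualization removes what the mediator explains", {
  withr::with_seed(43, B <- tiny_block(matrix(rnorm(300), 60, 5)))
  cv <- quick_cv(seed = 3)
  # target identical to a column of B: residual norm vanishes
  res <- residualize(B$values[, 2], B, cv, n_components = 5)
  target_c <- B$values[, 2] - mean(B$values[, 2])
  expect_lte(sqrt(sum(res$values^2)) / sqrt(sum(target_c^2)), 1e-6)
  # residual column means are zero
  d <- random_xy(n = 60, p = 5, q = 2, noise = 0.5, seed = 44)
  res2 <- residualize(d$Y, d$X, cv)
  expect_lt(max(abs(colMeans(res2$values))), 1e-10)
})

test_that("residualizing on an independent block leaves the target intact", {
  withr::with_seed(45, {
    B <- matrix(rnorm(500 * 3), 500, 3)
    target <- rnorm(500)
  })
  res <- residualize(target, B, quick_cv(seed = 5), n_components = 1)
  expect_gte(cor(target, drop(res$values)), 0.95)
})

test_that("training effects equal squared (partial) correlations univariately", {
  for (seed in c(3, 14, 27)) {
    d <- generate_trivariate(c(0.4, 0.5, 0.3), n = 120, seed = seed)
    oracle <- empirical_uni_effects(drop(d$A$values), drop(d$B$values),
                                    drop(d$C$values))
    cv <- quick_cv(seed = 1)
    g <- global_effect(d$A, d$C, cv, n_components = 1,
                       estimation = "training")
    p <- partial_effect(d$A, d$C, d$B, cv, n_components = 1,
                        n_components_CB = 1, n_components_AB = 1,
                        estimation = "training")
    expect_equal(g$mean_percent / 100, oracle$global, tolerance = 1e-8)
    expect_equal(p$mean_percent / 100, oracle$partial, tolerance = 1e-8)
  }
})

test_that("an irrelevant mediator leaves the partial effect at the global one", {
  # B independent of A and C: conditioning should change nothing (population)
  d <- generate_trivariate(c(0, 0.6, 0), n = 600, seed = 61)
  cv <- cv_config(k = 5, repeats = 5, seed = 6, max_components = 1)
  g <- global_effect(d$A, d$C, cv)
  p <- partial_effect(d$A, d$C, d$B, cv)
  expect_lt(abs(g$mean_percent - p$mean_percent), 5)
})

test_that("a mediator that contains the input exactly degenerates to zero", {
  withr::with_seed(47, A <- tiny_block(matrix(rnorm(120), 40, 3)))
  B <- data_block(cbind(A$values, A$values[, 1] + A$values[, 2]),
                  A$sample_ids, paste0("b", 1:4))
  withr::with_seed(48, C <- rnorm(40))
  expect_warning(
    est <- partial_effect(A, C, B, quick_cv(seed = 7),
                          n_components_CB = 2, n_components_AB = 3),
    "reproduces")
  expect_identical(est$mean_percent, 0)
  expect_true(est$degenerate)
})

test_that("partial effect is invariant to invertible rescaling of the mediator", {
  d <- generate_trivariate(c(0.5, 0.4, 0.5), n = 150, seed = 71)
  cv <- quick_cv(seed = 9)
  args <- list(n_components = 1, n_components_CB = 1, n_components_AB = 1,
               estimation = "training")
  p1 <- do.call(partial_effect, c(list(d$A, d$C, d$B, cv), args))
  B2 <- data_block(d$B$values * -3.7, d$B$sample_ids, d$B$variable_ids)
  p2 <- do.call(partial_effect, c(list(d$A, d$C, B2, cv), args))
  expect_equal(p1$mean_percent, p2$mean_percent, tolerance = 1e-8)
})

test_that("run_path assembles effects, VIPs and fold-changes per role", {
  dat <- generate_multiblock(synthetic_spec(
    n_samples = 60, p_A = 4, p_B = 10, seed = 81, noise_sd_A = 0.4,
    noise_sd_B = 0.4))
  A <- scale_unit_variance(dat$A); B <- scale_unit_variance(dat$B)
  cv <- cv_config(k = 5, repeats = 4, seed = 19, max_components = 3)
  rep1 <- run_path(path_diagram("A", "B"), list(A = A, B = B), dat$outcome,
                   cv, n_boot = 25,
                   unscaled_blocks = list(A = dat$A))
  expect_s3_class(rep1, "path_report")
  expect_identical(rep1$global$kind, "global")
  expect_identical(rep1$partial$kind, "partial")
  expect_length(rep1$vip_global$observed_vip, 4)
  expect_length(rep1$vip_partial$observed_vip, 4)
  expect_length(rep1$log2_fc, 4)
  # swapping the roles reverses which block is residualized
  rep2 <- run_path(path_diagram("B", "A"), list(A = A, B = B), dat$outcome,
                   cv, n_boot = 25)
  expect_length(rep2$vip_global$observed_vip, 10)
  expect_error(run_path(path_diagram("Z", "A"), list(A = A, B = B),
                        dat$outcome, cv), "unknown block")
})
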