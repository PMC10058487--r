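test_that("the generator is a deterministic function of its spec", {
  s <- synthetic_spec(n_samples = 40, p_A = 3, p_B = 8, seed = 7)
  d1 <- generate_multiblock(s)
  d2 <- generate_multiblock(s)
  expect_identical(d1$A$values, d2$A$values)
  expect_identical(d1$outcome$coded, d2$outcome$coded)
  d3 <- generate_multiblock(synthetic_spec(n_samples = 40, p_A = 3, p_B = 8,
                                           seed = 8))
  expect_false(identical(d1$A$values, d3$A$values))
})

test_that("defaults mirror the case-study dimensions with balanced classes", {
  d <- generate_multiblock(synthetic_spec(seed = 3))
  expect_identical(dim(d$A$values), c(99L, 6L))
  expect_identical(dim(d$B$values), c(99L, 102L))
  counts <- table(d$outcome$labels)
  expect_true(all(counts %in% 49:50))
})

test_that("noise-free blocks have the rank of their loadings", {
  s <- synthetic_spec(n_samples = 50, p_A = 5, p_B = 12, noise_sd_A = 0,
                      noise_sd_B = 0, seed = 11,
                      mediation_scenario = "full_mediation", n_latents = 2)
  d <- generate_multiblock(s)
  expect_identical(qr(d$A$values)$rank, qr(d$truth$loadings_A)$rank)
  expect_lte(qr(d$B$values)$rank, 2L)
})

test_that("trivariate draws honor the requested correlation structure", {
  d <- generate_trivariate(c(0, 0, 0), n = 1000, seed = 13)
  X <- cbind(d$A$values, d$B$values, d$C$values)
  off <- cor(X)[upper.tri(diag(3))]
  expect_true(all(abs(off) <= 0.1))
  # Markov chain r_AC = r_AB * r_BC is a valid (PSD) construction
  expect_silent(generate_trivariate(c(0.9, 0.81, 0.9), n = 10, seed = 1))
  expect_error(generate_trivariate(c(0.9, -0.9, 0.9), n = 10, seed = 1),
               "positive semi-definite")
})

test_that("population oracles evaluate the closed forms", {
  eff <- population_effects_unidimensional(c(0, 0.6, 0))
  expect_equal(eff$global, 0.36)
  expect_equal(eff$partial, 0.36)
  chain <- population_effects_unidimensional(c(0.8, 0.8 * 0.7, 0.7))
  expect_equal(chain$partial, 0, tolerance = 1e-12)
  eq <- population_effects_unidimensional(c(0.5, 0.5, 0.5))
  expect_equal(eq$global, 0.25)
  expect_equal(eq$partial, (1 / 3)^2)
  expect_error(population_effects_unidimensional(c(1, 0.5, 0.5)),
               "degenerate")
})

test_that("full-data effects on a large trivariate sample recover the truth", {
  spec_r <- c(0.6, 0.5, 0.4)
  d <- generate_trivariate(spec_r, n = 5000, seed = 17)
  pop <- population_effects_unidimensional(spec_r)
  cv <- quick_cv(seed = 1)
  g <- global_effect(d$A, d$C, cv, n_components = 1, estimation = "training")
  p <- partial_effect(d$A, d$C, d$B, cv, n_components = 1,
                      n_components_CB = 1, n_components_AB = 1,
                      estimation = "training")
  expect_lt(abs(g$mean_percent / 100 - pop$global), 0.02)
  expect_lt(abs(p$mean_percent / 100 - pop$partial), 0.02)
})

test_that("shared-plus-unique structure puts the partial below the global", {
  cv <- cv_config(k = 5, repeats = 4, seed = 2, max_components = 4)
  wins <- 0L
  for (seed in 1:5) {
    d <- generate_multiblock(synthetic_spec(
      n_samples = 150, p_A = 5, p_B = 20, seed = seed,
      mediation_scenario = "shared_plus_unique"))
    A <- scale_unit_variance(d$A); B <- scale_unit_variance(d$B)
    cv$strata <- d$outcome$labels
    g <- global_effect(A, d$outcome$coded, cv)
    p <- partial_effect(A, d$outcome$coded, B, cv)
    if (p$mean_percent < g$mean_percent) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
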