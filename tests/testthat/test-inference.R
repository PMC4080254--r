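test_that("genome validation rejects out-of-range samples", {
  expect_error(unit_genome(rep(0.5, 9)), "exactly 10 slots")
  expect_error(unit_genome(c(rep(0.5, 9), 1)), "strictly inside")
  expect_error(unit_genome(c(rep(0.5, 9), 0)), "strictly inside")
  expect_error(unit_genome(rep(0.5, 10), k = 0), "positive")
})

test_that("sampler reproduces the constrained-construction arithmetic", {
  # choose genome slots so that b1 = 18470.6419 and x1 = 659.2193, then a
  # b3-slot sample of 0.5 must give b3 = (b1/k2 - b2) / (0.5 * x1)
  f <- data_derived_constants()
  r <- rep(0.5, 10)
  r[1] <- f[["k1"]] * 1000 / 731.7409       # a1 slot -> a1 = 731.7409
  r[5] <- f[["k2"]] * 1000 / 18470.6419     # b1 slot -> b1 = 18470.6419
  p <- sample_parameters(unit_genome(r))
  expect_equal(p[["a1"]], 731.7409, tolerance = 1e-10)
  expect_equal(p[["b1"]], 18470.6419, tolerance = 1e-10)
  expect_equal(p[["b3"]], 40.42, tolerance = 1e-3)
  # independent oracle: the backed-out b3 satisfies its inequality
  x1 <- (p[["a1"]] - p[["k1"]]) / (p[["k1"]] * p[["a4"]])
  expect_lt(p[["b1"]], p[["k2"]] * (p[["b2"]] + p[["b3"]] * x1))
})

test_that("the reference estimate is a sampler image", {
  # the ten free parameters of the published set are reproduced exactly by
  # the construction, with every implied genome sample inside (0, 1)
  f <- data_derived_constants()
  k <- 1000
  x1 <- (731.7409 - f[["k1"]]) / (f[["k1"]] * f[["a4"]])
  z2 <- (12391.1968 - f[["k3"]]) / (f[["k3"]] * f[["c5"]])
  r <- c(f[["k1"]] * k / 731.7409,                       # a1
         856.1247 / k,                                   # a2
         398.9719 / k,                                   # a5
         (731.7409 / f[["k1"]] - 1) / (44.8982 * z2),    # a6
         f[["k2"]] * k / 18470.6419,                     # b1
         (18470.6419 / f[["k2"]] - 1) / (37.3615 * x1),  # b3
         (18470.6419 / f[["k2"]] - 1) / (55.0375 * z2),  # b5
         f[["k3"]] * k / 12391.1968,                     # c1
         (12391.1968 / f[["k3"]] - 1) / (710.4490 * x1), # c3
         522.4385 / k)                                   # c4
  expect_true(all(r > 0 & r < 1))
  p <- sample_parameters(unit_genome(r, k))
  expect_equal(setNames(as.numeric(p), names(p)),
               setNames(as.numeric(ref_params), names(ref_params)),
               tolerance = 1e-6)
})

test_that("every sampled set satisfies all seven inequalities", {
  set.seed(99)
  for (i in 1:200) {
    p <- sample_parameters(unit_genome(runif(10, 1e-6, 1 - 1e-6)))
    expect_true(all(constraint_margins(p) > 0))
    cond <- stability_conditions(p)
    expect_true(cond$trivial_unstable && cond$erythroid_stable &&
                cond$myeloid_stable)
  }
})

test_that("samples near 1 drive parameters to their inequality boundaries", {
  r_near <- rep(1 - 1e-9, 10)
  p <- sample_parameters(unit_genome(r_near))
  m <- constraint_margins(p)
  # constrained margins shrink toward zero relative to the thresholds
  expect_lt(m[["ery_b"]] / p[["b1"]], 1e-6)
  expect_lt(m[["mye_a"]] / p[["a1"]], 1e-6)
  expect_true(all(m > 0))
})

test_that("switching check distinguishes the two commitment routes", {
  ok <- check_switching(ref_params, ref_primed)
  expect_true(ok)
  d <- attr(ok, "distances")
  expect_lt(d[["erythroid"]], 0.01)
  expect_lt(d[["myeloid"]], 0.01)
  # no myeloid attractor to reach: z2 < 0 when c1 = 0
  v <- setNames(as.numeric(ref_params), names(ref_params))
  v["c1"] <- 0
  expect_false(as.logical(check_switching(rate_constants(v), ref_primed)))
  # missing primed state is a precondition error
  expect_error(check_switching(rate_constants(v), primed = NULL),
               "primed")
})

test_that("penalty values live on the ladder, never in (1, 2)", {
  cfg <- ga_config()
  U <- robustness_samples(20, 7)
  set.seed(303)
  vals <- replicate(30, {
    p <- sample_parameters(unit_genome(runif(10, 1e-6, 1 - 1e-6)))
    evaluate_penalty(p, cfg, U)$value
  })
  expect_true(all(vals %in% c(4, 3, 2) | (vals >= 0 & vals <= 1)))
  expect_false(any(vals > 1 & vals < 2))
})

test_that("frozen perturbation samples make the robustness score deterministic", {
  U <- robustness_samples(30, 5)
  f1 <- tristability_fraction(ref_params, sigma = 0.5, U = U,
                              warm_start = ref_primed_vec)
  f2 <- tristability_fraction(ref_params, sigma = 0.5, U = U,
                              warm_start = ref_primed_vec)
  expect_identical(f1, f2)
})

test_that("a one-generation GA returns the best of its initial population", {
  cfg <- ga_config(population_size = 8, n_generations = 1, seed = 42,
                   robustness_n = 5)
  fit <- run_ga(cfg)
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$history$best[2], min(fit$history$best))
  expect_lte(fit$penalty$value, fit$history$best[1])
})

test_that("GA runs are reproducible and elitism keeps best non-increasing", {
  cfg <- ga_config(population_size = 10, n_generations = 3, seed = 11,
                   robustness_n = 5)
  fit1 <- run_ga(cfg)
  fit2 <- run_ga(cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(setNames(as.numeric(fit1$params), names(fit1$params)),
                   setNames(as.numeric(fit2$params), names(fit2$params)))
  expect_true(all(diff(fit1$history$best) <= 0))
})
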