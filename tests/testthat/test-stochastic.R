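test_that("count rescaling preserves the deterministic field", {
  omega <- 50
  pc <- scale_to_counts(ref_params, omega)
  st <- c(3.2, 11.4, 0.9)
  f_conc <- gata_rhs(st, 0, ref_params)
  f_count <- gata_rhs(st * omega, 0, pc)
  expect_equal(f_count, omega * f_conc, tolerance = 1e-12)
  expect_equal(as.numeric(scale_to_counts(ref_params, 1)),
               as.numeric(ref_params))
})

test_that("the extinct state is absorbing for a single leap", {
  sch <- schedule_preset("stochastic", mu = 1)
  set.seed(1)
  out <- tau_leap_step(c(0, 0, 0), 100, ref_params, sch, tau = 0.01)
  expect_identical(out, c(0, 0, 0))
})

test_that("degradation-only leap has the Poisson mean k2 * Y * tau", {
  v <- setNames(rep(0, 23), names(ref_params))
  v[c("a3", "b2", "c2", "b4", "c5", "a4")] <- 1   # keep denominators positive
  v["k2"] <- 1.3863
  toy <- rate_constants(v)
  sch <- switch_schedule(0, 0, 1, 0)
  set.seed(21)
  dec <- replicate(1e4, 10000 - tau_leap_step(c(0, 10000, 0), 5, toy, sch,
                                              tau = 0.01)[2])
  # mean decrement 138.63, MC standard error sqrt(138.63 / 1e4) ~ 0.12
  expect_equal(mean(dec), 138.63, tolerance = 0.6 / 138.63)
})

test_that("mu = 0 suppresses the transfer channel entirely", {
  # isolate the transfer: no synthesis, no decay, Y held by zero rates
  v <- setNames(rep(0, 23), names(ref_params))
  v[c("a3", "b2", "c2", "a4", "b4", "c5")] <- 1
  toy <- rate_constants(v)
  sch0 <- switch_schedule(25, 0, 10, mu = 0)
  sch1 <- switch_schedule(25, 0, 10, mu = 1)
  set.seed(33)
  same <- replicate(200, tau_leap_step(c(0, 50, 0), 5, toy, sch0, 0.1)[1])
  expect_true(all(same == 0))
  set.seed(33)
  moved <- replicate(200, tau_leap_step(c(0, 50, 0), 5, toy, sch1, 0.1)[1])
  expect_gt(sum(moved), 0)
})

test_that("stochastic paths are reproducible from (seed, run index)", {
  cfg <- stochastic_config(n_runs = 2, seed = 9, t_end = 30,
                           schedule = schedule_preset("stochastic", mu = 0.28))
  tr1 <- simulate_stochastic(ref_params, cfg, run_index = 2)
  tr2 <- simulate_stochastic(ref_params, cfg, run_index = 2)
  expect_identical(tr1$X, tr2$X)
  expect_identical(tr1$Y, tr2$Y)
  expect_identical(tr1$Z, tr2$Z)
  tr3 <- simulate_stochastic(ref_params, cfg, run_index = 1)
  expect_false(identical(tr1$X, tr3$X))
  # counts remain non-negative integers
  expect_true(all(tr1$X >= 0 & tr1$X == floor(tr1$X)))
  expect_true(all(tr1$Y >= 0 & tr1$Z >= 0))
})

test_that("clamping events are rare at the default stepsize", {
  cfg <- stochastic_config(seed = 4, t_end = 250,
                           schedule = schedule_preset("stochastic", mu = 0.28))
  tr <- simulate_stochastic(ref_params, cfg)
  expect_lt(attr(tr, "clamped") / (3 * attr(tr, "steps")), 0.001)
})

test_that("endpoints classify to the nearest attractor with margin", {
  att <- steady_states(ref_params, seed = 1)
  omega <- 1000
  for (lab in c("erythroid", "myeloid", "primed")) {
    exact <- round(c(att[[lab]]$x, att[[lab]]$y, att[[lab]]$z) * omega)
    expect_identical(classify_endpoint(exact, att, omega), lab)
    # classification robust to 5% jitter around the attractor
    set.seed(17)
    for (i in 1:5) {
      jit <- pmax(round(exact * (1 + runif(3, -0.05, 0.05))), 0)
      expect_identical(classify_endpoint(jit, att, omega), lab)
    }
  }
  att_nop <- att
  att_nop$primed <- NULL
  expect_error(classify_endpoint(c(0, 0, 0), att_nop, omega), "primed")
})

test_that("lineage fractions are counts over runs and sum to one", {
  cfg <- stochastic_config(n_runs = 12, seed = 6)
  lf <- lineage_fractions(ref_params, cfg, mu_grid = c(0.05, 1.5))
  expect_equal(lf$erythroid + lf$primed + lf$myeloid, c(1, 1))
  expect_true(all(lf$erythroid >= 0 & lf$primed >= 0 & lf$myeloid >= 0))
  counts <- lf$n_runs[1] * c(lf$erythroid, lf$primed, lf$myeloid)
  expect_equal(counts, round(counts))
  # the extreme mu values commit to opposite lineages
  expect_gt(lf$myeloid[lf$mu == 0.05], 0.5)
  expect_gt(lf$erythroid[lf$mu == 1.5], 0.5)
})
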