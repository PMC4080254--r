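test_that("origin is a fixed point and analytic states zero the RHS", {
  expect_equal(gata_rhs(c(0, 0, 0), 0, ref_params), c(0, 0, 0))
  # substitution of the closed-form committed states
  x1 <- (ref_params[["a1"]] - ref_params[["k1"]]) /
        (ref_params[["k1"]] * ref_params[["a4"]])
  z2 <- (ref_params[["c1"]] - ref_params[["k3"]]) /
        (ref_params[["k3"]] * ref_params[["c5"]])
  expect_equal(x1, 659.22, tolerance = 1e-4)
  expect_equal(z2, 252.38, tolerance = 1e-4)
  f_ery <- gata_rhs(c(x1, 0, 0), 0, ref_params)
  f_mye <- gata_rhs(c(0, 0, z2), 0, ref_params)
  expect_lt(max(abs(f_ery)) / x1, 1e-8)
  expect_lt(max(abs(f_mye)) / z2, 1e-8)
})

test_that("analytic residuals vanish for arbitrary constraint-free sets", {
  for (p in random_free_params(25, seed = 41)) {
    ss <- analytic_steady_states(p)
    for (s in ss) {
      v <- c(s$x, s$y, s$z)
      if (all(v >= 0)) {
        expect_lt(max(abs(gata_rhs(v, 0, p))), 1e-10 * max(1, max(v)))
      }
    }
  }
})

test_that("transfer term feeds GATA-1 only inside the window and with mu > 0", {
  sch <- switch_schedule(6, 500, 1500, mu = 0.5)
  st <- c(1, 2, 3)
  inside <- gata_rhs(st, 1000, ref_params, sch)
  outside <- gata_rhs(st, 10, ref_params, sch)
  # dx gains mu*k2star*y, dy loses k2star*y, dz unchanged
  expect_equal(inside[1] - outside[1], 0.5 * 6 * 2)
  expect_equal(inside[2] - outside[2], -6 * 2)
  expect_equal(inside[3], outside[3])
})

test_that("stability conditions hold for the reference set and fail when off", {
  cond <- stability_conditions(ref_params)
  expect_true(cond$trivial_unstable)
  expect_true(cond$erythroid_stable)
  expect_true(cond$myeloid_stable)
  # all synthesis below decay thresholds: trivial state becomes stable
  v <- setNames(as.numeric(ref_params), names(ref_params))
  v[c("a1", "b1", "c1")] <- 0
  expect_false(stability_conditions(rate_constants(v))$trivial_unstable)
})

test_that("Jacobian decouples for a diagonal-only toy model", {
  v <- setNames(as.numeric(ref_params), names(ref_params))
  v[c("a2", "a5", "a6", "a7", "b3", "b5", "b6", "c3", "c4", "c6", "c7")] <- 0
  toy <- rate_constants(v)
  st <- c(2, 3, 4)
  J <- gata_jacobian(st, toy)
  expect_equal(J[upper.tri(J)], rep(0, 3))
  expect_equal(J[lower.tri(J)], rep(0, 3))
  # per-gene linearized rates: d/dx [a1 x / (a3 + a4 x)] - k1, etc.
  p <- as.list(v)
  expect_equal(J[1, 1], p$a1 * p$a3 / (p$a3 + p$a4 * st[1])^2 - p$k1)
  expect_equal(J[2, 2], p$b1 * p$b2 / (p$b2 + p$b4 * st[2])^2 - p$k2)
  expect_equal(J[3, 3], p$c1 * p$c2 / (p$c2 + p$c5 * st[3])^2 - p$k3)
})

test_that("eigenvalue classification matches the fixed-point roles", {
  expect_true(is_stable(ref_ery, ref_params))
  expect_true(is_stable(ref_mye, ref_params))
  expect_false(is_stable(c(0, 0, 0), ref_params))
  expect_error(is_stable(c(5, 5, 5), ref_params), "not a fixed point")
})

test_that("primed state exists, is interior, stable, and seed-reproducible", {
  expect_false(is.null(ref_primed))
  expect_true(all(ref_primed_vec > 0))
  expect_true(ref_primed$stable)
  expect_lt(max(abs(gata_rhs(ref_primed_vec, 0, ref_params))), 1e-8)
  again <- find_primed_state(ref_params, seed = 1)
  expect_identical(ref_primed_vec, c(again$x, again$y, again$z))
})

test_that("one-gene reduction matches its closed-form fixed point", {
  # keep only GATA-1's own terms: 1D dynamics with root (a1 - k1 a3)/(k1 a4)
  v <- setNames(rep(0, 23), names(ref_params))
  v[c("a1", "a3", "a4", "k1", "k2", "k3", "b2", "c2", "c5", "b4")] <-
    c(100, 1, 2, 0.5, 1, 1, 1, 1, 1, 1)
  p1 <- rate_constants(v)
  xstar <- (100 - 0.5) / (0.5 * 2)
  expect_equal(gata_rhs(c(xstar, 0, 0), 0, p1), c(0, 0, 0))
  tr <- simulate_ode(p1, null_sched <- switch_schedule(0, 0, 1, 0),
                     c(1, 0, 0), 200, n_out = 21)
  expect_equal(as.numeric(tr[nrow(tr), "x"]), xstar, tolerance = 1e-6)
})

test_that("ODE trajectories stay non-negative and hold fixed points", {
  tr <- simulate_ode(ref_params, switch_schedule(0, 0, 1, 0),
                     ref_primed_vec, 500, n_out = 51)
  expect_true(all(tr$x >= 0 & tr$y >= 0 & tr$z >= 0))
  expect_true(all(diff(tr$time) > 0))
  drift <- rel_distance(as.numeric(tr[nrow(tr), c("x", "y", "z")]),
                        ref_primed_vec)
  expect_lt(drift, 1e-4)
})

test_that("switch window drives commitment and is integrator-tolerance robust", {
  run <- function(mu, rtol, atol) {
    tr <- simulate_ode(ref_params, switch_schedule(6, 500, 1500, mu),
                       ref_primed_vec, 3000, n_out = 61,
                       rtol = rtol, atol = atol)
    as.numeric(tr[nrow(tr), c("x", "y", "z")])
  }
  classify <- function(e) {
    d <- c(ery = rel_distance(e, ref_ery), mye = rel_distance(e, ref_mye),
           pri = rel_distance(e, ref_primed_vec))
    names(which.min(d))
  }
  for (mu in c(1, 0, 0.32)) {
    default <- classify(run(mu, 1e-8, 1e-10))
    halved <- classify(run(mu, 5e-9, 5e-11))
    expect_identical(default, halved)
  }
})

test_that("perturbation-return accepts attractors and rejects the repeller", {
  expect_true(validate_steady_state_by_perturbation(
    ref_params, ref_ery, strength = 0.05, n_trials = 10, seed = 5))
  expect_false(validate_steady_state_by_perturbation(
    ref_params, c(0, 0, 0), strength = 0.05, n_trials = 5, seed = 5))
  # zero strength is trivially accepted
  expect_true(validate_steady_state_by_perturbation(
    ref_params, ref_mye, strength = 0, n_trials = 2, seed = 5))
})
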