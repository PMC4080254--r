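#' Configuration of the discrete stochastic simulator
#'
#' @param tau leap stepsize in hours (default 0.01).
#' @param omega copy-number scale: molecules per concentration unit (default
#'   1000). Concentration attractors map to count attractors as
#'   `omega * (x, y, z)`. The scale controls the intrinsic noise level; see
#'   [scale_to_counts()] for how the rate constants transform.
#' @param t_end simulation horizon in hours; defaults to 300 h past the
#'   switch window (the lineage read-out time).
#' @param n_runs ensemble size (default 1).
#' @param seed master seed; each run uses a substream derived from
#'   `(seed, run index)`, so ensembles are reproducible and independent of
#'   evaluation order.
#' @param schedule a [switch_schedule()]; defaults to the stochastic preset
#'   (`k2* = 25` on `[50, 200]`).
#' @param save_every interval between saved states, hours (default 1).
#' @return object of class `stochastic_config`.
#' @export
stochastic_config <- function(tau = 0.01, omega = 1000, t_end = NULL,
                              n_runs = 1, seed = 1,
                              schedule = schedule_preset("stochastic"),
                              save_every = 1) {
  stopifnot(tau > 0, omega > 0, n_runs >= 1, save_every > 0)
  if (is.null(t_end)) t_end <- schedule$t_off + 300
  stopifnot(t_end > 0)
  structure(list(tau = tau, omega = omega, t_end = t_end,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 schedule = schedule, save_every = save_every),
            class = "stochastic_config")
}

#' Rescale rate constants from concentrations to molecule counts
#'
#' With counts `X = omega * x`, the count dynamics keep the same functional
#' form provided the occupancy denominators are expressed in counts: the
#' coefficients of linear state terms (`a4, a5, a6, b3, b4, b5, c3, c4, c5`)
#' are divided by `omega` and those of bilinear terms (`a7, b6, c6, c7`) by
#' `omega^2`. Synthesis numerator coefficients and degradation rates are
#' unchanged. As `omega` grows the ensemble mean of the stochastic model
#' converges to `omega` times the ODE solution.
#'
#' @param params a [rate_constants()] vector (concentration units).
#' @param omega molecules per concentration unit.
#' @return a [rate_constants()] vector in count units.
#' @export
scale_to_counts <- function(params, omega) {
  stopifnot(omega > 0)
  p <- unclass(params)[PARAM_NAMES]
  linear <- c("a4", "a5", "a6", "b3", "b4", "b5", "c3", "c4", "c5")
  bilinear <- c("a7", "b6", "c6", "c7")
  p[linear] <- p[linear] / omega
  p[bilinear] <- p[bilinear] / omega^2
  rate_constants(p)
}

#' One Poisson tau-leap update
#'
#' Advances integer copy numbers `(X, Y, Z)` by one leap of length `tau`:
#' each of the seven event channels (three productions, three degradations —
#' the GATA-2 channel with total rate `(k2 + k2*(t)) Y` split into its two
#' draws — and the `mu k2*(t) Y` transfer into X) contributes an independent
#' Poisson variate with mean `rate * tau`. Coordinates are clamped at zero.
#' Mainly useful for unit-level verification; ensemble simulation goes
#' through the compiled path in [simulate_stochastic()].
#'
#' @param state integer counts `(X, Y, Z)`, non-negative.
#' @param t current time (hours).
#' @param params count-scale [rate_constants()] (see [scale_to_counts()]).
#' @param schedule a [switch_schedule()].
#' @param tau leap size (hours).
#' @return updated counts (numeric length 3).
#' @export
tau_leap_step <- function(state, t, params, schedule, tau) {
  stopifnot(length(state) == 3, all(state >= 0), all(state == floor(state)))
  p <- as.list(unclass(params))
  ks <- schedule_value(schedule, t)
  X <- state[1]; Y <- state[2]; Z <- state[3]
  D1 <- p$a3 + p$a4*X + p$a5*Y + p$a6*Z + p$a7*X*Z
  D2 <- p$b2 + p$b3*X + p$b4*Y + p$b5*Z + p$b6*Y*Z
  D3 <- p$c2 + p$c3*X + p$c4*Y + p$c5*Z + p$c6*X*Z + p$c7*Y*Z
  X2 <- X + stats::rpois(1, (p$a1*X + p$a2*Y)/D1 * tau) -
        stats::rpois(1, p$k1*X*tau) +
        stats::rpois(1, schedule$mu * ks * Y * tau)
  Y2 <- Y + stats::rpois(1, p$b1*Y/D2 * tau) -
        stats::rpois(1, p$k2*Y*tau) - stats::rpois(1, ks*Y*tau)
  Z2 <- Z + stats::rpois(1, p$c1*Z/D3 * tau) - stats::rpois(1, p$k3*Z*tau)
  pmax(c(X2, Y2, Z2), 0)
}

# Deterministic per-run substream seed, kept within 32-bit integer range.
run_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(run_index) * 9973) %%
             2147483647)
}

#' Simulate one stochastic trajectory
#'
#' Iterates the Poisson tau-leap from `init` to `cfg$t_end`, recording the
#' state every `cfg$save_every` hours. The run is seeded from
#' `(cfg$seed, run_index)`, so any ensemble member can be regenerated in
#' isolation.
#'
#' @param params concentration-scale [rate_constants()]; rescaled internally
#'   with [scale_to_counts()].
#' @param cfg a [stochastic_config()].
#' @param init initial copy numbers; defaults to the deterministic primed
#'   state rounded to integers at scale `cfg$omega`.
#' @param run_index ensemble member index (default 1).
#' @return data frame of class `gata_trajectory` with columns
#'   `time, X, Y, Z` (counts); attributes `clamped` (number of negative
#'   excursions clamped to zero) and `steps`.
#' @export
#' @examples
#' cfg <- stochastic_config(n_runs = 1, seed = 7,
#'                          schedule = schedule_preset("stochastic", mu = 0.28))
#' tr <- simulate_stochastic(reference_params(), cfg)
#' tail(tr, 2)
simulate_stochastic <- function(params, cfg, init = NULL, run_index = 1) {
  stopifnot(inherits(cfg, "stochastic_config"))
  pc <- scale_to_counts(params, cfg$omega)
  if (is.null(init)) {
    primed <- find_primed_state(params, seed = cfg$seed)
    if (is.null(primed)) {
      stop("no primed state to initialize from; supply init", call. = FALSE)
    }
    init <- round(state_vec(primed) * cfg$omega)
  }
  stopifnot(length(init) == 3, all(init >= 0))
  set.seed(run_seed(cfg$seed, run_index))
  sch <- cfg$schedule
  m <- .tau_leap_cpp(param_vector(pc), sch$mu, sch$k2_star, sch$t_on,
                     sch$t_off, cfg$tau, cfg$t_end, cfg$save_every,
                     as.numeric(init))
  df <- data.frame(time = m[, 1], X = m[, 2], Y = m[, 3], Z = m[, 4])
  out <- new_trajectory(df, sch)
  attr(out, "clamped") <- attr(m, "clamped")
  attr(out, "steps") <- attr(m, "steps")
  out
}

#' Classify a stochastic endpoint by nearest attractor
#'
#' Assigns a lineage label by relative Euclidean distance on
#' `log1p`-transformed coordinates between the endpoint (converted back to
#' concentration scale) and the three attractors. The log transform makes the
#' comparison scale-free across the several orders of magnitude separating
#' committed and primed expression levels. Exact ties break deterministically
#' in the order erythroid, myeloid, primed.
#'
#' @param state endpoint copy numbers `(X, Y, Z)`.
#' @param attractors a [steady_states()] set including a primed state.
#' @param omega copy-number scale of `state`.
#' @return one of `"erythroid"`, `"myeloid"`, `"primed"`.
#' @export
classify_endpoint <- function(state, attractors, omega) {
  if (is.null(attractors$primed)) {
    stop("attractor set lacks a primed state", call. = FALSE)
  }
  conc <- as.numeric(state) / omega
  labs <- c("erythroid", "myeloid", "primed")
  d <- vapply(labs, function(l) {
    a <- state_vec(attractors[[l]])
    sqrt(sum((log1p(conc) - log1p(a))^2))
  }, numeric(1))
  labs[which.min(d)]  # which.min takes the first of tied minima
}

#' Lineage-commitment fractions across a GATA-1 availability sweep
#'
#' For each value of `mu` on the grid, runs `cfg$n_runs` stochastic
#' simulations from the primed state through the switch window and classifies
#' the endpoint at the read-out time (`cfg$t_end`, by default 300 h past the
#' window). Fractions are run counts over `n_runs`, so each row sums to one
#' exactly.
#'
#' @param params a [rate_constants()] vector.
#' @param cfg a [stochastic_config()]; its schedule supplies `k2_star` and
#'   the window, and its `mu` is overridden by the grid.
#' @param mu_grid vector of GATA-1 availability values (default
#'   `seq(0, 1.5, by = 0.1)`).
#' @return data frame of class `lineage_fractions` with columns
#'   `mu, erythroid, primed, myeloid, n_runs`.
#' @export
#' @examples
#' \donttest{
#' cfg <- stochastic_config(n_runs = 50, seed = 1)
#' lineage_fractions(reference_params(), cfg, mu_grid = c(0.05, 1.5))
#' }
lineage_fractions <- function(params, cfg,
                              mu_grid = seq(0, 1.5, by = 0.1)) {
  stopifnot(inherits(cfg, "stochastic_config"), all(mu_grid >= 0))
  attractors <- steady_states(params, seed = cfg$seed)
  if (is.null(attractors$primed)) {
    stop("model has no primed state; the sweep starts from it",
         call. = FALSE)
  }
  init <- round(state_vec(attractors$primed) * cfg$omega)
  pc <- scale_to_counts(params, cfg$omega)
  pv <- param_vector(pc)
  sch <- cfg$schedule
  rows <- lapply(seq_along(mu_grid), function(i) {
    mu <- mu_grid[i]
    counts <- c(erythroid = 0, primed = 0, myeloid = 0)
    for (r in seq_len(cfg$n_runs)) {
      set.seed(run_seed(cfg$seed + i * 1000L, r))
      m <- .tau_leap_cpp(pv, mu, sch$k2_star, sch$t_on, sch$t_off, cfg$tau,
                         cfg$t_end, cfg$t_end, as.numeric(init))
      lab <- classify_endpoint(m[nrow(m), 2:4], attractors, cfg$omega)
      counts[lab] <- counts[lab] + 1
    }
    data.frame(mu = mu,
               erythroid = counts[["erythroid"]] / cfg$n_runs,
               primed = counts[["primed"]] / cfg$n_runs,
               myeloid = counts[["myeloid"]] / cfg$n_runs,
               n_runs = cfg$n_runs)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lineage_fractions", "data.frame")
  out
}
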