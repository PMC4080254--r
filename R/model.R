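#' Right-hand side of the lineage-decision ODE model
#'
#' Evaluates the time derivatives of the GATA-1 (`x`), GATA-2 (`y`) and PU.1
#' (`z`) concentrations. During the switch window the GATA-2 equation gains
#' the extra degradation `-k2*(t) y` and the GATA-1 equation the transfer
#' term `+mu k2*(t) y` (GATA-1 occupying the chromatin sites vacated by
#' GATA-2).
#'
#' @param state numeric length-3 vector `(x, y, z)`, all >= 0.
#' @param t time in hours (>= 0).
#' @param params a [rate_constants()] vector.
#' @param schedule a [switch_schedule()]; defaults to no switch.
#' @return numeric length-3 vector of derivatives.
#' @export
#' @examples
#' gata_rhs(c(0, 0, 0), 0, reference_params())  # origin is a fixed point
gata_rhs <- function(state, t = 0, params, schedule = null_schedule()) {
  stopifnot(length(state) == 3, all(state >= 0))
  p <- param_vector(params)
  denom_guard(p, state)
  .rhs_cpp(as.numeric(state), p, schedule_value(schedule, t), schedule$mu)
}

# The Shea-Ackers denominators vanish only when the basal occupancy term and
# every state-dependent term are simultaneously zero.
denom_guard <- function(p, state) {
  x <- state[1]; y <- state[2]; z <- state[3]
  d <- c(p[3] + p[4]*x + p[5]*y + p[6]*z + p[7]*x*z,
         p[9] + p[10]*x + p[11]*y + p[12]*z + p[13]*y*z,
         p[15] + p[16]*x + p[17]*y + p[18]*z + p[19]*x*z + p[20]*y*z)
  if (any(d == 0)) {
    stop("promoter occupancy denominator is zero at this state ",
         "(basal term and all binding terms vanish)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Jacobian of the model right-hand side
#'
#' Analytic Jacobian of the `k2* = 0` vector field, used for eigenvalue-based
#' stability classification of fixed points.
#'
#' @inheritParams gata_rhs
#' @return 3x3 numeric matrix.
#' @export
gata_jacobian <- function(state, params) {
  stopifnot(length(state) == 3)
  .jac_cpp(as.numeric(state), param_vector(params))
}

#' Eigenvalue stability of a fixed point
#'
#' Checks that `state` is an approximate fixed point of the `k2* = 0` field
#' (max-norm residual below `residual_tol`) and classifies it as stable iff
#' every eigenvalue of the Jacobian has real part below `-1e-9`. The strict
#' negative threshold leaves a margin band so that points exactly on a
#' stability boundary are not classified as stable by rounding.
#'
#' @inheritParams gata_rhs
#' @param residual_tol residual tolerance for the fixed-point precondition.
#' @return `TRUE`/`FALSE`.
#' @export
is_stable <- function(state, params, residual_tol = 1e-6) {
  f <- .rhs_cpp(as.numeric(state), param_vector(params), 0, 0)
  if (max(abs(f)) > residual_tol) {
    stop("state is not a fixed point (residual ", format(max(abs(f))),
         " > ", format(residual_tol), ")", call. = FALSE)
  }
  ev <- eigen(gata_jacobian(state, params), only.values = TRUE)$values
  max(Re(ev)) < -1e-9
}

steady_state <- function(x, y, z, stable, label,
                         physical = all(c(x, y, z) >= 0)) {
  structure(list(x = x, y = y, z = z, stable = stable, label = label,
                 physical = physical),
            class = "gata_steady_state")
}

#' @export
print.gata_steady_state <- function(x, ...) {
  cat(sprintf("<steady_state %s> (x, y, z) = (%.4g, %.4g, %.4g)  %s%s\n",
              x$label, x$x, x$y, x$z,
              if (x$stable) "stable" else "unstable",
              if (!x$physical) " [non-physical]" else ""))
  invisible(x)
}

#' @export
as.double.gata_steady_state <- function(x, ...) c(x$x, x$y, x$z)

# Internal: plain numeric (x, y, z) from a steady state or numeric vector.
state_vec <- function(s) {
  if (inherits(s, "gata_steady_state")) c(s$x, s$y, s$z) else as.numeric(s)
}

#' Analytic steady states of the model
#'
#' With `k2* = 0` and zero basal expression, three fixed points follow in
#' closed form: the trivial state `(0, 0, 0)`, the erythroid state
#' `((a1 - k1 a3)/(k1 a4), 0, 0)` with high GATA-1, and the myeloid state
#' `(0, 0, (c1 - k3 c2)/(k3 c5))` with high PU.1. Stability is classified by
#' the closed-form inequality conditions (see [stability_conditions()]):
#' the trivial state is flagged unstable whenever any gene's synthesis rate
#' exceeds its basal decay threshold, and each committed state is stable when
#' the remaining two genes are repressed below their growth thresholds.
#' A negative coordinate (synthesis too weak to sustain the lineage) is
#' reported with `stable = FALSE` and `physical = FALSE` rather than as an
#' error, so parameter scans can cross existence boundaries.
#'
#' @param params a [rate_constants()] vector with `k1 a4 != 0` and
#'   `k3 c5 != 0`.
#' @return list with elements `trivial`, `erythroid`, `myeloid`, each a
#'   steady-state object.
#' @export
#' @examples
#' analytic_steady_states(reference_params())
analytic_steady_states <- function(params) {
  p <- as.list(unclass(params))
  if (p$k1 * p$a4 == 0 || p$k3 * p$c5 == 0) {
    stop("analytic steady states require k1*a4 != 0 and k3*c5 != 0",
         call. = FALSE)
  }
  x1 <- (p$a1 - p$k1 * p$a3) / (p$k1 * p$a4)
  z2 <- (p$c1 - p$k3 * p$c2) / (p$k3 * p$c5)
  cond <- stability_conditions(params)
  list(
    trivial   = steady_state(0, 0, 0, stable = !cond$trivial_unstable,
                             label = "trivial"),
    erythroid = steady_state(x1, 0, 0,
                             stable = cond$erythroid_stable && x1 >= 0,
                             label = "erythroid", physical = x1 >= 0),
    myeloid   = steady_state(0, 0, z2,
                             stable = cond$myeloid_stable && z2 >= 0,
                             label = "myeloid", physical = z2 >= 0)
  )
}

#' Closed-form stability conditions for the analytic steady states
#'
#' Evaluates the seven inequalities that govern the analytic fixed points:
#' the trivial state is unstable if any of `a1 > a3 k1`, `b1 > b2 k2`,
#' `c1 > c2 k3` holds; the erythroid state (GATA-1 level `x1`) is stable if
#' `b1 < k2 (b2 + b3 x1)` and `c1 < k3 (c2 + c3 x1)`; the myeloid state
#' (PU.1 level `z2`) is stable if `a1 < k1 (a3 + a6 z2)` and
#' `b1 < k2 (b2 + b5 z2)`. These conditions agree with the sign of the
#' leading Jacobian eigenvalue at the respective states whenever the states
#' are non-negative.
#'
#' @param params a [rate_constants()] vector.
#' @return named list of logicals `trivial_unstable`, `erythroid_stable`,
#'   `myeloid_stable`.
#' @export
stability_conditions <- function(params) {
  p <- as.list(unclass(params))
  x1 <- (p$a1 - p$k1 * p$a3) / (p$k1 * p$a4)
  z2 <- (p$c1 - p$k3 * p$c2) / (p$k3 * p$c5)
  list(
    trivial_unstable = (p$a1 > p$a3 * p$k1) || (p$b1 > p$b2 * p$k2) ||
                       (p$c1 > p$c2 * p$k3),
    erythroid_stable = (p$b1 < p$k2 * (p$b2 + p$b3 * x1)) &&
                       (p$c1 < p$k3 * (p$c2 + p$c3 * x1)),
    myeloid_stable   = (p$a1 < p$k1 * (p$a3 + p$a6 * z2)) &&
                       (p$b1 < p$k2 * (p$b2 + p$b5 * z2))
  )
}

#' Locate the primed (progenitor) steady state
#'
#' The fourth fixed point — low co-expression of all three genes, the primed
#' progenitor condition — has no closed form. It is located numerically by a
#' damped Newton iteration on the `k2* = 0` field, restarted from random
#' initial guesses drawn log-uniformly between `1e-2` and the largest
#' attractor coordinate on each axis. A root qualifies when its max-norm
#' residual is below `residual_tol` and all components are strictly positive;
#' stability is classified by the Jacobian eigenvalues.
#'
#' @param params a [rate_constants()] vector.
#' @param n_restarts number of random restarts (default 100).
#' @param seed optional integer seed; identical seeds give identical results.
#' @param residual_tol acceptance residual for a root.
#' @param require_stable if `TRUE` (default) only an eigenvalue-stable root
#'   is returned.
#' @param warm_start optional length-3 vector tried before the random
#'   restarts (used by perturbation scans to reuse the unperturbed root).
#' @return a steady-state object labelled `"primed"`, or `NULL` when no
#'   qualifying root is found (absence is a value, not an error).
#' @export
#' @examples
#' find_primed_state(reference_params(), seed = 1)
find_primed_state <- function(params, n_restarts = 100, seed = NULL,
                              residual_tol = 1e-8, require_stable = TRUE,
                              warm_start = NULL) {
  p <- param_vector(params)
  pl <- as.list(unclass(params))
  x1 <- (pl$a1 - pl$k1 * pl$a3) / (pl$k1 * pl$a4)
  z2 <- (pl$c1 - pl$k3 * pl$c2) / (pl$k3 * pl$c5)
  hi <- max(x1, z2, 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  check_root <- function(guess) {
    r <- .newton_cpp(as.numeric(guess), p)
    if (r$residual < residual_tol && all(r$root > 1e-4)) {
      ev <- eigen(.jac_cpp(r$root, p), only.values = TRUE)$values
      stable <- max(Re(ev)) < -1e-9
      if (stable || !require_stable) {
        return(steady_state(r$root[1], r$root[2], r$root[3],
                            stable = stable, label = "primed"))
      }
    }
    NULL
  }
  if (!is.null(warm_start)) {
    hit <- check_root(warm_start)
    if (!is.null(hit)) return(hit)
  }
  for (i in seq_len(n_restarts)) {
    guess <- exp(runif(3, log(1e-2), log(hi)))
    hit <- check_root(guess)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' All four steady states with stability labels
#'
#' Convenience wrapper combining [analytic_steady_states()] and
#' [find_primed_state()].
#'
#' @inheritParams find_primed_state
#' @return an object of class `gata_steady_state_set` with elements
#'   `trivial`, `erythroid`, `myeloid` and `primed` (the latter `NULL` when
#'   no interior root is found).
#' @export
steady_states <- function(params, n_restarts = 100, seed = NULL) {
  a <- analytic_steady_states(params)
  a$primed <- find_primed_state(params, n_restarts = n_restarts, seed = seed)
  structure(a, class = "gata_steady_state_set")
}

#' @export
print.gata_steady_state_set <- function(x, ...) {
  cat("<steady_state_set>\n")
  for (nm in c("trivial", "erythroid", "myeloid", "primed")) {
    if (is.null(x[[nm]])) cat(sprintf("  %-9s absent\n", nm))
    else { cat("  "); print(x[[nm]]) }
  }
  invisible(x)
}

new_trajectory <- function(df, schedule) {
  structure(df, schedule = schedule,
            class = c("gata_trajectory", "data.frame"))
}

#' Integrate the deterministic model across a switch window
#'
#' Integrates the ODE system with `deSolve::ode` (stiff-capable `lsoda`),
#' splitting the time span at `t_on` and `t_off` so that the discontinuity of
#' the scheduled degradation rate always falls on a segment boundary and is
#' never stepped across by the adaptive integrator. State components are
#' clipped at zero (trajectories can graze the axes to within integrator
#' noise).
#'
#' @param params a [rate_constants()] vector.
#' @param schedule a [switch_schedule()].
#' @param init initial state `(x, y, z)`, non-negative.
#' @param t_end final time in hours (> 0).
#' @param n_out approximate number of output rows (default 601).
#' @param rtol,atol relative / absolute integration tolerances.
#' @return a data frame of class `gata_trajectory` with columns
#'   `time, x, y, z`; the schedule used is attached as an attribute.
#' @export
#' @examples
#' p <- reference_params()
#' pr <- find_primed_state(p, seed = 1)
#' tr <- simulate_ode(p, schedule_preset("ode", mu = 1), as.numeric(pr), 3000)
#' tail(tr, 1)  # committed to the erythroid attractor
simulate_ode <- function(params, schedule, init, t_end, n_out = 601,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(init) == 3, all(init >= 0), t_end > 0)
  p <- param_vector(params)
  breaks <- sort(unique(c(0, t_end,
                          schedule$t_on[schedule$t_on > 0 & schedule$t_on < t_end],
                          schedule$t_off[schedule$t_off > 0 & schedule$t_off < t_end])))
  times <- sort(unique(c(seq(0, t_end, length.out = n_out), breaks)))
  deriv <- function(t, s, k2s) list(.rhs_cpp(pmax(s, 0), p, k2s, schedule$mu))
  out <- NULL
  state <- as.numeric(init)
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    # the window is closed, so its own rate applies on [t_on, t_off]
    k2s <- schedule_value(schedule, (t0 + t1) / 2)
    seg <- tryCatch(
      deSolve::ode(y = state, times = seg_times, func = deriv, parms = k2s,
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) {
        stop(sprintf("ODE integration failed on segment [%g, %g]: %s",
                     t0, t1, conditionMessage(w)), call. = FALSE)
      }
    )
    state <- pmax(as.numeric(seg[nrow(seg), 2:4]), 0)
    keep <- if (is.null(out)) seq_len(nrow(seg)) else 2:nrow(seg)
    out <- rbind(out, seg[keep, , drop = FALSE])
  }
  df <- data.frame(time = out[, 1], x = pmax(out[, 2], 0),
                   y = pmax(out[, 3], 0), z = pmax(out[, 4], 0))
  new_trajectory(df, schedule)
}

# Relative distance used for attractor proximity and convergence checks.
rel_dist <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(1, sqrt(sum(b^2)))
}

#' Validate a steady state by perturbation-and-return
#'
#' A numerically located fixed point is accepted only if trajectories started
#' from randomly perturbed copies relax back onto it. Each coordinate is
#' perturbed multiplicatively by `1 + strength * u` with `u ~ U(-1, 1)`;
#' coordinates that are exactly zero instead receive a small absolute kick
#' `strength * |u| / 100`, since multiplicative noise cannot probe the
#' stability of an extinct gene. The kick is kept two orders of magnitude
#' below the relative strength because the committed states sit close to
#' strongly repressing cross terms: a re-expression excursion must stay in
#' the linear regime to test stability rather than basin width.
#'
#' @param params a [rate_constants()] vector.
#' @param state candidate fixed point, length-3 non-negative.
#' @param strength relative perturbation strength (default 0.05).
#' @param n_trials number of perturbed restarts (default 10).
#' @param seed optional integer seed.
#' @param t_relax relaxation horizon in hours (default 300).
#' @param tol relative return distance counted as convergence
#'   (default 1e-3).
#' @return `TRUE` iff all trials return to `state`.
#' @export
validate_steady_state_by_perturbation <- function(params, state,
                                                  strength = 0.05,
                                                  n_trials = 10, seed = NULL,
                                                  t_relax = 300, tol = 1e-3) {
  stopifnot(length(state) == 3, all(state >= 0), strength >= 0)
  state <- as.numeric(state)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sch <- null_schedule()
  for (i in seq_len(n_trials)) {
    u <- runif(3, -1, 1)
    pert <- state * (1 + strength * u)
    pert[state == 0] <- strength * abs(u[state == 0]) / 100
    tr <- simulate_ode(params, sch, pert, t_relax, n_out = 11)
    endpoint <- as.numeric(tr[nrow(tr), c("x", "y", "z")])
    if (rel_dist(endpoint, state) > tol) return(FALSE)
  }
  TRUE
}
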