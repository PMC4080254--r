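#' Shared uniform samples for parameter perturbation
#'
#' Draws the `U[j, k] ~ U(0, 1)` matrix used by [perturb_parameters()] and
#' [tristability_fraction()]. Freezing one matrix and reusing it across
#' candidates makes robustness scores directly comparable (and, per
#' candidate, deterministic).
#'
#' @param n_sets number of perturbed sets (columns).
#' @param seed integer seed.
#' @return 23 x `n_sets` numeric matrix.
#' @export
robustness_samples <- function(n_sets, seed) {
  stopifnot(n_sets >= 1)
  set.seed(as.integer(seed))
  matrix(runif(23 * n_sets), nrow = 23, ncol = n_sets)
}

#' Multiplicatively perturbed copies of a parameter set
#'
#' Each rate constant `a_j` in each set `k` becomes
#' `a_j * (1 + sigma * (U[j, k] - 0.5))`. With `sigma <= 2` all outputs stay
#' non-negative.
#'
#' @param params a [rate_constants()] vector.
#' @param sigma perturbation strength (>= 0).
#' @param n_sets number of perturbed sets (ignored when `U` is given).
#' @param seed integer seed used when `U` is not supplied.
#' @param U optional pre-drawn 23 x n matrix from [robustness_samples()].
#' @return list of [rate_constants()] vectors.
#' @export
#' @examples
#' perturb_parameters(reference_params(), sigma = 0.5, n_sets = 2, seed = 1)
perturb_parameters <- function(params, sigma = 0.5, n_sets = 1000,
                               seed = NULL, U = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(U)) {
    if (is.null(seed)) stop("supply either U or seed", call. = FALSE)
    U <- robustness_samples(n_sets, seed)
  }
  stopifnot(nrow(U) == 23)
  base <- as.numeric(unclass(params)[PARAM_NAMES])
  lapply(seq_len(ncol(U)), function(k) {
    rate_constants(setNames(base * (1 + sigma * (U[, k] - 0.5)), PARAM_NAMES))
  })
}

#' Does a parameter set retain tristability?
#'
#' Operational definition used by the robustness and bifurcation scans: the
#' two analytic committed states exist (non-negative coordinates) and are
#' stable by the closed-form inequality conditions, and a strictly positive,
#' eigenvalue-stable primed root exists. The primed-root search warm-starts
#' from a supplied point (typically the unperturbed primed state) and falls
#' back to a fixed deterministic grid of log-spaced initial guesses, so the
#' result is deterministic for given inputs.
#'
#' @param params a [rate_constants()] vector.
#' @param warm_start optional length-3 starting point for the primed search.
#' @return `TRUE`/`FALSE`.
#' @export
is_tristable <- function(params, warm_start = NULL) {
  p <- as.list(unclass(params))
  if (p$k1 * p$a4 == 0 || p$k3 * p$c5 == 0) return(FALSE)
  x1 <- (p$a1 - p$k1 * p$a3) / (p$k1 * p$a4)
  z2 <- (p$c1 - p$k3 * p$c2) / (p$k3 * p$c5)
  if (x1 <= 0 || z2 <= 0) return(FALSE)
  cond <- stability_conditions(params)
  if (!(cond$trivial_unstable && cond$erythroid_stable &&
        cond$myeloid_stable)) {
    return(FALSE)
  }
  pv <- param_vector(params)
  check <- function(guess) {
    r <- .newton_cpp(as.numeric(guess), pv)
    if (r$residual < 1e-8 && all(r$root > 1e-4)) {
      ev <- eigen(.jac_cpp(r$root, pv), only.values = TRUE)$values
      return(max(Re(ev)) < -1e-9)
    }
    FALSE
  }
  if (!is.null(warm_start) && check(warm_start)) return(TRUE)
  hi <- max(x1, z2, 1)
  axis <- exp(seq(log(1e-2), log(hi), length.out = 4))
  for (gx in axis) for (gy in axis) for (gz in axis) {
    if (check(c(gx, gy, gz))) return(TRUE)
  }
  FALSE
}

#' Fraction of perturbed parameter sets retaining tristability
#'
#' The robustness measure of a parameter estimate: perturb all 23 rate
#' constants multiplicatively (see [perturb_parameters()]) and report the
#' fraction of perturbed sets under which the model still has three stable
#' steady states. The complementary fraction (sets NOT maintaining
#' tristability) is the final stage of [evaluate_penalty()].
#'
#' @inheritParams perturb_parameters
#' @param warm_start optional primed state of the unperturbed set, used to
#'   warm-start the perturbed primed searches.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' p <- reference_params()
#' pr <- find_primed_state(p, seed = 1)
#' tristability_fraction(p, sigma = 0.5, n_sets = 50, seed = 1,
#'                       warm_start = as.numeric(pr))
tristability_fraction <- function(params, sigma = 0.5, n_sets = 1000,
                                  seed = NULL, U = NULL, warm_start = NULL) {
  if (is.null(warm_start)) {
    pr <- find_primed_state(params, seed = if (is.null(seed)) 1 else seed)
    warm_start <- if (is.null(pr)) NULL else state_vec(pr)
  }
  sets <- perturb_parameters(params, sigma = sigma, n_sets = n_sets,
                             seed = seed, U = U)
  ok <- vapply(sets, is_tristable, logical(1), warm_start = warm_start)
  mean(ok)
}

#' Single-parameter bifurcation scan of tristability
#'
#' Re-evaluates tristability on a grid of values of one rate constant from 0
#' to twice its current value, holding all other constants fixed. For each
#' grid value the scan records whether the model is tristable, the analytic
#' attractor coordinates, and the primed-state coordinates when an interior
#' stable root exists (searched with a warm start from the previous grid
#' point to follow the branch).
#'
#' @param params a [rate_constants()] vector (the baseline estimate).
#' @param parameter_name one of the 23 rate-constant names.
#' @param n_grid number of grid points (default 41).
#' @return a data frame of class `bifurcation_scan` with columns
#'   `value, tristable, x_erythroid, z_myeloid, primed_x, primed_y, primed_z`
#'   (primed columns are `NA` when no interior stable root is found).
#' @export
#' @examples
#' sc <- bifurcation_scan(reference_params(), "a2", n_grid = 5)
#' all(sc$tristable)
bifurcation_scan <- function(params, parameter_name, n_grid = 41) {
  if (!parameter_name %in% PARAM_NAMES) {
    stop("unknown parameter: ", parameter_name, call. = FALSE)
  }
  base <- unclass(params)[PARAM_NAMES]
  grid <- seq(0, 2 * base[[parameter_name]], length.out = n_grid)
  baseline_primed <- find_primed_state(params, seed = 1)
  warm <- if (is.null(baseline_primed)) NULL else state_vec(baseline_primed)
  rows <- vector("list", n_grid)
  for (i in seq_len(n_grid)) {
    q <- base
    q[[parameter_name]] <- grid[i]
    qp <- rate_constants(setNames(as.numeric(q), PARAM_NAMES))
    pl <- as.list(q)
    degenerate <- pl$k1 * pl$a4 == 0 || pl$k3 * pl$c5 == 0
    x1 <- if (degenerate) NA_real_ else
      (pl$a1 - pl$k1 * pl$a3) / (pl$k1 * pl$a4)
    z2 <- if (degenerate) NA_real_ else
      (pl$c1 - pl$k3 * pl$c2) / (pl$k3 * pl$c5)
    primed <- if (degenerate) NULL else
      find_primed_state(qp, n_restarts = 30, seed = 1, warm_start = warm)
    tri <- !degenerate && is_tristable(qp, warm_start = warm)
    if (!is.null(primed)) warm <- state_vec(primed)
    rows[[i]] <- data.frame(
      value = grid[i], tristable = tri,
      x_erythroid = x1, z_myeloid = z2,
      primed_x = if (is.null(primed)) NA_real_ else primed$x,
      primed_y = if (is.null(primed)) NA_real_ else primed$y,
      primed_z = if (is.null(primed)) NA_real_ else primed$z
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "parameter_name") <- parameter_name
  class(out) <- c("bifurcation_scan", "data.frame")
  out
}
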