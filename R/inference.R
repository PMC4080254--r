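#' Unit-interval genome for constrained parameter sampling
#'
#' The inference procedure never mutates model parameters directly: the
#' genome is a vector of ten samples in the open unit interval, one per free
#' degree of freedom, plus a synthesis-scale factor `k`. The constrained
#' construction in [sample_parameters()] maps any such genome to a parameter
#' set that satisfies all seven steady-state inequality constraints by
#' construction.
#'
#' Slot order (fixed): `a1, a2, a5, a6, b1, b3, b5, c1, c3, c4` — the slot
#' name is the parameter whose value the sample determines.
#'
#' @param r numeric vector of length 10, every entry strictly inside (0, 1).
#' @param k synthesis scale factor (> 0). Small scales (k below roughly 100)
#'   do not support genetic switching, so the default is 1000.
#' @return object of class `unit_genome`.
#' @export
unit_genome <- function(r, k = 1000) {
  if (length(r) != 10) {
    stop("genome must have exactly 10 slots, got ", length(r), call. = FALSE)
  }
  if (any(r <= 0 | r >= 1)) {
    stop("all genome samples must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("k must be a positive scalar", call. = FALSE)
  }
  structure(list(r = as.numeric(r), k = k), class = "unit_genome")
}

GENOME_SLOTS <- c("a1", "a2", "a5", "a6", "b1", "b3", "b5", "c1", "c3", "c4")

#' Construct a constraint-satisfying parameter set from a genome
#'
#' Maps ten unit-interval samples to the ten free rate constants so that the
#' seven steady-state inequalities hold by construction (three guarantee the
#' trivial state is unstable, two that the erythroid state is stable, two
#' that the myeloid state is stable):
#' \itemize{
#'   \item synthesis rates exceed their decay thresholds by the factor
#'     `k/r`: `a1 = (k1 a3 / r) k`, `b1 = (k2 b2 / r) k`,
#'     `c1 = (k3 c2 / r) k`;
#'   \item repression coefficients are backed out of the stability
#'     inequalities at the analytic attractor coordinates `x1`, `z2`:
#'     `b3 = (b1/k2 - b2)/(r x1)`, `c3 = (c1/k3 - c2)/(r x1)`,
#'     `a6 = (a1/k1 - a3)/(r z2)`, `b5 = (b1/k2 - b2)/(r z2)`;
#'   \item the remaining synthesis-scale parameters are direct draws on
#'     `(0, k)`: `a2 = r k`, `a5 = r k`, `c4 = r k`.
#' }
#' As each `r` approaches 1 the corresponding parameter approaches its
#' inequality boundary. Every output passes [stability_conditions()] with all
#' three entries `TRUE`.
#'
#' @param genome a [unit_genome()].
#' @param fixed named vector supplying the fixed constants (normalization
#'   `a3 = b2 = c2 = 1`, data-derived binding terms and degradation rates);
#'   defaults to [data_derived_constants()].
#' @return a [rate_constants()] vector.
#' @export
#' @examples
#' g <- unit_genome(rep(0.5, 10))
#' p <- sample_parameters(g)
#' stability_conditions(p)  # all TRUE by construction
sample_parameters <- function(genome, fixed = data_derived_constants()) {
  stopifnot(inherits(genome, "unit_genome"))
  need <- c("a3", "b2", "c2", "a4", "a7", "b4", "b6", "c5", "c6", "c7",
            "k1", "k2", "k3")
  missing <- setdiff(need, names(fixed))
  if (length(missing)) {
    stop("fixed constants missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- as.list(fixed[need])
  r <- setNames(genome$r, GENOME_SLOTS)
  k <- genome$k
  a1 <- f$k1 * f$a3 / r[["a1"]] * k
  b1 <- f$k2 * f$b2 / r[["b1"]] * k
  c1 <- f$k3 * f$c2 / r[["c1"]] * k
  x1 <- (a1 - f$k1 * f$a3) / (f$k1 * f$a4)
  z2 <- (c1 - f$k3 * f$c2) / (f$k3 * f$c5)
  rate_constants(c(
    a1 = a1, a2 = r[["a2"]] * k, a3 = f$a3, a4 = f$a4, a5 = r[["a5"]] * k,
    a6 = (a1 / f$k1 - f$a3) / (r[["a6"]] * z2), a7 = f$a7,
    b1 = b1, b2 = f$b2,
    b3 = (b1 / f$k2 - f$b2) / (r[["b3"]] * x1), b4 = f$b4,
    b5 = (b1 / f$k2 - f$b2) / (r[["b5"]] * z2), b6 = f$b6,
    c1 = c1, c2 = f$c2,
    c3 = (c1 / f$k3 - f$c2) / (r[["c3"]] * x1), c4 = r[["c4"]] * k,
    c5 = f$c5, c6 = f$c6, c7 = f$c7,
    k1 = f$k1, k2 = f$k2, k3 = f$k3
  ))
}

#' Check that a parameter set realizes genetic switching
#'
#' Simulates the model twice from the primed state across the inference
#' switch window (`k2* = 20` on `[500, 1500]` hours by default): once with
#' `mu = 1` (GATA switch — must commit to the erythroid attractor) and once
#' with `mu = 0` (GATA-2 knockdown with GATA-1 absent — must commit to the
#' myeloid attractor). Commitment means the endpoint lies within relative
#' distance `tol` of the attractor; classification uses only the endpoint,
#' so it is independent of the trajectory output resolution.
#'
#' @param params a [rate_constants()] vector with a primed state.
#' @param primed optional primed state (length-3 or steady-state object); if
#'   missing it is located with [find_primed_state()], and an error is raised
#'   when none exists.
#' @param k2_star,t_on,t_off switch window (defaults: the inference window).
#' @param t_end simulation horizon (default 3000 h, leaving 1500 h of
#'   relaxation after the window).
#' @param tol relative endpoint distance counted as commitment
#'   (default 0.01).
#' @return `TRUE`/`FALSE`, with attribute `"distances"` carrying the two
#'   endpoint distances.
#' @export
check_switching <- function(params, primed = NULL, k2_star = 20,
                            t_on = 500, t_off = 1500, t_end = 3000,
                            tol = 0.01) {
  if (is.null(primed)) primed <- find_primed_state(params)
  if (is.null(primed)) {
    stop("no primed state found; switching is checked from the primed state",
         call. = FALSE)
  }
  init <- state_vec(primed)
  ss <- analytic_steady_states(params)
  ery <- state_vec(ss$erythroid)
  mye <- state_vec(ss$myeloid)
  endpoint <- function(mu) {
    sch <- switch_schedule(k2_star, t_on, t_off, mu)
    tr <- simulate_ode(params, sch, init, t_end, n_out = 31)
    as.numeric(tr[nrow(tr), c("x", "y", "z")])
  }
  d_ery <- rel_dist(endpoint(1), ery)
  d_mye <- rel_dist(endpoint(0), mye)
  structure(d_ery < tol && d_mye < tol,
            distances = c(erythroid = d_ery, myeloid = d_mye))
}

#' Configuration of the staged genetic-algorithm inference
#'
#' @param population_size individuals per generation (>= 2; the full-scale
#'   study uses 1000, the scaled-down default 50).
#' @param n_generations generations to evolve (full scale 100, default 10).
#' @param seed master seed; the whole run is reproducible from it.
#' @param k synthesis scale factor passed to the sampler (default 1000).
#' @param crossover_prob probability of uniform crossover (default 0.8).
#' @param mutation_sd standard deviation of the Gaussian genome mutation
#'   (default 0.15; applied in genome space and clipped to
#'   `(1e-6, 1 - 1e-6)`).
#' @param tournament_size selection tournament size (default 3).
#' @param robustness_n perturbed parameter sets per robustness evaluation
#'   (full scale 1000, default 50).
#' @param robustness_sigma perturbation strength for the robustness stage
#'   (default 0.5).
#' @param elitism number of genome-distinct elites carried over unchanged
#'   (default 2).
#' @param plateau_generations generations without improvement after which the
#'   exploration response kicks in (default 2).
#' @param plateau_sd inflated mutation sd used while on a plateau
#'   (default 0.4).
#' @param n_immigrants fresh uniform genomes injected per generation while on
#'   a plateau (default 15).
#' @param primed_restarts Newton restarts for the primed-state search inside
#'   the penalty evaluation (default 60).
#' @param validation_trials perturbation-return trials per steady state in
#'   the validation stage (default 3).
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, n_generations = 10, seed = 1,
                      k = 1000, crossover_prob = 0.8, mutation_sd = 0.15,
                      tournament_size = 3, robustness_n = 50,
                      robustness_sigma = 0.5, elitism = 2,
                      plateau_generations = 2, plateau_sd = 0.4,
                      n_immigrants = 15, primed_restarts = 60,
                      validation_trials = 3) {
  stopifnot(population_size >= 2, n_generations >= 1, robustness_sigma > 0,
            robustness_n >= 1, k > 0, tournament_size >= 1, elitism >= 1)
  structure(list(population_size = population_size,
                 n_generations = n_generations, seed = as.integer(seed),
                 k = k, crossover_prob = crossover_prob,
                 mutation_sd = mutation_sd,
                 tournament_size = tournament_size,
                 robustness_n = robustness_n,
                 robustness_sigma = robustness_sigma, elitism = elitism,
                 plateau_generations = plateau_generations,
                 plateau_sd = plateau_sd, n_immigrants = n_immigrants,
                 primed_restarts = primed_restarts,
                 validation_trials = validation_trials),
            class = "ga_config")
}

penalty_score <- function(value, stage_failed, robustness_fraction = NA_real_) {
  structure(list(value = value, stage_failed = stage_failed,
                 robustness_fraction = robustness_fraction),
            class = "penalty_score")
}

#' @export
print.penalty_score <- function(x, ...) {
  cat(sprintf("<penalty_score> value = %g (stage failed: %s)\n",
              x$value, x$stage_failed))
  invisible(x)
}

#' Staged multi-objective penalty of a parameter set
#'
#' Scores a candidate against four ordered objectives. Each failed stage
#' dominates the maximal score of all later stages, so the penalty is:
#' \itemize{
#'   \item 4 — no strictly positive stable primed root exists (stage O1);
#'   \item 3 — the located steady states fail perturbation-return validation
#'     (stage O2);
#'   \item 2 — the model does not realize genetic switching (stage O3);
#'   \item otherwise the robustness fraction in `[0, 1]`: the proportion of
#'     multiplicatively perturbed parameter sets under which the model does
#'     NOT retain tristability (stage O4; smaller is more robust).
#' }
#' The same perturbation samples `U` are used for every candidate in a run so
#' robustness scores are comparable; with frozen `U` the score is a
#' deterministic function of the parameters.
#'
#' @param params a [rate_constants()] vector.
#' @param cfg a [ga_config()].
#' @param U optional 23 x `robustness_n` matrix of uniform samples; generated
#'   from `cfg$seed` when omitted (see [robustness_samples()]).
#' @return a `penalty_score` object: `value`, `stage_failed` (one of
#'   `"O1"`, `"O2"`, `"O3"`, `"none"`), and `robustness_fraction` (only
#'   meaningful when no stage failed).
#' @export
evaluate_penalty <- function(params, cfg = ga_config(), U = NULL) {
  if (is.null(U)) U <- robustness_samples(cfg$robustness_n, cfg$seed)
  primed <- find_primed_state(params, n_restarts = cfg$primed_restarts)
  if (is.null(primed)) return(penalty_score(4, "O1"))
  ss <- analytic_steady_states(params)
  states <- list(state_vec(primed), state_vec(ss$erythroid),
                 state_vec(ss$myeloid))
  ok <- vapply(states, function(s) {
    validate_steady_state_by_perturbation(params, s,
                                          n_trials = cfg$validation_trials)
  }, logical(1))
  if (!all(ok)) return(penalty_score(3, "O2"))
  if (!isTRUE(check_switching(params, primed))) {
    return(penalty_score(2, "O3"))
  }
  frac_keep <- tristability_fraction(params, sigma = cfg$robustness_sigma,
                                     U = U,
                                     warm_start = state_vec(primed))
  penalty_score(1 - frac_keep, "none", robustness_fraction = 1 - frac_keep)
}

#' Infer model parameters with the staged genetic algorithm
#'
#' Evolves populations of unit-interval genomes (see [unit_genome()]),
#' minimizing [evaluate_penalty()]. Mutation and crossover act on the genome
#' samples, never on model parameters, so every candidate satisfies the seven
#' stability constraints by construction. Selection is by tournament;
#' genome-distinct elites are carried over unchanged, which makes the best
#' penalty non-increasing across generations. When the best penalty
#' stagnates, the mutation scale is temporarily inflated and a few fresh
#' random genomes are injected to escape the flat plateau between the
#' switching stage and the robustness stage.
#'
#' @param cfg a [ga_config()].
#' @param fixed fixed constants for [sample_parameters()].
#' @return list with `params` (best [rate_constants()]), `genome`,
#'   `penalty` (a `penalty_score`), and `history` (data frame
#'   `generation, best, mean`; generation 0 is the initial population).
#' @export
#' @examples
#' \donttest{
#' fit <- run_ga(ga_config(population_size = 20, n_generations = 3, seed = 1))
#' fit$history
#' }
run_ga <- function(cfg = ga_config(), fixed = data_derived_constants()) {
  stopifnot(inherits(cfg, "ga_config"))
  set.seed(cfg$seed)
  U <- matrix(runif(23 * cfg$robustness_n), 23, cfg$robustness_n)
  pop <- cfg$population_size
  P <- matrix(runif(pop * 10, 1e-6, 1 - 1e-6), pop, 10)
  score_one <- function(r) {
    evaluate_penalty(sample_parameters(unit_genome(r, cfg$k), fixed), cfg, U)
  }
  scores <- apply(P, 1, score_one)
  fit <- vapply(scores, function(s) s$value, numeric(1))
  history <- data.frame(generation = 0, best = min(fit), mean = mean(fit))
  stall <- 0
  for (g in seq_len(cfg$n_generations)) {
    on_plateau <- stall >= cfg$plateau_generations
    sd_mut <- if (on_plateau) cfg$plateau_sd else cfg$mutation_sd
    n_imm <- if (on_plateau) min(cfg$n_immigrants, pop - cfg$elitism) else 0
    ord <- order(fit)
    keep <- ord[1]
    for (j in ord[-1]) {
      if (length(keep) >= cfg$elitism) break
      dist_ok <- all(vapply(keep, function(kk) {
        sqrt(sum((P[j, ] - P[kk, ])^2)) > 0.3
      }, logical(1)))
      if (dist_ok) keep <- c(keep, j)
    }
    newP <- P[keep, , drop = FALSE]
    new_scores <- scores[keep]
    while (nrow(newP) < pop - n_imm) {
      t1 <- sample.int(pop, cfg$tournament_size)
      t2 <- sample.int(pop, cfg$tournament_size)
      pa <- P[t1[which.min(fit[t1])], ]
      pb <- P[t2[which.min(fit[t2])], ]
      child <- if (runif(1) < cfg$crossover_prob) {
        ifelse(runif(10) < 0.5, pa, pb)
      } else pa
      child <- child + rnorm(10, 0, sd_mut)
      newP <- rbind(newP, pmin(pmax(child, 1e-6), 1 - 1e-6))
    }
    while (nrow(newP) < pop) {
      newP <- rbind(newP, runif(10, 1e-6, 1 - 1e-6))
    }
    fresh <- apply(newP[(length(keep) + 1):pop, , drop = FALSE], 1, score_one)
    P <- newP
    scores <- c(new_scores, fresh)
    prev_best <- min(fit)
    fit <- vapply(scores, function(s) s$value, numeric(1))
    stall <- if (min(fit) < prev_best - 1e-12) 0 else stall + 1
    history <- rbind(history,
                     data.frame(generation = g, best = min(fit),
                                mean = mean(fit)))
  }
  best <- which.min(fit)
  list(params = sample_parameters(unit_genome(P[best, ], cfg$k), fixed),
       genome = unit_genome(P[best, ], cfg$k),
       penalty = scores[[best]],
       history = history)
}
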