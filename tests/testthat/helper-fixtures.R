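# Shared fixtures, computed once per test session.

ref_params <- reference_params()

# Primed state of the reference set (deterministic from seed).
ref_primed <- find_primed_state(ref_params, seed = 1)
ref_primed_vec <- c(ref_primed$x, ref_primed$y, ref_primed$z)

ref_analytic <- analytic_steady_states(ref_params)
ref_ery <- c(ref_analytic$erythroid$x, 0, 0)
ref_mye <- c(0, 0, ref_analytic$myeloid$z)

# Relative Euclidean distance, the commitment metric used throughout.
rel_distance <- function(a, b) sqrt(sum((a - b)^2)) / max(1, sqrt(sum(b^2)))

# Random parameter sets with NO built-in constraints, for oracle comparisons:
# log-uniform coefficients over generous ranges.
random_free_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- exp(runif(23, log(1e-2), log(1e4)))
    names(v) <- c("a1", "a2", "a3", "a4", "a5", "a6", "a7",
                  "b1", "b2", "b3", "b4", "b5", "b6",
                  "c1", "c2", "c3", "c4", "c5", "c6", "c7",
                  "k1", "k2", "k3")
    v[c("k1", "k2", "k3")] <- exp(runif(3, log(0.05), log(5)))
    rate_constants(v)
  })
}

# Seven inequality margins of the constrained sampler (positive = satisfied).
constraint_margins <- function(p) {
  p <- as.list(unclass(p))
  x1 <- (p$a1 - p$k1 * p$a3) / (p$k1 * p$a4)
  z2 <- (p$c1 - p$k3 * p$c2) / (p$k3 * p$c5)
  c(trivial_a = p$a1 - p$a3 * p$k1,
    trivial_b = p$b1 - p$b2 * p$k2,
    trivial_c = p$c1 - p$c2 * p$k3,
    ery_b = p$k2 * (p$b2 + p$b3 * x1) - p$b1,
    ery_c = p$k3 * (p$c2 + p$c3 * x1) - p$c1,
    mye_a = p$k1 * (p$a3 + p$a6 * z2) - p$a1,
    mye_b = p$k2 * (p$b2 + p$b5 * z2) - p$b1)
}
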