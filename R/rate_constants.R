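#' Kinetic rate constants of the three-gene lineage-decision model
#'
#' Bundles the 23 rate constants of the GATA-1/GATA-2/PU.1 network into a
#' validated named vector. The model tracks the concentrations `x`, `y`, `z`
#' of GATA-1, GATA-2 and PU.1. Each gene is transcribed at a Shea-Ackers
#' rational rate (synthesis numerator over an occupancy-weighted denominator)
#' and degraded linearly:
#' \deqn{dx/dt = (a_1 x + a_2 y) / (a_3 + a_4 x + a_5 y + a_6 z + a_7 x z) - k_1 x}
#' \deqn{dy/dt = b_1 y / (b_2 + b_3 x + b_4 y + b_5 z + b_6 y z) - k_2 y}
#' \deqn{dz/dt = c_1 z / (c_2 + c_3 x + c_4 y + c_5 z + c_6 x z + c_7 y z) - k_3 z}
#' Basal expression is assumed zero, so the origin is always a fixed point.
#'
#' @param values a named numeric vector or list with entries
#'   `a1..a7`, `b1..b6`, `c1..c7`, `k1..k3`. All must be finite and
#'   non-negative.
#' @param inference_constraints if `TRUE`, additionally require
#'   `a3 = b2 = c2 = 1` (the normalization used during parameter inference).
#' @param equality_constraints if `TRUE`, additionally require `b6 = a7` and
#'   `c7 = c6` (GATA-1 and GATA-2 share DNA binding sites, and the PU.1
#'   promoter binds its two repressing complexes at the same rate).
#'
#' @return a named numeric vector of length 23 with class `rate_constants`.
#' @seealso [reference_params()] for the published estimate shipped with the
#'   package, [sample_parameters()] for the constraint-satisfying sampler.
#' @export
#' @examples
#' p <- reference_params()
#' rate_constants(p)  # revalidates
rate_constants <- function(values, inference_constraints = FALSE,
                           equality_constraints = FALSE) {
  values <- unlist(values)
  if (!is.numeric(values)) {
    stop("rate constants must be numeric", call. = FALSE)
  }
  missing <- setdiff(PARAM_NAMES, names(values))
  if (length(missing)) {
    stop("missing rate constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- values[PARAM_NAMES]
  bad <- PARAM_NAMES[!is.finite(p) | p < 0]
  if (length(bad)) {
    stop("rate constants must be finite and >= 0; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (inference_constraints &&
      !isTRUE(all(p[c("a3", "b2", "c2")] == 1))) {
    stop("inference mode requires a3 = b2 = c2 = 1", call. = FALSE)
  }
  if (equality_constraints) {
    if (p[["b6"]] != p[["a7"]]) {
      stop("equality constraint violated: b6 must equal a7", call. = FALSE)
    }
    if (p[["c7"]] != p[["c6"]]) {
      stop("equality constraint violated: c7 must equal c6", call. = FALSE)
    }
  }
  structure(p, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> 23 kinetic parameters\n")
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Published reference parameter estimate
#'
#' The 23-parameter estimate, obtained by the staged genetic-algorithm
#' inference, under which the deterministic model is tristable (erythroid,
#' myeloid and primed attractors all stable) and realizes genetic switching.
#' This set is also shipped as a JSON fixture under
#' `system.file("extdata", "reference_params.json", package = "gataswitch")`.
#'
#' @return a [rate_constants()] vector.
#' @export
#' @examples
#' p <- reference_params()
#' analytic_steady_states(p)
reference_params <- function() {
  rate_constants(c(
    a1 = 731.7409, a2 = 856.1247, a3 = 1, a4 = 1.6, a5 = 398.9719,
    a6 = 44.8982, a7 = 53.0,
    b1 = 18470.6419, b2 = 1, b3 = 37.3615, b4 = 942.1939, b5 = 55.0375,
    b6 = 53.0,
    c1 = 12391.1968, c2 = 1, c3 = 710.4490, c4 = 522.4385, c5 = 170.0,
    c6 = 1700.0, c7 = 1700.0,
    k1 = 0.6931, k2 = 1.3863, k3 = 0.2888
  ))
}

#' Degradation rate from a protein half-life
#'
#' Converts a first-order decay half-life to the corresponding rate constant,
#' `log(2) / half_life`. The degradation rates of the three model proteins
#' derive from measured half-lives: GATA-1 one hour, GATA-2 thirty minutes,
#' PU.1 about 2.4 hours.
#'
#' @param half_life protein half-life in hours; must be positive.
#' @return degradation rate in events per hour.
#' @export
#' @examples
#' derive_degradation_rate(1)    # 0.6931 (GATA-1)
#' derive_degradation_rate(0.5)  # 1.3863 (GATA-2)
#' derive_degradation_rate(2.4)  # 0.2888 (PU.1)
derive_degradation_rate <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) ||
      any(half_life <= 0)) {
    stop("half_life must be a positive finite number (hours)", call. = FALSE)
  }
  log(2) / half_life
}

#' The data-derived parameter subset held fixed during inference
#'
#' Nine coefficients plus the three degradation rates are pinned by
#' experimental measurements and by the inference normalization, leaving ten
#' free degrees of freedom for the genome of [sample_parameters()]:
#' `a3 = b2 = c2 = 1` (normalization), `a4`, `a7`, `b4`, `c5`, `c6`
#' (promoter binding terms), the equalities `b6 = a7` and `c7 = c6`, and the
#' half-life-derived `k1`, `k2`, `k3`.
#'
#' @return named numeric vector of the 13 fixed entries.
#' @export
data_derived_constants <- function() {
  c(a3 = 1, b2 = 1, c2 = 1,
    a4 = 1.6, a7 = 53.0, b4 = 942.1939, b6 = 53.0,
    c5 = 170.0, c6 = 1700.0, c7 = 1700.0,
    k1 = 0.6931, k2 = 1.3863, k3 = 0.2888)
}

# Strip class/names for the C++ core, which expects the canonical order.
param_vector <- function(params) {
  as.numeric(unclass(params)[PARAM_NAMES])
}
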