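#' Time-windowed GATA-switch schedule
#'
#' The GATA switch — displacement of GATA-2 by GATA-1 at shared chromatin
#' sites — is modelled as a transient extra degradation of GATA-2: the rate
#' `k2_star` applies on the closed window `[t_on, t_off]` and is zero
#' elsewhere. The displaced GATA-2 feeds GATA-1 synthesis through the coupled
#' term `mu * k2_star * y` in the GATA-1 equation; `mu` scales the
#' availability of GATA-1 at the vacated sites. `mu = 0` encodes a GATA-2
#' knockdown with GATA-1 absent, `mu > 0` a GATA switch.
#'
#' @param k2_star extra GATA-2 degradation rate during the window (per hour,
#'   >= 0).
#' @param t_on,t_off window boundaries in hours, `t_on < t_off`.
#' @param mu GATA-1 availability factor (dimensionless, >= 0).
#' @return an object of class `switch_schedule`.
#' @seealso [schedule_value()], [schedule_preset()]
#' @export
#' @examples
#' sch <- switch_schedule(k2_star = 6, t_on = 500, t_off = 1500, mu = 1)
#' schedule_value(sch, c(0, 500, 1000, 1500, 2000))
switch_schedule <- function(k2_star, t_on, t_off, mu = 1) {
  stopifnot(is.numeric(k2_star), length(k2_star) == 1, is.finite(k2_star),
            k2_star >= 0,
            is.numeric(t_on), length(t_on) == 1, is.finite(t_on),
            is.numeric(t_off), length(t_off) == 1, is.finite(t_off),
            is.numeric(mu), length(mu) == 1, is.finite(mu), mu >= 0)
  if (t_on >= t_off) stop("t_on must be < t_off", call. = FALSE)
  structure(list(k2_star = k2_star, t_on = t_on, t_off = t_off, mu = mu),
            class = "switch_schedule")
}

#' @export
print.switch_schedule <- function(x, ...) {
  cat(sprintf("<switch_schedule> k2* = %g on [%g, %g] h, mu = %g\n",
              x$k2_star, x$t_on, x$t_off, x$mu))
  invisible(x)
}

#' Evaluate the scheduled GATA-2 degradation rate at given times
#'
#' @param schedule a [switch_schedule()].
#' @param t time or vector of times (hours, >= 0).
#' @return `k2_star` inside the closed window `[t_on, t_off]`, 0 outside.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "switch_schedule"), is.numeric(t), all(t >= 0))
  ifelse(t >= schedule$t_on & t <= schedule$t_off, schedule$k2_star, 0)
}

#' Switch-schedule presets used across the analyses
#'
#' Three window magnitudes recur in the analyses and ship as presets:
#' \describe{
#'   \item{`"ode"`}{`k2* = 6` on `[500, 1500]` — the deterministic switching
#'     scenarios.}
#'   \item{`"inference"`}{`k2* = 20` on `[500, 1500]` — the switching
#'     validation stage of the parameter-inference procedure.}
#'   \item{`"stochastic"`}{`k2* = 25` on `[50, 200]` — the shorter window
#'     used by the stochastic ensembles.}
#' }
#'
#' @param name one of `"ode"`, `"inference"`, `"stochastic"`.
#' @param mu GATA-1 availability factor, default 1.
#' @return a [switch_schedule()].
#' @export
#' @examples
#' schedule_preset("stochastic", mu = 0.28)
schedule_preset <- function(name = c("ode", "inference", "stochastic"),
                            mu = 1) {
  name <- match.arg(name)
  switch(name,
    ode        = switch_schedule(6,  500, 1500, mu),
    inference  = switch_schedule(20, 500, 1500, mu),
    stochastic = switch_schedule(25, 50,  200,  mu)
  )
}

# Internal: schedule with the window switched off entirely.
null_schedule <- function() switch_schedule(0, 0, 1, 0)
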