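#' @useDynLib symregpk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rbinom optim nlminb setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' PK rate-constant parameter vector
#'
#' Constructs the parameter vector of the three-compartment mammillary model
#' in its rate-constant parameterization: first-order transfer rates
#' `k10, k12, k13, k21, k31` (1/s) and the central compartment volume `V1`
#' (L).  Elimination (`k10`) occurs from the central compartment, which is
#' also where drug is infused and plasma concentration is observed.
#'
#' @param k10,k12,k13,k21,k31 transfer rate constants, 1/s; strictly positive.
#' @param V1 central compartment volume, L; strictly positive.
#' @return An object of class `pk_rates`: a named numeric vector of length 6.
#' @examples
#' p <- pk_rates(0.1, 0.2, 0.05, 0.1, 0.05, 10)
#' rates_to_clearances(p)
#' @export
pk_rates <- function(k10, k12, k13, k21, k31, V1) {
  p <- c(k10 = k10, k12 = k12, k13 = k13, k21 = k21, k31 = k31, V1 = V1)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("invalid PK parameters: all rate constants and V1 must be strictly positive and finite")
  structure(p, class = "pk_rates")
}

# internal constructor without the positivity check (network outputs can touch
# the |.| kink at zero; simulation wrappers floor the values instead)
new_pk_rates <- function(p) {
  structure(setNames(as.numeric(p),
                     c("k10", "k12", "k13", "k21", "k31", "V1")),
            class = "pk_rates")
}

#' @export
print.pk_rates <- function(x, ...) {
  cat("Three-compartment PK rates [1/s], V1 [L]:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' PK clearance/volume parameter vector
#'
#' The common alternative parameterization: elimination clearance `CL` and
#' inter-compartmental clearances `Q2`, `Q3` (L/s), with compartment volumes
#' `V1`, `V2`, `V3` (L).
#'
#' @param CL,Q2,Q3 clearances, L/s; strictly positive.
#' @param V1,V2,V3 compartment volumes, L; strictly positive.
#' @return An object of class `pk_clearances` (named numeric vector).
#' @export
pk_clearances <- function(CL, Q2, Q3, V1, V2, V3) {
  p <- c(CL = CL, Q2 = Q2, Q3 = Q3, V1 = V1, V2 = V2, V3 = V3)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("invalid PK parameters: all clearances and volumes must be strictly positive and finite")
  structure(p, class = "pk_clearances")
}

#' Convert rate constants to clearances/volumes
#'
#' `CL = k10 V1`, `Q2 = k12 V1`, `Q3 = k13 V1`, `V2 = (k12/k21) V1`,
#' `V3 = (k13/k31) V1`.
#'
#' @param p a [pk_rates] object.
#' @return A [pk_clearances] object.
#' @export
rates_to_clearances <- function(p) {
  if (!inherits(p, "pk_rates")) p <- do.call(pk_rates, as.list(p))
  pk_clearances(CL = p[["k10"]] * p[["V1"]],
                Q2 = p[["k12"]] * p[["V1"]],
                Q3 = p[["k13"]] * p[["V1"]],
                V1 = p[["V1"]],
                V2 = p[["k12"]] / p[["k21"]] * p[["V1"]],
                V3 = p[["k13"]] / p[["k31"]] * p[["V1"]])
}

#' Convert clearances/volumes to rate constants
#'
#' Inverse of [rates_to_clearances()]: `k10 = CL/V1`, `k12 = Q2/V1`,
#' `k13 = Q3/V1`, `k21 = Q2/V2`, `k31 = Q3/V3`.
#'
#' @param c a [pk_clearances] object.
#' @return A [pk_rates] object.
#' @export
clearances_to_rates <- function(c) {
  if (!inherits(c, "pk_clearances")) c <- do.call(pk_clearances, as.list(c))
  pk_rates(k10 = c[["CL"]] / c[["V1"]],
           k12 = c[["Q2"]] / c[["V1"]],
           k13 = c[["Q3"]] / c[["V1"]],
           k21 = c[["Q2"]] / c[["V2"]],
           k31 = c[["Q3"]] / c[["V3"]],
           V1 = c[["V1"]])
}

#' Piecewise-constant infusion profile
#'
#' Event `j` sets the infusion rate to `rates[j]` (ug/s) at `times[j]`
#' (seconds); the rate holds until the next event.  Before the first event the
#' rate is zero.  Bolus doses are represented upstream as short high-rate
#' infusions; the simulator only supports zero-order input.
#'
#' @param times strictly increasing event times, s; first event at `>= 0`.
#' @param rates non-negative infusion rates, ug/s, one per event.
#' @return An object of class `pk_dosing`.
#' @export
dosing_profile <- function(times, rates) {
  times <- as.numeric(times); rates <- as.numeric(rates)
  if (length(times) != length(rates))
    stop("times and rates must have equal length")
  if (length(times) == 0L) stop("dosing profile needs at least one event")
  if (any(!is.finite(times)) || any(!is.finite(rates)))
    stop("dosing events must be finite")
  if (times[1] < 0) stop("first dose event time must be >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("dose event times must be strictly increasing")
  if (any(rates < 0)) stop("infusion rates must be non-negative")
  structure(list(times = times, rates = rates), class = "pk_dosing")
}

#' @export
print.pk_dosing <- function(x, ...) {
  cat(sprintf("Infusion profile: %d events, t in [%g, %g] s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate plasma concentration under piecewise-constant infusion
#'
#' Exact simulation of the three-compartment mammillary model: between dose
#' events the system is linear time-invariant, and the state is advanced with
#' the matrix exponential of the augmented system matrix (zero-order-hold
#' discretization).  Observation times are merged into the event grid, so
#' concentrations are evaluated exactly, never interpolated.  The initial
#' state is zero drug in all compartments at `t = 0`.
#'
#' @param p a [pk_rates] object.
#' @param dosing a [dosing_profile] object.
#' @param obs_times observation times, s, all `>= 0` (any order).
#' @return Numeric vector of central-compartment concentrations (ug/L), one
#'   per observation time, in the input order.
#' @seealso [pk_simulate_jacobian()] for parameter derivatives.
#' @examples
#' p <- pk_rates(0.01, 0.005, 0.001, 0.003, 0.0005, 10)
#' d <- dosing_profile(c(0, 600), c(100, 0))
#' pk_simulate(p, d, c(60, 300, 600, 1200))
#' @export
pk_simulate <- function(p, dosing, obs_times) {
  if (!inherits(p, "pk_rates")) p <- do.call(pk_rates, as.list(p))
  stopifnot(inherits(dosing, "pk_dosing"))
  obs_times <- as.numeric(obs_times)
  if (any(!is.finite(obs_times)) || any(obs_times < 0))
    stop("observation times must be finite and >= 0")
  ord <- order(obs_times)
  sorted <- as.numeric(.sim_cpp(as.numeric(p), dosing$times, dosing$rates,
                                obs_times[ord]))
  out <- numeric(length(sorted))
  out[ord] <- sorted
  out
}

#' Concentration and its parameter Jacobian
#'
#' Same exact discretization as [pk_simulate()], with derivatives of each
#' concentration with respect to the six PK parameters computed by the
#' complex-step method (exact to machine precision).  This is the
#' differentiability contract consumed by the training module.
#'
#' @inheritParams pk_simulate
#' @return A list with `conc` (numeric vector) and `jac` (matrix, one row per
#'   observation, columns `k10, k12, k13, k21, k31, V1`).
#' @export
pk_simulate_jacobian <- function(p, dosing, obs_times) {
  if (!inherits(p, "pk_rates")) p <- do.call(pk_rates, as.list(p))
  stopifnot(inherits(dosing, "pk_dosing"))
  obs_times <- as.numeric(obs_times)
  if (any(!is.finite(obs_times)) || any(obs_times < 0))
    stop("observation times must be finite and >= 0")
  ord <- order(obs_times)
  res <- .sim_jac_cpp(as.numeric(p), dosing$times, dosing$rates,
                      obs_times[ord])
  conc <- numeric(length(obs_times))
  conc[ord] <- as.numeric(res$conc)
  jac <- matrix(0, length(obs_times), 6,
                dimnames = list(NULL, c("k10", "k12", "k13", "k21", "k31",
                                        "V1")))
  jac[ord, ] <- res$jac
  list(conc = conc, jac = jac)
}

#' Steady-state central concentration under constant infusion
#'
#' Setting all derivatives of the mammillary model to zero gives the mass
#' balance `u = k10 V1 x1`, so the steady-state concentration is
#' `u / (k10 V1)` regardless of the peripheral compartments.
#'
#' @param p a [pk_rates] object.
#' @param u constant infusion rate, ug/s, `>= 0`.
#' @return Steady-state concentration, ug/L.
#' @export
steady_state_concentration <- function(p, u) {
  if (!inherits(p, "pk_rates")) p <- do.call(pk_rates, as.list(p))
  if (!is.finite(u) || u < 0) stop("infusion rate must be finite and >= 0")
  u / (p[["k10"]] * p[["V1"]])
}
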