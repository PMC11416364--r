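#' Per-sample logarithmic error
#'
#' `LE = ln(C_obs / C_pred)`, the dimensionless log ratio of observed to
#' predicted concentration.  Positive LE means the model under-predicts.
#'
#' @param c_obs,c_pred observed and predicted concentrations, ug/L; both must
#'   be strictly positive (log errors are undefined otherwise).
#' @return Numeric vector of log errors.
#' @export
log_error <- function(c_obs, c_pred) {
  if (any(!is.finite(c_obs)) || any(!is.finite(c_pred)) ||
      any(c_obs <= 0) || any(c_pred <= 0))
    stop("log errors require strictly positive concentrations")
  log(c_obs / c_pred)
}

#' Per-sample prediction error (percent)
#'
#' `PE = 100 (C_obs - C_pred) / C_pred`.  When `C_pred` is exactly zero the
#' error is set to zero to avoid division by zero.
#'
#' @param c_obs,c_pred observed and predicted concentrations, ug/L, `>= 0`.
#' @return Numeric vector of percent errors.
#' @export
prediction_error <- function(c_obs, c_pred) {
  if (any(!is.finite(c_obs)) || any(!is.finite(c_pred)) ||
      any(c_obs < 0) || any(c_pred < 0))
    stop("prediction errors require finite non-negative concentrations")
  ifelse(c_pred == 0, 0, 100 * (c_obs - c_pred) / c_pred)
}

#' Per-sample error table
#'
#' Computes LE, ALE (= |LE|), PE, and APE (= |PE|) for paired observation and
#' prediction vectors.
#'
#' @inheritParams log_error
#' @return A data frame with columns `le`, `ale`, `pe`, `ape`.
#' @export
sample_errors <- function(c_obs, c_pred) {
  le <- log_error(c_obs, c_pred)
  pe <- prediction_error(c_obs, c_pred)
  data.frame(le = le, ale = abs(le), pe = pe, ape = abs(pe))
}

#' Per-individual median errors
#'
#' Medians over an individual's samples of the four per-sample errors,
#' yielding MdALE, MdLE, MdAPE and MdPE.  An even sample count uses the mean
#' of the two central order statistics (the [stats::median()] convention).
#'
#' @param c_obs,c_pred observed and predicted concentrations at shared times.
#' @param id optional individual identifier carried into the result.
#' @return A list of class `individual_error` with fields `individual_id`,
#'   `md_ale`, `md_le`, `md_ape`, `md_pe`, `n_obs`.
#' @export
individual_medians <- function(c_obs, c_pred, id = NA) {
  if (length(c_obs) == 0L) stop("individual has no observations")
  if (length(c_obs) != length(c_pred))
    stop("observed and predicted series must have equal length")
  e <- sample_errors(c_obs, c_pred)
  structure(list(individual_id = id,
                 md_ale = median(e$ale), md_le = median(e$le),
                 md_ape = median(e$ape), md_pe = median(e$pe),
                 n_obs = length(c_obs)),
            class = "individual_error")
}

#' Population loss J_ALE
#'
#' The training loss: the unweighted mean over individuals of their median
#' absolute logarithmic errors, `J_ALE = (1/n) sum_i MdALE_i`.
#'
#' @param individual_errors either a list of `individual_error` objects or a
#'   numeric vector of per-individual MdALE values.
#' @return A list with `j_ale` and `n_individuals`.
#' @export
population_loss <- function(individual_errors) {
  if (is.numeric(individual_errors)) {
    md <- individual_errors
  } else {
    md <- vapply(individual_errors, function(e) e$md_ale, numeric(1))
  }
  if (length(md) == 0L) stop("population loss requires at least one individual")
  list(j_ale = mean(md), n_individuals = length(md))
}

#' Clinically acceptable log-error bounds
#'
#' The conventional clinically acceptable ranges for per-individual median
#' prediction errors are 10-20 % for bias (MdPE) and 20-40 % for accuracy
#' (MdAPE).  On the log-error scale these translate to `ln(1.20)` and
#' `ln(1.40)`, conventionally rounded to two decimals: 0.18 and 0.34.
#'
#' @param rounded if `FALSE`, return the unrounded `ln(1.2)`, `ln(1.4)`.
#' @return Named numeric vector `c(le_bound =, ale_bound =)`.
#' @export
clinical_bounds <- function(rounded = TRUE) {
  b <- c(le_bound = log(1.20), ale_bound = log(1.40))
  if (rounded) round(b, 2) else b
}
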