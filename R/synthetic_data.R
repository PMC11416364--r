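## Synthetic cohort generator: covariates spanning the demonstrator study's
## ranges, a bolus-plus-maintenance step infusion template, log-spaced
## sampling, and multiplicative lognormal observation noise (the natural
## companion of a log-ratio loss).

#' Cohort generator configuration
#'
#' Defaults emulate the demonstrator propofol study population: ages 0-88
#' years, weights 0.68-160 kg, BMI 6.2-52.8 kg/m^2, 65 % male, 70 % arterial
#' sampling.  Dosing is a weight-based induction bolus delivered as a short
#' high-rate infusion followed by a maintenance infusion with a mid-course
#' step change and a washout phase; observations are log-spaced during the
#' infusion plus decay samples after it.
#'
#' @param n_individuals cohort size.
#' @param age_range,wgt_range,bmi_range covariate ranges (years, kg, kg/m^2).
#' @param p_male,p_arterial category probabilities.
#' @param bmi_wgt_cor mixing weight in `[0, 1]` tying the BMI draw to the
#'   weight draw (0 = independent).
#' @param bolus_mg_per_kg,bolus_duration_s induction bolus (mg/kg over s).
#' @param maintenance_mg_kg_h maintenance infusion rate (mg/kg/h).
#' @param step_factor multiplier applied to the maintenance rate halfway
#'   through the infusion (a step change).
#' @param infusion_duration_s,total_duration_s infusion end and study end, s.
#' @param n_obs observations per individual.
#' @param noise_sd standard deviation of the lognormal observation noise on
#'   the log scale (multiplicative).
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 100,
                          age_range = c(0, 88), wgt_range = c(0.68, 160),
                          bmi_range = c(6.2, 52.8),
                          p_male = 670 / 1031, p_arterial = 727 / 1033,
                          bmi_wgt_cor = 0.3,
                          bolus_mg_per_kg = 2, bolus_duration_s = 30,
                          maintenance_mg_kg_h = 6, step_factor = 0.5,
                          infusion_duration_s = 3600,
                          total_duration_s = 7200,
                          n_obs = 10, noise_sd = 0.15, seed = 1) {
  stopifnot(n_individuals >= 1, noise_sd >= 0, n_obs >= 2,
            bmi_wgt_cor >= 0, bmi_wgt_cor <= 1,
            infusion_duration_s > bolus_duration_s,
            total_duration_s >= infusion_duration_s)
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample a covariate cohort
#'
#' Continuous covariates are uniform over the configured ranges (BMI
#' optionally rank-tied to weight through `bmi_wgt_cor`); gender and
#' sampling site are Bernoulli draws.  Seeded and reproducible.
#'
#' @param cfg a [cohort_config].
#' @return Data frame with columns `id`, `age`, `wgt`, `bmi`, `gender`,
#'   `site`.
#' @export
sample_cohort <- function(cfg = cohort_config()) {
  set.seed(as.integer(cfg$seed))
  n <- cfg$n_individuals
  u_w <- runif(n)
  u_b <- pmin(pmax(cfg$bmi_wgt_cor * u_w +
                     (1 - cfg$bmi_wgt_cor) * runif(n), 0), 1)
  data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = cfg$age_range[1] + runif(n) * diff(cfg$age_range),
    wgt = cfg$wgt_range[1] + u_w * diff(cfg$wgt_range),
    bmi = cfg$bmi_range[1] + u_b * diff(cfg$bmi_range),
    gender = ifelse(rbinom(n, 1, cfg$p_male) == 1, "M", "F"),
    site = ifelse(rbinom(n, 1, cfg$p_arterial) == 1, "A", "V"),
    stringsAsFactors = FALSE)
}

# weight-based step infusion template (rates in ug/s)
template_dosing <- function(wgt, cfg) {
  bolus_rate <- cfg$bolus_mg_per_kg * 1000 * wgt / cfg$bolus_duration_s
  maint_rate <- cfg$maintenance_mg_kg_h * 1000 * wgt / 3600
  t_step <- cfg$bolus_duration_s +
    (cfg$infusion_duration_s - cfg$bolus_duration_s) / 2
  dosing_profile(
    times = c(0, cfg$bolus_duration_s, t_step, cfg$infusion_duration_s),
    rates = c(bolus_rate, maint_rate, maint_rate * cfg$step_factor, 0))
}

# log-spaced sampling during the infusion plus washout decay samples; the
# first sample sits right after the induction bolus, where the central
# volume is still visible before redistribution
template_obs_times <- function(cfg) {
  n_inf <- ceiling(cfg$n_obs * 0.6)
  n_post <- cfg$n_obs - n_inf
  t_inf <- exp(seq(log(cfg$bolus_duration_s + 2),
                   log(cfg$infusion_duration_s), length.out = n_inf))
  if (n_post > 0) {
    t_post <- cfg$infusion_duration_s +
      exp(seq(log(60), log(cfg$total_duration_s - cfg$infusion_duration_s),
              length.out = n_post))
  } else t_post <- numeric(0)
  round(c(t_inf, t_post))
}

#' Generate a synthetic dataset from a known covariate model
#'
#' For each cohort member the true covariate model supplies PK parameters,
#' the dosing template is simulated exactly, and observations are corrupted
#' with independent multiplicative lognormal noise:
#' `C_obs = C_pred * exp(e)`, `e ~ N(0, sd^2)`.  Observation times where the
#' true concentration is zero are excluded.
#'
#' @param cohort a data frame from [sample_cohort()] (or `NULL` to sample
#'   one from `cfg`).
#' @param true_model either `"published"` (the bundled propofol covariate
#'   model), a function `f(age, wgt, bmi, gender, site)` returning a
#'   [pk_rates], or a named list of expression trees.
#' @param cfg a [cohort_config].
#' @return A `pk_dataset` with a `ground_truth` attribute holding the
#'   per-individual true parameters and the generator manifest.
#' @export
generate_dataset <- function(cohort = NULL, true_model = "published",
                             cfg = cohort_config()) {
  if (is.null(cohort)) cohort <- sample_cohort(cfg)
  model_fn <- resolve_model(true_model)
  set.seed(as.integer(cfg$seed) + 1L)  # noise stream distinct from cohort
  obs_times <- template_obs_times(cfg)
  inds <- vector("list", nrow(cohort))
  truth <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cv <- cohort[i, ]
    th <- model_fn(cv$age, cv$wgt, cv$bmi, cv$gender, cv$site)
    if (any(as.numeric(th) <= 0))
      stop("true model produced non-positive PK parameters for individual ",
           cv$id)
    dosing <- template_dosing(cv$wgt, cfg)
    cpred <- pk_simulate(th, dosing, obs_times)
    keep <- cpred > 0
    eps <- rnorm(sum(keep), 0, cfg$noise_sd)
    inds[[i]] <- list(id = cv$id, age = cv$age, wgt = cv$wgt, bmi = cv$bmi,
                      gender = cv$gender, site = cv$site, dosing = dosing,
                      obs = data.frame(time = obs_times[keep],
                                       conc = cpred[keep] * exp(eps)))
    truth[[i]] <- th
  }
  names(truth) <- cohort$id
  ds <- new_dataset(inds, normalization_spec(),
                    provenance = "synthetic")
  ds$ground_truth <- list(model = true_model, parameters = truth,
                          manifest = unclass(cfg))
  ds
}

resolve_model <- function(true_model) {
  if (is.function(true_model)) return(true_model)
  if (identical(true_model, "published"))
    return(function(age, wgt, bmi, gender, site)
      published_model(age, wgt, bmi, gender, site))
  if (is.list(true_model)) {
    spec <- attr(true_model, "spec")
    if (is.null(spec)) spec <- normalization_spec()
    return(function(age, wgt, bmi, gender, site) {
      th <- vapply(true_model, evaluate_expression, numeric(1), age = age,
                   wgt = wgt, bmi = bmi, gender = gender, site = site,
                   spec = spec)
      new_pk_rates(th)
    })
  }
  stop("true_model must be 'published', a function, or expression trees")
}

#' Merge close dose events
#'
#' Consecutive rate-change events closer than `dt_min` in time or differing
#' by less than `rate_min` in rate are merged: the earlier event's time is
#' kept, the later event's rate wins.  The operation is idempotent.  This is
#' the standard preprocessing applied to the demonstrator data set
#' (defaults: 1 s, 0.5 ug/s).
#'
#' @param profile a [dosing_profile].
#' @param dt_min time tolerance, s.
#' @param rate_min rate tolerance, ug/s.
#' @return A merged [dosing_profile].
#' @export
merge_close_doses <- function(profile, dt_min = 1, rate_min = 0.5) {
  stopifnot(inherits(profile, "pk_dosing"))
  one_pass <- function(times, rates) {
    kt <- times[1]; kr <- rates[1]
    out_t <- numeric(0); out_r <- numeric(0)
    for (j in seq_along(times)[-1]) {
      if (times[j] - kt < dt_min || abs(rates[j] - kr) < rate_min) {
        kr <- rates[j]          # keep earlier time, later rate
      } else {
        out_t <- c(out_t, kt); out_r <- c(out_r, kr)
        kt <- times[j]; kr <- rates[j]
      }
    }
    list(times = c(out_t, kt), rates = c(out_r, kr))
  }
  cur <- list(times = profile$times, rates = profile$rates)
  repeat {                      # iterate to a fixpoint so merging is idempotent
    nxt <- one_pass(cur$times, cur$rates)
    if (length(nxt$times) == length(cur$times)) break
    cur <- nxt
  }
  dosing_profile(cur$times, cur$rates)
}
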