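# Independent oracles and fixture builders used across the suite.

# Adaptive Dormand-Prince RK45 integration of the three-compartment ODE under
# piecewise-constant infusion -- deliberately independent of the package's
# matrix-exponential path.
ode_oracle <- function(p, dosing, obs_times, tol = 1e-10) {
  p <- as.numeric(p)
  k10 <- p[1]; k12 <- p[2]; k13 <- p[3]; k21 <- p[4]; k31 <- p[5]; V1 <- p[6]
  rhs <- function(x, u) {
    c(-(k10 + k12 + k13) * x[1] + k21 * x[2] + k31 * x[3] + u / V1,
      k12 * x[1] - k21 * x[2],
      k13 * x[1] - k31 * x[3])
  }
  # Dormand-Prince coefficients
  a <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  step_to <- function(x, u, t0, t1) {
    t <- t0
    h <- max((t1 - t0) / 10, 1e-8)
    while (t < t1) {
      h <- min(h, t1 - t)
      k <- matrix(0, 3, 7)
      k[, 1] <- rhs(x, u)
      for (s in 1:5)
        k[, s + 1] <- rhs(x + h * as.numeric(k[, 1:s, drop = FALSE] %*%
                                               a[[s]]), u)
      x5 <- x + h * as.numeric(k[, 1:6, drop = FALSE] %*% a[[6]])
      k[, 7] <- rhs(x5, u)
      x4 <- x + h * as.numeric(k %*% b4)
      err <- max(abs(x5 - x4) / pmax(abs(x5), 1))
      if (err <= tol || h < 1e-10) {
        t <- t + h
        x <- x + h * as.numeric(k %*% b5)
      }
      h <- h * min(5, max(0.2, 0.9 * (tol / max(err, 1e-16))^0.2))
    }
    x
  }
  obs_sorted <- sort(obs_times)
  brk <- sort(unique(c(dosing$times, obs_sorted)))
  x <- c(0, 0, 0)
  t <- 0
  u <- 0
  ie <- 1
  out <- setNames(numeric(length(obs_sorted)), NULL)
  for (tb in brk) {
    if (tb > t) {
      x <- step_to(x, u, t, tb)
      t <- tb
    }
    while (ie <= length(dosing$times) && dosing$times[ie] <= t) {
      u <- dosing$rates[ie]
      ie <- ie + 1
    }
    out[obs_sorted == tb] <- x[1]
  }
  out[match(obs_times, obs_sorted)]
}

# random valid parameter vector with realistic scales
random_pk_rates <- function() {
  pk_rates(k10 = exp(runif(1, log(1e-3), log(0.05))),
           k12 = exp(runif(1, log(1e-3), log(0.5))),
           k13 = exp(runif(1, log(1e-4), log(0.05))),
           k21 = exp(runif(1, log(1e-3), log(0.05))),
           k31 = exp(runif(1, log(1e-4), log(5e-3))),
           V1 = exp(runif(1, log(0.5), log(50))))
}

random_dosing <- function(n_events = 4) {
  times <- sort(runif(n_events, 0, 3000))
  times[1] <- 0
  dosing_profile(times, c(runif(n_events - 1, 0, 500), 0))
}

# small in-class generator: k10 and V1 affine in normalized weight, the
# remaining parameters constant
inclass_model <- function(age, wgt, bmi, gender, site) {
  w <- wgt / 160
  pk_rates(0.004 * w + 0.003, 0.01, 0.001, 0.005, 2e-4, 15 * w + 0.5)
}

small_dataset <- function(n = 8, seed = 3, noise_sd = 0.15, n_obs = 7,
                          model = "published") {
  generate_dataset(true_model = model,
                   cfg = cohort_config(n_individuals = n, seed = seed,
                                       n_obs = n_obs, noise_sd = noise_sd))
}

# a bank hand-wired to the identity path: theta = |w * phi[j] + b| for
# chosen network entries; all other weights zero
handwired_bank <- function(wiring) {
  bank <- init_bank(1)
  for (nm in names(bank$networks)) {
    for (li in 1:3) {
      lay <- bank$networks[[nm]]$layers[[li]]
      lay$W[] <- 0
      lay$b[] <- 0
      bank$networks[[nm]]$layers[[li]] <- lay
    }
    w <- wiring[[nm]]
    l1 <- bank$networks[[nm]]$layers[[1]]
    if (!is.null(w$cov)) l1$W[1, w$cov] <- w$slope
    l1$b[1] <- w$intercept
    bank$networks[[nm]]$layers[[1]] <- l1
    l2 <- bank$networks[[nm]]$layers[[2]]
    l2$W[1, 1] <- 1
    bank$networks[[nm]]$layers[[2]] <- l2
    l3 <- bank$networks[[nm]]$layers[[3]]
    l3$W[1, 1] <- 1
    bank$networks[[nm]]$layers[[3]] <- l3
  }
  bank
}

# wiring that reproduces inclass_model through the identity path
inclass_wiring <- list(
  k10 = list(cov = 2, slope = 0.004, intercept = 0.003),
  k12 = list(intercept = 0.01),
  k13 = list(intercept = 0.001),
  k21 = list(intercept = 0.005),
  k31 = list(intercept = 2e-4),
  V1 = list(cov = 2, slope = 15, intercept = 0.5))

published_model_trees_for_test <- function() symregpk:::published_model_trees()
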