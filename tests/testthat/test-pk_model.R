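test_that("parameterization conversions match closed forms and round-trip", {
  p <- pk_rates(k10 = 0.1, k12 = 0.2, k13 = 0.05, k21 = 0.1, k31 = 0.05,
                V1 = 10)
  cl <- rates_to_clearances(p)
  expect_equal(unclass(cl),
               c(CL = 1, Q2 = 2, Q3 = 0.5, V1 = 10, V2 = 20, V3 = 10))
  expect_equal(unclass(clearances_to_rates(cl)), unclass(p))

  # k21 = k12 gives V2 = V1; V2 = V1 gives k21 = k12
  p2 <- pk_rates(0.1, 0.07, 0.05, 0.07, 0.05, 3)
  expect_equal(rates_to_clearances(p2)[["V2"]], 3)
  c2 <- pk_clearances(CL = 1, Q2 = 2, Q3 = 0.5, V1 = 10, V2 = 10, V3 = 7)
  r2 <- clearances_to_rates(c2)
  expect_equal(r2[["k21"]], r2[["k12"]])

  set.seed(1)
  for (i in 1:20) {
    p <- random_pk_rates()
    expect_equal(unclass(clearances_to_rates(rates_to_clearances(p))),
                 unclass(p), tolerance = 1e-12)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(pk_rates(0, 0.2, 0.05, 0.1, 0.05, 10), "positive")
  expect_error(pk_rates(0.1, 0.2, 0.05, 0.1, 0.05, -1), "positive")
  expect_error(pk_clearances(1, 2, 0.5, 10, 20, Inf), "positive")
  expect_error(dosing_profile(c(0, 0), c(1, 2)), "increasing")
  expect_error(dosing_profile(c(-1, 5), c(1, 2)), ">= 0")
  expect_error(dosing_profile(0, -1), "non-negative")
})

test_that("simulate reproduces the one-compartment closed form", {
  # peripheral rates at machine-tiny values approximate the 1-compartment
  # limit: C(t) = u/(V1 k10) (1 - exp(-k10 t))
  p <- pk_rates(0.01, 1e-14, 1e-14, 1e-7, 1e-7, 10)
  d <- dosing_profile(0, 100)
  expect_equal(pk_simulate(p, d, 100), 1000 * (1 - exp(-1)),
               tolerance = 1e-6)
  tt <- c(10, 50, 200, 1000)
  expect_equal(pk_simulate(p, d, tt), 1000 * (1 - exp(-0.01 * tt)),
               tolerance = 1e-6)
})

test_that("zero input gives zero concentration; obs order is preserved", {
  p <- random_pk_rates()
  d <- dosing_profile(0, 0)
  expect_equal(pk_simulate(p, d, c(0, 10, 500)), c(0, 0, 0))

  d2 <- dosing_profile(c(0, 300), c(100, 0))
  tt <- c(500, 10, 300, 10)   # unsorted with a duplicate
  out <- pk_simulate(p, d2, tt)
  expect_equal(out[2], out[4])
  expect_equal(out, pk_simulate(p, d2, tt))
  expect_equal(out[c(2, 3, 1)], pk_simulate(p, d2, sort(unique(tt))))
})

test_that("simulate matches the adaptive RK45 oracle on random instances", {
  set.seed(42)
  for (i in 1:15) {
    p <- random_pk_rates()
    d <- random_dosing()
    tt <- sort(runif(8, 1, 4000))
    got <- pk_simulate(p, d, tt)
    ref <- ode_oracle(p, d, tt, tol = 1e-9)
    expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-8)), 1e-6)
  }
})

test_that("superposition holds (LTI property)", {
  set.seed(7)
  for (i in 1:5) {
    p <- random_pk_rates()
    t1 <- dosing_profile(c(0, 500), c(200, 0))
    t2 <- dosing_profile(c(100, 900), c(50, 0))
    # sum of the two profiles on the merged event grid
    grid <- sort(unique(c(t1$times, t2$times)))
    rate_at <- function(d, t) {
      idx <- findInterval(t, d$times)
      ifelse(idx == 0, 0, d$rates[pmax(idx, 1)])
    }
    both <- dosing_profile(grid, rate_at(t1, grid) + rate_at(t2, grid))
    tt <- c(50, 400, 700, 1200)
    s <- pk_simulate(p, t1, tt) + pk_simulate(p, t2, tt)
    expect_equal(pk_simulate(p, both, tt), s, tolerance = 1e-9)
  }
})

test_that("complex-step jacobian matches central finite differences", {
  set.seed(11)
  for (i in 1:5) {
    p <- random_pk_rates()
    d <- random_dosing()
    tt <- sort(runif(6, 10, 4000))
    jac <- pk_simulate_jacobian(p, d, tt)$jac
    for (k in 1:6) {
      h <- 1e-6 * as.numeric(p)[k]
      pp <- as.numeric(p); pm <- pp
      pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
      fd <- (pk_simulate(do.call(pk_rates, as.list(pp)), d, tt) -
             pk_simulate(do.call(pk_rates, as.list(pm)), d, tt)) / (2 * h)
      denom <- pmax(abs(fd), max(abs(fd)) * 1e-3 + 1e-12)
      expect_lt(max(abs(jac[, k] - fd) / denom), 1e-4)
    }
  }
})

test_that("concentrations stay non-negative under non-negative input", {
  set.seed(5)
  for (i in 1:20) {
    p <- random_pk_rates()
    d <- random_dosing(5)
    conc <- pk_simulate(p, d, seq(0, 5000, length.out = 40))
    expect_true(all(conc >= 0))
  }
})

test_that("steady state matches simulation and the mass-balance formula", {
  p <- pk_rates(0.01, 0.005, 0.001, 0.003, 5e-4, 10)
  expect_equal(steady_state_concentration(p, 100), 1000)
  expect_equal(steady_state_concentration(p, 0), 0)
  # simulate far beyond the slowest time constant
  d <- dosing_profile(0, 100)
  t_slow <- 1 / min(as.numeric(p)[1:5])
  conc <- pk_simulate(p, d, 50 * t_slow)
  expect_equal(conc, 1000, tolerance = 1e-3)
})

test_that("domain errors are reported", {
  p <- random_pk_rates()
  d <- dosing_profile(0, 10)
  expect_error(pk_simulate(p, d, -5), ">= 0")
  expect_error(pk_simulate(p, d, NaN), "finite")
})
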