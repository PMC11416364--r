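test_that("covariate normalization follows the spec'd conventions", {
  spec <- normalization_spec()
  phi <- normalize_covariates(88, 80, 26.4, "M", "A", spec)
  expect_equal(unname(phi["age"]), 1.0)
  expect_equal(unname(phi["gender"]), 0.5)
  expect_equal(unname(phi["site"]), 0.5)
  phi2 <- normalize_covariates(44, 160, 52.8, "F", "V", spec)
  expect_equal(unname(phi2), c(0.5, 1, 1, -0.5, -0.5))
  expect_error(normalize_covariates(40, 70, 25, "X", "A", spec), "gender")
  expect_warning(normalize_covariates(120, 70, 25, "M", "A", spec),
                 "extrapolating")
})

test_that("base expressions match their definitions with guards", {
  expect_equal(base_expr_g1(c(7, 2, 3, -2, 3)), c(7, 6, 8))
  expect_equal(base_expr_g1(c(0, 0, 5, 1, 0)), c(0, 0, 1))
  # guarded zero base: |0| -> eps, eps^0 = 1; negative exponent stays finite
  g <- base_expr_g1(c(0, 0, 0, 0, -1))
  expect_equal(g[3], 1e6)
  expect_true(is.finite(g[3]))

  expect_equal(base_expr_g2(c(1, 2, 3, 4, 0)), c(1, 6, 4))
  expect_equal(base_expr_g2(c(0, 0, 0, 5, 4)), c(0, 0, 1))
  g2 <- base_expr_g2(c(0, 0, 0, 5, -1))    # denominator guard
  expect_true(is.finite(g2[3]))
  expect_lte(abs(g2[3]), 5 / 1e-6)

  expect_equal(base_expr_g3(-0.3), 0.3)
  expect_equal(base_expr_g3(0), 0)

  # guards do not perturb well-scaled inputs
  z <- c(0.3, -1.2, 0.7, 0.4, 1.3)
  expect_equal(base_expr_g1(z), c(z[1], z[2] * z[3], abs(z[4])^z[5]))
  expect_equal(base_expr_g2(z), c(z[1], z[2] * z[3], z[4] / (z[5] + 1)))
})

test_that("layer_forward equals the affine/base composition", {
  set.seed(10)
  bank <- init_bank(3)
  l1 <- bank$networks$k10$layers[[1]]
  x <- runif(5)
  z <- as.numeric(l1$W %*% x + l1$b)
  expect_equal(layer_forward(l1, x),
               c(z[1], z[2] * z[3], max(abs(z[4]), 1e-6)^z[5]),
               tolerance = 1e-12)
  # all-zero layer: the guarded 0^0 convention gives (0, 0, 1)
  l0 <- l1; l0$W[] <- 0; l0$b[] <- 0
  expect_equal(layer_forward(l0, x), c(0, 0, 1))
  expect_error(layer_forward(l1, runif(3)), "length 5")
})

test_that("init_bank is seed-deterministic with the nominal architecture", {
  b1 <- init_bank(1)
  b2 <- init_bank(1)
  b3 <- init_bank(2)
  expect_identical(gamma_vector(b1), gamma_vector(b2))
  expect_false(identical(gamma_vector(b1), gamma_vector(b3)))
  expect_equal(n_gamma(b1), 6 * 54)
  expect_equal(symregpk:::net_unmasked_count(b1$networks$V1), 54)
})

test_that("bank output is non-negative and identity wiring passes through", {
  set.seed(4)
  for (i in 1:25) {
    bank <- init_bank(i)
    phi <- c(runif(3), sample(c(-0.5, 0.5), 2, TRUE))
    expect_true(all(as.numeric(bank_forward(bank, phi)) >= 0))
  }
  # hand-wired identity path reproduces an affine function of one covariate
  bank <- handwired_bank(inclass_wiring)
  phi <- normalize_covariates(40, 80, 25, "M", "A")
  th <- bank_forward(bank, phi)
  expect_equal(th[["k10"]], 0.004 * 0.5 + 0.003, tolerance = 1e-12)
  expect_equal(th[["V1"]], 15 * 0.5 + 0.5, tolerance = 1e-12)
  expect_equal(th[["k31"]], 2e-4, tolerance = 1e-12)
})

test_that("vectorized forward agrees with the scalar path", {
  set.seed(12)
  bank <- init_bank(8)
  Phi <- rbind(matrix(runif(15), 3), matrix(sample(c(-.5, .5), 10, TRUE), 2))
  for (nm in names(bank$networks)) {
    f <- symregpk:::vec_forward(bank$networks[[nm]], Phi, 1e-6, 1e-6)
    for (i in 1:5) {
      sc <- symregpk:::net_forward_cache(bank$networks[[nm]], Phi[, i],
                                         1e-6, 1e-6)
      expect_equal(f$theta[i], sc$theta, tolerance = 1e-12)
    }
  }
})

test_that("masking is sound: pruned entries are zero and stay out of gamma", {
  bank <- init_bank(5)
  n0 <- n_gamma(bank)
  # manually masking an entry equals setting it to zero
  phi <- normalize_covariates(30, 60, 22, "F", "V")
  b_zero <- bank
  l <- b_zero$networks$k12$layers[[1]]
  l$W[2, 3] <- 0
  b_zero$networks$k12$layers[[1]] <- l
  b_mask <- symregpk:::mask_entry(bank, "k12", 1, "W", 2 + (3 - 1) * 5)
  expect_equal(as.numeric(bank_forward(b_mask, phi)),
               as.numeric(bank_forward(b_zero, phi)))
  expect_equal(n_gamma(b_mask), n0 - 1)
  # gamma round trip preserves masks
  g <- gamma_vector(b_mask)
  b_back <- set_gamma(b_mask, g + 1)
  expect_equal(b_back$networks$k12$layers[[1]]$W[2, 3], 0)
  expect_equal(gamma_vector(b_back), g + 1)
})

test_that("prune_covariate removes dependence on the covariate", {
  bank <- init_bank(6)
  expect_equal(active_covariates(bank, "k10"), 1:5)
  bank2 <- prune_covariate(bank, "k10", 3)
  expect_equal(active_covariates(bank2, "k10"), c(1, 2, 4, 5))
  phi <- normalize_covariates(30, 60, 22, "F", "V")
  phi2 <- phi; phi2["bmi"] <- phi2["bmi"] + 0.2
  expect_equal(bank_forward(bank2, phi)[["k10"]],
               bank_forward(bank2, phi2)[["k10"]])
  # other networks are untouched
  expect_equal(active_covariates(bank2, "V1"), 1:5)
  expect_error(prune_covariate(bank2, "k10", 3), "not active")
  for (k in c(1, 2, 4)) bank2 <- prune_covariate(bank2, "k10", k)
  expect_error(prune_covariate(bank2, "k10", 5), "last active")
})

test_that("bank JSON serialization round-trips bit-exactly", {
  bank <- init_bank(9)
  bank <- prune_covariate(bank, "k21", 2)
  f <- tempfile(fileext = ".json")
  bank_to_json(bank, f)
  back <- bank_from_json(f)
  expect_identical(gamma_vector(back), gamma_vector(bank))
  expect_identical(back$networks$k21$layers[[1]]$Wmask,
                   bank$networks$k21$layers[[1]]$Wmask)
  expect_equal(back$spec$age_max, bank$spec$age_max)
  phi <- normalize_covariates(71, 90, 30, "M", "V")
  expect_identical(as.numeric(bank_forward(back, phi)),
                   as.numeric(bank_forward(bank, phi)))
  unlink(f)
})
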