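random_raw_cov <- function() {
  list(age = runif(1, 0, 88), wgt = runif(1, 0.68, 160),
       bmi = runif(1, 6.2, 52.8), gender = sample(c("M", "F"), 1),
       site = sample(c("A", "V"), 1))
}

eval_tree_at <- function(tree, rc, spec = normalization_spec()) {
  evaluate_expression(tree, rc$age, rc$wgt, rc$bmi, rc$gender, rc$site, spec)
}

test_that("extracted expressions reproduce the network forward pass", {
  set.seed(21)
  for (s in 1:6) {
    bank <- init_bank(s)
    if (s > 2) {  # exercise pruned mask states too
      bank <- prune_covariate(bank, "k10", sample(5, 1))
      sal <- gamma_index(bank)
      sal$salience <- runif(nrow(sal))
      class(sal) <- c("salience_table", "data.frame")
      bank <- prune_parameters(bank, sal, 20, per_network = TRUE)
    }
    trees <- extract_expression(bank)
    for (i in 1:18) {
      rc <- random_raw_cov()
      phi <- normalize_covariates(rc$age, rc$wgt, rc$bmi, rc$gender, rc$site,
                                  bank$spec, warn = FALSE)
      th <- as.numeric(bank_forward(bank, phi))
      tv <- vapply(trees, eval_tree_at, numeric(1), rc = rc)
      expect_lt(max(abs(th - tv) / pmax(abs(th), 1e-6)), 1e-9)
    }
  }
})

test_that("all-zero network folds to the constant |b3|", {
  bank <- handwired_bank(list(k10 = list(intercept = 0.1),
                              k12 = list(intercept = 0.2),
                              k13 = list(intercept = 0.3),
                              k21 = list(intercept = 0.4),
                              k31 = list(intercept = 0.5),
                              V1 = list(intercept = -0.7)))
  # wipe even the identity wiring of one network: output |b3| = 0
  for (li in 1:3) {
    lay <- bank$networks$V1$layers[[li]]
    lay$W[] <- 0; lay$b[] <- 0
    bank$networks$V1$layers[[li]] <- lay
  }
  trees <- extract_expression(bank)
  expect_equal(trees$V1$type, "const")
  expect_equal(trees$V1$value, 0)
  expect_equal(trees$k10$type, "const")
  expect_equal(trees$k10$value, 0.1)
})

test_that("the abs root is dropped only when provably sign-definite", {
  # theta = |0.4 phi_age + 0.2|: positive over the domain -> abs dropped
  bank <- handwired_bank(list(k10 = list(cov = 1, slope = 0.4,
                                         intercept = 0.2),
                              k12 = list(intercept = 0.1),
                              k13 = list(intercept = 0.1),
                              k21 = list(intercept = 0.1),
                              k31 = list(intercept = 0.1),
                              V1 = list(cov = 4, slope = 1,
                                        intercept = 0.1)))
  trees <- extract_expression(bank)
  has_abs <- function(t) {
    if (identical(t$type, "abs")) return(TRUE)
    kids <- switch(t$type, sum = t$terms, prod = list(t$a, t$b),
                   div = list(t$num, t$den), pow = list(t$base, t$expo),
                   list())
    any(vapply(kids, has_abs, logical(1)))
  }
  expect_false(has_abs(trees$k10))
  # V1 = |phi_gender + 0.1| spans sign over {-0.5, +0.5}: abs kept
  expect_true(has_abs(trees$V1))
})

test_that("published model matches the printed coefficients", {
  # weight term at the normalization maximum: 0.00441 + 0.00342
  expect_equal(as.numeric(published_model(40, 160, 24, "M"))[1], 0.00783)
  # intercept at zero weight
  expect_equal(as.numeric(published_model(40, 1e-12, 24, "M"))[1], 0.00342,
               tolerance = 1e-6)
  # k31 intercept and gender-specific age slopes
  expect_equal(as.numeric(published_model(1e-12, 70, 24, "M"))[5], 4.52e-5,
               tolerance = 1e-6)
  expect_equal(as.numeric(published_model(88, 70, 24, "M"))[5],
               4.52e-5 + 1.92e-5)
  expect_equal(as.numeric(published_model(88, 70, 24, "F"))[5], 2.60e-5)
  # outputs positive over a covariate grid, both genders
  grid <- expand.grid(age = seq(0, 88, length.out = 10),
                      wgt = seq(0.68, 160, length.out = 10),
                      bmi = seq(6.2, 52.8, length.out = 10),
                      gender = c("M", "F"))
  ok <- vapply(seq_len(nrow(grid)), function(i)
    all(as.numeric(published_model(grid$age[i], grid$wgt[i], grid$bmi[i],
                                   as.character(grid$gender[i]))) > 0),
    logical(1))
  expect_true(all(ok))
})

test_that("published model ignores the sampling site", {
  set.seed(31)
  for (i in 1:20) {
    rc <- random_raw_cov()
    a <- published_model(rc$age, rc$wgt, rc$bmi, rc$gender, "A")
    v <- published_model(rc$age, rc$wgt, rc$bmi, rc$gender, "V")
    expect_identical(as.numeric(a), as.numeric(v))
  }
})

test_that("text rendering round-trips through the parser", {
  set.seed(41)
  expect_equal(render(symregpk:::ex_const(0.5), "text"), "0.5")
  trees <- published_model_trees_for_test()
  for (nm in names(trees)) {
    s <- render(trees[[nm]], "text")
    f <- parse_expression(s)
    for (i in 1:12) {
      rc <- random_raw_cov()
      expect_equal(f(rc$age, rc$wgt, rc$bmi, rc$gender, rc$site),
                   eval_tree_at(trees[[nm]], rc), tolerance = 1e-12)
    }
  }
  # the k10 rendering carries both printed coefficients
  s10 <- render(trees$k10, "text")
  expect_match(s10, "0.00441", fixed = TRUE)
  expect_match(s10, "0.00342", fixed = TRUE)
  expect_match(render(trees$k10, "latex"), "\\frac", fixed = TRUE)
})

test_that("categorical splitting reproduces the per-gender variants", {
  trees <- published_model_trees_for_test()
  v <- split_categorical(trees$k31, "gender")
  am <- eval_tree_at(v$M, list(age = 88, wgt = 70, bmi = 24, gender = "M",
                               site = "A"))
  af <- eval_tree_at(v$F, list(age = 88, wgt = 70, bmi = 24, gender = "F",
                               site = "A"))
  expect_equal(am, 4.52e-5 + 1.92e-5)
  expect_equal(af, 4.52e-5 - 1.92e-5)
})

test_that("expression files are written", {
  bank <- init_bank(2)
  d <- tempfile()
  export_expressions(bank, d)
  expect_true(file.exists(file.path(d, "expressions.txt")))
  expect_true(file.exists(file.path(d, "expressions.tex")))
  js <- jsonlite::fromJSON(file.path(d, "expressions.json"),
                           simplifyVector = FALSE)
  expect_named(js, names(bank$networks))
  unlink(d, recursive = TRUE)
})
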