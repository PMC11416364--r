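test_that("training loss composes the module-level pieces", {
  ds <- small_dataset(n = 4, seed = 19, noise_sd = 0.2)
  bank <- init_bank(7)
  manual <- mean(vapply(ds$individuals, function(ind) {
    phi <- normalize_covariates(ind$age, ind$wgt, ind$bmi, ind$gender,
                                ind$site, bank$spec, warn = FALSE)
    th <- bank_forward(bank, phi)
    cpred <- pk_simulate(do.call(pk_rates, as.list(pmax(as.numeric(th),
                                                        1e-10))),
                         ind$dosing, ind$obs$time)
    individual_medians(ind$obs$conc, pmax(cpred, 1e-12))$md_ale
  }, numeric(1)))
  expect_equal(training_loss(bank, ds), manual, tolerance = 1e-10)
})

test_that("self-consistency and the e-scaling identity hold", {
  ds <- small_dataset(n = 5, seed = 7, noise_sd = 0, model = inclass_model)
  bank <- handwired_bank(inclass_wiring)
  expect_lt(training_loss(bank, ds), 1e-12)
  # inflating V1 by e scales every predicted concentration by 1/e,
  # so every ALE (and hence J_ALE) equals exactly 1
  wiring_e <- inclass_wiring
  wiring_e$V1$slope <- wiring_e$V1$slope * exp(1)
  wiring_e$V1$intercept <- wiring_e$V1$intercept * exp(1)
  expect_equal(training_loss(handwired_bank(wiring_e), ds), 1,
               tolerance = 1e-9)
})

test_that("loss gradient matches finite differences at random points", {
  ds <- small_dataset(n = 5, seed = 3, noise_sd = 0.15)
  bank <- init_bank(2)
  arr <- symregpk:::dataset_arrays(ds, bank$spec)
  lg <- symregpk:::bank_loss_grad(bank, arr)
  g <- gamma_vector(bank)
  set.seed(50)
  idx <- sample(length(g), 20)
  fd <- vapply(idx, function(k) {
    h <- 1e-5 * max(abs(g[k]), 1e-2)
    gp <- g; gm <- g
    gp[k] <- gp[k] + h; gm[k] <- gm[k] - h
    (training_loss(set_gamma(bank, gp), ds) -
       training_loss(set_gamma(bank, gm), ds)) / (2 * h)
  }, numeric(1))
  denom <- pmax(abs(fd), 1e-4)
  expect_lt(max(abs(lg$grad[idx] - fd) / denom), 1e-3)
})

test_that("ADAM solves a convex surrogate and honors the stopping contract", {
  target <- c(3, -2, 0.5)
  fn <- function(x) list(value = sum((x - target)^2),
                         grad = 2 * (x - target))
  cfg <- train_config(lr = 0.05, max_epochs = 3000,
                      convergence_window = 50, convergence_rtol = 1e-10)
  opt <- adam_optimize(fn, c(0, 0, 0), cfg)
  expect_lt(max(abs(opt$par - target)), 1e-3)
  expect_true(opt$converged)
  # stopping contract on the running best
  w <- cfg$convergence_window
  best <- cummin(opt$history)
  e <- opt$epochs
  expect_lt((best[e - w] - best[e]) / max(best[e - w], 1e-12),
            cfg$convergence_rtol)
})

test_that("train is deterministic and leaves masked entries untouched", {
  ds <- small_dataset(n = 4, seed = 5, noise_sd = 0.1)
  bank <- prune_covariate(init_bank(3), "k12", 4)
  cfg <- train_config(lr = 0.02, max_epochs = 8)
  f1 <- train(bank, ds, cfg)
  f2 <- train(bank, ds, cfg)
  expect_identical(gamma_vector(f1$bank), gamma_vector(f2$bank))
  expect_identical(bank_to_json(f1$bank), bank_to_json(f2$bank))
  expect_equal(f1$bank$networks$k12$layers[[1]]$W[, 4], rep(0, 5))
  expect_equal(f1$final_loss, training_loss(f1$bank, ds))
})

test_that("minibatch mode trains, is reproducible, and reports full loss", {
  ds <- small_dataset(n = 8, seed = 6, noise_sd = 0.1)
  bank <- init_bank(4)
  cfg <- train_config(lr = 0.02, max_epochs = 12, batch_size = 3)
  f1 <- train(bank, ds, cfg)
  f2 <- train(bank, ds, cfg)
  expect_identical(gamma_vector(f1$bank), gamma_vector(f2$bank))
  expect_equal(f1$final_loss, training_loss(f1$bank, ds))
})

test_that("salience is zero for zero-valued parameters and non-negative", {
  ds <- small_dataset(n = 4, seed = 9, noise_sd = 0.1)
  bank <- init_bank(4)
  l <- bank$networks$k10$layers[[1]]
  l$W[1, 1] <- 0
  bank$networks$k10$layers[[1]] <- l
  sal <- parameter_salience(bank, ds)
  expect_true(all(sal$salience >= 0))
  row <- sal[sal$network == "k10" & sal$layer == 1 & sal$kind == "W" &
               sal$index == 1, ]
  expect_equal(row$salience, 0)
  expect_equal(nrow(sal), n_gamma(bank))
})

test_that("covariate salience identifies the generating covariate", {
  # truth bank on its own noise-free data is an exact minimum; the only
  # covariate the k10 network uses is weight
  ds <- small_dataset(n = 10, seed = 13, noise_sd = 0, model = inclass_model)
  bank <- handwired_bank(inclass_wiring)
  sal <- covariate_salience(bank, ds)
  k10s <- sal[sal$network == "k10", ]
  expect_equal(k10s$covariate[which.max(k10s$salience)], "wgt")
  # a pruned covariate has zero salience
  bank2 <- prune_covariate(init_bank(2), "k21", 5)
  sal2 <- covariate_salience(bank2, ds)
  expect_false(any(sal2$network == "k21" & sal2$covariate_index == 5))
})

test_that("parameter pruning follows counts and zero-pruning is neutral", {
  ds <- small_dataset(n = 3, seed = 11, noise_sd = 0.1)
  bank <- init_bank(6)
  sal <- parameter_salience(bank, ds)
  b44 <- prune_parameters(bank, sal[sal$network == "k10", ], 10)
  expect_equal(symregpk:::net_unmasked_count(b44$networks$k10), 44)
  expect_equal(symregpk:::net_unmasked_count(b44$networks$k12), 54)
  # repeated single prunes down to 12 in one network
  b <- b44
  while (symregpk:::net_unmasked_count(b$networks$k10) > 12) {
    s <- parameter_salience(b, ds)
    b <- prune_parameters(b, s[s$network == "k10", ], 1)
  }
  expect_equal(symregpk:::net_unmasked_count(b$networks$k10), 12)
  expect_error(prune_parameters(b, parameter_salience(b, ds), 60),
               "too few")
  # masking a zero-valued entry does not change the forward pass
  bz <- init_bank(8)
  lz <- bz$networks$V1$layers[[2]]
  lz$W[3, 2] <- 0
  bz$networks$V1$layers[[2]] <- lz
  phi <- normalize_covariates(50, 90, 28, "F", "A")
  before <- as.numeric(bank_forward(bz, phi))
  bzm <- symregpk:::mask_entry(bz, "V1", 2, "W", 3 + (2 - 1) * 5)
  expect_identical(as.numeric(bank_forward(bzm, phi)), before)
})

test_that("a no-op schedule degenerates the recipe to plain training", {
  ds <- small_dataset(n = 4, seed = 21, noise_sd = 0.1)
  cfg <- train_config(lr = 0.02, max_epochs = 5)
  sched <- prune_schedule(target_covariates_per_network = 5,
                          target_parameters_per_network = 54)
  fit <- run_recipe(ds, sched, cfg, seed = 2)
  stages <- vapply(fit$steps, `[[`, "", "stage")
  expect_equal(stages, c("initial_train", "final_train"))
  expect_equal(n_gamma(fit$bank), 324)
  expect_length(fit$expressions, 6)
})

test_that("multi-restart keeps the best run and matches its contract", {
  ds <- small_dataset(n = 4, seed = 23, noise_sd = 0.1)
  cfg <- train_config(lr = 0.02, max_epochs = 4)
  sched <- prune_schedule(target_covariates_per_network = 5,
                          target_parameters_per_network = 54)
  best <- multi_restart(ds, sched, cfg, n_restarts = 3, base_seed = 5)
  expect_equal(best$restarts_used, 3)
  expect_equal(best$final_loss, min(best$restart_losses))
  single <- run_recipe(ds, sched, cfg, seed = 5)
  one <- multi_restart(ds, sched, cfg, n_restarts = 1, base_seed = 5)
  expect_equal(one$final_loss, single$final_loss)
  expect_identical(gamma_vector(one$bank), gamma_vector(single$bank))
})

test_that("cross-validation partitions individuals into disjoint folds", {
  ds <- small_dataset(n = 10, seed = 27, noise_sd = 0.15)
  cfg <- train_config(lr = 0.03, max_epochs = 30, convergence_window = 25)
  sched <- prune_schedule(target_covariates_per_network = 5,
                          target_parameters_per_network = 54)
  cv <- cross_validate(ds, sched, cfg, k = 5, seed = 3)
  expect_length(cv$fold_losses, 5)
  expect_equal(sort(tabulate(cv$fold, 5)), rep(2L, 5))
  expect_equal(length(cv$fold), 10)
  expect_equal(cv$mean, mean(cv$fold_losses))
  expect_true(all(is.finite(cv$fold_losses)))
  # barely-trained models should not grossly over-fit
  expect_lt(cv$mean, 1.5 * mean(cv$train_losses) + 0.05)
})
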