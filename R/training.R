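## Training and pruning: full-batch ADAM on the population loss J_ALE
## (simulator in the loop), Hessian-diagonal salience scores for parameters
## and covariates, and the sequential train/prune recipe.

#' Training configuration
#'
#' @param lr ADAM learning rate.
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = none).
#'   The median-of-samples loss has a piecewise-smooth gradient, so a mild
#'   decay lets ADAM settle into a minimum instead of oscillating around it.
#' @param beta1,beta2,eps ADAM moment decay rates and stabilizer.
#' @param max_epochs epoch cap for the initial and final training stages.
#' @param retrain_epochs epoch cap for the retraining stages between pruning
#'   iterations (defaults to `max_epochs`).
#' @param convergence_window,convergence_rtol training stops when the
#'   relative loss improvement over the last `convergence_window` epochs
#'   falls below `convergence_rtol`.
#' @param batch_size `NULL` for full-batch gradients (the default; the
#'   cohorts are small), or an integer for minibatch mode: each epoch uses a
#'   seeded random subset of individuals, and the reported/converged loss is
#'   re-evaluated on the full cohort every few epochs.
#' @param verbose print per-stage progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, lr_decay = 1, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8,
                         max_epochs = 5000, retrain_epochs = max_epochs,
                         convergence_window = 50, convergence_rtol = 1e-5,
                         batch_size = NULL, verbose = FALSE) {
  stopifnot(lr > 0, lr_decay > 0, lr_decay <= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps > 0,
            max_epochs >= 1, retrain_epochs >= 1, convergence_window >= 1,
            convergence_rtol >= 0,
            is.null(batch_size) || batch_size >= 1)
  structure(list(lr = lr, lr_decay = lr_decay, beta1 = beta1, beta2 = beta2,
                 eps = eps,
                 max_epochs = max_epochs, retrain_epochs = retrain_epochs,
                 convergence_window = convergence_window,
                 convergence_rtol = convergence_rtol,
                 batch_size = batch_size, verbose = verbose),
            class = "train_config")
}

#' Pruning schedule
#'
#' Demonstrator defaults: prune covariates one at a time (per network) down
#' to 2; then remove the 10 least salient parameters in the first parameter
#' pruning iteration and 1 per subsequent iteration, down to 12 per network.
#'
#' @param target_covariates_per_network covariates kept per network.
#' @param first_parameter_prune_count parameters removed in the first
#'   parameter-pruning iteration.
#' @param subsequent_parameter_prune_count parameters removed per later
#'   iteration.
#' @param target_parameters_per_network unmasked scalars kept per network.
#' @return A list of class `prune_schedule`.
#' @export
prune_schedule <- function(target_covariates_per_network = 2,
                           first_parameter_prune_count = 10,
                           subsequent_parameter_prune_count = 1,
                           target_parameters_per_network = 12) {
  stopifnot(target_covariates_per_network >= 1,
            first_parameter_prune_count >= 1,
            subsequent_parameter_prune_count >= 1,
            target_parameters_per_network >= 1)
  structure(list(
    target_covariates_per_network = target_covariates_per_network,
    first_parameter_prune_count = first_parameter_prune_count,
    subsequent_parameter_prune_count = subsequent_parameter_prune_count,
    target_parameters_per_network = target_parameters_per_network),
    class = "prune_schedule")
}

## flat arrays for the C++ population kernels
dataset_arrays <- function(dataset, spec = NULL) {
  if (is.null(spec)) spec <- dataset$normalization
  inds <- dataset$individuals
  phi <- vapply(inds, function(ind)
    normalize_covariates(ind$age, ind$wgt, ind$bmi, ind$gender, ind$site,
                         spec, warn = FALSE), numeric(5))
  list(phi = phi,
       evt = lapply(inds, function(i) i$dosing$times),
       evr = lapply(inds, function(i) i$dosing$rates),
       obst = lapply(inds, function(i) i$obs$time),
       cobs = lapply(inds, function(i) i$obs$conc),
       ids = vapply(inds, function(i) as.character(i$id), ""))
}

theta_matrix <- function(bank, phi) {
  th <- do.call(rbind, lapply(bank$networks, function(net)
    vec_forward(net, phi, bank$eps_pow, bank$eps_div)$theta))
  pmax(th, 1e-10)
}

pop_mdale <- function(theta, arr) {
  .pop_mdale_cpp(theta, arr$evt, arr$evr, arr$obst, arr$cobs)
}

#' Population training loss of a bank on a dataset
#'
#' For each individual: normalize covariates, evaluate the bank to PK
#' parameters, simulate at the observation times, take the median absolute
#' logarithmic error; then average over individuals (J_ALE).
#'
#' @param bank a `symreg_bank`.
#' @param dataset a `pk_dataset` (see [read_dataset()] / [generate_dataset()]).
#' @return Scalar J_ALE.
#' @export
training_loss <- function(bank, dataset) {
  arr <- dataset_arrays(dataset, bank$spec)
  mean(pop_mdale(theta_matrix(bank, arr$phi), arr))
}

# loss and full gradient w.r.t. gamma (vectorized over individuals)
bank_loss_grad <- function(bank, arr) {
  n <- ncol(arr$phi)
  fw <- lapply(bank$networks, vec_forward, Phi = arr$phi,
               eps_pow = bank$eps_pow, eps_div = bank$eps_div)
  theta <- pmax(do.call(rbind, lapply(fw, `[[`, "theta")), 1e-10)
  res <- .pop_grad_cpp(theta, arr$evt, arr$evr, arr$obst, arr$cobs)
  grads <- lapply(seq_along(fw), function(k) {
    up <- res$dtheta[k, ] / n
    up[fw[[k]]$theta < 1e-10] <- 0   # floored outputs: no gradient flow
    vec_backprop(bank$networks[[k]], fw[[k]], arr$phi, up,
                 bank$eps_pow, bank$eps_div)
  })
  list(loss = mean(res$mdale), grad = unlist(grads, use.names = FALSE),
       mdale = res$mdale)
}

#' Generic full-batch ADAM optimizer
#'
#' Minimizes `fn`, which must return `list(value =, grad =)`.  Stops when the
#' relative improvement over `convergence_window` epochs drops below
#' `convergence_rtol`, or at `max_epochs`.  The best iterate seen is
#' returned.
#'
#' @param fn objective closure returning value and gradient.
#' @param x0 initial parameter vector.
#' @param cfg a [train_config]; `max_epochs` is taken from `epochs` if given.
#' @param epochs optional epoch cap overriding `cfg$max_epochs`.
#' @return List with `par`, `value`, `history` (loss per epoch), `epochs`,
#'   `converged`.
#' @export
adam_optimize <- function(fn, x0, cfg = train_config(), epochs = NULL) {
  max_ep <- if (is.null(epochs)) cfg$max_epochs else epochs
  x <- x0
  m <- v <- numeric(length(x0))
  hist <- best_hist <- numeric(max_ep)
  best_x <- x; best_val <- Inf
  conv <- FALSE
  e <- 0L
  lr <- cfg$lr
  while (e < max_ep) {
    e <- e + 1L
    r <- fn(x)
    if (!is.finite(r$value))
      stop("non-finite loss at epoch ", e,
           "; guard failure (inspect parameter scales / dosing profile)")
    hist[e] <- r$value
    if (r$value < best_val) { best_val <- r$value; best_x <- x }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * r$grad
    v <- cfg$beta2 * v + (1 - cfg$beta2) * r$grad^2
    mh <- m / (1 - cfg$beta1^e)
    vh <- v / (1 - cfg$beta2^e)
    x <- x - lr * mh / (sqrt(vh) + cfg$eps)
    lr <- lr * cfg$lr_decay
    best_hist[e] <- best_val
    w <- cfg$convergence_window
    if (e > w) {
      ref <- best_hist[e - w]   # judge convergence on the running best:
      # the nonsmooth median loss makes the raw iterates oscillate
      if ((ref - best_val) / max(abs(ref), 1e-12) < cfg$convergence_rtol) {
        conv <- TRUE
        break
      }
    }
  }
  list(par = best_x, value = best_val, history = hist[seq_len(e)],
       epochs = e, converged = conv)
}

#' Train a network bank by back-propagation through the simulator
#'
#' Full-batch ADAM on J_ALE.  Masked (pruned) entries are excluded from the
#' trainable vector and never move.  Deterministic given the bank and config.
#'
#' @param bank a `symreg_bank`.
#' @param dataset a `pk_dataset`.
#' @param cfg a [train_config].
#' @param epochs optional epoch cap overriding `cfg$max_epochs`.
#' @return A `fit_result`: list with `bank`, `loss_history`, `final_loss`,
#'   `epochs`, `converged`, `seed`.
#' @export
train <- function(bank, dataset, cfg = train_config(), epochs = NULL) {
  arr <- dataset_arrays(dataset, bank$spec)
  n <- ncol(arr$phi)
  bank_env <- bank
  bs <- cfg$batch_size
  if (is.null(bs) || bs >= n) {
    fn <- function(gamma) {
      bank_env <<- set_gamma(bank_env, gamma)
      r <- bank_loss_grad(bank_env, arr)
      list(value = r$loss, grad = r$grad)
    }
  } else {
    # minibatch mode: seeded subsets; the full loss (used for best-tracking
    # and convergence) is refreshed every few epochs
    set.seed(bank$seed %||% 0L)
    counter <- 0L
    sub_arr <- function(idx) list(phi = arr$phi[, idx, drop = FALSE],
                                  evt = arr$evt[idx], evr = arr$evr[idx],
                                  obst = arr$obst[idx],
                                  cobs = arr$cobs[idx], ids = arr$ids[idx])
    fn <- function(gamma) {
      bank_env <<- set_gamma(bank_env, gamma)
      counter <<- counter + 1L
      r <- bank_loss_grad(bank_env, sub_arr(sample(n, bs)))
      val <- if (counter %% 10L == 1L)
        mean(pop_mdale(theta_matrix(bank_env, arr$phi), arr)) else r$loss
      list(value = val, grad = r$grad)
    }
  }
  opt <- adam_optimize(fn, gamma_vector(bank), cfg, epochs = epochs)
  bank <- set_gamma(bank, opt$par)
  final_loss <- if (is.null(bs) || bs >= n) opt$value else
    mean(pop_mdale(theta_matrix(bank, arr$phi), arr))
  structure(list(bank = bank, loss_history = opt$history,
                 final_loss = final_loss, epochs = opt$epochs,
                 converged = opt$converged, seed = bank$seed,
                 restarts_used = 1L),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("symregpk fit: J_ALE = %.6g after %d epochs (%s)\n",
              x$final_loss, x$epochs,
              if (isTRUE(x$converged)) "converged" else "epoch cap"))
  invisible(x)
}

## ---- salience ------------------------------------------------------------

#' Parameter salience (Hessian-diagonal scores)
#'
#' For each trainable scalar, `S = gamma^2 * H` where `H` is the
#' corresponding diagonal element of the Hessian of J_ALE, estimated by a
#' central second difference of the loss.  The step is proportional to the
#' parameter's own magnitude (`h_rel * |gamma|`, floored at 1e-7): curvature
#' around a small scale-carrying weight lives on the scale of that weight,
#' so an absolute step would average it away.  At a (near-)minimum the score
#' is the second-order Taylor estimate of the loss increase from zeroing the
#' parameter.  Negative curvature estimates (which can occur away from an
#' exact minimum) are clamped to zero.
#'
#' @param bank a trained `symreg_bank`.
#' @param dataset a `pk_dataset`.
#' @param h_rel relative finite-difference step.
#' @param warn warn when negative Hessian diagonals were clamped.
#' @return A data frame (`salience_table`): one row per trainable scalar
#'   with columns `network`, `layer`, `kind`, `index`, `value`, `hessian`,
#'   `salience`, in [gamma_vector()] order.
#' @export
parameter_salience <- function(bank, dataset, h_rel = 1e-2, warn = FALSE) {
  arr <- dataset_arrays(dataset, bank$spec)
  idx <- gamma_index(bank)
  theta0 <- theta_matrix(bank, arr$phi)
  J0 <- mean(pop_mdale(theta0, arr))
  H <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    nm <- idx$network[r]
    h <- max(h_rel * abs(idx$value[r]), 1e-7)
    m <- match(nm, names(bank$networks))
    Js <- vapply(c(h, -h), function(dh) {
      net <- bank$networks[[nm]]
      lay <- net$layers[[idx$layer[r]]]
      if (idx$kind[r] == "W") lay$W[idx$index[r]] <- lay$W[idx$index[r]] + dh
      else lay$b[idx$index[r]] <- lay$b[idx$index[r]] + dh
      net$layers[[idx$layer[r]]] <- lay
      th <- theta0   # only the perturbed network's parameter changes
      th[m, ] <- pmax(vec_forward(net, arr$phi, bank$eps_pow,
                                  bank$eps_div)$theta, 1e-10)
      mean(pop_mdale(th, arr))
    }, numeric(1))
    H[r] <- (Js[1] - 2 * J0 + Js[2]) / h^2
  }
  nneg <- sum(H < 0)
  if (warn && nneg > 0)
    warning(nneg, " negative Hessian diagonal(s) clamped to zero")
  idx$hessian <- H
  idx$salience <- idx$value^2 * pmax(H, 0)
  class(idx) <- c("salience_table", "data.frame")
  idx
}

#' Covariate salience
#'
#' For each network and active covariate `k`:
#' `S = sum_i phi_ik^2 * (H_i)_k`, where `(H_i)_k` is the `k`-th diagonal
#' element of the Hessian of individual `i`'s MdALE with respect to the
#' normalized covariate input of that network (central second difference,
#' negative values clamped to zero).
#'
#' @param bank a trained `symreg_bank`.
#' @param dataset a `pk_dataset`.
#' @param h finite-difference step on the normalized covariate scale.
#' @return Data frame with columns `network`, `covariate_index`, `covariate`,
#'   `salience`.
#' @export
covariate_salience <- function(bank, dataset, h = 1e-3) {
  arr <- dataset_arrays(dataset, bank$spec)
  n <- ncol(arr$phi)
  theta0 <- theta_matrix(bank, arr$phi)
  md0 <- pop_mdale(theta0, arr)
  rows <- list()
  for (m in seq_along(bank$networks)) {
    nm <- names(bank$networks)[m]
    net <- bank$networks[[m]]
    for (k in active_covariates(bank, nm)) {
      mds <- lapply(c(h, -h), function(dh) {
        Phi <- arr$phi
        Phi[k, ] <- Phi[k, ] + dh
        th <- theta0
        th[m, ] <- pmax(vec_forward(net, Phi, bank$eps_pow,
                                    bank$eps_div)$theta, 1e-10)
        pop_mdale(th, arr)
      })
      Hi <- (mds[[1]] - 2 * md0 + mds[[2]]) / h^2
      S <- sum(arr$phi[k, ]^2 * pmax(Hi, 0))
      rows[[length(rows) + 1L]] <- data.frame(
        network = nm, covariate_index = k, covariate = .cov_names[k],
        salience = S)
    }
  }
  do.call(rbind, rows)
}

#' Prune the least salient parameters
#'
#' Masks the `count` lowest-salience unmasked scalars to zero (per network by
#' default, matching per-network complexity targets; set
#' `per_network = FALSE` for a global cut).  Ties are broken by stable
#' position in the trainable vector.
#'
#' @param bank a `symreg_bank`.
#' @param salience a table from [parameter_salience()].
#' @param count number of parameters to remove (per network if
#'   `per_network`).
#' @param per_network prune each network independently.
#' @param min_remaining refuse to leave a network with fewer unmasked
#'   scalars than this.
#' @return The updated bank.
#' @export
prune_parameters <- function(bank, salience, count, per_network = TRUE,
                             min_remaining = 1) {
  groups <- if (per_network) split(seq_len(nrow(salience)),
                                   salience$network) else
    list(all = seq_len(nrow(salience)))
  for (g in groups) {
    if (count >= length(g) ||
        length(g) - count < min_remaining)
      stop("pruning count leaves too few trainable parameters")
    ord <- g[order(salience$salience[g], seq_along(g))]
    for (r in ord[seq_len(count)]) {
      bank <- mask_entry(bank, salience$network[r], salience$layer[r],
                         salience$kind[r], salience$index[r])
    }
  }
  bank
}

## ---- the recipe ----------------------------------------------------------

#' Sequential train-and-prune recipe
#'
#' Runs the full procedure: initialize a dense bank (1), train to
#' convergence (2), alternate covariate-salience pruning and retraining
#' until each network keeps the target number of covariates (3-5), then
#' alternate parameter-salience pruning and retraining until each network
#' keeps the target number of trainable scalars (6-9; the first iteration
#' removes `first_parameter_prune_count`, later ones
#' `subsequent_parameter_prune_count`), train the final structure (10) and
#' extract readable expressions (11).
#'
#' @param dataset a `pk_dataset`.
#' @param schedule a [prune_schedule].
#' @param cfg a [train_config]; intermediate retrains are capped at
#'   `cfg$retrain_epochs`.
#' @param seed integer seed for the weight initialization.
#' @param spec normalization spec for the bank (defaults to the dataset's).
#' @param init_sd initial weight scale passed to [init_bank()].
#' @param output_scale optional per-parameter init magnitudes, see
#'   [init_bank()].
#' @return A `fit_result` with additional fields `expressions` (extracted
#'   trees) and `steps` (per-stage log of losses and pruned targets).
#' @export
run_recipe <- function(dataset, schedule = prune_schedule(),
                       cfg = train_config(), seed = 1,
                       spec = NULL, init_sd = 0.3, output_scale = NULL) {
  if (is.null(spec)) spec <- dataset$normalization
  if (is.null(spec)) spec <- normalization_spec()
  steps <- list()
  note <- function(stage, ...) {
    steps[[length(steps) + 1L]] <<- c(list(stage = stage), list(...))
    if (cfg$verbose) {
      extra <- list(...)
      cat(sprintf("[recipe] %s %s\n", stage,
                  paste(names(extra), vapply(extra, function(v)
                    paste(format(v), collapse = ","), ""),
                    sep = "=", collapse = " ")))
    }
  }

  bank <- init_bank(seed, spec = spec, init_sd = init_sd,
                    output_scale = output_scale)
  fit <- train(bank, dataset, cfg)
  bank <- fit$bank
  note("initial_train", loss = fit$final_loss, epochs = fit$epochs)

  tgt_cov <- schedule$target_covariates_per_network
  repeat {
    over <- names(bank$networks)[vapply(names(bank$networks), function(nm)
      length(active_covariates(bank, nm)), numeric(1)) > tgt_cov]
    if (length(over) == 0L) break
    sal <- covariate_salience(bank, dataset)
    for (nm in over) {
      cand <- sal[sal$network == nm, ]
      victim <- cand$covariate_index[order(cand$salience,
                                           cand$covariate_index)][1]
      bank <- prune_covariate(bank, nm, victim)
      note("prune_covariate", network = nm, covariate = .cov_names[victim])
    }
    fit <- train(bank, dataset, cfg, epochs = cfg$retrain_epochs)
    bank <- fit$bank
    note("retrain_after_covariate_prune", loss = fit$final_loss,
         epochs = fit$epochs)
  }

  tgt_par <- schedule$target_parameters_per_network
  first <- TRUE
  repeat {
    counts <- vapply(bank$networks, net_unmasked_count, numeric(1))
    if (all(counts <= tgt_par)) break
    sal <- parameter_salience(bank, dataset)
    want <- if (first) schedule$first_parameter_prune_count else
      schedule$subsequent_parameter_prune_count
    for (nm in names(bank$networks)) {
      excess <- net_unmasked_count(bank$networks[[nm]]) - tgt_par
      cnt <- min(want, excess)
      if (cnt <= 0) next
      snet <- sal[sal$network == nm, ]
      victims <- snet[order(snet$salience, seq_len(nrow(snet))), ][
        seq_len(cnt), ]
      bank <- prune_parameters(bank, snet, cnt, per_network = TRUE)
      note("prune_parameters", network = nm, count = cnt,
           removed = paste(sprintf("L%d%s[%d](g=%.3g,S=%.2g)",
                                   victims$layer, victims$kind,
                                   victims$index, victims$value,
                                   victims$salience), collapse = " "))
    }
    note("post_prune_loss", loss = training_loss(bank, dataset))
    first <- FALSE
    fit <- train(bank, dataset, cfg, epochs = cfg$retrain_epochs)
    bank <- fit$bank
    note("retrain_after_parameter_prune", loss = fit$final_loss,
         epochs = fit$epochs)
  }

  fit <- train(bank, dataset, cfg)
  bank <- fit$bank
  note("final_train", loss = fit$final_loss, epochs = fit$epochs)

  fit$bank <- bank
  fit$seed <- seed
  fit$expressions <- extract_expression(bank)
  fit$steps <- steps
  fit
}

#' Run the recipe from several random initializations
#'
#' Executes [run_recipe()] with seeds `base_seed, ..., base_seed + n - 1`
#' and keeps the fit with the lowest final training loss.  The default of 8
#' restarts mitigates poor initializations.
#'
#' @inheritParams run_recipe
#' @param n_restarts number of independent runs.
#' @param base_seed seed of the first run.
#' @return The best `fit_result`, with `restarts_used` and `restart_losses`.
#' @export
multi_restart <- function(dataset, schedule = prune_schedule(),
                          cfg = train_config(), n_restarts = 8,
                          base_seed = 1, spec = NULL, init_sd = 0.3,
                          output_scale = NULL) {
  stopifnot(n_restarts >= 1)
  best <- NULL
  losses <- rep(NA_real_, n_restarts)
  errs <- character(0)
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      run_recipe(dataset, schedule, cfg, seed = base_seed + r - 1L,
                 spec = spec, init_sd = init_sd,
                 output_scale = output_scale),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errs <- c(errs, conditionMessage(fit))
      next
    }
    losses[r] <- fit$final_loss
    if (is.null(best) || fit$final_loss < best$final_loss) best <- fit
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(unique(errs), collapse = "; "))
  best$restarts_used <- n_restarts
  best$restart_losses <- losses
  best
}

#' k-fold cross-validation of the recipe
#'
#' Individuals are partitioned into `k` near-equal folds by a seeded
#' shuffle; the recipe is trained on `k - 1` folds and J_ALE evaluated on
#' the held-out fold.
#'
#' @inheritParams run_recipe
#' @param k number of folds (>= 2).
#' @return List with `fold_losses` (validation J_ALE per fold),
#'   `train_losses`, `mean`, `range`.
#' @export
cross_validate <- function(dataset, schedule = prune_schedule(),
                           cfg = train_config(), k = 5, seed = 1) {
  n <- length(dataset$individuals)
  stopifnot(k >= 2, n >= k)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  val <- tr <- numeric(k)
  for (f in seq_len(k)) {
    if (sum(fold == f) == 0L) stop("empty validation fold")
    dtr <- subset_dataset(dataset, which(fold != f))
    dva <- subset_dataset(dataset, which(fold == f))
    fit <- run_recipe(dtr, schedule, cfg, seed = seed + f)
    tr[f] <- fit$final_loss
    val[f] <- training_loss(fit$bank, dva)
  }
  list(fold_losses = val, train_losses = tr, mean = mean(val),
       range = range(val), fold = fold)
}
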