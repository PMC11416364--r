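# symregpk

Automatic discovery of human-readable covariate model structures for
compartmental pharmacokinetics, by symbolic regression networks trained
through an exact, differentiable PK simulator and sparsified with
Hessian-salience pruning.

## Who this is for

Pharmacometricians and methods researchers who want the *structure* of a
covariate model — which patient covariates enter which PK parameter, and
through what algebraic form — selected automatically from infusion/
concentration time-series data, instead of by stepwise manual search, while
keeping the result a readable closed-form expression.

## The model in brief

Drug disposition follows the three-compartment mammillary model

    x1' = -(k10 + k12 + k13) x1 + k21 x2 + k31 x3 + u / V1
    x2' =   k12 x1 - k21 x2
    x3' =   k13 x1 - k31 x3

(concentrations in µg/L, rates in 1/s, infusion u in µg/s, central volume V1
in L). A covariate model f maps each patient's covariate vector
φ = (age, weight, BMI, gender, sampling site) to the parameter vector
θ = (k10, k12, k13, k21, k31, V1). Here f is a bank of six three-layer
symbolic regression networks whose "activations" are algebraic base
expressions — identity, product, guarded power |z4|^z5, guarded division
z4/(z5+1), and |·| — so a sparse trained bank *is* a formula.

Training minimizes the population mean of per-individual median absolute
logarithmic errors,

    J_ALE = (1/n) Σ_i median_j | ln(C_obs,ij / C_pred,ij) |,

with full-batch ADAM; gradients flow by backprop through the network and the
complex-step Jacobian of an exact (matrix-exponential) simulator. Sparsity
comes from salience pruning: at a trained minimum the loss increase from
zeroing a parameter γk is approximated by S(γk) = γk² Hk (Hessian diagonal),
and analogously per covariate; the least salient targets are removed and the
network retrained, down to 2 covariates and 12 parameters per network.
Covariate-free baselines (one shared θ; one θ per individual) bracket the
achievable loss.

## Worked example

```r
library(symregpk)

# a synthetic cohort from the bundled published propofol covariate model,
# with 15% multiplicative lognormal observation noise
ds <- generate_dataset(cfg = cohort_config(n_individuals = 60, seed = 7,
                                           n_obs = 10, noise_sd = 0.15))

# covariate-free performance limits
cm <- fit_constant_model(ds, seed = 2)
im <- fit_individual_models(ds, warm_start = cm)

# symbolic regression: train + prune to 2 covariates / 12 parameters per
# net, restarted from several initializations (initialization matters)
fit <- multi_restart(ds, prune_schedule(),
                     train_config(lr = 0.02, lr_decay = 0.999,
                                  max_epochs = 800, retrain_epochs = 150,
                                  convergence_window = 150,
                                  convergence_rtol = 1e-8),
                     n_restarts = 4, base_seed = 1, init_sd = 0.1,
                     output_scale = c(k10 = 0.01, k12 = 0.1, k13 = 0.005,
                                      k21 = 0.01, k31 = 5e-4, V1 = 5))
round(fit$restart_losses, 4)
#> [1] 0.7170 1.1813 0.3677 0.6964

c(constant = cm$loss, symreg = fit$final_loss, individual = im$loss)
#>   constant     symreg individual
#> 0.80494858 0.36765774 0.03171539
```

The three numbers are J_ALE losses: the shared-parameter model (0.805) is the
floor any covariate model must beat, the per-individual fits (0.032) are the
ceiling (they over-fit the σ = 0.15 noise, whose population floor is
Φ⁻¹(0.75)·σ ≈ 0.101), and the learned covariate model lands in between
(0.368) — the same qualitative ordering the method reports on real data. The
restart spread (0.37–1.18) is why the recipe is run from several seeds.
`render(fit$expressions$V1, "text")` prints the recovered central-volume
formula (here an affine-and-rational expression in `WGT/160`);
`export_expressions(fit$bank, "out/")` writes text, LaTeX and JSON forms.

A CLI wraps the same pipeline:

```sh
Rscript inst/cli/symregpk.R generate --out cohort.csv --seed 7 --n 60
Rscript inst/cli/symregpk.R evaluate --data cohort.csv --published
Rscript inst/cli/symregpk.R fit --data cohort.csv --out-dir fit/ --restarts 8
```

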