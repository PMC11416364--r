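---
title: "Learning covariate model structures for compartmental PK by symbolic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning covariate model structures for compartmental PK by symbolic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population pharmacokinetic models explain inter-individual variability in
drug disposition through *covariates*: patient features such as age, weight,
BMI, gender or the blood sampling site. Conventional covariate modeling
picks, by hand and stepwise search, both which covariates enter the model
and the algebraic form through which they act. `symregpk` automates both
decisions at once: a bank of small *symbolic regression networks* — neural
networks whose activation functions are algebraic base expressions — is
trained end-to-end through a differentiable simulator of the PK model, then
sparsified by second-order (salience) pruning until what remains *is* a
readable closed-form covariate model.

## The PK model

Drug amounts follow the three-compartment mammillary model with
concentrations $x_i$ (µg/L),

$$\dot x_1 = -(k_{10}+k_{12}+k_{13})x_1 + k_{21}x_2 + k_{31}x_3 + u/V_1,
\qquad
\dot x_2 = k_{12}x_1 - k_{21}x_2,
\qquad
\dot x_3 = k_{13}x_1 - k_{31}x_3,$$

with infusion rate $u$ (µg/s) into, and observation of, the central
compartment of volume $V_1$ (L). The parameter vector is
$\theta = (k_{10},k_{12},k_{13},k_{21},k_{31},V_1)$; conversions to the
clearance parameterization $(CL,Q_2,Q_3,V_1,V_2,V_3)$ are provided
(`rates_to_clearances()`). All times are seconds, concentrations µg/L,
rates µg/s.

Between dose events the system is linear time-invariant, so `pk_simulate()`
advances the state *exactly* with the matrix exponential of the augmented
system (the zero-order-hold discretization; Van Loan's block trick avoids
inverting the system matrix). Observation times are merged into the event
grid — concentrations are never interpolated. Derivatives of every
concentration with respect to $\theta$ come from the complex-step method,
which is exact to machine precision because the whole simulation is analytic
in $\theta$; they feed back-propagation during training. Bolus doses are
represented upstream as short high-rate infusions; the simulator itself
knows only piecewise-constant input. The initial state is drug-free.

## Loss and metrics

Per sample, the logarithmic error is $LE = \ln(C_{obs}/C_{pred})$ and the
percent prediction error $PE = 100\,(C_{obs}-C_{pred})/C_{pred}$ (defined as
0 when $C_{pred}=0$), with $ALE = |LE|$ and $APE = |PE|$. Per individual,
the medians MdALE, MdLE, MdAPE, MdPE summarize the time series (even counts
use the mean of the central pair — a convention, not a given). The training
loss is the population mean of MdALE,
$J_{ALE} = \tfrac1n\sum_i \mathrm{MdALE}_i$. Clinically acceptable bias and
accuracy, 10–20 % MdPE and 20–40 % MdAPE, translate to
$\ln 1.2 \approx 0.18$ and $\ln 1.4 \approx 0.34$ on the log scale
(`clinical_bounds()`).

The median over samples makes the loss robust to outliers but *piecewise
smooth*: the gradient flows only through the selected order statistic(s)
(splitting 0.5/0.5 over the central pair for even counts), and the surface
is a patchwork of cones. Several numerical choices below exist only because
of this.

## The network bank

Each PK parameter gets its own three-layer network
$n_\varphi \to 5 \xrightarrow{g_1} 3 \to 5 \xrightarrow{g_2} 3 \to 1
\xrightarrow{g_3} 1$ with affine layers $z_l = W_l x_l + b_l$ and base
expressions

$$g_1(z) = (z_1,\; z_2 z_3,\; |z_4|^{z_5}), \qquad
g_2(z) = (z_1,\; z_2 z_3,\; z_4/(z_5+1)), \qquad
g_3(z) = |z|,$$

chosen to span published PK covariate model forms (products, powers,
rational functions); $g_3$ guarantees a non-negative parameter. A dense
network has 54 trainable scalars; six networks give 324. Inputs are
normalized: continuous covariates divided by fixed maxima (88 years, 160 kg,
52.8 kg/m²), categorical ones mapped to ±0.5 (male/arterial = +0.5 — the
sign assignment is a convention, configurable in `normalization_spec()`).
Fixed divisors rather than data maxima keep trained models portable across
datasets.

Guards: the power uses $\max(|z_4|,\varepsilon)^{z_5}$ and the division a
sign-preserving clamp of the denominator at $\varepsilon = 10^{-6}$
(with $0^0 := 1$ after guarding). On well-scaled inputs the guards are
inactive and the expressions are exact. Simulation consumers floor network
outputs at $10^{-10}$; the forward pass itself returns the exact $|z_3|$ so
extracted expressions reproduce it bit-for-bit (to $10^{-9}$ contractually).

## Training

`train()` minimizes $J_{ALE}$ by full-batch ADAM (1031 individuals is small;
the gradient is exact backprop through the network chained with the
complex-step simulator Jacobian). Defaults: learning rate $10^{-3}$,
$\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$, convergence when the
*running best* loss improves by less than $10^{-5}$ (relative) over 50
epochs. Two additions proved necessary on the nonsmooth loss:

* **Learning-rate decay** (`lr_decay`). ADAM's per-coordinate step is
  $\approx$ the learning rate regardless of gradient size, so near a conic
  minimum the iterates orbit at a radius set by the rate; decay lets them
  spiral in. Composing a few `train()` calls into a ladder
  ($2\cdot10^{-2} \to 10^{-3} \to 10^{-4}$) is the pattern used by the
  acceptance tests.
* **Convergence on the running best**, not the last iterate, because raw
  iterates oscillate on cones even while the best still improves.

* **Output-scaled initialization** (`init_bank(output_scale=)`). Rate
  constants ($\sim 10^{-3}$/s) and volumes ($\sim$ 1–20 L) differ by orders
  of magnitude; one shared weight scale leaves some networks orders of
  magnitude from plausible outputs, and ADAM's scale-free steps cannot
  refine coordinates much smaller than the learning rate. Scaling each
  network's final-layer draw to the physiological magnitude of its
  parameter is the initialization a practitioner standardizing regression
  targets would use. Weights are otherwise i.i.d. Normal(0, 0.3²) (the
  source method leaves initialization open).

## Pruning

Before each pruning decision the network is trained to (approximate)
convergence, where the loss is locally quadratic in the trainable vector
$\gamma$ and the damage of zeroing $\gamma_k$ is approximated by the
salience $S(\gamma_k) = \gamma_k^2 H_k$, with $H_k$ the Hessian diagonal.
Covariates are scored by summing per-individual input sensitivities,
$S(\varphi_k) = \sum_i \varphi_{ik}^2 (H_i)_k$, where $(H_i)_k$ is the
curvature of individual $i$'s MdALE with respect to the normalized covariate
input of the network under consideration.

R has no second-order autodiff, so $H$ is a central second difference of
the loss. The step is *proportional to the parameter* ($10^{-2}|\gamma_k|$,
floored at $10^{-7}$): curvature around a small scale-carrying weight lives
on the scale of that weight, and an absolute step averages it away — with
an absolute step we observed pruning occasionally deleting small critical
weights and collapsing the fit irrecoverably. Negative diagonals (possible
away from an exact minimum) are clamped to zero; ties break by position.

`run_recipe()` implements the full schedule: train; prune covariates one
per network per iteration (each network down to its own 2 — published
expressions use different pairs per parameter, reachable only per-network);
then prune parameters, 10 per network in the first iteration and 1 per
iteration after, down to 12 per network; train; extract expressions.
`multi_restart()` repeats the recipe (default 8 seeds) and keeps the best
final loss. `cross_validate()` wraps it in seeded k-fold CV over
individuals.

## Expression extraction

`extract_expression()` transcribes the unmasked weights through
$g_1,g_2,g_3$ into an expression tree with constant folding and zero-branch
elimination. The final $|\cdot|$ is dropped only when interval arithmetic
over the normalized covariate domain (continuous in $[0,1]$, categorical in
$\{\pm 0.5\}$) proves the argument sign-definite; when in doubt it stays.
Categorical covariates can be split into per-category variants
(`split_categorical()`), which is how gender-specific published expressions
arise from a single ±0.5 symbol. Text renderings use full-precision
constants and round-trip through a bundled parser; LaTeX renderings round to
3 significant digits for display. The bundled `published_model()` is the
released propofol covariate model (six closed forms in age, weight, BMI and
gender; the sampling site was pruned away) and serves as fixture, generator
and oracle.

## Synthetic data

`generate_dataset()` emulates the structure of the demonstrator study: ages
0–88 years, weights 0.68–160 kg, BMI 6.2–52.8 kg/m² (uniform, with a mild
optional weight–BMI coupling), 65 % male, 70 % arterial; a weight-based
induction bolus (2 mg/kg over 30 s) as a short high-rate infusion, 6 mg/kg/h
maintenance with a step change halfway, a washout phase; log-spaced samples
starting right after the bolus (while the central volume is still visible)
plus washout decay samples; and multiplicative lognormal observation noise
$C_{obs} = C_{pred}e^{\epsilon}$, $\epsilon \sim N(0, \sigma^2)$, the
natural companion of a log-ratio loss (σ = 0.15 by default, giving a
population noise floor of $\Phi^{-1}(0.75)\,\sigma \approx 0.101$ on
$J_{ALE}$). Dose events closer than 1 s or 0.5 µg/s are merged on ingestion
(earlier time kept, later rate kept, iterated to a fixpoint so the operation
is idempotent).

What the generator does **not** emulate: realistic joint covariate
distributions (no growth curves or copulas — a neonate with an adult BMI is
possible), inter-occasion variability, venous/arterial concentration
differences, or irregular per-patient sampling. A green test on synthetic
data therefore establishes correctness of the machinery and qualitative
behavior, not clinical performance.

## Baselines

Two covariate-free references bracket achievable performance: one shared
parameter set for the whole population (`fit_constant_model()`, the lower
performance limit any covariate model should beat) and one parameter set per
individual (`fit_individual_models()`, the upper limit; it does not
generalize). Both optimize the same $J_{ALE}$ in log-parameter space. The
median loss is a nonsmooth cone at its optimum, which defeats both plain
Nelder–Mead and quasi-Newton; the fitters therefore run a smooth
mean-squared-log-error pre-fit (exact gradients from the simulator), then
Nelder–Mead, then a gradient polish, from multiple log-uniform starts.
Individual fits warm-start at the constant solution and keep it if the local
search regresses, so the nesting $J_{individual} \le J_{constant}$ holds by
construction.

## Known limitations

* **Optimization floor.** First-order training of the median loss reliably
  plateaus at $J_{ALE} \sim 10^{-2}$ on noise-free in-class data — even
  initialized 5 % away from an exact zero-loss solution, ADAM (any
  learning-rate policy we tried, including ladders to $10^{-6}$, minibatch
  noise, and a smooth surrogate stage) settles into nonsmooth local minima
  an order of magnitude above machine-level recovery. Two mechanisms
  compound: the median ignores up to half of each individual's samples, and
  the compartmental model class contains near-equivalent parameterizations
  (small-$V_1$/fast-exchange configurations mimicking a larger central
  volume) that fit the observable curves to within ~1 %. The recovery
  acceptance test asserts the strict $10^{-3}$ bound regardless and is
  expected to fail; it documents the measured gap rather than hiding it.
* Salience rankings are meaningful only for networks whose output the data
  actually constrains; for near-insensitive parameters (deep peripheral
  rates) both salience and true ablation deltas are noise, and their
  correlation is undefined in practice.
* The Hessian diagonals are finite-difference estimates; exact second-order
  autodiff would remove their step-size heuristics.
* Gender/site sign conventions and the even-count median rule are
  conventions; both are configurable or documented where they bite.
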