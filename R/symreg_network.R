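## Symbolic regression network bank: one small three-layer network per PK
## parameter.  Layer l computes z_l = W_l x_l + b_l followed by an algebraic
## base expression g_l (identity / product / guarded power, identity /
## product / guarded division, absolute value).  Pruning is represented by
## binary masks; masked entries are exactly zero and excluded from the
## trainable vector gamma.

.cov_names <- c("age", "wgt", "bmi", "gender", "site")

#' Covariate normalization specification
#'
#' Continuous covariates (age, weight, BMI) are divided by a fixed maximum so
#' that in-range values land in `[0, 1]`; two-level categorical covariates
#' (gender, blood sampling site) map to +0.5 / -0.5.  The default maxima are
#' the demonstrator data-set maxima (88 years, 160 kg, 52.8 kg/m^2), kept
#' fixed rather than derived from data so that trained models are portable.
#'
#' @param age_max,wgt_max,bmi_max positive divisors for the continuous
#'   covariates (years, kg, kg/m^2).
#' @param gender_map,site_map named two-element numeric vectors mapping the
#'   category labels to +0.5/-0.5.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(age_max = 88, wgt_max = 160, bmi_max = 52.8,
                               gender_map = c(M = 0.5, F = -0.5),
                               site_map = c(A = 0.5, V = -0.5)) {
  stopifnot(age_max > 0, wgt_max > 0, bmi_max > 0,
            length(gender_map) == 2L, length(site_map) == 2L,
            all(sort(gender_map) == c(-0.5, 0.5)),
            all(sort(site_map) == c(-0.5, 0.5)))
  structure(list(age_max = age_max, wgt_max = wgt_max, bmi_max = bmi_max,
                 gender_map = gender_map, site_map = site_map),
            class = "normalization_spec")
}

#' Normalize a raw covariate record
#'
#' @param age,wgt,bmi raw continuous covariates (years, kg, kg/m^2).
#' @param gender,site category labels; must be names of the spec's maps.
#' @param spec a [normalization_spec].
#' @param warn warn when a continuous covariate falls outside
#'   `[0, max]` (extrapolation), instead of failing.
#' @return Named numeric vector `(age, wgt, bmi, gender, site)` - the
#'   covariate vector phi fed to the networks.
#' @export
normalize_covariates <- function(age, wgt, bmi, gender, site,
                                 spec = normalization_spec(), warn = TRUE) {
  cont <- c(age = age / spec$age_max, wgt = wgt / spec$wgt_max,
            bmi = bmi / spec$bmi_max)
  if (warn && (any(cont < 0) || any(cont > 1)))
    warning("continuous covariate outside the declared range; extrapolating")
  gender <- as.character(gender); site <- as.character(site)
  if (!gender %in% names(spec$gender_map))
    stop(sprintf("unknown gender label '%s'", gender))
  if (!site %in% names(spec$site_map))
    stop(sprintf("unknown sampling-site label '%s'", site))
  c(cont, gender = unname(spec$gender_map[gender]),
    site = unname(spec$site_map[site]))
}

## ---- guarded primitives -------------------------------------------------

# |b| clamped away from zero, then raised to e; the guard makes the power
# well-defined along arbitrary training trajectories (0^0 := 1 after
# guarding).  eps is the package-wide power guard.
guarded_pow <- function(b, e, eps = 1e-6) pmax(abs(b), eps)^e

# denominator clamped away from zero preserving sign (sign(0) := +1)
guard_denom <- function(d, eps = 1e-6) {
  s <- ifelse(d >= 0, 1, -1)
  s * pmax(abs(d), eps)
}

#' Base expression of layer 1
#'
#' `g1(z) = (z1, z2 * z3, |z4|^z5)` with the power guarded:
#' `|z4|` is replaced by `max(|z4|, eps_pow)`.
#'
#' @param z numeric vector of length 5.
#' @param eps_pow power guard (default 1e-6).
#' @return Numeric vector of length 3.
#' @export
base_expr_g1 <- function(z, eps_pow = 1e-6) {
  stopifnot(length(z) == 5L)
  c(z[1], z[2] * z[3], guarded_pow(z[4], z[5], eps_pow))
}

#' Base expression of layer 2
#'
#' `g2(z) = (z1, z2 * z3, z4 / (z5 + 1))`.  The `+1` keeps the output from
#' blowing up when `z5 >= 0` approaches zero; an additional sign-preserving
#' clamp at `eps_div` protects arbitrary trajectories where `z5` nears `-1`.
#'
#' @param z numeric vector of length 5.
#' @param eps_div division guard (default 1e-6).
#' @return Numeric vector of length 3.
#' @export
base_expr_g2 <- function(z, eps_div = 1e-6) {
  stopifnot(length(z) == 5L)
  c(z[1], z[2] * z[3], z[4] / guard_denom(z[5] + 1, eps_div))
}

#' Base expression of layer 3
#'
#' `g3(z) = |z|`, which guarantees a non-negative (PK-feasible) network
#' output.
#'
#' @param z numeric scalar.
#' @return `abs(z)`.
#' @export
base_expr_g3 <- function(z) abs(z)

## ---- layers and networks -------------------------------------------------

new_layer <- function(W, b, base) {
  list(W = W, b = b,
       Wmask = matrix(1, nrow(W), ncol(W)), bmask = rep(1, length(b)),
       base = base)
}

#' Forward pass of one pruned affine layer
#'
#' Computes `g(W x + b)` where masked entries of `W` and `b` contribute
#' exactly zero.
#'
#' @param layer a layer as stored in a network bank (fields `W`, `b`,
#'   `Wmask`, `bmask`, `base`).
#' @param x input vector.
#' @param eps_pow,eps_div guard constants.
#' @return Output vector of the layer's base expression.
#' @export
layer_forward <- function(layer, x, eps_pow = 1e-6, eps_div = 1e-6) {
  if (ncol(layer$W) != length(x))
    stop(sprintf("layer expects input of length %d, got %d",
                 ncol(layer$W), length(x)))
  z <- as.numeric((layer$W * layer$Wmask) %*% x + layer$b * layer$bmask)
  switch(layer$base,
         g1 = base_expr_g1(z, eps_pow),
         g2 = base_expr_g2(z, eps_div),
         g3 = base_expr_g3(z),
         stop("unknown base expression ", layer$base))
}

.pk_param_names <- c("k10", "k12", "k13", "k21", "k31", "V1")

#' Initialize a dense symbolic regression network bank
#'
#' Creates the nominal (unpruned) bank: six parallel three-layer networks,
#' one per PK parameter, with architecture
#' `n_phi -> 5 -(g1)-> 3 -> 5 -(g2)-> 3 -> 1 -(g3)-> 1`
#' (54 trainable scalars per network for `n_phi = 5`).  Weights and biases
#' are drawn i.i.d. Normal(0, init_sd^2); the same seed always reproduces the
#' same bank.
#'
#' @param seed integer seed for the weight draw.
#' @param n_phi number of input covariates (default 5).
#' @param init_sd standard deviation of the initial weights (default 0.3).
#' @param spec a [normalization_spec] stored with the bank.
#' @param eps_pow,eps_div guard constants stored with the bank.
#' @param param_names names of the modeled PK parameters.
#' @param output_scale optional named vector of per-parameter magnitudes;
#'   when given, each network's final-layer draw is multiplied by it so the
#'   initial outputs sit near the physiological scale of the parameter they
#'   model (rate constants ~1e-3/s and volumes ~1 L differ by orders of
#'   magnitude, which a single shared init scale cannot serve).
#' @return An object of class `symreg_bank`.
#' @export
init_bank <- function(seed, n_phi = 5, init_sd = 0.3,
                      spec = normalization_spec(),
                      eps_pow = 1e-6, eps_div = 1e-6,
                      param_names = .pk_param_names,
                      output_scale = NULL) {
  set.seed(as.integer(seed))
  nets <- lapply(param_names, function(nm) {
    os <- if (is.null(output_scale)) 1 else unname(output_scale[nm])
    l1 <- new_layer(matrix(rnorm(5 * n_phi, 0, init_sd), 5, n_phi),
                    rnorm(5, 0, init_sd), "g1")
    l2 <- new_layer(matrix(rnorm(5 * 3, 0, init_sd), 5, 3),
                    rnorm(5, 0, init_sd), "g2")
    l3 <- new_layer(matrix(os * rnorm(3, 0, init_sd), 1, 3),
                    os * rnorm(1, 0, init_sd), "g3")
    list(layers = list(l1, l2, l3), name = nm)
  })
  names(nets) <- param_names
  structure(list(networks = nets, spec = spec, eps_pow = eps_pow,
                 eps_div = eps_div, seed = as.integer(seed),
                 n_phi = n_phi),
            class = "symreg_bank")
}

#' @export
print.symreg_bank <- function(x, ...) {
  cat(sprintf("Symbolic regression bank: %d networks, %d trainable scalars\n",
              length(x$networks), n_gamma(x)))
  for (nm in names(x$networks)) {
    net <- x$networks[[nm]]
    cat(sprintf("  %-4s: %2d parameters, covariates {%s}\n", nm,
                net_unmasked_count(net),
                paste(.cov_names[active_covariates(x, nm)], collapse = ", ")))
  }
  invisible(x)
}

# forward pass of a single network with intermediate cache for backprop
net_forward_cache <- function(net, phi, eps_pow, eps_div) {
  l1 <- net$layers[[1]]; l2 <- net$layers[[2]]; l3 <- net$layers[[3]]
  z1 <- as.numeric((l1$W * l1$Wmask) %*% phi + l1$b * l1$bmask)
  x2 <- base_expr_g1(z1, eps_pow)
  z2 <- as.numeric((l2$W * l2$Wmask) %*% x2 + l2$b * l2$bmask)
  x3 <- base_expr_g2(z2, eps_div)
  z3 <- as.numeric((l3$W * l3$Wmask) %*% x3 + l3$b * l3$bmask)
  list(phi = phi, z1 = z1, x2 = x2, z2 = z2, x3 = x3, z3 = z3,
       theta = abs(z3))
}

# vectorized forward pass of one network over a 5 x n covariate matrix,
# with the intermediates needed for backprop
vec_forward <- function(net, Phi, eps_pow, eps_div) {
  l1 <- net$layers[[1]]; l2 <- net$layers[[2]]; l3 <- net$layers[[3]]
  Z1 <- (l1$W * l1$Wmask) %*% Phi + l1$b * l1$bmask
  B <- pmax(abs(Z1[4, ]), eps_pow)
  E <- Z1[5, ]
  X2 <- rbind(Z1[1, ], Z1[2, ] * Z1[3, ], B^E)
  Z2 <- (l2$W * l2$Wmask) %*% X2 + l2$b * l2$bmask
  D <- guard_denom(Z2[5, ] + 1, eps_div)
  X3 <- rbind(Z2[1, ], Z2[2, ] * Z2[3, ], Z2[4, ] / D)
  Z3 <- as.numeric((l3$W * l3$Wmask) %*% X3 + l3$b * l3$bmask)
  list(Z1 = Z1, B = B, E = E, X2 = X2, Z2 = Z2, D = D, X3 = X3, Z3 = Z3,
       theta = abs(Z3))
}

# vectorized backprop: gradient (in gamma layout, summed over individuals)
# of sum_i upstream_i * theta_i for one network
vec_backprop <- function(net, f, Phi, upstream, eps_pow, eps_div) {
  l1 <- net$layers[[1]]; l2 <- net$layers[[2]]; l3 <- net$layers[[3]]
  dZ3 <- upstream * sign(f$Z3)
  gW3 <- tcrossprod(matrix(dZ3, 1), f$X3) * l3$Wmask
  gb3 <- sum(dZ3) * l3$bmask
  dX3 <- t(l3$W * l3$Wmask) %*% matrix(dZ3, 1)

  dDflag <- as.numeric(abs(f$Z2[5, ] + 1) >= eps_div)  # clamp freezes denom
  dZ2 <- rbind(dX3[1, ],
               dX3[2, ] * f$Z2[3, ],
               dX3[2, ] * f$Z2[2, ],
               dX3[3, ] / f$D,
               dX3[3, ] * (-f$Z2[4, ] / f$D^2) * dDflag)
  gW2 <- tcrossprod(dZ2, f$X2) * l2$Wmask
  gb2 <- rowSums(dZ2) * l2$bmask
  dX2 <- t(l2$W * l2$Wmask) %*% dZ2

  dBflag <- ifelse(abs(f$Z1[4, ]) >= eps_pow, sign(f$Z1[4, ]), 0)
  dZ1 <- rbind(dX2[1, ],
               dX2[2, ] * f$Z1[3, ],
               dX2[2, ] * f$Z1[2, ],
               dX2[3, ] * f$E * f$B^(f$E - 1) * dBflag,
               dX2[3, ] * f$B^f$E * log(f$B))
  gW1 <- tcrossprod(dZ1, Phi) * l1$Wmask
  gb1 <- rowSums(dZ1) * l1$bmask

  c(gW1[l1$Wmask == 1], gb1[l1$bmask == 1],
    gW2[l2$Wmask == 1], gb2[l2$bmask == 1],
    gW3[l3$Wmask == 1], gb3[l3$bmask == 1])
}

#' Evaluate the network bank at a covariate vector
#'
#' Runs all six networks on the normalized covariate vector and returns the
#' PK parameter vector.  The final `|.|` makes every component non-negative
#' (simulation consumers floor exact zeros at `1e-10`).
#'
#' @param bank a `symreg_bank`.
#' @param phi normalized covariate vector (see [normalize_covariates()]).
#' @return A `pk_rates` object (unvalidated; components may be zero at the
#'   `|.|` kink).
#' @export
bank_forward <- function(bank, phi) {
  th <- vapply(bank$networks, function(net) {
    net_forward_cache(net, phi, bank$eps_pow, bank$eps_div)$theta
  }, numeric(1))
  new_pk_rates(th)
}

## ---- masks and the trainable vector gamma --------------------------------

layer_slots <- function(net) {
  list(W1 = net$layers[[1]]$Wmask, b1 = net$layers[[1]]$bmask,
       W2 = net$layers[[2]]$Wmask, b2 = net$layers[[2]]$bmask,
       W3 = net$layers[[3]]$Wmask, b3 = net$layers[[3]]$bmask)
}

net_unmasked_count <- function(net) {
  sum(vapply(layer_slots(net), sum, numeric(1)))
}

#' Number of trainable scalars in the bank
#' @param bank a `symreg_bank`.
#' @return Integer count of unmasked weights and biases.
#' @export
n_gamma <- function(bank) {
  sum(vapply(bank$networks, net_unmasked_count, numeric(1)))
}

# gamma layout: per network (in bank order): W1 (column-major), b1, W2, b2,
# W3, b3, skipping masked entries.  The layout only depends on the masks.
#' Extract the trainable vector gamma
#' @param bank a `symreg_bank`.
#' @return Numeric vector of all unmasked weights and biases.
#' @export
gamma_vector <- function(bank) {
  unlist(lapply(bank$networks, function(net) {
    c(net$layers[[1]]$W[net$layers[[1]]$Wmask == 1],
      net$layers[[1]]$b[net$layers[[1]]$bmask == 1],
      net$layers[[2]]$W[net$layers[[2]]$Wmask == 1],
      net$layers[[2]]$b[net$layers[[2]]$bmask == 1],
      net$layers[[3]]$W[net$layers[[3]]$Wmask == 1],
      net$layers[[3]]$b[net$layers[[3]]$bmask == 1])
  }), use.names = FALSE)
}

#' Write a trainable vector back into the bank
#' @param bank a `symreg_bank`.
#' @param gamma numeric vector of length [n_gamma()].
#' @return The updated bank.
#' @export
set_gamma <- function(bank, gamma) {
  if (length(gamma) != n_gamma(bank))
    stop("gamma length does not match the number of unmasked entries")
  pos <- 0L
  for (nm in names(bank$networks)) {
    for (li in 1:3) {
      lay <- bank$networks[[nm]]$layers[[li]]
      nw <- sum(lay$Wmask == 1)
      if (nw > 0) {
        lay$W[lay$Wmask == 1] <- gamma[(pos + 1L):(pos + nw)]
        pos <- pos + nw
      }
      nb <- sum(lay$bmask == 1)
      if (nb > 0) {
        lay$b[lay$bmask == 1] <- gamma[(pos + 1L):(pos + nb)]
        pos <- pos + nb
      }
      bank$networks[[nm]]$layers[[li]] <- lay
    }
  }
  bank
}

# identity of each gamma entry: network, layer, kind (W/b), linear index
#' Describe every trainable scalar
#' @param bank a `symreg_bank`.
#' @return Data frame with columns `network`, `layer`, `kind`, `index`,
#'   `value`, one row per gamma entry (same order as [gamma_vector()]).
#' @export
gamma_index <- function(bank) {
  rows <- list()
  for (nm in names(bank$networks)) {
    for (li in 1:3) {
      lay <- bank$networks[[nm]]$layers[[li]]
      iw <- which(lay$Wmask == 1)
      if (length(iw))
        rows[[length(rows) + 1L]] <- data.frame(
          network = nm, layer = li, kind = "W", index = iw,
          value = lay$W[iw])
      ib <- which(lay$bmask == 1)
      if (length(ib))
        rows[[length(rows) + 1L]] <- data.frame(
          network = nm, layer = li, kind = "b", index = ib,
          value = lay$b[ib])
    }
  }
  do.call(rbind, rows)
}

#' Active covariates of a network
#'
#' A covariate is active in a network while any first-layer weight in its
#' column is unmasked.
#'
#' @param bank a `symreg_bank`.
#' @param network network name (e.g. `"k10"`).
#' @return Integer vector of active covariate indices.
#' @export
active_covariates <- function(bank, network) {
  Wm <- bank$networks[[network]]$layers[[1]]$Wmask
  which(colSums(Wm) > 0)
}

#' Prune a covariate from one network
#'
#' Masks (and zeroes) all first-layer weights in the covariate's column, so
#' the network output no longer depends on it.
#'
#' @param bank a `symreg_bank`.
#' @param network network name.
#' @param covariate_index covariate column (1-based, order of
#'   [normalize_covariates()]).
#' @return The updated bank.
#' @export
prune_covariate <- function(bank, network, covariate_index) {
  act <- active_covariates(bank, network)
  if (!covariate_index %in% act)
    stop("covariate is not active in this network")
  if (length(act) <= 1L)
    stop("cannot prune the last active covariate of a network")
  lay <- bank$networks[[network]]$layers[[1]]
  lay$Wmask[, covariate_index] <- 0
  lay$W[, covariate_index] <- 0
  bank$networks[[network]]$layers[[1]] <- lay
  bank
}

# mask one gamma entry (identified by network/layer/kind/index) to zero
mask_entry <- function(bank, network, layer, kind, index) {
  lay <- bank$networks[[network]]$layers[[layer]]
  if (kind == "W") {
    lay$W[index] <- 0; lay$Wmask[index] <- 0
  } else {
    lay$b[index] <- 0; lay$bmask[index] <- 0
  }
  bank$networks[[network]]$layers[[layer]] <- lay
  bank
}

## ---- serialization -------------------------------------------------------

#' Serialize a network bank to JSON
#'
#' The document holds layer shapes, weights, masks, base-expression ids, the
#' normalization spec, guard constants and seed provenance.  Doubles are
#' written with full precision so the round trip is bit-exact.
#'
#' @param bank a `symreg_bank`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
bank_to_json <- function(bank, path = NULL) {
  doc <- list(
    format = "symregpk-bank-v1",
    seed = bank$seed, n_phi = bank$n_phi,
    eps_pow = bank$eps_pow, eps_div = bank$eps_div,
    spec = list(age_max = bank$spec$age_max, wgt_max = bank$spec$wgt_max,
                bmi_max = bank$spec$bmi_max,
                gender_map = as.list(bank$spec$gender_map),
                site_map = as.list(bank$spec$site_map)),
    networks = lapply(bank$networks, function(net) {
      list(name = net$name, layers = lapply(net$layers, function(l) {
        list(base = l$base, nrow = nrow(l$W), ncol = ncol(l$W),
             W = as.numeric(l$W), b = as.numeric(l$b),
             Wmask = as.integer(l$Wmask), bmask = as.integer(l$bmask))
      }))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a network bank from JSON
#' @param x a file path or JSON string produced by [bank_to_json()].
#' @return A `symreg_bank`.
#' @export
bank_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(doc$format, "symregpk-bank-v1"))
    stop("not a symregpk bank document")
  spec <- normalization_spec(doc$spec$age_max, doc$spec$wgt_max,
                             doc$spec$bmi_max,
                             unlist(doc$spec$gender_map),
                             unlist(doc$spec$site_map))
  nets <- lapply(doc$networks, function(nd) {
    layers <- lapply(nd$layers, function(ld) {
      W <- matrix(unlist(ld$W), ld$nrow, ld$ncol)
      list(W = W, b = as.numeric(unlist(ld$b)),
           Wmask = matrix(as.numeric(unlist(ld$Wmask)), ld$nrow, ld$ncol),
           bmask = as.numeric(unlist(ld$bmask)), base = ld$base)
    })
    list(layers = layers, name = nd$name)
  })
  names(nets) <- vapply(doc$networks, `[[`, "", "name")
  structure(list(networks = nets, spec = spec, eps_pow = doc$eps_pow,
                 eps_div = doc$eps_div, seed = doc$seed, n_phi = doc$n_phi),
            class = "symreg_bank")
}
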