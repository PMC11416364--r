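## Expression trees: the human-readable form of a (pruned) network.  Nodes
## are plain lists: const(value), cov(name) [evaluates to the *normalized*
## covariate], sum(terms), prod(a, b), div(num, den), pow(base, exponent)
## [guarded |base|^exponent], abs(a).  The guard conventions are identical to
## the network's, so tree evaluation reproduces the forward pass.

ex_const <- function(v) list(type = "const", value = v)
ex_cov <- function(name) list(type = "cov", name = name)
ex_sum <- function(terms) list(type = "sum", terms = terms)
ex_prod <- function(a, b) list(type = "prod", a = a, b = b)
ex_div <- function(num, den) list(type = "div", num = num, den = den)
ex_pow <- function(base, expo) list(type = "pow", base = base, expo = expo)
ex_abs <- function(a) list(type = "abs", a = a)

is_const <- function(t) identical(t$type, "const")

## constant folding and structural simplification (zero/one elimination)
fold_tree <- function(t, eps_pow = 1e-6, eps_div = 1e-6) {
  switch(t$type,
    const = t,
    cov = t,
    sum = {
      terms <- lapply(t$terms, fold_tree, eps_pow = eps_pow, eps_div = eps_div)
      cval <- 0; rest <- list()
      for (tm in terms) {
        if (is_const(tm)) cval <- cval + tm$value else rest[[length(rest) + 1L]] <- tm
      }
      if (length(rest) == 0L) return(ex_const(cval))
      if (cval != 0) rest[[length(rest) + 1L]] <- ex_const(cval)
      if (length(rest) == 1L) rest[[1L]] else ex_sum(rest)
    },
    prod = {
      a <- fold_tree(t$a, eps_pow, eps_div); b <- fold_tree(t$b, eps_pow, eps_div)
      if (is_const(a) && is_const(b)) return(ex_const(a$value * b$value))
      if (is_const(a) && a$value == 0) return(ex_const(0))
      if (is_const(b) && b$value == 0) return(ex_const(0))
      if (is_const(a) && a$value == 1) return(b)
      if (is_const(b) && b$value == 1) return(a)
      ex_prod(a, b)
    },
    div = {
      num <- fold_tree(t$num, eps_pow, eps_div); den <- fold_tree(t$den, eps_pow, eps_div)
      if (is_const(num) && num$value == 0) return(ex_const(0))
      if (is_const(num) && is_const(den))
        return(ex_const(num$value / guard_denom(den$value, eps_div)))
      if (is_const(den) && abs(den$value) >= eps_div && den$value == 1) return(num)
      ex_div(num, den)
    },
    pow = {
      base <- fold_tree(t$base, eps_pow, eps_div); expo <- fold_tree(t$expo, eps_pow, eps_div)
      if (is_const(expo) && expo$value == 0) return(ex_const(1))
      if (is_const(base) && is_const(expo))
        return(ex_const(guarded_pow(base$value, expo$value, eps_pow)))
      ex_pow(base, expo)
    },
    abs = {
      a <- fold_tree(t$a, eps_pow, eps_div)
      if (is_const(a)) return(ex_const(abs(a$value)))
      ex_abs(a)
    },
    stop("unknown node type ", t$type))
}

## conservative interval arithmetic over the normalized covariate domain
## (continuous in [0,1], categorical in {-0.5, +0.5}); used to discharge the
## final |.| when its argument is provably sign-definite
tree_interval <- function(t, eps_pow = 1e-6, eps_div = 1e-6) {
  switch(t$type,
    const = c(t$value, t$value),
    cov = if (t$name %in% c("gender", "site")) c(-0.5, 0.5) else c(0, 1),
    sum = {
      iv <- c(0, 0)
      for (tm in t$terms) iv <- iv + tree_interval(tm, eps_pow, eps_div)
      iv
    },
    prod = {
      a <- tree_interval(t$a, eps_pow, eps_div); b <- tree_interval(t$b, eps_pow, eps_div)
      pr <- c(a[1] * b[1], a[1] * b[2], a[2] * b[1], a[2] * b[2])
      range(pr)
    },
    div = {
      num <- tree_interval(t$num, eps_pow, eps_div); den <- tree_interval(t$den, eps_pow, eps_div)
      if (den[1] <= eps_div && den[2] >= -eps_div) return(c(-Inf, Inf))
      qs <- c(num[1] / den[1], num[1] / den[2], num[2] / den[1], num[2] / den[2])
      range(qs)
    },
    pow = {
      b <- tree_interval(t$base, eps_pow, eps_div); e <- tree_interval(t$expo, eps_pow, eps_div)
      ab <- c(max(min(abs(b[1]), abs(b[2])), eps_pow), max(abs(b)))
      if (b[1] < 0 && b[2] > 0) ab[1] <- eps_pow
      cs <- as.vector(outer(ab, e, `^`))
      range(cs)
    },
    abs = {
      a <- tree_interval(t$a, eps_pow, eps_div)
      if (a[1] >= 0) a else if (a[2] <= 0) c(-a[2], -a[1]) else c(0, max(abs(a)))
    },
    stop("unknown node type ", t$type))
}

drop_abs_if_provable <- function(t, eps_pow, eps_div) {
  if (!identical(t$type, "abs")) return(t)
  iv <- tree_interval(t$a, eps_pow, eps_div)
  if (all(is.finite(iv)) && iv[1] >= 0) return(t$a)
  if (all(is.finite(iv)) && iv[2] <= 0)
    return(fold_tree(ex_prod(ex_const(-1), t$a), eps_pow, eps_div))
  t
}

## symbolic affine map: inputs is a list of trees; returns a list of trees
sym_affine <- function(W, b, Wmask, bmask, inputs) {
  lapply(seq_len(nrow(W)), function(i) {
    terms <- list()
    for (j in seq_len(ncol(W))) {
      w <- W[i, j] * Wmask[i, j]
      if (w != 0)
        terms[[length(terms) + 1L]] <- ex_prod(ex_const(w), inputs[[j]])
    }
    bi <- b[i] * bmask[i]
    if (bi != 0) terms[[length(terms) + 1L]] <- ex_const(bi)
    if (length(terms) == 0L) ex_const(0)
    else if (length(terms) == 1L) terms[[1L]] else ex_sum(terms)
  })
}

#' Extract closed-form expressions from a network bank
#'
#' Transcribes each network's active weights through the base expressions
#' into an expression tree, with constant folding and zero-branch
#' elimination.  The final `|.|` is dropped only when interval arithmetic
#' over the normalized covariate domain proves its argument sign-definite
#' (conservative: kept when in doubt).
#'
#' @param bank a `symreg_bank` in any mask state.
#' @return Named list of expression trees, one per PK parameter, with
#'   attribute `spec` (the bank's normalization spec).
#' @export
extract_expression <- function(bank) {
  ep <- bank$eps_pow; ed <- bank$eps_div
  phi <- lapply(.cov_names[seq_len(bank$n_phi)], ex_cov)
  out <- lapply(bank$networks, function(net) {
    l1 <- net$layers[[1]]; l2 <- net$layers[[2]]; l3 <- net$layers[[3]]
    z1 <- sym_affine(l1$W, l1$b, l1$Wmask, l1$bmask, phi)
    x2 <- list(z1[[1]], ex_prod(z1[[2]], z1[[3]]), ex_pow(z1[[4]], z1[[5]]))
    z2 <- sym_affine(l2$W, l2$b, l2$Wmask, l2$bmask, x2)
    x3 <- list(z2[[1]], ex_prod(z2[[2]], z2[[3]]),
               ex_div(z2[[4]], ex_sum(list(z2[[5]], ex_const(1)))))
    z3 <- sym_affine(l3$W, l3$b, l3$Wmask, l3$bmask, x3)
    t <- fold_tree(ex_abs(z3[[1]]), ep, ed)
    if (!is_const(t)) t <- drop_abs_if_provable(t, ep, ed)
    t
  })
  attr(out, "spec") <- bank$spec
  attr(out, "eps_pow") <- ep
  attr(out, "eps_div") <- ed
  out
}

tree_eval <- function(t, phi, eps_pow = 1e-6, eps_div = 1e-6) {
  switch(t$type,
    const = t$value,
    cov = {
      if (!t$name %in% names(phi)) stop("missing covariate '", t$name, "'")
      unname(phi[[t$name]])
    },
    sum = sum(vapply(t$terms, tree_eval, numeric(1), phi = phi,
                     eps_pow = eps_pow, eps_div = eps_div)),
    prod = tree_eval(t$a, phi, eps_pow, eps_div) *
           tree_eval(t$b, phi, eps_pow, eps_div),
    div = tree_eval(t$num, phi, eps_pow, eps_div) /
          guard_denom(tree_eval(t$den, phi, eps_pow, eps_div), eps_div),
    pow = guarded_pow(tree_eval(t$base, phi, eps_pow, eps_div),
                      tree_eval(t$expo, phi, eps_pow, eps_div), eps_pow),
    abs = abs(tree_eval(t$a, phi, eps_pow, eps_div)),
    stop("unknown node type ", t$type))
}

#' Evaluate an expression tree at raw covariates
#'
#' Raw covariates are normalized by `spec` and substituted for the tree's
#' covariate symbols; evaluation uses the same guard conventions as the
#' network forward pass.
#'
#' @param tree an expression tree (one element of [extract_expression()]).
#' @param age,wgt,bmi,gender,site raw covariates.
#' @param spec a [normalization_spec].
#' @param eps_pow,eps_div guard constants.
#' @return Numeric scalar.
#' @export
evaluate_expression <- function(tree, age, wgt, bmi, gender, site,
                                spec = normalization_spec(),
                                eps_pow = 1e-6, eps_div = 1e-6) {
  phi <- normalize_covariates(age, wgt, bmi, gender, site, spec, warn = FALSE)
  tree_eval(tree, phi, eps_pow, eps_div)
}

## ---- rendering -----------------------------------------------------------

num_str <- function(v) trimws(formatC(v, digits = 15, format = "g"))
num_str_pretty <- function(v) trimws(formatC(v, digits = 3, format = "g"))

cov_sym_text <- function(name, spec) {
  switch(name,
    age = sprintf("(AGE/%s)", num_str(spec$age_max)),
    wgt = sprintf("(WGT/%s)", num_str(spec$wgt_max)),
    bmi = sprintf("(BMI/%s)", num_str(spec$bmi_max)),
    gender = "GDR", site = "SITE")
}

render_text <- function(t, spec, digits_fn) {
  r <- function(t) {
    switch(t$type,
      const = digits_fn(t$value),
      cov = cov_sym_text(t$name, spec),
      sum = paste0("(", paste(vapply(t$terms, r, ""), collapse = " + "), ")"),
      prod = paste0("(", r(t$a), " * ", r(t$b), ")"),
      div = paste0("(", r(t$num), " / ", r(t$den), ")"),
      pow = paste0("abs(", r(t$base), ")^(", r(t$expo), ")"),
      abs = paste0("abs(", r(t$a), ")"))
  }
  r(t)
}

cov_sym_latex <- function(name, spec) {
  switch(name,
    age = "\\frac{\\mathrm{AGE}}{\\mathrm{AGE}_{\\max}}",
    wgt = "\\frac{\\mathrm{WGT}}{\\mathrm{WGT}_{\\max}}",
    bmi = "\\frac{\\mathrm{BMI}}{\\mathrm{BMI}_{\\max}}",
    gender = "\\mathrm{GDR}", site = "\\mathrm{SITE}")
}

render_latex <- function(t, spec) {
  r <- function(t) {
    switch(t$type,
      const = num_str_pretty(t$value),
      cov = cov_sym_latex(t$name, spec),
      sum = paste0("\\left(", paste(vapply(t$terms, r, ""), collapse = " + "),
                   "\\right)"),
      prod = paste0(r(t$a), " \\cdot ", r(t$b)),
      div = paste0("\\frac{", r(t$num), "}{", r(t$den), "}"),
      pow = paste0("\\left|", r(t$base), "\\right|^{", r(t$expo), "}"),
      abs = paste0("\\left|", r(t$a), "\\right|"))
  }
  r(t)
}

#' Render an expression tree
#'
#' The `text` form uses full-precision constants and round-trips through
#' [parse_expression()] to an equivalent tree; the `latex` form rounds
#' constants to 3 significant digits for display.
#'
#' @param tree an expression tree.
#' @param format `"text"` or `"latex"`.
#' @param spec a [normalization_spec] supplying the covariate divisors.
#' @return A character string.
#' @export
render <- function(tree, format = c("text", "latex"),
                   spec = normalization_spec()) {
  format <- match.arg(format)
  if (format == "text") render_text(tree, spec, num_str)
  else render_latex(tree, spec)
}

#' Parse the text rendering of an expression
#'
#' A small recursive-descent parser for the grammar emitted by
#' [render()]: numbers, symbols (`AGE`, `WGT`, `BMI`, `GDR`, `SITE`),
#' `+ - * / ^`, `abs()` and parentheses.  Symbols evaluate to *raw*
#' covariates; dividing by the rendered maxima reproduces normalization, so
#' the parsed tree evaluates identically to the original.
#'
#' @param s a string produced by `render(tree, "text")`.
#' @return A function `f(age, wgt, bmi, gender, site, spec)` evaluating the
#'   parsed expression (gender/site passed as labels).
#' @export
parse_expression <- function(s) {
  toks <- regmatches(s, gregexpr(
    "-?[0-9]+\\.?[0-9]*(e[-+]?[0-9]+)?|[A-Za-z]+|[()+*/^-]", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  expect <- function(t) {
    got <- advance()
    if (!identical(got, t)) stop("parse error: expected '", t, "', got '", got, "'")
  }
  parse_primary <- function() {
    t <- peek()
    if (t == "(") { advance(); e <- parse_sum(); expect(")"); return(e) }
    if (t == "abs") {
      advance(); expect("("); e <- parse_sum(); expect(")")
      return(ex_abs(e))
    }
    if (t %in% c("AGE", "WGT", "BMI", "GDR", "SITE")) {
      advance()
      nm <- c(AGE = "age", WGT = "wgt", BMI = "bmi", GDR = "gender",
              SITE = "site")[[t]]
      return(list(type = "rawcov", name = nm))
    }
    if (t == "-") { advance(); return(ex_prod(ex_const(-1), parse_primary())) }
    if (grepl("^-?[0-9.]", t)) { advance(); return(ex_const(as.numeric(t))) }
    stop("parse error at '", t, "'")
  }
  parse_pow <- function() {
    b <- parse_primary()
    if (peek() == "^") {
      advance()
      e <- parse_pow()
      # abs(x)^(e) renders from a pow node; fold abs back into the guard
      if (identical(b$type, "abs")) return(ex_pow(b$a, e))
      return(ex_pow(b, e))
    }
    b
  }
  parse_term <- function() {
    x <- parse_pow()
    while (peek() %in% c("*", "/")) {
      op <- advance()
      y <- parse_pow()
      x <- if (op == "*") ex_prod(x, y) else ex_div(x, y)
    }
    x
  }
  parse_sum <- function() {
    terms <- list(parse_term())
    while (peek() %in% c("+", "-")) {
      op <- advance()
      y <- parse_term()
      if (op == "-") y <- ex_prod(ex_const(-1), y)
      terms[[length(terms) + 1L]] <- y
    }
    if (length(terms) == 1L) terms[[1L]] else ex_sum(terms)
  }
  tree <- parse_sum()
  if (pos <= length(toks)) stop("parse error: trailing input")
  eval_raw <- function(t, raw, eps_pow, eps_div) {
    if (identical(t$type, "rawcov")) return(raw[[t$name]])
    switch(t$type,
      const = t$value,
      sum = sum(vapply(t$terms, eval_raw, numeric(1), raw = raw,
                       eps_pow = eps_pow, eps_div = eps_div)),
      prod = eval_raw(t$a, raw, eps_pow, eps_div) *
             eval_raw(t$b, raw, eps_pow, eps_div),
      div = eval_raw(t$num, raw, eps_pow, eps_div) /
            guard_denom(eval_raw(t$den, raw, eps_pow, eps_div), eps_div),
      pow = guarded_pow(eval_raw(t$base, raw, eps_pow, eps_div),
                        eval_raw(t$expo, raw, eps_pow, eps_div), eps_pow),
      abs = abs(eval_raw(t$a, raw, eps_pow, eps_div)))
  }
  function(age, wgt, bmi, gender, site, spec = normalization_spec(),
           eps_pow = 1e-6, eps_div = 1e-6) {
    raw <- list(age = age, wgt = wgt, bmi = bmi,
                gender = unname(spec$gender_map[as.character(gender)]),
                site = unname(spec$site_map[as.character(site)]))
    eval_raw(tree, raw, eps_pow, eps_div)
  }
}

#' Split a tree on a categorical covariate
#'
#' Substitutes each category value (+0.5/-0.5) for the covariate symbol and
#' folds constants, producing per-category expression variants (e.g. separate
#' male/female formulas).
#'
#' @param tree an expression tree.
#' @param covariate `"gender"` or `"site"`.
#' @param spec a [normalization_spec].
#' @return Named list of folded trees, one per category label.
#' @export
split_categorical <- function(tree, covariate = "gender",
                              spec = normalization_spec()) {
  map <- if (covariate == "gender") spec$gender_map else spec$site_map
  subst <- function(t, v) {
    if (identical(t$type, "cov") && identical(t$name, covariate))
      return(ex_const(v))
    switch(t$type,
      const = t, cov = t,
      sum = ex_sum(lapply(t$terms, subst, v = v)),
      prod = ex_prod(subst(t$a, v), subst(t$b, v)),
      div = ex_div(subst(t$num, v), subst(t$den, v)),
      pow = ex_pow(subst(t$base, v), subst(t$expo, v)),
      abs = ex_abs(subst(t$a, v)))
  }
  out <- lapply(map, function(v) fold_tree(subst(tree, v)))
  names(out) <- names(map)
  out
}

## ---- published covariate model fixture -----------------------------------

# The released propofol covariate model: six closed-form expressions in
# normalized age (A), weight (W), BMI (B) and gender (g = +0.5 male / -0.5
# female); the sampling site was pruned away and does not appear.  Gender
# enters symmetrically (+/- terms), encoded here as 2g * coefficient.
published_model_trees <- function() {
  A <- ex_cov("age"); W <- ex_cov("wgt"); B <- ex_cov("bmi")
  G <- ex_cov("gender")
  cmul <- function(c, t) ex_prod(ex_const(c), t)
  gmul <- function(c, t) ex_prod(ex_prod(ex_const(2 * c), G), t)
  sq <- function(t) ex_prod(t, t)

  k10 <- ex_sum(list(cmul(0.00441, W), ex_const(0.00342)))
  k12 <- ex_abs(ex_div(
    ex_sum(list(cmul(0.158, A), cmul(-0.00431, B), ex_const(-0.188))),
    ex_sum(list(cmul(0.64, A), cmul(-0.0174, B), ex_const(-0.743)))))
  k13 <- ex_div(
    ex_sum(list(cmul(0.0058, sq(A)), gmul(0.00208, A), ex_const(0.0026))),
    ex_sum(list(cmul(2.75, sq(A)), gmul(0.985, A), ex_const(0.601))))
  k21 <- ex_abs(ex_sum(list(
    cmul(0.00408, sq(B)), cmul(-8.16e-4, B),
    cmul(-0.0057, ex_prod(B, W)), ex_const(0.00218))))
  k31 <- ex_sum(list(ex_const(4.52e-5), gmul(1.92e-5, A)))
  V1 <- ex_sum(list(cmul(0.0596, A), cmul(18.7, W), cmul(-13.7, sq(W)),
                    cmul(-3.5, ex_prod(A, W)), ex_const(-0.0557)))
  out <- list(k10 = k10, k12 = k12, k13 = k13, k21 = k21, k31 = k31, V1 = V1)
  attr(out, "spec") <- normalization_spec()
  out
}

#' Published propofol covariate model
#'
#' Evaluates the released symbolic-regression covariate model for propofol:
#' closed-form expressions mapping age, weight, BMI and gender to the six
#' three-compartment PK parameters (normalization maxima 88 years, 160 kg,
#' 52.8 kg/m^2).  The blood sampling site was pruned away during model
#' development, so `site` has no effect on the output.
#'
#' @param age age, years.
#' @param wgt weight, kg.
#' @param bmi body mass index, kg/m^2.
#' @param gender `"M"` or `"F"`.
#' @param site `"A"` or `"V"`; accepted for interface uniformity, unused.
#' @return A [pk_rates] object.
#' @examples
#' published_model(age = 35, wgt = 70, bmi = 24, gender = "M")
#' @export
published_model <- function(age, wgt, bmi, gender, site = "A") {
  trees <- published_model_trees()
  spec <- attr(trees, "spec")
  th <- vapply(trees, evaluate_expression, numeric(1), age = age, wgt = wgt,
               bmi = bmi, gender = gender, site = site, spec = spec)
  new_pk_rates(th)
}

#' Write the expressions of a bank to text and LaTeX files
#'
#' @param bank a `symreg_bank`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of extracted trees.
#' @export
export_expressions <- function(bank, dir) {
  trees <- extract_expression(bank)
  spec <- attr(trees, "spec")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- vapply(names(trees), function(nm)
    sprintf("%s = %s", nm, render(trees[[nm]], "text", spec)), "")
  writeLines(txt, file.path(dir, "expressions.txt"))
  tex <- vapply(names(trees), function(nm)
    sprintf("%s &= %s \\\\", nm, render(trees[[nm]], "latex", spec)), "")
  writeLines(c("\\begin{align}", tex, "\\end{align}"),
             file.path(dir, "expressions.tex"))
  jsonlite::write_json(lapply(trees, identity),
                       file.path(dir, "expressions.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(trees)
}
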