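## Dataset container, CSV reader/writer and the command-line shell.
##
## CSV dialect (one row per event):
##   id, time_s, rate_ugps (empty on observation rows), conc_ugpl (empty on
##   dose rows), age_y, wgt_kg, bmi, gender {M,F}, site {A,V}
## Covariates are repeated on every row and must be constant within an id.

.dialect_version <- "symregpk-csv-v1"
.dialect_cols <- c("id", "time_s", "rate_ugps", "conc_ugpl", "age_y",
                   "wgt_kg", "bmi", "gender", "site")

new_dataset <- function(individuals, normalization = normalization_spec(),
                        provenance = NA_character_) {
  ids <- vapply(individuals, function(i) as.character(i$id), "")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  structure(list(individuals = individuals, normalization = normalization,
                 provenance = provenance),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$individuals, function(i) nrow(i$obs), numeric(1)))
  cat(sprintf("pk_dataset: %d individuals, %d observations\n",
              length(x$individuals), nobs))
  invisible(x)
}

#' Subset a dataset by individual index
#' @param dataset a `pk_dataset`.
#' @param idx integer indices of individuals to keep.
#' @return A `pk_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  new_dataset(dataset$individuals[idx], dataset$normalization,
              dataset$provenance)
}

#' Read a dataset from the package CSV dialect
#'
#' Parses the documented one-row-per-event CSV dialect, validates the
#' structural invariants (unique ids, covariates constant within id,
#' positive observed concentrations, at least one dose event and one
#' observation per individual) with row-numbered diagnostics, and by default
#' applies [merge_close_doses()] with the standard tolerances (1 s,
#' 0.5 ug/s).
#'
#' @param path CSV file path.
#' @param merge apply dose-event merging (default `TRUE`).
#' @param spec a [normalization_spec] attached to the dataset.
#' @return A `pk_dataset`.
#' @export
read_dataset <- function(path, merge = TRUE, spec = normalization_spec()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.dialect_cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rown <- seq_len(nrow(df))
  is_dose <- !is.na(df$rate_ugps)
  is_obs <- !is.na(df$conc_ugpl)
  bad <- which(is_dose == is_obs)
  if (length(bad))
    stop("row ", bad[1], ": exactly one of rate_ugps/conc_ugpl must be set")
  badc <- which(is_obs & df$conc_ugpl <= 0)
  if (length(badc))
    stop("row ", badc[1], ": observed concentration must be > 0")
  badl <- which(!df$gender %in% c("M", "F") | !df$site %in% c("A", "V"))
  if (length(badl))
    stop("row ", badl[1], ": unknown gender/site label")

  inds <- lapply(split(rown, df$id), function(rr) {
    d <- df[rr, ]
    for (cv in c("age_y", "wgt_kg", "bmi", "gender", "site")) {
      if (length(unique(d[[cv]])) != 1L)
        stop("row ", rr[which(d[[cv]] != d[[cv]][1])[1]],
             ": covariate ", cv, " not constant within id ", d$id[1])
    }
    dr <- d[!is.na(d$rate_ugps), ]
    ob <- d[!is.na(d$conc_ugpl), ]
    if (nrow(dr) == 0L) stop("individual ", d$id[1], " has no dose events")
    if (nrow(ob) == 0L) stop("individual ", d$id[1], " has no observations")
    dosing <- dosing_profile(dr$time_s[order(dr$time_s)],
                             dr$rate_ugps[order(dr$time_s)])
    if (merge) dosing <- merge_close_doses(dosing)
    oo <- order(ob$time_s)
    list(id = d$id[1], age = d$age_y[1], wgt = d$wgt_kg[1], bmi = d$bmi[1],
         gender = d$gender[1], site = d$site[1], dosing = dosing,
         obs = data.frame(time = ob$time_s[oo], conc = ob$conc_ugpl[oo]))
  })
  inds <- inds[order(names(inds))]
  names(inds) <- NULL
  new_dataset(inds, spec, provenance = normalizePath(path))
}

#' Write a dataset in the package CSV dialect
#'
#' Deterministic column order and full-precision number formatting; a header
#' comment carries the dialect version.  The output contains no timestamps,
#' so a fixed dataset always produces identical bytes.
#'
#' @param dataset a `pk_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  rows <- lapply(dataset$individuals, function(ind) {
    base <- sprintf("%s,%%s,%%s,%%s,%s,%s,%s,%s,%s", ind$id,
                    fmt(ind$age), fmt(ind$wgt), fmt(ind$bmi),
                    ind$gender, ind$site)
    c(sprintf(base, fmt(ind$dosing$times), fmt(ind$dosing$rates), ""),
      sprintf(base, fmt(ind$obs$time), "", fmt(ind$obs$conc)))
  })
  lines <- c(sprintf("# %s", .dialect_version),
             paste(.dialect_cols, collapse = ","),
             unlist(rows))
  writeLines(lines, path)
  invisible(path)
}

## ---- model evaluation ----------------------------------------------------

# resolve a "model" (bank, function, constant pk_rates, per-individual list)
# to per-individual PK parameters
model_theta <- function(model, ind, spec) {
  if (inherits(model, "symreg_bank")) {
    phi <- normalize_covariates(ind$age, ind$wgt, ind$bmi, ind$gender,
                                ind$site, model$spec, warn = FALSE)
    return(bank_forward(model, phi))
  }
  if (inherits(model, "pk_rates")) return(model)
  if (is.function(model))
    return(model(ind$age, ind$wgt, ind$bmi, ind$gender, ind$site))
  if (is.list(model) && !is.null(model[[as.character(ind$id)]]))
    return(model[[as.character(ind$id)]])
  stop("cannot resolve model for individual ", ind$id)
}

#' Evaluate a model's predictive performance on a dataset
#'
#' Simulates each individual under the model's PK parameters and reports the
#' per-individual median errors plus the four population summary metrics
#' (means over individuals of MdALE, MdLE, MdAPE, MdPE).
#'
#' @param model a `symreg_bank`, a covariate-model function, a single
#'   [pk_rates] (constant model), or a named per-individual list of
#'   [pk_rates].
#' @param dataset a `pk_dataset`.
#' @return List with `per_individual` (data frame) and `population` (named
#'   vector `mean_mdale`, `mean_mdle`, `mean_mdape`, `mean_mdpe`, plus
#'   `j_ale` as an alias of `mean_mdale`).
#' @export
evaluate_model <- function(model, dataset) {
  rows <- lapply(dataset$individuals, function(ind) {
    th <- model_theta(model, ind, dataset$normalization)
    cpred <- pk_simulate(do.call(pk_rates, as.list(pmax(as.numeric(th),
                                                        1e-10))),
                         ind$dosing, ind$obs$time)
    e <- individual_medians(ind$obs$conc, pmax(cpred, 1e-12), id = ind$id)
    data.frame(id = ind$id, md_ale = e$md_ale, md_le = e$md_le,
               md_ape = e$md_ape, md_pe = e$md_pe, n_obs = e$n_obs)
  })
  per <- do.call(rbind, rows)
  pop <- c(mean_mdale = mean(per$md_ale), mean_mdle = mean(per$md_le),
           mean_mdape = mean(per$md_ape), mean_mdpe = mean(per$md_pe))
  list(per_individual = per,
       population = c(pop, j_ale = unname(pop["mean_mdale"])))
}

## ---- command-line interface ----------------------------------------------

cli_usage <- function() {
  cat("usage: symregpk <command> [options]\n",
      "commands:\n",
      "  generate  --out FILE [--config FILE.yaml] [--seed N] [--n N]\n",
      "  fit       --data FILE --out-dir DIR [--config FILE.yaml]",
      " [--seed N] [--restarts N]\n",
      "  evaluate  --data FILE (--bank FILE | --published)\n",
      "  baselines --data FILE [--seed N] [--out FILE]\n",
      "  export    --bank FILE --out-dir DIR\n",
      "  simulate  --params k10,k12,k13,k21,k31,V1 --times t1,t2,..",
      " --rates r1,r2,.. --obs t1,t2,..\n", sep = "")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key %in% c("published", "no-merge")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for --", key)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_config <- function(opts) {
  if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
}

cfg_from_list <- function(lst, what) {
  fields <- names(formals(what))
  do.call(what, lst[intersect(names(lst), fields)])
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic dataset files), `fit` (multi-restart
#' recipe; writes bank JSON, expressions and a run manifest), `evaluate`
#' (population error table), `baselines` (constant and per-individual
#' covariate-free fits), `export` (text/LaTeX expressions from a bank file),
#' `simulate` (concentration series for given parameters and dosing).
#' Options may come from a YAML config file (`--config`) with command-line
#' flags taking precedence.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments, so an `Rscript` wrapper can call `run_cli()`).
#' @return Invisibly, the subcommand's result object.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cli_usage()
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- cli_opts(args[-1])
  conf <- cli_config(opts)
  seed <- as.integer(opts$seed %||% conf$seed %||% 1)

  res <- switch(cmd,
    generate = {
      lst <- conf
      if (!is.null(opts$n)) lst$n_individuals <- as.integer(opts$n)
      lst$seed <- seed
      cfg <- cfg_from_list(lst, cohort_config)
      ds <- generate_dataset(cfg = cfg)
      write_dataset(ds, opts$out %||% stop("--out required"))
      manifest <- list(command = "generate", seed = seed,
                       config = unclass(cfg),
                       dialect = .dialect_version)
      jsonlite::write_json(manifest, paste0(opts$out, ".manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      ds
    },
    fit = {
      ds <- read_dataset(opts$data %||% stop("--data required"),
                         merge = is.null(opts$`no-merge`))
      cfg <- cfg_from_list(conf, train_config)
      sched <- cfg_from_list(conf, prune_schedule)
      n_restarts <- as.integer(opts$restarts %||% conf$n_restarts %||% 8)
      fit <- multi_restart(ds, sched, cfg, n_restarts = n_restarts,
                           base_seed = seed)
      out_dir <- opts$`out-dir` %||% stop("--out-dir required")
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      bank_to_json(fit$bank, file.path(out_dir, "bank.json"))
      export_expressions(fit$bank, out_dir)
      manifest <- list(command = "fit", seed = seed,
                       n_restarts = n_restarts,
                       config = unclass(cfg), schedule = unclass(sched),
                       final_loss = fit$final_loss,
                       restart_losses = fit$restart_losses,
                       loss_history = fit$loss_history,
                       dialect = .dialect_version)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    evaluate = {
      ds <- read_dataset(opts$data %||% stop("--data required"),
                         merge = is.null(opts$`no-merge`))
      model <- if (isTRUE(opts$published)) {
        function(age, wgt, bmi, gender, site)
          published_model(age, wgt, bmi, gender, site)
      } else bank_from_json(opts$bank %||% stop("--bank or --published required"))
      ev <- evaluate_model(model, ds)
      print(round(ev$population, 4))
      ev
    },
    baselines = {
      ds <- read_dataset(opts$data %||% stop("--data required"),
                         merge = is.null(opts$`no-merge`))
      cm <- fit_constant_model(ds, seed = seed)
      im <- fit_individual_models(ds, seed = seed, warm_start = cm)
      cat(sprintf("constant model J_ALE = %.4g\n", cm$loss))
      cat(sprintf("individual models J_ALE = %.4g\n", im$loss))
      if (!is.null(opts$out)) {
        jsonlite::write_json(
          list(constant = list(loss = cm$loss,
                               parameters = as.list(unclass(cm$parameters))),
               individual = list(loss = im$loss)),
          opts$out, auto_unbox = TRUE, digits = NA)
      }
      list(constant = cm, individual = im)
    },
    export = {
      bank <- bank_from_json(opts$bank %||% stop("--bank required"))
      export_expressions(bank, opts$`out-dir` %||% stop("--out-dir required"))
    },
    simulate = {
      p <- do.call(pk_rates,
                   as.list(as.numeric(strsplit(opts$params, ",")[[1]])))
      d <- dosing_profile(as.numeric(strsplit(opts$times, ",")[[1]]),
                          as.numeric(strsplit(opts$rates, ",")[[1]]))
      tt <- as.numeric(strsplit(opts$obs, ",")[[1]])
      conc <- pk_simulate(p, d, tt)
      cat(paste(sprintf("%g,%g", tt, conc), collapse = "\n"), "\n")
      data.frame(time = tt, conc = conc)
    },
    {
      cli_usage()
      stop("unknown command: ", cmd)
    })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
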