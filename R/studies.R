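#' Truth presets for the simulation studies
#'
#' `study_truth("recovery")` is the two-regime parameter-recovery scenario
#' (Ancestral OU(alpha 2, theta 2, sigma 1), R1 OU(5, 0, 0.5), `X0 = 0`).
#' `"M1"`, `"M2"`, `"M3"` are the increasing-complexity model-evaluation
#' scenarios (one, two and four OU regimes).
#'
#' @param name preset name.
#' @return List with `regimes`, per-regime `params`, and `X0`.
#' @export
study_truth <- function(name = c("recovery", "M1", "M2", "M3")) {
  name <- match.arg(name)
  ou <- function(a, t, s) c(alpha = a, theta = t, sigma = s)
  switch(name,
    recovery = list(X0 = 0, regimes = list(Ancestral = ou(2, 2, 1),
                                           R1 = ou(5, 0, 0.5))),
    M1 = list(X0 = 0, regimes = list(Ancestral = ou(2, 2, 1))),
    M2 = list(X0 = 0, regimes = list(Ancestral = ou(2, 2, 2),
                                     R1 = ou(1, -2, 1))),
    M3 = list(X0 = 0, regimes = list(Ancestral = ou(3, 2, 2),
                                     R1 = ou(2, 1, 1),
                                     R2 = ou(2, -1, 1),
                                     R3 = ou(3, -2, 2))))
}

truth_vector <- function(truth) {
  out <- c(X0 = truth$X0)
  for (r in names(truth$regimes)) {
    v <- truth$regimes[[r]]
    out <- c(out, stats::setNames(v, paste0(names(v), "_", r)))
  }
  out
}

#' Prior configurations for the prior-sensitivity study
#'
#' Three progressively more informative prior configurations for the
#' two-regime recovery scenario: configuration 1 is the diffuse default,
#' 2 centers the optima near their true values with moderate spread, and 3
#' tightens most scales further.
#'
#' @param which configuration index (1, 2 or 3).
#' @return Named list of `mgpm_prior` objects keyed by parameter name.
#' @export
sensitivity_priors <- function(which = 1) {
  hn <- prior_halfnormal; no <- prior_normal
  switch(as.character(which),
    "1" = list(X0 = no(0, 10),
               alpha_Ancestral = hn(10), theta_Ancestral = no(0, 10),
               sigma_Ancestral = hn(10),
               alpha_R1 = hn(10), theta_R1 = no(0, 10), sigma_R1 = hn(10)),
    "2" = list(X0 = no(0, 5),
               alpha_Ancestral = hn(5), theta_Ancestral = no(2, 5),
               sigma_Ancestral = hn(5),
               alpha_R1 = hn(5), theta_R1 = no(0, 5), sigma_R1 = hn(5)),
    "3" = list(X0 = no(0, 2),
               alpha_Ancestral = hn(1), theta_Ancestral = no(2, 2),
               sigma_Ancestral = hn(1),
               alpha_R1 = hn(5), theta_R1 = no(0, 2), sigma_R1 = hn(1)),
    stop("unknown prior configuration"))
}

#' Informative model-evaluation priors
#'
#' Per-model informative prior lists for the model-evaluation scenarios
#' `M1`, `M2`, `M3` (used by the prior-sensitivity rerun of the model
#' evaluation study): Normal(sd 2) priors centered at the regime optima and
#' Half-Normal scales 1-3 on the positive parameters.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`.
#' @return Named list of priors keyed by parameter name.
#' @export
model_eval_priors <- function(model = c("M1", "M2", "M3")) {
  model <- match.arg(model)
  hn <- prior_halfnormal; no <- prior_normal
  reg <- function(r, a, t, s) {
    stats::setNames(list(hn(a), no(t, 2), hn(s)),
                    paste0(c("alpha_", "theta_", "sigma_"), r))
  }
  switch(model,
    M1 = c(list(X0 = no(0, 2)), reg("Ancestral", 2, 2, 1)),
    M2 = c(list(X0 = no(0, 2)), reg("Ancestral", 2, 2, 2), reg("R1", 1, -2, 1)),
    M3 = c(list(X0 = no(0, 2)), reg("Ancestral", 3, 2, 2), reg("R1", 2, 1, 1),
           reg("R2", 2, -1, 1), reg("R3", 3, -2, 2)))
}

#' Configure a simulation study
#'
#' Bundles everything a seeded study run needs: the study kind, the fixture
#' tree (or a user-supplied tree for full-fidelity reruns), replicate count,
#' PMC sample size, and the master seed from which all per-replicate seeds
#' are derived.
#'
#' @param study `"param-recovery"`, `"model-eval"`, or
#'   `"prior-sensitivity"`.
#' @param R replicates per scenario.
#' @param S PMC posterior sample size per fit.
#' @param n_tips fixture tree size (ignored when `tree` is given).
#' @param seed master seed.
#' @param tree optional `phylo` (e.g. an empirical chronogram) replacing the
#'   seeded Yule fixture.
#' @param paintings optional named list of `mgpm_painting`s replacing the
#'   seeded clade picks (names: `recovery`, `M1`, `M2`, `M3` as relevant).
#' @param ml_starts restarts for the maximum-likelihood comparator.
#' @param S_p predictive replicates per fit (model evaluation study).
#' @return An object of class `mgpm_study_config`.
#' @export
study_config <- function(study = c("param-recovery", "model-eval",
                                   "prior-sensitivity"),
                         R = 20, S = 2000, n_tips = 50, seed = 1,
                         tree = NULL, paintings = NULL, ml_starts = 10,
                         S_p = S) {
  study <- match.arg(study)
  structure(list(study = study, R = R, S = S, n_tips = n_tips, seed = seed,
                 tree = tree, paintings = paintings, ml_starts = ml_starts,
                 S_p = S_p),
            class = "mgpm_study_config")
}

study_tree <- function(cfg) {
  if (!is.null(cfg$tree)) cfg$tree
  else random_ultrametric_tree(cfg$n_tips, seed = cfg$seed)
}

study_paintings <- function(cfg, tree) {
  if (!is.null(cfg$paintings)) return(cfg$paintings)
  cl3 <- disjoint_clades(tree, 3, seed = cfg$seed)
  list(
    recovery = paint_regimes(tree, clades = cl3["R1"], default = "Ancestral"),
    M1 = paint_regimes(tree, default = "Ancestral"),
    M2 = paint_regimes(tree, clades = cl3["R1"], default = "Ancestral"),
    M3 = paint_regimes(tree, clades = cl3, default = "Ancestral"))
}

# K disjoint clades named R1..RK, reusing the seeded picker
disjoint_clades <- function(tree, K, seed) {
  p <- random_painting(tree, K + 1L, seed = seed)
  lapply(stats::setNames(paste0("R", seq_len(K)), paste0("R", seq_len(K))),
         function(r) {
           kids <- which(as.character(p) == r)
           # crown node: the painted node none of whose painted siblings is
           # its ancestor; with clade painting this is the shallowest one
           kids[which.min(node_depths(tree)[kids])]
         })
}

replicate_seeds <- function(master, n, salt = 0L) {
  local_seed(master + salt, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the parameter-recovery simulation study
#'
#' For each replicate: simulate tip data from the two-regime OU truth, run
#' the PMC posterior fit and the multi-start maximum-likelihood comparator,
#' and record posterior medians, 95% credible bounds, coverage indicators
#' and ML estimates.
#'
#' @param cfg an [study_config()] (study `"param-recovery"`).
#' @param priors prior configuration: a preset name or a named prior list
#'   (see [sensitivity_priors()]).
#' @param verbose print per-replicate progress.
#' @return A data frame, one row per replicate x parameter, with columns
#'   `replicate`, `parameter`, `truth`, `median`, `lo`, `hi`, `covered`,
#'   `width`, `ml`.
#' @export
run_param_recovery <- function(cfg, priors = "diffuse", verbose = FALSE) {
  tree <- study_tree(cfg)
  painting <- study_paintings(cfg, tree)$recovery
  truth <- study_truth("recovery")
  tv <- truth_vector(truth)
  model <- mgpm(tree, painting, kinds = "OU", priors = priors)
  seeds <- replicate_seeds(cfg$seed, 3L * cfg$R, salt = 11L)
  out <- vector("list", cfg$R)
  for (r in seq_len(cfg$R)) {
    x <- simulate_tips(model, tv, nsim = 1, seed = seeds[3 * r - 2])[1, ]
    fit <- mgpm_fit(model, x, nsample = cfg$S, seed = seeds[3 * r - 1])
    ml <- mgpm_ml(model, x, n_starts = cfg$ml_starts, seed = seeds[3 * r])
    ci <- credible_interval(fit, level = 0.95)
    med <- coef(fit, type = "median")
    nm <- names(med)
    out[[r]] <- data.frame(replicate = r, parameter = nm,
                           truth = unname(tv[nm]), median = unname(med),
                           lo = ci[nm, "lo"], hi = ci[nm, "hi"],
                           covered = tv[nm] >= ci[nm, "lo"] & tv[nm] <= ci[nm, "hi"],
                           width = ci[nm, "hi"] - ci[nm, "lo"],
                           ml = unname(ml$par[nm]), ess = fit$ess,
                           stringsAsFactors = FALSE)
    if (verbose) message("replicate ", r, "/", cfg$R, " done (ESS ",
                         round(fit$ess), ")")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the model-evaluation simulation study
#'
#' The 3 x 3 design: data are simulated from each of `M1`, `M2`, `M3`
#' (one, two and four OU regimes) and every dataset is fitted under all
#' three model configurations; each fit is scored by the posterior
#' predictive loss at `lambda` of 1, `ln(p)` and `p`.
#'
#' @param cfg an [study_config()].
#' @param priors `"moderate"` (default), another preset name, or
#'   `"informative"` to use the per-model [model_eval_priors()].
#' @param verbose print progress.
#' @return A data frame with columns `data_model`, `fit_model`, `replicate`,
#'   `p`, `sse`, `var_term`, `ppl_1`, `ppl_lnp`, `ppl_p`.
#' @export
run_model_eval <- function(cfg, priors = "moderate", verbose = FALSE) {
  tree <- study_tree(cfg)
  pts <- study_paintings(cfg, tree)
  names_m <- c("M1", "M2", "M3")
  models <- lapply(names_m, function(m) {
    pr <- if (identical(priors, "informative")) model_eval_priors(m) else priors
    mgpm(tree, pts[[m]], kinds = "OU", priors = pr)
  })
  names(models) <- names_m
  out <- list()
  for (dm in names_m) {
    truth <- truth_vector(study_truth(dm))
    seeds <- replicate_seeds(cfg$seed, cfg$R * 7L, salt = match(dm, names_m))
    for (r in seq_len(cfg$R)) {
      base <- (r - 1L) * 7L
      x <- simulate_tips(models[[dm]], truth, nsim = 1,
                         seed = seeds[base + 1])[1, ]
      for (fm in names_m) {
        j <- match(fm, names_m)
        fit <- mgpm_fit(models[[fm]], x, nsample = cfg$S,
                        seed = seeds[base + 1 + j])
        pd <- posterior_predictive_draws(fit, S_p = cfg$S_p,
                                         seed = seeds[base + 4 + j])
        sc <- ppl(pd, x, 1)
        p <- n_params(models[[fm]])
        out[[length(out) + 1L]] <- data.frame(
          data_model = dm, fit_model = fm, replicate = r, p = p,
          sse = sc$sse, var_term = sc$var_term, ppl_1 = sc$total,
          ppl_lnp = sc$sse + log(p) * sc$var_term,
          ppl_p = sc$sse + p * sc$var_term, stringsAsFactors = FALSE)
      }
      if (verbose) message(dm, " replicate ", r, "/", cfg$R, " done")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the prior-sensitivity study
#'
#' Reruns the parameter-recovery study under the three prior configurations
#' of [sensitivity_priors()] and summarizes, per parameter and
#' configuration, the dispersion (variance of posterior medians across
#' replicates) and bias of the medians.
#'
#' @param cfg an [study_config()].
#' @param verbose print progress.
#' @return A list with `raw` (the stacked per-replicate table, with a
#'   `prior` column) and `summary` (per prior x parameter: median variance,
#'   bias, coverage).
#' @export
run_prior_sensitivity <- function(cfg, verbose = FALSE) {
  raw <- do.call(rbind, lapply(1:3, function(k) {
    res <- run_param_recovery(cfg, priors = sensitivity_priors(k),
                              verbose = verbose)
    res$prior <- k
    res
  }))
  agg <- do.call(rbind, lapply(split(raw, raw[c("prior", "parameter")]),
    function(d) data.frame(prior = d$prior[1], parameter = d$parameter[1],
                           median_var = stats::var(d$median),
                           bias = mean(d$median - d$truth),
                           coverage = mean(d$covered))))
  rownames(agg) <- NULL
  list(raw = raw, summary = agg)
}
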