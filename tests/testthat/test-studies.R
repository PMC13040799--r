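test_that("study truth presets carry the published scenario parameters", {
  rec <- study_truth("recovery")
  expect_equal(mgpm:::truth_vector(rec),
               c(X0 = 0, alpha_Ancestral = 2, theta_Ancestral = 2,
                 sigma_Ancestral = 1, alpha_R1 = 5, theta_R1 = 0,
                 sigma_R1 = 0.5))
  m2 <- study_truth("M2")
  expect_equal(m2$regimes$Ancestral, c(alpha = 2, theta = 2, sigma = 2))
  expect_equal(m2$regimes$R1, c(alpha = 1, theta = -2, sigma = 1))
  m3 <- study_truth("M3")
  expect_equal(length(m3$regimes), 4)
  expect_equal(m3$regimes$R3, c(alpha = 3, theta = -2, sigma = 2))
})

test_that("sensitivity prior configurations are as specified", {
  p3 <- sensitivity_priors(3)
  expect_equal(p3$alpha_Ancestral$scale, 1)
  expect_equal(p3$theta_Ancestral, prior_normal(2, 2))
  expect_equal(p3$alpha_R1$scale, 5)
  expect_equal(p3$X0$sd, 2)
  p2 <- sensitivity_priors(2)
  expect_true(all(vapply(p2[c("alpha_Ancestral", "sigma_Ancestral",
                              "alpha_R1", "sigma_R1")],
                         function(p) p$scale == 5, logical(1))))
  me <- model_eval_priors("M3")
  expect_equal(me$alpha_Ancestral$scale, 3)
  expect_equal(me$theta_R2, prior_normal(-1, 2))
  expect_equal(me$sigma_R3$scale, 2)
})

test_that("model configurations round-trip through JSON serialization", {
  tr <- random_ultrametric_tree(12, seed = 3)
  p <- random_painting(tr, 2, seed = 3)
  m <- mgpm(tr, p, kinds = c(Ancestral = "OU", R1 = "BM"),
            priors = sensitivity_priors(2)[c("X0", "alpha_Ancestral",
                                             "theta_Ancestral",
                                             "sigma_Ancestral", "sigma_R1")],
            fixed = c(sigma_R1 = 0.5))
  tmp <- tempfile(fileext = ".json")
  write_model_config(m, tmp, params = c(X0 = 0, alpha_Ancestral = 2,
                                        theta_Ancestral = 2,
                                        sigma_Ancestral = 1, sigma_R1 = 0.5))
  m2 <- read_model_config(tmp, tr)
  expect_equal(as.character(m2$painting), as.character(m$painting))
  expect_equal(m2$regimes, m$regimes)
  expect_equal(m2$kinds, m$kinds)
  expect_equal(m2$fixed, m$fixed)
  expect_equal(m2$priors, m$priors)
  expect_equal(m2$params[["alpha_Ancestral"]], 2)
})

test_that("study runs are reproducible from the master seed", {
  cfg <- study_config("param-recovery", R = 2, S = 250, n_tips = 15,
                      seed = 9, ml_starts = 2)
  r1 <- suppressWarnings(run_param_recovery(cfg))
  r2 <- suppressWarnings(run_param_recovery(cfg))
  expect_identical(r1, r2)
  expect_setequal(unique(r1$parameter),
                  names(mgpm:::truth_vector(study_truth("recovery"))))
  expect_true(all(r1$lo <= r1$median & r1$median <= r1$hi))
  expect_true(all(r1$width > 0))
})

test_that("the model-evaluation grid scores every data/fit pair", {
  cfg <- study_config("model-eval", R = 1, S = 200, n_tips = 15, seed = 5,
                      S_p = 200)
  res <- suppressWarnings(run_model_eval(cfg))
  expect_equal(nrow(res), 9)
  expect_setequal(unique(res$data_model), c("M1", "M2", "M3"))
  expect_setequal(unique(res$fit_model), c("M1", "M2", "M3"))
  expect_equal(res$ppl_1, res$sse + res$var_term, tolerance = 1e-12)
  expect_equal(res$ppl_lnp, res$sse + log(res$p) * res$var_term,
               tolerance = 1e-12)
  expect_equal(res$p[res$fit_model == "M3"], rep(13, 3))
  res2 <- suppressWarnings(run_model_eval(cfg))
  expect_identical(res, res2)
})

test_that("tighter priors shrink the spread of posterior medians", {
  cfg <- study_config("prior-sensitivity", R = 2, S = 200, n_tips = 15,
                      seed = 7, ml_starts = 2)
  ps <- suppressWarnings(run_prior_sensitivity(cfg))
  expect_setequal(unique(ps$raw$prior), 1:3)
  expect_equal(nrow(ps$summary), 21) # 3 priors x 7 parameters
  expect_true(all(is.finite(ps$summary$median_var)))
  # the most informative configuration is at least as concentrated as the
  # diffuse one for a majority of parameters
  v1 <- ps$summary$median_var[ps$summary$prior == 1]
  v3 <- ps$summary$median_var[ps$summary$prior == 3]
  expect_gte(mean(v3 <= v1), 0.5)
})
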