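test_that("forward simulation collapses to X0 as the diffusion vanishes", {
  tr <- random_ultrametric_tree(6, seed = 1)
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  x <- simulate_tips(m, c(X0 = 1.7, sigma_Ancestral = 1e-8), nsim = 3,
                     seed = 2)
  expect_equal(unname(as.vector(x)), rep(1.7, 18), tolerance = 1e-6)
})

test_that("simulated tip moments match the analytic tip distribution", {
  inst <- random_instance(5, 2, seed = 55)
  td <- tip_distribution(inst$model, inst$theta)
  nsim <- 10000
  x <- simulate_tips(inst$model, inst$theta, nsim = nsim, seed = 3)
  x <- x[, names(td$mean)]
  se_mean <- sqrt(diag(td$cov) / nsim)
  expect_true(all(abs(colMeans(x) - td$mean) < 4 * se_mean))
  emp_cov <- stats::cov(x)
  # covariance entries: SE ~ sqrt((s_ii s_jj + s_ij^2) / n)
  se_cov <- sqrt((outer(diag(td$cov), diag(td$cov)) + td$cov^2) / nsim)
  expect_true(all(abs(emp_cov - td$cov) < 5 * se_cov))
})

test_that("strong selection drives tip means to the terminal optimum", {
  tr <- read_newick("(A:1,B:1);")
  m <- mgpm(tr, kinds = "OU", priors = "diffuse")
  x <- simulate_tips(m, c(X0 = -5, alpha_Ancestral = 60,
                          theta_Ancestral = 2.5, sigma_Ancestral = 0.3),
                     nsim = 4000, seed = 4)
  expect_equal(unname(colMeans(x)), c(2.5, 2.5), tolerance = 0.05)
})

test_that("a one-atom posterior predicts from the model at that parameter", {
  tr <- random_ultrametric_tree(8, seed = 5)
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  th <- c(X0 = 0.5, sigma_Ancestral = 1.1)
  fit <- structure(list(model = m, draws = rbind(th), weights = 1, S = 1),
                   class = "mgpm_fit")
  pd <- posterior_predictive_draws(fit, S_p = 4000, seed = 6)
  td <- tip_distribution(m, th)
  expect_true(all(abs(pd$m - td$mean) < 4 * sqrt(diag(td$cov) / 4000)))
  # bookkeeping identities: stored statistics recompute from the replicates
  expect_identical(pd$m, colMeans(pd$replicates))
  expect_identical(pd$s2, apply(pd$replicates, 2, stats::var))
})

test_that("the loss decomposes into SSE plus lambda times the variance term", {
  reps <- rbind(c(1, 2), c(3, 4))
  sc <- ppl(reps, c(1, 2))
  expect_equal(sc$sse, 2)
  expect_equal(sc$var_term, 4)
  expect_equal(sc$total, 6)
  sc4 <- ppl(reps, c(1, 2), lambda = log(4))
  expect_equal(sc4$total, 2 + log(4) * 4, tolerance = 1e-12)

  exact <- rbind(c(1, 2), c(1, 2))
  expect_equal(ppl(exact, c(1, 2))$total, 0)
})

test_that("the loss is invariant to replicate order and tip labelling order", {
  set.seed(7)
  reps <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  x <- stats::setNames(rnorm(4), letters[1:4])
  s1 <- ppl(reps, x)
  s2 <- ppl(reps[sample(10), ], x)
  s3 <- ppl(reps, x[c("d", "b", "a", "c")])
  expect_equal(s1$total, s2$total, tolerance = 1e-12)
  expect_equal(s1$total, s3$total, tolerance = 1e-12)
  expect_error(ppl(reps, stats::setNames(rnorm(4), c("a", "b", "c", "z"))),
               "labels")
})

test_that("predictive density curves are exact normal mixtures that integrate to one", {
  tr <- read_newick("(A:2);")
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  th <- c(X0 = 1, sigma_Ancestral = 0.8)
  fit <- structure(list(model = m, draws = rbind(th), weights = 1, S = 1),
                   class = "mgpm_fit")
  grid <- seq(-5, 7, length.out = 601)
  pd <- predictive_density_at_tips(fit, grid, S = 50, seed = 8)
  expect_equal(pd$density["A", ],
               stats::dnorm(grid, 1, 0.8 * sqrt(2)), tolerance = 1e-10)
  h <- grid[2] - grid[1]
  expect_equal(sum(pd$density["A", ]) * h, 1, tolerance = 1e-3)
})

test_that("density-curve means agree with predictive-replicate means", {
  cj <- conjugate_fixture(n_tips = 10, seed = 9)
  fit <- mgpm_fit(cj$model, cj$x, nsample = 1000, seed = 10)
  grid <- seq(-8, 10, length.out = 901)
  pd <- predictive_density_at_tips(fit, grid, S = 500, seed = 11)
  h <- grid[2] - grid[1]
  mass <- rowSums(pd$density) * h
  expect_true(all(abs(mass - 1) < 1e-3))
  mix_mean <- as.vector(pd$density %*% grid) * h
  draws <- posterior_predictive_draws(fit, S_p = 4000, seed = 12)
  se <- sqrt(draws$s2 / 4000) + 0.02
  expect_true(all(abs(mix_mean - draws$m) < 4 * se))
})

test_that("model comparison scores duplicates identically and matches the base loss", {
  cj <- conjugate_fixture(n_tips = 10, seed = 13)
  fit <- mgpm_fit(cj$model, cj$x, nsample = 500, seed = 14)
  tab <- model_comparison(cj$x, list(a = fit, b = fit), S_p = 500, seed = 15)
  expect_equal(tab$ppl_1[tab$model == "a"], tab$ppl_1[tab$model == "b"])
  pd <- posterior_predictive_draws(fit, S_p = 500, seed = 15)
  expect_equal(tab$ppl_1[tab$model == "a"], ppl(pd, cj$x, 1)$total,
               tolerance = 1e-12)
  expect_equal(tab$ppl_p, tab$sse + tab$p * tab$var_term, tolerance = 1e-12)
})

test_that("posterior-predictive residuals align with the observed tips", {
  cj <- conjugate_fixture(n_tips = 8, seed = 16)
  fit <- mgpm_fit(cj$model, cj$x, nsample = 400, seed = 17)
  r <- residuals(fit, S_p = 500, seed = 18)
  expect_equal(names(r), cj$model$plan$tip_labels)
  pd <- posterior_predictive_draws(fit, S_p = 500, seed = 18)
  expect_equal(unname(r), unname(cj$x[names(r)] - pd$m), tolerance = 1e-12)
})
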