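gauss_target <- function(mu, Sigma) {
  Si <- solve(Sigma)
  function(z) -0.5 * drop(t(z - mu) %*% Si %*% (z - mu))
}

test_that("the Laplace approximation is exact on Gaussian targets", {
  mu <- c(1, -2)
  Sigma <- matrix(c(2, 0.7, 0.7, 1), 2)
  la <- laplace_approximation(gauss_target(mu, Sigma),
                              function(n) matrix(rnorm(2 * n, sd = 3), n, 2),
                              n_starts = 4, seed = 1)
  expect_equal(unname(la$mode), mu, tolerance = 1e-5)
  expect_equal(unname(la$cov), Sigma, tolerance = 1e-4)
  expect_false(la$spd_repaired)
  la2 <- laplace_approximation(gauss_target(mu, Sigma),
                               function(n) matrix(rnorm(2 * n, sd = 3), n, 2),
                               n_starts = 4, seed = 1)
  expect_identical(la$mode, la2$mode)
  expect_identical(la$cov, la2$cov)
})

test_that("the Laplace stage matches the conjugate closed-form posterior", {
  cj <- conjugate_fixture(n_tips = 20, seed = 4)
  lp <- mgpm:::make_logpost(cj$model, cj$x)
  la <- laplace_approximation(lp, function(n)
    mgpm:::sample_prior_z(cj$model, n), n_starts = 3, seed = 2)
  expect_equal(unname(la$mode), cj$post_mean, tolerance = 1e-4)
  expect_equal(sqrt(la$cov[1, 1]), cj$post_sd, tolerance = 1e-3)
})

test_that("importance weights are uniform when the target equals the proposal", {
  q <- list(mode = c(0, 0), cov = diag(2))
  s <- importance_stage(gauss_target(c(0, 0), diag(2)), q, S = 500, seed = 3)
  expect_equal(s$weights, rep(1 / 500, 500), tolerance = 1e-12)
  expect_equal(s$ess, 500, tolerance = 1e-9)
})

test_that("a far-off target degenerates the importance stage with a warning", {
  q <- list(mode = c(0, 0), cov = diag(2) * 0.01)
  expect_warning(
    s <- importance_stage(gauss_target(c(50, 50), diag(2) * 0.01), q,
                          S = 200, seed = 4),
    "degenera")
  expect_lt(s$ess, 2)
})

test_that("importance estimates hit known moments within Monte Carlo error", {
  q <- list(mode = 0.5, cov = matrix(4))
  s <- importance_stage(function(z) -0.5 * (z - 2)^2 / 0.49, q,
                        S = 10000, seed = 5)
  m <- sum(s$draws[, 1] * s$weights)
  se <- mgpm:::weighted_mcse(s$draws[, 1], s$weights)
  expect_lt(abs(m - 2), 3 * se)
})

test_that("multinomial resampling is categorical, seeded, and validated", {
  expect_equal(multinomial_resample(c(1, 0, 0), 50, seed = 1), rep(1L, 50))
  i1 <- multinomial_resample(rep(0.25, 4), 100, seed = 9)
  expect_identical(i1, multinomial_resample(rep(0.25, 4), 100, seed = 9))
  expect_error(multinomial_resample(c(0.5, 0.2), 10), "simplex")
  idx <- multinomial_resample(rep(0.2, 5), 1e5, seed = 2)
  chi <- stats::chisq.test(tabulate(idx, 5))
  expect_gt(chi$p.value, 0.001)
})

test_that("the shrink rule reproduces the (1/S) diag(var) kernel covariance", {
  set.seed(6)
  res <- matrix(rnorm(400 * 3, sd = c(1, 2, 3)), 400, 3, byrow = TRUE)
  s <- rejuvenate_and_reweight(function(z) -0.5 * sum(z^2 / c(1, 4, 9)),
                               res, seed = 7, kernel_scale = "shrink")
  expect_equal(s$kernel_sd, sqrt(apply(res, 2, var) / 400), tolerance = 1e-12)
})

test_that("rejuvenation floors degenerate spreads and recovers Gaussian moments", {
  res <- matrix(1.5, 100, 2) # all identical points
  expect_warning(
    s <- rejuvenate_and_reweight(function(z) -0.5 * sum(z^2), res, seed = 8),
    "variance")
  expect_true(all(is.finite(s$weights)))

  # end-to-end on a Gaussian target: importance + resample + rejuvenate
  target <- gauss_target(c(1, -1), diag(c(0.5, 2)))
  q <- list(mode = c(0.8, -0.7), cov = diag(c(1, 3)))
  s1 <- importance_stage(target, q, 4000, seed = 9)
  idx <- multinomial_resample(s1$weights, 4000, seed = 10)
  s2 <- rejuvenate_and_reweight(target, s1$draws[idx, ], seed = 11)
  m <- colSums(s2$draws * s2$weights)
  for (j in 1:2) {
    se <- mgpm:::weighted_mcse(s2$draws[, j], s2$weights)
    expect_lt(abs(m[j] - c(1, -1)[j]), 3 * se)
  }
  v <- colSums(sweep(s2$draws, 2, m)^2 * s2$weights)
  expect_equal(unname(v), c(0.5, 2), tolerance = 0.2)
})

test_that("one PMC pass spends exactly 2S likelihood evaluations after Laplace", {
  cj <- conjugate_fixture(n_tips = 10, seed = 12)
  fit <- mgpm_fit(cj$model, cj$x, nsample = 400, seed = 13)
  expect_equal(fit$n_loglik - fit$n_loglik_laplace, 2 * 400)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(fit$ess >= 1 && fit$ess <= 400 + 1e-9)
})

test_that("fits are reproducible and independent of the parallel flag", {
  cj <- conjugate_fixture(n_tips = 10, seed = 12)
  f1 <- mgpm_fit(cj$model, cj$x, nsample = 300, seed = 21)
  f2 <- mgpm_fit(cj$model, cj$x, nsample = 300, seed = 21)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$draws, f2$draws)
  f3 <- mgpm_fit(cj$model, cj$x, nsample = 300, seed = 21, parallel = TRUE)
  expect_equal(f3$weights, f1$weights, tolerance = 1e-12)
  expect_equal(f3$draws, f1$draws, tolerance = 1e-12)
})

test_that("posterior-mean MC error shrinks like 1/sqrt(S)", {
  cj <- conjugate_fixture(n_tips = 15, seed = 30)
  se_at <- function(S) {
    ses <- vapply(1:6, function(k) {
      fit <- mgpm_fit(cj$model, cj$x, nsample = S, seed = 40 + k)
      coef(fit)[["X0"]]
    }, numeric(1))
    stats::sd(ses)
  }
  r <- se_at(300) / se_at(3000)
  expect_gt(r, 1.5)
  expect_lt(r, 7)
})
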