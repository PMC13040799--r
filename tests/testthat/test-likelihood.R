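test_that("a single tip under BM reduces to one Gaussian density", {
  tr <- read_newick("(A:2.5);")
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  ll <- pruning_loglik(m, c(X0 = 0.7, sigma_Ancestral = 1.3), c(A = -0.4))
  expect_equal(ll, stats::dnorm(-0.4, 0.7, 1.3 * sqrt(2.5), log = TRUE),
               tolerance = 1e-12)
})

test_that("pruning equals the dense multivariate-normal oracle on random MGPMs", {
  count <- 0
  for (seed in 1:70) {
    n <- sample(2:20, 1)
    K <- sample(1:3, 1)
    inst <- random_instance(n, K, seed = 1000 + seed)
    ll1 <- pruning_loglik(inst$model, inst$theta, inst$x)
    ll2 <- dense_loglik_oracle(inst$model, inst$theta, inst$x)
    expect_equal(ll1, ll2, tolerance = 1e-8)
    count <- count + 1
  }
  expect_equal(count, 70)
})

test_that("the cherry BM covariance follows the shared-path rule", {
  tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  td <- tip_distribution(m, c(X0 = 0, sigma_Ancestral = 2))
  ab <- match(c("A", "B"), names(td$mean))
  expect_equal(td$cov[ab[1], ab[2]], 4 * 0.5, tolerance = 1e-12) # sigma^2 s
  expect_equal(diag(td$cov), rep(4 * 1.5, 3), tolerance = 1e-12, # sigma^2 (s+t)
               ignore_attr = TRUE)
})

test_that("the likelihood is exchangeable over a symmetric cherry and over tip order", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  m <- mgpm(tr, kinds = "OU", priors = "diffuse")
  p <- c(X0 = 0, alpha_Ancestral = 1.2, theta_Ancestral = 0.5,
         sigma_Ancestral = 0.9)
  expect_equal(pruning_loglik(m, p, c(A = 0.3, B = -0.8, C = 0.1)),
               pruning_loglik(m, p, c(A = -0.8, B = 0.3, C = 0.1)),
               tolerance = 1e-12)
  # same tree written with children in a different order
  tr2 <- read_newick("(C:2,(B:1,A:1):1);")
  m2 <- mgpm(tr2, kinds = "OU", priors = "diffuse")
  expect_equal(pruning_loglik(m2, p, c(A = 0.3, B = -0.8, C = 0.1)),
               pruning_loglik(m, p, c(A = 0.3, B = -0.8, C = 0.1)),
               tolerance = 1e-12)
})

test_that("exp(loglik) integrates to one over the data space (n = 2)", {
  tr <- read_newick("(A:1,B:1);")
  m <- mgpm(tr, kinds = "OU", priors = "diffuse")
  p <- c(X0 = 0.2, alpha_Ancestral = 1.5, theta_Ancestral = 1,
         sigma_Ancestral = 0.8)
  g <- seq(-4, 5, length.out = 161)
  h <- g[2] - g[1]
  dens <- outer(g, g, Vectorize(function(a, b)
    exp(pruning_loglik(m, p, c(A = a, B = b)))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-4)
})

test_that("zero-length internal edges compose exactly as a Dirac", {
  tr <- read_newick("((A:1,B:1):0,C:1);")
  m <- mgpm(tr, kinds = "BM", priors = "diffuse")
  p <- c(X0 = 0, sigma_Ancestral = 1)
  x <- c(A = 0.4, B = -0.2, C = 1.1)
  expect_equal(pruning_loglik(m, p, x), dense_loglik_oracle(m, p, x),
               tolerance = 1e-10)
})

test_that("runtime grows roughly linearly with the number of tips", {
  m1 <- mgpm(random_ultrametric_tree(100, seed = 1), kinds = "OU",
             priors = "diffuse")
  m2 <- mgpm(random_ultrametric_tree(1000, seed = 1), kinds = "OU",
             priors = "diffuse")
  p <- c(X0 = 0, alpha_Ancestral = 1, theta_Ancestral = 0,
         sigma_Ancestral = 1)
  x1 <- simulate_tips(m1, p, seed = 2)[1, ]
  x2 <- simulate_tips(m2, p, seed = 2)[1, ]
  t1 <- system.time(for (i in 1:50) pruning_loglik(m1, p, x1))[["elapsed"]]
  t2 <- system.time(for (i in 1:50) pruning_loglik(m2, p, x2))[["elapsed"]]
  expect_lt(t2, 20 * max(t1, 0.005))
})

test_that("maximum likelihood recovers the closed-form BM rate with X0 known", {
  tr <- random_ultrametric_tree(15, seed = 6)
  m <- mgpm(tr, kinds = "BM", priors = "diffuse", fixed = c(X0 = 0.5))
  x <- simulate_tips(m, c(X0 = 0.5, sigma_Ancestral = 1.2), seed = 7)[1, ]
  T0 <- tip_distribution(m, c(X0 = 0.5, sigma_Ancestral = 1))$cov
  xc <- mgpm:::align_tips(m, x) - 0.5
  s2_hat <- drop(xc %*% solve(T0) %*% xc) / 15
  fit <- mgpm_ml(m, x, n_starts = 5, seed = 8)
  expect_equal(unname(fit$par["sigma_Ancestral"]^2), s2_hat,
               tolerance = 1e-4)
})

test_that("maximum likelihood fits are deterministic given the seed", {
  inst <- random_instance(12, 2, seed = 77)
  f1 <- mgpm_ml(inst$model, inst$x, n_starts = 3, seed = 5)
  f2 <- mgpm_ml(inst$model, inst$x, n_starts = 3, seed = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})
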