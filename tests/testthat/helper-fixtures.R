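# shared fixture builders; everything is generated in code under fixed seeds

# a random MGPM instance for likelihood cross-checks: seeded Yule tree,
# random total edge painting with K regimes (all used), random mixed kinds
# and parameters, and one simulated trait vector
random_instance <- function(n_tips, K, seed) {
  set.seed(seed)
  tree <- random_ultrametric_tree(n_tips, seed = seed)
  n_node <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  children <- setdiff(seq_len(n_node), root)
  K <- min(K, length(children))
  regs <- paste0("G", seq_len(K))
  lab <- sample(c(regs, sample(regs, length(children) - K, replace = TRUE)))
  names(lab) <- as.character(children)
  painting <- paint_regimes(tree, edges = lab)
  kinds <- sample(c("BM", "OU"), K, replace = TRUE)
  names(kinds) <- attr(painting, "regimes")
  model <- mgpm(tree, painting, kinds = kinds, priors = "diffuse")
  theta <- stats::setNames(numeric(nrow(model$layout)), model$layout$name)
  theta["X0"] <- stats::runif(1, -2, 2)
  for (nm in model$layout$name) {
    role <- model$layout$role[model$layout$name == nm]
    theta[nm] <- switch(role, X0 = theta["X0"],
                        alpha = stats::runif(1, 0.2, 4),
                        theta = stats::runif(1, -3, 3),
                        sigma = stats::runif(1, 0.3, 2))
  }
  x <- simulate_tips(model, theta, nsim = 1, seed = seed + 1)[1, ]
  list(model = model, theta = theta, x = x)
}

# the reduced-scale recovery fixture shared by sampler-quality tests
recovery_fixture <- function(n_tips = 50, seed = 1) {
  tree <- random_ultrametric_tree(n_tips, seed = seed)
  painting <- random_painting(tree, 2, seed = seed)
  model <- mgpm(tree, painting, kinds = "OU", priors = "diffuse")
  truth <- c(X0 = 0, alpha_Ancestral = 2, theta_Ancestral = 2,
             sigma_Ancestral = 1, alpha_R1 = 5, theta_R1 = 0, sigma_R1 = 0.5)
  list(model = model, truth = truth)
}

# conjugate BM model: only X0 free under a Normal prior, sigma fixed;
# closed-form posterior from the dense tip distribution
conjugate_fixture <- function(n_tips = 20, seed = 4, prior_mean = 0,
                              prior_sd = 5, sigma = 1) {
  tree <- random_ultrametric_tree(n_tips, seed = seed)
  model <- mgpm(tree, kinds = "BM",
                priors = list(X0 = prior_normal(prior_mean, prior_sd)),
                fixed = c(sigma_Ancestral = sigma))
  x <- simulate_tips(model, c(X0 = 1, sigma_Ancestral = sigma),
                     nsim = 1, seed = seed + 1)[1, ]
  td <- tip_distribution(model, c(X0 = 0, sigma_Ancestral = sigma))
  Si <- solve(td$cov)
  one <- rep(1, n_tips)
  prec <- 1 / prior_sd^2 + drop(one %*% Si %*% one)
  post_mean <- (prior_mean / prior_sd^2 + drop(one %*% Si %*% x)) / prec
  list(model = model, x = x, post_mean = post_mean, post_sd = sqrt(1 / prec))
}

# delta-method MC standard error of the weighted sd estimate
mcse_sd <- function(x, w) {
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  mcse_var <- sqrt(sum(w^2 * ((x - m)^2 - v)^2))
  mcse_var / (2 * sqrt(v))
}
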