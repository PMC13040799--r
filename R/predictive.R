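#' Simulate trait values at the tips of an MGPM
#'
#' Forward (pre-order) simulation from the root state `X0`: each node's value
#' is drawn from `N(a * parent + b, V)` with its own edge's regime
#' coefficients. Replicates are simulated jointly (vectorized across the
#' node loop), so large replicate counts are cheap.
#'
#' @param model an [mgpm()].
#' @param params full parameter values (named vector/list).
#' @param nsim number of replicate tip vectors.
#' @param seed integer RNG seed.
#' @return A `nsim x n` matrix of tip values, columns named by tip label.
#' @examples
#' tr <- random_ultrametric_tree(5, seed = 1)
#' simulate_tips(mgpm(tr, kinds = "BM"), c(X0 = 0, sigma_Ancestral = 1),
#'               nsim = 3, seed = 2)
#' @export
simulate_tips <- function(model, params, nsim = 1, seed = 1) {
  theta <- as_full_params(model, params)
  cf <- edge_coefficients(model, theta)
  plan <- model$plan
  local_seed(seed, {
    val <- matrix(0, nsim, plan$n_node)
    val[, plan$root] <- theta$X0
    for (e in rev(seq_along(plan$pa))) { # pre-order
      u <- plan$pa[e]; v <- plan$ch[e]
      val[, v] <- cf$a[e] * val[, u] + cf$b[e] +
        sqrt(cf$V[e]) * stats::rnorm(nsim)
    }
    out <- val[, seq_len(plan$n), drop = FALSE]
    colnames(out) <- plan$tip_labels
    out
  })
}

#' @export
simulate.mgpm <- function(object, nsim = 1, seed = 1, params, ...) {
  simulate_tips(object, params, nsim = nsim, seed = seed)
}

#' Posterior predictive replicates at the tips
#'
#' Draws `S_p` parameter vectors from the weighted posterior sample by
#' multinomial resampling, then simulates one replicate tip vector from each.
#' Stores the replicates together with the per-tip predictive means and
#' (unbiased) variances used by the posterior predictive loss.
#'
#' @param fit an [mgpm_fit()].
#' @param S_p number of predictive replicates (default: the fit's `S`).
#' @param seed integer RNG seed.
#' @return An object of class `mgpm_predictive`: list with `replicates`
#'   (`S_p x n`), `m` (per-tip predictive means), `s2` (per-tip predictive
#'   variances).
#' @export
posterior_predictive_draws <- function(fit, S_p = fit$S, seed = 1) {
  stopifnot(S_p >= 2)
  seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  idx <- multinomial_resample(fit$weights, S_p, seed = seeds[1])
  reps <- matrix(0, S_p, length(fit$model$plan$tip_labels))
  # one pre-order pass per distinct resampled parameter value
  tab <- table(idx)
  uidx <- as.integer(names(tab))
  sub_seeds <- local_seed(seeds[2],
                          sample.int(.Machine$integer.max - 1L, length(uidx)))
  rows <- split(seq_len(S_p), match(idx, uidx))
  for (k in seq_along(uidx)) {
    th <- full_params(fit$model, fit$draws[uidx[k], ])
    reps[rows[[k]], ] <- simulate_tips(fit$model, th,
                                       nsim = length(rows[[k]]),
                                       seed = sub_seeds[k])
  }
  colnames(reps) <- fit$model$plan$tip_labels
  structure(list(replicates = reps,
                 m = colMeans(reps),
                 s2 = apply(reps, 2, stats::var),
                 S_p = S_p),
            class = "mgpm_predictive")
}

#' @export
simulate.mgpm_fit <- function(object, nsim = object$S, seed = 1, ...) {
  posterior_predictive_draws(object, S_p = nsim, seed = seed)$replicates
}

#' Posterior predictive loss
#'
#' The estimated posterior predictive loss of a model for observed tips `x`
#' is `sum_i (x_i - m_i)^2 + lambda * sum_i s2_i`, where `m_i` and `s2_i` are
#' the mean and variance of the posterior predictive replicates at tip `i`.
#' `lambda = 1` is the plain loss; `lambda = p` or `lambda = log(p)` (with
#' `p` the model's parameter count) penalize complexity explicitly.
#'
#' @param draws an `mgpm_predictive` (or a plain `S_p x n` replicate matrix),
#'   or an `mgpm_fit` (replicates are then simulated, see `...`).
#' @param x observed tip values, named by tip label (or in replicate column
#'   order).
#' @param lambda variance-term multiplier (>= 1).
#' @param ... for the `mgpm_fit` method: `S_p`, `seed` passed to
#'   [posterior_predictive_draws()].
#' @return An object of class `mgpm_ppl`: list with `sse`, `var_term`,
#'   `lambda`, `total`.
#' @examples
#' reps <- rbind(c(1, 2), c(3, 4))
#' ppl(reps, c(1, 2)) # sse 2, var term 4, total 6
#' @export
ppl <- function(draws, x, lambda = 1, ...) {
  UseMethod("ppl")
}

#' @export
ppl.mgpm_fit <- function(draws, x, lambda = 1, S_p = draws$S, seed = 1, ...) {
  pd <- posterior_predictive_draws(draws, S_p = S_p, seed = seed)
  ppl(pd, x, lambda)
}

#' @export
ppl.mgpm_predictive <- function(draws, x, lambda = 1, ...) {
  ppl_core(draws$m, draws$s2, x, lambda, names(draws$m))
}

#' @export
ppl.matrix <- function(draws, x, lambda = 1, ...) {
  ppl_core(colMeans(draws), apply(draws, 2, stats::var), x, lambda,
           colnames(draws))
}

ppl_core <- function(m, s2, x, lambda, labels) {
  stopifnot(lambda >= 1)
  if (!is.null(names(x)) && !is.null(labels)) {
    if (!setequal(names(x), labels)) stop("tip labels do not match")
    x <- x[labels]
  } else if (length(x) != length(m)) stop("tip count mismatch")
  structure(list(sse = sum((x - m)^2), var_term = sum(s2), lambda = lambda,
                 total = sum((x - m)^2) + lambda * sum(s2)),
            class = "mgpm_ppl")
}

#' @export
print.mgpm_ppl <- function(x, ...) {
  cat(sprintf("Posterior predictive loss: %.4f (SSE %.4f + lambda %.4g x variance %.4f)\n",
              x$total, x$sse, x$lambda, x$var_term))
  invisible(x)
}

#' @export
residuals.mgpm_fit <- function(object, S_p = object$S, seed = 1, ...) {
  pd <- posterior_predictive_draws(object, S_p = S_p, seed = seed)
  xv <- stats::setNames(object$x, object$model$plan$tip_labels)
  xv - pd$m
}

#' Posterior predictive density curves at the tips
#'
#' Estimates each tip's marginal posterior predictive density as an
#' equal-weight mixture of normals: `S` parameter vectors are resampled from
#' the posterior, each tip's marginal mean and variance under a draw are
#' composed exactly along its root-to-tip path (no kernel smoothing), and
#' the univariate normal densities are averaged on the supplied grid.
#'
#' @param fit an [mgpm_fit()].
#' @param grid numeric vector of trait values at which to evaluate.
#' @param S number of posterior draws in the mixture.
#' @param seed integer RNG seed (for the resampling step).
#' @return A list with `grid` and `density` (`n x length(grid)` matrix,
#'   rows named by tip).
#' @export
predictive_density_at_tips <- function(fit, grid, S = 1000, seed = 1) {
  stopifnot(length(grid) > 0)
  idx <- multinomial_resample(fit$weights, S, seed = seed)
  model <- fit$model
  plan <- model$plan
  n <- plan$n
  dens <- matrix(0, n, length(grid),
                 dimnames = list(plan$tip_labels, NULL))
  tab <- table(idx)
  uidx <- as.integer(names(tab))
  cnt <- as.integer(tab)
  for (k in seq_along(uidx)) {
    td <- tip_distribution(model, full_params(model, fit$draws[uidx[k], ]))
    sd_i <- sqrt(diag(td$cov))
    for (i in seq_len(n)) {
      dens[i, ] <- dens[i, ] +
        cnt[k] * stats::dnorm(grid, td$mean[i], sd_i[i])
    }
  }
  list(grid = grid, density = dens / S)
}

#' @export
predict.mgpm_fit <- function(object, type = c("replicates", "density"),
                             S_p = object$S, grid = NULL, seed = 1, ...) {
  type <- match.arg(type)
  if (type == "replicates")
    posterior_predictive_draws(object, S_p = S_p, seed = seed)
  else {
    if (is.null(grid)) {
      r <- range(object$x)
      grid <- seq(r[1] - 2 * diff(r) - 1, r[2] + 2 * diff(r) + 1,
                  length.out = 512)
    }
    predictive_density_at_tips(object, grid, S = min(S_p, 1000), seed = seed)
  }
}

#' Compare fitted MGPMs by posterior predictive loss
#'
#' Computes, for each fitted model, the SSE and variance terms and the loss
#' at `lambda = 1`, `lambda = ln(p)` and `lambda = p` (`p` = parameter count
#' including `X0`), and ranks the models by the chosen rule.
#'
#' @param x observed tip values (shared by all fits).
#' @param fits named list of `mgpm_fit` objects on the same tree and data.
#' @param S_p predictive replicates per model.
#' @param lambda_rule which column to rank by: `"1"`, `"lnp"`, or `"p"`.
#' @param seed integer RNG seed.
#' @return A data frame (one row per model) ordered by the chosen loss.
#' @export
model_comparison <- function(x, fits, S_p = NULL, lambda_rule = c("1", "lnp", "p"),
                             seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  tip_sets <- lapply(fits, function(f) f$model$plan$tip_labels)
  if (!all(vapply(tip_sets, setequal, logical(1), y = tip_sets[[1]])))
    stop("fits are not on the same tree")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    sp <- if (is.null(S_p)) f$S else S_p
    pd <- posterior_predictive_draws(f, S_p = sp, seed = seed)
    p <- n_params(f$model)
    base <- ppl(pd, x, 1)
    data.frame(model = nm, p = p, sse = base$sse, var_term = base$var_term,
               ppl_1 = base$total,
               ppl_lnp = base$sse + log(p) * base$var_term,
               ppl_p = base$sse + p * base$var_term,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- switch(lambda_rule, "1" = out$ppl_1, lnp = out$ppl_lnp, p = out$ppl_p)
  out <- out[order(key), ]
  rownames(out) <- NULL
  out
}
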