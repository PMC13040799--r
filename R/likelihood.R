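#' MGPM log-likelihood by the pruning algorithm
#'
#' Evaluates the log-density of the tip data under the model in O(n), by
#' post-order message passing: each node's partial likelihood, as a function
#' of its parent's state, is a log-scale Gaussian quadratic; sibling messages
#' add, and internal states are integrated out in closed form edge by edge.
#' The root state `X0` is a parameter (no root integration): the summed root
#' message is evaluated at its value.
#'
#' @param model an [mgpm()].
#' @param params full parameter values: named vector/list covering the model
#'   layout (fixed parameters may be omitted).
#' @param x named numeric vector of tip trait values (names = tip labels,
#'   assumed already on the real line, e.g. log scale).
#' @return The log-likelihood (scalar). `-Inf` for degenerate parameter
#'   values (e.g. zero variance on a terminal edge).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' m <- mgpm(tr, kinds = "BM")
#' pruning_loglik(m, c(X0 = 0, sigma_Ancestral = 1), c(A = 0.1, B = -0.2, C = 0.3))
#' @export
pruning_loglik <- function(model, params, x) {
  theta <- as_full_params(model, params)
  xv <- align_tips(model, x)
  cf <- edge_coefficients(model, theta)
  plan <- model$plan
  tipval <- numeric(plan$n_node)
  tipval[seq_len(plan$n)] <- xv
  C_pruning_loglik(plan$pa, plan$ch, cf$a, cf$b, cf$V,
                   tipval, plan$is_tip, plan$n_node, plan$root,
                   theta$X0)
}

align_tips <- function(model, x) {
  lab <- model$plan$tip_labels
  if (is.null(names(x))) {
    if (length(x) != length(lab)) stop("trait vector length mismatch")
    return(as.numeric(x))
  }
  if (!setequal(names(x), lab)) stop("trait labels do not match the tree's tips")
  v <- as.numeric(x[lab])
  if (any(!is.finite(v))) stop("non-finite trait value")
  v
}

#' Analytic tip distribution and dense-likelihood oracle
#'
#' `tip_distribution()` builds the exact n-variate normal implied by the
#' model at given parameters by a pre-order covariance recursion: for a child
#' `v` of `u` across an edge with coefficients `(a, b, V)`,
#' `mean_v = a*mean_u + b`, `Var_v = a^2 Var_u + V`, and
#' `Cov(v, w) = a Cov(u, w)` for nodes `w` not below `v`; the root has mean
#' `X0` and variance 0. `dense_loglik_oracle()` evaluates the resulting
#' multivariate normal log-density directly (O(n^3)); it is an independent
#' cross-check of [pruning_loglik()] for small trees.
#'
#' @inheritParams pruning_loglik
#' @return `tip_distribution()`: a list with `mean` (length n) and `cov`
#'   (n x n), tip-ordered; `dense_loglik_oracle()`: the log-likelihood.
#' @export
tip_distribution <- function(model, params) {
  theta <- as_full_params(model, params)
  plan <- model$plan
  cf <- edge_coefficients(model, theta)
  N <- plan$n_node
  mean_v <- numeric(N); mean_v[plan$root] <- theta$X0
  S <- matrix(0, N, N)
  # pre-order: reverse of the postorder edge list
  for (e in rev(seq_along(plan$pa))) {
    u <- plan$pa[e]; v <- plan$ch[e]
    a <- cf$a[e]
    mean_v[v] <- a * mean_v[u] + cf$b[e]
    S[v, ] <- a * S[u, ]
    S[, v] <- S[v, ]
    S[v, v] <- a^2 * S[u, u] + cf$V[e]
  }
  tips <- seq_len(plan$n)
  list(mean = stats::setNames(mean_v[tips], plan$tip_labels),
       cov = S[tips, tips, drop = FALSE])
}

#' @rdname tip_distribution
#' @param x named numeric vector of tip values.
#' @export
dense_loglik_oracle <- function(model, params, x) {
  td <- tip_distribution(model, params)
  xv <- align_tips(model, x)
  R <- tryCatch(chol(td$cov), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  u <- backsolve(R, xv - td$mean, transpose = TRUE)
  -0.5 * sum(u^2) - sum(log(diag(R))) - 0.5 * length(xv) * log(2 * pi)
}

# log-likelihood closure over the free unbounded vector z, with an eval counter
make_logpost <- function(model, x, counter = NULL) {
  xv <- align_tips(model, x)
  names(xv) <- model$plan$tip_labels
  function(z) {
    if (!is.null(counter)) counter$n <- counter$n + 1L
    theta <- full_params(model, from_unbounded(model, z))
    ll <- pruning_loglik(model, theta, xv)
    ll + model_log_prior(model, z)
  }
}

make_loglik_z <- function(model, x, counter = NULL) {
  xv <- align_tips(model, x)
  names(xv) <- model$plan$tip_labels
  function(z) {
    if (!is.null(counter)) counter$n <- counter$n + 1L
    pruning_loglik(model, full_params(model, from_unbounded(model, z)), xv)
  }
}

#' Multi-start maximum likelihood baseline fit
#'
#' Bounded maximization of the pruning log-likelihood in the unbounded
#' parameter space, restarted from seeded uniform draws inside the search
#' box; the best converged run is returned. This is the frequentist
#' comparator for the Bayesian fit.
#'
#' @param model an [mgpm()].
#' @param x named tip trait vector.
#' @param n_starts number of random restarts.
#' @param box_positive,box_real search boxes, in the original space, for
#'   positive (`alpha`, `sigma`) and unconstrained (`X0`, `theta`)
#'   parameters.
#' @param seed integer RNG seed (restart draws are deterministic given it).
#' @return An object of class `mgpm_ml`: list with `par` (full named
#'   parameter vector at the optimum), `loglik`, and `starts` (per-start
#'   convergence diagnostics).
#' @export
mgpm_ml <- function(model, x, n_starts = 10,
                    box_positive = c(0, 100), box_real = c(-200, 200),
                    seed = 1) {
  ls <- model$layout$log_transform[model$free]
  d <- sum(model$free)
  # map the box through the transform; a zero lower bound on a positive
  # parameter opens the box downward, truncated for L-BFGS-B
  lo <- ifelse(ls, log(pmax(box_positive[1], 1e-10)), box_real[1])
  hi <- ifelse(ls, log(box_positive[2]), box_real[2])
  nll <- make_loglik_z(model, x)
  f <- function(z) {
    v <- nll(z)
    if (!is.finite(v)) 1e10 else -v
  }
  runs <- local_seed(seed, {
    # random initialization: uniform over the search box in the original
    # space (positive parameters floored away from zero), then transformed
    starts <- matrix(stats::runif(n_starts * d,
                                  rep(ifelse(ls, max(box_positive[1], 1e-4),
                                             box_real[1]), each = n_starts),
                                  rep(ifelse(ls, box_positive[2], box_real[2]),
                                      each = n_starts)),
                     n_starts, d)
    starts[, ls] <- log(starts[, ls, drop = FALSE])
    lapply(seq_len(n_starts), function(i) {
      tryCatch(stats::optim(starts[i, ], f, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 500)),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all maximum-likelihood starts failed")
  vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  theta <- full_params(model, from_unbounded(model, best$par))
  structure(list(par = unlist(theta), loglik = -best$value,
                 convergence = best$convergence,
                 starts = data.frame(value = -vals, ok = ok)),
            class = "mgpm_ml")
}

#' @export
print.mgpm_ml <- function(x, ...) {
  cat("Maximum likelihood MGPM fit; log-likelihood", format(x$loglik), "\n")
  print(round(x$par, 4))
  invisible(x)
}
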