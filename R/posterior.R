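#' Posterior expectation of a function of the parameters
#'
#' Self-normalized importance-sampling estimate
#' `E[h(Theta) | x] ~ sum_i h(Theta_i) w_i` over the weighted posterior
#' sample.
#'
#' @param fit an [mgpm_fit()], or a list with elements `draws` (S x d matrix,
#'   original parameter space) and `weights`.
#' @param h function of one draw (a named numeric vector); may return a
#'   vector.
#' @return The weighted expectation (scalar or vector).
#' @examples
#' s <- list(draws = cbind(a = c(1, 3)), weights = c(0.5, 0.5))
#' weighted_expectation(s, function(th) th["a"]) # 2
#' @export
weighted_expectation <- function(fit, h) {
  H <- do.call(rbind, lapply(seq_len(nrow(fit$draws)),
                             function(i) h(fit$draws[i, ])))
  if (any(!is.finite(H[fit$weights > 0, , drop = FALSE])))
    stop("h is non-finite at a positively weighted draw")
  out <- colSums(H * fit$weights)
  if (length(out) == 1L) unname(out) else out
}

# left-continuous inverse of the weighted step ECDF: the first atom whose
# cumulative weight reaches p (atoms carry their full mass)
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o])
  vapply(p, function(pp) x[o][which(cw >= pp - 1e-12)[1L]], numeric(1))
}

weighted_mean <- function(x, w) sum(x * w)
weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2)
}
# delta-method Monte Carlo SE of the self-normalized IS mean
weighted_mcse <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w^2 * (x - m)^2))
}

#' Summarize a fitted MGPM posterior
#'
#' Per-parameter weighted posterior summaries in the original parameter
#' space: mean, standard deviation, Monte Carlo standard error of the mean
#' (self-normalized importance-sampling delta method), and 2.5% / 50% /
#' 97.5% quantiles by the left-continuous inverse of the weighted ECDF.
#'
#' @param object an `mgpm_fit`.
#' @param ... unused.
#' @return A `summary.mgpm_fit`: data frame (one row per free parameter)
#'   plus `ess` and `log_evidence` attributes.
#' @export
summary.mgpm_fit <- function(object, ...) {
  if (object$ess < 50)
    warning("effective sample size below 50; summaries are unreliable")
  w <- object$weights
  tab <- do.call(rbind, lapply(colnames(object$draws), function(nm) {
    x <- object$draws[, nm]
    q <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
    data.frame(parameter = nm, mean = weighted_mean(x, w),
               sd = sqrt(weighted_var(x, w)), mcse = weighted_mcse(x, w),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(tab, ess = object$ess, log_evidence = object$log_evidence,
            S = object$S, class = c("summary.mgpm_fit", "data.frame"))
}

#' @export
print.summary.mgpm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (S = %d, ESS = %.1f)\n",
              attr(x, "S"), attr(x, "ess")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.mgpm_fit <- function(x, ...) {
  cat(sprintf("MGPM posterior fit: %d free parameter(s), S = %d, ESS = %.1f\n",
              ncol(x$draws), x$S, x$ess))
  cat(sprintf("log-evidence estimate %.4f; %d likelihood evaluations\n",
              x$log_evidence, x$n_loglik))
  print(summary(x))
  invisible(x)
}

#' @export
coef.mgpm_fit <- function(object, type = c("mean", "median"), ...) {
  type <- match.arg(type)
  w <- object$weights
  vapply(colnames(object$draws), function(nm) {
    if (type == "mean") weighted_mean(object$draws[, nm], w)
    else weighted_quantile(object$draws[, nm], w, 0.5)
  }, numeric(1))
}

#' Equal-tailed credible interval
#'
#' @param fit an `mgpm_fit`.
#' @param parameter parameter name (default: all free parameters).
#' @param level interval mass (default 0.95).
#' @return A matrix with columns `lo`, `hi` (one row per parameter).
#' @export
credible_interval <- function(fit, parameter = NULL, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.null(parameter)) parameter <- colnames(fit$draws)
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- t(vapply(parameter, function(nm)
    weighted_quantile(fit$draws[, nm], fit$weights, p), numeric(2)))
  colnames(out) <- c("lo", "hi")
  out
}

#' Marginal posterior density plots
#'
#' Weighted kernel density estimates of each free parameter's marginal
#' posterior, with the prior density overlaid (dashed).
#'
#' @param x an `mgpm_fit`.
#' @param parameters which parameters to plot (default all).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.mgpm_fit <- function(x, parameters = colnames(x$draws), ...) {
  k <- length(parameters)
  op <- graphics::par(mfrow = c(ceiling(k / 3), min(k, 3)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in parameters) {
    d <- stats::density(x$draws[, nm], weights = x$weights)
    graphics::plot(d, main = nm, xlab = nm, ...)
    pr <- x$model$priors[[nm]]
    if (!is.null(pr)) {
      graphics::curve(exp(prior_logpdf(pr, x_)), xname = "x_",
                      from = min(d$x), to = max(d$x), add = TRUE, lty = 2)
    }
  }
  invisible(x)
}
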