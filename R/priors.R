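#' Prior distribution constructors
#'
#' Per-parameter prior building blocks for an MGPM. `prior_normal()` is the
#' usual choice for unconstrained parameters (the root state `X0` and OU
#' optima `theta`); `prior_halfnormal()` for positive parameters (`alpha`,
#' `sigma`). The joint prior of a model is the product of its per-parameter
#' priors (independence).
#'
#' @param mean,sd Normal location and standard deviation (`sd > 0`).
#' @param scale Half-Normal scale (> 0); the density is
#'   `sqrt(2/pi)/scale * exp(-x^2/(2*scale^2))` on `x >= 0`.
#' @return An object of class `mgpm_prior`.
#' @examples
#' p <- prior_halfnormal(10)
#' prior_quantile(p, 0.95)
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  stopifnot(sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd),
            class = "mgpm_prior")
}

#' @rdname prior_normal
#' @export
prior_halfnormal <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(family = "halfnormal", scale = scale),
            class = "mgpm_prior")
}

#' @export
print.mgpm_prior <- function(x, ...) {
  cat(format_prior(x), "\n")
  invisible(x)
}

format_prior <- function(p) {
  switch(p$family,
         normal = sprintf("Normal(mean = %.4g, sd = %.4g)", p$mean, p$sd),
         halfnormal = sprintf("Half-Normal(scale = %.4g)", p$scale))
}

#' Evaluate, sample and invert a prior
#'
#' @param prior an `mgpm_prior`.
#' @param x,p,n evaluation points, probabilities, draw count.
#' @return Log-density values, quantiles, or random draws.
#' @export
prior_logpdf <- function(prior, x) {
  switch(prior$family,
         normal = stats::dnorm(x, prior$mean, prior$sd, log = TRUE),
         halfnormal = ifelse(x < 0, -Inf,
                             log(2) + stats::dnorm(x, 0, prior$scale, log = TRUE)))
}

#' @rdname prior_logpdf
#' @export
prior_quantile <- function(prior, p) {
  switch(prior$family,
         normal = stats::qnorm(p, prior$mean, prior$sd),
         halfnormal = prior$scale * stats::qnorm((1 + p) / 2))
}

#' @rdname prior_logpdf
#' @export
prior_sample <- function(prior, n = 1) {
  switch(prior$family,
         normal = stats::rnorm(n, prior$mean, prior$sd),
         halfnormal = abs(stats::rnorm(n, 0, prior$scale)))
}

#' Fit a Normal prior to two stated quantiles
#'
#' Returns the unique Normal distribution whose `p_lo` quantile is `q_lo` and
#' whose `p_hi` quantile is `q_hi`. Used to encode interval beliefs about
#' unconstrained parameters, e.g. "the optimum log-trait lies between log(1)
#' and log(50) with 80% prior probability".
#'
#' @param q_lo,q_hi stated quantile values (`q_lo < q_hi`).
#' @param p_lo,p_hi their probabilities (`0 < p_lo < p_hi < 1`).
#' @return A `prior_normal()` object.
#' @examples
#' normal_from_quantiles(0, 0.10, log(50), 0.90) # N(1.9560, var 2.3295)
#' @export
normal_from_quantiles <- function(q_lo, p_lo, q_hi, p_hi) {
  stopifnot(p_lo < p_hi, q_lo < q_hi, p_lo > 0, p_hi < 1)
  z_lo <- stats::qnorm(p_lo); z_hi <- stats::qnorm(p_hi)
  sd <- (q_hi - q_lo) / (z_hi - z_lo)
  prior_normal(mean = q_lo - sd * z_lo, sd = sd)
}

#' Fit a Half-Normal prior to one stated quantile
#'
#' Returns the Half-Normal whose `p` quantile equals `q`; its scale is
#' `q / qnorm((1 + p) / 2)`.
#'
#' @param q stated quantile value (> 0).
#' @param p its probability (0 < p < 1).
#' @return A `prior_halfnormal()` object.
#' @examples
#' halfnormal_from_quantile(4.9410, 0.95) # scale 2.5210
#' @export
halfnormal_from_quantile <- function(q, p) {
  stopifnot(q > 0, p > 0, p < 1)
  prior_halfnormal(scale = q / stats::qnorm((1 + p) / 2))
}

#' Calibrate the selection-strength prior from a phylogenetic half-life
#'
#' The phylogenetic half-life of an OU process is `t_half = ln(2) / alpha`:
#' the time to close half the distance from the ancestral state to the
#' optimum. Declaring the shortest plausible half-life as a fraction of the
#' tree height `t_H` yields an upper reference value
#' `alpha_star = ln(2) / (halflife_fraction * t_H)`, and the prior is the
#' Half-Normal whose `p` quantile sits at `alpha_star`.
#'
#' @param t_H tree height, in time units.
#' @param halflife_fraction shortest plausible half-life as a fraction of
#'   `t_H` (default 0.01).
#' @param p quantile matched to `alpha_star` (default 0.95).
#' @return A `prior_halfnormal()` with attribute `alpha_star`.
#' @examples
#' alpha_prior_from_halflife(14.02854, 0.01, 0.95) # alpha* 4.9410, scale 2.5210
#' @export
alpha_prior_from_halflife <- function(t_H, halflife_fraction = 0.01, p = 0.95) {
  stopifnot(t_H > 0, halflife_fraction > 0, p > 0, p < 1)
  alpha_star <- log(2) / (halflife_fraction * t_H)
  out <- halfnormal_from_quantile(alpha_star, p)
  attr(out, "alpha_star") <- alpha_star
  out
}

#' Calibrate the diffusion-rate prior from a plausible tip variance
#'
#' Under BM the trait variance accumulated over the whole tree height is
#' `sigma^2 t_H`; declaring a high-but-plausible marginal tip variance
#' `tip_var` gives the reference rate `sigma_star = sqrt(tip_var / t_H)`
#' (BM bounds the OU variance from above, so the calibration is conservative
#' for OU regimes). The prior is the Half-Normal whose `p` quantile sits at
#' `sigma_star`.
#'
#' @param tip_var plausible marginal trait variance at the tips (> 0).
#' @param t_H tree height.
#' @param p matched quantile (default 0.95).
#' @return A `prior_halfnormal()` with attribute `sigma_star`.
#' @examples
#' sigma_prior_from_tip_variance(4.6591, 14.02854, 0.95) # sigma* 0.5763, scale 0.2940
#' @export
sigma_prior_from_tip_variance <- function(tip_var, t_H, p = 0.95) {
  stopifnot(tip_var > 0, t_H > 0, p > 0, p < 1)
  sigma_star <- sqrt(tip_var / t_H)
  out <- halfnormal_from_quantile(sigma_star, p)
  attr(out, "sigma_star") <- sigma_star
  out
}

#' Named prior presets
#'
#' Three ready-made prior configurations used by the simulation-study
#' harnesses: `"diffuse"` (Half-Normal(10) on positive parameters,
#' Normal(0, sd 10) on unconstrained ones), `"moderate"` (Half-Normal(5),
#' Normal(0, sd 5)), and `"cervidae"` (the antler-size configuration: Normal
#' with 10%/90% quantiles at log(1 cm) and log(50 cm) for `X0` and `theta`,
#' half-life- and tip-variance-calibrated Half-Normals for `alpha` and
#' `sigma`).
#'
#' @param name preset name.
#' @return A function `(role) -> mgpm_prior`, where role is one of
#'   `"X0"`, `"alpha"`, `"theta"`, `"sigma"`.
#' @export
prior_preset <- function(name = c("diffuse", "moderate", "cervidae")) {
  name <- match.arg(name)
  switch(name,
    diffuse = function(role)
      switch(role,
             alpha = , sigma = prior_halfnormal(10),
             prior_normal(0, 10)),
    moderate = function(role)
      switch(role,
             alpha = , sigma = prior_halfnormal(5),
             prior_normal(0, 5)),
    cervidae = {
      tH <- 14.02854
      real <- normal_from_quantiles(0, 0.10, log(50), 0.90)
      a <- alpha_prior_from_halflife(tH, 0.01, 0.95)
      s <- sigma_prior_from_tip_variance(2 * real$sd^2, tH, 0.95)
      function(role) switch(role, alpha = a, sigma = s, real)
    })
}

# joint log prior in the unbounded space:
# sum_j log p_j(g^{-1}(z)_j) + sum_{log slots} z_j
log_prior_z <- function(priors, log_slot, z) {
  theta <- ifelse(log_slot, exp(z), z)
  s <- 0
  for (j in seq_along(priors)) s <- s + prior_logpdf(priors[[j]], theta[j])
  s + sum(z[log_slot])
}
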