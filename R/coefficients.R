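#' Gaussian transition coefficients for Brownian motion
#'
#' For an edge of length `l` under BM with rate `sigma`, the trait transition
#' is `x(t) | x(s) ~ N(a*x(s) + b, V)` with `a = 1`, `b = 0`, `V = sigma^2 l`.
#'
#' @param sigma diffusion rate (> 0), trait units per square-root time.
#' @param l elapsed time (>= 0); vectorized.
#' @return A list with numeric components `a`, `b`, `V`.
#' @examples
#' bm_coefficients(1, 3) # V = 3
#' @export
bm_coefficients <- function(sigma, l) {
  stopifnot(sigma > 0)
  if (any(l < 0)) stop("negative elapsed time")
  list(a = rep(1, length(l)), b = rep(0, length(l)), V = sigma^2 * l)
}

#' Gaussian transition coefficients for the Ornstein-Uhlenbeck process
#'
#' For an edge of length `l` under OU with selection strength `alpha` (1/time),
#' optimum `theta` and diffusion `sigma`, the transition is
#' `N(a*x(s) + b, V)` with `a = exp(-alpha*l)`, `b = (1 - exp(-alpha*l)) theta`
#' and `V = sigma^2 (1 - exp(-2*alpha*l)) / (2*alpha)`. Evaluated through
#' `expm1()` so the BM limit `alpha -> 0` (`a -> 1`, `b -> 0`,
#' `V -> sigma^2 l`) is reached without cancellation.
#'
#' @param alpha selection strength (> 0). `alpha = 0` is BM: use
#'   [bm_coefficients()].
#' @param theta optimum trait value.
#' @param sigma diffusion rate (> 0).
#' @param l elapsed time (>= 0); vectorized.
#' @return A list with numeric components `a`, `b`, `V`.
#' @examples
#' ou_coefficients(2, 2, 1, 0.5)
#' @export
ou_coefficients <- function(alpha, theta, sigma, l) {
  stopifnot(alpha >= 0, sigma > 0)
  if (any(l < 0)) stop("negative elapsed time")
  if (alpha == 0) {
    # continuous limit (reached e.g. by exp() underflow of a log-scale
    # optimizer step); the modelling choice "this regime is BM" is made at
    # the model level, not here
    return(list(a = rep(1, length(l)), b = rep(0, length(l)),
                V = sigma^2 * l))
  }
  em <- expm1(-alpha * l)          # e^{-alpha l} - 1
  list(a = 1 + em,
       b = -em * theta,
       V = sigma^2 * (-expm1(-2 * alpha * l)) / (2 * alpha))
}

# per-edge (a, b, V) vectors in plan edge order, given full parameter values
edge_coefficients <- function(model, theta) {
  plan <- model$plan
  ne <- length(plan$len)
  a <- numeric(ne); b <- numeric(ne); V <- numeric(ne)
  for (k in seq_along(model$kinds)) {
    idx <- which(plan$regime == k)
    if (!length(idx)) next
    l <- plan$len[idx]
    if (model$kinds[k] == "BM") {
      s <- theta[[paste0("sigma_", model$regimes[k])]]
      cf <- bm_coefficients(s, l)
    } else {
      r <- model$regimes[k]
      cf <- ou_coefficients(theta[[paste0("alpha_", r)]],
                            theta[[paste0("theta_", r)]],
                            theta[[paste0("sigma_", r)]], l)
    }
    a[idx] <- cf$a; b[idx] <- cf$b; V[idx] <- cf$V
  }
  list(a = a, b = b, V = V)
}
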