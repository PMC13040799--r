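#' Specify a mixed Gaussian phylogenetic model
#'
#' An MGPM couples a fixed ultrametric tree, a regime painting of its edges,
#' a process kind (BM or OU) per regime, and independent per-parameter priors.
#' Every regime has its own parameters (BM: `sigma`; OU: `alpha`, `theta`,
#' `sigma`); the ancestral state at the root, `X0`, is a single free parameter
#' shared by all regimes. The flat parameter vector is ordered
#' `(X0, theta_regime1, ..., theta_regimeK)` with `(alpha, theta, sigma)`
#' inside each OU regime.
#'
#' @param tree a `phylo` object (rooted, ultrametric, branch lengths in time
#'   units).
#' @param painting an [paint_regimes()] result; `NULL` paints a single
#'   `"Ancestral"` regime over the whole tree.
#' @param kinds character vector of process kinds (`"BM"` or `"OU"`), named by
#'   regime, or a single value recycled to all regimes. Default `"OU"`.
#' @param priors either a preset name (see [prior_preset()]) or a named list
#'   of `mgpm_prior` objects keyed by parameter name (e.g.
#'   `alpha_Ancestral`). Only free parameters need priors.
#' @param fixed named numeric vector of parameters to hold fixed (excluded
#'   from inference), e.g. `c(sigma_Ancestral = 1)`.
#' @param rel_tol ultrametricity tolerance passed to
#'   [validate_ultrametric()].
#' @param allow_nonultrametric skip the ultrametricity check (the half-life
#'   and tip-variance prior calibrations presume a single tree height, so this
#'   is off by default).
#' @return An object of class `mgpm` with the parameter layout, transform to
#'   unbounded space, and a precomputed traversal plan.
#' @examples
#' tr <- random_ultrametric_tree(20, seed = 1)
#' m <- mgpm(tr, random_painting(tr, 2, seed = 1), kinds = "OU",
#'           priors = "diffuse")
#' m
#' @export
mgpm <- function(tree, painting = NULL, kinds = "OU", priors = "diffuse",
                 fixed = NULL, rel_tol = 1e-6, allow_nonultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!allow_nonultrametric) validate_ultrametric(tree, rel_tol)
  if (is.null(painting)) painting <- paint_regimes(tree, default = "Ancestral")
  n_node <- ape::Ntip(tree) + tree$Nnode
  if (length(painting) != n_node) stop("painting does not match the tree")
  regimes <- attr(painting, "regimes")
  K <- attr(painting, "K")
  used <- unique(as.character(painting[!is.na(painting)]))
  if (!setequal(used, regimes)) stop("every regime must cover at least one edge")

  if (length(kinds) == 1L && is.null(names(kinds))) kinds <- rep(kinds, K)
  if (is.null(names(kinds))) names(kinds) <- regimes
  kinds <- kinds[regimes]
  if (anyNA(kinds) || !all(kinds %in% c("BM", "OU")))
    stop("kinds must be 'BM' or 'OU', one per regime")

  layout <- data.frame(
    name = "X0", regime = NA_character_, role = "X0",
    log_transform = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    r <- regimes[k]
    roles <- if (kinds[k] == "BM") "sigma" else c("alpha", "theta", "sigma")
    layout <- rbind(layout, data.frame(
      name = paste0(roles, "_", r), regime = r, role = roles,
      log_transform = roles %in% c("alpha", "sigma"),
      stringsAsFactors = FALSE))
  }

  fixed <- unlist(fixed)
  if (length(fixed)) {
    if (!all(names(fixed) %in% layout$name))
      stop("unknown fixed parameter: ",
           setdiff(names(fixed), layout$name)[1L])
  }
  free <- !(layout$name %in% names(fixed))

  if (is.character(priors)) {
    pf <- prior_preset(priors)
    pl <- lapply(layout$role[free], pf)
    names(pl) <- layout$name[free]
    priors <- pl
  } else {
    miss <- setdiff(layout$name[free], names(priors))
    if (length(miss)) stop("missing prior for parameter: ", miss[1L])
    priors <- priors[layout$name[free]]
  }

  structure(list(tree = tree, painting = painting, regimes = regimes, K = K,
                 kinds = kinds, layout = layout, free = free, fixed = fixed,
                 priors = priors, plan = tree_plan(tree, painting),
                 t_H = tree_height(tree)),
            class = "mgpm")
}

#' @export
print.mgpm <- function(x, ...) {
  cat(sprintf("Mixed Gaussian phylogenetic model: %d tips, %d regime(s), d = %d (%d free)\n",
              ape::Ntip(x$tree), x$K, nrow(x$layout), sum(x$free)))
  for (k in seq_len(x$K)) {
    cat(sprintf("  %-12s %s  (%d edges)\n", x$regimes[k], x$kinds[k],
                sum(x$plan$regime == k, na.rm = TRUE)))
  }
  for (i in seq_len(nrow(x$layout))) {
    nm <- x$layout$name[i]
    if (x$free[i]) {
      cat(sprintf("  %-16s ~ %s\n", nm, format_prior(x$priors[[nm]])))
    } else {
      cat(sprintf("  %-16s = %.4g (fixed)\n", nm, x$fixed[[nm]]))
    }
  }
  invisible(x)
}

#' Parameter packing and transforms
#'
#' `param_names()` gives the flat parameter order `(X0, ...)`;
#' `n_params()` its length (the model dimension used for complexity
#' penalties). `to_unbounded()` maps free parameters to the real line
#' (`log` on `alpha` and `sigma`, identity elsewhere); `from_unbounded()`
#' inverts it; `log_jacobian()` is the log-Jacobian of the inverse map,
#' i.e. the sum of `z` over log-transformed coordinates.
#'
#' @param model an `mgpm`.
#' @param free if `TRUE`, restrict to free (non-fixed) parameters.
#' @param theta named (or layout-ordered) numeric vector of free parameters.
#' @param z unbounded vector.
#' @return Names, dimensions, or transformed vectors.
#' @export
param_names <- function(model, free = FALSE) {
  if (free) model$layout$name[model$free] else model$layout$name
}

#' @rdname param_names
#' @export
n_params <- function(model, free = FALSE) {
  if (free) sum(model$free) else nrow(model$layout)
}

#' @rdname param_names
#' @export
to_unbounded <- function(model, theta) {
  ls <- model$layout$log_transform[model$free]
  theta <- as.numeric(theta)
  if (length(theta) != sum(model$free)) stop("parameter length mismatch")
  if (any(theta[ls] <= 0)) stop("non-positive value in a log-transformed slot")
  z <- theta
  z[ls] <- log(theta[ls])
  stats::setNames(z, param_names(model, free = TRUE))
}

#' @rdname param_names
#' @export
from_unbounded <- function(model, z) {
  ls <- model$layout$log_transform[model$free]
  if (length(z) != sum(model$free)) stop("parameter length mismatch")
  th <- as.numeric(z)
  th[ls] <- exp(th[ls])
  stats::setNames(th, param_names(model, free = TRUE))
}

#' @rdname param_names
#' @export
log_jacobian <- function(model, z) {
  sum(z[model$layout$log_transform[model$free]])
}

# assemble the full named parameter list from a free vector
full_params <- function(model, theta_free) {
  full <- stats::setNames(numeric(nrow(model$layout)), model$layout$name)
  full[param_names(model, free = TRUE)] <- theta_free
  if (length(model$fixed)) full[names(model$fixed)] <- model$fixed
  as.list(full)
}

# coerce a user-supplied full parameter spec (named vector/list) to the layout
as_full_params <- function(model, params) {
  params <- unlist(params)
  nm <- model$layout$name
  if (is.null(names(params))) {
    if (length(params) != length(nm)) stop("parameter length mismatch")
    names(params) <- nm
  }
  miss <- setdiff(nm, c(names(params), names(model$fixed)))
  if (length(miss)) stop("missing parameter: ", miss[1L])
  full <- stats::setNames(numeric(length(nm)), nm)
  if (length(model$fixed)) full[names(model$fixed)] <- model$fixed
  full[intersect(names(params), nm)] <- params[intersect(names(params), nm)]
  as.list(full)
}

# joint log prior (+ Jacobian) of the free parameters at unbounded z
model_log_prior <- function(model, z) {
  log_prior_z(model$priors, model$layout$log_transform[model$free], z)
}

# draw n starting points from the transformed prior (rows = draws)
sample_prior_z <- function(model, n) {
  ls <- model$layout$log_transform[model$free]
  d <- sum(model$free)
  z <- matrix(0, n, d)
  for (j in seq_len(d)) {
    x <- prior_sample(model$priors[[j]], n)
    z[, j] <- if (ls[j]) log(x) else x
  }
  colnames(z) <- param_names(model, free = TRUE)
  z
}
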