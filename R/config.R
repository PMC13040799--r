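#' Serialize and restore a model configuration
#'
#' A model configuration captures everything except the tree and the data:
#' the regime painting (as an explicit child-node/tip-label -> regime map),
#' the per-regime process kinds, the per-parameter priors, fixed parameter
#' values, and optionally a full "true" parameter vector for simulation.
#' Stored as JSON so that study presets and command-line runs round-trip
#' exactly.
#'
#' @param model an [mgpm()].
#' @param path output file; `NULL` returns the JSON string.
#' @param params optional named parameter vector to embed.
#' @return `write_model_config()`: the path or JSON string invisibly;
#'   `read_model_config()`: an `mgpm` (with `$params` attached when present).
#' @export
write_model_config <- function(model, path = NULL, params = NULL) {
  n <- ape::Ntip(model$tree)
  ids <- which(!is.na(model$painting))
  key <- ifelse(ids <= n, model$tree$tip.label[ids], as.character(ids))
  cfg <- list(
    edges = stats::setNames(as.list(as.character(model$painting[ids])), key),
    regimes = model$regimes,
    kinds = as.list(model$kinds),
    priors = lapply(model$priors, unclass),
    fixed = as.list(model$fixed))
  if (!is.null(params)) cfg$params <- as.list(params)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_model_config
#' @param json JSON string or file path.
#' @param tree the `phylo` object the configuration refers to.
#' @export
read_model_config <- function(json, tree) {
  cfg <- if (file.exists(json)) jsonlite::fromJSON(json, simplifyVector = FALSE)
         else jsonlite::fromJSON(json, simplifyVector = FALSE)
  edges <- unlist(cfg$edges)
  painting <- paint_regimes(tree, edges = edges, default = NULL)
  # restore declared regime order
  lev <- unlist(cfg$regimes)
  pa <- factor(as.character(painting), levels = lev)
  painting <- structure(pa, K = length(lev), regimes = lev,
                        class = c("mgpm_painting", "factor"))
  priors <- lapply(cfg$priors, function(p) {
    if (p$family == "normal") prior_normal(p$mean, p$sd)
    else prior_halfnormal(p$scale)
  })
  m <- mgpm(tree, painting, kinds = unlist(cfg$kinds), priors = priors,
            fixed = unlist(cfg$fixed))
  if (!is.null(cfg$params)) m$params <- unlist(cfg$params)
  m
}

#' Read a two-column trait table
#'
#' @param path CSV with columns `tip` (label) and `value`.
#' @return Named numeric vector.
#' @export
read_trait_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("trait CSV needs two columns: tip, value")
  stats::setNames(as.numeric(d[[2]]), as.character(d[[1]]))
}

#' @rdname read_trait_csv
#' @param x named numeric vector of tip values.
#' @export
write_trait_csv <- function(x, path) {
  utils::write.csv(data.frame(tip = names(x), value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}
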