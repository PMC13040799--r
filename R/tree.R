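#' Read a rooted phylogenetic tree from Newick text or a file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be rooted,
#' carry a branch length on every non-root edge, and have unique tip labels.
#' Node numbering follows the `ape` convention: tips `1..n`, root `n + 1`.
#'
#' @param text Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @param file path to a Newick file (used when `text` is `NULL`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr) # 2
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("Newick parse failure")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("every non-root edge must carry a branch length")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 15) {
  ape::write.tree(tree, digits = digits)
}

#' Root-to-node depths and tree height
#'
#' `node_depths()` returns the time from the root to every node;
#' `tree_height()` returns the maximum root-to-tip depth `t_H`.
#'
#' @param tree a `phylo` object.
#' @return Numeric vector of depths (length tips + internal nodes), or a scalar.
#' @export
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  d <- numeric(n_node)
  # parent rows precede child rows in cladewise order from the root
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pr$edge))) {
    d[pr$edge[e, 2L]] <- d[pr$edge[e, 1L]] + pr$edge.length[e]
  }
  d
}

#' @rdname node_depths
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Validate that a tree is ultrametric
#'
#' Checks that every root-to-tip path length equals the tree height `t_H`
#' within a relative tolerance, and that all edge lengths are non-negative.
#'
#' @param tree a `phylo` object.
#' @param rel_tol maximum allowed deviation of any tip depth from `t_H`,
#'   relative to `t_H`. Default `1e-6` tolerates the rounding noise commonly
#'   present in published chronograms.
#' @return Invisibly `TRUE`; signals an error naming the offending tip
#'   otherwise.
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-6) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n <- ape::Ntip(tree)
  depths <- node_depths(tree)[seq_len(n)]
  tH <- max(depths)
  dev <- abs(depths - tH)
  if (tH > 0 && any(dev > rel_tol * tH)) {
    i <- which.max(dev)
    stop(sprintf("tree is not ultrametric: tip '%s' has depth %.10g but height is %.10g",
                 tree$tip.label[i], depths[i], tH))
  }
  invisible(TRUE)
}

#' Generate a random ultrametric fixture tree
#'
#' Simulates a pure-birth (Yule) tree with [ape::rphylo()] and rescales it to
#' unit height. Deterministic for a fixed seed; ultrametric by construction.
#'
#' @param n_tips number of tips (>= 1).
#' @param seed integer RNG seed.
#' @return A `phylo` object of height 1.
#' @examples
#' tr <- random_ultrametric_tree(50, seed = 7)
#' validate_ultrametric(tr, rel_tol = 1e-9)
#' @export
random_ultrametric_tree <- function(n_tips, seed = 1) {
  if (n_tips < 1) stop("n_tips must be >= 1")
  if (n_tips == 1L) return(read_newick("(t1:1);"))
  tr <- local_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$edge.length <- tr$edge.length / tree_height(tr)
  tr
}

# run expr under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# all edges (identified by child node) in the clade rooted at `node`,
# including the stem edge of `node` itself
clade_edge_children <- function(tree, node) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  root <- ape::Ntip(tree) + 1L
  setdiff(out, root)
}

resolve_node <- function(tree, ref) {
  n <- ape::Ntip(tree)
  if (is.character(ref)) {
    if (length(ref) == 1L) {
      i <- match(ref, tree$tip.label)
      if (is.na(i)) stop("unknown tip label: ", ref)
      return(i)
    }
    i <- match(ref, tree$tip.label)
    if (anyNA(i)) stop("unknown tip label: ", ref[which(is.na(i))[1L]])
    return(ape::getMRCA(tree, i))
  }
  ref <- as.integer(ref)
  if (length(ref) > 1L) return(ape::getMRCA(tree, ref))
  if (ref < 1L || ref > n + tree$Nnode) stop("unknown node: ", ref)
  ref
}

#' Paint evolutionary regimes onto a tree
#'
#' Assigns every edge of the tree to exactly one regime. A regime painting can
#' be given either as clade declarations over a default (ancestral) regime, or
#' as an explicit edge table. Edges are identified by their child node; the
#' root owns no edge and carries no regime. A clade declaration paints the
#' whole subtree below (and including the stem edge of) its crown node;
#' declarations are applied in order, later ones overriding earlier ones on
#' overlapping edges. Two clades may share a regime name, producing a
#' disconnected regime.
#'
#' @param tree a `phylo` object.
#' @param clades named list: regime name -> crown node, given as a node
#'   number, a tip label, or a character/integer vector of tips whose MRCA is
#'   the crown. Repeated names are allowed (disconnected regimes).
#' @param default name of the regime covering all undeclared edges. Set to
#'   `NULL` to require the declarations to cover the tree.
#' @param edges alternative explicit spec: vector of regime names, named by
#'   child node number or tip label, one entry per edge.
#' @return An object of class `mgpm_painting`: a factor of length
#'   tips + internal nodes giving each node's stem-edge regime (`NA` at the
#'   root), with attributes `K` and `regimes`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' p <- paint_regimes(tr, clades = list(R1 = c("A", "B")))
#' table(p, useNA = "ifany")
#' @export
paint_regimes <- function(tree, clades = list(), default = "Ancestral",
                          edges = NULL) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  lab <- rep(NA_character_, n_node)
  if (!is.null(edges)) {
    nm <- names(edges)
    if (is.null(nm)) stop("explicit edge spec must be named by child node or tip label")
    idx <- suppressWarnings(as.integer(nm))
    idx[is.na(idx)] <- match(nm[is.na(idx)], tree$tip.label)
    if (anyNA(idx)) stop("unknown node/tip reference in edge spec")
    lab[idx] <- as.character(edges)
  } else {
    if (!is.null(default)) lab[-root] <- default
    for (i in seq_along(clades)) {
      nm <- names(clades)[i]
      if (is.null(nm) || !nzchar(nm)) stop("clade declarations must be named by regime")
      node <- resolve_node(tree, clades[[i]])
      lab[clade_edge_children(tree, node)] <- nm
    }
  }
  non_root <- setdiff(seq_len(n_node), root)
  if (anyNA(lab[non_root])) {
    stop("uncovered edge (child node ", non_root[is.na(lab[non_root])][1L],
         ") and no default regime given")
  }
  levels <- unique(c(if (!is.null(default) && is.null(edges)) default,
                     lab[non_root]))
  out <- factor(lab, levels = levels)
  structure(out, K = length(levels), regimes = levels,
            class = c("mgpm_painting", "factor"))
}

#' @export
print.mgpm_painting <- function(x, ...) {
  cat("Regime painting:", attr(x, "K"), "regime(s)\n")
  print(table(edges = as.character(x)))
  invisible(x)
}

#' Draw a random clade-based regime painting
#'
#' Picks `K - 1` disjoint clades (by seeded random choice among internal nodes
#' whose clade size lies within a tip-fraction window) and paints them as
#' regimes `R1, R2, ...` over an ancestral background. Used by the simulation
#' study harnesses to stand in for a hand-chosen regime configuration.
#'
#' @param tree a `phylo` object.
#' @param K total number of regimes (>= 1).
#' @param seed integer RNG seed.
#' @param frac two-element vector: admissible clade size as a fraction of the
#'   tip count.
#' @return An `mgpm_painting`.
#' @export
random_painting <- function(tree, K = 2, seed = 1, frac = c(0.15, 0.45)) {
  if (K == 1L) return(paint_regimes(tree, default = "Ancestral"))
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  root <- n + 1L
  sizes <- vapply(seq.int(root + 1L, n_node), function(v)
    sum(clade_edge_children(tree, v) <= n), integer(1))
  cand <- seq.int(root + 1L, n_node)[sizes >= frac[1] * n & sizes <= frac[2] * n]
  all_internal <- seq.int(root + 1L, n_node)
  local_seed(seed, {
    chosen <- integer(0)
    taken <- integer(0)
    for (k in seq_len(K - 1L)) {
      free_of <- function(set) set[!set %in% taken &
        vapply(set, function(v) !any(clade_edge_children(tree, v) %in% taken) &&
                 !any(chosen %in% clade_edge_children(tree, v)), logical(1))]
      ok <- free_of(cand)
      # small trees may not fit K clades inside the size window; fall back to
      # any remaining disjoint clade with at least two tips
      if (!length(ok)) ok <- free_of(all_internal)
      if (!length(ok)) stop("cannot place ", K - 1L, " disjoint clades on this tree")
      v <- ok[sample.int(length(ok), 1L)]
      chosen <- c(chosen, v)
      taken <- c(taken, v, clade_edge_children(tree, v))
    }
    cl <- as.list(chosen)
    names(cl) <- paste0("R", seq_along(cl))
    paint_regimes(tree, clades = cl, default = "Ancestral")
  })
}

# topology plan reused by likelihood / simulation: postorder edge arrays
tree_plan <- function(tree, painting) {
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(po$edge[, 2L], tree$edge[, 2L]) # edge rows, postorder
  list(n = n, n_node = n_node, root = n + 1L,
       pa = po$edge[, 1L], ch = po$edge[, 2L],
       len = po$edge.length,
       regime = as.integer(unclass(painting))[po$edge[, 2L]],
       is_tip = seq_len(n_node) <= n,
       tip_labels = tree$tip.label)
}
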