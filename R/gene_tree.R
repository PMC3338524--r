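## Per-group gene trees: BIONJ construction, midpoint rooting, and
## enumeration of testable internal nodes.

#' Build an unrooted BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbour joining (BIONJ) as implemented in
#' \pkg{ape}; negative branch-length estimates are clamped to zero.
#'
#' @param distances a `dist` object or symmetric numeric matrix with
#'   at least three taxa and finite entries.
#' @return an unrooted `phylo` tree.
#' @export
build_bionj <- function(distances) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) stop("BIONJ needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  tr <- ape::bionj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.  If
#' the tree has zero diameter (all branch lengths zero) the root is
#' placed, deterministically, on the edge leading to the alphabetically
#' first tip.
#'
#' @param tree a `phylo` tree (rooted input is re-rooted; the operation is
#'   idempotent on the rooted topology).
#' @return a rooted, binary `phylo` tree in cladewise order.
#' @export
root_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) stop("need at least 3 taxa to root")
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) {
    rt <- ape::root(tree, outgroup = sort(tree$tip.label)[1L],
                    resolve.root = TRUE)
  } else {
    rt <- phangorn::midpoint(tree)
  }
  if (!ape::is.binary(rt)) rt <- ape::multi2di(rt)
  stats::reorder(rt, "cladewise")
}

#' Enumerate testable internal nodes of a rooted gene tree
#'
#' Every internal node splits the leaves into the two clades descending
#' from its children plus the outgroup of all remaining leaves.  A node is
#' testable when both clades contain at least `min_clade` sequences and
#' the outgroup is non-empty; in particular the root itself is never
#' testable because its outgroup is empty.
#'
#' @param tree a rooted binary `phylo` tree.
#' @param min_clade minimum sequences per descendant clade (default 4).
#' @param min_outgroup minimum outgroup size (default 1).
#' @return a list of `node_partition` objects in preorder; each has
#'   `node_id`, `clade_a`, `clade_b`, `outgroup` (tip-label character
#'   vectors).
#' @export
enumerate_testable_nodes <- function(tree, min_clade = 4, min_outgroup = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, type = "tips")
  internal <- unique(tree$edge[, 1L])   # preorder in cladewise edge order
  out <- list()
  for (v in internal) {
    children <- tree$edge[tree$edge[, 1L] == v, 2L]
    if (length(children) != 2L) next
    a <- desc[[children[1L]]]
    b <- desc[[children[2L]]]
    o <- setdiff(seq_len(ntip), c(a, b))
    if (length(a) >= min_clade && length(b) >= min_clade &&
        length(o) >= min_outgroup) {
      out[[length(out) + 1L]] <- structure(
        list(node_id = v,
             clade_a = tree$tip.label[sort(a)],
             clade_b = tree$tip.label[sort(b)],
             outgroup = tree$tip.label[sort(o)]),
        class = "node_partition")
    }
  }
  out
}

#' @export
print.node_partition <- function(x, ...) {
  cat("node", x$node_id, ": clades", length(x$clade_a), "+",
      length(x$clade_b), "vs outgroup", length(x$outgroup), "\n")
  invisible(x)
}

#' Build the rooted gene tree for an alignment group
#'
#' Convenience pipeline: maximum-likelihood pairwise distances under
#' JTT + gamma, BIONJ agglomeration, and midpoint rooting.
#'
#' @param group an [alignment_group()].
#' @param model a [rate_model()].
#' @param d_max saturation cap for pairwise distances.
#' @return a rooted binary `phylo` tree whose tips are the group's
#'   sequence ids.
#' @export
gene_tree <- function(group, model = rate_model(), d_max = 10) {
  stopifnot(inherits(group, "alignment_group"))
  root_tree(build_bionj(pairwise_distances(group, model, d_max)))
}
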