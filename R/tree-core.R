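#' Read a rooted, strictly bifurcating phylogeny from Newick
#'
#' Parses a Newick string or file and validates the tree for use with the
#' M statistic: the tree must be rooted, strictly bifurcating (every internal
#' node has exactly two children), and have at least three uniquely labelled
#' tips. Branch lengths are optional — the M statistic never reads them —
#' but when present they must be non-negative.
#'
#' @param x a Newick string, or the path to a file containing one tree.
#' @param bifurcate if `TRUE`, polytomies are resolved into a random
#'   bifurcation with zero-length branches (via [ape::multi2di()]) instead of
#'   raising an error. This departs from the method's stated restriction to
#'   dichotomous trees and is off by default.
#' @return an object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @seealso [decompose_subtrees()], [m_stat()]
#' @export
read_newick <- function(x, bifurcate = FALSE) {
  if (length(x) != 1L || !is.character(x)) {
    stop("`x` must be a single Newick string or file path", call. = FALSE)
  }
  tr <- if (file.exists(x) && !grepl(";", x, fixed = TRUE)) {
    tryCatch(ape::read.tree(file = x), error = function(e) {
      stop("failed to parse Newick file '", x, "': ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    tryCatch(ape::read.tree(text = x), error = function(e) {
      stop("failed to parse Newick: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(tr)) stop("failed to parse Newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (bifurcate && !ape::is.binary(tr)) {
    tr <- ape::multi2di(tr, random = TRUE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  validate_phylogeny(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree a `"phylo"` object.
#' @param path output file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

#' Validate a phylogeny for the M statistic
#'
#' Checks the invariants required by the subtree decomposition: rooted,
#' strictly bifurcating, >= 3 tips, unique non-empty tip labels, and
#' non-negative branch lengths when present. Polytomies (including the basal
#' trifurcation of an unrooted tree) are a hard error naming the offending
#' node.
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 3L) stop("tree has fewer than 3 tips (", n, ")", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label", call. = FALSE)
  ## child counts per internal node; exactly 2 everywhere <=> binary rooted
  deg <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  bad <- which(deg > 2L)
  if (length(bad)) {
    stop("polytomy at internal node ", bad[1L], " (", deg[bad[1L]],
         " children); the M statistic requires a strictly bifurcating",
         " rooted tree", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length", call. = FALSE)
  }
  invisible(tree)
}

#' Decompose a phylogeny into scored subtrees
#'
#' Every internal node with at least three descendant tips roots a subtree;
#' its two child branches partition the subtree's tips into the "first" and
#' "second" branch sets (ordered as in the input Newick — the M statistic is
#' insensitive to this order because both branches are weighted equally).
#' Internal nodes with exactly two tips (cherries) are excluded.
#'
#' @param tree a valid `"phylo"` object.
#' @return a list of class `"subtree_partition"`; each element has
#'   `node` (internal node id), `first` and `second` (character vectors of
#'   tip labels). The decomposition depends only on the topology, never on
#'   branch lengths.
#' @examples
#' decompose_subtrees(read_newick("(((A,B),C),D);"))
#' @export
decompose_subtrees <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  kids <- children_map(tree)
  sz <- clade_sizes(tree)
  nodes <- which(sz >= 3L)
  nodes <- nodes[nodes > n] # internal only
  nodes <- sort(nodes)
  tipsets <- clade_tip_sets(tree)
  out <- lapply(nodes, function(v) {
    ch <- kids[[v]]
    list(node = v,
         first = tree$tip.label[tipsets[[ch[1L]]]],
         second = tree$tip.label[tipsets[[ch[2L]]]])
  })
  structure(out, class = "subtree_partition", n_tips = n)
}

#' @export
print.subtree_partition <- function(x, ...) {
  cat("Subtree partition:", length(x), "subtree(s) on",
      attr(x, "n_tips"), "tips\n")
  for (e in x) {
    cat(sprintf("  node %d: {%s} | {%s}\n", e$node,
                paste(e$first, collapse = ","),
                paste(e$second, collapse = ",")))
  }
  invisible(x)
}

#' Map every unordered tip pair to its most recent common ancestor
#'
#' The cross pairs of the subtree rooted at node v are exactly the pairs
#' whose MRCA is v, so binning pair distances by MRCA lets all subtree means
#' be evaluated in one O(n^2) pass per permutation.
#'
#' @param tree a valid `"phylo"` object.
#' @return a data.frame with columns `i`, `j` (tip indices, i < j) and
#'   `mrca` (internal node id), one row per unordered tip pair.
#' @export
pair_mrca_index <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  M <- ape::mrca(tree)
  ut <- upper.tri(M)
  ij <- which(ut, arr.ind = TRUE)
  data.frame(i = ij[, 1L], j = ij[, 2L], mrca = M[ut])
}

## ---- internal topology helpers ------------------------------------------

## children of each node, indexed by node id (NULL for tips)
children_map <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  ed <- matrix(as.integer(tree$edge), ncol = 2L)
  for (e in seq_len(nrow(ed))) {
    p <- ed[e, 1L]
    kids[[p]] <- c(kids[[p]], ed[e, 2L])
  }
  kids
}

## number of descendant tips per node (tips count 1)
clade_sizes <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sz <- c(rep(1L, n), rep(0L, tree$Nnode))
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ed))) {
    sz[ed[e, 1L]] <- sz[ed[e, 1L]] + sz[ed[e, 2L]]
  }
  sz
}

## descendant tip index sets per node
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ed))) {
    p <- ed[e, 1L]
    sets[[p]] <- c(sets[[p]], sets[[ed[e, 2L]]])
  }
  sets
}

## root node id (ape convention: n_tips + 1, but derive defensively)
root_node <- function(tree) {
  setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
}

#' Is a tree ultrametric?
#'
#' Thin wrapper over [ape::is.ultrametric()] with an absolute tolerance on
#' root-to-tip depth differences.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param tol absolute tolerance.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  ape::is.ultrametric(tree, tol = tol, option = 2)
}
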