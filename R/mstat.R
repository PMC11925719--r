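#' Score one subtree for the monotonicity constraint
#'
#' A subtree (an internal node with >= 3 descendant tips) satisfies the
#' monotonicity constraint on a branch when the mean pairwise trait distance
#' within that branch does not exceed the mean trait distance across the two
#' branches. Each of the two branches contributes 1/2 when its constraint
#' holds (ties count as holding); a single-tip branch has within-branch
#' distance 0 and therefore always holds.
#'
#' @param first,second character vectors of tip labels for the two branches;
#'   disjoint, jointly >= 3 tips.
#' @param D a species-pairwise trait distance matrix with dimnames.
#' @return a list with `d_first`, `d_second`, `d_cross` (mean distances) and
#'   `m` (score in \{0, 0.5, 1\}).
#' @export
subtree_score <- function(first, second, D) {
  D <- as_distance_matrix(D)
  if (length(intersect(first, second))) {
    stop("branch tip sets overlap", call. = FALSE)
  }
  if (length(first) + length(second) < 3L) {
    stop("subtree needs >= 3 tips", call. = FALSE)
  }
  missing <- setdiff(c(first, second), rownames(D))
  if (length(missing)) {
    stop("tips absent from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  within_mean <- function(tips) {
    if (length(tips) < 2L) return(0)
    sub <- D[tips, tips, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  d1 <- within_mean(first)
  d2 <- within_mean(second)
  dc <- mean(D[first, second, drop = FALSE])
  list(d_first = d1, d_second = d2, d_cross = dc,
       m = 0.5 * (d1 <= dc) + 0.5 * (d2 <= dc))
}

#' The M statistic
#'
#' Measures phylogenetic signal as the mean, over all subtrees rooted at
#' internal nodes with at least three descendant tips, of the subtree score
#' ([subtree_score()]). M lies in [0, 1]; larger values mean that species
#' close on the tree also carry similar trait values. Only the topology is
#' used — branch lengths never enter the computation.
#'
#' @param tree a valid `"phylo"` object.
#' @param D species-pairwise trait distance matrix (e.g. from
#'   [gower_distance()]); its labels must cover the tree's tips.
#' @param method `"fast"` bins pair distances by most-recent-common-ancestor
#'   node and evaluates all subtree means in one O(n^2) pass; `"naive"`
#'   enumerates each subtree explicitly. Both give identical results; the
#'   naive path exists as a readable reference.
#' @return the M statistic, a number in [0, 1].
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' D <- matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' m_stat(tr, D)
#' @export
m_stat <- function(tree, D, method = c("fast", "naive")) {
  method <- match.arg(method)
  D <- as_distance_matrix(D)
  missing <- setdiff(tree$tip.label, rownames(D))
  if (length(missing)) {
    stop("tips without trait distances: ", paste(missing, collapse = ", "),
         "; prune the tree or complete the trait table", call. = FALSE)
  }
  if (method == "naive") {
    part <- decompose_subtrees(tree)
    return(mean(vapply(part, function(e) {
      subtree_score(e$first, e$second, D)$m
    }, numeric(1))))
  }
  idx <- m_index(tree)
  Dt <- D[tree$tip.label, tree$tip.label]
  m_eval(idx, Dt[cbind(idx$pi, idx$pj)])
}

## ---- fast evaluation machinery ------------------------------------------
## Cross pairs of the subtree rooted at v are exactly the tip pairs whose
## MRCA is v, so per-node cross sums come from one rowsum() over all pairs,
## and within-clade sums follow by accumulating cross sums over descendant
## internal nodes. One index object per tree serves every permutation.

m_index <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  nint <- tree$Nnode
  pairs <- pair_mrca_index(tree)
  mrca_int <- pairs$mrca - n # internal index 1..nint
  sz <- clade_sizes(tree)
  kids <- children_map(tree)

  ## ancestor indicator: A[v, u] = 1 if internal node u lies in clade(v)
  par <- integer(n + nint)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  A <- matrix(0, nint, nint)
  for (u in seq_len(nint)) {
    v <- u + n
    repeat {
      A[v - n, u] <- 1
      if (v == root_node(tree)) break
      v <- par[v]
    }
  }

  q <- which(sz[(n + 1L):(n + nint)] >= 3L) # qualifying internal indices
  c1 <- vapply(q, function(u) kids[[u + n]][1L], integer(1))
  c2 <- vapply(q, function(u) kids[[u + n]][2L], integer(1))
  n1 <- sz[c1]; n2 <- sz[c2]
  list(n = n, nint = nint, pi = pairs$i, pj = pairs$j,
       mrca_int = mrca_int, A = A, q = q,
       c1_int = ifelse(c1 > n, c1 - n, NA_integer_),
       c2_int = ifelse(c2 > n, c2 - n, NA_integer_),
       w1 = choose(n1, 2), w2 = choose(n2, 2), wc = n1 * n2)
}

## dvec: pair distances ordered as (idx$pi, idx$pj)
m_eval <- function(idx, dvec) {
  cross <- numeric(idx$nint)
  cs <- rowsum(dvec, idx$mrca_int)
  cross[as.integer(rownames(cs))] <- cs
  S <- drop(idx$A %*% cross) # within-clade pair-distance sums
  d1 <- ifelse(is.na(idx$c1_int), 0, S[idx$c1_int] / pmax(idx$w1, 1))
  d2 <- ifelse(is.na(idx$c2_int), 0, S[idx$c2_int] / pmax(idx$w2, 1))
  dc <- cross[idx$q] / idx$wc
  mean(0.5 * (d1 <= dc) + 0.5 * (d2 <= dc))
}

#' Permutation test for the M statistic
#'
#' Computes the observed M from the true species-to-tip assignment, then
#' builds a null distribution by repeatedly assigning whole trait rows to
#' tips uniformly at random (preserving trait-trait correlation) and
#' recomputing M against the fixed topology. The right-tailed p-value is
#' `(1 + #\{null M >= observed M\}) / (n_perm + 1)`.
#'
#' Permuting rows of the trait table is equivalent to jointly permuting the
#' rows and columns of the trait distance matrix, so the distance matrix is
#' computed once and only its indexing is shuffled.
#'
#' @param tree a valid `"phylo"` object.
#' @param traits a [trait_table()], or a precomputed species-pairwise
#'   distance matrix.
#' @param columns trait columns to use (trait tables only; default all).
#'   Multiple columns are combined with equal-weight Gower distance unless
#'   the table carries explicit weights.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @param alpha significance level (default 0.05).
#' @param prune if `TRUE`, species present in only one of tree/traits are
#'   dropped with a warning; otherwise a label mismatch is an error.
#' @param ordinal passed to [gower_distance()].
#' @return an object of class `"m_result"`: observed `M`, `null_M`
#'   (length `n_perm`), `p_value`, `significant`, plus test metadata.
#' @examples
#' tr <- read_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
#' tt <- trait_table(data.frame(x = c(1, 1.1, 2, 5, 5.2),
#'                              row.names = c("A", "B", "C", "D", "E")),
#'                   types = c(x = "continuous"))
#' m_test(tr, tt, n_perm = 99, seed = 1)
#' @export
m_test <- function(tree, traits, columns = NULL, n_perm = 999, seed = NULL,
                   alpha = 0.05, prune = FALSE,
                   ordinal = c("podani", "raw")) {
  stopifnot(n_perm >= 1)
  ordinal <- match.arg(ordinal)
  types_used <- NULL
  if (inherits(traits, "trait_table")) {
    if (is.null(columns)) columns <- names(traits$data)
    sp_tab <- rownames(traits$data)
    extra_tree <- setdiff(tree$tip.label, sp_tab)
    extra_tab <- setdiff(sp_tab, tree$tip.label)
    if (length(extra_tree) || length(extra_tab)) {
      if (!prune) {
        stop("species mismatch between tree and trait table (",
             length(extra_tree), " only in tree, ", length(extra_tab),
             " only in table); set prune = TRUE to analyse the intersection",
             call. = FALSE)
      }
      keep <- intersect(tree$tip.label, sp_tab)
      warning("pruned to ", length(keep), " shared species; dropped: ",
              paste(c(extra_tree, extra_tab), collapse = ", "),
              call. = FALSE)
      tree <- ape::keep.tip(tree, keep)
      traits$data <- traits$data[keep, , drop = FALSE]
    }
    types_used <- traits$types[columns]
    D <- gower_distance(traits, columns = columns, ordinal = ordinal)
  } else {
    D <- as_distance_matrix(traits)
    missing <- setdiff(tree$tip.label, rownames(D))
    if (length(missing)) {
      if (!prune) {
        stop("tips without trait distances: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      keep <- intersect(tree$tip.label, rownames(D))
      warning("pruned to ", length(keep), " shared species", call. = FALSE)
      tree <- ape::keep.tip(tree, keep)
    }
    if (is.null(columns)) columns <- "distance"
  }
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (!is.null(types_used)) {
    if (any(types_used == "continuous") && n < 25) {
      warning("only ", n, " tips: the test is underpowered for continuous ",
              "traits below ~25 tips", call. = FALSE)
    }
    if (any(types_used != "continuous") && n < 50) {
      warning("only ", n, " tips: the test is underpowered for discrete ",
              "traits below ~50 tips", call. = FALSE)
    }
  }
  Dt <- D[tree$tip.label, tree$tip.label]
  off <- Dt[upper.tri(Dt)]
  if (length(unique(off)) == 1L) {
    warning("all pairwise trait distances are identical (constant trait?); ",
            "M is permutation-invariant and p = 1", call. = FALSE)
  }
  idx <- m_index(tree)
  if (!is.null(seed)) set.seed(seed)
  lin <- (idx$pj - 1L) * n + idx$pi # linear indices into Dt
  M_obs <- m_eval(idx, Dt[lin])
  null_M <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    m_eval(idx, Dt[(perm[idx$pj] - 1L) * n + perm[idx$pi]])
  }, numeric(1))
  p <- (1 + sum(null_M >= M_obs)) / (n_perm + 1)
  structure(list(M = M_obs, null_M = null_M, p_value = p,
                 significant = p <= alpha, n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 alpha = alpha, n_subtrees = length(idx$q), n_species = n,
                 columns = columns),
            class = "m_result")
}

#' @export
print.m_result <- function(x, ...) {
  cat("M statistic permutation test\n")
  cat(sprintf("  traits:     %s\n", paste(x$columns, collapse = " + ")))
  cat(sprintf("  species:    %d   subtrees: %d\n", x$n_species, x$n_subtrees))
  cat(sprintf("  M observed: %.4f\n", x$M))
  cat(sprintf("  p-value:    %.4g  (%d permutations, alpha = %g)%s\n",
              x$p_value, x$n_perm, x$alpha,
              if (x$significant) "  *significant*" else ""))
  invisible(x)
}

#' Serialise an M test result
#'
#' @param x an `"m_result"`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`. The null distribution is omitted;
#'   all test metadata (including the seed) is kept for provenance.
#' @return `path`, invisibly.
#' @export
write_m_result <- function(x, path, format = c("json", "tsv")) {
  stopifnot(inherits(x, "m_result"))
  format <- match.arg(format)
  rec <- list(M = x$M, p_value = x$p_value, significant = x$significant,
              n_perm = x$n_perm, seed = x$seed, alpha = x$alpha,
              n_subtrees = x$n_subtrees, n_species = x$n_species,
              columns = paste(x$columns, collapse = "+"))
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(rec), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
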