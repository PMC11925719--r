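#' Simulate a pure-birth (Yule) tree
#'
#' Grows a tree from two lineages: with k extant lineages the waiting time to
#' the next split is Exponential(k * birth_rate) and the splitting lineage is
#' chosen uniformly. Growth stops when the lineage count reaches `n_tips`;
#' one final inter-event time is drawn (at rate `n_tips * birth_rate`) and
#' all tips are cut at that epoch, so the tree is exactly ultrametric. The
#' expected root-to-tip depth is `sum_{k=2..n_tips} 1 / (birth_rate * k)`.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per lineage per unit time (default 0.05).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return an ultrametric, strictly bifurcating `"phylo"` object with tips
#'   labelled `t1 ... tn`.
#' @examples
#' tr <- yule_tree(20, seed = 1)
#' is_ultrametric(tr)
#' @export
yule_tree <- function(n_tips, birth_rate = 0.05, seed = NULL) {
  stopifnot(n_tips >= 3, birth_rate > 0)
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)
  nn <- 2L * n_tips - 1L # total nodes
  left <- integer(nn); right <- integer(nn)
  born <- numeric(nn); blen <- numeric(nn)
  ## node 1 is the root, splitting at time 0 into nodes 2 and 3
  nxt <- 1L
  newnode <- function(t0) {
    nxt <<- nxt + 1L
    born[nxt] <<- t0
    nxt
  }
  born[1L] <- 0
  left[1L] <- newnode(0); right[1L] <- newnode(0)
  active <- c(left[1L], right[1L])
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * birth_rate)
    who <- active[sample.int(k, 1L)]
    blen[who] <- t - born[who]
    left[who] <- newnode(t); right[who] <- newnode(t)
    active <- c(active[active != who], left[who], right[who])
  }
  t_end <- t + stats::rexp(1L, rate = n_tips * birth_rate)
  blen[active] <- t_end - born[active]

  ## convert to an ape "phylo": tips 1..n, internals n+1.. in preorder
  is_tip <- left == 0L
  id <- integer(nn)
  tip_ct <- 0L; int_ct <- 0L
  edge <- matrix(0L, nn - 1L, 2L); elen <- numeric(nn - 1L); ne <- 0L
  stack <- 1L
  order_seen <- integer(0)
  ## iterative preorder assigning ids and emitting edges
  assign_id <- function(v) {
    if (is_tip[v]) { tip_ct <<- tip_ct + 1L; id[v] <<- tip_ct }
    else { int_ct <<- int_ct + 1L; id[v] <<- n_tips + int_ct }
  }
  assign_id(1L)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (is_tip[v]) next
    for (ch in c(left[v], right[v])) assign_id(ch)
    for (ch in c(left[v], right[v])) {
      ne <- ne + 1L
      edge[ne, ] <- c(id[v], id[ch]); elen[ne] <- blen[ch]
    }
    stack <- c(stack, right[v], left[v])
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = paste0("t", seq_len(n_tips)),
                       Nnode = n_tips - 1L),
                  class = "phylo", order = "cladewise")
  validate_phylogeny(tr)
  tr
}

#' Simulate a continuous trait by Brownian motion
#'
#' Recursively from the root: a child's value is its parent's value plus a
#' Normal(0, sigma^2 * branch_length) increment, i.e. `sigma` is the
#' standard deviation of the diffusion per unit square-root branch length.
#' Delegates to [ape::rTraitCont()].
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param sigma diffusion standard deviation per unit branch length
#'   (default 0.01).
#' @param root_value trait value at the root (default 0).
#' @param seed optional integer seed.
#' @return a named numeric vector, one value per tip.
#' @export
bm_trait <- function(tree, sigma = 0.01, root_value = 0, seed = NULL) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; Brownian motion needs them",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sigma, root.value = root_value)
}

#' Blend a Brownian trait with its own random shuffle
#'
#' Builds a continuous trait of prescribed phylogenetic signal intensity w:
#' `trait = w * trait_bm + (1 - w) * trait_rand`, where `trait_rand` is a
#' uniform random permutation of `trait_bm` across species. At w = 1 the
#' signal is unequivocal; at w = 0 the trait is pure noise with the same
#' marginal values.
#'
#' @param trait_bm named numeric vector (tip labels as names).
#' @param w signal intensity in [0, 1].
#' @param seed optional integer seed.
#' @return a named numeric vector aligned with `names(trait_bm)`.
#' @export
mix_continuous <- function(trait_bm, w, seed = NULL) {
  stopifnot(w >= 0, w <= 1)
  if (!is.null(seed)) set.seed(seed)
  rnd <- unname(trait_bm)[sample.int(length(trait_bm))]
  out <- w * unname(trait_bm) + (1 - w) * rnd
  names(out) <- names(trait_bm)
  out
}

#' Simulate a discrete trait under the equal-rates Mk model
#'
#' Continuous-time Markov evolution with the same transition rate between
#' every ordered pair of states; the root state is drawn uniformly.
#' Delegates to [ape::rTraitDisc()] with an equal-rates model, whose rate
#' matrix is scaled by the uniform stationary frequencies: the effective
#' off-diagonal rate is `rate / n_states`, so for two states the change
#' probability over a branch of length t is `(1 - exp(-rate * t)) / 2`.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param n_states number of states (>= 2); states are labelled
#'   `A, B, C, ...`.
#' @param rate equal change-rate parameter (default 0.01).
#' @param seed optional integer seed.
#' @return a named character vector, one state per tip.
#' @export
mk_trait <- function(tree, n_states, rate = 0.01, seed = NULL) {
  stopifnot(n_states >= 2)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; the Mk model needs them", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  root <- sample.int(n_states, 1L)
  x <- ape::rTraitDisc(tree, model = "ER", k = n_states, rate = rate,
                       root.value = root)
  stats::setNames(as.character(x), names(x))
}

#' Degrade the phylogenetic signal of a discrete trait
#'
#' A uniformly chosen subset of `round(w * n)` species keeps its simulated
#' state; the states of the remaining species are randomly permuted among
#' themselves (fixed points allowed). The multiset of states is preserved
#' for every w; w = 1 returns the input unchanged, w = 0 shuffles everything.
#'
#' @param trait_mk named character vector from [mk_trait()].
#' @param w proportion of species retaining their state, in [0, 1].
#' @param seed optional integer seed.
#' @return a named character vector aligned with `names(trait_mk)`.
#' @export
degrade_discrete <- function(trait_mk, w, seed = NULL) {
  stopifnot(w >= 0, w <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(trait_mk)
  n_keep <- round(w * n)
  keep <- if (n_keep > 0) sample.int(n, n_keep) else integer(0)
  rest <- setdiff(seq_len(n), keep)
  out <- trait_mk
  if (length(rest) > 1L) {
    out[rest] <- trait_mk[rest][sample.int(length(rest))]
  }
  out
}
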