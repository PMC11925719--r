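## shared fixtures, built in code

## random labelled distance matrix over the tips of a tree
rand_dist <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  D <- as.matrix(stats::dist(matrix(stats::runif(2 * n), n)))
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

## one-column continuous trait table from a named vector
tt_from_vec <- function(x, type = "continuous", name = "trait") {
  df <- data.frame(v = unname(x), row.names = names(x))
  names(df) <- name
  trait_table(df, types = stats::setNames(type, name))
}

## 4-species x 3-trait mixed fixture with hand-computed Gower distances
## traits: continuous x = 0,2,4,8 (range 8); nominal r,r,b,g;
## ordinal codes 1,2,2,3 -> midranks 1,2.5,2.5,4 (range 3)
mixed_fixture <- function() {
  trait_table(
    data.frame(size = c(0, 2, 4, 8),
               colour = c("red", "red", "blue", "green"),
               iucn = c(1, 2, 2, 3),
               row.names = c("s1", "s2", "s3", "s4")),
    types = c(size = "continuous", colour = "nominal", iucn = "ordinal"))
}

## expected Gower matrix for mixed_fixture(), equal weights, hand arithmetic
mixed_fixture_expected <- function() {
  ## per-pair means of (continuous, nominal, ordinal-midrank) dissimilarities
  d12 <- (2 / 8 + 0 + 1.5 / 3) / 3
  d13 <- (4 / 8 + 1 + 1.5 / 3) / 3
  d14 <- (8 / 8 + 1 + 3 / 3) / 3
  d23 <- (2 / 8 + 1 + 0) / 3
  d24 <- (6 / 8 + 1 + 1.5 / 3) / 3
  d34 <- (4 / 8 + 1 + 1.5 / 3) / 3
  E <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  E[1, 2] <- E[2, 1] <- d12; E[1, 3] <- E[3, 1] <- d13
  E[1, 4] <- E[4, 1] <- d14; E[2, 3] <- E[3, 2] <- d23
  E[2, 4] <- E[4, 2] <- d24; E[3, 4] <- E[4, 3] <- d34
  E
}
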