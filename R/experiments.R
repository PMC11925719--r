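## Power-analysis drivers: detection-rate curves over the signal intensity
## w for single traits, and detection-rate surfaces over (w1, w2) for
## two-trait combinations. Replicate-level seeds are derived
## deterministically from the master seed and the cell coordinates, so
## every cell is reproducible independently of execution order.

## integer hash chain; keeps values in [1, 2^31 - 2]
derive_seed <- function(master, ...) {
  s <- as.double(master %% 2147483647L)
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) * 1000003 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

power_cell <- function(sim_fun, n_replicates, n_perm, alpha, seeds) {
  hits <- vapply(seq_len(n_replicates), function(r) {
    res <- sim_fun(seeds[r])
    res$p_value <= alpha
  }, logical(1))
  mean(hits)
}

#' Detection-rate curve for a single continuous trait
#'
#' For each signal intensity w in `w_grid` and each replicate: simulate a
#' pure-birth tree, evolve a Brownian-motion trait along it, blend it with
#' its own shuffle at weight w ([mix_continuous()]), and run the M
#' permutation test. The detection rate is the fraction of replicates with
#' p <= alpha.
#'
#' @param n_tips tips per simulated tree.
#' @param w_grid signal intensities in [0, 1] (default 0, 0.1, ..., 1).
#' @param n_replicates replicates per cell (default 20).
#' @param n_perm permutations per test (default 199).
#' @param alpha significance level (default 0.05).
#' @param seed master seed; per-cell seeds are derived from it.
#' @param birth_rate,sigma simulation parameters (defaults 0.05 and 0.01).
#' @return a data.frame of class `"power_grid"`: one row per cell with the
#'   full effective configuration and `detection_rate`.
#' @export
power_curve_continuous <- function(n_tips, w_grid = seq(0, 1, by = 0.1),
                                   n_replicates = 20, n_perm = 199,
                                   alpha = 0.05, seed = 1,
                                   birth_rate = 0.05, sigma = 0.01) {
  stopifnot(all(w_grid >= 0 & w_grid <= 1))
  rate <- vapply(seq_along(w_grid), function(ci) {
    w <- w_grid[ci]
    seeds <- vapply(seq_len(n_replicates),
                    function(r) derive_seed(seed, 1L, round(w * 1000), r),
                    integer(1))
    power_cell(function(s) {
      set.seed(s)
      tr <- yule_tree(n_tips, birth_rate)
      x <- mix_continuous(bm_trait(tr, sigma = sigma), w)
      tt <- trait_table(data.frame(trait = unname(x), row.names = names(x)),
                        types = c(trait = "continuous"))
      suppressWarnings(m_test(tr, tt, n_perm = n_perm, alpha = alpha))
    }, n_replicates, n_perm, alpha, seeds)
  }, numeric(1))
  structure(data.frame(w = w_grid, n_tips = n_tips,
                       n_replicates = n_replicates, n_perm = n_perm,
                       alpha = alpha, seed = seed, detection_rate = rate),
            class = c("power_grid", "data.frame"))
}

#' Detection-rate curve for a single discrete trait
#'
#' As [power_curve_continuous()], but the trait evolves under the
#' equal-rates Mk model and the signal is degraded by shuffling the states
#' of a `(1 - w)` proportion of species ([degrade_discrete()]).
#'
#' @inheritParams power_curve_continuous
#' @param n_states number of Mk states (the study grid is 2, 3, 5, 10;
#'   other values are accepted as extrapolation).
#' @param mk_rate Mk transition rate (default 0.01).
#' @return a `"power_grid"` data.frame with an `n_states` column.
#' @export
power_curve_discrete <- function(n_tips, n_states,
                                 w_grid = seq(0, 1, by = 0.1),
                                 n_replicates = 20, n_perm = 199,
                                 alpha = 0.05, seed = 1,
                                 birth_rate = 0.05, mk_rate = 0.01) {
  stopifnot(all(w_grid >= 0 & w_grid <= 1))
  rate <- vapply(seq_along(w_grid), function(ci) {
    w <- w_grid[ci]
    seeds <- vapply(seq_len(n_replicates),
                    function(r) derive_seed(seed, 2L, n_states, round(w * 1000), r),
                    integer(1))
    power_cell(function(s) {
      set.seed(s)
      tr <- yule_tree(n_tips, birth_rate)
      x <- degrade_discrete(mk_trait(tr, n_states, rate = mk_rate), w)
      tt <- trait_table(data.frame(trait = unname(x), row.names = names(x)),
                        types = c(trait = "nominal"))
      suppressWarnings(m_test(tr, tt, n_perm = n_perm, alpha = alpha))
    }, n_replicates, n_perm, alpha, seeds)
  }, numeric(1))
  structure(data.frame(w = w_grid, n_tips = n_tips, n_states = n_states,
                       n_replicates = n_replicates, n_perm = n_perm,
                       alpha = alpha, seed = seed, detection_rate = rate),
            class = c("power_grid", "data.frame"))
}

#' Detection-rate surface for two-trait combinations
#'
#' Per cell (w1, w2): two traits are simulated independently on the same
#' tree at intensities w1 and w2, combined into a single equal-weight Gower
#' distance ([combine_columns()]), and tested jointly with the M statistic.
#'
#' @inheritParams power_curve_discrete
#' @param trait_kind `"continuous"` (Brownian motion + blend) or
#'   `"discrete"` (Mk + shuffle degradation).
#' @param w1_grid,w2_grid intensity grids for the two traits.
#' @param sigma Brownian-motion standard deviation (continuous kind).
#' @return a `"power_grid"` data.frame with one row per (w1, w2) cell.
#' @export
power_surface_pairs <- function(trait_kind = c("continuous", "discrete"),
                                n_tips, n_states = NULL,
                                w1_grid = seq(0, 1, by = 0.1),
                                w2_grid = seq(0, 1, by = 0.1),
                                n_replicates = 20, n_perm = 199,
                                alpha = 0.05, seed = 1,
                                birth_rate = 0.05, sigma = 0.01,
                                mk_rate = 0.01) {
  trait_kind <- match.arg(trait_kind)
  if (trait_kind == "discrete" && is.null(n_states)) {
    stop("n_states is required for discrete traits", call. = FALSE)
  }
  grid <- expand.grid(w1 = w1_grid, w2 = w2_grid)
  rate <- vapply(seq_len(nrow(grid)), function(ci) {
    w1 <- grid$w1[ci]; w2 <- grid$w2[ci]
    seeds <- vapply(seq_len(n_replicates),
                    function(r) derive_seed(seed, 3L, round(w1 * 1000),
                                            round(w2 * 1000), r),
                    integer(1))
    power_cell(function(s) {
      set.seed(s)
      tr <- yule_tree(n_tips, birth_rate)
      if (trait_kind == "continuous") {
        x1 <- mix_continuous(bm_trait(tr, sigma = sigma), w1)
        x2 <- mix_continuous(bm_trait(tr, sigma = sigma), w2)
        df <- data.frame(trait1 = unname(x1), trait2 = unname(x2),
                         row.names = names(x1))
        types <- c(trait1 = "continuous", trait2 = "continuous")
      } else {
        x1 <- degrade_discrete(mk_trait(tr, n_states, rate = mk_rate), w1)
        x2 <- degrade_discrete(mk_trait(tr, n_states, rate = mk_rate), w2)
        df <- data.frame(trait1 = unname(x1), trait2 = unname(x2),
                         row.names = names(x1))
        types <- c(trait1 = "nominal", trait2 = "nominal")
      }
      tt <- trait_table(df, types = types)
      D <- combine_columns(tt, c("trait1", "trait2"))
      suppressWarnings(m_test(tr, D, n_perm = n_perm, alpha = alpha))
    }, n_replicates, n_perm, alpha, seeds)
  }, numeric(1))
  out <- data.frame(w1 = grid$w1, w2 = grid$w2, n_tips = n_tips,
                    n_replicates = n_replicates, n_perm = n_perm,
                    alpha = alpha, seed = seed, detection_rate = rate)
  if (!is.null(n_states)) out$n_states <- n_states
  structure(out, class = c("power_grid", "data.frame"))
}

#' Write a power grid as tidy TSV
#'
#' @param grid a `"power_grid"` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_power_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
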