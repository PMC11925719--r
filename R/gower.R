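#' Construct a trait table
#'
#' A trait table couples a species-by-trait data frame with a declared
#' statistical type and weight per trait. Types drive how each trait enters
#' Gower's distance: `continuous` traits contribute range-normalised absolute
#' differences, `nominal` traits contribute 0/1 mismatch, and `ordinal`
#' traits are rank-transformed (midranks for ties) and then treated as
#' continuous.
#'
#' @param data a data.frame of trait values; rows are species. Species labels
#'   are taken from `species` if given, else from `rownames(data)`.
#' @param types named character vector mapping every trait column to one of
#'   `"continuous"`, `"nominal"`, `"ordinal"`.
#' @param weights named numeric vector of positive per-trait weights;
#'   defaults to 1 for every trait. Unequal weights change the M statistic
#'   and should be used deliberately.
#' @param species optional character vector of species labels, same length
#'   as `nrow(data)`.
#' @return an object of class `"trait_table"`.
#' @examples
#' tt <- trait_table(
#'   data.frame(mass = c(1, 2, 8), colour = c("red", "red", "blue"),
#'              row.names = c("A", "B", "C")),
#'   types = c(mass = "continuous", colour = "nominal"))
#' @export
trait_table <- function(data, types, weights = NULL, species = NULL) {
  data <- as.data.frame(data)
  if (!is.null(species)) {
    if (length(species) != nrow(data)) {
      stop("`species` length must match nrow(data)", call. = FALSE)
    }
    rownames(data) <- species
  }
  sp <- rownames(data)
  auto_rn <- .row_names_info(data) < 0L # 1..n placeholder, no real labels
  if (is.null(sp) || auto_rn || anyDuplicated(sp) || any(!nzchar(sp))) {
    stop("species labels must be present, unique and non-empty", call. = FALSE)
  }
  types <- unlist(types)
  miss <- setdiff(names(data), names(types))
  if (length(miss)) {
    stop("no declared type for trait(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  types <- types[names(data)]
  ok <- types %in% c("continuous", "nominal", "ordinal")
  if (!all(ok)) {
    stop("invalid trait type(s): ", paste(unique(types[!ok]), collapse = ", "),
         "; must be continuous, nominal or ordinal", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(data)), names(data))
  } else {
    weights <- unlist(weights)
    w <- stats::setNames(rep(1, ncol(data)), names(data))
    w[names(weights)] <- weights
    weights <- w
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("trait weights must be finite and >= 0", call. = FALSE)
  }
  for (cn in names(data)) {
    if (types[[cn]] == "continuous" && !is.numeric(data[[cn]])) {
      data[[cn]] <- suppressWarnings(as.numeric(as.character(data[[cn]])))
    }
    if (all(is.na(data[[cn]]))) {
      stop("trait '", cn, "' has no non-missing values", call. = FALSE)
    }
  }
  structure(list(data = data, types = types, weights = weights),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", nrow(x$data), "species x", ncol(x$data), "trait(s)\n")
  info <- data.frame(type = unname(x$types), weight = unname(x$weights),
                     missing = colSums(is.na(x$data)),
                     row.names = names(x$data))
  print(info)
  invisible(x)
}

#' Read a trait table from CSV/TSV with a sidecar type declaration
#'
#' The trait file has species labels in its first column. Types (and
#' optional weights) come from a small sidecar file with columns
#' `trait,type[,weight]`, one row per trait column. Empty cells and "NA"
#' are missing values.
#'
#' @param path trait CSV/TSV (delimiter sniffed from the extension: `.tsv`
#'   reads tab, anything else comma).
#' @param types_path sidecar declaration file, same delimiter rule.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, types_path) {
  sep <- function(p) if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep(path),
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("trait file needs a species column plus >= 1 trait",
                           call. = FALSE)
  decl <- utils::read.table(types_path, header = TRUE, sep = sep(types_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("trait", "type") %in% names(decl))) {
    stop("type declaration needs columns 'trait' and 'type'", call. = FALSE)
  }
  types <- stats::setNames(decl$type, decl$trait)
  weights <- if ("weight" %in% names(decl)) {
    stats::setNames(decl$weight, decl$trait)
  }
  df <- raw[, -1L, drop = FALSE]
  rownames(df) <- raw[[1L]]
  trait_table(df, types = types, weights = weights)
}

#' Gower's distance on a trait table
#'
#' Computes the species-pairwise Gower dissimilarity: the weighted mean,
#' over traits observed in both species, of per-trait dissimilarities.
#' Continuous traits contribute `|x_i - x_j| / range`, nominal traits 0/1
#' mismatch, and ordinal traits are converted to midranks and then
#' range-normalised (Podani's convention). All distances lie in [0, 1].
#'
#' Missing values are handled by pairwise deletion: the weights are
#' renormalised over the traits observed in both members of a pair. A pair
#' of species sharing no observed trait is an error. A continuous trait with
#' zero range contributes distance 0 for every pair, with a warning.
#'
#' @param table a [trait_table()].
#' @param columns traits to use (default: all).
#' @param ordinal how ordinal traits are encoded: `"podani"` (midranks,
#'   default) or `"raw"` (integer codes treated as continuous).
#' @return a symmetric numeric matrix with zero diagonal, species labels as
#'   dimnames, values in [0, 1].
#' @references Gower, J. C. (1971) A general coefficient of similarity and
#'   some of its properties. Biometrics 27, 857-871. Podani, J. (1999)
#'   Extending Gower's general coefficient of similarity to ordinal
#'   characters. Taxon 48, 331-340.
#' @export
gower_distance <- function(table, columns = NULL,
                           ordinal = c("podani", "raw")) {
  stopifnot(inherits(table, "trait_table"))
  ordinal <- match.arg(ordinal)
  if (is.null(columns)) columns <- names(table$data)
  unknown <- setdiff(columns, names(table$data))
  if (length(unknown)) {
    stop("unknown trait column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(columns)) stop("no trait columns selected", call. = FALSE)
  sp <- rownames(table$data)
  n <- length(sp)
  if (n < 2L) stop("need >= 2 species", call. = FALSE)

  num <- matrix(0, n, n) # weighted dissimilarity sum
  den <- matrix(0, n, n) # weight sum over jointly observed traits
  for (cn in columns) {
    w <- table$weights[[cn]]
    if (w == 0) next
    x <- table$data[[cn]]
    type <- table$types[[cn]]
    if (type == "ordinal") {
      x <- if (ordinal == "podani") {
        r <- rank(x, na.last = "keep", ties.method = "average")
        r
      } else {
        as.numeric(if (is.factor(x)) unclass(x) else x)
      }
      type <- "continuous"
    }
    obs <- !is.na(x)
    if (type == "continuous") {
      rng <- diff(range(x, na.rm = TRUE))
      if (rng == 0) {
        warning("trait '", cn, "' has zero range; it contributes distance 0",
                call. = FALSE)
        d <- matrix(0, n, n)
      } else {
        d <- abs(outer(x, x, "-")) / rng
      }
    } else { # nominal
      xc <- as.character(x)
      d <- 1 - outer(xc, xc, function(a, b) as.numeric(a == b))
    }
    pairobs <- outer(obs, obs, "&")
    d[!pairobs] <- 0
    num <- num + w * d
    den <- den + w * pairobs
  }
  bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("species pair (", sp[bad[1L, 1L]], ", ", sp[bad[1L, 2L]],
         ") shares no jointly observed trait with positive weight",
         call. = FALSE)
  }
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(sp, sp)
  D
}

#' Combine traits into a single equal-weight Gower distance
#'
#' The multi-trait pathway of the M statistic: a group of traits is reduced
#' to one dissimilarity matrix by Gower's distance with equal weights,
#' regardless of the weights stored in the table.
#'
#' @param table a [trait_table()].
#' @param group character vector of trait names to combine.
#' @inheritParams gower_distance
#' @return a symmetric distance matrix, as [gower_distance()].
#' @export
combine_columns <- function(table, group, ordinal = c("podani", "raw")) {
  stopifnot(inherits(table, "trait_table"))
  eq <- table
  eq$weights[] <- 1
  gower_distance(eq, columns = group, ordinal = match.arg(ordinal))
}

## validate a user-supplied distance matrix
as_distance_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || !is.numeric(D)) stop("not a numeric matrix",
                                            call. = FALSE)
  if (nrow(D) != ncol(D)) stop("distance matrix not square", call. = FALSE)
  if (is.null(rownames(D))) stop("distance matrix needs species dimnames",
                                 call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric",
                                      call. = FALSE)
  D
}
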