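test_that("continuous traits are range-normalised", {
  tt <- tt_from_vec(c(A = 2, B = 4, C = 6))
  D <- gower_distance(tt)
  expect_equal(D["A", "C"], 1)
  expect_equal(D["A", "B"], 0.5)
  expect_equal(D["B", "C"], 0.5)
  expect_equal(diag(D), setNames(rep(0, 3), c("A", "B", "C")))

  ## identical species are at distance zero
  t2 <- trait_table(data.frame(x = c(1, 1, 2), y = c("u", "u", "v"),
                               row.names = c("A", "B", "C")),
                    types = c(x = "continuous", y = "nominal"))
  expect_equal(gower_distance(t2)["A", "B"], 0)
})

test_that("mixed continuous + nominal pair averages per-trait terms", {
  ## continuous 1 vs 3 on range [1,5] gives 0.5; nominal mismatch gives 1;
  ## equal-weight mean is 0.75
  tt <- trait_table(data.frame(x = c(1, 3, 5),
                               col = c("red", "blue", "red"),
                               row.names = c("A", "B", "C")),
                    types = c(x = "continuous", col = "nominal"))
  expect_equal(gower_distance(tt)["A", "B"], 0.75)
})

test_that("hand-computed 4x3 mixed fixture reproduced to 1e-12", {
  D <- gower_distance(mixed_fixture())
  expect_equal(D, mixed_fixture_expected(), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("gower matches the independent daisy reference", {
  skip_if_not_installed("cluster")
  tt <- mixed_fixture()
  ## continuous + nominal columns: canonical Gower in both implementations
  ours <- gower_distance(tt, c("size", "colour"))
  df <- data.frame(size = tt$data$size, colour = factor(tt$data$colour))
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  dimnames(ref) <- dimnames(ours)
  expect_equal(ours, ref, tolerance = 1e-12)

  ## ordinal as raw integer codes: daisy's treatment of ordered factors
  ours3 <- gower_distance(tt, ordinal = "raw")
  df3 <- cbind(df, iucn = factor(tt$data$iucn, ordered = TRUE))
  ref3 <- as.matrix(cluster::daisy(df3, metric = "gower"))
  dimnames(ref3) <- dimnames(ours3)
  expect_equal(ours3, ref3, tolerance = 1e-12)
})

test_that("gower is invariant to affine transforms and zero-weight columns", {
  set.seed(3)
  x <- rnorm(6)
  names(x) <- paste0("s", 1:6)
  tt <- tt_from_vec(x)
  tta <- tt_from_vec(3.7 * x - 11)
  expect_equal(gower_distance(tt), gower_distance(tta), tolerance = 1e-12)

  ## a zero-weight column contributes nothing
  tt2 <- trait_table(data.frame(x = unname(x), junk = rnorm(6),
                                row.names = names(x)),
                     types = c(x = "continuous", junk = "continuous"),
                     weights = c(junk = 0))
  expect_equal(unname(gower_distance(tt2)), unname(gower_distance(tt)),
               tolerance = 1e-12)
})

test_that("missing values use pairwise deletion with renormalised weights", {
  tt <- trait_table(data.frame(x = c(0, 1, NA), y = c("a", "b", "b"),
                               row.names = c("A", "B", "C")),
                    types = c(x = "continuous", y = "nominal"))
  D <- gower_distance(tt)
  ## A-B sees both traits; A-C and B-C see only the nominal one
  expect_equal(D["A", "B"], (1 + 1) / 2)
  expect_equal(D["A", "C"], 1)
  expect_equal(D["B", "C"], 0)

  ## a pair with no jointly observed trait is an error naming the pair
  tt2 <- trait_table(data.frame(x = c(0, NA, 1), y = c(NA, 3, 4),
                                row.names = c("A", "B", "C")),
                     types = c(x = "continuous", y = "continuous"))
  expect_error(gower_distance(tt2), "A, B")
})

test_that("zero-range continuous column warns and contributes 0", {
  tt <- trait_table(data.frame(x = c(5, 5, 5), y = c(0, 1, 2),
                               row.names = c("A", "B", "C")),
                    types = c(x = "continuous", y = "continuous"))
  expect_warning(D <- gower_distance(tt), "zero range")
  ## the flat trait dilutes: mean of 0 and the y-term
  expect_equal(D["A", "C"], 0.5)
})

test_that("ordinal midranks handle ties (Podani) and differ from raw codes", {
  tt <- trait_table(data.frame(o = c(1, 1, 2, 5),
                               row.names = paste0("s", 1:4)),
                    types = c(o = "ordinal"))
  D <- gower_distance(tt)
  ## midranks 1.5, 1.5, 3, 4 on range 2.5
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 1.5 / 2.5)
  expect_equal(D["s3", "s4"], 1 / 2.5)
  Draw <- gower_distance(tt, ordinal = "raw")
  expect_equal(Draw["s3", "s4"], 3 / 4)
})

test_that("combine_columns equals equal-weight gower over the group", {
  tt <- mixed_fixture()
  ## degenerate group of one
  expect_equal(combine_columns(tt, "size"), gower_distance(tt, "size"))
  ## two identical columns collapse to the single-column distance
  tt2 <- trait_table(data.frame(a = tt$data$size, b = tt$data$size,
                                row.names = rownames(tt$data)),
                     types = c(a = "continuous", b = "continuous"))
  expect_equal(combine_columns(tt2, c("a", "b")),
               gower_distance(tt2, "a"), tolerance = 1e-12)
  ## fully observed equal weights: elementwise mean of the two matrices
  D1 <- gower_distance(tt, "size")
  D2 <- gower_distance(tt, "colour")
  expect_equal(combine_columns(tt, c("size", "colour")), (D1 + D2) / 2,
               tolerance = 1e-12)
  ## combine ignores stored weights
  tt3 <- mixed_fixture()
  tt3$weights[] <- c(10, 1, 1)
  expect_equal(combine_columns(tt3, c("size", "colour")), (D1 + D2) / 2,
               tolerance = 1e-12)
})

test_that("trait table validation catches bad input", {
  expect_error(trait_table(data.frame(x = 1:3), types = c(x = "continuous")),
               "species labels")
  df <- data.frame(x = 1:3, row.names = c("A", "B", "C"))
  expect_error(trait_table(df, types = c(y = "continuous")), "no declared type")
  expect_error(trait_table(df, types = c(x = "numericish")), "invalid trait type")
  expect_error(trait_table(data.frame(x = c(NA, NA, NA),
                                      row.names = c("A", "B", "C")),
                           types = c(x = "continuous")), "no non-missing")
  expect_error(gower_distance(trait_table(df, c(x = "continuous")), "nope"),
               "unknown trait")
})

test_that("trait tables round-trip through CSV with a sidecar declaration", {
  tt <- mixed_fixture()
  traits <- file.path(tempdir(), "traits.csv")
  types <- file.path(tempdir(), "types.csv")
  write.csv(cbind(species = rownames(tt$data), tt$data), traits,
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(trait = names(tt$data), type = unname(tt$types),
                       weight = unname(tt$weights)),
            types, row.names = FALSE, quote = FALSE)
  rt <- read_trait_table(traits, types)
  expect_equal(gower_distance(rt), gower_distance(tt), tolerance = 1e-12)
})
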