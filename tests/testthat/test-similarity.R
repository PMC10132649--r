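test_that("importance weights are a simplex over shared features", {
  pipe <- small_pipeline()
  w <- pipe$weights
  expect_s3_class(w, "importance_weights")
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_true(all(w$weight >= 0))
  expect_identical(w$feature, colnames(pipe$shared$source))
})

test_that("outcome-free shared features trigger the uniform fallback", {
  set.seed(31)
  n <- 300
  Xs <- normalize_unit(matrix(stats::rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("s", 1:4))))
  y <- stats::rbinom(n, 1, 0.1)
  expect_warning(w <- importance_weights(Xs, y, seed = 2), "uniform")
  expect_equal(w$weight, rep(0.25, 4))
})

test_that("a dominant shared predictor receives the largest weight", {
  set.seed(32)
  n <- 1200
  strong <- stats::rbinom(n, 1, 0.4)
  X <- cbind(strong = strong,
             matrix(stats::rbinom(n * 5, 1, 0.3), n, 5,
                    dimnames = list(NULL, paste0("w", 1:5))))
  y <- stats::rbinom(n, 1, stats::plogis(-2 + 2 * strong))
  w <- importance_weights(normalize_unit(X), y, seed = 3)
  expect_equal(w$feature[which.max(w$weight)], "strong")
})

test_that("weighted Manhattan distance matches hand computation", {
  expect_equal(weighted_manhattan(c(1, 2, 3), c(1, 2, 3), rep(1 / 3, 3)), 0)
  expect_equal(
    weighted_manhattan(c(1, 0, 1), c(0, 0, 0), c(0.5, 0.25, 0.25)), 0.75)
  # uniform weights reduce to plain Manhattan / J
  x <- c(0.2, 0.9, 0.4); y <- c(0.7, 0.1, 0.4)
  expect_equal(weighted_manhattan(x, y, rep(1 / 3, 3)),
               sum(abs(x - y)) / 3)
  # positive scaling of weights preserves neighbour ranking
  w <- c(0.6, 0.3, 0.1)
  expect_equal(weighted_manhattan(x, y, 5 * w),
               5 * weighted_manhattan(x, y, w))
  expect_error(weighted_manhattan(1:3, 1:2, c(0.5, 0.5)), "equal length")
})

test_that("weighted Pearson reduces to cor() and honors its contracts", {
  set.seed(33)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  expect_equal(weighted_pearson(x, y, rep(1 / 6, 6)), stats::cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, x, rep(1 / 6, 6)), 1)
  w <- stats::runif(6); w <- w / sum(w)
  expect_equal(weighted_pearson(x, 2 + 3 * x, w), 1, tolerance = 1e-12)
  expect_warning(r <- weighted_pearson(rep(1, 6), y, w), "zero weighted")
  expect_equal(r, -1)
})

test_that("similarity matrices equal the naive per-pair loop", {
  set.seed(34)
  X <- matrix(stats::runif(20 * 7), 20, 7,
              dimnames = list(NULL, paste0("f", 1:7)))
  Y <- matrix(stats::runif(30 * 7), 30, 7,
              dimnames = list(NULL, paste0("f", 1:7)))
  w <- stats::runif(7); w <- w / sum(w)
  for (m in c("r", "d")) {
    S <- similarity_matrix(X, Y, m)
    expect_equal(unclass(S), similarity_oracle(X, Y, m, rep(1 / 7, 7)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  for (m in c("rw", "dw")) {
    S <- similarity_matrix(X, Y, m, weights = w)
    expect_equal(unclass(S), similarity_oracle(X, Y, m, w),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # blocking must not change values
  S1 <- similarity_matrix(X, Y, "dw", weights = w, block_size = 3L)
  S2 <- similarity_matrix(X, Y, "dw", weights = w, block_size = 1024L)
  expect_equal(unclass(S1), unclass(S2))
})

test_that("uniform weights reproduce the unweighted measures", {
  set.seed(35)
  X <- matrix(stats::runif(8 * 5), 8, 5)
  Y <- matrix(stats::runif(9 * 5), 9, 5)
  u <- rep(1 / 5, 5)
  expect_equal(unclass(similarity_matrix(X, Y, "rw", weights = u)),
               unclass(similarity_matrix(X, Y, "r")), tolerance = 1e-12,
               ignore_attr = TRUE)
  Sd <- similarity_matrix(X, Y, "d")
  Sdw <- similarity_matrix(X, Y, "dw", weights = u)
  expect_equal(unclass(Sdw), unclass(Sd), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a target row identical to a source row self-matches", {
  set.seed(36)
  Y <- matrix(stats::runif(6 * 4), 6, 4)
  X <- rbind(Y[3, ], stats::runif(4))
  expect_equal(similarity_matrix(X, Y, "r")[1, 3], 1)
  expect_equal(similarity_matrix(X, Y, "d")[1, 3], 0)
})

test_that("Manhattan similarity is a metric on sampled triples", {
  set.seed(37)
  w <- stats::runif(5); w <- w / sum(w)
  for (i in 1:50) {
    a <- stats::runif(5); b <- stats::runif(5); cc <- stats::runif(5)
    dab <- weighted_manhattan(a, b, w)
    expect_equal(dab, weighted_manhattan(b, a, w))
    expect_lte(weighted_manhattan(a, cc, w),
               dab + weighted_manhattan(b, cc, w) + 1e-12)
  }
})

test_that("degenerate constant rows are assigned -1, not an error", {
  X <- rbind(c(0.5, 0.5, 0.5), c(0.1, 0.9, 0.3))
  Y <- rbind(c(0.2, 0.4, 0.6), c(0.7, 0.7, 0.7))
  S <- similarity_matrix(X, Y, "r")
  expect_equal(S[1, ], c(-1, -1))
  expect_equal(S[2, 2], -1)
  expect_equal(attr(S, "n_degenerate"), 3L)
})
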