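test_that("FDR adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("marginal screening finds planted signal and flags degeneracies", {
  set.seed(101)
  n <- 2000
  covs <- cbind(age = stats::runif(n), sex = stats::rbinom(n, 1, 0.5))
  x_signal <- stats::rbinom(n, 1, 0.3)
  eta <- log(5) * x_signal - 2.2  # true odds ratio 5
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  X <- cbind(signal = x_signal,
             noise1 = stats::rnorm(n), noise2 = stats::rbinom(n, 1, 0.2),
             flat = rep(1, n),
             mirror = y)  # perfect separation
  scr <- marginal_screen(X, y, covs)
  expect_s3_class(scr, "screening_result")
  row <- function(f) scr[scr$feature == f, ]
  expect_true(row("signal")$pass)
  expect_equal(row("signal")$estimate, log(5), tolerance = 0.15)
  expect_equal(row("flat")$status, "constant")
  expect_equal(row("mirror")$status, "unstable")
  expect_false(row("flat")$pass)
  expect_false(row("mirror")$pass)
})

test_that("null features pass the screen at no more than the nominal rate", {
  set.seed(55)
  n <- 1000
  y <- stats::rbinom(n, 1, 0.1)
  covs <- cbind(age = stats::runif(n), sex = stats::rbinom(n, 1, 0.5))
  X <- matrix(stats::rnorm(n * 50), n, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  scr <- marginal_screen(X, y, covs)
  # under the global null BH controls FWER at alpha; most runs pass nothing
  expect_lte(mean(scr$pass), 0.10)
})

test_that("elastic net recovers a strong predictor among noise", {
  set.seed(11)
  n <- 1500
  X <- matrix(stats::rnorm(n * 51), n, 51,
              dimnames = list(NULL, c("strong", paste0("noise", 1:50))))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * X[, "strong"]))
  X01 <- normalize_unit(X)
  fit <- fit_elastic_net(X01, y, seed = 4)
  expect_s3_class(fit, "enet_fit")
  expect_true(fit$coefficients[["strong"]] > 0)
  expect_equal(unname(which.max(abs(fit$coefficients))),
               which(colnames(X) == "strong"))
})

test_that("infinite penalty gives the null model with logit(case rate)", {
  set.seed(12)
  n <- 800
  X <- normalize_unit(matrix(stats::rnorm(n * 5), n, 5))
  y <- stats::rbinom(n, 1, 0.3)
  fit <- fit_elastic_net(X, y, lambda = 1e6)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, stats::qlogis(mean(y)), tolerance = 1e-4)
})

test_that("duplicated predictive columns are co-selected with equal signs", {
  set.seed(13)
  n <- 1500
  x <- stats::rnorm(n)
  X <- cbind(a = x, b = x, c = stats::rnorm(n), d = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.2 * x))
  fit <- fit_elastic_net(normalize_unit(X), y, seed = 6)
  expect_true(fit$coefficients[["a"]] > 0)
  expect_true(fit$coefficients[["b"]] > 0)
  # grouping property of the mixed penalty: near-equal coefficients
  expect_equal(fit$coefficients[["a"]], fit$coefficients[["b"]],
               tolerance = 0.05)
})

test_that("stratified splits preserve case counts on both sides", {
  set.seed(14)
  y <- c(rep(1, 20), rep(0, 180))
  for (s in 1:10) {
    train <- sdohfusion:::stratified_split(y, 0.9, seed = s)
    expect_equal(sum(y[train]) + sum(y[!train]), 20)
    expect_equal(sum(y[train]), 18)
    expect_gte(sum(y[!train]), 1)
  }
})

test_that("stability selection is reproducible and honors the 50% rule", {
  set.seed(15)
  n <- 600
  x_strong <- stats::rnorm(n)
  X <- cbind(strong = x_strong,
             matrix(stats::rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("n", 1:10))))
  y <- stats::rbinom(n, 1, stats::plogis(-1.2 + 1.5 * x_strong))
  covs <- cbind(age = stats::runif(n), sex = stats::rbinom(n, 1, 0.5))
  sel1 <- stability_select(X, y, covs, n_repeats = 5, seed = 99)
  sel2 <- stability_select(X, y, covs, n_repeats = 5, seed = 99)
  expect_identical(tibble::as_tibble(sel1), tibble::as_tibble(sel2))
  expect_equal(sel1$frequency, sel1$n_selected / 5)
  expect_identical(sel1$kept, sel1$frequency >= 0.5)
  expect_true(sel1$kept[sel1$feature == "strong"])
  expect_gt(sel1$mean_coef[sel1$feature == "strong"], 0)
})

test_that("stability selection keeps nothing on pure noise", {
  set.seed(16)
  n <- 800
  X <- matrix(stats::rnorm(n * 30), n, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  y <- stats::rbinom(n, 1, 0.08)
  covs <- cbind(age = stats::runif(n), sex = stats::rbinom(n, 1, 0.5))
  sel <- stability_select(X, y, covs, n_repeats = 5, seed = 5)
  expect_lte(sum(sel$kept & !sel$is_covariate), 1)
})

test_that("source-side selection returns SDoH features only", {
  pipe <- small_pipeline()
  sel <- select_source_sdoh(pipe$source, n_repeats = 4, seed = 17)
  roles <- cohort_roles(pipe$source)
  expect_true(all(sel$kept_sdoh %in% roles$sdoh))
  expect_s3_class(sel$selection, "selection_summary")
  # the planted features are recovered
  expect_true(all(c("sdoh_01", "sdoh_02") %in% sel$kept_sdoh))
})
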