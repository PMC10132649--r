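#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in the
#' rank order of the raw p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Marginal outcome screening of candidate features
#'
#' Fits one logistic regression per candidate feature, `outcome ~ feature +
#' covariates`, and takes the Wald p-value for the feature coefficient. The
#' p-values are FDR-adjusted across the candidate family and a feature
#' passes when its adjusted p-value is strictly below `alpha`. Constant
#' features and features whose fit is unstable (non-convergence, separation,
#' aliasing) are excluded and flagged rather than failing the screen.
#'
#' @param X Matrix or data frame of candidate features (columns named).
#' @param y Binary outcome vector (0/1).
#' @param covariates Matrix or data frame of adjustment covariates included
#'   in every per-feature fit (at minimum age and sex; for fused-feature
#'   screening also the screened diagnosis indicators).
#' @param alpha Threshold applied to the adjusted p-value (default 0.10).
#' @return A tibble classed `"screening_result"` with one row per candidate:
#'   `feature`, `estimate`, `se`, `p_value`, `p_adjusted`, `pass`, `status`
#'   (`"ok"`, `"constant"` or `"unstable"`).
#' @export
marginal_screen <- function(X, y, covariates, alpha = 0.10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  covariates <- as.matrix(covariates)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(covariates) == length(y))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }

  n <- length(y)
  base <- cbind(`(Intercept)` = 1, covariates)
  res <- purrr::map(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (max(xj) - min(xj) <= 0) {
      return(list(est = NA_real_, se = NA_real_, p = NA_real_,
                  status = "constant"))
    }
    wald_feature_test(cbind(base[, 1, drop = FALSE], feature = xj,
                            base[, -1, drop = FALSE]), y)
  })
  out <- tibble::tibble(
    feature = colnames(X),
    estimate = purrr::map_dbl(res, "est"),
    se = purrr::map_dbl(res, "se"),
    p_value = purrr::map_dbl(res, "p"),
    status = purrr::map_chr(res, "status"))
  out$p_adjusted <- NA_real_
  ok <- out$status == "ok"
  if (any(ok)) out$p_adjusted[ok] <- bh_adjust(out$p_value[ok])
  out$pass <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  class(out) <- c("screening_result", class(out))
  out
}

# Wald z-test for the column named "feature" of a logistic design matrix.
wald_feature_test <- function(xmat, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(xmat, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(list(est = NA_real_, se = NA_real_, p = NA_real_,
                status = "unstable"))
  }
  p_rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(p_rank)]
  jf <- match("feature", colnames(xmat))
  pos <- match(jf, piv)
  if (is.na(pos)) { # feature aliased with covariates
    return(list(est = NA_real_, se = NA_real_, p = NA_real_,
                status = "unstable"))
  }
  covmat <- chol2inv(fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE])
  est <- fit$coefficients[jf]
  se <- sqrt(covmat[pos, pos])
  if (!is.finite(se) || se > 30 || abs(est) > 15) {
    return(list(est = est, se = se, p = NA_real_, status = "unstable"))
  }
  z <- est / se
  list(est = unname(est), se = se,
       p = 2 * stats::pnorm(-abs(z)), status = "ok")
}

# Deterministic stratified fold assignment for cross-validation.
stratified_foldid <- function(y, nfolds, seed) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Penalized logistic regression with cross-validated penalty choice
#'
#' Fits an elastic-net logistic model and chooses the penalty strength by
#' stratified cross-validation (folds are assigned deterministically from
#' `seed`, within cases and controls separately so rare cases appear in
#' every fold). The mixing parameter defaults to an equal blend of ridge
#' and lasso.
#'
#' @param X Numeric candidate matrix, columns on the unit scale.
#' @param y Binary outcome (0/1).
#' @param enet_alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param nfolds Cross-validation folds (default 5; reduced if a class has
#'   fewer members than folds).
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda,lambda.min.ratio Penalty path resolution and depth; the
#'   defaults (60 values down to 1% of the null penalty) cover the
#'   cross-validated optimum for unit-scale predictors at a fraction of the
#'   cost of glmnet's deeper default path.
#' @param lambda Optional fixed penalty; when given, cross-validation is
#'   skipped and the model is fit at exactly this penalty.
#' @return A list classed `"enet_fit"`: `intercept`, `coefficients` (named
#'   vector over columns of `X`), `lambda` (chosen penalty), `enet_alpha`,
#'   `nfolds`, `seed`, and `bounds` if `X` carried normalization bounds.
#' @export
fit_elastic_net <- function(X, y, enet_alpha = 0.5, nfolds = 5, seed = 1,
                            nlambda = 60, lambda.min.ratio = 0.01,
                            lambda = NULL) {
  bounds <- attr(X, "bounds")
  X <- unclass_matrix(as.matrix(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome must contain both classes",
                                  call. = FALSE)
  ranges <- apply(X, 2, function(v) max(v) - min(v))
  if (all(ranges <= 0)) stop("all candidate columns are constant",
                             call. = FALSE)
  padded <- FALSE
  if (ncol(X) < 2) { # glmnet needs >= 2 columns
    X <- cbind(X, `.pad.` = 0)
    padded <- TRUE
  }
  nfolds <- max(2L, min(nfolds, min(table(y))))
  if (is.null(lambda)) {
    foldid <- stratified_foldid(y, nfolds, seed)
    # glmnet warns about small per-fold class counts on rare outcomes; the
    # stratified folds already guarantee cases in every fold
    cv <- suppressWarnings(
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = enet_alpha,
                        foldid = foldid, standardize = FALSE,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda.min.ratio))
    chosen <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else { # fixed penalty, no cross-validation
    fit0 <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = enet_alpha,
                     lambda = lambda, standardize = FALSE))
    chosen <- lambda
    beta <- as.numeric(stats::coef(fit0, s = lambda))
  }
  names(beta) <- c("(Intercept)", colnames(X))
  coefs <- beta[-1]
  if (padded) coefs <- coefs[names(coefs) != ".pad."]
  structure(list(intercept = unname(beta[1]), coefficients = coefs,
                 lambda = chosen, enet_alpha = enet_alpha,
                 nfolds = nfolds, seed = seed, bounds = bounds),
            class = "enet_fit")
}

# Stratified train indicator: train_frac of each outcome class, both sides
# non-empty whenever a class has >= 2 members.
stratified_split <- function(y, train_frac, seed) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- round(train_frac * length(idx))
    if (length(idx) >= 2) n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Stability selection by repeated screen-then-fit resampling
#'
#' Repeats, over stratified train/validation splits, the two-stage
#' procedure: marginal FDR screening of the candidates (adjusting for the
#' covariates) followed by an elastic-net logistic fit on the survivors
#' plus the covariates. A feature counts as selected in a repeat when its
#' elastic-net coefficient is nonzero at the cross-validated penalty.
#' Features selected in at least `freq_threshold` of the repeats are
#' flagged as kept.
#'
#' @inheritParams marginal_screen
#' @param n_repeats Number of resampled fits (default 10).
#' @param train_frac Fraction of each outcome class assigned to training
#'   (default 0.9).
#' @param freq_threshold Minimum selection frequency to keep a feature
#'   (default 0.5).
#' @param enet_alpha,nfolds Passed to [fit_elastic_net()].
#' @param seed Integer seed; repeat `r` uses `seed + r` for its split and
#'   fold assignment.
#' @return A tibble classed `"selection_summary"`: per feature (covariates
#'   included) the selection count `n_selected`, `frequency`, mean and sd
#'   of the coefficient over the repeats where it was selected, `mean_odds
#'   = exp(mean_coef)`, and the `kept` flag.
#' @export
stability_select <- function(X, y, covariates, alpha = 0.10,
                             n_repeats = 10, train_frac = 0.9,
                             freq_threshold = 0.5,
                             enet_alpha = 0.5, nfolds = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  covariates <- as.matrix(covariates)
  y <- as.numeric(y)
  features <- c(colnames(covariates), colnames(X))

  coef_mat <- matrix(NA_real_, n_repeats, length(features),
                     dimnames = list(NULL, features))
  for (r in seq_len(n_repeats)) {
    train <- stratified_split(y, train_frac, seed = seed + r)
    if (sum(y[train]) == 0) {
      stop("repeat ", r, ": no cases in training fold (seed ", seed + r,
           "); check stratification inputs", call. = FALSE)
    }
    scr <- marginal_screen(X[train, , drop = FALSE], y[train],
                           covariates[train, , drop = FALSE], alpha = alpha)
    keep <- scr$feature[scr$pass]
    cand <- cbind(covariates[train, , drop = FALSE],
                  X[train, keep, drop = FALSE])
    cand <- normalize_unit(cand)
    fit <- fit_elastic_net(cand, y[train], enet_alpha = enet_alpha,
                           nfolds = nfolds, seed = seed + r)
    row <- stats::setNames(rep(0, length(features)), features)
    row[names(fit$coefficients)] <- fit$coefficients
    coef_mat[r, ] <- row
  }

  selected <- coef_mat != 0
  n_sel <- colSums(selected)
  mean_coef <- vapply(seq_along(features), function(j) {
    v <- coef_mat[selected[, j], j]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  sd_coef <- vapply(seq_along(features), function(j) {
    v <- coef_mat[selected[, j], j]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))

  out <- tibble::tibble(
    feature = features,
    is_covariate = features %in% colnames(covariates),
    n_selected = as.integer(n_sel),
    frequency = unname(n_sel) / n_repeats,
    mean_coef = mean_coef,
    sd_coef = sd_coef,
    mean_odds = exp(mean_coef),
    kept = unname(n_sel) / n_repeats >= freq_threshold)
  attr(out, "n_repeats") <- n_repeats
  attr(out, "freq_threshold") <- freq_threshold
  attr(out, "seed") <- seed
  class(out) <- c("selection_summary", class(out))
  out
}

#' Select outcome-relevant SDoH features in the source cohort
#'
#' The survey-side feature-selection stage: the mock diagnosis indicators
#' and SDoH features are jointly submitted to [stability_select()] with age
#' and sex as adjustment covariates — marginal FDR screening followed by an
#' elastic-net fit, repeated over stratified 90/10 resamples — and the SDoH
#' features selected in at least half of the resamples are kept for
#' fusion into the target cohort.
#'
#' @param source A source cohort tibble ([as_cohort()]) with complete SDoH
#'   columns (see [impute_sdoh()]).
#' @inheritParams stability_select
#' @return A list: `kept_sdoh` (character vector of SDoH columns to fuse)
#'   and `selection` (the full `"selection_summary"` over mock dx and SDoH
#'   candidates).
#' @export
select_source_sdoh <- function(source, alpha = 0.10, n_repeats = 10,
                               train_frac = 0.9, freq_threshold = 0.5,
                               enet_alpha = 0.5, nfolds = 5, seed = 1) {
  roles <- cohort_roles(source)
  if (length(roles$sdoh) == 0) stop("source cohort has no SDoH columns",
                                    call. = FALSE)
  sdat <- as.data.frame(source)
  X <- as.matrix(sdat[, c(roles$dx, roles$sdoh), drop = FALSE])
  covs <- cbind(age = as.numeric(sdat[[roles$age]]),
                sex = as.numeric(sdat[[roles$sex]]))
  sel <- stability_select(X, sdat[[roles$outcome]], covs, alpha = alpha,
                          n_repeats = n_repeats, train_frac = train_frac,
                          freq_threshold = freq_threshold,
                          enet_alpha = enet_alpha, nfolds = nfolds,
                          seed = seed)
  list(kept_sdoh = intersect(sel$feature[sel$kept], roles$sdoh),
       selection = sel)
}
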