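#' Fit a risk model variant on the target cohort
#'
#' Implements the screen-then-fit modeling procedure for the three model
#' variants compared by the framework:
#' * `conventional` — age, sex and diagnosis-category indicators;
#' * `sdoh_only` — age, sex and fused SDoH features;
#' * `fusion` — all of the above.
#'
#' Diagnosis candidates are marginally screened against age and sex; fused
#' candidates are screened against age, sex and the screened diagnosis
#' indicators (for the fusion variant). Survivors plus age and sex (always
#' admitted as candidates) enter an elastic-net logistic fit on the unit
#' scale. Screening and normalization bounds are computed on the rows used
#' for fitting only, so repeated-split evaluation never leaks validation
#' rows.
#'
#' @param target A target cohort tibble ([as_cohort()]).
#' @param fused A `"fused_features"` tibble row-aligned with `target`
#'   (required for `sdoh_only` and `fusion`).
#' @param variant One of `"conventional"`, `"sdoh_only"`, `"fusion"`.
#' @param rows Optional integer/logical index of training rows (default
#'   all rows).
#' @param alpha Marginal screening threshold on the FDR-adjusted p-value.
#' @param enet_alpha,nfolds Passed to [fit_elastic_net()].
#' @param seed Seed for fold assignment.
#' @return A list classed `"sdoh_model"` with the intercept, nonzero
#'   coefficients, feature list, normalization bounds, screening traces
#'   and the chosen penalty.
#' @export
fit_model <- function(target, fused = NULL,
                      variant = c("conventional", "sdoh_only", "fusion"),
                      rows = NULL, alpha = 0.10, enet_alpha = 0.5,
                      nfolds = 5, seed = 1) {
  variant <- match.arg(variant)
  roles <- cohort_roles(target)
  if (variant != "conventional" && is.null(fused)) {
    stop("variant '", variant, "' requires fused features", call. = FALSE)
  }
  if (!is.null(fused) && nrow(fused) != nrow(target)) {
    stop("fused features are not row-aligned with the target cohort",
         call. = FALSE)
  }
  if (is.null(rows)) rows <- seq_len(nrow(target))

  tdat <- as.data.frame(target)[rows, , drop = FALSE]
  y <- as.numeric(tdat[[roles$outcome]])
  if (length(unique(y)) < 2) {
    stop("training rows must contain at least one case and one control",
         call. = FALSE)
  }
  demo <- cbind(age = as.numeric(tdat[[roles$age]]),
                sex = as.numeric(tdat[[roles$sex]]))
  X_dx <- as.matrix(tdat[, roles$dx, drop = FALSE])
  X_fused <- if (!is.null(fused)) {
    as.matrix(as.data.frame(fused)[rows, , drop = FALSE])
  } else NULL

  screening <- list()
  blocks <- list(demo)
  if (variant %in% c("conventional", "fusion")) {
    scr_dx <- marginal_screen(X_dx, y, demo, alpha = alpha)
    screening$dx <- scr_dx
    blocks <- c(blocks, list(X_dx[, scr_dx$feature[scr_dx$pass],
                                  drop = FALSE]))
  }
  if (variant %in% c("sdoh_only", "fusion")) {
    fused_covs <- if (variant == "fusion") {
      kept_dx <- screening$dx$feature[screening$dx$pass]
      cbind(demo, X_dx[, kept_dx, drop = FALSE])
    } else demo
    scr_f <- marginal_screen(X_fused, y, fused_covs, alpha = alpha)
    screening$fused <- scr_f
    blocks <- c(blocks, list(X_fused[, scr_f$feature[scr_f$pass],
                                     drop = FALSE]))
  }
  cand <- do.call(cbind, blocks)
  if (ncol(cand) == ncol(demo)) {
    warning("no candidate survived screening; fitting on demographics alone",
            call. = FALSE)
  }
  cand_norm <- normalize_unit(cand)
  fit <- fit_elastic_net(cand_norm, y, enet_alpha = enet_alpha,
                         nfolds = nfolds, seed = seed)

  structure(list(
    variant = variant,
    intercept = fit$intercept,
    coefficients = fit$coefficients,
    features = colnames(cand),
    bounds = attr(cand_norm, "bounds"),
    lambda = fit$lambda,
    enet_alpha = enet_alpha,
    alpha = alpha,
    screening = screening,
    roles = roles,
    seed = seed,
    n_train = length(y),
    n_cases = sum(y)), class = "sdoh_model")
}

#' Predict outcome risk from a fitted model
#'
#' Rebuilds the model's feature columns from the target cohort (and fused
#' features, if the variant uses them), applies the stored training
#' normalization bounds — values outside the training range map outside
#' `[0, 1]` and are scored as-is — and returns the logistic risk score.
#'
#' @param fit A `"sdoh_model"`.
#' @param target Target cohort tibble.
#' @param fused Fused feature tibble row-aligned with `target` (if the
#'   model retains fused columns).
#' @param rows Optional row index (default all rows).
#' @return Numeric vector of risk scores in `(0, 1)`.
#' @export
predict_risk <- function(fit, target, fused = NULL, rows = NULL) {
  stopifnot(inherits(fit, "sdoh_model"))
  roles <- fit$roles
  if (is.null(rows)) rows <- seq_len(nrow(target))
  tdat <- as.data.frame(target)[rows, , drop = FALSE]
  avail <- cbind(age = as.numeric(tdat[[roles$age]]),
                 sex = as.numeric(tdat[[roles$sex]]),
                 as.matrix(tdat[, roles$dx, drop = FALSE]))
  if (!is.null(fused)) {
    avail <- cbind(avail, as.matrix(as.data.frame(fused)[rows, ,
                                                         drop = FALSE]))
  }
  missing_feats <- setdiff(fit$features, colnames(avail))
  if (length(missing_feats) > 0) {
    stop("missing retained feature(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  X <- avail[, fit$features, drop = FALSE]
  X <- normalize_unit(X, bounds = fit$bounds)
  eta <- fit$intercept +
    drop(unclass_matrix(X) %*% fit$coefficients[fit$features])
  unname(stats::plogis(eta))
}

#' @exportS3Method base::print
print.sdoh_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("sdoh_model ('%s'): %d candidates, %d retained (lambda = %.4g)\n",
              x$variant, length(x$features), nz, x$lambda))
  cat(sprintf("  trained on %d rows (%d cases)\n", x$n_train, x$n_cases))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted risk model
#'
#' @param x A `"sdoh_model"`.
#' @param keep_zero Include zero coefficients (default `FALSE`).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log-odds on the unit feature
#'   scale) and `odds_ratio`.
#' @export
tidy.sdoh_model <- function(x, keep_zero = FALSE, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        odds_ratio = exp(unname(x$coefficients)))
  if (!keep_zero) out <- dplyr::filter(out, .data$estimate != 0)
  dplyr::arrange(out, dplyr::desc(abs(.data$estimate)))
}

#' One-row summary of a fitted risk model
#'
#' @param x A `"sdoh_model"`.
#' @param ... Unused.
#' @return Tibble with the variant, candidate and retained feature counts,
#'   penalty, and training sizes.
#' @export
glance.sdoh_model <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_candidates = length(x$features),
                 n_retained = sum(x$coefficients != 0),
                 lambda = x$lambda,
                 enet_alpha = x$enet_alpha,
                 n_train = x$n_train,
                 n_cases = x$n_cases)
}
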