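#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen case
#' outscores a randomly chosen control, with ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome labels (0/1), aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and PPV at a fixed specificity
#'
#' Chooses the smallest score threshold whose specificity among controls is
#' at least `level` (prediction rule: positive when `score >= threshold`),
#' then reports the sensitivity and positive predictive value at that
#' threshold.
#'
#' @inheritParams auc
#' @param level Required specificity, e.g. 0.90 or 0.95.
#' @return Tibble with one row: `specificity_level`, `threshold`,
#'   `specificity` (achieved), `sensitivity`, `ppv` (NA when no subject is
#'   predicted positive).
#' @export
sens_ppv_at_specificity <- function(scores, labels, level) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  stopifnot(level > 0, level < 1)
  controls <- scores[labels == 0]
  # candidate cuts: every observed score, plus one above the maximum
  cuts <- sort(unique(scores))
  spec <- vapply(cuts, function(t) mean(controls < t), numeric(1))
  ok <- which(spec >= level)
  threshold <- if (length(ok) > 0) cuts[ok[1]] else max(scores) + 1
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1)
  fp <- sum(pos & labels == 0)
  tibble::tibble(
    specificity_level = level,
    threshold = threshold,
    specificity = mean(controls < threshold),
    sensitivity = tp / n1,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Flag the top decile of risk scores
#'
#' Flags the `ceiling(0.10 * n)` highest scores as predicted positives;
#' ties at the boundary are broken by ascending row index.
#'
#' @param scores Numeric risk scores.
#' @param prop Proportion flagged (default 0.10).
#' @return Logical vector aligned with `scores`.
#' @export
top_decile_classify <- function(scores, prop = 0.10) {
  n <- length(scores)
  if (n == 0) stop("empty scores", call. = FALSE)
  m <- ceiling(prop * n)
  flags <- logical(n)
  flags[order(-scores, seq_len(n))[seq_len(m)]] <- TRUE
  flags
}

split_metrics <- function(scores, y) {
  s95 <- sens_ppv_at_specificity(scores, y, 0.95)
  s90 <- sens_ppv_at_specificity(scores, y, 0.90)
  tibble::tibble(auc = auc(scores, y),
                 sens_95 = s95$sensitivity, sens_90 = s90$sensitivity,
                 ppv_95 = s95$ppv, ppv_90 = s90$ppv)
}

summarise_metric <- function(x) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  se <- stats::sd(x, na.rm = TRUE) / sqrt(n)
  tibble::tibble(mean = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
}

#' Repeated-split evaluation of the model variants
#'
#' Runs the full screen-select-fit pipeline for each requested variant on
#' repeated stratified 90/10 train/validation splits — the identical split
#' sequence for every variant, so comparisons are paired — and summarizes
#' out-of-sample AUC, sensitivity and PPV at 90% and 95% specificity as
#' means with normal-approximation 95% confidence intervals over the
#' splits. When both `fusion` and `conventional` are evaluated, the paired
#' per-split fusion-minus-conventional differences are summarized too.
#' Per-variant selection summaries (how often each feature had a nonzero
#' coefficient across the split fits) are also returned.
#'
#' @inheritParams fit_model
#' @param variants Character subset of
#'   `c("conventional", "sdoh_only", "fusion")`.
#' @param n_splits Number of repeated splits (default 10).
#' @param train_frac Training fraction per outcome class (default 0.9).
#' @param freq_threshold Stability threshold for the `kept` flag in the
#'   selection summaries (default 0.5).
#' @param seed Integer seed; split `s` uses `seed + s`.
#' @return A list classed `"performance_summary"`:
#'   * `performance` — tibble (variant, metric, mean, ci_lo, ci_hi),
#'   * `differences` — paired fusion-minus-conventional tibble (or NULL),
#'   * `splits` — per-split metric tibble,
#'   * `selection` — named list of `"selection_summary"` tibbles,
#'   * `case_counts` — validation-fold case counts per split.
#' @export
repeated_split_evaluate <- function(target, fused = NULL,
                                    variants = c("conventional", "fusion"),
                                    n_splits = 10, train_frac = 0.9,
                                    alpha = 0.10, enet_alpha = 0.5,
                                    nfolds = 5, freq_threshold = 0.5,
                                    seed = 1) {
  variants <- match.arg(variants,
                        c("conventional", "sdoh_only", "fusion"),
                        several.ok = TRUE)
  roles <- cohort_roles(target)
  y <- as.numeric(as.data.frame(target)[[roles$outcome]])
  n <- length(y)

  splits <- list()
  notes <- character()
  for (s in seq_len(n_splits)) {
    split_seed <- seed + s
    repeat {
      train <- stratified_split(y, train_frac, seed = split_seed)
      if (sum(y[!train]) > 0 && sum(y[train]) > 0) break
      notes <- c(notes, sprintf(
        "split %d: validation fold lacked cases; resampled (seed %d)",
        s, split_seed + 1000L))
      split_seed <- split_seed + 1000L
    }
    splits[[s]] <- train
  }

  per_split <- list()
  coef_traces <- stats::setNames(
    lapply(variants, function(v) list()), variants)
  for (s in seq_len(n_splits)) {
    train <- splits[[s]]
    test_rows <- which(!train)
    for (v in variants) {
      fit <- fit_model(target, fused = fused, variant = v,
                       rows = which(train), alpha = alpha,
                       enet_alpha = enet_alpha, nfolds = nfolds,
                       seed = seed + s)
      scores <- predict_risk(fit, target, fused = fused, rows = test_rows)
      per_split[[length(per_split) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(split = s, variant = v,
                       n_test = length(test_rows),
                       cases_test = sum(y[test_rows])),
        split_metrics(scores, y[test_rows]))
      coef_traces[[v]][[s]] <- fit$coefficients
    }
  }
  split_tbl <- dplyr::bind_rows(per_split)

  metrics <- c("auc", "sens_95", "sens_90", "ppv_95", "ppv_90")
  performance <- split_tbl |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$variant, .data$metric) |>
    dplyr::reframe(summarise_metric(.data$value)) |>
    dplyr::mutate(metric = factor(.data$metric, levels = metrics)) |>
    dplyr::arrange(.data$variant, .data$metric)

  differences <- NULL
  if (all(c("conventional", "fusion") %in% variants)) {
    wide <- split_tbl |>
      dplyr::filter(.data$variant %in% c("conventional", "fusion")) |>
      tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                          values_to = "value") |>
      tidyr::pivot_wider(id_cols = c("split", "metric"),
                         names_from = "variant", values_from = "value") |>
      dplyr::mutate(diff = .data$fusion - .data$conventional)
    differences <- wide |>
      dplyr::group_by(.data$metric) |>
      dplyr::reframe(summarise_metric(.data$diff)) |>
      dplyr::mutate(metric = factor(.data$metric, levels = metrics)) |>
      dplyr::arrange(.data$metric)
  }

  selection <- lapply(coef_traces, function(tr) {
    summarise_coef_trace(tr, n_splits, freq_threshold, seed)
  })

  structure(list(performance = performance, differences = differences,
                 splits = split_tbl, selection = selection,
                 case_counts = split_tbl |>
                   dplyr::distinct(.data$split, .data$cases_test),
                 notes = notes, seed = seed, n_splits = n_splits),
            class = "performance_summary")
}

summarise_coef_trace <- function(traces, n_repeats, freq_threshold, seed) {
  features <- unique(unlist(lapply(traces, names)))
  mat <- matrix(0, n_repeats, length(features),
                dimnames = list(NULL, features))
  for (r in seq_along(traces)) mat[r, names(traces[[r]])] <- traces[[r]]
  selected <- mat != 0
  n_sel <- colSums(selected)
  mean_coef <- vapply(seq_along(features), function(j) {
    v <- mat[selected[, j], j]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  sd_coef <- vapply(seq_along(features), function(j) {
    v <- mat[selected[, j], j]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))
  out <- tibble::tibble(feature = features,
                        is_covariate = features %in% c("age", "sex"),
                        n_selected = as.integer(n_sel),
                        frequency = unname(n_sel) / n_repeats,
                        mean_coef = mean_coef, sd_coef = sd_coef,
                        mean_odds = exp(mean_coef),
                        kept = unname(n_sel) / n_repeats >= freq_threshold)
  attr(out, "n_repeats") <- n_repeats
  attr(out, "freq_threshold") <- freq_threshold
  attr(out, "seed") <- seed
  class(out) <- c("selection_summary", class(out))
  out
}

#' @exportS3Method base::print
print.performance_summary <- function(x, ...) {
  cat(sprintf("performance_summary over %d splits (seed %d)\n",
              x$n_splits, x$seed))
  print(tidyr::pivot_wider(
    dplyr::mutate(x$performance,
                  cell = sprintf("%.3f (%.3f, %.3f)", .data$mean,
                                 .data$ci_lo, .data$ci_hi)),
    id_cols = "variant", names_from = "metric", values_from = "cell"))
  if (!is.null(x$differences)) {
    cat("fusion - conventional (paired):\n")
    print(x$differences)
  }
  invisible(x)
}

is_fused_name <- function(x) {
  grepl(" \\((r|rw|d|dw), \\d+\\)$", x)
}

parse_fused_name <- function(x) {
  m <- regmatches(x, regexec("^(.*) \\((r|rw|d|dw), (\\d+)\\)$", x))
  tibble::tibble(
    column = x,
    feature = vapply(m, function(g) if (length(g) == 4) g[2] else NA_character_,
                     character(1)),
    method = vapply(m, function(g) if (length(g) == 4) g[3] else NA_character_,
                    character(1)),
    k = vapply(m, function(g) if (length(g) == 4) as.integer(g[4]) else NA_integer_,
               integer(1)))
}

#' Compare the cases identified by two prediction rules
#'
#' Partitions the cases (true events) into four groups — flagged by both
#' rules, by rule A only, by rule B only, or by neither — and compares
#' every supplied feature across the groups: one-way ANOVA for continuous
#' features, chi-square for binary/categorical ones. Features whose
#' omnibus p-value falls below `alpha` get the A-only versus B-only
#' contrast; contrasts on fused-feature columns (names matching the
#' `"(method, k)"` convention, or `fused_cols`) are judged at the
#' family-corrected threshold `alpha / family_size`.
#'
#' @param pred_a,pred_b Logical predicted-positive flags aligned with the
#'   rows of `case_features` (e.g. conventional and fusion model top-decile
#'   flags restricted to the cases).
#' @param case_features Data frame of features for the case subjects.
#' @param family_size Number of related fused versions per feature family
#'   (default 20 = 4 methods x 5 ranks).
#' @param alpha Overall significance level (default 0.05).
#' @param fused_cols Optional character vector naming the fused columns;
#'   by default inferred from the naming convention.
#' @return A list classed `"case_overlap"`: `groups` (counts per group)
#'   and `features` (per-feature tibble with group statistics, test type,
#'   omnibus and contrast p-values, the threshold applied and the
#'   significance flag).
#' @export
case_overlap_comparison <- function(pred_a, pred_b, case_features,
                                    family_size = 20, alpha = 0.05,
                                    fused_cols = NULL) {
  stopifnot(length(pred_a) == nrow(case_features),
            length(pred_b) == nrow(case_features))
  pred_a <- as.logical(pred_a); pred_b <- as.logical(pred_b)
  group <- dplyr::case_when(
    pred_a & pred_b ~ "both",
    pred_a & !pred_b ~ "a_only",
    !pred_a & pred_b ~ "b_only",
    TRUE ~ "neither")
  group <- factor(group, levels = c("both", "a_only", "b_only", "neither"))
  group_counts <- as.integer(table(group))
  groups <- tibble::tibble(group = levels(group), n = group_counts)
  if (is.null(fused_cols)) {
    fused_cols <- names(case_features)[is_fused_name(names(case_features))]
  }
  corrected <- alpha / family_size

  rows <- lapply(names(case_features), function(f) {
    x <- case_features[[f]]
    is_binary <- length(unique(x[!is.na(x)])) <= 2
    stat_by <- tapply(x, group, function(v) mean(v, na.rm = TRUE))
    sd_by <- tapply(x, group, function(v) stats::sd(v, na.rm = TRUE))
    use <- !is.na(x)
    g_use <- droplevels(group[use])
    enough <- length(levels(g_use)) >= 2 &&
      all(table(g_use) >= 2) && stats::sd(x[use]) > 0
    omnibus_p <- NA_real_
    test <- if (is_binary) "chi-square" else "anova"
    if (enough) {
      omnibus_p <- if (is_binary) {
        suppressWarnings(stats::chisq.test(table(g_use, x[use]))$p.value)
      } else {
        stats::anova(stats::aov(x[use] ~ g_use))[["Pr(>F)"]][1]
      }
    } else {
      test <- paste0(test, " (skipped)")
    }
    contrast_p <- NA_real_
    ab <- use & group %in% c("a_only", "b_only")
    if (!is.na(omnibus_p) && omnibus_p < alpha &&
        sum(group[ab] == "a_only") >= 2 && sum(group[ab] == "b_only") >= 2) {
      contrast_p <- if (is_binary) {
        tab <- table(droplevels(group[ab]), x[ab])
        if (all(dim(tab) == 2)) {
          suppressWarnings(stats::chisq.test(tab)$p.value)
        } else NA_real_
      } else if (stats::sd(x[ab]) > 0) {
        stats::t.test(x[ab] ~ droplevels(group[ab]))$p.value
      } else NA_real_
    }
    threshold <- if (f %in% fused_cols) corrected else alpha
    tibble::tibble(
      feature = f, test = test,
      stat_both = stat_by[["both"]], stat_a_only = stat_by[["a_only"]],
      stat_b_only = stat_by[["b_only"]], stat_neither = stat_by[["neither"]],
      sd_both = sd_by[["both"]], sd_a_only = sd_by[["a_only"]],
      sd_b_only = sd_by[["b_only"]], sd_neither = sd_by[["neither"]],
      omnibus_p = omnibus_p, contrast_p = contrast_p,
      threshold = threshold,
      significant = !is.na(contrast_p) & contrast_p < threshold)
  })
  structure(list(groups = groups,
                 features = dplyr::bind_rows(rows),
                 alpha = alpha, family_size = family_size,
                 corrected_threshold = corrected),
            class = "case_overlap")
}

#' Marginal importance ranking of fused SDoH features
#'
#' Enters each fused candidate column, one at a time, into a full-data
#' logistic regression controlling for age, sex and the screened diagnosis
#' indicators; FDR-adjusts the per-column p-values; and, per underlying
#' SDoH feature, reports the best (method, k) version under the
#' lexicographic rule: smallest adjusted p-value, then largest absolute
#' coefficient, then largest selection frequency. Non-convergent columns
#' rank last with a flag.
#'
#' @param target Target cohort tibble.
#' @param fused A `"fused_features"` tibble row-aligned with `target`.
#' @param dx_covariates Character vector of screened diagnosis columns to
#'   control for (may be empty).
#' @param selection Optional `"selection_summary"` whose per-column
#'   selection counts are attached and used as the final tie-break.
#' @return A tibble classed `"importance_ranking"` with exactly one row
#'   per SDoH feature: best `method` and `k`, `log_odds`, `se`,
#'   `p_value`, `p_adjusted`, `n_selected`, ordered by the ranking rule.
#' @export
rank_fused_importance <- function(target, fused, dx_covariates = character(),
                                  selection = NULL) {
  roles <- cohort_roles(target)
  tdat <- as.data.frame(target)
  y <- as.numeric(tdat[[roles$outcome]])
  grid <- fusion_grid(fused)
  covs <- cbind(age = as.numeric(tdat[[roles$age]]),
                sex = as.numeric(tdat[[roles$sex]]))
  if (length(dx_covariates) > 0) {
    covs <- cbind(covs, as.matrix(tdat[, dx_covariates, drop = FALSE]))
  }
  Xf <- normalize_unit(as.matrix(as.data.frame(fused)))
  scr <- marginal_screen(unclass_matrix(Xf), y, covs, alpha = 1)

  res <- dplyr::left_join(grid,
                          dplyr::rename(scr, column = "feature"),
                          by = "column")
  if (!is.null(selection)) {
    res <- dplyr::left_join(
      res,
      dplyr::select(tibble::as_tibble(selection), column = "feature",
                    n_selected = "n_selected"),
      by = "column")
    res$n_selected[is.na(res$n_selected)] <- 0L
  } else {
    res$n_selected <- NA_integer_
  }
  res <- res |>
    dplyr::mutate(
      unstable = .data$status != "ok",
      p_rank = ifelse(.data$unstable, Inf, .data$p_adjusted),
      abs_coef = ifelse(.data$unstable, -Inf, abs(.data$estimate))) |>
    dplyr::arrange(.data$p_rank, dplyr::desc(.data$abs_coef),
                   dplyr::desc(.data$n_selected))
  best <- res |>
    dplyr::group_by(.data$feature) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_rank, dplyr::desc(.data$abs_coef),
                   dplyr::desc(.data$n_selected)) |>
    dplyr::transmute(feature = .data$feature, method = .data$method,
                     k = .data$k, column = .data$column,
                     log_odds = .data$estimate, se = .data$se,
                     p_value = .data$p_value,
                     p_adjusted = .data$p_adjusted,
                     n_selected = .data$n_selected,
                     unstable = .data$unstable)
  class(best) <- c("importance_ranking", class(best))
  best
}
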