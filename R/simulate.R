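#' Configuration for the linked-cohort simulator
#'
#' Defines the shape and signal structure of a pair of linked cohorts: a
#' clinical target cohort (diagnosis indicators and outcome only) and a
#' survey source cohort that additionally carries social-determinant (SDoH)
#' columns. Both cohorts share a latent vector `z` per subject that drives
#' the shared diagnosis indicators and the SDoH values, so that similarity
#' on the shared block is informative about a subject's unobserved SDoH —
#' the precondition cross-cohort fusion relies on.
#'
#' Outcomes are Bernoulli with a logit linear in a subset of diagnosis
#' indicators and (in both cohorts) the subject's own SDoH values; in the
#' target the SDoH values exist but are withheld from the emitted table.
#' Intercepts are calibrated so realized case rates match the configured
#' rates. Default case rates (1.24% target, 3.54% source) and the ~1.2%
#' SDoH missingness mirror the cohort descriptions the package emulates.
#'
#' @param n_target,n_source Cohort sizes.
#' @param n_shared_dx Number of shared (mock) diagnosis indicators.
#' @param n_target_only_dx Number of diagnosis categories present only in
#'   the target cohort. These are idiosyncratic clinical events outside the
#'   latent social axis: independent Bernoulli draws, of which the first
#'   `n_signal_dx` carry direct outcome effects.
#' @param n_sdoh Number of SDoH features in the source cohort.
#' @param n_informative_sdoh How many SDoH features carry outcome signal
#'   (alternating protective/risk signs).
#' @param latent_dim Dimension of the shared latent vector.
#' @param effect_latent_dx Norm of each diagnosis indicator's latent loading
#'   (log-odds scale).
#' @param effect_latent_sdoh Norm of each informative SDoH feature's
#'   latent loading (SDoH residual noise has standard deviation 0.8).
#' @param effect_latent_sdoh_noise Latent loading norm of the
#'   non-informative SDoH features; smaller by default, reflecting that
#'   outcome-relevant social determinants tend to be the ones aligned with
#'   the shared comorbidity axis.
#' @param effect_sdoh_outcome Absolute log-odds effect of each informative
#'   SDoH value on the outcome.
#' @param effect_dx_outcome Log-odds effect of each signal-carrying
#'   target-only diagnosis indicator (the first `n_signal_dx` of them).
#' @param effect_shared_dx_outcome Direct log-odds effect of the first
#'   `n_signal_dx` shared indicators. Defaults to 0: the shared (mock)
#'   conditions influence the outcome only through the latent axis they
#'   share with the SDoH features, while the target-only diagnosis
#'   categories carry the direct clinical signal.
#' @param n_signal_dx Number of indicators (per block) given a direct
#'   outcome effect.
#' @param target_case_rate,source_case_rate Desired outcome prevalences.
#' @param sdoh_missing_rate Completely-at-random missingness applied to the
#'   emitted source SDoH columns.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list classed `"sim_config"`.
#' @export
sim_config <- function(n_target = 4000, n_source = 2000,
                       n_shared_dx = 40, n_target_only_dx = 80,
                       n_sdoh = 23, n_informative_sdoh = 2,
                       latent_dim = 2,
                       effect_latent_dx = 0.3,
                       effect_latent_sdoh = 1.3,
                       effect_latent_sdoh_noise = 0.1,
                       effect_sdoh_outcome = 2.0,
                       effect_dx_outcome = 1.2,
                       effect_shared_dx_outcome = 0,
                       n_signal_dx = 12,
                       target_case_rate = 0.0124,
                       source_case_rate = 0.0354,
                       sdoh_missing_rate = 0.012,
                       seed = 1) {
  cfg <- list(n_target = n_target, n_source = n_source,
              n_shared_dx = n_shared_dx, n_target_only_dx = n_target_only_dx,
              n_sdoh = n_sdoh, n_informative_sdoh = n_informative_sdoh,
              latent_dim = latent_dim,
              effect_latent_dx = effect_latent_dx,
              effect_latent_sdoh = effect_latent_sdoh,
              effect_latent_sdoh_noise = effect_latent_sdoh_noise,
              effect_sdoh_outcome = effect_sdoh_outcome,
              effect_dx_outcome = effect_dx_outcome,
              effect_shared_dx_outcome = effect_shared_dx_outcome,
              n_signal_dx = n_signal_dx,
              target_case_rate = target_case_rate,
              source_case_rate = source_case_rate,
              sdoh_missing_rate = sdoh_missing_rate,
              seed = as.integer(seed))
  counts <- cfg[c("n_target", "n_source", "n_shared_dx", "n_target_only_dx",
                  "n_sdoh", "latent_dim")]
  if (any(unlist(counts) < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (cfg$n_informative_sdoh > cfg$n_sdoh) {
    stop("n_informative_sdoh must not exceed n_sdoh", call. = FALSE)
  }
  rates <- c(cfg$target_case_rate, cfg$source_case_rate)
  if (any(rates <= 0 | rates >= 0.5)) {
    stop("case rates must lie in (0, 0.5)", call. = FALSE)
  }
  if (cfg$sdoh_missing_rate < 0 || cfg$sdoh_missing_rate >= 1) {
    stop("sdoh_missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' A null simulator configuration
#'
#' All effect sizes set to zero, so the outcome is independent of every
#' feature; any model's expected out-of-sample AUC is 0.5.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `"sim_config"`.
#' @export
sim_config_null <- function(...) {
  sim_config(effect_latent_dx = 0, effect_latent_sdoh = 0,
             effect_latent_sdoh_noise = 0,
             effect_sdoh_outcome = 0, effect_dx_outcome = 0,
             effect_shared_dx_outcome = 0, ...)
}

#' Calibrate a logistic intercept to a desired event rate
#'
#' Finds `a` such that `mean(plogis(a + eta))` equals `rate`, by monotone
#' root-finding.
#'
#' @param eta Vector of linear predictors (without intercept).
#' @param rate Desired mean event probability, in (0, 1).
#' @param tol Convergence tolerance on the mean probability.
#' @return The intercept (a scalar).
#' @export
calibrate_intercept <- function(eta, rate, tol = 1e-9) {
  if (rate <= 0 || rate >= 1) stop("rate must be in (0, 1)", call. = FALSE)
  f <- function(a) mean(stats::plogis(a + eta)) - rate
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0) {
    stop("cannot calibrate intercept to rate ", rate,
         ": linear predictors too extreme; use weaker effects", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

unit_rows <- function(n, d) {
  # random directions of unit norm, one per row
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

#' Simulate linked target and source cohorts
#'
#' Draws both cohorts from the shared-latent-factor model described in
#' [sim_config()]. The emitted target table contains no SDoH columns (the
#' subject's true SDoH values are withheld into the ground truth); the
#' source table contains all of them, with completely-at-random missingness
#' at the configured rate.
#'
#' @param config A [sim_config()].
#' @return A list classed `"linked_cohorts"` with elements:
#'   * `target` — target cohort tibble (id, age, sex, `dx_*`, outcome),
#'   * `source` — source cohort tibble (id, age, sex, shared `dx_*`,
#'     `sdoh_*`, outcome),
#'   * `shared_map` — [shared_feature_spec()] covering age, sex and the
#'     shared diagnosis indicators,
#'   * `truth` — ground truth: generative coefficients, informative SDoH
#'     names with signed effects, per-subject latent vectors, the withheld
#'     target SDoH matrix, and calibrated intercepts.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  d <- cfg$latent_dim
  shared_dx_names <- sprintf("dx_s%02d", seq_len(cfg$n_shared_dx))
  target_dx_names <- sprintf("dx_t%02d", seq_len(cfg$n_target_only_dx))
  sdoh_names <- sprintf("sdoh_%02d", seq_len(cfg$n_sdoh))

  # structural coefficients, drawn once and shared by both cohorts
  b_shared <- cfg$effect_latent_dx * unit_rows(cfg$n_shared_dx, d)
  b_tonly <- matrix(0, cfg$n_target_only_dx, d) # latent-free clinical events
  prev_shared <- stats::runif(cfg$n_shared_dx, 0.05, 0.35)
  prev_tonly <- stats::runif(cfg$n_target_only_dx, 0.02, 0.25)
  # noise SDoH: weak random loadings; informative SDoH: each anchored to
  # its own latent domain (axis-aligned), so planted features carry
  # distinct transferable signals rather than collinear proxies
  sdoh_load <- cfg$effect_latent_sdoh_noise * unit_rows(cfg$n_sdoh, d)
  for (f in seq_len(cfg$n_informative_sdoh)) {
    axis <- rep(0, d)
    axis[(f - 1L) %% d + 1L] <- 1
    sdoh_load[f, ] <- cfg$effect_latent_sdoh * axis
  }
  sdoh_noise_sd <- 0.8

  inf_idx <- seq_len(cfg$n_informative_sdoh)
  sdoh_sign <- rep(0, cfg$n_sdoh)
  if (cfg$n_informative_sdoh > 0) {
    sdoh_sign[inf_idx] <- rep_len(c(1, -1), cfg$n_informative_sdoh)
  }
  sdoh_beta <- sdoh_sign * cfg$effect_sdoh_outcome

  k_sig <- min(cfg$n_signal_dx, cfg$n_shared_dx)
  k_sig_t <- min(cfg$n_signal_dx, cfg$n_target_only_dx)
  dx_beta_shared <- c(rep(cfg$effect_shared_dx_outcome, k_sig),
                      rep(0, cfg$n_shared_dx - k_sig))
  dx_beta_tonly <- c(rep(cfg$effect_dx_outcome, k_sig_t),
                     rep(0, cfg$n_target_only_dx - k_sig_t))

  draw_cohort <- function(n, rate, with_target_only, ages) {
    z <- matrix(stats::rnorm(n * d), n, d)
    age <- sample(ages, n, replace = TRUE)
    sex <- stats::rbinom(n, 1, 0.5)
    dx_s <- draw_dx(z, b_shared, prev_shared)
    dx_t <- if (with_target_only) draw_dx(z, b_tonly, prev_tonly) else NULL
    sdoh <- z %*% t(sdoh_load) +
      matrix(stats::rnorm(n * cfg$n_sdoh, sd = sdoh_noise_sd), n, cfg$n_sdoh)
    colnames(sdoh) <- sdoh_names
    eta <- drop(dx_s %*% dx_beta_shared) + drop(sdoh %*% sdoh_beta)
    if (with_target_only) eta <- eta + drop(dx_t %*% dx_beta_tonly)
    a <- calibrate_intercept(eta, rate)
    outcome <- stats::rbinom(n, 1, stats::plogis(a + eta))
    list(z = z, age = age, sex = sex, dx_s = dx_s, dx_t = dx_t,
         sdoh = sdoh, outcome = outcome, intercept = a)
  }

  tgt <- draw_cohort(cfg$n_target, cfg$target_case_rate, TRUE, 10:24)
  src <- draw_cohort(cfg$n_source, cfg$source_case_rate, FALSE, 10:20)

  colnames(tgt$dx_s) <- colnames(src$dx_s) <- shared_dx_names
  colnames(tgt$dx_t) <- target_dx_names

  target <- tibble::as_tibble(cbind(
    data.frame(subject_id = sprintf("T%05d", seq_len(cfg$n_target)),
               age = tgt$age, sex = tgt$sex),
    as.data.frame(tgt$dx_s), as.data.frame(tgt$dx_t),
    data.frame(outcome = tgt$outcome)))

  sdoh_emit <- src$sdoh
  if (cfg$sdoh_missing_rate > 0) {
    mask <- matrix(stats::runif(length(sdoh_emit)) < cfg$sdoh_missing_rate,
                   nrow(sdoh_emit), ncol(sdoh_emit))
    sdoh_emit[mask] <- NA_real_
  }
  source <- tibble::as_tibble(cbind(
    data.frame(subject_id = sprintf("S%05d", seq_len(cfg$n_source)),
               age = src$age, sex = src$sex),
    as.data.frame(src$dx_s), as.data.frame(sdoh_emit),
    data.frame(outcome = src$outcome)))

  shared_map <- shared_feature_spec(
    target_cols = c("age", "sex", shared_dx_names),
    source_cols = c("age", "sex", shared_dx_names))

  truth <- list(
    config = cfg,
    informative_sdoh = tibble::tibble(
      feature = sdoh_names[inf_idx],
      sign = sdoh_sign[inf_idx],
      effect = sdoh_beta[inf_idx]),
    dx_effects = tibble::tibble(
      feature = c(shared_dx_names, target_dx_names),
      effect = c(dx_beta_shared, dx_beta_tonly)),
    sdoh_loadings = sdoh_load,
    latent_target = tgt$z,
    latent_source = src$z,
    target_sdoh_withheld = tgt$sdoh,
    intercepts = c(target = tgt$intercept, source = src$intercept))

  structure(list(target = target, source = source,
                 shared_map = shared_map, truth = truth),
            class = "linked_cohorts")
}

draw_dx <- function(z, loadings, prev) {
  eta <- z %*% t(loadings)
  p <- stats::plogis(sweep(eta, 2, stats::qlogis(prev), "+"))
  matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write simulated cohorts to disk
#'
#' Emits `target.csv`, `source.csv`, `shared_map.csv` and `truth.json`
#' into a directory, the on-disk form consumed by [read_cohort()] and
#' [read_shared_map()].
#'
#' @param sim A `"linked_cohorts"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  stopifnot(inherits(sim, "linked_cohorts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$target, file.path(dir, "target.csv"), progress = FALSE)
  readr::write_csv(sim$source, file.path(dir, "source.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(feature = sim$shared_map$feature,
                   target_column = sim$shared_map$target_col,
                   source_column = sim$shared_map$source_col),
    file.path(dir, "shared_map.csv"), progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- sim$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
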