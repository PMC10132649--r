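# Shared fixtures, built in code at test time.

toy_target <- function() {
  tibble::tibble(
    subject_id = paste0("T", 1:6),
    age = c(12L, 15L, 18L, 21L, 14L, 19L),
    sex = c(0, 1, 0, 1, 1, 0),
    dx_a = c(1, 0, 1, 0, 0, 1),
    dx_b = c(0, 0, 1, 1, 0, 0),
    outcome = c(0, 0, 1, 0, 1, 0))
}

toy_source <- function() {
  tibble::tibble(
    subject_id = paste0("S", 1:5),
    age = c(11L, 16L, 19L, 13L, 17L),
    sex = c(1, 0, 0, 1, 0),
    dx_a = c(0, 1, 1, 0, 0),
    dx_b = c(1, 0, 0, 0, 1),
    sdoh_support = c(4.5, 2.0, NA, 3.5, 1.0),
    sdoh_safety = c(0.9, 0.4, 0.7, NA, 0.2),
    outcome = c(0, 1, 0, 0, 1))
}

toy_shared_map <- function() {
  shared_feature_spec(target_cols = c("age", "sex", "dx_a", "dx_b"),
                      source_cols = c("age", "sex", "dx_a", "dx_b"))
}

# A small linked-cohort pipeline fixture, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (!is.null(.fixture_env$pipe)) return(.fixture_env$pipe)
  cfg <- sim_config(n_target = 1200, n_source = 600,
                    target_case_rate = 0.12, source_case_rate = 0.15,
                    seed = 401)
  sim <- simulate_cohorts(cfg)
  target <- as_cohort(sim$target, "target")
  source <- impute_sdoh(as_cohort(sim$source, "source"))
  fz <- fuse_cohorts(target, source, sim$shared_map,
                     sdoh_features = c("sdoh_01", "sdoh_02", "sdoh_05"),
                     methods = c("r", "d"), k_grid = c(10, 50),
                     seed = 401)
  .fixture_env$pipe <- list(sim = sim, target = target, source = source,
                            fused = fz$fused, weights = fz$weights,
                            sims = fz$sims, shared = fz$shared)
  .fixture_env$pipe
}

# Brute-force oracles -------------------------------------------------------

# textbook step-up FDR adjustment, written independently of the package
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    idx <- o[i]
    rank_i <- m - i + 1
    running <- min(running, m / rank_i * p[idx])
    adj[i] <- min(running, 1)
  }
  adj[ro]
}

# AUC by exhaustive enumeration of case-control pairs
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# sensitivity/PPV at fixed specificity by exhaustive threshold sweep
sens_ppv_oracle <- function(scores, labels, level) {
  cand <- sort(unique(c(scores, max(scores) + 1)))
  best <- NULL
  for (t in cand) {
    spec <- mean(scores[labels == 0] < t)
    if (spec >= level) { best <- t; break }
  }
  pos <- scores >= best
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  list(threshold = best,
       sensitivity = tp / sum(labels == 1),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# naive per-pair similarity loop
similarity_oracle <- function(X, Y, method, w) {
  n <- nrow(X); m <- nrow(Y)
  S <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i, j] <- if (method %in% c("d", "dw")) {
      sum(w * abs(X[i, ] - Y[j, ]))
    } else {
      wn <- w / sum(w)
      xc <- X[i, ] - sum(wn * X[i, ]); yc <- Y[j, ] - sum(wn * Y[j, ])
      sum(wn * xc * yc) / sqrt(sum(wn * xc^2) * sum(wn * yc^2))
    }
  }
  S
}
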