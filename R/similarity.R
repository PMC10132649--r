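#' Outcome-driven importance weights for the shared features
#'
#' Fits an elastic-net logistic model of the outcome on the shared features
#' in the source cohort; the weight of each shared feature is the absolute
#' value of its coefficient, renormalized to sum to one. When the penalized
#' fit shrinks every coefficient to zero the weights fall back to uniform
#' with a warning, so downstream weighted similarities reduce to their
#' unweighted forms.
#'
#' @param source_shared Source-side shared feature matrix on the unit scale
#'   (from [build_shared_matrices()]).
#' @param y Binary outcome of the source cohort.
#' @param seed Seed for the cross-validated fit.
#' @param ... Passed to [fit_elastic_net()].
#' @return A tibble classed `"importance_weights"` with columns `feature`
#'   and `weight` (non-negative, summing to 1), and a `provenance`
#'   attribute describing the source model.
#' @export
importance_weights <- function(source_shared, y, seed = 1, ...) {
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  fit <- fit_elastic_net(source_shared, y, seed = seed, ...)
  w <- abs(fit$coefficients)
  uniform_fallback <- sum(w) == 0
  if (uniform_fallback) {
    warning("all shared-feature coefficients are zero; ",
            "falling back to uniform weights", call. = FALSE)
    w[] <- 1
  }
  out <- tibble::tibble(feature = names(w), weight = unname(w / sum(w)))
  attr(out, "provenance") <- list(
    model = "elastic-net logistic fit of outcome on shared features (source cohort)",
    lambda = fit$lambda, enet_alpha = fit$enet_alpha, seed = seed,
    uniform_fallback = uniform_fallback)
  class(out) <- c("importance_weights", class(out))
  out
}

as_weight_vector <- function(w, features = NULL) {
  if (inherits(w, "importance_weights") || is.data.frame(w)) {
    v <- stats::setNames(w$weight, w$feature)
  } else {
    v <- w
  }
  if (!is.null(features)) {
    if (!is.null(names(v)) && all(features %in% names(v))) {
      v <- v[features]
    } else if (length(v) != length(features)) {
      stop("weights do not align with the shared features", call. = FALSE)
    }
  }
  if (any(v < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(v) <= 0) stop("at least one weight must be positive", call. = FALSE)
  unname(v)
}

#' Weighted Manhattan distance between two feature vectors
#'
#' `sum(w * abs(x - y))`. With uniform weights `1/J` this equals the plain
#' Manhattan distance divided by the number of features; rescaling all
#' weights by a positive constant rescales the distance without changing
#' neighbour rankings.
#'
#' @param x,y Equal-length numeric vectors.
#' @param w Non-negative weights aligned with `x` (an
#'   [importance_weights()] tibble is accepted).
#' @return The distance (lower = more similar).
#' @export
weighted_manhattan <- function(x, y, w) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  w <- as_weight_vector(w)
  if (length(w) != length(x)) stop("weights must align with x",
                                   call. = FALSE)
  sum(w * abs(x - y))
}

#' Weighted Pearson correlation between two feature vectors
#'
#' Centers both vectors at their weighted means and correlates with weights:
#' `r_w = sum(w (x - xbar_w)(y - ybar_w)) / sqrt(sum(w (x - xbar_w)^2) *
#' sum(w (y - ybar_w)^2))`. Uniform weights reduce it exactly to the
#' ordinary Pearson correlation. A vector with zero weighted variance has
#' no defined correlation; such a pair is assigned the worst similarity
#' (-1) with a warning.
#'
#' @inheritParams weighted_manhattan
#' @param center `"weighted"` (default) centers at weighted means;
#'   `"unweighted"` centers at plain means.
#' @return The correlation in `[-1, 1]` (higher = more similar).
#' @export
weighted_pearson <- function(x, y, w, center = c("weighted", "unweighted")) {
  center <- match.arg(center)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  w <- as_weight_vector(w)
  if (length(w) != length(x)) stop("weights must align with x", call. = FALSE)
  w <- w / sum(w)
  if (center == "weighted") {
    xc <- x - sum(w * x); yc <- y - sum(w * y)
  } else {
    xc <- x - mean(x); yc <- y - mean(y)
  }
  vx <- sum(w * xc^2); vy <- sum(w * yc^2)
  if (vx <= 0 || vy <= 0) {
    warning("zero weighted variance; assigning similarity -1", call. = FALSE)
    return(-1)
  }
  min(1, max(-1, sum(w * xc * yc) / sqrt(vx * vy)))
}

#' Pairwise target-by-source similarity matrix
#'
#' Computes all `n_target x n_source` outcome-specific similarities over
#' the shared features under one of four methods, following the shorthand
#' `r` (Pearson), `rw` (weighted Pearson), `d` (Manhattan distance), `dw`
#' (weighted Manhattan). Unweighted methods use uniform weights `1/J`, so
#' `r` is the ordinary Pearson correlation and `d` the Manhattan distance
#' scaled by `1/J` — with identical neighbour rankings to the plain
#' distance. Degenerate Pearson pairs (zero weighted variance on either
#' side) are assigned -1 and counted, never erroring.
#'
#' @param target_shared,source_shared Aligned shared-feature matrices
#'   (identical column order) from [build_shared_matrices()].
#' @param method One of `"r"`, `"rw"`, `"d"`, `"dw"`.
#' @param weights Required for `rw`/`dw`: an [importance_weights()] tibble
#'   or non-negative vector aligned with the shared columns.
#' @param center Passed to the weighted Pearson computation.
#' @param block_size Target rows processed per block (memory control only;
#'   results do not depend on it).
#' @return A dense `n_target x n_source` matrix classed
#'   `"similarity_matrix"` with attributes `method`, `higher_is_similar`
#'   and `n_degenerate` (count of -1-assigned Pearson pairs).
#' @export
similarity_matrix <- function(target_shared, source_shared,
                              method = c("r", "rw", "d", "dw"),
                              weights = NULL,
                              center = c("weighted", "unweighted"),
                              block_size = 1024L) {
  method <- match.arg(method)
  center <- match.arg(center)
  X <- as.matrix(target_shared); Y <- as.matrix(source_shared)
  if (ncol(X) != ncol(Y)) stop("shared columns are not aligned",
                               call. = FALSE)
  J <- ncol(X)
  if (method %in% c("r", "d")) {
    w <- rep(1 / J, J)
  } else {
    if (is.null(weights)) stop("method '", method, "' requires weights",
                               call. = FALSE)
    w <- as_weight_vector(weights, colnames(X))
  }

  if (method %in% c("r", "rw")) {
    wn <- w / sum(w)
    if (center == "weighted") {
      Xc <- X - drop(X %*% wn); Yc <- Y - drop(Y %*% wn)
    } else {
      Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
    }
    Xw <- sweep(Xc, 2, wn, "*")
    sx <- sqrt(rowSums(Xw * Xc))
    sy <- sqrt(rowSums(sweep(Yc, 2, wn, "*") * Yc))
    S <- Xw %*% t(Yc)
    denom <- outer(sx, sy)
    degenerate <- denom <= 0
    denom[degenerate] <- 1
    S <- S / denom
    S[S > 1] <- 1; S[S < -1] <- -1
    S[degenerate] <- -1
    n_degenerate <- sum(degenerate)
    higher <- TRUE
  } else {
    n_t <- nrow(X)
    S <- matrix(0, n_t, nrow(Y))
    starts <- seq(1L, n_t, by = block_size)
    for (s in starts) {
      rows <- s:min(s + block_size - 1L, n_t)
      acc <- matrix(0, length(rows), nrow(Y))
      for (j in seq_len(J)) {
        if (w[j] == 0) next
        acc <- acc + w[j] * abs(outer(X[rows, j], Y[, j], "-"))
      }
      S[rows, ] <- acc
    }
    n_degenerate <- 0L
    higher <- FALSE
  }
  structure(S, method = method, higher_is_similar = higher,
            n_degenerate = n_degenerate, class = "similarity_matrix")
}

#' @exportS3Method base::print
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%d x %d], method '%s' (%s)\n",
              nrow(x), ncol(x), attr(x, "method"),
              if (attr(x, "higher_is_similar")) "higher = more similar"
              else "lower = more similar"))
  if (attr(x, "n_degenerate") > 0) {
    cat("  degenerate pairs assigned -1:", attr(x, "n_degenerate"), "\n")
  }
  invisible(x)
}
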