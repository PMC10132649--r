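#' Indices of the k most similar source participants
#'
#' Orders one row of a similarity matrix under its orientation and returns
#' the first `k` source indices. Ties are broken by ascending source index,
#' so the result is deterministic.
#'
#' @param sim_row Numeric vector of similarity scores for one target
#'   patient.
#' @param k Number of matches, `k <= length(sim_row)`.
#' @param higher_is_similar `TRUE` for correlation-type scores, `FALSE`
#'   for distances.
#' @return Integer vector of `k` source indices, most similar first.
#' @export
top_k_indices <- function(sim_row, k, higher_is_similar = TRUE) {
  if (k > length(sim_row)) {
    stop("k (", k, ") exceeds the number of source participants (",
         length(sim_row), ")", call. = FALSE)
  }
  key <- if (higher_is_similar) -sim_row else sim_row
  order(key, seq_along(sim_row))[seq_len(k)]
}

#' Fuse one source feature into the target cohort
#'
#' For every target patient, averages the source feature over that
#' patient's `k` top-ranked source matches (unweighted arithmetic mean).
#'
#' @param sim A [similarity_matrix()].
#' @param source_values Complete numeric vector of the source feature
#'   (post-imputation), one value per source participant.
#' @param k Number of top matches to average.
#' @return Numeric vector of fused values, one per target patient; each
#'   value lies within the observed range of `source_values`.
#' @export
fuse_feature <- function(sim, source_values, k) {
  stopifnot(length(source_values) == ncol(sim))
  if (anyNA(source_values)) {
    stop("source feature has missing values; impute before fusing",
         call. = FALSE)
  }
  higher <- attr(sim, "higher_is_similar")
  if (is.null(higher)) higher <- TRUE
  apply(unclass(sim), 1, function(row) {
    mean(source_values[top_k_indices(row, k, higher)])
  })
}

#' Expand the full fused-candidate grid
#'
#' Generates every fused version of the selected source SDoH features over
#' the similarity-method x top-k grid: one column per (feature, method, k)
#' combination, named `"<feature> (<method>, <k>)"`. With 12 selected
#' features, 4 methods and the default 5-point k grid this yields 240
#' candidate columns.
#'
#' @param sims Named list of [similarity_matrix()] objects, one per
#'   requested method (names among `"r"`, `"rw"`, `"d"`, `"dw"`).
#' @param source_values Data frame or matrix of the selected source SDoH
#'   features (complete, raw survey scale), one row per source participant.
#' @param k_grid Ordered vector of match counts (default
#'   `c(10, 20, 50, 100, 200)`); every `k` must not exceed the source size.
#' @return A tibble classed `"fused_features"`, one row per target patient,
#'   with a `fusion_grid` attribute mapping each column to its
#'   (feature, method, k) triple.
#' @export
expand_candidates <- function(sims, source_values,
                              k_grid = c(10, 20, 50, 100, 200)) {
  if (is.null(names(sims)) || any(!nzchar(names(sims)))) {
    stop("'sims' must be a named list of similarity matrices", call. = FALSE)
  }
  bad <- setdiff(names(sims), c("r", "rw", "d", "dw"))
  if (length(bad) > 0) stop("unknown similarity method(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  V <- as.matrix(source_values)
  if (is.null(colnames(V))) colnames(V) <- paste0("sdoh", seq_len(ncol(V)))
  if (anyNA(V)) stop("source SDoH values must be complete (impute first)",
                     call. = FALSE)
  n_source <- nrow(V)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1) || any(k_grid > n_source)) {
    stop("every k must lie in [1, n_source = ", n_source, "]", call. = FALSE)
  }
  max_k <- max(k_grid)

  cols <- list()
  grid <- list()
  for (m in names(sims)) {
    sim <- sims[[m]]
    if (ncol(sim) != n_source) {
      stop("similarity matrix '", m, "' does not match the source size",
           call. = FALSE)
    }
    higher <- attr(sim, "higher_is_similar")
    # rank once per method: top max_k source indices per target patient
    ord <- t(apply(unclass(sim), 1, function(row) {
      top_k_indices(row, max_k, higher)
    }))
    for (f in colnames(V)) {
      vals <- matrix(V[, f][ord], nrow(ord), max_k)
      csum <- t(apply(vals, 1, cumsum))
      for (k in k_grid) {
        nm <- sprintf("%s (%s, %d)", f, m, k)
        cols[[nm]] <- csum[, k] / k
        grid[[nm]] <- tibble::tibble(column = nm, feature = f,
                                     method = m, k = k)
      }
    }
  }
  out <- tibble::as_tibble(cols)
  attr(out, "fusion_grid") <- dplyr::bind_rows(grid)
  class(out) <- c("fused_features", class(out))
  out
}

#' Grid metadata of a fused feature set
#'
#' @param fused A `"fused_features"` tibble.
#' @return Tibble with columns `column`, `feature`, `method`, `k`.
#' @export
fusion_grid <- function(fused) {
  g <- attr(fused, "fusion_grid")
  if (is.null(g)) stop("not a fused feature set: missing 'fusion_grid'",
                       call. = FALSE)
  g
}

#' End-to-end fusion of source SDoH features into a target cohort
#'
#' Convenience pipeline for the transfer step: builds the aligned shared
#' matrices, fits source-side importance weights, computes the similarity
#' matrices for the requested methods, and expands the fused candidate
#' grid for the given SDoH features.
#'
#' @param target,source Cohort tibbles ([as_cohort()]); source SDoH must
#'   be complete (see [impute_sdoh()]).
#' @param shared_map A [shared_feature_spec()].
#' @param sdoh_features Character vector of source SDoH columns to fuse;
#'   defaults to all of them.
#' @param methods Similarity methods to use (default all four).
#' @param k_grid Top-k grid (default `c(10, 20, 50, 100, 200)`).
#' @param seed Seed for the importance-weight model.
#' @return A list: `fused` (the [expand_candidates()] tibble), `weights`,
#'   `sims`, and `shared` (the matrices and bounds).
#' @export
fuse_cohorts <- function(target, source, shared_map,
                         sdoh_features = NULL,
                         methods = c("r", "rw", "d", "dw"),
                         k_grid = c(10, 20, 50, 100, 200), seed = 1) {
  roles <- cohort_roles(source)
  if (is.null(sdoh_features)) sdoh_features <- roles$sdoh
  shared <- build_shared_matrices(target, source, shared_map)
  y_src <- source[[roles$outcome]]
  w <- importance_weights(shared$source, y_src, seed = seed)
  sims <- lapply(stats::setNames(methods, methods), function(m) {
    similarity_matrix(shared$target, shared$source, method = m, weights = w)
  })
  fused <- expand_candidates(
    sims, as.data.frame(source)[, sdoh_features, drop = FALSE],
    k_grid = k_grid)
  list(fused = fused, weights = w, sims = sims, shared = shared)
}
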