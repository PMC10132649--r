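#' Read and validate a cohort table
#'
#' Loads a delimited cohort file and validates it as either a clinical
#' *target* cohort (demographics, binary diagnosis-category indicators and a
#' binary outcome) or a survey *source* cohort (demographics, mock diagnosis
#' indicators, numeric social-determinant columns and a binary outcome).
#' Column roles are inferred from prefixes: diagnosis indicators start with
#' `dx_` and social-determinant columns with `sdoh_`.
#'
#' @param path Path to a CSV file with a header row. Missing values may be
#'   empty cells or `"NA"`.
#' @param side `"target"` or `"source"`.
#' @param id_col,age_col,sex_col,outcome_col Names of the identifier, age,
#'   sex and outcome columns.
#' @param dx_prefix,sdoh_prefix Prefixes identifying diagnosis-indicator and
#'   social-determinant columns.
#' @return A tibble classed `"target_cohort"` or `"source_cohort"` with a
#'   `cohort_roles` attribute listing the column roles.
#' @export
read_cohort <- function(path, side = c("target", "source"),
                        id_col = "subject_id", age_col = "age",
                        sex_col = "sex", outcome_col = "outcome",
                        dx_prefix = "dx_", sdoh_prefix = "sdoh_") {
  side <- match.arg(side)
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  dat <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  as_cohort(dat, side = side, id_col = id_col, age_col = age_col,
            sex_col = sex_col, outcome_col = outcome_col,
            dx_prefix = dx_prefix, sdoh_prefix = sdoh_prefix)
}

#' Validate an in-memory data frame as a cohort
#'
#' @inheritParams read_cohort
#' @param data A data frame.
#' @return A validated cohort tibble; see [read_cohort()].
#' @export
as_cohort <- function(data, side = c("target", "source"),
                      id_col = "subject_id", age_col = "age",
                      sex_col = "sex", outcome_col = "outcome",
                      dx_prefix = "dx_", sdoh_prefix = "sdoh_") {
  side <- match.arg(side)
  data <- tibble::as_tibble(data)
  required <- c(id_col, age_col, sex_col, outcome_col)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dx_cols <- grep(paste0("^", dx_prefix), names(data), value = TRUE)
  sdoh_cols <- grep(paste0("^", sdoh_prefix), names(data), value = TRUE)
  if (length(dx_cols) == 0) {
    stop("schema error: no diagnosis columns with prefix '", dx_prefix, "'",
         call. = FALSE)
  }
  if (side == "source" && length(sdoh_cols) == 0) {
    stop("schema error: source cohort has no columns with prefix '",
         sdoh_prefix, "'", call. = FALSE)
  }
  if (anyDuplicated(data[[id_col]])) {
    dup <- data[[id_col]][duplicated(data[[id_col]])][1]
    stop("validation error: duplicate subject_id '", dup, "'", call. = FALSE)
  }
  for (col in c(outcome_col, sex_col, dx_cols)) {
    check_binary_column(data[[col]], col)
  }
  roles <- list(id = id_col, age = age_col, sex = sex_col,
                outcome = outcome_col, dx = dx_cols, sdoh = sdoh_cols)
  structure(data,
            cohort_roles = roles,
            class = c(paste0(side, "_cohort"), class(data)))
}

check_binary_column <- function(x, name) {
  bad <- which(!is.na(x) & !(x %in% c(0, 1)))
  if (length(bad) > 0) {
    stop(sprintf(
      "validation error: non-binary value '%s' in column '%s' at row %d",
      as.character(x[bad[1]]), name, bad[1]), call. = FALSE)
  }
  bad_na <- which(is.na(x))
  if (length(bad_na) > 0) {
    stop(sprintf("validation error: missing value in binary column '%s' at row %d",
                 name, bad_na[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Column roles of a cohort
#' @param cohort A cohort tibble from [as_cohort()].
#' @return Named list with elements `id`, `age`, `sex`, `outcome`, `dx`, `sdoh`.
#' @export
cohort_roles <- function(cohort) {
  roles <- attr(cohort, "cohort_roles")
  if (is.null(roles)) stop("not a cohort: missing 'cohort_roles' attribute",
                           call. = FALSE)
  roles
}

#' Aggregate ICD-9 codes to their three-digit category
#'
#' Five-digit diagnosis codes are collapsed to the higher-level category used
#' for modeling: numeric codes keep their first three digits, V codes keep
#' `"V"` plus two digits, and E codes keep `"E"` plus three digits (so
#' `"296.33"` becomes `"296"`, `"V62.84"` becomes `"V62"`, and `"E950.1"`
#' becomes `"E950"`). The operation is idempotent.
#'
#' @param codes Character vector of diagnosis codes (dots allowed).
#' @return Character vector of category labels, same length as `codes`.
#' @export
icd3_category <- function(codes) {
  if (!is.character(codes)) codes <- as.character(codes)
  if (any(is.na(codes) | !nzchar(trimws(codes)))) {
    stop("empty diagnosis code", call. = FALSE)
  }
  codes <- toupper(gsub("\\.", "", trimws(codes)))
  first <- substr(codes, 1, 1)
  width <- ifelse(first == "E", 4L, ifelse(first == "V", 3L, 3L))
  substr(codes, 1, width)
}

#' Median imputation of a numeric vector
#'
#' Replaces missing entries by the median of the observed entries; observed
#' entries are untouched.
#'
#' @param x Numeric vector with at least one observed value.
#' @return Complete numeric vector.
#' @export
impute_median <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) {
    stop("cannot impute an all-missing column (no median exists)",
         call. = FALSE)
  }
  x[is.na(x)] <- stats::median(obs)
  x
}

#' Median-impute the SDoH columns of a source cohort
#'
#' @param cohort A source cohort tibble.
#' @return The cohort with every `sdoh` column complete.
#' @export
impute_sdoh <- function(cohort) {
  roles <- cohort_roles(cohort)
  for (col in roles$sdoh) cohort[[col]] <- impute_median(cohort[[col]])
  cohort
}

#' Rescale a feature matrix to the unit interval
#'
#' Applies the affine map `(x - min) / (max - min)` per column. Constant
#' columns map to 0 and are flagged. When `bounds` is supplied (e.g. bounds
#' recorded on training data) they are reused, and values outside `[0, 1]`
#' are permitted.
#'
#' @param x Numeric matrix (or data frame of numeric columns).
#' @param bounds Optional bounds tibble from a previous call (columns
#'   `feature`, `min`, `max`).
#' @return Numeric matrix on the unit scale with attributes `bounds` (a
#'   tibble reusable on new data) and `constant` (logical flag per column).
#' @export
normalize_unit <- function(x, bounds = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(bounds)) {
    mins <- apply(x, 2, min, na.rm = TRUE)
    maxs <- apply(x, 2, max, na.rm = TRUE)
  } else {
    idx <- match(colnames(x), bounds$feature)
    if (anyNA(idx)) {
      stop("no stored bounds for feature(s): ",
           paste(colnames(x)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    mins <- bounds$min[idx]
    maxs <- bounds$max[idx]
  }
  rng <- maxs - mins
  constant <- rng <= 0
  rng[constant] <- 1 # constant features map to 0, not NaN
  out <- sweep(sweep(x, 2, mins, "-"), 2, rng, "/")
  out[, constant] <- 0
  attr(out, "bounds") <- tibble::tibble(feature = colnames(x),
                                        min = unname(mins), max = unname(maxs))
  attr(out, "constant") <- stats::setNames(constant, colnames(x))
  out
}

#' Invert a unit-interval rescaling
#'
#' @param x Matrix previously produced by [normalize_unit()].
#' @param bounds Bounds tibble, defaulting to the attribute stored on `x`.
#' @return Matrix on the original scale.
#' @export
denormalize_unit <- function(x, bounds = attr(x, "bounds")) {
  if (is.null(bounds)) stop("no bounds available", call. = FALSE)
  idx <- match(colnames(x), bounds$feature)
  rng <- bounds$max[idx] - bounds$min[idx]
  sweep(sweep(unclass_matrix(x), 2, rng, "*"), 2, bounds$min[idx], "+")
}

unclass_matrix <- function(x) {
  attr(x, "bounds") <- NULL
  attr(x, "constant") <- NULL
  x
}

#' Define the shared feature block linking the two cohorts
#'
#' @param target_cols,source_cols Equal-length character vectors of paired
#'   column names (target column i corresponds to source column i).
#' @param feature Optional display names; defaults to `target_cols`.
#' @return Tibble classed `"shared_feature_spec"` with columns `feature`,
#'   `target_col`, `source_col`.
#' @export
shared_feature_spec <- function(target_cols, source_cols,
                                feature = target_cols) {
  if (length(target_cols) != length(source_cols)) {
    stop("target_cols and source_cols must pair one-to-one", call. = FALSE)
  }
  out <- tibble::tibble(feature = feature, target_col = target_cols,
                        source_col = source_cols)
  class(out) <- c("shared_feature_spec", class(out))
  out
}

#' Read a shared-feature mapping file
#'
#' Expects a delimited file with columns `target_column` and `source_column`
#' (optional `feature` display names).
#'
#' @param path Path to the mapping CSV.
#' @return A [shared_feature_spec()] tibble.
#' @export
read_shared_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("target_column", "source_column")
  if (!all(need %in% names(map))) {
    stop("shared map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  feature <- if ("feature" %in% names(map)) map$feature else map$target_column
  shared_feature_spec(map$target_column, map$source_column, feature)
}

#' Build aligned shared-feature matrices for the two cohorts
#'
#' Extracts the shared feature block from each cohort in the order fixed by
#' `spec` and rescales both sides to the unit interval. By default the
#' min/max bounds are pooled over both cohorts, so that e.g. "age 18" lands
#' on the same point of the unit scale on both sides; per-side bounds are
#' available for sensitivity analysis.
#'
#' @param target,source Cohort tibbles.
#' @param spec A [shared_feature_spec()].
#' @param pooled_bounds Pool normalization bounds across cohorts (default)
#'   or normalize each side by its own bounds.
#' @return List with matrices `target` and `source` (identical column order,
#'   columns named by `spec$feature`) and the `bounds` tibble used.
#' @export
build_shared_matrices <- function(target, source, spec, pooled_bounds = TRUE) {
  miss_t <- setdiff(spec$target_col, names(target))
  miss_s <- setdiff(spec$source_col, names(source))
  if (length(miss_t) > 0 || length(miss_s) > 0) {
    stop("unresolvable shared feature(s): ",
         paste(c(miss_t, miss_s), collapse = ", "), call. = FALSE)
  }
  xt <- as.matrix(as.data.frame(target)[, spec$target_col, drop = FALSE])
  xs <- as.matrix(as.data.frame(source)[, spec$source_col, drop = FALSE])
  colnames(xt) <- colnames(xs) <- spec$feature
  if (pooled_bounds) {
    pooled <- normalize_unit(rbind(xt, xs))
    bounds <- attr(pooled, "bounds")
    xt <- normalize_unit(xt, bounds = bounds)
    xs <- normalize_unit(xs, bounds = bounds)
  } else {
    xt <- normalize_unit(xt)
    xs <- normalize_unit(xs)
    bounds <- attr(xt, "bounds")
  }
  list(target = unclass_matrix(xt), source = unclass_matrix(xs),
       bounds = bounds)
}
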