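#' Batch median scaling
#'
#' For each metabolite, values within each instrument batch are divided by
#' the within-batch median of the non-missing values, so that each batch
#' (and hence the metabolite) has median 1. Missing cells stay missing.
#' A metabolite with no observed value in any batch cannot be scaled and is
#' dropped with a warning (its ids are attached as attribute `"dropped"`).
#'
#' @param x numeric matrix, metabolites x samples, `NA` = missing.
#' @param batch batch label per column.
#' @return the scaled matrix (possibly with rows dropped).
#' @export
median_scale <- function(x, batch) {
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  all_missing <- rowSums(!is.na(x)) == 0
  dropped <- rownames(x)[all_missing]
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " metabolite(s) with no observed value in any batch: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    x <- x[!all_missing, , drop = FALSE]
  }
  out <- x
  for (b in unique(batch)) {
    cols <- which(batch == b)
    sub <- x[, cols, drop = FALSE]
    med <- apply(sub, 1, stats::median, na.rm = TRUE)  # NaN if all-NA in batch
    out[, cols] <- sub / med
  }
  attr(out, "dropped") <- dropped
  out
}

#' Minimum-value imputation
#'
#' Replaces each missing cell with the metabolite's minimum observed value
#' across all batches and samples — the standard treatment for
#' below-detection-limit dropouts on median-scaled data.
#'
#' @param x scaled matrix with `NA` for missing cells; every row must have
#'   at least one observed value.
#' @return list with `matrix` (complete) and `mask` (logical matrix marking
#'   imputed cells).
#' @export
impute_minimum <- function(x) {
  stopifnot(is.matrix(x))
  none_observed <- rowSums(!is.na(x)) == 0
  if (any(none_observed)) {
    stop("metabolite(s) with zero observed values (should have been dropped): ",
         paste(rownames(x)[none_observed], collapse = ", "))
  }
  mask <- is.na(x)
  row_min <- apply(x, 1, min, na.rm = TRUE)
  out <- x
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) out[idx] <- row_min[idx[, 1]]
  list(matrix = out, mask = mask)
}

#' Natural-log transformation
#'
#' @param x complete matrix of strictly positive values.
#' @return element-wise natural logarithm of `x`.
#' @export
log_transform <- function(x) {
  stopifnot(is.matrix(x))
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive value at [%s, %s]; log transform undefined",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  if (anyNA(x)) stop("matrix has missing cells; impute before log transform")
  log(x)
}

#' Normalize a peak-area study
#'
#' Runs the full preprocessing chain: batch median scaling, removal of
#' metabolites observed in fewer than `min_observed` samples (no variance
#' estimate is possible for them), minimum imputation, and natural-log
#' transformation.
#'
#' @param study a [peak_area_study()].
#' @param min_observed minimum number of observed (non-missing) samples a
#'   metabolite needs to be retained (default 2).
#' @return an object of class `normalized_study` with elements `tissue`,
#'   `sample_ids`, `group`, `batch`, `scaled` (complete median-scaled,
#'   imputed matrix), `imputed_mask`, `logged` (natural log of `scaled`)
#'   and `dropped` (ids removed).
#' @export
normalize_study <- function(study, min_observed = 2) {
  stopifnot(inherits(study, "peak_area_study"))
  scaled <- median_scale(study$raw, study$batch)
  dropped <- attr(scaled, "dropped")
  attr(scaled, "dropped") <- NULL
  thin <- rowSums(!is.na(scaled)) < min_observed
  if (any(thin)) {
    message("dropping ", sum(thin), " metabolite(s) observed in < ",
            min_observed, " samples")
    dropped <- c(dropped, rownames(scaled)[thin])
    scaled <- scaled[!thin, , drop = FALSE]
  }
  imp <- impute_minimum(scaled)
  structure(
    list(
      tissue = study$tissue,
      metabolite_ids = rownames(imp$matrix),
      sample_ids = study$sample_ids,
      group = study$group,
      batch = study$batch,
      scaled = imp$matrix,
      imputed_mask = imp$mask,
      logged = log_transform(imp$matrix),
      dropped = dropped
    ),
    class = "normalized_study"
  )
}

#' @export
print.normalized_study <- function(x, ...) {
  cat(sprintf(
    "<normalized_study> tissue=%s: %d metabolites x %d samples; %d cells imputed (%.1f%%); %d metabolites dropped\n",
    x$tissue, nrow(x$scaled), ncol(x$scaled), sum(x$imputed_mask),
    100 * mean(x$imputed_mask), length(x$dropped)
  ))
  invisible(x)
}
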