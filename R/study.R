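#' The nine top-level metabolite categories
#'
#' Closed vocabulary of super-pathway categories used by the annotation
#' platform. Every metabolite annotation must use one of these.
#'
#' @export
SUPER_PATHWAYS <- c(
  "Amino Acid", "Carbohydrate", "Cofactors and Vitamins", "Energy",
  "Lipid", "Nucleotide", "Partially characterized molecules",
  "Peptide", "Xenobiotics"
)

GROUP_LEVELS <- c("D0", "D5")

#' Construct a peak-area study
#'
#' Bundles a raw peak-area matrix (metabolites x samples) with per-sample
#' group and instrument-batch labels for one tissue. Missing cells (below
#' detection limit) are `NA`; all present values must be strictly positive.
#'
#' @param raw numeric matrix, metabolites in rows (rownames = metabolite ids),
#'   samples in columns (colnames = sample ids). `NA` marks a missing cell.
#' @param group character vector, one of `"D0"` (control) or `"D5"` (5-day
#'   ventilation), one per sample, in column order or named by sample id.
#' @param batch character/integer vector of instrument-batch labels, one per
#'   sample, in column order or named by sample id.
#' @param tissue single tissue label.
#' @param excluded_samples ids of samples already dropped from this study
#'   (bookkeeping only; they must not appear in `raw`).
#' @return an object of class `peak_area_study`.
#' @export
peak_area_study <- function(raw, group, batch, tissue = "tissue",
                            excluded_samples = character()) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix")
  }
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    stop("`raw` must have metabolite ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(raw))) stop("duplicated metabolite ids")
  if (anyDuplicated(colnames(raw))) stop("duplicated sample ids")
  sample_ids <- colnames(raw)
  group <- align_to_samples(group, sample_ids, "group")
  batch <- align_to_samples(batch, sample_ids, "batch")
  bad_group <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group labels: ", paste(bad_group, collapse = ", "),
         " (expected D0/D5)")
  }
  if (any(!is.na(raw) & raw <= 0)) {
    stop("all present peak areas must be > 0")
  }
  tab <- table(factor(group, levels = GROUP_LEVELS))
  if (any(tab < 2)) {
    stop("need at least 2 samples per group; have ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  if (any(excluded_samples %in% sample_ids)) {
    stop("excluded_samples must not appear among the study's samples")
  }
  structure(
    list(
      tissue = as.character(tissue)[1],
      metabolite_ids = rownames(raw),
      sample_ids = sample_ids,
      raw = raw,
      group = stats::setNames(as.character(group), sample_ids),
      batch = stats::setNames(as.character(batch), sample_ids),
      excluded_samples = as.character(excluded_samples)
    ),
    class = "peak_area_study"
  )
}

align_to_samples <- function(x, sample_ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing)) {
      stop("metadata missing ", what, " for sample(s): ",
           paste(missing, collapse = ", "))
    }
    x <- x[sample_ids]
  } else if (length(x) != length(sample_ids)) {
    stop("`", what, "` must have one entry per sample")
  }
  if (anyNA(x)) stop("`", what, "` contains NA")
  x
}

#' @export
print.peak_area_study <- function(x, ...) {
  cat(sprintf(
    "<peak_area_study> tissue=%s: %d metabolites x %d samples (D0=%d, D5=%d, batches=%d)\n",
    x$tissue, nrow(x$raw), ncol(x$raw),
    sum(x$group == "D0"), sum(x$group == "D5"),
    length(unique(x$batch))
  ))
  if (length(x$excluded_samples)) {
    cat("  excluded samples:", paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a peak-area study from TSV files
#'
#' The matrix TSV has `metabolite_id` as its first column and one column per
#' sample; empty fields and `"NA"` are read as missing. The metadata TSV has
#' columns `sample_id`, `group`, `batch` and optionally `tissue`; it must
#' cover every matrix column.
#'
#' @param matrix_path path to the peak-area matrix TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param tissue tissue label; defaults to the (unique) `tissue` metadata
#'   column if present.
#' @return a [peak_area_study()].
#' @export
read_peak_area_study <- function(matrix_path, metadata_path, tissue = NULL) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              na.strings = c("", "NA"),
                              stringsAsFactors = FALSE)
  if (ncol(mat_df) < 2 || tolower(names(mat_df)[1]) != "metabolite_id") {
    stop("matrix TSV must start with a `metabolite_id` column")
  }
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            na.strings = c("", "NA"),
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(meta))) {
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  }
  raw <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(raw) <- "double"
  rownames(raw) <- as.character(mat_df[[1]])
  missing_meta <- setdiff(colnames(raw), meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing row(s) for sample(s): ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(raw), meta$sample_id), ]
  if (is.null(tissue)) {
    tissue <- if ("tissue" %in% names(meta)) unique(meta$tissue)[1] else "tissue"
  }
  peak_area_study(
    raw = raw,
    group = stats::setNames(meta$group, meta$sample_id),
    batch = stats::setNames(as.character(meta$batch), meta$sample_id),
    tissue = tissue
  )
}

#' Write a peak-area study to TSV files
#'
#' Inverse of [read_peak_area_study()]; missing cells are written as `NA`.
#'
#' @param study a `peak_area_study`.
#' @param matrix_path,metadata_path output paths.
#' @export
write_study <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "peak_area_study"))
  df <- data.frame(metabolite_id = rownames(study$raw), study$raw,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  meta <- data.frame(
    sample_id = study$sample_ids,
    group = unname(study$group),
    batch = unname(study$batch),
    tissue = study$tissue,
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(matrix_path, metadata_path))
}

#' Drop excluded samples from a study
#'
#' Removes the given sample columns (e.g. a sample flagged as abnormal
#' during platform QC) and records them in `excluded_samples`.
#'
#' @param study a `peak_area_study`.
#' @param excluded_ids sample ids to drop; must be a subset of the study's
#'   samples. Dropping may not leave any group with fewer than 2 samples.
#' @return the reduced study.
#' @export
apply_exclusions <- function(study, excluded_ids) {
  stopifnot(inherits(study, "peak_area_study"))
  excluded_ids <- as.character(excluded_ids)
  if (!length(excluded_ids)) return(study)
  unknown <- setdiff(excluded_ids, study$sample_ids)
  if (length(unknown)) {
    stop("cannot exclude unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(study$sample_ids, excluded_ids)
  peak_area_study(
    raw = study$raw[, keep, drop = FALSE],
    group = study$group[keep],
    batch = study$batch[keep],
    tissue = study$tissue,
    excluded_samples = union(study$excluded_samples, excluded_ids)
  )
}

#' Read a metabolite annotation table
#'
#' TSV with columns `metabolite_id`, `name`, `super_pathway`, `sub_pathway`
#' and optionally a logical `is_named` override. Without the override,
#' compounds whose display name matches the platform's unnamed convention
#' (`X-` followed by digits) are flagged `is_named = FALSE`.
#'
#' @param path annotation TSV path.
#' @return data.frame with columns `metabolite_id`, `display_name`,
#'   `is_named`, `super_pathway`, `sub_pathway`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("metabolite_id", "name", "super_pathway", "sub_pathway")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  ann <- data.frame(
    metabolite_id = as.character(df$metabolite_id),
    display_name = as.character(df$name),
    super_pathway = as.character(df$super_pathway),
    sub_pathway = as.character(df$sub_pathway),
    stringsAsFactors = FALSE
  )
  ann$is_named <- if ("is_named" %in% names(df)) {
    as.logical(df$is_named)
  } else {
    !grepl("^X-?[0-9]+$", ann$display_name)
  }
  validate_annotations(ann)
  ann[, c("metabolite_id", "display_name", "is_named",
          "super_pathway", "sub_pathway")]
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$metabolite_id)) {
    stop("duplicated metabolite_id in annotations")
  }
  bad <- setdiff(unique(ann$super_pathway), SUPER_PATHWAYS)
  if (length(bad)) {
    stop("super_pathway outside the 9-category vocabulary: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a metabolite annotation table
#'
#' @param ann annotation data.frame as returned by [read_annotations()].
#' @param path output TSV path.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(
    metabolite_id = ann$metabolite_id,
    name = ann$display_name,
    super_pathway = ann$super_pathway,
    sub_pathway = ann$sub_pathway,
    is_named = ann$is_named,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a generic result table as TSV
#'
#' Floats are written at full precision (15 significant digits) so that
#' write/read round-trips are faithful.
#'
#' @param df data.frame.
#' @param path output TSV path.
#' @export
write_result_table <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 15, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records counts, thresholds, seeds and the package version alongside the
#' tabular outputs of a run.
#'
#' @param summary named list.
#' @param path output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  summary$package_version <- as.character(utils::packageVersion("metsig"))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
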