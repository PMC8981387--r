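#' Two-group linear-model test for one metabolite
#'
#' Two-sided p-value from a two-group fixed-effect linear model on logged
#' values, i.e. the pooled-variance t-test. One observation per animal per
#' tissue leaves no random-effect structure, so this is the full model for
#' the design. Degenerate cases: zero pooled variance with equal group means
#' gives p = 1 (conservative); zero pooled variance with unequal means gives
#' p = 0 with attribute `degenerate = TRUE`.
#'
#' @param values logged values, one per sample.
#' @param group group label per sample (`"D0"`/`"D5"`), each with >= 2
#'   samples.
#' @return p-value in \[0, 1\].
#' @export
test_metabolite <- function(values, group) {
  g <- factor(group, levels = GROUP_LEVELS)
  n0 <- sum(g == "D0"); n1 <- sum(g == "D5")
  if (n0 < 2 || n1 < 2) stop("need >= 2 samples per group")
  if (any(!is.finite(values))) stop("values must be finite")
  x0 <- values[g == "D0"]; x1 <- values[g == "D5"]
  sp2 <- (sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)) / (n0 + n1 - 2)
  d <- mean(x1) - mean(x0)
  if (sp2 == 0) {
    p <- if (d == 0) 1 else structure(0, degenerate = TRUE)
    return(p)
  }
  tstat <- d / sqrt(sp2 * (1 / n0 + 1 / n1))
  2 * stats::pt(abs(tstat), df = n0 + n1 - 2, lower.tail = FALSE)
}

#' Group fold change for one metabolite
#'
#' Ratio of arithmetic group means on the median-scaled, imputed (pre-log)
#' scale: `FC = mean(D5) / mean(D0)`. The absolute fold change is
#' `max(FC, 1/FC)`, symmetric in direction. An exact tie (`FC = 1`) is
#' labelled `"up"` but can never pass the DM cutoff.
#'
#' @param values scaled, imputed (pre-log) values, one per sample.
#' @param group group label per sample.
#' @return list with `fold_change`, `abs_fold_change`, `direction`.
#' @export
fold_change <- function(values, group) {
  g <- factor(group, levels = GROUP_LEVELS)
  m0 <- mean(values[g == "D0"]); m1 <- mean(values[g == "D5"])
  if (m0 <= 0 || m1 <= 0) stop("group means must be > 0")
  fc <- m1 / m0
  list(
    fold_change = fc,
    abs_fold_change = max(fc, 1 / fc),
    direction = if (fc >= 1) "up" else "down"
  )
}

#' Per-metabolite differential statistics for a normalized study
#'
#' Vectorized over metabolites: pooled-variance t-test p-values on the
#' logged matrix and fold changes on the pre-log scaled matrix. A
#' Benjamini-Hochberg adjusted p-value column is included for information
#' only; DM calling uses the raw p.
#'
#' @param norm a [normalize_study()] result.
#' @param fc_method `"mean_ratio"` (default; ratio of arithmetic group means
#'   on the pre-log scale) or `"log_mean"` (anti-log of the mean log
#'   difference).
#' @return data.frame with one row per metabolite: `metabolite_id`,
#'   `fold_change`, `abs_fold_change`, `log2_fc`, `p_value`, `p_adj_bh`,
#'   `direction`.
#' @export
fit_differential <- function(norm, fc_method = c("mean_ratio", "log_mean")) {
  stopifnot(inherits(norm, "normalized_study"))
  fc_method <- match.arg(fc_method)
  g <- factor(norm$group, levels = GROUP_LEVELS)
  i0 <- which(g == "D0"); i1 <- which(g == "D5")
  n0 <- length(i0); n1 <- length(i1)
  L <- norm$logged
  m0 <- rowMeans(L[, i0, drop = FALSE])
  m1 <- rowMeans(L[, i1, drop = FALSE])
  ss0 <- rowSums((L[, i0, drop = FALSE] - m0)^2)
  ss1 <- rowSums((L[, i1, drop = FALSE] - m1)^2)
  sp2 <- (ss0 + ss1) / (n0 + n1 - 2)
  d <- m1 - m0
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tstat <- d / se
  p <- 2 * stats::pt(abs(tstat), df = n0 + n1 - 2, lower.tail = FALSE)
  p[sp2 == 0 & d == 0] <- 1
  p[sp2 == 0 & d != 0] <- 0
  fc <- if (fc_method == "mean_ratio") {
    S <- norm$scaled
    rowMeans(S[, i1, drop = FALSE]) / rowMeans(S[, i0, drop = FALSE])
  } else {
    exp(d)
  }
  data.frame(
    metabolite_id = norm$metabolite_ids,
    fold_change = fc,
    abs_fold_change = pmax(fc, 1 / fc),
    log2_fc = log2(fc),
    p_value = p,
    p_adj_bh = stats::p.adjust(p, method = "BH"),
    direction = ifelse(fc >= 1, "up", "down"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call differential metabolites (DMs)
#'
#' A metabolite is a DM when `p_value < p_threshold` (strict) and
#' `abs_fold_change >= fc_threshold` (inclusive).
#'
#' @param results data.frame from [fit_differential()].
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @param fc_threshold absolute fold-change cutoff (default 1.5).
#' @return `results` with an added logical `is_dm` column.
#' @export
call_dms <- function(results, p_threshold = 0.05, fc_threshold = 1.5) {
  stopifnot(all(c("p_value", "abs_fold_change") %in% names(results)))
  results$is_dm <- results$p_value < p_threshold &
    results$abs_fold_change >= fc_threshold
  results
}

#' Tissue-level DM summary
#'
#' @param results output of [call_dms()].
#' @param tissue tissue label.
#' @return list with `tissue`, `n_detected`, `n_dm`, `n_up`, `n_down`,
#'   `pct_dm`.
#' @export
dm_summary <- function(results, tissue = "tissue") {
  stopifnot("is_dm" %in% names(results))
  n_dm <- sum(results$is_dm)
  list(
    tissue = tissue,
    n_detected = nrow(results),
    n_dm = n_dm,
    n_up = sum(results$is_dm & results$direction == "up"),
    n_down = sum(results$is_dm & results$direction == "down"),
    pct_dm = pct_dms(n_dm, nrow(results))
  )
}

#' Percentage of DMs among detected metabolites
#'
#' @param n_dm number of DMs.
#' @param n_detected number of detected metabolites (> 0).
#' @return percentage, reported to 1 decimal.
#' @export
pct_dms <- function(n_dm, n_detected) {
  if (n_detected <= 0) stop("n_detected must be > 0")
  if (n_dm > n_detected) stop("n_dm cannot exceed n_detected")
  round(100 * n_dm / n_detected, 1)
}

#' Three-set Venn region counts
#'
#' Counts of the 7 regions of a three-set Venn diagram over metabolite id
#' sets (e.g. DMs or detected metabolites per tissue).
#'
#' @param sets named list of 3 character vectors.
#' @return named integer vector with regions `"<A>_only"`, `"<B>_only"`,
#'   `"<C>_only"`, `"<A>&<B>"`, `"<A>&<C>"`, `"<B>&<C>"`, `"all"` where
#'   pairwise regions exclude the triple intersection.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) == 3)
  nm <- names(sets)
  if (is.null(nm)) nm <- c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c <- unique(sets[[3]])
  universe <- unique(c(a, b, c))
  in_a <- universe %in% a; in_b <- universe %in% b; in_c <- universe %in% c
  counts <- c(
    sum(in_a & !in_b & !in_c),
    sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c),
    sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c),
    sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c)
  )
  names(counts) <- c(
    paste0(nm, "_only"),
    paste0(nm[1], "&", nm[2]), paste0(nm[1], "&", nm[3]),
    paste0(nm[2], "&", nm[3]), "all"
  )
  counts
}

#' PCA overview of a logged matrix
#'
#' Centered (not scaled) principal components of the samples, via SVD.
#' Sign convention: each component is flipped so that its
#' largest-magnitude metabolite loading is positive.
#'
#' @param logged logged matrix, metabolites x samples, >= 3 samples.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_var` (proportions, non-increasing), `sdev`.
#' @export
pca_overview <- function(logged) {
  stopifnot(is.matrix(logged), ncol(logged) >= 3)
  pc <- stats::prcomp(t(logged), center = TRUE, scale. = FALSE)
  if (all(pc$sdev < .Machine$double.eps^0.5)) {
    warning("constant matrix: zero variance in all components")
  }
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  tot <- sum(pc$sdev^2)
  list(
    scores = pc$x,
    loadings = pc$rotation,
    explained_var = if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev)),
    sdev = pc$sdev
  )
}

#' Hierarchical clustering of the DM submatrix
#'
#' Average-linkage clustering on Euclidean distances of row-standardized
#' logged values (each metabolite centered and scaled to unit variance;
#' zero-variance rows become all-zero). Rows and columns are ordered by id
#' before clustering so the result is deterministic under input reordering.
#'
#' @param logged_dm logged matrix restricted to DMs (metabolites x samples).
#' @param margin cluster `"samples"` (columns) or `"metabolites"` (rows).
#' @return an [stats::hclust] object; leaf label order in `$labels[$order]`.
#' @export
hierarchical_clustering <- function(logged_dm,
                                    margin = c("samples", "metabolites")) {
  margin <- match.arg(margin)
  stopifnot(is.matrix(logged_dm), nrow(logged_dm) >= 2, ncol(logged_dm) >= 2)
  z <- logged_dm[order(rownames(logged_dm)), order(colnames(logged_dm)),
                 drop = FALSE]
  mu <- rowMeans(z)
  sd <- apply(z, 1, stats::sd)
  z <- (z - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  obj <- if (margin == "samples") t(z) else z
  stats::hclust(stats::dist(obj, method = "euclidean"), method = "average")
}
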