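#' Pathway direction z statistic
#'
#' Signed statistic summarizing the imbalance of increased vs decreased DMs
#' within a pathway: `(up - down) / sqrt(up + down)`. The square-root
#' denominator is the standard form of this statistic (the count of DMs in
#' the term under a fair-coin null has variance count/4, and up - down has
#' standard deviation sqrt(count)); the plain-count denominator, which
#' rescales the statistic into \[-1, 1\], is available for comparison.
#'
#' @param up number of increased DMs in the pathway.
#' @param down number of decreased DMs in the pathway.
#' @param denominator `"sqrt"` (default) or `"count"`.
#' @return the z statistic (unrounded; round to 2 decimals for reporting).
#' @export
pathway_zscore <- function(up, down, denominator = c("sqrt", "count")) {
  denominator <- match.arg(denominator)
  stopifnot(up >= 0, down >= 0)
  count <- up + down
  if (count == 0) stop("pathway has no DMs: zscore undefined")
  (up - down) / switch(denominator, sqrt = sqrt(count), count = count)
}

#' Pathway enrichment value
#'
#' Ratio of the DM proportion inside the pathway to the DM proportion
#' outside it, on the named-metabolite background:
#' `EV = (k/m) / ((n - k)/(N - m))`.
#'
#' @param k DMs in the pathway (named metabolites).
#' @param m detected named metabolites in the pathway (>= 1, < N).
#' @param n DMs among all detected named metabolites (>= k).
#' @param N all detected named metabolites.
#' @return the enrichment value; `Inf` when every DM lies in this pathway
#'   (`n == k`).
#' @export
enrichment_value <- function(k, m, n, N) {
  stopifnot(k >= 0, k <= m, n >= k, N >= n)
  if (m < 1) stop("m must be >= 1")
  if (N <= m) stop("pathway is the whole background (N <= m): EV undefined")
  if (n == k) return(Inf)
  (k / m) / ((n - k) / (N - m))
}

#' Score every pathway with at least one DM
#'
#' Computes, per sub-pathway, the DM counts (`k`, `up`, `down`), the
#' named-metabolite margins (`m`, `n`, `N`), the direction z statistic, the
#' enrichment value, and the signature flag
#' `|zscore| >= z_cutoff & EV >= ev_cutoff & k >= min_dms`.
#' All pathway-level counting is restricted to named metabolites; unnamed
#' ("X-" tagged) compounds remain DMs for volcano/Venn purposes but are
#' excluded from the enrichment background. Pathways failing the `min_dms`
#' filter are still listed (with `is_signature = FALSE`) so sub-threshold
#' pathways stay reportable.
#'
#' @param results output of [call_dms()] for one tissue; the rows define the
#'   tissue's detected-metabolite background.
#' @param annotations annotation data.frame ([read_annotations()]); must
#'   cover every DM.
#' @param z_cutoff,ev_cutoff,min_dms signature cutoffs (defaults 2.5, 1.5, 5).
#' @param zscore_denominator passed to [pathway_zscore()].
#' @return data.frame with one row per sub-pathway containing >= 1 DM,
#'   sorted by decreasing `|zscore|`.
#' @export
score_all_pathways <- function(results, annotations, z_cutoff = 2.5,
                               ev_cutoff = 1.5, min_dms = 5,
                               zscore_denominator = c("sqrt", "count")) {
  zscore_denominator <- match.arg(zscore_denominator)
  stopifnot("is_dm" %in% names(results))
  dm_ids <- results$metabolite_id[results$is_dm]
  unannotated <- setdiff(dm_ids, annotations$metabolite_id)
  if (length(unannotated)) {
    stop("DM(s) lacking annotation: ", paste(unannotated, collapse = ", "))
  }
  ann <- annotations[match(results$metabolite_id, annotations$metabolite_id), ]
  named <- !is.na(ann$is_named) & ann$is_named
  N <- sum(named)
  n <- sum(named & results$is_dm)
  paths <- unique(ann$sub_pathway[named & results$is_dm])
  if (!length(paths)) {
    return(data.frame(
      sub_pathway = character(), super_pathway = character(),
      k = integer(), up = integer(), down = integer(),
      m = integer(), n = integer(), N = integer(),
      zscore = numeric(), enrichment_value = numeric(),
      is_signature = logical(), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(paths, function(pw) {
    in_pw <- named & ann$sub_pathway == pw
    is_dm_pw <- in_pw & results$is_dm
    up <- sum(is_dm_pw & results$direction == "up")
    down <- sum(is_dm_pw & results$direction == "down")
    k <- up + down
    m <- sum(in_pw)
    data.frame(
      sub_pathway = pw,
      super_pathway = ann$super_pathway[which(in_pw)[1]],
      k = k, up = up, down = down, m = m, n = n, N = N,
      zscore = pathway_zscore(up, down, zscore_denominator),
      enrichment_value = enrichment_value(k, m, n, N),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$is_signature <- abs(out$zscore) >= z_cutoff &
    out$enrichment_value >= ev_cutoff & out$k >= min_dms
  out[order(-abs(out$zscore), out$sub_pathway), , drop = FALSE]
}

#' Signed ranking statistic for MSEA
#'
#' `sign(log FC) * -log10(p)`, the default ranking for set enrichment over
#' differential results. p-values are floored at 1e-300 to keep the
#' statistic finite for degenerate tests.
#'
#' @param results data.frame from [fit_differential()].
#' @return named numeric vector (names = metabolite ids).
#' @export
rank_metabolites <- function(results) {
  p <- pmax(results$p_value, 1e-300)
  s <- sign(log(results$fold_change)) * -log10(p)
  stats::setNames(s, results$metabolite_id)
}

gsea_es <- function(ranked_ids, stats_sorted, set_ids, weight = 1) {
  hit <- ranked_ids %in% set_ids
  n <- length(ranked_ids)
  nh <- sum(hit)
  w <- abs(stats_sorted)^weight
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) denom_hit <- 1
  step <- ifelse(hit, w / denom_hit, -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Metabolite set enrichment analysis (MSEA)
#'
#' GSEA-style weighted Kolmogorov-Smirnov running-sum enrichment over
#' metabolites ranked by a signed statistic, with a set-label permutation
#' null: for each set, `n_perm` random same-size sets are drawn from the
#' background, the normalized enrichment score is
#' `NES = ES / mean(|permuted ES| of matching sign)`, and the p-value is the
#' add-one-corrected fraction of matching-sign permutations at least as
#' extreme as the observed ES.
#'
#' @param stats named numeric vector of signed ranking statistics over the
#'   tissue's background metabolites (see [rank_metabolites()]).
#' @param sets named list of metabolite-id vectors (sub-pathway members).
#'   Sets with fewer than `min_size` detected members are skipped with a
#'   warning; a set spanning the whole background is degenerate (ES ~ 0) and
#'   flagged.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed; results are deterministic given it.
#' @param weight exponent on `|stat|` in the running sum (default 1).
#' @param min_size minimum detected set size (default 2).
#' @return data.frame with `set`, `size` (detected members), `es`, `nes`,
#'   `p_value`, `significant` (p < 0.05), `degenerate`.
#' @export
msea <- function(stats, sets, n_perm = 1000, seed = 1, weight = 1,
                 min_size = 2) {
  stopifnot(n_perm >= 100, !is.null(names(stats)))
  ord <- order(stats, decreasing = TRUE)
  ranked_ids <- names(stats)[ord]
  stats_sorted <- unname(stats[ord])
  n <- length(ranked_ids)
  sizes <- vapply(sets, function(s) sum(ranked_ids %in% s), integer(1))
  skip <- sizes < min_size
  if (any(skip)) {
    warning("skipping ", sum(skip), " set(s) with < ", min_size,
            " detected members: ",
            paste(utils::head(names(sets)[skip], 5), collapse = ", "))
  }
  keep <- names(sets)[!skip]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  rows <- lapply(keep, function(nm) {
    size <- sizes[[nm]]
    degenerate <- size >= n
    es <- gsea_es(ranked_ids, stats_sorted, sets[[nm]], weight)
    perm <- vapply(seq_len(n_perm), function(i) {
      gsea_es(ranked_ids, stats_sorted, sample(ranked_ids, size), weight)
    }, numeric(1))
    same_sign <- perm * sign(es) > 0
    nes <- if (any(same_sign)) es / mean(abs(perm[same_sign])) else 0
    p <- (1 + sum(same_sign & abs(perm) >= abs(es))) / (1 + sum(same_sign))
    data.frame(
      set = nm, size = size, es = es, nes = nes, p_value = p,
      significant = p < 0.05, degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(set = character(), size = integer(), es = numeric(),
               nes = numeric(), p_value = numeric(), significant = logical(),
               degenerate = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' MSEA over sub-pathways for one tissue
#'
#' Convenience wrapper: ranks the tissue's tested metabolites by
#' [rank_metabolites()], builds one set per sub-pathway from the named
#' detected metabolites (the per-tissue background), and runs [msea()].
#'
#' @param results data.frame from [fit_differential()] (the tissue's tested
#'   metabolites).
#' @param annotations annotation data.frame.
#' @param ... passed on to [msea()].
#' @return [msea()] result with column `set` renamed `sub_pathway`.
#' @export
msea_pathways <- function(results, annotations, ...) {
  ann <- annotations[match(results$metabolite_id, annotations$metabolite_id), ]
  named <- !is.na(ann$is_named) & ann$is_named
  stats <- rank_metabolites(results[named, , drop = FALSE])
  sets <- split(ann$metabolite_id[named], ann$sub_pathway[named])
  out <- msea(stats, sets, ...)
  names(out)[names(out) == "set"] <- "sub_pathway"
  out
}

#' Cross-tissue enrichment comparison
#'
#' Union of sub-pathways containing at least `min_dms` DMs in any tissue,
#' with per-tissue DM count, NES and p. A pathway with no detected members
#' in a tissue is marked `"not detected"`, distinct from detected but
#' non-significant.
#'
#' @param pathway_tables named list (per tissue) of [score_all_pathways()]
#'   outputs.
#' @param msea_tables named list (per tissue) of [msea_pathways()] outputs;
#'   same names as `pathway_tables`.
#' @param min_dms retention filter (default 5).
#' @return data.frame with one row per retained pathway and, per tissue,
#'   columns `<tissue>_k`, `<tissue>_nes`, `<tissue>_p`, `<tissue>_status`
#'   in `{"significant", "ns", "not detected"}`.
#' @export
compare_tissues <- function(pathway_tables, msea_tables, min_dms = 5) {
  stopifnot(length(pathway_tables) >= 1,
            identical(names(pathway_tables), names(msea_tables)))
  tissues <- names(pathway_tables)
  keep <- unique(unlist(lapply(pathway_tables, function(tb) {
    tb$sub_pathway[tb$k >= min_dms]
  })))
  out <- data.frame(sub_pathway = sort(keep), stringsAsFactors = FALSE)
  for (ts in tissues) {
    ptab <- pathway_tables[[ts]]
    mtab <- msea_tables[[ts]]
    ik <- match(out$sub_pathway, ptab$sub_pathway)
    im <- match(out$sub_pathway, mtab$sub_pathway)
    detected <- !is.na(im)
    out[[paste0(ts, "_k")]] <- ifelse(is.na(ik), 0L, ptab$k[ik])
    out[[paste0(ts, "_nes")]] <- ifelse(detected, mtab$nes[im], NA_real_)
    out[[paste0(ts, "_p")]] <- ifelse(detected, mtab$p_value[im], NA_real_)
    out[[paste0(ts, "_status")]] <- ifelse(
      !detected, "not detected",
      ifelse(!is.na(im) & mtab$p_value[im] < 0.05, "significant", "ns")
    )
  }
  out
}
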