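#' Run configuration for the full pipeline
#'
#' @param tissues named list, one entry per tissue, each a list with
#'   `matrix` and `metadata` TSV paths and optionally `exclude` (sample ids
#'   to drop before analysis).
#' @param annotations path to the annotation TSV shared by all tissues.
#' @param edges optional path to a chemical-chemical edge list TSV; when
#'   absent the network stage is skipped.
#' @param p_threshold,fc_threshold DM cutoffs (defaults 0.05, 1.5).
#' @param z_cutoff,ev_cutoff,min_dms pathway signature cutoffs
#'   (defaults 2.5, 1.5, 5).
#' @param min_score edge confidence threshold (default 700).
#' @param n_perm,seed MSEA permutations and seed.
#' @param top_k hubs flagged per tissue (default 4).
#' @return validated run config (class `run_config`).
#' @export
run_config <- function(tissues, annotations, edges = NULL,
                       p_threshold = 0.05, fc_threshold = 1.5,
                       z_cutoff = 2.5, ev_cutoff = 1.5, min_dms = 5,
                       min_score = 700, n_perm = 1000, seed = 1,
                       top_k = 4) {
  stopifnot(length(tissues) >= 1, !is.null(names(tissues)),
            p_threshold > 0, fc_threshold > 0, z_cutoff > 0,
            ev_cutoff > 0, min_dms > 0, min_score >= 0, n_perm >= 100)
  structure(
    list(tissues = tissues, annotations = annotations, edges = edges,
         p_threshold = p_threshold, fc_threshold = fc_threshold,
         z_cutoff = z_cutoff, ev_cutoff = ev_cutoff, min_dms = min_dms,
         min_score = min_score, n_perm = n_perm, seed = as.integer(seed),
         top_k = top_k),
    class = "run_config"
  )
}

#' Run the full per-tissue pipeline
#'
#' For each tissue: read, apply exclusions, normalize, test, call DMs,
#' score pathways, run MSEA, and (when an edge list is supplied) build the
#' DM interaction network and rank hubs. Then computes cross-tissue Venn
#' counts (detected and DM sets) and the cross-tissue enrichment
#' comparison. All tables are written as TSV under `out_dir` plus one
#' `summary.json` with counts, thresholds and seeds; re-running with the
#' same config reproduces the outputs exactly.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  annotations <- read_annotations(config$annotations)
  edge_list <- if (!is.null(config$edges)) read_edge_list(config$edges)

  per_tissue <- list()
  pathway_tables <- list()
  msea_tables <- list()
  detected_sets <- list()
  dm_sets <- list()
  for (ts in names(config$tissues)) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("[", ts, "/", what, "] ", conditionMessage(e), call. = FALSE)
      })
    }
    spec <- config$tissues[[ts]]
    study <- stage("read",
                   read_peak_area_study(spec$matrix, spec$metadata, tissue = ts))
    if (length(spec$exclude)) {
      study <- stage("exclude", apply_exclusions(study, spec$exclude))
    }
    norm <- stage("normalize", normalize_study(study))
    res <- stage("differential", {
      call_dms(fit_differential(norm),
               p_threshold = config$p_threshold,
               fc_threshold = config$fc_threshold)
    })
    summ <- dm_summary(res, tissue = ts)
    pw <- stage("enrichment", {
      score_all_pathways(res, annotations,
                         z_cutoff = config$z_cutoff,
                         ev_cutoff = config$ev_cutoff,
                         min_dms = config$min_dms)
    })
    ms <- stage("msea", {
      suppressWarnings(msea_pathways(res, annotations,
                                     n_perm = config$n_perm,
                                     seed = config$seed))
    })
    tdir <- file.path(out_dir, ts)
    dir.create(tdir, showWarnings = FALSE)
    write_result_table(cbind(
      data.frame(metabolite_id = rownames(norm$logged)), as.data.frame(norm$logged)
    ), file.path(tdir, "normalized.tsv"))
    write_result_table(res, file.path(tdir, "dms.tsv"))
    write_result_table(
      data.frame(metabolite_id = res$metabolite_id,
                 log2_fc = res$log2_fc,
                 neg_log10_p = -log10(pmax(res$p_value, 1e-300)),
                 is_dm = res$is_dm),
      file.path(tdir, "volcano.tsv")
    )
    write_result_table(pw, file.path(tdir, "pathways.tsv"))
    # four-quadrant chart data: EV vs |zscore|, signature flag
    write_result_table(
      data.frame(sub_pathway = pw$sub_pathway, enrichment_value = pw$enrichment_value,
                 abs_zscore = abs(pw$zscore), zscore = pw$zscore, k = pw$k,
                 is_signature = pw$is_signature),
      file.path(tdir, "four_quadrant.tsv")
    )
    write_result_table(ms, file.path(tdir, "msea.tsv"))

    hubs <- NULL
    if (!is.null(edge_list) && summ$n_dm > 0) {
      ig <- stage("network", {
        build_subnetwork(res$metabolite_id[res$is_dm], edge_list,
                         min_score = config$min_score)
      })
      hubs <- annotate_hub_directions(rank_hubs(ig, top_k = config$top_k), res)
      write_network(ig, hubs,
                    file.path(tdir, "network_edges.tsv"),
                    file.path(tdir, "network_nodes.tsv"))
    }
    per_tissue[[ts]] <- list(
      summary = summ,
      excluded = study$excluded_samples,
      n_samples = table(study$group),
      dropped = norm$dropped,
      n_imputed = sum(norm$imputed_mask),
      n_signature = sum(pw$is_signature),
      top_hubs = if (!is.null(hubs)) utils::head(hubs$metabolite_id, config$top_k)
    )
    pathway_tables[[ts]] <- pw
    msea_tables[[ts]] <- ms
    detected_sets[[ts]] <- res$metabolite_id
    dm_sets[[ts]] <- res$metabolite_id[res$is_dm]
  }

  if (length(dm_sets) == 3) {
    vd <- venn_counts(detected_sets)
    vm <- venn_counts(dm_sets)
    write_result_table(data.frame(region = names(vd), count = unname(vd)),
                       file.path(out_dir, "venn_detected.tsv"))
    write_result_table(data.frame(region = names(vm), count = unname(vm)),
                       file.path(out_dir, "venn_dms.tsv"))
  }
  cmp <- compare_tissues(pathway_tables, msea_tables, min_dms = config$min_dms)
  write_result_table(cmp, file.path(out_dir, "msea_comparison.tsv"))

  summary <- list(
    thresholds = config[c("p_threshold", "fc_threshold", "z_cutoff",
                          "ev_cutoff", "min_dms", "min_score", "n_perm")],
    seed = config$seed,
    tissues = lapply(per_tissue, function(x) {
      list(n_detected = x$summary$n_detected, n_dm = x$summary$n_dm,
           n_up = x$summary$n_up, n_down = x$summary$n_down,
           pct_dm = x$summary$pct_dm,
           n_samples = as.list(x$n_samples),
           excluded_samples = x$excluded,
           dropped_metabolites = x$dropped,
           n_imputed_cells = x$n_imputed,
           n_signature_pathways = x$n_signature,
           top_hubs = x$top_hubs)
    })
  )
  write_run_summary(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Render a markdown report for a completed run
#'
#' Summarizes DM counts and percentages, the top-ranked DMs (largest
#' absolute fold change, ties broken by p), signature pathways and top
#' hubs per tissue.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param n_top how many top DMs to list per tissue (default 5).
#' @return the report as a character scalar (also written to
#'   `report.md` inside `run_dir`). An incomplete run produces an error
#'   listing the missing artifacts.
#' @export
make_report <- function(run_dir, n_top = 5) {
  summary_path <- file.path(run_dir, "summary.json")
  if (!file.exists(summary_path)) stop("missing artifact: summary.json")
  summ <- jsonlite::read_json(summary_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lines <- c("# Metabolomics pipeline report", "")
  for (ts in names(summ$tissues)) {
    info <- summ$tissues[[ts]]
    missing <- c("dms.tsv", "pathways.tsv")[!file.exists(
      file.path(run_dir, ts, c("dms.tsv", "pathways.tsv")))]
    if (length(missing)) {
      stop("incomplete run: missing ", paste(file.path(ts, missing), collapse = ", "))
    }
    dms <- utils::read.delim(file.path(run_dir, ts, "dms.tsv"))
    pw <- utils::read.delim(file.path(run_dir, ts, "pathways.tsv"))
    lines <- c(lines, paste0("## ", ts), "",
               sprintf("- detected metabolites: %d", info$n_detected),
               sprintf("- differential metabolites: %d (%s%%): %d up, %d down",
                       info$n_dm, format(info$pct_dm), info$n_up, info$n_down))
    if (info$n_dm == 0) {
      lines <- c(lines, "- no differential metabolites at the configured cutoffs", "")
      next
    }
    top <- dms[dms$is_dm, ]
    top <- top[order(-top$abs_fold_change, top$p_value), ]
    top <- utils::head(top, n_top)
    lines <- c(lines, "- top-ranked DMs (by absolute fold change, then p):",
               sprintf("    - %s (FC %.2f, p %.2g, %s)", top$metabolite_id,
                       top$fold_change, top$p_value, top$direction))
    sig <- pw[pw$is_signature, ]
    lines <- c(lines,
               if (nrow(sig)) {
                 c("- signature pathways (|z| and EV above cutoffs, k >= min):",
                   sprintf("    - %s (k=%d, zscore %.2f, EV %.2f)",
                           sig$sub_pathway, sig$k, sig$zscore,
                           sig$enrichment_value))
               } else "- no signature pathways",
               if (!is.null(info$top_hubs) && length(info$top_hubs)) {
                 paste0("- top network hubs: ",
                        paste(unlist(info$top_hubs), collapse = ", "))
               },
               "")
  }
  report <- paste(lines, collapse = "\n")
  writeLines(report, file.path(run_dir, "report.md"))
  invisible(report)
}
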