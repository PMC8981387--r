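#!/usr/bin/env Rscript
# Preprocess each tissue (batch median scaling, minimum imputation, natural
# log) and call differential metabolites (p < 0.05, |FC| >= 1.5). Also
# reproduces the overview products: PCA scores, sample clustering, volcano
# data, and the cross-tissue Venn counts. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(metsig))

datadir <- "results/data"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tissues <- c("diaphragm", "intercostal", "lung")
detected <- list()
dm_sets <- list()
for (ts in tissues) {
  study <- read_peak_area_study(file.path(datadir, paste0(ts, "_matrix.tsv")),
                                file.path(datadir, paste0(ts, "_metadata.tsv")))
  norm <- normalize_study(study)
  res <- call_dms(fit_differential(norm))
  summ <- dm_summary(res, ts)
  message(sprintf("%s: %d DMs of %d detected (%.1f%%): %d up, %d down",
                  ts, summ$n_dm, summ$n_detected, summ$pct_dm,
                  summ$n_up, summ$n_down))
  truth <- utils::read.delim(file.path(datadir, paste0(ts, "_ground_truth.tsv")))
  planted <- truth$metabolite_id[truth$true_direction != "null"]
  message(sprintf("  recovered %d / %d planted DMs",
                  sum(res$metabolite_id[res$is_dm] %in% planted),
                  length(planted)))

  write_result_table(res, file.path(out, paste0(ts, "_dms.tsv")))
  pc <- pca_overview(norm$logged)
  write_result_table(
    data.frame(sample_id = rownames(pc$scores),
               group = norm$group[rownames(pc$scores)],
               pc1 = pc$scores[, 1], pc2 = pc$scores[, 2],
               var1 = pc$explained_var[1], var2 = pc$explained_var[2]),
    file.path(out, paste0(ts, "_pca.tsv")))
  hc <- hierarchical_clustering(norm$logged[res$is_dm, ], margin = "samples")
  writeLines(hc$labels[hc$order], file.path(out, paste0(ts, "_leaf_order.txt")))
  detected[[ts]] <- res$metabolite_id
  dm_sets[[ts]] <- res$metabolite_id[res$is_dm]
}

vd <- venn_counts(detected)
vm <- venn_counts(dm_sets)
write_result_table(data.frame(region = names(vd), detected = unname(vd),
                              dms = unname(vm)),
                   file.path(out, "venn_counts.tsv"))
message("metabolites detected in all three tissues: ", vd[["all"]])
message("DMs shared by all three tissues: ", vm[["all"]])
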