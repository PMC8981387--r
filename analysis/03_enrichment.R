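#!/usr/bin/env Rscript
# Pathway signature scoring (direction zscore + enrichment value on the
# named-metabolite background) and MSEA per tissue, then the cross-tissue
# comparison. Run analysis/02_differential.R first.

suppressPackageStartupMessages(library(metsig))

datadir <- "results/data"
dmdir <- "results/differential"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotations(file.path(datadir, "annotations.tsv"))
tissues <- c("diaphragm", "intercostal", "lung")

pathway_tables <- list()
msea_tables <- list()
for (ts in tissues) {
  res <- utils::read.delim(file.path(dmdir, paste0(ts, "_dms.tsv")))
  pw <- score_all_pathways(res, ann)
  sig <- pw[pw$is_signature, ]
  message(sprintf("%s: %d scored pathways, %d signatures", ts, nrow(pw),
                  nrow(sig)))
  for (i in seq_len(nrow(sig))) {
    message(sprintf("  %s (k=%d, zscore %.2f, EV %.2f)", sig$sub_pathway[i],
                    sig$k[i], sig$zscore[i], sig$enrichment_value[i]))
  }
  ms <- suppressWarnings(
    msea_pathways(res, ann, n_perm = 1000, seed = 20260919))
  write_result_table(pw, file.path(out, paste0(ts, "_pathways.tsv")))
  write_result_table(ms, file.path(out, paste0(ts, "_msea.tsv")))
  # four-quadrant chart data: x = EV, y = |zscore|
  write_result_table(
    data.frame(sub_pathway = pw$sub_pathway,
               enrichment_value = pw$enrichment_value,
               abs_zscore = abs(pw$zscore), zscore = pw$zscore,
               k = pw$k, is_signature = pw$is_signature),
    file.path(out, paste0(ts, "_four_quadrant.tsv")))
  pathway_tables[[ts]] <- pw
  msea_tables[[ts]] <- ms
}

cmp <- compare_tissues(pathway_tables, msea_tables)
write_result_table(cmp, file.path(out, "msea_comparison.tsv"))
message("cross-tissue comparison: ", nrow(cmp),
        " pathways with >= 5 DMs in any tissue")
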