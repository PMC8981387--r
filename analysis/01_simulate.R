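#!/usr/bin/env Rscript
# Generate the synthetic three-tissue study used by the downstream analysis
# steps: panels sized like the real tissues (817 / 786 / 941 detected
# metabolites, 680 co-detected), five samples per group, two instrument
# batches, left-censored dropouts, and planted differential sets mirroring
# the tissue pathway signatures. Writes TSV inputs under results/data/.

suppressPackageStartupMessages(library(metsig))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

planted <- list(
  list(sub_pathway = "Leucine, Isoleucine and Valine Metabolism",
       super_pathway = "Amino Acid", n_members = 15, fold = 3,
       direction = "up"),
  list(sub_pathway = "Benzoate Metabolism",
       super_pathway = "Xenobiotics", n_members = 11, fold = 3,
       direction = "down"),
  list(sub_pathway = "Purine Metabolism, (Hypo)Xanthine/Inosine containing",
       super_pathway = "Nucleotide", n_members = 10, fold = 3,
       direction = "up"),
  # pyruvate-like pattern: down in the muscles, up in lung
  list(sub_pathway = "Glycolysis, Gluconeogenesis, and Pyruvate Metabolism",
       super_pathway = "Energy", n_members = 6, fold = 3, direction = "down",
       direction_by_tissue = c(lung = "up"))
)

cfg <- simulation_config(
  seed = 20260919,
  n_metabolites = c(817, 786, 941), n_core = 680,
  tissues = c("diaphragm", "intercostal", "lung"),
  planted_dm_sets = planted
)
mt <- simulate_multi_tissue(cfg)

for (ts in names(mt$studies)) {
  write_study(mt$studies[[ts]],
              file.path(out, paste0(ts, "_matrix.tsv")),
              file.path(out, paste0(ts, "_metadata.tsv")))
  write_result_table(mt$truths[[ts]],
                     file.path(out, paste0(ts, "_ground_truth.tsv")))
  message(sprintf("%s: %d metabolites x %d samples, %d cells missing",
                  ts, nrow(mt$studies[[ts]]$raw), ncol(mt$studies[[ts]]$raw),
                  sum(is.na(mt$studies[[ts]]$raw))))
}
write_annotations(mt$annotations, file.path(out, "annotations.tsv"))

# chemical-chemical edge list over the shared core panel; the planted
# glycolysis members act as designated hubs
hubs <- mt$annotations$metabolite_id[
  mt$annotations$sub_pathway ==
    "Glycolysis, Gluconeogenesis, and Pyruvate Metabolism"][1:3]
el <- simulate_edge_list(mt$panels$diaphragm, seed = 20260919,
                         hub_spec = hubs, background_p = 0.02)
utils::write.table(el, file.path(out, "edges.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("edge list: %d edges, hubs: %s",
                nrow(el), paste(hubs, collapse = ", ")))

v <- venn_counts(mt$panels)
message("co-detected in all tissues: ", v[["all"]])
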