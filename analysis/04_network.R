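#!/usr/bin/env Rscript
# Metabolite-metabolite interaction subnetworks: induce the DM subgraph on
# the high-confidence edge list (score >= 700) per tissue and rank hubs by
# component-normalized betweenness. Run analysis/02_differential.R first.

suppressPackageStartupMessages(library(metsig))

datadir <- "results/data"
dmdir <- "results/differential"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

edges <- read_edge_list(file.path(datadir, "edges.tsv"))
for (ts in c("diaphragm", "intercostal", "lung")) {
  res <- utils::read.delim(file.path(dmdir, paste0(ts, "_dms.tsv")))
  dm_ids <- res$metabolite_id[res$is_dm]
  ig <- build_subnetwork(dm_ids, edges, min_score = 700)
  hubs <- annotate_hub_directions(rank_hubs(ig, top_k = 4), res)
  write_network(ig, hubs,
                file.path(out, paste0(ts, "_edges.tsv")),
                file.path(out, paste0(ts, "_nodes.tsv")))
  top <- hubs[hubs$is_top, ]
  message(sprintf("%s: %d nodes, %d edges, %d isolated DMs; top hubs:",
                  ts, igraph::vcount(ig$graph), nrow(ig$edges),
                  length(ig$isolated)))
  for (i in seq_len(nrow(top))) {
    message(sprintf("  %s (betweenness %.3f, degree %d, %s)",
                    top$metabolite_id[i], top$betweenness[i],
                    top$degree[i], top$direction[i]))
  }
}
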