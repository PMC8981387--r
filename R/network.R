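#' Read a chemical-chemical edge list
#'
#' TSV with columns `chemical_a`, `chemical_b`, `combined_score` (integer
#' confidence on the 0-1000 scale). Malformed rows are reported with their
#' line numbers.
#'
#' @param path edge list TSV path.
#' @return data.frame with the three columns.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("chemical_a", "chemical_b", "combined_score")
  if (!all(need %in% names(df))) {
    stop("edge list TSV must have columns: ", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000 |
                 is.na(df$chemical_a) | is.na(df$chemical_b) |
                 df$chemical_a == "" | df$chemical_b == "")
  if (length(bad)) {
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  df$combined_score <- score
  df[need]
}

#' Build the DM interaction subnetwork
#'
#' Induced subgraph of the confidence-scored edge list on the DM ids:
#' edges are kept when both endpoints are DMs and the score passes the
#' confidence threshold (default 700, the conventional "high confidence"
#' tier of the 0-1000 scale). Self-loops are removed and duplicate edges
#' collapsed keeping the maximum score. DMs with no retained edge are
#' excluded from the graph but reported.
#'
#' @param dm_ids nonempty character vector of DM metabolite ids.
#' @param edge_list data.frame with columns `chemical_a`, `chemical_b`,
#'   `combined_score`.
#' @param min_score minimum confidence score (default 700).
#' @return object of class `interaction_graph`: list with `graph` (an
#'   [igraph::graph] with edge attribute `combined_score`), `edges`
#'   (filtered data.frame), `isolated` (DM ids outside the graph),
#'   `min_score`.
#' @export
build_subnetwork <- function(dm_ids, edge_list, min_score = 700) {
  stopifnot(length(dm_ids) >= 1)
  need <- c("chemical_a", "chemical_b", "combined_score")
  if (!all(need %in% names(edge_list))) {
    stop("edge_list must have columns: ", paste(need, collapse = ", "))
  }
  e <- edge_list
  e <- e[e$chemical_a %in% dm_ids & e$chemical_b %in% dm_ids &
           e$combined_score >= min_score &
           e$chemical_a != e$chemical_b, , drop = FALSE]
  if (nrow(e)) {
    # canonical unordered pair, then keep the max score per pair
    lo <- pmin(e$chemical_a, e$chemical_b)
    hi <- pmax(e$chemical_a, e$chemical_b)
    key <- paste(lo, hi, sep = "\r")
    agg <- tapply(e$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    e <- data.frame(chemical_a = pairs[, 1], chemical_b = pairs[, 2],
                    combined_score = as.numeric(agg),
                    stringsAsFactors = FALSE, row.names = NULL)
    e <- e[order(e$chemical_a, e$chemical_b), , drop = FALSE]
  }
  nodes <- sort(unique(c(e$chemical_a, e$chemical_b)))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = if (length(nodes)) nodes)
  structure(
    list(graph = g, edges = e,
         isolated = sort(setdiff(dm_ids, nodes)),
         min_score = min_score),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph> %d nodes, %d edges (score >= %s); %d isolated DMs\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    format(x$min_score), length(x$isolated)
  ))
  invisible(x)
}

#' Rank metabolite hubs by betweenness centrality
#'
#' Exact shortest-path betweenness on the unweighted graph (confidence
#' scores are used only for filtering), normalized within each connected
#' component by `(nc - 1)(nc - 2)/2` where `nc` is the component size, so
#' disconnected components are ranked jointly on a comparable scale. Ties
#' are broken by degree (descending) then id (ascending).
#'
#' @param ig an `interaction_graph` from [build_subnetwork()].
#' @param top_k how many top hubs to flag (default 4).
#' @return data.frame with `metabolite_id`, `betweenness` (normalized),
#'   `betweenness_raw`, `degree`, `rank`, `is_top`; zero rows for an empty
#'   graph.
#' @export
rank_hubs <- function(ig, top_k = 4) {
  stopifnot(inherits(ig, "interaction_graph"))
  g <- ig$graph
  nv <- igraph::vcount(g)
  if (nv == 0 || igraph::ecount(g) == 0) {
    return(data.frame(metabolite_id = character(), betweenness = numeric(),
                      betweenness_raw = numeric(), degree = integer(),
                      rank = integer(), is_top = logical(),
                      stringsAsFactors = FALSE))
  }
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  comp <- igraph::components(g)
  nc <- comp$csize[comp$membership]
  denom <- (nc - 1) * (nc - 2) / 2
  norm <- ifelse(denom > 0, raw / denom, 0)
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name
  ord <- order(-norm, -deg, ids)
  out <- data.frame(
    metabolite_id = ids[ord],
    betweenness = unname(norm[ord]),
    betweenness_raw = unname(raw[ord]),
    degree = unname(deg[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  out$is_top <- out$rank <= top_k
  out
}

#' Attach differential direction and fold change to a hub ranking
#'
#' @param ranking data.frame from [rank_hubs()].
#' @param results differential results covering every ranked node.
#' @return `ranking` with added `direction` and `log2_fc` columns.
#' @export
annotate_hub_directions <- function(ranking, results) {
  i <- match(ranking$metabolite_id, results$metabolite_id)
  if (anyNA(i)) {
    stop("no differential record for node(s): ",
         paste(ranking$metabolite_id[is.na(i)], collapse = ", "))
  }
  ranking$direction <- results$direction[i]
  ranking$log2_fc <- results$log2_fc[i]
  ranking
}

#' Export an interaction graph as edge and node-attribute TSVs
#'
#' @param ig an `interaction_graph`.
#' @param ranking annotated hub ranking ([annotate_hub_directions()]).
#' @param edges_path,nodes_path output TSV paths.
#' @export
write_network <- function(ig, ranking, edges_path, nodes_path) {
  write_result_table(ig$edges, edges_path)
  write_result_table(ranking, nodes_path)
  invisible(c(edges_path, nodes_path))
}
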