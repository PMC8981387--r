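#' Simulation configuration
#'
#' Parameters of the synthetic peak-area generator. Peak areas are
#' log-normal: `area_ij = exp(base_i + effect_i * [group_j == D5] +
#' batch_j + noise_ij)` with metabolite baselines
#' `base_i ~ N(base_log_mean, base_log_sd)`, batch factors shared across
#' metabolites (`N(0, batch_effect_sd)` per batch), residual noise
#' `N(0, noise_log_sd)`, and a planted group effect `+/- log(fold)` on the
#' members of each planted set. Values below the metabolite's
#' `dropout_quantile` detection limit go missing (left-censored,
#' missing-not-at-random), which is what minimum imputation presumes.
#'
#' @param seed integer RNG seed.
#' @param n_metabolites metabolites per tissue (scalar, or one per tissue
#'   for [simulate_multi_tissue()]).
#' @param n_samples samples per group (D0 and D5 each).
#' @param n_batches number of instrument batches.
#' @param batch_effect_sd log-scale SD of multiplicative batch factors.
#' @param base_log_mean,base_log_sd mean/SD of metabolite baseline log
#'   abundances.
#' @param noise_log_sd residual log-scale SD within groups.
#' @param dropout_quantile detection-limit quantile in \[0, 0.5\]; 0 means
#'   no missingness.
#' @param planted_dm_sets list of planted differential sets, each a list
#'   with `sub_pathway`, `n_members`, `fold` (> 1), `direction`
#'   (`"up"`/`"down"`), and optionally `direction_by_tissue` (named
#'   character vector overriding `direction` per tissue).
#' @param tissue_overlap_fraction fraction of the smallest tissue panel
#'   shared across all tissues (multi-tissue only).
#' @param n_core optional explicit size of the shared core panel,
#'   overriding `tissue_overlap_fraction`.
#' @param tissues tissue labels for [simulate_multi_tissue()].
#' @param unnamed_fraction fraction of non-planted metabolites given
#'   unnamed "X-#####" display names.
#' @return validated config object (class `simulation_config`).
#' @export
simulation_config <- function(seed = 1,
                              n_metabolites = 200,
                              n_samples = 5,
                              n_batches = 2,
                              batch_effect_sd = 0.5,
                              base_log_mean = 13,
                              base_log_sd = 1.5,
                              noise_log_sd = 0.4,
                              dropout_quantile = 0.1,
                              planted_dm_sets = list(),
                              tissue_overlap_fraction = 0.8,
                              n_core = NULL,
                              tissues = c("diaphragm", "intercostal", "lung"),
                              unnamed_fraction = 0.1) {
  stopifnot(
    all(n_metabolites > 0), n_samples >= 2, n_batches >= 1,
    batch_effect_sd >= 0, base_log_sd >= 0, noise_log_sd >= 0,
    dropout_quantile >= 0, dropout_quantile <= 0.5,
    tissue_overlap_fraction > 0, tissue_overlap_fraction <= 1,
    unnamed_fraction >= 0, unnamed_fraction < 1
  )
  for (set in planted_dm_sets) {
    stopifnot(!is.null(set$sub_pathway), set$n_members >= 1, set$fold > 1)
    if (!is.null(set$direction)) {
      stopifnot(set$direction %in% c("up", "down"))
    }
  }
  total_planted <- sum(vapply(planted_dm_sets,
                              function(s) as.integer(s$n_members), integer(1)))
  if (total_planted > min(n_metabolites)) {
    stop("planted sets (", total_planted,
         " metabolites) exceed n_metabolites")
  }
  structure(
    list(seed = as.integer(seed), n_metabolites = n_metabolites,
         n_samples = n_samples, n_batches = n_batches,
         batch_effect_sd = batch_effect_sd, base_log_mean = base_log_mean,
         base_log_sd = base_log_sd, noise_log_sd = noise_log_sd,
         dropout_quantile = dropout_quantile,
         planted_dm_sets = planted_dm_sets,
         tissue_overlap_fraction = tissue_overlap_fraction,
         n_core = n_core, tissues = tissues,
         unnamed_fraction = unnamed_fraction),
    class = "simulation_config"
  )
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file; keys as in
#'   [simulation_config()].
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  do.call(simulation_config, raw)
}

# one RNG stream per (seed, tissue): adding a tissue never perturbs another
tissue_seed <- function(seed, tissue) {
  h <- sum(utf8ToInt(tissue) * seq_along(utf8ToInt(tissue)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

build_metabolite_pool <- function(n_total, planted_dm_sets, unnamed_fraction,
                                  seed, id_prefix = "met_") {
  ids <- sprintf("%s%05d", id_prefix, seq_len(n_total))
  ann <- data.frame(
    metabolite_id = ids,
    display_name = paste0("metabolite ", seq_len(n_total)),
    is_named = TRUE,
    super_pathway = NA_character_,
    sub_pathway = NA_character_,
    stringsAsFactors = FALSE
  )
  pos <- 1L
  planted_members <- list()
  for (set in planted_dm_sets) {
    take <- pos:(pos + set$n_members - 1L)
    ann$sub_pathway[take] <- set$sub_pathway
    ann$super_pathway[take] <- set$super_pathway %||% "Amino Acid"
    planted_members[[set$sub_pathway]] <- ids[take]
    pos <- pos + set$n_members
  }
  rest <- which(is.na(ann$sub_pathway))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (length(rest)) {
    n_bg <- max(1L, ceiling(length(rest) / 12))
    bg_names <- sprintf("Background Pathway %02d", seq_len(n_bg))
    bg_super <- rep_len(SUPER_PATHWAYS, n_bg)
    pick <- sort(rep_len(seq_len(n_bg), length(rest)))
    ann$sub_pathway[rest] <- bg_names[pick]
    ann$super_pathway[rest] <- bg_super[pick]
    n_unnamed <- round(unnamed_fraction * length(rest))
    if (n_unnamed > 0) {
      un <- sample(rest, n_unnamed)
      ann$display_name[un] <- sprintf("X-%05d", 10000 + seq_along(un))
      ann$is_named[un] <- FALSE
    }
  }
  list(annotations = ann, planted_members = planted_members)
}

#' Simulate a single-tissue peak-area study
#'
#' Generates a [peak_area_study()] plus annotations and planted ground
#' truth under the model described in [simulation_config()]. Deterministic
#' given `(config$seed, tissue)`.
#'
#' @param config a [simulation_config()].
#' @param tissue tissue label (selects the RNG stream and any per-tissue
#'   planted direction).
#' @param pool optional shared metabolite pool (internal; used by
#'   [simulate_multi_tissue()]); when supplied, `panel_ids` selects this
#'   tissue's panel.
#' @param panel_ids optional metabolite ids to simulate (default: all of
#'   the pool / a fresh pool of `n_metabolites`).
#' @return list with `study`, `annotations`, `truth` (data.frame
#'   `metabolite_id`, `true_direction`, `true_fc`) and `planted_counts`
#'   (per planted sub-pathway: up/down member counts in this tissue).
#' @export
simulate_study <- function(config, tissue = "tissue1", pool = NULL,
                           panel_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n_met <- config$n_metabolites[1]
  if (is.null(pool)) {
    pool <- build_metabolite_pool(n_met, config$planted_dm_sets,
                                  config$unnamed_fraction,
                                  tissue_seed(config$seed, "pool"))
  }
  ann <- pool$annotations
  if (is.null(panel_ids)) panel_ids <- ann$metabolite_id
  ann_panel <- ann[match(panel_ids, ann$metabolite_id), ]
  n <- length(panel_ids)
  ns <- config$n_samples
  sample_ids <- c(sprintf("%s_D0_%d", tissue, seq_len(ns)),
                  sprintf("%s_D5_%d", tissue, seq_len(ns)))
  group <- rep(c("D0", "D5"), each = ns)
  batch <- rep_len(sprintf("B%d", seq_len(config$n_batches)), 2 * ns)

  effect <- stats::setNames(numeric(n), panel_ids)
  true_fc <- stats::setNames(rep(1, n), panel_ids)
  true_dir <- stats::setNames(rep("null", n), panel_ids)
  planted_counts <- list()
  for (set in config$planted_dm_sets) {
    members <- intersect(pool$planted_members[[set$sub_pathway]], panel_ids)
    if (!length(members)) next
    dir <- set$direction %||% "up"
    if (!is.null(set$direction_by_tissue) &&
        tissue %in% names(set$direction_by_tissue)) {
      dir <- set$direction_by_tissue[[tissue]]
    }
    effect[members] <- if (dir == "up") log(set$fold) else -log(set$fold)
    true_fc[members] <- if (dir == "up") set$fold else 1 / set$fold
    true_dir[members] <- dir
    planted_counts[[set$sub_pathway]] <-
      list(up = if (dir == "up") length(members) else 0L,
           down = if (dir == "down") length(members) else 0L)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(tissue_seed(config$seed, tissue))
  # standard normals scaled by the config so that RNG consumption (and hence
  # every other draw) is invariant to changes in the SD parameters
  base <- config$base_log_mean + config$base_log_sd * stats::rnorm(n)
  batch_fx <- stats::setNames(
    config$batch_effect_sd * stats::rnorm(config$n_batches),
    sprintf("B%d", seq_len(config$n_batches))
  )
  noise <- matrix(config$noise_log_sd * stats::rnorm(n * 2 * ns), n, 2 * ns)
  loga <- base + outer(effect, as.numeric(group == "D5")) +
    matrix(batch_fx[batch], n, 2 * ns, byrow = TRUE) + noise
  raw <- exp(loga)
  dimnames(raw) <- list(panel_ids, sample_ids)
  if (config$dropout_quantile > 0) {
    for (i in seq_len(n)) {
      lim <- stats::quantile(raw[i, ], config$dropout_quantile, names = FALSE)
      raw[i, raw[i, ] < lim] <- NA
    }
  }
  truth <- data.frame(
    metabolite_id = panel_ids,
    true_direction = unname(true_dir),
    true_fc = unname(true_fc),
    stringsAsFactors = FALSE
  )
  list(
    study = peak_area_study(raw, group, batch, tissue = tissue),
    annotations = ann_panel,
    truth = truth,
    planted_counts = planted_counts
  )
}

#' Simulate a multi-tissue study set with a shared core panel
#'
#' Builds one global metabolite pool, assigns each tissue a panel made of a
#' shared core (detected in every tissue) plus tissue-private metabolites
#' (disjoint across tissues), and simulates each tissue on its own RNG
#' stream. Planted sets live inside the core so every tissue carries them.
#'
#' @param config a [simulation_config()]; `n_metabolites` may be one value
#'   per tissue. The core size is `n_core` if given, otherwise
#'   `round(tissue_overlap_fraction * min(n_metabolites))`.
#' @return list with `studies`, `truths`, `planted_counts` (named by
#'   tissue), shared `annotations`, and `panels` (ids per tissue).
#' @export
simulate_multi_tissue <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tissues <- config$tissues
  n_t <- rep_len(config$n_metabolites, length(tissues))
  n_core <- config$n_core %||%
    round(config$tissue_overlap_fraction * min(n_t))
  n_core <- min(n_core, min(n_t))
  total_planted <- sum(vapply(config$planted_dm_sets,
                              function(s) as.integer(s$n_members), integer(1)))
  if (total_planted > n_core) {
    stop("planted sets exceed the shared core panel (", n_core, ")")
  }
  n_private <- n_t - n_core
  n_total <- n_core + sum(n_private)
  pool <- build_metabolite_pool(n_total, config$planted_dm_sets,
                                config$unnamed_fraction,
                                tissue_seed(config$seed, "pool"))
  ids <- pool$annotations$metabolite_id
  core_ids <- ids[seq_len(n_core)]
  panels <- list()
  offset <- n_core
  for (i in seq_along(tissues)) {
    priv <- if (n_private[i] > 0) ids[offset + seq_len(n_private[i])] else character()
    offset <- offset + n_private[i]
    panels[[tissues[i]]] <- c(core_ids, priv)
  }
  sims <- lapply(tissues, function(ts) {
    simulate_study(config, tissue = ts, pool = pool,
                   panel_ids = panels[[ts]])
  })
  names(sims) <- tissues
  list(
    studies = lapply(sims, `[[`, "study"),
    truths = lapply(sims, `[[`, "truth"),
    planted_counts = lapply(sims, `[[`, "planted_counts"),
    annotations = pool$annotations,
    panels = panels
  )
}

#' Simulate a STITCH-style chemical-chemical edge list
#'
#' Erdős–Rényi background edges plus designated high-connectivity hubs.
#' Hub edges carry high confidence scores (700-999) so they survive the
#' default filtering; background scores span 150-999. No self-loops; one
#' row per unordered pair (max score kept).
#'
#' @param metabolite_ids node ids (>= 2).
#' @param seed integer seed.
#' @param hub_spec ids to receive high connectivity (each connected to
#'   about half of all nodes); with the default background density this
#'   gives hubs degree at least 3x the median degree.
#' @param background_p background edge probability (default 0.05).
#' @param hub_degree_frac fraction of nodes each hub connects to
#'   (default 0.5).
#' @return data.frame with columns `chemical_a`, `chemical_b`,
#'   `combined_score` (integer 0-1000).
#' @export
simulate_edge_list <- function(metabolite_ids, seed = 1,
                               hub_spec = character(),
                               background_p = 0.05,
                               hub_degree_frac = 0.5) {
  n <- length(metabolite_ids)
  stopifnot(n >= 2, all(hub_spec %in% metabolite_ids))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pairs <- t(utils::combn(metabolite_ids, 2))
  pick <- stats::runif(nrow(pairs)) < background_p
  a <- pairs[pick, 1]; b <- pairs[pick, 2]
  score <- sample(150:999, sum(pick), replace = TRUE)
  for (h in hub_spec) {
    others <- setdiff(metabolite_ids, h)
    k <- min(length(others), ceiling(hub_degree_frac * n))
    tgt <- sample(others, k)
    a <- c(a, rep(h, k)); b <- c(b, tgt)
    score <- c(score, sample(700:999, k, replace = TRUE))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  agg <- tapply(score, key, max)
  out <- data.frame(
    chemical_a = lo[keep], chemical_b = hi[keep],
    combined_score = as.integer(agg[key[keep]]),
    stringsAsFactors = FALSE
  )
  out[order(out$chemical_a, out$chemical_b), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
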