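# shared fixtures and independent oracles, all built in code

# tiny 3-metabolite x 4-sample study; one missing cell in m3
tiny_study <- function() {
  raw <- matrix(
    c(2, 4, 6, 8,
      5, 5, 5, 5,
      1, 3, NA, 9),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("m1", "m2", "m3"), c("s1", "s2", "s3", "s4"))
  )
  peak_area_study(raw, group = c("D0", "D0", "D5", "D5"),
                  batch = c("B1", "B1", "B1", "B1"), tissue = "muscle")
}

tiny_annotations <- function() {
  data.frame(
    metabolite_id = c("m1", "m2", "m3"),
    display_name = c("alanine", "X-23639", "citrate"),
    is_named = c(TRUE, FALSE, TRUE),
    super_pathway = c("Amino Acid", "Xenobiotics", "Energy"),
    sub_pathway = c("Alanine Metabolism", "Chemical", "TCA Cycle"),
    stringsAsFactors = FALSE
  )
}

# planted sets mirroring the study's tissue signatures; ~36% DM prevalence
# in a 100-metabolite panel, matching the reported 29.6-42% DM percentages
planted_sets_default <- function() {
  list(
    list(sub_pathway = "Leucine, Isoleucine and Valine Metabolism",
         super_pathway = "Amino Acid", n_members = 15, fold = 3,
         direction = "up"),
    list(sub_pathway = "Benzoate Metabolism",
         super_pathway = "Xenobiotics", n_members = 11, fold = 3,
         direction = "down"),
    list(sub_pathway = "Purine Metabolism, (Hypo)Xanthine/Inosine containing",
         super_pathway = "Nucleotide", n_members = 10, fold = 3,
         direction = "up")
  )
}

# independent betweenness oracle: shortest-path counts from adjacency-matrix
# powers (number of minimal-length walks = number of shortest paths), then
# pair dependencies summed directly. Returns raw (unnormalized) betweenness
# and the distance matrix.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  Np <- diag(n)
  Ak <- diag(n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% adj
    newly <- is.infinite(D) & Ak > 0
    D[newly] <- k
    Np[newly] <- Ak[newly]
  }
  bt <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (is.finite(D[s, t]) && D[s, v] + D[v, t] == D[s, t]) {
          bt[v] <- bt[v] + Np[s, v] * Np[v, t] / Np[s, t]
        }
      }
    }
  }
  list(raw = bt / 2, dist = D)  # each unordered pair visited twice
}

# component-normalized oracle matching rank_hubs' convention
betweenness_oracle_norm <- function(adj) {
  o <- betweenness_oracle(adj)
  comp_size <- rowSums(is.finite(o$dist))
  denom <- (comp_size - 1) * (comp_size - 2) / 2
  ifelse(denom > 0, o$raw / denom, 0)
}

# adjacency matrix -> edge list data.frame with a fixed high score
adj_to_edges <- function(adj, ids, score = 900) {
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  data.frame(chemical_a = ids[idx[, 1]], chemical_b = ids[idx[, 2]],
             combined_score = rep(score, nrow(idx)),
             stringsAsFactors = FALSE)
}

random_adjacency <- function(n, p) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# the ten (up, down, printed zscore) listings from the source study;
# two splits are uniquely implied by the printed value
printed_zscore_table <- function() {
  data.frame(
    pathway = c("Benzoate Metabolism (diaphragm)", "Dipeptide",
                "Leucine, Isoleucine and Valine Metabolism",
                "Purine Metabolism, (Hypo)Xanthine/Inosine containing",
                "Monoacylglycerol", "Phosphatidylinositol (PI)",
                "Fatty Acid Metabolism (Acyl Carnitine, Polyunsaturated)",
                "Fatty Acid Metabolism (Acyl Carnitine, Long Chain Saturated)",
                "Benzoate Metabolism (lung)", "Food Component/Plant"),
    up = c(0, 1, 15, 10, 10, 7, 12, 8, 0, 1),
    down = c(11, 12, 0, 0, 0, 0, 0, 0, 9, 9),
    printed = c(-3.32, -3.05, 3.87, 3.16, 3.16, 2.65, 3.46, 2.83, -3.00, -2.53),
    stringsAsFactors = FALSE
  )
}
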