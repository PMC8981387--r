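test_that("pathway zscore reproduces every printed (count, zscore) pair", {
  tab <- printed_zscore_table()
  for (i in seq_len(nrow(tab))) {
    expect_equal(round(pathway_zscore(tab$up[i], tab$down[i]), 2),
                 tab$printed[i],
                 label = tab$pathway[i])
  }
  # balanced pathway scores zero; literal count denominator stays in [-1, 1]
  expect_equal(pathway_zscore(4, 4), 0)
  expect_equal(pathway_zscore(15, 0, denominator = "count"), 1)
  expect_error(pathway_zscore(0, 0), "undefined")
})

test_that("zscore is bounded by sqrt(k), sharp iff unidirectional, monotone", {
  set.seed(2)
  for (i in 1:50) {
    k <- sample(1:30, 1)
    up <- sample(0:k, 1)
    z <- pathway_zscore(up, k - up)
    expect_lte(abs(z), sqrt(k) + 1e-12)
    expect_identical(abs(abs(z) - sqrt(k)) < 1e-12, up == 0 || up == k)
  }
  # monotone in (up - down) at fixed count
  k <- 12
  zs <- vapply(0:k, function(u) pathway_zscore(u, k - u), numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("enrichment value matches the ratio definition and its boundaries", {
  # equal in-set and out-of-set DM proportions -> EV exactly 1
  expect_equal(enrichment_value(1, 2, 10, 20), 1)
  expect_equal(enrichment_value(12, 20, 290, 941), 1.99, tolerance = 5e-3)
  expect_identical(enrichment_value(4, 10, 4, 100), Inf)
  expect_error(enrichment_value(2, 5, 4, 5), "background")
  # scale consistency: doubling k, m, n-k and N-m leaves EV unchanged
  set.seed(3)
  for (i in 1:25) {
    m <- sample(2:30, 1); k <- sample(0:m, 1)
    extra_dm <- sample(1:50, 1); extra_bg <- sample(51:200, 1)
    n <- k + extra_dm; N <- m + extra_bg
    ev <- enrichment_value(k, m, n, N)
    ev2 <- enrichment_value(2 * k, 2 * m, 2 * k + 2 * extra_dm,
                            2 * m + 2 * extra_bg)
    expect_equal(ev, ev2, tolerance = 1e-12)
    # EV > 1 iff hypergeometric enrichment is more extreme than depletion
    p_enrich <- phyper(k - 1, n, N - n, m, lower.tail = FALSE)
    p_deplete <- phyper(k, n, N - n, m, lower.tail = TRUE)
    if (abs(ev - 1) > 1e-9 && abs(p_enrich - p_deplete) > 1e-9) {
      expect_identical(ev > 1, p_enrich < p_deplete)
    }
  }
})

test_that("score_all_pathways counts on the named background and flags signatures", {
  # 20 named + 2 unnamed metabolites; pathway P has 8 named members, 7 down DMs
  ids <- sprintf("m%02d", 1:22)
  ann <- data.frame(
    metabolite_id = ids,
    display_name = c(sprintf("cpd%02d", 1:20), "X-10001", "X-10002"),
    is_named = c(rep(TRUE, 20), FALSE, FALSE),
    super_pathway = "Amino Acid",
    sub_pathway = c(rep("P", 8), rep("Q", 12), "Chemical", "Chemical"),
    stringsAsFactors = FALSE
  )
  res <- data.frame(
    metabolite_id = ids,
    fold_change = c(rep(0.5, 7), rep(1.2, 13), 2, 2),
    abs_fold_change = c(rep(2, 7), rep(1.2, 13), 2, 2),
    log2_fc = 0,
    p_value = c(rep(0.01, 7), rep(0.5, 13), 0.01, 0.01),
    direction = c(rep("down", 7), rep("up", 15)),
    stringsAsFactors = FALSE
  )
  res <- call_dms(res)
  pw <- score_all_pathways(res, ann)
  p <- pw[pw$sub_pathway == "P", ]
  # unnamed DMs are excluded from all margins: n = 7, N = 20
  expect_identical(c(p$k, p$up, p$down, p$m, p$n, p$N),
                   c(7L, 0L, 7L, 8L, 7L, 20L))
  expect_equal(p$zscore, -7 / sqrt(7))
  expect_identical(p$enrichment_value, Inf)  # every named DM is in P
  expect_true(p$is_signature)
  # k >= m and k <= n invariants
  expect_true(all(pw$k <= pw$m & pw$k <= pw$n & pw$m <= pw$N))
  # a DM without any annotation row is an error listing the id
  expect_error(score_all_pathways(res, ann[-1, ]), "m01")
})

test_that("sub-threshold pathways stay listed but unflagged", {
  ids <- sprintf("m%02d", 1:30)
  ann <- data.frame(
    metabolite_id = ids, display_name = ids, is_named = TRUE,
    super_pathway = "Lipid",
    sub_pathway = c(rep("small", 4), rep("bg", 26)),
    stringsAsFactors = FALSE
  )
  res <- call_dms(data.frame(
    metabolite_id = ids,
    fold_change = c(rep(2, 4), rep(2, 6), rep(1, 20)),
    abs_fold_change = c(rep(2, 4), rep(2, 6), rep(1, 20)),
    log2_fc = 1,
    p_value = c(rep(0.01, 10), rep(0.9, 20)),
    direction = "up", stringsAsFactors = FALSE
  ))
  pw <- score_all_pathways(res, ann)
  small <- pw[pw$sub_pathway == "small", ]
  expect_identical(small$k, 4L)        # |z| = 2 < 2.5 and k < 5
  expect_false(small$is_signature)
})

test_that("msea enrichment score agrees with the independent GSEA statistic", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  stats <- sort(setNames(rnorm(50), sprintf("m%02d", 1:50)), decreasing = TRUE)
  set_ids <- names(stats)[c(2, 5, 9, 20, 41)]
  es <- metsig:::gsea_es(names(stats), unname(stats), set_ids, weight = 1)
  oracle <- fgsea::calcGseaStat(unname(stats), which(names(stats) %in% set_ids),
                                gseaParam = 1)
  expect_equal(es, oracle, tolerance = 1e-8)
})

test_that("msea finds concordant sets and is deterministic given the seed", {
  set.seed(23)
  stats <- setNames(rnorm(80), sprintf("m%02d", 1:80))
  top <- names(sort(stats, decreasing = TRUE))[1:10]
  sets <- list(top10 = top, whole = names(stats),
               tiny = names(stats)[1])
  expect_warning(out <- msea(stats, sets, n_perm = 200, seed = 5), "tiny")
  r <- out[out$set == "top10", ]
  expect_gt(r$es, 0)
  expect_identical(sign(r$nes), sign(r$es))
  expect_lt(r$p_value, 0.05)
  # whole-background set: no contrast possible; every permutation is the
  # same set, so p saturates at 1 and the row is flagged
  expect_true(out$degenerate[out$set == "whole"])
  expect_equal(out$p_value[out$set == "whole"], 1)
  again <- suppressWarnings(msea(stats, sets, n_perm = 200, seed = 5))
  expect_identical(out, again)
  expect_true(all(out$p_value > 0 & out$p_value <= 1))
})

test_that("msea p-values are roughly uniform for random null sets", {
  set.seed(29)
  stats <- setNames(rnorm(60), sprintf("m%02d", 1:60))
  ps <- vapply(1:200, function(i) {
    sets <- list(s = sample(names(stats), 8))
    msea(stats, sets, n_perm = 100, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)  # far from piling near zero
})

test_that("planted-direction sets get matching NES sign in simulation", {
  hits <- 0
  for (r in 1:20) {
    cfg <- simulation_config(seed = 100 + r, n_metabolites = 80,
                             planted_dm_sets = planted_sets_default()[1:2])
    sim <- simulate_study(cfg, "t")
    res <- fit_differential(normalize_study(sim$study))
    ms <- suppressWarnings(
      msea_pathways(res, sim$annotations, n_perm = 100, seed = r))
    up <- ms$nes[ms$sub_pathway == "Leucine, Isoleucine and Valine Metabolism"]
    down <- ms$nes[ms$sub_pathway == "Benzoate Metabolism"]
    hits <- hits + (up > 0 && down < 0)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("cross-tissue comparison distinguishes not-detected from non-significant", {
  pt <- list(
    A = data.frame(sub_pathway = c("p1", "p2"), k = c(6L, 2L),
                   stringsAsFactors = FALSE),
    B = data.frame(sub_pathway = "p2", k = 5L, stringsAsFactors = FALSE)
  )
  mt <- list(
    A = data.frame(sub_pathway = c("p1", "p2"), nes = c(2.1, -0.4),
                   p_value = c(0.01, 0.6), stringsAsFactors = FALSE),
    B = data.frame(sub_pathway = "p2", nes = 1.1, p_value = 0.2,
                   stringsAsFactors = FALSE)
  )
  cmp <- compare_tissues(pt, mt)
  expect_setequal(cmp$sub_pathway, c("p1", "p2"))  # p2 kept: k >= 5 in B
  expect_identical(cmp$B_status[cmp$sub_pathway == "p1"], "not detected")
  expect_identical(cmp$A_status[cmp$sub_pathway == "p1"], "significant")
  expect_identical(cmp$A_status[cmp$sub_pathway == "p2"], "ns")
  # single-tissue input reduces to that tissue's filtered table
  solo <- compare_tissues(pt["A"], mt["A"])
  expect_identical(solo$sub_pathway, "p1")
})
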