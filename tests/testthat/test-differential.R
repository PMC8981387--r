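test_that("two-group test matches the pooled t-test oracle", {
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(10)
    g <- rep(c("D0", "D5"), each = 5)
    oracle <- t.test(v[g == "D5"], v[g == "D0"], var.equal = TRUE)$p.value
    expect_equal(test_metabolite(v, g), oracle, tolerance = 1e-12)
  }
  # identical groups -> no effect
  expect_equal(test_metabolite(c(1, 2, 3, 1, 2, 3),
                               rep(c("D0", "D5"), each = 3)), 1)
  # near-separated groups -> tiny p (closed-form t arithmetic)
  v <- c(0, 0, 0, 5, 5, 5) + c(1, -1, 0, 1, -1, 0) * 1e-3
  expect_lt(test_metabolite(v, rep(c("D0", "D5"), each = 3)), 1e-4)
  # degenerate variances
  expect_equal(test_metabolite(rep(1, 6), rep(c("D0", "D5"), each = 3)), 1)
  p0 <- test_metabolite(rep(c(0, 5), each = 3), rep(c("D0", "D5"), each = 3))
  expect_equal(as.numeric(p0), 0)
  expect_true(attr(p0, "degenerate"))
})

test_that("vectorized fit agrees with the per-metabolite functions", {
  set.seed(42)
  cfg <- simulation_config(seed = 3, n_metabolites = 40)
  sim <- simulate_study(cfg, "t")
  norm <- normalize_study(sim$study)
  res <- fit_differential(norm)
  for (i in sample(nrow(res), 10)) {
    id <- res$metabolite_id[i]
    expect_equal(res$p_value[i],
                 as.numeric(test_metabolite(norm$logged[id, ], norm$group)),
                 tolerance = 1e-12)
    fc <- fold_change(norm$scaled[id, ], norm$group)
    expect_equal(res$fold_change[i], fc$fold_change, tolerance = 1e-12)
    expect_identical(res$direction[i], fc$direction)
  }
  # and with the lm formulation of the same model
  id <- res$metabolite_id[1]
  fit <- lm(norm$logged[id, ] ~ factor(norm$group))
  expect_equal(res$p_value[1], summary(fit)$coefficients[2, 4],
               tolerance = 1e-10)
})

test_that("fold change is the D5/D0 mean ratio with symmetric absolute value", {
  g <- rep(c("D0", "D5"), each = 2)
  up <- fold_change(c(1.0, 1.0, 1.6, 1.6), g)
  expect_equal(up$fold_change, 1.6)
  expect_equal(up$abs_fold_change, 1.6)
  expect_identical(up$direction, "up")
  down <- fold_change(c(1.0, 1.0, 0.6, 0.6), g)
  expect_equal(down$fold_change, 0.6)
  expect_equal(down$abs_fold_change, 1 / 0.6)
  expect_identical(down$direction, "down")
  tie <- fold_change(c(1, 1, 1, 1), g)
  expect_equal(tie$abs_fold_change, 1)
  expect_identical(tie$direction, "up")
})

test_that("DM calling uses strict p and inclusive FC boundaries", {
  res <- data.frame(
    metabolite_id = c("a", "b", "c", "d"),
    fold_change = c(2, 1.5, 3, 1),
    abs_fold_change = c(2, 1.5, 3, 1),
    log2_fc = log2(c(2, 1.5, 3, 1)),
    p_value = c(0.01, 0.049, 0.05, 0.001),
    direction = c("up", "up", "up", "up"),
    stringsAsFactors = FALSE
  )
  out <- call_dms(res)
  expect_identical(out$is_dm, c(TRUE, TRUE, FALSE, FALSE))
  summ <- dm_summary(out, "muscle")
  expect_identical(summ$n_dm, 2L)
  expect_identical(summ$n_up + summ$n_down, summ$n_dm)
  expect_equal(summ$pct_dm, 50)
})

test_that("DM status is invariant to a shared monotone rescaling of raw data", {
  set.seed(9)
  cfg <- simulation_config(seed = 5, n_metabolites = 50,
                           planted_dm_sets = planted_sets_default()[1])
  sim <- simulate_study(cfg, "t")
  base <- call_dms(fit_differential(normalize_study(sim$study)))
  scaled_study <- peak_area_study(sim$study$raw * 37.5, sim$study$group,
                                  sim$study$batch, tissue = "t")
  rescaled <- call_dms(fit_differential(normalize_study(scaled_study)))
  expect_identical(base$is_dm, rescaled$is_dm)
  expect_identical(base$direction, rescaled$direction)
})

test_that("DM percentages reproduce the per-tissue worked examples", {
  expect_equal(pct_dms(242, 817), 29.6)
  expect_equal(pct_dms(330, 786), 42)
  expect_equal(pct_dms(290, 941), 30.8)
  expect_equal(pct_dms(0, 100), 0)
  expect_error(pct_dms(5, 4), "exceed")
})

test_that("venn counts match brute-force region enumeration", {
  counts <- venn_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                             C = "c"))
  expect_identical(unname(counts[c("A_only", "B_only", "C_only")]),
                   c(1L, 1L, 0L))
  expect_identical(unname(counts["A&B"]), 1L)
  expect_identical(unname(counts["all"]), 1L)
  expect_identical(sum(counts), 4L)  # |union|
  same <- venn_counts(list(A = letters[1:4], B = letters[1:4], C = letters[1:4]))
  expect_identical(unname(same["all"]), 4L)
  expect_identical(sum(same), 4L)
  disj <- venn_counts(list(A = "a", B = "b", C = "c"))
  expect_identical(unname(disj[c("A_only", "B_only", "C_only")]), c(1L, 1L, 1L))
  expect_identical(sum(disj), 3L)
  # random sets vs direct set algebra
  set.seed(13)
  for (i in 1:10) {
    sets <- lapply(1:3, function(.) sample(letters, sample(5:20, 1)))
    names(sets) <- c("A", "B", "C")
    v <- venn_counts(sets)
    expect_identical(unname(v["all"]),
                     length(Reduce(intersect, sets)))
    expect_identical(sum(v), length(Reduce(union, sets)))
  }
})

test_that("PCA overview separates planted groups and conserves variance", {
  cfg <- simulation_config(seed = 8, n_metabolites = 80, dropout_quantile = 0,
                           planted_dm_sets = planted_sets_default())
  sim <- simulate_study(cfg, "t")
  norm <- normalize_study(sim$study)
  pc <- pca_overview(norm$logged)
  expect_true(all(diff(pc$explained_var) <= 1e-12))
  expect_equal(sum(pc$sdev^2), sum(apply(t(norm$logged), 2, var)),
               tolerance = 1e-8)
  # group centroids separated along PC1: silhouette-like margin > 0
  pc1 <- pc$scores[, 1]
  g <- norm$group
  expect_gt(abs(mean(pc1[g == "D5"]) - mean(pc1[g == "D0"])),
            max(sd(pc1[g == "D5"]), sd(pc1[g == "D0"])))
  # duplicate samples get identical scores
  dup <- cbind(norm$logged, dup = norm$logged[, 1])
  colnames(dup) <- c(colnames(norm$logged), "dup")
  sc <- pca_overview(dup)$scores
  expect_equal(sc[1, ], sc[ncol(dup), ], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("hierarchical clustering groups samples by planted condition", {
  cfg <- simulation_config(seed = 12, n_metabolites = 60, dropout_quantile = 0,
                           planted_dm_sets = planted_sets_default())
  sim <- simulate_study(cfg, "t")
  norm <- normalize_study(sim$study)
  res <- call_dms(fit_differential(norm))
  hc <- hierarchical_clustering(norm$logged[res$is_dm, ], margin = "samples")
  top2 <- cutree(hc, k = 2)
  expect_identical(length(unique(top2[grepl("D0", names(top2))])), 1L)
  expect_identical(length(unique(top2[grepl("D5", names(top2))])), 1L)
  # two identical samples merge first at height 0
  m <- matrix(c(1, 1, 5, 2, 2, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  hc2 <- hierarchical_clustering(m, margin = "samples")
  expect_equal(hc2$height[1], 0)
  expect_setequal(hc2$labels[-hc2$merge[1, ]], c("s1", "s2"))
  # leaf order is deterministic under input reordering
  perm <- norm$logged[res$is_dm, ][sample(sum(res$is_dm)), sample(ncol(norm$logged))]
  hc3 <- hierarchical_clustering(perm, margin = "samples")
  expect_identical(hc$labels[hc$order], hc3$labels[hc3$order])
})
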