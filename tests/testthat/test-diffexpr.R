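test_that("median-of-ratios size factors match hand computation and scale", {
  # identical columns -> unit factors
  m <- matrix(c(3L, 7L, 3L, 7L), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # [[2,4],[4,8]]: geometric means (sqrt(8), sqrt(32)); per-sample ratios are
  # (1/sqrt 2, sqrt 2) for both features, so the medians are exactly those
  m2 <- matrix(c(2L, 4L, 4L, 8L), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling one column by c multiplies its factor by c relative to the other
  # columns (the per-feature geometric means absorb a common c^(1/n), so the
  # invariant lives in the factor ratios)
  set.seed(2)
  for (i in 1:5) {
    m3 <- matrix(rnbinom(60, mu = 50, size = 5) + 1L, 10, 6,
                 dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
    sf0 <- size_factors(m3)
    m4 <- m3
    m4[, 3] <- m4[, 3] * 5L
    sf1 <- size_factors(m4)
    expect_equal(sf1[3] / sf1[1], 5 * sf0[3] / sf0[1], tolerance = 1e-12)
    expect_equal(sf1[2] / sf1[1], sf0[2] / sf0[1], tolerance = 1e-12)
  }

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)),
               class = "holoscope_validation_error")
})

test_that("BH adjustment follows the step-up definition and its invariances", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  # NA propagated, excluded from ranking
  expect_equal(adjust_bh(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
  # permutation invariance
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_error(adjust_bh(c(0.1, 1.2)), class = "holoscope_validation_error")
})

test_that("a flat single feature gives exactly zero log2 fold change", {
  design <- one_community_design()
  counts <- matrix(10L, 1, 8, dimnames = list("r1", design$sample_id))
  res <- nb_fit_test(counts, design, model = "salinity_within_community",
                     sf = rep(1, 8))[[1]]
  expect_equal(res$log2_fold_change, 0, tolerance = 1e-8)
  expect_false(res$significant)
})

test_that("Wald statistics agree with an independent joint-ML oracle", {
  design <- one_community_design()
  group <- as.integer(design$salinity == "NSW15")
  set.seed(31)
  for (i in 1:4) {
    y <- rnbinom(8, mu = 60 * 2^(0.8 * group), size = 8)
    counts <- matrix(as.integer(y), 1, 8,
                     dimnames = list("r1", design$sample_id))
    res <- nb_fit_test(counts, design, model = "salinity_within_community",
                       sf = rep(1, 8))[[1]]
    orc <- oracle_nb_wald(y, group)
    expect_equal(res$log2_fold_change, orc$log2fc, tolerance = 1e-3)
    expect_equal(res$pvalue, orc$p, tolerance = 1e-3)
  }
})

test_that("the engine tracks DESeq2 on a shared fixture", {
  design <- one_community_design()
  set.seed(12)
  sim <- simulate_count_matrix(
    150, design, dispersion = 0.1, seed = 12,
    effects = data.frame(feature = 1:30, log2fc = 1.5, type = "salinity"))
  mine <- nb_fit_test(sim$counts, design,
                      model = "salinity_within_community")[[1]]
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, data.frame(salinity = factor(design$salinity,
                                               levels = c("NSW100", "NSW15"))),
      ~ salinity)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  common <- intersect(mine$feature_id, rownames(ref))
  lfc_cor <- cor(mine$log2_fold_change[match(common, mine$feature_id)],
                 ref[common, "log2FoldChange"])
  expect_gt(lfc_cor, 0.97)
  # significance calls largely agree despite different dispersion estimators
  mine_sig <- mine$significant[match(common, mine$feature_id)]
  ref_sig <- !is.na(ref[common, "padj"]) & ref[common, "padj"] < 0.05 &
    abs(ref[common, "log2FoldChange"]) > log2(1.5)
  expect_gt(mean(mine_sig == ref_sig), 0.9)
})

test_that("two-factor pooling is invariant to relabelling the tolerant communities", {
  design <- make_design()
  sim <- simulate_count_matrix(
    40, design, dispersion = 0.1, seed = 77,
    effects = data.frame(feature = 1:10, log2fc = 1.5, type = "interaction"))
  r1 <- nb_fit_test(sim$counts, design, model = "tolerance_x_salinity",
                    tolerant_communities = c("MC1", "MC2"))
  r2 <- nb_fit_test(sim$counts, design, model = "tolerance_x_salinity",
                    tolerant_communities = c("MC2", "MC1"))
  expect_equal(r1$interaction$stat, r2$interaction$stat, tolerance = 1e-10)
  expect_equal(r1$microbiome$log2_fold_change, r2$microbiome$log2_fold_change,
               tolerance = 1e-10)
})

test_that("degenerate designs and features are rejected or dropped", {
  design <- one_community_design(replicates = 1L)
  counts <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), design$sample_id))
  expect_error(nb_fit_test(counts, design, "salinity_within_community"),
               class = "holoscope_validation_error")

  design4 <- one_community_design()
  counts4 <- rbind(live = rep(8L, 8), dead = rep(0L, 8))
  colnames(counts4) <- design4$sample_id
  res <- nb_fit_test(counts4, design4, "salinity_within_community",
                     sf = rep(1, 8))[[1]]
  expect_identical(attr(res, "dropped"), "dead")
  expect_identical(res$feature_id, "live")
})

test_that("pathway summaries count tested reactions and apply the strict rule", {
  res <- data.frame(
    feature_id = paste0("r", 1:8),
    base_mean = 10, log2_fold_change = c(2, 2, -2, 0.1, 2, 2, 0.1, 0.1),
    lfc_se = 1, stat = 1,
    pvalue = 0.01, padj = c(0.01, 0.01, 0.01, 0.8, 0.01, 0.01, 0.8, 0.8),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  pmap <- list(r1 = "P_34", r2 = "P_34", r3 = "P_34", r4 = "P_34",
               r5 = "P_24", r6 = "P_24", r7 = "P_24", r8 = "P_24",
               r9 = "P_untested")
  summ <- summarize_pathways(res, pmap)
  p34 <- summ[summ$pathway_id == "P_34", ]
  expect_equal(p34$fraction, 0.75)
  expect_true(p34$flagged)
  expect_equal(p34$n_induced, 2L)
  expect_equal(p34$n_repressed, 1L)
  # exactly half is NOT flagged (strict >)
  p24 <- summ[summ$pathway_id == "P_24", ]
  expect_equal(p24$fraction, 0.5)
  expect_false(p24$flagged)
  # untested pathway reported with zero tested reactions
  expect_equal(summ$n_reactions_tested[summ$pathway_id == "P_untested"], 0L)
  expect_identical(nrow(summarize_pathways(res, list())), 0L)
})

test_that("ordination transform has the expected algebraic properties", {
  set.seed(6)
  m <- matrix(rnbinom(60, mu = 100, size = 10), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  m[1, ] <- 42L  # constant feature
  ord <- transform_for_ordination(m, sf = rep(1, 6))
  # constant feature contributes nothing to any axis
  expect_equal(unname(ord$transformed[1, ] - mean(ord$transformed[1, ])),
               rep(0, 6))
  # duplicated sample columns get identical coordinates
  m2 <- cbind(m, s7 = m[, 6])
  ord2 <- transform_for_ordination(m2, sf = rep(1, 7))
  expect_equal(ord2$coordinates["s6", ], ord2$coordinates["s7", ],
               tolerance = 1e-8)
  # variance shares equal the closed-form eigenvalues of the centred
  # cross-product (independent eigendecomposition)
  y <- log2(m + 1)
  yc <- y - rowMeans(y)
  ev <- eigen(crossprod(yc), symmetric = TRUE)$values
  ev <- ev[ev > 1e-10]
  expect_equal(ord$percent_var[seq_along(ev)], 100 * ev / sum(ev),
               tolerance = 1e-8)
  expect_equal(sum(ord$percent_var), 100)
})
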