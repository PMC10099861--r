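make_toy_catalog <- function() {
  b1 <- metabolic_network("bin1", list(
    reaction("RXN-A", c(S = 1), c(P = 1), genes = c("g1", "g2")),
    reaction("RXN-C", c(P = 1), c(Q = 1), genes = "g1")))
  b2 <- metabolic_network("bin2", list(
    reaction("RXN-A", c(S = 1), c(P = 1), genes = "g3")))
  bin_catalog(list(bin1 = b1, bin2 = b2))
}

test_that("gene counts are summed into reaction space with full attribution", {
  catalog <- make_toy_catalog()
  counts <- matrix(c(5L, 3L, 2L), 3, 1,
                   dimnames = list(c("g1", "g2", "g3"), "s1"))
  rc <- aggregate_gene_to_reaction(counts, catalog)
  # cross-bin summation: bin1 {g1,g2} + bin2 {g3}
  expect_equal(rc$counts["RXN-A", "s1"], 10L)
  # g1 is annotated to RXN-A and RXN-C: contributes fully to both
  expect_equal(rc$counts["RXN-C", "s1"], 5L)
  # no row for reactions without mapped genes
  expect_false("RXN-B" %in% rownames(rc$counts))
  # provenance records every contributor
  expect_setequal(rc$provenance[["RXN-A"]]$gene_id, c("g1", "g2", "g3"))
})

test_that("count conservation holds under brute-force re-summation", {
  holo <- generate_holobiont(n_bins = 5, reactions_per_bin = 10, seed = 21)
  sim <- simulate_counts(holo$catalog, seed = 21)
  rc <- aggregate_gene_to_reaction(sim$counts, holo$catalog)
  # re-sum every reaction row from its provenance, independently
  for (r in sample(rownames(rc$counts), 25)) {
    genes <- rc$provenance[[r]]$gene_id
    expect_identical(unname(rc$counts[r, ]),
                     as.integer(colSums(sim$counts[genes, , drop = FALSE])))
  }
  # global conservation: sum over reactions = sum over genes weighted by the
  # number of reactions each gene maps to
  multiplicity <- table(unlist(lapply(rc$provenance, `[[`, "gene_id")))
  weighted <- colSums(sim$counts[names(multiplicity), , drop = FALSE] *
                        as.integer(multiplicity))
  expect_equal(unname(colSums(rc$counts)), unname(weighted))
})

test_that("bin activity fractions follow the chosen denominator", {
  catalog <- make_toy_catalog()
  counts <- matrix(c(10L, 20L, 70L), 3, 1,
                   dimnames = list(c("g1", "g2", "g3"), "s1"))
  act <- bin_activity(counts, catalog, denominator = "bacterial_total")
  expect_equal(act["bin1", "s1"], 0.3)
  expect_equal(act["bin2", "s1"], 0.7)
  expect_equal(colSums(act), c(s1 = 1))  # fractions partition the total

  design <- data.frame(sample_id = "s1", community = "MC1",
                       salinity = "NSW100", replicate = 1, total_mapped = 1000)
  act2 <- bin_activity(counts, catalog, denominator = "total_mapped",
                       design = design)
  expect_equal(act2["bin1", "s1"], 0.03)
  expect_equal(act2["bin2", "s1"], 0.07)

  design$total_mapped <- 0
  expect_error(bin_activity(counts, catalog, "total_mapped", design),
               "s1", class = "holoscope_validation_error")
})

test_that("the active-bin rule applies >= on fraction and replicate count", {
  act <- rbind(
    active3of4 = c(0.003, 0.0021, 0.0019, 0.004),
    zero = c(0, 0, 0, 0),
    only2of4 = c(0.002, 0.002, 0.001, 0.001),
    exactly_at = c(0.002, 0.002, 0.002, 0.0001))
  colnames(act) <- paste0("s", 1:4)
  design <- data.frame(sample_id = paste0("s", 1:4), community = "MC1",
                       salinity = "NSW15", replicate = 1:4,
                       total_mapped = 1e6)
  res <- select_active_bins(act, design, "MC1", "NSW15")
  expect_setequal(res$active_bins, c("active3of4", "exactly_at"))

  # monotone in both rule parameters
  lower_thr <- select_active_bins(act, design, "MC1", "NSW15",
                                  threshold = 0.001)
  expect_true(all(res$active_bins %in% lower_thr$active_bins))
  lower_rep <- select_active_bins(act, design, "MC1", "NSW15",
                                  min_replicates = 2)
  expect_true(all(res$active_bins %in% lower_rep$active_bins))

  expect_error(select_active_bins(act, design, "MC9", "NSW15"),
               class = "holoscope_validation_error")
})

test_that("correlation-distance average-linkage clustering matches the exhaustive oracle", {
  set.seed(4)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("b", 1:5), paste0("s", 1:10)))
  cl <- cluster_profiles(m)
  d <- 1 - cor(t(m))
  coph_oracle <- oracle_upgma_cophenetic(as.dist(d))
  coph_hc <- as.matrix(stats::cophenetic(cl$hclust))
  expect_equal(coph_hc[rownames(coph_oracle), colnames(coph_oracle)],
               coph_oracle, tolerance = 1e-12)

  # identical rows have distance 0 and merge first
  m2 <- rbind(m, b1copy = m["b1", ] )
  cl2 <- cluster_profiles(m2)
  first <- sort(cl2$hclust$labels[-cl2$hclust$merge[1, ]])
  expect_identical(first, c("b1", "b1copy"))
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)

  # a row and its negation sit at the maximal correlation distance 2
  m3 <- rbind(a = m["b1", ], b = -m["b1", ])
  expect_equal(max(1 - cor(t(m3))), 2)

  # unit-variance scaling: every returned row has mean 0, sd 1
  expect_true(all(abs(rowMeans(cl$scaled)) < 1e-12))
  expect_equal(unname(apply(cl$scaled, 1, sd)), rep(1, 5))

  # zero-variance rows are excluded and reported
  m4 <- rbind(m, flat = rep(3, 10))
  cl4 <- cluster_profiles(m4)
  expect_identical(cl4$dropped, "flat")
  expect_error(cluster_profiles(m4[c("flat", "b1"), ]),
               class = "holoscope_validation_error")
})

test_that("one-way ANOVA on mRNA ratios matches the manual decomposition", {
  # 3 groups x 3 replicates, textbook sums of squares by hand
  design <- data.frame(sample_id = paste0("s", 1:9),
                       community = rep(c("MC1", "MC2", "MC3"), each = 3),
                       salinity = "NSW100", replicate = rep(1:3, 3),
                       total_mapped = 1e6)
  algal <- setNames(rep(100, 9), design$sample_id)
  bact <- setNames(c(10, 12, 14, 20, 22, 24, 31, 33, 35), design$sample_id)
  res <- mrna_ratio(design, bact, algal)
  y <- bact / 100
  groups <- rep(1:3, each = 3)
  grand <- mean(y)
  ss_between <- sum(3 * (tapply(y, groups, mean) - grand)^2)
  ss_within <- sum((y - ave(y, groups))^2)
  f_manual <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$anova$F, f_manual, tolerance = 1e-10)

  # all ratios equal: F = 0, p = 1 boundary
  flat <- mrna_ratio(design, setNames(rep(50, 9), design$sample_id), algal)
  expect_equal(flat$anova$F, 0)
  expect_equal(flat$anova$p_value, 1)
})

test_that("a planted four-fold ratio shift is the only Tukey-distinct group", {
  design <- make_design()
  set.seed(9)
  algal <- setNames(rep(1e6, nrow(design)), design$sample_id)
  bact <- setNames(rnorm(nrow(design), 5e4, 2e3), design$sample_id)
  shift <- design$community == "MC3" & design$salinity == "NSW15"
  bact[shift] <- bact[shift] * 4
  res <- mrna_ratio(design, bact, algal)
  lt <- res$letters
  expect_identical(unname(lt["MC3_NSW15"]), "b")
  expect_true(all(lt[setdiff(names(lt), "MC3_NSW15")] == "a"))
})
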