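test_that("correlation distance is the 1 - rho transform", {
  rho <- matrix(c(1, 0.4, -1,
                  0.4, 1, 0,
                  -1, 0, 1), 3, 3,
                dimnames = list(paste0("o", 1:3), paste0("o", 1:3)))
  d <- correlation_distance(rho)
  expect_equal(as.matrix(d)["o1", "o2"], 0.6)
  expect_equal(as.matrix(d)["o1", "o3"], 2)
  expect_true(all(diag(as.matrix(d)) == 0))
  rho_bad <- rho; rho_bad[1, 2] <- 0.9
  expect_error(correlation_distance(rho_bad), "symmetric")
})

test_that("Ward trees have monotone heights and split planted blocks", {
  # two tight blocks
  rho <- matrix(0, 8, 8)
  rho[1:4, 1:4] <- 0.8
  rho[5:8, 5:8] <- 0.8
  diag(rho) <- 1
  dimnames(rho) <- list(sprintf("o%02d", 1:8), sprintf("o%02d", 1:8))
  hc <- ward_tree(correlation_distance(rho))
  expect_true(all(diff(hc$height) >= -1e-12))
  top_left <- guildscan:::hclust_members(hc, hc$merge[nrow(hc$merge), 1])
  expect_true(setequal(top_left, sprintf("o%02d", 1:4)) ||
              setequal(top_left, sprintf("o%02d", 5:8)))

  # single pair: one merge
  rho2 <- diag(2); dimnames(rho2) <- list(c("a", "b"), c("a", "b"))
  hc2 <- ward_tree(correlation_distance(rho2))
  expect_equal(nrow(hc2$merge), 1)
})

test_that("partitioning recovers planted guilds and is order-invariant", {
  # guilds of 10: every node that must split holds >= 20 OTUs, where the
  # permutation p-value can reach the 0.001 acceptance boundary (a 10-OTU
  # node has only 252 balanced relabelings, so re-drawing the observed
  # labeling alone floors its p-value near 0.009)
  gs <- guild_spec(4, 10, 0.8)
  g <- generate_guild_counts(100, gs, 10000, seed = 18)
  sr <- sparcc(g$table, n_draws = 10, n_bootstrap = 0, seed = 4)
  d <- correlation_distance(sr$rho)
  part <- partition_by_permanova(ward_tree(d), d, alpha = 0.001,
                                 n_perm = 999, seed = 6)
  expect_equal(part$n_cags, 4)
  expect_equal(ari(part$cag, g$partition[names(part$cag)]), 1)
  expect_true(all(part$tests$p.value[part$tests$accepted] <= 0.001))

  # permuting OTU order leaves the partition (as sets) unchanged
  perm <- sample(ncol(g$table$counts))
  rho_p <- sr$rho[perm, perm]
  d_p <- correlation_distance(rho_p)
  part_p <- partition_by_permanova(ward_tree(d_p), d_p, alpha = 0.001,
                                   n_perm = 999, seed = 6)
  expect_equal(ari(part_p$cag[names(part$cag)], part$cag), 1)
})

test_that("structureless data collapses to a single CAG", {
  gs <- guild_spec(4, 5, 0.3, between_corr = 0.3)  # within == between
  g <- generate_guild_counts(60, gs, 8000, seed = 27)
  sr <- sparcc(g$table, n_draws = 10, n_bootstrap = 0, seed = 3)
  d <- correlation_distance(sr$rho)
  part <- partition_by_permanova(ward_tree(d), d, alpha = 0.001,
                                 n_perm = 999, seed = 9)
  expect_equal(part$n_cags, 1)
})

test_that("alpha = 1 splits until the two-member rule halts", {
  set.seed(2)
  rho <- cov2cor(crossprod(matrix(rnorm(400), 20, 20)))
  dimnames(rho) <- list(sprintf("o%02d", 1:20), sprintf("o%02d", 1:20))
  d <- correlation_distance(rho)
  part <- partition_by_permanova(ward_tree(d), d, alpha = 1,
                                 n_perm = 9, seed = 1)
  # at alpha = 1 every tested split is accepted; only the singleton-blocking
  # (>= 2 OTUs per child) rule halts the recursion
  expect_true(all(part$tests$accepted))
  expect_gt(part$n_cags, 1)
})

test_that("CAG abundances sum member OTUs and conserve totals", {
  rel <- rbind(s1 = c(0.1, 0.2, 0.3, 0.4),
               s2 = c(0.4, 0.3, 0.2, 0.1))
  colnames(rel) <- paste0("o", 1:4)
  cag <- setNames(c(1L, 1L, 2L, 2L), paste0("o", 1:4))
  ab <- cag_abundance(rel, cag)
  expect_equal(unname(ab$abundance[, "CAG1"]), c(0.3, 0.7))
  expect_equal(unname(rowSums(ab$abundance)), unname(rowSums(rel)),
               tolerance = 1e-12)
  # single CAG holding everything equals the per-sample total
  ab1 <- cag_abundance(rel, setNames(rep(1L, 4), paste0("o", 1:4)))
  expect_equal(unname(ab1$abundance[, 1]), unname(rowSums(rel)))
  expect_error(cag_abundance(rel[, 1:3], cag), "missing")
})

test_that("paired CAG tests flag the planted arm-specific effect", {
  gs <- guild_spec(3, 5, 0.7)
  eff <- effect_spec(target_guilds = 2, log2_fold_change = 1, arm = "MET")
  ch <- generate_paired_cohort(50, gs, eff, seed = 55)
  tab <- bind_timepoints(ch)
  rel <- relative_abundance(tab)
  truth_cag <- ch$truth$partition
  ab <- cag_abundance(rel, truth_cag)
  res_met <- compare_cag_paired(ab, tab$sample_meta, arm = "MET")
  res_amc <- compare_cag_paired(ab, tab$sample_meta, arm = "AMC")
  expect_lt(res_met$p.value[res_met$cag == "CAG2"], 0.05)
  expect_equal(res_met$direction[res_met$cag == "CAG2"], "increased")
  expect_gt(res_amc$p.value[res_amc$cag == "CAG2"], 0.05)

  # identical timepoints: all differences zero -> error path
  ab0 <- ab
  w12 <- grepl("week12", rownames(ab0$abundance))
  ab0$abundance[w12, ] <-
    ab0$abundance[sub("week12", "week0", rownames(ab0$abundance))[w12], ]
  expect_error(compare_cag_paired(ab0, tab$sample_meta, arm = "MET"),
               "degenerate")
})

test_that("network export thresholds edges and flags silent CAGs", {
  rho <- matrix(0, 6, 6)
  rho[1:3, 1:3] <- 0.8
  rho[4:5, 4:5] <- 0.9
  diag(rho) <- 1
  dimnames(rho) <- list(paste0("o", 1:6), paste0("o", 1:6))
  cag <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), paste0("o", 1:6))
  mab <- setNames(rep(0.1, 6), paste0("o", 1:6))

  net <- export_network(rho, cag, mab, edge_threshold = 0.4)
  expect_true(all(net$edges$rho > 0.4))
  within <- cag[net$edges$from] == cag[net$edges$to]
  expect_true(all(within))                 # planted blocks: no cross edges
  expect_equal(net$excluded_cags, 3L)      # the singleton CAG has no edge

  none <- export_network(rho, cag, mab, edge_threshold = 1)
  expect_equal(nrow(none$edges), 0)
  expect_setequal(none$excluded_cags, 1:3)

  full <- export_network(pmax(rho, 0.01), cag, mab, edge_threshold = -1)
  expect_equal(nrow(full$edges), choose(6, 2))

  dir <- tempfile()
  export_network(rho, cag, mab, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("nodes.tsv", "edges.tsv",
                                               "network.graphml")))))
})
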