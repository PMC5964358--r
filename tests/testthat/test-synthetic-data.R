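test_that("guild counts conserve library size and are seed-deterministic", {
  gs <- guild_spec(2, 5, 0.6)
  g <- generate_guild_counts(20, gs, library_size = 3000, seed = 9)
  expect_true(all(rowSums(g$table$counts) == 3000))
  expect_true(all(g$table$counts >= 0))
  g2 <- generate_guild_counts(20, gs, library_size = 3000, seed = 9)
  expect_identical(g, g2)
  g3 <- generate_guild_counts(20, gs, library_size = 3000, seed = 10)
  expect_false(identical(g$table$counts, g3$table$counts))
})

test_that("planted guild structure shows in the latent basis correlations", {
  gs <- guild_spec(4, 10, 0.8, between_corr = 0)
  g <- generate_guild_counts(200, gs, seed = 3)
  cc <- cor(g$basis)
  within <- cc[outer(g$partition, g$partition, "==") & upper.tri(cc)]
  between <- cc[outer(g$partition, g$partition, "!=") & upper.tri(cc)]
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.7)
  expect_lt(abs(mean(between)), 0.1)
})

test_that("uncorrelated single-guild counts yield near-zero clr correlations", {
  # D large enough that the residual clr closure bias -1/(D-1) is small
  gs <- guild_spec(1, 50, 0)
  g <- generate_guild_counts(500, gs, library_size = 20000, seed = 11)
  f <- (g$table$counts + 0.5) / rowSums(g$table$counts + 0.5)
  clr <- log(f) - rowMeans(log(f))
  cc <- cor(clr)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.05)
})

test_that("invalid guild specs are rejected", {
  expect_error(guild_spec(2, 5, 0.2, between_corr = 0.5), "within_corr")
  expect_error(guild_spec(2, 5, 1.2), "within_corr")
})

test_that("paired cohort plants arm-specific fold changes", {
  gs <- guild_spec(3, 5, 0.7)
  eff <- effect_spec(target_guilds = 2, log2_fold_change = 1, arm = "MET")
  ch <- generate_paired_cohort(30, gs, eff, seed = 21)
  rel0 <- relative_abundance(ch$table_week0)
  rel12 <- relative_abundance(ch$table_week12)
  g2 <- names(ch$truth$partition)[ch$truth$partition == 2]
  arm <- ch$table_week0$sample_meta$arm
  d_met <- mean(rowSums(rel12[arm == "MET", g2])) -
    mean(rowSums(rel0[arm == "MET", g2]))
  d_amc <- mean(rowSums(rel12[arm == "AMC", g2])) -
    mean(rowSums(rel0[arm == "AMC", g2]))
  expect_gt(d_met, 0.05)
  expect_lt(abs(d_amc), 0.05)
})

test_that("null cohort timepoints are exchangeable", {
  gs <- guild_spec(3, 5, 0.7)
  eff <- effect_spec()
  ch <- generate_paired_cohort(50, gs, eff, seed = 33)
  rel0 <- relative_abundance(ch$table_week0)
  rel12 <- relative_abundance(ch$table_week12)
  p <- vapply(seq_len(ncol(rel0)), function(j) {
    suppressWarnings(wilcox.test(rel0[, j], rel12[, j])$p.value)
  }, numeric(1))
  expect_gt(median(p), 0.2)
})

test_that("clinical deltas track the planted guild coupling", {
  gs <- guild_spec(3, 5, 0.7)
  eff <- effect_spec(target_guilds = 1, log2_fold_change = 1, arm = "both",
                     clinical_couplings = list(
                       FBG = list(guild = 1, slope = -1, sd = 0.01)))
  ch <- generate_paired_cohort(50, gs, eff, seed = 17)
  d_clin <- ch$clinical$FBG_week12 - ch$clinical$FBG_week0
  d_guild <- ch$truth$guild_delta[, "guild1"]
  ct <- cor.test(d_guild, d_clin, method = "spearman")
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)

  expect_error(generate_paired_cohort(
    10, gs, effect_spec(clinical_couplings =
                          list(X = list(guild = 9, slope = 1, sd = 1))),
    seed = 1), "unknown guild")
})

test_that("read-pair generator honors overlap geometry and error profile", {
  tpl <- random_template(440, seed = 2)   # 2*250 - 60
  rp <- generate_read_pairs(tpl, 25, read_len = 250, overlap_len = 60,
                            error_profile = 40, qual_sd = 0, seed = 8)
  merged <- vapply(seq_along(rp$fwd), function(i) {
    !guildscan:::is_merge_rejection(merge_pair(rp$fwd[[i]], rp$rev[[i]]))
  }, logical(1))
  expect_true(all(merged))

  rp49 <- generate_read_pairs(random_template(451, seed = 3), 10,
                              read_len = 250, overlap_len = 49,
                              error_profile = 40, qual_sd = 0, seed = 8)
  rej <- vapply(seq_along(rp49$fwd), function(i) {
    guildscan:::is_merge_rejection(merge_pair(rp49$fwd[[i]], rp49$rev[[i]]))
  }, logical(1))
  expect_true(all(rej))

  # low-quality terminal bases are trimmed by their run length
  prof <- c(rep(10, 5), rep(38, 240), rep(10, 5))
  rp_lo <- generate_read_pairs(tpl, 1, read_len = 250, overlap_len = 60,
                               error_profile = prof, qual_sd = 0, seed = 4)
  tr <- trim_low_quality_ends(rp_lo$fwd[[1]])
  expect_equal(nchar(tr$bases), 240)

  expect_error(generate_read_pairs(random_template(100, seed = 1), 1,
                                   read_len = 80, overlap_len = 20,
                                   seed = 1),
               "shorter than")
})

test_that("random trees are rooted binary with the requested leaves", {
  labs <- sprintf("OTU%02d", 1:12)
  tr <- generate_random_tree(labs, seed = 6)
  expect_setequal(tr$tip.label, labs)
  expect_equal(tr$Nnode, 11)               # n - 1 internal nodes
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))

  expect_identical(ape::write.tree(generate_random_tree(labs, seed = 6)),
                   ape::write.tree(tr))

  tr2 <- generate_random_tree(c("a", "b"), seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_error(generate_random_tree(c("a", "a"), seed = 1), "duplicate")
})
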