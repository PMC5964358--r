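star_tree <- function(labels) {
  ape::read.tree(text = paste0("(", paste0(labels, ":1", collapse = ","),
                               ");"))
}

test_that("all five distances hit their closed-form anchors", {
  counts <- matrix(c(2, 0, 1,
                     1, 1, 1), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_equal(as.matrix(distance_matrix(counts, "bray_curtis"))[1, 2],
               1 / 3, tolerance = 1e-12)

  ident <- rbind(s1 = c(2, 0, 1), s2 = c(2, 0, 1))
  colnames(ident) <- c("a", "b", "c")
  tr <- star_tree(c("a", "b", "c"))
  for (m in c("bray_curtis", "jaccard_binary", "jaccard_weighted")) {
    expect_equal(as.matrix(distance_matrix(ident, m))[1, 2], 0)
  }
  for (m in c("unifrac_unweighted", "unifrac_weighted")) {
    expect_equal(as.matrix(distance_matrix(ident, m, tree = tr))[1, 2], 0)
  }

  disj <- rbind(s1 = c(3, 2, 0, 0), s2 = c(0, 0, 1, 4))
  colnames(disj) <- letters[1:4]
  tr4 <- star_tree(letters[1:4])
  for (m in c("bray_curtis", "jaccard_binary", "jaccard_weighted")) {
    expect_equal(as.matrix(distance_matrix(disj, m))[1, 2], 1)
  }
  for (m in c("unifrac_unweighted", "unifrac_weighted")) {
    expect_equal(as.matrix(distance_matrix(disj, m, tree = tr4))[1, 2], 1)
  }

  # presence/absence input of equal richness (so closure rescales both
  # samples identically): weighted jaccard reduces to binary jaccard
  pa <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 1, 0))
  colnames(pa) <- letters[1:4]
  expect_equal(as.matrix(distance_matrix(pa, "jaccard_weighted")),
               as.matrix(distance_matrix(pa, "jaccard_binary")))
})

test_that("distances stay bounded and agree with vegan/picante oracles", {
  gs <- guild_spec(2, 6, 0.5)
  g <- generate_guild_counts(12, gs, 2000, seed = 14)
  rel <- relative_abundance(g$table)
  tr <- generate_random_tree(colnames(rel), seed = 5)
  for (m in c("bray_curtis", "jaccard_binary", "jaccard_weighted",
              "unifrac_unweighted", "unifrac_weighted")) {
    dm <- as.matrix(distance_matrix(g$table, m, tree = tr))
    expect_true(all(dm >= 0 & dm <= 1 + 1e-12), info = m)
    expect_equal(dm, t(dm), tolerance = 1e-12)
    expect_true(all(diag(dm) == 0), info = m)
  }
  skip_if_not_installed("vegan")
  expect_equal(as.matrix(distance_matrix(g$table, "bray_curtis")),
               as.matrix(vegan::vegdist(rel, "bray")),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.matrix(distance_matrix(g$table, "jaccard_binary")),
               as.matrix(vegan::vegdist(rel, "jaccard", binary = TRUE)),
               tolerance = 1e-10, ignore_attr = TRUE)
  skip_if_not_installed("picante")
  expect_equal(
    as.matrix(distance_matrix(g$table, "unifrac_unweighted", tree = tr)),
    as.matrix(picante::unifrac(rel, tr)),
    tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("UniFrac rejects trees missing leaves", {
  counts <- rbind(s1 = c(1, 1), s2 = c(1, 2))
  colnames(counts) <- c("a", "zzz")
  expect_error(distance_matrix(counts, "unifrac_unweighted",
                               tree = star_tree(c("a", "b"))),
               "zzz")
})

test_that("PCA scores span the data variance", {
  set.seed(8)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  ord <- pca_ordination(x)
  expect_equal(sum(ord$eig), sum(apply(x, 2, var)), tolerance = 1e-10)
  expect_true(all(diff(ord$eig) <= 1e-12))
  # duplicated samples coincide in score space
  x2 <- rbind(x, dup = x[1, ])
  rownames(x2)[11] <- "dup"
  ord2 <- pca_ordination(x2)
  expect_equal(unname(ord2$scores["dup", ]), unname(ord2$scores["s1", ]),
               tolerance = 1e-10)
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord <- pcoa_ordination(distance_matrix_obj(d, "euclidean"))
  rec <- as.matrix(dist(ord$scores[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # eigenvalue sum equals the trace of the Gower-centered matrix
  a <- -0.5 * d^2
  ctr <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(ord$eig), sum(diag(ctr)), tolerance = 1e-8)

  # three equidistant points: the two axes carry equal eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord3 <- pcoa_ordination(distance_matrix_obj(d3, "custom"))
  expect_equal(ord3$eig[1], ord3$eig[2], tolerance = 1e-10)
})

test_that("MANOVA on scores detects shifts and rejects degenerate input", {
  set.seed(5)
  scores <- matrix(rnorm(200), 100, 2)
  grp <- rep(c("a", "b"), each = 50)
  shifted <- scores
  shifted[grp == "b", ] <- shifted[grp == "b", ] + 2
  expect_lt(manova_on_scores(shifted, grp)$p.value, 1e-4)
  expect_error(manova_on_scores(scores, rep("a", 100)), "2 groups")

  # null calibration: p-values approximately uniform
  pvals <- vapply(1:200, function(i) {
    manova_on_scores(matrix(rnorm(80), 40, 2),
                     sample(rep(c("a", "b"), each = 20)))$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("PERMANOVA separates planted clouds and matches vegan", {
  set.seed(3)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  lab <- rep(c("a", "b"), each = 10)
  res <- permanova(distance_matrix_obj(d, "euclidean"), lab,
                   n_perm = 999, seed = 2)
  expect_equal(res$p.value, 1 / 1000)

  expect_error(permanova(d, c("a", rep("b", 19))), "at least 2 members")

  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(as.dist(d) ~ lab,
                       permutations = 99,
                       data = data.frame(lab = lab))
  expect_equal(res$f, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA F-ratio is invariant to balanced sample duplication", {
  set.seed(6)
  pts <- rnorm(12)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  lab <- rep(c("a", "b"), 6)
  r1 <- permanova(d, lab, n_perm = 9, seed = 1)
  dd <- as.matrix(dist(c(pts, pts)))
  dimnames(dd) <- list(paste0("s", 1:24), paste0("s", 1:24))
  r2 <- permanova(dd, c(lab, lab), n_perm = 9, seed = 1)
  # the among/within sum-of-squares ratio is duplication-invariant; the
  # pseudo-F rescales only through its degrees of freedom
  expect_equal(r1$ss_among / r1$ss_within, r2$ss_among / r2$ss_within,
               tolerance = 1e-10)
  expect_equal(r2$f, r1$f * (r2$df2 / r1$df2) * (r1$df1 / r2$df1),
               tolerance = 1e-10)
})

test_that("per-subject shifts are zero for identical timepoints", {
  gs <- guild_spec(2, 4, 0.5)
  ch <- generate_paired_cohort(5, gs, effect_spec(), seed = 44)
  tab <- bind_timepoints(ch)
  # make week12 identical to week0 for one subject
  dm <- distance_matrix(tab, "bray_curtis")
  m <- as.matrix(dm)
  m["subj001_week12", ] <- m["subj001_week0", ]
  m[, "subj001_week12"] <- m[, "subj001_week0"]
  m["subj001_week0", "subj001_week12"] <- 0
  m["subj001_week12", "subj001_week0"] <- 0
  res <- paired_shift_comparison(distance_matrix_obj(m, "bray_curtis"),
                                 tab$sample_meta)
  expect_equal(res$shifts[res$shifts$subject == "subj001", "bray_curtis"], 0)
  expect_equal(nrow(res$tests), 1)
  expect_true(res$tests$p.value > 0 && res$tests$p.value <= 1)
})
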