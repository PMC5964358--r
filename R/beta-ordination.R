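# Beta diversity over five bounded metrics, PCA/PCoA ordination, MANOVA on
# scores, a seeded one-way PERMANOVA engine, and the per-subject
# microbiota-shift comparison between arms.

dm_metrics <- c("bray_curtis", "jaccard_binary", "jaccard_weighted",
                "unifrac_unweighted", "unifrac_weighted")

#' Construct a labeled distance matrix
#'
#' @param m symmetric nonnegative matrix with zero diagonal; dimnames
#'   required.
#' @param metric metric tag (free-form; the five pipeline metrics are
#'   `r paste(dm_metrics, collapse = ", ")`).
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix_obj <- function(m, metric = "custom") {
  m <- as.matrix(m)
  check_symmetric(m, tol = 1e-12, what = "distance matrix")
  if (any(abs(diag(m)) > 0)) stop("distance matrix diagonal must be 0")
  if (any(m < -1e-12)) stop("distances must be nonnegative")
  diag(m) <- 0
  m[m < 0] <- 0
  if (is.null(rownames(m))) stop("distance matrix must carry labels")
  structure(list(matrix = m, metric = metric, labels = rownames(m)),
            class = "distance_matrix")
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$matrix

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s over %d samples (range %.3f-%.3f)\n",
              x$metric, nrow(x$matrix), min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Pairwise beta-diversity distances
#'
#' Metrics (all bounded in `[0, 1]`), computed on per-sample relative
#' abundances (presence/absence for the binary metrics):
#' * `bray_curtis`: `sum|x-y| / sum(x+y)`
#' * `jaccard_binary`: `1 - |A ∩ B| / |A ∪ B]`
#' * `jaccard_weighted` (Ruzicka): `1 - sum min(x,y) / sum max(x,y)`
#' * `unifrac_unweighted`: branch length unique to one community over the
#'   branch length observed in either
#' * `unifrac_weighted`: normalized weighted form,
#'   `sum b |p_A - p_B| / sum b (p_A + p_B)`
#'
#' @param table an [otu_table()] or counts/abundance matrix (samples x
#'   OTUs).
#' @param metric one of the five metric names.
#' @param tree a `phylo` tree covering every OTU (UniFrac metrics only).
#' @return A [distance_matrix_obj()].
#' @export
distance_matrix <- function(table, metric, tree = NULL) {
  metric <- match.arg(metric, dm_metrics)
  x <- relative_abundance(table)
  n <- nrow(x)
  labs <- rownames(x)
  if (startsWith(metric, "unifrac")) {
    if (is.null(tree)) stop("UniFrac requires a phylogenetic tree")
    return(unifrac_distance(x, tree, weighted = metric == "unifrac_weighted"))
  }
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- x[i, ]; b <- x[j, ]
      d <- switch(metric,
        bray_curtis = sum(abs(a - b)) / sum(a + b),
        jaccard_binary = {
          pa <- a > 0; pb <- b > 0
          1 - sum(pa & pb) / sum(pa | pb)
        },
        jaccard_weighted = 1 - sum(pmin(a, b)) / sum(pmax(a, b)))
      m[i, j] <- m[j, i] <- d
    }
  }
  distance_matrix_obj(m, metric)
}

# Per-edge descendant abundance totals by postorder accumulation; the core
# of both UniFrac variants.
unifrac_distance <- function(x, tree, weighted) {
  missing <- setdiff(colnames(x), tree$tip.label)
  if (length(missing)) {
    stop("tree is missing leaves for OTU(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n <- nrow(x)
  node_ab <- matrix(0, n, ntip + nnode)
  # tips absent from the table keep zero abundance in every sample
  present <- which(tree$tip.label %in% colnames(x))
  node_ab[, present] <- x[, tree$tip.label[present], drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    node_ab[, tree$edge[e, 1]] <- node_ab[, tree$edge[e, 1]] +
      node_ab[, tree$edge[e, 2]]
  }
  edge_ab <- node_ab[, tree$edge[, 2], drop = FALSE]  # samples x edges
  blen <- tree$edge.length
  labs <- rownames(x)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pa <- edge_ab[i, ]; pb <- edge_ab[j, ]
      d <- if (weighted) {
        denom <- sum(blen * (pa + pb))
        if (denom == 0) 0 else sum(blen * abs(pa - pb)) / denom
      } else {
        ha <- pa > 0; hb <- pb > 0
        denom <- sum(blen[ha | hb])
        if (denom == 0) 0 else sum(blen[xor(ha, hb)]) / denom
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  distance_matrix_obj(
    m, if (weighted) "unifrac_weighted" else "unifrac_unweighted")
}

#' Principal-component analysis of a normalized table
#'
#' Column-centered (unscaled) PCA of the log10-normalized abundance matrix.
#'
#' @param x real matrix (samples x OTUs), e.g. from [normalize_log()].
#' @return list of class `ordination`: `scores` (samples x components),
#'   `eig` (component variances, nonincreasing), `var_explained`, `method`.
#' @export
pca_ordination <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs >= 2 samples and >= 2 OTUs")
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-300)) stop("rank-0 input")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  structure(list(scores = p$x, eig = eig,
                 var_explained = eig / sum(eig), method = "PCA"),
            class = "ordination")
}

#' Principal-coordinate analysis of a distance matrix
#'
#' Gower double-centering and eigendecomposition. Negative eigenvalues are
#' retained and reported uncorrected; coordinates are built from the
#' positive eigenvalues only.
#'
#' @param dm a [distance_matrix_obj()].
#' @return list of class `ordination`: `scores`, `eig` (all eigenvalues,
#'   nonincreasing, negatives included), `var_explained` (over positive
#'   eigenvalues), `method`.
#' @export
pcoa_ordination <- function(dm) {
  m <- as.matrix(dm)
  n <- nrow(m)
  res <- suppressWarnings(cmdscale(as.dist(m), k = n - 1, eig = TRUE))
  eig <- res$eig
  pos <- eig > max(eig) * 1e-10
  scores <- res$points[, seq_len(min(ncol(res$points), sum(pos))),
                       drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(scores = scores, eig = eig,
                 var_explained = eig[pos] / sum(eig[pos]),
                 method = "PCoA"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, %d samples, first axes explain %s\n",
              x$method, nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * head(x$var_explained, 2)),
                    collapse = " / ")))
  invisible(x)
}

#' One-way MANOVA on leading ordination scores
#'
#' Wilks' lambda with its F approximation on the first `n_components`
#' score columns.
#'
#' @param scores an `ordination` or a samples x components score matrix.
#' @param group_labels grouping factor, one level per sample (>= 2 levels).
#' @param n_components leading components to use (default 2).
#' @return list: `wilks`, `f`, `df1`, `df2`, `p.value`.
#' @export
manova_on_scores <- function(scores, group_labels, n_components = 2L) {
  if (inherits(scores, "ordination")) scores <- scores$scores
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("MANOVA needs at least 2 groups")
  if (n_components < 2) stop("use at least 2 components (MANOVA response)")
  if (n_components > nrow(scores) - nlevels(g)) {
    stop("too many components for the sample size; reduce n_components")
  }
  y <- as.matrix(scores[, seq_len(n_components), drop = FALSE])
  fit <- manova(y ~ g)
  st <- tryCatch(summary(fit, test = "Wilks")$stats,
                 error = function(e) {
                   stop("singular within-group covariance; ",
                        "try fewer components", call. = FALSE)
                 })
  list(wilks = st[1, "Wilks"], f = st[1, "approx F"],
       df1 = st[1, "num Df"], df2 = st[1, "den Df"],
       p.value = st[1, "Pr(>F)"])
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances with a seeded
#' label-permutation null: `SS_T = sum_{i<j} d_ij^2 / N`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_A = SS_T - SS_W`,
#' `F = (SS_A/(a-1)) / (SS_W/(N-a))`. The permutation p-value carries the
#' +1 correction: `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param dm a [distance_matrix_obj()] (or square matrix).
#' @param labels grouping vector, every group of size >= 2.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list: `f`, `p.value`, `ss_among`, `ss_within`, `df1`, `df2`,
#'   `n_perm`.
#' @export
permanova <- function(dm, labels, n_perm = 999L, seed = 1L) {
  m <- if (inherits(dm, "distance_matrix")) dm$matrix else as.matrix(dm)
  g <- factor(labels)
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  d2 <- m^2
  n <- nrow(m)
  a <- nlevels(g)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w_of <- function(gr) {
    s <- 0
    for (lv in levels(gr)) {
      idx <- which(gr == lv)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_w <- ss_w_of(g)
  ss_a <- ss_t - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (n - a))
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gp <- g[sample.int(n)]
      sw <- ss_w_of(gp)
      ((ss_t - sw) / (a - 1)) / (sw / (n - a))
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  list(f = f_obs, p.value = p, ss_among = ss_a, ss_within = ss_w,
       df1 = a - 1, df2 = n - a, n_perm = as.integer(n_perm))
}

#' Between-arm comparison of per-subject microbiota shifts
#'
#' The shift of a subject under one metric is the distance between their
#' week-0 and week-12 samples. Shifts are compared between arms with a
#' two-sided Mann-Whitney U test, one test per metric.
#'
#' @param dms a named list of [distance_matrix_obj()]s (one per metric) or
#'   a single one; all computed over the stacked two-timepoint samples.
#' @param sample_meta data.frame with `subject`, `arm`, `timepoint`
#'   (week0/week12) rows matching the distance-matrix labels (rownames).
#' @return list: `shifts` (data.frame subject, arm, one column per metric)
#'   and `tests` (data.frame metric, statistic, p.value). Subjects missing
#'   a timepoint are skipped with a warning.
#' @export
paired_shift_comparison <- function(dms, sample_meta) {
  if (inherits(dms, "distance_matrix")) {
    dms <- setNames(list(dms), dms$metric)
  }
  subjects <- unique(sample_meta$subject)
  rows0 <- rownames(sample_meta)[sample_meta$timepoint == "week0"]
  rows12 <- rownames(sample_meta)[sample_meta$timepoint == "week12"]
  s0 <- setNames(rows0, sample_meta[rows0, "subject"])
  s12 <- setNames(rows12, sample_meta[rows12, "subject"])
  ok <- subjects %in% names(s0) & subjects %in% names(s12)
  if (any(!ok)) {
    warning("skipping subject(s) missing a timepoint: ",
            paste(head(subjects[!ok], 5), collapse = ", "))
    subjects <- subjects[ok]
  }
  arm <- sample_meta[s0[subjects], "arm"]
  shifts <- data.frame(subject = subjects, arm = arm,
                       stringsAsFactors = FALSE)
  tests <- data.frame(metric = names(dms), statistic = NA_real_,
                      p.value = NA_real_, stringsAsFactors = FALSE)
  arms <- unique(arm)
  for (k in seq_along(dms)) {
    m <- as.matrix(dms[[k]])
    sh <- vapply(subjects, function(s) m[s0[[s]], s12[[s]]], numeric(1))
    shifts[[names(dms)[k]]] <- unname(sh)
    if (length(arms) == 2) {
      ht <- wilcox.test(sh[arm == arms[1]], sh[arm == arms[2]],
                        exact = NULL)
      tests$statistic[k] <- unname(ht$statistic)
      tests$p.value[k] <- ht$p.value
    }
  }
  list(shifts = shifts, tests = tests)
}

#' Write a labeled distance matrix as square TSV
#' @param dm a [distance_matrix_obj()].
#' @param path output file.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- cbind(sample = rownames(m), as.data.frame(m, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
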