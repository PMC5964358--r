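# Alpha diversity: observed richness, bias-corrected Chao1, Shannon (log2)
# and Simpson (1 - D), with Monte-Carlo rarefaction curves and the paired
# before/after Wilcoxon comparison.

alpha_metrics <- c("observed_otus", "chao1", "shannon", "simpson")

alpha_one <- function(counts, metric) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total <= 0) stop("alpha diversity undefined on a zero-sum sample")
  s_obs <- length(counts)
  switch(metric,
    observed_otus = s_obs,
    chao1 = {
      f1 <- sum(counts == 1)
      f2 <- sum(counts == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    shannon = {
      p <- counts / total
      -sum(p * log2(p))
    },
    simpson = {
      p <- counts / total
      1 - sum(p^2)
    },
    stop("unknown metric '", metric, "'"))
}

#' Alpha diversity of a sample or a table
#'
#' Metrics: `observed_otus` (count of OTUs with nonzero reads); `chao1`
#' (bias-corrected, `S_obs + F1(F1-1)/(2(F2+1))` with F1/F2 the singleton
#' and doubleton counts); `shannon` (`-sum p log2 p`, in bits); `simpson`
#' (`1 - sum p^2`, the complement of Simpson's concentration, in `[0,1]`).
#'
#' @param x a nonnegative integer count vector, or an [otu_table()].
#' @param metric one of the four metric names, or `"all"`.
#' @return For a vector: a scalar (or named vector with `"all"`). For a
#'   table: a data.frame, samples as rows, metrics as columns.
#' @export
alpha_diversity <- function(x, metric = "all") {
  metrics <- if (identical(metric, "all")) alpha_metrics
             else match.arg(metric, alpha_metrics, several.ok = TRUE)
  if (inherits(x, "otu_table")) {
    out <- as.data.frame(lapply(setNames(metrics, metrics), function(m)
      apply(x$counts, 1, alpha_one, metric = m)))
    rownames(out) <- rownames(x$counts)
    return(out)
  }
  res <- vapply(metrics, function(m) alpha_one(as.numeric(x), m), numeric(1))
  if (length(res) == 1L) unname(res) else res
}

#' Monte-Carlo rarefaction curve for one sample
#'
#' Mean observed OTU count over `n_reps` without-replacement subsamples at
#' each depth; depths above the sample total are skipped with a warning.
#'
#' @param counts nonnegative integer vector.
#' @param depths increasing depth grid.
#' @param n_reps subsamples per depth (default 100).
#' @param seed RNG seed.
#' @return data.frame with `depth` and `mean_observed`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 100L, seed = 1L) {
  counts <- as.numeric(counts)
  total <- sum(counts)
  ok <- depths <= total
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " depth(s) above the sample total ", total)
    depths <- depths[ok]
  }
  pool <- rep.int(seq_along(counts), counts)
  with_seed(seed, {
    mean_obs <- vapply(depths, function(d) {
      mean(vapply(seq_len(n_reps), function(i) {
        length(unique(sample(pool, d, replace = FALSE)))
      }, numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, mean_observed = mean_obs)
  })
}

#' Paired before/after comparison of an alpha-diversity metric
#'
#' Two-sided Wilcoxon signed-rank test on per-subject differences
#' (after - before). Zero differences are dropped (the classic Wilcoxon
#' treatment); the test errors when fewer than two nonzero differences
#' remain.
#'
#' @param before,after numeric vectors of per-subject values, aligned by
#'   position (or by names when both are named).
#' @return list: `statistic` (signed-rank V), `p.value`, `n_used`.
#' @export
compare_alpha_paired <- function(before, after) {
  if (!is.null(names(before)) && !is.null(names(after))) {
    after <- after[names(before)]
  }
  if (length(before) != length(after)) {
    stop("before/after must cover the same subjects")
  }
  d <- after - before
  if (sum(d != 0, na.rm = TRUE) < 2) {
    stop("fewer than 2 nonzero paired differences; test undefined")
  }
  ht <- wilcox.test(after, before, paired = TRUE, exact = NULL)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n_used = sum(d != 0, na.rm = TRUE))
}
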