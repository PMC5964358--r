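# Basis (composition-corrected) correlation estimation. Relative-abundance
# data are closed to a constant sum, which biases naive Pearson correlation
# toward -1/(D-1); the estimator here works on the observable log-ratio
# variances t_ij = var log(x_i/x_j), which are invariant to the closure,
# and solves for latent per-OTU basis variances under a sparsity
# approximation.

#' Posterior fraction draws from a count table
#'
#' Each draw samples every sample's composition from
#' `Dirichlet(counts + 1)`, so zero counts still yield strictly positive
#' fractions.
#'
#' @param counts nonnegative integer matrix (samples x OTUs) or
#'   [otu_table()].
#' @param n_draws number of replicate fraction matrices.
#' @param seed RNG seed.
#' @return list of `n_draws` matrices, each samples x OTUs with rows
#'   summing to 1.
#' @export
estimate_fractions <- function(counts, n_draws = 20L, seed = 1L) {
  m <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers")
  }
  n <- nrow(m); d <- ncol(m)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(k) {
      g <- matrix(rgamma(n * d, shape = as.numeric(t(m)) + 1, rate = 1),
                  n, d, byrow = TRUE)
      out <- g / rowSums(g)
      dimnames(out) <- dimnames(m)
      out
    })
  })
}

#' Basis correlations from one fraction matrix
#'
#' Computes the log-ratio variance matrix `t_ij = var log(x_i/x_j)`, solves
#' the sparsity-approximation linear system for the basis variances
#' `omega`, and forms
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
#' clipped to `[-1, 1]`. Strongly correlated pairs violate the sparsity
#' assumption, so the most-correlated pair with `|rho|` above
#' `exclusion_threshold` is iteratively removed from the sums and the
#' system re-solved. By default exclusion iterates until no remaining pair
#' exceeds the threshold (or the system would become singular), so that on
#' data whose non-excluded pairs are truly uncorrelated the solution
#' approaches the no-contamination oracle; `max_exclusions` caps the
#' rounds. OTUs whose solved basis variance is nonpositive are degenerate
#' under the approximation; their correlations are set to 0 with a warning.
#'
#' @param fractions strictly positive samples x OTUs fraction matrix.
#' @param exclusion_threshold `|rho|` above which a pair is excluded from
#'   the variance sums (default 0.1).
#' @param max_exclusions maximum exclusion rounds (default `Inf`:
#'   iterate to convergence).
#' @return Symmetric correlation matrix with unit diagonal, plus an
#'   `excluded` attribute listing the removed pairs.
#' @export
basis_correlations <- function(fractions, exclusion_threshold = 0.1,
                               max_exclusions = Inf) {
  x <- as.matrix(fractions)
  d <- ncol(x)
  if (d < 4) stop("need at least 4 OTUs for the basis-variance system")
  if (any(x <= 0)) stop("fractions must be strictly positive")
  l <- log(x)
  v <- apply(l, 2, var)
  cv <- cov(l)
  tmat <- outer(v, v, "+") - 2 * cv          # t_ij = var(log x_i - log x_j)
  diag(tmat) <- 0

  # helper: solve for omega given the current pair-exclusion mask, then rho
  solve_rho <- function(excl) {
    mmat <- matrix(1, d, d)
    diag(mmat) <- d - 1
    tm <- tmat
    if (length(excl)) {
      for (pr in excl) {
        i <- pr[1]; j <- pr[2]
        mmat[i, j] <- mmat[j, i] <- 0
        mmat[i, i] <- mmat[i, i] - 1
        mmat[j, j] <- mmat[j, j] - 1
        tm[i, j] <- tm[j, i] <- 0
      }
    }
    ti <- rowSums(tm)
    omega <- tryCatch(solve(mmat, ti), error = function(e) NULL)
    if (is.null(omega)) return(NULL)
    bad <- omega <= 0
    om <- pmax(omega, .Machine$double.eps)
    rho <- (outer(om, om, "+") - tmat) / (2 * sqrt(outer(om, om)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (any(bad)) {
      rho[bad, ] <- 0
      rho[, bad] <- 0
      diag(rho) <- 1
    }
    list(rho = rho, bad = bad)
  }

  excl <- list()
  res <- solve_rho(excl)
  if (is.null(res)) stop("basis-variance system is singular")
  round <- 0L
  while (round < max_exclusions) {
    round <- round + 1L
    cand <- abs(res$rho)
    diag(cand) <- 0
    for (pr in excl) cand[pr[1], pr[2]] <- cand[pr[2], pr[1]] <- 0
    top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[top[1], top[2]] <= exclusion_threshold) break
    excl[[length(excl) + 1L]] <- sort(unname(c(top[1], top[2])))
    nxt <- solve_rho(excl)
    if (is.null(nxt)) {
      excl <- excl[-length(excl)]
      break
    }
    res <- nxt
  }
  if (any(res$bad)) {
    warning("nonpositive basis variance for ", sum(res$bad),
            " OTU(s); their correlations were set to 0")
  }
  rho <- res$rho
  dimnames(rho) <- list(colnames(x), colnames(x))
  attr(rho, "excluded") <- excl
  rho
}

#' SparCC-style basis correlations with bootstrap pseudo-p-values
#'
#' The point estimate is the element-wise median of [basis_correlations()]
#' over `n_draws` Dirichlet fraction draws. Significance is assessed by
#' resampling whole samples (rows) with replacement `n_bootstrap` times,
#' re-running the full estimator, and forming two-sided pseudo-p-values
#' `p = (1 + #[|rho_boot| >= |rho_obs|]) / (1 + n_bootstrap)`.
#'
#' @param counts nonnegative integer matrix or [otu_table()] (typically the
#'   prevalence-filtered core table).
#' @param n_draws inner Dirichlet draws (default 20).
#' @param exclusion_threshold see [basis_correlations()].
#' @param n_bootstrap bootstrap resamples for pseudo-p-values (default 100;
#'   0 skips the bootstrap and returns `pvals = NULL`).
#' @param max_exclusions see [basis_correlations()].
#' @param seed RNG seed; the whole result is a pure function of
#'   (inputs, seed).
#' @return list of class `sparcc_result`: `rho` (symmetric, unit
#'   diagonal), `pvals` (same shape; the meaningless diagonal is set to the
#'   smallest attainable value `1/(1+n_bootstrap)`), `n_draws`,
#'   `n_bootstrap`, `excluded` (pairs excluded per draw).
#' @export
sparcc <- function(counts, n_draws = 20L, exclusion_threshold = 0.1,
                   n_bootstrap = 100L, max_exclusions = Inf, seed = 1L) {
  m <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  if (nrow(m) < 8) {
    warning("fewer than 8 samples; SparCC estimates will be unstable")
  }
  point <- function(cnt, sd) {
    draws <- estimate_fractions(cnt, n_draws = n_draws, seed = sd)
    rhos <- lapply(draws, basis_correlations,
                   exclusion_threshold = exclusion_threshold,
                   max_exclusions = max_exclusions)
    arr <- simplify2array(rhos)
    r <- apply(arr, c(1, 2), median)
    attr(r, "excluded") <- lapply(rhos, attr, "excluded")
    r
  }
  rho <- with_seed(seed, suppressWarnings(point(m, sample.int(2^31 - 1, 1))))
  excluded <- attr(rho, "excluded")
  attr(rho, "excluded") <- NULL
  pvals <- NULL
  if (n_bootstrap > 0) {
    exceed <- matrix(0L, nrow(rho), ncol(rho))
    with_seed(seed + 1L, {
      for (b in seq_len(n_bootstrap)) {
        idx <- sample.int(nrow(m), replace = TRUE)
        rb <- suppressWarnings(point(m[idx, , drop = FALSE],
                                     sample.int(2^31 - 1, 1)))
        exceed <- exceed + (abs(rb) >= abs(rho))
      }
    })
    pvals <- (1 + exceed) / (1 + n_bootstrap)
    diag(pvals) <- 1 / (1 + n_bootstrap)
    dimnames(pvals) <- dimnames(rho)
  }
  structure(list(rho = rho, pvals = pvals, n_draws = as.integer(n_draws),
                 n_bootstrap = as.integer(n_bootstrap),
                 excluded = excluded),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(
    "<sparcc_result> %d OTUs, %d draws, %d bootstraps; |rho| mean %.3f, max %.3f\n",
    nrow(x$rho), x$n_draws, x$n_bootstrap, mean(abs(off)), max(abs(off))))
  invisible(x)
}

#' Write SparCC correlation and p-value matrices as TSV
#' @param x a `sparcc_result`.
#' @param rho_path,pvals_path output files (`pvals_path` optional).
#' @export
write_sparcc <- function(x, rho_path, pvals_path = NULL) {
  wr <- function(m, path) {
    df <- cbind(otu = rownames(m), as.data.frame(m, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(x$rho, rho_path)
  if (!is.null(pvals_path) && !is.null(x$pvals)) wr(x$pvals, pvals_path)
  invisible(rho_path)
}
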