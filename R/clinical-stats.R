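# Clinical endpoints and their statistics: HOMA indices, LOCF imputation,
# paired t tests, ANCOVA with the baseline as covariate, and the
# CAG x clinical Spearman association grid.

#' Homeostasis-model (HOMA) indices
#'
#' Matthews-form indices from fasting glucose and insulin:
#' `HOMA-IR = FBG * insulin / 22.5` and
#' `HOMA-beta = 20 * insulin / (FBG - 3.5)`. Units: glucose in mmol/L,
#' insulin in uIU/mL. HOMA-beta is undefined at `FBG <= 3.5` and returned
#' as `NA` with a warning.
#'
#' @param fbg fasting blood glucose (mmol/L), vectorized.
#' @param insulin fasting insulin (uIU/mL), nonnegative.
#' @return data.frame with columns `homa_ir` and `homa_beta`.
#' @export
homa_indices <- function(fbg, insulin) {
  stopifnot(length(fbg) == length(insulin))
  if (any(insulin < 0, na.rm = TRUE)) stop("insulin must be nonnegative")
  ir <- fbg * insulin / 22.5
  beta <- 20 * insulin / (fbg - 3.5)
  bad <- !is.na(fbg) & fbg <= 3.5
  if (any(bad)) {
    warning("HOMA-beta undefined for ", sum(bad),
            " record(s) with FBG <= 3.5 mmol/L; returned NA")
    beta[bad] <- NA_real_
  }
  data.frame(homa_ir = ir, homa_beta = beta)
}

#' Last-observation-carried-forward imputation
#'
#' For each subject, visits are ordered and every missing value is replaced
#' by the most recent prior observed value. Observed values are never
#' altered. Subjects missing the baseline (first scheduled) visit are
#' excluded with a warning.
#'
#' @param data data.frame in long layout: one row per subject-visit.
#' @param subject_col,visit_col column names for subject id and visit
#'   (numeric or ordered).
#' @param value_cols columns to impute.
#' @return The completed data.frame (possibly with subjects dropped).
#' @export
locf_impute <- function(data, subject_col = "subject", visit_col = "week",
                        value_cols) {
  data <- data[order(data[[subject_col]], data[[visit_col]]), ,
               drop = FALSE]
  drop_subjects <- character(0)
  for (s in unique(data[[subject_col]])) {
    idx <- which(data[[subject_col]] == s)
    for (v in value_cols) {
      vals <- data[idx, v]
      if (is.na(vals[1])) {
        drop_subjects <- union(drop_subjects, s)
        next
      }
      for (i in seq_along(vals)[-1]) {
        if (is.na(vals[i])) vals[i] <- vals[i - 1]
      }
      data[idx, v] <- vals
    }
  }
  if (length(drop_subjects)) {
    warning("excluding subject(s) with missing baseline: ",
            paste(head(drop_subjects, 5), collapse = ", "))
    data <- data[!data[[subject_col]] %in% drop_subjects, , drop = FALSE]
  }
  data
}

#' Paired two-tailed t test on a clinical endpoint within one arm
#'
#' @param week0,week12 per-subject values, aligned by position.
#' @return list: `t`, `df`, `p.value`, `mean_delta`.
#' @export
paired_endpoint_test <- function(week0, week12) {
  keep <- !is.na(week0) & !is.na(week12)
  if (sum(keep) < 3) stop("need at least 3 complete pairs")
  d <- week12[keep] - week0[keep]
  if (sd(d) <= sqrt(.Machine$double.eps) * max(1, abs(mean(d)))) {
    stop("zero variance of paired differences; t test undefined")
  }
  ht <- t.test(week12[keep], week0[keep], paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_delta = mean(d))
}

#' ANCOVA comparison of arms with the baseline as covariate
#'
#' Fits `endpoint ~ baseline + arm` by least squares and reports the arm
#' coefficient with its t-based p-value. A constant (collinear) baseline is
#' dropped with a warning, reducing the model to a two-group comparison.
#'
#' @param endpoint week-12 values.
#' @param baseline week-0 values.
#' @param arm two-level grouping vector.
#' @return list: `effect` (adjusted difference, second arm level minus
#'   first), `se`, `t`, `p.value`, `model` (the `lm` fit).
#' @export
ancova_between_arms <- function(endpoint, baseline, arm) {
  g <- factor(arm)
  if (nlevels(g) != 2) stop("ANCOVA comparison requires exactly 2 arms")
  keep <- !is.na(endpoint) & !is.na(baseline) & !is.na(g)
  endpoint <- endpoint[keep]; baseline <- baseline[keep]; g <- droplevels(g[keep])
  if (sd(baseline) == 0) {
    warning("constant baseline; covariate dropped")
    fit <- lm(endpoint ~ g)
  } else {
    fit <- lm(endpoint ~ baseline + g)
  }
  co <- summary(fit)$coefficients
  row <- grep("^g", rownames(co))
  list(effect = co[row, "Estimate"], se = co[row, "Std. Error"],
       t = co[row, "t value"], p.value = co[row, "Pr(>|t|)"], model = fit)
}

#' Spearman association grid between CAG and clinical deltas
#'
#' For every (CAG, clinical variable) pair, the Spearman rank correlation
#' between per-subject deltas (week12 - week0) with its two-sided p-value
#' (exact for small n without ties, t approximation otherwise, as in
#' [stats::cor.test()]). A constant column leaves the pair masked as `NA`
#' with a warning.
#'
#' @param cag_deltas subjects x CAGs matrix of abundance deltas.
#' @param clinical_deltas subjects x variables matrix/data.frame of
#'   clinical deltas, rows aligned with `cag_deltas`.
#' @param key_cags optional subset of CAG columns.
#' @return list of class `association_grid`: `r` and `p` matrices
#'   (CAGs x variables).
#' @export
cag_clinical_association <- function(cag_deltas, clinical_deltas,
                                     key_cags = NULL) {
  cd <- as.matrix(cag_deltas)
  if (!is.null(key_cags)) cd <- cd[, key_cags, drop = FALSE]
  cl <- as.data.frame(clinical_deltas)
  if (nrow(cd) != nrow(cl)) stop("subjects must align across inputs")
  r <- p <- matrix(NA_real_, ncol(cd), ncol(cl),
                   dimnames = list(colnames(cd), colnames(cl)))
  masked <- 0L
  for (i in seq_len(ncol(cd))) {
    for (j in seq_len(ncol(cl))) {
      x <- cd[, i]; y <- cl[[j]]
      if (sd(x, na.rm = TRUE) == 0 || sd(y, na.rm = TRUE) == 0) {
        masked <- masked + 1L
        next
      }
      ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
      r[i, j] <- unname(ht$estimate)
      p[i, j] <- ht$p.value
    }
  }
  if (masked > 0) {
    warning(masked, " constant pair(s) masked as NA")
  }
  structure(list(r = r, p = p), class = "association_grid")
}

#' @export
print.association_grid <- function(x, ...) {
  sig <- sum(x$p < 0.05, na.rm = TRUE)
  cat(sprintf("<association_grid> %d CAGs x %d variables; %d pair(s) at p < 0.05\n",
              nrow(x$r), ncol(x$r), sig))
  invisible(x)
}

#' Write an association grid as a TSV pair
#' @param x an `association_grid`.
#' @param r_path,p_path output files for the R and p matrices.
#' @export
write_association_grid <- function(x, r_path, p_path) {
  wr <- function(m, path) {
    df <- cbind(cag = rownames(m), as.data.frame(m, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(x$r, r_path)
  wr(x$p, p_path)
  invisible(r_path)
}
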