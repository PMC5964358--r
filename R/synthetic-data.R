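# Synthetic data with known ground truth: guild-structured compositional
# counts (correlated log-normal basis -> multinomial reads), paired two-arm
# cohorts with planted fold-changes and clinical couplings, FASTQ read
# pairs, and random trees. All generators are pure functions of
# (parameters, seed).

#' Specify a guild covariance structure
#'
#' Describes the latent (basis) abundance model: log basis abundances are
#' multivariate normal with unit variance, exchangeable correlation
#' `within_corr` inside each guild block and `between_corr` across blocks.
#'
#' @param n_guilds number of guilds.
#' @param otus_per_guild OTUs per guild.
#' @param within_corr target Pearson correlation of log basis abundances
#'   within a guild, in `[0, 1]`.
#' @param between_corr correlation across guilds, in `[0, 1)` (default 0).
#' @param basis_logmean_sd spread (sd) of per-OTU mean log abundances
#'   (default 1).
#' @return A `guild_spec`.
#' @export
guild_spec <- function(n_guilds, otus_per_guild, within_corr,
                       between_corr = 0, basis_logmean_sd = 1) {
  stopifnot(n_guilds >= 1, otus_per_guild >= 1,
            within_corr >= 0, within_corr <= 1,
            between_corr >= 0, between_corr < 1,
            basis_logmean_sd > 0)
  if (within_corr < between_corr) {
    stop("within_corr must be >= between_corr for identifiable guilds")
  }
  structure(list(n_guilds = as.integer(n_guilds),
                 otus_per_guild = as.integer(otus_per_guild),
                 within_corr = within_corr,
                 between_corr = between_corr,
                 basis_logmean_sd = basis_logmean_sd),
            class = "guild_spec")
}

# Exchangeable block correlation matrix implied by a guild_spec, with a
# PSD check (rejects a spec whose implied covariance is not PSD).
guild_sigma <- function(spec) {
  d <- spec$n_guilds * spec$otus_per_guild
  sigma <- matrix(spec$between_corr, d, d)
  for (g in seq_len(spec$n_guilds)) {
    idx <- ((g - 1L) * spec$otus_per_guild + 1L):(g * spec$otus_per_guild)
    sigma[idx, idx] <- spec$within_corr
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("guild_spec implies a non-positive-semi-definite covariance ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  }
  sigma
}

# Draw an n x d matrix of correlated standard normals via the symmetric
# eigendecomposition square root (handles the semi-definite boundary).
rmvnorm_block <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  a <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = ncol(sigma))
  matrix(rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% t(a)
}

#' Generate guild-structured compositional counts
#'
#' Per sample, log basis abundances are multivariate normal with the block
#' covariance of `spec` around per-OTU means drawn once from
#' `N(0, basis_logmean_sd^2)`; basis abundances are exponentiated, closed
#' to fractions, and reads drawn by multinomial sampling at `library_size`.
#'
#' @param n_samples number of samples (>= 2).
#' @param spec a [guild_spec()].
#' @param library_size reads per sample (>= 1).
#' @param seed RNG seed.
#' @return list: `table` (an [otu_table()], every row summing to
#'   `library_size`), `partition` (named integer vector, the true OTU ->
#'   guild map), and `basis` (the latent log-basis matrix, exposed for
#'   oracle checks only).
#' @export
generate_guild_counts <- function(n_samples, spec, library_size = 10000L,
                                  seed = 1L) {
  stopifnot(n_samples >= 2, library_size >= 1)
  sigma <- guild_sigma(spec)
  d <- ncol(sigma)
  with_seed(seed, {
    mu <- rnorm(d, 0, spec$basis_logmean_sd)
    logbasis <- sweep(rmvnorm_block(n_samples, sigma), 2, mu, "+")
    draw_counts_from_logbasis(logbasis, library_size, spec)
  })
}

# Shared tail of the generators: close log-basis rows to fractions and
# draw multinomial reads. Not seeded itself; callers hold the seed.
draw_counts_from_logbasis <- function(logbasis, library_size, spec,
                                      sample_ids = NULL) {
  n <- nrow(logbasis)
  d <- ncol(logbasis)
  basis <- exp(logbasis)
  frac <- basis / rowSums(basis)
  counts <- t(vapply(seq_len(n), function(i) {
    as.integer(rmultinom(1, library_size, frac[i, ]))
  }, integer(d)))
  otu_ids <- sprintf("OTU%03d", seq_len(d))
  sample_ids <- sample_ids %||% sprintf("S%03d", seq_len(n))
  dimnames(counts) <- list(sample_ids, otu_ids)
  dimnames(logbasis) <- dimnames(counts)
  partition <- setNames(rep(seq_len(spec$n_guilds),
                            each = spec$otus_per_guild), otu_ids)
  list(table = otu_table(counts), partition = partition, basis = logbasis)
}

#' Specify planted treatment effects and clinical couplings
#'
#' @param target_guilds integer guild indices receiving a fold-change.
#' @param log2_fold_change per-target-guild log2 fold-change at week 12
#'   (scalar recycled).
#' @param arm which arm is treated: `"MET"`, `"AMC"` or `"both"`.
#' @param clinical_couplings named list; each element
#'   `list(guild =, slope =, sd =)` couples a clinical variable's
#'   week12-week0 delta linearly to the named guild's relative-abundance
#'   delta plus Gaussian noise.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(target_guilds = integer(0), log2_fold_change = 0,
                        arm = "both", clinical_couplings = list()) {
  arm <- match.arg(arm, c("MET", "AMC", "both"))
  lfc <- rep_len(log2_fold_change, length(target_guilds))
  stopifnot(all(is.finite(lfc)))
  for (nm in names(clinical_couplings)) {
    cc <- clinical_couplings[[nm]]
    stopifnot(is.numeric(cc$guild), is.numeric(cc$slope), cc$sd > 0)
  }
  structure(list(target_guilds = as.integer(target_guilds),
                 log2_fold_change = lfc, arm = arm,
                 clinical_couplings = clinical_couplings),
            class = "effect_spec")
}

# Nominal baseline distributions (mean, sd) for a few common clinical
# variables, in their conventional units; unknown variables fall back to
# standard normal baselines. Only the deltas carry planted signal.
clinical_baselines <- function(var) {
  defaults <- list(FBG = c(8.5, 1.5), PBG2h = c(14, 3), HbA1c = c(8, 1),
                   insulin = c(12, 5), TG = c(2.5, 0.8), TC = c(5.2, 1),
                   LDLc = c(3.2, 0.8), HDLc = c(1.2, 0.3),
                   weight = c(75, 10), BMI = c(27, 3))
  defaults[[var]] %||% c(0, 1)
}

#' Generate a paired two-arm cohort with planted effects
#'
#' Subjects are split evenly into arms `MET` and `AMC`; each contributes one
#' week-0 and one week-12 sample, both drawn from the guild model of `spec`
#' (independent draws, shared per-OTU means). In the treated arm(s), week-12
#' basis abundances of each target guild are multiplied by
#' `2^log2_fold_change` before closure. Clinical week12-week0 deltas equal
#' `slope * (guild relative-abundance delta) + N(0, sd)` per coupling,
#' computed on the true basis fractions.
#'
#' @param n_per_arm subjects per arm (>= 3).
#' @param spec a [guild_spec()].
#' @param effect an [effect_spec()].
#' @param library_size reads per sample (default 10000).
#' @param seed RNG seed.
#' @return list of class `cohort_dataset`: `table_week0`, `table_week12`
#'   (each an [otu_table()] with `subject`, `arm`, `timepoint` metadata),
#'   `clinical` (wide data.frame: subject, arm, `<var>_week0`,
#'   `<var>_week12`), and `truth` (spec, effect, OTU -> guild partition,
#'   per-subject true guild abundance deltas).
#' @export
generate_paired_cohort <- function(n_per_arm, spec, effect,
                                   library_size = 10000L, seed = 1L) {
  stopifnot(n_per_arm >= 3)
  bad <- setdiff(vapply(effect$clinical_couplings, function(cc)
    as.integer(cc$guild), integer(1)), seq_len(spec$n_guilds))
  if (length(bad)) {
    stop("clinical coupling references unknown guild(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(setdiff(effect$target_guilds, seq_len(spec$n_guilds)))) {
    stop("target_guilds outside 1..n_guilds")
  }

  sigma <- guild_sigma(spec)
  d <- ncol(sigma)
  n <- 2L * n_per_arm
  subjects <- sprintf("subj%03d", seq_len(n))
  arm <- rep(c("MET", "AMC"), each = n_per_arm)
  treated <- if (effect$arm == "both") rep(TRUE, n) else arm == effect$arm

  with_seed(seed, {
    mu <- rnorm(d, 0, spec$basis_logmean_sd)
    lb0 <- sweep(rmvnorm_block(n, sigma), 2, mu, "+")
    lb12 <- sweep(rmvnorm_block(n, sigma), 2, mu, "+")
    guild_of <- rep(seq_len(spec$n_guilds), each = spec$otus_per_guild)
    for (k in seq_along(effect$target_guilds)) {
      g <- effect$target_guilds[k]
      idx <- which(guild_of == g)
      lb12[treated, idx] <- lb12[treated, idx] +
        effect$log2_fold_change[k] * log(2)
    }

    w0 <- draw_counts_from_logbasis(lb0, library_size, spec,
                                    paste0(subjects, "_week0"))
    w12 <- draw_counts_from_logbasis(lb12, library_size, spec,
                                     paste0(subjects, "_week12"))

    # true guild relative abundances per subject/timepoint, from the basis
    frac0 <- exp(lb0) / rowSums(exp(lb0))
    frac12 <- exp(lb12) / rowSums(exp(lb12))
    g_ab0 <- vapply(seq_len(spec$n_guilds), function(g)
      rowSums(frac0[, guild_of == g, drop = FALSE]), numeric(n))
    g_ab12 <- vapply(seq_len(spec$n_guilds), function(g)
      rowSums(frac12[, guild_of == g, drop = FALSE]), numeric(n))
    g_delta <- g_ab12 - g_ab0
    colnames(g_delta) <- paste0("guild", seq_len(spec$n_guilds))

    clinical <- data.frame(subject = subjects, arm = arm,
                           stringsAsFactors = FALSE)
    for (nm in names(effect$clinical_couplings)) {
      cc <- effect$clinical_couplings[[nm]]
      bl <- clinical_baselines(nm)
      base <- rnorm(n, bl[1], bl[2])
      delta <- cc$slope * g_delta[, cc$guild] + rnorm(n, 0, cc$sd)
      clinical[[paste0(nm, "_week0")]] <- base
      clinical[[paste0(nm, "_week12")]] <- base + delta
    }

    meta0 <- data.frame(subject = subjects, arm = arm, timepoint = "week0",
                        stringsAsFactors = FALSE)
    meta12 <- data.frame(subject = subjects, arm = arm, timepoint = "week12",
                         stringsAsFactors = FALSE)
    structure(list(
      table_week0 = otu_table(w0$table$counts, sample_meta = meta0),
      table_week12 = otu_table(w12$table$counts, sample_meta = meta12),
      clinical = clinical,
      truth = list(spec = spec, effect = effect, partition = w0$partition,
                   guild_delta = g_delta)),
      class = "cohort_dataset")
  })
}

#' Stack the two timepoint tables of a cohort into one table
#' @param cohort a `cohort_dataset`.
#' @return An [otu_table()] with both timepoints and full metadata.
#' @export
bind_timepoints <- function(cohort) {
  counts <- rbind(cohort$table_week0$counts, cohort$table_week12$counts)
  meta <- rbind(cohort$table_week0$sample_meta,
                cohort$table_week12$sample_meta)
  otu_table(counts, sample_meta = meta)
}

#' Generate overlapping paired-end reads from templates
#'
#' For each template the forward read covers positions `1..read_len` and the
#' reverse read (emitted reverse-complemented, as sequenced) covers the last
#' `read_len` positions of the first `2*read_len - overlap_len` template
#' bases, so mates overlap by exactly `overlap_len`. Per-base qualities are
#' drawn as `round(N(profile, qual_sd))` clipped to `[2, 41]`, and each base
#' is substituted with probability `10^(-Q/10)`.
#'
#' @param templates character vector of template sequences (each at least
#'   `2*read_len - overlap_len` long).
#' @param n_reads_per_template pairs per template.
#' @param read_len read length.
#' @param overlap_len exact overlap between mates (`<= read_len`).
#' @param error_profile per-position mean Phred scores (recycled to
#'   `read_len`), default Q35.
#' @param qual_sd sd of the quality draw (0 gives the profile exactly).
#' @param seed RNG seed.
#' @return list with `fwd` and `rev`, equal-length lists of
#'   [seq_record()]s; mates pair by position.
#' @export
generate_read_pairs <- function(templates, n_reads_per_template, read_len,
                                overlap_len, error_profile = 35,
                                qual_sd = 0, seed = 1L) {
  stopifnot(length(templates) >= 1, overlap_len <= read_len,
            n_reads_per_template >= 1)
  span <- 2L * read_len - overlap_len
  short <- nchar(templates) < span
  if (any(short)) {
    stop("template(s) shorter than 2*read_len - overlap_len = ", span, ": ",
         paste(head(which(short), 5), collapse = ", "))
  }
  profile <- rep_len(error_profile, read_len)
  with_seed(seed, {
    fwd <- list(); rev_ <- list()
    k <- 0L
    for (ti in seq_along(templates)) {
      tpl <- toupper(substr(templates[ti], 1L, span))
      f_tpl <- substr(tpl, 1L, read_len)
      r_tpl <- substr(tpl, span - read_len + 1L, span)
      for (j in seq_len(n_reads_per_template)) {
        k <- k + 1L
        id <- sprintf("tpl%d_read%d", ti, j)
        f <- mutate_read(f_tpl, profile, qual_sd)
        r <- mutate_read(r_tpl, profile, qual_sd)
        fwd[[k]] <- seq_record(paste0(id, "/1"), f$bases, f$quals)
        rev_[[k]] <- seq_record(paste0(id, "/2"), revcomp(r$bases),
                                rev(r$quals))
      }
    }
    list(fwd = fwd, rev = rev_)
  })
}

# Draw qualities around the profile and inject substitution errors at the
# Phred-implied rate. Uses the ambient RNG stream.
mutate_read <- function(tpl, profile, qual_sd) {
  n <- nchar(tpl)
  q <- as.integer(pmin(41, pmax(2, round(rnorm(n, profile, qual_sd)))))
  bases <- strsplit(tpl, "", fixed = TRUE)[[1]]
  err <- runif(n) < 10^(-q / 10)
  if (any(err)) {
    for (i in which(err)) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
    }
  }
  list(bases = paste(bases, collapse = ""), quals = q)
}

#' Generate a random DNA template
#' @param len template length.
#' @param seed RNG seed.
#' @return A DNA string.
#' @export
random_template <- function(len, seed = 1L) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

#' Generate a random rooted binary tree over OTU labels
#'
#' @param otu_labels unique leaf labels (>= 2).
#' @param seed RNG seed.
#' @return An [ape::rtree()]-style `phylo` object with strictly positive
#'   branch lengths; byte-identical newick on repeated calls with the same
#'   seed.
#' @export
generate_random_tree <- function(otu_labels, seed = 1L) {
  if (length(otu_labels) < 2) stop("need at least 2 labels")
  if (anyDuplicated(otu_labels)) stop("duplicate OTU labels")
  with_seed(seed, ape::rtree(length(otu_labels), rooted = TRUE,
                             tip.label = sample(otu_labels)))
}

#' Write the ground-truth sidecar of a synthetic dataset as JSON
#'
#' @param truth the `truth` element of a `cohort_dataset` or the
#'   `partition` of [generate_guild_counts()].
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE), path)
  invisible(path)
}
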