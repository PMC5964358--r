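# Fixtures built in code at test time; nothing on disk.

# A 60-pair FASTQ-level QC fixture with known composition:
#   20 clean pairs        -> merge to 400 bp at ~Q40, pass
#   20 pairs, 49-bp overlap -> rejected at the >= 50 bp merge rule
#   10 pairs merging to 399 bp -> rejected by the length filter
#   10 pairs at Q23       -> merge but fail the expected-error filter
make_qc_fixture <- function(seed = 101) {
  tpl400 <- random_template(400, seed = seed)
  tpl451 <- random_template(451, seed = seed + 1)
  tpl399 <- random_template(399, seed = seed + 2)
  clean <- generate_read_pairs(tpl400, 20, read_len = 250, overlap_len = 100,
                               error_profile = 40, qual_sd = 0,
                               seed = seed + 3)
  short_ov <- generate_read_pairs(tpl451, 20, read_len = 250,
                                  overlap_len = 49, error_profile = 40,
                                  qual_sd = 0, seed = seed + 4)
  short_len <- generate_read_pairs(tpl399, 10, read_len = 225,
                                   overlap_len = 51, error_profile = 40,
                                   qual_sd = 0, seed = seed + 5)
  high_ee <- generate_read_pairs(tpl400, 10, read_len = 250,
                                 overlap_len = 100, error_profile = 23,
                                 qual_sd = 0, seed = seed + 6)
  list(fwd = c(clean$fwd, short_ov$fwd, short_len$fwd, high_ee$fwd),
       rev = c(clean$rev, short_ov$rev, short_len$rev, high_ee$rev))
}

# Flat seq_record constructor for hand-built reads
rec <- function(bases, quals, id = "r") seq_record(id, bases, quals)

# Adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- si * sj / comb2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (no ties / zeros assumed).
wilcoxon_signed_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  if (v_obs > n * (n + 1) / 4) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank configurations
mann_whitney_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # U statistic for x
  idx <- utils::combn(n + m, n)
  base_ranks <- seq_len(n + m)
  w_all <- apply(idx, 2, function(sel) sum(base_ranks[sel])) -
    n * (n + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  if (w_obs > n * m / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}
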