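# Read quality control: end trimming, overlap merging, length/expected-error
# filtering. The three rules run in fixed order (trim -> merge -> filter).

#' Construct a sequence record
#'
#' A minimal container for one read: an id, a DNA string over A/C/G/T/N and
#' an integer Phred quality per base.
#'
#' @param id character scalar read identifier.
#' @param bases DNA string (uppercase A/C/G/T/N).
#' @param quals integer vector of Phred scores, one per base, in `[0, 60]`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, bases, quals) {
  bases <- toupper(as.character(bases))
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals)) {
    stop("bases and quals must have equal length (read '", id, "')")
  }
  if (length(quals) && (min(quals) < 0L || max(quals) > 60L)) {
    stop("Phred scores must lie in [0, 60] (read '", id, "')")
  }
  if (nchar(bases) && grepl("[^ACGTN]", bases)) {
    stop("bases must be over the alphabet {A,C,G,T,N} (read '", id, "')")
  }
  structure(list(id = id, bases = bases, quals = quals),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  [%d bp, mean Q %.1f]\n", x$id,
              nchar(x$bases),
              if (length(x$quals)) mean(x$quals) else NA_real_))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$bases)

#' Trim low-quality ends of a read
#'
#' Strips the longest prefix and suffix such that the first and last retained
#' base both have Phred quality strictly greater than `q_threshold`. Interior
#' bases are never touched; the scan moves end-inward from both ends only.
#' The empty read is a legal result (it is removed later by the length
#' filter).
#'
#' @param read a [seq_record()].
#' @param q_threshold bases with quality `<= q_threshold` are trimmed from
#'   the ends (default 20).
#' @return A trimmed `seq_record` (possibly empty).
#' @export
trim_low_quality_ends <- function(read, q_threshold = 20L) {
  q <- read$quals
  keep <- which(q > q_threshold)
  if (!length(keep)) {
    return(seq_record(read$id, "", integer(0)))
  }
  from <- keep[1]
  to <- keep[length(keep)]
  seq_record(read$id, substr(read$bases, from, to), q[from:to])
}

#' Expected number of sequencing errors of a read
#'
#' The sum over bases of the Phred-implied error probability,
#' `sum(10^(-Q/10))`.
#'
#' @param quals integer Phred vector (nonempty).
#' @return Expected error count (real).
#' @export
expected_errors <- function(quals) {
  if (!length(quals)) stop("expected_errors() requires a nonempty read")
  sum(10^(-as.numeric(quals) / 10))
}

#' Merge a forward/reverse read pair by ungapped overlap
#'
#' The reverse read is reverse-complemented, then every suffix(forward) /
#' prefix(reverse-complement) overlap of length at least `min_overlap` is
#' scored. Among overlaps whose mismatch fraction is `<= max_mismatch_frac`
#' the one maximizing matches minus mismatches (ties: the longer overlap) is
#' merged. In the overlap the base with the higher Phred quality is emitted
#' and its quality is the maximum of the two (ties keep the forward base);
#' no posterior quality recomputation is attempted.
#'
#' @param fwd,rev forward and reverse [seq_record()]s; `rev` is in raw
#'   sequencing orientation.
#' @param min_overlap minimum acceptable overlap length in bp (default 50).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @return A merged `seq_record`, or `NULL` with attribute-free rejection:
#'   a list of class `merge_rejection` carrying a `reason` string
#'   (`"too_short_to_merge"` or `"no_overlap"`).
#' @export
merge_pair <- function(fwd, rev, min_overlap = 50L, max_mismatch_frac = 0.1) {
  nf <- nchar(fwd$bases)
  nr <- nchar(rev$bases)
  if (nf < min_overlap || nr < min_overlap) {
    return(structure(list(reason = "too_short_to_merge"),
                     class = "merge_rejection"))
  }
  rc_bases <- strsplit(revcomp(rev$bases), "", fixed = TRUE)[[1]]
  rc_quals <- rev(rev$quals)
  f_bases <- strsplit(fwd$bases, "", fixed = TRUE)[[1]]
  f_quals <- fwd$quals

  best <- NULL
  best_score <- -Inf
  for (L in seq(min_overlap, min(nf, nr))) {
    fi <- (nf - L + 1L):nf
    ri <- 1L:L
    mism <- sum(f_bases[fi] != rc_bases[ri])
    if (mism / L > max_mismatch_frac) next
    score <- (L - mism) - mism
    if (score > best_score || (score == best_score && L > best$L)) {
      best <- list(L = L, mism = mism)
      best_score <- score
    }
  }
  if (is.null(best)) {
    return(structure(list(reason = "no_overlap"), class = "merge_rejection"))
  }
  L <- best$L
  fi <- (nf - L + 1L):nf
  ri <- 1L:L
  take_rev <- rc_quals[ri] > f_quals[fi]
  ov_bases <- ifelse(take_rev, rc_bases[ri], f_bases[fi])
  ov_quals <- pmax(f_quals[fi], rc_quals[ri])
  merged_bases <- paste(c(f_bases[seq_len(nf - L)], ov_bases,
                          rc_bases[seq(L + 1L, length.out = nr - L)]),
                        collapse = "")
  merged_quals <- c(f_quals[seq_len(nf - L)], ov_quals,
                    rc_quals[seq(L + 1L, length.out = nr - L)])
  seq_record(paste0(fwd$id, ":merged"), merged_bases, merged_quals)
}

is_merge_rejection <- function(x) inherits(x, "merge_rejection")

#' Length and expected-error filter for merged reads
#'
#' Keeps a read iff its length is `>= min_len` and its expected errors are
#' strictly `< max_ee`. With the defaults this is "longer than 399 bp and
#' fewer than 0.5 expected errors".
#'
#' @param merged list of merged [seq_record()]s.
#' @param min_len minimum retained length (default 400).
#' @param max_ee strict upper bound on expected errors (default 0.5).
#' @return list with `reads` (the survivors) and `reasons` (named integer
#'   counts of rejections: `too_short`, `high_expected_errors`).
#' @export
filter_reads <- function(merged, min_len = 400L, max_ee = 0.5) {
  reasons <- c(too_short = 0L, high_expected_errors = 0L)
  keep <- vector("list", length(merged))
  k <- 0L
  for (r in merged) {
    if (nchar(r$bases) < min_len) {
      reasons[["too_short"]] <- reasons[["too_short"]] + 1L
    } else if (expected_errors(r$quals) >= max_ee) {
      reasons[["high_expected_errors"]] <-
        reasons[["high_expected_errors"]] + 1L
    } else {
      k <- k + 1L
      keep[[k]] <- r
    }
  }
  list(reads = keep[seq_len(k)], reasons = reasons)
}

#' Run the full three-rule QC procedure on paired reads
#'
#' Fixed order: (i) end-trim both mates at quality `<= trunc_qual`;
#' (ii) merge pairs with an overlap of at least `min_overlap` bp;
#' (iii) keep merged reads of length `>= min_len` with expected errors
#' `< max_ee`.
#'
#' @param fwd,rev equal-length lists of [seq_record()]s (mate pairs by
#'   position).
#' @param trunc_qual end-trim threshold (rule i), default 20.
#' @param min_overlap minimum merge overlap (rule ii), default 50.
#' @param max_mismatch_frac merge mismatch tolerance, default 0.1.
#' @param min_len,max_ee rule (iii) thresholds, defaults 400 and 0.5.
#' @return list with `reads` (passing merged reads) and `report`, a
#'   `qc_report` whose rejection reasons partition the non-passing pairs.
#' @export
qc_pipeline <- function(fwd, rev, trunc_qual = 20L, min_overlap = 50L,
                        max_mismatch_frac = 0.1, min_len = 400L,
                        max_ee = 0.5) {
  if (length(fwd) != length(rev)) stop("fwd and rev must pair up 1:1")
  n_input <- length(fwd)
  merge_reasons <- c(too_short_to_merge = 0L, no_overlap = 0L)
  merged <- vector("list", n_input)
  k <- 0L
  for (i in seq_len(n_input)) {
    f <- trim_low_quality_ends(fwd[[i]], trunc_qual)
    r <- trim_low_quality_ends(rev[[i]], trunc_qual)
    m <- merge_pair(f, r, min_overlap = min_overlap,
                    max_mismatch_frac = max_mismatch_frac)
    if (is_merge_rejection(m)) {
      merge_reasons[[m$reason]] <- merge_reasons[[m$reason]] + 1L
    } else {
      k <- k + 1L
      merged[[k]] <- m
    }
  }
  merged <- merged[seq_len(k)]
  filt <- filter_reads(merged, min_len = min_len, max_ee = max_ee)
  report <- qc_report(n_input_pairs = n_input, n_merged = k,
                      n_passed = length(filt$reads),
                      reasons = c(merge_reasons, filt$reasons))
  list(reads = filt$reads, report = report)
}

#' Construct (and validate) a QC report
#'
#' @param n_input_pairs,n_merged,n_passed stage counts.
#' @param reasons named integer vector of rejection reasons.
#' @return A `qc_report`; construction fails unless
#'   `n_passed <= n_merged <= n_input_pairs` and the reasons sum to
#'   `n_input_pairs - n_passed`.
#' @export
qc_report <- function(n_input_pairs, n_merged, n_passed, reasons) {
  if (!(n_passed <= n_merged && n_merged <= n_input_pairs)) {
    stop("inconsistent QC counts: need n_passed <= n_merged <= n_input_pairs")
  }
  if (sum(reasons) != n_input_pairs - n_passed) {
    stop("rejection reasons must partition the non-passing pairs")
  }
  structure(list(n_input_pairs = as.integer(n_input_pairs),
                 n_merged = as.integer(n_merged),
                 n_passed = as.integer(n_passed),
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC report\n")
  cat(sprintf("  input pairs : %d\n", x$n_input_pairs))
  cat(sprintf("  merged      : %d\n", x$n_merged))
  cat(sprintf("  passed      : %d\n", x$n_passed))
  cat("  rejections  :\n")
  for (nm in names(x$reasons)) {
    cat(sprintf("    %-22s %d\n", nm, x$reasons[[nm]]))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param x a `qc_report`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
qc_report_json <- function(x, path = NULL) {
  obj <- list(n_input_pairs = x$n_input_pairs, n_merged = x$n_merged,
              n_passed = x$n_passed, reasons = as.list(x$reasons))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33, gzip-transparent) into seq_records
#'
#' @param path FASTQ(.gz) file.
#' @return list of [seq_record()]s.
#' @export
read_fastq <- function(path) {
  # conversions warn about (empty) mcols being dropped; nothing is lost
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    quals <- as(Biostrings::quality(x), "IntegerList")
    ids <- names(x)
    lapply(seq_along(x), function(i) {
      seq_record(ids[i], as.character(x[[i]]), as.integer(quals[[i]]))
    })
  })
}

#' Write seq_records as FASTQ (Phred+33)
#'
#' @param records list of [seq_record()]s.
#' @param path output file; a `.gz` suffix compresses.
#' @export
write_fastq <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "bases"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  qstr <- vapply(records, function(r) {
    intToUtf8(r$quals + 33L, multiple = FALSE)
  }, character(1))
  # constructor/writer warn about dropping (empty) mcols; nothing is lost
  suppressWarnings({
    qs <- Biostrings::QualityScaledDNAStringSet(
      seqs, Biostrings::PhredQuality(Biostrings::BStringSet(qstr)))
    Biostrings::writeQualityScaledXStringSet(
      qs, path, compress = grepl("\\.gz$", path))
  })
  invisible(path)
}
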