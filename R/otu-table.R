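# The sample x OTU count table is the hub object of the pipeline, together
# with greedy 97%-identity clustering and the standard table transforms
# (rarefaction, relative abundance, prevalence filter, log-normalization).

#' Construct a sample x OTU count table
#'
#' @param counts nonnegative integer matrix, samples as rows, OTUs as
#'   columns; dimnames required (sample ids, OTU ids).
#' @param sample_meta optional data.frame with one row per sample (matched
#'   by rowname order) carrying at least `subject`, `arm`, `timepoint` when
#'   available.
#' @param taxonomy optional character vector of per-OTU labels.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, sample_meta = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample rownames and OTU colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != nrow(counts)) {
      stop("sample_meta must have one row per sample")
    }
    rownames(sample_meta) <- rownames(counts)
  }
  if (!is.null(taxonomy) && length(taxonomy) != ncol(counts)) {
    stop("taxonomy must have one entry per OTU")
  }
  structure(list(counts = counts, sample_meta = sample_meta,
                 taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs, total reads %.0f\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  if (!is.null(x$sample_meta)) {
    cat("  metadata:", paste(colnames(x$sample_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Greedy centroid clustering of reads into OTUs
#'
#' Reads are dereplicated into unique sequences; uniques are processed in
#' decreasing abundance (ties broken lexicographically by sequence). Each
#' unique joins the first existing centroid whose global-alignment identity
#' (matches / alignment columns, terminal gaps included) is at least
#' `identity`, otherwise it founds a new centroid.
#'
#' @param seqs character vector of uppercase DNA sequences named by read id
#'   (duplicate sequences are dereplicated internally, abundance = read
#'   count), or a named abundance-annotated unique set via `abundances`.
#' @param identity clustering identity threshold in `(0, 1]` (default 0.97).
#' @param abundances optional per-sequence abundances when `seqs` is already
#'   dereplicated.
#' @return list of class `otu_assignment`: `assignment` data.frame
#'   (read_id, otu, identity) covering every input id, and `centroids`, a
#'   named character vector of representative sequences.
#' @export
cluster_otus <- function(seqs, identity = 0.97, abundances = NULL) {
  if (!length(seqs)) {
    return(structure(list(assignment = data.frame(read_id = character(0),
                                                  otu = character(0),
                                                  identity = numeric(0)),
                          centroids = character(0)),
                     class = "otu_assignment"))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  seqs <- toupper(seqs)
  if (is.null(abundances)) {
    uniq <- tapply(rep(1L, length(seqs)), seqs, sum)
  } else {
    uniq <- tapply(abundances, seqs, sum)
  }
  useq <- names(uniq)
  ord <- order(-as.numeric(uniq), useq)
  useq <- useq[ord]

  centroids <- character(0)
  u_otu <- character(length(useq))
  u_id <- numeric(length(useq))
  names(u_otu) <- names(u_id) <- useq
  for (s in useq) {
    hit <- NA_character_
    hit_id <- NA_real_
    for (j in seq_along(centroids)) {
      pid <- alignment_identity(s, centroids[[j]])
      if (pid >= identity) {
        hit <- names(centroids)[j]
        hit_id <- pid
        break
      }
    }
    if (is.na(hit)) {
      nm <- sprintf("OTU%d", length(centroids) + 1L)
      centroids[[nm]] <- s
      u_otu[[s]] <- nm
      u_id[[s]] <- 1
    } else {
      u_otu[[s]] <- hit
      u_id[[s]] <- hit_id
    }
  }
  assignment <- data.frame(read_id = names(seqs),
                           otu = unname(u_otu[seqs]),
                           identity = unname(u_id[seqs]),
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, centroids = unlist(centroids)),
            class = "otu_assignment")
}

# Global (Needleman-Wunsch) identity: matched columns / total alignment
# columns, gaps counted in the denominator.
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb) / length(pa)
}

#' Tabulate OTU assignments into a count table
#'
#' @param assign an `otu_assignment` from [cluster_otus()].
#' @param read_sample_map named character vector mapping read id to
#'   sample id; every assigned read must be present.
#' @return An [otu_table()] with `counts[s, o]` = reads of sample `s`
#'   assigned to OTU `o`. Samples with zero assigned reads are retained as
#'   zero rows when present in the map.
#' @export
build_table <- function(assign, read_sample_map) {
  a <- assign$assignment
  unknown <- setdiff(a$read_id, names(read_sample_map))
  if (length(unknown)) {
    stop("reads with no sample mapping: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  samples <- sort(unique(unname(read_sample_map)))
  otus <- names(assign$centroids)
  counts <- matrix(0L, length(samples), length(otus),
                   dimnames = list(samples, otus))
  if (nrow(a)) {
    tab <- table(factor(read_sample_map[a$read_id], levels = samples),
                 factor(a$otu, levels = otus))
    counts[] <- as.integer(tab)
  }
  otu_table(counts)
}

#' Rarefy a count table to even depth
#'
#' Each sample with total count at least `depth` is replaced by a uniform
#' without-replacement subsample of exactly `depth` reads; samples below
#' `depth` are dropped with a warning.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (default 5000).
#' @param seed RNG seed.
#' @return A rarefied [otu_table()]; errors if no sample reaches `depth`.
#' @export
rarefy <- function(table, depth = 5000L, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth ", depth)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(head(rownames(table$counts)[!keep], 5), collapse = ", "))
  }
  counts <- table$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(counts, 1, function(row) {
      pool <- rep.int(seq_along(row), row)
      picked <- sample(pool, depth, replace = FALSE)
      tabulate(picked, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(counts)
  otu_table(out,
            sample_meta = if (!is.null(table$sample_meta))
              table$sample_meta[keep, , drop = FALSE],
            taxonomy = table$taxonomy)
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] or a counts matrix.
#' @return Real matrix whose rows sum to 1; errors on an all-zero sample.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(head(rownames(counts)[totals == 0], 5), collapse = ", "))
  }
  sweep(counts, 1, totals, "/")
}

#' Restrict a table to core OTUs by prevalence
#'
#' Keeps an OTU iff the fraction of samples in which it is observed
#' (count > 0) is strictly greater than `min_prevalence`.
#'
#' @param table an [otu_table()].
#' @param min_prevalence strict prevalence threshold (default 0.20).
#' @return The [otu_table()] restricted to core OTUs.
#' @export
core_otus <- function(table, min_prevalence = 0.20) {
  prev <- colMeans(table$counts > 0)
  keep <- prev > min_prevalence
  otu_table(table$counts[, keep, drop = FALSE],
            sample_meta = table$sample_meta,
            taxonomy = table$taxonomy[keep])
}

#' Normalized, log10-transformed abundance matrix
#'
#' `log10(relative abundance + pseudocount)`; the ordination input.
#'
#' @param table an [otu_table()] or counts matrix.
#' @param pseudocount strictly positive offset (default 1e-6).
#' @return Real matrix, same shape as the table.
#' @export
normalize_log <- function(table, pseudocount = 1e-6) {
  stopifnot(pseudocount > 0)
  log10(relative_abundance(table) + pseudocount)
}

#' Write an OTU table as TSV
#'
#' Samples as rows; metadata columns are prefixed `#` and precede the OTU
#' id columns, so the file round-trips through [read_otu_table()].
#'
#' @param table an [otu_table()].
#' @param path output file.
#' @export
write_otu_table <- function(table, path) {
  df <- as.data.frame(table$counts, check.names = FALSE)
  if (!is.null(table$sample_meta)) {
    meta <- table$sample_meta
    colnames(meta) <- paste0("#", colnames(meta))
    df <- cbind(meta, df)
  }
  df <- cbind(sample = rownames(table$counts), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table written by [write_otu_table()]
#' @param path TSV file.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "")
  rownames(df) <- df$sample
  df$sample <- NULL
  meta_cols <- grepl("^#", colnames(df))
  meta <- if (any(meta_cols)) {
    m <- df[, meta_cols, drop = FALSE]
    colnames(m) <- sub("^#", "", colnames(m))
    m
  }
  counts <- as.matrix(df[, !meta_cols, drop = FALSE])
  otu_table(counts, sample_meta = meta)
}
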