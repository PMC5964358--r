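# Co-abundance groups (CAGs): Ward clustering of the SparCC correlation
# distance over core OTUs, with each candidate split validated by
# PERMANOVA; CAG abundance quantification; paired abundance tests; and
# Cytoscape-ready network export.

#' Correlation distance over OTUs
#'
#' `d_ij = 1 - rho_ij` (range `[0, 2]`, zero diagonal).
#'
#' @param rho symmetric correlation matrix (e.g. `sparcc()$rho`).
#' @return A [distance_matrix_obj()] over OTUs, metric `"correlation"`.
#' @export
correlation_distance <- function(rho) {
  rho <- as.matrix(rho)
  check_symmetric(rho, tol = 1e-8, what = "correlation matrix")
  m <- 1 - rho
  diag(m) <- 0
  distance_matrix_obj(m, "correlation")
}

#' Ward dendrogram over the OTU correlation distance
#'
#' Agglomerative Ward linkage (Lance-Williams `ward.D` update) on the given
#' dissimilarity. OTUs are sorted lexicographically first so the merge
#' order, and hence the downstream partition, is invariant to input order.
#'
#' @param dm a [distance_matrix_obj()] over OTUs.
#' @return An [stats::hclust] object.
#' @export
ward_tree <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 2) stop("need at least 2 OTUs")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hclust(as.dist(m), method = "ward.D")
}

# Leaf labels under each node of an hclust merge tree. Node indices:
# negative = leaf (original observation), positive = merge row.
hclust_members <- function(hc, node) {
  if (node < 0) return(hc$labels[-node])
  c(hclust_members(hc, hc$merge[node, 1]),
    hclust_members(hc, hc$merge[node, 2]))
}

#' Partition OTUs into CAGs by PERMANOVA-validated Ward splits
#'
#' Top-down traversal of the Ward dendrogram: at each node, PERMANOVA
#' (seeded, `n_perm` permutations) is run on the correlation distance
#' restricted to the node's OTUs, with the two child memberships as
#' labels. The split is accepted iff `p <= alpha` and both children hold
#' at least 2 OTUs (a node whose best split isolates a single OTU is kept
#' whole); accepted children are recursed into. The leaves of the
#' accepted-split tree are the CAGs.
#'
#' @param dendrogram an [stats::hclust] from [ward_tree()].
#' @param dm the [distance_matrix_obj()] the dendrogram was built from.
#' @param alpha significance level for accepting a split (default 0.001).
#' @param n_perm permutations per PERMANOVA (default 999).
#' @param seed RNG seed.
#' @return list of class `cag_partition`: `cag` (named integer vector,
#'   OTU -> CAG id), `n_cags`, `tests` (data.frame of every node tested:
#'   size, p-value, accepted), `dendrogram`.
#' @export
partition_by_permanova <- function(dendrogram, dm, alpha = 0.001,
                                   n_perm = 999L, seed = 1L) {
  m <- as.matrix(dm)
  labels <- dendrogram$labels
  if (!setequal(labels, rownames(m))) {
    stop("dendrogram and distance matrix cover different OTUs")
  }
  tests <- list()
  groups <- list()
  counter <- 0L

  recurse <- function(node, node_seed) {
    members <- hclust_members(dendrogram, node)
    if (node < 0) {
      groups[[length(groups) + 1L]] <<- members
      return(invisible(NULL))
    }
    left <- hclust_members(dendrogram, dendrogram$merge[node, 1])
    right <- hclust_members(dendrogram, dendrogram$merge[node, 2])
    if (length(left) < 2 || length(right) < 2) {
      # singleton-blocking rule: keep the node whole
      groups[[length(groups) + 1L]] <<- members
      return(invisible(NULL))
    }
    try_split(node, members, left, right, node_seed)
  }

  try_split <- function(node, members, left, right, node_seed) {
    sub <- m[members, members, drop = FALSE]
    lab <- ifelse(members %in% left, "L", "R")
    pv <- permanova(sub, lab, n_perm = n_perm, seed = node_seed)
    accepted <- pv$p.value <= alpha
    tests[[length(tests) + 1L]] <<-
      data.frame(node = node, size = length(members), p.value = pv$p.value,
                 accepted = accepted)
    if (accepted) {
      recurse(dendrogram$merge[node, 1], node_seed + 1013L)
      recurse(dendrogram$merge[node, 2], node_seed + 2027L)
    } else {
      groups[[length(groups) + 1L]] <<- members
    }
    invisible(NULL)
  }

  recurse(nrow(dendrogram$merge), as.integer(seed))

  # stable CAG numbering: by sorted first member label
  groups <- groups[order(vapply(groups, function(g) sort(g)[1], ""))]
  cag <- integer(0)
  for (i in seq_along(groups)) {
    cag[groups[[i]]] <- i
  }
  structure(list(cag = cag[sort(names(cag))],
                 n_cags = length(groups),
                 tests = if (length(tests)) do.call(rbind, tests)
                         else data.frame(node = integer(0)),
                 dendrogram = dendrogram),
            class = "cag_partition")
}

#' @export
print.cag_partition <- function(x, ...) {
  cat(sprintf("<cag_partition> %d OTUs in %d CAGs (sizes: %s)\n",
              length(x$cag), x$n_cags,
              paste(sort(table(x$cag), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Per-sample CAG abundances
#'
#' The abundance of a CAG in a sample is the sum of the relative
#' abundances of its member OTUs.
#'
#' @param rel_table samples x OTUs relative-abundance matrix (or an
#'   [otu_table()], converted internally); columns must cover every OTU of
#'   the partition.
#' @param partition a `cag_partition` (or named OTU -> CAG vector).
#' @return list of class `cag_abundance`: `abundance` (samples x CAGs
#'   matrix) and `members` (list of member OTU ids per CAG).
#' @export
cag_abundance <- function(rel_table, partition) {
  rel <- if (inherits(rel_table, "otu_table")) relative_abundance(rel_table)
         else as.matrix(rel_table)
  cag <- if (inherits(partition, "cag_partition")) partition$cag
         else partition
  missing <- setdiff(names(cag), colnames(rel))
  if (length(missing)) {
    stop("table is missing partition OTU(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  ids <- sort(unique(cag))
  ab <- vapply(ids, function(k) {
    rowSums(rel[, names(cag)[cag == k], drop = FALSE])
  }, numeric(nrow(rel)))
  ab <- matrix(ab, nrow = nrow(rel),
               dimnames = list(rownames(rel), paste0("CAG", ids)))
  members <- lapply(ids, function(k) names(cag)[cag == k])
  names(members) <- paste0("CAG", ids)
  structure(list(abundance = ab, members = members),
            class = "cag_abundance")
}

#' Paired within-arm CAG abundance change tests
#'
#' Two-sided Wilcoxon signed-rank test of week-12 versus week-0 CAG
#' abundance within one arm, one test per CAG. A CAG whose paired
#' differences are all zero (or fewer than 2 nonzero) yields `NA` with a
#' warning; if every CAG is degenerate the call errors.
#'
#' @param cag_table a `cag_abundance` (or samples x CAGs matrix) over the
#'   stacked two-timepoint samples.
#' @param sample_meta data.frame with `subject`, `arm`, `timepoint` rows
#'   matching the abundance rownames.
#' @param arm which arm to test.
#' @return data.frame: cag, n_pairs, median_delta, statistic, p.value,
#'   direction (increased/decreased at p < 0.05).
#' @export
compare_cag_paired <- function(cag_table, sample_meta, arm) {
  ab <- if (inherits(cag_table, "cag_abundance")) cag_table$abundance
        else as.matrix(cag_table)
  meta <- sample_meta[sample_meta$arm == arm, , drop = FALSE]
  subj <- unique(meta$subject)
  r0 <- rownames(meta)[meta$timepoint == "week0"]
  r12 <- rownames(meta)[meta$timepoint == "week12"]
  s0 <- setNames(r0, meta[r0, "subject"])
  s12 <- setNames(r12, meta[r12, "subject"])
  ok <- subj %in% names(s0) & subj %in% names(s12)
  if (any(!ok)) {
    warning("skipping unpaired subject(s): ",
            paste(head(subj[!ok], 5), collapse = ", "))
    subj <- subj[ok]
  }
  out <- data.frame(cag = colnames(ab), n_pairs = length(subj),
                    median_delta = NA_real_, statistic = NA_real_,
                    p.value = NA_real_, direction = NA_character_,
                    stringsAsFactors = FALSE)
  degenerate <- 0L
  for (k in seq_len(ncol(ab))) {
    d <- ab[s12[subj], k] - ab[s0[subj], k]
    out$median_delta[k] <- median(d)
    if (sum(d != 0) < 2) {
      degenerate <- degenerate + 1L
      next
    }
    ht <- suppressWarnings(
      wilcox.test(ab[s12[subj], k], ab[s0[subj], k], paired = TRUE))
    out$statistic[k] <- unname(ht$statistic)
    out$p.value[k] <- ht$p.value
    if (ht$p.value < 0.05) {
      out$direction[k] <- if (median(d) > 0) "increased" else "decreased"
    }
  }
  if (degenerate == ncol(ab)) {
    stop("all CAGs have degenerate (all-zero) paired differences")
  }
  if (degenerate > 0) {
    warning(degenerate, " CAG(s) with < 2 nonzero paired differences ",
            "returned NA")
  }
  out
}

#' Export the co-abundance network for Cytoscape
#'
#' Edges connect OTU pairs whose correlation exceeds `edge_threshold`
#' (positive correlations only by default; `mode = "absolute"` thresholds
#' `|rho|`). Nodes carry their CAG id (colour key) and mean relative
#' abundance (size key); CAGs none of whose members touch a qualifying
#' edge are flagged as excluded from display.
#'
#' @param rho OTU x OTU correlation matrix.
#' @param partition a `cag_partition` (or named OTU -> CAG vector).
#' @param mean_abundance named per-OTU mean relative abundance.
#' @param edge_threshold correlation threshold (default 0.4).
#' @param mode `"positive"` (rho > threshold) or `"absolute"`
#'   (|rho| > threshold).
#' @param dir optional output directory; when given, writes `nodes.tsv`,
#'   `edges.tsv` and `network.graphml`.
#' @return list: `nodes` (data.frame otu, cag, mean_abundance, displayed),
#'   `edges` (data.frame from, to, rho), `excluded_cags` (ids with no
#'   qualifying edge), and `graph` (an igraph object).
#' @export
export_network <- function(rho, partition, mean_abundance,
                           edge_threshold = 0.4,
                           mode = c("positive", "absolute"), dir = NULL) {
  mode <- match.arg(mode)
  rho <- as.matrix(rho)
  cag <- if (inherits(partition, "cag_partition")) partition$cag
         else partition
  otus <- rownames(rho)
  val <- if (mode == "absolute") abs(rho) else rho
  idx <- which(upper.tri(val) & val > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(from = otus[idx[, 1]], to = otus[idx[, 2]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  touched <- unique(c(edges$from, edges$to))
  nodes <- data.frame(otu = otus,
                      cag = unname(cag[otus]),
                      mean_abundance = unname(mean_abundance[otus]),
                      displayed = otus %in% touched,
                      stringsAsFactors = FALSE)
  disp_cags <- unique(nodes$cag[nodes$displayed])
  excluded <- setdiff(unique(nodes$cag), disp_cags)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    igraph::write_graph(g, file.path(dir, "network.graphml"),
                        format = "graphml")
  }
  list(nodes = nodes, edges = edges, excluded_cags = sort(excluded),
       graph = g)
}
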