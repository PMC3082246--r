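#' Build an activity-profile matrix of group-versus-rest t-values
#'
#' For each TF (condition) and each assay (feature), computes the pooled
#' two-sample t of the TF's labeled gene set against all other genes in the
#' signal matrix, plus the matching rank-sum p. This is the per-label activity
#' profile underlying the enrichment heat maps: rows are assays, columns are
#' TFs, one matrix per label.
#'
#' @param gene_signals a `gene_signal_matrix` from [map_probes_to_genes()].
#' @param targets list of [binding_target_set()] (already passed through
#'   [filter_tfs()]).
#' @param label `"functional"` or `"nonfunctional"`: which gene set forms the
#'   group.
#' @param strict_rest if TRUE the rest excludes the TF's other-labeled targets
#'   as well; default FALSE ("all other probes on the array").
#' @param welch use the Welch t instead of pooled-variance.
#' @param ranksum also compute rank-sum p-values (default TRUE).
#' @return an `activity_profile_matrix`: list with `tvalues`, `pvalues`,
#'   `ranksum_pvalues` (features x conditions), `region_tag`, `label`,
#'   `feature_class`.
#' @export
build_activity_matrix <- function(gene_signals, targets,
                                  label = c("functional", "nonfunctional"),
                                  strict_rest = FALSE, welch = FALSE,
                                  ranksum = TRUE) {
  label <- match.arg(label)
  v <- gene_signals$values
  feats <- colnames(v)
  tf_ids <- vapply(targets, `[[`, "", "tf_id")
  tv <- pv <- rv <- matrix(NA_real_, length(feats), length(tf_ids),
                           dimnames = list(feats, tf_ids))
  for (j in seq_along(targets)) {
    ts <- targets[[j]]
    grp_genes <- if (label == "functional") ts$functional_genes else ts$nonfunctional_genes
    grp <- rownames(v) %in% grp_genes
    rest <- !grp
    if (strict_rest) {
      other <- if (label == "functional") ts$nonfunctional_genes else ts$functional_genes
      rest <- rest & !(rownames(v) %in% other)
    }
    if (sum(grp) < 2L || sum(rest) < 2L) next
    for (f in seq_along(feats)) {
      res <- group_t_statistic(v[grp, f], v[rest, f], welch = welch)
      tv[f, j] <- res$t
      pv[f, j] <- res$p
      if (ranksum && !is.na(res$t)) {
        rv[f, j] <- ranksum_statistic(v[grp, f], v[rest, f])$p
      }
    }
  }
  structure(list(tvalues = tv, pvalues = pv,
                 ranksum_pvalues = if (ranksum) rv else NULL,
                 region_tag = gene_signals$region, label = label,
                 feature_class = gene_signals$assay_class[feats]),
            class = "activity_profile_matrix")
}

#' @export
print.activity_profile_matrix <- function(x, ...) {
  cat(sprintf("activity_profile_matrix: %d features x %d conditions [%s, %s]\n",
              nrow(x$tvalues), ncol(x$tvalues), x$region_tag, x$label))
  invisible(x)
}

#' Signed log10 p-value matrix for heat-map display
#'
#' @param activity an `activity_profile_matrix`.
#' @param which `"t"` (default) or `"ranksum"`: which p-values to transform.
#' @return matrix of -log10(p) signed by the direction of effect.
#' @export
log10_p_matrix <- function(activity, which = c("t", "ranksum")) {
  which <- match.arg(which)
  p <- if (which == "t") activity$pvalues else activity$ranksum_pvalues
  if (is.null(p)) stop_histofunc("requested p-value matrix not present")
  signed_log10_p(p, activity$tvalues)
}

#' Hierarchically cluster an activity matrix for heat-map export
#'
#' Average-linkage agglomerative clustering of both rows and columns using
#' 1 - Pearson correlation distance (optionally uncentered). Rows or columns
#' that are constant (zero variance) get distance 1 to everything, with a
#' warning. Rows/columns with missing values are handled with pairwise
#' complete correlations.
#'
#' @param activity an `activity_profile_matrix` or plain numeric matrix.
#' @param uncentered if TRUE use the uncentered correlation.
#' @return list of class `cluster_tree` with `row_tree` and `col_tree`
#'   ([stats::hclust] objects) plus the matrix clustered.
#' @export
hierarchical_cluster <- function(activity, uncentered = FALSE) {
  m <- if (inherits(activity, "activity_profile_matrix")) activity$tvalues else activity
  keep_r <- rowSums(!is.na(m)) >= 2
  keep_c <- colSums(!is.na(m)) >= 2
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_histofunc("need >= 2 features and >= 2 conditions with data")
  }
  # deterministic tie-breaking: sort by name where names exist
  if (!is.null(rownames(m))) m <- m[order(rownames(m)), , drop = FALSE]
  if (!is.null(colnames(m))) m <- m[, order(colnames(m)), drop = FALSE]
  row_tree <- stats::hclust(correlation_distance(m, uncentered), method = "average")
  col_tree <- stats::hclust(correlation_distance(t(m), uncentered), method = "average")
  structure(list(row_tree = row_tree, col_tree = col_tree, matrix = m),
            class = "cluster_tree")
}

correlation_distance <- function(m, uncentered = FALSE) {
  if (uncentered) {
    norm <- sqrt(rowSums(m^2, na.rm = TRUE))
    cc <- tcrossprod(m / pmax(norm, .Machine$double.eps))
  } else {
    cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  }
  if (anyNA(cc)) {
    warning("constant feature(s): correlation undefined, distance set to 1",
            call. = FALSE)
    cc[is.na(cc)] <- 0
  }
  stats::as.dist(1 - cc)
}

#' Export a clustered matrix in Cluster 3.0 format
#'
#' Writes `.cdt` (reordered data table) and `.gtr`/`.atr` (row/column tree)
#' files compatible with Java TreeView.
#'
#' @param tree a `cluster_tree` from [hierarchical_cluster()].
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
export_cdt <- function(tree, prefix) {
  m <- tree$matrix
  ro <- tree$row_tree$order
  co <- tree$col_tree$order
  gid <- sprintf("GENE%dX", seq_len(nrow(m)))
  aid <- sprintf("ARRY%dX", seq_len(ncol(m)))
  cdt <- file.path(paste0(prefix, ".cdt"))
  header <- c("GID\tUNIQID\tNAME\tGWEIGHT", colnames(m)[co])
  lines <- c(paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)[co]),
                   collapse = "\t"),
             paste(c("AID", "", "", "", aid[co]), collapse = "\t"),
             paste(c("EWEIGHT", "", "", "", rep("1", length(co))), collapse = "\t"))
  body <- vapply(ro, function(i) {
    paste(c(gid[i], rownames(m)[i], rownames(m)[i], "1",
            formatC(m[i, co], format = "g", digits = 6)), collapse = "\t")
  }, "")
  writeLines(c(lines, body), cdt)
  write_tree_file <- function(h, ids, path, prefix_chr) {
    n <- length(h$order)
    node <- sprintf("NODE%dX", seq_len(nrow(h$merge)))
    lab <- function(k) if (k < 0) ids[-k] else node[k]
    rows <- vapply(seq_len(nrow(h$merge)), function(i) {
      paste(c(node[i], lab(h$merge[i, 1L]), lab(h$merge[i, 2L]),
              formatC(1 - h$height[i], format = "g", digits = 6)),
            collapse = "\t")
    }, "")
    writeLines(rows, path)
  }
  gtr <- paste0(prefix, ".gtr"); atr <- paste0(prefix, ".atr")
  write_tree_file(tree$row_tree, gid, gtr)
  write_tree_file(tree$col_tree, aid, atr)
  invisible(c(cdt, gtr, atr))
}

#' Write an activity matrix to TSV
#'
#' @param activity an `activity_profile_matrix`.
#' @param path output path.
#' @param what `"t"`, `"p"`, or `"ranksum"`.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(activity, path, what = c("t", "p", "ranksum")) {
  what <- match.arg(what)
  m <- switch(what, t = activity$tvalues, p = activity$pvalues,
              ranksum = activity$ranksum_pvalues)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
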