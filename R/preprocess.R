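#' Normalize modification channels by local nucleosome occupancy
#'
#' Measured modification levels in a region are confounded by how often that
#' region is occupied by a nucleosome. For each probe the mean of the H3 and
#' H4 occupancy channels is computed, and every modification-class channel is
#' divided by that mean. Occupancy, HAT and binding channels pass through
#' unchanged. Probes whose mean occupancy is within `eps` of zero get missing
#' modification values (division would be meaningless there).
#'
#' @param signals a raw-scale [probe_signal_matrix()].
#' @param h3_assay,h4_assay assay ids of the two occupancy channels.
#' @param eps guard threshold on |denominator| (default 1e-8).
#' @param unlog_before_normalize if TRUE, values are treated as log2 ratios:
#'   channels are exponentiated before division and re-logged after.
#' @return the matrix with `scale_tag = "nucleosome_normalized"`.
#' @export
normalize_by_nucleosome <- function(signals, h3_assay, h4_assay, eps = 1e-8,
                                    unlog_before_normalize = FALSE) {
  stopifnot(inherits(signals, "probe_signal_matrix"))
  if (signals$scale_tag != "raw") {
    stop_histofunc("nucleosome normalization requires raw-scale input, got ",
                   signals$scale_tag)
  }
  assays <- colnames(signals$values)
  if (!all(c(h3_assay, h4_assay) %in% assays)) {
    stop_histofunc("occupancy assays not found: ",
                   paste(setdiff(c(h3_assay, h4_assay), assays), collapse = ", "))
  }
  v <- signals$values
  h3 <- v[, h3_assay]
  h4 <- v[, h4_assay]
  if (unlog_before_normalize) {
    h3 <- 2^h3
    h4 <- 2^h4
  }
  denom <- (h3 + h4) / 2
  bad <- !is.na(denom) & abs(denom) < eps
  mod_cols <- which(signals$assay_class == "modification")
  for (j in mod_cols) {
    if (unlog_before_normalize) {
      v[, j] <- log2(2^v[, j] / denom)
    } else {
      v[, j] <- v[, j] / denom
    }
    v[bad | is.na(denom), j] <- NA_real_
  }
  if (any(bad)) {
    warning(sum(bad), " probe(s) with near-zero mean occupancy; ",
            "modification values set missing", call. = FALSE)
  }
  out <- signals
  out$values <- v
  out$scale_tag <- "nucleosome_normalized"
  out
}

#' Z-score every assay column
#'
#' Per assay, subtracts the mean and divides by the sample (n-1) standard
#' deviation over non-missing probes. A constant column becomes all zeros
#' (with a warning) rather than NaN.
#'
#' @param signals a [probe_signal_matrix()] on any scale except `zscore`.
#' @return the matrix with `scale_tag = "zscore"`.
#' @export
zscore_signals <- function(signals) {
  stopifnot(inherits(signals, "probe_signal_matrix"))
  if (signals$scale_tag == "zscore") {
    stop_histofunc("signals are already Z-scored")
  }
  v <- signals$values
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  if (any(const)) {
    warning("constant column(s) set to zero: ",
            paste(colnames(v)[const], collapse = ", "), call. = FALSE)
    sdv[const] <- 1
  }
  v <- sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
  out <- signals
  out$values <- v
  out$scale_tag <- "zscore"
  out
}

#' Aggregate probe-level signals to gene level
#'
#' One row per gene with at least one probe in the requested region; the gene
#' value per assay is the mean over that gene's probes, ignoring missing
#' cells. A gene's cell is missing only if all its probes are missing for that
#' assay.
#'
#' @param signals a [probe_signal_matrix()].
#' @param annotation a [probe_annotation()] data.frame.
#' @param region `"ORF"` or `"promoter"`.
#' @return a `gene_signal_matrix`: list with `values` (genes x assays),
#'   `region`, `n_probes_per_gene`, `assay_class`, `scale_tag`.
#' @export
map_probes_to_genes <- function(signals, annotation, region = c("ORF", "promoter")) {
  region <- match.arg(region)
  stopifnot(inherits(signals, "probe_signal_matrix"))
  ann <- annotation[annotation$region == region &
                      annotation$probe_id %in% rownames(signals$values), ,
                    drop = FALSE]
  if (nrow(ann) == 0L) stop_histofunc("no probes map to region ", region)
  v <- signals$values[ann$probe_id, , drop = FALSE]
  gene <- factor(ann$gene_id, levels = unique(ann$gene_id))
  agg <- rowsum(ifelse(is.na(v), 0, v), gene, na.rm = FALSE)
  cnt <- rowsum((!is.na(v)) * 1, gene)
  out <- agg / cnt
  out[cnt == 0] <- NA_real_
  structure(list(values = out,
                 region = region,
                 n_probes_per_gene = stats::setNames(as.integer(table(gene)),
                                                     levels(gene)),
                 assay_class = signals$assay_class,
                 scale_tag = signals$scale_tag,
                 dataset_id = signals$dataset_id),
            class = "gene_signal_matrix")
}

#' @export
print.gene_signal_matrix <- function(x, ...) {
  cat(sprintf("gene_signal_matrix: %d genes x %d assays [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$region, x$scale_tag))
  invisible(x)
}

#' Filter TFs by data overlap and target count
#'
#' Drops TFs whose targets intersect the available genes in fewer than
#' `min_overlap` elements, or whose total target count (after restriction to
#' the available genes) is below `min_targets`. Remaining target sets are
#' restricted to `genes_available`.
#'
#' @param targets list of [binding_target_set()].
#' @param genes_available character vector of genes present in the signal
#'   matrix.
#' @param min_overlap minimum overlap with the modification data (default 5).
#' @param min_targets minimum total binding targets (default 20).
#' @return filtered list of restricted target sets.
#' @export
filter_tfs <- function(targets, genes_available, min_overlap = 5,
                       min_targets = 20) {
  stopifnot(min_overlap >= 0, min_targets >= 0)
  kept <- lapply(targets, function(ts) {
    fun <- intersect(ts$functional_genes, genes_available)
    non <- intersect(ts$nonfunctional_genes, genes_available)
    n_overlap <- length(fun) + length(non)
    n_total <- length(ts$functional_genes) + length(ts$nonfunctional_genes)
    if (n_overlap < min_overlap || n_total < min_targets) return(NULL)
    binding_target_set(ts$tf_id, fun, non, ts$universe)
  })
  Filter(Negate(is.null), kept)
}
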