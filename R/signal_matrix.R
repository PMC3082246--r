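#' Probe-level signal matrix
#'
#' The raw substrate of all preprocessing: a probes x assays matrix of
#' ChIP-chip style measurements (log-ratio or Z-score scale) together with an
#' assay-class tag per column and a scale tag tracking which transformations
#' have been applied. Assay classes distinguish histone-modification channels
#' (which are nucleosome-normalized) from occupancy (H3/H4), HAT occupancy and
#' TF-binding channels (which pass through normalization unchanged).
#'
#' @param values numeric matrix, probes x assays. `NA` marks missing cells.
#' @param probe_ids character vector of unique probe identifiers (rownames
#'   used if missing).
#' @param assay_ids character vector of unique assay identifiers (colnames
#'   used if missing).
#' @param assay_class character vector, one of `"modification"`,
#'   `"occupancy"`, `"HAT"`, `"binding"` per assay.
#' @param scale_tag one of `"raw"`, `"nucleosome_normalized"`, `"zscore"`.
#' @param dataset_id optional tag keeping separately analyzed datasets apart.
#' @return an object of class `probe_signal_matrix`.
#' @export
probe_signal_matrix <- function(values, probe_ids = rownames(values),
                                assay_ids = colnames(values),
                                assay_class,
                                scale_tag = c("raw", "nucleosome_normalized", "zscore"),
                                dataset_id = "default") {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(assay_ids)) {
    stop_histofunc("probe_ids and assay_ids are required")
  }
  if (length(probe_ids) != nrow(values) || length(assay_ids) != ncol(values)) {
    stop_histofunc("id lists do not match matrix dimensions")
  }
  if (anyDuplicated(probe_ids)) {
    stop_histofunc("duplicate probe ids: ",
                   paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(assay_ids)) stop_histofunc("duplicate assay ids")
  assay_class <- match_assay_class(assay_class, assay_ids)
  dimnames(values) <- list(probe_ids, assay_ids)
  structure(list(values = values, assay_class = assay_class,
                 scale_tag = scale_tag, dataset_id = dataset_id),
            class = "probe_signal_matrix")
}

match_assay_class <- function(assay_class, assay_ids) {
  valid <- c("modification", "occupancy", "HAT", "binding")
  if (length(assay_class) == 1L) assay_class <- rep(assay_class, length(assay_ids))
  if (!is.null(names(assay_class))) assay_class <- assay_class[assay_ids]
  if (length(assay_class) != length(assay_ids) || anyNA(assay_class) ||
      !all(assay_class %in% valid)) {
    stop_histofunc("assay_class must map every assay to one of ",
                   paste(valid, collapse = "/"))
  }
  stats::setNames(as.character(assay_class), assay_ids)
}

#' @export
print.probe_signal_matrix <- function(x, ...) {
  cat(sprintf("probe_signal_matrix: %d probes x %d assays [%s] dataset=%s\n",
              nrow(x$values), ncol(x$values), x$scale_tag, x$dataset_id))
  cat("assay classes:", paste(sprintf("%s=%s", names(x$assay_class), x$assay_class),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.probe_signal_matrix <- function(x) dim(x$values)

#' Read a probe-level signal table
#'
#' Expects a TSV with a header row of assay ids and a first column of probe
#' ids. Missing values use a configurable NA token and stay missing (never
#' imputed to zero).
#'
#' @param path path to the TSV file.
#' @param assay_class_map named character vector mapping assay id to class
#'   (`modification`/`occupancy`/`HAT`/`binding`), or a single class for all.
#' @param na_token string encoding missing cells (default `"NA"`).
#' @param dataset_id dataset tag, see [probe_signal_matrix()].
#' @return a [probe_signal_matrix()].
#' @export
read_signal_table <- function(path, assay_class_map, na_token = "NA",
                              dataset_id = "default") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = na_token, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_histofunc("malformed header: need probe_id plus >=1 assay")
  probe_ids <- tab[[1L]]
  if (anyDuplicated(probe_ids)) {
    stop_histofunc("duplicate probe ids: ",
                   paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(values <- matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(probe_ids, colnames(raw))))
  bad <- !is.na(raw) & is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_histofunc(sprintf("non-numeric cell at probe '%s', assay '%s': '%s'",
                           probe_ids[idx[1L]], colnames(raw)[idx[2L]],
                           raw[idx[1L], idx[2L]]))
  }
  probe_signal_matrix(values, probe_ids, colnames(raw), assay_class_map,
                      scale_tag = "raw", dataset_id = dataset_id)
}

#' Write a signal matrix to TSV
#'
#' @param signals a [probe_signal_matrix()].
#' @param path output path.
#' @param na_token token used for missing values.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path, na_token = "NA") {
  df <- data.frame(probe_id = rownames(signals$values), signals$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na_token)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Columns: probe_id, chrom, start, end, region (ORF|promoter), gene_id.
#' Coordinates are 0-based half-open throughout.
#'
#' @param path TSV path.
#' @return a `data.frame` of class `probe_annotation`.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  probe_annotation(ann)
}

#' Construct/validate a probe annotation
#'
#' @param ann data.frame with columns probe_id, chrom, start, end, region,
#'   gene_id.
#' @return validated `probe_annotation` data.frame.
#' @export
probe_annotation <- function(ann) {
  need <- c("probe_id", "chrom", "start", "end", "region", "gene_id")
  if (!all(need %in% names(ann))) {
    stop_histofunc("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$probe_id)) stop_histofunc("duplicate probe ids in annotation")
  if (!all(ann$region %in% c("ORF", "promoter"))) {
    stop_histofunc("region must be ORF or promoter")
  }
  if (any(ann$start >= ann$end)) stop_histofunc("start must be < end (0-based half-open)")
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read per-TF target lists
#'
#' TSV with columns tf_id, gene_id, label (functional|nonfunctional). Returns
#' one binding-target set per TF.
#'
#' @param path TSV path.
#' @param universe character vector of all genes on the array.
#' @return named list of [binding_target_set()] objects.
#' @export
read_target_table <- function(path, universe) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("tf_id", "gene_id", "label")
  if (!all(need %in% names(tab))) {
    stop_histofunc("target table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$label %in% c("functional", "nonfunctional"))) {
    stop_histofunc("label must be functional or nonfunctional")
  }
  lapply(split(tab, tab$tf_id), function(d) {
    binding_target_set(d$tf_id[1L],
                       functional_genes = d$gene_id[d$label == "functional"],
                       nonfunctional_genes = d$gene_id[d$label == "nonfunctional"],
                       universe = universe)
  })
}

#' Per-TF partition of bound genes
#'
#' Functional targets are genes the TF binds and regulates ("bind and
#' couple"); non-functional targets are bound but not regulated ("bind not
#' couple").
#'
#' @param tf_id TF identifier.
#' @param functional_genes,nonfunctional_genes disjoint gene sets.
#' @param universe all genes on the array; both sets must be subsets.
#' @return object of class `binding_target_set`.
#' @export
binding_target_set <- function(tf_id, functional_genes, nonfunctional_genes,
                               universe) {
  functional_genes <- unique(as.character(functional_genes))
  nonfunctional_genes <- unique(as.character(nonfunctional_genes))
  if (length(intersect(functional_genes, nonfunctional_genes)) > 0L) {
    stop_histofunc("functional and nonfunctional sets overlap for ", tf_id)
  }
  if (!all(c(functional_genes, nonfunctional_genes) %in% universe)) {
    stop_histofunc("target genes outside universe for ", tf_id)
  }
  structure(list(tf_id = tf_id, functional_genes = functional_genes,
                 nonfunctional_genes = nonfunctional_genes,
                 universe = as.character(universe)),
            class = "binding_target_set")
}

#' Write target sets to TSV
#'
#' @param targets list of [binding_target_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(targets, path) {
  rows <- do.call(rbind, lapply(targets, function(ts) {
    rbind(
      if (length(ts$functional_genes))
        data.frame(tf_id = ts$tf_id, gene_id = ts$functional_genes,
                   label = "functional"),
      if (length(ts$nonfunctional_genes))
        data.frame(tf_id = ts$tf_id, gene_id = ts$nonfunctional_genes,
                   label = "nonfunctional")
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
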