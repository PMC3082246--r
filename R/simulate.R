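#' Configuration for the synthetic study generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes for yeast ChIP-chip data: per-probe Gaussian log-ratio noise,
#' positive nucleosome-occupancy channels coupled into normalization,
#' TF-specific perturbation of a subset of histone-lysine channels at
#' functional targets, flat (one shared constant offset across all channels)
#' modification profiles at non-functional targets, and multiple probes per
#' gene/promoter region.
#'
#' @param n_genes number of genes.
#' @param n_tfs number of transcription factors.
#' @param n_modifications number of histone-modification channels.
#' @param probes_per_region probes per gene per region (>= 1).
#' @param targets_per_tf binding targets drawn per TF.
#' @param frac_functional fraction of each TF's targets that are functional.
#' @param effect_size standardized mean shift (Z units) applied to perturbed
#'   channels at functional targets and to promoter binding at all targets.
#' @param noise_sd SD of i.i.d. Gaussian probe noise.
#' @param flat_offset_sd SD of the per-gene baseline level shared by all
#'   modification channels (every gene sits characteristically high or low in
#'   overall modification). At non-functional targets this baseline is the
#'   only structure, producing their flat high-or-low profiles.
#' @param n_programs number of regulatory programs. Real histone marks move
#'   in co-regulated groups (e.g. active-promoter acetylation marks) and real
#'   TFs co-bind in communities; each program ties one group of modification
#'   channels to one community of TFs. Within a program, a TF's functional
#'   targets carry the program's modification signature (with the TF's
#'   direction) and are co-bound by the program's other TFs.
#' @param frac_activators probability that a program perturbs its channels
#'   upward (activator-like community); the rest deplete them
#'   (repressor-like). The direction is shared by a program's TFs: a
#'   co-regulating community acts on its marks in one direction.
#' @param cobind_strength relative strength of cofactor (same-program)
#'   binding at functional targets, as a fraction of the primary TF's
#'   binding shift. Set to 0 to disable co-binding.
#' @param tf_strength_range range of the per-TF multiplier applied to both
#'   binding and modification effects; TFs differ in regulatory strength, and
#'   this heterogeneity is what couples binding enrichment to modification
#'   change across TFs.
#' @param occupancy_sd SD of the log-occupancy channels (exponentiated to the
#'   positive ratio scale).
#' @param seed integer random seed; identical config + seed gives
#'   byte-identical output.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_tfs = 32, n_modifications = 8,
                             probes_per_region = 2, targets_per_tf = 60,
                             frac_functional = 0.5, effect_size = 1.5,
                             noise_sd = 1, flat_offset_sd = 1.5,
                             n_programs = 3L, frac_activators = 0.8,
                             cobind_strength = 0.6,
                             tf_strength_range = c(0.5, 1.5),
                             occupancy_sd = 0.25, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_modifications = as.integer(n_modifications),
              probes_per_region = as.integer(probes_per_region),
              targets_per_tf = as.integer(targets_per_tf),
              frac_functional = frac_functional, effect_size = effect_size,
              noise_sd = noise_sd, flat_offset_sd = flat_offset_sd,
              n_programs = as.integer(n_programs),
              frac_activators = frac_activators,
              cobind_strength = cobind_strength,
              tf_strength_range = as.numeric(tf_strength_range),
              occupancy_sd = occupancy_sd, seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_tfs, cfg$n_modifications,
              cfg$probes_per_region, cfg$targets_per_tf)
  if (any(counts <= 0L)) stop_histofunc("all counts must be positive")
  if (cfg$frac_functional < 0 || cfg$frac_functional > 1) {
    stop_histofunc("frac_functional must be in [0,1]")
  }
  if (cfg$noise_sd <= 0) stop_histofunc("noise_sd must be > 0")
  if (cfg$n_programs < 1L || cfg$n_programs > cfg$n_modifications ||
      cfg$n_programs > cfg$n_tfs) {
    stop_histofunc("n_programs must be in [1, min(n_modifications, n_tfs)]")
  }
  if (cfg$frac_activators < 0 || cfg$frac_activators > 1) {
    stop_histofunc("frac_activators must be in [0,1]")
  }
  if (cfg$targets_per_tf > cfg$n_genes) {
    stop_histofunc("targets_per_tf exceeds n_genes")
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate a probe annotation
#'
#' Genes are laid end to end on one synthetic chromosome; each gene gets
#' `probes_per_region` probes in its 1 kb body (ORF) and the same number in
#' the 500 bp promoter upstream of the TSS. Coordinates are 0-based half-open.
#'
#' @param config a [synthetic_config()].
#' @return a [probe_annotation()] data.frame.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gene_len <- 1000L
  prom_len <- 500L
  pitch <- gene_len + prom_len + 100L
  p <- config$probes_per_region
  rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%04d", g)
    tss <- (g - 1L) * pitch + prom_len
    orf_starts <- tss + (seq_len(p) - 1L) * (gene_len %/% p)
    prom_starts <- (tss - prom_len) + (seq_len(p) - 1L) * (prom_len %/% p)
    rows[[g]] <- data.frame(
      probe_id = c(sprintf("%s_orf_p%d", gene_id, seq_len(p)),
                   sprintf("%s_prom_p%d", gene_id, seq_len(p))),
      chrom = "chrS",
      start = c(orf_starts, prom_starts),
      end = c(orf_starts + (gene_len %/% p), prom_starts + (prom_len %/% p)),
      region = rep(c("ORF", "promoter"), each = p),
      gene_id = gene_id,
      stringsAsFactors = FALSE)
  }
  probe_annotation(do.call(rbind, rows))
}

#' Simulate a binding study with functional/non-functional labels
#'
#' For each TF a random subset of genes becomes its targets; a fraction
#' `frac_functional` are labeled functional ("bind and couple"), the rest
#' non-functional ("bind not couple"). Both classes are bound, so promoter
#' probes of all targets receive a positive binding shift of
#' `effect_size * strength(tf)` on that TF's binding channel, on top of
#' standard-normal log-ratio noise. Functional targets are additionally
#' co-bound by the TF's same-program cofactor TFs at `cobind_strength` of the
#' primary shift: coupled (regulating) binding happens inside a co-regulating
#' community, while non-functional binding does not recruit it.
#'
#' @param annotation a [probe_annotation()] from [simulate_annotation()].
#' @param config the same [synthetic_config()].
#' @return list with `targets` (list of [binding_target_set()]), `binding`
#'   (a [probe_signal_matrix()] of TF binding channels), and `truth`
#'   (ground-truth record, see Details).
#' @details The `truth` element records, per TF, the functional and
#'   non-functional gene sets, the signature vector over modification
#'   channels (drawn here so histone simulation can reuse it), and the per-TF
#'   strength multiplier.
#' @export
simulate_binding_study <- function(annotation, config) {
  stopifnot(inherits(config, "synthetic_config"), nrow(annotation) > 0L)
  genes <- unique(annotation$gene_id)
  n_fun <- round(config$targets_per_tf * config$frac_functional)
  n_non <- config$targets_per_tf - n_fun
  if ((config$frac_functional > 0 && config$frac_functional < 1) &&
      (n_fun < 2L || n_non < 2L)) {
    stop_histofunc("each TF needs >= 2 targets per represented class")
  }
  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  with_seed(derive_seed(config$seed, "binding"), {
    strengths <- stats::runif(config$n_tfs, config$tf_strength_range[1L],
                              config$tf_strength_range[2L])
    names(strengths) <- tf_ids
    # programs tie a group of modification channels to a community of TFs
    programs <- rep_len(seq_len(config$n_programs), config$n_tfs)
    names(programs) <- tf_ids
    channel_program <- rep_len(seq_len(config$n_programs), config$n_modifications)
    # direction of mark perturbation is a property of the co-regulating
    # community: activator-like programs raise their marks, repressor-like
    # programs deplete them
    program_dir <- ifelse(stats::runif(config$n_programs) < config$frac_activators,
                          1, -1)
    directions <- program_dir[programs]
    names(directions) <- tf_ids
    signatures <- lapply(tf_ids, function(tf) {
      as.numeric(channel_program == programs[[tf]]) * directions[[tf]]
    })
    names(signatures) <- tf_ids
    targets <- lapply(tf_ids, function(tf) {
      tg <- sample(genes, config$targets_per_tf)
      binding_target_set(tf, functional_genes = tg[seq_len(n_fun)],
                         nonfunctional_genes = if (n_non > 0L) tg[n_fun + seq_len(n_non)] else character(),
                         universe = genes)
    })
    names(targets) <- tf_ids
    values <- matrix(stats::rnorm(nrow(annotation) * config$n_tfs,
                                  sd = config$noise_sd),
                     nrow = nrow(annotation),
                     dimnames = list(annotation$probe_id, tf_ids))
    prom <- annotation$region == "promoter"
    for (tf in tf_ids) {
      bound <- annotation$gene_id %in% c(targets[[tf]]$functional_genes,
                                         targets[[tf]]$nonfunctional_genes)
      values[prom & bound, tf] <- values[prom & bound, tf] +
        config$effect_size * strengths[[tf]]
      if (config$cobind_strength > 0) {
        cofactors <- setdiff(tf_ids[programs == programs[[tf]]], tf)
        fun_bound <- prom & annotation$gene_id %in% targets[[tf]]$functional_genes
        for (cf in cofactors) {
          values[fun_bound, cf] <- values[fun_bound, cf] +
            config$cobind_strength * config$effect_size * strengths[[tf]]
        }
      }
    }
  })
  truth <- structure(list(
    functional = lapply(targets, `[[`, "functional_genes"),
    nonfunctional = lapply(targets, `[[`, "nonfunctional_genes"),
    signatures = signatures, strengths = strengths,
    programs = programs, directions = directions,
    occupancy_baseline = NULL), class = "synthetic_truth")
  binding <- probe_signal_matrix(values, annotation$probe_id, tf_ids,
                                 assay_class = "binding", scale_tag = "raw")
  list(targets = targets, binding = binding, truth = truth)
}

#' Simulate histone-modification, occupancy and HAT channels
#'
#' ORF probes of each TF's functional targets receive that TF's signature
#' (`effect_size * strength * sign` on each perturbed channel). Every gene
#' additionally carries one flat baseline (SD `flat_offset_sd`) shared by all
#' modification channels, so non-functional targets — which receive no
#' signature — show flat profiles that may sit high or low. All probes carry
#' i.i.d. Gaussian noise. Two occupancy channels (H3, H4) are generated
#' strictly positive on the ratio scale so nucleosome normalization is
#' exercised, and two HAT-occupancy channels (ESA1-, GCN5-like) each track the
#' modification-channel group of one program.
#'
#' @param annotation a [probe_annotation()].
#' @param truth the ground-truth record from [simulate_binding_study()].
#' @param config the same [synthetic_config()].
#' @return a raw-scale [probe_signal_matrix()] with modification, occupancy
#'   and HAT channels; the occupancy baseline per probe is appended to
#'   `truth` by reference semantics only in the returned attribute
#'   `occupancy_baseline`.
#' @export
simulate_histone_signals <- function(annotation, truth, config) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  if (!all(unlist(truth$functional) %in% annotation$gene_id)) {
    stop_histofunc("truth references genes absent from annotation")
  }
  n_probe <- nrow(annotation)
  nm <- config$n_modifications
  mod_ids <- sprintf("mod%02d", seq_len(nm))
  hat_ids <- c("HAT_esa1", "HAT_gcn5")
  occ_ids <- c("H3", "H4")
  with_seed(derive_seed(config$seed, "histone"), {
    mods <- matrix(stats::rnorm(n_probe * nm, sd = config$noise_sd),
                   nrow = n_probe, dimnames = list(annotation$probe_id, mod_ids))
    orf <- annotation$region == "ORF"
    genes <- annotation$gene_id
    for (tf in names(truth$functional)) {
      shift <- truth$signatures[[tf]] * config$effect_size * truth$strengths[[tf]]
      idx <- orf & genes %in% truth$functional[[tf]]
      mods[idx, ] <- sweep(mods[idx, , drop = FALSE], 2L, shift, "+")
    }
    # every gene carries one flat baseline level shared by all modification
    # channels (genes sit at characteristically high or low overall
    # acetylation); at non-functional targets this baseline is the only
    # structure, giving the flat high-or-low profiles
    gene_ids <- unique(genes)
    offsets <- stats::rnorm(length(gene_ids), sd = config$flat_offset_sd)
    names(offsets) <- gene_ids
    idx_orf <- which(orf)
    mods[idx_orf, ] <- mods[idx_orf, ] + offsets[genes[idx_orf]]
    # positive occupancy channels on the ratio scale
    occ_base <- exp(stats::rnorm(n_probe, mean = 0, sd = config$occupancy_sd))
    occ <- cbind(H3 = occ_base * exp(stats::rnorm(n_probe, sd = 0.05)),
                 H4 = occ_base * exp(stats::rnorm(n_probe, sd = 0.05)))
    # each HAT writes a specific set of marks, so its occupancy tracks the
    # channel group of one program (Esa1- and Gcn5-like specificity)
    channel_program <- rep_len(seq_len(config$n_programs), nm)
    hat <- vapply(seq_along(hat_ids), function(k) {
      prog <- ((k - 1L) %% config$n_programs) + 1L
      grp <- mods[, channel_program == prog, drop = FALSE]
      0.8 * rowMeans(grp) + stats::rnorm(n_probe, sd = config$noise_sd * 0.6)
    }, numeric(n_probe))
    colnames(hat) <- hat_ids
  })
  values <- cbind(mods, occ, hat)
  cls <- c(rep("modification", nm), rep("occupancy", 2L), rep("HAT", 2L))
  out <- probe_signal_matrix(values, annotation$probe_id,
                             c(mod_ids, occ_ids, hat_ids),
                             assay_class = stats::setNames(cls, c(mod_ids, occ_ids, hat_ids)),
                             scale_tag = "raw")
  attr(out, "occupancy_baseline") <- stats::setNames(occ_base, annotation$probe_id)
  out
}

#' Run the full generator and optionally write study files
#'
#' Convenience wrapper calling [simulate_annotation()],
#' [simulate_binding_study()] and [simulate_histone_signals()] under one
#' config, optionally writing the TSV/JSON files the preprocessing stage
#' reads.
#'
#' @param config a [synthetic_config()].
#' @param outdir if non-NULL, a directory to write annotation.tsv,
#'   binding.tsv, histone.tsv, targets.tsv and truth.json into.
#' @return list with `annotation`, `targets`, `binding`, `histone`, `truth`.
#' @export
simulate_study <- function(config, outdir = NULL) {
  ann <- simulate_annotation(config)
  bs <- simulate_binding_study(ann, config)
  hist <- simulate_histone_signals(ann, bs$truth, config)
  out <- list(annotation = ann, targets = bs$targets, binding = bs$binding,
              histone = hist, truth = bs$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ann, file.path(outdir, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_signal_table(bs$binding, file.path(outdir, "binding.tsv"))
    write_signal_table(hist, file.path(outdir, "histone.tsv"))
    write_target_table(bs$targets, file.path(outdir, "targets.tsv"))
    jsonlite::write_json(
      list(functional = bs$truth$functional,
           nonfunctional = bs$truth$nonfunctional,
           signatures = bs$truth$signatures,
           strengths = as.list(bs$truth$strengths)),
      file.path(outdir, "truth.json"), auto_unbox = FALSE, digits = NA)
  }
  out
}
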