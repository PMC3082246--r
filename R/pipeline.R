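#' Default pipeline configuration
#'
#' Returns the full run configuration with the analysis defaults: TF
#' filtering at a minimum of 5 overlapping targets and 20 total binding
#' targets, cluster count K automatic (or fixed), network significance level
#' p < 0.003, a 2-hidden-unit classifier evaluated over 10 random half-splits.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param synthetic named list of [synthetic_config()] overrides.
#' @return a `run_config` list.
#' @export
default_run_config <- function(outdir = "histofunc_run", seed = 1L,
                               synthetic = list()) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    synthetic = synthetic,
    preprocess = list(h3 = "H3", h4 = "H4", unlog_before_normalize = FALSE),
    filter = list(min_overlap = 5, min_targets = 20),
    enrich = list(strict_rest = FALSE, welch = FALSE),
    network = list(K = "auto", p_threshold = 0.003, epochs = 60),
    classify = list(n_hidden = 2, n_splits = 10, cv10 = FALSE,
                    include_occupancy = TRUE, include_hat = TRUE)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the sections of [default_run_config()];
#'   missing entries take the defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the five stages in dependency order — simulate, preprocess,
#' enrich, network, classify — writing each stage's outputs and a manifest
#' (inputs, parameters, seed, md5 checksums) under the configured output
#' directory. Re-running with an identical configuration is a no-op unless
#' `force = TRUE`.
#'
#' @param config a `run_config` (see [default_run_config()]) or path to a
#'   YAML file.
#' @param force re-run even when an identical-config manifest exists.
#' @return the run manifest (list), invisibly writes `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(), force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(outdir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(as.character(old$config_json), as.character(cfg_json))) {
      message("identical configuration already run; use force = TRUE to re-run")
      return(invisible(old))
    }
  }
  manifest <- list(config_json = as.character(cfg_json), stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, parameters = params, seed = config$seed,
      outputs = as.list(tools::md5sum(files)))
  }

  # stage 1: simulate
  scfg <- do.call(synthetic_config, c(config$synthetic,
                                      list(seed = derive_seed(config$seed, "sim"))))
  sim <- simulate_study(scfg, outdir = file.path(outdir, "simulated"))
  note("simulate", scfg[setdiff(names(scfg), "")],
       list.files(file.path(outdir, "simulated"), full.names = TRUE))

  # stage 2: preprocess
  hist_norm <- normalize_by_nucleosome(
    sim$histone, config$preprocess$h3, config$preprocess$h4,
    unlog_before_normalize = isTRUE(config$preprocess$unlog_before_normalize))
  hist_z <- zscore_signals(hist_norm)
  bind_z <- zscore_signals(sim$binding)
  orf <- map_probes_to_genes(hist_z, sim$annotation, "ORF")
  prom_bind <- map_probes_to_genes(bind_z, sim$annotation, "promoter")
  targets <- filter_tfs(sim$targets, rownames(orf$values),
                        config$filter$min_overlap, config$filter$min_targets)
  if (length(targets) == 0L) stop_histofunc("stage preprocess: no TFs survive filtering")
  pre_dir <- file.path(outdir, "preprocessed")
  dir.create(pre_dir, showWarnings = FALSE)
  orf_path <- file.path(pre_dir, "orf_gene_signals.tsv")
  utils::write.table(data.frame(gene_id = rownames(orf$values), orf$values),
                     orf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  note("preprocess", config$preprocess, orf_path)

  # stage 3: enrich (both labels, both statistics)
  enr_dir <- file.path(outdir, "enrichment")
  dir.create(enr_dir, showWarnings = FALSE)
  activity <- list()
  enr_files <- character()
  for (lab in c("functional", "nonfunctional")) {
    mod_act <- build_activity_matrix(orf, targets, lab,
                                     strict_rest = isTRUE(config$enrich$strict_rest),
                                     welch = isTRUE(config$enrich$welch))
    bind_act <- build_activity_matrix(prom_bind, targets, lab,
                                      strict_rest = isTRUE(config$enrich$strict_rest),
                                      welch = isTRUE(config$enrich$welch))
    activity[[lab]] <- list(modification = mod_act, binding = bind_act)
    f1 <- file.path(enr_dir, paste0("tvalues_mod_", lab, ".tsv"))
    write_activity_table(mod_act, f1)
    tree <- hierarchical_cluster(mod_act)
    cdt <- export_cdt(tree, file.path(enr_dir, paste0("heatmap_", lab)))
    enr_files <- c(enr_files, f1, cdt)
  }
  note("enrich", config$enrich, enr_files)

  # stage 4: network per label
  net_dir <- file.path(outdir, "network")
  dir.create(net_dir, showWarnings = FALSE)
  networks <- list()
  net_files <- character()
  for (lab in c("functional", "nonfunctional")) {
    comb <- combine_profiles(activity[[lab]]$binding,
                             activity[[lab]]$modification, lab)
    K <- config$network$K
    if (identical(K, "auto")) {
      K <- estimate_k_by_stress(comb, seed = derive_seed(config$seed, paste0("k", lab)),
                                epochs = config$network$epochs)$K
    }
    model <- neural_gas_fit(comb, as.integer(K),
                            seed = derive_seed(config$seed, paste0("ng", lab)),
                            epochs = config$network$epochs)
    gg <- ggm_fit(model$centers, seed = derive_seed(config$seed, paste0("ggm", lab)))
    net <- build_network(model, gg$pcor, gg$pvalues,
                         threshold = config$network$p_threshold,
                         origin = comb$origin)
    networks[[lab]] <- net
    net_files <- c(net_files, export_network(net, file.path(net_dir, lab)))
  }
  note("network", config$network, net_files)

  # stage 5: classify per TF
  cls_dir <- file.path(outdir, "classify")
  dir.create(cls_dir, showWarnings = FALSE)
  arch_hidden <- config$classify$n_hidden
  reports <- lapply(targets, function(ts) {
    data <- tryCatch(build_feature_table(orf, ts,
                                         include_occupancy = isTRUE(config$classify$include_occupancy),
                                         include_hat = isTRUE(config$classify$include_hat)),
                     error = function(e) NULL)
    if (is.null(data)) return(NULL)
    rep <- evaluate_random_splits(data, bnn_architecture(ncol(data$X), arch_hidden),
                                  n_splits = config$classify$n_splits,
                                  seed = derive_seed(config$seed, paste0("cls", ts$tf_id)))
    out <- list(tf = ts$tf_id,
                n_functional = sum(data$t == 1L),
                n_nonfunctional = sum(data$t == 0L),
                mpcc = rep$mpcc,
                mean_total_correct = rep$mean_total_correct,
                confusion = as.list(rep$mean_confusion),
                per_split = rep$per_split)
    if (isTRUE(config$classify$cv10)) {
      cv <- crossvalidate_10fold(data, bnn_architecture(ncol(data$X), arch_hidden),
                                 seed = derive_seed(config$seed, paste0("cv", ts$tf_id)))
      out$cv_mpcc <- cv$mpcc
    }
    out
  })
  reports <- Filter(Negate(is.null), reports)
  cls_path <- file.path(cls_dir, "classification.json")
  jsonlite::write_json(reports, cls_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  note("classify", config$classify, cls_path)

  manifest$networks <- lapply(networks, function(n)
    list(edges = nrow(n$edges), clusters = nrow(n$nodes)))
  manifest$mpcc <- as.list(stats::setNames(vapply(reports, `[[`, 0, "mpcc"),
                                           vapply(reports, `[[`, "", "tf")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a plain-text summary of a pipeline run
#'
#' Writes a ranked MPCC table, the network edge counts per label, and
#' pointers to the heat-map and network files recorded in the manifest.
#'
#' @param manifest a manifest list from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @param path output file (default `summary.txt` beside the manifest).
#' @return the summary lines, invisibly.
#' @export
report_run <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    if (is.null(path)) path <- file.path(dirname(manifest), "summary.txt")
    manifest <- jsonlite::read_json(manifest)
  }
  lines <- c("histofunc pipeline summary", "==========================", "")
  if (!is.null(manifest$mpcc) && length(manifest$mpcc)) {
    mp <- unlist(manifest$mpcc)
    ord <- order(-mp)
    lines <- c(lines, "Classifier MPCC by TF (ranked):",
               sprintf("  %2d. %-8s MPCC = %5.1f", seq_along(ord),
                       names(mp)[ord], mp[ord]), "")
  }
  if (!is.null(manifest$networks)) {
    lines <- c(lines, "Networks:",
               vapply(names(manifest$networks), function(lab)
                 sprintf("  %-14s %s clusters, %s edges", lab,
                         manifest$networks[[lab]]$clusters,
                         manifest$networks[[lab]]$edges), ""), "")
  }
  lines <- c(lines, "Stage outputs:")
  for (st in manifest$stages) {
    lines <- c(lines, sprintf("  [%s]", st$stage),
               sprintf("    %s", names(st$outputs)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
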