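# small study configurations and hand-built objects shared across tests

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 120, n_tfs = 4, n_modifications = 6,
                   probes_per_region = 2, targets_per_tf = 24,
                   frac_functional = 0.5, effect_size = 1.5, noise_sd = 1,
                   flat_offset_sd = 1.5, n_programs = 2, seed = 42)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# a probe signal matrix with known values for preprocessing oracles
toy_signals <- function(n_probes = 12, n_mods = 3, seed = 7) {
  withr::with_seed(seed, {
    mods <- matrix(rnorm(n_probes * n_mods), n_probes)
    occ <- matrix(exp(rnorm(n_probes * 2, sd = 0.3)), n_probes)
  })
  values <- cbind(mods, occ)
  ids <- sprintf("p%02d", seq_len(n_probes))
  assays <- c(sprintf("ac%d", seq_len(n_mods)), "H3", "H4")
  probe_signal_matrix(values, ids, assays,
                      assay_class = c(rep("modification", n_mods),
                                      "occupancy", "occupancy"))
}

# hand-built target sets over a simple gene universe
toy_targets <- function(universe = sprintf("g%02d", 1:30)) {
  list(
    A = binding_target_set("A", universe[1:6], universe[7:12], universe),
    B = binding_target_set("B", universe[1:3], universe[4:5], universe)
  )
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
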