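test_that("synthetic_config validates its inputs", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_genes = 0), "positive")
  expect_error(synthetic_config(frac_functional = 1.2), "frac_functional")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_programs = 9, n_modifications = 8), "n_programs")
  expect_error(synthetic_config(targets_per_tf = 700, n_genes = 600), "exceeds")
})

test_that("annotation lays out ORF and promoter probes per gene", {
  cfg <- tiny_config(n_genes = 25, probes_per_region = 3)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 25 * 2 * 3)
  expect_false(any(duplicated(ann$probe_id)))
  expect_true(all(ann$start < ann$end))
  expect_setequal(unique(ann$region), c("ORF", "promoter"))
  per_gene <- table(ann$gene_id, ann$region)
  expect_true(all(per_gene == 3))
  # promoter probes lie upstream of the gene's ORF probes
  for (g in unique(ann$gene_id)[1:5]) {
    sub <- ann[ann$gene_id == g, ]
    expect_lt(max(sub$end[sub$region == "promoter"]),
              min(sub$start[sub$region == "ORF"]) + 1)
  }
})

test_that("the generator is deterministic in config + seed", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(tiny_config(seed = 7))
  expect_identical(a$histone$values, b$histone$values)
  expect_identical(a$binding$values, b$binding$values)
  expect_identical(lapply(a$targets, unclass), lapply(b$targets, unclass))
  c <- simulate_study(tiny_config(seed = 8))
  expect_false(identical(a$histone$values, c$histone$values))
})

test_that("target sets have the configured sizes and are disjoint", {
  cfg <- tiny_config(n_genes = 120, targets_per_tf = 40, frac_functional = 0.5)
  sim <- simulate_study(cfg)
  for (ts in sim$targets) {
    expect_length(ts$functional_genes, 20)
    expect_length(ts$nonfunctional_genes, 20)
    expect_length(intersect(ts$functional_genes, ts$nonfunctional_genes), 0)
    expect_true(all(c(ts$functional_genes, ts$nonfunctional_genes) %in%
                      sim$annotation$gene_id))
  }
})

test_that("promoter binding is elevated at targets by the configured effect", {
  cfg <- tiny_config(n_genes = 300, targets_per_tf = 80, effect_size = 2,
                     cobind_strength = 0, seed = 5)
  sim <- simulate_study(cfg)
  ann <- sim$annotation
  prom <- ann$region == "promoter"
  for (tf in names(sim$targets)[1:4]) {
    tg <- c(sim$targets[[tf]]$functional_genes,
            sim$targets[[tf]]$nonfunctional_genes)
    on <- sim$binding$values[prom & ann$gene_id %in% tg, tf]
    off <- sim$binding$values[prom & !(ann$gene_id %in% tg), tf]
    est <- mean(on) - mean(off)
    want <- cfg$effect_size * sim$truth$strengths[[tf]]
    expect_equal(est, want, tolerance = 0.35)  # mean of ~160 noisy probes
    # ORF probes carry no binding shift
    orf_on <- sim$binding$values[!prom & ann$gene_id %in% tg, tf]
    expect_lt(abs(mean(orf_on)), 0.35)
  }
})

test_that("cofactor co-binding appears only at functional targets", {
  cfg <- tiny_config(n_genes = 300, targets_per_tf = 80, effect_size = 2,
                     cobind_strength = 0.6, n_programs = 2, seed = 9)
  sim <- simulate_study(cfg)
  ann <- sim$annotation
  prom <- ann$region == "promoter"
  programs <- sim$truth$programs
  tf <- names(programs)[1]
  cof <- setdiff(names(programs)[programs == programs[[tf]]], tf)[1]
  other <- names(programs)[programs != programs[[tf]]][1]
  fun <- sim$targets[[tf]]$functional_genes
  non <- sim$targets[[tf]]$nonfunctional_genes
  # exclude genes the cofactor itself binds, to isolate the co-binding shift
  own <- function(x) c(sim$targets[[x]]$functional_genes,
                       sim$targets[[x]]$nonfunctional_genes)
  fun_c <- setdiff(fun, own(cof)); non_c <- setdiff(non, own(cof))
  m_fun <- mean(sim$binding$values[prom & ann$gene_id %in% fun_c, cof])
  m_non <- mean(sim$binding$values[prom & ann$gene_id %in% non_c, cof])
  expect_gt(m_fun - m_non, 0.3)    # cofactor bound at functional targets only
  fun_o <- setdiff(fun, own(other)); non_o <- setdiff(non, own(other))
  m_fun_o <- mean(sim$binding$values[prom & ann$gene_id %in% fun_o, other])
  expect_lt(abs(m_fun_o), 0.4)     # out-of-program TF sees no shift
})

test_that("histone signatures shift perturbed channels at functional ORFs", {
  cfg <- tiny_config(n_genes = 300, targets_per_tf = 80, effect_size = 2, seed = 3)
  sim <- simulate_study(cfg)
  ann <- sim$annotation
  orf <- ann$region == "ORF"
  mods <- sprintf("mod%02d", seq_len(cfg$n_modifications))
  tf <- names(sim$targets)[1]
  sig <- sim$truth$signatures[[tf]]
  fun <- sim$targets[[tf]]$functional_genes
  # restrict to genes only this TF targets functionally, to avoid overlap
  others <- unique(c(unlist(sim$truth$functional[names(sim$targets) != tf]),
                     unlist(sim$truth$nonfunctional)))
  clean <- setdiff(fun, others)
  shift <- colMeans(sim$histone$values[orf & ann$gene_id %in% clean, mods])
  want <- sig * cfg$effect_size * sim$truth$strengths[[tf]]
  expect_equal(unname(shift), want, tolerance = 0.5)
})

test_that("every gene carries one flat baseline across modification channels", {
  cfg <- tiny_config(n_genes = 300, targets_per_tf = 80, flat_offset_sd = 1.5,
                     seed = 21)
  sim <- simulate_study(cfg)
  ann <- sim$annotation
  orf <- ann$region == "ORF"
  mods <- sprintf("mod%02d", seq_len(cfg$n_modifications))
  nonfun <- setdiff(unique(unlist(sim$truth$nonfunctional)),
                    unique(unlist(sim$truth$functional)))
  gm <- rowsum(sim$histone$values[orf & ann$gene_id %in% nonfun, mods],
               ann$gene_id[orf & ann$gene_id %in% nonfun]) / cfg$probes_per_region
  # the shared baseline makes every pair of channels positively correlated
  cc <- cor(gm)
  expect_gt(min(cc[upper.tri(cc)]), 0.2)
  # untargeted genes carry the same baseline coupling (it is a gene property)
  free <- setdiff(ann$gene_id, unique(unlist(c(sim$truth$functional,
                                               sim$truth$nonfunctional))))
  gm0 <- rowsum(sim$histone$values[orf & ann$gene_id %in% free, mods],
                ann$gene_id[orf & ann$gene_id %in% free]) / cfg$probes_per_region
  cc0 <- cor(gm0)
  expect_gt(min(cc0[upper.tri(cc0)]), 0.2)
  # centering each gene at its channel mean removes the coupling
  res <- gm0 - rowMeans(gm0)
  expect_lt(mean(abs(cor(res)[upper.tri(cc0)])), 0.35)
})

test_that("occupancy channels are positive and mutually consistent", {
  sim <- simulate_study(tiny_config(seed = 2))
  occ <- sim$histone$values[, c("H3", "H4")]
  expect_true(all(occ > 0))
  expect_gt(cor(occ[, 1], occ[, 2]), 0.8)
  expect_identical(unname(sim$histone$assay_class[c("H3", "H4")]),
                   c("occupancy", "occupancy"))
  expect_identical(unname(sim$histone$assay_class[c("HAT_esa1", "HAT_gcn5")]),
                   c("HAT", "HAT"))
})

test_that("simulate_study writes files that round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 4)
  sim <- simulate_study(cfg, outdir = dir)
  expect_setequal(list.files(dir), c("annotation.tsv", "binding.tsv",
                                     "histone.tsv", "targets.tsv", "truth.json"))
  ann <- read_annotation_table(file.path(dir, "annotation.tsv"))
  expect_equal(nrow(ann), nrow(sim$annotation))
  hz <- read_signal_table(file.path(dir, "histone.tsv"),
                          assay_class_map = sim$histone$assay_class)
  expect_equal(hz$values, sim$histone$values, tolerance = 1e-12)
  tg <- read_target_table(file.path(dir, "targets.tsv"), universe = ann$gene_id)
  expect_setequal(names(tg), names(sim$targets))
  expect_setequal(tg$TF01$functional_genes, sim$targets$TF01$functional_genes)
})
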