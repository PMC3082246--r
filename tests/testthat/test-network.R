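# small helpers for clustering tests
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
  rownames(x) <- sprintf("pt%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# agreement of two partitions up to relabeling (exact match required)
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

make_activity <- function(m, label = "functional", class = "binding") {
  structure(list(tvalues = m, pvalues = m * 0 + 0.5,
                 label = label,
                 feature_class = stats::setNames(rep(class, nrow(m)),
                                                 rownames(m))),
            class = "activity_profile_matrix")
}

test_that("combine_profiles stacks features and tracks their origin", {
  b <- matrix(1:6, 2, dimnames = list(c("TFa", "TFb"), c("c1", "c2", "c3")))
  m <- matrix(7:12, 2, dimnames = list(c("mod1", "mod2"), c("c1", "c2", "c3")))
  comb <- combine_profiles(make_activity(b), make_activity(m, class = "modification"),
                           "functional")
  expect_equal(dim(comb$values), c(4L, 3L))
  expect_equal(unname(comb$origin),
               c("binding", "binding", "modification", "modification"))
  expect_equal(comb$tvalues, rbind(b, m))
  # standardized rows are centered with unit norm (1 - Pearson geometry)
  expect_equal(unname(rowMeans(comb$values)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(comb$values^2)), rep(1, 4), tolerance = 1e-12)
  raw <- combine_profiles(make_activity(b), make_activity(m, class = "modification"),
                          "functional", standardize = FALSE)
  expect_equal(raw$values, rbind(b, m))
  bad <- make_activity(m[, c(2, 1, 3)], class = "modification")
  colnames(bad$tvalues) <- c("cX", "c1", "c3")
  expect_error(combine_profiles(make_activity(b), bad, "functional"),
               "condition ids")
  expect_error(combine_profiles(make_activity(b),
                                make_activity(m, label = "nonfunctional",
                                              class = "modification"),
                                "functional"), "label")
})

test_that("neural gas recovers well-separated blobs exactly", {
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8))
  blobs <- make_blobs(12, centers, sd = 0.4, seed = 31)
  fit <- neural_gas_fit(blobs$x, K = 3, seed = 5)
  expect_true(same_partition(fit$assignments, blobs$labels))
  # codebook vectors sit near the true centers
  got <- fit$centers[order(fit$centers[, 1] + fit$centers[, 2]), ]
  want <- centers[order(centers[, 1] + centers[, 2]), ]
  expect_lt(max(abs(got - want)), 0.5)
  # deterministic under the same seed
  fit2 <- neural_gas_fit(blobs$x, K = 3, seed = 5)
  expect_identical(fit$centers, fit2$centers)
})

test_that("stress elbow finds the true number of distinct profiles", {
  protos <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 0, 5, 5))
  blobs <- make_blobs(10, protos, sd = 0.2, seed = 17)
  est <- estimate_k_by_stress(blobs$x, k_range = 2:8, seed = 11)
  expect_equal(est$K, 3L)
  expect_named(est$stress_by_k, as.character(2:8))
  # stress drops steeply up to K = 3, then flattens
  expect_gt(est$stress_by_k["2"] - est$stress_by_k["3"],
            10 * (est$stress_by_k["3"] - est$stress_by_k["4"]))
  expect_equal(estimate_k_by_stress(blobs$x, override = 18)$K, 18L)
})

test_that("knn assignment places held-out points with their blob", {
  centers <- rbind(c(0, 0), c(6, 6))
  blobs <- make_blobs(15, centers, sd = 0.4, seed = 13)
  fit <- neural_gas_fit(blobs$x, K = 2, seed = 3)
  new_pts <- rbind(a = c(0.2, -0.1), b = c(5.8, 6.3), c = c(6.2, 5.7))
  got <- knn_assign(fit, new_pts, k_neighbors = 3)
  expect_equal(unname(got["a"] == got["b"]), FALSE)
  expect_equal(got[["b"]], got[["c"]])
  expect_equal(got[["a"]], unname(fit$assignments[1]))  # blob-1 cluster
  expect_error(knn_assign(fit, new_pts, k_neighbors = 100), "k_neighbors")
})

test_that("partial correlations invert a known precision structure", {
  # chain X1 - X2 - X3: direct links only along the chain
  omega <- matrix(c(2, -0.8, 0,
                    -0.8, 2, -0.8,
                    0, -0.8, 2), 3, byrow = TRUE)
  sigma <- solve(omega)
  pc <- partial_correlation(sigma)
  expect_equal(diag(pc), rep(1, 3))
  expect_equal(pc[1, 2], 0.8 / 2, tolerance = 1e-12)
  expect_equal(pc[1, 3], 0, tolerance = 1e-12)     # no direct 1-3 link
  expect_equal(pc, t(pc))
})

test_that("shrinkage intensity behaves at the sample-size extremes", {
  withr::with_seed(41, {
    f <- rnorm(2000)                       # strong common factor, many samples
    x_cor <- matrix(rep(f, 5), 5, byrow = TRUE) + matrix(rnorm(5 * 2000), 5) / 2
    x_tiny <- matrix(rnorm(12 * 6), 12)    # independent, K > n
  })
  s_cor <- shrink_covariance(x_cor)
  s_tiny <- shrink_covariance(x_tiny)
  # strong true correlations, well estimated: little shrinkage needed
  expect_lt(s_cor$lambda, 0.05)
  # independent variables: estimated correlations are pure noise, shrink hard
  expect_gt(s_tiny$lambda, 0.5)
  expect_true(s_tiny$lambda <= 1 && s_tiny$lambda >= 0)
  # diagonal (variances) is never shrunk
  expect_equal(diag(s_cor$cov), apply(x_cor, 1, var), tolerance = 1e-12)
  # shrunken covariance is invertible even when K > n
  expect_silent(solve(s_tiny$cov))
})

test_that("the GGM separates direct from mediated dependence", {
  # X1 -> X2 -> X3 chain sampled with plenty of conditions
  n <- 200
  withr::with_seed(47, {
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + rnorm(n, sd = 0.5)
    x3 <- 0.9 * x2 + rnorm(n, sd = 0.5)
    x4 <- rnorm(n)
  })
  centers <- rbind(v1 = x1, v2 = x2, v3 = x3, v4 = x4)
  gg <- ggm_fit(centers)
  expect_equal(gg$method, "fisher_z")
  expect_equal(gg$df, n - 2 - 3)
  # marginal correlation 1-3 is strong, but the partial correlation vanishes
  expect_gt(abs(cor(x1, x3)), 0.5)
  expect_lt(abs(gg$pcor["v1", "v3"]), 0.2)
  expect_lt(gg$pvalues["v1", "v2"], 0.003)
  expect_lt(gg$pvalues["v2", "v3"], 0.003)
  expect_gt(gg$pvalues["v1", "v4"], 0.003)
})

test_that("the permutation fallback engages when degrees of freedom run out", {
  withr::with_seed(53, centers <- matrix(rnorm(10 * 6), 10,
                                         dimnames = list(letters[1:10], NULL)))
  gg <- ggm_fit(centers, n_perm = 200, seed = 2)
  expect_equal(gg$method, "permutation")
  expect_true(all(gg$pvalues >= 1 / 201 & gg$pvalues <= 1))
  # permutation p-values are reproducible under the same seed
  gg2 <- ggm_fit(centers, n_perm = 200, seed = 2)
  expect_identical(gg$pvalues, gg2$pvalues)
})

test_that("build_network thresholds edges and labels nodes", {
  centers <- rbind(c(0, 0), c(6, 6))
  blobs <- make_blobs(6, centers, sd = 0.3, seed = 59)
  fit <- neural_gas_fit(blobs$x, K = 2, seed = 3)
  pcor <- matrix(c(1, 0.9, 0.9, 1), 2)
  pv <- matrix(c(1, 0.001, 0.001, 1), 2)
  origin <- stats::setNames(rep(c("binding", "modification"), each = 6),
                            rownames(blobs$x))
  net <- build_network(fit, pcor, pv, threshold = 0.003, origin = origin)
  expect_s3_class(net, "ggm_network")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$pcor, 0.9)
  expect_equal(sort(net$nodes$origin), c("binding", "modification"))
  expect_equal(net$edges$link, "binding--modification")
  expect_true(all(net$nodes$representative %in% rownames(blobs$x)))
  # sub-threshold p leaves no edges
  net0 <- build_network(fit, pcor, pv, threshold = 1e-4, origin = origin)
  expect_equal(nrow(net0$edges), 0L)
})

test_that("network export writes graphml, sif and membership files", {
  centers <- rbind(c(0, 0), c(6, 6))
  blobs <- make_blobs(5, centers, sd = 0.3, seed = 61)
  fit <- neural_gas_fit(blobs$x, K = 2, seed = 3)
  net <- build_network(fit, matrix(c(1, .8, .8, 1), 2),
                       matrix(c(1, .001, .001, 1), 2))
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- export_network(net, prefix)
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(files[1], format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_match(readLines(files[2]), "1 pcor 2")
})
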