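#' Combine binding and modification activity profiles
#'
#' Row-stacks the promoter-binding activity profile (one t-value row per TF
#' binding channel) with the ORF-modification activity profile (one row per
#' histone-modification channel) over a shared set of analyzed-TF conditions.
#' This is the feature space the protein clusters and the partial-correlation
#' network are built on: in the study design this pipeline targets, 203 TF
#' binding features plus 8 modification features across 32 analyzed TFs.
#'
#' @param binding_activity activity matrix computed on the promoter region.
#' @param modification_activity activity matrix computed on the ORF region.
#' @param label which label both inputs carry (checked).
#' @param standardize if TRUE (default), each feature row is centered and
#'   scaled to unit norm, so the Euclidean distance the vector quantization
#'   uses becomes monotone in 1 - Pearson correlation — the same geometry as
#'   the heat-map clustering. Profiles then group by shape rather than by
#'   magnitude, which keeps strong and weak members of one co-binding group in
#'   one cluster. Raw t-values are kept in `tvalues`.
#' @return a `combined_profile`: list with `values` (features x conditions,
#'   standardized when requested), `tvalues` (raw), `origin`
#'   ("binding"/"modification" per feature), `label`.
#' @export
combine_profiles <- function(binding_activity, modification_activity,
                             label = c("functional", "nonfunctional"),
                             standardize = TRUE) {
  label <- match.arg(label)
  if (!identical(colnames(binding_activity$tvalues),
                 colnames(modification_activity$tvalues))) {
    stop_histofunc("condition ids differ between binding and modification profiles")
  }
  if (binding_activity$label != label || modification_activity$label != label) {
    stop_histofunc("activity matrices carry a different label than requested")
  }
  b <- binding_activity$tvalues
  m <- modification_activity$tvalues
  if (any(rownames(b) %in% rownames(m))) stop_histofunc("duplicate feature ids")
  tvalues <- rbind(b, m)
  values <- tvalues
  if (standardize) {
    ctr <- values - rowMeans(values)
    nrm <- sqrt(rowSums(ctr^2))
    flat <- nrm <= .Machine$double.eps
    if (any(flat)) {
      warning(sum(flat), " constant feature profile(s) left at zero", call. = FALSE)
      nrm[flat] <- 1
    }
    values <- ctr / nrm
  }
  origin <- c(as.character(binding_activity$feature_class %||%
                             rep("binding", nrow(b))),
              as.character(modification_activity$feature_class %||%
                             rep("modification", nrow(m))))
  structure(list(values = values, tvalues = tvalues,
                 origin = stats::setNames(origin, rownames(values)),
                 label = label),
            class = "combined_profile")
}

#' Fit a neural-gas codebook to feature profiles
#'
#' Competitive-learning vector quantization: each presented feature vector
#' updates every codebook vector with weight exp(-rank/lambda), where rank
#' orders codebooks by distance to the presented vector. Learning rate and
#' neighborhood range lambda decay exponentially from their initial to final
#' values over the training schedule. Final assignments are by nearest
#' codebook; an empty cluster is re-seeded at the point farthest from its
#' assigned codebook.
#'
#' @param profile a `combined_profile` or plain numeric matrix (rows are the
#'   items to cluster). Rows with any missing value are dropped with a warning.
#' @param K number of codebook vectors (>= 2, <= rows).
#' @param seed RNG seed for initialization and presentation order.
#' @param epochs passes over the data (default 60).
#' @param lr initial and final learning rate (default c(0.5, 0.01)).
#' @param lambda initial and final neighborhood range; default c(K/2, 0.01).
#' @param restarts independent fits from different initializations; the
#'   codebook with the lowest quantization error is kept (vector quantization
#'   is non-convex, so single fits can land in poor local optima).
#' @return a `cluster_model`: list with `K`, `assignments`, `centers`,
#'   `quantization_error`, `seed`.
#' @export
neural_gas_fit <- function(profile, K, seed = 1L, epochs = 60L,
                           lr = c(0.5, 0.01), lambda = NULL, restarts = 3L) {
  x <- profile_matrix(profile)
  fits <- lapply(seq_len(restarts), function(r) {
    neural_gas_fit_once(x, K, seed = derive_seed(seed, paste0("restart", r)),
                        epochs = epochs, lr = lr, lambda = lambda)
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "quantization_error"))]]
  best$seed <- seed
  best
}

neural_gas_fit_once <- function(x, K, seed, epochs = 60L,
                                lr = c(0.5, 0.01), lambda = NULL) {
  if (K < 2L || K > nrow(x)) stop_histofunc("K must be in [2, number of features]")
  if (is.null(lambda)) lambda <- c(max(K / 2, 1), 0.01)
  n <- nrow(x)
  t_max <- epochs * n
  with_seed(seed, {
    centers <- x[sample.int(n, K), , drop = FALSE]
    step <- 0L
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        frac <- step / max(t_max - 1L, 1L)
        eps_t <- lr[1L] * (lr[2L] / lr[1L])^frac
        lam_t <- lambda[1L] * (lambda[2L] / lambda[1L])^frac
        d2 <- rowSums((centers - matrix(x[i, ], K, ncol(x), byrow = TRUE))^2)
        rk <- rank(d2, ties.method = "first") - 1L
        h <- eps_t * exp(-rk / lam_t)
        centers <- centers + h * (matrix(x[i, ], K, ncol(x), byrow = TRUE) - centers)
        step <- step + 1L
      }
    }
  })
  assign <- nearest_center(x, centers)
  # re-seed empty codebooks at the farthest point from its current codebook
  for (k in seq_len(K)) {
    if (!any(assign == k)) {
      warning("empty cluster ", k, " re-seeded at farthest point", call. = FALSE)
      d2 <- rowSums((x - centers[assign, , drop = FALSE])^2)
      far <- which.max(d2)
      centers[k, ] <- x[far, ]
      assign <- nearest_center(x, centers)
    }
  }
  rownames(centers) <- sprintf("cluster%02d", seq_len(K))
  qe <- sum(rowSums((x - centers[assign, , drop = FALSE])^2))
  structure(list(K = K,
                 assignments = stats::setNames(assign, rownames(x)),
                 centers = centers, quantization_error = qe,
                 data = x, seed = seed),
            class = "cluster_model")
}

profile_matrix <- function(profile) {
  x <- if (inherits(profile, "combined_profile")) profile$values else as.matrix(profile)
  drop <- rowSums(is.na(x)) > 0
  if (any(drop)) {
    warning(sum(drop), " feature(s) with missing values dropped before clustering",
            call. = FALSE)
    x <- x[!drop, , drop = FALSE]
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%03d", seq_len(nrow(x)))
  x
}

nearest_center <- function(x, centers) {
  d <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * tcrossprod(x, centers)
  max.col(-d, ties.method = "first")
}

#' Choose the number of clusters by the stress function
#'
#' The stress at K is the normalized quantization error of a fitted
#' neural-gas codebook: sum of squared distances to the nearest codebook
#' divided by the total sum of squares around the grand mean, i.e. the
#' fraction of total variance left unexplained. K is chosen by an elbow rule:
#' the model stops growing at the last K before the stress improvement of the
#' next codebook — the extra fraction of total variance it explains — drops
#' below `threshold`.
#'
#' @param profile matrix or `combined_profile` to cluster.
#' @param k_range candidate K values (default 2 to min(15, rows - 1)).
#' @param seed RNG seed.
#' @param threshold stress-improvement cutoff, as a fraction of total
#'   variance (default 0.05).
#' @param override if non-NULL, skip estimation and return this K (the study
#'   design this mirrors fixed K = 18).
#' @param ... passed to [neural_gas_fit()] (e.g. `restarts`, `epochs`).
#' @return list with `K` and `stress_by_k` (named numeric).
#' @export
estimate_k_by_stress <- function(profile, k_range = NULL, seed = 1L,
                                 threshold = 0.05, override = NULL, ...) {
  x <- profile_matrix(profile)
  if (!is.null(override)) {
    return(list(K = as.integer(override), stress_by_k = NULL))
  }
  if (is.null(k_range)) k_range <- 2:min(15L, nrow(x) - 1L)
  if (min(k_range) < 2L || max(k_range) > nrow(x) - 1L) {
    stop_histofunc("k_range must lie within [2, features - 1]")
  }
  tss <- sum(sweep(x, 2L, colMeans(x))^2)
  stress <- vapply(k_range, function(k) {
    fit <- neural_gas_fit(x, k, seed = derive_seed(seed, paste0("stress", k)), ...)
    fit$quantization_error / tss
  }, 0)
  names(stress) <- k_range
  K <- max(k_range)
  for (i in seq_along(k_range)[-1L]) {
    if (stress[i - 1L] - stress[i] < threshold) { K <- k_range[i - 1L]; break }
  }
  list(K = as.integer(K), stress_by_k = stress)
}

#' Assign held-out features to clusters by K nearest neighbours
#'
#' Features not used in codebook training are assigned by majority vote of
#' the `k_neighbors` nearest already-assigned features (Euclidean distance);
#' ties are broken by the single nearest neighbour.
#'
#' @param model a fitted `cluster_model`.
#' @param new_features matrix of new feature profiles (same columns).
#' @param k_neighbors number of neighbours (default 3).
#' @return integer cluster assignments named by feature.
#' @export
knn_assign <- function(model, new_features, k_neighbors = 3L) {
  new_features <- as.matrix(new_features)
  if (k_neighbors > length(model$assignments)) {
    stop_histofunc("k_neighbors larger than the assigned population")
  }
  ref <- model$data
  out <- integer(nrow(new_features))
  for (i in seq_len(nrow(new_features))) {
    d <- sqrt(rowSums((ref - matrix(new_features[i, ], nrow(ref), ncol(ref),
                                    byrow = TRUE))^2))
    ord <- order(d)
    nb <- model$assignments[ord[seq_len(k_neighbors)]]
    tab <- table(nb)
    win <- as.integer(names(tab)[tab == max(tab)])
    out[i] <- if (length(win) == 1L) win else model$assignments[ord[1L]]
  }
  stats::setNames(out, rownames(new_features))
}

#' Shrinkage partial-correlation estimate with significance tests
#'
#' Estimates the covariance of the cluster centers across conditions with
#' analytic shrinkage of the correlation matrix toward the identity
#' (Schafer-Strimmer), inverts it, and converts the precision matrix Omega to
#' partial correlations rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj).
#' P-values use the Fisher z-transform with effective degrees of freedom
#' n - (K - 2) - 3 when that is positive, otherwise an empirical permutation
#' null (each variable's condition series permuted independently).
#'
#' @param centers K x n matrix: cluster centers (rows) across conditions.
#' @param n_perm permutations for the fallback null (default 1000).
#' @param shrink if FALSE, invert the sample covariance directly (fails when
#'   singular); shrinkage is the default and is always used when K >= n.
#' @param seed seed for the permutation fallback.
#' @return list with `pcor`, `pvalues` (K x K), `lambda` (shrinkage
#'   intensity), `df`, `method`.
#' @export
ggm_fit <- function(centers, n_perm = 1000L, shrink = TRUE, seed = 1L) {
  centers <- as.matrix(centers)
  K <- nrow(centers); n <- ncol(centers)
  if (n <= 3L) stop_histofunc("need more than 3 conditions for the GGM")
  sigma <- shrink_covariance(centers, shrink = shrink || K >= n)
  pcor <- partial_correlation(sigma$cov)
  df <- n - (K - 2L) - 3L
  if (df >= 1L) {
    z <- atanh(pmin(pmax(pcor, -1 + 1e-12), 1 - 1e-12))
    pv <- 2 * stats::pnorm(-abs(z) * sqrt(df))
    method <- "fisher_z"
  } else {
    pv <- with_seed(seed, pcor_permutation_p(centers, pcor, n_perm, shrink))
    method <- "permutation"
  }
  diag(pv) <- 1
  dimnames(pv) <- dimnames(pcor)
  list(pcor = pcor, pvalues = pv, lambda = sigma$lambda, df = df,
       method = method)
}

#' Partial correlations from a covariance matrix
#'
#' @param sigma positive-definite covariance matrix.
#' @return matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(sigma) {
  omega <- solve(sigma)
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(sigma)
  pc
}

#' Shrinkage covariance estimate
#'
#' Schafer-Strimmer analytic shrinkage of the sample correlation matrix
#' toward the identity, re-scaled to a covariance. The optimal intensity is
#' estimated from the variances of the sample correlations; variances on the
#' diagonal are never shrunk, and the result is positive definite even when
#' there are more variables than observations.
#'
#' @param x numeric matrix with variables in rows and observations in columns.
#' @param shrink if FALSE return the plain sample covariance (lambda 0).
#' @return list with `cov` (shrunken covariance) and `lambda` (intensity).
#' @export
shrink_covariance <- function(x, shrink = TRUE) {
  n <- ncol(x)                      # observations (conditions)
  xc <- t(scale(t(x), center = TRUE, scale = FALSE))
  s <- tcrossprod(xc) / (n - 1)
  sdv <- sqrt(diag(s))
  sdv[sdv == 0] <- .Machine$double.eps
  r <- s / tcrossprod(sdv)
  lambda <- 0
  if (shrink) {
    xs <- xc / sdv                  # standardized rows
    w_mean <- tcrossprod(xs) / n    # mean of w_kij = mean products
    var_r <- matrix(0, nrow(x), nrow(x))
    for (k in seq_len(n)) {
      wk <- tcrossprod(xs[, k])
      var_r <- var_r + (wk - w_mean)^2
    }
    var_r <- var_r * n / ((n - 1)^3)
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
    r <- (1 - lambda) * r
    diag(r) <- 1
  }
  cov <- r * tcrossprod(sdv)
  dimnames(cov) <- list(rownames(x), rownames(x))
  list(cov = cov, lambda = lambda)
}

pcor_permutation_p <- function(centers, pcor, n_perm, shrink) {
  K <- nrow(centers); n <- ncol(centers)
  exceed <- matrix(0, K, K)
  for (b in seq_len(n_perm)) {
    perm <- t(apply(centers, 1L, sample))
    pc_b <- partial_correlation(shrink_covariance(perm, shrink = shrink)$cov)
    exceed <- exceed + (abs(pc_b) >= abs(pcor))
  }
  (1 + exceed) / (n_perm + 1)
}

#' Build the protein-histone modification interaction network
#'
#' Edges are cluster pairs whose partial-correlation p-value falls below the
#' significance threshold (default p < 0.003). Each node carries its member
#' features and a representative member (the feature nearest the cluster
#' center).
#'
#' @param model a `cluster_model` from [neural_gas_fit()].
#' @param pcor,pvalues matrices from [ggm_fit()].
#' @param threshold significance level (default 0.003).
#' @param origin optional named origin vector ("binding"/"modification") per
#'   feature, used to tag nodes and edges.
#' @return a `ggm_network`: list with `nodes` (data.frame), `edges`
#'   (data.frame with pcor and p), `threshold`.
#' @export
build_network <- function(model, pcor, pvalues, threshold = 0.003,
                          origin = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  K <- model$K
  members <- split(names(model$assignments), model$assignments)
  reps <- vapply(seq_len(K), function(k) {
    ids <- members[[as.character(k)]]
    if (is.null(ids)) return(NA_character_)
    d <- sqrt(rowSums((model$data[ids, , drop = FALSE] -
                         matrix(model$centers[k, ], length(ids),
                                ncol(model$centers), byrow = TRUE))^2))
    ids[which.min(d)]
  }, "")
  node_origin <- if (is.null(origin)) rep(NA_character_, K) else {
    vapply(seq_len(K), function(k) {
      ids <- members[[as.character(k)]]
      if (is.null(ids)) return(NA_character_)
      paste(sort(unique(origin[ids])), collapse = "+")
    }, "")
  }
  nodes <- data.frame(
    cluster = seq_len(K),
    representative = reps,
    n_members = vapply(seq_len(K), function(k)
      length(members[[as.character(k)]] %||% character()), 0L),
    members = vapply(seq_len(K), function(k)
      paste(members[[as.character(k)]] %||% character(), collapse = ","), ""),
    origin = node_origin,
    stringsAsFactors = FALSE)
  idx <- which(upper.tri(pvalues) & pvalues < threshold, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1L], to = idx[, 2L],
                      pcor = pcor[idx], p = pvalues[idx])
  if (nrow(edges) > 0L && !is.null(origin)) {
    edges$link <- paste(pmin(node_origin[edges$from], node_origin[edges$to]),
                        pmax(node_origin[edges$from], node_origin[edges$to]),
                        sep = "--")
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("ggm_network: %d clusters, %d edges at p < %g\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a network as GraphML and SIF
#'
#' @param network a `ggm_network`.
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>.sif`, and `<prefix>_clusters.tsv`.
#' @return files written, invisibly.
#' @export
export_network <- function(network, prefix) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(network$edges)) network$edges[, c("from", "to", "pcor", "p")]
        else data.frame(from = integer(), to = integer(),
                        pcor = numeric(), p = numeric()),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$cluster,
                          representative = network$nodes$representative,
                          members = network$nodes$members))
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  sif <- paste0(prefix, ".sif")
  if (nrow(network$edges)) {
    writeLines(sprintf("%d pcor %d", network$edges$from, network$edges$to), sif)
  } else {
    writeLines(character(), sif)
  }
  memb <- paste0(prefix, "_clusters.tsv")
  utils::write.table(network$nodes, memb, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml, sif, memb))
}
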