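#' Bayesian neural network architecture
#'
#' One hidden layer of logistic-sigmoid units and a logistic-sigmoid output,
#' so the network output y(x; w, A) lies in (0, 1) and is read as
#' P(t = 1 | x, w, A) for binary targets t. Two hidden units is the working
#' default for the functional-binding classification task.
#'
#' @param n_inputs number of input features.
#' @param n_hidden hidden units (default 2).
#' @return a `bnn_architecture` list.
#' @export
bnn_architecture <- function(n_inputs, n_hidden = 2L) {
  stopifnot(n_inputs >= 1L, n_hidden >= 1L)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden)),
            class = "bnn_architecture")
}

n_params <- function(arch) {
  arch$n_hidden * arch$n_inputs + arch$n_hidden + arch$n_hidden + 1L
}

# w layout: W1 (h x d, row-major by hidden unit), b1 (h), w2 (h), b2 (1)
unpack_w <- function(w, arch) {
  d <- arch$n_inputs; h <- arch$n_hidden
  list(W1 = matrix(w[seq_len(h * d)], h, d, byrow = TRUE),
       b1 = w[h * d + seq_len(h)],
       w2 = w[h * d + h + seq_len(h)],
       b2 = w[h * d + 2L * h + 1L])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the classification network
#'
#' @param model a `bnn_model` (or a list with `w` and `arch`).
#' @param X matrix of examples x features (a single example may be a vector).
#' @return vector of outputs y in (0, 1).
#' @export
bnn_forward <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  arch <- model$arch
  if (ncol(X) != arch$n_inputs) stop_histofunc("feature dimension mismatch")
  p <- unpack_w(model$w, arch)
  H <- sigmoid(X %*% t(p$W1) + matrix(p$b1, nrow(X), arch$n_hidden, byrow = TRUE))
  as.vector(sigmoid(H %*% p$w2 + p$b2))
}

#' Evidence-framework objective M(w) = E_D + alpha * E_w
#'
#' E_D is the binary cross-entropy over the m training examples,
#' -sum(t log y + (1 - t) log(1 - y)), with probability clamping at 1e-12;
#' E_w = 1/2 sum_i w_i^2 is the regularizer over the i network parameters.
#'
#' @param w parameter vector.
#' @param arch a [bnn_architecture()].
#' @param X,t training examples and binary labels.
#' @param alpha regularization hyperparameter (> 0; 0 gives the pure
#'   cross-entropy).
#' @return scalar objective value.
#' @export
bnn_objective <- function(w, arch, X, t, alpha) {
  y <- bnn_forward(list(w = w, arch = arch), X)
  y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  ed <- -sum(t * log(y) + (1 - t) * log(1 - y))
  ed + alpha * 0.5 * sum(w^2)
}

#' Analytic gradient of the objective
#'
#' Backpropagation through the single hidden layer; the data-term gradient
#' plus alpha * w.
#'
#' @inheritParams bnn_objective
#' @return gradient vector of length `n_params(arch)`.
#' @export
bnn_gradient <- function(w, arch, X, t, alpha) {
  X <- as.matrix(X)
  p <- unpack_w(w, arch)
  H <- sigmoid(X %*% t(p$W1) + matrix(p$b1, nrow(X), arch$n_hidden, byrow = TRUE))
  y <- as.vector(sigmoid(H %*% p$w2 + p$b2))
  delta <- y - t                                   # dE_D/df for cross-entropy
  g_w2 <- as.vector(crossprod(H, delta))
  g_b2 <- sum(delta)
  back <- (delta %o% p$w2) * H * (1 - H)           # m x h
  g_W1 <- crossprod(back, X)                       # h x d
  g_b1 <- colSums(back)
  c(as.vector(t(g_W1)), g_b1, g_w2, g_b2) + alpha * w
}

#' Gauss-Newton approximation to the data-error Hessian
#'
#' For a logistic output the Hessian of the cross-entropy data error is
#' approximated by \eqn{\sum_m y_m (1 - y_m) g_m g_m^T}, with \eqn{g_m} the
#' gradient of the output pre-activation for example \eqn{m}. The
#' approximation is positive semi-definite by construction, which keeps the
#' evidence-framework eigenvalues non-negative.
#'
#' @param w packed weight vector.
#' @param arch a [bnn_architecture()].
#' @param X numeric feature matrix (examples in rows).
#' @return the `length(w)` x `length(w)` Gauss-Newton matrix.
#' @export
bnn_gauss_newton <- function(w, arch, X) {
  X <- as.matrix(X)
  p <- unpack_w(w, arch)
  H <- sigmoid(X %*% t(p$W1) + matrix(p$b1, nrow(X), arch$n_hidden, byrow = TRUE))
  y <- as.vector(sigmoid(H %*% p$w2 + p$b2))
  np <- n_params(arch)
  GN <- matrix(0, np, np)
  for (m in seq_len(nrow(X))) {
    hm <- H[m, ]
    dW1 <- (p$w2 * hm * (1 - hm)) %o% X[m, ]       # h x d
    g <- c(as.vector(t(dW1)), p$w2 * hm * (1 - hm), hm, 1)
    GN <- GN + y[m] * (1 - y[m]) * tcrossprod(g)
  }
  GN
}

#' Train the network under the evidence framework
#'
#' Alternates (inner) gradient-based minimization of M(w) at fixed alpha with
#' (outer) re-estimation of alpha from a Gaussian approximation to the weight
#' posterior: alpha <- gamma / (2 E_w), gamma = sum_i lambda_i /
#' (lambda_i + alpha), where lambda_i are the eigenvalues of the Gauss-Newton
#' approximation to the data-error Hessian at the current optimum. The outer
#' loop stops when alpha changes by less than 1% or `max_outer` cycles.
#'
#' @param X examples x features matrix (Z-scored features expected).
#' @param t binary labels (both classes must be present).
#' @param arch a [bnn_architecture()].
#' @param seed RNG seed for the N(0, 0.1^2) weight initialization.
#' @param alpha0 initial alpha (default 0.01).
#' @param max_outer maximum alpha re-estimation cycles (default 10).
#' @param max_inner maximum optimizer iterations per cycle (default 200).
#' @param tol inner convergence tolerance (default 1e-8).
#' @param alpha_max cap applied when gamma degenerates to ~0 (default 1e6).
#' @param fixed_alpha if TRUE, skip re-estimation and train at `alpha0`.
#' @return a `bnn_model`: list with `w`, `arch`, `alpha`,
#'   `hessian_eigenvalues`, `gamma`, `objective_trace`, `alpha_trace`, `seed`.
#' @export
bnn_train <- function(X, t, arch, seed = 1L, alpha0 = 0.01, max_outer = 10L,
                      max_inner = 200L, tol = 1e-8, alpha_max = 1e6,
                      fixed_alpha = FALSE) {
  X <- as.matrix(X)
  t <- as.numeric(t)
  if (!all(t %in% c(0, 1))) stop_histofunc("labels must be 0/1")
  if (length(unique(t)) < 2L) stop_histofunc("both classes must be present")
  np <- n_params(arch)
  w <- with_seed(seed, stats::rnorm(np, sd = 0.1))
  alpha <- alpha0
  trace <- numeric(0)
  alpha_trace <- alpha
  lam <- NULL; gam <- NA_real_
  for (outer in seq_len(max_outer)) {
    opt <- stats::optim(w, fn = bnn_objective, gr = bnn_gradient,
                        arch = arch, X = X, t = t, alpha = alpha,
                        method = "BFGS",
                        control = list(maxit = max_inner, reltol = tol))
    if (!is.finite(opt$value)) stop_histofunc("non-finite objective during training")
    w <- opt$par
    trace <- c(trace, opt$value)
    if (fixed_alpha) break
    lam <- eigen(bnn_gauss_newton(w, arch, X), symmetric = TRUE,
                 only.values = TRUE)$values
    lam <- pmax(lam, 0)
    gam <- sum(lam / (lam + alpha))
    ew <- 0.5 * sum(w^2)
    new_alpha <- if (gam < 1e-10 || ew < 1e-12) {
      warning("degenerate gamma or E_w; alpha capped", call. = FALSE)
      alpha_max
    } else {
      min(gam / (2 * ew), alpha_max)
    }
    converged <- abs(new_alpha - alpha) / alpha < 0.01
    alpha <- new_alpha
    alpha_trace <- c(alpha_trace, alpha)
    if (converged) break
  }
  structure(list(w = w, arch = arch, alpha = alpha,
                 hessian_eigenvalues = lam, gamma = gam,
                 objective_trace = trace, alpha_trace = alpha_trace,
                 seed = seed),
            class = "bnn_model")
}

#' Predict class labels
#'
#' @param model a trained `bnn_model`.
#' @param X matrix of examples.
#' @param threshold decision threshold on y (default 0.5); y equal to the
#'   threshold is classified positive.
#' @return integer vector of 0/1 labels.
#' @export
bnn_predict <- function(model, X, threshold = 0.5) {
  as.integer(bnn_forward(model, X) >= threshold)
}

#' Build the per-TF labeled classification dataset
#'
#' Rows are the TF's functional and non-functional target genes present in
#' the (ORF-region, Z-scored) gene signal matrix with no missing selected
#' features; features are the modification channels plus, optionally, the
#' occupancy and HAT channels.
#'
#' @param gene_signals an ORF `gene_signal_matrix` on the zscore scale.
#' @param targets a single [binding_target_set()].
#' @param include_occupancy,include_hat include those assay classes as
#'   features (default TRUE, matching a design where nucleosome density and
#'   HAT occupancy are informative channels).
#' @return a `labeled_dataset`: list with `X`, `t` (1 = functional), `genes`,
#'   `tf_id`.
#' @export
build_feature_table <- function(gene_signals, targets,
                                include_occupancy = TRUE, include_hat = TRUE) {
  if (gene_signals$region != "ORF") {
    stop_histofunc("classification features come from the ORF region")
  }
  keep_class <- c("modification",
                  if (include_occupancy) "occupancy",
                  if (include_hat) "HAT")
  cols <- names(gene_signals$assay_class)[gene_signals$assay_class %in% keep_class]
  cols <- intersect(cols, colnames(gene_signals$values))
  genes <- c(targets$functional_genes, targets$nonfunctional_genes)
  lab <- c(rep(1L, length(targets$functional_genes)),
           rep(0L, length(targets$nonfunctional_genes)))
  present <- genes %in% rownames(gene_signals$values)
  genes <- genes[present]; lab <- lab[present]
  X <- gene_signals$values[genes, cols, drop = FALSE]
  complete <- rowSums(is.na(X)) == 0L
  if (any(!complete)) {
    message(sum(!complete), " gene(s) dropped for missing features")
  }
  X <- X[complete, , drop = FALSE]; lab <- lab[complete]; genes <- genes[complete]
  if (sum(lab == 1L) < 2L || sum(lab == 0L) < 2L) {
    stop_histofunc("fewer than 2 usable genes in a class for ", targets$tf_id)
  }
  structure(list(X = X, t = lab, genes = genes, tf_id = targets$tf_id),
            class = "labeled_dataset")
}

#' Repeated stratified half-split evaluation
#'
#' The evaluation protocol for the functional-binding classifier: the
#' available examples are split in half (stratified by class) into training
#' and test sets, a network is trained on the first half and scored on the
#' second, and the split is repeated `n_splits` times. The headline figure is
#' the MPCC, the mean percentage of correct classifications over the test
#' sets, alongside the mean total number correct and the mean confusion
#' matrix.
#'
#' @param data a `labeled_dataset`.
#' @param arch a [bnn_architecture()]; defaults to 2 hidden units on the
#'   data's features.
#' @param n_splits number of random splits (default 10).
#' @param seed RNG seed controlling splits and weight initializations.
#' @param ... passed to [bnn_train()].
#' @return a `classification_report`: list with `mpcc`, `mean_total_correct`,
#'   `mean_confusion` (TP/FP/TN/FN), `per_split` data.frame, `n_splits`.
#' @export
evaluate_random_splits <- function(data, arch = NULL, n_splits = 10L,
                                   seed = 1L, ...) {
  if (is.null(arch)) arch <- bnn_architecture(ncol(data$X))
  pos <- which(data$t == 1L); neg <- which(data$t == 0L)
  if (length(pos) < 4L || length(neg) < 4L) {
    stop_histofunc("need >= 4 examples per class for half-split evaluation")
  }
  splits <- with_seed(derive_seed(seed, "splits"), {
    lapply(seq_len(n_splits), function(s) {
      train <- c(sample(pos, floor(length(pos) / 2)),
                 sample(neg, floor(length(neg) / 2)))
      list(train = train, test = setdiff(seq_along(data$t), train))
    })
  })
  per <- lapply(seq_len(n_splits), function(s) {
    tr <- splits[[s]]$train; te <- splits[[s]]$test
    model <- bnn_train(data$X[tr, , drop = FALSE], data$t[tr], arch,
                       seed = derive_seed(seed, paste0("init", s)), ...)
    pred <- bnn_predict(model, data$X[te, , drop = FALSE])
    truth <- data$t[te]
    data.frame(split = s,
               pcc = 100 * mean(pred == truth),
               n_correct = sum(pred == truth),
               tp = sum(pred == 1 & truth == 1),
               fp = sum(pred == 1 & truth == 0),
               tn = sum(pred == 0 & truth == 0),
               fn = sum(pred == 0 & truth == 1))
  })
  per <- do.call(rbind, per)
  structure(list(mpcc = mean(per$pcc),
                 mean_total_correct = mean(per$n_correct),
                 mean_confusion = colMeans(per[, c("tp", "fp", "tn", "fn")]),
                 per_split = per, n_splits = n_splits,
                 tf_id = data$tf_id),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report%s: MPCC = %.1f over %d splits, mean correct = %.1f\n",
              if (!is.null(x$tf_id)) paste0(" [", x$tf_id, "]") else "",
              x$mpcc, x$n_splits, x$mean_total_correct))
  invisible(x)
}

#' Stratified 10-fold cross-validation
#'
#' Same metrics as [evaluate_random_splits()], computed over stratified
#' folds; every example is tested exactly once. If a class has fewer than 10
#' examples the fold count is reduced with a warning.
#'
#' @inheritParams evaluate_random_splits
#' @param n_folds number of folds (default 10).
#' @return a `classification_report` (per_split holds per-fold rows).
#' @export
crossvalidate_10fold <- function(data, arch = NULL, seed = 1L, n_folds = 10L, ...) {
  if (is.null(arch)) arch <- bnn_architecture(ncol(data$X))
  n_min <- min(sum(data$t == 1L), sum(data$t == 0L))
  if (n_min < n_folds) {
    warning("reducing folds to ", n_min, call. = FALSE)
    n_folds <- n_min
  }
  folds <- with_seed(derive_seed(seed, "folds"), {
    f <- integer(length(data$t))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(data$t == cls))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  per <- lapply(seq_len(n_folds), function(k) {
    te <- which(folds == k); tr <- which(folds != k)
    model <- bnn_train(data$X[tr, , drop = FALSE], data$t[tr], arch,
                       seed = derive_seed(seed, paste0("cvinit", k)), ...)
    pred <- bnn_predict(model, data$X[te, , drop = FALSE])
    truth <- data$t[te]
    data.frame(split = k, pcc = 100 * mean(pred == truth),
               n_correct = sum(pred == truth),
               tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
               tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
  })
  per <- do.call(rbind, per)
  structure(list(mpcc = mean(per$pcc),
                 mean_total_correct = mean(per$n_correct),
                 mean_confusion = colMeans(per[, c("tp", "fp", "tn", "fn")]),
                 per_split = per, n_splits = n_folds, tf_id = data$tf_id),
            class = "classification_report")
}
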