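# Cross-sample profiling: dimensionality reduction and sample correlation.
# Samples are the observations throughout (the matrix is transposed before
# any embedding).

#' Dimensionality reduction of samples
#'
#' Embeds the samples of an experiment in `k` dimensions. `"pca"` uses
#' singular value decomposition on the centered (optionally scaled)
#' sample-by-lipid matrix with a deterministic sign convention (the largest
#' absolute loading of each component is positive), so results are
#' reproducible and invariant to lipid row order. `"tsne"` and `"umap"`
#' are compact implementations of the t-SNE and UMAP algorithms sized for
#' the tens-of-samples designs typical of lipidomics; both are stochastic
#' and fully determined by `seed`.
#'
#' @param exp A `lipid_experiment`.
#' @param method One of `"pca"`, `"tsne"`, `"umap"`.
#' @param k Embedding dimension, at least 2 (default 2).
#' @param seed Integer seed for the stochastic methods (default 0).
#' @param scale. For PCA, scale lipids to unit variance (default `FALSE`);
#'   constant lipids are left unscaled.
#' @param perplexity t-SNE perplexity; default `min(30, (n-1)/3)`.
#' @param n_neighbors UMAP neighborhood size; default `min(15, n-1)`.
#' @return An `embedding`: list with `method`, `coordinates`
#'   (samples x k matrix, sample row names), `explained_variance_ratio`
#'   (PCA only, one value per returned component) and `seed`.
#' @export
reduce_dimensions <- function(exp, method = c("pca", "tsne", "umap"),
                              k = 2L, seed = 0L, scale. = FALSE,
                              perplexity = NULL, n_neighbors = NULL) {
  stopifnot(inherits(exp, "lipid_experiment"))
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  X <- t(exp$matrix)  # samples x lipids
  n <- nrow(X)
  if (method == "pca") {
    if (k > n) stop("k exceeds the number of samples")
    X <- scale(X, center = TRUE, scale = FALSE)
    if (scale.) {
      sds <- apply(X, 2L, stats::sd)
      X[, sds > 0] <- sweep(X[, sds > 0, drop = FALSE], 2L, sds[sds > 0], `/`)
    }
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    m <- ncol(pc$x)
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    # sign convention: largest-|loading| entry of each component positive
    for (j in seq_len(m)) {
      piv <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[piv, j] < 0) {
        pc$rotation[, j] <- -pc$rotation[, j]
        pc$x[, j] <- -pc$x[, j]
      }
    }
    coords <- matrix(0, n, k, dimnames = list(exp$samples, paste0("PC", seq_len(k))))
    take <- min(k, m)
    coords[, seq_len(take)] <- pc$x[, seq_len(take), drop = FALSE]
    ratio <- rep(0, k)
    ratio[seq_len(take)] <- evr[seq_len(take)]
    out <- list(method = "pca", coordinates = coords,
                explained_variance_ratio = ratio, seed = seed)
  } else if (method == "tsne") {
    if (is.null(perplexity)) perplexity <- max(1, min(30, (n - 1) / 3))
    coords <- tsne_embed(X, k = k, perplexity = perplexity, seed = seed)
    dimnames(coords) <- list(exp$samples, paste0("TSNE", seq_len(k)))
    out <- list(method = "tsne", coordinates = coords,
                explained_variance_ratio = NULL, seed = seed)
  } else {
    if (is.null(n_neighbors)) n_neighbors <- max(2L, min(15L, n - 1L))
    coords <- umap_embed(X, k = k, n_neighbors = n_neighbors, seed = seed)
    dimnames(coords) <- list(exp$samples, paste0("UMAP", seq_len(k)))
    out <- list(method = "umap", coordinates = coords,
                explained_variance_ratio = NULL, seed = seed)
  }
  structure(out, class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> ", x$method, ", ", nrow(x$coordinates), " samples x ",
      ncol(x$coordinates), " dims\n", sep = "")
  if (!is.null(x$explained_variance_ratio)) {
    cat("  explained variance ratio:",
        paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  }
  invisible(x)
}

# --- t-SNE ------------------------------------------------------------------
# Exact (non Barnes-Hut) t-SNE; quadratic in n, which is fine for sample
# counts in the tens.

tsne_embed <- function(X, k, perplexity, seed, max_iter = 500L, eta = 100) {
  n <- nrow(X)
  if (n < 3L) stop("t-SNE needs at least 3 samples")
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (it in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  Y <- matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
  dY <- matrix(0, n, k); iY <- matrix(0, n, k); gains <- matrix(1, n, k)
  momentum <- 0.5
  P_run <- P * 4  # early exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 101L) P_run <- P
    if (iter == 21L) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P_run - Q) * num
    dY <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(dY) != sign(iY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    iY <- momentum * iY - eta * (gains * dY)
    Y <- Y + iY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

# --- UMAP-style embedding ---------------------------------------------------
# Fuzzy k-NN graph with smooth-kNN bandwidth calibration, symmetrized by the
# probabilistic t-conorm, laid out by full-batch gradient descent on the
# fuzzy cross-entropy with the standard low-dimensional kernel
# 1/(1 + a d^(2b)) (a, b for min_dist = 0.1). Full-batch is affordable at
# lipidomics sample counts and makes the result a deterministic function of
# the seed.

umap_embed <- function(X, k, n_neighbors, seed, n_iter = 300L, lr = 0.05,
                       a = 1.577, b = 0.8951) {
  n <- nrow(X)
  if (n < 3L) stop("UMAP needs at least 3 samples")
  n_neighbors <- min(n_neighbors, n - 1L)
  D <- as.matrix(stats::dist(X))
  W <- matrix(0, n, n)
  target <- log2(n_neighbors + 1)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    nn <- order(d)[seq_len(n_neighbors)]
    dn <- d[nn]
    rho <- min(dn[dn > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    lo <- 1e-8; hi <- max(dn) + 1
    sigma <- 1
    for (it in 1:64) {
      sigma <- (lo + hi) / 2
      s <- sum(exp(-pmax(dn - rho, 0) / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) hi <- sigma else lo <- sigma
    }
    w <- exp(-pmax(dn - rho, 0) / sigma)
    idx <- which(seq_len(n) != i)[nn]
    W[i, idx] <- w
  }
  W <- W + t(W) - W * t(W)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  Y <- matrix(stats::rnorm(n * k, sd = 1), n, k)
  for (iter in seq_len(n_iter)) {
    G <- matrix(0, n, k)
    d2 <- as.matrix(stats::dist(Y))^2
    phi <- 1 / (1 + a * d2^b)
    diag(phi) <- 0
    # attractive + repulsive cross-entropy gradient wrt squared distance
    eps <- 1e-9
    dphi <- -a * b * pmax(d2, eps)^(b - 1) * phi^2      # d phi / d d2
    coef <- (-W / pmax(phi, eps) +
               (1 - W) / pmax(1 - phi, eps)) * dphi
    diag(coef) <- 0
    for (j in seq_len(k)) {
      diffj <- outer(Y[, j], Y[, j], `-`)
      G[, j] <- 2 * rowSums(coef * diffj)
    }
    gn <- sqrt(sum(G^2))
    if (gn > 0) G <- G / gn * min(gn, n)  # gradient clipping
    Y <- Y - lr * (1 - iter / (n_iter + 1)) * G * n
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

# --- sample correlation -----------------------------------------------------

#' Sample-sample correlation with a clustered ordering
#'
#' Computes the pairwise correlation between samples over all lipids and a
#' deterministic leaf order from average-linkage hierarchical clustering of
#' the dissimilarity `1 - r`. Zero-variance samples (correlation
#' undefined) are excluded and reported.
#'
#' @param exp A `lipid_experiment` with at least 2 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list of class `sample_correlation`: `correlation` (samples x
#'   samples, unit diagonal), `order` (dendrogram leaf order of the
#'   retained samples), `excluded` (names of zero-variance samples) and
#'   `method`.
#' @export
sample_correlation <- function(exp, method = c("pearson", "spearman")) {
  stopifnot(inherits(exp, "lipid_experiment"))
  method <- match.arg(method)
  M <- exp$matrix
  if (ncol(M) < 2L) stop("at least 2 samples required")
  sds <- apply(M, 2L, stats::sd)
  excluded <- colnames(M)[sds == 0]
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) < 2L) stop("fewer than 2 samples with nonzero variance")
  r <- stats::cor(M, method = method)
  diag(r) <- 1
  ord <- if (ncol(M) > 2L) {
    stats::hclust(stats::as.dist(1 - r), method = "average")$order
  } else seq_len(ncol(M))
  structure(list(correlation = r, order = ord, excluded = excluded,
                 method = method),
            class = "sample_correlation")
}

# Seed handling: run a block under a fixed seed without disturbing the
# caller's RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
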