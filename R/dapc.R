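#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per site, columns are centered (no
#' variance scaling) and the centered matrix is decomposed by SVD.
#'
#' @param m a filtered [snp_matrix()] or numeric matrix.
#' @param n_axes number of axes to retain (default: all with non-null
#'   variance).
#' @return A list of class `pca_model`: `center` (column means), `loadings`
#'   (sites x axes), `scores` (individuals x axes), `eigenvalues`
#'   (variance along each axis, = d^2 / n).
#' @export
run_pca <- function(m, n_axes = NULL) {
  X <- if (inherits(m, "snp_matrix")) m$calls else as.matrix(m)
  ids <- if (inherits(m, "snp_matrix")) m$individuals$id else rownames(X)
  n <- nrow(X)
  if (n < 2) stop("PCA needs at least 2 individuals")
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1) %/% n + 1]
  Xc <- sweep(X, 2, cm)
  sv <- svd(Xc)
  eig <- sv$d^2 / n
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (is.null(n_axes)) n_axes <- pos
  n_axes <- min(n_axes, pos)
  keep <- seq_len(n_axes)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_axes)
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", keep)
  structure(list(center = cm, loadings = sv$v[, keep, drop = FALSE],
                 scores = scores, eigenvalues = eig[keep]),
            class = "pca_model")
}

kmeans_bic <- function(wss, K, n) n * log(max(wss, 1e-12) / n) + K * log(n)

#' K-means cluster search with BIC selection
#'
#' For each K in 1..`K_max` the best of `n_start` k-means initializations by
#' within-cluster sum of squares is kept and scored with
#' `BIC(K) = n log(WSS_K / n) + K log(n)`; the optimal K minimizes BIC.
#'
#' @param scores individuals x axes PC score matrix (or a `pca_model`).
#' @param K_max largest cluster number tried.
#' @param n_start number of k-means starts per K.
#' @param seed RNG seed.
#' @param n_pcs number of leading score columns used in the search; the
#'   default is the N/3 rule of thumb (at most a third as many axes as
#'   individuals), which keeps the between-group signal while dropping the
#'   bulk of the per-locus sampling noise that otherwise rewards spurious
#'   splits.
#' @return A list of class `cluster_search`: `table` (K, WSS, BIC),
#'   `assignments` (list per K), `optimal_K`, `groups` (assignment at the
#'   optimum).
#' @export
find_clusters <- function(scores, K_max, n_start = 500L, seed = 1L,
                          n_pcs = NULL) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(n_pcs)) n_pcs <- max(K_max, floor(n / 3))
  scores <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  if (K_max > n) stop("K_max exceeds the number of individuals")
  set.seed(seed)
  Ks <- seq_len(K_max)
  wss <- rep(NA_real_, K_max)
  assignments <- vector("list", K_max)
  for (K in Ks) {
    if (K == 1L) {
      wss[K] <- sum(sweep(scores, 2, colMeans(scores))^2)
      assignments[[K]] <- rep(1L, n)
      next
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(scores, centers = K, nstart = n_start,
                                     iter.max = 50L)),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < K) {
      # re-try once with fresh starts; persistent failure drops this K
      km <- tryCatch(
        suppressWarnings(stats::kmeans(scores, centers = K, nstart = n_start,
                                       iter.max = 50L)),
        error = function(e) NULL)
    }
    if (is.null(km)) {
      warning("k-means failed at K = ", K, "; dropped from the BIC curve")
      next
    }
    wss[K] <- km$tot.withinss
    assignments[[K]] <- km$cluster
  }
  bic <- vapply(Ks, function(K)
    if (is.na(wss[K])) NA_real_ else kmeans_bic(wss[K], K, n), 0)
  optimal_K <- Ks[which.min(bic)]
  structure(list(table = data.frame(K = Ks, WSS = wss, BIC = bic),
                 assignments = assignments, optimal_K = optimal_K,
                 groups = assignments[[optimal_K]]),
            class = "cluster_search")
}

#' @export
print.cluster_search <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("optimal K =", x$optimal_K, "(minimum BIC)\n")
  invisible(x)
}

#' Discriminant assignment of individuals to clusters
#'
#' Linear discriminant axes are built from the between/within scatter of the
#' retained PCs; posterior membership probabilities use Gaussian
#' class-conditional densities with a shared within-group covariance and
#' equal priors.  Assignment is the posterior argmax.
#'
#' @param scores individuals x axes PC score matrix (or `pca_model`).
#' @param labels group label per individual (>= 2 groups, each >= 2 members).
#' @param n_pcs number of leading score columns used (default: smallest
#'   number explaining >= 90 percent of the score variance).
#' @param n_da number of discriminant axes kept (default: groups - 1).
#' @param ridge ridge added to a singular within-scatter matrix.
#' @return A list of class `dapc_model`: `posterior` (rows sum to 1),
#'   `assign`, `da_axes`, `group_means`, `n_pcs`, `labels`.
#' @export
fit_assign <- function(scores, labels, n_pcs = NULL, n_da = NULL,
                       ridge = 1e-8) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 members")
  if (is.null(n_pcs)) {
    v <- apply(scores, 2, var)
    n_pcs <- which(cumsum(v) / sum(v) >= 0.9)[1]
  }
  n_pcs <- min(n_pcs, ncol(scores))
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  G <- nlevels(labels)
  n <- nrow(X)
  mu <- rowsum(X, labels) / as.vector(table(labels))
  # pooled within-group covariance
  Xi <- X - mu[as.integer(labels), , drop = FALSE]
  W <- crossprod(Xi) / (n - G)
  if (rcond(W) < 1e-12) {
    W <- W + diag(ridge, ncol(W))
    message("singular within-scatter; ridge ", ridge, " added")
  }
  Winv <- solve(W)
  # discriminant axes: eigenvectors of W^-1 B
  grand <- colMeans(X)
  B <- crossprod(sweep(mu, 2, grand) * sqrt(as.vector(table(labels)))) / n
  eg <- eigen(Winv %*% B)
  if (is.null(n_da)) n_da <- G - 1L
  n_da <- min(n_da, ncol(X), G - 1L)
  da_axes <- Re(eg$vectors[, seq_len(n_da), drop = FALSE])
  # posteriors from Mahalanobis distances to group means, equal priors
  d2 <- sapply(seq_len(G), function(g) {
    diff <- sweep(X, 2, mu[g, ])
    rowSums((diff %*% Winv) * diff)
  })
  d2 <- matrix(d2, nrow = n)
  lp <- -0.5 * d2
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  colnames(post) <- levels(labels)
  rownames(post) <- rownames(scores)
  assign <- factor(levels(labels)[max.col(post, ties.method = "first")],
                   levels = levels(labels))
  structure(list(posterior = post, assign = assign, da_axes = da_axes,
                 group_means = mu, n_pcs = n_pcs, labels = labels,
                 within_inv = Winv),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d groups, %d retained PCs\n",
              nlevels(x$labels), x$n_pcs))
  print(table(truth = x$labels, assigned = x$assign))
  invisible(x)
}

#' Full DAPC convenience wrapper
#'
#' PCA, k-means BIC cluster search and discriminant assignment in one call.
#'
#' @param m a filtered [snp_matrix()].
#' @param K_max largest cluster number tried.
#' @param n_start k-means restarts.
#' @param seed RNG seed.
#' @param n_pcs retained PCs for the discriminant step (default 90 percent
#'   variance rule).
#' @return list with `pca`, `clusters` (a `cluster_search`) and `dapc` (a
#'   `dapc_model` at the optimal K, NULL when optimal K = 1).
#' @export
dapc <- function(m, K_max = 9L, n_start = 500L, seed = 1L, n_pcs = NULL) {
  pca <- run_pca(m)
  cs <- find_clusters(pca$scores, K_max = K_max, n_start = n_start,
                      seed = seed, n_pcs = NULL)
  model <- if (cs$optimal_K >= 2L)
    fit_assign(pca$scores, cs$groups, n_pcs = n_pcs) else NULL
  list(pca = pca, clusters = cs, dapc = model)
}
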