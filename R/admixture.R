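#' MCMC/EM configuration for admixture-model fits
#'
#' @param burn_in burn-in sweeps discarded before averaging.
#' @param reps post-burn-in sweeps.
#' @param n_chains independent replicate chains per K.
#' @param K_range contiguous grid of cluster numbers.
#' @param seed base RNG seed; chain `c` at cluster number `K` derives its own
#'   stream deterministically from it.
#' @param lambda symmetric Beta/Dirichlet prior for cluster allele
#'   frequencies.
#' @param infer_alpha update the shared Dirichlet concentration by a
#'   Metropolis step (uniform prior on (0, `alpha_max`)); when FALSE, `alpha`
#'   is held fixed.
#' @param alpha initial (or fixed) Dirichlet concentration of ancestry rows.
#' @param alpha_max upper bound of the uniform prior on alpha.
#' @param alpha_prop_sd Metropolis proposal standard deviation.
#' @param method `"gibbs"` (posterior-mean estimates from the sampler) or
#'   `"em"` (deterministic MAP estimates, useful for fast exact-ish tests).
#' @param em_maxit,em_tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(burn_in = 10000L, reps = 50000L, n_chains = 3L,
                       K_range = 1:9, seed = 1L, lambda = 1,
                       infer_alpha = TRUE, alpha = 1, alpha_max = 10,
                       alpha_prop_sd = 0.05,
                       method = c("gibbs", "em"),
                       em_maxit = 500L, em_tol = 1e-6, ll_thin = 1L) {
  if (burn_in <= 0 || reps <= 0) stop("burn_in and reps must be positive")
  if (!length(K_range)) stop("K_range is empty")
  structure(list(burn_in = as.integer(burn_in), reps = as.integer(reps),
                 n_chains = as.integer(n_chains),
                 K_range = as.integer(K_range), seed = as.integer(seed),
                 lambda = lambda, infer_alpha = infer_alpha, alpha = alpha,
                 alpha_max = alpha_max, alpha_prop_sd = alpha_prop_sd,
                 method = match.arg(method),
                 em_maxit = as.integer(em_maxit), em_tol = em_tol,
                 ll_thin = as.integer(ll_thin)),
            class = "run_config")
}

#' Reduced MCMC profile for desk-scale runs
#'
#' Same model, shorter chains (1,000 burn-in + 5,000 repetitions); intended
#' for tests and synthetic panels of a few hundred loci.
#'
#' @param ... overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
reduced_profile <- function(...) {
  args <- list(...)
  defaults <- list(burn_in = 1000L, reps = 5000L, ll_thin = 5L)
  do.call(run_config, utils::modifyList(defaults, args))
}

#' Admixture-model data log-likelihood
#'
#' Sum over non-missing calls of the binomial log-probability of the alt
#' dosage under per-call alt frequency theta_il = sum_k Q_ik P_kl, with
#' frequencies clamped to (1e-9, 1 - 1e-9).
#'
#' @param m a [snp_matrix()] (or an integer dosage matrix).
#' @param Q N x K ancestry proportions.
#' @param P K x L cluster alt-allele frequencies.
#' @return Finite log-likelihood.
#' @export
admix_loglik <- function(m, Q, P) {
  G <- if (inherits(m, "snp_matrix")) m$calls else m
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(Q) != nrow(G)) stop("Q rows do not match individuals")
  if (ncol(Q) != nrow(P)) stop("Q columns do not match P rows")
  if (ncol(P) != ncol(G)) stop("P columns do not match sites")
  admix_loglik_cpp(G, Q, P)
}

# Deterministic EM (MAP) fit of the admixture model.  Supervised semantics:
# rows listed in `fixed_pop` (values 1..K, NA free) are pinned to their
# indicator and, when also flagged in `freq_source`, are the only rows whose
# expected allele-origin counts update P.
admix_em <- function(G, K, lambda = 1, maxit = 500L, tol = 1e-6,
                     fixed_pop = NULL, freq_source = NULL) {
  N <- nrow(G); L <- ncol(G)
  na <- is.na(G)
  xalt <- ifelse(na, 0, G)
  xref <- ifelse(na, 0, 2 - G)
  if (is.null(fixed_pop)) fixed_pop <- rep(NA_integer_, N)
  if (is.null(freq_source)) freq_source <- rep(TRUE, N)
  free <- is.na(fixed_pop)
  Q <- matrix(rgamma(N * K, 1), N, K)
  Q <- Q / rowSums(Q)
  for (i in which(!free)) Q[i, ] <- as.numeric(seq_len(K) == fixed_pop[i])
  P <- matrix(runif(K * L, 0.2, 0.8), K, L)
  eps <- 1e-9
  ll_old <- -Inf
  trace <- numeric(0)
  src <- which(freq_source)
  for (it in seq_len(maxit)) {
    theta <- Q %*% P
    theta <- pmin(pmax(theta, eps), 1 - eps)
    Qnum <- matrix(0, N, K)
    Palt <- matrix(0, K, L); Ptot <- matrix(0, K, L)
    for (k in seq_len(K)) {
      Ak <- (Q[, k] %o% P[k, ]) / theta           # resp. of alt copies to k
      Bk <- (Q[, k] %o% (1 - P[k, ])) / (1 - theta)
      wa <- xalt * Ak; wb <- xref * Bk
      Qnum[, k] <- rowSums(wa + wb)
      Palt[k, ] <- colSums(wa[src, , drop = FALSE])
      Ptot[k, ] <- Palt[k, ] + colSums(wb[src, , drop = FALSE])
    }
    Qnew <- Qnum / pmax(rowSums(Qnum), eps)
    Q[free, ] <- Qnew[free, , drop = FALSE]
    P <- (lambda - 1 + Palt) / (2 * (lambda - 1) + pmax(Ptot, eps))
    P <- pmin(pmax(P, eps), 1 - eps)
    ll <- admix_loglik_cpp(G, Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(Q = Q, P = P, lnL_trace = trace, alpha = NA_real_)
}

new_ancestry_fit <- function(K, Q, P, alpha, lnL_trace, burn_in, method, ids) {
  rownames(Q) <- ids
  colnames(Q) <- paste0("cluster", seq_len(K))
  rownames(P) <- paste0("cluster", seq_len(K))
  post <- if (method == "gibbs") lnL_trace[-seq_len(burn_in)] else lnL_trace
  post <- post[!is.na(post)]
  lnP <- if (method == "gibbs" && length(post) > 1) {
    mean(post) - var(post) / 2          # harmonic-style evidence estimate
  } else {
    post[length(post)]
  }
  structure(list(K = K, Q = Q, P = P, alpha = alpha,
                 lnP_data = lnP, lnL_trace = lnL_trace, method = method),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, %d individuals, %d loci (%s)\n",
              x$K, nrow(x$Q), ncol(x$P), x$method))
  cat(sprintf("  lnP(data) = %.2f, alpha = %s\n", x$lnP_data,
              format(x$alpha, digits = 3)))
  invisible(x)
}

# order clusters by descending total ancestry mass for stable output
canonicalize_clusters <- function(fit) {
  ord <- order(colSums(fit$Q), decreasing = TRUE)
  fit$Q <- fit$Q[, ord, drop = FALSE]
  fit$P <- fit$P[ord, , drop = FALSE]
  colnames(fit$Q) <- paste0("cluster", seq_len(fit$K))
  rownames(fit$P) <- colnames(fit$Q)
  fit
}

#' Unsupervised admixture-model fit
#'
#' Gibbs sampler over latent allele origins: each allele copy is assigned to
#' a cluster with probability proportional to `Q_ik * P(allele | k)`; cluster
#' frequencies are redrawn from `Beta(lambda + alt, lambda + ref)`, ancestry
#' rows from `Dirichlet(alpha + origin counts)`, and the shared concentration
#' alpha by a Metropolis step under a uniform(0, 10) prior.  Posterior means
#' of Q and P are taken over post-burn-in sweeps and clusters are ordered by
#' descending total ancestry.  `method = "em"` runs the deterministic MAP
#' counterpart instead.
#'
#' @param m a filtered [snp_matrix()].
#' @param K number of clusters (>= 1).
#' @param cfg a [run_config()].
#' @param chain replicate index; offsets the RNG stream.
#' @return An `ancestry_fit` with elements `K`, `Q`, `P`, `alpha`,
#'   `lnP_data` (mean minus half-variance of the post-burn-in log-likelihood
#'   trace) and `lnL_trace`.
#' @export
fit_unsupervised <- function(m, K, cfg = run_config(), chain = 1L) {
  G <- if (inherits(m, "snp_matrix")) m$calls else m
  ids <- if (inherits(m, "snp_matrix")) m$individuals$id else rownames(G)
  if (K > nrow(G)) stop("K exceeds the number of individuals")
  set.seed(cfg$seed + 1000L * K + chain)
  if (cfg$method == "em") {
    res <- admix_em(G, K, lambda = cfg$lambda, maxit = cfg$em_maxit,
                    tol = cfg$em_tol)
    alpha <- NA_real_
  } else {
    res <- admix_gibbs_cpp(G, K, cfg$burn_in, cfg$reps, cfg$lambda,
                           cfg$infer_alpha && K > 1, cfg$alpha,
                           rep(-1L, nrow(G)), rep(TRUE, nrow(G)),
                           cfg$alpha_prop_sd, cfg$alpha_max, cfg$ll_thin)
    alpha <- mean(res$alpha_trace[-seq_len(cfg$burn_in)])
  }
  if (K == 1L) res$Q[] <- 1
  fit <- new_ancestry_fit(K, res$Q, res$P, alpha, res$lnL_trace,
                          cfg$burn_in, cfg$method, ids)
  canonicalize_clusters(fit)
}

#' Population prior for supervised ancestry inference
#'
#' @param labels per-individual predefined population index (1..K) or NA.
#' @param flags logical; TRUE marks individuals used both as fixed-ancestry
#'   members of their population and as the sole source of its allele
#'   frequencies.  Defaults to every labeled individual.
#' @return A list of class `pop_prior`.
#' @export
pop_prior <- function(labels, flags = !is.na(labels)) {
  labels <- as.integer(labels)
  if (any(flags & is.na(labels))) stop("flagged individuals must be labeled")
  structure(list(labels = labels, flags = flags), class = "pop_prior")
}

#' Supervised admixture-model fit with fixed source frequencies
#'
#' Flagged individuals are pinned to the indicator ancestry of their
#' predefined population (zero migration prior) and are the only ones whose
#' allele origins update the cluster frequencies; unlabeled individuals
#' receive admixture-model ancestry against those frequencies.
#'
#' @param m a filtered [snp_matrix()].
#' @param K number of clusters; population labels must lie in 1..K.
#' @param prior a [pop_prior()].
#' @param cfg a [run_config()].
#' @param chain replicate index.
#' @return An `ancestry_fit`; clusters stay in population-label order.
#' @export
fit_supervised <- function(m, K, prior, cfg = run_config(), chain = 1L) {
  G <- if (inherits(m, "snp_matrix")) m$calls else m
  ids <- if (inherits(m, "snp_matrix")) m$individuals$id else rownames(G)
  labs <- prior$labels
  if (any(!is.na(labs) & (labs < 1L | labs > K)))
    stop("population labels must lie in 1..K")
  for (k in seq_len(K)) {
    if (!any(prior$flags & !is.na(labs) & labs == k))
      stop("predefined population ", k, " has no flagged individual")
  }
  fixed <- ifelse(prior$flags, labs, NA_integer_)
  set.seed(cfg$seed + 1000L * K + chain)
  if (cfg$method == "em") {
    res <- admix_em(G, K, lambda = cfg$lambda, maxit = cfg$em_maxit,
                    tol = cfg$em_tol, fixed_pop = fixed,
                    freq_source = prior$flags)
    alpha <- NA_real_
  } else {
    res <- admix_gibbs_cpp(G, K, cfg$burn_in, cfg$reps, cfg$lambda,
                           cfg$infer_alpha && K > 1, cfg$alpha,
                           ifelse(is.na(fixed), -1L, fixed - 1L),
                           prior$flags, cfg$alpha_prop_sd, cfg$alpha_max,
                           cfg$ll_thin)
    alpha <- mean(res$alpha_trace[-seq_len(cfg$burn_in)])
  }
  new_ancestry_fit(K, res$Q, res$P, alpha, res$lnL_trace,
                   cfg$burn_in, cfg$method, ids)
}

#' Replicate admixture runs over a K grid
#'
#' @param m a filtered [snp_matrix()].
#' @param cfg a [run_config()]; `K_range` and `n_chains` define the grid.
#' @param keep_fits keep every `ancestry_fit` (memory-heavy) or only the
#'   log-evidence table.
#' @return A list with `lnP` (data.frame of K, chain, lnP_data) and, when
#'   requested, `fits` (list indexed by "K<k>.chain<c>").
#' @export
fit_replicates <- function(m, cfg = run_config(), keep_fits = TRUE) {
  rows <- expand.grid(chain = seq_len(cfg$n_chains), K = cfg$K_range)
  fits <- list()
  lnp <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    K <- rows$K[r]; ch <- rows$chain[r]
    fit <- fit_unsupervised(m, K, cfg, chain = ch)
    lnp[r] <- fit$lnP_data
    if (keep_fits) fits[[sprintf("K%d.chain%d", K, ch)]] <- fit
  }
  out <- list(lnP = data.frame(K = rows$K, chain = rows$chain,
                               lnP_data = lnp))
  if (keep_fits) out$fits <- fits
  out
}

#' Evanno delta-K model selection
#'
#' Given replicate log-evidence estimates per K on a contiguous grid,
#' computes L(K) = mean over replicates, L'(K) = L(K) - L(K-1),
#' |L''(K)| = |L(K+1) - 2 L(K) + L(K-1)| and delta-K = |L''(K)| / sd(L(K)).
#' The optimum is the interior K maximizing delta-K.
#'
#' @param runs data.frame with columns `K` and `lnP_data` (one row per
#'   replicate), e.g. `fit_replicates(...)$lnP`.
#' @return A list of class `evanno_result`: per-K table (`mean_L`, `sd_L`,
#'   `Lp`, `Lpp_abs`, `deltaK`) and `optimal_K`.
#' @export
evanno <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs) && !is.null(runs$lnP))
    runs <- runs$lnP
  Ks <- sort(unique(runs$K))
  if (length(Ks) >= 2 && any(diff(Ks) != 1L)) stop("K grid must be contiguous")
  reps <- table(runs$K)
  if (any(reps < 3)) stop("need >= 3 replicates per K for Evanno delta-K")
  mean_L <- tapply(runs$lnP_data, runs$K, mean)[as.character(Ks)]
  sd_L <- tapply(runs$lnP_data, runs$K, sd)[as.character(Ks)]
  nK <- length(Ks)
  Lp <- c(NA, diff(mean_L))
  Lpp <- rep(NA_real_, nK)
  if (nK >= 3) {
    for (j in 2:(nK - 1)) Lpp[j] <- abs(mean_L[j + 1] - 2 * mean_L[j] + mean_L[j - 1])
  }
  deltaK <- ifelse(!is.na(Lpp) & sd_L > 0, Lpp / sd_L, NA_real_)
  tab <- data.frame(K = Ks, mean_L = as.numeric(mean_L),
                    sd_L = as.numeric(sd_L), Lp = as.numeric(Lp),
                    Lpp_abs = Lpp, deltaK = deltaK)
  if (all(is.na(deltaK)))
    stop("delta-K undefined at every K (zero replicate variance); ",
         "inspect mean lnP(data) directly")
  optimal_K <- Ks[which.max(deltaK)]
  structure(list(table = tab, optimal_K = optimal_K),
            class = "evanno_result")
}

#' @export
print.evanno_result <- function(x, ...) {
  cat("Evanno delta-K model selection\n")
  print(x$table, row.names = FALSE)
  cat("optimal K =", x$optimal_K, "\n")
  invisible(x)
}

#' Match clusters of one fit to a reference by greedy maximum shared Q
#'
#' Admixture clusters are exchangeable; for reporting, the columns of `fit`
#' are permuted to best match `ref` (greedy assignment maximizing the summed
#' shared ancestry mass of each matched pair over common individuals).
#'
#' @param fit an `ancestry_fit` (or bare Q matrix with rownames).
#' @param ref reference `ancestry_fit` or Q matrix; must overlap in
#'   individuals and have at least as many clusters.
#' @return `fit` with permuted clusters (or the permuted Q matrix).
#' @export
match_clusters <- function(fit, ref) {
  Qf <- if (inherits(fit, "ancestry_fit")) fit$Q else as.matrix(fit)
  Qr <- if (inherits(ref, "ancestry_fit")) ref$Q else as.matrix(ref)
  common <- intersect(rownames(Qf), rownames(Qr))
  if (!length(common)) stop("no overlapping individuals to match on")
  A <- crossprod(Qf[common, , drop = FALSE],
                 Qr[common, , drop = FALSE])  # K_f x K_r shared mass proxy
  Kf <- ncol(Qf)
  perm <- integer(Kf)
  used_ref <- logical(ncol(Qr))
  done_fit <- logical(Kf)
  for (step in seq_len(Kf)) {
    A2 <- A
    A2[done_fit, ] <- -Inf
    A2[, used_ref] <- -Inf
    best <- which(A2 == max(A2), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    used_ref[best[2]] <- TRUE
    done_fit[best[1]] <- TRUE
  }
  ord <- order(perm)
  if (inherits(fit, "ancestry_fit")) {
    fit$Q <- fit$Q[, ord, drop = FALSE]
    fit$P <- fit$P[ord, , drop = FALSE]
    colnames(fit$Q) <- paste0("cluster", seq_len(Kf))
    rownames(fit$P) <- colnames(fit$Q)
    fit
  } else {
    Qf[, ord, drop = FALSE]
  }
}

#' Write a Q matrix as TSV
#'
#' @param fit an `ancestry_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(fit, path) {
  df <- data.frame(id = rownames(fit$Q), fit$Q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
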