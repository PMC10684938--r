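#' Per-group allele frequencies, sample sizes and observed heterozygosity
#'
#' The substrate of the diversity statistics: for every group and locus, the
#' number of diploid individuals with a call (`n`), the alt-allele frequency
#' (`p`) and the observed heterozygote fraction (`Ho`), all over non-missing
#' calls.
#'
#' @param m a [snp_matrix()].
#' @param grouping group label per individual (NA excludes an individual).
#' @return A list of class `grouped_freqs` with `groups` (level names) and
#'   matrices `n`, `p`, `Ho` of shape groups x loci.
#' @export
group_freqs <- function(m, grouping) {
  G <- if (inherits(m, "snp_matrix")) m$calls else as.matrix(m)
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 1) stop("no groups supplied")
  if (any(table(grouping) == 0)) stop("empty group in grouping factor")
  levs <- levels(grouping)
  L <- ncol(G)
  n <- p <- Ho <- matrix(0, length(levs), L,
                         dimnames = list(levs, NULL))
  for (s in seq_along(levs)) {
    sub <- G[which(grouping == levs[s]), , drop = FALSE]
    called <- colSums(!is.na(sub))
    n[s, ] <- called
    p[s, ] <- ifelse(called > 0, colSums(sub, na.rm = TRUE) / (2 * called), NA)
    Ho[s, ] <- ifelse(called > 0,
                      colSums(sub == 1L, na.rm = TRUE) / called, NA)
  }
  structure(list(groups = levs, n = n, p = p, Ho = Ho),
            class = "grouped_freqs")
}

#' Sample-size-corrected heterozygosity components at one locus
#'
#' Harmonic-mean (Nei/Chesser-style) estimators: with `ntilde` the harmonic
#' mean of per-group sample sizes and `S` groups,
#' `Ho = mean_s Ho_s`,
#' `Hs = ntilde/(ntilde-1) * (1 - mean_s sum_a p_sa^2 - Ho/(2 ntilde))`,
#' `Ht = 1 - sum_a pbar_a^2 + Hs/(ntilde S) - Ho/(2 ntilde S)`.
#'
#' @param gf a [group_freqs()] object.
#' @param locus locus index.
#' @param groups subset of group names to use (default all).
#' @return Named numeric vector `c(Ho, Hs, Ht)`, or NULL when fewer than two
#'   groups have calls or the harmonic-mean sample size is <= 1.
#' @export
nei_components <- function(gf, locus, groups = gf$groups) {
  gsel <- match(groups, gf$groups)
  n <- gf$n[gsel, locus]
  ok <- n >= 1
  if (sum(ok) < 2) return(NULL)
  n <- n[ok]
  p <- gf$p[gsel[ok], locus]
  ho <- gf$Ho[gsel[ok], locus]
  S <- length(n)
  ntilde <- S / sum(1 / n)
  if (ntilde <= 1) return(NULL)
  Ho <- mean(ho)
  sum_p2 <- mean(p^2 + (1 - p)^2)
  Hs <- (ntilde / (ntilde - 1)) * (1 - sum_p2 - Ho / (2 * ntilde))
  pbar <- mean(p)
  Ht <- 1 - (pbar^2 + (1 - pbar)^2) + Hs / (ntilde * S) - Ho / (2 * ntilde * S)
  c(Ho = Ho, Hs = Hs, Ht = Ht)
}

mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n_loci = length(x))
}

#' Sample-size-corrected gene diversity per group
#'
#' Per locus and group, `D = (2n/(2n-1)) * (1 - p^2 - (1-p)^2)` (unbiased
#' expected heterozygosity), then mean and standard error across loci.
#'
#' @param gf a [group_freqs()] object.
#' @return data.frame with one row per group: `group`, `D`, `se`, `n_loci`.
#' @export
gene_diversity <- function(gf) {
  out <- lapply(seq_along(gf$groups), function(s) {
    n <- gf$n[s, ]; p <- gf$p[s, ]
    ok <- n >= 1
    d <- (2 * n[ok] / (2 * n[ok] - 1)) * (1 - p[ok]^2 - (1 - p[ok])^2)
    ms <- mean_se(d)
    data.frame(group = gf$groups[s], D = ms["mean"], se = ms["se"],
               n_loci = ms["n_loci"], row.names = NULL)
  })
  do.call(rbind, out)
}

#' Multi-locus F-statistics with sample-size correction
#'
#' Per locus, `F_ST = 1 - Hs/Ht` and `F_IS = 1 - Ho/Hs` from
#' [nei_components()]; means and standard errors are taken across loci,
#' excluding loci where a statistic is undefined (e.g. `Hs = 0` for F_IS).
#' Per-group F_ST (differentiation of one subpopulation from the total) is
#' `1 - Hs_group/Ht_total` with `Ht` from the pooled set of all groups, and
#' per-group F_IS is `1 - Ho_group/Hs_group` within the group.
#'
#' @param gf a [group_freqs()] object (>= 2 groups for F_ST).
#' @return A list of class `diversity_result`: `overall` (data.frame with
#'   rows F_ST and F_IS: mean, se, n_loci), `per_group` (data.frame with
#'   per-group D, F_ST, F_IS and their SEs), `per_locus` (list of raw
#'   vectors).
#' @export
f_statistics <- function(gf) {
  L <- ncol(gf$n)
  S <- length(gf$groups)
  fst <- fis <- rep(NA_real_, L)
  ht_tot <- hs_by_group <- NULL
  comp <- vector("list", L)
  for (l in seq_len(L)) {
    nc <- nei_components(gf, l)
    comp[[l]] <- nc
    if (is.null(nc)) next
    if (nc[["Ht"]] > 0) fst[l] <- 1 - nc[["Hs"]] / nc[["Ht"]]
    if (nc[["Hs"]] > 0) fis[l] <- 1 - nc[["Ho"]] / nc[["Hs"]]
  }
  overall <- rbind(F_ST = mean_se(fst), F_IS = mean_se(fis))
  overall <- data.frame(statistic = rownames(overall), overall,
                        row.names = NULL)
  # multilocus (ratio-of-locus-means) estimators: unbiased for the
  # generating divergence even when per-locus ratios are noisy
  ho_v <- vapply(comp, function(nc) if (is.null(nc)) NA_real_ else nc[["Ho"]], 0)
  hs_v <- vapply(comp, function(nc) if (is.null(nc)) NA_real_ else nc[["Hs"]], 0)
  ht_v <- vapply(comp, function(nc) if (is.null(nc)) NA_real_ else nc[["Ht"]], 0)
  multilocus <- c(F_ST = 1 - mean(hs_v, na.rm = TRUE) / mean(ht_v, na.rm = TRUE),
                  F_IS = 1 - mean(ho_v, na.rm = TRUE) / mean(hs_v, na.rm = TRUE))

  # per-group statistics against the pooled total
  per_group <- lapply(seq_len(S), function(s) {
    fst_g <- fis_g <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      nc <- comp[[l]]
      if (is.null(nc)) next
      n_g <- gf$n[s, l]
      if (n_g < 2) next
      p_g <- gf$p[s, l]; ho_g <- gf$Ho[s, l]
      # within-group gene diversity, sample-size corrected
      hs_g <- (n_g / (n_g - 1)) *
        (1 - p_g^2 - (1 - p_g)^2 - ho_g / (2 * n_g))
      if (nc[["Ht"]] > 0) fst_g[l] <- 1 - hs_g / nc[["Ht"]]
      if (hs_g > 0) fis_g[l] <- 1 - ho_g / hs_g
    }
    st <- mean_se(fst_g); si <- mean_se(fis_g)
    data.frame(group = gf$groups[s],
               F_ST = st["mean"], F_ST_se = st["se"],
               F_IS = si["mean"], F_IS_se = si["se"],
               n_loci = st["n_loci"], row.names = NULL)
  })
  per_group <- do.call(rbind, per_group)
  D <- gene_diversity(gf)
  per_group <- merge(D, per_group, by = "group", sort = FALSE)
  structure(list(overall = overall, multilocus = multilocus,
                 per_group = per_group,
                 per_locus = list(F_ST = fst, F_IS = fis)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Multi-locus F-statistics (mean +/- SE across loci)\n")
  print(x$overall, row.names = FALSE)
  cat("\nPer-group statistics vs the pooled total\n")
  print(x$per_group, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Jost's D between two groups
#'
#' Per locus, `D = ((Ht - Hs)/(1 - Hs)) * S/(S - 1)` with `S = 2` and the
#' sample-size-corrected `Hs`, `Ht` of [nei_components()]; the mean and
#' standard error are taken across loci.  Negative per-locus values from
#' sampling noise are retained (not clamped).
#'
#' @param gf a [group_freqs()] object.
#' @param pair character or integer vector of exactly two groups.
#' @return Named vector `c(mean, se, n_loci)`.
#' @export
jost_d <- function(gf, pair) {
  if (length(pair) != 2) stop("pair must name exactly 2 groups")
  if (is.numeric(pair)) pair <- gf$groups[pair]
  L <- ncol(gf$n)
  d <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    nc <- nei_components(gf, l, groups = pair)
    if (is.null(nc) || nc[["Hs"]] >= 1) next
    d[l] <- (nc[["Ht"]] - nc[["Hs"]]) / (1 - nc[["Hs"]]) * 2
  }
  mean_se(d)
}

#' Pairwise Jost's D matrix across all groups
#'
#' @param gf a [group_freqs()] object.
#' @return A list of class `jost_d_matrix` with symmetric matrices `mean`
#'   and `se` (diagonal 0).
#' @export
jost_d_matrix <- function(gf) {
  S <- length(gf$groups)
  m <- se <- matrix(0, S, S, dimnames = list(gf$groups, gf$groups))
  for (a in seq_len(S - 1)) {
    for (b in (a + 1):S) {
      res <- jost_d(gf, c(gf$groups[a], gf$groups[b]))
      m[a, b] <- m[b, a] <- res[["mean"]]
      se[a, b] <- se[b, a] <- res[["se"]]
    }
  }
  structure(list(mean = m, se = se), class = "jost_d_matrix")
}

#' @export
print.jost_d_matrix <- function(x, ...) {
  cat("Pairwise Jost's D (mean across loci)\n")
  print(round(x$mean, 4))
  invisible(x)
}
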