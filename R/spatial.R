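#' Great-circle distance between coordinate pairs
#'
#' Haversine formula with Earth radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; vectors recycle.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

geo_dist_matrix <- function(lat, lon, ids = NULL) {
  n <- length(lat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  (d + t(d)) / 2
}

#' Minimum-spanning connectivity network of collection sites
#'
#' Kruskal's algorithm on pairwise great-circle distances; ties are broken by
#' the lexicographic (site id, site id) pair so the tree is deterministic.
#' The adjacency is row-normalized into the spatial weight matrix used for
#' lagged scores.
#'
#' @param sites data.frame with columns `site_id`, `lat`, `lon` (e.g. the
#'   `sites` component of [pool_by_site()]).
#' @return A list of class `site_graph`: `sites`, `edges` (data.frame
#'   `from`, `to`, `km`), `adjacency` (0/1 symmetric), `W` (row-normalized
#'   weights).
#' @export
build_mst <- function(sites) {
  n <- nrow(sites)
  if (n < 2) stop("need at least 2 sites")
  ids <- as.character(sites$site_id)
  d <- geo_dist_matrix(sites$lat, sites$lon, ids)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ed <- data.frame(i = pairs[, 1], j = pairs[, 2], km = d[pairs])
  a <- pmin(ids[ed$i], ids[ed$j]); b <- pmax(ids[ed$i], ids[ed$j])
  ed <- ed[order(ed$km, a, b), ]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    ri <- find(ed$i[r]); rj <- find(ed$j[r])
    if (ri != rj) { parent[ri] <- rj; keep[r] <- TRUE }
  }
  ed <- ed[keep, , drop = FALSE]
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  adj[cbind(ed$i, ed$j)] <- 1
  adj[cbind(ed$j, ed$i)] <- 1
  W <- adj / rowSums(adj)
  structure(list(sites = sites,
                 edges = data.frame(from = ids[ed$i], to = ids[ed$j],
                                    km = ed$km, stringsAsFactors = FALSE),
                 adjacency = adj, W = W),
            class = "site_graph")
}

#' @export
print.site_graph <- function(x, ...) {
  cat(sprintf("site_graph: %d sites, %d edges, total length %.1f km\n",
              nrow(x$sites), nrow(x$edges), sum(x$edges$km)))
  invisible(x)
}

#' Export a site graph as GraphML
#'
#' @param g a [build_mst()] graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  ig <- igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = data.frame(name = as.character(g$sites$site_id),
                          lat = g$sites$lat, lon = g$sites$lon))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Spatial principal component analysis of site allele frequencies
#'
#' Columns of the site x locus frequency matrix are centered (missing values
#' mean-imputed); with the symmetrized weight matrix Omega = (W + W')/2 the
#' axes are eigenvectors of (1/n) X' Omega X, so each eigenvalue is the
#' product of the score variance and a Moran-type spatial autocorrelation.
#' Positive eigenvalues capture global (cline-like) structure.  Lagged
#' scores are the row-normalized-neighborhood averages `W %*% scores`.
#'
#' @param f a `site_freq_matrix` from [pool_by_site()] or a plain sites x
#'   loci matrix.
#' @param g a [build_mst()] graph over the same sites (same row order).
#' @param n_retain number of leading positive axes to keep.
#' @return A list of class `spca_result`: `eigenvalues` (all, descending),
#'   `scores`, `lagged_scores`, `var_component`, `moran_component`,
#'   `n_retained`.
#' @export
spca <- function(f, g, n_retain = 2L) {
  X <- if (inherits(f, "site_freq_matrix")) f$freq else as.matrix(f)
  n <- nrow(X)
  if (n != nrow(g$W)) stop("frequency rows do not match graph nodes")
  if (any(rowSums(g$adjacency) == 0)) stop("graph is disconnected")
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1) %/% n + 1]
  Xc <- sweep(X, 2, cm)
  Omega <- (g$W + t(g$W)) / 2
  M <- crossprod(Xc, Omega %*% Xc) / n
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  vals <- eg$values
  n_pos <- sum(vals > max(abs(vals)) * 1e-10)
  n_retain <- min(n_retain, max(n_pos, 0L))
  axes <- eg$vectors[, seq_len(max(n_retain, 1L)), drop = FALSE]
  scores <- Xc %*% axes[, seq_len(n_retain), drop = FALSE]
  lagged <- g$W %*% scores
  ids <- as.character(g$sites$site_id)
  if (length(ids) == n) rownames(scores) <- rownames(lagged) <- ids
  var_comp <- apply(scores, 2, function(s) sum(s^2) / n)
  moran <- apply(scores, 2, function(s)
    as.numeric(crossprod(s, Omega %*% s) / crossprod(s)))
  structure(list(eigenvalues = vals, scores = scores,
                 lagged_scores = lagged, var_component = var_comp,
                 moran_component = moran, n_retained = n_retain),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat(sprintf("spca_result: %d retained axes of %d sites\n",
              x$n_retained, nrow(x$scores)))
  ev <- x$eigenvalues
  pos <- ev[ev > 0]
  cat("  leading eigenvalues:",
      paste(sprintf("%.4g", head(pos, 4)), collapse = ", "), "\n")
  if (x$n_retained)
    cat("  variance share of retained axes:",
        paste(sprintf("%.1f%%", 100 * pos[seq_len(x$n_retained)] / sum(abs(ev))),
              collapse = ", "), "\n")
  invisible(x)
}

#' Geographic thinning of accessions
#'
#' Greedy scan in stable id order keeping an accession iff its coordinates
#' lie at least `min_km` from every previously kept accession.  Both
#' individuals of an accession are kept or dropped together (the accession is
#' the sampling unit).
#'
#' @param individuals data.frame with `id`, `accession`, `lat`, `lon`.
#' @param min_km minimum pairwise distance among kept accessions.
#' @return Character vector of kept individual ids.
#' @export
geo_thin <- function(individuals, min_km = 25) {
  ind <- individuals[!is.na(individuals$lat) & !is.na(individuals$lon), ]
  acc <- ind$accession
  if (all(is.na(acc))) acc <- ind$id
  first <- !duplicated(acc)
  units <- data.frame(accession = acc[first], lat = ind$lat[first],
                      lon = ind$lon[first], stringsAsFactors = FALSE)
  units <- units[order(units$accession), ]
  kept_lat <- numeric(0); kept_lon <- numeric(0)
  kept <- character(0)
  for (r in seq_len(nrow(units))) {
    if (!length(kept) ||
        all(haversine_km(units$lat[r], units$lon[r], kept_lat, kept_lon) >= min_km)) {
      kept <- c(kept, units$accession[r])
      kept_lat <- c(kept_lat, units$lat[r])
      kept_lon <- c(kept_lon, units$lon[r])
    }
  }
  ind$id[acc %in% kept]
}

#' Coefficient of determination between ancestry and geography
#'
#' Regresses each coordinate on the K - 1 free ancestry components (the full
#' Q matrix is collinear) and reports the regression r-squared.
#'
#' @param Q N x K ancestry matrix (rows sum to 1, K >= 2).
#' @param coords data.frame or matrix with columns `lat` and `lon` (either
#'   may be absent).
#' @return Named numeric vector of r-squared values per coordinate.
#' @export
geo_correlation <- function(Q, coords) {
  Q <- as.matrix(Q)
  K <- ncol(Q)
  if (K < 2) stop("need K >= 2 ancestry components")
  coords <- as.data.frame(coords)
  if (nrow(coords) != nrow(Q)) stop("coordinate rows do not match Q")
  if (nrow(Q) < K + 1) stop("need more individuals than ancestry components")
  X <- Q[, -K, drop = FALSE]
  out <- c()
  for (col in intersect(c("lat", "lon"), names(coords))) {
    y <- coords[[col]]
    ok <- !is.na(y)
    fit <- stats::lm(y[ok] ~ X[ok, , drop = FALSE])
    out[col] <- summary(fit)$r.squared
  }
  out
}
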