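#' Identity-by-state genetic distance
#'
#' For each pair of individuals, with per-locus allele dose `p = dosage/2`,
#' the per-locus distance is `p_i (1 - p_j) + (1 - p_i) p_j` — the
#' probability that one allele drawn from each individual differs — averaged
#' over loci where both have calls.
#'
#' @param m a [snp_matrix()] with >= 2 individuals.
#' @return A symmetric `dist`-free numeric matrix with zero diagonal and
#'   individual ids as dimnames; entries are NA for pairs with no shared
#'   loci.
#' @export
ibs_distance <- function(m) {
  G <- if (inherits(m, "snp_matrix")) m$calls else as.matrix(m)
  ids <- if (inherits(m, "snp_matrix")) m$individuals$id else rownames(G)
  if (nrow(G) < 2) stop("need >= 2 individuals")
  A <- G / 2
  M <- !is.na(A)
  A0 <- ifelse(M, A, 0)
  shared <- M %*% t(M)
  # sum over shared loci of p_i + p_j - 2 p_i p_j
  cross <- A0 %*% t(A0)
  si <- A0 %*% t(M)     # sum of p_i over loci where j called
  d <- (si + t(si) - 2 * cross) / shared
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

# Move the deficit of a clamped negative branch to its sibling/parent edge,
# preserving leaf-to-leaf path lengths through the affected node as far as
# the tree allows.
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(tree$edge.length) != e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- max(0, tree$edge.length[sibs[1]] + deficit)
    }
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (ape's implementation); negative branch lengths
#' are clamped to zero with the deficit moved to a sibling branch.
#'
#' @param d symmetric distance matrix with zero diagonal (e.g.
#'   [ibs_distance()]).
#' @return An [ape::nj()] `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (anyNA(d)) stop("distance matrix has missing entries; NJ needs a complete matrix")
  if (nrow(d) < 3) stop("need >= 3 taxa")
  tree <- ape::nj(as.dist(d))
  clamp_negative_branches(tree)
}

#' Root a tree at the candidate in the maximum observed pairwise distance
#'
#' Scans the distance matrix for the globally maximal entry among pairs that
#' involve at least one candidate leaf (typically outgroup-species
#' individuals); the tree is rooted on that leaf's pendant edge.  Ties are
#' broken by the lexicographically smaller id.
#'
#' @param tree a `phylo` tree.
#' @param d the distance matrix the tree was built from.
#' @param candidates character vector of candidate leaf ids.
#' @return A rooted `phylo` tree; the chosen leaf is attached as attribute
#'   `"root_leaf"`.
#' @export
root_at_max_distance <- function(tree, d, candidates) {
  if (!length(candidates)) stop("no root candidates supplied")
  d <- as.matrix(d)
  if (!all(candidates %in% rownames(d))) stop("candidate not in distance matrix")
  sub <- d[candidates, , drop = FALSE]
  mx <- max(sub, na.rm = TRUE)
  hits <- which(sub == mx, arr.ind = TRUE)
  leaf <- sort(candidates[hits[, 1]])[1]
  rooted <- ape::root(tree, outgroup = leaf, resolve.root = TRUE)
  attr(rooted, "root_leaf") <- leaf
  rooted
}

#' Collapse identical plastid SSR haplotypes
#'
#' Groups identical allele-size vectors over the SSR loci; individuals with
#' any missing call must be excluded beforehand.
#'
#' @param s an [ssr_table()] with no missing calls.
#' @param groups optional per-individual nuclear group labels used for the
#'   node composition annotation.
#' @return A list of class `haplo_nodes`: `haplotypes` (unique allele
#'   matrix), `count` (carriers per node), `members` (list of ids),
#'   `composition` (node x group count matrix or NULL).
#' @export
collapse_haplotypes <- function(s, groups = NULL) {
  if (anyNA(s$alleles))
    stop("SSR table has missing calls; drop those individuals first")
  key <- apply(s$alleles, 1, paste, collapse = "_")
  uniq <- unique(key)
  idx <- match(key, uniq)
  members <- split(s$ids, idx)
  names(members) <- paste0("H", seq_along(uniq))
  hap <- s$alleles[match(uniq, key), , drop = FALSE]
  rownames(hap) <- names(members)
  colnames(hap) <- s$loci
  comp <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    comp <- t(vapply(seq_along(uniq), function(h)
      as.numeric(table(groups[idx == h])), numeric(nlevels(groups))))
    dimnames(comp) <- list(names(members), levels(groups))
  }
  structure(list(haplotypes = hap,
                 count = lengths(members),
                 members = members,
                 composition = comp),
            class = "haplo_nodes")
}

#' SSR haplotype distance: number of differing loci
#'
#' @param hap unique-haplotype allele matrix (nodes x loci).
#' @param method `"loci"` counts differing loci; `"steps"` sums absolute
#'   repeat-size differences.
#' @return Symmetric integer matrix.
#' @export
haplotype_distance <- function(hap, method = c("loci", "steps")) {
  method <- match.arg(method)
  n <- nrow(hap)
  d <- matrix(0L, n, n, dimnames = list(rownames(hap), rownames(hap)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- if (method == "loci") sum(hap[i, ] != hap[j, ])
            else sum(abs(hap[i, ] - hap[j, ]))
      d[i, j] <- d[j, i] <- as.integer(dd)
    }
  }
  d
}

#' Minimum-spanning network over haplotype nodes
#'
#' The edge set is the union of all minimum spanning trees: an edge (u, v)
#' of weight w belongs to some MST iff u and v lie in different connected
#' components of the graph restricted to edges of weight < w.  Tied edges at
#' the joining threshold are therefore all retained.
#'
#' @param nodes a [collapse_haplotypes()] result (or a plain haplotype
#'   matrix).
#' @param method distance flavour passed to [haplotype_distance()].
#' @return A list of class `haplo_network`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `d`), `distance` matrix.
#' @export
msn <- function(nodes, method = c("loci", "steps")) {
  hap <- if (inherits(nodes, "haplo_nodes")) nodes$haplotypes else as.matrix(nodes)
  if (nrow(hap) < 2) stop("need >= 2 haplotype nodes")
  d <- haplotype_distance(hap, method = match.arg(method))
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    # components of the strictly-lighter subgraph
    lighter <- pairs[w < w[r], , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nrow(lighter)) {
      for (q in seq_len(nrow(lighter))) {
        a <- find(lighter[q, 1]); b <- find(lighter[q, 2])
        if (a != b) parent[a] <- b
      }
    }
    keep[r] <- find(pairs[r, 1]) != find(pairs[r, 2])
  }
  ids <- rownames(d)
  edges <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                      d = w[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, distance = d),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  nn <- if (inherits(x$nodes, "haplo_nodes")) length(x$nodes$count)
        else nrow(x$distance)
  cat(sprintf("haplo_network: %d haplotype nodes, %d minimum-spanning edges\n",
              nn, nrow(x$edges)))
  invisible(x)
}

#' Write a distance matrix as square TSV or PHYLIP
#'
#' @param d symmetric distance matrix.
#' @param path output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  d <- as.matrix(d)
  if (format == "tsv") {
    utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(formatC(rownames(d)[i], width = -10),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
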