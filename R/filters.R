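#' Genotype filter parameters
#'
#' Defaults mirror the standard post-calling cascade for RAD-seq rice panels:
#' retain the two most common alleles per record, cap the per-site
#' heterozygous fraction at 0.5, mask calls whose total allelic depth lies
#' outside \[7, 400\], require minor allele frequency >= 0.01 and calls at
#' >= 66\% of individuals, drop individuals with > 40\% missing calls, and
#' (for spatial analyses) thin sites to >= 100 bp spacing.
#'
#' @param max_het_fraction maximum heterozygous fraction among non-missing
#'   calls at a site.
#' @param depth_min,depth_max bounds on total (ref + alt) read depth of an
#'   individual call; calls outside are masked missing.
#' @param maf_min minimum minor allele frequency.
#' @param site_presence_min minimum fraction of individuals with a call.
#' @param indiv_missing_max maximum per-individual missing fraction.
#' @param thin_bp minimum between-site spacing for [thin_sites()], or NULL.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(max_het_fraction = 0.5,
                          depth_min = 7L, depth_max = 400L,
                          maf_min = 0.01,
                          site_presence_min = 0.66,
                          indiv_missing_max = 0.40,
                          thin_bp = 100L) {
  props <- c(max_het_fraction, maf_min, site_presence_min, indiv_missing_max)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (depth_min > depth_max) stop("depth_min > depth_max")
  structure(list(max_het_fraction = max_het_fraction,
                 depth_min = as.integer(depth_min),
                 depth_max = as.integer(depth_max),
                 maf_min = maf_min,
                 site_presence_min = site_presence_min,
                 indiv_missing_max = indiv_missing_max,
                 thin_bp = thin_bp),
            class = "filter_params")
}

# Reduce multi-allelic records to their two most common alleles.  Calls
# carrying any other allele become missing; the retained pair is re-encoded
# as ref (more common) / alt with dosage counting the alt allele.
reduce_top2 <- function(m) {
  if (is.null(m$multi)) return(m)
  idx <- m$multi$idx
  for (r in seq_along(idx)) {
    j <- idx[r]
    a1 <- m$multi$a1[, r]; a2 <- m$multi$a2[, r]
    tab <- table(c(a1, a2))
    # two most common alleles; ties broken by the lower allele index
    ord <- order(-as.integer(tab), as.integer(names(tab)))
    keep <- as.integer(names(tab))[ord][seq_len(min(2L, length(tab)))]
    if (length(keep) == 1L) keep <- c(keep, setdiff(0:1, keep)[1])
    ok <- !is.na(a1) & a1 %in% keep & a2 %in% keep
    dose <- ifelse(ok, (a1 == keep[2]) + (a2 == keep[2]), NA_integer_)
    m$calls[, j] <- as.integer(dose)
    alleles <- c(m$sites$ref[j],
                 strsplit(m$sites$alt[j], ",", fixed = TRUE)[[1]])
    m$sites$ref[j] <- alleles[keep[1] + 1L]
    m$sites$alt[j] <- alleles[keep[2] + 1L]
  }
  m$multi <- NULL
  m
}

#' Apply the site-level filter cascade
#'
#' Filter order is fixed: (1) multi-allelic records are reduced to their two
#' most common alleles (other calls masked), (2) calls with total allelic
#' depth outside `[depth_min, depth_max]` are masked, then sites are dropped
#' when (3) the heterozygous fraction among remaining calls exceeds
#' `max_het_fraction`, (4) minor allele frequency falls below `maf_min`, or
#' (5) the fraction of individuals with a call falls below
#' `site_presence_min`.  Each dropped site is attributed to the first rule it
#' fails; the log is attached as attribute `"filter_log"`.
#'
#' @param m a [snp_matrix()].
#' @param p a [filter_params()].
#' @return The filtered `snp_matrix` (input is not modified).
#' @export
filter_sites <- function(m, p = filter_params()) {
  stopifnot(inherits(m, "snp_matrix"))
  m <- reduce_top2(m)
  if (!is.null(m$ref_depth)) {
    total <- m$ref_depth + m$alt_depth
    bad <- !is.na(total) & (total < p$depth_min | total > p$depth_max)
    m$calls[bad] <- NA_integer_
  }
  n <- nrow(m$calls)
  n_called <- colSums(!is.na(m$calls))
  het_frac <- colSums(m$calls == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  freq <- colSums(m$calls, na.rm = TRUE) / pmax(2L * n_called, 1L)
  maf <- pmin(freq, 1 - freq)
  presence <- n_called / n

  rule <- rep(NA_character_, ncol(m$calls))
  rule[is.na(rule) & n_called > 0 & het_frac > p$max_het_fraction] <- "het_fraction"
  rule[is.na(rule) & maf < p$maf_min] <- "maf"
  rule[is.na(rule) & presence < p$site_presence_min] <- "site_presence"
  keep <- is.na(rule)
  log <- data.frame(chrom = m$sites$chrom[!keep], pos = m$sites$pos[!keep],
                    rule = rule[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) warning("all sites removed by filters")
  out <- m[, keep]
  attr(out, "filter_log") <- log
  out
}

#' Drop individuals with excess missing calls
#'
#' @param m a [snp_matrix()].
#' @param p a [filter_params()]; individuals with missing fraction strictly
#'   greater than `indiv_missing_max` are removed.
#' @return Filtered `snp_matrix`; surviving order preserved.
#' @export
filter_individuals <- function(m, p = filter_params()) {
  miss <- rowMeans(is.na(m$calls))
  keep <- miss <= p$indiv_missing_max
  dropped <- m$individuals$id[!keep]
  out <- m[keep, ]
  attr(out, "dropped_individuals") <- dropped
  out
}

#' Thin sites to a minimum physical spacing
#'
#' Greedy left-to-right scan within each chromosome: a site is kept iff its
#' position is at least `min_bp` beyond the last kept position; the first
#' site of each chromosome is always kept.
#'
#' @param m a [snp_matrix()] with sites sorted by (chrom, pos).
#' @param min_bp minimum spacing in base pairs.
#' @return Thinned `snp_matrix`.
#' @export
thin_sites <- function(m, min_bp = 100L) {
  ord <- order(m$sites$chrom, m$sites$pos)
  if (!identical(ord, seq_along(ord))) m <- m[, ord]
  keep <- logical(ncol(m$calls))
  last_chrom <- NULL; last_pos <- -Inf
  for (j in seq_len(ncol(m$calls))) {
    ch <- m$sites$chrom[j]; pos <- m$sites$pos[j]
    if (!identical(ch, last_chrom) || pos - last_pos >= min_bp) {
      keep[j] <- TRUE
      last_chrom <- ch; last_pos <- pos
    }
  }
  m[, keep]
}

#' Pool genotypes by collection site and estimate allele frequencies
#'
#' Individuals sharing coordinates (after rounding to `digits` decimal
#' places) form one collection site; the alt-allele frequency per site and
#' locus is computed over non-missing calls.
#'
#' @param m a [snp_matrix()] whose individuals carry `lat`/`lon`.
#' @param digits coordinate rounding used to merge near-duplicate sites.
#' @return A list of class `site_freq_matrix` with components `freq` (sites x
#'   loci matrix, NA where a site has no calls), `sites` (data.frame with
#'   `site_id`, `lat`, `lon`, `n`), and `site_of` (per-individual site id,
#'   NA for individuals without coordinates).
#' @export
pool_by_site <- function(m, digits = 4) {
  lat <- round(m$individuals$lat, digits)
  lon <- round(m$individuals$lon, digits)
  has <- !is.na(lat) & !is.na(lon)
  if (any(!has))
    warning(sum(!has), " individuals without coordinates excluded from pooling")
  key <- ifelse(has, paste(lat, lon, sep = "_"), NA_character_)
  uniq <- unique(key[has])
  site_of <- match(key, uniq)
  nloc <- ncol(m$calls)
  freq <- matrix(NA_real_, length(uniq), nloc)
  nvec <- integer(length(uniq))
  slat <- numeric(length(uniq)); slon <- numeric(length(uniq))
  for (s in seq_along(uniq)) {
    rows <- which(site_of == s)
    nvec[s] <- length(rows)
    slat[s] <- lat[rows[1]]; slon[s] <- lon[rows[1]]
    sub <- m$calls[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    f <- colSums(sub, na.rm = TRUE) / (2 * called)
    f[called == 0] <- NA_real_
    freq[s, ] <- f
  }
  structure(list(freq = freq,
                 sites = data.frame(site_id = uniq, lat = slat, lon = slon,
                                    n = nvec, stringsAsFactors = FALSE),
                 site_of = setNames(site_of, m$individuals$id)),
            class = "site_freq_matrix")
}
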