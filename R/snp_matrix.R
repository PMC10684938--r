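#' SNP genotype matrix with individual and site metadata
#'
#' The central container of the nuclear analyses: an individuals x sites
#' matrix of alt-allele dosages in \{0, 1, 2\} with `NA` marking missing
#' calls, optional per-call allelic read depths, per-individual metadata
#' (species label, accession, collection coordinates) and per-site metadata
#' (chromosome, position, ref/alt alleles).
#'
#' @param calls integer matrix, individuals x sites; entries 0/1/2 or NA.
#' @param individuals data.frame with at least column `id`; optional columns
#'   `species`, `accession`, `lat`, `lon`.  Row order matches `calls` rows.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.  Row
#'   order matches `calls` columns.
#' @param ref_depth,alt_depth optional integer matrices of per-call allelic
#'   read depths, same shape as `calls`.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, individuals, sites,
                       ref_depth = NULL, alt_depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(individuals$id)) stop("individuals need an 'id' column")
  individuals$id <- as.character(individuals$id)
  for (col in c("species", "accession")) {
    if (is.null(individuals[[col]])) individuals[[col]] <- NA_character_
  }
  for (col in c("lat", "lon")) {
    if (is.null(individuals[[col]])) individuals[[col]] <- NA_real_
  }
  x <- structure(list(calls = calls, individuals = individuals, sites = sites,
                      ref_depth = ref_depth, alt_depth = alt_depth),
                 class = "snp_matrix")
  validate_snp_matrix(x)
  x
}

validate_snp_matrix <- function(x) {
  n <- nrow(x$calls); L <- ncol(x$calls)
  if (nrow(x$individuals) != n)
    stop("calls has ", n, " rows but individuals has ", nrow(x$individuals))
  if (nrow(x$sites) != L)
    stop("calls has ", L, " columns but sites has ", nrow(x$sites))
  bad <- x$calls[!is.na(x$calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing calls must be 0, 1 or 2")
  if (anyDuplicated(x$individuals$id))
    stop("duplicated individual ids: ",
         paste(unique(x$individuals$id[duplicated(x$individuals$id)]),
               collapse = ", "))
  lat <- x$individuals$lat; lon <- x$individuals$lon
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  for (d in c("ref_depth", "alt_depth")) {
    if (!is.null(x[[d]]) && !identical(dim(x[[d]]), dim(x$calls)))
      stop(d, " dimensions do not match calls")
  }
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$calls)

#' @export
print.snp_matrix <- function(x, ...) {
  n <- nrow(x$calls); L <- ncol(x$calls)
  miss <- mean(is.na(x$calls))
  cat(sprintf("snp_matrix: %d individuals x %d sites (%.1f%% missing calls)\n",
              n, L, 100 * miss))
  if (!is.null(x$ref_depth)) cat("  allelic depths present\n")
  sp <- table(x$individuals$species, useNA = "no")
  if (length(sp)) cat("  species:",
                      paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a snp_matrix by individuals and/or sites
#'
#' @param x a [snp_matrix()].
#' @param i individual index (logical, integer, or character ids).
#' @param j site index (logical or integer).
#' @param ... unused.
#' @return A new `snp_matrix`.
#' @export
`[.snp_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$individuals$id)
  if (anyNA(i)) stop("unknown individual id in subset")
  sub_depth <- function(d) if (is.null(d)) NULL else d[i, j, drop = FALSE]
  snp_matrix(x$calls[i, j, drop = FALSE],
             x$individuals[i, , drop = FALSE],
             x$sites[j, , drop = FALSE],
             ref_depth = sub_depth(x$ref_depth),
             alt_depth = sub_depth(x$alt_depth))
}

#' Sort sites by chromosome then position
#' @param x a [snp_matrix()].
#' @return A `snp_matrix` with sites in (chrom, pos) order.
#' @export
sort_sites <- function(x) {
  ord <- order(x$sites$chrom, x$sites$pos)
  x[, ord]
}

#' Per-individual missing-call fraction
#' @param x a [snp_matrix()].
#' @return Named numeric vector.
#' @export
individual_missingness <- function(x) {
  setNames(rowMeans(is.na(x$calls)), x$individuals$id)
}

#' Per-site alt-allele frequency over non-missing calls
#' @param x a [snp_matrix()].
#' @return Numeric vector, NA where no calls.
#' @export
site_freq <- function(x) {
  colSums(x$calls, na.rm = TRUE) / (2 * colSums(!is.na(x$calls)))
}
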