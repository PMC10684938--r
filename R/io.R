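#' Read a VCF file into a snp_matrix
#'
#' Parses a diploid VCF (4.x) with per-call `GT` and, when present, `AD`
#' fields.  Biallelic records are encoded directly as alt-allele dosage;
#' multi-allelic records are retained with their full allele-index pairs so
#' that [filter_sites()] can reduce them to the two most common alleles.
#' Missing genotypes (`./.`) become missing calls.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @return A [snp_matrix()].  When the file contains multi-allelic records an
#'   internal `multi` component carries their raw allele pairs for the
#'   top-two-allele reduction.
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  # allele-index pairs; sites x individuals in vcfR orientation
  stripped <- gsub("[|]", "/", gt)
  pieces <- strsplit(as.vector(stripped), "/", fixed = TRUE)
  npl <- lengths(pieces)
  known <- !is.na(as.vector(stripped))
  if (any(npl[known] != 2L)) {
    bad <- which(known & npl != 2L)[1]
    stop("ploidy != 2 at record line for site index ",
         (bad - 1L) %% nrow(gt) + 1L)
  }
  a1 <- matrix(suppressWarnings(as.integer(vapply(pieces, `[`, "", 1L))),
               nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(
    as.integer(vapply(pieces, function(p) if (length(p) >= 2) p[2] else NA_character_, ""))),
    nrow = nrow(gt))
  calls <- a1 + a2                         # alt dosage for biallelic records
  calls[is.na(a1) | is.na(a2)] <- NA_integer_

  multi_idx <- which(grepl(",", fix$ALT, fixed = TRUE))
  # dosage is only meaningful vs ALT index 1 for biallelic records; blank
  # multi-allelic dosages until filter_sites() reduces them
  if (length(multi_idx)) calls[multi_idx, ] <- NA_integer_

  ref_depth <- alt_depth <- NULL
  if ("AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (!is.null(ad)) {
      adsplit <- strsplit(as.vector(ad), ",", fixed = TRUE)
      ref_depth <- matrix(suppressWarnings(
        as.integer(vapply(adsplit, `[`, "", 1L))), nrow = nrow(ad))
      alt_depth <- matrix(suppressWarnings(
        as.integer(vapply(adsplit, function(p)
          if (length(p) >= 2) p[2] else NA_character_, ""))), nrow = nrow(ad))
    }
  }

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  individuals <- data.frame(id = colnames(gt), stringsAsFactors = FALSE)
  m <- snp_matrix(t(calls), individuals, sites,
                  ref_depth = if (is.null(ref_depth)) NULL else t(ref_depth),
                  alt_depth = if (is.null(alt_depth)) NULL else t(alt_depth))
  if (length(multi_idx)) {
    m$multi <- list(idx = multi_idx,
                    a1 = t(a1[multi_idx, , drop = FALSE]),
                    a2 = t(a2[multi_idx, , drop = FALSE]))
  }
  m
}

#' Write a snp_matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 with GT (and AD when depths are present).
#'
#' @param m a biallelic [snp_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=obake",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$individuals$id), collapse = "\t"), con)
  has_ad <- !is.null(m$ref_depth)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  L <- ncol(m$calls)
  fmt <- if (has_ad) "GT:AD" else "GT"
  lines <- character(L)
  for (l in seq_len(L)) {
    g <- m$calls[, l]
    gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    if (has_ad) {
      rd <- m$ref_depth[, l]; ad <- m$alt_depth[, l]
      adstr <- ifelse(is.na(rd) | is.na(ad), ".",
                      paste(rd, ad, sep = ","))
      gt <- paste(gt, adstr, sep = ":")
    }
    lines[l] <- paste(c(m$sites$chrom[l], m$sites$pos[l], ".",
                        m$sites$ref[l], m$sites$alt[l], ".", "PASS", ".",
                        fmt, gt), collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read individual metadata from CSV
#'
#' Expected columns: `id`, `species`, `accession`, `lat`, `lon`.  Extra
#' columns are kept.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "accession", "lat", "lon")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  meta$id <- as.character(meta$id)
  meta
}

#' Attach metadata to a snp_matrix by individual id
#'
#' @param m a [snp_matrix()].
#' @param meta data.frame from [read_metadata()].
#' @return `m` with individual metadata filled in.
#' @export
attach_metadata <- function(m, meta) {
  idx <- match(m$individuals$id, meta$id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " individuals missing from metadata")
  for (col in setdiff(names(meta), "id")) {
    m$individuals[[col]] <- meta[[col]][idx]
  }
  validate_snp_matrix(m)
  m
}

#' Plastid SSR genotype table
#'
#' Haploid allele sizes (integer fragment lengths) at a fixed set of plastid
#' microsatellite loci, one allele per locus per individual.
#'
#' @param ids character vector of individual ids.
#' @param alleles integer matrix, individuals x loci; NA marks a failed call.
#' @param loci locus names; defaults to the column names of `alleles`.
#' @return An object of class `ssr_table`.
#' @export
ssr_table <- function(ids, alleles, loci = colnames(alleles)) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(loci)) loci <- paste0("ssr", seq_len(ncol(alleles)))
  if (length(ids) != nrow(alleles)) stop("ids do not match allele rows")
  ok <- alleles[!is.na(alleles)]
  if (length(ok) && any(ok <= 0L)) stop("allele sizes must be positive")
  structure(list(ids = as.character(ids), alleles = alleles,
                 loci = as.character(loci)),
            class = "ssr_table")
}

#' @export
print.ssr_table <- function(x, ...) {
  cat(sprintf("ssr_table: %d individuals x %d plastid loci\n",
              length(x$ids), length(x$loci)))
  invisible(x)
}

#' Read a plastid SSR table from CSV
#'
#' First column `id`, remaining columns one per locus with integer allele
#' sizes; empty cells are missing.
#'
#' @param path CSV path.
#' @return An [ssr_table()].
#' @export
read_ssr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("SSR CSV must start with an 'id' column")
  ssr_table(df$id, as.matrix(df[, -1, drop = FALSE]),
            loci = names(df)[-1])
}

#' Write the per-site filter log as TSV
#'
#' @param log data.frame with columns `chrom`, `pos`, `rule` as produced by
#'   [filter_sites()] (attribute `"filter_log"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
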