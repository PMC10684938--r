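# Shared fixture builders.  Everything is generated in code at test time.

vcf_header <- function(samples, ad = TRUE) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, gts, ads = NULL) {
  fmt <- if (is.null(ads)) "GT" else "GT:AD"
  cells <- if (is.null(ads)) gts else paste(gts, ads, sep = ":")
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, cells),
        collapse = "\t")
}

write_vcf_fixture <- function(lines, samples, ad = TRUE) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples, ad), lines), path)
  path
}

# Hand-built 20-site, 5-individual VCF exercising every rule of the filter
# cascade under default filter_params().  The expected survivor set and the
# rule attributed to each dropped site are enumerated by hand:
#
#  site             genotypes (I1..I5)          fate (rule)
#  chr1:100   0/0 0/1 1/1 0/0 0/0              keep
#  chr1:200   0/1 0/1 0/1 0/0 ./.              drop het (3/4 = 0.75 > 0.5)
#  chr1:300   0/0 0/0 0/0 0/0 0/0              drop maf (0 < 0.01)
#  chr1:400   0/1 0/1 0/1 0/0 0/0  AD(3,2) x2  drop presence (2 calls masked
#                                               by depth 5 < 7 -> 3/5 = 0.6)
#  chr1:500   0/0 0/1 ./. ./. 0/0              drop presence (3/5)
#  chr1:600   ALT=T,G: 0/1 1/1 2/2 0/0 0/0     keep (G carrier masked by
#                                               top-2 rule; 4 calls remain)
#  chr1:700   ALT=T,G: 2/2 2/2 0/2 0/0 0/1     keep (allele counts A=4, T=1,
#                                               G=5: top two are {G, A}, the
#                                               0/1 call is masked, and the
#                                               record re-encodes with ref=G
#                                               (more common), alt=A)
#  chr1:800   0/1 0/0 0/0 0/1 0/1 AD(250,200)  keep (depth 450 > 400 masks
#                                               I1; het 2/4 = 0.5 boundary)
#  chr1:900   0/1 0/1 0/1 0/0 0/0              drop het (3/5 = 0.6)
#  chr1:1000  0/1 x5                           drop het (1.0)
#  chr1:1100  1/1 x5                           drop maf (freq 1, maf 0)
#  chr1:1200  0/0 0/0 0/0 0/0 0/1              keep (maf 0.1)
#  chr1:1300  0/0 1/1 1/1 0/0 0/1              keep
#  chr1:1400  0/1 0/0 0/0 0/0 0/0 AD(200,200)  keep (depth 400 boundary kept)
#  chr1:1500  0/1 0/0 0/0 0/0 1/1 AD(3,4)      keep (depth 7 boundary kept)
#  chr2:100   0/0 0/0 0/1 0/0 0/0              keep
#  chr2:150   0/1 0/1 0/0 0/0 ./.              keep (het 2/4 = 0.5 boundary)
#  chr2:220   0/0 0/0 1/1 1/1 1/1              keep
#  chr2:300   0/0 0/0 ./. 0/0 0/0              drop maf (monomorphic)
#  chr2:400   0/1 ./. ./. 0/0 0/0              drop presence (3/5)
toy_vcf_20 <- function() {
  d <- "10,10"   # depth 20: always inside [7, 400]
  ds <- function(...) c(...)
  recs <- c(
    vcf_record("chr1", 100, "A", "T", c("0/0","0/1","1/1","0/0","0/0"),
               rep(d, 5)),
    vcf_record("chr1", 200, "A", "T", c("0/1","0/1","0/1","0/0","./."),
               c(d, d, d, d, ".")),
    vcf_record("chr1", 300, "A", "T", rep("0/0", 5), rep(d, 5)),
    vcf_record("chr1", 400, "A", "T", c("0/1","0/1","0/1","0/0","0/0"),
               c("3,2", "3,2", d, d, d)),
    vcf_record("chr1", 500, "A", "T", c("0/0","0/1","./.","./.","0/0"),
               c(d, d, ".", ".", d)),
    vcf_record("chr1", 600, "A", "T,G", c("0/1","1/1","2/2","0/0","0/0"),
               rep(d, 5)),
    vcf_record("chr1", 700, "A", "T,G", c("2/2","2/2","0/2","0/0","0/1"),
               rep(d, 5)),
    vcf_record("chr1", 800, "A", "T", c("0/1","0/0","0/0","0/1","0/1"),
               c("250,200", d, d, d, d)),
    vcf_record("chr1", 900, "A", "T", c("0/1","0/1","0/1","0/0","0/0"),
               rep(d, 5)),
    vcf_record("chr1", 1000, "A", "T", rep("0/1", 5), rep(d, 5)),
    vcf_record("chr1", 1100, "A", "T", rep("1/1", 5), rep(d, 5)),
    vcf_record("chr1", 1200, "A", "T", c("0/0","0/0","0/0","0/0","0/1"),
               rep(d, 5)),
    vcf_record("chr1", 1300, "A", "T", c("0/0","1/1","1/1","0/0","0/1"),
               rep(d, 5)),
    vcf_record("chr1", 1400, "A", "T", c("0/1","0/0","0/0","0/0","0/0"),
               c("200,200", d, d, d, d)),
    vcf_record("chr1", 1500, "A", "T", c("0/1","0/0","0/0","0/0","1/1"),
               c("3,4", d, d, d, d)),
    vcf_record("chr2", 100, "C", "G", c("0/0","0/0","0/1","0/0","0/0"),
               rep(d, 5)),
    vcf_record("chr2", 150, "C", "G", c("0/1","0/1","0/0","0/0","./."),
               c(d, d, d, d, ".")),
    vcf_record("chr2", 220, "C", "G", c("0/0","0/0","1/1","1/1","1/1"),
               rep(d, 5)),
    vcf_record("chr2", 300, "C", "G", c("0/0","0/0","./.","0/0","0/0"),
               c(d, d, ".", d, d)),
    vcf_record("chr2", 400, "C", "G", c("0/1","./.","./.","0/0","0/0"),
               c(d, ".", ".", d, d)))
  list(path = write_vcf_fixture(recs, paste0("I", 1:5)),
       expected_keep = data.frame(
         chrom = c(rep("chr1", 8), rep("chr2", 3)),
         pos = c(100, 600, 700, 800, 1200, 1300, 1400, 1500, 100, 150, 220)),
       expected_drop = data.frame(
         chrom = c(rep("chr1", 7), rep("chr2", 2)),
         pos = c(200, 300, 400, 500, 900, 1000, 1100, 300, 400),
         rule = c("het_fraction", "maf", "site_presence", "site_presence",
                  "het_fraction", "het_fraction", "maf", "maf",
                  "site_presence")))
}

# small deterministic snp_matrix from a dosage matrix
toy_snp <- function(G, lat = NULL, lon = NULL, species = NULL,
                    accession = NULL) {
  n <- nrow(G); L <- ncol(G)
  ids <- rownames(G) %||% paste0("ind", seq_len(n))
  ind <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(species)) ind$species <- species
  if (!is.null(accession)) ind$accession <- accession
  if (!is.null(lat)) { ind$lat <- lat; ind$lon <- lon }
  snp_matrix(G, ind,
             data.frame(chrom = "chr1", pos = 100L * seq_len(L),
                        ref = "A", alt = "T", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force minimum spanning tree total weight by spanning-tree enumeration
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (rows in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    sub <- pairs[rows, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (q in seq_len(nrow(sub))) {
      a <- find(sub[q, 1]); b <- find(sub[q, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(d[sub]))
  }
  best
}

# brute-force union of all minimum spanning trees (edge set)
brute_msn_edges <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- brute_mst_weight(d)
  in_union <- matrix(FALSE, n, n)
  for (rows in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    sub <- pairs[rows, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (q in seq_len(nrow(sub))) {
      a <- find(sub[q, 1]); b <- find(sub[q, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok && abs(sum(d[sub]) - best) < 1e-9) {
      in_union[sub] <- TRUE
    }
  }
  in_union | t(in_union)
}
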