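test_that("read_vcf encodes genotypes, missing calls and allelic depths", {
  recs <- c(
    vcf_record("chr1", 10, "A", "T", c("0/0", "0/1", "1/1"),
               c("5,0", "3,4", "0,6")),
    vcf_record("chr1", 20, "A", "C", c("./.", "0/0", "0/1"),
               c(".", "8,0", "2,9")))
  m <- read_vcf(write_vcf_fixture(recs, c("s1", "s2", "s3")))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m$calls[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(m$calls[, 2]), c(NA_integer_, 0L, 1L))
  expect_equal(unname(m$ref_depth[2, 1]), 3L)
  expect_equal(unname(m$alt_depth[2, 1]), 4L)
  expect_equal(m$individuals$id, c("s1", "s2", "s3"))
})

test_that("read_vcf rejects non-diploid genotypes", {
  recs <- vcf_record("chr1", 10, "A", "T", c("0/0", "0/1/1"))
  expect_error(read_vcf(write_vcf_fixture(recs, c("s1", "s2"), ad = FALSE)),
               "ploidy")
})

test_that("phased genotype separators are accepted", {
  recs <- vcf_record("chr1", 10, "A", "T", c("0|1", "1|1"))
  m <- read_vcf(write_vcf_fixture(recs, c("s1", "s2"), ad = FALSE))
  expect_equal(unname(m$calls[, 1]), c(1L, 2L))
})

test_that("filter_sites applies each rule and attributes drops correctly", {
  # heterozygous fraction 3/4 among non-missing calls
  m <- toy_snp(rbind(a = 1L, b = 1L, c = 1L, d = 0L))
  out <- filter_sites(m, filter_params())
  expect_equal(ncol(out$calls), 0L)
  expect_equal(attr(out, "filter_log")$rule, "het_fraction")

  # depth outside [7, 400] masks the call before site-level tests
  m2 <- toy_snp(matrix(c(1L, 1L, 0L, 0L, 0L), 5, 1))
  m2$ref_depth <- matrix(c(3L, 10L, 10L, 10L, 10L), 5, 1)
  m2$alt_depth <- matrix(c(2L, 10L, 10L, 10L, 10L), 5, 1)
  out2 <- filter_sites(m2, filter_params())
  expect_equal(ncol(out2$calls), 1L)   # 4/5 presence, het 1/4, maf 1/8
  expect_true(is.na(out2$calls[1, 1])) # the (3,2) call was masked

  # minor allele frequency below 1 percent
  g <- matrix(0L, 100, 1); g[1, 1] <- 1L   # 1 alt of 200 alleles
  out3 <- filter_sites(toy_snp(g), filter_params())
  expect_equal(ncol(out3$calls), 0L)
  expect_equal(attr(out3, "filter_log")$rule, "maf")
})

test_that("filtering is idempotent and never grows the matrix", {
  set.seed(42)
  G <- matrix(sample(c(0L, 1L, 2L, NA), 400, replace = TRUE,
                     prob = c(0.4, 0.2, 0.3, 0.1)), 20, 20)
  m <- toy_snp(G)
  once <- filter_sites(m, filter_params())
  twice <- filter_sites(once, filter_params())
  expect_equal(twice$calls, once$calls)
  expect_equal(twice$sites, once$sites)
  expect_lte(ncol(once$calls), ncol(m$calls))
})

test_that("filter_individuals drops on strict missingness excess", {
  G <- rbind(miss41 = c(rep(NA_integer_, 41), rep(0L, 59)),
             miss40 = c(rep(NA_integer_, 40), rep(0L, 60)),
             full   = rep(1L, 100))
  out <- filter_individuals(toy_snp(G), filter_params())
  expect_equal(out$individuals$id, c("miss40", "full"))
  expect_equal(attr(out, "dropped_individuals"), "miss41")
  # all-complete input is the identity
  out2 <- filter_individuals(toy_snp(matrix(0L, 3, 4)), filter_params())
  expect_equal(nrow(out2$calls), 3L)
})

test_that("thin_sites keeps greedy >= min_bp spacing per chromosome", {
  m <- toy_snp(matrix(0L, 2, 3))
  m$sites$pos <- c(100L, 150L, 250L)
  out <- thin_sites(m, 100L)
  expect_equal(out$sites$pos, c(100L, 250L))

  m2 <- toy_snp(matrix(0L, 2, 3))
  m2$sites$pos <- c(1L, 101L, 201L)
  expect_equal(thin_sites(m2, 100L)$sites$pos, c(1L, 101L, 201L))

  # one site per chromosome is untouched
  m3 <- toy_snp(matrix(0L, 2, 3))
  m3$sites$chrom <- c("chr1", "chr2", "chr3")
  m3$sites$pos <- c(5L, 5L, 5L)
  expect_equal(dim(thin_sites(m3, 100L)), c(2L, 3L))

  # property: surviving gaps are always >= min_bp
  set.seed(7)
  m4 <- toy_snp(matrix(0L, 2, 50))
  m4$sites$pos <- sort(sample.int(2000, 50))
  out4 <- thin_sites(m4, 75L)
  expect_true(all(diff(out4$sites$pos) >= 75))
})

test_that("pool_by_site pools by exact rounded coordinates", {
  G <- rbind(a = c(0L, NA), b = c(2L, NA), c = c(1L, 1L))
  m <- toy_snp(G, lat = c(1, 1, 2), lon = c(3, 3, 4))
  f <- pool_by_site(m)
  expect_equal(nrow(f$sites), 2L)
  expect_equal(f$freq[1, 1], 0.5)       # calls (0, 2) -> 0.5
  expect_true(is.na(f$freq[1, 2]))      # all calls missing at that locus
  expect_equal(f$sites$n, c(2L, 1L))

  # three sites against a hand-computed table
  G2 <- rbind(p = c(0L, 2L), q = c(2L, 2L), r = c(1L, 0L), s = c(1L, 2L))
  m2 <- toy_snp(G2, lat = c(1, 1, 2, 3), lon = c(0, 0, 0, 0))
  f2 <- pool_by_site(m2)
  expect_equal(f2$freq, rbind(c(0.5, 1), c(0.5, 0), c(0.5, 1)))

  # individuals without coordinates are excluded with a warning
  m3 <- toy_snp(G, lat = c(1, 1, NA), lon = c(3, 3, NA))
  expect_warning(f3 <- pool_by_site(m3), "without coordinates")
  expect_equal(nrow(f3$sites), 1L)
})

test_that("write_vcf / read_vcf round trip preserves calls and depths", {
  pan <- sim_panel(sim_spec(seed = 11, n_loci = 40, n_per_subpop = 4,
                            n_sativa = 3, n_barthii = 2, n_glaberrima = 2))
  path <- tempfile(fileext = ".vcf")
  write_vcf(pan$snp, path)
  back <- read_vcf(path)
  expect_equal(unname(back$calls), unname(pan$snp$calls))
  expect_equal(unname(back$ref_depth[!is.na(pan$snp$calls)]),
               unname(pan$snp$ref_depth[!is.na(pan$snp$calls)]))
  expect_equal(back$individuals$id, pan$snp$individuals$id)
})

test_that("ssr_table validates and round trips through CSV", {
  s <- ssr_table(c("a", "b"), rbind(c(100L, 105L), c(101L, 105L)),
                 loci = c("L1", "L2"))
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = s$ids, s$alleles), path, row.names = FALSE)
  back <- read_ssr(path)
  expect_equal(back$alleles, s$alleles, ignore_attr = TRUE)
  expect_error(ssr_table("a", matrix(-3L, 1, 1)), "positive")
})
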