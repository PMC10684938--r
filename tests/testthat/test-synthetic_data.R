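test_that("Balding-Nichols draws collapse to the parent as F -> 0", {
  set.seed(1)
  p <- runif(500, 0.05, 0.95)
  child <- bn_draw(p, 1e-4)
  expect_lt(max(abs(child - p)), 0.05)
  expect_equal(bn_draw(p, 0), p)
})

test_that("generator divergence parameters come out in measured F_ST units", {
  set.seed(2)
  p <- runif(10000, 0.05, 0.95)
  c2 <- bn_coef(0.3, S = 2)
  p1 <- bn_draw(p, c2); p2 <- bn_draw(p, c2)
  # multilocus Nei F_ST from the parametric frequencies
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  fst <- 1 - mean(hs) / mean(ht)
  expect_equal(fst, 0.3, tolerance = 0.02)
})

test_that("frequency tables are reproducible under a fixed seed", {
  sp <- sim_spec(seed = 5, n_loci = 100)
  set.seed(sp$seed); f1 <- sim_frequencies(sp)
  set.seed(sp$seed); f2 <- sim_frequencies(sp)
  expect_identical(f1, f2)
})

test_that("sim_individual honours inbreeding in its heterozygosity", {
  set.seed(3)
  g1 <- sim_individual(rep(0.5, 4000), 1, f_is = 1)
  expect_true(all(g1 != 1L))
  g0 <- sim_individual(rep(0.5, 4000), 1, f_is = 0)
  expect_equal(mean(g0 == 1L), 0.5, tolerance = 0.04)
  expect_error(sim_individual(rep(0.5, 10), c(0.7, 0.6)), "simplex")
})

test_that("pedigree simulation matches Mendelian expectations", {
  set.seed(4)
  L <- 2000
  pools <- list(longistaminata = runif(L, 0.05, 0.95),
                sativa = runif(L, 0.05, 0.95))

  f1 <- sim_pedigree(pools, pedigree_spec("F1", n = 3))
  expect_true(all(f1$truth$longistaminata == 0.5))
  expect_true(all(f1$truth$sativa == 0.5))
  expect_equal(f1$truth$maternal, rep("longistaminata", 3))

  bc1 <- sim_pedigree(pools, pedigree_spec("BC1(longistaminata)", n = 30))
  expect_equal(mean(bc1$truth$sativa), 0.25, tolerance = 0.02)
  expect_lt(sd(bc1$truth$sativa), 3 * 0.25 / sqrt(L) * 2)

  # RIL heterozygosity drops to ~ (1/2)^5 of the F1 level
  ril <- sim_pedigree(pools, pedigree_spec("RIL", maternal = "sativa",
                                           n = 20))
  het_f1 <- mean(f1$genotypes == 1L)
  het_ril <- mean(ril$genotypes == 1L)
  expect_equal(het_ril / het_f1, (1 / 2)^5, tolerance = 0.02)
  expect_equal(ril$truth$maternal, rep("sativa", 20))
})

test_that("pedigree grammar errors name the offending token", {
  expect_error(pedigree_spec("F1 > NONSENSE"), "token 2")
  expect_error(pedigree_spec("SELF3"), "must start")
  expect_error(pedigree_spec(""), "parse error|empty")
})

test_that("plastid haplotypes are maternally faithful and species-distinct", {
  founders <- obake:::ssr_founders()
  # founders themselves differ by >= 3 loci between species
  for (a in 1:3) for (b in (a + 1):4) {
    expect_gte(sum(founders[a, ] != founders[b, ]), 3)
  }

  lin <- data.frame(id = c("w1", "hyb"),
                    maternal = c("longistaminata", "longistaminata"),
                    mutate = c(TRUE, FALSE))
  set.seed(6)
  s0 <- sim_plastid(lin, mut_rate = 0)
  expect_equal(unname(s0$alleles[1, ]), unname(founders["longistaminata", ]))
  expect_equal(unname(s0$alleles[2, ]), unname(founders["longistaminata", ]))

  # low mutation rate: no cross-species haplotype sharing over many draws
  set.seed(7)
  lin2 <- data.frame(id = sprintf("x%03d", 1:200),
                     maternal = rep(c("longistaminata", "sativa"), 100),
                     mutate = TRUE)
  s2 <- sim_plastid(lin2, mut_rate = 0.02)
  key <- apply(s2$alleles, 1, paste, collapse = "_")
  shared <- intersect(key[lin2$maternal == "longistaminata"],
                      key[lin2$maternal == "sativa"])
  expect_length(shared, 0)
})

test_that("emitted panels survive the file round trip", {
  sp <- sim_spec(seed = 31, n_loci = 60, n_per_subpop = 6, n_sativa = 4,
                 n_barthii = 3, n_glaberrima = 3,
                 pedigrees = list(pedigree_spec("F1", n = 2, label = "F1")))
  dir <- tempfile()
  out <- emit_panel(sp, dir)
  m <- read_vcf(out$vcf)
  m <- attach_metadata(m, read_metadata(out$meta))
  expect_equal(unname(m$calls), unname(out$panel$snp$calls))
  expect_equal(m$individuals$species, out$panel$snp$individuals$species)
  s <- read_ssr(out$ssr)
  expect_equal(s$alleles, out$panel$ssr$alleles, ignore_attr = TRUE)

  # byte-identical regeneration under the same spec and seed
  dir2 <- tempfile()
  emit_panel(sp, dir2)
  for (f in c("panel.vcf", "metadata.csv", "ssr.csv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("missing-rate and depth models hit their moments", {
  sp <- sim_spec(seed = 41, n_loci = 400, n_per_subpop = 20, n_sativa = 10,
                 n_barthii = 5, n_glaberrima = 5, missing_rate = 0.1,
                 depth_mean = 30)
  pan <- sim_panel(sp)
  expect_equal(mean(is.na(pan$snp$calls)), 0.1, tolerance = 0.01)
  tot <- pan$snp$ref_depth + pan$snp$alt_depth
  expect_equal(mean(tot[!is.na(pan$snp$calls)]), 30, tolerance = 1)
})

test_that("panel truth dimensions line up with the emitted genotypes", {
  sp <- sim_spec(seed = 51, n_loci = 50, n_per_subpop = 4, n_sativa = 3,
                 n_barthii = 2, n_glaberrima = 2)
  pan <- sim_panel(sp)
  expect_equal(nrow(pan$truth), nrow(pan$snp$calls))
  expect_equal(pan$truth$id, pan$snp$individuals$id)
  wild <- pan$truth$species == "longistaminata"
  qsub <- as.matrix(pan$truth[wild, c("q_NW", "q_Pan", "q_S")])
  expect_true(all(abs(rowSums(qsub) + pan$truth$q_sativa[wild] - 1) < 1e-9))
})
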