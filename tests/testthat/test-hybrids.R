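test_that("threshold calibration brackets the control minimum", {
  t1 <- calibrate_thresholds(c(0.05, 0.12, 0.18))
  expect_lt(t1$lower, 0.05)
  expect_true(all(c(0.05, 0.12, 0.18) >= t1$lower &
                  c(0.05, 0.12, 0.18) <= t1$upper))
  expect_equal(t1$lower + t1$upper, 1)

  t0 <- calibrate_thresholds()
  expect_equal(t0$lower, 0.044)
  expect_equal(t0$upper, 0.956)

  t5 <- calibrate_thresholds(0.5)
  expect_true(0.5 >= t5$lower && 0.5 <= t5$upper)
  expect_error(calibrate_thresholds(c(0.1, 1.2)), "strictly")
})

test_that("classification reproduces the reference-entry behaviour", {
  t <- calibrate_thresholds()
  p1 <- ancestry_profile("e1", 0.79, 0.18, 0.04)   # high-sativa entry
  c1 <- classify_hybrid(p1, t)
  expect_equal(c1$status, "putative_hybrid")
  expect_equal(c1$direction, "into_sativa")

  p2 <- ancestry_profile("F1c", 0.47, 0.53, 0.00)  # F1 control profile
  c2 <- classify_hybrid(p2, t)
  expect_equal(c2$status, "putative_hybrid")
  expect_equal(c2$direction, "into_longistaminata")

  p3 <- ancestry_profile("pure", 0.01, 0.99, 0.00)
  expect_equal(classify_hybrid(p3, t)$status, "pure")

  # sativa-labeled entries measure admixture symmetrically
  p4 <- ancestry_profile("sat", 0.99, 0.01, 0.00, species_label = "sativa")
  expect_equal(classify_hybrid(p4, t)$status, "pure")
})

test_that("generation bands follow pedigree expectations in order", {
  t <- calibrate_thresholds()
  band_of <- function(qs, ql, qb = 1 - qs - ql) {
    call <- classify_hybrid(ancestry_profile("x", qs, ql, qb), t)
    generation_band(call)$generation_band
  }
  expect_equal(band_of(0.53, 0.46, 0.01), "F1_F2")
  expect_equal(band_of(0.24, 0.76, 0.00), "BC1")
  expect_equal(band_of(0.08, 0.92, 0.00), "BC2")  # |0.08 - 0.125| <= 0.06
  expect_equal(band_of(0.32, 0.68, 0.00), "advanced")

  pure_call <- classify_hybrid(ancestry_profile("p", 0.01, 0.99, 0), t)
  expect_error(generation_band(pure_call), "putative")
})

test_that("no calibration control is ever classified pure", {
  set.seed(17)
  for (rep in 1:20) {
    controls <- runif(sample(1:6, 1), 0.01, 0.99)
    t <- calibrate_thresholds(controls)
    for (v in controls) {
      p <- ancestry_profile("c", v, 1 - v, 0)
      expect_equal(classify_hybrid(p, t)$status, "putative_hybrid")
    }
  }
})

test_that("direction and band ignore the arrangement of outgroup remainder", {
  t <- calibrate_thresholds()
  a <- classify_hybrid(ancestry_profile("x", 0.30, 0.62, 0.08), t)
  b <- classify_hybrid(ancestry_profile("x", 0.30, 0.62, 0.08), t)
  expect_equal(a$direction, b$direction)
  ba <- generation_band(a)$generation_band
  expect_equal(ba, generation_band(b)$generation_band)
})

test_that("cytonuclear checks read the maternal parent off the plastid", {
  p <- ancestry_profile("h", 0.3, 0.69, 0.01, plastid_group = "longistaminata")
  cy <- cytonuclear_check(p)
  expect_equal(cy$maternal_parent, "longistaminata")
  expect_true(cy$consistent)

  p2 <- ancestry_profile("ctrl", 0.47, 0.53, 0.00, plastid_group = "sativa")
  expect_equal(cytonuclear_check(p2)$maternal_parent, "sativa")

  p3 <- ancestry_profile("m", 0.3, 0.7, 0.0)
  cy3 <- cytonuclear_check(p3)
  expect_true(is.na(cy3$maternal_parent))
  expect_true(is.na(cy3$consistent))
})

test_that("the shipped hybrid reference panel is intact", {
  hp <- hybrid_panel()
  expect_equal(nrow(hp), 36L)
  expect_equal(sum(hp$type == "control"), 17L)
  expect_equal(sum(hp$type == "putative"), 19L)
  expect_true(all(abs(hp$q_sativa + hp$q_longistaminata +
                        hp$q_barthii_glaberrima - 1) <= 0.02))
})

test_that("low-level admixture summaries match hand counts", {
  profiles <- data.frame(
    entry = paste0("e", 1:6),
    q_sativa = c(0.030, 0.040, 0.020, 0.300, 0.000, 0.000),
    q_longistaminata = c(0.962, 0.958, 0.972, 0.690, 1.000, 1.000),
    q_barthii_glaberrima = c(0.008, 0.002, 0.008, 0.010, 0.000, 0.000))
  grouping <- c("S", "S", "S", "S", "N", "N")
  smry <- low_level_admixture_summary(profiles, grouping)
  s_sat <- smry[smry$group == "S" & smry$component == "q_sativa", ]
  expect_equal(s_sat$mean, 0.03)         # the 0.30 entry is hybrid, excluded
  expect_equal(s_sat$min, 0.02)
  expect_equal(s_sat$max, 0.04)
  n_sat <- smry[smry$group == "N" & smry$component == "q_sativa", ]
  expect_equal(c(n_sat$mean, n_sat$min, n_sat$max), c(0, 0, 0))
})

test_that("simulated ancient admixture is recovered by the summary", {
  peds <- list()
  sp <- sim_spec(seed = 23, n_loci = 600, n_per_subpop = 12, n_sativa = 10,
                 n_barthii = 5, n_glaberrima = 5,
                 ancient_admixture = c(S = 0.037))
  pan <- sim_panel(sp)
  wild <- pan$truth$species == "longistaminata"
  profiles <- data.frame(entry = pan$truth$id[wild],
                         q_sativa = pan$truth$q_sativa[wild],
                         q_longistaminata = pan$truth$q_longistaminata[wild],
                         q_barthii_glaberrima = pan$truth$q_bg[wild])
  smry <- low_level_admixture_summary(profiles, pan$truth$subpop[wild])
  s <- smry[smry$group == "S" & smry$component == "q_sativa", ]
  expect_equal(s$mean, 0.037, tolerance = 0.01)
})
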