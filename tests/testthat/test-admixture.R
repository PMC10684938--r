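test_that("admixture log-likelihood matches analytic values", {
  expect_equal(admix_loglik(matrix(1L, 1, 1), matrix(1, 1, 1),
                            matrix(0.5, 1, 1)),
               log(2) + 2 * log(0.5))
  expect_equal(admix_loglik(matrix(2L, 1, 1), matrix(1, 1, 1),
                            matrix(0.5, 1, 1)),
               2 * log(0.5))
  # clamped extreme frequencies at K = 2 mix back to theta = 0.5
  ll2 <- admix_loglik(matrix(1L, 1, 1), matrix(c(0.5, 0.5), 1, 2),
                      matrix(c(1, 0), 2, 1))
  expect_equal(ll2, log(2) + 2 * log(0.5), tolerance = 1e-6)
  expect_error(admix_loglik(matrix(1L, 2, 1), matrix(1, 1, 1),
                            matrix(0.5, 1, 1)), "Q rows")
})

test_that("lnL is invariant under cluster permutation", {
  set.seed(3)
  G <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  Q <- matrix(rgamma(18, 1), 6, 3); Q <- Q / rowSums(Q)
  P <- matrix(runif(30), 3, 10)
  perm <- c(3, 1, 2)
  expect_equal(admix_loglik(G, Q, P),
               admix_loglik(G, Q[, perm], P[perm, ]))
})

test_that("K = 1 fit returns unit ancestry for every individual", {
  G <- matrix(sample(0:2, 40, replace = TRUE), 4, 10)
  fit <- fit_unsupervised(G, 1, reduced_profile(burn_in = 50, reps = 100))
  expect_true(all(fit$Q == 1))
})

test_that("two populations fixed for opposite alleles resolve at K = 2", {
  L <- 300
  G <- rbind(matrix(0L, 20, L), matrix(2L, 20, L))
  rownames(G) <- paste0("i", 1:40)
  fit <- fit_unsupervised(G, 2,
                          reduced_profile(burn_in = 200, reps = 500, seed = 2))
  expect_true(all(apply(fit$Q, 1, max) >= 0.99))
  # the two groups land in different clusters
  expect_true(which.max(fit$Q[1, ]) != which.max(fit$Q[40, ]))
  # an F1 between them sits at (0.5, 0.5) within 0.03
  Gf1 <- rbind(G, f1 = rep(1L, L))
  fit2 <- fit_unsupervised(Gf1, 2,
                           reduced_profile(burn_in = 200, reps = 500, seed = 2))
  expect_equal(unname(fit2$Q[41, 1]), 0.5, tolerance = 0.03)
})

test_that("every reported Q row lies on the simplex", {
  set.seed(8)
  G <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20)
  for (K in c(2, 3)) {
    fit <- fit_unsupervised(G, K,
                            reduced_profile(burn_in = 50, reps = 150, seed = K))
    expect_true(all(fit$Q >= 0 & fit$Q <= 1))
    expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
    expect_true(all(fit$P > 0 & fit$P < 1))
    expect_true(all(is.finite(fit$lnL_trace[!is.na(fit$lnL_trace)])))
  }
})

test_that("fits are reproducible under a fixed seed", {
  G <- matrix(sample(0:2, 100, replace = TRUE), 5, 20)
  cfg <- reduced_profile(burn_in = 50, reps = 100, seed = 77)
  f1 <- fit_unsupervised(G, 2, cfg)
  f2 <- fit_unsupervised(G, 2, cfg)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnL_trace, f2$lnL_trace)
})

test_that("K larger than the panel errors", {
  expect_error(fit_unsupervised(matrix(0L, 3, 5), 4, reduced_profile()),
               "exceeds")
})

test_that("supervised fit pins sources and assigns unlabeled copies home", {
  set.seed(5)
  L <- 400
  p1 <- runif(L, 0.05, 0.3); p2 <- runif(L, 0.7, 0.95)
  draw <- function(p) as.integer(rbinom(L, 2, p))
  G <- rbind(t(replicate(8, draw(p1))), t(replicate(8, draw(p2))),
             copy1 = draw(p1), copy2 = draw(p2))
  rownames(G) <- c(paste0("a", 1:8), paste0("b", 1:8), "copy1", "copy2")
  prior <- pop_prior(c(rep(1L, 8), rep(2L, 8), NA, NA))
  fit <- fit_supervised(G, 2, prior,
                        reduced_profile(burn_in = 200, reps = 500, seed = 4))
  expect_true(all(fit$Q[1:8, 1] == 1))          # pinned indicators
  expect_gte(fit$Q["copy1", 1], 0.95)           # self-assignment
  expect_gte(fit$Q["copy2", 2], 0.95)
  # with everyone labeled, P reduces to frequency estimation
  prior_all <- pop_prior(c(rep(1L, 8), rep(2L, 8), 1L, 2L))
  fit_all <- fit_supervised(G, 2, prior_all,
                            reduced_profile(burn_in = 200, reps = 400,
                                            seed = 4))
  obs1 <- colMeans(G[c(1:8, 17), ]) / 2
  expect_lt(mean(abs(fit_all$P[1, ] - obs1)), 0.05)
})

test_that("supervised fit demands a source for every population", {
  G <- matrix(0L, 4, 5)
  expect_error(fit_supervised(G, 2, pop_prior(c(1L, 1L, NA, NA)),
                              reduced_profile()), "no flagged")
  expect_error(pop_prior(c(1L, NA), flags = c(TRUE, TRUE)), "labeled")
})

test_that("EM mode is deterministic and separates diverged pools", {
  L <- 200
  G <- rbind(matrix(0L, 10, L), matrix(2L, 10, L))
  rownames(G) <- paste0("i", 1:20)
  cfg <- run_config(method = "em", seed = 10)
  f1 <- fit_unsupervised(G, 2, cfg)
  f2 <- fit_unsupervised(G, 2, cfg)
  expect_identical(f1$Q, f2$Q)
  expect_true(all(apply(f1$Q, 1, max) > 0.99))
})

test_that("Evanno delta-K reproduces hand arithmetic and edge cases", {
  runs <- data.frame(K = rep(1:3, each = 3),
                     lnP_data = c(-101, -100, -99, -81, -80, -79,
                                  -79, -78, -77))
  ev <- evanno(runs)
  expect_equal(ev$table$mean_L, c(-100, -80, -78))
  expect_equal(ev$table$sd_L, rep(1, 3))
  expect_equal(ev$table$Lpp_abs[2], 18)    # |-78 + 160 - 100|
  expect_equal(ev$table$deltaK[2], 18)
  expect_equal(ev$optimal_K, 2L)

  # linear mean sequence: |L''| = 0 everywhere, delta-K = 0
  lin <- data.frame(K = rep(1:4, each = 3),
                    lnP_data = rep(c(-40, -30, -20, -10), each = 3) +
                      rep(c(-0.5, 0, 0.5), 4))
  evl <- evanno(lin)
  expect_true(all(evl$table$deltaK[2:3] == 0))

  # zero replicate variance leaves delta-K undefined at that K only
  z <- data.frame(K = rep(1:4, each = 3),
                  lnP_data = c(-101, -100, -99, -80, -80, -80,
                               -71, -70, -69, -69, -68, -67))
  evz <- evanno(z)
  expect_true(is.na(evz$table$deltaK[2]))
  expect_false(is.na(evz$table$deltaK[3]))

  # all interior delta-K undefined is an error pointing at lnP inspection
  z2 <- data.frame(K = rep(1:3, each = 3),
                   lnP_data = c(-101, -100, -99, -80, -80, -80,
                                -79, -78, -77))
  expect_error(evanno(z2), "lnP")

  expect_error(evanno(data.frame(K = rep(c(1, 3), each = 3),
                                 lnP_data = rnorm(6))), "contiguous")
  expect_error(evanno(data.frame(K = rep(1:3, each = 2),
                                 lnP_data = rnorm(6))), "replicates")
})

test_that("cluster matching aligns permuted fits", {
  set.seed(2)
  Q <- matrix(rgamma(30, 1), 10, 3); Q <- Q / rowSums(Q)
  rownames(Q) <- paste0("i", 1:10)
  perm <- c(2, 3, 1)
  matched <- match_clusters(Q[, perm], Q)
  expect_equal(unname(matched), unname(Q))
})
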