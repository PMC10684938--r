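test_that("IBS distance matches its per-locus definition", {
  G <- rbind(a = c(0L, 1L, 0L), b = c(2L, 1L, 0L))
  d <- ibs_distance(G)
  # loci: (0,2) -> 1, het/het -> 0.5, identical hom -> 0
  expect_equal(d["a", "b"], mean(c(1, 0.5, 0)))
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d, t(d))

  # missing calls restrict to shared loci
  G2 <- rbind(a = c(0L, NA, 1L), b = c(2L, 1L, NA))
  expect_equal(ibs_distance(G2)["a", "b"], 1)

  # no shared loci -> NA, and NJ refuses the incomplete matrix
  G3 <- rbind(a = c(0L, NA), b = c(NA, 2L), c = c(0L, 0L))
  d3 <- ibs_distance(G3)
  expect_true(is.na(d3["a", "b"]))
  expect_error(nj_tree(d3), "missing")
})

test_that("NJ reconstructs additive distances exactly", {
  # 4-taxon tree: A:1, B:2 joined, internal 1, C:3, D:4
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tree <- nj_tree(d)
  path <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, d, tolerance = 1e-9)
  # AB|CD split: drop the A pendant edge and B stays with A
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("A", "B")) ||
              ape::is.monophyletic(ape::unroot(tree), c("C", "D")))

  # 3 taxa: closed-form star lengths a=(dab+dac-dbc)/2 etc.
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], 1)
  expect_equal(len[["b"]], 2)
  expect_equal(len[["c"]], 4)
})

test_that("negative NJ branches are clamped without breaking determinism", {
  # near-ultrametric matrix with noise can yield negative branches
  set.seed(13)
  G <- matrix(sample(0:2, 6 * 50, replace = TRUE), 6, 50)
  rownames(G) <- paste0("t", 1:6)
  tree <- nj_tree(ibs_distance(G))
  expect_true(all(tree$edge.length >= 0))
  tree2 <- nj_tree(ibs_distance(G))
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))
})

test_that("rooting picks the candidate on the maximal pairwise distance", {
  d <- matrix(c(0, 1, 2, 9,
                1, 0, 2, 8,
                2, 2, 0, 7,
                9, 8, 7, 0), 4, 4,
              dimnames = list(c("w", "x", "y", "z"), c("w", "x", "y", "z")))
  tree <- nj_tree(d)
  rooted <- root_at_max_distance(tree, d, candidates = c("y", "z"))
  expect_equal(attr(rooted, "root_leaf"), "z")   # 9 involves w and z
  expect_true(ape::is.rooted(rooted))
  # rooting never changes leaf-to-leaf path lengths
  expect_equal(ape::cophenetic.phylo(rooted)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(tree)[rownames(d), rownames(d)],
               tolerance = 1e-12)

  # tie on the maximum: lexicographically smaller candidate id wins
  d2 <- d; d2["x", "z"] <- d2["z", "x"] <- 9
  rooted2 <- root_at_max_distance(nj_tree(d2), d2, candidates = c("z", "x"))
  expect_equal(attr(rooted2, "root_leaf"), "x")
  expect_error(root_at_max_distance(tree, d, character(0)), "candidates")
})

test_that("haplotype collapsing groups identical SSR vectors", {
  alle <- rbind(c(100L, 105L), c(100L, 105L), c(100L, 105L), c(102L, 105L))
  s <- ssr_table(paste0("i", 1:4), alle, loci = c("L1", "L2"))
  nodes <- collapse_haplotypes(s, groups = c("a", "a", "b", "b"))
  expect_equal(unname(nodes$count), c(3L, 1L))
  expect_equal(sum(nodes$count), 4L)
  expect_equal(unname(nodes$composition[1, ]), c(2, 1))

  # all identical -> one node
  s1 <- ssr_table(paste0("i", 1:3), matrix(100L, 3, 2))
  expect_equal(length(collapse_haplotypes(s1)$count), 1L)

  # oracle: dictionary grouping of 10 random vectors
  set.seed(14)
  mat <- matrix(sample(100:102, 70, replace = TRUE), 10, 7)
  s10 <- ssr_table(paste0("i", 1:10), mat)
  nodes10 <- collapse_haplotypes(s10)
  key <- apply(mat, 1, paste, collapse = "_")
  expect_equal(sort(as.integer(nodes10$count)),
               sort(as.integer(table(key))))

  s_na <- ssr_table("i1", matrix(c(100L, NA), 1, 2))
  expect_error(collapse_haplotypes(s_na), "missing")
})

test_that("minimum-spanning network retains all tied MST edges", {
  # 3 haplotypes at mutual distance 1: full triangle survives (all ties)
  hap <- rbind(H1 = 100L, H2 = 101L, H3 = 102L)
  net <- msn(hap)   # single locus, every pair differs at it
  expect_equal(nrow(net$edges), 3L)

  # triangle with distances 1, 1, 2: only the two distance-1 edges
  hap2 <- rbind(A = c(100L, 100L), B = c(101L, 100L), C = c(101L, 101L))
  net2 <- msn(hap2)
  expect_equal(nrow(net2$edges), 2L)
  expect_setequal(paste(net2$edges$from, net2$edges$to),
                  c("A B", "B C"))

  # oracle: union of all MSTs by spanning-tree enumeration on 6 nodes
  set.seed(15)
  hap6 <- matrix(sample(100:103, 6 * 7, replace = TRUE), 6, 7)
  rownames(hap6) <- paste0("H", 1:6)
  net6 <- msn(hap6)
  d6 <- haplotype_distance(hap6)
  oracle <- brute_msn_edges(d6)
  got <- matrix(FALSE, 6, 6, dimnames = dimnames(d6))
  for (r in seq_len(nrow(net6$edges)))
    got[net6$edges$from[r], net6$edges$to[r]] <- TRUE
  got <- got | t(got)
  expect_equal(unname(got), unname(oracle))
})

test_that("step-sum SSR distance is available as an option", {
  hap <- rbind(A = c(100L, 100L), B = c(103L, 100L))
  expect_equal(haplotype_distance(hap, "loci")["A", "B"], 1L)
  expect_equal(haplotype_distance(hap, "steps")["A", "B"], 3L)
})
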