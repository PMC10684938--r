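#' Balding-Nichols frequency draw around parent frequencies
#'
#' @param p parent allele-frequency vector.
#' @param c Balding-Nichols divergence coefficient in (0, 1); 0 returns `p`.
#' @return Child frequency vector, clamped to (1e-6, 1 - 1e-6).
#' @export
bn_draw <- function(p, c) {
  if (c <= 0) return(p)
  out <- rbeta(length(p), p * (1 - c) / c, (1 - p) * (1 - c) / c)
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Balding-Nichols coefficient for a target measured differentiation
#'
#' Divergence parameters of the generator are expressed in units of the
#' expected multi-locus Nei F_ST actually measured among the resulting
#' groups.  For S sibling groups drawn around a common parent, measured
#' F_ST ~ c (S - 1)/S / (1 - c/S), inverted here:
#' `c = S F / (S - 1 + mean(F))`.
#'
#' @param F target differentiation (vector allowed; groups may differ).
#' @param S number of sibling groups drawn around the parent.
#' @return Balding-Nichols coefficient(s).
#' @export
bn_coef <- function(F, S = 2) {
  S * F / (S - 1 + mean(F))
}

#' Specification of a synthetic rice panel
#'
#' Defines the study design the generator emulates: one outcrossing wild
#' species (*O. longistaminata*) with three geographically structured
#' subpopulations, a domesticated Asian species (*O. sativa*) with two
#' groups, an African outgroup pair (*O. barthii* / *O. glaberrima*) that
#' clusters as one pool, pedigreed interspecific hybrids, subpopulation
#' inbreeding, maternally inherited plastid SSR haplotypes, and
#' missing-data/read-depth models.  Divergence parameters are in units of
#' expected measured F_ST (see [bn_coef()]).
#'
#' @param seed mandatory RNG seed.
#' @param n_loci number of unlinked biallelic loci.
#' @param n_per_subpop diploid individuals per wild subpopulation (two per
#'   accession).
#' @param subpop_F named per-subpop differentiation targets; defaults match
#'   the 0.013-0.023 regime of wild-rice RAD panels.
#' @param split_F pairwise differentiation of the wild species vs the
#'   domesticated pool.
#' @param bg_pool_F divergence of the barthii/glaberrima pool from the
#'   ancestral pool.
#' @param bg_within_F differentiation between barthii and glaberrima (small:
#'   the pair clusters as one group).
#' @param sativa_groups_F differentiation between the two domesticated
#'   groups.
#' @param n_sativa individuals per domesticated group.
#' @param n_barthii,n_glaberrima outgroup sample sizes.
#' @param f_is named per-subpop inbreeding coefficients for the wild
#'   species; `f_is_outgroup` applies to the selfing species.
#' @param f_is_outgroup inbreeding of the domesticated/selfing species.
#' @param subpop_centers data.frame (lat, lon) of the three subpop centers.
#' @param mixing_steepness logistic decay (per km) of subpop ancestry weight
#'   with distance from the subpop center; larger = sharper boundaries.
#' @param ancient_admixture fraction of domesticated-pool ancestry blended
#'   into every member of a named subpop (e.g. `c(S = 0.037)`), emulating
#'   old introgression; default none.
#' @param missing_rate per-call missing probability.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param pedigrees list of [pedigree_spec()] entries.
#' @param ssr_mut_rate per-locus stepwise mutation probability per lineage.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed,
                     n_loci = 1000L,
                     n_per_subpop = 40L,
                     subpop_F = c(NW = 0.022, Pan = 0.013, S = 0.023),
                     split_F = 0.30,
                     bg_pool_F = 0.35,
                     bg_within_F = 0.01,
                     sativa_groups_F = 0.20,
                     n_sativa = 30L,
                     n_barthii = 12L,
                     n_glaberrima = 20L,
                     f_is = c(NW = 0.28, Pan = 0.29, S = 0.44),
                     f_is_outgroup = 0.95,
                     subpop_centers = data.frame(
                       lat = c(14, 0, -20), lon = c(-6, 25, 30),
                       row.names = c("NW", "Pan", "S")),
                     mixing_steepness = 0.0015,
                     ancient_admixture = NULL,
                     missing_rate = 0.03,
                     depth_mean = 30, depth_size = 5,
                     pedigrees = list(),
                     ssr_mut_rate = 0.02) {
  if (missing(seed)) stop("a seed is mandatory for any emitted dataset")
  Fs <- c(subpop_F, split_F, bg_pool_F, bg_within_F, sativa_groups_F)
  if (any(Fs <= 0 | Fs >= 1)) stop("divergence parameters must lie in (0, 1)")
  structure(as.list(environment()), class = "sim_spec")
}

#' Hierarchical allele-frequency table for a sim_spec
#'
#' Ancestral frequencies are uniform(0.05, 0.95); species pools and
#' subpopulations are Balding-Nichols draws around their parents with
#' coefficients from [bn_coef()].
#'
#' @param spec a [sim_spec()]; uses the current RNG state (seed the caller).
#' @return list with `p_anc`, `p_longi`, `p_sativa_pool`, `p_bg_pool`
#'   (vectors), `p_subpop` (3 x L), `p_sativa` (2 x L), `p_bg` (2 x L,
#'   barthii then glaberrima).
#' @export
sim_frequencies <- function(spec) {
  L <- spec$n_loci
  p_anc <- runif(L, 0.05, 0.95)
  c_split <- bn_coef(spec$split_F, S = 2)
  p_longi <- bn_draw(p_anc, c_split)
  p_sativa_pool <- bn_draw(p_anc, c_split)
  p_bg_pool <- bn_draw(p_anc, spec$bg_pool_F)
  S <- length(spec$subpop_F)
  c_sub <- bn_coef(spec$subpop_F, S = S)
  p_subpop <- t(vapply(seq_len(S), function(s) bn_draw(p_longi, c_sub[s]),
                       numeric(L)))
  rownames(p_subpop) <- names(spec$subpop_F)
  c_sat <- bn_coef(spec$sativa_groups_F, S = 2)
  p_sativa <- rbind(sativa1 = bn_draw(p_sativa_pool, c_sat),
                    sativa2 = bn_draw(p_sativa_pool, c_sat))
  c_bg <- bn_coef(spec$bg_within_F, S = 2)
  p_bg <- rbind(barthii = bn_draw(p_bg_pool, c_bg),
                glaberrima = bn_draw(p_bg_pool, c_bg))
  list(p_anc = p_anc, p_longi = p_longi, p_sativa_pool = p_sativa_pool,
       p_bg_pool = p_bg_pool, p_subpop = p_subpop, p_sativa = p_sativa,
       p_bg = p_bg)
}

#' Simulate one diploid genotype row
#'
#' Per locus the alt-allele probability is `theta = sum_k q_k p_k`; with
#' probability `f_is` a single allele draw is duplicated (forcing
#' homozygosity), otherwise two independent draws are made — producing an
#' expected heterozygosity deficit of factor `(1 - f_is)`.
#'
#' @param freqs pools x loci frequency matrix (or a single vector).
#' @param q ancestry weights over the pools (simplex).
#' @param f_is inbreeding coefficient in `[0, 1]`.
#' @return Integer dosage vector in \{0, 1, 2\}.
#' @export
sim_individual <- function(freqs, q = 1, f_is = 0) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  if (abs(sum(q) - 1) > 1e-6) stop("q must lie on the simplex")
  theta <- as.numeric(q %*% freqs)
  L <- length(theta)
  ibd <- runif(L) < f_is
  dose <- integer(L)
  dose[ibd] <- 2L * rbinom(sum(ibd), 1L, theta[ibd])
  dose[!ibd] <- rbinom(sum(!ibd), 2L, theta[!ibd])
  dose
}

#' Pedigree specification for controlled interspecific crosses
#'
#' The grammar is a `>`-separated chain starting implicitly from an
#' interspecific F1 between the maternal and paternal species:
#' `"F1"`, `"F2"` (F1 selfed once), `"BC1(species)"` / `"BC2(species)"`
#' (one/two successive backcrosses to the named recurrent parent, the hybrid
#' acting as mother), `"SELFk"` (k generations of selfing), and the alias
#' `"RIL"` (= `F1 > SELF5`).  Examples: `"F1"`, `"F2"`,
#' `"BC1(longistaminata)"`, `"F1 > SELF5"`.
#'
#' @param grammar crossing-scheme string.
#' @param maternal maternal parent species of the founding F1
#'   (`"longistaminata"` or `"sativa"`).
#' @param n number of independent progeny to emit.
#' @param label entry-label prefix.
#' @return A list of class `pedigree_spec`.
#' @export
pedigree_spec <- function(grammar, maternal = "longistaminata", n = 1L,
                          label = grammar) {
  parse_pedigree(grammar)  # validate now, fail early
  structure(list(grammar = grammar, maternal = maternal, n = as.integer(n),
                 label = label), class = "pedigree_spec")
}

# Parse a crossing grammar into a list of ops: list(op = "F1"|"SELF"|"BC",
# parent = species or NA).  Errors name the offending token position.
parse_pedigree <- function(grammar) {
  tokens <- trimws(strsplit(grammar, ">", fixed = TRUE)[[1]])
  if (!length(tokens)) stop("empty pedigree grammar")
  ops <- list()
  for (t in seq_along(tokens)) {
    tok <- tokens[t]
    if (tok == "RIL") {
      ops <- c(ops, list(list(op = "F1")),
               replicate(5, list(op = "SELF"), simplify = FALSE))
    } else if (tok == "F1") {
      ops <- c(ops, list(list(op = "F1")))
    } else if (tok == "F2") {
      ops <- c(ops, list(list(op = "F1")), list(list(op = "SELF")))
    } else if (grepl("^SELF[0-9]*$", tok)) {
      k <- sub("^SELF", "", tok)
      k <- if (nzchar(k)) as.integer(k) else 1L
      ops <- c(ops, replicate(k, list(op = "SELF"), simplify = FALSE))
    } else if (grepl("^BC[0-9]+\\([a-z_]+\\)$", tok)) {
      k <- as.integer(sub("^BC([0-9]+).*$", "\\1", tok))
      parent <- sub("^BC[0-9]+\\(([a-z_]+)\\)$", "\\1", tok)
      ops <- c(ops, replicate(k, list(op = "BC", parent = parent),
                              simplify = FALSE))
    } else {
      stop("pedigree grammar parse error at token ", t, ": '", tok, "'")
    }
  }
  if (ops[[1]]$op == "BC")   # BCn implies the founding interspecific F1
    ops <- c(list(list(op = "F1")), ops)
  if (ops[[1]]$op != "F1") stop("pedigree grammar must start with F1/F2/BCn/RIL")
  if (sum(vapply(ops, function(o) o$op == "F1", TRUE)) != 1L)
    stop("pedigree grammar may contain exactly one founding F1")
  ops
}

# Founder diploid of a species: two iid Bernoulli(p) haplotypes with
# species-origin labels.
sim_founder <- function(p, species) {
  L <- length(p)
  list(h1 = rbinom(L, 1, p), h2 = rbinom(L, 1, p),
       o1 = rep(species, L), o2 = rep(species, L),
       maternal = species)
}

sim_gamete <- function(ind) {
  pick <- runif(length(ind$h1)) < 0.5
  list(h = ifelse(pick, ind$h1, ind$h2),
       o = ifelse(pick, ind$o1, ind$o2))
}

sim_cross <- function(mother, father) {
  gm <- sim_gamete(mother); gf <- sim_gamete(father)
  list(h1 = gm$h, h2 = gf$h, o1 = gm$o, o2 = gf$o,
       maternal = mother$maternal)
}

#' Simulate pedigreed interspecific progeny with ground truth
#'
#' Founder gametes are drawn from the parental species allele-frequency
#' pools; crosses follow the grammar with independent Mendelian sampling per
#' locus (unlinked loci).  True ancestry is the realized fraction of allele
#' copies per species; the maternal lineage is tracked through the chain.
#'
#' @param freqs named list of species frequency vectors, e.g.
#'   `list(longistaminata = ..., sativa = ...)`.
#' @param ped a [pedigree_spec()].
#' @return list with `genotypes` (n x L dosage matrix), `truth` (data.frame:
#'   id, pedigree, maternal, true ancestry fraction per species).
#' @export
sim_pedigree <- function(freqs, ped) {
  ops <- parse_pedigree(ped$grammar)
  species <- names(freqs)
  if (!ped$maternal %in% species)
    stop("maternal species '", ped$maternal, "' not in frequency pools")
  paternal <- setdiff(species, ped$maternal)[1]
  L <- length(freqs[[1]])
  G <- matrix(0L, ped$n, L)
  truth <- vector("list", ped$n)
  for (r in seq_len(ped$n)) {
    ind <- NULL
    for (o in ops) {
      if (o$op == "F1") {
        mom <- sim_founder(freqs[[ped$maternal]], ped$maternal)
        dad <- sim_founder(freqs[[paternal]], paternal)
        ind <- sim_cross(mom, dad)
      } else if (o$op == "SELF") {
        ind <- sim_cross(ind, ind)
      } else if (o$op == "BC") {
        if (!o$parent %in% species)
          stop("backcross parent '", o$parent, "' not in frequency pools")
        rec <- sim_founder(freqs[[o$parent]], o$parent)
        ind <- sim_cross(ind, rec)
      }
    }
    G[r, ] <- as.integer(ind$h1 + ind$h2)
    anc <- vapply(species, function(s)
      (sum(ind$o1 == s) + sum(ind$o2 == s)) / (2 * L), 0)
    truth[[r]] <- data.frame(id = paste0(ped$label, "_", r),
                             pedigree = ped$grammar,
                             maternal = ind$maternal,
                             t(anc), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(G) <- truth$id
  list(genotypes = G, truth = truth)
}

# species founder SSR haplotypes: >= 3 locus differences apart
ssr_founders <- function() {
  rbind(longistaminata = c(101L, 105L, 110L, 98L, 120L, 115L, 103L),
        sativa         = c(105L, 105L, 113L, 98L, 124L, 115L, 106L),
        barthii        = c(101L, 109L, 110L, 102L, 120L, 119L, 103L),
        glaberrima     = c(101L, 113L, 110L, 102L, 121L, 119L, 104L))
}

#' Simulate maternally inherited plastid SSR haplotypes
#'
#' Each lineage starts from its maternal species' founder haplotype and
#' accumulates stepwise (+/- 1 repeat) mutations at rate `mut_rate` per
#' locus; hybrids inherit the maternal lineage's haplotype unchanged
#' (`mutate = FALSE` rows).
#'
#' @param lineages data.frame with columns `id` and `maternal` (species) and
#'   optional logical `mutate` (default TRUE for wild/outgroup individuals).
#' @param mut_rate per-locus mutation probability.
#' @return An [ssr_table()].
#' @export
sim_plastid <- function(lineages, mut_rate = 0.02) {
  founders <- ssr_founders()
  n <- nrow(lineages)
  nl <- ncol(founders)
  mut <- lineages$mutate %||% rep(TRUE, n)
  alleles <- matrix(0L, n, nl)
  for (i in seq_len(n)) {
    h <- founders[lineages$maternal[i], ]
    if (mut[i]) {
      hit <- runif(nl) < mut_rate
      h[hit] <- h[hit] + sample(c(-1L, 1L), sum(hit), replace = TRUE)
    }
    alleles[i, ] <- h
  }
  ssr_table(lineages$id, alleles,
            loci = paste0("cpSSR", seq_len(nl)))
}

# subpop ancestry weights from geography: exp(-steepness * km to center)
gradient_q <- function(lat, lon, centers, steepness) {
  w <- vapply(seq_len(nrow(centers)), function(k)
    exp(-steepness * haversine_km(lat, lon, centers$lat[k], centers$lon[k])),
    numeric(length(lat)))
  w <- matrix(w, nrow = length(lat))
  w / rowSums(w)
}

#' Generate a full synthetic panel with ground truth
#'
#' Assembles the complete study design of a [sim_spec()]: geographically
#' structured wild subpopulations with ancestry gradients and inbreeding,
#' two domesticated groups, the outgroup pair, pedigreed hybrids, plastid
#' haplotypes, and missing-data/read-depth models.  All randomness is under
#' `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return A list of class `sim_panel`: `snp` (a [snp_matrix()]), `ssr` (an
#'   [ssr_table()]), `truth` (data.frame with per-individual species,
#'   subpop, true species-level ancestry `q_longistaminata`, `q_sativa`,
#'   `q_bg`, subpop-level `q_NW`/`q_Pan`/`q_S`, pedigree, maternal lineage,
#'   `f_is`, coordinates), and `freqs`.
#' @export
sim_panel <- function(spec) {
  set.seed(spec$seed)
  fr <- sim_frequencies(spec)
  L <- spec$n_loci
  centers <- spec$subpop_centers
  subpops <- names(spec$subpop_F)

  ids <- character(0); calls <- list(); truth <- list()
  lineage <- list()

  # --- wild species: accessions of two, grid + jitter around centers ----
  anc_adm <- spec$ancient_admixture
  for (s in seq_along(subpops)) {
    n_acc <- ceiling(spec$n_per_subpop / 2)
    # accession coordinates: jittered grid around the subpop center
    g <- expand.grid(dlat = seq(-4, 4, length.out = ceiling(sqrt(n_acc))),
                     dlon = seq(-4, 4, length.out = ceiling(sqrt(n_acc))))
    g <- g[seq_len(n_acc), ]
    alat <- centers$lat[s] + g$dlat + runif(n_acc, -0.5, 0.5)
    alon <- centers$lon[s] + g$dlon + runif(n_acc, -0.5, 0.5)
    qs <- gradient_q(alat, alon, centers, spec$mixing_steepness)
    fis <- spec$f_is[[subpops[s]]]
    adm <- if (!is.null(anc_adm) && subpops[s] %in% names(anc_adm))
      anc_adm[[subpops[s]]] else 0
    for (a in seq_len(n_acc)) {
      acc_id <- sprintf("L%s%03d", subpops[s], a)
      for (rep in 1:2) {
        i <- length(ids) + 1L
        id <- sprintf("%s.%d", acc_id, rep)
        q_sub <- qs[a, ] * (1 - adm)
        pools <- rbind(fr$p_subpop, sativa_pool = fr$p_sativa_pool)
        qv <- c(q_sub, adm)
        calls[[i]] <- sim_individual(pools, qv, fis)
        ids[i] <- id
        truth[[i]] <- data.frame(
          id = id, species = "longistaminata", subpop = subpops[s],
          accession = acc_id, lat = alat[a], lon = alon[a],
          q_longistaminata = 1 - adm, q_sativa = adm, q_bg = 0,
          q_NW = q_sub[1], q_Pan = q_sub[2], q_S = q_sub[3],
          pedigree = NA_character_, maternal = "longistaminata",
          f_is = fis, stringsAsFactors = FALSE)
        lineage[[i]] <- list(maternal = "longistaminata", mutate = TRUE)
      }
    }
  }

  # --- outgroups --------------------------------------------------------
  add_outgroup <- function(pool_row, species, subpop, n, center, calls, ids,
                           truth, lineage, fis, q_triplet) {
    for (k in seq_len(n)) {
      i <- length(ids) + 1L
      id <- sprintf("%s_%03d", toupper(subpop), k)
      calls[[i]] <- sim_individual(pool_row, 1, fis)
      ids[i] <- id
      truth[[i]] <- data.frame(
        id = id, species = species, subpop = subpop,
        accession = id, lat = center[1] + runif(1, -2, 2),
        lon = center[2] + runif(1, -2, 2),
        q_longistaminata = q_triplet[1], q_sativa = q_triplet[2],
        q_bg = q_triplet[3],
        q_NW = 0, q_Pan = 0, q_S = 0,
        pedigree = NA_character_, maternal = species,
        f_is = fis, stringsAsFactors = FALSE)
      lineage[[i]] <- list(maternal = species, mutate = TRUE)
    }
    list(calls = calls, ids = ids, truth = truth, lineage = lineage)
  }
  st <- add_outgroup(fr$p_sativa[1, ], "sativa", "sativa1", spec$n_sativa,
                     c(20, 100), calls, ids, truth, lineage,
                     spec$f_is_outgroup, c(0, 1, 0))
  st <- add_outgroup(fr$p_sativa[2, ], "sativa", "sativa2", spec$n_sativa,
                     c(35, 135), st$calls, st$ids, st$truth, st$lineage,
                     spec$f_is_outgroup, c(0, 1, 0))
  st <- add_outgroup(fr$p_bg[1, ], "barthii", "barthii", spec$n_barthii,
                     c(12, 0), st$calls, st$ids, st$truth, st$lineage,
                     spec$f_is_outgroup, c(0, 0, 1))
  st <- add_outgroup(fr$p_bg[2, ], "glaberrima", "glaberrima",
                     spec$n_glaberrima, c(10, -8), st$calls, st$ids,
                     st$truth, st$lineage, spec$f_is_outgroup, c(0, 0, 1))
  calls <- st$calls; ids <- st$ids; truth <- st$truth; lineage <- st$lineage

  # --- pedigreed hybrids ------------------------------------------------
  ped_pools <- list(longistaminata = fr$p_longi,
                    sativa = fr$p_sativa_pool)
  for (ped in spec$pedigrees) {
    res <- sim_pedigree(ped_pools, ped)
    for (r in seq_len(nrow(res$truth))) {
      i <- length(ids) + 1L
      calls[[i]] <- res$genotypes[r, ]
      ids[i] <- res$truth$id[r]
      truth[[i]] <- data.frame(
        id = res$truth$id[r], species = "control_hybrid",
        subpop = "hybrid", accession = res$truth$id[r],
        lat = NA_real_, lon = NA_real_,
        q_longistaminata = res$truth$longistaminata[r],
        q_sativa = res$truth$sativa[r], q_bg = 0,
        q_NW = 0, q_Pan = 0, q_S = 0,
        pedigree = res$truth$pedigree[r],
        maternal = res$truth$maternal[r],
        f_is = 0, stringsAsFactors = FALSE)
      lineage[[i]] <- list(maternal = res$truth$maternal[r], mutate = FALSE)
    }
  }

  G <- do.call(rbind, calls)
  rownames(G) <- ids
  truth <- do.call(rbind, truth)

  # --- missing data and read depths ------------------------------------
  n <- nrow(G)
  miss <- matrix(runif(n * L) < spec$missing_rate, n, L)
  G[miss] <- NA_integer_
  total <- matrix(rnbinom(n * L, mu = spec$depth_mean, size = spec$depth_size),
                  n, L)
  total[miss] <- 0L
  alt_p <- ifelse(is.na(G), 0, G / 2)
  altd <- matrix(rbinom(n * L, as.vector(total), as.vector(alt_p)), n, L)
  refd <- total - altd

  sites <- data.frame(chrom = paste0("chr", (seq_len(L) - 1L) %% 4L + 1L),
                      pos = 150L * ((seq_len(L) - 1L) %/% 4L) + 101L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  individuals <- data.frame(id = ids, species = truth$species,
                            accession = truth$accession,
                            lat = truth$lat, lon = truth$lon,
                            stringsAsFactors = FALSE)
  snp <- snp_matrix(G, individuals, sites, ref_depth = refd, alt_depth = altd)
  snp <- sort_sites(snp)

  lin <- data.frame(id = ids,
                    maternal = vapply(lineage, `[[`, "", "maternal"),
                    mutate = vapply(lineage, `[[`, TRUE, "mutate"),
                    stringsAsFactors = FALSE)
  ssr <- sim_plastid(lin, spec$ssr_mut_rate)

  structure(list(snp = snp, ssr = ssr, truth = truth, freqs = fr,
                 spec = spec),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:\n  ")
  print(x$snp)
  cat(sprintf("  plastid SSR table: %d individuals\n", length(x$ssr$ids)))
  invisible(x)
}

#' Six-cluster design panel for cluster-number recovery checks
#'
#' A clean realization of the all-species design as six discrete,
#' variance-homogeneous clusters: the three wild subpopulations, the two
#' domesticated groups, and the outgroup pair drawn as one pool.  Every
#' cluster gets the same moderate inbreeding so the spherical
#' equal-variance assumption behind the k-means BIC holds.
#'
#' @param seed RNG seed.
#' @param n_loci loci (default 6,000 — enough to resolve the ~0.02
#'   subpopulation differentiation).
#' @param n_per_cluster individuals per cluster.
#' @param f_is shared inbreeding coefficient.
#' @return list with `snp` (a [snp_matrix()]) and `truth` (cluster label per
#'   individual).
#' @export
sim_design_panel <- function(seed, n_loci = 6000L, n_per_cluster = 30L,
                             f_is = 0.3) {
  set.seed(seed)
  sp <- sim_spec(seed = seed, n_loci = n_loci)
  fr <- sim_frequencies(sp)
  pools <- rbind(fr$p_subpop, fr$p_sativa, bg = fr$p_bg_pool)
  G <- do.call(rbind, lapply(seq_len(nrow(pools)), function(k)
    t(vapply(seq_len(n_per_cluster),
             function(i) sim_individual(pools[k, ], 1, f_is),
             integer(n_loci)))))
  truth <- rep(rownames(pools), each = n_per_cluster)
  ids <- paste0(truth, "_", sequence(rep(n_per_cluster, nrow(pools))))
  rownames(G) <- ids
  sites <- data.frame(chrom = "chr1",
                      pos = 150L * seq_len(n_loci), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  snp <- snp_matrix(G, data.frame(id = ids, species = truth,
                                  stringsAsFactors = FALSE), sites)
  list(snp = snp, truth = truth)
}

#' Pedigree-validation panel for supervised ancestry checks
#'
#' Reference individuals drawn from homogeneous species pools (domesticated
#' Asian, wild African, outgroup pair) plus pedigreed interspecific progeny,
#' with full ground truth.  Used to validate supervised ancestry recovery
#' against Mendelian expectations (F1 at 0.5, BC1 at 0.75, BC2 at 0.875).
#'
#' @param seed RNG seed.
#' @param n_loci loci.
#' @param n_src reference individuals per predefined group.
#' @param pedigrees list of [pedigree_spec()]; the default covers F1, F2,
#'   BC1, BC2 and RILs.
#' @return list with `calls` (dosage matrix), `prior` (a [pop_prior()]:
#'   group 1 = sativa, 2 = longistaminata, 3 = outgroup pair), `truth`
#'   (data.frame for the progeny: id, pedigree, maternal, true ancestry
#'   fractions), `is_progeny` (logical row index).
#' @export
sim_pedigree_panel <- function(seed, n_loci = 1000L, n_src = 25L,
                               pedigrees = list(
                                 pedigree_spec("F1", n = 5, label = "F1"),
                                 pedigree_spec("F2", n = 5, label = "F2"),
                                 pedigree_spec("BC1(longistaminata)", n = 6,
                                               label = "BC1"),
                                 pedigree_spec("BC2(longistaminata)", n = 6,
                                               label = "BC2"),
                                 pedigree_spec("RIL", maternal = "sativa",
                                               n = 6, label = "RIL"))) {
  set.seed(seed)
  sp <- sim_spec(seed = seed, n_loci = n_loci)
  fr <- sim_frequencies(sp)
  pools <- list(sativa = fr$p_sativa_pool, longistaminata = fr$p_longi,
                bg = fr$p_bg_pool)
  src <- function(p, f_is) t(vapply(seq_len(n_src), function(i)
    sim_individual(p, 1, f_is), integer(n_loci)))
  G <- rbind(src(pools$sativa, 0.9), src(pools$longistaminata, 0.3),
             src(pools$bg, 0.9))
  rownames(G) <- paste0(rep(c("sat", "lon", "bg"), each = n_src),
                        seq_len(n_src))
  ped <- lapply(pedigrees, function(p)
    sim_pedigree(pools[c("longistaminata", "sativa")], p))
  Gh <- do.call(rbind, lapply(ped, `[[`, "genotypes"))
  truth <- do.call(rbind, lapply(ped, `[[`, "truth"))
  G <- rbind(G, Gh)
  lab <- c(rep(1:3, each = n_src), rep(NA_integer_, nrow(Gh)))
  list(calls = G, prior = pop_prior(lab, !is.na(lab)), truth = truth,
       is_progeny = c(rep(FALSE, 3 * n_src), rep(TRUE, nrow(Gh))))
}

#' Two-group panel for estimator-recovery checks
#'
#' Two groups at a target measured differentiation `F`, each of `n_ind`
#' individuals at `n_loci` unlinked loci, optional inbreeding.
#'
#' @param F target pairwise F_ST.
#' @param n_ind individuals per group.
#' @param n_loci loci.
#' @param f_is inbreeding coefficient applied to both groups.
#' @param seed RNG seed.
#' @return list with `calls` (dosage matrix), `grouping` (factor), `p1`,
#'   `p2`.
#' @export
sim_two_groups <- function(F, n_ind = 50L, n_loci = 2000L, f_is = 0,
                           seed = 1L) {
  set.seed(seed)
  p_anc <- runif(n_loci, 0.05, 0.95)
  c2 <- bn_coef(F, S = 2)
  p1 <- bn_draw(p_anc, c2)
  p2 <- bn_draw(p_anc, c2)
  G <- rbind(
    t(vapply(seq_len(n_ind), function(i) sim_individual(p1, 1, f_is),
             integer(n_loci))),
    t(vapply(seq_len(n_ind), function(i) sim_individual(p2, 1, f_is),
             integer(n_loci))))
  rownames(G) <- c(paste0("A", seq_len(n_ind)), paste0("B", seq_len(n_ind)))
  list(calls = G, grouping = factor(rep(c("A", "B"), each = n_ind)),
       p1 = p1, p2 = p2)
}

#' Emit a synthetic panel to files
#'
#' Writes the VCF (with simulated allelic depths), individual metadata CSV,
#' plastid SSR CSV and ground-truth TSV; identical spec + seed give
#' identical files.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return list of file paths plus the in-memory `sim_panel`, invisibly.
#' @export
emit_panel <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim_panel(spec)
  paths <- list(vcf = file.path(dir, "panel.vcf"),
                meta = file.path(dir, "metadata.csv"),
                ssr = file.path(dir, "ssr.csv"),
                truth = file.path(dir, "truth.tsv"))
  write_vcf(panel$snp, paths$vcf)
  utils::write.csv(panel$snp$individuals, paths$meta, row.names = FALSE,
                   quote = FALSE)
  ssr_df <- data.frame(id = panel$ssr$ids, panel$ssr$alleles)
  names(ssr_df) <- c("id", panel$ssr$loci)
  utils::write.csv(ssr_df, paths$ssr, row.names = FALSE, quote = FALSE)
  utils::write.table(panel$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(panel = panel)))
}
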