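#' Pipeline configuration
#'
#' Bundles the stage parameters of the multi-pass analysis: filter
#' settings, MCMC profile, hybrid thresholds and subset rules.
#'
#' @param filter a [filter_params()].
#' @param mcmc a [run_config()]; the default here is the reduced profile
#'   (1,000 burn-in + 5,000 reps) suitable for synthetic desk-scale panels.
#' @param thresholds a [calibrate_thresholds()] band for classification.
#' @param pass2_cutoff admixture cutoff excluding entries from the
#'   within-species pass (narrative "> 4.5 percent" rule; distinct from the
#'   classification band's 4.4 percent lower edge).
#' @param thin_km geographic thinning distance for the sampling-evenness
#'   re-analysis.
#' @param K_max DAPC search ceiling.
#' @param n_start k-means restarts.
#' @param seed global seed recorded in outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_params(),
                            mcmc = reduced_profile(),
                            thresholds = calibrate_thresholds(),
                            pass2_cutoff = 0.045,
                            thin_km = 25,
                            K_max = 9L,
                            n_start = 50L,
                            seed = 1L) {
  structure(list(filter = filter, mcmc = mcmc, thresholds = thresholds,
                 pass2_cutoff = pass2_cutoff, thin_km = thin_km,
                 K_max = K_max, n_start = n_start, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' First analysis pass: all-species structure and hybrid screen
#'
#' Filters the genotype matrix, runs replicate unsupervised admixture fits
#' over the K grid with Evanno model selection, runs DAPC, then screens for
#' putative interspecific hybrids: at the Evanno-optimal K (expected 2 for a
#' wild-species-vs-outgroups panel) the outgroup admixture of each
#' wild-labeled individual is compared against the calibrated band.
#'
#' @param m a [snp_matrix()] with species metadata.
#' @param cfg a [pipeline_config()].
#' @param focal species label of the focal wild species.
#' @return list of class `pass1_result`: `filtered` matrix, `replicates`,
#'   `evanno`, `dapc`, `q_outgroup` (per focal individual), `hybrid_ids`,
#'   `report` (data.frame).
#' @export
run_pass1 <- function(m, cfg = pipeline_config(), focal = "longistaminata") {
  mf <- filter_individuals(m, cfg$filter)
  mf <- filter_sites(mf, cfg$filter)
  reps <- fit_replicates(mf, cfg$mcmc, keep_fits = TRUE)
  ev <- evanno(reps$lnP)
  K_opt <- ev$optimal_K
  # pick the replicate with the best evidence at the optimal K
  sel <- reps$lnP[reps$lnP$K == K_opt, ]
  best_chain <- sel$chain[which.max(sel$lnP_data)]
  fit <- reps$fits[[sprintf("K%d.chain%d", K_opt, best_chain)]]
  # outgroup cluster(s): those where the focal species carries a minority
  focal_rows <- mf$individuals$species == focal
  own_cluster <- which.max(colMeans(fit$Q[focal_rows, , drop = FALSE]))
  q_outgroup <- 1 - fit$Q[, own_cluster]
  names(q_outgroup) <- mf$individuals$id
  t <- cfg$thresholds
  is_hybrid <- focal_rows & q_outgroup >= t$lower & q_outgroup <= t$upper
  d <- dapc(mf, K_max = cfg$K_max, n_start = cfg$n_start, seed = cfg$seed)
  report <- data.frame(id = mf$individuals$id,
                       species = mf$individuals$species,
                       q_outgroup = q_outgroup,
                       status = ifelse(!focal_rows, "outgroup",
                                       ifelse(is_hybrid, "putative_hybrid",
                                              "pure")),
                       stringsAsFactors = FALSE)
  structure(list(filtered = mf, replicates = reps, evanno = ev, fit = fit,
                 dapc = d, q_outgroup = q_outgroup,
                 hybrid_ids = mf$individuals$id[is_hybrid],
                 report = report, seed = cfg$seed),
            class = "pass1_result")
}

#' Second pass: within-species structure on the sub-threshold subset
#'
#' Subsets to focal-species individuals below the pass-2 admixture cutoff,
#' re-applies the site filters (MAF and presence are recomputed on the
#' subset, so the site count shrinks), and reruns the admixture replicates
#' and DAPC.
#'
#' @param m the unfiltered [snp_matrix()] fed to pass 1.
#' @param pass1 a [run_pass1()] result.
#' @param cfg a [pipeline_config()].
#' @param focal focal species label.
#' @return list of class `pass2_result`: `filtered`, `replicates`, `evanno`,
#'   `dapc`, `groups` (DAPC assignment at the optimal K).
#' @export
run_pass2 <- function(m, pass1, cfg = pipeline_config(),
                      focal = "longistaminata") {
  rep1 <- pass1$report
  keep_ids <- rep1$id[rep1$species == focal &
                        rep1$q_outgroup < cfg$pass2_cutoff]
  if (length(keep_ids) < 6)
    stop("pass-2 subset too small (", length(keep_ids), " individuals)")
  sub <- m[match(keep_ids, m$individuals$id), ]
  mf <- filter_sites(filter_individuals(sub, cfg$filter), cfg$filter)
  reps <- fit_replicates(mf, cfg$mcmc, keep_fits = TRUE)
  ev <- tryCatch(evanno(reps$lnP), error = function(e) NULL)
  d <- dapc(mf, K_max = min(cfg$K_max, nrow(mf$calls) - 1L),
            n_start = cfg$n_start, seed = cfg$seed)
  structure(list(filtered = mf, replicates = reps, evanno = ev, dapc = d,
                 groups = d$clusters$groups, seed = cfg$seed),
            class = "pass2_result")
}

#' Supervised ancestry pass at K = 3
#'
#' Individuals of each predefined group (focal wild species, domesticated
#' species, outgroup pair) with zero detected interspecific admixture in
#' pass 1 are flagged as frequency sources; supervised replicate fits are
#' averaged per entry into an ancestry-profile table for the hybrids module.
#'
#' @param m the unfiltered [snp_matrix()].
#' @param pass1 a [run_pass1()] result.
#' @param cfg a [pipeline_config()].
#' @param group_of named mapping from species label to predefined group
#'   1..3 (1 = sativa, 2 = longistaminata, 3 = barthii/glaberrima).
#' @param focal species label of the focal wild species (whose pass-1
#'   outgroup admixture is read directly; other species are measured from
#'   the opposite side of the split).
#' @param pure_max admixture below which a pass-1 individual counts as a
#'   zero-admixture reference (default 0.5 percent).
#' @return data.frame of ancestry profiles (`entry`, `q_sativa`,
#'   `q_longistaminata`, `q_barthii_glaberrima`, `species_label`).
#' @export
run_supervised <- function(m, pass1, cfg = pipeline_config(),
                           group_of = c(sativa = 1, longistaminata = 2,
                                        barthii = 3, glaberrima = 3),
                           focal = "longistaminata",
                           pure_max = 0.005) {
  mf <- pass1$filtered
  sp <- mf$individuals$species
  qo <- pass1$q_outgroup
  labels <- unname(group_of[sp])
  # purity is measured toward the individual's own side of the pass-1
  # wild-vs-outgroups split
  own_adm <- ifelse(sp == focal, qo, 1 - qo)
  flags <- !is.na(labels) & own_adm <= pure_max &
    sp %in% names(group_of)
  for (k in 1:3) {
    members <- !is.na(labels) & labels == k
    if (!any(members))
      stop("predefined group ", k, " has no members")
    if (!any(flags & members)) {
      # no member passes the purity cutoff (small panels estimate admixture
      # noisily): fall back to the three least-admixed members
      take <- which(members)[order(own_adm[members])[seq_len(min(3, sum(members)))]]
      flags[take] <- TRUE
      message("group ", k, ": no zero-admixture reference; using the ",
              length(take), " least-admixed members")
    }
  }
  prior <- pop_prior(ifelse(flags, labels, NA_integer_), flags)
  cfgK <- cfg$mcmc
  Qsum <- 0
  for (ch in seq_len(cfgK$n_chains)) {
    fit <- fit_supervised(mf, 3L, prior, cfgK, chain = ch)
    Qsum <- Qsum + fit$Q
  }
  Q <- Qsum / cfgK$n_chains
  data.frame(entry = mf$individuals$id,
             q_sativa = Q[, 1], q_longistaminata = Q[, 2],
             q_barthii_glaberrima = Q[, 3],
             species_label = sp, stringsAsFactors = FALSE)
}

#' Cross-tabulate two group assignments after label matching
#'
#' Cluster labels are arbitrary; the labels of `b` are first mapped onto
#' those of `a` by greedy maximum agreement over the shared individuals,
#' then moved individuals are listed.
#'
#' @param a,b named vectors (or factors) of group labels; names are
#'   individual ids.
#' @return list: `table` (cross-tabulation), `moved` (data.frame id,
#'   from, to), `mapping` (b-label -> a-label).
#' @export
compare_assignments <- function(a, b) {
  ids <- intersect(names(a), names(b))
  if (!length(ids)) stop("assignments share no individuals")
  a <- as.character(a[ids]); b <- as.character(b[ids])
  la <- unique(a); lb <- unique(b)
  agree <- outer(lb, la, Vectorize(function(x, y) sum(b == x & a == y)))
  mapping <- setNames(rep(NA_character_, length(lb)), lb)
  A <- agree
  for (step in seq_len(min(length(lb), length(la)))) {
    best <- which(A == max(A), arr.ind = TRUE)[1, ]
    mapping[lb[best[1]]] <- la[best[2]]
    A[best[1], ] <- -1; A[, best[2]] <- -1
  }
  # unmatched b labels keep their own name
  mapping[is.na(mapping)] <- names(mapping)[is.na(mapping)]
  b_mapped <- unname(mapping[b])
  moved <- data.frame(id = ids, from = a, to = b_mapped,
                      stringsAsFactors = FALSE)
  moved <- moved[moved$from != moved$to, ]
  list(table = table(from = a, to = b_mapped), moved = moved,
       mapping = mapping)
}
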