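#' Reference hybrid-panel Q values
#'
#' Published supervised (K = 3) ancestry proportions for the rice
#' interspecific hybrid reference panel: 17 known *O. sativa* x
#' *O. longistaminata* progeny from a controlled cross (one F1, two F2, 14
#' RILs) and 19 putative recent hybrids detected among genebank
#' *O. longistaminata* accessions.  Columns: `entry`, `q_sativa`,
#' `q_longistaminata`, `q_barthii_glaberrima`, `origin`, `type`
#' (control/putative).
#'
#' @return data.frame of 36 entries.
#' @export
hybrid_panel <- function() {
  path <- system.file("extdata", "hybrid_panel_q.tsv", package = "obake")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Calibrate hybrid-classification thresholds from control hybrids
#'
#' The lower threshold is the minimum outgroup-admixture value observed in
#' control interspecific RILs, rounded down to 3 decimals and lowered by one
#' grid step (0.001) so the band contains every control; the band is
#' symmetric (`upper = 1 - lower`).  Without controls the default band is
#' (0.044, 0.956).
#'
#' @param controls numeric vector of control outgroup-admixture values in
#'   (0, 1), or NULL.
#' @return A list of class `hybrid_thresholds` with `lower`, `upper`,
#'   `calibration`.
#' @export
calibrate_thresholds <- function(controls = NULL) {
  if (is.null(controls) || !length(controls)) {
    lower <- 0.044
  } else {
    if (any(controls <= 0 | controls >= 1))
      stop("control admixture values must lie strictly in (0, 1)")
    # the band is symmetric, so a control at admixture c and one at 1 - c
    # constrain it equally: fold onto the nearer simplex corner first
    m <- min(pmin(controls, 1 - controls))
    lower <- floor(m * 1000) / 1000 - 0.001
    lower <- max(lower, .Machine$double.eps)
  }
  structure(list(lower = lower, upper = 1 - lower,
                 calibration = controls),
            class = "hybrid_thresholds")
}

#' @export
print.hybrid_thresholds <- function(x, ...) {
  cat(sprintf("hybrid_thresholds: putative-hybrid band [%.3f, %.3f]\n",
              x$lower, x$upper))
  invisible(x)
}

#' Ancestry profile of one entry
#'
#' @param entry entry id.
#' @param q_sativa,q_longistaminata,q_barthii_glaberrima supervised ancestry
#'   proportions (replicate means); must sum to 1 within 0.02.
#' @param species_label nominal species of the entry
#'   (`"longistaminata"`, `"sativa"`, `"control_hybrid"`, ...).
#' @param plastid_group maternal plastid group
#'   (`"longistaminata"`, `"sativa"`, `"barthii"`) or NA.
#' @param origin free-text origin label.
#' @return A list of class `ancestry_profile`.
#' @export
ancestry_profile <- function(entry, q_sativa, q_longistaminata,
                             q_barthii_glaberrima,
                             species_label = "longistaminata",
                             plastid_group = NA_character_,
                             origin = NA_character_) {
  tot <- q_sativa + q_longistaminata + q_barthii_glaberrima
  if (abs(tot - 1) > 0.02)
    stop("Q components of '", entry, "' sum to ", round(tot, 3),
         "; expected 1 within 0.02")
  structure(list(entry = entry, q_sativa = q_sativa,
                 q_longistaminata = q_longistaminata,
                 q_barthii_glaberrima = q_barthii_glaberrima,
                 species_label = species_label,
                 plastid_group = plastid_group, origin = origin),
            class = "ancestry_profile")
}

outgroup_admixture <- function(p, sativa_only = FALSE) {
  if (identical(p$species_label, "sativa")) {
    1 - p$q_sativa
  } else if (sativa_only) {
    p$q_sativa
  } else {
    1 - p$q_longistaminata
  }
}

#' Classify an entry as pure or putative interspecific hybrid
#'
#' The outgroup admixture of a longistaminata-labeled entry is its total
#' non-conspecific ancestry `1 - Q_longistaminata` (symmetric for
#' sativa-labeled entries); the entry is a putative hybrid iff that value
#' lies inside the calibrated band.  The introgression direction compares
#' the two focal components: `into_sativa` when `Q_sativa >
#' Q_longistaminata` (domesticated genome carries the wild introgression),
#' `into_longistaminata` for the converse, `balanced` on an exact tie.
#'
#' @param p an [ancestry_profile()].
#' @param t a [calibrate_thresholds()] band.
#' @param sativa_only measure admixture as `Q_sativa` alone instead of total
#'   non-conspecific ancestry.
#' @return A list of class `hybrid_call` with `entry`, `status`,
#'   `outgroup_admixture`, `direction`, `generation_band` (filled by
#'   [generation_band()]), `flag_borderline` (TRUE inside [0.044, 0.045)).
#' @export
classify_hybrid <- function(p, t = calibrate_thresholds(),
                            sativa_only = FALSE) {
  adm <- outgroup_admixture(p, sativa_only = sativa_only)
  hybrid <- adm >= t$lower & adm <= t$upper
  direction <- if (!hybrid) "none"
  else if (p$q_sativa > p$q_longistaminata) "into_sativa"
  else if (p$q_longistaminata > p$q_sativa) "into_longistaminata"
  else "balanced"
  structure(list(entry = p$entry,
                 status = if (hybrid) "putative_hybrid" else "pure",
                 outgroup_admixture = adm,
                 direction = direction,
                 generation_band = "none",
                 flag_borderline = adm >= 0.044 & adm < 0.045,
                 profile = p),
            class = "hybrid_call")
}

#' Assign a putative hybrid to a generation band
#'
#' The minority-parent proportion `q_min = min(Q_sativa, Q_longistaminata)`
#' is compared with pedigree expectations: F1/F2 at 0.5, BC1 at 0.25, BC2 at
#' 0.125, each within a half-width `delta`; anything else is `advanced`.
#' Overlapping bands resolve in that order.
#'
#' @param call a [classify_hybrid()] result with status `putative_hybrid`.
#' @param delta band half-width (default 0.06, wide enough to contain the
#'   F1/F2 controls at 0.46-0.49 minority ancestry).
#' @return The `hybrid_call` with `generation_band` set to one of `F1_F2`,
#'   `BC1`, `BC2`, `advanced`.
#' @export
generation_band <- function(call, delta = 0.06) {
  if (call$status != "putative_hybrid")
    stop("generation band is defined only for putative hybrids")
  p <- call$profile
  q_min <- min(p$q_sativa, p$q_longistaminata)
  band <- if (abs(q_min - 0.5) <= delta) "F1_F2"
  else if (abs(q_min - 0.25) <= delta) "BC1"
  else if (abs(q_min - 0.125) <= delta) "BC2"
  else "advanced"
  call$generation_band <- band
  call
}

#' Cytonuclear consistency check
#'
#' The maternal parent is read off the (maternally inherited) plastid group;
#' the call is consistent when the maternal species also contributes nuclear
#' ancestry.
#'
#' @param p an [ancestry_profile()].
#' @return list with `maternal_parent` and `consistent` (both NA when the
#'   plastid group is missing).
#' @export
cytonuclear_check <- function(p) {
  if (is.na(p$plastid_group))
    return(list(maternal_parent = NA_character_, consistent = NA))
  q_maternal <- switch(p$plastid_group,
                       longistaminata = p$q_longistaminata,
                       sativa = p$q_sativa,
                       barthii = p$q_barthii_glaberrima,
                       0)
  list(maternal_parent = p$plastid_group, consistent = q_maternal > 0)
}

#' Classify a whole table of ancestry profiles
#'
#' @param profiles data.frame with columns `entry`, `q_sativa`,
#'   `q_longistaminata`, `q_barthii_glaberrima` and optionally
#'   `species_label`, `plastid_group`, `origin`.
#' @param t a [calibrate_thresholds()] band.
#' @param delta generation-band half-width.
#' @param sativa_only see [classify_hybrid()].
#' @return data.frame, one row per entry: Q triple, `status`,
#'   `outgroup_admixture`, `direction`, `generation_band`,
#'   `maternal_parent`, `cytonuclear_consistent`, `flag_borderline`.
#' @export
classify_panel <- function(profiles, t = calibrate_thresholds(),
                           delta = 0.06, sativa_only = FALSE) {
  rows <- lapply(seq_len(nrow(profiles)), function(r) {
    row <- profiles[r, ]
    p <- ancestry_profile(row$entry, row$q_sativa, row$q_longistaminata,
                          row$q_barthii_glaberrima,
                          species_label = row$species_label %||% "longistaminata",
                          plastid_group = row$plastid_group %||% NA_character_,
                          origin = row$origin %||% NA_character_)
    call <- classify_hybrid(p, t, sativa_only = sativa_only)
    if (call$status == "putative_hybrid") call <- generation_band(call, delta)
    cy <- cytonuclear_check(p)
    data.frame(entry = p$entry, q_sativa = p$q_sativa,
               q_longistaminata = p$q_longistaminata,
               q_barthii_glaberrima = p$q_barthii_glaberrima,
               status = call$status,
               outgroup_admixture = call$outgroup_admixture,
               direction = call$direction,
               generation_band = call$generation_band,
               maternal_parent = cy$maternal_parent,
               cytonuclear_consistent = cy$consistent,
               flag_borderline = call$flag_borderline,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Low-level admixture summary among sub-threshold individuals
#'
#' Per group, the mean and range of each outgroup ancestry component among
#' individuals classified pure (below the hybrid band) — the summary used to
#' separate ancient low-level introgression from recent hybridization.
#'
#' @param profiles data.frame as in [classify_panel()].
#' @param grouping group label per profile row.
#' @param t a [calibrate_thresholds()] band.
#' @return data.frame per group and component: `group`, `component`,
#'   `mean`, `min`, `max`, `n`.
#' @export
low_level_admixture_summary <- function(profiles, grouping,
                                        t = calibrate_thresholds()) {
  calls <- classify_panel(profiles, t)
  pure <- calls$status == "pure"
  grouping <- as.factor(grouping)
  out <- list()
  for (g in levels(grouping)) {
    rows <- pure & grouping == g
    if (!any(rows)) {
      warning("group '", g, "' has no sub-threshold individuals; omitted")
      next
    }
    for (comp in c("q_sativa", "q_barthii_glaberrima")) {
      v <- calls[[comp]][rows]
      out[[length(out) + 1]] <- data.frame(
        group = g, component = comp, mean = mean(v), min = min(v),
        max = max(v), n = sum(rows), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
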