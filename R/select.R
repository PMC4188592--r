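#' Criteria constants for significant-concentration threshold selection
#'
#' The published selection procedure weighs several expert-judgment criteria
#' simultaneously; this object makes every constant explicit so a selection
#' is auditable and repeatable.
#'
#' @param jump_min minimum successive area ratio for a step to qualify as
#'   the defining jump (default 1.2 -- the sponge-ground worked case
#'   qualified at 1.25).
#' @param min_new_points minimum number of new point observations that must
#'   support a jump; below it the jump is a "single point" artefact
#'   (default 3).
#' @param min_spread minimum count of new points required inside the
#'   bridging region of a polygon merge for the merge to count as evidence
#'   of a continuous distribution (default 2).
#' @param low_density_fraction fraction of the candidate threshold below
#'   which the mean density of newly added area marks the jump as "new area
#'   of very low density" (default 0.5).
#' @param plateau_tol maximum relative area change (ratio - 1) that counts
#'   as the flat "establishment" phase of the curve (default 0.10).
#' @return Object of class `vme_criteria`.
#' @export
selection_criteria <- function(jump_min = 1.2, min_new_points = 3,
                               min_spread = 2, low_density_fraction = 0.5,
                               plateau_tol = 0.10) {
  stopifnot(jump_min > 1, min_new_points > 0, min_spread > 0,
            low_density_fraction > 0, plateau_tol > 0)
  structure(list(jump_min = jump_min, min_new_points = min_new_points,
                 min_spread = min_spread,
                 low_density_fraction = low_density_fraction,
                 plateau_tol = plateau_tol),
            class = "vme_criteria")
}

# establishment bookkeeping shared by find_candidates / select_threshold:
# first non-empty step, and the step where the curve first flattens
.curve_phases <- function(curve, criteria) {
  a <- curve$summary$total_area_km2
  r <- curve$summary$area_ratio
  f <- which(a > 0)[1]
  if (is.na(f)) return(list(first = NA_integer_, established = NA_integer_))
  est <- which(seq_along(r) > f & !is.na(r) & r <= 1 + criteria$plateau_tol)[1]
  list(first = f, established = est)
}

#' Find candidate threshold jumps on a threshold-area curve
#'
#' A candidate is a successive pair of thresholds whose area ratio is at
#' least `jump_min`, occurring after the curve has established: after the
#' first non-empty step the curve must first flatten to within
#' `plateau_tol` (the high-biomass aggregation cores are fully mapped)
#' before a jump can mark the transition to dispersed individuals.
#' Candidates are returned in decreasing order of area ratio.
#'
#' @param curve a `vme_curve` from [build_curve()].
#' @param criteria a [selection_criteria()] object.
#' @return Data frame with one row per candidate: `step` (index into
#'   `curve$steps`), `upper_level`, `lower_level`, `area_ratio`,
#'   `n_new_points`, `n_new_points_in_new_areas`, `n_merges`.
#' @export
find_candidates <- function(curve, criteria = selection_criteria()) {
  if (nrow(curve$summary) < 3) stop("curve needs at least 3 steps")
  ph <- .curve_phases(curve, criteria)
  s <- curve$summary
  empty <- data.frame(step = integer(0), upper_level = numeric(0),
                      lower_level = numeric(0), area_ratio = numeric(0),
                      n_new_points = integer(0),
                      n_new_points_in_new_areas = integer(0),
                      n_merges = integer(0))
  if (is.na(ph$first) || is.na(ph$established)) return(empty)
  j <- which(seq_len(nrow(s)) > ph$established & !is.na(s$area_ratio) &
             s$area_ratio >= criteria$jump_min)
  if (!length(j)) return(empty)
  out <- data.frame(step = j,
                    upper_level = s$threshold[j - 1],
                    lower_level = s$threshold[j],
                    area_ratio = s$area_ratio[j],
                    n_new_points = s$n_new_points[j],
                    n_new_points_in_new_areas = s$n_new_points_in_new_areas[j],
                    n_merges = s$n_merges[j])
  out[order(-out$area_ratio), , drop = FALSE]
}

#' Rejection flags for a candidate threshold jump
#'
#' Encodes the published cases for rejecting an area jump:
#' \describe{
#'   \item{`single-point-jump`}{the area increase rests on fewer than
#'     `min_new_points` new observations (e.g. a jump "created through the
#'     inclusion of a datum").}
#'   \item{`merge-without-support`}{more than half of the step's area
#'     growth comes from polygon merges whose bridging regions contain
#'     fewer than `min_spread` new points -- little evidence of a
#'     continuous distribution between the joined aggregations.}
#'   \item{`low-density-new-area`}{the newly added area has mean density
#'     below `low_density_fraction` times the candidate threshold.}
#' }
#'
#' @param candidate one row of [find_candidates()] output.
#' @param curve the `vme_curve` the candidate came from.
#' @param criteria a [selection_criteria()] object.
#' @return Character vector of flags (empty when the candidate stands).
#' @export
apply_rejection_rules <- function(candidate, curve, criteria = selection_criteria()) {
  flags <- character(0)
  st <- curve$steps[[candidate$step]]
  if (st$n_new_points < criteria$min_new_points)
    flags <- c(flags, "single-point-jump")
  if (length(st$merges)) {
    unsupported <- sum(vapply(st$merges, function(m)
      if (m$support_points < criteria$min_spread) max(m$growth_km2, 0) else 0,
      numeric(1)))
    growth <- st$cell_area_km2 -
      curve$steps[[candidate$step - 1]]$cell_area_km2
    if (growth > 0 && unsupported > 0.5 * growth)
      flags <- c(flags, "merge-without-support")
  }
  if (is.finite(st$mean_new_area_value) &&
      st$mean_new_area_value < criteria$low_density_fraction * candidate$upper_level)
    flags <- c(flags, "low-density-new-area")
  flags
}

#' Select the significant-concentration threshold from a curve
#'
#' Candidates (area jumps of at least `jump_min` after establishment) are
#' taken in decreasing order of area ratio; the rejection rules act as a
#' veto, and the selected threshold is the *upper* level of the first
#' unflagged candidate -- the catch weight whose polygons delimit the
#' aggregations just before the curve inflates with dispersed individuals.
#' When every candidate is vetoed, or no jump qualifies, no threshold is
#' returned and the audit trail explains why.
#'
#' @param curve a `vme_curve`.
#' @param criteria a [selection_criteria()] object.
#' @return Object of class `vme_selection`: list with `selected_threshold`
#'   (`NA` when none), `selected_step`, `candidates` (with a `flags`
#'   list-column), `curve_flags` (`gradual-increase` when the curve never
#'   flattens, `no-large-jump` when no qualifying jump exists) and
#'   `narrative` (character lines).
#' @export
select_threshold <- function(curve, criteria = selection_criteria()) {
  ph <- .curve_phases(curve, criteria)
  cand <- find_candidates(curve, criteria)
  narrative <- character(0)
  curve_flags <- character(0)
  say <- function(...) narrative <<- c(narrative, sprintf(...))

  if (is.na(ph$first)) {
    say("no threshold encloses any area; nothing to select")
    curve_flags <- "no-large-jump"
  } else if (is.na(ph$established)) {
    say("curve grows at every step and never flattens below %.0f%%: gradual increase, no aggregation signal",
        100 * criteria$plateau_tol)
    curve_flags <- "gradual-increase"
  } else {
    say("aggregations established by the %.4g threshold (area change within %.0f%%)",
        curve$summary$threshold[ph$established], 100 * criteria$plateau_tol)
    if (!nrow(cand)) {
      say("no successive area ratio reaches %.3g after establishment: no large jump",
          criteria$jump_min)
      curve_flags <- "no-large-jump"
    }
  }

  flags <- vector("list", nrow(cand))
  selected <- NA_real_
  selected_step <- NA_integer_
  if (nrow(cand)) for (i in seq_len(nrow(cand))) {
    fl <- apply_rejection_rules(cand[i, ], curve, criteria)
    flags[[i]] <- fl
    say("candidate %.4g -> %.4g: area x%.3g on %d new points (%d in new areas, %d merges)%s",
        cand$upper_level[i], cand$lower_level[i], cand$area_ratio[i],
        cand$n_new_points[i], cand$n_new_points_in_new_areas[i],
        cand$n_merges[i],
        if (length(fl)) paste0(" REJECTED: ", paste(fl, collapse = ", ")) else " ACCEPTED")
    if (!length(fl) && is.na(selected)) {
      selected <- cand$upper_level[i]
      selected_step <- cand$step[i]
    }
  }
  if (nrow(cand) && is.na(selected))
    say("every candidate vetoed; no significant-concentration threshold with sufficient support")
  if (!is.na(selected))
    say("selected threshold: %.4g (upper level of the accepted jump)", selected)
  cand$flags <- flags
  structure(list(selected_threshold = selected, selected_step = selected_step,
                 candidates = cand, curve_flags = curve_flags,
                 narrative = narrative, criteria = criteria),
            class = "vme_selection")
}

#' @export
print.vme_selection <- function(x, ...) {
  cat("<vme_selection>\n")
  for (l in x$narrative) cat(" ", l, "\n")
  invisible(x)
}

#' Biomass and area fractions enclosed by threshold polygons
#'
#' For a selected threshold this reports how concentrated the taxon is: the
#' fraction of total recorded biomass falling inside the polygons, and the
#' polygon area as a fraction of the sampled area.  By default the sampled
#' area is estimated as the convex hull of all trawl-set locations
#' (including zero catches); pass `sampled_area_km2` to use an explicit
#' survey-footprint mask instead.
#'
#' @param surface the `vme_surface` the polygons were contoured from.
#' @param polys a `vme_polygons` object (may be empty).
#' @param records records whose biomass is accounted (typically the
#'   harmonized positive catches); zero-biomass rows, when present,
#'   contribute to the sampled-area hull only.
#' @param sampled_area_km2 optional explicit sampled area.
#' @return List with `biomass_fraction`, `area_fraction`,
#'   `enclosed_biomass_kg`, `total_biomass_kg`, `polygon_area_km2` and
#'   `sampled_area_km2`.
#' @export
summarize_enclosure <- function(surface, polys, records, sampled_area_km2 = NULL) {
  df <- as.data.frame(records)
  total <- sum(df$biomass, na.rm = TRUE)
  if (total <= 0) stop("zero total biomass: nothing to enclose")
  if (is.null(sampled_area_km2))
    sampled_area_km2 <- convex_hull_area(df$x, df$y) / 1e6
  if (is.null(polys) || !length(polys$rings))
    return(list(biomass_fraction = 0, area_fraction = 0,
                enclosed_biomass_kg = 0, total_biomass_kg = total,
                polygon_area_km2 = 0, sampled_area_km2 = sampled_area_km2))
  pos <- df[df$biomass > 0, ]
  inside <- surface_value_at(surface, pos$x, pos$y) >= polys$level
  enclosed <- sum(pos$biomass[inside])
  list(biomass_fraction = enclosed / total,
       area_fraction = polys$total_area_km2 / sampled_area_km2,
       enclosed_biomass_kg = enclosed, total_biomass_kg = total,
       polygon_area_km2 = polys$total_area_km2,
       sampled_area_km2 = sampled_area_km2)
}
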