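#' Two-sample Kolmogorov-Smirnov test on catch-weight samples
#'
#' D is the supremum absolute difference between the two empirical CDFs.
#' The p-value is exact when `min(n_a, n_b) <= 25` and asymptotic otherwise;
#' Table-style survey comparisons involve hundreds of records per group, for
#' which the asymptotic null is the appropriate regime.  Catch weights are
#' recorded to finite precision, so ties can occur; with ties the exact
#' p-value is unavailable and the approximate one is used silently.
#'
#' @param a,b numeric biomass samples (kg), each nonempty.
#' @return List with `ks_stat`, `p_value`, `n_a`, `n_b` and `unreliable`
#'   (`TRUE` when either sample has fewer than 10 values).
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty sample in KS test")
  exact <- min(length(a), length(b)) <= 25
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(ks_stat = unname(kt$statistic), p_value = min(1, unname(kt$p.value)),
       n_a = length(a), n_b = length(b),
       unreliable = min(length(a), length(b)) < 10)
}

#' Ladder of KS tests over ascending catch-weight thresholds
#'
#' For each threshold `t` the two samples are restricted to `{x >= t}` and
#' compared with [ks_two_sample()].  Levels where either restricted sample
#' has fewer than `min_n` values are reported but flagged
#' `insufficient_n` and excluded from threshold decisions.
#'
#' @param a,b numeric biomass samples (kg).
#' @param thresholds strictly increasing vector of catch-weight levels (kg).
#'   A threshold of 0 compares the strictly positive catches (zero catches
#'   are absences, not weights).
#' @param alpha significance level (default 0.05).
#' @param min_n minimum restricted sample size for a usable level (default 5).
#' @param group_a,group_b labels carried into the output.
#' @return Data frame of class `vme_ks_ladder`: one row per threshold with
#'   `threshold`, `n_a`, `n_b`, `ks_stat`, `p_value`, `significant`,
#'   `insufficient_n`.
#' @export
threshold_ladder <- function(a, b, thresholds, alpha = 0.05, min_n = 5,
                             group_a = "A", group_b = "B") {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (!length(a) || !length(b)) stop("empty sample")
  rows <- lapply(thresholds, function(t) {
    ra <- a[if (t > 0) a >= t else a > 0]
    rb <- b[if (t > 0) b >= t else b > 0]
    if (length(ra) < min_n || length(rb) < min_n) {
      return(data.frame(threshold = t, n_a = length(ra), n_b = length(rb),
                        ks_stat = NA_real_, p_value = NA_real_,
                        significant = NA, insufficient_n = TRUE))
    }
    k <- ks_two_sample(ra, rb)
    data.frame(threshold = t, n_a = k$n_a, n_b = k$n_b,
               ks_stat = k$ks_stat, p_value = k$p_value,
               significant = k$p_value < alpha, insufficient_n = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("vme_ks_ladder", "data.frame"),
            alpha = alpha, group_a = group_a, group_b = group_b)
}

# lowest usable level that is non-significant and has no significant usable
# level above it; NA when no level qualifies
.ladder_decision <- function(ladder) {
  ok <- !ladder$insufficient_n
  if (!any(ok)) return(NA_real_)
  sig <- ladder$significant & ok
  qual <- vapply(seq_len(nrow(ladder)), function(i) {
    ok[i] && !ladder$significant[i] && !any(sig[seq_len(nrow(ladder)) > i])
  }, logical(1))
  if (!any(qual)) return(NA_real_)
  ladder$threshold[which(qual)[1]]
}

#' Harmonize multi-survey catch records for one taxon
#'
#' Reproduces the two-stage pooling decision used for multi-gear trawl
#' series.  Stage 1: within the dominant gear, catches from the two tow
#' durations are compared over the threshold ladder; the duration threshold
#' is the lowest level that is non-significant with no significant level
#' above it.  Stage 2: the pooled dominant-gear catches (at or above the
#' duration threshold) are compared against the other gear over the ladder
#' levels from that threshold upward.  The combinable threshold is the
#' larger of the two.  No multiple-testing correction is applied across
#' ladder levels; each level is judged at `alpha` on its own, mirroring the
#' published procedure (noted in `decision_note`).
#'
#' When pooling at the combinable threshold would leave fewer than 10% of
#' the positive records, the result recommends fitting separate regional
#' models instead (the small-gorgonian situation).
#'
#' @param records a `vme_records` data frame with `gear` and (optionally)
#'   `duration` and `taxon` columns.
#' @param taxon taxon label; when the records carry a `taxon` column the
#'   collection is subset to it.
#' @param thresholds ascending ladder of catch-weight levels (kg).  Default
#'   `c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 10)`.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum restricted sample size per level (default 5).
#' @return Object of class `vme_harmonization`: list with `taxon`,
#'   `duration_threshold`, `gear_threshold`, `combinable_threshold`,
#'   `ladder` (row-bound `vme_ks_ladder`s with a `comparison` column) and
#'   `decision_note`.
#' @export
harmonize_surveys <- function(records, taxon = NULL,
                              thresholds = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 10),
                              alpha = 0.05, min_n = 5) {
  df <- as.data.frame(records)
  if (!is.null(taxon) && "taxon" %in% names(df)) df <- df[df$taxon == taxon, ]
  if (!nrow(df)) stop("no records for taxon ", taxon)
  pos <- df[df$biomass > 0, ]

  gears <- if ("gear" %in% names(df)) unique(df$gear) else character(0)
  durs  <- if ("duration" %in% names(df)) unique(df$duration[!is.na(df$duration)]) else numeric(0)

  result <- function(dur_thr, gear_thr, ladder, note) {
    comb <- if (is.na(dur_thr) || (length(gears) > 1 && is.na(gear_thr))) NA_real_
            else max(dur_thr, gear_thr, na.rm = TRUE)
    structure(list(taxon = taxon %||% "all",
                   duration_threshold = dur_thr, gear_threshold = gear_thr,
                   combinable_threshold = comb, ladder = ladder,
                   decision_note = note),
              class = "vme_harmonization")
  }

  if (length(gears) <= 1 && length(durs) <= 1)
    return(result(0, NA_real_, NULL,
                  "single gear and duration group: no harmonization needed"))

  notes <- c("per-level KS tests at alpha with no multiple-testing correction across ladder levels")
  ladders <- list()

  # stage 1: duration ladder within the dominant gear (or all records when
  # a single gear is present)
  if (length(gears) > 1) {
    ngear <- table(pos$gear)
    main_gear <- names(ngear)[which.max(ngear)]
    main <- pos[pos$gear == main_gear, ]
  } else {
    main_gear <- if (length(gears)) gears else "all"
    main <- pos
  }
  dur_thr <- 0
  if (length(unique(main$duration[!is.na(main$duration)])) > 1) {
    nd <- sort(table(main$duration), decreasing = TRUE)
    d1 <- as.numeric(names(nd)[1]); d2 <- as.numeric(names(nd)[2])
    lad <- threshold_ladder(main$biomass[main$duration == d1],
                            main$biomass[main$duration == d2],
                            thresholds, alpha, min_n,
                            group_a = paste0(main_gear, " ", d1, " min"),
                            group_b = paste0(main_gear, " ", d2, " min"))
    lad$comparison <- "duration"
    ladders$duration <- lad
    dur_thr <- .ladder_decision(lad)
    if (is.na(dur_thr))
      notes <- c(notes, "no ladder level harmonizes the tow durations")
  } else {
    notes <- c(notes, "single duration group: duration threshold trivially 0")
  }

  # stage 2: pooled dominant gear vs the other gear, from dur_thr upward
  gear_thr <- if (length(gears) > 1) NA_real_ else 0
  if (length(gears) > 1 && !is.na(dur_thr)) {
    other <- pos[pos$gear != main_gear, ]
    ogear <- names(sort(table(other$gear), decreasing = TRUE))[1]
    other <- other[other$gear == ogear, ]
    lvls <- thresholds[thresholds >= dur_thr]
    pooled <- main$biomass[if (dur_thr > 0) main$biomass >= dur_thr else main$biomass > 0]
    if (length(lvls) && nrow(other)) {
      lad2 <- threshold_ladder(pooled, other$biomass, lvls, alpha, min_n,
                               group_a = paste0("pooled ", main_gear),
                               group_b = ogear)
      lad2$comparison <- "gear"
      ladders$gear <- lad2
      gear_thr <- .ladder_decision(lad2)
      if (is.na(gear_thr))
        notes <- c(notes, "no ladder level harmonizes the gear types")
    }
  }

  ladder <- if (length(ladders)) do.call(rbind, ladders) else NULL
  comb <- if (is.na(dur_thr) || (length(gears) > 1 && is.na(gear_thr))) NA_real_
          else max(dur_thr, gear_thr, na.rm = TRUE)
  if (!is.na(comb)) {
    frac <- mean(pos$biomass >= max(comb, .Machine$double.xmin))
    if (comb == 0) frac <- 1
    if (frac < 0.10)
      notes <- c(notes, sprintf(
        paste0("pooling at %.3g kg keeps only %.1f%% of positive records; ",
               "consider separate per-region models instead of pooled KDE"),
        comb, 100 * frac))
  } else {
    notes <- c(notes, "surveys not combinable over this ladder; fit separate per-survey/region models")
  }
  result(dur_thr, gear_thr, ladder, paste(notes, collapse = "; "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vme_harmonization <- function(x, ...) {
  cat("<vme_harmonization>", x$taxon, "\n")
  cat(sprintf("  duration threshold: %s kg\n  gear threshold: %s kg\n  combinable: %s kg\n",
              format(x$duration_threshold), format(x$gear_threshold),
              format(x$combinable_threshold)))
  cat("  note:", x$decision_note, "\n")
  invisible(x)
}

#' Export a harmonization ladder as CSV
#'
#' One row per (comparison, threshold) pair with sample sizes, D and p --
#' the layout of a survey-comparison summary table.
#'
#' @param x a `vme_harmonization` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_harmonization_csv <- function(x, path) {
  lad <- x$ladder
  if (is.null(lad)) lad <- data.frame()
  write.csv(as.data.frame(lad), path, row.names = FALSE)
  invisible(path)
}
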