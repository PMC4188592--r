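#' Construct an analysis extent
#'
#' Planar bounding box in projected meters.  All analysis is done in a single
#' projected coordinate system (the original application used UTM NAD83 Zone
#' 23); the package never reprojects -- coordinates must arrive planar.
#'
#' @param xmin,ymin,xmax,ymax planar bounds (m).
#' @return An object of class `vme_extent` with fields `xmin`, `ymin`,
#'   `xmax`, `ymax`, `width`, `height`.
#' @export
extent <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.finite(xmin), is.finite(ymin), is.finite(xmax), is.finite(ymax))
  if (xmax <= xmin || ymax <= ymin)
    stop("degenerate extent: xmax must exceed xmin and ymax must exceed ymin")
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                 width = xmax - xmin, height = ymax - ymin),
            class = "vme_extent")
}

#' @export
print.vme_extent <- function(x, ...) {
  cat(sprintf("<vme_extent> [%g, %g] x [%g, %g]  (%.3g m x %.3g m)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$width, x$height))
  invisible(x)
}

#' Bounding extent of survey records
#'
#' Tight bounding box of the trawl-set start positions.  The extent drives
#' the default kernel search radius and cell size, so at least two distinct
#' locations are required.
#'
#' @param records a `vme_records` data frame (see [read_survey_records()]).
#' @return A [extent()] object.
#' @export
data_extent <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 records to define an extent")
  xr <- range(records$x); yr <- range(records$y)
  if (xr[1] == xr[2] && yr[1] == yr[2])
    stop("degenerate extent: all points coincident")
  if (xr[1] == xr[2] || yr[1] == yr[2])
    stop("degenerate extent: zero width or height")
  extent(xr[1], yr[1], xr[2], yr[2])
}

.required_fields <- c("x", "y", "biomass")
.optional_fields <- c("survey_id", "gear", "duration", "speed", "taxon")

#' Read and validate trawl-survey point-biomass records
#'
#' Reads a delimited text file with one row per trawl set, applies a column
#' mapping, validates the field invariants (finite planar coordinates,
#' biomass >= 0, duration > 0, speed > 0 when present) and returns the clean
#' rows as a `vme_records` data frame.  Rows failing validation are dropped
#' with row-indexed diagnostics attached as `attr(x, "rejected")`; the count
#' of zero-biomass (null) sets is reported via `attr(x, "n_zero_biomass")`.
#'
#' Zero-biomass sets are retained in the collection: they inform diagnostics
#' (e.g. isolated records surrounded by null sets, sampled-area estimation)
#' but are excluded from kernel density input by default.
#'
#' @param path CSV file path (header row, "." decimal point).
#' @param column_map named character vector mapping package field names
#'   (`x`, `y`, `biomass`, and optionally `survey_id`, `gear`, `duration`,
#'   `speed`, `taxon`) to column names in the file.  Defaults to identity.
#' @param crs_note free-text note recording the projected CRS of the
#'   coordinates (metadata only; no reprojection is performed).
#' @return A data frame of class `vme_records` with attributes `crs`,
#'   `rejected` (data frame of row index + reason) and `n_zero_biomass`.
#' @export
read_survey_records <- function(path, column_map = NULL, crs_note = "unspecified planar CRS") {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  as_survey_records(raw, column_map = column_map, crs_note = crs_note)
}

#' Validate a data frame of trawl-set records
#'
#' Workhorse behind [read_survey_records()]; accepts an in-memory data frame
#' (columns may be character, as read from text) and applies the same
#' mapping and validation.
#'
#' @inheritParams read_survey_records
#' @param df data frame with one row per trawl set.
#' @return A `vme_records` data frame; see [read_survey_records()].
#' @export
as_survey_records <- function(df, column_map = NULL, crs_note = "unspecified planar CRS") {
  fields <- c(.required_fields, .optional_fields)
  map <- setNames(fields, fields)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), fields)
    if (length(bad)) stop("unknown field(s) in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing_req <- .required_fields[!map[.required_fields] %in% names(df)]
  if (length(missing_req))
    stop("missing required column(s): ",
         paste(map[missing_req], collapse = ", "), call. = FALSE)

  present <- fields[map[fields] %in% names(df)]
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(df), ncol = 0))
  for (f in present) out[[f]] <- df[[map[[f]]]]

  numeric_fields <- intersect(c("x", "y", "biomass", "duration", "speed"), present)
  reasons <- rep(NA_character_, nrow(out))
  note <- function(idx, msg) {
    reasons[idx & is.na(reasons)] <<- msg
  }
  for (f in numeric_fields) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- !is.na(out[[f]]) & out[[f]] != "" & is.na(v)
    note(bad, paste0("non-numeric ", f))
    out[[f]] <- v
  }
  note(!is.finite(out$x) | !is.finite(out$y), "missing or non-finite coordinate")
  note(is.na(out$biomass), "missing biomass")
  note(!is.na(out$biomass) & out$biomass < 0, "negative biomass")
  if ("duration" %in% present)
    note(!is.na(out$duration) & out$duration <= 0, "non-positive duration")
  if ("speed" %in% present)
    note(!is.na(out$speed) & out$speed <= 0, "non-positive speed")

  bad <- !is.na(reasons)
  rejected <- data.frame(row = which(bad), reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("%d row(s) rejected during validation; see attr(x, 'rejected')",
                    nrow(rejected)), call. = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("vme_records", "data.frame"),
            crs = crs_note,
            rejected = rejected,
            n_zero_biomass = sum(out$biomass == 0))
}

#' Write survey records back to CSV
#'
#' Values are written with full precision (`format(..., digits = 15)` via
#' `write.csv`) so that a write/read round trip preserves every field for
#' finite decimal inputs.
#'
#' @param records a `vme_records` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Tow length from vessel speed and duration
#'
#' Trawl length in nautical miles: speed (knots) x duration (hours).  Used
#' for catch-weight vs. tow-length diagnostics; records without a speed are
#' returned as `NA` (unavailable, not an error).
#'
#' @param records a `vme_records` data frame, or anything with `speed` and
#'   `duration` columns.
#' @return Numeric vector of tow lengths (nmi), `NA` where speed is absent.
#' @export
compute_tow_length <- function(records) {
  if (!all(c("duration") %in% names(records)))
    stop("records carry no duration field")
  dur <- records$duration
  if (any(!is.na(dur) & dur <= 0)) stop("non-positive duration")
  if (!"speed" %in% names(records)) return(rep(NA_real_, nrow(records)))
  sp <- records$speed
  if (any(!is.na(sp) & sp <= 0)) stop("non-positive speed")
  sp * dur / 60
}

#' Extent to JSON
#'
#' @param x a [extent()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extent_json <- function(x, path) {
  jsonlite::write_json(unclass(x)[c("xmin", "ymin", "xmax", "ymax")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
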