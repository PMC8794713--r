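# Domain tables, readers/writers and calendar conventions.
#
# Tables are plain data.frames with documented columns (see README).  The
# landscape is a list of habitat patches carrying planar polygon geometry.
# Dates are ISO strings on disk and Date objects in memory.

#' Canonical habitat categories
#'
#' The five reserved habitat labels; every other label is namespaced under
#' \code{"other:<label>"} when a landscape is read, and rare habitats are
#' pooled into \code{"other"} by the compositional stage.
#' @export
CANONICAL_HABITATS <- c("winter_wheat", "sugar_beet", "corn",
                        "annual_flower_strip", "field_path")

#' Normalize a habitat label
#'
#' Reserved labels pass through; anything else becomes \code{other:<label>}.
#'
#' @param label Character vector of habitat labels.
#' @return Character vector of normalized labels.
#' @export
normalize_habitat <- function(label) {
  ifelse(label %in% CANONICAL_HABITATS | startsWith(label, "other"),
         label, paste0("other:", label))
}

#' Study configuration
#'
#' Bundles the analysis conventions shared by all stages.  \code{day_one}
#' is a month-day string applied within each calendar year (day 1 of the
#' breeding season; default April 25, the earliest documented hatch date).
#'
#' @param day_one Month-day string "MM-DD" marking day 1 of the season.
#' @param home_range_percentile Distance percentile defining the shared
#'   home-range radius, in (0, 1].
#' @param pseudo_absences_per_home_range Pseudo-absence points drawn per
#'   home range.
#' @param n_randomizations Iterations for the compositional randomization
#'   test.
#' @param frequent_habitat_fraction Fraction of home ranges in which a
#'   habitat must occur to get its own compositional category.
#' @param mcp_fraction Fraction of points retained by the minimum convex
#'   polygon (0.95 for MCP95).
#' @param mcp_min_points Minimum landing points for a nest to enter the
#'   MCP analysis.
#' @param rng_seed Integer seed; mandatory for every stochastic stage.
#' @return A list of class \code{study_config}.
#' @export
study_config <- function(day_one = "04-25",
                         home_range_percentile = 0.95,
                         pseudo_absences_per_home_range = 240L,
                         n_randomizations = 1000L,
                         frequent_habitat_fraction = 1 / 3,
                         mcp_fraction = 0.95,
                         mcp_min_points = 20L,
                         rng_seed = 1L) {
  stopifnot(home_range_percentile > 0, home_range_percentile <= 1,
            frequent_habitat_fraction > 0, frequent_habitat_fraction <= 1,
            mcp_fraction > 0, mcp_fraction <= 1,
            pseudo_absences_per_home_range >= 1, n_randomizations >= 1,
            is.numeric(rng_seed), length(rng_seed) == 1)
  structure(list(day_one = day_one,
                 home_range_percentile = home_range_percentile,
                 pseudo_absences_per_home_range = as.integer(pseudo_absences_per_home_range),
                 n_randomizations = as.integer(n_randomizations),
                 frequent_habitat_fraction = frequent_habitat_fraction,
                 mcp_fraction = mcp_fraction,
                 mcp_min_points = as.integer(mcp_min_points),
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

#' Day of the breeding season
#'
#' Day 1 is \code{day_one} (April 25 by default) of the date's own year;
#' each calendar day increments the index by 1.  Dates before day 1 give
#' values <= 0 with a warning.
#'
#' @param date A Date vector.
#' @param config A [study_config()].
#' @return Integer vector of season days.
#' @export
day_of_season <- function(date, config = study_config()) {
  date <- as.Date(date)
  origin <- as.Date(paste0(format(date, "%Y"), "-", config$day_one))
  d <- as.integer(date - origin) + 1L
  if (any(d <= 0L, na.rm = TRUE))
    warning("date(s) before season day one; day_of_season <= 0")
  d
}

# --- landscape ---------------------------------------------------------

new_patch <- function(patch_id, habitat_type, year, geometry) {
  geometry <- as.matrix(geometry)
  if (nrow(geometry) < 3L)
    stop("patch ", patch_id, ": polygon needs >= 3 vertices")
  a <- poly_area(geometry)
  if (!is.finite(a) || a <= 0)
    stop("patch ", patch_id, ": polygon has zero or invalid area")
  list(patch_id = patch_id,
       habitat_type = habitat_type,
       year = as.integer(year),
       geometry = ccw(geometry),
       area_m2 = a,
       bbox = c(min(geometry[, 1]), max(geometry[, 1]),
                min(geometry[, 2]), max(geometry[, 2])))
}

#' Assemble a landscape from patch descriptions
#'
#' @param patches List of lists with patch_id, habitat_type, year and a
#'   two-column vertex matrix \code{geometry}.
#' @param year Study year of the mosaic.
#' @return A list of class \code{landscape} with validated patches.
#' @export
make_landscape <- function(patches, year) {
  known <- vapply(patches, function(p) p$habitat_type, "")
  unknown <- setdiff(unique(known),
                     c(CANONICAL_HABITATS, grep("^other", unique(known), value = TRUE)))
  if (length(unknown))
    warning("habitat label(s) mapped to other:* namespace: ",
            paste(unknown, collapse = ", "))
  built <- lapply(patches, function(p)
    new_patch(p$patch_id, normalize_habitat(p$habitat_type), year, p$geometry))
  ids <- vapply(built, function(p) p$patch_id, "")
  if (anyDuplicated(ids))
    stop("duplicate patch_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(year = as.integer(year), patches = built), class = "landscape")
}

#' Read a landscape from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features (outer ring only) with
#' \code{patch_id}, \code{habitat_type} and \code{year} properties and
#' planar metric coordinates.  Unknown habitat labels are namespaced under
#' \code{other:} with a warning; malformed geometry or a missing
#' habitat_type is a hard error naming the feature.
#'
#' @param path GeoJSON file path.
#' @param year Study year to select (features of other years are dropped).
#' @return A \code{landscape}.
#' @export
read_landscape <- function(path, year) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  patches <- list()
  for (f in gj$features) {
    pr <- f$properties
    if (is.null(pr$patch_id)) stop("feature without patch_id in ", path)
    if (is.null(pr$habitat_type))
      stop("feature ", pr$patch_id, ": missing habitat_type")
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature ", pr$patch_id, ": geometry type must be Polygon")
    if (!is.null(pr$year) && as.integer(pr$year) != as.integer(year)) next
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    # drop the closing vertex GeoJSON requires
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3L || poly_area(xy) <= 0)
      stop("feature ", pr$patch_id, ": malformed or zero-area polygon")
    patches[[length(patches) + 1L]] <-
      list(patch_id = pr$patch_id, habitat_type = pr$habitat_type, geometry = xy)
  }
  make_landscape(patches, year)
}

#' Write a landscape to GeoJSON
#'
#' @param landscape A \code{landscape}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  feats <- lapply(landscape$patches, function(p) {
    ring <- rbind(p$geometry, p$geometry[1, ])
    list(type = "Feature",
         properties = list(patch_id = p$patch_id,
                           habitat_type = p$habitat_type,
                           year = p$year),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- tabular data ------------------------------------------------------

table_files <- c(nests = "nests.csv", sessions = "sessions.csv",
                 landing_points = "landing_points.csv",
                 arthropod_samples = "arthropod_samples.csv",
                 vegetation = "vegetation.csv")

#' Read the observation tables of a data directory
#'
#' Reads nests, sessions, landing points, arthropod samples and vegetation
#' records, coerces types, and validates cross-references and invariants
#' (see [validate_dataset()]).  A dangling foreign key, a session longer
#' than 90 min or more than 10 landing points per session is a hard error.
#'
#' @param dir_path Directory containing the CSV tables.
#' @return A named list of data.frames (a \code{lark_data} object).
#' @export
read_tables <- function(dir_path) {
  tabs <- lapply(table_files, function(f) {
    p <- file.path(dir_path, f)
    if (!file.exists(p)) stop("missing table: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  names(tabs) <- names(table_files)
  tabs$nests$hatch_date <- as.Date(tabs$nests$hatch_date)
  tabs$sessions$date <- as.Date(tabs$sessions$date)
  tabs$arthropod_samples$date <- as.Date(tabs$arthropod_samples$date)
  tabs$vegetation$date <- as.Date(tabs$vegetation$date)
  validate_dataset(tabs)
  tabs
}

#' Write the observation tables to a data directory
#'
#' @param data Named list of tables as returned by [read_tables()] or the
#'   synthetic generator.
#' @param dir_path Output directory (created if absent).
#' @return \code{dir_path}, invisibly.
#' @export
write_tables <- function(data, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(table_files))
    utils::write.csv(data[[nm]], file.path(dir_path, table_files[[nm]]),
                     row.names = FALSE)
  invisible(dir_path)
}

#' Validate dataset integrity
#'
#' Checks id uniqueness, foreign keys (landing point -> session -> nest,
#' sample/vegetation patch ids are not checked against a landscape here),
#' session duration <= 90 min and <= 10 landing points per session.
#'
#' @param data Named list of tables.
#' @return \code{TRUE} invisibly; errors describe every violation found.
#' @export
validate_dataset <- function(data) {
  errs <- character(0)
  if (anyDuplicated(data$nests$nest_id))
    errs <- c(errs, "duplicate nest_ids")
  if (anyDuplicated(data$sessions$session_id))
    errs <- c(errs, "duplicate session_ids")
  bad <- setdiff(data$sessions$nest_id, data$nests$nest_id)
  if (length(bad))
    errs <- c(errs, paste("sessions reference unknown nests:",
                          paste(bad, collapse = ", ")))
  bad <- setdiff(data$landing_points$session_id, data$sessions$session_id)
  if (length(bad))
    errs <- c(errs, paste("landing points reference unknown sessions:",
                          paste(bad, collapse = ", ")))
  bad <- setdiff(data$landing_points$nest_id, data$nests$nest_id)
  if (length(bad))
    errs <- c(errs, paste("landing points reference unknown nests:",
                          paste(bad, collapse = ", ")))
  too_long <- data$sessions$session_id[data$sessions$duration_min > 90 |
                                         data$sessions$duration_min <= 0]
  if (length(too_long))
    errs <- c(errs, paste("sessions with duration outside (0, 90] min:",
                          paste(too_long, collapse = ", ")))
  cnt <- table(data$landing_points$session_id)
  if (any(cnt > 10))
    errs <- c(errs, paste("sessions with > 10 landing points:",
                          paste(names(cnt)[cnt > 10], collapse = ", ")))
  if (any(data$sessions$chick_age_days < 0))
    errs <- c(errs, "negative chick ages")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(TRUE)
}

#' Keep only landing points with a certain location
#'
#' Points whose exact landing spot was ambiguous in the field
#' (\code{safe = FALSE}) are excluded once, centrally, before any analysis.
#'
#' @param points Landing-point table.
#' @return List with \code{points} (safe subset) and \code{summary}
#'   (n_total, n_safe, n_excluded, excluded_pct rounded to one decimal;
#'   excluded_pct is NA for empty input).
#' @export
filter_safe_points <- function(points) {
  n <- nrow(points)
  keep <- if (n) points[points$safe, , drop = FALSE] else points
  list(points = keep,
       summary = list(
         n_total = n,
         n_safe = nrow(keep),
         n_excluded = n - nrow(keep),
         excluded_pct = if (n) round(100 * (n - nrow(keep)) / n, 1) else NA_real_))
}

#' Nest accounting summary
#'
#' Counts nests by status and reports the number of nests analyzable for
#' foraging observation (status \code{"observed"}): found nests minus those
#' inactive before observation, with unobservable surroundings, or with
#' chicks already (about to be) fledged when found.
#'
#' @param nests Nest table with a \code{status} column.
#' @return Named list of counts.
#' @export
nest_accounting <- function(nests) {
  tab <- table(factor(nests$status,
                      levels = c("observed", "inactive_before_observation",
                                 "unobservable", "chicks_too_old")))
  list(n_found = nrow(nests),
       n_inactive = unname(tab[["inactive_before_observation"]]),
       n_unobservable = unname(tab[["unobservable"]]),
       n_chicks_too_old = unname(tab[["chicks_too_old"]]),
       n_observed = unname(tab[["observed"]]))
}

#' Chick starvation summary
#'
#' @param nests Nest table with \code{n_chicks} and \code{n_starved}.
#' @return List with total chicks, starved chicks, and the starvation
#'   percentage rounded to one decimal.
#' @export
chick_starvation <- function(nests) {
  tot <- sum(nests$n_chicks, na.rm = TRUE)
  st <- sum(nests$n_starved, na.rm = TRUE)
  list(n_chicks = tot, n_starved = st,
       starved_pct = if (tot) round(100 * st / tot, 1) else NA_real_)
}
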