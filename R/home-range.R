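# Home ranges: a single study-wide radius from the nest-weighted distance
# percentile, per-nest discs clipped against the habitat mosaic, and plain
# or distance-weighted habitat availability plus realized habitat use.

# Euclidean distance from each landing point to its own nest.
point_nest_distances <- function(nests, points) {
  idx <- match(points$nest_id, nests$nest_id)
  if (anyNA(idx)) stop("landing points reference unknown nests")
  sqrt((points$x - nests$x[idx])^2 + (points$y - nests$y[idx])^2)
}

#' Weighted percentile with equal weight per nest
#'
#' Each point carries weight 1/n_i (n_i = points of its nest); the
#' percentile is the smallest distance whose cumulative normalized weight
#' reaches \code{percentile} (no interpolation), which is well defined
#' under unequal weights.
#'
#' @param nests Nest table.
#' @param landing_points Safe landing points.
#' @param percentile Probability in (0, 1].
#' @return Radius in meters.
#' @export
estimate_radius <- function(nests, landing_points, percentile = 0.95) {
  stopifnot(percentile > 0, percentile <= 1)
  pts <- landing_points[landing_points$safe, , drop = FALSE]
  if (!nrow(pts)) stop("no safe landing points")
  d <- point_nest_distances(nests, pts)
  w <- 1 / table(pts$nest_id)[pts$nest_id]
  o <- order(d)
  cw <- cumsum(as.numeric(w[o])) / sum(w)
  d[o][which(cw >= percentile - 1e-12)[1]]
}

#' Build a fixed-radius home range around a nest
#'
#' The disc is approximated by a 256-vertex polygon and every overlapping
#' patch is clipped against it; unmapped area inside the disc is recorded
#' as a coverage gap, never silently renormalized away.
#'
#' @param nest One-row nest table (or list with nest_id, x, y).
#' @param landscape A \code{landscape}.
#' @param radius_m Shared home-range radius (m).
#' @param n_vertices Disc polygon resolution.
#' @return A list of class \code{home_range}.
#' @export
build_home_range <- function(nest, landscape, radius_m, n_vertices = 256L) {
  stopifnot(radius_m > 0)
  center <- c(nest$x, nest$y)
  # circumscribed polygon: the closed disc (points at d == radius) is fully
  # inside, at the cost of a ~1e-4 relative area overshoot
  disc <- disc_polygon(center, radius_m / cos(pi / n_vertices), n_vertices)
  disc_area <- poly_area(disc)
  keep <- list()
  for (p in landscape$patches) {
    if (p$bbox[1] > center[1] + radius_m || p$bbox[2] < center[1] - radius_m ||
        p$bbox[3] > center[2] + radius_m || p$bbox[4] < center[2] - radius_m)
      next
    # a patch whose vertices all lie within the radius sits inside the
    # (circumscribed) disc polygon: no clipping needed
    vd2 <- (p$geometry[, 1] - center[1])^2 + (p$geometry[, 2] - center[2])^2
    cl <- if (max(vd2) <= radius_m^2) p$geometry
          else clip_polygon(p$geometry, disc)
    if (nrow(cl) >= 3L) {
      a <- poly_area(cl)
      if (a > 0)
        keep[[length(keep) + 1L]] <- list(patch_id = p$patch_id,
                                          habitat_type = p$habitat_type,
                                          geometry = cl, area_m2 = a,
                                          bbox = c(range(cl[, 1]), range(cl[, 2])))
    }
  }
  covered <- sum(vapply(keep, function(p) p$area_m2, 0))
  structure(list(nest_id = nest$nest_id, center = center,
                 radius_m = radius_m, patches = keep,
                 disc_area_m2 = disc_area,
                 coverage_gap_m2 = max(0, disc_area - covered)),
            class = "home_range")
}

#' Nest-weighted flight-distance profile
#'
#' Histogram estimate of the pooled distance-use distribution f(d), with
#' each nest contributing total weight 1; the spatial availability weight
#' of a grid cell at distance d is then f(d) / (2 pi d).
#'
#' @param nests Nest table.
#' @param landing_points Safe landing points (all nests pooled).
#' @param bin_m Histogram bin width (m).
#' @return List of class \code{distance_profile} with breaks and density.
#' @export
distance_profile <- function(nests, landing_points, bin_m = 10) {
  pts <- landing_points[landing_points$safe, , drop = FALSE]
  if (nrow(pts) < 50)
    stop("need >= 50 safe landing points to estimate the distance profile")
  d <- point_nest_distances(nests, pts)
  w <- as.numeric(1 / table(pts$nest_id)[pts$nest_id])
  breaks <- seq(0, max(d) + bin_m, by = bin_m)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  dens <- numeric(length(breaks) - 1L)
  agg <- tapply(w, bin, sum)
  dens[as.integer(names(agg))] <- agg / (sum(w) * bin_m)
  structure(list(breaks = breaks, density = dens, bin_m = bin_m),
            class = "distance_profile")
}

profile_density <- function(profile, d) {
  bin <- findInterval(d, profile$breaks, rightmost.closed = TRUE)
  out <- numeric(length(d))
  ok <- bin >= 1L & bin <= length(profile$density)
  out[ok] <- profile$density[bin[ok]]
  out
}

#' Habitat availability within a home range
#'
#' Discretizes the disc on a square grid; with \code{weighting =
#' "distance"} each cell is weighted by f(d) / (2 pi d), the per-unit-area
#' intensity implied by the pooled distance-use profile, so near-nest area
#' counts more; with \code{weighting = "flat"} the result equals the plain
#' area share.  Cells in coverage gaps are excluded from the denominator
#' and reported.
#'
#' @param home_range A \code{home_range}.
#' @param profile A [distance_profile()] (required for distance weighting).
#' @param grid_m Grid cell size (m); must be <= radius / 10.
#' @param weighting "distance" or "flat".
#' @return List with \code{available} (habitat, available_pct),
#'   \code{coverage_gap_pct} and \code{n_cells}.
#' @export
weighted_surface_area <- function(home_range, profile = NULL, grid_m = 5,
                                  weighting = c("distance", "flat")) {
  weighting <- match.arg(weighting)
  r <- home_range$radius_m
  if (grid_m > r / 10) stop("grid_m coarser than radius/10")
  if (weighting == "distance" && is.null(profile))
    stop("distance weighting needs a distance_profile")
  m <- ceiling(r / grid_m)
  off <- (seq(-m, m - 1L) + 0.5) * grid_m   # symmetric about the nest
  gx <- rep(home_range$center[1] + off, times = length(off))
  gy <- rep(home_range$center[2] + off, each = length(off))
  d <- sqrt((gx - home_range$center[1])^2 + (gy - home_range$center[2])^2)
  keep <- d <= r
  gx <- gx[keep]; gy <- gy[keep]; d <- d[keep]
  loc <- locate_points(structure(list(year = NA_integer_,
                                      patches = home_range$patches),
                                 class = "landscape"), gx, gy)
  w <- if (weighting == "flat") rep(1, length(d)) else
    profile_density(profile, d) / (2 * pi * pmax(d, grid_m / 2))
  mapped <- !is.na(loc$habitat_type)
  tot <- sum(w[mapped])
  if (tot <= 0) stop("no weight on mapped cells; check the distance profile")
  agg <- tapply(w[mapped], loc$habitat_type[mapped], sum)
  data_av <- data.frame(habitat = names(agg),
                        available_pct = 100 * as.numeric(agg) / tot,
                        stringsAsFactors = FALSE)
  list(available = data_av[order(-data_av$available_pct), ],
       coverage_gap_pct = 100 * sum(!mapped) / length(mapped),
       n_cells = length(mapped))
}

#' Realized habitat use within a home range
#'
#' The share of a nest's in-range safe landing points per habitat, using
#' the mapped habitat at each point's coordinates (the field-observed label
#' is kept for QC).  Disc membership is closed: points exactly on the
#' radius are included.
#'
#' @param home_range A \code{home_range}.
#' @param landing_points Safe landing points of the nest.
#' @return List with \code{use} (habitat, n_points, used_pct),
#'   \code{n_in_range}, \code{n_out_of_range}, \code{n_unmapped} and
#'   \code{empty} flag.
#' @export
habitat_use <- function(home_range, landing_points) {
  pts <- landing_points[landing_points$nest_id == home_range$nest_id &
                          landing_points$safe, , drop = FALSE]
  d <- sqrt((pts$x - home_range$center[1])^2 + (pts$y - home_range$center[2])^2)
  inr <- d <= home_range$radius_m + 1e-9
  pin <- pts[inr, , drop = FALSE]
  loc <- locate_points(structure(list(year = NA_integer_,
                                      patches = home_range$patches),
                                 class = "landscape"), pin$x, pin$y)
  mapped <- !is.na(loc$habitat_type)
  n_use <- table(loc$habitat_type[mapped])
  use <- data.frame(habitat = names(n_use), n_points = as.integer(n_use),
                    used_pct = 100 * as.integer(n_use) / nrow(pin),
                    stringsAsFactors = FALSE)
  list(use = use[order(-use$used_pct), ],
       n_in_range = nrow(pin),
       n_out_of_range = sum(!inr),
       n_unmapped = sum(!mapped),
       empty = nrow(pin) == 0L)
}
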