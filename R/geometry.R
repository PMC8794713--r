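# Planar polygon primitives.  All coordinates are metric (meters) in a
# projected frame; distances are Euclidean.  Polygons are two-column
# matrices of vertices (one ring, not closed: the last vertex differs from
# the first); orientation is normalized where it matters.

#' Signed area of a polygon ring (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param xy Two-column numeric matrix of vertices (open ring).
#' @return Signed area in squared input units.
#' @keywords internal
poly_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Unsigned polygon area
#' @inheritParams poly_area_signed
#' @return Area (>= 0) in squared input units.
#' @export
poly_area <- function(xy) abs(poly_area_signed(xy))

#' Regular polygon approximation of a disc
#'
#' @param center Numeric length-2, disc center (m).
#' @param radius Disc radius in m.
#' @param n Number of vertices (default 256).
#' @return Counter-clockwise two-column vertex matrix.
#' @export
disc_polygon <- function(center, radius, n = 256L) {
  stopifnot(radius > 0, n >= 8L)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radius * cos(theta), center[2] + radius * sin(theta))
}

# Ensure counter-clockwise orientation.
ccw <- function(xy) if (poly_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy

#' Clip a polygon against a convex polygon (Sutherland--Hodgman)
#'
#' The clip polygon must be convex (the home-range disc always is); the
#' subject polygon may be concave.  Degenerate results (area ~ 0) return a
#' zero-row matrix.
#'
#' @param subject Two-column vertex matrix (open ring), any orientation.
#' @param clip Convex two-column vertex matrix (open ring).
#' @return Clipped polygon vertex matrix (possibly zero rows).
#' @export
clip_polygon <- function(subject, clip) {
  out <- ccw(subject)
  cl <- ccw(clip)
  nc <- nrow(cl)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- cl[i, ]
    b <- cl[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    inside <- side >= 0
    if (all(inside)) next
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    crossing <- inside != inside[nxt]
    t <- ifelse(crossing, side / (side - side[nxt]), NA_real_)
    ix <- out[, 1] + t * (out[nxt, 1] - out[, 1])
    iy <- out[, 2] + t * (out[nxt, 2] - out[, 2])
    # slot 2j-1 holds vertex j (if inside), slot 2j its exit/entry point
    xs <- rep(NA_real_, 2L * n); ys <- xs
    xs[2L * seq_len(n) - 1L][inside] <- out[inside, 1]
    ys[2L * seq_len(n) - 1L][inside] <- out[inside, 2]
    xs[2L * seq_len(n)][crossing] <- ix[crossing]
    ys[2L * seq_len(n)][crossing] <- iy[crossing]
    keep <- !is.na(xs)
    out <- cbind(xs[keep], ys[keep])
  }
  if (nrow(out) >= 3L && poly_area(out) > 1e-9) unname(out) else out[0, , drop = FALSE]
}

#' Test points for inclusion in a polygon (even-odd ray casting)
#'
#' Vectorized over points.  Points exactly on an edge may fall on either
#' side; callers that care about boundaries (the disc) test distances
#' directly instead.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column vertex matrix (open ring).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Locate points in a landscape
#'
#' Assigns each point the patch (and habitat) whose polygon contains it,
#' using bounding-box prefilters.  Points in no patch get NA.  Where thin
#' patches (field paths) overlap field edges, the later patch in the
#' landscape order wins, so linear features drawn on top of fields are
#' honored.
#'
#' @param landscape A landscape object (see [read_landscape()]).
#' @param px,py Point coordinates (m).
#' @return data.frame with columns patch_id, habitat_type (NA when unmapped).
#' @export
locate_points <- function(landscape, px, py) {
  patch_id <- rep(NA_character_, length(px))
  habitat <- rep(NA_character_, length(px))
  for (p in landscape$patches) {
    bb <- p$bbox
    cand <- which(px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4])
    if (!length(cand)) next
    hit <- cand[point_in_polygon(px[cand], py[cand], p$geometry)]
    if (length(hit)) {
      patch_id[hit] <- p$patch_id
      habitat[hit] <- p$habitat_type
    }
  }
  data.frame(patch_id = patch_id, habitat_type = habitat,
             stringsAsFactors = FALSE)
}

#' Area of the convex hull of a point set
#'
#' @param xy Two-column coordinate matrix.
#' @return Hull area; 0 when fewer than 3 distinct points.
#' @export
convex_hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) return(0)
  poly_area(xy[h, , drop = FALSE])
}
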