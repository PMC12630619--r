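# Cross-sectional geometry (CSG) of cortical bone rings.
#
# A diaphyseal cross-section is modelled as a cortical ring bounded by a
# periosteal (outer) and an endosteal (inner) polygonal contour in a fixed
# anatomical frame: +y anterior, +x lateral (right-side convention). All
# engineering-beam quantities (CA, TA, second moments of area, polar section
# modulus) follow from exact polygon moment formulas (Green's theorem) and
# composite-area subtraction of the medullary cavity.

# ---- low-level polygon machinery -------------------------------------------

# drop a duplicated closing vertex, coerce to n x 2 numeric matrix
as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L) stop("a ring must be an n x 2 matrix", call. = FALSE)
  storage.mode(ring) <- "double"
  if (anyNA(ring)) stop("ring coordinates contain NA", call. = FALSE)
  n <- nrow(ring)
  if (n >= 2L && isTRUE(all.equal(ring[1L, ], ring[n, ],
                                  check.attributes = FALSE))) {
    ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(ring) < 3L) stop("a ring needs at least 3 distinct vertices",
                            call. = FALSE)
  ring
}

signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# normalize winding to counterclockwise (positive signed area)
normalize_winding <- function(ring) {
  if (signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

# O(n^2) segment-intersection check; interior crossings only
is_simple_ring <- function(ring) {
  n <- nrow(ring)
  p <- ring
  q <- ring[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    # skip adjacent edges (share a vertex)
    j <- setdiff(seq.int(i + 1L, n), c(i + 1L, if (i == 1L) n))
    if (!length(j)) next
    d1 <- cross2(q[i, ] - p[i, ], p[j, , drop = FALSE] -
                   matrix(p[i, ], length(j), 2L, byrow = TRUE))
    d2 <- cross2(q[i, ] - p[i, ], q[j, , drop = FALSE] -
                   matrix(p[i, ], length(j), 2L, byrow = TRUE))
    d3 <- cross2_rows(q[j, , drop = FALSE] - p[j, , drop = FALSE],
                      matrix(p[i, ], length(j), 2L, byrow = TRUE) -
                        p[j, , drop = FALSE])
    d4 <- cross2_rows(q[j, , drop = FALSE] - p[j, , drop = FALSE],
                      matrix(q[i, ], length(j), 2L, byrow = TRUE) -
                        p[j, , drop = FALSE])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# cross product of one vector with rows of a matrix
cross2 <- function(v, m) v[1L] * m[, 2L] - v[2L] * m[, 1L]
# rowwise cross products of two matrices
cross2_rows <- function(a, b) a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]

# even-odd point-in-polygon, vectorized over points
points_in_ring <- function(pts, ring) {
  x <- pts[, 1L]; y <- pts[, 2L]
  inside <- rep(FALSE, length(x))
  n <- nrow(ring)
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Area, centroid and second moments of a simple polygon
#'
#' Exact Green's-theorem moment formulas for a simple closed polygon. The
#' winding is normalized to counterclockwise so the area is positive; the
#' second moments `Ix`, `Iy`, `Ixy` are reported about axes through the
#' polygon's own centroid.
#'
#' @param ring n x 2 matrix of ordered vertices (closed implicitly; a
#'   duplicated last vertex is tolerated), at least 3 vertices.
#' @param check Verify that the ring is simple (non-self-intersecting);
#'   default `TRUE`.
#' @return List with `area`, `centroid` (length-2), `Ix`, `Iy`, `Ixy`.
#' @examples
#' sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
#' polygon_moments(sq)  # area 1, Ix = Iy = 1/12
#' @export
polygon_moments <- function(ring, check = TRUE) {
  ring <- normalize_winding(as_ring(ring))
  a <- signed_area(ring)
  if (a <= 0 || !is.finite(a)) {
    stop("degenerate ring: non-positive area", call. = FALSE)
  }
  if (check && !is_simple_ring(ring)) {
    stop("self-intersecting ring", call. = FALSE)
  }
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ix0 <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iy0 <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy0 <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = a, centroid = c(cx, cy),
       Ix = ix0 - a * cy^2, Iy = iy0 - a * cx^2, Ixy = ixy0 - a * cx * cy)
}

# ---- section contour container ---------------------------------------------

#' Construct a diaphyseal section contour
#'
#' Pairs a periosteal (outer) and an endosteal (inner) ring in the
#' anatomical frame +y = anterior, +x = lateral. Rings are validated
#' (simple, endosteal strictly inside periosteal) and their winding
#' normalized to counterclockwise.
#'
#' @param specimen_id,element,location_label Metadata; `location_label` is a
#'   percentage of biomechanical length (`"20"`, `"35"`, `"50"`, `"65"`,
#'   `"80"`) or `"IC"` for the radial interosseous crest.
#' @param periosteal,endosteal n x 2 vertex matrices (>= 8 vertices each),
#'   coordinates in mm.
#' @param side `"L"` or `"R"`. Left sections are mirrored to the right-side
#'   frame by the analysis functions, not here.
#' @param check Run geometric validation (default `TRUE`).
#' @return Object of class `section_contour`.
#' @export
section_contour <- function(specimen_id, element, periosteal, endosteal,
                            side = "R", location_label = "50",
                            check = TRUE) {
  element <- match.arg(element, c("femur", "tibia", "radius"))
  side <- match.arg(side, c("L", "R"))
  periosteal <- normalize_winding(as_ring(periosteal))
  endosteal <- normalize_winding(as_ring(endosteal))
  if (nrow(periosteal) < 8L || nrow(endosteal) < 8L) {
    stop("each ring needs at least 8 vertices", call. = FALSE)
  }
  if (check) {
    if (!is_simple_ring(periosteal)) {
      stop("periosteal ring is self-intersecting", call. = FALSE)
    }
    if (!is_simple_ring(endosteal)) {
      stop("endosteal ring is self-intersecting", call. = FALSE)
    }
    if (signed_area(endosteal) >= signed_area(periosteal)) {
      stop("endosteal area must be smaller than periosteal area",
           call. = FALSE)
    }
    if (!all(points_in_ring(endosteal, periosteal))) {
      stop("endosteal ring must lie inside the periosteal ring",
           call. = FALSE)
    }
  }
  structure(list(specimen_id = specimen_id, element = element, side = side,
                 location_label = as.character(location_label),
                 periosteal = periosteal, endosteal = endosteal),
            class = "section_contour")
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("Section %s %s (%s, %s%%-type location '%s'): %d + %d vertices\n",
              x$specimen_id, x$element, x$side, "", x$location_label,
              nrow(x$periosteal), nrow(x$endosteal)))
  invisible(x)
}

# mirror a left section into the right-side frame (x -> -x)
mirror_section <- function(section) {
  if (section$side != "L") return(section)
  flip <- function(r) normalize_winding(cbind(-r[, 1L], r[, 2L]))
  section$periosteal <- flip(section$periosteal)
  section$endosteal <- flip(section$endosteal)
  section$side <- "R"
  section
}

# ---- CSG properties --------------------------------------------------------

#' Cross-sectional geometry properties of a cortical ring
#'
#' Computes the standard beam-model quantities of a cortical section: total
#' subperiosteal area `TA`, cortical area `CA`, second moments of area
#' `Ix`, `Iy`, `Ixy` about the cortical centroid, principal moments
#' `Imax >= Imin` with the orientation `theta` of the major principal axis
#' (radians from +x, in (-pi/2, pi/2\]), polar moment `J = Imax + Imin`, and
#' the polar section modulus `Zp = J / r_max` where `r_max` is the largest
#' distance from the cortical centroid to the periosteal contour. The
#' medullary cavity is removed by composite-area subtraction with
#' parallel-axis transfer. Left-side sections are mirrored into the
#' right-side frame before computation so sides can be pooled.
#'
#' @param section A [section_contour()].
#' @return Object of class `csg_properties`: list with `CA`, `TA`, `Ix`,
#'   `Iy`, `Ixy`, `Imax`, `Imin`, `theta`, `J`, `Zp`, `ratio`
#'   (`Imax/Imin`), `centroid`, plus the section metadata.
#' @examples
#' ring <- function(r, n = 256) {
#'   a <- seq(0, 2 * pi, length.out = n + 1)[-1]
#'   cbind(r * cos(a), r * sin(a))
#' }
#' s <- section_contour("demo", "femur", ring(15), ring(9))
#' csg_properties(s)$CA  # ~ pi * (15^2 - 9^2)
#' @export
csg_properties <- function(section) {
  stopifnot(inherits(section, "section_contour"))
  section <- mirror_section(section)
  # rings were validated at construction; moments need no re-check
  mp <- polygon_moments(section$periosteal, check = FALSE)
  me <- polygon_moments(section$endosteal, check = FALSE)
  TA <- mp$area
  CA <- TA - me$area
  centroid <- (mp$area * mp$centroid - me$area * me$centroid) / CA
  transfer <- function(m, a) {
    d <- m$centroid - centroid
    c(Ix = m$Ix + a * d[2L]^2, Iy = m$Iy + a * d[1L]^2,
      Ixy = m$Ixy + a * d[1L] * d[2L])
  }
  tp <- transfer(mp, mp$area)
  te <- transfer(me, me$area)
  Ix <- unname(tp["Ix"] - te["Ix"])
  Iy <- unname(tp["Iy"] - te["Iy"])
  Ixy <- unname(tp["Ixy"] - te["Ixy"])
  # principal decomposition of the orientation tensor [[Iy, Ixy], [Ixy, Ix]]:
  # eigenvalues are Imax/Imin; theta is the major geometric axis vs +x
  avg <- (Ix + Iy) / 2
  R <- sqrt(((Iy - Ix) / 2)^2 + Ixy^2)
  Imax <- avg + R
  Imin <- avg - R
  theta <- 0.5 * atan2(2 * Ixy, Iy - Ix)
  if (theta <= -pi / 2 + 1e-15) theta <- theta + pi
  r_max <- sqrt(max((section$periosteal[, 1L] - centroid[1L])^2 +
                      (section$periosteal[, 2L] - centroid[2L])^2))
  J <- Ix + Iy
  structure(list(specimen_id = section$specimen_id,
                 element = section$element, side = section$side,
                 location_label = section$location_label,
                 CA = CA, TA = TA, Ix = Ix, Iy = Iy, Ixy = Ixy,
                 Imax = Imax, Imin = Imin, theta = theta, J = J,
                 Zp = J / r_max, ratio = Imax / Imin, centroid = centroid),
            class = "csg_properties")
}

#' @export
print.csg_properties <- function(x, ...) {
  cat(sprintf("CSG %s %s @%s: CA %.2f TA %.2f mm^2; Imax %.1f Imin %.1f mm^4; Zp %.1f mm^3\n",
              x$specimen_id, x$element, x$location_label, x$CA, x$TA,
              x$Imax, x$Imin, x$Zp))
  invisible(x)
}

#' Standard diaphyseal section locations for an element
#'
#' Percentages of biomechanical length measured from the distal end: femur
#' 35/50/80 (80% is subtrochanteric, at the gluteal buttress), tibia
#' 20/35/50; the radius uses the point of maximum medial projection of the
#' interosseous crest (`"IC"`). The mid-proximal 65% location is available
#' for femur and tibia via `all = TRUE`.
#'
#' @param element `"femur"`, `"tibia"` or `"radius"`.
#' @param all Include the optional 65% location (default `FALSE`).
#' @return Character vector of location labels.
#' @export
section_locations <- function(element, all = FALSE) {
  element <- match.arg(element, c("femur", "tibia", "radius"))
  switch(element,
         femur = if (all) c("35", "50", "65", "80") else c("35", "50", "80"),
         tibia = if (all) c("20", "35", "50", "65") else c("20", "35", "50"),
         radius = "IC")
}

#' Locate the interosseous crest along a series of radius sections
#'
#' Given sections sampled along the radial diaphysis (ordered from distal to
#' proximal), returns the index of the section with the largest medial
#' periosteal extension from its own periosteal centroid (medial = -x in the
#' right-side frame; left sections are mirrored first). Ties go to the most
#' distal (lowest-index) section.
#'
#' @param sections List of [section_contour()] objects, distal first.
#' @return Integer index into `sections`.
#' @export
locate_interosseous_crest <- function(sections) {
  if (!length(sections)) stop("empty section series", call. = FALSE)
  ext <- vapply(sections, function(s) {
    stopifnot(inherits(s, "section_contour"))
    s <- mirror_section(s)
    m <- polygon_moments(s$periosteal, check = FALSE)
    m$centroid[1L] - min(s$periosteal[, 1L])
  }, numeric(1L))
  # strict inequality keeps the most distal section on ties
  which.max(ext > ext[which.max(ext)] - 1e-12)
}

#' Tabulate CSG properties for a set of sections
#'
#' @param sections List of [section_contour()] objects.
#' @return `data.frame` with one row per section and columns `specimen_id`,
#'   `element`, `side`, `location`, `CA_mm2`, `TA_mm2`, `Ix_mm4`, `Iy_mm4`,
#'   `Imax_mm4`, `Imin_mm4`, `Zp_mm3`, `ratio`, `theta_rad`.
#' @export
csg_table <- function(sections) {
  if (inherits(sections, "section_contour")) sections <- list(sections)
  rows <- lapply(sections, function(s) {
    p <- csg_properties(s)
    data.frame(specimen_id = p$specimen_id, element = p$element,
               side = s$side, location = p$location_label,
               CA_mm2 = p$CA, TA_mm2 = p$TA, Ix_mm4 = p$Ix, Iy_mm4 = p$Iy,
               Imax_mm4 = p$Imax, Imin_mm4 = p$Imin, Zp_mm3 = p$Zp,
               ratio = p$ratio, theta_rad = p$theta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
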