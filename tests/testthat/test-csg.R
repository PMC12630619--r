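test_that("polygon moments match textbook closed forms", {
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  m <- polygon_moments(sq)
  expect_equal(m$area, 1)
  expect_equal(m$centroid, c(0, 0))
  expect_equal(m$Ix, 1 / 12)
  expect_equal(m$Iy, 1 / 12)
  expect_equal(m$Ixy, 0)
  # 720-gon approximation of a circle R = 10
  mc <- polygon_moments(circle_ring(10, 720))
  expect_equal(mc$area, pi * 100, tolerance = 1e-3)
  expect_equal(mc$Ix, pi * 1e4 / 4, tolerance = 1e-3)
  expect_equal(mc$Iy, pi * 1e4 / 4, tolerance = 1e-3)
  # winding direction does not matter
  expect_equal(polygon_moments(sq[4:1, ])$area, 1)
})

test_that("centroid-relative moments are translation invariant", {
  ring <- ellipse_ring(7, 4, 256)
  m0 <- polygon_moments(ring)
  m1 <- polygon_moments(sweep(ring, 2L, c(5, -3), `+`))
  expect_equal(m1$centroid, m0$centroid + c(5, -3))
  expect_equal(m1$Ix, m0$Ix, tolerance = 1e-12)
  expect_equal(m1$Iy, m0$Iy, tolerance = 1e-12)
  expect_equal(m1$Ixy, m0$Ixy, tolerance = 1e-9)
})

test_that("degenerate and self-intersecting rings are rejected", {
  expect_error(polygon_moments(cbind(c(0, 1), c(0, 1))), "3 distinct")
  bowtie <- cbind(c(0, 2, 0, 1), c(0, 1, 1, 0))
  expect_error(polygon_moments(bowtie), "self-intersecting")
  flat <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(polygon_moments(flat), "degenerate")
})

test_that("solid-ellipse principal moments have ratio a^2/b^2 and theta 0", {
  m <- polygon_moments(ellipse_ring(2, 1, 1024))
  expect_equal(m$Iy / m$Ix, 4, tolerance = 1e-4)  # pi a^3 b / 4 vs pi a b^3 / 4
  ring <- ellipse_ring(2, 1, 1024)
  s <- section_contour("ell", "femur", ring, ellipse_ring(0.4, 0.2, 64))
  p <- csg_properties(s)
  expect_equal(p$theta, 0, tolerance = 1e-9)
})

test_that("cortical annulus properties match the closed forms", {
  s <- section_contour("ann", "femur", circle_ring(15, 1440),
                       circle_ring(9, 1440))
  p <- csg_properties(s)
  expect_equal(p$TA, pi * 225, tolerance = 2e-3)
  expect_equal(p$CA, pi * (225 - 81), tolerance = 2e-3)
  expect_equal(p$Ix, pi * (15^4 - 9^4) / 4, tolerance = 2e-3)
  expect_equal(p$Iy, p$Ix, tolerance = 1e-6)
  expect_equal(p$ratio, 1, tolerance = 1e-6)
  expect_equal(p$J, pi * (15^4 - 9^4) / 2, tolerance = 2e-3)
  expect_equal(p$Zp, pi * (15^4 - 9^4) / 2 / 15, tolerance = 2e-3)
  expect_equal(p$J, p$Imax + p$Imin, tolerance = 1e-12)
  expect_equal(p$J, p$Ix + p$Iy, tolerance = 1e-12)
})

test_that("eccentric-canal sections agree with the parallel-axis oracle", {
  gs <- generate_section(section_spec("eccentric_canal", outer = 15,
                                      inner = 9, canal_offset = c(2, 0),
                                      n_vertices = 1440))
  p <- csg_properties(gs$section)
  o <- gs$oracle
  for (q in c("CA", "TA", "Ix", "Iy", "Imax", "Imin", "J", "Zp")) {
    expect_equal(p[[q]], o[[q]], tolerance = 2e-3)
  }
})

test_that("the engine agrees with pixel integration on every generator family", {
  cases <- list(
    list(spec = section_spec("annulus", outer = 15, inner = 9,
                             n_vertices = 1440),
         out = inside_ellipse(15, 15), inn = inside_ellipse(9, 9), b = 16),
    list(spec = section_spec("elliptical_annulus", outer = c(18, 12),
                             inner = c(11, 7), n_vertices = 1440),
         out = inside_ellipse(18, 12), inn = inside_ellipse(11, 7), b = 19),
    list(spec = section_spec("eccentric_canal", outer = c(15, 13),
                             inner = c(8, 7), canal_offset = c(2.5, -1),
                             n_vertices = 1440),
         out = inside_ellipse(15, 13), inn = inside_ellipse(8, 7,
                                                            c(2.5, -1)),
         b = 16),
    list(spec = section_spec("buttressed", outer = c(14, 11),
                             inner = c(8, 6.5), buttress_amplitude = 3,
                             n_vertices = 1440),
         out = inside_buttressed(14, 11, 3, 225 * pi / 180, 8),
         inn = inside_ellipse(8, 6.5), b = 19))
  for (cs in cases) {
    p <- csg_properties(generate_section(cs$spec)$section)
    o <- raster_csg(cs$out, cs$inn, c(-cs$b, cs$b), c(-cs$b, cs$b),
                    n = 1500)
    for (q in c("CA", "Ix", "Iy", "Imax", "Imin", "J")) {
      expect_equal(p[[q]], o[[q]], tolerance = 2e-3)
    }
  }
})

test_that("properties scale as area s^2, moments s^4, Zp s^3", {
  base <- generate_section(section_spec("eccentric_canal", outer = c(15, 12),
                                        inner = c(8, 7),
                                        canal_offset = c(1.5, 0.5),
                                        n_vertices = 720))$section
  p0 <- csg_properties(base)
  for (s in c(0.5, 2, 10)) {
    scaled <- section_contour("s", base$element, base$periosteal * s,
                              base$endosteal * s, check = FALSE)
    p1 <- csg_properties(scaled)
    expect_equal(p1$CA, p0$CA * s^2, tolerance = 1e-9)
    expect_equal(p1$TA, p0$TA * s^2, tolerance = 1e-9)
    expect_equal(p1$Imax, p0$Imax * s^4, tolerance = 1e-9)
    expect_equal(p1$Imin, p0$Imin * s^4, tolerance = 1e-9)
    expect_equal(p1$Zp, p0$Zp * s^3, tolerance = 1e-9)
    expect_equal(p1$ratio, p0$ratio, tolerance = 1e-9)
    expect_equal(p1$theta, p0$theta, tolerance = 1e-9)
  }
})

test_that("rigid rotation preserves invariants and shifts theta mod pi", {
  base <- generate_section(section_spec("elliptical_annulus",
                                        outer = c(18, 12), inner = c(11, 7),
                                        n_vertices = 720))$section
  p0 <- csg_properties(base)
  rot <- function(m, ang) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    m %*% t(R)
  }
  for (phi in c(0.3, 1.2, 2.8)) {
    turned <- section_contour("r", base$element, rot(base$periosteal, phi),
                              rot(base$endosteal, phi), check = FALSE)
    p1 <- csg_properties(turned)
    for (q in c("TA", "CA", "Imax", "Imin", "J", "Zp")) {
      expect_equal(p1[[q]], p0[[q]], tolerance = 1e-6)
    }
    shift <- (p1$theta - p0$theta - phi) %% pi
    expect_true(min(shift, pi - shift) < 1e-6)
  }
})

test_that("left sections are mirrored into the right-side frame", {
  gs <- generate_section(section_spec("eccentric_canal", outer = c(15, 12),
                                      inner = c(8, 7),
                                      canal_offset = c(2, 1),
                                      n_vertices = 512))$section
  left <- section_contour("l", gs$element,
                          cbind(-gs$periosteal[, 1], gs$periosteal[, 2]),
                          cbind(-gs$endosteal[, 1], gs$endosteal[, 2]),
                          side = "L", check = FALSE)
  pR <- csg_properties(gs)
  pL <- csg_properties(left)
  expect_equal(pL$CA, pR$CA, tolerance = 1e-9)
  expect_equal(pL$Imax, pR$Imax, tolerance = 1e-9)
  expect_equal(pL$Zp, pR$Zp, tolerance = 1e-9)
  expect_equal(pL$centroid, pR$centroid, tolerance = 1e-9)
})

test_that("property values converge with ring resolution", {
  vals <- lapply(c(720, 1440), function(n) {
    csg_properties(generate_section(section_spec(
      "elliptical_annulus", outer = c(18, 12), inner = c(11, 7),
      n_vertices = n))$section)
  })
  for (q in c("CA", "TA", "Imax", "Imin", "Zp")) {
    expect_lt(abs(vals[[2]][[q]] / vals[[1]][[q]] - 1), 5e-4)
  }
})

test_that("standard section locations are reported per element", {
  expect_equal(section_locations("femur"), c("35", "50", "80"))
  expect_equal(section_locations("femur", all = TRUE),
               c("35", "50", "65", "80"))
  expect_equal(section_locations("tibia"), c("20", "35", "50"))
  expect_equal(section_locations("radius"), "IC")
  expect_error(section_locations("humerus"))
})

test_that("interosseous crest is located at the maximum medial extension", {
  # constructed series: section 3 carries the largest medial spike
  mk <- function(amp) generate_section(section_spec(
    "buttressed", outer = c(7, 5.5), inner = c(3.5, 2.8),
    buttress_amplitude = amp, buttress_angle = pi,
    n_vertices = 128), element = "radius")$section
  series <- lapply(c(0.5, 1, 3, 1, 0.5), mk)
  expect_equal(locate_interosseous_crest(series), 3L)
  # all-circular series ties -> most distal (first) section
  circ <- replicate(4, generate_section(section_spec(
    "annulus", outer = 7, inner = 3, n_vertices = 128),
    element = "radius")$section, simplify = FALSE)
  expect_equal(locate_interosseous_crest(circ), 1L)
  # generator ground truth: crest peaking at 43% of the series
  series43 <- generate_radius_series(n_sections = 21, peak_at = 0.43)
  idx <- locate_interosseous_crest(series43)
  z <- (idx - 1) / 20
  expect_lt(abs(z - 0.43), 0.05 / 2 + 1e-9)  # nearest section on the grid
  expect_error(locate_interosseous_crest(list()), "empty")
})

test_that("csg_table has the standard column layout", {
  secs <- list(
    generate_section(section_spec("annulus", outer = 15, inner = 9,
                                  n_vertices = 128), "a", "femur",
                     location_label = "50")$section,
    generate_section(section_spec("elliptical_annulus", outer = c(12, 9),
                                  inner = c(7, 5), n_vertices = 128),
                     "b", "tibia", location_label = "35")$section)
  tab <- csg_table(secs)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("specimen_id", "element", "location", "CA_mm2",
                    "TA_mm2", "Ix_mm4", "Iy_mm4", "Imax_mm4", "Imin_mm4",
                    "Zp_mm3") %in% names(tab)))
  expect_true(all(tab$CA_mm2 < tab$TA_mm2))
  expect_true(all(tab$Imax_mm4 >= tab$Imin_mm4))
})
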