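# Synthetic-data generators: parametric cortical-ring cross-sections with
# closed-form oracles, selection-biased assemblages, and two-group shape
# samples. These stand in for scan-derived contours so every stage of the
# pipeline can be exercised and validated without any external data.

#' Specify a parametric cortical-ring section
#'
#' Four families of increasing anatomical flavour, all sampled radially
#' about the ring centres so the contours are star-shaped and simple:
#' \describe{
#'   \item{`annulus`}{concentric circles, outer radius `outer[1]`, inner
#'     `inner[1]`.}
#'   \item{`elliptical_annulus`}{concentric ellipses with semi-axes
#'     `outer = c(a, b)` and `inner = c(a2, b2)` (x then y).}
#'   \item{`eccentric_canal`}{outer ellipse centred at the origin, inner
#'     ellipse displaced by `canal_offset` (mm).}
#'   \item{`buttressed`}{elliptical outer ring carrying a von Mises-shaped
#'     radial bump of height `buttress_amplitude` (mm) centred at polar
#'     angle `buttress_angle` (radians from +x; the default 225 degrees is
#'     posteromedial for a right bone), concentration `buttress_kappa`.
#'     Emulates localized cortical reinforcement.}
#' }
#'
#' @param family One of `"annulus"`, `"elliptical_annulus"`,
#'   `"eccentric_canal"`, `"buttressed"`.
#' @param outer,inner Semi-axes in mm (length 1 or 2; a single value gives a
#'   circle).
#' @param canal_offset Inner-ring centre displacement, length-2 mm vector.
#' @param buttress_amplitude,buttress_angle,buttress_kappa Bump height (mm),
#'   position (rad) and concentration.
#' @param n_vertices Vertices per ring (>= 32, default 720).
#' @param noise_sd Radial Gaussian noise sd in mm, applied after the oracle
#'   is computed; internally capped at 5% of the minimum cortical thickness
#'   so rings stay simple.
#' @param seed Integer seed for the noise (default `NULL`: no noise without
#'   a seed unless `noise_sd = 0`).
#' @return Object of class `section_spec`.
#' @export
section_spec <- function(family = c("annulus", "elliptical_annulus",
                                    "eccentric_canal", "buttressed"),
                         outer = 15, inner = 9, canal_offset = c(0, 0),
                         buttress_amplitude = 0,
                         buttress_angle = 225 * pi / 180,
                         buttress_kappa = 8,
                         n_vertices = 720, noise_sd = 0, seed = NULL) {
  family <- match.arg(family)
  if (length(outer) == 1L) outer <- c(outer, outer)
  if (length(inner) == 1L) inner <- c(inner, inner)
  if (any(outer <= 0) || any(inner <= 0)) {
    stop("semi-axes must be positive", call. = FALSE)
  }
  if (n_vertices < 32L) stop("`n_vertices` must be >= 32", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  # inner ring strictly inside outer at zero noise
  off <- sqrt(sum(canal_offset^2))
  if (any(inner + off >= outer)) {
    stop("inner ring (plus canal offset) must lie strictly inside the outer ring",
         call. = FALSE)
  }
  structure(list(family = family, outer = outer, inner = inner,
                 canal_offset = canal_offset,
                 buttress_amplitude = buttress_amplitude,
                 buttress_angle = buttress_angle,
                 buttress_kappa = buttress_kappa,
                 n_vertices = as.integer(n_vertices),
                 noise_sd = noise_sd, seed = seed),
            class = "section_spec")
}

# polar radius of an ellipse about its centre
ellipse_radius <- function(a, b, alpha) {
  a * b / sqrt((b * cos(alpha))^2 + (a * sin(alpha))^2)
}

# closed-form moments of a solid ellipse about its own centre
ellipse_moments <- function(a, b) {
  list(area = pi * a * b, Ix = pi * a * b^3 / 4, Iy = pi * a^3 * b / 4)
}

# closed-form CSG oracle for the analytic families (parallel-axis composite)
section_oracle <- function(spec) {
  if (spec$family == "buttressed" && spec$buttress_amplitude != 0) {
    return(NULL)
  }
  a <- spec$outer[1L]; b <- spec$outer[2L]
  a2 <- spec$inner[1L]; b2 <- spec$inner[2L]
  off <- spec$canal_offset
  mo <- ellipse_moments(a, b)
  mi <- ellipse_moments(a2, b2)
  TA <- mo$area
  CA <- TA - mi$area
  centroid <- -mi$area * off / CA
  do_ <- -centroid            # outer centre relative to cortical centroid
  di <- off - centroid
  Ix <- (mo$Ix + mo$area * do_[2L]^2) - (mi$Ix + mi$area * di[2L]^2)
  Iy <- (mo$Iy + mo$area * do_[1L]^2) - (mi$Iy + mi$area * di[1L]^2)
  Ixy <- mo$area * do_[1L] * do_[2L] - mi$area * di[1L] * di[2L]
  avg <- (Ix + Iy) / 2
  R <- sqrt(((Iy - Ix) / 2)^2 + Ixy^2)
  alpha <- seq(0, 2 * pi, length.out = 4097L)[-1L]
  pts <- cbind(ellipse_radius(a, b, alpha) * cos(alpha) - centroid[1L],
               ellipse_radius(a, b, alpha) * sin(alpha) - centroid[2L])
  r_max <- sqrt(max(rowSums(pts^2)))
  J <- Ix + Iy
  list(CA = CA, TA = TA, Ix = Ix, Iy = Iy, Ixy = Ixy,
       Imax = avg + R, Imin = avg - R,
       theta = 0.5 * atan2(2 * Ixy, Iy - Ix), J = J, Zp = J / r_max,
       ratio = (avg + R) / (avg - R), centroid = centroid)
}

#' Generate a parametric cortical-ring section
#'
#' Samples the periosteal and endosteal rings of a [section_spec()] at
#' `n_vertices` equally spaced polar angles, attaches the closed-form CSG
#' oracle where one exists (all families except a buttressed ring with
#' non-zero amplitude), then applies seeded radial Gaussian noise. The
#' oracle describes the noise-free shape.
#'
#' @param spec A [section_spec()].
#' @param specimen_id,element,side,location_label Metadata for the resulting
#'   [section_contour()].
#' @return List with elements `section` (a [section_contour()]) and `oracle`
#'   (closed-form CSG property list, or `NULL` for the buttressed family).
#' @examples
#' gs <- generate_section(section_spec("annulus", outer = 15, inner = 9))
#' gs$oracle$TA  # pi * 225
#' @export
generate_section <- function(spec, specimen_id = "synthetic",
                             element = "femur", side = "R",
                             location_label = "50") {
  stopifnot(inherits(spec, "section_spec"))
  n <- spec$n_vertices
  alpha <- 2 * pi * (seq_len(n) - 1L) / n
  r_out <- ellipse_radius(spec$outer[1L], spec$outer[2L], alpha)
  if (spec$family == "buttressed" && spec$buttress_amplitude != 0) {
    r_out <- r_out + spec$buttress_amplitude *
      exp(spec$buttress_kappa * (cos(alpha - spec$buttress_angle) - 1))
  }
  r_in <- ellipse_radius(spec$inner[1L], spec$inner[2L], alpha)
  oracle <- section_oracle(spec)
  peri <- cbind(r_out * cos(alpha), r_out * sin(alpha))
  endo <- cbind(spec$canal_offset[1L] + r_in * cos(alpha),
                spec$canal_offset[2L] + r_in * sin(alpha))
  if (spec$noise_sd > 0) {
    # cap noise at 5% of minimum cortical thickness so rings stay simple
    dmin <- min_ring_distance(peri, endo)
    sd_used <- min(spec$noise_sd, 0.05 * dmin)
    jitter <- with_seed(spec$seed, stats::rnorm(2L * n, sd = sd_used))
    peri <- cbind((r_out + jitter[seq_len(n)]) * cos(alpha),
                  (r_out + jitter[seq_len(n)]) * sin(alpha))
    rj <- r_in + jitter[n + seq_len(n)]
    endo <- cbind(spec$canal_offset[1L] + rj * cos(alpha),
                  spec$canal_offset[2L] + rj * sin(alpha))
  }
  section <- section_contour(specimen_id, element, peri, endo,
                             side = side, location_label = location_label,
                             check = FALSE)
  list(section = section, oracle = oracle)
}

# minimum distance between two vertex sets, chunked to bound memory
min_ring_distance <- function(a, b) {
  step <- 256L
  dmin <- Inf
  for (i in seq(1L, nrow(a), by = step)) {
    idx <- i:min(i + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), `+`) -
      2 * a[idx, , drop = FALSE] %*% t(b)
    dmin <- min(dmin, min(d2))
  }
  sqrt(max(dmin, 0))
}

#' Generate a selection-biased assemblage from a reference population
#'
#' Draws `MNI` individuals without replacement from a finite reference
#' population, where the probability of drawing category i at each step is
#' proportional to `remaining_i * weight_i`. Equal weights reproduce the
#' multivariate hypergeometric null; skewed weights implement the
#' alternative hypothesis of deliberate selection of some categories.
#'
#' @param population A `reference_population`.
#' @param MNI Number of individuals to draw (<= `population$N`).
#' @param selection_weights Positive length-3 weights over (F, M, JUV);
#'   default `c(1, 1, 1)` (unbiased).
#' @param seed Integer seed.
#' @return An [assemblage_composition()].
#' @export
generate_assemblage <- function(population, MNI,
                                selection_weights = c(1, 1, 1), seed = 1) {
  stopifnot(inherits(population, "reference_population"))
  if (MNI > population$N) stop("MNI exceeds population size", call. = FALSE)
  if (length(selection_weights) != 3L || any(selection_weights <= 0)) {
    stop("`selection_weights` must be 3 positive reals", call. = FALSE)
  }
  counts <- with_seed(seed, {
    remaining <- as.numeric(population$counts)
    drawn <- c(0, 0, 0)
    for (i in seq_len(MNI)) {
      w <- remaining * selection_weights
      cat_i <- sample.int(3L, 1L, prob = w / sum(w))
      remaining[cat_i] <- remaining[cat_i] - 1
      drawn[cat_i] <- drawn[cat_i] + 1
    }
    drawn
  })
  assemblage_composition(counts, label = sprintf("sim_%s", population$label))
}

#' Generate a two-group sample of landmark configurations
#'
#' Builds `n_per_group` specimens per group from two [section_spec()]
#' templates: each specimen's semi-axes are jittered multiplicatively
#' (lognormal, sd `param_jitter` on the log scale), a noise-free section is
#' generated, semilandmarks are extracted, and isotropic Gaussian landmark
#' noise (sd `landmark_noise_sd` mm) is added. All randomness is governed by
#' `seed`.
#'
#' @param template_a,template_b [section_spec()] templates for the two
#'   groups.
#' @param n_per_group Specimens per group (>= 3).
#' @param landmark_noise_sd Landmark noise sd in mm (default 0.1).
#' @param param_jitter Log-scale sd of the semi-axis jitter (default 0.03).
#' @param k Landmarks per contour (default 21).
#' @param seed Integer seed.
#' @param labels Group labels (default `c("A", "B")`).
#' @return List of [landmark_configuration()] objects with `group` set.
#' @export
generate_shape_sample <- function(template_a, template_b, n_per_group = 20,
                                  landmark_noise_sd = 0.1,
                                  param_jitter = 0.03, k = 21, seed = 1,
                                  labels = c("A", "B")) {
  stopifnot(inherits(template_a, "section_spec"),
            inherits(template_b, "section_spec"))
  if (n_per_group < 3L) stop("need n >= 3 per group", call. = FALSE)
  templates <- list(template_a, template_b)
  with_seed(seed, {
    out <- list()
    for (g in 1:2) {
      for (i in seq_len(n_per_group)) {
        spec <- templates[[g]]
        fac <- exp(stats::rnorm(2L, sd = param_jitter))
        spec$outer <- spec$outer * fac
        spec$inner <- spec$inner * fac
        spec$noise_sd <- 0
        sec <- generate_section(spec,
                                specimen_id = sprintf("%s%02d", labels[g], i))
        lm <- extract_semilandmarks(sec$section, k = k)
        lm$points <- lm$points +
          matrix(stats::rnorm(2L * nrow(lm$points), sd = landmark_noise_sd),
                 ncol = 2L)
        lm$group <- labels[g]
        out[[length(out) + 1L]] <- lm
      }
    }
    out
  })
}

#' Generate a synthetic radius section series with a parametric crest
#'
#' Builds an ordered (distal to proximal) series of buttressed sections
#' whose medial crest amplitude follows a Gaussian envelope along the
#' diaphysis, peaking at the fraction `peak_at` of the series length. The
#' crest points medially (-x in the right-side frame). Ground truth for
#' [locate_interosseous_crest()].
#'
#' @param n_sections Number of sections (>= 2).
#' @param peak_at Fractional position of the crest peak in (0, 1).
#' @param amplitude Peak crest height in mm.
#' @param outer,inner Base semi-axes in mm.
#' @param envelope_sd Width of the Gaussian envelope (fractional units).
#' @param n_vertices Vertices per ring.
#' @return List of [section_contour()] objects, distal first.
#' @export
generate_radius_series <- function(n_sections = 11, peak_at = 0.43,
                                   amplitude = 3, outer = c(7, 5.5),
                                   inner = c(3.5, 2.8),
                                   envelope_sd = 0.15, n_vertices = 256) {
  stopifnot(n_sections >= 2)
  z <- (seq_len(n_sections) - 1L) / (n_sections - 1L)
  lapply(seq_len(n_sections), function(i) {
    amp <- amplitude * exp(-(z[i] - peak_at)^2 / (2 * envelope_sd^2))
    spec <- section_spec("buttressed", outer = outer, inner = inner,
                         buttress_amplitude = amp,
                         buttress_angle = pi,  # medial
                         n_vertices = n_vertices)
    generate_section(spec, specimen_id = sprintf("rad_%02d", i),
                     element = "radius", location_label = "IC")$section
  })
}
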