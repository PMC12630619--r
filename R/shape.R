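# Landmark-based geometric morphometrics of cross-sectional shape:
# equiangular semilandmark extraction, generalized Procrustes analysis,
# PCA of Procrustes coordinates, group confidence ellipses, wireframes.

#' Construct a landmark configuration
#'
#' A cross-section is represented by 2k ordered semilandmarks: points
#' 1..k on the periosteal contour and k+1..2k on the endosteal contour,
#' with point `i` and point `i + k` lying on the same ray from the
#' extraction centre. The standard scheme uses k = 21 (42 landmarks).
#'
#' @param points 2k x 2 numeric matrix.
#' @param specimen_id,group,location_label Metadata.
#' @param k Landmarks per contour (default `nrow(points) / 2`).
#' @return Object of class `landmark_configuration`.
#' @export
landmark_configuration <- function(points, specimen_id = "specimen",
                                   group = NA_character_,
                                   location_label = NA_character_,
                                   k = nrow(points) / 2) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || anyNA(points)) {
    stop("`points` must be a numeric 2k x 2 matrix", call. = FALSE)
  }
  if (nrow(points) != 2 * k) {
    stop("`points` must have exactly 2k rows", call. = FALSE)
  }
  structure(list(points = points, specimen_id = specimen_id, group = group,
                 location_label = location_label, k = as.integer(k)),
            class = "landmark_configuration")
}

#' @export
print.landmark_configuration <- function(x, ...) {
  cat(sprintf("Landmark configuration %s: %d points (%d per contour)%s\n",
              x$specimen_id, nrow(x$points), x$k,
              if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  invisible(x)
}

# intersect ray origin + t*dir (t > 0) with a polygon; returns sorted t values
ray_ring_intersections <- function(origin, dir, ring) {
  p1 <- ring
  p2 <- ring[c(seq_len(nrow(ring))[-1L], 1L), , drop = FALSE]
  e <- p2 - p1
  w <- sweep(p1, 2L, origin)
  denom <- dir[1L] * e[, 2L] - dir[2L] * e[, 1L]
  ok <- abs(denom) > 1e-12
  t <- (w[, 1L] * e[, 2L] - w[, 2L] * e[, 1L]) / denom
  u <- (w[, 1L] * dir[2L] - w[, 2L] * dir[1L]) / -denom
  hit <- ok & u >= -1e-12 & u <= 1 + 1e-12 & t > 1e-12
  sort(t[hit])
}

#' Extract equiangular semilandmarks from a section contour
#'
#' Casts `k` rays from the cortical centroid at equal angular spacing
#' `2*pi/k`, the first ray pointing anteriorly (+y) and subsequent rays
#' proceeding laterally (clockwise in the right-side frame). Each ray
#' contributes the farthest intersection with the periosteal ring (landmark
#' 1..k) and the nearest intersection with the endosteal ring (landmark
#' k+1..2k). Left sections are mirrored to the right-side frame first.
#'
#' @param section A [section_contour()].
#' @param k Landmarks per contour (default 21, giving 42 in total).
#' @return A [landmark_configuration()] with 2k points.
#' @export
extract_semilandmarks <- function(section, k = 21) {
  stopifnot(inherits(section, "section_contour"), k >= 3)
  section <- mirror_section(section)
  centre <- csg_properties(section)$centroid
  angles <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k
  peri <- matrix(NA_real_, k, 2L)
  endo <- matrix(NA_real_, k, 2L)
  for (j in seq_len(k)) {
    d <- c(cos(angles[j]), sin(angles[j]))
    tp <- ray_ring_intersections(centre, d, section$periosteal)
    te <- ray_ring_intersections(centre, d, section$endosteal)
    if (!length(tp) || !length(te)) {
      stop("extraction centre falls outside a ring: no ray intersection",
           call. = FALSE)
    }
    peri[j, ] <- centre + max(tp) * d
    endo[j, ] <- centre + min(te) * d
  }
  landmark_configuration(rbind(peri, endo),
                         specimen_id = section$specimen_id,
                         location_label = section$location_label, k = k)
}

# ---- Procrustes machinery --------------------------------------------------

centroid_size <- function(points) {
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2L, ctr)^2))
}

# centre at origin and scale to unit centroid size
pre_shape <- function(points) {
  ctr <- colMeans(points)
  points <- sweep(points, 2L, ctr)
  cs <- sqrt(sum(points^2))
  if (cs < 1e-12) stop("degenerate (zero-size) configuration", call. = FALSE)
  points / cs
}

# optimal rotation (no reflection) of centered 2D config X onto ref,
# via complex linear regression: exact in two dimensions
rotate_onto <- function(X, ref) {
  zx <- complex(real = X[, 1L], imaginary = X[, 2L])
  zr <- complex(real = ref[, 1L], imaginary = ref[, 2L])
  ang <- Arg(sum(Conj(zx) * zr))
  rotate_by(X, ang)
}

# rotate row-vector points counterclockwise by ang
rotate_by <- function(X, ang) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  X %*% t(R)
}

#' Generalized Procrustes analysis
#'
#' Superimposes a sample of landmark configurations by removing translation
#' (centering), size (scaling to unit centroid size) and rotation
#' (iterative least-squares alignment to the evolving consensus, without
#' reflection) until the consensus changes by less than `tol` or `max_iter`
#' iterations are reached. The output is put in a canonical orientation —
#' the consensus is rotated so its first landmark (the anterior periosteal
#' semilandmark under the standard extraction scheme) points along +y —
#' which makes the result invariant to similarity transforms of the inputs.
#'
#' @param configs List of [landmark_configuration()] objects or k x 2
#'   matrices with equal landmark counts (>= 2 configurations).
#' @param tol Convergence tolerance on the consensus (default 1e-10).
#' @param max_iter Maximum iterations (default 100).
#' @return Object of class `procrustes_aligned`: list with `configs`
#'   (aligned k x 2 matrices, centroid at origin, unit centroid size),
#'   `centroid_sizes` (original sizes), `mean_shape` (arithmetic mean of
#'   the aligned configurations), `iterations`, `specimen_ids`, `groups`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2L) stop("need at least 2 configurations",
                                 call. = FALSE)
  ids <- vapply(seq_along(configs), function(i) {
    c0 <- configs[[i]]
    if (inherits(c0, "landmark_configuration")) c0$specimen_id
    else paste0("config_", i)
  }, character(1L))
  groups <- vapply(configs, function(c0) {
    if (inherits(c0, "landmark_configuration")) as.character(c0$group)
    else NA_character_
  }, character(1L))
  mats <- lapply(configs, function(c0) {
    if (inherits(c0, "landmark_configuration")) c0$points else as.matrix(c0)
  })
  kset <- unique(vapply(mats, nrow, integer(1L)))
  if (length(kset) != 1L) {
    stop("all configurations must have the same landmark count",
         call. = FALSE)
  }
  sizes <- vapply(mats, centroid_size, numeric(1L))
  mats <- lapply(mats, pre_shape)
  ref <- mats[[1L]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mats <- lapply(mats, rotate_onto, ref = ref)
    consensus <- Reduce(`+`, mats) / length(mats)
    consensus <- consensus / sqrt(sum(consensus^2))
    if (sqrt(sum((consensus - ref)^2)) < tol || iter >= max_iter) {
      ref <- consensus
      break
    }
    ref <- consensus
  }
  mats <- lapply(mats, rotate_onto, ref = ref)
  mean_shape <- Reduce(`+`, mats) / length(mats)
  # canonical orientation: first mean landmark along +y
  u <- mean_shape[1L, ]
  ang <- pi / 2 - atan2(u[2L], u[1L])
  mats <- lapply(mats, rotate_by, ang = ang)
  mean_shape <- rotate_by(mean_shape, ang)
  structure(list(configs = mats, centroid_sizes = sizes,
                 mean_shape = mean_shape, iterations = iter,
                 specimen_ids = ids, groups = groups),
            class = "procrustes_aligned")
}

#' @export
print.procrustes_aligned <- function(x, ...) {
  cat(sprintf("GPA: %d configurations, %d landmarks, %d iterations\n",
              length(x$configs), nrow(x$mean_shape), x$iterations))
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' Centres and scales both configurations to unit centroid size, rotates the
#' first onto the second (no reflection) and returns the root summed
#' squared difference.
#'
#' @param a,b k x 2 matrices or [landmark_configuration()] objects.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (inherits(a, "landmark_configuration")) a <- a$points
  if (inherits(b, "landmark_configuration")) b <- b$points
  a <- pre_shape(as.matrix(a))
  b <- pre_shape(as.matrix(b))
  sqrt(sum((rotate_onto(a, b) - b)^2))
}

# ---- PCA of Procrustes coordinates -----------------------------------------

#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance of the flattened aligned
#' coordinates (mean-centred, covariance with divisor n so that eigenvalues
#' are per-specimen mean squared deviations and duplicating the sample
#' leaves the spectrum unchanged). The sum of the eigenvalues equals the
#' total Procrustes variance of the sample. Loading signs follow a fixed
#' convention: the largest-magnitude coordinate of each loading is
#' positive.
#'
#' @param aligned A `procrustes_aligned` object from
#'   [generalized_procrustes()] (>= 3 specimens).
#' @return Object of class `shape_pca`: list with `eigenvalues`
#'   (non-increasing), `scores` (n x p matrix, rows named by specimen),
#'   `loadings` (2k*2 x p orthonormal matrix), `mean_vector`, `mean_shape`,
#'   `groups`, `total_variance`.
#' @export
shape_pca <- function(aligned) {
  stopifnot(inherits(aligned, "procrustes_aligned"))
  n <- length(aligned$configs)
  if (n < 3L) stop("PCA needs at least 3 specimens", call. = FALSE)
  X <- t(vapply(aligned$configs, as.vector,
                numeric(length(aligned$configs[[1L]]))))
  mean_vec <- colMeans(X)
  Xc <- sweep(X, 2L, mean_vec)
  dec <- svd(Xc)
  eigenvalues <- dec$d^2 / n
  loadings <- dec$v
  scores <- Xc %*% loadings
  # deterministic sign convention
  for (j in seq_len(ncol(loadings))) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- aligned$specimen_ids
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(eigenvalues = eigenvalues, scores = scores,
                 loadings = loadings, mean_vector = mean_vec,
                 mean_shape = aligned$mean_shape, groups = aligned$groups,
                 total_variance = sum(Xc^2) / n),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  pvar <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("Shape PCA: %d specimens; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), pvar[1L],
              if (length(pvar) > 1L) pvar[2L] else 0))
  invisible(x)
}

#' Group confidence ellipse in a two-dimensional score space
#'
#' Normal-theory confidence ellipse at the given level for a group's scatter
#' in (say) PC1/PC2 space: centre at the group mean, semi-axes equal to the
#' square roots of the covariance eigenvalues scaled by
#' `sqrt(qchisq(level, 2))`, orientation from the leading eigenvector.
#'
#' @param scores_2d n x 2 matrix of coordinates (n >= 3).
#' @param level Coverage level (default 0.95).
#' @return List with `centre`, `axes` (semi-axis lengths, major first),
#'   `angle` (radians), `level`, `n`.
#' @export
group_confidence_ellipse <- function(scores_2d, level = 0.95) {
  scores_2d <- as.matrix(scores_2d)
  if (nrow(scores_2d) < 3L) stop("ellipse needs n >= 3", call. = FALSE)
  if (ncol(scores_2d) != 2L) stop("`scores_2d` must have 2 columns",
                                  call. = FALSE)
  centre <- colMeans(scores_2d)
  ev <- eigen(stats::cov(scores_2d), symmetric = TRUE)
  scale <- sqrt(stats::qchisq(level, df = 2))
  list(centre = centre, axes = sqrt(pmax(ev$values, 0)) * scale,
       angle = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L]),
       level = level, n = nrow(scores_2d))
}

# polygonal outline of an ellipse, for plotting
ellipse_outline <- function(ellipse, n = 120) {
  a <- seq(0, 2 * pi, length.out = n + 1L)
  unit <- cbind(ellipse$axes[1L] * cos(a), ellipse$axes[2L] * sin(a))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2L, 2L)
  sweep(unit %*% t(rot), 2L, ellipse$centre, `+`)
}

#' Landmark configuration along a principal component
#'
#' Deforms the mean shape along one PC: `mean + score * loading(pc)`,
#' reshaped to 2k landmarks. Used for the +/- 0.1 wireframes that visualize
#' what a PC axis means anatomically; connectivity is the two closed
#' polylines 1..k (periosteal) and k+1..2k (endosteal).
#'
#' @param result A `shape_pca` object.
#' @param pc Component index.
#' @param score PC score of the deformed configuration (default 0.1).
#' @return 2k x 2 coordinate matrix.
#' @export
wireframe_config <- function(result, pc, score = 0.1) {
  stopifnot(inherits(result, "shape_pca"))
  if (pc < 1 || pc > ncol(result$loadings)) {
    stop("`pc` out of range", call. = FALSE)
  }
  v <- result$mean_vector + score * result$loadings[, pc]
  matrix(v, ncol = 2L)
}

#' Plot a shape PCA ordination with group ellipses
#'
#' Scatter of two PC scores with normal-theory confidence ellipses per
#' group (groups with n >= 3).
#'
#' @param x A `shape_pca` object.
#' @param pcs Length-2 integer vector of components to plot (default 1:2).
#' @param level Ellipse coverage level (default 0.95).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of group ellipses.
#' @export
plot.shape_pca <- function(x, pcs = c(1L, 2L), level = 0.95, ...) {
  s <- x$scores[, pcs, drop = FALSE]
  groups <- x$groups
  cols <- if (all(is.na(groups))) rep(1L, nrow(s))
          else as.integer(factor(groups))
  pvar <- 100 * x$eigenvalues / sum(x$eigenvalues)
  graphics::plot(s, col = cols, pch = 16, asp = 1,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1L], pvar[pcs[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2L], pvar[pcs[2L]]),
                 ...)
  ells <- list()
  if (!all(is.na(groups))) {
    for (g in unique(stats::na.omit(groups))) {
      sub <- s[which(groups == g), , drop = FALSE]
      if (nrow(sub) >= 3L) {
        e <- group_confidence_ellipse(sub, level)
        graphics::lines(ellipse_outline(e),
                        col = cols[which(groups == g)[1L]])
        ells[[g]] <- e
      }
    }
  }
  invisible(ells)
}
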