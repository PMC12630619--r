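test_that("semilandmark extraction returns 2k points on shared rays", {
  s <- section_contour("conc", "femur", circle_ring(15, 720),
                       circle_ring(9, 720), check = FALSE)
  lm <- extract_semilandmarks(s, k = 21)
  expect_equal(nrow(lm$points), 42L)
  r_peri <- sqrt(rowSums(lm$points[1:21, ]^2))
  r_endo <- sqrt(rowSums(lm$points[22:42, ]^2))
  expect_equal(r_peri, rep(15, 21), tolerance = 1e-4)
  expect_equal(r_endo, rep(9, 21), tolerance = 1e-4)
  # first ray is anterior (+y), second proceeds laterally (+x side)
  expect_equal(lm$points[1, ], c(0, 15), tolerance = 1e-4)
  expect_gt(lm$points[2, 1], 0)
  # periosteal k and endosteal k+21 lie on the same ray from the centre
  ang_p <- atan2(lm$points[1:21, 2], lm$points[1:21, 1])
  ang_e <- atan2(lm$points[22:42, 2], lm$points[22:42, 1])
  expect_equal(ang_p, ang_e, tolerance = 1e-6)
})

test_that("extraction radii follow the ellipse polar form", {
  a <- 2; b <- 1
  s <- section_contour("ell", "femur", ellipse_ring(a, b, 1024),
                       ellipse_ring(a / 4, b / 4, 256), check = FALSE)
  lm <- extract_semilandmarks(s, k = 21)
  ang <- atan2(lm$points[1:21, 2], lm$points[1:21, 1])
  r_expect <- a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
  expect_equal(sqrt(rowSums(lm$points[1:21, ]^2)), r_expect,
               tolerance = 1e-4)
})

test_that("extraction yields 42 landmarks across generator families", {
  specs <- list(
    section_spec("annulus", outer = 15, inner = 9, n_vertices = 256),
    section_spec("eccentric_canal", outer = c(15, 12), inner = c(7, 6),
                 canal_offset = c(2, -1), n_vertices = 256),
    section_spec("buttressed", outer = c(14, 11), inner = c(8, 6),
                 buttress_amplitude = 3, n_vertices = 256))
  for (sp in specs) {
    lm <- extract_semilandmarks(generate_section(sp)$section)
    expect_equal(nrow(lm$points), 42L)
  }
})

test_that("Procrustes distance is zero under similarity transforms", {
  lm <- extract_semilandmarks(generate_section(section_spec(
    "eccentric_canal", outer = c(15, 12), inner = c(8, 7),
    canal_offset = c(2, 0), n_vertices = 256))$section)
  expect_equal(procrustes_distance(lm, lm), 0)
  set.seed(21)
  copy <- random_similarity(lm$points)
  expect_lt(procrustes_distance(lm$points, copy), 1e-9)
})

test_that("two-configuration alignment matches closed-form and vegan oracles", {
  tri_a <- cbind(c(0, 4, 1), c(0, 0, 3))
  tri_b <- cbind(c(0, 3, 0), c(0, 1, 2))
  d_pkg <- procrustes_distance(tri_a, tri_b)
  expect_gt(d_pkg, 0.05)
  expect_equal(d_pkg, opa_distance_complex(tri_a, tri_b), tolerance = 1e-12)
  # a similar triangle collapses the distance to zero
  sim <- cbind(c(0, 2, -1), c(0, 2, 2))  # tri_a rotated 45 deg, scaled
  expect_lt(procrustes_distance(tri_a, sim), 1e-9)
  skip_if_not_installed("vegan")
  # vegan's symmetric ss is the squared full-Procrustes distance 1 - |s|^2;
  # our partial distance is sqrt(2 - 2|s|): same |s| links the two
  s_mod <- 1 - d_pkg^2 / 2
  v <- vegan::procrustes(tri_b, tri_a, symmetric = TRUE)
  expect_equal(v$ss, 1 - s_mod^2, tolerance = 1e-9)
})

test_that("GPA centres, scales and converges; mean is the aligned average", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 15), inner = c(9, 9)),
    section_spec("elliptical_annulus", outer = c(15, 22.5),
                 inner = c(9, 13.5)),
    n_per_group = 8, seed = 31)
  al <- generalized_procrustes(configs)
  expect_lt(al$iterations, 100L)
  for (m in al$configs) {
    expect_equal(colMeans(m), c(0, 0), tolerance = 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  expect_equal(al$mean_shape, Reduce(`+`, al$configs) / length(al$configs),
               tolerance = 1e-12)
  expect_error(generalized_procrustes(configs[1]), "at least 2")
})

test_that("GPA output is invariant to similarity transforms of the inputs", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 15), inner = c(9, 9)),
    section_spec("elliptical_annulus", outer = c(15, 22.5),
                 inner = c(9, 13.5)),
    n_per_group = 6, seed = 32)
  al <- generalized_procrustes(configs)
  set.seed(33)
  transformed <- lapply(configs, function(c0) {
    c0$points <- random_similarity(c0$points)
    c0
  })
  al2 <- generalized_procrustes(transformed)
  expect_lt(max(abs(al$mean_shape - al2$mean_shape)), 1e-8)
  for (i in seq_along(al$configs)) {
    expect_lt(max(abs(al$configs[[i]] - al2$configs[[i]])), 1e-8)
  }
})

test_that("PCA eigenvalues sum to the total Procrustes variance", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 14), inner = c(9, 8)),
    section_spec("elliptical_annulus", outer = c(15, 20), inner = c(9, 12)),
    n_per_group = 10, seed = 41)
  pca <- shape_pca(generalized_procrustes(configs))
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_true(all(pca$eigenvalues >= -1e-12))
  # loadings are orthonormal
  G <- crossprod(pca$loadings)
  expect_equal(G, diag(ncol(pca$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a rank-1 deformation is captured by PC1", {
  base <- extract_semilandmarks(generate_section(section_spec(
    "elliptical_annulus", outer = c(15, 14), inner = c(9, 8),
    n_vertices = 256))$section)$points
  direction <- matrix(0, 42, 2)
  direction[, 2] <- base[, 2] / 15  # pure anteroposterior stretch
  set.seed(5)
  configs <- lapply(seq_len(12), function(i) {
    landmark_configuration(base + runif(1, -2, 2) * direction,
                           specimen_id = sprintf("s%02d", i))
  })
  pca <- shape_pca(generalized_procrustes(configs))
  expect_gt(pca$eigenvalues[1] / sum(pca$eigenvalues), 0.99)
})

test_that("duplicating the sample leaves the eigenvalue spectrum unchanged", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 14), inner = c(9, 8)),
    section_spec("elliptical_annulus", outer = c(15, 18), inner = c(9, 11)),
    n_per_group = 5, seed = 43)
  p1 <- shape_pca(generalized_procrustes(configs))
  p2 <- shape_pca(generalized_procrustes(c(configs, configs)))
  k <- length(p1$eigenvalues)
  expect_equal(p2$eigenvalues[seq_len(k)], p1$eigenvalues,
               tolerance = 1e-6)
})

test_that("confidence ellipses have chi-square geometry and ~95% coverage", {
  set.seed(51)
  X <- matrix(rnorm(2 * 4000), ncol = 2)
  e <- group_confidence_ellipse(X, 0.95)
  expect_equal(e$axes, rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
  expect_equal(e$centre, c(0, 0), tolerance = 0.06)
  # Monte Carlo coverage: Mahalanobis distance against the chi-square bound
  inside <- mahalanobis(X, colMeans(X), cov(X)) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.01)
  # collinear points give a degenerate minor axis
  line <- cbind(seq_len(10), 2 * seq_len(10))
  el <- group_confidence_ellipse(line)
  expect_lt(el$axes[2], 1e-9)
  expect_error(group_confidence_ellipse(X[1:2, ]), "n >= 3")
})

test_that("wireframes deform the mean shape linearly along a PC", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 15), inner = c(9, 9)),
    section_spec("elliptical_annulus", outer = c(15, 21), inner = c(9, 12)),
    n_per_group = 8, seed = 61)
  pca <- shape_pca(generalized_procrustes(configs))
  expect_equal(wireframe_config(pca, 1, 0),
               matrix(pca$mean_vector, ncol = 2), tolerance = 1e-12)
  up <- wireframe_config(pca, 1, 0.1)
  down <- wireframe_config(pca, 1, -0.1)
  expect_equal((up + down) / 2, matrix(pca$mean_vector, ncol = 2),
               tolerance = 1e-12)
  expect_error(wireframe_config(pca, 99), "out of range")
  # the PC1 extreme resembles the elongated template up to similarity
  elong <- extract_semilandmarks(generate_section(section_spec(
    "elliptical_annulus", outer = c(15, 21), inner = c(9, 12),
    n_vertices = 256))$section)$points
  score_b <- mean(pca$scores[vapply(configs, function(c0) c0$group, "") ==
                               "B", 1])
  wf <- wireframe_config(pca, 1, score_b)
  circ <- extract_semilandmarks(generate_section(section_spec(
    "elliptical_annulus", outer = c(15, 15), inner = c(9, 9),
    n_vertices = 256))$section)$points
  expect_lt(procrustes_distance(wf, elong), procrustes_distance(wf, circ))
})

test_that("circular and AP-elongated groups separate on PC1", {
  configs <- generate_shape_sample(
    section_spec("elliptical_annulus", outer = c(15, 15), inner = c(9, 9)),
    section_spec("elliptical_annulus", outer = c(15, 22.5),
                 inner = c(9, 13.5)),
    n_per_group = 20, landmark_noise_sd = 0.1, seed = 42)
  pca <- shape_pca(generalized_procrustes(configs))
  g <- vapply(configs, function(c0) c0$group, "")
  s_a <- pca$scores[g == "A", 1]
  s_b <- pca$scores[g == "B", 1]
  # zero overlap between the score distributions
  expect_true(max(s_a) < min(s_b) || max(s_b) < min(s_a))
  # and the PCA is reproducible for a fixed seed
  pca2 <- shape_pca(generalized_procrustes(configs))
  expect_equal(pca$scores, pca2$scores)
})
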