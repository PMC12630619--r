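# Independent oracles and small geometry builders used across the tests.
# Everything here is written from the analytic definitions, not by calling
# the package's own geometry engine.

# polygonal ring sampled on a circle/ellipse (parametric, counterclockwise)
circle_ring <- function(r, n = 720, centre = c(0, 0)) {
  a <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1L] + r * cos(a), centre[2L] + r * sin(a))
}

ellipse_ring <- function(a, b, n = 720, centre = c(0, 0)) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1L] + a * cos(t), centre[2L] + b * sin(t))
}

# pixel-integration CSG oracle: second moments of the region where
# inside(x, y) is TRUE, computed on an n x n grid of cell centres.
# Returns the same quantities as the polygon engine, from first principles.
raster_csg <- function(inside_outer, inside_inner, xlim, ylim, n = 1500) {
  hx <- diff(xlim) / n
  hy <- diff(ylim) / n
  xs <- xlim[1L] + (seq_len(n) - 0.5) * hx
  A <- 0; Sx <- 0; Sy <- 0; Sxx <- 0; Syy <- 0; Sxy <- 0; N <- 0
  for (i in seq_len(n)) {       # loop rows to bound memory
    y <- ylim[1L] + (i - 0.5) * hy
    m <- inside_outer(xs, y) & !inside_inner(xs, y)
    if (!any(m)) next
    x <- xs[m]
    k <- length(x)
    N <- N + k
    Sx <- Sx + sum(x); Sy <- Sy + k * y
    Sxx <- Sxx + sum(x^2); Syy <- Syy + k * y^2; Sxy <- Sxy + sum(x) * y
  }
  dA <- hx * hy
  area <- N * dA
  cx <- Sx / N
  cy <- Sy / N
  # pixel self-moment correction h^2/12 per cell
  Ix <- (Syy - N * cy^2) * dA + N * dA * hy^2 / 12
  Iy <- (Sxx - N * cx^2) * dA + N * dA * hx^2 / 12
  Ixy <- (Sxy - N * cx * cy) * dA
  avg <- (Ix + Iy) / 2
  R <- sqrt(((Iy - Ix) / 2)^2 + Ixy^2)
  list(CA = area, centroid = c(cx, cy), Ix = Ix, Iy = Iy, Ixy = Ixy,
       Imax = avg + R, Imin = avg - R, J = Ix + Iy)
}

# analytic inside-tests for the generator families
inside_ellipse <- function(a, b, centre = c(0, 0)) {
  function(x, y) ((x - centre[1L]) / a)^2 + ((y - centre[2L]) / b)^2 <= 1
}

inside_buttressed <- function(a, b, amp, mu, kappa) {
  function(x, y) {
    al <- atan2(y, x)
    r <- sqrt(x^2 + y^2)
    re <- a * b / sqrt((b * cos(al))^2 + (a * sin(al))^2)
    r <= re + amp * exp(kappa * (cos(al - mu) - 1))
  }
}

# closed-form ordinary Procrustes superimposition of two centered,
# unit-size 2D configurations via complex linear regression; returns the
# residual distance after the optimal rotation
opa_distance_complex <- function(A, B) {
  centre_unit <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  A <- centre_unit(A)
  B <- centre_unit(B)
  za <- complex(real = A[, 1L], imaginary = A[, 2L])
  zb <- complex(real = B[, 1L], imaginary = B[, 2L])
  s <- sum(Conj(za) * zb)
  sqrt(max(0, 2 - 2 * Mod(s)))
}

# enumerate all (F, M, JUV) compositions with a fixed MNI
all_compositions <- function(mni) {
  out <- list()
  for (f in 0:mni) for (m in 0:(mni - f)) {
    out[[length(out) + 1L]] <- c(f, m, mni - f - m)
  }
  out
}

# multivariate hypergeometric pmf, written out independently
mvhyper_pmf <- function(counts, K, N, mni) {
  prod(choose(K, counts)) / choose(N, mni)
}

# apply a random similarity transform (rotation, scale, translation)
random_similarity <- function(points) {
  ang <- stats::runif(1, 0, 2 * pi)
  sc <- stats::runif(1, 0.5, 2)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  sc * points %*% t(R) +
    matrix(stats::runif(2, -10, 10), nrow(points), 2L, byrow = TRUE)
}
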