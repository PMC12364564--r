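# Shared fixtures and independent oracles used across the test files.

# A random proper rotation matrix (2D or 3D).
random_rotation <- function(d = 3L) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Brute-force least-squares circle: 3-parameter grid search refined around
# the best cell. Independent of the package's algebraic + Gauss-Newton path.
grid_circle_oracle <- function(pts, center0, r0, span, steps = 15L) {
  best <- NULL
  grid1 <- function(c0, r, h) {
    cx <- seq(c0[1] - h, c0[1] + h, length.out = steps)
    cy <- seq(c0[2] - h, c0[2] + h, length.out = steps)
    rr <- seq(max(1e-6, r - h), r + h, length.out = steps)
    for (a in cx) for (b in cy) for (r_ in rr) {
      sse <- sum((sqrt((pts[, 1] - a)^2 + (pts[, 2] - b)^2) - r_)^2)
      if (is.null(best) || sse < best$sse) best <<- list(c = c(a, b), r = r_, sse = sse)
    }
    best
  }
  h <- span
  c0 <- center0; r <- r0
  for (k in 1:6) {
    grid1(c0, r, h)
    c0 <- best$c; r <- best$r
    h <- h * 2.2 / steps
  }
  best
}

# Monte Carlo mesh volume oracle: ray casting along +x on a y/z grid of
# rays; the length of the inside intervals integrates the volume.
raycast_volume_oracle <- function(mesh, n = 60L) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  ylim <- range(v[, 2L]); zlim <- range(v[, 3L])
  ys <- seq(ylim[1], ylim[2], length.out = n + 1L)
  zs <- seq(zlim[1], zlim[2], length.out = n + 1L)
  ys <- (ys[-1L] + ys[-(n + 1L)]) / 2
  zs <- (zs[-1L] + zs[-(n + 1L)]) / 2
  cell <- diff(ylim) / n * diff(zlim) / n
  grid <- expand.grid(y = ys, z = zs)
  total_len <- 0
  # Moeller-Trumbore with ray direction +x, vectorised over rays per triangle
  e1 <- b - a; e2 <- c_ - a
  # h = dir x e2 = (0, -e2z, e2y); det = e1 . h
  det <- -e1[, 2L] * e2[, 3L] + e1[, 3L] * e2[, 2L]
  xs_all <- vector("list", nrow(f))
  hits_ray <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    if (abs(det[t]) < 1e-14) next
    sx <- grid$y - a[t, 2L]; sz <- grid$z - a[t, 3L]
    u <- (-sx * e2[t, 3L] + sz * e2[t, 2L]) / det[t]
    # q = s x e1 with s = (sy, sz) in the yz components and sx unknown but
    # u,v only need yz parts since dir = +x
    qv <- (sx * e1[t, 3L] - sz * e1[t, 2L]) / det[t]
    ok <- u >= 0 & qv >= 0 & (u + qv) <= 1
    if (!any(ok)) next
    xhit <- a[t, 1L] + u[ok] * e1[t, 1L] + qv[ok] * e2[t, 1L]
    xs_all[[t]] <- xhit
    hits_ray[[t]] <- which(ok)
  }
  ray_id <- unlist(hits_ray)
  xhit <- unlist(xs_all)
  if (length(ray_id) == 0L) return(0)
  sp <- split(xhit, ray_id)
  for (r in sp) {
    r <- sort(r)
    if (length(r) %% 2L == 0L) {
      total_len <- total_len + sum(r[seq(2, length(r), 2)] -
                                     r[seq(1, length(r), 2)])
    }
  }
  total_len * cell
}

# Closed-form ordinary Procrustes superimposition of b onto a (both k x 3):
# the minimised sum of squares after centering, unit-size scaling and the
# optimal rotation via SVD; independent of the package's iterative GPA.
opa_distance_oracle <- function(a, b) {
  ctr <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- ctr(a); b <- ctr(b)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  trace <- sum(s$d[-length(s$d)]) + d * s$d[length(s$d)]
  sqrt(max(0, 2 - 2 * trace))
}

# Simple tetrahedron mesh for pseudo-landmark tests.
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  spine_mesh(v, f)
}

# Axis-aligned unit cube mesh (12 triangles, outward orientation).
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces by hand, CCW from outside
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),      # z = 0 (normal -z)
    c(5, 6, 8), c(5, 8, 7),      # z = 1
    c(1, 2, 6), c(1, 6, 5),      # y = 0
    c(3, 7, 8), c(3, 8, 4),      # y = 1
    c(1, 5, 7), c(1, 7, 3),      # x = 0
    c(2, 4, 8), c(2, 8, 6)       # x = 1
  )
  spine_mesh(v, f)
}

# Random landmark array of n specimens around a base configuration.
random_landmark_array <- function(n = 8L, k = 6L, noise = 0.1, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(k * 3), k, 3)
  arr <- array(NA_real_, c(k, 3L, n),
               dimnames = list(NULL, c("x", "y", "z"), paste0("s", seq_len(n))))
  for (i in seq_len(n)) {
    arr[, , i] <- base + matrix(rnorm(k * 3, 0, noise), k, 3)
  }
  arr
}
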