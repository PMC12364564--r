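test_that("landmark CSVs parse in long and wide format to the same array", {
  arr <- random_landmark_array(n = 3L, k = 10L, seed = 4L)
  long <- do.call(rbind, lapply(dimnames(arr)[[3L]], function(s) {
    data.frame(specimen = s, landmark = 1:10, x = arr[, 1, s],
               y = arr[, 2, s], z = arr[, 3, s])
  }))
  p_long <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, p_long, row.names = FALSE)
  a1 <- read_landmarks(p_long)
  expect_identical(dim(a1), c(10L, 3L, 3L))
  expect_equal(a1[, , "s2"], arr[, , "s2"], tolerance = 1e-12,
               ignore_attr = TRUE)

  wide <- data.frame(specimen = dimnames(arr)[[3L]],
                     t(apply(arr, 3L, function(m) as.numeric(t(m)))))
  names(wide)[-1L] <- paste0(rep(c("x", "y", "z"), 10),
                             rep(1:10, each = 3))
  p_wide <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, p_wide, row.names = FALSE)
  a2 <- read_landmarks(p_wide)
  expect_equal(a2, a1, tolerance = 1e-12)
})

test_that("ragged landmark counts are rejected", {
  bad <- data.frame(specimen = c(rep("a", 5), rep("b", 4)),
                    landmark = c(1:5, 1:4),
                    x = rnorm(9), y = rnorm(9), z = rnorm(9))
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_landmarks(p), "ragged")
})

test_that("farthest-point sampling is deterministic and maximises spread", {
  mesh <- tetrahedron_mesh()
  one <- pseudo_landmarks(mesh, 1L, seed = 7L)
  expect_identical(dim(one), c(1L, 3L))
  expect_true(any(apply(mesh$vertices, 1L, function(v) all(v == one[1L, ]))))
  # k = 4 on a regular tetrahedron must return all four vertices
  four <- pseudo_landmarks(mesh, 4L, seed = 7L)
  expect_identical(nrow(unique(round(four, 9))), 4L)
  expect_identical(pseudo_landmarks(mesh, 4L, seed = 7L), four)
  expect_error(pseudo_landmarks(mesh, 5L), "vertex count")
})

test_that("GPA sends similarity copies to zero Procrustes distance", {
  arr <- random_landmark_array(n = 3L, k = 6L, noise = 0, seed = 2L)
  # all copies identical -> all distances 0
  g <- gpa(arr)
  expect_lt(max(g$distances), 1e-10)

  set.seed(5)
  a <- matrix(rnorm(18), 6, 3)
  b <- 3.1 * a %*% random_rotation() + rep(c(2, -1, 0.5), each = 6)
  expect_lt(procrustes_distance(a, b), 1e-8)
})

test_that("aligned configurations are centered with unit centroid size", {
  arr <- random_landmark_array(n = 6L, k = 5L, seed = 3L)
  g <- gpa(arr)
  for (i in 1:6) {
    m <- g$aligned[, , i]
    expect_lt(max(abs(colMeans(m))), 1e-8)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-8)
  }
  # consensus is a fixed point of one more iteration
  cons2 <- apply(g$aligned, c(1, 2), mean)
  cons2 <- cons2 / sqrt(sum(scale(cons2, scale = FALSE)^2))
  expect_lt(sqrt(mean((cons2 - g$consensus)^2)), 1e-6)
})

test_that("two-shape GPA distance equals the closed-form superimposition", {
  set.seed(8)
  for (rep in 1:5) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    d_oracle <- opa_distance_oracle(a, b)
    expect_equal(procrustes_distance(a, b), d_oracle, tolerance = 1e-8)
  }
})

test_that("GPA results are invariant to similarity transforms of the input", {
  arr <- random_landmark_array(n = 6L, k = 7L, seed = 10L)
  g0 <- gpa(arr)
  p0 <- shape_pca(g0)
  arr2 <- arr
  set.seed(11)
  for (i in seq_len(dim(arr)[3L])) {
    arr2[, , i] <- runif(1, 0.5, 4) * arr[, , i] %*% random_rotation() +
      rep(runif(3, -10, 10), each = 7)
  }
  g2 <- gpa(arr2)
  expect_equal(g2$distances, g0$distances, tolerance = 1e-8)
  expect_equal(shape_pca(g2)$variance, p0$variance, tolerance = 1e-8)
})

test_that("Procrustes distance behaves like a metric on random triples", {
  set.seed(21)
  for (rep in 1:10) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    c_ <- matrix(rnorm(12), 4, 3)
    dab <- procrustes_distance(a, b)
    dba <- procrustes_distance(b, a)
    expect_equal(dab, dba, tolerance = 1e-8)
    expect_lte(procrustes_distance(a, c_),
               dab + procrustes_distance(b, c_) + 1e-10)
  }
})

test_that("shape PCA matches an eigen-decomposition oracle", {
  arr <- random_landmark_array(n = 5L, k = 4L, seed = 12L)
  g <- gpa(arr)
  p <- shape_pca(g)
  expect_equal(sum(p$variance), 1, tolerance = 1e-9)
  # oracle: eigen of the covariance of the vectorised aligned data
  X <- t(apply(g$aligned, 3L, as.numeric))
  ev <- eigen(stats::cov(X))
  keep <- seq_along(p$variance)
  expect_equal(p$variance, (ev$values / sum(ev$values[ev$values > 1e-18]))[keep],
               tolerance = 1e-8)
  # scores match up to sign
  Xc <- scale(X, scale = FALSE)
  for (j in keep) {
    s_o <- Xc %*% ev$vectors[, j]
    agree <- min(max(abs(p$scores[, j] - s_o)), max(abs(p$scores[, j] + s_o)))
    expect_lt(agree, 1e-8)
  }
  # axes orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA flags a single direction of variation with all the variance", {
  # aligned data constructed directly on a line in shape space, so the
  # eigen-decomposition itself is isolated from the alignment step
  set.seed(30)
  base <- matrix(rnorm(12), 4, 3)
  base <- scale(base, scale = FALSE)
  base <- base / sqrt(sum(base^2))
  dir <- scale(matrix(rnorm(12), 4, 3), scale = FALSE)
  arr <- array(NA_real_, c(4, 3, 6))
  for (i in 1:6) arr[, , i] <- base + (i / 20) * dir
  g <- structure(list(aligned = arr, consensus = base,
                      distances = rep(0, 6), iterations = 1L),
                 class = "gpa")
  p <- shape_pca(g)
  expect_equal(p$variance[1L], 1, tolerance = 1e-9)
})
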