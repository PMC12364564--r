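# Landmark-based geometric morphometrics: generalized Procrustes analysis,
# shape PCA and pseudo-landmark sampling.

#' Read landmark configurations from CSV
#'
#' Accepts long format (columns `specimen`, `landmark`, `x`, `y`, `z`) or
#' wide format (one row per specimen: `specimen`, `x1`, `y1`, `z1`, `x2`,
#' ...). All specimens must share the same landmark count, and landmark
#' correspondence across specimens is assumed given (e.g. produced by an
#' automated alignment tool).
#'
#' @param path CSV file path.
#' @return a `k x 3 x n` array (landmarks x coordinates x specimens) with
#'   specimen ids as the third dimension names.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df) <- nm
  if (all(c("specimen", "landmark", "x", "y", "z") %in% nm)) {
    if (anyDuplicated(df[, c("specimen", "landmark")])) {
      stopf("duplicated specimen/landmark rows in '%s'", path)
    }
    sp <- unique(df$specimen)
    ks <- vapply(split(df, df$specimen), nrow, integer(1))
    if (length(unique(ks)) != 1L) {
      stopf("ragged landmark counts across specimens: %s",
            paste(sort(unique(ks)), collapse = ", "))
    }
    k <- ks[[1L]]
    arr <- array(NA_real_, c(k, 3L, length(sp)),
                 dimnames = list(NULL, c("x", "y", "z"), sp))
    for (s in sp) {
      rows <- df[df$specimen == s, ]
      rows <- rows[order(rows$landmark), ]
      arr[, , s] <- as.matrix(rows[, c("x", "y", "z")])
    }
  } else if ("specimen" %in% nm) {
    coords <- df[, setdiff(nm, "specimen"), drop = FALSE]
    if (ncol(coords) %% 3L != 0L) {
      stopf("wide-format landmark CSV must have 3k coordinate columns")
    }
    if (anyDuplicated(df$specimen)) stopf("duplicated specimen ids in '%s'", path)
    k <- ncol(coords) %/% 3L
    arr <- array(NA_real_, c(k, 3L, nrow(df)),
                 dimnames = list(NULL, c("x", "y", "z"), df$specimen))
    for (i in seq_len(nrow(df))) {
      arr[, , i] <- matrix(as.numeric(coords[i, ]), ncol = 3L, byrow = TRUE)
    }
  } else {
    stopf("unrecognised landmark CSV layout in '%s'", path)
  }
  if (anyNA(arr)) stopf("missing coordinates in '%s'", path)
  validate_landmarks(arr)
  arr
}

validate_landmarks <- function(arr) {
  if (length(dim(arr)) != 3L || dim(arr)[2L] != 3L) {
    stopf("landmarks must be a k x 3 x n array")
  }
  if (dim(arr)[1L] < 4L) stopf("at least 4 landmarks per specimen required")
  cs <- apply(arr, 3L, function(m) sqrt(sum(scale(m, scale = FALSE)^2)))
  if (any(cs < 1e-12)) {
    stopf("degenerate (zero-size) configuration: %s",
          paste(dimnames(arr)[[3L]][cs < 1e-12], collapse = ", "))
  }
  invisible(arr)
}

centroid_size <- function(m) sqrt(sum(scale(m, scale = FALSE)^2))

# Optimal rotation of configuration m onto target t (both centered), by SVD;
# proper rotation (no reflection) unless allow_reflection.
opt_rotate <- function(m, target, allow_reflection = FALSE) {
  s <- svd(crossprod(target, m))
  R <- s$v %*% t(s$u)
  if (!allow_reflection && det(R) < 0) {
    v <- s$v
    v[, ncol(v)] <- -v[, ncol(v)]
    R <- v %*% t(s$u)
  }
  m %*% R
}

#' Generalized Procrustes analysis
#'
#' Moves a set of landmark configurations into a common shape space:
#' each configuration is centered, scaled to unit centroid size and rotated
#' to the running consensus by the optimal (least-squares) rotation; the
#' consensus is recomputed and the loop repeats until it stabilises.
#' Rotations are proper by default (reflections excluded), since chirality
#' of bilateral structures is biologically meaningful.
#'
#' @param landmarks a `k x 3 x n` array (see [read_landmarks()]), n >= 2.
#' @param max_iter maximum alignment iterations.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus.
#' @param allow_reflection permit improper rotations.
#' @return an object of class `gpa` with `aligned` (k x 3 x n array of
#'   aligned configurations, each centered with unit centroid size),
#'   `consensus` (k x 3 mean configuration), `distances` (per-specimen
#'   Procrustes distance to the consensus) and `iterations`.
#' @export
gpa <- function(landmarks, max_iter = 100L, tol = 1e-10,
                allow_reflection = FALSE) {
  validate_landmarks(landmarks)
  n <- dim(landmarks)[3L]
  if (n < 2L) stopf("GPA needs at least 2 specimens")
  aligned <- landmarks
  for (i in seq_len(n)) {
    m <- scale(landmarks[, , i], scale = FALSE)
    aligned[, , i] <- m / centroid_size(m)
  }
  consensus <- aligned[, , 1L]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      aligned[, , i] <- opt_rotate(aligned[, , i], consensus,
                                   allow_reflection)
    }
    new_cons <- apply(aligned, c(1L, 2L), mean)
    new_cons <- new_cons / centroid_size(new_cons)
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol && it > 1L) {
      dists <- apply(aligned, 3L, function(m) sqrt(sum((m - consensus)^2)))
      return(structure(list(aligned = aligned, consensus = consensus,
                            distances = dists, iterations = it),
                       class = "gpa"))
    }
  }
  stopf("GPA did not converge in %d iterations (last consensus change %.3g)",
        max_iter, delta)
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("GPA: %d specimens, %d landmarks, converged in %d iterations\n",
              dim(x$aligned)[3L], dim(x$aligned)[1L], x$iterations))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Partial Procrustes distance: the root sum of squared differences after
#' both configurations are centered, scaled to unit centroid size and
#' optimally rotated onto each other.
#'
#' @param a,b `k x 3` landmark matrices.
#' @param allow_reflection permit improper rotations.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  ca <- scale(a, scale = FALSE); ca <- ca / centroid_size(ca)
  cb <- scale(b, scale = FALSE); cb <- cb / centroid_size(cb)
  rb <- opt_rotate(cb, ca, allow_reflection)
  sqrt(sum((ca - rb)^2))
}

#' Principal component analysis of aligned shapes
#'
#' PCA of the vectorised GPA-aligned coordinates: scores are the centered
#' data projected on the covariance eigenvectors. Each axis is oriented so
#' that its largest-magnitude loading is positive, making score signs
#' platform independent.
#'
#' @param g a [gpa()] result.
#' @return object of class `shape_pca`: `scores` (n x n_axes), `variance`
#'   (proportion of variance per axis, summing to 1 over all retained
#'   axes), `loadings` (one column per axis), `center` (the vectorised
#'   consensus of the data).
#' @export
shape_pca <- function(g) {
  stopifnot(inherits(g, "gpa"))
  n <- dim(g$aligned)[3L]
  if (n < 2L) stopf("PCA needs at least 2 specimens")
  X <- t(apply(g$aligned, 3L, as.numeric))   # n x 3k
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vars <- pc$sdev[keep]^2
  structure(list(scores = scores, variance = vars / sum(vars),
                 loadings = loadings, center = pc$center),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  v <- x$variance[seq_len(min(4L, length(x$variance)))]
  cat(sprintf("shape PCA: %d specimens; variance explained: %s\n",
              nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_along(v), 100 * v),
                    collapse = ", ")))
  invisible(x)
}

#' Pseudo-landmarks by farthest-point sampling
#'
#' Samples `k` well-spread vertices from a mesh surface by farthest-point
#' sampling from a seeded random start vertex; a deterministic stand-in for
#' automated landmark correspondence tools when only desk-scale geometry is
#' needed.
#'
#' @param mesh a [spine_mesh()].
#' @param k number of points (<= vertex count).
#' @param seed integer seed choosing the start vertex.
#' @return `k x 3` matrix of sampled vertices.
#' @export
pseudo_landmarks <- function(mesh, k, seed = 1L) {
  stopifnot(inherits(mesh, "spine_mesh"))
  v <- mesh$vertices
  nv <- nrow(v)
  if (k > nv) stopf("k = %d exceeds the vertex count (%d)", k, nv)
  start <- with_seed(seed, sample.int(nv, 1L))
  picked <- integer(k)
  picked[1L] <- start
  d2 <- colSums((t(v) - v[start, ])^2)
  if (k > 1L) {
    for (i in 2:k) {
      nxt <- which.max(d2)
      picked[i] <- nxt
      d2 <- pmin(d2, colSums((t(v) - v[nxt, ])^2))
    }
  }
  v[picked, , drop = FALSE]
}
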