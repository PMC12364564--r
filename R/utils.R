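# Internal helpers shared across modules.

# Run `expr` with a reproducible RNG stream without disturbing the caller's
# global RNG state. All seeded operations in the package go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Signed area of a closed polygon (vertices as n x 2 matrix, not repeated).
polygon_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Cumulative boundary arclength of a closed polygon, starting at vertex 1.
polygon_arclength <- function(v) {
  d <- sqrt(rowSums((v - v[c(2:nrow(v), 1L), , drop = FALSE])^2))
  c(0, cumsum(d[-length(d)]))
}

# Maximum pairwise vertex distance (caliper length of the outline).
polygon_longest_axis <- function(v) {
  # convex hull keeps the extremes; O(h^2) on the hull is cheap
  h <- grDevices::chull(v)
  hv <- v[h, , drop = FALSE]
  dm <- as.matrix(stats::dist(hv))
  max(dm)
}

# Exact simplicity test: no two non-adjacent edges of the closed polygon
# intersect. Vectorised over all edge pairs.
polygon_is_simple <- function(v, tol = 1e-12) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  p1 <- v
  p2 <- v[c(2:n, 1L), , drop = FALSE]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  a1 <- p1[i, , drop = FALSE]; a2 <- p2[i, , drop = FALSE]
  b1 <- p1[j, , drop = FALSE]; b2 <- p2[j, , drop = FALSE]
  d1 <- a2 - a1; d2 <- b2 - b1
  denom <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  rx <- b1[, 1L] - a1[, 1L]; ry <- b1[, 2L] - a1[, 2L]
  t_num <- rx * d2[, 2L] - ry * d2[, 1L]
  u_num <- rx * d1[, 2L] - ry * d1[, 1L]
  nonpar <- abs(denom) > tol
  t <- t_num[nonpar] / denom[nonpar]
  u <- u_num[nonpar] / denom[nonpar]
  crossing <- t > tol & t < 1 - tol & u > tol & u < 1 - tol
  if (any(crossing)) return(FALSE)
  # parallel overlapping segments
  par <- !nonpar & abs(u_num) <= tol
  if (any(par)) {
    for (k in which(par)) {
      aa <- rbind(a1[k, ], a2[k, ]); bb <- rbind(b1[k, ], b2[k, ])
      ax <- range(aa[, 1L]); bx <- range(bb[, 1L])
      ay <- range(aa[, 2L]); by <- range(bb[, 2L])
      if (ax[1L] <= bx[2L] + tol && bx[1L] <= ax[2L] + tol &&
          ay[1L] <= by[2L] + tol && by[1L] <= ay[2L] + tol) {
        return(FALSE)
      }
    }
  }
  TRUE
}
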