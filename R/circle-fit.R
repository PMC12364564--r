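#' Least-squares circle fit
#'
#' Fits a circle to 2D points by an algebraic (Kasa) fit followed by
#' Gauss-Newton refinement of the geometric (radial) residuals. This is the
#' primitive behind the tip radius-of-curvature and structural-curvature
#' measurements: sharpness of a puncture tool is conventionally summarised by
#' the radius of the circular arc that best fits its apex, and whole-tool
#' curvature by a circle fit to its centerline.
#'
#' @param points numeric matrix (n x 2) of point coordinates; n >= 3 and the
#'   points must not be collinear.
#' @param max_iter maximum Gauss-Newton iterations for the geometric
#'   refinement.
#' @param tol convergence tolerance on the relative parameter update.
#' @return an object of class `circle_fit`: a list with `center` (length-2
#'   numeric), `radius`, `rmse` (root-mean-square radial residual) and
#'   `n_points`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' fit <- fit_circle(cbind(cos(th), sin(th)))
#' fit$radius  # 1
#' @export
fit_circle <- function(points, max_iter = 50L, tol = 1e-12) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stopf("`points` must be an n x 2 matrix with n >= 3")
  }
  if (anyNA(points)) stopf("`points` contains missing values")
  n <- nrow(points)
  ctr <- colMeans(points)
  x <- points[, 1L] - ctr[1L]
  y <- points[, 2L] - ctr[2L]
  # collinearity check via second singular value
  sv <- svd(cbind(x, y), nu = 0L, nv = 0L)$d
  scale <- max(sv[1L], .Machine$double.eps)
  if (sv[2L] / scale < 1e-9) {
    stopf("circle fit is degenerate: the %d points are (near-)collinear", n)
  }

  # Kasa algebraic fit (exact on noiseless circle points, numerically
  # stable on shallow arcs) seeds the geometric refinement
  z <- x^2 + y^2
  k <- qr.solve(cbind(2 * x, 2 * y, 1), z)
  cx <- k[1L]; cy <- k[2L]
  r <- sqrt(max(k[3L] + cx^2 + cy^2, .Machine$double.eps))

  # Gauss-Newton on radial residuals r_i(cx, cy, r) = |p_i - c| - r
  par <- c(cx, cy, r)
  for (it in seq_len(max_iter)) {
    dx <- x - par[1L]; dy <- y - par[2L]
    di <- sqrt(dx^2 + dy^2)
    di[di < .Machine$double.eps] <- .Machine$double.eps
    res <- di - par[3L]
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    par <- par + step
    if (max(abs(step)) < tol * max(abs(par), 1)) break
  }
  dx <- x - par[1L]; dy <- y - par[2L]
  res <- sqrt(dx^2 + dy^2) - par[3L]
  structure(
    list(center = c(par[1L] + ctr[1L], par[2L] + ctr[2L]),
         radius = par[3L],
         rmse = sqrt(mean(res^2)),
         n_points = n),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle fit: center (%.4g, %.4g), radius %.4g, rmse %.3g (n = %d)\n",
              x$center[1L], x$center[2L], x$radius, x$rmse, x$n_points))
  invisible(x)
}
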