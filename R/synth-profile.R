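#' Parameter set for synthetic spine profiles
#'
#' Bundles and validates the generative parameters of a synthetic spine:
#' an outline tapering around a circular-arc centerline, with a wedge apex of
#' a given tip angle rounded by a circular cap of a given radius. These are
#' the generative counterparts of the three tool-property metrics (tip angle,
#' tip radius of curvature, structural curvature), so every generated profile
#' carries exact ground truth for them.
#'
#' @param length longest-axis length of the finished profile, mm (> 0). All
#'   profiles are scaled to a common longest axis, mirroring the convention of
#'   testing shape (not size) effects.
#' @param tip_angle apex wedge angle, degrees (5-120).
#' @param tip_roc radius of the circular cap rounding the apex, mm; must be
#'   smaller than `base_width / 2`.
#' @param structural_curvature arc angle, degrees (0-150), subtended by the
#'   physical centerline (tip to base) on its generating circle. 0 gives a
#'   straight cone.
#' @param base_width maximum outline width, mm; the tapering half-width
#'   saturates at `base_width / 2`.
#' @param waviness dimensionless amplitude (>= 0) of a sinusoidal lateral
#'   perturbation of the centerline, in units of `base_width`; 0 (default)
#'   gives a smooth spine.
#' @param lateral_compression out-of-plane to in-plane width ratio in (0, 1],
#'   used when revolving the profile into a mesh; 1 gives circular
#'   cross-sections.
#' @param n_points number of polygon vertices (>= 64).
#' @param seed integer seed (only consumed by downstream stochastic steps;
#'   the profile itself is deterministic).
#' @return a validated list of class `spine_gen_params`.
#' @export
spine_gen_params <- function(length = 3.22, tip_angle = 30, tip_roc = 0.06,
                             structural_curvature = 20, base_width = NULL,
                             waviness = 0, lateral_compression = 1,
                             n_points = 512L, seed = 1L) {
  if (is.null(base_width)) {
    # wide enough that the flanks stay straight through the tip-angle
    # measurement window, while keeping the tool slender enough for a
    # well-defined centerline
    base_width <- max(0.12, 0.35 * sin(deg2rad(tip_angle) / 2)) * length
  }
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(tip_angle, "tip_angle", lower = 5, upper = 120)
  check_number(tip_roc, "tip_roc", lower = 0, strict_lower = TRUE)
  check_number(structural_curvature, "structural_curvature", lower = 0,
               upper = 180, strict_upper = TRUE)
  check_number(base_width, "base_width", lower = 0, strict_lower = TRUE)
  check_number(waviness, "waviness", lower = 0)
  check_number(lateral_compression, "lateral_compression", lower = 0,
               upper = 1, strict_lower = TRUE)
  if (!is.numeric(n_points) || n_points < 64) {
    stopf("`n_points` must be >= 64")
  }
  beta <- deg2rad(tip_angle) / 2
  if (tip_roc * cos(beta) >= base_width / 2) {
    stopf(paste0("invalid parameter combination: the rounded tip cap ",
                 "(width %.3g) is wider than the local outline width (%.3g)"),
          2 * tip_roc * cos(beta), base_width)
  }
  structure(list(length = length, tip_angle = tip_angle, tip_roc = tip_roc,
                 structural_curvature = structural_curvature,
                 base_width = base_width, waviness = waviness,
                 lateral_compression = lateral_compression,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "spine_gen_params")
}

#' Spine profile container
#'
#' A closed 2D polygon describing a spine outline in its local sagittal plane
#' (the plane in which test rotations occur), with the tip pointing toward -y
#' at a 0 degree approach angle.
#'
#' @param vertices n x 2 numeric matrix of polygon vertices in order (not
#'   repeated at the end), mm.
#' @param tip_index index of the apex vertex.
#' @param check if `TRUE`, verify the polygon is simple (no
#'   self-intersections).
#' @return an object of class `spine_profile`.
#' @export
spine_profile <- function(vertices, tip_index, check = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 8L) {
    stopf("`vertices` must be an n x 2 matrix with n >= 8")
  }
  if (check && !polygon_is_simple(vertices)) {
    stopf("profile polygon is not simple (self-intersecting)")
  }
  if (polygon_signed_area(vertices) < 0) {
    n <- nrow(vertices)
    vertices <- vertices[n:1, , drop = FALSE]
    tip_index <- n + 1L - tip_index
  }
  structure(list(vertices = vertices, tip_index = as.integer(tip_index)),
            class = "spine_profile")
}

#' @export
print.spine_profile <- function(x, ...) {
  cat(sprintf("spine profile: %d vertices, longest axis %.4g mm\n",
              nrow(x$vertices), polygon_longest_axis(x$vertices)))
  invisible(x)
}

# Centerline position/tangent for an arc of curvature 1/R starting at the
# origin with tangent +y (tip pointing -y), curving toward -x. `s` is
# arclength from the physical tip front. R = Inf gives a straight line.
arc_point <- function(s, R) {
  if (!is.finite(R)) return(cbind(0 * s, s))
  cbind(R * (cos(s / R) - 1), R * sin(s / R))
}
arc_angle_at <- function(s, R) {
  if (!is.finite(R)) return(rep(pi / 2, length(s)))
  pi / 2 + s / R
}

#' Generate a synthetic spine profile with exact ground truth
#'
#' Constructs a closed outline by sweeping a tapering half-width along a
#' circular-arc centerline and rounding the apex with an exact circular cap.
#' The centerline length is solved (by root finding) so that the finished
#' outline's longest axis equals `params$length`; the cap radius and the arc
#' angle are therefore exact in final units and are returned as ground truth.
#'
#' Half-width along the centerline is `tan(tip_angle/2) * t` (t = distance
#' from the ideal wedge apex), saturating at `base_width / 2`; the apex is
#' rounded by the circle of radius `tip_roc` inscribed in the wedge, and the
#' base is cut flat. A nonzero `waviness` adds a sinusoidal lateral
#' displacement to the centerline (tapered to zero at both ends).
#'
#' @param params a [spine_gen_params()] object.
#' @return a list with components `profile` (a [spine_profile()]) and
#'   `ground_truth`: tip_angle (deg), tip_roc (mm), tip_roc_norm,
#'   structural_curvature (deg), length (mm), aspect_ratio, max_width (mm),
#'   centerline (matrix, ordered base to tip), arc_radius (mm; `Inf` when
#'   straight) and `lateral_compression`.
#' @examples
#' gs <- generate_spine_profile(spine_gen_params(tip_angle = 60,
#'                                               structural_curvature = 0))
#' gs$ground_truth$tip_angle
#' @export
generate_spine_profile <- function(params) {
  stopifnot(inherits(params, "spine_gen_params"))
  p <- params
  beta <- deg2rad(p$tip_angle) / 2
  r <- p$tip_roc
  t_c <- r / sin(beta)          # cap center distance from ideal apex
  t_front <- t_c - r            # physical tip front
  t_tan <- t_c * cos(beta)^2    # cap/flank tangency
  theta <- deg2rad(p$structural_curvature)

  build <- function(Lambda, n_flank, n_cap, n_base) {
    s_phys <- Lambda - t_front
    R <- if (theta > 1e-9) s_phys / theta else Inf
    half_w <- function(t) pmin(tan(beta) * t, p$base_width / 2)
    # flank stations, ideal-apex parameter t from tangency to base
    t_st <- seq(t_tan, Lambda, length.out = n_flank)
    s_st <- t_st - t_front
    cl <- arc_point(s_st, R)
    psi <- arc_angle_at(s_st, R)
    if (p$waviness > 0) {
      u <- (s_st - s_st[1L]) / (s_phys - s_st[1L] + .Machine$double.eps)
      amp <- p$waviness * p$base_width
      off <- amp * sin(2 * pi * 2.5 * u) * sin(pi * u)^2
      nrm0 <- cbind(-sin(psi), cos(psi))
      cl <- cl + off * nrm0
      # recompute tangent direction numerically
      dv <- rbind(cl[2L, ] - cl[1L, ], (cl[-(1:2), ] - cl[1:(n_flank - 2L), ]) / 2,
                  cl[n_flank, ] - cl[n_flank - 1L, ])
      psi <- atan2(dv[, 2L], dv[, 1L])
    }
    nrm <- cbind(-sin(psi), cos(psi))
    h <- half_w(t_st)
    left <- cl + h * nrm
    right <- cl - h * nrm
    # exact circular cap between the two tangencies
    cap_c <- arc_point(t_c - t_front, R)
    psi_c <- arc_angle_at(t_c - t_front, R)
    gam <- seq(psi_c - (pi / 2 + beta), psi_c - (3 * pi / 2 - beta),
               length.out = n_cap)
    cap <- cbind(cap_c[1L] + r * cos(gam), cap_c[2L] + r * sin(gam))
    base_seg <- cbind(
      seq(right[n_flank, 1L], left[n_flank, 1L], length.out = n_base + 2L),
      seq(right[n_flank, 2L], left[n_flank, 2L], length.out = n_base + 2L)
    )
    # order: right flank base->tip, cap right->left (through apex), left
    # flank tip->base, base edge left->right (interior points only)
    verts <- rbind(right[n_flank:1, , drop = FALSE],
                   cap,
                   left,
                   base_seg[(n_base + 1L):2L, , drop = FALSE])
    tip_index <- n_flank + (n_cap + 1L) %/% 2L
    list(vertices = verts, tip_index = tip_index,
         centerline = rbind(cl[n_flank:1, , drop = FALSE],
                            cbind(cap_c[1L] + r * cos(psi_c - pi),
                                  cap_c[2L] + r * sin(psi_c - pi))),
         R = R, s_phys = s_phys)
  }

  # vertex budget: cap gets points proportional to its share of the boundary
  # but at least 24; base edge a small fixed share
  n_cap <- max(25L, as.integer(round(p$n_points * 0.12)))
  if (n_cap %% 2L == 0L) n_cap <- n_cap + 1L  # odd count puts a vertex at the apex
  n_base <- max(4L, as.integer(round(p$n_points * 0.03)))
  n_flank <- max(16L, (p$n_points - n_cap - n_base) %/% 2L)

  axis_len <- function(Lambda) {
    b <- build(Lambda, 64L, 24L, 2L)  # coarse build is enough for the solve
    polygon_longest_axis(b$vertices)
  }
  lo <- max(t_tan * 1.1, 0.02 * p$length)
  hi <- 4 * p$length
  if (axis_len(lo) > p$length) {
    stopf(paste0("invalid parameter combination: the rounded tip cap alone ",
                 "is longer than the requested length"))
  }
  Lambda <- stats::uniroot(function(L) axis_len(L) - p$length,
                           lower = lo, upper = hi, tol = 1e-10)$root
  b <- build(Lambda, n_flank, n_cap, n_base)
  prof <- spine_profile(b$vertices, b$tip_index, check = TRUE)
  max_w <- 2 * min(half_width_max <- p$base_width / 2,
                   tan(beta) * Lambda)
  achieved <- polygon_longest_axis(b$vertices)
  gt <- list(
    tip_angle = p$tip_angle,
    tip_roc = r,
    tip_roc_norm = r / p$length,
    structural_curvature = p$structural_curvature,
    length = achieved,
    max_width = max_w,
    aspect_ratio = max_w / achieved,
    centerline = b$centerline,
    arc_radius = b$R,
    lateral_compression = p$lateral_compression
  )
  list(profile = prof, ground_truth = gt)
}

#' Write / read a spine profile as a CSV polygon
#'
#' Plain-text interchange for profiles: a two-column CSV (`x_mm`, `y_mm`) of
#' ordered polygon vertices, with the apex index recorded in a `tip` column
#' (1 for the apex vertex, 0 elsewhere).
#'
#' @param profile a [spine_profile()].
#' @param path file path.
#' @return `read_spine_profile` returns a [spine_profile()];
#'   `write_spine_profile` returns `path` invisibly.
#' @export
write_spine_profile <- function(profile, path) {
  stopifnot(inherits(profile, "spine_profile"))
  df <- data.frame(x_mm = profile$vertices[, 1L],
                   y_mm = profile$vertices[, 2L],
                   tip = as.integer(seq_len(nrow(profile$vertices)) ==
                                      profile$tip_index))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spine_profile
#' @export
read_spine_profile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "tip")
  if (!all(need %in% names(df))) {
    stopf("profile CSV must have columns %s", paste(need, collapse = ", "))
  }
  spine_profile(cbind(df$x_mm, df$y_mm), which(df$tip == 1L)[1L])
}
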