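# Tool-property metrics from 2D profiles: centerline extraction, tip angle,
# tip radius of curvature, structural curvature, morphotype classification.

# Boundary arclength distance from the tip vertex along each side of the
# outline. Returns, per side, vertex indices ordered away from the apex and
# their distances.
flank_arclengths <- function(profile) {
  v <- profile$vertices
  n <- nrow(v)
  ti <- profile$tip_index
  edge_len <- sqrt(rowSums((v[c(2:n, 1L), , drop = FALSE] - v)^2))
  # side A: indices ti+1, ti+2, ... ; side B: ti-1, ti-2, ...
  idx_a <- ((ti:(ti + n - 2L)) %% n) + 1L       # ti+1 .. around
  dist_a <- cumsum(edge_len[((ti - 1L):(ti + n - 3L)) %% n + 1L])
  idx_b <- (((ti - 2L):(ti - n)) %% n) + 1L     # ti-1 .. around
  # edge from idx_b[k] to its successor lies toward the tip
  dist_b <- cumsum(edge_len[idx_b])
  list(a = list(idx = idx_a, dist = dist_a),
       b = list(idx = idx_b, dist = dist_b))
}

point_in_polygon <- function(pt, v) {
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > pt[2L]) != (yn > pt[2L]))
  if (!any(crosses)) return(FALSE)
  xs <- x[crosses] + (pt[2L] - y[crosses]) / (yn[crosses] - y[crosses]) *
    (xn[crosses] - x[crosses])
  sum(xs > pt[1L]) %% 2L == 1L
}

# Intersections of the line p0 + tau * dir with all polygon edges; returns
# tau values (sorted) and the index of the crossed edge for each.
line_polygon_tau <- function(p0, dir, v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  denom <- dir[1L] * ey - dir[2L] * ex
  ok <- abs(denom) > 1e-14
  rx <- a[, 1L] - p0[1L]; ry <- a[, 2L] - p0[2L]
  tau <- (rx * ey - ry * ex) / denom
  u <- (rx * dir[2L] - ry * dir[1L]) / denom
  hit <- which(ok & u >= 0 & u < 1)
  o <- order(tau[hit])
  list(tau = tau[hit][o], edge = hit[o])
}

#' Extract the centerline of a spine profile
#'
#' Traces the locus of cross-section midpoints from the apex to the base.
#' Slices are taken perpendicular to the locally estimated axis direction
#' (updated as the trace advances), so the trace follows curved and hooked
#' spines; for an outline built as symmetric offsets around a circular-arc
#' centerline the midpoints recover that arc exactly (up to discretisation).
#' The trace starts at the apex vertex and ends where the axis exits through
#' the base, giving the base midpoint.
#'
#' @param profile a [spine_profile()].
#' @param n_stations number of stations in the returned polyline (>= 2). The
#'   first station is the base midpoint and the last is the apex vertex.
#' @return an `n_stations x 2` matrix ordered base to tip, with attribute
#'   `half_width`: the local cross-section half-width at each station (0 at
#'   the apex).
#' @export
extract_centerline <- function(profile, n_stations = 200L) {
  stopifnot(inherits(profile, "spine_profile"))
  if (n_stations < 2L) stopf("`n_stations` must be >= 2")
  v <- profile$vertices
  n <- nrow(v)
  tip <- v[profile$tip_index, ]
  per <- polygon_arclength(v)
  total <- per[n] + sqrt(sum((v[n, ] - v[1L, ])^2))
  # initial direction: from the apex toward the midpoint of the chord
  # between the two flanks a short way down the outline
  fl <- flank_arclengths(profile)
  probe <- 0.02 * total
  pa <- v[fl$a$idx[which.min(abs(fl$a$dist - probe))], ]
  pb <- v[fl$b$idx[which.min(abs(fl$b$dist - probe))], ]
  d0 <- (pa + pb) / 2 - tip
  d0 <- d0 / sqrt(sum(d0^2))

  step <- total / 600
  max_steps <- 3000L
  mids <- matrix(NA_real_, max_steps + 2L, 2L)
  hws <- numeric(max_steps + 2L)
  mids[1L, ] <- tip
  hws[1L] <- 0
  edge_vec <- v[c(2:n, 1L), , drop = FALSE] - v
  d <- d0
  m <- tip
  cnt <- 1L
  for (it in seq_len(max_steps)) {
    p_next <- m + step * d
    if (!point_in_polygon(p_next, v)) break   # exited through the base
    nrm <- c(-d[2L], d[1L])
    hit <- line_polygon_tau(p_next, nrm, v)
    lo <- which(hit$tau <= 0)
    hi <- which(hit$tau > 0)
    if (length(lo) == 0L || length(hi) == 0L) {
      stopf("centerline trace failed: cross-section at station %d is not simply connected", it)
    }
    i_lo <- lo[which.max(hit$tau[lo])]
    i_hi <- hi[which.min(hit$tau[hi])]
    t_lo <- hit$tau[i_lo]; t_hi <- hit$tau[i_hi]
    m_new <- p_next + (t_lo + t_hi) / 2 * nrm
    hw <- (t_hi - t_lo) / 2
    # a sudden width collapse or strongly off-center chord means the slice
    # clipped the base corner: the base has been reached
    if (it > 10L && (hw < 0.8 * hws[cnt] || abs(t_lo + t_hi) / 2 > 0.5 * hw)) {
      break
    }
    cnt <- cnt + 1L
    mids[cnt, ] <- m_new
    hws[cnt] <- hw
    # axis direction from the boundary tangents at the two crossings,
    # weighted so their cross-axis components cancel: for symmetric offsets
    # of a straight or circular-arc centerline the weighted combination is
    # exactly the centerline tangent, and the estimate does not feed back
    # through the midpoints (secant-based updates oscillate in tapering
    # regions)
    e1 <- edge_vec[hit$edge[i_lo], ]
    e2 <- edge_vec[hit$edge[i_hi], ]
    e1 <- e1 / sqrt(sum(e1^2)); e2 <- e2 / sqrt(sum(e2^2))
    if (sum(e1 * d) < 0) e1 <- -e1
    if (sum(e2 * d) < 0) e2 <- -e2
    u1n <- sum(e1 * nrm); u2n <- sum(e2 * nrm)
    # cancellation is only meaningful when the flanks diverge to opposite
    # sides; otherwise (parallel-sided region) the plain bisector is the
    # tube direction
    s <- if (u1n * u2n < 0) u2n / (u2n - u1n) else 0.5
    s <- max(0.1, min(0.9, s))
    bis <- s * e1 + (1 - s) * e2
    blen <- sqrt(sum(bis^2))
    if (blen > 1e-9) d <- bis / blen
    m <- m_new
  }
  if (cnt < 3L) stopf("centerline trace failed near the apex")
  mids <- mids[seq_len(cnt), , drop = FALSE]
  hws <- hws[seq_len(cnt)]

  # Fixed-point refinement: re-slice perpendicular to wide-window chord
  # tangents of the current polyline. For a circular arc the chord between
  # points at s -/+ w/2 is exactly parallel to the tangent at s, so wide
  # windows cost no accuracy on arcs while suppressing the short-wavelength
  # errors the marching seed leaves in blunt tapering regions (window
  # proportional to the local width keeps the update a contraction).
  mids <- mids[nrow(mids):1L, , drop = FALSE]   # base -> tip
  hws <- rev(hws)
  for (pass in 1:5) {
    seg <- sqrt(rowSums((mids[-1L, , drop = FALSE] -
                           mids[-nrow(mids), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    ok <- c(TRUE, diff(s) > 1e-12)
    s <- s[ok]; mids <- mids[ok, , drop = FALSE]; hws <- hws[ok]
    stot <- s[length(s)]
    k <- 160L
    s_st <- seq(0, stot, length.out = k)
    px <- stats::approx(s, mids[, 1L], xout = s_st)$y
    py <- stats::approx(s, mids[, 2L], xout = s_st)$y
    ph <- stats::approx(s, hws, xout = s_st)$y
    at <- function(sq) cbind(stats::approx(s, mids[, 1L], xout = sq, rule = 2)$y,
                             stats::approx(s, mids[, 2L], xout = sq, rule = 2)$y)
    new_p <- cbind(px, py)
    new_h <- ph
    updated <- logical(k)
    for (i in 2:(k - 1L)) {
      w <- min(max(4 * ph[i], 8 * stot / k), 0.8 * stot)
      a <- at(max(0, s_st[i] - w / 2))
      b <- at(min(stot, s_st[i] + w / 2))
      tg <- b - a
      tl <- sqrt(sum(tg^2))
      if (tl < 1e-12) next
      tg <- tg / tl
      nr <- c(-tg[2L], tg[1L])
      p0 <- c(px[i], py[i])
      hit <- line_polygon_tau(p0, nr, v)
      lo <- which(hit$tau <= 0); hi <- which(hit$tau > 0)
      if (!length(lo) || !length(hi)) next
      i_lo <- lo[which.max(hit$tau[lo])]
      i_hi <- hi[which.min(hit$tau[hi])]
      t_lo <- hit$tau[i_lo]; t_hi <- hit$tau[i_hi]
      # a valid cross-section crosses two flank edges, which run roughly
      # along the axis; an edge nearly perpendicular to the axis is the
      # base edge, so the slice missed the tool body
      e1 <- edge_vec[hit$edge[i_lo], ]; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- edge_vec[hit$edge[i_hi], ]; e2 <- e2 / sqrt(sum(e2^2))
      if (min(abs(sum(e1 * tg)), abs(sum(e2 * tg))) < 0.35) next
      new_p[i, ] <- p0 + (t_lo + t_hi) / 2 * nr
      new_h[i] <- (t_hi - t_lo) / 2
      updated[i] <- TRUE
    }
    new_p[k, ] <- tip
    new_h[k] <- 0
    # drop stale stations at the base end (their slices hit the base edge)
    # and rebuild the base endpoint as the axis exit through the boundary
    first_ok <- which(updated)[1L]
    if (is.na(first_ok)) first_ok <- 2L
    keep_i <- c(first_ok - 1L, first_ok:k)
    new_p <- new_p[unique(keep_i), , drop = FALSE]
    new_h <- new_h[unique(keep_i)]
    j <- 2L
    tg0 <- new_p[j, ] - new_p[min(j + 2L, nrow(new_p)), ]
    tg0 <- tg0 / sqrt(sum(tg0^2))
    tau_exit <- line_polygon_tau(new_p[j, ], tg0, v)$tau
    tau_exit <- tau_exit[tau_exit > 1e-9]
    if (length(tau_exit)) {
      new_p[1L, ] <- new_p[j, ] + min(tau_exit) * tg0
      new_h[1L] <- new_h[j]
    }
    mids <- new_p
    hws <- new_h
  }
  base_mid <- mids[1L, ]
  cnt <- nrow(mids)

  if (n_stations == 2L) {
    out <- rbind(base_mid, tip)
    dimnames(out) <- NULL
    attr(out, "half_width") <- c(hws[1L], 0)
    return(out)
  }
  # resample (already base -> tip) by arclength
  seg <- sqrt(rowSums((mids[-1L, , drop = FALSE] -
                         mids[-nrow(mids), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  keep2 <- c(TRUE, diff(s) > 1e-12)
  s <- s[keep2]; mids <- mids[keep2, , drop = FALSE]; hws <- hws[keep2]
  s_out <- seq(0, s[length(s)], length.out = n_stations)
  out <- cbind(stats::approx(s, mids[, 1L], xout = s_out)$y,
               stats::approx(s, mids[, 2L], xout = s_out)$y)
  out[1L, ] <- base_mid
  out[n_stations, ] <- tip
  hw_out <- stats::approx(s, hws, xout = s_out)$y
  dimnames(out) <- NULL
  attr(out, "half_width") <- hw_out
  out
}

# Vertices of one flank within a boundary-arclength window of the apex.
flank_points <- function(profile, from, to) {
  fl <- flank_arclengths(profile)
  v <- profile$vertices
  pick <- function(side) {
    sel <- side$dist > from & side$dist <= to
    v[side$idx[sel], , drop = FALSE]
  }
  list(a = pick(fl$a), b = pick(fl$b))
}

# Total-least-squares line direction, oriented away from the apex.
tls_direction <- function(pts, apex) {
  ctr <- colMeans(pts)
  d <- svd(sweep(pts, 2L, ctr))$v[, 1L]
  if (sum(d * (ctr - apex)) < 0) d <- -d
  d
}

#' Measure the tip angle of a spine profile
#'
#' The tip angle is the wedge angle formed by the tapering flanks near the
#' apex: total-least-squares lines are fit to the two flank point sets lying
#' within `flank_window` of the apex (by boundary arclength, as a fraction of
#' the longest-axis length), excluding the rounded cap within
#' `cap_exclusion`, and the angle between the two fitted lines is returned.
#'
#' @param profile a [spine_profile()].
#' @param flank_window outer window bound, fraction of longest-axis length in
#'   (0, 1).
#' @param cap_exclusion inner bound excluding the rounded cap, fraction of
#'   longest-axis length; must be smaller than `flank_window`.
#' @return tip angle in degrees, in (0, 180).
#' @export
measure_tip_angle <- function(profile, flank_window = 0.15,
                              cap_exclusion = 0.05) {
  stopifnot(inherits(profile, "spine_profile"))
  check_number(flank_window, "flank_window", 0, 1, TRUE, TRUE)
  check_number(cap_exclusion, "cap_exclusion", 0, 1, FALSE, TRUE)
  if (cap_exclusion >= flank_window) {
    stopf("`cap_exclusion` must be smaller than `flank_window`")
  }
  L <- polygon_longest_axis(profile$vertices)
  fp <- flank_points(profile, cap_exclusion * L, flank_window * L)
  if (nrow(fp$a) < 5L || nrow(fp$b) < 5L) {
    stopf("too few flank points in the window (%d / %d); widen `flank_window` or increase profile resolution",
          nrow(fp$a), nrow(fp$b))
  }
  apex <- profile$vertices[profile$tip_index, ]
  da <- tls_direction(fp$a, apex)
  db <- tls_direction(fp$b, apex)
  rad2deg(acos(max(-1, min(1, sum(da * db)))))
}

#' Measure the tip radius of curvature
#'
#' Fits a circle to the outline points within `cap_window` (boundary
#' arclength, fraction of the longest-axis length) of the apex. The
#' normalised value divides by the longest-axis length, so it is comparable
#' across tools scaled to a common length. A fit whose root-mean-square
#' residual exceeds `rmse_tol` times the radius is flagged unreliable (this
#' happens when the window reaches past the rounded cap onto straight
#' flanks, where no circle describes the outline).
#'
#' @param profile a [spine_profile()].
#' @param cap_window window size as a fraction of longest-axis length
#'   (default 0.05).
#' @param rmse_tol relative residual threshold for the `reliable` flag.
#' @param adaptive if `TRUE` (default) and the fit at `cap_window` is
#'   unreliable, the window is repeatedly shrunk (by 30%) until the fit
#'   becomes reliable or too few points remain; the fit from the last usable
#'   window is returned. With `adaptive = FALSE` the fixed window is used
#'   as given.
#' @return list with `tip_roc` (mm), `tip_roc_norm`, `rmse` (mm),
#'   `cap_window` (the window actually used) and `reliable` (logical).
#' @export
measure_tip_roc <- function(profile, cap_window = 0.05, rmse_tol = 0.02,
                            adaptive = TRUE) {
  stopifnot(inherits(profile, "spine_profile"))
  check_number(cap_window, "cap_window", 0, 1, TRUE, TRUE)
  L <- polygon_longest_axis(profile$vertices)
  apex <- profile$vertices[profile$tip_index, , drop = FALSE]
  fit_window <- function(w) {
    fp <- flank_points(profile, 0, w * L)
    pts <- rbind(apex, fp$a, fp$b)
    if (nrow(pts) < 6L) return(NULL)
    fit_circle(pts)
  }
  w <- cap_window
  fit <- fit_window(w)
  if (is.null(fit)) {
    stopf("degenerate cap: too few points within the cap window")
  }
  if (adaptive) {
    while (fit$rmse > rmse_tol * fit$radius) {
      w_new <- w * 0.7
      cand <- fit_window(w_new)
      if (is.null(cand)) break
      w <- w_new
      fit <- cand
    }
  }
  list(tip_roc = fit$radius,
       tip_roc_norm = fit$radius / L,
       rmse = fit$rmse,
       cap_window = w,
       reliable = fit$rmse <= rmse_tol * fit$radius)
}

#' Measure structural curvature
#'
#' Whole-tool curvature is summarised by a circle fit to the centerline: the
#' fit starts at the tip and is extended station by station toward the base
#' for as long as the circle still bisects the tool, operationalised as every
#' included station lying within `deviation_tol` of its local half-width from
#' the fitted circle. The returned value is the arc angle (degrees) subtended
#' at the fitted center between the tip and the last included station.
#' Nearly straight centerlines (fit radius over 1000 times the length)
#' return 0.
#'
#' @param profile a [spine_profile()].
#' @param deviation_tol allowed radial deviation as a fraction of the local
#'   half-width (default 0.25). A floor of 5% of the maximum half-width is
#'   applied so that the vanishing width at the apex does not veto the fit.
#' @param n_stations number of centerline stations traced.
#' @return structural curvature in degrees (>= 0), with attributes `radius`
#'   (fitted circle radius, mm) and `n_used` (stations included).
#' @export
measure_structural_curvature <- function(profile, deviation_tol = 0.25,
                                         n_stations = 200L) {
  stopifnot(inherits(profile, "spine_profile"))
  cl <- extract_centerline(profile, n_stations)
  hw <- attr(cl, "half_width")
  L <- polygon_longest_axis(profile$vertices)
  pts <- cl[nrow(cl):1L, , drop = FALSE]   # tip -> base
  hw <- rev(hw)
  n <- nrow(pts)
  # skip the rounded-cap zone right at the apex: its stations carry no
  # curvature information and their jitter destabilises small fits
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  i0 <- max(2L, which(s >= 0.03 * s[n])[1L])
  tol <- deviation_tol * pmax(hw, 0.1 * max(hw, na.rm = TRUE))

  safe_fit <- function(p) {
    tryCatch(fit_circle(p), error = function(e) NULL)
  }
  ok_fit <- function(k) {
    idx <- i0:k
    cand <- safe_fit(pts[idx, , drop = FALSE])
    if (is.null(cand)) return(NULL)
    dev <- abs(sqrt((pts[idx, 1L] - cand$center[1L])^2 +
                      (pts[idx, 2L] - cand$center[2L])^2) - cand$radius)
    if (any(dev > tol[idx], na.rm = TRUE)) return(NULL)
    cand
  }
  # largest tip-anchored run of stations whose best-fit circle still
  # bisects the tool: search downward from the full centerline (large fits
  # are well conditioned; small ones overfit jitter)
  k_min <- min(n, i0 + max(8L, n %/% 10L))
  fit <- NULL
  k_used <- k_min
  for (k in unique(c(seq(n, k_min, by = -max(1L, n %/% 50L)), k_min))) {
    fit <- ok_fit(k)
    if (!is.null(fit)) { k_used <- k; break }
  }
  if (is.null(fit)) {
    fit <- safe_fit(pts[i0:k_min, , drop = FALSE])
    k_used <- k_min
  }
  if (is.null(fit) || fit$radius > 1e3 * L) {
    return(structure(0, radius = if (is.null(fit)) Inf else fit$radius,
                     n_used = k_used))
  }
  # accumulated arc angle tip -> last included station
  ang <- atan2(pts[i0:k_used, 2L] - fit$center[2L],
               pts[i0:k_used, 1L] - fit$center[1L])
  dd <- diff(ang)
  dd <- (dd + pi) %% (2 * pi) - pi
  structure(abs(sum(dd)) * 180 / pi, radius = fit$radius, n_used = k_used)
}

#' Morphotype classification
#'
#' Assigns the four binary morphotype traits used to choose "markedly
#' different" spine shapes: elongate vs short, hooked vs not hooked, wavy vs
#' straight, conical vs laterally compressed. All thresholds are exposed and
#' recorded in the result.
#'
#' @param metrics a list or one-row data frame with at least `aspect_ratio`
#'   and `structural_curvature` (see [spine_metrics()]).
#' @param centerline centerline polyline from [extract_centerline()] (used
#'   for waviness).
#' @param lateral_compression out-of-plane to in-plane width ratio (1 for
#'   circular cross-sections); from mesh measurement or generation metadata.
#' @param elongate_threshold aspect-ratio threshold: spines with aspect ratio
#'   below it are elongate (default 0.5, i.e. short spines have aspect ratio
#'   approximately over 50%).
#' @param hooked_threshold structural curvature (degrees) at or above which a
#'   spine is hooked (default 60).
#' @param conical_threshold lateral-compression ratio at or above which a
#'   spine counts as conical (default 0.8).
#' @param wavy_min_turn minimum per-station turning angle (degrees) for a
#'   bend to count toward waviness (filters numerical jitter).
#' @return a list of class `morphotype` with logical fields `elongate`,
#'   `hooked`, `wavy`, `conical` and a `thresholds` record.
#' @export
classify_morphotype <- function(metrics, centerline,
                                lateral_compression = 1,
                                elongate_threshold = 0.5,
                                hooked_threshold = 60,
                                conical_threshold = 0.8,
                                wavy_min_turn = 1) {
  m <- as.list(metrics)
  v1 <- centerline[-1L, , drop = FALSE] - centerline[-nrow(centerline), , drop = FALSE]
  # signed turning angles at interior stations
  a <- v1[-nrow(v1), , drop = FALSE]
  b <- v1[-1L, , drop = FALSE]
  crossz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  dot <- rowSums(a * b)
  turn <- rad2deg(atan2(crossz, dot))
  sig <- sign(turn[abs(turn) > wavy_min_turn])
  changes <- if (length(sig) > 1L) sum(diff(sig) != 0) else 0L
  structure(list(
    elongate = m$aspect_ratio < elongate_threshold,
    hooked = m$structural_curvature >= hooked_threshold,
    wavy = changes >= 2L,
    conical = lateral_compression >= conical_threshold,
    thresholds = list(elongate_threshold = elongate_threshold,
                      hooked_threshold = hooked_threshold,
                      conical_threshold = conical_threshold,
                      wavy_min_turn = wavy_min_turn)
  ), class = "morphotype")
}

#' Measure all tool-property metrics of a spine
#'
#' Convenience wrapper running the individual measurements and returning one
#' row per spine, mirroring the per-spine metrics table written for a study:
#' length, tip angle, tip radius of curvature (absolute and
#' length-normalised), structural curvature, aspect ratio, volume (when a
#' mesh is supplied) and morphotype flags.
#'
#' @param profile a [spine_profile()].
#' @param mesh optional [spine_mesh()] for volume and lateral compression.
#' @param spine_id identifier recorded in the output row.
#' @param flank_window,cap_exclusion,cap_window,deviation_tol measurement
#'   windows; see the individual functions.
#' @return a one-row data frame.
#' @export
spine_metrics <- function(profile, mesh = NULL, spine_id = "spine",
                          flank_window = 0.15, cap_exclusion = 0.05,
                          cap_window = 0.05, deviation_tol = 0.25) {
  L <- polygon_longest_axis(profile$vertices)
  cl <- extract_centerline(profile, 200L)
  hw <- attr(cl, "half_width")
  tip_angle <- measure_tip_angle(profile, flank_window, cap_exclusion)
  roc <- measure_tip_roc(profile, cap_window)
  sc <- measure_structural_curvature(profile, deviation_tol)
  aspect <- 2 * max(hw, na.rm = TRUE) / L
  lc <- 1
  vol <- NA_real_
  if (!is.null(mesh)) {
    vol <- measure_volume(mesh)
    zr <- diff(range(mesh$vertices[, 3L]))
    xr <- 2 * max(hw, na.rm = TRUE)
    lc <- if (xr > 0) min(1, zr / xr) else 1
  }
  mt <- classify_morphotype(
    list(aspect_ratio = aspect, structural_curvature = as.numeric(sc)),
    cl, lateral_compression = lc
  )
  data.frame(spine_id = spine_id, length_mm = L,
             tip_angle_deg = tip_angle,
             tip_roc_mm = roc$tip_roc, tip_roc_norm = roc$tip_roc_norm,
             tip_roc_reliable = roc$reliable,
             structural_curvature_deg = as.numeric(sc),
             volume_mm3 = vol, aspect_ratio = aspect,
             elongate = mt$elongate, hooked = mt$hooked, wavy = mt$wavy,
             conical = mt$conical,
             stringsAsFactors = FALSE)
}
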