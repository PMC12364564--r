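# Triangle-mesh construction from profiles, signed volume, OBJ interchange.

#' Spine mesh container
#'
#' A triangle mesh as a vertex matrix and a face index matrix, the minimal
#' representation needed for volume measurement and pseudo-landmark sampling.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices; faces are
#'   oriented counter-clockwise seen from outside.
#' @return an object of class `spine_mesh`.
#' @export
spine_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stopf("`vertices` must be n x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stopf("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "spine_mesh")
}

#' @export
print.spine_mesh <- function(x, ...) {
  cat(sprintf("spine mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Edge audit: a closed orientable surface has every undirected edge shared by
# exactly two faces with opposite directions. Returns the count of open
# (boundary) edges.
mesh_open_edges <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  tab <- table(key)
  sum(tab != 2L)
}

#' Revolve a spine profile into a watertight triangle mesh
#'
#' Sweeps elliptical cross-sections along the profile centerline: at each
#' station the section has in-plane semi-axis equal to the local half-width
#' and out-of-plane semi-axis scaled by `lateral_compression` (1 gives a
#' solid of revolution with circular sections). The mesh is closed with a
#' tip fan at the apex and a base fan at the base centroid.
#'
#' @param profile a [spine_profile()].
#' @param lateral_compression out-of-plane scaling ratio in (0, 1].
#' @param n_stations number of sweep stations along the centerline.
#' @param n_around vertices per cross-section ring.
#' @return a [spine_mesh()].
#' @export
generate_spine_mesh <- function(profile, lateral_compression = 1,
                                n_stations = 96L, n_around = 32L) {
  stopifnot(inherits(profile, "spine_profile"))
  check_number(lateral_compression, "lateral_compression", 0, 1,
               strict_lower = TRUE)
  cl <- extract_centerline(profile, n_stations)
  hw <- attr(cl, "half_width")
  n <- nrow(cl)
  # drop stations with (near-)zero width at the apex end; keep base
  keep <- which(hw > 1e-9)
  cl_k <- cl[keep, , drop = FALSE]
  hw_k <- hw[keep]
  m <- nrow(cl_k)
  tang <- rbind(cl_k[2L, ] - cl_k[1L, ],
                (cl_k[-(1:2), , drop = FALSE] - cl_k[seq_len(m - 2L), , drop = FALSE]) / 2,
                cl_k[m, ] - cl_k[m - 1L, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2L], tang[, 1L])
  phi <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  cphi <- cos(phi); sphi <- sin(phi)
  verts <- matrix(NA_real_, m * n_around + 2L, 3L)
  for (i in seq_len(m)) {
    ring <- cbind(cl_k[i, 1L] + hw_k[i] * cphi * nrm[i, 1L],
                  cl_k[i, 2L] + hw_k[i] * cphi * nrm[i, 2L],
                  hw_k[i] * lateral_compression * sphi)
    verts[(i - 1L) * n_around + seq_len(n_around), ] <- ring
  }
  apex <- profile$vertices[profile$tip_index, ]
  i_tip <- m * n_around + 1L
  i_base <- m * n_around + 2L
  verts[i_tip, ] <- c(apex, 0)
  verts[i_base, ] <- c(cl_k[1L, ], 0)

  ring_idx <- function(i) (i - 1L) * n_around + seq_len(n_around)
  faces <- vector("list", m + 1L)
  # side quads between consecutive rings (station 1 = base end)
  for (i in seq_len(m - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    faces[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  # tip fan: last ring to apex (edge direction opposite to the last band)
  tl <- ring_idx(m); tl2 <- c(tl[-1L], tl[1L])
  faces[[m]] <- cbind(tl2, tl, i_tip)
  # base fan: first ring to base center
  b1 <- ring_idx(1L); b12 <- c(b1[-1L], b1[1L])
  faces[[m + 1L]] <- cbind(b1, b12, i_base)
  mesh <- spine_mesh(verts, do.call(rbind, faces))
  if (measure_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Mesh volume by the divergence theorem
#'
#' Signed volume as the sum of signed tetrahedra spanned by the origin and
#' each triangle; positive for consistently outward-oriented faces. The mesh
#' must be watertight (every edge shared by exactly two faces).
#'
#' @param mesh a [spine_mesh()].
#' @return volume in cubic mm.
#' @export
measure_volume <- function(mesh) {
  stopifnot(inherits(mesh, "spine_mesh"))
  open_e <- mesh_open_edges(mesh)
  if (open_e > 0L) {
    stopf("mesh is not watertight: %d open edges", open_e)
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
        a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
        a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Read and write Wavefront OBJ meshes
#'
#' Minimal OBJ interchange: `v` and `f` records only (triangular faces;
#' polygonal faces are fan-triangulated on read).
#'
#' @param mesh a [spine_mesh()].
#' @param path file path.
#' @return `read_obj` returns a [spine_mesh()]; `write_obj` returns `path`
#'   invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "spine_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (length(vl) == 0L || length(fl) == 0L) {
    stopf("no vertices or faces found in OBJ file '%s'", path)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v ", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f ", "", fl)), "\\s+"),
                                 function(x) {
    idx <- as.integer(sub("/.*", "", x))
    if (length(idx) < 3L) stopf("face with fewer than 3 vertices in OBJ")
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  spine_mesh(verts, faces)
}
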