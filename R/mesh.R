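#' Triangulated surface mesh
#'
#' Vertices are continuous 0-based voxel coordinates (convertible to mm by
#' multiplying with the grid spacing); faces index vertices (1-based).
#'
#' @param vertices numeric `n x 3` matrix.
#' @param faces integer `m x 3` matrix of vertex indices.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract the boundary surface of a binary mask
#'
#' Builds the closed, watertight isosurface of the 0/1 mask at level 0.5
#' as the quadrangulated boundary between foreground and background voxels
#' (each voxel face shared with background becomes two triangles). Voxel
#' `i` occupies the cube `[i - 0.5, i + 0.5]` in 0-based coordinates, so
#' vertices lie on the half-integer lattice.
#'
#' @param mask a nonempty [mask_volume()].
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- mask$voxels
  if (sum(m) == 0) stop("cannot extract a surface from an empty mask")
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  corner_list <- list()
  # For a face with outward normal along +-axis, the 4 corners in a
  # consistent winding (outward for +, mirrored for -).
  quad_corners <- function(axis, sgn) {
    others <- setdiff(1:3, axis)
    base <- matrix(0, 4, 3)
    base[, axis] <- sgn * 0.5
    o <- matrix(c(-0.5, -0.5, 0.5, -0.5, 0.5, 0.5, -0.5, 0.5),
                4, 2, byrow = TRUE)
    if (sgn < 0) o <- o[c(1, 4, 3, 2), ]
    base[, others[1]] <- o[, 1]
    base[, others[2]] <- o[, 2]
    base
  }
  for (axis in 1:3) {
    for (sgn in c(1, -1)) {
      nb <- shift_rep_pad(pad, axis, sgn)
      face <- pad == 1 & nb == 0
      idx <- which(face[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)],
                   arr.ind = TRUE)
      if (nrow(idx) == 0) next
      centers <- idx - 1  # 0-based voxel centers
      qc <- quad_corners(axis, sgn)
      for (k in 1:4) {
        corner_list[[length(corner_list) + 1L]] <-
          sweep(centers, 2, qc[k, ], "+")
      }
    }
  }
  # corner_list holds per-direction blocks of 4 corner sets; rebuild quads
  # in order: every 4 consecutive entries belong to one direction block
  quads <- list()
  for (b in seq(1, length(corner_list), by = 4)) {
    nfb <- nrow(corner_list[[b]])
    quads[[length(quads) + 1L]] <- array(
      c(corner_list[[b]], corner_list[[b + 1]],
        corner_list[[b + 2]], corner_list[[b + 3]]),
      c(nfb, 3, 4))
  }
  nq <- sum(vapply(quads, function(q) dim(q)[1], integer(1)))
  allc <- matrix(0, nq * 4L, 3L)
  pos <- 0L
  for (q in quads) {
    nfb <- dim(q)[1]
    for (k in 1:4) {
      allc[pos + seq_len(nfb) + (k - 1L) * nfb, ] <- q[, , k]
    }
    # interleave: rows for this block are [corner1 rows, corner2 rows, ...]
    pos <- pos + 4L * nfb
  }
  # encode half-integer coords as integers for dedup
  key <- (allc[, 1] * 2 + 1) + (allc[, 2] * 2 + 1) * 8192 +
    (allc[, 3] * 2 + 1) * 8192^2
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- allc[match(uk, key), , drop = FALSE]
  faces <- matrix(0L, 0L, 3L)
  pos <- 0L
  for (q in quads) {
    nfb <- dim(q)[1]
    i1 <- vid[pos + seq_len(nfb)]
    i2 <- vid[pos + nfb + seq_len(nfb)]
    i3 <- vid[pos + 2L * nfb + seq_len(nfb)]
    i4 <- vid[pos + 3L * nfb + seq_len(nfb)]
    faces <- rbind(faces, cbind(i1, i2, i3), cbind(i1, i3, i4))
    pos <- pos + 4L * nfb
  }
  dimnames(faces) <- NULL
  surface_mesh(verts, faces)
}

# shift of a padded array used only inside extract_surface
shift_rep_pad <- function(pad, axis, by) {
  n <- dim(pad)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis,
         pad[idx, , , drop = FALSE],
         pad[, idx, , drop = FALSE],
         pad[, , idx, drop = FALSE])
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
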