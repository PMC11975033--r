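## Triangle-mesh primitives: incremental 3-D convex hull, closed-mesh
## checks, signed volume, Laplacian smoothing, and ray-parity containment.
##
## Meshes are lists with `vertices` (n x 3, micrometers) and `faces`
## (m x 3 integer vertex indices, counter-clockwise seen from outside).

new_mesh <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x) / 1e9))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; the absolute value
#' is returned so the enclosed volume is orientation-independent (heavy
#' smoothing can invert a mesh through its centroid).
#'
#' @param mesh A `surface_mesh`.
#' @return Volume in cubic micrometers.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6) / 6)
}

#' Check that a mesh is closed and consistently oriented
#'
#' @param mesh A `surface_mesh`.
#' @return `TRUE` iff every undirected edge is shared by exactly two faces
#'   and every directed edge appears exactly once.
#' @export
is_closed_mesh <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) < 4L) return(FALSE)
  dir_edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  dkey <- paste(dir_edges[, 1], dir_edges[, 2])
  if (anyDuplicated(dkey)) return(FALSE)
  ukey <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                pmax(dir_edges[, 1], dir_edges[, 2]))
  all(table(ukey) == 2L)
}

## Incremental convex hull. Every input point on the hull surface becomes a
## vertex; interior points are skipped. Errors on coplanar/degenerate input.
convex_hull_3d <- function(points, tol = NULL) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  if (ncol(P) != 3L) stopf("points must be n x 3")
  n <- nrow(P)
  if (n < 4L) {
    stopf("need at least 4 points for a 3-D hull (got %d)", n,
          class = "atlastrace_degeneracy_error")
  }
  scale <- max(apply(P, 2, function(col) diff(range(col))))
  if (is.null(tol)) tol <- 1e-9 * max(scale, 1)

  ## initial simplex: farthest pair among axis extremes, then farthest from
  ## the line, then farthest from the plane
  ext <- unique(c(apply(P, 2, which.min), apply(P, 2, which.max)))
  best <- c(ext[1], ext[2]); bd <- -1
  for (i in ext) for (j in ext) if (i < j) {
    d <- sum((P[i, ] - P[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  i1 <- best[1]; i2 <- best[2]
  if (sqrt(bd) < tol) {
    stopf("degenerate point cloud (all points coincide)",
          class = "atlastrace_degeneracy_error")
  }
  dir <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  t_ <- as.numeric(rel %*% dir) / sum(dir^2)
  perp <- rel - outer(t_, dir)
  d_line <- sqrt(rowSums(perp^2))
  i3 <- which.max(d_line)
  if (d_line[i3] < tol) {
    stopf("degenerate point cloud (points are collinear)",
          class = "atlastrace_degeneracy_error")
  }
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  d_plane <- abs(as.numeric(rel %*% nrm))
  i4 <- which.max(d_plane)
  if (d_plane[i4] < tol) {
    stopf("degenerate point cloud (points are coplanar)",
          class = "atlastrace_degeneracy_error")
  }

  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))

  face_planes <- function(faces) {
    a <- P[faces[, 1], , drop = FALSE]
    b <- P[faces[, 2], , drop = FALSE]
    c_ <- P[faces[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c_ - a
    N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(N^2))
    N <- N / len
    off <- rowSums(N * a)
    ## orient outward relative to the interior point
    flip <- as.numeric(N %*% interior) - off > 0
    N[flip, ] <- -N[flip, , drop = FALSE]
    off[flip] <- -off[flip]
    list(N = N, off = off)
  }
  pl <- face_planes(faces)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- as.numeric(pl$N %*% P[p, ]) - pl$off > tol
    if (!any(vis)) next
    vis_faces <- faces[vis, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                   vis_faces[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], new_faces)
    new_pl <- face_planes(new_faces)
    pl <- list(N = rbind(pl$N[!vis, , drop = FALSE], new_pl$N),
               off = c(pl$off[!vis], new_pl$off))
  }

  ## compact vertex set and enforce outward counter-clockwise winding
  used <- sort(unique(as.vector(faces)))
  remap <- integer(n); remap[used] <- seq_along(used)
  V <- P[used, , drop = FALSE]
  F <- matrix(remap[faces], ncol = 3)
  ctr <- colMeans(V)
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inward <- rowSums(N * sweep(a, 2, ctr)) < 0
  F[inward, c(2, 3)] <- F[inward, c(3, 2)]
  dimnames(V) <- NULL
  new_mesh(V, F)
}

#' Laplacian smoothing of a closed mesh
#'
#' Each iteration simultaneously moves every vertex by
#' `lambda * (centroid of topological neighbors - vertex)`; the topology is
#' unchanged and `iterations = 0` returns the input mesh.
#'
#' @param mesh A closed `surface_mesh`.
#' @param iterations Non-negative integer number of iterations (default 10).
#' @param lambda Step size in (0, 1] (default 0.5).
#' @return The smoothed `surface_mesh`.
#' @export
laplacian_smooth <- function(mesh, iterations = 10L, lambda = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"),
            is_count(iterations), lambda > 0, lambda <= 1)
  if (iterations == 0L) return(mesh)
  F <- mesh$faces
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  edges <- unique(rbind(edges, edges[, c(2, 1)]))
  neigh <- split(edges[, 2], edges[, 1])
  neigh <- neigh[order(as.integer(names(neigh)))]
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    centroids <- t(vapply(neigh, function(idx) colMeans(V[idx, , drop = FALSE]),
                          numeric(3)))
    V <- V + lambda * (centroids - V)
  }
  new_mesh(V, F)
}

## x-coordinates where the ray line {y = y0, z = z0} crosses the mesh
## surface, used for parity containment tests. Degenerate hits (edge or
## vertex grazing, or rays in the plane of a face) retry the whole line with
## a deterministic jitter.
line_crossings <- function(V, F, y0, z0, tol_rel = 1e-9, depth = 0L) {
  if (depth > 6L) stopf("containment test failed to escape a degenerate ray")
  ay <- V[F[, 1], 2]; az <- V[F[, 1], 3]
  by <- V[F[, 2], 2]; bz <- V[F[, 2], 3]
  cy <- V[F[, 3], 2]; cz <- V[F[, 3], 3]
  ## 2-D edge functions of the projected triangle at (y0, z0)
  w0 <- (cy - by) * (z0 - bz) - (cz - bz) * (y0 - by)
  w1 <- (ay - cy) * (z0 - cz) - (az - cz) * (y0 - cy)
  w2 <- (by - ay) * (z0 - az) - (bz - az) * (y0 - ay)
  area2 <- w0 + w1 + w2
  absw <- abs(w0) + abs(w1) + abs(w2)
  scale2 <- max(absw, 1)
  degenerate_proj <- abs(area2) <= tol_rel * scale2
  inside <- !degenerate_proj &
    ((w0 >= 0 & w1 >= 0 & w2 >= 0) | (w0 <= 0 & w1 <= 0 & w2 <= 0))
  ## grazing an edge or vertex of a non-degenerate triangle
  margin_bad <- inside & (pmin(abs(w0), abs(w1), abs(w2)) <= tol_rel * absw)
  ## ray in (or near) the plane of an edge-on triangle: only degenerate if
  ## the projected point sits on the collapsed triangle
  near_collapsed <- degenerate_proj & (absw <= tol_rel * scale2 * 10)
  if (any(margin_bad) ||
      (any(near_collapsed) && any(edge_on_hit(V, F, y0, z0, near_collapsed)))) {
    span <- max(abs(V)) + 1
    jit <- span * 1e-7 * (depth + 1)
    return(line_crossings(V, F, y0 + jit, z0 + 2.3 * jit, tol_rel, depth + 1L))
  }
  if (!any(inside)) return(numeric(0))
  fi <- which(inside)
  lam0 <- w0[fi] / area2[fi]
  lam1 <- w1[fi] / area2[fi]
  lam2 <- w2[fi] / area2[fi]
  lam0 * V[F[fi, 1], 1] + lam1 * V[F[fi, 2], 1] + lam2 * V[F[fi, 3], 1]
}

## for triangles whose (y,z) projection is collapsed: does (y0,z0) lie near
## one of the projected segments?
edge_on_hit <- function(V, F, y0, z0, which_faces) {
  idx <- which(which_faces)
  hit <- logical(0)
  for (f in idx) {
    vy <- V[F[f, ], 2]; vz <- V[F[f, ], 3]
    dmin <- min(sqrt((y0 - vy)^2 + (z0 - vz)^2))
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      p1 <- c(vy[e[1]], vz[e[1]]); p2 <- c(vy[e[2]], vz[e[2]])
      seg <- p2 - p1
      len2 <- sum(seg^2)
      if (len2 > 0) {
        t_ <- min(max(((y0 - p1[1]) * seg[1] + (z0 - p1[2]) * seg[2]) / len2,
                      0), 1)
        d <- sqrt((y0 - p1[1] - t_ * seg[1])^2 + (z0 - p1[2] - t_ * seg[2])^2)
        dmin <- min(dmin, d)
      }
    }
    span <- max(diff(range(vy)), diff(range(vz)), abs(y0), abs(z0), 1)
    hit <- c(hit, dmin < 1e-7 * span)
  }
  hit
}

#' Test whether points lie inside a closed mesh
#'
#' Ray-parity containment: a point is inside iff an axis ray from it crosses
#' the surface an odd number of times. Points are grouped by their (z, ml)
#' ray line so voxel-grid queries share surface intersections.
#'
#' @param mesh A closed `surface_mesh`.
#' @param points Numeric matrix (n x 3).
#' @return Logical vector.
#' @export
points_in_mesh <- function(mesh, points) {
  if (!is_closed_mesh(mesh)) {
    stopf("mesh is not closed", class = "atlastrace_topology_error")
  }
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) return(logical(0))
  V <- mesh$vertices
  F <- mesh$faces
  key <- paste(pts[, 2], pts[, 3])
  out <- logical(nrow(pts))
  for (k in unique(key)) {
    rows <- which(key == k)
    xs <- line_crossings(V, F, pts[rows[1], 2], pts[rows[1], 3])
    if (length(xs)) {
      counts <- vapply(pts[rows, 1], function(x0) sum(xs > x0), numeric(1))
      out[rows] <- counts %% 2 == 1
    }
  }
  out
}

## deterministic quasi-uniform sampling of an ellipsoid surface
## (Fibonacci sphere lattice mapped through the radii)
ellipsoid_surface_points <- function(center, radii, n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  u <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  sweep(u %*% diag(radii), 2, center, `+`)
}
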