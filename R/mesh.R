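#' Triangulated vessel surface mesh
#'
#' Minimal container for a triangulated surface: a matrix of vertex
#' coordinates in millimetres and a matrix of vertex-index triples. The main
#' vessel is expected to be a closed (watertight) tube; branch stubs may be
#' present as additional connected components.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 4L) {
    stop("`vertices` must be an n x 3 matrix with n >= 4")
  }
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop("`faces` must be an m x 3 matrix of vertex indices")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("`faces` references vertices outside 1..nrow(vertices)")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat(sprintf(
    "surface_mesh: %d vertices, %d faces\n  bounding box (mm): [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f]\n",
    nrow(x$vertices), nrow(x$faces),
    rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]
  ))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; only meaningful for a
#' watertight, consistently oriented mesh.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3 (absolute value).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz)) / 6
}

# Intersect a mesh with the plane through `point` with unit `normal`.
# Returns a list of closed loops, each an ordered k x 3 matrix of points.
# Vertices numerically on the plane are nudged to one side so that every
# crossing triangle contributes exactly one chord; adjacent triangles share
# chord endpoints exactly because each endpoint is computed once per
# canonical mesh edge.
slice_mesh <- function(mesh, point, normal, tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  normal <- normal / sqrt(sum(normal^2))
  d <- (v[, 1] - point[1]) * normal[1] +
    (v[, 2] - point[2]) * normal[2] +
    (v[, 3] - point[3]) * normal[3]
  on_plane <- abs(d) < tol
  if (any(on_plane)) d[on_plane] <- tol
  pos <- d > 0

  ea <- cbind(f[, 1], f[, 2], f[, 3])
  eb <- cbind(f[, 2], f[, 3], f[, 1])
  crossing <- matrix(pos[ea] != pos[eb], nrow(f), 3)
  tri_cross <- rowSums(crossing) == 2L
  if (!any(tri_cross)) return(list())

  ea <- ea[tri_cross, , drop = FALSE]
  eb <- eb[tri_cross, , drop = FALSE]
  crossing <- crossing[tri_cross, , drop = FALSE]

  # flatten (triangle, edge) pairs that cross; 2 per triangle
  hit <- which(t(crossing))                       # column-major over edges
  tri_id <- (hit - 1L) %/% 3L + 1L
  edge_slot <- (hit - 1L) %% 3L + 1L
  a_idx <- ea[cbind(tri_id, edge_slot)]
  b_idx <- eb[cbind(tri_id, edge_slot)]
  lo <- pmin(a_idx, b_idx)
  hi <- pmax(a_idx, b_idx)
  key <- paste(lo, hi)
  ukey <- unique(key)
  kid <- match(key, ukey)

  first <- !duplicated(kid)
  lo1 <- lo[first][order(kid[first])]
  hi1 <- hi[first][order(kid[first])]
  t_par <- d[lo1] / (d[lo1] - d[hi1])
  pts <- v[lo1, , drop = FALSE] +
    t_par * (v[hi1, , drop = FALSE] - v[lo1, , drop = FALSE])

  # segments: per crossing triangle, the pair of edge ids
  seg <- matrix(kid, ncol = 2, byrow = TRUE)

  # incidence of edge ids in segments; closed manifold => degree 2 everywhere
  n_edge <- length(ukey)
  inc <- vector("list", n_edge)
  for (s in seq_len(nrow(seg))) {
    inc[[seg[s, 1]]] <- c(inc[[seg[s, 1]]], s)
    inc[[seg[s, 2]]] <- c(inc[[seg[s, 2]]], s)
  }

  used <- logical(nrow(seg))
  loops <- list()
  for (s0 in seq_len(nrow(seg))) {
    if (used[s0]) next
    path <- integer(0)
    cur_seg <- s0
    cur_edge <- seg[s0, 1]
    start_edge <- cur_edge
    open <- FALSE
    repeat {
      used[cur_seg] <- TRUE
      path <- c(path, cur_edge)
      nxt_edge <- if (seg[cur_seg, 1] == cur_edge) seg[cur_seg, 2] else seg[cur_seg, 1]
      if (nxt_edge == start_edge) break
      cand <- inc[[nxt_edge]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) { # boundary: open polyline
        path <- c(path, nxt_edge)
        open <- TRUE
        break
      }
      cur_edge <- nxt_edge
      cur_seg <- cand[1L]
    }
    loop_pts <- pts[path, , drop = FALSE]
    attr(loop_pts, "open") <- open
    loops[[length(loops) + 1L]] <- loop_pts
  }
  loops
}

# Distance along unit ray (origin, dir) to the first mesh intersection
# (Moller-Trumbore over all faces); Inf if the ray misses.
ray_mesh_distance <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  pv <- cbind(
    dir[2] * e2[, 3] - dir[3] * e2[, 2],
    dir[3] * e2[, 1] - dir[1] * e2[, 3],
    dir[1] * e2[, 2] - dir[2] * e2[, 1]
  )
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- matrix(origin, nrow(a), 3, byrow = TRUE) - a
  u <- rowSums(tv * pv) / det
  qv <- cbind(
    tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
    tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
    tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1]
  )
  w <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  t_hit <- rowSums(e2 * qv) / det
  hit <- ok & u >= 0 & w >= 0 & (u + w) <= 1 & t_hit > 1e-9
  if (!any(hit)) return(Inf)
  min(t_hit[hit])
}

# Orthonormal in-plane basis for a unit normal.
plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(
    normal[2] * u[3] - normal[3] * u[2],
    normal[3] * u[1] - normal[1] * u[3],
    normal[1] * u[2] - normal[2] * u[1]
  )
  list(u = u, v = v)
}

# Area, centroid (3D) and 2D coordinates of a closed planar loop.
section_properties <- function(loop, point, normal) {
  b <- plane_basis(normal)
  rel <- sweep(loop, 2, point)
  x <- rel %*% b$u
  y <- rel %*% b$v
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  area <- sum(cr) / 2
  if (abs(area) < 1e-12) {
    cx <- mean(x); cy <- mean(y)
  } else {
    cx <- sum((x + x[j]) * cr) / (6 * area)
    cy <- sum((y + y[j]) * cr) / (6 * area)
  }
  centroid <- point + cx * b$u + cy * b$v
  list(area = abs(area), centroid = centroid, x = x, y = y)
}

# Is the 2D origin (the plane point) inside the loop? Ray-crossing test in
# the plane coordinates returned by section_properties().
loop_contains_origin <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  crosses <- ((y > 0) != (y[j] > 0)) &
    (0 < x + (0 - y) * (x[j] - x) / (y[j] - y))
  sum(crosses) %% 2L == 1L
}

# The closed section through `point` (normal `normal`) that contains `point`;
# NULL if none. Falls back to the loop whose centroid is nearest when the
# containment test fails for every closed loop (grazing sections).
section_at <- function(mesh, point, normal, require_containing = TRUE) {
  loops <- slice_mesh(mesh, point, normal)
  loops <- Filter(function(l) !isTRUE(attr(l, "open")) && nrow(l) >= 3, loops)
  if (length(loops) == 0L) return(NULL)
  props <- lapply(loops, section_properties, point = point, normal = normal)
  inside <- vapply(props, function(p) loop_contains_origin(p$x, p$y), logical(1))
  if (any(inside)) {
    areas <- vapply(props, `[[`, numeric(1), "area")
    areas[!inside] <- -Inf
    return(props[[which.max(areas)]])
  }
  if (require_containing) return(NULL)
  d2 <- vapply(props, function(p) sum((p$centroid - point)^2), numeric(1))
  props[[which.min(d2)]]
}
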