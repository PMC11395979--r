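#' Parametric synthetic thoracic aorta
#'
#' A stylised candy-cane aorta: straight ascending limb, circular arch and
#' straight descending limb in the x-z plane, a smoothly varying radius
#' profile with an optional Gaussian-shaped narrowing (the coarctation), and
#' three arch branches (BCA, LCCA, LSCA) ordered by arc length. All lengths
#' in millimetres.
#'
#' The radius at arc length `s` is
#' `r(s) = r_base(s) * (1 - depth * exp(-(s - location)^2 / (2 width^2)))`
#' where `r_base` interpolates the control radii, so a narrowing of depth 0.5
#' halves the local diameter.
#'
#' @param patient_id identifier string.
#' @param label `"normal"` or `"coa"`.
#' @param asc_length,arch_radius,desc_length geometry of the ascending limb,
#'   arch (semi-circle) and descending limb, mm.
#' @param radius_ctrl data frame with columns `s_frac` (fraction of total arc
#'   length, increasing) and `r` (mm > 0): control points of the baseline
#'   radius profile.
#' @param narrowing list with `depth` in `[0, 1)`, `width` (Gaussian sigma,
#'   mm) and `location` (arc length mm; `NULL` places it just distal to the
#'   arch, the usual coarctation site).
#' @param branches data frame with columns `name`, `s_origin` (arc length mm
#'   on the arch), `radius` (mm) and `length` (mm); must contain exactly
#'   BCA, LCCA, LSCA in order of `s_origin`.
#' @return object of class `"synthetic_aorta"`.
#' @export
synthetic_aorta <- function(patient_id = "synthetic-1",
                            label = c("normal", "coa"),
                            asc_length = 25,
                            arch_radius = 15,
                            desc_length = 50,
                            radius_ctrl = NULL,
                            narrowing = list(depth = 0, width = 5, location = NULL),
                            branches = NULL) {
  label <- match.arg(label)
  total <- asc_length + pi * arch_radius + desc_length
  if (is.null(radius_ctrl)) {
    radius_ctrl <- data.frame(
      s_frac = c(0, 0.2, 0.4, 0.6, 0.8, 1),
      r = c(5.2, 4.8, 4.3, 4.1, 4.3, 3.6)
    )
  }
  stopifnot(
    all(radius_ctrl$r > 0),
    !is.unsorted(radius_ctrl$s_frac, strictly = TRUE)
  )
  if (is.null(narrowing$location)) {
    narrowing$location <- asc_length + pi * arch_radius + 0.15 * desc_length
  }
  if (is.null(narrowing$width)) narrowing$width <- 5
  stopifnot(narrowing$depth >= 0, narrowing$depth < 1, narrowing$width > 0)
  if (is.null(branches)) {
    arch0 <- asc_length
    branches <- data.frame(
      name = c("BCA", "LCCA", "LSCA"),
      s_origin = arch0 + pi * arch_radius * c(0.30, 0.50, 0.68),
      radius = c(2.4, 1.7, 1.8),
      length = c(10, 9, 9)
    )
  }
  if (!identical(sort(branches$name), c("BCA", "LCCA", "LSCA"))) {
    stop("branches must be exactly BCA, LCCA and LSCA")
  }
  branches <- branches[order(branches$s_origin), ]
  a <- structure(list(
    patient_id = patient_id,
    label = label,
    asc_length = asc_length,
    arch_radius = arch_radius,
    desc_length = desc_length,
    total_length = total,
    radius_ctrl = radius_ctrl,
    narrowing = narrowing,
    branches = branches
  ), class = "synthetic_aorta")
  # radius must stay positive everywhere
  s_chk <- seq(0, total, length.out = 400)
  if (any(aorta_radius(a, s_chk) <= 0)) stop("radius profile not positive everywhere")
  a
}

#' @export
print.synthetic_aorta <- function(x, ...) {
  cat(sprintf(
    "synthetic_aorta %s (%s): length %.1f mm, narrowing depth %.2f at s = %.1f mm\n",
    x$patient_id, x$label, x$total_length, x$narrowing$depth, x$narrowing$location
  ))
  invisible(x)
}

# Analytic centerline point(s) at arc length s (vectorised). The curve lies
# in the y = 0 plane: up the ascending limb, over a semi-circular arch, down
# the descending limb.
aorta_centerline_point <- function(a, s) {
  s <- pmin(pmax(s, 0), a$total_length)
  arch_len <- pi * a$arch_radius
  out <- matrix(0, length(s), 3)
  seg1 <- s <= a$asc_length
  seg2 <- !seg1 & s <= a$asc_length + arch_len
  seg3 <- !(seg1 | seg2)
  if (any(seg1)) out[seg1, ] <- cbind(0, 0, s[seg1])
  if (any(seg2)) {
    th <- (s[seg2] - a$asc_length) / a$arch_radius   # 0..pi
    out[seg2, ] <- cbind(
      a$arch_radius * (1 - cos(th)), 0, a$asc_length + a$arch_radius * sin(th)
    )
  }
  if (any(seg3)) {
    sd3 <- s[seg3] - a$asc_length - arch_len
    out[seg3, ] <- cbind(2 * a$arch_radius, 0, a$asc_length - sd3)
  }
  out
}

aorta_centerline_tangent <- function(a, s) {
  s <- pmin(pmax(s, 0), a$total_length)
  arch_len <- pi * a$arch_radius
  out <- matrix(0, length(s), 3)
  seg1 <- s <= a$asc_length
  seg2 <- !seg1 & s <= a$asc_length + arch_len
  seg3 <- !(seg1 | seg2)
  if (any(seg1)) out[seg1, ] <- matrix(c(0, 0, 1), sum(seg1), 3, byrow = TRUE)
  if (any(seg2)) {
    th <- (s[seg2] - a$asc_length) / a$arch_radius
    out[seg2, ] <- cbind(sin(th), 0, cos(th))
  }
  if (any(seg3)) out[seg3, ] <- matrix(c(0, 0, -1), sum(seg3), 3, byrow = TRUE)
  out
}

#' Analytic radius of a synthetic aorta at arc length s
#'
#' @param a a [synthetic_aorta()].
#' @param s arc length(s) in mm from the inlet.
#' @return radius in mm (vectorised over `s`).
#' @export
aorta_radius <- function(a, s) {
  base <- stats::spline(
    a$radius_ctrl$s_frac * a$total_length, a$radius_ctrl$r,
    xout = pmin(pmax(s, 0), a$total_length), method = "natural"
  )$y
  nr <- a$narrowing
  base * (1 - nr$depth * exp(-(s - nr$location)^2 / (2 * nr$width^2)))
}

# Outward branch axis at arc length s: the unit vector closest to +z that is
# perpendicular to the local centerline tangent (branches leave the arch
# superiorly).
aorta_branch_direction <- function(a, s) {
  t <- drop(aorta_centerline_tangent(a, s))
  up <- c(0, 0, 1)
  d <- up - sum(up * t) * t
  n <- sqrt(sum(d^2))
  if (n < 1e-8) {
    d <- c(1, 0, 0) - t[1] * t
    n <- sqrt(sum(d^2))
  }
  d / n
}

#' Ground-truth landmark diameters of a synthetic aorta
#'
#' Evaluates the analytic radius profile at the landmark stations implied by
#' the geometry: D1 one centimetre above the sinotubular junction (taken as
#' the inlet), D2 at the ascending-to-arch transition, D3 at the distal arch,
#' D0 as the global minimum diameter over the descending segment, D4 as the
#' maximum (greatest dilation) of the descending segment distal to the
#' narrowing, D5 near the aortic hiatus (distal end), and the three branch
#' diameters from the branch specs.
#'
#' @param a a [synthetic_aorta()].
#' @return named numeric vector with the nine diameters (mm).
#' @export
aorta_true_profile <- function(a) {
  arch_len <- pi * a$arch_radius
  arch0 <- a$asc_length
  arch1 <- a$asc_length + arch_len
  desc <- seq(arch1, a$total_length, by = 0.01)
  r_desc <- aorta_radius(a, desc)
  c(
    D1 = 2 * aorta_radius(a, 10),
    D2 = 2 * aorta_radius(a, arch0),
    D3 = 2 * aorta_radius(a, arch1 - 2),
    D0 = 2 * min(r_desc),
    D4 = 2 * max(r_desc),
    D5 = 2 * aorta_radius(a, a$total_length - 0.03 * a$total_length),
    DBCA = 2 * a$branches$radius[a$branches$name == "BCA"],
    DLCCA = 2 * a$branches$radius[a$branches$name == "LCCA"],
    DLSCA = 2 * a$branches$radius[a$branches$name == "LSCA"]
  )
}

#' Triangulated surface mesh of a synthetic aorta
#'
#' Sweeps the analytic radius profile along the centerline using
#' parallel-transported frames (no twist), producing a watertight main tube
#' (optionally capped) plus capped branch-stub tubes for the three arch
#' branches. Branch stubs are separate connected components anchored at the
#' arch centerline; they intersect the main tube wall, which is irrelevant
#' for cross-section measurement.
#'
#' @param a a [synthetic_aorta()].
#' @param n_circ circumferential samples per ring (>= 16).
#' @param n_axial axial stations along the main vessel (>= 50).
#' @param caps close the inlet/outlet with triangle fans (watertight tube).
#' @param branches include branch stubs.
#' @return a [surface_mesh()].
#' @export
make_tube_mesh <- function(a, n_circ = 48, n_axial = 200,
                           caps = TRUE, branches = TRUE) {
  stopifnot(n_circ >= 16, n_axial >= 50)
  s <- seq(0, a$total_length, length.out = n_axial)
  centers <- aorta_centerline_point(a, s)
  tangents <- aorta_centerline_tangent(a, s)
  radii <- aorta_radius(a, s)

  # self-intersection guard: well-separated stations must not touch
  sep <- 6 * max(radii)
  for (i in seq_len(n_axial)) {
    far <- which(abs(s - s[i]) > sep)
    if (length(far)) {
      d <- sqrt(rowSums((centers[far, , drop = FALSE] -
        matrix(centers[i, ], length(far), 3, byrow = TRUE))^2))
      if (any(d < radii[i] + radii[far])) {
        stop("self-intersecting centerline: stations ",
             round(s[i], 1), " mm and ", round(s[far[which.min(d)]], 1),
             " mm overlap")
      }
    }
  }

  tube <- sweep_tube(centers, tangents, radii, n_circ, caps = caps)
  verts <- tube$vertices
  faces <- tube$faces

  if (branches) {
    for (b in seq_len(nrow(a$branches))) {
      sp <- a$branches[b, ]
      p0 <- drop(aorta_centerline_point(a, sp$s_origin))
      dir <- aorta_branch_direction(a, sp$s_origin)
      nb <- 10L
      bc <- matrix(p0, nb, 3, byrow = TRUE) +
        outer(seq(0, sp$length, length.out = nb), dir)
      bt <- matrix(dir, nb, 3, byrow = TRUE)
      stub <- sweep_tube(bc, bt, rep(sp$radius, nb), max(24L, n_circ %/% 2L),
                         caps = TRUE)
      faces <- rbind(faces, stub$faces + nrow(verts))
      verts <- rbind(verts, stub$vertices)
    }
  }
  surface_mesh(verts, faces)
}

#' Generic swept-tube mesh
#'
#' Watertight triangulated tube sweeping a per-station radius along an
#' arbitrary polyline centerline (tangents from centered differences,
#' frames parallel transported). Useful for building analytic fixtures:
#' cylinders, tori, stenosed straight tubes.
#'
#' @param centers n x 3 matrix of centerline points (mm), n >= 2.
#' @param radii numeric vector of station radii (mm), length n or 1.
#' @param n_circ circumferential resolution (default 48).
#' @param caps close both ends with triangle fans (default TRUE).
#' @return a [surface_mesh()].
#' @export
tube_mesh <- function(centers, radii, n_circ = 48, caps = TRUE) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, nrow(centers) >= 2, all(radii > 0))
  n <- nrow(centers)
  radii <- rep_len(radii, n)
  tang <- matrix(0, n, 3)
  tang[1, ] <- centers[2, ] - centers[1, ]
  tang[n, ] <- centers[n, ] - centers[n - 1, ]
  if (n > 2) {
    tang[2:(n - 1), ] <- centers[3:n, , drop = FALSE] -
      centers[1:(n - 2), , drop = FALSE]
  }
  tube <- sweep_tube(centers, tang, radii, n_circ, caps = caps)
  surface_mesh(tube$vertices, tube$faces)
}

# Generic swept tube: rings of n_circ vertices around each center, quads
# split into triangles, optional fan caps. Frames are parallel transported.
sweep_tube <- function(centers, tangents, radii, n_circ, caps = TRUE) {
  n <- nrow(centers)
  u <- matrix(0, n, 3)
  v <- matrix(0, n, 3)
  t1 <- tangents[1, ] / sqrt(sum(tangents[1, ]^2))
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u[1, ] <- ref - sum(ref * t1) * t1
  u[1, ] <- u[1, ] / sqrt(sum(u[1, ]^2))
  for (i in seq_len(n)) {
    ti <- tangents[i, ] / sqrt(sum(tangents[i, ]^2))
    if (i > 1) {
      w <- u[i - 1, ] - sum(u[i - 1, ] * ti) * ti
      u[i, ] <- w / sqrt(sum(w^2))
    }
    v[i, ] <- c(
      ti[2] * u[i, 3] - ti[3] * u[i, 2],
      ti[3] * u[i, 1] - ti[1] * u[i, 3],
      ti[1] * u[i, 2] - ti[2] * u[i, 1]
    )
  }
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  ct <- cos(theta); st <- sin(theta)
  verts <- matrix(0, n * n_circ, 3)
  for (i in seq_len(n)) {
    ring <- matrix(centers[i, ], n_circ, 3, byrow = TRUE) +
      radii[i] * (outer(ct, u[i, ]) + outer(st, v[i, ]))
    verts[((i - 1L) * n_circ + 1L):(i * n_circ), ] <- ring
  }
  idx <- function(i, k) (i - 1L) * n_circ + ((k - 1L) %% n_circ) + 1L
  f <- vector("list", n - 1L)
  ks <- seq_len(n_circ)
  for (i in seq_len(n - 1L)) {
    a1 <- idx(i, ks); a2 <- idx(i, ks + 1L)
    b1 <- idx(i + 1L, ks); b2 <- idx(i + 1L, ks + 1L)
    f[[i]] <- rbind(cbind(a1, a2, b1), cbind(a2, b2, b1))
  }
  faces <- do.call(rbind, f)
  if (caps) {
    c0 <- nrow(verts) + 1L
    c1 <- nrow(verts) + 2L
    verts <- rbind(verts, centers[1, ], centers[n, ])
    faces <- rbind(
      faces,
      cbind(idx(1L, ks + 1L), idx(1L, ks), c0),
      cbind(idx(n, ks), idx(n, ks + 1L), c1)
    )
  }
  list(vertices = verts, faces = faces)
}

#' Sample a field on a regular grid inside a spherical landmark domain
#'
#' Landmark hemodynamic characteristics are averages over small spherical
#' domains (1 mm diameter) centred at the landmark. This samples a scalar
#' field on a cubic grid restricted to points strictly inside the sphere.
#' The default grid spacing of 0.084 mm was chosen once so the in-sphere
#' count falls in the 850-900 range used for landmark averaging; the grid is
#' centred on the sphere centre, so it is symmetric and the mean of a linear
#' field equals its value at the centre.
#'
#' @param center 3-vector, sphere centre (mm).
#' @param field either a single number (constant field) or a function taking
#'   an n x 3 matrix of points and returning n field values.
#' @param diameter sphere diameter in mm (default 1).
#' @param spacing grid spacing in mm (default 0.084).
#' @return data frame with columns `x`, `y`, `z`, `value`.
#' @export
sample_sphere_points <- function(center, field, diameter = 1, spacing = 0.084) {
  stopifnot(length(center) == 3, is.finite(center), diameter > 0, spacing > 0)
  r <- diameter / 2
  m <- floor(r / spacing)
  g <- seq(-m, m)
  grid <- as.matrix(expand.grid(i = g, j = g, k = g))
  keep <- rowSums(grid^2) * spacing^2 < r^2
  pts <- grid[keep, , drop = FALSE] * spacing
  pts <- sweep(pts, 2, center, `+`)
  vals <- if (is.function(field)) field(pts) else rep(as.numeric(field), nrow(pts))
  stopifnot(length(vals) == nrow(pts))
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], value = vals)
}
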