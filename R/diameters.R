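#' Equivalent-circle diameter of a vessel cross-section
#'
#' Intersects the mesh with the plane through the centerline point at arc
#' length `s`, normal to the local tangent, keeps the connected intersection
#' polygon containing the centerline point, and returns the
#' equivalent-circle diameter `2 * sqrt(area / pi)`. The area-based
#' definition is robust to mildly elliptic sections.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()] of the main vessel.
#' @param s arc length in mm (scalar, within the centerline range).
#' @return diameter in mm.
#' @export
cross_section_diameter <- function(mesh, cl, s) {
  stopifnot(length(s) == 1L, is.finite(s))
  if (s < min(cl$arc_length) || s > max(cl$arc_length)) {
    stop("arc length ", s, " mm outside the centerline range")
  }
  at <- centerline_at(cl, s)
  sec <- section_at(mesh, at$point, at$tangent)
  if (is.null(sec)) {
    stop("no closed cross-section containing the centerline point at ",
         round(s, 2), " mm")
  }
  2 * sqrt(sec$area / pi)
}

#' Locate the narrowest cross-section over an arc-length range
#'
#' Dense initial scan (step at most 0.5 mm) followed by golden-section
#' refinement around the best scan point. Returns the global minimum
#' diameter over the range — on a coarctation this is the coarctation
#' diameter D0 and its location.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centerline()].
#' @param s_range length-2 numeric, arc-length interval (mm) to search
#'   (inside the descending segment for D0).
#' @param scan_step initial scan step, mm (default 0.5).
#' @param tol golden-section interval tolerance, mm (default 0.02).
#' @return list with `s` (arc length of the minimum, mm) and `diameter` (mm).
#' @export
find_min_diameter <- function(mesh, cl, s_range, scan_step = 0.5, tol = 0.02) {
  optimize_diameter(mesh, cl, s_range, scan_step, tol, maximize = FALSE)
}

# Shared scan + golden-section machinery; maximize = TRUE finds the greatest
# dilation (D4) instead of the narrowest section.
optimize_diameter <- function(mesh, cl, s_range, scan_step = 0.5, tol = 0.02,
                              maximize = FALSE) {
  stopifnot(length(s_range) == 2L, is.finite(s_range))
  s_range <- sort(s_range)
  if (diff(s_range) <= 0) stop("empty arc-length range")
  f <- function(s) {
    d <- cross_section_diameter(mesh, cl, s)
    if (maximize) -d else d
  }
  grid <- seq(s_range[1], s_range[2],
              length.out = max(3L, ceiling(diff(s_range) / scan_step) + 1L))
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    }
  }
  s_best <- (lo + hi) / 2
  d_best <- cross_section_diameter(mesh, cl, s_best)
  # never worse than the scan grid itself
  if ((!maximize && min(vals) < d_best) || (maximize && -min(vals) > d_best)) {
    s_best <- grid[i]
    d_best <- if (maximize) -vals[i] else vals[i]
  }
  list(s = s_best, diameter = d_best)
}

#' Landmark configuration for automatic morphometry
#'
#' Anchors for the nine landmark diameters, expressed as arc lengths or
#' arc-length fractions of the extracted centerline. Anatomical definitions
#' (e.g. "1 cm above the sinotubular junction") are operationalised as
#' configurable anchors because meshes carry no anatomical labels.
#'
#' @param s_stj arc length of the sinotubular junction (mm; default 0, the
#'   inlet). D1 is measured `d1_offset` mm distal to it.
#' @param d1_offset offset of D1 from the sinotubular junction, mm
#'   (default 10 = 1 cm).
#' @param frac_D2,frac_D3 arc-length fractions for the ascending-to-arch
#'   transition (D2) and distal arch (D3).
#' @param desc_range length-2 arc-length fractions bounding the descending
#'   segment searched for the narrowest (D0) and most dilated (D4) sections.
#' @param frac_D5 arc-length fraction of the aortic hiatus level (D5).
#' @param branches named list (`BCA`, `LCCA`, `LSCA`), each with `origin`
#'   (3-vector, mm) and `direction` (unit 3-vector) of the branch axis;
#'   branch diameters are measured `branch_offset` mm distal to the origin.
#' @param branch_offset distance from the branch origin saddle to the
#'   measurement plane, mm (default 2).
#' @return list of class `"landmark_config"`.
#' @export
landmark_config <- function(s_stj = 0, d1_offset = 10,
                            frac_D2 = NULL, frac_D3 = NULL,
                            desc_range = NULL, frac_D5 = 0.97,
                            branches = NULL, branch_offset = 2) {
  structure(list(
    s_stj = s_stj, d1_offset = d1_offset,
    frac_D2 = frac_D2, frac_D3 = frac_D3,
    desc_range = desc_range, frac_D5 = frac_D5,
    branches = branches, branch_offset = branch_offset
  ), class = "landmark_config")
}

#' Landmark configuration implied by a synthetic aorta's geometry
#'
#' @param a a [synthetic_aorta()].
#' @return a [landmark_config()] whose anchors match the stations used by
#'   [aorta_true_profile()], with branch origins and axes taken from the
#'   branch specs.
#' @export
aorta_landmark_config <- function(a) {
  arch_len <- pi * a$arch_radius
  arch1 <- a$asc_length + arch_len
  br <- lapply(seq_len(nrow(a$branches)), function(i) {
    sp <- a$branches[i, ]
    dir <- aorta_branch_direction(a, sp$s_origin)
    p0 <- drop(aorta_centerline_point(a, sp$s_origin))
    # origin saddle: where the branch axis meets the main-vessel wall
    list(origin = p0 + aorta_radius(a, sp$s_origin) * dir, direction = dir)
  })
  names(br) <- a$branches$name
  landmark_config(
    s_stj = 0, d1_offset = 10,
    frac_D2 = a$asc_length / a$total_length,
    frac_D3 = (arch1 - 2) / a$total_length,
    desc_range = c(arch1 / a$total_length, 1),
    frac_D5 = 0.97,
    branches = br
  )
}

#' Measure the nine landmark diameters of an aorta mesh
#'
#' Produces one morphometric profile: D1, D2, D3 and D5 at configured
#' stations, D0 as the narrowest and D4 as the most dilated descending
#' cross-section (both located by scan + golden-section search), and the
#' three branch diameters measured on the branch stubs a fixed distance
#' distal to their origin.
#'
#' @param mesh a [surface_mesh()] including branch stubs.
#' @param cl a [centerline()] of the main vessel.
#' @param cfg a [landmark_config()].
#' @return named numeric vector (mm) with elements
#'   `D1, D2, D3, D0, D4, D5, DBCA, DLCCA, DLSCA`.
#' @export
measure_landmarks <- function(mesh, cl, cfg) {
  stopifnot(inherits(cfg, "landmark_config"))
  L <- max(cl$arc_length)
  need <- c("frac_D2", "frac_D3", "desc_range")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss)) stop("landmark_config lacks: ", paste(miss, collapse = ", "))

  d1 <- cross_section_diameter(mesh, cl, cfg$s_stj + cfg$d1_offset)
  d2 <- cross_section_diameter(mesh, cl, cfg$frac_D2 * L)
  d3 <- cross_section_diameter(mesh, cl, cfg$frac_D3 * L)
  d5 <- cross_section_diameter(mesh, cl, cfg$frac_D5 * L)
  rng <- cfg$desc_range * L
  rng[2] <- min(rng[2], L - 1)           # stay off the distal cap
  d0 <- find_min_diameter(mesh, cl, rng)
  d4 <- optimize_diameter(mesh, cl, rng, maximize = TRUE)

  branch_names <- c("BCA", "LCCA", "LSCA")
  db <- vapply(branch_names, function(nm) {
    b <- cfg$branches[[nm]]
    if (is.null(b)) stop("missing branch in landmark_config: ", nm)
    p <- b$origin + cfg$branch_offset * b$direction
    sec <- section_at(mesh, p, b$direction)
    if (is.null(sec)) stop("missing branch on mesh: ", nm,
                           " (no closed section at its measurement plane)")
    2 * sqrt(sec$area / pi)
  }, numeric(1))

  c(D1 = d1, D2 = d2, D3 = d3, D0 = d0$diameter, D4 = d4$diameter, D5 = d5,
    DBCA = db[["BCA"]], DLCCA = db[["LCCA"]], DLSCA = db[["LSCA"]])
}

#' Agreement between automatic and manual morphometry
#'
#' Pearson correlation per diameter between paired automatic and manual
#' measurements, the standard cross-check when an automatic algorithm
#' replaces manual caliper placement. Diameters whose correlation cannot be
#' computed (constant column) are reported as `NA` with a warning.
#'
#' @param auto,manual data frames (or matrices) of paired measurements with
#'   identical diameter columns, one row per subject.
#' @return data frame with columns `diameter`, `r` and `n`, ordered as the
#'   input columns, with attributes `best` and `worst` naming the most and
#'   least concordant diameters.
#' @export
agreement_report <- function(auto, manual) {
  auto <- as.data.frame(auto)
  manual <- as.data.frame(manual)
  common <- intersect(names(auto), names(manual))
  common <- common[vapply(common, function(k) is.numeric(auto[[k]]), logical(1))]
  if (length(common) == 0L) stop("no shared numeric diameter columns")
  if (nrow(auto) != nrow(manual)) stop("unpaired records")
  if (nrow(auto) < 3L) stop("need at least 3 paired records")
  r <- vapply(common, function(k) {
    if (stats::sd(auto[[k]]) == 0 || stats::sd(manual[[k]]) == 0) {
      warning("correlation undefined for constant column: ", k)
      return(NA_real_)
    }
    stats::cor(auto[[k]], manual[[k]])
  }, numeric(1))
  out <- data.frame(diameter = common, r = unname(r), n = nrow(auto),
                    row.names = NULL)
  ok <- !is.na(out$r)
  attr(out, "best") <- if (any(ok)) out$diameter[ok][which.max(out$r[ok])] else NA
  attr(out, "worst") <- if (any(ok)) out$diameter[ok][which.min(out$r[ok])] else NA
  out
}
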