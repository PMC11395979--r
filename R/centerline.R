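#' Vessel centerline
#'
#' Ordered centerline points with cumulative arc length and unit tangents.
#'
#' @param points n x 3 matrix of ordered centerline points (mm).
#' @return object of class `"centerline"` with `points`, `arc_length`
#'   (strictly increasing, starting at 0) and `tangents` (unit rows).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d <= 0)) stop("centerline points must be distinct and ordered")
  s <- c(0, cumsum(d))
  n <- nrow(points)
  tang <- rbind(
    points[2, ] - points[1, ],
    points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE],
    points[n, ] - points[n - 1, ]
  )
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, arc_length = s, tangents = tang),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, arc length %.1f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

# Linear interpolation of point and tangent at arc length s.
centerline_at <- function(cl, s) {
  smax <- max(cl$arc_length)
  s <- pmin(pmax(s, 0), smax)
  i <- findInterval(s, cl$arc_length, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(cl$points) - 1L)
  w <- (s - cl$arc_length[i]) / (cl$arc_length[i + 1L] - cl$arc_length[i])
  p <- cl$points[i, , drop = FALSE] * (1 - w) +
    cl$points[i + 1L, , drop = FALSE] * w
  t <- cl$tangents[i, , drop = FALSE] * (1 - w) +
    cl$tangents[i + 1L, , drop = FALSE] * w
  t <- t / sqrt(rowSums(t^2))
  list(point = drop(p), tangent = drop(t))
}

#' Extract the centerline of a tubular surface mesh
#'
#' Marching cross-section centroids: starting from a plane fitted to the
#' mesh points nearest the inlet hint, the current cutting plane is iterated
#' to a fixed point (slice, move the plane to the section centroid, repeat),
#' the centroid is recorded, and the plane advances by a fixed step along
#' the running direction. Marching stops when no closed cross-section
#' containing the marching point exists any more (past the distal end).
#'
#' @param mesh a [surface_mesh()] whose main component is a closed tube.
#' @param inlet_hint 3-vector on or near the inlet ring/cap (mm).
#' @param step marching step in mm (default 1).
#' @param tol fixed-point tolerance on the centroid, mm (default 1e-4).
#' @param max_steps safety cap on the number of stations.
#' @return a [centerline()] spanning inlet to distal outlet.
#' @export
extract_centerline <- function(mesh, inlet_hint, step = 1, tol = 1e-4,
                               max_steps = 2000L) {
  stopifnot(length(inlet_hint) == 3, is.finite(inlet_hint))
  v <- mesh$vertices
  d2 <- (v[, 1] - inlet_hint[1])^2 + (v[, 2] - inlet_hint[2])^2 +
    (v[, 3] - inlet_hint[3])^2
  near <- v[order(d2)[seq_len(min(40L, nrow(v)))], , drop = FALSE]
  ctr <- colMeans(near)
  cv <- stats::cov(near)
  eg <- eigen(cv, symmetric = TRUE)
  normal <- eg$vectors[, 3]                  # smallest-variance direction
  # orient into the mesh body
  body <- colMeans(v)
  if (sum((body - ctr) * normal) < 0) normal <- -normal

  settle <- function(p, dir) {
    # fixed-point iteration of the section centroid at fixed normal
    sec <- NULL
    for (it in 1:25) {
      sec_new <- section_at(mesh, p, dir)
      if (is.null(sec_new)) return(sec)   # last good section (or NULL)
      shift <- sqrt(sum((sec_new$centroid - p)^2))
      p <- sec_new$centroid
      sec <- sec_new
      if (shift < tol) break
    }
    sec
  }

  # first station: just inside the inlet ring plane (a plane exactly on the
  # cap has no crossing chords), so the centerline spans nearly the whole
  # vessel
  sec0 <- settle(ctr + (step / 50) * normal, normal)
  if (is.null(sec0)) {
    stop("no closed cross-section at the inlet (arc length 0 mm); ",
         "check the inlet hint")
  }
  pts <- list(sec0$centroid)
  dir <- normal
  k <- 1L
  cur_step <- step
  while (k < max_steps) {
    q <- pts[[k]]
    sec <- settle(q + cur_step * dir, dir)
    ok <- FALSE
    if (!is.null(sec)) {
      move <- sec$centroid - q
      nn <- sqrt(sum(move^2))
      # accept only clear forward progress; a sharp turn or a long jump
      # means the cutting plane has run into the distal corner
      ok <- nn > tol && nn < 3 * step && sum(move * dir) > 0.5 * nn
    }
    if (!ok) {
      if (cur_step > step / 64) {       # approach the end with finer steps
        cur_step <- cur_step / 2
        next
      }
      break
    }
    k <- k + 1L
    pts[[k]] <- sec$centroid
    dir <- move / nn
  }
  if (length(pts) < 2L) stop("centerline extraction failed: fewer than 2 stations")
  p <- do.call(rbind, pts)
  # extend both ends to the vessel surface (end caps) along the end
  # tangents, so the arc length spans the whole vessel
  d_in <- p[1, ] - p[2, ]
  d_in <- d_in / sqrt(sum(d_in^2))
  t_in <- ray_mesh_distance(mesh, p[1, ], d_in)
  if (is.finite(t_in) && t_in > 1e-6 && t_in < 3 * step) {
    p <- rbind(p[1, ] + t_in * d_in, p)
  }
  n <- nrow(p)
  d_out <- p[n, ] - p[n - 1, ]
  d_out <- d_out / sqrt(sum(d_out^2))
  t_out <- ray_mesh_distance(mesh, p[n, ], d_out)
  if (is.finite(t_out) && t_out > 1e-6 && t_out < 3 * step) {
    p <- rbind(p, p[n, ] + t_out * d_out)
  }
  centerline(p)
}
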