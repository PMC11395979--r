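#' Read a surface mesh from an STL file
#'
#' Auto-detects the ASCII and binary STL dialects. Duplicate vertices
#' (STL stores each facet's corners independently) are merged exactly, so
#' shared edges are recovered and the mesh can be sliced. Binary STL stores
#' float32 coordinates, so a binary round trip is exact only to single
#' precision (about 1e-5 mm at 100 mm); the ASCII writer keeps full double
#' precision.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_raw <- readBin(path, "raw", n = 512L)
  # ASCII dialect: leading "solid" and a "facet" keyword in the head;
  # detection is done on raw bytes so binary content cannot confuse it
  lead <- head_raw[!(head_raw %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d)))]
  is_ascii <- length(lead) >= 5L &&
    identical(lead[1:5], charToRaw("solid")) &&
    length(grepRaw("facet", head_raw, fixed = TRUE)) > 0L
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L) {
    stop("malformed STL: vertex count ", nrow(tri), " not a multiple of 3")
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)                       # header
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 0L) stop("malformed binary STL: bad facet count at byte 80")
  expected <- 84 + 50 * as.numeric(n)
  if (size < expected) {
    stop("malformed binary STL: file truncated at byte ", size,
         " (expected ", expected, " bytes for ", n, " facets)")
  }
  body <- readBin(con, "raw", n = 50L * n)
  dim(body) <- c(50L, n)
  floats <- readBin(as.vector(body[1:48, ]), "numeric", n = 12L * n,
                    size = 4L, endian = "little")
  dim(floats) <- c(12L, n)
  # rows 4..12 are the three vertices; 1..3 the stored normal (ignored)
  v <- floats[4:12, , drop = FALSE]
  matrix(as.vector(v), ncol = 3L, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L) stop("malformed ASCII STL: no vertex lines")
  parts <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) {
    stop("malformed ASCII STL: bad vertex at line ", vl[bad[1]])
  }
  coords <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  )
  if (any(!is.finite(coords))) {
    stop("malformed ASCII STL: non-numeric vertex at line ",
         vl[which(colSums(!is.finite(coords)) > 0)[1]])
  }
  t(coords)
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write the 84-byte-header binary dialect (default TRUE);
#'   otherwise full-precision ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len

  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "binary STL (coameta)"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- rbind(t(nrm), t(a), t(b), t(c_))      # 12 floats per facet
    raw_f <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    dim(raw_f) <- c(48L, nrow(f))
    rec <- rbind(raw_f, matrix(as.raw(0), 2L, nrow(f)))  # 2-byte attribute
    writeBin(as.vector(rec), con)
  } else {
    fmt <- function(x) sprintf("%.12g", x)
    out <- character(7L * nrow(f) + 2L)
    out[1] <- "solid coameta"
    k <- 2L
    for (i in seq_len(nrow(f))) {
      out[k:(k + 6L)] <- c(
        sprintf("  facet normal %s %s %s",
                fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(a[i, 1]), fmt(a[i, 2]), fmt(a[i, 3])),
        sprintf("      vertex %s %s %s", fmt(b[i, 1]), fmt(b[i, 2]), fmt(b[i, 3])),
        sprintf("      vertex %s %s %s", fmt(c_[i, 1]), fmt(c_[i, 2]), fmt(c_[i, 3])),
        "    endloop",
        "  endfacet"
      )
      k <- k + 7L
    }
    out[k] <- "endsolid coameta"
    writeLines(out, path)
  }
  invisible(path)
}
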