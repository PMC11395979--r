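# Mesh fixtures built in code at test time. The elliptic tube is constructed
# here by hand (independently of the package's sweep machinery) so section
# areas can be checked against the analytic pi*a*b oracle.

elliptic_cylinder_fixture <- function(a = 4, b = 9, L = 40,
                                      n_circ = 128, n_axial = 30) {
  z <- seq(0, L, length.out = n_axial)
  theta <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  verts <- do.call(rbind, lapply(z, function(zz) {
    cbind(a * cos(theta), b * sin(theta), zz)
  }))
  idx <- function(i, k) (i - 1L) * n_circ + ((k - 1L) %% n_circ) + 1L
  ks <- seq_len(n_circ)
  faces <- do.call(rbind, lapply(seq_len(n_axial - 1L), function(i) {
    rbind(
      cbind(idx(i, ks), idx(i, ks + 1L), idx(i + 1L, ks)),
      cbind(idx(i, ks + 1L), idx(i + 1L, ks + 1L), idx(i + 1L, ks))
    )
  }))
  c0 <- nrow(verts) + 1L
  c1 <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, L))
  faces <- rbind(
    faces,
    cbind(idx(1L, ks + 1L), idx(1L, ks), c0),
    cbind(idx(n_axial, ks), idx(n_axial, ks + 1L), c1)
  )
  surface_mesh(verts, faces)
}

cylinder_fixture <- function(r = 5, L = 60, n_circ = 64, n_axial = 60) {
  tube_mesh(cbind(0, 0, seq(0, L, length.out = n_axial)), r, n_circ = n_circ)
}

# straight tube with a Gaussian narrowing in its radius profile
stenosed_tube_fixture <- function(r = 6, L = 120, depth = 0.4, loc = 60,
                                  width = 8, n_circ = 64, n_axial = 240) {
  z <- seq(0, L, length.out = n_axial)
  radii <- r * (1 - depth * exp(-(z - loc)^2 / (2 * width^2)))
  tube_mesh(cbind(0, 0, z), radii, n_circ = n_circ)
}

stenosed_radius <- function(z, r = 6, depth = 0.4, loc = 60, width = 8) {
  r * (1 - depth * exp(-(z - loc)^2 / (2 * width^2)))
}

# rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# a named profile vector for hand-arithmetic checks
profile_vec <- function(D1 = 10, D2 = 9.5, D3 = 8.5, D0 = 7, D4 = 9,
                        D5 = 7, DBCA = 4.5, DLCCA = 3.3, DLSCA = 3.6) {
  c(D1 = D1, D2 = D2, D3 = D3, D0 = D0, D4 = D4, D5 = D5,
    DBCA = DBCA, DLCCA = DLCCA, DLSCA = DLSCA)
}

# negative log-likelihood of logistic regression, for brute-force oracles
logistic_nll <- function(beta, X, y01) {
  eta <- drop(cbind(1, X) %*% beta)
  -sum(y01 * eta - log1p(exp(eta)))
}
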