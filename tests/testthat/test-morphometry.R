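test_that("centerline of a straight cylinder lies on its axis", {
  cyl <- cylinder_fixture(r = 5, L = 60)
  cl <- extract_centerline(cyl, c(0, 0, 0))
  expect_lt(max(sqrt(rowSums(cl$points[, 1:2, drop = FALSE]^2))), 1e-3)
  expect_equal(max(cl$arc_length), 60, tolerance = 0.01)
})

test_that("quarter-torus centerline recovers the analytic arc length", {
  th <- seq(0, pi / 2, length.out = 100)
  tor <- tube_mesh(cbind(20 * cos(th), 20 * sin(th), 0), 5, n_circ = 64)
  cl <- extract_centerline(tor, c(20, 0, 0))
  expect_equal(max(cl$arc_length), (pi / 2) * 20, tolerance = 0.01)
})

test_that("centerline extraction is equivariant under rigid motions", {
  cyl <- cylinder_fixture(r = 4, L = 40, n_axial = 50)
  R <- rotation_matrix(c(1, 2, 0.5), 0.9)
  shift <- c(10, -3, 7)
  moved <- surface_mesh(sweep(cyl$vertices %*% t(R), 2, shift, `+`),
                        cyl$faces)
  cl0 <- extract_centerline(cyl, c(0, 0, 0))
  cl1 <- extract_centerline(moved, drop(R %*% c(0, 0, 0)) + shift)
  expect_equal(max(cl0$arc_length), max(cl1$arc_length), tolerance = 1e-3)
  # stations mapped back coincide with the original axis
  back <- sweep(cl1$points, 2, shift) %*% R
  expect_lt(max(sqrt(rowSums(back[, 1:2, drop = FALSE]^2))), 1e-3)
})

test_that("cross-section diameter matches analytic circular and elliptic areas", {
  cyl <- cylinder_fixture(r = 5, L = 60, n_circ = 256)
  cl <- extract_centerline(cyl, c(0, 0, 0))
  for (s in c(10, 30, 50)) {
    expect_equal(cross_section_diameter(cyl, cl, s), 10, tolerance = 1e-3)
  }
  # elliptic semi-axes 4 and 9: equivalent-circle diameter 2*sqrt(36) = 12
  ell <- elliptic_cylinder_fixture(a = 4, b = 9, L = 40, n_circ = 256)
  clE <- centerline(cbind(0, 0, seq(1, 39, length.out = 30)))
  expect_equal(cross_section_diameter(ell, clE, 19), 12, tolerance = 0.01)
})

test_that("small tangent errors barely perturb the measured diameter", {
  cyl <- cylinder_fixture(r = 5, L = 60, n_circ = 128)
  d0 <- 2 * sqrt(coameta:::section_at(cyl, c(0, 0, 30), c(0, 0, 1))$area / pi)
  tilt <- c(sin(2 * pi / 180), 0, cos(2 * pi / 180))
  d1 <- 2 * sqrt(coameta:::section_at(cyl, c(0, 0, 30), tilt)$area / pi)
  expect_lt(abs(d1 - d0) / d0, 0.005)
})

test_that("measured diameters are rigid-motion invariant and homogeneous", {
  cyl <- cylinder_fixture(r = 5, L = 40, n_axial = 50)
  axis_cl <- centerline(cbind(0, 0, seq(0.5, 39.5, length.out = 40)))
  d_ref <- cross_section_diameter(cyl, axis_cl, 20)

  R <- rotation_matrix(c(0.3, -1, 2), 1.2)
  shift <- c(-4, 8, 2)
  moved <- surface_mesh(sweep(cyl$vertices %*% t(R), 2, shift, `+`),
                        cyl$faces)
  moved_cl <- centerline(sweep(axis_cl$points %*% t(R), 2, shift, `+`))
  d_mov <- cross_section_diameter(moved, moved_cl, 20)
  expect_equal(d_mov, d_ref, tolerance = 1e-6)

  k <- 2.7   # uniform scaling scales every diameter by k
  scaled <- surface_mesh(k * cyl$vertices, cyl$faces)
  scaled_cl <- centerline(k * axis_cl$points)
  expect_equal(cross_section_diameter(scaled, scaled_cl, k * 20), k * d_ref,
               tolerance = 1e-6 * d_ref)
})

test_that("minimal-diameter search matches the analytic narrowing", {
  mesh <- stenosed_tube_fixture(r = 6, depth = 0.4, loc = 60, width = 8)
  cl <- extract_centerline(mesh, c(0, 0, 0))
  res <- find_min_diameter(mesh, cl, c(20, 100))
  expect_equal(res$diameter, 2 * 6 * 0.6, tolerance = 0.01 * 7.2)
  expect_equal(res$s, 60, tolerance = 1)

  # flat objective: any location acceptable, diameter equals the constant
  flat <- cylinder_fixture(r = 5, L = 60)
  clF <- extract_centerline(flat, c(0, 0, 0))
  resF <- find_min_diameter(flat, clF, c(10, 50))
  expect_equal(resF$diameter, 10, tolerance = 0.01)

  expect_error(find_min_diameter(mesh, cl, c(40, 40)), "empty")
})

test_that("minimal-diameter search dominates brute-force scans", {
  mesh <- stenosed_tube_fixture(r = 6, depth = 0.3, loc = 45, width = 10,
                                L = 100, n_axial = 200)
  cl <- extract_centerline(mesh, c(0, 0, 0))
  res <- find_min_diameter(mesh, cl, c(15, 85))
  set.seed(99)
  s_rand <- runif(200, 15, 85)
  d_rand <- vapply(s_rand, function(s) cross_section_diameter(mesh, cl, s),
                   numeric(1))
  expect_true(all(res$diameter <= d_rand * (1 + 1e-9)))
  # never above the 0.1 mm exhaustive scan by more than 0.5%
  d_scan <- vapply(seq(15, 85, by = 0.1),
                   function(s) cross_section_diameter(mesh, cl, s),
                   numeric(1))
  expect_lte(res$diameter, min(d_scan) * 1.005)
})

test_that("landmark profiles recover generator ground truth within 2%", {
  for (depth in c(0, 0.45)) {
    a <- synthetic_aorta(narrowing = list(depth = depth, width = 5))
    mesh <- make_tube_mesh(a)
    cl <- extract_centerline(mesh, c(0, 0, 0))
    prof <- measure_landmarks(mesh, cl, aorta_landmark_config(a))
    truth <- aorta_true_profile(a)
    expect_true(all(abs(prof - truth) / truth < 0.02),
                info = paste("depth", depth))
    expect_true(all(prof > 0))
  }
})

test_that("without narrowing, a flat descending profile gives D0 = D3", {
  a <- synthetic_aorta(
    radius_ctrl = data.frame(s_frac = c(0, 1), r = c(4.2, 4.2)),
    narrowing = list(depth = 0, width = 5)
  )
  mesh <- make_tube_mesh(a)
  cl <- extract_centerline(mesh, c(0, 0, 0))
  prof <- measure_landmarks(mesh, cl, aorta_landmark_config(a))
  expect_equal(prof[["D0"]], prof[["D3"]], tolerance = 0.02 * prof[["D3"]])
})

test_that("missing branches are reported by name", {
  a <- synthetic_aorta()
  mesh <- make_tube_mesh(a, branches = FALSE)
  cl <- extract_centerline(mesh, c(0, 0, 0))
  cfg <- aorta_landmark_config(a)
  expect_error(measure_landmarks(mesh, cl, cfg), "BCA")
  cfg2 <- cfg
  cfg2$branches$LCCA <- NULL
  expect_error(measure_landmarks(make_tube_mesh(a), cl, cfg2), "LCCA")
})

test_that("agreement report matches the attenuation oracle", {
  set.seed(31)
  n <- 60
  auto <- data.frame(D1 = rnorm(n, 10, 1.2), D0 = rnorm(n, 6, 1.5))
  # identical columns: perfect agreement
  same <- agreement_report(auto, auto)
  expect_true(all(abs(same$r - 1) < 1e-12))

  # manual = auto + independent noise: r ~ 1/sqrt(1 + sd_noise^2/var_auto)
  sd_noise <- 0.8
  manual <- auto + matrix(rnorm(2 * n, 0, sd_noise), n, 2)
  rep <- agreement_report(auto, manual)
  r_exp <- 1 / sqrt(1 + sd_noise^2 / apply(auto, 2, var))
  expect_true(all(abs(rep$r - r_exp) < 0.1))

  # degenerate constant column: NA with a warning
  manual2 <- manual
  manual2$D1 <- 5
  expect_warning(rep2 <- agreement_report(auto, manual2), "constant")
  expect_true(is.na(rep2$r[rep2$diameter == "D1"]))
  expect_error(agreement_report(auto[1:2, ], manual[1:2, ]), "3")
})
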