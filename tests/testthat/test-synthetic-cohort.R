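test_that("class-conditional morphometry honours the stated orderings", {
  m <- sample_morphometry(cohort_config(seed = 7))
  agg <- aggregate(m[, c("D0", "D3", "D1", "DBCA", "D5")],
                   by = list(label = m$label), mean)
  coa <- agg[agg$label == "coa", ]
  nrm <- agg[agg$label == "normal", ]
  expect_lt(coa$D0, nrm$D0)
  expect_lt(coa$D3, nrm$D3)
  expect_lt(coa$D1, nrm$D1)
  expect_gt(coa$DBCA, nrm$DBCA)
  expect_gt(coa$D5, nrm$D5)
  # within-record constraint defining D0
  expect_true(all(m$D0 <= pmin(m$D3, m$D4)))
  expect_true(all(m[, coameta:::DIAMETERS] > 0))
})

test_that("zero-sd sampling degenerates to the class mean vectors", {
  dp <- coameta:::default_diameter_params()
  for (cls in c("normal", "coa")) dp[[cls]]$sd[] <- 0
  m <- sample_morphometry(cohort_config(n_per_class = 3, seed = 1,
                                        diameter_params = dp))
  for (cls in c("normal", "coa")) {
    rows <- m[m$label == cls, coameta:::DIAMETERS]
    expect_equal(unname(as.matrix(rows)),
                 matrix(dp[[cls]]$mean[coameta:::DIAMETERS], 3, 9,
                        byrow = TRUE))
  }
})

test_that("normal-class D0 spread exceeds CoA D0 spread across seeds", {
  # Monte-Carlo check of the generator's own dispersion contract
  wins <- vapply(1:100, function(s) {
    m <- sample_morphometry(cohort_config(n_per_class = 500, seed = s))
    sd(m$D0[m$label == "normal"]) > sd(m$D0[m$label == "coa"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("identical seed and config give a byte-identical cohort CSV", {
  cfg <- cohort_config(seed = 11)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(simulate_cohort(cfg), f1)
  write_cohort_csv(simulate_cohort(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("outlet velocities are equal under symmetric splits and diameters", {
  cfg <- cohort_config(seed = 2, noise_sd_v = 0, noise_sd_p = 0,
                       v_inlet_sd = 0, redistribution = 0,
                       flow_split = c(BCA = 0.25, LCCA = 0.25,
                                      LSCA = 0.25, O5 = 0.25))
  m <- profile_vec(DBCA = 6, DLCCA = 6, DLSCA = 6, D5 = 6)
  h <- forward_hemodynamics(m, cfg)
  outs <- h[c("v_OBCA", "v_OLCCA", "v_OLSCA", "v_O5")]
  expect_lt(diff(range(outs)), 1e-12)
})

test_that("the stenosis gradient is near-zero without narrowing and grows with it", {
  cfg <- cohort_config(seed = 2, noise_sd_v = 0, noise_sd_p = 0, v_inlet_sd = 0)
  m_open <- profile_vec(D0 = 8.5, D3 = 8.5)          # D0 = D3: no narrowing
  m_sten <- profile_vec(D0 = 0.4 * 8.5, D3 = 8.5)
  h_open <- forward_hemodynamics(m_open, cfg)
  h_sten <- forward_hemodynamics(m_sten, cfg)
  g_open <- h_open[["p_M3"]] - h_open[["p_M4"]]
  g_sten <- h_sten[["p_M3"]] - h_sten[["p_M4"]]
  expect_lte(g_open, cfg$friction + 1e-12)           # friction-only bound
  expect_gt(g_sten, g_open)
})

test_that("zero-noise records satisfy the squared-diameter flow balance", {
  cfg <- cohort_config(n_per_class = 10, seed = 5,
                       noise_sd_v = 0, noise_sd_p = 0)
  coh <- simulate_cohort(cfg)
  resid <- abs(coh$v_P1 * coh$D1^2 -
    (coh$v_OBCA * coh$DBCA^2 + coh$v_OLCCA * coh$DLCCA^2 +
       coh$v_OLSCA * coh$DLSCA^2 + coh$v_O5 * coh$D5^2))
  expect_lt(max(resid), 1e-10)
})

test_that("degenerate morphometry is rejected with informative errors", {
  cfg <- cohort_config(seed = 1)
  m <- profile_vec(D0 = 0)
  expect_error(forward_hemodynamics(m, cfg), "D0")
  # impossible truncated draw names the offending parameter
  dp <- coameta:::default_diameter_params()
  dp$normal$mean["D1"] <- 0.001
  dp$normal$sd["D1"] <- 0       # degenerate at the boundary is fine
  dp$normal$mean["D0"] <- 5     # but D0 mean far above min(D3, D4) with sd 0
  dp$normal$sd["D0"] <- 0
  dp$normal$mean["D3"] <- 2
  expect_error(
    sample_morphometry(cohort_config(seed = 1, diameter_params = dp)),
    "D0"
  )
})

test_that("tube meshes are faithful sweeps of the radius profile", {
  # straight cylinder: every wall vertex sits on the 5 mm radius
  cyl <- tube_mesh(cbind(0, 0, seq(0, 40, length.out = 60)), 5,
                   n_circ = 48, caps = FALSE)
  rad <- sqrt(cyl$vertices[, 1]^2 + cyl$vertices[, 2]^2)
  expect_lt(max(abs(rad - 5)), 1e-9)

  # candy-cane narrowing: minimal slice diameter approaches depth * 2r
  a <- synthetic_aorta(
    radius_ctrl = data.frame(s_frac = c(0, 1), r = c(4.2, 4.2)),
    narrowing = list(depth = 0.5, width = 6)
  )
  mesh <- make_tube_mesh(a, n_circ = 96, n_axial = 400, branches = FALSE)
  cl <- extract_centerline(mesh, c(0, 0, 0))
  arch1 <- a$asc_length + pi * a$arch_radius
  d0 <- find_min_diameter(mesh, cl, c(arch1, max(cl$arc_length) - 2))
  expect_equal(d0$diameter, 0.5 * 2 * 4.2, tolerance = 0.01)

  # doubling resolution changes enclosed volume by < 1%
  v1 <- mesh_volume(make_tube_mesh(a, n_circ = 24, n_axial = 100,
                                   branches = FALSE))
  v2 <- mesh_volume(make_tube_mesh(a, n_circ = 48, n_axial = 200,
                                   branches = FALSE))
  expect_lt(abs(v2 - v1) / v2, 0.01)
  # and converges to the analytic volume of the swept tube
  s <- seq(0, a$total_length, length.out = 4000)
  v_true <- sum(pi * aorta_radius(a, s)^2) * diff(s)[1]
  expect_equal(v2, v_true, tolerance = 0.01)
})

test_that("self-intersecting centerlines are refused", {
  a <- synthetic_aorta(arch_radius = 4)   # limbs 8 mm apart, radius ~4-5 mm
  expect_error(make_tube_mesh(a, n_axial = 120), "self-intersecting")
})

test_that("sphere sampling meets the density contract", {
  for (ctr in list(c(0, 0, 0), c(12.3, -4.5, 8))) {
    sp <- sample_sphere_points(ctr, 0)
    expect_true(nrow(sp) >= 850 && nrow(sp) <= 900)
    # strictly inside the 1 mm diameter sphere
    r <- sqrt((sp$x - ctr[1])^2 + (sp$y - ctr[2])^2 + (sp$z - ctr[3])^2)
    expect_true(all(r < 0.5))
  }
  sp <- sample_sphere_points(c(1, 1, 1), function(p) 2 * p[, 2] - p[, 3])
  expect_equal(mean(sp$value), 2 * 1 - 1, tolerance = 1e-6)
})
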