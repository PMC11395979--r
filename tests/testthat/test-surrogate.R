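test_that("ratio features evaluate exactly and scale as 1/k^2", {
  m <- profile_vec(D1 = 10, DBCA = 5)
  expect_equal(drop(build_features(m, "D1/DBCA^2")), c("D1/DBCA^2" = 0.4))

  terms <- c("D1/DBCA^2", "D0/DBCA^2", "D4/DBCA^2")
  f1 <- build_features(m, terms)
  k <- 1.7
  m2 <- m
  m2["DBCA"] <- k * m["DBCA"]
  expect_equal(build_features(m2, terms), f1 / k^2)

  # hand-coded oracle for the v(M4) term list on one record
  eq9 <- surrogate_forms()$v_M4
  f <- build_features(m, eq9, p_hat_P1 = 13)
  oracle <- c(m[["D1"]] / m[["D4"]]^2, m[["DBCA"]] / m[["D4"]]^2,
              m[["DLCCA"]] / m[["D4"]]^2, m[["D3"]] / m[["D4"]]^2, 13)
  expect_equal(unname(drop(f)), oracle)

  m0 <- profile_vec(DBCA = 0)
  expect_error(build_features(m0, "D1/DBCA^2"), "denominator")
  expect_error(build_features(m, "p_hat_P1"), "p_hat_P1")
})

test_that("least-squares fitting matches oracles and handles degeneracy", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  y_exact <- drop(1.5 + X %*% beta)
  fit <- fit_linear(X, y_exact)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-8)
  expect_lt(abs(fit$intercept - 1.5), 1e-8)

  # noisy fit equals the brute-force normal-equations oracle
  y <- y_exact + rnorm(20, 0, 0.5)
  fit2 <- fit_linear(X, y)
  Xi <- cbind(1, X)
  beta_ne <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_lt(max(abs(c(fit2$intercept, fit2$coefficients) - drop(beta_ne))),
            1e-8)

  expect_equal(fit_linear(X, rep(4, 20))$r_squared, 0)
  X_bad <- cbind(X, d = X[, "a"] * 2)
  expect_error(fit_linear(X_bad, y), "collinear")
  expect_error(fit_linear(X[1:4, ], y[1:4]), "n > p")
})

test_that("published pressure models evaluate to their printed arithmetic", {
  zero <- as.data.frame(t(setNames(rep(0, 9), names(profile_vec()))))
  expect_equal(predict_pressure_P1(zero), 11.14)
  expect_equal(predict_pressure_M2(zero), 11.2)

  m <- profile_vec(D1 = 10, DBCA = 8, D0 = 6, D5 = 9)
  expect_equal(predict_pressure_P1(m), 16.03, tolerance = 1e-10)

  # +1 mm on D0 lowers predicted inlet pressure by 0.55 kPa
  m2 <- m
  m2["D0"] <- m["D0"] + 1
  expect_equal(predict_pressure_P1(m2) - predict_pressure_P1(m), -0.55)
})

test_that("published velocity models evaluate to their printed arithmetic", {
  base <- profile_vec(D1 = 0, D0 = 0, D4 = 0, DBCA = 1)
  expect_equal(predict_velocity(base, "OBCA", p_hat_P1 = 0), -0.42)

  m <- profile_vec(D1 = 8, D0 = 4, D4 = 8, DBCA = 2)
  expect_equal(predict_velocity(m, "OBCA", p_hat_P1 = 10), 1.35,
               tolerance = 1e-10)

  # smaller D0 (tighter coarctation) raises the branch velocity
  lo <- profile_vec(D0 = 3)
  hi <- profile_vec(D0 = 6)
  expect_gt(predict_velocity(lo, "OBCA", 13), predict_velocity(hi, "OBCA", 13))
})

test_that("chained prediction equals its manual two-step composition", {
  m <- profile_vec()
  ch <- chain_predict(m)
  p_hat <- predict_pressure_P1(m)
  expect_equal(ch$p_P1, p_hat)
  expect_equal(ch$v_OBCA, predict_velocity(m, "OBCA", p_hat))
  expect_equal(ch$v_M4, predict_velocity(m, "M4", p_hat))
  expect_equal(ch$v_O5, predict_velocity(m, "O5", p_hat))

  # total D1 sensitivity of v_O5 (direct + pressure path) vs finite differences
  h <- 1e-6
  up <- m; up["D1"] <- m["D1"] + h
  dn <- m; dn["D1"] <- m["D1"] - h
  fd <- (chain_predict(up)$v_O5 - chain_predict(dn)$v_O5) / (2 * h)
  analytic <- 0.29 / m[["D5"]]^2 + (-0.06) * 0.34
  expect_equal(fd, analytic, tolerance = 1e-4)
})

test_that("noise-free equation-mode cohorts identify the generating coefficients", {
  cfg <- cohort_config(seed = 3, hemo_model = "equations",
                       noise_sd_v = 0, noise_sd_p = 0, v_inlet_sd = 0)
  fits <- fit_surrogates(simulate_cohort(cfg))
  pub <- published_surrogates()
  for (k in names(fits)) {
    expect_lt(max(abs(c(
      fits[[k]]$intercept - pub[[k]]$intercept,
      fits[[k]]$coefficients - pub[[k]]$coefficients
    ))), 1e-6)
  }
})

test_that("refitted surrogates stay statistically significant on default cohorts", {
  # low R^2 but small model p-level, in most cohorts
  p_ok <- vapply(1:100, function(s) {
    fits <- fit_surrogates(simulate_cohort(cohort_config(seed = s)))
    all(vapply(fits, function(f) f$p_level < 0.05, logical(1)))
  }, logical(1))
  expect_gte(mean(p_ok), 0.8)
})

test_that("correlation report ranks the descending-outlet velocity highest", {
  coh <- simulate_cohort(cohort_config(seed = 21))
  fits <- fit_surrogates(coh)
  pred <- chain_predict(coh, fits)
  rep <- correlation_report(coh[, names(pred)], pred)

  expect_true(all(rep$r[rep$feature %in% c("v_O5", "v_M4")] > 0.5))
  r_o5 <- rep$r[rep$feature == "v_O5"]
  r_ob <- rep$r[rep$feature == "v_OBCA"]
  expect_gte(r_o5, r_ob)

  # identical frames: all r = 1
  same <- correlation_report(pred, pred)
  expect_true(all(abs(same$r - 1) < 1e-12))

  # independent predictions: |r| below the null band in >= 95% of seeds
  nulls <- vapply(1:100, function(s) {
    set.seed(s)
    a <- data.frame(v_O5 = rnorm(60))
    b <- data.frame(v_O5 = rnorm(60))
    abs(correlation_report(a, b)$r) < 0.35
  }, logical(1))
  expect_gte(mean(nulls), 0.95)

  expect_error(correlation_report(coh[1:2, ], pred[1:2, ]), "3")
})
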