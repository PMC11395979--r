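test_that("stratified 80:20 split has the expected sizes and determinism", {
  coh <- simulate_cohort(cohort_config(seed = 1))
  plan <- split_80_20(coh, seed = 4)
  expect_length(plan$test, 12)
  expect_length(plan$train, 48)
  expect_setequal(c(plan$train, plan$test), seq_len(60))
  expect_length(intersect(plan$train, plan$test), 0)
  # stratification: 6 test records per class
  expect_equal(unname(table(coh$label[plan$test])), c(6L, 6L),
               ignore_attr = TRUE)
  # determinism
  plan2 <- split_80_20(coh, seed = 4)
  expect_identical(plan, plan2)

  tiny <- data.frame(label = c("normal", "normal", "normal", "coa", "coa"))
  expect_length(split_80_20(tiny, seed = 1)$test, 1)

  onec <- data.frame(label = rep("normal", 10))
  expect_error(split_80_20(onec, seed = 1), "absent")
})

test_that("IRLS logistic fits match symmetry and brute-force oracles", {
  # symmetric two-point problem: intercept must vanish
  X <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_logistic(X, c(0, 1), standardize = FALSE)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_true(fit$separated)     # two separable points

  # 6-record overlapping data: IRLS equals brute-force likelihood maximum
  X6 <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1,
               dimnames = list(NULL, "x"))
  y6 <- c(0, 1, 0, 1, 0, 1)
  fit6 <- fit_logistic(X6, y6, standardize = FALSE)
  expect_true(fit6$converged)
  expect_false(fit6$separated)
  opt <- optim(c(0, 0), logistic_nll, X = X6, y01 = y6, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_lt(max(abs(c(fit6$intercept, fit6$coefficients) - opt$par)), 1e-4)
  # and equals the standard GLM fit
  glmfit <- suppressWarnings(
    glm(y6 ~ X6, family = binomial())
  )
  expect_lt(max(abs(c(fit6$intercept, fit6$coefficients) -
                      unname(coef(glmfit)))), 1e-6)

  expect_error(
    fit_logistic(cbind(x = rep(1, 6), z = rnorm(6)), y6),
    "constant.*x"
  )
  expect_error(fit_logistic(X6, rep(1, 6)), "both classes")
})

test_that("strongly separated diameters raise the separation flag", {
  coh <- simulate_cohort(cohort_config(seed = 8))
  fit <- fit_logistic(coh[, c("D1", "DBCA", "D3", "D0", "D5")], coh$label)
  expect_true(fit$separated)
  # D0 carries the largest standardized coefficient magnitude
  expect_equal(names(which.max(abs(fit$coefficients))), "D0")
})

test_that("classification is strict at the threshold and monotone", {
  clf <- published_classifier("hemo")
  # all-zero features: z = intercept = 0, P = 0.5, classified normal
  X0 <- as.data.frame(t(setNames(rep(0, 5), clf$features)))
  out <- classify(clf, X0)
  expect_equal(out$probability, 0.5)
  expect_equal(out$label, "normal")

  # large positive z approaches probability 1
  Xbig <- X0
  Xbig$v_OBCA <- 50
  expect_gt(classify(clf, Xbig)$probability, 0.999)

  # monotone increasing in a positive-coefficient feature
  probs <- vapply(c(-1, 0, 1, 2), function(v) {
    X <- X0
    X$v_OBCA <- v
    classify(clf, X)$probability
  }, numeric(1))
  expect_true(all(diff(probs) > 0))

  expect_error(classify(clf, X0[, 1:3]), "missing feature")
})

test_that("published tables are wired by feature name with a free intercept", {
  t1 <- published_classifier("morpho")
  expect_equal(t1$features, c("D1", "DBCA", "D3", "D0", "D5"))
  expect_equal(unname(t1$coefficients),
               c(-0.399, 0.999, 0.11, -1.726, 1.134))
  t3 <- published_classifier("meta", intercept = 0.7)
  X0 <- as.data.frame(t(setNames(rep(0, 5), t3$features)))
  expect_equal(classify(t3, X0)$probability, plogis(0.7))
})

test_that("accuracy reproduces the printed fractions and its invariances", {
  truth <- rep(c("normal", "coa"), each = 6)
  pred1 <- truth
  pred1[1] <- "coa"
  expect_equal(round(accuracy(pred1, truth)$accuracy, 2), 0.92)
  pred3 <- truth
  pred3[1:3] <- "coa"          # three of the six normals misread
  expect_equal(round(accuracy(pred3, truth)$accuracy, 2), 0.75)
  expect_equal(accuracy(truth, truth)$accuracy, 1)

  # label-permutation invariance and range
  flip <- function(x) ifelse(x == "coa", "normal", "coa")
  a1 <- accuracy(pred3, truth)$accuracy
  a2 <- accuracy(flip(pred3), flip(truth))$accuracy
  expect_equal(a1, a2)
  expect_true(a1 >= 0 && a1 <= 1)
  cm <- accuracy(pred3, truth)$confusion
  expect_equal(sum(cm), 12)

  expect_error(accuracy(pred3[1:5], truth), "length")
})
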