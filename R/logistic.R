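#' Stratified 80:20 train/test split
#'
#' Randomly divides a labelled cohort into training and test sets in an
#' 80:20 ratio, stratified by class so both classes appear in both sets.
#' Reproducible: the same seed and cohort give the same plan.
#'
#' @param cohort data frame with a `label` column (`"normal"` / `"coa"`).
#' @param seed integer seed for the split.
#' @param test_frac test fraction (default 0.2).
#' @return object of class `"split_plan"`: list with integer row indices
#'   `train` and `test` (disjoint, union = all rows) and the `seed`.
#' @export
split_80_20 <- function(cohort, seed, test_frac = 0.2) {
  stopifnot(is.data.frame(cohort), "label" %in% names(cohort),
            nrow(cohort) >= 5)
  classes <- unique(cohort$label)
  if (!all(c("normal", "coa") %in% classes)) {
    stop("a class is absent from the cohort: need both normal and coa")
  }
  set.seed(stage_seed(seed, "split"))
  test <- integer(0)
  for (cls in sort(classes)) {
    idx <- which(cohort$label == cls)
    k <- round(test_frac * length(idx))
    k <- min(k, length(idx) - 1L)        # keep every class in training
    if (k > 0) test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  structure(list(
    train = setdiff(seq_len(nrow(cohort)), test),
    test = test,
    seed = as.integer(seed)
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

new_logistic_classifier <- function(features, coefficients, intercept,
                                    threshold = 0.5, center = NULL,
                                    scale = NULL, mode = "published",
                                    converged = NA, separated = NA,
                                    loglik = NA_real_, iterations = NA_integer_,
                                    n = NA_integer_) {
  stopifnot(length(coefficients) == length(features),
            threshold > 0, threshold < 1)
  structure(list(
    features = features,
    coefficients = stats::setNames(as.numeric(coefficients), features),
    intercept = intercept, threshold = threshold,
    center = center, scale = scale, mode = mode,
    converged = converged, separated = separated,
    loglik = loglik, iterations = iterations, n = n
  ), class = "logistic_classifier")
}

#' @export
print.logistic_classifier <- function(x, ...) {
  cat(sprintf("logistic_classifier (%s%s): threshold %.2f\n", x$mode,
              if (isTRUE(x$separated)) ", separated training data" else "",
              x$threshold))
  cat(sprintf("  intercept %.4g; %s\n", x$intercept,
              paste(sprintf("%s (%.4g)", x$features, x$coefficients),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a binary logistic classifier by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, with coarctation (`"coa"`) as the positive class. Iteration
#' stops when the log-likelihood changes by less than `tol` (default 1e-8)
#' or after `max_iter` (default 100) iterations. Features are z-scored
#' before fitting by default (the standardization parameters are stored in
#' the classifier, so prediction accepts raw features); standardization
#' makes coefficient magnitudes comparable across mm- and kPa-scaled
#' features.
#'
#' Perfectly (or quasi-) separated training data make the likelihood
#' maximum lie at infinite coefficients; this is detected — every fitted
#' probability collapsing onto its label — and reported via the `separated`
#' flag, with the iteration-capped fit still returned and usable for
#' classification.
#'
#' @param X feature matrix or data frame.
#' @param y labels: factor/character with levels `"normal"`/`"coa"`, or a
#'   0/1 vector (1 = CoA).
#' @param standardize z-score features before fitting (default TRUE).
#' @param threshold classification threshold on the CoA probability.
#' @param max_iter,tol IRLS controls.
#' @return a `logistic_classifier` with fit diagnostics (`converged`,
#'   `separated`, `loglik`, `iterations`).
#' @export
fit_logistic <- function(X, y, standardize = TRUE, threshold = 0.5,
                         max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y01 <- encode_labels(y)
  stopifnot(nrow(X) == length(y01))
  if (length(unique(y01)) < 2L) stop("both classes must be present in training data")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    stop("constant feature(s): ", paste(colnames(X)[const], collapse = ", "))
  }
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  } else {
    center <- NULL; scale <- NULL; Xs <- X
  }
  Xi <- cbind(1, Xs)
  beta <- numeric(ncol(Xi))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    p <- stats::plogis(eta)
    ll <- sum(y01 * log(pmax(p, 1e-300)) + (1 - y01) * log(pmax(1 - p, 1e-300)))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y01 - p) / w
    fit <- stats::lm.wfit(Xi, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) break
    beta <- beta_new
  }
  eta <- drop(Xi %*% beta)
  p <- stats::plogis(eta)
  ll <- sum(y01 * log(pmax(p, 1e-300)) + (1 - y01) * log(pmax(1 - p, 1e-300)))
  # separation: every fitted probability has collapsed onto its label
  separated <- all(abs(p - y01) < 1e-4)
  new_logistic_classifier(
    features = colnames(X), coefficients = beta[-1L], intercept = beta[[1L]],
    threshold = threshold, center = center, scale = scale, mode = "fitted",
    converged = converged, separated = separated,
    loglik = ll, iterations = iter, n = nrow(X)
  )
}

encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("normal", "coa"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(y == "coa"))
  }
  stopifnot(all(y %in% c(0, 1)))
  as.integer(y)
}

#' Classify aortas with a logistic classifier
#'
#' Computes the CoA probability for each record and classifies as CoA when
#' the probability strictly exceeds the threshold — a record exactly at the
#' threshold (e.g. linear predictor 0 at threshold 0.5) is classified
#' normal.
#'
#' @param clf a `logistic_classifier`.
#' @param X feature matrix or data frame containing (at least) the
#'   classifier's features, in any column order.
#' @return data frame with `probability` and `label` columns.
#' @export
classify <- function(clf, X) {
  stopifnot(inherits(clf, "logistic_classifier"))
  X <- as.data.frame(X)
  miss <- setdiff(clf$features, names(X))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  Xm <- as.matrix(X[, clf$features, drop = FALSE])
  storage.mode(Xm) <- "double"
  if (!is.null(clf$center)) {
    Xm <- sweep(sweep(Xm, 2, clf$center), 2, clf$scale, `/`)
  }
  eta <- drop(clf$intercept + Xm %*% clf$coefficients)
  p <- stats::plogis(eta)
  data.frame(
    probability = p,
    label = ifelse(p > clf$threshold, "coa", "normal"),
    stringsAsFactors = FALSE
  )
}

#' Classification accuracy and confusion counts
#'
#' @param pred,truth label vectors (`"normal"`/`"coa"`) of equal length.
#' @return list with `accuracy` (correct / total), `n`, `errors`, and the
#'   2 x 2 `confusion` table (rows = truth, columns = prediction).
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  if (length(pred) < 1L) stop("need at least one record")
  pred <- as.character(pred)
  truth <- as.character(truth)
  lev <- c("normal", "coa")
  conf <- table(
    truth = factor(truth, levels = lev),
    predicted = factor(pred, levels = lev)
  )
  list(
    accuracy = mean(pred == truth),
    n = length(pred),
    errors = sum(pred != truth),
    confusion = conf
  )
}

# Printed coefficient tables of the three published classifiers. The
# morphometric table prints five slope-like coefficients and no intercept;
# its mapping (and the free intercept) is therefore explicit configuration
# rather than a silent guess. The metamodel table prints the same value
# (-1.05) for all three velocity coefficients, which looks like a
# typesetting artifact; it is shipped verbatim and flagged here.
published_classifier_tables <- function() {
  list(
    morpho = list(
      features = c("D1", "DBCA", "D3", "D0", "D5"),
      coefficients = c(-0.399, 0.999, 0.11, -1.726, 1.134)
    ),
    hemo = list(
      features = c("v_OBCA", "v_M3", "v_O5", "p_P1", "p_M1"),
      coefficients = c(1.377, -1.472, -1.914, 0.482, 0.414)
    ),
    meta = list(
      features = c("v_OBCA", "v_M3", "v_O5", "p_P1", "p_M1"),
      coefficients = c(-1.05, -1.05, -1.05, 1.138, 0.799)
    )
  )
}

#' Published logistic classifiers
#'
#' The three printed coefficient sets: `"morpho"` (five landmark
#' diameters), `"hemo"` (landmark velocities and pressures) and `"meta"`
#' (the same features, surrogate-predicted). None of the printed tables
#' documents an intercept, so the intercept is exposed as configuration
#' (default 0); the feature mapping follows the table column names. The
#' metamodel table's three identical velocity coefficients are shipped
#' verbatim (suspected typesetting artifact in the source table).
#'
#' @param which `"morpho"`, `"hemo"` or `"meta"`.
#' @param intercept intercept to use (default 0; not printed in the tables).
#' @param threshold classification threshold (default 0.5).
#' @param features optional feature-name override (same length as the
#'   table's coefficient list) if your column naming differs.
#' @return a `logistic_classifier` in `"published"` mode operating on raw
#'   (unstandardized) features.
#' @export
published_classifier <- function(which = c("morpho", "hemo", "meta"),
                                 intercept = 0, threshold = 0.5,
                                 features = NULL) {
  which <- match.arg(which)
  tab <- published_classifier_tables()[[which]]
  if (is.null(features)) features <- tab$features
  stopifnot(length(features) == length(tab$coefficients))
  new_logistic_classifier(
    features = features, coefficients = tab$coefficients,
    intercept = intercept, threshold = threshold, mode = "published"
  )
}
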