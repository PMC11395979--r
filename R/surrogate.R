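# Term language for surrogate regressions. A term is one of
#   "D1"           a diameter entered linearly (mm)
#   "D1/DBCA^2"    a squared-diameter ratio feature (1/mm)
#   "p_hat_P1"     the chained predicted inlet pressure (kPa)
# Ratio features arise from the flow-balance (continuity) view of the arch:
# velocity scales as upstream flow over the squared local diameter.
parse_term <- function(term) {
  if (term == "p_hat_P1") return(list(type = "phat"))
  if (grepl("^[A-Z0-9]+/[A-Z0-9]+\\^2$", term)) {
    parts <- strsplit(sub("\\^2$", "", term), "/")[[1]]
    return(list(type = "ratio", num = parts[1], den = parts[2]))
  }
  if (term %in% DIAMETERS) return(list(type = "linear", var = term))
  stop("unknown term: ", term)
}

#' Build surrogate regression features from morphometry
#'
#' Evaluates a term list on one or more morphometric profiles: linear
#' diameter terms pass through, ratio terms `Di/Dj^2` divide one diameter by
#' the square of another, and the `p_hat_P1` term injects the chained
#' predicted inlet pressure. Column order follows the term list.
#'
#' @param m named numeric vector of the nine diameters, or a data frame of
#'   profiles (one row per record).
#' @param terms character vector of terms, e.g.
#'   `c("D1/DBCA^2", "D0/DBCA^2", "D4/DBCA^2", "p_hat_P1")`.
#' @param p_hat_P1 numeric vector of predicted inlet pressures (kPa),
#'   required when `"p_hat_P1"` is among the terms.
#' @return numeric matrix, one row per record, columns named by term.
#' @export
build_features <- function(m, terms, p_hat_P1 = NULL) {
  if (!is.data.frame(m)) m <- as.data.frame(as.list(m))
  n <- nrow(m)
  out <- matrix(NA_real_, n, length(terms), dimnames = list(NULL, terms))
  for (j in seq_along(terms)) {
    t <- parse_term(terms[j])
    out[, j] <- switch(t$type,
      linear = m[[t$var]],
      ratio = {
        den <- m[[t$den]]
        if (any(den == 0)) stop("zero denominator diameter: ", t$den)
        m[[t$num]] / den^2
      },
      phat = {
        if (is.null(p_hat_P1)) stop("term p_hat_P1 requires `p_hat_P1`")
        stopifnot(length(p_hat_P1) %in% c(1L, n))
        rep_len(p_hat_P1, n)
      }
    )
  }
  out
}

new_surrogate_model <- function(response, terms, coefficients, intercept,
                                r_squared = NA_real_, p_level = NA_real_,
                                n = NA_integer_, mode = "published",
                                vcov = NULL, sigma = NA_real_) {
  stopifnot(length(coefficients) == length(terms))
  structure(list(
    response = response, terms = terms,
    coefficients = stats::setNames(as.numeric(coefficients), terms),
    intercept = intercept,
    r_squared = r_squared, p_level = p_level, n = n, mode = mode,
    vcov = vcov, sigma = sigma
  ), class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("surrogate_model for %s (%s mode)\n", x$response, x$mode))
  cat(sprintf("  intercept %.4g; terms: %s\n", x$intercept,
              paste(sprintf("%s (%.4g)", x$terms, x$coefficients),
                    collapse = ", ")))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f, model p-level = %.3g, n = %d\n",
                x$r_squared, x$p_level, x$n))
  }
  invisible(x)
}

#' Published surrogate regression models
#'
#' The five printed regressions relating landmark hemodynamics to
#' morphometry: inlet and pre-stenotic pressures as linear functions of
#' diameters, and the three landmark velocities as functions of
#' squared-diameter ratio features plus the chained predicted inlet
#' pressure. Coefficients, R-squared and model p-levels are the printed
#' values; they make the models executable even though the patient data
#' behind them are unavailable.
#'
#' @return named list of `surrogate_model` objects:
#'   `p_P1`, `p_M2` (kPa), `v_OBCA`, `v_M4`, `v_O5` (m/s).
#' @export
published_surrogates <- function() {
  list(
    p_P1 = new_surrogate_model(
      "p_P1", c("D1", "DBCA", "D0", "D5"),
      c(0.34, -0.29, -0.55, 0.79), 11.14,
      r_squared = 0.224, p_level = 0.00839, n = 60L
    ),
    p_M2 = new_surrogate_model(
      "p_M2", c("D2", "DBCA", "D0", "D5"),
      c(0.45, -0.27, -0.53, 0.47), 11.2,
      r_squared = 0.255, p_level = 0.00319, n = 60L
    ),
    v_OBCA = new_surrogate_model(
      "v_OBCA", c("D1/DBCA^2", "D0/DBCA^2", "D4/DBCA^2", "p_hat_P1"),
      c(0.07, -0.27, 0.1, 0.17), -0.42,
      r_squared = 0.23, p_level = 0.00695, n = 60L
    ),
    v_M4 = new_surrogate_model(
      "v_M4", c("D1/D4^2", "DBCA/D4^2", "DLCCA/D4^2", "D3/D4^2", "p_hat_P1"),
      c(0.39, -0.87, -2.17, 0.58, -0.04), 1.67,
      r_squared = 0.421, p_level = 0.00002, n = 60L
    ),
    v_O5 = new_surrogate_model(
      "v_O5", c("D1/D5^2", "DBCA/D5^2", "DLCCA/D5^2", "D3/D5^2", "p_hat_P1"),
      c(0.29, -0.87, -1.25, 0.75, -0.06), 1.7,
      r_squared = 0.521, p_level = 1e-05, n = 60L
    )
  )
}

# Linear evaluation of a surrogate model on profiles.
evaluate_linear_terms <- function(model, m, p_hat_P1 = NULL) {
  X <- build_features(m, model$terms, p_hat_P1 = p_hat_P1)
  drop(model$intercept + X %*% model$coefficients)
}

#' Fit a linear surrogate regression by least squares
#'
#' Ordinary least squares through a QR (orthogonal) decomposition, with the
#' usual diagnostics: coefficient estimates, `R^2 = 1 - SSR/SST`, and a
#' single model p-level from the overall F statistic against the
#' intercept-only model.
#'
#' @param X feature matrix or data frame (one column per term; no intercept
#'   column — it is added internally).
#' @param y numeric response vector.
#' @param response name of the response (for the returned model object).
#' @return a `surrogate_model` in `"fitted"` mode, carrying the coefficient
#'   covariance matrix and residual sd for interval construction.
#' @export
fit_linear <- function(X, y, response = "y") {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), nrow(X) == length(y))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[(qrx$rank + 1L):ncol(Xi)]]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  df2 <- n - p - 1L
  if (sst > 0 && ssr > 1e-300) {
    fstat <- ((sst - ssr) / p) / (ssr / df2)
    p_level <- stats::pf(fstat, p, df2, lower.tail = FALSE)
  } else {
    p_level <- if (sst > 0) 0 else NA_real_
  }
  sigma2 <- ssr / df2
  xtx_inv <- chol2inv(qr.R(qrx))
  dimnames(xtx_inv) <- list(colnames(Xi), colnames(Xi))
  new_surrogate_model(
    response, colnames(X), beta[-1L], beta[[1L]],
    r_squared = r2, p_level = p_level, n = n, mode = "fitted",
    vcov = sigma2 * xtx_inv, sigma = sqrt(sigma2)
  )
}

# 95% (default) confidence intervals for intercept + coefficients of a
# fitted surrogate model.
surrogate_confint <- function(model, level = 0.95) {
  stopifnot(model$mode == "fitted", !is.null(model$vcov))
  est <- c(`(Intercept)` = model$intercept, model$coefficients)
  se <- sqrt(diag(model$vcov))
  tq <- stats::qt(1 - (1 - level) / 2, model$n - length(est))
  cbind(lower = est - tq * se, upper = est + tq * se)
}

#' Canonical surrogate term lists
#'
#' The model forms of the five surrogate regressions (same terms as
#' [published_surrogates()]), used when refitting them to a cohort.
#'
#' @return named list of character term vectors.
#' @export
surrogate_forms <- function() {
  lapply(published_surrogates(), function(m) m$terms)
}

#' Fit the chained surrogate regressions to a cohort
#'
#' Reproduces the chained construction: the inlet-pressure model is fitted
#' first, its in-sample predictions are injected as the `p_hat_P1` regressor
#' of the three velocity models, and the pre-stenotic pressure model is
#' fitted independently.
#'
#' @param cohort data frame holding the nine diameters and the response
#'   columns `p_P1`, `p_M2`, `v_OBCA`, `v_M4`, `v_O5` (typically a training
#'   split of [simulate_cohort()] output).
#' @param forms named list of term vectors, default [surrogate_forms()].
#' @return named list of fitted `surrogate_model` objects.
#' @export
fit_surrogates <- function(cohort, forms = surrogate_forms()) {
  needed <- c("p_P1", "p_M2", "v_OBCA", "v_M4", "v_O5")
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) stop("cohort lacks response columns: ",
                         paste(miss, collapse = ", "))
  models <- list()
  models$p_P1 <- fit_linear(
    build_features(cohort, forms$p_P1), cohort$p_P1, "p_P1"
  )
  p_hat <- evaluate_linear_terms(models$p_P1, cohort)
  models$p_M2 <- fit_linear(
    build_features(cohort, forms$p_M2), cohort$p_M2, "p_M2"
  )
  for (resp in c("v_OBCA", "v_M4", "v_O5")) {
    models[[resp]] <- fit_linear(
      build_features(cohort, forms[[resp]], p_hat_P1 = p_hat),
      cohort[[resp]], resp
    )
  }
  models
}

#' Predict landmark pressures from morphometry
#'
#' Linear evaluation of the inlet (`p_P1`) or pre-stenotic (`p_M2`) pressure
#' surrogate; the two models differ only in using D1 versus D2, matching the
#' aortic segment where each pressure lives.
#'
#' @param m profile vector or data frame of profiles.
#' @param models list of surrogate models ([published_surrogates()] by
#'   default, or a [fit_surrogates()] result).
#' @return predicted pressure(s), kPa.
#' @export
predict_pressure_P1 <- function(m, models = published_surrogates()) {
  evaluate_linear_terms(models$p_P1, m)
}

#' @rdname predict_pressure_P1
#' @export
predict_pressure_M2 <- function(m, models = published_surrogates()) {
  evaluate_linear_terms(models$p_M2, m)
}

#' Predict a landmark velocity from morphometry
#'
#' Evaluates one of the three velocity surrogates. The chained predicted
#' inlet pressure must be supplied (it is a regressor of every velocity
#' model).
#'
#' @param m profile vector or data frame of profiles.
#' @param which `"OBCA"`, `"M4"` or `"O5"`.
#' @param p_hat_P1 predicted inlet pressure(s), kPa.
#' @param models list of surrogate models.
#' @return predicted velocity (m/s).
#' @export
predict_velocity <- function(m, which = c("OBCA", "M4", "O5"), p_hat_P1,
                             models = published_surrogates()) {
  which <- match.arg(which)
  evaluate_linear_terms(models[[paste0("v_", which)]], m, p_hat_P1 = p_hat_P1)
}

#' Chained surrogate prediction of the canonical hemodynamic subset
#'
#' Evaluates the inlet-pressure model first and feeds its prediction into
#' the three velocity models; the pre-stenotic pressure model is evaluated
#' independently.
#'
#' @param m profile vector or data frame of profiles.
#' @param models list of surrogate models (published or fitted; do not mix).
#' @return data frame with columns `p_P1`, `p_M2`, `v_OBCA`, `v_M4`, `v_O5`.
#' @export
chain_predict <- function(m, models = published_surrogates()) {
  p_hat <- predict_pressure_P1(m, models)
  data.frame(
    p_P1 = p_hat,
    p_M2 = predict_pressure_M2(m, models),
    v_OBCA = predict_velocity(m, "OBCA", p_hat, models),
    v_M4 = predict_velocity(m, "M4", p_hat, models),
    v_O5 = predict_velocity(m, "O5", p_hat, models)
  )
}

#' Correlation between observed and surrogate-predicted hemodynamics
#'
#' Pearson correlation per hemodynamic feature between observed values and
#' surrogate predictions — the standard adequacy report for a metamodel.
#'
#' @param observed,predicted data frames with matching hemodynamic columns,
#'   paired by row.
#' @return data frame with columns `feature` and `r`, with attribute `best`
#'   naming the most accurately predicted feature.
#' @export
correlation_report <- function(observed, predicted) {
  common <- intersect(names(observed), names(predicted))
  common <- common[vapply(common, function(k) is.numeric(observed[[k]]),
                          logical(1))]
  if (length(common) == 0L) stop("no shared hemodynamic columns")
  if (nrow(observed) != nrow(predicted)) stop("unpaired records")
  if (nrow(observed) < 3L) stop("need at least 3 paired records")
  r <- vapply(common, function(k) {
    if (stats::sd(observed[[k]]) == 0 || stats::sd(predicted[[k]]) == 0) {
      return(NA_real_)
    }
    stats::cor(observed[[k]], predicted[[k]])
  }, numeric(1))
  out <- data.frame(feature = common, r = unname(r), row.names = NULL)
  ok <- !is.na(out$r)
  attr(out, "best") <- if (any(ok)) out$feature[ok][which.max(out$r[ok])] else NA
  out
}
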