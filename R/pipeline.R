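# Short stable hash of an R object (FNV-1a over its serialization),
# used to stamp outputs with the configuration they came from.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Default feature sets. The hemodynamic set is the surrogate-predictable
# quintet, so the direct and metamodel classifiers are compared on
# identical features; the literal published-equation set
# (v_OBCA, v_M3, v_O5, p_P1, p_M1) remains available via `hemo_features`.
MORPHO_FEATURES <- c("D1", "DBCA", "D3", "D0", "D5")
HEMO_FEATURES_PREDICTABLE <- c("v_OBCA", "v_M4", "v_O5", "p_P1", "p_M2")
HEMO_FEATURES_ALL <- c(paste0("v_", LANDMARKS), paste0("p_", LANDMARKS))

#' Run the full morphometry-to-classification pipeline
#'
#' End-to-end protocol on a labelled cohort: (1) one stratified 80:20
#' split; (2) surrogate regressions fitted on the training set only;
#' (3) chained surrogate prediction for every record; (4) three logistic
#' classifiers fitted on the training set — morphometric (five diameters),
#' hemodynamic (observed features) and metamodel (surrogate-predicted
#' features); (5) all three evaluated on the identical test set, plus a
#' correlation report of observed versus predicted hemodynamics.
#'
#' The hemodynamic and metamodel classifiers use the same feature names so
#' their accuracies are directly comparable; by default these are the five
#' surrogate-predictable features. Setting `all_features = TRUE` swaps the
#' hemodynamic classifier's features for the complete 18-landmark set (an
#' ablation that typically does worse).
#'
#' @param cohort data frame from [simulate_cohort()] (or the same schema).
#' @param seed integer seed controlling the split.
#' @param hemo_features feature names for the hemodynamic and metamodel
#'   classifiers (default the surrogate-predictable set).
#' @param morpho_features diameter features for the morphometric
#'   classifier.
#' @param all_features use every landmark velocity and pressure in the
#'   hemodynamic classifier (ablation mode).
#' @param standardize z-score classifier features (default TRUE).
#' @return object of class `"pipeline_result"`: split plan, fitted
#'   surrogates, three classifiers, per-classifier accuracy objects,
#'   misclassified ids, correlation report and provenance.
#' @export
run_pipeline <- function(cohort, seed = 1L,
                         hemo_features = HEMO_FEATURES_PREDICTABLE,
                         morpho_features = MORPHO_FEATURES,
                         all_features = FALSE,
                         standardize = TRUE) {
  stopifnot(all(DIAMETERS %in% names(cohort)), "label" %in% names(cohort))
  config <- list(
    seed = as.integer(seed), hemo_features = hemo_features,
    morpho_features = morpho_features, all_features = all_features,
    standardize = standardize
  )
  plan <- split_80_20(cohort, seed)
  train <- cohort[plan$train, ]
  test <- cohort[plan$test, ]

  surrogates <- fit_surrogates(train)
  predicted <- chain_predict(cohort, surrogates)

  direct_features <- if (all_features) HEMO_FEATURES_ALL else hemo_features
  meta_features <- intersect(hemo_features, names(predicted))
  if (length(meta_features) < length(hemo_features)) {
    stop("hemo_features outside the surrogate-predictable set: ",
         paste(setdiff(hemo_features, names(predicted)), collapse = ", "),
         " (metamodel features must be predictable)")
  }

  clf_morpho <- fit_logistic(train[, morpho_features], train$label,
                             standardize = standardize)
  clf_hemo <- fit_logistic(train[, direct_features], train$label,
                           standardize = standardize)
  clf_meta <- fit_logistic(predicted[plan$train, meta_features], train$label,
                           standardize = standardize)

  pred_morpho <- classify(clf_morpho, test)
  pred_hemo <- classify(clf_hemo, test)
  pred_meta <- classify(clf_meta, predicted[plan$test, ])

  acc <- list(
    morpho = accuracy(pred_morpho$label, test$label),
    hemo = accuracy(pred_hemo$label, test$label),
    meta = accuracy(pred_meta$label, test$label)
  )
  mis <- list(
    morpho = test$patient_id[pred_morpho$label != test$label],
    hemo = test$patient_id[pred_hemo$label != test$label],
    meta = test$patient_id[pred_meta$label != test$label]
  )
  correlations <- correlation_report(
    cohort[, names(predicted)], predicted
  )

  structure(list(
    plan = plan,
    surrogates = surrogates,
    classifiers = list(morpho = clf_morpho, hemo = clf_hemo, meta = clf_meta),
    accuracy = acc,
    misclassified = mis,
    predictions = list(morpho = pred_morpho, hemo = pred_hemo,
                       meta = pred_meta),
    predicted_hemodynamics = predicted,
    correlations = correlations,
    provenance = list(seed = as.integer(seed), config = config,
                      config_hash = config_hash(config),
                      n = nrow(cohort))
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result (n = %d, seed = %d, config %s)\n",
    x$provenance$n, x$provenance$seed, x$provenance$config_hash
  ))
  cat(sprintf(
    "  test accuracy: morphometric %.2f | hemodynamic %.2f | metamodel %.2f\n",
    x$accuracy$morpho$accuracy, x$accuracy$hemo$accuracy,
    x$accuracy$meta$accuracy
  ))
  invisible(x)
}

#' Summarise a pipeline result
#'
#' Tabulates the three test accuracies with confusion counts, the
#' misclassified patient ids, and the observed-versus-predicted correlation
#' per hemodynamic feature, as a plain list that serialises losslessly to
#' JSON.
#'
#' @param res a [run_pipeline()] result.
#' @return list with elements `accuracies`, `confusion`, `misclassified`,
#'   `correlations` and `provenance`.
#' @export
compare_report <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  list(
    accuracies = lapply(res$accuracy, function(a) a$accuracy),
    test_n = res$accuracy$morpho$n,
    confusion = lapply(res$accuracy, function(a) {
      m <- as.matrix(a$confusion)
      list(dimnames = dimnames(m), counts = unclass(m))
    }),
    misclassified = res$misclassified,
    correlations = stats::setNames(
      as.list(res$correlations$r), res$correlations$feature
    ),
    provenance = res$provenance[c("seed", "config_hash", "n")]
  )
}
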