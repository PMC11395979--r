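# Canonical cohort CSV column order.
cohort_schema <- function() {
  c("patient_id", "label", DIAMETERS,
    paste0("v_", LANDMARKS), paste0("p_", LANDMARKS))
}

#' Read and write cohort CSV files
#'
#' The cohort schema is `patient_id`, `label`, the nine diameters (mm),
#' then the nine landmark velocities (m/s) and nine pressures (kPa).
#' Hemodynamic columns are optional on read — a morphometry-only file loads
#' with `has_hemodynamics = FALSE` and still supports the morphometric
#' classifier. Unknown columns are preserved; writing uses the canonical
#' column order (then any extras) so identical cohorts give byte-identical
#' files.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()`: data frame with attribute
#'   `has_hemodynamics`. `write_cohort_csv()`: `path`, invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("patient_id", "label", DIAMETERS)
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("cohort CSV lacks mandatory column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$label), c("normal", "coa"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  hemo <- c(paste0("v_", LANDMARKS), paste0("p_", LANDMARKS))
  attr(df, "has_hemodynamics") <- all(hemo %in% names(df))
  df
}

#' @rdname read_cohort_csv
#' @param cohort data frame in the cohort schema (hemodynamic columns
#'   optional).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  first <- intersect(cohort_schema(), names(cohort))
  rest <- setdiff(names(cohort), first)
  utils::write.csv(cohort[, c(first, rest), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON (by extension). Recognised fields:
#' `n_per_class`, `seed`, `hemo_model`, `noise_sd_v`, `noise_sd_p`,
#' `flow_split` (named list over BCA/LCCA/LSCA/O5), `v_inlet_mean`,
#' `v_inlet_sd`, `p_base`, `friction`, `loss_coeff`, `backup_frac`,
#' `redistribution`, `diameter_params` (per-class named mean/sd lists),
#' plus pipeline fields `hemo_features`, `all_features`, `standardize`.
#' Everything is validated before any stage runs; unknown fields are an
#' error.
#'
#' @param path YAML or JSON file.
#' @return list with a validated `cohort` ([cohort_config()]) element and
#'   the pipeline fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort_fields <- c(
    "n_per_class", "seed", "hemo_model", "noise_sd_v", "noise_sd_p",
    "flow_split", "v_inlet_mean", "v_inlet_sd", "p_base", "friction",
    "loss_coeff", "backup_frac", "redistribution", "diameter_params"
  )
  pipeline_fields <- c("hemo_features", "all_features", "standardize")
  unknown <- setdiff(names(raw), c(cohort_fields, pipeline_fields))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw[intersect(names(raw), cohort_fields)]
  if (!is.null(args$flow_split)) args$flow_split <- unlist(args$flow_split)
  if (!is.null(args$diameter_params)) {
    args$diameter_params <- lapply(args$diameter_params, function(cls) {
      list(mean = unlist(cls$mean), sd = unlist(cls$sd))
    })
  }
  cfg <- do.call(cohort_config, args)
  pl <- raw[intersect(names(raw), pipeline_fields)]
  if (!is.null(pl$hemo_features)) pl$hemo_features <- unlist(pl$hemo_features)
  c(list(cohort = cfg), pl)
}
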