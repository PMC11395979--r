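DIAMETERS <- c("D1", "D2", "D3", "D0", "D4", "D5", "DBCA", "DLCCA", "DLSCA")

# Class-conditional diameter distributions (mm) for the synthetic cohort.
# NOT patient-derived: these are the package's stylised study conditions,
# chosen once to reproduce the qualitative class structure of infant
# thoracic aortas — in coarctation, D0 (and with it D3, D1) shifts down,
# with D0 both smaller and tighter; DBCA and D5 shift up, DBCA with more
# spread; the remaining diameters barely differ between classes.
default_diameter_params <- function() {
  list(
    normal = list(
      mean = c(D1 = 10.4, D2 = 9.6, D3 = 8.6, D0 = 7.7, D4 = 9.0, D5 = 6.9,
               DBCA = 4.6, DLCCA = 3.3, DLSCA = 3.6),
      sd = c(D1 = 1.15, D2 = 1.05, D3 = 0.95, D0 = 0.85, D4 = 1.05, D5 = 0.85,
             DBCA = 0.55, DLCCA = 0.45, DLSCA = 0.50)
    ),
    coa = list(
      mean = c(D1 = 9.2, D2 = 9.4, D3 = 6.8, D0 = 2.9, D4 = 9.3, D5 = 7.6,
               DBCA = 5.6, DLCCA = 3.4, DLSCA = 3.7),
      sd = c(D1 = 1.10, D2 = 1.05, D3 = 0.95, D0 = 0.50, D4 = 1.15, D5 = 0.90,
             DBCA = 0.95, DLCCA = 0.50, DLSCA = 0.55)
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the generator: sample size, class-conditional
#' diameter distributions, the flow-balance forward model's parameters, and
#' the additive Gaussian noise standard deviations for the hemodynamic
#' responses. The defaults are stylised study conditions, not patient data.
#'
#' @param n_per_class records per class (normal, coa); default 30.
#' @param diameter_params list with elements `normal` and `coa`, each with
#'   named `mean` and `sd` vectors over the nine diameters (mm).
#' @param flow_split named fractions of inlet flow routed to the four
#'   outlets (`BCA`, `LCCA`, `LSCA`, `O5`); must sum to 1. These are the
#'   baseline (unobstructed) fractions; a coarctation shifts flow from the
#'   descending outlet to the branches via `redistribution`.
#' @param v_inlet_mean,v_inlet_sd inlet velocity distribution, m/s.
#' @param p_base baseline inlet pressure, kPa.
#' @param friction per-station frictional pressure drop, kPa.
#' @param loss_coeff stenosis pressure-loss coefficient: the loss between
#'   the stations bracketing the narrowing is
#'   `loss_coeff * ((D3/D0)^4 - 1) * v_P1^2` kPa.
#' @param backup_frac fraction of the stenosis loss reflected as elevated
#'   inlet pressure (proximal hypertension).
#' @param redistribution strength of flow redirection away from the
#'   descending outlet as the stenosis tightens.
#' @param noise_sd_v,noise_sd_p additive Gaussian noise sd applied last to
#'   every velocity (m/s) and pressure (kPa) response.
#' @param hemo_model `"balance"` (mass-balance forward model, default) or
#'   `"equations"` (the five canonical responses generated from the
#'   published regression forms plus noise — the ground truth used by
#'   identifiability and coverage studies).
#' @param seed integer seed; identical seed and config give an identical
#'   cohort.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_class = 30,
                          diameter_params = default_diameter_params(),
                          flow_split = c(BCA = 0.16, LCCA = 0.07,
                                         LSCA = 0.08, O5 = 0.69),
                          v_inlet_mean = 0.75, v_inlet_sd = 0.30,
                          p_base = 12.8, friction = 0.06,
                          loss_coeff = 0.15, backup_frac = 0.6,
                          redistribution = 0.2,
                          noise_sd_v = 0.25, noise_sd_p = 0.8,
                          hemo_model = c("balance", "equations"),
                          seed = 1L) {
  hemo_model <- match.arg(hemo_model)
  stopifnot(
    n_per_class >= 1,
    abs(sum(flow_split) - 1) < 1e-8, all(flow_split > 0),
    identical(sort(names(flow_split)), sort(c("BCA", "LCCA", "LSCA", "O5"))),
    v_inlet_sd >= 0, noise_sd_v >= 0, noise_sd_p >= 0,
    friction >= 0, loss_coeff >= 0,
    backup_frac >= 0, backup_frac <= 1
  )
  for (cls in c("normal", "coa")) {
    p <- diameter_params[[cls]]
    if (!all(DIAMETERS %in% names(p$mean)) || !all(DIAMETERS %in% names(p$sd))) {
      stop("diameter_params$", cls, " must name all of: ",
           paste(DIAMETERS, collapse = ", "))
    }
    stopifnot(all(p$mean > 0), all(p$sd >= 0))
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    diameter_params = diameter_params,
    flow_split = flow_split[c("BCA", "LCCA", "LSCA", "O5")],
    v_inlet_mean = v_inlet_mean, v_inlet_sd = v_inlet_sd,
    p_base = p_base, friction = friction,
    loss_coeff = loss_coeff, backup_frac = backup_frac,
    redistribution = redistribution,
    noise_sd_v = noise_sd_v, noise_sd_p = noise_sd_p,
    hemo_model = hemo_model,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Deterministic sub-seed for a named pipeline stage, so stages are
# reproducible independently of execution order. Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

# One truncated-normal draw on (lower, upper); rejection with a capped
# number of attempts, as the tails involved here are never extreme.
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf,
                        what = "value", max_attempts = 100L) {
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      stop("degenerate draw for ", what, ": mean ", mean,
           " outside (", lower, ", ", upper, ")")
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_attempts)) {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok) {
      if (is.finite(upper)) { out[i] <- upper; next }  # boundary mass
      stop("no positive draw for ", what, " after ", max_attempts,
           " rejection attempts (mean ", mean, ", sd ", sd, ")")
    }
  }
  out
}

#' Sample class-conditional landmark morphometry
#'
#' Draws one morphometric profile per synthetic patient from truncated
#' normal distributions (truncated at zero). Within each record the
#' narrowest descending diameter is constrained to its definition,
#' `D0 <= min(D3, D4)`, by upper truncation of the D0 draw.
#'
#' @param cfg a [cohort_config()].
#' @return data frame with `patient_id`, `label` and the nine diameter
#'   columns (mm), `2 * n_per_class` rows (normal first).
#' @export
sample_morphometry <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(stage_seed(cfg$seed, "morphometry"))
  rows <- list()
  id <- 0L
  for (cls in c("normal", "coa")) {
    p <- cfg$diameter_params[[cls]]
    for (i in seq_len(cfg$n_per_class)) {
      id <- id + 1L
      d <- numeric(length(DIAMETERS))
      names(d) <- DIAMETERS
      for (nm in setdiff(DIAMETERS, "D0")) {
        d[nm] <- rtrunc_norm(1, p$mean[[nm]], p$sd[[nm]], lower = 0, what = nm)
      }
      d["D0"] <- rtrunc_norm(1, p$mean[["D0"]], p$sd[["D0"]],
                             lower = 0, upper = min(d["D3"], d["D4"]),
                             what = "D0")
      rows[[id]] <- data.frame(
        patient_id = sprintf("S%03d", id), label = cls, t(d)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward hemodynamics from one morphometric profile
#'
#' The flow-balance forward model: an inlet velocity is drawn, volumetric
#' flow (as velocity times squared diameter) is split over the four outlets
#' — with a fraction redirected from the descending outlet to the branches
#' as the stenosis severity `(D3/D0)^4` grows — and outlet velocities follow
#' from continuity, which therefore holds exactly before noise. Pressures
#' decrease from the inlet by a small per-station friction drop plus a
#' stenosis loss concentrated between the M3 and M4 stations and growing as
#' `(D3/D0)^4`; part of that loss backs up as elevated inlet pressure.
#' Independent Gaussian noise is added last; velocities are reported in m/s,
#' pressures in kPa.
#'
#' In `hemo_model = "equations"` mode the five canonical responses
#' (`p_P1`, `p_M2`, `v_OBCA`, `v_M4`, `v_O5`) are replaced by the published
#' regression forms evaluated on the profile plus noise, giving data whose
#' generating process is exactly the surrogate model family.
#'
#' @param m named numeric vector (or one-row data frame) with the nine
#'   diameters, mm; all must be positive (`D0 = 0` would mean infinite
#'   stenosis loss and is an error).
#' @param cfg a [cohort_config()]. The RNG is used as-is; seed management
#'   belongs to [simulate_cohort()].
#' @return named numeric vector with `v_*` (m/s) and `p_*` (kPa) at the
#'   nine landmarks.
#' @export
forward_hemodynamics <- function(m, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.data.frame(m)) m <- unlist(m[1, DIAMETERS])
  m <- m[DIAMETERS]
  if (any(!is.finite(m)) || any(m < 0)) stop("diameters must be positive")
  if (m[["D0"]] <= 0) stop("D0 = 0: stenosis loss is infinite")
  if (any(m == 0)) stop("diameters must be positive")

  v_P1 <- rtrunc_norm(1, cfg$v_inlet_mean, cfg$v_inlet_sd,
                      lower = 0.05, what = "v_P1")
  Q <- v_P1 * m[["D1"]]^2                    # generator units: (m/s) mm^2
  S <- (m[["D3"]] / m[["D0"]])^4             # stenosis severity

  w <- cfg$flow_split
  w[["O5"]] <- w[["O5"]] / (1 + cfg$redistribution * (S - 1))
  w <- w / sum(w)

  v <- c(
    P1 = v_P1,
    OBCA = w[["BCA"]] * Q / m[["DBCA"]]^2,
    OLCCA = w[["LCCA"]] * Q / m[["DLCCA"]]^2,
    OLSCA = w[["LSCA"]] * Q / m[["DLSCA"]]^2,
    M1 = Q / m[["D2"]]^2,
    M2 = w[["O5"]] * Q / m[["D3"]]^2,
    M3 = w[["O5"]] * Q / m[["D4"]]^2,
    M4 = w[["O5"]] * Q / m[["D5"]]^2,
    O5 = w[["O5"]] * Q / m[["D5"]]^2
  )

  dp_sten <- cfg$loss_coeff * (S - 1) * v_P1^2
  f <- cfg$friction
  p_P1 <- cfg$p_base + cfg$backup_frac * dp_sten
  p_M1 <- p_P1 - f
  p_M2 <- p_M1 - f
  p_M3 <- p_M2 - f
  p_M4 <- p_M3 - f - dp_sten
  p <- c(
    P1 = p_P1,
    OBCA = p_M1 - f,
    OLCCA = p_M2 - f,
    OLSCA = p_M2 - f,
    M1 = p_M1, M2 = p_M2, M3 = p_M3, M4 = p_M4,
    O5 = p_M4 - f
  )

  if (cfg$hemo_model == "equations") {
    eq <- published_surrogates()
    p_hat <- evaluate_linear_terms(eq$p_P1, m, p_hat_P1 = NA)
    p[["P1"]] <- p_hat
    p[["M2"]] <- evaluate_linear_terms(eq$p_M2, m, p_hat_P1 = NA)
    v[["OBCA"]] <- evaluate_linear_terms(eq$v_OBCA, m, p_hat_P1 = p_hat)
    v[["M4"]] <- evaluate_linear_terms(eq$v_M4, m, p_hat_P1 = p_hat)
    v[["O5"]] <- evaluate_linear_terms(eq$v_O5, m, p_hat_P1 = p_hat)
  }

  if (cfg$noise_sd_v > 0) {
    v <- v + stats::rnorm(length(v), 0, cfg$noise_sd_v)
    # physical (balance) records cannot carry negative speeds; the
    # equations fixture must stay exactly within the linear model family
    if (cfg$hemo_model == "balance") v <- pmax(v, 0)
  }
  if (cfg$noise_sd_p > 0) p <- p + stats::rnorm(length(p), 0, cfg$noise_sd_p)

  names(v) <- paste0("v_", names(v))
  names(p) <- paste0("p_", names(p))
  c(v, p)
}

#' Simulate a complete synthetic cohort
#'
#' Class-conditional morphometry ([sample_morphometry()]) followed by the
#' forward hemodynamic model ([forward_hemodynamics()]) for every record.
#' Fully reproducible: the configuration seed is expanded into per-stage
#' substreams, so the same seed and config give a byte-identical cohort.
#'
#' @param cfg a [cohort_config()].
#' @return data frame in the cohort schema: `patient_id`, `label`, the nine
#'   diameters (mm), then `v_*` (m/s) and `p_*` (kPa) at the nine landmarks.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  morpho <- sample_morphometry(cfg)
  set.seed(stage_seed(cfg$seed, "hemodynamics"))
  hemo <- t(vapply(
    seq_len(nrow(morpho)),
    function(i) forward_hemodynamics(unlist(morpho[i, DIAMETERS]), cfg),
    numeric(18)
  ))
  cbind(morpho, as.data.frame(hemo))
}
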