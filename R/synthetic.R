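# Synthetic two-arm DKA cohort generator.
#
# The generator emulates the study conditions the analysis pipeline assumes:
# admission chemistry of an adult DKA cohort, a chloride-rich (GI, Na-Cl
# difference 0) versus chloride non-rich (GII, difference > 32 mmol) fluid
# assignment, a six-hour mass-balance evolution that produces the
# hyperchloremia pattern (GI: higher Cl, lower BE_Cl/pH/PaCO2; similar Na and
# SIG), and an ICU length of stay driven by delta-Cl and delta-lactate.
# The evolution model is a deliberately minimal mass-balance + respiratory
# compensation construction; every constant is exposed in the config.

#' Configuration for the synthetic DKA cohort generator
#'
#' Defaults encode the emulated study conditions: 22 chloride-rich (GI) and
#' 13 chloride non-rich (GII) patients, admission distributions centred on a
#' severe-DKA presentation (pH 7.10 +/- 0.10, PaCO2 ~16 mmHg, Cl 106 mmol/L,
#' strong ion gap ~19 mmol/L), a fluid menu of 0.9\% saline for GI and
#' craftwork/Isolyte/Isolyte-S for GII calibrated to a median regimen Na-Cl
#' difference of ~144 mmol (range 95-263), and an LOS model
#' `LOS = 2.0 + 0.2 * delta_Cl + 0.3 * delta_lactate + N(0, 0.5)` floored at
#' one day.
#'
#' @param n_gi,n_gii Patients per arm (>= 2 each).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param admission Named list of admission distribution parameters (means,
#'   sds, log-scale parameters, truncation bounds, ketone probabilities, and
#'   the target strong-ion-gap distribution). Partial lists override defaults.
#' @param fluids Named list of regimen parameters (GI saline volume
#'   distribution, co-fluid probabilities, GII fluid menu probabilities and
#'   target Na-Cl difference distribution).
#' @param evolution Named list of six-hour evolution parameters:
#'   `distribution_volume_l_per_kg` (0.2), `retained_fluid_fraction` (0.6),
#'   `excretion_fraction` (0.3, urinary Na/Cl excretion),
#'   `sig_clearance_rate_per_h` (0.12), Winter's respiratory compensation
#'   slope/intercept (1.5, 8) with noise sd 2 mmHg, and the nuisance-chemistry
#'   terms (potassium shift, lactate retention, glucose decline, dilution).
#' @param los Named list: `intercept`, `beta_delta_cl`, `beta_delta_lactate`,
#'   `noise_sd` (days).
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_gi = 22, n_gii = 13, seed = 1,
                                    admission = list(), fluids = list(),
                                    evolution = list(), los = list()) {
  adm <- utils::modifyList(list(
    ph_mean = 7.10, ph_sd = 0.10,
    paco2_mean = 16, paco2_sd = 5, paco2_min = 6, paco2_max = 32,
    na_mean = 134, na_sd = 6,
    k_mean = 4.2, k_sd = 0.8, k_min = 1.8,
    lactate_meanlog = log(2), lactate_sdlog = 0.5,
    lactate_min = 0.4, lactate_max = 12,
    albumin_mean = 38, albumin_sd = 5, albumin_min = 15,
    phosphate_mean = 1.2, phosphate_sd = 0.3, phosphate_min = 0.3,
    ca_mean = 4.6, ca_sd = 0.3, mg_mean = 1.6, mg_sd = 0.2,
    glucose_meanlog = log(450), glucose_sdlog = 0.3,
    glucose_min = 150, glucose_max = 1200,
    hct_mean = 40, hct_sd = 3,
    urea_meanlog = log(58), urea_sdlog = 0.5,
    creatinine_meanlog = log(1.6), creatinine_sdlog = 0.4,
    ketone_probs = c(0.05, 0.10, 0.35, 0.35, 0.15),
    sig_mean = 19, sig_sd = 6, sig_min = 5,
    age_mean = 51, age_sd = 21, age_min = 19, age_max = 95,
    male_prob = 0.42,
    bmi_mean = 25, bmi_sd = 4.5, bmi_min = 16, bmi_max = 45,
    height_mean = 1.70, height_sd = 0.08,
    apache2_mean = 16, apache2_sd = 5, cci_lambda = 3, sofa_lambda = 2.6,
    insulin_meanlog = log(0.08), insulin_sdlog = 0.4,
    urine_meanlog = log(3), urine_sdlog = 0.6,
    max_draw_factor = 10000
  ), admission)
  fl <- utils::modifyList(list(
    gi_saline_mean = 2302, gi_saline_sd = 1188,
    gi_saline_min = 300, gi_saline_max = 6000,
    gi_dextrose_prob = 0.25, gi_halfsaline_prob = 0.20,
    gi_cofluid_min = 250, gi_cofluid_max = 1500,
    gii_fluids = c("craftwork 0.45% NaCl + NaHCO3", "Isolyte", "Isolyte-S"),
    gii_fluid_probs = c(5, 4, 4) / 13,
    gii_diff_meanlog = log(144), gii_diff_sdlog = 0.25,
    gii_diff_min = 95, gii_diff_max = 263,
    gii_saline_prob = 0.30, gii_saline_min = 250, gii_saline_max = 1000,
    nahco3_zero_prob_gi = 0.25, nahco3_mean_gi = 80, nahco3_sd_gi = 70,
    nahco3_max_gi = 350,
    nahco3_zero_prob_gii = 0.20, nahco3_mean_gii = 95, nahco3_sd_gii = 35,
    nahco3_max_gii = 150,
    kcl_zero_prob = 0.70, kcl_min = 5, kcl_max = 75
  ), fluids)
  evo <- utils::modifyList(list(
    distribution_volume_l_per_kg = 0.2,
    retained_fluid_fraction = 0.6,
    excretion_fraction = 0.3,
    sig_clearance_rate_per_h = 0.12,
    winters_slope = 1.5, winters_intercept = 8, winters_noise_sd = 2,
    paco2_floor = 10,
    k_shift = -0.8, k_noise_sd = 0.3, k_floor = 2.0,
    lactate_retention = 0.75, lactate_noise_sdlog = 0.15, lactate_floor = 0.4,
    glucose_decline = 0.4, glucose_noise_sdlog = 0.10, glucose_floor = 100,
    ketone_drop_prob = 0.5
  ), evolution)
  losc <- utils::modifyList(list(
    intercept = 2.0, beta_delta_cl = 0.2, beta_delta_lactate = 0.3,
    noise_sd = 0.5
  ), los)
  if (n_gi < 2 || n_gii < 2)
    stop("synthetic_cohort_config: need at least 2 patients per arm",
         call. = FALSE)
  for (nm in c("retained_fluid_fraction", "excretion_fraction"))
    if (evo[[nm]] < 0 || evo[[nm]] > 1)
      stop("synthetic_cohort_config: `", nm, "` must be in [0, 1]",
           call. = FALSE)
  if (evo$sig_clearance_rate_per_h < 0)
    stop("synthetic_cohort_config: `sig_clearance_rate_per_h` must be >= 0",
         call. = FALSE)
  structure(list(n_gi = n_gi, n_gii = n_gii, seed = seed,
                 admission = adm, fluids = fl, evolution = evo, los = losc),
            class = "synthetic_cohort_config")
}

# truncated normal / lognormal by rejection (bounds are loose, so cheap)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  it <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    it <- it + 1L
    if (it > 10000L)
      stop("rtnorm: truncation bounds infeasible", call. = FALSE)
  }
  out
}

rtlnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  exp(rtnorm(n, meanlog, sdlog, log(max(lower, 1e-12)), log(upper)))
}

#' Draw coherent DKA admission panels
#'
#' Draws pH and PaCO2, sets the measured bicarbonate by Henderson-Hasselbalch
#' (internal coherence), draws the remaining chemistry, and *solves* chloride
#' so that the panel's strong ion gap equals a drawn target
#' (Normal(19, 6) truncated at >= 5 mmol/L by default). Panels are rejected
#' and redrawn until the DKA definition ([is_dka()]) holds, so every emitted
#' panel is a DKA presentation by construction.
#'
#' @param n Number of panels.
#' @param config A [synthetic_cohort_config()]; only `$admission` is used.
#' @param constants An [acid_base_constants()] object.
#' @return Data frame of admission panels (columns as in [strong_ion_gap()]
#'   plus `hco3`, `sbe`, `glucose`, `hct`, `ketones`, `urea`, `creatinine`,
#'   and the drawn `sig_target`).
#' @export
draw_admission_panel <- function(n, config = synthetic_cohort_config(),
                                 constants = acid_base_constants()) {
  a <- config$admission
  accepted <- NULL
  drawn <- 0L
  while (is.null(accepted) || nrow(accepted) < n) {
    m <- max(2L * n, 64L)
    drawn <- drawn + m
    if (drawn > a$max_draw_factor * n)
      stop("draw_admission_panel: config-infeasible (rejection loop ",
           "exceeded ", a$max_draw_factor, " draws per panel)", call. = FALSE)
    cand <- data.frame(
      ph = rtnorm(m, a$ph_mean, a$ph_sd, 6.5, 7.8),
      paco2 = rtnorm(m, a$paco2_mean, a$paco2_sd, a$paco2_min, a$paco2_max),
      na = rtnorm(m, a$na_mean, a$na_sd, 110, 160),
      k = rtnorm(m, a$k_mean, a$k_sd, a$k_min, 8),
      ca = rtnorm(m, a$ca_mean, a$ca_sd, 2, 7),
      mg = rtnorm(m, a$mg_mean, a$mg_sd, 0.5, 4),
      lactate = rtlnorm(m, a$lactate_meanlog, a$lactate_sdlog,
                        a$lactate_min, a$lactate_max),
      albumin = rtnorm(m, a$albumin_mean, a$albumin_sd, a$albumin_min, 60),
      phosphate = rtnorm(m, a$phosphate_mean, a$phosphate_sd,
                         a$phosphate_min, 4),
      glucose = rtlnorm(m, a$glucose_meanlog, a$glucose_sdlog,
                        a$glucose_min, a$glucose_max),
      hct = rtnorm(m, a$hct_mean, a$hct_sd, 20, 60),
      ketones = as.numeric(sample(0:4, m, replace = TRUE,
                                  prob = a$ketone_probs)),
      urea = rtlnorm(m, a$urea_meanlog, a$urea_sdlog, 10, 250),
      creatinine = rtlnorm(m, a$creatinine_meanlog, a$creatinine_sdlog,
                           0.3, 8),
      sig_target = rtnorm(m, a$sig_mean, a$sig_sd, a$sig_min, Inf)
    )
    cand$hco3 <- bicarbonate_from_gas(cand$ph, cand$paco2, constants)
    cand$sbe <- standard_base_excess(cand$ph, cand$paco2, constants)
    # chloride solved from the SIG identity:
    # SIG = (Na + K + Ca + Mg - Cl - lactate) - HCO3 - AlbQ - PiQ
    cand$cl <- cand$na + cand$k + cand$ca + cand$mg - cand$lactate -
      cand$hco3 -
      albumin_charge(cand$albumin, cand$ph, constants) -
      phosphate_charge(cand$phosphate, cand$ph, constants) -
      cand$sig_target
    keep <- is_dka(cand) & cand$cl > 60 & cand$cl < 140
    accepted <- rbind(accepted, cand[keep, , drop = FALSE])
  }
  accepted <- accepted[seq_len(n), , drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

#' Assign a first-six-hour fluid regimen
#'
#' GI patients receive 0.9\% saline (volume Normal(2302, 1188) mL truncated
#' above 300 mL) plus, with moderate probability, zero-difference co-fluids
#' (5\% dextrose, 0.45\% saline); every GI regimen has total Na-Cl difference
#' exactly 0. GII patients receive one of the craftwork / Isolyte / Isolyte-S
#' fluids with volume set from a drawn target regimen difference
#' (lognormal, median 144 mmol, truncated to [95, 263]) plus, occasionally,
#' some 0.9\% saline; every GII regimen has difference > 32 mmol by
#' construction.
#'
#' @param arm Character vector of `"GI"` / `"GII"`, one per patient.
#' @param patient_id Character vector of ids, same length.
#' @param config A [synthetic_cohort_config()].
#' @param registry Fluid registry used to convert target differences to
#'   volumes.
#' @return Data frame of administrations: `patient_id`, `fluid_name`,
#'   `volume_ml`, `window` (all `"first_6h"`).
#' @export
assign_regimen <- function(arm, patient_id,
                           config = synthetic_cohort_config(),
                           registry = default_fluid_registry()) {
  stopifnot(length(arm) == length(patient_id))
  f <- config$fluids
  diffs <- sodium_chloride_difference(registry)
  rows <- vector("list", length(arm))
  for (i in seq_along(arm)) {
    if (arm[i] == "GI") {
      vol <- rtnorm(1, f$gi_saline_mean, f$gi_saline_sd,
                    f$gi_saline_min, f$gi_saline_max)
      r <- data.frame(patient_id = patient_id[i], fluid_name = "0.9% NaCl",
                      volume_ml = vol, window = "first_6h",
                      stringsAsFactors = FALSE)
      if (stats::runif(1) < f$gi_dextrose_prob)
        r <- rbind(r, data.frame(patient_id = patient_id[i],
                                 fluid_name = "5% dextrose",
                                 volume_ml = stats::runif(1, f$gi_cofluid_min,
                                                          f$gi_cofluid_max),
                                 window = "first_6h"))
      if (stats::runif(1) < f$gi_halfsaline_prob)
        r <- rbind(r, data.frame(patient_id = patient_id[i],
                                 fluid_name = "0.45% NaCl",
                                 volume_ml = stats::runif(1, f$gi_cofluid_min,
                                                          f$gi_cofluid_max),
                                 window = "first_6h"))
    } else {
      main <- sample(f$gii_fluids, 1, prob = f$gii_fluid_probs)
      d <- rtlnorm(1, f$gii_diff_meanlog, f$gii_diff_sdlog,
                   f$gii_diff_min, f$gii_diff_max)
      vol <- 1000 * d / diffs[[main]]
      r <- data.frame(patient_id = patient_id[i], fluid_name = main,
                      volume_ml = vol, window = "first_6h",
                      stringsAsFactors = FALSE)
      if (stats::runif(1) < f$gii_saline_prob)
        r <- rbind(r, data.frame(patient_id = patient_id[i],
                                 fluid_name = "0.9% NaCl",
                                 volume_ml = stats::runif(1, f$gii_saline_min,
                                                          f$gii_saline_max),
                                 window = "first_6h"))
    }
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Solve the consistent (pH, PaCO2, HCO3) triple at a target standard base
# excess: HCO3 from the inverted Van Slyke equation, PaCO2 from Winter's
# compensation (plus the patient's admission deviation from Winter's line and
# a noise term), pH from Henderson-Hasselbalch. The scalar equation in pH is
# monotone, so uniroot is reliable.
solve_gas_from_sbe <- function(sbe, resp_offset, noise, constants, evo) {
  k <- constants
  hco3_fun <- function(ph)
    sbe / k$vanslyke_factor + k$vanslyke_hco3_ref -
      k$vanslyke_ph_slope * (ph - 7.40)
  paco2_fun <- function(h)
    pmax(evo$paco2_floor,
         evo$winters_slope * h + evo$winters_intercept + resp_offset + noise)
  f <- function(ph) {
    h <- hco3_fun(ph)
    ph - (k$pK + log10(h / (k$co2_solubility_coeff * paco2_fun(h))))
  }
  ph_hi <- 7.40 + (sbe / k$vanslyke_factor + k$vanslyke_hco3_ref - 0.5) /
    k$vanslyke_ph_slope
  lo <- 6.0
  hi <- min(7.8, ph_hi)
  if (hi <= lo)
    stop("solve_gas_from_sbe: target SBE (", signif(sbe, 3),
         ") admits no physiological solution", call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  h <- hco3_fun(root)
  list(ph = root, hco3 = h, paco2 = paco2_fun(h))
}

#' Evolve an admission panel through six hours of fluid therapy
#'
#' A minimal mass-balance model. Chloride and sodium are diluted into a
#' distribution volume `V = 0.2 L/kg * weight` and loaded with the retained
#' fraction of the infused electrolytes:
#' `Cl_6h = (Cl_0 * V + (1 - excretion) * Cl_load) / (V + retained * V_inf)`
#' (sodium analogous, including NaHCO3 bolus sodium). The strong ion gap
#' decays exponentially (ketoanion clearance under insulin),
#' `SIG_6h = SIG_0 * exp(-rate * 6)`. The standard base excess moves by the
#' change in base-excess chloride plus the cleared SIG plus the bicarbonate
#' bolus per distribution volume; the consistent 6th-hour gas
#' (pH, PaCO2, HCO3) is then solved from the Van Slyke equation, Winter's
#' respiratory compensation (keeping the patient's admission deviation from
#' Winter's line, plus noise), and Henderson-Hasselbalch. With zero infusion,
#' zero clearance and zero noise the panel is a fixed point.
#'
#' @param panel0 Admission panel data frame (rows = patients).
#' @param regimen Data frame aligned with `panel0`:
#'   `total_volume_ml`, `administered_na_mmol`, `administered_cl_mmol`
#'   (a [electrolyte_load()] summary).
#' @param weight_kg Patient weight vector.
#' @param nahco3_bolus_mmol NaHCO3 bolus per patient (mmol), default 0.
#' @param config A [synthetic_cohort_config()]; only `$evolution` is used.
#' @param constants An [acid_base_constants()] object.
#' @return Data frame of 6th-hour panels (same panel columns as `panel0`).
#' @export
evolve_six_hours <- function(panel0, regimen, weight_kg,
                             nahco3_bolus_mmol = 0,
                             config = synthetic_cohort_config(),
                             constants = acid_base_constants()) {
  evo <- config$evolution
  k <- as_constants(constants)
  n <- nrow(panel0)
  nahco3_bolus_mmol <- rep_len(nahco3_bolus_mmol, n)

  V <- evo$distribution_volume_l_per_kg * weight_kg
  if (any(V <= 0))
    stop("evolve_six_hours: non-positive distribution volume ",
         "(check `weight_kg`)", call. = FALSE)
  v_inf <- regimen$total_volume_ml / 1000
  retain <- 1 - evo$excretion_fraction
  denom <- V + evo$retained_fluid_fraction * v_inf

  cl6 <- (panel0$cl * V + retain * regimen$administered_cl_mmol) / denom
  na6 <- (panel0$na * V +
            retain * (regimen$administered_na_mmol + nahco3_bolus_mmol)) /
    denom
  if (any(cl6 <= 0))
    stop("evolve_six_hours: non-physical chloride (parameter `cl`)",
         call. = FALSE)
  if (any(na6 <= 0))
    stop("evolve_six_hours: non-physical sodium (parameter `na`)",
         call. = FALSE)

  sig0 <- strong_ion_gap(panel0, k)
  sig6 <- sig0 * exp(-evo$sig_clearance_rate_per_h * 6)
  becl0 <- base_excess_chloride(panel0$na, panel0$cl, k)
  becl6 <- base_excess_chloride(na6, cl6, k)
  sbe0 <- standard_base_excess(panel0$ph, panel0$paco2, k)
  sbe6 <- sbe0 + (becl6 - becl0) + (sig0 - sig6) + nahco3_bolus_mmol / V

  hco3_0 <- bicarbonate_from_gas(panel0$ph, panel0$paco2, k)
  resp_offset <- panel0$paco2 -
    (evo$winters_slope * hco3_0 + evo$winters_intercept)
  noise <- stats::rnorm(n, 0, evo$winters_noise_sd)

  gas <- lapply(seq_len(n), function(i)
    solve_gas_from_sbe(sbe6[i], resp_offset[i], noise[i], k, evo))
  ph6 <- vapply(gas, `[[`, numeric(1), "ph")
  paco2_6 <- vapply(gas, `[[`, numeric(1), "paco2")
  hco3_6 <- vapply(gas, `[[`, numeric(1), "hco3")
  if (any(hco3_6 <= 0))
    stop("evolve_six_hours: non-physical bicarbonate (parameter `sbe`)",
         call. = FALSE)

  dil <- V / denom
  out <- data.frame(
    ph = ph6, paco2 = paco2_6, hco3 = hco3_6, sbe = sbe6,
    na = na6,
    k = pmax(evo$k_floor,
             panel0$k + evo$k_shift + stats::rnorm(n, 0, evo$k_noise_sd)),
    ca = panel0$ca * dil, mg = panel0$mg * dil,
    cl = cl6,
    lactate = pmax(evo$lactate_floor,
                   panel0$lactate * evo$lactate_retention *
                     exp(stats::rnorm(n, 0, evo$lactate_noise_sdlog))),
    albumin = panel0$albumin * dil,
    phosphate = panel0$phosphate * dil,
    glucose = pmax(evo$glucose_floor,
                   panel0$glucose * (1 - evo$glucose_decline) *
                     exp(stats::rnorm(n, 0, evo$glucose_noise_sdlog))),
    hct = panel0$hct * dil,
    ketones = pmax(0, panel0$ketones -
                     stats::rbinom(n, 1, evo$ketone_drop_prob))
  )
  rownames(out) <- NULL
  out
}

#' Generate a synthetic two-arm DKA cohort
#'
#' Full pipeline: coherent DKA admission panels ([draw_admission_panel()]),
#' per-arm fluid regimens ([assign_regimen()]) whose electrolyte loads are
#' accounted with [electrolyte_load()], six-hour evolution
#' ([evolve_six_hours()]), 24th-hour renal chemistry, and an ICU length of
#' stay generated as
#' `LOS = intercept + beta_Cl * delta_Cl + beta_lac * delta_lactate + noise`
#' floored at one day. The generating parameters are returned alongside the
#' table so recovery tests can compare estimates with truth. Fully
#' reproducible: the same config (including `seed`) yields an identical
#' cohort.
#'
#' @param config A [synthetic_cohort_config()].
#' @param constants An [acid_base_constants()] object.
#' @param registry Fluid registry for regimen assignment and accounting.
#' @return A list of class `dka_simulation`: `cohort` (derived wide table,
#'   see [derive_cohort()]), `administrations` (fluid administration rows),
#'   and `ground_truth` (seed, LOS coefficients, per-patient SIG targets and
#'   arm labels).
#' @examples
#' sim <- generate_cohort(synthetic_cohort_config(seed = 42))
#' sim$cohort
#' @export
generate_cohort <- function(config = synthetic_cohort_config(),
                            constants = acid_base_constants(),
                            registry = default_fluid_registry()) {
  set.seed(config$seed)
  a <- config$admission
  f <- config$fluids
  n <- config$n_gi + config$n_gii
  arm <- rep(c("GI", "GII"), c(config$n_gi, config$n_gii))
  patient_id <- sprintf("p%03d", seq_len(n))

  panels <- draw_admission_panel(n, config, constants)

  age <- rtnorm(n, a$age_mean, a$age_sd, a$age_min, a$age_max)
  sex <- ifelse(stats::runif(n) < a$male_prob, "male", "female")
  bmi <- rtnorm(n, a$bmi_mean, a$bmi_sd, a$bmi_min, a$bmi_max)
  height <- rtnorm(n, a$height_mean, a$height_sd, 1.45, 2.05)
  weight <- bmi * height^2
  cci <- as.numeric(pmin(stats::rpois(n, a$cci_lambda), 12L))
  apache2 <- round(rtnorm(n, a$apache2_mean, a$apache2_sd, 4, 40))
  sofa <- as.numeric(pmin(stats::rpois(n, a$sofa_lambda), 18L))
  insulin <- rtlnorm(n, a$insulin_meanlog, a$insulin_sdlog, 0.01, 0.6)
  urine <- rtlnorm(n, a$urine_meanlog, a$urine_sdlog, 0.2, 12)

  gi <- arm == "GI"
  nahco3 <- numeric(n)
  give <- stats::runif(n) >= ifelse(gi, f$nahco3_zero_prob_gi,
                                    f$nahco3_zero_prob_gii)
  nahco3[give & gi] <- rtnorm(sum(give & gi), f$nahco3_mean_gi,
                              f$nahco3_sd_gi, 0, f$nahco3_max_gi)
  nahco3[give & !gi] <- rtnorm(sum(give & !gi), f$nahco3_mean_gii,
                               f$nahco3_sd_gii, 0, f$nahco3_max_gii)
  kcl <- numeric(n)
  give_k <- stats::runif(n) >= f$kcl_zero_prob
  kcl[give_k] <- stats::runif(sum(give_k), f$kcl_min, f$kcl_max)

  admins <- assign_regimen(arm, patient_id, config, registry)
  loads <- electrolyte_load(admins, registry)
  loads <- loads[match(patient_id, loads$patient_id), , drop = FALSE]
  if (!identical(unname(loads$group_label), unname(arm)))
    stop("generate_cohort: a regimen failed to classify to its arm",
         call. = FALSE)

  h6 <- evolve_six_hours(panels, loads, weight, nahco3, config, constants)

  urea_h24 <- panels$urea * 0.6 * exp(stats::rnorm(n, 0, 0.2))
  creat_h24 <- panels$creatinine * 0.8 * exp(stats::rnorm(n, 0, 0.15))
  ketones_h24 <- pmax(0, panels$ketones - sample(1:2, n, replace = TRUE))

  delta_cl <- h6$cl - panels$cl
  delta_lac <- h6$lactate - panels$lactate
  losc <- config$los
  los <- pmax(1, losc$intercept + losc$beta_delta_cl * delta_cl +
                losc$beta_delta_lactate * delta_lac +
                stats::rnorm(n, 0, losc$noise_sd))

  tab <- data.frame(patient_id = patient_id, age = age, sex = sex, bmi = bmi,
                    weight_kg = weight, cci = cci, apache2 = apache2,
                    sofa = sofa, nahco3_bolus_mmol = nahco3, kcl_mmol = kcl,
                    insulin_u_per_kg_h = insulin,
                    urine_output_ml_kg_h = urine,
                    los_icu_days = los, group_label = arm,
                    stringsAsFactors = FALSE)
  for (v in c(panel_vars_core, panel_vars_renal))
    tab[[paste0(v, "_adm")]] <- panels[[v]]
  for (v in panel_vars_core)
    tab[[paste0(v, "_h6")]] <- h6[[v]]
  tab$urea_h24 <- urea_h24
  tab$creatinine_h24 <- creat_h24
  tab$ketones_h24 <- ketones_h24

  cohort <- derive_cohort(tab, constants)
  structure(list(
    cohort = cohort,
    administrations = admins,
    ground_truth = list(seed = config$seed,
                        los_intercept = losc$intercept,
                        beta_delta_cl = losc$beta_delta_cl,
                        beta_delta_lactate = losc$beta_delta_lactate,
                        los_noise_sd = losc$noise_sd,
                        sig_target = panels$sig_target,
                        arm = arm)),
    class = "dka_simulation")
}

#' @export
print.dka_simulation <- function(x, ...) {
  cat("Synthetic DKA cohort simulation (seed ", x$ground_truth$seed, ")\n",
      sep = "")
  print(x$cohort)
  invisible(x)
}
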