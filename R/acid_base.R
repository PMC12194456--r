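#' Physicochemical acid-base constants
#'
#' Bundles the constants used throughout the Stewart/Figge-Fencl computations:
#' the plasma CO2 solubility coefficient and pK of the Henderson-Hasselbalch
#' relation, the Figge linear charge models for albumin and phosphate, the
#' reference sodium-chloride difference defining base-excess chloride, and the
#' Van Slyke coefficients for standard base excess.
#'
#' The CO2 solubility coefficient defaults to 0.0307 mmol/L/mmHg, the standard
#' plasma value; at pH 7.40 and PaCO2 40 mmHg it yields a bicarbonate of
#' 24.5 mmol/L. Values sometimes quoted an order of magnitude lower produce
#' physiologically impossible bicarbonate and are not used.
#'
#' @param co2_solubility_coeff Plasma CO2 solubility, mmol/L per mmHg.
#' @param pK Apparent pK of the bicarbonate buffer system.
#' @param reference_na_cl_difference Reference Na - Cl difference (mmol/L)
#'   defining base-excess chloride; 32 by convention.
#' @param albumin_slope,albumin_intercept Figge albumin charge model:
#'   charge = albumin * (slope * pH - intercept), albumin in g/L.
#' @param phosphate_slope,phosphate_intercept Figge phosphate charge model:
#'   charge = phosphate * (slope * pH - intercept), phosphate in mmol/L.
#' @param vanslyke_factor,vanslyke_hco3_ref,vanslyke_ph_slope Van Slyke
#'   standard base excess: SBE = factor * (HCO3 - hco3_ref +
#'   ph_slope * (pH - 7.40)).
#' @return An object of class `acid_base_constants` (a named list).
#' @examples
#' k <- acid_base_constants()
#' bicarbonate_from_gas(7.40, 40, k)
#' @export
acid_base_constants <- function(co2_solubility_coeff = 0.0307,
                                pK = 6.1,
                                reference_na_cl_difference = 32,
                                albumin_slope = 0.123,
                                albumin_intercept = 0.631,
                                phosphate_slope = 0.309,
                                phosphate_intercept = 0.469,
                                vanslyke_factor = 0.9287,
                                vanslyke_hco3_ref = 24.4,
                                vanslyke_ph_slope = 14.83) {
  k <- list(co2_solubility_coeff = co2_solubility_coeff,
            pK = pK,
            reference_na_cl_difference = reference_na_cl_difference,
            albumin_slope = albumin_slope,
            albumin_intercept = albumin_intercept,
            phosphate_slope = phosphate_slope,
            phosphate_intercept = phosphate_intercept,
            vanslyke_factor = vanslyke_factor,
            vanslyke_hco3_ref = vanslyke_hco3_ref,
            vanslyke_ph_slope = vanslyke_ph_slope)
  bad <- names(k)[!vapply(k, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("acid_base_constants: non-positive or non-scalar value for ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(k, class = "acid_base_constants")
}

#' Read acid-base constant overrides from a JSON file
#'
#' The file holds a flat JSON object whose keys are a subset of the arguments
#' of [acid_base_constants()]; unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return An `acid_base_constants` object.
#' @export
read_constants <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(acid_base_constants))
  unknown <- setdiff(names(ov), known)
  if (length(unknown))
    stop("read_constants: unknown constant(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(acid_base_constants, as.list(ov))
}

as_constants <- function(constants) {
  if (is.null(constants)) return(acid_base_constants())
  if (!inherits(constants, "acid_base_constants"))
    stop("`constants` must be created by acid_base_constants()", call. = FALSE)
  constants
}

#' @export
print.acid_base_constants <- function(x, ...) {
  cat("Acid-base constants:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Bicarbonate from blood gas (Henderson-Hasselbalch)
#'
#' Computes plasma bicarbonate as `coeff * PaCO2 * 10^(pH - pK)`.
#' Vectorised over `ph` and `paco2`.
#'
#' @param ph Arterial pH (unitless).
#' @param paco2 Arterial CO2 partial pressure, mmHg; must be positive.
#' @param constants An [acid_base_constants()] object.
#' @return Bicarbonate concentration, mmol/L.
#' @examples
#' bicarbonate_from_gas(7.40, 40)  # ~24.5
#' @export
bicarbonate_from_gas <- function(ph, paco2, constants = acid_base_constants()) {
  k <- as_constants(constants)
  if (any(!is.finite(paco2)) || any(paco2 <= 0))
    stop("bicarbonate_from_gas: `paco2` must be positive and finite",
         call. = FALSE)
  k$co2_solubility_coeff * paco2 * 10^(ph - k$pK)
}

#' Figge albumin charge
#'
#' Negative charge carried by albumin at a given pH:
#' `albumin * (0.123 * pH - 0.631)` with albumin in g/L. The formula value is
#' returned unclamped (it is negative below pH ~5.13).
#'
#' @param albumin Albumin concentration, g/L (non-negative).
#' @param ph Arterial pH.
#' @inheritParams bicarbonate_from_gas
#' @return Charge, mmol/L (mEq/L).
#' @export
albumin_charge <- function(albumin, ph, constants = acid_base_constants()) {
  k <- as_constants(constants)
  if (any(albumin < 0, na.rm = TRUE))
    stop("albumin_charge: `albumin` must be non-negative", call. = FALSE)
  albumin * (k$albumin_slope * ph - k$albumin_intercept)
}

#' Figge phosphate charge
#'
#' Negative charge carried by inorganic phosphate:
#' `phosphate * (0.309 * pH - 0.469)` with phosphate in mmol/L; unclamped.
#'
#' @param phosphate Phosphate concentration, mmol/L (non-negative).
#' @inheritParams albumin_charge
#' @return Charge, mmol/L (mEq/L).
#' @export
phosphate_charge <- function(phosphate, ph, constants = acid_base_constants()) {
  k <- as_constants(constants)
  if (any(phosphate < 0, na.rm = TRUE))
    stop("phosphate_charge: `phosphate` must be non-negative", call. = FALSE)
  phosphate * (k$phosphate_slope * ph - k$phosphate_intercept)
}

#' Convert a divalent ion concentration from mmol/L to mEq/L
#'
#' The strong ion difference is a charge balance, so calcium and magnesium
#' enter it in mEq/L (ionized-equivalent charge). Laboratories reporting
#' mmol/L can be converted with this helper.
#'
#' @param x Concentration in mmol/L.
#' @param valence Ion valence (2 for Ca2+ and Mg2+).
#' @return Concentration in mEq/L.
#' @export
mmol_to_meq <- function(x, valence = 2) x * valence

sig_fields <- c("na", "k", "ca", "mg", "cl", "lactate", "ph", "paco2",
                "albumin", "phosphate")

check_panel_fields <- function(panel, fields, caller) {
  if (!is.list(panel))
    stop(caller, ": `panel` must be a data frame or named list", call. = FALSE)
  missing_nm <- setdiff(fields, names(panel))
  if (length(missing_nm))
    stop(caller, ": missing required field(s): ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  for (nm in fields)
    if (any(is.na(panel[[nm]])))
      stop(caller, ": missing (NA) values in field `", nm, "`", call. = FALSE)
  invisible(panel)
}

#' Strong ion gap (Figge-Fencl)
#'
#' The apparent strong ion difference `SIDa = Na + K + Ca + Mg - Cl - lactate`
#' minus the effective buffering charges: bicarbonate (from pH and PaCO2),
#' albumin charge, and phosphate charge. A positive SIG indicates unmeasured
#' anions (in DKA, predominantly beta-hydroxybutyrate). No clamping is applied.
#'
#' @param panel A data frame (or named list) with columns `na`, `k`, `ca`,
#'   `mg`, `cl`, `lactate`, `ph`, `paco2`, `albumin`, `phosphate`. Sodium,
#'   potassium, chloride and lactate in mmol/L; calcium and magnesium in mEq/L
#'   (see [mmol_to_meq()]); albumin in g/L; phosphate in mmol/L.
#' @inheritParams bicarbonate_from_gas
#' @return Strong ion gap, mmol/L; vectorised over panel rows.
#' @examples
#' strong_ion_gap(data.frame(na = 140, k = 4, ca = 4.4, mg = 1.6, cl = 105,
#'                           lactate = 1, ph = 7.40, paco2 = 40,
#'                           albumin = 42, phosphate = 1.2))
#' @export
strong_ion_gap <- function(panel, constants = acid_base_constants()) {
  k <- as_constants(constants)
  check_panel_fields(panel, sig_fields, "strong_ion_gap")
  sida <- panel$na + panel$k + panel$ca + panel$mg - panel$cl - panel$lactate
  sida -
    bicarbonate_from_gas(panel$ph, panel$paco2, k) -
    albumin_charge(panel$albumin, panel$ph, k) -
    phosphate_charge(panel$phosphate, panel$ph, k)
}

#' Base-excess chloride
#'
#' `BE_Cl = Na - Cl - 32` (mmol/L). Negative values indicate chloride excess
#' relative to sodium (a hyperchloraemic acidifying effect), positive values
#' hypochloraemia.
#'
#' @param na Sodium, mmol/L.
#' @param cl Chloride, mmol/L.
#' @inheritParams bicarbonate_from_gas
#' @return Base-excess chloride, mmol/L.
#' @examples
#' base_excess_chloride(138, 112)  # -6, hyperchloremic
#' base_excess_chloride(139, 104)  #  3, hypochloremic
#' @export
base_excess_chloride <- function(na, cl, constants = acid_base_constants()) {
  k <- as_constants(constants)
  if (any(na < 0 | cl < 0, na.rm = TRUE))
    stop("base_excess_chloride: concentrations must be non-negative",
         call. = FALSE)
  na - cl - k$reference_na_cl_difference
}

#' Classify chloremia from base-excess chloride
#'
#' `BE_Cl < 0` is hyperchloremic, `BE_Cl > 0` hypochloremic, and exactly zero
#' (the reference value) normochloremic.
#'
#' @param be_cl Base-excess chloride, mmol/L; must be finite.
#' @return A character vector with levels `"hyperchloremic"`,
#'   `"normochloremic"`, `"hypochloremic"`.
#' @export
classify_chloremia <- function(be_cl) {
  if (any(!is.finite(be_cl)))
    stop("classify_chloremia: `be_cl` must be finite", call. = FALSE)
  ifelse(be_cl < 0, "hyperchloremic",
         ifelse(be_cl > 0, "hypochloremic", "normochloremic"))
}

#' Standard base excess (Van Slyke)
#'
#' `SBE = 0.9287 * (HCO3 - 24.4 + 14.83 * (pH - 7.40))` with bicarbonate
#' computed from the gas via [bicarbonate_from_gas()]. This is a standard
#' in-vitro approximation; blood-gas analyzers use closely related forms.
#'
#' @inheritParams bicarbonate_from_gas
#' @return Standard base excess, mmol/L.
#' @export
standard_base_excess <- function(ph, paco2, constants = acid_base_constants()) {
  k <- as_constants(constants)
  hco3 <- bicarbonate_from_gas(ph, paco2, k)
  k$vanslyke_factor * (hco3 - k$vanslyke_hco3_ref +
                         k$vanslyke_ph_slope * (ph - 7.40))
}

#' Diabetic ketoacidosis case definition
#'
#' TRUE iff all four guideline criteria hold: blood glucose > 200 mg/dL,
#' measured bicarbonate < 15 mmol/L, pH < 7.3, and urine ketones >= 2(+).
#' Inequalities on glucose, bicarbonate and pH are strict; the ketone
#' threshold is inclusive.
#'
#' @param panel A data frame (or named list) with fields `glucose` (mg/dL),
#'   `hco3` (measured bicarbonate, mmol/L), `ph`, and `ketones`
#'   (ordinal 0-4).
#' @return Logical, vectorised over rows.
#' @export
is_dka <- function(panel) {
  check_panel_fields(panel, c("glucose", "hco3", "ph", "ketones"), "is_dka")
  panel$glucose > 200 & panel$hco3 < 15 & panel$ph < 7.3 & panel$ketones >= 2
}
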