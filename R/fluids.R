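#' Default intravenous fluid registry
#'
#' Per-litre electrolyte content of the fluids used in the first six hours of
#' DKA management: 0.9\% saline and its dextrose variants, 0.45\% saline and
#' variants, plain 5\% dextrose, 20\% human albumin, 6\% HES, a locally
#' compounded ("craftwork") 0.45\% NaCl + NaHCO3 mixture, and the balanced
#' crystalloids Isolyte and Isolyte-S.
#'
#' The craftwork fluid is registered at its conventional printed composition
#' (Na 143, Cl 83 mmol/L, bicarbonate 65 mmol/L); recomputing it from its
#' recipe with [mix_fluids()] (935 mL 0.45\% NaCl + 65 mL 8.4\% NaHCO3) gives
#' approximately Na 137 / Cl 72 mmol/L. Both are legitimate; the registry
#' keeps the printed values and the discrepancy is documented rather than
#' silently corrected.
#'
#' @return A data frame of class `fluid_registry` with columns `name`,
#'   `na_mmol_per_l`, `cl_mmol_per_l`, `bicarbonate_mmol_per_l`,
#'   `dextrose_flag`.
#' @examples
#' reg <- default_fluid_registry()
#' sodium_chloride_difference(reg)
#' @export
default_fluid_registry <- function() {
  reg <- data.frame(
    name = c("0.9% NaCl",
             "5% dextrose 0.9% NaCl",
             "0.45% NaCl",
             "5% dextrose 0.45% NaCl",
             "5% dextrose",
             "human albumin 20%",
             "HES 6%",
             "craftwork 0.45% NaCl + NaHCO3",
             "Isolyte",
             "Isolyte-S"),
    na_mmol_per_l = c(154, 154, 77, 77, 0, 125, 154, 143, 140, 141),
    cl_mmol_per_l = c(154, 154, 77, 77, 0, 100, 154, 83, 103, 98),
    bicarbonate_mmol_per_l = c(0, 0, 0, 0, 0, 0, 0, 65, 0, 0),
    dextrose_flag = c(FALSE, TRUE, FALSE, TRUE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  validate_fluid_registry(reg)
}

validate_fluid_registry <- function(reg) {
  req <- c("name", "na_mmol_per_l", "cl_mmol_per_l", "bicarbonate_mmol_per_l")
  missing_nm <- setdiff(req, names(reg))
  if (length(missing_nm))
    stop("fluid registry: missing column(s): ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  if (anyDuplicated(reg$name))
    stop("fluid registry: duplicate fluid name(s): ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "),
         call. = FALSE)
  num <- c("na_mmol_per_l", "cl_mmol_per_l", "bicarbonate_mmol_per_l")
  for (nm in num)
    if (any(!is.finite(reg[[nm]]) | reg[[nm]] < 0))
      stop("fluid registry: `", nm, "` must be finite and non-negative",
           call. = FALSE)
  if (is.null(reg$dextrose_flag)) reg$dextrose_flag <- FALSE
  class(reg) <- c("fluid_registry", "data.frame")
  reg
}

#' Read a fluid registry from CSV
#'
#' Columns: `name`, `na_mmol_per_l`, `cl_mmol_per_l`, `bicarbonate_mmol_per_l`
#' and optionally `dextrose_flag`.
#'
#' @param path Path to a CSV file.
#' @return A `fluid_registry` data frame.
#' @export
read_fluid_registry <- function(path) {
  validate_fluid_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-litre sodium-chloride difference of a fluid
#'
#' @param fluid A fluid registry (or any data frame with `na_mmol_per_l` and
#'   `cl_mmol_per_l` columns).
#' @return Named numeric vector, `na - cl` per litre (mmol/L), one entry per
#'   registry row.
#' @examples
#' sodium_chloride_difference(default_fluid_registry())
#' @export
sodium_chloride_difference <- function(fluid) {
  if (is.null(fluid$na_mmol_per_l) || is.null(fluid$cl_mmol_per_l))
    stop("sodium_chloride_difference: need `na_mmol_per_l` and ",
         "`cl_mmol_per_l` columns", call. = FALSE)
  stats::setNames(fluid$na_mmol_per_l - fluid$cl_mmol_per_l, fluid$name)
}

#' Mix fluids by volume
#'
#' Volume-weighted mixture of fluid compositions: concentrations are averaged
#' with volume weights and the total volume is the sum of the parts (no
#' excess-volume chemistry).
#'
#' @param components Data frame of compositions (columns as in
#'   [default_fluid_registry()]), one row per component.
#' @param volumes_ml Numeric vector of component volumes in mL, same length as
#'   `nrow(components)`; total must be positive.
#' @param name Name given to the mixture.
#' @return A one-row composition data frame.
#' @examples
#' reg <- default_fluid_registry()
#' halfsaline <- reg[reg$name == "0.45% NaCl", ]
#' bicarb <- data.frame(name = "8.4% NaHCO3", na_mmol_per_l = 1000,
#'                      cl_mmol_per_l = 0, bicarbonate_mmol_per_l = 1000,
#'                      dextrose_flag = FALSE)
#' mix_fluids(rbind(halfsaline, bicarb), c(935, 65))
#' @export
mix_fluids <- function(components, volumes_ml, name = "mixture") {
  if (NROW(components) == 0L)
    stop("mix_fluids: empty component list", call. = FALSE)
  if (length(volumes_ml) != NROW(components))
    stop("mix_fluids: `volumes_ml` must match the number of components",
         call. = FALSE)
  if (any(volumes_ml < 0))
    stop("mix_fluids: negative component volume", call. = FALSE)
  total <- sum(volumes_ml)
  if (total <= 0)
    stop("mix_fluids: total volume must be positive", call. = FALSE)
  w <- volumes_ml / total
  data.frame(
    name = name,
    na_mmol_per_l = sum(w * components$na_mmol_per_l),
    cl_mmol_per_l = sum(w * components$cl_mmol_per_l),
    bicarbonate_mmol_per_l = sum(w * components$bicarbonate_mmol_per_l),
    dextrose_flag = any(components$dextrose_flag),
    total_volume_ml = total,
    stringsAsFactors = FALSE
  )
}

#' Electrolyte load of administered fluids
#'
#' Sums, per patient, the sodium and chloride delivered by fluid
#' administrations in a time window: `load = sum(volume_L * mmol_per_L)`.
#' Electrolytes given as additives (NaHCO3 boluses, KCl) are *not* part of the
#' fluid load; chloride from KCl can be tracked through `additive_cl_mmol`
#' and is merged into the chloride load only when `merge_additives = TRUE`
#' (off by default, mirroring the "only from fluids" accounting convention).
#'
#' @param admins Data frame of administrations with columns `patient_id`,
#'   `fluid_name`, `volume_ml`, `window`.
#' @param registry A fluid registry; defaults to [default_fluid_registry()].
#' @param window Which administration window to account
#'   (`"first_6h"` or `"later"`); rows in other windows are ignored.
#' @param additive_cl_mmol Optional data frame `patient_id`,
#'   `additive_cl_mmol` with per-patient additive chloride.
#' @param merge_additives If TRUE, additive chloride is added to the chloride
#'   load before the Na-Cl difference is formed (sensitivity analysis).
#' @return A data frame of class `regimen_summary`, one row per patient:
#'   `patient_id`, `total_volume_ml`, `administered_na_mmol`,
#'   `administered_cl_mmol`, `additive_cl_mmol`, `na_cl_difference_mmol`,
#'   `group_label`.
#' @examples
#' adm <- data.frame(patient_id = "p1", fluid_name = "0.9% NaCl",
#'                   volume_ml = 2000, window = "first_6h")
#' electrolyte_load(adm)
#' @export
electrolyte_load <- function(admins, registry = default_fluid_registry(),
                             window = "first_6h",
                             additive_cl_mmol = NULL,
                             merge_additives = FALSE) {
  registry <- validate_fluid_registry(as.data.frame(registry))
  req <- c("patient_id", "fluid_name", "volume_ml", "window")
  missing_nm <- setdiff(req, names(admins))
  if (length(missing_nm))
    stop("electrolyte_load: administrations missing column(s): ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  ids <- unique(admins$patient_id)
  if (length(ids) == 0L) {
    out <- data.frame(patient_id = character(0), total_volume_ml = numeric(0),
                      administered_na_mmol = numeric(0),
                      administered_cl_mmol = numeric(0),
                      additive_cl_mmol = numeric(0),
                      na_cl_difference_mmol = numeric(0),
                      group_label = character(0), stringsAsFactors = FALSE)
    class(out) <- c("regimen_summary", "data.frame")
    return(out)
  }
  admins <- admins[admins$window == window, , drop = FALSE]
  unknown <- setdiff(unique(admins$fluid_name), registry$name)
  if (length(unknown))
    stop("electrolyte_load: fluid(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(admins$volume_ml < 0))
    stop("electrolyte_load: negative administration volume", call. = FALSE)
  idx <- match(admins$fluid_name, registry$name)
  vol_l <- admins$volume_ml / 1000
  per <- data.frame(
    patient_id = admins$patient_id,
    vol = admins$volume_ml,
    na = vol_l * registry$na_mmol_per_l[idx],
    cl = vol_l * registry$cl_mmol_per_l[idx]
  )
  agg <- function(x) {
    s <- tapply(x, factor(per$patient_id, levels = ids), sum)
    as.numeric(ifelse(is.na(s), 0, s))
  }
  out <- data.frame(patient_id = ids,
                    total_volume_ml = agg(per$vol),
                    administered_na_mmol = agg(per$na),
                    administered_cl_mmol = agg(per$cl),
                    additive_cl_mmol = 0,
                    stringsAsFactors = FALSE)
  if (!is.null(additive_cl_mmol)) {
    m <- match(out$patient_id, additive_cl_mmol$patient_id)
    out$additive_cl_mmol <- ifelse(is.na(m), 0,
                                   additive_cl_mmol$additive_cl_mmol[m])
  }
  cl_for_diff <- out$administered_cl_mmol +
    if (merge_additives) out$additive_cl_mmol else 0
  out$na_cl_difference_mmol <- out$administered_na_mmol - cl_for_diff
  out$group_label <- classify_regimen(out$na_cl_difference_mmol)
  class(out) <- c("regimen_summary", "data.frame")
  out
}

#' Classify a fluid regimen as chloride-rich (GI) or chloride non-rich (GII)
#'
#' A first-6-hour regimen whose total fluid Na-Cl difference is exactly zero
#' is chloride-rich (`GI`); a difference greater than 32 mmol is chloride
#' non-rich (`GII`); anything in between (or negative) is `unclassified`.
#'
#' @param na_cl_difference_mmol Total regimen Na-Cl difference, mmol. A
#'   `regimen_summary` data frame is also accepted.
#' @param tol Numerical tolerance for "exactly zero".
#' @return Character vector with values `"GI"`, `"GII"`, `"unclassified"`.
#' @export
classify_regimen <- function(na_cl_difference_mmol, tol = 1e-9) {
  d <- if (is.data.frame(na_cl_difference_mmol))
    na_cl_difference_mmol$na_cl_difference_mmol else na_cl_difference_mmol
  ifelse(abs(d) <= tol, "GI",
         ifelse(d > 32, "GII", "unclassified"))
}
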