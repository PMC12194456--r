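# Wide cohort schema: one row per patient; panel variables carry a timepoint
# suffix (_adm, _h6; urea/creatinine/ketones also at _h24).

panel_vars_core <- c("ph", "paco2", "hco3", "sbe", "na", "k", "ca", "mg",
                     "cl", "lactate", "albumin", "phosphate", "glucose",
                     "hct", "ketones")
panel_vars_renal <- c("urea", "creatinine")

demo_vars <- c("patient_id", "age", "sex", "bmi", "weight_kg", "cci",
               "apache2", "sofa", "nahco3_bolus_mmol", "kcl_mmol",
               "insulin_u_per_kg_h", "urine_output_ml_kg_h", "los_icu_days",
               "group_label")

# fields that must be present (non-NA) for a patient to be analysable
required_adm <- c("ph", "paco2", "hco3", "na", "k", "ca", "mg", "cl",
                  "lactate", "albumin", "phosphate", "glucose", "ketones")
required_h6 <- c("ph", "paco2", "hco3", "na", "k", "ca", "mg", "cl",
                 "lactate", "albumin", "phosphate", "glucose")

#' Column names of the wide cohort table
#'
#' One row per patient: demographics/outcomes, admission and 6th-hour blood
#' gas + chemistry panels (suffixes `_adm`, `_h6`), and 24th-hour urea,
#' creatinine and urine ketones (suffix `_h24`).
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c(demo_vars,
    paste0(c(panel_vars_core, panel_vars_renal), "_adm"),
    paste0(panel_vars_core, "_h6"),
    paste0(c(panel_vars_renal, "ketones"), "_h24"))
}

#' Extract one timepoint's panel from a wide cohort table
#'
#' @param table Wide cohort data frame.
#' @param timepoint `"adm"`, `"h6"` or `"h24"`.
#' @return Data frame with unsuffixed panel column names (plus `patient_id`).
#' @export
panel_at <- function(table, timepoint = c("adm", "h6", "h24")) {
  timepoint <- match.arg(timepoint)
  suffix <- paste0("_", timepoint)
  cols <- names(table)[endsWith(names(table), suffix)]
  out <- table[, cols, drop = FALSE]
  names(out) <- sub(paste0(suffix, "$"), "", cols)
  out$patient_id <- table$patient_id
  out
}

#' Inclusion and exclusion filters for a DKA cohort
#'
#' Keeps adult patients (`age > 18`, strict) whose admission panel satisfies
#' the DKA definition ([is_dka()]) and who have no missing value in any field
#' required for the six-hour analysis (full admission and 6th-hour panels;
#' 24th-hour renal values are optional). Excluded rows are returned in a log,
#' one reason per patient (the first rule that fails, in the order
#' paediatric, not-DKA, missing-data).
#'
#' @param table Wide cohort data frame (see [cohort_columns()]).
#' @return A list with `included` (filtered table) and `exclusion_log`
#'   (data frame `patient_id`, `reason`).
#' @export
apply_inclusion_filters <- function(table) {
  reason <- rep(NA_character_, nrow(table))

  miss_req <- rep(FALSE, nrow(table))
  for (v in required_adm)
    miss_req <- miss_req | is.na(table[[paste0(v, "_adm")]])
  for (v in required_h6)
    miss_req <- miss_req | is.na(table[[paste0(v, "_h6")]])
  miss_req <- miss_req | is.na(table$los_icu_days) | is.na(table$age)

  adm <- panel_at(table, "adm")
  dka <- rep(FALSE, nrow(table))
  ok_dka_fields <- !(is.na(adm$glucose) | is.na(adm$hco3) |
                       is.na(adm$ph) | is.na(adm$ketones))
  if (any(ok_dka_fields))
    dka[ok_dka_fields] <- is_dka(adm[ok_dka_fields, , drop = FALSE])

  paediatric <- !is.na(table$age) & table$age <= 18
  reason[miss_req] <- "missing data"
  reason[ok_dka_fields & !dka & is.na(reason)] <- "not DKA at admission"
  reason[paediatric] <- "paediatric (age <= 18)"

  excluded <- !is.na(reason)
  list(included = table[!excluded, , drop = FALSE],
       exclusion_log = data.frame(patient_id = table$patient_id[excluded],
                                  reason = reason[excluded],
                                  stringsAsFactors = FALSE))
}

delta_vars <- c("ph", "paco2", "hco3", "na", "cl", "lactate", "glucose")

#' Six-hour delta values
#'
#' `delta_X = X(6th hour) - X(admission)` for pH, PaCO2, HCO3, Na, Cl,
#' lactate and glucose, plus the derived strong ion gap and base-excess
#' chloride. By construction `delta_becl = delta_na - delta_cl`.
#'
#' @param table Wide cohort data frame with complete admission and 6th-hour
#'   panels.
#' @param constants An [acid_base_constants()] object.
#' @return Data frame of `delta_*` columns, one row per patient.
#' @export
compute_deltas <- function(table, constants = acid_base_constants()) {
  adm <- panel_at(table, "adm")
  h6 <- panel_at(table, "h6")
  for (v in c(delta_vars, "k")) {
    for (p in list(adm = adm, h6 = h6)) {
      if (is.null(p[[v]]))
        stop("compute_deltas: missing panel field `", v, "`", call. = FALSE)
    }
    if (any(is.na(adm[[v]])) || any(is.na(h6[[v]])))
      stop("compute_deltas: NA in panel field `", v,
           "`; filter the cohort first", call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(table)))
  for (v in delta_vars)
    out[[paste0("delta_", v)]] <- h6[[v]] - adm[[v]]
  out$delta_sig <- strong_ion_gap(h6, constants) -
    strong_ion_gap(adm, constants)
  out$delta_becl <- base_excess_chloride(h6$na, h6$cl, constants) -
    base_excess_chloride(adm$na, adm$cl, constants)
  out
}

#' Add derived acid-base columns to a cohort table
#'
#' Computes, per patient and timepoint, the strong ion gap (`sig_adm`,
#' `sig_h6`), base-excess chloride (`becl_adm`, `becl_h6`), formula-derived
#' bicarbonate and standard base excess (`hco3_calc_*`, `sbe_calc_*` -- the
#' `hco3_*`/`sbe_*` columns hold analyzer-reported values, and the two can be
#' compared), and the six-hour deltas of [compute_deltas()]. Re-running on an
#' already-derived table recomputes and overwrites, so the operation is
#' idempotent.
#'
#' @inheritParams compute_deltas
#' @return The table with derived columns appended, classed `dka_cohort`.
#' @export
derive_cohort <- function(table, constants = acid_base_constants()) {
  for (tp in c("adm", "h6")) {
    p <- panel_at(table, tp)
    table[[paste0("sig_", tp)]] <- strong_ion_gap(p, constants)
    table[[paste0("becl_", tp)]] <- base_excess_chloride(p$na, p$cl, constants)
    table[[paste0("hco3_calc_", tp)]] <-
      bicarbonate_from_gas(p$ph, p$paco2, constants)
    table[[paste0("sbe_calc_", tp)]] <-
      standard_base_excess(p$ph, p$paco2, constants)
  }
  deltas <- compute_deltas(table, constants)
  for (nm in names(deltas)) table[[nm]] <- deltas[[nm]]
  class(table) <- unique(c("dka_cohort", class(table)))
  table
}

#' @export
print.dka_cohort <- function(x, ...) {
  n <- table(factor(x$group_label, levels = c("GI", "GII", "unclassified")))
  cat(sprintf("DKA cohort: %d patients (GI %d, GII %d, unclassified %d)\n",
              nrow(x), n[["GI"]], n[["GII"]], n[["unclassified"]]))
  derived <- intersect(c("sig_adm", "becl_adm", "delta_cl"), names(x))
  cat(if (length(derived) == 3) "Derived columns present.\n"
      else "Derived columns absent; run derive_cohort().\n")
  invisible(x)
}

#' Incidence per 1000 admissions
#'
#' @param cases Number of cases.
#' @param admissions Number of admissions (> 0, >= cases).
#' @return `1000 * cases / admissions`, rounded to one decimal.
#' @examples
#' incidence_per_1000(51, 17231)  # 3.0
#' @export
incidence_per_1000 <- function(cases, admissions) {
  if (any(admissions <= 0))
    stop("incidence_per_1000: `admissions` must be positive", call. = FALSE)
  if (any(cases > admissions) || any(cases < 0))
    stop("incidence_per_1000: need 0 <= cases <= admissions", call. = FALSE)
  round(1000 * cases / admissions, 1)
}

#' Per-group counts and percentages of a condition
#'
#' Counts, within each fluid group, how many patients satisfy a condition
#' (for example `becl_adm < 0`, hyperchloremia at admission), with
#' percentages to one decimal.
#'
#' @param table Cohort data frame with a `group_label` column.
#' @param condition A logical vector aligned with the rows of `table`, or a
#'   one-sided formula evaluated in the table (e.g. `~ becl_adm < 0`).
#' @return Data frame `group`, `n`, `count`, `pct`.
#' @examples
#' tab <- data.frame(group_label = rep(c("GI", "GII"), c(22, 13)),
#'                   becl_adm = c(rep(-1, 15), rep(1, 7), rep(-1, 12), 1))
#' group_counts(tab, ~ becl_adm < 0)
#' @export
group_counts <- function(table, condition) {
  cond <- if (inherits(condition, "formula"))
    eval(condition[[2]], table, environment(condition)) else condition
  if (!is.logical(cond) || length(cond) != nrow(table))
    stop("group_counts: `condition` must yield one logical per row",
         call. = FALSE)
  if (any(is.na(cond)))
    stop("group_counts: condition not evaluable (NA) on some rows",
         call. = FALSE)
  g <- factor(table$group_label)
  n <- as.integer(table(g))
  count <- as.integer(tapply(cond, g, sum))
  data.frame(group = levels(g), n = n, count = count,
             pct = round(100 * count / n, 1),
             stringsAsFactors = FALSE)
}
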