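# CSV interchange and end-to-end pipeline entry points.
#
# CSV conventions: UTF-8, "." decimal separator, column names as in
# cohort_columns() / the administration schema, missing values as empty
# cells. Numeric columns are written with 17 significant digits so that a
# write-read round trip reproduces every double exactly.

fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

write_lossless_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

abort_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("dkafluids_schema_error",
                                             "error", "condition")))
}

#' Write / read a wide cohort CSV
#'
#' @param table Wide cohort data frame.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the validated data frame;
#'   `write_cohort_csv` the path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  write_lossless_csv(as.data.frame(table)[,
    union(intersect(cohort_columns(), names(table)),
          setdiff(names(table), cohort_columns())), drop = FALSE], path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_nm <- setdiff(cohort_columns(), names(tab))
  if (length(missing_nm))
    abort_schema("cohort CSV ", path, ": missing column(s): ",
                 paste(missing_nm, collapse = ", "))
  num <- setdiff(cohort_columns(), c("patient_id", "sex", "group_label"))
  for (nm in num) {
    if (!is.numeric(tab[[nm]]) && !all(is.na(tab[[nm]])))
      abort_schema("cohort CSV ", path, ": column `", nm,
                   "` is not numeric")
    tab[[nm]] <- as.numeric(tab[[nm]])  # canonical double storage
  }
  tab
}

#' Write / read a fluid administration CSV
#'
#' Columns: `patient_id`, `fluid_name`, `volume_ml`, `window`.
#'
#' @param admins Administration data frame.
#' @param path CSV path.
#' @return `read_administrations_csv` returns the validated data frame.
#' @export
write_administrations_csv <- function(admins, path) {
  write_lossless_csv(admins, path)
}

#' @rdname write_administrations_csv
#' @export
read_administrations_csv <- function(path) {
  adm <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "fluid_name", "volume_ml", "window")
  missing_nm <- setdiff(req, names(adm))
  if (length(missing_nm))
    abort_schema("administrations CSV ", path, ": missing column(s): ",
                 paste(missing_nm, collapse = ", "))
  if (!is.numeric(adm$volume_ml))
    abort_schema("administrations CSV ", path, ": `volume_ml` not numeric")
  adm
}

# Polynomial rolling hash over the JSON rendering of a config; a cheap
# fingerprint for logging which configuration produced an output bundle.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [generate_cohort()] and writes `cohort.csv`, `administrations.csv`
#' and `ground_truth.json` (seed, config hash, generating parameters) into
#' `out_dir`, creating it if needed.
#'
#' @param config A [synthetic_cohort_config()].
#' @param out_dir Output directory.
#' @param seed Optional seed overriding `config$seed`.
#' @return The `dka_simulation` object, invisibly.
#' @export
run_simulate <- function(config = synthetic_cohort_config(), out_dir,
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  sim <- generate_cohort(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort_csv(sim$cohort, file.path(out_dir, "cohort.csv"))
  write_administrations_csv(sim$administrations,
                            file.path(out_dir, "administrations.csv"))
  gt <- c(sim$ground_truth, list(config_hash = config_hash(config)))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

analysis_variables <- function() {
  list(
    admission = c("age", "bmi", "cci", "apache2", "sofa",
                  "ph_adm", "paco2_adm", "hco3_adm", "sbe_adm", "na_adm",
                  "cl_adm", "becl_adm", "k_adm", "lactate_adm", "hct_adm",
                  "glucose_adm", "sig_adm", "ketones_adm", "urea_adm",
                  "creatinine_adm", "sex"),
    h6 = c("ph_h6", "paco2_h6", "hco3_h6", "sbe_h6", "na_h6", "cl_h6",
           "becl_h6", "k_h6", "lactate_h6", "hct_h6", "glucose_h6",
           "sig_h6", "los_icu_days"),
    deltas = c("delta_ph", "delta_paco2", "delta_hco3", "delta_na",
               "delta_cl", "delta_lactate", "delta_glucose", "delta_sig",
               "delta_becl"),
    fluids = c("total_volume_ml", "administered_na_mmol",
               "administered_cl_mmol", "na_cl_difference_mmol")
  )
}

#' Run the full retrospective-style analysis
#'
#' Ingest (data frames or CSV paths) -> inclusion filters -> derived columns
#' -> per-patient electrolyte loads -> admission, 6th-hour, delta and fluid
#' comparisons between GI and GII -> LOS correlations -> LOS regression ->
#' hyperchloremia/severe-acidosis group counts. The analysis is entirely
#' deterministic in its input. When `out_dir` is given, comparison tables
#' (`comparison_admission.csv`, `comparison_h6.csv`, `comparison_deltas.csv`,
#' `comparison_fluids.csv`), the regression table (`regression.csv`) and a
#' JSON summary (`summary.json`) are written; nothing is written if any stage
#' fails.
#'
#' @param cohort Wide cohort data frame or path to a cohort CSV.
#' @param admins Administration data frame or CSV path.
#' @param out_dir Optional output directory for the report bundle.
#' @param constants An [acid_base_constants()] object.
#' @param registry Fluid registry for the load accounting.
#' @param predictors Predictor set for [los_regression()].
#' @return A list of class `dka_analysis`: `included`, `exclusion_log`,
#'   `loads`, `comparisons` (per block), `correlations`, `regression`,
#'   `counts`.
#' @export
run_analyze <- function(cohort, admins, out_dir = NULL,
                        constants = acid_base_constants(),
                        registry = default_fluid_registry(),
                        predictors = los_predictors()) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (is.character(admins)) admins <- read_administrations_csv(admins)

  flt <- apply_inclusion_filters(cohort)
  tab <- flt$included
  if (nrow(tab) == 0)
    abort_schema("run_analyze: no patient passes the inclusion filters")
  tab <- derive_cohort(tab, constants)
  groups <- unique(tab$group_label)
  if (length(setdiff(c("GI", "GII"), groups)))
    stop(errorCondition(
      paste0("run_analyze: need both fluid groups, found only: ",
             paste(groups, collapse = ", ")),
      class = c("dkafluids_degenerate_error", "error", "condition")))

  loads <- electrolyte_load(admins, registry)
  loads <- loads[match(tab$patient_id, loads$patient_id), , drop = FALSE]
  with_loads <- cbind(tab, loads[, c("total_volume_ml",
                                     "administered_na_mmol",
                                     "administered_cl_mmol",
                                     "na_cl_difference_mmol")])

  vars <- analysis_variables()
  comparisons <- lapply(vars, function(v)
    comparison_table(with_loads, intersect(v, names(with_loads))))

  correlations <- do.call(rbind, lapply(
    c("delta_ph", "delta_paco2", "delta_hco3", "delta_na", "delta_cl",
      "delta_lactate", "delta_sig", "delta_becl"),
    function(v) {
      ct <- correlate_with_los(tab, v)
      data.frame(variable = v, r = ct$r, p_value = ct$p_value, n = ct$n)
    }))

  regression <- los_regression(tab, predictors)

  counts <- list(
    hyperchloremic_admission = group_counts(tab, ~ becl_adm < 0),
    ph_le_7_admission = group_counts(tab, ~ ph_adm <= 7.0),
    hyperchloremic_h6 = group_counts(tab, ~ becl_h6 < 0)
  )

  res <- structure(list(included = tab, exclusion_log = flt$exclusion_log,
                        loads = loads, comparisons = comparisons,
                        correlations = correlations, regression = regression,
                        counts = counts),
                   class = "dka_analysis")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(comparisons))
      write_lossless_csv(comparisons[[nm]],
                         file.path(out_dir, paste0("comparison_", nm, ".csv")))
    write_lossless_csv(regression$coefficients,
                       file.path(out_dir, "regression.csv"))
    summary_json <- list(
      n_included = nrow(tab),
      n_excluded = nrow(flt$exclusion_log),
      group_sizes = as.list(table(tab$group_label)),
      r_squared = regression$r_squared,
      durbin_watson = regression$durbin_watson,
      correlations = correlations,
      counts = counts,
      note = "two-sided tests at nominal alpha 0.05; no multiplicity correction"
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}

#' @export
print.dka_analysis <- function(x, ...) {
  cat(sprintf("DKA fluid-therapy analysis: %d included, %d excluded\n",
              nrow(x$included), nrow(x$exclusion_log)))
  gs <- table(x$included$group_label)
  cat("Groups:", paste(sprintf("%s = %d", names(gs), gs), collapse = ", "),
      "\n\n6th-hour comparisons (GI vs GII):\n")
  h6 <- x$comparisons$h6
  print(h6[, c("variable", "group1", "group2", "test_used", "p_value")],
        row.names = FALSE, digits = 3)
  cat("\n")
  print(x$regression)
  invisible(x)
}
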