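test_that("the cohort generator is deterministic in its seed", {
  cfg <- synthetic_cohort_config(n_gi = 6, n_gii = 5, seed = 99)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$administrations, s2$administrations)
  s3 <- generate_cohort(synthetic_cohort_config(n_gi = 6, n_gii = 5,
                                                seed = 100))
  expect_false(identical(s1$cohort$cl_h6, s3$cohort$cl_h6))
})

test_that("admission panels are DKA by construction with the drawn SIG", {
  set.seed(41)
  panels <- draw_admission_panel(300)
  expect_true(all(is_dka(panels)))
  expect_equal(strong_ion_gap(panels), panels$sig_target, tolerance = 1e-6)
  expect_true(all(panels$sig_target >= 5))
  # generator calibration: mean pH close to the 7.10 target
  set.seed(42)
  big <- draw_admission_panel(1000)
  expect_equal(mean(big$ph), 7.10, tolerance = 0.02)
  expect_equal(mean(big$cl), 106, tolerance = 4)
})

test_that("an infeasible admission config raises a rejection error", {
  cfg <- synthetic_cohort_config(
    admission = list(glucose_meanlog = log(170), glucose_sdlog = 0.01,
                     glucose_min = 160, glucose_max = 180,
                     max_draw_factor = 50))
  set.seed(43)
  expect_error(draw_admission_panel(2, cfg), "config-infeasible")
})

test_that("regimens classify to their arm by construction", {
  set.seed(44)
  arm <- rep(c("GI", "GII"), c(40, 40))
  ids <- sprintf("q%03d", seq_along(arm))
  admins <- assign_regimen(arm, ids)
  loads <- electrolyte_load(admins)
  loads <- loads[match(ids, loads$patient_id), ]
  expect_identical(unname(loads$group_label), arm)
  expect_true(all(abs(loads$na_cl_difference_mmol[arm == "GI"]) < 1e-9))
  gii_d <- loads$na_cl_difference_mmol[arm == "GII"]
  expect_true(all(gii_d > 32))
  # calibration of the GII target difference
  set.seed(45)
  many <- assign_regimen(rep("GII", 500), sprintf("r%03d", 1:500))
  md <- median(electrolyte_load(many)$na_cl_difference_mmol)
  expect_gt(md, 95); expect_lt(md, 263)
})

quiet_evolution <- list(winters_noise_sd = 0, k_noise_sd = 0, k_shift = 0,
                        lactate_noise_sdlog = 0, lactate_retention = 1,
                        glucose_noise_sdlog = 0, glucose_decline = 0,
                        ketone_drop_prob = 0, sig_clearance_rate_per_h = 0)

test_that("six-hour evolution has the untreated panel as a fixed point", {
  set.seed(46)
  p0 <- draw_admission_panel(5)
  cfg <- synthetic_cohort_config(evolution = quiet_evolution)
  none <- data.frame(total_volume_ml = 0, administered_na_mmol = 0,
                     administered_cl_mmol = 0)
  h6 <- evolve_six_hours(p0, none[rep(1, 5), ], weight_kg = rep(70, 5),
                         nahco3_bolus_mmol = 0, config = cfg)
  for (v in names(h6))
    expect_equal(h6[[v]], p0[[v]], tolerance = 1e-6, info = v)
})

test_that("chloride-rich fluid raises Cl and lowers BE_Cl versus balanced", {
  set.seed(47)
  p0 <- draw_admission_panel(10)
  reg <- default_fluid_registry()
  vol <- 3000
  mk_load <- function(fluid) data.frame(
    total_volume_ml = vol,
    administered_na_mmol = vol / 1000 * reg$na_mmol_per_l[reg$name == fluid],
    administered_cl_mmol = vol / 1000 * reg$cl_mmol_per_l[reg$name == fluid])
  cfg <- synthetic_cohort_config(evolution = quiet_evolution)
  saline <- evolve_six_hours(p0, mk_load("0.9% NaCl")[rep(1, 10), ],
                             rep(70, 10), 0, cfg)
  balanced <- evolve_six_hours(p0, mk_load("Isolyte")[rep(1, 10), ],
                               rep(70, 10), 0, cfg)
  expect_true(all(saline$cl > balanced$cl))
  expect_true(all(base_excess_chloride(saline$na, saline$cl) <
                    base_excess_chloride(balanced$na, balanced$cl)))
})

test_that("the strong ion gap strictly decays under treatment", {
  sim <- generate_cohort(synthetic_cohort_config(seed = 48))
  expect_true(all(sim$cohort$sig_h6 < sim$cohort$sig_adm))
})

test_that("full urinary chloride excretion collapses the arm difference", {
  gap <- function(excretion, seed = 49) {
    cfg <- synthetic_cohort_config(
      n_gi = 60, n_gii = 60, seed = seed,
      evolution = list(excretion_fraction = excretion))
    co <- generate_cohort(cfg)$cohort
    median(co$cl_h6[co$group_label == "GI"]) -
      median(co$cl_h6[co$group_label == "GII"])
  }
  expect_lt(abs(gap(1)), abs(gap(0.3)))
})

test_that("emitted panels keep the BE_Cl bookkeeping identity exactly", {
  sim <- generate_cohort(synthetic_cohort_config(seed = 50))
  co <- sim$cohort
  expect_identical(co$delta_becl, co$delta_na - co$delta_cl)
  expect_equal(co$becl_h6, co$na_h6 - co$cl_h6 - 32)
})

test_that("negative intermediate concentrations raise a named error", {
  set.seed(51)
  p0 <- draw_admission_panel(2)
  huge_cl <- data.frame(total_volume_ml = 500, administered_na_mmol = 0,
                        administered_cl_mmol = 0)
  # an absurd negative-weight patient makes the distribution volume invalid
  expect_error(evolve_six_hours(p0, huge_cl[rep(1, 2), ], weight_kg = c(-1, 70)),
               "distribution volume")
})

test_that("six-hour BE_Cl separates the arms in most seeds at study size", {
  sig <- vapply(1:25, function(s) {
    sim <- generate_cohort(synthetic_cohort_config(seed = s))
    compare_groups(sim$cohort, "becl_h6")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(sig), 0.5)
})

test_that("delta-Cl correlates positively with LOS across seeds", {
  pos <- vapply(1:30, function(s) {
    sim <- generate_cohort(synthetic_cohort_config(seed = 1000 + s))
    correlate_with_los(sim$cohort, "delta_cl")$r > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})
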