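test_that("registry reproduces the per-litre Na-Cl differences", {
  reg <- default_fluid_registry()
  d <- sodium_chloride_difference(reg)
  expect_identical(unname(d[["0.9% NaCl"]]), 0)
  expect_identical(unname(d[["Isolyte"]]), 37)
  expect_identical(unname(d[["Isolyte-S"]]), 43)
  zero_fluids <- c("5% dextrose 0.9% NaCl", "0.45% NaCl",
                   "5% dextrose 0.45% NaCl", "5% dextrose", "HES 6%")
  expect_true(all(d[zero_fluids] == 0))
  # the craftwork fluid is registered at its conventional concentrations
  # (143/83); those are internally inconsistent with a "difference 50" label,
  # and the package keeps the concentrations: 143 - 83 = 60.
  expect_identical(unname(d[["craftwork 0.45% NaCl + NaHCO3"]]), 60)
  expect_error(validate_fluid_registry(rbind(reg, reg[1, ])), "duplicate")
})

test_that("mixing is volume-weighted, idempotent, and respects the recipe", {
  reg <- default_fluid_registry()
  halfsaline <- reg[reg$name == "0.45% NaCl", ]
  bicarb <- data.frame(name = "8.4% NaHCO3", na_mmol_per_l = 1000,
                       cl_mmol_per_l = 0, bicarbonate_mmol_per_l = 1000,
                       dextrose_flag = FALSE)
  craft <- mix_fluids(rbind(halfsaline, bicarb), c(935, 65))
  expect_equal(craft$na_mmol_per_l, (0.935 * 77 + 0.065 * 1000) / 1,
               tolerance = 1e-12)
  expect_equal(craft$cl_mmol_per_l, 0.935 * 77, tolerance = 1e-12)
  expect_equal(craft$na_mmol_per_l, 137.0, tolerance = 0.01)
  expect_equal(craft$cl_mmol_per_l, 72.0, tolerance = 0.01)

  self <- mix_fluids(rbind(halfsaline, halfsaline), c(300, 700))
  expect_equal(self$na_mmol_per_l, halfsaline$na_mmol_per_l)
  expect_equal(self$cl_mmol_per_l, halfsaline$cl_mmol_per_l)

  a <- data.frame(name = "a", na_mmol_per_l = 100, cl_mmol_per_l = 100,
                  bicarbonate_mmol_per_l = 0, dextrose_flag = FALSE)
  b <- transform(a, name = "b", na_mmol_per_l = 0, cl_mmol_per_l = 0)
  mid <- mix_fluids(rbind(a, b), c(500, 500))
  expect_equal(c(mid$na_mmol_per_l, mid$cl_mmol_per_l), c(50, 50))

  expect_error(mix_fluids(halfsaline[0, ], numeric(0)), "empty")
  expect_error(mix_fluids(rbind(a, b), c(0, 0)), "positive")
})

test_that("mixture Na-Cl difference is the volume-weighted mean difference", {
  reg <- default_fluid_registry()
  set.seed(21)
  for (i in 1:20) {
    pick <- sample(nrow(reg), 3)
    vols <- runif(3, 100, 2000)
    mixed <- mix_fluids(reg[pick, ], vols)
    expect_equal(unname(sodium_chloride_difference(mixed)),
                 sum(vols / sum(vols) *
                       sodium_chloride_difference(reg[pick, ])),
                 tolerance = 1e-9)
  }
})

test_that("electrolyte loads are linear in volume and classify regimens", {
  adm <- data.frame(patient_id = c("p1", "p2"),
                    fluid_name = c("0.9% NaCl", "Isolyte"),
                    volume_ml = c(2000, 3300), window = "first_6h")
  load <- electrolyte_load(adm)
  expect_equal(load$administered_na_mmol, c(2 * 154, 3.3 * 140))
  expect_equal(load$administered_cl_mmol, c(2 * 154, 3.3 * 103))
  expect_equal(load$na_cl_difference_mmol, c(0, 3.3 * 37), tolerance = 1e-9)
  expect_identical(load$group_label, c("GI", "GII"))

  empty <- electrolyte_load(adm[0, ])
  expect_identical(nrow(empty), 0L)
  later_only <- electrolyte_load(transform(adm[1, ], window = "later"))
  expect_equal(later_only$administered_na_mmol, 0)

  expect_error(electrolyte_load(transform(adm, fluid_name = "brine")),
               "brine")
})

test_that("electrolyte load is additive and degree-1 homogeneous", {
  reg <- default_fluid_registry()
  set.seed(22)
  mk <- function(n) data.frame(patient_id = "p1",
                               fluid_name = sample(reg$name, n, replace = TRUE),
                               volume_ml = runif(n, 50, 2500),
                               window = "first_6h")
  a <- mk(4); b <- mk(3)
  both <- electrolyte_load(rbind(a, b))
  sep <- electrolyte_load(a)$administered_cl_mmol +
    electrolyte_load(b)$administered_cl_mmol
  expect_equal(both$administered_cl_mmol, sep, tolerance = 1e-12)
  scaled <- a; scaled$volume_ml <- 3 * a$volume_ml
  expect_equal(electrolyte_load(scaled)$administered_na_mmol,
               3 * electrolyte_load(a)$administered_na_mmol,
               tolerance = 1e-12)
})

test_that("additive chloride stays out of the fluid accounting unless merged", {
  adm <- data.frame(patient_id = "p1", fluid_name = "Isolyte",
                    volume_ml = 3000, window = "first_6h")
  extra <- data.frame(patient_id = "p1", additive_cl_mmol = 40)
  off <- electrolyte_load(adm, additive_cl_mmol = extra)
  on <- electrolyte_load(adm, additive_cl_mmol = extra, merge_additives = TRUE)
  expect_equal(off$na_cl_difference_mmol, 3 * 37, tolerance = 1e-9)
  expect_equal(on$na_cl_difference_mmol, 3 * 37 - 40, tolerance = 1e-9)
  expect_equal(off$additive_cl_mmol, 40)
})

test_that("regimen classification follows the 0 / >32 mmol rule", {
  expect_identical(classify_regimen(c(0, 144, 20, -5, 32, 32.001)),
                   c("GI", "GII", "unclassified", "unclassified",
                     "unclassified", "GII"))
})
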