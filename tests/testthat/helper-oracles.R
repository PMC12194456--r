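# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the code paths they verify.

# Term-by-term strong-ion-gap computation, written out with the literal
# constants rather than through the package's helpers.
sig_oracle <- function(p) {
  hco3 <- 0.0307 * p$paco2 * 10^(p$ph - 6.1)
  alb_q <- p$albumin * (0.123 * p$ph - 0.631)
  pi_q <- p$phosphate * (0.309 * p$ph - 0.469)
  (p$na + p$k + p$ca + p$mg - p$cl - p$lactate) - hco3 - alb_q - pi_q
}

random_panels <- function(n) {
  data.frame(
    na = runif(n, 115, 155), k = runif(n, 2, 7),
    ca = runif(n, 3, 6), mg = runif(n, 0.8, 2.5),
    cl = runif(n, 85, 130), lactate = runif(n, 0.4, 10),
    ph = runif(n, 6.8, 7.6), paco2 = runif(n, 10, 70),
    albumin = runif(n, 15, 55), phosphate = runif(n, 0.4, 3)
  )
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled sample to the two groups (no ties assumed).
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables no more probable than the observed one.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo power of the two-sided pooled-variance two-sample t-test.
mc_t_power <- function(n1, n2, mean_diff, sd, alpha, reps = 10000) {
  x <- matrix(stats::rnorm(reps * n1, mean_diff, sd), nrow = reps)
  y <- matrix(stats::rnorm(reps * n2, 0, sd), nrow = reps)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, n1 + n2 - 2))
}

# Minimal hand-built wide cohort row (all analysis fields present) for
# filter/delta tests; values loosely follow a severe DKA admission.
toy_patient <- function(patient_id = "t1", age = 52, group = "GI",
                        cl_adm = 106, cl_h6 = 112, na_adm = 135,
                        na_h6 = 138, glucose_adm = 426, hco3_adm = 7.2,
                        ph_adm = 7.10, ketones_adm = 3, los = 3) {
  row <- data.frame(
    patient_id = patient_id, age = age, sex = "female", bmi = 24.2,
    weight_kg = 70, cci = 3, apache2 = 14, sofa = 2,
    nahco3_bolus_mmol = 60, kcl_mmol = 0, insulin_u_per_kg_h = 0.08,
    urine_output_ml_kg_h = 3.6, los_icu_days = los, group_label = group,
    ph_adm = ph_adm, paco2_adm = 16.4, hco3_adm = hco3_adm, sbe_adm = -24.7,
    na_adm = na_adm, k_adm = 4.4, ca_adm = 4.6, mg_adm = 1.6, cl_adm = cl_adm,
    lactate_adm = 2.1, albumin_adm = 38, phosphate_adm = 1.2,
    glucose_adm = glucose_adm, hct_adm = 40.9, ketones_adm = ketones_adm,
    urea_adm = 56, creatinine_adm = 1.5,
    ph_h6 = 7.28, paco2_h6 = 23.0, hco3_h6 = 12.9, sbe_h6 = -14.6,
    na_h6 = na_h6, k_h6 = 3.5, ca_h6 = 4.3, mg_h6 = 1.5, cl_h6 = cl_h6,
    lactate_h6 = 1.5, albumin_h6 = 34, phosphate_h6 = 1.1,
    glucose_h6 = 256, hct_h6 = 35.9, ketones_h6 = 2,
    urea_h24 = 30, creatinine_h24 = 1.1, ketones_h24 = 2,
    stringsAsFactors = FALSE
  )
  row[, dkafluids::cohort_columns()]
}

toy_cohort <- function(n_gi = 4, n_gii = 4) {
  rows <- lapply(seq_len(n_gi + n_gii), function(i) {
    gi <- i <= n_gi
    toy_patient(patient_id = sprintf("t%02d", i),
                group = if (gi) "GI" else "GII",
                cl_adm = 106 + (i %% 3), cl_h6 = if (gi) 112 + (i %% 3)
                else 104 + (i %% 2),
                na_adm = 134 + (i %% 4), na_h6 = 138 + (i %% 3),
                los = if (gi) 3 + 0.2 * i else 2 + 0.1 * i)
  })
  do.call(rbind, rows)
}
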