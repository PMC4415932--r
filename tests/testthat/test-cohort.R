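test_that("cohort specifications validate their inputs", {
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(noise_sd = -0.1), "noise_sd")
  expect_error(cohort_spec(baseline = list(sbat_ff = c(1.2, 0.05),
                                           sat_ff = c(0.85, 0.05),
                                           sbat_r2s = c(21, 2),
                                           sat_r2s = c(20, 3))), "FF means")
  expect_equal(cohort_spec()$n_subjects, 9L)
  expect_equal(cohort_spec(mode = "procedure_study")$n_subjects, 8L)
  expect_equal(cohort_spec(mode = "procedure_study")$sat_posture_ff_drift,
               c(-0.75, 0.64))
})

test_that("effect semantics: lipid persists, perfusion reverses, drift is late", {
  ## lipid-only: the reheated change equals the cold change exactly
  led <- coolbat:::draw_cohort_truth(
    cohort_spec(seed = 4, sbat_lipid_ff_change = c(-1.94, 1.83),
                sbat_perfusion_ff_change = c(0, 0)))$ledger
  w <- reshape(led[, c("subject", "state", "sbat_ff")], direction = "wide",
               idvar = "subject", timevar = "state")
  expect_equal(w$sbat_ff.Cold - w$sbat_ff.Baseline,
               w$sbat_ff.Reheated - w$sbat_ff.Baseline)
  ## perfusion-only: the reheated state returns to baseline exactly
  led2 <- coolbat:::draw_cohort_truth(
    cohort_spec(seed = 4, sbat_lipid_ff_change = c(0, 0),
                sbat_perfusion_ff_change = c(-2, 0.5)))$ledger
  w2 <- reshape(led2[, c("subject", "state", "sbat_ff")], direction = "wide",
                idvar = "subject", timevar = "state")
  expect_equal(w2$sbat_ff.Reheated, w2$sbat_ff.Baseline)
  expect_false(isTRUE(all.equal(w2$sbat_ff.Cold, w2$sbat_ff.Baseline)))
  ## posture drift acts on SAT only between Cold and Reheated
  led3 <- coolbat:::draw_cohort_truth(cohort_spec(seed = 5))$ledger
  w3 <- reshape(led3[, c("subject", "state", "sat_ff")], direction = "wide",
                idvar = "subject", timevar = "state")
  drift <- (w3$sat_ff.Reheated - w3$sat_ff.Cold) * 100
  expect_lt(abs(mean(drift) - (-0.79)), 3 * 0.27 / sqrt(9) + 1e-9)
  ## reversible R2* effect returns to baseline on reheating
  w4 <- reshape(led3[, c("subject", "state", "sbat_r2s")], direction = "wide",
                idvar = "subject", timevar = "state")
  expect_equal(w4$sbat_r2s.Reheated, w4$sbat_r2s.Baseline)
})

test_that("ledger means converge to the specification as the cohort grows", {
  spec <- cohort_spec(n_subjects = 200, seed = 6)
  led <- coolbat:::draw_cohort_truth(spec)$ledger
  base <- led[led$state == "Baseline", ]
  se <- function(s) s / sqrt(200)
  expect_lt(abs(mean(base$sbat_ff) - 0.828), 3 * se(0.050))
  expect_lt(abs(mean(base$sat_ff) - 0.852), 3 * se(0.051))
  expect_lt(abs(mean(base$sbat_r2s) - 21.0), 3 * se(1.8))
  expect_lt(abs(mean(base$sat_r2s) - 19.6), 3 * se(2.8))
  chg <- (led$sbat_ff[led$state == "Cold"] - base$sbat_ff) * 100
  expect_lt(abs(mean(chg) - (-1.94)), 3 * se(1.83))
})

test_that("measurement-level simulation is deterministic and well-formed", {
  m1 <- simulate_measurements(cohort_spec(seed = 9))
  m2 <- simulate_measurements(cohort_spec(seed = 9))
  expect_identical(m1, m2)
  expect_setequal(unique(m1$voi), c("sbat", "sat"))
  expect_equal(nrow(m1), 9 * 3 * 2)
  m3 <- simulate_measurements(cohort_spec(seed = 10))
  expect_false(identical(m1$mean_ff_pct, m3$mean_ff_pct))
})

test_that("simulated subjects carry coherent images, truths and crude masks", {
  spec <- cohort_spec(seed = 12, grid_shape = c(24, 24, 6), n_subjects = 2,
                      noise_sd = 0.02)
  p <- acquisition_protocol(grid_shape = c(24, 24, 6))
  sub <- coolbat:::simulate_subject(spec, 1, p, fat_spectrum())
  expect_setequal(names(sub), c("Baseline", "Cold", "Reheated"))
  st <- sub$Cold
  expect_s3_class(st$image, "multiecho_image")
  expect_equal(dim(st$image$signal), c(24, 24, 6, 6))
  ## crude mask over-segments: it contains non-sBAT boundary voxels
  sbat <- label_mask(st$truth, "sbat")
  expect_gt(sum(st$crude_mask & !sbat) / sum(st$crude_mask), 0.10)
  expect_gt(sum(st$crude_mask & sbat), 0)
  ## baseline is the unmoved reference state
  expect_equal(sub$Baseline$motion$translation, c(0, 0, 0))
  expect_true(any(st$motion$translation != 0))
  ## determinism of the imaging chain
  sub2 <- coolbat:::simulate_subject(spec, 1, p, fat_spectrum())
  expect_identical(st$image$signal, sub2$Cold$image$signal)
})

test_that("a null cohort differs across states only by the rigid offsets", {
  spec <- cohort_spec(seed = 13, grid_shape = c(24, 24, 6), n_subjects = 2,
                      noise_sd = 0, sbat_lipid_ff_change = c(0, 0),
                      sbat_perfusion_ff_change = c(0, 0),
                      sat_cold_ff_change = c(0, 0),
                      sat_posture_ff_drift = c(0, 0),
                      r2s_changes = list(sbat = list(cold = c(0, 0), reversible = TRUE),
                                         sat = list(cold = c(0, 0), reversible = FALSE)))
  led <- coolbat:::draw_cohort_truth(spec)$ledger
  for (col in c("sbat_ff", "sat_ff", "sbat_r2s", "sat_r2s")) {
    w <- reshape(led[, c("subject", "state", col)], direction = "wide",
                 idvar = "subject", timevar = "state")
    expect_equal(w[[paste0(col, ".Cold")]], w[[paste0(col, ".Baseline")]])
    expect_equal(w[[paste0(col, ".Reheated")]], w[[paste0(col, ".Baseline")]])
  }
  sub <- coolbat:::simulate_subject(spec, 1,
                                    acquisition_protocol(grid_shape = c(24, 24, 6)),
                                    fat_spectrum())
  ## the states share tissue parameters and differ by recorded motion only
  expect_equal(sub$Cold$truth$tissue_params, sub$Baseline$truth$tissue_params)
  expect_true(any(sub$Cold$motion$translation != 0) ||
                any(sub$Cold$motion$rotation != 0))
  expect_equal(sum(label_mask(sub$Cold$truth, "sbat")),
               sum(label_mask(sub$Baseline$truth, "sbat")), tolerance = 0.1)
})

test_that("simulate_cohort assembles the full study and its exact ledger", {
  spec <- cohort_spec(seed = 14, grid_shape = c(24, 24, 6), n_subjects = 2)
  sim <- simulate_cohort(spec)
  expect_length(sim$subjects, 2)
  expect_equal(nrow(sim$ledger), 2 * 3)
  expect_setequal(as.character(unique(sim$ledger$state)),
                  c("Baseline", "Cold", "Reheated"))
  ## the ledger value is the exact assigned tissue FF of the phantom
  tr <- sim$subjects[[1]]$Baseline$truth
  row <- sim$ledger[sim$ledger$subject == 1 & sim$ledger$state == "Baseline", ]
  expect_equal(tr$tissue_params$ff[tr$tissue_params$tissue == "sbat"],
               row$sbat_ff)
})
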