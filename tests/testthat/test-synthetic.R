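# Synthetic cohort generator: determinism, target recovery, covariates.

test_that("identical config and seed give bit-identical cohorts", {
  cc <- cohort_config(n_participants = 6, days = 3, seed = 42)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$labels, b$labels)
})

test_that("subtype apportionment reproduces the reference cluster sizes", {
  cc <- cohort_config(n_participants = 208, seed = 1)
  coh <- simulate_cohort(cc, mode = "measures")
  expect_equal(as.vector(table(coh$labels$subtype)[
    names(pb_reference_profiles()$n)]), c(46, 114, 48))
  # every participant carries exactly one label
  expect_setequal(coh$labels$participant_id, coh$measures$participant_id)
  expect_false(anyDuplicated(coh$labels$participant_id) > 0)
})

test_that("invalid spec proportions and unknown measures are rejected", {
  specs <- default_subtype_specs()
  specs[[1]]$proportion <- specs[[1]]$proportion + 0.1
  expect_error(simulate_cohort(cohort_config(n_participants = 10),
                               specs = specs), "sum to 1")
  expect_error(subtype_spec("x", 1, c(bogus = 1), c(bogus = 1),
                            list()), "unknown measure")
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(epoch_length = 45), "divide 60")
})

test_that("target draws have the subtype's long-run mean and honor SD = 0", {
  specs <- default_subtype_specs()
  sed <- specs[[which(vapply(specs, `[[`, character(1), "name") ==
                        "most_sedentary")]]
  set.seed(101)
  draws <- replicate(10000, draw_measure_targets(sed)[["pct_sb"]])
  expect_lt(abs(mean(draws) - 69.0), 0.5)
  frozen <- subtype_spec("frozen", 1,
                         target_means = sed$target_means,
                         target_sds = sed$target_sds * 0,
                         covariates = sed$covariates)
  expect_equal(draw_measure_targets(frozen), sed$target_means)
})

test_that("infeasible day-part occupancy is detected", {
  specs <- default_subtype_specs()
  bad <- specs[[1]]
  means <- bad$target_means
  means[["pct_sb"]] <- 95
  means[["d_sb2"]] <- 40  # evening occupancy implied > 100
  bad <- subtype_spec("bad", 1, means, bad$target_sds * 0, bad$covariates)
  expect_error(draw_measure_targets(bad), "infeasible")
})

test_that("covariate draws match the reference distributions", {
  specs <- default_subtype_specs()
  act <- specs[[which(vapply(specs, `[[`, character(1), "name") ==
                        "most_active")]]
  set.seed(7)
  ages <- replicate(10000, generate_covariates(act)$age)
  expect_lt(abs(mean(ages) - 44.4), 0.5)
  expect_true(all(ages >= 18 & ages <= 70))
  allf <- act
  allf$covariates$male_fraction <- 0
  expect_true(all(replicate(50, generate_covariates(allf)$sex) == "F"))
  # cohort-level male fraction near the reference 56/212
  coh <- simulate_cohort(cohort_config(n_participants = 424, seed = 5),
                         mode = "measures")
  expect_lt(abs(mean(coh$covariates$sex == "M") - 56 / 212), 0.06)
  expect_true(all(coh$covariates$cis20r >= 35 & coh$covariates$cis20r <= 56))
  expect_true(all(coh$covariates$edss < 6))
  expect_true(all(coh$covariates$edss * 2 == round(coh$covariates$edss * 2)))
})

test_that("a fully sedentary subtype yields only sedentary worn epochs", {
  specs <- default_subtype_specs()
  s <- specs[[1]]
  means <- s$target_means
  means[["pct_sb"]] <- 100; means[["tt_mvpa"]] <- 0
  means[["d_sb1"]] <- 0; means[["d_sb2"]] <- 0
  deg <- subtype_spec("deg", 1, means, s$target_sds * 0, s$covariates)
  coh <- simulate_cohort(cohort_config(n_participants = 2, days = 2,
                                       invalid_day_rate = 0, seed = 3),
                         specs = list(deg))
  lab <- classify_intensity(coh$epochs$counts, coh$epochs$worn)
  expect_true(all(lab == "SB"))
})

test_that("occupancy conserves wear time and counts are in state ranges", {
  coh <- simulate_cohort(cohort_config(n_participants = 4, days = 2,
                                       invalid_day_rate = 0, seed = 9))
  lab <- classify_intensity(coh$epochs$counts, coh$epochs$worn)
  # partition: every worn epoch is exactly one of SB/light/MVPA
  expect_equal(sum(lab %in% c("SB", "light", "MVPA")), nrow(coh$epochs))
  expect_true(all(coh$epochs$counts >= 0))
  expect_true(all(coh$epochs$counts == round(coh$epochs$counts)))
})

test_that("epoch-level measures recover the drawn targets", {
  coh <- simulate_cohort(cohort_config(n_participants = 50, seed = 7))
  mt <- measures_table(coh$epochs)
  m <- merge(mt$measures, coh$targets, by = "participant_id",
             suffixes = c("", ".t"))
  expect_gte(nrow(m), 40)
  expect_true(all(abs(m$pct_sb - m$pct_sb.t) <= 3))
  expect_true(all(abs(m$tt_mvpa - m$tt_mvpa.t) <= 15))
  expect_true(all(abs(m$sb_nob - m$sb_nob.t) <= 25))
  expect_true(all(abs(m$d_sb1 - m$d_sb1.t) <= 3))
  expect_true(all(abs(m$d_sb2 - m$d_sb2.t) <= 3))
})

test_that("measure-level fast mode matches epoch mode cluster recovery", {
  cc <- cohort_config(n_participants = 120, seed = 21)
  fast <- simulate_cohort(cc, mode = "measures")
  full <- simulate_cohort(cc, mode = "epoch")
  # matched seeds: identical latent draws
  expect_identical(fast$labels, full$labels)
  expect_identical(fast$targets, full$targets)
  mt <- measures_table(full$epochs)
  truth <- setNames(fast$labels$subtype, fast$labels$participant_id)
  fit_fast <- suppressWarnings(pb_subtype(fast$measures, k = 3, seed = 2))
  fit_full <- suppressWarnings(
    pb_subtype(mt$measures, keys = pb_key_measures(), k = 3, seed = 2))
  ari_fast <- ari_of(cluster_labels(fit_fast),
                     truth[names(cluster_labels(fit_fast))])
  ari_full <- ari_of(cluster_labels(fit_full),
                     truth[names(cluster_labels(fit_full))])
  expect_lt(abs(ari_fast - ari_full), 0.05)
})

test_that("cohort CSVs round-trip through the epoch reader", {
  coh <- simulate_cohort(cohort_config(n_participants = 3, days = 2,
                                       seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_epoch_csv(file.path(dir, "epochs.csv"))
  expect_equal(nrow(back), nrow(coh$epochs))
  expect_equal(back$counts, coh$epochs$counts)
  expect_equal(back$timestamp, coh$epochs$timestamp)
})
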