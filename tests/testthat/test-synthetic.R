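test_that("a subject recording has one press marker per trial and is seed-deterministic", {
  sim <- simulate_subject(subject_spec(n_trials = 30, seed = 42))
  expect_equal(nrow(sim$recording$events), 30)
  expect_true(all(sim$recording$events$code == "press"))

  a <- simulate_subject(subject_spec(n_trials = 4, seed = 9))
  b <- simulate_subject(subject_spec(n_trials = 4, seed = 9))
  expect_identical(a$recording$signal, b$recording$signal)
  c <- simulate_subject(subject_spec(n_trials = 4, seed = 10))
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("a null subject (no potential, no oscillations) has a flat band-power topography", {
  sim <- simulate_subject(subject_spec(n_trials = 15, erp_peak_amp = 0,
                                       erp_ipsi_amp = 0,
                                       band_gains = c(gamma = 0), seed = 13))
  ep <- preprocess_recording(sim$recording, subject = "S", hand = "right")
  topo <- colMeans(band_power(psd_epochs(ep), "gamma"))
  # relative spread stays within chance levels for 15-trial channel means
  expect_lt((max(topo) - min(topo)) / mean(topo), 0.3)
})

test_that("the injected variance budget is conserved", {
  rel <- vapply(1:3, function(s) {
    spec_on <- subject_spec(n_trials = 10, seed = 300 + s)
    spec_off <- subject_spec(n_trials = 10, erp_peak_amp = 0, erp_ipsi_amp = 0,
                             band_gains = c(gamma = 0), seed = 300 + s)
    on <- simulate_subject(spec_on)
    off <- simulate_subject(spec_off)
    added <- apply(on$recording$signal, 1, var) - apply(off$recording$signal, 1, var)
    sum(added) / sum(on$predicted_added_var)
  }, numeric(1))
  expect_lt(abs(mean(rel) - 1), 0.05)
})

test_that("gamma topography peaks at the electrode nearest the latent hotspot", {
  draws <- cohort_hotspot_draws(cohort_spec(n_subjects = 10, hands = "right"), seed = 31)
  pos <- electrode_positions(default_montage())
  hits <- vapply(seq_len(nrow(draws)), function(i) {
    sim <- simulate_subject(subject_spec(
      hand = "right", hotspot = as.numeric(draws[i, c("x", "y", "z")]),
      n_trials = 10, seed = draws$rec_seed[i]))
    ep <- preprocess_recording(sim$recording, subject = draws$subject[i], hand = "right")
    topo <- colMeans(band_power(psd_epochs(ep), "gamma"))
    d <- sqrt(rowSums(sweep(pos, 2, sim$hotspot)^2))
    names(which.max(topo)) == names(which.min(d))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cohort hotspot draws honor the center, jitter, and determinism", {
  cs0 <- cohort_spec(n_subjects = 10, hotspot_jitter_sd = 0)
  d0 <- cohort_hotspot_draws(cs0, seed = 3)
  ctr <- cs0$hotspot_center
  right <- d0[d0$hand == "right", ]
  left <- d0[d0$hand == "left", ]
  expect_true(all(abs(as.matrix(right[, c("x", "y", "z")]) -
                        rep(ctr, each = nrow(right))) < 1e-12))
  expect_true(all(abs(as.matrix(left[, c("x", "y", "z")]) -
                        rep(ctr * c(-1, 1, 1), each = nrow(left))) < 1e-12))

  d1 <- cohort_hotspot_draws(cohort_spec(n_subjects = 100, hands = "right",
                                         hotspot_jitter_sd = 1), seed = 8)
  sds <- apply(as.matrix(d1[, c("x", "y", "z")]), 2, sd)
  expect_true(all(sds > 0.8 & sds < 1.2))

  expect_identical(cohort_hotspot_draws(cohort_spec(), seed = 5),
                   cohort_hotspot_draws(cohort_spec(), seed = 5))
})

test_that("simulated cohorts are reproducible tibbles with one recording per row", {
  cs <- cohort_spec(n_subjects = 2, hands = "right", n_trials = 3)
  co <- simulate_cohort(cs, seed = 4)
  expect_s3_class(co, "hotspot_cohort")
  expect_equal(nrow(co), 2)
  co2 <- simulate_cohort(cs, seed = 4)
  expect_identical(co$recording[[1]]$signal, co2$recording[[1]]$signal)
  expect_identical(cohort_truths(co), cohort_truths(co2))
})

test_that("the 10-pulse MEP rule accepts strictly more than 5 suprathreshold responses", {
  expect_true(mep_accepts_hotspot(c(rep(60, 6), rep(20, 4))))
  expect_false(mep_accepts_hotspot(c(rep(60, 5), rep(20, 5))))
  expect_false(mep_accepts_hotspot(rep(0, 10)))
  # threshold is exclusive: exactly 50 uV does not count
  expect_false(mep_accepts_hotspot(rep(50, 10)))
  expect_error(mep_accepts_hotspot(rep(60, 9)), "exactly 10")
  expect_error(mep_accepts_hotspot(c(rep(60, 9), -1)), "non-negative")
})
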