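test_that("subject parameters are deterministic and centered on group scales", {
  spec <- cohort_spec(global_seed = 7)
  p1 <- make_subject_params(spec, "control", 1)
  p2 <- make_subject_params(spec, "control", 1)
  expect_identical(p1, p2)

  expect_error(make_subject_params(spec, "patient", 1), "patient")

  # group centers: average draws over many subjects approach the Table-scale
  # defaults (65.30 bpm control mean HR, 1.20 bpm prevalent HR SD)
  big <- cohort_spec(n_control = 2000, n_prodromal = 1, n_prevalent = 2000,
                     global_seed = 11)
  ctrl_means <- vapply(1:2000, function(i) make_subject_params(big, "control", i)$hr_mean,
                       numeric(1))
  prev_sds <- vapply(1:2000, function(i) make_subject_params(big, "prevalent", i)$hr_sd,
                     numeric(1))
  expect_equal(mean(ctrl_means), 65.30, tolerance = 0.01)
  expect_equal(mean(prev_sds), 1.20, tolerance = 0.20)

  # morphology grading: none / intermediate / maximal
  expect_identical(make_subject_params(spec, "control", 2)$morph_delta, 0)
  expect_identical(make_subject_params(spec, "prodromal", 2)$morph_delta, 0.5)
  expect_identical(make_subject_params(spec, "prevalent", 2)$morph_delta, 1.0)
})

test_that("RR series covers the duration and matches its HR targets", {
  spec <- cohort_spec(hr_mean_spread = 0, hr_sd_spread = 0,
                      hr_mean = 60, hr_sd = 0)
  p <- make_subject_params(spec, "control", 1)
  rr <- generate_rr_series(p, 10)
  expect_true(all(rr == 1.0))
  expect_length(rr, 10)

  p2 <- make_subject_params(cohort_spec(global_seed = 3), "control", 1)
  p2$hr_mean <- 65
  p2$hr_sd <- 2.6
  rr2 <- generate_rr_series(p2, 60 / 65 * 10000)
  hr <- 60 / rr2
  expect_gt(length(rr2), 9000)
  expect_equal(mean(hr), 65, tolerance = 0.01 * 65)
  expect_equal(sd(hr), 2.6, tolerance = 0.01 * 2.6 + 3 * 2.6 / sqrt(length(hr)))

  expect_true(all(rr2 > 0))
  expect_gte(sum(rr2), 60 / 65 * 10000)

  # degenerate: one beat slower than the record
  p3 <- p2
  p3$hr_mean <- 2 / 60 * 60  # 2 bpm -> RR = 30 s... but truncation floors at 20 bpm
  p3$hr_mean <- 20
  p3$hr_sd <- 0
  expect_warning(generate_rr_series(p3, 2), "single beat")
})

test_that("synthesized records have the right shape and ground truth", {
  spec <- cohort_spec()
  p <- make_subject_params(spec, "prodromal", 1)
  rec <- synthesize_ecg(p, spec)
  expect_length(rec$samples, round(10 * 500))
  expect_true(all(diff(rec$r_times) > 0.25))
  expect_true(all(rec$r_times >= 0 & rec$r_times < 10))

  # no modulation, no noise, fixed HR -> strictly periodic waveform
  spec0 <- cohort_spec(hr_mean = 60, hr_sd = 0, hr_mean_spread = 0,
                       hr_sd_spread = 0, morph_delta = 0, noise_sd = 0,
                       alt_depth = 0, osc_amp = 0)
  rec0 <- synthesize_ecg(make_subject_params(spec0, "control", 1), spec0)
  period <- 500  # one beat at 60 bpm
  interior <- rec0$samples[1001:3000]
  shifted <- rec0$samples[1001:3000 + period]
  expect_lt(max(abs(interior - shifted)), 1e-5)
})

test_that("cohort generation is reproducible and respects the group design", {
  spec <- cohort_spec(n_control = 3, n_prodromal = 2, n_prevalent = 1,
                      global_seed = 5)
  coh <- generate_cohort(spec)
  expect_length(coh$records, 6)
  expect_equal(as.integer(table(factor(coh$manifest$group,
                                       levels = c("control", "prodromal", "prevalent")))),
               c(3, 2, 1))

  coh2 <- generate_cohort(spec)
  expect_identical(lapply(coh$records, `[[`, "samples"),
                   lapply(coh2$records, `[[`, "samples"))

  empty <- generate_cohort(cohort_spec(n_control = 0, n_prodromal = 0,
                                       n_prevalent = 0))
  expect_length(empty$records, 0)
  expect_identical(nrow(empty$manifest), 0L)

  # write/read round trip is byte-identical across regenerations
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(coh, d1)
  write_cohort(generate_cohort(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_cohort(d1)
  expect_equal(back$records[["control_001"]]$samples,
               coh$records[["control_001"]]$samples, tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mean HR recovered from detected peaks matches the target at zero HR variance", {
  spec <- cohort_spec(hr_sd = 0, hr_sd_spread = 0, noise_sd = 0,
                      global_seed = 21)
  for (g in c("control", "prodromal", "prevalent")) {
    p <- make_subject_params(spec, g, 1)
    rec <- synthesize_ecg(p, spec)
    hr <- instantaneous_hr(detect_r_peaks(rec))
    expect_lt(abs(mean(hr) - p$hr_mean), 1.0)
  }
})

test_that("prodromal dissimilarity to the references falls as its duty fraction rises", {
  # effect-size monotonicity of the generator, assessed on feature means
  ref_spec <- cohort_spec(n_control = 0, n_prodromal = 0, n_prevalent = 10,
                          global_seed = 31)
  refs <- lapply(generate_cohort(ref_spec)$records, downsample_to_8hz)
  mean_feat <- vapply(c(0, 0.5, 1.0), function(duty) {
    spec <- cohort_spec(n_control = 0, n_prodromal = 25, n_prevalent = 0,
                        global_seed = 32,
                        morph_delta = c(0, duty, 1))
    tgts <- lapply(generate_cohort(spec)$records, downsample_to_8hz)
    mean(pspr_feature_matrix(tgts, refs))
  }, numeric(1))
  expect_true(all(diff(mean_feat) < 0))
})
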