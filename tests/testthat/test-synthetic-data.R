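test_that("phantom construction is deterministic and hosts every region", {
  s1 <- simulate_sessions(test_phantom_spec(seed = 7))
  s2 <- simulate_sessions(test_phantom_spec(seed = 7))
  expect_identical(s1$sessions$noncontrast$t1, s2$sessions$noncontrast$t1)
  expect_identical(s1$sessions$interictal$t1, s2$sessions$interictal$t1)
  expect_identical(s1$labels$labels, s2$labels$labels)

  ph <- make_phantom(phantom_spec())
  counts <- vapply(ph$labels$dict, function(v) sum(ph$labels$labels == v),
                   integer(1))
  expect_true(all(counts >= 30))
  # SSS restricted to exactly 3 consecutive coronal slices
  sss_j <- unique(which(roi_mask(ph$labels, "sss"), arr.ind = TRUE)[, 2])
  expect_length(sss_j, 3L)
  expect_equal(diff(sort(sss_j)), c(1L, 1L))

  expect_error(make_phantom(phantom_spec(shape = c(32, 32, 32))), "too small")
  expect_error(phantom_spec(shape = c(16, 16, 16)), "too small")
})

test_that("crisp rendering assigns exactly the tissue T1 inside each region", {
  spec <- phantom_spec(pv_sigma = 0)
  ph <- make_phantom(spec)
  tofl <- c(cortex = "cortex", hippocampus_l = "hippocampus",
            amygdala_r = "amygdala", piriform_l = "piriform",
            white_matter = "white_matter", csf = "csf", sss = "blood")
  for (nm in names(tofl)) {
    vox <- ph$t1$t1[roi_mask(ph$labels, nm)]
    expect_true(all(vox == spec$t1_tissues[[tofl[[nm]]]]), label = nm)
  }
  # partial-volume rendering keeps interiors exact but mixes boundaries
  ph_pv <- make_phantom(phantom_spec(pv_sigma = 0.6))
  wm <- ph_pv$t1$t1[roi_mask(ph_pv$labels, "white_matter")]
  expect_true(any(wm == 850) && any(wm != 850))
})

test_that("relaxivity model shortens T1 correctly and guards its domain", {
  t1 <- qt1_volume(array(1000, c(3, 3, 3)))
  # hand arithmetic: R1 = 1 s^-1, r1 C = 0.5 s^-1 -> T1_post = 2000/3 ms
  post <- apply_contrast(t1, array(0.1, c(3, 3, 3)), r1 = 5)
  expect_equal(post$t1[2, 2, 2], 2000 / 3, tolerance = 1e-13)

  # zero dose is the exact identity
  same <- apply_contrast(t1, array(0, c(3, 3, 3)), r1 = 5)
  expect_identical(same$t1, t1$t1)

  # doubling the concentration never increases T1 anywhere
  set.seed(1)
  conc <- array(stats::runif(27, 0, 0.5), c(3, 3, 3))
  p1 <- apply_contrast(t1, conc, r1 = 5)
  p2 <- apply_contrast(t1, 2 * conc, r1 = 5)
  expect_true(all(p2$t1 <= p1$t1))
  expect_true(all(p1$t1 <= t1$t1))

  expect_error(apply_contrast(t1, array(-0.1, c(3, 3, 3))), "non-negative")
  expect_error(apply_contrast(t1, array(0, c(2, 2, 2))), "shape")
})

test_that("session simulation honors the leakage mechanism exactly", {
  # no leakage, no noise, no motion: Delta-qT1_ni is identically zero
  # outside the vascular reference
  spec <- test_phantom_spec(noise_sd = 0, motion_mm = 0, motion_deg = 0)
  sim <- simulate_sessions(spec)
  d_ni <- sim$sessions$noncontrast$t1 - sim$sessions$interictal$t1
  outside_sss <- !roi_mask(sim$labels, "sss")
  expect_true(all(d_ni[outside_sss] == 0))
  # conservation: noncontrast session is the baseline phantom exactly
  expect_identical(sim$sessions$noncontrast$t1, make_phantom(spec)$t1$t1)

  # piriform leakage raises the piriform ground truth above cortex
  spec_l <- test_phantom_spec(noise_sd = 0, motion_mm = 0, motion_deg = 0,
                              leakage = list(interictal = c(piriform_l = 0.05,
                                                            piriform_r = 0.05),
                                             postictal = c()))
  tru <- simulate_sessions(spec_l)$truth
  expect_gt(tru$delta_ni[tru$roi == "piriform_l"],
            tru$delta_ni[tru$roi == "cortex"])
  expect_equal(tru$delta_ni[tru$roi == "cortex"], 0)
})

test_that("ground-truth Delta-qT1 matches the analytic relaxivity value", {
  # crisp rendering: every piriform voxel carries exactly the tissue T1, so
  # the ROI-mean ground truth equals the closed form
  spec <- test_phantom_spec(pv_sigma = 0, noise_sd = 0, motion_mm = 0,
                            motion_deg = 0, c_vasc_ii = 0.5, r1 = 5,
                            leakage = list(interictal = c(piriform_l = 0.04),
                                           postictal = c()))
  tru <- simulate_sessions(spec)$truth
  t1_pre <- spec$t1_tissues[["piriform"]]
  conc <- 0.04 * 0.5
  expected <- t1_pre - 1 / (1 / t1_pre + (5 / 1000) * conc)
  expect_equal(tru$delta_ni[tru$roi == "piriform_l"], expected,
               tolerance = 1e-12)
  sss_expected <- spec$t1_tissues[["blood"]] -
    1 / (1 / spec$t1_tissues[["blood"]] + (5 / 1000) * 0.5)
  expect_equal(tru$delta_ni[tru$roi == "sss"], sss_expected, tolerance = 1e-12)
  expect_equal(tru$norm_ni[tru$roi == "piriform_l"], expected / sss_expected,
               tolerance = 1e-12)
})

test_that("cohort generator reproduces the designed covariate structure", {
  cs <- cohort_spec(seed = 11)
  c1 <- simulate_cohort(cs)
  c2 <- simulate_cohort(cs)
  expect_identical(c1$table, c2$table)

  expect_equal(nrow(c1$subjects), 37)
  expect_equal(sum(c1$subjects$group == "TLE"), 14)
  expect_true(all(c1$subjects$duration >= 2 & c1$subjects$duration <= 44))
  expect_true(all(c1$subjects$latency_ii >= 18 & c1$subjects$latency_ii <= 266))

  # memory scores: normative N(100, 10) puts Phi(-1) ~ 0.159 below 90;
  # binomial 3-SE band on 5 aggregated seeded cohorts of 10000
  fracs <- vapply(1:5, function(s) {
    big <- simulate_cohort(cohort_spec(n_tle = 5000, n_etle = 5000, seed = s))
    mean(big$subjects$verbal_memory < 90)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - stats::pnorm(-1)),
            3 * sqrt(0.159 * 0.841 / 50000))

  expect_error(cohort_spec(n_tle = 0), "at least one")
})

test_that("null cohorts show no systematic ROI differences", {
  # with zero effects, the mean piriform-minus-cortex difference across
  # seeded replicates is within Monte-Carlo error of zero
  set.seed(42)
  diffs <- vapply(1:200, function(r) {
    cs <- cohort_spec(n_tle = 8, n_etle = 8, duration_slope_ni = 0,
                      baseline_ni = 0, seed = 5000 + r)
    tab <- simulate_cohort(cs)$table
    ni <- tab[tab$kind == "ni", ]
    mean(ni$value[ni$roi == "piriform_l"]) - mean(ni$value[ni$roi == "cortex"])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("an injected duration slope is recovered by OLS at n = 37", {
  cs <- cohort_spec(duration_slope_ni = 0.0015, seed = 9)
  tab <- simulate_cohort(cs)$table
  ni <- tab[tab$kind == "ni" & tab$roi == "cortex", ]   # independent rows
  fit <- fit_linear_model(ni, "value", terms = "duration")
  b <- fit$coefficients[fit$coefficients$term == "duration", ]
  expect_lt(abs(b$estimate - 0.0015), 2 * b$se)
})
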