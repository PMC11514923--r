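make_vol <- function(vals, session = "noncontrast", dim3 = c(4, 4, 4)) {
  qt1_volume(array(vals, dim3), session = session)
}

test_that("subtraction maps follow the session arithmetic", {
  nc <- make_vol(1200, "noncontrast")
  ii <- make_vol(1100, "interictal")
  pi_ <- make_vol(1000, "postictal")

  d_ni <- compute_delta(nc, ii, "ni")
  expect_true(all(d_ni$data == 100))
  d_ip <- compute_delta(ii, pi_, "ip")
  expect_true(all(d_ip$data == 100))

  # identical inputs give the all-zero map
  zero <- compute_delta(nc, make_vol(1200, "interictal"), "ni")
  expect_true(all(zero$data == 0))

  # session labels are checked against the requested kind
  expect_error(compute_delta(ii, pi_, "ni"), "requires sessions")
  expect_error(compute_delta(nc, make_vol(1100, "interictal", c(3, 3, 3)), "ni"),
               "shape")
  # the valid mask is the AND of the input masks
  nc2 <- nc; nc2$mask[1, 1, 1] <- FALSE
  d2 <- compute_delta(nc2, ii, "ni")
  expect_false(d2$mask[1, 1, 1])
  expect_true(is.na(d2$data[1, 1, 1]))
})

test_that("SSS normalization divides by the reference mean and guards zero", {
  labels <- roi_label_map(array(c(rep(1L, 32), rep(40L, 32)), c(4, 4, 4)),
                          dict = c(cortex = 1L, sss = 40L))
  data <- array(c(rep(100, 32), rep(200, 32)), c(4, 4, 4))
  map <- delta_qt1_map(data, "ni", mask = array(TRUE, c(4, 4, 4)))

  nm <- normalize_by_sss(map, labels)
  expect_equal(nm$sss_mean, 200)
  expect_true(all(nm$data[labels$labels == 1L] == 0.5))
  expect_equal(mean(nm$data[labels$labels == 40L]), 1)   # SSS mean is 1
  expect_true(nm$normalized)
  expect_error(normalize_by_sss(nm, labels), "already normalized")

  # scale invariance: k * raw map has the same normalized map
  map_k <- delta_qt1_map(data * 37, "ni", mask = map$mask)
  nm_k <- normalize_by_sss(map_k, labels)
  expect_equal(nm_k$data, nm$data, tolerance = 1e-14)

  # zero vascular contrast is refused
  flat <- delta_qt1_map(array(c(rep(100, 32), rep(0, 32)), c(4, 4, 4)),
                        "ni", mask = map$mask)
  expect_error(normalize_by_sss(flat, labels), "floor")
})

test_that("ROI readout reports sample statistics and explicit missingness", {
  labels <- roi_label_map(array(c(rep(1L, 16), rep(11L, 3), rep(31L, 13),
                                  rep(40L, 32)), c(4, 4, 4)),
                          dict = c(cortex = 1L, hippocampus_l = 11L,
                                   piriform_l = 31L, sss = 40L))
  data <- array(0, c(4, 4, 4))
  data[labels$labels == 1L] <- 5
  data[labels$labels == 11L] <- c(1, 2, 3)
  mask <- array(TRUE, c(4, 4, 4))
  mask[labels$labels == 31L] <- FALSE          # piriform entirely invalid
  map <- delta_qt1_map(data, "ni", mask = mask)

  expect_warning(out <- roi_readout(map, labels,
                                    rois = c("cortex", "hippocampus_l",
                                             "piriform_l")),
                 "no valid voxels")
  expect_equal(out$mean[out$roi == "cortex"], 5)
  expect_equal(out$sd[out$roi == "cortex"], 0)
  expect_equal(out$mean[out$roi == "hippocampus_l"], 2)
  expect_equal(out$sd[out$roi == "hippocampus_l"], 1)   # sample (n-1) SD
  expect_true(is.na(out$mean[out$roi == "piriform_l"]))
  expect_equal(out$n_voxels[out$roi == "piriform_l"], 0L)

  expect_error(roi_readout(map, labels, rois = "amygdala_l"), "absent")

  # hemisphere filter keeps only the requested side plus bilateral regions
  left <- suppressWarnings(roi_readout(map, labels, hemisphere = "left",
                                       rois = c("cortex", "hippocampus_l",
                                                "piriform_l")))
  expect_setequal(left$roi, c("cortex", "hippocampus_l", "piriform_l"))
})

test_that("whole-cortex label excludes the separately analyzed structures", {
  ph <- make_phantom(test_phantom_spec())
  cortex <- roi_mask(ph$labels, "cortex")
  for (nm in parenchymal_rois())
    expect_false(any(cortex & roi_mask(ph$labels, nm)))
})

test_that("readout matches ground truth exactly before any registration", {
  spec <- test_phantom_spec(noise_sd = 0, motion_mm = 0, motion_deg = 0,
                            leakage = list(interictal = c(piriform_l = 0.03,
                                                          piriform_r = 0.03),
                                           postictal = c()))
  sim <- simulate_sessions(spec)
  raw <- compute_delta(sim$sessions$noncontrast, sim$sessions$interictal, "ni")
  rr <- roi_readout(raw, sim$labels)
  m <- merge(rr, sim$truth, by = "roi")
  expect_equal(m$mean, m$delta_ni, tolerance = 1e-12)

  # running the full register -> subtract -> normalize chain on these
  # already-aligned sessions stays within 3% on the leakage regions
  res <- run_subject(sim$sessions, sim$labels)
  ni <- merge(res$readout[res$readout$kind == "ni", ], sim$truth, by = "roi")
  nz <- ni$norm_ni != 0
  expect_lt(max(abs(ni$mean[nz] / ni$norm_ni[nz] - 1)), 0.03)
  expect_lt(max(abs(ni$mean[!nz])), 0.005)
})

test_that("the piriform biomarker responds monotonically to leakage while cortex stays fixed", {
  lam <- c(0.01, 0.03, 0.06)
  readouts <- lapply(lam, function(l) {
    spec <- test_phantom_spec(noise_sd = 0, motion_mm = 0, motion_deg = 0,
                              leakage = list(interictal = c(piriform_l = l,
                                                            piriform_r = l),
                                             postictal = c()))
    sim <- simulate_sessions(spec)
    raw <- compute_delta(sim$sessions$noncontrast, sim$sessions$interictal, "ni")
    nm <- normalize_by_sss(raw, sim$labels)
    roi_readout(nm, sim$labels)
  })
  piri <- vapply(readouts, function(r) r$mean[r$roi == "piriform_l"], numeric(1))
  cort <- vapply(readouts, function(r) r$mean[r$roi == "cortex"], numeric(1))
  sss <- vapply(readouts, function(r) r$mean[r$roi == "sss"], numeric(1))
  expect_true(all(diff(piri) > 0))
  expect_true(all(cort == 0))
  expect_equal(sss, rep(1, 3), tolerance = 1e-14)
})
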