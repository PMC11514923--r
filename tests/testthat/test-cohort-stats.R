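test_that("Kruskal-Wallis H matches hand-computed rank statistics", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H, 27 / 7,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(1, 2, 3))$H, 2, tolerance = 1e-12)

  allsame <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p, 1)

  expect_error(kruskal_wallis(list(c(1, 2))), "two groups")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "non-empty")
  expect_error(kruskal_wallis(list(1, 2)), "three observations")
})

test_that("Kruskal-Wallis p is consistent with exhaustive permutation on tiny samples", {
  set.seed(31)
  for (r in 1:4) {
    groups <- list(round(stats::rnorm(3), 1), round(stats::rnorm(3), 1),
                   round(stats::rnorm(4), 1))
    p_chisq <- kruskal_wallis(groups)$p
    p_perm <- kw_perm_p_oracle(groups)
    # chi-square approximation agrees with the exact permutation null to a
    # documented consistency band at these sizes
    expect_lt(abs(p_chisq - p_perm), 0.15)
  }
})

test_that("Dunn z agrees with a brute-force rank-sum oracle for two groups", {
  set.seed(13)
  for (r in 1:8) {
    x <- stats::rnorm(sample(4:9, 1))
    y <- stats::rnorm(sample(4:9, 1)) + stats::runif(1, -1, 1)
    if (r %% 2 == 0) { x <- round(x); y <- round(y) }   # force ties
    dn <- dunn_posthoc(list(a = x, b = y))
    expect_equal(abs(dn$z["a", "b"]), abs(ranksum_z_oracle(x, y)),
                 tolerance = 1e-12)
  }
})

test_that("Dunn adjustment caps at one and keeps the matrix symmetric", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1.1, 2.1, 3.1, 4.1))
  dn <- dunn_posthoc(g)
  expect_equal(dn$p_adjusted["a", "b"], 1)     # identical groups
  expect_true(all(dn$p_adjusted >= 0 & dn$p_adjusted <= 1))
  expect_identical(dn$p_adjusted, t(dn$p_adjusted))
  expect_equal(unname(diag(dn$p_adjusted)), rep(1, 3))
  expect_equal(unname(diag(dn$z)), rep(0, 3))

  # Bonferroni with capping: adjusted p is exactly min(1, m * raw p)
  off <- upper.tri(dn$p_raw)
  expect_equal(dn$p_adjusted[off], pmin(1, 3 * dn$p_raw[off]),
               tolerance = 1e-14)
  holm <- dunn_posthoc(g, adjustment = "holm")
  expect_true(all(holm$p_adjusted <= dn$p_adjusted + 1e-15))
})

test_that("Glass' delta uses the reference SD and flags large effects", {
  expect_equal(as.numeric(glass_delta(c(4, 5, 6), c(4, 5, 6))), 0)

  d <- glass_delta(c(2, 2, 2), c(0, 1, 2))   # ref mean 1, sample SD 1
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "large"))

  d2 <- glass_delta(c(0, 0, 0), c(0, 1, 2))  # sign follows roi - reference
  expect_equal(as.numeric(d2), -1)

  expect_false(attr(glass_delta(c(1.5), c(0, 1, 2)), "large"))
  expect_error(glass_delta(c(1, 2), c(5, 5, 5)), "SD")
  expect_error(glass_delta(c(1, 2), c(5)), "n >= 2")
})

test_that("Glass' delta estimator is nearly unbiased at reference n = 14", {
  set.seed(97)
  for (d_true in c(0, 0.5, 1.5)) {
    est <- replicate(2000, {
      ref <- stats::rnorm(14)
      roi <- stats::rnorm(14, mean = d_true)
      as.numeric(glass_delta(roi, ref))
    })
    expect_lt(abs(mean(est) - d_true), 0.08)
  }
})

test_that("memory impairment is a strict threshold at 90", {
  expect_equal(classify_memory(89), "impaired")
  expect_equal(classify_memory(90), "unimpaired")
  expect_equal(classify_memory(110, "figural"), "unimpaired")
  expect_true(is.na(classify_memory(NA_real_)))
  expect_equal(classify_memory(c(85, 95, NA)),
               c("impaired", "unimpaired", NA_character_))
})

test_that("linear models recover exact coefficients and match the normal equations", {
  # exact fit on a noiseless line
  tab <- data.frame(duration = c(1, 2, 5, 9), value = 1 + 2 * c(1, 2, 5, 9))
  fit <- suppressWarnings(fit_linear_model(tab, "value", terms = "duration"))
  expect_equal(fit$coefficients$estimate,
               c(1, 2), tolerance = 1e-12)
  expect_lt(max(abs(stats::residuals(fit$fit))), 1e-12)

  # constructed 2-ROI table: cortex slope 0.001, piriform slope 0.002,
  # so the interaction coefficient is exactly 0.001
  dur <- c(0, 10, 20, 30)
  tab2 <- rbind(data.frame(duration = dur, roi = "cortex",
                           value = 0.01 + 0.001 * dur),
                data.frame(duration = dur, roi = "piriform_l",
                           value = 0.03 + 0.002 * dur))
  fit2 <- suppressWarnings(
    fit_linear_model(tab2, "value", terms = c("duration", "roi"),
                     interactions = TRUE))
  cf <- fit2$coefficients
  expect_equal(cf$estimate[cf$term == "duration"], 0.001, tolerance = 1e-12)
  expect_equal(cf$estimate[cf$term == "duration:roipiriform"], 0.001,
               tolerance = 1e-12)

  # oracle equivalence on random tables
  set.seed(8)
  for (r in 1:5) {
    n <- 20
    tab3 <- data.frame(duration = stats::runif(n, 0, 40),
                       latency = stats::runif(n, 18, 266),
                       roi = sample(c("cortex", "piriform_l", "amygdala_l"),
                                    n, replace = TRUE),
                       value = stats::rnorm(n))
    fit3 <- fit_linear_model(tab3, "value",
                             terms = c("duration", "latency", "roi"))
    X <- stats::model.matrix(~ duration + latency +
                               stats::relevel(factor(qt1bbb:::roi_family(tab3$roi)),
                                              "cortex"), data = tab3)
    beta <- ols_oracle(X, tab3$value)
    expect_equal(unname(fit3$coefficients$estimate), unname(as.vector(beta)),
                 tolerance = 1e-8)
  }

  # rank deficiency is refused with the aliased term named
  tab4 <- data.frame(duration = c(1, 2, 3, 4), latency = c(2, 4, 6, 8),
                     value = stats::rnorm(4))
  expect_error(fit_linear_model(tab4, "value", terms = c("duration", "latency")),
               "rank deficient")
  expect_error(fit_linear_model(tab4, "value", terms = "unknown_term"),
               "unknown terms")
})

test_that("the analysis battery respects prerequisites and row order", {
  cs <- cohort_spec(n_tle = 10, n_etle = 10,
                    effects_ni = list(TLE = c(piriform = 0.05)), seed = 21)
  tab <- simulate_cohort(cs)$table
  res <- run_group_analyses(tab)

  expect_true(all(c("roi_comparison", "duration_regression", "ipsilateral",
                    "memory") %in% names(res) | length(res$skipped) > 0))
  rc <- res$roi_comparison
  expect_true(all(rc$dunn_p_vs_cortex >= 0 & rc$dunn_p_vs_cortex <= 1))
  expect_equal(sign(rc$glass_delta[rc$group == "TLE" & rc$kind == "ni" &
                                     rc$roi == "piriform"]), 1)

  # row-order invariance of every result table
  set.seed(1)
  res2 <- run_group_analyses(tab[sample(nrow(tab)), ])
  expect_equal(res$roi_comparison, res2$roi_comparison)
  expect_equal(res$duration_regression, res2$duration_regression)

  # subjects with unknown side never enter ipsilateral outputs
  n_known <- length(unique(tab$id[tab$side != "unknown"]))
  expect_true(all(res$ipsilateral$comparison$n == n_known))

  # no subject with known side -> scenario skipped with a reason
  tab_unk <- tab
  tab_unk$side <- "unknown"
  res3 <- run_group_analyses(tab_unk, scenarios = "ipsilateral")
  expect_true("ipsilateral" %in% names(res3$skipped))
})

test_that("injected duration slopes are recovered within 2 SE in >= 93% of replicates", {
  # one row per subject (cortex) so the OLS errors are independent; the
  # stacked subject x ROI table has within-subject correlation from the
  # shared random intercept, where naive OLS intervals undercover
  hits <- vapply(1:100, function(r) {
    cs <- cohort_spec(duration_slope_ni = 0.001, seed = 3000 + r)
    ni <- simulate_cohort(cs)$table
    ni <- ni[ni$kind == "ni" & ni$roi == "cortex", ]
    fit <- fit_linear_model(ni, "value", terms = "duration")
    b <- fit$coefficients[fit$coefficients$term == "duration", ]
    abs(b$estimate - 0.001) <= 2 * b$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})
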