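test_that("efflux ratio, candidacy band and transport-mode calls", {
  ab4 <- papp_summary("4", "AP_BL", 9.91e-6, 0.21e-6, 6)
  ba4 <- papp_summary("4", "BL_AP", 18.97e-6, 0.38e-6, 6)
  er4 <- efflux_ratio(ab4, ba4)
  expect_equal(round(er4$ratio, 2), 1.91)
  expect_true(er4$pgp_candidate)                  # high band, >= 1.9
  expect_identical(er4$transport_mode, "passive-consistent")  # still < 2.0
  expect_identical(er4$ratio_sd_method, "error-propagation")

  ab10 <- papp_summary("10", "AP_BL", 7.29e-6, 0.17e-6, 6)
  ba10 <- papp_summary("10", "BL_AP", 3.73e-6, 0.33e-6, 6)
  er10 <- efflux_ratio(ab10, ba10)
  expect_equal(round(er10$ratio, 2), 0.51)
  expect_true(er10$pgp_candidate)                 # low band, <= 0.55
  expect_identical(er10$absorption_class, "moderate")

  sym_ab <- papp_summary("s", "AP_BL", 2e-5)
  sym_ba <- papp_summary("s", "BL_AP", 2e-5)
  ers <- efflux_ratio(sym_ab, sym_ba)
  expect_equal(ers$ratio, 1.0)
  expect_false(ers$pgp_candidate)
  expect_identical(ers$transport_mode, "passive-consistent")

  expect_error(efflux_ratio(ab4, papp_summary("10", "BL_AP", 1e-5)),
               class = "twr_validation_error")
})

test_that("swapping directions inverts the ratio exactly", {
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 1e-6, 5e-5)
    b <- runif(1, 1e-6, 5e-5)
    f <- efflux_ratio(papp_summary("c", "AP_BL", a),
                      papp_summary("c", "BL_AP", b))$ratio
    g <- efflux_ratio(papp_summary("c", "AP_BL", b),
                      papp_summary("c", "BL_AP", a))$ratio
    expect_equal(f * g, 1, tolerance = 1e-12)
  }
})

test_that("paired replicates yield a paired-ratio SD", {
  s_ab <- lapply(1:4, function(r) {
    make_series(90, 0.54 * c(1, 1.1, 0.9, 1.05)[r], id = "c", rep = r)
  })
  s_ba <- lapply(1:4, function(r) {
    make_series(90, 1.08 * c(1, 1.1, 0.9, 1.05)[r], id = "c",
                direction = "BL_AP", rep = r)
  })
  er <- efflux_ratio(papp_estimate(s_ab), papp_estimate(s_ba))
  expect_identical(er$ratio_sd_method, "paired-replicates")
  # perfectly correlated replicates: per-replicate ratios are constant
  expect_equal(er$ratio_sd, 0, tolerance = 1e-12)
})

test_that("absorption classes follow the strict 1e-5 / 1e-6 thresholds", {
  expect_identical(absorption_class(4.36e-5), "well")      # caffeine
  expect_identical(absorption_class(7.61e-7), "poor")      # atenolol
  expect_identical(absorption_class(9.91e-6), "moderate")  # compound 4
  # boundaries fall in the moderate class (strict inequalities)
  expect_identical(absorption_class(1e-5), "moderate")
  expect_identical(absorption_class(1e-6), "moderate")
  # monotone in Papp
  grid <- 10^seq(-7, -4, length.out = 25)
  classes <- vapply(grid, absorption_class, "")
  ord <- c(poor = 1, moderate = 2, well = 3)
  expect_true(all(diff(ord[classes]) >= 0))
})

test_that("inhibitor contrast: hand arithmetic, null case, single replicate", {
  r <- inhibition_contrast(c(4.4, 4.5, 4.54), c(1.5, 1.6, 1.64))
  expect_equal(r$pct_change,
               100 * (mean(c(4.4, 4.5, 4.54)) - mean(c(1.5, 1.6, 1.64))) /
                 mean(c(4.4, 4.5, 4.54)))
  expect_true(r$significant)

  # the probe-substrate means: 4.47 -> 1.58 is a 64.65% drop
  expect_equal(inhibition_contrast(4.47, 1.58)$pct_change,
               100 * (4.47 - 1.58) / 4.47, tolerance = 1e-12) |>
    suppressWarnings()

  same <- inhibition_contrast(c(2, 2.1, 1.9), c(2, 2.1, 1.9))
  expect_equal(same$pct_change, 0)
  expect_false(same$significant)

  expect_warning(one <- inhibition_contrast(2.0, c(1.0, 1.1)),
                 class = "twr_no_test")
  expect_true(is.na(one$p_value))
})

test_that("a strong inhibitor effect is detected in nearly all simulations", {
  hits <- vapply(1:500, function(i) {
    sc <- sim_scenario(true_papp = 2e-5, efflux_multiplier = 2,
                       inhibitor_effect = 1, noise_cv = 0.05, sink = TRUE,
                       times = 90, n_replicates = 6, seed = 20000 + i)
    ratios <- replicate_ratios(simulate_transport(sc)$data)
    isTRUE(inhibition_contrast(ratios$baseline, ratios$inhibitor)$significant)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("intracellular accumulation fold change", {
  acc <- accumulation_fold(34.51, 153.64)
  expect_equal(round(acc$fold_change, 2), 4.45)
  expect_equal(accumulation_fold(c(5, 5), c(5, 5))$fold_change, 1.0)
  expect_equal(accumulation_fold(c(10, 10), c(30, 30))$fold_change, 3.0)
  expect_error(accumulation_fold(c(10, -1), c(30, 30)),
               class = "twr_validation_error")
})

test_that("monolayer validation passes on reference markers and fails on defects", {
  caf <- papp_summary("caffeine", "AP_BL", 4.36e-5, 4.86e-6, 6)
  ate <- papp_summary("atenolol", "AP_BL", 7.61e-7, 0.16e-6, 6)
  teer <- c(1321, 1548, 1586, 1635, 1573)

  v <- model_validation_report(caf, ate, 1.58, teer)
  expect_true(v$pass)
  expect_length(v$reasons, 0)

  bad_ate <- papp_summary("atenolol", "AP_BL", 5e-5)
  v2 <- model_validation_report(caf, bad_ate, 1.58, teer)
  expect_false(v2$pass)
  expect_true(any(grepl("poor-marker not poor", v2$reasons)))

  v3 <- model_validation_report(caf, ate, 1.58, c(teer, 800))
  expect_false(v3$pass)

  v4 <- model_validation_report(caf, ate, 4.4, teer)  # probe not inhibited
  expect_false(v4$pass)

  expect_error(model_validation_report(NULL, ate, 1.58, teer),
               class = "twr_incomplete_validation")
})

test_that("classify_compounds produces one classified row per compound", {
  est <- apr_papp_estimates()
  cl <- classify_compounds(est[!est$compound_id %in% c("caffeine", "atenolol"), ])
  expect_equal(nrow(cl), 12)
  expect_setequal(cl$absorption_class[cl$compound_id %in% c("4", "10")],
                  "moderate")
  expect_identical(cl$absorption_class[cl$compound_id == "11"], "well")
  expect_true(all(cl$pgp_candidate[cl$compound_id %in% c("4", "10")]))
})
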