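test_that("calibration fit reproduces an exact line and its inversion", {
  x <- c(1, 50, 150)
  std <- data.frame(compound_id = "umbelliferone", nominal_conc = x,
                    peak_area = 14.82 * x + 4.21)
  cur <- fit_calibration(std)
  expect_equal(cur$slope, 14.82)
  expect_equal(cur$intercept, 4.21)
  expect_equal(cur$r, 1.0)
  expect_equal(cur$range_low, 1)
  expect_equal(cur$range_high, 150)

  # inverting the regression at the 50 uM response
  expect_equal(unclass(back_calculate(cur, 745.21))[1], 50, tolerance = 1e-12)
  # area equal to the intercept maps to zero concentration (flagged as
  # below the validated range, not rejected)
  expect_warning(zero <- back_calculate(cur, 4.21),
                 class = "twr_out_of_range")
  expect_equal(as.numeric(zero), 0)
})

test_that("identity-slope curve back-calculates areas unchanged", {
  cur <- calibration_curve("x", slope = 1, intercept = 0)
  expect_equal(as.numeric(back_calculate(cur, 7.5)), 7.5)
})

test_that("noisy fits agree with an independent closed-form OLS oracle", {
  set.seed(42)
  x <- rep(c(1, 5, 25, 75, 150), each = 2)
  y <- 10 * x + 2 + rnorm(length(x), 0, 0.5)
  std <- data.frame(compound_id = "s", nominal_conc = x, peak_area = y)
  cur <- fit_calibration(std)
  oracle <- ols_oracle(x, y)
  expect_equal(cur$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(cur$intercept, oracle$intercept, tolerance = 1e-10)
  # r^2 equals the coefficient of determination computed independently
  ss_res <- sum((y - (oracle$intercept + oracle$slope * x))^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(cur$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-10)
})

test_that("fit is invariant to standard order and round-trips noiseless data", {
  x <- c(2, 10, 40, 80, 150)
  std <- data.frame(compound_id = "s", nominal_conc = x,
                    peak_area = 12.58 * x - 22.87)
  cur1 <- fit_calibration(std)
  cur2 <- fit_calibration(std[sample(nrow(std)), ])
  expect_equal(cur1$slope, cur2$slope)
  expect_equal(cur1$intercept, cur2$intercept)
  # round-trip: predicted response back-calculates to the nominal value
  pred <- cur1$slope * x + cur1$intercept
  expect_equal(as.numeric(back_calculate(cur1, pred)), x, tolerance = 1e-10)
})

test_that("degenerate and invalid calibration designs are rejected", {
  flat <- data.frame(compound_id = "f", nominal_conc = c(1, 50, 150),
                     peak_area = c(100, 100, 100))
  expect_error(fit_calibration(flat), class = "twr_degenerate_error")
  two <- data.frame(compound_id = "f", nominal_conc = c(1, 1, 150),
                    peak_area = c(10, 11, 1500))
  expect_error(fit_calibration(two), class = "twr_degenerate_error")
  mixed <- data.frame(compound_id = c("a", "a", "b"),
                      nominal_conc = c(1, 50, 150),
                      peak_area = c(10, 500, 1500))
  expect_error(fit_calibration(mixed), class = "twr_validation_error")
})

test_that("out-of-range back-calculations are flagged, not clipped", {
  cur <- calibration_curve("x", 10, 0, range_low = 1, range_high = 150)
  expect_warning(res <- back_calculate(cur, c(50, 5000)),
                 class = "twr_out_of_range")
  expect_equal(as.numeric(res), c(5, 500))
  expect_equal(attr(res, "out_of_range"), c(FALSE, TRUE))
})

test_that("QC metrics: exact replicates, hand-computed RSD, freeze-thaw", {
  perfect <- data.frame(day = 1, conc = c(50, 50, 50))
  r <- qc_metrics(perfect, nominal = 50)
  expect_equal(r$intraday_rsd, 0)
  expect_equal(r$accuracy, 100)

  spread <- data.frame(day = 1, conc = c(45, 50, 55))
  r2 <- qc_metrics(spread, nominal = 50)
  expect_equal(r2$accuracy, 100)
  expect_equal(r2$intraday_rsd, 10)  # sd({45,50,55}) = 5; 5/50

  ft <- data.frame(day = c(1, 1, 1, 1), cycle = c(0, 0, 3, 3),
                   conc = c(50, 50, 48, 49))
  r3 <- qc_metrics(ft, nominal = 50)
  expect_equal(r3$freeze_thaw_pct, 100 * 48.5 / 50)
  expect_true(r3$freeze_thaw_ok)  # 97% is inside the +/-5% window

  expect_error(qc_metrics(data.frame(day = 1, conc = 50), nominal = 50),
               class = "twr_degenerate_error")
})

test_that("interday RSD uses the SD of day means around the grand mean", {
  d <- data.frame(day = rep(1:3, each = 3),
                  conc = c(49, 50, 51, 51, 52, 53, 47, 48, 49))
  r <- qc_metrics(d, nominal = 50)
  day_means <- c(50, 52, 48)
  expect_equal(r$interday_rsd, 100 * sd(day_means) / mean(day_means))
})

test_that("simulated QC with 3% noise lands inside the accepted accuracy window", {
  set.seed(7)
  ok <- vapply(c(5, 50, 150), function(level) {
    concs <- level * exp(rnorm(9, -0.0005, sqrt(log(1 + 0.03^2))))
    r <- qc_metrics(data.frame(day = rep(1:3, each = 3), conc = concs),
                    nominal = level)
    r$accuracy >= 85.18 && r$accuracy <= 107.71
  }, TRUE)
  expect_true(all(ok))
})

test_that("calibration simulator: exact recovery and Monte-Carlo slope calibration", {
  std <- simulate_calibration(14.82, 4.21, levels = c(1, 10, 50, 100, 150),
                              noise_cv = 0, seed = 3)
  cur <- fit_calibration(std)
  expect_equal(cur$slope, 14.82, tolerance = 1e-12)
  expect_equal(cur$intercept, 4.21, tolerance = 1e-9)
  expect_equal(cur$r, 1.0, tolerance = 1e-12)

  # 200 noisy repeats: the mean fitted slope sits within 3 SEs of truth
  slopes <- vapply(1:200, function(i) {
    s <- simulate_calibration(14.82, 4.21, levels = c(1, 10, 50, 100, 150),
                              noise_cv = 0.02, seed = 1000 + i)
    fit_calibration(s)$slope
  }, 1.0)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 14.82), 3 * se + 1e-9)

  # single level propagates to a degenerate-design error downstream
  one <- simulate_calibration(10, 0, levels = 50, noise_cv = 0, seed = 1,
                              replicates = 3)
  expect_error(fit_calibration(one), class = "twr_degenerate_error")
})
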