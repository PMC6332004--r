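test_that("appearance rate: endpoint, zero-transport and exact-line cases", {
  # 0.54 umol after 90 min -> 0.54/5400 umol/s
  expect_equal(appearance_rate(make_series(90, 0.54)), 1e-4)
  expect_equal(appearance_rate(make_series(c(30, 60, 90), c(0, 0, 0))), 0)
  # exact line Q = 2e-4 * t(s): rate independent of sampling grid
  for (grid in list(c(30, 90), c(10, 20, 40, 80, 160), c(5, 180))) {
    s <- make_series(grid, 2e-4 * grid * 60)
    expect_equal(appearance_rate(s), 2e-4, tolerance = 1e-12)
  }
  expect_error(appearance_rate(make_series(0, 0.1)),
               class = "twr_degenerate_error")  # all times zero: no rate
})

test_that("Papp combines rate, area and donor concentration correctly", {
  g <- insert_geometry(area = 1.12)
  # rate 1e-4 umol/s, C0 50 uM = 0.05 umol/cm3 -> 1e-4/(1.12*0.05)
  s <- make_series(90, 0.54, c0 = 50, geometry = g)
  expect_equal(papp(s), 1e-4 / (1.12 * 0.05), tolerance = 1e-12)
  expect_equal(papp(make_series(90, 0, c0 = 50, geometry = g)), 0)
})

test_that("Papp is invariant to joint rescaling of Q and C0", {
  g <- insert_geometry()
  s1 <- make_series(c(30, 60, 90), c(0.1, 0.2, 0.3), c0 = 50, geometry = g)
  s2 <- make_series(c(30, 60, 90), 2.5 * c(0.1, 0.2, 0.3), c0 = 125,
                    geometry = g)
  expect_equal(papp(s1), papp(s2), tolerance = 1e-12)
})

test_that("TEER gate: pass, boundary fail, and missing-with-warning", {
  expect_true(teer_gate(1321))
  expect_false(teer_gate(999.9))
  expect_false(teer_gate(1000))  # strictly above the threshold is required
  expect_warning(res <- teer_gate(NA_real_), class = "twr_missing_teer")
  expect_true(res)
  expect_error(teer_gate(1500, threshold = -1), class = "twr_validation_error")
})

test_that("sink-condition simulator round-trips the true Papp exactly", {
  sc <- sim_scenario(true_papp = 2e-5, noise_cv = 0, sink = TRUE,
                     times = c(30, 60, 90), n_replicates = 1)
  out <- simulate_transport(sc)
  d <- out$data[out$data$direction == "AP_BL", ]
  s <- transport_series("sim", "AP_BL", d$time_min, d$receiver_amount_umol,
                        50, sc$geometry)
  expect_equal(papp(s), 2e-5, tolerance = 1e-12)
})

test_that("non-sink Papp estimates converge to truth at early times", {
  g <- insert_geometry()
  early <- sim_scenario(true_papp = 2e-5, noise_cv = 0, sink = FALSE,
                        times = 1, n_replicates = 1, geometry = g)
  late <- sim_scenario(true_papp = 2e-5, noise_cv = 0, sink = FALSE,
                       times = 180, n_replicates = 1, geometry = g)
  p_of <- function(sc) {
    d <- simulate_transport(sc)$data
    d <- d[d$direction == "AP_BL", ]
    papp(transport_series("sim", "AP_BL", d$time_min,
                          d$receiver_amount_umol, 50, g))
  }
  p_early <- p_of(early)
  p_late <- p_of(late)
  expect_lt(abs(p_early - 2e-5) / 2e-5, 0.01)       # within 1% at 1 min
  expect_gt(abs(p_late - 2e-5), abs(p_early - 2e-5)) # worse at 180 min
})

test_that("mass balance arithmetic and flagging thresholds", {
  mb <- mass_balance(1.0, 0.40, 0.50, 0.05)
  expect_equal(mb$recovery_pct, 95)
  expect_equal(mb$intracellular_pct, 5)
  expect_false(mb$flagged)

  # low-recovery / high-intracellular pattern is flagged
  mb2 <- mass_balance(1.0, 0.30, 0.25, 0.11)
  expect_equal(mb2$recovery_pct, 66)
  expect_equal(mb2$intracellular_pct, 11)
  expect_true(mb2$flagged)
  expect_length(mb2$flags, 2)

  mb3 <- mass_balance(1.0, 1.0, 0, 0)
  expect_equal(mb3$recovery_pct, 100)
  expect_equal(mb3$intracellular_pct, 0)

  expect_error(mass_balance(1, -0.1, 0.5, 0), class = "twr_validation_error")
})

test_that("noiseless simulation conserves mass and recovers 100%", {
  sc <- sim_scenario(noise_cv = 0, sink = FALSE, times = c(30, 60, 90, 180),
                     n_replicates = 1)
  out <- simulate_transport(sc)
  d <- out$data[out$data$direction == "AP_BL", ]
  donor0 <- 50 / 1000 * sc$geometry$vol_ap
  # donor + receiver = dosed amount at every sampled time
  expect_equal(d$donor_amount_umol + d$receiver_amount_umol,
               rep(donor0, nrow(d)), tolerance = 1e-12)
  last <- d[nrow(d), ]
  mb <- mass_balance(donor0, last$donor_amount_umol,
                     last$receiver_amount_umol, 0)
  expect_equal(mb$recovery_pct, 100, tolerance = 1e-10)
})

test_that("interval rate profiles distinguish sink from non-sink kinetics", {
  times <- c(30, 60, 90, 120, 150, 180)
  nonsink <- simulate_transport(sim_scenario(noise_cv = 0, sink = FALSE,
                                             times = times, n_replicates = 1))
  d <- nonsink$data[nonsink$data$direction == "AP_BL", ]
  s <- make_series(d$time_min, d$receiver_amount_umol)
  rp <- rate_profile(s)
  expect_true(all(diff(rp$table$rate_umol_s) < 0))  # strictly decreasing
  expect_identical(rp$trend, "decreasing")

  sink <- simulate_transport(sim_scenario(noise_cv = 0, sink = TRUE,
                                          times = times, n_replicates = 1))
  d2 <- sink$data[sink$data$direction == "AP_BL", ]
  rp2 <- rate_profile(make_series(d2$time_min, d2$receiver_amount_umol))
  expect_identical(rp2$trend, "constant")
})

test_that("saturable efflux bends the rate-concentration curve above Km", {
  # oracle: closed-form Michaelis-Menten scaling of the BL->AP rate
  concs <- c(10, 25, 50, 75, 100, 125)
  km <- 50
  g <- insert_geometry()
  rates <- vapply(concs, function(c0) {
    sc <- sim_scenario(true_papp = 2e-5, efflux_multiplier = 3, km = km,
                       c0 = c0, noise_cv = 0, sink = TRUE, times = 90,
                       n_replicates = 1, geometry = g)
    d <- simulate_transport(sc)$data
    d <- d[d$direction == "BL_AP", ]
    appearance_rate(transport_series("sim", "BL_AP", d$time_min,
                                     d$receiver_amount_umol, c0, g))
  }, 1.0)
  oracle <- vapply(concs, function(c0) {
    p <- 2e-5 * (1 + (3 - 1) / (1 + c0 / km))
    p * g$area * c0 / 1000
  }, 1.0)
  expect_equal(rates, oracle, tolerance = 1e-10)
  rp <- rate_profile(data.frame(conc_uM = concs, rate_umol_s = rates),
                     by = "concentration")
  # local slope of rate vs concentration declines above Km
  local_slope <- diff(rates) / diff(concs)
  expect_true(all(diff(local_slope) < 0))
  expect_identical(rp$trend, "increasing")
})

test_that("papp_table aggregates replicates and applies the TEER gate", {
  sc <- sim_scenario(true_papp = 2e-5, efflux_multiplier = 2, noise_cv = 0,
                     sink = TRUE, n_replicates = 3)
  d <- simulate_transport(sc)$data
  names(d)[names(d) == "receiver_amount_umol"] <- "receiver_amount_umol"
  pt <- papp_table(d, sc$geometry)
  expect_equal(nrow(pt$replicates), 6)
  est <- pt$estimates
  expect_equal(est$mean[est$direction == "AP_BL"], 2e-5, tolerance = 1e-12)
  expect_equal(est$mean[est$direction == "BL_AP"], 4e-5, tolerance = 1e-12)
  expect_equal(est$sd, c(0, 0), tolerance = 1e-15)

  d$teer_ohm_cm2[d$replicate == 1] <- 800
  expect_warning(pt2 <- papp_table(d, sc$geometry), class = "twr_teer_fail")
  expect_equal(unique(pt2$estimates$n), 2L)
})
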