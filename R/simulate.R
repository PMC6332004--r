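#' Define a transwell simulation scenario
#'
#' Ground-truth parameters for the two-compartment transwell simulator.
#' Defaults mirror the study conditions the pipeline targets: 50 uM donor
#' concentration on a standard 12 mm insert, six replicate inserts sampled
#' at 30/60/90 min, 5% multiplicative measurement noise, and non-sink
#' kinetics (receiver back-pressure makes the transport rate decline with
#' time, as observed for these compounds).
#'
#' @param true_papp Absorptive (AP->BL) apparent permeability, cm/s.
#' @param efflux_multiplier BL->AP Papp = multiplier x AP->BL Papp; 1 means
#'   symmetric passive transport.
#' @param inhibitor_effect Fraction of the efflux asymmetry abolished by the
#'   inhibitor in the inhibitor arm: 1 = full reversal to symmetric, 0 = no
#'   effect, `NA` = no inhibitor arm simulated.
#' @param km Michaelis constant (uM) of the saturable efflux-attributable
#'   component; `Inf` (default) disables saturation.
#' @param c0 Donor concentration, uM.
#' @param geometry An [insert_geometry()].
#' @param times Sampling times, minutes.
#' @param n_replicates Replicate inserts per direction and arm.
#' @param noise_cv Multiplicative (log-normal) measurement noise coefficient
#'   of variation, as a fraction (0.05 = 5%).
#' @param sink If `TRUE`, ideal sink conditions (cumulative amount linear in
#'   time); if `FALSE` (default) the closed-form two-compartment solution.
#' @param seed Integer seed driving a per-replicate deterministic stream.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(true_papp = 2e-5, efflux_multiplier = 1,
                         inhibitor_effect = NA_real_, km = Inf, c0 = 50,
                         geometry = insert_geometry(),
                         times = c(30, 60, 90), n_replicates = 6,
                         noise_cv = 0.05, sink = FALSE, seed = 1L) {
  if (!is.finite(true_papp) || true_papp <= 0) {
    stop_validation("true_papp must be > 0")
  }
  if (!is.finite(efflux_multiplier) || efflux_multiplier <= 0) {
    stop_validation("efflux_multiplier must be > 0")
  }
  if (!is.na(inhibitor_effect) &&
      (inhibitor_effect < 0 || inhibitor_effect > 1)) {
    stop_validation("inhibitor_effect must be in [0, 1] or NA")
  }
  if (km <= 0) stop_validation("km must be > 0 (Inf disables saturation)")
  if (c0 <= 0) stop_validation("c0 must be > 0")
  if (length(times) < 1L || any(times <= 0) || any(diff(times) <= 0)) {
    stop_validation("times must be positive and strictly increasing")
  }
  if (n_replicates < 1L) stop_validation("n_replicates must be >= 1")
  if (noise_cv < 0) stop_validation("noise_cv must be >= 0")
  stopifnot(inherits(geometry, "insert_geometry"))
  structure(list(true_papp = true_papp, efflux_multiplier = efflux_multiplier,
                 inhibitor_effect = inhibitor_effect, km = km, c0 = c0,
                 geometry = geometry, times = as.numeric(times),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, sink = isTRUE(sink),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# Effective directional Papp for a scenario: the asymmetric
# (efflux-attributable) component (multiplier - 1) is scaled by
# 1/(1 + C0/Km) (saturation) and by (1 - inhibitor_effect) in the inhibitor
# arm; AP->BL keeps the base permeability.
effective_papp <- function(scenario, direction, arm = "baseline") {
  m <- scenario$efflux_multiplier
  sat <- 1 / (1 + scenario$c0 / scenario$km)
  inh <- if (arm == "inhibitor" && !is.na(scenario$inhibitor_effect)) {
    1 - scenario$inhibitor_effect
  } else 1
  m_eff <- 1 + (m - 1) * sat * inh
  if (direction == DIR_BL_AP) scenario$true_papp * m_eff else scenario$true_papp
}

# Closed-form receiver amount (umol) at times t (min) for donor conc c0
# (uM), insert geometry and permeability p (cm/s).
closed_form_q <- function(p, c0_uM, geometry, direction, times_min, sink) {
  c0 <- c0_uM / 1000                      # umol/cm3
  a <- geometry$area
  vd <- donor_volume(geometry, direction)  # cm3
  vr <- receiver_volume(geometry, direction)
  t_s <- times_min * 60
  if (sink) {
    p * a * c0 * t_s
  } else {
    k <- p * a * (1 / vd + 1 / vr)
    c0 * vd * (vr / (vd + vr)) * (1 - exp(-k * t_s))
  }
}

#' Simulate a bidirectional transwell experiment with known truth
#'
#' Generates cumulative receiver amounts per direction, replicate and (when
#' an inhibitor effect is set) arm, from the sink-condition line
#' Q(t) = Papp A C0 t or the two-compartment closed form
#' Q(t) = C0 Vd (Vr/(Vd+Vr)) (1 - exp(-kt)) with
#' k = Papp A (1/Vd + 1/Vr). Measurement noise is multiplicative
#' log-normal with the scenario's CV, applied independently per replicate
#' and time point from a per-replicate deterministic stream, so any subset
#' of the design is reproducible from the global seed.
#'
#' @param scenario A [sim_scenario()].
#' @return A `sim_output` list: `data` (tibble with columns `compound_id`,
#'   `arm`, `direction`, `replicate`, `time_min`, `receiver_amount_umol`,
#'   `donor_amount_umol` (noiseless complement), `donor_conc_uM`,
#'   `teer_ohm_cm2`) and `truth` (the scenario plus the effective
#'   directional Papp values per arm).
#' @export
simulate_transport <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  arms <- if (is.na(scenario$inhibitor_effect)) "baseline" else
    c("baseline", "inhibitor")
  g <- scenario$geometry
  nt <- length(scenario$times)
  nrep <- scenario$n_replicates
  sdlog <- sqrt(log(1 + scenario$noise_cv^2))
  blocks <- list()
  idx <- 0L
  for (arm in arms) {
    for (direction in c(DIR_AP_BL, DIR_BL_AP)) {
      p_eff <- effective_papp(scenario, direction, arm)
      q0 <- closed_form_q(p_eff, scenario$c0, g, direction, scenario$times,
                          scenario$sink)
      donor0 <- scenario$c0 / 1000 * donor_volume(g, direction)
      q <- matrix(q0, nrow = nt, ncol = nrep)
      if (scenario$noise_cv > 0) {
        for (rep in seq_len(nrep)) {
          set.seed(substream_seed(scenario$seed, idx + rep))
          q[, rep] <- q0 * rlnorm(nt, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
      }
      idx <- idx + nrep
      blocks[[length(blocks) + 1L]] <- list(
        arm = rep(arm, nt * nrep), direction = rep(direction, nt * nrep),
        replicate = rep(seq_len(nrep), each = nt),
        time_min = rep(scenario$times, nrep),
        receiver_amount_umol = as.vector(q),
        donor_amount_umol = rep(donor0 - q0, nrep))
    }
  }
  pull <- function(field) do.call(c, lapply(blocks, `[[`, field))
  data <- tibble::tibble(
    compound_id = "sim", arm = pull("arm"), direction = pull("direction"),
    replicate = pull("replicate"), time_min = pull("time_min"),
    receiver_amount_umol = pull("receiver_amount_umol"),
    donor_amount_umol = pull("donor_amount_umol"),
    donor_conc_uM = scenario$c0, teer_ohm_cm2 = 1500)
  truth <- list(
    scenario = scenario,
    papp = lapply(setNames(nm = arms), function(a) {
      c(AP_BL = effective_papp(scenario, DIR_AP_BL, a),
        BL_AP = effective_papp(scenario, DIR_BL_AP, a))
    }))
  structure(list(data = data, truth = truth), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  sc <- x$truth$scenario
  cat(sprintf("<sim_output> %d rows | true Papp %.3g cm/s, multiplier %.2g, %s, cv %.1f%%\n",
              nrow(x$data), sc$true_papp, sc$efflux_multiplier,
              ifelse(sc$sink, "sink", "non-sink"), 100 * sc$noise_cv))
  invisible(x)
}

#' Estimate Papp and the efflux ratio from simulated (or real) tidy data
#'
#' Convenience wrapper: runs [papp_table()] per arm and computes the efflux
#' ratio from paired replicates.
#'
#' @param data Tidy transport tibble (as from [simulate_transport()]`$data`
#'   or [read_transport_csv()]); an `arm` column is optional.
#' @param geometry An [insert_geometry()].
#' @return Tibble with one row per arm: estimated AP_BL and BL_AP Papp
#'   (mean, sd), the efflux ratio and its paired-replicate SD.
#' @export
estimate_from_data <- function(data, geometry = insert_geometry()) {
  if (!"arm" %in% names(data)) data$arm <- "baseline"
  rows <- lapply(split(data, data$arm), function(d) {
    pt <- papp_table(d, geometry)
    reps <- pt$replicates
    ab <- reps[reps$direction == DIR_AP_BL, , drop = FALSE]
    ba <- reps[reps$direction == DIR_BL_AP, , drop = FALSE]
    ratios <- if (nrow(ab) == nrow(ba) && nrow(ab) > 0L) {
      ba$papp_cm_s[order(ba$replicate)] / ab$papp_cm_s[order(ab$replicate)]
    } else NA_real_
    tibble::tibble(
      arm = d$arm[1L],
      papp_ap_bl = mean(ab$papp_cm_s), papp_ap_bl_sd = sd(ab$papp_cm_s),
      papp_bl_ap = mean(ba$papp_cm_s), papp_bl_ap_sd = sd(ba$papp_cm_s),
      n = nrow(ab),
      efflux_ratio = mean(ba$papp_cm_s) / mean(ab$papp_cm_s),
      ratio_sd = if (all(is.na(ratios))) NA_real_ else sd(ratios))
  })
  dplyr::bind_rows(rows)
}

#' Per-replicate efflux ratios from simulated data, by arm
#'
#' @param data Tidy transport tibble with an `arm` column.
#' @param geometry An [insert_geometry()].
#' @return Named list of numeric ratio vectors, one per arm.
#' @export
replicate_ratios <- function(data, geometry = insert_geometry()) {
  if (!"arm" %in% names(data)) data$arm <- "baseline"
  lapply(split(data, data$arm), function(a) {
    per_dir <- function(dir) {
      vapply(sort(unique(a$replicate)), function(r) {
        d <- a[a$direction == dir & a$replicate == r, , drop = FALSE]
        d <- d[order(d$time_min), , drop = FALSE]
        papp(transport_series(d$compound_id[1L], dir, d$time_min,
                              d$receiver_amount_umol, d$donor_conc_uM[1L],
                              geometry, r))
      }, 1.0)
    }
    per_dir(DIR_BL_AP) / per_dir(DIR_AP_BL)
  })
}

#' Simulate HPLC calibration standards
#'
#' Peak areas follow area = slope x conc + intercept, perturbed by
#' multiplicative log-normal noise with the given CV.
#'
#' @param true_slope,true_intercept Line coefficients.
#' @param levels Nominal concentrations, uM.
#' @param noise_cv Fractional CV of the multiplicative noise (0 = exact).
#' @param seed Integer seed.
#' @param replicates Standards per level.
#' @param compound_id Identifier.
#' @return Tibble of calibration standards (`compound_id`, `nominal_conc`,
#'   `peak_area`).
#' @export
simulate_calibration <- function(true_slope, true_intercept, levels,
                                 noise_cv = 0, seed = 1L, replicates = 1L,
                                 compound_id = "sim") {
  if (length(levels) < 1L) stop_validation("levels must be nonempty")
  x <- rep(as.numeric(levels), each = replicates)
  mu <- true_slope * x + true_intercept
  y <- mu
  if (noise_cv > 0) {
    set.seed(substream_seed(seed, 1L))
    sdlog <- sqrt(log(1 + noise_cv^2))
    y <- mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tibble::tibble(compound_id = compound_id, nominal_conc = x, peak_area = y)
}
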