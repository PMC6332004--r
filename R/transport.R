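#' Transwell insert geometry
#'
#' Membrane area and compartment volumes of a transwell insert. Defaults are
#' a standard 12 mm insert (area 1.12 cm2) with 0.5 mL apical and 1.5 mL
#' basolateral medium.
#'
#' @param area Membrane surface area, cm2.
#' @param vol_ap Apical volume, mL.
#' @param vol_bl Basolateral volume, mL.
#' @return An `insert_geometry` object.
#' @export
insert_geometry <- function(area = 1.12, vol_ap = 0.5, vol_bl = 1.5) {
  if (any(!is.finite(c(area, vol_ap, vol_bl))) ||
      any(c(area, vol_ap, vol_bl) <= 0)) {
    stop_validation("insert geometry values must all be positive")
  }
  structure(list(area = area, vol_ap = vol_ap, vol_bl = vol_bl),
            class = "insert_geometry")
}

#' @export
print.insert_geometry <- function(x, ...) {
  cat(sprintf("<insert_geometry> A = %.3g cm2, AP %.3g mL, BL %.3g mL\n",
              x$area, x$vol_ap, x$vol_bl))
  invisible(x)
}

# donor / receiver volume (cm3 = mL) for a direction
donor_volume <- function(geometry, direction) {
  if (direction == DIR_AP_BL) geometry$vol_ap else geometry$vol_bl
}
receiver_volume <- function(geometry, direction) {
  if (direction == DIR_AP_BL) geometry$vol_bl else geometry$vol_ap
}

#' One replicate of a bidirectional transport experiment
#'
#' Cumulative receiver-side amounts over time for one compound, one transport
#' direction and one replicate insert. Internally all amounts are umol, time
#' is carried in minutes and converted to seconds where rates are formed, and
#' donor concentration is converted from uM to umol/cm3 at the boundary.
#'
#' @param compound_id Identifier.
#' @param direction `"AP_BL"` or `"BL_AP"` (common spellings such as
#'   `"AP-BL"` are normalized).
#' @param times_min Sampling times, minutes, strictly increasing, >= 1 point.
#' @param q_umol Cumulative receiver amount at each time, umol, non-negative.
#' @param c0_uM Initial donor concentration, uM (> 0).
#' @param geometry An [insert_geometry()].
#' @param replicate Replicate index.
#' @param teer Transepithelial electrical resistance, Ohm cm2 (optional).
#' @return A `transport_series` object.
#' @export
transport_series <- function(compound_id, direction, times_min, q_umol, c0_uM,
                             geometry = insert_geometry(), replicate = 1L,
                             teer = NA_real_) {
  direction <- normalize_direction(direction)
  if (length(times_min) != length(q_umol) || length(times_min) < 1L) {
    stop_validation("times_min and q_umol must have equal length >= 1")
  }
  if (any(diff(times_min) <= 0)) {
    stop_validation("times_min must be strictly increasing")
  }
  if (any(times_min < 0)) stop_validation("times_min must be non-negative")
  if (any(q_umol < -sqrt(.Machine$double.eps))) {
    stop_validation("q_umol must be non-negative")
  }
  if (!is.finite(c0_uM) || c0_uM <= 0) stop_validation("c0_uM must be > 0")
  stopifnot(inherits(geometry, "insert_geometry"))
  structure(list(compound_id = compound_id, direction = direction,
                 replicate = as.integer(replicate),
                 times_min = as.numeric(times_min),
                 q_umol = pmax(as.numeric(q_umol), 0),
                 c0_uM = c0_uM, geometry = geometry, teer = teer),
            class = "transport_series")
}

#' @export
print.transport_series <- function(x, ...) {
  cat(sprintf("<transport_series> %s %s rep %d: %d point(s), C0 %.3g uM%s\n",
              x$compound_id, x$direction, x$replicate, length(x$times_min),
              x$c0_uM,
              ifelse(is.na(x$teer), "", sprintf(", TEER %.0f Ohm cm2", x$teer))))
  invisible(x)
}

#' Monolayer integrity gate on TEER
#'
#' Inserts are used only when their transepithelial electrical resistance
#' exceeds the threshold (default 1000 Ohm cm2). A missing TEER passes with
#' a warning rather than silently dropping data.
#'
#' @param x A `transport_series` or a numeric TEER value.
#' @param threshold Ohm cm2, > 0.
#' @return Logical: `TRUE` if the monolayer passes.
#' @export
teer_gate <- function(x, threshold = 1000) {
  if (!is.finite(threshold) || threshold <= 0) {
    stop_validation("TEER threshold must be > 0")
  }
  teer <- if (inherits(x, "transport_series")) x$teer else as.numeric(x)
  if (length(teer) != 1L) stop_validation("teer_gate expects a single value")
  if (is.na(teer)) {
    twr_warn("TEER missing; monolayer passed by default", "twr_missing_teer")
    return(TRUE)
  }
  teer > threshold
}

#' Linear appearance rate in the receiver compartment
#'
#' dQ/dt in umol/s. With a single sampled time point the through-origin
#' estimate Q(t)/t is used (an endpoint design); with several points the
#' slope of a through-origin least-squares fit of cumulative amount on time
#' is used, since Q(0) = 0 physically. Time is converted from minutes to
#' seconds.
#'
#' @param series A [transport_series()].
#' @return Rate, umol/s.
#' @export
appearance_rate <- function(series) {
  stopifnot(inherits(series, "transport_series"))
  t_s <- series$times_min * 60
  q <- series$q_umol
  keep <- t_s > 0
  if (!any(keep)) stop_degenerate("appearance rate undefined: all times zero")
  t_s <- t_s[keep]; q <- q[keep]
  if (length(t_s) == 1L) return(q / t_s)
  # through-origin OLS slope
  sum(q * t_s) / sum(t_s^2)
}

#' Apparent permeability coefficient for one replicate
#'
#' \deqn{P_{app} = \frac{dQ/dt}{A \cdot C_0}}{Papp = (dQ/dt) / (A * C0)}
#' with dQ/dt the receiver appearance rate (umol/s), A the insert membrane
#' area (cm2) and C0 the initial donor concentration (converted uM ->
#' umol/cm3). Result in cm/s.
#'
#' @param series A [transport_series()].
#' @return Papp, cm/s.
#' @examples
#' g <- insert_geometry()
#' s <- transport_series("x", "AP_BL", times_min = 90, q_umol = 0.54,
#'                       c0_uM = 50, geometry = g)
#' papp(s)
#' @export
papp <- function(series) {
  stopifnot(inherits(series, "transport_series"))
  c0 <- series$c0_uM / 1000  # uM -> umol/cm3
  if (c0 <= 0) stop_validation("donor concentration must be > 0")
  appearance_rate(series) / (series$geometry$area * c0)
}

#' Aggregate replicate Papp values into a mean +/- SD estimate
#'
#' @param series_list List of [transport_series()] for one compound and one
#'   direction (replicates).
#' @return A `papp_estimate`: list with `compound_id`, `direction`, `mean`,
#'   `sd`, `n` and the per-replicate values in `values`.
#' @export
papp_estimate <- function(series_list) {
  if (inherits(series_list, "transport_series")) series_list <- list(series_list)
  ids <- unique(vapply(series_list, `[[`, "", "compound_id"))
  dirs <- unique(vapply(series_list, `[[`, "", "direction"))
  if (length(ids) != 1L || length(dirs) != 1L) {
    stop_validation("papp_estimate needs one compound and one direction")
  }
  vals <- vapply(series_list, papp, 1.0)
  new_papp_estimate(ids, dirs, mean(vals),
                    if (length(vals) > 1L) sd(vals) else 0,
                    length(vals), vals)
}

#' Construct a Papp estimate from summary statistics
#'
#' For transcribed summary tables (mean +/- SD, n) where per-replicate values
#' are unavailable.
#'
#' @param compound_id Identifier.
#' @param direction `"AP_BL"` or `"BL_AP"`.
#' @param mean Mean Papp, cm/s.
#' @param sd SD of Papp, cm/s.
#' @param n Replicate count.
#' @return A `papp_estimate`.
#' @export
papp_summary <- function(compound_id, direction, mean, sd = 0, n = 1L) {
  new_papp_estimate(compound_id, normalize_direction(direction),
                    mean, sd, as.integer(n), NULL)
}

new_papp_estimate <- function(compound_id, direction, mean, sd, n, values) {
  if (!is.finite(mean)) stop_validation("Papp mean must be finite")
  if (n >= 1L && sd < 0) stop_validation("Papp sd must be >= 0")
  structure(list(compound_id = compound_id, direction = direction,
                 mean = mean, sd = sd, n = n, values = values),
            class = "papp_estimate")
}

#' @export
print.papp_estimate <- function(x, ...) {
  cat(sprintf("<papp_estimate> %s %s: %.3g +/- %.2g cm/s (n = %d)\n",
              x$compound_id, x$direction, x$mean, x$sd, x$n))
  invisible(x)
}

#' Per-replicate and aggregated Papp from a tidy measurement table
#'
#' @param data Data frame with columns `compound_id`, `direction`,
#'   `replicate`, `time_min`, `receiver_amount_umol`, `donor_conc_uM`, and
#'   optionally `teer_ohm_cm2`.
#' @param geometry An [insert_geometry()].
#' @param teer_threshold Monolayer gate (Ohm cm2); replicates failing the
#'   gate are dropped with a warning. `NULL` disables the gate.
#' @return A list with `replicates` (tibble of per-replicate Papp) and
#'   `estimates` (tibble with one row per compound x direction: mean, sd, n).
#' @export
papp_table <- function(data, geometry = insert_geometry(),
                       teer_threshold = 1000) {
  need <- c("compound_id", "direction", "replicate", "time_min",
            "receiver_amount_umol", "donor_conc_uM")
  if (!all(need %in% names(data))) {
    stop_validation(sprintf("transport table must have columns: %s",
                            paste(need, collapse = ", ")))
  }
  data$direction <- normalize_direction(data$direction)
  has_teer <- "teer_ohm_cm2" %in% names(data)

  key <- interaction(data$compound_id, data$direction, data$replicate,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, , drop = FALSE]
    d <- d[order(d$time_min), , drop = FALSE]
    teer <- if (has_teer) d$teer_ohm_cm2[1L] else NA_real_
    s <- transport_series(d$compound_id[1L], d$direction[1L], d$time_min,
                          d$receiver_amount_umol, d$donor_conc_uM[1L],
                          geometry, d$replicate[1L], teer)
    ok <- if (is.null(teer_threshold)) TRUE else
      suppressWarnings(teer_gate(s, teer_threshold))
    tibble::tibble(compound_id = s$compound_id, direction = s$direction,
                   replicate = s$replicate, papp_cm_s = papp(s),
                   teer_ohm_cm2 = teer, teer_pass = ok)
  })
  reps <- dplyr::bind_rows(rows)
  n_fail <- sum(!reps$teer_pass)
  if (n_fail > 0L) {
    twr_warn(sprintf("%d replicate(s) failed the TEER gate and were excluded",
                     n_fail), "twr_teer_fail")
  }
  kept <- reps[reps$teer_pass, , drop = FALSE]
  est <- dplyr::summarise(
    dplyr::group_by(kept, .data$compound_id, .data$direction),
    mean = mean(.data$papp_cm_s),
    sd = ifelse(dplyr::n() > 1L, sd(.data$papp_cm_s), 0),
    n = dplyr::n(), .groups = "drop")
  list(replicates = reps, estimates = est)
}

#' Mass balance / recovery of a transport experiment
#'
#' Recovery is the percentage of the initially dosed amount recovered across
#' donor, receiver and intracellular compartments. Per common acceptance
#' practice for these assays, recovery < 85% or intracellular accumulation
#' > 7% is flagged (both thresholds configurable).
#'
#' @param donor_initial,donor_final,receiver_final,intracellular Amounts,
#'   umol; `donor_initial` > 0, all others >= 0.
#' @param compound_id Identifier (optional).
#' @param recovery_min Flag threshold, percent of dose recovered.
#' @param intracellular_max Flag threshold, percent of dose intracellular.
#' @return A `mass_balance` list: `recovery_pct`, `intracellular_pct`,
#'   `flagged`, `flags` (character).
#' @export
mass_balance <- function(donor_initial, donor_final, receiver_final,
                         intracellular = 0, compound_id = NA_character_,
                         recovery_min = 85, intracellular_max = 7) {
  amounts <- c(donor_initial, donor_final, receiver_final, intracellular)
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop_validation("all amounts must be finite and non-negative")
  }
  if (donor_initial <= 0) stop_validation("donor_initial must be > 0")
  recovery <- 100 * (donor_final + receiver_final + intracellular) / donor_initial
  intra <- 100 * intracellular / donor_initial
  flags <- character()
  if (recovery < recovery_min) {
    flags <- c(flags, sprintf("low recovery (%.1f%% < %g%%)", recovery,
                              recovery_min))
  }
  if (intra > intracellular_max) {
    flags <- c(flags, sprintf("high intracellular accumulation (%.1f%% > %g%%)",
                              intra, intracellular_max))
  }
  structure(list(compound_id = compound_id, recovery_pct = recovery,
                 intracellular_pct = intra, flagged = length(flags) > 0L,
                 flags = flags),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass_balance>%s recovery %.1f%%, intracellular %.1f%%%s\n",
              ifelse(is.na(x$compound_id), "", paste0(" ", x$compound_id)),
              x$recovery_pct, x$intracellular_pct,
              ifelse(x$flagged, paste0("  [", paste(x$flags, collapse = "; "), "]"),
                     "")))
  invisible(x)
}

#' Interval transport rates and their trend
#'
#' Splits a cumulative time course into per-interval rates (delta Q / delta
#' t, umol/s) and summarises their trend against time: under sink conditions
#' the rate is constant, while receiver-side saturation makes it decline.
#' With `by = "concentration"` the same summary is computed for endpoint
#' rates across a donor-concentration sweep, where saturable (e.g.
#' carrier-mediated) transport bends the rate-concentration line downward at
#' high concentration.
#'
#' @param x For `by = "time"`: a [transport_series()] with >= 3 time points
#'   (>= 2 intervals). For `by = "concentration"`: a data frame with columns
#'   `conc_uM` and `rate_umol_s`.
#' @param by `"time"` or `"concentration"`.
#' @return A `rate_profile` list: `table` (tibble of interval midpoints or
#'   concentrations and rates), `slope` (trend of rate against the grouping
#'   axis), and `trend` (`"increasing"`, `"decreasing"` or `"constant"`).
#' @export
rate_profile <- function(x, by = c("time", "concentration")) {
  by <- match.arg(by)
  if (by == "time") {
    stopifnot(inherits(x, "transport_series"))
    t_s <- x$times_min * 60
    if (t_s[1L] > 0) { t_s <- c(0, t_s); q <- c(0, x$q_umol) } else q <- x$q_umol
    if (length(t_s) < 3L) stop_validation("need >= 2 intervals for a rate profile")
    rates <- diff(q) / diff(t_s)
    axis <- (t_s[-1L] + t_s[-length(t_s)]) / 2
    tab <- tibble::tibble(t_mid_s = axis, rate_umol_s = rates)
  } else {
    if (!all(c("conc_uM", "rate_umol_s") %in% names(x))) {
      stop_validation("concentration profile needs columns conc_uM and rate_umol_s")
    }
    if (nrow(x) < 2L) stop_validation("need >= 2 concentrations")
    x <- x[order(x$conc_uM), , drop = FALSE]
    axis <- x$conc_uM
    rates <- x$rate_umol_s
    tab <- tibble::tibble(conc_uM = axis, rate_umol_s = rates)
  }
  slope <- unname(coef(lm(rates ~ axis))[2L])
  tol <- 1e-10 * max(abs(rates), 1e-300)
  trend <- if (abs(slope) * diff(range(axis)) < tol) "constant" else
    if (slope > 0) "increasing" else "decreasing"
  structure(list(table = tab, by = by, slope = slope, trend = trend),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> by %s: %d interval(s), trend %s (slope %.3g)\n",
              x$by, nrow(x$table), x$trend, x$slope))
  invisible(x)
}

#' Read a tidy transport measurement CSV
#'
#' @param path CSV with columns `compound_id`, `direction`, `replicate`,
#'   `time_min`, `receiver_amount_umol`, `donor_conc_uM` and optionally
#'   `teer_ohm_cm2`.
#' @return A tibble with normalized direction labels.
#' @export
read_transport_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compound_id", "direction", "replicate", "time_min",
            "receiver_amount_umol", "donor_conc_uM")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_validation(sprintf("transport CSV missing column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  df$direction <- normalize_direction(df$direction)
  df
}
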