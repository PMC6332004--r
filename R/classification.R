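#' Efflux ratio and transport-mode call for one compound
#'
#' The efflux ratio is Papp(BL->AP) / Papp(AP->BL). Ratios below 2.0 are
#' consistent with passive diffusion; ratios near or above 2.0, or near or
#' below 0.5, mark the compound as a candidate for carrier-mediated
#' (P-glycoprotein) transport and motivate an inhibitor experiment. The
#' candidacy band defaults to ratio >= 1.9 (high) or <= 0.55 (low).
#'
#' When both estimates carry per-replicate values with matching n, the ratio
#' SD is the SD of the paired per-replicate ratios; otherwise it falls back
#' to first-order (delta-method) error propagation from the two means/SDs,
#' and the result is labelled accordingly in `ratio_sd_method`.
#'
#' @param ap_bl,bl_ap `papp_estimate` objects for the same compound in the
#'   absorptive and secretory directions.
#' @param passive_max Ratio below which transport is called
#'   passive-consistent (default 2.0).
#' @param candidate_high,candidate_low P-gp candidacy band edges.
#' @return An `efflux_result` list: `compound_id`, `ratio`, `ratio_sd`,
#'   `ratio_sd_method`, `absorption_class`, `pgp_candidate`,
#'   `transport_mode`.
#' @examples
#' ab <- papp_summary("peucedanol", "AP_BL", 9.91e-6, 0.21e-6, 6)
#' ba <- papp_summary("peucedanol", "BL_AP", 18.97e-6, 0.38e-6, 6)
#' efflux_ratio(ab, ba)
#' @export
efflux_ratio <- function(ap_bl, bl_ap, passive_max = 2.0,
                         candidate_high = 1.9, candidate_low = 0.55) {
  stopifnot(inherits(ap_bl, "papp_estimate"), inherits(bl_ap, "papp_estimate"))
  if (!identical(ap_bl$compound_id, bl_ap$compound_id)) {
    stop_validation(sprintf("compound mismatch: %s vs %s",
                            ap_bl$compound_id, bl_ap$compound_id))
  }
  if (ap_bl$direction != DIR_AP_BL || bl_ap$direction != DIR_BL_AP) {
    stop_validation("arguments must be the AP_BL and BL_AP estimates, in order")
  }
  if (ap_bl$mean <= 0) stop_validation("AP_BL mean Papp must be > 0 for a ratio")
  if (bl_ap$mean <= 0) stop_validation("BL_AP mean Papp must be > 0")
  ratio <- bl_ap$mean / ap_bl$mean

  paired <- !is.null(ap_bl$values) && !is.null(bl_ap$values) &&
    length(ap_bl$values) == length(bl_ap$values) && length(ap_bl$values) > 1L
  if (paired) {
    ratio_sd <- sd(bl_ap$values / ap_bl$values)
    method <- "paired-replicates"
  } else if (ap_bl$n > 1L && bl_ap$n > 1L) {
    # first-order propagation: var(r)/r^2 ~ cv_a^2 + cv_b^2
    ratio_sd <- ratio * sqrt((ap_bl$sd / ap_bl$mean)^2 +
                             (bl_ap$sd / bl_ap$mean)^2)
    method <- "error-propagation"
  } else {
    ratio_sd <- NA_real_
    method <- "none"
  }

  structure(list(
    compound_id = ap_bl$compound_id,
    ratio = ratio,
    ratio_sd = ratio_sd,
    ratio_sd_method = method,
    absorption_class = absorption_class(ap_bl),
    pgp_candidate = ratio >= candidate_high || ratio <= candidate_low,
    transport_mode = if (ratio < passive_max) "passive-consistent" else
      "efflux-suspected"
  ), class = "efflux_result")
}

#' @export
print.efflux_result <- function(x, ...) {
  cat(sprintf("<efflux_result> %s: ratio %.2f%s, %s, %s%s\n",
              x$compound_id, x$ratio,
              ifelse(is.na(x$ratio_sd), "", sprintf(" +/- %.2f", x$ratio_sd)),
              x$absorption_class, x$transport_mode,
              ifelse(x$pgp_candidate, " [P-gp candidate]", "")))
  invisible(x)
}

#' Absorption class from the absorptive-direction Papp
#'
#' Compounds with AP->BL Papp above 1e-5 cm/s are classified as well
#' absorbed, below 1e-6 cm/s as poorly absorbed, and in between as
#' moderately absorbed. Both inequalities are strict, so the boundary values
#' themselves fall in the moderate class.
#'
#' @param x A `papp_estimate` (AP_BL) or a positive numeric Papp in cm/s.
#' @param well_min,poor_max Class boundaries, cm/s.
#' @return `"well"`, `"moderate"` or `"poor"`.
#' @examples
#' absorption_class(4.36e-5) # caffeine -> "well"
#' absorption_class(7.61e-7) # atenolol -> "poor"
#' @export
absorption_class <- function(x, well_min = 1e-5, poor_max = 1e-6) {
  p <- if (inherits(x, "papp_estimate")) x$mean else as.numeric(x)
  if (length(p) != 1L || !is.finite(p) || p <= 0) {
    stop_validation("absorption_class needs a single positive Papp")
  }
  if (p > well_min) "well" else if (p < poor_max) "poor" else "moderate"
}

#' Inhibitor contrast on efflux ratios
#'
#' Compares per-replicate efflux ratios measured without and with an efflux
#' inhibitor (e.g. 100 uM verapamil for P-gp). Reports the percentage drop
#' of the mean ratio and, with >= 2 replicates in each arm, a two-sample
#' unequal-variance (Welch) test; the significance call uses alpha = 0.01 by
#' convention for these assays.
#'
#' @param without,with_inhibitor Numeric vectors of per-replicate efflux
#'   ratios for the two arms.
#' @param compound_id Identifier (optional).
#' @param alpha Significance level (default 0.01).
#' @return An `inhibition_result` list: `ratio_without`, `ratio_with`,
#'   `pct_change`, `p_value`, `significant`, `n_without`, `n_with`, `alpha`.
#' @export
inhibition_contrast <- function(without, with_inhibitor,
                                compound_id = NA_character_, alpha = 0.01) {
  if (length(without) < 1L || length(with_inhibitor) < 1L) {
    stop_validation("both arms must be nonempty")
  }
  if (any(!is.finite(c(without, with_inhibitor)))) {
    stop_validation("ratios must be finite")
  }
  rw <- mean(without)
  ri <- mean(with_inhibitor)
  pct <- 100 * (rw - ri) / rw
  if (length(without) < 2L || length(with_inhibitor) < 2L) {
    twr_warn("single replicate in an arm: no significance test performed",
             "twr_no_test")
    p <- NA_real_
    sig <- NA
  } else {
    p <- t.test(without, with_inhibitor, var.equal = FALSE)$p.value
    sig <- p < alpha
  }
  structure(list(compound_id = compound_id, ratio_without = rw,
                 ratio_with = ri, pct_change = pct, p_value = p,
                 significant = sig, n_without = length(without),
                 n_with = length(with_inhibitor), alpha = alpha),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("<inhibition_result>%s ratio %.2f -> %.2f (%+.1f%% change)",
              ifelse(is.na(x$compound_id), "", paste0(" ", x$compound_id)),
              x$ratio_without, x$ratio_with, -x$pct_change))
  if (!is.na(x$p_value)) {
    cat(sprintf(", p = %.3g (%s at alpha = %g)", x$p_value,
                ifelse(isTRUE(x$significant), "significant", "not significant"),
                x$alpha))
  }
  cat("\n")
  invisible(x)
}

#' Intracellular accumulation fold change
#'
#' Ratio of mean intracellular probe fluorescence with inhibitor to the
#' baseline (inhibitor-absent) mean — the standard functional readout for
#' efflux-pump expression with rhodamine 123.
#'
#' @param baseline,inhibited Positive fluorescence intensities per replicate.
#' @param probe_id Identifier (default "Rh123").
#' @return An `accumulation_result` list with `fold_change`.
#' @export
accumulation_fold <- function(baseline, inhibited, probe_id = "Rh123") {
  if (length(baseline) < 1L || length(inhibited) < 1L) {
    stop_validation("both arms must be nonempty")
  }
  if (any(!is.finite(c(baseline, inhibited))) ||
      any(c(baseline, inhibited) <= 0)) {
    stop_validation("fluorescence intensities must be positive")
  }
  structure(list(probe_id = probe_id,
                 fold_change = mean(inhibited) / mean(baseline),
                 baseline_mean = mean(baseline),
                 inhibited_mean = mean(inhibited)),
            class = "accumulation_result")
}

#' @export
print.accumulation_result <- function(x, ...) {
  cat(sprintf("<accumulation_result> %s: %.2f-fold (%.4g -> %.4g)\n",
              x$probe_id, x$fold_change, x$baseline_mean, x$inhibited_mean))
  invisible(x)
}

#' Validate a monolayer as an in vitro barrier model
#'
#' A cell monolayer is accepted as a blood-brain-barrier surrogate when
#' (i) the well-transported passive marker (caffeine) classifies "well",
#' (ii) the poorly-transported marker (atenolol) classifies "poor",
#' (iii) every TEER value exceeds the integrity threshold, and
#' (iv) the efflux-probe (Rh123) ratio falls below 2.0 under the P-gp
#' inhibitor, demonstrating functional, inhibitable efflux.
#'
#' @param well_marker,poor_marker `papp_estimate` objects (AP_BL) for the
#'   two marker compounds.
#' @param probe_inhibited_ratio Efflux ratio of the probe substrate in the
#'   inhibitor arm (numeric), or an `inhibition_result`.
#' @param teer Numeric vector of monolayer TEER values, Ohm cm2.
#' @param teer_threshold Integrity gate (default 1000 Ohm cm2).
#' @param passive_max Inhibited-probe ratio bound (default 2.0).
#' @return A `validation_report` list: `pass` and `reasons` (character,
#'   empty when passing).
#' @export
model_validation_report <- function(well_marker, poor_marker,
                                    probe_inhibited_ratio, teer,
                                    teer_threshold = 1000, passive_max = 2.0) {
  if (missing(well_marker) || missing(poor_marker) ||
      is.null(well_marker) || is.null(poor_marker)) {
    twr_stop("marker compound estimates are required for validation",
             "twr_incomplete_validation")
  }
  reasons <- character()
  if (absorption_class(well_marker) != "well") {
    reasons <- c(reasons, "well-marker not classified 'well'")
  }
  if (absorption_class(poor_marker) != "poor") {
    reasons <- c(reasons, "poor-marker not poor")
  }
  if (length(teer) == 0L || any(is.na(teer))) {
    reasons <- c(reasons, "TEER values missing")
  } else if (any(teer <= teer_threshold)) {
    reasons <- c(reasons, sprintf("TEER at or below %g Ohm cm2", teer_threshold))
  }
  pr <- if (inherits(probe_inhibited_ratio, "inhibition_result")) {
    probe_inhibited_ratio$ratio_with
  } else as.numeric(probe_inhibited_ratio)
  if (!is.finite(pr)) {
    twr_stop("efflux-probe inhibited ratio is required for validation",
             "twr_incomplete_validation")
  }
  if (pr >= passive_max) {
    reasons <- c(reasons,
                 sprintf("probe ratio %.2f not reduced below %.1f by inhibitor",
                         pr, passive_max))
  }
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 teer_threshold = teer_threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s\n", ifelse(x$pass, "PASS", "FAIL")))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Classification table for a set of bidirectional Papp estimates
#'
#' @param estimates Tibble with columns `compound_id`, `direction`, `mean`,
#'   `sd`, `n` (as produced by [papp_table()] or [apr_papp_estimates()]).
#' @param ... Threshold arguments forwarded to [efflux_ratio()].
#' @return Tibble: one row per compound with both Papp means, efflux ratio
#'   (full precision plus a 2-decimal display column), absorption class,
#'   transport mode, and P-gp candidacy.
#' @export
classify_compounds <- function(estimates, ...) {
  wide <- split(estimates, estimates$compound_id)
  rows <- lapply(wide, function(d) {
    ab <- d[d$direction == DIR_AP_BL, , drop = FALSE]
    ba <- d[d$direction == DIR_BL_AP, , drop = FALSE]
    if (nrow(ab) != 1L) return(NULL)
    cls <- absorption_class(ab$mean)
    if (nrow(ba) != 1L) {
      return(tibble::tibble(compound_id = ab$compound_id,
                            papp_ap_bl = ab$mean, papp_bl_ap = NA_real_,
                            efflux_ratio = NA_real_, ratio_display = NA_character_,
                            absorption_class = cls,
                            transport_mode = NA_character_,
                            pgp_candidate = NA))
    }
    er <- efflux_ratio(papp_summary(ab$compound_id, DIR_AP_BL, ab$mean, ab$sd, ab$n),
                       papp_summary(ab$compound_id, DIR_BL_AP, ba$mean, ba$sd, ba$n),
                       ...)
    tibble::tibble(compound_id = ab$compound_id,
                   papp_ap_bl = ab$mean, papp_bl_ap = ba$mean,
                   efflux_ratio = er$ratio,
                   ratio_display = sprintf("%.2f", er$ratio),
                   absorption_class = cls,
                   transport_mode = er$transport_mode,
                   pgp_candidate = er$pgp_candidate)
  })
  dplyr::bind_rows(rows)
}
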