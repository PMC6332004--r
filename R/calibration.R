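#' Fit a linear HPLC calibration curve
#'
#' Ordinary least-squares fit of detector peak area against nominal
#' concentration for a single compound, the standard bioanalytical
#' peak-area-versus-concentration regression \eqn{y = a x + b}. An optional
#' `1/x` weighting is available but off by default, matching plain linear
#' regression practice for these assays.
#'
#' @param standards Data frame with columns `compound_id`, `nominal_conc`
#'   (micromolar, > 0) and `peak_area` (detector response). All rows must
#'   belong to one compound and at least three distinct concentration levels
#'   are required.
#' @param weighting `"none"` (default) for unweighted OLS, or `"1/x"` for
#'   inverse-concentration weights.
#'
#' @return A `calibration_curve` object: list with `compound_id`, `slope`
#'   (area per uM), `intercept` (area), `r` (Pearson correlation of x and y),
#'   `r_squared`, `range_low` and `range_high` (uM, the validated range =
#'   the span of the standards), `n`, and `weighting`.
#'
#' @examples
#' std <- data.frame(compound_id = "umbelliferone",
#'                   nominal_conc = c(1, 50, 150),
#'                   peak_area = 14.82 * c(1, 50, 150) + 4.21)
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  req <- c("compound_id", "nominal_conc", "peak_area")
  if (!all(req %in% names(standards))) {
    stop_validation(sprintf("standards must have columns: %s",
                            paste(req, collapse = ", ")))
  }
  ids <- unique(standards$compound_id)
  if (length(ids) != 1L) {
    stop_validation(sprintf(
      "calibration standards mix %d compounds (%s); fit one compound at a time",
      length(ids), paste(ids, collapse = ", ")))
  }
  x <- standards$nominal_conc
  y <- standards$peak_area
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_validation("nominal_conc must be finite and > 0")
  }
  if (any(!is.finite(y))) stop_validation("peak_area must be finite")
  if (length(unique(x)) < 3L) {
    stop_degenerate("calibration needs >= 3 distinct concentration levels")
  }
  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop_degenerate(sprintf(
      "degenerate calibration for %s: fitted slope %.3g is not > 0", ids, slope))
  }
  r <- stats::cor(x, y)
  structure(list(
    compound_id = ids,
    slope = slope,
    intercept = intercept,
    r = r,
    r_squared = r^2,
    range_low = min(x),
    range_high = max(x),
    n = length(x),
    weighting = weighting
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s\n", x$compound_id))
  cat(sprintf("  y = %.4gx %s %.4g   (r = %.4f, n = %d)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$r, x$n))
  cat(sprintf("  validated range: %.3g-%.3g uM\n", x$range_low, x$range_high))
  invisible(x)
}

#' Build a calibration curve from known coefficients
#'
#' Wraps externally reported regression coefficients (e.g. transcribed method
#' sheets) into a `calibration_curve` for back-calculation without refitting.
#'
#' @param compound_id Identifier.
#' @param slope Area per uM; must be > 0.
#' @param intercept Area.
#' @param r Correlation coefficient (optional).
#' @param range_low,range_high Validated concentration range, uM.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(compound_id, slope, intercept, r = NA_real_,
                              range_low = -Inf, range_high = Inf) {
  if (!is.finite(slope) || slope <= 0) stop_validation("slope must be > 0")
  if (!is.na(r) && (r < -1 || r > 1)) stop_validation("r must lie in [-1, 1]")
  if (range_low >= range_high) stop_validation("range_low must be < range_high")
  structure(list(compound_id = compound_id, slope = slope,
                 intercept = intercept, r = r, r_squared = r^2,
                 range_low = range_low, range_high = range_high,
                 n = NA_integer_, weighting = "none"),
            class = "calibration_curve")
}

#' Back-calculate concentrations from peak areas
#'
#' Inverts the calibration regression: concentration = (area - intercept) /
#' slope. Values falling outside the validated range are flagged with a
#' warning and an `out_of_range` attribute, but never clipped or rejected.
#'
#' @param curve A `calibration_curve`.
#' @param peak_area Numeric vector of detector responses.
#' @return Numeric vector of concentrations (uM) with logical attribute
#'   `out_of_range`.
#' @examples
#' curve <- calibration_curve("umbelliferone", 14.82, 4.21,
#'                            range_low = 1, range_high = 150)
#' back_calculate(curve, 745.21) # 50 uM
#' @export
back_calculate <- function(curve, peak_area) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (peak_area - curve$intercept) / curve$slope
  oor <- is.finite(conc) & (conc < curve$range_low | conc > curve$range_high)
  if (any(oor)) {
    twr_warn(sprintf(
      "%d back-calculated value(s) outside validated range [%.3g, %.3g] uM for %s",
      sum(oor), curve$range_low, curve$range_high, curve$compound_id),
      "twr_out_of_range")
  }
  attr(conc, "out_of_range") <- oor
  conc
}

#' Precision, accuracy and freeze-thaw QC metrics at one level
#'
#' Standard bioanalytical QC summary at a single nominal concentration:
#' intraday precision is the pooled within-day relative standard deviation,
#' interday precision is the RSD of the day means around the grand mean, and
#' accuracy is the grand mean as a percentage of nominal. If freeze-thaw
#' cycle data are supplied, stability is the post-cycle mean as a percentage
#' of the cycle-0 (baseline) mean, with an acceptance window of +/- 5%.
#'
#' @param replicate_concs Data frame with columns `day` and `conc`
#'   (back-calculated, uM); optionally `cycle` (integer, 0 = baseline) for
#'   freeze-thaw stability, and `compound_id`.
#' @param nominal Nominal QC concentration, uM.
#' @param freeze_thaw_window Half-width (percent) of the stability acceptance
#'   band around 100%; default 5.
#' @return A `qc_report` list: `compound_id`, `level`, `intraday_rsd`,
#'   `interday_rsd`, `accuracy` (all percent), `freeze_thaw_pct` (NA when no
#'   cycle data), `freeze_thaw_ok`, `n_days`, `n`.
#' @export
qc_metrics <- function(replicate_concs, nominal, freeze_thaw_window = 5) {
  if (!all(c("day", "conc") %in% names(replicate_concs))) {
    stop_validation("replicate_concs needs columns day and conc")
  }
  if (!is.finite(nominal) || nominal <= 0) stop_validation("nominal must be > 0")
  cid <- if ("compound_id" %in% names(replicate_concs)) {
    unique(replicate_concs$compound_id)[1L]
  } else NA_character_

  cyc <- if ("cycle" %in% names(replicate_concs)) replicate_concs$cycle else
    rep(0L, nrow(replicate_concs))
  base <- replicate_concs[cyc == 0 | is.na(cyc), , drop = FALSE]
  if (nrow(base) < 2L) stop_degenerate("precision undefined with < 2 replicates")

  days <- split(base$conc, base$day)
  if (any(vapply(days, length, 1L) < 2L)) {
    stop_degenerate("each day needs >= 2 replicates for intraday precision")
  }
  grand <- mean(base$conc)
  # pooled within-day SD, df-weighted
  ss <- vapply(days, function(v) sum((v - mean(v))^2), 1.0)
  df <- vapply(days, function(v) length(v) - 1L, 1L)
  pooled_sd <- sqrt(sum(ss) / sum(df))
  intraday <- 100 * pooled_sd / grand
  day_means <- vapply(days, mean, 1.0)
  interday <- if (length(day_means) >= 2L) {
    100 * sd(day_means) / mean(day_means)
  } else NA_real_
  accuracy <- 100 * grand / nominal

  ft <- NA_real_
  ft_ok <- NA
  post <- replicate_concs[!is.na(cyc) & cyc > 0, , drop = FALSE]
  if (nrow(post) > 0L) {
    last <- post[post$cycle == max(post$cycle), , drop = FALSE]
    ft <- 100 * mean(last$conc) / mean(base$conc)
    ft_ok <- abs(ft - 100) <= freeze_thaw_window
  }

  structure(list(compound_id = cid, level = nominal,
                 intraday_rsd = intraday, interday_rsd = interday,
                 accuracy = accuracy, freeze_thaw_pct = ft,
                 freeze_thaw_ok = ft_ok,
                 n_days = length(days), n = nrow(base)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s @ %.3g uM (n = %d over %d day(s))\n",
              ifelse(is.na(x$compound_id), "?", x$compound_id),
              x$level, x$n, x$n_days))
  cat(sprintf("  intraday RSD %.2f%% | interday RSD %s | accuracy %.2f%%\n",
              x$intraday_rsd,
              ifelse(is.na(x$interday_rsd), "NA",
                     sprintf("%.2f%%", x$interday_rsd)),
              x$accuracy))
  if (!is.na(x$freeze_thaw_pct)) {
    cat(sprintf("  freeze-thaw %.2f%% of baseline (%s)\n", x$freeze_thaw_pct,
                ifelse(isTRUE(x$freeze_thaw_ok), "within window", "OUT OF WINDOW")))
  }
  invisible(x)
}

#' Read calibration standards or QC samples from CSV
#'
#' @param path CSV with columns `compound_id`, `day`, `level_uM`, `peak_area`
#'   and optionally `cycle`.
#' @return A tibble.
#' @export
read_calibration_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compound_id", "level_uM", "peak_area")
  if (!all(need %in% names(df))) {
    stop_validation(sprintf("calibration CSV must have columns: %s",
                            paste(need, collapse = ", ")))
  }
  df
}
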