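#' Study configuration
#'
#' Central knobs of the analysis pipeline with their documented defaults:
#' TEER integrity gate 1000 Ohm cm2; absorption class boundaries 1e-5 /
#' 1e-6 cm/s; passive-transport ratio bound 2.0; P-gp candidacy band
#' ratio >= 1.9 or <= 0.55; inhibition test alpha 0.01; recovery flag
#' < 85% of dose; intracellular flag > 7%; QSPR breakpoint fixed at log D
#' 2.5 with unit amplitude.
#'
#' @param geometry An [insert_geometry()].
#' @param teer_threshold Ohm cm2.
#' @param well_min,poor_max Absorption class boundaries, cm/s.
#' @param passive_max Efflux-ratio bound for passive consistency.
#' @param candidate_high,candidate_low P-gp candidacy band.
#' @param alpha Significance level for inhibitor contrasts.
#' @param recovery_min,intracellular_max Mass-balance flag thresholds, %.
#' @param qspr_x0 Breakpoint (single value) or scan grid.
#' @param plateau_threshold Flatness bound for [permeability_band()].
#' @param seed Integer seed for any stochastic stage.
#' @return A `study_config` list.
#' @export
study_config <- function(geometry = insert_geometry(), teer_threshold = 1000,
                         well_min = 1e-5, poor_max = 1e-6, passive_max = 2.0,
                         candidate_high = 1.9, candidate_low = 0.55,
                         alpha = 0.01, recovery_min = 85,
                         intracellular_max = 7, qspr_x0 = 2.5,
                         plateau_threshold = 0.1, seed = 1L) {
  if (teer_threshold <= 0) stop_validation("teer_threshold must be > 0")
  if (!(poor_max < well_min)) stop_validation("need poor_max < well_min")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (candidate_low >= candidate_high) {
    stop_validation("candidate_low must be < candidate_high")
  }
  structure(list(geometry = geometry, teer_threshold = teer_threshold,
                 well_min = well_min, poor_max = poor_max,
                 passive_max = passive_max, candidate_high = candidate_high,
                 candidate_low = candidate_low, alpha = alpha,
                 recovery_min = recovery_min,
                 intracellular_max = intracellular_max, qspr_x0 = qspr_x0,
                 plateau_threshold = plateau_threshold,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Save / load a study configuration as YAML
#'
#' Round-trips exactly: `load_study_config(save_study_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `save_study_config` returns the path invisibly;
#'   `load_study_config` returns a `study_config`.
#' @export
save_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  flat <- unclass(config)
  flat$geometry <- unclass(flat$geometry)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname save_study_config
#' @export
load_study_config <- function(path) {
  flat <- yaml::read_yaml(path)
  g <- flat$geometry
  flat$geometry <- NULL
  do.call(study_config,
          c(list(geometry = insert_geometry(g$area, g$vol_ap, g$vol_bl)), flat))
}

#' Run the full study pipeline
#'
#' Orchestrates monolayer validation, TEER gating, classification, the
#' lipophilicity-permeability (QSPR) fit and the QC appendix over whatever
#' inputs are supplied; stages whose inputs are missing are skipped with an
#' explicit notice in the report log rather than failing. The report is
#' deterministic for fixed inputs, configuration and seed.
#'
#' @param estimates Tibble of Papp estimates (`compound_id`, `direction`,
#'   `mean`, `sd`, `n`, optional `teer_mean`), or `NULL` when `transport`
#'   is given.
#' @param transport Tidy per-timepoint transport tibble (see
#'   [read_transport_csv()]); converted to estimates via [papp_table()].
#' @param compounds Tibble with `compound_id`, `mw`, `logd` for the QSPR
#'   stage (optional).
#' @param rh123 A list as from [rh123_reference()] (optional; enables the
#'   validation block).
#' @param calibration Tibble of QC samples (`compound_id`, `day`,
#'   `level_uM`, `conc` or `peak_area`) for the QC appendix (optional).
#' @param config A [study_config()].
#' @return A `study_report` list: `validation`, `classification`, `qspr`
#'   (model + points + bands), `qc`, `flags` (tibble with provenance),
#'   `log` (character stage lines), `config`.
#' @export
run_study <- function(estimates = NULL, transport = NULL, compounds = NULL,
                      rh123 = NULL, calibration = NULL,
                      config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  flags <- list()
  flag <- function(compound_id, what, value) {
    flags[[length(flags) + 1L]] <<- tibble::tibble(
      compound_id = as.character(compound_id), flag = what,
      value = value)
  }

  if (is.null(estimates) && is.null(transport)) {
    stop_validation("supply estimates or transport measurements")
  }
  if (is.null(estimates)) {
    pt <- papp_table(transport, config$geometry, config$teer_threshold)
    estimates <- pt$estimates
    note("kinetics: %d measurement rows -> %d estimates",
         nrow(transport), nrow(estimates))
  } else {
    need <- c("compound_id", "direction", "mean")
    if (!all(need %in% names(estimates))) {
      stop_validation(sprintf("estimates must have columns: %s",
                              paste(need, collapse = ", ")))
    }
    if (!"sd" %in% names(estimates)) estimates$sd <- 0
    if (!"n" %in% names(estimates)) estimates$n <- 1L
    note("kinetics: %d precomputed estimate rows", nrow(estimates))
  }

  # TEER gate on summary TEER where available
  if ("teer_mean" %in% names(estimates)) {
    pass <- is.na(estimates$teer_mean) |
      estimates$teer_mean > config$teer_threshold
    n_fail <- sum(!pass)
    if (n_fail > 0L) {
      for (id in unique(estimates$compound_id[!pass])) {
        flag(id, "teer_fail",
             sprintf("TEER <= %g Ohm cm2", config$teer_threshold))
      }
      note("teer: %d estimate row(s) failed the %g Ohm cm2 gate and were excluded",
           n_fail, config$teer_threshold)
    } else {
      note("teer: all monolayers above %g Ohm cm2", config$teer_threshold)
    }
    estimates <- estimates[pass, , drop = FALSE]
  }

  # validation block
  validation <- NULL
  have_markers <- all(c("caffeine", "atenolol") %in% estimates$compound_id)
  if (have_markers && !is.null(rh123)) {
    caf <- estimates[estimates$compound_id == "caffeine" &
                       estimates$direction == DIR_AP_BL, ][1L, ]
    ate <- estimates[estimates$compound_id == "atenolol" &
                       estimates$direction == DIR_AP_BL, ][1L, ]
    teer_vals <- if ("teer_mean" %in% names(estimates)) {
      estimates$teer_mean[!is.na(estimates$teer_mean)]
    } else numeric()
    inh_ratio <- rh123$ratio$mean[rh123$ratio$arm != "baseline"][1L]
    validation <- model_validation_report(
      papp_summary("caffeine", DIR_AP_BL, caf$mean, caf$sd, caf$n),
      papp_summary("atenolol", DIR_AP_BL, ate$mean, ate$sd, ate$n),
      inh_ratio,
      if (length(teer_vals) > 0L) teer_vals else NA_real_,
      teer_threshold = config$teer_threshold,
      passive_max = config$passive_max)
    note("validation: %s", ifelse(validation$pass, "pass",
                                  paste(validation$reasons, collapse = "; ")))
  } else {
    note("validation: skipped (markers or efflux-probe control missing)")
  }

  # classification
  test_set <- estimates[!estimates$compound_id %in% c("caffeine", "atenolol"), ,
                        drop = FALSE]
  classification <- NULL
  if (nrow(test_set) > 0L) {
    classification <- classify_compounds(
      test_set, passive_max = config$passive_max,
      candidate_high = config$candidate_high,
      candidate_low = config$candidate_low)
    if (!is.null(classification) && nrow(classification) > 0L) {
      for (i in which(classification$pgp_candidate %in% TRUE)) {
        flag(classification$compound_id[i], "pgp_candidate",
             sprintf("efflux ratio %.2f in candidacy band",
                     classification$efflux_ratio[i]))
      }
      note("classification: %d compound(s) classified", nrow(classification))
    }
  } else {
    note("classification: skipped (no test compounds passed gating)")
  }

  # QSPR
  qspr <- NULL
  if (!is.null(compounds) && !is.null(classification) &&
      nrow(classification) > 0L) {
    usable <- compounds[is.finite(compounds$mw) & is.finite(compounds$logd), ,
                        drop = FALSE]
    pts <- tryCatch(qspr_points(test_set, usable), error = function(e) NULL)
    if (!is.null(pts) && nrow(pts) >= 5L) {
      model <- fit_sigmoid(pts, x0 = config$qspr_x0)
      bands <- permeability_band(model, pts$x, config$plateau_threshold)
      qspr <- list(model = model, points = pts,
                   bands = tibble::tibble(compound_id = pts$compound_id,
                                          logd = pts$x, band = bands),
                   sse = attr(model, "sse"))
      note("qspr: fitted on %d points, SSE %.4g", nrow(pts), attr(model, "sse"))
    } else {
      note("qspr: skipped (fewer than 5 usable points)")
    }
  } else {
    note("qspr: skipped (no compound table or no classification)")
  }

  # QC appendix
  qc <- NULL
  if (!is.null(calibration)) {
    if (!"conc" %in% names(calibration) && "peak_area" %in% names(calibration)) {
      stop_validation(
        "calibration QC needs back-calculated 'conc' (use back_calculate first)")
    }
    parts <- split(calibration,
                   interaction(calibration$compound_id, calibration$level_uM,
                               drop = TRUE))
    qc_rows <- lapply(parts, function(d) {
      r <- qc_metrics(d, nominal = d$level_uM[1L])
      tibble::tibble(compound_id = d$compound_id[1L], level = r$level,
                     intraday_rsd = r$intraday_rsd,
                     interday_rsd = r$interday_rsd, accuracy = r$accuracy,
                     freeze_thaw_pct = r$freeze_thaw_pct)
    })
    qc <- dplyr::bind_rows(qc_rows)
    note("qc: %d level(s) summarised", nrow(qc))
  } else {
    note("qc: skipped (no calibration data)")
  }

  flags_tbl <- if (length(flags) > 0L) dplyr::bind_rows(flags) else
    tibble::tibble(compound_id = character(), flag = character(),
                   value = character())

  structure(list(validation = validation, classification = classification,
                 qspr = qspr, qc = qc, flags = flags_tbl, log = log,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (l in x$log) cat("  * ", l, "\n", sep = "")
  if (nrow(x$flags) > 0L) {
    cat("  flags:\n")
    for (i in seq_len(nrow(x$flags))) {
      cat(sprintf("    - %s: %s (%s)\n", x$flags$compound_id[i],
                  x$flags$flag[i], x$flags$value[i]))
    }
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `classification.csv`, `qc.csv` (when present), `flags.csv`,
#' `qspr_model.json`, `validation.json` and `report_log.txt` under
#' `out_dir`. Numbers are written at full precision; rounding is a
#' display-time concern only.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if missing).
#' @param plot Also write `qspr_plot.pdf` (default FALSE; plot output is
#'   not byte-stable across platforms).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir, plot = FALSE) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$classification)) {
    readr::write_csv(report$classification,
                     file.path(out_dir, "classification.csv"))
  }
  if (!is.null(report$qc)) {
    readr::write_csv(report$qc, file.path(out_dir, "qc.csv"))
  }
  readr::write_csv(report$flags, file.path(out_dir, "flags.csv"))
  if (!is.null(report$qspr)) {
    write_sigmoid_json(report$qspr$model,
                       file.path(out_dir, "qspr_model.json"))
    readr::write_csv(report$qspr$bands, file.path(out_dir, "qspr_bands.csv"))
    if (plot) {
      p <- plot_qspr(report$qspr$points, report$qspr$model)
      ggplot2::ggsave(file.path(out_dir, "qspr_plot.pdf"), p,
                      width = 6, height = 4)
    }
  }
  if (!is.null(report$validation)) {
    jsonlite::write_json(
      list(pass = report$validation$pass, reasons = report$validation$reasons),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE)
  }
  writeLines(report$log, file.path(out_dir, "report_log.txt"))
  invisible(out_dir)
}
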