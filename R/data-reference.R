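# Reference datasets: bidirectional Papp summaries for twelve Angelicae
# Pubescentis Radix coumarins and two passive-diffusion markers across an
# MDCK-pHaMDR monolayer (50 uM donor, 90 min, n = 6), plus the rhodamine
# 123 / verapamil P-gp functional control (10 uM, n = 4). Values are the
# published summary statistics; molecular weights are a synthetic fixture
# (see inst/extdata/coumarin_mw_synthetic.csv).

#' Compound table for the APR coumarin reference set
#'
#' Identity, molecular weight and log D (pH 7.4) for the twelve coumarins
#' (umbelliferone, osthol, scopoletin, peucedanol, ulopterol, angepubebisin,
#' psoralen, xanthotoxin, bergapten, isoimperatorin, columbianadin,
#' columbianetin acetate) and the caffeine/atenolol markers. Molecular
#' weights come from the shipped synthetic fixture file (derived from
#' molecular formulas, angepubebisin approximate).
#'
#' @return Tibble: `compound_id`, `name`, `mw` (g/mol), `logd` (pH 7.4; NA
#'   for the markers).
#' @export
apr_compounds <- function() {
  mw_path <- system.file("extdata", "coumarin_mw_synthetic.csv",
                         package = "transwellr", mustWork = TRUE)
  mw <- readr::read_csv(mw_path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(compound_id = "c"))
  logd <- c("1" = 1.44, "2" = 4.08, "3" = 1.65, "4" = 0.63, "5" = 1.09,
            "6" = 3.40, "7" = 2.08, "8" = 2.17, "9" = 2.17, "10" = 3.7,
            "11" = 4.28, "12" = 2.54)
  mw$logd <- unname(logd[mw$compound_id])
  mw
}

#' Bidirectional Papp reference estimates for the APR coumarin set
#'
#' Mean +/- SD apparent permeability (cm/s, n = 6) in both transport
#' directions for the twelve coumarins, with per-insert TEER summaries, and
#' the AP->BL values for the caffeine (10 uM) and atenolol (200 uM)
#' markers. The caffeine marker Papp used for model validation is
#' 4.36e-5 cm/s and atenolol 7.61e-7 cm/s.
#'
#' @return Tibble: `compound_id`, `direction`, `mean`, `sd` (cm/s), `n`,
#'   `logd`, `teer_mean`, `teer_sd` (Ohm cm2).
#' @export
apr_papp_estimates <- function() {
  # compound_id, ap_bl mean/sd, bl_ap mean/sd (x1e-6 cm/s), logd, teer
  tab <- tibble::tribble(
    ~compound_id, ~ab_m, ~ab_s, ~ba_m, ~ba_s, ~logd, ~teer_m, ~teer_s,
    "1",  35.86, 2.28, 32.79, 1.25, 1.44, 1321, 129,
    "2",  23.79, 1.44, 20.37, 3.04, 4.08, 1548, 104,
    "3",  37.10, 1.97, 27.38, 3.51, 1.65, 1586, 194,
    "4",   9.91, 0.21, 18.97, 0.38, 0.63, 1595,  93,
    "5",  22.36, 4.02, 26.66, 2.94, 1.09, 1664, 190,
    "6",  20.85, 1.32, 18.73, 1.02, 3.40, 1347, 110,
    "7",  27.34, 2.35, 26.75, 2.75, 2.08, 1549,  82,
    "8",  26.21, 3.54, 23.34, 1.67, 2.17, 1298, 161,
    "9",  43.62, 2.13, 37.38, 5.81, 2.17, 1595, 173,
    "10",  7.29, 0.17,  3.73, 0.33, 3.70, 1615, 136,
    "11", 10.42, 0.95,  7.12, 0.12, 4.28, 1429, 152,
    "12", 38.34, 1.72, 33.74, 6.35, 2.54, 1463, 119)
  coum <- dplyr::bind_rows(
    tibble::tibble(compound_id = tab$compound_id, direction = DIR_AP_BL,
                   mean = tab$ab_m * 1e-6, sd = tab$ab_s * 1e-6, n = 6L,
                   logd = tab$logd, teer_mean = tab$teer_m,
                   teer_sd = tab$teer_s),
    tibble::tibble(compound_id = tab$compound_id, direction = DIR_BL_AP,
                   mean = tab$ba_m * 1e-6, sd = tab$ba_s * 1e-6, n = 6L,
                   logd = tab$logd, teer_mean = tab$teer_m,
                   teer_sd = tab$teer_s))
  markers <- tibble::tibble(
    compound_id = c("caffeine", "atenolol"), direction = DIR_AP_BL,
    mean = c(4.36e-5, 7.61e-7), sd = c(4.86e-6, 0.16e-6), n = 6L,
    logd = NA_real_, teer_mean = c(1635, 1573), teer_sd = c(53, 91))
  dplyr::bind_rows(coum, markers)
}

#' Rhodamine 123 / verapamil P-gp functional control data
#'
#' Bidirectional Papp of the P-gp probe substrate rhodamine 123 (10 uM,
#' n = 4) with and without 100 uM verapamil, the printed efflux ratios
#' (mean +/- SD) and the intracellular accumulation fluorescence
#' intensities.
#'
#' @return List with `papp` (tibble: arm, direction, mean, sd in cm/s, n),
#'   `ratio` (tibble: arm, mean, sd) and `fluorescence` (tibble: arm, mean,
#'   sd).
#' @export
rh123_reference <- function() {
  list(
    papp = tibble::tibble(
      arm = rep(c("baseline", "verapamil"), each = 2L),
      direction = rep(c(DIR_AP_BL, DIR_BL_AP), 2L),
      mean = c(11.81, 52.74, 5.36, 8.51) * 1e-7,
      sd = c(0.56, 2.09, 0.41, 1.43) * 1e-7,
      n = 4L),
    ratio = tibble::tibble(arm = c("baseline", "verapamil"),
                           mean = c(4.47, 1.58), sd = c(0.24, 0.208)),
    fluorescence = tibble::tibble(arm = c("baseline", "verapamil"),
                                  mean = c(34.51, 153.64), sd = c(1.18, 3.28)))
}

#' Full reference fixture for the APR coumarin transport study
#'
#' Packages the compound table, the bidirectional Papp summary table and
#' the Rh123 control into one object, the inputs the study-level pipeline
#' consumes when reproducing the reference analysis.
#'
#' @return List with `compounds`, `papp`, `rh123`.
#' @export
apr_reference <- function() {
  list(compounds = apr_compounds(), papp = apr_papp_estimates(),
       rh123 = rh123_reference())
}
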