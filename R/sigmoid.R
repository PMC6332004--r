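#' Piecewise-sigmoid lipophilicity-permeability model
#'
#' A two-branch logistic model of the permeability index
#' y = log10(Papp * MW^0.5) as a function of lipophilicity x = log D:
#' \deqn{f(x) = \mathrm{logistic}(b_1 x - a_1) + c \quad (x \le x_0)}
#' \deqn{f(x) = \mathrm{logistic}(a_2 - b_2 x) + c \quad (x > x_0)}
#' with logistic(z) = 1/(1 + exp(-z)). The right offset is never free: the
#' continuity constraint a2 = (b1 + b2) x0 - a1 makes the two branches meet
#' exactly at the breakpoint x0, so permeability rises with log D up to x0
#' and falls beyond it. The amplitude is fixed at 1; c is the shared lower
#' asymptote.
#'
#' @param b1,b2 Branch steepnesses (> 0), per log D unit.
#' @param a1 Left-branch offset.
#' @param c Vertical offset (lower asymptote).
#' @param x0 Breakpoint, log D units.
#' @return A `sigmoid_model` list with `b1`, `a1`, `b2`, `a2` (derived),
#'   `c`, `x0`.
#' @export
sigmoid_model <- function(b1, a1, b2, c, x0 = 2.5) {
  if (!is.finite(b1) || b1 <= 0 || !is.finite(b2) || b2 <= 0) {
    stop_validation("branch slopes b1, b2 must be > 0")
  }
  if (any(!is.finite(c(a1, c, x0)))) stop_validation("parameters must be finite")
  structure(list(b1 = b1, a1 = a1, b2 = b2,
                 a2 = (b1 + b2) * x0 - a1, c = c, x0 = x0),
            class = "sigmoid_model")
}

#' Reference model for coumarin permeability across an MDCK-pHaMDR monolayer
#'
#' The piecewise-sigmoid fit relating log10(Papp_AP-BL * MW^0.5) to log D
#' (pH 7.4) for the twelve Angelicae Pubescentis Radix coumarins:
#' b1 = 2.9, a1 = 2.25, b2 = 3.3 (so a2 = 13.25), c = -4.227, breakpoint
#' x0 = 2.5. Both branch exponent arguments equal 5 at the breakpoint, so
#' the model is exactly continuous there.
#'
#' @return A `sigmoid_model`.
#' @export
apr_sigmoid <- function() sigmoid_model(b1 = 2.9, a1 = 2.25, b2 = 3.3,
                                        c = -4.227, x0 = 2.5)

#' Evaluate a piecewise-sigmoid model
#'
#' @param model A [sigmoid_model()].
#' @param x Numeric vector of log D values.
#' @return Predicted y = log10(Papp * MW^0.5).
#' @export
evaluate_sigmoid <- function(model, x) {
  stopifnot(inherits(model, "sigmoid_model"))
  z <- ifelse(x <= model$x0, model$b1 * x - model$a1, model$a2 - model$b2 * x)
  plogis(z) + model$c
}

#' @export
predict.sigmoid_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  evaluate_sigmoid(object, x)
}

#' @export
print.sigmoid_model <- function(x, ...) {
  cat("<sigmoid_model> piecewise logistic, linked at x0 =", x$x0, "\n")
  cat(sprintf("  x <= %g: 1/(1+exp(-(%.4g x - %.4g))) %+.4g\n",
              x$x0, x$b1, x$a1, x$c))
  cat(sprintf("  x  > %g: 1/(1+exp(%.4g x - %.4g)) %+.4g\n",
              x$x0, x$b2, x$a2, x$c))
  if (!is.null(attr(x, "sse"))) {
    cat(sprintf("  SSE %.4g on %d point(s)\n", attr(x, "sse"),
                attr(x, "n_points")))
  }
  invisible(x)
}

#' Derivative of the model with respect to log D
#'
#' @param model A [sigmoid_model()].
#' @param x log D values.
#' @return df/dx (positive on the rising branch, negative on the falling).
#' @export
sigmoid_slope <- function(model, x) {
  stopifnot(inherits(model, "sigmoid_model"))
  z <- ifelse(x <= model$x0, model$b1 * x - model$a1, model$a2 - model$b2 * x)
  s <- plogis(z)
  ifelse(x <= model$x0, model$b1, -model$b2) * s * (1 - s)
}

#' Permeability index point for the lipophilicity model
#'
#' Forms the model's response variable y = log10(Papp * MW^0.5) (Papp in
#' cm/s, MW in g/mol) and pairs it with the compound's log D. The MW^0.5
#' factor is the classical size correction for transcellular diffusion.
#'
#' @param papp A `papp_estimate` in the AP_BL direction, or a positive
#'   numeric Papp (cm/s).
#' @param compound A list/row with `mw` (> 0) and `logd`; `compound_id`
#'   optional.
#' @return A one-row tibble: `compound_id`, `x` (log D), `y`.
#' @examples
#' qspr_point(43.62e-6, list(compound_id = "bergapten", mw = 216.19,
#'                           logd = 2.17))
#' @export
qspr_point <- function(papp, compound) {
  p <- if (inherits(papp, "papp_estimate")) papp$mean else as.numeric(papp)
  if (!is.finite(p) || p <= 0) stop_validation("Papp must be positive for log10")
  if (!is.finite(compound$mw) || compound$mw <= 0) {
    stop_validation("molecular weight must be > 0")
  }
  tibble::tibble(
    compound_id = if (!is.null(compound$compound_id)) compound$compound_id else
      NA_character_,
    x = as.numeric(compound$logd),
    y = log10(p * sqrt(compound$mw)))
}

#' Permeability-index table for many compounds
#'
#' @param estimates Tibble of Papp estimates (`compound_id`, `direction`,
#'   `mean`); only AP_BL rows are used.
#' @param compounds Tibble with `compound_id`, `mw`, `logd`.
#' @return Tibble of (`compound_id`, `x`, `y`) rows, one per compound
#'   present in both tables.
#' @export
qspr_points <- function(estimates, compounds) {
  ab <- estimates[estimates$direction == DIR_AP_BL,
                  c("compound_id", "mean"), drop = FALSE]
  m <- merge(ab, compounds[, c("compound_id", "mw", "logd")],
             by = "compound_id")
  m <- m[is.finite(m$mw) & is.finite(m$logd) & is.finite(m$mean) & m$mean > 0, ,
         drop = FALSE]
  if (nrow(m) == 0L) stop_validation("no compounds shared between tables")
  out <- lapply(seq_len(nrow(m)), function(i) {
    qspr_point(m$mean[i], list(compound_id = m$compound_id[i],
                               mw = m$mw[i], logd = m$logd[i]))
  })
  dplyr::bind_rows(out)
}

sigmoid_sse <- function(par, x, y, x0) {
  m <- list(b1 = par[1L], a1 = par[2L], b2 = par[3L],
            a2 = (par[1L] + par[3L]) * x0 - par[2L], c = par[4L], x0 = x0)
  z <- ifelse(x <= x0, m$b1 * x - m$a1, m$a2 - m$b2 * x)
  sum((plogis(z) + m$c - y)^2)
}

#' Fit the linked piecewise-sigmoid model
#'
#' Constrained nonlinear least squares over (b1, a1, b2, c) with a2
#' eliminated by the continuity constraint. The optimizer is bounded
#' (b1, b2 in (0, 20], c in [-8, 0], a1 in [-60, 60]) and multi-started
#' from a fixed deterministic grid of 16 starting points, the best local
#' minimum winning; the landscape has mirror-symmetric local minima, which
#' single starts fall into. The breakpoint is fixed by default; passing a
#' grid in `x0` scans it and keeps the SSE-minimizing value.
#'
#' @param points Tibble with columns `x` and `y` (see [qspr_points()]), or
#'   separate `x`/`y` vectors via `y`.
#' @param y Optional numeric y if `points` is a numeric x vector.
#' @param x0 Breakpoint (single value, default 2.5) or a numeric grid to
#'   scan.
#' @param n_starts Number of deterministic starts (default 16).
#' @return A fitted `sigmoid_model` with attributes `sse`, `residuals`,
#'   `n_points`, `degenerate` (TRUE when the fit hit slope bounds, e.g. on
#'   constant data) and `convergence`.
#' @export
fit_sigmoid <- function(points, y = NULL, x0 = 2.5, n_starts = 16L) {
  if (is.data.frame(points)) {
    x <- points$x; yy <- points$y
  } else {
    x <- as.numeric(points); yy <- as.numeric(y)
  }
  if (length(x) != length(yy) || length(x) < 5L) {
    stop_validation("need >= 5 (x, y) points")
  }
  if (any(!is.finite(x)) || any(!is.finite(yy))) {
    stop_validation("x and y must be finite")
  }
  x0 <- as.numeric(x0)
  fit_one_x0 <- function(bp) {
    if (all(x <= bp) || all(x > bp)) {
      stop_degenerate(sprintf(
        "all points on one side of the breakpoint x0 = %g: under-determined", bp))
    }
    lower <- c(1e-3, -60, 1e-3, -8)
    upper <- c(20, 60, 20, 0)
    # deterministic start grid spanning gentle/steep slopes and offsets
    b_grid <- c(1, 3, 6, 12)
    c_grid <- c(min(yy) - 0.2, min(yy) - 1)
    starts <- expand.grid(b1 = b_grid[c(1, 3)], b2 = b_grid[c(2, 4)],
                          a1f = c(0.35, 0.75), c0 = c_grid)
    starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      p0 <- c(starts$b1[i], starts$b1[i] * (min(x) + starts$a1f[i] *
                (bp - min(x))), starts$b2[i], max(min(starts$c0[i], 0), -8))
      o <- tryCatch(
        optim(p0, sigmoid_sse, x = x, y = yy, x0 = bp, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(factr = 1e1, maxit = 1000)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      twr_stop("sigmoid fit failed to converge from any start",
               "twr_nonconvergence")
    }
    best$x0 <- bp
    best
  }
  fits <- lapply(x0, fit_one_x0)
  sses <- vapply(fits, `[[`, 1.0, "value")
  best <- fits[[which.min(sses)]]

  par <- best$par
  hit <- par[1L] <= 1e-3 + 1e-9 || par[3L] <= 1e-3 + 1e-9 ||
    par[1L] >= 20 - 1e-6 || par[3L] >= 20 - 1e-6
  if (hit) {
    twr_warn("fit hit slope bounds: data may be flat or non-sigmoidal; fit flagged degenerate",
             "twr_degenerate_fit")
  }
  m <- sigmoid_model(b1 = par[1L], a1 = par[2L], b2 = par[3L], c = par[4L],
                     x0 = best$x0)
  attr(m, "sse") <- best$value
  attr(m, "residuals") <- yy - evaluate_sigmoid(m, x)
  attr(m, "n_points") <- length(x)
  attr(m, "degenerate") <- hit
  attr(m, "convergence") <- best$convergence
  if (length(x0) > 1L) attr(m, "x0_scan") <- setNames(sses, x0)
  m
}

#' Lipophilicity band of a compound under a fitted model
#'
#' Assigns a compound's log D to one of three regimes of the
#' permeability-lipophilicity curve: `"high-plateau"` where the model is
#' nearly flat (|df/dx| below `plateau_threshold`, default 0.1 per log D
#' unit, i.e. permeability insensitive to lipophilicity), `"descending-left"`
#' on the steep rising branch below the breakpoint (too hydrophilic), and
#' `"descending-right"` on the falling branch above it (too lipophilic).
#'
#' @param model A [sigmoid_model()].
#' @param logd log D value(s).
#' @param plateau_threshold Flatness bound on |df/dx|.
#' @return Character vector of band labels.
#' @export
permeability_band <- function(model, logd, plateau_threshold = 0.1) {
  d <- sigmoid_slope(model, logd)
  ifelse(abs(d) < plateau_threshold, "high-plateau",
         ifelse(logd <= model$x0, "descending-left", "descending-right"))
}

#' Plot the lipophilicity-permeability relationship
#'
#' @param points Tibble from [qspr_points()].
#' @param model Optional fitted or reference [sigmoid_model()] overlaid as a
#'   curve.
#' @return A ggplot object.
#' @export
plot_qspr <- function(points, model = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log D (pH 7.4)",
                  y = expression(log[10](P[app] %.% MW^0.5))) +
    ggplot2::theme_bw()
  if (!is.null(model)) {
    grid <- seq(min(points$x) - 0.25, max(points$x) + 0.25, length.out = 400)
    curve_df <- tibble::tibble(x = grid, y = evaluate_sigmoid(model, grid))
    p <- p + ggplot2::geom_line(data = curve_df, colour = "steelblue")
  }
  p
}

#' Serialize a sigmoid model to JSON
#'
#' @param model A fitted [sigmoid_model()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sigmoid_json <- function(model, path) {
  rec <- list(b1 = model$b1, a1 = model$a1, b2 = model$b2, a2 = model$a2,
              c = model$c, x0 = model$x0,
              constraint_residual =
                model$a2 - ((model$b1 + model$b2) * model$x0 - model$a1),
              sse = attr(model, "sse"),
              n_points = attr(model, "n_points"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
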