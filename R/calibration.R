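#' Build a delta-scale calibration model
#'
#' Maps measured delta values onto an assigned reference scale (VPDB,
#' VCDT, air) using laboratory standards. One-point calibration shifts by
#' a constant offset through a single anchor; two-point calibration fits
#' the affine map through two anchors, which also corrects a
#' scale-expansion (slope) distortion.
#'
#' @param measured Measured delta values of the anchors, in per mil.
#' @param assigned Assigned (known) delta values of the anchors, in per
#'   mil; same length as `measured` (1 for one-point, 2 for two-point).
#' @return An object of class `"delta_calibration"` with fields `mode`
#'   (`"one_point"` or `"two_point"`), `slope`, `intercept_permil` and the
#'   anchor table.
#' @examples
#' cal <- delta_calibration(measured = c(0, 10), assigned = c(0, 20))
#' calibrate(cal, 5)
#' @export
delta_calibration <- function(measured, assigned) {
  if (length(measured) != length(assigned)) {
    abort("`measured` and `assigned` must have the same length.")
  }
  if (!length(measured) %in% 1:2) {
    abort("Supply one anchor (one-point) or two anchors (two-point).")
  }
  if (any(!is.finite(measured)) || any(!is.finite(assigned))) {
    abort("Anchor values must be finite.")
  }
  if (length(measured) == 1) {
    mode <- "one_point"
    slope <- 1
    intercept <- assigned - measured
  } else {
    if (measured[1] == measured[2]) {
      abort("Singular calibration: the two anchors have equal measured values.")
    }
    mode <- "two_point"
    slope <- (assigned[2] - assigned[1]) / (measured[2] - measured[1])
    intercept <- assigned[1] - slope * measured[1]
  }
  structure(
    list(
      mode = mode,
      slope = slope,
      intercept_permil = intercept,
      anchors = tibble(measured_permil = measured,
                       assigned_permil = assigned)
    ),
    class = "delta_calibration"
  )
}

#' Apply a calibration model to measured delta values
#'
#' @param model A [delta_calibration()] object.
#' @param measured_delta Measured delta value(s) in per mil.
#' @return Calibrated delta value(s) on the assigned scale, in per mil.
#' @export
calibrate <- function(model, measured_delta) {
  if (!inherits(model, "delta_calibration")) {
    abort("`model` must be a `delta_calibration` object.")
  }
  model$slope * measured_delta + model$intercept_permil
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat(sprintf("Delta-scale calibration (%s)\n", gsub("_", "-", x$mode)))
  cat(sprintf("  slope: %.6g   intercept: %.4g permil\n",
              x$slope, x$intercept_permil))
  cat(sprintf("  anchors: %s\n",
              paste(sprintf("%.4g -> %.4g", x$anchors$measured_permil,
                            x$anchors$assigned_permil), collapse = ", ")))
  invisible(x)
}

#' Tidy a calibration model
#'
#' @param x A [delta_calibration()] object.
#' @param ... Unused.
#' @return A tibble with one row per anchor: `measured_permil`,
#'   `assigned_permil`, `fitted_permil`, `residual_permil`.
#' @export
tidy.delta_calibration <- function(x, ...) {
  dplyr::mutate(
    x$anchors,
    fitted_permil = calibrate(x, .data$measured_permil),
    residual_permil = .data$assigned_permil - .data$fitted_permil
  )
}

#' Glance at a calibration model
#'
#' @param x A [delta_calibration()] object.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `slope`, `intercept_permil`,
#'   `n_anchors`.
#' @export
glance.delta_calibration <- function(x, ...) {
  tibble(
    mode = x$mode,
    slope = x$slope,
    intercept_permil = x$intercept_permil,
    n_anchors = nrow(x$anchors)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
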