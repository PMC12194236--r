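#' Linear PKA-to-HKA calibration model
#'
#' A calibration maps the photographic pelvis-knee-ankle angle to an estimated
#' radiographic hip-knee-ankle angle through `HKA = intercept + slope * PKA`.
#' The slope must be positive: the mapping preserves the varus/valgus
#' orientation of the scale.
#'
#' @param intercept intercept in degrees.
#' @param slope positive dimensionless slope.
#' @param see standard error of the estimate in degrees (residual SD of the
#'   fit; 0 for a noise-free fit).
#' @param source `"published"` or `"fitted"`.
#' @param n_fit number of limb pairs behind the fit (0 if not refitted here).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(intercept, slope, see = NA_real_,
                              source = c("fitted", "published"), n_fit = 0L) {
  source <- match.arg(source)
  stopifnot(is.numeric(intercept), is.numeric(slope), length(slope) == 1L)
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive (orientation-preserving mapping)",
         call. = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept), slope = as.numeric(slope),
         see = as.numeric(see), source = source, n_fit = as.integer(n_fit)),
    class = "calibration_model"
  )
}

#' The published PKA-to-HKA calibration
#'
#' The reference clinical calibration, `HKA = -10.54 + 1.0364 * PKA`, with a
#' standard error of the estimate of 1.2427 degrees, derived from 33 limbs of
#' 17 orthopedic patients measured in both modalities by a single rater.
#' Use it to estimate a radiographic HKA when no radiograph is available.
#'
#' @return A `calibration_model` with `source = "published"`.
#' @export
published_calibration <- function() {
  m <- calibration_model(intercept = -10.54, slope = 1.0364, see = 1.2427,
                         source = "published", n_fit = 0L)
  attr(m, "provenance") <- list(n_limbs = 33L, n_subjects = 17L, raters = 1L)
  m
}

#' Fit a PKA-to-HKA calibration from paired measurements
#'
#' Ordinary least squares with HKA as the response and PKA as the predictor
#' (see [ols_fit()]).
#'
#' @param pka photographic angles in degrees.
#' @param hka paired radiographic angles in degrees.
#' @return A `calibration_model` with `source = "fitted"` and the fit's
#'   regression attached as attribute `"fit"`.
#' @export
fit_calibration <- function(pka, hka) {
  fit <- ols_fit(pka, hka)
  m <- calibration_model(intercept = fit$intercept, slope = fit$slope,
                         see = fit$see, source = "fitted", n_fit = fit$n)
  attr(m, "fit") <- fit
  m
}

#' Estimate HKA from PKA through a calibration model
#'
#' Evaluates `intercept + slope * pka`. Inputs outside the plausible
#' (90, 270)-degree range are still evaluated but flagged: the returned value
#' carries attribute `extrapolated = TRUE` and a warning is raised, since the
#' linear mapping was established on clinical angles near 180 degrees.
#'
#' @param model a [calibration_model()].
#' @param pka photographic angle(s) in degrees.
#' @return Estimated HKA in degrees (vectorized over `pka`).
#' @export
apply_calibration <- function(model, pka) {
  stopifnot(inherits(model, "calibration_model"))
  pka <- as.numeric(pka)
  est <- model$intercept + model$slope * pka
  out_of_range <- !is.na(pka) & (pka <= 90 | pka >= 270)
  if (any(out_of_range)) {
    warning(sprintf("%d PKA value(s) outside (90, 270): extrapolating",
                    sum(out_of_range)), call. = FALSE)
    attr(est, "extrapolated") <- out_of_range
  }
  est
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> HKA = %.4f + %.4f * PKA  (SEE %.4f, %s%s)\n",
              x$intercept, x$slope, x$see, x$source,
              if (x$n_fit > 0) sprintf(", n = %d", x$n_fit) else ""))
  invisible(x)
}

#' Write / read a calibration model as JSON
#'
#' @param model a [calibration_model()].
#' @param path file path.
#' @return `read_calibration` returns a `calibration_model`;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$intercept, x$slope, x$see %||% NA_real_,
                    source = x$source %||% "fitted", n_fit = x$n_fit %||% 0L)
}
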