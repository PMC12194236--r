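# Landmark sets required per imaging modality. The photographic knee/ankle
# centres are derived from skin-marker pairs; the radiographic centres are
# digitized directly on the bone.
PHOTO_LANDMARKS <- c("ASIS", "MED_CONDYLE", "LAT_CONDYLE",
                     "MED_MALLEOLUS", "LAT_MALLEOLUS")
RADIO_LANDMARKS <- c("ASIS", "FEMORAL_HEAD_CENTER", "FEMORAL_NOTCH_CENTER",
                     "TIBIAL_EMINENCE_CENTER", "ANKLE_ARTICULAR_CENTER")

#' Create a 2D point
#'
#' Plain numeric pair used for all landmark positions, in millimetres in the
#' limb-local frame (+x medial for that limb, +y superior).
#'
#' @param x,y finite numeric coordinates.
#' @return An object of class `point2d` (named numeric vector).
#' @export
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    stop("point2d coordinates must be single finite numbers", call. = FALSE)
  }
  structure(c(x = as.numeric(x), y = as.numeric(y)), class = "point2d")
}

#' Digitized landmark set for one limb
#'
#' Bundles the digitized 2D landmark coordinates of a single limb in a single
#' imaging modality, together with the limb side and the image scale.
#' Photographs require the skin-marker set (ASIS, medial/lateral condyle,
#' medial/lateral malleolus); radiographs require the bony-centre set (ASIS,
#' femoral head centre, femoral notch centre, tibial eminence centre, ankle
#' articular centre).
#'
#' @param side `"left"` or `"right"`.
#' @param modality `"photograph"` or `"radiograph"`.
#' @param landmarks named list of [point2d()] objects (or length-2 numeric
#'   vectors), keyed by landmark name.
#' @param scale_mm_per_px positive scale; 1 if coordinates are already metric.
#' @return An object of class `limb_annotation`.
#' @export
limb_annotation <- function(side, modality, landmarks, scale_mm_per_px = 1) {
  side <- match.arg(side, c("left", "right"))
  modality <- match.arg(modality, c("photograph", "radiograph"))
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0) {
    stop("scale_mm_per_px must be a single positive number", call. = FALSE)
  }
  landmarks <- lapply(landmarks, function(p) {
    if (inherits(p, "point2d")) p else point2d(p[[1]], p[[2]])
  })
  required <- if (modality == "photograph") PHOTO_LANDMARKS else RADIO_LANDMARKS
  missing <- setdiff(required, names(landmarks))
  if (length(missing) > 0L) {
    stop(sprintf("missing required %s landmark(s): %s", modality,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  # coincident required landmarks would fabricate an axis from a single point
  pts <- do.call(rbind, lapply(landmarks[required], unclass))
  if (anyDuplicated(round(pts, 12L)) > 0L) {
    stop("required landmarks must not coincide", call. = FALSE)
  }
  structure(
    list(side = side, modality = modality, landmarks = landmarks,
         scale_mm_per_px = as.numeric(scale_mm_per_px)),
    class = "limb_annotation"
  )
}

#' @export
print.limb_annotation <- function(x, ...) {
  cat(sprintf("<limb_annotation> %s %s, %d landmarks, scale %g mm/px\n",
              x$side, x$modality, length(x$landmarks), x$scale_mm_per_px))
  invisible(x)
}

#' Convert image coordinates to the limb-local frame
#'
#' Image coordinates follow the usual raster convention (x right, y down,
#' anterior view, subject facing the camera). The limb-local frame has
#' +x medial for that limb and +y superior, which makes the varus sign rule
#' side-independent. For a right limb medial is image-right, so x is kept and
#' y negated; for a left limb x is negated as well. Coordinates are scaled
#' uniformly by `scale_mm_per_px`.
#'
#' @param points list of [point2d()] (or length-2 numerics) in image pixels.
#' @param side `"left"` or `"right"`.
#' @param scale_mm_per_px positive mm-per-pixel scale.
#' @return List of `point2d` in the limb-local metric frame.
#' @export
to_limb_frame <- function(points, side, scale_mm_per_px = 1) {
  side <- match.arg(side, c("left", "right"))
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0) {
    stop("scale_mm_per_px must be a single positive number", call. = FALSE)
  }
  sx <- if (side == "left") -1 else 1
  lapply(points, function(p) {
    p <- if (inherits(p, "point2d")) p else point2d(p[[1]], p[[2]])
    point2d(sx * p[["x"]] * scale_mm_per_px, -p[["y"]] * scale_mm_per_px)
  })
}

#' Midpoint of two landmarks
#'
#' Used for the photographic knee centre (between the condyle markers) and
#' ankle centre (between the malleolus markers).
#'
#' @param a,b distinct [point2d()] objects.
#' @return The arithmetic midpoint as `point2d`.
#' @export
midpoint <- function(a, b) {
  if (!inherits(a, "point2d")) a <- point2d(a[[1]], a[[2]])
  if (!inherits(b, "point2d")) b <- point2d(b[[1]], b[[2]])
  if (isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))) {
    stop("cannot take the midpoint of coincident points", call. = FALSE)
  }
  point2d((a[["x"]] + b[["x"]]) / 2, (a[["y"]] + b[["y"]]) / 2)
}

#' Signed angle between two axis directions
#'
#' Returns the counter-clockwise rotation (degrees, in (-180, 180]) taking the
#' proximal axis direction onto the distal axis direction in the limb-local
#' frame, computed with the two-argument arctangent of the cross and dot
#' products (numerically stable for near-parallel axes).
#'
#' @param d_prox,d_dist nonzero direction vectors (`point2d` or length-2).
#' @return Signed rotation in degrees.
#' @export
signed_axis_angle <- function(d_prox, d_dist) {
  p <- as.numeric(unclass(if (inherits(d_prox, "point2d")) d_prox else point2d(d_prox[[1]], d_prox[[2]])))
  d <- as.numeric(unclass(if (inherits(d_dist, "point2d")) d_dist else point2d(d_dist[[1]], d_dist[[2]])))
  if (sum(p^2) == 0 || sum(d^2) == 0) {
    stop("axis directions must be nonzero", call. = FALSE)
  }
  cross <- p[1] * d[2] - p[2] * d[1]
  dot <- p[1] * d[1] + p[2] * d[2]
  ang <- atan2(cross, dot) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

angle_result <- function(value, kind, side) {
  kind <- match.arg(kind, c("PKA", "HKA", "FMA_FTA"))
  side <- match.arg(side, c("left", "right"))
  if (kind %in% c("PKA", "HKA")) {
    if (value <= 90 || value >= 270) {
      stop(sprintf("%s angle %.3f outside the plausible (90, 270) range",
                   kind, value), call. = FALSE)
    }
  } else if (value < 0 || value >= 90) {
    stop("FMA-FTA angle must lie in [0, 90)", call. = FALSE)
  }
  structure(list(value = value, kind = kind, side = side),
            class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  lbl <- if (x$kind == "FMA_FTA") "" else
    sprintf(" (%s)", classify_alignment(x))
  cat(sprintf("<angle_result> %s %s: %.3f deg%s\n",
              sub("_", "-", x$kind), x$side, x$value, lbl))
  invisible(x)
}

.get_landmark <- function(ann, name) {
  p <- ann$landmarks[[name]]
  if (is.null(p)) stop(sprintf("missing landmark: %s", name), call. = FALSE)
  p
}

.direction <- function(from, to) {
  d <- c(to[["x"]] - from[["x"]], to[["y"]] - from[["y"]])
  if (sum(d^2) == 0) stop("degenerate axis: endpoints coincide", call. = FALSE)
  point2d(d[1], d[2])
}

#' Pelvis-knee-ankle angle from a photographic annotation
#'
#' The photographic femoral topographic axis (pFTA) runs from the ASIS to the
#' knee centre (midpoint of the condyle markers); the tibial topographic axis
#' (TTA) runs from the knee centre to the ankle centre (midpoint of the
#' malleolus markers). The PKA is the medial angle between them: 180 degrees
#' for a straight limb, below 180 varus, above 180 valgus.
#'
#' @param ann a photographic [limb_annotation()] in the limb-local frame.
#' @return An `angle_result` of kind `"PKA"`.
#' @export
pka_angle <- function(ann) {
  stopifnot(inherits(ann, "limb_annotation"))
  if (ann$modality != "photograph") {
    stop("pka_angle requires a photograph annotation", call. = FALSE)
  }
  asis <- .get_landmark(ann, "ASIS")
  knee <- midpoint(.get_landmark(ann, "MED_CONDYLE"),
                   .get_landmark(ann, "LAT_CONDYLE"))
  ankle <- midpoint(.get_landmark(ann, "MED_MALLEOLUS"),
                    .get_landmark(ann, "LAT_MALLEOLUS"))
  pfta <- .direction(asis, knee)
  tta <- .direction(knee, ankle)
  angle_result(180 - signed_axis_angle(pfta, tta), "PKA", ann$side)
}

#' Hip-knee-ankle angle from a radiographic annotation
#'
#' The femoral mechanical axis (FMA) runs from the femoral head centre to the
#' femoral notch centre; the tibial mechanical axis (TMA) from the tibial
#' eminence centre to the ankle articular centre. The HKA is the medial angle
#' between them (<180 varus, >180 valgus).
#'
#' @param ann a radiographic [limb_annotation()] in the limb-local frame.
#' @return An `angle_result` of kind `"HKA"`.
#' @export
hka_angle <- function(ann) {
  stopifnot(inherits(ann, "limb_annotation"))
  if (ann$modality != "radiograph") {
    stop("hka_angle requires a radiograph annotation", call. = FALSE)
  }
  fma <- .direction(.get_landmark(ann, "FEMORAL_HEAD_CENTER"),
                    .get_landmark(ann, "FEMORAL_NOTCH_CENTER"))
  tma <- .direction(.get_landmark(ann, "TIBIAL_EMINENCE_CENTER"),
                    .get_landmark(ann, "ANKLE_ARTICULAR_CENTER"))
  angle_result(180 - signed_axis_angle(fma, tma), "HKA", ann$side)
}

#' Angle between the femoral mechanical and topographic axes
#'
#' The radiographic femoral topographic axis (rFTA) runs from the ASIS to the
#' femoral notch centre. Its unsigned angle to the femoral mechanical axis
#' quantifies how far the palpable ASIS-based axis deviates from the true
#' mechanical axis; it is the systematic offset between PKA and HKA.
#'
#' @param ann a radiographic [limb_annotation()] in the limb-local frame.
#' @return An `angle_result` of kind `"FMA_FTA"` (unsigned, in `[0, 90)`).
#' @export
fma_fta_angle <- function(ann) {
  stopifnot(inherits(ann, "limb_annotation"))
  if (ann$modality != "radiograph") {
    stop("fma_fta_angle requires a radiograph annotation", call. = FALSE)
  }
  notch <- .get_landmark(ann, "FEMORAL_NOTCH_CENTER")
  fma <- .direction(.get_landmark(ann, "FEMORAL_HEAD_CENTER"), notch)
  rfta <- .direction(.get_landmark(ann, "ASIS"), notch)
  angle_result(abs(signed_axis_angle(fma, rfta)), "FMA_FTA", ann$side)
}

#' Classify frontal alignment from a PKA or HKA angle
#'
#' Values below 180 degrees denote varus, above 180 valgus. A configurable
#' tolerance widens the neutral band; by default only exactly 180 is neutral.
#'
#' @param angle an `angle_result` of kind PKA or HKA, or a bare numeric angle.
#' @param tolerance half-width (degrees) of the neutral band around 180.
#' @return `"varus"`, `"neutral"` or `"valgus"`.
#' @export
classify_alignment <- function(angle, tolerance = 0) {
  if (inherits(angle, "angle_result")) {
    if (angle$kind == "FMA_FTA") {
      stop("FMA-FTA is an unsigned inter-axis angle; varus/valgus does not apply",
           call. = FALSE)
    }
    value <- angle$value
  } else {
    value <- as.numeric(angle)
  }
  stopifnot(is.finite(value), tolerance >= 0)
  if (value < 180 - tolerance) "varus"
  else if (value > 180 + tolerance) "valgus"
  else "neutral"
}
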