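# CSV schemas
#
# landmarks (long): subject_id, limb_side, modality, session, rater,
#                   landmark_name, x_px, y_px, scale_mm_per_px
# angles:          subject_id, limb_side, modality, session, rater,
#                   angle_kind, value_deg, classification
# pairs:           subject_id, limb_side, pka_deg, hka_deg [, fma_fta_deg]
# ratings (wide):  subject_id, then one column per measurement label

LANDMARK_COLS <- c("subject_id", "limb_side", "modality", "session", "rater",
                   "landmark_name", "x_px", "y_px", "scale_mm_per_px")

#' Read a long-format landmark CSV
#'
#' @param path CSV file with the landmark schema (header required, UTF-8,
#'   comma separator, decimal point).
#' @return Data frame of digitized landmarks.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(LANDMARK_COLS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("landmark CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a long-format landmark CSV
#'
#' @param df landmark data frame (see [read_landmarks()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(df, path) {
  utils::write.csv(df[, LANDMARK_COLS], path, row.names = FALSE)
  invisible(path)
}

# one annotation per (subject, side, modality, session, rater) group
annotation_from_rows <- function(rows) {
  scale <- unique(rows$scale_mm_per_px)
  if (length(scale) != 1L) {
    stop("inconsistent scale_mm_per_px within one annotation", call. = FALSE)
  }
  side <- unique(rows$limb_side)
  modality <- unique(rows$modality)
  pts_img <- lapply(seq_len(nrow(rows)), function(i) {
    point2d(rows$x_px[i], rows$y_px[i])
  })
  names(pts_img) <- rows$landmark_name
  pts <- to_limb_frame(pts_img, side = side, scale_mm_per_px = scale)
  names(pts) <- rows$landmark_name
  limb_annotation(side = side, modality = modality, landmarks = pts,
                  scale_mm_per_px = 1)
}

#' Compute alignment angles from a digitized landmark table
#'
#' Groups the long-format landmark table by subject, limb, modality, session
#' and rater, converts each group from image to limb-local coordinates, and
#' computes the modality's angles: PKA for photographs; HKA and FMA-FTA for
#' radiographs.
#'
#' @param landmarks landmark data frame or CSV path (see [read_landmarks()]).
#' @param calibration optional [calibration_model()]; when supplied, each PKA
#'   row gains an `hka_est_deg` column with the calibrated HKA estimate.
#' @return Angles data frame (one row per angle; `classification` is `NA` for
#'   the unsigned FMA-FTA angle).
#' @export
measure_landmarks <- function(landmarks, calibration = NULL) {
  df <- if (is.character(landmarks)) read_landmarks(landmarks) else landmarks
  key <- interaction(df$subject_id, df$limb_side, df$modality, df$session,
                     df$rater, drop = TRUE)
  out <- lapply(split(df, key), function(rows) {
    ann <- annotation_from_rows(rows)
    meta <- rows[1L, c("subject_id", "limb_side", "modality", "session",
                       "rater")]
    angles <- if (ann$modality == "photograph") {
      list(pka_angle(ann))
    } else {
      list(hka_angle(ann), fma_fta_angle(ann))
    }
    do.call(rbind, lapply(angles, function(a) {
      cbind(meta, data.frame(
        angle_kind = a$kind, value_deg = a$value,
        classification = if (a$kind == "FMA_FTA") NA_character_
                         else classify_alignment(a),
        stringsAsFactors = FALSE
      ))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_model"))
    res$hka_est_deg <- ifelse(
      res$angle_kind == "PKA",
      calibration$intercept + calibration$slope * res$value_deg,
      NA_real_
    )
  }
  res
}

#' Read a wide ratings CSV into a ratings matrix
#'
#' First column is `subject_id`; every remaining column is one measurement.
#'
#' @param path CSV file.
#' @return A [ratings_matrix()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"subject_id" %in% names(df)) {
    stop("ratings CSV must have a subject_id column", call. = FALSE)
  }
  meas <- setdiff(names(df), "subject_id")
  complete <- stats::complete.cases(df[meas])
  if (!all(complete)) {
    message(sprintf("dropping %d incomplete ratings row(s)", sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  ratings_matrix(as.matrix(df[meas]), subject_ids = as.character(df$subject_id),
                 measurement_labels = meas)
}

#' Read a paired-angles CSV
#'
#' Requires `pka_deg` and `hka_deg` columns; incomplete pairs are dropped
#' with a message.
#'
#' @param path CSV file.
#' @return Data frame of complete pairs.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(c("pka_deg", "hka_deg"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("pairs CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  complete <- stats::complete.cases(df[, c("pka_deg", "hka_deg")])
  if (!all(complete)) {
    message(sprintf("dropping %d incomplete pair(s)", sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  df
}
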