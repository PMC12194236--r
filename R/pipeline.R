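summary_stats <- function(x) {
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       n = length(x))
}

#' Run the accuracy study
#'
#' Photograph-vs-radiograph method comparison on paired PKA/HKA angles:
#' Pearson correlation, least-squares calibration regression (HKA on PKA),
#' Bland-Altman analysis of the differences HKA - PKA, and group summaries.
#' Display rounding (angles 1 decimal, bias/limits 3 decimals, r 2 decimals)
#' happens only in the print method; the report keeps full precision.
#'
#' @param pairs data frame with `pka_deg`/`hka_deg` (and optionally
#'   `fma_fta_deg`), a pairs CSV path, or a long landmark table/CSV (detected
#'   by its `landmark_name` column and measured via [measure_landmarks()];
#'   explicit angle columns win over landmarks when both are present).
#' @return An object of class `accuracy_report`.
#' @export
run_accuracy_study <- function(pairs) {
  if (is.character(pairs)) {
    header <- names(utils::read.csv(pairs, nrows = 1L))
    pairs <- if ("landmark_name" %in% header && !"pka_deg" %in% header) {
      read_landmarks(pairs)
    } else {
      read_pairs(pairs)
    }
  }
  if ("landmark_name" %in% names(pairs) && !"pka_deg" %in% names(pairs)) {
    angles <- measure_landmarks(pairs)
    wide <- stats::reshape(
      angles[, c("subject_id", "limb_side", "angle_kind", "value_deg")],
      idvar = c("subject_id", "limb_side"), timevar = "angle_kind",
      direction = "wide"
    )
    names(wide) <- sub("^value_deg\\.PKA$", "pka_deg",
                       sub("^value_deg\\.HKA$", "hka_deg",
                           sub("^value_deg\\.FMA_FTA$", "fma_fta_deg",
                               names(wide))))
    pairs <- wide
  } else if ("landmark_name" %in% names(pairs)) {
    message("both angle columns and landmarks present; using angle columns")
  }
  keep <- stats::complete.cases(pairs[, c("pka_deg", "hka_deg")])
  if (!all(keep)) {
    message(sprintf("dropping %d incomplete pair(s)", sum(!keep)))
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) < 3L) {
    stop("accuracy study needs at least 3 complete PKA/HKA pairs", call. = FALSE)
  }
  pka <- pairs$pka_deg
  hka <- pairs$hka_deg
  reg <- ols_fit(pka, hka)
  cor_ <- pearson_r(pka, hka)
  ba <- bland_altman(hka, pka)        # radiographic minus photographic
  summaries <- list(pka = summary_stats(pka), hka = summary_stats(hka))
  if ("fma_fta_deg" %in% names(pairs) && !anyNA(pairs$fma_fta_deg)) {
    summaries$fma_fta <- summary_stats(pairs$fma_fta_deg)
  }
  structure(
    list(n_pairs = length(pka), pearson = cor_, regression = reg,
         bland_altman = ba, summaries = summaries),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy study, %d limb pairs\n", x$n_pairs))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-8s %.1f +/- %.1f deg (range %.1f-%.1f)\n",
                toupper(sub("_", "-", nm)), s$mean, s$sd, s$min, s$max))
  }
  cat(sprintf("  Pearson r = %.2f (p = %.2g)\n", x$pearson$r, x$pearson$p_value))
  cat(sprintf("  HKA = %.2f + %.4f * PKA  (R2 = %.3f, SEE = %.4f)\n",
              x$regression$intercept, x$regression$slope, x$regression$r2,
              x$regression$see))
  cat(sprintf("  Bland-Altman (HKA - PKA): bias %.3f, LoA %.3f to %.3f\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

icc_ba_pair <- function(m) {
  v <- m$values
  list(icc = icc2k(m), bland_altman = bland_altman(v[, 1L], v[, 2L]))
}

#' Run the reliability study
#'
#' Mirrors the three reliability designs and their reporting layout: per-rater
#' intrarater rows (ICC(2,2) plus Bland-Altman of the two readings), one
#' pooled interrater ICC(2,k) over all raters plus pairwise Bland-Altman rows
#' per rater pair (no pooled Bland-Altman and no pairwise ICC are invented),
#' and one test-retest row (ICC(2,2) plus Bland-Altman of the two
#' photographs).
#'
#' @param ratings output of [generate_reliability_dataset()], or a list with
#'   elements `intrarater` (list of n-x-2 [ratings_matrix()]), `interrater`
#'   (n x k, k >= 2) and `test_retest` (n x 2).
#' @return An object of class `reliability_report`.
#' @export
run_reliability_study <- function(ratings) {
  need <- c("intrarater", "interrater", "test_retest")
  if (!is.list(ratings) || !all(need %in% names(ratings))) {
    stop("ratings must list intrarater, interrater and test_retest designs",
         call. = FALSE)
  }
  intrarater <- lapply(ratings$intrarater, as_ratings)
  interrater <- as_ratings(ratings$interrater)
  test_retest <- as_ratings(ratings$test_retest)
  for (nm in names(intrarater)) {
    if (ncol(intrarater[[nm]]$values) != 2L) {
      stop(sprintf("intrarater design (%s) must have exactly 2 readings", nm),
           call. = FALSE)
    }
  }
  if (ncol(test_retest$values) != 2L) {
    stop("test-retest design must have exactly 2 photographs", call. = FALSE)
  }
  if (ncol(interrater$values) < 2L) {
    stop("interrater design needs at least 2 raters", call. = FALSE)
  }
  raters <- colnames(interrater$values)
  pairs <- utils::combn(seq_along(raters), 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) {
    v <- interrater$values
    list(raters = raters[p], bland_altman = bland_altman(v[, p[1L]], v[, p[2L]]))
  })
  names(pairwise) <- vapply(pairs, function(p) {
    paste(raters[p], collapse = "_vs_")
  }, character(1))
  structure(
    list(intrarater = lapply(intrarater, icc_ba_pair),
         interrater = list(icc = icc2k(interrater), pairwise = pairwise),
         test_retest = icc_ba_pair(test_retest)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  fmt_icc <- function(i) sprintf("%.3f (%.3f, %.3f) %s", i$estimate,
                                 i$ci_low, i$ci_high, i$interpretation)
  fmt_ba <- function(b) sprintf("%.2f (%.2f, %.2f)", b$bias, b$loa_low,
                                b$loa_high)
  cat("Reliability study\n Intrarater:\n")
  for (nm in names(x$intrarater)) {
    cat(sprintf("   %-10s ICC %s  BA %s\n", nm,
                fmt_icc(x$intrarater[[nm]]$icc),
                fmt_ba(x$intrarater[[nm]]$bland_altman)))
  }
  cat(sprintf(" Interrater (pooled): ICC %s\n", fmt_icc(x$interrater$icc)))
  for (nm in names(x$interrater$pairwise)) {
    cat(sprintf("   %-18s BA %s\n", nm,
                fmt_ba(x$interrater$pairwise[[nm]]$bland_altman)))
  }
  cat(sprintf(" Test-retest: ICC %s  BA %s\n", fmt_icc(x$test_retest$icc),
              fmt_ba(x$test_retest$bland_altman)))
  invisible(x)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(report)
}

#' Write a study report as JSON
#'
#' Serializes an accuracy or reliability report (full precision) together
#' with an optional provenance block.
#'
#' @param report an `accuracy_report` or `reliability_report`.
#' @param path output JSON file.
#' @param provenance optional named list (seed, config hash, version, ...).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, provenance = NULL) {
  x <- report_to_list(report)
  x$report_type <- class(report)[1L]
  x$schema_version <- "1.0"
  if (!is.null(provenance)) x$provenance <- provenance
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Flatten a study report into a tidy statistics table
#'
#' @param report an `accuracy_report` or `reliability_report`.
#' @return Data frame with columns `design`, `statistic`, `value`.
#' @export
report_to_table <- function(report) {
  rows <- list()
  add <- function(design, stats_list) {
    keep <- vapply(stats_list, function(v) {
      is.numeric(v) && length(v) == 1L
    }, logical(1))
    rows[[length(rows) + 1L]] <<- data.frame(
      design = design, statistic = names(stats_list)[keep],
      value = as.numeric(unlist(stats_list[keep])), stringsAsFactors = FALSE
    )
  }
  if (inherits(report, "accuracy_report")) {
    add("pearson", report$pearson)
    add("regression", unclass(report$regression))
    add("bland_altman", unclass(report$bland_altman))
    for (nm in names(report$summaries)) {
      add(paste0("summary_", nm), report$summaries[[nm]])
    }
  } else if (inherits(report, "reliability_report")) {
    for (nm in names(report$intrarater)) {
      add(paste0("intrarater_", nm, "_icc"),
          unclass(report$intrarater[[nm]]$icc))
      add(paste0("intrarater_", nm, "_ba"),
          unclass(report$intrarater[[nm]]$bland_altman))
    }
    add("interrater_icc", unclass(report$interrater$icc))
    for (nm in names(report$interrater$pairwise)) {
      add(paste0("interrater_", nm, "_ba"),
          unclass(report$interrater$pairwise[[nm]]$bland_altman))
    }
    add("test_retest_icc", unclass(report$test_retest$icc))
    add("test_retest_ba", unclass(report$test_retest$bland_altman))
  } else {
    stop("unknown report type", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out[!out$statistic %in% c("interpretation"), , drop = FALSE]
}
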