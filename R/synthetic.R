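# Hierarchical pseudo-random substreams: each (seed, key...) tuple maps to a
# deterministic 31-bit sub-seed, so adding raters/sessions never perturbs the
# subject-level draws and identical configs reproduce bit-identical datasets.
substream_seed <- function(seed, ...) {
  keys <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (k in keys) {
    h <- (h * 131 + 7) %% 2147483629
    for (ch in utf8ToInt(k)) h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h)
}

with_substream <- function(seed_int, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed_int)
  force(expr)
}

rnorm_trunc0 <- function(n, mean, sd) {
  # truncated-at-zero normal by rejection; the configured means sit several
  # SDs above zero so rejection is rare
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Configuration of the synthetic cohort and rater-noise model
#'
#' All distributional parameters of the limb generator and the measurement
#' noise model, plus the master seed. Group presets reproduce the two study
#' populations: `"orthopedic"` (patients with alignment deformity, wide HKA
#' spread) and `"healthy"` (young adults, narrow spread). The photographic
#' angle is constructed additively as
#' `PKA = HKA + FMA-FTA + ankle-centre offset`, so the healthy preset's
#' true-HKA moments are chosen to yield a noise-free PKA of 182.6 +/- 2.5
#' degrees.
#'
#' @param group `"orthopedic"` or `"healthy"`; sets population defaults.
#' @param n_subjects number of subjects (>= 3).
#' @param true_hka_mean,true_hka_sd population moments of the true HKA (deg).
#' @param fma_fta_mean,fma_fta_sd moments of the mechanical-vs-topographic
#'   femoral axis angle (deg, truncated at 0).
#' @param ankle_center_offset_mean,ankle_center_offset_sd extra
#'   photographic-minus-radiographic axis discrepancy from the surface ankle
#'   centre (deg).
#' @param femur_len_mm,tibia_len_mm segment lengths (mm).
#' @param landmark_noise_sd_mm per-marking isotropic digitization noise (mm).
#' @param rater_bias_sd_mm SD of each rater's systematic per-landmark shift (mm).
#' @param session_sd_deg SD of the stance change between photographs (deg,
#'   applied as a tibial-segment rotation).
#' @param seed master integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(group = c("orthopedic", "healthy"),
                              n_subjects = NULL,
                              true_hka_mean = NULL, true_hka_sd = NULL,
                              fma_fta_mean = 3.1, fma_fta_sd = 1.0,
                              ankle_center_offset_mean = 0.8,
                              ankle_center_offset_sd = 0.3,
                              femur_len_mm = 430, tibia_len_mm = 380,
                              landmark_noise_sd_mm = 1.5,
                              rater_bias_sd_mm = 1.5,
                              session_sd_deg = 0.5,
                              seed = 1L) {
  group <- match.arg(group)
  if (is.null(n_subjects)) n_subjects <- if (group == "orthopedic") 17L else 50L
  if (group == "orthopedic") {
    if (is.null(true_hka_mean)) true_hka_mean <- 178.8
    if (is.null(true_hka_sd)) true_hka_sd <- 5.2
  } else {
    # back out HKA moments from the healthy-group PKA target 182.6 +/- 2.5,
    # accounting for the alignment coupling of the discrepancy (below):
    # sd(PKA) = (1 - gamma) * sd(HKA) combined with the residual discrepancy
    # variance gives sd(HKA)^2 = sdP^4 / (sdP^2 - sdD^2)
    sd_d2 <- fma_fta_sd^2 + ankle_center_offset_sd^2
    if (is.null(true_hka_mean)) {
      true_hka_mean <- 182.6 - fma_fta_mean - ankle_center_offset_mean
    }
    if (is.null(true_hka_sd)) {
      true_hka_sd <- if (sd_d2 >= 2.5^2) 0 else sqrt(2.5^4 / (2.5^2 - sd_d2))
    }
  }
  cfg <- list(group = group, n_subjects = as.integer(n_subjects),
              true_hka_mean = true_hka_mean, true_hka_sd = true_hka_sd,
              fma_fta_mean = fma_fta_mean, fma_fta_sd = fma_fta_sd,
              ankle_center_offset_mean = ankle_center_offset_mean,
              ankle_center_offset_sd = ankle_center_offset_sd,
              femur_len_mm = femur_len_mm, tibia_len_mm = tibia_len_mm,
              landmark_noise_sd_mm = landmark_noise_sd_mm,
              rater_bias_sd_mm = rater_bias_sd_mm,
              session_sd_deg = session_sd_deg,
              seed = as.integer(seed))
  # The photo-radio discrepancy (FMA-FTA + ankle offset) is mildly coupled to
  # alignment: its conditional mean shifts by -gamma * (HKA - mean). gamma is
  # chosen from the configured variances so the population regression of HKA
  # on noise-free PKA has unit slope (gamma * (1 - gamma) = var_D / var_HKA),
  # matching the near-unit calibration slope seen clinically; a purely
  # additive independent discrepancy would attenuate the slope below that.
  cfg$alignment_coupling <- if (cfg$true_hka_sd > 0) {
    c_ratio <- (cfg$fma_fta_sd^2 + cfg$ankle_center_offset_sd^2) /
      cfg$true_hka_sd^2
    0.5 * (1 - sqrt(max(1 - 4 * c_ratio, 0)))
  } else 0
  sds <- c(cfg$true_hka_sd, cfg$fma_fta_sd, cfg$ankle_center_offset_sd,
           cfg$landmark_noise_sd_mm, cfg$rater_bias_sd_mm, cfg$session_sd_deg)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise/population SDs must be finite and non-negative", call. = FALSE)
  }
  if (cfg$femur_len_mm <= 0 || cfg$tibia_len_mm <= 0) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  if (cfg$n_subjects < 3L) stop("n_subjects must be at least 3", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %s group, n = %d, ",
                     "HKA %.1f +/- %.2f deg, seed %d\n"),
              x$group, x$n_subjects, x$true_hka_mean, x$true_hka_sd, x$seed))
  invisible(x)
}

# direction "down rotated CCW by theta degrees" in the limb-local frame
.u_dir <- function(theta_deg) {
  t <- theta_deg * pi / 180
  c(sin(t), -cos(t))
}

#' Draw one synthetic limb with known true alignment
#'
#' Builds a planar skeleton in the limb-local frame: femoral head above the
#' knee, tibial axis rotated off the femoral axis by the drawn varus/valgus
#' deviation, ASIS offset laterally so the mechanical-vs-topographic femoral
#' axis angle matches its draw, and photographic surface landmarks placed so
#' the noise-free PKA equals `true HKA + FMA-FTA + ankle-centre offset`.
#' Deterministic given the config seed and subject id.
#'
#' @param cfg a [simulation_config()].
#' @param subject_id integer or label identifying the subject (substream key).
#' @param side `"left"` or `"right"` (ground truth is stored in the limb-local
#'   frame, which is side-independent).
#' @return An object of class `true_limb` with the true angles and the
#'   noise-free landmark sets of both modalities.
#' @export
generate_subject <- function(cfg, subject_id = 1L, side = "right") {
  stopifnot(inherits(cfg, "simulation_config"))
  side <- match.arg(side, c("left", "right"))
  gamma <- cfg$alignment_coupling %||% 0
  draws <- with_substream(substream_seed(cfg$seed, "subject", subject_id, side), {
    hka <- stats::rnorm(1, cfg$true_hka_mean, cfg$true_hka_sd)
    list(hka = hka,
         fma_fta = rnorm_trunc0(
           1, cfg$fma_fta_mean + gamma * (cfg$true_hka_mean - hka),
           cfg$fma_fta_sd),
         offset = stats::rnorm(1, cfg$ankle_center_offset_mean,
                               cfg$ankle_center_offset_sd))
  })
  true_hka <- draws$hka
  phi <- draws$fma_fta
  off <- draws$offset
  delta <- 180 - true_hka              # CCW femoral->tibial axis rotation
  lf <- cfg$femur_len_mm
  lt <- cfg$tibia_len_mm

  knee <- c(0, lt)                      # femoral notch = knee centre
  head <- knee + c(0, lf)
  eminence <- knee + 10 * .u_dir(delta) # just distal of the notch, on the axis
  ankle_r <- knee + lt * .u_dir(delta)
  # ASIS sits proximal of the femoral head (1.15 femur lengths from the
  # notch), offset laterally so the rFTA-FMA angle equals the drawn value;
  # never coincides with the head even at a zero angle
  asis <- knee + 1.15 * lf * c(-sin(phi * pi / 180), cos(phi * pi / 180))

  ankle_p <- knee + lt * .u_dir(delta - off)
  knee_w <- 90                          # condyle / malleolus marker spans (mm)
  mall_w <- 70
  radiograph <- list(
    ASIS = asis, FEMORAL_HEAD_CENTER = head, FEMORAL_NOTCH_CENTER = knee,
    TIBIAL_EMINENCE_CENTER = eminence, ANKLE_ARTICULAR_CENTER = ankle_r
  )
  photograph <- list(
    ASIS = asis,
    MED_CONDYLE = knee + c(knee_w / 2, 0),
    LAT_CONDYLE = knee - c(knee_w / 2, 0),
    MED_MALLEOLUS = ankle_p + c(mall_w / 2, 0),
    LAT_MALLEOLUS = ankle_p - c(mall_w / 2, 0)
  )
  structure(
    list(subject_id = subject_id, side = side,
         true_hka = true_hka, true_fma_fta = phi, ankle_offset = off,
         true_pka = true_hka + phi + off,
         radiograph = radiograph, photograph = photograph,
         knee_center = knee),
    class = "true_limb"
  )
}

#' @export
print.true_limb <- function(x, ...) {
  cat(sprintf("<true_limb> subject %s (%s): HKA %.2f, PKA %.2f, FMA-FTA %.2f\n",
              x$subject_id, x$side, x$true_hka, x$true_pka, x$true_fma_fta))
  invisible(x)
}

.rot2 <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

#' Render a noisy landmark annotation of a synthetic limb
#'
#' Applies, in order: the session stance perturbation (photographs only; a
#' rotation of the tibial segment about the knee centre, shared by every
#' rendering of that subject's photograph in that session), the rater's
#' systematic per-landmark shift (constant for that rater across subjects and
#' sessions), and fresh per-marking isotropic digitization noise. All draws
#' are deterministic given the config seed and the id tuple.
#'
#' @param limb a [generate_subject()] result.
#' @param modality `"photograph"` or `"radiograph"`.
#' @param rater_id,session_id,reading_id identifiers (substream keys).
#' @param cfg the [simulation_config()] used to generate the limb.
#' @return A [limb_annotation()] in the limb-local frame (scale 1).
#' @export
render_annotations <- function(limb, modality, rater_id = 1L, session_id = 1L,
                               reading_id = 1L, cfg) {
  stopifnot(inherits(limb, "true_limb"), inherits(cfg, "simulation_config"))
  modality <- match.arg(modality, c("photograph", "radiograph"))
  pts <- limb[[modality]]

  if (modality == "photograph" && cfg$session_sd_deg > 0) {
    eps <- with_substream(
      substream_seed(cfg$seed, "session", limb$subject_id, limb$side, session_id),
      stats::rnorm(1, 0, cfg$session_sd_deg)
    )
    rot <- .rot2(eps)
    kc <- limb$knee_center
    for (nm in c("MED_MALLEOLUS", "LAT_MALLEOLUS")) {
      pts[[nm]] <- as.numeric(kc + rot %*% (pts[[nm]] - kc))
    }
  }

  if (cfg$rater_bias_sd_mm > 0) {
    for (nm in names(pts)) {
      shift <- with_substream(
        substream_seed(cfg$seed, "raterbias", rater_id, modality, nm),
        stats::rnorm(2, 0, cfg$rater_bias_sd_mm)
      )
      pts[[nm]] <- pts[[nm]] + shift
    }
  }

  if (cfg$landmark_noise_sd_mm > 0) {
    noise <- with_substream(
      substream_seed(cfg$seed, "marking", limb$subject_id, limb$side, modality,
                     session_id, rater_id, reading_id),
      matrix(stats::rnorm(2L * length(pts), 0, cfg$landmark_noise_sd_mm),
             ncol = 2L)
    )
    for (i in seq_along(pts)) pts[[i]] <- pts[[i]] + noise[i, ]
  }

  limb_annotation(side = limb$side, modality = modality,
                  landmarks = pts, scale_mm_per_px = 1)
}

#' Generate a paired PKA/HKA accuracy dataset
#'
#' Emulates the accuracy study design: a cohort of limbs measured in both
#' modalities by one rater in one session (the stance perturbation is not
#' drawn: photograph and radiograph share the acquisition). By default 33
#' limbs from `ceiling(33/2) = 17` subjects, limbs pooled as independent
#' observations.
#'
#' @param cfg a [simulation_config()] (orthopedic preset matches the design).
#' @param n_limbs number of limbs (default 33).
#' @param one_limb_per_subject if `TRUE`, each limb belongs to a distinct
#'   subject (per-subject analysis toggle); otherwise limbs are assigned
#'   bilaterally to `ceiling(n_limbs / 2)` subjects.
#' @return Data frame with columns `subject_id`, `limb_side`, `pka_deg`,
#'   `hka_deg`, `fma_fta_deg`, `true_hka`, `true_pka`.
#' @export
generate_accuracy_dataset <- function(cfg, n_limbs = 33L,
                                      one_limb_per_subject = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"), n_limbs >= 3L)
  if (one_limb_per_subject) {
    subj <- seq_len(n_limbs)
    side <- rep("right", n_limbs)
  } else {
    subj <- rep(seq_len(ceiling(n_limbs / 2)), each = 2L)[seq_len(n_limbs)]
    side <- rep(c("right", "left"), length.out = n_limbs)
  }
  cfg_acc <- cfg
  cfg_acc$session_sd_deg <- 0   # single shared acquisition
  # a single rater's systematic shift is unidentifiable from the population
  # photo-radio offset in this design; the generator attributes the whole
  # systematic discrepancy to fma_fta + ankle_center_offset
  cfg_acc$rater_bias_sd_mm <- 0
  rows <- lapply(seq_len(n_limbs), function(i) {
    limb <- generate_subject(cfg_acc, subject_id = subj[i], side = side[i])
    photo <- render_annotations(limb, "photograph", rater_id = 1L,
                                session_id = 1L, reading_id = 1L, cfg_acc)
    radio <- render_annotations(limb, "radiograph", rater_id = 1L,
                                session_id = 1L, reading_id = 1L, cfg_acc)
    data.frame(subject_id = subj[i], limb_side = side[i],
               pka_deg = pka_angle(photo)$value,
               hka_deg = hka_angle(radio)$value,
               fma_fta_deg = fma_fta_angle(radio)$value,
               true_hka = limb$true_hka, true_pka = limb$true_pka)
  })
  do.call(rbind, rows)
}

#' Generate the reliability study's rating matrices
#'
#' Emulates the reliability design: one limb per subject photographed in
#' `n_sessions` sessions, each photograph digitized `n_readings` times by each
#' of `n_raters` raters. Returns the three rating designs: per-rater
#' intrarater matrices (reading 1 vs 2 of session 1), the interrater matrix
#' (first readings of session 1, one column per rater), and the test-retest
#' matrix (first readings of sessions 1 and 2, rows stacked over raters).
#'
#' @param cfg a [simulation_config()] (healthy preset matches the design).
#' @param n_raters,n_sessions,n_readings design sizes (defaults 3, 2, 2).
#' @param side which limb (default `"right"`).
#' @return List with `long` (every rendered measurement), `intrarater`
#'   (list of [ratings_matrix()] per rater), `interrater`, `test_retest`.
#' @export
generate_reliability_dataset <- function(cfg, n_raters = 3L, n_sessions = 2L,
                                         n_readings = 2L, side = "right") {
  stopifnot(inherits(cfg, "simulation_config"),
            n_raters >= 2L, n_sessions >= 2L, n_readings >= 2L)
  grid <- expand.grid(reading = seq_len(n_readings), rater = seq_len(n_raters),
                      session = seq_len(n_sessions),
                      subject = seq_len(cfg$n_subjects))
  pka <- numeric(nrow(grid))
  limbs <- lapply(seq_len(cfg$n_subjects), function(s) {
    generate_subject(cfg, subject_id = s, side = side)
  })
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ann <- render_annotations(limbs[[g$subject]], "photograph",
                              rater_id = g$rater, session_id = g$session,
                              reading_id = g$reading, cfg)
    pka[i] <- pka_angle(ann)$value
  }
  long <- data.frame(subject_id = grid$subject, limb_side = side,
                     session = grid$session, rater = grid$rater,
                     reading = grid$reading, pka_deg = pka)

  cell <- function(subject, session, rater, reading) {
    long$pka_deg[long$subject_id == subject & long$session == session &
                   long$rater == rater & long$reading == reading]
  }
  ns <- cfg$n_subjects
  intrarater <- lapply(seq_len(n_raters), function(r) {
    m <- cbind(vapply(seq_len(ns), cell, numeric(1), session = 1L,
                      rater = r, reading = 1L),
               vapply(seq_len(ns), cell, numeric(1), session = 1L,
                      rater = r, reading = 2L))
    ratings_matrix(m, measurement_labels = c("reading1", "reading2"))
  })
  names(intrarater) <- paste0("rater", seq_len(n_raters))
  inter <- vapply(seq_len(n_raters), function(r) {
    vapply(seq_len(ns), cell, numeric(1), session = 1L, rater = r,
           reading = 1L)
  }, numeric(ns))
  interrater <- ratings_matrix(inter,
                               measurement_labels = paste0("rater",
                                                           seq_len(n_raters)))
  tr <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
    cbind(vapply(seq_len(ns), cell, numeric(1), session = 1L, rater = r,
                 reading = 1L),
          vapply(seq_len(ns), cell, numeric(1), session = 2L, rater = r,
                 reading = 1L))
  }))
  test_retest <- ratings_matrix(
    tr,
    subject_ids = paste0("S", rep(seq_len(ns), times = n_raters),
                         "_r", rep(seq_len(n_raters), each = ns)),
    measurement_labels = c("photo1", "photo2")
  )
  list(long = long, intrarater = intrarater, interrater = interrater,
       test_retest = test_retest)
}
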