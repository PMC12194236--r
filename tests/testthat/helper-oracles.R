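# Independent oracles and fixture builders. These stay deliberately separate
# from the package's own code paths: rotation matrices for angles, explicit
# sums / aov / lm / solve() for the statistics.

rot_mat <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# direction "straight down" rotated CCW by theta, via the rotation matrix
down_rotated <- function(theta_deg) as.numeric(rot_mat(theta_deg) %*% c(0, -1))

# photographic configuration whose tibial axis is rotated by delta (CCW, deg)
# off the femoral axis: planned PKA = 180 - delta
make_photo_config <- function(delta_deg, femur = 400, tibia = 400,
                              knee_w = 100, mall_w = 60) {
  knee <- c(0, tibia)
  ankle <- knee + tibia * down_rotated(delta_deg)
  list(
    ASIS = c(0, tibia + femur),
    MED_CONDYLE = knee + c(knee_w / 2, 0),
    LAT_CONDYLE = knee - c(knee_w / 2, 0),
    MED_MALLEOLUS = ankle + c(mall_w / 2, 0),
    LAT_MALLEOLUS = ankle - c(mall_w / 2, 0)
  )
}

make_radio_config <- function(delta_deg, femur = 400, tibia = 400) {
  knee <- c(0, tibia)
  list(
    ASIS = c(-20, tibia + femur + 50),
    FEMORAL_HEAD_CENTER = knee + c(0, femur),
    FEMORAL_NOTCH_CENTER = knee,
    TIBIAL_EMINENCE_CENTER = knee + 10 * down_rotated(delta_deg),
    ANKLE_ARTICULAR_CENTER = knee + tibia * down_rotated(delta_deg)
  )
}

photo_ann <- function(delta_deg, side = "right", ...) {
  limb_annotation(side, "photograph", make_photo_config(delta_deg, ...))
}

radio_ann <- function(delta_deg, side = "right", ...) {
  limb_annotation(side, "radiograph", make_radio_config(delta_deg, ...))
}

# brute-force two-way mean squares by explicit double loops
ms_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - g)^2
  list(ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
       ms_error = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}

# ICC(A,k) point estimate straight from the oracle mean squares
icc_ak_oracle <- function(m) {
  ms <- ms_oracle(m)
  (ms$ms_rows - ms$ms_error) / (ms$ms_rows + (ms$ms_cols - ms$ms_error) / nrow(m))
}

# OLS via the normal equations, solved with base linear algebra
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       see = sqrt(sum(res^2) / (length(y) - 2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

random_ratings <- function(n, k, subject_sd = 2, col_sd = 0.5, noise_sd = 0.5) {
  subj <- rnorm(n, 0, subject_sd)
  cols <- rnorm(k, 0, col_sd)
  outer(subj, cols, "+") + matrix(rnorm(n * k, 0, noise_sd), n, k) + 180
}
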