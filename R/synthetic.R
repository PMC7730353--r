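#' Default synthetic activity archetypes
#'
#' Builds a seeded generator specification with class archetypes shaped
#' like waist-mounted IMU activity data: static postures are distinct
#' constant gravity orientations plus Gaussian noise (sitting / standing /
#' laying analogues); dynamic activities add a quasi-periodic,
#' amplitude-modulated oscillation at a class-specific fundamental in the
#' human-locomotion band 0.5-4 Hz (walking / stairs analogues), with
#' pairwise fundamental separation of at least 0.5 Hz. The 5-class default
#' mirrors the laying / sitting / standing / walking / climbing-stairs
#' inventory of the public smartphone dataset; 128 samples at 50 Hz per
#' window give the same 6 x 128 = 768 flattened geometry.
#'
#' Fixed magnitudes (documented, not tuned per run): gravity 1 g;
#' oscillation amplitude 0.4 g with modulation depth 0.3 at one quarter of
#' the fundamental; accelerometer noise sd 0.05 g; gyroscope noise sd
#' 0.05 rad/s, band-limited by a short circular moving average.
#'
#' @param n_classes number of classes, 2..10 (static and dynamic
#'   archetypes split as evenly as possible, statics first).
#' @param n_per_class windows per class (>= 1).
#' @param samples window length in samples (>= 16; default 128).
#' @param seed integer seed, part of the specification.
#' @param sample_rate Hz (default 50).
#' @param noise_sd accelerometer noise sd in g (default 0.05).
#' @return a list of class `synthetic_spec` with an `archetypes` tibble
#'   (`name`, `kind`, `fundamental_hz`, `amplitude`, `modulation_depth`,
#'   `or_x`, `or_y`, `or_z`, `noise_sd`) plus `n_per_class`, `samples`,
#'   `channels` (6), `sample_rate`, `gyro_noise_sd`, `seed`.
#' @export
#' @examples
#' spec <- default_synthetic_spec(5, n_per_class = 10, seed = 1)
#' spec$archetypes$name
default_synthetic_spec <- function(n_classes, n_per_class = 200,
                                   samples = 128, seed = 1,
                                   sample_rate = 50, noise_sd = 0.05) {
  if (n_classes < 2 || n_classes > 10) abort("n_classes must be in 2..10")
  if (n_per_class < 1) abort("n_per_class must be >= 1")
  if (samples < 16) abort("samples must be >= 16")
  # postures are tilted, never perfectly axis-aligned, and each has a
  # distinct gravity-component magnitude profile: a power spectrum is
  # blind to pure time shifts, so two single-axis orientations that only
  # swap which channel holds gravity would be spectrally identical
  static_orients <- rbind(
    c(0.90, 0.44, 0),     # laying: gravity mostly along the device x axis
    c(0, 0.60, 0.80),     # sitting: reclined torso
    c(0, 0.15, 0.99),     # standing: near-upright
    c(0.35, -0.50, 0.79), # reclined
    c(0.55, 0.30, 0.78)   # leaning
  )
  static_names <- c("laying", "sitting", "standing", "reclined", "leaning")
  dynamic_funds <- c(1.8, 1.0, 2.6, 3.4, 0.5)  # walking-like first
  dynamic_names <- c("walking", "climbing_stairs", "jogging", "running",
                     "shuffling")
  n_static <- ceiling(n_classes / 2)
  n_dynamic <- n_classes - n_static
  rows <- list()
  for (i in seq_len(n_static)) {
    o <- static_orients[i, ] / sqrt(sum(static_orients[i, ]^2))
    rows[[length(rows) + 1]] <- tibble(
      name = static_names[i], kind = "static", fundamental_hz = NA_real_,
      amplitude = 0, modulation_depth = 0,
      or_x = o[1], or_y = o[2], or_z = o[3], noise_sd = noise_sd)
  }
  for (i in seq_len(n_dynamic)) {
    rows[[length(rows) + 1]] <- tibble(
      name = dynamic_names[i], kind = "dynamic",
      fundamental_hz = dynamic_funds[i],
      amplitude = 0.4, modulation_depth = 0.3,
      or_x = 0, or_y = 0, or_z = 1, noise_sd = noise_sd)
  }
  structure(
    list(archetypes = dplyr::bind_rows(rows), n_per_class = n_per_class,
         samples = samples, channels = 6L, sample_rate = sample_rate,
         gyro_noise_sd = 0.05, seed = seed),
    class = "synthetic_spec"
  )
}

validate_synthetic_spec <- function(spec) {
  a <- spec$archetypes
  if (spec$n_per_class < 1 || spec$samples < 16) {
    abort("invalid spec: n_per_class >= 1 and samples >= 16 required")
  }
  norms <- sqrt(a$or_x^2 + a$or_y^2 + a$or_z^2)
  if (any(abs(norms - 1) > 1e-9)) abort("orientations must be unit vectors")
  dyn <- a[a$kind == "dynamic", ]
  if (any(!is.na(dyn$fundamental_hz) &
          (dyn$fundamental_hz <= 0 |
           dyn$fundamental_hz >= spec$sample_rate / 2))) {
    abort("dynamic fundamentals must lie in (0, sample_rate/2)")
  }
  if (any(a$noise_sd < 0)) abort("noise_sd must be >= 0")
  invisible(spec)
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic given the spec (which includes the seed): one shared
#' random stream consumed class-major then window-major. Per window the
#' three accelerometer channels carry 1 g times the class orientation,
#' plus — for dynamic classes — an amplitude-modulated sinusoid
#' `amplitude * (1 + depth * sin(2 pi f/4 t)) * sin(2 pi f t + phi)`
#' projected on a per-window random unit axis with per-window random phase
#' `phi`, plus white Gaussian noise; the three gyroscope channels carry
#' band-limited noise plus (dynamic) the oscillation's time derivative
#' scaled to rad/s.
#'
#' @param spec a [default_synthetic_spec()] (or hand-built) specification.
#' @return a [har_dataset()] with `n_per_class` windows per class,
#'   contiguous 0-based labels in archetype order.
#' @export
generate_windows <- function(spec) {
  validate_synthetic_spec(spec)
  a <- spec$archetypes
  n_cl <- nrow(a)
  n <- spec$samples
  t <- (seq_len(n) - 1) / spec$sample_rate
  gyro_rate_scale <- 0.5  # rad/s of angular rate per g of oscillation
  rows <- vector("list", n_cl * spec$n_per_class)
  withr_seed(spec$seed, {
    wi <- 0L
    for (k in seq_len(n_cl)) {
      orient <- c(a$or_x[k], a$or_y[k], a$or_z[k])
      for (w in seq_len(spec$n_per_class)) {
        acc <- matrix(rep(orient, each = n), nrow = 3, byrow = TRUE)
        gyro <- matrix(0, 3, n)
        if (a$kind[k] == "dynamic") {
          axis <- rnorm(3)
          axis <- axis / sqrt(sum(axis^2))
          phi <- runif(1, 0, 2 * pi)
          f <- a$fundamental_hz[k]
          am <- 1 + a$modulation_depth[k] * sin(2 * pi * (f / 4) * t)
          osc <- a$amplitude[k] * am * sin(2 * pi * f * t + phi)
          dosc <- a$amplitude[k] * am * (2 * pi * f) *
            cos(2 * pi * f * t + phi)
          acc <- acc + outer(axis, osc)
          gyro <- gyro + outer(axis, dosc) * gyro_rate_scale /
            (2 * pi * f)
        }
        if (a$noise_sd[k] > 0) {
          acc <- acc + matrix(rnorm(3 * n, sd = a$noise_sd[k]), 3, n)
        }
        gn <- matrix(rnorm(3 * n, sd = spec$gyro_noise_sd), 3, n)
        for (ch in 1:3) {  # band-limit with a circular 5-point average
          gn[ch, ] <- as.numeric(stats::filter(gn[ch, ], rep(1 / 5, 5),
                                               circular = TRUE))
        }
        gyro <- gyro + gn * sqrt(5)  # keep sd at gyro_noise_sd
        vals <- rbind(acc, gyro)
        colnames(vals) <- paste0("s", seq_len(n) - 1)
        rows[[wi + 1L]] <- dplyr::bind_cols(
          tibble(window_id = wi, label = k - 1L, channel = 0:5),
          as_tibble(vals))
        wi <- wi + 1L
      }
    }
  })
  har_dataset(dplyr::bind_rows(rows),
              sample_rate = spec$sample_rate,
              class_names = a$name,
              channel_names = c("acc_x", "acc_y", "acc_z",
                                "gyro_x", "gyro_y", "gyro_z"))
}

#' Write a synthetic spec as a JSON sidecar
#' @param spec a `synthetic_spec`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
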