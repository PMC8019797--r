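#' Synthetic B-mode phantom configuration
#'
#' Parameters of the virtual ultrasound phantom used to exercise the pipeline
#' without hardware. The generator emulates the two frame regimes the method
#' relies on: off-tissue frames showing only arc-shaped reverberation bands on
#' a dark background, and in-contact frames showing a speckled tissue band
#' whose depth extent grows with applied force (then saturates) and whose
#' noise statistics grow with force.
#'
#' Forces are in newtons (N), intensities on the 8-bit scale. The tissue band
#' extent follows
#' \deqn{e(F) = e_{min} + s\,(e_{max} - e_{min})\,(1 - e^{-(F - F_c)/\tau})}
#' for forces above the contact threshold \eqn{F_c}; the in-band additive
#' noise standard deviation is \eqn{\sigma(F) = \sigma_0 + s\,\sigma_1 (F -
#' F_c)} and the multiplicative speckle contrast \eqn{c(F) = c_0 + s\,c_1 (F -
#' F_c)}. `response_contrast` \eqn{s} scales all force dependence; at
#' \eqn{s = 0} frames carry no information about force, which is the
#' zero-class-separation condition used in recovery sweeps.
#'
#' @param shape integer `c(M, N)` frame dimensions (rows = depth).
#' @param background background intensity of dark regions.
#' @param arc_count,arc_start,arc_spacing,arc_width,arc_brightness,arc_decay,arc_curvature
#'   reverberation-arc pattern: number of arcs, depth fraction of the first
#'   arc, spacing between arcs (fraction of M), Gaussian half-width in rows,
#'   peak brightness of the first arc, per-arc brightness decay factor, and
#'   downward bend at the lateral edges (fraction of M).
#' @param nc_noise_sd additive noise s.d. outside tissue (and on no-contact
#'   frames).
#' @param contact_threshold force (N) below which the probe is not coupled and
#'   a no-contact frame is rendered. Default 1.5 N.
#' @param band_top top of the tissue band as a fraction of M.
#' @param extent_min,extent_max,extent_tau compression response: minimum and
#'   saturating band extent (fraction of M) and the exponential force constant
#'   (N).
#' @param tissue_brightness mean intensity of the tissue band.
#' @param speckle_base,speckle_slope multiplicative Rayleigh speckle contrast
#'   at contact and its growth per N.
#' @param noise_sd_base,noise_sd_slope in-band additive noise s.d. at contact
#'   and its growth per N.
#' @param response_contrast scale `s` of all force dependence in `[0, 1]`.
#' @param quality_band force interval `c(F_lo, F_hi)` (N) whose frames are
#'   labeled high quality.
#' @param gap distance (N) between the quality band edges and the sampled
#'   low-quality in-contact force regimes (the separability dial).
#' @param f_max maximum force of the scanning sweep (N).
#' @param seed base seed making the phantom (and its cached reference frame)
#'   reproducible.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L),
                           background = 6,
                           arc_count = 4L, arc_start = 0.12, arc_spacing = 0.16,
                           arc_width = 1.6, arc_brightness = 110,
                           arc_decay = 0.78, arc_curvature = 0.06,
                           nc_noise_sd = 2,
                           contact_threshold = 1.5,
                           band_top = 0.05,
                           extent_min = 0.25, extent_max = 0.95, extent_tau = 6,
                           tissue_brightness = 120,
                           speckle_base = 0.5, speckle_slope = 0.02,
                           noise_sd_base = 2, noise_sd_slope = 0.6,
                           response_contrast = 1,
                           quality_band = c(4, 9), gap = 2,
                           f_max = 20,
                           seed = 1L) {
  cfg <- list(shape = as.integer(shape), background = background,
              arc_count = as.integer(arc_count), arc_start = arc_start,
              arc_spacing = arc_spacing, arc_width = arc_width,
              arc_brightness = arc_brightness, arc_decay = arc_decay,
              arc_curvature = arc_curvature, nc_noise_sd = nc_noise_sd,
              contact_threshold = contact_threshold, band_top = band_top,
              extent_min = extent_min, extent_max = extent_max,
              extent_tau = extent_tau, tissue_brightness = tissue_brightness,
              speckle_base = speckle_base, speckle_slope = speckle_slope,
              noise_sd_base = noise_sd_base, noise_sd_slope = noise_sd_slope,
              response_contrast = response_contrast,
              quality_band = as.numeric(quality_band), gap = gap,
              f_max = f_max, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$shape) != 2L || any(cfg$shape < 8L))
    stop_sonoqc("phantom shape must be at least 8 x 8", "sonoqc_config_error")
  qb <- cfg$quality_band
  if (length(qb) != 2L || !(0 < qb[1] && qb[1] < qb[2] && qb[2] <= cfg$f_max))
    stop_sonoqc("quality_band must satisfy 0 < F_lo < F_hi <= f_max",
                "sonoqc_config_error")
  if (cfg$extent_min <= 0 || cfg$extent_max > 1 ||
      cfg$extent_min > cfg$extent_max)
    stop_sonoqc("band extents must lie in (0, 1] with extent_min <= extent_max",
                "sonoqc_config_error")
  if (cfg$gap < 0) stop_sonoqc("gap must be >= 0", "sonoqc_config_error")
  if (cfg$response_contrast < 0)
    stop_sonoqc("response_contrast must be >= 0", "sonoqc_config_error")
  invisible(cfg)
}

#' Create a virtual phantom
#'
#' Instantiates a phantom from its configuration and caches the no-contact
#' reference frame (rendered at the config's base seed), which all feature
#' extraction correlates against.
#'
#' @param config a [phantom_config()].
#' @return list of class `virtual_phantom` with fields `config` and
#'   `reference`.
#' @export
virtual_phantom <- function(config = phantom_config()) {
  ph <- structure(list(config = config, reference = NULL),
                  class = "virtual_phantom")
  ph$reference <- render_no_contact(ph, seed = config$seed)
  ph
}

# Deterministic arc pattern (reverberation bands) shared by all no-contact
# renders of a phantom.
arc_pattern <- function(cfg) {
  M <- cfg$shape[1]; N <- cfg$shape[2]
  img <- matrix(cfg$background, M, N)
  lat <- ((seq_len(N) - (N + 1) / 2) / (N / 2))  # [-1, 1] across the aperture
  rows <- seq_len(M)
  for (k in seq_len(cfg$arc_count)) {
    depth <- cfg$arc_start + (k - 1) * cfg$arc_spacing
    amp <- cfg$arc_brightness * cfg$arc_decay^(k - 1)
    center <- M * (depth + cfg$arc_curvature * lat^2)  # bends downward at edges
    prof <- exp(-outer(rows, center, `-`)^2 / (2 * cfg$arc_width^2))
    img <- img + amp * prof
  }
  img
}

#' Render a no-contact frame
#'
#' Dark background with bright arc-shaped reverberation bands plus light
#' additive speckle. Deterministic given `(config, seed)`.
#'
#' @param phantom a [virtual_phantom()].
#' @param seed integer seed for the speckle component; defaults to the
#'   phantom's base seed (reproducing the cached reference).
#' @return frame matrix (8-bit quantized).
#' @export
render_no_contact <- function(phantom, seed = phantom$config$seed) {
  cfg <- phantom$config
  base <- arc_pattern(cfg)
  with_seed(seed, {
    noisy <- base + rnorm(length(base), sd = cfg$nc_noise_sd)
    as_us_frame(round(clamp(noisy, 0, 255)))
  })
}

# Band extent (fraction of M) for a given force; monotone, saturating.
band_extent <- function(cfg, force) {
  s <- cfg$response_contrast
  f <- pmax(force - cfg$contact_threshold, 0)
  cfg$extent_min + s * (cfg$extent_max - cfg$extent_min) *
    (1 - exp(-f / cfg$extent_tau))
}

#' Render an in-contact frame at a given force
#'
#' Below the contact-threshold force a no-contact frame is returned. Above it,
#' a speckled tissue band is rendered: multiplicative Rayleigh speckle (unit
#' mean) on a bright band whose depth extent follows the compression response,
#' plus in-band additive Gaussian noise whose s.d. follows the noise response,
#' then 8-bit quantization. The band bottom is stochastically rounded so the
#' expected extent varies smoothly with force despite row quantization.
#'
#' @inheritParams render_no_contact
#' @param force applied probe force in N (>= 0).
#' @return frame matrix (8-bit quantized).
#' @export
render_contact <- function(phantom, force, seed = phantom$config$seed) {
  if (!is.numeric(force) || length(force) != 1L || force < 0)
    stop_sonoqc("force must be a non-negative scalar (N)", "sonoqc_domain_error")
  cfg <- phantom$config
  if (force < cfg$contact_threshold) return(render_no_contact(phantom, seed))
  M <- cfg$shape[1]; N <- cfg$shape[2]
  s <- cfg$response_contrast
  df <- force - cfg$contact_threshold
  contrast <- clamp(cfg$speckle_base + s * cfg$speckle_slope * df, 0, 1.5)
  add_sd <- cfg$noise_sd_base + s * cfg$noise_sd_slope * df
  extent <- band_extent(cfg, force)
  with_seed(seed, {
    img <- matrix(cfg$background, M, N) +
      rnorm(M * N, sd = cfg$nc_noise_sd)
    top <- max(1L, round(cfg$band_top * M) + 1L)
    bottom_f <- (cfg$band_top + extent) * M
    bottom <- min(M, floor(bottom_f + runif(1)))  # stochastic rounding
    if (bottom >= top) {
      band_rows <- top:bottom
      n_px <- length(band_rows) * N
      # Rayleigh amplitude scaled to unit mean: scale b = sqrt(2/pi)
      ray <- sqrt(2 / pi) * sqrt(-2 * log(runif(n_px)))
      band <- cfg$tissue_brightness * (1 + contrast * (ray - 1)) +
        rnorm(n_px, sd = add_sd)
      img[band_rows, ] <- band
    }
    as_us_frame(round(clamp(img, 0, 255)))
  })
}

#' @exportS3Method
print.virtual_phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("virtual B-mode phantom: %d x %d frames, seed %d\n",
              cfg$shape[1], cfg$shape[2], cfg$seed))
  cat(sprintf("  contact threshold %.2f N; quality band [%.1f, %.1f] N, gap %.1f N\n",
              cfg$contact_threshold, cfg$quality_band[1], cfg$quality_band[2],
              cfg$gap))
  cat(sprintf("  compression response: extent %.2f -> %.2f of depth (tau %.1f N)\n",
              cfg$extent_min, cfg$extent_max, cfg$extent_tau))
  invisible(x)
}

# Default force sampler: "high" forces are uniform in the quality band; "low"
# forces are drawn uniformly from one of the available off-band regimes
# (no-contact, under-compressed below F_lo - gap, over-compressed above
# F_hi + gap), chosen with equal probability.
default_force_sampler <- function(cfg) {
  qb <- cfg$quality_band
  lows <- list(c(0, cfg$contact_threshold))
  if (qb[1] - cfg$gap > cfg$contact_threshold)
    lows <- c(lows, list(c(cfg$contact_threshold, qb[1] - cfg$gap)))
  if (qb[2] + cfg$gap < cfg$f_max)
    lows <- c(lows, list(c(qb[2] + cfg$gap, cfg$f_max)))
  function(label) {
    if (label == "high") return(runif(1, qb[1], qb[2]))
    rg <- lows[[sample.int(length(lows), 1L)]]
    runif(1, rg[1], rg[2])
  }
}

# In-contact-only sampler (used e.g. in class-separation sweeps, where the
# gate would otherwise classify all no-contact frames correctly by itself).
in_contact_force_sampler <- function(cfg) {
  qb <- cfg$quality_band
  lows <- list()
  if (qb[1] - cfg$gap > cfg$contact_threshold)
    lows <- c(lows, list(c(cfg$contact_threshold, qb[1] - cfg$gap)))
  if (qb[2] + cfg$gap < cfg$f_max)
    lows <- c(lows, list(c(qb[2] + cfg$gap, cfg$f_max)))
  if (length(lows) == 0L)
    stop_sonoqc("no in-contact low-quality force regime exists for this config",
                "sonoqc_config_error")
  function(label) {
    if (label == "high") return(runif(1, qb[1], qb[2]))
    rg <- lows[[sample.int(length(lows), 1L)]]
    runif(1, rg[1], rg[2])
  }
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` forces inside the quality band (labeled `"high"`) and
#' `n_per_class` outside it (no-contact, under- and over-compressed regimes;
#' labeled `"low"`), renders one frame per force, and optionally writes the
#' frames as PNG plus a CSV manifest. Fully reproducible from `seed`.
#'
#' @param phantom a [virtual_phantom()].
#' @param n_per_class frames per class (>= 1).
#' @param dir output directory for PNG frames and `manifest.csv`; `NULL`
#'   (default) keeps the dataset in memory only.
#' @param force_sampler optional function `f(label)` returning a force; the
#'   default samples as described above.
#' @param seed integer seed.
#' @return a [labeled_frame_set()] with in-memory frames and a `force` column
#'   in its entries.
#' @export
generate_dataset <- function(phantom, n_per_class, dir = NULL,
                             force_sampler = NULL, seed = phantom$config$seed) {
  if (n_per_class < 1L)
    stop_sonoqc("n_per_class must be >= 1", "sonoqc_config_error")
  cfg <- phantom$config
  if (is.null(force_sampler)) force_sampler <- default_force_sampler(cfg)
  labels <- rep(c("high", "low"), each = n_per_class)
  forces <- with_seed(seed, vapply(labels, force_sampler, numeric(1)))
  n <- length(labels)
  ids <- sprintf("frame_%05d", seq_len(n))
  frames <- lapply(seq_len(n), function(i)
    render_contact(phantom, forces[i], seed = derive_seed(seed, i)))
  names(frames) <- ids
  paths <- rep(NA_character_, n)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) {
      ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop_sonoqc(sprintf("cannot create directory: %s", dir),
                           "sonoqc_io_error")
    }
    paths <- file.path(dir, paste0(ids, ".png"))
    for (i in seq_len(n)) write_frame(frames[[i]], paths[i])
    manifest <- data.frame(frame_id = ids, path = paths, label = labels,
                           force = forces, stringsAsFactors = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  labeled_frame_set(frames = frames, labels = labels, ids = ids,
                    paths = paths, forces = forces)
}
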