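#' Feature-extraction configuration
#'
#' Thresholds and window size for the three B-mode quality features.
#'
#' @param t_corr correlation threshold in \code{[0, 1]} for the contact gate.
#'   Default 0.7.
#' @param t_comp intensity threshold in \code{[0, 255]} for the compression
#'   feature. Default 20 (8-bit scale).
#' @param wiener_window integer vector \code{c(P, Q)} of odd window dimensions
#'   for the adaptive Wiener filter. Default \code{c(5, 5)}.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(t_corr = 0.7, t_comp = 20, wiener_window = c(5L, 5L)) {
  if (!is.numeric(t_corr) || length(t_corr) != 1L || t_corr < 0 || t_corr > 1)
    stop_sonoqc("t_corr must be a scalar in [0, 1]", "sonoqc_config_error")
  if (!is.numeric(t_comp) || length(t_comp) != 1L || t_comp < 0 || t_comp > 255)
    stop_sonoqc("t_comp must be a scalar in [0, 255]", "sonoqc_config_error")
  w <- as.integer(wiener_window)
  if (length(w) != 2L || any(w < 1L) || any(w %% 2L == 0L))
    stop_sonoqc("wiener_window must be two odd positive integers",
                "sonoqc_config_error")
  structure(list(t_corr = t_corr, t_comp = t_comp, wiener_window = w),
            class = "feature_config")
}

#' Pearson correlation between a frame and the no-contact reference
#'
#' The contact feature is the Pearson correlation between the current frame
#' and the reference frame acquired with the probe off the tissue: centered
#' cross-product over the product of centered norms, taken over all pixels.
#'
#' @param frame,reference numeric frame matrices of identical shape.
#' @return correlation in \code{[-1, 1]}.
#' @seealso [contact_gate()]
#' @export
compute_correlation <- function(frame, reference) {
  check_same_shape(frame, reference)
  a <- as.vector(frame); b <- as.vector(reference)
  if (sd(a) == 0 || sd(b) == 0)
    stop_sonoqc("correlation undefined: a frame has zero intensity variance",
                "sonoqc_degenerate_error")
  r <- cor(a, b)
  clamp(r, -1, 1)
}

#' Contact gate
#'
#' Fires (returns 1) when the frame is highly correlated with the no-contact
#' reference, i.e. the probe is judged not to be coupled to tissue. The
#' boundary is inclusive: correlation equal to `t_corr` fires the gate.
#'
#' @param correlation_raw Pearson correlation in \code{[-1, 1]}.
#' @param t_corr threshold in \code{[0, 1]}.
#' @return integer 0 or 1.
#' @export
contact_gate <- function(correlation_raw, t_corr = 0.7) {
  if (correlation_raw > 1 || correlation_raw < -1)
    stop_sonoqc("correlation_raw must lie in [-1, 1]", "sonoqc_range_error")
  if (correlation_raw >= t_corr) 1L else 0L
}

#' Tissue-compression feature
#'
#' Depth extent of the supra-threshold pixels relative to frame height: with U
#' and L the maximum and minimum (0-based) row indices containing any pixel at
#' or above `t_comp`, the feature is \code{(U - L) / M}. A proxy for tissue
#' deformation under probe force.
#'
#' @param frame numeric frame matrix.
#' @param t_comp intensity threshold on the 8-bit scale.
#' @return list with `compression` in \code{[0, 1]} and `no_signal` (TRUE when
#'   no pixel reaches the threshold, in which case compression is 0).
#' @export
compute_compression <- function(frame, t_comp = 20) {
  frame <- as_us_frame(frame)
  bright <- which(rowSums(frame >= t_comp) > 0L)
  if (length(bright) == 0L)
    return(list(compression = 0, no_signal = TRUE))
  list(compression = (max(bright) - min(bright)) / nrow(frame),
       no_signal = FALSE)
}

#' Adaptive Wiener filter for speckle suppression
#'
#' Pixelwise adaptive Wiener filter: local mean and variance over a P x Q
#' neighborhood (reflect-padded borders), a global noise-variance estimate
#' equal to the mean of the local variances, and the filtered pixel
#' \deqn{I_f = \mu + \frac{\max(\sigma^2 - \nu^2, 0)}{\max(\sigma^2,
#' \epsilon)} (I - \mu).}
#' The numerator clamp keeps the gain in \code{[0, 1]} where the local
#' variance falls below the noise floor.
#'
#' @param frame numeric frame matrix.
#' @param window integer \code{c(P, Q)}, odd, no larger than the frame.
#' @param eps denominator guard (default 1e-12).
#' @return list with `filtered` (real-valued frame) and `stats`, a list of
#'   class `local_statistics` holding `mu`, `sigma2` and the scalar `nu2`.
#' @export
wiener_filter <- function(frame, window = c(5L, 5L), eps = 1e-12) {
  frame <- as_us_frame(frame)
  w <- as.integer(window)
  if (length(w) != 2L || any(w < 1L) || any(w %% 2L == 0L))
    stop_sonoqc("window must be two odd positive integers", "sonoqc_config_error")
  if (w[1] > nrow(frame) || w[2] > ncol(frame))
    stop_sonoqc("Wiener window larger than the frame", "sonoqc_config_error")
  res <- wiener_filter_cpp(frame, w[1], w[2], eps)
  list(filtered = res$filtered,
       stats = structure(list(mu = res$mu, sigma2 = res$sigma2, nu2 = res$nu2),
                         class = "local_statistics"))
}

#' Residual-noise feature
#'
#' Mean plus standard deviation of the signed residual between a frame and its
#' Wiener-filtered version: \eqn{f_n = \bar{I_n} + \sigma_n} with
#' \eqn{I_n = I - I_f}. Constant frames give exactly 0.
#'
#' @inheritParams wiener_filter
#' @return scalar noise feature (intensity units).
#' @export
compute_noise_feature <- function(frame, window = c(5L, 5L)) {
  flt <- wiener_filter(frame, window)
  noise <- frame - flt$filtered
  mean(noise) + sd_population_free(noise)
}

# Sample standard deviation over all pixels (denominator n - 1, as sd()).
sd_population_free <- function(x) sd(as.vector(x))

#' Extract the full feature vector for one frame
#'
#' Computes the contact gate, compression and noise features. A frame on which
#' the correlation is undefined (zero intensity variance in either image) is
#' treated as not-in-contact: the gate is set to 1 and the raw correlation is
#' recorded as `NA`.
#'
#' @param frame,reference numeric frame matrices of identical shape.
#' @param config a [feature_config()].
#' @return list of class `us_features` with fields `contact`,
#'   `correlation_raw`, `compression`, `noise`, `no_signal`.
#' @export
extract_features <- function(frame, reference, config = feature_config()) {
  check_same_shape(frame, reference)
  corr <- tryCatch(compute_correlation(frame, reference),
                   sonoqc_degenerate_error = function(e) NA_real_)
  gate <- if (is.na(corr)) 1L else contact_gate(corr, config$t_corr)
  comp <- compute_compression(frame, config$t_comp)
  noise <- compute_noise_feature(frame, config$wiener_window)
  structure(list(contact = gate, correlation_raw = corr,
                 compression = comp$compression, noise = noise,
                 no_signal = comp$no_signal),
            class = "us_features")
}

#' Feature table for a set of frames
#'
#' @param frames a named list of frame matrices, or a character vector of file
#'   paths (names/paths become `frame_id`).
#' @param reference no-contact reference frame.
#' @param config a [feature_config()].
#' @return data.frame with columns `frame_id`, `correlation_raw`, `contact`,
#'   `compression`, `noise`, `no_signal`.
#' @export
extract_features_table <- function(frames, reference, config = feature_config()) {
  if (is.character(frames)) {
    ids <- basename(frames)
    frames <- lapply(frames, read_frame)
    names(frames) <- ids
  }
  if (is.null(names(frames))) names(frames) <- sprintf("frame_%04d", seq_along(frames))
  rows <- lapply(names(frames), function(id) {
    fv <- extract_features(frames[[id]], reference, config)
    data.frame(frame_id = id, correlation_raw = fv$correlation_raw,
               contact = fv$contact, compression = fv$compression,
               noise = fv$noise, no_signal = fv$no_signal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @exportS3Method
print.us_features <- function(x, ...) {
  cat("ultrasound frame features\n")
  cat(sprintf("  correlation vs no-contact ref: %s (gate %s)\n",
              ifelse(is.na(x$correlation_raw), "undefined",
                     format(x$correlation_raw, digits = 4)),
              ifelse(x$contact == 1L, "fired: treated as no contact",
                     "clear: in contact")))
  cat(sprintf("  compression f_c: %.4f%s\n", x$compression,
              if (x$no_signal) " (no supra-threshold signal)" else ""))
  cat(sprintf("  noise f_n:       %.4f\n", x$noise))
  invisible(x)
}
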