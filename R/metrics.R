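# Normalized 2-D Gaussian window for SSIM (Wang et al. defaults: 11 x 11,
# sigma 1.5).
ssim_window <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1L) / 2L
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Structural similarity index (SSIM)
#'
#' Single-scale SSIM with 8-bit dynamic range L = 255, an 11 x 11 Gaussian
#' weighting window with sigma = 1.5, and stability constants
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}. Local statistics are
#' computed on the fully valid window positions and the returned value is the
#' mean of the local SSIM map.
#'
#' @param a,b numeric frame matrices of identical shape, at least as large as
#'   the window.
#' @param L dynamic range (default 255).
#' @param K1,K2 stability constants (defaults 0.01 and 0.03).
#' @param window_size,sigma Gaussian window size (odd) and width.
#' @return SSIM in \code{[-1, 1]}.
#' @export
ssim <- function(a, b, L = 255, K1 = 0.01, K2 = 0.03,
                 window_size = 11L, sigma = 1.5) {
  check_same_shape(a, b)
  M <- nrow(a); N <- ncol(a)
  if (window_size > M || window_size > N)
    stop_sonoqc("frames smaller than the SSIM window", "sonoqc_shape_error")
  w <- ssim_window(window_size, sigma)
  h <- (window_size - 1L) / 2L
  vr <- (h + 1L):(M - h); vc <- (h + 1L):(N - h)  # valid centers
  zero <- matrix(0, length(vr), length(vc))
  mu_a <- zero; mu_b <- zero; saa <- zero; sbb <- zero; sab <- zero
  for (dq in -h:h) {
    for (dp in -h:h) {
      wk <- w[dp + h + 1L, dq + h + 1L]
      sa <- a[vr + dp, vc + dq, drop = FALSE]
      sb <- b[vr + dp, vc + dq, drop = FALSE]
      mu_a <- mu_a + wk * sa
      mu_b <- mu_b + wk * sb
      saa <- saa + wk * sa * sa
      sbb <- sbb + wk * sb * sb
      sab <- sab + wk * sa * sb
    }
  }
  var_a <- saa - mu_a^2
  var_b <- sbb - mu_b^2
  cov_ab <- sab - mu_a * mu_b
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  map <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(map)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' \eqn{10 \log_{10}(255^2 / \mathrm{MSE})} in dB on the 8-bit scale;
#' `Inf` when the frames are identical (MSE = 0).
#'
#' @param a,b numeric frame matrices of identical shape.
#' @param L peak signal value (default 255).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, L = 255) {
  check_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

#' Compare algorithm-selected and subjectively selected frames
#'
#' Computes SSIM and PSNR per position between the frames a quality-assessment
#' run selected and the frames a human rater selected at the same positions,
#' producing a per-location table (location, SSIM, PSNR).
#'
#' @param algorithm_frames,subjective_frames equal-length lists of
#'   shape-matched frame matrices, or character vectors of file paths.
#' @param locations optional location labels; defaults to "position 1", ...
#' @return data.frame of class `similarity_report` with columns `location`,
#'   `ssim`, `psnr`.
#' @export
compare_selections <- function(algorithm_frames, subjective_frames,
                               locations = NULL) {
  if (is.character(algorithm_frames))
    algorithm_frames <- lapply(algorithm_frames, read_frame)
  if (is.character(subjective_frames))
    subjective_frames <- lapply(subjective_frames, read_frame)
  n <- length(algorithm_frames)
  if (n == 0L)
    stop_sonoqc("empty frame lists", "sonoqc_shape_error")
  if (n != length(subjective_frames))
    stop_sonoqc("frame lists must have equal length", "sonoqc_shape_error")
  if (is.null(locations)) locations <- sprintf("position %d", seq_len(n))
  out <- data.frame(location = locations,
                    ssim = vapply(seq_len(n), function(i)
                      ssim(algorithm_frames[[i]], subjective_frames[[i]]),
                      numeric(1)),
                    psnr = vapply(seq_len(n), function(i)
                      psnr(algorithm_frames[[i]], subjective_frames[[i]]),
                      numeric(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_report", "data.frame")
  out
}

#' @exportS3Method
print.similarity_report <- function(x, ...) {
  cat("similarity between algorithm-selected and subjective frames\n")
  df <- as.data.frame(x)
  df$ssim <- sprintf("%.2f", df$ssim)
  df$psnr <- ifelse(is.infinite(df$psnr), "Inf", sprintf("%.2f", df$psnr))
  print(df, row.names = FALSE)
  invisible(x)
}
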