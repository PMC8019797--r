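#' Ultrasound frames
#'
#' A frame is a plain numeric matrix of pixel intensities on the native 8-bit
#' scale \code{[0, 255]}. Rows run along the beam (depth, increasing downward)
#' and columns along the lateral direction, the usual B-mode convention. On
#' disk frames are 8-bit grayscale PNG or TIFF; in memory they may hold real
#' values (e.g. after filtering).
#'
#' @param pixels numeric matrix of intensities in \code{[0, 255]}.
#' @return \code{as_us_frame} returns the validated matrix.
#' @examples
#' f <- as_us_frame(matrix(0:254, 15, 17))
#' dim(f)
#' @export
as_us_frame <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_sonoqc("a frame must be a numeric matrix", "sonoqc_shape_error")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop_sonoqc("a frame must be at least 2 x 2", "sonoqc_shape_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_sonoqc("frame intensities must lie in [0, 255]", "sonoqc_range_error")
  storage.mode(pixels) <- "double"
  pixels
}

#' Read an 8-bit grayscale frame from PNG or TIFF
#'
#' @param path file path; format is chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return numeric matrix with integer intensities in \code{[0, 255]}.
#' @export
read_frame <- function(path) {
  if (!file.exists(path))
    stop_sonoqc(sprintf("frame file not found: %s", path), "sonoqc_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_sonoqc(sprintf("unsupported frame format '.%s' (%s)", ext, path),
                "sonoqc_io_error"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale-as-RGB
  as_us_frame(round(img * 255))
}

#' Write a frame as 8-bit grayscale PNG or TIFF
#'
#' Real-valued input is clamped to \code{[0, 255]} and rounded to the 8-bit
#' grid before writing.
#'
#' @param frame numeric matrix of intensities.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  frame <- round(clamp(frame, 0, 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(frame, target = path),
    tif = ,
    tiff = tiff::writeTIFF(frame, where = path, bits.per.sample = 8L),
    stop_sonoqc(sprintf("unsupported frame format '.%s' (%s)", ext, path),
                "sonoqc_io_error"))
  invisible(path)
}

#' List frame files in a directory in lexicographic order
#'
#' @param dir directory containing PNG/TIFF frames.
#' @return character vector of full paths, sorted lexicographically.
#' @export
list_frames <- function(dir) {
  if (!dir.exists(dir))
    stop_sonoqc(sprintf("frame directory not found: %s", dir), "sonoqc_io_error")
  sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                  full.names = TRUE))
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_sonoqc(sprintf("frame shapes differ: %dx%d vs %dx%d",
                        nrow(a), ncol(a), nrow(b), ncol(b)),
                "sonoqc_shape_error")
  invisible(TRUE)
}
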