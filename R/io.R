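# Image input/output.  PNG and TIFF readers return intensities on an 8-bit
# (0-255) scale by default, which is the scale the default parameters
# (intensity floor, length weight) are expressed in.

#' Read a single-channel grayscale image
#'
#' Reads PNG or TIFF (by file extension).  Multi-channel images are averaged
#' to one channel.  Readers return values in `[0, 1]`; with
#' `scale_8bit = TRUE` (default) these are rescaled to `[0, 255]` so the
#' package defaults apply directly.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param scale_8bit Multiply unit-range data by 255 (default `TRUE`).
#' @return A numeric matrix.
#' @export
read_gray_image <- function(path, scale_8bit = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])),
                                               drop = FALSE], c(1, 2), mean)
  if (scale_8bit) img <- img * 255
  img
}

#' Write segmentation outputs
#'
#' Writes the label map as an 8-bit grayscale PNG (labels scaled by
#' `floor(255 / N)`, masked-out pixels 0), the estimated intensity-domain
#' bias field and the bias-corrected image as 32-bit float TIFF (each scaled
#' to `[0, 1]` by its maximum, recorded in the summary), the energy trace (if
#' tracked) as CSV, and a JSON run summary (constants, stddevs, iterations,
#' scales).
#'
#' @param result A [segment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_segmentation <- function(result, dir) {
  stopifnot(inherits(result, "segmentation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- result$config$n_phases
  paths <- c(labels = file.path(dir, "labels.png"),
             bias = file.path(dir, "bias.tif"),
             corrected = file.path(dir, "corrected.tif"),
             summary = file.path(dir, "summary.json"))
  png::writePNG(result$labels * floor(255 / n) / 255, paths["labels"])
  bias_scale <- max(result$bias_field)
  corr_scale <- max(result$corrected)
  tiff::writeTIFF(result$bias_field / bias_scale, paths["bias"],
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(result$corrected / corr_scale, paths["corrected"],
                  bits.per.sample = 32L, reduce = FALSE)
  if (!is.null(result$energy)) {
    paths <- c(paths, energy = file.path(dir, "energy.csv"))
    utils::write.csv(result$energy, paths["energy"], row.names = FALSE)
  }
  summary <- list(
    n_phases = n,
    iterations = result$iterations,
    converged = result$converged,
    constants = result$constants,
    constants_normalized = result$constants_normalized,
    stddevs = result$stddevs,
    bias_tiff_scale = bias_scale,
    corrected_tiff_scale = corr_scale,
    label_png_step = floor(255 / n)
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
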