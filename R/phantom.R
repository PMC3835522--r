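# Synthetic phantoms with known ground truth: a piecewise-constant tissue
# image, a smooth multiplicative bias field, and noise composed under one of
# the three standard image-formation models:
#   "scanner"      J = I * b + n        (scanner noise, independent of bias)
#   "biological"   J = (I + n) * b      (biological noise, scaled by bias)
#   "log_additive" log J = log I + log b + n
# For the first two models `noise_sd` is in intensity units; for the
# log-additive model it is in log-intensity units.

#' Phantom specification
#'
#' Describes a synthetic test image: region geometry, per-region true
#' intensities, a smooth bias field, a noise level and a formation model.
#' The default is the package's standard recovery phantom: 128 x 128, three
#' discs on a background, constants (40, 100, 160, 220) on an 8-bit scale, a
#' radial quadratic bias with 40% total variation, scanner noise of sd 10.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param regions List of labelled shapes (as in [initialize_level_set()]
#'   seeds: `type = "disc"` with `center`/`radius`, or `type = "rect"` with
#'   `rows`/`cols`).  Shapes are painted in order over a background label 1,
#'   receiving labels 2, 3, ...
#' @param constants True intensity per region, background first; length must
#'   be `length(regions) + 1`.
#' @param bias A bias spec for [make_smooth_bias()], or `NULL` for no bias.
#' @param noise_sd Noise standard deviation: a scalar, or one value per
#'   region.  Intensity units for models `"scanner"`/`"biological"`,
#'   log-intensity units for `"log_additive"`.
#' @param model Formation model (see above).
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         regions = list(
                           list(type = "disc", center = c(40, 40), radius = 20),
                           list(type = "disc", center = c(40, 92), radius = 20),
                           list(type = "disc", center = c(92, 64), radius = 22)),
                         constants = c(40, 100, 160, 220),
                         bias = list(type = "quadratic", amplitude = 0.4),
                         noise_sd = 10,
                         model = c("scanner", "biological", "log_additive"),
                         seed = 7L) {
  model <- match.arg(model)
  n_regions <- length(regions) + 1L
  if (length(constants) != n_regions)
    stop("need one constant per region (background first): expected ",
         n_regions, ", got ", length(constants), call. = FALSE)
  if (any(constants <= 0)) stop("constants must be positive", call. = FALSE)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, n_regions)
  if (length(noise_sd) != n_regions || any(noise_sd < 0))
    stop("noise_sd must be a nonnegative scalar or one value per region",
         call. = FALSE)
  structure(list(shape = as.integer(shape), regions = regions,
                 constants = constants, bias = bias, noise_sd = noise_sd,
                 model = model, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Smooth multiplicative bias field
#'
#' Builds a strictly positive, slowly varying field with mean exactly 1.
#' `type = "constant"` gives an all-ones field.  `type = "quadratic"` gives a
#' radial quadratic ramp whose minimum is `(1 - amplitude)` times its maximum
#' (so `amplitude = 0.4` is a 40% total intensity variation).
#' `type = "blurred"` Gaussian-blurs a white-noise field (blur width
#' `blur_sigma`, default 32 px) and rescales it to `1 +/- amplitude` before
#' mean-normalising.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param spec List with `type` and the fields above; `center` (row, col)
#'   optionally relocates the quadratic's apex (default: image centre).
#' @param seed Integer seed (used by `"blurred"` only).
#' @return A positive matrix with mean 1.
#' @export
make_smooth_bias <- function(shape, spec = list(type = "quadratic", amplitude = 0.4),
                             seed = 1L) {
  nr <- shape[1]; nc <- shape[2]
  type <- spec$type %||% "constant"
  raw <- switch(type,
    constant = matrix(1, nr, nc),
    quadratic = {
      amp <- spec$amplitude %||% 0.4
      ctr <- spec$center %||% c((nr + 1) / 2, (nc + 1) / 2)
      d2 <- outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, "+")
      q <- d2 / max(d2)
      1 - amp * q   # in [1 - amp, 1]: min = (1 - amp) * max
    },
    blurred = {
      amp <- spec$amplitude %||% 0.4
      bs <- spec$blur_sigma %||% 32
      z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
      z <- separable_gaussian_blur(z, bs)
      z <- z - mean(z)
      1 + amp * z / max(abs(z))
    },
    stop("unknown bias spec type: ", type, call. = FALSE)
  )
  b <- raw / mean(raw)
  if (any(b <= 0)) stop("bias field is not strictly positive", call. = FALSE)
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring any
# pre-existing global state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Large-support separable Gaussian blur with replicate padding; used only to
# synthesise smooth random bias fields.
separable_gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  pad_r <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  rows <- apply(pad_r, 2, function(col) stats::filter(col, g, sides = 2))
  rows <- rows[(r + 1):(r + nrow(m)), , drop = FALSE]
  pad_c <- rows[, c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r)), drop = FALSE]
  cols <- t(apply(pad_c, 1, function(row) stats::filter(row, g, sides = 2)))
  cols[, (r + 1):(r + ncol(m)), drop = FALSE]
}

#' Ground-truth label map from a region geometry
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param regions Shape list as in [phantom_spec()]; painted in order over a
#'   background of label 1.
#' @return Integer matrix of labels `1..(length(regions) + 1)`.
#' @export
make_label_map <- function(shape, regions) {
  lab <- matrix(1L, shape[1], shape[2])
  for (i in seq_along(regions))
    lab[seed_mask(shape, regions[[i]])] <- i + 1L
  lab
}

#' Generate a phantom bundle
#'
#' Builds the piecewise-constant true image from the geometry and constants,
#' the smooth bias field (mean 1), and composes them with noise under the
#' requested formation model.  The observed image is clamped to be strictly
#' positive.  Regeneration with the same spec reproduces the bundle
#' bit-for-bit.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `image` (observed J),
#'   `labels` (true label map), `bias` (true bias field, mean 1), `true_image`
#'   (noise- and bias-free I), `constants`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- make_label_map(spec$shape, spec$regions)
  I <- matrix(spec$constants[labels], spec$shape[1], spec$shape[2])
  b <- if (is.null(spec$bias)) matrix(1, spec$shape[1], spec$shape[2])
       else make_smooth_bias(spec$shape, spec$bias, seed = spec$seed)
  sd_map <- matrix(spec$noise_sd[labels], spec$shape[1], spec$shape[2])
  n <- with_seed(spec$seed,
                 matrix(stats::rnorm(length(I)), spec$shape[1], spec$shape[2])) * sd_map
  J <- switch(spec$model,
    scanner = I * b + n,
    biological = (I + n) * b,
    log_additive = exp(log(I) + log(b) + n)
  )
  J <- pmax(J, 1e-8)
  structure(list(image = J, labels = labels, bias = b, true_image = I,
                 constants = spec$constants, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %dx%d: %d regions, model '%s', noise sd %s, seed %d\n",
              nrow(x$image), ncol(x$image), length(x$constants),
              x$spec$model, paste(unique(x$spec$noise_sd), collapse = "/"),
              x$spec$seed))
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Writes the observed image and true bias as 32-bit float TIFF (each scaled
#' to `[0, 1]` by its maximum), the label map as an 8-bit grayscale PNG
#' (label index scaled by `floor(255 / N)`), and a JSON sidecar echoing the
#' spec together with the TIFF scale factors.
#'
#' @param phantom A [generate_phantom()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, "image.tif"),
             labels = file.path(dir, "labels.png"),
             bias = file.path(dir, "bias.tif"),
             spec = file.path(dir, "spec.json"))
  image_scale <- max(phantom$image)
  bias_scale <- max(phantom$bias)
  tiff::writeTIFF(phantom$image / image_scale, paths["image"],
                  bits.per.sample = 32L, reduce = FALSE)
  n <- length(phantom$constants)
  png::writePNG(phantom$labels * floor(255 / n) / 255, paths["labels"])
  tiff::writeTIFF(phantom$bias / bias_scale, paths["bias"],
                  bits.per.sample = 32L, reduce = FALSE)
  spec <- phantom$spec
  class(spec) <- NULL
  jsonlite::write_json(list(spec = spec, image_tiff_scale = image_scale,
                            bias_tiff_scale = bias_scale, label_png_step = floor(255 / n)),
                       paths["spec"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
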