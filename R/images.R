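# Stimulus construction: grayscale -> two-tone (Mooney) transforms.
#
# Images are plain numeric matrices with luminance in [0, 255] (row =
# image row, origin top-left). Binarized outputs use exactly {0, 255}.

#' Two-tone transform parameters
#'
#' Bundles the Gaussian smoothing level and luminance threshold that define
#' a two-tone (Mooney) transform. Catch stimuli are two-tones made without
#' smoothing, so `is_catch = TRUE` forces `sigma = 0`.
#'
#' @param sigma Standard deviation of the Gaussian smoothing filter, in
#'   pixels (`sigma >= 0`; `0` means no smoothing).
#' @param threshold Luminance cut in `[0, 255]`. Smoothed pixels strictly
#'   greater than the threshold map to white (255), all others to black (0).
#' @param is_catch Logical; catch transforms must have `sigma == 0`.
#' @return An object of class `"twotone_params"`.
#' @examples
#' twotone_params(sigma = 8, threshold = 120)
#' @export
twotone_params <- function(sigma, threshold, is_catch = (sigma == 0)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop_invalid("sigma must be a single finite number >= 0")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 255)
    stop_invalid("threshold must lie in [0, 255]")
  if (isTRUE(is_catch) && sigma != 0)
    stop_invalid("catch stimuli are unsmoothed: is_catch implies sigma == 0")
  structure(list(sigma = sigma, threshold = threshold,
                 is_catch = isTRUE(is_catch)),
            class = "twotone_params")
}

#' @export
print.twotone_params <- function(x, ...) {
  cat(sprintf("two-tone transform: sigma = %g px, threshold = %g%s\n",
              x$sigma, x$threshold, if (x$is_catch) " (catch)" else ""))
  invisible(x)
}

#' Touchscreen display geometry
#'
#' Display scale used throughout the pipeline: stimuli are presented at a
#' fixed physical height, so millimetre measures derive from a single
#' mm-per-pixel factor. Defaults are 680 px rendered at 273.9 mm
#' (roughly 30 degrees of visual angle at the study's viewing distance).
#'
#' @param image_height_px Stimulus height in pixels.
#' @param image_height_mm Physical stimulus height in millimetres.
#' @return An object of class `"display_geometry"` with the derived
#'   `mm_per_px` scale.
#' @examples
#' display_geometry()$mm_per_px
#' @export
display_geometry <- function(image_height_px = 680, image_height_mm = 273.9) {
  if (image_height_px <= 0 || image_height_mm <= 0)
    stop_invalid("display dimensions must be positive")
  structure(list(image_height_px = image_height_px,
                 image_height_mm = image_height_mm,
                 mm_per_px = image_height_mm / image_height_px),
            class = "display_geometry")
}

# symmetric-reflect index into 1..n (edge pixel repeated):
# ... 2 1 | 1 2 ... n | n n-1 ...
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with symmetric-reflect boundary padding
blur_gaussian <- function(img, sigma) {
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv_cols <- function(m) {          # convolve down each column
    n <- nrow(m)
    pad <- m[reflect_index((1L - r):(n + r), n), , drop = FALSE]
    K <- matrix(0, n, n + 2L * r)
    for (i in seq_len(n)) K[i, i:(i + 2L * r)] <- k
    K %*% pad
  }
  t(conv_cols(t(conv_cols(img))))
}

binarize <- function(img, threshold) (img > threshold) * 255

#' Make a two-tone (Mooney) image
#'
#' Smooths a grayscale image with a Gaussian filter and thresholds the
#' result to a strictly binary black/white image. Smoothing uses
#' symmetric-reflect boundary padding; pixels strictly above the threshold
#' become white (255), pixels at or below it black (0).
#'
#' @param gray Numeric matrix of luminance in `[0, 255]`, at least 8x8.
#' @param params A [twotone_params()] object.
#' @return A binary matrix of class `"twotone_image"` with the transform
#'   parameters attached as attribute `"params"`.
#' @examples
#' g <- matrix(seq(0, 255, length.out = 64), 64, 64)
#' tt <- make_twotone(g, twotone_params(sigma = 2, threshold = 127.5))
#' unique(as.vector(tt))
#' @seealso [make_catch()], [make_morph_sequence()]
#' @export
make_twotone <- function(gray, params) {
  assert_grayscale(gray)
  stopifnot(inherits(params, "twotone_params"))
  out <- binarize(blur_gaussian(gray, params$sigma), params$threshold)
  structure(out, params = params, class = c("twotone_image", class(out)))
}

#' Make a catch (unsmoothed two-tone) image
#'
#' Catch stimuli are two-tones generated by thresholding alone, with no
#' smoothing — easily recognizable, and used to index task compliance.
#' Equivalent to `make_twotone()` with `sigma = 0`.
#'
#' @inheritParams make_twotone
#' @param threshold Luminance cut in `[0, 255]`.
#' @export
make_catch <- function(gray, threshold) {
  make_twotone(gray, twotone_params(sigma = 0, threshold = threshold,
                                    is_catch = TRUE))
}

is_binary_image <- function(img) length(unique(as.vector(img))) <= 2L

quantize_levels <- function(img, n_levels) {
  stopifnot(n_levels >= 2L)
  round(img / 255 * (n_levels - 1)) / (n_levels - 1) * 255
}

morph_level_schedule <- function(n_steps) {
  if (n_steps == 5L) return(c(255L, 64L, 16L, 4L, 2L))
  lv <- round(exp(seq(log(255), log(2), length.out = n_steps)))
  # enforce strict decrease for very long schedules
  for (i in seq(2L, n_steps)) lv[i] <- min(lv[i], lv[i - 1L] - 1L)
  if (lv[n_steps] < 2L) stop_invalid("n_steps too large for a 255->2 schedule")
  as.integer(lv)
}

#' Grayscale-to-two-tone morph sequence
#'
#' Builds the frame sequence used to morph a grayscale cue into its
#' two-tone: luminance is re-quantized with a decreasing number of levels
#' (default schedule 255, 64, 16, 4, 2 over five steps), with smoothing
#' applied only on the final, binary frame, which is bitwise-equal to
#' `make_twotone(gray, params)`.
#'
#' @inheritParams make_twotone
#' @param n_steps Number of frames (>= 2).
#' @param levels Optional integer vector of quantization levels per frame,
#'   strictly decreasing and ending at 2; derived from `n_steps` if `NULL`.
#' @return An object of class `"morph_sequence"`: a list with `frames`
#'   (list of matrices), `levels`, `n_steps` and `params`.
#' @export
make_morph_sequence <- function(gray, params, n_steps = 5L, levels = NULL) {
  assert_grayscale(gray)
  if (!is.numeric(n_steps) || n_steps < 2L)
    stop_invalid("n_steps must be an integer >= 2")
  n_steps <- as.integer(n_steps)
  if (is.null(levels)) levels <- morph_level_schedule(n_steps)
  levels <- as.integer(levels)
  if (length(levels) != n_steps || any(diff(levels) >= 0L) ||
      levels[n_steps] != 2L)
    stop_invalid("levels must be strictly decreasing, one per frame, ending at 2")
  frames <- vector("list", n_steps)
  for (k in seq_len(n_steps - 1L))
    frames[[k]] <- quantize_levels(gray, levels[k])
  frames[[n_steps]] <- make_twotone(gray, params)
  structure(list(frames = frames, levels = levels, n_steps = n_steps,
                 params = params),
            class = "morph_sequence")
}

#' @export
print.morph_sequence <- function(x, ...) {
  cat(sprintf("morph sequence: %d frames, levels %s\n", x$n_steps,
              paste(x$levels, collapse = " -> ")))
  invisible(x)
}

resize_weights <- function(n_in, n_out, method) {
  pos <- ((seq_len(n_out)) - 0.5) * n_in / n_out + 0.5
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    i <- pmin(pmax(round(pos), 1L), n_in)
    W[cbind(seq_len(n_out), i)] <- 1
  } else {
    lo <- pmin(pmax(floor(pos), 1L), n_in)
    hi <- pmin(lo + 1L, n_in)
    w <- pmin(pmax(pos - lo, 0), 1)
    W[cbind(seq_len(n_out), lo)] <- W[cbind(seq_len(n_out), lo)] + (1 - w)
    W[cbind(seq_len(n_out), hi)] <- W[cbind(seq_len(n_out), hi)] + w
  }
  W
}

#' Resize an image to the display height
#'
#' Rescales to the display's fixed pixel height, preserving aspect ratio.
#' Binary (two-tone) images are resized with nearest-neighbour sampling so
#' they stay binary; grayscale images use bilinear interpolation.
#'
#' @param img Numeric image matrix.
#' @param geometry A [display_geometry()].
#' @param method `"auto"` (nearest for binary inputs, bilinear otherwise),
#'   `"nearest"`, or `"bilinear"`.
#' @return The resized matrix, `geometry$image_height_px` rows tall.
#' @export
resize_to_display <- function(img, geometry = display_geometry(),
                              method = c("auto", "nearest", "bilinear")) {
  assert_image(img)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is_binary_image(img)) "nearest" else "bilinear"
  h_out <- as.integer(geometry$image_height_px)
  if (nrow(img) == h_out) return(img)
  w_out <- max(1L, as.integer(round(ncol(img) * h_out / nrow(img))))
  R <- resize_weights(nrow(img), h_out, method)
  C <- resize_weights(ncol(img), w_out, method)
  R %*% unclass(img) %*% t(C)
}

#' Choose two-tone parameters for an image
#'
#' Stimulus sets use smoothing and threshold levels that vary per image.
#' This utility picks `sigma` as a fraction of image height and the
#' threshold as the luminance quantile of the smoothed image that yields a
#' target black-pixel fraction, and records both in the returned
#' parameters.
#'
#' @param gray Grayscale matrix.
#' @param sigma_frac Smoothing SD as a fraction of image height.
#' @param target_black Desired black-pixel fraction of the two-tone
#'   (default 0.5, the midpoint of the 0.45-0.55 band typically used).
#' @return A [twotone_params()] object whose threshold achieves the target
#'   black fraction on this image.
#' @export
choose_twotone_params <- function(gray, sigma_frac = 0.012,
                                  target_black = 0.5) {
  assert_grayscale(gray)
  if (target_black <= 0 || target_black >= 1)
    stop_invalid("target_black must lie strictly within (0, 1)")
  sigma <- sigma_frac * nrow(gray)
  sm <- blur_gaussian(gray, sigma)
  # pixels <= threshold are black, so the target quantile is the threshold
  thr <- as.numeric(quantile(sm, target_black, type = 1))
  thr <- min(max(thr, 0), 255)
  twotone_params(sigma = sigma, threshold = thr)
}

# PNG I/O -------------------------------------------------------------------

#' Read an image as a grayscale luminance matrix
#'
#' Reads an 8-bit PNG; RGB(A) inputs are converted to luminance with the
#' Rec. 601 weights. Values are returned on the 0-255 scale.
#'
#' @param path PNG file path.
#' @export
read_grayscale_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    a <- if (ch >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
         else a[, , 1]
  }
  a * 255
}

#' Write a luminance matrix as an 8-bit grayscale PNG
#'
#' @param img Matrix in `[0, 255]`.
#' @param path Output file path.
#' @export
write_grayscale_png <- function(img, path) {
  assert_image(img)
  png::writePNG(pmin(pmax(unclass(img) / 255, 0), 1), path)
  invisible(path)
}

#' Export a morph sequence as numbered PNG frames plus a JSON manifest
#'
#' @param ms A [make_morph_sequence()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
export_morph_sequence <- function(ms, dir) {
  stopifnot(inherits(ms, "morph_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(ms$n_steps))
    write_grayscale_png(ms$frames[[k]],
                        file.path(dir, sprintf("frame_%02d.png", k)))
  manifest <- list(n_steps = ms$n_steps, levels = ms$levels,
                   sigma = ms$params$sigma, threshold = ms$params$threshold,
                   is_catch = ms$params$is_catch)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
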