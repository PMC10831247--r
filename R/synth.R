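# Synthetic grayscale fixtures: smooth gradients + embedded high-contrast
# shapes + optional 1/f ("pink") noise, so the two-tone transform produces
# nontrivial figure/ground structure without any photographs.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic grayscale image
#'
#' Builds the recipe consumed by [generate_synthetic_grayscale()]: a
#' mid-grey background, an optional smooth linear luminance gradient,
#' `n_shapes` embedded high-contrast shapes (ellipses and convex
#' polygons), and additive noise with either a flat ("white") or
#' naturalistic 1/f ("pink") amplitude spectrum.
#'
#' @param width,height Image size in pixels (>= 8).
#' @param background Background luminance (default mid-grey, 128).
#' @param gradient_amp Peak-to-peak amplitude of a linear luminance ramp in
#'   a random direction; 0 disables it.
#' @param n_shapes Number of embedded shapes.
#' @param noise `"pink"`, `"white"` or `"none"`.
#' @param noise_sd Noise standard deviation in luminance units. The
#'   default is calibrated so synthetic grayscales land in the Sobel
#'   edge-density range typical of grayscale photographs (roughly 0.1),
#'   giving the fixtures photograph-like fine-scale texture.
#' @return A list of class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(width = 256, height = 256, background = 128,
                                 gradient_amp = 40, n_shapes = 3,
                                 noise = c("pink", "white", "none"),
                                 noise_sd = 35) {
  if (width < 8 || height < 8) stop_invalid("images must be at least 8x8")
  noise <- match.arg(noise)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, gradient_amp = gradient_amp,
                 n_shapes = as.integer(n_shapes), noise = noise,
                 noise_sd = noise_sd),
            class = "synthetic_image_spec")
}

pink_noise <- function(h, w, target_sd) {
  z <- matrix(rnorm(h * w), h, w)
  ky <- seq_len(h) - 1L; kx <- seq_len(w) - 1L
  fy <- pmin(ky, h - ky) / h
  fx <- pmin(kx, w - kx) / w
  f <- sqrt(outer(fy^2, fx^2, "+"))
  f[1, 1] <- Inf                       # remove DC
  n <- Re(fft(fft(z) / f, inverse = TRUE)) / (h * w)
  n / sd(n) * target_sd
}

rasterize_ellipse <- function(h, w, cx, cy, rx, ry, angle) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  u <- (x * cos(angle) + y * sin(angle)) / rx
  v <- (-x * sin(angle) + y * cos(angle)) / ry
  u^2 + v^2 <= 1
}

rasterize_polygon <- function(h, w, vertices) {
  x <- rep(seq_len(w), each = h)
  y <- rep(seq_len(h), times = w)
  matrix(points_in_polygon(x, y, vertices), h, w)
}

random_shape <- function(h, w, background) {
  kind <- sample(c("ellipse", "polygon"), 1L)
  cx <- runif(1, 0.2 * w, 0.8 * w)
  cy <- runif(1, 0.2 * h, 0.8 * h)
  # high contrast against the background, either polarity
  lum <- background + sample(c(-1, 1), 1L) * runif(1, 70, 110)
  lum <- min(max(lum, 5), 250)
  if (kind == "ellipse") {
    sh <- list(kind = "ellipse", cx = cx, cy = cy,
               rx = runif(1, 0.06, 0.16) * w, ry = runif(1, 0.06, 0.16) * h,
               angle = runif(1, 0, pi), luminance = lum)
  } else {
    nv <- sample(4:7, 1L)
    th <- (seq_len(nv) - 1L) * 2 * pi / nv + runif(nv, -0.25, 0.25) * 2 * pi / nv
    rad <- runif(nv, 0.06, 0.15) * min(h, w)
    sh <- list(kind = "polygon", cx = cx, cy = cy,
               vertices = cbind(x = cx + rad * cos(th), y = cy + rad * sin(th)),
               luminance = lum)
  }
  sh
}

#' Generate a deterministic synthetic grayscale image
#'
#' Renders a [synthetic_image_spec()] with a seeded RNG: identical seeds
#' give bitwise-identical images. Shapes are drawn opaquely over the
#' gradient background, then noise is added and luminance clamped to
#' `[0, 255]`. The drawn shape descriptions are attached as attribute
#' `"shapes"` so tests and ROI builders can target them.
#'
#' @param seed Integer seed.
#' @param spec A [synthetic_image_spec()].
#' @return A luminance matrix in `[0, 255]`.
#' @export
generate_synthetic_grayscale <- function(seed, spec = synthetic_image_spec()) {
  if (!inherits(spec, "synthetic_image_spec"))
    stop_invalid("spec must be a synthetic_image_spec")
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    img <- matrix(spec$background, h, w)
    if (spec$gradient_amp > 0) {
      th <- runif(1, 0, 2 * pi)
      gx <- matrix(rep(seq_len(w), each = h), h, w) / w - 0.5
      gy <- matrix(rep(seq_len(h), times = w), h, w) / h - 0.5
      ramp <- gx * cos(th) + gy * sin(th)
      img <- img + spec$gradient_amp * ramp / (max(ramp) - min(ramp) + 1e-12)
    }
    shapes <- list()
    if (spec$n_shapes > 0) {
      for (s in seq_len(spec$n_shapes)) {
        sh <- random_shape(h, w, spec$background)
        mask <- if (sh$kind == "ellipse")
          rasterize_ellipse(h, w, sh$cx, sh$cy, sh$rx, sh$ry, sh$angle)
        else rasterize_polygon(h, w, sh$vertices)
        img[mask] <- sh$luminance
        sh$area_px <- sum(mask)
        shapes[[s]] <- sh
      }
    }
    if (spec$noise == "pink") img <- img + pink_noise(h, w, spec$noise_sd)
    if (spec$noise == "white") img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 255)
    attr(img, "shapes") <- shapes
    img
  })
}

#' Generate a matched set of synthetic grayscale/two-tone stimuli
#'
#' Convenience builder for fixture sets: for each image it generates a
#' synthetic grayscale, picks per-image transform parameters with
#' [choose_twotone_params()], and returns the grayscale, the smoothed
#' two-tone, and a catch version (thresholded without smoothing).
#'
#' @param n_images Number of stimuli.
#' @param seed Integer seed; image `i` uses `seed + i`.
#' @param spec Shared [synthetic_image_spec()].
#' @param sigma_frac Smoothing SD as a fraction of image height.
#' @return A list with one element per image: `gray`, `twotone`, `catch`,
#'   and `params`.
#' @export
synthetic_stimulus_set <- function(n_images = 10, seed = 1,
                                   spec = synthetic_image_spec(),
                                   sigma_frac = 0.012) {
  lapply(seq_len(n_images), function(i) {
    g <- generate_synthetic_grayscale(seed + i, spec)
    p <- choose_twotone_params(g, sigma_frac = sigma_frac)
    list(gray = g,
         twotone = make_twotone(g, p),
         catch = make_catch(g, p$threshold),
         params = p)
  })
}
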