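# Low-level image statistics: Sobel edge density, and contrast energy /
# spatial coherence as Weibull scale/shape summaries of centre-surround
# (difference-of-Gaussians) contrast magnitude distributions computed at a
# fine (parvocellular-like) and a coarse (magnocellular-like) spatial scale.

SOBEL_STEP_RESPONSE <- 4 * 255  # |Gx| of an ideal 0 -> 255 vertical step

#' Sobel edge density
#'
#' Mean normalized Sobel gradient magnitude over interior pixels: the 3x3
#' Sobel operators are applied, per-pixel magnitude is divided by the
#' response of an ideal 0-to-255 luminance step (so values are comparable
#' across images) and capped at 1, then averaged. A constant image scores
#' 0; images dominated by full-contrast edges approach but do not exceed 1.
#'
#' @param img Numeric luminance matrix in `[0, 255]`, at least 3x3.
#' @return Scalar in `[0, 1]`.
#' @export
edge_density <- function(img) {
  assert_image(img, what = "image")
  img <- unclass(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) stop_invalid("image is smaller than the 3x3 Sobel kernel")
  s <- function(di, dj) img[(2L + di):(h - 1L + di), (2L + dj):(w - 1L + dj)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  mag <- pmin(sqrt(gx^2 + gy^2) / SOBEL_STEP_RESPONSE, 1)
  mean(mag)
}

#' Centre-surround local contrast map
#'
#' Difference-of-Gaussians filtering emulating retino-geniculate contrast
#' extraction: the image is smoothed with a centre and a wider surround
#' Gaussian and the absolute difference taken per pixel. `"parvo"` uses a
#' fine centre scale, `"magno"` a centre `scale_ratio` times coarser; the
#' surround SD is `surround_ratio` times the centre SD at either scale.
#' Both kernels integrate to one, so a constant image maps to all zeros
#' (DC rejection).
#'
#' @param img Luminance matrix.
#' @param scale `"parvo"` (fine) or `"magno"` (coarse).
#' @param center_sigma Centre SD in pixels at the parvo scale.
#' @param scale_ratio Magno:parvo centre-SD ratio.
#' @param surround_ratio Surround:centre SD ratio.
#' @return Nonnegative matrix of local contrast magnitudes.
#' @export
contrast_map <- function(img, scale = c("parvo", "magno"),
                         center_sigma = 1, scale_ratio = 4,
                         surround_ratio = 1.6) {
  assert_image(img)
  scale <- match.arg(scale)
  sc <- if (scale == "parvo") center_sigma else center_sigma * scale_ratio
  need <- 2L * max(1L, ceiling(4 * sc * surround_ratio)) + 1L
  if (nrow(img) < need || ncol(img) < need)
    stop_invalid("image smaller than the ", scale, " filter support (",
                 need, " px)")
  abs(blur_gaussian(unclass(img), sc) -
        blur_gaussian(unclass(img), sc * surround_ratio))
}

#' Weibull fit of a contrast-magnitude sample
#'
#' Maximum-likelihood Weibull parameters of a positive contrast sample.
#' The scale parameter (beta) is reported as contrast energy (CE) and the
#' shape parameter (gamma) as spatial coherence (SC). Zero values are
#' excluded before fitting (the Weibull likelihood is undefined at 0) and
#' the excluded fraction is reported; an all-zero sample returns the
#' degenerate sentinel `CE = 0`, `SC = NA` with a warning.
#'
#' @param contrast_values Numeric vector of nonnegative contrasts with at
#'   least 50 strictly positive values.
#' @param zero_tol Values at or below `zero_tol * max(contrast_values)`
#'   (or below an absolute floor of 1e-9, far beneath any real contrast
#'   on the 0-255 luminance scale) are treated as zero contrast and
#'   excluded: filtering flat image regions leaves floating-point
#'   cancellation dust many orders of magnitude below real contrasts,
#'   which would otherwise dominate the shape estimate.
#' @return List with `CE`, `SC`, `n_used`, `excluded_fraction`.
#' @export
weibull_fit <- function(contrast_values, zero_tol = 1e-8) {
  if (!is.numeric(contrast_values) || any(!is.finite(contrast_values)))
    stop_invalid("contrast_values must be finite numeric")
  cut <- max(zero_tol * max(contrast_values, 0), 1e-9)
  x <- contrast_values[contrast_values > cut]
  excluded <- 1 - length(x) / length(contrast_values)
  if (length(x) == 0L) {
    warning("all-zero contrast sample: returning degenerate CE = 0 sentinel")
    return(list(CE = 0, SC = NA_real_, n_used = 0L, excluded_fraction = excluded))
  }
  if (length(x) < 50L)
    stop_invalid("need >= 50 strictly positive contrast values, got ", length(x))
  fit <- tryCatch(
    MASS::fitdistr(x, "weibull", lower = c(1e-8, 1e-12)),
    error = function(e) suppressWarnings(MASS::fitdistr(x, "weibull")))
  list(CE = unname(fit$estimate["scale"]),
       SC = unname(fit$estimate["shape"]),
       n_used = length(x), excluded_fraction = excluded)
}

#' Bundle the image statistics of one stimulus
#'
#' Computes edge density and the pooled-scale (parvo + magno) Weibull
#' contrast summaries CE and SC for one image, together with the two-tone
#' transform parameters that produced it. Per-scale fits are included.
#'
#' @param img Luminance matrix.
#' @param params Optional [twotone_params()] of the stimulus (recorded in
#'   the output; taken from the image's `"params"` attribute if absent).
#' @inheritParams contrast_map
#' @return An object of class `"image_stats"`.
#' @export
compute_stats <- function(img, params = attr(img, "params"),
                          center_sigma = 1, scale_ratio = 4,
                          surround_ratio = 1.6) {
  assert_image(img)
  mp <- contrast_map(img, "parvo", center_sigma, scale_ratio, surround_ratio)
  mm <- contrast_map(img, "magno", center_sigma, scale_ratio, surround_ratio)
  fit_or_sentinel <- function(v) {
    if (all(v <= max(1e-8 * max(v, 0), 1e-9))) {
      warning("constant image: degenerate contrast distribution")
      list(CE = 0, SC = NA_real_, n_used = 0L, excluded_fraction = 1)
    } else weibull_fit(v)
  }
  pooled <- fit_or_sentinel(c(as.vector(mp), as.vector(mm)))
  fp <- fit_or_sentinel(as.vector(mp))
  fm <- fit_or_sentinel(as.vector(mm))
  structure(list(
    edge_density = edge_density(img),
    CE = pooled$CE, SC = pooled$SC,
    CE_parvo = fp$CE, SC_parvo = fp$SC,
    CE_magno = fm$CE, SC_magno = fm$SC,
    excluded_fraction = pooled$excluded_fraction,
    sigma = if (!is.null(params)) params$sigma else NA_real_,
    threshold = if (!is.null(params)) params$threshold else NA_real_),
    class = "image_stats")
}

#' @export
print.image_stats <- function(x, ...) {
  cat(sprintf("image stats: edge density %.4f, CE %.3f, SC %.3f (sigma %.3g, threshold %.3g)\n",
              x$edge_density, x$CE, x$SC, x$sigma, x$threshold))
  invisible(x)
}

#' Change in image statistics under two-tone transformation
#'
#' @param stats_twotone,stats_gray `"image_stats"` for the two-tone and its
#'   source grayscale.
#' @return List with `d_edge`, `d_CE`, `d_SC` (two-tone minus grayscale).
#' @export
stats_delta <- function(stats_twotone, stats_gray) {
  stopifnot(inherits(stats_twotone, "image_stats"),
            inherits(stats_gray, "image_stats"))
  list(d_edge = stats_twotone$edge_density - stats_gray$edge_density,
       d_CE = stats_twotone$CE - stats_gray$CE,
       d_SC = stats_twotone$SC - stats_gray$SC)
}

#' Imagewise correlation of an image statistic with performance
#'
#' Pearson correlation (with two-sided p) across images between a column
#' of an image-statistics table and a column of an imagewise performance
#' table, joined on `image_id`.
#'
#' @param stats_table Data frame with `image_id` and the `stat` column.
#' @param performance_table Data frame with `image_id` and the `measure`
#'   column.
#' @param stat,measure Column names to correlate.
#' @return A `"correlation_result"`: list with `r`, `p`, `n`.
#' @export
stats_correlation <- function(stats_table, performance_table,
                              stat = "sigma", measure = "naive_accuracy") {
  m <- merge(stats_table[, c("image_id", stat)],
             performance_table[, c("image_id", measure)], by = "image_id")
  pearson_correlation(m[[stat]], m[[measure]])
}

pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_invalid("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("correlation undefined: zero variance in one of the columns")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}
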