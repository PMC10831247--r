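# Independent oracles used across the suite. Each re-derives a quantity
# by a different route than the implementation: direct convolution loops,
# scanline rasterization, grid-search likelihood maximization.

# strip provenance attributes/class, keeping only the pixel matrix
as_plain <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# direct (non-separable) Gaussian convolution with symmetric reflection
oracle_gaussian_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k2 <- outer(g1, g1)
  k2 <- k2 / sum(k2)
  refl <- function(i, n) {
    i <- (i - 1L) %% (2L * n)
    ifelse(i < n, i + 1L, 2L * n - i)
  }
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in (-r):r) for (dj in (-r):r)
      acc <- acc + k2[di + r + 1L, dj + r + 1L] *
        img[refl(i + di, h), refl(j + dj, w)]
    out[i, j] <- acc
  }
  out
}

# brute-force 3x3 Sobel edge density (interior pixels, same normalization)
oracle_edge_density <- function(img) {
  h <- nrow(img); w <- ncol(img)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # column-major
  ky <- t(kx)
  vals <- numeric(0)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    gx <- sum(nb * kx); gy <- sum(nb * ky)
    vals <- c(vals, min(sqrt(gx^2 + gy^2) / (4 * 255), 1))
  }
  mean(vals)
}

# scanline even-odd raster mask: TRUE at integer lattice points inside the
# polygon; membership test by table lookup (interval filling, a different
# algorithm than the package's crossing-count test)
oracle_raster_mask <- function(vertices, width, height) {
  mask <- matrix(FALSE, height + 1L, width + 1L)  # (y + 1, x + 1) indexing
  n <- nrow(vertices)
  for (y in 0:height) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- vertices[i, 2]; y2 <- vertices[j, 2]
      if ((y1 > y) != (y2 > y)) {
        x1 <- vertices[i, 1]; x2 <- vertices[j, 1]
        xs <- c(xs, x1 + (y - y1) * (x2 - x1) / (y2 - y1))
      }
      j <- i
    }
    xs <- sort(xs)
    k <- 1L
    while (k < length(xs) + 1L && k + 1L <= length(xs)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1L])
      if (a <= b) {
        a <- max(a, 0L); b <- min(b, width)
        if (a <= b) mask[y + 1L, (a:b) + 1L] <- TRUE
      }
      k <- k + 2L
    }
  }
  mask
}

oracle_mask_lookup <- function(mask, x, y) mask[cbind(y + 1L, x + 1L)]

# grid-search Weibull MLE: iterative zooming over (shape, scale)
oracle_weibull_grid <- function(x, n_grid = 61L, n_zoom = 5L) {
  n <- length(x); slx <- sum(log(x))
  # Weibull loglik: n log k - n k log b + (k-1) sum log x - sum (x/b)^k
  ll <- function(k, b) n * log(k) - n * k * log(b) + (k - 1) * slx - sum((x / b)^k)
  k_rng <- c(0.05, 20); b_rng <- range(x) * c(0.1, 2)
  for (z in seq_len(n_zoom)) {
    ks <- exp(seq(log(k_rng[1]), log(k_rng[2]), length.out = n_grid))
    bs <- exp(seq(log(b_rng[1]), log(b_rng[2]), length.out = n_grid))
    L <- outer(ks, bs, Vectorize(ll))
    best <- arrayInd(which.max(L), dim(L))
    ki <- best[1]; bi <- best[2]
    k_rng <- ks[c(max(1, ki - 1L), min(n_grid, ki + 1L))]
    b_rng <- bs[c(max(1, bi - 1L), min(n_grid, bi + 1L))]
  }
  c(shape = ks[ki], scale = bs[bi])
}

# lightweight recognition-only simulator for inference calibration tests:
# crossed random intercepts, logistic link, no touches
sim_recognition <- function(group_mu, n_per_group, n_images,
                            sd_participant = 0.8, sd_image = 0.6) {
  groups <- names(group_mu)
  pid <- unlist(lapply(seq_along(groups), function(g)
    sprintf("%s_p%02d", groups[g], seq_len(n_per_group[g]))))
  grp <- rep(groups, n_per_group)
  u <- rnorm(length(pid), 0, sd_participant)
  v <- rnorm(n_images, 0, sd_image)
  d <- expand.grid(p = seq_along(pid), i = seq_len(n_images))
  eta <- group_mu[grp[d$p]] + u[d$p] + v[d$i]
  data.frame(participant_id = pid[d$p], age_group = grp[d$p],
             image_id = sprintf("img%02d", d$i),
             correct = rbinom(nrow(d), 1, plogis(eta)),
             stringsAsFactors = FALSE)
}

# minimal single-group end-to-end replicate: simulate -> score -> LRT on
# the recognized/unrecognized pointing gap
pointing_gap_lrt <- function(preset, n_participants, seed) {
  cfg <- cohort_config(group_sizes = n_participants, group_labels = "grp",
                       seed = seed)
  sim <- simulate_cohort(cfg, params = list(grp = preset),
                         re = random_effects())
  scored <- score_trials(sim$trials, sim$rois,
                         make_synthetic_scheme(unique(sim$trials$image_id)))
  kept <- apply_exclusions(scored)
  lng <- targets_long(kept$pointing)
  lng <- lng[!lng$is_catch & lng$attempted, ]
  lng$correct <- as.numeric(lng$correct)
  lng$recognized <- as.numeric(lng$naive_correct)
  if (length(unique(lng$recognized)) < 2L) return(NA_real_)
  full <- fit_mixed_logistic(lng, model_spec("correct", "recognized"))
  red <- fit_mixed_logistic(lng, model_spec("correct", character(0)))
  lrt(full, red)$p
}
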