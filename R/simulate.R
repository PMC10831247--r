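# Synthetic behavioral cohort: trial tables and touch coordinates with the
# statistical structure the multilevel analysis assumes — crossed
# participant and image random intercepts on naive recognition, an
# additive log-odds cueing (reorganization) gain for naively unrecognized
# images, and a touch mixture of on-target scatter, local-feature capture
# and diffuse guessing.

#' Cohort design configuration
#'
#' Defaults reproduce the reference study design: four age groups of
#' 31/23/18/13 participants, 20 experimental two-tone trials interspersed
#' with 4 easy catch trials (every 5th trial is a catch), two pointing
#' targets per image.
#'
#' @param group_sizes Participants per age group, youngest first.
#' @param group_labels Age-group labels.
#' @param n_twotone_images Number of experimental two-tone images.
#' @param n_catch Number of catch images.
#' @param targets_per_image Pointing targets per image.
#' @param seed Integer seed for the cohort RNG.
#' @return A `"cohort_config"` list.
#' @export
cohort_config <- function(group_sizes = c(31L, 23L, 18L, 13L),
                          group_labels = c("4-5y", "7-9y", "10-12y", "adult"),
                          n_twotone_images = 20L, n_catch = 4L,
                          targets_per_image = 2L, seed = 1L) {
  if (length(group_sizes) != length(group_labels))
    stop_invalid("one size per group label required")
  if (any(group_sizes < 1L) || n_twotone_images < 1L || n_catch < 0L ||
      targets_per_image < 1L)
    stop_invalid("all cohort counts must be positive")
  structure(list(group_sizes = as.integer(group_sizes),
                 group_labels = group_labels,
                 n_twotone_images = as.integer(n_twotone_images),
                 n_catch = as.integer(n_catch),
                 targets_per_image = as.integer(targets_per_image),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Age-group generative parameters
#'
#' @param mu_naive Log-odds of naive two-tone recognition (group mean of
#'   the latent logistic model).
#' @param reorg_gain Added log-odds of cued recognition for naively
#'   unrecognized images — the perceptual-reorganization parameter.
#' @param mu_gray Log-odds of correct grayscale naming.
#' @param touch_sd_mm SD of on-target touch scatter, millimetres.
#' @param p_local Probability that an unrecognized-touch lands on a
#'   local-distractor feature (when one exists) rather than being a
#'   diffuse guess.
#' @param p_attempt Probability a given target is attempted.
#' @return An `"age_group_params"` list.
#' @export
age_group_params <- function(mu_naive, reorg_gain, mu_gray = qlogis(0.99),
                             touch_sd_mm = 6, p_local = 0.25,
                             p_attempt = 0.95) {
  stopifnot(is.finite(mu_naive), is.finite(reorg_gain), touch_sd_mm > 0,
            p_local >= 0, p_local <= 1, p_attempt >= 0, p_attempt <= 1)
  structure(list(mu_naive = mu_naive, reorg_gain = reorg_gain,
                 mu_gray = mu_gray, touch_sd_mm = touch_sd_mm,
                 p_local = p_local, p_attempt = p_attempt),
            class = "age_group_params")
}

#' Crossed random-effect standard deviations
#'
#' @param sd_participant SD of participant intercepts (log-odds).
#' @param sd_image SD of image intercepts (log-odds).
#' @export
random_effects <- function(sd_participant = 0.8, sd_image = 0.6) {
  stopifnot(sd_participant >= 0, sd_image >= 0)
  structure(list(sd_participant = sd_participant, sd_image = sd_image),
            class = "random_effects")
}

#' Illustrative developmental presets
#'
#' Four age-group parameter sets with monotonically increasing naive
#' recognition (marginal accuracy rising from roughly a quarter correct in
#' the youngest group to roughly two thirds in adults) and monotonically
#' increasing reorganization gain — zero in the youngest group, saturating
#' in adults so that cued pointing is equivalent for previously
#' recognized and unrecognized images. The youngest group has the highest
#' local-capture probability and the largest touch scatter; grayscale
#' naming is near ceiling at all ages. Values are illustrative presets,
#' not fitted estimates.
#'
#' @return Named list of [age_group_params()], youngest first.
#' @export
make_presets <- function() {
  list(
    "4-5y"   = age_group_params(mu_naive = qlogis(0.26), reorg_gain = 0,
                                touch_sd_mm = 11, p_local = 0.55,
                                p_attempt = 0.88),
    "7-9y"   = age_group_params(mu_naive = qlogis(0.42), reorg_gain = 1.5,
                                touch_sd_mm = 9, p_local = 0.35,
                                p_attempt = 0.93),
    "10-12y" = age_group_params(mu_naive = qlogis(0.56), reorg_gain = 3.5,
                                touch_sd_mm = 7, p_local = 0.15,
                                p_attempt = 0.97),
    "adult"  = age_group_params(mu_naive = qlogis(0.63), reorg_gain = 6,
                                touch_sd_mm = 5, p_local = 0,
                                p_attempt = 0.99))
}

# catch stimuli are easy at every age: fixed high recognition log-odds
CATCH_MU <- 3

# trial order with a catch in every 5th position
catch_schedule <- function(n_twotone, n_catch) {
  n_total <- n_twotone + n_catch
  catch_pos <- seq(5L, by = 5L, length.out = n_catch)
  catch_pos <- catch_pos[catch_pos <= n_total]
  list(n_total = n_total, catch_positions = catch_pos)
}

draw_touch <- function(center, sd_px, h) {
  pmin(pmax(center + rnorm(2, 0, sd_px), 0), h)
}

#' Simulate a touchscreen cohort
#'
#' Generates a full synthetic dataset: a wide trial table (one row per
#' participant x image with naming labels and per-target touch
#' coordinates for the cued two-tone and grayscale-control conditions),
#' the ROI layout, and a ground-truth latent table for recovery tests.
#'
#' The generative model mirrors the analysis model: grayscale naming is
#' Bernoulli(plogis(mu_gray)); naive recognition is
#' Bernoulli(plogis(mu_naive + u_participant + v_image)) with crossed
#' Gaussian random intercepts; cued recognition is certain for naively
#' recognized images and otherwise adds `reorg_gain` to the linear
#' predictor. Touches on recognized targets scatter isotropically around
#' the correct ROI centroid; unrecognized touches land near a
#' local-distractor centroid with probability `p_local` (when the target
#' has one) and are otherwise uniform over the display. Grayscale-control
#' touches scatter tightly around the correct centroid at every age.
#'
#' @param config A [cohort_config()].
#' @param params Named list of [age_group_params()], one per group label.
#' @param re A [random_effects()].
#' @param rois Optional `roi_set`; auto-generated with
#'   [make_synthetic_rois()] if `NULL`.
#' @param geometry A [display_geometry()].
#' @param gs_touch_sd_mm Grayscale-condition touch scatter SD (mm).
#' @return A `"simulated_cohort"`: list with `trials`, `rois`, `truth`,
#'   `participants`, `images`, `config`, `params`, `re`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            params = make_presets(),
                            re = random_effects(),
                            rois = NULL,
                            geometry = display_geometry(),
                            gs_touch_sd_mm = 3) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(config$group_labels %in% names(params)))
    stop_invalid("params must be a named list covering every group label")
  h <- geometry$image_height_px
  px_per_mm <- 1 / geometry$mm_per_px
  tt_ids <- sprintf("img%02d", seq_len(config$n_twotone_images))
  catch_ids <- sprintf("catch%02d", seq_len(config$n_catch))
  all_ids <- c(tt_ids, catch_ids)
  with_seed(config$seed, {
    if (is.null(rois))
      rois <- make_synthetic_rois(all_ids, config$targets_per_image,
                                  geometry,
                                  seed = sample.int(2^30, 1L))
    # participants
    pid <- character(0); grp <- character(0)
    for (g in seq_along(config$group_labels)) {
      n <- config$group_sizes[g]
      pid <- c(pid, sprintf("%s_p%03d", gsub("[^0-9a-zA-Z]", "", config$group_labels[g]),
                            seq_len(n)))
      grp <- c(grp, rep(config$group_labels[g], n))
    }
    u <- rnorm(length(pid), 0, re$sd_participant)
    v <- rnorm(length(tt_ids), 0, re$sd_image)
    names(u) <- pid; names(v) <- tt_ids
    sched <- catch_schedule(config$n_twotone_images, config$n_catch)

    rows <- vector("list", length(pid) * sched$n_total)
    truth <- vector("list", length(rows))
    k <- 0L
    for (p in seq_along(pid)) {
      par <- params[[grp[p]]]
      # per-participant randomized trial order, catch every 5th slot
      order_tt <- sample(tt_ids)
      order_catch <- sample(catch_ids)
      trial_imgs <- character(sched$n_total)
      trial_imgs[sched$catch_positions] <- order_catch
      trial_imgs[setdiff(seq_len(sched$n_total), sched$catch_positions)] <- order_tt
      for (s in seq_len(sched$n_total)) {
        img <- trial_imgs[s]
        is_catch <- img %in% catch_ids
        eta_naive <- if (is_catch) CATCH_MU + u[p]
                     else par$mu_naive + u[p] + v[img]
        naive <- rbinom(1L, 1L, plogis(eta_naive)) == 1L
        cued <- naive ||
          rbinom(1L, 1L, plogis(eta_naive + par$reorg_gain)) == 1L
        gray_ok <- rbinom(1L, 1L, plogis(par$mu_gray)) == 1L
        label <- paste0("label_", img)
        naive_name <- if (naive) label else sample(c("thing", "blob"), 1L)
        gray_name <- if (gray_ok) label else "thing"
        row <- list(participant_id = pid[p], age_group = grp[p],
                    image_id = img, trial_order = s, is_catch = is_catch,
                    naive_name = naive_name, grayscale_name = gray_name)
        for (t in seq_len(config$targets_per_image)) {
          cr <- roi_get(rois, img, t, "correct")
          loc <- roi_get(rois, img, t, "local_distractor")
          ctr <- polygon_centroid(cr$vertices)
          tt <- gs <- c(NA_real_, NA_real_)
          if (rbinom(1L, 1L, par$p_attempt) == 1L) {
            if (cued || is_catch) {
              tt <- draw_touch(ctr, par$touch_sd_mm * px_per_mm, h)
            } else if (!is.null(loc) && runif(1) < par$p_local) {
              tt <- draw_touch(polygon_centroid(loc$vertices),
                               par$touch_sd_mm * px_per_mm, h)
            } else {
              tt <- runif(2, 0, h)
            }
          }
          if (rbinom(1L, 1L, min(1, par$p_attempt + 0.04)) == 1L)
            gs <- draw_touch(ctr, gs_touch_sd_mm * px_per_mm, h)
          row[touch_cols("tt", t)] <- tt
          row[touch_cols("gs", t)] <- gs
        }
        k <- k + 1L
        rows[[k]] <- row
        truth[[k]] <- list(participant_id = pid[p], image_id = img,
                           eta_naive = unname(eta_naive),
                           naive = naive, cued = cued,
                           gray_ok = gray_ok)
      }
    }
    trials <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    truth <- do.call(rbind, lapply(truth, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    structure(list(trials = trials, rois = rois, truth = truth,
                   participants = data.frame(participant_id = pid,
                                             age_group = grp, u = unname(u)),
                   images = data.frame(image_id = tt_ids, v = unname(v)),
                   config = config, params = params, re = re,
                   geometry = geometry),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d participants (%s), %d trials\n",
              nrow(x$participants),
              paste(x$config$group_sizes, collapse = "/"),
              nrow(x$trials)))
  invisible(x)
}

#' Default naming scheme for a simulated cohort
#'
#' Each image accepts its own label plus a synonym in the same cluster;
#' `"thing"` and `"animal"` are rejected superordinate labels.
#'
#' @param image_ids Image identifiers.
#' @export
make_synthetic_scheme <- function(image_ids) {
  coding_scheme(setNames(lapply(image_ids, function(img) {
    lab <- paste0("label_", img)
    syn <- paste0("syn_", img)
    list(accepted = c(lab, syn), rejected = c("thing", "animal"),
         clusters = setNames(c("c1", "c1"), c(lab, syn)))
  }), image_ids))
}

#' Write a simulated cohort to disk
#'
#' Emits `trials.csv`, `rois.json`, `truth.csv` and `scheme.json` under
#' `dir`.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write_rois(sim$rois, file.path(dir, "rois.json"))
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_coding_scheme(make_synthetic_scheme(unique(sim$trials$image_id)),
                      file.path(dir, "scheme.json"))
  invisible(dir)
}
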