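# Scoring of naming and touchscreen pointing responses: basic-level naming
# codes, ROI membership, millimetre pointing distance, trial exclusions,
# and the local/global pointing-error taxonomy.

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:punct:]]", "", x)
}

#' Build or read a per-image naming coding scheme
#'
#' For each image the scheme lists accepted basic/subordinate labels,
#' rejected superordinate labels, and a synonym map assigning each
#' accepted label to a cluster; naive and grayscale names must fall in the
#' same cluster to count as consistent.
#'
#' @param entries Named list (by image id); each element a list with
#'   character vectors `accepted`, `rejected`, and named character
#'   `clusters` mapping accepted labels to cluster ids.
#' @return A `"coding_scheme"` object.
#' @export
coding_scheme <- function(entries) {
  for (img in names(entries)) {
    e <- entries[[img]]
    e$accepted <- normalize_label(e$accepted)
    e$rejected <- normalize_label(e$rejected)
    if (length(intersect(e$accepted, e$rejected)))
      stop_invalid("image ", img, ": accepted and rejected labels overlap")
    if (is.null(e$clusters))
      e$clusters <- setNames(rep("c1", length(e$accepted)), e$accepted)
    names(e$clusters) <- normalize_label(names(e$clusters))
    entries[[img]] <- e
  }
  structure(entries, class = "coding_scheme")
}

#' @rdname coding_scheme
#' @param path JSON file path.
#' @export
read_coding_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  coding_scheme(lapply(raw, function(e) {
    list(accepted = as.character(e$accepted),
         rejected = as.character(e$rejected),
         clusters = unlist(e$clusters))
  }))
}

#' @rdname coding_scheme
#' @param scheme A `"coding_scheme"`.
#' @export
write_coding_scheme <- function(scheme, path) {
  jsonlite::write_json(lapply(unclass(scheme), function(e)
    list(accepted = e$accepted, rejected = e$rejected,
         clusters = as.list(e$clusters))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score naive and grayscale naming for one trial
#'
#' Grayscale naming is correct iff the (normalized) label is in the
#' image's accepted set. Naive two-tone naming is correct iff the naive
#' label is accepted *and* consistent (same synonym cluster) with a
#' correct grayscale name; superordinate labels are always incorrect, and
#' an empty label (refusal to guess) is simply incorrect, not an error.
#'
#' @param naive_name,grayscale_name Response labels.
#' @param scheme A [coding_scheme()].
#' @param image_id Image identifier (must be present in `scheme`).
#' @return List with logicals `naive_correct`, `grayscale_correct`.
#' @export
score_naming <- function(naive_name, grayscale_name, scheme, image_id) {
  e <- scheme[[image_id]]
  if (is.null(e)) stop_invalid("no coding-scheme entry for image ", image_id)
  nn <- normalize_label(naive_name)
  gn <- normalize_label(grayscale_name)
  gray_ok <- nzchar(gn) && gn %in% e$accepted
  naive_ok <- gray_ok && nzchar(nn) && nn %in% e$accepted &&
    identical(unname(e$clusters[nn]), unname(e$clusters[gn]))
  list(naive_correct = naive_ok, grayscale_correct = gray_ok)
}

#' Pointing distance between corresponding touches, in millimetres
#'
#' Euclidean pixel distance between the cued two-tone touch and the
#' grayscale-control touch for the same target, converted to millimetres
#' with the display's mm-per-pixel scale (273.9 mm / 680 px by default).
#' Returns `NA` (a missing-data sentinel handled by the exclusion rules)
#' when either touch is missing.
#'
#' @param touch_twotone,touch_grayscale Length-2 `(x, y)` pixel
#'   coordinates, possibly `NA`.
#' @param geometry A [display_geometry()].
#' @return Distance in mm, or `NA_real_`.
#' @export
pointing_distance <- function(touch_twotone, touch_grayscale,
                              geometry = display_geometry()) {
  if (any(is.na(touch_twotone)) || any(is.na(touch_grayscale)))
    return(NA_real_)
  sqrt(sum((touch_twotone - touch_grayscale)^2)) * geometry$mm_per_px
}

#' Classify a pointing error as correct / local / global / other
#'
#' Taxonomy with precedence correct > local > global > other: a touch in
#' the correct ROI is `correct`; otherwise a touch inside any
#' local-distractor ROI (an incorrect feature matching the target's local
#' shape) is `local`; otherwise a touch within the similar polygon of
#' three times the correct ROI's area (close to the correct location) is
#' `global`; anything else is `other`. A missing touch is `missing`.
#'
#' @param touch `(x, y)` pixel coordinates or `NA`.
#' @param correct_roi The target's correct [roi()].
#' @param local_rois List of local-distractor [roi()]s (possibly empty).
#' @param global_area_factor Area multiplier of the global region.
#' @return One of `"correct"`, `"local"`, `"global"`, `"other"`,
#'   `"missing"`.
#' @export
classify_error <- function(touch, correct_roi, local_rois = list(),
                           global_area_factor = 3) {
  if (any(is.na(touch))) return("missing")
  if (point_in_roi(touch, correct_roi)) return("correct")
  for (lr in local_rois) if (point_in_roi(touch, lr)) return("local")
  if (point_in_roi(touch, scale_roi(correct_roi, global_area_factor)))
    return("global")
  "other"
}

touch_cols <- function(cond, target) paste0(cond, "_", c("x", "y"), target)

get_touch <- function(row, cond, target) {
  v <- as.numeric(unlist(row[touch_cols(cond, target)]))
  if (any(is.na(v))) c(NA_real_, NA_real_) else v
}

#' Score a trial table against ROIs and a coding scheme
#'
#' Takes the wide trial table (one row per participant x image, with
#' two-tone touches `tt_x1 ... tt_y2` and grayscale-control touches
#' `gs_x1 ... gs_y2`) and returns it augmented with naming correctness,
#' per-target ROI membership for both conditions, pointing distances in
#' mm, and the local/global error class of each two-tone touch.
#'
#' @param trials Data frame with columns `participant_id`, `age_group`,
#'   `image_id`, `is_catch`, `naive_name`, `grayscale_name`, and the
#'   touch-coordinate columns (missing touches as `NA`).
#' @param rois An `roi_set` covering every image.
#' @param scheme A [coding_scheme()].
#' @param geometry A [display_geometry()].
#' @param targets_per_image Targets per image (default 2).
#' @return A `scored trials` data frame (one row per trial).
#' @export
score_trials <- function(trials, rois, scheme,
                         geometry = display_geometry(),
                         targets_per_image = 2L) {
  n <- nrow(trials)
  out <- trials[, c("participant_id", "age_group", "image_id", "is_catch")]
  out$naive_correct <- out$grayscale_correct <- NA
  tcols <- function(stub) paste0(stub, seq_len(targets_per_image))
  for (cn in c(tcols("attempted_"), tcols("gs_attempted_"),
               tcols("correct_"), tcols("gs_loc_")))
    out[[cn]] <- NA
  for (cn in tcols("dist_mm_")) out[[cn]] <- NA_real_
  for (cn in tcols("class_")) out[[cn]] <- NA_character_
  for (cn in tcols("roi_area_")) out[[cn]] <- NA_real_

  nn <- normalize_label(trials$naive_name)
  gn <- normalize_label(trials$grayscale_name)
  for (img in unique(trials$image_id)) {
    e <- scheme[[img]]
    if (is.null(e)) stop_invalid("no coding-scheme entry for image ", img)
    ix <- which(trials$image_id == img)
    gray_ok <- nzchar(gn[ix]) & gn[ix] %in% e$accepted
    naive_ok <- gray_ok & nzchar(nn[ix]) & nn[ix] %in% e$accepted &
      !is.na(e$clusters[nn[ix]]) &
      unname(e$clusters[nn[ix]]) == unname(e$clusters[gn[ix]])
    out$grayscale_correct[ix] <- gray_ok
    out$naive_correct[ix] <- naive_ok & !is.na(naive_ok)

    for (t in seq_len(targets_per_image)) {
      cr <- roi_get(rois, img, t, "correct")
      if (is.null(cr)) stop_invalid("no correct ROI for image ", img,
                                    " target ", t)
      loc <- roi_get(rois, img, t, "local_distractor")
      glob <- scale_roi(cr, 3)
      ttx <- trials[[paste0("tt_x", t)]][ix]; tty <- trials[[paste0("tt_y", t)]][ix]
      gsx <- trials[[paste0("gs_x", t)]][ix]; gsy <- trials[[paste0("gs_y", t)]][ix]
      tt_ok <- !is.na(ttx) & !is.na(tty)
      gs_ok <- !is.na(gsx) & !is.na(gsy)
      in_cr <- in_gs <- in_loc <- in_glob <- rep(NA, length(ix))
      if (any(tt_ok)) {
        in_cr[tt_ok] <- points_in_polygon(ttx[tt_ok], tty[tt_ok], cr$vertices)
        in_loc[tt_ok] <- if (is.null(loc)) FALSE
          else points_in_polygon(ttx[tt_ok], tty[tt_ok], loc$vertices)
        in_glob[tt_ok] <- points_in_polygon(ttx[tt_ok], tty[tt_ok], glob$vertices)
      }
      if (any(gs_ok))
        in_gs[gs_ok] <- points_in_polygon(gsx[gs_ok], gsy[gs_ok], cr$vertices)
      out[[paste0("attempted_", t)]][ix] <- tt_ok
      out[[paste0("gs_attempted_", t)]][ix] <- gs_ok
      out[[paste0("correct_", t)]][ix] <- in_cr
      out[[paste0("gs_loc_", t)]][ix] <- in_gs
      out[[paste0("dist_mm_", t)]][ix] <-
        ifelse(tt_ok & gs_ok,
               sqrt((ttx - gsx)^2 + (tty - gsy)^2) * geometry$mm_per_px,
               NA_real_)
      # precedence: correct > local > global > other; missing if no touch
      out[[paste0("class_", t)]][ix] <-
        ifelse(!tt_ok, "missing",
               ifelse(in_cr, "correct",
                      ifelse(in_loc, "local",
                             ifelse(in_glob, "global", "other"))))
      out[[paste0("roi_area_", t)]][ix] <- cr$area_px2
    }
  }
  out
}

#' Apply the two-tier trial exclusion rules
#'
#' Tier (a): trials whose grayscale image was named incorrectly are
#' excluded from all analyses. Tier (b), for cued-pointing analyses only:
#' trials are additionally excluded when not both targets were attempted
#' in both the two-tone and grayscale conditions
#' (`"incomplete_targets"`), or when either target was not correctly
#' localized in the grayscale condition (`"grayscale_localization"`).
#'
#' @param scored A [score_trials()] result.
#' @param targets_per_image Targets per trial.
#' @return List with `naming` (trials kept for naming analyses),
#'   `pointing` (trials kept for cued-pointing analyses), and `excluded`
#'   (data frame of excluded rows with a machine-readable `reason` and
#'   `tier`).
#' @export
apply_exclusions <- function(scored, targets_per_image = 2L) {
  ts <- seq_len(targets_per_image)
  tier_a <- !scored$grayscale_correct
  att <- rowSums(!as.matrix(
    scored[, c(paste0("attempted_", ts), paste0("gs_attempted_", ts))])) > 0
  gs_fail <- rowSums(
    !as.matrix(scored[, paste0("gs_loc_", ts)]) |
      is.na(as.matrix(scored[, paste0("gs_loc_", ts)]))) > 0
  reason_b <- ifelse(att, "incomplete_targets",
                     ifelse(gs_fail, "grayscale_localization", NA))
  tier_b <- !tier_a & !is.na(reason_b)
  excl_a <- scored[tier_a, , drop = FALSE]
  excl_a$reason <- rep("grayscale_naming", nrow(excl_a))
  excl_a$tier <- rep("a", nrow(excl_a))
  excl_b <- scored[tier_b, , drop = FALSE]
  excl_b$reason <- reason_b[tier_b]
  excl_b$tier <- rep("b", nrow(excl_b))
  excluded <- rbind(excl_a, excl_b)
  list(naming = scored[!tier_a, , drop = FALSE],
       pointing = scored[!tier_a & is.na(reason_b), , drop = FALSE],
       excluded = excluded)
}

#' Reshape scored trials to one row per target
#'
#' The long format used by the pointing models: columns `participant_id`,
#' `age_group`, `image_id`, `is_catch`, `target_id`, `naive_correct`,
#' `attempted`, `correct`, `dist_mm`, `error_class`, `roi_area`.
#'
#' @inheritParams apply_exclusions
#' @export
targets_long <- function(scored, targets_per_image = 2L) {
  pieces <- lapply(seq_len(targets_per_image), function(t) {
    data.frame(
      participant_id = scored$participant_id,
      age_group = scored$age_group,
      image_id = scored$image_id,
      is_catch = scored$is_catch,
      target_id = t,
      naive_correct = scored$naive_correct,
      attempted = scored[[paste0("attempted_", t)]],
      correct = scored[[paste0("correct_", t)]],
      dist_mm = scored[[paste0("dist_mm_", t)]],
      error_class = scored[[paste0("class_", t)]],
      roi_area = scored[[paste0("roi_area_", t)]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Aggregate performance measures
#'
#' Per-participant, per-image or per-age-group means of naive naming
#' accuracy, cued pointing accuracy (proportion of attempted targets whose
#' touch fell in the correct ROI) and mean pointing distance, optionally
#' split by prior recognition (naively recognized vs unrecognized
#' two-tones). Empty cells are reported as `NA`, never 0. Catch trials
#' are excluded from the aggregates.
#'
#' @param scored A [score_trials()] result *after* exclusions (pass the
#'   appropriate tier from [apply_exclusions()]).
#' @param level `"participant"`, `"image"` or `"age_group"`.
#' @param measure `"naive_accuracy"`, `"pointing_accuracy"` or
#'   `"pointing_distance"`.
#' @param by_recognition Split by naive recognition status?
#' @param targets_per_image Targets per trial.
#' @return Data frame of unit means (column `mean`, with `n` units).
#' @export
aggregate_performance <- function(scored,
                                  level = c("participant", "image", "age_group"),
                                  measure = c("naive_accuracy",
                                              "pointing_accuracy",
                                              "pointing_distance"),
                                  by_recognition = FALSE,
                                  targets_per_image = 2L) {
  level <- match.arg(level)
  measure <- match.arg(measure)
  if (nrow(scored) == 0L) stop_invalid("no trials to aggregate")
  key <- switch(level, participant = "participant_id",
                image = "image_id", age_group = "age_group")
  if (measure == "naive_accuracy") {
    d <- scored[!scored$is_catch, c(key, "naive_correct")]
    names(d) <- c("unit", "value")
  } else {
    lng <- targets_long(scored, targets_per_image)
    lng <- lng[!lng$is_catch & lng$attempted, ]
    val <- if (measure == "pointing_accuracy") as.numeric(lng$correct)
           else lng$dist_mm
    d <- data.frame(unit = lng[[key]], value = val,
                    recognized = lng$naive_correct)
  }
  if (by_recognition) {
    if (measure == "naive_accuracy")
      stop_invalid("naive accuracy cannot be split by its own outcome")
    agg <- aggregate(value ~ unit + recognized, data = d, FUN = mean,
                     na.rm = TRUE, drop = TRUE)
  } else {
    d$recognized <- NULL
    agg <- aggregate(value ~ unit, data = d, FUN = mean, na.rm = TRUE)
  }
  names(agg)[names(agg) == "value"] <- "mean"
  names(agg)[names(agg) == "unit"] <- level
  agg$mean[is.nan(agg$mean)] <- NA_real_
  agg
}

#' Tabulate the local/global error taxonomy by age group
#'
#' Among *incorrect* attempted two-tone touches for targets that have a
#' local-distractor ROI, the proportion classified `local` and the
#' proportion classified `global`, per age group.
#'
#' @param scored Scored trials kept for pointing analyses.
#' @param rois The `roi_set` used for scoring.
#' @param targets_per_image Targets per trial.
#' @return Data frame with `age_group`, `n_errors`, `p_local`, `p_global`.
#' @export
error_taxonomy_table <- function(scored, rois, targets_per_image = 2L) {
  lng <- targets_long(scored, targets_per_image)
  has_local <- vapply(seq_len(nrow(lng)), function(i)
    !is.null(roi_get(rois, lng$image_id[i], lng$target_id[i],
                     "local_distractor")), logical(1))
  err <- lng[!lng$is_catch & lng$attempted & !lng$correct & has_local, ]
  groups <- unique(as.character(lng$age_group))
  do.call(rbind, lapply(groups, function(g) {
    e <- err[as.character(err$age_group) == g, ]
    data.frame(age_group = g, n_errors = nrow(e),
               p_local = if (nrow(e)) mean(e$error_class == "local") else NA_real_,
               p_global = if (nrow(e)) mean(e$error_class == "global") else NA_real_)
  }))
}
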