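# End-to-end orchestration: generate stimuli -> image stats -> simulate
# (or ingest) a cohort -> score -> multilevel analyses, with a resolved
# config and a seed-traceable manifest beside every output.

# tiny djb2-style string hash for the run manifest (no binary dependencies)
fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every tunable of a full synthetic-experiment run. The resolved
#' configuration is serialized (YAML) next to the results of every run,
#' and round-trips losslessly.
#'
#' @param seed Master seed for the run.
#' @param cohort A [cohort_config()] (its own seed is set from `seed`).
#' @param params Named list of [age_group_params()].
#' @param re A [random_effects()].
#' @param geometry A [display_geometry()].
#' @param n_stimulus_images Synthetic stimuli to build for the
#'   image-statistics stage.
#' @param stimulus_spec A [synthetic_image_spec()].
#' @param boot_reps Bootstrap resamples for group-mean CIs.
#' @return A `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(seed = seed),
                            params = make_presets(),
                            re = random_effects(),
                            geometry = display_geometry(),
                            n_stimulus_images = 6L,
                            stimulus_spec = synthetic_image_spec(),
                            boot_reps = 2000L) {
  if (n_stimulus_images < 1L) stop_invalid("need at least one stimulus image")
  structure(list(seed = as.integer(seed), cohort = cohort, params = params,
                 re = re, geometry = geometry,
                 n_stimulus_images = as.integer(n_stimulus_images),
                 stimulus_spec = stimulus_spec,
                 boot_reps = as.integer(boot_reps)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  rapply(unclass(config), f = function(x) x, how = "replace")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    seed = raw$seed,
    cohort = do.call(cohort_config, raw$cohort),
    params = lapply(raw$params, function(p) do.call(age_group_params, p)),
    re = do.call(random_effects, raw$re),
    geometry = display_geometry(raw$geometry$image_height_px,
                                raw$geometry$image_height_mm),
    n_stimulus_images = raw$n_stimulus_images,
    stimulus_spec = do.call(synthetic_image_spec, raw$stimulus_spec),
    boot_reps = raw$boot_reps)
}

#' Read and validate a trial CSV
#'
#' Rejects malformed rows (missing required columns, non-numeric touch
#' coordinates, coordinates outside the display) with row-numbered
#' errors instead of silent coercion.
#'
#' @param path CSV path in the [simulate_cohort()] trial schema.
#' @param geometry Display geometry used for the bounds check.
#' @param targets_per_image Targets per trial.
#' @export
read_trials <- function(path, geometry = display_geometry(),
                        targets_per_image = 2L) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age_group", "image_id", "is_catch",
            "naive_name", "grayscale_name",
            unlist(lapply(seq_len(targets_per_image), function(t)
              c(touch_cols("tt", t), touch_cols("gs", t)))))
  missing <- setdiff(need, names(tr))
  if (length(missing))
    stop_invalid("trial file lacks columns: ", paste(missing, collapse = ", "))
  coord_cols <- grep("^(tt|gs)_[xy]", names(tr), value = TRUE)
  for (cc in coord_cols) {
    v <- tr[[cc]]
    bad <- which(!is.na(v) & (!is.numeric(v) | v < 0 |
                                v > geometry$image_height_px))
    if (length(bad))
      stop_invalid("column ", cc, ": invalid coordinates at rows ",
                   paste(head(bad, 5L), collapse = ", "))
  }
  tr$is_catch <- as.logical(tr$is_catch)
  tr
}

group_summary <- function(scored, measure, boot_reps, seed, by_recognition = FALSE) {
  per_part <- aggregate_performance(scored, "participant", measure,
                                    by_recognition = by_recognition)
  grp_of <- unique(scored[, c("participant_id", "age_group")])
  per_part$age_group <- grp_of$age_group[match(per_part$participant,
                                               grp_of$participant_id)]
  keys <- if (by_recognition) c("age_group", "recognized") else "age_group"
  split_keys <- interaction(per_part[keys], drop = TRUE)
  cells <- split(per_part, split_keys)
  out <- lapply(seq_along(cells), function(ci_idx) {
    d <- cells[[ci_idx]]
    ci <- if (nrow(d) >= 2L)
      bootstrap_ci(d$mean, reps = boot_reps, seed = seed + 31L * ci_idx)
    else c(low = NA_real_, high = NA_real_)
    res <- list(age_group = as.character(d$age_group[1]),
                mean = mean(d$mean, na.rm = TRUE),
                ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                n_participants = nrow(d))
    if (by_recognition) res$recognized <- d$recognized[1]
    res
  })
  unname(out)
}

#' Run all the study analyses on a scored dataset
#'
#' Produces the full inference report: the age-effect likelihood-ratio
#' test and pairwise Wald contrasts for naive naming; the
#' recognized-by-age LRT and contrasts for cued pointing accuracy and
#' log pointing distance; bootstrapped group means; the local/global
#' error taxonomy; imagewise between-group correlations of naive naming;
#' and the exclusion tally.
#'
#' @param scored A [score_trials()] result (before exclusions).
#' @param rois The `roi_set` used in scoring.
#' @param boot_reps Bootstrap resamples for group-mean CIs.
#' @param seed Seed for the bootstrap draws.
#' @return A nested list report (JSON-serializable).
#' @export
analyze_cohort <- function(scored, rois, boot_reps = 2000L, seed = 1L) {
  kept <- apply_exclusions(scored)
  naming <- kept$naming[!kept$naming$is_catch, ]
  naming$correct <- as.numeric(naming$naive_correct)

  m_full <- fit_mixed_logistic(naming, model_spec("correct", "age_group"))
  m_red <- fit_mixed_logistic(naming, model_spec("correct", character(0)))
  naming_lrt <- lrt(m_full, m_red)
  child_terms <- grep("^age_group", m_full$coefficients$term, value = TRUE)
  naming_wald <- lapply(child_terms, function(tm) {
    w <- wald_contrast(m_full, tm)
    list(term = tm, z = w$z, p = w$p)
  })

  lng <- targets_long(kept$pointing)
  lng <- lng[!lng$is_catch & lng$attempted, ]
  lng$correct <- as.numeric(lng$correct)
  lng$recognized <- as.numeric(lng$naive_correct)
  sp_full <- model_spec("correct",
                        c("recognized", "age_group", "recognized:age_group"),
                        random = c("participant", "image", "roi_area"))
  sp_red <- model_spec("correct", c("recognized", "age_group"),
                       random = c("participant", "image", "roi_area"))
  p_full <- fit_mixed_logistic(lng, sp_full)
  p_red <- fit_mixed_logistic(lng, sp_red)
  pointing_lrt <- lrt(p_full, p_red)
  adult_gap <- wald_contrast(p_full, "recognized")
  int_terms <- grep("^recognized:age_group", p_full$coefficients$term,
                    value = TRUE)
  pointing_wald <- lapply(int_terms, function(tm) {
    w <- wald_contrast(p_full, tm)
    list(term = tm, z = w$z, p = w$p)
  })

  dl <- lng[!is.na(lng$dist_mm) & lng$dist_mm >= 0, ]
  spd_full <- sp_full; spd_full$outcome <- "dist_mm"
  spd_red <- sp_red; spd_red$outcome <- "dist_mm"
  d_full <- fit_distance_model(dl, spd_full)
  d_red <- fit_distance_model(dl, spd_red)
  distance_lrt <- lrt(d_full, d_red)
  distance_adult_gap <- wald_contrast(d_full, "recognized")

  tax <- error_taxonomy_table(kept$pointing, rois)

  img_acc <- function(group) {
    d <- naming[naming$age_group == group, ]
    aggregate_performance(d, "image", "naive_accuracy")
  }
  groups <- unique(as.character(naming$age_group))
  cors <- list()
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) for (j in seq(i + 1L, length(groups))) {
      ct <- tryCatch(imagewise_correlation(img_acc(groups[i]), img_acc(groups[j])),
                     error = function(e) NULL)
      if (!is.null(ct))
        cors[[paste(groups[i], groups[j], sep = "_vs_")]] <-
          list(r = ct$r, p = ct$p, n = ct$n)
    }
  }

  excl <- kept$excluded
  tally <- if (nrow(excl)) as.list(table(excl$reason)) else list()

  list(
    n_trials = nrow(scored),
    n_kept_naming = nrow(kept$naming),
    n_kept_pointing = nrow(kept$pointing),
    exclusion_tally = tally,
    naming = list(
      lrt = unclass(naming_lrt), wald = naming_wald,
      group_means = group_summary(kept$naming, "naive_accuracy",
                                  boot_reps, seed)),
    pointing_accuracy = list(
      lrt = unclass(pointing_lrt),
      adult_gap = list(z = adult_gap$z, p = adult_gap$p),
      wald = pointing_wald,
      group_means = group_summary(kept$pointing, "pointing_accuracy",
                                  boot_reps, seed + 1L),
      group_means_by_recognition =
        group_summary(kept$pointing, "pointing_accuracy",
                      boot_reps, seed + 2L, by_recognition = TRUE)),
    pointing_distance = list(
      lrt = unclass(distance_lrt),
      adult_gap = list(z = distance_adult_gap$z, p = distance_adult_gap$p),
      group_means = group_summary(kept$pointing, "pointing_distance",
                                  boot_reps, seed + 3L)),
    error_taxonomy = lapply(seq_len(nrow(tax)), function(i) as.list(tax[i, ])),
    imagewise_correlations = cors)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full synthetic-experiment pipeline
#'
#' Stages: (1) generate synthetic grayscale stimuli and their two-tone /
#' catch versions and compute per-image statistics (`stats.csv`); (2)
#' simulate the cohort (`trials.csv`, `rois.json`, `truth.csv`,
#' `scheme.json`); (3) score and apply exclusions (`scored.csv`); (4)
#' run the multilevel analyses (`results.json`). The resolved config
#' (`config.yaml`) and a manifest with the seed and config hash are
#' written alongside. Runs are idempotent given the seed: repeated runs
#' produce byte-identical `results.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the report list (stage 4).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop_invalid("config must be a pipeline_config [stage: validate]")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid(sprintf("[stage: %s] %s", stage, conditionMessage(e))))
  }

  stats_df <- run_stage("stimuli", {
    stim <- synthetic_stimulus_set(config$n_stimulus_images,
                                   seed = config$seed * 1000L,
                                   spec = config$stimulus_spec)
    rows <- lapply(seq_along(stim), function(i) {
      s <- stim[[i]]
      for (cond in c("gray", "twotone", "catch")) {
        st <- suppressWarnings(compute_stats(s[[cond]], s$params))
        row <- data.frame(image_id = sprintf("stim%02d", i), condition = cond,
                          sigma = if (cond == "twotone") s$params$sigma else 0,
                          threshold = s$params$threshold,
                          edge_density = st$edge_density,
                          CE = st$CE, SC = st$SC)
        if (cond == "gray") out <- row else out <- rbind(out, row)
      }
      out
    })
    df <- do.call(rbind, rows)
    write.csv(df, file.path(out_dir, "stats.csv"), row.names = FALSE)
    pipeline_log("stimuli", "%d images, %d stat rows",
                 config$n_stimulus_images, nrow(df))
    df
  })

  sim <- run_stage("simulate", {
    s <- simulate_cohort(config$cohort, config$params, config$re,
                         geometry = config$geometry)
    write_cohort(s, out_dir)
    pipeline_log("simulate", "%d trials from %d participants",
                 nrow(s$trials), nrow(s$participants))
    s
  })

  scored <- run_stage("score", {
    sc <- score_trials(sim$trials, sim$rois,
                       make_synthetic_scheme(unique(sim$trials$image_id)),
                       config$geometry)
    write.csv(sc, file.path(out_dir, "scored.csv"), row.names = FALSE)
    kept <- apply_exclusions(sc)
    pipeline_log("score", "%d scored; kept %d naming / %d pointing; excluded %d",
                 nrow(sc), nrow(kept$naming), nrow(kept$pointing),
                 nrow(kept$excluded))
    sc
  })

  report <- run_stage("analyze", {
    rep <- analyze_cohort(scored, sim$rois, boot_reps = config$boot_reps,
                          seed = config$seed)
    rep$seed <- config$seed
    jsonlite::write_json(rep, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log("analyze", "naming X2(%d) = %.2f; reorganization X2(%d) = %.2f",
                 rep$naming$lrt$df, rep$naming$lrt$chi2,
                 rep$pointing_accuracy$lrt$df, rep$pointing_accuracy$lrt$chi2)
    rep
  })

  manifest <- list(seed = config$seed,
                   config_hash = fnv1a(paste(deparse(config_to_list(config)),
                                             collapse = "")),
                   files = c("config.yaml", "stats.csv", "trials.csv",
                             "rois.json", "truth.csv", "scheme.json",
                             "scored.csv", "results.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
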