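# ROI geometry and behavioral scoring: polygon membership, the 3x global
# region, mm distances, naming codes, exclusions and aggregation.

concave_poly <- cbind(c(10, 60, 60, 35, 10), c(10, 10, 50, 30, 50))

test_that("point_in_roi handles centroid, boundary and outside cases", {
  r <- roi("img", 1, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  expect_true(point_in_roi(c(5, 5), r))
  expect_true(point_in_roi(c(0, 5), r))    # boundary counts as inside
  expect_true(point_in_roi(c(10, 10), r))  # vertex counts as inside
  expect_false(point_in_roi(c(25, 5), r))  # outside the bounding box
  rc <- roi("img", 1, concave_poly)
  expect_false(point_in_roi(c(35, 45), rc))  # in the concave notch
  expect_true(point_in_roi(c(15, 45), rc))
})

test_that("polygon membership agrees with mgcv's independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  for (k in 1:5) {
    nv <- 7
    th <- (seq_len(nv) - 1) * 2 * pi / nv + runif(nv, -0.2, 0.2)
    v <- cbind(50 + 30 * runif(nv, 0.6, 1.3) * cos(th),
               50 + 30 * runif(nv, 0.6, 1.3) * sin(th))
    px <- runif(400, 0, 100); py <- runif(400, 0, 100)
    got <- twotone:::points_in_polygon(px, py, v)
    ref <- mgcv::in.out(rbind(v, v[1, ]), cbind(px, py))
    # continuous random points are almost surely off-boundary
    expect_equal(got, ref)
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(roi("i", 1, cbind(c(0, 1), c(0, 1))), "3 rows")
  expect_error(roi("i", 1, cbind(c(0, 1, 2), c(0, 1, 2))), "positive area")
  bowtie <- cbind(c(0, 10, 10, 0), c(0, 8, 0, 10))  # crossing, nonzero area
  expect_error(roi("i", 1, bowtie), "simple")
})

test_that("scale_roi triples area exactly and preserves the centroid", {
  sq <- roi("i", 1, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  s3 <- scale_roi(sq, 3)
  expect_equal(s3$area_px2, 300, tolerance = 1e-9)
  expect_equal(twotone:::polygon_centroid(s3$vertices),
               twotone:::polygon_centroid(sq$vertices), tolerance = 1e-9)
  expect_equal(diff(range(s3$vertices[, 1])), 10 * sqrt(3), tolerance = 1e-9)
  expect_equal(scale_roi(sq, 1)$vertices, sq$vertices)
  # irregular 7-gon: output shoelace area is 3x the input shoelace area
  set.seed(22)
  th <- sort(runif(7, 0, 2 * pi))
  v <- cbind(100 + 40 * cos(th), 100 + 40 * sin(th))
  r7 <- roi("i", 1, v)
  shoelace <- function(v) {
    j <- c(2:nrow(v), 1)
    abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  }
  expect_equal(shoelace(scale_roi(r7, 3)$vertices), 3 * shoelace(v),
               tolerance = 1e-6)
})

test_that("pointing distance uses the display scale and is symmetric", {
  geo <- display_geometry()
  expect_equal(pointing_distance(c(0, 0), c(300, 400), geo),
               500 * 273.9 / 680, tolerance = 1e-9)
  expect_equal(pointing_distance(c(0, 0), c(300, 400), geo), 201.40,
               tolerance = 0.01)
  expect_equal(pointing_distance(c(12, 30), c(12, 30), geo), 0)
  expect_equal(pointing_distance(c(5, 9), c(100, 7), geo),
               pointing_distance(c(100, 7), c(5, 9), geo))
  expect_true(is.na(pointing_distance(c(NA, 2), c(0, 0), geo)))
})

test_that("error taxonomy follows the correct > local > global > other precedence", {
  correct <- roi("i", 1, cbind(c(100, 120, 120, 100), c(100, 100, 120, 120)))
  local1 <- roi("i", 1, cbind(c(300, 320, 320, 300), c(300, 300, 320, 320)),
                kind = "local_distractor")
  expect_equal(classify_error(c(110, 110), correct, list(local1)), "correct")
  expect_equal(classify_error(c(310, 310), correct, list(local1)), "local")
  # just outside the correct square but inside the 3x region
  expect_equal(classify_error(c(122, 110), correct, list(local1)), "global")
  expect_equal(classify_error(c(200, 200), correct, list(local1)), "other")
  expect_equal(classify_error(c(NA, NA), correct, list(local1)), "missing")
  # overlap: a local ROI overlapping the correct ROI loses on precedence
  local_on_top <- roi("i", 1, correct$vertices, kind = "local_distractor")
  expect_equal(classify_error(c(110, 110), correct, list(local_on_top)),
               "correct")
})

test_that("naming codes accept consistent basic-level labels and reject superordinates", {
  sch <- coding_scheme(list(
    tiger = list(accepted = c("tiger", "cat"), rejected = "animal",
                 clusters = c(tiger = "felid", cat = "felid")),
    cow = list(accepted = c("cow", "bull"), rejected = "animal",
               clusters = c(cow = "bovid", bull = "bovid"))))
  # subordinate/basic flexibility with cross-stage consistency
  r <- score_naming("cat", "cat", sch, "tiger")
  expect_true(r$naive_correct && r$grayscale_correct)
  r <- score_naming("tiger", "cat", sch, "tiger")
  expect_true(r$grayscale_correct)
  expect_true(r$naive_correct)  # same synonym cluster
  # superordinate label is always incorrect
  r <- score_naming("cow", "animal", sch, "cow")
  expect_false(r$grayscale_correct)
  expect_false(r$naive_correct)
  # refusal to guess: incorrect, not an error
  r <- score_naming("", "cow", sch, "cow")
  expect_false(r$naive_correct)
  expect_true(r$grayscale_correct)
  expect_error(score_naming("x", "y", sch, "zebra"), "coding-scheme")
})

make_toy_scored <- function() {
  # 10 trials: 2 grayscale-naming failures (tier a), then among the rest
  # 1 incomplete-targets and 2 grayscale-localization failures (tier b)
  df <- data.frame(
    participant_id = sprintf("p%02d", 1:10), age_group = "adult",
    image_id = sprintf("i%02d", 1:10), is_catch = FALSE,
    naive_correct = rep(c(TRUE, FALSE), 5),
    grayscale_correct = c(FALSE, FALSE, rep(TRUE, 8)),
    attempted_1 = TRUE, attempted_2 = c(rep(TRUE, 2), FALSE, rep(TRUE, 7)),
    gs_attempted_1 = TRUE, gs_attempted_2 = TRUE,
    correct_1 = TRUE, correct_2 = TRUE,
    gs_loc_1 = c(rep(TRUE, 3), FALSE, FALSE, rep(TRUE, 5)),
    gs_loc_2 = TRUE,
    dist_mm_1 = 5, dist_mm_2 = 6,
    class_1 = "correct", class_2 = "correct",
    roi_area_1 = 2000, roi_area_2 = 2000,
    stringsAsFactors = FALSE)
  df$correct_2[3] <- NA; df$class_2[3] <- "missing"; df$dist_mm_2[3] <- NA
  df
}

test_that("exclusion tiers drop the documented trials with reason codes", {
  toy <- make_toy_scored()
  kept <- apply_exclusions(toy)
  expect_equal(nrow(kept$naming), 8)             # 10 - 2 naming failures
  expect_equal(nrow(kept$pointing), 10 - 2 - 3)  # additionally 1 + 2 tier b
  expect_setequal(unique(kept$excluded$reason),
                  c("grayscale_naming", "incomplete_targets",
                    "grayscale_localization"))
  expect_equal(sum(kept$excluded$reason == "grayscale_naming"), 2)
  expect_equal(sum(kept$excluded$reason == "incomplete_targets"), 1)
  expect_equal(sum(kept$excluded$reason == "grayscale_localization"), 2)
  # brute-force rule-by-rule oracle over all rows
  for (i in seq_len(nrow(toy))) {
    in_naming <- toy$grayscale_correct[i]
    in_pointing <- in_naming &&
      all(unlist(toy[i, c("attempted_1", "attempted_2",
                          "gs_attempted_1", "gs_attempted_2")])) &&
      isTRUE(toy$gs_loc_1[i]) && isTRUE(toy$gs_loc_2[i])
    expect_equal(toy$participant_id[i] %in% kept$naming$participant_id,
                 in_naming)
    expect_equal(toy$participant_id[i] %in% kept$pointing$participant_id,
                 in_pointing)
  }
  # monotonicity: failing one more grayscale naming never increases kept counts
  toy2 <- toy; toy2$grayscale_correct[6] <- FALSE
  kept2 <- apply_exclusions(toy2)
  expect_lte(nrow(kept2$naming), nrow(kept$naming))
  expect_lte(nrow(kept2$pointing), nrow(kept$pointing))
})

test_that("aggregation matches a flat recomputation and reports empty cells as missing", {
  toy <- make_toy_scored()
  kept <- apply_exclusions(toy)
  agg <- aggregate_performance(kept$naming, "age_group", "naive_accuracy")
  expect_equal(agg$mean, mean(kept$naming$naive_correct))
  aggp <- aggregate_performance(kept$pointing, "participant",
                                "pointing_accuracy")
  expect_true(all(aggp$mean == 1))   # all scored touches are in the ROI
  aggd <- aggregate_performance(kept$pointing, "participant",
                                "pointing_distance")
  expect_equal(aggd$mean, rep(5.5, nrow(aggd)))
  expect_error(aggregate_performance(kept$naming[0, ], "participant",
                                     "naive_accuracy"), "no trials")
})

test_that("scored cohorts aggregate identically to a flat group-by of the raw table", {
  cfg <- cohort_config(group_sizes = c(4, 4), group_labels = c("4-5y", "adult"),
                       seed = 31)
  sim <- simulate_cohort(cfg)
  scored <- score_trials(sim$trials, sim$rois,
                         make_synthetic_scheme(unique(sim$trials$image_id)))
  kept <- apply_exclusions(scored)
  agg <- aggregate_performance(kept$naming, "participant", "naive_accuracy")
  flat <- tapply(kept$naming$naive_correct[!kept$naming$is_catch],
                 kept$naming$participant_id[!kept$naming$is_catch], mean)
  expect_equal(agg$mean, as.vector(flat[agg$participant]))
  # class conservation: every attempted target gets exactly one class, and
  # counts per class sum to the attempted-target count
  lng <- targets_long(scored)
  expect_true(all(lng$error_class[!lng$attempted] == "missing"))
  expect_true(all(lng$error_class[lng$attempted] %in%
                    c("correct", "local", "global", "other")))
  expect_equal(sum(table(lng$error_class[lng$attempted])), sum(lng$attempted))
  expect_true(all((lng$error_class == "correct") == lng$correct,
                  na.rm = TRUE))
})

test_that("centroid touches are always correct; uniform touches hit at the area rate", {
  set.seed(32)
  rs <- make_synthetic_rois(sprintf("i%d", 1:12), seed = 5)
  correct <- Filter(function(r) r$kind == "correct", rs)
  for (r in correct)
    expect_true(point_in_roi(twotone:::polygon_centroid(r$vertices), r))
  h <- 680
  n <- 20000
  px <- runif(n, 0, h); py <- runif(n, 0, h)
  hits <- vapply(correct, function(r)
    sum(twotone:::points_in_polygon(px, py, r$vertices)), numeric(1))
  areas <- vapply(correct, `[[`, numeric(1), "area_px2")
  expect_equal(sum(hits) / (n * length(correct)),
               mean(areas) / h^2, tolerance = 0.15)
})
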