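# Inference layer: mixed logistic and log-distance fits, LRT, Wald
# contrasts, bootstrap CIs and imagewise correlations.

test_that("with zero random-effect variance the fixed effects match plain logistic regression", {
  set.seed(57)  # a draw whose variance estimates collapse to the boundary
  d <- sim_recognition(c(a = -0.5, adult = 0.5), c(30, 30), 15,
                       sd_participant = 0, sd_image = 0)
  fit <- fit_mixed_logistic(d, model_spec("correct", "age_group"))
  expect_equal(unname(fit$re_sd), c(0, 0), tolerance = 1e-6)
  ref <- glm(correct ~ relevel(factor(age_group), "adult"), binomial, d)
  expect_lt(max(abs(unname(coef(fit)) - unname(coef(ref)))), 1e-3)
  expect_true(fit$converged)
  expect_s3_class(fit, "twotone_fit")
  expect_output(print(fit), "logistic")
})

test_that("all-success outcomes raise a separation warning without crashing", {
  d <- data.frame(participant_id = rep(sprintf("p%d", 1:10), each = 8),
                  image_id = rep(sprintf("i%d", 1:8), 10),
                  age_group = "adult", correct = 1)
  expect_warning(fit <- fit_mixed_logistic(d, model_spec("correct", character(0))),
                 "separation")
  expect_false(fit$converged)
})

test_that("likelihood-ratio tests behave on self-comparison and reject invalid pairs", {
  set.seed(52)
  d <- sim_recognition(c(young = -1, adult = 0.5), c(20, 20), 12)
  full <- fit_mixed_logistic(d, model_spec("correct", "age_group"))
  red <- fit_mixed_logistic(d, model_spec("correct", character(0)))
  self <- lrt(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  out <- lrt(full, red)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1L)
  expect_error(lrt(red, full), "nested")
  d2 <- d[-(1:5), ]
  red2 <- fit_mixed_logistic(d2, model_spec("correct", character(0)))
  expect_error(lrt(full, red2), "different numbers")
})

test_that("a four-level age factor gives a 3-df test", {
  set.seed(53)
  d <- sim_recognition(c("4-5y" = -1, "7-9y" = -0.5, "10-12y" = 0.2,
                         adult = 0.5), c(10, 8, 7, 6), 12)
  full <- fit_mixed_logistic(d, model_spec("correct", "age_group"))
  red <- fit_mixed_logistic(d, model_spec("correct", character(0)))
  expect_equal(lrt(full, red)$df, 3L)
  # adult reference: coefficient names are child-vs-adult contrasts
  expect_setequal(grep("age_group", full$coefficients$term, value = TRUE),
                  c("age_group4-5y", "age_group7-9y", "age_group10-12y"))
})

test_that("Wald contrasts convert estimates to z and p as expected", {
  set.seed(54)
  d <- sim_recognition(c(young = -1, adult = 0.5), c(20, 20), 12)
  fit <- fit_mixed_logistic(d, model_spec("correct", "age_group"))
  w <- wald_contrast(fit, "age_groupyoung")
  i <- match("age_groupyoung", fit$coefficients$term)
  expect_equal(w$z, fit$coefficients$estimate[i] / fit$coefficients$se[i])
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_error(wald_contrast(fit, "nope"), "no coefficient")
  # synthetic borderline case: estimate at 1.96 SE has p = 0.05
  fit2 <- fit
  fit2$coefficients$estimate[i] <- 1.96 * fit2$coefficients$se[i]
  w2 <- wald_contrast(fit2, "age_groupyoung")
  expect_equal(w2$p, 0.05, tolerance = 1e-3)
  fit2$coefficients$estimate[i] <- 0
  expect_equal(wald_contrast(fit2, "age_groupyoung")$z, 0)
  expect_equal(wald_contrast(fit2, "age_groupyoung")$p, 1)
})

test_that("null Wald contrasts reject at about the nominal 5% rate", {
  set.seed(55)
  rej <- mean(replicate(120, {
    d <- sim_recognition(c(young = 0.2, adult = 0.2), c(12, 12), 10,
                         sd_participant = 0.5, sd_image = 0.4)
    fit <- suppressWarnings(
      fit_mixed_logistic(d, model_spec("correct", "age_group")))
    wald_contrast(fit, "age_groupyoung")$p < 0.05
  }))
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.12)
})

test_that("the log-distance model recovers structure and transforms predictably", {
  # constant distances: intercept log d, residual variance ~ 0
  d0 <- data.frame(participant_id = rep(sprintf("p%d", 1:6), each = 6),
                   image_id = rep(sprintf("i%d", 1:6), 6),
                   dist_mm = 7)
  f0 <- suppressMessages(
    fit_distance_model(d0, model_spec("dist_mm", character(0))))
  expect_equal(unname(coef(f0)["(Intercept)"]), log(7), tolerance = 1e-6)
  # scaling all distances multiplies only the intercept
  set.seed(56)
  d1 <- data.frame(participant_id = rep(sprintf("p%d", 1:12), each = 12),
                   image_id = rep(sprintf("i%d", 1:12), 12),
                   age_group = rep(c("young", "adult"), each = 72),
                   dist_mm = exp(rnorm(144, 2, 0.5)))
  d2 <- d1; d2$dist_mm <- 10 * d1$dist_mm
  f1 <- fit_distance_model(d1, model_spec("dist_mm", "age_group"))
  f2 <- fit_distance_model(d2, model_spec("dist_mm", "age_group"))
  expect_equal(unname(coef(f2)["(Intercept)"] - coef(f1)["(Intercept)"]),
               log(10), tolerance = 1e-6)
  expect_equal(unname(coef(f2)["age_groupyoung"]),
               unname(coef(f1)["age_groupyoung"]), tolerance = 1e-6)
  expect_error(fit_distance_model(within(d1, dist_mm[1] <- -2),
                                  model_spec("dist_mm", "age_group")),
               "nonnegative")
})

test_that("the log-distance model recovers a known group ratio", {
  set.seed(58)
  np <- c(31, 13); ni <- 20
  grp <- rep(c("young", "adult"), np)
  pid <- sprintf("p%03d", seq_len(sum(np)))
  u <- rnorm(sum(np), 0, 0.15); v <- rnorm(ni, 0, 0.1)
  d <- expand.grid(p = seq_len(sum(np)), i = seq_len(ni))
  mu <- log(10) + log(1.5) * (grp[d$p] == "young")
  d <- data.frame(participant_id = pid[d$p], age_group = grp[d$p],
                  image_id = sprintf("i%d", d$i),
                  dist_mm = exp(mu + u[d$p] + v[d$i] + rnorm(nrow(d), 0, 0.3)))
  fit <- fit_distance_model(d, model_spec("dist_mm", "age_group"))
  ratio <- exp(unname(coef(fit)["age_groupyoung"]))
  expect_lt(abs(ratio - 1.5), 0.1)
  i <- match("age_groupyoung", fit$coefficients$term)
  expect_equal(fit$coefficients$ratio[i], ratio)
})

test_that("ROI-area random intercepts are deciled and accepted by the pointing model", {
  set.seed(58)
  d <- sim_recognition(c(young = -0.5, adult = 0.5), c(15, 15), 12)
  d$roi_area <- runif(nrow(d), 1000, 6000)
  sp <- model_spec("correct", "age_group",
                   random = c("participant", "image", "roi_area"))
  fit <- suppressMessages(suppressWarnings(fit_mixed_logistic(d, sp)))
  expect_true("roi_area_bin" %in% names(fit$model@flist))
  expect_error(fit_mixed_logistic(within(d, roi_area <- NULL), sp),
               "roi_area")
})

test_that("bootstrap CIs are percentile-correct, seeded and shift-equivariant", {
  expect_equal(unname(bootstrap_ci(rep(3, 10), seed = 1)), c(3, 3))
  set.seed(59)
  x <- rnorm(100)
  ci <- bootstrap_ci(x, reps = 10000, seed = 2)
  expect_lt(max(abs(unname(ci - mean(x)) - c(-1.96, 1.96) / sqrt(100))), 0.03)
  expect_true(ci["low"] < 0 && ci["high"] > 0)
  expect_identical(bootstrap_ci(x, seed = 7), bootstrap_ci(x, seed = 7))
  ci5 <- bootstrap_ci(x + 5, reps = 10000, seed = 2)
  expect_equal(unname(ci5 - ci), c(5, 5), tolerance = 1e-9)
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("imagewise correlations recover exact relations and the null rate", {
  a <- data.frame(image_id = letters[1:12], mean = 1:12)
  expect_equal(imagewise_correlation(a, a)$r, 1)
  b <- a; b$mean <- 13 - a$mean
  expect_equal(imagewise_correlation(a, b)$r, -1)
  set.seed(60)
  hits <- mean(replicate(1000, {
    x <- data.frame(image_id = 1:20, mean = rnorm(20))
    y <- data.frame(image_id = 1:20, mean = rnorm(20))
    abs(imagewise_correlation(x, y)$r) > 0.4438
  }))
  expect_lt(abs(hits - 0.05), 0.02)
})
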