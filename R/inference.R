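# Multilevel inference layer: crossed random-intercept logistic models,
# Gaussian mixed models on log distance, likelihood-ratio tests, Wald
# contrasts, percentile-bootstrap CIs and imagewise Pearson correlations.
# Mixed models are fitted with lme4 (Laplace approximation).

#' Specify a multilevel model
#'
#' @param outcome Response column: a binary 0/1 column for logistic
#'   models, or a strictly positive distance column for the log-distance
#'   model.
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `"age_group"`, or `c("recognized", "age_group", "recognized:age_group")`
#'   for the recognized-by-age analysis).
#' @param random Subset of `c("participant", "image", "roi_area")` to
#'   enter as crossed random intercepts. `"roi_area"` is grouped into
#'   area-decile bins (a continuous grouping factor is ill-defined).
#' @param reference Reference level of `age_group` (default `"adult"`, so
#'   coefficients are child-vs-adult contrasts).
#' @return A `"model_spec"`.
#' @export
model_spec <- function(outcome, fixed = "age_group",
                       random = c("participant", "image"),
                       reference = "adult") {
  random <- match.arg(random, c("participant", "image", "roi_area"),
                      several.ok = TRUE)
  if (length(random) == 0L) stop_invalid("multilevel fits need at least one random intercept")
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 reference = reference),
            class = "model_spec")
}

re_term <- function(r) switch(r,
  participant = "(1 | participant_id)",
  image = "(1 | image_id)",
  roi_area = "(1 | roi_area_bin)")

build_formula <- function(spec) {
  rhs <- paste(c(if (length(spec$fixed)) spec$fixed else "1",
                 vapply(spec$random, re_term, character(1))),
               collapse = " + ")
  as.formula(paste(spec$outcome, "~", rhs))
}

prepare_model_data <- function(data, spec, n_area_bins = 10L) {
  if ("age_group" %in% names(data)) {
    data$age_group <- factor(data$age_group)
    if (spec$reference %in% levels(data$age_group))
      data$age_group <- relevel(data$age_group, ref = spec$reference)
  }
  if ("roi_area" %in% spec$random) {
    if (!"roi_area" %in% names(data))
      stop_invalid("spec includes an roi_area intercept but data has no roi_area column")
    qs <- unique(quantile(data$roi_area, probs = seq(0, 1, length.out = n_area_bins + 1L),
                          na.rm = TRUE))
    data$roi_area_bin <- cut(data$roi_area, breaks = qs, include.lowest = TRUE)
  }
  for (r in intersect(spec$random, c("participant", "image"))) {
    col <- paste0(substr(r, 1, 100), "_id")
    if (!col %in% names(data)) stop_invalid("data lacks column ", col)
    if (length(unique(data[[col]])) < 2L)
      stop_invalid("random factor ", col, " needs >= 2 levels")
  }
  data
}

new_twotone_fit <- function(model, spec, family, converged, messages) {
  sm <- summary(model)$coefficients
  coefs <- data.frame(term = rownames(sm),
                      estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 1] / sm[, 2],
                      p = 2 * pnorm(-abs(sm[, 1] / sm[, 2])),
                      row.names = NULL)
  vc <- lme4::VarCorr(model)
  re_sd <- vapply(vc, function(m) attr(m, "stddev")[[1]], numeric(1))
  structure(list(model = model, spec = spec, family = family,
                 coefficients = coefs, re_sd = re_sd,
                 logLik = as.numeric(logLik(model)),
                 df = attr(logLik(model), "df"),
                 n_obs = stats::nobs(model),
                 converged = converged, messages = messages),
            class = "twotone_fit")
}

fit_glmm <- function(data, spec, family, nAGQ) {
  data <- prepare_model_data(data, spec)
  data <- data[stats::complete.cases(
    data[, all.vars(build_formula(spec)), drop = FALSE]), , drop = FALSE]
  msgs <- character(0)
  collect <- function(w) { msgs <<- c(msgs, conditionMessage(w))
                           invokeRestart("muffleWarning") }
  fit <- withCallingHandlers({
    if (identical(family, "binomial"))
      lme4::glmer(build_formula(spec), data = data, family = stats::binomial(),
                  nAGQ = nAGQ,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE))
    else
      lme4::lmer(build_formula(spec), data = data, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
  }, warning = collect)
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    !any(grepl("converge", msgs, ignore.case = TRUE))
  list(fit = fit, converged = conv, messages = msgs, data = data)
}

#' Fit a multilevel logistic model with crossed random intercepts
#'
#' Logistic mixed model (Laplace approximation via lme4, bobyqa
#' optimizer) for binary recognition/pointing outcomes, with crossed
#' random intercepts for participants and images (and optionally ROI-area
#' decile bins for pointing models). Age-group coefficients use treatment
#' coding against the adult reference. Complete separation (any fixed
#' effect beyond ±10 log-odds) raises a warning and is flagged on the
#' result; no silent failures.
#'
#' @param data Long-format data frame (see [targets_long()]); must
#'   contain the outcome and grouping columns named in `spec`.
#' @param spec A [model_spec()] with a binary outcome.
#' @param nAGQ Integrand approximation order passed to [lme4::glmer()]
#'   (1 = Laplace).
#' @return A `"twotone_fit"` object.
#' @export
fit_mixed_logistic <- function(data, spec, nAGQ = 1L) {
  y <- data[[spec$outcome]]
  if (is.null(y)) stop_invalid("outcome column ", spec$outcome, " not found")
  if (!all(stats::na.omit(as.numeric(y)) %in% c(0, 1)))
    stop_invalid("outcome must be binary 0/1")
  if (length(unique(stats::na.omit(as.numeric(y)))) < 2L) {
    # constant response: the MLE sits at the boundary (complete separation)
    warning("complete separation: outcome is constant; returning an unconverged boundary fit")
    p_hat <- mean(as.numeric(y), na.rm = TRUE)
    return(structure(list(
      model = NULL, spec = spec, family = "binomial",
      coefficients = data.frame(term = "(Intercept)",
                                estimate = qlogis(p_hat), se = Inf,
                                z = 0, p = 1),
      re_sd = numeric(0), logLik = 0, df = NA_integer_,
      n_obs = sum(!is.na(y)), converged = FALSE, separation = TRUE,
      messages = "constant response"),
      class = "twotone_fit"))
  }
  res <- fit_glmm(data, spec, "binomial", nAGQ)
  out <- new_twotone_fit(res$fit, spec, "binomial", res$converged, res$messages)
  if (any(abs(out$coefficients$estimate) > 10) ||
      length(unique(stats::na.omit(as.numeric(y)))) < 2L) {
    warning("possible separation: extreme fixed-effect estimates; interpret with care")
    out$separation <- TRUE
    out$converged <- FALSE
  } else out$separation <- FALSE
  out
}

#' Fit the log-distance multilevel model
#'
#' Gaussian mixed model on log-transformed pointing distances (distances
#' are strictly positive; exact zeros are offset by half the smallest
#' positive distance, with a message) with the same crossed random
#' intercepts as the logistic models, fitted by maximum likelihood so
#' nested fits are comparable by likelihood ratio. Back-transformed
#' fixed effects (`exp(estimate)`) are multiplicative distance ratios.
#'
#' @param data Long-format data frame.
#' @param spec A [model_spec()] whose outcome is a positive distance
#'   column (mm).
#' @return A `"twotone_fit"` with `family = "lognormal"`.
#' @export
fit_distance_model <- function(data, spec) {
  d <- data[[spec$outcome]]
  if (is.null(d)) stop_invalid("outcome column ", spec$outcome, " not found")
  if (any(d < 0, na.rm = TRUE))
    stop_invalid("distances must be nonnegative")
  if (any(d == 0, na.rm = TRUE)) {
    off <- min(d[d > 0], na.rm = TRUE) / 2
    if (!is.finite(off) || off <= 0)
      stop_invalid("no positive distances to set the zero offset")
    message(sprintf("offsetting %d zero distances by %.4g mm",
                    sum(d == 0, na.rm = TRUE), off))
    d[d == 0] <- off
  }
  data$.log_dist <- log(d)
  spec2 <- spec; spec2$outcome <- ".log_dist"
  res <- fit_glmm(data, spec2, "gaussian", NULL)
  out <- new_twotone_fit(res$fit, spec, "lognormal", res$converged, res$messages)
  out$coefficients$ratio <- exp(out$coefficients$estimate)
  out
}

#' @export
print.twotone_fit <- function(x, digits = 3, ...) {
  cat(sprintf("multilevel %s fit: %s\n",
              if (x$family == "binomial") "logistic" else "log-distance",
              deparse(build_formula(x$spec))))
  cat(sprintf("  n = %d, logLik = %.2f (df %d), converged: %s\n",
              x$n_obs, x$logLik, x$df, x$converged))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.twotone_fit <- function(object, ...) {
  structure(list(fit = object, re_sd = object$re_sd), class = "summary.twotone_fit")
}

#' @export
print.summary.twotone_fit <- function(x, ...) {
  print(x$fit)
  cat("random-intercept SDs:\n")
  print(round(x$re_sd, 3))
  invisible(x)
}

#' @export
coef.twotone_fit <- function(object, ...)
  setNames(object$coefficients$estimate, object$coefficients$term)

#' @export
logLik.twotone_fit <- function(object, ...)
  structure(object$logLik, df = object$df, nobs = object$n_obs,
            class = "logLik")

#' @export
vcov.twotone_fit <- function(object, ...) as.matrix(vcov(object$model))

#' Likelihood-ratio test of nested multilevel fits
#'
#' Tests a full model against a reduced model without the effect of
#' interest: X2 = 2(l_full - l_reduced) (clamped at 0 against boundary
#' numerical noise), df = parameter-count difference, p from the
#' chi-squared reference.
#'
#' @param full,reduced `"twotone_fit"` objects on the same rows, reduced
#'   nested in full.
#' @return An `"lrt_result"`: list with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "twotone_fit"), inherits(reduced, "twotone_fit"))
  if (full$n_obs != reduced$n_obs)
    stop_invalid("models were fitted to different numbers of observations")
  df <- full$df - reduced$df
  if (df < 0) stop_invalid("reduced model must be nested in the full model")
  if (df == 0 && !isTRUE(all.equal(full$logLik, reduced$logLik)))
    stop_invalid("models with equal df are not nested")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  structure(list(chi2 = chi2, df = max(df, 0L),
                 p = if (df >= 1) pchisq(chi2, df, lower.tail = FALSE) else 1),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: X2(%d) = %.2f, p = %.3g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Wald test of a single coefficient
#'
#' `z = estimate / SE` with a two-sided normal p value; used for
#' pairwise age-group contrasts under treatment coding.
#'
#' @param fit A `"twotone_fit"`.
#' @param coefficient Coefficient (term) name.
#' @return A `"wald_result"`: list with `term`, `estimate`, `se`, `z`,
#'   `p`.
#' @export
wald_contrast <- function(fit, coefficient) {
  stopifnot(inherits(fit, "twotone_fit"))
  i <- match(coefficient, fit$coefficients$term)
  if (is.na(i)) stop_invalid("no coefficient named ", coefficient,
                             " (have: ", paste(fit$coefficients$term, collapse = ", "), ")")
  est <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  z <- if (est == 0) 0 else est / se
  structure(list(term = coefficient, estimate = est, se = se, z = z,
                 p = 2 * pnorm(-abs(z))),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald [%s]: z = %.2f, p = %.3g\n", x$term, x$z, x$p))
  invisible(x)
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param values Numeric sample (n >= 2).
#' @param reps Bootstrap resamples (default 10000).
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @param conf Confidence level.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, reps = 10000L, seed = NULL, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_invalid("need at least 2 values to bootstrap")
  with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * reps,
                             replace = TRUE), nrow = reps)
    means <- rowMeans(matrix(values[idx], nrow = reps))
    a <- (1 - conf) / 2
    setNames(as.numeric(quantile(means, c(a, 1 - a))), c("low", "high"))
  })
}

#' Imagewise Pearson correlation between two performance tables
#'
#' Correlates per-image means of a measure between two tables (e.g. two
#' age groups), joined on `image_id`.
#'
#' @param tableA,tableB Data frames with `image_id` and the measure
#'   column.
#' @param measure Column to correlate (default `"mean"`, as produced by
#'   [aggregate_performance()] at image level).
#' @return A `"correlation_result"`.
#' @export
imagewise_correlation <- function(tableA, tableB, measure = "mean") {
  ka <- if ("image_id" %in% names(tableA)) "image_id" else "image"
  kb <- if ("image_id" %in% names(tableB)) "image_id" else "image"
  m <- merge(setNames(tableA[, c(ka, measure)], c("image_id", "a")),
             setNames(tableB[, c(kb, measure)], c("image_id", "b")),
             by = "image_id")
  pearson_correlation(m$a, m$b)
}
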