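#' Change-from-baseline descriptives
#'
#' Computes per-unit change from baseline, where baseline is each unit's
#' earliest visit with data, and summarises it in the two conventions used
#' for trial endpoints: the *directional* mean (SD) of the signed changes and
#' the *absolute* mean (SD) of their magnitudes (change regardless of
#' direction).  When an `eye` column is present the unit is the eye and the
#' summary is reported per eye (OD, OS) and pooled over all eye-level
#' changes (OU); otherwise the unit is the participant.
#'
#' @param ds Data frame with columns `participant`, optional `eye`
#'   (`"OD"`/`"OS"`), `visit_month`, and `value`.
#' @param target_visit Visit month at which change is evaluated.
#' @param value_col Name of the outcome column (default `"value"`).
#'
#' @return A list with `changes` (one row per unit: baseline month, baseline
#'   value, target value, `change`) and `summary` (per group: `n`,
#'   `mean_change`, `sd_change`, `mean_abs_change`, `sd_abs_change`).
#' @examples
#' ds <- data.frame(participant = rep(c("A", "B"), each = 2),
#'                  visit_month = rep(c(0, 12), 2), value = c(3, 5, 4, 3))
#' change_from_baseline(ds, 12)$summary  # directional 0.5, absolute 1.5
#' @export
change_from_baseline <- function(ds, target_visit, value_col = "value") {
  if (!all(c("participant", "visit_month", value_col) %in% names(ds)))
    stop("`ds` must contain participant, visit_month and ", value_col,
         call. = FALSE)
  has_eye <- "eye" %in% names(ds) && any(!is.na(ds$eye))
  ds$`.unit` <- if (has_eye) paste(ds$participant, ds$eye) else ds$participant

  changes <- do.call(rbind, lapply(split(ds, ds$`.unit`), function(d) {
    d <- d[order(d$visit_month), , drop = FALSE]
    d <- d[!is.na(d[[value_col]]), , drop = FALSE]
    tgt <- d[d$visit_month == target_visit, , drop = FALSE]
    if (!nrow(d) || !nrow(tgt)) return(NULL)
    base <- d[1, , drop = FALSE]
    if (base$visit_month >= target_visit) return(NULL)
    data.frame(participant = d$participant[1],
               eye = if (has_eye) d$eye[1] else NA_character_,
               baseline_month = base$visit_month,
               baseline_value = base[[value_col]],
               target_value = tgt[[value_col]][1],
               change = tgt[[value_col]][1] - base[[value_col]])
  }))
  if (is.null(changes) || !nrow(changes))
    stop("no unit has both a baseline and visit month ", target_visit,
         call. = FALSE)
  rownames(changes) <- NULL

  summarise <- function(x, group) {
    data.frame(group = group, n = length(x),
               mean_change = mean(x),
               sd_change = if (length(x) > 1) sd(x) else NA_real_,
               mean_abs_change = mean(abs(x)),
               sd_abs_change = if (length(x) > 1) sd(abs(x)) else NA_real_)
  }
  summary <- if (has_eye) {
    rbind(summarise(changes$change[changes$eye == "OD"], "OD"),
          summarise(changes$change[changes$eye == "OS"], "OS"),
          summarise(changes$change, "OU"))
  } else {
    summarise(changes$change, "all")
  }
  rownames(summary) <- NULL
  list(changes = changes, summary = summary)
}

#' Significance label under the trial's 0.05 / 0.10 convention
#'
#' Labels a p-value as `"significant"` (p < 0.05), `"moderately significant"`
#' (0.05 <= p < 0.10) or `"not significant"` (p >= 0.10).  No multiplicity
#' adjustment is applied (all analyses being exploratory).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Character vector of labels.
#' @examples
#' significance_label(c(0.047, 0.08, 0.5))
#' @export
significance_label <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0 | p > 1))
    stop("`p` must contain probabilities in (0, 1]", call. = FALSE)
  ifelse(p < 0.05, "significant",
         ifelse(p < 0.10, "moderately significant", "not significant"))
}

#' Longitudinal mixed model for change from baseline
#'
#' Fits the trial's longitudinal model to a tidy visit-level outcome: visit
#' month enters as a categorical fixed effect with the earliest visit as
#' reference, so each coefficient is the modelled mean change from baseline
#' at that visit.  Participants contribute a random intercept (between-
#' participant baseline variation) and, by default, a random slope in months
#' (between-participant variation in rate of change).  When both eyes are
#' analysed together, eyes are nested within participants via an additional
#' eye-level random intercept; no eye fixed effect is included.  The induced
#' marginal covariance with a random intercept is the classical compound
#' symmetry structure (equal variances, equal correlations regardless of
#' time gap).  Estimation is by REML via [nlme::lme()].
#'
#' If the random intercept + slope model fails to converge, or its slope
#' variance collapses to the boundary, the model is automatically refitted
#' with a random intercept only and `fallback_applied` is set (with a
#' message) — the same cascade used when a full model cannot be estimated on
#' a small cohort.
#'
#' Confidence intervals and p-values for the fixed effects use the normal
#' approximation by default; `df_method = "contain"` instead uses the
#' containment t degrees of freedom reported by `lme`.
#'
#' @param ds Data frame with columns `participant`, optional `eye`,
#'   `visit_month`, and `value`.
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @param nest_eyes Nest eyes within participants; default: `TRUE` whenever
#'   an `eye` column with data is present.
#' @param conf_level Confidence level (default 0.95).
#' @param df_method `"normal"` (default) or `"contain"`.
#' @param value_col Name of the outcome column.
#'
#' @return An object of class `longitudinal_fit`: `estimates` (per-visit
#'   change from baseline with CI, p and significance label), `converged`,
#'   `fallback_applied`, `model_label`, `varcomp` and the underlying `lme`
#'   fit.
#' @export
fit_longitudinal <- function(ds, random = c("intercept_slope", "intercept"),
                             nest_eyes = NULL, conf_level = 0.95,
                             df_method = c("normal", "contain"),
                             value_col = "value") {
  random <- match.arg(random)
  df_method <- match.arg(df_method)
  if (!all(c("participant", "visit_month", value_col) %in% names(ds)))
    stop("`ds` must contain participant, visit_month and ", value_col,
         call. = FALSE)
  d <- ds[!is.na(ds[[value_col]]), , drop = FALSE]
  months <- sort(unique(d$visit_month))
  if (length(months) < 2L) stop("need at least 2 visits", call. = FALSE)
  if (length(unique(d$participant)) < 2L)
    stop("need at least 2 participants", call. = FALSE)

  has_eye <- "eye" %in% names(d) && any(!is.na(d$eye)) &&
    length(unique(d$eye)) > 1L
  if (is.null(nest_eyes)) nest_eyes <- has_eye

  dat <- data.frame(
    participant = factor(d$participant),
    visit_f = factor(d$visit_month, levels = months),
    month = as.numeric(d$visit_month),
    value = d[[value_col]]
  )
  if (nest_eyes) dat$eyeid <- factor(paste(d$participant, d$eye, sep = ":"))

  random_spec <- function(slope) {
    if (nest_eyes) {
      if (slope) list(participant = ~ 1 + month, eyeid = ~ 1)
      else       list(participant = ~ 1, eyeid = ~ 1)
    } else {
      if (slope) ~ 1 + month | participant else ~ 1 | participant
    }
  }

  fit_one <- function(slope) {
    nlme::lme(value ~ visit_f, random = random_spec(slope), data = dat,
              method = "REML")
  }

  slope_requested <- random == "intercept_slope"
  fallback_applied <- FALSE
  fit <- NULL
  if (slope_requested) {
    fit <- tryCatch(fit_one(TRUE), error = function(e) e)
    if (!inherits(fit, "error")) {
      # boundary check: a degenerate slope variance means the slope model is
      # not really supported by the data
      vc <- nlme::VarCorr(fit)
      sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
      slope_sd <- suppressWarnings(
        as.numeric(vc[grepl("^month$", rownames(vc)), "StdDev"][1]))
      resid_sd <- fit$sigma
      if (is.finite(slope_sd) && slope_sd < 1e-6 * max(resid_sd, 1e-12))
        fit <- simpleError("slope variance estimated at the boundary")
    }
    if (inherits(fit, "error")) {
      message("random intercept + slope model did not converge (",
              conditionMessage(fit),
              "); falling back to random intercept only")
      fallback_applied <- TRUE
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    fit <- tryCatch(fit_one(FALSE), error = function(e) e)
    if (inherits(fit, "error"))
      stop("longitudinal model failed to converge even with random ",
           "intercept only: ", conditionMessage(fit), call. = FALSE)
  }

  beta <- nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  terms <- paste0("visit_f", months[-1])
  est <- beta[terms]
  se <- sqrt(diag(V)[terms])
  if (df_method == "normal") {
    q <- qnorm(1 - (1 - conf_level) / 2)
    p <- 2 * pnorm(-abs(est / se))
  } else {
    tt <- summary(fit)$tTable
    dfs <- tt[terms, "DF"]
    q <- stats::qt(1 - (1 - conf_level) / 2, dfs)
    p <- 2 * stats::pt(-abs(est / se), dfs)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  estimates <- data.frame(
    visit_month = months[-1],
    estimate = as.numeric(est),
    se = as.numeric(se),
    ci_low = as.numeric(est - q * se),
    ci_high = as.numeric(est + q * se),
    p = as.numeric(p),
    label = significance_label(as.numeric(p))
  )
  rownames(estimates) <- NULL

  used_slope <- slope_requested && !fallback_applied
  model_label <- paste0(
    "linear mixed model: visit (categorical) fixed effect; random ",
    if (used_slope) "intercept + slope" else "intercept",
    " per participant",
    if (nest_eyes) ", eyes nested within participants" else "",
    "; compound-symmetry covariance; REML"
  )

  structure(
    list(estimates = estimates, converged = TRUE,
         fallback_applied = fallback_applied, model_label = model_label,
         varcomp = nlme::VarCorr(fit), sigma = fit$sigma,
         n_units = length(unique(if (nest_eyes) dat$eyeid else dat$participant)),
         fit = fit),
    class = "longitudinal_fit"
  )
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(x$model_label, "\n")
  if (x$fallback_applied)
    cat("note: random-slope model did not converge; intercept-only fallback used\n")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  month %g: %+.3f [%.3f, %.3f], p = %.3g (%s)\n",
                est$visit_month[i], est$estimate[i], est$ci_low[i],
                est$ci_high[i], est$p[i], est$label[i]))
  invisible(x)
}
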