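#' Validate a table of 8-point grader records
#'
#' A grade record is one grader's score for one image: a value on the 0-8
#' transillumination scale with at most one decimal place (graders could
#' interpolate between adjacent photographic standards).
#'
#' @param grades Data frame with columns `participant`, `eye`,
#'   `visit_month`, `grader_id`, `image_index`, `grade`.
#' @return The validated data frame, invisibly.
#' @export
validate_grades <- function(grades) {
  required <- c("participant", "eye", "visit_month", "grader_id",
                "image_index", "grade")
  missing <- setdiff(required, names(grades))
  if (length(missing))
    stop("grade table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- grades$grade
  if (anyNA(g) || any(g < 0 | g > 8))
    stop("grades must lie in [0, 8]", call. = FALSE)
  if (any(abs(g * 10 - round(g * 10)) > 1e-8))
    stop("grades must have at most one decimal place", call. = FALSE)
  invisible(grades)
}

#' Panel-mean transillumination scores
#'
#' Two-stage aggregation of an 8-point grading panel: within each
#' participant x eye x visit cell, each grader's grades are first averaged
#' over the available images (two per eye-visit in the standard design), and
#' those per-grader means are then averaged across graders.  The result is
#' the quantity analysed longitudinally.
#'
#' @param grades A validated grade table (see [validate_grades()]).
#' @return Data frame with one row per participant x eye x visit:
#'   `mean_score` and `n_graders_used`.
#' @examples
#' g <- expand.grid(participant = "P1", eye = "OD", visit_month = 0,
#'                  grader_id = c("A", "B"), image_index = 1:2)
#' g$grade <- c(4, 6, 5, 7)  # grader means 4.5 and 6.5
#' panel_scores(g)           # panel mean 5.5
#' @export
panel_scores <- function(grades) {
  validate_grades(grades)
  per_grader <- aggregate(grade ~ participant + eye + visit_month + grader_id,
                          data = grades, FUN = mean)
  out <- aggregate(grade ~ participant + eye + visit_month, data = per_grader,
                   FUN = mean)
  n <- aggregate(grade ~ participant + eye + visit_month, data = per_grader,
                 FUN = length)
  names(out)[names(out) == "grade"] <- "mean_score"
  out$n_graders_used <- n$grade
  out <- out[order(out$participant, out$eye, out$visit_month), ]
  rownames(out) <- NULL
  out
}

#' Intergrader reliability (intraclass correlation) for one eye-visit
#'
#' Builds the participants x graders matrix of per-grader image-mean grades
#' for the requested eye and visit and computes the two-way random-effects,
#' absolute-agreement intraclass correlation coefficient.  Graders are
#' treated as a random sample of graders; participants are the targets.  The
#' single-measure form ICC(A,1) is reported as primary (the reliability of
#' one grader), with the average-measure form ICC(A,k) (the reliability of
#' the k-grader panel mean) alongside.  95% confidence intervals follow the
#' mean-square / Satterthwaite construction of McGraw & Wong for agreement
#' ICCs; the average-measure interval is the Spearman-Brown transform of the
#' single-measure one.
#'
#' @param grades A grade table (see [validate_grades()]).
#' @param eye,visit_month Optional filters selecting one eye-visit cell; omit
#'   to use all supplied rows as a single cell.
#' @param allow_missing If `FALSE` (default) an incomplete participants x
#'   graders matrix is an error; if `TRUE`, participants with any missing
#'   grader mean are dropped (complete-case).
#' @param conf_level Confidence level for the intervals.
#'
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`
#'   (single measure), `icc_avg`, `ci_low_avg`, `ci_high_avg` (average
#'   measure), `model_label`, `n_participants`, `n_graders`, `eye`,
#'   `visit_month`.
#' @export
intergrader_icc <- function(grades, eye = NULL, visit_month = NULL,
                            allow_missing = FALSE, conf_level = 0.95) {
  validate_grades(grades)
  d <- grades
  if (!is.null(eye)) d <- d[d$eye == eye, , drop = FALSE]
  if (!is.null(visit_month))
    d <- d[d$visit_month == visit_month, , drop = FALSE]
  if (!nrow(d)) stop("no grades for the requested eye/visit", call. = FALSE)

  per_grader <- aggregate(grade ~ participant + grader_id, data = d,
                          FUN = mean)
  M <- tapply(per_grader$grade, list(per_grader$participant,
                                     per_grader$grader_id), mean)
  if (anyNA(M)) {
    if (!allow_missing)
      stop("incomplete grading panel: every grader must grade every ",
           "participant (set `allow_missing = TRUE` for complete-case use)",
           call. = FALSE)
    M <- M[rowSums(is.na(M)) == 0L, , drop = FALSE]
  }
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L)
    stop("ICC needs at least 2 participants and 2 graders", call. = FALSE)
  if (max(M) - min(M) < .Machine$double.eps^0.5)
    stop("ICC undefined for constant grades", call. = FALSE)

  grand <- mean(M)
  rowm <- rowMeans(M); colm <- colMeans(M)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((M - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icck <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  alpha <- 1 - conf_level
  sb <- function(r) k * r / (1 + (k - 1) * r)  # Spearman-Brown step-up
  if (1 - icc1 < 1e-12) {
    ci1 <- c(icc1, icc1)
  } else {
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci1 <- c(lower, upper)
  }

  structure(
    list(icc = icc1, ci_low = ci1[1], ci_high = ci1[2],
         icc_avg = icck, ci_low_avg = sb(ci1[1]), ci_high_avg = sb(ci1[2]),
         model_label = "two-way random effects, absolute agreement, single measure (ICC(A,1))",
         n_participants = n, n_graders = k,
         eye = if (is.null(eye)) NA_character_ else eye,
         visit_month = if (is.null(visit_month)) NA_real_ else visit_month,
         conf_level = conf_level,
         mean_squares = c(MSR = MSR, MSC = MSC, MSE = MSE)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f, %.3f]; ICC(A,%d) = %.3f [%.3f, %.3f]\n",
              x$icc, x$ci_low, x$ci_high, x$n_graders, x$icc_avg,
              x$ci_low_avg, x$ci_high_avg))
  cat(sprintf("  %s; n = %d participants, k = %d graders\n",
              x$model_label, x$n_participants, x$n_graders))
  invisible(x)
}

#' Intergrader ICC for every eye-visit cell
#'
#' @inheritParams intergrader_icc
#' @return Data frame with one row per eye x visit: point estimate and CI of
#'   the single- and average-measure agreement ICCs.
#' @export
icc_by_visit <- function(grades, allow_missing = FALSE, conf_level = 0.95) {
  validate_grades(grades)
  cells <- unique(grades[, c("eye", "visit_month")])
  cells <- cells[order(cells$eye, cells$visit_month), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- intergrader_icc(grades, eye = cells$eye[i],
                         visit_month = cells$visit_month[i],
                         allow_missing = allow_missing,
                         conf_level = conf_level)
    data.frame(eye = r$eye, visit_month = r$visit_month, icc = r$icc,
               ci_low = r$ci_low, ci_high = r$ci_high, icc_avg = r$icc_avg,
               ci_low_avg = r$ci_low_avg, ci_high_avg = r$ci_high_avg,
               n_participants = r$n_participants, n_graders = r$n_graders)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation between panel and semiquantitative scores
#'
#' Agreement between the two scoring routes for the same eyes: the human
#' 8-point panel means and the automated semiquantitative image scores are
#' paired on participant x eye x visit, pooled across eyes and visits, and
#' summarised by Spearman's rank correlation (midranks for ties).
#'
#' @param panel Output of [panel_scores()] (or any data frame with
#'   `participant`, `eye`, `visit_month`, `mean_score`).
#' @param semiquant The `eye_visit_scores` table of [score_image_set()] (same
#'   columns).
#' @return Spearman's rank correlation coefficient (single number).
#' @export
method_correlation <- function(panel, semiquant) {
  m <- merge(panel[, c("participant", "eye", "visit_month", "mean_score")],
             semiquant[, c("participant", "eye", "visit_month", "mean_score")],
             by = c("participant", "eye", "visit_month"),
             suffixes = c("_panel", "_semiquant"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop("method correlation needs at least 3 paired eye-visit observations",
         call. = FALSE)
  cor(m$mean_score_panel, m$mean_score_semiquant, method = "spearman")
}
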