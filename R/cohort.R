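#' Ground-truth parameters for a synthetic pigmentation cohort
#'
#' Defines the generating model for a synthetic trial cohort with known
#' truth, mirroring the pilot-study design: 5 participants, both eyes,
#' visits at months 0, 3, 6, 9, 12, 15 and 18 (the two baseline visits being
#' collapsed to month 0; set `second_baseline = TRUE` to add a second
#' baseline at month 1 and exercise the earliest-baseline rule), a panel of
#' 18 graders scoring 2 images per eye-visit to one decimal place, diffuse
#' reflectance spectra per body site, hair PTCA/4-AHP chemistry and ETDRS
#' letters read.
#'
#' The latent eye-visit transillumination score is
#' `L(i, e, t) = latent_baseline_mean + b_i + s_i * t + c_ie +
#' fixed_visit_effects[t]`, clamped to \[0, 8\], with participant intercepts
#' `b_i ~ N(0, sd_intercept^2)`, participant slopes
#' `s_i ~ N(0, sd_slope^2)` and eye intercepts `c_ie ~ N(0, eye_sd^2)`.
#' Grader g's grade of one image is
#' `round_1(clamp(L + gamma_g + eps, 0, 8))` with grader bias
#' `gamma_g ~ N(0, grader_bias_sd^2)` and per-grade noise
#' `eps ~ N(0, grader_noise_sd^2)`.
#'
#' @param n_participants Number of participants (default 5).
#' @param visit_months Strictly increasing visit months including 0.
#' @param latent_baseline_mean Mean latent baseline score on the 0-8 scale.
#' @param sd_intercept,sd_slope,eye_sd Between-participant intercept SD
#'   (score units), slope SD (score units/month) and between-eye SD.
#' @param fixed_visit_effects Named vector mapping each visit month to the
#'   true mean change from baseline at that visit (score units); must cover
#'   `visit_months` and be 0 at month 0.
#' @param grader_bias_sd,grader_noise_sd Grader bias and per-grade noise SDs
#'   (score units).
#' @param n_graders Panel size (default 18, >= 2).
#' @param images_per_eye_visit Images captured per eye-visit (default 2).
#' @param image_geometry,image_size,image_noise_sd Rendering parameters for
#'   the synthetic TI photographs (see [render_ti_image()]).
#' @param reflectometry_truth Data frame with columns `site`, `baseline_m`,
#'   `shift_12` (true M-index change at month 12, held thereafter),
#'   `participant_sd` and `replicate_sd`; see
#'   [default_reflectometry_truth()].
#' @param hair_truth List with per-marker baseline mean/SD (ng/mg, realised
#'   as a lognormal across participants), true shifts at months 12 and 18,
#'   and a residual SD; see [default_hair_truth()].
#' @param acuity_truth List with baseline letters mean, participant/eye SDs,
#'   residual SD and per-visit true letter gains; see
#'   [default_acuity_truth()].
#' @param second_baseline Add a second baseline visit at month 1 (true
#'   effect 0).
#' @param seed Integer seed controlling all generation.
#'
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_participants = 5,
                         visit_months = c(0, 3, 6, 9, 12, 15, 18),
                         latent_baseline_mean = 4,
                         sd_intercept = 1.0,
                         sd_slope = 0.03,
                         eye_sd = 0.2,
                         fixed_visit_effects = c(`0` = 0, `3` = 0.25,
                                                 `6` = 0.5, `9` = 0.75,
                                                 `12` = 1, `15` = 1, `18` = 1),
                         grader_bias_sd = 0.3,
                         grader_noise_sd = 0.5,
                         n_graders = 18,
                         images_per_eye_visit = 2,
                         image_geometry = iris_geometry(120, 120, 100, 30),
                         image_size = c(241, 241),
                         image_noise_sd = 3,
                         reflectometry_truth = default_reflectometry_truth(),
                         hair_truth = default_hair_truth(),
                         acuity_truth = default_acuity_truth(),
                         second_baseline = FALSE,
                         seed = 1L) {
  fail <- function(field, why) stop("invalid `", field, "`: ", why,
                                    call. = FALSE)
  if (!is.numeric(n_participants) || n_participants < 1)
    fail("n_participants", "must be a positive count")
  if (is.unsorted(visit_months, strictly = TRUE))
    fail("visit_months", "must be strictly increasing")
  if (!0 %in% visit_months) fail("visit_months", "must include month 0")
  for (nm in c("sd_intercept", "sd_slope", "eye_sd", "grader_bias_sd",
               "grader_noise_sd", "image_noise_sd")) {
    if (get(nm) < 0) fail(nm, "standard deviations must be >= 0")
  }
  if (n_graders < 2) fail("n_graders", "must be >= 2")
  if (images_per_eye_visit < 1) fail("images_per_eye_visit", "must be >= 1")
  if (isTRUE(second_baseline)) {
    visit_months <- sort(unique(c(visit_months, 1)))
    fixed_visit_effects <- c(fixed_visit_effects, `1` = 0)
  }
  missing_eff <- setdiff(visit_months, as.numeric(names(fixed_visit_effects)))
  if (length(missing_eff))
    fail("fixed_visit_effects",
         paste("no effect given for visit month(s)",
               paste(missing_eff, collapse = ", ")))
  if (abs(fixed_visit_effects[["0"]]) > 0)
    fail("fixed_visit_effects", "the month-0 effect must be 0")
  if (!all(c("site", "baseline_m", "shift_12", "participant_sd",
             "replicate_sd") %in% names(reflectometry_truth)))
    fail("reflectometry_truth",
         "needs columns site, baseline_m, shift_12, participant_sd, replicate_sd")
  if (!is.numeric(seed) || length(seed) != 1L)
    fail("seed", "must be a single integer")

  structure(
    list(n_participants = as.integer(n_participants),
         visit_months = visit_months,
         latent_baseline_mean = latent_baseline_mean,
         sd_intercept = sd_intercept, sd_slope = sd_slope, eye_sd = eye_sd,
         fixed_visit_effects = fixed_visit_effects,
         grader_bias_sd = grader_bias_sd,
         grader_noise_sd = grader_noise_sd,
         n_graders = as.integer(n_graders),
         images_per_eye_visit = as.integer(images_per_eye_visit),
         image_geometry = image_geometry, image_size = image_size,
         image_noise_sd = image_noise_sd,
         reflectometry_truth = reflectometry_truth,
         hair_truth = hair_truth, acuity_truth = acuity_truth,
         second_baseline = isTRUE(second_baseline),
         seed = as.integer(seed)),
    class = "cohort_truth"
  )
}

#' Default ground truth for the reflectometry arm
#'
#' Baseline M indices typical of lightly pigmented (OCA-1B) skin and hair,
#' with true month-12 M-index shifts matching the magnitudes observed in the
#' pilot study (inner bicep +1.72, outer forearm +3.4, hair +17.3; other
#' sites essentially flat).  Shifts ramp linearly from month 0 to month 12
#' and are held afterwards.
#'
#' @return Data frame with columns `site`, `baseline_m`, `shift_12`,
#'   `participant_sd`, `replicate_sd`.
#' @export
default_reflectometry_truth <- function() {
  data.frame(
    site = c("forehead", "inner_forearm", "outer_forearm", "inner_bicep",
             "lower_back", "hair"),
    baseline_m = c(30, 28, 29, 27, 30, 55),
    shift_12 = c(0.5, 1.0, 3.4, 1.72, 0.5, 17.3),
    participant_sd = c(3, 3, 3, 3, 3, 8),
    replicate_sd = c(1, 1, 1, 1, 1, 2)
  )
}

#' Default ground truth for the hair chemistry arm
#'
#' Baseline PTCA and 4-AHP distributions matching the pilot cohort's
#' baseline mean (SD) of 26.22 (20.59) and 13.28 (19.66) ng/mg, realised as
#' lognormals, with true additive shifts at month 12 of +7.62 (PTCA) and
#' -5.92 (4-AHP) ng/mg ramping linearly during treatment and relaxing
#' towards the observed safety-visit values (+0.52 / -5.24) by month 18.
#'
#' @return A list with elements `ptca`, `ahp4` (each `mean`, `sd`,
#'   `shift_12`, `shift_18`) and `resid_sd`.
#' @export
default_hair_truth <- function() {
  list(
    ptca = list(mean = 26.22, sd = 20.59, shift_12 = 7.62, shift_18 = 0.52),
    ahp4 = list(mean = 13.28, sd = 19.66, shift_12 = -5.92, shift_18 = -5.24),
    resid_sd = 2
  )
}

#' Default ground truth for the visual-acuity arm
#'
#' ETDRS letters read: baseline around 55 letters (roughly 20/80) with
#' between-participant and between-eye variation, and true mean letter gains
#' ramping to 4.6 at month 12 (the magnitude seen in the pilot study) and a
#' little higher thereafter.
#'
#' @return A list with `mean_letters`, `participant_sd`, `eye_sd`,
#'   `resid_sd` and named per-visit `visit_effects`.
#' @export
default_acuity_truth <- function() {
  list(mean_letters = 55, participant_sd = 8, eye_sd = 3, resid_sd = 2,
       visit_effects = c(`0` = 0, `1` = 0, `3` = 1.5, `6` = 2.5, `9` = 3.5,
                         `12` = 4.6, `15` = 5, `18` = 6))
}

round1 <- function(x) round(x, 1)
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Latent eye-visit scores plus the participant/eye random effects that
# produced them.  RNG state: caller seeds.
latent_scores <- function(truth, eyes = c("OD", "OS")) {
  n <- truth$n_participants
  pid <- sprintf("P%03d", seq_len(n))
  b <- rnorm(n, 0, truth$sd_intercept)
  s <- rnorm(n, 0, truth$sd_slope)
  ce <- matrix(rnorm(n * length(eyes), 0, truth$eye_sd), nrow = n)
  grid <- expand.grid(participant = pid, eye = eyes,
                      visit_month = truth$visit_months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant, grid$eye, grid$visit_month), ]
  rownames(grid) <- NULL
  i <- match(grid$participant, pid)
  e <- match(grid$eye, eyes)
  eff <- truth$fixed_visit_effects[as.character(grid$visit_month)]
  grid$latent_raw <- truth$latent_baseline_mean + b[i] + s[i] *
    grid$visit_month + ce[cbind(i, e)] + as.numeric(eff)
  grid$latent <- clamp(grid$latent_raw, 0, 8)
  list(table = grid, b = b, s = s, participants = pid)
}

#' Simulate visit-level outcomes from a cohort truth
#'
#' Lightweight simulator for model-validation studies: draws the latent
#' trajectory (random intercepts and slopes plus the true visit effects) and
#' adds independent measurement noise, without rendering images or grades.
#' The latent values are *not* clamped to the 0-8 scale here, so the
#' generating model matches the fitted mixed model exactly and recovery is
#' unbiased.
#'
#' @param truth A [cohort_truth()].
#' @param resid_sd Measurement noise SD in outcome units (default 0.5).
#' @param eyes If `TRUE`, simulate both eyes (adding the eye-level
#'   intercept); if `FALSE` (default) one record per participant-visit.
#' @param seed Seed; defaults to `truth$seed`.
#' @return Data frame with `participant`, optional `eye`, `visit_month`,
#'   `value`.
#' @export
simulate_latent_scores <- function(truth, resid_sd = 0.5, eyes = FALSE,
                                   seed = truth$seed) {
  set.seed(seed)
  ls <- latent_scores(truth, eyes = if (eyes) c("OD", "OS") else "OD")
  out <- ls$table
  out$value <- out$latent_raw + rnorm(nrow(out), 0, resid_sd)
  cols <- c("participant", if (eyes) "eye", "visit_month", "value")
  out[, cols]
}

#' Generate a complete synthetic cohort bundle
#'
#' Produces, from explicit ground truth and a seed, every input the analysis
#' pipeline consumes: rendered TI images whose annulus red level encodes the
#' latent score, the 18-grader panel's grade table, reflectance spectra
#' whose M index follows the per-site truth, hair PTCA/4-AHP chemistry, and
#' ETDRS letters read.  Generation is deterministic given the truth (each
#' data stream is seeded from `truth$seed` plus a fixed offset, so e.g. the
#' grade table does not depend on whether images were requested).
#'
#' @param truth A [cohort_truth()].
#' @param include Character vector of streams to generate, any of
#'   `"images"`, `"grades"`, `"spectra"`, `"hair"`, `"acuity"`.
#' @return An object of class `synthetic_bundle`: `images` (named list of
#'   [ti_image()]), `grades`, `spectra`, `hair`, `acuity` (data frames),
#'   `latent` (the latent eye-visit table) and `truth`.
#' @export
generate_cohort <- function(truth,
                            include = c("images", "grades", "spectra",
                                        "hair", "acuity")) {
  if (!inherits(truth, "cohort_truth"))
    stop("`truth` must be a `cohort_truth` object", call. = FALSE)
  include <- match.arg(include, several.ok = TRUE)
  eyes <- c("OD", "OS")

  set.seed(truth$seed)
  ls <- latent_scores(truth, eyes = eyes)
  latent <- ls$table

  bundle <- list(images = NULL, grades = NULL, spectra = NULL, hair = NULL,
                 acuity = NULL, latent = latent, truth = truth)

  if ("grades" %in% include) {
    set.seed(truth$seed + 1L)
    gid <- sprintf("G%02d", seq_len(truth$n_graders))
    gamma <- rnorm(truth$n_graders, 0, truth$grader_bias_sd)
    g <- expand.grid(image_index = seq_len(truth$images_per_eye_visit),
                     grader_id = gid, row = seq_len(nrow(latent)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- data.frame(latent[g$row, c("participant", "eye", "visit_month")],
                    grader_id = g$grader_id, image_index = g$image_index,
                    L = latent$latent[g$row])
    eps <- rnorm(nrow(g), 0, truth$grader_noise_sd)
    bias <- gamma[match(g$grader_id, gid)]
    g$grade <- round1(clamp(g$L + bias + eps, 0, 8))
    g$L <- NULL
    g <- g[order(g$participant, g$eye, g$visit_month, g$grader_id,
                 g$image_index), ]
    rownames(g) <- NULL
    bundle$grades <- g
  }

  if ("images" %in% include) {
    set.seed(truth$seed + 2L)
    imgs <- vector("list", nrow(latent) * truth$images_per_eye_visit)
    nms <- character(length(imgs))
    k <- 0L
    for (r in seq_len(nrow(latent))) {
      for (ii in seq_len(truth$images_per_eye_visit)) {
        k <- k + 1L
        imgs[[k]] <- render_ti_image(
          latent$latent[r], truth$image_geometry, size = truth$image_size,
          noise_sd = truth$image_noise_sd, seed = NULL,
          participant = latent$participant[r], eye = latent$eye[r],
          visit_month = latent$visit_month[r], image_index = ii)
        nms[k] <- sprintf("%s_%s_m%02d_img%d", latent$participant[r],
                          latent$eye[r], latent$visit_month[r], ii)
      }
    }
    names(imgs) <- nms
    bundle$images <- imgs
  }

  if ("spectra" %in% include) {
    set.seed(truth$seed + 3L)
    rt <- truth$reflectometry_truth
    pid <- ls$participants
    rows <- list()
    for (si in seq_len(nrow(rt))) {
      offs <- rnorm(length(pid), 0, rt$participant_sd[si])
      for (pi in seq_along(pid)) {
        for (t in truth$visit_months) {
          target <- rt$baseline_m[si] + offs[pi] +
            rt$shift_12[si] * min(t, 12) / 12
          for (rep in 1:5) {
            m <- target + rnorm(1, 0, rt$replicate_sd[si])
            rows[[length(rows) + 1L]] <- data.frame(
              participant = pid[pi], visit_month = t, site = rt$site[si],
              replicate = rep, wavelength = wavelength_grid(),
              pr = synth_spectrum(m))
          }
        }
      }
    }
    sp <- do.call(rbind, rows)
    rownames(sp) <- NULL
    bundle$spectra <- sp
  }

  if ("hair" %in% include) {
    set.seed(truth$seed + 4L)
    ht <- truth$hair_truth
    pid <- ls$participants
    draw_marker <- function(mk) {
      sdlog <- sqrt(log(1 + (mk$sd / mk$mean)^2))
      meanlog <- log(mk$mean) - sdlog^2 / 2
      base <- rlnorm(length(pid), meanlog, sdlog)
      vapply(truth$visit_months, function(t) {
        shift <- if (t <= 12) mk$shift_12 * t / 12
        else mk$shift_12 + (mk$shift_18 - mk$shift_12) * (t - 12) / 6
        pmax(base + shift + rnorm(length(pid), 0, ht$resid_sd), 0)
      }, numeric(length(pid)))
    }
    ptca <- draw_marker(ht$ptca)
    ahp4 <- draw_marker(ht$ahp4)
    hair <- expand.grid(participant = pid, visit_month = truth$visit_months,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(hair$participant, pid)
    j <- match(hair$visit_month, truth$visit_months)
    hair$ptca <- ptca[cbind(i, j)]
    hair$ahp4 <- ahp4[cbind(i, j)]
    hair <- hair[order(hair$participant, hair$visit_month), ]
    rownames(hair) <- NULL
    bundle$hair <- hair
  }

  if ("acuity" %in% include) {
    set.seed(truth$seed + 5L)
    at <- truth$acuity_truth
    pid <- ls$participants
    missing_eff <- setdiff(truth$visit_months,
                           as.numeric(names(at$visit_effects)))
    if (length(missing_eff))
      stop("invalid `acuity_truth`: no visit effect for month(s) ",
           paste(missing_eff, collapse = ", "), call. = FALSE)
    base_p <- rnorm(length(pid), at$mean_letters, at$participant_sd)
    base_e <- matrix(rnorm(length(pid) * 2, 0, at$eye_sd), ncol = 2)
    ac <- expand.grid(participant = pid, eye = eyes,
                      visit_month = truth$visit_months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(ac$participant, pid)
    e <- match(ac$eye, eyes)
    eff <- as.numeric(at$visit_effects[as.character(ac$visit_month)])
    ac$letters <- round(pmax(base_p[i] + base_e[cbind(i, e)] + eff +
                               rnorm(nrow(ac), 0, at$resid_sd), 0))
    ac <- ac[order(ac$participant, ac$eye, ac$visit_month), ]
    rownames(ac) <- NULL
    bundle$acuity <- ac
  }

  structure(bundle, class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d participants, visits %s\n",
    x$truth$n_participants, paste(x$truth$visit_months, collapse = ", ")))
  cat(sprintf("  images: %s, grades: %s, spectra: %s, hair: %s, acuity: %s\n",
              if (is.null(x$images)) "-" else length(x$images),
              if (is.null(x$grades)) "-" else nrow(x$grades),
              if (is.null(x$spectra)) "-" else nrow(x$spectra),
              if (is.null(x$hair)) "-" else nrow(x$hair),
              if (is.null(x$acuity)) "-" else nrow(x$acuity)))
  invisible(x)
}

# Synthetic diffuse reflectance spectrum with an exactly specified M index:
# the 640-670 nm melanin band is flat at 100 * 10^(-m / 100) percent
# reflectance, and the remaining wavelengths follow a smooth ramp (reflectance
# rising with wavelength, as for light skin) that the index must ignore.
synth_spectrum <- function(m) {
  grid <- wavelength_grid()
  band_pr <- 100 * 10^(-m / 100)
  pr <- band_pr * (0.7 + 0.4 * (grid - 400) / 300)
  pr[grid %in% c(640, 650, 660, 670)] <- band_pr
  pr
}
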