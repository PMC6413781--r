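#' Semiquantitative iris transillumination score of one image
#'
#' Automated counterpart of human 8-point TI grading.  At each retained site
#' of the 16-site [sampling_layout()], the red channel is smoothed with a
#' Gaussian kernel and averaged over the pixels of the site disk intersected
#' with the open iris annulus; the mean of the per-site means is mapped
#' linearly to a 0-8 score (`8 x mean / 255`), so 0 corresponds to no
#' transmitted light and 8 to a fully saturated red reflex.
#'
#' The smoothing is *masked*: it is a normalised Gaussian average over
#' annulus pixels only, so the saturated pupil reflex and the dark background
#' never bleed into the measured signal.  For a constant-red annulus the
#' score is therefore exactly independent of `blur_sigma` and `disk_radius`
#' and equals the plain annulus mean.  Green and blue channels are ignored.
#'
#' @param image A [ti_image()].
#' @param blur_sigma Standard deviation of the Gaussian smoothing kernel in
#'   pixels; defaults to 25 px at the reference resolution, rescaled by
#'   `iris_radius / scale_reference`.  `0` disables smoothing.
#' @param disk_radius,scale_reference Passed to [sampling_layout()].
#' @param layout Optional precomputed [sampling_layout()] (must match the
#'   image geometry).
#'
#' @return An object of class `semiquant_score`: a list with `score` (0-8),
#'   `per_site_red` (named mean red values of the retained sites),
#'   `n_sites_used`, and `excluded` (the layout's exclusion table).
#' @examples
#' g <- iris_geometry(60, 60, 50, 15)
#' semiquant_score(render_ti_image(4, g, size = c(121, 121)))
#' @export
semiquant_score <- function(image, blur_sigma = NULL, disk_radius = NULL,
                            scale_reference = 1000, layout = NULL) {
  if (!inherits(image, "ti_image")) stop("`image` must be a `ti_image`")
  g <- image$geometry
  if (is.null(layout))
    layout <- sampling_layout(g, scale_reference = scale_reference,
                              disk_radius = disk_radius)
  if (is.null(blur_sigma)) blur_sigma <- 25 * g$iris_radius / scale_reference
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)

  keep <- setdiff(layout$sites$site, layout$excluded$site)
  if (length(keep) == 0L)
    stop("no valid sampling sites: all 16 disks miss the iris annulus",
         call. = FALSE)

  red <- image$pixels[, , 1]
  grid <- pixel_grid(g, dim(red))
  mask <- grid$r > g$pupil_radius & grid$r < g$iris_radius
  smoothed <- masked_blur(red, mask, blur_sigma)

  rd2 <- layout$disk_radius^2
  per_site <- vapply(keep, function(s) {
    sx <- layout$sites$x[s]; sy <- layout$sites$y[s]
    sel <- mask & ((grid$X - sx)^2 + (grid$Y - sy)^2 <= rd2)
    if (!any(sel)) return(NA_real_)
    mean(smoothed[sel])
  }, numeric(1))
  names(per_site) <- paste0("site", keep)

  used <- !is.na(per_site)
  if (!any(used))
    stop("no valid sampling sites: retained disks contain no annulus pixels",
         call. = FALSE)

  structure(
    list(score = 8 * mean(per_site[used]) / 255,
         per_site_red = per_site[used],
         n_sites_used = sum(used),
         excluded = layout$excluded),
    class = "semiquant_score"
  )
}

#' @export
print.semiquant_score <- function(x, ...) {
  cat(sprintf("semiquantitative TI score %.3f (%d of 16 sites used)\n",
              x$score, x$n_sites_used))
  invisible(x)
}

# Normalised Gaussian smoothing restricted to `mask`: the value at a masked
# pixel is a Gaussian-weighted average of masked pixels only.  Implemented as
# gauss(x * m) / gauss(m); contributions from outside the mask cancel exactly.
masked_blur <- function(x, mask, sigma) {
  if (sigma <= 0) return(x)
  m <- mask * 1
  num <- EBImage::gblur(x * m, sigma = sigma)
  den <- EBImage::gblur(m, sigma = sigma)
  out <- x
  out[mask] <- num[mask] / den[mask]
  out
}

#' Score a set of transillumination images and average per eye-visit
#'
#' Scores each image with [semiquant_score()] and averages the available
#' image scores within each participant x eye x visit cell (two images per
#' eye-visit in the standard design; a single image yields a degenerate mean
#' with `n_images = 1`).
#'
#' @param images A list of [ti_image()] objects carrying identifiers.
#' @param ... Scoring parameters passed to [semiquant_score()].
#'
#' @return A list with `image_scores` (one row per image) and
#'   `eye_visit_scores` (one row per participant x eye x visit with
#'   `mean_score` and `n_images`).
#' @export
score_image_set <- function(images, ...) {
  if (!length(images)) stop("`images` must be a non-empty list", call. = FALSE)
  ids <- data.frame(
    participant = vapply(images, function(i) i$participant, character(1)),
    eye = vapply(images, function(i) i$eye, character(1)),
    visit_month = vapply(images, function(i) i$visit_month, numeric(1)),
    image_index = vapply(images, function(i) i$image_index, integer(1))
  )
  key <- with(ids, paste(participant, eye, visit_month, image_index))
  if (anyDuplicated(key))
    stop("duplicate (participant, eye, visit_month, image_index) among images",
         call. = FALSE)
  ids$score <- vapply(images, function(i) semiquant_score(i, ...)$score,
                      numeric(1))

  agg <- aggregate(score ~ participant + eye + visit_month, data = ids,
                   FUN = mean)
  cnt <- aggregate(score ~ participant + eye + visit_month, data = ids,
                   FUN = length)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg$n_images <- cnt$score
  agg <- agg[order(agg$participant, agg$eye, agg$visit_month), ]
  rownames(agg) <- NULL
  list(image_scores = ids, eye_visit_scores = agg)
}
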