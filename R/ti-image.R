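#' Construct a transillumination image object
#'
#' Bundles an 8-bit RGB raster with its [iris_geometry()] annotation and the
#' identifiers used throughout the pipeline.
#'
#' @param pixels An `H x W x 3` numeric array of 8-bit intensities (0-255),
#'   channels ordered red, green, blue.  Pixel `[i, j, ]` sits at 0-based
#'   coordinates `(x, y) = (j - 1, i - 1)`.
#' @param geometry An [iris_geometry()]; the full iris circle must lie within
#'   the raster.
#' @param participant,eye,visit_month,image_index Identifiers; `eye` is
#'   `"OD"` or `"OS"` and `image_index` is 1 or 2 in the two-images-per-eye
#'   design.
#'
#' @return An object of class `ti_image`.
#' @export
ti_image <- function(pixels, geometry, participant = NA_character_,
                     eye = NA_character_, visit_month = NA_real_,
                     image_index = NA_integer_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("`pixels` must contain 8-bit intensities in [0, 255]", call. = FALSE)
  assert_geometry(geometry)
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  g <- geometry
  if (g$center_x - g$iris_radius < 0 || g$center_x + g$iris_radius > W - 1 ||
      g$center_y - g$iris_radius < 0 || g$center_y + g$iris_radius > H - 1)
    stop("geometry exceeds image bounds: the iris circle must lie within the raster",
         call. = FALSE)
  if (!is.na(eye) && !eye %in% c("OD", "OS"))
    stop("`eye` must be \"OD\" or \"OS\"", call. = FALSE)
  structure(
    list(pixels = pixels, geometry = geometry,
         participant = as.character(participant), eye = as.character(eye),
         visit_month = as.numeric(visit_month),
         image_index = as.integer(image_index)),
    class = "ti_image"
  )
}

#' @export
print.ti_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ti_image %d x %d  [%s %s month %s image %s]\n", d[1], d[2],
              x$participant, x$eye, format(x$visit_month), x$image_index))
  invisible(x)
}

# Squared distance of every pixel centre from the annotated iris centre,
# plus the 0-based coordinate grids (used for disk membership tests).
pixel_grid <- function(geometry, dims) {
  H <- dims[1]; W <- dims[2]
  X <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  Y <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)
  r <- sqrt((X - geometry$center_x)^2 + (Y - geometry$center_y)^2)
  list(X = X, Y = Y, r = r)
}

# Open-annulus mask: pixel centres strictly between the pupil and iris circles.
annulus_mask <- function(geometry, dims) {
  r <- pixel_grid(geometry, dims)$r
  r > geometry$pupil_radius & r < geometry$iris_radius
}

#' Render a synthetic transillumination image from a latent score
#'
#' Inverse model of the semiquantitative scorer: the iris annulus is filled
#' with a red-channel level of `latent_score / 8 * 255` plus optional
#' zero-mean Gaussian pixel noise, the pupil disk is rendered as a saturated
#' red reflex (the light returning from the retina), and the background is
#' dark.  Green and blue channels carry arbitrary low values; the scorer must
#' ignore them.  No attempt is made to simulate iris texture or slit-lamp
#' optics.
#'
#' @param latent_score Latent transillumination score in \[0, 8\] (higher =
#'   more transillumination = less iris melanin).
#' @param geometry An [iris_geometry()].
#' @param size Integer `c(H, W)` raster size in pixels; must contain the iris
#'   circle.
#' @param noise_sd Standard deviation of the Gaussian pixel noise added to
#'   the annulus red channel, in 8-bit intensity units.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so that a cohort generator can drive many renders from one seed).
#' @param participant,eye,visit_month,image_index Identifiers stored on the
#'   image.
#'
#' @return A [ti_image()].
#' @examples
#' g <- iris_geometry(60, 60, 50, 15)
#' img <- render_ti_image(4, g, size = c(121, 121), noise_sd = 0)
#' @export
render_ti_image <- function(latent_score, geometry, size = c(241, 241),
                            noise_sd = 0, seed = NULL,
                            participant = NA_character_, eye = NA_character_,
                            visit_month = NA_real_, image_index = NA_integer_) {
  if (!is.numeric(latent_score) || length(latent_score) != 1L ||
      latent_score < 0 || latent_score > 8)
    stop("`latent_score` must be a single value in [0, 8]", call. = FALSE)
  assert_geometry(geometry)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  H <- size[1]; W <- size[2]
  g <- geometry
  if (g$center_x - g$iris_radius < 0 || g$center_x + g$iris_radius > W - 1 ||
      g$center_y - g$iris_radius < 0 || g$center_y + g$iris_radius > H - 1)
    stop("geometry exceeds image bounds: the iris circle must lie within the raster",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  r <- pixel_grid(geometry, c(H, W))$r
  pupil <- r <= g$pupil_radius
  annulus <- r > g$pupil_radius & r < g$iris_radius

  red <- matrix(8, H, W)              # dark background
  red[pupil] <- 255                   # saturated red reflex
  level <- latent_score / 8 * 255
  vals <- rep(level, sum(annulus))
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), sd = noise_sd)
  red[annulus] <- pmin(pmax(round(vals), 0), 255)

  green <- matrix(5, H, W); green[annulus] <- 30; green[pupil] <- 12
  blue  <- matrix(4, H, W); blue[annulus]  <- 24; blue[pupil]  <- 10

  ti_image(array(c(red, green, blue), dim = c(H, W, 3)), geometry,
           participant = participant, eye = eye, visit_month = visit_month,
           image_index = image_index)
}

#' Read and write transillumination images as PNG
#'
#' 8-bit RGB PNG input/output.  `read_ti_image()` attaches the supplied
#' geometry and identifiers; `write_ti_image()` stores the raster losslessly.
#'
#' @param path File path.
#' @param geometry An [iris_geometry()] for the image being read.
#' @param ... Identifiers passed on to [ti_image()].
#' @return `read_ti_image()` returns a [ti_image()]; `write_ti_image()`
#'   returns `path` invisibly.
#' @export
read_ti_image <- function(path, geometry, ...) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  ti_image(round(px * 255), geometry, ...)
}

#' @rdname read_ti_image
#' @param image A [ti_image()] to write.
#' @export
write_ti_image <- function(image, path) {
  if (!inherits(image, "ti_image")) stop("`image` must be a `ti_image`")
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}
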