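#' Iris geometry annotation for a transillumination photograph
#'
#' Describes the hand-annotated circle model of one anterior-segment
#' transillumination (TI) image: the common centre of the iris and pupil
#' circles and their radii.  Coordinates are continuous, 0-based pixel
#' positions with x increasing rightwards and y increasing downwards, so a
#' pixel in row `i`, column `j` of the raster sits at `(x, y) = (j - 1, i - 1)`.
#'
#' @param center_x,center_y Centre of the iris circle in pixels.
#' @param iris_radius Radius of the iris (limbus) circle in pixels.
#' @param pupil_radius Radius of the pupil circle in pixels; must be strictly
#'   between 0 and `iris_radius`.
#'
#' @return An object of class `iris_geometry`.
#' @examples
#' iris_geometry(120, 120, iris_radius = 100, pupil_radius = 30)
#' @export
iris_geometry <- function(center_x, center_y, iris_radius, pupil_radius) {
  for (nm in c("center_x", "center_y", "iris_radius", "pupil_radius")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (iris_radius <= 0)
    stop("`iris_radius` must be positive", call. = FALSE)
  if (pupil_radius <= 0 || pupil_radius >= iris_radius)
    stop("`pupil_radius` must satisfy 0 < pupil_radius < iris_radius",
         call. = FALSE)
  structure(
    list(center_x = center_x, center_y = center_y,
         iris_radius = iris_radius, pupil_radius = pupil_radius),
    class = "iris_geometry"
  )
}

#' @export
print.iris_geometry <- function(x, ...) {
  cat(sprintf(
    "iris geometry: centre (%.1f, %.1f), iris radius %.1f px, pupil radius %.1f px\n",
    x$center_x, x$center_y, x$iris_radius, x$pupil_radius))
  invisible(x)
}

assert_geometry <- function(geometry) {
  if (!inherits(geometry, "iris_geometry"))
    stop("`geometry` must be an `iris_geometry` object", call. = FALSE)
  invisible(geometry)
}

#' Sixteen-site sampling layout over an annotated iris
#'
#' Reproduces the quadrant-subdivision construction used for semiquantitative
#' TI scoring.  The bounding square of the iris circle is split by vertical
#' and horizontal lines through the centre into four quadrant squares of side
#' `iris_radius`; each quadrant is split into four equal sub-squares, and the
#' 16 sub-square centres are the sampling sites, i.e. offsets of
#' (±R/4 or ±3R/4, ±R/4 or ±3R/4) from the iris centre.  Each site carries a
#' sampling disk whose nominal radius is 75 px at the reference resolution,
#' rescaled in proportion to the annotated iris radius.  Sites whose disk has
#' no geometric overlap with the open iris annulus
#' (`pupil_radius < r < iris_radius`) are recorded as excluded: the four
#' corner sites can fall wholly outside the iris circle and the four inner
#' sites wholly inside the pupil (through which the bright retinal red reflex,
#' not iris melanin, is seen).
#'
#' @param geometry An [iris_geometry()].
#' @param scale_reference Iris radius, in pixels, at which the nominal 75 px
#'   disk applies.  The default of 1000 px corresponds to a typical
#'   hand-drawn iris circle on the native 3504 x 2336 slit-lamp frames; pass
#'   `scale_reference = geometry$iris_radius` to force the native 75 px disk.
#' @param disk_radius Optional explicit disk radius in pixels, overriding the
#'   scaled default.
#'
#' @return An object of class `sampling_layout` with elements `sites` (a
#'   data frame of the 16 nominal sites with their offsets and distances from
#'   the centre), `disk_radius`, and `excluded` (a data frame of excluded
#'   site indices with reasons, possibly empty).
#' @examples
#' g <- iris_geometry(0, 0, 100, 30)
#' sampling_layout(g, scale_reference = 100)
#' @export
sampling_layout <- function(geometry, scale_reference = 1000,
                            disk_radius = NULL) {
  assert_geometry(geometry)
  R <- geometry$iris_radius
  if (is.null(disk_radius)) {
    if (!is.numeric(scale_reference) || length(scale_reference) != 1L ||
        scale_reference <= 0)
      stop("`scale_reference` must be a single positive number", call. = FALSE)
    disk_radius <- 75 * R / scale_reference
  }
  if (!is.numeric(disk_radius) || length(disk_radius) != 1L || disk_radius <= 0)
    stop("`disk_radius` must be a single positive number", call. = FALSE)

  off <- c(-3, -1, 1, 3) / 4 * R
  grid <- expand.grid(dx = off, dy = off, KEEP.OUT.ATTRS = FALSE)
  d <- sqrt(grid$dx^2 + grid$dy^2)
  sites <- data.frame(
    site = seq_len(16L),
    x = geometry$center_x + grid$dx,
    y = geometry$center_y + grid$dy,
    dist = d
  )

  # A disk intersects the open annulus pupil < r < iris (circles concentric)
  # iff its nearest point lies inside the iris circle and its farthest point
  # lies outside the pupil circle.
  outside_iris <- d - disk_radius >= R
  inside_pupil <- d + disk_radius <= geometry$pupil_radius
  excluded <- data.frame(
    site = sites$site[outside_iris | inside_pupil],
    reason = c("outside iris", "inside pupil")[
      1L + inside_pupil[outside_iris | inside_pupil]]
  )

  structure(
    list(sites = sites, disk_radius = disk_radius, excluded = excluded,
         geometry = geometry),
    class = "sampling_layout"
  )
}

#' @export
print.sampling_layout <- function(x, ...) {
  cat(sprintf("sampling layout: 16 sites, disk radius %.2f px, %d excluded\n",
              x$disk_radius, nrow(x$excluded)))
  if (nrow(x$excluded) > 0)
    print(x$excluded, row.names = FALSE)
  invisible(x)
}
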