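# Shared fixtures, built in code.

# ti_image with a constant red annulus and configurable pupil/background
# levels (defaults mimic the renderer: bright pupil, dark background).
const_annulus_image <- function(value, geometry = iris_geometry(120, 120, 100, 30),
                                size = c(241, 241), pupil_red = 255,
                                background_red = 8, green = 30, blue = 24) {
  grid <- expand.grid(x = seq_len(size[2]) - 1, y = seq_len(size[1]) - 1)
  r <- matrix(sqrt((grid$x - geometry$center_x)^2 +
                     (grid$y - geometry$center_y)^2),
              nrow = size[1], byrow = TRUE)
  red <- matrix(background_red, size[1], size[2])
  red[r <= geometry$pupil_radius] <- pupil_red
  red[r > geometry$pupil_radius & r < geometry$iris_radius] <- value
  px <- array(0, dim = c(size[1], size[2], 3))
  px[, , 1] <- red
  px[, , 2] <- green
  px[, , 3] <- blue
  ti_image(px, geometry)
}

# long grade table from a participants x graders matrix (one image each)
grades_from_matrix <- function(M, eye = "OD", visit_month = 0) {
  participants <- if (is.null(rownames(M))) paste0("P", seq_len(nrow(M)))
  else rownames(M)
  graders <- if (is.null(colnames(M))) paste0("G", seq_len(ncol(M)))
  else colnames(M)
  g <- expand.grid(participant = participants, grader_id = graders,
                   stringsAsFactors = FALSE)
  g$eye <- eye
  g$visit_month <- visit_month
  g$image_index <- 1L
  g$grade <- M[cbind(match(g$participant, participants),
                     match(g$grader_id, graders))]
  g
}

# Dense-sampling oracle for "does this sampling disk overlap the open iris
# annulus": samples the disk boundary circle finely (the extremal points of
# the disk always lie there) plus an interior polar grid.
brute_force_disk_overlap <- function(site_x, site_y, disk_radius, geometry) {
  th <- seq(0, 2 * pi, length.out = 4097)[-1]
  px <- c(site_x + disk_radius * cos(th), site_x)
  py <- c(site_y + disk_radius * sin(th), site_y)
  for (f in seq(0.1, 0.9, by = 0.1)) {
    px <- c(px, site_x + f * disk_radius * cos(th[seq(1, 4096, by = 64)]))
    py <- c(py, site_y + f * disk_radius * sin(th[seq(1, 4096, by = 64)]))
  }
  r <- sqrt((px - geometry$center_x)^2 + (py - geometry$center_y)^2)
  any(r > geometry$pupil_radius & r < geometry$iris_radius)
}

# flat reference spectrum on the standard grid
flat_spectrum <- function(pr) {
  stats::setNames(rep(pr, 31), seq(400, 700, 10))
}
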