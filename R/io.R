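#' Write a synthetic bundle to disk
#'
#' Materialises a [generate_cohort()] bundle as the on-disk formats the
#' pipeline reads: 8-bit RGB PNG images under `images/`, a `geometry.csv`
#' sidecar (one row per image with its identifiers and circle model), and
#' CSV tables `grades.csv`, `spectra.csv` (long format), `hair.csv`,
#' `acuity.csv`, plus the generating truth as `truth.yaml` and a
#' `manifest.yaml` linking all outputs.  All tables are comma-separated
#' UTF-8 with a header row; eyes are coded OD/OS, visits as integer months.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "synthetic_bundle"))
    stop("`bundle` must be a `synthetic_bundle`", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  if (!is.null(bundle$images)) {
    imgdir <- file.path(dir, "images")
    dir.create(imgdir, showWarnings = FALSE)
    geo <- do.call(rbind, lapply(names(bundle$images), function(nm) {
      im <- bundle$images[[nm]]
      g <- im$geometry
      data.frame(image = paste0(nm, ".png"), participant = im$participant,
                 eye = im$eye, visit_month = im$visit_month,
                 image_index = im$image_index, center_x = g$center_x,
                 center_y = g$center_y, iris_radius = g$iris_radius,
                 pupil_radius = g$pupil_radius)
    }))
    for (nm in names(bundle$images))
      write_ti_image(bundle$images[[nm]], file.path(imgdir,
                                                    paste0(nm, ".png")))
    write_table(geo, file.path(dir, "geometry.csv"))
    files <- c(files, "geometry.csv", file.path("images", geo$image))
  }
  for (tbl in c("grades", "spectra", "hair", "acuity")) {
    if (!is.null(bundle[[tbl]])) {
      write_table(bundle[[tbl]], file.path(dir, paste0(tbl, ".csv")))
      files <- c(files, paste0(tbl, ".csv"))
    }
  }
  yaml::write_yaml(truth_as_list(bundle$truth), file.path(dir, "truth.yaml"))
  yaml::write_yaml(list(files = as.list(c(files, "truth.yaml")),
                        seed = bundle$truth$seed,
                        package_version = as.character(packageVersion("melaquant"))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

truth_as_list <- function(truth) {
  tr <- unclass(truth)
  tr$image_geometry <- unclass(tr$image_geometry)
  tr$fixed_visit_effects <- as.list(tr$fixed_visit_effects)
  tr$reflectometry_truth <- lapply(
    split(tr$reflectometry_truth, seq_len(nrow(tr$reflectometry_truth))),
    as.list)
  names(tr$reflectometry_truth) <- NULL
  tr$acuity_truth$visit_effects <- as.list(tr$acuity_truth$visit_effects)
  tr
}

# Deterministic CSV writing: fixed field order, no row names, no quoting of
# numbers, so identical inputs give byte-identical files.
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read pipeline input tables
#'
#' Readers for the standard CSV inputs: grade tables
#' (`participant,eye,visit_month,grader_id,image_index,grade`), long or wide
#' reflectance spectra, hair chemistry and acuity tables, and image geometry
#' sidecars.  Wide spectra have one column per wavelength (named e.g.
#' `pr_400` ... `pr_700` or plain `400` ... `700`) and are converted to the
#' long format used internally.
#'
#' @param path CSV file path.
#' @return A data frame (long format for spectra).
#' @export
read_grades <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  validate_grades(g)
  g
}

#' @rdname read_grades
#' @export
read_spectra <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"wavelength" %in% names(s)) {
    wl_cols <- grep("^(pr_)?[0-9]+$", names(s), value = TRUE)
    if (!length(wl_cols))
      stop("`", path, "` has neither a wavelength column nor wavelength-named ",
           "columns", call. = FALSE)
    id_cols <- setdiff(names(s), wl_cols)
    long <- do.call(rbind, lapply(wl_cols, function(cn) {
      data.frame(s[id_cols],
                 wavelength = as.numeric(sub("^pr_", "", cn)), pr = s[[cn]])
    }))
    s <- long[order(long$participant, long$visit_month, long$site,
                    long$replicate, long$wavelength), ]
    rownames(s) <- NULL
  }
  assert_spectra(s)
  s
}

#' @rdname read_grades
#' @export
read_geometry <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("image", "participant", "eye", "visit_month", "image_index",
                "center_x", "center_y", "iris_radius", "pupil_radius")
  missing <- setdiff(required, names(g))
  if (length(missing))
    stop("geometry table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  g
}

#' Read a directory of TI images with their geometry sidecar
#'
#' @param images_dir Directory containing the PNG files named in the
#'   geometry table.
#' @param geometry A geometry data frame from [read_geometry()] (or the path
#'   to one).
#' @return A named list of [ti_image()] objects.
#' @export
read_ti_images <- function(images_dir, geometry) {
  if (is.character(geometry)) geometry <- read_geometry(geometry)
  imgs <- lapply(seq_len(nrow(geometry)), function(i) {
    r <- geometry[i, ]
    read_ti_image(file.path(images_dir, r$image),
                  iris_geometry(r$center_x, r$center_y, r$iris_radius,
                                r$pupil_radius),
                  participant = r$participant, eye = r$eye,
                  visit_month = r$visit_month, image_index = r$image_index)
  })
  names(imgs) <- sub("\\.png$", "", geometry$image)
  imgs
}
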