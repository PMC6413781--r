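#' Melanin (M) index of a diffuse reflectance spectrum
#'
#' The M index summarises melanin content from percent reflectance (PR) in
#' the 640-670 nm band, where melanin dominates absorption and haemoglobin
#' contributes little:
#'
#' \deqn{E = \frac{(PR_{650} + PR_{660} + 0.5\,PR_{640} + 0.5\,PR_{670})/3}{100}}
#' \deqn{M = 100 \log_{10}(1/E)}
#'
#' so a perfect reflector (PR = 100 at all band wavelengths) has M = 0 and a
#' uniform 10% band reflectance has M = 100; multiplying the band
#' reflectances by 10 lowers M by exactly 100.  Wavelengths outside the band
#' do not enter the index.
#'
#' @param pr Percent reflectance values.  Either a numeric vector named by
#'   wavelength (nm), a numeric vector accompanied by `wavelengths`, or a
#'   data frame with columns `wavelength` and `pr`.
#' @param wavelengths Wavelength grid in nm when `pr` is an unnamed vector.
#'
#' @return The M index (dimensionless).
#' @examples
#' m_index(rep(100, 31), seq(400, 700, 10))  # 0
#' m_index(c(`640` = 10, `650` = 10, `660` = 10, `670` = 10))  # 100
#' @export
m_index <- function(pr, wavelengths = NULL) {
  if (is.data.frame(pr)) {
    wavelengths <- pr$wavelength
    pr <- pr$pr
  } else if (is.null(wavelengths)) {
    if (is.null(names(pr)))
      stop("supply `wavelengths` or name `pr` by wavelength", call. = FALSE)
    wavelengths <- as.numeric(names(pr))
  }
  band <- c(640, 650, 660, 670)
  idx <- match(band, wavelengths)
  if (anyNA(idx))
    stop("percent reflectance at 640, 650, 660 and 670 nm is required",
         call. = FALSE)
  p <- as.numeric(pr[idx])
  if (anyNA(p) || any(p < 0))
    stop("percent reflectance must be non-negative and non-missing",
         call. = FALSE)
  eqn <- ((p[2] + p[3] + 0.5 * p[1] + 0.5 * p[4]) / 3) / 100
  if (eqn <= 0)
    stop("non-positive reflectance at melanin wavelengths", call. = FALSE)
  100 * log10(1 / eqn)
}

wavelength_grid <- function() seq(400, 700, by = 10)

assert_spectra <- function(spectra) {
  required <- c("participant", "visit_month", "site", "replicate",
                "wavelength", "pr")
  missing <- setdiff(required, names(spectra))
  if (length(missing))
    stop("spectra table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(spectra$pr < 0, na.rm = TRUE))
    stop("percent reflectance must be >= 0", call. = FALSE)
  grid <- wavelength_grid()
  key <- with(spectra, paste(participant, visit_month, site, replicate))
  n_wl <- tapply(spectra$wavelength, key,
                 function(w) length(intersect(grid, w)))
  if (any(n_wl < length(grid)))
    stop("each replicate spectrum must cover the full 400-700 nm grid in ",
         "10 nm steps", call. = FALSE)
  invisible(spectra)
}

#' Per-site melanin index summaries
#'
#' Computes the M index of every replicate spectrum and aggregates within
#' participant x visit x site.  The default aggregates the per-replicate M
#' indices by their arithmetic mean (the M index being the analysed
#' quantity); `aggregate = "mean-spectrum"` instead averages the replicate
#' spectra wavelength-wise and takes the M index of the mean spectrum.
#'
#' @param spectra Long-format data frame with columns `participant`,
#'   `visit_month`, `site`, `replicate`, `wavelength`, `pr` (five replicates
#'   per site in the standard protocol; hair spectra are processed
#'   identically under site `"hair"`).
#' @param aggregate `"mean-m"` (default) or `"mean-spectrum"`.
#' @return Data frame with one row per participant x visit x site:
#'   `m_index` and `n_replicates`.
#' @export
summarize_site <- function(spectra, aggregate = c("mean-m", "mean-spectrum")) {
  aggregate <- match.arg(aggregate)
  assert_spectra(spectra)
  key_cols <- c("participant", "visit_month", "site")
  if (aggregate == "mean-m") {
    rep_m <- by(spectra, spectra[c(key_cols, "replicate")], function(d) {
      cbind(unique(d[c(key_cols, "replicate")]),
            m = m_index(d$pr, d$wavelength))
    }, simplify = FALSE)
    rep_m <- do.call(rbind, rep_m[!vapply(rep_m, is.null, logical(1))])
    out <- stats::aggregate(m ~ participant + visit_month + site, data = rep_m,
                     FUN = mean)
    n <- stats::aggregate(m ~ participant + visit_month + site, data = rep_m,
                   FUN = length)
  } else {
    mean_pr <- stats::aggregate(pr ~ participant + visit_month + site + wavelength,
                         data = spectra, FUN = mean)
    out <- by(mean_pr, mean_pr[key_cols], function(d) {
      cbind(unique(d[key_cols]), m = m_index(d$pr, d$wavelength))
    }, simplify = FALSE)
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    nrep <- stats::aggregate(replicate ~ participant + visit_month + site,
                      data = unique(spectra[c(key_cols, "replicate")]),
                      FUN = length)
    n <- data.frame(nrep[key_cols], m = nrep$replicate)
    out <- merge(out, setNames(n, c(key_cols, "n")), by = key_cols)
    names(out)[names(out) == "m"] <- "m_index"
    names(out)[names(out) == "n"] <- "n_replicates"
    out <- out[order(out$participant, out$visit_month, out$site), ]
    rownames(out) <- NULL
    return(out)
  }
  names(out)[names(out) == "m"] <- "m_index"
  out$n_replicates <- n$m
  out <- out[order(out$participant, out$visit_month, out$site), ]
  rownames(out) <- NULL
  out
}

#' Check spectrophotometer calibration references
#'
#' Sessions are bracketed by measurements of a standard white surface
#' (nominally 100% reflectance) and a standard light trap (nominally 0%).
#' This check flags sessions whose references deviate beyond tolerance at
#' any wavelength.
#'
#' @param white,dark Reference spectra: numeric vectors named by wavelength,
#'   vectors with a `wavelengths` attribute via [m_index()] conventions, or
#'   data frames with `wavelength` and `pr` columns.  Both must cover the
#'   full 400-700 nm grid.
#' @param tolerance Allowed absolute deviation in percentage points
#'   (default 2).
#' @return A list with `pass` (logical) and `deviations`, a data frame of
#'   out-of-tolerance wavelengths per reference (empty when passing).
#' @export
calibration_check <- function(white, dark, tolerance = 2) {
  as_spec <- function(x, label) {
    if (is.data.frame(x)) {
      wl <- x$wavelength; pr <- x$pr
    } else {
      if (is.null(names(x)))
        stop("`", label, "` must carry wavelengths (names or data frame)",
             call. = FALSE)
      wl <- as.numeric(names(x)); pr <- as.numeric(x)
    }
    grid <- wavelength_grid()
    idx <- match(grid, wl)
    if (anyNA(idx))
      stop("`", label, "` must cover the full 400-700 nm grid", call. = FALSE)
    data.frame(wavelength = grid, pr = pr[idx])
  }
  w <- as_spec(white, "white")
  d <- as_spec(dark, "dark")
  dev <- rbind(
    data.frame(reference = "white", wavelength = w$wavelength,
               deviation = w$pr - 100),
    data.frame(reference = "dark", wavelength = d$wavelength,
               deviation = d$pr - 0)
  )
  bad <- dev[abs(dev$deviation) > tolerance, , drop = FALSE]
  rownames(bad) <- NULL
  list(pass = nrow(bad) == 0L, deviations = bad, tolerance = tolerance)
}
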