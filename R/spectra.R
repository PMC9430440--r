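# Spectrum container and the synthetic FTIR generator: sums of Gaussian
# components on a wavenumber grid with polynomial baseline and white noise,
# the model class the fitting module assumes for the O-D stretch band.

GAUSS_AREA_CONST <- sqrt(pi / (4 * log(2))) # area = amplitude * fwhm * const

gauss_profile <- function(nu, center, fwhm, amplitude) {
  amplitude * exp(-4 * log(2) * (nu - center)^2 / fwhm^2)
}

#' Construct a spectrum
#'
#' @param wavenumber ascending numeric grid, cm^-1.
#' @param absorbance numeric, same length, absorbance units.
#' @param temperature optional temperature in Celsius (metadata).
#' @param wt_dmso optional DMSO mass percent (metadata).
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wavenumber, absorbance, temperature = NA_real_,
                     wt_dmso = NA_real_) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance lengths differ")
  }
  if (any(diff(wavenumber) <= 0)) stop("wavenumber grid must be strictly ascending")
  if (any(!is.finite(absorbance))) stop("absorbances must be finite")
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 temperature = temperature, wt_dmso = wt_dmso),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1", length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (!is.na(x$temperature)) cat(sprintf(", T=%g C", x$temperature))
  if (!is.na(x$wt_dmso)) cat(sprintf(", %g wt%% DMSO", x$wt_dmso))
  cat("\n")
  invisible(x)
}

#' Specification of a synthetic spectrum
#'
#' @param components data frame or matrix with columns `center` (cm^-1),
#'   `fwhm` (cm^-1, > 0), `amplitude` (>= 0); one row per Gaussian.
#' @param grid numeric `c(min, max, step)` in cm^-1.
#' @param noise_sd Gaussian noise standard deviation, absorbance units.
#' @param baseline numeric polynomial coefficients (constant first),
#'   evaluated on the wavenumber grid.
#' @param seed integer seed for the noise.
#' @return a `spectrum_spec` list.
#' @export
spectrum_spec <- function(components, grid = c(2300, 2700, 0.5),
                          noise_sd = 0, baseline = 0, seed = 1L) {
  components <- as.data.frame(components)
  stopifnot(all(c("center", "fwhm", "amplitude") %in% names(components)),
            all(components$fwhm > 0), all(components$amplitude >= 0),
            grid[1] < grid[2], grid[3] > 0, noise_sd >= 0)
  structure(list(components = components, grid = grid, noise_sd = noise_sd,
                 baseline = as.numeric(baseline), seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a synthetic spectrum
#'
#' Absorbance is the baseline polynomial plus a sum of Gaussians
#' `A exp(-4 ln2 (nu - nu0)^2 / FWHM^2)` plus i.i.d. Gaussian noise;
#' deterministic under the spec's seed.
#'
#' @param spec a [spectrum_spec()].
#' @param temperature,wt_dmso optional metadata stored on the result.
#' @return a [spectrum()].
#' @export
synth_spectrum <- function(spec, temperature = NA_real_, wt_dmso = NA_real_) {
  stopifnot(inherits(spec, "spectrum_spec"))
  nu <- seq(spec$grid[1], spec$grid[2], by = spec$grid[3])
  ab <- outer(nu, seq_along(spec$baseline) - 1, "^") %*% spec$baseline
  ab <- as.numeric(ab)
  for (k in seq_len(nrow(spec$components))) {
    cmp <- spec$components[k, ]
    ab <- ab + gauss_profile(nu, cmp$center, cmp$fwhm, cmp$amplitude)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    ab <- ab + stats::rnorm(length(nu), sd = spec$noise_sd)
  }
  spectrum(nu, ab, temperature = temperature, wt_dmso = wt_dmso)
}

#' Read a two-column spectrum CSV
#'
#' Expects columns `wavenumber`, `absorbance`; metadata may be carried in
#' leading comment lines `# temperature_C=...` and `# wt_dmso=...`.
#'
#' @param path CSV file path.
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- regmatches(meta_lines,
                    regexec(paste0(key, "\\s*=\\s*(-?[0-9.eE+]+)"), meta_lines))
    v <- unlist(lapply(m, function(x) if (length(x) >= 2) x[2] else NULL))
    if (length(v)) as.numeric(v[1]) else NA_real_
  }
  tab <- utils::read.csv(text = lines, comment.char = "#")
  spectrum(tab$wavenumber, tab$absorbance,
           temperature = get_meta("temperature_C"),
           wt_dmso = get_meta("wt_dmso"))
}

#' Write a spectrum CSV
#' @param spec a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.na(spec$temperature)) {
    writeLines(sprintf("# temperature_C=%g", spec$temperature), con)
  }
  if (!is.na(spec$wt_dmso)) {
    writeLines(sprintf("# wt_dmso=%g", spec$wt_dmso), con)
  }
  utils::write.csv(data.frame(wavenumber = spec$wavenumber,
                              absorbance = spec$absorbance),
                   con, row.names = FALSE)
  invisible(path)
}
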