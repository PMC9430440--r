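# Multi-Gaussian decomposition of O-D stretch FTIR spectra. The band is
# modelled as a sum of 3-4 Gaussian components plus a polynomial baseline,
# fitted by bounded trust-region least squares (Levenberg-Marquardt via
# minpack.lm) with deterministic jittered restarts. For ice-phase spectra
# three narrow components (a dominant peak and two phonon sidebands)
# suffice; DMSO mixtures need a fourth broad (~120 cm^-1) component from
# disordered first-shell water.

fit_param_names <- function(n_components, n_base) {
  c(as.vector(t(outer(seq_len(n_components), c("amp", "center", "fwhm"),
                      function(i, s) paste0(s, i)))),
    paste0("b", seq_len(n_base) - 1L))
}

fit_model <- function(par, nu, n_components, nu_ref) {
  y <- 0
  for (k in seq_len(n_components)) {
    off <- 3 * (k - 1)
    y <- y + gauss_profile(nu, par[off + 2], par[off + 3], par[off + 1])
  }
  base <- par[(3 * n_components + 1):length(par)]
  y + as.numeric(outer(nu - nu_ref, seq_along(base) - 1, "^") %*% base)
}

default_init <- function(nu, ab, n_components) {
  peak <- nu[which.max(ab)]
  amp <- max(ab)
  comps <- rbind(
    c(amp, peak, 30),
    c(0.3 * amp, peak - 60, 30),
    c(0.3 * amp, peak + 60, 30))
  if (n_components == 4L) {
    comps <- rbind(comps, c(0.3 * amp, 2470, 120))
  }
  comps
}

#' Fit a sum of Gaussians to a spectrum
#'
#' Bounded nonlinear least squares of `n_components` Gaussians plus a
#' polynomial baseline to the windowed spectrum. Amplitudes are constrained
#' non-negative, FWHMs to `[2, 400]` cm^-1 and centers to the window, which
#' prevents component swapping and unphysical solutions. The fit is
#' deterministic: the default initialization places the dominant component
#' at the global maximum, sidebands at -60/+60 cm^-1 and (for 4 components)
#' a broad component near 2470 cm^-1 with a 120 cm^-1 starting width, and
#' any restarts jitter it under a fixed seed.
#'
#' @param spec a [spectrum()].
#' @param n_components 3 or 4.
#' @param window `c(lo, hi)` in cm^-1; default 2300-2700 (the O-D stretch
#'   region).
#' @param init optional matrix of starting values, rows
#'   `(amplitude, center, fwhm)`.
#' @param baseline `"linear"` (default), `"constant"` or `"quadratic"`.
#' @param exclude_co2 drop the 2330-2370 cm^-1 band (residual CO2
#'   absorption) from the fit window.
#' @param max_restarts jittered restarts allowed after a failed attempt.
#' @param seed seed for the restart jitter.
#' @return a `gaussian_fit`: components (sorted by center, with closed-form
#'   areas), baseline coefficients, residual RMS, window.
#' @export
fit_gaussians <- function(spec, n_components = 4L, window = c(2300, 2700),
                          init = NULL,
                          baseline = c("linear", "constant", "quadratic"),
                          exclude_co2 = FALSE, max_restarts = 5L, seed = 1L) {
  stopifnot(inherits(spec, "spectrum"), n_components %in% c(3L, 4L))
  baseline <- match.arg(baseline)
  n_base <- switch(baseline, constant = 1L, linear = 2L, quadratic = 3L)
  use <- spec$wavenumber >= window[1] & spec$wavenumber <= window[2]
  if (exclude_co2) {
    use <- use & !(spec$wavenumber >= 2330 & spec$wavenumber <= 2370)
  }
  nu <- spec$wavenumber[use]; ab <- spec$absorbance[use]
  if (length(nu) < 3 * n_components + n_base + 1L) {
    stop("window contains too few points for the requested model")
  }
  nu_ref <- mean(window)
  comps0 <- if (is.null(init)) default_init(nu, ab, n_components) else
    as.matrix(init)
  if (nrow(comps0) != n_components) {
    stop("init must have one row per component")
  }
  comps0[, 2] <- pmin(pmax(comps0[, 2], window[1]), window[2])
  par0 <- c(t(comps0), rep(0, n_base))
  lower <- c(rep(c(0, window[1], 2), n_components), rep(-Inf, n_base))
  upper <- c(rep(c(Inf, window[2], 400), n_components), rep(Inf, n_base))
  resid_fn <- function(par) fit_model(par, nu, n_components, nu_ref) - ab

  run_fit <- function(par) {
    minpack.lm::nls.lm(par, lower, upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1024, ftol = 1e-12, ptol = 1e-12))
  }
  dev0 <- sum(resid_fn(par0)^2)
  set.seed(seed)
  best <- NULL
  par_try <- par0
  for (attempt in seq_len(max_restarts + 1L)) {
    fit <- tryCatch(run_fit(par_try), error = function(e) NULL)
    if (!is.null(fit)) {
      # info 1-4: converged; 5: iteration cap with tolerances already tiny,
      # accepted when the solution improved on the start (near-degenerate
      # components, e.g. a redundant 4th peak, stall the step criterion)
      ok <- (fit$info %in% 1:4 || (fit$info == 5L && fit$deviance < dev0)) &&
        all(is.finite(fit$par))
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (ok && fit$deviance <= dev0 + 1e-12) break
    }
    jitter <- stats::rnorm(length(par0), sd = c(
      rep(c(0.05 * max(ab), 10, 5), n_components), rep(0, n_base)))
    par_try <- pmin(pmax(par0 + jitter, lower + 1e-9),
                    ifelse(is.finite(upper), upper - 1e-9, par0 + abs(jitter)))
  }
  if (is.null(best)) {
    stop("Gaussian fit failed to converge after restarts")
  }
  if (!(best$info %in% 1:4 || (best$info == 5L && best$deviance < dev0))) {
    cond <- structure(
      class = c("hbmap_fit_error", "error", "condition"),
      list(message = sprintf(
        "Gaussian fit did not converge (info=%d, deviance=%.4g); best-so-far attached",
        best$info, best$deviance),
        call = sys.call(-1), best = best))
    stop(cond)
  }
  par <- best$par
  comp <- data.frame(
    amplitude = par[seq(1, by = 3, length.out = n_components)],
    center = par[seq(2, by = 3, length.out = n_components)],
    fwhm = par[seq(3, by = 3, length.out = n_components)])
  comp <- comp[order(comp$center), c("center", "fwhm", "amplitude")]
  rownames(comp) <- NULL
  comp$area <- comp$amplitude * comp$fwhm * GAUSS_AREA_CONST
  structure(list(
    components = comp,
    baseline = stats::setNames(par[(3 * n_components + 1):length(par)],
                               paste0("b", seq_len(n_base) - 1L)),
    baseline_ref = nu_ref,
    residual_rms = sqrt(best$deviance / length(nu)),
    window = window,
    n_points = length(nu)),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d components, window %g-%g cm^-1, RMS %.4g\n",
              nrow(x$components), x$window[1], x$window[2], x$residual_rms))
  print(format(x$components, digits = 5))
  invisible(x)
}

#' Evaluate a fitted model on a wavenumber grid
#' @param fit a `gaussian_fit`.
#' @param nu wavenumber grid, cm^-1.
#' @return fitted absorbance values.
#' @export
predict_gaussian_fit <- function(fit, nu) {
  y <- as.numeric(outer(nu - fit$baseline_ref,
                        seq_along(fit$baseline) - 1, "^") %*% fit$baseline)
  for (k in seq_len(nrow(fit$components))) {
    y <- y + gauss_profile(nu, fit$components$center[k],
                           fit$components$fwhm[k],
                           fit$components$amplitude[k])
  }
  y
}

#' Per-component peak metrics
#'
#' Areas use the Gaussian closed form
#' `area = amplitude * FWHM * sqrt(pi / (4 ln 2))`; area fractions are over
#' the components only (baseline excluded) and sum to 1.
#'
#' @param fit a `gaussian_fit`.
#' @return data frame `center`, `fwhm`, `amplitude`, `area`,
#'   `area_fraction`.
#' @export
peak_metrics <- function(fit) {
  comp <- fit$components
  comp$area_fraction <- comp$area / sum(comp$area)
  comp
}

#' Fit a temperature series of spectra
#'
#' Fits every spectrum, optionally warm-starting each fit from the previous
#' temperature's solution (`link = TRUE`), which keeps component identities
#' stable across the series; components are then labelled by their center
#' order. Input must be sorted by temperature; unsorted input is auto-sorted
#' with a warning. A failed single-temperature fit is recorded and the
#' series continues.
#'
#' @param spectra list of [spectrum()] objects with `temperature` metadata.
#' @param n_components 3 or 4.
#' @param link warm-start each fit from its neighbour's solution.
#' @param ... passed to [fit_gaussians()].
#' @return list with `fits` (per temperature, `NULL` on failure) and
#'   `trend` (data frame `temperature`, `component`, `center`, `fwhm`,
#'   `amplitude`, `area`).
#' @export
temperature_series <- function(spectra, n_components = 4L, link = TRUE, ...) {
  temps <- vapply(spectra, function(s) s$temperature, numeric(1))
  if (anyNA(temps)) stop("every spectrum needs temperature metadata")
  if (is.unsorted(temps)) {
    warning("spectra not sorted by temperature; auto-sorting")
    ord <- order(temps)
    spectra <- spectra[ord]; temps <- temps[ord]
  }
  fits <- vector("list", length(spectra))
  trend <- list()
  prev_init <- NULL
  for (i in seq_along(spectra)) {
    init <- if (link) prev_init else NULL
    fits[[i]] <- tryCatch(
      fit_gaussians(spectra[[i]], n_components, init = init, ...),
      error = function(e) {
        warning(sprintf("fit at T=%g C failed: %s", temps[i],
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(fits[[i]])) {
      cmp <- fits[[i]]$components
      prev_init <- as.matrix(cmp[, c("amplitude", "center", "fwhm")])
      trend[[length(trend) + 1L]] <- data.frame(
        temperature = temps[i], component = seq_len(nrow(cmp)),
        center = cmp$center, fwhm = cmp$fwhm,
        amplitude = cmp$amplitude, area = cmp$area)
    }
  }
  list(fits = fits, trend = do.call(rbind, trend))
}

#' Sharpness of a melting-type transition in a parameter trend
#'
#' Locates the transition as the temperature interval with the largest
#' absolute first difference of the tracked parameter, and scores its
#' sharpness as that maximum difference divided by the median absolute
#' difference over the rest of the series. A step change scores large; a
#' uniform linear drift scores about 1; a flat series is flagged as
#' undefined.
#'
#' @param temperature numeric, ascending, length >= 5.
#' @param value tracked parameter (a component's center, FWHM or area).
#' @param flat_tol differences below this (absolute) count as flat.
#' @return list `transition_temperature` (midpoint of the steepest
#'   interval), `sharpness`, `flat` (logical).
#' @export
transition_sharpness <- function(temperature, value, flat_tol = 1e-12) {
  stopifnot(length(temperature) >= 5, length(value) == length(temperature))
  if (is.unsorted(temperature)) stop("temperatures must be ascending")
  d <- abs(diff(value))
  if (all(d < flat_tol)) {
    return(list(transition_temperature = NA_real_, sharpness = NA_real_,
                flat = TRUE))
  }
  i <- which.max(d)
  others <- d[-i]
  list(transition_temperature = mean(temperature[c(i, i + 1L)]),
       sharpness = d[i] / max(stats::median(others), flat_tol),
       flat = FALSE)
}
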