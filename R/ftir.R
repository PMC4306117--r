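#' Absorbance spectrum container
#'
#' A mid-infrared absorbance spectrum on a strictly monotone wavenumber
#' grid, conventionally descending 4000 to 700 cm⁻¹ at 2 cm⁻¹ steps as
#' acquired by ATR-FTIR.
#'
#' @param wavenumbers Wavenumber grid in cm⁻¹, strictly monotone.
#' @param absorbance Absorbance values, same length, finite.
#' @return An object of class `ftir_spectrum` (a data frame).
#' @export
ftir_spectrum <- function(wavenumbers, absorbance) {
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have the same length")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance)))
    stop("spectrum contains non-finite values")
  structure(data.frame(wavenumber = wavenumbers, absorbance = absorbance),
            class = c("ftir_spectrum", "data.frame"))
}

#' Default spectral bands of the three plaque components
#'
#' Band table for the synthetic spectrum generator, centred on standard
#' mid-IR assignments: the lipid ester C=O stretch near 1745 cm⁻¹, the
#' collagen amide I band near 1655 cm⁻¹, and the phosphate ν3 band of
#' calcification (hydroxyapatite) near 1030 cm⁻¹.  Band areas are set from
#' the requested composition ratios with the collagen area as the unit.
#'
#' @param lip_col,calc_col Target lipid:collagen and
#'   calcification:collagen peak-area ratios.
#' @param collagen_area Absolute collagen band area
#'   (absorbance · cm⁻¹).
#' @return Data frame with columns `component`, `centre`, `fwhm`, `area`.
#' @export
default_bands <- function(lip_col = 1, calc_col = 1, collagen_area = 1) {
  data.frame(
    component = c("lipid", "collagen", "calcification"),
    centre = c(1745, 1655, 1030),
    fwhm = c(14, 20, 40),
    area = c(lip_col, 1, calc_col) * collagen_area)
}

#' Synthetic spectrum specification
#'
#' @param bands Data frame (`component`, `centre` cm⁻¹, `fwhm` cm⁻¹,
#'   `area` absorbance·cm⁻¹); see [default_bands()].  Centres must lie in
#'   the wavenumber range and areas must be non-negative.
#' @param wavenumber_range `c(high, low)` in cm⁻¹ (descending grid).
#' @param resolution Grid step, cm⁻¹ (default 2).
#' @param baseline `c(offset, slope)`; the baseline is
#'   `offset + slope * wavenumber`.
#' @param noise_sd Absorbance noise SD.
#' @param shape `"gaussian"` (default) or `"lorentzian"` band profiles.
#' @param seed RNG seed.
#' @return A list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(bands = default_bands(),
                          wavenumber_range = c(4000, 700), resolution = 2,
                          baseline = c(offset = 0.02, slope = 0),
                          noise_sd = 0, shape = c("gaussian", "lorentzian"),
                          seed = 1L) {
  shape <- match.arg(shape)
  lo <- min(wavenumber_range); hi <- max(wavenumber_range)
  stopifnot(resolution > 0, noise_sd >= 0,
            all(c("centre", "fwhm", "area") %in% names(bands)))
  if (any(bands$centre < lo) || any(bands$centre > hi))
    stop("all band centres must lie inside the wavenumber range")
  if (any(bands$area < 0)) stop("band areas must be non-negative")
  if (any(bands$fwhm <= 0)) stop("band widths must be positive")
  structure(list(bands = bands, wavenumber_range = c(hi, lo),
                 resolution = resolution,
                 baseline = c(offset = unname(baseline[1]),
                              slope = unname(baseline[2])),
                 noise_sd = noise_sd, shape = shape, seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a synthetic absorbance spectrum
#'
#' Absorbance = baseline + sum of band profiles + Gaussian noise, on a
#' descending wavenumber grid.  Band profiles are parameterised by total
#' area, so with zero noise the numerically integrated area of an isolated
#' band equals its specified area up to quadrature error.
#'
#' @param spec A [spectrum_spec()].
#' @return An [ftir_spectrum()].
#' @export
generate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  wn <- seq(spec$wavenumber_range[1], spec$wavenumber_range[2],
            by = -spec$resolution)
  ab <- spec$baseline[["offset"]] + spec$baseline[["slope"]] * wn
  for (b in seq_len(nrow(spec$bands))) {
    ctr <- spec$bands$centre[b]
    fwhm <- spec$bands$fwhm[b]
    area <- spec$bands$area[b]
    if (spec$shape == "gaussian") {
      s <- fwhm / (2 * sqrt(2 * log(2)))
      ab <- ab + area / (s * sqrt(2 * pi)) * exp(-0.5 * ((wn - ctr) / s)^2)
    } else {
      g <- fwhm / 2
      ab <- ab + area / pi * g / ((wn - ctr)^2 + g^2)
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    ab <- ab + rnorm(length(ab), sd = spec$noise_sd)
  }
  ftir_spectrum(wn, ab)
}

#' Band integration window
#'
#' @param component One of `"lipid"`, `"collagen"`, `"calcification"`.
#' @param low,high Window bounds in cm⁻¹, `700 <= low < high <= 4000`.
#' @param baseline_mode `"linear-endpoints"` (subtract the chord between
#'   the window's endpoint absorbances, common ATR practice) or `"none"`.
#' @return A list of class `band_window`.
#' @export
band_window <- function(component, low, high,
                        baseline_mode = c("linear-endpoints", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(low >= 700, high <= 4000, low < high)
  structure(list(component = component, low = low, high = high,
                 baseline_mode = baseline_mode),
            class = "band_window")
}

#' Default integration windows
#'
#' Windows around the standard assignments: lipid ester carbonyl
#' 1710--1770 cm⁻¹, collagen amide I 1600--1690 cm⁻¹, phosphate ν3
#' 960--1100 cm⁻¹.  These are configuration, not constants: instruments
#' and software differ in their exact limits.
#'
#' @param baseline_mode Passed to each [band_window()].
#' @return Named list of three [band_window()] objects.
#' @export
default_band_windows <- function(baseline_mode = "linear-endpoints") {
  list(lipid = band_window("lipid", 1710, 1770, baseline_mode),
       collagen = band_window("collagen", 1600, 1690, baseline_mode),
       calcification = band_window("calcification", 960, 1100, baseline_mode))
}

#' Baseline-corrected peak area over a window
#'
#' Trapezoidal integral of absorbance minus baseline over the window's
#' samples.  With `baseline_mode = "linear-endpoints"` the baseline is the
#' chord between the absorbances at the first and last samples inside the
#' window; with `"none"` the raw absorbance is integrated.  A negative net
#' area (noise below baseline) is floored at zero with a warning.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param window A [band_window()].
#' @return Peak area in absorbance · cm⁻¹.
#' @export
integrate_band <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "ftir_spectrum"), inherits(window, "band_window"))
  wn <- spectrum$wavenumber
  if (window$low < min(wn) || window$high > max(wn))
    stop(sprintf("window [%g, %g] lies outside the spectrum range [%g, %g]",
                 window$low, window$high, min(wn), max(wn)))
  keep <- wn >= window$low & wn <= window$high
  if (sum(keep) < 3L)
    stop("fewer than 3 samples inside the integration window")
  x <- wn[keep]; y <- spectrum$absorbance[keep]
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (window$baseline_mode == "linear-endpoints") {
    n <- length(x)
    chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    y <- y - chord
  }
  a <- pracma::trapz(x, y)
  if (a < 0) {
    warning("negative net band area floored at 0")
    a <- 0
  }
  a
}

#' Composition ratios of a single spectrum
#'
#' Lipid:collagen and calcification:collagen baseline-corrected peak-area
#' ratios for one measurement location.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param windows Named list with `lipid`, `collagen` and `calcification`
#'   [band_window()]s (default [default_band_windows()]).
#' @return An object of class `composition_ratios` with fields `lip_col`,
#'   `calc_col`, `n_locations` (= 1) and `per_location` (data frame).
#'   When the collagen area is zero both ratios are `NA` (flagged
#'   undefined) with a warning.
#' @export
composition_ratios <- function(spectrum, windows = default_band_windows()) {
  stopifnot(all(c("lipid", "collagen", "calcification") %in% names(windows)))
  a_lip <- integrate_band(spectrum, windows$lipid)
  a_col <- integrate_band(spectrum, windows$collagen)
  a_cal <- integrate_band(spectrum, windows$calcification)
  if (a_col == 0) {
    warning("collagen band area is zero: composition ratios undefined")
    lip_col <- calc_col <- NA_real_
  } else {
    lip_col <- a_lip / a_col
    calc_col <- a_cal / a_col
  }
  structure(list(lip_col = lip_col, calc_col = calc_col, n_locations = 1L,
                 per_location = data.frame(location = 1L, lip_col = lip_col,
                                           calc_col = calc_col)),
            class = "composition_ratios")
}

#' Average composition ratios over measurement locations
#'
#' Arithmetic mean of each ratio across locations (mean of ratios, not
#' ratio of mean areas); per-location values are retained for dispersion
#' reporting.
#'
#' @param ratios List of [composition_ratios()] objects, one per location.
#' @return A `composition_ratios` object with `n_locations` equal to the
#'   total number of locations.
#' @export
average_over_locations <- function(ratios) {
  if (length(ratios) == 0L) stop("no locations to average")
  stopifnot(all(vapply(ratios, inherits, logical(1), "composition_ratios")))
  per <- do.call(rbind, lapply(ratios, `[[`, "per_location"))
  per$location <- seq_len(nrow(per))
  structure(list(lip_col = mean(per$lip_col), calc_col = mean(per$calc_col),
                 n_locations = nrow(per), per_location = per),
            class = "composition_ratios")
}

#' @export
print.composition_ratios <- function(x, ...) {
  cat(sprintf("<composition_ratios> Lip:Col = %.4g, Calc:Col = %.4g (%d location%s)\n",
              x$lip_col, x$calc_col, x$n_locations,
              if (x$n_locations == 1L) "" else "s"))
  invisible(x)
}
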