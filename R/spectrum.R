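#' Spectrum container
#'
#' A vibrational spectrum: a strictly monotonic wavenumber grid (cm^-1) with
#' one intensity per grid point and free-form metadata (label, ion, dose).
#' Descending grids are silently reversed to the ascending canonical order;
#' duplicate wavenumbers and non-finite values are rejected.
#'
#' @param wavenumbers Numeric grid (cm^-1), strictly monotonic.
#' @param intensities Numeric, same length.
#' @param meta Named list of annotations.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(intensities) ||
      any(!is.finite(wavenumbers)) || any(!is.finite(intensities)))
    stop("spectrum contains non-finite values", call. = FALSE)
  d <- diff(wavenumbers)
  if (length(d) && all(d < 0)) {           # descending input: canonicalize
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
    d <- -rev(d)
  }
  if (any(d <= 0))
    stop("wavenumbers must be strictly monotonic without duplicates",
         call. = FALSE)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavenumbers)

# restrict to [lo, hi] (inclusive); errors if the result is empty
crop_spectrum <- function(spec, lo, hi) {
  keep <- spec$wavenumbers >= lo & spec$wavenumbers <= hi
  if (!any(keep))
    stop("coverage error: grid does not intersect [", lo, ", ", hi, "] cm^-1",
         call. = FALSE)
  spectrum(spec$wavenumbers[keep], spec$intensities[keep], spec$meta)
}

require_min_points <- function(spec, n, what) {
  if (length(spec$wavenumbers) < n)
    stop(what, " requires at least ", n, " grid points", call. = FALSE)
  invisible(spec)
}
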