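#' Uniform wavenumber grid
#'
#' Constructs the descending, evenly spaced wavenumber axis on which all
#' spectra in a [spectra_set()] live. FT-NIR instruments report an optical
#' resolution (here 16 cm-1) but store interferogram-zero-filled digital
#' points at half that interval, so the acquisition axis of 11,536--3952 cm-1
#' holds (11536 - 3952)/8 + 1 = 949 points at 8 cm-1 spacing.
#'
#' @param high Highest wavenumber (cm-1), inclusive.
#' @param low Lowest wavenumber (cm-1), inclusive; `high >= low`.
#' @param spacing Positive digital point spacing (cm-1). `(high - low)` must
#'   be an exact multiple of `spacing`.
#' @return An object of class `"nir_grid"`: a list with elements `high`,
#'   `low`, `spacing` and `points` (wavenumbers, strictly descending).
#' @examples
#' g <- nir_grid(11536, 3952, 8)
#' length(g$points)  # 949
#' @seealso [acquisition_grid()], [spectra_set()]
#' @export
nir_grid <- function(high, low, spacing) {
  stopifnot(is.numeric(high), is.numeric(low), is.numeric(spacing),
            length(high) == 1L, length(low) == 1L, length(spacing) == 1L)
  if (spacing <= 0)
    stop("grid spacing must be > 0, got ", spacing)
  if (high < low)
    stop("grid high (", high, ") must be >= low (", low, ")")
  k <- (high - low) / spacing
  if (abs(k - round(k)) > 1e-8)
    stop("grid range (", high, " - ", low, " = ", high - low,
         ") is not an integer multiple of spacing ", spacing)
  k <- round(k)
  points <- high - spacing * (0:k)
  structure(list(high = high, low = low, spacing = spacing, points = points),
            class = "nir_grid")
}

#' The full FT-NIR acquisition grid
#'
#' 11,536--3952 cm-1 at 8 cm-1 digital spacing: 949 points.
#' @return A [nir_grid()].
#' @export
acquisition_grid <- function() nir_grid(11536, 3952, 8)

#' @export
print.nir_grid <- function(x, ...) {
  cat(sprintf("<nir_grid> %g to %g cm-1, spacing %g cm-1 (%d points)\n",
              x$high, x$low, x$spacing, length(x$points)))
  invisible(x)
}

#' @export
length.nir_grid <- function(x) length(x$points)

#' Convert wavenumber (cm-1) to wavelength (nm) and back
#'
#' @param wavenumber Wavenumbers in cm-1.
#' @param nm Wavelengths in nm.
#' @return Numeric vector of the converted values.
#' @examples
#' wavenumber_to_nm(8230)  # ~1215 nm
#' @export
wavenumber_to_nm <- function(wavenumber) 1e7 / wavenumber

#' @rdname wavenumber_to_nm
#' @export
nm_to_wavenumber <- function(nm) 1e7 / nm
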