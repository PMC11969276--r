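#' Construct a UV-vis spectrum
#'
#' A spectrum is an absorbance trace on a strictly increasing wavelength
#' grid, the basic unit of spectrophotometric titration data.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param absorbance Numeric vector of absorbances (AU), same length as
#'   `wavelength`, all finite.
#' @return An object of class `uv_spectrum` with elements `wavelength`
#'   and `absorbance`.
#' @examples
#' s <- uv_spectrum(300:310, rep(0.5, 11))
#' s
#' @export
uv_spectrum <- function(wavelength, absorbance) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two wavelength points", call. = FALSE)
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have equal length", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbances must be finite", call. = FALSE)
  structure(list(wavelength = wavelength, absorbance = absorbance),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %d points, %.6g-%.6g nm, max A = %.4g\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$absorbance)))
  invisible(x)
}

#' @export
as.data.frame.uv_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

is_uv_spectrum <- function(x) inherits(x, "uv_spectrum")

same_grid <- function(a, b) {
  length(a$wavelength) == length(b$wavelength) &&
    all(a$wavelength == b$wavelength)
}

#' Bundle the four pure-species spectra of an acid pair
#'
#' The basis holds the spectra of the fully protonated and fully
#' deprotonated forms of both acids of a relative-acidity measurement,
#' each normalized to unit formal concentration of its parent acid and
#' all on one common wavelength grid.  Mixture spectra recorded during
#' the titration are modelled as non-negative linear combinations of
#' these four columns.
#'
#' @param s_ha,s_a Spectra of the neutral and anionic forms of the first
#'   acid (HA / A-), as [uv_spectrum] objects.
#' @param s_hb,s_b Spectra of the neutral and anionic forms of the
#'   second acid (HB / B-).
#' @return An object of class `species_basis`.
#' @seealso [unmix()], [resample_to_common_grid()]
#' @export
species_basis <- function(s_ha, s_a, s_hb, s_b) {
  sp <- list(s_ha = s_ha, s_a = s_a, s_hb = s_hb, s_b = s_b)
  if (!all(vapply(sp, is_uv_spectrum, logical(1))))
    stop("all four basis components must be uv_spectrum objects", call. = FALSE)
  for (nm in names(sp)[-1])
    if (!same_grid(sp$s_ha, sp[[nm]]))
      stop("basis spectra must share one wavelength grid", call. = FALSE)
  zero <- vapply(sp, function(s) all(s$absorbance == 0), logical(1))
  if (any(zero))
    stop("basis spectrum is identically zero: ",
         paste(names(sp)[zero], collapse = ", "), call. = FALSE)
  structure(sp, class = "species_basis")
}

#' @export
print.species_basis <- function(x, ...) {
  cat(sprintf("<species_basis> 4 spectra on %d-point grid (%.6g-%.6g nm)\n",
              length(x$s_ha$wavelength), min(x$s_ha$wavelength),
              max(x$s_ha$wavelength)))
  invisible(x)
}

# 4-column matrix view of a basis (columns HA, A, HB, B)
basis_matrix <- function(basis) {
  m <- cbind(HA = basis$s_ha$absorbance, A = basis$s_a$absorbance,
             HB = basis$s_hb$absorbance, B = basis$s_b$absorbance)
  m
}

#' Resample spectra onto a common wavelength grid
#'
#' Spectra registered on different instrument grids are linearly
#' interpolated onto the grid formed by all recorded wavelengths inside
#' the overlap of their ranges.  No extrapolation is performed: points
#' outside any spectrum's range are dropped.
#'
#' @param spectra A list of [uv_spectrum] objects with overlapping
#'   wavelength ranges.
#' @return A list of [uv_spectrum] objects sharing one grid.
#' @examples
#' a <- uv_spectrum(200:400, rep(1, 201))
#' b <- uv_spectrum(250:450, rep(2, 201))
#' out <- resample_to_common_grid(list(a, b))
#' range(out[[1]]$wavelength)  # 250 400
#' @export
resample_to_common_grid <- function(spectra) {
  if (!is.list(spectra) || !length(spectra) ||
      !all(vapply(spectra, is_uv_spectrum, logical(1))))
    stop("spectra must be a non-empty list of uv_spectrum objects",
         call. = FALSE)
  lo <- max(vapply(spectra, function(s) min(s$wavelength), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavelength), numeric(1)))
  if (lo > hi)
    stop("spectra have no overlapping wavelength range", call. = FALSE)
  grid <- sort(unique(unlist(lapply(spectra, `[[`, "wavelength"))))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L)
    stop("wavelength overlap contains fewer than two grid points",
         call. = FALSE)
  out <- lapply(spectra, function(s) {
    a <- stats::approx(s$wavelength, s$absorbance, xout = grid)$y
    uv_spectrum(grid, a)
  })
  names(out) <- names(spectra)
  out
}
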