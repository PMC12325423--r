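#' Scatter-band configuration
#'
#' Widths of the four excised scattering bands, as (above, below) extents in
#' nm around each band center along the emission axis: first/second-order
#' Rayleigh and first/second-order Raman. Defaults are +20/-10 (30 nm total),
#' +20/-15 (35 nm), +5/-15 (20 nm) and +10/-15 (25 nm). The Raman line is
#' placed by a constant wavenumber shift (default 3382 cm^-1, the water O-H
#' stretch convention of common EEM scatter-removal tools).
#'
#' @param rayleigh1,rayleigh2,raman1,raman2 lists with elements `enabled`,
#'   `above` (nm), `below` (nm).
#' @param raman_shift Raman shift in cm^-1, > 0.
#' @param interpolation gap-filling method: `"linear_emission"`,
#'   `"pchip_emission"` or `"none"`.
#' @return A list of class `"scatter_band_config"`.
#' @export
scatter_band_config <- function(
    rayleigh1 = list(enabled = TRUE, above = 20, below = 10),
    rayleigh2 = list(enabled = TRUE, above = 20, below = 15),
    raman1 = list(enabled = TRUE, above = 5, below = 15),
    raman2 = list(enabled = TRUE, above = 10, below = 15),
    raman_shift = 3382,
    interpolation = c("linear_emission", "pchip_emission", "none")) {
  interpolation <- match.arg(interpolation)
  bands <- list(rayleigh1 = rayleigh1, rayleigh2 = rayleigh2,
                raman1 = raman1, raman2 = raman2)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    stopifnot(is.list(b), all(c("enabled", "above", "below") %in% names(b)))
    if (b$above < 0 || b$below < 0)
      stop(sprintf("band %s: widths must be >= 0", nm), call. = FALSE)
  }
  if (raman_shift <= 0) stop("raman_shift must be > 0", call. = FALSE)
  structure(c(bands, list(raman_shift = raman_shift,
                          interpolation = interpolation)),
            class = "scatter_band_config")
}

#' Subtract a blank EEM
#'
#' Cellwise subtraction of the solvent blank surface from a sample surface.
#' The output mask is the union of the two input masks.
#'
#' @param sample,blank [eem()] objects on identical grids.
#' @param clip_negative if `TRUE`, negative differences are set to 0. Off by
#'   default: the non-negativity constraints of the PARAFAC fit absorb the
#'   small negatives that subtraction leaves.
#' @return The blank-subtracted [eem()].
#' @export
subtract_blank <- function(sample, blank, clip_negative = FALSE) {
  validate_eem(sample); validate_eem(blank)
  if (!same_grids(sample, blank))
    stop("sample and blank grids differ", call. = FALSE)
  x <- sample$x - blank$x
  if (clip_negative) x[x < 0] <- 0
  mask <- sample$mask | blank$mask
  x[mask] <- 0
  eem(ex = sample$ex, em = sample$em, x = x, mask = mask, meta = sample$meta)
}

#' Emission-axis centers of the four scattering lines
#'
#' For excitation wavelength `ex`, the elastic lines sit at `ex` (first-order
#' Rayleigh) and `2*ex` (second order); the Raman line is displaced by a
#' constant wavenumber shift, `raman1 = 1e7 / (1e7/ex - shift)` nm, with its
#' second order at twice that wavelength.
#'
#' @param ex excitation wavelength(s), nm, > 0.
#' @param raman_shift Raman shift, cm^-1.
#' @return A list with numeric elements `rayleigh1`, `rayleigh2`, `raman1`,
#'   `raman2` (nm, vectorised over `ex`).
#' @export
scatter_centers <- function(ex, raman_shift = 3382) {
  stopifnot(all(ex > 0))
  wn <- 1e7 / ex
  if (any(raman_shift >= wn))
    stop("raman_shift >= excitation wavenumber: Raman line undefined",
         call. = FALSE)
  raman1 <- 1e7 / (wn - raman_shift)
  list(rayleigh1 = ex, rayleigh2 = 2 * ex, raman1 = raman1, raman2 = 2 * raman1)
}

#' Build the scatter excision mask for an EEM
#'
#' Cell (j, k) is masked iff the emission wavelength at j falls inside
#' `[center - below, center + above]` of any enabled band evaluated at the
#' excitation wavelength at k. Bands lying entirely outside the emission grid
#' mask nothing.
#'
#' @param e an [eem()] object.
#' @param config a [scatter_band_config()].
#' @return Logical matrix, same shape as `e$x`.
#' @export
build_scatter_mask <- function(e, config = scatter_band_config()) {
  validate_eem(e)
  stopifnot(inherits(config, "scatter_band_config"))
  mask <- matrix(FALSE, length(e$em), length(e$ex))
  ctr <- scatter_centers(e$ex, config$raman_shift)
  for (nm in c("rayleigh1", "rayleigh2", "raman1", "raman2")) {
    b <- config[[nm]]
    if (!isTRUE(b$enabled)) next
    for (k in seq_along(e$ex)) {
      c0 <- ctr[[nm]][k]
      mask[e$em >= c0 - b$below & e$em <= c0 + b$above, k] <- TRUE
    }
  }
  mask
}

#' Interpolate over masked cells along the emission axis
#'
#' Fills excised cells column by column (one excitation wavelength at a time)
#' by interpolation over emission. Leading/trailing masked runs are filled
#' with the nearest unmasked value. Unmasked cells are returned unchanged;
#' the output has an all-`FALSE` mask.
#'
#' @param e an [eem()] with a mask.
#' @param method `"linear_emission"` (default) or `"pchip_emission"`
#'   (monotone Hermite).
#' @return The gap-filled [eem()]; columns with fewer than two unmasked
#'   points are zero-filled and listed in `meta$zero_filled_ex`.
#' @export
interpolate_gaps <- function(e, method = c("linear_emission", "pchip_emission")) {
  method <- match.arg(method)
  validate_eem(e)
  if (all(e$mask)) stop("EEM is fully masked; cannot interpolate", call. = FALSE)
  x <- e$x
  zero_cols <- numeric(0)
  for (k in seq_along(e$ex)) {
    mk <- e$mask[, k]
    if (!any(mk)) next
    ok <- which(!mk)
    if (length(ok) < 2L) {
      x[, k] <- 0
      zero_cols <- c(zero_cols, e$ex[k])
      next
    }
    xi <- e$em[ok]; yi <- x[ok, k]
    bad <- which(mk)
    fill <- if (method == "linear_emission") {
      stats::approx(xi, yi, xout = e$em[bad], rule = 2)$y
    } else {
      f <- stats::splinefun(xi, yi, method = "monoH.FC")
      v <- f(e$em[bad])
      # nearest-value extension outside the unmasked range
      v[e$em[bad] < min(xi)] <- yi[which.min(xi)]
      v[e$em[bad] > max(xi)] <- yi[which.max(xi)]
      v
    }
    x[bad, k] <- fill
  }
  meta <- e$meta
  if (length(zero_cols)) meta$zero_filled_ex <- zero_cols
  eem(ex = e$ex, em = e$em, x = x,
      mask = matrix(FALSE, nrow(x), ncol(x)), meta = meta)
}

#' Residual scatter level inside the excision bands
#'
#' Measures how much signal remains in the (former) scatter bands of a
#' processed EEM, as the maximum absolute deviation of band cells from the
#' background obtained by interpolating across the bands from the
#' surrounding cells. A well-processed surface gives a level near 0; an
#' untouched ridge gives a level on the order of the ridge height.
#'
#' @param e a processed [eem()] (no masked cells expected).
#' @param config a [scatter_band_config()].
#' @return Maximum absolute deviation (AU) over band cells; 0 if no band
#'   cell intersects the grid.
#' @export
residual_scatter_level <- function(e, config = scatter_band_config()) {
  validate_eem(e)
  band <- build_scatter_mask(e, config)
  if (!any(band)) return(0)
  tmp <- eem(ex = e$ex, em = e$em, x = e$x, mask = band, meta = e$meta)
  bg <- interpolate_gaps(tmp, method = "linear_emission")
  max(abs(e$x[band] - bg$x[band]))
}

#' Preprocess one EEM surface
#'
#' The standard order used throughout the analysis: blank subtraction first
#' (subtraction alone does not remove sample scattering), then scatter-band
#' excision, then gap interpolation along emission. Optionally, cells below
#' the first-order Rayleigh line (emission shorter than excitation minus the
#' band's lower width), which carry no fluorescence, are zeroed.
#'
#' @param sample the measured [eem()].
#' @param blank the blank [eem()], or `NULL` to skip subtraction.
#' @param config a [scatter_band_config()].
#' @param clip_negative passed to [subtract_blank()].
#' @param zero_below_rayleigh zero the physically meaningless region below
#'   the first-order Rayleigh line (default `TRUE`).
#' @return The processed [eem()] (no masked cells, all values finite).
#' @export
preprocess_eem <- function(sample, blank = NULL,
                           config = scatter_band_config(),
                           clip_negative = FALSE,
                           zero_below_rayleigh = TRUE) {
  e <- if (is.null(blank)) sample else
    subtract_blank(sample, blank, clip_negative = clip_negative)
  band <- build_scatter_mask(e, config)
  e2 <- eem(ex = e$ex, em = e$em, x = e$x, mask = e$mask | band, meta = e$meta)
  out <- if (config$interpolation == "none") {
    x <- e2$x; x[e2$mask] <- 0
    eem(ex = e$ex, em = e$em, x = x,
        mask = matrix(FALSE, nrow(x), ncol(x)), meta = e$meta)
  } else {
    interpolate_gaps(e2, method = config$interpolation)
  }
  if (zero_below_rayleigh) {
    below <- config$rayleigh1$below
    for (k in seq_along(out$ex))
      out$x[out$em < out$ex[k] - below, k] <- 0
  }
  out
}
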