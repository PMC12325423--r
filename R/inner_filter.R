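#' Build a dilution curve at one wavelength pair
#'
#' Extracts fluorescence intensity as a function of dilution factor for one
#' source sample, read at the grid cell nearest to the requested
#' (excitation, emission) pair — no interpolation, to stay on measured cells.
#' With `pair = "peak"` the cell is the intensity argmax of the most dilute
#' EEM (where inner filter effects are weakest).
#'
#' @param eems list of [eem()] objects for one source, any order.
#' @param DFs numeric dilution factors, one per EEM.
#' @param pair numeric `c(ex, em)` in nm, or `"peak"`.
#' @param source_id identifier stored on the curve.
#' @return A list of class `"dilution_curve"`: `source_id`, `ex`, `em`,
#'   `points` (data.frame `DF`, `intensity`, DF increasing).
#' @export
build_dilution_curve <- function(eems, DFs, pair = "peak", source_id = "source") {
  stopifnot(is.list(eems), length(eems) == length(DFs))
  if (length(eems) < 2L)
    stop("at least two dilutions are required for a dilution curve",
         call. = FALSE)
  lapply(eems, validate_eem)
  ord <- order(DFs)
  eems <- eems[ord]; DFs <- DFs[ord]
  if (any(diff(DFs) <= 0))
    stop("dilution factors must be distinct", call. = FALSE)
  ref <- eems[[1L]]  # most dilute
  if (identical(pair, "peak")) {
    idx <- arrayInd(which.max(ref$x), dim(ref$x))
    pair <- c(ref$ex[idx[2L]], ref$em[idx[1L]])
  }
  stopifnot(is.numeric(pair), length(pair) == 2L)
  k <- which.min(abs(ref$ex - pair[1L]))
  j <- which.min(abs(ref$em - pair[2L]))
  intensity <- vapply(eems, function(e) {
    if (!same_grids(e, ref)) stop("EEM grids differ within one source",
                                  call. = FALSE)
    e$x[j, k]
  }, numeric(1))
  structure(list(source_id = source_id, ex = ref$ex[k], em = ref$em[j],
                 points = data.frame(DF = DFs, intensity = intensity)),
            class = "dilution_curve")
}

#' Detect inner filter effects on a dilution curve
#'
#' In the thin (low-absorbance) limit fluorescence is proportional to DF; a
#' curve whose maximum falls short of the most concentrated point signals
#' inner-filter attenuation. The curve is flagged when its maximum does not
#' sit at the largest DF and the intensity at the largest DF has dropped more
#' than `drop_tol` below that maximum.
#'
#' @param curve a [build_dilution_curve()] result.
#' @param drop_tol fractional drop below the maximum required to flag
#'   (default 0.05); guards against flagging noise on flat-topped curves.
#' @return List: `flag` (logical), `peak_DF` (DF of the curve maximum),
#'   `linear_range_max_DF` (largest DF up to which intensity/DF stays within
#'   `drop_tol` of its small-DF limit, `NA` if even the first ratio pair
#'   deviates).
#' @export
detect_inner_filter <- function(curve, drop_tol = 0.05) {
  stopifnot(inherits(curve, "dilution_curve"), drop_tol > 0)
  pts <- curve$points
  y <- pts$intensity; d <- pts$DF; n <- length(y)
  if (all(y == 0)) stop("dilution curve carries no signal", call. = FALSE)
  imax <- which.max(y)
  flag <- (imax < n) && (y[n] < (1 - drop_tol) * y[imax])
  ratio <- y / d
  within <- abs(ratio / ratio[1L] - 1) <= drop_tol
  m <- if (within[1L]) max(which(cumall(within))) else NA_integer_
  list(flag = flag,
       peak_DF = d[imax],
       linear_range_max_DF = if (is.na(m)) NA_real_ else d[m])
}

cumall <- function(x) cumsum(!x) == 0

#' Thin-limit sample selection for PARAFAC
#'
#' The trilinear model assumes fluorescence proportional to concentration,
#' which holds only for sufficiently diluted samples. Records with
#' `DF <= threshold` are kept; named overrides are kept regardless and tagged
#' as such, since measured curves may show individual samples to be linear
#' beyond the blanket threshold.
#'
#' @param records data.frame with `sample_id` and `DF` columns.
#' @param threshold DF cutoff (default 0.0025).
#' @param overrides character vector of sample_ids to keep regardless of DF.
#' @return List with `included` (subset of `records`, input order preserved)
#'   and `report` (data.frame: sample_id, DF, decision, reason).
#' @export
select_thin_limit <- function(records, threshold = 0.0025,
                              overrides = character(0)) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "DF") %in% names(records)))
  keep_thr <- records$DF <= threshold
  keep_ovr <- records$sample_id %in% overrides
  keep <- keep_thr | keep_ovr
  decision <- ifelse(keep, "included", "excluded")
  reason <- ifelse(keep_ovr, "override",
                   ifelse(keep_thr, sprintf("DF <= %g", threshold),
                          sprintf("DF > %g", threshold)))
  report <- data.frame(sample_id = records$sample_id, DF = records$DF,
                       decision = decision, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(keep))
    warning("thin-limit selection kept no samples", call. = FALSE)
  list(included = records[keep, , drop = FALSE], report = report)
}
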