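#' Construct an excitation-emission matrix (EEM)
#'
#' An EEM holds one fluorescence surface on rectangular wavelength grids:
#' intensity is indexed `[emission, excitation]` in arbitrary fluorometer
#' units (AU). Cells excised from the surface (e.g. scatter bands) are
#' recorded in a logical mask, `TRUE` = missing.
#'
#' @param ex numeric vector of excitation wavelengths (nm), strictly
#'   increasing.
#' @param em numeric vector of emission wavelengths (nm), strictly increasing.
#' @param x intensity matrix, `length(em)` rows by `length(ex)` columns.
#' @param mask logical matrix of the same shape as `x`; `TRUE` marks excised
#'   or missing cells. Defaults to all-`FALSE`.
#' @param meta named list of free-form annotations.
#' @return An object of class `"eem"`: a list with elements `ex`, `em`, `x`,
#'   `mask`, `meta`.
#' @examples
#' e <- eem(ex = c(250, 260), em = c(300, 310, 320),
#'          x = matrix(1:6, nrow = 3))
#' dim(e$x)
#' @export
eem <- function(ex, em, x, mask = NULL, meta = list()) {
  ex <- as.numeric(ex)
  em <- as.numeric(em)
  x <- as.matrix(x)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(x), ncol(x))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  obj <- structure(list(ex = ex, em = em, x = x, mask = mask, meta = meta),
                   class = "eem")
  validate_eem(obj)
  obj
}

validate_eem <- function(e) {
  stopifnot(inherits(e, "eem"))
  if (length(e$ex) < 1L || length(e$em) < 1L)
    stop("EEM grids must be non-empty", call. = FALSE)
  if (any(diff(e$ex) <= 0))
    stop("excitation grid must be strictly increasing", call. = FALSE)
  if (any(diff(e$em) <= 0))
    stop("emission grid must be strictly increasing", call. = FALSE)
  if (!all(dim(e$x) == c(length(e$em), length(e$ex))))
    stop("intensity must be length(em) x length(ex)", call. = FALSE)
  if (!all(dim(e$mask) == dim(e$x)))
    stop("mask must have the same shape as intensity", call. = FALSE)
  if (any(!is.finite(e$x[!e$mask])))
    stop("intensities must be finite where unmasked", call. = FALSE)
  invisible(e)
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d em x %d ex  (em %g-%g nm, ex %g-%g nm), %d masked cell(s)\n",
              length(x$em), length(x$ex), min(x$em), max(x$em),
              min(x$ex), max(x$ex), sum(x$mask)))
  invisible(x)
}

same_grids <- function(a, b) {
  length(a$ex) == length(b$ex) && length(a$em) == length(b$em) &&
    all(a$ex == b$ex) && all(a$em == b$em)
}

#' Dilution factor from volumes
#'
#' The dilution factor DF = c/c0 = V0 / (V0 + Vsolvent) is the concentration
#' fraction remaining after adding solvent to an initial sample volume. It is
#' used as the concentration proxy throughout the dilution-series analysis
#' (distinct from the dilution *ratio* V0/Vsolvent).
#'
#' @param V0 initial sample volume (any volume unit, e.g. uL), > 0.
#' @param V_solvent added solvent volume in the same unit, >= 0.
#' @return DF, dimensionless, in (0, 1].
#' @examples
#' dilution_factor(1, 799)   # 1:800 dilution -> 1.25e-3
#' @export
dilution_factor <- function(V0, V_solvent) {
  if (!is.numeric(V0) || !is.numeric(V_solvent))
    stop("volumes must be numeric", call. = FALSE)
  if (any(V0 <= 0)) stop("V0 must be positive", call. = FALSE)
  if (any(V_solvent < 0)) stop("V_solvent must be non-negative", call. = FALSE)
  V0 / (V0 + V_solvent)
}

#' Parse a "1:N" dilution label
#'
#' Labels follow the initial-to-total-volume convention, so `"1:N"` means
#' DF = 1/N (e.g. `"1:200"` is DF = 0.005). This convention reproduces every
#' printed DF in the study exactly; the alternative V0:Vsolvent reading would
#' give 1/(N+1).
#'
#' @param label character scalar of the form `"1:N"` with integer N >= 1.
#' @return DF = 1/N.
#' @examples
#' parse_dilution_label("1:6400")  # 1.5625e-4
#' @export
parse_dilution_label <- function(label) {
  if (!is.character(label) || length(label) != 1L)
    stop("label must be a single string", call. = FALSE)
  if (!grepl("^1:[0-9]+$", label))
    stop(sprintf("malformed dilution label '%s' (expected \"1:N\")", label),
         call. = FALSE)
  n <- as.numeric(sub("^1:", "", label))
  if (n < 1) stop("N must be >= 1", call. = FALSE)
  1 / n
}

#' Serial dilution schedule
#'
#' Builds the ordered list of (label, DF) pairs for a geometric serial
#' dilution starting at `start_label` and multiplying N by `step_factor`.
#'
#' @param start_label starting label, e.g. `"1:100"`.
#' @param step_factor integer >= 2, dilution step between consecutive levels.
#' @param n number of levels, >= 1.
#' @return data.frame with columns `label` (character) and `DF` (numeric,
#'   strictly decreasing).
#' @examples
#' serial_dilution_schedule("1:100", 2, 7)  # 1:100 ... 1:6400
#' @export
serial_dilution_schedule <- function(start_label, step_factor, n) {
  stopifnot(n >= 1, step_factor >= 2)
  n0 <- 1 / parse_dilution_label(start_label)
  ns <- n0 * step_factor^(seq_len(n) - 1)
  labels <- sprintf("1:%d", as.integer(round(ns)))
  data.frame(label = labels, DF = 1 / ns, stringsAsFactors = FALSE)
}

#' Resolve sample records from a manifest table
#'
#' Each row describes one measured EEM. The dilution factor must come from
#' exactly one source per row: explicit `DF`, a `dilution_label`, or the
#' volume pair (`V0_uL`, `Vsolvent_uL`).
#'
#' @param manifest data.frame with columns `sample_id` plus any of `species`,
#'   `condition`, `source_pool_id`, `blank_id`, `eem_path`, and one DF source.
#' @return The manifest with a resolved numeric `DF` column and a `df_source`
#'   column naming which field supplied it.
#' @export
sample_records <- function(manifest) {
  stopifnot(is.data.frame(manifest), "sample_id" %in% names(manifest))
  if (anyDuplicated(manifest$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  if ("df_source" %in% names(manifest)) {  # already resolved: idempotent
    if (!all(is.finite(manifest$DF) & manifest$DF > 0 & manifest$DF <= 1))
      stop("resolved DF values must be in (0, 1]", call. = FALSE)
    return(manifest)
  }
  n <- nrow(manifest)
  get_col <- function(nm) if (nm %in% names(manifest)) manifest[[nm]] else rep(NA, n)
  df_expl <- suppressWarnings(as.numeric(get_col("DF")))
  lab <- as.character(get_col("dilution_label"))
  v0 <- suppressWarnings(as.numeric(get_col("V0_uL")))
  vs <- suppressWarnings(as.numeric(get_col("Vsolvent_uL")))
  DF <- numeric(n)
  src <- character(n)
  for (i in seq_len(n)) {
    has <- c(explicit = is.finite(df_expl[i]),
             label = !is.na(lab[i]) && nzchar(lab[i]),
             volumes = is.finite(v0[i]) && is.finite(vs[i]))
    if (sum(has) != 1L)
      stop(sprintf("sample '%s': exactly one DF source required (got %d)",
                   manifest$sample_id[i], sum(has)), call. = FALSE)
    if (has[["explicit"]]) {
      DF[i] <- df_expl[i]; src[i] <- "explicit"
    } else if (has[["label"]]) {
      DF[i] <- parse_dilution_label(lab[i]); src[i] <- "label"
    } else {
      DF[i] <- dilution_factor(v0[i], vs[i]); src[i] <- "volumes"
    }
    if (!(DF[i] > 0 && DF[i] <= 1))
      stop(sprintf("sample '%s': DF must be in (0, 1]", manifest$sample_id[i]),
           call. = FALSE)
  }
  manifest$DF <- DF
  manifest$df_source <- src
  manifest
}

#' Read an EEM from a delimited matrix file
#'
#' Default dialect: cell (1,1) empty, header row holds excitation wavelengths
#' (nm), first column holds emission wavelengths (nm). The transposed dialect
#' swaps the roles. Empty fields are the sentinel for masked (excised) cells.
#'
#' @param path file path.
#' @param dialect `"standard"` (rows = emission) or `"transposed"`.
#' @param sep field separator; `","` by default.
#' @return An [eem()] object.
#' @export
read_eem <- function(path, dialect = c("standard", "transposed"), sep = ",") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("EEM file has fewer than 2 rows", call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol0 <- length(cells[[1L]])
  num <- function(s, row, col) {
    s <- trimws(s)
    if (!nzchar(s)) return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                   s, row, col, path), call. = FALSE)
    v
  }
  header <- vapply(seq_len(ncol0 - 1L), function(j)
    num(cells[[1L]][j + 1L], 1L, j + 1L), numeric(1))
  nr <- length(cells) - 1L
  rowwl <- numeric(nr)
  mat <- matrix(NA_real_, nr, ncol0 - 1L)
  for (i in seq_len(nr)) {
    row <- cells[[i + 1L]]
    # trailing empty fields may be dropped by strsplit; pad
    if (length(row) < ncol0) row <- c(row, rep("", ncol0 - length(row)))
    if (length(row) != ncol0)
      stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                   i + 1L, path, length(row), ncol0), call. = FALSE)
    rowwl[i] <- num(row[1L], i + 1L, 1L)
    for (j in seq_len(ncol0 - 1L)) mat[i, j] <- num(row[j + 1L], i + 1L, j + 1L)
  }
  if (any(is.na(rowwl)) || any(diff(rowwl) <= 0))
    stop(sprintf("first-column wavelength grid of %s is not strictly increasing",
                 path), call. = FALSE)
  if (any(is.na(header)) || any(diff(header) <= 0))
    stop(sprintf("header wavelength grid of %s is not strictly increasing",
                 path), call. = FALSE)
  mask <- is.na(mat)
  mat[mask] <- 0
  if (dialect == "standard") {
    eem(ex = header, em = rowwl, x = mat, mask = mask)
  } else {
    eem(ex = rowwl, em = header, x = t(mat), mask = t(mask))
  }
}

#' Write an EEM to a delimited matrix file
#'
#' Inverse of [read_eem()]: numbers are written with full precision
#' (`%.17g`), so a write-then-read round trip reproduces grids and unmasked
#' intensities exactly. Masked cells are written as empty fields.
#'
#' @param e an [eem()] object.
#' @param path output file path.
#' @param dialect `"standard"` or `"transposed"`.
#' @param sep field separator.
#' @export
write_eem <- function(e, path, dialect = c("standard", "transposed"), sep = ",") {
  dialect <- match.arg(dialect)
  validate_eem(e)
  fmt <- function(v) sprintf("%.17g", v)
  if (dialect == "standard") {
    rows <- e$em; cols <- e$ex; m <- e$x; msk <- e$mask
  } else {
    rows <- e$ex; cols <- e$em; m <- t(e$x); msk <- t(e$mask)
  }
  out <- character(length(rows) + 1L)
  out[1L] <- paste(c("", fmt(cols)), collapse = sep)
  for (i in seq_along(rows)) {
    vals <- fmt(m[i, ])
    vals[msk[i, ]] <- ""
    out[i + 1L] <- paste(c(fmt(rows[i]), vals), collapse = sep)
  }
  writeLines(out, path)
  invisible(path)
}

#' Stack EEMs into a three-way tensor
#'
#' Aligns a list of EEMs sharing wavelength grids into the samples x emission
#' x excitation array consumed by the PARAFAC fit. With `regrid = TRUE`,
#' surfaces measured on different grids are bilinearly interpolated onto the
#' intersection grid (the first EEM's wavelengths restricted to the range
#' covered by every input); interpolation never extrapolates.
#'
#' @param eems list of [eem()] objects, same length as `records`.
#' @param records data.frame of sample records (see [sample_records()]).
#' @param regrid if `TRUE`, interpolate all EEMs onto a common grid; if
#'   `FALSE` (default) a grid mismatch is an error.
#' @return An object of class `"eem_tensor"`: list with `values` (I x J x K
#'   array), `mask` (logical array), `em`, `ex`, `samples`.
#' @export
stack_eems <- function(eems, records, regrid = FALSE) {
  stopifnot(is.list(eems), length(eems) >= 1L)
  if (!is.data.frame(records) || nrow(records) != length(eems))
    stop("records must have one row per EEM", call. = FALSE)
  lapply(eems, validate_eem)
  ref <- eems[[1L]]
  if (!all(vapply(eems, same_grids, logical(1), b = ref))) {
    if (!regrid)
      stop("EEM grids differ; set regrid = TRUE to interpolate onto a common grid",
           call. = FALSE)
    ex_lo <- max(vapply(eems, function(e) min(e$ex), numeric(1)))
    ex_hi <- min(vapply(eems, function(e) max(e$ex), numeric(1)))
    em_lo <- max(vapply(eems, function(e) min(e$em), numeric(1)))
    em_hi <- min(vapply(eems, function(e) max(e$em), numeric(1)))
    ex_t <- ref$ex[ref$ex >= ex_lo & ref$ex <= ex_hi]
    em_t <- ref$em[ref$em >= em_lo & ref$em <= em_hi]
    if (length(ex_t) < 1L || length(em_t) < 1L)
      stop("no common wavelength range to regrid onto", call. = FALSE)
    eems <- lapply(eems, regrid_eem, ex_t = ex_t, em_t = em_t)
    ref <- eems[[1L]]
  }
  I <- length(eems); J <- length(ref$em); K <- length(ref$ex)
  values <- array(0, dim = c(I, J, K))
  mask <- array(FALSE, dim = c(I, J, K))
  for (i in seq_len(I)) {
    values[i, , ] <- eems[[i]]$x
    mask[i, , ] <- eems[[i]]$mask
  }
  structure(list(values = values, mask = mask,
                 em = ref$em, ex = ref$ex, samples = records),
            class = "eem_tensor")
}

# bilinear regrid via successive 1-D linear interpolation; target grid must
# lie inside the source range (no extrapolation by construction)
regrid_eem <- function(e, ex_t, em_t) {
  x <- e$x
  x[e$mask] <- NA_real_
  tmp <- matrix(NA_real_, length(em_t), ncol(x))
  for (k in seq_len(ncol(x))) {
    ok <- !is.na(x[, k])
    tmp[, k] <- if (sum(ok) >= 2L)
      stats::approx(e$em[ok], x[ok, k], xout = em_t, rule = 1)$y
    else NA_real_
  }
  out <- matrix(NA_real_, length(em_t), length(ex_t))
  for (j in seq_len(length(em_t))) {
    ok <- !is.na(tmp[j, ])
    out[j, ] <- if (sum(ok) >= 2L)
      stats::approx(e$ex[ok], tmp[j, ok], xout = ex_t, rule = 1)$y
    else NA_real_
  }
  mask <- is.na(out)
  out[mask] <- 0
  eem(ex = ex_t, em = em_t, x = out, mask = mask, meta = e$meta)
}

#' @export
print.eem_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<eem_tensor> %d sample(s) x %d em x %d ex\n", d[1], d[2], d[3]))
  invisible(x)
}
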