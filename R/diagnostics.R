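#' Moving-window discrepancy maps between modeled and observed tensors
#'
#' Zero-dimensional fit indicators (RSS, core consistency) cannot localise
#' where on the excitation-emission plane a PARAFAC model fails. This routine
#' pools the residual (modeled minus observed) over samples and, for each
#' grid cell, computes local bias, population standard deviation and RMSE
#' over a 2-D moving window of all cells within +/- `window_fraction` of the
#' cell's emission and excitation wavelengths (a wavelength-proportional
#' window, truncated at grid edges). With population SD the identity
#' `rmse^2 = bias^2 + sd^2` holds exactly per window.
#'
#' @param observed,modeled `eem_tensor`s on identical grids, or plain
#'   I x J x K arrays (then `em`/`ex` must be supplied).
#' @param window_fraction half-width of the window as a fraction of the
#'   center wavelength (default 0.10). Use `fixed_nm` instead for an absolute
#'   half-width in nm.
#' @param fixed_nm optional absolute window half-width (nm); overrides
#'   `window_fraction`.
#' @param em,ex wavelength grids, required when arrays are passed.
#' @return A list of class `"discrepancy_maps"`: `bias`, `sd`, `rmse`
#'   (J x K matrices, AU), `window_fraction`, and `rma` (list `slope`,
#'   `intercept`, `r2` from [rma_fit()] of modeled on observed over all
#'   cells).
#' @export
discrepancy_maps <- function(observed, modeled, window_fraction = 0.10,
                             fixed_nm = NULL, em = NULL, ex = NULL) {
  if (inherits(observed, "eem_tensor")) { em <- observed$em; ex <- observed$ex; observed <- observed$values }
  if (inherits(modeled, "eem_tensor")) modeled <- modeled$values
  if (!all(dim(observed) == dim(modeled)))
    stop("observed and modeled tensors differ in shape", call. = FALSE)
  stopifnot(!is.null(em), !is.null(ex))
  R <- modeled - observed
  J <- length(em); K <- length(ex)
  win <- function(grid, center) {
    hw <- if (is.null(fixed_nm)) window_fraction * center else fixed_nm
    which(abs(grid - center) <= hw)
  }
  em_win <- lapply(em, win, grid = em)
  ex_win <- lapply(ex, win, grid = ex)
  bias <- sd_m <- rmse <- matrix(0, J, K)
  for (j in seq_len(J)) {
    jj <- em_win[[j]]
    for (k in seq_len(K)) {
      r <- R[, jj, ex_win[[k]]]
      mu <- mean(r)
      ms <- mean(r^2)
      bias[j, k] <- mu
      rmse[j, k] <- sqrt(ms)
      sd_m[j, k] <- sqrt(max(ms - mu^2, 0))
    }
  }
  rma <- tryCatch(rma_fit(as.vector(observed), as.vector(modeled)),
                  error = function(e) list(slope = NA_real_,
                                           intercept = NA_real_, r2 = NA_real_))
  structure(list(bias = bias, sd = sd_m, rmse = rmse,
                 window_fraction = if (is.null(fixed_nm)) window_fraction else NA_real_,
                 fixed_nm = fixed_nm, em = em, ex = ex, rma = rma),
            class = "discrepancy_maps")
}

#' Reduced major axis (RMA) regression
#'
#' Symmetric line fit appropriate when both variables carry error (as both
#' observed and modeled fluorescence do): slope is `sign(cor) * sd(y)/sd(x)`,
#' the line passes through the centroid, and `r2` is the squared Pearson
#' correlation. Swapping x and y inverts the slope and leaves `r2` unchanged.
#'
#' @param x,y numeric vectors of equal length >= 3 with positive variance.
#' @return List: `slope`, `intercept`, `r2`.
#' @export
rma_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("RMA regression needs at least 3 points", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("zero variance in x or y: RMA slope undefined", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (slope == 0) slope <- sy / sx  # r == 0: conventionally positive
  list(slope = slope, intercept = mean(y) - slope * mean(x), r2 = r^2)
}

#' Per-sample fit quality of a PARAFAC model
#'
#' @param model a `parafac_model`.
#' @param tensor the observed `eem_tensor`.
#' @return data.frame with one row per sample: `sample_id`, `rmse`
#'   (root-mean-square residual over the surface), `mean_fluorescence`
#'   (mean absolute observed intensity), `rmse_over_mean` (`NA` for
#'   zero-mean samples), `core_consistency_context` (the model-level core
#'   consistency, repeated for context).
#' @export
per_sample_fit <- function(model, tensor) {
  stopifnot(inherits(tensor, "eem_tensor"))
  Xh <- reconstruct_parafac(model)
  I <- dim(tensor$values)[1]
  ids <- if (!is.null(tensor$samples$sample_id)) tensor$samples$sample_id
         else as.character(seq_len(I))
  rmse <- mf <- numeric(I)
  for (i in seq_len(I)) {
    res <- tensor$values[i, , ] - Xh[i, , ]
    rmse[i] <- sqrt(mean(res^2))
    mf[i] <- mean(abs(tensor$values[i, , ]))
  }
  data.frame(sample_id = ids, rmse = rmse, mean_fluorescence = mf,
             rmse_over_mean = ifelse(mf > 0, rmse / mf, NA_real_),
             core_consistency_context = model$core_consistency,
             stringsAsFactors = FALSE)
}

#' Score-dilution factor curves
#'
#' Joins fitted factor scores with sample dilution factors and groups them
#' into per-(factor, source) curves ordered by DF, reporting whether each
#' curve is monotone non-decreasing in DF (within `1e-9 * max(score)`): in
#' the thin limit scores are proportional to fluorophore concentration, so
#' any inversion flags residual inner-filter or fitting trouble.
#'
#' @param model a `parafac_model` whose sample table carries `sample_id`,
#'   `DF` and (optionally) `source_pool_id`.
#' @param records optional data.frame overriding the model's sample table.
#' @return List of class `"score_curves"`: `curves` (list of lists with
#'   `factor_id`, `source_id`, `points`) and `monotonic` (data.frame with
#'   per-curve flag and first offending DF pair, if any).
#' @export
score_df_curves <- function(model, records = NULL) {
  recs <- if (is.null(records)) model$samples else records
  if (is.null(recs) || !all(c("sample_id", "DF") %in% names(recs)))
    stop("sample records with sample_id and DF are required", call. = FALSE)
  if (nrow(recs) != nrow(model$A))
    stop("records do not match the model's samples", call. = FALSE)
  if (any(!is.finite(recs$DF)))
    stop("missing DF for a scored sample", call. = FALSE)
  src <- if ("source_pool_id" %in% names(recs)) recs$source_pool_id
         else rep("all", nrow(recs))
  curves <- list()
  mono_rows <- list()
  for (f in seq_len(model$F)) {
    for (s in unique(src)) {
      sel <- which(src == s)
      if (length(sel) < 2L) next
      ord <- sel[order(recs$DF[sel])]
      pts <- data.frame(DF = recs$DF[ord], score = model$A[ord, f])
      tol <- 1e-9 * max(abs(pts$score), .Machine$double.eps)
      drops <- which(diff(pts$score) < -tol)
      curves[[length(curves) + 1L]] <-
        list(factor_id = f, source_id = s, points = pts)
      mono_rows[[length(mono_rows) + 1L]] <- data.frame(
        factor_id = f, source_id = s, monotone = length(drops) == 0L,
        first_violation_DF = if (length(drops)) pts$DF[drops[1L]] else NA_real_)
    }
  }
  structure(list(curves = curves, monotonic = do.call(rbind, mono_rows)),
            class = "score_curves")
}

#' Equal-score concentration ratios between sources
#'
#' At a fixed score level (a proxy of a fixed, univocal fluorescence), the DF
#' each source needs to reach that score is inversely proportional to its
#' fluorophore concentration. For each curve the DF at `score_level` is found
#' by log-log linear interpolation (dilution series are geometric), and the
#' concentration ratio of a source relative to the reference is
#' `DF*(reference) / DF*(source)`.
#'
#' @param curves a `score_curves` object or a plain list of curves (each
#'   with `source_id` and `points`), typically restricted to one factor.
#' @param score_level score at which sources are compared (default 1000).
#' @param reference_source `source_id` of the denominator source.
#' @return Named numeric vector of ratios, one per source (reference = 1).
#' @export
concentration_ratio_at_score <- function(curves, score_level = 1000,
                                         reference_source) {
  if (inherits(curves, "score_curves")) curves <- curves$curves
  stopifnot(length(curves) >= 1, score_level > 0)
  df_star <- vapply(curves, function(cv) {
    pts <- cv$points
    if (any(diff(pts$score) < 0))
      stop(sprintf("curve for source '%s' is not monotone in DF", cv$source_id),
           call. = FALSE)
    if (score_level < min(pts$score) || score_level > max(pts$score))
      stop(sprintf("curve for source '%s' does not bracket score %g (range %g-%g)",
                   cv$source_id, score_level, min(pts$score), max(pts$score)),
           call. = FALSE)
    i <- findInterval(score_level, pts$score, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(pts) - 1L)
    s0 <- pts$score[i]; s1 <- pts$score[i + 1L]
    d0 <- pts$DF[i]; d1 <- pts$DF[i + 1L]
    if (s1 == s0) return(sqrt(d0 * d1))
    t <- (log(score_level) - log(s0)) / (log(s1) - log(s0))
    exp(log(d0) + t * (log(d1) - log(d0)))
  }, numeric(1))
  names(df_star) <- vapply(curves, `[[`, character(1), "source_id")
  if (!reference_source %in% names(df_star))
    stop(sprintf("reference source '%s' has no curve", reference_source),
         call. = FALSE)
  df_star[[reference_source]] / df_star
}
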