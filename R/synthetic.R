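#' Gaussian spectral profile
#'
#' Unit-maximum Gaussian loading shape,
#' `exp(-4 ln 2 (lambda - peak)^2 / fwhm^2)`, used for the emission and
#' excitation profiles of synthetic fluorophores (value 0.5 exactly at
#' `peak +/- fwhm/2`).
#'
#' @param peak peak wavelength (nm).
#' @param fwhm full width at half maximum (nm), > 0.
#' @param grid wavelength grid (nm).
#' @return Numeric vector on `grid`, maximum 1 when the peak is on-grid.
#' @export
gaussian_profile <- function(peak, fwhm, grid) {
  stopifnot(fwhm > 0)
  exp(-4 * log(2) * (grid - peak)^2 / fwhm^2)
}

#' Define a synthetic fluorophore
#'
#' @param name label.
#' @param peak_ex,peak_em peak wavelengths (nm); `peak_em > peak_ex` (Stokes
#'   shift).
#' @param fwhm_ex,fwhm_em full widths at half maximum (nm), > 0.
#' @param quantum_scale fluorescence output, AU per unit concentration at
#'   DF = 1.
#' @param absorptivity decadic absorbance per unit concentration at DF = 1
#'   (drives the fluorophore's own inner-filter contribution).
#' @return List of class `"fluorophore"`.
#' @export
fluorophore <- function(name, peak_ex, peak_em, fwhm_ex, fwhm_em,
                        quantum_scale, absorptivity = 0) {
  if (peak_em <= peak_ex)
    stop("peak_em must exceed peak_ex (Stokes shift)", call. = FALSE)
  stopifnot(fwhm_ex > 0, fwhm_em > 0, quantum_scale >= 0, absorptivity >= 0)
  structure(list(name = name, peak_ex = peak_ex, peak_em = peak_em,
                 fwhm_ex = fwhm_ex, fwhm_em = fwhm_em,
                 quantum_scale = quantum_scale, absorptivity = absorptivity),
            class = "fluorophore")
}

#' Default synthetic study scenario
#'
#' Emulates a two-species bile fluorescence dilution study: seven source
#' samples (three lab-conditioned AME pools, one AME from a reference river,
#' one AME from a polluted river, two lab-conditioned PIO individuals),
#' serially diluted 1:100 to 1:6400, measured on a 190-400 nm excitation /
#' 250-600 nm emission grid at 5 nm steps. Three Gaussian fluorophores are
#' planted: a tryptophan-like family (Ex 225 / Em 360), a second AME-dominant
#' family (Ex 290 / Em 450), and a PIO-dominant family (Ex 345 / Em 410).
#' Factor-1 concentrations across POLLUT : REF : LAB : PIO are 16 : 3 : 1 :
#' 0.09; factor 2 follows 21 : 4 : 1 : 0.25 (relative to LAB); factor 3 is
#' about 6 times more abundant in PIO. Measurement physics: a broad solvent
#' blank, Rayleigh/Raman scatter ridges, inner-filter attenuation dominated
#' by a per-source bile-matrix absorbance (AME absorbance 174 decadic
#' exponent units, putting the dilution-curve maximum at
#' DF = 1/(174 ln 10) = 2.5e-3, the concentrated end of the 1:400-1:800
#' window, which also keeps scores monotone in DF throughout the thin
#' limit; PIO non-absorbing so its curves stay linear), and
#' i.i.d. Gaussian noise with sd equal to `noise_relative` times the study's
#' maximum fluorescent signal.
#'
#' @param extended_em if `TRUE`, extend the emission grid to 650 nm
#'   (81 points instead of the default 71).
#' @param inner_filter enable inner-filter attenuation (default `TRUE`).
#' @param scatter enable scatter ridges (default `TRUE`).
#' @param noise_relative noise sd as a fraction of the study's maximum
#'   signal (default 0.01); set 0 for noise-free data.
#' @param schedule dilution schedule data.frame (`label`, `DF`), default
#'   `serial_dilution_schedule("1:100", 2, 7)`.
#' @param seed master seed fixing all randomness.
#' @return A list of class `"eem_scenario"`.
#' @export
default_scenario <- function(extended_em = FALSE, inner_filter = TRUE,
                             scatter = TRUE, noise_relative = 0.01,
                             schedule = serial_dilution_schedule("1:100", 2, 7),
                             seed = 42L) {
  fluors <- list(
    fluorophore("trp_like", 225, 360, 40, 60, quantum_scale = 2e6, absorptivity = 5),
    fluorophore("ame_secondary", 290, 450, 50, 70, quantum_scale = 1e6, absorptivity = 3),
    fluorophore("pio_main", 345, 410, 45, 60, quantum_scale = 5e5, absorptivity = 0))
  sources <- list(
    list(source_id = "AME_LAB_1", species = "AME", condition = "LAB",
         conc = c(1, 0.5, 0.2), matrix_absorbance = 174),
    list(source_id = "AME_LAB_2", species = "AME", condition = "LAB",
         conc = c(1, 0.5, 0.2), matrix_absorbance = 174),
    list(source_id = "AME_LAB_3", species = "AME", condition = "LAB",
         conc = c(1, 0.5, 0.2), matrix_absorbance = 174),
    list(source_id = "AME_REF", species = "AME", condition = "REF",
         conc = c(3, 2.0, 0.2), matrix_absorbance = 174),
    list(source_id = "AME_POLLUT", species = "AME", condition = "POLLUT",
         conc = c(16, 10.5, 0.25), matrix_absorbance = 174),
    list(source_id = "PIO_1", species = "PIO", condition = "LAB",
         conc = c(0.09, 0.125, 1.1), matrix_absorbance = 0),
    list(source_id = "PIO_2", species = "PIO", condition = "LAB",
         conc = c(0.09, 0.125, 1.3), matrix_absorbance = 0))
  structure(list(
    ex_grid = seq(190, 400, by = 5),
    em_grid = seq(250, if (extended_em) 650 else 600, by = 5),
    fluorophores = fluors,
    sources = sources,
    schedule = schedule,
    blank = list(amp = 10, peak_ex = 230, peak_em = 300,
                 fwhm_ex = 60, fwhm_em = 80, offset = 1),
    scatter = list(enabled = scatter,
                   amp = c(rayleigh1 = 300, rayleigh2 = 80,
                           raman1 = 60, raman2 = 30),
                   sd = c(rayleigh1 = 2, rayleigh2 = 2,
                          raman1 = 1.5, raman2 = 1.5),
                   raman_shift = 3382,
                   blank_fraction = 0.3),
    inner_filter = inner_filter,
    matrix_abs = list(ref_wavelength = 225, decay_nm = 150),
    noise_relative = noise_relative,
    noise_sd = NULL,
    seed = as.integer(seed)), class = "eem_scenario")
}

scenario_source <- function(scenario, source_id) {
  for (s in scenario$sources) if (s$source_id == source_id) return(s)
  stop(sprintf("unknown source '%s'", source_id), call. = FALSE)
}

scenario_loadings <- function(scenario) {
  B <- vapply(scenario$fluorophores,
              function(f) gaussian_profile(f$peak_em, f$fwhm_em, scenario$em_grid),
              numeric(length(scenario$em_grid)))
  C <- vapply(scenario$fluorophores,
              function(f) gaussian_profile(f$peak_ex, f$fwhm_ex, scenario$ex_grid),
              numeric(length(scenario$ex_grid)))
  list(B = B, C = C)
}

# fluorescent signal surface (linear trilinear part times inner-filter
# attenuation), before blank, ridges and noise
signal_surface <- function(scenario, src, DF, loadings) {
  B <- loadings$B; C <- loadings$C
  qs <- vapply(scenario$fluorophores, `[[`, numeric(1), "quantum_scale")
  ab <- vapply(scenario$fluorophores, `[[`, numeric(1), "absorptivity")
  scores <- src$conc * DF * qs
  L <- B %*% (scores * t(C))
  atten <- NULL
  if (isTRUE(scenario$inner_filter)) {
    mprof <- function(l) exp(-(l - scenario$matrix_abs$ref_wavelength) /
                               scenario$matrix_abs$decay_nm)
    A_ex <- DF * (as.vector(C %*% (src$conc * ab)) +
                    src$matrix_absorbance * mprof(scenario$ex_grid))
    A_em <- DF * (as.vector(B %*% (src$conc * ab)) +
                    src$matrix_absorbance * mprof(scenario$em_grid))
    atten <- 10^(-(outer(A_em, A_ex, `+`)) / 2)
    L <- L * atten
  }
  list(L = L, scores = scores, atten = atten)
}

blank_surface <- function(scenario) {
  b <- scenario$blank
  b$amp * outer(gaussian_profile(b$peak_em, b$fwhm_em, scenario$em_grid),
                gaussian_profile(b$peak_ex, b$fwhm_ex, scenario$ex_grid)) +
    b$offset
}

# ridges truncated at 3 sd and clipped to the default excision band extents,
# so the planted scatter lies entirely inside the bands that remove it
ridge_surface <- function(scenario) {
  sc <- scenario$scatter
  em <- scenario$em_grid; ex <- scenario$ex_grid
  out <- matrix(0, length(em), length(ex))
  if (!isTRUE(sc$enabled)) return(out)
  ctr <- scatter_centers(ex, sc$raman_shift)
  ext <- list(rayleigh1 = c(10, 20), rayleigh2 = c(15, 20),
              raman1 = c(15, 5), raman2 = c(15, 10))  # (below, above)
  for (band in names(sc$amp)) {
    sd_b <- sc$sd[[band]]
    lo <- min(3 * sd_b, ext[[band]][1]); hi <- min(3 * sd_b, ext[[band]][2])
    for (k in seq_along(ex)) {
      c0 <- ctr[[band]][k]
      sel <- em >= c0 - lo & em <= c0 + hi
      out[sel, k] <- out[sel, k] +
        sc$amp[[band]] * exp(-(em[sel] - c0)^2 / (2 * sd_b^2))
    }
  }
  out
}

#' Generate one synthetic EEM with known ground truth
#'
#' Forward model: trilinear fluorescence
#' `L[j,k] = sum_f conc_f * DF * quantum_f * b_jf * c_kf`, multiplied (when
#' inner-filter is enabled) by `10^(-(A_ex(k) + A_em(j))/2)` with decadic
#' absorbances from the fluorophores' absorptivities plus the source's
#' bile-matrix absorbance; then the blank surface, Rayleigh/Raman ridges and
#' i.i.d. Gaussian noise are added.
#'
#' @param scenario an `eem_scenario` (see [default_scenario()]).
#' @param source_id one of the scenario's source ids.
#' @param DF dilution factor in (0, 1].
#' @param noise_sd noise standard deviation (AU); defaults to
#'   `scenario$noise_sd`, or 0 when that is unset.
#' @param seed seed for the noise draw (same seed, same EEM bit for bit).
#' @return List: `eem` (the measured surface), `truth` (list with `L` the
#'   noiseless fluorescent signal, `scores`, unit-max `B`, `C` loadings).
#' @export
make_eem <- function(scenario, source_id, DF, noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "eem_scenario"), DF > 0, DF <= 1)
  src <- scenario_source(scenario, source_id)
  loadings <- scenario_loadings(scenario)
  sig <- signal_surface(scenario, src, DF, loadings)
  x <- sig$L + blank_surface(scenario) + ridge_surface(scenario)
  if (is.null(noise_sd)) noise_sd <- scenario$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
  }
  e <- eem(ex = scenario$ex_grid, em = scenario$em_grid, x = x,
           meta = list(source_id = source_id, DF = DF))
  list(eem = e,
       truth = list(L = sig$L, scores = sig$scores,
                    B = loadings$B, C = loadings$C))
}

#' Generate the blank EEM of a scenario
#'
#' The solvent blank carries the blank surface, attenuated scatter ridges
#' (`blank_fraction` of the sample ridge amplitude: a cuvette of solvent
#' scatters less than bile) and noise; subtracting it from samples therefore
#' leaves residual ridges, which is why scatter excision follows blank
#' subtraction.
#'
#' @param scenario an `eem_scenario`.
#' @param noise_sd,seed as in [make_eem()].
#' @return An [eem()].
#' @export
make_blank <- function(scenario, noise_sd = NULL, seed = 2L) {
  x <- blank_surface(scenario) +
    scenario$scatter$blank_fraction * ridge_surface(scenario)
  if (is.null(noise_sd)) noise_sd <- scenario$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
  }
  eem(ex = scenario$ex_grid, em = scenario$em_grid, x = x,
      meta = list(blank = TRUE))
}

#' Generate a full synthetic dilution study
#'
#' Produces every (source, dilution) EEM of the scenario, the blank, a sample
#' manifest and the ground-truth bundle. The noise sd, when not set
#' explicitly in the scenario, is `noise_relative` times the maximum
#' noiseless fluorescent signal over the whole study; per-sample noise seeds
#' are derived from the scenario's master seed.
#'
#' @param scenario an `eem_scenario`.
#' @param dir optional directory: when given, EEM CSVs, `manifest.csv` and a
#'   `truth.json` (if \pkg{jsonlite} is available) are written there and the
#'   manifest gains `eem_path` columns.
#' @return List of class `"eem_study"`: `manifest` (with resolved `DF`),
#'   `eems` (named list), `blank`, `truth` (loadings, per-sample scores
#'   table, concentration table, `noise_sd`), `scenario`.
#' @export
make_study <- function(scenario = default_scenario(), dir = NULL) {
  stopifnot(inherits(scenario, "eem_scenario"))
  sched <- scenario$schedule
  loadings <- scenario_loadings(scenario)
  rows <- list(); surfaces <- list(); truths <- list()
  for (src in scenario$sources) {
    for (d in seq_len(nrow(sched))) {
      sid <- sprintf("%s_%s", src$source_id, gsub(":", "-", sched$label[d]))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, species = src$species, condition = src$condition,
        source_pool_id = src$source_id, dilution_label = sched$label[d],
        blank_id = "BLANK", stringsAsFactors = FALSE)
      sig <- signal_surface(scenario, src, sched$DF[d], loadings)
      surfaces[[sid]] <- sig
    }
  }
  manifest <- sample_records(do.call(rbind, rows))
  noise_sd <- scenario$noise_sd
  if (is.null(noise_sd)) {
    max_sig <- max(vapply(surfaces, function(s) max(s$L), numeric(1)))
    noise_sd <- scenario$noise_relative * max_sig
  }
  set.seed(scenario$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(surfaces) + 1L)
  bg <- blank_surface(scenario) + ridge_surface(scenario)
  eems <- list()
  score_rows <- list()
  for (i in seq_along(surfaces)) {
    sid <- names(surfaces)[i]
    x <- surfaces[[sid]]$L + bg
    if (noise_sd > 0) {
      set.seed(seeds[i])
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    }
    eems[[sid]] <- eem(ex = scenario$ex_grid, em = scenario$em_grid, x = x,
                       meta = list(sample_id = sid))
    score_rows[[i]] <- data.frame(sample_id = sid,
                                  t(surfaces[[sid]]$scores))
  }
  scores <- do.call(rbind, score_rows)
  names(scores)[-1L] <- vapply(scenario$fluorophores, `[[`, character(1), "name")
  blank <- make_blank(scenario, noise_sd = noise_sd, seed = seeds[length(seeds)])
  conc <- do.call(rbind, lapply(scenario$sources, function(s)
    data.frame(source_id = s$source_id, t(s$conc))))
  names(conc)[-1L] <- names(scores)[-1L]
  study <- structure(list(manifest = manifest, eems = eems, blank = blank,
                          truth = list(B = loadings$B, C = loadings$C,
                                       scores = scores, concentrations = conc,
                                       noise_sd = noise_sd),
                          scenario = scenario),
                     class = "eem_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a synthetic study to disk as plain-text files
#'
#' @param study an `eem_study` from [make_study()].
#' @param dir output directory (created if needed).
#' @return The manifest with `eem_path` filled in, invisibly; also updates
#'   `study$manifest` on the returned study object when reassigned.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(study$manifest))
  for (i in seq_len(nrow(study$manifest))) {
    sid <- study$manifest$sample_id[i]
    paths[i] <- file.path(dir, paste0(sid, ".csv"))
    write_eem(study$eems[[sid]], paths[i])
  }
  write_eem(study$blank, file.path(dir, "BLANK.csv"))
  manifest <- study$manifest
  manifest$eem_path <- paths
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(scores = study$truth$scores,
           concentrations = study$truth$concentrations,
           noise_sd = study$truth$noise_sd),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}
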