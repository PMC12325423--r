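test_that("blank subtraction is cellwise with mask union and optional clipping", {
  set.seed(3)
  s <- toy_eem(fm = function(em) em / 100, fx = function(ex) ex / 100)
  z <- toy_eem(fm = function(em) rep(0, length(em)))
  expect_equal(subtract_blank(s, s)$x, matrix(0, 6, 5))
  expect_identical(subtract_blank(s, z)$x, s$x)

  b <- toy_eem(fm = function(em) rep(8, length(em)))
  s5 <- toy_eem(fm = function(em) rep(5, length(em)))
  expect_true(all(subtract_blank(s5, b, clip_negative = TRUE)$x == 0))
  expect_true(all(subtract_blank(s5, b)$x == -3))

  s$mask[1, 2] <- TRUE
  b2 <- toy_eem(fm = function(em) rep(1, length(em)))
  b2$mask[3, 4] <- TRUE
  out <- subtract_blank(s, b2)
  expect_true(out$mask[1, 2] && out$mask[3, 4])
  expect_equal(sum(out$mask), 2)

  bad <- toy_eem(ex = seq(251, 291, 10))
  expect_error(subtract_blank(s, bad), "grids")
})

test_that("scatter line centers follow elastic and wavenumber-shift arithmetic", {
  c300 <- scatter_centers(300, 1234)
  expect_equal(c300$rayleigh1, 300)
  expect_equal(c300$rayleigh2, 600)
  expect_equal(scatter_centers(350, 3382)$raman1, 1e7 / (1e7 / 350 - 3382))
  expect_equal(scatter_centers(350, 3382)$raman1, 396.99, tolerance = 1e-4)
  c250 <- scatter_centers(250, 3382)
  expect_equal(c250$raman1, 273.10, tolerance = 1e-4)
  expect_equal(c250$raman2, 546.20, tolerance = 1e-4)
  expect_error(scatter_centers(250, 40000), "undefined")
})

test_that("scatter mask geometry reproduces the four band extents", {
  e <- eem(ex = c(300), em = seq(200, 700, 1), x = matrix(0, 501, 1))
  cfg <- scatter_band_config()
  # adjacent bands can merge (Rayleigh-1 [290,320] touches Raman-1
  # [318.9,338.9] at ex 300), so each band's extent is measured with only
  # that band enabled, at its default widths
  one_band <- function(which) {
    args <- list(rayleigh1 = list(enabled = FALSE, above = 20, below = 10),
                 rayleigh2 = list(enabled = FALSE, above = 20, below = 15),
                 raman1 = list(enabled = FALSE, above = 5, below = 15),
                 raman2 = list(enabled = FALSE, above = 10, below = 15))
    args[[which]]$enabled <- TRUE
    do.call(scatter_band_config, args)
  }
  # 1 nm grid aligned to the band center, so the excised interval's edges
  # are representable grid points
  span <- function(which) {
    cfg1 <- one_band(which)
    c0 <- scatter_centers(300, cfg1$raman_shift)[[which]]
    ealigned <- eem(ex = c(300), em = c0 + seq(-60, 60, 1),
                    x = matrix(0, 121, 1))
    m <- build_scatter_mask(ealigned, cfg1)
    diff(range(ealigned$em[m[, 1]]))
  }
  expect_equal(span("rayleigh1"), 30)   # +20/-10
  expect_equal(span("rayleigh2"), 35)   # +20/-15
  expect_equal(span("raman1"), 20)      # +5/-15
  expect_equal(span("raman2"), 25)      # +10/-15
  expect_equal(range(e$em[build_scatter_mask(e, one_band("rayleigh1"))[, 1]]),
               c(290, 320))

  off <- scatter_band_config(
    rayleigh1 = list(enabled = FALSE, above = 20, below = 10),
    rayleigh2 = list(enabled = FALSE, above = 20, below = 15),
    raman1 = list(enabled = FALSE, above = 5, below = 15),
    raman2 = list(enabled = FALSE, above = 10, below = 15))
  expect_false(any(build_scatter_mask(e, off)))

  # masking is idempotent: recomputing on a masked EEM gives the same mask
  m <- build_scatter_mask(e, cfg)
  e2 <- eem(e$ex, e$em, e$x, mask = m)
  expect_identical(build_scatter_mask(e2, cfg), m)

  # bands entirely outside the emission grid mask nothing
  e3 <- eem(ex = c(300), em = seq(340, 400, 1), x = matrix(0, 61, 1))
  expect_false(any(build_scatter_mask(e3, one_band("rayleigh2"))))
})

test_that("gap interpolation restores affine surfaces exactly and leaves unmasked cells untouched", {
  em <- seq(300, 400, 5)
  e <- toy_eem(em = em, fm = function(em) rep(7, length(em)))
  e$mask[5:8, 2] <- TRUE
  out <- interpolate_gaps(e)
  expect_true(all(out$x == 7))
  expect_false(any(out$mask))

  ramp <- toy_eem(em = em, fm = function(em) em)
  ramp$mask[4:9, 3] <- TRUE
  out2 <- interpolate_gaps(ramp)
  expect_equal(out2$x, outer(em, rep(1, 5), function(a, b) a))
  # bitwise equality for cells that were never masked
  expect_identical(out2$x[!ramp$mask], ramp$x[!ramp$mask])

  full <- toy_eem(em = em)
  full$mask[] <- TRUE
  expect_error(interpolate_gaps(full), "fully masked")

  # edge gaps: nearest-value extension
  edge <- toy_eem(em = em, fm = function(em) em)
  edge$mask[1:3, 1] <- TRUE
  edge$mask[19:21, 2] <- TRUE
  out3 <- interpolate_gaps(edge)
  expect_true(all(out3$x[1:3, 1] == em[4]))
  expect_true(all(out3$x[19:21, 2] == em[18]))
})

test_that("linear gap filling on a quadratic matches the chord error bound", {
  em <- seq(300, 400, 5)
  a <- 0.02
  quad <- toy_eem(em = em, fm = function(em) a * (em - 300)^2)
  gap <- em > 340 & em < 360            # masked run, chord spans 340-360
  quad$mask[gap, 2] <- TRUE
  out <- interpolate_gaps(quad)
  chord <- function(l) {
    f <- function(x) a * (x - 300)^2
    f(340) + (l - 340) / 20 * (f(360) - f(340))
  }
  expect_equal(out$x[gap, 2], chord(em[gap]), tolerance = 1e-12)
  # analytic chord-vs-parabola error, maximal at the midpoint
  err <- max(abs(out$x[, 2] - a * (em - 300)^2))
  expect_equal(err, a * (350 - 340) * (360 - 350), tolerance = 1e-9)
})

test_that("residual scatter level is ~0 after processing and large when untouched", {
  em <- seq(250, 650, 5)
  ex <- seq(250, 300, 10)
  bg <- 5
  x <- matrix(bg, length(em), length(ex))
  cfg <- scatter_band_config()
  # plant ridges exactly on the scatter lines
  ctr <- scatter_centers(ex, cfg$raman_shift)
  for (k in seq_along(ex)) for (band in names(ctr)) {
    sel <- abs(em - ctr[[band]][k]) <= 4
    x[sel, k] <- x[sel, k] + 100 * exp(-(em[sel] - ctr[[band]][k])^2 / 8)
  }
  raw <- eem(ex, em, x)
  expect_gte(residual_scatter_level(raw, cfg), 100 - bg - 1e-9)

  cleaned <- preprocess_eem(raw, blank = NULL, config = cfg,
                            zero_below_rayleigh = FALSE)
  expect_lt(residual_scatter_level(cleaned, cfg), 1e-9)
  expect_false(any(is.na(cleaned$x)))

  # ridge + smooth fluorophore: residual bounded by the chord error of the
  # smooth component (independent oracle via stats::approx per column)
  smooth <- 10 * outer(gaussian_profile(380, 100, em),
                       gaussian_profile(280, 80, ex))
  withridge <- eem(ex, em, x - bg + smooth)
  cleaned2 <- preprocess_eem(withridge, config = cfg,
                             zero_below_rayleigh = FALSE)
  band <- build_scatter_mask(withridge, cfg)
  worst <- 0
  for (k in seq_along(ex)) {
    ok <- !band[, k]
    if (sum(ok) < 2) next
    chord <- approx(em[ok], smooth[ok, k], xout = em, rule = 2)$y
    worst <- max(worst, abs(chord - smooth[, k])[band[, k]])
  }
  dev <- max(abs(cleaned2$x[band] - smooth[band]))
  expect_equal(dev, worst, tolerance = 1e-9)
  expect_lt(dev, 2)  # gentle curvature keeps residuals below 2 AU
})

test_that("processed output is free of masks and non-finite values", {
  sc <- default_scenario()
  made <- make_eem(sc, "AME_LAB_1", 0.00125, noise_sd = 5, seed = 9)
  blank <- make_blank(sc, noise_sd = 5, seed = 10)
  out <- preprocess_eem(made$eem, blank)
  expect_false(any(out$mask))
  expect_true(all(is.finite(out$x)))
})
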