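# --- independent oracles ------------------------------------------------

# triple-loop residual sum of squares
rss_brute <- function(A, B, C, X) {
  total <- 0
  for (i in seq_len(dim(X)[1])) for (j in seq_len(dim(X)[2]))
    for (k in seq_len(dim(X)[3])) {
      xhat <- sum(A[i, ] * B[j, ] * C[k, ])
      total <- total + (X[i, j, k] - xhat)^2
    }
  total
}

# CORCONDIA by direct normal equations on the Kronecker design:
# vec(X) = (C (x) B (x) A) vec(G), solved with base lm.fit
corcondia_brute <- function(A, B, C, X) {
  F <- ncol(A)
  design <- kronecker(C, kronecker(B, A))
  g <- qr.coef(qr(design), as.vector(X))
  Tsup <- array(0, c(F, F, F))
  for (f in seq_len(F)) Tsup[f, f, f] <- 1
  100 * (1 - sum((g - as.vector(Tsup))^2) / F)
}

cong2 <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

# --- tests ---------------------------------------------------------------

test_that("rank-1 tensors are recovered exactly", {
  set.seed(21)
  a <- runif(4) + 0.5; b <- runif(6) + 0.5; c <- runif(5) + 0.5
  X <- rank_tensor(cbind(a), cbind(b), cbind(c))
  tens <- toy_tensor(X)
  m <- fit_parafac(tens, 1, fit_options(n_starts = 3, seed = 5))
  expect_lt(m$rss / sum(X^2), 1e-10)
  expect_gt(cong2(m$B[, 1], b), 0.9999)
  expect_gt(cong2(m$C[, 1], c), 0.9999)
  expect_gt(cong2(m$A[, 1], a), 0.9999)
  expect_equal(m$core_consistency, 100)
})

test_that("noiseless rank-2 and rank-3 tensors with distinct Gaussian factors are recovered", {
  em <- seq(300, 500, 10); ex <- seq(220, 360, 10)
  for (F in 2:3) {
    B <- sapply(c(350, 430, 470)[1:F], gaussian_profile, fwhm = 60, grid = em)
    C <- sapply(c(240, 300, 340)[1:F], gaussian_profile, fwhm = 50, grid = ex)
    set.seed(F)
    A <- matrix(runif(6 * F, 0.5, 2), 6, F)
    X <- rank_tensor(A, B, C)
    m <- fit_parafac(toy_tensor(X, em, ex), F,
                     fit_options(n_starts = 10, seed = 17))
    expect_lt(m$rss / sum(X^2), 1e-10)
    for (f in seq_len(F)) {
      best <- max(vapply(seq_len(F), function(g)
        cong2(c(m$B[, g], m$C[, g]), c(B[, f], C[, f])), numeric(1)))
      expect_gt(best, 0.999)
    }
  }
})

test_that("all-zero tensors give zero scores and zero RSS", {
  tens <- toy_tensor(array(0, c(3, 4, 5)))
  m <- fit_parafac(tens, 1, fit_options(n_starts = 2, seed = 1))
  expect_equal(m$rss, 0)
  expect_true(all(m$A == 0))
})

test_that("NaNs are rejected and over-factoring warns", {
  X <- array(1, c(2, 3, 4)); X[1, 1, 1] <- NaN
  expect_error(fit_parafac(toy_tensor(X), 1), "non-finite")
  X[1, 1, 1] <- 1
  expect_warning(fit_parafac(toy_tensor(X), 3,
                             fit_options(n_starts = 1, max_iter = 5)),
                 "rank-deficient")
})

test_that("model RSS equals the brute-force triple loop", {
  set.seed(33)
  X <- array(runif(3 * 4 * 5), c(3, 4, 5))
  tens <- toy_tensor(X)
  m <- fit_parafac(tens, 2, fit_options(n_starts = 2, max_iter = 50, seed = 2))
  expect_equal(parafac_rss(m, tens), rss_brute(m$A, m$B, m$C, X),
               tolerance = 1e-10)
  expect_equal(m$rss, parafac_rss(m, tens), tolerance = 1e-8)

  # constant offset: RSS = N * delta^2
  a <- c(1, 2); b <- c(1, 1, 2); c <- c(2, 1)
  X1 <- rank_tensor(cbind(a), cbind(b), cbind(c))
  t1 <- toy_tensor(X1)
  m1 <- fit_parafac(t1, 1, fit_options(n_starts = 2, seed = 3))
  delta <- 0.25
  t2 <- toy_tensor(X1 + delta)
  expect_equal(parafac_rss(m1, t2), length(X1) * delta^2, tolerance = 1e-8)
})

test_that("core consistency matches its definition and brute-force oracle", {
  # any F = 1 model scores exactly 100
  set.seed(8)
  X <- array(runif(24), c(2, 3, 4))
  tens <- toy_tensor(X)
  m1 <- fit_parafac(tens, 1, fit_options(n_starts = 2, max_iter = 100, seed = 4))
  expect_equal(core_consistency(m1, tens), 100, tolerance = 1e-8)

  # 2x2x2 tensor with a non-trilinear perturbation: compare to the direct
  # 8x8 normal-equations solution
  A <- matrix(c(1, 0.3, 0.4, 1), 2, 2)
  B <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  C <- matrix(c(1, 0.1, 0.6, 1), 2, 2)
  X2 <- rank_tensor(A, B, C)
  X2[1, 2, 1] <- X2[1, 2, 1] + 0.3   # break exact trilinearity
  X2[2, 1, 2] <- X2[2, 1, 2] - 0.2
  t2 <- toy_tensor(X2)
  model <- structure(list(F = 2, A = A, B = B, C = C,
                          em = t2$em, ex = t2$ex),
                     class = "parafac_model")
  expect_equal(core_consistency(model, t2), corcondia_brute(A, B, C, X2),
               tolerance = 1e-9)

  # degenerate loadings are refused
  Abad <- cbind(c(1, 2), c(2, 4))
  bad <- structure(list(F = 2, A = Abad, B = B, C = C), class = "parafac_model")
  expect_error(core_consistency(bad, t2), "degenerate")
})

test_that("ALS residuals are monotone and constraints hold after every fit", {
  set.seed(55)
  for (rep in 1:4) {
    F_true <- sample(1:3, 1)
    A <- matrix(runif(5 * F_true), 5, F_true)
    B <- matrix(runif(7 * F_true), 7, F_true)
    C <- matrix(runif(6 * F_true), 6, F_true)
    X <- rank_tensor(A, B, C) +
      array(rnorm(5 * 7 * 6, sd = 0.01), c(5, 7, 6))
    m <- fit_parafac(toy_tensor(X), F_true,
                     fit_options(n_starts = 2, seed = rep))
    expect_true(all(diff(m$rss_trace) <= 1e-8 * max(m$rss_trace[1], 1)))
    expect_true(min(m$A, m$B, m$C) >= 0)
    expect_true(all(apply(m$B, 2, max) <= 1 + 1e-12))
    expect_true(all(apply(m$C, 2, max) <= 1 + 1e-12))
  }
})

test_that("reconstruction is invariant to the loading scaling convention", {
  set.seed(14)
  A <- matrix(runif(8), 4, 2); B <- matrix(runif(10), 5, 2)
  C <- matrix(runif(6), 3, 2)
  m <- structure(list(F = 2, A = A, B = B, C = C), class = "parafac_model")
  # rescale columns arbitrarily, compensating in A
  s1 <- c(3, 0.2); s2 <- c(0.5, 7)
  m2 <- m
  m2$B <- sweep(B, 2, s1, `*`); m2$C <- sweep(C, 2, s2, `*`)
  m2$A <- sweep(A, 2, s1 * s2, `/`)
  expect_equal(reconstruct_parafac(m), reconstruct_parafac(m2),
               tolerance = 1e-12)
})

test_that("factor sweep tabulates diagnostics and flags over-factoring", {
  em <- seq(300, 500, 20); ex <- seq(220, 360, 20)
  B <- sapply(c(350, 450), gaussian_profile, fwhm = 60, grid = em)
  C <- sapply(c(240, 320), gaussian_profile, fwhm = 50, grid = ex)
  # majority vote over seeds: over-factored core consistency below true-F
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed + 100)
    A <- matrix(runif(10 * 2, 0.5, 2), 10, 2)
    X <- rank_tensor(A, B, C)
    sw <- model_sweep(toy_tensor(X, em, ex), 1:3,
                      fit_options(n_starts = 4, seed = seed))
    expect_equal(sw$table$F, 1:3)
    expect_lt(sw$table$rss[2] / sum(X^2), 1e-8)
    cc <- sw$table$core_consistency
    expect_equal(cc[2], 100, tolerance = 1e-4)
    if (is.na(cc[3]) || cc[3] < cc[2] - 1e-6) wins <- wins + 1
  }
  expect_gt(wins, 2)

  one <- model_sweep(toy_tensor(array(runif(24), c(2, 3, 4))), 1:1,
                     fit_options(n_starts = 1, max_iter = 50))
  expect_equal(nrow(one$table), 1)
})

test_that("factor matching recovers permutations and congruences", {
  em <- seq(300, 500, 10); ex <- seq(220, 360, 10)
  B <- sapply(c(350, 430, 470), gaussian_profile, fwhm = 60, grid = em)
  C <- sapply(c(240, 300, 340), gaussian_profile, fwhm = 50, grid = ex)
  A <- matrix(runif(9, 0.5, 2), 3, 3)
  mk <- function(A, B, C) structure(
    list(F = ncol(B), A = A, B = B, C = C, em = em, ex = ex),
    class = "parafac_model")
  m <- mk(A, B, C)
  self <- match_factors(m, m)
  expect_equal(self$permutation, 1:3)
  expect_equal(self$congruence, rep(1, 3))

  p <- c(3, 1, 2)
  mp <- mk(A[, p], B[, p], C[, p])
  rec <- match_factors(m, mp)
  expect_equal(p[rec$permutation], 1:3)
  expect_equal(rec$congruence, rep(1, 3))

  # congruence of a 10 nm-shifted tryptophan-like factor equals the direct
  # discrete cosine of the concatenated profiles
  b1 <- gaussian_profile(360, 60, em); c1 <- gaussian_profile(225, 40, ex)
  b2 <- gaussian_profile(370, 60, em); c2 <- gaussian_profile(235, 40, ex)
  ma <- mk(matrix(1), cbind(b1), cbind(c1))
  mb <- mk(matrix(1), cbind(b2), cbind(c2))
  got <- match_factors(ma, mb)$congruence
  expected <- sum(c(b1, c1) * c(b2, c2)) /
    sqrt(sum(c(b1, c1)^2) * sum(c(b2, c2)^2))
  expect_equal(got, expected, tolerance = 1e-12)

  mg <- mk(matrix(1), cbind(b1), cbind(c1))
  mg$em <- em + 5
  expect_error(match_factors(ma, mg), "grids")
})

test_that("peak locations come from loading argmaxes with low-wavelength ties", {
  em <- seq(300, 500, 10); ex <- seq(220, 360, 10)
  B <- cbind(gaussian_profile(360, 60, em), rep(0.7, length(em)))
  C <- cbind(gaussian_profile(225, 40, ex), rep(0.7, length(ex)))
  m <- structure(list(F = 2, A = matrix(1, 1, 2), B = B, C = C,
                      em = em, ex = ex), class = "parafac_model")
  expect_equal(peak_location(m, 1), c(ex = 220, em = 360))
  expect_equal(peak_location(m, 2), c(ex = 220, em = 300))  # ties: lowest
  expect_error(peak_location(m, 3))
})

test_that("scores are proportional to planted concentrations in the thin limit", {
  sc <- clean_scenario()
  st <- make_study(sc)
  sel <- select_thin_limit(st$manifest)
  tens <- stack_eems(st$eems[sel$included$sample_id], sel$included)
  m <- fit_parafac(tens, 3, fit_options(n_starts = 4, seed = 11))
  truth <- st$truth$scores[match(sel$included$sample_id,
                                 st$truth$scores$sample_id), ]
  for (f in 1:3) {
    planted <- truth[[1 + f]]
    fitted_col <- which.max(abs(cor(m$A, planted)))
    slope <- sum(m$A[, fitted_col] * planted) / sum(planted^2)
    rel <- abs(m$A[, fitted_col] - slope * planted) / max(planted)
    expect_lt(max(rel), 0.02)
  }
})
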