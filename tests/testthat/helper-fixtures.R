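# Small in-code fixtures shared across test files.

# simple EEM with a separable surface on compact grids
toy_eem <- function(ex = seq(250, 290, 10), em = seq(300, 350, 10),
                    fx = function(ex) rep(1, length(ex)),
                    fm = function(em) rep(1, length(em)),
                    mask = NULL) {
  x <- outer(fm(em), fx(ex))
  eem(ex = ex, em = em, x = x, mask = mask)
}

# wrap a plain array as an eem_tensor
toy_tensor <- function(X, em = NULL, ex = NULL, DF = NULL, source = NULL) {
  d <- dim(X)
  if (is.null(em)) em <- seq(300, by = 10, length.out = d[2])
  if (is.null(ex)) ex <- seq(250, by = 10, length.out = d[3])
  if (is.null(DF)) DF <- seq_len(d[1]) / 1000
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(d[1])), DF = DF)
  if (!is.null(source)) samples$source_pool_id <- source
  structure(list(values = X, mask = array(FALSE, d), em = em, ex = ex,
                 samples = samples), class = "eem_tensor")
}

# exact rank-F tensor from given factor matrices
rank_tensor <- function(A, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  X <- array(0, c(I, J, K))
  for (f in seq_len(ncol(A)))
    for (i in seq_len(I)) X[i, , ] <- X[i, , ] + A[i, f] * outer(B[, f], C[, f])
  X
}

# scenario stripped to the pure trilinear signal (no blank, ridges,
# attenuation or noise), optionally with fewer sources/dilutions
clean_scenario <- function(n_sources = NULL, n_dilutions = NULL) {
  sc <- default_scenario(noise_relative = 0, inner_filter = FALSE,
                         scatter = FALSE)
  sc$blank$amp <- 0
  sc$blank$offset <- 0
  if (!is.null(n_sources)) sc$sources <- sc$sources[seq_len(n_sources)]
  if (!is.null(n_dilutions)) sc$schedule <- sc$schedule[seq_len(n_dilutions), ]
  sc
}

# independent Tucker congruence between matched columns of two loading sets,
# used to compare fitted factors against generator truth
truth_congruence <- function(model, B_true, C_true) {
  Fq <- ncol(B_true)
  best <- numeric(Fq)
  for (f in seq_len(Fq)) {
    v <- c(B_true[, f] / max(B_true[, f]), C_true[, f] / max(C_true[, f]))
    cong <- vapply(seq_len(model$F), function(g) {
      u <- c(model$B[, g], model$C[, g])
      sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    }, numeric(1))
    best[f] <- max(cong)
  }
  best
}
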