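#' Options for the PARAFAC alternating least squares fit
#'
#' @param nonneg logical length-3 (or scalar) flag per mode (scores, emission
#'   loadings, excitation loadings); all `TRUE` by default.
#' @param tol convergence criterion: relative change in residual sum of
#'   squares between iterations (default 1e-6).
#' @param max_iter maximum ALS iterations per start (default 2500).
#' @param n_starts number of random restarts; the lowest-RSS solution wins
#'   (default 10).
#' @param init `"random_nonneg"` (|N(0,1)| entries) or `"svd_based"`
#'   (absolute leading singular vectors of each unfolding).
#' @param seed master seed; per-start seeds are derived from it.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(nonneg = TRUE, tol = 1e-6, max_iter = 2500,
                        n_starts = 10, init = c("random_nonneg", "svd_based"),
                        seed = 1L) {
  init <- match.arg(init)
  nonneg <- rep_len(as.logical(nonneg), 3L)
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1)
  structure(list(nonneg = nonneg, tol = tol, max_iter = max_iter,
                 n_starts = n_starts, init = init, seed = as.integer(seed)),
            class = "fit_options")
}

# column-wise Khatri-Rao product with rows ordered (first factor varying
# fastest): out[(j,k), f] = B[j, f] * C[k, f]
khatri_rao <- function(C, B) {
  out <- matrix(0, nrow(B) * nrow(C), ncol(B))
  for (f in seq_len(ncol(B))) out[, f] <- as.vector(outer(B[, f], C[, f]))
  out
}

unfold1 <- function(X) { d <- dim(X); dim(X) <- c(d[1], d[2] * d[3]); X }
unfold2 <- function(X) { d <- dim(X); Y <- aperm(X, c(2, 1, 3)); dim(Y) <- c(d[2], d[1] * d[3]); Y }
unfold3 <- function(X) { d <- dim(X); Y <- aperm(X, c(3, 1, 2)); dim(Y) <- c(d[3], d[1] * d[2]); Y }

# solve min ||Z t(M) - t(Xu)|| for M (rows of the updated mode), with
# ZtZ = Hadamard product of the other modes' Gram matrices
mode_update <- function(XuZ, ZtZ, nonneg) {
  if (nonneg) {
    t(nnls_normal(ZtZ, t(XuZ)))
  } else {
    t(solve(ZtZ + diag(1e-12 * max(diag(ZtZ), 1), nrow(ZtZ)), t(XuZ)))
  }
}

als_single <- function(X1, X2, X3, dims, F, opts, start_seed) {
  I <- dims[1]; J <- dims[2]; K <- dims[3]
  set.seed(start_seed)
  if (opts$init == "random_nonneg") {
    A <- matrix(abs(stats::rnorm(I * F)), I, F)
    B <- matrix(abs(stats::rnorm(J * F)), J, F)
    C <- matrix(abs(stats::rnorm(K * F)), K, F)
  } else {
    svd_init <- function(M, n) {
      s <- svd(M, nu = min(F, ncol(M), nrow(M)), nv = 0)
      U <- abs(s$u)
      if (ncol(U) < F) U <- cbind(U, matrix(abs(stats::rnorm(n * (F - ncol(U)))), n, F - ncol(U)))
      U
    }
    A <- svd_init(X1, I); B <- svd_init(X2, J); C <- svd_init(X3, K)
  }
  normX2 <- sum(X1^2)
  rss_trace <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(opts$max_iter)) {
    n_iter <- it
    B <- mode_update(X2 %*% khatri_rao(C, A), crossprod(C) * crossprod(A), opts$nonneg[2])
    C <- mode_update(X3 %*% khatri_rao(B, A), crossprod(B) * crossprod(A), opts$nonneg[3])
    Z1 <- khatri_rao(C, B)
    ZtZ1 <- crossprod(B) * crossprod(C)
    X1Z <- X1 %*% Z1
    A <- mode_update(X1Z, ZtZ1, opts$nonneg[1])
    rss_now <- normX2 - 2 * sum(A * X1Z) + sum(crossprod(A) * ZtZ1)
    rss_now <- max(rss_now, 0)
    rss_trace <- c(rss_trace, rss_now)
    if (is.finite(rss_prev)) {
      denom <- max(rss_prev, .Machine$double.eps)
      if (abs(rss_prev - rss_now) / denom < opts$tol) { converged <- TRUE; break }
    }
    if (rss_now <= normX2 * 1e-14) { converged <- TRUE; break }
    rss_prev <- rss_now
  }
  list(A = A, B = B, C = C, rss = rss_trace[length(rss_trace)],
       rss_trace = rss_trace, converged = converged, n_iter = n_iter)
}

#' Fit a non-negative PARAFAC model to an EEM tensor
#'
#' Decomposes the samples x emission x excitation tensor as
#' `X[i,j,k] = sum_f A[i,f] B[j,f] C[k,f] + e[i,j,k]` by alternating least
#' squares with non-negative sub-solves per mode, restarted `n_starts` times
#' from different initialisations; the lowest-RSS solution is returned.
#' Emission and excitation loading columns are scaled to unit maximum with
#' the magnitude absorbed into the scores, so scores act as concentration
#' proxies comparable across samples. Factors are ordered by descending
#' total score (ties broken by ascending excitation peak wavelength).
#'
#' @param tensor an `eem_tensor` from [stack_eems()] (fully interpolated: no
#'   masked cells may enter the fit).
#' @param F number of factors, >= 1.
#' @param opts a [fit_options()] list.
#' @return An object of class `"parafac_model"`: `F`, `A` (I x F scores),
#'   `B` (J x F emission loadings), `C` (K x F excitation loadings), `rss`,
#'   `core_consistency`, `n_iter`, `converged`, `seed`, `scaling`,
#'   `rss_trace`, plus the tensor's grids and sample table.
#' @export
fit_parafac <- function(tensor, F, opts = fit_options()) {
  stopifnot(inherits(tensor, "eem_tensor"), F >= 1)
  X <- tensor$values
  if (any(!is.finite(X))) stop("tensor contains non-finite values", call. = FALSE)
  d <- dim(X)
  if (F > min(d))
    warning(sprintf("F = %d exceeds min tensor dimension %d: rank-deficient risk",
                    F, min(d)), call. = FALSE)
  X1 <- unfold1(X); X2 <- unfold2(X); X3 <- unfold3(X)
  set.seed(opts$seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, opts$n_starts)
  best <- NULL
  for (s in seq_len(opts$n_starts)) {
    run <- als_single(X1, X2, X3, d, F, opts, start_seeds[s])
    if (is.null(best) || run$rss < best$rss) best <- run
  }
  model <- finalize_model(best, tensor, F, opts)
  model$core_consistency <- tryCatch(core_consistency(model, tensor),
                                     error = function(e) NA_real_)
  model
}

finalize_model <- function(run, tensor, F, opts) {
  A <- run$A; B <- run$B; C <- run$C
  for (f in seq_len(F)) {
    bm <- max(abs(B[, f])); cm <- max(abs(C[, f]))
    if (bm > 0) { B[, f] <- B[, f] / bm } else bm <- 1
    if (cm > 0) { C[, f] <- C[, f] / cm } else cm <- 1
    # keep the peak positive for sign-indeterminate (unconstrained) fits
    if (B[which.max(abs(B[, f])), f] < 0) { B[, f] <- -B[, f]; A[, f] <- -A[, f] }
    if (C[which.max(abs(C[, f])), f] < 0) { C[, f] <- -C[, f]; A[, f] <- -A[, f] }
    A[, f] <- A[, f] * bm * cm
  }
  totals <- colSums(A)
  ex_peak <- tensor$ex[apply(C, 2, which.max)]
  ord <- order(-totals, ex_peak)
  structure(list(F = F, A = A[, ord, drop = FALSE], B = B[, ord, drop = FALSE],
                 C = C[, ord, drop = FALSE], rss = run$rss,
                 core_consistency = NA_real_, n_iter = run$n_iter,
                 converged = run$converged, seed = opts$seed,
                 scaling = "unit_max_BC", rss_trace = run$rss_trace,
                 em = tensor$em, ex = tensor$ex, samples = tensor$samples),
            class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> F = %d, RSS = %.6g, core consistency = %s, %d iteration(s)%s\n",
              x$F, x$rss,
              ifelse(is.na(x$core_consistency), "NA",
                     sprintf("%.1f%%", x$core_consistency)),
              x$n_iter, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Reconstruct the modeled tensor from a PARAFAC model
#'
#' @param model a `parafac_model`.
#' @return Numeric I x J x K array `X_hat`; invariant to the scaling
#'   convention of the loadings.
#' @export
reconstruct_parafac <- function(model) {
  I <- nrow(model$A); J <- nrow(model$B); K <- nrow(model$C)
  Xh <- model$A %*% t(khatri_rao(model$C, model$B))
  array(Xh, dim = c(I, J, K))
}

#' Residual sum of squares of a PARAFAC model
#'
#' @param model a `parafac_model`.
#' @param tensor the observed `eem_tensor`.
#' @return `sum((X - X_hat)^2)` over all cells (AU^2).
#' @export
parafac_rss <- function(model, tensor) {
  stopifnot(inherits(tensor, "eem_tensor"))
  Xh <- reconstruct_parafac(model)
  if (!all(dim(Xh) == dim(tensor$values)))
    stop("model and tensor dimensions disagree", call. = FALSE)
  sum((tensor$values - Xh)^2)
}

pinv_mat <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(s$d)
  pos <- s$d > tol
  if (!any(pos)) stop("matrix has no numerical rank", call. = FALSE)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

ttm <- function(Tarr, M, mode) {
  d <- dim(Tarr)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  Y <- aperm(Tarr, perm)
  dy <- dim(Y)
  dim(Y) <- c(dy[1], dy[2] * dy[3])
  Z <- M %*% Y
  dim(Z) <- c(nrow(M), dy[2], dy[3])
  aperm(Z, order(perm))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Solves the least-squares Tucker core G of the observed tensor given the
#' fitted PARAFAC loadings, and scores how close G is to the F x F x F
#' superidentity T the trilinear model implies:
#' `100 * (1 - sum((G - T)^2) / sum(T^2))`. Values near 100 indicate valid
#' trilinear structure; the statistic drops sharply (and may go negative,
#' reported unclipped) when the model is over-factored.
#'
#' @param model a `parafac_model`.
#' @param tensor the observed `eem_tensor`.
#' @return Core consistency in percent (<= 100, possibly negative).
#' @export
core_consistency <- function(model, tensor) {
  stopifnot(inherits(model, "parafac_model"), inherits(tensor, "eem_tensor"))
  F <- model$F
  for (M in list(model$A, model$B, model$C)) {
    s <- svd(M, nu = 0, nv = 0)$d
    if (length(s) < F || s[F] <= max(s) * 1e-12 || max(s) == 0)
      stop("degenerate model: loading matrix numerically rank-deficient",
           call. = FALSE)
  }
  G <- ttm(ttm(ttm(tensor$values, pinv_mat(model$A), 1),
               pinv_mat(model$B), 2), pinv_mat(model$C), 3)
  Tsuper <- array(0, dim = c(F, F, F))
  for (f in seq_len(F)) Tsuper[f, f, f] <- 1
  100 * (1 - sum((G - Tsuper)^2) / F)
}

#' Sweep the number of PARAFAC factors
#'
#' Fits the tensor at each factor count in `F_range` and tabulates the model
#' selection diagnostics (core consistency, RSS, convergence). For
#' best-of-starts fits RSS should be non-increasing in F; violations are
#' reported as local-optimum warnings, not errors.
#'
#' @param tensor an `eem_tensor`.
#' @param F_range integer vector of factor counts (default 1:7).
#' @param opts a [fit_options()].
#' @return A list of class `"parafac_sweep"`: `table` (data.frame with F,
#'   core_consistency, rss, converged, n_iter) and `models` (list of fitted
#'   `parafac_model`s, named by F).
#' @export
model_sweep <- function(tensor, F_range = 1:7, opts = fit_options()) {
  stopifnot(length(F_range) >= 1)
  models <- list()
  rows <- vector("list", length(F_range))
  for (idx in seq_along(F_range)) {
    F <- F_range[idx]
    m <- fit_parafac(tensor, F, opts)
    models[[as.character(F)]] <- m
    rows[[idx]] <- data.frame(F = F, core_consistency = m$core_consistency,
                              rss = m$rss, converged = m$converged,
                              n_iter = m$n_iter)
  }
  tab <- do.call(rbind, rows)
  if (any(diff(tab$rss) > 1e-8 * max(tab$rss, 1)))
    warning("RSS increased with F: some fits likely hit local optima",
            call. = FALSE)
  structure(list(table = tab, models = models), class = "parafac_sweep")
}

#' @export
print.parafac_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Choose a working factor count from a sweep table
#'
#' A single-factor model has core consistency 100 by construction, so the
#' maximum over F is uninformative. The working count is instead the largest
#' F reached while core consistency stays acceptable: scanning upward from
#' F = 1, a candidate is accepted while its core consistency is at least
#' `cc_min` and has not collapsed by more than `max_drop` points relative to
#' the previously accepted model; the scan stops at the first violation.
#'
#' @param sweep_table data.frame with columns `F` and `core_consistency`
#'   (as produced by [model_sweep()]).
#' @param cc_min minimum acceptable core consistency (default 70, the
#'   conventional good-adjustment floor).
#' @param max_drop largest tolerated drop between consecutive accepted
#'   models (default 20 points).
#' @return The chosen factor count.
#' @export
choose_factor_count <- function(sweep_table, cc_min = 70, max_drop = 20) {
  ord <- order(sweep_table$F)
  Fs <- sweep_table$F[ord]
  cc <- sweep_table$core_consistency[ord]
  best <- Fs[1L]
  prev <- cc[1L]
  if (is.na(prev)) return(best)
  for (i in seq_along(Fs)[-1L]) {
    if (is.na(cc[i]) || cc[i] < cc_min || prev - cc[i] > max_drop) break
    best <- Fs[i]; prev <- cc[i]
  }
  best
}

tucker_congruence <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Match factors between two PARAFAC models
#'
#' Finds the factor permutation of `model_b` maximising the summed Tucker
#' congruence of concatenated (emission, excitation) loading profiles with
#' `model_a`. Used to track a factor's persistence across dataset subsets.
#'
#' @param model_a,model_b `parafac_model`s fitted on identical wavelength
#'   grids (factor counts may differ; the smaller count is matched).
#' @return List: `permutation` (for each factor of `model_a`, the matched
#'   column of `model_b`) and `congruence` (per matched pair, in `[-1, 1]`).
#' @export
match_factors <- function(model_a, model_b) {
  if (length(model_a$em) != length(model_b$em) ||
      length(model_a$ex) != length(model_b$ex) ||
      any(model_a$em != model_b$em) || any(model_a$ex != model_b$ex))
    stop("models are on different wavelength grids", call. = FALSE)
  Fa <- model_a$F; Fb <- model_b$F
  C <- matrix(0, Fa, Fb)
  for (f in seq_len(Fa)) for (g in seq_len(Fb))
    C[f, g] <- tucker_congruence(c(model_a$B[, f], model_a$C[, f]),
                                 c(model_b$B[, g], model_b$C[, g]))
  n <- min(Fa, Fb)
  # exhaustive assignment over the larger mode's permutations (F is small)
  if (Fa <= Fb) {
    best <- NULL; best_val <- -Inf
    for (p in all_permutations(Fb)) {
      sel <- p[seq_len(n)]
      val <- sum(C[cbind(seq_len(n), sel)])
      if (val > best_val) { best_val <- val; best <- sel }
    }
    perm <- best
  } else {
    best <- NULL; best_val <- -Inf
    for (p in all_permutations(Fa)) {
      sel <- p[seq_len(n)]
      val <- sum(C[cbind(sel, seq_len(n))])
      if (val > best_val) { best_val <- val; best <- p }
    }
    perm <- rep(NA_integer_, Fa)
    perm[best[seq_len(n)]] <- seq_len(n)
  }
  list(permutation = perm,
       congruence = C[cbind(seq_len(min(Fa, length(perm))),
                            perm[seq_len(min(Fa, length(perm)))])])
}

#' Peak excitation/emission wavelengths of a factor
#'
#' @param model a `parafac_model`.
#' @param f factor index, `1 <= f <= F`.
#' @return Named numeric `c(ex =, em =)`: argmax wavelengths of the
#'   excitation and emission loading columns (ties resolve to the lowest
#'   wavelength).
#' @export
peak_location <- function(model, f) {
  stopifnot(f >= 1, f <= model$F)
  c(ex = model$ex[which.max(model$C[, f])],
    em = model$em[which.max(model$B[, f])])
}
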