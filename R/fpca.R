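# Functional PCA of a pooled covariance surface: centering, raw and
# smoothed covariance, noise variance, eigendecomposition, scores and
# trajectory reconstruction.

#' Center each gene at its own mean
#'
#' Subtracts the per-gene mean over observed values, so that magnitude
#' differences between genes do not masquerade as shape variation.
#'
#' @param data Wide expression tibble (or internal matrix form).
#' @return List with `gene_means` (length-n) and `centered` (n x K matrix,
#'   `NA` where unobserved).
#' @export
center_by_gene_mean <- function(data) {
  em <- as_expr_mat(data)
  gene_means <- rowMeans(em$values, na.rm = TRUE)
  centered <- em$values - gene_means
  list(gene_ids = em$gene_ids, times = em$times,
       gene_means = gene_means, centered = centered, observed = em$observed)
}

#' Raw pooled covariance on the time grid
#'
#' Empirical covariance aggregated over all genes: entry (k, l) is the
#' average of products of centered values at times k and l over the genes
#' observed at both. The diagonal carries the noise-variance ridge and is
#' excluded later by the surface smoother.
#'
#' @param centered Result of [center_by_gene_mean()].
#' @return K x K symmetric matrix; entries with no jointly observed gene
#'   are `NA`.
#' @export
raw_covariance <- function(centered) {
  Z <- centered$centered
  if (nrow(Z) < 2) stop("need at least two genes for a pooled covariance")
  obs <- centered$observed + 0
  Z0 <- ifelse(is.na(Z), 0, Z)
  counts <- crossprod(obs)
  C <- crossprod(Z0)
  C <- ifelse(counts > 0, C / pmax(counts, 1), NA_real_)
  (C + t(C)) / 2
}

# Off-diagonal entries of a covariance matrix in long form.
offdiag_points <- function(raw, grid) {
  K <- length(grid)
  idx <- which(row(raw) != col(raw) & !is.na(raw), arr.ind = TRUE)
  list(s = grid[idx[, 1]], t = grid[idx[, 2]], z = raw[idx])
}

# Candidate bandwidths: 12-point logarithmic grid on
# [0.25 * median spacing, range / 2]. The low edge deliberately reaches
# below the grid spacing: GCV guards against overfitting through the
# hat-trace penalty, and candidates whose local fits turn singular are
# skipped during selection.
bandwidth_grid <- function(grid, n_bw = 12) {
  lo <- 0.25 * stats::median(diff(grid))
  hi <- diff(range(grid)) / 2
  exp(seq(log(lo), log(hi), length.out = n_bw))
}

# GCV score for the 2-D surface smoother at one bandwidth, evaluated on
# the off-diagonal raw entries (the fitting data themselves).
gcv_score_2d <- function(pts, h, cross = TRUE) {
  fit <- lwls2d_cpp(pts$s, pts$t, pts$z, pts$s, pts$t, h, cross, TRUE)
  if (anyNA(fit$fit) || anyNA(fit$hat)) return(Inf)
  N <- length(pts$z)
  tr <- sum(fit$hat)
  if (!is.finite(tr) || tr >= N) return(Inf)
  N * sum((pts$z - fit$fit)^2) / (N - tr)^2
}

#' Smooth the raw covariance surface
#'
#' Two-dimensional local weighted least-squares fit with a Gaussian kernel
#' and local basis \{1, ds, dt, ds dt\} (linear in each coordinate), applied
#' to the off-diagonal raw covariance entries only: the diagonal is
#' contaminated by the measurement-noise ridge and is excluded from the
#' fit, then filled in by evaluating the smooth surface there. The
#' bandwidth (shared by both coordinates) is chosen by generalized
#' cross-validation over a 12-point logarithmic grid spanning a quarter
#' of the median grid spacing to half the time range, unless given;
#' candidates whose local fits are singular are skipped.
#'
#' @param raw K x K raw covariance (diagonal present; it is ignored).
#' @param grid The K sampling times.
#' @param bandwidth Positive number, or `"gcv"` (default).
#' @param eval_grid Times at which to evaluate the smooth surface
#'   (default `grid`).
#' @return List with `smooth` (symmetric matrix on `eval_grid`),
#'   `bandwidth` (the one used) and `gcv` (per-candidate scores, or `NULL`).
#' @export
smooth_covariance <- function(raw, grid, bandwidth = "gcv", eval_grid = NULL) {
  K <- length(grid)
  if (K < 4) stop("need at least 4 time points to smooth a covariance surface")
  if (max(abs(raw - t(raw)), na.rm = TRUE) > 1e-8) stop("raw covariance must be symmetric")
  if (is.null(eval_grid)) eval_grid <- grid
  pts <- offdiag_points(raw, grid)

  targets <- expand.grid(s = eval_grid, t = eval_grid)
  eval_at <- function(h) {
    fit <- lwls2d_cpp(pts$s, pts$t, pts$z, targets$s, targets$t, h, TRUE, FALSE)$fit
    if (anyNA(fit)) NULL else fit
  }

  gcv <- NULL
  if (identical(bandwidth, "gcv")) {
    cand <- bandwidth_grid(grid)
    gcv <- vapply(cand, function(h) gcv_score_2d(pts, h), numeric(1))
    if (all(!is.finite(gcv))) stop("GCV failed at every candidate bandwidth")
    # best GCV candidate whose full-surface evaluation is well posed
    fit <- NULL
    for (j in order(gcv)) {
      if (!is.finite(gcv[j])) break
      fit <- eval_at(cand[j])
      if (!is.null(fit)) { h <- cand[j]; break }
    }
    if (is.null(fit)) stop("GCV failed at every candidate bandwidth")
    gcv <- tibble::tibble(bandwidth = cand, gcv = gcv)
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be a positive number or 'gcv'")
    repeat {
      fit <- eval_at(h)
      if (!is.null(fit)) break
      h <- h * 1.5
      if (h > 10 * diff(range(grid))) stop("covariance smoother failed even at very large bandwidths")
      warning("bandwidth too small for some target points; enlarged to ", signif(h, 4))
    }
  }
  S <- matrix(fit, length(eval_grid), length(eval_grid))
  list(smooth = (S + t(S)) / 2, bandwidth = h, gcv = gcv)
}

#' Estimate the measurement-noise variance
#'
#' The diagonal of the raw covariance equals the smooth covariance
#' diagonal plus the noise variance. The estimator takes the averaged
#' difference between a local linear smoother along the diagonal
#' (diagonal entries included) and a local quadratic smoother in the
#' direction perpendicular to the diagonal (diagonal entries excluded),
#' averaged over the central portion of the time range, and clips the
#' result at zero.
#'
#' @param raw K x K raw covariance.
#' @param grid The K sampling times (K >= 5).
#' @param bandwidth Positive number; default selects by 1-D GCV on the
#'   diagonal entries.
#' @param trim Fraction of the time range trimmed at each end before
#'   averaging (default 0.1, i.e. the central 80 percent).
#' @return Nonnegative scalar estimate of the noise variance.
#' @export
estimate_noise_variance <- function(raw, grid, bandwidth = NULL, trim = 0.1) {
  K <- length(grid)
  if (K < 5) stop("need at least 5 time points to estimate the noise variance")
  dvals <- diag(raw)
  if (is.null(bandwidth)) {
    cand <- bandwidth_grid(grid)
    scores <- vapply(cand, function(h) {
      fit <- lwls1d_cpp(grid, dvals, grid, h, 1L, TRUE)
      if (anyNA(fit$fit) || anyNA(fit$hat)) return(Inf)
      tr <- sum(fit$hat)
      if (!is.finite(tr) || tr >= K) return(Inf)
      K * sum((dvals - fit$fit)^2) / (K - tr)^2
    }, numeric(1))
    bandwidth <- cand[which.min(scores)]
  }
  V <- lwls1d_cpp(grid, dvals, grid, bandwidth, 1L, FALSE)$fit
  pts <- offdiag_points(raw, grid)
  Q <- lwls_diag_quad_cpp(pts$s, pts$t, pts$z, grid, bandwidth)
  a <- min(grid); b <- max(grid); R <- b - a
  keep <- grid >= a + trim * R & grid <= b - trim * R
  sigma2 <- mean(V[keep] - Q[keep], na.rm = TRUE)
  if (!is.finite(sigma2)) stop("noise-variance estimate is not finite")
  if (sigma2 < 0) {
    warning("negative noise-variance estimate (", signif(sigma2, 4), ") clipped to 0")
    sigma2 <- 0
  }
  sigma2
}

#' Eigendecompose a smoothed covariance surface
#'
#' Solves the discretized eigenproblem under trapezoid quadrature so the
#' resulting eigenfunctions are orthonormal in L2 on the observed range:
#' with W the diagonal quadrature-weight matrix, the symmetric problem
#' `W^(1/2) G W^(1/2)` is solved densely and eigenvectors are mapped back
#' by `W^(-1/2)`. Nonpositive eigenvalues (possible since a smoothed
#' surface need not be positive semi-definite) are dropped. Each
#' eigenfunction is scaled so that its entry of largest absolute value is
#' positive.
#'
#' @param smooth K x K symmetric smoothed covariance.
#' @param grid The K time points.
#' @return List with `eigenvalues` (positive, nonincreasing),
#'   `eigenfunctions` (K x L_max matrix of discretized functions), `fve`
#'   (cumulative fraction of variation explained) and `grid`.
#' @export
eigendecompose <- function(smooth, grid) {
  if (max(abs(smooth - t(smooth))) > 1e-8) stop("smoothed covariance must be symmetric")
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  B <- smooth * tcrossprod(sw)      # W^(1/2) G W^(1/2)
  es <- eigen(B, symmetric = TRUE)
  pos <- es$values > 0
  if (!any(pos)) stop("covariance estimate has no positive component")
  lambda <- es$values[pos]
  phi <- es$vectors[, pos, drop = FALSE] / sw
  # sign convention: largest-|value| entry positive
  for (l in seq_along(lambda)) {
    j <- which.max(abs(phi[, l]))
    if (phi[j, l] < 0) phi[, l] <- -phi[, l]
  }
  list(eigenvalues = lambda, eigenfunctions = phi,
       fve = cumsum(lambda) / sum(lambda), grid = grid)
}

#' Choose the number of components by fraction of variation explained
#'
#' @param eigenvalues Positive eigenvalues, nonincreasing.
#' @param method Only `"fve"` is supported.
#' @param threshold FVE threshold in (0, 1]; the smallest L whose
#'   cumulative FVE exceeds it is returned. Default 0.90.
#' @return Integer L.
#' @export
select_components <- function(eigenvalues, method = "fve", threshold = 0.90) {
  method <- match.arg(method, "fve")
  if (length(eigenvalues) < 1 || eigenvalues[1] <= 0) stop("need at least one positive eigenvalue")
  fve <- cumsum(eigenvalues) / sum(eigenvalues)
  L <- which(fve > threshold)[1]
  if (is.na(L)) L <- length(eigenvalues)
  as.integer(L)
}

# Fill missing entries of centered rows by linear interpolation inside the
# observed range and nearest-value extension at the ends.
interpolate_missing <- function(centered, grid) {
  out <- centered
  bad <- which(rowSums(is.na(centered)) > 0)
  for (i in bad) {
    obs <- !is.na(centered[i, ])
    out[i, ] <- approx(grid[obs], centered[i, obs], xout = grid, rule = 2)$y
  }
  out
}

#' Estimate functional principal component scores
#'
#' Dense-design integral scores: the trapezoid approximation of the inner
#' product of each centered trajectory with each eigenfunction. Missing
#' entries are linearly interpolated (nearest-value extension at the
#' range ends) before integration.
#'
#' @param centered Result of [center_by_gene_mean()], or an n x K matrix.
#' @param eig Result of [eigendecompose()].
#' @param L Number of components to score (default: all).
#' @return n x L score matrix.
#' @export
estimate_scores <- function(centered, eig, L = NULL) {
  Z <- if (is.list(centered)) centered$centered else centered
  if (is.null(L)) L <- ncol(eig$eigenfunctions)
  Z <- interpolate_missing(Z, eig$grid)
  w <- trapezoid_weights(eig$grid)
  phi <- eig$eigenfunctions[, seq_len(L), drop = FALSE]
  Z %*% (w * phi)
}

#' Reconstruct gene trajectories from scores
#'
#' Fitted trajectory = gene mean + sum of scores times eigenfunctions,
#' evaluated on the grid. When the original data are supplied, the
#' residual sum of squares over observed entries is returned as well.
#'
#' @param gene_means Length-n vector of gene means.
#' @param scores n x L score matrix.
#' @param eig Result of [eigendecompose()].
#' @param data Optional wide expression tibble / internal form for RSS.
#' @return List with `fitted` (n x K) and `rss` (length n, `NA` without data).
#' @export
reconstruct <- function(gene_means, scores, eig, data = NULL) {
  L <- ncol(scores)
  phi <- eig$eigenfunctions[, seq_len(L), drop = FALSE]
  fitted <- gene_means + scores %*% t(phi)
  rss <- rep(NA_real_, nrow(fitted))
  if (!is.null(data)) {
    em <- as_expr_mat(data)
    res2 <- (em$values - fitted)^2
    res2[!em$observed] <- 0
    rss <- rowSums(res2)
  }
  list(fitted = fitted, rss = rss)
}

#' Functional principal component analysis of an expression matrix
#'
#' Runs the full pooled-covariance pipeline: per-gene centering, raw
#' covariance aggregated over all genes, surface smoothing with
#' GCV-selected bandwidth (diagonal excluded), noise-variance estimation
#' from the diagonal ridge, eigendecomposition under trapezoid
#' quadrature, component selection by fraction of variation explained,
#' integral scores and trajectory reconstruction.
#'
#' @param data Wide expression tibble: `gene` column plus numeric-named
#'   time columns; `NA` marks missing values.
#' @param fve FVE threshold for choosing the number of components
#'   (default 0.90).
#' @param bandwidth Surface-smoother bandwidth, or `"gcv"` (default).
#' @param eval_grid Optional grid on which to tabulate eigenfunctions
#'   (defaults to the sampling times).
#' @return An object of class `tc_fpca`; see [tidy.tc_fpca()] and
#'   [glance.tc_fpca()].
#' @export
#' @examples
#' sim <- simulate_one_group(n = 50, pi0 = 1, seed = 1)
#' fit <- fpca(sim$data)
#' glance(fit)
fpca <- function(data, fve = 0.90, bandwidth = "gcv", eval_grid = NULL) {
  em <- as_expr_mat(data)
  cen <- center_by_gene_mean(em)
  raw <- raw_covariance(cen)
  sm <- smooth_covariance(raw, em$times, bandwidth = bandwidth, eval_grid = eval_grid)
  sigma2 <- estimate_noise_variance(raw, em$times)
  grid_out <- if (is.null(eval_grid)) em$times else eval_grid
  eig <- eigendecompose(sm$smooth, grid_out)
  L <- select_components(eig$eigenvalues, threshold = fve)
  # score on the observation grid (a subset of eval_grid in pooled designs)
  phi_obs <- eig$eigenfunctions[match(time_key(em$times), time_key(grid_out)), , drop = FALSE]
  eig_obs <- list(eigenvalues = eig$eigenvalues, eigenfunctions = phi_obs, grid = em$times)
  scores <- estimate_scores(cen, eig_obs, L = L)
  rec <- reconstruct(cen$gene_means, scores, eig_obs, data = em)
  res2 <- (em$values - cen$gene_means)^2
  res2[!em$observed] <- 0
  rss0 <- rowSums(res2)
  structure(
    list(gene_ids = em$gene_ids, times = em$times, data = em,
         gene_means = cen$gene_means, centered = cen$centered,
         raw_cov = raw, smooth_cov = sm$smooth, bandwidth = sm$bandwidth,
         sigma2 = sigma2, eig = eig, fve_threshold = fve, L = L,
         scores = scores, fitted = rec$fitted, rss0 = rss0, rss1 = rec$rss),
    class = "tc_fpca"
  )
}
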