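# Synthetic time-course data: Karhunen-Loeve curves on a Fourier
# eigenbasis plus i.i.d. Gaussian measurement noise, with ground-truth
# differential labels.

# Orthonormal cosine/sine basis on [a, b]:
#   l = 1: -sqrt(2/(b-a)) cos(2 pi (t-a)/(b-a))
#   l = 2:  sqrt(2/(b-a)) sin(2 pi (t-a)/(b-a))
#   l = 3: -sqrt(2/(b-a)) cos(4 pi (t-a)/(b-a))
cos_sin_basis <- function(t, a, b, l) {
  amp <- sqrt(2 / (b - a))
  u <- (t - a) / (b - a)
  switch(l,
    -amp * cos(2 * pi * u),
     amp * sin(2 * pi * u),
    -amp * cos(4 * pi * u)
  )
}

#' Eigenbasis of the one-group simulation model
#'
#' Three L2-orthonormal Fourier functions on `[a, b]`: a negated cosine,
#' the matching sine, and a negated cosine at double frequency.
#'
#' @param t Times inside `[a, b]`.
#' @param a,b Interval endpoints (defaults 100 and 305).
#' @return Length(t) x 3 matrix with columns `phi1..phi3`.
#' @export
basis_one_group <- function(t, a = 100, b = 305) {
  if (any(t < a | t > b)) stop("times must lie within [", a, ", ", b, "]")
  out <- vapply(1:3, function(l) cos_sin_basis(t, a, b, l), numeric(length(t)))
  out <- matrix(out, ncol = 3, dimnames = list(NULL, paste0("phi", 1:3)))
  out
}

#' Eigenbasis of the two-group simulation model
#'
#' The first two functions of the same Fourier family on `[a, b]`
#' (defaults 100 and 244).
#'
#' @inheritParams basis_one_group
#' @return Length(t) x 2 matrix with columns `psi1`, `psi2`.
#' @export
basis_two_group <- function(t, a = 100, b = 244) {
  if (any(t < a | t > b)) stop("times must lie within [", a, ", ", b, "]")
  out <- vapply(1:2, function(l) cos_sin_basis(t, a, b, l), numeric(length(t)))
  matrix(out, ncol = 2, dimnames = list(NULL, paste0("psi", 1:2)))
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a one-group time-course dataset
#'
#' Non-differential genes have flat true curves `X(t) = 0`; differential
#' genes have `X(t) = sum_l xi_l phi_l(t)` over the three-function
#' Fourier basis with independent scores `xi_l ~ N(0, lambda_l)`,
#' `lambda = (4, 2, 1)`. Observations add i.i.d. `N(0, 0.01)` noise. The
#' default design is 21 equally spaced time points on `[100, 305]`.
#'
#' @param n Number of genes.
#' @param pi0 Proportion of differential genes; exactly `round(pi0 * n)`
#'   genes are differential.
#' @param seed RNG seed.
#' @param times Optional custom sampling times inside `[100, 305]`.
#' @param lambda Score variances (default `c(4, 2, 1)`).
#' @param sigma2 Noise variance (default 0.01).
#' @return List with `data` (wide expression tibble), `truth` (tibble
#'   gene/differential), and `params`.
#' @export
simulate_one_group <- function(n, pi0, seed = 1, times = NULL,
                               lambda = c(4, 2, 1), sigma2 = 0.01) {
  stopifnot(n >= 2, pi0 >= 0, pi0 <= 1)
  a <- 100; b <- 305
  if (is.null(times)) times <- seq(a, b, length.out = 21)
  K <- length(times)
  phi <- basis_one_group(times, a, b)
  set.seed(seed)
  n_diff <- round(pi0 * n)
  truth <- rep(FALSE, n)
  truth[sample.int(n, n_diff)] <- TRUE
  X <- matrix(0, n, K)
  if (n_diff > 0) {
    xi <- matrix(rnorm(n_diff * 3), n_diff, 3) %*% diag(sqrt(lambda), 3)
    X[truth, ] <- xi %*% t(phi)
  }
  Y <- X + matrix(rnorm(n * K, sd = sqrt(sigma2)), n, K)
  ids <- sim_gene_ids(n)
  data <- dplyr::bind_cols(
    tibble::tibble(gene = ids),
    tibble::as_tibble(`colnames<-`(Y, format(times, trim = TRUE, digits = 10)))
  )
  list(
    data = data,
    truth = tibble::tibble(gene = ids, differential = truth),
    params = list(model = "one-group", n = n, pi0 = pi0, lambda = lambda,
                  sigma2 = sigma2, times = times, seed = seed)
  )
}

#' Simulate a two-group time-course dataset
#'
#' Both groups draw `X_j(t) = sum_l (xi_l + gamma_jl) psi_l(t)` on the
#' two-function Fourier basis of `[100, 244]`. The shared scores
#' `xi_l ~ N(0, lambda_xi_l)` are drawn once per gene, so
#' non-differential genes (`gamma = 0`) have identical true curves in
#' both groups and the between-group null holds for them; differential
#' genes add group-specific `gamma_jl ~ N(0, lambda_gamma_l)` drawn
#' independently per group. `lambda_xi = (4, 2)`,
#' `lambda_gamma = (5, 3)`; noise is `N(0, 0.01)`. Default designs: 15
#' ("wild") and 22 ("mutant") equally spaced points on `[100, 244]`.
#'
#' @inheritParams simulate_one_group
#' @param times Optional list of two time vectors inside `[100, 244]`.
#' @param lambda_xi,lambda_gamma Score variances of the shared and the
#'   differential components.
#' @return List with `data` (list of two wide expression tibbles),
#'   `truth`, and `params`.
#' @export
simulate_two_group <- function(n, pi0, seed = 1, times = NULL,
                               lambda_xi = c(4, 2), lambda_gamma = c(5, 3),
                               sigma2 = 0.01) {
  stopifnot(n >= 2, pi0 >= 0, pi0 <= 1)
  a <- 100; b <- 244
  if (is.null(times)) {
    times <- list(seq(a, b, length.out = 15), seq(a, b, length.out = 22))
  }
  stopifnot(length(times) == 2)
  set.seed(seed)
  n_diff <- round(pi0 * n)
  truth <- rep(FALSE, n)
  truth[sample.int(n, n_diff)] <- TRUE
  ids <- sim_gene_ids(n)
  xi <- matrix(rnorm(n * 2), n, 2) %*% diag(sqrt(lambda_xi), 2)
  data <- vector("list", 2)
  for (j in 1:2) {
    psi <- basis_two_group(times[[j]], a, b)
    K <- length(times[[j]])
    gam <- matrix(rnorm(n * 2), n, 2) %*% diag(sqrt(lambda_gamma), 2)
    gam[!truth, ] <- 0
    Y <- (xi + gam) %*% t(psi) + matrix(rnorm(n * K, sd = sqrt(sigma2)), n, K)
    data[[j]] <- dplyr::bind_cols(
      tibble::tibble(gene = ids),
      tibble::as_tibble(`colnames<-`(Y, format(times[[j]], trim = TRUE, digits = 10)))
    )
  }
  names(data) <- c("wild", "mutant")
  list(
    data = data,
    truth = tibble::tibble(gene = ids, differential = truth),
    params = list(model = "two-group", n = n, pi0 = pi0,
                  lambda_xi = lambda_xi, lambda_gamma = lambda_gamma,
                  sigma2 = sigma2, times = times, seed = seed)
  )
}
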