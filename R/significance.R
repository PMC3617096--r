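# Variance-stabilized permutation F-test: statistics, permutation nulls,
# genewise and pooled p-values, FDR control.

#' Variance-stabilized F-statistic
#'
#' `F = (rss0 - rss1) / (rss1 + delta)`: the improvement of the
#' eigenfunction fit over the null fit, relative to the residual noise,
#' stabilized by `delta` so that genes with tiny residuals do not blow
#' up the statistic. No degrees-of-freedom scaling is applied; with a
#' common design and a common number of components it would not change
#' the ordering of the statistics.
#'
#' @param rss0,rss1 Nonnegative residual sums of squares under the null
#'   and alternative fits.
#' @param delta Positive stabilizer, normally the estimated noise
#'   variance (floored at 1e-8).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(rss0, rss1, delta) {
  if (any(rss0 < 0) || any(rss1 < 0)) stop("residual sums of squares must be nonnegative")
  delta <- max(delta, 1e-8)
  (rss0 - rss1) / (rss1 + delta)
}

#' Genewise permutation p-values
#'
#' Each gene's p-value counts exceedances among its own permutation
#' statistics: `p_i = #\{b : F_i^(b) >= F_i\} / B`.
#'
#' @param observed_f Length-n observed statistics.
#' @param null Permutation null: a B x n matrix of statistics (or the
#'   list returned by the `permute_*` functions).
#' @param smooth_p Add-one smoothing `(count + 1) / (B + 1)` for users
#'   concerned about exact-zero p-values (default `FALSE`, matching the
#'   plain counting definition).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
pvalues_genewise <- function(observed_f, null, smooth_p = FALSE) {
  stats <- if (is.list(null)) null$stats else null
  if (ncol(stats) != length(observed_f)) stop("null and observed statistics disagree in length")
  B <- nrow(stats)
  cnt <- colSums(stats >= rep(observed_f, each = B))
  if (smooth_p) (cnt + 1) / (B + 1) else cnt / B
}

#' Pooled permutation p-values
#'
#' Exceedances are counted over the permutation statistics of all genes:
#' `p_i = #\{(b, j) : F_j^(b) >= F_i\} / (n B)`. This preserves the
#' ordering of the observed statistics in the ordering of the p-values
#' and yields fewer false positives than the genewise definition.
#'
#' @inheritParams pvalues_genewise
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
pvalues_pooled <- function(observed_f, null, smooth_p = FALSE) {
  stats <- if (is.list(null)) null$stats else null
  if (ncol(stats) != length(observed_f)) stop("null and observed statistics disagree in length")
  S <- sort(as.numeric(stats))
  nB <- length(S)
  cnt <- nB - findInterval(observed_f, S, left.open = TRUE)  # #\{S >= F_i\}
  if (smooth_p) (cnt + 1) / (nB + 1) else cnt / nB
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p_adj_(k) = min over m >= k of n p_(m) / m`,
#' capped at 1) with rejection at the requested level, computed with
#' [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param level FDR level for the rejection flags (default 0.05).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
bh_adjust <- function(p, level = 0.05) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p_adjusted <- p.adjust(p, method = "BH")
  list(p_adjusted = p_adjusted, rejected = p_adjusted <= level)
}

#' Permutation null for the one-group test
#'
#' Each permutation sample randomly re-matches the expression
#' measurements with their sampling times: one random permutation of the
#' K time labels per sample, applied identically to every gene
#' (preserving inter-gene correlation under the null); set
#' `joint = FALSE` to draw an independent permutation per gene. For
#' efficiency the eigenfunctions and the stabilizer are frozen at their
#' observed-data values, and gene means (hence the null RSS) are
#' permutation-invariant.
#'
#' @param data Wide expression tibble.
#' @param eig Eigensystem from [eigendecompose()] (or a `tc_fpca` fit,
#'   whose selected components are used).
#' @param delta Stabilizer frozen from the observed data.
#' @param B Number of permutation samples.
#' @param seed RNG seed.
#' @param L Number of components (default: all columns of the
#'   eigensystem, or the fit's selected L).
#' @param joint Apply the same time permutation to every gene (default).
#' @param perms Optional B x K integer matrix of predetermined
#'   permutations (test hook; overrides `B`, `seed`, `joint`).
#' @return List with `stats` (B x n matrix of null F-statistics), `B`,
#'   and `seed`.
#' @export
permute_one_group <- function(data, eig, delta, B = 1000, seed = 1,
                              L = NULL, joint = TRUE, perms = NULL) {
  if (inherits(eig, "tc_fpca")) {
    if (is.null(L)) L <- eig$L
    eig <- eig$eig
  }
  em <- as_expr_mat(data)
  cen <- center_by_gene_mean(em)
  null_one_group(em, cen, eig, delta, B = B, seed = seed, L = L,
                 joint = joint, perms = perms)
}

# Internal permutation engine; `cen` precomputed by the caller.
null_one_group <- function(em, cen, eig, delta, B, seed, L = NULL,
                           joint = TRUE, perms = NULL) {
  K <- length(em$times)
  n <- length(em$gene_ids)
  if (is.null(L)) L <- ncol(eig$eigenfunctions)
  phi <- eig$eigenfunctions[, seq_len(L), drop = FALSE]
  w <- trapezoid_weights(em$times)
  phiw <- w * phi
  tphi <- t(phi)
  Z <- cen$centered
  res0 <- Z; res0[!em$observed] <- 0
  rss0 <- rowSums(res0^2)
  has_missing <- !all(em$observed)
  delta <- max(delta, 1e-8)

  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    if (ncol(perms) != K) stop("perms must have one column per time point")
    B <- nrow(perms)
  } else {
    set.seed(seed)
  }
  stats <- matrix(NA_real_, B, n)
  for (b in seq_len(B)) {
    if (!is.null(perms)) {
      Zp <- Z[, perms[b, ], drop = FALSE]
      obs_p <- em$observed[, perms[b, ], drop = FALSE]
    } else if (joint) {
      pb <- sample.int(K)
      Zp <- Z[, pb, drop = FALSE]
      obs_p <- em$observed[, pb, drop = FALSE]
    } else {
      idx <- vapply(seq_len(n), function(i) sample.int(K), integer(K))  # K x n
      sel <- cbind(rep(seq_len(n), each = K), as.vector(idx))
      Zp <- matrix(Z[sel], n, K, byrow = TRUE)
      obs_p <- matrix(em$observed[sel], n, K, byrow = TRUE)
    }
    Zs <- if (has_missing) {
      tmp <- Zp; tmp[!obs_p] <- NA_real_
      interpolate_missing(tmp, em$times)
    } else Zp
    S <- Zs %*% phiw
    res <- Zp - S %*% tphi
    res[!obs_p] <- 0
    rss1 <- rowSums(res^2)
    stats[b, ] <- (rss0 - rss1) / (rss1 + delta)
  }
  list(stats = stats, B = B, seed = seed)
}

# Assemble a tidy result table from observed statistics and a null.
ftest_table <- function(gene_ids, rss0, rss1, f, null, pvalue, fdr_level, smooth_p) {
  p <- switch(pvalue,
    pooled = pvalues_pooled(f, null, smooth_p = smooth_p),
    genewise = pvalues_genewise(f, null, smooth_p = smooth_p)
  )
  adj <- bh_adjust(p, level = fdr_level)
  tibble::tibble(
    gene = gene_ids, rss0 = rss0, rss1 = rss1, statistic = f,
    p_value = p, p_adjusted = adj$p_adjusted, rejected = adj$rejected
  )
}

#' One-group test for non-flat expression profiles
#'
#' Tests, for every gene, whether the expression curve is constant in
#' time. The null fit is the gene's own mean; the alternative fit is the
#' FPCA reconstruction sharing eigenfunctions across all genes. The null
#' distribution of the variance-stabilized F-statistics is generated by
#' permuting time labels, with the eigenfunctions and stabilizer frozen
#' at their observed-data values.
#'
#' @param data Wide expression tibble (`gene` column + numeric-named time
#'   columns).
#' @param fve FVE threshold for the number of components (default 0.90).
#' @param B Number of permutations (default 10000; at least a few hundred
#'   are needed for meaningful p-values).
#' @param seed RNG seed.
#' @param pvalue `"pooled"` (exceedances counted over all genes' null
#'   statistics; the default) or `"genewise"`.
#' @param fdr_level Benjamini-Hochberg FDR level (default 0.05).
#' @param bandwidth Covariance-smoother bandwidth or `"gcv"`.
#' @param joint One shared permutation per sample (default) or
#'   per-gene-independent permutations.
#' @param smooth_p Add-one p-value smoothing (default `FALSE`).
#' @param keep_null Retain the B x n null statistic matrix in the result.
#' @return Object of class `tc_ftest`; `tidy()` gives the per-gene table
#'   (gene, rss0, rss1, statistic, p_value, p_adjusted, rejected),
#'   `glance()` the test-level settings.
#' @export
#' @examples
#' sim <- simulate_one_group(n = 60, pi0 = 0.5, seed = 1)
#' res <- one_group_test(sim$data, B = 200, seed = 2, fdr_level = 0.05)
#' dplyr::count(tidy(res), rejected)
one_group_test <- function(data, fve = 0.90, B = 10000, seed = 1,
                           pvalue = c("pooled", "genewise"), fdr_level = 0.05,
                           bandwidth = "gcv", joint = TRUE, smooth_p = FALSE,
                           keep_null = FALSE) {
  pvalue <- match.arg(pvalue)
  if (B < 100) warning("B < 100 permutations gives very coarse p-values")
  em <- as_expr_mat(data)
  fit <- fpca(em, fve = fve, bandwidth = bandwidth)
  delta <- max(fit$sigma2, 1e-8)
  f <- f_statistic(fit$rss0, fit$rss1, delta)
  cen <- list(centered = fit$centered, gene_means = fit$gene_means)
  eig_sel <- list(eigenvalues = fit$eig$eigenvalues[seq_len(fit$L)],
                  eigenfunctions = fit$eig$eigenfunctions[, seq_len(fit$L), drop = FALSE],
                  grid = fit$times)
  null <- null_one_group(em, cen, eig_sel, delta, B = B, seed = seed, joint = joint)
  table <- ftest_table(em$gene_ids, fit$rss0, fit$rss1, f, null, pvalue, fdr_level, smooth_p)
  structure(
    list(table = table, delta = delta, sigma2 = fit$sigma2, L = fit$L,
         bandwidth = fit$bandwidth, B = null$B, seed = seed, pvalue = pvalue,
         fdr_level = fdr_level, design = "one-group", fpca = fit,
         null = if (keep_null) null else NULL),
    class = "tc_ftest"
  )
}

#' Write a test result table to TSV
#'
#' Columns `gene, rss0, rss1, F, p, p_adjusted, rejected`, preceded by
#' `#`-prefixed metadata lines recording the stabilizer, the number of
#' components per arm, bandwidths, B and the seed.
#'
#' @param result A `tc_ftest` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(result, path) {
  stopifnot(inherits(result, "tc_ftest"))
  g <- glance(result)
  meta <- sprintf("# %s = %s", names(g),
                  vapply(g, function(x) format(x, digits = 10), character(1)))
  tab <- result$table
  fmt <- function(x) if (is.double(x)) format(x, trim = TRUE, digits = 10, scientific = FALSE) else as.character(x)
  body <- do.call(paste, c(lapply(tab, fmt), sep = "\t"))
  writeLines(c(meta, paste(c("gene", "rss0", "rss1", "F", "p", "p_adjusted", "rejected"),
                           collapse = "\t"), body), path)
  invisible(path)
}
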