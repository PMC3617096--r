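# Multi-group comparison: pooled-null vs per-group FPCA fits, and
# permutation of group labels within time points or time bins.

# Linear-interpolation operator from source times to destination times
# (nearest-value extension outside the source range): a |src| x |dst|
# matrix applied on the right of a row-wise value matrix.
interp_matrix <- function(src, dst) {
  m <- length(src)
  M <- matrix(0, m, length(dst))
  i <- findInterval(dst, src)
  for (k in seq_along(dst)) {
    if (i[k] <= 0) M[1, k] <- 1
    else if (i[k] >= m) M[m, k] <- 1
    else {
      a <- (dst[k] - src[i[k]]) / (src[i[k] + 1] - src[i[k]])
      M[i[k], k] <- 1 - a
      M[i[k] + 1, k] <- a
    }
  }
  M
}

bin_index <- function(t, edges) {
  i <- findInterval(t, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Build a time-bin scheme for multi-group permutation
#'
#' Divides the common time interval into contiguous bins of the given
#' width (the last bin is closed at the right end). Bins in which any
#' group has no observation are dropped from the permutation (their
#' observations still enter the F-statistics); a warning names each such
#' bin.
#'
#' @param groups List of wide expression tibbles, or of numeric time
#'   vectors.
#' @param bin_width Positive bin width in time units.
#' @return Object of class `tc_bins`: list with `edges`, a `bins` tibble
#'   (bin, lower, upper, per-group counts, retained) and the bin index of
#'   every group's time points.
#' @export
make_bins <- function(groups, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  tl <- lapply(groups, function(g) if (is.numeric(g)) g else as_expr_mat(g)$times)
  a <- min(unlist(tl)); b <- max(unlist(tl))
  edges <- seq(a, b, by = bin_width)
  if (tail(edges, 1) < b) edges <- c(edges, b)
  if (length(edges) < 2) edges <- c(a, b)
  nb <- length(edges) - 1L
  counts <- vapply(tl, function(tt) tabulate(bin_index(tt, edges), nb), integer(nb))
  counts <- matrix(counts, nrow = nb)
  present <- counts >= 1L
  retained <- apply(present, 1, all)
  partial <- which(!retained & apply(present, 1, any))
  for (m in partial) {
    warning(sprintf("bin [%g, %g) lacks observations from some group and is dropped from permutation",
                    edges[m], edges[m + 1]))
  }
  if (!any(retained)) stop("all bins dropped: no bin contains observations from every group")
  bins <- tibble::tibble(
    bin = seq_len(nb), lower = edges[-length(edges)], upper = edges[-1],
    retained = retained
  )
  for (j in seq_along(tl)) bins[[paste0("n_group", j)]] <- counts[, j]
  structure(
    list(edges = edges, bins = bins,
         assignment = lapply(tl, bin_index, edges = edges)),
    class = "tc_bins"
  )
}

# Collapse columns sharing a time label by averaging (after centering).
# Fast path when times are unique and there are no missing values.
collapse_columns <- function(values, times, observed = NULL) {
  key <- time_key(times)
  uk <- sort(unique(key))
  if (!anyDuplicated(key) && is.null(observed)) {
    ord <- order(key)
    return(list(values = values[, ord, drop = FALSE], times = uk))
  }
  m <- length(key)
  Mind <- matrix(0, m, length(uk))
  Mind[cbind(seq_len(m), match(key, uk))] <- 1
  if (is.null(observed)) {
    vals <- values %*% Mind
    vals <- sweep(vals, 2, colSums(Mind), "/")
  } else {
    v0 <- ifelse(observed, values, 0)
    vals <- v0 %*% Mind
    cnts <- (observed + 0) %*% Mind
    vals <- ifelse(cnts > 0, vals / pmax(cnts, 1), NA_real_)
  }
  list(values = vals, times = uk)
}

# RSS of one arm's eigenfunction fit to a column subset of the pooled
# matrix: per-gene mean over the columns, integral scores against `phi`
# tabulated on the union grid (keyed by `ukey`), residuals over observed
# entries of the original columns. Scores are always integrated on the
# full union grid, with the columns' centered values carried over by
# linear interpolation, so that quadrature is identical for the observed
# arm and for every permuted arm regardless of which times the arm holds.
arm_rss <- function(pooled, cols, phi, ukey, w_union) {
  Y <- pooled$values[, cols, drop = FALSE]
  obs <- pooled$observed[, cols, drop = FALSE]
  tms <- pooled$times[cols]
  ord <- order(tms)
  Y <- Y[, ord, drop = FALSE]; obs <- obs[, ord, drop = FALSE]; tms <- tms[ord]
  has_missing <- !all(obs)
  mu <- if (has_missing) rowMeans(ifelse(obs, Y, NA), na.rm = TRUE) else rowMeans(Y)
  Z <- Y - mu
  cc <- collapse_columns(Z, tms, observed = if (has_missing) obs else NULL)
  uidx <- match(time_key(cc$times), ukey)
  # carry the centered values onto the union grid by linear interpolation
  if (anyNA(cc$values)) {
    Zu <- matrix(NA_real_, nrow(Z), length(ukey))
    Zu[, uidx] <- cc$values
    Zu <- interpolate_missing(Zu, as.numeric(ukey))
  } else {
    Zu <- cc$values %*% interp_matrix(as.numeric(cc$times), as.numeric(ukey))
  }
  S <- Zu %*% (w_union * phi)
  fitted_c <- S %*% t(phi[uidx, , drop = FALSE])
  map <- match(time_key(tms), time_key(cc$times))
  res <- Z - fitted_c[, map, drop = FALSE]
  res[!obs] <- 0
  rowSums(res^2)
}

# Observed-data setup shared by the multi-group test and its
# permutation null: pooled columns, union grid, fixed eigensystems per
# arm, fixed stabilizer, observed RSS0/RSS1/F.
multi_setup <- function(ems, fve = 0.90, bandwidth = "gcv") {
  J <- length(ems)
  if (J < 2) stop("need at least two groups")
  ids <- ems[[1]]$gene_ids
  for (j in seq_len(J)[-1]) {
    if (!identical(ems[[j]]$gene_ids, ids)) stop("gene id lists differ across groups")
  }
  n <- length(ids)
  union_grid <- sort(unique(time_key(unlist(lapply(ems, `[[`, "times")))))
  ukey <- time_key(union_grid)
  w_union <- trapezoid_weights(union_grid)

  pooled <- list(
    values = do.call(cbind, lapply(ems, `[[`, "values")),
    observed = do.call(cbind, lapply(ems, `[[`, "observed")),
    times = unlist(lapply(ems, `[[`, "times")),
    group = rep(seq_len(J), vapply(ems, function(e) length(e$times), integer(1)))
  )
  has_missing <- !all(pooled$observed)

  # pooled-null arm on the union grid
  mu0 <- if (has_missing) rowMeans(ifelse(pooled$observed, pooled$values, NA), na.rm = TRUE) else rowMeans(pooled$values)
  Z0 <- pooled$values - mu0
  cc0 <- collapse_columns(Z0, pooled$times, observed = if (has_missing) pooled$observed else NULL)
  cen0 <- list(centered = cc0$values, observed = !is.na(cc0$values))
  raw0 <- raw_covariance(cen0)
  sm0 <- smooth_covariance(raw0, cc0$times, bandwidth = bandwidth, eval_grid = union_grid)
  eig0 <- eigendecompose(sm0$smooth, union_grid)
  L0 <- select_components(eig0$eigenvalues, threshold = fve)
  phi0 <- eig0$eigenfunctions[, seq_len(L0), drop = FALSE]

  # per-group arms, eigenfunctions tabulated on the union grid
  arms <- vector("list", J)
  for (j in seq_len(J)) {
    cen_j <- center_by_gene_mean(ems[[j]])
    raw_j <- raw_covariance(cen_j)
    sm_j <- smooth_covariance(raw_j, ems[[j]]$times, bandwidth = bandwidth,
                              eval_grid = union_grid)
    sig_j <- estimate_noise_variance(raw_j, ems[[j]]$times)
    eig_j <- eigendecompose(sm_j$smooth, union_grid)
    L_j <- select_components(eig_j$eigenvalues, threshold = fve)
    arms[[j]] <- list(phi = eig_j$eigenfunctions[, seq_len(L_j), drop = FALSE],
                      L = L_j, sigma2 = sig_j, bandwidth = sm_j$bandwidth,
                      eig = eig_j)
  }
  delta <- max(max(vapply(arms, `[[`, numeric(1), "sigma2")), 1e-8)

  # observed statistics; RSS0 is invariant under group-label permutation
  rss0 <- arm_rss(pooled, seq_along(pooled$times), phi0, ukey, w_union)
  rss1 <- rep(0, n)
  for (j in seq_len(J)) {
    rss1 <- rss1 + arm_rss(pooled, which(pooled$group == j), arms[[j]]$phi, ukey, w_union)
  }
  f <- (rss0 - rss1) / (rss1 + delta)

  list(gene_ids = ids, n = n, J = J, pooled = pooled, union_grid = union_grid,
       ukey = ukey, w_union = w_union, mu0 = mu0, phi0 = phi0, L0 = L0, eig0 = eig0,
       bandwidth0 = sm0$bandwidth, arms = arms, delta = delta,
       rss0 = rss0, rss1 = rss1, f = f)
}

# Resolve the permutation scheme into per-bin pooled column index sets.
scheme_columns <- function(setup, scheme) {
  tms <- setup$pooled$times
  grp <- setup$pooled$group
  if (is.null(scheme)) {
    # per-time-point permutation requires a shared grid
    keys <- lapply(split(time_key(tms), grp), function(k) sort(unique(k)))
    if (length(unique(keys)) != 1L) {
      stop("groups have different time grids; supply bin_width for binned permutation")
    }
    bins <- split(seq_along(tms), time_key(tms))
  } else {
    stopifnot(inherits(scheme, "tc_bins"))
    idx <- bin_index(tms, scheme$edges)
    retained <- scheme$bins$bin[scheme$bins$retained]
    bins <- split(seq_along(tms), idx)
    bins <- bins[names(bins) %in% as.character(retained)]
    # diagnostics: every retained bin must hold every group
    for (nm in names(bins)) {
      g <- unique(grp[bins[[nm]]])
      if (length(g) < setup$J) {
        stop("retained bin ", nm, " lacks observations from group(s) ",
             paste(setdiff(seq_len(setup$J), g), collapse = ", "))
      }
    }
  }
  unname(bins)
}

# Permutation engine: re-partition group labels within bins, recompute
# per-group RSS with the fixed eigensystems and stabilizer.
null_multi_group <- function(setup, bins, B, seed, assignments = NULL) {
  grp0 <- setup$pooled$group
  if (!is.null(assignments)) {
    B <- length(assignments)
  } else {
    set.seed(seed)
  }
  stats <- matrix(NA_real_, B, setup$n)
  for (b in seq_len(B)) {
    lab <- grp0
    if (!is.null(assignments)) {
      lab <- assignments[[b]]
      if (length(lab) != length(grp0)) stop("assignment length must match pooled columns")
    } else {
      for (cols in bins) lab[cols] <- grp0[cols][sample.int(length(cols))]
    }
    rss1 <- rep(0, setup$n)
    for (j in seq_len(setup$J)) {
      rss1 <- rss1 + arm_rss(setup$pooled, which(lab == j), setup$arms[[j]]$phi,
                             setup$ukey, setup$w_union)
    }
    stats[b, ] <- (setup$rss0 - rss1) / (rss1 + setup$delta)
  }
  list(stats = stats, B = B, seed = seed)
}

#' Permutation null for the multi-group test
#'
#' Within each time point (or each retained time bin), the pooled
#' observations are randomly re-partitioned into groups of the original
#' sizes; the same re-partition is applied to every gene. F-statistics
#' are recomputed with the eigensystems and stabilizer frozen at their
#' observed-data values; the pooled-null RSS is invariant under the
#' re-partition and is reused.
#'
#' @param groups List of wide expression tibbles with identical gene ids.
#' @param bin_width Bin width for groups with different time grids;
#'   `NULL` (default) permutes within exact time points and requires a
#'   shared grid.
#' @param B Number of permutation samples.
#' @param seed RNG seed.
#' @param fve,bandwidth Passed to the FPCA arms.
#' @param assignments Optional list (length B) of integer vectors giving
#'   each pooled column's group per sample (test hook; overrides `B`,
#'   `seed`).
#' @return List with `stats` (B x n null F matrix), `B`, `seed`.
#' @export
permute_multi_group <- function(groups, bin_width = NULL, B = 1000, seed = 1,
                                fve = 0.90, bandwidth = "gcv", assignments = NULL) {
  ems <- lapply(groups, as_expr_mat)
  setup <- multi_setup(ems, fve = fve, bandwidth = bandwidth)
  scheme <- if (is.null(bin_width)) NULL else make_bins(lapply(ems, `[[`, "times"), bin_width)
  bins <- scheme_columns(setup, scheme)
  null_multi_group(setup, bins, B = B, seed = seed, assignments = assignments)
}

#' Multi-group test for differential expression profiles
#'
#' Tests, for every gene, whether its expression profile is the same in
#' all experimental groups. The alternative fit runs a separate FPCA per
#' group (own eigenfunctions, own component number, own noise variance);
#' the null fit pools the observations of all groups into one sample on
#' the union time grid. The variance-stabilized F-statistic uses
#' `delta = max` of the per-group noise variances, and its null
#' distribution is generated by re-partitioning group labels within time
#' points, or within time bins when the groups were sampled on different
#' grids.
#'
#' @inheritParams one_group_test
#' @param groups List of at least two wide expression tibbles with
#'   identical gene ids.
#' @param bin_width Bin width for the permutation when group time grids
#'   differ; `NULL` (default) permutes within exact time points.
#' @return Object of class `tc_ftest`; see [one_group_test()].
#' @export
#' @examples
#' sim <- simulate_two_group(n = 60, pi0 = 0.5, seed = 1)
#' res <- multi_group_test(sim$data, B = 200, seed = 2, bin_width = 10)
#' dplyr::count(tidy(res), rejected)
multi_group_test <- function(groups, fve = 0.90, B = 10000, seed = 1,
                             pvalue = c("pooled", "genewise"), fdr_level = 0.05,
                             bandwidth = "gcv", bin_width = NULL,
                             smooth_p = FALSE, keep_null = FALSE) {
  pvalue <- match.arg(pvalue)
  if (B < 100) warning("B < 100 permutations gives very coarse p-values")
  ems <- lapply(groups, as_expr_mat)
  setup <- multi_setup(ems, fve = fve, bandwidth = bandwidth)
  scheme <- if (is.null(bin_width)) NULL else make_bins(lapply(ems, `[[`, "times"), bin_width)
  bins <- scheme_columns(setup, scheme)
  null <- null_multi_group(setup, bins, B = B, seed = seed)
  table <- ftest_table(setup$gene_ids, setup$rss0, setup$rss1, setup$f,
                       null, pvalue, fdr_level, smooth_p)
  structure(
    list(table = table, delta = setup$delta,
         sigma2 = vapply(setup$arms, `[[`, numeric(1), "sigma2"),
         L = c(pooled = setup$L0, vapply(setup$arms, `[[`, integer(1), "L")),
         bandwidth = c(pooled = setup$bandwidth0,
                       vapply(setup$arms, `[[`, numeric(1), "bandwidth")),
         B = null$B, seed = seed, pvalue = pvalue, fdr_level = fdr_level,
         design = "multi-group", bins = scheme, setup = setup,
         null = if (keep_null) null else NULL),
    class = "tc_ftest"
  )
}
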