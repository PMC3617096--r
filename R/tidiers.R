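# Broom-style accessors and print methods for fitted objects.

#' Tidy a functional PCA fit
#'
#' @param x A `tc_fpca` object from [fpca()].
#' @param ... Unused.
#' @return Per-gene tibble: gene, mean, null and eigenfunction-fit RSS,
#'   and one `score_l` column per selected component.
#' @method tidy tc_fpca
#' @export
tidy.tc_fpca <- function(x, ...) {
  sc <- x$scores
  colnames(sc) <- paste0("score_", seq_len(ncol(sc)))
  dplyr::bind_cols(
    tibble::tibble(gene = x$gene_ids, mean = x$gene_means,
                   rss0 = x$rss0, rss1 = x$rss1),
    tibble::as_tibble(sc)
  )
}

#' Glance at a functional PCA fit
#'
#' @inheritParams tidy.tc_fpca
#' @return One-row tibble: sizes, selected L, cumulative FVE at L, noise
#'   variance, bandwidth and leading eigenvalues.
#' @method glance tc_fpca
#' @export
glance.tc_fpca <- function(x, ...) {
  ev <- x$eig$eigenvalues
  out <- tibble::tibble(
    n_genes = length(x$gene_ids), n_times = length(x$times),
    L = x$L, fve = x$eig$fve[x$L], sigma2 = x$sigma2, bandwidth = x$bandwidth
  )
  for (l in seq_len(min(3, length(ev)))) out[[paste0("lambda_", l)]] <- ev[l]
  out
}

#' @export
print.tc_fpca <- function(x, ...) {
  cat("Functional PCA fit (pooled covariance)\n")
  cat(sprintf("  %d genes x %d time points on [%g, %g]\n",
              length(x$gene_ids), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  L = %d components (FVE %.1f%%), sigma^2 = %.4g, bandwidth = %.4g\n",
              x$L, 100 * x$eig$fve[x$L], x$sigma2, x$bandwidth))
  invisible(x)
}

#' Tidy a permutation F-test result
#'
#' @param x A `tc_ftest` object.
#' @param ... Unused.
#' @return Per-gene tibble: gene, rss0, rss1, statistic, p_value,
#'   p_adjusted, rejected.
#' @method tidy tc_ftest
#' @export
tidy.tc_ftest <- function(x, ...) x$table

#' Glance at a permutation F-test result
#'
#' @inheritParams tidy.tc_ftest
#' @return One-row tibble with the test settings (design, stabilizer,
#'   components, bandwidths, permutations, seed, p-value mode, FDR
#'   level) and the rejection count.
#' @method glance tc_ftest
#' @export
glance.tc_ftest <- function(x, ...) {
  tibble::tibble(
    design = x$design, n_genes = nrow(x$table),
    delta = x$delta, L = paste(x$L, collapse = "/"),
    bandwidth = paste(signif(x$bandwidth, 6), collapse = "/"),
    B = x$B, seed = x$seed, pvalue = x$pvalue, fdr_level = x$fdr_level,
    n_rejected = sum(x$table$rejected)
  )
}

#' @export
print.tc_ftest <- function(x, ...) {
  cat(sprintf("Permutation F-test (%s), %d genes, B = %d, %s p-values\n",
              x$design, nrow(x$table), x$B, x$pvalue))
  cat(sprintf("  delta = %.4g, rejected %d genes at FDR %.3g\n",
              x$delta, sum(x$table$rejected), x$fdr_level))
  print(x$table, n = 10)
  invisible(x)
}
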