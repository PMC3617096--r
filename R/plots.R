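# ggplot2 graphics for fitted objects.

#' Plot a functional PCA fit
#'
#' @param object A `tc_fpca` object.
#' @param type `"eigenfunctions"` (default), `"covariance"` (smoothed
#'   surface as a tile map), or `"fit"` (observed points and fitted
#'   trajectories for a few genes).
#' @param genes Gene ids to show when `type = "fit"` (default: first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tc_fpca
#' @export
autoplot.tc_fpca <- function(object, type = c("eigenfunctions", "covariance", "fit"),
                             genes = NULL, ...) {
  type <- match.arg(type)
  if (type == "eigenfunctions") {
    phi <- object$eig$eigenfunctions[, seq_len(object$L), drop = FALSE]
    df <- tibble::tibble(
      time = rep(object$eig$grid, ncol(phi)),
      value = as.vector(phi),
      component = factor(rep(seq_len(ncol(phi)), each = nrow(phi)))
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$component)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time", y = expression(phi[l](t)),
                      title = "Estimated eigenfunctions")
    )
  }
  if (type == "covariance") {
    g <- object$eig$grid
    df <- tidyr::expand_grid(s = g, t = g)
    df$value <- as.vector(object$smooth_cov)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$t, fill = .data$value)) +
        ggplot2::geom_tile() +
        ggplot2::labs(title = "Smoothed covariance surface", fill = "G(s,t)")
    )
  }
  if (is.null(genes)) genes <- head(object$gene_ids, 4)
  idx <- match(genes, object$gene_ids)
  if (anyNA(idx)) stop("unknown gene id(s): ", paste(genes[is.na(idx)], collapse = ", "))
  df <- tibble::tibble(
    gene = rep(genes, each = length(object$times)),
    time = rep(object$times, length(idx)),
    observed = as.vector(t(object$data$values[idx, , drop = FALSE])),
    fitted = as.vector(t(object$fitted[idx, , drop = FALSE]))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$observed)) +
    ggplot2::geom_point(shape = 8, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(y = "expression", title = "Observed values and FPCA trajectories")
}

#' Plot a permutation F-test result
#'
#' @param object A `tc_ftest` object.
#' @param type `"pvalues"` (histogram of permutation p-values, default)
#'   or `"statistic"` (p-value against F, coloured by rejection).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tc_ftest
#' @export
autoplot.tc_ftest <- function(object, type = c("pvalues", "statistic"), ...) {
  type <- match.arg(type)
  tab <- object$table
  if (type == "pvalues") {
    return(
      ggplot2::ggplot(tab, ggplot2::aes(.data$p_value)) +
        ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                                fill = "grey70", colour = "grey30") +
        ggplot2::labs(x = "permutation p-value", y = "genes",
                      title = sprintf("%s p-values (%s test)", object$pvalue, object$design))
    )
  }
  ggplot2::ggplot(tab, ggplot2::aes(.data$statistic, .data$p_value, colour = .data$rejected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "F statistic", y = "p-value",
                  title = sprintf("Rejections at FDR %.3g", object$fdr_level))
}
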