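# Replicated simulation studies: empirical false positive rate and
# sensitivity of the permutation F-test under the generating models.

#' Empirical FPR and sensitivity of a rejection set
#'
#' FPR here is the realized false discovery proportion: falsely rejected
#' hypotheses over total rejections, defined as 0 when nothing is
#' rejected. Sensitivity is the proportion of truly differential genes
#' rejected, `NA` when no gene is truly differential.
#'
#' @param rejected Logical rejection flags.
#' @param truth Logical ground-truth differential labels.
#' @return Named list with `fpr` and `sensitivity`.
#' @export
fpr_sensitivity <- function(rejected, truth) {
  stopifnot(length(rejected) == length(truth))
  n_rej <- sum(rejected)
  fpr <- if (n_rej == 0) 0 else sum(rejected & !truth) / n_rej
  sens <- if (sum(truth) == 0) NA_real_ else sum(rejected & truth) / sum(truth)
  list(fpr = fpr, sensitivity = sens)
}

# One simulation replicate: simulate, fit, one permutation null, then
# rejection metrics for every (p-value mode, FDR level) combination.
study_rep <- function(mode, pi0, fdr_levels, pvalue_modes, n, B, fve,
                      bin_width, rep_seed, null_seed, smooth_p = FALSE) {
  if (mode == "one") {
    sim <- simulate_one_group(n, pi0, seed = rep_seed)
    em <- as_expr_mat(sim$data)
    fit <- fpca(em, fve = fve)
    delta <- max(fit$sigma2, 1e-8)
    f <- f_statistic(fit$rss0, fit$rss1, delta)
    cen <- list(centered = fit$centered, gene_means = fit$gene_means)
    eig_sel <- list(eigenvalues = fit$eig$eigenvalues[seq_len(fit$L)],
                    eigenfunctions = fit$eig$eigenfunctions[, seq_len(fit$L), drop = FALSE],
                    grid = fit$times)
    null <- null_one_group(em, cen, eig_sel, delta, B = B, seed = null_seed)
  } else {
    sim <- simulate_two_group(n, pi0, seed = rep_seed)
    ems <- lapply(sim$data, as_expr_mat)
    setup <- multi_setup(ems, fve = fve)
    scheme <- make_bins(lapply(ems, `[[`, "times"), bin_width)
    bins <- scheme_columns(setup, scheme)
    f <- setup$f
    null <- null_multi_group(setup, bins, B = B, seed = null_seed)
  }
  truth <- sim$truth$differential
  out <- list()
  for (pm in pvalue_modes) {
    p <- if (pm == "pooled") pvalues_pooled(f, null, smooth_p = smooth_p)
         else pvalues_genewise(f, null, smooth_p = smooth_p)
    for (lev in fdr_levels) {
      adj <- bh_adjust(p, level = lev)
      m <- fpr_sensitivity(adj$rejected, truth)
      out[[length(out) + 1L]] <- tibble::tibble(
        pvalue = pm, fdr_level = lev, fpr = m$fpr, sensitivity = m$sensitivity,
        n_rejected = sum(adj$rejected)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Run a replicated simulation study
#'
#' For each replicate: simulate a dataset under the requested generating
#' model, run the permutation F-test once, and evaluate both p-value
#' definitions (from the same permutation null) at every FDR level.
#' Results are averaged over replicates.
#'
#' @param mode `"one"` (single-group test of non-flat profiles) or
#'   `"two"` (two-group comparison).
#' @param pi0 Proportion of differential genes in the generator.
#' @param fdr_levels FDR levels to evaluate (default `c(0.01, 0.05)`).
#' @param pvalue_modes P-value definitions to evaluate (default both).
#' @param reps Number of simulation replicates (default 50).
#' @param n Genes per replicate (default 1000).
#' @param B Permutations per replicate (default 1000).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param fve FVE threshold (default 0.90).
#' @param bin_width Bin width for the two-group permutation (default 10).
#' @return Tibble with one row per (pvalue, fdr_level): mean `fpr` and
#'   `sensitivity`, the study settings, and the per-replicate metrics as
#'   a nested list-column `per_rep`.
#' @export
run_study <- function(mode = c("one", "two"), pi0, fdr_levels = c(0.01, 0.05),
                      pvalue_modes = c("pooled", "genewise"), reps = 50,
                      n = 1000, B = 1000, seed = 1, fve = 0.90, bin_width = 10) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  seeds <- derive_seeds(seed, 2L * reps)
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    dplyr::mutate(
      study_rep(mode, pi0, fdr_levels, pvalue_modes, n, B, fve, bin_width,
                rep_seed = seeds[2L * r - 1L], null_seed = seeds[2L * r]),
      rep = r
    )
  })
  out <- per_rep |>
    dplyr::group_by(.data$pvalue, .data$fdr_level) |>
    dplyr::summarise(
      fpr_mean = mean(.data$fpr),
      sensitivity_mean = mean(.data$sensitivity),
      .groups = "drop"
    ) |>
    dplyr::mutate(mode = mode, pi0 = pi0, reps = reps, n = n, B = B, seed = seed)
  out$per_rep <- lapply(seq_len(nrow(out)), function(i) {
    dplyr::filter(per_rep, .data$pvalue == out$pvalue[i], .data$fdr_level == out$fdr_level[i])
  })
  out
}
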