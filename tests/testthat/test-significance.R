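# F-statistic arithmetic, p-value definitions, FDR control, and the
# one-group permutation null.

test_that("F-statistic follows the stabilized ratio exactly", {
  expect_equal(f_statistic(2, 1, 0.01), 1 / 1.01)
  expect_equal(f_statistic(3, 3, 0.01), 0)
  expect_equal(f_statistic(3, 0, 0.01), 300)
  expect_error(f_statistic(-1, 0, 0.01), "nonnegative")
  # zero sigma^2 is floored, keeping the statistic finite
  expect_true(is.finite(f_statistic(1, 0, 0)))
})

test_that("genewise p-values count exceedances per gene", {
  null <- matrix(c(5, 1, 0, 2), 4, 1)
  expect_equal(pvalues_genewise(2, null), 0.5)
  expect_equal(pvalues_genewise(10, null), 0)
  expect_equal(pvalues_genewise(0, null), 1)
  # add-one smoothing shifts counts by 1/(B+1)
  expect_equal(pvalues_genewise(2, null, smooth_p = TRUE), 3 / 5)
})

test_that("pooled p-values count exceedances over all genes and preserve ordering", {
  null <- matrix(c(3, 1, 2, 0), 2, 2)  # gene1: (3,1); gene2: (2,0)
  expect_equal(pvalues_pooled(c(2.5, 0.5), null), c(1 / 4, 3 / 4))
  # ties in observed F get equal p
  expect_equal(pvalues_pooled(c(1.5, 1.5), null), c(0.5, 0.5))
  # monotonicity: larger F never gets a larger p
  set.seed(4)
  f <- rnorm(50)
  nm <- matrix(rnorm(500), 10, 50)
  p <- pvalues_pooled(f, nm)
  expect_true(all(diff(p[order(f)]) <= 0))
  # exact tie with a null value counts as an exceedance (>=)
  expect_equal(pvalues_pooled(3, matrix(c(3, 1), 2, 1)), 0.5)
})

test_that("BH adjustment matches the step-up enumeration oracle", {
  p <- c(0.001, 0.02, 0.04, 0.8)
  adj <- bh_adjust(p, level = 0.05)
  expect_equal(sum(adj$rejected), 2L)
  expect_true(all(adj$rejected[1:2]))
  # brute-force step-up: largest k with p_(k) <= k * alpha / m
  oracle_reject <- function(p, alpha) {
    m <- length(p); o <- order(p); ps <- p[o]
    k <- max(c(0L, which(ps <= seq_len(m) * alpha / m)))
    rej <- rep(FALSE, m); if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(8)
  for (r in 1:25) {
    pr <- runif(40)^2
    a <- runif(1, 0.01, 0.2)
    expect_identical(bh_adjust(pr, a)$rejected, oracle_reject(pr, a))
  }
  expect_true(all(bh_adjust(rep(0, 5))$rejected))
  expect_false(any(bh_adjust(rep(1, 5))$rejected))
  # adjusted p-values never fall below raw ones
  pr <- runif(30)
  expect_true(all(bh_adjust(pr)$p_adjusted >= pr))
})

test_that("identity permutation reproduces the observed statistics exactly", {
  sim <- simulate_one_group(40, pi0 = 0.5, seed = 2)
  fit <- fpca(sim$data)
  delta <- max(fit$sigma2, 1e-8)
  f_obs <- f_statistic(fit$rss0, fit$rss1, delta)
  K <- length(fit$times)
  null <- permute_one_group(sim$data, fit, delta,
                            perms = matrix(seq_len(K), 1))
  expect_equal(as.numeric(null$stats[1, ]), as.numeric(f_obs), tolerance = 1e-12)
})

test_that("sampled permutation null matches exhaustive enumeration at K = 3", {
  set.seed(6)
  tt <- c(0, 1, 2)
  Y <- matrix(rnorm(15, sd = 0.5), 5, 3) + c(0, 2, 0, 1, 0)
  df <- wide_tibble(Y, tt)
  cen <- center_by_gene_mean(df)
  phi <- matrix(c(-1, 0, 1) / sqrt(2), 3, 1)  # L2-normalized on {0,1,2}
  eig <- manual_eig(phi, tt)
  delta <- 0.05
  perms <- all_perms(3)
  exact <- permute_one_group(df, eig, delta, perms = perms)
  # brute-force oracle: recompute F for each permutation from first principles
  w <- fpcatest:::trapezoid_weights(tt)
  for (b in seq_len(nrow(perms))) {
    Zp <- cen$centered[, perms[b, ]]
    xi <- Zp %*% (w * phi)
    rss1 <- rowSums((Zp - xi %*% t(phi))^2)
    rss0 <- rowSums(cen$centered^2)
    expect_equal(as.numeric(exact$stats[b, ]), (rss0 - rss1) / (rss1 + delta),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # sampling with large B draws the 6 permutations uniformly
  samp <- permute_one_group(df, eig, delta, B = 3000, seed = 9)
  key <- apply(round(samp$stats, 10), 1, paste, collapse = ",")
  ekey <- apply(round(exact$stats, 10), 1, paste, collapse = ",")
  expect_true(all(key %in% ekey))
  # permutations can share an F vector (sign-symmetric basis); compare
  # against the exact multiplicities
  lev <- unique(ekey)
  counts <- table(factor(key, levels = lev))
  probs <- as.numeric(table(factor(ekey, levels = lev))) / length(ekey)
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.01)
})

test_that("a flat gene's observed F is exchangeable with its permutation null", {
  set.seed(13)
  sim <- simulate_one_group(200, pi0 = 0.3, seed = 31)
  res <- one_group_test(sim$data, B = 2000, seed = 14, pvalue = "genewise",
                        keep_null = TRUE)
  flat <- which(!sim$truth$differential)
  p_flat <- tidy(res)$p_value[flat]
  # genewise p-values of null genes behave like uniforms, not like signal
  expect_gt(mean(p_flat), 0.4)
  expect_lt(mean(p_flat), 0.65)
  expect_gt(mean(p_flat > 0.2), 0.6)
})

test_that("identical gene rows receive identical statistics and p-values", {
  set.seed(15)
  y <- rnorm(21, sd = 0.3) + 2 * basis_one_group(seq(100, 305, length.out = 21))[, 1]
  Y <- matrix(y, 50, 21, byrow = TRUE)
  df <- wide_tibble(Y, seq(100, 305, length.out = 21))
  res <- suppressWarnings(one_group_test(df, B = 200, seed = 3))
  tab <- tidy(res)
  expect_equal(max(tab$statistic) - min(tab$statistic), 0)
  expect_equal(max(tab$p_value) - min(tab$p_value), 0)
})

test_that("results are bitwise reproducible for a fixed seed", {
  sim <- simulate_one_group(80, pi0 = 0.25, seed = 17)
  r1 <- one_group_test(sim$data, B = 300, seed = 42)
  r2 <- one_group_test(sim$data, B = 300, seed = 42)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- one_group_test(sim$data, B = 300, seed = 43)
  expect_false(identical(tidy(r1)$p_value, tidy(r3)$p_value))
})

test_that("per-gene-independent permutation mode is available and calibrated", {
  sim <- simulate_one_group(100, pi0 = 0, seed = 19)
  res <- one_group_test(sim$data, B = 400, seed = 5, joint = FALSE)
  expect_lte(sum(tidy(res)$rejected), 2L)
})

test_that("results TSV round-trips the p-values at 10 significant digits", {
  sim <- simulate_one_group(30, pi0 = 0.5, seed = 23)
  res <- one_group_test(sim$data, B = 200, seed = 6)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(res, tf)
  meta <- grep("^#", readLines(tf), value = TRUE)
  expect_gte(length(meta), 8)
  back <- utils::read.delim(tf, comment.char = "#")
  expect_equal(back$p, tidy(res)$p_value, tolerance = 1e-9)
  expect_equal(back$gene, tidy(res)$gene)
})
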