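# Small fixture builders shared across test files.

# Wide expression tibble from a value matrix and time vector.
wide_tibble <- function(values, times, ids = sprintf("g%03d", seq_len(nrow(values)))) {
  colnames(values) <- format(times, trim = TRUE, digits = 10)
  dplyr::bind_cols(tibble::tibble(gene = ids), tibble::as_tibble(values))
}

# Eigensystem list in the internal layout, from explicit basis columns.
manual_eig <- function(phi, grid, eigenvalues = rep(1, ncol(phi))) {
  list(eigenvalues = eigenvalues, eigenfunctions = phi,
       fve = cumsum(eigenvalues) / sum(eigenvalues), grid = grid)
}

# All permutations of 1..k (k small).
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
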