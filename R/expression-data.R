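# Expression data: wide tibbles at the interface (column `gene` plus one
# numeric-named column per sampling time), a plain matrix form internally.

# Internal representation: list(gene_ids, times, values [n x K], observed
# [n x K logical]). Times strictly increasing; missing values are NA in
# `values` with `observed` FALSE.
as_expr_mat <- function(data, min_obs = 3L) {
  if (is.list(data) && inherits(data, "fpcatest_expr_mat")) return(data)
  if (!is.data.frame(data)) {
    stop("expression data must be a data frame with a `gene` column and numeric-named time columns")
  }
  nm <- names(data)
  gene_col <- which(nm == "gene")
  if (length(gene_col) != 1L) {
    stop("expression data must have exactly one `gene` column")
  }
  gene_ids <- as.character(data[[gene_col]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  times_raw <- suppressWarnings(as.numeric(nm[-gene_col]))
  if (anyNA(times_raw)) {
    stop("non-numeric time columns: ", paste(nm[-gene_col][is.na(times_raw)], collapse = ", "))
  }
  values <- as.matrix(data[, -gene_col, drop = FALSE])
  storage.mode(values) <- "double"

  # Replicate columns (duplicated time labels) are pre-averaged.
  key <- time_key(times_raw)
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    cnt <- t(rowsum(t(!is.na(values)) + 0, grp))
    sums <- t(rowsum(t(ifelse(is.na(values), 0, values)), grp))
    values <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
    times_raw <- unique(key)
  }
  ord <- order(times_raw)
  times <- times_raw[ord]
  values <- values[, ord, drop = FALSE]
  if (any(diff(times) <= 0)) stop("sampling times must be strictly increasing")

  observed <- !is.na(values)
  n_obs <- rowSums(observed)
  if (any(n_obs < min_obs)) {
    bad <- gene_ids[n_obs < min_obs]
    stop("genes with fewer than ", min_obs, " observed values: ",
         paste(head(bad, 5), collapse = ", "))
  }
  structure(
    list(gene_ids = gene_ids, times = times, values = values, observed = observed),
    class = "fpcatest_expr_mat"
  )
}

# Back to the wide-tibble interface form.
expr_tibble <- function(em) {
  vals <- em$values
  colnames(vals) <- format(em$times, trim = TRUE, digits = 10, scientific = FALSE)
  dplyr::bind_cols(tibble::tibble(gene = em$gene_ids), tibble::as_tibble(vals))
}

#' Read a gene-by-time expression matrix from TSV
#'
#' The expected layout is the one used for microarray series matrices:
#' cell (1,1) is the literal `gene`, the remaining header cells are numeric
#' sampling times, each following row is one gene. Duplicated time labels
#' denote replicate columns and are averaged on read; `NA` or empty cells
#' are treated as missing.
#'
#' @param path Path to a tab-separated file.
#' @return A wide tibble with a `gene` column and one numeric-named column
#'   per (unique, sorted) sampling time.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\t1\t2\t3", "g1\t0.1\t0.2\t0.3"), tf)
#' read_expression_tsv(tf)
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nfields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                 blank.lines.skip = TRUE, quote = "")
  if (length(unique(nfields)) > 1L) {
    bad <- which(nfields != nfields[1])
    stop("ragged rows at line(s): ", paste(head(bad, 5), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), blank.lines.skip = TRUE)
  if (nrow(raw) < 2L) stop("expression file needs a header and at least one gene row")
  header <- unlist(raw[1, ], use.names = FALSE)
  if (is.na(header[1]) || header[1] != "gene") {
    stop("cell (1,1) must be the literal 'gene', got: ", header[1])
  }
  times <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(times)) {
    stop("non-numeric time header at column(s): ",
         paste(which(is.na(times)) + 1L, collapse = ", "))
  }
  body <- raw[-1, , drop = FALSE]
  gene <- body[[1]]
  if (anyNA(gene)) stop("missing gene id at data line(s): ", paste(which(is.na(gene)) + 1L, collapse = ", "))
  if (anyDuplicated(gene)) {
    stop("duplicate gene ids: ", paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(body[, -1, drop = FALSE])), nrow = nrow(body))
  )
  bad_cells <- !is.na(as.matrix(body[, -1, drop = FALSE])) & is.na(vals)
  if (any(bad_cells)) {
    stop("non-numeric expression value at data line(s): ",
         paste(unique(which(rowSums(bad_cells) > 0) + 1L), collapse = ", "))
  }
  df <- data.frame(gene = gene, vals, check.names = FALSE)
  names(df) <- c("gene", as.character(times))
  # validate + replicate-average through the standard constructor; the
  # >= 3 observations precondition is enforced at analysis time, not read time
  expr_tibble(as_expr_mat(df, min_obs = 1L))
}

#' Write a fitted covariance surface and eigensystem to TSV
#'
#' For inspection outside R: writes `<prefix>.covariance.tsv` (the
#' smoothed surface with the grid as header and first column) and
#' `<prefix>.eigensystem.tsv` (eigenvalues, cumulative FVE, and the
#' discretized eigenfunctions by column).
#'
#' @param fit A `tc_fpca` object from [fpca()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_fpca_tsv <- function(fit, prefix) {
  stopifnot(inherits(fit, "tc_fpca"))
  fmt <- function(x) format(x, trim = TRUE, digits = 10, scientific = FALSE)
  g <- fmt(fit$eig$grid)
  p1 <- paste0(prefix, ".covariance.tsv")
  writeLines(c(paste(c("time", g), collapse = "\t"),
               paste(g, apply(fmt(fit$smooth_cov), 1, paste, collapse = "\t"),
                     sep = "\t")), p1)
  p2 <- paste0(prefix, ".eigensystem.tsv")
  L_max <- length(fit$eig$eigenvalues)
  header <- paste(c("time", paste0("phi", seq_len(L_max))), collapse = "\t")
  meta <- c(sprintf("# eigenvalues = %s", paste(fmt(fit$eig$eigenvalues), collapse = ", ")),
            sprintf("# fve = %s", paste(fmt(fit$eig$fve), collapse = ", ")),
            sprintf("# L = %d", fit$L))
  writeLines(c(meta, header,
               paste(g, apply(fmt(fit$eig$eigenfunctions), 1, paste, collapse = "\t"),
                     sep = "\t")), p2)
  invisible(c(p1, p2))
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]; numbers are written with 10
#' significant digits.
#'
#' @param data Wide expression tibble (`gene` column + numeric-named time columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path) {
  em <- as_expr_mat(data, min_obs = 0L)
  header <- paste(c("gene", format(em$times, trim = TRUE, digits = 10, scientific = FALSE)),
                  collapse = "\t")
  vals <- format(em$values, trim = TRUE, digits = 10, scientific = FALSE)
  vals[!em$observed] <- "NA"
  lines <- c(header, paste(em$gene_ids, apply(vals, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
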