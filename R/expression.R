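#' Expression tables
#'
#' Throughout the package an expression dataset is an ordinary tibble whose
#' first column, `gene`, holds unique gene symbols and whose remaining
#' columns hold one numeric sample each (log-scale intensities). This keeps
#' datasets pipe-friendly; linear algebra happens on the matrix view.
#'
#' @param x a tibble or data frame in expression layout.
#' @return `expr_matrix()` returns a genes-by-samples numeric matrix with
#'   gene symbols as row names; `as_expression()` returns a validated
#'   expression tibble.
#' @examples
#' d <- tibble::tibble(gene = c("A", "B"), s1 = c(1, 2), s2 = c(3, 4))
#' expr_matrix(d)
#' @export
expr_matrix <- function(x) {
  x <- as_expression(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname expr_matrix
#' @export
as_expression <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene row names")
    x <- dplyr::bind_cols(tibble(gene = rownames(x)), as_tibble(x))
  }
  x <- as_tibble(x)
  if (ncol(x) < 2L) abort("expression table needs a gene column and at least one sample")
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  dup <- unique(x$gene[duplicated(x$gene)])
  if (length(dup) > 0L) {
    abort(paste0(
      "duplicate gene symbols: ", paste(head(dup, 5L), collapse = ", "),
      if (length(dup) > 5L) ", ..." else ""
    ))
  }
  sample_ids <- names(x)[-1]
  if (anyDuplicated(sample_ids)) abort("duplicate sample IDs")
  bad <- !vapply(x[-1], is.numeric, logical(1))
  if (any(bad)) abort(paste0("non-numeric sample columns: ", paste(sample_ids[bad], collapse = ", ")))
  if (any(!vapply(x[-1], function(col) all(is.finite(col)), logical(1)))) {
    abort("expression values must be finite (no missing values)")
  }
  x
}

n_samples <- function(x) ncol(x) - 1L

#' Read / write expression TSV
#'
#' The on-disk format is a tab-separated table with a header row; the first
#' column holds gene symbols, remaining columns one sample each. Values are
#' written with 6 significant digits, so `read_expression_tsv(write_expression_tsv(d))`
#' reproduces `d` up to that formatting.
#'
#' @param path file path.
#' @param x expression tibble (see [as_expression()]).
#' @return `read_expression_tsv()` returns an expression tibble;
#'   `write_expression_tsv()` returns `x` invisibly.
#' @export
read_expression_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2L) abort("expression TSV needs a gene column and at least one sample column")
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    conv <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(conv) & !is.na(vals[[j]]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        vals[[j]][bad[1]], bad[1], names(vals)[j]
      ))
    }
    if (anyNA(conv)) {
      abort(sprintf("missing value at row %d, column '%s'",
                    which(is.na(conv))[1], names(vals)[j]))
    }
    vals[[j]] <- conv
  }
  as_expression(dplyr::bind_cols(raw[1], vals))
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_expression(x)
  out <- dplyr::mutate(x, dplyr::across(-1, ~ signif(.x, 6)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Collapse probe-level measurements to one row per gene
#'
#' Microarray platforms measure a gene with several probes; downstream
#' network analysis wants one profile per gene symbol. The representative
#' probe for each symbol is the one with the highest mean intensity across
#' samples (the MaxMean rule, which favours well-measured probes); ties go
#' to the lexicographically smallest probe ID. No values are synthesised:
#' every output row is one of the input rows.
#'
#' @param probes tibble whose first column `probe` holds unique probe IDs,
#'   remaining columns numeric samples.
#' @param annotation tibble with columns `probe` and `symbol`.
#' @return expression tibble, one row per symbol, sorted by symbol.
#' @export
collapse_probes <- function(probes, annotation) {
  probes <- as_tibble(probes)
  names(probes)[1] <- "probe"
  probes$probe <- as.character(probes$probe)
  if (anyDuplicated(probes$probe)) abort("duplicate probe IDs")
  annotation <- as_tibble(annotation)
  if (!all(c("probe", "symbol") %in% names(annotation))) {
    abort("annotation needs columns 'probe' and 'symbol'")
  }
  if (anyDuplicated(annotation$probe)) abort("annotation probe IDs must be unique")
  missing <- setdiff(probes$probe, annotation$probe)
  if (length(missing) > 0L) {
    abort(paste0("probes missing from annotation: ", paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(probes[, -1, drop = FALSE])
  means <- rowMeans(mat)
  map <- annotation[match(probes$probe, annotation$probe), ]
  picked <- tibble(
    probe = probes$probe, symbol = as.character(map$symbol), mean = means
  ) |>
    dplyr::arrange(.data$symbol, dplyr::desc(.data$mean), .data$probe) |>
    dplyr::distinct(.data$symbol, .keep_all = TRUE)
  idx <- match(picked$probe, probes$probe)
  as_expression(dplyr::bind_cols(
    tibble(gene = picked$symbol), probes[idx, -1, drop = FALSE]
  ))
}

#' Restrict datasets to their common gene symbols
#'
#' Cross-platform comparison requires one shared gene universe: every
#' output dataset carries exactly the sorted intersection of the input
#' symbol sets, in the same order, with sample columns untouched. The
#' operation is idempotent and invariant to the input order.
#'
#' @param datasets list of expression tibbles, each already collapsed to
#'   unique symbols.
#' @return list of expression tibbles with identical `gene` vectors.
#' @export
merge_by_symbol <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  datasets <- lapply(datasets, as_expression)
  common <- Reduce(intersect, lapply(datasets, function(d) d$gene))
  if (length(common) == 0L) abort("no gene symbols shared by all datasets")
  common <- sort(common)
  lapply(datasets, function(d) d[match(common, d$gene), , drop = FALSE])
}

#' Flag outlier arrays by standardized inter-array correlation
#'
#' Each sample's mean Pearson correlation with every other sample (IAC) is
#' computed across genes and standardized across samples; samples whose
#' standardized IAC falls below `z_cut` are flagged in a single pass. This
#' is a deterministic surrogate for visually pruning a sample dendrogram
#' built from inter-array correlations. A constant (zero-variance) sample
#' is flagged unconditionally with a warning.
#'
#' @param x expression tibble with at least 5 samples.
#' @param z_cut flagging threshold on the standardized IAC (default -3).
#' @return list with `flagged` (character sample IDs), `iac` (tibble of
#'   sample, iac, z) and `filtered` (the dataset without flagged samples).
#' @export
detect_outlier_samples <- function(x, z_cut = -3) {
  x <- as_expression(x)
  if (n_samples(x) < 5L) abort("need at least 5 samples for outlier detection")
  m <- expr_matrix(x)
  ids <- colnames(m)
  const <- apply(m, 2L, function(v) sd(v) == 0)
  if (any(const)) {
    warn(paste0("constant sample(s) flagged: ", paste(ids[const], collapse = ", ")))
  }
  cc <- suppressWarnings(cor(m))
  diag(cc) <- NA_real_
  iac <- rowMeans(cc, na.rm = TRUE)
  iac[const] <- NA_real_
  z <- (iac - mean(iac, na.rm = TRUE)) / sd(iac, na.rm = TRUE)
  if (!is.finite(sd(iac, na.rm = TRUE)) || isTRUE(sd(iac, na.rm = TRUE) == 0)) {
    z <- rep(0, length(iac))          # all arrays equally typical
  }
  flag <- const | (!is.na(z) & z < z_cut)
  keep <- c(TRUE, !flag)              # gene column always kept
  list(
    flagged = ids[flag],
    iac = tibble(sample = ids, iac = iac, z = z, flagged = flag),
    filtered = x[, keep, drop = FALSE]
  )
}

#' Remove additive batch offsets by mean centering
#'
#' Per gene and per batch, the batch mean is subtracted and the gene's
#' grand mean added back, so each gene's overall mean is preserved while
#' additive batch shifts vanish. Batches with a single sample are left
#' unchanged with a warning. This is a plain location adjustment, not an
#' empirical-Bayes batch correction.
#'
#' @param x expression tibble.
#' @param batch character/factor vector of batch labels, one per sample,
#'   or a tibble with columns `sample` and `batch`.
#' @return expression tibble of the same shape.
#' @export
center_batches <- function(x, batch) {
  x <- as_expression(x)
  m <- expr_matrix(x)
  if (is.data.frame(batch)) {
    if (!all(c("sample", "batch") %in% names(batch))) {
      abort("batch table needs columns 'sample' and 'batch'")
    }
    idx <- match(colnames(m), batch$sample)
    if (anyNA(idx)) abort("every sample needs a batch label")
    batch <- batch$batch[idx]
  }
  batch <- as.character(batch)
  if (length(batch) != ncol(m)) abort("one batch label per sample required")
  singletons <- names(which(table(batch) == 1L))
  if (length(singletons) > 0L) {
    warn(paste0("single-sample batch left unchanged: ", paste(singletons, collapse = ", ")))
  }
  grand <- rowMeans(m)
  for (b in setdiff(unique(batch), singletons)) {
    j <- which(batch == b)
    m[, j] <- m[, j] - rowMeans(m[, j, drop = FALSE]) + grand
  }
  as_expression(m)
}
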