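#' Cross-dataset agreement of per-gene summaries
#'
#' Computes a per-gene summary within each dataset — the row mean
#' (`"mean"`) or whole-network connectivity under the network parameters
#' (`"connectivity"`) — and correlates the two summaries across genes
#' with the biweight midcorrelation (robust against outlying genes), with
#' a correlation-test p-value at n = gene count.
#'
#' @param a,b expression tibbles over the same gene universe (post-merge).
#' @param summary `"mean"` or `"connectivity"`.
#' @param params [network_params()] (used for connectivity).
#' @param bonferroni_n Bonferroni multiplier.
#' @return one-row tibble: summary, r, p, p_bonferroni, n.
#' @export
compare_gene_summaries <- function(a, b, summary = c("mean", "connectivity"),
                                   params = network_params(),
                                   bonferroni_n = 50) {
  summary <- match.arg(summary)
  a <- as_expression(a); b <- as_expression(b)
  if (!identical(sort(a$gene), sort(b$gene))) {
    abort("datasets must share one gene universe (run merge_by_symbol first)")
  }
  b <- b[match(a$gene, b$gene), ]
  summarize <- function(d) {
    if (summary == "mean") return(rowMeans(expr_matrix(d)))
    adj <- adjacency(correlation_matrix(d, method = params$method), params)
    setNames(connectivity(adj)$k, rownames(adj))
  }
  sa <- summarize(a); sb <- summarize(b)
  r <- bicor(sa, sb)
  p <- as.numeric(correlation_test_p(r, length(sa)))
  tibble(summary = summary, r = r, p = p,
         p_bonferroni = min(1, p * bonferroni_n), n = length(sa))
}

#' Combined module membership across preserved modules
#'
#' When several preserved modules are indistinguishable in a tissue
#' (their eigengenes correlate near +/-1), their per-module MM vectors
#' can be averaged into one combined measure after aligning signs:
#' `combined_i = sum_q w_q s_q MM_qi / sum_q w_q`, default weights 1.
#' Signs are supplied or chosen automatically as the sign of the
#' correlation between each module's MM vector and the anchor module's,
#' which flips any module whose eigengene is negatively related to the
#' rest.
#'
#' @param mm module-membership table from [module_membership()] (long) or
#'   a wide tibble with a `gene` column and one MM column per module.
#' @param modules modules to combine (default: all in `mm`).
#' @param signs optional named vector of +/-1 per module.
#' @param weights optional named non-negative weights (default equal).
#' @param anchor module whose sign is fixed at +1 for automatic signs
#'   (default: first of `modules`).
#' @return tibble: gene, combined_mm, plus attribute `signs`.
#' @export
combine_mm <- function(mm, modules = NULL, signs = NULL, weights = NULL,
                       anchor = NULL) {
  wide <- mm_wide(mm)
  if (is.null(modules)) modules <- setdiff(names(wide), "gene")
  missing <- setdiff(modules, names(wide))
  if (length(missing) > 0L) {
    abort(paste0("modules absent from MM table: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(wide[modules])
  if (is.null(weights)) weights <- setNames(rep(1, length(modules)), modules)
  weights <- weights[modules]
  if (anyNA(weights) || any(weights < 0)) abort("weights must be non-negative")
  if (sum(weights) == 0) abort("total weight is zero")
  if (is.null(anchor)) anchor <- modules[1]
  if (is.null(signs)) {
    signs <- vapply(modules, function(q) {
      s <- sign(safe_cor(m[, q], m[, anchor]))
      if (s == 0) 1 else s
    }, numeric(1))
  } else {
    signs <- signs[modules]
    if (anyNA(signs) || !all(signs %in% c(-1, 1))) abort("signs must be +/-1 per module")
  }
  combined <- as.vector(m %*% (signs * weights)) / sum(weights)
  out <- tibble(gene = wide$gene, combined_mm = combined)
  attr(out, "signs") <- signs
  attr(out, "modules") <- modules
  out
}

mm_wide <- function(mm) {
  mm <- as_tibble(mm)
  if (all(c("gene", "module", "mm") %in% names(mm))) {
    return(tidyr::pivot_wider(mm[, c("gene", "module", "mm")],
                              names_from = "module", values_from = "mm"))
  }
  if (!"gene" %in% names(mm)) abort("MM table needs a 'gene' column")
  mm
}

#' Select preserved intramodular hub genes
#'
#' A gene is a preserved hub when its combined MM is consistently extreme
#' in both tissues: above `+threshold` in both, or below `-threshold` in
#' both (strict inequalities). The default 0.35 corresponds to a highly
#' significant module membership at the sample sizes this analysis
#' targets.
#'
#' @param mm_ref,mm_test tibbles with columns gene, combined_mm over a
#'   shared gene universe.
#' @param threshold in (0, 1); default 0.35.
#' @return tibble: gene, mm_ref, mm_test, for the selected genes.
#' @export
select_hub_genes <- function(mm_ref, mm_test, threshold = 0.35) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  mm_ref <- as_tibble(mm_ref); mm_test <- as_tibble(mm_test)
  if (!setequal(mm_ref$gene, mm_test$gene)) abort("gene universes differ")
  j <- dplyr::inner_join(
    dplyr::rename(mm_ref, mm_ref = "combined_mm"),
    dplyr::rename(mm_test, mm_test = "combined_mm"), by = "gene"
  )
  dplyr::filter(
    j,
    (.data$mm_ref > threshold & .data$mm_test > threshold) |
      (.data$mm_ref < -threshold & .data$mm_test < -threshold)
  )
}

#' One-sided hypergeometric overlap test
#'
#' Given two gene sets inside a universe, the probability of observing at
#' least the realized overlap under random draws:
#' `p = P(X >= overlap)` for `X ~ hypergeometric(|universe|, |A|, |B|)`,
#' computed by exact summation of the tail.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return one-row tibble: n_a, n_b, n_universe, overlap, expected, p.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  n <- length(universe); na <- length(set_a); nb <- length(set_b)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1, na, n - na, nb, lower.tail = FALSE)
  tibble(n_a = na, n_b = nb, n_universe = n, overlap = ov,
         expected = na * nb / n, p = p)
}

#' Coverage percentages at the reporting precision
#'
#' What fraction of a network's genes belongs to the listed modules,
#' rounded to the convention of the pipeline's reports: whole percent for
#' module coverage, one decimal for hub-gene fractions.
#'
#' @param module_sizes integer vector of module gene counts
#'   (`sum <= network_size`).
#' @param network_size total genes in the network.
#' @param digits rounding digits of the percentage (0 for coverage,
#'   1 for hub fractions).
#' @return list: `per_module` (percentages, named like `module_sizes`)
#'   and `total`.
#' @export
coverage_percentages <- function(module_sizes, network_size, digits = 0) {
  if (network_size <= 0) abort("network size must be positive")
  if (sum(module_sizes) > network_size) abort("module sizes exceed network size")
  pct <- function(k) round(100 * k / network_size, digits)
  list(per_module = vapply(module_sizes, pct, numeric(1)),
       total = pct(sum(module_sizes)))
}

#' Compare heritability across gene groups
#'
#' Classic one-way analysis of variance of heritability estimates by gene
#' group (e.g. preserved hubs vs network genes vs all genes), with group
#' means for barplots.
#'
#' @param groups named list of character gene vectors (>= 2 groups, each
#'   >= 2 genes). A gene may appear in several groups (groups are
#'   overlapping strata, as in hub-vs-network comparisons); each
#'   membership contributes one observation.
#' @param table tibble with columns gene, h2.
#' @return list of class `heritability_comparison`: `means` tibble
#'   (group, n, mean_h2), `f`, `p`, `fit` (the aov object).
#' @export
heritability_comparison <- function(groups, table) {
  if (length(groups) < 2L) abort("need at least 2 groups")
  table <- as_tibble(table)
  if (!all(c("gene", "h2") %in% names(table))) abort("table needs columns gene, h2")
  df <- purrr::imap(groups, function(genes, name) {
    if (length(genes) < 2L) abort(paste0("group '", name, "' has fewer than 2 genes"))
    missing <- setdiff(genes, table$gene)
    if (length(missing) > 0L) {
      abort(paste0("genes absent from heritability table: ",
                   paste(head(missing, 5L), collapse = ", ")))
    }
    tibble(group = name, h2 = table$h2[match(genes, table$gene)])
  }) |> dplyr::bind_rows()
  df$group <- factor(df$group, levels = names(groups))
  fit <- aov(h2 ~ group, data = df)
  an <- anova(fit)
  means <- df |> dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_h2 = mean(.data$h2), .groups = "drop")
  structure(list(means = means, f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                 fit = fit), class = "heritability_comparison")
}

#' @rdname heritability_comparison
#' @param x a `heritability_comparison`.
#' @param ... unused.
#' @method tidy heritability_comparison
#' @export
tidy.heritability_comparison <- function(x, ...) x$means

#' @rdname heritability_comparison
#' @method glance heritability_comparison
#' @export
glance.heritability_comparison <- function(x, ...) {
  tibble(f = x$f, p = x$p, n_groups = nrow(x$means))
}

#' @rdname heritability_comparison
#' @param object a `heritability_comparison`.
#' @method autoplot heritability_comparison
#' @export
autoplot.heritability_comparison <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$group, y = .data$mean_h2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean heritability") +
    ggplot2::theme_minimal()
}

#' Marker gene / eigengene correlations
#'
#' Correlates each marker gene's expression profile with each module
#' eigengene; markers missing from the dataset are listed and skipped
#' with a warning.
#'
#' @param eigengenes an `eigengene_set` or its tibble.
#' @param x expression tibble.
#' @param markers character vector of marker symbols.
#' @param bonferroni_n multiplier; default the table size.
#' @return tibble: module, marker, r, p, p_bonferroni.
#' @export
marker_correlations <- function(eigengenes, x, markers, bonferroni_n = NULL) {
  x <- as_expression(x)
  me_tbl <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes else as_tibble(eigengenes)
  found <- intersect(markers, x$gene)
  missing <- setdiff(markers, x$gene)
  if (length(missing) > 0L) {
    warn(paste0("markers absent from dataset, skipped: ",
                paste(missing, collapse = ", ")))
  }
  if (length(found) == 0L) abort("no marker genes found in dataset")
  shared <- intersect(names(x)[-1], me_tbl$sample)
  m <- expr_matrix(x)[found, shared, drop = FALSE]
  me_m <- as.matrix(me_tbl[match(shared, me_tbl$sample), -1, drop = FALSE])
  cc <- cor(me_m, t(m))               # modules x markers
  if (is.null(bonferroni_n)) bonferroni_n <- length(cc)
  tidyr::expand_grid(module = rownames(cc), marker = colnames(cc)) |>
    dplyr::mutate(
      r = as.vector(t(cc)),           # row-major: module-major order matches expand_grid
      p = correlation_test_p_vec(.data$r, length(shared)),
      p_bonferroni = pmin(1, .data$p * bonferroni_n)
    )
}
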