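#' Module preservation statistics and permutation Zsummary
#'
#' Whether a module found in a reference tissue is still a module in a
#' test tissue is judged by six network statistics, three about density
#' (is the module still a tight cluster in the test data?) and three
#' about connectivity (is the wiring pattern reproduced?):
#'
#' * `mean_adjacency` (density) — mean off-diagonal soft-thresholded
#'   adjacency among module genes in the test data;
#' * `prop_var_explained` (density) — variance explained by the module
#'   eigengene recomputed in the test data;
#' * `mean_abs_kme` (density) — mean absolute correlation of module genes
#'   with that test-data eigengene;
#' * `cor_kim` (connectivity) — correlation of the intramodular
#'   connectivity vectors between reference and test;
#' * `cor_kme` (connectivity) — correlation of the kME vectors, each
#'   computed against its own dataset's (sign-aligned) module eigengene;
#' * `cor_cor` (connectivity) — correlation between the vectorized
#'   upper-triangular gene-gene correlation matrices.
#'
#' Each observed statistic is standardized against a permutation null in
#' which module membership is replaced by random gene sets of the same
#' size drawn from the merged gene universe:
#' `Z_s = (obs_s - mean_perm_s) / sd_perm_s`. `Zdensity` is the median of
#' the density Zs, `Zconnectivity` the median of the connectivity Zs, and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Under the null of no
#' preservation each Z is approximately standard normal; by convention
#' `Zsummary < 2` is no evidence of preservation, `> 5` moderate and
#' `> 10` strong preservation.
#'
#' @name preservation
NULL

# Internal fast path. Zr/Zt: genes x samples, rows standardized (sd divisor
# n-1). Cr/Ct: universe correlation matrices. idx: integer gene indices.
preservation_stats_engine <- function(Zr, Zt, Cr, Ct, idx, beta) {
  cr <- Cr[idx, idx]
  ct <- Ct[idx, idx]
  q <- length(idx)
  at <- abs(ct)^beta
  d1 <- (sum(at) - q) / (q * (q - 1))

  er <- eigen(cr, symmetric = TRUE)
  et <- eigen(ct, symmetric = TRUE)
  # kME against each dataset's own module eigengene, sign-aligned to the
  # module mean profile (standardized rows => cor identities apply)
  kme_r <- module_kme_from_eigen(Zr[idx, , drop = FALSE], er)
  kme_t <- module_kme_from_eigen(Zt[idx, , drop = FALSE], et)
  d2 <- et$values[1] / q
  d3 <- mean(abs(kme_t))

  ar <- abs(cr)^beta
  kim_r <- rowSums(ar) - 1
  kim_t <- rowSums(at) - 1
  ut <- upper.tri(cr)
  c(
    mean_adjacency = d1,
    prop_var_explained = d2,
    mean_abs_kme = d3,
    cor_kim = safe_cor(kim_r, kim_t),
    cor_kme = safe_cor(kme_r, kme_t),
    cor_cor = safe_cor(cr[ut], ct[ut])
  )
}

module_kme_from_eigen <- function(Z, eig) {
  u1 <- eig$vectors[, 1]
  me <- drop(crossprod(Z, u1))        # sample-length eigengene direction
  if (safe_cor(me, colMeans(Z)) < 0) me <- -me
  me <- (me - mean(me)) / sd(me)
  m <- ncol(Z)
  drop(Z %*% me) / (m - 1)            # cor(x_i, me): rows already standardized
}

safe_cor <- function(a, b) {
  if (length(a) < 2L) return(0)
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  as.numeric(cor(a, b))
}

# rows standardized to mean 0, sd 1 (divisor n-1)
standardize_rows <- function(m) {
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene profiles: ",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  (m - rowMeans(m)) / sds
}

#' Observed preservation statistics for one module
#'
#' @param ref,test expression tibbles sharing the module genes.
#' @param module_genes character vector of module member symbols (>= 3).
#' @param params [network_params()].
#' @return one-row tibble with the six statistics described in
#'   [preservation].
#' @export
preservation_statistics <- function(ref, test, module_genes,
                                    params = network_params()) {
  ref <- as_expression(ref); test <- as_expression(test)
  if (length(module_genes) < 3L) abort("module needs at least 3 genes")
  for (d in list(ref, test)) {
    missing <- setdiff(module_genes, d$gene)
    if (length(missing) > 0L) {
      abort(paste0("module genes absent from a dataset: ",
                   paste(head(missing, 5L), collapse = ", ")))
    }
  }
  Zr <- standardize_rows(expr_matrix(ref)[module_genes, , drop = FALSE])
  Zt <- standardize_rows(expr_matrix(test)[module_genes, , drop = FALSE])
  m_r <- ncol(Zr); m_t <- ncol(Zt)
  Cr <- tcrossprod(Zr) / (m_r - 1); Ct <- tcrossprod(Zt) / (m_t - 1)
  stats <- preservation_stats_engine(Zr, Zt, Cr, Ct, seq_along(module_genes),
                                     params$beta)
  dplyr::bind_cols(tibble(n_genes = length(module_genes)),
                   as_tibble(as.list(stats)))
}

# deterministic 32-bit stream seed from master seed + module label
module_stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483647)
}

DENSITY_STATS <- c("mean_adjacency", "prop_var_explained", "mean_abs_kme")
CONNECTIVITY_STATS <- c("cor_kim", "cor_kme", "cor_cor")

#' Permutation-based module preservation (Zsummary)
#'
#' For each non-grey module of the assignment, the six statistics of
#' [preservation] are computed on the observed module genes and on
#' `n_perm` random gene sets of the same size drawn without replacement
#' from the merged gene universe (all genes present in both datasets,
#' grey included). Each module gets an independent, deterministic
#' permutation stream derived from the master seed and the module label,
#' so results are reproducible and modules of equal size do not share
#' draws.
#'
#' @param ref,test expression tibbles.
#' @param assignment tibble gene, module covering the reference genes.
#' @param n_perm number of permutations (>= 50; default 200).
#' @param seed master RNG seed.
#' @param params [network_params()].
#' @return object of class `module_preservation`: tibble `summary`
#'   (module, size, Zdensity, Zconnectivity, Zsummary, verdict), tibble
#'   `statistics` (per module and statistic: observed, permutation
#'   mean/sd, Z), plus `n_perm`, `seed`, `params`.
#' @export
module_preservation <- function(ref, test, assignment, n_perm = 200, seed,
                                params = network_params()) {
  if (missing(seed)) abort("seed must be given explicitly")
  if (n_perm < 50L) abort("n_perm must be at least 50")
  ref <- as_expression(ref); test <- as_expression(test)
  assignment <- as_tibble(assignment)
  universe <- intersect(ref$gene, test$gene)
  if (length(universe) < 10L) abort("merged gene universe too small")
  universe <- sort(universe)

  Zr <- standardize_rows(expr_matrix(ref)[universe, , drop = FALSE])
  Zt <- standardize_rows(expr_matrix(test)[universe, , drop = FALSE])
  Cr <- tcrossprod(Zr) / (ncol(Zr) - 1)
  Ct <- tcrossprod(Zt) / (ncol(Zt) - 1)

  mods <- setdiff(unique(assignment$module), "grey")
  mods <- mods[order(match(mods, module_colors(64)), mods)]
  stat_rows <- list(); sum_rows <- list()
  for (q in mods) {
    genes_q <- intersect(assignment$gene[assignment$module == q], universe)
    n_q <- length(genes_q)
    if (n_q < 3L) {
      warn(paste0("module '", q, "' has fewer than 3 genes in the universe; skipped"))
      next
    }
    idx <- match(genes_q, universe)
    obs <- preservation_stats_engine(Zr, Zt, Cr, Ct, idx, params$beta)

    perm <- matrix(NA_real_, nrow = n_perm, ncol = length(obs),
                   dimnames = list(NULL, names(obs)))
    stream <- module_stream_seed(seed, q)
    withr::local_seed(stream)
    for (b in seq_len(n_perm)) {
      ridx <- sample.int(length(universe), n_q)
      perm[b, ] <- preservation_stats_engine(Zr, Zt, Cr, Ct, ridx, params$beta)
    }
    mu <- colMeans(perm)
    sdv <- apply(perm, 2L, sd)
    z <- (obs - mu) / sdv
    degenerate <- sdv == 0
    if (any(degenerate)) {
      warn(paste0("zero permutation sd for ", paste(names(obs)[degenerate], collapse = ", "),
                  " in module '", q, "'; excluded from medians"))
      z[degenerate] <- NA_real_
    }
    z_density <- median(z[DENSITY_STATS], na.rm = TRUE)
    z_connectivity <- median(z[CONNECTIVITY_STATS], na.rm = TRUE)
    z_summary <- (z_density + z_connectivity) / 2
    stat_rows[[q]] <- tibble(
      module = q, statistic = names(obs),
      class = ifelse(names(obs) %in% DENSITY_STATS, "density", "connectivity"),
      observed = unname(obs), perm_mean = unname(mu), perm_sd = unname(sdv),
      z = unname(z)
    )
    sum_rows[[q]] <- tibble(
      module = q, size = n_q, Zdensity = z_density,
      Zconnectivity = z_connectivity, Zsummary = z_summary,
      verdict = preservation_verdict(z_summary)
    )
  }
  structure(list(
    summary = dplyr::bind_rows(sum_rows),
    statistics = dplyr::bind_rows(stat_rows),
    n_perm = as.integer(n_perm), seed = as.integer(seed), params = params,
    universe_size = length(universe)
  ), class = "module_preservation")
}

#' Null calibration of the preservation Z statistics
#'
#' Under the null hypothesis of no module preservation each per-statistic
#' Z should be approximately standard normal. This experiment draws
#' `n_modules` random gene sets of size `module_size` from a pure-noise
#' two-tissue simulation (no planted structure, so the null holds by
#' construction), runs the full permutation machinery on each, and
#' returns every per-statistic Z. Well-calibrated statistics have Z means
#' near 0 and standard deviations near 1 across replicate modules.
#'
#' @param n_modules number of replicate random "modules" (>= 2).
#' @param module_size genes per random module.
#' @param n_genes universe size of the noise simulation.
#' @param n_samples samples per tissue.
#' @param n_perm permutations per module.
#' @param seed master seed; determines the simulation, the random module
#'   draws and every permutation stream.
#' @param params [network_params()].
#' @return tibble: replicate, statistic, class, z.
#' @export
preservation_null_calibration <- function(n_modules = 200, module_size = 50,
                                          n_genes = 1000, n_samples = 100,
                                          n_perm = 200, seed,
                                          params = network_params()) {
  if (missing(seed)) abort("seed must be given explicitly")
  study <- simulate_scenario(synthetic_scenario(
    tissues = c(ref = n_samples, test = n_samples),
    modules = list(), n_background_genes = n_genes, seed = seed
  ))
  genes <- study$expression$ref$gene
  withr::local_seed(seed + 1L)
  draws <- lapply(seq_len(n_modules), function(i) sample(genes, module_size))
  purrr::imap(draws, function(gs, i) {
    asg <- tibble(gene = genes,
                  module = ifelse(genes %in% gs, "m", "grey"))
    p <- module_preservation(study$expression$ref, study$expression$test,
                             asg, n_perm = n_perm, seed = seed + 1L + i,
                             params = params)
    dplyr::mutate(p$statistics[, c("statistic", "class", "z")],
                  replicate = i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Interpret a Zsummary value
#'
#' @param z Zsummary value(s).
#' @return character: `"none"` (< 2), `"weak-to-moderate"` (2-5),
#'   `"moderate"` (5-10) or `"strong"` (> 10).
#' @export
preservation_verdict <- function(z) {
  dplyr::case_when(
    z > 10 ~ "strong",
    z > 5 ~ "moderate",
    z >= 2 ~ "weak-to-moderate",
    TRUE ~ "none"
  )
}

#' @export
print.module_preservation <- function(x, ...) {
  cat("Module preservation (", x$n_perm, " permutations, seed ", x$seed,
      ", universe ", x$universe_size, " genes)\n\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname module_preservation
#' @param x a `module_preservation` object.
#' @param ... unused.
#' @method tidy module_preservation
#' @export
tidy.module_preservation <- function(x, ...) x$statistics

#' @rdname module_preservation
#' @method glance module_preservation
#' @export
glance.module_preservation <- function(x, ...) {
  tibble(
    n_modules = nrow(x$summary),
    n_strong = sum(x$summary$verdict == "strong"),
    n_perm = x$n_perm, seed = x$seed,
    universe_size = x$universe_size, beta = x$params$beta
  )
}

#' Preservation barplot
#'
#' Horizontal bars of Zsummary per module with reference lines at the
#' moderate (5) and strong (10) preservation thresholds.
#'
#' @param object a `module_preservation` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot module_preservation
#' @export
autoplot.module_preservation <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Zsummary,
                                   y = stats::reorder(.data$module, .data$Zsummary))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$module), show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_vline(xintercept = c(5, 10), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "preservation Zsummary", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write preservation results
#'
#' JSON (per module: observed statistics, permutation moments, Zs,
#' verdict, n_perm, seed) plus a flat TSV summary suitable for the
#' barplot.
#'
#' @param x `module_preservation` object.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_preservation <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "module_preservation"))
  if (!is.null(json_path)) {
    payload <- list(
      n_perm = x$n_perm, seed = x$seed, universe_size = x$universe_size,
      beta = x$params$beta,
      density_statistics = DENSITY_STATS,
      connectivity_statistics = CONNECTIVITY_STATS,
      summary = x$summary, statistics = x$statistics
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(tsv_path)) readr::write_tsv(x$summary, tsv_path, progress = FALSE)
  invisible(x)
}
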