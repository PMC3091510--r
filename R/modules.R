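#' Standard module color vocabulary
#'
#' Modules are labeled by size rank with the field's conventional ordered
#' color list (largest module = turquoise, then blue, brown, yellow,
#' green, ...); "grey" is reserved for unassigned background genes.
#'
#' @param n number of labels wanted.
#' @return character vector of `n` color labels.
#' @export
module_colors <- function(n) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
  )
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("module", seq_len(n - length(base))))
}

#' Detect co-expression modules as dendrogram branches
#'
#' Genes are clustered by average-linkage hierarchical clustering on
#' `1 - TOM` and the tree is cut at the fixed dissimilarity `cut_height`
#' (default 0.99, the conventional static cut on the 1 - TOM scale:
#' unrelated genes sit at dissimilarity ~1, so only genuinely
#' interconnected branches assemble below the cut). Branches holding at
#' least `min_module_size` genes become modules, labeled by size rank
#' with the standard colors; everything else is grey. The procedure is a
#' deterministic static-height variant of dynamic branch cutting: given
#' the same input it always yields the same labels, and the labels do not
#' depend on gene input order.
#'
#' @param x expression tibble.
#' @param params [network_params()].
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_height absolute 1 - TOM height at which the tree is cut
#'   (default 0.99).
#' @return list of class `module_detection` with `assignment` (tibble
#'   gene, module), `dendrogram` (hclust) and the parameters used.
#' @export
detect_modules <- function(x, params = network_params(), min_module_size = 30,
                           cut_height = 0.99) {
  x <- as_expression(x)
  genes <- x$gene
  ord <- order(genes)                 # canonical order: labels invariant to input order
  xo <- x[ord, , drop = FALSE]
  cc <- correlation_matrix(xo, method = params$method)
  tomm <- tom(adjacency(cc, params))
  hc <- hclust(as.dist(1 - tomm), method = "average")
  if (length(genes) < min_module_size) {
    warn("fewer genes than min_module_size: all genes grey")
    assignment <- tibble(gene = genes, module = "grey")
    return(structure(list(assignment = assignment, dendrogram = hc,
                          params = params, min_module_size = min_module_size,
                          cut_height = cut_height),
                     class = "module_detection"))
  }
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # deterministic ordering: by size desc, ties by smallest member symbol
  first_gene <- vapply(keep, function(id) min(xo$gene[cl == id]), character(1))
  keep <- keep[order(-as.integer(sizes[keep]), first_gene)]
  labels <- rep("grey", length(cl))
  cols <- module_colors(length(keep))
  for (i in seq_along(keep)) labels[cl == keep[i]] <- cols[i]
  assignment <- tibble(gene = xo$gene, module = labels)
  assignment <- assignment[match(genes, assignment$gene), ]
  structure(list(assignment = assignment, dendrogram = hc, params = params,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "module_detection")
}

#' Module eigengene: first principal component of a module
#'
#' Gene profiles are standardized (mean 0, sd 1 across samples) and the
#' module eigengene is the first right singular vector of the module's
#' standardized gene-by-sample matrix, scaled to unit variance. Its sign
#' is anchored so that the eigengene correlates non-negatively with the
#' module's mean standardized profile. `prop_var_explained` is the first
#' squared singular value over the total.
#'
#' @param x expression tibble.
#' @param genes character vector of module member genes (>= 2).
#' @return list with `me` (named sample-length vector, unit variance),
#'   `prop_var_explained`.
#' @export
module_eigengene <- function(x, genes) {
  x <- as_expression(x)
  if (length(genes) < 2L) abort("a module needs at least 2 genes")
  missing <- setdiff(genes, x$gene)
  if (length(missing) > 0L) {
    abort(paste0("module genes absent from dataset: ", paste(missing, collapse = ", ")))
  }
  m <- expr_matrix(x)[genes, , drop = FALSE]
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene in module: ",
                 paste(genes[sds == 0], collapse = ", ")))
  }
  z <- (m - rowMeans(m)) / sds
  sv <- svd(z)
  me <- sv$v[, 1]
  pve <- sv$d[1]^2 / sum(sv$d^2)
  if (cor(me, colMeans(z)) < 0) me <- -me
  me <- me / sd(me)
  names(me) <- colnames(m)
  list(me = me, prop_var_explained = pve)
}

#' Eigengenes for every module of an assignment
#'
#' @param x expression tibble.
#' @param assignment tibble with columns gene, module ("grey" skipped).
#' @return list of class `eigengene_set`: `eigengenes` tibble
#'   (sample column + one column per module), `prop_var_explained` named
#'   vector.
#' @export
module_eigengenes <- function(x, assignment) {
  x <- as_expression(x)
  assignment <- as_tibble(assignment)
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0L) abort("no non-grey modules in assignment")
  mods <- mods[order(match(mods, module_colors(64)), mods)]
  fits <- lapply(mods, function(q) {
    module_eigengene(x, assignment$gene[assignment$module == q])
  })
  me_tbl <- tibble(sample = names(fits[[1]]$me))
  for (i in seq_along(mods)) me_tbl[[mods[i]]] <- unname(fits[[i]]$me)
  structure(list(
    eigengenes = me_tbl,
    prop_var_explained = setNames(
      vapply(fits, `[[`, numeric(1), "prop_var_explained"), mods)
  ), class = "eigengene_set")
}

#' Two-sided p-value of a correlation
#'
#' Student-t test of a correlation coefficient: `t = r sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom, two-sided. `|r| = 1` gives exactly 0; a
#' p-value that underflows to 0 for `|r| < 1` is returned as the smallest
#' representable positive double with attribute `underflow = TRUE`.
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of paired observations (>= 4).
#' @return the p-value.
#' @export
correlation_test_p <- function(r, n) {
  if (abs(r) > 1 + 1e-12) abort("|r| must be <= 1")
  if (n < 4L) abort("need n >= 4")
  r <- min(1, max(-1, r))
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  if (p == 0) {
    p <- .Machine$double.xmin
    attr(p, "underflow") <- TRUE
  }
  p
}

# vectorized, attribute-free variant for tables
correlation_test_p_vec <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- 2 * pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)),
              df = n - 2)
  p[abs(r) == 1] <- 0
  p[p == 0 & abs(r) < 1] <- .Machine$double.xmin
  p
}

#' Module membership (kME) of every gene against every eigengene
#'
#' `MM_qi = cor(x_i, ME_q)`: how correlated gene i's profile is with
#' module q's eigengene. Computed for all genes against all modules —
#' including genes outside the module — with two-sided correlation-test
#' p-values and Bonferroni-corrected p-values
#' (`p_bonferroni = min(1, p * bonferroni_n)`; default multiplier 50, the
#' conventional test count of the pipeline's reports).
#'
#' @param x expression tibble.
#' @param eigengenes an `eigengene_set` from [module_eigengenes()], or its
#'   `eigengenes` tibble.
#' @param bonferroni_n multiplier for the Bonferroni correction.
#' @return long tibble: gene, module, mm, p, p_bonferroni.
#' @export
module_membership <- function(x, eigengenes, bonferroni_n = 50) {
  x <- as_expression(x)
  me_tbl <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes else as_tibble(eigengenes)
  if (n_samples(x) < 4L) abort("need at least 4 samples")
  shared <- intersect(names(x)[-1], me_tbl$sample)
  if (length(shared) < 4L) abort("dataset and eigengenes share fewer than 4 samples")
  m <- expr_matrix(x)[, shared, drop = FALSE]
  me_m <- as.matrix(me_tbl[match(shared, me_tbl$sample), -1, drop = FALSE])
  mm <- cor(t(m), me_m)
  n <- length(shared)
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble(gene = rownames(mm)), as_tibble(mm)),
    -1, names_to = "module", values_to = "mm"
  ) |>
    dplyr::mutate(
      p = correlation_test_p_vec(.data$mm, n),
      p_bonferroni = pmin(1, .data$p * bonferroni_n)
    )
}

#' Eigengene relationship network
#'
#' Pairwise correlations between module eigengenes, with correlation-test
#' p-values, plus an average-linkage dendrogram on `1 - cor` summarising
#' how modules relate (highly correlated eigengenes mean the modules are
#' hard to distinguish in that dataset).
#'
#' @param eigengenes an `eigengene_set` or its tibble.
#' @param bonferroni_n Bonferroni multiplier for the p-values.
#' @return list: `correlations` (long tibble module_a, module_b, r, p,
#'   p_bonferroni), `cor_matrix`, `dendrogram` (hclust), `newick` string.
#' @export
eigengene_network <- function(eigengenes, bonferroni_n = 50) {
  me_tbl <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes else as_tibble(eigengenes)
  if (ncol(me_tbl) < 3L) abort("need at least 2 modules")
  me_m <- as.matrix(me_tbl[, -1, drop = FALSE])
  cc <- cor(me_m)
  n <- nrow(me_m)
  hc <- hclust(as.dist(1 - cc), method = "average")
  long <- tidyr::expand_grid(module_a = colnames(cc), module_b = colnames(cc)) |>
    dplyr::mutate(
      r = as.vector(t(cc)),
      p = correlation_test_p_vec(.data$r, n),
      p_bonferroni = pmin(1, .data$p * bonferroni_n)
    )
  list(correlations = long, cor_matrix = cc, dendrogram = hc,
       newick = hclust_newick(hc))
}

# Newick export of an hclust tree via ape
hclust_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
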