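#' Network construction parameters
#'
#' An unsigned weighted network raises the absolute correlation to a soft
#' threshold power, `a_ij = |cor(x_i, x_j)|^beta`. The power emphasises
#' strong co-expression while keeping the network continuous; `beta = 6`
#' is the conventional default for unsigned networks and is used
#' throughout unless overridden.
#'
#' @param beta positive soft-threshold power.
#' @param method correlation estimator, `"pearson"` or `"bicor"`.
#' @return a list of class `network_params`.
#' @export
network_params <- function(beta = 6, method = c("pearson", "bicor")) {
  method <- match.arg(method)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("beta must be a positive number")
  }
  structure(list(beta = beta, method = method, sign_mode = "unsigned"),
            class = "network_params")
}

#' Biweight midcorrelation
#'
#' A robust correlation that downweights observations far from the median.
#' With `u_a = (x_a - med(x)) / (9 mad(x))` (unnormalized median absolute
#' deviation) and weights `w_a = (1 - u_a^2)^2` for `|u_a| < 1` (zero
#' otherwise), the statistic is the normalized weighted cross-product of
#' the median-centered vectors. Observations beyond nine MADs from the
#' median get zero weight, so a single outlying array cannot dominate the
#' estimate. When a vector's MAD is zero the weights are undefined and the
#' estimator falls back to Pearson for that pair, with a warning.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return a single correlation in `[-1, 1]`.
#' @examples
#' x <- rnorm(20)
#' bicor(x, x)   # exactly 1
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 4L) abort("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  wx <- bicor_weights(x)
  wy <- bicor_weights(y)
  if (is.null(wx) || is.null(wy)) {
    warn("zero MAD: falling back to Pearson correlation")
    return(as.numeric(cor(x, y)))
  }
  a <- wx$w * (x - wx$med)
  b <- wy$w * (y - wy$med)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) {
    warn("all observations zero-weighted: falling back to Pearson correlation")
    return(as.numeric(cor(x, y)))
  }
  min(1, max(-1, sum(a * b) / den))
}

bicor_weights <- function(x) {
  med <- median(x)
  s <- mad(x, constant = 1)
  if (s == 0) return(NULL)
  u <- (x - med) / (9 * s)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  list(med = med, w = w)
}

# rows of `m` (genes) scaled so that tcrossprod gives the correlation matrix
cor_prepared_rows <- function(m, method) {
  if (method == "pearson") {
    cen <- m - rowMeans(m)
    nrm <- sqrt(rowSums(cen^2))
    return(cen / nrm)
  }
  t(apply(m, 1L, function(x) {
    wx <- bicor_weights(x)
    if (is.null(wx)) {
      a <- x - mean(x)               # per-gene Pearson fallback
    } else {
      a <- wx$w * (x - wx$med)
    }
    a / sqrt(sum(a^2))
  }))
}

#' All pairwise gene-gene correlations
#'
#' @param x expression tibble (genes in rows of the matrix view).
#' @param method `"pearson"` or `"bicor"`.
#' @param drop_constant drop constant genes instead of erroring.
#' @return symmetric correlation matrix with unit diagonal, gene symbols
#'   as dimnames, and attribute `method`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "bicor"),
                               drop_constant = FALSE) {
  method <- match.arg(method)
  m <- expr_matrix(x)
  if (ncol(m) < 4L) abort("need at least 4 samples")
  const <- which(apply(m, 1L, sd) == 0)
  if (length(const) > 0L) {
    if (!drop_constant) {
      abort(paste0("constant gene profiles: ",
                   paste(rownames(m)[const], collapse = ", ")))
    }
    m <- m[-const, , drop = FALSE]
  }
  if (method == "bicor") {
    zero_mad <- rownames(m)[apply(m, 1L, function(v) mad(v, constant = 1) == 0)]
    if (length(zero_mad) > 0L) {
      warn(paste0("zero MAD, Pearson fallback for: ",
                  paste(zero_mad, collapse = ", ")))
    }
  }
  v <- cor_prepared_rows(m, method)
  cc <- tcrossprod(v)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(m), rownames(m))
  attr(cc, "method") <- method
  cc
}

#' Soft-thresholded unsigned adjacency
#'
#' `a_ij = |c_ij|^beta` off the diagonal; the diagonal is stored as 1 by
#' convention but excluded from connectivity and topological-overlap sums.
#'
#' @param cor_mat symmetric correlation matrix (unit diagonal).
#' @param params [network_params()].
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(cor_mat, params = network_params()) {
  check_square(cor_mat)
  if (max(abs(cor_mat)) > 1 + 1e-8) abort("correlations must lie in [-1, 1]")
  a <- abs(cor_mat)^params$beta
  diag(a) <- 1
  a
}

#' Whole-network and intramodular connectivity
#'
#' Whole-network connectivity `k_i` is the sum of a gene's adjacencies to
#' all *other* genes (the self-adjacency is excluded). Intramodular
#' connectivity `kim` restricts the sum to genes sharing the module label;
#' grey (unassigned) genes get `NA`.
#'
#' @param adj adjacency matrix.
#' @param assignment optional tibble with columns `gene` and `module`
#'   covering every network gene.
#' @return tibble with columns `gene`, `k` and (given an assignment)
#'   `module`, `kim`.
#' @export
connectivity <- function(adj, assignment = NULL) {
  check_square(adj)
  genes <- rownames(adj)
  out <- tibble(gene = genes, k = unname(rowSums(adj) - diag(adj)))
  if (!is.null(assignment)) {
    assignment <- as_tibble(assignment)
    if (!setequal(assignment$gene, genes)) {
      abort("assignment must cover exactly the network genes")
    }
    mod <- assignment$module[match(genes, assignment$gene)]
    kim <- rep(NA_real_, length(genes))
    for (q in setdiff(unique(mod), "grey")) {
      j <- which(mod == q)
      sub <- adj[j, j, drop = FALSE]
      kim[j] <- rowSums(sub) - diag(sub)
    }
    out$module <- mod
    out$kim <- kim
  }
  out
}

#' Topological overlap matrix
#'
#' The topological overlap of genes i and j combines their direct
#' adjacency with the adjacency they share through common neighbours:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k` the whole-network
#' connectivity. `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj adjacency matrix (>= 3 genes).
#' @return symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
tom <- function(adj) {
  check_square(adj)
  if (nrow(adj) < 3L) abort("topological overlap needs at least 3 genes")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # L_ij = sum_u a_iu a_uj, u != i,j
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  t_mat <- (l + a) / (kmin + 1 - a)
  t_mat <- (t_mat + t(t_mat)) / 2
  diag(t_mat) <- 1
  t_mat[t_mat < 0] <- 0
  t_mat[t_mat > 1] <- 1
  dimnames(t_mat) <- dimnames(adj)
  t_mat
}

check_square <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("expected a square matrix")
  if (max(abs(m - t(m))) > 1e-8) abort("matrix must be symmetric")
  if (is.null(rownames(m))) abort("matrix needs gene dimnames")
  invisible(m)
}
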