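# Independent brute-force oracles. These re-derive each quantity from its
# definition with plain loops, deliberately sharing no code with the
# package internals.

oracle_bicor <- function(x, y) {
  mx <- median(x); my <- median(y)
  madx <- median(abs(x - mx)); mady <- median(abs(y - my))
  ux <- (x - mx) / (9 * madx); uy <- (y - my) / (9 * mady)
  wx <- ifelse(abs(ux) < 1, (1 - ux^2)^2, 0)
  wy <- ifelse(abs(uy) < 1, (1 - uy^2)^2, 0)
  num <- sum(wx * wy * (x - mx) * (y - my))
  num / sqrt(sum((wx * (x - mx))^2) * sum((wy * (y - my))^2))
}

oracle_connectivity <- function(adj) {
  n <- nrow(adj)
  k <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) k[i] <- k[i] + adj[i, j]
  }
  k
}

oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  k <- oracle_connectivity(adj)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

oracle_anova_f <- function(values, group) {
  groups <- split(values, group)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(values) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# P(X >= ov) by direct summation of hypergeometric masses via choose()
oracle_hyper_p <- function(ov, na, nb, n) {
  kmax <- min(na, nb)
  total <- 0
  for (k in ov:kmax) {
    total <- total + choose(na, k) * choose(n - na, nb - k) / choose(n, nb)
  }
  total
}

# first principal component of gene-standardized module matrix, via prcomp
oracle_eigengene <- function(mat) {
  z <- t(scale(t(mat)))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  if (cor(me, colMeans(z)) < 0) me <- -me
  list(me = me / sd(me), pve = pc$sdev[1]^2 / sum(pc$sdev^2))
}

# small random expression tibble
rand_expression <- function(n_genes, n_samples, seed, prefix = "G") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  preservr::as_expression(m)
}

# two planted correlation blocks plus noise, for module-recovery tests
planted_blocks <- function(block_sizes, n_noise, n_samples, r = 0.8, seed = 1) {
  set.seed(seed)
  rows <- list(); labels <- character(0)
  for (b in seq_along(block_sizes)) {
    e <- rnorm(n_samples)
    for (i in seq_len(block_sizes[b])) {
      rows[[length(rows) + 1L]] <- r * e + sqrt(1 - r^2) * rnorm(n_samples)
      labels <- c(labels, paste0("block", b))
    }
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1L]] <- rnorm(n_samples)
    labels <- c(labels, "noise")
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("g%04d", seq_len(nrow(m))),
                      sprintf("s%03d", seq_len(n_samples)))
  list(data = preservr::as_expression(m), truth = labels)
}
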