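test_that("planted correlation blocks are recovered as modules", {
  pb <- planted_blocks(c(100, 100), n_noise = 0, n_samples = 100, r = 0.8, seed = 21)
  det <- detect_modules(pb$data, min_module_size = 30)
  asg <- det$assignment
  labs <- setdiff(unique(asg$module), "grey")
  expect_length(labs, 2)
  # >= 95% of each block under one label
  for (b in c("block1", "block2")) {
    block_labels <- asg$module[pb$truth == b]
    expect_gte(max(table(block_labels)) / length(block_labels), 0.95)
  }
  # largest module gets the first standard color
  expect_true(all(labs %in% c("turquoise", "blue")))
})

test_that("pure noise yields mostly grey; tiny inputs are all grey", {
  noise <- rand_expression(300, 60, seed = 22)
  det <- detect_modules(noise, min_module_size = 30)
  expect_gte(mean(det$assignment$module == "grey"), 0.9)

  small <- rand_expression(10, 20, seed = 23)
  expect_warning(det2 <- detect_modules(small, min_module_size = 30), "grey")
  expect_true(all(det2$assignment$module == "grey"))
})

test_that("a degenerate perfectly-correlated block lands in one module", {
  set.seed(24)
  e <- rnorm(50)
  m <- rbind(
    t(sapply(1:50, function(i) e * sample(c(1, -1), 1))),
    matrix(rnorm(10 * 50), 10, 50)
  )
  m <- m + matrix(rnorm(length(m), sd = 1e-6), nrow(m))  # break exact ties
  dimnames(m) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:50))
  det <- detect_modules(as_expression(m), min_module_size = 30)
  block_mods <- det$assignment$module[1:50]
  expect_length(unique(block_mods), 1)
  expect_false(unique(block_mods) == "grey")
})

test_that("module labels are invariant to gene input order", {
  pb <- planted_blocks(c(50, 40), n_noise = 30, n_samples = 80, r = 0.8, seed = 25)
  det1 <- detect_modules(pb$data, min_module_size = 20)
  set.seed(26)
  perm <- sample(nrow(pb$data))
  det2 <- detect_modules(pb$data[perm, ], min_module_size = 20)
  merged <- dplyr::inner_join(det1$assignment, det2$assignment, by = "gene")
  expect_equal(merged$module.x, merged$module.y)
})

test_that("module eigengene matches an SVD oracle and its contracts", {
  d <- rand_expression(20, 30, seed = 27)
  fit <- module_eigengene(d, d$gene)
  orc <- oracle_eigengene(expr_matrix(d))
  expect_equal(unname(fit$me), unname(orc$me), tolerance = 1e-6)
  expect_equal(fit$prop_var_explained, orc$pve, tolerance = 1e-10)
  expect_equal(sd(fit$me), 1, tolerance = 1e-12)

  # rank-1 module (same profile up to sign flips): pve = 1
  set.seed(28)
  e <- rnorm(25)
  m <- rbind(e, 2 * e + 1, -e, 3 * e)
  dimnames(m) <- list(c("a", "b", "c", "d"), sprintf("s%02d", 1:25))
  fit1 <- module_eigengene(as_expression(m), c("a", "b", "c", "d"))
  expect_equal(fit1$prop_var_explained, 1, tolerance = 1e-12)

  # sign orientation: non-negative correlation with module mean profile
  for (seed in 29:31) {
    d2 <- rand_expression(10, 15, seed = seed)
    f <- module_eigengene(d2, d2$gene)
    z <- t(scale(t(expr_matrix(d2))))
    expect_gte(cor(f$me, colMeans(z)), 0)
  }

  # ME explains at least as much variance as any single gene's profile
  z <- t(scale(t(expr_matrix(d))))
  me_var <- sum(cor(t(z), module_eigengene(d, d$gene)$me)^2)
  for (i in seq_len(nrow(z))) {
    gene_var <- sum(cor(t(z), z[i, ])^2)
    expect_lte(gene_var, me_var + 1e-8)
  }

  d3 <- d; d3[4, -1] <- as.list(rep(1, 30))
  expect_error(module_eigengene(d3, d3$gene), d3$gene[4])
})

test_that("correlation test p-values follow the t distribution", {
  expect_equal(correlation_test_p(0, 10), 1)
  expect_equal(correlation_test_p(1, 10), 0)
  expect_equal(correlation_test_p(-1, 10), 0)
  # r = 0.5, n = 12: two-sided tail of t = r sqrt((n-2)/(1-r^2)) at 10 df
  t_exp <- 0.5 * sqrt(10 / (1 - 0.25))
  expect_equal(correlation_test_p(0.5, 12), 2 * (1 - pt(t_exp, 10)),
               tolerance = 1e-12)
  # underflow is flagged, not zero
  p <- correlation_test_p(1 - 1e-15, 1000)
  expect_gt(p, 0)
  expect_true(isTRUE(attr(p, "underflow")))
  expect_error(correlation_test_p(1.5, 10), "r")
  expect_error(correlation_test_p(0.5, 3), "n")
})

test_that("module membership is the gene-eigengene correlation with p-values", {
  pb <- planted_blocks(c(30, 25), n_noise = 10, n_samples = 50, r = 0.8, seed = 33)
  asg <- tibble::tibble(gene = pb$data$gene,
                        module = ifelse(pb$truth == "noise", "grey", pb$truth))
  mes <- module_eigengenes(pb$data, asg)
  mm <- module_membership(pb$data, mes, bonferroni_n = 50)
  expect_setequal(unique(mm$module), c("block1", "block2"))
  expect_equal(nrow(mm), nrow(pb$data) * 2)   # all genes x all modules

  # mm equals direct correlation; p from the shared helper; bonferroni capped
  m <- expr_matrix(pb$data)
  me1 <- mes$eigengenes$block1
  i <- which(pb$data$gene == pb$data$gene[1])
  expect_equal(mm$mm[mm$gene == pb$data$gene[1] & mm$module == "block1"],
               cor(m[1, ], me1), tolerance = 1e-12)
  r_mid <- mm$mm[50]
  expect_equal(mm$p[50], as.numeric(correlation_test_p(r_mid, 50)),
               tolerance = 1e-12)
  expect_equal(mm$p_bonferroni, pmin(1, mm$p * 50))

  # a gene equal to the eigengene has mm 1; its negative -1
  d2 <- pb$data
  d2[1, -1] <- as.list(me1)
  d2[2, -1] <- as.list(-me1)
  mm2 <- module_membership(d2, mes)
  expect_equal(mm2$mm[mm2$gene == d2$gene[1] & mm2$module == "block1"], 1)
  expect_equal(mm2$mm[mm2$gene == d2$gene[2] & mm2$module == "block1"], -1)
})

test_that("kME tracks intramodular connectivity inside a module", {
  pb <- planted_blocks(c(100), n_noise = 50, n_samples = 120, r = 0.75, seed = 34)
  asg <- tibble::tibble(gene = pb$data$gene,
                        module = ifelse(pb$truth == "block1", "blue", "grey"))
  adj <- adjacency(correlation_matrix(pb$data), network_params())
  k <- connectivity(adj, asg)
  mes <- module_eigengenes(pb$data, asg)
  mm <- module_membership(pb$data, mes)
  blue <- dplyr::inner_join(
    dplyr::filter(mm, module == "blue"), k, by = "gene"
  ) |> dplyr::filter(module.y == "blue")
  rho <- cor(abs(blue$mm), blue$kim, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("eigengene network recovers planted eigengene relations", {
  study <- simulate_scenario(synthetic_scenario(
    tissues = c(t1 = 200L),
    modules = list(
      module_spec("blue", 60, c(0.6, 0.9), "t1"),
      module_spec("green", 40, c(0.6, 0.9), "t1", anti_correlated = "blue")
    ),
    n_background_genes = 50, seed = 35
  ))
  asg <- study$truth[, c("gene", "module")]
  mes <- module_eigengenes(study$expression$t1, asg)
  en <- eigengene_network(mes)
  expect_equal(en$cor_matrix, t(en$cor_matrix))
  expect_equal(unname(diag(en$cor_matrix)), c(1, 1))
  expect_lte(en$cor_matrix["blue", "green"], -0.9)
  expect_match(en$newick, "blue")

  # duplicate module (same genes under two labels) correlates at 1
  asg2 <- dplyr::bind_rows(asg,
    dplyr::mutate(asg[asg$module == "blue", ], module = "bluecopy"))
  # same gene set twice is not representable in one assignment; correlate
  # eigengene sets computed separately instead
  me_a <- module_eigengene(study$expression$t1, asg$gene[asg$module == "blue"])
  expect_equal(cor(me_a$me, mes$eigengenes$blue), 1, tolerance = 1e-10)
})
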