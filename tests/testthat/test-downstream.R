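test_that("summary agreement is 1 for self and ~0 for independent data", {
  a <- rand_expression(300, 30, seed = 61)
  self <- compare_gene_summaries(a, a, "mean")
  expect_equal(self$r, 1, tolerance = 1e-12)

  b <- rand_expression(300, 30, seed = 62)   # same symbols, independent draws
  null_r <- compare_gene_summaries(a, b, "mean")$r
  expect_lt(abs(null_r), 0.1)

  # planted shared structure beats the independent-data correlation
  study <- simulate_scenario(synthetic_scenario(
    tissues = c(x = 50L, y = 50L),
    modules = list(module_spec("blue", 150, c(0.6, 0.9), c("x", "y"))),
    n_background_genes = 150, seed = 63
  ))
  shared_r <- compare_gene_summaries(study$expression$x, study$expression$y,
                                     "connectivity")$r
  null_conn <- compare_gene_summaries(a, b, "connectivity")$r
  expect_gt(shared_r, null_conn)

  mismatched <- rand_expression(10, 30, seed = 64)
  expect_error(compare_gene_summaries(a, mismatched), "universe")
})

test_that("combined MM is the sign-aligned weighted average", {
  mm <- tibble::tibble(gene = c("g1"), m1 = 0.6, m2 = 0.7, m3 = -0.65)
  out <- combine_mm(mm, signs = c(m1 = 1, m2 = 1, m3 = -1))
  expect_equal(out$combined_mm, (0.6 + 0.7 + 0.65) / 3)
  expect_equal(out$combined_mm, 0.65)

  # single module: identity
  one <- combine_mm(tibble::tibble(gene = c("a", "b"), m1 = c(0.3, -0.2)))
  expect_equal(one$combined_mm, c(0.3, -0.2))

  # automatic signs flip an anti-correlated module
  set.seed(65)
  base <- rnorm(200)
  mm2 <- tibble::tibble(
    gene = sprintf("g%03d", 1:200),
    blue = base + rnorm(200, sd = 0.2),
    yellow = base + rnorm(200, sd = 0.2),
    green = -base + rnorm(200, sd = 0.2)
  )
  out2 <- combine_mm(mm2, anchor = "blue")
  expect_equal(unname(attr(out2, "signs")), c(1, 1, -1))
  expect_gt(cor(out2$combined_mm, base), 0.9)

  expect_error(combine_mm(mm, weights = c(m1 = 0, m2 = 0, m3 = 0)), "weight")
})

test_that("hub selection applies the strict sign-consistent threshold", {
  mm_ref <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                           combined_mm = c(0.5, 0.5, 0.35, -0.6, 0.4))
  mm_test <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                            combined_mm = c(0.4, -0.5, 0.9, -0.45, 0.36))
  sel <- select_hub_genes(mm_ref, mm_test, 0.35)
  expect_setequal(sel$gene, c("a", "d", "e"))   # b sign-inconsistent, c boundary

  # exhaustive brute-force equivalence on random vectors
  set.seed(66)
  genes <- sprintf("g%03d", 1:300)
  r1 <- tibble::tibble(gene = genes, combined_mm = runif(300, -1, 1))
  r2 <- tibble::tibble(gene = genes, combined_mm = runif(300, -1, 1))
  for (t in c(0.2, 0.35, 0.5)) {
    sel <- select_hub_genes(r1, r2, t)
    manual <- genes[(r1$combined_mm > t & r2$combined_mm > t) |
                    (r1$combined_mm < -t & r2$combined_mm < -t)]
    expect_setequal(sel$gene, manual)
  }
  # monotone in threshold
  s1 <- select_hub_genes(r1, r2, 0.2)$gene
  s2 <- select_hub_genes(r1, r2, 0.5)$gene
  expect_true(all(s2 %in% s1))
  expect_error(select_hub_genes(r1, r2, 1.5), "threshold")
})

test_that("hypergeometric overlap test matches direct enumeration", {
  u <- sprintf("u%02d", 1:10)
  res <- overlap_fisher(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_p(5, 5, 5, 10), tolerance = 1e-12)

  # disjoint partition: overlap 0, p = 1
  res0 <- overlap_fisher(u[1:5], u[6:10], u)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)

  # degenerate: both sets equal the universe
  resu <- overlap_fisher(u, u, u)
  expect_equal(resu$overlap, 10)
  expect_equal(resu$p, 1)

  # p decreases as overlap grows with fixed margins
  set.seed(67)
  ps <- vapply(2:5, function(ov) {
    a <- u[1:5]; b <- c(u[1:ov], u[6:(6 + 5 - ov - 1)])
    overlap_fisher(a, b, u)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # random instances agree with the choose() enumeration
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    uu <- sprintf("x%02d", seq_len(n))
    a <- sample(uu, sample(2:n, 1)); b <- sample(uu, sample(2:n, 1))
    expect_equal(overlap_fisher(a, b, uu)$p,
                 oracle_hyper_p(length(intersect(a, b)), length(a), length(b), n),
                 tolerance = 1e-10)
  }
  expect_error(overlap_fisher(c("zzz"), u[1:2], u), "subset")
})

test_that("coverage percentages reproduce the reporting arithmetic", {
  expect_equal(coverage_percentages(c(690, 421, 658), 2640)$total, 67)
  expect_equal(coverage_percentages(357, 2640, digits = 1)$total, 13.5)
  expect_equal(coverage_percentages(c(254), 2063)$total, 12)
  expect_equal(coverage_percentages(c(819), 2001)$total, 41)
  expect_equal(coverage_percentages(integer(0), 100)$total, 0)
  expect_error(coverage_percentages(10, 0), "positive")
  expect_error(coverage_percentages(c(60, 50), 100), "exceed")
})

test_that("heritability ANOVA matches the mean-square oracle", {
  tbl <- tibble::tibble(gene = sprintf("g%02d", 1:12),
                        h2 = c(0.5, 0.6, 0.4, 0.55, 0.3, 0.2, 0.35, 0.25,
                               0.1, 0.15, 0.2, 0.12))
  groups <- list(high = tbl$gene[1:4], mid = tbl$gene[5:8], low = tbl$gene[9:12])
  hc <- heritability_comparison(groups, tbl)
  f_orc <- oracle_anova_f(tbl$h2, rep(c("high", "mid", "low"), each = 4))
  expect_equal(hc$f, f_orc, tolerance = 1e-10)
  expect_equal(tidy(hc)$mean_h2, c(mean(tbl$h2[1:4]), mean(tbl$h2[5:8]),
                                   mean(tbl$h2[9:12])))
  expect_s3_class(autoplot(hc), "ggplot")

  # identical groups: F = 0, p = 1
  same <- tibble::tibble(gene = c("a", "b", "c", "d", "e", "f"),
                         h2 = rep(c(0.1, 0.2, 0.3), 2))
  hc0 <- heritability_comparison(list(g1 = same$gene[1:3], g2 = same$gene[4:6]),
                                 same)
  expect_equal(hc0$f, 0, tolerance = 1e-12)
  expect_equal(hc0$p, 1, tolerance = 1e-12)

  expect_error(heritability_comparison(list(a = "g01"), tbl), "2 groups")
  expect_error(heritability_comparison(list(a = tbl$gene[1:2],
                                            b = c("nope1", "nope2")),
                                       tbl), "absent")
})

test_that("null-group heritability comparisons rarely reach significance", {
  set.seed(68)
  hits <- 0
  for (rep in 1:100) {
    tbl <- tibble::tibble(gene = sprintf("g%03d", 1:60), h2 = runif(60))
    g <- list(a = tbl$gene[1:30], b = tbl$gene[31:60])
    if (heritability_comparison(g, tbl)$p <= 0.01) hits <- hits + 1
  }
  expect_lte(hits / 100, 0.05)
})

test_that("marker correlations pick up planted marker-eigengene ties", {
  study <- simulate_scenario(default_scenario(69))
  asg <- study$truth[, c("gene", "module")]
  mes <- module_eigengenes(study$expression$brain, asg)
  mk <- marker_correlations(mes, study$expression$brain, study$markers)
  expect_equal(nrow(mk), length(unique(asg$module[asg$module != "grey"])) *
                 length(study$markers))
  blue_rows <- mk[mk$module == "blue", ]
  expect_true(all(abs(blue_rows$r) >= 0.5))
  # marker identical to an eigengene correlates at 1
  d2 <- study$expression$brain
  d2[1, -1] <- as.list(mes$eigengenes$blue)
  mk2 <- marker_correlations(mes, d2, d2$gene[1])
  expect_equal(mk2$r[mk2$module == "blue"], 1, tolerance = 1e-12)
  # missing markers are skipped with a warning
  expect_warning(mk3 <- marker_correlations(mes, study$expression$brain,
                                            c(study$markers, "ABSENT")),
                 "ABSENT")
  expect_equal(nrow(mk3), nrow(mk))
})

test_that("preserved hubs carry higher simulated heritability", {
  study <- simulate_scenario(default_scenario(70))
  asg <- study$truth[, c("gene", "module")]
  mm <- purrr::imap(study$expression, function(d, tn) {
    module_membership(d, module_eigengenes(d, asg))
  })
  # blue/green share one latent factor; yellow is its own: combine MM only
  # within coalescing groups, select hubs per group, take the union
  hub_genes <- unlist(lapply(list(c("blue", "green"), "yellow"), function(grp) {
    cmm <- lapply(mm, combine_mm, modules = grp, anchor = grp[1])
    select_hub_genes(cmm$brain, cmm$blood, 0.35)$gene
  }))
  hubs <- tibble::tibble(gene = unique(hub_genes))
  expect_gt(nrow(hubs), 20)
  network_genes <- asg$gene[asg$module != "grey"]
  other <- setdiff(network_genes, hubs$gene)
  h <- study$heritability
  wt <- wilcox.test(h$h2[h$gene %in% hubs$gene], h$h2[h$gene %in% other],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
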