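#' Specify a planted co-expression module
#'
#' Each planted module follows a single-factor model: in every tissue
#' where it is preserved, member gene i is generated as
#' `x_i = r_i e_q + sqrt(1 - r_i^2) eps_i`, where `e_q` is that tissue's
#' standard-normal eigengene profile, `r_i` is the gene's target
#' eigengene correlation (kME) drawn once, uniformly, from `kme_range`,
#' and `eps_i` is independent noise. In tissues not listed in
#' `preserved_in`, the same gene symbols carry pure noise.
#'
#' @param label module color/name.
#' @param size gene count (>= 3).
#' @param kme_range length-2 numeric, `0 < low <= high < 1`.
#' @param preserved_in character vector of tissue names where the module's
#'   co-expression structure is reproduced.
#' @param anti_correlated `NULL`, or the label of a partner module whose
#'   eigengene this module's eigengene is the negative of (exercises the
#'   sign-flipping in eigengene and combined-membership analyses).
#' @return list of class `module_spec`.
#' @export
module_spec <- function(label, size, kme_range, preserved_in,
                        anti_correlated = NULL) {
  if (size < 3L) abort("module size must be >= 3")
  if (length(kme_range) != 2L || kme_range[1] <= 0 || kme_range[2] >= 1 ||
      kme_range[1] > kme_range[2]) {
    abort("kme_range must satisfy 0 < low <= high < 1")
  }
  structure(list(label = as.character(label), size = as.integer(size),
                 kme_range = as.numeric(kme_range),
                 preserved_in = as.character(preserved_in),
                 anti_correlated = anti_correlated),
            class = "module_spec")
}

#' Parameterize a multi-tissue synthetic scenario
#'
#' @param tissues named integer vector: sample count per tissue (each >= 4).
#' @param modules list of [module_spec()] objects.
#' @param n_background_genes count of unassigned (grey) pure-noise genes.
#' @param noise_sd residual standard deviation (1 makes each gene's target
#'   kME exact in expectation; other values shrink or inflate it).
#' @param heritability_model length-3 numeric: mean h2 of preserved-hub
#'   genes, mean h2 of all other genes, estimation noise sd. Means must
#'   lie in `[0, 1]`.
#' @param marker_genes number of designated marker ("CD-like") genes
#'   generated with high correlation against the first module preserved
#'   in every tissue.
#' @param seed RNG seed; required explicitly, fully determines all output.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(tissues, modules, n_background_genes = 0,
                               noise_sd = 1,
                               heritability_model = c(0.32, 0.23, 0.1),
                               marker_genes = 0, seed) {
  if (missing(seed)) abort("seed must be given explicitly")
  if (is.null(names(tissues)) || any(names(tissues) == "")) {
    abort("tissues must be a named vector of sample counts")
  }
  if (any(tissues < 4L)) abort("every tissue needs at least 4 samples")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "module_spec")) abort("modules must be module_spec objects")
    bad <- setdiff(m$preserved_in, names(tissues))
    if (length(bad) > 0L) {
      abort(paste0("module '", m$label, "' preserved in unknown tissue(s): ",
                   paste(bad, collapse = ", ")))
    }
    m
  })
  labels <- vapply(modules, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("duplicate module labels")
  for (m in modules) {
    if (!is.null(m$anti_correlated) && !(m$anti_correlated %in% labels)) {
      abort(paste0("anti_correlated partner '", m$anti_correlated, "' is not a module"))
    }
  }
  if (any(heritability_model[1:2] < 0) || any(heritability_model[1:2] > 1)) {
    abort("heritability means must lie in [0, 1]")
  }
  structure(list(
    tissues = tissues, modules = modules,
    n_background_genes = as.integer(n_background_genes),
    noise_sd = noise_sd, heritability_model = as.numeric(heritability_model),
    marker_genes = as.integer(marker_genes), seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' The package's default study scenario
#'
#' Two tissues ("brain", "blood") of 100 samples each; three modules
#' (blue 100, yellow 80, green 60 genes; target kME uniform on 0.6-0.9)
#' preserved in both tissues, with green the negative partner of blue;
#' one brain-only module (brown, 60 genes); 1000 background genes, so
#' preserved-module genes are about a fifth of the universe, the
#' proportion typical of cross-tissue studies where most measured genes
#' sit outside any preserved module;
#' heritability means 0.32 for preserved hubs versus 0.23 otherwise with
#' estimation noise 0.1; five marker genes tied to the blue eigengene.
#'
#' @param seed RNG seed.
#' @return a `synthetic_scenario`.
#' @export
default_scenario <- function(seed) {
  synthetic_scenario(
    tissues = c(brain = 100L, blood = 100L),
    modules = list(
      module_spec("blue", 100, c(0.6, 0.9), c("brain", "blood")),
      module_spec("yellow", 80, c(0.6, 0.9), c("brain", "blood")),
      module_spec("green", 60, c(0.6, 0.9), c("brain", "blood"),
                  anti_correlated = "blue"),
      module_spec("brown", 60, c(0.6, 0.9), "brain")
    ),
    n_background_genes = 1000,
    noise_sd = 1,
    heritability_model = c(0.32, 0.23, 0.1),
    marker_genes = 5,
    seed = seed
  )
}

#' Simulate a multi-tissue expression study
#'
#' Generates one expression tibble per tissue over a shared gene universe,
#' the ground-truth module assignment, a per-gene heritability table and a
#' marker gene list, all determined by the scenario's seed. Per-tissue
#' eigengene profiles are independent draws (different tissues come from
#' different individuals); a gene's target kME `r_i` is drawn once and
#' reused in every tissue where its module is preserved, so connectivity
#' patterns — not just co-membership — are shared across tissues.
#' Heritability estimates are drawn from a truncated normal with the
#' higher mean for preserved-hub genes (members of a module preserved in
#' at least two tissues whose `r_i` is at or above the midpoint of the
#' module's kme_range) and the lower mean otherwise.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list of class `synthetic_study`: `expression` (named list of
#'   expression tibbles), `truth` (tibble gene, module, r, is_hub),
#'   `heritability` (tibble gene, h2), `markers` (character vector),
#'   `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  mods <- scenario$modules
  labels <- vapply(mods, `[[`, character(1), "label")

  gene_tbl <- dplyr::bind_rows(
    purrr::map(mods, function(m) tibble(
      gene = sprintf("%s_%03d", toupper(m$label), seq_len(m$size)),
      module = m$label
    )),
    tibble(
      gene = sprintf("BG_%04d", seq_len(scenario$n_background_genes)),
      module = "grey"
    )
  )
  if (anyDuplicated(gene_tbl$gene)) abort("duplicate gene symbols across modules")

  # target kME per gene, shared across tissues
  gene_tbl$r <- NA_real_
  for (m in mods) {
    idx <- gene_tbl$module == m$label
    gene_tbl$r[idx] <- runif(m$size, m$kme_range[1], m$kme_range[2])
  }

  marker_names <- character(0)
  anchor <- NULL
  if (scenario$marker_genes > 0L) {
    in_all <- vapply(mods, function(m) setequal(m$preserved_in, names(scenario$tissues)),
                     logical(1))
    if (!any(in_all)) abort("marker genes need a module preserved in every tissue")
    anchor <- labels[which(in_all)[1]]
    marker_names <- sprintf("CDL_%02d", seq_len(scenario$marker_genes))
    marker_r <- runif(scenario$marker_genes, 0.7, 0.9)
    gene_tbl <- dplyr::bind_rows(
      gene_tbl, tibble(gene = marker_names, module = "grey", r = marker_r)
    )
  }

  expression <- purrr::imap(as.list(scenario$tissues), function(n_s, tissue) {
    n_s <- as.integer(n_s)
    eig <- list()
    for (m in mods) {                 # partner eigengenes drawn first pass
      if (is.null(m$anti_correlated)) eig[[m$label]] <- rnorm(n_s)
    }
    for (m in mods) {
      if (!is.null(m$anti_correlated)) eig[[m$label]] <- -eig[[m$anti_correlated]]
    }
    vals <- matrix(NA_real_, nrow = nrow(gene_tbl), ncol = n_s)
    for (i in seq_len(nrow(gene_tbl))) {
      mod_i <- gene_tbl$module[i]
      gene_i <- gene_tbl$gene[i]
      is_marker <- gene_i %in% marker_names
      factor_lab <- if (is_marker) anchor else mod_i
      preserved_here <- if (is_marker) {
        TRUE                         # markers track the anchor wherever it lives
      } else {
        mod_i != "grey" && tissue %in% mods[[match(mod_i, labels)]]$preserved_in
      }
      eps <- rnorm(n_s, sd = scenario$noise_sd)
      if (preserved_here && !is.null(eig[[factor_lab]])) {
        r_i <- gene_tbl$r[i]
        vals[i, ] <- r_i * eig[[factor_lab]] + sqrt(1 - r_i^2) * eps
      } else {
        vals[i, ] <- eps
      }
    }
    colnames(vals) <- sprintf("%s_s%03d", tissue, seq_len(n_s))
    rownames(vals) <- gene_tbl$gene
    as_expression(vals)
  })

  n_pres <- vapply(mods, function(m) length(m$preserved_in), integer(1))
  multi <- labels[n_pres >= 2L]
  mid <- setNames(vapply(mods, function(m) mean(m$kme_range), numeric(1)), labels)
  gene_tbl$is_hub <- gene_tbl$module %in% multi &
    gene_tbl$r >= mid[gene_tbl$module]
  gene_tbl$is_hub[is.na(gene_tbl$is_hub)] <- FALSE

  hm <- scenario$heritability_model
  h2 <- rnorm(nrow(gene_tbl),
              mean = ifelse(gene_tbl$is_hub, hm[1], hm[2]), sd = hm[3])
  h2 <- pmin(1, pmax(0, h2))

  structure(list(
    expression = expression,
    truth = gene_tbl,
    heritability = tibble(gene = gene_tbl$gene, h2 = h2),
    markers = marker_names,
    scenario = scenario
  ), class = "synthetic_study")
}

#' Write a simulated study to disk
#'
#' Expression TSV per tissue, truth assignment TSV (gene, module),
#' heritability TSV (gene, h2), marker list (one symbol per line) and the
#' scenario as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tissue in names(study$expression)) {
    write_expression_tsv(study$expression[[tissue]],
                         file.path(dir, paste0("expression_", tissue, ".tsv")))
  }
  readr::write_tsv(study$truth[, c("gene", "module")],
                   file.path(dir, "truth_modules.tsv"), progress = FALSE)
  readr::write_tsv(study$heritability, file.path(dir, "heritability.tsv"),
                   progress = FALSE)
  writeLines(study$markers, file.path(dir, "markers.txt"))
  sc <- study$scenario
  sc$modules <- lapply(sc$modules, unclass)
  jsonlite::write_json(unclass(sc), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
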