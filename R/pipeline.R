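#' Pipeline run configuration
#'
#' A single JSON-serializable list that fully determines a run: input
#' paths (or a synthetic scenario), network parameters, module-detection
#' and preservation settings, downstream thresholds and the output
#' directory. Stage order mirrors the analysis: preprocess, networks,
#' reference modules, preservation in each test tissue, eigengene/MM
#' analyses, hub selection, heritability and markers.
#'
#' @param reference name of the reference tissue.
#' @param inputs named list of expression TSV paths per tissue, or `NULL`
#'   when `scenario_seed` is given (the default scenario is simulated).
#' @param out_dir run directory.
#' @param scenario_seed seed for [default_scenario()] when simulating.
#' @param beta,cor_method network parameters.
#' @param min_module_size,cut_height module-detection settings
#'   (cut_height is the absolute 1 - TOM cut, default 0.99).
#' @param n_perm,seed preservation settings.
#' @param mm_threshold hub-gene combined-MM threshold.
#' @param bonferroni_n Bonferroni multiplier for reports.
#' @param heritability_path,marker_path optional TSV / gene-list paths
#'   (ignored when simulating; the simulated tables are used).
#' @param outlier_z standardized inter-array-correlation cut.
#' @return list of class `run_config`.
#' @export
run_config <- function(reference, inputs = NULL, out_dir,
                       scenario_seed = NULL, beta = 6,
                       cor_method = "pearson", min_module_size = 30,
                       cut_height = 0.99, n_perm = 200, seed,
                       mm_threshold = 0.35, bonferroni_n = 50,
                       heritability_path = NULL, marker_path = NULL,
                       outlier_z = -3) {
  if (missing(seed)) abort("seed is required")
  if (missing(out_dir)) abort("out_dir is required")
  if (is.null(inputs) && is.null(scenario_seed)) {
    abort("either inputs or scenario_seed must be given")
  }
  if (!is.null(inputs)) {
    if (is.null(names(inputs))) abort("inputs must be named by tissue")
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files) > 0L) {
      abort(paste0("input file(s) not found: ", paste(missing_files, collapse = ", ")))
    }
    if (!reference %in% names(inputs)) abort("reference must be one of the input tissues")
  }
  structure(list(
    reference = reference, inputs = inputs, out_dir = out_dir,
    scenario_seed = scenario_seed, beta = beta, cor_method = cor_method,
    min_module_size = min_module_size,
    cut_height = cut_height, n_perm = n_perm,
    seed = as.integer(seed), mm_threshold = mm_threshold,
    bonferroni_n = bonferroni_n, heritability_path = heritability_path,
    marker_path = marker_path, outlier_z = outlier_z
  ), class = "run_config")
}

#' @rdname run_config
#' @param path JSON file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$inputs <- if (length(cfg$inputs) > 0L) as.list(cfg$inputs) else NULL
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

stage_log <- function(dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = file.path(dir, "log.txt"), append = TRUE)
}

#' Run the full cross-tissue preservation pipeline
#'
#' Executes the stages in order, writing each stage's outputs into the
#' run directory (append-only; stages never rewrite earlier outputs) and
#' a final `report.json` aggregating cross-dataset summary correlations,
#' preservation results, hub selections, coverage percentages and, when
#' available, heritability and marker analyses. Identical configurations
#' produce byte-identical reports; wall-clock timing goes only to
#' `log.txt`.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly; the report as attribute
#'   `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir <- config$out_dir
  write_run_config(config, file.path(dir, "config.json"))
  params <- network_params(beta = config$beta, method = config$cor_method)
  # report body carries analysis parameters only; paths live in config.json
  report <- list(parameters = unclass(config)[setdiff(names(config),
                                                      c("out_dir", "inputs"))])

  # -- simulate / load ------------------------------------------------------
  heritability <- NULL; markers <- character(0)
  if (!is.null(config$scenario_seed)) {
    stage_log(dir, "simulate", paste("default scenario, seed", config$scenario_seed))
    study <- simulate_scenario(default_scenario(config$scenario_seed))
    write_study(study, file.path(dir, "simulated"))
    datasets <- study$expression
    heritability <- study$heritability
    markers <- study$markers
  } else {
    stage_log(dir, "load", paste(length(config$inputs), "tissue datasets"))
    datasets <- lapply(config$inputs, read_expression_tsv)
    if (!is.null(config$heritability_path)) {
      heritability <- readr::read_tsv(config$heritability_path,
                                      col_types = "cd", progress = FALSE)
    }
    if (!is.null(config$marker_path)) {
      markers <- readLines(config$marker_path)
      markers <- markers[nzchar(markers)]
    }
  }
  if (!config$reference %in% names(datasets)) abort("reference tissue missing")

  # -- preprocess -----------------------------------------------------------
  for (tissue in names(datasets)) {
    res <- detect_outlier_samples(datasets[[tissue]], z_cut = config$outlier_z)
    if (length(res$flagged) > 0L) {
      stage_log(dir, "preprocess",
                paste0(tissue, ": removed ", length(res$flagged), " outlier arrays"))
    }
    datasets[[tissue]] <- res$filtered
  }
  datasets <- merge_by_symbol(datasets)
  report$n_genes_merged <- nrow(datasets[[1]])
  stage_log(dir, "preprocess", paste("merged universe:", nrow(datasets[[1]]), "genes"))

  ref_name <- config$reference
  test_names <- setdiff(names(datasets), ref_name)

  # -- cross-dataset summary agreement -------------------------------------
  report$summary_agreement <- purrr::map(test_names, function(tn) {
    dplyr::bind_rows(
      compare_gene_summaries(datasets[[ref_name]], datasets[[tn]], "mean",
                             params, config$bonferroni_n),
      compare_gene_summaries(datasets[[ref_name]], datasets[[tn]],
                             "connectivity", params, config$bonferroni_n)
    ) |> dplyr::mutate(test_tissue = tn, .before = 1)
  }) |> dplyr::bind_rows()
  stage_log(dir, "network", "summary agreement computed")

  # -- reference modules ----------------------------------------------------
  det <- detect_modules(datasets[[ref_name]], params,
                        min_module_size = config$min_module_size,
                        cut_height = config$cut_height)
  readr::write_tsv(det$assignment, file.path(dir, "modules_reference.tsv"),
                   progress = FALSE)
  module_sizes <- table(det$assignment$module)
  report$reference_modules <- as.list(module_sizes)
  stage_log(dir, "modules", paste(sum(names(module_sizes) != "grey"),
                                  "modules detected in", ref_name))
  non_grey <- setdiff(names(module_sizes), "grey")
  if (length(non_grey) == 0L) abort("stage modules: no modules detected in reference")

  # -- preservation in each test tissue ------------------------------------
  preservation <- purrr::map(test_names, function(tn) {
    pres <- module_preservation(datasets[[ref_name]], datasets[[tn]],
                                det$assignment, n_perm = config$n_perm,
                                seed = config$seed, params = params)
    write_preservation(pres,
                       json_path = file.path(dir, paste0("preservation_", tn, ".json")),
                       tsv_path = file.path(dir, paste0("preservation_", tn, ".tsv")))
    stage_log(dir, "preserve", paste0(tn, ": ",
                                      sum(pres$summary$verdict == "strong"),
                                      " strong module(s)"))
    pres
  })
  names(preservation) <- test_names
  report$preservation <- purrr::map(preservation, "summary")

  preserved_mods <- Reduce(intersect, purrr::map(preservation, function(p) {
    p$summary$module[p$summary$Zsummary > 10]
  }))
  report$preserved_modules <- preserved_mods
  cov <- coverage_percentages(
    as.integer(module_sizes[preserved_mods]),
    sum(module_sizes[non_grey]), digits = 0
  )
  report$preserved_coverage_pct <- cov$total

  # -- eigengene / MM analyses ---------------------------------------------
  mes <- lapply(datasets, module_eigengenes, assignment = det$assignment)
  if (length(non_grey) >= 2L) {
    en <- eigengene_network(mes[[ref_name]], config$bonferroni_n)
    readr::write_tsv(en$correlations, file.path(dir, "eigengene_network.tsv"),
                     progress = FALSE)
  }
  mm <- purrr::imap(datasets, function(d, tn) {
    module_membership(d, mes[[tn]], config$bonferroni_n)
  })
  for (tn in names(mm)) {
    readr::write_tsv(mm[[tn]], file.path(dir, paste0("mm_", tn, ".tsv")),
                     progress = FALSE)
  }
  stage_log(dir, "downstream", "eigengenes and module membership computed")

  # -- hubs -----------------------------------------------------------------
  # combined MM is only meaningful across modules whose eigengenes have
  # coalesced; group preserved modules by reference-tissue eigengene
  # correlation, combine within groups, select per group, union
  combine_modules <- if (length(preserved_mods) > 0L) preserved_mods else non_grey
  groups <- group_modules_by_eigengene(mes[[ref_name]], combine_modules)
  hub_sets <- lapply(groups, function(grp) {
    cmm <- lapply(names(datasets), function(tn) {
      combine_mm(mm[[tn]], modules = grp)
    })
    names(cmm) <- names(datasets)
    sets <- purrr::map(test_names, function(tn) {
      select_hub_genes(cmm[[ref_name]], cmm[[tn]], config$mm_threshold)$gene
    })
    Reduce(intersect, sets)
  })
  hub_genes <- sort(unique(unlist(hub_sets)))
  writeLines(hub_genes, file.path(dir, "preserved_hub_genes.txt"))
  network_genes <- det$assignment$gene[det$assignment$module != "grey"]
  report$n_hub_genes <- length(hub_genes)
  report$hub_fraction_pct <- coverage_percentages(
    length(hub_genes), length(network_genes), digits = 1
  )$total
  stage_log(dir, "downstream", paste(length(hub_genes), "preserved hub genes"))

  # -- heritability / markers ----------------------------------------------
  if (!is.null(heritability)) {
    groups <- list(
      preserved_hubs = intersect(hub_genes, heritability$gene),
      network_genes = intersect(network_genes, heritability$gene),
      all_genes = heritability$gene
    )
    if (all(lengths(groups) >= 2L)) {
      hc <- heritability_comparison(groups, heritability)
      report$heritability <- list(means = hc$means, f = hc$f, p = hc$p)
      stage_log(dir, "downstream", sprintf("heritability ANOVA p = %.3g", hc$p))
    }
  }
  if (length(markers) > 0L) {
    mk <- marker_correlations(mes[[ref_name]], datasets[[ref_name]], markers,
                              bonferroni_n = config$bonferroni_n)
    readr::write_tsv(mk, file.path(dir, "marker_correlations.tsv"),
                     progress = FALSE)
    report$marker_correlations <- mk
  }

  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  stage_log(dir, "report", "report.json written")
  out <- invisible(dir)
  attr(out, "report") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-linkage grouping of modules whose eigengenes have coalesced
# (|cor| >= threshold); combined MM is only meaningful within such groups
group_modules_by_eigengene <- function(eigengenes, modules, threshold = 0.6) {
  me_tbl <- if (inherits(eigengenes, "eigengene_set")) eigengenes$eigengenes else eigengenes
  modules <- intersect(modules, names(me_tbl))
  if (length(modules) <= 1L) return(list(modules))
  cc <- abs(cor(as.matrix(me_tbl[modules])))
  hc <- hclust(as.dist(1 - cc), method = "single")
  cl <- cutree(hc, h = 1 - threshold)
  unname(split(modules, cl))
}
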