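#' Default pipeline configuration
#'
#' Either supply `expression_path` / `phenotype_path` (TSV / CSV inputs) or
#' leave them NULL to run on a synthetic cohort drawn by [generate_cohort()]
#' with the parameters of the `synthetic` block.
#'
#' @param output_dir Where results are written.
#' @param seed Seed for the synthetic cohort.
#' @return Config list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(output_dir = tempfile("comod_run_"),
                                    seed = 1L) {
  list(
    expression_path = NULL,
    phenotype_path = NULL,
    gene_sets_path = NULL,
    synthetic = list(seed = seed),
    beta = NULL,
    beta_grid = 1:12,
    r2_threshold = 0.8,
    cut_height = "auto",
    min_module_size = 30L,
    refine = TRUE,
    kme_min = 0.3,
    alpha = 0.05,
    traits = c("t2d_status", "hba1c", "secretion_glucose", "secretion_K"),
    covariates = c("age", "sex", "bmi"),
    output_dir = output_dir
  )
}

#' Run the full co-expression analysis pipeline
#'
#' Executes similarity, soft-power selection, adjacency, TOM, module
#' detection (with optional eigengene refinement), eigengenes, eigengene -
#' trait associations (adjusted and unadjusted), gene-set enrichment of each
#' module against the labelled / supplied gene set, and the hub analyses
#' (connectivity - trait correlation, set connectivity comparison). All
#' results are written as TSV/CSV/JSON under `config$output_dir` together
#' with a run log recording seeds, parameters and package version. On a
#' stage failure, partial outputs are kept and a `failed/STAGE` marker is
#' written before the error propagates.
#'
#' @param config List as produced by [default_pipeline_config()], or a path
#'   to a YAML file with the same fields.
#' @return Invisible list with the in-memory results (`network`, `partition`,
#'   `eigengenes`, `associations`, `enrichment`, `kin`, `truth`, `paths`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- utils::modifyList(default_pipeline_config(), yaml::read_yaml(config))
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(cfg$expression_path) && !is.null(cfg$synthetic)) {
    cfg$synthetic <- NULL    # file inputs take precedence; exactly one source
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("comod")),
              r_version = as.character(getRversion()),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = cfg[setdiff(names(cfg), "tree")])
  stage <- "load"
  on_fail <- function(e, stage) {
    dir.create(file.path(cfg$output_dir, "failed"), showWarnings = FALSE)
    writeLines(conditionMessage(e), file.path(cfg$output_dir, "failed", stage))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(name, expr) {
    stage_t0 <- Sys.time()
    message("[comod] stage: ", name)
    out <- tryCatch(expr, error = function(e) on_fail(e, name))
    log$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - stage_t0, units = "secs"))
    out
  }

  inputs <- run_stage("load", {
    if (!is.null(cfg$expression_path)) {
      X <- read_expression_table(cfg$expression_path)
      pheno <- read_phenotype_table(cfg$phenotype_path)
      truth <- NULL
      gene_set <- if (!is.null(cfg$gene_sets_path)) read_gene_sets(cfg$gene_sets_path)[[1L]] else NULL
    } else {
      syn <- do.call(generate_cohort, cfg$synthetic)
      X <- syn$expression
      pheno <- syn$phenotype
      truth <- syn$truth
      gene_set <- truth$labelled_set
      write_expression_table(X, file.path(cfg$output_dir, "expression.tsv"))
      write_phenotype_table(pheno, file.path(cfg$output_dir, "phenotype.csv"))
    }
    list(X = X, pheno = pheno, truth = truth, gene_set = gene_set)
  })
  X <- inputs$X

  net <- run_stage("network", {
    build_network(X, beta = cfg[["beta"]], beta_grid = cfg$beta_grid,
                  r2_threshold = cfg$r2_threshold)
  })
  log$beta <- net$beta
  log$beta_flagged <- net$beta_flagged

  partition <- run_stage("modules", {
    part <- detect_modules(net$D, min_module_size = cfg$min_module_size,
                           cut_height = cfg$cut_height)
    if (isTRUE(cfg$refine)) part <- refine_modules(X, part, kme_min = cfg$kme_min)
    write_partition(part, file.path(cfg$output_dir, "partition.tsv"))
    part
  })

  eigs <- run_stage("eigengenes", {
    eigs <- module_eigengenes(X, partition)
    if (length(eigs)) {
      M <- vapply(eigs, function(e) e$values, numeric(ncol(X)))
      utils::write.table(data.frame(sample_id = colnames(X), M),
                         file.path(cfg$output_dir, "eigengenes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    eigs
  })

  assoc <- run_stage("trait_association", {
    rows <- list()
    for (e in eigs) {
      for (tr in cfg$traits) {
        for (covs in list(character(0L), cfg$covariates)) {
          r <- tryCatch(
            associate_eigengene_trait(e, inputs$pheno, tr, covariates = covs),
            error = function(err) NULL)
          if (!is.null(r)) rows[[length(rows) + 1L]] <- r
        }
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(cfg$output_dir, "trait_associations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    tab
  })

  enr <- run_stage("enrichment", {
    if (is.null(inputs$gene_set) || partition$n_modules == 0L) NULL else {
      rows <- lapply(seq_len(partition$n_modules), function(m) {
        members <- names(partition$labels)[partition$labels == m]
        r <- fisher_enrichment(inputs$gene_set, members, rownames(X))
        cbind(module = m, r)
      })
      tab <- do.call(rbind, rows)
      tab$q <- bh_adjust(tab$p)
      utils::write.table(tab, file.path(cfg$output_dir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      tab
    }
  })

  kin <- run_stage("connectivity", {
    ki <- intramodular_connectivity(net$A, partition)
    utils::write.table(ki, file.path(cfg$output_dir, "kin.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    hub <- NULL
    if (partition$n_modules > 0L && !is.null(inputs$gene_set)) {
      # hub analysis inside the most enriched module (or module 1)
      m <- if (!is.null(enr)) enr$module[which.min(enr$p)] else 1L
      members <- names(partition$labels)[partition$labels == m]
      kv <- stats::setNames(ki$k_in, ki$gene_id)[members]
      gtr <- gene_trait_correlations(X[members, , drop = FALSE], inputs$pheno,
                                     cfg$traits[1L])
      ktc <- connectivity_trait_correlation(kv, gtr)
      set_in <- intersect(inputs$gene_set, members)
      cmp <- if (length(set_in) && length(setdiff(members, set_in))) {
        connectivity_set_comparison(kv, set_in, members)
      } else NULL
      hub <- list(module = m, kin_trait = ktc, set_comparison = cmp)
      jsonlite::write_json(hub, file.path(cfg$output_dir, "hub_analysis.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    list(table = ki, hub = hub)
  })

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(cfg$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(network = net, partition = partition, eigengenes = eigs,
                 associations = assoc, enrichment = enr, kin = kin,
                 truth = inputs$truth,
                 paths = list(output_dir = cfg$output_dir)))
}
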