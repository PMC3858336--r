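#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks for an end-to-end synthetic run:
#' simulate blood counts and expression, estimate the epistasis panel,
#' classify c-Myb gene sets, run enrichment.  Any subset of stages may be
#' enabled; `epistasis` depends on `simulate` output (or a `counts_path`),
#' `genesets` and `gsea` on the simulated expression (or an `expr_path` +
#' annotations).
#'
#' @param stages character vector drawn from
#'   `c("simulate", "epistasis", "genesets", "gsea")`.
#' @param blood a [blood_sim_config()].
#' @param expr an [expr_sim_config()].
#' @param design an [epistasis_design()].
#' @param params a [filter_params()].
#' @param perm a [permutation_config()].
#' @param level confidence level for the epistasis panel.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir output directory, created if needed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "epistasis",
                                       "genesets", "gsea"),
                            blood = blood_sim_config(),
                            expr = expr_sim_config(),
                            design = epistasis_design(),
                            params = filter_params(),
                            perm = permutation_config(),
                            level = 0.95,
                            seed = 1L,
                            out_dir = tempfile("hematrio_run_")) {
  known <- c("simulate", "epistasis", "genesets", "gsea")
  unknown <- setdiff(stages, known)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(stages = stages, blood = blood, expr = expr,
                 design = design, params = params, perm = perm,
                 level = level, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the synthetic analysis pipeline
#'
#' Executes the enabled stages in order (simulate, epistasis, genesets,
#' gsea), writes each stage's tables under `config$out_dir` and returns a
#' run manifest listing every output file and seed used.  A stage failure
#' is recorded in the manifest and halts dependent stages.  Given the same
#' config and seed the outputs are identical apart from the manifest
#' timestamp.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character()
  seeds <- list(global = config$seed)
  failure <- NULL
  blood <- expr <- NULL

  emit <- function(obj, file, writer) {
    p <- file.path(config$out_dir, file)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  if ("simulate" %in% config$stages) {
    cfg_b <- config$blood; cfg_b$seed <- config$seed
    cfg_e <- config$expr; cfg_e$seed <- config$seed + 1L
    seeds$blood <- cfg_b$seed; seeds$expr <- cfg_e$seed
    say("simulate: blood counts (", cfg_b$n_per_group, "/group, ",
        cfg_b$n_experiments, " experiments) and expression (",
        cfg_e$n_genes, " genes)")
    blood <- simulate_blood_counts(cfg_b)
    expr <- simulate_expression(cfg_e)
    emit(blood, "blood_counts.csv", write_counts_csv)
    emit(expr, "expression.gct", write_gct)
    emit(expr, "samples.tsv", write_sample_annotation)
    emit(expr$truth, "expression_truth.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  res <- list()
  run_stage <- function(name, fn) {
    if (!name %in% config$stages || !is.null(failure)) return(invisible())
    r <- tryCatch(fn(), error = function(e) {
      failure <<- list(stage = name, message = conditionMessage(e))
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    res[[name]] <<- r
    invisible()
  }

  run_stage("epistasis", function() {
    if (is.null(blood)) stop("epistasis stage needs simulated blood counts")
    panel <- run_epistasis_panel(blood, config$design, level = config$level)
    emit(panel, "epistasis_panel.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    panel
  })

  run_stage("genesets", function() {
    if (is.null(expr)) stop("genesets stage needs simulated expression")
    means <- average_replicates(expr)
    present <- presence_filter(means, c("WT.ctrl", "WT.myb"),
                               config$params$presence_floor)
    sets <- classify_myb_response(means, "WT.ctrl", "WT.myb",
                                  config$params, genes = present)
    gsr <- kix_sensitivity(sets, means, "WT.myb", "KIX.myb", config$params)
    emit(list(myb_activated = gsr$activated,
              myb_repressed = gsr$repressed,
              kix_sensitive_activated = gsr$kix_sensitive_activated,
              kix_sensitive_repressed = gsr$kix_sensitive_repressed),
         "gene_sets.gmt", write_gmt)
    gsr
  })

  run_stage("gsea", function() {
    if (is.null(expr)) stop("gsea stage needs simulated expression")
    gsr <- res$genesets
    sets <- if (!is.null(gsr)) {
      list(myb_activated = gsr$activated, myb_repressed = gsr$repressed)
    } else {
      stop("gsea stage needs the genesets stage")
    }
    treated <- expr$samples$treatment == "myb"
    sub <- expr$values[, treated, drop = FALSE]
    classes <- expr$samples$genotype[treated]
    cfg_p <- config$perm; cfg_p$seed <- config$seed + 2L
    seeds$gsea <<- cfg_p$seed
    enr <- permutation_significance(sub, classes, sets, cfg_p,
                                    positive_class = "WT")
    emit(as.data.frame(enr), "enrichment.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    enr
  })

  manifest <- list(
    tool = "hematrio",
    version = as.character(utils::packageVersion("hematrio")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stages = config$stages,
    seeds = seeds,
    level = config$level,
    outputs = basename(outputs),
    checksums = stats::setNames(
      vapply(outputs, function(p) unname(tools::md5sum(p)), character(1)),
      basename(outputs)),
    failure = failure
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("run complete: ", length(outputs), " output file(s) in ", config$out_dir)
  invisible(manifest)
}
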