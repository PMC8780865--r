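# Pipeline orchestration: one flat YAML config drives cytotoxicity
# classification, per-chemical differential expression, pathway enrichment
# profiles, module detection and activity, candidate-gene selection and the
# fold-change benchmark, with a deterministic run manifest.

#' Read and validate a run configuration
#'
#' The configuration is a flat YAML file. Recognised keys: input paths
#' (`plates`, `counts`, `design`, `gmt`, `evidence`, `gold`, `models` (a
#' name -> path map), `ortholog_map`), stage parameters (`alpha`, `de_p`,
#' `kme_threshold`, `power`, `min_module_size`, `icx`, `thresholds` as
#' `min:max:step`, `target_modules`, `map_tables`, `chemicals`), and `seed`
#' / `out_dir`. Stages whose inputs are absent are skipped.
#'
#' @param path YAML file path.
#' @param overrides named list overriding config values (CLI flags).
#' @return validated config list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  validate_config(cfg, base = dirname(path))
}

validate_config <- function(cfg, base = ".") {
  defaults <- list(alpha = 0.05, de_p = 0.05, kme_threshold = 0.65,
                   power = "auto", min_module_size = 20,
                   icx = c(10, 50), thresholds = "0:2:0.05",
                   seed = 1, out_dir = "hlctox_out")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("config error: `seed` must be a single integer")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("config error: `alpha` out of (0, 1]")
  path_keys <- c("plates", "counts", "design", "gmt", "evidence", "gold",
                 "ortholog_map")
  for (k in path_keys) {
    if (!is.null(cfg[[k]])) {
      p <- cfg[[k]]
      if (!file.exists(p)) p <- file.path(base, cfg[[k]])
      if (!file.exists(p)) {
        stop(sprintf("config error: `%s` file not found: %s", k, cfg[[k]]))
      }
      cfg[[k]] <- p
    }
  }
  if (!is.null(cfg$models)) {
    for (m in names(cfg$models)) {
      p <- cfg$models[[m]]
      if (!file.exists(p)) p <- file.path(base, cfg$models[[m]])
      if (!file.exists(p)) {
        stop(sprintf("config error: model table not found: %s", cfg$models[[m]]))
      }
      cfg$models[[m]] <- p
    }
  }
  if (!is.null(cfg$counts) && is.null(cfg$design)) {
    stop("config error: `counts` requires `design`")
  }
  cfg
}

parse_grid <- function(spec) {
  if (is.numeric(spec)) return(spec)
  p <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
  if (length(p) != 3 || anyNA(p)) stop("threshold grid must be min:max:step")
  seq(p[1], p[2], by = p[3])
}

log_msg <- function(...) {
  if (!isTRUE(getOption("hlctox.quiet", FALSE))) {
    message("[hlctox] ", sprintf(...))
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order and where inputs are configured: acute-cytotoxicity
#' classification of the LDH plates; per-chemical concentration-response
#' differential expression; pathway enrichment profiles; co-expression
#' module detection, kME and activity scoring; candidate-gene selection;
#' and the fold-change concordance benchmark. All outputs are plain TSV /
#' JSON under `out_dir`, plus a `manifest.json` recording the package
#' version, seed, parameters, and MD5 hashes of inputs and outputs. Runs
#' are byte-identical under a fixed config and seed.
#'
#' @param config config list (from [read_run_config()]) or a YAML path.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @param stages subset of `c("cytotox", "de", "enrich", "modules",
#'   "select-genes", "benchmark")` to run; `NULL` (default) runs every
#'   stage whose inputs are configured. Dependencies are honoured:
#'   `"select-genes"` implies the differential-expression and module
#'   stages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL, stages = NULL) {
  all_stages <- c("cytotox", "de", "enrich", "modules", "select-genes",
                  "benchmark")
  if (!is.null(stages)) {
    bad <- setdiff(stages, all_stages)
    if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  want <- function(s) is.null(stages) || s %in% stages
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_config(config)
  out <- out_dir %||% cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name) {
    p <- file.path(out, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }

  if (want("cytotox") && !is.null(cfg$plates)) {
    log_msg("cytotox: classifying LDH plates")
    plates <- read_plate_tsv(cfg$plates)
    res <- analyze_plates(plates, icx = cfg$icx)
    emit(res$summary, "cytotox_summary.tsv")
  }

  de_tables <- list()
  counts_stage <- any(vapply(c("de", "enrich", "modules", "select-genes"),
                             want, logical(1)))
  if (counts_stage && !is.null(cfg$counts)) {
    counts <- read_counts_tsv(cfg$counts)
    design <- read_design_tsv(cfg$design)
    chems <- cfg$chemicals %||%
      sort(unique(design$chemical[design$concentration_uM > 0]))
    expr <- log2cpm(counts)
    if (want("de") || want("select-genes")) {
      for (ch in chems) {
        log_msg("diffexpr: %s", ch)
        tab <- run_de(counts, design, ch, alpha = cfg$alpha)
        de_tables[[ch]] <- tab
        emit(tab, sprintf("de_%s.tsv", ch))
        if (want("de") && sum(tab$status == "ok") >= 20) {
          zm <- top_gene_zscore_matrix(tab, expr, design, ch, k = 20)
          emit(data.frame(gene = rownames(zm), zm, check.names = FALSE),
               sprintf("heatmap_%s.tsv", ch))
        }
      }
    }

    if (want("enrich") && !is.null(cfg$gmt)) {
      gene_sets <- read_gmt(cfg$gmt)
      prof <- list()
      for (ch in chems) {
        log_msg("enrichment: %s", ch)
        pr <- enrichment_profile(counts, design, ch, gene_sets,
                                 de_p = cfg$de_p)
        pr$records$chemical <- ch
        prof[[ch]] <- pr$records
      }
      emit(do.call(rbind, prof), "enrichment.tsv")
    }

    ms <- NULL
    if (want("modules") || want("select-genes")) {
      log_msg("coexpression: detecting modules")
      ms <- find_modules(expr, power = cfg$power,
                         min_size = cfg$min_module_size)
      emit(data.frame(gene = names(ms$modules), module = unname(ms$modules),
                      kME = unname(ms$kme)), "modules.tsv")
      if (!is.null(ms$eigengenes)) {
        emit(data.frame(sample_id = rownames(ms$eigengenes), ms$eigengenes,
                        check.names = FALSE), "eigengenes.tsv")
        act <- module_activity(expr, ms)
        emit(data.frame(module = rownames(act), act, check.names = FALSE),
             "module_activity.tsv")
      }
    }

    if (want("select-genes") && !is.null(cfg$evidence) &&
        length(de_tables) > 0 && !is.null(ms$kme)) {
      log_msg("gene selection")
      evidence <- readLines(cfg$evidence, warn = FALSE)
      targets <- cfg$target_modules %||%
        setdiff(unique(ms$modules), "unassigned")
      cand <- select_candidates(ms, de_tables, evidence, targets,
                                kme_threshold = cfg$kme_threshold,
                                de_alpha = cfg$alpha)
      emit(cand, "candidates.tsv")
    }
  }

  if (want("benchmark") && !is.null(cfg$gold) && !is.null(cfg$models)) {
    log_msg("benchmark: %d model(s)", length(cfg$models))
    gold <- read_fold_change_tsv(cfg$gold)
    models <- lapply(cfg$models, read_fold_change_tsv)
    om <- if (!is.null(cfg$ortholog_map)) read_ortholog_map_tsv(cfg$ortholog_map)
    bm <- benchmark_models(models, gold, ortholog_map = om,
                           map_tables = cfg$map_tables %||% character(),
                           thresholds = parse_grid(cfg$thresholds))
    emit(bm$curves, "benchmark_curves.tsv")
    emit(bm$similarity, "benchmark_similarity.tsv")
    bj <- file.path(out, "benchmark_summary.json")
    jsonlite::write_json(list(universe_size = bm$universe_size,
                              recovered_at_one = as.list(bm$recovered_at_one)),
                         bj, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "benchmark_summary.json")
  }

  inputs <- cfg[intersect(names(cfg), c("plates", "counts", "design", "gmt",
                                        "evidence", "gold", "ortholog_map"))]
  if (!is.null(cfg$models)) inputs <- c(inputs, cfg$models)
  manifest <- list(
    package = "hlctox",
    version = as.character(utils::packageVersion("hlctox")),
    seed = cfg$seed,
    parameters = cfg[intersect(names(cfg), c("alpha", "de_p", "kme_threshold",
                                             "power", "min_module_size",
                                             "icx", "thresholds",
                                             "target_modules"))],
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1))),
    output_md5 = as.list(vapply(outputs, function(f)
      unname(tools::md5sum(file.path(out, f))), character(1)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate the synthetic demo study and run the pipeline on it
#'
#' Writes all synthetic inputs (LDH plate panel, counts, design, stress
#' gene sets, evidence list, benchmark tables) under `dir/inputs`, a
#' `config.yaml`, and the full pipeline outputs under `dir/results`.
#'
#' @param dir working directory for the demo.
#' @param seed integer seed controlling every synthetic input.
#' @param n_genes probes in the synthetic panel (default 300).
#' @param run run the pipeline on the generated inputs (default `TRUE`);
#'   `FALSE` only writes the inputs and `config.yaml`.
#' @return invisibly, the run manifest (or the config list when
#'   `run = FALSE`).
#' @export
run_demo <- function(dir = tempfile("hlctox_demo"), seed = 1,
                     n_genes = 300, run = TRUE) {
  inp <- file.path(dir, "inputs")
  dir.create(inp, recursive = TRUE, showWarnings = FALSE)

  plates <- simulate_plate_panel(seed = derive_seed(seed, "plates"))
  write_plate_tsv(plates, file.path(inp, "plates.tsv"))

  study <- simulate_study(n_genes = n_genes,
                          seed = derive_seed(seed, "study"))
  write_counts_tsv(study$counts, file.path(inp, "counts.tsv"))
  write_design_tsv(study$design, file.path(inp, "design.tsv"))
  write_gmt(study$gene_sets, file.path(inp, "stress_pathways.gmt"))
  writeLines(sort(unique(unlist(study$responsive_genes))),
             file.path(inp, "evidence.txt"))

  bt <- with_rng(derive_seed(seed, "benchfc"), {
    fc <- stats::setNames(stats::rnorm(200, 0, 1.5), sprintf("B%03d", 1:200))
    benchmark_truth(fc, names(fc)[abs(fc) > 1],
                    concordance = list(
                      hlc = list(scale = 0.8, noise_sd = 0.3),
                      hepg2 = list(scale = 0.4, noise_sd = 0.3),
                      primary_hep = list(scale = 1.0, noise_sd = 0.15)))
  })
  bench <- generate_benchmark(bt, seed = derive_seed(seed, "bench"))
  utils::write.table(bench$gold, file.path(inp, "gold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  model_paths <- list()
  for (m in names(bench$models)) {
    p <- file.path(inp, sprintf("model_%s.tsv", m))
    utils::write.table(bench$models[[m]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    model_paths[[m]] <- p
  }

  cfg <- list(plates = file.path(inp, "plates.tsv"),
              counts = file.path(inp, "counts.tsv"),
              design = file.path(inp, "design.tsv"),
              gmt = file.path(inp, "stress_pathways.gmt"),
              evidence = file.path(inp, "evidence.txt"),
              gold = file.path(inp, "gold.tsv"),
              models = model_paths,
              seed = seed,
              out_dir = file.path(dir, "results"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!run) return(invisible(cfg))
  run_pipeline(cfg)
}
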