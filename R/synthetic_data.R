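# Synthetic data generators: ground-truthed LDH plates, negative-binomial
# count matrices with planted co-expression modules and pathway effects, and
# paired model/gold fold-change tables with controlled concordance.

#' Ground truth for a synthetic LDH cytotoxicity plate
#'
#' Describes one chemical's true dose-response on the cytotoxicity scale
#' (a four-parameter logistic curve) together with the absorbance levels of
#' the untreated negative control and the lysed positive control, and the
#' absorbance-scale noise of the plate reader.
#'
#' @param chemical chemical label.
#' @param b hill slope (unitless, > 0).
#' @param c lower asymptote, percent cytotoxicity.
#' @param d upper asymptote, percent cytotoxicity.
#' @param e inflection concentration in uM (> 0).
#' @param noise_sd Gaussian noise standard deviation on the absorbance scale.
#' @param nc_abs,pc_abs negative-/positive-control absorbance (AU);
#'   `nc_abs < pc_abs` is required.
#' @return an object of class `plate_truth`.
#' @export
#' @examples
#' plate_truth("amiodarone", b = 2, e = 10, d = 80)
plate_truth <- function(chemical, b = 2, c = 0, d = 100, e = 50,
                        noise_sd = 2, nc_abs = 0.2, pc_abs = 0.9) {
  stop_if_not_scalar_number(e, "e")
  if (e <= 0) stop("inflection concentration `e` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (nc_abs >= pc_abs) stop("`nc_abs` must be below `pc_abs`")
  structure(list(chemical = as.character(chemical), b = b, c = c, d = d,
                 e = e, noise_sd = noise_sd, nc_abs = nc_abs,
                 pc_abs = pc_abs),
            class = "plate_truth")
}

#' Simulate an LDH absorbance plate from a dose-response truth
#'
#' Each sample well's absorbance is the control-anchored rescaling of the
#' true cytotoxicity curve,
#' `nc_abs + (pc_abs - nc_abs) * f4PL(conc) / 100`, plus Gaussian noise.
#' Negative- and positive-control wells (one set per replicate) are included
#' with the same noise model.
#'
#' @param truth a [plate_truth()] object.
#' @param concentrations nonnegative treatment concentrations in uM.
#' @param replicates number of replicate wells per concentration (>= 1).
#' @param seed integer seed; fixed seed gives bit-identical plates.
#' @return a data.frame with columns `well_id`, `chemical`,
#'   `concentration_uM`, `role` (`"sample"`, `"NC"` or `"PC"`), `absorbance`.
#' @export
generate_plate <- function(truth, concentrations, replicates = 3, seed = 1) {
  stopifnot(inherits(truth, "plate_truth"))
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (replicates < 1) stop("`replicates` must be at least 1")
  conc <- rep(concentrations, each = replicates)
  cyto <- four_pl(conc, truth$b, truth$c, truth$d, truth$e)
  span <- truth$pc_abs - truth$nc_abs
  n_ctrl <- replicates
  with_rng(seed, {
    abs_sample <- truth$nc_abs + span * cyto / 100 +
      stats::rnorm(length(conc), 0, truth$noise_sd)
    abs_nc <- truth$nc_abs + stats::rnorm(n_ctrl, 0, truth$noise_sd)
    abs_pc <- truth$pc_abs + stats::rnorm(n_ctrl, 0, truth$noise_sd)
    data.frame(
      well_id = sprintf("%s_w%03d", truth$chemical,
                        seq_len(length(conc) + 2L * n_ctrl)),
      chemical = truth$chemical,
      concentration_uM = c(conc, rep(0, 2L * n_ctrl)),
      role = c(rep("sample", length(conc)), rep("NC", n_ctrl),
               rep("PC", n_ctrl)),
      absorbance = c(abs_sample, abs_nc, abs_pc),
      stringsAsFactors = FALSE
    )
  })
}

#' Ground truth for a synthetic targeted-RNA-seq count matrix
#'
#' Bundles the generative parameters of the count simulator: a module
#' assignment for every gene, pathway annotations, per-(gene, chemical)
#' concentration effects on the log2 mean, negative-binomial dispersions,
#' baseline means and expected library sizes.
#'
#' @param module_assignment named character vector, gene -> module label;
#'   every gene has exactly one module.
#' @param pathway_sets named list of character vectors, pathway -> gene ids.
#' @param effect_profile data.frame with columns `gene`, `chemical`,
#'   `log2fc_per_uM`; genes absent for a chemical have zero effect.
#' @param dispersion named numeric vector of NB dispersions alpha >= 0
#'   (variance = mu + alpha * mu^2); one per gene.
#' @param baseline_mean named numeric vector of positive baseline means.
#' @param library_size optional named numeric vector of expected per-sample
#'   total counts; `NULL` leaves the baseline scale untouched.
#' @param module_sdlog log-scale SD of the shared per-(module, sample)
#'   log-normal latent factor that induces within-module correlation.
#' @return an object of class `count_truth`.
#' @export
count_truth <- function(module_assignment, pathway_sets, effect_profile,
                        dispersion, baseline_mean, library_size = NULL,
                        module_sdlog = 0.15) {
  genes <- names(baseline_mean)
  if (is.null(genes)) stop("`baseline_mean` must be named by gene")
  if (!setequal(names(module_assignment), genes) ||
      !setequal(names(dispersion), genes)) {
    stop("module_assignment, dispersion and baseline_mean must cover the same genes")
  }
  if (any(!is.finite(dispersion)) || any(dispersion < 0)) {
    stop("dispersions must be finite and nonnegative")
  }
  if (any(baseline_mean <= 0)) stop("baseline means must be positive")
  if (!all(c("gene", "chemical", "log2fc_per_uM") %in% names(effect_profile))) {
    stop("`effect_profile` needs columns gene, chemical, log2fc_per_uM")
  }
  structure(list(
    module_assignment = module_assignment[genes],
    pathway_sets = pathway_sets,
    effect_profile = effect_profile,
    dispersion = dispersion[genes],
    baseline_mean = baseline_mean,
    library_size = library_size,
    module_sdlog = module_sdlog
  ), class = "count_truth")
}

#' Simulate a probe-level count matrix from a count truth
#'
#' Counts are drawn from a negative binomial with mean
#' `size_factor * baseline * 2^(effect * concentration) * latent`, where
#' `latent` is a log-normal factor shared by all genes of a module within a
#' sample (inducing positive within-module correlation) and the NB variance
#' is `mu + alpha * mu^2` (`alpha = 0` degenerates to Poisson).
#'
#' @param truth a [count_truth()] object.
#' @param design a sample design data.frame with columns `sample_id`,
#'   `chemical`, `concentration_uM` (plus optional `time_h`, `replicate`).
#' @param seed integer seed.
#' @return integer matrix, genes x samples, with dimnames.
#' @export
generate_counts <- function(truth, design, seed = 1) {
  stopifnot(inherits(truth, "count_truth"))
  if (any(design$concentration_uM < 0)) stop("design concentrations must be nonnegative")
  known <- unique(truth$effect_profile$chemical)
  treated <- design$chemical[design$concentration_uM > 0]
  if (length(setdiff(unique(treated), c(known, "vehicle", "control"))) > 0 &&
      nrow(truth$effect_profile) > 0) {
    unknown <- setdiff(unique(treated), c(known, "vehicle", "control"))
    stop(sprintf("chemical(s) not in effect profile: %s",
                 paste(unknown, collapse = ", ")))
  }
  genes <- names(truth$baseline_mean)
  g <- length(genes)
  n <- nrow(design)
  modules <- unique(truth$module_assignment)
  mod_idx <- match(truth$module_assignment, modules)

  # log2 effect per uM for each gene under each sample's chemical
  eff <- matrix(0, g, n)
  if (nrow(truth$effect_profile) > 0) {
    key <- paste(truth$effect_profile$gene, truth$effect_profile$chemical)
    eff_map <- stats::setNames(truth$effect_profile$log2fc_per_uM, key)
    for (j in seq_len(n)) {
      k <- paste(genes, design$chemical[j])
      hit <- k %in% names(eff_map)
      if (any(hit)) eff[hit, j] <- eff_map[k[hit]]
    }
  }

  sf <- rep(1, n)
  if (!is.null(truth$library_size)) {
    ls <- truth$library_size[design$sample_id]
    if (anyNA(ls)) stop("library_size must be named by design sample ids")
    sf <- ls / sum(truth$baseline_mean)
  }

  with_rng(seed, {
    # shared latent factor per (module, sample); mean 1 on the natural scale
    sdl <- truth$module_sdlog
    lat <- matrix(stats::rlnorm(length(modules) * n, meanlog = -sdl^2 / 2,
                                sdlog = sdl),
                  length(modules), n)
    conc <- matrix(design$concentration_uM, g, n, byrow = TRUE)
    mu <- truth$baseline_mean * 2^(eff * conc) * lat[mod_idx, , drop = FALSE] *
      matrix(sf, g, n, byrow = TRUE)
    counts <- matrix(0L, g, n, dimnames = list(genes, design$sample_id))
    alpha <- truth$dispersion
    pois <- alpha == 0
    for (i in seq_len(g)) {
      counts[i, ] <- if (pois[i]) stats::rpois(n, mu[i, ])
                     else stats::rnbinom(n, size = 1 / alpha[i], mu = mu[i, ])
    }
    counts
  })
}

#' Ground truth for a synthetic fold-change benchmark
#'
#' @param gold_log2fc named numeric vector of gold-standard log2 fold
#'   changes.
#' @param gold_de_set character vector of genes designated differentially
#'   expressed in the gold standard; must have nonzero gold fold change.
#' @param concordance named list, one entry per model, each a list with
#'   `scale` (multiplier on the gold fold change) and `noise_sd`.
#' @return an object of class `benchmark_truth`.
#' @export
benchmark_truth <- function(gold_log2fc, gold_de_set, concordance) {
  if (length(gold_log2fc) == 0) stop("empty gene universe")
  if (is.null(names(gold_log2fc))) stop("`gold_log2fc` must be named by gene")
  bad <- setdiff(gold_de_set, names(gold_log2fc)[gold_log2fc != 0])
  if (length(bad) > 0) {
    stop("gold DE genes must have nonzero gold fold change: ",
         paste(bad, collapse = ", "))
  }
  for (m in names(concordance)) {
    if (!all(is.finite(unlist(concordance[[m]])))) {
      stop("concordance values must be finite")
    }
  }
  structure(list(gold_log2fc = gold_log2fc, gold_de_set = gold_de_set,
                 concordance = concordance),
            class = "benchmark_truth")
}

#' Simulate paired model/gold fold-change tables
#'
#' Each model's log2 fold change is `scale * gold + N(0, noise_sd)`, so the
#' downstream per-gene similarity ratio is controlled by construction.
#'
#' @param truth a [benchmark_truth()] object.
#' @param seed integer seed.
#' @return a list with `gold` (data.frame `gene`, `log2fc`, `de_flag`) and
#'   `models` (named list of data.frames `gene`, `log2fc`).
#' @export
generate_benchmark <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "benchmark_truth"))
  genes <- names(truth$gold_log2fc)
  gold <- data.frame(gene = genes, log2fc = unname(truth$gold_log2fc),
                     de_flag = genes %in% truth$gold_de_set,
                     stringsAsFactors = FALSE)
  models <- vector("list", length(truth$concordance))
  names(models) <- names(truth$concordance)
  for (i in seq_along(models)) {
    cc <- truth$concordance[[i]]
    fc <- with_rng(derive_seed(seed, names(models)[i]), {
      cc$scale * truth$gold_log2fc +
        stats::rnorm(length(genes), 0, cc$noise_sd)
    })
    models[[i]] <- data.frame(gene = genes, log2fc = unname(fc),
                              stringsAsFactors = FALSE)
  }
  list(gold = gold, models = models)
}

#' Build the synthetic study: design, truth and counts for a chemical panel
#'
#' Emulates a targeted stress-panel experiment: `n_genes` probes partitioned
#' into co-expression modules, eight stress-pathway gene sets carved out of
#' the first modules, and concentration-dependent log2 effects planted in
#' the pathway genes of the responsive chemicals. Defaults describe the
#' study conditions used throughout the package's tests and demo: five
#' concentrations per chemical (vehicle included), three replicates,
#' moderate NB dispersion, and log-normal library sizes with CV 0.2.
#'
#' @param n_genes number of probes.
#' @param n_modules number of planted co-expression modules.
#' @param chemicals character vector of treatment chemicals.
#' @param responsive named list, chemical -> list(pathways = character,
#'   effect = log2FC per unit of scaled concentration); chemicals absent
#'   here are transcriptionally silent.
#' @param concentrations per-chemical concentration series (uM), vehicle 0
#'   first; shared across chemicals on a relative scale.
#' @param replicates replicates per concentration.
#' @param dispersion_range range of per-gene NB dispersions.
#' @param baseline_range range of per-gene baseline mean counts.
#' @param library_cv coefficient of variation of expected library sizes.
#' @param module_sdlog within-module latent-factor log-SD.
#' @param seed integer seed.
#' @return list with `truth` (a [count_truth()]), `design` (data.frame),
#'   `counts` (matrix), `gene_sets` (named list) and `responsive_genes`
#'   (named list, chemical -> planted genes).
#' @export
simulate_study <- function(n_genes = 400,
                           n_modules = 8,
                           chemicals = c("amiodarone", "paraquat",
                                         "diclofenac", "clozapine",
                                         "gentamicin", "ibuprofen",
                                         "olanzapine"),
                           responsive = list(
                             amiodarone = list(pathways = c("ATF4", "XBP1"), effect = 0.9),
                             diclofenac = list(pathways = c("ATF4", "XBP1", "NRF2"), effect = 1.2),
                             paraquat = list(pathways = c("NRF2", "HIF1A"), effect = 0.8),
                             clozapine = list(pathways = "P53", effect = 0.6),
                             ibuprofen = list(pathways = "ATF4", effect = 0.7)
                           ),
                           concentrations = c(0, 0.25, 0.5, 1, 2),
                           replicates = 3,
                           dispersion_range = c(0.01, 0.2),
                           baseline_range = c(50, 500),
                           library_cv = 0.2,
                           module_sdlog = 0.2,
                           seed = 1) {
  pathways <- c("ATF4", "XBP1", "NRF2", "HIF1A", "PPARG", "AhR", "P53", "NFKB")
  genes <- sprintf("G%04d", seq_len(n_genes))
  modules <- sprintf("mod%02d", seq_len(n_modules))
  # contiguous gene blocks per module
  block <- rep(seq_len(n_modules),
               diff(round(seq(0, n_genes, length.out = n_modules + 1))))
  assignment <- stats::setNames(modules[block], genes)
  # one stress pathway per leading module (pathway sets nest inside modules so
  # planted pathway effects and planted modules reinforce each other)
  gene_sets <- list()
  for (i in seq_along(pathways)) {
    mod <- modules[((i - 1) %% n_modules) + 1]
    members <- genes[assignment == mod]
    gene_sets[[pathways[i]]] <- members[seq_len(min(30, length(members)))]
  }
  eff <- do.call(rbind, lapply(names(responsive), function(ch) {
    spec <- responsive[[ch]]
    gs <- unique(unlist(gene_sets[spec$pathways]))
    data.frame(gene = gs, chemical = ch, log2fc_per_uM = spec$effect,
               stringsAsFactors = FALSE)
  }))
  if (is.null(eff)) eff <- data.frame(gene = character(), chemical = character(),
                                      log2fc_per_uM = numeric())
  # register transcriptionally silent chemicals with an explicit zero effect
  silent <- setdiff(chemicals, names(responsive))
  if (length(silent) > 0) {
    eff <- rbind(eff, data.frame(gene = genes[1], chemical = silent,
                                 log2fc_per_uM = 0, stringsAsFactors = FALSE))
  }

  design <- do.call(rbind, lapply(chemicals, function(ch) {
    expand.grid(replicate = seq_len(replicates),
                concentration_uM = concentrations,
                chemical = ch, stringsAsFactors = FALSE)
  }))
  design$time_h <- 48
  design$sample_id <- sprintf("%s_c%g_r%d", design$chemical,
                              design$concentration_uM, design$replicate)
  design <- design[, c("sample_id", "chemical", "concentration_uM",
                       "time_h", "replicate")]

  par <- with_rng(derive_seed(seed, "truthpars"), list(
    dispersion = stats::setNames(stats::runif(n_genes, dispersion_range[1],
                                              dispersion_range[2]), genes),
    baseline = stats::setNames(stats::runif(n_genes, baseline_range[1],
                                            baseline_range[2]), genes),
    libsize = NULL
  ))
  if (library_cv > 0) {
    sdl <- sqrt(log(1 + library_cv^2))
    par$libsize <- with_rng(derive_seed(seed, "libsize"), {
      stats::setNames(sum(par$baseline) *
                        stats::rlnorm(nrow(design), -sdl^2 / 2, sdl),
                      design$sample_id)
    })
  }
  truth <- count_truth(assignment, gene_sets, eff, par$dispersion,
                       par$baseline, par$libsize, module_sdlog = module_sdlog)
  counts <- generate_counts(truth, design, seed = derive_seed(seed, "counts"))
  responsive_genes <- lapply(responsive, function(spec)
    unique(unlist(gene_sets[spec$pathways])))
  list(truth = truth, design = design, counts = counts,
       gene_sets = gene_sets, responsive_genes = responsive_genes)
}

#' Simulate the 14-chemical LDH plate panel
#'
#' Four acutely hepatotoxic chemicals (amiodarone, paraquat, diclofenac,
#' clozapine) get genuine dose-dependent LDH release; the remaining ten get
#' flat curves, mirroring the panel composition of an acute hepatotoxicity
#' screen.
#'
#' @param seed integer seed.
#' @param replicates replicate wells per concentration.
#' @param noise_sd absorbance noise SD.
#' @return one data.frame of plate wells for all 14 chemicals.
#' @export
simulate_plate_panel <- function(seed = 1, replicates = 3, noise_sd = 0.01) {
  responsive <- list(
    amiodarone = list(e = 10, d = 80, b = 2),
    paraquat = list(e = 50, d = 90, b = 1.5),
    diclofenac = list(e = 100, d = 70, b = 2.5),
    clozapine = list(e = 40, d = 60, b = 2)
  )
  flat <- c("gentamicin", "lead_chloride", "ceria_nanoparticles", "busulfan",
            "doxorubicin", "cyclosporine_a", "pamidronate", "ibuprofen",
            "olanzapine", "valproic_acid")
  plates <- list()
  for (ch in names(responsive)) {
    p <- responsive[[ch]]
    tr <- plate_truth(ch, b = p$b, c = 0, d = p$d, e = p$e,
                      noise_sd = noise_sd)
    conc <- p$e * c(0, 1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)
    plates[[ch]] <- generate_plate(tr, conc, replicates,
                                   seed = derive_seed(seed, ch))
  }
  for (ch in flat) {
    tr <- plate_truth(ch, b = 1, c = 0, d = 0.0, e = 50, noise_sd = noise_sd)
    conc <- c(0, 6.25, 12.5, 25, 50, 100, 200, 400)
    plates[[ch]] <- generate_plate(tr, conc, replicates,
                                   seed = derive_seed(seed, ch))
  }
  do.call(rbind, c(plates, list(make.row.names = FALSE)))
}
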