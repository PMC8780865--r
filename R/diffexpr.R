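# Per-gene concentration-response differential expression: median-of-ratios
# normalisation, log2 CPM, a negative-binomial GLM with a linear
# concentration covariate and Wald test, BH adjustment, and the top-gene
# Z-score matrix used for heatmaps.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across zero-free genes of
#' the ratio of its count to the per-gene geometric mean reference; factors
#' are rescaled to geometric mean 1. When no gene is free of zeros the
#' function falls back to total-count ratios with a warning.
#'
#' @param counts nonnegative gene x sample count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  zero_free <- rowSums(counts == 0) == 0
  if (!any(zero_free)) {
    warning("no zero-free gene; falling back to total-count ratios")
    sf <- colSums(counts)
  } else {
    ref <- apply(counts[zero_free, , drop = FALSE], 1, geo_mean)
    sf <- apply(counts[zero_free, , drop = FALSE] / ref, 2, stats::median)
  }
  sf <- sf / geo_mean(sf)
  stats::setNames(sf, colnames(counts))
}

#' log2 counts-per-million
#'
#' `log2(1e6 * count / library_size + 1)` with library size the column sum;
#' the pseudocount of 1 bounds zero counts at 0. When size factors are
#' supplied, counts are first divided by them (the closed form above is
#' recovered when all factors are 1).
#'
#' @param counts gene x sample count matrix.
#' @param size_factors optional positive per-sample factors.
#' @return matrix of log2 CPM values, same dimnames as `counts`.
#' @export
log2cpm <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(size_factors)) {
    if (any(size_factors <= 0)) stop("size factors must be positive")
    counts <- sweep(counts, 2, size_factors, "/")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero column sum: empty sample")
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
}

# Method-of-moments NB dispersion, pooled across concentration groups on
# size-factor-normalised counts: alpha = max(0, sum w (s^2 - m) / sum w m^2)
# with w the within-group degrees of freedom. No cross-gene shrinkage.
mom_dispersion <- function(y, groups) {
  num <- 0; den <- 0
  for (g in unique(groups)) {
    yi <- y[groups == g]
    if (length(yi) < 2) next
    w <- length(yi) - 1
    m <- mean(yi)
    num <- num + w * (stats::var(yi) - m)
    den <- den + w * m^2
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Fit the per-gene concentration-response NB GLM
#'
#' Negative-binomial GLM with log link, `log(size_factor)` offset and the
#' linear model `intercept + beta * concentration`; dispersion is a pooled
#' method-of-moments estimate across concentration groups (no cross-gene
#' shrinkage), degenerating to a Poisson GLM at dispersion 0. Significance
#' is the Wald statistic `beta / SE(beta)` with the standard error scaled
#' by the residual Pearson dispersion of the fit and referred to a
#' t distribution on the residual degrees of freedom — a quasi-likelihood
#' small-sample correction that keeps the test calibrated at the few
#' replicates typical of a screen.
#'
#' @param counts integer counts for one gene across samples.
#' @param concentrations sample concentrations (uM), >= 2 distinct values.
#' @param size_factors positive per-sample factors (default all 1).
#' @param dispersion NB dispersion alpha; `NULL` (default) estimates it by
#'   method of moments; `0` forces the Poisson fit.
#' @return one-row data.frame: `beta`, `se`, `wald`, `p`, `mean_expr`,
#'   `dispersion`, `status` (`"ok"`, `"untestable"` or `"nonconverged"`).
#' @export
fit_gene_glm <- function(counts, concentrations, size_factors = NULL,
                         dispersion = NULL) {
  n <- length(counts)
  if (length(concentrations) != n) stop("length mismatch")
  if (length(unique(concentrations)) < 2) stop("need >= 2 distinct concentrations")
  if (n < 3) stop("need >= 3 samples")
  sf <- size_factors %||% rep(1, n)
  if (any(sf <= 0)) stop("size factors must be positive")
  # normalise to geometric mean 1 so a common rescaling of the factors
  # cannot leak into the dispersion estimate or the test
  sf <- sf / geo_mean(sf)
  out <- data.frame(beta = 0, se = NA_real_, wald = NA_real_, p = 1,
                    mean_expr = mean(counts / sf), dispersion = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  if (all(counts == 0)) {
    out$status <- "untestable"
    return(out)
  }
  alpha <- dispersion %||% mom_dispersion(counts / sf, concentrations)
  out$dispersion <- alpha
  fam <- if (alpha <= 0) stats::poisson()
         else MASS::negative.binomial(theta = 1 / alpha)
  fit <- tryCatch(
    suppressWarnings(stats::glm(counts ~ concentrations,
                                family = fam, offset = log(sf))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    out$status <- "nonconverged"
    return(out)
  }
  sm <- summary(fit, dispersion = 1)
  cf <- sm$coefficients
  if (nrow(cf) < 2 || !is.finite(cf[2, 2]) || cf[2, 2] <= 0) {
    out$status <- "nonconverged"
    return(out)
  }
  # quasi-likelihood scale: residual Pearson dispersion of the working fit
  df_res <- fit$df.residual
  phi <- if (df_res > 0) {
    max(sum(stats::residuals(fit, "pearson")^2) / df_res, 1e-8)
  } else 1
  beta_ln <- cf[2, 1]                 # per-uM effect on the natural-log mean
  se_ln <- cf[2, 2] * sqrt(phi)
  out$beta <- beta_ln / log(2)        # report on the log2 scale
  out$se <- se_ln / log(2)
  out$wald <- beta_ln / se_ln
  out$p <- if (df_res > 0) 2 * stats::pt(-abs(out$wald), df = df_res)
           else 2 * stats::pnorm(-abs(out$wald))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1 and
#' returned in the original order (wraps [stats::p.adjust()]).
#'
#' @param p p-values in `[0, 1]`; `NA` is rejected.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Concentration-response differential expression for one chemical
#'
#' Subsets the design to the chemical's samples (vehicle included), fits the
#' per-gene NB GLM of [fit_gene_glm()] against the raw uM concentration (or
#' `log10(conc + 1)` when `log_conc = TRUE`), adjusts p-values by BH, and
#' returns the table sorted by adjusted p. The DE set is
#' `p_adj < alpha`.
#'
#' @param counts gene x sample count matrix.
#' @param design design data.frame (`sample_id`, `chemical`,
#'   `concentration_uM`, ...). Samples at concentration 0 are shared vehicle
#'   controls and are always included.
#' @param chemical chemical to test.
#' @param alpha adjusted-p threshold defining the DE set (default 0.05).
#' @param log_conc use log10(concentration + 1) as the covariate.
#' @return data.frame sorted by `p_adj`: `gene`, `beta`, `se`, `wald`, `p`,
#'   `p_adj`, `mean_expr`, `status`, `de`.
#' @export
run_de <- function(counts, design, chemical, alpha = 0.05, log_conc = FALSE) {
  if (!chemical %in% design$chemical) {
    stop(sprintf("chemical '%s' absent from design", chemical))
  }
  keep <- design$chemical == chemical | design$concentration_uM == 0
  des <- design[keep, , drop = FALSE]
  counts <- as.matrix(counts)[, des$sample_id, drop = FALSE]
  conc <- des$concentration_uM
  if (length(unique(conc)) < 2) stop("need vehicle plus >= 1 concentration")
  if (log_conc) conc <- log10(conc + 1)
  sf <- size_factors(counts)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    fit_gene_glm(counts[i, ], conc, sf)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(gene = rownames(counts), tab, stringsAsFactors = FALSE)
  tab$p_adj <- bh_adjust(tab$p)
  tab$de <- tab$p_adj < alpha & tab$status == "ok"
  ord <- order(tab$p_adj, tab$p, -abs(tab$beta), tab$gene)
  rownames(tab) <- NULL
  tab[ord, c("gene", "beta", "se", "wald", "p", "p_adj", "mean_expr",
             "status", "de")]
}

#' Z-score matrix of the top differentially expressed genes
#'
#' Selects the `k` genes with smallest adjusted p (ties broken by larger
#' `|beta|`, then gene id), averages their log2 CPM over replicates within
#' each concentration, and standardises each gene's row to mean 0 and SD 1
#' across concentrations — the matrix behind a dose-response heatmap.
#'
#' @param de_table output of [run_de()].
#' @param expr log2 CPM matrix (genes x samples), as from [log2cpm()].
#' @param design design rows matching `expr`'s columns.
#' @param chemical chemical whose samples (plus vehicle) to use.
#' @param k number of genes (default 20).
#' @return gene x concentration matrix of Z-scores.
#' @export
top_gene_zscore_matrix <- function(de_table, expr, design, chemical, k = 20) {
  testable <- de_table[de_table$status == "ok", , drop = FALSE]
  if (nrow(testable) < k) stop("fewer than k testable genes")
  ord <- order(testable$p_adj, -abs(testable$beta), testable$gene)
  top <- testable$gene[ord][seq_len(k)]
  keep <- design$chemical == chemical | design$concentration_uM == 0
  des <- design[keep, , drop = FALSE]
  concs <- sort(unique(des$concentration_uM))
  if (length(concs) < 2) stop("need >= 2 concentrations to standardise")
  avg <- vapply(concs, function(cc) {
    ids <- des$sample_id[des$concentration_uM == cc]
    rowMeans(expr[top, ids, drop = FALSE])
  }, numeric(length(top)))
  avg <- matrix(avg, nrow = length(top),
                dimnames = list(top, as.character(concs)))
  z <- t(apply(avg, 1, function(r) (r - mean(r)) / stats::sd(r)))
  z <- matrix(z, nrow = nrow(avg), dimnames = dimnames(avg))
  z
}
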