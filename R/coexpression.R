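# Signed co-expression networks: soft-thresholded adjacency, topological
# overlap, hierarchical module detection, module eigengenes/kME, and a
# rank-based per-sample module-activity score.

#' Signed soft-thresholded co-expression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power` with Pearson correlation across
#' samples, so anticorrelated genes get adjacency near 0 (the signed
#' convention) and the diagonal is exactly 1. Zero-variance genes get zero
#' off-diagonal adjacency, with a warning.
#'
#' @param expr gene x sample expression matrix (e.g. log2 CPM).
#' @param power soft-threshold exponent, >= 1.
#' @return symmetric gene x gene adjacency in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, power = 12) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (power < 1) stop("power must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(expr)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s): correlations set to 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  a <- ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Pick the soft-threshold power by approximate scale-free fit
#'
#' For each candidate power, regresses log10 frequency on log10 mean
#' connectivity over 10 connectivity bins and returns the smallest power
#' whose fit reaches `r2_target`; falls back to 12 when none qualifies or
#' the network is too small to assess.
#'
#' @param expr gene x sample expression matrix.
#' @param powers candidate powers (>= 1), ascending.
#' @param r2_target scale-free model fit target (default 0.8).
#' @return list with `power`, and `fit_table` (power, r2, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16),
                                r2_target = 0.8) {
  expr <- as.matrix(expr)
  if (any(powers < 1)) stop("candidate powers must be >= 1")
  powers <- sort(powers)
  if (nrow(expr) < 20) {
    warning("fewer than 20 genes: returning fallback power 12")
    return(list(power = 12, fit_table = NULL))
  }
  rows <- lapply(powers, function(p) {
    a <- signed_adjacency(expr, p)
    k <- rowSums(a) - 1
    data.frame(power = p, r2 = scale_free_r2(k), mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2) & tab$r2 >= r2_target)
  list(power = if (length(ok) > 0) tab$power[ok[1]] else 12, fit_table = tab)
}

# R^2 of log10(frequency) ~ log10(mean connectivity) over 10 bins of k
scale_free_r2 <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < nbins) return(NA_real_)
  bins <- cut(k, breaks = nbins)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
  summary(fit)$r.squared
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i` the connectivity excluding the diagonal and the sum over `u`
#' excluding `i` and `j`; the diagonal is 1, and the dissimilarity used for
#' clustering is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return symmetric TOM matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-8)) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a   # (A^2)_ij counts shared neighbours u != i, j since diag 0
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' fraction (`cut_height_frac`, default 0.99) of the maximal merge height;
#' clusters below `min_size` are labelled `"unassigned"`. Modules whose
#' eigengenes correlate above `merge_cor` are merged once after detection.
#' Labels are `"M1", "M2", ...` in decreasing size order, with the lowest
#' gene index breaking ties.
#'
#' @param dissimilarity square gene x gene dissimilarity (1 - TOM).
#' @param expr gene x sample expression matrix, needed for eigengene-based
#'   merging; `NULL` skips merging.
#' @param min_size minimal module size (default 20, >= 2).
#' @param cut_height_frac fraction of the maximal merge height at which the
#'   tree is cut (default 0.99).
#' @param merge_cor eigengene correlation above which modules merge
#'   (default 0.9).
#' @return an object of class `module_set`: list with `modules` (named gene
#'   -> label vector), `eigengenes` (sample x module matrix, when `expr`
#'   given), `kme` (named vector), `dendrogram` (hclust).
#' @export
detect_modules <- function(dissimilarity, expr = NULL, min_size = 20,
                           cut_height_frac = 0.99, merge_cor = 0.9) {
  if (min_size < 2) stop("min_size must be >= 2")
  d <- as.matrix(dissimilarity)
  genes <- rownames(d) %||% sprintf("g%d", seq_len(nrow(d)))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- cut_height_frac * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  labels <- ifelse(sizes[as.character(raw)] >= min_size,
                   as.character(raw), "unassigned")
  names(labels) <- genes

  if (!is.null(expr)) {
    labels <- merge_close_modules(labels, expr, merge_cor)
  }
  # deterministic relabel: decreasing size, ties by lowest member index
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) > 0) {
    size <- vapply(mods, function(m) sum(labels == m), integer(1))
    first <- vapply(mods, function(m) which(labels == m)[1], integer(1))
    mods <- mods[order(-size, first)]
    map <- stats::setNames(sprintf("M%d", seq_along(mods)), mods)
    labels[labels != "unassigned"] <- map[labels[labels != "unassigned"]]
  }
  out <- list(modules = labels, eigengenes = NULL, kme = NULL,
              dendrogram = tree)
  class(out) <- "module_set"
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    mods <- setdiff(unique(labels), "unassigned")
    eg <- sapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m]))
    if (length(mods) > 0) {
      eg <- matrix(eg, ncol = length(mods),
                   dimnames = list(colnames(expr), mods))
      kme_all <- stats::setNames(rep(NA_real_, length(labels)), names(labels))
      for (m in mods) {
        members <- names(labels)[labels == m]
        kme_all[members] <- kme(expr[members, , drop = FALSE], eg[, m])
      }
      out$eigengenes <- eg
      out$kme <- kme_all
    }
  }
  out
}

# single merging pass: join module pairs whose eigengenes correlate above
# the threshold (transitively, via connected components)
merge_close_modules <- function(labels, expr, merge_cor) {
  expr <- as.matrix(expr)
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) < 2) return(labels)
  eg <- sapply(mods, function(m)
    module_eigengene(expr, names(labels)[labels == m]))
  cc <- stats::cor(eg)
  parent <- seq_along(mods)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(mods)) for (j in seq_along(mods)) {
    if (i < j && cc[i, j] > merge_cor) {
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_along(mods), find, integer(1))
  map <- stats::setNames(mods[root], mods)
  labels[labels != "unassigned"] <- map[labels[labels != "unassigned"]]
  labels
}

#' Module eigengene
#'
#' First principal component of the gene-standardised module submatrix,
#' returned as a unit-norm per-sample score vector, sign-oriented so that
#' its mean correlation with the module's genes is positive.
#'
#' @param expr gene x sample expression matrix.
#' @param module_genes gene ids of the module (nonempty).
#' @return numeric vector of per-sample scores (unit norm).
#' @export
module_eigengene <- function(expr, module_genes) {
  if (length(module_genes) == 0) stop("module is empty")
  x <- as.matrix(expr)[module_genes, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  xs <- (x - rowMeans(x)) / sds
  sv <- svd(xs, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  cors <- suppressWarnings(stats::cor(t(x), eg))
  if (mean(cors, na.rm = TRUE) < 0) eg <- -eg
  stats::setNames(eg, colnames(x))
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression profile with an eigengene;
#' the cluster-centrality measure used for candidate-gene selection.
#'
#' @param expr gene x sample expression matrix (rows are the genes to score).
#' @param eigengene per-sample eigengene scores.
#' @return named numeric vector in `[-1, 1]`.
#' @export
kme <- function(expr, eigengene) {
  x <- as.matrix(expr)
  stats::setNames(as.numeric(suppressWarnings(stats::cor(t(x), eigengene))),
                  rownames(x))
}

#' Rank-based per-sample module activity
#'
#' Within each sample, all genes are ranked by expression; a module's
#' activity is the difference between the mean rank of its genes and the
#' mean rank of the remaining genes, divided by the maximal attainable gap
#' (half the number of genes), giving a score in `[-1, 1]` that is
#' invariant to any monotone transform of the sample's expression values.
#'
#' @param expr gene x sample expression matrix.
#' @param modules named gene -> module label vector (a `module_set`'s
#'   `modules`, or any labelling; `"unassigned"` genes count only as
#'   background).
#' @return module x sample activity matrix.
#' @export
module_activity <- function(expr, modules) {
  expr <- as.matrix(expr)
  if (is.list(modules) && inherits(modules, "module_set")) {
    modules <- modules$modules
  }
  modules <- modules[rownames(expr)]
  mods <- setdiff(unique(modules), "unassigned")
  if (length(mods) == 0) stop("no assigned module")
  g <- nrow(expr)
  ranks <- apply(expr, 2, rank)
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    idx <- which(modules == m)
    if (length(idx) == g) stop("module covers all genes; activity undefined")
    gap_max <- g / 2
    out[m, ] <- (colMeans(ranks[idx, , drop = FALSE]) -
                   colMeans(ranks[-idx, , drop = FALSE])) / gap_max
  }
  out
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$modules)
  cat("module_set with", sum(names(tab) != "unassigned"), "modules over",
      length(x$modules), "genes\n")
  print(tab)
  invisible(x)
}

#' One-call module detection from expression
#'
#' Convenience wrapper: adjacency at the given (or automatically picked)
#' power, TOM, and [detect_modules()].
#'
#' @param expr gene x sample expression matrix (log2 CPM recommended).
#' @param power soft threshold; `"auto"` runs [pick_soft_threshold()].
#' @param min_size minimal module size.
#' @param ... passed to [detect_modules()].
#' @return a `module_set` (with `power` attribute).
#' @export
find_modules <- function(expr, power = "auto", min_size = 20, ...) {
  if (identical(power, "auto")) {
    power <- pick_soft_threshold(expr)$power
  }
  adj <- signed_adjacency(expr, power)
  tom <- tom_similarity(adj)
  ms <- detect_modules(1 - tom, expr = expr, min_size = min_size, ...)
  attr(ms, "power") <- power
  ms
}
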