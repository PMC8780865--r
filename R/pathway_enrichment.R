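# Stress-pathway overrepresentation: a hypergeometric-variance z-score per
# pathway per treatment, and concentration-resolved enrichment profiles.

#' Hypergeometric overrepresentation z-score
#'
#' With `N` probes in the universe, `R` differentially expressed, `n`
#' annotated to the pathway and `r` both,
#' `z = (r - n R / N) / sqrt(n (R/N) (1 - R/N) (1 - (n - 1)/(N - 1)))` —
#' the observed pathway DE count standardised by the mean and variance of
#' the hypergeometric draw of `n` probes from the universe. Symmetric in
#' `n` and `R`. Degenerate configurations (`R` 0 or `N`, `n` 0, or
#' `n = N = 1`) have zero variance and return `NA`.
#'
#' @param N,R,r,n nonnegative integer counts with `r` at most `min(n, R)`,
#'   `n <= N`, `R <= N`, `N >= 2`; vectors recycle.
#' @return z-score(s), `NA` where the variance is zero.
#' @export
#' @examples
#' enrichment_zscore(3000, 300, 10, 30)
enrichment_zscore <- function(N, R, r, n) {
  if (any(N < 2)) stop("universe must contain at least 2 probes")
  if (any(r > pmin(n, R)) || any(n > N) || any(R > N) ||
      any(c(N, R, r, n) < 0)) {
    stop("require 0 <= r <= min(n, R), n <= N, R <= N")
  }
  q <- R / N
  v <- n * q * (1 - q) * (1 - (n - 1) / (N - 1))
  z <- suppressWarnings((r - n * q) / sqrt(v))
  # degenerate configurations (R = 0, R = N, n = 0 or n = N) have zero
  # variance and no defined score
  z[rep_len(v <= 0, length(z))] <- NA_real_
  z
}

#' Parse a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to GMT
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @param description per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description, gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway overrepresentation among DE probes
#'
#' Intersects every gene set with the assayed probe universe and scores it
#' with [enrichment_zscore()]; a pathway is flagged significant when
#' `|z| >= threshold`, with direction the sign of the excess of the observed
#' pathway DE count over its expectation `n*R/N`.
#'
#' @param de_flags named logical vector over the whole probe universe
#'   (`TRUE` = differentially expressed, conventionally at raw p < 0.05).
#' @param gene_sets named list of pathway gene sets (GMT-style).
#' @param threshold significance threshold on `|z|` (default 1.96).
#' @return data.frame: `pathway`, `N`, `R`, `n`, `r`, `z`, `direction`,
#'   `significant`; pathways with no probe in the universe are skipped with
#'   a warning.
#' @export
enrich_pathways <- function(de_flags, gene_sets, threshold = 1.96) {
  if (length(de_flags) == 0) stop("empty probe universe")
  universe <- names(de_flags)
  if (is.null(universe)) stop("`de_flags` must be named by probe")
  N <- length(universe)
  R <- sum(de_flags)
  rows <- lapply(names(gene_sets), function(pw) {
    members <- intersect(gene_sets[[pw]], universe)
    n <- length(members)
    if (n == 0) {
      warning(sprintf("pathway '%s' has no probes in the universe; skipped", pw))
      return(NULL)
    }
    r <- sum(de_flags[members])
    z <- if (R == 0 || R == N || N < 2) NA_real_
         else enrichment_zscore(N, R, r, n)
    data.frame(pathway = pw, N = N, R = R, n = n, r = r, z = z,
               direction = sign(r - n * R / N),
               significant = !is.na(z) && abs(z) >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), N = integer(), R = integer(),
                      n = integer(), r = integer(), z = numeric(),
                      direction = numeric(), significant = logical())
  }
  rownames(out) <- NULL
  out
}

#' Concentration-resolved pathway enrichment profile
#'
#' For each positive concentration of the chemical, recomputes DE flags
#' from the vehicle-vs-that-concentration contrast (per-gene NB GLM, raw
#' `p < de_p` by default, matching the enrichment score's own DE
#' definition) and scores every pathway, yielding a pathway x concentration
#' z matrix.
#'
#' @param counts gene x sample count matrix.
#' @param design design data.frame.
#' @param chemical chemical to profile.
#' @param gene_sets named list of pathway gene sets.
#' @param de_p DE p-value cutoff (default 0.05, unadjusted).
#' @param adjusted flag DE on BH-adjusted p instead of raw p.
#' @param threshold significance threshold on `|z|`.
#' @return list with `z` (pathway x concentration matrix) and `records`
#'   (long data.frame with one row per pathway per concentration).
#' @export
enrichment_profile <- function(counts, design, chemical, gene_sets,
                               de_p = 0.05, adjusted = FALSE,
                               threshold = 1.96) {
  concs <- sort(unique(design$concentration_uM[design$chemical == chemical]))
  concs <- concs[concs > 0]
  if (length(concs) < 1) stop("chemical has no positive concentration")
  counts <- as.matrix(counts)
  recs <- list()
  for (cc in concs) {
    keep <- (design$chemical == chemical & design$concentration_uM == cc) |
      design$concentration_uM == 0
    des <- design[keep, , drop = FALSE]
    tab <- run_de(counts[, des$sample_id, drop = FALSE], des, chemical)
    pv <- if (adjusted) tab$p_adj else tab$p
    flags <- stats::setNames(pv < de_p & tab$status == "ok", tab$gene)
    flags <- flags[rownames(counts)]
    er <- enrich_pathways(flags, gene_sets, threshold = threshold)
    if (nrow(er) > 0) er$concentration_uM <- cc
    recs[[as.character(cc)]] <- er
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  pws <- unique(records$pathway)
  z <- matrix(NA_real_, length(pws), length(concs),
              dimnames = list(pws, as.character(concs)))
  for (i in seq_len(nrow(records))) {
    z[records$pathway[i], as.character(records$concentration_uM[i])] <-
      records$z[i]
  }
  list(z = z, records = records)
}
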