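# Cross-model fold-change concordance: ortholog harmonisation to a common
# gene space restricted to the gold-standard DE set, the per-gene similarity
# ratio of model to gold log2 fold change, recovery curves over a threshold
# grid, and the count recovered at similarity >= 1.

#' Harmonize fold-change tables onto the gold-standard DE gene space
#'
#' Non-human gene symbols are mapped through the supplied two-column
#' ortholog table (ambiguous one-to-many rows, in either direction, are
#' dropped with a warning, as are unmapped symbols); the gene space is then
#' the intersection of all tables, restricted to the gold-standard DE set.
#'
#' @param tables named list of model fold-change data.frames (`gene`,
#'   `log2fc`, optional `p_adj`, `de_flag`).
#' @param gold gold-standard data.frame (`gene`, `log2fc`, plus `de_flag`
#'   or `p_adj`).
#' @param ortholog_map optional data.frame (`source_symbol`,
#'   `human_symbol`) applied to any table whose `map` attribute or listing
#'   in `map_tables` requests it.
#' @param map_tables names of the tables whose symbols need ortholog
#'   mapping (default none).
#' @param gold_alpha adjusted-p cutoff defining the gold DE set when
#'   `de_flag` is absent (default 0.05).
#' @return list with `gold` and `models` restricted to the common gold-DE
#'   universe, and `universe` (the gene ids retained).
#' @export
harmonize_tables <- function(tables, gold, ortholog_map = NULL,
                             map_tables = character(), gold_alpha = 0.05) {
  if (length(tables) == 0) stop("no model tables supplied")
  if (!is.null(ortholog_map) && length(map_tables) > 0) {
    dup <- ortholog_map$source_symbol[duplicated(ortholog_map$source_symbol)]
    dup2 <- ortholog_map$human_symbol[duplicated(ortholog_map$human_symbol)]
    amb <- ortholog_map$source_symbol %in% dup |
      ortholog_map$human_symbol %in% dup2
    if (any(amb)) {
      warning(sum(amb), " ambiguous ortholog mapping(s) dropped")
      ortholog_map <- ortholog_map[!amb, , drop = FALSE]
    }
    map <- stats::setNames(ortholog_map$human_symbol,
                           ortholog_map$source_symbol)
    for (nm in map_tables) {
      tab <- tables[[nm]]
      mapped <- map[tab$gene]
      if (anyNA(mapped)) {
        warning(sum(is.na(mapped)), " unmapped symbol(s) dropped from '",
                nm, "'")
      }
      tab$gene <- unname(mapped)
      tables[[nm]] <- tab[!is.na(tab$gene), , drop = FALSE]
    }
  }
  gold_de <- if ("de_flag" %in% names(gold)) {
    gold$gene[gold$de_flag]
  } else if ("p_adj" %in% names(gold)) {
    gold$gene[gold$p_adj < gold_alpha]
  } else {
    stop("gold table needs a `de_flag` or `p_adj` column to define its DE set")
  }
  universe <- Reduce(intersect, c(list(gold$gene), lapply(tables, `[[`, "gene")))
  universe <- intersect(universe, gold_de)
  if (length(universe) == 0) stop("empty common gene space after harmonization")
  shrink <- function(tab) {
    tab <- tab[match(universe, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  list(gold = shrink(gold), models = lapply(tables, shrink),
       universe = universe)
}

#' Per-gene similarity of model to gold fold change
#'
#' `Si = log2FC_model / log2FC_gold`: 1 means the model reproduces the gold
#' induction exactly, 0.5 half of it, and a sign mismatch yields a negative
#' value. Genes with zero gold fold change (excluded upstream by the gold-DE
#' restriction) return `NA`.
#'
#' @param fc_model,fc_gold log2 fold changes (vectors recycle).
#' @return similarity ratio(s).
#' @export
similarity <- function(fc_model, fc_gold) {
  ifelse(fc_gold == 0, NA_real_, fc_model / fc_gold)
}

#' Recovery curve over a similarity-threshold grid
#'
#' For each threshold `t`, counts the gold-DE genes whose similarity is at
#' least `t` (signed comparison: discordant genes never count at
#' nonnegative thresholds).
#'
#' @param si per-gene similarity values (nonempty; `NA` dropped).
#' @param thresholds ascending threshold grid (default 0 to 2 by 0.05).
#' @return data.frame `threshold`, `count`; `universe_size` attribute.
#' @export
recovery_curve <- function(si, thresholds = seq(0, 2, by = 0.05)) {
  si <- si[!is.na(si)]
  if (length(si) == 0) stop("empty similarity set")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  counts <- vapply(thresholds, function(t) sum(si >= t), integer(1))
  out <- data.frame(threshold = thresholds, count = counts)
  attr(out, "universe_size") <- length(si)
  out
}

#' Genes recovered at similarity >= 1
#'
#' The headline benchmark count: genes whose fold induction in the model is
#' of equal or higher magnitude (same direction) than in the gold standard.
#'
#' @param si per-gene similarity values.
#' @return integer count.
#' @export
recovered_at_one <- function(si) {
  sum(si >= 1, na.rm = TRUE)
}

#' Run the full fold-change concordance benchmark
#'
#' Harmonizes all tables, computes per-gene similarity, the recovery curve
#' and the similarity >= 1 count for each model.
#'
#' @inheritParams harmonize_tables
#' @param thresholds passed to [recovery_curve()].
#' @return list with `universe_size`, `similarity` (long data.frame:
#'   `model`, `gene`, `fc_model`, `fc_gold`, `si`), `curves` (long
#'   data.frame: `model`, `threshold`, `count`), `recovered_at_one` (named
#'   integer vector).
#' @export
benchmark_models <- function(tables, gold, ortholog_map = NULL,
                             map_tables = character(), gold_alpha = 0.05,
                             thresholds = seq(0, 2, by = 0.05)) {
  h <- harmonize_tables(tables, gold, ortholog_map, map_tables, gold_alpha)
  sims <- lapply(names(h$models), function(m) {
    data.frame(model = m, gene = h$universe,
               fc_model = h$models[[m]]$log2fc, fc_gold = h$gold$log2fc,
               si = similarity(h$models[[m]]$log2fc, h$gold$log2fc),
               stringsAsFactors = FALSE)
  })
  sims <- do.call(rbind, sims)
  curves <- do.call(rbind, lapply(names(h$models), function(m) {
    rc <- recovery_curve(sims$si[sims$model == m], thresholds)
    cbind(model = m, rc, stringsAsFactors = FALSE)
  }))
  r1 <- vapply(names(h$models), function(m)
    recovered_at_one(sims$si[sims$model == m]), integer(1))
  list(universe_size = length(h$universe), similarity = sims,
       curves = curves, recovered_at_one = r1)
}
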