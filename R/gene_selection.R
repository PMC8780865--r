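# Candidate stress-gene selection: the intersection of cluster centrality,
# concentration-dependent induction, and curated literature evidence.

#' Select candidate genes by centrality, induction and evidence
#'
#' A gene is selected when it (1) belongs to one of the target modules with
#' kME strictly above `kme_threshold`, (2) shows significantly increasing
#' induction with concentration for at least one chemical (`beta > 0` and
#' `p_adj < de_alpha`), and (3) appears on the curated evidence list.
#' Candidates are ranked by kME (descending), ties by best adjusted p, then
#' gene id.
#'
#' @param assignment a `module_set` (from [detect_modules()] /
#'   [find_modules()]) or a list with `modules` and `kme`.
#' @param de_tables named list of [run_de()] tables, one per chemical.
#' @param evidence_list character vector of curated gene ids.
#' @param target_modules module labels to draw candidates from (nonempty).
#' @param kme_threshold cluster-centrality cutoff, strict (default 0.65).
#' @param de_alpha adjusted-p cutoff for the induction filter (default 0.05).
#' @return data.frame: `gene`, `module`, `kme`, `best_chemical`,
#'   `best_p_adj`, ranked as above; zero rows when nothing passes.
#' @export
select_candidates <- function(assignment, de_tables, evidence_list,
                              target_modules, kme_threshold = 0.65,
                              de_alpha = 0.05) {
  if (length(target_modules) == 0) stop("no target modules given")
  if (kme_threshold <= 0 || kme_threshold > 1) {
    stop("kme_threshold must lie in (0, 1]")
  }
  modules <- assignment$modules
  kme_v <- assignment$kme
  central <- names(modules)[modules %in% target_modules &
                              !is.na(kme_v) & kme_v > kme_threshold]
  induced <- lapply(de_tables, function(tab) {
    tab$gene[tab$status == "ok" & tab$beta > 0 & tab$p_adj < de_alpha]
  })
  induced_any <- unique(unlist(induced))
  hits <- Reduce(intersect, list(central, induced_any,
                                 unique(as.character(evidence_list))))
  if (length(hits) == 0) {
    return(data.frame(gene = character(), module = character(),
                      kme = numeric(), best_chemical = character(),
                      best_p_adj = numeric(), stringsAsFactors = FALSE))
  }
  best <- t(vapply(hits, function(g) {
    ps <- vapply(names(de_tables), function(ch) {
      tab <- de_tables[[ch]]
      i <- match(g, tab$gene)
      if (!is.na(i) && tab$status[i] == "ok" && tab$beta[i] > 0) {
        tab$p_adj[i]
      } else NA_real_
    }, numeric(1))
    i <- which.min(ps)
    c(chem = names(de_tables)[i], p = unname(ps[i]))
  }, character(2)))
  out <- data.frame(gene = hits, module = unname(modules[hits]),
                    kme = unname(kme_v[hits]),
                    best_chemical = unname(best[, "chem"]),
                    best_p_adj = as.numeric(best[, "p"]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$kme, out$best_p_adj, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
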