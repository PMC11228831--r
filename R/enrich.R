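# Fisher-exact enrichment of functional terms among inversion genes against
# the genomic background, with Benjamini-Hochberg FDR control.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value by the point-probability convention: the sum of
#' hypergeometric probabilities of all tables (with fixed margins) no more
#' probable than the observed one, with a small relative slack on the
#' comparison. The reported odds ratio is the sample cross-product
#' `(a d) / (b c)`; zero cells give 0 or Inf rather than a conditional MLE.
#' Degenerate margins (an empty row or column) give `p = 1`.
#'
#' @param a,b,c,d non-negative integer cell counts: `a` = inversion genes
#'   with the term, `b` = inversion genes without, `c` = background genes
#'   with, `d` = background genes without.
#' @return `list(odds_ratio, p_two_sided)`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  .assert(all(cells >= 0), "cell counts must be non-negative")
  .assert(all(cells == round(cells)), "cell counts must be integers")
  .assert(sum(cells) > 0, "grand total must be positive")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(odds_ratio = or, p_two_sided = 1))
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  list(odds_ratio = or, p_two_sided = min(p, 1))
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return q values in the original order, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  .assert(all(p_values >= 0 & p_values <= 1, na.rm = FALSE),
          "p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of inversion genes against the background
#'
#' Tests each functional term once (regardless of category) with a 2x2
#' Fisher's exact test comparing term membership among inversion genes versus
#' the rest of the gene universe, then adjusts across terms with
#' Benjamini-Hochberg. Terms carried by no gene are skipped. No ontology
#' graph propagation is performed: terms are tested exactly as annotated.
#'
#' @param annotations data frame with columns `gene_id`, `term_id` and
#'   optionally `category` (one row per assignment).
#' @param ci_genes character vector of genes inside the inversion; must all
#'   belong to the universe.
#' @param universe optional character vector of all genes (the test
#'   universe); defaults to the genes present in `annotations` plus
#'   `ci_genes`.
#' @param alpha FDR threshold for the significant subset (default 0.05).
#' @return `list(records, significant, category_counts)`: `records` has one
#'   row per tested term (`term_id, category, a, b, c, d, odds_ratio,
#'   p_two_sided, q_bh, significant`), sorted by `q_bh`;
#'   `category_counts` tallies significant terms per category.
#' @export
term_enrichment <- function(annotations, ci_genes, universe = NULL,
                            alpha = 0.05) {
  .assert(length(ci_genes) > 0, "the inversion gene set is empty")
  ci_genes <- unique(as.character(ci_genes))
  universe <- unique(as.character(universe %||%
                                    c(annotations$gene_id, ci_genes)))
  outside <- setdiff(ci_genes, universe)
  .assert(length(outside) == 0L,
          paste0("inversion genes absent from the universe: ",
                 paste(utils::head(outside, 5), collapse = ", ")))
  n_ci <- length(ci_genes)
  n_bg <- length(universe) - n_ci
  genes_by_term <- split(annotations$gene_id, annotations$term_id)
  cat_by_term <- if ("category" %in% names(annotations)) {
    u <- !duplicated(annotations$term_id)
    stats::setNames(as.character(annotations$category[u]),
                    annotations$term_id[u])
  } else NULL
  is_ci <- stats::setNames(universe %in% ci_genes, universe)
  rows <- lapply(names(genes_by_term), function(term) {
    g <- unique(genes_by_term[[term]])
    g <- g[g %in% universe]
    a <- sum(is_ci[g])
    cc <- length(g) - a
    if (a + cc == 0) return(NULL)
    ft <- fisher_exact_2x2(a, n_ci - a, cc, n_bg - cc)
    data.frame(term_id = term,
               category = if (is.null(cat_by_term)) "NA" else
                 cat_by_term[[term]],
               a = a, b = n_ci - a, c = cc, d = n_bg - cc,
               odds_ratio = ft$odds_ratio, p_two_sided = ft$p_two_sided)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  .assert(length(rows) > 0, "no testable terms")
  rec <- do.call(rbind, rows)
  rec$q_bh <- bh_fdr(rec$p_two_sided)
  rec$significant <- rec$q_bh <= alpha
  rec <- rec[order(rec$q_bh, rec$p_two_sided, rec$term_id), ]
  rownames(rec) <- NULL
  sig <- rec[rec$significant, , drop = FALSE]
  category_counts <- table(factor(sig$category,
                                  levels = c("BP", "MF", "CC", "NA")))
  list(records = rec, significant = sig,
       category_counts = as.list(category_counts))
}
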