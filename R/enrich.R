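#' Fisher's exact test on a 2x2 contingency table
#'
#' Cell layout: `a` = in-set and annotated, `b` = in-set not annotated,
#' `c` = annotated outside the set, `d` = neither. The default one-sided
#' `"greater"` alternative tests enrichment of the annotation in the set
#' (upper hypergeometric tail); `"two.sided"` is available.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The p-value.
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("Fisher test undefined: a table margin is zero")
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control: adjusted values are monotone in the
#' p-value ranking, capped at 1, and returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Term enrichment of a gene set against a universe
#'
#' For every annotation term with at least one annotated gene in the
#' universe, builds the 2x2 table (in set vs not) x (annotated vs not), runs
#' the one-sided Fisher exact test for enrichment, and applies
#' Benjamini-Hochberg correction across all tested terms.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all genes considered.
#' @param annotations data.frame with columns `gene`, `term` (one pair per
#'   row), e.g. from [read_annotations()].
#' @param alpha significance threshold applied to the adjusted p-values.
#' @return data.frame with one row per tested term: counts, odds ratio, raw
#'   and adjusted p, and a `significant` flag; ordered by adjusted p.
#' @export
go_enrichment <- function(gene_set, universe, annotations, alpha = 0.05) {
  universe <- unique(as.character(universe))
  gene_set <- unique(as.character(gene_set))
  if (length(universe) == 0L) stop("empty gene universe")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (is.null(annotations$gene) || is.null(annotations$term) ||
      nrow(annotations) == 0L)
    stop("annotations must be a nonempty data.frame with columns gene, term")
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotations fall inside the universe")
  # degenerate tables (a zero margin) admit no enrichment: p = 1
  p_or_1 <- function(a, b, cc, d) {
    if (min(a + b, cc + d, a + cc, b + d) == 0) 1
    else fisher_exact(a, b, cc, d)
  }
  by_term <- split(unique(ann[c("gene", "term")])$gene,
                   unique(ann[c("gene", "term")])$term)
  rows <- lapply(names(by_term), function(tm) {
    genes <- by_term[[tm]]
    a <- length(intersect(gene_set, genes))
    b <- length(gene_set) - a
    cc <- length(genes) - a
    d <- length(universe) - a - b - cc
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(term = tm, set_annotated = a, set_other = b,
               out_annotated = cc, out_other = d, odds_ratio = or,
               p = p_or_1(a, b, cc, d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p)
  res$significant <- res$p_adjusted <= alpha
  res[order(res$p_adjusted, res$p, res$term), , drop = FALSE]
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV file with columns gene, term (no ontology propagation is
#'   applied).
#' @return data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop("annotation file needs two columns: gene, term")
  stats::setNames(ann[, 1:2], c("gene", "term"))
}
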