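#' Conservative percentile subsets of feature weights
#'
#' Selects the top (or bottom) X-percentile features by weight with a
#' conservative tie rule: on the positive side the cutoff is the smallest
#' weight value above which X\% or less of all features lie, and only
#' features strictly above it are returned; ties straddling the cutoff are
#' therefore excluded rather than over-selecting. The negative side is the
#' exact mirror (largest value below which X\% or less lie, strict "below").
#' Consequently the selected set never exceeds `floor(X/100 * n)` features.
#'
#' @param weights named numeric vector of feature weights.
#' @param X percentile in (0, 50].
#' @param side `"positive"` (largest weights) or `"negative"` (smallest).
#' @return Character vector of selected feature names (possibly empty; a
#'   warning is issued when all weights are tied).
#' @export
percentile_threshold <- function(weights, X,
                                 side = c("positive", "negative")) {
  side <- match.arg(side)
  stopifnot(!is.null(names(weights)), X > 0, X <= 50)
  n <- length(weights)
  limit <- floor(X / 100 * n)
  vals <- sort(unique(weights))
  if (length(vals) == 1L) {
    warning("all weights are equal; percentile subset is empty")
    return(character(0))
  }
  if (side == "positive") {
    ok <- vals[vapply(vals, function(v) sum(weights > v) <= limit,
                      logical(1))]
    cutoff <- min(ok) # smallest qualifying weight value
    names(weights)[weights > cutoff]
  } else {
    ok <- vals[vapply(vals, function(v) sum(weights < v) <= limit,
                      logical(1))]
    cutoff <- max(ok) # largest qualifying weight value
    names(weights)[weights < cutoff]
  }
}

#' Importance ranks and percentile flags for model feature weights
#'
#' Orders features by weight to define an importance rank (1 = largest
#' positive weight, i.e. most strongly associated with the positive class;
#' the last rank is the most negative weight) and flags membership in the
#' conservative top/bottom 10th and 25th percentile subsets (see
#' [percentile_threshold()]).
#'
#' @param weights named numeric vector (e.g. `coef()` of a [cc_classify()]
#'   fit).
#' @return data.frame with columns `feature`, `weight`, `rank`, `top10`,
#'   `top25`, `bottom10`, `bottom25`, ordered by rank.
#' @export
importance_table <- function(weights) {
  stopifnot(!is.null(names(weights)))
  ord <- order(-weights, names(weights))
  res <- data.frame(feature = names(weights)[ord],
                    weight = unname(weights)[ord],
                    rank = seq_along(weights),
                    stringsAsFactors = FALSE)
  flag <- function(X, side) {
    sel <- suppressWarnings(percentile_threshold(weights, X, side))
    res$feature %in% sel
  }
  res$top10 <- flag(10, "positive"); res$top25 <- flag(25, "positive")
  res$bottom10 <- flag(10, "negative"); res$bottom25 <- flag(25, "negative")
  rownames(res) <- NULL
  res
}

# Split a tagged feature id ("tag:TF" or "tag:P->S") into its TF members.
feature_members <- function(ids) {
  core <- sub("^[^:]*:", "", ids)
  lapply(strsplit(core, "->", fixed = TRUE), function(p) p)
}

#' Importance subnetwork from top-percentile features
#'
#' Builds the GRN spanned by the top-decile features of the general
#' cell-cycle model: FFL-pair features contribute directed TF-TF edges,
#' TF-target features contribute (possibly isolated) TF nodes. Each edge is
#' annotated with the set of phases in whose phase-specific model the same
#' feature is also in the top percentile. Modules are the connected
#' components of the undirected projection.
#'
#' @param top_features character vector of tagged feature ids selected for
#'   the general model (e.g. from [percentile_threshold()]).
#' @param phase_top named list (phase -> character vector) of top feature ids
#'   of each phase-specific model.
#' @return Object of class `importance_grn`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `feature`, `phases` as comma-joined string), `membership`
#'   (named module id per node), `n_modules`, `n_isolated`.
#' @export
build_importance_grn <- function(top_features, phase_top = list()) {
  if (length(top_features) == 0L) {
    warning("empty top feature set; returning an empty network")
    return(structure(list(nodes = character(0),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             feature = character(),
                                             phases = character(),
                                             stringsAsFactors = FALSE),
                          membership = integer(0), n_modules = 0L,
                          n_isolated = 0L),
                     class = "importance_grn"))
  }
  members <- feature_members(top_features)
  is_pair <- lengths(members) == 2L
  nodes <- unique(unlist(members))
  edges <- if (any(is_pair)) {
    pair <- members[is_pair]
    feat <- top_features[is_pair]
    ann <- vapply(feat, function(f) {
      ph <- names(phase_top)[vapply(phase_top, function(s) f %in% s,
                                    logical(1))]
      paste(ph, collapse = ",")
    }, character(1))
    data.frame(from = vapply(pair, `[`, character(1), 1L),
               to = vapply(pair, `[`, character(1), 2L),
               feature = feat, phases = unname(ann),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), feature = character(),
               phases = character(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  structure(list(nodes = nodes, edges = edges,
                 membership = comp$membership,
                 n_modules = comp$no,
                 n_isolated = sum(deg == 0)),
            class = "importance_grn")
}

#' @export
print.importance_grn <- function(x, ...) {
  cat(sprintf(
    "Importance GRN: %d TFs, %d TF-TF edges, %d modules (%d isolated TFs)\n",
    length(x$nodes), nrow(x$edges), x$n_modules, x$n_isolated))
  invisible(x)
}

#' Write an importance subnetwork as an annotated edge/node TSV pair
#'
#' @param x an `importance_grn`.
#' @param edge_path,node_path output TSV paths (node table carries module
#'   membership).
#' @return `edge_path`, invisibly.
#' @export
write_importance_grn <- function(x, edge_path, node_path) {
  utils::write.table(x$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- data.frame(node = x$nodes,
                      module = unname(x$membership[x$nodes]))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}

#' Enrichment of annotated regulators among important TFs
#'
#' One-sided Fisher exact test of whether TFs annotated as (cell-cycle)
#' regulators are over-represented among the top-percentile TF set, against
#' the universe of all TFs in the model's feature set.
#'
#' @param top_tfs character vector of important TFs.
#' @param annotated character vector of annotated regulators (subset of
#'   `all_tfs`).
#' @param all_tfs the TF universe.
#' @return List with the 2x2 counts and the one-sided p-value.
#' @export
known_regulator_enrichment <- function(top_tfs, annotated, all_tfs) {
  all_tfs <- unique(all_tfs)
  if (length(all_tfs) == 0L) stop("empty TF universe")
  if (!all(annotated %in% all_tfs))
    stop("annotated regulators must lie inside the TF universe")
  top_tfs <- intersect(unique(top_tfs), all_tfs)
  a <- length(intersect(top_tfs, annotated))
  b <- length(top_tfs) - a
  cc <- length(setdiff(annotated, top_tfs))
  d <- length(all_tfs) - a - b - cc
  p <- if (min(a + b, cc + d, a + cc, b + d) == 0) 1
       else fisher_exact(a, b, cc, d) # a zero margin admits no enrichment
  list(in_top_annotated = a, in_top_other = b, out_annotated = cc,
       out_other = d, p = p)
}
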