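#' Build a binary gene-by-feature matrix from GRNs and FFL sets
#'
#' Two feature kinds are supported. For a GRN source (`"tf"` kind) there is
#' one column per TF, set to 1 when that TF targets the gene. For an FFL
#' source (`"ffl"` kind) there is one column per ordered (primary, secondary)
#' TF pair, set to 1 when the gene is the target of that pair's FFL. Column
#' names carry the source tag (`"tag:TF"` or `"tag:P->S"`) so that matrices
#' combined across data sets never collide. Genes without a single feature
#' are dropped (their count is attached as attribute `"n_dropped"`).
#'
#' @param sources named list of `grn` objects and/or FFL data.frames (from
#'   [enumerate_ffls()]); names are used as source tags.
#' @param genes optional character vector fixing the candidate gene rows;
#'   defaults to all genes targeted by any source.
#' @return Binary matrix (genes x features) with attributes
#'   `"feature_kind"`, `"feature_source"` (per column) and `"n_dropped"`.
#' @export
build_feature_matrix <- function(sources, genes = NULL) {
  stopifnot(is.list(sources), length(sources) >= 1L)
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("sources must be a named list (names become dataset tags)")
  cols <- list(); kind <- character(); src <- character()
  for (tag in names(sources)) {
    s <- sources[[tag]]
    if (inherits(s, "grn")) {
      adj <- lapply(grn_adjacency(s), unique)
      for (tf in names(adj)) {
        cols[[paste(tag, tf, sep = ":")]] <- adj[[tf]]
        kind <- c(kind, "tf-target"); src <- c(src, tag)
      }
    } else if (is.data.frame(s) && all(c("primary", "secondary", "target")
                                       %in% names(s))) {
      pair <- paste0(s$primary, "->", s$secondary)
      for (pr in unique(pair)) {
        cols[[paste(tag, pr, sep = ":")]] <- unique(s$target[pair == pr])
        kind <- c(kind, "ffl-pair"); src <- c(src, tag)
      }
    } else stop("source '", tag, "' is neither a grn nor an FFL data.frame")
  }
  if (length(cols) == 0L) stop("sources yielded no features")
  if (is.null(genes)) genes <- sort(unique(unlist(cols, use.names = FALSE)))
  genes <- unique(as.character(genes))
  x <- matrix(0L, nrow = length(genes), ncol = length(cols),
              dimnames = list(genes, names(cols)))
  for (j in seq_along(cols)) {
    hit <- genes %in% cols[[j]]
    x[hit, j] <- 1L
  }
  keep <- rowSums(x) > 0L
  if (!any(keep)) stop("no gene retains at least one feature")
  out <- x[keep, , drop = FALSE]
  attr(out, "feature_kind") <- stats::setNames(kind, colnames(out))
  attr(out, "feature_source") <- stats::setNames(src, colnames(out))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Column-wise union of feature matrices
#'
#' Combines feature matrices (e.g. important-feature subsets from different
#' data sets or feature kinds) over the union of their gene rows, filling 0
#' where a gene was absent, collapsing duplicate feature columns (so the
#' operation is idempotent), and re-filtering genes to keep only rows with at
#' least one feature.
#'
#' @param matrices list of matrices from [build_feature_matrix()] (possibly
#'   column-subsetted).
#' @return Combined binary matrix with merged `"feature_kind"` /
#'   `"feature_source"` attributes.
#' @export
combine_feature_matrices <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  matrices <- Filter(function(m) !is.null(m) && ncol(m) > 0L, matrices)
  if (length(matrices) == 0L) stop("no features to combine")
  genes <- sort(unique(unlist(lapply(matrices, rownames))))
  kind <- character(); src <- character()
  blocks <- lapply(matrices, function(m) {
    out <- matrix(0L, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    k <- attr(m, "feature_kind") %||%
      stats::setNames(rep(NA_character_, ncol(m)), colnames(m))
    s <- attr(m, "feature_source") %||%
      stats::setNames(rep(NA_character_, ncol(m)), colnames(m))
    kind <<- c(kind, k[colnames(m)])
    src <<- c(src, s[colnames(m)])
    out
  })
  x <- do.call(cbind, blocks)
  dup <- duplicated(colnames(x))
  x <- x[, !dup, drop = FALSE]
  kind <- kind[!dup]; src <- src[!dup]
  keep <- rowSums(x) > 0L
  if (!any(keep)) stop("combined feature set covers no genes")
  out <- x[keep, , drop = FALSE]
  attr(out, "feature_kind") <- stats::setNames(kind, colnames(out))
  attr(out, "feature_source") <- stats::setNames(src, colnames(out))
  out
}

#' Read/write a binary feature matrix as TSV
#'
#' @param x feature matrix (genes in rows, features in columns).
#' @param path file path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` an integer matrix.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "integer"
  rownames(x) <- df[[1]]
  x
}
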