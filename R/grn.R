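#' Construct a gene regulatory network from TF-target pairs
#'
#' A GRN is a set of directed transcription-factor (TF) to target-gene
#' interactions. Duplicate pairs are collapsed; gene identifiers are treated
#' as case-sensitive opaque strings (no synonym resolution). Self-loops (a TF
#' listed as its own target) are retained.
#'
#' @param tf character vector of regulator gene ids.
#' @param target character vector of target gene ids, same length as `tf`.
#' @param name label for the data source (e.g. "ChIP", "Deletion").
#' @return An object of class `grn`: a list with elements `name` and
#'   `interactions` (a deduplicated data.frame with columns `tf`, `target`).
#' @examples
#' g <- grn(c("TF1", "TF1", "TF2"), c("g1", "g2", "g1"), name = "toy")
#' n_interactions(g)
#' @export
grn <- function(tf, target, name = "GRN") {
  stopifnot(length(tf) == length(target))
  tf <- as.character(tf)
  target <- as.character(target)
  if (anyNA(tf) || anyNA(target)) stop("NA gene identifiers are not allowed")
  keep <- !duplicated(interaction_key(tf, target))
  structure(
    list(name = name,
         interactions = data.frame(tf = tf[keep], target = target[keep],
                                   stringsAsFactors = FALSE)),
    class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("GRN '%s': %d interactions, %d TFs, %d target genes\n",
              x$name, n_interactions(x), length(grn_tfs(x)),
              length(grn_targets(x))))
  invisible(x)
}

#' Accessors for GRN components
#'
#' `grn_tfs()` and `grn_targets()` return the regulator and target gene sets
#' (projections of the interaction set); `n_interactions()` the number of
#' unique directed interactions; `grn_nodes()` the union of both gene sets.
#'
#' @param x a `grn` object.
#' @return Character vector of gene ids, or an integer count.
#' @export
grn_tfs <- function(x) unique(x$interactions$tf)

#' @rdname grn_tfs
#' @export
grn_targets <- function(x) unique(x$interactions$target)

#' @rdname grn_tfs
#' @export
grn_nodes <- function(x) unique(c(x$interactions$tf, x$interactions$target))

#' @rdname grn_tfs
#' @export
n_interactions <- function(x) nrow(x$interactions)

# Per-TF out-neighbourhoods as a named list of character vectors.
grn_adjacency <- function(x) {
  split(x$interactions$target, factor(x$interactions$tf,
                                      levels = grn_tfs(x)))
}

# Per-TF out-degree, named integer vector.
grn_out_degree <- function(x) {
  tab <- table(x$interactions$tf)
  stats::setNames(as.integer(tab), names(tab))
}

grn_keys <- function(x) interaction_key(x$interactions$tf, x$interactions$target)

#' Read a TF-target edge list from a delimited text file
#'
#' Lines are split on tabs or runs of whitespace; the first two tokens are
#' taken as (tf, target). A header line is auto-detected: if either of the
#' first line's two leading tokens never reappears as a gene id in the rest of
#' the file, the line is treated as a header and skipped (override with
#' `header`). Malformed lines (< 2 tokens) are skipped with a warning;
#' duplicate pairs are collapsed. Parsing counts are attached as the
#' `"parse_log"` attribute.
#'
#' @param path file path.
#' @param name dataset label; defaults to the file name.
#' @param header `NA` (auto-detect, the default), `TRUE` or `FALSE`.
#' @return A `grn` object.
#' @export
read_edge_list <- function(path, name = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  skip_header <- isTRUE(header)
  if (is.na(header) && length(toks) > 1L && length(toks[[1L]]) >= 2L) {
    rest <- unique(unlist(lapply(toks[-1L], function(t) t[1:2])))
    first2 <- toks[[1L]][1:2]
    skip_header <- any(!first2 %in% rest)
  }
  if (skip_header) toks <- toks[-1L]
  if (length(toks) == 0L) stop("no data lines in edge-list file: ", path)
  ok <- vapply(toks, function(t) length(t) >= 2L, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(sprintf("%d malformed line(s) skipped in %s", n_skipped, path))
  tf <- vapply(toks[ok], `[`, character(1), 1L)
  target <- vapply(toks[ok], `[`, character(1), 2L)
  if (length(tf) == 0L) stop("no parsable interactions in: ", path)
  n_dup <- sum(duplicated(interaction_key(tf, target)))
  g <- grn(tf, target, name = name %||% basename(path))
  attr(g, "parse_log") <- c(parsed = length(tf), duplicates = n_dup,
                            skipped = n_skipped)
  g
}

#' Write a GRN as a two-column TSV edge list
#'
#' @param x a `grn` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "grn"))
  utils::write.table(x$interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
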