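#' Enumerate feed-forward loops in a GRN
#'
#' A feed-forward loop (FFL) is an ordered triplet (primary TF, secondary TF,
#' target): the primary TF regulates the secondary TF, and both regulate the
#' target. A gene is a TF if it appears as a regulator anywhere in the
#' network. The target must differ from both regulators, and self-loops never
#' contribute to the motif. Mutual regulation between two TFs yields both
#' role-ordered triplets when they share a target.
#'
#' @param x a `grn` object.
#' @return data.frame with columns `primary`, `secondary`, `target`; zero
#'   rows for a GRN without FFLs.
#' @examples
#' g <- grn(rep(c("TF1", "TF2"), c(4, 3)),
#'          c("TF2", "Tar1", "Tar2", "Tar3", "Tar2", "Tar3", "Tar4"))
#' enumerate_ffls(g) # TF1 -> TF2 with targets Tar2 and Tar3
#' @export
enumerate_ffls <- function(x) {
  stopifnot(inherits(x, "grn"))
  empty <- data.frame(primary = character(), secondary = character(),
                      target = character(), stringsAsFactors = FALSE)
  if (n_interactions(x) == 0L) return(empty)
  adj <- lapply(grn_adjacency(x), unique)
  tfs <- names(adj)
  out <- vector("list", 0L)
  for (p in tfs) {
    secondaries <- setdiff(intersect(adj[[p]], tfs), p)
    for (s in secondaries) {
      common <- setdiff(intersect(adj[[p]], adj[[s]]), c(p, s))
      if (length(common))
        out[[length(out) + 1L]] <- data.frame(
          primary = p, secondary = s, target = common,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

ffl_keys <- function(ffls) {
  paste(ffls$primary, ffls$secondary, ffls$target, sep = "\t")
}

#' Expected FFL count and z-score from mean connectivity
#'
#' In a randomly wired network the expected number of FFLs is approximated by
#' the cube of the mean connectivity lambda = (number of interactions) /
#' (number of nodes, TFs and targets pooled), with standard deviation equal
#' to the square root of that mean. The z-score is (observed - expected) /
#' sd.
#'
#' @param x a `grn` object.
#' @param observed observed FFL count; defaults to `nrow(enumerate_ffls(x))`.
#' @return An object of class `motif_stats` with fields `observed`, `lambda`,
#'   `expected_mean`, `expected_sd`, `z` (Inf when the expectation is 0 but
#'   FFLs were observed; NA when both are 0).
#' @export
expected_ffl_stats <- function(x, observed = NULL) {
  stopifnot(inherits(x, "grn"))
  if (n_interactions(x) == 0L) stop("GRN is empty")
  if (is.null(observed)) observed <- nrow(enumerate_ffls(x))
  lambda <- n_interactions(x) / length(grn_nodes(x))
  m <- lambda^3
  s <- sqrt(m)
  z <- if (s > 0) (observed - m) / s
       else if (observed > 0) Inf else NA_real_
  structure(list(observed = observed, lambda = lambda, expected_mean = m,
                 expected_sd = s, z = z),
            class = "motif_stats")
}

#' @export
print.motif_stats <- function(x, ...) {
  cat(sprintf(
    "FFLs: observed %d, expected %.2f +/- %.2f (lambda = %.3f), z = %.2f\n",
    x$observed, x$expected_mean, x$expected_sd, x$lambda, x$z))
  invisible(x)
}

#' Cross-dataset overlap of FFL sets
#'
#' Over the union of triplets from all sets, reports the fraction present in
#' exactly one set and the count present in every set.
#'
#' @param ffl_sets list (length >= 2) of FFL data.frames as returned by
#'   [enumerate_ffls()].
#' @return List with `n_union`, `fraction_unique`, `common_to_all`,
#'   `multiplicity`.
#' @export
ffl_overlap <- function(ffl_sets) {
  stopifnot(is.list(ffl_sets), length(ffl_sets) >= 2L)
  key_sets <- lapply(ffl_sets, function(f) unique(ffl_keys(f)))
  mult <- table(unlist(key_sets, use.names = FALSE))
  mult <- stats::setNames(as.integer(mult), names(mult))
  list(n_union = length(mult),
       fraction_unique = if (length(mult)) mean(mult == 1L) else NA_real_,
       common_to_all = sum(mult == length(ffl_sets)),
       multiplicity = mult)
}

#' Read/write FFL triplet tables as 3-column TSV
#'
#' @param ffls FFL data.frame (`primary`, `secondary`, `target`).
#' @param path file path.
#' @return `write_ffls()` returns `path` invisibly; `read_ffls()` the
#'   data.frame.
#' @export
write_ffls <- function(ffls, path) {
  utils::write.table(ffls[, c("primary", "secondary", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ffls
#' @export
read_ffls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
}
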