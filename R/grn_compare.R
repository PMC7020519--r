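#' Observed interaction overlap between two GRNs
#'
#' The overlap coefficient is the size of the intersection of the two
#' interaction sets divided by the size of the smaller set, so it ranges from
#' 0 (disjoint) to 1 (the smaller network is contained in the larger).
#'
#' @param a,b `grn` objects (both nonempty).
#' @return List with `observed` (intersection count) and `coefficient`.
#' @examples
#' a <- grn(c("t1", "t1", "t2"), c("g1", "g2", "g1"))
#' b <- grn(c("t1", "t2"), c("g2", "g2"))
#' pairwise_overlap(a, b) # observed 1, coefficient 1/2
#' @export
pairwise_overlap <- function(a, b) {
  stopifnot(inherits(a, "grn"), inherits(b, "grn"))
  if (n_interactions(a) == 0L || n_interactions(b) == 0L)
    stop("overlap is undefined for an empty GRN")
  obs <- length(intersect(grn_keys(a), grn_keys(b)))
  list(observed = obs,
       coefficient = obs / min(n_interactions(a), n_interactions(b)))
}

# One degree-preserving randomization: each TF keeps its out-degree but
# draws its targets uniformly without replacement from the pool.
randomized_keys <- function(degrees, pool) {
  unlist(lapply(names(degrees), function(tf)
    interaction_key(tf, sample(pool, degrees[[tf]]))), use.names = FALSE)
}

#' Randomization null for the interaction overlap of two GRNs
#'
#' For each permutation, every TF in each network is reassigned a uniform
#' random set of target genes drawn without replacement from `pool`, with the
#' set size equal to that TF's real out-degree. The overlap between the two
#' randomized networks is recomputed, giving a null distribution that
#' preserves per-TF degrees but randomizes which genes are targeted. The
#' observed overlap is compared to this null with a two-tailed z-test on the
#' normal approximation.
#'
#' @param a,b `grn` objects.
#' @param pool character vector of candidate target genes; conventionally the
#'   union of target genes across all data sets under comparison.
#' @param n_perm number of randomizations (default 1000).
#' @param seed integer seed; the draw sequence is deterministic given it.
#' @return An object of class `overlap_stats`: observed overlap and
#'   coefficient, `null_mean`, `null_sd`, `z`, `p_two_tailed`,
#'   `n_permutations`, and `undefined` (TRUE when `null_sd` is 0, in which
#'   case `z` and `p_two_tailed` are NA).
#' @export
randomized_overlap_null <- function(a, b, pool, n_perm = 1000, seed = 1) {
  obs <- pairwise_overlap(a, b)
  pool <- unique(as.character(pool))
  deg_a <- grn_out_degree(a)
  deg_b <- grn_out_degree(b)
  if (any(c(deg_a, deg_b) > length(pool)))
    stop("a TF's out-degree exceeds the size of the target pool")
  draws <- with_seed(derive_seed(seed, "overlap_null"), {
    vapply(seq_len(n_perm), function(i) {
      length(intersect(randomized_keys(deg_a, pool),
                       randomized_keys(deg_b, pool)))
    }, numeric(1))
  })
  m <- mean(draws)
  s <- stats::sd(draws)
  undefined <- !is.finite(s) || s == 0
  z <- if (undefined) NA_real_ else (obs$observed - m) / s
  p <- if (undefined) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(observed_overlap = obs$observed,
                 overlap_coefficient = obs$coefficient,
                 null_mean = m, null_sd = s, z = z, p_two_tailed = p,
                 n_permutations = n_perm, undefined = undefined),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d (coefficient %.3f); null %.2f +/- %.2f over %d permutations\n",
    x$observed_overlap, x$overlap_coefficient, x$null_mean, x$null_sd,
    x$n_permutations))
  if (x$undefined) cat("z undefined (degenerate null: sd = 0)\n")
  else cat(sprintf("z = %.3f, two-tailed p = %.3g\n", x$z, x$p_two_tailed))
  invisible(x)
}

#' Pearson correlation of per-TF interaction counts between two GRNs
#'
#' Compares how many targets each TF has in one data set versus another. By
#' default only TFs present in both networks enter the comparison
#' (`mode = "shared"`); `mode = "union"` zero-fills degrees for TFs absent
#' from one network, which tends to inflate the correlation.
#'
#' @param a,b `grn` objects.
#' @param mode `"shared"` (default) or `"union"`.
#' @return Pearson's r.
#' @export
per_tf_degree_correlation <- function(a, b, mode = c("shared", "union")) {
  mode <- match.arg(mode)
  deg_a <- grn_out_degree(a)
  deg_b <- grn_out_degree(b)
  tfs <- if (mode == "shared") intersect(names(deg_a), names(deg_b))
         else union(names(deg_a), names(deg_b))
  if (length(tfs) < 3L)
    stop("need at least 3 TFs in the comparison set, got ", length(tfs))
  va <- ifelse(tfs %in% names(deg_a), deg_a[tfs], 0L)
  vb <- ifelse(tfs %in% names(deg_b), deg_b[tfs], 0L)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("degree correlation undefined: constant degree vector")
  stats::cor(va, vb)
}

#' Uniqueness of interactions across a collection of GRNs
#'
#' Pools the interaction union across data sets, counts in how many data sets
#' each interaction occurs, and reports the fraction unique to a single data
#' set, plus for each TF whether a majority (> 50\%) of its pooled
#' interactions are unique to one data set.
#'
#' @param grns list of `grn` objects (at least 2).
#' @return List with `n_union`, `fraction_unique`, `fraction_shared`,
#'   `multiplicity` (named integer vector over the interaction union),
#'   `tf_majority_unique` (named logical per TF) and
#'   `tf_majority_unique_fraction`.
#' @export
interaction_uniqueness <- function(grns) {
  stopifnot(is.list(grns), length(grns) >= 2L)
  key_sets <- lapply(grns, grn_keys)
  mult <- table(unlist(lapply(key_sets, unique), use.names = FALSE))
  mult <- stats::setNames(as.integer(mult), names(mult))
  frac_unique <- mean(mult == 1L)
  tf_of <- sub("\t.*$", "", names(mult))
  maj <- tapply(mult == 1L, tf_of, mean) > 0.5
  list(n_union = length(mult),
       fraction_unique = frac_unique,
       fraction_shared = 1 - frac_unique,
       multiplicity = mult,
       tf_majority_unique = maj,
       tf_majority_unique_fraction = mean(maj))
}
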