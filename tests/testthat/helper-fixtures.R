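# Shared fixtures and independent oracles, all built in code.

# The worked GRN example: TF1 regulates TF2 and three targets, TF2 regulates
# three targets; TF1->TF2 forms FFLs with Tar2 and Tar3 only.
toy_ffl_grn <- function() {
  grn(c("TF1", "TF1", "TF1", "TF1", "TF2", "TF2", "TF2"),
      c("TF2", "Tar1", "Tar2", "Tar3", "Tar2", "Tar3", "Tar4"),
      name = "toy")
}

# Uniform random GRN over at most `n_nodes` labelled nodes.
random_small_grn <- function(n_nodes = 12, p_edge = 0.2) {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- expand.grid(tf = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  grn(pairs$tf[keep], pairs$target[keep], name = "rand")
}

# Exhaustive FFL oracle: loop over every ordered node triplet and test the
# three motif edges directly on the edge set.
brute_force_ffls <- function(g) {
  keys <- cycleGRN:::grn_keys(g)
  has <- function(a, b) paste(a, b, sep = "\t") %in% keys
  tfs <- grn_tfs(g)
  nodes <- grn_nodes(g)
  out <- list()
  for (p in tfs) for (s in tfs) for (t_ in nodes) {
    if (p == s || t_ == p || t_ == s) next
    if (has(p, s) && has(p, t_) && has(s, t_))
      out[[length(out) + 1L]] <- c(p, s, t_)
  }
  if (length(out) == 0L)
    return(data.frame(primary = character(), secondary = character(),
                      target = character(), stringsAsFactors = FALSE))
  stats::setNames(as.data.frame(do.call(rbind, out),
                                stringsAsFactors = FALSE),
                  c("primary", "secondary", "target"))
}

sort_ffl_keys <- function(ffls) sort(cycleGRN:::ffl_keys(ffls))

# Hypergeometric upper-tail oracle for 2x2 enrichment via explicit
# combinatorial sums (no distribution functions).
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + c          # annotated
  n <- b + d          # not annotated
  k <- a + b          # set size
  ks <- max(0, k - n):min(k, m)
  probs <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  sum(probs[ks >= a])
}

# Primal objective of the C-SVM: 0.5*||w||^2 + C * sum hinge.
svm_objective <- function(w, b, x, y, C) {
  margin <- (2 * y - 1) * (drop(x %*% w) + b)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - margin))
}

# Direct brute-force minimization of the primal from many starts.
svm_oracle_objective <- function(x, y, C, n_starts = 30) {
  obj <- function(p) svm_objective(p[-length(p)], p[length(p)], x, y, C)
  best <- Inf
  for (i in seq_len(n_starts)) {
    p0 <- stats::rnorm(ncol(x) + 1, 0, 2)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# Small planted-signal world shared by classifier tests.
make_planted_world <- function(seed = 5, effect = 1, noise_sd = 0,
                               n_tfs = 25, n_genes = 400,
                               out_degree_mean = 8) {
  sc <- synth_config(n_tfs = n_tfs, n_genes = n_genes,
                     out_degree_mean = out_degree_mean, n_datasets = 2,
                     pairwise_overlap_target = 0.3, planted_ffl_count = 0,
                     phase_sizes = c(G1 = 40, S = 30, "S-G2" = 25,
                                     "G2-M" = 30, "M-G1" = 20),
                     tfs_per_phase = 2, tf_phase_effect = effect,
                     noise_sd = noise_sd, seed = seed)
  gen <- generate_grn_collection(sc)
  labels <- generate_phase_labels(sc)
  pl <- plant_tf_phase_signal(gen$grns, labels, sc)
  fm <- build_feature_matrix(pl$grns, genes = names(labels))
  list(config = sc, fm = fm, labels = labels,
       tf_phase_map = pl$tf_phase_map, grns = pl$grns)
}
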