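#' Cell-cycle phase names
#'
#' The five expression-peak classes of cycling genes, in temporal order.
#' @export
CC_PHASES <- c("G1", "S", "S-G2", "G2-M", "M-G1")

#' Configuration of the synthetic GRN / expression generator
#'
#' Defines the study conditions under which the whole analysis is exercised:
#' several TF-target edge lists over a shared gene universe with tunable
#' pairwise interaction overlap, geometric per-TF out-degrees, planted FFLs,
#' phase labels with sizes spanning the 71-300 gene range typical of yeast
#' phase clusters, and two-cycle sinusoidal expression with phase-offset
#' peaks (consecutive phases offset by period/5, i.e. 25 min for the 125-min
#' convention) normalized to \[0, 1\].
#'
#' @param n_tfs,n_genes number of TFs and of (non-TF) genes in the universe.
#' @param out_degree_mean mean per-TF out-degree (geometric distribution,
#'   minimum 1).
#' @param n_datasets number of edge lists to generate.
#' @param pairwise_overlap_target target expected pairwise overlap
#'   coefficient between data sets, in \[0, 1\]; attainability (it cannot lie
#'   below the chance level implied by the degrees) is checked at generation.
#' @param planted_ffl_count number of FFL triplets planted into every data
#'   set.
#' @param phase_sizes named integer vector, genes per phase (names from
#'   `CC_PHASES`); remaining genes are labeled "none".
#' @param tfs_per_phase number of TFs linked to each phase by
#'   [plant_tf_phase_signal()].
#' @param tf_phase_effect probability boost with which a phase-linked TF
#'   targets each gene of its phase (>= 0; values above 1 are clipped).
#' @param period_minutes cell-cycle period in minutes.
#' @param n_timepoints samples across two periods (at least 4).
#' @param noise_sd Gaussian noise sd added to expression before
#'   normalization.
#' @param seed root seed; all stage generators derive sub-seeds from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_tfs = 100, n_genes = 2000,
                         out_degree_mean = 50, n_datasets = 5,
                         pairwise_overlap_target = 0.1,
                         planted_ffl_count = 20,
                         phase_sizes = c(G1 = 300, S = 120, "S-G2" = 100,
                                         "G2-M" = 150, "M-G1" = 71),
                         tfs_per_phase = 2,
                         tf_phase_effect = 0.3,
                         period_minutes = 125,
                         n_timepoints = 36,
                         noise_sd = 0.05,
                         seed = 1) {
  stopifnot(n_tfs >= 2, n_genes >= 1, out_degree_mean >= 1,
            n_datasets >= 1, planted_ffl_count >= 0,
            tfs_per_phase >= 0, tf_phase_effect >= 0,
            period_minutes > 0, noise_sd >= 0)
  if (pairwise_overlap_target < 0 || pairwise_overlap_target > 1)
    stop("pairwise_overlap_target must lie in [0, 1]")
  if (n_timepoints < 4)
    stop("n_timepoints must be at least 4 to resolve a cycle")
  if (length(phase_sizes)) {
    if (is.null(names(phase_sizes)) ||
        !all(names(phase_sizes) %in% CC_PHASES))
      stop("phase_sizes names must come from CC_PHASES")
    if (sum(phase_sizes) > n_genes)
      stop("phase_sizes total exceeds the gene universe")
  }
  structure(list(n_tfs = n_tfs, n_genes = n_genes,
                 out_degree_mean = out_degree_mean,
                 n_datasets = n_datasets,
                 pairwise_overlap_target = pairwise_overlap_target,
                 planted_ffl_count = planted_ffl_count,
                 phase_sizes = phase_sizes, tfs_per_phase = tfs_per_phase,
                 tf_phase_effect = tf_phase_effect,
                 period_minutes = period_minutes,
                 n_timepoints = n_timepoints, noise_sd = noise_sd,
                 seed = seed),
            class = "synth_config")
}

synth_tf_ids <- function(config) sprintf("tf%03d", seq_len(config$n_tfs))
synth_gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

# Expected pairwise overlap coefficient of the core-sharing mechanism for a
# given shared fraction rho: per TF, both data sets contain the core (an
# expected rho*d subset of the TF's candidate pool) plus independent uniform
# remainders, whose expected intersection is (d-k)^2 / (N-k).
expected_overlap_coefficient <- function(rho, degrees, pool_size) {
  per_tf <- vapply(degrees, function(d) {
    k0 <- floor(rho * d); frac <- rho * d - k0
    val <- function(k) k + if (pool_size > k) (d - k)^2 / (pool_size - k)
                           else 0
    (1 - frac) * val(k0) + frac * val(min(k0 + 1, d))
  }, numeric(1))
  sum(per_tf) / sum(degrees)
}

# Solve the shared-core fraction that attains the target coefficient.
solve_core_fraction <- function(target, degrees, pool_size) {
  g <- function(rho) expected_overlap_coefficient(rho, degrees, pool_size)
  lo <- g(0)
  if (target >= 1) return(1)
  if (target < lo - 1e-12)
    stop(sprintf(paste0("pairwise_overlap_target %.3f is unattainable: ",
                        "chance-level overlap is already %.3f given the ",
                        "degrees"), target, lo))
  if (target <= lo) return(0)
  stats::uniroot(function(r) g(r) - target, c(0, 1), tol = 1e-10)$root
}

#' Generate a collection of GRNs with controlled overlap and planted FFLs
#'
#' Draws one out-degree per TF from a geometric distribution (minimum 1,
#' mean `out_degree_mean`), then gives each TF a shared "core" target set
#' plus dataset-specific random targets from its candidate pool (all genes
#' and other TFs). The core fraction is solved so that the expected pairwise
#' overlap coefficient between data sets equals `pairwise_overlap_target`.
#' `planted_ffl_count` FFL triplets (primary TF, secondary TF, gene target)
#' are then wired into every data set.
#'
#' @param config a [synth_config()].
#' @return List with `grns` (named list of `grn` objects), and `truth`
#'   recording `planted_ffls`, the realized `degrees`, the solved
#'   `core_fraction`, and the id universe.
#' @export
generate_grn_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tfs <- synth_tf_ids(config); genes <- synth_gene_ids(config)
  universe <- c(tfs, genes)
  pool_size <- length(universe) - 1L   # each TF may target anything but itself
  with_seed(derive_seed(config$seed, "grn"), {
    degrees <- pmin(1L + stats::rgeom(config$n_tfs,
                                      1 / config$out_degree_mean),
                    pool_size)
    rho <- solve_core_fraction(config$pairwise_overlap_target, degrees,
                               pool_size)
    edge_lists <- replicate(config$n_datasets,
                            list(tf = character(), target = character()),
                            simplify = FALSE)
    for (i in seq_along(tfs)) {
      pool <- setdiff(universe, tfs[i])
      d <- degrees[i]
      k <- floor(rho * d) + (stats::runif(1) < rho * d - floor(rho * d))
      k <- min(k, d)
      core <- if (k > 0) sample(pool, k) else character(0)
      rest <- setdiff(pool, core)
      for (ds in seq_len(config$n_datasets)) {
        extra <- if (d - k > 0) sample(rest, d - k) else character(0)
        tgt <- c(core, extra)
        edge_lists[[ds]]$tf <- c(edge_lists[[ds]]$tf, rep(tfs[i], d))
        edge_lists[[ds]]$target <- c(edge_lists[[ds]]$target, tgt)
      }
    }
    planted <- NULL
    if (config$planted_ffl_count > 0) {
      seen <- character(0)
      rows <- list()
      while (length(rows) < config$planted_ffl_count) {
        ps <- sample(tfs, 2)
        t_ <- sample(genes, 1)
        key <- paste(ps[1], ps[2], t_, sep = "\t")
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- c(ps[1], ps[2], t_)
      }
      planted <- stats::setNames(
        as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE),
        c("primary", "secondary", "target"))
      for (ds in seq_len(config$n_datasets)) {
        edge_lists[[ds]]$tf <- c(edge_lists[[ds]]$tf, planted$primary,
                                 planted$primary, planted$secondary)
        edge_lists[[ds]]$target <- c(edge_lists[[ds]]$target,
                                     planted$secondary, planted$target,
                                     planted$target)
      }
    }
    grns <- lapply(seq_len(config$n_datasets), function(ds)
      grn(edge_lists[[ds]]$tf, edge_lists[[ds]]$target,
          name = sprintf("synth%02d", ds)))
    names(grns) <- vapply(grns, `[[`, character(1), "name")
    list(grns = grns,
         truth = list(planted_ffls = planted,
                      degrees = stats::setNames(degrees, tfs),
                      core_fraction = rho,
                      tfs = tfs, genes = genes))
  })
}

#' Assign cell-cycle phase labels to the synthetic gene universe
#'
#' Exactly `phase_sizes[p]` genes receive phase `p` (disjoint draws from the
#' gene universe); all remaining genes are labeled "none".
#'
#' @param config a [synth_config()].
#' @param genes gene universe; defaults to the generator's id scheme.
#' @return Named character vector gene -> phase.
#' @export
generate_phase_labels <- function(config, genes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  genes <- genes %||% synth_gene_ids(config)
  sizes <- config$phase_sizes
  if (sum(sizes) > length(genes))
    stop("phase sizes exceed the gene universe")
  labels <- stats::setNames(rep("none", length(genes)), genes)
  if (length(sizes) == 0L || sum(sizes) == 0L) return(labels)
  with_seed(derive_seed(config$seed, "labels"), {
    shuffled <- sample(genes)
    at <- 0L
    for (p in names(sizes)) {
      if (sizes[[p]] == 0) next
      labels[shuffled[(at + 1L):(at + sizes[[p]])]] <- p
      at <- at + sizes[[p]]
    }
  })
  labels
}

phase_offsets <- function(period) {
  stats::setNames((seq_along(CC_PHASES) - 1) * period / length(CC_PHASES),
                  CC_PHASES)
}

#' Generate sinusoidal two-cycle expression traces for labeled genes
#'
#' Each cyclic gene's trace is a cosine over two periods peaking at its
#' phase's offset (consecutive phases offset by period/5), plus Gaussian
#' noise, then min-max normalized to \[0, 1\]. Non-cyclic genes get noise
#' around a constant level (0.5 before normalization). TFs in
#' `tf_phase_map` receive the cyclic trace of their phase; other mapped-in
#' TFs a constant one.
#'
#' @param labels named character vector gene -> phase, e.g. from
#'   [generate_phase_labels()].
#' @param config a [synth_config()].
#' @param tf_phase_map optional named character vector TF -> phase (or
#'   "none") to append TF traces, e.g. from [plant_tf_phase_signal()].
#' @return Numeric matrix (genes x time points); column names are sampling
#'   times in minutes spanning two periods.
#' @export
generate_expression <- function(labels, config, tf_phase_map = NULL) {
  stopifnot(inherits(config, "synth_config"), !is.null(names(labels)))
  if (config$n_timepoints < 4)
    stop("n_timepoints must be at least 4 to resolve a cycle")
  period <- config$period_minutes
  times <- seq(0, 2 * period, length.out = config$n_timepoints)
  offs <- phase_offsets(period)
  all_labels <- c(labels, tf_phase_map)
  x <- matrix(NA_real_, length(all_labels), length(times),
              dimnames = list(names(all_labels), as.character(times)))
  for (i in seq_along(all_labels)) {
    ph <- all_labels[[i]]
    x[i, ] <- if (ph %in% CC_PHASES)
      cos(2 * pi * (times - offs[[ph]]) / period)
    else 0.5
  }
  if (config$noise_sd > 0)
    x <- x + with_seed(derive_seed(config$seed, "expression"),
                       matrix(stats::rnorm(length(x), 0, config$noise_sd),
                              nrow(x)))
  # min-max normalize each trace; an exactly constant trace maps to 0.5
  rng <- apply(x, 1, range)
  span <- rng[2, ] - rng[1, ]
  norm <- (x - rng[1, ]) / ifelse(span > 0, span, 1)
  norm[span == 0, ] <- 0.5
  attr(norm, "times") <- times
  norm
}

#' Plant a recoverable TF-to-phase association signal into GRNs
#'
#' Links `tfs_per_phase` TFs to each phase, then, independently in every
#' data set, adds an edge from each phase-linked TF to each gene of its
#' phase with probability `tf_phase_effect` (on top of the background
#' edges already present). This creates the TF -> phase structure that the
#' classification protocol assumes is recoverable; the link map is returned
#' as ground truth.
#'
#' @param grns named list of `grn` objects.
#' @param labels named character vector gene -> phase.
#' @param config a [synth_config()].
#' @param tf_phase_map optional explicit named map TF -> phase; by default
#'   TFs are drawn without replacement from the networks' TF union.
#' @return List with modified `grns` and the `tf_phase_map` used.
#' @export
plant_tf_phase_signal <- function(grns, labels, config,
                                  tf_phase_map = NULL) {
  stopifnot(inherits(config, "synth_config"))
  effect <- config$tf_phase_effect
  if (effect > 1) {
    warning("tf_phase_effect > 1 clipped to 1")
    effect <- 1
  }
  phases <- intersect(CC_PHASES, unique(labels))
  if (is.null(tf_phase_map)) {
    all_tfs <- unique(unlist(lapply(grns, grn_tfs)))
    need <- config$tfs_per_phase * length(phases)
    if (need > length(all_tfs))
      stop("not enough TFs to link ", config$tfs_per_phase, " per phase")
    tf_phase_map <- with_seed(derive_seed(config$seed, "tf_phase_map"), {
      chosen <- sample(all_tfs, need)
      stats::setNames(rep(phases, each = config$tfs_per_phase), chosen)
    })
  }
  if (effect > 0 && length(tf_phase_map)) {
    grns <- with_seed(derive_seed(config$seed, "plant"), {
      lapply(grns, function(g) {
        tf_new <- character(); tgt_new <- character()
        for (tf in names(tf_phase_map)) {
          ph <- tf_phase_map[[tf]]
          if (!ph %in% CC_PHASES) next
          phase_genes <- names(labels)[labels == ph]
          hit <- phase_genes[stats::runif(length(phase_genes)) < effect]
          tf_new <- c(tf_new, rep(tf, length(hit)))
          tgt_new <- c(tgt_new, hit)
        }
        grn(c(g$interactions$tf, tf_new),
            c(g$interactions$target, tgt_new), name = g$name)
      })
    })
  }
  list(grns = grns, tf_phase_map = tf_phase_map)
}

#' Simulate noisy FFL expression time courses from known dynamics
#'
#' The primary trace is the forcing function evaluated on the grid; the
#' secondary and target traces are the exact model solution
#' ([ffl_solve()]) plus Gaussian noise.
#'
#' @param params named vector with `alpha_S`, `alpha_T`, `beta_ST`,
#'   `beta_PS`, `beta_PT`.
#' @param forcing a forcing specification (see [sinusoid_forcing()]).
#' @param times strictly increasing sampling grid (minutes).
#' @param noise_sd Gaussian noise sd on the secondary/target traces.
#' @param seed seed for the noise draw.
#' @param S0,T0 initial expression levels.
#' @return Matrix with rows `primary`, `secondary`, `target`.
#' @export
simulate_ffl_timecourses <- function(params, forcing, times, noise_sd = 0,
                                     seed = 1, S0 = 0, T0 = 0) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  model <- ffl_ode_model(params[["alpha_S"]], params[["alpha_T"]],
                         params[["beta_ST"]], params[["beta_PS"]],
                         params[["beta_PT"]], forcing, S0 = S0, T0 = T0)
  sol <- ffl_solve(model, times)
  out <- rbind(primary = forcing_fun(forcing)(times),
               secondary = sol[, "S"], target = sol[, "T"])
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, "ffl_noise"),
                       matrix(stats::rnorm(2 * length(times), 0, noise_sd),
                              nrow = 2))
    out[2:3, ] <- out[2:3, ] + noise
  }
  colnames(out) <- as.character(times)
  out
}

#' Read/write phase labels and expression matrices as TSV
#'
#' Labels are a 2-column TSV (gene, phase); expression a TSV matrix whose
#' header row holds the sampling times in minutes.
#'
#' @param labels named character vector gene -> phase.
#' @param x expression matrix (genes x times).
#' @param path file path.
#' @return Writers return `path` invisibly; readers the parsed object.
#' @export
write_phase_labels <- function(labels, path) {
  utils::write.table(data.frame(gene = names(labels),
                                phase = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_labels
#' @export
read_phase_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  stats::setNames(df$phase, df$gene)
}

#' @rdname write_phase_labels
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_labels
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  attr(x, "times") <- as.numeric(colnames(x))
  x
}
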