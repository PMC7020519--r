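# End-to-end orchestration. Every stage communicates with the next only
# through serialized artifacts in the output directory, so stages can be run
# in separate processes (or re-run individually) and the whole pipeline is
# reproducible from the manifest: config + root seed determine every output
# bit-for-bit.

default_pipeline_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "overlap", "motifs", "classify", "importance",
               "dynamics", "enrich"),
    simulate = list(),                 # synth_config() overrides
    overlap = list(n_perm = 1000),
    classify = list(classes = c("cyclic", CC_PHASES),
                    features = "tf",   # tf | ffl | both
                    c_grid = c(0.01, 0.1, 0.5, 1, 1.5, 2.0),
                    r_grid = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
                    n_balanced_sets = 100, n_folds = 10),
    importance = list(percentile = 10),
    dynamics = list(max_ffls = 20, control_triplets = 0),
    paths = list()                     # external inputs when not simulating
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  base <- default_pipeline_config()
  for (nm in names(config)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(config[[nm]]))
      utils::modifyList(base[[nm]], config[[nm]]) else config[[nm]]
  }
  # YAML maps arrive as lists; synth_config wants a named vector
  if (is.list(base$simulate$phase_sizes))
    base$simulate$phase_sizes <- unlist(base$simulate$phase_sizes)
  base
}

pipeline_edge_files <- function(out_dir, config) {
  paths <- config$paths$edge_lists
  if (!is.null(paths)) return(stats::setNames(paths, names(paths)))
  files <- sort(list.files(out_dir, pattern = "^grn_.*\\.tsv$",
                           full.names = TRUE))
  stats::setNames(files, sub("^grn_(.*)\\.tsv$", "\\1", basename(files)))
}

read_pipeline_grns <- function(out_dir, config) {
  files <- pipeline_edge_files(out_dir, config)
  if (length(files) == 0L)
    stop("no edge lists available; run the simulate stage or set ",
         "paths$edge_lists")
  grns <- lapply(names(files), function(nm)
    read_edge_list(files[[nm]], name = nm))
  stats::setNames(grns, names(files))
}

pipeline_labels_path <- function(out_dir, config)
  config$paths$labels %||% file.path(out_dir, "labels.tsv")

pipeline_expression_path <- function(out_dir, config)
  config$paths$expression %||% file.path(out_dir, "expression.tsv")

stage_simulate <- function(config, out_dir) {
  sc <- do.call(synth_config, utils::modifyList(
    config$simulate, list(seed = derive_seed(config$seed, "simulate"))))
  gen <- generate_grn_collection(sc)
  labels <- generate_phase_labels(sc)
  planted <- plant_tf_phase_signal(gen$grns, labels, sc)
  # every TF gets a trace (phase-linked TFs cycle, the rest are constant)
  tf_map <- stats::setNames(rep("none", length(gen$truth$tfs)),
                            gen$truth$tfs)
  tf_map[names(planted$tf_phase_map)] <- planted$tf_phase_map
  expr <- generate_expression(labels, sc, tf_phase_map = tf_map)
  for (g in planted$grns)
    write_edge_list(g, file.path(out_dir, sprintf("grn_%s.tsv", g$name)))
  write_phase_labels(labels, file.path(out_dir, "labels.tsv"))
  write_expression(expr, file.path(out_dir, "expression.tsv"))
  truth <- list(planted_ffls = gen$truth$planted_ffls,
                tf_phase_map = as.list(planted$tf_phase_map),
                core_fraction = gen$truth$core_fraction,
                degrees = as.list(gen$truth$degrees))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # synthetic annotation table: phase-linked TFs carry a regulator term
  ann <- data.frame(gene = names(planted$tf_phase_map),
                    term = "cell_cycle_regulation",
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

stage_overlap <- function(config, out_dir) {
  grns <- read_pipeline_grns(out_dir, config)
  if (length(grns) < 2L) stop("overlap stage needs at least 2 data sets")
  pool <- unique(unlist(lapply(grns, grn_targets)))
  combos <- utils::combn(names(grns), 2, simplify = FALSE)
  rows <- lapply(seq_along(combos), function(i) {
    nm <- combos[[i]]
    st <- randomized_overlap_null(
      grns[[nm[1]]], grns[[nm[2]]], pool,
      n_perm = config$overlap$n_perm,
      seed = derive_seed(config$seed, paste0("overlap_", i)))
    r <- tryCatch(per_tf_degree_correlation(grns[[nm[1]]], grns[[nm[2]]]),
                  error = function(e) NA_real_)
    data.frame(a = nm[1], b = nm[2], observed = st$observed_overlap,
               coefficient = st$overlap_coefficient,
               null_mean = st$null_mean, null_sd = st$null_sd, z = st$z,
               p_two_tailed = st$p_two_tailed, degree_pcc = r,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(out_dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  uniq <- interaction_uniqueness(grns)
  jsonlite::write_json(
    list(n_union = uniq$n_union, fraction_unique = uniq$fraction_unique,
         tf_majority_unique_fraction = uniq$tf_majority_unique_fraction),
    file.path(out_dir, "uniqueness.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

stage_motifs <- function(config, out_dir) {
  grns <- read_pipeline_grns(out_dir, config)
  ffl_sets <- lapply(grns, enumerate_ffls)
  stats_rows <- lapply(names(grns), function(nm) {
    write_ffls(ffl_sets[[nm]],
               file.path(out_dir, sprintf("ffls_%s.tsv", nm)))
    st <- expected_ffl_stats(grns[[nm]], nrow(ffl_sets[[nm]]))
    data.frame(dataset = nm, observed = st$observed, lambda = st$lambda,
               expected_mean = st$expected_mean,
               expected_sd = st$expected_sd, z = st$z,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, stats_rows),
                     file.path(out_dir, "motif_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(ffl_sets) >= 2L) {
    ov <- ffl_overlap(ffl_sets)
    jsonlite::write_json(
      list(n_union = ov$n_union, fraction_unique = ov$fraction_unique,
           common_to_all = ov$common_to_all),
      file.path(out_dir, "ffl_overlap.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

pipeline_feature_matrix <- function(config, out_dir) {
  grns <- read_pipeline_grns(out_dir, config)
  kind <- config$classify$features
  sources <- list()
  if (kind %in% c("tf", "both"))
    for (nm in names(grns)) sources[[nm]] <- grns[[nm]]
  if (kind %in% c("ffl", "both"))
    for (nm in names(grns)) {
      f <- file.path(out_dir, sprintf("ffls_%s.tsv", nm))
      if (!file.exists(f))
        stop("classify with FFL features needs the motifs stage outputs")
      sources[[paste0(nm, "_ffl")]] <- read_ffls(f)
    }
  labels <- read_phase_labels(pipeline_labels_path(out_dir, config))
  build_feature_matrix(sources, genes = names(labels))
}

stage_classify <- function(config, out_dir) {
  fm <- pipeline_feature_matrix(config, out_dir)
  labels <- read_phase_labels(pipeline_labels_path(out_dir, config))
  for (cls in config$classify$classes) {
    cfg <- svm_ensemble_config(
      c_grid = config$classify$c_grid, r_grid = config$classify$r_grid,
      n_balanced_sets = config$classify$n_balanced_sets,
      n_folds = config$classify$n_folds,
      seed = derive_seed(config$seed, paste0("classify_", cls)))
    fit <- cc_classify(fm, labels, positive_class = cls, config = cfg)
    jsonlite::write_json(
      list(class = cls, best_C = fit$best$C, best_R = fit$best$R,
           auc = fit$best$auc, n_genes = length(fit$scores),
           n_positive = sum(fit$y), n_features = length(fit$weights)),
      file.path(out_dir, sprintf("classify_%s.json", cls)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(
      importance_table(coef(fit)),
      file.path(out_dir, sprintf("weights_%s.tsv", cls)), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

read_weights <- function(out_dir, cls) {
  f <- file.path(out_dir, sprintf("weights_%s.tsv", cls))
  if (!file.exists(f)) return(NULL)
  df <- utils::read.table(f, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$weight, df$feature)
}

stage_importance <- function(config, out_dir) {
  general <- read_weights(out_dir, "cyclic")
  if (is.null(general))
    stop("importance stage needs the classify stage outputs (cyclic model)")
  X <- config$importance$percentile
  top <- percentile_threshold(general, X, "positive")
  phase_top <- list()
  for (ph in CC_PHASES) {
    w <- read_weights(out_dir, ph)
    if (!is.null(w))
      phase_top[[ph]] <- percentile_threshold(w, X, "positive")
  }
  net <- build_importance_grn(top, phase_top)
  write_importance_grn(net, file.path(out_dir, "importance_edges.tsv"),
                       file.path(out_dir, "importance_nodes.tsv"))
  out <- list(percentile = X, n_top_features = length(top),
              n_nodes = length(net$nodes), n_edges = nrow(net$edges),
              n_modules = net$n_modules, n_isolated = net$n_isolated)
  truth_file <- file.path(out_dir, "truth.json")
  if (file.exists(truth_file)) {
    truth <- jsonlite::read_json(truth_file)
    planted_tfs <- names(truth$tf_phase_map)
    universe <- unique(unlist(feature_members(names(general))))
    enr <- known_regulator_enrichment(
      unique(unlist(feature_members(top))),
      intersect(planted_tfs, universe), universe)
    out$planted_regulator_enrichment_p <- enr$p
  }
  jsonlite::write_json(out, file.path(out_dir, "importance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

stage_dynamics <- function(config, out_dir) {
  expr <- read_expression(pipeline_expression_path(out_dir, config))
  times <- attr(expr, "times")
  truth_file <- file.path(out_dir, "truth.json")
  ffls <- if (file.exists(truth_file)) {
    tr <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
    tr$planted_ffls
  } else {
    files <- sort(list.files(out_dir, pattern = "^ffls_.*\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("dynamics stage needs FFLs (motifs stage) or planted truth")
    read_ffls(files[[1]])
  }
  n <- min(nrow(ffls), config$dynamics$max_ffls)
  res <- validate_ffl_set(ffls[seq_len(n), , drop = FALSE], expr, times,
                          control_triplets = config$dynamics$control_triplets,
                          seed = derive_seed(config$seed, "dynamics"))
  if (!is.null(res$results))
    utils::write.table(res$results, file.path(out_dir, "ffl_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_fit = res$n_fit, n_skipped = res$n_skipped,
         fraction_accepted = res$fraction_accepted,
         control_fraction_accepted =
           if (!is.null(res$control)) res$control$fraction_accepted
           else NULL),
    file.path(out_dir, "dynamics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

stage_enrich <- function(config, out_dir) {
  ann_path <- config$paths$annotations %||%
    file.path(out_dir, "annotations.tsv")
  if (!file.exists(ann_path))
    stop("enrich stage needs an annotation table (simulate stage or ",
         "paths$annotations)")
  ann <- read_annotations(ann_path)
  general <- read_weights(out_dir, "cyclic")
  if (is.null(general))
    stop("enrich stage needs the classify stage outputs (cyclic model)")
  top <- percentile_threshold(general, config$importance$percentile,
                              "positive")
  universe <- unique(unlist(feature_members(names(general))))
  gene_set <- intersect(unique(unlist(feature_members(top))), universe)
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  if (nrow(ann) == 0L) {
    jsonlite::write_json(list(n_terms = 0),
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(NULL))
  }
  res <- go_enrichment(gene_set, universe, ann)
  utils::write.table(res, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_terms = nrow(res), min_p_adjusted = min(res$p_adjusted)),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

#' Run the cell-cycle GRN analysis pipeline
#'
#' Executes the requested stages in order — simulate, overlap, motifs,
#' classify (general cyclic model plus one per phase), importance,
#' dynamics, enrich — against an artifact directory. Stages exchange data
#' only through the serialized artifacts they write (TSV/JSON), so any
#' stage can be re-run, or run in a separate process, given the directory.
#' A `manifest.json` records the effective configuration, package version,
#' stages run and an MD5 checksum per output file; identical configurations
#' produce identical manifests.
#'
#' @param config configuration list or path to a YAML file. Top-level keys:
#'   `seed`, `stages`, `simulate` (overrides for [synth_config()]),
#'   `overlap$n_perm`, `classify` (`classes`, `features` = "tf"/"ffl"/
#'   "both", `c_grid`, `r_grid`, `n_balanced_sets`, `n_folds`),
#'   `importance$percentile`, `dynamics` (`max_ffls`, `control_triplets`),
#'   and `paths` (`edge_lists`, `labels`, `expression`, `annotations`) for
#'   running on external data instead of the simulate stage.
#' @param out_dir artifact directory (created if missing).
#' @param stages optional subset of stages to run, in the given order;
#'   defaults to `config$stages`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, stages = NULL) {
  config <- load_pipeline_config(config)
  stages <- stages %||% config$stages
  known <- c("simulate", "overlap", "motifs", "classify", "importance",
             "dynamics", "enrich")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(simulate = stage_simulate, overlap = stage_overlap,
                  motifs = stage_motifs, classify = stage_classify,
                  importance = stage_importance, dynamics = stage_dynamics,
                  enrich = stage_enrich)
  for (st in stages) {
    message("[", st, "] running")
    tryCatch(runners[[st]](config, out_dir),
             error = function(e)
               stop("stage '", st, "' failed: ", conditionMessage(e),
                    call. = FALSE))
  }
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "cycleGRN",
    version = as.character(utils::packageVersion("cycleGRN")),
    seed = config$seed,
    stages = stages,
    classification_targets = config$classify$classes,
    config = config,
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(outputs)))))
  names(manifest$outputs) <- sort(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
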