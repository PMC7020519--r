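#' Train a linear support vector machine
#'
#' L2-regularized hinge-loss linear classifier (libsvm C-classification via
#' \pkg{e1071}) with penalty `C`. Inputs are used unscaled so the recovered
#' weights refer to the original binary features. The returned decision
#' function is `score(x) = x %*% w + b`, oriented so that larger scores mean
#' the positive class.
#'
#' @param x numeric matrix (samples x features).
#' @param y logical (or 0/1) class labels; both classes must be present.
#' @param C penalty parameter.
#' @param tolerance termination tolerance of the underlying solver; the
#'   default is tight enough that the primal objective is optimal to ~1e-4.
#' @return List with `w` (named weight vector), `b` (bias) and `C`.
#' @export
train_linear_svm <- function(x, y, C = 1, tolerance = 1e-6) {
  y <- as.logical(y)
  if (anyNA(y)) stop("labels must be TRUE/FALSE or 0/1")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first label it encountered
  first_class <- fit$levels[fit$labels[1]]
  if (first_class != "pos") { w <- -w; b <- -b }
  list(w = stats::setNames(as.numeric(w), colnames(x)), b = b, C = C)
}

svm_score <- function(model, x) drop(x %*% model$w + model$b)

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a random positive outscores a random negative, with
#' half credit for ties: AUC = (R_pos - n_pos (n_pos + 1) / 2) /
#' (n_pos n_neg) using midranks. 0.5 corresponds to an uninformative
#' classifier, 1.0 to a perfect one.
#'
#' @param scores numeric vector of decision scores.
#' @param labels logical vector, TRUE for positives; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: one class is absent")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Balanced training subsets with a negative:positive ratio R
#'
#' Each subset contains every positive example plus a uniform random sample
#' (without replacement) of `round(R * n_pos)` negatives; `R = 1` gives the
#' classic balanced (1-to-1) construction.
#'
#' @param y logical class labels over the sample universe.
#' @param R ratio of negatives to positives.
#' @param n_sets number of subsets.
#' @param seed integer seed (draws are deterministic given it).
#' @return List of integer index vectors into `y`.
#' @export
make_training_sets <- function(y, R = 1, n_sets = 100, seed = 1) {
  y <- as.logical(y)
  pos <- which(y); neg <- which(!y)
  if (length(pos) < 5L || length(neg) < 5L)
    stop("need at least 5 positive and 5 negative examples, got ",
         length(pos), " / ", length(neg))
  n_draw <- round(R * length(pos))
  if (n_draw > length(neg))
    stop(sprintf(paste0("R = %g requires %d negatives but only %d are ",
                        "available; use a smaller R"),
                 R, n_draw, length(neg)))
  with_seed(derive_seed(seed, "training_sets"), {
    lapply(seq_len(n_sets), function(i) c(pos, sample(neg, n_draw)))
  })
}

#' Default configuration for the balanced-ensemble SVM protocol
#'
#' The hyper-parameter grid spans the penalty `C` and the negative:positive
#' training ratio `R`; each (C, R) cell is evaluated with `n_balanced_sets`
#' resampled training subsets and `n_folds`-fold cross-validation inside each
#' subset.
#'
#' @param c_grid penalty grid.
#' @param r_grid negative:positive ratio grid.
#' @param n_balanced_sets number of resampled training subsets per cell.
#' @param n_folds cross-validation folds within each subset.
#' @param seed root seed; all per-cell and per-subset draws derive from it.
#' @return List of class `svm_ensemble_config`.
#' @export
svm_ensemble_config <- function(c_grid = c(0.01, 0.1, 0.5, 1, 1.5, 2.0),
                                r_grid = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3,
                                           3.5, 4),
                                n_balanced_sets = 100,
                                n_folds = 10,
                                seed = 1) {
  stopifnot(length(c_grid) >= 1L, length(r_grid) >= 1L,
            n_balanced_sets >= 1L, n_folds >= 2L)
  structure(list(c_grid = c_grid, r_grid = r_grid,
                 n_balanced_sets = n_balanced_sets, n_folds = n_folds,
                 seed = seed),
            class = "svm_ensemble_config")
}

# Positive-class indicator from a phase label assignment. "cyclic" means any
# phase other than "none"; otherwise the named phase itself. Genes missing
# from `labels` count as "none".
positive_indicator <- function(genes, labels, positive_class) {
  lab <- rep("none", length(genes))
  hit <- genes %in% names(labels)
  lab[hit] <- unname(labels[genes[hit]])
  if (positive_class == "cyclic") lab != "none" else lab == positive_class
}

# Score every gene for one balanced subset: genes inside the subset get
# out-of-fold cross-validated scores (a gene is never scored by a model whose
# training data contained it); genes outside the subset are scored by the
# model trained on the full subset. Returns list(scores, w, b).
score_one_set <- function(x, y, idx, C, n_folds, fold_seed) {
  n <- nrow(x)
  scores <- numeric(n)
  k <- min(n_folds, length(idx))
  # stratified fold assignment keeps both classes in every training split
  fold <- integer(length(idx))
  with_seed(fold_seed, {
    for (cls in c(TRUE, FALSE)) {
      m <- which(y[idx] == cls)
      fold[m] <- sample(rep(seq_len(k), length.out = length(m)))
    }
  })
  for (f in seq_len(k)) {
    test <- idx[fold == f]
    train <- idx[fold != f]
    model <- train_linear_svm(x[train, , drop = FALSE], y[train], C)
    scores[test] <- svm_score(model, x[test, , drop = FALSE])
  }
  full <- train_linear_svm(x[idx, , drop = FALSE], y[idx], C)
  outside <- setdiff(seq_len(n), idx)
  if (length(outside))
    scores[outside] <- svm_score(full, x[outside, , drop = FALSE])
  list(scores = scores, w = full$w, b = full$b)
}

# Evaluate one (C, R) grid cell; per-gene scores averaged over subsets.
evaluate_combo <- function(x, y, C, R, config, keep_runs = FALSE) {
  sets <- make_training_sets(y, R, config$n_balanced_sets,
                             seed = derive_seed(config$seed,
                                                sprintf("C%g_R%g", C, R)))
  score_sum <- numeric(nrow(x))
  w_runs <- if (keep_runs)
    matrix(NA_real_, length(sets), ncol(x),
           dimnames = list(NULL, colnames(x)))
  w_sum <- numeric(ncol(x)); b_sum <- 0
  for (i in seq_along(sets)) {
    res <- score_one_set(x, y, sets[[i]], C, config$n_folds,
                         fold_seed = derive_seed(
                           config$seed, sprintf("C%g_R%g_set%d", C, R, i)))
    score_sum <- score_sum + res$scores
    w_sum <- w_sum + res$w; b_sum <- b_sum + res$b
    if (keep_runs) w_runs[i, ] <- res$w
  }
  scores <- score_sum / length(sets)
  list(auc = auc_roc(scores, y), scores = scores,
       w_mean = stats::setNames(w_sum / length(sets), colnames(x)),
       b_mean = b_sum / length(sets), w_runs = w_runs)
}

#' Balanced-ensemble linear-SVM classification of cell-cycle genes
#'
#' The core classification protocol. For every (C, R) pair on the grid,
#' `n_balanced_sets` training subsets are drawn (all positives plus
#' `round(R * n_pos)` random negatives). Within each subset genes are scored
#' out-of-fold by `n_folds`-fold cross-validation; genes outside the subset
#' are scored by the model trained on the whole subset, so every gene in the
#' matrix receives a score and no gene is ever scored by a model trained on
#' it. Scores are averaged across subsets and the AUC-ROC computed against
#' all genes. The (C, R) pair maximizing this averaged-score AUC defines the
#' representative model (ties broken toward smaller C, then smaller R);
#' per-feature weights are the mean over its subsets' full-subset models.
#'
#' @param x binary feature matrix from [build_feature_matrix()].
#' @param labels named character vector gene -> phase (one of "G1", "S",
#'   "S-G2", "G2-M", "M-G1", "none"); genes absent from it count as "none".
#' @param positive_class `"cyclic"` (any non-"none" phase, the general
#'   model) or a single phase name.
#' @param config an [svm_ensemble_config()].
#' @return Object of class `cc_svm` with the AUC grid, best (C, R), averaged
#'   per-gene scores, mean feature weights and per-run weights of the best
#'   cell. Methods: `print`, `summary`, `coef` (mean weights), `predict`.
#' @seealso [importance_table()], [percentile_threshold()]
#' @export
cc_classify <- function(x, labels, positive_class = "cyclic",
                        config = svm_ensemble_config()) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  y <- positive_indicator(rownames(x), labels, positive_class)
  if (sum(y) < 5L || sum(!y) < 5L)
    stop("need at least 5 positives and 5 negatives after feature filtering")
  grid <- expand.grid(C = config$c_grid, R = config$r_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- NA_real_
  grid$feasible <- round(grid$R * sum(y)) <= sum(!y) &
    round(grid$R * sum(y)) >= 1
  if (!any(grid$feasible))
    stop("no feasible R value for ", sum(y), " positives and ",
         sum(!y), " negatives")
  if (!all(grid$feasible))
    warning(sum(!grid$feasible), " infeasible (C, R) cell(s) skipped")
  for (i in which(grid$feasible)) {
    grid$auc[i] <- evaluate_combo(x, y, grid$C[i], grid$R[i], config)$auc
  }
  ok <- which(grid$feasible)
  best_i <- ok[order(-grid$auc[ok], grid$C[ok], grid$R[ok])][1]
  best <- evaluate_combo(x, y, grid$C[best_i], grid$R[best_i], config,
                         keep_runs = TRUE)
  structure(list(
    auc_grid = grid,
    best = list(C = grid$C[best_i], R = grid$R[best_i],
                auc = grid$auc[best_i]),
    scores = stats::setNames(best$scores, rownames(x)),
    weights = best$w_mean,
    bias = best$b_mean,
    weights_runs = best$w_runs,
    y = stats::setNames(y, rownames(x)),
    positive_class = positive_class,
    feature_kind = attr(x, "feature_kind"),
    feature_source = attr(x, "feature_source"),
    config = config), class = "cc_svm")
}

#' @export
print.cc_svm <- function(x, ...) {
  cat(sprintf(
    "Balanced-ensemble linear SVM ('%s'): %d genes (%d positive), %d features\n",
    x$positive_class, length(x$scores), sum(x$y), length(x$weights)))
  cat(sprintf("Best grid cell: C = %g, R = %g, AUC-ROC = %.3f\n",
              x$best$C, x$best$R, x$best$auc))
  invisible(x)
}

#' @export
summary.cc_svm <- function(object, ...) {
  g <- object$auc_grid
  tab <- stats::xtabs(auc ~ C + R, data = g[g$feasible, ])
  cat("AUC-ROC over the (C, R) grid (averaged-score ensemble):\n")
  print(round(tab, 3))
  print(object)
  invisible(object$auc_grid)
}

#' @export
coef.cc_svm <- function(object, ...) object$weights

#' @export
predict.cc_svm <- function(object, newx, ...) {
  stopifnot(is.matrix(newx))
  newx <- newx[, names(object$weights), drop = FALSE]
  drop(newx %*% object$weights + object$bias)
}

#' Two-way ANOVA of classifier performance by class and data set
#'
#' Fits the fixed-effects model S = C + D + C*D, where S is a model's
#' AUC-ROC, C the positive-class set and D the regulatory data set, with
#' type-I sums of squares on a balanced design (via [stats::aov()]).
#'
#' @param perf data.frame with numeric column `auc` and factors `class`,
#'   `dataset`.
#' @return data.frame with one row per term (class, dataset, interaction,
#'   residuals): `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
anova_performance <- function(perf) {
  stopifnot(all(c("auc", "class", "dataset") %in% names(perf)))
  perf$class <- factor(perf$class); perf$dataset <- factor(perf$dataset)
  if (nlevels(perf$class) < 2L || nlevels(perf$dataset) < 2L)
    stop("need at least 2 levels per factor")
  cells <- table(perf$class, perf$dataset)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[idx[, 1]], colnames(cells)[idx[, 2]],
               sep = ":", collapse = ", "))
  }
  fit <- stats::aov(auc ~ class * dataset, data = perf)
  s <- summary(fit)[[1]]
  n <- nrow(s)
  # without residual degrees of freedom (one replicate per cell) aov
  # reports no F statistics
  data.frame(term = trimws(rownames(s)), df = s[["Df"]],
             sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
             F = s[["F value"]] %||% rep(NA_real_, n),
             p = s[["Pr(>F)"]] %||% rep(NA_real_, n),
             stringsAsFactors = FALSE)
}
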