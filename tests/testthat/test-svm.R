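test_that("linear SVM orients weights toward the positive class", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(FALSE, FALSE, TRUE, TRUE)
  for (C in c(0.01, 1, 100))
    expect_gt(train_linear_svm(x, y, C)$w[["f"]], 0)
  expect_error(train_linear_svm(x, rep(TRUE, 4)), "single class")
})

test_that("label flip negates the decision function", {
  withr::local_seed(31)
  x <- matrix(rbinom(400, 1, 0.3), nrow = 40)
  colnames(x) <- paste0("f", 1:10)
  y <- rbinom(40, 1, 0.5) == 1
  m1 <- train_linear_svm(x, y, 1)
  m2 <- train_linear_svm(x, !y, 1)
  expect_equal(m1$w, -m2$w, tolerance = 1e-6)
  expect_equal(m1$b, -m2$b, tolerance = 1e-6)
})

test_that("SVM objective matches a brute-force primal minimization", {
  withr::local_seed(77)
  x <- matrix(c(0, 0, 1, 1.2,
                0, 1, 0.2, 1), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(FALSE, FALSE, TRUE, TRUE)
  for (C in c(0.5, 1, 5)) {
    m <- train_linear_svm(x, y, C)
    obj_svm <- svm_objective(m$w, m$b, x, y, C)
    obj_oracle <- svm_oracle_objective(x, y, C)
    expect_lt(abs(obj_svm - obj_oracle), 1e-4)
  }
})

test_that("AUC follows the Mann-Whitney tie convention", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auc_roc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # hand count: 3 of 4 positive-negative pairs concordant
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auc_roc(1:3, rep(TRUE, 3)), "one class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::local_seed(5)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4) == 1
  a <- auc_roc(s, y)
  expect_equal(auc_roc(exp(s), y), a)
  expect_equal(auc_roc(rank(s), y), a)
  skip_if_not_installed("pROC")
  # cross-check against an independent ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(a, ref)
})

test_that("balanced sets honor the negative:positive ratio R", {
  y <- rep(c(TRUE, FALSE), c(10, 100))
  s1 <- make_training_sets(y, R = 1, n_sets = 20, seed = 2)
  expect_true(all(lengths(s1) == 20L))
  s2 <- make_training_sets(y, R = 2, n_sets = 5, seed = 2)
  expect_true(all(lengths(s2) == 30L))
  for (s in s2) {
    expect_equal(sum(y[s]), 10L)          # every positive, once
    expect_false(anyDuplicated(s) > 0)    # negatives without replacement
  }
  expect_error(make_training_sets(rep(c(TRUE, FALSE), c(10, 30)), R = 4),
               "smaller R")
  expect_identical(make_training_sets(y, 1, 5, seed = 7),
                   make_training_sets(y, 1, 5, seed = 7))
})

test_that("out-of-fold scoring cannot leak gene identity", {
  # with one unique indicator feature per gene a memorizing model would be
  # perfect; honest out-of-fold scores must stay near chance inside the set
  n <- 40
  x <- diag(1L, n)
  dimnames(x) <- list(paste0("g", 1:n), paste0("self", 1:n))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  res <- cycleGRN:::score_one_set(x, y, seq_len(n), C = 10, n_folds = 5,
                                  fold_seed = 1)
  oof_auc <- auc_roc(res$scores, y)
  full <- train_linear_svm(x, y, 10)
  memorized_auc <- auc_roc(cycleGRN:::svm_score(full, x), y)
  expect_gt(memorized_auc, 0.99)
  expect_lt(oof_auc, 0.75)
})

test_that("the ensemble recovers a strong planted signal and is deterministic", {
  world <- make_planted_world(seed = 5, effect = 1, noise_sd = 0)
  cfg <- svm_ensemble_config(c_grid = c(0.1, 1), r_grid = c(0.25, 0.5),
                             n_balanced_sets = 8, n_folds = 5, seed = 11)
  fit <- cc_classify(world$fm, world$labels, "cyclic", cfg)
  expect_gte(fit$best$auc, 0.95)
  expect_true(all(fit$auc_grid$auc[fit$auc_grid$feasible] <= 1))
  fit2 <- cc_classify(world$fm, world$labels, "cyclic", cfg)
  expect_identical(fit$auc_grid, fit2$auc_grid)
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$weights_runs, fit2$weights_runs)
  # planted TFs carry large positive weights in the fitted model
  imp <- importance_table(coef(fit))
  planted <- unlist(lapply(names(world$tf_phase_map), function(tf)
    paste0(names(world$grns), ":", tf)))
  planted_ranks <- imp$rank[imp$feature %in% planted]
  expect_lt(stats::median(planted_ranks), 0.25 * nrow(imp))
})

test_that("infeasible R cells are skipped with a warning", {
  world <- make_planted_world(seed = 6, effect = 1)
  cfg <- svm_ensemble_config(c_grid = 1, r_grid = c(0.5, 4),
                             n_balanced_sets = 3, n_folds = 3, seed = 1)
  expect_warning(fit <- cc_classify(world$fm, world$labels, "cyclic", cfg),
                 "infeasible")
  expect_equal(sum(fit$auc_grid$feasible), 1L)
})

test_that("two-way performance ANOVA decomposes sums of squares exactly", {
  withr::local_seed(8)
  perf <- expand.grid(class = paste0("c", 1:3), dataset = paste0("d", 1:5),
                      rep = 1:3)
  perf$auc <- stats::runif(nrow(perf), 0.5, 1)
  res <- anova_performance(perf)
  # brute-force type-I decomposition for a balanced design
  mu <- mean(perf$auc)
  ss_class <- sum(tapply(perf$auc, perf$class,
                         function(v) length(v) * (mean(v) - mu)^2))
  ss_data <- sum(tapply(perf$auc, perf$dataset,
                        function(v) length(v) * (mean(v) - mu)^2))
  cell <- tapply(perf$auc, list(perf$class, perf$dataset), mean)
  ss_cells <- sum(3 * (cell - mu)^2)
  ss_int <- ss_cells - ss_class - ss_data
  ss_tot <- sum((perf$auc - mu)^2)
  expect_equal(res$sum_sq[res$term == "class"], ss_class,
               tolerance = 1e-10)
  expect_equal(res$sum_sq[res$term == "dataset"], ss_data,
               tolerance = 1e-10)
  expect_equal(res$sum_sq[res$term == "class:dataset"], ss_int,
               tolerance = 1e-10)
  expect_equal(sum(res$sum_sq), ss_tot, tolerance = 1e-10)
})

test_that("an additive noise-free response has zero interaction", {
  perf <- expand.grid(class = c("a", "b"), dataset = c("x", "y"))
  perf$auc <- c(0.6, 0.7, 0.8, 0.9) # class effect 0.1, dataset effect 0.2
  res <- anova_performance(perf)
  expect_equal(res$sum_sq[res$term == "class:dataset"], 0,
               tolerance = 1e-12)
  # a constant response carries no variance at all
  perf$auc <- 0.5
  res0 <- anova_performance(perf)
  expect_equal(sum(res0$sum_sq), 0, tolerance = 1e-12)
})

test_that("empty design cells are reported by name", {
  perf <- data.frame(class = c("a", "a", "b"), dataset = c("x", "y", "x"),
                     auc = c(0.5, 0.6, 0.7))
  expect_error(anova_performance(perf), "b:y")
})
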