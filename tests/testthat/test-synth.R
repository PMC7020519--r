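small_config <- function(...) {
  args <- utils::modifyList(
    list(n_tfs = 15, n_genes = 200, out_degree_mean = 10,
         n_datasets = 3, pairwise_overlap_target = 0.3,
         planted_ffl_count = 8,
         phase_sizes = c(G1 = 20, S = 15, "S-G2" = 12, "G2-M" = 15,
                         "M-G1" = 10),
         tfs_per_phase = 2, tf_phase_effect = 0.5,
         n_timepoints = 24, noise_sd = 0.05, seed = 9),
    list(...))
  do.call(synth_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(synth_config(phase_sizes = c(G1 = 500), n_genes = 100),
               "exceeds")
  expect_error(synth_config(n_timepoints = 3), "at least 4")
  expect_error(synth_config(pairwise_overlap_target = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(phase_sizes = c(BAD = 5)), "CC_PHASES")
  # overlap below the chance level implied by the degrees is unattainable
  dense <- synth_config(n_tfs = 5, n_genes = 20, out_degree_mean = 15,
                        pairwise_overlap_target = 0.01,
                        phase_sizes = c(G1 = 5))
  expect_error(generate_grn_collection(dense), "unattainable")
})

test_that("generation is deterministic byte-for-byte under a fixed seed", {
  cfg <- small_config()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  for (f in c(f1, f2)) {
    gen <- generate_grn_collection(cfg)
    labels <- generate_phase_labels(cfg)
    expr <- generate_expression(labels, cfg)
    write_edge_list(gen$grns[[2]], f)
    cat(labels, file = f, append = TRUE)
    cat(expr[1:20, ], file = f, append = TRUE)
  }
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a single-dataset request returns one GRN", {
  cfg <- small_config(n_datasets = 1)
  gen <- generate_grn_collection(cfg)
  expect_length(gen$grns, 1L)
})

test_that("overlap target 1 forces identical data sets", {
  cfg <- small_config(pairwise_overlap_target = 1, planted_ffl_count = 0)
  gen <- generate_grn_collection(cfg)
  ov <- pairwise_overlap(gen$grns[[1]], gen$grns[[3]])
  expect_equal(ov$coefficient, 1.0)
})

test_that("mean realized overlap coefficient hits the target", {
  cfg <- synth_config(n_tfs = 20, n_genes = 300, out_degree_mean = 12,
                      n_datasets = 2, pairwise_overlap_target = 0.3,
                      planted_ffl_count = 0, phase_sizes = c(G1 = 10),
                      noise_sd = 0, seed = 1)
  coefs <- vapply(1:100, function(s) {
    cfg$seed <- s
    gen <- generate_grn_collection(cfg)
    pairwise_overlap(gen$grns[[1]], gen$grns[[2]])$coefficient
  }, numeric(1))
  se <- stats::sd(coefs) / sqrt(length(coefs))
  expect_lt(abs(mean(coefs) - 0.3), 3 * se)
})

test_that("every planted FFL is recovered by motif enumeration", {
  gen <- generate_grn_collection(small_config())
  planted <- sort_ffl_keys(gen$truth$planted_ffls)
  for (g in gen$grns)
    expect_true(all(planted %in% sort_ffl_keys(enumerate_ffls(g))))
})

test_that("phase labels conserve the requested counts exactly", {
  cfg <- small_config()
  labels <- generate_phase_labels(cfg)
  counts <- table(factor(labels, levels = c(CC_PHASES, "none")))
  for (p in names(cfg$phase_sizes))
    expect_equal(unname(counts[p]), cfg$phase_sizes[[p]],
                 ignore_attr = TRUE)
  expect_equal(sum(counts), cfg$n_genes)
  # boundary sizes at the 71-300 endpoints of the phase-cluster range
  big <- synth_config(n_genes = 500, phase_sizes = c(G1 = 300, "M-G1" = 71))
  lb <- generate_phase_labels(big)
  expect_equal(sum(lb == "G1"), 300)
  expect_equal(sum(lb == "M-G1"), 71)
  none <- synth_config(phase_sizes = c(G1 = 0))
  expect_true(all(generate_phase_labels(none) == "none"))
})

test_that("expression traces are normalized and peak at the phase offset", {
  cfg <- small_config(noise_sd = 0.05)
  labels <- generate_phase_labels(cfg)
  expr <- generate_expression(labels, cfg)
  expect_equal(unname(apply(expr, 1, min)), rep(0, nrow(expr)))
  expect_equal(unname(apply(expr, 1, max)), rep(1, nrow(expr)))
  # noise-free G1 gene peaks exactly at its offset (t = 0 for G1)
  cfg0 <- small_config(noise_sd = 0)
  expr0 <- generate_expression(labels, cfg0)
  times <- attr(expr0, "times")
  g1 <- names(labels)[labels == "G1"][1]
  first_period <- times < cfg0$period_minutes
  expect_equal(times[first_period][which.max(expr0[g1, first_period])], 0)
  expect_error(generate_expression(labels, small_config(n_timepoints = 3)),
               "at least 4")
})

test_that("assigned phase order matches recovered peak times", {
  cfg <- synth_config(n_tfs = 5, n_genes = 250, out_degree_mean = 5,
                      phase_sizes = c(G1 = 40, S = 40, "S-G2" = 40,
                                      "G2-M" = 40, "M-G1" = 40),
                      n_timepoints = 50, noise_sd = 0.05, seed = 4)
  labels <- generate_phase_labels(cfg)
  expr <- generate_expression(labels, cfg)
  times <- attr(expr, "times")
  cyc <- names(labels)[labels != "none"]
  first <- times < cfg$period_minutes
  peak <- vapply(cyc, function(g)
    times[first][which.max(expr[g, first])], numeric(1))
  # peak time is circular: a G1 peak at t = 0 reappears at t = period, so
  # unwrap the boundary half-offset before ranking
  half_off <- cfg$period_minutes / 10
  peak <- ifelse(peak > cfg$period_minutes - half_off,
                 peak - cfg$period_minutes, peak)
  phase_idx <- match(labels[cyc], CC_PHASES)
  expect_gt(stats::cor(phase_idx, peak, method = "spearman"), 0.95)
})

test_that("planted TF-phase signal raises in-phase targeting", {
  cfg <- small_config(tf_phase_effect = 0.4)
  gen <- generate_grn_collection(cfg)
  labels <- generate_phase_labels(cfg)
  pl <- plant_tf_phase_signal(gen$grns, labels, cfg)
  in_frac <- c(); out_frac <- c()
  for (g in pl$grns) {
    adj <- cycleGRN:::grn_adjacency(g)
    for (tf in names(pl$tf_phase_map)) {
      ph <- pl$tf_phase_map[[tf]]
      in_genes <- names(labels)[labels == ph]
      out_genes <- names(labels)[labels != ph]
      in_frac <- c(in_frac, mean(in_genes %in% adj[[tf]]))
      out_frac <- c(out_frac, mean(out_genes %in% adj[[tf]]))
    }
  }
  expect_gt(mean(in_frac), mean(out_frac))
  # deterministic limit: effect 1 targets every in-phase gene
  cfg1 <- small_config(tf_phase_effect = 1)
  pl1 <- plant_tf_phase_signal(gen$grns, labels, cfg1)
  adj1 <- cycleGRN:::grn_adjacency(pl1$grns[[1]])
  tf <- names(pl1$tf_phase_map)[1]
  ph <- pl1$tf_phase_map[[tf]]
  expect_true(all(names(labels)[labels == ph] %in% adj1[[tf]]))
  # effect 0 leaves the networks untouched
  cfg0 <- small_config(tf_phase_effect = 0)
  pl0 <- plant_tf_phase_signal(gen$grns, labels, cfg0)
  expect_identical(cycleGRN:::grn_keys(pl0$grns[[1]]),
                   cycleGRN:::grn_keys(gen$grns[[1]]))
})

test_that("simulated FFL time courses follow the shared ODE solution", {
  params <- c(alpha_S = -1, alpha_T = -0.5, beta_ST = 0, beta_PS = 0,
              beta_PT = 0)
  tt <- seq(0, 5, by = 0.25)
  sim <- simulate_ffl_timecourses(params, constant_forcing(1), tt,
                                  noise_sd = 0, S0 = 1, T0 = 1)
  expect_equal(unname(sim["secondary", ]), exp(-tt), tolerance = 1e-10)
  params2 <- c(alpha_S = -0.1, alpha_T = -0.2, beta_ST = 0.3,
               beta_PS = 0.2, beta_PT = 0.1)
  f <- sinusoid_forcing(0.5, 125, phase = 10, offset = 0.6)
  sim2 <- simulate_ffl_timecourses(params2, f, seq(0, 250, by = 10),
                                   noise_sd = 0, S0 = 0.4, T0 = 0.3)
  sol <- ffl_solve(ffl_ode_model(-0.1, -0.2, 0.3, 0.2, 0.1, f,
                                 S0 = 0.4, T0 = 0.3),
                   seq(0, 250, by = 10))
  expect_equal(unname(sim2["secondary", ]), unname(sol[, "S"]))
  expect_equal(unname(sim2["target", ]), unname(sol[, "T"]))
  # byte-identical reruns under a fixed seed
  a <- simulate_ffl_timecourses(params2, f, seq(0, 250, by = 10),
                                noise_sd = 0.05, seed = 3)
  b <- simulate_ffl_timecourses(params2, f, seq(0, 250, by = 10),
                                noise_sd = 0.05, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_ffl_timecourses(params2, f, c(0, 0, 1)),
               "increasing")
})

test_that("label and expression tables round-trip through TSV", {
  cfg <- small_config()
  labels <- generate_phase_labels(cfg)
  expr <- generate_expression(labels, cfg)
  fl <- withr::local_tempfile(); fe <- withr::local_tempfile()
  write_phase_labels(labels, fl)
  write_expression(expr, fe)
  expect_identical(read_phase_labels(fl), labels)
  back <- read_expression(fe)
  expect_equal(unname(back), unname(expr), tolerance = 1e-12)
  expect_equal(attr(back, "times"), attr(expr, "times"))
})
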