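test_that("decoupled decay reproduces the exponential closed forms", {
  m <- ffl_ode_model(-1, -0.4, 0, 0, 0, constant_forcing(0), S0 = 1,
                     T0 = 2)
  tt <- seq(0, 6, by = 0.5)
  sol <- ffl_solve(m, tt, method = "closed")
  expect_equal(unname(sol[, "S"]), exp(-tt), tolerance = 1e-12)
  expect_equal(unname(sol[, "T"]), 2 * exp(-0.4 * tt), tolerance = 1e-12)
})

test_that("constant forcing drives the secondary TF to -beta_PS/alpha_S", {
  m <- ffl_ode_model(-0.5, -1, 0, 1, 0, constant_forcing(1), S0 = 0,
                     T0 = 0)
  sol <- ffl_solve(m, c(1, 5, 50, 100), method = "closed")
  expect_equal(unname(sol[4, "S"]), 2, tolerance = 1e-8)
})

test_that("closed form agrees with numeric integration across random models", {
  withr::local_seed(21)
  tt <- seq(0, 250, by = 5)
  for (i in 1:20) {
    m <- ffl_ode_model(stats::runif(1, -1, -0.01),
                       stats::runif(1, -1, -0.01),
                       stats::runif(1, 0, 0.5), stats::runif(1, 0, 0.5),
                       stats::runif(1, 0, 0.5),
                       sinusoid_forcing(stats::runif(1, 0.2, 1),
                                        stats::runif(1, 50, 200),
                                        stats::runif(1, 0, 100),
                                        stats::runif(1, 0, 1)),
                       S0 = stats::runif(1), T0 = stats::runif(1))
    expect_lt(max(abs(ffl_solve(m, tt, "closed") -
                        ffl_solve(m, tt, "numeric"))), 1e-6)
  }
})

test_that("zero and equal decay rates use the degenerate closed form", {
  tt <- seq(0, 40, by = 2)
  m0 <- ffl_ode_model(0, -0.3, 0.2, 0.1, 0.1, constant_forcing(1),
                      S0 = 1, T0 = 0)
  expect_lt(max(abs(ffl_solve(m0, tt, "closed") -
                      ffl_solve(m0, tt, "numeric"))), 1e-6)
  # exact: S'(t) = beta_PS with alpha_S = 0 gives a linear ramp
  expect_equal(unname(ffl_solve(m0, tt, "closed")[, "S"]), 1 + 0.1 * tt,
               tolerance = 1e-10)
  m_eq <- ffl_ode_model(-0.2, -0.2, 0.2, 0.1, 0.1,
                        sinusoid_forcing(1, 125), S0 = 1, T0 = 0)
  expect_lt(max(abs(ffl_solve(m_eq, tt, "closed") -
                      ffl_solve(m_eq, tt, "numeric"))), 1e-6)
})

test_that("the solution is jointly linear in (S0, T0, f)", {
  tt <- seq(0, 100, by = 5)
  base <- list(alpha_S = -0.1, alpha_T = -0.3, beta_ST = 0.4,
               beta_PS = 0.2, beta_PT = 0.1)
  solve_with <- function(scale) {
    f <- sinusoid_forcing(0.5 * scale, 125, phase = 10,
                          offset = 0.2 * scale)
    m <- ffl_ode_model(base$alpha_S, base$alpha_T, base$beta_ST,
                       base$beta_PS, base$beta_PT, f,
                       S0 = 0.3 * scale, T0 = 0.7 * scale)
    ffl_solve(m, tt, "closed")
  }
  expect_equal(solve_with(3), 3 * solve_with(1), tolerance = 1e-8)
})

test_that("sinusoid fitting recovers forcing parameters", {
  tt <- seq(0, 250, length.out = 40)
  truth <- sinusoid_forcing(0.42, 125, phase = 30, offset = 0.55)
  f <- fit_sinusoid(tt, cycleGRN:::forcing_fun(truth)(tt))
  expect_equal(f$amplitude, 0.42, tolerance = 1e-3)
  expect_equal(f$period, 125, tolerance = 1e-2)
  expect_equal(f$offset, 0.55, tolerance = 1e-3)
  # phase is recovered modulo the period
  expect_equal((f$phase - 30) %% 125, 0, tolerance = 1e-2)
})

test_that("noise-free self-simulated FFLs are recovered within tolerance", {
  truth <- c(alpha_S = -0.08, alpha_T = -0.05, beta_ST = 0.06,
             beta_PS = 0.1, beta_PT = 0.04)
  f <- sinusoid_forcing(0.5, 125, phase = 20, offset = 0.5)
  tt <- seq(0, 250, length.out = 36)
  sim <- simulate_ffl_timecourses(truth, f, tt, noise_sd = 0, S0 = 0.3,
                                  T0 = 0.2)
  fit <- ffl_fit(sim["primary", ], sim["secondary", ], sim["target", ],
                 tt)
  rel <- abs(coef(fit) - truth) / abs(truth)
  expect_lt(max(rel[c("alpha_S", "alpha_T")]), 0.05)
  expect_lt(max(rel[c("beta_ST", "beta_PS", "beta_PT")]), 0.10)
  expect_true(fit$accepted)
  expect_true(fit$converged && fit$moved_from_init)
})

test_that("sign-violating dynamics are rejected by the acceptance filter", {
  growth <- c(alpha_S = 0.02, alpha_T = -0.05, beta_ST = 0.06,
              beta_PS = 0.1, beta_PT = 0.04)
  f <- sinusoid_forcing(0.5, 125, phase = 20, offset = 0.5)
  tt <- seq(0, 250, length.out = 36)
  sim <- simulate_ffl_timecourses(growth, f, tt, noise_sd = 0, S0 = 0.3,
                                  T0 = 0.2)
  fit <- ffl_fit(sim["primary", ], sim["secondary", ], sim["target", ],
                 tt)
  expect_false(fit$accepted)
})

test_that("a fit that never leaves the initial vector is not accepted", {
  # a constant primary is represented exactly by the forcing fit, so data
  # simulated from the initial vector leaves the optimizer nothing to
  # improve: the fit returns the init vector and must not be accepted
  init <- c(alpha_S = -0.1, alpha_T = -0.1, beta_ST = 0.1, beta_PS = 0.1,
            beta_PT = 0.1)
  f <- constant_forcing(0.5)
  tt <- seq(0, 250, length.out = 30)
  sim <- simulate_ffl_timecourses(init, f, tt, noise_sd = 0, S0 = 0.4,
                                  T0 = 0.4)
  fit <- ffl_fit(sim["primary", ], sim["secondary", ], sim["target", ],
                 tt, init = init)
  expect_false(fit$moved_from_init)
  expect_false(fit$accepted)
})

test_that("the likelihood peaks at the truth for noise-free data", {
  truth <- c(alpha_S = -0.08, alpha_T = -0.05, beta_ST = 0.06,
             beta_PS = 0.1, beta_PT = 0.04)
  f <- sinusoid_forcing(0.5, 125, phase = 20, offset = 0.5)
  tt <- seq(0, 250, length.out = 30)
  sim <- simulate_ffl_timecourses(truth, f, tt, noise_sd = 0, S0 = 0.3,
                                  T0 = 0.2)
  obs <- rbind(S = sim["secondary", ], T = sim["target", ])
  sse_at <- function(p) {
    m <- ffl_ode_model(p[1], p[2], p[3], p[4], p[5], f, S0 = 0.3,
                       T0 = 0.2)
    sum((t(ffl_solve(m, tt)) - obs)^2)
  }
  withr::local_seed(33)
  for (i in 1:10) {
    pert <- truth * (1 + stats::runif(5, -0.2, 0.2))
    expect_lte(sse_at(truth), sse_at(pert))
  }
})

test_that("fit methods expose coefficients, residuals and simulations", {
  truth <- c(alpha_S = -0.1, alpha_T = -0.06, beta_ST = 0.05,
             beta_PS = 0.08, beta_PT = 0.03)
  f <- sinusoid_forcing(0.4, 125, phase = 10, offset = 0.5)
  tt <- seq(0, 250, length.out = 25)
  sim <- simulate_ffl_timecourses(truth, f, tt, noise_sd = 0.02, seed = 4,
                                  S0 = 0.3, T0 = 0.2)
  fit <- ffl_fit(sim["primary", ], sim["secondary", ], sim["target", ],
                 tt)
  expect_named(coef(fit), names(truth))
  expect_equal(dim(residuals(fit)), c(length(tt), 2L))
  expect_equal(fitted(fit) + residuals(fit), fit$observed)
  expect_equal(predict(fit), fitted(fit))
  expect_s3_class(logLik(fit), "logLik")
  s <- simulate(fit, nsim = 2, seed = 1)
  expect_length(s, 2L)
  expect_equal(dim(s[[1]]), dim(fitted(fit)))
})

test_that("acceptance is monotone non-increasing in noise", {
  truth <- c(alpha_S = -0.08, alpha_T = -0.05, beta_ST = 0.06,
             beta_PS = 0.1, beta_PT = 0.04)
  f <- sinusoid_forcing(0.5, 125, phase = 20, offset = 0.5)
  tt <- seq(0, 250, length.out = 25)
  frac <- vapply(c(0.0, 0.05, 0.4), function(noise) {
    acc <- vapply(1:6, function(s) {
      sim <- simulate_ffl_timecourses(truth, f, tt, noise_sd = noise,
                                      seed = s, S0 = 0.3, T0 = 0.2)
      ffl_fit(sim["primary", ], sim["secondary", ], sim["target", ],
              tt)$accepted
    }, logical(1))
    mean(acc)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
})

test_that("validate_ffl_set handles empty input and missing traces", {
  empty <- data.frame(primary = character(), secondary = character(),
                      target = character())
  expr <- matrix(stats::runif(20), 2, 10,
                 dimnames = list(c("a", "b"), NULL))
  res <- validate_ffl_set(empty, expr, seq(0, 90, by = 10))
  expect_true(is.na(res$fraction_accepted))
  expect_equal(res$n_fit, 0L)
  miss <- data.frame(primary = "a", secondary = "b", target = "zzz",
                     stringsAsFactors = FALSE)
  res2 <- validate_ffl_set(miss, expr, seq(0, 90, by = 10))
  expect_equal(res2$n_skipped, 1L)
})
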