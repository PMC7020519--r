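# Linear FFL transcription-dynamics model:
#   dS/dt = alpha_S * S + beta_PS * f(t)
#   dT/dt = beta_ST * S + alpha_T * T + beta_PT * f(t)
# S, T: expression of the secondary TF and the target gene; alpha_* their
# decay rates; beta_* production rates; f(t) the (independent) expression of
# the primary TF driving both.
#
# The closed-form path represents solutions as finite sums of terms
# coef * t^k * exp(s*t) with complex coef/s. Sinusoidal or constant forcing
# stays inside this family (including resonant/degenerate cases, which pick
# up secular t^k factors), so the first-order chain S -> T is solved exactly
# by variation of parameters.

terms_new <- function(coef, s, k) {
  list(coef = as.complex(coef), s = as.complex(s), k = as.integer(k))
}

terms_bind <- function(...) {
  ts <- list(...)
  terms_new(unlist(lapply(ts, `[[`, "coef")),
            unlist(lapply(ts, `[[`, "s")),
            unlist(lapply(ts, `[[`, "k")))
}

terms_scale <- function(t, fac) terms_new(t$coef * fac, t$s, t$k)

terms_eval <- function(t, times) {
  out <- numeric(length(times))
  for (i in seq_along(t$coef))
    out <- out + Re(t$coef[i] * times^t$k[i] * exp(t$s[i] * times))
  out
}

# Particular solution of x' = a x + coef t^k exp(s t), one forcing term.
term_response <- function(coef, s, k, a, tol = 1e-9) {
  if (abs(s - a) < tol * (1 + abs(a))) {
    # resonant: integral of t^k gives t^(k+1)/(k+1)
    terms_new(coef / (k + 1), a, k + 1L)
  } else {
    cs <- complex(length.out = k + 1L)
    cs[k + 1L] <- coef / (s - a)             # coefficient of t^k
    if (k > 0) for (j in seq(k, 1)) cs[j] <- -j * cs[j + 1L] / (s - a)
    terms_new(cs, rep(s, k + 1L), seq(0L, k))
  }
}

# Full solution of x' = a x + forcing, x(0) = x0.
lin_solve <- function(a, forcing, x0) {
  parts <- lapply(seq_along(forcing$coef), function(i)
    term_response(forcing$coef[i], forcing$s[i], forcing$k[i], a))
  p <- do.call(terms_bind, parts)
  hom <- terms_new(x0 - terms_eval(p, 0), a, 0L)
  terms_bind(p, hom)
}

# Forcing term decomposition: f(t) = offset + A cos(2 pi (t - phase)/period)
forcing_terms <- function(forcing) {
  if (forcing$type == "constant")
    return(terms_new(forcing$value, 0, 0L))
  if (forcing$type != "sinusoid")
    stop("no closed form for forcing type '", forcing$type, "'")
  w <- 2 * pi / forcing$period
  half <- forcing$amplitude / 2 * exp(complex(imaginary = -w * forcing$phase))
  terms_bind(terms_new(forcing$offset, 0, 0L),
             terms_new(half, complex(imaginary = w), 0L),
             terms_new(Conj(half), complex(imaginary = -w), 0L))
}

# f(t) as an R function (any forcing type; "trace" is linearly interpolated).
forcing_fun <- function(forcing) {
  switch(forcing$type,
         constant = function(t) rep(forcing$value, length(t)),
         sinusoid = function(t)
           forcing$offset + forcing$amplitude *
             cos(2 * pi * (t - forcing$phase) / forcing$period),
         trace = stats::approxfun(forcing$times, forcing$values, rule = 2),
         stop("unknown forcing type '", forcing$type, "'"))
}

#' Specify the primary-TF forcing of the FFL dynamics model
#'
#' @param amplitude,period,phase,offset sinusoid parameters of
#'   `f(t) = offset + amplitude * cos(2*pi*(t - phase)/period)` (period in
#'   minutes, phase the time of peak).
#' @param value constant level for `constant_forcing()`.
#' @param times,values sampled trace for `trace_forcing()` (piecewise-linear
#'   interpolation; numeric integration only).
#' @return A forcing specification list.
#' @export
sinusoid_forcing <- function(amplitude, period, phase = 0, offset = 0) {
  stopifnot(period > 0)
  list(type = "sinusoid", amplitude = amplitude, period = period,
       phase = phase, offset = offset)
}

#' @rdname sinusoid_forcing
#' @export
constant_forcing <- function(value) list(type = "constant", value = value)

#' @rdname sinusoid_forcing
#' @export
trace_forcing <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  list(type = "trace", times = times, values = values)
}

#' Linear ODE model of feed-forward-loop expression dynamics
#'
#' Constructs the two-equation linear model in which the secondary TF `S` is
#' produced in proportion to the primary TF's expression `f(t)` and decays at
#' rate `alpha_S`, while the target `T` is produced in proportion to both
#' `S` and `f(t)` and decays at rate `alpha_T` (rates per minute).
#' Biologically reasonable dynamics have negative decay rates and positive
#' production rates; the constructor imposes no constraints because fitting
#' explores the unconstrained space and reasonableness is judged afterwards
#' by the acceptance filter.
#'
#' @param alpha_S,alpha_T decay rates of secondary TF and target.
#' @param beta_ST production rate of the target driven by the secondary TF.
#' @param beta_PS,beta_PT production rates of secondary TF and target driven
#'   by the primary TF.
#' @param forcing a forcing specification (see [sinusoid_forcing()]).
#' @param S0,T0 initial expression levels.
#' @return Object of class `ffl_ode`.
#' @export
ffl_ode_model <- function(alpha_S, alpha_T, beta_ST, beta_PS, beta_PT,
                          forcing, S0 = 0, T0 = 0) {
  structure(list(alpha_S = alpha_S, alpha_T = alpha_T, beta_ST = beta_ST,
                 beta_PS = beta_PS, beta_PT = beta_PT, forcing = forcing,
                 S0 = S0, T0 = T0),
            class = "ffl_ode")
}

#' @export
print.ffl_ode <- function(x, ...) {
  cat(sprintf(
    "FFL ODE model: alpha_S=%.4g alpha_T=%.4g beta_ST=%.4g beta_PS=%.4g beta_PT=%.4g (forcing: %s)\n",
    x$alpha_S, x$alpha_T, x$beta_ST, x$beta_PS, x$beta_PT, x$forcing$type))
  invisible(x)
}

ffl_solve_closed <- function(model, times) {
  f <- forcing_terms(model$forcing)
  s_terms <- lin_solve(model$alpha_S, terms_scale(f, model$beta_PS),
                       model$S0)
  t_force <- terms_bind(terms_scale(s_terms, model$beta_ST),
                        terms_scale(f, model$beta_PT))
  t_terms <- lin_solve(model$alpha_T, t_force, model$T0)
  cbind(S = terms_eval(s_terms, times), T = terms_eval(t_terms, times))
}

ffl_solve_numeric <- function(model, times) {
  f <- forcing_fun(model$forcing)
  deriv <- function(t, y, parms) {
    list(c(model$alpha_S * y[1] + model$beta_PS * f(t),
           model$beta_ST * y[1] + model$alpha_T * y[2] +
             model$beta_PT * f(t)))
  }
  t0 <- times[1]
  sol <- deSolve::ode(y = c(S = model$S0, T = model$T0),
                      times = if (t0 == 0) times else c(0, times),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  sol <- sol[match(times, sol[, "time"]), , drop = FALSE]
  cbind(S = sol[, "S"], T = sol[, "T"])
}

#' Solve the FFL dynamics model over a time grid
#'
#' Uses the exact closed-form solution (variation of parameters on the
#' linear chain) for constant or sinusoidal forcing, and adaptive numeric
#' integration otherwise; `method` can force either path. Resonant and
#' zero-decay cases are handled by the degenerate closed form with secular
#' polynomial terms.
#'
#' @param model an [ffl_ode_model()].
#' @param times increasing numeric vector (minutes); the initial conditions
#'   refer to t = 0.
#' @param method `"auto"` (default), `"closed"` or `"numeric"`.
#' @return Matrix with columns `S` and `T`, one row per time.
#' @export
ffl_solve <- function(model, times, method = c("auto", "closed", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ffl_ode"))
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  closed_ok <- model$forcing$type %in% c("constant", "sinusoid")
  if (method == "closed" && !closed_ok)
    stop("closed form unavailable for forcing type '", model$forcing$type,
         "'")
  if (method == "numeric" || !closed_ok) ffl_solve_numeric(model, times)
  else ffl_solve_closed(model, times)
}

#' Least-squares sinusoid fit to an expression trace
#'
#' Fits `offset + amplitude * cos(2*pi*(t - phase)/period)` to a trace. For
#' each candidate period the amplitude/phase/offset subproblem is linear and
#' solved exactly; the best candidate on a dense period grid is then polished
#' by Nelder-Mead over all four parameters. Used to represent the primary
#' TF's expression as the forcing function before ODE fitting.
#'
#' @param times,values the trace.
#' @param periods optional candidate period grid (minutes); defaults to a
#'   dense grid spanning one sixth to twice the observed time span.
#' @return A [sinusoid_forcing()] specification with attribute `"sse"`.
#' @export
fit_sinusoid <- function(times, values, periods = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 4L)
  span <- diff(range(times))
  if (is.null(periods))
    periods <- seq(span / 6, 2 * span, length.out = 240)
  best <- NULL; best_sse <- Inf
  for (P in periods) {
    w <- 2 * pi / P
    X <- cbind(1, cos(w * times), sin(w * times))
    fit <- stats::lm.fit(X, values)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(P, fit$coefficients) }
  }
  P <- best[1]; b0 <- best[2]; b1 <- best[3]; b2 <- best[4]
  A <- sqrt(b1^2 + b2^2)
  phase <- atan2(b2, b1) / (2 * pi / P)
  obj <- function(p) {
    pred <- p[4] + p[1] * cos(2 * pi * (times - p[3]) / p[2])
    sum((values - pred)^2)
  }
  polish <- stats::optim(c(A, P, phase, b0), obj, method = "Nelder-Mead",
                         control = list(maxit = 500))
  p <- unname(polish$par)
  out <- sinusoid_forcing(amplitude = abs(p[1]), period = abs(p[2]),
                          phase = if (p[1] < 0)
                            p[3] + abs(p[2]) / 2 else p[3],
                          offset = p[4])
  attr(out, "sse") <- polish$value
  out
}

#' Maximum-likelihood fit of the FFL dynamics model to observed traces
#'
#' Fits the five kinetic parameters (`alpha_S`, `alpha_T`, `beta_ST`,
#' `beta_PS`, `beta_PT`) by Gaussian maximum likelihood with a shared
#' residual standard deviation across the secondary and target traces
#' (equivalent to joint least squares with the noise variance profiled out).
#' The primary TF's trace defines the forcing: by default a sinusoid is
#' least-squares-fitted to it ([fit_sinusoid()]), keeping the closed-form
#' solution available; `forcing = "trace"` interpolates the raw trace
#' instead. Initial expression levels are taken from the first observed time
#' point; optimization is a single deterministic local search (Nelder-Mead
#' followed by a BFGS polish) from one fixed initial parameter vector.
#'
#' An FFL fit is *accepted* when the optimizer converged, the solution moved
#' away from the initial vector (any parameter changed by more than 1e-6
#' relative), both decay rates are negative and all production rates are
#' positive — the filter separating kinetically reasonable fits from
#' degenerate ones.
#'
#' @param primary,secondary,target expression traces aligned to `times`.
#' @param times strictly increasing time grid, at least 8 points.
#' @param init named initial parameter vector (fixed across fits).
#' @param forcing `"sinusoid"` (default) or `"trace"`.
#' @param maxit iteration cap passed to both optimizer stages.
#' @return Object of class `ffl_fit`: fitted `model`, `par`, `logLik`,
#'   `sigma`, `converged`, `moved_from_init`, `accepted`, `fitted` values
#'   and the data. Methods: `print`, `coef`, `logLik`, `fitted`,
#'   `residuals`, `predict`, `simulate`.
#' @export
ffl_fit <- function(primary, secondary, target, times,
                    init = c(alpha_S = -0.1, alpha_T = -0.1,
                             beta_ST = 0.1, beta_PS = 0.1, beta_PT = 0.1),
                    forcing = c("sinusoid", "trace"),
                    maxit = 1000) {
  forcing <- match.arg(forcing)
  stopifnot(length(times) >= 8L, !is.unsorted(times, strictly = TRUE),
            length(primary) == length(times),
            length(secondary) == length(times),
            length(target) == length(times))
  fspec <- if (forcing == "sinusoid") fit_sinusoid(times, primary)
           else trace_forcing(times, primary)
  S0 <- unname(secondary[1]); T0 <- unname(target[1])
  obs <- cbind(S = as.numeric(secondary), T = as.numeric(target))
  objective <- function(par) {
    m <- ffl_ode_model(par[1], par[2], par[3], par[4], par[5], fspec,
                       S0 = S0, T0 = T0)
    pred <- tryCatch(ffl_solve(m, times), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((pred - obs)^2)
  }
  nm <- stats::optim(init, objective, method = "Nelder-Mead",
                     control = list(maxit = maxit))
  fit <- tryCatch(
    stats::optim(nm$par, objective, method = "BFGS",
                 control = list(maxit = maxit)),
    error = function(e) nm)
  if (fit$value > nm$value) fit <- nm
  par <- stats::setNames(fit$par, names(init))
  model <- ffl_ode_model(par[1], par[2], par[3], par[4], par[5], fspec,
                         S0 = S0, T0 = T0)
  pred <- ffl_solve(model, times)
  n_obs <- 2 * length(times)
  sse <- sum((pred - obs)^2)
  sigma2 <- sse / n_obs
  loglik <- if (sigma2 > 0) -n_obs / 2 * (log(2 * pi * sigma2) + 1)
            else Inf
  converged <- fit$convergence == 0
  moved <- any(abs(par - init) > 1e-6 * pmax(1, abs(init)))
  accepted <- converged && moved && par[1] < 0 && par[2] < 0 &&
    all(par[3:5] > 0)
  structure(list(model = model, par = par, init = init,
                 logLik = loglik, sigma = sqrt(sigma2), sse = sse,
                 converged = converged, moved_from_init = moved,
                 accepted = unname(accepted),
                 fitted = pred, times = times, observed = obs,
                 forcing_type = forcing),
            class = "ffl_fit")
}

#' @export
print.ffl_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf(
    "logLik = %.2f, residual sd = %.4g; converged: %s, moved: %s, accepted: %s\n",
    x$logLik, x$sigma, x$converged, x$moved_from_init, x$accepted))
  invisible(x)
}

#' @export
coef.ffl_fit <- function(object, ...) object$par

#' @export
logLik.ffl_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par) + 1, class = "logLik")
}

#' @export
fitted.ffl_fit <- function(object, ...) object$fitted

#' @export
residuals.ffl_fit <- function(object, ...) object$observed - object$fitted

#' @export
predict.ffl_fit <- function(object, times = object$times, ...) {
  ffl_solve(object$model, times)
}

#' @export
simulate.ffl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    object$fitted + stats::rnorm(length(object$fitted), 0, object$sigma))
}

#' Validate a set of FFLs against expression time courses
#'
#' Fits the FFL dynamics model to every triplet and reports the fraction
#' whose fit passes the acceptance filter (negative decay rates, positive
#' production rates, converged, non-initial). Optionally fits a control set
#' of random TF-TF-target triplets (uniform over TFs and profiled genes,
#' excluding real FFL triplets) for comparison: genuinely co-regulated
#' triplets are expected to be accepted more often than random ones.
#'
#' @param ffls FFL data.frame (`primary`, `secondary`, `target`).
#' @param expression numeric matrix, genes x time points, rownames = genes.
#' @param times time grid (minutes) matching the expression columns.
#' @param control_triplets number of random control triplets (0 = none).
#' @param tfs TF pool for control triplets; defaults to the TFs appearing in
#'   `ffls`.
#' @param seed seed for the control draw.
#' @param ... passed to [ffl_fit()].
#' @return List with `n_fit`, `n_skipped`, `n_accepted`,
#'   `fraction_accepted` (NA for an empty FFL list), a per-FFL `results`
#'   data.frame, and (when requested) `control` with the same structure.
#' @export
validate_ffl_set <- function(ffls, expression, times, control_triplets = 0,
                             tfs = NULL, seed = 1, ...) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            ncol(expression) == length(times))
  fit_triplets <- function(trip) {
    rows <- vector("list", nrow(trip))
    n_skipped <- 0L
    for (i in seq_len(nrow(trip))) {
      ids <- c(trip$primary[i], trip$secondary[i], trip$target[i])
      if (!all(ids %in% rownames(expression))) {
        n_skipped <- n_skipped + 1L
        next
      }
      f <- ffl_fit(expression[ids[1], ], expression[ids[2], ],
                   expression[ids[3], ], times, ...)
      rows[[i]] <- data.frame(
        primary = ids[1], secondary = ids[2], target = ids[3],
        t(f$par), logLik = f$logLik, sigma = f$sigma,
        converged = f$converged, moved = f$moved_from_init,
        accepted = f$accepted, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    list(results = res, n_skipped = n_skipped)
  }
  main <- fit_triplets(ffls)
  n_fit <- if (is.null(main$results)) 0L else nrow(main$results)
  out <- list(n_fit = n_fit, n_skipped = main$n_skipped,
              n_accepted = if (n_fit) sum(main$results$accepted) else 0L,
              fraction_accepted = if (n_fit)
                mean(main$results$accepted) else NA_real_,
              results = main$results)
  if (control_triplets > 0) {
    tfs <- tfs %||% unique(c(ffls$primary, ffls$secondary))
    tfs <- intersect(tfs, rownames(expression))
    genes <- rownames(expression)
    if (length(tfs) < 2L) stop("need at least 2 profiled TFs for controls")
    real <- ffl_keys(ffls)
    trip <- with_seed(derive_seed(seed, "control_triplets"), {
      acc <- list()
      while (length(acc) < control_triplets) {
        p <- sample(tfs, 1); s <- sample(setdiff(tfs, p), 1)
        t_ <- sample(setdiff(genes, c(p, s)), 1)
        if (!paste(p, s, t_, sep = "\t") %in% real)
          acc[[length(acc) + 1L]] <- c(p, s, t_)
      }
      as.data.frame(do.call(rbind, acc), stringsAsFactors = FALSE) |>
        stats::setNames(c("primary", "secondary", "target"))
    })
    ctrl <- fit_triplets(trip)
    n_cf <- if (is.null(ctrl$results)) 0L else nrow(ctrl$results)
    out$control <- list(
      n_fit = n_cf, n_skipped = ctrl$n_skipped,
      fraction_accepted = if (n_cf) mean(ctrl$results$accepted)
                          else NA_real_,
      results = ctrl$results)
  }
  out
}
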