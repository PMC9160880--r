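# ---- flux model construction, fitting, and confidence intervals ------------
#
# The flux space is the affine set {v : S v = 0, fixed fluxes} with
# exchange fluxes of reversible reactions as extra free parameters. The
# fit minimizes the (SD-weighted) residual sum of squares between
# measured and simulated fragment MIDs by bounded least squares from
# multiple random starts; goodness of fit is a chi-square test; per-flux
# confidence intervals come from a grid-search (profile) of the RSS.

#' Build a constrained flux model
#'
#' Fixes measured uptake/secretion fluxes and biomass effluxes
#' (precursor demand coefficient x growth rate), then parameterizes the
#' remaining feasible affine space by an orthonormal null-space basis.
#'
#' @param net A `metabolic_network`.
#' @param rates Optional `specific_rates` from [specific_rates()].
#' @param analyte_map Named character vector mapping analyte names of
#'   `rates` to exchange reaction ids, e.g. `c(glucose = "upt")`.
#' @param demand Named numeric vector: biomass-drain reaction id ->
#'   precursor demand coefficient (mmol gDCW^-1); the efflux is fixed at
#'   coefficient x growth rate.
#' @param fixed Additional named fluxes to fix directly.
#' @param exch_ub Upper bound for exchange fluxes (mmol gDCW^-1 h^-1).
#' @return A `flux_model`.
#' @export
build_constraints <- function(net, rates = NULL, analyte_map = NULL,
                              demand = NULL, fixed = NULL, exch_ub = 5) {
  rids <- vapply(net$reactions, `[[`, "", "id")
  constraints <- c()
  if (!is.null(rates)) {
    for (a in names(analyte_map)) {
      if (is.null(rates$analytes[[a]]))
        stop("no measured rate for analyte '", a, "'")
      if (!analyte_map[[a]] %in% rids)
        stop("analyte '", a, "' maps to unknown reaction '", analyte_map[[a]], "'")
      constraints[analyte_map[[a]]] <- rates$analytes[[a]]$rate
    }
    if (!is.null(demand)) {
      if (any(demand < 0)) stop("demand coefficients must be >= 0")
      for (r in names(demand)) {
        if (!r %in% rids) stop("demand names unknown reaction '", r, "'")
        constraints[r] <- demand[[r]] * rates$mu
      }
    }
  }
  if (!is.null(fixed)) constraints[names(fixed)] <- fixed
  sys <- constrained_system(net, constraints)
  rev_ids <- rids[vapply(net$reactions, `[[`, FALSE, "reversible")]
  lb <- vapply(net$reactions, `[[`, 0, "lb")
  ub <- vapply(net$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- rids
  structure(list(net = net, constraints = constraints, sys = sys,
                 rev_ids = rev_ids, lb = lb, ub = ub, exch_ub = exch_ub,
                 n_free = ncol(sys$N) + length(rev_ids)),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("<flux_model> %d reactions, %d fixed, %d free (net %d + exchange %d)\n",
              length(x$sys$reaction_ids), length(x$constraints), x$n_free,
              ncol(x$sys$N), length(x$rev_ids)))
  invisible(x)
}

# free parameters (theta, exch) -> flux vector list(net, exch)
model_fluxes <- function(model, par) {
  nt <- ncol(model$sys$N)
  theta <- par[seq_len(nt)]
  v <- model$sys$v0 + if (nt) drop(model$sys$N %*% theta) else 0
  names(v) <- model$sys$reaction_ids
  ex <- par[nt + seq_along(model$rev_ids)]
  names(ex) <- model$rev_ids
  list(net = v, exch = ex)
}

# project a flux vector back to free parameters (orthonormal N)
model_params <- function(model, fluxes) {
  nt <- ncol(model$sys$N)
  theta <- if (nt) drop(crossprod(model$sys$N, fluxes$net[model$sys$reaction_ids] -
                                    model$sys$v0)) else numeric()
  c(theta, unname(fluxes$exch[model$rev_ids]))
}

# residual closure shared by fitting and profiling; caches the EMU
# decomposition and the measurement layout
make_fit_context <- function(model, measurements, fragments, labeling,
                             weighted = TRUE, penalty = 1e3) {
  frag_ids <- vapply(fragments, `[[`, "", "id")
  names(fragments) <- frag_ids
  measurements <- measurements[intersect(names(measurements), frag_ids)]
  if (!length(measurements)) stop("no measurement matches the fragment library")
  emu_lists <- lapply(fragments[names(measurements)], map_fragment_to_emus,
                      net = model$net)
  emunet <- decompose(model$net, unique(unlist(
    lapply(emu_lists, function(l) vapply(l, `[[`, "", "id")),
    use.names = FALSE)))
  meas_vec <- unlist(lapply(measurements, `[[`, "fractions"), use.names = FALSE)
  sd_vec <- unlist(lapply(measurements, `[[`, "sd"), use.names = FALSE)
  sim_vec <- function(fluxes) {
    mids <- simulate_mids(emunet, fluxes, labeling)
    unlist(lapply(names(measurements), function(f)
      Reduce(convolve_mid, mids[vapply(emu_lists[[f]], `[[`, "", "id")])),
      use.names = FALSE)
  }
  bound_resid <- function(fluxes) {
    v <- fluxes$net
    penalty * c(pmax(model$lb - v, 0), pmax(v - model$ub, 0))
  }
  residuals <- function(par) {
    fluxes <- model_fluxes(model, par)
    # evaluate MIDs with directions forced non-negative for the linear solve
    fl <- fluxes
    irrev <- !(names(fl$net) %in% model$rev_ids)
    fl$net[irrev] <- pmax(fl$net[irrev], 0)
    sim <- tryCatch(sim_vec(fl), error = function(e) NULL)
    if (is.null(sim))
      return(rep(1e3, length(meas_vec) + 2 * length(fluxes$net)))
    r <- if (weighted) (sim - meas_vec) / sd_vec else sim - meas_vec
    c(r, bound_resid(fluxes))
  }
  list(residuals = residuals, sim_vec = sim_vec, meas = meas_vec,
       sd = sd_vec, n_data = length(meas_vec), emunet = emunet,
       measurements = measurements, weighted = weighted)
}

#' Residual sum of squares between measured and simulated MIDs
#'
#' Sum over fragments and mass channels of `((sim - meas) / sd)^2`
#' (SD-weighted, the default) or `(sim - meas)^2` (unweighted).
#'
#' @param model A `flux_model`.
#' @param fluxes Flux vector `list(net =, exch =)`.
#' @param measurements Named list of `measured_mid` (names = fragment
#'   ids).
#' @param fragments Fragment library (list of `fragment_def`).
#' @param labeling Tracer labeling, as in [simulate_mids()].
#' @param weighted Divide residuals by the measurement SD (default TRUE).
#' @return Numeric RSS.
#' @export
objective_rss <- function(model, fluxes, measurements, fragments, labeling,
                          weighted = TRUE) {
  ctx <- make_fit_context(model, measurements, fragments, labeling, weighted)
  sim <- ctx$sim_vec(fluxes)
  r <- if (weighted) (sim - ctx$meas) / ctx$sd else sim - ctx$meas
  sum(r^2)
}

#' Chi-square acceptance threshold for the flux fit
#'
#' The `(1 - alpha)` quantile of the chi-square distribution with
#' `n_data - n_free` degrees of freedom; an SD-weighted RSS at or below
#' this threshold means the model explains the measured MIDs at level
#' `alpha`.
#'
#' @param n_data Number of independent measured mass channels.
#' @param n_free Degrees of freedom of the reaction model.
#' @param alpha Significance level (default 0.05).
#' @return Numeric threshold.
#' @export
chi_square_threshold <- function(n_data, n_free, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  df <- n_data - n_free
  if (df <= 0) stop("n_data must exceed n_free")
  stats::qchisq(1 - alpha, df)
}

#' Fit fluxes to measured MIDs by multistart least squares
#'
#' Bounded Levenberg-Marquardt minimization of the (weighted) residuals
#' over the free net-flux coordinates and exchange fluxes, from
#' `n_starts` random feasible starts; deterministic given `seed`.
#'
#' @inheritParams objective_rss
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed controlling the starts.
#' @param alpha Significance level for the chi-square test.
#' @param init Optional list of parameter vectors used as additional
#'   warm starts.
#' @return A `fit_result`: `fluxes`, `rss`, `n_data`, `n_free`,
#'   `threshold`, `pass`, `start_rss`, `par`, `seed`, `weighted`.
#' @export
fit_fluxes <- function(model, measurements, fragments, labeling,
                       n_starts = 20, seed = 1L, weighted = TRUE,
                       alpha = 0.05, init = NULL) {
  stopifnot(n_starts >= 1)
  ctx <- make_fit_context(model, measurements, fragments, labeling, weighted)
  nt <- ncol(model$sys$N); nx <- length(model$rev_ids)
  lower <- c(rep(-Inf, nt), rep(0, nx))
  upper <- c(rep(Inf, nt), rep(model$exch_ub, nx))
  scale <- max(abs(model$constraints), abs(model$sys$v0), 1)
  starts <- withr::with_seed(seed, c(init, lapply(seq_len(n_starts), function(i)
    c(stats::runif(nt, -scale, scale), stats::runif(nx, 0, model$exch_ub)))))
  best <- NULL; start_rss <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(starts[[i]], lower, upper, ctx$residuals,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, nprint = 0)),
      error = function(e) NULL)
    if (is.null(fit)) { start_rss[i] <- NA; next }
    fl <- model_fluxes(model, fit$par)
    viol <- max(c(pmax(model$lb - fl$net, 0), pmax(fl$net - model$ub, 0)))
    sim <- tryCatch(ctx$sim_vec(fl), error = function(e) NULL)
    if (is.null(sim) || viol > 1e-6 * scale) { start_rss[i] <- NA; next }
    r <- if (weighted) (sim - ctx$meas) / ctx$sd else sim - ctx$meas
    start_rss[i] <- sum(r^2)
    if (is.null(best) || start_rss[i] < best$rss)
      best <- list(par = fit$par, rss = start_rss[i], fluxes = fl)
  }
  if (is.null(best))
    stop("all optimization starts failed or ended infeasible")
  threshold <- chi_square_threshold(ctx$n_data, model$n_free, alpha)
  structure(list(fluxes = best$fluxes, rss = best$rss, par = best$par,
                 n_data = ctx$n_data, n_free = model$n_free,
                 alpha = alpha, threshold = threshold,
                 pass = best$rss <= threshold, start_rss = start_rss,
                 seed = seed, weighted = weighted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> RSS %.3f (%s), %d data, %d free, chi2 threshold %.1f -> %s\n",
              x$rss, if (x$weighted) "SD-weighted" else "unweighted",
              x$n_data, x$n_free, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Chi-square goodness-of-fit report
#'
#' @param fit A `fit_result`.
#' @return List: `rss`, `df`, `threshold`, `pass`, `p_value`.
#' @export
goodness_of_fit <- function(fit) {
  df <- fit$n_data - fit$n_free
  list(rss = fit$rss, df = df, threshold = fit$threshold,
       pass = fit$rss <= fit$threshold,
       p_value = stats::pchisq(fit$rss, df, lower.tail = FALSE))
}

#' Confidence interval from a one-dimensional RSS profile
#'
#' Walks the profile outward from the optimum on a grid, then refines
#' each RSS = RSS_min + delta crossing by bisection. The interval is
#' `{value : RSS(value) <= RSS_min + delta}`; with
#' `delta = qchisq(level, 1)` this is the profile-likelihood CI.
#'
#' @param profile Function: flux value -> profiled RSS.
#' @param center Optimum flux value.
#' @param rss_min RSS at the optimum.
#' @param delta RSS increase defining the interval (3.84 at level 0.95).
#' @param step Initial grid step.
#' @param lower,upper Feasible bounds; an endpoint that reaches a bound
#'   is reported bound-censored.
#' @param tol Absolute bisection tolerance on the endpoint.
#' @param max_steps Maximum grid steps per side.
#' @return List: `lower`, `upper`, `lower_censored`, `upper_censored`.
#' @export
ci_from_profile <- function(profile, center, rss_min, delta, step,
                            lower = -Inf, upper = Inf, tol = 1e-3,
                            max_steps = 200L) {
  target <- rss_min + delta
  scan <- function(dir) {
    x_in <- center; censored <- FALSE; x_out <- NA
    for (k in seq_len(max_steps)) {
      x <- center + dir * k * step
      if (x < lower || x > upper) {
        x <- if (dir < 0) lower else upper
        if (profile(x) <= target) return(list(end = x, censored = TRUE))
        x_out <- x
        break
      }
      if (profile(x) > target) { x_out <- x; break }
      x_in <- x
    }
    if (is.na(x_out)) return(list(end = x_in, censored = TRUE))
    # bisection between inside (<= target) and outside (> target)
    a <- x_in; b <- x_out
    while (abs(b - a) > tol) {
      m <- (a + b) / 2
      if (profile(m) <= target) a <- m else b <- m
    }
    list(end = (a + b) / 2, censored = FALSE)
  }
  lo <- scan(-1); hi <- scan(1)
  list(lower = lo$end, upper = hi$end,
       lower_censored = lo$censored, upper_censored = hi$censored)
}

#' Grid-search (profile-likelihood) confidence interval for one flux
#'
#' Fixes the named net flux on a grid, re-optimizes all remaining free
#' fluxes at each grid point (warm-started from the neighboring
#' solution), and returns the interval where the profiled RSS stays
#' within `qchisq(level, 1)` of the optimum; endpoints are refined by
#' bisection.
#'
#' @inheritParams objective_rss
#' @param fit The best `fit_result` for `model`.
#' @param flux_id Net-flux (reaction) id to profile.
#' @param level Confidence level (default 0.95).
#' @param n_starts Random restarts per grid point in addition to the
#'   warm start.
#' @param tol_rel Endpoint tolerance relative to `max(1, |estimate|)`.
#' @return A `flux_ci`: `flux`, `estimate`, `lower`, `upper`, `level`,
#'   censoring flags.
#' @export
grid_search_ci <- function(model, measurements, fragments, labeling, fit,
                           flux_id, level = 0.95, n_starts = 2,
                           tol_rel = 1e-3, weighted = TRUE) {
  if (!flux_id %in% model$sys$reaction_ids) stop("unknown flux id: ", flux_id)
  if (flux_id %in% names(model$constraints))
    stop("flux '", flux_id, "' is fixed by a constraint")
  delta <- stats::qchisq(level, 1)
  v_star <- fit$fluxes$net[[flux_id]]
  rss_min <- fit$rss
  warm <- new.env(parent = emptyenv())
  warm$fluxes <- fit$fluxes
  profile <- function(val) {
    m2 <- build_constraints(model$net,
                            fixed = c(model$constraints,
                                      stats::setNames(val, flux_id)),
                            exch_ub = model$exch_ub)
    wf <- warm$fluxes; wf$net[[flux_id]] <- val
    f2 <- tryCatch(
      fit_fluxes(m2, measurements, fragments, labeling,
                 n_starts = n_starts, seed = fit$seed + 1L,
                 weighted = weighted,
                 init = list(model_params(m2, wf))),
      error = function(e) NULL)
    if (is.null(f2)) return(Inf)
    warm$fluxes <- f2$fluxes
    f2$rss
  }
  # curvature-based initial step: quadratic approximation of the profile
  d <- max(0.05 * abs(v_star), 0.02)
  curv <- (profile(v_star + d) + profile(v_star - d) - 2 * rss_min) / d^2
  s <- if (is.finite(curv) && curv > 0) sqrt(2 / curv) else max(abs(v_star), 1) / 4
  step <- max(sqrt(delta) * s / 5, 1e-4)
  tol <- tol_rel * max(1, abs(v_star))
  ci <- ci_from_profile(profile, v_star, rss_min, delta, step,
                        lower = model$lb[[flux_id]],
                        upper = model$ub[[flux_id]], tol = tol)
  structure(list(flux = flux_id, estimate = v_star, lower = ci$lower,
                 upper = ci$upper, level = level,
                 lower_censored = ci$lower_censored,
                 upper_censored = ci$upper_censored),
            class = "flux_ci")
}

#' @export
print.flux_ci <- function(x, ...) {
  cat(sprintf("%s = %.3f, %d%% CI [%.3f, %.3f]%s\n", x$flux, x$estimate,
              round(100 * x$level), x$lower, x$upper,
              if (x$lower_censored || x$upper_censored) " (bound-censored)" else ""))
  invisible(x)
}

#' Compare two confidence intervals for the same flux
#'
#' Two strains differ significantly in a flux when their confidence
#' intervals are disjoint; intervals sharing an endpoint are treated as
#' overlapping (closed intervals).
#'
#' @param ci_a,ci_b `flux_ci` objects or numeric `c(lower, upper)`.
#' @return List: `significant` (TRUE iff disjoint), `overlap`.
#' @export
compare_ci <- function(ci_a, ci_b) {
  as_range <- function(x) if (inherits(x, "flux_ci")) c(x$lower, x$upper) else x
  a <- as_range(ci_a); b <- as_range(ci_b)
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  disjoint <- a[2] < b[1] || b[2] < a[1]
  list(significant = disjoint, overlap = !disjoint)
}
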