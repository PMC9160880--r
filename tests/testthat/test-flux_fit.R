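# shared small fixture: one noisy TOY_CMP dataset and its flux model
local({
  sc <- make_scenario("TOY_CMP", "ref", seed = 7)
  dat <- simulate_measurements(sc)
  net <- make_network("TOY_CMP")
  tr <- sc$truth
  model <- build_constraints(net, fixed = c(upt = tr$net[["upt"]],
                                            bio = tr$net[["bio"]],
                                            ovf = tr$net[["ovf"]]))

  test_that("build_constraints fixes measured rates and computes the basis", {
    expect_s3_class(model, "flux_model")
    expect_equal(model$n_free, 2)  # emp/ppp split + iso exchange
    v <- emuflux:::model_fluxes(model, rep(0, model$n_free))
    expect_equal(unname(v$net["upt"]), tr$net[["upt"]])
    # steady state holds everywhere in the parameterization
    S <- stoichiometric_matrix(net)
    expect_lt(max(abs(S %*% emuflux:::model_fluxes(model, c(0.3, 1))$net)), 1e-9)
  })

  test_that("rate-driven constraint building maps analytes to exchange
             reactions and demands to biomass efflux", {
    sc0 <- make_scenario("TOY_CMP", "ref", tc_noise_sd = 0, seed = 2)
    d0 <- simulate_measurements(sc0)
    r <- specific_rates(d0$time_course, consumed = "glucose")
    m <- build_constraints(net, rates = r,
                           analyte_map = c(glucose = "upt", acetate = "ovf"),
                           demand = c(bio = 2.2))
    expect_equal(unname(m$constraints["upt"]), r$analytes$glucose$rate)
    expect_equal(unname(m$constraints["bio"]), 2.2 * r$mu)
    expect_error(build_constraints(net, rates = r,
                                   analyte_map = c(glucose = "nope")),
                 "unknown reaction")
    expect_error(build_constraints(net, rates = r,
                                   analyte_map = c(citrate = "upt")),
                 "no measured rate")
  })

  test_that("infeasible fixed rates violating carbon balance error out", {
    # upt fixed twice inconsistently via chain: emp+ppp+bio must equal upt
    expect_error(build_constraints(net, fixed = c(upt = 1, emp = 5, ppp = 5,
                                                  bio = 5)),
                 "infeasible")
  })

  test_that("the weighted RSS is zero at truth on noiseless data and follows
             its definition channel-wise", {
    sc0 <- make_scenario("TOY_CMP", "ref", mid_sd = 0, seed = 3)
    sc0$mid_sd <- 0
    d0 <- simulate_measurements(sc0)
    # measured_mid stores a floor SD of 1e-6 when the noise SD is 0
    rss0 <- objective_rss(model, list(net = tr$net, exch = tr$exch),
                          d0$mids, d0$fragments, sc0$labeling)
    expect_lt(rss0, 1e-6)

    # perturb one channel of one fragment by exactly 1 SD
    d1 <- d0
    frac <- d1$mids$FragP$fractions
    sdv <- 0.003
    d1$mids$FragP <- measured_mid("FragP", frac + c(sdv, -sdv, 0) * 1,
                                  sd = sdv)
    rss1 <- objective_rss(model, list(net = tr$net, exch = tr$exch),
                          d1$mids, d1$fragments, sc0$labeling)
    expect_equal(rss1, 2, tolerance = 0.05)  # two channels moved 1 SD each
    rss_u <- objective_rss(model, list(net = tr$net, exch = tr$exch),
                           d1$mids, d1$fragments, sc0$labeling,
                           weighted = FALSE)
    expect_equal(rss_u, 2 * sdv^2, tolerance = 0.05 * 2 * sdv^2)
  })

  test_that("multistart fitting recovers the known flux split and is
             reproducible given the seed", {
    fit <- fit_fluxes(model, dat$mids, dat$fragments,
                      make_scenario("TOY_CMP")$labeling,
                      n_starts = 8, seed = 11)
    expect_s3_class(fit, "fit_result")
    expect_lt(abs(fit$fluxes$net[["emp"]] - tr$net[["emp"]]), 0.1)
    expect_true(fit$pass)
    fit2 <- fit_fluxes(model, dat$mids, dat$fragments,
                       make_scenario("TOY_CMP")$labeling,
                       n_starts = 8, seed = 11)
    expect_identical(fit$par, fit2$par)
    expect_identical(fit$rss, fit2$rss)
    # more starts can only improve the best RSS
    fit1 <- fit_fluxes(model, dat$mids, dat$fragments,
                       make_scenario("TOY_CMP")$labeling,
                       n_starts = 1, seed = 11)
    expect_gte(fit1$rss, fit$rss - 1e-9)
  })

  test_that("noiseless parameter recovery is near-exact", {
    sc0 <- make_scenario("TOY_CMP", "ref", mid_sd = 1e-8, seed = 9)
    d0 <- simulate_measurements(sc0)
    fit <- fit_fluxes(model, d0$mids, d0$fragments, sc0$labeling,
                      n_starts = 6, seed = 2)
    expect_lt(abs(fit$fluxes$net[["emp"]] - tr$net[["emp"]]), 1e-3)
    expect_lt(abs(fit$fluxes$exch[["iso"]] - tr$exch[["iso"]]), 0.05)
  })
})

test_that("chi-square threshold matches the reference quantiles and is
           monotone in the data count", {
  expect_equal(round(chi_square_threshold(111, 16), 1), 118.8)
  expect_equal(chi_square_threshold(2, 1), stats::qchisq(0.95, 1),
               tolerance = 1e-12)
  expect_equal(round(chi_square_threshold(2, 1), 2), 3.84)
  th <- vapply(c(50, 100, 200), chi_square_threshold, 0, n_free = 16)
  expect_true(all(diff(th) > 0))
  expect_error(chi_square_threshold(5, 5), "exceed")
})

test_that("goodness of fit passes below and fails above the threshold", {
  mk <- function(rss) structure(list(rss = rss, n_data = 111, n_free = 16,
                                     threshold = chi_square_threshold(111, 16),
                                     weighted = TRUE), class = "fit_result")
  expect_true(goodness_of_fit(mk(65.5))$pass)
  expect_true(goodness_of_fit(mk(87.1))$pass)
  th <- chi_square_threshold(111, 16)
  expect_false(goodness_of_fit(mk(th + 1e-6))$pass)
})

test_that("profile-CI machinery reproduces the Wald interval on a quadratic
           RSS surface", {
  v_star <- 4.2; s <- 0.31; rss_min <- 55
  quad <- function(v) rss_min + ((v - v_star) / s)^2
  ci <- ci_from_profile(quad, v_star, rss_min, delta = stats::qchisq(0.95, 1),
                        step = s / 3, tol = 1e-5)
  expect_equal(ci$lower, v_star - 1.959964 * s, tolerance = 1e-3)
  expect_equal(ci$upper, v_star + 1.959964 * s, tolerance = 1e-3)
  expect_false(ci$lower_censored || ci$upper_censored)
})

test_that("profile CI reports bound censoring on an open-ended surface", {
  flat <- function(v) 10  # never exceeds the threshold
  ci <- ci_from_profile(flat, 1, 10, delta = 3.84, step = 0.5,
                        lower = 0, upper = 5, tol = 1e-4)
  expect_true(ci$lower_censored && ci$upper_censored)
  expect_equal(c(ci$lower, ci$upper), c(0, 5))
})

test_that("grid-search CI covers truth and narrows as noise vanishes", {
  net <- make_network("TOY_CMP")
  tr <- toy_cmp_truth("ref")
  model <- build_constraints(net, fixed = c(upt = tr$net[["upt"]],
                                            bio = tr$net[["bio"]],
                                            ovf = tr$net[["ovf"]]))
  widths <- vapply(c(0.003, 0.0005), function(sdv) {
    sc <- make_scenario("TOY_CMP", "ref", mid_sd = sdv, seed = 21)
    d <- simulate_measurements(sc)
    fit <- fit_fluxes(model, d$mids, d$fragments, sc$labeling,
                      n_starts = 6, seed = 3)
    ci <- grid_search_ci(model, d$mids, d$fragments, sc$labeling, fit, "emp")
    expect_lte(ci$lower, fit$fluxes$net[["emp"]] + 1e-9)
    expect_gte(ci$upper, fit$fluxes$net[["emp"]] - 1e-9)
    ci$upper - ci$lower
  }, 0)
  expect_lt(widths[2], widths[1])
  expect_error(grid_search_ci(model, NULL, NULL, NULL,
                              list(fluxes = NULL), "upt"),
               "fixed by a constraint")
})

test_that("CI comparison follows the non-overlap significance rule", {
  expect_true(compare_ci(c(3.8, 4.5), c(2.3, 3.0))$significant)
  expect_false(compare_ci(c(1, 3), c(2, 4))$significant)
  expect_false(compare_ci(c(1, 2), c(2, 3))$significant)  # closed intervals
})
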