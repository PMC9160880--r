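# ---- synthetic-data generators ---------------------------------------------
#
# Every input the pipeline consumes (labeling experiments, culture time
# courses, expression tables) can be generated from a scenario with known
# ground truth, so each analysis stage is testable end to end. All
# generators are pure functions of (scenario, seed).

#' Built-in atom-mapped network presets
#'
#' `TOY1` is a minimal two-route network (two alternative atom orderings
#' of A -> B feeding a cleavage reaction), the smallest model on which
#' positional labeling distinguishes pathway usage. `TOY_CMP` mimics the
#' branch structure of central carbon metabolism at toy scale: a
#' glycolysis-like route and a PPP-like route that decarboxylate
#' different carbon positions, a reversible isomerase, acetate-like
#' overflow, a biomass drain, and a TCA-like cycle entered through a
#' condensation (convolution) reaction. Its non-substrate metabolites
#' carry 11 carbons in total, so the exhaustive isotopomer oracle applies.
#'
#' @param preset `"TOY1"` or `"TOY_CMP"`.
#' @return A `metabolic_network`.
#' @export
make_network <- function(preset = c("TOY1", "TOY_CMP")) {
  preset <- match.arg(preset)
  text <- switch(preset,
    TOY1 = "
      met Aex 2 substrate
      met A 2 balanced
      met B 2 balanced
      met C 1 sink
      met D 1 sink
      upt: Aex (ab) -> A (ab)
      v1: A (ab) -> B (ab)
      v3: A (ab) -> B (ba)
      v2: B (ab) -> C (a) + D (b)
    ",
    TOY_CMP = "
      # toy central-metabolism analogue: glucose-like 3-carbon substrate
      met Gex 3 substrate
      met G 3 balanced
      met R 2 balanced
      met P 2 balanced
      met O 1 balanced
      met T 3 balanced
      met Ace 2 sink
      met CO2 1 sink
      met Bio 3 sink
      upt: Gex (abc) -> G (abc)
      emp: G (abc) -> P (ab) + CO2 (c)    # glycolysis-like, loses C3
      ppp: G (abc) -> R (bc) + CO2 (a)    # PPP-like, loses C1
      iso: R (ab) <-> P (ab)              # reversible isomerase
      ovf: P (ab) -> Ace (ab)             # acetate overflow
      cs:  P (ab) + O (c) -> T (abc)      # condensation into TCA-like cycle
      tca: T (abc) -> O (a) + CO2 (b) + CO2 (c)
      bio: G (abc) -> Bio (abc)           # biomass drain
    ")
  parse_network(text)
}

#' Default tracer labeling for a network preset
#'
#' TOY1 defaults to 100\% position-1 labeled substrate. TOY_CMP defaults
#' to a mixed tracer (80\% position-1 labeled + 20\% uniformly labeled),
#' a design that separates the decarboxylating branches while keeping
#' higher mass channels informative.
#'
#' @param preset Network preset id.
#' @return Labeling list as consumed by [simulate_mids()].
#' @export
default_labeling <- function(preset = c("TOY1", "TOY_CMP")) {
  preset <- match.arg(preset)
  switch(preset,
    TOY1 = list(Aex = list(list(pattern = "10", fraction = 1))),
    TOY_CMP = list(Gex = list(list(pattern = "100", fraction = 0.8),
                              list(pattern = "111", fraction = 0.2))))
}

#' Ground-truth flux distributions for TOY_CMP
#'
#' Two flux states emulating the study conditions of a genome-reduced
#' reference strain and its regulator-repaired derivative: glucose uptake
#' and acetate overflow taken from the measured specific rates (5.9 vs
#' 6.7 and 2.7 vs 4.4 mmol gDCW^-1 h^-1), biomass drain = demand
#' coefficient x growth rate, and a PPP-like branch flux that decreases
#' between the two states while glycolysis increases.
#'
#' @param strain `"ref"` (reference, MGB874-like rates) or `"abrb"`
#'   (derivative, OA191-like rates).
#' @param demand_coef Biomass precursor demand coefficient
#'   (mmol gDCW^-1) multiplying the growth rate; default 2.2.
#' @return List with `net` (named fluxes), `exch`, `mu`, `nu`, `rho`,
#'   `rho_suc`.
#' @export
toy_cmp_truth <- function(strain = c("ref", "abrb"), demand_coef = 2.2) {
  strain <- match.arg(strain)
  par <- switch(strain,
    ref  = list(mu = 0.46, nu = 5.9, rho = 2.7, rho_suc = 0.2, ppp = 1.5, exch = 0.5),
    abrb = list(mu = 0.51, nu = 6.7, rho = 4.4, rho_suc = 0.2, ppp = 1.0, exch = 0.5))
  bio <- demand_coef * par$mu
  emp <- par$nu - par$ppp - bio
  p_in <- emp + par$ppp
  cs <- p_in - par$rho
  stopifnot(emp > 0, cs > 0)
  list(net = c(upt = par$nu, emp = emp, ppp = par$ppp, iso = par$ppp,
               ovf = par$rho, cs = cs, tca = cs, bio = bio),
       exch = c(iso = par$exch),
       mu = par$mu, nu = par$nu, rho = par$rho, rho_suc = par$rho_suc)
}

#' Define a synthetic scenario
#'
#' Bundles all generator parameters: the network preset, ground-truth
#' fluxes, tracer, MID noise, culture time-course parameters and
#' expression parameters. Defaults reflect the study conditions: growth
#' rate 0.46 h^-1, glucose uptake 5.9, acetate production 2.7, succinate
#' 0.2 mmol gDCW^-1 h^-1 for the reference state; per-channel MID SD
#' 0.003 mass fractions; cultures sampled every 15 min over 6 h starting
#' from 10 g l^-1 glucose (55.5 mmol l^-1).
#'
#' @param preset Network preset id.
#' @param strain `"ref"` or `"abrb"` (TOY_CMP flux states).
#' @param mid_sd Additive Gaussian SD per MID mass channel.
#' @param tc_noise_sd Multiplicative (log-normal) noise SD of the time
#'   course; 0 for noiseless cultures.
#' @param dt Sampling interval of the time course (h).
#' @param t_end Final sampling time (h).
#' @param seed Integer seed; all generated data are pure functions of it.
#' @param expr Expression-generator parameters; see
#'   [simulate_expression()].
#' @return A `flux_scenario` list.
#' @export
make_scenario <- function(preset = "TOY_CMP", strain = "ref",
                          mid_sd = 0.003, tc_noise_sd = 0.02,
                          dt = 0.25, t_end = 6, seed = 1L,
                          expr = list()) {
  truth <- if (preset == "TOY_CMP") toy_cmp_truth(strain)
           else list(net = c(upt = 1, v1 = 0.5, v3 = 0.5, v2 = 1),
                     exch = numeric(),
                     mu = 0.46, nu = 5.9, rho = 2.7, rho_suc = 0.2)
  expr_defaults <- list(n_genes = 2000L, n_rep = 3L, sd = 0.3,
                        base_mean = 8, base_sd = 1.5,
                        shifts = c(AbrB = 1, CMP = -1, amino = -0.5,
                                   purine = -1, pyrimidine = -1),
                        set_sizes = c(AbrB = 150L, CMP = 100L, amino = 60L,
                                      purine = 40L, pyrimidine = 40L),
                        n_dual = 10L)
  expr <- utils::modifyList(expr_defaults, expr)
  structure(list(preset = preset, strain = strain, truth = truth,
                 labeling = default_labeling(preset), mid_sd = mid_sd,
                 tc = list(mu = truth$mu, nu = truth$nu, rho = truth$rho,
                           rho_suc = truth$rho_suc, X0 = 0.05,
                           glc0 = 55.5, dt = dt, t_end = t_end,
                           noise_sd = tc_noise_sd),
                 expr = expr, seed = as.integer(seed)),
            class = "flux_scenario")
}

#' Simulate labeling measurements and a culture time course
#'
#' MIDs are simulated at the ground-truth fluxes for the scenario's
#' fragment set, perturbed with i.i.d. Gaussian noise per mass channel
#' (clipped at 0 and renormalized), and returned with the generating SD
#' as the measurement SD. The culture integrates dX/dt = mu X,
#' d[glc]/dt = -nu X, d[ace]/dt = rho X, d[suc]/dt = rho_suc X exactly on
#' the sampling grid, with multiplicative log-normal noise.
#'
#' @param scenario A `flux_scenario`.
#' @param fragments Fragment definitions (default: the scenario preset's
#'   synthetic library, [toy_fragment_library()]).
#' @return List with `mids` (list of `measured_mid`), `time_course`
#'   (data.frame), `truth`, `fragments`, `scenario`.
#' @export
simulate_measurements <- function(scenario,
                                  fragments = toy_fragment_library(scenario$preset)) {
  stopifnot(inherits(scenario, "flux_scenario"))
  withr::with_seed(scenario$seed, {
    net <- make_network(scenario$preset)
    emus <- unlist(lapply(fragments, function(f)
      vapply(map_fragment_to_emus(f, net), `[[`, "", "id")), use.names = FALSE)
    emunet <- decompose(net, unique(emus))
    sim <- simulate_mids(emunet, scenario$truth, scenario$labeling)
    mids <- lapply(fragments, function(f) {
      ids <- vapply(map_fragment_to_emus(f, net), `[[`, "", "id")
      clean <- Reduce(convolve_mid, sim[ids])
      noisy <- clean + stats::rnorm(length(clean), 0, scenario$mid_sd)
      noisy <- pmax(noisy, 0)
      noisy <- noisy / sum(noisy)
      measured_mid(f$id, noisy, sd = rep(max(scenario$mid_sd, 1e-6),
                                         length(noisy)))
    })
    names(mids) <- vapply(fragments, `[[`, "", "id")
    tc <- scenario$tc
    t <- seq(0, tc$t_end, by = tc$dt)
    X <- tc$X0 * exp(tc$mu * t)
    cum <- tc$X0 / tc$mu * (exp(tc$mu * t) - 1)  # integral of X
    noise <- function(n) if (tc$noise_sd > 0)
      exp(stats::rnorm(n, 0, tc$noise_sd)) else rep(1, n)
    time_course <- data.frame(
      time_h = t,
      biomass = X * noise(length(t)),
      glucose = (tc$glc0 - tc$nu * cum) * noise(length(t)),
      acetate = (tc$rho * cum) * noise(length(t)),
      succinate = (tc$rho_suc * cum) * noise(length(t)))
    list(mids = mids, time_course = time_course, truth = scenario$truth,
         fragments = fragments, scenario = scenario)
  })
}

#' Simulate a gene-expression table with set-level shifts
#'
#' Log-normal signals: per-gene baseline log2 level drawn once, replicate
#' signals with Gaussian log2 noise, and genes of a regulated set shifted
#' by the configured log2 amount in condition B relative to condition A.
#' A block of genes is deliberately assigned to both the AbrB and CMP
#' sets to exercise the dual-membership exclusion rule.
#'
#' @param scenario A `flux_scenario` (uses its `expr` and `seed` fields).
#' @return An `expression_table`; see [expression_table()].
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  p <- scenario$expr
  withr::with_seed(scenario$seed + 1L, {
    n <- p$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    stopifnot(sum(p$set_sizes) + p$n_dual <= n)
    pool <- genes
    sets <- list()
    for (s in names(p$set_sizes)) {
      sets[[s]] <- pool[seq_len(p$set_sizes[[s]])]
      pool <- pool[-seq_len(p$set_sizes[[s]])]
    }
    dual <- pool[seq_len(p$n_dual)]   # members of both AbrB and CMP
    sets$AbrB <- c(sets$AbrB, dual)
    sets$CMP <- c(sets$CMP, dual)
    base <- stats::rnorm(n, p$base_mean, p$base_sd)
    shift <- numeric(n); names(shift) <- genes
    for (s in names(p$shifts))
      shift[sets[[s]]] <- shift[sets[[s]]] + p$shifts[[s]]
    cond <- rep(c("A", "B"), each = p$n_rep)
    samples <- sprintf("%s%d", cond, rep(seq_len(p$n_rep), 2))
    log2sig <- matrix(base, n, length(samples)) +
      outer(shift, as.numeric(cond == "B")) +
      matrix(stats::rnorm(n * length(samples), 0, p$sd), n)
    signals <- 2^log2sig
    dimnames(signals) <- list(genes, samples)
    expression_table(signals, stats::setNames(cond, samples), sets)
  })
}
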