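# ---- exhaustive positional-isotopomer oracle -------------------------------
#
# Independent of the EMU machinery: tracks the full 2^n isotopomer
# distribution of every non-substrate metabolite and solves the
# steady-state balance by fixed-point iteration (production-normalized
# convex update, geometrically convergent for networks with positive
# throughput). Used to verify EMU simulations on small networks.

#' Exact MIDs by exhaustive isotopomer enumeration
#'
#' Computes steady-state positional-isotopomer distributions of every
#' balanced and sink metabolite over all `2^n` labeling states, then
#' marginalizes to the mass isotopomer distributions of the requested
#' EMUs. Intended as a brute-force oracle for [simulate_mids()] on
#' networks whose non-substrate metabolites carry at most `cap` carbons in
#' total.
#'
#' @param net A `metabolic_network`.
#' @param fluxes As in [simulate_mids()].
#' @param labeling As in [simulate_mids()].
#' @param targets List of EMUs ([emu()]) or character EMU ids.
#' @param natural_13c 13C probability for `N` pattern positions.
#' @param cap Maximum total carbon count over non-substrate metabolites.
#' @param tol Convergence tolerance on successive isotopomer changes.
#' @param max_iter Iteration cap.
#' @return Named list of MID vectors, one per target EMU id.
#' @export
enumerate_isotopomers <- function(net, fluxes, labeling, targets,
                                  natural_13c = 0.0107, cap = 12L,
                                  tol = 1e-13, max_iter = 200000L) {
  if (is.character(targets)) targets <- lapply(targets, parse_emu_id)
  targets <- lapply(targets, function(t) emu(t$met, t$idx))
  roles <- stats::setNames(net$metabolites$role, net$metabolites$id)
  ncarb <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  unknown <- net$metabolites$id[net$metabolites$role != "substrate" &
                                  net$metabolites$n_carbons > 0L]
  bal <- net$metabolites$id[net$metabolites$role == "balanced"]
  if (sum(ncarb[bal]) > cap)
    stop("network exceeds the isotopomer enumeration cap of ", cap,
         " balanced carbons")

  # fixed input distributions over 2^n states (bit i-1 <=> carbon i labeled)
  state_dist_from_labeling <- function(met) {
    n <- ncarb[[met]]
    comp <- labeling[[met]]
    if (is.null(comp)) stop("no labeling specified for substrate ", met)
    d <- numeric(2^n)
    for (c in comp) {
      p <- pattern_probs(c$pattern, natural_13c)
      d2 <- numeric(2^n)  # bit i-1 set <=> carbon i labeled
      for (s in 0:(2^n - 1)) {
        pr <- c$fraction
        for (i in seq_len(n))
          pr <- pr * if (bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L) p[i] else 1 - p[i]
        d2[s + 1L] <- pr
      }
      d <- d + d2
    }
    d
  }
  dists <- list()
  for (m in net$metabolites$id[net$metabolites$role == "substrate"])
    if (ncarb[[m]] > 0L) dists[[m]] <- state_dist_from_labeling(m)
  for (m in unknown) {
    dists[[m]] <- numeric(2^ncarb[[m]]); dists[[m]][1L] <- 1
  }

  directed <- directed_reactions(net)
  v <- directed_flux_values(directed, fluxes)

  # precompute, per (directed reaction, product instance of an unknown
  # metabolite): for each substrate instance, the product-state bits
  # contributed by each of its 2^n_si states
  terms <- list()
  for (k in seq_along(directed)) {
    dr <- directed[[k]]
    if (v[k] <= 0) next
    sub_maps <- lapply(dr$substrates, function(t) strsplit(t$map, "")[[1]])
    for (pi in seq_along(dr$products)) {
      met <- dr$products[[pi]]$met
      if (!met %in% unknown) next
      pmap <- strsplit(dr$products[[pi]]$map, "")[[1]]
      contrib <- list()
      for (si in seq_along(dr$substrates)) {
        smap <- sub_maps[[si]]
        # product bit contributed by each substrate position (0 = none)
        pbit_of_spos <- integer(length(smap))
        for (sp in seq_along(smap)) {
          j <- match(smap[sp], pmap)
          if (!is.na(j)) pbit_of_spos[sp] <- bitwShiftL(1L, j - 1L)
        }
        ns <- length(smap)
        pbits <- integer(2^ns)
        for (s in 0:(2^ns - 1)) {
          b <- 0L
          for (sp in seq_len(ns))
            if (bitwAnd(s, bitwShiftL(1L, sp - 1L)) > 0L)
              b <- bitwOr(b, pbit_of_spos[sp])
          pbits[s + 1L] <- b
        }
        contrib[[si]] <- list(met = dr$substrates[[si]]$met, pbits = pbits)
      }
      terms[[length(terms) + 1L]] <- list(met = met, flux = v[k],
                                          np = length(pmap), contrib = contrib)
    }
  }
  prod_flux <- stats::setNames(numeric(length(unknown)), unknown)
  for (t in terms) prod_flux[t$met] <- prod_flux[t$met] + t$flux
  if (any(prod_flux <= 0))
    stop("degenerate flux distribution: zero production for ",
         paste(unknown[prod_flux <= 0], collapse = ", "))

  term_dist <- function(t) {
    # fold substrate instances into the product-state distribution one at a
    # time; substrates map to disjoint product bits, unmapped substrate
    # carbons marginalize out automatically
    acc <- numeric(2^t$np); acc[1L] <- 1
    for (co in t$contrib) {
      d <- dists[[co$met]]
      nxt <- numeric(2^t$np)
      nz <- which(acc != 0)
      for (a in nz) {
        pa <- acc[a]
        idx <- (a - 1L) + co$pbits + 1L
        for (s in seq_along(co$pbits))
          nxt[idx[s]] <- nxt[idx[s]] + pa * d[s]
      }
      acc <- nxt
    }
    acc
  }

  for (iter in seq_len(max_iter)) {
    produced <- lapply(stats::setNames(unknown, unknown),
                       function(m) numeric(2^ncarb[[m]]))
    for (t in terms)
      produced[[t$met]] <- produced[[t$met]] + t$flux * term_dist(t)
    delta <- 0
    for (m in unknown) {
      newd <- produced[[m]] / prod_flux[m]
      delta <- max(delta, max(abs(newd - dists[[m]])))
      dists[[m]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("isotopomer fixed point not fully converged (delta = ",
            format(delta), ")")

  out <- list()
  for (t in targets) {
    d <- dists[[t$met]]
    if (is.null(d)) stop("no distribution for metabolite ", t$met)
    n <- ncarb[[t$met]]
    mid <- numeric(t$size + 1L)
    for (s in 0:(2^n - 1)) {
      mass <- sum(vapply(t$idx, function(i)
        bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L, FALSE))
      mid[mass + 1L] <- mid[mass + 1L] + d[s + 1L]
    }
    out[[t$id]] <- mid
  }
  out
}
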