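# shared fixtures built in code

toy1_fluxes <- function(v1 = 0.5, v3 = 0.5) {
  list(net = c(upt = v1 + v3, v1 = v1, v3 = v3, v2 = v1 + v3),
       exch = numeric())
}

toy1_labeling <- function() list(Aex = list(list(pattern = "10", fraction = 1)))

# random feasible flux vector for TOY_CMP: positive branch splits around
# the ground-truth scale
random_toy_cmp_fluxes <- function() {
  upt <- stats::runif(1, 3, 8)
  bio <- stats::runif(1, 0.3, 0.25 * upt)
  ppp <- stats::runif(1, 0.2, 0.35 * (upt - bio))
  emp <- upt - bio - ppp
  ovf <- stats::runif(1, 0.1, 0.8 * (emp + ppp))
  cs <- emp + ppp - ovf
  list(net = c(upt = upt, emp = emp, ppp = ppp, iso = ppp, ovf = ovf,
               cs = cs, tca = cs, bio = bio),
       exch = c(iso = stats::runif(1, 0, 2)))
}

random_labeling <- function() {
  f <- stats::runif(1, 0.2, 0.9)
  g <- stats::runif(1, 0, 1 - f)
  list(Gex = list(list(pattern = "100", fraction = f),
                  list(pattern = "111", fraction = g),
                  list(pattern = "0N0", fraction = 1 - f - g)))
}

# independent brute-force one-sided Mann-Whitney p-value: rank-sum over
# all reassignments (midranks handle ties); distinct from the package's
# pair-counting enumeration
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_along(b) + length(a)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  mean(Us >= U_obs - 1e-9)
}
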