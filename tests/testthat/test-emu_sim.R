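test_that("TOY1 decomposition traces the two alternative atom routes", {
  net <- make_network("TOY1")
  em <- decompose(net, "C[1]")
  expect_setequal(names(em$emus),
                  c("C[1]", "B[1]", "A[1]", "A[2]", "Aex[1]", "Aex[2]"))
  b1 <- em$emus[["B[1]"]]
  expect_setequal(vapply(b1$terms, function(t) t$sources, ""),
                  c("A[1]", "A[2]"))
})

test_that("a linear identity chain needs no convolutions; condensation makes one", {
  chain <- parse_network("
    met A 2 substrate
    met B 2 balanced
    met C 2 balanced
    met X 2 sink
    r1: A (ab) -> B (ab)
    r2: B (ab) -> C (ab)
    rx: C (ab) -> X (ab)
  ")
  em <- decompose(chain, "C[1,2]")
  expect_true(all(vapply(unlist(lapply(em$emus, `[[`, "terms"),
                                recursive = FALSE),
                         function(t) length(t$sources) == 1L, TRUE)))

  cond <- parse_network("
    met B 2 substrate
    met C 1 substrate
    met D 3 balanced
    met X 3 sink
    r: B (ab) + C (c) -> D (abc)
    rx: D (abc) -> X (abc)
  ")
  emc <- decompose(cond, "D[1,2,3]")
  conv <- Filter(function(t) length(t$sources) == 2L,
                 emc$emus[["D[1,2,3]"]]$terms)
  expect_length(conv, 1)
  expect_setequal(conv[[1]]$sources, c("B[1,2]", "C[1]"))
})

test_that("unreachable target EMUs raise a connectivity error", {
  net <- parse_network("
    met A 1 substrate
    met B 1 balanced
    met Z 1 balanced
    met X 1 sink
    r1: A (a) -> B (a)
    r2: B (a) -> X (a)
  ")
  expect_error(decompose(net, "Z[1]"), "unreachable|produces")
})

test_that("TOY1 MIDs match hand-derived label splits", {
  net <- make_network("TOY1")
  em <- decompose(net, "C[1]")
  lab <- toy1_labeling()
  expect_equal(simulate_mids(em, toy1_fluxes(0.5, 0.5), lab)[["C[1]"]],
               c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(simulate_mids(em, toy1_fluxes(1, 0), lab)[["C[1]"]],
               c(0, 1), tolerance = 1e-12)
  # unlabeled input: all mass in M+0
  un <- list(Aex = list(list(pattern = "00", fraction = 1)))
  em2 <- decompose(net, c("C[1]", "B[1,2]"))
  s <- simulate_mids(em2, toy1_fluxes(0.3, 0.7), un)
  expect_equal(s[["C[1]"]], c(1, 0))
  expect_equal(s[["B[1,2]"]], c(1, 0, 0))
})

test_that("zero production through a dead branch names the degenerate EMU", {
  net <- parse_network("
    met A 1 substrate
    met B 1 balanced
    met X 1 sink
    r1: A (a) -> B (a)
    r2: B (a) -> X (a)
  ")
  em <- decompose(net, "X[1]")
  expect_error(simulate_mids(em, list(net = c(r1 = 0, r2 = 0), exch = numeric()),
                             list(A = list(list(pattern = "1", fraction = 1)))),
               "zero total production")
})

test_that("convolution preserves mass, commutes and associates", {
  expect_equal(convolve_mid(c(1, 0), c(1, 0)), c(1, 0, 0))
  expect_equal(convolve_mid(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  set.seed(11)
  for (i in 1:20) {
    a <- stats::runif(sample(2:5, 1)); a <- a / sum(a)
    b <- stats::runif(sample(2:5, 1)); b <- b / sum(b)
    c <- stats::runif(sample(2:5, 1)); c <- c / sum(c)
    expect_equal(sum(convolve_mid(a, b)), 1, tolerance = 1e-12)
    expect_equal(convolve_mid(a, b), convolve_mid(b, a), tolerance = 1e-12)
    expect_equal(convolve_mid(convolve_mid(a, b), c),
                 convolve_mid(a, convolve_mid(b, c)), tolerance = 1e-12)
  }
})

test_that("EMU simulation equals exhaustive isotopomer enumeration on random
           draws (TOY1 and TOY_CMP)", {
  set.seed(101)
  net1 <- make_network("TOY1")
  em1 <- decompose(net1, c("C[1]", "B[1,2]", "D[1]"))
  for (i in 1:15) {
    fl <- toy1_fluxes(stats::runif(1, 0.05, 2), stats::runif(1, 0.05, 2))
    f <- stats::runif(1)
    lab <- list(Aex = list(list(pattern = "10", fraction = f),
                           list(pattern = "NN", fraction = 1 - f)))
    s <- simulate_mids(em1, fl, lab)
    o <- enumerate_isotopomers(net1, fl, lab, c("C[1]", "B[1,2]", "D[1]"))
    for (id in names(o)) expect_lt(max(abs(s[[id]] - o[[id]])), 1e-9)
  }
  net2 <- make_network("TOY_CMP")
  targets <- c("P[1,2]", "G[1,2,3]", "R[1,2]", "T[1,2,3]", "T[2,3]", "Ace[1,2]")
  em2 <- decompose(net2, targets)
  for (i in 1:15) {
    fl <- random_toy_cmp_fluxes()
    lab <- random_labeling()
    s <- simulate_mids(em2, fl, lab)
    o <- enumerate_isotopomers(net2, fl, lab, targets)
    for (id in targets) expect_lt(max(abs(s[[id]] - o[[id]])), 1e-9)
  }
})

test_that("simulated MIDs are stochastic vectors and scale-invariant in flux", {
  set.seed(7)
  net <- make_network("TOY_CMP")
  targets <- c("P[1,2]", "T[1,2,3]", "G[1,2,3]")
  em <- decompose(net, targets)
  for (i in 1:10) {
    fl <- random_toy_cmp_fluxes()
    lab <- random_labeling()
    s <- simulate_mids(em, fl, lab)
    for (id in targets) {
      expect_true(all(s[[id]] >= -1e-9))
      expect_equal(sum(s[[id]]), 1, tolerance = 1e-9)
    }
    k <- stats::runif(1, 0.1, 10)
    fl2 <- list(net = fl$net * k, exch = fl$exch * k)
    s2 <- simulate_mids(em, fl2, lab)
    for (id in targets) expect_equal(s2[[id]], s[[id]], tolerance = 1e-9)
  }
})

test_that("reversible exchange mixes label against the net direction", {
  # with net iso flux R -> P, exchange carries P label back into R
  net <- make_network("TOY_CMP")
  em <- decompose(net, "R[1,2]")
  lab <- default_labeling("TOY_CMP")
  base <- random_toy_cmp_fluxes()
  noex <- base; noex$exch["iso"] <- 0
  hiex <- base; hiex$exch["iso"] <- 50
  s0 <- simulate_mids(em, noex, lab)[["R[1,2]"]]
  s1 <- simulate_mids(em, hiex, lab)[["R[1,2]"]]
  em_p <- decompose(net, "P[1,2]")
  p1 <- simulate_mids(em_p, hiex, lab)[["P[1,2]"]]
  # at infinite exchange R and P MIDs converge
  expect_lt(max(abs(s1 - p1)), 0.05)
  expect_gt(max(abs(s1 - s0)), 1e-3)
})

test_that("labeling input validation rejects malformed mixtures", {
  net <- make_network("TOY1")
  em <- decompose(net, "C[1]")
  expect_error(simulate_mids(em, toy1_fluxes(),
                             list(Aex = list(list(pattern = "10", fraction = 0.7)))),
               "sum to 1")
  expect_error(simulate_mids(em, toy1_fluxes(),
                             list(Aex = list(list(pattern = "1x", fraction = 1)))),
               "0, 1, N")
})
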