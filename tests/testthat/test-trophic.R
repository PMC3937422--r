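test_that("trophic positions solve hand-checkable diets", {
  # pure consumer of a producer sits at 2
  net <- make_net(c("P->H" = 1), imports = c(P = 1), respiration = c(H = 1))
  expect_equal(trophic_positions(net)$tp[["H"]], 2)
  # 50% producer, 50% herbivore -> 2.5
  net <- make_net(c("P->H" = 2, "P->O" = 1, "H->O" = 1),
                  imports = c(P = 3), respiration = c(H = 1, O = 2))
  tp <- trophic_positions(net)$tp
  expect_equal(tp[["O"]], 2.5)
  # cannibal: x = 1 + 0.5 * 1 + 0.5 * x  ->  x = 3
  net <- make_net(c("P->C" = 1, "C->C" = 1),
                  imports = c(P = 1), exports = c(C = 1))
  expect_equal(trophic_positions(net)$tp[["C"]], 3)
})

test_that("fractional level weights sum to 1 and reproduce TP", {
  net <- generate_balanced_network(cfg = scenario_config(seed = 2),
                                   phase = 5)
  dec <- trophic_positions(net)
  sums <- rowSums(dec$levels)
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-9)
  k <- as.numeric(colnames(dec$levels))
  expect_equal(as.vector(dec$levels %*% k), unname(dec$tp),
               tolerance = 1e-9)
  expect_true(all(dec$tp[setdiff(net$nodes, "PDOM")] >= 1))
})

test_that("linear solve agrees with the walk-expansion oracle", {
  set.seed(99)
  for (rep in 1:12) {
    # random acyclic-ish web with a basal producer and possible self-loop
    n <- sample(3:6, 1)
    nodes <- LETTERS[1:n]
    Tm <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (j in 2:n) {
      prey <- sample(seq_len(j - 1), sample(seq_len(j - 1), 1))
      Tm[prey, j] <- stats::runif(length(prey), 0.5, 2)
    }
    if (stats::runif(1) < 0.5) Tm[n, n] <- 0.3   # cannibal loop
    net <- flow_network(Tm, imports = c(stats::setNames(1, "A")),
                        exports = stats::setNames(rep(1, n), nodes))
    basal <- c(A = 1)
    got <- trophic_positions(net, basal = basal)$tp
    want <- oracle_tp(net, basal, cut = 1e-14)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("consumers without ingestion or basal path are errors", {
  net <- make_net(c("P->H" = 1), nodes = c("P", "H", "X"),
                  imports = c(P = 1), respiration = c(H = 1))
  expect_error(trophic_positions(net, basal = c(P = 1)),
               "zero total ingestion")
})

test_that("trophic pyramids conserve the distributed quantity", {
  # chain producer -> herbivore -> carnivore, biomasses (3, 2, 1)
  net <- make_net(c("P->H" = 2, "H->C" = 1),
                  imports = c(P = 2), respiration = c(H = 1, C = 1))
  pyr <- trophic_pyramid(net, c(P = 3, H = 2, C = 1))
  expect_equal(pyr[["1"]], 3); expect_equal(pyr[["2"]], 2)
  expect_equal(pyr[["3"]], 1)
  # omnivore 50/50 on levels 1 and 2 contributes half to levels 2 and 3
  net <- make_net(c("P->H" = 2, "P->O" = 1, "H->O" = 1),
                  imports = c(P = 3), respiration = c(H = 1, O = 2))
  pyr <- trophic_pyramid(net, c(P = 0, H = 0, O = 4))
  expect_equal(pyr[["2"]], 2); expect_equal(pyr[["3"]], 2)
  # conservation on a full synthetic web
  net <- generate_balanced_network(cfg = scenario_config(seed = 5),
                                   phase = 3)
  q <- stats::setNames(stats::runif(9, 1, 10), net$nodes)
  pyr <- trophic_pyramid(net, q)
  expect_equal(sum(pyr), sum(q), tolerance = 1e-9)
})

test_that("transfer efficiency from production ratios", {
  expect_equal(transfer_efficiency_production(c(`1` = 100, `2` = 30,
                                                `3` = 9)), 0.3)
  expect_equal(transfer_efficiency_production(c(`1` = 5, `2` = 5,
                                                `3` = 5)), 1)
  # geometric vs arithmetic mean differ when ratios differ
  p <- c(`1` = 100, `2` = 50, `3` = 5)
  expect_equal(transfer_efficiency_production(p), sqrt(0.05))
  expect_equal(transfer_efficiency_production(p, type = "arithmetic"),
               0.3)
  expect_error(transfer_efficiency_production(c(`1` = 1, `2` = 0,
                                                `3` = 1)), "zero")
})

test_that("transfer efficiency from the size spectrum", {
  expect_equal(transfer_efficiency_from_spectrum(-1, 1e4, A = 0.25), 0.1)
  expect_equal(transfer_efficiency_from_spectrum(-1, 1e4, A = 0), 1)
  # monotone in the slope at fixed PPMR
  te <- sapply(c(-1.4, -1.2, -1, -0.8), transfer_efficiency_from_spectrum,
               ppmr = 1e4)
  expect_true(all(diff(te) > 0))
  expect_error(transfer_efficiency_from_spectrum(-1, 0.5), "PPMR")
  # consistency: production ratios of a community built to satisfy
  # B_{k+1}/B_k = TE * PPMR^A reproduce the spectrum-based estimate
  TE <- 0.25; ppmr <- 2^10; A <- 0.25
  sss <- log2(TE * ppmr^A) / log2(ppmr) - 1   # inverse of the relation
  expect_equal(transfer_efficiency_from_spectrum(sss, ppmr, A), TE,
               tolerance = 1e-12)
  # community built to satisfy B_{k+1}/B_k = TE * PPMR^A (trophic levels
  # one PPMR apart on the size axis): the measured spectrum slope yields
  # the same TE as the production ratios
  cls <- log2(ppmr) * (0:3)
  B <- 100 * (TE * ppmr^A)^(0:3)
  slope <- size_spectrum_slope(data.frame(size_class = cls, biomass = B))
  expect_equal(transfer_efficiency_from_spectrum(slope, ppmr, A), TE,
               tolerance = 1e-9)
  prod <- stats::setNames(100 * TE^(0:2), c("1", "2", "3"))
  expect_equal(transfer_efficiency_production(prod), TE)
})

test_that("weighted PPMR is a weighted geometric mean", {
  w <- lc_ppmr_weights()
  expect_equal(weighted_ppmr(rep(100, 4), w), 100)
  expect_equal(weighted_ppmr(c(1e2, 1e2, 1e4, 1e4), w), 10^3.6)
  expect_error(weighted_ppmr(c(1, 1, 1, 1), c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
})

test_that("size spectrum slope closed forms", {
  cls <- 0:5
  expect_equal(size_spectrum_slope(data.frame(size_class = cls,
                                              biomass = rep(4, 6))), -1)
  expect_equal(size_spectrum_slope(data.frame(size_class = cls,
                                              biomass = 2^cls)), 0)
  expect_equal(size_spectrum_slope(data.frame(size_class = cls,
                                              biomass = 2^(2 * cls))), 1)
  expect_error(size_spectrum_slope(data.frame(size_class = 1,
                                              biomass = 5)), "at least 2")
})

test_that("metabolic activity and allometric exponent recovery", {
  ma <- metabolic_activity(c(a = 10, b = 2), c(a = 20, b = 20))
  expect_equal(ma$PB_tot, 0.3)
  expect_equal(unname(ma$PB), c(0.5, 0.1))
  expect_equal(metabolic_activity(c(x = 4), c(x = 4))$PB_tot, 1)
  M <- 2^(1:8)
  expect_equal(allometric_exponent(3 * M^(-0.25), M), -0.25)
})

test_that("system residence time is stock over outflow", {
  net <- make_net(c("A->B" = 20), imports = c(A = 20),
                  exports = c(B = 12), respiration = c(B = 8))
  expect_equal(system_residence_time(net, c(A = 60, B = 40)), 5)
  # linear in the stock
  expect_equal(system_residence_time(net, 2 * c(A = 60, B = 40)), 10)
  none <- make_net(c("A->B" = 1), imports = c(A = 1))
  expect_error(system_residence_time(none, c(A = 1)), "outflow")
})

test_that("diet composition fractions by resource class", {
  net <- make_net(c("Alg->Z" = 9, "Bac->Z" = 1),
                  imports = c(Alg = 9, Bac = 1), respiration = c(Z = 10))
  cls <- c(Alg = "autotroph", Bac = "bacterial", Z = "animal")
  dc <- diet_composition(net, cls)
  expect_equal(dc["Z", "autotroph"], 0.9)
  expect_equal(dc["Z", "bacterial"], 0.1)
  expect_equal(sum(dc["Z", ]), 1)
  expect_equal(sum(dc["pooled", ]), 1)
})

test_that("diet stoichiometry pools flows, not ratios", {
  # two prey with C:P 50 and 150, equal C-flows -> pooled C:P 75
  netC <- make_net(c("A->Z" = 100, "B->Z" = 100),
                   imports = c(A = 100, B = 100), respiration = c(Z = 200))
  netP <- make_net(c("A->Z" = 2, "B->Z" = 2 / 3),
                   imports = c(A = 2, B = 2 / 3),
                   exports = c(Z = 2 + 2 / 3), element = "P")
  cp <- diet_stoichiometry(netC, netP)
  expect_equal(cp[["Z"]], 75)
  # doubling all C flows doubles the ratio
  netC2 <- make_net(c("A->Z" = 200, "B->Z" = 200),
                    imports = c(A = 200, B = 200),
                    respiration = c(Z = 400))
  expect_equal(diet_stoichiometry(netC2, netP)[["Z"]], 150)
  # topology mismatch is an error
  netP2 <- make_net(c("A->Z" = 2), nodes = c("A", "B", "Z"),
                    imports = c(A = 2), exports = c(Z = 2), element = "P")
  expect_error(diet_stoichiometry(netC, netP2), "topology mismatch")
})
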