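test_that("flow information on hand-evaluable webs", {
  single <- make_net(c("A->B" = 1), imports = c(A = 1),
                     respiration = c(B = 1))
  fi <- flow_information(single)
  expect_equal(fi$H_flow, 0); expect_equal(fi$AMI, 0)
  expect_equal(fi$Phi, 0)

  fan <- fan_net()
  fi <- flow_information(fan)
  expect_equal(fi$H_flow, 1); expect_equal(fi$AMI, 0)
  expect_equal(fi$Phi, 1)

  fi <- flow_information(chain_net())
  expect_equal(fi$H_flow, 1); expect_equal(fi$AMI, 1)
  expect_equal(fi$Phi, 0)
})

test_that("weighted connectance reduces to binary link density on
           uniform regular webs", {
  single <- make_net(c("A->B" = 1), imports = c(A = 1),
                     respiration = c(B = 1))
  wc <- weighted_connectance(single)
  expect_equal(wc$Conn_w, 1); expect_equal(wc$C_w, 0.5)

  wc <- weighted_connectance(fan_net())
  expect_equal(wc$Conn_w, sqrt(2))
  expect_equal(wc$C_w, sqrt(2) / 3)

  # uniform flows on a k-regular directed graph: Conn_w = k = L/S
  for (k in 1:3) {
    n <- 5
    nodes <- LETTERS[1:n]
    Tm <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (i in seq_len(n)) for (s in seq_len(k))
      Tm[i, ((i + s - 1) %% n) + 1] <- 2.5
    net <- flow_network(Tm)
    wc <- weighted_connectance(net)
    expect_equal(wc$Conn_w, k, tolerance = 1e-12)
    expect_equal(wc$C_w, k / n, tolerance = 1e-12)
  }
})

test_that("ascendency identities hold on any generated network", {
  for (s in c(2, 17)) {
    for (p in c(2, 4, 6)) {
      net <- generate_balanced_network(cfg = scenario_config(seed = s),
                                       phase = p)
      a <- ascendency_suite(net)
      expect_equal(a$Asc, a$TST * a$AMI, tolerance = 1e-12)
      expect_equal(a$K_dev, a$TST * a$H_flow, tolerance = 1e-12)
      expect_equal(a$L_over, a$K_dev - a$Asc, tolerance = 1e-9)
      expect_equal(a$Asc_rel, a$AMI / a$H_flow, tolerance = 1e-12)
      expect_gte(a$AMI, 0); expect_lte(a$AMI, a$H_flow)
      expect_gte(a$Asc_rel, 0); expect_lte(a$Asc_rel, 1)
    }
  }
})

test_that("chain and fan ascendency boundary cases", {
  a <- ascendency_suite(chain_net(), selection = "trophic_detrital")
  expect_equal(a$Asc, 2); expect_equal(a$K_dev, 2)
  expect_equal(a$Asc_rel, 1); expect_equal(a$F, 0)
  a <- ascendency_suite(fan_net(), selection = "trophic_detrital")
  expect_equal(a$Asc, 0); expect_equal(a$Asc_rel, 0)
  expect_equal(a$F, 0)
})

test_that("fitness F = -x log x peaks at 1/e", {
  x <- seq(0.001, 0.999, by = 1e-4)
  F <- -x * log(x)
  expect_equal(x[which.max(F)], exp(-1), tolerance = 1e-3)
})

test_that("scale invariance under global flow rescaling", {
  net <- generate_balanced_network(cfg = scenario_config(seed = 8),
                                   phase = 5)
  scaled <- flow_network(net$T * 37, imports = net$imports * 37,
                         exports = net$exports * 37,
                         respiration = net$respiration * 37,
                         element = "C", phase = net$phase)
  a1 <- ascendency_suite(net); a2 <- ascendency_suite(scaled)
  expect_equal(a2$H_flow, a1$H_flow, tolerance = 1e-12)
  expect_equal(a2$AMI, a1$AMI, tolerance = 1e-12)
  expect_equal(a2$C_w, a1$C_w, tolerance = 1e-12)
  expect_equal(a2$Asc_rel, a1$Asc_rel, tolerance = 1e-12)
  expect_equal(a2$Asc, 37 * a1$Asc, tolerance = 1e-9)
  expect_equal(a2$K_dev, 37 * a1$K_dev, tolerance = 1e-9)
  p1 <- weighted_path_length(net); p2 <- weighted_path_length(scaled)
  expect_equal(p2$D, p1$D)
  q1 <- weighted_clustering(net); q2 <- weighted_clustering(scaled)
  expect_equal(q2$Q, q1$Q, tolerance = 1e-12)
})

test_that("weighted path length on simple topologies", {
  # complete uniform graph: D = 1
  nodes <- LETTERS[1:4]
  Tm <- matrix(1, 4, 4, dimnames = list(nodes, nodes)); diag(Tm) <- 0
  expect_equal(weighted_path_length(flow_network(Tm))$D, 1)
  # 3-node path A-B-C: distances 1, 1, 2 -> D = 4/3; too sparse for the
  # random-graph normalization
  path <- make_net(c("A->B" = 1, "B->C" = 1))
  expect_warning(wp <- weighted_path_length(path), "undefined")
  expect_equal(wp$D, 4 / 3)
  expect_equal(wp$d["A", "C"], 2)
  expect_true(is.na(wp$D_norm))
})

test_that("path selection agrees with exhaustive enumeration on small
           webs", {
  set.seed(7)
  for (rep in 1:20) {
    net <- random_small_net(sample(3:5, 1), p_link = 0.5)
    sw <- planksucc:::.symmetric_web(net)
    if (nrow(sw$W) < 2 || sw$L / sw$S <= 1) next
    f <- planksucc:::.relative_strengths(sw$W)
    wp <- suppressWarnings(weighted_path_length(net))
    n <- nrow(sw$W)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      o <- oracle_paths(sw$W, f, i, j)
      if (is.infinite(o$d)) {
        expect_true(is.infinite(wp$d[i, j]))
      } else {
        expect_equal(unname(wp$d[i, j]), o$d)
        expect_equal(unname(wp$score[i, j]), o$score, tolerance = 1e-9)
      }
    }
  }
})

test_that("weighted clustering closed forms and oracle agreement", {
  tri <- make_net(c("A->B" = 1, "B->C" = 1, "C->A" = 1))
  qc <- weighted_clustering(tri)
  expect_equal(unname(qc$q), rep(1, 3))
  expect_equal(qc$Q_norm, 1 / (3 / 9))
  # star graph has no closed triplets
  star <- make_net(c("A->B" = 2, "A->C" = 1, "A->D" = 1))
  expect_equal(weighted_clustering(star)$Q, 0)
  # hand-evaluated weighted triplet: q = 0.375
  net <- make_net(c("I->J" = 2, "I->H" = 1, "I->L" = 1, "J->H" = 0.5))
  q <- weighted_clustering(net)$q
  expect_equal(unname(q["I"]), ((2 + 1) / 2 * 2) / (4 * 2))
  expect_equal(unname(q["I"]), 0.375)
  # oracle agreement on random small webs
  set.seed(11)
  for (rep in 1:15) {
    net <- random_small_net(sample(3:5, 1), p_link = 0.6)
    sw <- planksucc:::.symmetric_web(net)
    if (nrow(sw$W) == 0) next
    q <- weighted_clustering(net)$q
    for (i in seq_len(nrow(sw$W)))
      expect_equal(unname(q[i]), oracle_clustering_q(sw$W, i),
                   tolerance = 1e-9)
  }
})
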