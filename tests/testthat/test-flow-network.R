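test_that("constructor and validation reject malformed networks", {
  Tm <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  Tm["A", "B"] <- -0.5
  expect_error(flow_network(Tm), "negative flow")
  Tm["A", "B"] <- 1
  expect_error(flow_network(Tm, imports = c(X = 1)), "unknown node")
  expect_error(flow_network(Tm, respiration = c(B = 1), element = "P"),
               "phosphorus")
})

test_that("mass balance report flags residuals at the right node", {
  net <- make_net(c("A->B" = 1), imports = c(A = 1), respiration = c(B = 1))
  rep <- validate_mass_balance(net, rtol = 1e-6)
  expect_true(attr(rep, "pass"))
  expect_equal(rep$residual, c(0, 0))

  bad <- make_net(c("A->B" = 1), imports = c(A = 1),
                  respiration = c(B = 0.5))
  rep <- validate_mass_balance(bad, rtol = 1e-6)
  expect_false(attr(rep, "pass"))
  expect_equal(attr(rep, "worst"), "B")
  expect_equal(rep$residual[rep$node == "B"], 0.5)
})

test_that("total system throughput follows the flow-set convention", {
  net <- chain_net()
  expect_equal(total_system_throughput(net, "trophic_detrital"), 2)
  # full throughput counts the import and the respiration once each
  expect_equal(total_system_throughput(net, "full_throughput"), 4)
  empty <- flow_network(matrix(0, 2, 2,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  expect_error(total_system_throughput(empty), "empty selection")
})

test_that("CSV round trip reproduces a network exactly", {
  net <- generate_balanced_network(cfg = scenario_config(seed = 7),
                                   phase = 5)
  ef <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".csv")
  write_flow_network(net, ef, nf)
  back <- read_flow_network(ef, nf)
  expect_equal(back$T, net$T)
  expect_equal(back$imports, net$imports)
  expect_equal(back$exports, net$exports)
  expect_equal(back$respiration, net$respiration)
  expect_identical(back$element, net$element)
  expect_identical(back$phase, net$phase)
  # writing what was read back is byte-stable
  ef2 <- tempfile(fileext = ".csv"); nf2 <- tempfile(fileext = ".csv")
  write_flow_network(back, ef2, nf2)
  expect_identical(readLines(ef), readLines(ef2))
  expect_identical(readLines(nf), readLines(nf2))
  unlink(c(ef, nf, ef2, nf2))
})

test_that("reader rejects malformed edge files", {
  nf <- tempfile(fileext = ".csv")
  writeLines("node,import,export\nA,1,0\nB,0,1", nf)
  ef <- tempfile(fileext = ".csv")
  writeLines("source,target,flow\nA,B,-0.5", ef)
  expect_error(read_flow_network(ef, nf), "negative flow")
  writeLines("source,target,flow\nA,B,1\nA,B,2", ef)
  expect_error(read_flow_network(ef, nf), "duplicate")
  writeLines("source,target,flow\nA,C,1", ef)
  expect_error(read_flow_network(ef, nf), "unknown node")
  unlink(c(ef, nf))
})

test_that("aggregation conserves throughput, boundaries and balance", {
  net8 <- generate_balanced_network(cfg = scenario_config(seed = 3),
                                    phase = 4)
  net24 <- disaggregate_flows(net8)
  agg <- aggregate_network(net24, lc_aggregation_map("24to8"))
  expect_equal(sort(agg$nodes), sort(net8$nodes))
  ord <- net8$nodes
  expect_equal(agg$T[ord, ord], net8$T, tolerance = 1e-12)
  expect_equal(agg$imports[ord], net8$imports, tolerance = 1e-12)
  expect_equal(agg$exports[ord], net8$exports, tolerance = 1e-12)
  expect_equal(total_system_throughput(agg, "full_throughput"),
               total_system_throughput(net8, "full_throughput"))
  expect_true(attr(validate_mass_balance(agg, rtol = 1e-9), "pass"))
  # identity mapping returns the same network
  idm <- stats::setNames(net8$nodes, net8$nodes)
  same <- aggregate_network(net8, idm)
  expect_equal(same$T[ord, ord], net8$T)
  # missing node in the mapping is an error
  expect_error(aggregate_network(net8, idm[-1]), "missing node")
})

test_that("aggregating to 5 compartments keeps balance and self-loops", {
  net8 <- generate_balanced_network(cfg = scenario_config(seed = 3),
                                    phase = 2)
  net5 <- aggregate_network(net8, lc_aggregation_map("8to5"))
  expect_setequal(net5$nodes, c("Auto", "Bac", "Bactv", "Herb", "Carn",
                                "PDOM"))
  expect_true(attr(validate_mass_balance(net5, rtol = 1e-9), "pass"))
  # intra-compartment feeding becomes flagged self-loops
  expect_true("Herb" %in% attr(net5, "self_loops"))
})

test_that("disaggregation splits uniformly and is exactly invertible", {
  # one consumer guild covering 5 resource guilds: flow of 10 -> 5 x 2
  g <- lc_guilds()
  net8 <- generate_balanced_network(cfg = scenario_config(seed = 11),
                                    phase = 6)
  net24 <- disaggregate_flows(net8, g)
  # HNF group has a single guild eating APP and Bac equally
  hnf_in <- net8$T["Phy", "HNF"]
  expect_equal(net24$T["APP", "HNF"], hnf_in)   # only Phy guild in HNF diet
  # detrital split: each Phy guild returns an equal share
  expect_equal(net24$T["Alg1", "PDOM"], net8$T["Phy", "PDOM"] / 6)
  # the CarnCru self-loop disaggregates onto cyclopoid cannibalism only
  expect_gt(net24$T["Cyc", "Cyc"], 0)
  expect_equal(sum(net24$T[c("Cyc", "Lep"), c("Cyc", "Lep")]),
               net8$T["CarnCru", "CarnCru"])
})
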