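# Simple, Complex, and Hybrid contagion dynamics

test_that("simple contagion extremes behave deterministically", {
  g <- bah_network(80, homophily = 0.6, seed = 1)
  expect_equal(run_simple(g, 1, infectivity = 1)$final_density, 1)
  r0 <- run_simple(g, 5, infectivity = 0)
  expect_equal(r0$final_density, 1 / 80)
  expect_equal(sum(r0$final_states != "susceptible"), 1)
  expect_error(run_simple(g, 200, 0.5), "out of range")
  expect_error(run_simple(g, 1, 1.5), "infectivity")
})

test_that("3-node path seeded at the center matches the exact outcome law", {
  # two independent Bernoulli(1/2) trials: rho_f in {1/3, 2/3, 1} with
  # probabilities 1/4, 1/2, 1/4
  g <- path_graph(3)
  set.seed(42)
  rho <- replicate(20000, run_simple(g, 2, infectivity = 0.5)$final_density)
  freq <- table(factor(round(rho, 10),
                       levels = round(c(1 / 3, 2 / 3, 1), 10)))
  p <- c(0.25, 0.5, 0.25)
  for (j in 1:3)
    expect_lt(abs(freq[[j]] - 20000 * p[j]),
              3 * sqrt(20000 * p[j] * (1 - p[j])))
  expect_equal(mean(rho), 2 / 3, tolerance = 0.02)
})

test_that("complex contagion follows the strict threshold rule", {
  # node with 4 neighbors: 1 informed -> stays susceptible at T = 1/3;
  # 2 informed -> adopts
  g <- star_graph(4)
  st <- c("susceptible", "informed", rep("susceptible", 3))
  expect_true(is_absorbing(g, st, "complex", threshold = 1 / 3))
  st2 <- c("susceptible", "informed", "informed", "susceptible", "susceptible")
  expect_false(is_absorbing(g, st2, "complex", threshold = 1 / 3))

  # T = 0: full cascade on a connected network
  gb <- bah_network(60, homophily = 0.4, seed = 3)
  expect_equal(run_complex(gb, 7, threshold = 0)$final_density, 1)

  # star seeded at a leaf: hub fraction 1/4, full cascade iff T < 1/4
  r_low <- run_complex(g, 2, threshold = 0.2)
  expect_equal(r_low$final_density, 1)
  r_high <- run_complex(g, 2, threshold = 0.3)
  expect_equal(sum(r_high$final_states != "susceptible"), 1)

  # T >= 1: seed only
  expect_equal(run_complex(gb, 1, threshold = 1)$final_density, 1 / 60)
})

test_that("hybrid contagion reduces to its limiting cases", {
  # all nodes in the seed's group: identical to simple contagion at lambda=1
  g <- with_groups(bah_network(50, homophily = 0.5, seed = 8), integer(0))
  expect_equal(run_hybrid(g, 3, threshold = 0.4)$final_density, 1)

  # T >= 1: complex nodes never adopt; informed set = nodes reachable from
  # the seed through seed-group-only paths (graph-reachability oracle),
  # plus nothing else
  gb <- bah_network(100, homophily = 0.7, seed = 12)
  grp <- igraph::V(gb)$group
  maj <- which(grp == "majority")
  seedv <- maj[5]
  r <- run_hybrid(gb, seedv, threshold = 1)
  sub <- igraph::induced_subgraph(gb, maj)
  comp <- igraph::components(sub)
  reach <- maj[comp$membership == comp$membership[match(seedv, maj)]]
  expect_setequal(which(r$final_states != "susceptible"), reach)

  # mechanism map: seed group simple, other complex
  expect_true(all(r$mechanism[grp == "majority"] == "simple"))
  expect_true(all(r$mechanism[grp == "minority"] == "complex"))
})

test_that("final state of threshold dynamics is order-invariant", {
  # monotone update: the absorbing state must not depend on sweep order
  g <- bah_network(120, homophily = 0.65, seed = 21)
  maj <- which(igraph::V(g)$group == "majority")[3]
  ref_c <- run_complex(g, maj, threshold = 0.25, seed = 1)$final_states
  ref_h <- run_hybrid(g, maj, threshold = 0.25, seed = 1)$final_states
  for (s in 2:6) {
    expect_identical(run_complex(g, maj, 0.25, seed = s)$final_states, ref_c)
    expect_identical(run_hybrid(g, maj, 0.25, seed = s)$final_states, ref_h)
  }
})

test_that("informed sets shrink monotonically in the threshold", {
  # deterministic absorbing states: subset relation must hold exactly
  g <- bah_network(150, homophily = 0.6, seed = 31)
  seedv <- which(igraph::V(g)$group == "majority")[1]
  for (model in c("complex", "hybrid")) {
    run1 <- if (model == "complex") run_complex else run_hybrid
    prev <- NULL
    for (T_ in c(0.05, 0.15, 0.3, 0.6, 1)) {
      cur <- which(run1(g, seedv, T_)$final_states != "susceptible")
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("mean informed density grows with infectivity", {
  g <- bah_network(150, homophily = 0.5, seed = 41)
  set.seed(99)
  m1 <- mean(replicate(400, run_simple(g, 1, 0.3)$final_density))
  m2 <- mean(replicate(400, run_simple(g, 1, 0.7)$final_density))
  expect_gt(m2, m1)
})

test_that("no illegal state transitions are produced", {
  # states are only ever S, I, R; simple runs end with no informed-but-not-
  # recovered spreaders left (absorbing), and the seed always knows
  g <- bah_network(60, homophily = 0.5, seed = 51)
  for (run in list(run_simple(g, 2, 0.4, seed = 1),
                   run_complex(g, 2, 0.2, seed = 2),
                   run_hybrid(g, 2, 0.2, seed = 3))) {
    expect_true(all(run$final_states %in%
                      c("susceptible", "informed", "recovered")))
    expect_true(run$final_states[2] != "susceptible")
    expect_equal(sum(run$informed_count_per_group),
                 sum(run$final_states != "susceptible"))
  }
  r <- run_simple(g, 2, 0.4, seed = 1)
  expect_true(is_absorbing(g, as.character(r$final_states), "simple"))
})

test_that("absorbing-state checks match hand-computed cases", {
  g <- star_graph(4)
  all_informed <- rep("informed", 5)
  expect_true(is_absorbing(g, all_informed, "simple"))
  # hub susceptible with 1 of 4 leaves informed at T = 0.3, no simple nodes
  st <- c("susceptible", "informed", rep("susceptible", 3))
  expect_true(is_absorbing(g, st, "complex", threshold = 0.3))
  expect_false(is_absorbing(g, st, "complex", threshold = 0.2))
  # a pending lambda=1 attempt makes a hybrid state non-absorbing
  gh <- with_groups(g, minority_idx = 3:5)
  expect_false(is_absorbing(gh, st, "hybrid", threshold = 0.9,
                            simple_group = "majority"))
})

test_that("replicate_cascades reports per-run group densities consistently", {
  g <- bah_network(80, homophily = 0.6, seed = 61)
  df <- replicate_cascades(g, "hybrid", 40, threshold = 0.2,
                           source_group = "majority", seed = 5)
  expect_equal(nrow(df), 40)
  expect_true(all(df$seed_group == "majority"))
  nm <- sum(igraph::V(g)$group == "minority")
  nM <- 80 - nm
  recon <- (df$rho_minority * nm + df$rho_majority * nM) / 80
  expect_equal(recon, df$rho_f, tolerance = 1e-12)
  # determinism under a fixed seed
  df2 <- replicate_cascades(g, "hybrid", 40, threshold = 0.2,
                            source_group = "majority", seed = 5)
  expect_identical(df, df2)
})
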