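# Homophilic preferential-attachment generator

test_that("group assignment follows the Bernoulli law and validates input", {
  expect_error(assign_groups(10, 1.2), "minority_fraction")
  expect_error(assign_groups(10, 0), "minority_fraction")
  expect_warning(assign_groups(10, 0.6), "not the smaller")
  # degenerate boundary: always majority
  expect_true(all(assign_groups(50, 0, allow_degenerate = TRUE) == "majority"))
  # binomial concentration: 1e5 draws at f = 0.2 within 3 SDs
  set.seed(101)
  draws <- assign_groups(1e5, 0.2)
  f_hat <- mean(draws == "minority")
  expect_lt(abs(f_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
})

test_that("attachment weights implement the homophily kernel exactly", {
  # two same-group candidates with degrees 2 and 1 at h = 0.7 -> 2/3, 1/3
  g <- with_groups(path_graph(3), minority_idx = 1:3)
  w <- attachment_weights(g, "minority", 0.7)
  expect_equal(unname(w$weights), c(1, 2, 1) / 4)
  expect_false(w$degenerate)
  w2 <- attachment_weights(igraph::induced_subgraph(g, 1:2), "minority", 0.7)
  expect_equal(unname(w2$raw), c(0.7, 0.7))

  # cross-group weight is exactly zero at h = 1
  g2 <- with_groups(path_graph(4), minority_idx = c(1, 2))
  w3 <- attachment_weights(g2, "minority", 1)
  expect_identical(unname(w3$raw[3:4]), c(0, 0))
  expect_equal(sum(w3$weights), 1)

  # h = 0.5: proportional to degree alone
  w4 <- attachment_weights(g2, "minority", 0.5)
  expect_equal(unname(w4$weights), igraph::degree(g2) / sum(igraph::degree(g2)))

  # degenerate flag when every weight vanishes
  g3 <- with_groups(igraph::make_empty_graph(2, directed = FALSE), 1)
  expect_true(attachment_weights(g3, "minority", 0.5)$degenerate)
})

test_that("kernel sampling frequencies match the normalized weights", {
  # fixed 5-node network (star, mixed groups), 1e5 draws from the
  # attachment_weights distribution, each category within 3 multinomial SDs
  g <- with_groups(star_graph(4), minority_idx = c(1, 2))
  w <- attachment_weights(g, "minority", 0.7)$weights
  expect_equal(sum(w), 1)
  set.seed(77)
  n_draw <- 1e5
  sim <- tabulate(sample.int(5, n_draw, replace = TRUE, prob = w), nbins = 5)
  for (j in 1:5) {
    p <- unname(w[j])
    expect_lt(abs(sim[j] - n_draw * p), 3 * sqrt(n_draw * p * (1 - p)) + 1)
  }
})

test_that("generated networks satisfy the structural invariants", {
  # m = 1, bridged seed: tree with N - 1 edges, connected, for several h
  for (h in c(0, 0.3, 0.5, 0.9, 1)) {
    g <- bah_network(70, m_links = 1, minority_fraction = 0.2, homophily = h,
                     seed = 400 + round(100 * h))
    expect_equal(igraph::ecount(g), 69)
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
    if (h < 1) expect_true(igraph::is_connected(g))
  }
  # h = 1, bridged: the only cross-group edge is the seed bridge
  g1 <- bah_network(300, homophily = 1, seed = 11)
  expect_equal(group_degree_summary(g1)$between_edges, 1)

  # isolated seed: exactly two components for every h (m = 1)
  for (h in c(0.2, 0.5, 1)) {
    gi <- suppressWarnings(
      bah_network(100, homophily = h, seed_mode = "isolated",
                  seed = 500 + round(100 * h)))
    expect_equal(igraph::count_components(gi), 2)
    if (h == 1)
      expect_equal(group_degree_summary(gi)$between_edges, 0)
  }

  # m = 2 stays simple
  g2 <- bah_network(50, m_links = 2, homophily = 0.7, seed = 9)
  expect_false(any(igraph::which_multiple(g2)))
  expect_equal(igraph::ecount(g2), 1 + 48 * 2)
})

test_that("identical seeds reproduce identical edge lists", {
  g1 <- bah_network(200, homophily = 0.7, seed = 123)
  g2 <- bah_network(200, homophily = 0.7, seed = 123)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::V(g1)$group, igraph::V(g2)$group)
})

test_that("parameter validation rejects out-of-range configurations", {
  expect_error(bah_network(2), "n_nodes")
  expect_error(bah_network(10, minority_fraction = 1.2), "minority_fraction")
  expect_error(bah_network(10, homophily = -0.1), "homophily")
  expect_warning(bah_network(10, minority_fraction = 0.6, seed = 1),
                 "not the smaller")
})

test_that("heterophilic hubs are minority nodes and are larger", {
  # ensemble comparison at N = 1000, f_a = 0.2: h = 0.2 vs h = 0.7
  set.seed(2024)
  reps <- 60
  hub_min <- logical(reps)
  max02 <- max07 <- numeric(reps)
  for (i in seq_len(reps)) {
    s02 <- group_degree_summary(bah_network(1000, homophily = 0.2))
    s07 <- group_degree_summary(bah_network(1000, homophily = 0.7))
    hub_min[i] <- s02$hub_group == "minority"
    max02[i] <- s02$hub_degree
    max07[i] <- s07$hub_degree
  }
  expect_gt(mean(hub_min), 0.5)       # hubs are minority nodes when h < 0.5
  expect_gt(mean(max02), mean(max07)) # heterophilic hubs have larger degree
})

test_that("group_degree_summary conserves edge counts", {
  g <- bah_network(150, m_links = 2, homophily = 0.6, seed = 5)
  s <- group_degree_summary(g)
  expect_equal(sum(s$groups$within_edges) + s$between_edges, s$total_edges)
  expect_equal(s$total_edges, igraph::ecount(g))

  # 2-node cross-group network: one between edge, no within edges
  g2 <- with_groups(path_graph(2), minority_idx = 1)
  s2 <- group_degree_summary(g2)
  expect_equal(s2$between_edges, 1)
  expect_equal(sum(s2$groups$within_edges), 0)
})

test_that("h = 0.5 reduces to group-blind preferential attachment", {
  # two-sample KS on maximum degree vs igraph::sample_pa grown from the same
  # two-node seed (500 replicates each)
  reps <- 500
  set.seed(31)
  max_bah <- vapply(seq_len(reps), function(i)
    max(igraph::degree(bah_network(120, homophily = 0.5))), numeric(1))
  seed_graph <- igraph::make_graph(c(1, 2), directed = FALSE)
  max_ba <- vapply(seq_len(reps), function(i)
    max(igraph::degree(igraph::sample_pa(
      120, power = 1, m = 1, start.graph = seed_graph, zero.appeal = 1e-12,
      directed = FALSE))), numeric(1))
  ks <- suppressWarnings(stats::ks.test(max_bah, max_ba))
  expect_gt(ks$p.value, 0.01)
})
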