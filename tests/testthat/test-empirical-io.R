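# Empirical network reading, largest component, homophily estimation,
# and result serialization

write_fixture <- function(edges, attrs) {
  ef <- tempfile(fileext = ".tsv")
  af <- tempfile(fileext = ".tsv")
  writeLines(edges, ef)
  writeLines(attrs, af)
  list(edges = ef, attrs = af)
}

test_that("the reader collapses duplicates, drops loops, and maps groups", {
  f <- write_fixture(c("# comment line", "a\tb", "b\tc", "a\tb", "c\tc"),
                     c("a\tx", "b\ty", "c\ty"))
  g <- suppressMessages(
    read_attributed_network(f$edges, f$attrs, minority_label = "x"))
  expect_equal(igraph::ecount(g), 2)          # duplicate + self-loop removed
  expect_equal(igraph::vcount(g), 3)
  expect_equal(sort(unique(igraph::V(g)$group)), c("majority", "minority"))
  expect_equal(igraph::V(g)$group[igraph::V(g)$name == "a"], "minority")
  # default minority = the rarer label
  g2 <- suppressMessages(read_attributed_network(f$edges, f$attrs))
  expect_equal(sum(igraph::V(g2)$group == "minority"), 1)
})

test_that("the reader fails loudly on bad input", {
  f <- write_fixture(c("a\tb", "b\tz"), c("a\tx", "b\ty"))
  expect_error(read_attributed_network(f$edges, f$attrs), "z")
  f3 <- write_fixture("a\tb", c("a\tx", "b\ty", "c\tz"))
  expect_error(read_attributed_network(f3$edges, f3$attrs), "2 group")
  f4 <- write_fixture("a\tb", c("a\tx", "b\ty"))
  expect_error(read_attributed_network(f4$edges, f4$attrs,
                                       minority_label = "nope"), "nope")
})

test_that("largest_component keeps the right component and is idempotent", {
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - e, x - y, y - z)
  lc <- largest_component(g)
  expect_equal(igraph::vcount(lc), 5)
  expect_identical(igraph::vcount(largest_component(lc)), igraph::vcount(lc))
  # connected graph: identity
  expect_equal(igraph::vcount(largest_component(path_graph(4))), 4)
  # equal sizes: the component holding the smallest vertex wins, with a note
  g2 <- igraph::make_graph(~ a - b, c - d)
  expect_message(lc2 <- largest_component(g2), "tie")
  expect_setequal(igraph::V(lc2)$name, c("a", "b"))
})

test_that("homophily estimation recovers generator parameters", {
  # parameter recovery over the operating range; mean absolute error < 0.05
  hs <- c(0.2, 0.5, 0.7, 0.9)
  errs <- vapply(seq_along(hs), function(i) {
    g <- bah_network(1000, homophily = hs[i], seed = 700 + i)
    fit <- estimate_homophily(g, n_matching_reps = 50, seed = 800 + i)
    abs(fit$h_hat - hs[i])
  }, numeric(1))
  expect_lt(mean(errs), 0.05)

  g1 <- with_groups(path_graph(4), integer(0))
  expect_error(estimate_homophily(g1), "both groups")
})

test_that("network writers round-trip through their formats", {
  g <- bah_network(40, homophily = 0.8, seed = 15)
  ef <- tempfile(); af <- tempfile(); gml <- tempfile(fileext = ".graphml")
  write_edge_list(g, ef, header = "n=40")
  write_node_attributes(g, af)
  el <- utils::read.table(ef, comment.char = "#")
  expect_equal(nrow(el), igraph::ecount(g))
  at <- utils::read.table(af)
  expect_setequal(unique(at$V2), c("m", "M"))
  expect_equal(sum(at$V2 == "m"),
               sum(igraph::V(g)$group == "minority"))
  # the TSV pair reads back to an isomorphic attributed graph
  g2 <- read_attributed_network(ef, af, minority_label = "m")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sum(igraph::V(g2)$group == "minority"),
               sum(igraph::V(g)$group == "minority"))
  # GraphML keeps the group attribute
  write_network_graphml(g, gml)
  g3 <- read_network_graphml(gml)
  expect_equal(igraph::V(g3)$group, igraph::V(g)$group)
})

test_that("result objects round-trip through JSON", {
  m <- estimate_it_matrix(bah_config(80, homophily = 0.7),
                          dynamics_config("hybrid", threshold = 0.2),
                          n_realizations = 10, seed = 16)
  f <- tempfile(fileext = ".json")
  write_results(m, f)
  back <- read_results(f)
  expect_s3_class(back, "it_matrix")
  expect_equal(back$it, m$it)
  expect_equal(back$se, m$se)
  expect_equal(back$n_realizations, m$n_realizations)

  b <- bias_decompose(m)
  fb <- tempfile(fileext = ".json")
  write_results(b, fb)
  expect_equal(unlist(read_results(fb)), unlist(b), tolerance = 1e-12)
})

test_that("divergent thresholds serialize as an explicit string", {
  sw <- structure(list(
    results = data.frame(h = c(0.5, 0.7), source = "majority",
                         t_c = c(0.2, NA), divergent = c(FALSE, TRUE),
                         flagged = FALSE),
    model = "hybrid", n_realizations = 10L), class = "homophily_sweep")
  fj <- tempfile(fileext = ".json")
  write_results(sw, fj)
  expect_true(any(grepl("divergent", readLines(fj))))
  expect_false(any(grepl("NaN", readLines(fj))))
  back <- read_results(fj)
  expect_true(back$results$divergent[2])
  expect_true(is.na(back$results$t_c[2]))
  # CSV path
  fc <- tempfile(fileext = ".csv")
  write_results(sw, fc, format = "csv")
  expect_true(any(grepl("divergent", readLines(fc))))
  back2 <- read_results(fc)
  expect_true(back2$divergent[2])
})

test_that("empty record sets still produce a valid file with header", {
  f <- tempfile(fileext = ".csv")
  write_results(data.frame(h = numeric(0), rho = numeric(0)), f,
                format = "csv")
  back <- read_results(f)
  expect_equal(nrow(back), 0)
  expect_equal(names(back), c("h", "rho"))
})
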