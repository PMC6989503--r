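test_that("edge-list reader handles comments, dedup, self-loops and errors", {
  p <- write_tmp_edgelist(c("# a comment", "a b", "b c", "a c"))
  g <- read_edge_list(p)
  expect_equal(g$n, 3)
  expect_equal(edge_count(g), 3)
  expect_true(graphs_isomorphic(g, triangle_graph()))

  # reversed duplicate collapses silently
  p2 <- write_tmp_edgelist(c("a b", "b a"))
  expect_silent(g2 <- read_edge_list(p2))
  expect_equal(c(g2$n, edge_count(g2)), c(2, 1))

  # self-loop dropped with one warning
  p3 <- write_tmp_edgelist(c("a a", "a b"))
  expect_warning(g3 <- read_edge_list(p3), "self-loop")
  expect_equal(c(g3$n, edge_count(g3)), c(2, 1))

  # extra columns warn; short line errors with its line number
  expect_warning(read_edge_list(write_tmp_edgelist(c("a b 1.5"))), "column")
  expect_error(read_edge_list(write_tmp_edgelist(c("a b", "c"))), "line 2")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("edge list and GraphML writers round-trip labels", {
  g <- net_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)),
                 labels = c("alpha", "beta", "gamma", "delta"))
  p <- tempfile(fileext = ".txt")
  write_edge_list(g, p)
  g2 <- read_edge_list(p)
  expect_setequal(g2$labels, g$labels)
  expect_true(graphs_isomorphic(g, g2))

  p3 <- tempfile(fileext = ".graphml")
  write_graphml(g, p3)
  g3 <- read_graphml(p3)
  expect_setequal(g3$labels, g$labels)
  expect_true(graphs_isomorphic(g, g3))
})

test_that("net_graph enforces simple-graph invariants", {
  expect_error(net_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(net_graph(3, rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(net_graph(3, rbind(c(1, 4))), "outside")
  g <- net_graph(5, rbind(c(3, 1), c(2, 5)))
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  expect_equal(sum(degree_sequence(g)), 2 * edge_count(g))
})

test_that("er_graph respects the G(N,M) contract", {
  expect_equal(edge_count(er_graph(4, 6, seed = 1)), 6)
  expect_true(graphs_isomorphic(er_graph(4, 6, seed = 1),
                                net_graph(4, t(combn(4, 2)))))
  expect_equal(edge_count(er_graph(100, 0, seed = 1)), 0)
  g1 <- er_graph(50, 100, seed = 1)
  g2 <- er_graph(50, 100, seed = 2)
  expect_equal(c(edge_count(g1), edge_count(g2)), c(100, 100))
  expect_false(identical(g1$edges, g2$edges))
  expect_identical(er_graph(50, 100, seed = 1)$edges, g1$edges)
  expect_error(er_graph(10, 46), "out of range")
})

test_that("shuffle_links preserves N and E and mixes the right fraction", {
  g <- er_graph(80, 200, seed = 3)
  expect_identical(shuffle_links(g, 0, seed = 1)$edges, g$edges)

  gs <- shuffle_links(g, 1, seed = 4)
  expect_equal(edge_count(gs), 200)
  expect_equal(gs$n, 80)

  # exactly half the links are rewired; replacement edges are drawn from
  # the vacant pairs after removal, so they may coincide with removed ones
  # and the retained count can slightly exceed E/2 but never fall below it
  g5 <- shuffle_links(g, 0.5, seed = 5)
  kept <- length(intersect(
    (g$edges[, 1] - 1) * g$n + g$edges[, 2],
    (g5$edges[, 1] - 1) * g5$n + g5$edges[, 2]))
  expect_gte(kept, 100)
  expect_lt(kept, 120)
  expect_equal(edge_count(g5), 200)
  expect_error(shuffle_links(g, 1.2), "0, 1")
})

test_that("perturb_links add/remove obey bounds and identities", {
  g <- er_graph(30, 60, seed = 1)
  expect_identical(perturb_links(g, "add", m = 0)$edges, g$edges)
  expect_equal(edge_count(perturb_links(g, "remove", m = 60, seed = 1)), 0)
  full <- perturb_links(g, "add", m = choose(30, 2) - 60, seed = 1)
  expect_equal(edge_count(full), choose(30, 2))
  expect_error(perturb_links(g, "remove", m = 61), "more links")
  expect_error(perturb_links(g, "add", m = choose(30, 2)), "vacant")
  # fraction interface rounds half-up
  expect_equal(edge_count(perturb_links(g, "remove", f = 0.25, seed = 1)), 45)
})

test_that("combine_graphs unions disjoint edge sets and errors on overlap", {
  ga <- net_graph(3, rbind(c(1, 2)))
  gb <- net_graph(3, rbind(c(2, 3)))
  expect_identical(combine_graphs(ga, net_graph(3))$edges, ga$edges)
  path <- combine_graphs(ga, gb)
  expect_equal(edge_count(path), 2)
  expect_error(combine_graphs(ga, ga), "overlap")
  expect_error(combine_graphs(ga, net_graph(4)), "same node set")

  # degree sequence of the union is the elementwise sum
  a <- er_graph(40, 80, seed = 1)
  vac <- perturb_links(a, "add", m = 50, seed = 2)
  b <- net_graph(40, vac$edges[!((vac$edges[, 1] - 1) * 40 + vac$edges[, 2]) %in%
                                ((a$edges[, 1] - 1) * 40 + a$edges[, 2]), ])
  expect_equal(degree_sequence(combine_graphs(a, b)),
               degree_sequence(a) + degree_sequence(b))
})

test_that("circle_model builds the ring lattice", {
  g6 <- circle_model(6, 2)
  expect_equal(edge_count(g6), 6)
  expect_true(all(degree_sequence(g6) == 2))
  g10 <- circle_model(10, 4)
  expect_equal(edge_count(g10), 20)
  expect_true(all(degree_sequence(g10) == 4))
  # N=5, k_c=4 wraps to the complete graph
  expect_true(graphs_isomorphic(circle_model(5, 4), net_graph(5, t(combn(5, 2)))))
  expect_error(circle_model(10, 3), "even")
  expect_error(circle_model(10, 10), "k_c")
})

test_that("chung_lu_q_matrix matches hand values, caps, and expected degrees", {
  q <- chung_lu_q_matrix(rep(3, 6))
  expect_true(all(abs(q[upper.tri(q)] - 3 / 6) < 1e-12))

  q2 <- chung_lu_q_matrix(c(3, 1, 1, 1))
  expect_equal(q2[1, 2], 0.5)
  expect_equal(q2[2, 3], 1 / 6)

  q3 <- chung_lu_q_matrix(c(5, 5, 1, 1))
  expect_equal(q3[1, 2], 1) # 25/12 capped

  expect_error(chung_lu_q_matrix(c(0, 0)), "zero")
  expect_error(chung_lu_q_matrix(c(2, 1)), "even")

  # expected degree identity: sum_j q_ij = k_i - k_i^2/sum(k) (zero diagonal)
  deg <- c(3, 2, 2, 1)
  q4 <- chung_lu_q_matrix(deg)
  expect_equal(rowSums(q4), deg - deg^2 / sum(deg), tolerance = 1e-12)
})

test_that("powerlaw_degrees hits the target mean with an even sum", {
  for (n in c(300, 800)) {
    k <- powerlaw_degrees(n, 12)
    expect_equal(sum(k) %% 2, 0)
    expect_lt(abs(mean(k) - 12) / 12, 0.05)
    expect_true(all(k >= 1))
    expect_true(max(k) <= sqrt(12 * n) + 1)
  }
})

test_that("validity band warnings fire on extreme densities", {
  expect_warning(check_validity_band(er_graph(200, 300, seed = 1)), "sparse")
  expect_silent(check_validity_band(er_graph(200, 2000, seed = 1)))
})
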