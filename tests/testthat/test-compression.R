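test_that("binary_entropy matches hand values and is symmetric", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.25), 0.8112781, tolerance = 1e-6)
  expect_equal(binary_entropy(0.1), binary_entropy(0.9))
  expect_error(binary_entropy(1.1), "0, 1")
})

test_that("the ceiling matches the closed form and rejects its domain edge", {
  # direct evaluation: C(100,2) h(0.1) - 100 log2 100
  r <- max_compression_length(100, 495)
  expect_equal(r, 4950 * binary_entropy(0.1) - 100 * log2(100), tolerance = 1e-12)
  expect_equal(round(r), 1657)
  # h is symmetric in E <-> C(N,2) - E
  expect_equal(max_compression_length(100, 4950 - 495), r, tolerance = 1e-9)
  expect_error(max_compression_length(100, 5), "sparse or dense")
})

test_that("structure coding round-trips exactly up to isomorphism", {
  # edgeless and complete
  for (g in list(net_graph(5), net_graph(4, t(combn(4, 2))),
                 circle_model(6, 2), triangle_graph())) {
    dec <- decode_structure(encode_structure(g, seed = 1))
    expect_true(graphs_isomorphic(g, dec))
  }
  # random G(10, 20): exact isomorphism, via both decode paths
  for (s in 1:5) {
    g <- er_graph(10, 20, seed = s)
    enc <- encode_structure(g, seed = s + 10)
    expect_true(graphs_isomorphic(g, decode_structure(enc)))
    expect_true(graphs_isomorphic(g, decode_structure(enc, from = "payload")))
  }
})

test_that("coding conserves E and the degree multiset on random graphs", {
  set.seed(1)
  for (s in 1:50) {
    n <- sample(5:40, 1)
    e <- sample.int(choose(n, 2), 1)
    g <- er_graph(n, e, seed = s)
    dec <- decode_structure(encode_structure(g, seed = s))
    expect_equal(edge_count(dec), e)
    expect_equal(sort(degree_sequence(dec)), sort(degree_sequence(g)))
  }
})

test_that("corrupt symbol streams raise decode errors", {
  g <- er_graph(12, 30, seed = 1)
  enc <- encode_structure(g, seed = 1)
  bad <- enc
  bad$b2 <- bad$b2[-length(bad$b2)] # drop last symbol
  expect_error(decode_structure(bad), "corrupt")
  bad2 <- enc
  bad2$b2[1] <- 999L
  expect_error(decode_structure(bad2), "corrupt")
})

test_that("encoding is deterministic given seed and policy", {
  g <- er_graph(40, 150, seed = 2)
  e1 <- encode_structure(g, seed = 5)
  e2 <- encode_structure(g, seed = 5)
  expect_identical(e1$payload1, e2$payload1)
  expect_identical(e1$payload2, e2$payload2)
  e3 <- encode_structure(g, seed = 6)
  expect_false(identical(e1$payload2, e3$payload2))
})

test_that("adaptive entropy coder is lossless and near-optimal", {
  # constant sequence compresses to a handful of bits
  z <- entropy_code(rep(0L, 1000), alphabet = 2)
  expect_lte(z$nbits, 30)
  expect_identical(entropy_decode(z), rep(0L, 1000))

  # random bit strings round-trip exactly
  set.seed(7)
  x <- sample(0:1, 5000, replace = TRUE)
  cx <- entropy_code(x)
  expect_identical(entropy_decode(cx), as.integer(x))

  # fair coin: length within 2% of n bits
  y <- sample(0:1, 1e4, replace = TRUE)
  cy <- entropy_code(y)
  expect_lt(abs(cy$nbits - 1e4) / 1e4, 0.02)

  # larger alphabet, biased: within empirical entropy + redundancy
  s <- sample(0:5, 4000, replace = TRUE, prob = c(.4, .3, .1, .1, .05, .05))
  cs <- entropy_code(s, alphabet = 6)
  expect_identical(entropy_decode(cs), as.integer(s))
  hemp <- ref_entropy(tabulate(s + 1, 6) / 4000)
  expect_lt(cs$nbits, 4000 * hemp + 6 * log2(4000) + 64)

  # empty input is valid
  ce <- entropy_code(integer(0), alphabet = 2)
  expect_identical(entropy_decode(ce), integer(0))
})

test_that("compression_length: near-zero for edgeless, calibrated on ER", {
  cr0 <- compression_length(net_graph(100), runs = 5, seed = 1)
  expect_lte(cr0$L, 48) # coder flush overhead only: structural entropy is 0

  cr <- compression_length(er_graph(200, 1000, seed = 3), runs = 20, seed = 1)
  expect_lt(abs(cr$L - cr$R) / cr$R, 0.10)
  expect_equal(cr$L_star, cr$L / cr$R)
  expect_length(cr$per_run, 20)
})

test_that("mean L increases strictly with shuffling of a structured graph", {
  g <- structured_graph(150, 8, extra = 75, seed = 2)
  ls <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    gs <- if (f > 0) shuffle_links(g, f, seed = 40 + round(100 * f)) else g
    compression_length(gs, runs = 20, seed = 1)$L
  }, numeric(1))
  expect_true(all(diff(ls) > 0))
})

test_that("traversal order policy moves L by at most 2 percent", {
  g <- chung_lu_graph(powerlaw_degrees(300, 10), seed = 4)
  l <- vapply(c("random", "high_degree_first", "low_degree_first"),
              function(p) compression_length(g, runs = 15, seed = 1,
                                             order_policy = p)$L,
              numeric(1))
  expect_lt((max(l) - min(l)) / mean(l), 0.02)
})

test_that("normalized_length: ER near 1, ring lattice far below", {
  er <- normalized_length(er_graph(200, 1200, seed = 5), runs = 15, seed = 1)
  expect_true(er$L_star > 0.9 && er$L_star < 1.1)
  ring <- normalized_length(circle_model(200, 12), runs = 15, seed = 1)
  expect_lt(ring$L_star, 0.5 * er$L_star)
  # shuffled fraction interpolates between the two
  g <- structured_graph(150, 8, extra = 75, seed = 2)
  l0 <- normalized_length(g, runs = 15, seed = 1)$L_star
  l3 <- normalized_length(shuffle_links(g, 0.3, seed = 1), runs = 15, seed = 1)$L_star
  l1 <- normalized_length(shuffle_links(g, 1, seed = 1), runs = 15, seed = 1)$L_star
  expect_true(l0 < l3 && l3 < l1)
  expect_error(normalized_length(er_graph(100, 5, seed = 1)), "sparse or dense")
})

test_that("the binary container round-trips encoded graphs", {
  g <- er_graph(25, 60, seed = 9)
  enc <- encode_structure(g, seed = 2)
  path <- tempfile(fileext = ".npc")
  write_encoded(enc, path)
  enc2 <- read_encoded(path)
  expect_equal(enc2$n, 25)
  dec <- decode_structure(enc2, from = "payload")
  expect_true(graphs_isomorphic(g, dec))
  # bad magic rejected
  writeBin(charToRaw("XXXX"), path)
  expect_error(read_encoded(path), "container")
})
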