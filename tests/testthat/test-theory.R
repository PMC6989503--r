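test_that("u_term matches closed forms and hand sums", {
  n <- 20
  z <- matrix(0, n, n)
  expect_equal(u_term(z), 0)

  q <- matrix(0.1, n, n); diag(q) <- 0
  expect_equal(u_term(q), choose(n, 2) * 0.1 * log2(1 / 0.1))

  # hand evaluation on a 4-node block pattern
  qb <- matrix(0.25, 4, 4)
  qb[1, 2] <- qb[2, 1] <- 0.5
  qb[3, 4] <- qb[4, 3] <- 0.5
  diag(qb) <- 0
  expect_equal(u_term(qb), -(2 * 0.5 * log2(0.5) + 4 * 0.25 * log2(0.25)))
  expect_error(u_term(matrix(c(0, 2, 2, 0), 2)), "0, 1")
})

test_that("structural_entropy: uniform Q reduces to the ceiling; Taylor is tight when sparse", {
  n <- 100
  q <- matrix(0.1, n, n); diag(q) <- 0
  se <- structural_entropy(q)
  expect_equal(se$exact, max_compression_length(n, 0.1 * choose(n, 2)),
               tolerance = 1e-9)

  # sparse Q with the N log N term well clear of cancelling the pair term
  qs <- matrix(0.01, 500, 500); diag(qs) <- 0
  ses <- structural_entropy(qs)
  expect_lt(abs(ses$exact - ses$approx) / ses$exact, 0.01)

  qo <- matrix(1, 50, 50); diag(qo) <- 0
  expect_warning(seo <- structural_entropy(qo), "non-positive")
  expect_equal(seo$exact, -50 * log2(50))
  expect_true(seo$nonpositive)
})

test_that("q_entropy matches uniform, degenerate and brute-force values", {
  n <- 30
  q <- matrix(0.2, n, n); diag(q) <- 0
  expect_equal(q_entropy(q), log2(choose(n, 2)))

  q1 <- matrix(0, 5, 5); q1[1, 2] <- q1[2, 1] <- 0.7
  expect_equal(q_entropy(q1), 0)

  # independent brute-force sum for Chung-Lu degrees (3,2,2,1)
  deg <- c(3, 2, 2, 1)
  qc <- chung_lu_q_matrix(deg)
  qq <- qc[upper.tri(qc)]
  expect_equal(q_entropy(qc), ref_entropy(qq / sum(qq)))
  expect_error(q_entropy(matrix(0, 4, 4)), "no mass")
})

test_that("coarse-grained entropy obeys the log2(N) shift", {
  # uniform Q, N odd so pairs split into exact groups of N
  n <- 101
  q <- matrix(0.1, n, n); diag(q) <- 0
  expect_equal(coarse_grained_entropy(q), q_entropy(q) - log2(n),
               tolerance = 1e-9)

  # all mass inside one group -> zero entropy
  qd <- matrix(0, 40, 40)
  qd[1, 2:21] <- qd[2:21, 1] <- 0.5
  expect_equal(coarse_grained_entropy(qd), 0, tolerance = 1e-9)

  # scale-free Chung-Lu at N = 200: shift identity within 0.1 bits
  qc <- chung_lu_q_matrix(powerlaw_degrees(200, 10))
  expect_lt(abs(coarse_grained_entropy(qc) - (q_entropy(qc) - log2(200))), 0.1)
})

test_that("analytic TBPA entropy matches the uniform closed form", {
  n <- 200
  q <- matrix(0.05, n, n); diag(q) <- 0
  ht <- h_tbpa_analytic(q)
  expect_equal(ht$H, log2((n - 1) / 2), tolerance = 1e-9)
  expect_equal(ht$H_star, 1, tolerance = 0.01)
  expect_error(h_tbpa_analytic(matrix(0, 5, 5)), "zero")
})

test_that("numeric TBPA entropy: uniform baseline, ordering, and agreement", {
  n <- 150
  q <- matrix(8 / n, n, n); diag(q) <- 0
  hn <- h_tbpa_numeric(q, seed = 2, samples = 10)
  expect_lt(abs(hn$H - (log2(n) - 1)), 0.12)

  # two-tier Q: half the pairs 10x more likely -> lower entropy than uniform
  set.seed(3)
  qt <- matrix(0, 50, 50)
  ut <- upper.tri(qt)
  vals <- ifelse(seq_len(sum(ut)) %% 2 == 0, 0.2, 0.02)
  qt[ut] <- vals
  qt <- qt + t(qt)
  htier <- h_tbpa_numeric(qt, seed = 2, samples = 10)
  huni <- h_tbpa_numeric(matrix(ifelse(diag(50) == 1, 0, 0.11), 50, 50),
                         seed = 2, samples = 10)
  expect_lt(htier$H, huni$H)

  # Chung-Lu: numeric vs coarse-grained and analytic within the stated band
  qc <- chung_lu_q_matrix(powerlaw_degrees(400, 10))
  hnc <- h_tbpa_numeric(qc, seed = 4, samples = 10)
  expect_lt(abs(hnc$H - coarse_grained_entropy(qc)), 0.2)
  expect_lt(abs(hnc$H - h_tbpa_analytic(qc)$H), 0.2)
})

test_that("theory_line variants match hand arithmetic and pass through (1,1)", {
  tl <- theory_line(100, 2, "eq_limit")
  expect_equal(c(tl$slope, tl$intercept), c(0, 1))
  expect_equal(theory_line(100, 1e6, "eq_limit")$slope, 1, tolerance = 1e-5)

  tl8 <- theory_line(1e4, 16, "eq_largeN")
  expect_equal(tl8$slope, 1 - 2 / 16 - 4 / log2(1e4), tolerance = 1e-12)

  # slope + intercept = 1 exactly for the two asymptotic forms
  for (v in c("eq_largeN", "eq_limit")) {
    tlv <- theory_line(500, 12, v)
    expect_equal(tlv$slope + tlv$intercept, 1)
  }
  # finite-size line passes within 0.03 of (1, 1) in the validity band
  for (n in c(500, 1000)) for (k in c(12, 24)) {
    tlf <- theory_line(n, k, "eq_full")
    expect_lt(abs(tlf$slope + tlf$intercept - 1), 0.03)
  }
  expect_error(theory_line(100, 0, "eq_limit"), "positive")
  expect_error(theory_line(100, 12, "eq_nope"))
})

test_that("sample_from_q hits degenerate and moment targets", {
  expect_equal(edge_count(sample_from_q(matrix(0, 20, 20), seed = 1)), 0)
  q1 <- matrix(1, 10, 10); diag(q1) <- 0
  expect_equal(edge_count(sample_from_q(q1, seed = 1)), choose(10, 2))

  # mean edge count across seeds within 3 sigma of sum(q)
  n <- 30
  q <- chung_lu_q_matrix(powerlaw_degrees(n, 6))
  mu <- sum(q[upper.tri(q)])
  sd1 <- sqrt(sum(q[upper.tri(q)] * (1 - q[upper.tri(q)])))
  es <- vapply(1:200, function(s) edge_count(sample_from_q(q, seed = s)),
               numeric(1))
  expect_lt(abs(mean(es) - mu), 3 * sd1 / sqrt(200))
})
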