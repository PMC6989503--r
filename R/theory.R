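#' Validate a link-probability matrix Q
#'
#' @param Q symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @return Invisibly the matrix, after checks.
#' @keywords internal
validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  if (any(Q < 0 | Q > 1)) stop("Q entries must be in [0, 1]")
  if (any(abs(Q - t(Q)) > 1e-12)) stop("Q must be symmetric")
  if (any(diag(Q) != 0)) stop("Q must have a zero diagonal")
  invisible(Q)
}

upper_tri_q <- function(Q) Q[upper.tri(Q)]

q_avg_degree <- function(Q) 2 * sum(upper_tri_q(Q)) / nrow(Q)

#' The U term of an edge-independent random graph
#'
#' \eqn{U = -\sum_{i>j} q_{ij} \log_2 q_{ij}} (with `0 log 0 = 0`), the
#' linear-order part of the structural entropy of the model Q.
#'
#' @param Q link-probability matrix.
#' @return U in bits.
#' @export
u_term <- function(Q) {
  validate_q(Q)
  q <- upper_tri_q(Q)
  q <- q[q > 0]
  -sum(q * log2(q))
}

#' Structural entropy of an edge-independent random graph
#'
#' Exact form \eqn{\sum_{i>j} h(q_{ij}) - N \log_2 N} and its first-order
#' Taylor approximation \eqn{U - N \log_2 N + N \langle k \rangle / (2 \ln 2)}
#' (accurate for sparse Q).  This is the expected shortest compression
#' length of networks sampled from Q.
#'
#' @param Q link-probability matrix.
#' @return List with `exact`, `approx` (both bits), `k_avg` and a
#'   `nonpositive` flag (set, with a warning, when the exact value is <= 0
#'   and therefore unusable as a normalizer).
#' @export
structural_entropy <- function(Q) {
  validate_q(Q)
  n <- nrow(Q)
  k <- q_avg_degree(Q)
  exact <- sum(binary_entropy(upper_tri_q(Q))) - n * log2(n)
  approx <- u_term(Q) - n * log2(n) + n * k / (2 * log(2))
  nonpos <- exact <= 0
  if (nonpos) warning("structural entropy is non-positive; Q is too sparse/dense")
  list(exact = exact, approx = approx, k_avg = k, nonpositive = nonpos)
}

#' Entropy of the link-probability distribution H_Q
#'
#' Shannon entropy (bits) of the upper-triangle entries of Q normalized to a
#' probability distribution over pairs.
#'
#' @param Q link-probability matrix with positive total mass.
#' @return H_Q in bits.
#' @export
q_entropy <- function(Q) {
  validate_q(Q)
  q <- upper_tri_q(Q)
  s <- sum(q)
  if (s <= 0) stop("Q has no mass")
  p <- q[q > 0] / s
  -sum(p * log2(p))
}

#' Coarse-grained entropy of Q
#'
#' Sorts the upper-triangle link probabilities in descending order, groups
#' consecutive runs of N values (the last group may be short), replaces each
#' group by its total mass, and returns the entropy of the resulting
#' distribution.  For uniform Q (and N dividing the pair count) this equals
#' `q_entropy(Q) - log2(N)` exactly, and it approximates the rank entropy of
#' the theoretical best predicting algorithm.
#'
#' @param Q link-probability matrix.
#' @param n group width; defaults to `nrow(Q)`.
#' @return Coarse-grained entropy in bits.
#' @export
coarse_grained_entropy <- function(Q, n = nrow(Q)) {
  validate_q(Q)
  q <- sort(upper_tri_q(Q), decreasing = TRUE)
  s <- sum(q)
  if (s <= 0) stop("Q has no mass")
  grp <- ceiling(seq_along(q) / n)
  mass <- as.numeric(tapply(q, grp, sum)) / s
  mass <- mass[mass > 0]
  -sum(mass * log2(mass))
}

#' Analytic rank entropy of the theoretical best predicting algorithm
#'
#' \deqn{H_{TBPA} \approx \frac{2}{N \langle k \rangle} U +
#'       \log_2 \frac{\langle k \rangle}{2}}
#' with \eqn{\langle k \rangle} taken from Q (an expectation, not a sampled
#' graph), and the normalized \eqn{H^*_{TBPA} = H_{TBPA} / (\log_2 N - 1)}.
#'
#' @param Q link-probability matrix with positive average degree.
#' @return List with `H` (bits) and `H_star`.
#' @export
h_tbpa_analytic <- function(Q) {
  validate_q(Q)
  n <- nrow(Q)
  k <- q_avg_degree(Q)
  if (k <= 0) stop("average degree of Q is zero")
  H <- 2 / (n * k) * u_term(Q) + log2(k / 2)
  list(H = H, H_star = H / (log2(n) - 1))
}

#' Sampled rank entropy of the theoretical best predicting algorithm
#'
#' Samples graphs from Q; for each sampled edge, ranks its probability
#' `q_e` (descending) among the probabilities of all non-links of the
#' sampled graph plus the edge itself, and bins the ranks with width N.
#' The binned distributions are averaged across the `samples` draws and the
#' entropy of the averaged distribution is returned (averaging first
#' removes the downward finite-sample bias of per-draw entropies; per-draw
#' entropies are also reported).  Equal probabilities are ranked in seeded
#' uniform-random order by default (`ties = "midrank"` gives the
#' deterministic tie-corrected rank instead; see the package vignette for
#' why random order is the default).
#'
#' @param Q link-probability matrix.
#' @param seed integer seed.
#' @param samples number of sampled graphs (default 20).
#' @param ties `"random"` or `"midrank"`.
#' @return List with `H` (mean bits over samples), `H_star`, `per_sample`.
#' @export
h_tbpa_numeric <- function(Q, seed = 1, samples = 20,
                           ties = c("random", "midrank")) {
  ties <- match.arg(ties)
  validate_q(Q)
  n <- nrow(Q)
  q <- upper_tri_q(Q)
  with_seed(seed, {
    p_avg <- NULL
    per_sample <- numeric(samples)
    for (s in seq_len(samples)) {
      edge <- logical(length(q))
      for (try in 1:50) {
        edge <- stats::runif(length(q)) < q
        if (any(edge)) break
      }
      if (!any(edge)) stop("Q produced empty graphs in 50 attempts")
      # rank each sampled edge among non-link probabilities plus itself
      r <- rank_among_nonlinks(q, edge, ties)
      d <- bin_ranks(r, n, m = sum(!edge) + 1)
      per_sample[s] <- distribution_entropy(d)
      p <- d$p
      if (is.null(p_avg)) p_avg <- p
      else {
        len <- max(length(p_avg), length(p))
        p_avg <- c(p_avg, rep(0, len - length(p_avg))) +
          c(p, rep(0, len - length(p)))
      }
    }
    p_avg <- p_avg / samples
    H <- distribution_entropy(p_avg)
    list(H = H, H_star = H / (log2(n) - 1), per_sample = per_sample)
  })
}

# For each linked pair e: rank of q_e among {q of non-links} + e itself.
rank_among_nonlinks <- function(q, edge, ties) {
  qe <- q[edge]
  qn <- q[!edge]
  qns <- sort(qn, decreasing = TRUE)
  n_ge <- findInterval(-qe, -qns)               # non-links with q >= qe
  n_gt <- findInterval(-qe, -qns, left.open = TRUE) # non-links with q > qe
  tied <- n_ge - n_gt + 1 # + the edge itself
  if (ties == "random") {
    n_gt + floor(stats::runif(length(qe)) * tied) + 1
  } else {
    n_gt + (tied + 1) / 2
  }
}

#' Theoretical line relating L* and H*_TBPA
#'
#' Slope and intercept of the linear law for edge-independent random
#' graphs, in three nested approximations: the full finite-size form
#' (`"eq_full"`), the large-N simplification (`"eq_largeN"`, slope
#' `1 - 2/k - log2(k)/log2(N)`), and the thermodynamic limit (`"eq_limit"`,
#' slope `1 - 2/k`).  The last two satisfy slope + intercept = 1 exactly:
#' the Erdos-Renyi point (1, 1) is on the line.
#'
#' @param n node count.
#' @param k average degree (> 0).
#' @param variant `"eq_full"`, `"eq_largeN"` or `"eq_limit"`.
#' @return A `theory_line` list with `slope`, `intercept`, `variant`, `n`, `k`.
#' @export
theory_line <- function(n, k, variant = c("eq_full", "eq_largeN", "eq_limit")) {
  variant <- match.arg(variant)
  if (k <= 0) stop("k must be positive")
  if (variant == "eq_full") {
    e <- k * n / 2
    r <- max_compression_length(n, e) # errors when the ceiling is <= 0
    slope <- 2 * r / (k * n * log2(n / 2))
    intercept <- (2 * log2(n) / k + log2(k / 2) - 1 / log(2)) / log2(n / 2)
  } else if (variant == "eq_largeN") {
    slope <- 1 - 2 / k - log2(k) / log2(n)
    intercept <- 2 / k + log2(k) / log2(n)
  } else {
    slope <- 1 - 2 / k
    intercept <- 2 / k
  }
  structure(list(slope = slope, intercept = intercept, variant = variant,
                 n = n, k = k), class = "theory_line")
}

#' @export
print.theory_line <- function(x, ...) {
  cat(sprintf("theory_line [%s]: H* = %.4f L* + %.4f  (N = %g, <k> = %g)\n",
              x$variant, x$slope, x$intercept, x$n, x$k))
  invisible(x)
}

#' Sample a graph from a link-probability matrix
#'
#' Independent Bernoulli(q_ij) draw per pair.
#'
#' @param Q link-probability matrix.
#' @param seed integer seed.
#' @return A `net_graph`.
#' @export
sample_from_q <- function(Q, seed = 1) {
  validate_q(Q)
  n <- nrow(Q)
  with_seed(seed, {
    q <- upper_tri_q(Q)
    hit <- which(stats::runif(length(q)) < q)
    ut <- which(upper.tri(Q), arr.ind = TRUE)
    net_graph(n, ut[hit, , drop = FALSE])
  })
}
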