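#' Construct an undirected simple graph
#'
#' The basic container of the package: a simple undirected graph on nodes
#' `1..n` with an edge matrix in canonical form (each row `u < v`, rows
#' sorted, no duplicates, no self-loops).  Original node labels, if any,
#' are retained so that file writers can round-trip them.
#'
#' @param n number of nodes (integer, >= 1).
#' @param edges two-column matrix (or empty) of node indices in `1..n`.
#' @param labels character vector of length `n` with the original node
#'   labels; defaults to `as.character(1:n)`.
#' @return An object of class `net_graph` with elements `n`, `edges`
#'   (canonical integer matrix) and `labels`.
#' @examples
#' g <- net_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' degree_sequence(g)
#' @export
net_graph <- function(n, edges = matrix(integer(), 0, 2), labels = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1, n >= 1)
  edges <- canonical_edges(n, edges)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  stopifnot(length(labels) == n)
  structure(list(n = n, edges = edges, labels = labels), class = "net_graph")
}

canonical_edges <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint outside 1..n")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    key <- (edges[, 1] - 1) * n + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]
  }
  dimnames(edges) <- NULL
  edges
}

#' @export
print.net_graph <- function(x, ...) {
  cat(sprintf("net_graph: N = %d, E = %d, <k> = %.3f, q = %.5f\n",
              x$n, nrow(x$edges), average_degree(x), edge_density(x)))
  invisible(x)
}

#' Number of edges
#' @param g a `net_graph`.
#' @return Integer edge count E.
#' @export
edge_count <- function(g) nrow(g$edges)

#' Degree sequence
#' @param g a `net_graph`.
#' @return Integer vector of node degrees \eqn{k_i}, length `g$n`.
#' @export
degree_sequence <- function(g) {
  tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = g$n)
}

#' Average degree 2E/N
#' @param g a `net_graph`.
#' @export
average_degree <- function(g) 2 * nrow(g$edges) / g$n

#' Edge density E / C(N,2)
#' @param g a `net_graph`.
#' @export
edge_density <- function(g) {
  if (g$n < 2) return(0)
  nrow(g$edges) / choose(g$n, 2)
}

edge_keys <- function(g) (g$edges[, 1] - 1) * g$n + g$edges[, 2]

keys_to_edges <- function(keys, n) {
  cbind(as.integer((keys - 1) %/% n) + 1L, as.integer((keys - 1) %% n) + 1L)
}

# keys of all C(n,2) pairs would be too large to materialise for big n;
# vacant pairs are sampled by rejection instead (see sample_vacant_pairs).

sample_vacant_pairs <- function(g, m) {
  # uniform sample (without replacement) of m non-edges of g
  n <- g$n
  total <- choose(n, 2)
  e <- nrow(g$edges)
  if (m > total - e) stop("not enough vacant pairs")
  occupied <- edge_keys(g)
  if (total <= 4 * (e + m) || total <= 1e6) {
    u <- rep(seq_len(n - 1), times = (n - 1):1)
    v <- sequence((n - 1):1, from = 2) + rep(seq_len(n - 1) - 1L, (n - 1):1)
    keys <- (u - 1) * n + v
    vacant <- setdiff(keys, occupied)
    pick <- sample(length(vacant), m)
    return(keys_to_edges(vacant[pick], n))
  }
  got <- integer(0)
  while (length(got) < m) {
    cand_u <- sample.int(n, 2 * (m - length(got)) + 16, replace = TRUE)
    cand_v <- sample.int(n, length(cand_u), replace = TRUE)
    ok <- cand_u != cand_v
    a <- pmin(cand_u, cand_v)[ok]
    b <- pmax(cand_u, cand_v)[ok]
    k <- (a - 1) * n + b
    k <- setdiff(k, c(occupied, got))
    got <- c(got, k)
  }
  keys_to_edges(got[seq_len(m)], n)
}

#' Warn when a graph leaves the validity band of the compression law
#'
#' The linear law between normalized compression length and rank entropy is
#' derived for networks with `ln N << <k> << N - ln N`.  Outside that band
#' the normalizing ceiling becomes small or negative and the law is not
#' expected to hold.
#'
#' @param g a `net_graph`.
#' @return Invisibly, `TRUE` when inside the band; otherwise `FALSE`, with a
#'   warning describing which side was violated.
#' @export
check_validity_band <- function(g) {
  k <- average_degree(g)
  lo <- log(g$n)
  hi <- g$n - log(g$n)
  ok <- (k > lo) && (k < hi)
  if (k <= lo)
    warning(sprintf("average degree %.2f <= ln N = %.2f: network too sparse for the law", k, lo))
  if (k >= hi)
    warning(sprintf("average degree %.2f >= N - ln N = %.2f: network too dense for the law", k, hi))
  invisible(ok)
}

# ------------------------------------------------------------------ I/O --

#' Read a whitespace-delimited edge list
#'
#' Lines starting with `#` are comments.  The first two tokens of each line
#' are node labels (arbitrary strings); extra columns (e.g. weights) are
#' ignored with a warning.  Nodes are relabeled to contiguous indices with
#' the original labels retained in the returned graph.  Duplicate edges are
#' deduplicated silently; self-loops are dropped and counted in a warning.
#'
#' @param path file path.
#' @return A `net_graph`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2)
  if (length(bad))
    stop(sprintf("parse error at line %d: fewer than 2 tokens", idx[bad[1]]))
  if (any(vapply(toks, length, 1L) > 2))
    warning("extra columns ignored (networks are treated as unweighted)")
  a <- vapply(toks, `[`, "", 1)
  b <- vapply(toks, `[`, "", 2)
  labels <- unique(c(a, b))
  u <- match(a, labels)
  v <- match(b, labels)
  loops <- u == v
  if (any(loops))
    warning(sprintf("%d self-loop(s) dropped", sum(loops)))
  u <- u[!loops]
  v <- v[!loops]
  n <- length(labels)
  key <- unique((pmin(u, v) - 1) * n + pmax(u, v))
  net_graph(n, keys_to_edges(key, n), labels = labels)
}

#' Write a graph as a plain edge list
#' @param g a `net_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d E=%d", g$n, nrow(g$edges)), con)
  if (nrow(g$edges))
    writeLines(paste(g$labels[g$edges[, 1]], g$labels[g$edges[, 2]]), con)
  invisible(path)
}

#' Convert to / from igraph
#'
#' The original labels travel as the `name` vertex attribute, so GraphML
#' round-trips preserve the relabeling map.
#' @param g a `net_graph`.
#' @return `as_igraph`: an igraph object; `from_igraph`: a `net_graph`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  igraph::set_vertex_attr(ig, "name", value = g$labels)
}

#' @rdname as_igraph
#' @param ig an igraph object (coerced to simple undirected).
#' @export
from_igraph <- function(ig) {
  ig <- igraph::as_undirected(igraph::simplify(ig))
  labels <- igraph::vertex_attr(ig, "name")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(ig)))
  net_graph(igraph::vcount(ig), igraph::as_edgelist(ig, names = FALSE),
            labels = as.character(labels))
}

#' Read / write GraphML
#' @param path file path.
#' @return `read_graphml`: a `net_graph`.
#' @export
read_graphml <- function(path) from_igraph(igraph::read_graph(path, format = "graphml"))

#' @rdname read_graphml
#' @param g a `net_graph`.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

# ------------------------------------------------------------ generators --

#' Erdos-Renyi random graph with a fixed number of edges, G(N, M)
#'
#' Exactly `e` edges drawn uniformly without replacement from all C(N,2)
#' pairs.  The fixed-edge-count convention is used (rather than Bernoulli
#' G(N,p)) because all normalizations in this package compare networks at
#' the same number of nodes and links.
#'
#' @param n node count.
#' @param e edge count, `0 <= e <= choose(n,2)`.
#' @param seed integer seed; all randomness flows from it.
#' @return A `net_graph`.
#' @examples
#' er_graph(50, 100, seed = 1)
#' @export
er_graph <- function(n, e, seed = 1) {
  total <- choose(n, 2)
  if (e < 0 || e > total) stop("edge count out of range [0, C(N,2)]")
  with_seed(seed, {
    g0 <- net_graph(n)
    if (e > 0) net_graph(n, sample_vacant_pairs(g0, e)) else g0
  })
}

#' Ring lattice ("circle model")
#'
#' Every node is linked to its `k_c` closest nodes on a circle (`k_c/2` on
#' each side), producing a maximally regular, highly compressible and
#' trivially predictable structure; used to probe where the randomness
#' assumptions of the compression law break down.
#'
#' @param n node count.
#' @param k_c even neighbour count, `2 <= k_c < n`.
#' @return A `net_graph` with `E = n * k_c / 2` and all degrees `k_c`.
#' @examples
#' circle_model(10, 4)
#' @export
circle_model <- function(n, k_c) {
  if (k_c %% 2 != 0) stop("k_c must be even")
  if (k_c < 2 || k_c >= n) stop("k_c must satisfy 2 <= k_c < n")
  i <- rep(seq_len(n), each = k_c / 2)
  d <- rep(seq_len(k_c / 2), times = n)
  j <- ((i - 1 + d) %% n) + 1
  net_graph(n, cbind(i, j))
}

#' Chung-Lu link-probability matrix from a degree sequence
#'
#' Edge-independent random-graph model in which pair (i, j) is linked with
#' probability `q_ij = min(1, k_i * k_j / sum(k))`, so that expected degrees
#' match the prescribed sequence whenever no entry is capped.
#'
#' @param degrees non-negative integer (or numeric) target degrees; the sum
#'   must be even and positive.
#' @return Symmetric N x N matrix with zero diagonal, entries in \[0, 1\].
#' @examples
#' chung_lu_q_matrix(c(3, 1, 1, 1))
#' @export
chung_lu_q_matrix <- function(degrees) {
  if (any(degrees < 0)) stop("degrees must be non-negative")
  s <- sum(degrees)
  if (s <= 0) stop("all-zero degree sequence")
  if (s %% 2 != 0) stop("degree sum must be even")
  q <- outer(degrees, degrees) / s
  q[q > 1] <- 1
  diag(q) <- 0
  unname(q)
}

#' Sample a Chung-Lu graph from a degree sequence
#' @inheritParams chung_lu_q_matrix
#' @param seed integer seed.
#' @return A `net_graph` drawn from [chung_lu_q_matrix()] probabilities.
#' @export
chung_lu_graph <- function(degrees, seed = 1) {
  sample_from_q(chung_lu_q_matrix(degrees), seed = seed)
}

#' Deterministic power-law-ish degree sequence
#'
#' Quantile construction `k_i ~ ((i - 0.5)/n)^(-1/(gamma-1))`, rescaled to a
#' target average degree and capped at `sqrt(2E)` (the standard Chung-Lu cap
#' keeping all `q_ij <= 1`), with the sum adjusted to be even.  Deterministic
#' given its arguments, which makes ensemble sweeps reproducible without
#' extra seeds.
#'
#' @param n node count.
#' @param k_target desired average degree.
#' @param gamma power-law exponent (> 2 for a finite mean), default 2.5.
#' @return Integer degree vector of length `n` with an even, positive sum.
#' @export
powerlaw_degrees <- function(n, k_target, gamma = 2.5) {
  u <- (seq_len(n) - 0.5) / n
  raw <- u^(-1 / (gamma - 1))
  k <- raw * (k_target / mean(raw))
  cap <- sqrt(k_target * n) # sqrt(2E) with E = n k / 2
  k <- pmin(k, cap)
  # rescale the uncapped part so the mean survives the cap
  for (it in 1:20) {
    excess <- n * k_target - sum(k)
    free <- k < cap
    if (abs(excess) < 0.5 || !any(free)) break
    k[free] <- pmin(k[free] * (1 + excess / sum(k[free])), cap)
  }
  k <- pmax(1L, as.integer(round(k)))
  if (sum(k) %% 2 != 0) k[which.min(k)] <- k[which.min(k)] + 1L
  sort(k, decreasing = TRUE)
}

# --------------------------------------------------------- perturbations --

#' Shuffle a fraction of links
#'
#' Removes `round(f * E)` edges chosen uniformly at random and adds the same
#' number of uniformly random vacant pairs (replacement edges may coincide
#' with removed ones), preserving N and E.  At `f = 1` the result is
#' distributed as an Erdos-Renyi G(N, E) graph.
#'
#' @param g a `net_graph`.
#' @param f fraction in \[0, 1\] of links to rewire; the count is
#'   `floor(f * E + 0.5)` (round-half-up).
#' @param seed integer seed.
#' @return A `net_graph` with the same N and E.
#' @export
shuffle_links <- function(g, f, seed = 1) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  e <- nrow(g$edges)
  m <- floor(f * e + 0.5)
  if (m == 0) return(g)
  with_seed(seed, {
    drop <- sample.int(e, m)
    kept <- net_graph(g$n, g$edges[-drop, , drop = FALSE], labels = g$labels)
    add <- sample_vacant_pairs(kept, m)
    net_graph(g$n, rbind(kept$edges, add), labels = g$labels)
  })
}

#' Randomly add or remove links
#'
#' @param g a `net_graph`.
#' @param mode `"add"` or `"remove"`.
#' @param m number of links to add/remove; alternatively give `f`, a
#'   fraction of E (remove) or of vacant pairs (add).
#' @param f optional fraction used when `m` is missing.
#' @param seed integer seed.
#' @return A `net_graph` on the same node set.
#' @export
perturb_links <- function(g, mode = c("add", "remove"), m = NULL, f = NULL,
                          seed = 1) {
  mode <- match.arg(mode)
  e <- nrow(g$edges)
  vacant <- choose(g$n, 2) - e
  if (is.null(m)) {
    if (is.null(f)) stop("give either m or f")
    m <- floor(f * (if (mode == "remove") e else vacant) + 0.5)
  }
  if (m < 0) stop("m must be non-negative")
  if (mode == "remove" && m > e) stop("cannot remove more links than E")
  if (mode == "add" && m > vacant) stop("cannot add more links than vacant pairs")
  if (m == 0) return(g)
  with_seed(seed, {
    if (mode == "remove") {
      drop <- sample.int(e, m)
      net_graph(g$n, g$edges[-drop, , drop = FALSE], labels = g$labels)
    } else {
      add <- sample_vacant_pairs(g, m)
      net_graph(g$n, rbind(g$edges, add), labels = g$labels)
    }
  })
}

#' Combine two edge-disjoint graphs on the same node set
#'
#' Union of the two edge sets.  Overlapping edges are an error rather than
#' being deduplicated: the additivity property of compression lengths is
#' only well-posed for independent, non-overlapping link sets.
#'
#' @param ga,gb `net_graph`s with equal `n`.
#' @return A `net_graph` with `E = E_A + E_B`.
#' @export
combine_graphs <- function(ga, gb) {
  if (ga$n != gb$n) stop("graphs must share the same node set")
  ka <- edge_keys(ga)
  kb <- edge_keys(gb)
  if (length(intersect(ka, kb)))
    stop("edge sets overlap; combine requires disjoint link sets")
  net_graph(ga$n, rbind(ga$edges, gb$edges), labels = ga$labels)
}

# ------------------------------------------------------------- utilities --

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
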