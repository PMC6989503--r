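#' Registered link-prediction algorithms
#'
#' The default suite of 11 similarity indices used to estimate the
#' best-performing-algorithm (BPAA) entropy: the neighbourhood indices
#' common neighbours (`cn`), resource allocation (`ra`), Adamic-Adar
#' (`aa`), `jaccard`, `salton` and preferential attachment (`pa`), which
#' have a fast shared C++ leave-one-out path; and the global indices local
#' path (`lp`), `katz`, average commute time (`act`), local random walk
#' (`lrw`) and the structural perturbation method (`spm`), which score via
#' dense spectral linear algebra and are intended for moderate network
#' sizes.
#'
#' @return Character vector of algorithm names.
#' @export
lp_algorithms <- function() {
  c(local_algorithms(), "lp", "katz", "act", "lrw", "spm")
}

local_algorithms <- function() c("cn", "ra", "aa", "jaccard", "salton", "pa")

adjacency_matrix <- function(g) {
  a <- matrix(0, g$n, g$n)
  if (nrow(g$edges)) {
    a[g$edges] <- 1
    a[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  a
}

# ------------------------------------------------------------- scorers --
# Each scorer returns a symmetric N x N score matrix; higher = more likely
# link.  Diagonals are meaningless and never read.

score_matrix <- function(a, algorithm, params = list()) {
  deg <- rowSums(a)
  n <- nrow(a)
  switch(algorithm,
    cn = a %*% a,
    ra = {
      w <- ifelse(deg > 0, 1 / deg, 0)
      a %*% (w * a)
    },
    aa = {
      w <- ifelse(deg > 1, 1 / log(deg), 0)
      a %*% (w * a)
    },
    jaccard = {
      cn <- a %*% a
      denom <- outer(deg, deg, "+") - cn
      ifelse(denom > 0, cn / denom, 0)
    },
    salton = {
      cn <- a %*% a
      denom <- sqrt(outer(deg, deg))
      ifelse(denom > 0, cn / denom, 0)
    },
    pa = outer(deg, deg),
    lp = {
      eps <- params$eps %||% 0.001
      a2 <- a %*% a
      a2 + eps * a2 %*% a
    },
    katz = {
      lmax <- max(abs(eigen(a, symmetric = TRUE, only.values = TRUE)$values))
      beta <- params$beta %||% (if (lmax > 0) 0.5 / lmax else 0.5)
      if (lmax > 0 && beta >= 1 / lmax)
        stop("katz beta must be < 1/lambda_max for the series to converge")
      solve(diag(n) - beta * a) - diag(n)
    },
    act = {
      lap <- diag(deg) - a
      e <- eigen(lap, symmetric = TRUE)
      keep <- e$values > 1e-10 * max(e$values, 1)
      lp_ <- e$vectors[, keep, drop = FALSE] %*%
        (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
      d <- diag(lp_)
      denom <- outer(d, d, "+") - 2 * lp_
      ifelse(denom > 1e-12, 1 / denom, 0)
    },
    lrw = {
      t_steps <- params$t %||% 3
      e2 <- sum(deg)
      if (e2 == 0) return(matrix(0, n, n))
      p <- ifelse(deg > 0, 1 / deg, 0) * a
      pt <- p
      if (t_steps > 1) for (i in seq_len(t_steps - 1)) pt <- pt %*% p
      m <- (deg / e2) * pt
      m + t(m)
    },
    spm = score_spm(a, params),
    stop("unknown algorithm: ", algorithm)
  )
}

# Structural perturbation method: remove a fraction of links, first-order
# eigen-perturbation of the reduced adjacency, reconstruct, average over
# independent perturbation sets.  Near-degenerate eigenvalues (relative gap
# < 1e-10) are handled as a block by re-diagonalising the perturbation
# inside the degenerate eigenspace.
score_spm <- function(a, params = list()) {
  frac <- params$frac %||% 0.1
  reps <- params$reps %||% 10
  n <- nrow(a)
  ut <- which(upper.tri(a) & a > 0)
  e <- length(ut)
  if (e < 2) return(a %*% a) # degenerate graph: fall back to CN shape
  m <- max(1, round(frac * e))
  acc <- matrix(0, n, n)
  for (rep in seq_len(reps)) {
    drop <- sample(ut, m)
    da <- matrix(0, n, n)
    da[drop] <- 1
    da <- da + t(da)
    ar <- a - da
    eg <- eigen(ar, symmetric = TRUE)
    vals <- eg$values
    vecs <- eg$vectors
    scale <- max(abs(vals), 1)
    blocks <- cumsum(c(1, diff(vals) < -1e-10 * scale)) # descending order
    dl <- numeric(n)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      if (length(idx) == 1) {
        dl[idx] <- drop(t(vecs[, idx]) %*% da %*% vecs[, idx])
      } else {
        sub <- t(vecs[, idx]) %*% da %*% vecs[, idx]
        se <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
        vecs[, idx] <- vecs[, idx] %*% se$vectors
        dl[idx] <- se$values
      }
    }
    acc <- acc + vecs %*% ((vals + dl) * t(vecs))
  }
  acc / reps
}

#' Score candidate node pairs
#'
#' @param g a `net_graph`.
#' @param pairs two-column matrix of node index pairs to score (typically
#'   non-adjacent pairs, optionally including one probe pair).
#' @param algorithm one of [lp_algorithms()].
#' @param params named list of algorithm parameters (e.g. `beta` for katz,
#'   `t` for lrw, `frac`/`reps` for spm, `eps` for lp).
#' @param seed seed for stochastic algorithms (spm).
#' @return A `score_table` data.frame with columns `u`, `v`, `score`.
#' @examples
#' g <- net_graph(4, rbind(c(1,2), c(2,3), c(3,4), c(1,4), c(1,3)))
#' score_pairs(g, cbind(2, 4), "cn")   # two common neighbours
#' @export
score_pairs <- function(g, pairs, algorithm, params = list(), seed = 1) {
  if (!algorithm %in% lp_algorithms()) stop("unknown algorithm: ", algorithm)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  s <- with_seed(seed, score_matrix(adjacency_matrix(g), algorithm, params))
  out <- data.frame(u = pairs[, 1], v = pairs[, 2], score = s[pairs])
  attr(out, "algorithm") <- algorithm
  class(out) <- c("score_table", class(out))
  out
}

#' Leave-one-out rank sequence of the existing links
#'
#' For every edge e of the graph: remove it, score all unlinked pairs of
#' the reduced graph (a candidate set of size `M = C(N,2) - E + 1` that
#' contains e itself), and record the descending-score rank of e.  The
#' graph is restored after each removal; ranks are returned in input edge
#' order.
#'
#' Ties: with `ties = "random"` (default) equal scores are ordered by a
#' seeded uniform-random permutation of the tie block, which reproduces the
#' uniform rank distribution expected on Erdos-Renyi graphs; `"midrank"`
#' gives the deterministic tie-corrected rank
#' \eqn{r = higher + (tied + 1)/2} instead.
#'
#' @param g a `net_graph` with at least one edge.
#' @param algorithm one of [lp_algorithms()].
#' @param params algorithm parameters, as in [score_pairs()].
#' @param seed integer seed.
#' @param ties `"random"` or `"midrank"`.
#' @return A `rank_sequence`: `r` (one rank per edge), `m`, `algorithm`.
#' @export
leave_one_out_ranks <- function(g, algorithm, params = list(), seed = 1,
                                ties = c("random", "midrank")) {
  ties <- match.arg(ties)
  if (nrow(g$edges) < 1) stop("graph has no edges")
  if (algorithm %in% local_algorithms() && length(params) == 0)
    return(loo_ranks_local(g, algorithm, seed = seed, ties = ties)[[algorithm]])
  a <- adjacency_matrix(g)
  m <- choose(g$n, 2) - nrow(g$edges) + 1
  with_seed(seed, {
    r <- vapply(seq_len(nrow(g$edges)), function(i) {
      u <- g$edges[i, 1]
      v <- g$edges[i, 2]
      a[u, v] <- 0 # local copy: the package-level graph is untouched
      a[v, u] <- 0
      s <- tryCatch(score_matrix(a, algorithm, params), error = function(e)
        stop(sprintf("algorithm %s failed on removal of edge (%d,%d): %s",
                     algorithm, u, v, conditionMessage(e)), call. = FALSE))
      cand <- upper.tri(a) & a == 0
      sc <- s[cand]
      se <- s[u, v]
      higher <- sum(sc > se)
      tied <- sum(sc == se)
      if (ties == "random") higher + floor(stats::runif(1) * tied) + 1
      else higher + (tied + 1) / 2
    }, numeric(1))
    new_rank_sequence(r, m, algorithm)
  })
}

new_rank_sequence <- function(r, m, algorithm) {
  stopifnot(all(r >= 1), all(r <= m))
  structure(list(r = r, m = m, algorithm = algorithm), class = "rank_sequence")
}

#' @export
print.rank_sequence <- function(x, ...) {
  cat(sprintf("rank_sequence [%s]: E = %d, M = %g, mean r = %.1f\n",
              x$algorithm, length(x$r), x$m, mean(x$r)))
  invisible(x)
}

#' Leave-one-out ranks for all neighbourhood indices in one sweep
#'
#' The six local indices share the neighbourhood-intersection computation,
#' so a single C++ pass ranks all of them.
#'
#' @param g a `net_graph`.
#' @param algorithms subset of `c("cn","ra","aa","jaccard","salton","pa")`.
#' @param seed integer seed.
#' @param ties `"random"` or `"midrank"`.
#' @return Named list of `rank_sequence` objects.
#' @export
loo_ranks_local <- function(g, algorithms = local_algorithms(), seed = 1,
                            ties = c("random", "midrank")) {
  ties <- match.arg(ties)
  bad <- setdiff(algorithms, local_algorithms())
  if (length(bad)) stop("not a local algorithm: ", paste(bad, collapse = ", "))
  if (nrow(g$edges) < 1) stop("graph has no edges")
  rk <- with_seed(seed, cpp_loo_local(g$n, g$edges - 1L, ties == "random"))
  m <- choose(g$n, 2) - nrow(g$edges) + 1
  stats::setNames(
    lapply(algorithms, function(a) new_rank_sequence(unname(rk[, a]), m, a)),
    algorithms)
}
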