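#' Constants of the empirical prediction law
#'
#' The linear law `H* = slope * L* + intercept` fitted across empirical
#' networks (slope 1.63, intercept -0.63; the line passes through the
#' Erdos-Renyi point (1, 1)).  The constants can be overridden for
#' re-fitted laws via `options(netpred.law = c(slope, intercept))`.
#'
#' @return Named numeric vector `c(slope = , intercept = )`.
#' @export
prediction_law <- function() {
  law <- getOption("netpred.law", c(slope = 1.63, intercept = -0.63))
  stats::setNames(as.numeric(law), c("slope", "intercept"))
}

#' Bin a rank sequence into width-N intervals
#'
#' Rank r falls into bin `ceiling(r / n)` (fractional tie-corrected ranks
#' use the same formula), giving about N/2 bins over the candidate range
#' `1..M`; `p_j` are observed proportions (no smoothing).  Binning by a
#' width equal to the network size removes the contribution of N to the
#' entropy.
#'
#' @param d ranks: a `rank_sequence` from [leave_one_out_ranks()] or a
#'   numeric vector (then give `m`).
#' @param n bin width = node count.
#' @param m candidate-set size `M = C(N,2) - E + 1` (taken from a
#'   `rank_sequence` automatically).
#' @return A `binned_ranks` object: `p` (probabilities summing to 1),
#'   `bins`, `width`, `m`.
#' @export
bin_ranks <- function(d, n, m = NULL) {
  if (inherits(d, "rank_sequence")) {
    if (is.null(m)) m <- d$m
    d <- d$r
  }
  if (is.null(m)) stop("candidate-set size m is required for bare rank vectors")
  if (any(d < 1 | d > m)) stop("rank outside [1, M]")
  bins <- ceiling(m / n)
  j <- pmin(ceiling(d / n), bins)
  p <- tabulate(j, nbins = bins) / length(d)
  structure(list(p = p, bins = bins, width = n, m = m), class = "binned_ranks")
}

#' Shannon entropy of a binned rank distribution
#'
#' @param p a `binned_ranks` object or a probability vector (summing to 1).
#' @return Entropy in bits, with `0 log 0 = 0`.
#' @export
distribution_entropy <- function(p) {
  if (inherits(p, "binned_ranks")) p <- p$p
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("not a probability distribution")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalize a rank entropy by the Erdos-Renyi baseline
#'
#' `H* = H / (log2(N) - 1)`; the denominator is the (closed-form) rank
#' entropy of an ER network of the same size, making H* comparable across
#' network sizes.
#'
#' @param h entropy in bits.
#' @param n node count (> 2).
#' @return H*.
#' @export
normalized_entropy <- function(h, n) {
  if (n <= 2) stop("normalization requires n > 2")
  h / (log2(n) - 1)
}

#' Best-performing-algorithm rank entropy (BPAA)
#'
#' Runs the leave-one-out ranking, width-N binning and entropy for each
#' algorithm, and reports the minimum entropy across algorithms as the
#' closest computable estimate of the network's intrinsic predictability.
#' Individual algorithm failures are recorded and skipped; the call fails
#' only if every algorithm fails.
#'
#' @param g a `net_graph`.
#' @param algorithms character vector of registered algorithm names (see
#'   [lp_algorithms()]); defaults to the fast neighbourhood-based set.
#' @param seed integer seed (tie order and stochastic algorithms).
#' @param ties tie-handling, see [leave_one_out_ranks()].
#' @param params optional named list of per-algorithm parameter lists.
#' @return A `predictability_estimate`: `H` (bits), `H_star`, `algorithm`
#'   (the argmin), `table` (per-algorithm H and H*), `errors`.
#' @export
bpaa <- function(g, algorithms = c("cn", "ra", "jaccard"), seed = 1,
                 ties = c("random", "midrank"), params = list()) {
  ties <- match.arg(ties)
  stopifnot(length(algorithms) >= 1)
  hs <- rep(NA_real_, length(algorithms))
  names(hs) <- algorithms
  errors <- list()
  local_set <- intersect(algorithms, local_algorithms())
  if (length(local_set) > 1) {
    # one C++ sweep scores all neighbourhood indices together
    rk <- tryCatch(loo_ranks_local(g, local_set, seed = seed, ties = ties),
                   error = function(e) e)
    if (inherits(rk, "error")) {
      errors[["local"]] <- conditionMessage(rk)
    } else {
      for (a in local_set)
        hs[a] <- distribution_entropy(bin_ranks(rk[[a]], g$n))
    }
  } else {
    local_set <- character()
  }
  for (a in setdiff(algorithms, local_set)) {
    res <- tryCatch({
      d <- leave_one_out_ranks(g, a, params = params[[a]] %||% list(),
                               seed = seed, ties = ties)
      distribution_entropy(bin_ranks(d, g$n))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[a]] <- conditionMessage(res)
    else hs[a] <- res
  }
  if (all(is.na(hs)))
    stop("all algorithms failed: ",
         paste(names(errors), unlist(errors), sep = ": ", collapse = "; "))
  best <- names(hs)[which.min(hs)]
  out <- list(H = unname(hs[best]),
              H_star = normalized_entropy(unname(hs[best]), g$n),
              algorithm = best,
              table = data.frame(algorithm = names(hs), H = unname(hs),
                                 H_star = normalized_entropy(unname(hs), g$n)),
              errors = errors, seed = seed, ties = ties)
  class(out) <- "predictability_estimate"
  out
}

#' @export
print.predictability_estimate <- function(x, ...) {
  cat(sprintf("BPAA: H = %.4f bits (H* = %.4f) via %s\n",
              x$H, x$H_star, x$algorithm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Signed distance of an algorithm's entropy from the empirical law
#'
#' `gap = H*_alg - (slope * L* + intercept)` with the law constants from
#' [prediction_law()].  Positive values quantify how far the algorithm is
#' from the best achievable performance at this compression length: room
#' left for better algorithms.
#'
#' @param l_star normalized compression length.
#' @param h_star_alg normalized rank entropy of the algorithm.
#' @return Signed gap.
#' @export
line_gap <- function(l_star, h_star_alg) {
  law <- prediction_law()
  unname(h_star_alg - (law[["slope"]] * l_star + law[["intercept"]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
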