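#' Target rank entropy implied by a compression length
#'
#' Inverts the empirical law: a network with normalized compression length
#' L* has (un-normalized) best-algorithm rank entropy
#' `(slope * L* + intercept) * (log2 N - 1)` bits.  Values below zero (very
#' compressible networks, outside the law's fitted range) are clamped to 0
#' with a warning.
#'
#' @param l_star normalized compression length.
#' @param n node count.
#' @return Entropy target in bits.
#' @export
target_entropy <- function(l_star, n) {
  law <- prediction_law()
  h <- (law[["slope"]] * l_star + law[["intercept"]]) * (log2(n) - 1)
  if (any(h < 0)) {
    warning("target entropy clamped to 0: L* below the root of the law")
    h <- pmax(h, 0)
  }
  h
}

# Entropy of the extremal "top block + uniform tail" distribution used by
# the upper bounds: top C bins hold P (uniformly), the remaining
# N/2 - C bins share 1 - P uniformly.  N/2 enters as a real number.
upper_bound_lhs <- function(p, n, c) {
  tailbins <- n / 2 - c
  -p * log2(p / c) - ifelse(p < 1, (1 - p) * log2((1 - p) / tailbins), 0)
}

bisect <- function(f, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(list(root = lo, iterations = 0, residual = 0))
  if (fhi == 0) return(list(root = hi, iterations = 0, residual = 0))
  if ((flo > 0) == (fhi > 0)) stop("bisection bracket does not straddle a root")
  it <- 0
  while (it < maxit && (hi - lo) > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.na(fm)) stop("bisection hit an undefined value")
    if ((fm > 0) == (flo > 0)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
      fhi <- fm
    }
    it <- it + 1
  }
  list(root = (lo + hi) / 2, iterations = it, residual = f((lo + hi) / 2))
}

#' Upper bound on top-C prediction precision at a given entropy
#'
#' Solves the implicit equation for the maximum achievable probability
#' `P_C` that a removed link ranks in the top C width-N intervals, over all
#' decreasing rank distributions with the target entropy:
#' \deqn{-\bar P \log_2(\bar P / C) - (1-\bar P) \log_2\frac{1-\bar P}{N/2 - C}
#'       = H}
#' on the branch `P >= 2C/N`, by bisection to |residual| <= 1e-10.
#' `upper_p1()` is the `C = 1` case.
#'
#' @param h_target entropy in bits, in `[0, log2(N/2)]` (for `upper_pc`,
#'   at most the entropy of the uniform distribution).
#' @param n node count.
#' @param c number of top intervals C, `1 <= C <= N/2`.
#' @return A `precision_bound` list: `bound`, plus solver diagnostics
#'   `iterations` and `residual`.
#' @export
upper_pc <- function(h_target, n, c = 1) {
  if (c < 1 || c > n / 2) stop("C must be in [1, N/2]")
  hmax <- log2(n / 2)
  if (h_target < 0 || h_target > hmax + 1e-12)
    stop("entropy target outside [0, log2(N/2)]")
  if (n / 2 - c < 1e-9) { # degenerate: all bins are "top" bins
    return(structure(list(bound = 1, c = c, n = n, h_target = h_target,
                          iterations = 0, residual = 0),
                     class = "precision_bound"))
  }
  if (h_target <= log2(c)) {
    # even all mass in the top C bins cannot push the entropy below log2(C):
    # the constraint is slack and the trivial bound 1 applies
    return(structure(list(bound = 1, c = c, n = n, h_target = h_target,
                          iterations = 0, residual = 0),
                     class = "precision_bound"))
  }
  f <- function(p) upper_bound_lhs(p, n, c) - h_target
  sol <- bisect(f, 2 * c / n, 1)
  structure(list(bound = sol$root, c = c, n = n, h_target = h_target,
                 iterations = sol$iterations, residual = sol$residual),
            class = "precision_bound")
}

#' @rdname upper_pc
#' @export
upper_p1 <- function(h_target, n) upper_pc(h_target, n, c = 1)

#' @export
print.precision_bound <- function(x, ...) {
  cat(sprintf("precision bound: %.6f (N = %g, C = %g, H = %.4f bits, %d iter, resid %.2e)\n",
              x$bound, x$n, x$c, x$h_target, x$iterations, x$residual))
  invisible(x)
}

#' Lower bound on top-1 precision (explicit form)
#'
#' `p1 >= 2^(-H)`: since every probability is at most p1, the entropy is at
#' least `log2(1/p1)`.  Explicit, and never violated by any feasible
#' decreasing distribution.
#'
#' @param h_target entropy in bits (>= 0).
#' @return The lower bound.
#' @export
lower_p1 <- function(h_target) {
  if (any(h_target < 0)) stop("entropy must be non-negative")
  2^(-h_target)
}

# Minimum entropy of a decreasing distribution on n/2 bins whose top-C mass
# is exactly p: top block (P - (C-1)x, x, ..., x), tail filled at level x
# (the cap) with one fractional remainder; minimized over x.
min_entropy_given_pc <- function(p, n, c) {
  xlx <- function(x) ifelse(x > 1e-300, x * log2(x), 0)
  tailbins <- n / 2 - c
  hx <- function(x) {
    p1 <- p - (c - 1) * x
    mfull <- floor((1 - p) / x + 1e-12)
    rem <- 1 - p - mfull * x
    if (mfull > tailbins || (mfull == tailbins && rem > 1e-12)) return(Inf)
    -xlx(p1) - (c - 1) * xlx(x) - mfull * xlx(x) - xlx(rem)
  }
  if (p >= 1 - 1e-15) {
    # all mass in the top block: most concentrated is p1 = 1
    return(0)
  }
  lo <- max((1 - p) / tailbins, 1e-12)
  hi <- p / c
  if (lo > hi) return(Inf) # infeasible: tail cannot absorb 1 - P
  if (hi - lo < 1e-11) return(hx(hi))
  opt <- stats::optimize(hx, c(lo, hi), tol = 1e-12)
  min(opt$objective, hx(lo), hx(hi))
}

#' Lower bound on top-C precision (numerical minimization)
#'
#' Minimizes `P_C` over decreasing rank distributions with the target
#' entropy, by a direct constrained search: a candidate `P` is feasible iff
#' the minimum entropy attainable at that `P` (top block plus tail capped
#' at `p_C`, the extremal configuration) does not exceed the target; the
#' smallest feasible `P` is found by bisection.  Consistent with
#' `lower_p1()` at `C = 1` up to the fractional-bin correction.
#'
#' @inheritParams upper_pc
#' @return A `precision_bound` list with solver diagnostics.
#' @export
lower_pc <- function(h_target, n, c = 1) {
  if (c < 1 || c > n / 2) stop("C must be in [1, N/2]")
  hmax <- log2(n / 2)
  if (h_target < 0 || h_target > hmax + 1e-12)
    stop("entropy target outside [0, log2(N/2)]")
  if (h_target == 0)
    return(structure(list(bound = 1, c = c, n = n, h_target = h_target,
                          iterations = 0, residual = 0),
                     class = "precision_bound"))
  f <- function(p) min_entropy_given_pc(p, n, c) - h_target
  lo <- 2 * c / n
  if (f(lo) <= 0) {
    # already feasible at the uniform point: bound is the uniform value
    return(structure(list(bound = lo, c = c, n = n, h_target = h_target,
                          iterations = 0, residual = f(lo)),
                     class = "precision_bound"))
  }
  sol <- bisect(function(p) if (is.finite(f(p))) f(p) else 1, lo, 1,
                tol = 1e-10)
  structure(list(bound = sol$root, c = c, n = n, h_target = h_target,
                 iterations = sol$iterations, residual = sol$residual),
            class = "precision_bound")
}

#' Empirical top-C precision of a rank sequence
#'
#' Bins the leave-one-out ranks with width N and returns the mass of the
#' top C bins: the fraction of removed links recovered among the top `C*N`
#' predictions.
#'
#' @param d a `rank_sequence` (or numeric ranks with `m` supplied).
#' @param n bin width = node count.
#' @param c number of top intervals.
#' @param m candidate-set size for bare rank vectors.
#' @return `P_C` in \[0, 1\].
#' @export
precision_from_ranks <- function(d, n, c = 1, m = NULL) {
  b <- bin_ranks(d, n, m = m)
  sum(b$p[seq_len(min(c, b$bins))])
}

#' Conservative value estimate of a network dataset
#'
#' \deqn{V \approx \Theta \cdot 2^{-(1.63 L/R - 0.63)(\log_2 N - 1)}}
#' The exponent is the entropy target implied by the compression length;
#' `V` equals `Theta * lower_p1(target_entropy(L/R, N))` exactly, i.e. the
#' external economic value discounted by the guaranteed top-interval
#' precision.  `Theta` may be given directly or as `theta * n_predictions`.
#'
#' @param l compression length in bits (e.g. `compression_length(g)$L`).
#' @param n node count.
#' @param e edge count.
#' @param theta external economic variable Theta (>= 0); alternatively a
#'   unit cost, combined with `n_predictions`.
#' @param n_predictions optional number of predicted interactions, in which
#'   case Theta = `theta * n_predictions`.
#' @return A `value_estimate` list: `V`, `Theta`, `L_star`, `h_target`.
#' @export
commercial_value <- function(l, n, e, theta, n_predictions = NULL) {
  if (theta < 0) stop("Theta must be non-negative")
  big_theta <- if (is.null(n_predictions)) theta else theta * n_predictions
  r <- max_compression_length(n, e)
  h <- target_entropy(l / r, n)
  structure(list(V = big_theta * 2^(-h), Theta = big_theta,
                 L_star = l / r, h_target = h, n = n, e = e),
            class = "value_estimate")
}

#' @export
print.value_estimate <- function(x, ...) {
  cat(sprintf("value_estimate: V = %.4g of Theta = %.4g (L* = %.4f, H = %.4f bits)\n",
              x$V, x$Theta, x$L_star, x$h_target))
  invisible(x)
}
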