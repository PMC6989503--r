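# independent oracle for the upper bounds: dense grid over the extremal
# family (top block uniform at P/C, tail uniform), pick the largest P whose
# maximum entropy still reaches the target
oracle_upper <- function(h, n, C = 1, grid_n = 2e5) {
  p <- seq(2 * C / n, 1, length.out = grid_n)
  hmax <- -p * log2(p / C) -
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n / 2 - C)), 0)
  max(p[hmax >= h])
}

# independent oracle for the lower bound: minimize P_C over decreasing
# distributions with entropy ~= h, optimizing unconstrained increments
# (any decreasing p is a tail-cumsum of non-negative increments)
oracle_lower <- function(h, n, C, starts = 8) {
  b <- floor(n / 2)
  best <- 1
  for (s in seq_len(starts)) {
    set.seed(100 + s)
    obj <- function(ld) {
      d <- exp(ld)
      p <- rev(cumsum(rev(d)))
      p <- p / sum(p)
      hh <- ref_entropy(p)
      sum(p[seq_len(C)]) + 50 * (hh - h)^2
    }
    o <- stats::optim(stats::rnorm(b, -3, 2), obj, method = "BFGS",
                      control = list(maxit = 400))
    d <- exp(o$par)
    p <- rev(cumsum(rev(d)))
    p <- p / sum(p)
    if (abs(ref_entropy(p) - h) < 2e-3) best <- min(best, sum(p[seq_len(C)]))
  }
  best
}
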