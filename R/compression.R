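#' Binary entropy h(q) in bits
#'
#' \eqn{h(q) = -q \log_2 q - (1-q) \log_2 (1-q)}, with `0 log 0 = 0`.
#' @param q probability (vectorized), in \[0, 1\].
#' @return Entropy in bits.
#' @examples
#' binary_entropy(0.5) # 1
#' @export
binary_entropy <- function(q) {
  if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  -xlx(q) - xlx(1 - q)
}

#' Theoretical maximum compression length (the ceiling)
#'
#' Structural entropy of an Erdos-Renyi graph with the same N and E:
#' \deqn{R = {N \choose 2} h(q) - N \log_2 N, \quad q = E / {N \choose 2}.}
#' This is the normalizer turning a compression length L into the
#' dimensionless L* = L / R.
#'
#' @param n node count.
#' @param e edge count.
#' @return The ceiling in bits (positive, or an error when the network is
#'   too sparse or dense for normalization).
#' @examples
#' max_compression_length(100, 495)
#' @export
max_compression_length <- function(n, e) {
  total <- choose(n, 2)
  if (e < 0 || e > total) stop("E out of range")
  r <- total * binary_entropy(e / total) - n * log2(n)
  if (r <= 0)
    stop("ceiling is non-positive: the network is too sparse or dense ",
         "to normalize (needs ln N << <k> << N - ln N)")
  r
}

#' Label-free structure encoding
#'
#' Encodes the graph into the bit sequence B1 (singleton-cell adjacency
#' bits) and the count sequence B2 (neighbour counts in larger cells) via
#' partition-refinement traversal, then entropy-codes both with an adaptive
#' arithmetic coder.  Node labels are not encoded: decoding reconstructs a
#' graph isomorphic to the input.
#'
#' @param g a `net_graph`.
#' @param seed integer seed for the traversal order.
#' @param order_policy `"random"` (default), `"high_degree_first"` or
#'   `"low_degree_first"`; degree ties are broken by the seeded random order.
#' @return An `encoded_graph`: raw symbol streams `b1`, `b2` (+ cell sizes),
#'   arithmetic-coded payloads and their bit lengths, and the traversal
#'   metadata (`n`, `order`).
#' @export
encode_structure <- function(g, seed = 1,
                             order_policy = c("random", "high_degree_first",
                                              "low_degree_first")) {
  order_policy <- match.arg(order_policy)
  ord <- with_seed(seed, {
    base <- sample.int(g$n)
    switch(order_policy,
      random = base,
      high_degree_first = base[order(degree_sequence(g)[base],
                                     decreasing = TRUE)],
      low_degree_first = base[order(degree_sequence(g)[base])])
  })
  enc <- cpp_encode_structure(g$n, g$edges - 1L, ord - 1L)
  enc$order_policy <- order_policy
  enc$seed <- seed
  class(enc) <- "encoded_graph"
  enc
}

#' @export
print.encoded_graph <- function(x, ...) {
  cat(sprintf("encoded_graph: N = %d, l(B1^) = %.0f bits, l(B2^) = %.0f bits\n",
              x$n, x$bits1, x$bits2))
  invisible(x)
}

#' Decode a structure encoding
#'
#' Inverse of [encode_structure()] up to isomorphism: the returned graph has
#' the same N, E and degree multiset as the encoded one (and is exactly
#' isomorphic to it).  Corrupt or truncated symbol streams raise an error.
#'
#' @param enc an `encoded_graph`.
#' @param n node count (defaults to the one recorded in `enc`).
#' @param from `"symbols"` decodes the raw B1/B2 streams; `"payload"` runs
#'   the full pipeline including arithmetic decoding.
#' @return A `net_graph` isomorphic to the encoded graph.
#' @export
decode_structure <- function(enc, n = enc$n, from = c("symbols", "payload")) {
  from <- match.arg(from)
  em <- if (from == "symbols") {
    cpp_decode_structure(n, enc$b1, enc$b2)
  } else {
    cpp_decode_payloads(n, enc$payload1, enc$payload2, enc$bits1, enc$bits2)
  }
  net_graph(n, em + 1L)
}

#' Adaptive entropy coding of a symbol sequence
#'
#' Lossless adaptive arithmetic coder (Krichevsky-Trofimov estimator) over a
#' finite alphabet `0..alphabet-1`.  Output length is within
#' `O(alphabet * log n)` bits of `n` times the empirical entropy.
#'
#' @param symbols integer vector of symbols in `0..alphabet-1`.
#' @param alphabet alphabet size; defaults to `max(symbols) + 1`.
#' @return A list with `payload` (raw), `nbits`, `n`, `alphabet`.
#' @examples
#' code <- entropy_code(rep(0L, 1000))
#' code$nbits  # a handful of bits
#' @export
entropy_code <- function(symbols, alphabet = NULL) {
  symbols <- as.integer(symbols)
  if (is.null(alphabet)) alphabet <- if (length(symbols)) max(symbols) + 1L else 1L
  cpp_entropy_code(symbols, as.integer(alphabet))
}

#' @rdname entropy_code
#' @param code a list as returned by [entropy_code()].
#' @return `entropy_decode`: the original integer symbol vector.
#' @export
entropy_decode <- function(code) {
  cpp_entropy_decode(code$payload, code$nbits, code$n, code$alphabet)
}

#' Shortest compression length of a graph
#'
#' Runs the two-stage compressor over `runs` seeded traversal orders and
#' reports the per-run total length `L = l(B1^) + l(B2^)` in bits, its mean
#' and standard deviation.  The ceiling and L* are attached when the
#' ceiling is positive.  Header overhead (N, metadata) is excluded: L counts
#' only the two coded payloads.
#'
#' @param g a `net_graph` with `n >= 2`.
#' @param runs number of traversals (default 50).
#' @param seed integer; run r uses `seed + r - 1`.
#' @param order_policy traversal policy, see [encode_structure()].
#' @return A `compression_result` with `L` (mean bits), `L_sd`, `per_run`,
#'   `R` (ceiling, or NA outside its domain), `L_star`, `L_star_sd`.
#' @export
compression_length <- function(g, runs = 50, seed = 1,
                               order_policy = "random") {
  if (g$n < 2) stop("compression length requires n >= 2")
  per_run <- vapply(seq_len(runs), function(r) {
    enc <- encode_structure(g, seed = seed + r - 1, order_policy = order_policy)
    enc$bits1 + enc$bits2
  }, numeric(1))
  r_ceiling <- tryCatch(max_compression_length(g$n, nrow(g$edges)),
                        error = function(e) NA_real_)
  res <- list(L = mean(per_run),
              L_sd = stats::sd(per_run),
              per_run = per_run,
              runs = runs,
              seed = seed,
              order_policy = order_policy,
              n = g$n,
              e = nrow(g$edges),
              R = r_ceiling,
              L_star = if (is.na(r_ceiling)) NA_real_ else mean(per_run) / r_ceiling,
              L_star_sd = if (is.na(r_ceiling)) NA_real_ else stats::sd(per_run) / r_ceiling)
  class(res) <- "compression_result"
  res
}

#' @export
print.compression_result <- function(x, ...) {
  cat(sprintf("compression_result: N = %d, E = %d\n", x$n, x$e))
  cat(sprintf("  L  = %.1f bits (sd %.1f over %d runs)\n", x$L, x$L_sd, x$runs))
  if (!is.na(x$R))
    cat(sprintf("  R  = %.1f bits, L* = %.4f (sd %.4f)\n", x$R, x$L_star, x$L_star_sd))
  else
    cat("  R  = NA (outside the normalization domain)\n")
  invisible(x)
}

#' Normalized compression length L*
#'
#' `L* = mean(L) / R` where R is the Erdos-Renyi ceiling for the same N and
#' E.  Errors when the ceiling is non-positive.
#'
#' @inheritParams compression_length
#' @return A `compression_result` (see [compression_length()]); its
#'   `L_star` element is the headline number.
#' @export
normalized_length <- function(g, runs = 50, seed = 1, order_policy = "random") {
  max_compression_length(g$n, nrow(g$edges)) # errors when R <= 0
  compression_length(g, runs = runs, seed = seed, order_policy = order_policy)
}

# ------------------------------------------------------ binary container --

#' Write / read an encoded graph container
#'
#' Versioned binary container: magic `"NPC1"`, version byte, N, payload bit
#' lengths, payloads.  Only the entropy-coded payloads are stored; decoding
#' uses [decode_structure()] with `from = "payload"`.
#'
#' @param enc an `encoded_graph`.
#' @param path file path.
#' @export
write_encoded <- function(enc, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("NPC1"), con)
  writeBin(1L, con, size = 1)
  writeBin(as.integer(enc$n), con, size = 4, endian = "little")
  writeBin(as.numeric(c(enc$bits1, enc$bits2)), con, endian = "little")
  writeBin(as.integer(c(length(enc$payload1), length(enc$payload2))), con,
           size = 4, endian = "little")
  writeBin(enc$payload1, con)
  writeBin(enc$payload2, con)
  invisible(path)
}

#' @rdname write_encoded
#' @return `read_encoded`: an `encoded_graph` restricted to payload data;
#'   decode with `decode_structure(enc, from = "payload")`.
#' @export
read_encoded <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "NPC1")) stop("not an encoded-graph container")
  version <- as.integer(readBin(con, "raw", 1))
  if (version != 1L) stop("unsupported container version ", version)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  bits <- readBin(con, "numeric", 2, endian = "little")
  lens <- readBin(con, "integer", 2, size = 4, endian = "little")
  enc <- list(n = n, bits1 = bits[1], bits2 = bits[2],
              payload1 = readBin(con, "raw", lens[1]),
              payload2 = readBin(con, "raw", lens[2]))
  class(enc) <- "encoded_graph"
  enc
}
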