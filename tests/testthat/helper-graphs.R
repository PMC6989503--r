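# Small fixture builders shared across the suite.  Everything is generated
# in code; no data files.

triangle_graph <- function() net_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))

# square with one chord: nodes 1..4, edges 1-2, 2-3, 3-4, 1-4, 1-3
chorded_square <- function() {
  net_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(1, 3)))
}

two_triangles <- function() {
  net_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
}

# structured seed graph for monotonicity checks: ring lattice plus random
# extra links added on vacant pairs (no overlap by construction)
structured_graph <- function(n = 150, k_c = 8, extra = round(n / 2), seed = 1) {
  perturb_links(circle_model(n, k_c), "add", m = extra, seed = seed)
}

graphs_isomorphic <- function(ga, gb) {
  igraph::isomorphic(as_igraph(ga), as_igraph(gb))
}

write_tmp_edgelist <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# entropy of a probability vector, written independently of the package
ref_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
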