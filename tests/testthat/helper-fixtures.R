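# In-code fixtures and independent oracles used across the suite.

# Build a neri_network directly from an edge data frame and per-condition
# expression matrices (rows = genes covering every network gene).
toy_network <- function(edges, control, disease) {
  g <- igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
  genes <- sort(igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, genes))
  structure(list(
    graph = g,
    expr = list(control = control[genes, , drop = FALSE],
                disease = disease[genes, , drop = FALSE]),
    n_dropped_genes = 0L
  ), class = "neri_network")
}

# A tiny network where the concordance of every path is known by
# construction: perfectly concordant expression in both conditions.
perfect_expr <- function(genes, n_samples = 4) {
  base <- seq_len(n_samples)
  m <- matrix(rep(base, each = length(genes)), length(genes), n_samples,
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  m
}

# Independent Kendall-W oracle: direct formula evaluation on a rank matrix
# (kept separate from the package implementation on purpose).
oracle_w <- function(R) {
  m <- nrow(R); n <- ncol(R)
  S <- sum((colSums(R) - m * (n + 1) / 2)^2)
  T <- sum(apply(R, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  den <- m^2 * (n^3 - n) - m * T
  if (den <= 0) 0 else 12 * S / den
}

# Brute-force W_max: enumerate ALL 2^m sign assignments, rank from scratch.
oracle_w_max <- function(profiles) {
  m <- nrow(profiles)
  best <- 0
  for (code in 0:(2^m - 1)) {
    signs <- ifelse(bitwAnd(code, 2^(seq_len(m) - 1)) > 0, -1, 1)
    R <- t(apply(profiles * signs, 1, rank, ties.method = "average"))
    best <- max(best, oracle_w(R))
  }
  min(best, 1)
}

# Brute-force shortest-path oracle: exhaustive simple paths (igraph) filtered
# to minimal length, as node-name vectors sorted lexicographically.
oracle_shortest_paths <- function(graph, s, t) {
  sp <- igraph::all_simple_paths(graph, from = s, to = t)
  if (length(sp) == 0) return(list())
  paths <- lapply(sp, function(p) igraph::V(graph)$name[p])
  lens <- lengths(paths)
  paths <- paths[lens == min(lens)]
  paths[order(vapply(paths, paste, character(1), collapse = "\r"))]
}

# Random connected graph on n nodes: spanning tree plus extra edges.
random_connected_graph <- function(n, extra = n) {
  to <- 2:n
  from <- vapply(to, function(v) sample.int(v - 1, 1), integer(1))
  more <- t(replicate(extra, sample.int(n, 2)))
  el <- rbind(cbind(from, to), more)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  nm <- sprintf("N%02d", seq_len(n))
  igraph::simplify(igraph::graph_from_data_frame(
    data.frame(a = nm[el[, 1]], b = nm[el[, 2]]), directed = FALSE))
}

# Score table with prescribed (x, delta) pairs, bypassing the path machinery.
toy_scoretable <- function(x, delta, x_ini = 5) {
  sd_ <- x * (1 + delta) / 2
  sc_ <- x * (1 - delta) / 2
  structure(data.frame(
    gene = sprintf("G%04d", seq_along(x)),
    sigma_control = sc_, sigma_disease = sd_,
    x = x, delta = delta,
    n_paths_control = 1L, n_paths_disease = 1L,
    filtered = x <= x_ini,
    stringsAsFactors = FALSE
  ), class = c("neri_scoretable", "data.frame"))
}
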