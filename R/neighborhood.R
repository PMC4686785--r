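#' Grow a seed set to its direct network neighborhood
#'
#' Seeds absent from the network are dropped with a warning. The neighborhood
#' `N` is the union of the seeds' direct interactors, excluding the seeds
#' themselves; downstream analysis connects `S` to `S` \eqn{\cup} `N` by
#' shortest paths.
#'
#' @param net A `neri_network`.
#' @param seeds Character vector of raw seed symbols.
#' @return List with `S` (seeds present, sorted), `N` (neighbors, sorted) and
#'   `dropped` (input symbols absent from the network).
#' @export
grow_seeds <- function(net, seeds) {
  stopifnot(inherits(net, "neri_network"))
  seeds <- unique(clean_symbols(seeds))
  genes <- igraph::V(net$graph)$name
  S <- sort(intersect(seeds, genes))
  dropped <- setdiff(seeds, genes)
  if (length(dropped)) {
    warning("seeds absent from the network: ", paste(dropped, collapse = ", "))
  }
  if (length(S) == 0) stop("no seed gene is present in the network")
  nb <- unique(unlist(lapply(S, function(s) {
    igraph::V(net$graph)$name[igraph::neighbors(net$graph, s)]
  })))
  list(S = S, N = sort(setdiff(nb, S)), dropped = dropped)
}

#' Enumerate all shortest paths between two genes
#'
#' Breadth-first distances from both endpoints identify the nodes lying on at
#' least one geodesic (`d(s, v) + d(v, t) = d(s, t)`); paths are then read off
#' the forward shortest-path DAG by depth-first traversal, expanding neighbors
#' in sorted symbol order so the output is in deterministic lexicographic
#' order. If more than `cap` shortest paths exist, the lexicographically first
#' `cap` are kept and the truncation is reported (attribute `truncated`).
#'
#' @param net A `neri_network`.
#' @param s,t Distinct gene symbols in the network.
#' @param cap Maximum number of paths returned (default 10000).
#' @return List of character vectors (node sequences from `s` to `t`), each of
#'   minimal length; empty list if `t` is unreachable.
#' @export
all_shortest_paths <- function(net, s, t, cap = 10000L) {
  stopifnot(inherits(net, "neri_network"), s != t)
  g <- net$graph
  d <- igraph::distances(g, v = c(s, t))
  dst <- d[1, t]
  if (!is.finite(dst)) return(list())
  names_all <- colnames(d)
  on_geo <- names_all[is.finite(d[1, ]) & is.finite(d[2, ]) &
                        d[1, ] + d[2, ] == dst]
  ds <- d[1, on_geo]

  # successor lists on the geodesic DAG, sorted for lexicographic output
  succ <- lapply(on_geo, function(u) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, u)]
    sort(nb[nb %in% on_geo[ds == ds[u] + 1]])
  })
  names(succ) <- on_geo

  paths <- vector("list", 0L)
  truncated <- FALSE
  # iterative DFS; stack entries are partial paths ending at their last node
  stack <- list(s)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    u <- p[length(p)]
    if (u == t) {
      if (length(paths) >= cap) { truncated <- TRUE; break }
      paths[[length(paths) + 1L]] <- p
      next
    }
    nxt <- succ[[u]]
    # push in reverse so the lexicographically smallest pops first
    for (v in rev(nxt)) stack[[length(stack) + 1L]] <- c(p, v)
  }
  if (truncated) {
    message(sprintf("all_shortest_paths: >%d shortest paths between %s and %s; keeping the lexicographically first %d",
                    cap, s, t, cap))
  }
  attr(paths, "truncated") <- truncated
  paths
}

#' Concordance threshold of the epsilon tie rule
#'
#' Paths whose `W_max` is at least `(1 - epsilon)` times the best path's
#' `W_max` are considered tied with the best. With a best concordance of 0.6
#' and `epsilon = 0.05` the inclusion threshold is `0.6 * 0.95 = 0.57`.
#'
#' @param w_best Best `W_max` among a pair's shortest paths.
#' @param epsilon Tie factor in `[0, 1)`.
#' @return The inclusion threshold `w_best * (1 - epsilon)`.
#' @export
tie_threshold <- function(w_best, epsilon) {
  stopifnot(epsilon >= 0, epsilon < 1)
  w_best * (1 - epsilon)
}

#' Select concordance-best shortest paths under the epsilon tie rule
#'
#' Computes `W_max` for every candidate path over one condition's samples and
#' keeps all paths whose concordance is within a factor `1 - epsilon` of the
#' best: `W_max(P) >= (1 - epsilon) * max`. With the default `epsilon = 0.05`
#' and a best value of 0.6, every path with `W_max >= 0.57` is considered tied
#' with the best and retained.
#'
#' @param paths Nonempty list of node sequences (character vectors).
#' @param net A `neri_network`.
#' @param condition `"control"` or `"disease"`.
#' @param epsilon Tie factor in `[0, 1)`; `epsilon = 0` keeps only paths
#'   achieving the maximum.
#' @param max_path_genes Enumeration cap passed to [w_max()].
#' @return List with `paths` (kept node sequences) and `w_max` (their
#'   concordance values).
#' @export
select_paths <- function(paths, net, condition = c("control", "disease"),
                         epsilon = 0.05, max_path_genes = 12L) {
  condition <- match.arg(condition)
  stopifnot(length(paths) >= 1, epsilon >= 0, epsilon < 1)
  em <- net$expr[[condition]]
  wm <- vapply(paths, function(p) {
    w_max(em[p, , drop = FALSE], max_genes = max_path_genes)$w_max
  }, numeric(1))
  keep <- wm >= tie_threshold(max(wm), epsilon)
  list(paths = paths[keep], w_max = wm[keep])
}

#' Build the selected path sets for both conditions
#'
#' Iterates every ordered pair `(s in S, t in S union N, s != t)`, enumerates
#' all shortest paths once per pair, and applies the epsilon tie rule
#' separately under each condition's expression (so the two conditions can
#' keep different paths with different `W_max`). Unreachable pairs are skipped
#' and counted.
#'
#' @param net A `neri_network`.
#' @param S,N Seed and neighborhood symbol vectors from [grow_seeds()].
#' @param epsilon Tie factor (default 0.05).
#' @param cap Per-pair shortest-path cap (default 10000).
#' @param max_path_genes Enumeration cap passed to [w_max()].
#' @return A `neri_pathsets`: list with one `neri_pathset` per condition, each
#'   holding `pairs` (named `s|t` entries with `s`, `t`, `paths`, `w_max`),
#'   `n_skipped` and `n_truncated`.
#' @export
build_pathsets <- function(net, S, N, epsilon = 0.05, cap = 10000L,
                           max_path_genes = 12L) {
  stopifnot(inherits(net, "neri_network"))
  targets <- sort(union(S, N))
  out <- list(control = list(), disease = list())
  n_skipped <- 0L
  n_truncated <- 0L
  for (s in S) {
    for (t in targets) {
      if (t == s) next
      cand <- all_shortest_paths(net, s, t, cap = cap)
      if (length(cand) == 0) { n_skipped <- n_skipped + 1L; next }
      if (isTRUE(attr(cand, "truncated"))) n_truncated <- n_truncated + 1L
      key <- paste(s, t, sep = "|")
      for (cond in c("control", "disease")) {
        sel <- select_paths(cand, net, cond, epsilon = epsilon,
                            max_path_genes = max_path_genes)
        out[[cond]][[key]] <- list(s = s, t = t,
                                   paths = sel$paths, w_max = sel$w_max)
      }
    }
  }
  if (n_skipped) message("build_pathsets: ", n_skipped, " unreachable pair(s) skipped")
  structure(list(
    control = structure(list(condition = "control", pairs = out$control,
                             n_skipped = n_skipped, n_truncated = n_truncated),
                        class = "neri_pathset"),
    disease = structure(list(condition = "disease", pairs = out$disease,
                             n_skipped = n_skipped, n_truncated = n_truncated),
                        class = "neri_pathset")
  ), class = "neri_pathsets")
}

#' Export a selected path set as a data frame
#'
#' One row per kept path: `s`, `t`, `condition`, dash-joined `path`, `w_max`.
#'
#' @param ps A `neri_pathset`.
#' @return A data frame suitable for TSV export.
#' @export
pathset_table <- function(ps) {
  stopifnot(inherits(ps, "neri_pathset"))
  rows <- lapply(ps$pairs, function(pr) {
    if (length(pr$paths) == 0) return(NULL)
    data.frame(s = pr$s, t = pr$t, condition = ps$condition,
               path = vapply(pr$paths, paste, character(1), collapse = "-"),
               w_max = pr$w_max, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(s = character(), t = character(), condition = character(),
                      path = character(), w_max = numeric())
  }
  out
}
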