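#' Analysis parameters
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the method's standard experimental setup: `epsilon = 0.05` (path tie
#' factor), `w_len = 2` and `w_step = 1` (sliding window length and step on
#' the X axis, in X units), `x_ini = 5` (only genes with X strictly greater
#' enter the differential analysis). The distance-decay base `lambda` has no
#' published setting; the default is 2 (each hop from a seed halves a path's
#' contribution) and should be stated with any reported result.
#'
#' @param lambda Distance-decay base, > 1.
#' @param epsilon Shortest-path tie factor in `[0, 1)`.
#' @param w_len Sliding window length (X units), > 0.
#' @param w_step Sliding window step (X units), > 0.
#' @param x_ini Intensity threshold: genes with `X <= x_ini` are flagged
#'   `filtered` and excluded from envelope fitting and Delta' ranking.
#' @param max_path_genes Cap on genes per path for W_max enumeration.
#' @param path_cap Cap on shortest paths enumerated per gene pair.
#' @param min_points_per_window Minimum unfiltered genes for a window to enter
#'   the envelope fit.
#' @param top_fraction Fraction of unfiltered genes returned by
#'   [rank_and_select()] by default.
#' @param envelope `"absolute"` fits one power law to the third quartile of
#'   `|Delta|`; `"signed"` fits separate envelopes to the positive and
#'   negative sides.
#' @return A `neri_params` list.
#' @export
neri_params <- function(lambda = 2, epsilon = 0.05, w_len = 2, w_step = 1,
                        x_ini = 5, max_path_genes = 12L, path_cap = 10000L,
                        min_points_per_window = 5L, top_fraction = 0.1,
                        envelope = c("absolute", "signed")) {
  envelope <- match.arg(envelope)
  if (lambda <= 1) stop("lambda must be > 1 (distance decay)")
  stopifnot(epsilon >= 0, epsilon < 1, w_len > 0, w_step > 0,
            max_path_genes >= 2, path_cap >= 1,
            top_fraction > 0, top_fraction <= 1)
  structure(list(lambda = lambda, epsilon = epsilon, w_len = w_len,
                 w_step = w_step, x_ini = x_ini,
                 max_path_genes = as.integer(max_path_genes),
                 path_cap = as.integer(path_cap),
                 min_points_per_window = as.integer(min_points_per_window),
                 top_fraction = top_fraction, envelope = envelope),
            class = "neri_params")
}

#' Per-condition gene importance score sigma
#'
#' For one condition's selected path set, each gene `g` accumulates, over
#' ordered seed/target pairs `(s, t)` and each selected path `P` of that pair,
#' \deqn{\sigma(g) = \sum_{s,t} \sum_{P} \lambda^{-d_{sg}} \, W_{max}(P) \, [g \in P]}
#' where `d_sg` is the unweighted graph distance from the pair's seed `s` to
#' `g` on the full integrated network (not the position within the path);
#' endpoints count as members, so a seed scores its own pairs at full weight
#' (`d_ss = 0`). Distances are computed once per seed by breadth-first search
#' and cached.
#'
#' @param pathset A `neri_pathset` (one condition).
#' @param net The `neri_network` the path set was built on.
#' @param S Seed symbols.
#' @param params A `neri_params` (uses `lambda`).
#' @return A `neri_scores`: list with `condition`, `sigma` (named numeric,
#'   zero for genes on no selected path omitted) and `n_paths` (per gene,
#'   number of selected paths containing it).
#' @export
sigma_scores <- function(pathset, net, S, params = neri_params()) {
  stopifnot(inherits(pathset, "neri_pathset"), inherits(net, "neri_network"))
  lambda <- params$lambda
  if (lambda <= 1) stop("lambda must be > 1")
  dist_from_seed <- igraph::distances(net$graph, v = S)
  sigma <- new.env(parent = emptyenv())
  npath <- new.env(parent = emptyenv())
  for (pr in pathset$pairs) {
    if (length(pr$paths) == 0) next
    drow <- dist_from_seed[pr$s, ]
    for (i in seq_along(pr$paths)) {
      p <- pr$paths[[i]]
      contrib <- lambda^(-drow[p]) * pr$w_max[i]
      for (j in seq_along(p)) {
        g <- p[j]
        sigma[[g]] <- (sigma[[g]] %||% 0) + contrib[j]
        npath[[g]] <- (npath[[g]] %||% 0L) + 1L
      }
    }
  }
  genes <- sort(ls(sigma))
  structure(list(
    condition = pathset$condition,
    sigma = stats::setNames(vapply(genes, function(g) sigma[[g]], numeric(1)), genes),
    n_paths = stats::setNames(vapply(genes, function(g) npath[[g]], integer(1)), genes)
  ), class = "neri_scores")
}
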