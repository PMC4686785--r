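#' Run the full prioritization analysis on in-memory objects
#'
#' Orchestrates neighborhood growth, per-condition path selection, sigma
#' scoring, and the differential X / Delta / Delta' analysis.
#'
#' @param net A `neri_network` from [integrate_network()].
#' @param seeds Character vector of seed symbols.
#' @param params A `neri_params`.
#' @return List: `scores` (a `neri_scoretable` with Delta' and ranks), `fit`
#'   (a `neri_powerlaw`), `pathsets`, `seed_info` (S, N, dropped), `top`
#'   (top-fraction genes by `|Delta'|`).
#' @export
neri_analyze <- function(net, seeds, params = neri_params()) {
  stopifnot(inherits(net, "neri_network"))
  si <- grow_seeds(net, seeds)
  ps <- build_pathsets(net, si$S, si$N, epsilon = params$epsilon,
                       cap = params$path_cap,
                       max_path_genes = params$max_path_genes)
  sc <- sigma_scores(ps$control, net, si$S, params)
  sd <- sigma_scores(ps$disease, net, si$S, params)
  tab <- compute_xdelta(sc, sd, params)
  fit <- fit_powerlaw(tab, params)
  tab <- compute_delta_prime(tab, fit)
  top <- rank_and_select(tab, "abs_delta_prime", params$top_fraction)
  list(scores = tab, fit = fit, pathsets = ps, seed_info = si, top = top)
}

#' Run the pipeline from input files and write all artifacts
#'
#' Reads one or more PPI edge lists, the expression matrix and condition
#' labels, and the seed list; optionally aggregates transcripts to genes via
#' a mapping table; integrates, analyzes, and writes to `outdir`:
#' `scores.tsv`, `pathsets_control.tsv`, `pathsets_disease.tsv`,
#' `powerlaw_fit.tsv`, `top_genes.txt` and `manifest.yaml` (parameter echo
#' including lambda, node/edge counts, skipped pairs, truncations). Outputs
#' are byte-identical across reruns of the same inputs and parameters.
#'
#' @param ppi Character vector of edge-list paths.
#' @param expr Expression TSV path.
#' @param labels Sample-condition TSV path.
#' @param seeds Seed list path (one symbol per line).
#' @param outdir Output directory (created if needed).
#' @param params A `neri_params`.
#' @param mapping Optional transcript-to-gene TSV path (columns transcript,
#'   gene); when given, expression rows are median-aggregated to genes first.
#' @param dialect Edge-list dialect, see [read_edge_list()].
#' @return Invisibly, the [neri_analyze()] result list.
#' @export
neri_run <- function(ppi, expr, labels, seeds, outdir = ".",
                     params = neri_params(), mapping = NULL,
                     dialect = "two_column_tsv") {
  run_stage <- function(stage, expr_) {
    tryCatch(expr_, error = function(e) {
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  edges <- run_stage("netio", {
    merge_edge_lists(lapply(ppi, read_edge_list, dialect = dialect))
  })
  ex <- run_stage("netio", {
    x <- read_expression(expr, labels)
    if (!is.null(mapping)) {
      x <- aggregate_transcripts(x, utils::read.delim(mapping, colClasses = "character"))
    }
    x
  })
  net <- run_stage("netio", integrate_network(edges, ex))
  seed_syms <- run_stage("netio", {
    s <- readLines(seeds)
    s[nzchar(trimws(s))]
  })
  res <- run_stage("analysis", neri_analyze(net, seed_syms, params))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(as.data.frame(res$scores)[, c("gene", "sigma_control", "sigma_disease",
                                   "x", "delta", "delta_prime",
                                   "rank_abs_delta_prime", "rank_x",
                                   "n_paths_control", "n_paths_disease",
                                   "filtered")], "scores.tsv")
  wt(pathset_table(res$pathsets$control), "pathsets_control.tsv")
  wt(pathset_table(res$pathsets$disease), "pathsets_disease.tsv")
  fit <- res$fit
  if (identical(fit$envelope, "signed")) {
    fr <- rbind(cbind(side = "positive", a = fit$positive$a, k = fit$positive$k,
                      fit$positive$window_points),
                cbind(side = "negative", a = fit$negative$a, k = fit$negative$k,
                      fit$negative$window_points))
  } else {
    fr <- cbind(side = "absolute", a = fit$a, k = fit$k, fit$window_points)
  }
  wt(fr, "powerlaw_fit.tsv")
  writeLines(res$top, file.path(outdir, "top_genes.txt"))
  manifest <- list(
    inputs = list(ppi = as.character(ppi), expr = expr, labels = labels,
                  seeds = seeds, mapping = mapping),
    params = unclass(params),
    network = list(n_genes = igraph::vcount(net$graph),
                   n_edges = igraph::ecount(net$graph)),
    seeds = list(n_used = length(res$seed_info$S),
                 n_dropped = length(res$seed_info$dropped),
                 n_neighborhood = length(res$seed_info$N)),
    pairs = list(n_skipped = res$pathsets$control$n_skipped,
                 n_truncated = res$pathsets$control$n_truncated),
    genes = list(n_scored = nrow(res$scores),
                 n_unfiltered = sum(!res$scores$filtered),
                 n_top = length(res$top))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(res)
}

#' Run the pipeline from a flat key-value config file
#'
#' The config (YAML, flat keys) mirrors the [neri_run()] arguments and the
#' [neri_params()] fields: `ppi` (one path or a list), `expr`, `labels`,
#' `seeds`, `outdir`, `mapping`, `dialect`, and any of `lambda`, `epsilon`,
#' `w_len`, `w_step`, `x_ini`, `max_path_genes`, `path_cap`,
#' `min_points_per_window`, `top_fraction`, `envelope`.
#'
#' @param path Config file path.
#' @return Invisibly, the [neri_analyze()] result list.
#' @export
neri_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("ppi", "expr", "labels", "seeds")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  pkeys <- intersect(names(cfg), names(formals(neri_params)))
  params <- do.call(neri_params, cfg[pkeys])
  neri_run(ppi = unlist(cfg$ppi), expr = cfg$expr, labels = cfg$labels,
           seeds = cfg$seeds, outdir = cfg$outdir %||% ".",
           params = params, mapping = cfg$mapping,
           dialect = cfg$dialect %||% "two_column_tsv")
}

#' MA-style diagnostic plot of the differential analysis
#'
#' X versus Delta with the fitted envelope and the selected top genes
#' highlighted; decoy-like high-X, low-|Delta'| genes sit on the right near
#' Delta = 0. Requires ggplot2.
#'
#' @param res A [neri_analyze()] result.
#' @return A ggplot object.
#' @export
neri_ma_plot <- function(res) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for neri_ma_plot")
  }
  tab <- as.data.frame(res$scores)
  tab$selected <- tab$gene %in% res$top
  tab$side <- ifelse(!tab$selected, "not selected",
                     ifelse(tab$delta >= 0, "disease-dominant", "control-dominant"))
  xr <- range(tab$x[!tab$filtered])
  grid <- data.frame(x = seq(xr[1], xr[2], length.out = 200))
  grid$f <- predict_envelope(res$fit, grid$x)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$side), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$f),
                       linetype = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = -.data$f),
                       linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`disease-dominant` = "red",
                                            `control-dominant` = "darkgreen",
                                            `not selected` = "grey60")) +
    ggplot2::labs(x = "X = sigma_C + sigma_D", y = "Delta", colour = NULL)
  }
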