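#' Generate a sparse scale-free benchmark network
#'
#' Preferential-attachment growth: `attachment` initial isolated nodes, then
#' each new node connects to `attachment` distinct existing nodes drawn with
#' probability proportional to degree + 1. The result is connected, has
#' exactly `attachment * (n_genes - attachment)` edges, and a heavy-tailed
#' degree distribution — the regime of real PPI interactomes. Symbols are
#' `G0001`, `G0002`, ...
#'
#' @param n_genes Number of genes; must exceed `attachment`.
#' @param attachment Edges added per new node, >= 1.
#' @param rng_seed Integer seed; identical seeds give identical networks.
#' @return A `neri_edgelist`.
#' @export
generate_network <- function(n_genes, attachment = 2L, rng_seed = 1L) {
  n <- as.integer(n_genes)
  a <- as.integer(attachment)
  if (!(n > a && a >= 1)) stop("need n_genes > attachment >= 1")
  with_rng(rng_seed, {
    deg <- integer(n)
    from <- integer(a * (n - a))
    to <- integer(a * (n - a))
    e <- 0L
    for (v in (a + 1L):n) {
      targets <- sample.int(v - 1L, a, prob = deg[seq_len(v - 1L)] + 1)
      for (u in targets) {
        e <- e + 1L
        from[e] <- u; to[e] <- v
        deg[u] <- deg[u] + 1L
      }
      deg[v] <- deg[v] + a
    }
    sym <- sprintf("G%04d", seq_len(n))
    lo <- pmin(sym[from], sym[to])
    hi <- pmax(sym[from], sym[to])
    ord <- order(lo, hi)
    structure(data.frame(gene_a = lo[ord], gene_b = hi[ord],
                         sources = "synthetic", stringsAsFactors = FALSE),
              class = c("neri_edgelist", "data.frame"),
              source_name = "synthetic")
  })
}

#' Generate two-condition expression with a planted differential module
#'
#' A single-factor model per condition emulates the coexpression structure
#' the method detects: in each condition a latent factor `F` (one value per
#' sample) drives the loaded genes, `value = rho * F + sqrt(1 - rho^2) * noise`
#' with standard normal noise. Seed genes follow the factor in both
#' conditions; planted module genes follow it in the disease condition only
#' (pure noise in control) — these are the differentially coexpressed truth;
#' decoy hub genes follow it equally in both conditions (high-degree,
#' non-differential — the ascertainment-bias trap); all remaining genes are
#' independent noise.
#'
#' @param edges A `neri_edgelist` for the network.
#' @param seeds Seed symbols, present in the network.
#' @param module_size Number of planted genes: the highest-degree members of
#'   the seeds' 1-2-hop neighborhood (ties broken by symbol), reflecting the
#'   disease-module hypothesis that disease genes form a topologically
#'   cohesive cluster around the seeds; error if the neighborhood is too
#'   small.
#' @param rho Factor loading in `[0, 1)`; within-group pairwise expression
#'   correlation is approximately `rho^2`.
#' @param n_samples Samples per condition.
#' @param n_decoys Number of decoy hubs (highest-degree non-seed, non-planted
#'   genes).
#' @param rng_seed Integer seed.
#' @return List with `expression` (a `neri_expression`) and `truth` (a
#'   `neri_truth`: `planted_genes`, `decoy_hubs`, `background`, `seeds`,
#'   generator parameters).
#' @export
generate_expression <- function(edges, seeds, module_size = 20L, rho = 0.9,
                                n_samples = 30L, n_decoys = 10L, rng_seed = 1L) {
  stopifnot(inherits(edges, "neri_edgelist"), rho >= 0, rho < 1, n_samples >= 3)
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE))
  genes <- sort(igraph::V(g)$name)
  seeds <- clean_symbols(seeds)
  if (!all(seeds %in% genes)) {
    stop("seeds absent from network: ", paste(setdiff(seeds, genes), collapse = ", "))
  }
  d <- igraph::distances(g, v = seeds)
  dmin <- apply(d, 2L, min)[genes]
  hop1 <- genes[dmin == 1]
  hop2 <- genes[dmin == 2]
  if (length(hop1) + length(hop2) < module_size) {
    stop("module_size ", module_size, " exceeds the ", length(hop1) + length(hop2),
         " genes within 2 hops of the seeds")
  }
  deg_all <- igraph::degree(g)
  cand <- c(hop1, hop2)
  planted <- sort(cand[order(-deg_all[cand], cand)][seq_len(module_size)])
  with_rng(rng_seed, {
    rest <- setdiff(genes, c(seeds, planted))
    deg <- deg_all[rest]
    decoys <- rest[order(-deg, rest)][seq_len(min(n_decoys, length(rest)))]
    background <- setdiff(rest, decoys)

    sample_ids <- sprintf("S%03d", seq_len(2L * n_samples))
    condition <- stats::setNames(rep(c("control", "disease"), each = n_samples),
                                 sample_ids)
    load_sd <- sqrt(1 - rho^2)
    values <- matrix(stats::rnorm(length(genes) * 2L * n_samples),
                     length(genes), 2L * n_samples,
                     dimnames = list(genes, sample_ids))
    for (cond in c("control", "disease")) {
      cols <- which(condition == cond)
      f <- stats::rnorm(length(cols))
      loaded <- if (cond == "disease") c(seeds, planted, decoys) else c(seeds, decoys)
      values[loaded, cols] <- rho * matrix(f, length(loaded), length(cols),
                                           byrow = TRUE) +
        load_sd * values[loaded, cols]
    }
    truth <- structure(list(
      planted_genes = planted,
      decoy_hubs = decoys,
      background = sort(background),
      seeds = sort(seeds),
      params = list(n_genes = length(genes), module_size = module_size,
                    rho = rho, n_samples = n_samples, n_decoys = n_decoys,
                    rng_seed = rng_seed)
    ), class = "neri_truth")
    list(expression = new_expression(values, condition), truth = truth)
  })
}

#' Full synthetic benchmark instance
#'
#' Generates a network, takes the `n_seeds` highest-degree nodes as seeds
#' (disease seed genes are well-connected interactome members; a seed set in
#' the sparse periphery would have no neighborhood to analyze), and generates
#' matched expression with a planted module and decoy hubs. Defaults define
#' the package's standard benchmark: 300 genes, attachment 2, 5 seeds, a
#' 20-gene planted module, factor loading 0.9, 30 samples per condition, 10
#' decoy hubs.
#'
#' @param n_genes,attachment Network size parameters (see
#'   [generate_network()]).
#' @param n_seeds Number of seed genes.
#' @param module_size,rho,n_samples,n_decoys Expression parameters (see
#'   [generate_expression()]).
#' @param rng_seed Integer seed for the whole instance.
#' @return List: `edges`, `seeds`, `expression`, `truth`.
#' @export
simulate_benchmark <- function(n_genes = 300L, attachment = 2L, n_seeds = 5L,
                               module_size = 20L, rho = 0.9, n_samples = 30L,
                               n_decoys = 10L, rng_seed = 1L) {
  edges <- generate_network(n_genes, attachment, rng_seed = rng_seed)
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE))
  deg <- igraph::degree(g)
  nm <- names(deg)
  seeds <- sort(nm[order(-deg, nm)][seq_len(n_seeds)])
  ge <- generate_expression(edges, seeds, module_size = module_size, rho = rho,
                            n_samples = n_samples, n_decoys = n_decoys,
                            rng_seed = rng_seed + 2L)
  list(edges = edges, seeds = seeds, expression = ge$expression,
       truth = ge$truth)
}

#' Write a benchmark instance as the pipeline's input files
#'
#' Emits the TSV formats [read_edge_list()] and [read_expression()] consume
#' (edge list, expression matrix, condition labels, seed list), plus the
#' truth labels, making the pipeline round-trip testable.
#'
#' @param bench Output of [simulate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             expr = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             seeds = file.path(dir, "seeds.txt"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(as.data.frame(bench$edges)[, c("gene_a", "gene_b")],
                     paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expr <- bench$expression
  utils::write.table(data.frame(gene = rownames(expr$values), expr$values,
                                check.names = FALSE),
                     paths["expr"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(expr$condition),
                                condition = as.character(expr$condition)),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(bench$seeds, paths["seeds"])
  tr <- bench$truth
  lab <- rbind(data.frame(gene = tr$planted_genes, role = "planted"),
               data.frame(gene = tr$decoy_hubs, role = "decoy_hub"),
               data.frame(gene = tr$seeds, role = "seed"),
               data.frame(gene = tr$background, role = "background"))
  utils::write.table(lab[order(lab$gene), ], paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Recovery metrics for a ranking against the planted truth
#'
#' `precision_at_k` is the fraction of the top `k` ranked genes that are
#' planted; `enrichment` is that precision divided by the random expectation
#' `|planted| / universe`.
#'
#' @param ranking Ordered gene symbols (best first).
#' @param truth A `neri_truth`.
#' @param k Depth, `1 <= k <= length(ranking)`.
#' @param universe_size Size of the gene universe for the random expectation;
#'   defaults to the generated network size.
#' @return List: `precision_at_k`, `enrichment`, `n_planted_in_top`.
#' @export
evaluate_recovery <- function(ranking, truth, k,
                              universe_size = truth$params$n_genes) {
  stopifnot(inherits(truth, "neri_truth"), k >= 1, k <= length(ranking))
  if (length(truth$planted_genes) == 0) stop("empty planted truth set")
  hits <- sum(ranking[seq_len(k)] %in% truth$planted_genes)
  prec <- hits / k
  list(precision_at_k = prec,
       enrichment = prec / (length(truth$planted_genes) / universe_size),
       n_planted_in_top = hits)
}
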