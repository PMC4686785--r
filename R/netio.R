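#' Read a PPI edge list
#'
#' Reads an undirected protein-protein interaction edge list keyed by gene
#' symbol. Symbols are upper-cased and whitespace-trimmed; self-pairs are
#' dropped; duplicate pairs (in either orientation) are collapsed. The number
#' of dropped rows is reported via `message()`.
#'
#' @param path Path to the input file.
#' @param dialect `"two_column_tsv"` for a headerless (or `geneA`/`geneB`
#'   headed) two-column TSV; `"psi_mi_tab"` for PSI-MI TAB 2.5, from which the
#'   two interactor gene-symbol alias columns (5 and 6, `(gene name)` entries)
#'   are extracted.
#' @param source_name Free-text label recorded as the edge provenance;
#'   defaults to the file name.
#' @return A `neri_edgelist`: data frame with columns `gene_a`, `gene_b`
#'   (canonical order `gene_a < gene_b`) and `sources`.
#' @export
read_edge_list <- function(path,
                           dialect = c("two_column_tsv", "psi_mi_tab"),
                           source_name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character", quote = "",
                      comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) stop("zero valid rows in edge list ", path,
                             " (unreadable or empty: ", conditionMessage(e), ")")
  )
  if (nrow(raw) == 0) stop("zero valid rows in edge list: ", path)

  if (dialect == "two_column_tsv") {
    if (ncol(raw) < 2) stop("zero valid rows in edge list: ", path,
                            " (need two tab-separated columns)")
    ab <- raw[, 1:2]
    # optional header row "geneA geneB"
    if (nrow(ab) > 0 && all(tolower(trimws(unlist(ab[1, ]))) %in% c("genea", "geneb"))) {
      ab <- ab[-1, , drop = FALSE]
    }
  } else {
    if (ncol(raw) < 6) stop("zero valid rows in edge list: ", path,
                            " (PSI-MI TAB needs >= 6 columns)")
    ab <- data.frame(V1 = psi_mi_symbol(raw[[5]]),
                     V2 = psi_mi_symbol(raw[[6]]))
  }

  a <- clean_symbols(ab[[1]])
  b <- clean_symbols(ab[[2]])
  keep <- a != "" & b != "" & !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n_in <- length(a)
  ok <- a != b
  lo <- pmin(a[ok], b[ok])
  hi <- pmax(a[ok], b[ok])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  if (sum(!dup) == 0) stop("zero valid rows in edge list: ", path)
  edges <- data.frame(gene_a = lo[!dup], gene_b = hi[!dup],
                      sources = source_name, stringsAsFactors = FALSE)
  dropped <- nrow(raw) - nrow(edges)
  message(sprintf("read_edge_list: %d edges from %s (%d rows dropped: self-pairs, duplicates, unparseable)",
                  nrow(edges), source_name, dropped))
  structure(edges, class = c("neri_edgelist", "data.frame"),
            source_name = source_name, n_dropped = dropped, n_input_rows = n_in)
}

# Extract a gene symbol from a PSI-MI TAB alias column entry, e.g.
# "uniprotkb:SNCA(gene name)|uniprotkb:PARK1(gene name synonym)" -> "SNCA".
psi_mi_symbol <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), function(parts) {
    gn <- grep("\\(gene name\\)$", parts, value = TRUE)
    pick <- if (length(gn)) gn[1] else if (length(parts)) parts[1] else ""
    sub("\\(.*\\)$", "", sub("^[^:]*:", "", pick))
  }, character(1))
}

#' Merge several edge lists into one
#'
#' Set union of unordered gene pairs across sources; the per-edge `sources`
#' column records which input lists contained each edge (comma-joined).
#' The union is commutative and associative over edge sets.
#'
#' @param lists A list of `neri_edgelist` objects (at least one).
#' @return A single `neri_edgelist`.
#' @export
merge_edge_lists <- function(lists) {
  if (inherits(lists, "neri_edgelist")) lists <- list(lists)
  stopifnot(length(lists) >= 1)
  all <- do.call(rbind, lapply(lists, function(x) as.data.frame(x)[c("gene_a", "gene_b", "sources")]))
  key <- paste(all$gene_a, all$gene_b, sep = "\r")
  src <- vapply(split(all$sources, key), function(s) paste(sort(unique(s)), collapse = ","), character(1))
  uk <- sort(unique(key))
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
                      gene_b = vapply(parts, `[`, character(1), 2L),
                      sources = unname(src[uk]), stringsAsFactors = FALSE)
  message(sprintf("merge_edge_lists: %d unique edges from %d source list(s)",
                  nrow(edges), length(lists)))
  structure(edges, class = c("neri_edgelist", "data.frame"), source_name = "merged")
}

#' Read a two-condition expression matrix
#'
#' Expression TSV: first column row identifiers (transcripts or genes), header
#' row sample identifiers. Condition labels TSV: two columns `sample_id`,
#' `condition` in `{control, disease}` (headerless or headed). Values are
#' expected on a post-normalization intensity scale; no normalization is
#' applied here.
#'
#' @param expr_path Path to the expression TSV.
#' @param labels_path Path to the sample-condition TSV.
#' @return A `neri_expression`: list with `values` (numeric matrix, rows named
#'   by row id) and `condition` (factor `control`/`disease` named by sample).
#' @export
read_expression <- function(expr_path, labels_path) {
  values <- as.matrix(utils::read.delim(expr_path, row.names = 1, check.names = FALSE))
  storage.mode(values) <- "double"
  lab <- utils::read.delim(labels_path, header = FALSE, colClasses = "character")
  if (tolower(trimws(lab[1, 2])) %in% c("condition", "label")) lab <- lab[-1, , drop = FALSE]
  condition <- stats::setNames(tolower(trimws(lab[[2]])), trimws(lab[[1]]))
  new_expression(values, condition)
}

# Validate and build a neri_expression from parts.
new_expression <- function(values, condition) {
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  missing_lab <- setdiff(colnames(values), names(condition))
  if (length(missing_lab)) {
    stop("samples without condition label: ", paste(missing_lab, collapse = ", "))
  }
  condition <- condition[colnames(values)]
  if (!all(condition %in% c("control", "disease"))) {
    stop("condition labels must be 'control' or 'disease'")
  }
  tab <- table(factor(condition, levels = c("control", "disease")))
  if (any(tab < 3)) stop("need at least 3 samples per condition; got ",
                         paste(names(tab), tab, sep = "=", collapse = ", "))
  structure(list(values = values,
                 condition = factor(condition, levels = c("control", "disease"))),
            class = "neri_expression")
}

#' Aggregate transcript rows to gene level by the median
#'
#' Each gene's expression profile is the per-sample median across its
#' transcripts. Rows without a mapping entry are dropped (with a message).
#' Duplicate gene rows arising after mapping are aggregated by the same rule.
#'
#' @param expr A `neri_expression` with transcript-level rows.
#' @param mapping Data frame with columns `transcript`, `gene` (or a named
#'   character vector, names = transcripts).
#' @return A gene-level `neri_expression`.
#' @export
aggregate_transcripts <- function(expr, mapping) {
  stopifnot(inherits(expr, "neri_expression"))
  if (is.data.frame(mapping)) {
    if (ncol(mapping) < 2 || nrow(mapping) == 0) {
      stop("empty transcript-to-gene mapping")
    }
    mapping <- stats::setNames(clean_symbols(mapping[[2]]), trimws(mapping[[1]]))
  } else {
    mapping <- stats::setNames(clean_symbols(mapping), trimws(names(mapping)))
  }
  if (length(mapping) == 0) stop("empty transcript-to-gene mapping")
  ids <- rownames(expr$values)
  gene <- mapping[ids]
  unmapped <- is.na(gene) | gene == ""
  if (any(unmapped)) {
    message(sprintf("aggregate_transcripts: dropping %d unmapped row(s)", sum(unmapped)))
  }
  v <- expr$values[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  if (nrow(v) == 0) stop("no mapped transcript rows remain")
  agg <- rowsum_median(v, gene)
  new_expression(agg, stats::setNames(as.character(expr$condition), colnames(expr$values)))
}

# Per-column median of rows grouped by `group`.
rowsum_median <- function(v, group) {
  groups <- sort(unique(group))
  out <- matrix(NA_real_, length(groups), ncol(v),
                dimnames = list(groups, colnames(v)))
  idx <- split(seq_along(group), group)
  for (g in groups) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) v[rows, ] else
      apply(v[rows, , drop = FALSE], 2L, stats::median)
  }
  out
}

#' Integrate a PPI edge list with gene-level expression
#'
#' Restricts the network to genes present in both the edge list and the
#' expression matrix, then to the largest connected component (ties in
#' component size broken by the lexicographically smallest member, logged).
#' Duplicate gene rows in the expression input are median-aggregated first.
#'
#' @param edges A `neri_edgelist`.
#' @param expr A gene-level `neri_expression`.
#' @return A `neri_network`: list with `graph` (undirected simple
#'   [igraph::igraph] on gene symbols), `expr` (list of `control` and
#'   `disease` gene-by-sample matrices covering every network gene), and
#'   `n_dropped_genes`.
#' @export
integrate_network <- function(edges, expr) {
  stopifnot(inherits(edges, "neri_edgelist"), inherits(expr, "neri_expression"))
  rn <- clean_symbols(rownames(expr$values))
  if (anyDuplicated(rn)) {
    message("integrate_network: aggregating duplicate expression rows by median")
    values <- rowsum_median(expr$values, rn)
  } else {
    values <- expr$values
    rownames(values) <- rn
  }
  net_genes <- union(edges$gene_a, edges$gene_b)
  common <- intersect(net_genes, rownames(values))
  if (length(common) == 0) stop("no genes shared between network and expression data")
  dropped <- length(net_genes) - length(common)

  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  g <- igraph::induced_subgraph(g, common)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # deterministic tie-break: component containing the smallest symbol
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    message("integrate_network: component-size tie broken toward component containing ",
            min(firsts))
    best <- best[which.min(firsts)]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  if (length(keep) < 3) stop("largest connected component has fewer than 3 genes")
  g <- igraph::induced_subgraph(g, sort(keep))
  genes <- sort(igraph::V(g)$name)
  # stable vertex order for reproducible downstream iteration
  g <- igraph::permute(g, match(igraph::V(g)$name, genes))

  cond <- expr$condition
  em <- values[genes, , drop = FALSE]
  message(sprintf("integrate_network: %d genes, %d interactions in the main connected component (%d network genes lacked expression)",
                  length(genes), igraph::ecount(g), dropped))
  structure(list(
    graph = g,
    expr = list(control = em[, cond == "control", drop = FALSE],
                disease = em[, cond == "disease", drop = FALSE]),
    n_dropped_genes = dropped
  ), class = "neri_network")
}

#' @export
print.neri_network <- function(x, ...) {
  cat(sprintf("neri_network: %d genes, %d interactions; %d control / %d disease samples\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              ncol(x$expr$control), ncol(x$expr$disease)))
  invisible(x)
}
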