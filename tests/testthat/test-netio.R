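write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_edge_list cleans self-pairs, duplicates and case", {
  f <- write_tsv_lines(c("A\tB", "B\tA", "C\tC"))
  el <- suppressMessages(read_edge_list(f))
  expect_equal(nrow(el), 1)
  expect_equal(el$gene_a, "A")
  expect_equal(el$gene_b, "B")
  expect_equal(attr(el, "n_dropped"), 2)

  f <- write_tsv_lines(c("geneA\tgeneB", " tp53 \tBRCA1", "A\tB", "B\tC", "A\tC"))
  el <- suppressMessages(read_edge_list(f))
  expect_setequal(paste(el$gene_a, el$gene_b),
                  c("BRCA1 TP53", "A B", "B C", "A C"))
})

test_that("read_edge_list rejects degenerate inputs", {
  f <- write_tsv_lines(character(0))
  expect_error(suppressMessages(read_edge_list(f)), "zero valid rows")
  f2 <- write_tsv_lines(c("C\tC"))
  expect_error(suppressMessages(read_edge_list(f2)), "zero valid rows")
  expect_error(read_edge_list(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("read_edge_list extracts symbols from PSI-MI TAB alias columns", {
  row <- paste("uniprotkb:P1", "uniprotkb:P2",
               "uniprotkb:P1", "uniprotkb:P2",
               "uniprotkb:snca(gene name)|x:alt(gene name synonym)",
               "uniprotkb:PARK7(gene name)",
               "x", "x", "x", "x", "x", "x", "x", "x", "x", sep = "\t")
  f <- write_tsv_lines(row)
  el <- suppressMessages(read_edge_list(f, dialect = "psi_mi_tab"))
  expect_equal(paste(el$gene_a, el$gene_b), "PARK7 SNCA")
})

test_that("merge_edge_lists is an orientation-insensitive union", {
  f1 <- write_tsv_lines(c("A\tB", "A\tC"))
  f2 <- write_tsv_lines(c("B\tA", "B\tC"))
  f3 <- write_tsv_lines(c("B\tC", "D\tE"))
  e1 <- suppressMessages(read_edge_list(f1))
  e2 <- suppressMessages(read_edge_list(f2))
  e3 <- suppressMessages(read_edge_list(f3))

  m12 <- suppressMessages(merge_edge_lists(list(e1, e2)))
  expect_setequal(paste(m12$gene_a, m12$gene_b), c("A B", "A C", "B C"))

  # single list is the identity on edges
  m1 <- suppressMessages(merge_edge_lists(list(e1)))
  expect_equal(m1$gene_a, e1$gene_a)
  expect_equal(m1$gene_b, e1$gene_b)

  # three lists of sizes 2, 2, 2 with one shared edge: union of 4
  m <- suppressMessages(merge_edge_lists(list(e1, e2, e3)))
  expect_equal(nrow(m), 4)
  # provenance recorded for the shared edge
  expect_true(grepl(",", m$sources[paste(m$gene_a, m$gene_b) == "B C"]))

  # commutative and associative over edge sets
  key <- function(x) sort(paste(x$gene_a, x$gene_b))
  suppressMessages({
    expect_equal(key(merge_edge_lists(list(e2, e1, e3))), key(m))
    expect_equal(key(merge_edge_lists(list(merge_edge_lists(list(e1, e2)), e3))),
                 key(m))
  })
})

test_that("aggregate_transcripts takes per-sample medians", {
  v <- rbind(t1 = c(1, 3), t2 = c(3, 5), t3 = c(10, 10))
  colnames(v) <- c("s1", "s2")
  cond <- c(s1 = "control", s2 = "control")
  # bypass the >=3-samples rule: validate via the mapping behavior only
  expr <- structure(list(values = v,
                         condition = factor(cond, c("control", "disease"))),
                    class = "neri_expression")
  agg <- neri:::rowsum_median(v, c("G", "G", "H"))
  expect_equal(agg["G", ], c(s1 = 2, s2 = 4))
  expect_equal(agg["H", ], c(s1 = 10, s2 = 10))
  # odd-count median
  agg3 <- neri:::rowsum_median(rbind(c(1, 0), c(2, 0), c(9, 0)), rep("G", 3))
  expect_equal(unname(agg3["G", 1]), 2)
})

test_that("aggregate_transcripts drops unmapped rows and validates mapping", {
  v <- matrix(seq_len(4 * 6), 4, 6,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:6)))
  cond <- setNames(rep(c("control", "disease"), each = 3), paste0("s", 1:6))
  expr <- neri:::new_expression(v, cond)
  map <- data.frame(transcript = c("t1", "t2", "t3"), gene = c("g1", "g1", "g2"))
  expect_message(agg <- aggregate_transcripts(expr, map), "unmapped")
  expect_setequal(rownames(agg$values), c("G1", "G2"))
  expect_equal(agg$values["G1", ], apply(v[1:2, ], 2, median))
  # one transcript per gene leaves values unchanged
  expect_equal(unname(agg$values["G2", ]), unname(v[3, ]))
  expect_error(aggregate_transcripts(
    expr, data.frame(transcript = character(), gene = character())), "empty")
})

make_expr_matrix <- function(genes, n = 6) {
  v <- matrix(rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, paste0("s", seq_len(n))))
  cond <- setNames(rep(c("control", "disease"), each = n / 2),
                   paste0("s", seq_len(n)))
  neri:::new_expression(v, cond)
}

test_that("integrate_network keeps the intersection's largest component", {
  el <- suppressMessages(read_edge_list(write_tsv_lines(
    c("A\tB", "B\tC", "C\tD", "D\tE", "X\tY", "Y\tZ"))))
  set.seed(1)
  # expression covers the 5-gene component plus X, Y, Z
  expr <- make_expr_matrix(c("A", "B", "C", "D", "E", "X", "Y", "Z"))
  net <- suppressMessages(integrate_network(el, expr))
  expect_setequal(igraph::V(net$graph)$name, c("A", "B", "C", "D", "E"))

  # a network gene without expression is removed before the LCC
  expr2 <- make_expr_matrix(c("A", "B", "X", "Y", "Z"))
  net2 <- suppressMessages(integrate_network(el, expr2))
  expect_setequal(igraph::V(net2$graph)$name, c("X", "Y", "Z"))

  expect_error(suppressMessages(
    integrate_network(el, make_expr_matrix(c("Q", "R", "S")))), "shared")
  expect_error(suppressMessages(
    integrate_network(el, make_expr_matrix(c("A", "B")))), "fewer than 3")
})

test_that("integrate_network is idempotent and leaves no isolated genes", {
  set.seed(2)
  el <- suppressMessages(read_edge_list(write_tsv_lines(
    c("A\tB", "B\tC", "A\tC", "C\tD"))))
  expr <- make_expr_matrix(c("A", "B", "C", "D"))
  net1 <- suppressMessages(integrate_network(el, expr))
  # re-integrate the integrated network's own edges
  edges2 <- structure(igraph::as_data_frame(net1$graph),
                      class = c("neri_edgelist", "data.frame"))
  names(edges2)[1:2] <- c("gene_a", "gene_b")
  net2 <- suppressMessages(integrate_network(edges2, expr))
  expect_equal(sort(igraph::V(net2$graph)$name), sort(igraph::V(net1$graph)$name))
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(net1$graph))
  expect_true(all(igraph::degree(net1$graph) >= 1))
  # every gene has complete expression vectors in both conditions
  expect_setequal(rownames(net1$expr$control), igraph::V(net1$graph)$name)
  expect_setequal(rownames(net1$expr$disease), igraph::V(net1$graph)$name)
  expect_false(anyNA(net1$expr$control))
})

test_that("expression loading validates labels and sample counts", {
  v <- matrix(1:12, 3, 4, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_error(neri:::new_expression(v, c(s1 = "control", s2 = "control",
                                          s3 = "disease", s4 = "disease")),
               "at least 3")
  v[1, 1] <- NA
  expect_error(neri:::new_expression(v, setNames(rep("control", 4),
                                                 paste0("s", 1:4))), "missing")
})
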