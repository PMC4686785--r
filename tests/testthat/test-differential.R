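make_scores <- function(sig, condition) {
  structure(list(condition = condition, sigma = sig,
                 n_paths = setNames(rep(1L, length(sig)), names(sig))),
            class = "neri_scores")
}

test_that("compute_xdelta combines condition scores per the definitions", {
  sc <- make_scores(c(g1 = 1, g2 = 2, g3 = 2, g5 = 0), "control")
  sd_ <- make_scores(c(g1 = 3, g2 = 2, g4 = 1.5), "disease")
  tab <- suppressMessages(compute_xdelta(sc, sd_))
  expect_equal(tab$x[tab$gene == "g1"], 4)
  expect_equal(tab$delta[tab$gene == "g1"], 0.5)
  expect_equal(tab$delta[tab$gene == "g2"], 0)
  # one-condition genes hit the boundary
  expect_equal(tab$delta[tab$gene == "g3"], -1)
  expect_equal(tab$delta[tab$gene == "g4"], 1)
  # x = 0 genes are dropped
  expect_false("g5" %in% tab$gene)
  # strictly-greater-than filter at x_ini
  tab5 <- suppressMessages(compute_xdelta(
    make_scores(c(a = 2.5, b = 2.6), "control"),
    make_scores(c(a = 2.5, b = 2.6), "disease")))
  expect_true(tab5$filtered[tab5$gene == "a"])  # x = 5 is filtered
  expect_false(tab5$filtered[tab5$gene == "b"]) # x = 5.2 is kept
  expect_error(compute_xdelta(sd_, sc), "order")
})

test_that("power-law fit recovers noiseless envelopes exactly", {
  # non-overlapping unit windows, 5 identical points at each midpoint,
  # |delta| = 2 / x exactly
  p <- neri_params(w_len = 1, w_step = 1)
  centers <- seq(5.5, 19.5, by = 1)
  x <- rep(centers, each = 5)
  tab <- toy_scoretable(x, 2 / x)
  fit <- fit_powerlaw(tab, p)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$k, 1, tolerance = 1e-9)

  # constant envelope: k = 0, a = c
  tab2 <- toy_scoretable(x, rep(0.25, length(x)))
  fit2 <- fit_powerlaw(tab2, p)
  expect_equal(fit2$k, 0, tolerance = 1e-9)
  expect_equal(fit2$a, 0.25, tolerance = 1e-9)

  # general (a, k) grid without noise
  tab3 <- toy_scoretable(x, 0.5 * x^(-0.7))
  fit3 <- fit_powerlaw(tab3, p)
  expect_equal(fit3$a, 0.5, tolerance = 1e-6)
  expect_equal(fit3$k, 0.7, tolerance = 1e-6)
})

test_that("power-law fit drops zero-quartile windows and signs of delta are irrelevant", {
  p <- neri_params(w_len = 1, w_step = 1)
  centers <- seq(5.5, 12.5, by = 1)
  x <- rep(centers, each = 5)
  y <- 2 / x
  y[x == 5.5] <- 0 # a fully null window
  expect_message(fit <- fit_powerlaw(toy_scoretable(x, y), p), "q3 = 0")
  expect_equal(fit$k, 1, tolerance = 1e-9)
  # Q3 is taken over |delta|: alternating signs change nothing
  fit_signed <- fit_powerlaw(toy_scoretable(x, y * rep_len(c(1, -1), length(y))), p)
  expect_equal(fit_signed$k, fit$k, tolerance = 1e-12)
  expect_error(fit_powerlaw(toy_scoretable(c(6, 6.2), c(.1, .1)), p),
               "fewer than 2")
})

test_that("delta_prime divides by the envelope and preserves order in |delta|", {
  p <- neri_params(w_len = 1, w_step = 1)
  centers <- seq(5.5, 14.5, by = 1)
  x <- rep(centers, each = 5)
  tab <- toy_scoretable(x, 0.6 * x^(-1))
  fit <- fit_powerlaw(tab, p)
  # crafted gene: delta 0.3 where f(x) = 0.6 -> delta' = 0.5
  x0 <- (0.6 / fit$a)^(-1 / fit$k)
  tab2 <- toy_scoretable(c(x, x0, x0, x0), c(0.6 / x, 0.3, 0, -0.15))
  tab2 <- compute_delta_prime(tab2, fit)
  n <- nrow(tab2)
  expect_equal(tab2$delta_prime[n - 2], 0.5, tolerance = 1e-9)
  expect_equal(tab2$delta_prime[n - 1], 0)
  expect_equal(tab2$delta_prime[n], -0.25, tolerance = 1e-9)
  # for equal x, |delta'| increases strictly with |delta|
  expect_gt(abs(tab2$delta_prime[n - 2]), abs(tab2$delta_prime[n]))
  # sign preserved
  expect_lt(tab2$delta_prime[n], 0)
})

test_that("rank columns cover unfiltered genes only", {
  p <- neri_params(w_len = 1, w_step = 1)
  x <- c(rep(seq(5.5, 10.5), each = 5), 2, 3)
  tab <- toy_scoretable(x, 0.9 * x^(-0.5))
  fit <- fit_powerlaw(tab, p)
  tab <- compute_delta_prime(tab, fit)
  expect_true(all(is.na(tab$rank_abs_delta_prime[tab$filtered])))
  expect_true(all(!is.na(tab$delta_prime))) # values tabulated for everyone
  un <- !tab$filtered
  expect_setequal(tab$rank_abs_delta_prime[un], seq_len(sum(un)))
})

test_that("rank_and_select orders by the chosen key with stable ties", {
  tab <- toy_scoretable(x = seq(6, 24, by = 2), delta = rep(0.5, 10))
  tab$delta_prime <- c(0.9, 0.2, 0.2, 0.8, 0.1, 0.7, 0.3, 0.6, 0.5, 0.4)
  expect_length(rank_and_select(tab, "abs_delta_prime", 0.2), 2)
  top <- rank_and_select(tab, "abs_delta_prime", 1)
  expect_equal(top[1:2], tab$gene[c(1, 4)])
  # tie at 0.2 resolves lexicographically, twice the same way
  expect_equal(rank_and_select(tab, "abs_delta_prime", 1),
               rank_and_select(tab, "abs_delta_prime", 1))
  tied <- top[8:9]
  expect_equal(tied, sort(tab$gene[c(2, 3)]))
  # ranking by x follows x descending
  expect_equal(rank_and_select(tab, "x", 1), rev(tab$gene))
  # scored universe includes filtered genes
  tab$filtered[1] <- TRUE
  expect_length(rank_and_select(tab, "x", 1), 9)
  expect_length(rank_and_select(tab, "x", 1, universe = "scored"), 10)
})

test_that("overlap_stats reproduces the replication arithmetic", {
  # three lists each 10% of the universe: expected proportion 0.1%
  uni <- sprintf("g%04d", 1:1000)
  lists <- list(uni[1:100], uni[51:150], uni[101:200])
  os <- overlap_stats(lists, 1000)
  expect_equal(os$expected_proportion, 0.001)
  expect_equal(os$expected_count, 1)

  # identical lists overlap completely
  os2 <- overlap_stats(list(uni[1:50], uni[1:50]), 1000)
  expect_equal(os2$observed_proportion, 1)
  expect_equal(os2$intersection, sort(uni[1:50]))

  expect_error(overlap_stats(list(uni, uni[1:10]), 100), "universe")
})

test_that("rank_agreement reports per-N intersections and correlations", {
  a <- c("a", "b", "c", "d")
  b <- c("b", "a", "c", "d")
  ra <- rank_agreement(a, a, n_grid = c(2, 4))
  expect_equal(ra$proportion, c(1, 1))
  expect_equal(ra$spearman, c(1, 1))

  # swapped top pair: full intersection, reversed order
  ra2 <- rank_agreement(a, b, n_grid = 2)
  expect_equal(ra2$proportion, 1)
  expect_equal(ra2$spearman, -1)

  # disjoint top-N
  ra3 <- rank_agreement(c("a", "b", "x", "y"), c("c", "d", "x", "y"), n_grid = 2)
  expect_equal(ra3$proportion, 0)
  expect_true(is.na(ra3$spearman))
})
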