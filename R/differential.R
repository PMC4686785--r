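#' Combine condition scores into intensity X and alteration Delta
#'
#' Over the union of genes scored in either condition (a missing score is 0):
#' `X = sigma_C + sigma_D` and `Delta = (sigma_D - sigma_C) / X`. Delta ranges
#' over `[-1, 1]`; negative values mean the control score dominates, positive
#' the disease score. Genes with `X = 0` are dropped (logged). Genes with
#' `X <= x_ini` are flagged `filtered`: large-X genes show systematically
#' smaller Delta (the MA-plot intensity effect), and the very-low-X tail is
#' too unstable to normalize, so only genes with X strictly above the
#' threshold take part in envelope fitting and Delta' ranking.
#'
#' @param sc,sd `neri_scores` for control and disease.
#' @param params A `neri_params` (uses `x_ini`).
#' @return A `neri_scoretable` data frame: `gene`, `sigma_control`,
#'   `sigma_disease`, `x`, `delta`, `n_paths_control`, `n_paths_disease`,
#'   `filtered`, rows ordered by gene symbol.
#' @export
compute_xdelta <- function(sc, sd, params = neri_params()) {
  stopifnot(inherits(sc, "neri_scores"), inherits(sd, "neri_scores"))
  if (sc$condition != "control" || sd$condition != "disease") {
    stop("compute_xdelta expects (control, disease) score objects in that order")
  }
  genes <- sort(union(names(sc$sigma), names(sd$sigma)))
  s_c <- stats::setNames(rep(0, length(genes)), genes)
  s_d <- s_c
  s_c[names(sc$sigma)] <- sc$sigma
  s_d[names(sd$sigma)] <- sd$sigma
  x <- s_c + s_d
  zero <- x == 0
  if (any(zero)) {
    message("compute_xdelta: dropping ", sum(zero), " gene(s) with X = 0")
    genes <- genes[!zero]; s_c <- s_c[!zero]; s_d <- s_d[!zero]; x <- x[!zero]
  }
  np_c <- stats::setNames(rep(0L, length(genes)), genes)
  np_d <- np_c
  np_c[intersect(genes, names(sc$n_paths))] <- sc$n_paths[intersect(genes, names(sc$n_paths))]
  np_d[intersect(genes, names(sd$n_paths))] <- sd$n_paths[intersect(genes, names(sd$n_paths))]
  tab <- data.frame(
    gene = genes,
    sigma_control = unname(s_c),
    sigma_disease = unname(s_d),
    x = unname(x),
    delta = unname((s_d - s_c) / x),
    n_paths_control = unname(np_c),
    n_paths_disease = unname(np_d),
    filtered = unname(x <= params$x_ini),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("neri_scoretable", "data.frame"))
}

# Window summary points: third quartile of `y` in sliding windows over `x`.
window_q3 <- function(x, y, w_len, w_step, x_ini, min_points) {
  starts <- seq(x_ini, max(x), by = w_step)
  pts <- lapply(starts, function(lo) {
    inw <- x >= lo & x < lo + w_len
    if (sum(inw) < min_points) return(NULL)
    q3 <- unname(stats::quantile(y[inw], 0.75, type = 7)) # linear interpolation
    data.frame(x_center = lo + w_len / 2, q3 = q3, n = sum(inw))
  })
  do.call(rbind, c(pts, list(make.row.names = FALSE)))
}

#' Fit the sliding-window third-quartile power-law envelope
#'
#' Windows `[x_ini + i * w_step, x_ini + i * w_step + w_len)` slide along the
#' X axis until the window start exceeds `max(X)`. In each window holding at
#' least `min_points_per_window` unfiltered genes, the third quartile (linear
#' interpolation between order statistics) of `|Delta|` is paired with the
#' window midpoint, and `f(x) = a * x^(-k)` is fitted to the summary points by
#' ordinary least squares on `log(q3) = log(a) - k * log(x_center)`. Windows
#' with `q3 = 0` cannot enter the log fit and are dropped (logged).
#'
#' With `envelope = "signed"` two independent envelopes are fitted: to the Q3
#' of `Delta` among positive-Delta genes and to the Q3 of `|Delta|` among
#' negative-Delta genes.
#'
#' @param table A `neri_scoretable` from [compute_xdelta()].
#' @param params A `neri_params` (uses `w_len`, `w_step`, `x_ini`,
#'   `min_points_per_window`, `envelope`).
#' @return A `neri_powerlaw`: `a`, `k`, `window_points` (data frame of
#'   `x_center`, `q3`, `n`); for signed envelopes, `positive` and `negative`
#'   sub-fits of the same shape.
#' @export
fit_powerlaw <- function(table, params = neri_params()) {
  stopifnot(inherits(table, "neri_scoretable"))
  use <- table[!table$filtered, , drop = FALSE]
  if (params$envelope == "signed") {
    pos <- use[use$delta > 0, , drop = FALSE]
    neg <- use[use$delta < 0, , drop = FALSE]
    fit <- list(
      positive = powerlaw_one_side(pos$x, abs(pos$delta), params),
      negative = powerlaw_one_side(neg$x, abs(neg$delta), params),
      envelope = "signed"
    )
    return(structure(fit, class = "neri_powerlaw"))
  }
  out <- powerlaw_one_side(use$x, abs(use$delta), params)
  out$envelope <- "absolute"
  structure(out, class = "neri_powerlaw")
}

powerlaw_one_side <- function(x, y, params) {
  if (length(x) == 0) stop("no unfiltered genes available for the envelope fit")
  mp <- params$min_points_per_window
  pts <- window_q3(x, y, params$w_len, params$w_step, params$x_ini, mp)
  # On sparse X distributions the requested occupancy can leave < 2 windows;
  # relax the minimum (down to 1) rather than abort, and say so.
  while ((is.null(pts) || nrow(pts) < 2) && mp > 1) {
    mp <- mp - 1L
    pts <- window_q3(x, y, params$w_len, params$w_step, params$x_ini, mp)
  }
  if (mp < params$min_points_per_window && !is.null(pts) && nrow(pts) >= 2) {
    message("fit_powerlaw: relaxed min_points_per_window to ", mp,
            " to obtain at least 2 windows")
  }
  if (is.null(pts) || nrow(pts) < 2) {
    stop("fewer than 2 usable windows for the power-law fit; ",
         "shrink w_len or x_ini")
  }
  zero <- pts$q3 <= 0
  if (any(zero)) {
    message("fit_powerlaw: dropping ", sum(zero), " window(s) with q3 = 0")
  }
  fitpts <- pts[!zero, , drop = FALSE]
  if (nrow(fitpts) < 2) {
    stop("fewer than 2 usable windows for the power-law fit; ",
         "shrink w_len/x_ini or lower min_points_per_window")
  }
  co <- stats::coef(stats::lm(log(q3) ~ log(x_center), data = fitpts))
  list(a = unname(exp(co[1])), k = unname(-co[2]), window_points = pts)
}

#' Evaluate a fitted power-law envelope
#'
#' `f(x) = a * x^(-k)`, including extrapolation beyond the fitted window
#' range. For signed envelopes, `side` picks the branch.
#'
#' @param fit A `neri_powerlaw`.
#' @param x Numeric vector of intensities.
#' @param side `"positive"` or `"negative"` (signed envelopes only).
#' @return `f(x)`.
#' @export
predict_envelope <- function(fit, x, side = c("positive", "negative")) {
  stopifnot(inherits(fit, "neri_powerlaw"))
  if (identical(fit$envelope, "signed")) {
    side <- match.arg(side)
    f <- fit[[side]]
  } else {
    f <- fit
  }
  v <- f$a * x^(-f$k)
  if (any(!is.finite(v)) || any(v <= 0)) stop("envelope evaluated non-positive")
  v
}

#' Normalize Delta by the intensity envelope: Delta'
#'
#' `Delta'(g) = Delta(g) / f(X(g))`, the envelope extrapolated across the
#' whole X range. Small-X genes (large natural alteration spread) are divided
#' by a large envelope value and large-X genes by a small one, making
#' alterations comparable across the intensity range. The sign of Delta'
#' matches Delta: positive means larger coexpression with the seeds in
#' disease, negative in control. Genes are ranked by descending `|Delta'|`
#' (and, for reference, by descending X), ties broken by gene symbol; the
#' rank columns cover unfiltered genes only — genes below the intensity floor
#' are not reported by the selection step, though their Delta' values are
#' tabulated.
#'
#' @param table A `neri_scoretable`.
#' @param fit A `neri_powerlaw` from [fit_powerlaw()].
#' @return The table with `delta_prime`, `rank_abs_delta_prime` and `rank_x`
#'   columns added (ranks NA for filtered genes).
#' @export
compute_delta_prime <- function(table, fit) {
  stopifnot(inherits(table, "neri_scoretable"), inherits(fit, "neri_powerlaw"))
  dp <- rep(NA_real_, nrow(table))
  un <- !table$filtered
  if (identical(fit$envelope, "signed")) {
    pos <- table$delta >= 0
    dp[pos] <- table$delta[pos] / predict_envelope(fit, table$x[pos], "positive")
    dp[!pos] <- table$delta[!pos] / predict_envelope(fit, table$x[!pos], "negative")
  } else {
    dp <- table$delta / predict_envelope(fit, table$x)
  }
  table$delta_prime <- dp
  ord_dp <- order(-abs(table$delta_prime[un]), table$gene[un])
  ord_x <- order(-table$x[un], table$gene[un])
  rk_dp <- rep(NA_integer_, nrow(table))
  rk_x <- rep(NA_integer_, nrow(table))
  rk_dp[which(un)[ord_dp]] <- seq_len(sum(un))
  rk_x[which(un)[ord_x]] <- seq_len(sum(un))
  table$rank_abs_delta_prime <- rk_dp
  table$rank_x <- rk_x
  table
}

#' Rank genes and select the top fraction
#'
#' Orders genes descending by `|Delta'|` or by X (ties broken by gene symbol,
#' so runs are reproducible) and returns the top
#' `ceiling(top_fraction * universe size)` symbols. The default universe is
#' the unfiltered genes (the method's reported selection); `"scored"` ranks
#' every path-covered gene, which benchmark evaluation uses so that recovery
#' is measured against the whole candidate universe.
#'
#' @param table A `neri_scoretable` with a `delta_prime` column.
#' @param by `"abs_delta_prime"` or `"x"`.
#' @param top_fraction Fraction in `(0, 1]`; defaults to 0.1.
#' @param universe `"unfiltered"` (default) or `"scored"`.
#' @return Character vector of gene symbols in rank order.
#' @export
rank_and_select <- function(table, by = c("abs_delta_prime", "x"),
                            top_fraction = 0.1,
                            universe = c("unfiltered", "scored")) {
  by <- match.arg(by)
  universe <- match.arg(universe)
  stopifnot(inherits(table, "neri_scoretable"),
            top_fraction > 0, top_fraction <= 1)
  un <- if (universe == "unfiltered") {
    table[!table$filtered, , drop = FALSE]
  } else {
    table
  }
  if (nrow(un) == 0) stop("no unfiltered genes to rank")
  key <- if (by == "abs_delta_prime") abs(un$delta_prime) else un$x
  ord <- order(-key, un$gene)
  un$gene[ord][seq_len(ceiling(top_fraction * nrow(un)))]
}

#' Multi-list replication overlap statistics
#'
#' For two or more gene lists drawn from a common universe: the intersection,
#' its observed size as a proportion of the mean list size, and the count and
#' proportion expected if the lists were drawn independently at random
#' (`universe * prod(len_i / universe)` and `prod(len_i / universe)`). Three
#' independent lists each covering 10% of the universe are expected to share
#' only 0.1% (10% x 10% x 10%) of a mean list.
#'
#' @param lists List of >= 2 nonempty character vectors.
#' @param universe_size Number of genes each list was drawn from; must be at
#'   least each list's size.
#' @return List: `intersection`, `observed_count`, `observed_proportion`,
#'   `expected_count`, `expected_proportion`.
#' @export
overlap_stats <- function(lists, universe_size) {
  stopifnot(length(lists) >= 2, all(lengths(lists) > 0))
  sizes <- lengths(lists)
  if (any(sizes > universe_size)) stop("universe smaller than a list")
  inter <- Reduce(intersect, lists)
  list(
    intersection = sort(inter),
    observed_count = length(inter),
    observed_proportion = length(inter) / mean(sizes),
    expected_count = universe_size * prod(sizes / universe_size),
    expected_proportion = prod(sizes / universe_size)
  )
}

#' Top-N agreement between two rankings
#'
#' For each N in `n_grid`: the proportion of genes shared by the two top-N
#' lists, and the Spearman correlation of the within-intersection rank
#' positions. The correlation is `NA` when the intersection holds fewer than
#' 2 genes; correlations on very small intersections (< 3 genes) are defined
#' but carry little information and fluctuate strongly.
#'
#' @param rank_a,rank_b Ordered gene vectors (best first).
#' @param n_grid Integer vector of list lengths, each within both rankings.
#' @return Data frame: `n`, `intersection_size`, `proportion`, `spearman`.
#' @export
rank_agreement <- function(rank_a, rank_b, n_grid) {
  stopifnot(all(n_grid >= 1), all(n_grid <= length(rank_a)),
            all(n_grid <= length(rank_b)))
  rows <- lapply(n_grid, function(n) {
    top_a <- rank_a[seq_len(n)]
    top_b <- rank_b[seq_len(n)]
    inter <- intersect(top_a, top_b)
    rho <- if (length(inter) < 2) NA_real_ else
      stats::cor(match(inter, top_a), match(inter, top_b), method = "spearman")
    data.frame(n = n, intersection_size = length(inter),
               proportion = length(inter) / n, spearman = rho)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
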