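#' Average (mid-rank) ranks of a numeric vector
#'
#' Ranks in ascending order (smallest value gets rank 1), with ties receiving
#' the mean of the ranks they span. This is the rank basis for Kendall's W:
#' each gene ("judge") ranks the samples ("objects") by expression.
#'
#' A constant vector is legal and yields all ranks equal to `(n + 1) / 2`;
#' a warning flags it because it carries no ordering information.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of mid-ranks in `[1, n]` summing to `n(n+1)/2`.
#' @export
#' @examples
#' average_ranks(c(0.1, 0.5, 0.3)) # 1 3 2
#' average_ranks(c(2, 2, 5))       # 1.5 1.5 3
average_ranks <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2, !anyNA(values))
  if (length(unique(values)) == 1L) {
    warning("constant profile: all ranks tied at (n+1)/2")
  }
  rank(values, ties.method = "average")
}

# Tie-correction term for one rank row: sum over tie groups of (t^3 - t).
tie_term <- function(rank_row) {
  t <- tabulate(match(rank_row, unique(rank_row)))
  sum(t^3 - t)
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among `m` rankings (rows) of `n` objects (columns), with the
#' standard correction for tied ranks:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m T}}
#' where \eqn{S = \sum_j (R_j - m(n+1)/2)^2} over column sums \eqn{R_j} and
#' \eqn{T} is the summed tie term \eqn{\sum (t^3 - t)} across rows. W is 1 for
#' perfect agreement and 0 for none; the value is clamped to `[0, 1]` against
#' floating-point drift.
#'
#' @param R Numeric matrix of ranks, rows = judges (genes), columns = objects
#'   (samples); rows must be valid mid-rank vectors.
#' @return Scalar W in `[0, 1]`. A fully tied matrix (zero denominator) returns
#'   0 with a warning.
#' @export
#' @examples
#' kendall_w(rbind(1:3, 1:3))   # 1
#' kendall_w(rbind(1:3, 3:1))   # 0
kendall_w <- function(R) {
  stopifnot(is.matrix(R), nrow(R) >= 2, ncol(R) >= 2)
  m <- nrow(R)
  n <- ncol(R)
  S <- sum((colSums(R) - m * (n + 1) / 2)^2)
  T <- sum(apply(R, 1L, tie_term))
  denom <- m^2 * (n^3 - n) - m * T
  if (denom <= 0) {
    warning("all rankings fully tied; W undefined, returning 0")
    return(0)
  }
  min(max(12 * S / denom, 0), 1)
}

#' Inversion-maximized concordance W_max
#'
#' Kendall's W made insensitive to the sign of coexpression: every gene profile
#' may be inverted (up- and down-regulation treated as equivalent), and the
#' sign assignment maximizing W is reported. All `2^(m-1)` assignments are
#' enumerated exactly, with the first gene fixed to `+1` (negating every
#' profile leaves W unchanged). Inversion is profile negation before ranking;
#' under mid-ranks this coincides with rank reversal `n + 1 - r`.
#'
#' Ties in the maximum are broken by the lexicographically smallest sign
#' vector (`+1` sorting before `-1`), so results are deterministic.
#'
#' @param profiles Numeric matrix, rows = gene expression profiles over one
#'   condition's samples (columns). `2 <= nrow <= max_genes`.
#' @param max_genes Cap on the number of profiles; enumeration is `2^(m-1)` so
#'   the cap guards pathological inputs (default 12).
#' @return A `neri_concordance` list: `w` (plain W of the unflipped profiles),
#'   `w_max`, and `signs` (`+1`/`-1` per gene, first gene `+1`).
#' @export
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
#' w_max(x) # w = 0, w_max = 1, signs +1 -1
w_max <- function(profiles, max_genes = 12L) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2)
  m <- nrow(profiles)
  n <- ncol(profiles)
  if (m < 2) stop("need at least 2 profiles")
  if (m > max_genes) {
    stop("path has ", m, " genes, above the enumeration cap of ", max_genes,
         "; raise max_path_genes if this is intended")
  }
  R <- t(apply(profiles, 1L, rank, ties.method = "average"))
  M <- (n + 1) - R # mid-ranks of the negated profile (mirror symmetry)

  # Denominator is invariant under inversion: tie structure is mirrored.
  T <- sum(apply(R, 1L, tie_term))
  denom <- m^2 * (n^3 - n) - m * T
  w_plain <- if (denom <= 0) 0 else
    min(max(12 * sum((colSums(R) - m * (n + 1) / 2)^2) / denom, 0), 1)
  if (denom <= 0) {
    warning("all rankings fully tied; W undefined, returning 0")
    return(structure(list(w = 0, w_max = 0, signs = rep(1, m)),
                     class = "neri_concordance"))
  }

  # flips: 2^(m-1) x m 0/1 matrix, gene 1 never flipped; row order is the
  # lexicographic order of sign vectors (+1 before -1), so which.max's
  # first-hit rule yields the lexicographically smallest argmax.
  flips <- as.matrix(expand.grid(rep(list(0:1), m - 1L)))[, (m - 1L):1, drop = FALSE]
  flips <- unname(cbind(0L, flips))
  base <- colSums(R)
  # column sums per assignment: flipping gene i replaces R[i,] by M[i,]
  cs <- flips %*% (M - R) + matrix(base, nrow(flips), n, byrow = TRUE)
  S <- rowSums((cs - m * (n + 1) / 2)^2)
  W <- pmin(pmax(12 * S / denom, 0), 1)
  best <- which.max(W)
  structure(
    list(w = w_plain, w_max = W[best], signs = 1 - 2 * as.numeric(flips[best, ])),
    class = "neri_concordance"
  )
}

#' @export
print.neri_concordance <- function(x, ...) {
  cat(sprintf("W = %.4f, W_max = %.4f, signs: %s\n",
              x$w, x$w_max, paste(ifelse(x$signs > 0, "+", "-"), collapse = "")))
  invisible(x)
}
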