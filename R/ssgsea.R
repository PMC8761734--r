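# Single-sample gene-set enrichment (ssGSEA) scoring of marker signatures,
# as used for immune-infiltration quantitation, plus the rank-sum group
# comparison applied to the resulting scores.

#' ssGSEA enrichment score of one gene set in one sample
#'
#' Genes are ranked by decreasing expression; the gene at descending
#' position `i` among `N` genes carries weight `(N - i + 1)^alpha` when it
#' belongs to the set.  The score is the integrated difference between the
#' weighted in-set cumulative distribution and the unweighted out-of-set
#' one:
#' `ES = sum_i [ P_in(i) - P_out(i) ]`.
#' The score depends only on the ranking, so it is invariant under strictly
#' monotone transforms of the expression values.
#'
#' @param expr Named numeric vector of expression values for one sample
#'   (>= 2 genes).
#' @param set Character vector of member gene ids.  Members absent from
#'   `expr` are dropped with a message.
#' @param alpha Rank weight exponent; `0.25` by default (the convention of
#'   the original ssGSEA implementations).
#' @param ties `"lexicographic"` (default) orders equal expression values by
#'   gene id so the score is deterministic; `"average"` additionally
#'   replaces the rank weights by tie-averaged ranks.
#' @return The enrichment score (a real number).
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25,
                         ties = c("lexicographic", "average")) {
  ties <- match.arg(ties)
  if (length(expr) < 2)
    stop("ssgsea_score: need at least 2 genes", call. = FALSE)
  if (is.null(names(expr)))
    stop("ssgsea_score: expression vector must be named", call. = FALSE)
  ids <- names(expr)
  present <- intersect(set, ids)
  dropped <- length(setdiff(set, ids))
  if (dropped > 0)
    message(sprintf("ssgsea_score: %d set member(s) absent from matrix",
                    dropped))
  N <- length(expr)
  m <- length(present)
  if (m == 0 || m == N)
    stop("ssgsea_score: degenerate gene set (empty after intersection, or ",
         "covering every gene)", call. = FALSE)
  ord <- order(-expr, ids)
  in_set <- ids[ord] %in% present
  w <- if (ties == "average") {
    r <- rank(expr, ties.method = "average")    # N for the highest value
    (r[ord])^alpha
  } else {
    (N - seq_len(N) + 1)^alpha
  }
  p_in <- cumsum(w * in_set) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (N - m)
  sum(p_in - p_out)
}

#' ssGSEA score matrix (sets x samples)
#'
#' Applies [ssgsea_score()] to every (set, sample) pair, optionally
#' rescaling each set's scores to `[0, 1]` across samples so infiltration
#' levels are comparable between sets.
#'
#' @param expr Numeric expression matrix, genes x samples, with dimnames.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Rank weight exponent, see [ssgsea_score()].
#' @param scale If `TRUE` (default) rescale scores to `[0, 1]`.
#' @param scale_method `"per_set"` (default) min-max scales each set row
#'   independently; `"global"` uses the one min/max of the whole matrix.
#' @param ties Tie handling, see [ssgsea_score()].
#' @return Numeric matrix of enrichment scores, sets x samples.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, scale = TRUE,
                   scale_method = c("per_set", "global"),
                   ties = c("lexicographic", "average")) {
  scale_method <- match.arg(scale_method)
  ties <- match.arg(ties)
  if (!length(sets)) stop("ssgsea: no gene sets", call. = FALSE)
  if (is.null(names(sets)))
    stop("ssgsea: gene-set list must be named", call. = FALSE)
  es <- matrix(NA_real_, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  for (s in seq_along(sets)) {
    for (j in seq_len(ncol(expr))) {
      es[s, j] <- tryCatch(
        suppressMessages(ssgsea_score(expr[, j], sets[[s]], alpha = alpha,
                                      ties = ties)),
        error = function(e)
          stop(sprintf("ssgsea: set '%s': %s", names(sets)[s],
                       conditionMessage(e)), call. = FALSE))
    }
  }
  if (scale) {
    if (scale_method == "global") {
      rng <- range(es)
      es <- if (diff(rng) == 0) es * 0 else (es - rng[1]) / diff(rng)
    } else {
      for (s in seq_len(nrow(es))) {
        rng <- range(es[s, ])
        es[s, ] <- if (diff(rng) == 0) 0 else (es[s, ] - rng[1]) / diff(rng)
      }
    }
  }
  es
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Rank-sum test with average ranks for ties and a two-sided p-value from
#' the normal approximation with tie-corrected variance and continuity
#' correction (via [stats::wilcox.test()]).  When every value in both
#' groups is identical the test is vacuous: the statistic is its null
#' expectation and `p = 1`, with a warning.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p.value`, and
#'   group sizes `n`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y))
    stop("rank_sum_test: both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1) {
    warning("rank_sum_test: all values identical; p = 1", call. = FALSE)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                n = c(length(x), length(y))))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = c(length(x), length(y)))
}
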