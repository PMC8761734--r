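# Pearson/Spearman correlation records and the thresholded feature screens
# (|r| > 0.2, p < 0.01 by default) used both for the GPCR-macrophage screen
# and the TF-accessibility screen.

#' Correlation record between two numeric vectors
#'
#' Pearson `r` is the usual product-moment coefficient; Spearman is Pearson
#' applied to tie-averaged ranks.  The two-sided p-value comes from the
#' exact t reference distribution, `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @param feature_a,feature_b Labels stored in the record.
#' @return One-row `data.frame`: `feature_a`, `feature_b`, `method`, `r`,
#'   `p`, `n`.
#' @export
cor_record <- function(x, y, method = c("pearson", "spearman"),
                       feature_a = "x", feature_b = "y") {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("cor_record: unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("cor_record: need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("cor_record: NA values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cor_record: constant input vector (correlation undefined)",
         call. = FALSE)
  r <- stats::cor(x, y, method = method)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  data.frame(feature_a = feature_a, feature_b = feature_b, method = method,
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}

#' Screen feature rows against a target vector at fixed thresholds
#'
#' Correlates every row of `features` with `target` over the shared samples
#' and keeps features passing `|r| > r_min` and `p < p_max` (both strict,
#' the standard screen thresholds).  Constant rows are skipped with
#' a message; results are sorted by decreasing `|r|` with ties broken by
#' feature id.
#'
#' @param features Numeric matrix, features x samples, with dimnames.
#' @param target Named numeric vector over (a superset/subset of) the same
#'   samples; alignment is by shared sample id.
#' @param method `"pearson"` or `"spearman"`.
#' @param r_min,p_max Screen thresholds (defaults 0.2 and 0.01).
#' @param target_name Label for `feature_b` in the records.
#' @param bh If `TRUE`, filter on Benjamini-Hochberg adjusted p instead of
#'   raw p (off by default, reproducing the raw-threshold procedure).
#' @return `data.frame` of passing correlation records; attribute
#'   `n_tested` holds the number of non-constant features screened.
#' @export
screen_features <- function(features, target, method = c("pearson", "spearman"),
                            r_min = 0.2, p_max = 0.01,
                            target_name = "target", bh = FALSE) {
  method <- match.arg(method)
  if (is.null(colnames(features)) || is.null(names(target)))
    stop("screen_features: features and target must carry sample ids",
         call. = FALSE)
  shared <- intersect(colnames(features), names(target))
  n_drop <- (ncol(features) - length(shared)) + (length(target) - length(shared))
  if (n_drop > 0)
    message(sprintf("screen_features: %d sample id(s) outside the intersection dropped",
                    n_drop))
  if (length(shared) < 3)
    stop("screen_features: fewer than 3 shared samples", call. = FALSE)
  fx <- features[, shared, drop = FALSE]
  ty <- target[shared]
  if (stats::sd(ty) == 0)
    stop("screen_features: constant target vector", call. = FALSE)
  recs <- vector("list", nrow(fx))
  skipped <- 0L
  for (i in seq_len(nrow(fx))) {
    if (stats::sd(fx[i, ]) == 0) { skipped <- skipped + 1L; next }
    recs[[i]] <- cor_record(fx[i, ], ty, method = method,
                            feature_a = rownames(fx)[i],
                            feature_b = target_name)
  }
  if (skipped > 0)
    message(sprintf("screen_features: %d constant feature row(s) skipped",
                    skipped))
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- cor_record(c(1, 2, 3), c(1, 2, 3))[0, ]
  n_tested <- nrow(recs)
  p_crit <- if (bh && n_tested > 0) stats::p.adjust(recs$p, "BH") else recs$p
  keep <- abs(recs$r) > r_min & p_crit < p_max
  out <- recs[keep, , drop = FALSE]
  out <- out[order(-abs(out$r), out$feature_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}
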