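# Survival analysis: follow-up filtering, Kaplan-Meier estimation,
# log-rank testing with the signed standardized statistic, maximally
# selected optimal cutpoint search, and Cox model fitting with Harrell
# concordance.  KM and Cox delegate to the `survival` package; the
# log-rank tally is implemented directly because the cutpoint rule needs
# the signed standardized statistic at every candidate split.

.check_clin <- function(clin) {
  if (!all(c("time", "event") %in% names(clin)))
    stop("clinical table needs 'time' and 'event' columns", call. = FALSE)
  if (any(clin$time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(clin$event %in% c(0, 1)))
    stop("event must be 0 or 1", call. = FALSE)
  invisible(clin)
}

#' Drop subjects with short follow-up
#'
#' Keeps records with follow-up strictly greater than `min_days` (so a
#' 90-day follow-up is excluded at the default), guarding survival analyses
#' against early non-disease-related deaths.  Order-preserving.
#'
#' @param clin Clinical table with `time` (days) and `event` columns.
#' @param min_days Strict lower bound on follow-up time, default 90.
#' @return The filtered table; the number removed is reported via `message`.
#' @export
filter_followup <- function(clin, min_days = 90) {
  .check_clin(clin)
  keep <- clin$time > min_days
  message(sprintf("filter_followup: kept %d of %d records (time > %g days)",
                  sum(keep), nrow(clin), min_days))
  out <- clin[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncate follow-up (e.g. for 5-year analyses)
#'
#' Subjects followed beyond `days` are censored at `days`.
#' @param clin Clinical table.
#' @param days Truncation horizon, default 1825 (5 years).
#' @return Clinical table with truncated times.
#' @export
truncate_followup <- function(clin, days = 1825) {
  .check_clin(clin)
  over <- clin$time > days
  clin$event[over] <- 0L
  clin$time[over] <- days
  clin
}

#' Kaplan-Meier product-limit estimate
#'
#' @param clin Clinical table (>= 1 record).
#' @return A step table `data.frame(time, n_risk, n_event, n_censor,
#'   survival)` including the `time = 0, survival = 1` anchor; evaluate it
#'   at arbitrary times with [km_survival_at()].
#' @export
km_estimate <- function(clin) {
  .check_clin(clin)
  if (nrow(clin) == 0) stop("km_estimate: no records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = clin)
  data.frame(time = c(0, fit$time),
             n_risk = c(nrow(clin), fit$n.risk),
             n_event = c(0, fit$n.event),
             n_censor = c(0, fit$n.censor),
             survival = c(1, fit$surv))
}

#' Evaluate a Kaplan-Meier step table at given times
#' @param km Step table from [km_estimate()].
#' @param t Times (days).
#' @return Survival probabilities (right-continuous step function).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (!length(idx)) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events for group A with the hypergeometric
#' variance accumulated over event times.  Reports the signed standardized
#' statistic `(O_A - E_A)/sqrt(V_A)` (positive when group A has more events
#' than expected), its square as the chi-square statistic, and a two-sided
#' p-value on 1 df.
#'
#' @param a,b Clinical tables for the two groups, both non-empty; at least
#'   one event overall.
#' @return List with `standardized`, `chisq`, `p.value`, `observed`,
#'   `expected` (both for group A), `variance`.
#' @export
logrank_test <- function(a, b) {
  .check_clin(a); .check_clin(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("logrank_test: both groups must be non-empty", call. = FALSE)
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(1L, 0L), c(nrow(a), nrow(b)))
  if (sum(event) == 0)
    stop("logrank_test: no events in either group (test undefined)",
         call. = FALSE)
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  z <- if (V > 0) (O - E) / sqrt(V) else 0
  chisq <- z^2
  list(standardized = z, chisq = chisq,
       p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every distinct observed covariate value whose `low (<= cut)` vs
#' `high (> cut)` split leaves both groups with at least `minprop` of the
#' subjects, computes the standardized log-rank statistic for each split,
#' and returns the split maximizing its absolute value (ties break toward
#' the smaller cutpoint).  The p-value at the selected split is the raw
#' log-rank p and is flagged as selection-biased: the maximal selection is
#' not corrected for.
#'
#' @param values Covariate, one value per clinical record (aligned by
#'   position, or by `sample_id` when `values` is named).
#' @param clin Clinical table.
#' @param minprop Minimum fraction of subjects in each group, default 0.1.
#' @return List with `cutpoint`, `statistic` (max |standardized|),
#'   `group_sizes` (low, high), `p_raw`, `selection_biased = TRUE`.
#' @export
optimal_cutoff <- function(values, clin, minprop = 0.1) {
  .check_clin(clin)
  if (!is.null(names(values)) && !is.null(clin$sample_id))
    values <- values[clin$sample_id]
  if (length(values) != nrow(clin) || anyNA(values))
    stop("optimal_cutoff: covariate does not align with clinical records",
         call. = FALSE)
  n <- nrow(clin)
  cand <- sort(unique(values))
  cand <- cand[-length(cand)]            # top value leaves the high group empty
  best <- NULL
  for (cut in cand) {
    low <- values <= cut
    if (sum(low) < minprop * n || sum(!low) < minprop * n) next
    lr <- tryCatch(logrank_test(clin[low, , drop = FALSE],
                                clin[!low, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(lr)) next
    if (is.null(best) || abs(lr$standardized) > best$statistic) {
      best <- list(cutpoint = cut, statistic = abs(lr$standardized),
                   group_sizes = c(low = sum(low), high = sum(!low)),
                   p_raw = lr$p.value, selection_biased = TRUE)
    }
  }
  if (is.null(best))
    stop("optimal_cutoff: no admissible split (constant covariate, minprop ",
         "too large, or no events)", call. = FALSE)
  best
}

#' Cox proportional-hazards fit with Harrell concordance
#'
#' Breslow partial-likelihood fit (Efron tie handling behind `ties`),
#' delegating to [survival::coxph()].  Monotone likelihood / non-converged
#' fits raise an error with diagnostics rather than returning silently
#' divergent coefficients.
#'
#' @param clin Clinical table carrying the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `"cox_fit"` with `coef`, `se`, `loglik` (at the
#'   optimum), `c_index`, `n`, `n_event`, and the underlying `fit`.
#' @export
cox_fit <- function(clin, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .check_clin(clin)
  if (sum(clin$event) < 1) stop("cox_fit: no events", call. = FALSE)
  miss <- setdiff(covariates, names(clin))
  if (length(miss))
    stop("cox_fit: covariate(s) not in table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = clin, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        stop("cox_fit: fit failure: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit))) ||
      any(abs(stats::coef(fit)) > 1e4))
    stop("cox_fit: divergent coefficients (monotone likelihood?)",
         call. = FALSE)
  conc <- survival::concordance(fit)
  structure(list(coef = stats::coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 loglik = fit$loglik[2],
                 c_index = unname(conc$concordance),
                 n = fit$n, n_event = fit$nevent,
                 ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d\n", x$ties, x$n,
              x$n_event))
  tab <- data.frame(coef = x$coef, se = x$se,
                    z = x$coef / x$se,
                    p = 2 * stats::pnorm(-abs(x$coef / x$se)))
  print(tab, ...)
  cat(sprintf("log partial likelihood = %.4f, C-index = %.4f\n",
              x$loglik, x$c_index))
  invisible(x)
}

#' Harrell concordance of a risk score against survival
#'
#' Fraction of comparable subject pairs whose risk ordering matches the
#' observed survival ordering (ties counted 0.5); 0.5 is chance level,
#' higher scores are read as higher risk.
#'
#' @param scores Numeric risk scores, one per record.
#' @param clin Clinical table.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, clin) {
  .check_clin(clin)
  df <- data.frame(time = clin$time, event = clin$event, s = scores)
  fit <- survival::concordance(survival::Surv(time, event) ~ s, data = df,
                               reverse = TRUE)
  unname(fit$concordance)
}
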