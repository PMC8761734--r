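# Independently coded oracles and small random-instance generators used
# across the suite.  Each oracle re-derives the quantity from its
# definition (brute force / direct formula), deliberately not sharing code
# with the implementation it checks.

# --- random instances -------------------------------------------------------

rand_intervals <- function(n, chroms = c("chrA", "chrB", "chrC"),
                           max_pos = 1e6, max_len = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), start,
            start + sample.int(max_len, n, replace = TRUE) - 1,
            name = sprintf("p%04d", seq_len(n)))
}

rand_genes <- function(n, chroms = c("chrA", "chrB", "chrC"),
                       max_pos = 1e6) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gene_models(sprintf("g%04d", sample(n)), sample(chroms, n, replace = TRUE),
              start, start + sample.int(20000, n, replace = TRUE) + 100,
              sample(c("+", "-"), n, replace = TRUE))
}

rand_clin <- function(n, rate = 1 / 300, cens = 1 / 400) {
  t_ev <- stats::rexp(n, rate)
  t_c <- stats::rexp(n, cens)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = round(pmin(t_ev, t_c), 1),
             event = as.integer(t_ev <= t_c), stringsAsFactors = FALSE)
}

# --- brute-force peak annotation -------------------------------------------

# Signed edge distance per the documented convention, one pair at a time.
oracle_distance <- function(pstart, pend, pchrom, gene) {
  if (gene$chrom != pchrom) return(NA_real_)
  tss <- gene$tss
  if (tss >= pstart && tss <= pend) return(0)
  gap <- if (tss < pstart) pstart - tss else tss - pend
  downstream <- if (gene$strand == "+") tss < pstart else tss > pend
  if (downstream) gap else -gap
}

oracle_annotate <- function(peaks, genes, tss_region = c(-2000, 2000)) {
  out <- data.frame(peak_id = peaks$name, gene_id = NA_character_,
                    distance_to_tss = NA_real_, category = "Other",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      d <- oracle_distance(peaks$start[i], peaks$end[i], peaks$chrom[i],
                           genes[j, ])
      if (is.na(d)) next
      if (abs(d) < abs(best_d) ||
          (abs(d) == abs(best_d) && genes$gene_id[j] < best_g)) {
        best_d <- d; best_g <- genes$gene_id[j]
      }
    }
    if (is.finite(best_d)) {
      out$gene_id[i] <- best_g
      out$distance_to_tss[i] <- best_d
      out$category[i] <-
        if (best_d < tss_region[1] || best_d > tss_region[2]) "Other"
        else if (abs(best_d) <= 1000) "Promoter (<=1kb)"
        else if (abs(best_d) <= 2000) "Promoter (1-2kb)"
        else "Other"
    }
  }
  out
}

# --- direct-formula ssGSEA --------------------------------------------------

oracle_ssgsea_one <- function(expr, set, alpha) {
  ids <- names(expr)
  set <- intersect(set, ids)
  N <- length(expr)
  ord <- order(-expr, ids)
  ranked <- ids[ord]
  es <- 0; pin <- 0; pout <- 0
  win <- sum((N - which(ranked %in% set) + 1)^alpha)
  nout <- N - length(set)
  for (i in seq_len(N)) {
    if (ranked[i] %in% set) pin <- pin + (N - i + 1)^alpha / win
    else pout <- pout + 1 / nout
    es <- es + (pin - pout)
  }
  es
}

oracle_ssgsea_matrix <- function(expr, sets, alpha, scale = FALSE) {
  es <- matrix(NA_real_, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  for (s in names(sets))
    for (j in colnames(expr))
      es[s, j] <- oracle_ssgsea_one(expr[, j], sets[[s]], alpha)
  if (scale)
    es <- t(apply(es, 1, function(x)
      if (max(x) == min(x)) rep(0, length(x))
      else (x - min(x)) / (max(x) - min(x))))
  es
}

# --- rank-sum normal approximation -----------------------------------------

oracle_ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
  list(statistic = U, p.value = 2 * stats::pnorm(-abs(z)))
}

# --- exhaustive maximally selected cutpoint --------------------------------

# Uses survdiff, not the package's log-rank tally, as the independent route.
oracle_cutoff <- function(values, clin, minprop = 0.1) {
  n <- nrow(clin)
  cand <- sort(unique(values))
  cand <- cand[-length(cand)]
  best <- NULL
  for (cut in cand) {
    low <- values <= cut
    if (sum(low) < minprop * n || sum(!low) < minprop * n) next
    df <- data.frame(time = clin$time, event = clin$event, g = low)
    if (sum(df$event) == 0) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
    z <- sqrt(sd$chisq)
    if (is.null(best) || z > best$statistic + 1e-12)
      best <- list(cutpoint = cut, statistic = z)
  }
  best
}

# --- merged-interval overlap -----------------------------------------------

# Base-by-base overlap count between one candidate interval and a peak set.
oracle_chip_overlap <- function(candidate, chip) {
  covered <- logical(candidate$end - candidate$start + 1)
  for (k in seq_len(nrow(chip))) {
    if (chip$chrom[k] != candidate$chrom) next
    lo <- max(chip$start[k], candidate$start)
    hi <- min(chip$end[k], candidate$end)
    if (lo <= hi)
      covered[(lo - candidate$start + 1):(hi - candidate$start + 1)] <- TRUE
  }
  sum(covered)
}
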