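# The five-step TF-discovery procedure: promoter-annotated peaks ->
# target-gene peak selection -> Pearson screen of TF expression against
# peak accessibility -> ChIP-seq overlap support -> optional
# overexpression direction check; plus the GPCR-infiltration screen that
# precedes target-gene selection in the study design.

#' Accessible promoter peaks overlapping a target gene's locus
#'
#' From peaks already restricted to promoter categories (the procedure
#' filters promoter peaks first), keeps those whose interval overlaps the
#' target gene's whole locus.  An empty result is a legitimate "no
#' accessible promoter" outcome.
#'
#' @param peaks Interval table of peaks.
#' @param annotations Matching [annotate_peaks()] output (rows joined to
#'   `peaks` by `peak_id`/`name`).
#' @param gene One-row gene-model table for the target gene.
#' @return The subset of `peaks` in a promoter category with positive
#'   overlap with the gene locus.
#' @export
target_gene_peaks <- function(peaks, annotations, gene) {
  stopifnot(nrow(gene) == 1)
  promo <- promoter_peaks(annotations)
  keep <- peaks[peaks$name %in% promo$peak_id, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  locus <- intervals(gene$chrom, gene$start, gene$end, name = gene$gene_id)
  ov <- overlap_bp(keep, locus)
  out <- keep[ov > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen TF expression against the accessibility of one target peak
#'
#' Pearson correlation of each TF's expression with the target peak's
#' accessibility over matched samples, thresholded at `|r| > r_min`,
#' `p < p_max` and ranked by decreasing `|r|`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param tf_ids TF identifiers; rows of `expr` are restricted to these.
#' @param peak_acc Named accessibility vector of the target peak.
#' @param r_min,p_max Screen thresholds, defaults 0.2 and 0.01.
#' @return `data.frame` of candidates: `tf_id`, `r`, `p`, `n`, ranked by
#'   decreasing `|r|`.
#' @export
tf_screen <- function(expr, tf_ids, peak_acc, r_min = 0.2, p_max = 0.01) {
  rows <- intersect(tf_ids, rownames(expr))
  if (!length(rows))
    stop("tf_screen: no TF rows found in the expression matrix",
         call. = FALSE)
  recs <- screen_features(expr[rows, , drop = FALSE], peak_acc,
                          method = "pearson", r_min = r_min, p_max = p_max,
                          target_name = "peak_accessibility")
  out <- data.frame(tf_id = recs$feature_a, r = recs$r, p = recs$p,
                    n = recs$n, stringsAsFactors = FALSE)
  attr(out, "n_tested") <- attr(recs, "n_tested")
  out
}

#' ChIP-seq overlap support for a candidate peak
#'
#' Total base pairs of a TF's ChIP-seq peaks overlapping the candidate peak
#' (ChIP peaks are merged first so shared bases count once).  An empty ChIP
#' set yields `overlap_bp = NA` and a warning - a "no data" outcome distinct
#' from a measured overlap of 0.
#'
#' @param candidate_peak One-row interval table.
#' @param chip_peaks Interval table of one TF's ChIP-seq peaks.
#' @param min_overlap Minimum bp for support, default 1.
#' @return List with `overlap_bp`, `supported`, `n_chip_peaks`.
#' @export
chip_support <- function(candidate_peak, chip_peaks, min_overlap = 1) {
  stopifnot(nrow(candidate_peak) == 1)
  if (is.null(chip_peaks) || nrow(chip_peaks) == 0) {
    warning("chip_support: empty ChIP peak set (no binding data)",
            call. = FALSE)
    return(list(overlap_bp = NA_integer_, supported = FALSE,
                n_chip_peaks = 0L))
  }
  merged <- merge_intervals(chip_peaks)
  ov <- sum(overlap_bp(merged, candidate_peak))
  list(overlap_bp = as.integer(ov), supported = ov >= min_overlap,
       n_chip_peaks = nrow(chip_peaks))
}

#' Direction and significance of an overexpression experiment
#'
#' Compares target-gene expression between control and overexpression
#' groups.  Both groups are checked with the Shapiro-Wilk normality test;
#' when both pass (p > 0.05, and have at least 3 values) a two-sided
#' Student t-test is used, otherwise the Wilcoxon rank-sum test.  Direction
#' is the sign of the median difference (overexpression minus control).
#'
#' @param control,overexpressed Numeric vectors, both with >= 2 values.
#' @return List with `direction` (`"+"`, `"-"` or `"0"`), `p.value`, and
#'   `test` (`"t"` or `"wilcoxon"`).
#' @export
overexpression_check <- function(control, overexpressed) {
  if (length(control) < 2 || length(overexpressed) < 2)
    stop("overexpression_check: both groups need >= 2 samples",
         call. = FALSE)
  if (stats::sd(c(control, overexpressed)) == 0)
    stop("overexpression_check: degenerate groups (no variation)",
         call. = FALSE)
  normal <- function(v) {
    length(v) >= 3 && stats::sd(v) > 0 &&
      stats::shapiro.test(v)$p.value > 0.05
  }
  use_t <- normal(control) && normal(overexpressed)
  p <- if (use_t)
    stats::t.test(overexpressed, control)$p.value
  else
    rank_sum_test(overexpressed, control)$p.value
  delta <- stats::median(overexpressed) - stats::median(control)
  list(direction = if (delta > 0) "+" else if (delta < 0) "-" else "0",
       p.value = p, test = if (use_t) "t" else "wilcoxon")
}

#' Spearman screen of a receptor family against an infiltration score
#'
#' Restricts the expression matrix to the given family (e.g. GPCRs) and
#' screens each member against a per-sample infiltration score (e.g. the
#' macrophage ssGSEA score) with Spearman correlation at the study's
#' thresholds.
#'
#' @param expr Expression matrix (genes x samples).
#' @param family_ids Gene ids of the family to screen.
#' @param scores Named numeric score vector over the same samples.
#' @param r_min,p_max Thresholds, defaults 0.2 and 0.01.
#' @return `data.frame` of passing correlation records.
#' @export
gpcr_macrophage_screen <- function(expr, family_ids, scores,
                                   r_min = 0.2, p_max = 0.01) {
  rows <- intersect(family_ids, rownames(expr))
  if (!length(rows))
    stop("gpcr_macrophage_screen: no family member found in the expression ",
         "matrix", call. = FALSE)
  screen_features(expr[rows, , drop = FALSE], scores, method = "spearman",
                  r_min = r_min, p_max = p_max,
                  target_name = "macrophage_score")
}

#' Resolve a run configuration's relative input paths
#'
#' Path-valued entries that do not exist as given are re-based against
#' `base` (typically the directory of the YAML file they came from), so
#' study directories are relocatable.
#'
#' @param config Named configuration list.
#' @param base Directory to resolve relative paths against.
#' @return The configuration with resolvable paths.
#' @export
resolve_config_paths <- function(config, base) {
  for (nm in c("genes", "peaks", "accessibility", "expression", "tf_list",
               "gpcr_list", "gmt", "chip_dir", "clinical")) {
    x <- config[[nm]]
    if (is.character(x) && length(x) == 1 && !file.exists(x) &&
        file.exists(file.path(base, x)))
      config[[nm]] <- file.path(base, x)
  }
  config
}

.as_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    base <- dirname(config)
    config <- resolve_config_paths(yaml::read_yaml(config), base)
  }
  defaults <- list(tss_region = c(-2000, 2000), r_min = 0.2, p_max = 0.01,
                   min_overlap_bp = 1, alpha = 0.25, minprop = 0.1,
                   min_followup_days = 90, out_dir = NULL, chip_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config$tss_region <- as.numeric(unlist(config$tss_region))
  config
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full TF-nomination pipeline
#'
#' Executes the procedure in order: annotate peaks against the gene models,
#' keep promoter-category peaks, select those overlapping the target gene's
#' locus, screen TF expression against each target peak's accessibility
#' (Pearson, `|r| > r_min`, `p < p_max`), and annotate each candidate with
#' ChIP-seq overlap support when binding data are available.  Per-stage
#' record counts are logged and returned.
#'
#' @param config Either a path to a YAML file or a named list with entries
#'   `genes`, `peaks`, `accessibility`, `expression`, `tf_list`,
#'   `target_gene`, optional `chip_dir` (directory of `<tf_id>.bed` files),
#'   and parameters `tss_region`, `r_min`, `p_max`, `min_overlap_bp`,
#'   optional `out_dir`.  Input entries may be paths or already-loaded
#'   objects.
#' @return A list of class `"tf_report"`: `target_gene`, `target_peaks`,
#'   `candidates` (per-peak ranked TF tables with ChIP columns), `verdict`,
#'   `stage_counts`, `params`.
#' @export
run_tf_pipeline <- function(config) {
  config <- .as_config(config)
  for (nm in c("genes", "peaks", "accessibility", "expression", "tf_list",
               "target_gene"))
    if (is.null(config[[nm]]))
      stop("run_tf_pipeline: missing config entry '", nm, "'",
           call. = FALSE)
  genes <- .load_input(config$genes, read_gene_table)
  peaks <- .load_input(config$peaks, read_bed)
  acc <- .load_input(config$accessibility, read_matrix)
  expr <- .load_input(config$expression, read_matrix)
  tf_ids <- .load_input(config$tf_list, read_id_list)

  if (!config$target_gene %in% genes$gene_id)
    stop("run_tf_pipeline: target gene '", config$target_gene,
         "' absent from the gene table", call. = FALSE)
  gene <- genes[genes$gene_id == config$target_gene, , drop = FALSE]

  ann <- annotate_peaks(peaks, genes, tss_region = config$tss_region)
  promo <- promoter_peaks(ann)
  tpeaks <- target_gene_peaks(peaks, ann, gene)
  counts <- list(peaks = nrow(peaks), promoter_peaks = nrow(promo),
                 target_gene_peaks = nrow(tpeaks))
  message(sprintf(
    "pipeline: %d peaks -> %d promoter peaks -> %d target-gene peaks",
    counts$peaks, counts$promoter_peaks, counts$target_gene_peaks))

  candidates <- list()
  if (nrow(tpeaks) > 0) {
    for (i in seq_len(nrow(tpeaks))) {
      pk <- tpeaks[i, , drop = FALSE]
      if (!pk$name %in% rownames(acc))
        stop("run_tf_pipeline: peak '", pk$name,
             "' missing from the accessibility matrix", call. = FALSE)
      cand <- suppressMessages(
        tf_screen(expr, tf_ids, acc[pk$name, ],
                  r_min = config$r_min, p_max = config$p_max))
      cand$chip_overlap_bp <- rep(NA_integer_, nrow(cand))
      cand$chip_supported <- rep(NA, nrow(cand))
      if (!is.null(config$chip_dir) && nrow(cand) > 0) {
        for (k in seq_len(nrow(cand))) {
          bed <- file.path(config$chip_dir,
                           paste0(cand$tf_id[k], ".bed"))
          if (file.exists(bed)) {
            cs <- suppressWarnings(
              chip_support(pk, read_bed(bed),
                           min_overlap = config$min_overlap_bp))
            cand$chip_overlap_bp[k] <- cs$overlap_bp
            cand$chip_supported[k] <- cs$supported
          }
        }
      }
      candidates[[pk$name]] <- cand
    }
  }
  verdict <- if (nrow(tpeaks) == 0) "no accessible promoter peak"
  else if (all(vapply(candidates, nrow, integer(1)) == 0))
    "no TF passed the screen"
  else "candidates nominated"

  report <- structure(list(
    target_gene = gene,
    target_peaks = tpeaks,
    candidates = candidates,
    verdict = verdict,
    stage_counts = counts,
    params = config[c("tss_region", "r_min", "p_max", "min_overlap_bp")]),
    class = "tf_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable), `candidates.tsv` (one row per
#' TF candidate per target peak) and `pipeline.log` (per-stage counts and
#' parameters) under `out_dir`.
#'
#' @param report A `"tf_report"` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cand_tab <- candidate_table(report)
  json <- list(
    target_gene = report$target_gene$gene_id,
    target_locus = sprintf("%s:%d-%d", report$target_gene$chrom,
                           as.integer(report$target_gene$start),
                           as.integer(report$target_gene$end)),
    verdict = report$verdict,
    stage_counts = report$stage_counts,
    params = report$params,
    target_peaks = if (nrow(report$target_peaks)) sprintf(
      "%s:%d-%d", report$target_peaks$chrom,
      as.integer(report$target_peaks$start),
      as.integer(report$target_peaks$end)) else character(0),
    candidates = cand_tab)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c(paste(c("peak_id", "tf_id", "r", "p", "n", "chip_overlap_bp",
                     "chip_supported"), collapse = "\t"))
  if (nrow(cand_tab))
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%d\t%s\t%s",
                              cand_tab$peak_id, cand_tab$tf_id,
                              fmt_num(cand_tab$r), fmt_num(cand_tab$p),
                              cand_tab$n,
                              ifelse(is.na(cand_tab$chip_overlap_bp), "NA",
                                     as.character(cand_tab$chip_overlap_bp)),
                              ifelse(is.na(cand_tab$chip_supported), "NA",
                                     as.character(cand_tab$chip_supported))))
  writeLines(lines, file.path(out_dir, "candidates.tsv"))
  writeLines(c(
    sprintf("target_gene\t%s", report$target_gene$gene_id),
    sprintf("verdict\t%s", report$verdict),
    sprintf("n_peaks\t%d", report$stage_counts$peaks),
    sprintf("n_promoter_peaks\t%d", report$stage_counts$promoter_peaks),
    sprintf("n_target_gene_peaks\t%d", report$stage_counts$target_gene_peaks),
    sprintf("tss_region\t%s", paste(report$params$tss_region, collapse = ",")),
    sprintf("r_min\t%s", fmt_num(report$params$r_min)),
    sprintf("p_max\t%s", fmt_num(report$params$p_max)),
    sprintf("min_overlap_bp\t%s", fmt_num(report$params$min_overlap_bp))),
    file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Flatten a report's per-peak candidate lists into one table
#' @param report A `"tf_report"` object.
#' @return `data.frame` with `peak_id` plus the candidate columns.
#' @export
candidate_table <- function(report) {
  if (!length(report$candidates))
    return(data.frame(peak_id = character(0), tf_id = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      chip_overlap_bp = integer(0),
                      chip_supported = logical(0)))
  out <- do.call(rbind, lapply(names(report$candidates), function(pk) {
    x <- report$candidates[[pk]]
    if (nrow(x) == 0) return(NULL)
    cbind(data.frame(peak_id = pk, stringsAsFactors = FALSE), x)
  }))
  if (is.null(out))
    return(candidate_table(structure(list(candidates = list()),
                                     class = "tf_report")))
  rownames(out) <- NULL
  out
}

#' @export
print.tf_report <- function(x, ...) {
  cat(sprintf("TF nomination report for %s (%s)\n",
              x$target_gene$gene_id, x$verdict))
  cat(sprintf("  peaks: %d total, %d promoter, %d on the target locus\n",
              x$stage_counts$peaks, x$stage_counts$promoter_peaks,
              x$stage_counts$target_gene_peaks))
  tab <- candidate_table(x)
  if (nrow(tab)) {
    cat("  top candidates:\n")
    print(utils::head(tab, 5), ...)
  }
  invisible(x)
}
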