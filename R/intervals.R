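# Genomic-interval arithmetic and nearest-TSS promoter annotation.
#
# All coordinates are 1-based inclusive internally; BED files are converted
# at the I/O boundary (read_bed/write_bed) and nowhere else.

PROMOTER_1KB <- "Promoter (<=1kb)"
PROMOTER_2KB <- "Promoter (1-2kb)"
CATEGORY_OTHER <- "Other"

#' Build a validated genomic-interval table
#'
#' Intervals are 1-based inclusive spans on a named chromosome, optionally
#' stranded.  This is the coordinate currency of the whole package: peaks,
#' gene loci and ChIP-seq binding regions are all interval tables.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param name Optional interval names; autogenerated when missing.
#' @return A `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' intervals("chr16", 19884686, 19885185, name = "target_peak")
#' @export
intervals <- function(chrom, start, end, strand = NULL, name = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- as.character(rep_len(chrom, n))
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (anyNA(chrom) || anyNA(start) || anyNA(end))
    stop("intervals: chrom/start/end must not contain NA", call. = FALSE)
  if (any(start != round(start)) || any(end != round(end)))
    stop("intervals: start/end must be whole numbers", call. = FALSE)
  if (any(start < 1))
    stop("intervals: start must be >= 1 (coordinates are 1-based)",
         call. = FALSE)
  bad <- which(start > end)
  if (length(bad))
    stop(sprintf("intervals: start > end for %d interval(s), first at row %d",
                 length(bad), bad[1]), call. = FALSE)
  strand <- if (is.null(strand)) rep_len("*", n) else
    as.character(rep_len(strand, n))
  if (!all(strand %in% c("+", "-", "*")))
    stop("intervals: strand must be one of '+', '-', '*'", call. = FALSE)
  name <- if (is.null(name)) sprintf("iv_%d", seq_len(n)) else
    as.character(rep_len(name, n))
  data.frame(name = name, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Overlap length of two interval tables, in base pairs
#'
#' Rows are paired (shorter table recycled).  The overlap of two 1-based
#' inclusive spans on the same chromosome is
#' `max(0, min(end) - max(start) + 1)`; intervals on different chromosomes
#' never overlap.  Symmetric in its arguments.
#'
#' @param a,b Interval tables as returned by [intervals()].
#' @return Integer vector of overlap lengths (0 when disjoint).
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]) + 1
  ov <- pmax(0, ov)
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  as.integer(ov)
}

#' Build a validated gene-model table
#'
#' A gene model is a stranded locus plus its transcription start site (TSS):
#' `locus start` on the plus strand, `locus end` on the minus strand.
#' Unstranded genes (`"*"` or `"."`) are treated as plus strand with a
#' warning.
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end Locus coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"` (unstranded coerced to `"+"`).
#' @param symbol Optional display symbols (defaults to `gene_id`).
#' @return A `data.frame` with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand`, `tss`.
#' @examples
#' gene_models("GPRC5B", "chr16", 19856691, 19886167, "-")
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        symbol = gene_id) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("gene_models: duplicate gene_id", call. = FALSE)
  iv <- intervals(chrom, start, end, strand = "+", name = gene_id)
  strand <- as.character(rep_len(strand, nrow(iv)))
  unstranded <- strand %in% c("*", ".")
  if (any(unstranded)) {
    warning(sprintf("gene_models: %d unstranded gene(s) treated as '+'",
                    sum(unstranded)), call. = FALSE)
    strand[unstranded] <- "+"
  }
  if (!all(strand %in% c("+", "-")))
    stop("gene_models: strand must be '+' or '-'", call. = FALSE)
  data.frame(gene_id = gene_id,
             symbol = as.character(rep_len(symbol, nrow(iv))),
             chrom = iv$chrom, start = iv$start, end = iv$end,
             strand = strand,
             tss = ifelse(strand == "+", iv$start, iv$end),
             stringsAsFactors = FALSE)
}

# Signed distance from a set of gene TSSs to one peak.  Positive when the
# peak lies downstream of the TSS in the gene's transcription direction,
# negative upstream, 0 when the peak covers the TSS (edge mode).  NA for
# genes on another chromosome.
.dist_one_peak <- function(pstart, pend, pchrom, genes,
                           mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  tss <- genes$tss
  if (mode == "midpoint") {
    pos <- floor((pstart + pend) / 2)
    d <- ifelse(genes$strand == "+", pos - tss, tss - pos)
  } else {
    gap <- ifelse(tss < pstart, pstart - tss,
                  ifelse(tss > pend, tss - pend, 0))
    # sign: is the peak on the downstream side of the TSS?
    downstream <- ifelse(genes$strand == "+", tss < pstart, tss > pend)
    d <- ifelse(gap == 0, 0, ifelse(downstream, gap, -gap))
  }
  d[genes$chrom != pchrom] <- NA_real_
  d
}

#' Signed peak-to-TSS distance
#'
#' Distance from a gene's TSS to the nearest peak edge (0 when the TSS lies
#' inside the peak), signed positive when the peak is downstream of the TSS
#' in the gene's transcription direction and negative when upstream.
#' `mode = "midpoint"` measures from the peak midpoint instead.
#'
#' @param peaks Interval table of peaks.
#' @param genes Gene-model table ([gene_models()]); rows paired with peaks
#'   (length-1 recycled).
#' @param mode `"edge"` (default) or `"midpoint"`.
#' @return Numeric vector of signed distances in bp; `NA` when peak and gene
#'   are on different chromosomes.
#' @export
distance_to_tss <- function(peaks, genes, mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  n <- max(nrow(peaks), nrow(genes))
  pi <- rep_len(seq_len(nrow(peaks)), n)
  gi <- rep_len(seq_len(nrow(genes)), n)
  vapply(seq_len(n), function(k) {
    .dist_one_peak(peaks$start[pi[k]], peaks$end[pi[k]], peaks$chrom[pi[k]],
                   genes[gi[k], , drop = FALSE], mode = mode)
  }, numeric(1))
}

.promoter_category <- function(d, tss_region) {
  ifelse(is.na(d) | d < tss_region[1] | d > tss_region[2], CATEGORY_OTHER,
         ifelse(abs(d) <= 1000, PROMOTER_1KB,
                ifelse(abs(d) <= 2000, PROMOTER_2KB, CATEGORY_OTHER)))
}

#' Annotate peaks with their nearest-TSS gene and promoter category
#'
#' Each peak is assigned the gene whose TSS minimizes the absolute signed
#' distance (ties broken toward the lexicographically smaller `gene_id`).
#' Peaks whose signed distance falls inside `tss_region` are labelled
#' `"Promoter (<=1kb)"` (|d| <= 1000) or `"Promoter (1-2kb)"`
#' (1000 < |d| <= 2000); everything else is `"Other"`.
#'
#' @param peaks Interval table of peaks.
#' @param genes Gene-model table; must be non-empty.
#' @param tss_region Signed promoter window around the TSS, default
#'   `c(-2000, 2000)`.
#' @param mode Distance mode passed to [distance_to_tss()].
#' @return A `data.frame` with one row per peak: `peak_id`, `gene_id`,
#'   `distance_to_tss`, `category`.
#' @export
annotate_peaks <- function(peaks, genes, tss_region = c(-2000, 2000),
                           mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  if (is.null(genes) || nrow(genes) == 0)
    stop("annotate_peaks: empty gene table", call. = FALSE)
  if (length(tss_region) != 2 || tss_region[1] > tss_region[2])
    stop("annotate_peaks: tss_region must be an ordered pair", call. = FALSE)
  ord <- order(genes$gene_id)          # lexicographic tie-break
  genes <- genes[ord, , drop = FALSE]
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- .dist_one_peak(peaks$start[i], peaks$end[i], peaks$chrom[i],
                        genes, mode = mode)
    if (all(is.na(d)))
      return(list(gene_id = NA_character_, d = NA_real_))
    j <- which.min(abs(d))             # first minimum = smallest gene_id
    list(gene_id = genes$gene_id[j], d = d[j])
  })
  d <- vapply(out, `[[`, numeric(1), "d")
  data.frame(peak_id = peaks$name,
             gene_id = vapply(out, `[[`, character(1), "gene_id"),
             distance_to_tss = d,
             category = .promoter_category(d, tss_region),
             stringsAsFactors = FALSE)
}

#' Keep only promoter-category peak annotations
#'
#' Order-preserving filter dropping `"Other"` rows.
#'
#' @param annotations Output of [annotate_peaks()].
#' @return The subset of rows with a promoter category.
#' @export
promoter_peaks <- function(annotations) {
  out <- annotations[annotations$category != CATEGORY_OTHER, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge overlapping intervals (single chromosome set assumed mixed; merged
# per chromosome).  Used before summing ChIP overlap so shared bases are not
# counted twice.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  pieces <- lapply(split(seq_len(nrow(iv)), iv$chrom), function(idx) {
    x <- iv[idx, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    ms <- x$start[1]; me <- x$end[1]
    starts <- ends <- numeric(0)
    for (k in seq_len(nrow(x))[-1]) {
      if (x$start[k] <= me + 1) {
        me <- max(me, x$end[k])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- x$start[k]; me <- x$end[k]
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    intervals(x$chrom[1], starts, ends)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$name <- sprintf("merged_%d", seq_len(nrow(out)))
  out
}
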