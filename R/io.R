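# Readers/writers for the plain-text formats the pipeline consumes: BED
# (0-based half-open on disk), TSV matrices, GMT gene sets, gene tables,
# TF lists and clinical tables.  TSV everywhere, UTF-8, no quoting.
# Reals are printed with "%.10g": fixed-precision g-format is idempotent
# under a parse/print cycle, so write -> read -> write is byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[x == round(x) & abs(x) < 1e15] <-
    sprintf("%d", as.integer(x[x == round(x) & abs(x) < 1e15]))
  out
}

#' Read a BED3/BED6 file as a 1-based interval table
#'
#' BED is 0-based half-open on disk; records are converted to the package's
#' 1-based inclusive coordinates here (and nowhere else).  `track`,
#' `browser` and `#` comment lines are tolerated.
#'
#' @param path Path to a BED file.
#' @return Interval table (see [intervals()]); column 4 becomes `name`,
#'   column 5 `score`, column 6 `strand` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(intervals(character(0), integer(0), integer(0))[0, ])
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("read_bed: line %d has fewer than 3 fields",
                 lineno[which(nf < 3)[1]]), call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("read_bed: non-numeric coordinates at line %d",
                 lineno[bad[1]]), call. = FALSE)
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop(sprintf("read_bed: invalid interval (start >= end) at line %d",
                 lineno[bad[1]]), call. = FALSE)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 character(1)),
                 sprintf("peak_%d", seq_along(fields)))
  strand <- rep("*", length(fields))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6)
  strand[!strand %in% c("+", "-")] <- "*"
  out <- intervals(chrom, start0 + 1, end0, strand = strand, name = name)
  if (any(nf >= 5)) {
    score <- rep(NA_real_, length(fields))
    score[nf >= 5] <- suppressWarnings(
      as.numeric(vapply(fields[nf >= 5], `[[`, character(1), 5)))
    out$score <- score
  }
  out
}

#' Write an interval table as BED
#'
#' Converts back to 0-based half-open coordinates.
#' @param iv Interval table.
#' @param path Output path.
#' @export
write_bed <- function(iv, path) {
  lines <- if (nrow(iv) == 0) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", iv$chrom, as.integer(iv$start - 1),
            as.integer(iv$end),
            iv$name,
            if (!is.null(iv$score)) fmt_num(ifelse(is.na(iv$score), 0, iv$score))
            else "0",
            iv$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a numeric TSV matrix (rows x samples)
#'
#' First column holds row ids, header row holds sample ids.  Duplicate row
#' ids, ragged rows and missing/non-numeric cells are rejected with their
#' coordinates.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop("read_matrix: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("read_matrix: empty file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  ncol <- length(samples)
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != ncol + 1))
    stop(sprintf("read_matrix: ragged row at line %d (%d fields, expected %d)",
                 which(nf != ncol + 1)[1] + 1, nf[nf != ncol + 1][1],
                 ncol + 1), call. = FALSE)
  ids <- vapply(body, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("read_matrix: duplicate row id '", dup[1], "'", call. = FALSE)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(ncol)))
  m <- if (ncol == 1) matrix(vals, ncol = 1) else t(vals)
  if (length(body) == 0) m <- matrix(numeric(0), 0, ncol)
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("read_matrix: missing/non-numeric value at row '%s', sample '%s'",
                 ids[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
  dimnames(m) <- list(ids, samples)
  m
}

#' Write a numeric matrix as TSV
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_header Header of the row-id column.
#' @export
write_matrix <- function(m, path, id_header = "id") {
  header <- paste(c(id_header, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("read_gmt: line %d has no members", i), call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("read_gmt: line %d has no members", i), call. = FALSE)
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model table from TSV
#'
#' Columns `gene_id`, `chrom`, `start`, `end`, `strand` (1-based inclusive);
#' strand `"."` is treated as `"+"` with a warning.
#'
#' @param path Path to a TSV file with a header row.
#' @return Gene-model table (see [gene_models()]).
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_gene_table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand,
              symbol = if ("symbol" %in% names(df)) df$symbol else df$gene_id)
}

#' Write a gene-model table as TSV
#' @param genes Gene-model table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  header <- "gene_id\tchrom\tstart\tend\tstrand\tsymbol"
  rows <- sprintf("%s\t%s\t%d\t%d\t%s\t%s", genes$gene_id, genes$chrom,
                  as.integer(genes$start), as.integer(genes$end),
                  genes$strand, genes$symbol)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Required columns `sample_id`, `time_days` (non-negative), `event`
#' (0 = censored, 1 = event); any further numeric columns are kept as
#' covariates.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `sample_id`, `time`, `event` and
#'   covariates.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("sample_id", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_clinical: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$time_days < 0))
    stop("read_clinical: negative follow-up time", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("read_clinical: event must be 0 or 1", call. = FALSE)
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time_days),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), need)
  for (cn in extra) out[[cn]] <- df[[cn]]
  out
}

#' Write a clinical survival table as TSV
#' @param clin Clinical table as from [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clin, path) {
  extra <- setdiff(names(clin), c("sample_id", "time", "event"))
  header <- paste(c("sample_id", "time_days", "event", extra),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(clin)), function(i) {
    vals <- vapply(extra, function(cn) {
      v <- clin[[cn]][i]
      if (is.numeric(v)) fmt_num(v) else as.character(v)
    }, character(1))
    paste(c(clin$sample_id[i], fmt_num(clin$time[i]),
            sprintf("%d", clin$event[i]), vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a one-id-per-line list (e.g. a TF or GPCR list)
#' @param path Path to a text file.
#' @return Character vector of ids (blank lines and `#` comments dropped).
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
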