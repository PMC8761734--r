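# Synthetic multi-omics study generator with planted ground truth: paired
# accessibility/expression matrices over the same samples carrying a
# planted TF -> promoter-peak -> target-gene regulatory chain, fabricated
# immune-marker signatures with a latent macrophage-infiltration score, a
# planted macrophage-correlated GPCR subset, and Cox-generated survival
# times.  Every file the pipeline consumes can be produced here, so the
# full analysis runs with no downloads.

.stage_seed <- function(config, k) (config$seed * 131L + k) %% 2147483647L

#' Simulation configuration with planted ground truth
#'
#' Defaults mirror the study conditions the pipeline is meant for: 41
#' tumor samples with paired accessibility and expression (plus 20 normal
#' expression-only samples), 50 TFs, a planted TF whose expression
#' correlates with the planted target-promoter peak at Pearson r = 0.6,
#' 28 disjoint 10-marker immune signatures, and proportional-hazards
#' survival times with a log-hazard ratio of 0.7 on the macrophage score.
#'
#' @param seed Integer master seed; every stage derives its own stream
#'   from it.
#' @param n_samples Paired tumor samples (accessibility + expression).
#' @param n_normal Normal expression-only samples.
#' @param n_genes Total gene models (must accommodate TFs, markers, GPCRs
#'   and the target).
#' @param n_tfs Number of TFs (first one is the planted driver).
#' @param n_peaks Total accessibility peaks (one is the planted promoter
#'   peak of the target gene).
#' @param planted_tf_effect Population Pearson correlation between planted
#'   TF expression and planted-peak accessibility, in (0, 1).
#' @param target_coupling Population correlation between planted-peak
#'   accessibility and target-gene expression.
#' @param n_immune_sets,markers_per_set Immune signature structure
#'   (disjoint marker sets).
#' @param n_gpcrs,n_planted_gpcrs GPCR family size and how many co-vary
#'   with the latent macrophage score.
#' @param gpcr_effect Correlation of planted GPCRs with the latent score.
#' @param noise_sd Log-scale expression noise.
#' @param marker_noise_sd Log-scale noise of immune-marker genes around
#'   their set's latent level.
#' @param infiltration_sd Between-sample spread of each signature's latent
#'   level.
#' @param survival_betas Named log-hazard ratios applied to score columns.
#' @param censoring_rate Expected fraction censored, in [0, 1).
#' @param short_followup_frac Fraction of subjects given follow-up <= 90
#'   days, to exercise the follow-up filter.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param chrom_length,n_chroms Synthetic genome geometry.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 41L, n_normal = 20L,
                       n_genes = 600L, n_tfs = 50L, n_peaks = 200L,
                       planted_tf_effect = 0.6, target_coupling = 0.6,
                       n_immune_sets = 28L, markers_per_set = 10L,
                       n_gpcrs = 40L, n_planted_gpcrs = 8L,
                       gpcr_effect = 0.7,
                       noise_sd = 0.5, marker_noise_sd = 0.3,
                       infiltration_sd = 0.5,
                       survival_betas = c(macrophage_score = 0.7),
                       censoring_rate = 0.3, short_followup_frac = 0.1,
                       baseline_hazard = log(2) / 730,
                       chrom_length = 5e7, n_chroms = 4L) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_normal = as.integer(n_normal), n_genes = as.integer(n_genes),
              n_tfs = as.integer(n_tfs), n_peaks = as.integer(n_peaks),
              planted_tf_effect = planted_tf_effect,
              target_coupling = target_coupling,
              n_immune_sets = as.integer(n_immune_sets),
              markers_per_set = as.integer(markers_per_set),
              n_gpcrs = as.integer(n_gpcrs),
              n_planted_gpcrs = as.integer(n_planted_gpcrs),
              gpcr_effect = gpcr_effect, noise_sd = noise_sd,
              marker_noise_sd = marker_noise_sd,
              infiltration_sd = infiltration_sd,
              survival_betas = survival_betas,
              censoring_rate = censoring_rate,
              short_followup_frac = short_followup_frac,
              baseline_hazard = baseline_hazard,
              chrom_length = chrom_length, n_chroms = as.integer(n_chroms))
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$n_tfs, cfg$n_peaks,
              cfg$n_immune_sets, cfg$markers_per_set, cfg$n_gpcrs)
  if (any(counts <= 0)) stop("sim_config: counts must be positive",
                             call. = FALSE)
  if (cfg$planted_tf_effect <= 0 || cfg$planted_tf_effect >= 1)
    stop("sim_config: planted_tf_effect must lie in (0, 1)", call. = FALSE)
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("sim_config: censoring_rate must lie in [0, 1)", call. = FALSE)
  need <- cfg$n_tfs + 1L + cfg$n_gpcrs +
    cfg$n_immune_sets * cfg$markers_per_set
  if (need > cfg$n_genes)
    stop(sprintf("sim_config: n_genes = %d cannot host %d role genes",
                 cfg$n_genes, need), call. = FALSE)
  if (cfg$n_planted_gpcrs > cfg$n_gpcrs)
    stop("sim_config: more planted GPCRs than GPCRs", call. = FALSE)
  structure(cfg, class = "sim_config")
}

.role_ids <- function(config) {
  list(tfs = sprintf("TF%03d", seq_len(config$n_tfs)),
       target = "TARGET1",
       gpcrs = sprintf("GPCR%03d", seq_len(config$n_gpcrs)),
       markers = sprintf("IMM%04d",
                         seq_len(config$n_immune_sets * config$markers_per_set)),
       planted_tf = "TF001")
}

#' Simulate non-overlapping gene models on a synthetic genome
#'
#' Genes (TFs, the target, GPCRs, immune markers and background genes) are
#' packed left to right on `n_chroms` synthetic chromosomes with random
#' lengths (2-20 kb) and intergenic gaps (5-20 kb); strands are assigned
#' at random.  Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return Gene-model table; the designated target gene has
#'   `gene_id = "TARGET1"`.
#' @export
simulate_gene_models <- function(config) {
  set.seed(.stage_seed(config, 1L))
  roles <- .role_ids(config)
  n_bg <- config$n_genes - config$n_tfs - 1L - config$n_gpcrs -
    length(roles$markers)
  ids <- c(roles$tfs, roles$target, roles$gpcrs, roles$markers,
           if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)))
  ids <- sample(ids)                      # scatter roles along the genome
  chrom_of <- sort(rep_len(seq_len(config$n_chroms), config$n_genes))
  lens <- round(stats::runif(config$n_genes, 2000, 20000))
  gaps <- round(stats::runif(config$n_genes, 5000, 20000))
  start <- end <- numeric(config$n_genes)
  pos <- rep(0, config$n_chroms)
  for (i in seq_len(config$n_genes)) {
    cc <- chrom_of[i]
    start[i] <- pos[cc] + gaps[i]
    end[i] <- start[i] + lens[i] - 1
    pos[cc] <- end[i]
    if (end[i] > config$chrom_length)
      stop("simulate_gene_models: infeasible packing (too many genes for ",
           "the chromosome length)", call. = FALSE)
  }
  gene_models(ids, sprintf("chrS%d", chrom_of), start, end,
              sample(c("+", "-"), config$n_genes, replace = TRUE))
}

# Solve for the noise SD that makes cor(x, x + e) equal rho, given sd(x).
.noise_for_cor <- function(sd_x, rho) sd_x * sqrt(1 / rho^2 - 1)

#' Simulate the planted regulatory chain
#'
#' Builds the peak set (one planted promoter peak covering the target
#' gene's TSS, promoter-proximal and distal decoys), the peak-accessibility
#' matrix over tumor samples, the gene-expression matrix over tumor and
#' normal samples, the TF list, and per-TF ChIP-seq peak sets.  The planted
#' TF's expression and the planted peak's accessibility have population
#' Pearson correlation `planted_tf_effect` (the noise variance is solved
#' analytically from the log-normal expression SD); target-gene expression
#' is positively coupled to the planted peak; decoys are independent noise.
#' The planted TF's ChIP set contains a jittered interval overlapping the
#' planted peak; all other ChIP intervals avoid it.
#'
#' @param config A [sim_config()].
#' @param genes Gene models from [simulate_gene_models()].
#' @return List with `peaks` (interval table), `accessibility`
#'   (peaks x tumor samples), `expression` (genes x all samples),
#'   `tf_list`, `chip` (named list of interval tables, one per TF),
#'   `planted_peak`, `planted_tf`, `samples`, `normal_samples`, `mu_g`.
#' @export
simulate_regulatory_chain <- function(config, genes) {
  set.seed(.stage_seed(config, 2L))
  roles <- .role_ids(config)
  tumor <- sprintf("S%03d", seq_len(config$n_samples))
  normal <- sprintf("N%03d", seq_len(config$n_normal))
  all_s <- c(tumor, normal)

  mu_g <- stats::rnorm(config$n_genes, 1, 0.5)
  names(mu_g) <- genes$gene_id
  expr <- exp(mu_g + config$noise_sd *
                matrix(stats::rnorm(config$n_genes * length(all_s)),
                       config$n_genes, length(all_s)))
  dimnames(expr) <- list(genes$gene_id, all_s)

  target <- genes[genes$gene_id == roles$target, , drop = FALSE]
  # planted promoter peak: covers the target TSS, overlaps the locus
  p_start <- pmax(1, target$tss - 200)
  p_end <- target$tss + 300
  n_pro <- round(0.6 * (config$n_peaks - 1))
  n_dist <- config$n_peaks - 1 - n_pro
  anchors <- genes[genes$gene_id != roles$target, , drop = FALSE]
  ai <- sample(nrow(anchors), n_pro + n_dist, replace = TRUE)
  off <- c(round(stats::runif(n_pro, -1800, 1800)),
           round(stats::runif(n_dist, 3000, 50000)) *
             sample(c(-1, 1), n_dist, replace = TRUE))
  width <- round(stats::runif(n_pro + n_dist, 300, 800))
  sgn <- ifelse(anchors$strand[ai] == "+", 1, -1)
  center <- anchors$tss[ai] + sgn * off
  ds <- pmax(1, center - floor(width / 2))
  de <- ds + width
  chroms <- c(target$chrom, anchors$chrom[ai])
  starts <- c(p_start, ds)
  ends <- c(p_end, de)
  ord <- sample(config$n_peaks)            # planted peak not always first
  peak_names <- sprintf("peak_%04d", seq_len(config$n_peaks))
  peaks <- intervals(chroms[ord], starts[ord], ends[ord], name = peak_names)
  planted_peak <- peak_names[which(ord == 1)]

  acc <- exp(1 + 0.6 * matrix(stats::rnorm(config$n_peaks * length(tumor)),
                              config$n_peaks, length(tumor)))
  dimnames(acc) <- list(peak_names, tumor)
  tf1 <- roles$planted_tf
  x <- expr[tf1, tumor]
  s <- config$noise_sd
  sd_x <- sqrt(exp(s^2) - 1) * exp(mu_g[tf1] + s^2 / 2)  # log-normal SD
  acc_planted <- x + stats::rnorm(length(tumor), 0,
                                  .noise_for_cor(sd_x, config$planted_tf_effect))
  acc[planted_peak, ] <- acc_planted + 5    # keep on a positive count scale
  sd_acc <- sd_x / config$planted_tf_effect
  expr[roles$target, tumor] <-
    acc[planted_peak, ] +
    stats::rnorm(length(tumor), 0,
                 .noise_for_cor(sd_acc, config$target_coupling))

  # ChIP peak sets: overlapping interval (jittered) for the planted TF,
  # rejection-sampled non-overlapping intervals everywhere else
  planted_iv <- peaks[peaks$name == planted_peak, , drop = FALSE]
  rand_chip <- function(k) {
    out <- NULL
    while (is.null(out) || nrow(out) < k) {
      st <- round(stats::runif(k, 1, config$chrom_length - 2000))
      iv <- intervals(sprintf("chrS%d",
                              sample(config$n_chroms, k, replace = TRUE)),
                      st, st + round(stats::runif(k, 200, 1500)))
      iv <- iv[overlap_bp(iv, planted_iv) == 0, , drop = FALSE]
      out <- rbind(out, iv)
    }
    out[seq_len(k), , drop = FALSE]
  }
  chip <- lapply(roles$tfs, function(tf) {
    iv <- rand_chip(4L)
    if (tf == tf1) {
      jit <- round(stats::runif(1, -100, 100))
      iv <- rbind(intervals(planted_iv$chrom,
                            pmax(1, planted_iv$start + jit - 200),
                            planted_iv$end + jit + 200), iv)
    }
    iv$name <- sprintf("%s_chip_%d", tf, seq_len(nrow(iv)))
    rownames(iv) <- NULL
    iv
  })
  names(chip) <- roles$tfs

  list(peaks = peaks, accessibility = acc, expression = expr,
       tf_list = roles$tfs, chip = chip, planted_peak = planted_peak,
       planted_tf = tf1, samples = tumor, normal_samples = normal,
       mu_g = mu_g)
}

#' Plant immune-signature structure and tumor/normal groups
#'
#' Fabricates `n_immune_sets` disjoint marker signatures; each set's marker
#' genes are shifted (on the log scale) by a per-sample latent level.  The
#' macrophage signature's latent level is higher in normal samples and
#' defines the latent infiltration score; a planted GPCR subset is made to
#' co-vary with that score while the remaining GPCRs stay independent
#' noise.
#'
#' @param config A [sim_config()].
#' @param chain Output of [simulate_regulatory_chain()].
#' @return List with updated `expression`, `sets` (named list, first set
#'   `"Macrophage"`), `groups` (`sample_id`, `group`), `latent` (named
#'   macrophage score), `gpcr_list`, `planted_gpcrs`.
#' @export
simulate_immune_and_groups <- function(config, chain) {
  set.seed(.stage_seed(config, 3L))
  roles <- .role_ids(config)
  expr <- chain$expression
  all_s <- colnames(expr)
  is_normal <- all_s %in% chain$normal_samples

  marker_split <- split(roles$markers,
                        rep(seq_len(config$n_immune_sets),
                            each = config$markers_per_set))
  set_names <- c("Macrophage",
                 sprintf("ImmuneSet%02d", seq_len(config$n_immune_sets)[-1]))
  sets <- stats::setNames(marker_split, set_names)
  if (anyDuplicated(unlist(sets)))
    stop("simulate_immune_and_groups: marker sets are not disjoint",
         call. = FALSE)

  delta <- c(1, stats::runif(config$n_immune_sets - 1, -0.5, 0.5))
  latent <- matrix(NA_real_, config$n_immune_sets, length(all_s),
                   dimnames = list(set_names, all_s))
  for (k in seq_len(config$n_immune_sets)) {
    latent[k, ] <- delta[k] * is_normal +
      stats::rnorm(length(all_s), 0, config$infiltration_sd)
    g <- sets[[k]]
    expr[g, ] <- exp(chain$mu_g[g] +
                       matrix(latent[k, ], length(g), length(all_s),
                              byrow = TRUE) +
                       config$marker_noise_sd *
                         matrix(stats::rnorm(length(g) * length(all_s)),
                                length(g), length(all_s)))
  }
  s_j <- latent["Macrophage", ]

  planted_gpcrs <- roles$gpcrs[seq_len(config$n_planted_gpcrs)]
  tau <- .noise_for_cor(stats::sd(s_j), config$gpcr_effect)
  for (g in planted_gpcrs)
    expr[g, ] <- exp(chain$mu_g[g] + s_j +
                       stats::rnorm(length(all_s), 0, tau))

  list(expression = expr, sets = sets,
       groups = data.frame(sample_id = all_s,
                           group = ifelse(is_normal, "normal", "tumor"),
                           stringsAsFactors = FALSE),
       latent = s_j, gpcr_list = roles$gpcrs,
       planted_gpcrs = planted_gpcrs)
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(beta * score))`; independent exponential
#' censoring is calibrated (by root finding) so the expected censoring
#' fraction equals `censoring_rate`, and a configured fraction of subjects
#' is given a follow-up of at most 90 days to exercise the follow-up
#' filter.
#'
#' @param config A [sim_config()].
#' @param scores `data.frame` with `sample_id` and one numeric column per
#'   named element of `config$survival_betas`.
#' @return Clinical table (`sample_id`, `time`, `event`, score columns).
#' @export
simulate_survival <- function(config, scores) {
  set.seed(.stage_seed(config, 4L))
  betas <- config$survival_betas
  miss <- setdiff(names(betas), names(scores))
  if (length(miss))
    stop("simulate_survival: score column(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(scores)
  x <- as.matrix(scores[, names(betas), drop = FALSE])
  lp <- drop(scale(x, scale = FALSE) %*% betas)
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  if (config$censoring_rate > 0) {
    cfrac <- function(logk) mean(exp(logk) / (rate + exp(logk))) -
      config$censoring_rate
    logk <- stats::uniroot(cfrac, c(-40, 10))$root
    t_cens <- stats::rexp(n, exp(logk))
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  n_short <- floor(config$short_followup_frac * n)
  if (n_short > 0) {
    idx <- sample(n, n_short)
    time[idx] <- stats::runif(n_short, 0, 90)
    event[idx] <- stats::rbinom(n_short, 1, 0.5)
  }
  out <- data.frame(sample_id = scores$sample_id, time = round(time, 1),
                    event = event, stringsAsFactors = FALSE)
  for (cn in names(betas)) out[[cn]] <- scores[[cn]]
  out
}

#' Generate and write a complete synthetic study
#'
#' Runs every generator stage and writes all pipeline inputs under
#' `out_dir`: `genes.tsv`, `peaks.bed`, `accessibility.tsv`,
#' `expression.tsv`, `tf_list.txt`, `gpcr_list.txt`, `immune_sets.gmt`,
#' `chip/<tf>.bed`, `groups.tsv`, `clinical.tsv`, a ready-to-run
#' `config.yaml`, and a `truth.json` sidecar naming the planted TF, peak,
#' GPCRs and survival effects.  Identical configs yield byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects, the `truth` list
#'   and the file `paths`.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- simulate_gene_models(config)
  chain <- simulate_regulatory_chain(config, genes)
  imm <- simulate_immune_and_groups(config, chain)

  tumor <- chain$samples
  scores <- data.frame(sample_id = tumor,
                       macrophage_score = imm$latent[tumor],
                       target_expr = imm$expression["TARGET1", tumor],
                       stringsAsFactors = FALSE)
  clinical <- simulate_survival(config, scores)

  paths <- list(
    genes = file.path(out_dir, "genes.tsv"),
    peaks = file.path(out_dir, "peaks.bed"),
    accessibility = file.path(out_dir, "accessibility.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    tf_list = file.path(out_dir, "tf_list.txt"),
    gpcr_list = file.path(out_dir, "gpcr_list.txt"),
    gmt = file.path(out_dir, "immune_sets.gmt"),
    chip_dir = file.path(out_dir, "chip"),
    groups = file.path(out_dir, "groups.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    config = file.path(out_dir, "config.yaml"),
    truth = file.path(out_dir, "truth.json"))

  write_gene_table(genes, paths$genes)
  write_bed(chain$peaks, paths$peaks)
  write_matrix(chain$accessibility, paths$accessibility, id_header = "peak_id")
  write_matrix(imm$expression, paths$expression, id_header = "gene_id")
  writeLines(chain$tf_list, paths$tf_list)
  writeLines(imm$gpcr_list, paths$gpcr_list)
  write_gmt(imm$sets, paths$gmt)
  dir.create(paths$chip_dir, showWarnings = FALSE)
  for (tf in names(chain$chip))
    write_bed(chain$chip[[tf]], file.path(paths$chip_dir,
                                          paste0(tf, ".bed")))
  writeLines(c("sample_id\tgroup",
               sprintf("%s\t%s", imm$groups$sample_id, imm$groups$group)),
             paths$groups)
  write_clinical(clinical, paths$clinical)

  # paths in config.yaml are relative to the config file, so a study
  # directory is relocatable and byte-identical across output locations
  run_cfg <- list(genes = "genes.tsv", peaks = "peaks.bed",
                  accessibility = "accessibility.tsv",
                  expression = "expression.tsv", tf_list = "tf_list.txt",
                  gpcr_list = "gpcr_list.txt", gmt = "immune_sets.gmt",
                  chip_dir = "chip", clinical = "clinical.tsv",
                  target_gene = "TARGET1",
                  tss_region = c(-2000, 2000), alpha = 0.25,
                  r_min = 0.2, p_max = 0.01, minprop = 0.1,
                  min_overlap_bp = 1, min_followup_days = 90,
                  seed = config$seed)
  yaml::write_yaml(run_cfg, paths$config)

  truth <- list(planted_tf = chain$planted_tf,
                planted_peak = chain$planted_peak,
                target_gene = "TARGET1",
                planted_gpcrs = imm$planted_gpcrs,
                planted_tf_effect = config$planted_tf_effect,
                survival_betas = as.list(config$survival_betas),
                seed = config$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(genes = genes, chain = chain, immune = imm,
                 clinical = clinical, truth = truth, paths = paths))
}
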