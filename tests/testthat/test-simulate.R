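# Synthetic-study generator: determinism, planted structure, round trips.

test_that("config validation catches impossible settings", {
  expect_error(sim_config(n_genes = 100), "cannot host")
  expect_error(sim_config(planted_tf_effect = 1.2), "planted_tf_effect")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(n_peaks = 0), "positive")
  cfg <- sim_config(seed = 1, n_genes = 20000, chrom_length = 1e6)
  expect_error(simulate_gene_models(cfg), "infeasible packing")
})

test_that("gene models are valid, disjoint per chromosome, mixed-strand", {
  cfg <- sim_config(seed = 61)
  genes <- simulate_gene_models(cfg)
  expect_identical(genes, simulate_gene_models(cfg))   # seed-deterministic
  expect_true(all(genes$start <= genes$end))
  expect_true(all(genes$tss >= genes$start & genes$tss <= genes$end))
  for (cc in split(genes, genes$chrom)) {
    cc <- cc[order(cc$start), ]
    expect_true(all(cc$start[-1] > cc$end[-nrow(cc)]))
  }
  frac_minus <- mean(genes$strand == "-")
  expect_gt(frac_minus, 0.4); expect_lt(frac_minus, 0.6)
  expect_true("TARGET1" %in% genes$gene_id)
})

test_that("planted TF-peak correlation hits its target at large n", {
  cfg <- sim_config(seed = 62, n_samples = 10000, n_genes = 400,
                    n_immune_sets = 28, markers_per_set = 10,
                    n_tfs = 10, n_gpcrs = 10, n_peaks = 20)
  genes <- simulate_gene_models(cfg)
  chain <- simulate_regulatory_chain(cfg, genes)
  r <- cor(chain$expression[chain$planted_tf, chain$samples],
           chain$accessibility[chain$planted_peak, ])
  expect_lt(abs(r - cfg$planted_tf_effect), 0.02)
  # decoy TFs are independent of the planted peak
  decoys <- setdiff(chain$tf_list, chain$planted_tf)
  rd <- vapply(decoys, function(tf)
    cor(chain$expression[tf, chain$samples],
        chain$accessibility[chain$planted_peak, ]), numeric(1))
  expect_lt(abs(mean(rd)), 0.05)
})

test_that("planted ChIP interval overlaps the planted peak, decoys never do", {
  for (seed in c(63, 64, 65)) {
    cfg <- sim_config(seed = seed)
    chain <- simulate_regulatory_chain(cfg, simulate_gene_models(cfg))
    pk <- chain$peaks[chain$peaks$name == chain$planted_peak, , drop = FALSE]
    cs <- chip_support(pk, chain$chip[[chain$planted_tf]])
    expect_true(cs$supported)
    for (tf in setdiff(chain$tf_list, chain$planted_tf)[1:5])
      expect_false(chip_support(pk, chain$chip[[tf]])$supported)
  }
})

test_that("immune structure: ssGSEA recovers the latent macrophage score", {
  cfg <- sim_config(seed = 66)
  chain <- simulate_regulatory_chain(cfg, simulate_gene_models(cfg))
  imm <- simulate_immune_and_groups(cfg, chain)
  es <- ssgsea(imm$expression, imm$sets)
  rho <- cor(es["Macrophage", ], imm$latent, method = "spearman")
  expect_gt(rho, 0.8)
  # macrophage signal planted higher in normal tissue
  tum <- imm$groups$sample_id[imm$groups$group == "tumor"]
  nor <- imm$groups$sample_id[imm$groups$group == "normal"]
  wt <- rank_sum_test(es["Macrophage", tum], es["Macrophage", nor])
  expect_lt(wt$p.value, 0.01)
  expect_lt(median(es["Macrophage", tum]), median(es["Macrophage", nor]))
  # planted GPCRs pass the spearman screen; most decoys do not
  hits <- suppressMessages(
    gpcr_macrophage_screen(imm$expression, imm$gpcr_list,
                           es["Macrophage", ]))
  expect_true(all(imm$planted_gpcrs %in% hits$feature_a))
  expect_lt(nrow(hits) - length(imm$planted_gpcrs), 5)
})

test_that("survival generator honours betas, censoring and short follow-ups", {
  cfg <- sim_config(seed = 67, short_followup_frac = 0.1,
                    censoring_rate = 0.3)
  n <- 1000
  scores <- data.frame(sample_id = sprintf("s%04d", 1:n),
                       macrophage_score = rnorm(n))
  clin <- simulate_survival(cfg, scores)
  expect_equal(nrow(clin), n)
  expect_true(all(clin$event %in% 0:1))
  expect_gte(mean(clin$time <= 90), 0.08)   # planted short-follow-up mass
  fit <- cox_fit(clin, "macrophage_score")
  expect_lt(abs(unname(fit$coef) - 0.7), 0.15)
  expect_lt(abs(mean(clin$event == 0) - 0.3), 0.1)
  # zero-beta configuration is null under a median split
  cfg0 <- sim_config(seed = 68, survival_betas = c(macrophage_score = 0),
                     short_followup_frac = 0)
  clin0 <- simulate_survival(cfg0, scores)
  grp <- scores$macrophage_score <= median(scores$macrophage_score)
  lr <- logrank_test(clin0[grp, ], clin0[!grp, ])
  expect_gt(lr$p.value, 0.01)
})

test_that("a full study is byte-identical under the same seed and round-trips", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- simulate_study(sim_config(seed = 69), d1)
  sim2 <- simulate_study(sim_config(seed = 69), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 55)           # includes 50 per-TF ChIP BEDs
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # all emitted files round-trip through the package's own readers
  genes <- read_gene_table(file.path(d1, "genes.tsv"))
  expect_identical(genes, sim1$genes)
  expect_equal(read_matrix(file.path(d1, "accessibility.tsv")),
               sim1$chain$accessibility, tolerance = 1e-9)
  expect_equal(read_matrix(file.path(d1, "expression.tsv")),
               sim1$immune$expression, tolerance = 1e-9)
  expect_identical(read_gmt(file.path(d1, "immune_sets.gmt")),
                   sim1$immune$sets)
  peaks <- read_bed(file.path(d1, "peaks.bed"))
  expect_equal(peaks[, c("name", "chrom", "start", "end")],
               sim1$chain$peaks[, c("name", "chrom", "start", "end")])
  clin <- read_clinical(file.path(d1, "clinical.tsv"))
  expect_equal(clin$time, sim1$clinical$time)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$planted_tf, sim1$truth$planted_tf)
  expect_equal(truth$planted_peak, sim1$truth$planted_peak)
})
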