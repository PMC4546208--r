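test_that("configuration validation rejects inconsistent parameters", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_hyper_dmr_genes = 0.7,
                          frac_hypo_dmr_genes = 0.5), "> 1")
  expect_error(sim_config(planted_delta_beta = 1.4), "fractions")
  expect_error(sim_config(deg_fold_change = 0), "deg_fold_change")
})

test_that("the generator is deterministic and stream-stable", {
  cfg <- tiny_config(seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)

  # one RNG stream per sample: a cohort with more pairs reproduces the
  # first pairs' methylation counts byte for byte
  cfg4 <- sim_config(n_pairs = 4L, n_genes = 30L, seed = 5)
  cfg6 <- sim_config(n_pairs = 6L, n_genes = 30L, seed = 5)
  m4 <- simulate_methylation_counts(cfg4, simulate_genome(cfg4),
                                    simulate_truth(cfg4, simulate_genome(cfg4)))
  g6 <- simulate_genome(cfg6)
  m6 <- simulate_methylation_counts(cfg6, g6, simulate_truth(cfg6, g6))
  # genomes agree because n_genes is unchanged; truth differs, so compare a
  # non-carrier normal sample only
  expect_identical(m4$samples[["P1_N"]]$pos, m6$samples[["P1_N"]]$pos)
})

test_that("promoters span 2700 bp and classify as their planted label", {
  g <- simulate_genome(tiny_config(seed = 2))
  expect_true(all(g$promoters$end - g$promoters$start == 2700L))
  seqs <- promoter_sequences(g$seq, g$promoters)
  got <- vapply(seqs, classify_promoter, "")
  expect_equal(unname(got), g$promoters$cpg_class)
  # CpG positions are derivable from the FASTA: every recorded site is a CG
  idx <- sample(nrow(g$cpg_sites), 50)
  dinuc <- substring(g$seq[["chr1"]], g$cpg_sites$pos[idx] + 1L,
                     g$cpg_sites$pos[idx] + 2L)
  expect_true(all(dinuc == "CG"))
})

test_that("methylation counts conserve depth and carry the planted shift", {
  cfg <- tiny_config(seed = 3)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(cfg, g)
  meth <- simulate_methylation_counts(cfg, g, tr)
  for (s in meth$samples)
    expect_true(all(s$count_M >= 0 & s$count_U >= 0))

  # planted hyper gene, carrier pair: promoter mean beta higher in tumor
  hyper <- names(tr$dmr)[vapply(tr$dmr, `[[`, "", "direction") == "hyper"]
  g1 <- hyper[1]
  pair <- tr$dmr[[g1]]$carriers[1]
  idx <- meth$sites$gene_id == g1
  bt <- meth$beta_true
  expect_gt(mean(bt[idx, paste0("P", pair, "_T")]) -
              mean(bt[idx, paste0("P", pair, "_N")]), 0)

  # zero effect and zero noise: tumor and normal true betas identical
  cfg0 <- tiny_config(seed = 3, planted_delta_beta = 0, beta_noise_sd = 0)
  m0 <- simulate_methylation_counts(cfg0, g, simulate_truth(cfg0, g))
  expect_equal(m0$beta_true[, "P1_T"], m0$beta_true[, "P1_N"])
})

test_that("empirical depth tracks the configured negative-binomial mean", {
  cfg <- sim_config(n_pairs = 1L, n_genes = 150L, seed = 7)
  g <- simulate_genome(cfg)
  meth <- simulate_methylation_counts(cfg, g, simulate_truth(cfg, g))
  depth <- meth$samples[["P1_T"]]$count_M + meth$samples[["P1_T"]]$count_U
  expect_gt(length(depth), 5000)
  expect_lt(abs(mean(depth) - cfg$mean_depth) / cfg$mean_depth, 0.05)
})

test_that("expression counts encode coupled fold changes and determinism", {
  cfg <- tiny_config(seed = 4)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(cfg, g)
  e1 <- simulate_expression_counts(cfg, tr)
  e2 <- simulate_expression_counts(cfg, tr)
  expect_identical(e1$counts, e2$counts)

  # coupled hyper-DMR gene: planted tumor/normal ratio is 1/fold_change
  hyper <- names(tr$dmr)[vapply(tr$dmr, `[[`, "", "direction") == "hyper"]
  for (g1 in hyper) {
    lfc <- tr$deg[[g1]]$lfc
    expect_true(all(lfc[tr$dmr[[g1]]$carriers] ==
                      -log2(cfg$deg_fold_change)))
  }
  # opposite coupling for every planted gene
  for (g1 in names(tr$dmr)) {
    mdir <- tr$dmr[[g1]]$direction
    edir <- tr$deg[[g1]]$direction
    expect_true((mdir == "hyper" && edir == "down") ||
                  (mdir == "hypo" && edir == "up"))
  }

  # fold change 1 plants no expression difference
  cfg1 <- tiny_config(seed = 4, deg_fold_change = 1)
  tr1 <- simulate_truth(cfg1, g)
  expect_true(all(vapply(tr1$deg, function(x) all(x$lfc == 0), TRUE)))
})

test_that("validation cohort plants per-pair differences in responders", {
  cfg <- sim_config(seed = 6, val_n_pairs = 78L)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(cfg, g)
  val <- simulate_validation_cohort(cfg, tr)
  expect_equal(ncol(val$beta), 156L)
  planted <- val$genes$gene_id[val$genes$planted]

  # responder count |delta| >= 0.2 near its analytic expectation
  tum <- val$manifest$sample_id[val$manifest$tissue == "T"]
  nor <- val$manifest$sample_id[val$manifest$tissue == "N"]
  sdd <- sqrt(2) * cfg$val_beta_sd
  p_resp <- pnorm(0.2, cfg$val_delta_beta, sdd, lower.tail = FALSE)
  p_null <- 2 * pnorm(-0.2, 0, sdd)
  expect_n <- 78 * (cfg$val_responder_fraction * p_resp +
                      (1 - cfg$val_responder_fraction) * p_null)
  counts <- vapply(planted, function(g1)
    sum(abs(val$beta[g1, tum] - val$beta[g1, nor]) >= 0.2), 0)
  sd_n <- sqrt(78 * 0.25)          # conservative binomial bound
  expect_true(all(abs(counts - expect_n) < 4 * sd_n))

  # perfect responders without noise show exactly the planted difference
  cfgx <- sim_config(seed = 6, val_responder_fraction = 1, val_beta_sd = 0)
  valx <- simulate_validation_cohort(cfgx, tr)
  px <- valx$genes$gene_id[valx$genes$planted][1]
  dx <- valx$beta[px, tum] - valx$beta[px, nor]
  sgn <- if (tr$dmr[[px]]$direction == "hyper") 1 else -1
  expect_equal(unname(dx), rep(sgn * cfgx$val_delta_beta, 78))
})

test_that("null validation genes stay non-significant at alpha 0.001", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s, val_n_pairs = 78L)
    g <- simulate_genome(cfg)
    tr <- simulate_truth(cfg, g)
    val <- simulate_validation_cohort(cfg, tr)
    res <- validate_cohort(val$beta, val$manifest)
    nulls <- val$genes$gene_id[!val$genes$planted]
    pv <- res$p_value[match(nulls, res$gene_id)]
    hits <- hits + sum(pv < 0.001, na.rm = TRUE)
    total <- total + length(nulls)
  }
  expect_lt(hits / total, 0.05)
})

test_that("cohort files are written deterministically", {
  cfg <- tiny_config(seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  # the coverage TSVs round-trip through the reader
  cov <- list.files(file.path(d1, "coverage"), full.names = TRUE)[1]
  back <- read_coverage_tsv(cov)
  co <- simulate_cohort(cfg)
  sid <- sub("[.]cov$", "", basename(cov))
  expect_equal(back$count_M, co$meth$samples[[sid]]$count_M)
})
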