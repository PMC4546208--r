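#' Configuration for the synthetic paired-cohort simulator
#'
#' Defines the study conditions emulated by the generator: an 8-pair
#' tumor/non-tumor discovery cohort sequenced to ~23x per CpG over
#' promoter-restricted CpGs, with planted recurrent hyper-/hypo-methylated
#' promoters whose expression is negatively coupled, and a 78-pair
#' validation-style cohort of per-amplicon mean beta values.
#'
#' @param n_pairs number of tumor/normal pairs in the discovery cohort.
#' @param n_genes number of genes (one promoter per gene).
#' @param mean_depth mean read depth per CpG (negative-binomial mean).
#' @param depth_dispersion negative-binomial size (shape) for depth; smaller
#'   is more overdispersed. Capture depth is overdispersed in practice.
#' @param frac_hyper_dmr_genes,frac_hypo_dmr_genes fractions of genes planted
#'   with a recurrent hyper-/hypo-methylated promoter DMR.
#' @param planted_delta_beta methylation shift (tumor minus normal beta) at
#'   planted DMR promoters in carrier pairs.
#' @param recurrence_fraction fraction of pairs carrying each planted effect.
#' @param deg_fold_change expression fold change planted at coupled genes
#'   (direction opposite to the methylation change).
#' @param frac_extra_deg fraction of genes given an expression change with no
#'   promoter DMR (recurrent DEGs that must not become candidates).
#' @param rna_mean_count mean expression count scale.
#' @param rna_dispersion within-pair negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2); biological variability across
#'   patients is modelled separately through shared per-patient gene effects.
#' @param class_props named proportions of HCP/ICP/LCP promoters.
#' @param baseline_beta named per-class baseline methylation (HCP low, LCP
#'   high, ICP intermediate).
#' @param beta_noise_sd SD of the per-gene per-sample methylation noise.
#' @param gene_spacing bp between consecutive promoter slots on the
#'   simulated chromosome (must exceed the 2700 bp promoter span).
#' @param val_n_pairs,val_delta_beta,val_responder_fraction,val_beta_sd
#'   validation-cohort size, planted per-pair beta difference, fraction of
#'   responder pairs, and amplicon-level beta noise SD.
#' @param seed master integer seed; every output stream derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 8L, n_genes = 300L, mean_depth = 23,
                       depth_dispersion = 8, frac_hyper_dmr_genes = 0.10,
                       frac_hypo_dmr_genes = 0.05, planted_delta_beta = 0.4,
                       recurrence_fraction = 0.8, deg_fold_change = 4,
                       frac_extra_deg = 0.05, rna_mean_count = 100,
                       rna_dispersion = 0.001,
                       class_props = c(HCP = 0.5, ICP = 0.3, LCP = 0.2),
                       baseline_beta = c(HCP = 0.1, ICP = 0.4, LCP = 0.7),
                       beta_noise_sd = 0.03, gene_spacing = 4000L,
                       val_n_pairs = 78L, val_delta_beta = 0.3,
                       val_responder_fraction = 0.8, val_beta_sd = 0.05,
                       seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1)
    abort("invalid config: n_genes must be a positive integer")
  if (!is_count(n_pairs) || n_pairs < 1)
    abort("invalid config: n_pairs must be a positive integer")
  if (!(is.numeric(mean_depth) && mean_depth > 0))
    abort("invalid config: mean_depth must be positive")
  if (!(is.numeric(depth_dispersion) && depth_dispersion > 0))
    abort("invalid config: depth_dispersion must be positive")
  for (f in c(frac_hyper_dmr_genes, frac_hypo_dmr_genes, planted_delta_beta,
              recurrence_fraction, frac_extra_deg, val_responder_fraction))
    if (!is_fraction(f)) abort("invalid config: fractions must lie in [0,1]")
  if (frac_hyper_dmr_genes + frac_hypo_dmr_genes > 1)
    abort("invalid config: frac_hyper_dmr_genes + frac_hypo_dmr_genes > 1")
  if (deg_fold_change <= 0) abort("invalid config: deg_fold_change must be positive")
  if (gene_spacing < 2700) abort("invalid config: gene_spacing must be >= 2700")
  stopifnot(setequal(names(class_props), c("HCP", "ICP", "LCP")),
            setequal(names(baseline_beta), c("HCP", "ICP", "LCP")))
  class_props <- class_props / sum(class_props)
  structure(list(
    n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    frac_hyper_dmr_genes = frac_hyper_dmr_genes,
    frac_hypo_dmr_genes = frac_hypo_dmr_genes,
    planted_delta_beta = planted_delta_beta,
    recurrence_fraction = recurrence_fraction,
    deg_fold_change = deg_fold_change, frac_extra_deg = frac_extra_deg,
    rna_mean_count = rna_mean_count, rna_dispersion = rna_dispersion,
    class_props = class_props[c("HCP", "ICP", "LCP")],
    baseline_beta = baseline_beta[c("HCP", "ICP", "LCP")],
    beta_noise_sd = beta_noise_sd, gene_spacing = as.integer(gene_spacing),
    val_n_pairs = as.integer(val_n_pairs), val_delta_beta = val_delta_beta,
    val_responder_fraction = val_responder_fraction, val_beta_sd = val_beta_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# ---- sequence generators ----------------------------------------------------

.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# iid sequence with target GC, then CpG depletion: each CG dinucleotide keeps
# its G with probability `keep`, otherwise the G mutates to A/T. Mimics the
# deamination-driven CpG depletion of bulk genomic sequence.
.depleted_seq <- function(len, gc, keep) {
  x <- .sample_bases(len, gc)
  i <- which(x[-length(x)] == "C" & x[-1L] == "G")
  if (length(i)) {
    hit <- i[stats::runif(length(i)) > keep]
    if (length(hit)) x[hit + 1L] <- sample(c("A", "T"), length(hit), replace = TRUE)
  }
  x
}

# CpG-island-like core: each step emits "CG" with probability p_cg, otherwise
# a single base at the given GC level.
.cpg_rich_seq <- function(len, p_cg = 0.18, gc = 0.55) {
  emit <- ifelse(stats::runif(len) < p_cg, "CG", .sample_bases(len, gc))
  unlist(strsplit(emit, "", fixed = TRUE), use.names = FALSE)[seq_len(len)]
}

.promoter_seq <- function(class) {
  switch(class,
    HCP = c(.depleted_seq(1400L, 0.45, 0.05), .cpg_rich_seq(700L),
            .depleted_seq(600L, 0.45, 0.05))[seq_len(2700L)],
    ICP = c(.depleted_seq(950L, 0.40, 0.05), .depleted_seq(800L, 0.50, 0.55),
            .depleted_seq(950L, 0.40, 0.05)),
    LCP = .depleted_seq(2700L, 0.40, 0.15),
    abort("unknown promoter class: ", class))
}

# ---- genome -----------------------------------------------------------------

#' Simulate a promoter-bearing genome with known promoter classes
#'
#' Lays one gene per slot on a single chromosome, synthesizes each promoter
#' sequence in one of three CpG-content styles (CpG-dense/GC-rich for HCP,
#' CpG-sparse for LCP, intermediate for ICP), and records the TSS, strand,
#' the 2700 bp promoter interval spanning -2200/+500 around the TSS, and all
#' promoter CpG positions. Each emitted promoter is guaranteed to classify
#' as its intended label under [classify_promoter()].
#'
#' @param config a [sim_config()].
#' @return A list with `seq` (named character vector of chromosome
#'   sequences), `annotation` (gene_id, chrom, tss, strand, cpg_class;
#'   0-based TSS), `promoters` (a promoter table as built by
#'   [promoter_from_tss()] plus `cpg_class`), and `cpg_sites`
#'   (gene_id, chrom, pos; 0-based position of the CpG's C).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_stream(config$seed, "genome", {
    n_class <- c(HCP = round(config$class_props[["HCP"]] * n),
                 ICP = round(config$class_props[["ICP"]] * n))
    n_class <- c(n_class, LCP = n - sum(n_class))
    classes <- sample(rep(names(n_class), n_class))
    spacing <- config$gene_spacing
    glen <- n * spacing + 200L
    genome <- .depleted_seq(glen, 0.40, 0.10)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    starts <- (seq_len(n) - 1L) * spacing          # promoter start, 0-based
    tss <- ifelse(strands == "+", starts + 2200L, starts + 500L)
    gene_ids <- sprintf("gene%03d", seq_len(n))
    for (i in seq_len(n)) {
      for (try in seq_len(25L)) {
        s <- .promoter_seq(classes[i])
        if (classify_promoter(paste(s, collapse = "")) == classes[i]) break
        if (try == 25L) abort("failed to synthesize a ", classes[i], " promoter")
      }
      genome[(starts[i] + 1L):(starts[i] + 2700L)] <- s
    }
    seq_str <- paste(genome, collapse = "")
    promoters <- promoter_from_tss(gene_ids, "chr1", tss, strands,
                                   chrom_length = glen)
    promoters$cpg_class <- classes
    cpg <- lapply(seq_len(n), function(i) {
      sub <- substr(seq_str, starts[i] + 1L, starts[i] + 2700L)
      m <- gregexpr("CG", sub, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) return(NULL)
      data.frame(gene_id = gene_ids[i], chrom = "chr1",
                 pos = starts[i] + as.integer(m) - 1L)
    })
    list(seq = c(chr1 = seq_str),
         annotation = data.frame(gene_id = gene_ids, chrom = "chr1",
                                 tss = tss, strand = strands,
                                 cpg_class = classes),
         promoters = promoters,
         cpg_sites = do.call(rbind, cpg))
  })
}

# ---- ground truth -----------------------------------------------------------

#' Plant ground-truth DMR and DEG effects
#'
#' Hyper-methylated DMRs are planted on HCP/ICP promoters and hypo-methylated
#' DMRs on ICP/LCP promoters (the class baselines leave no headroom for the
#' opposite assignments). Every planted DMR gene is expression-coupled with
#' the opposite direction; an additional set of genes carries an expression
#' change with no methylation change.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return An object of class `ground_truth`: `dmr` (per planted gene:
#'   direction and carrier pair indices), `deg` (per expression-changed gene:
#'   direction, carrier pairs, per-pair true log2 fold change), and
#'   `promoter_classes` (named HCP/ICP/LCP vector).
#' @export
simulate_truth <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  cls <- stats::setNames(genome$annotation$cpg_class, genome$annotation$gene_id)
  n <- config$n_genes
  n_hyper <- round(config$frac_hyper_dmr_genes * n)
  n_hypo <- round(config$frac_hypo_dmr_genes * n)
  n_carrier <- round(config$recurrence_fraction * config$n_pairs)
  with_stream(config$seed, "truth", {
    hyper_pool <- names(cls)[cls %in% c("HCP", "ICP")]
    hyper <- sample(hyper_pool, min(n_hyper, length(hyper_pool)))
    hypo_pool <- setdiff(names(cls)[cls %in% c("ICP", "LCP")], hyper)
    hypo <- sample(hypo_pool, min(n_hypo, length(hypo_pool)))
    dmr <- c(
      lapply(hyper, function(g) list(direction = "hyper",
        carriers = sort(sample(config$n_pairs, n_carrier)))),
      lapply(hypo, function(g) list(direction = "hypo",
        carriers = sort(sample(config$n_pairs, n_carrier)))))
    names(dmr) <- c(hyper, hypo)
    # coupled expression: opposite sign to the methylation change
    deg <- lapply(names(dmr), function(g) {
      dir <- if (dmr[[g]]$direction == "hyper") "down" else "up"
      lfc <- rep(0, config$n_pairs)
      lfc[dmr[[g]]$carriers] <- (if (dir == "up") 1 else -1) *
        log2(config$deg_fold_change)
      list(direction = dir, carriers = dmr[[g]]$carriers, lfc = lfc)
    })
    names(deg) <- names(dmr)
    n_extra <- round(config$frac_extra_deg * n)
    extra_pool <- setdiff(names(cls), names(dmr))
    extra <- sample(extra_pool, min(n_extra, length(extra_pool)))
    for (g in extra) {
      dir <- sample(c("up", "down"), 1L)
      carriers <- sort(sample(config$n_pairs, n_carrier))
      lfc <- rep(0, config$n_pairs)
      lfc[carriers] <- (if (dir == "up") 1 else -1) * log2(config$deg_fold_change)
      deg[[g]] <- list(direction = dir, carriers = carriers, lfc = lfc)
    }
    structure(list(dmr = dmr, deg = deg, promoter_classes = cls),
              class = "ground_truth")
  })
}

# ---- methylation counts -----------------------------------------------------

#' Simulate per-sample per-CpG bisulfite count profiles
#'
#' Per CpG and sample, read depth is negative binomial
#' (`mean_depth`, `depth_dispersion`) and the methylated count is binomial
#' at the site's true beta. True beta is a per-class baseline with shared
#' per-gene and per-site jitter, small per-gene per-sample noise, and the
#' planted `planted_delta_beta` shift (sign by direction) in tumor samples
#' of carrier pairs, clipped to [0, 1].
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return A list with `samples` (named list of coverage data frames:
#'   chrom, pos, count_M, count_U; only covered sites emitted), `beta_true`
#'   (sites x samples matrix of true betas), `sites` (gene_id, chrom, pos),
#'   and `manifest` (sample_id, patient_id, tissue).
#' @export
simulate_methylation_counts <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  sites <- genome$cpg_sites
  if (!all(names(truth$promoter_classes) %in% genome$annotation$gene_id))
    abort("ground truth does not match the simulated genome")
  n_sites <- nrow(sites)
  gene_of_site <- match(sites$gene_id, genome$annotation$gene_id)
  base_by_class <- config$baseline_beta[genome$annotation$cpg_class]
  site_beta0 <- with_stream(config$seed, "meth_baseline", {
    gene_base <- pmin(pmax(base_by_class +
      stats::rnorm(config$n_genes, 0, 0.05), 0.02), 0.98)
    pmin(pmax(gene_base[gene_of_site] + stats::rnorm(n_sites, 0, 0.05), 0), 1)
  })
  shift_site <- function(pair, tissue) {
    s <- numeric(n_sites)
    if (tissue != "T") return(s)
    for (g in names(truth$dmr)) {
      rec <- truth$dmr[[g]]
      if (pair %in% rec$carriers) {
        sign <- if (rec$direction == "hyper") 1 else -1
        s[sites$gene_id == g] <- sign * config$planted_delta_beta
      }
    }
    s
  }
  manifest <- data.frame(
    sample_id = paste0("P", rep(seq_len(config$n_pairs), each = 2L),
                       c("_T", "_N")),
    patient_id = paste0("P", rep(seq_len(config$n_pairs), each = 2L)),
    tissue = rep(c("T", "N"), config$n_pairs))
  beta_true <- matrix(NA_real_, n_sites, nrow(manifest),
                      dimnames = list(NULL, manifest$sample_id))
  samples <- vector("list", nrow(manifest))
  names(samples) <- manifest$sample_id
  for (k in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[k]
    pair <- as.integer(sub("^P(\\d+)_.*$", "\\1", sid))
    tissue <- manifest$tissue[k]
    samples[[k]] <- with_stream(config$seed, paste0("meth_", sid), {
      gnoise <- stats::rnorm(config$n_genes, 0, config$beta_noise_sd)
      b <- pmin(pmax(site_beta0 + gnoise[gene_of_site] +
                       shift_site(pair, tissue), 0), 1)
      beta_true[, k] <- b
      depth <- stats::rnbinom(n_sites, size = config$depth_dispersion,
                              mu = config$mean_depth)
      m <- stats::rbinom(n_sites, depth, b)
      keep <- depth > 0L
      data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                 count_M = m[keep], count_U = depth[keep] - m[keep])
    })
  }
  list(samples = samples, beta_true = beta_true,
       sites = sites, manifest = manifest)
}

# ---- expression counts ------------------------------------------------------

#' Simulate per-sample gene expression counts
#'
#' Gene baseline means are log-normal around `rna_mean_count`; per-patient
#' gene effects are shared by the tumor and normal sample of a pair (so they
#' cancel within pair); tumor means are scaled by the planted per-pair fold
#' change; counts are negative binomial with the small within-pair
#' dispersion `rna_dispersion`.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @return A list with `counts` (genes x samples integer matrix),
#'   `lengths` (named gene length vector, bp) and `manifest`.
#' @export
simulate_expression_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  gene_ids <- names(truth$promoter_classes)
  n <- length(gene_ids)
  gl <- with_stream(config$seed, "expr_genes", {
    lengths <- round(stats::runif(n, 500, 5000))
    mu0 <- stats::rlnorm(n, log(config$rna_mean_count) - 0.125, 0.5)
    list(lengths = stats::setNames(lengths, gene_ids),
         mu0 = stats::setNames(mu0, gene_ids))
  })
  pat_eff <- with_stream(config$seed, "expr_patients",
    matrix(stats::rlnorm(n * config$n_pairs, 0, 0.2), n, config$n_pairs,
           dimnames = list(gene_ids, NULL)))
  lfc <- matrix(0, n, config$n_pairs, dimnames = list(gene_ids, NULL))
  for (g in names(truth$deg)) lfc[g, ] <- truth$deg[[g]]$lfc
  manifest <- data.frame(
    sample_id = paste0("P", rep(seq_len(config$n_pairs), each = 2L),
                       c("_T", "_N")),
    patient_id = paste0("P", rep(seq_len(config$n_pairs), each = 2L)),
    tissue = rep(c("T", "N"), config$n_pairs))
  counts <- matrix(0L, n, nrow(manifest),
                   dimnames = list(gene_ids, manifest$sample_id))
  for (k in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[k]
    pair <- as.integer(sub("^P(\\d+)_.*$", "\\1", sid))
    mu <- gl$mu0 * pat_eff[, pair]
    if (manifest$tissue[k] == "T") mu <- mu * 2^lfc[, pair]
    counts[, k] <- with_stream(config$seed, paste0("expr_", sid), {
      if (config$rna_dispersion < 1e-12) stats::rpois(n, mu)
      else stats::rnbinom(n, size = 1 / config$rna_dispersion, mu = mu)
    })
  }
  list(counts = counts, lengths = gl$lengths, manifest = manifest)
}

# ---- validation cohort ------------------------------------------------------

#' Simulate a large validation cohort of per-amplicon mean beta values
#'
#' Emits one mean beta per gene amplicon per sample for a cohort of
#' `val_n_pairs` tumor/normal pairs. Planted (candidate) genes show the
#' planted `val_delta_beta` difference in a random `val_responder_fraction`
#' of pairs; the remaining (non-responder) pairs and all null genes differ
#' only by amplicon-level noise.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @return A list with `beta` (genes x samples matrix, samples `V#_T/V#_N`),
#'   `genes` (gene_id, planted, direction), `responders` (planted genes x
#'   pairs logical matrix), and `manifest`.
#' @export
simulate_validation_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  planted <- names(truth$dmr)
  nulls <- setdiff(names(truth$promoter_classes), names(truth$deg))
  np <- config$val_n_pairs
  with_stream(config$seed, "validation", {
    nulls <- sample(nulls, min(length(planted), length(nulls)))
    genes <- c(planted, nulls)
    dirs <- c(vapply(truth$dmr, `[[`, "", "direction"),
              stats::setNames(rep(NA_character_, length(nulls)), nulls))
    base <- pmin(pmax(config$baseline_beta[
      truth$promoter_classes[genes]] + stats::rnorm(length(genes), 0, 0.05),
      0.05), 0.95)
    resp <- matrix(stats::runif(length(planted) * np) <
                     config$val_responder_fraction,
                   length(planted), np, dimnames = list(planted, NULL))
    manifest <- data.frame(
      sample_id = paste0("V", rep(seq_len(np), each = 2L), c("_T", "_N")),
      patient_id = paste0("V", rep(seq_len(np), each = 2L)),
      tissue = rep(c("T", "N"), np))
    beta <- matrix(NA_real_, length(genes), 2L * np,
                   dimnames = list(genes, manifest$sample_id))
    for (p in seq_len(np)) {
      shift <- numeric(length(genes))
      idx <- match(planted, genes)
      shift[idx] <- ifelse(dirs[planted] == "hyper", 1, -1) *
        config$val_delta_beta * resp[, p]
      noise_t <- stats::rnorm(length(genes), 0, config$val_beta_sd)
      noise_n <- stats::rnorm(length(genes), 0, config$val_beta_sd)
      beta[, 2L * p - 1L] <- pmin(pmax(base + shift + noise_t, 0), 1)
      beta[, 2L * p] <- pmin(pmax(base + noise_n, 0), 1)
    }
    list(beta = beta,
         genes = data.frame(gene_id = genes, planted = genes %in% planted,
                            direction = unname(dirs[genes])),
         responders = resp, manifest = manifest)
  })
}

# ---- cohort wrapper and writers ---------------------------------------------

#' Simulate a complete paired cohort
#'
#' Runs [simulate_genome()], [simulate_truth()],
#' [simulate_methylation_counts()], [simulate_expression_counts()] and
#' [simulate_validation_cohort()] under one configuration.
#'
#' @param config a [sim_config()].
#' @param validation also simulate the validation cohort (default TRUE).
#' @return An object of class `meth_cohort`.
#' @export
simulate_cohort <- function(config = sim_config(), validation = TRUE) {
  genome <- simulate_genome(config)
  truth <- simulate_truth(config, genome)
  meth <- simulate_methylation_counts(config, genome, truth)
  expr <- simulate_expression_counts(config, truth)
  val <- if (validation) simulate_validation_cohort(config, truth) else NULL
  structure(list(config = config, genome = genome, truth = truth,
                 meth = meth, expr = expr, validation = val),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated paired cohort: %d pairs, %d genes, %d promoter CpGs, seed %d\n",
    x$config$n_pairs, x$config$n_genes, nrow(x$genome$cpg_sites),
    x$config$seed))
  cat(sprintf("  planted DMR genes: %d (%d hyper / %d hypo); DEG genes: %d\n",
              length(x$truth$dmr),
              sum(vapply(x$truth$dmr, `[[`, "", "direction") == "hyper"),
              sum(vapply(x$truth$dmr, `[[`, "", "direction") == "hypo"),
              length(x$truth$deg)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the genome FASTA, annotation TSV (gene_id, chrom, tss_1based,
#' strand), per-sample bismark-style coverage TSVs, gene count and length
#' TSVs, the pairing manifest, the validation beta table, and the ground
#' truth as JSON. Identical configurations produce byte-identical files.
#'
#' @param cohort a `meth_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$genome$seq), p)
  paths <- c(paths, p)
  ann <- cohort$genome$annotation
  p <- file.path(dir, "genes.tsv")
  utils::write.table(
    data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
               tss_1based = ann$tss + 1L, strand = ann$strand),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  covdir <- file.path(dir, "coverage")
  dir.create(covdir, showWarnings = FALSE)
  for (sid in names(cohort$meth$samples)) {
    p <- file.path(covdir, paste0(sid, ".cov"))
    write_coverage_tsv(cohort$meth$samples[[sid]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "gene_counts.tsv")
  utils::write.table(cbind(gene_id = rownames(cohort$expr$counts),
                           as.data.frame(cohort$expr$counts)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "gene_lengths.tsv")
  utils::write.table(data.frame(gene_id = names(cohort$expr$lengths),
                                length_bp = unname(cohort$expr$lengths)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "pairs.tsv")
  utils::write.table(cohort$meth$manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(cohort$validation)) {
    p <- file.path(dir, "validation_beta.tsv")
    utils::write.table(cbind(gene_id = rownames(cohort$validation$beta),
                             as.data.frame(cohort$validation$beta)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ground_truth.json")
  truth_json <- list(
    dmr_genes = lapply(cohort$truth$dmr, function(x)
      list(direction = x$direction, carriers = x$carriers)),
    deg_genes = lapply(cohort$truth$deg, function(x)
      list(direction = x$direction, carriers = x$carriers, log2_fc = x$lfc)),
    promoter_classes = as.list(cohort$truth$promoter_classes))
  writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE, digits = NA), p)
  paths <- c(paths, p)
  invisible(paths)
}
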