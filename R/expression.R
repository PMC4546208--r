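# Per-pair differential expression from RPKM, without replicates: an exact
# two-sided binomial test of the tumor count against the two-library
# expected proportion, BH-adjusted within each pair.

#' Compute RPKM from a gene count matrix
#'
#' `rpkm = count / (gene_length_kb * library_size_millions)`; library size
#' is the per-sample sum of raw counts.
#'
#' @param counts genes x samples matrix of non-negative counts (rownames =
#'   gene ids).
#' @param lengths named vector of gene lengths in bp (all genes present).
#' @return Genes x samples RPKM matrix.
#' @export
compute_rpkm <- function(counts, lengths) {
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    abort("genes without a length: ", paste(missing, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) abort("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("zero library size")
  sweep(sweep(counts, 1, len / 1000, "/"), 2, lib / 1e6, "/")
}

#' Per-pair differential expression test
#'
#' For each gene, the tumor count `c_T` is tested against
#' `Binomial(n = c_T + c_N, p0 = L_T / (L_T + L_N))` (two-sided, by summing
#' point probabilities not exceeding the observed one), where `L_T`, `L_N`
#' are the two library sizes. Fold change is computed on RPKM with a
#' pseudocount on both sides; a gene is significant when the RPKM fold
#' change exceeds `fc_cutoff` (in either direction) and the BH-adjusted
#' p-value is below `fdr`.
#'
#' @param tumor_counts,normal_counts named count vectors for the two samples
#'   of one pair.
#' @param lengths named gene length vector (bp).
#' @param fc_cutoff RPKM fold-change cutoff (default 2).
#' @param fdr FDR threshold (default 0.01).
#' @param pseudo_rpkm pseudocount added to both RPKM values (default 0.1).
#' @return A data frame: gene_id, count_t, count_n, rpkm_t, rpkm_n, log2_fc,
#'   p_value, q_value, direction ("up"/"down" in tumor), significant.
#' @export
pair_deg_test <- function(tumor_counts, normal_counts, lengths,
                          fc_cutoff = 2, fdr = 0.01, pseudo_rpkm = 0.1) {
  stopifnot(identical(names(tumor_counts), names(normal_counts)))
  lib_t <- sum(tumor_counts); lib_n <- sum(normal_counts)
  if (lib_t <= 0 || lib_n <= 0) abort("zero library size")
  cm <- cbind(T = tumor_counts, N = normal_counts)
  rpkm <- compute_rpkm(cm, lengths)
  p0 <- lib_t / (lib_t + lib_n)
  n <- tumor_counts + normal_counts
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0L) return(1)
    stats::binom.test(tumor_counts[i], n[i], p0)$p.value
  }, 0)
  fc <- (rpkm[, "T"] + pseudo_rpkm) / (rpkm[, "N"] + pseudo_rpkm)
  q <- bh_adjust(p)
  data.frame(gene_id = names(tumor_counts),
             count_t = unname(tumor_counts), count_n = unname(normal_counts),
             rpkm_t = unname(rpkm[, "T"]), rpkm_n = unname(rpkm[, "N"]),
             log2_fc = unname(log2(fc)), p_value = unname(p),
             q_value = unname(q),
             direction = unname(ifelse(fc >= 1, "up", "down")),
             significant = unname(pmax(fc, 1 / fc) > fc_cutoff & q < fdr),
             row.names = NULL)
}

#' Call DEGs for every pair of a cohort
#'
#' @param counts genes x samples count matrix.
#' @param lengths named gene length vector (bp).
#' @param manifest data frame with sample_id, patient_id, tissue.
#' @param ... passed to [pair_deg_test()].
#' @return A data frame of per-pair DEG calls with a pair_id column.
#' @export
call_degs <- function(counts, lengths, manifest, ...) {
  pairs <- split(manifest, manifest$patient_id)
  out <- lapply(names(pairs), function(pid) {
    pm <- pairs[[pid]]
    tid <- pm$sample_id[pm$tissue == "T"]
    nid <- pm$sample_id[pm$tissue == "N"]
    res <- pair_deg_test(stats::setNames(counts[, tid], rownames(counts)),
                         stats::setNames(counts[, nid], rownames(counts)),
                         lengths, ...)
    res$pair_id <- pid
    res
  })
  do.call(rbind, out)
}

#' Summarize DEG recurrence across pairs
#'
#' A gene is recurrent when it is significant with one consistent direction
#' in at least `recurrence_min` pairs.
#'
#' @param calls DEG call table from [call_degs()].
#' @param n_pairs number of pairs.
#' @param recurrence_min minimum supporting pairs (default 6 of 8).
#' @return A data frame: gene_id, n_pairs_up, n_pairs_down,
#'   dominant_direction, n_pairs_significant, recurrent, plus per-pair DEG
#'   totals as the `per_pair_totals` attribute.
#' @export
deg_recurrence <- function(calls, n_pairs, recurrence_min = 6L) {
  sig <- calls[calls$significant, , drop = FALSE]
  genes <- sort(unique(sig$gene_id))
  up <- table(factor(sig$gene_id[sig$direction == "up"], levels = genes))
  down <- table(factor(sig$gene_id[sig$direction == "down"], levels = genes))
  out <- data.frame(gene_id = genes,
                    n_pairs_up = as.integer(up),
                    n_pairs_down = as.integer(down))
  out$dominant_direction <- ifelse(out$n_pairs_up >= out$n_pairs_down,
                                   "up", "down")
  out$n_pairs_significant <- pmax(out$n_pairs_up, out$n_pairs_down)
  out$recurrent <- out$n_pairs_significant >= recurrence_min
  attr(out, "per_pair_totals") <- table(sig$pair_id)
  out
}
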