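# End-to-end convenience driver over a (simulated or real) paired cohort.

#' Aggregate per-CpG counts into per-region count matrices
#'
#' Sums methylated and total counts of all CpGs inside each region, per
#' sample -- the input expected by [top_variable_regions()].
#'
#' @param profiles named list of per-sample coverage data frames.
#' @param regions data frame with region id in the first column plus chrom,
#'   start, end (0-based half-open).
#' @return A list of regions x samples matrices: `meth`, `total`.
#' @export
aggregate_region_counts <- function(profiles, regions) {
  ids <- regions[[1L]]
  m <- tot <- matrix(0, nrow(regions), length(profiles),
                     dimnames = list(ids, names(profiles)))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    for (i in seq_len(nrow(regions))) {
      hit <- p$chrom == regions$chrom[i] & p$pos >= regions$start[i] &
        p$pos < regions$end[i]
      m[i, j] <- sum(p$count_M[hit])
      tot[i, j] <- sum(p$count_M[hit] + p$count_U[hit])
    }
  }
  list(meth = m, total = tot)
}

#' Run the full paired DMR/DEG/integration analysis on a cohort
#'
#' Per-pair promoter DMR detection (exact per-CpG tests, pair-level BH,
#' sliding windows), per-pair DEG calling (RPKM fold change + exact
#' binomial test), recurrence summaries, and DMR-DEG integration into the
#' negative-relationship candidate list.
#'
#' @param cohort a `meth_cohort` from [simulate_cohort()], or any list with
#'   the same `meth`, `expr` and `genome` components.
#' @param min_depth within-pair per-CpG depth filter.
#' @param window_cpgs,step_cpgs,min_sig,min_mean_delta,fdr,site_delta
#'   DMR sliding-window parameters (see [sliding_window_dmrs()]).
#' @param fc_cutoff,deg_fdr DEG thresholds (see [pair_deg_test()]).
#' @param recurrence_min,max_dmrs_per_pair recurrence rules.
#' @param min_pairs joint DMR+DEG support needed for a candidate.
#' @return A list: dmr_calls, dmr_recurrence, deg_calls, deg_recurrence,
#'   candidates, negative_candidates.
#' @export
run_pair_analysis <- function(cohort, min_depth = 4L, window_cpgs = 5L,
                              step_cpgs = 1L, min_sig = 3L,
                              min_mean_delta = 0.1, fdr = 0.05,
                              site_delta = 0.05, fc_cutoff = 2,
                              deg_fdr = 0.01, recurrence_min = 6L,
                              max_dmrs_per_pair = 2L, min_pairs = 5L) {
  n_pairs <- length(unique(cohort$meth$manifest$patient_id))
  dmr_calls <- detect_dmrs(cohort$meth$samples, cohort$meth$manifest,
                           cohort$genome$cpg_sites, min_depth = min_depth,
                           window_cpgs = window_cpgs, step_cpgs = step_cpgs,
                           min_sig = min_sig,
                           min_mean_delta = min_mean_delta, fdr = fdr,
                           site_delta = site_delta)
  dmr_rec <- summarize_recurrence(dmr_calls, n_pairs,
                                  recurrence_min = recurrence_min,
                                  max_dmrs_per_pair = max_dmrs_per_pair)
  deg_calls <- call_degs(cohort$expr$counts, cohort$expr$lengths,
                         cohort$expr$manifest, fc_cutoff = fc_cutoff,
                         fdr = deg_fdr)
  deg_rec <- deg_recurrence(deg_calls, n_pairs,
                            recurrence_min = recurrence_min)
  candidates <- match_dmr_deg(dmr_calls, deg_calls, min_pairs = min_pairs,
                              max_dmrs_per_pair = max_dmrs_per_pair)
  list(dmr_calls = dmr_calls, dmr_recurrence = dmr_rec,
       deg_calls = deg_calls, deg_recurrence = deg_rec,
       candidates = candidates,
       negative_candidates = filter_negative(candidates))
}
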