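# Per-pair differential methylation: exact site tests, FDR adjustment,
# sliding-window DMR calls within promoters, and cross-pair recurrence.

#' Two-sided Fisher's exact test for 2x2 methylation count tables
#'
#' Exact two-sided p-value for tables `[[M_T, U_T], [M_N, U_N]]`: the sum
#' of all hypergeometric point probabilities not exceeding that of the
#' observed table (with the usual relative tolerance), evaluated as two
#' tail probabilities around the distribution's mode. Fully vectorized
#' over sites, which makes whole-cohort testing fast at bisulfite depths.
#'
#' @param m_t,u_t methylated/unmethylated counts in the tumor sample.
#' @param m_n,u_n methylated/unmethylated counts in the normal sample.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_2x2 <- function(m_t, u_t, m_n, u_n) {
  tot <- m_t + u_t + m_n + u_n
  if (any(tot <= 0)) abort("zero total counts: depth filter violated upstream")
  white <- m_t + m_n; black <- u_t + u_n; drawn <- m_t + u_t
  a <- m_t
  thr <- stats::dhyper(a, white, black, drawn) * (1 + 1e-7)
  mode <- floor((drawn + 1) * (white + 1) / (tot + 2))
  lo <- pmax(0, drawn - black); hi <- pmin(drawn, white)
  mode <- pmin(pmax(mode, lo), hi)
  # mirror right-side observations so the observed value sits in the
  # non-increasing left tail: swapping the table's columns maps X to
  # drawn - X with white and black exchanged, preserving densities
  flip <- a > mode
  w <- ifelse(flip, black, white); b <- ifelse(flip, white, black)
  av <- ifelse(flip, drawn - a, a)
  hiv <- pmin(drawn, w)
  mv <- pmin(pmax(floor((drawn + 1) * (w + 1) / (tot + 2)),
                  pmax(0, drawn - b)), hiv)
  p_left <- stats::phyper(av, w, b, drawn)
  # smallest x in (mode, hi] with density <= thr (density is
  # non-increasing beyond the mode; binary search, vectorized)
  ls <- pmax(mv, av + 1)
  has_right <- hiv >= ls & stats::dhyper(hiv, w, b, drawn) <= thr
  hs <- hiv
  ls[!has_right] <- 0; hs[!has_right] <- 0
  idx <- which(ls < hs)
  while (length(idx)) {
    mid <- (ls[idx] + hs[idx]) %/% 2
    ok <- stats::dhyper(mid, w[idx], b[idx], drawn[idx]) <= thr[idx]
    hs[idx[ok]] <- mid[ok]
    ls[idx[!ok]] <- mid[!ok] + 1
    idx <- idx[ls[idx] < hs[idx]]
  }
  p_right <- numeric(length(ls))
  p_right[has_right] <- stats::phyper(ls[has_right] - 1, w[has_right],
                                      b[has_right], drawn[has_right],
                                      lower.tail = FALSE)
  pmin(p_left + p_right, 1)
}

#' Per-CpG differential methylation test for one tumor/normal pair
#'
#' Joins the two per-sample count profiles on sites covered at
#' `min_depth` or more in both samples, then applies [fisher_exact_2x2()]
#' and computes `delta_beta = beta_T - beta_N` per site.
#'
#' @param tumor,normal coverage data frames (chrom, pos, count_M, count_U).
#' @param min_depth within-pair minimum depth (both samples).
#' @return A data frame: chrom, pos, m_t, u_t, m_n, u_n, delta_beta,
#'   p_value.
#' @export
site_test <- function(tumor, normal, min_depth = 4L) {
  res <- site_join(tumor, normal, min_depth = min_depth)
  res$p_value <- if (nrow(res) > 0L)
    fisher_exact_2x2(res$m_t, res$u_t, res$m_n, res$u_n) else numeric(0)
  res
}

# Join two per-sample coverage profiles on sites covered at min_depth in
# both, with per-site delta_beta; no test applied.
site_join <- function(tumor, normal, min_depth = 4L) {
  kt <- paste(tumor$chrom, tumor$pos)
  kn <- paste(normal$chrom, normal$pos)
  i <- match(kt, kn)
  ok <- !is.na(i) &
    tumor$count_M + tumor$count_U >= min_depth &
    (normal$count_M + normal$count_U)[i] >= min_depth
  t2 <- tumor[ok, , drop = FALSE]
  n2 <- normal[i[ok], , drop = FALSE]
  if (nrow(t2) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      m_t = integer(0), u_t = integer(0), m_n = integer(0),
                      u_n = integer(0), delta_beta = numeric(0)))
  beta_t <- t2$count_M / (t2$count_M + t2$count_U)
  beta_n <- n2$count_M / (n2$count_M + n2$count_U)
  data.frame(chrom = t2$chrom, pos = t2$pos,
             m_t = t2$count_M, u_t = t2$count_U,
             m_n = n2$count_M, u_n = n2$count_U,
             delta_beta = beta_t - beta_n)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values p-values in [0, 1] (non-empty).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) abort("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pooled sliding-window statistics for one promoter
#'
#' For every window of `window_cpgs` consecutive CpGs (step `step_cpgs`):
#' the summed methylated/unmethylated counts of both samples, the pooled
#' beta difference, and the exact test p-value of the pooled table.
#'
#' @param sites position-ordered data frame with m_t, u_t, m_n, u_n.
#' @param window_cpgs,step_cpgs window size and step, in CpGs.
#' @return A data frame: start_idx (1-based site index of the window
#'   start), m_t, u_t, m_n, u_n, delta, p_value; zero rows when fewer than
#'   `window_cpgs` sites.
#' @export
window_pool <- function(sites, window_cpgs = 5L, step_cpgs = 1L) {
  n <- nrow(sites)
  if (n < window_cpgs)
    return(data.frame(start_idx = integer(0), m_t = numeric(0),
                      u_t = numeric(0), m_n = numeric(0), u_n = numeric(0),
                      delta = numeric(0), p_value = numeric(0)))
  starts <- seq.int(1L, n - window_cpgs + 1L, by = step_cpgs)
  ends <- starts + window_cpgs - 1L
  wsum <- function(v) { cv <- cumsum(v); cv[ends] - c(0, cv)[starts] }
  mt <- wsum(sites$m_t); ut <- wsum(sites$u_t)
  mn <- wsum(sites$m_n); un <- wsum(sites$u_n)
  data.frame(start_idx = starts, m_t = mt, u_t = ut, m_n = mn, u_n = un,
             delta = mt / (mt + ut) - mn / (mn + un),
             p_value = fisher_exact_2x2(mt, ut, mn, un))
}

#' Sliding-window DMR calls within one promoter
#'
#' Windows of `window_cpgs` consecutive CpGs (step `step_cpgs`) are tested
#' for regional differential methylation. Under the default
#' `method = "pooled"` the window's methylated/unmethylated counts are
#' summed over its CpGs and tested with [fisher_exact_2x2()]; window
#' p-values are BH-adjusted across all windows of the pair when called
#' from [detect_dmrs()] (or across the promoter's windows when this
#' function is used standalone), and a window
#' qualifies when its q-value is below `fdr`, the lower `delta_conf`
#' confidence bound of the pooled beta difference is at least
#' `min_mean_delta` in the window's direction, and at least `min_sig` of
#' its sites support that direction with `|delta_beta| >= site_delta`.
#' Under `method = "site_count"` a window instead qualifies when at least
#' `min_sig` of its sites are individually significant (site q-value below
#' `fdr` and `|delta_beta| >= site_delta`) with `|mean delta|` of those
#' sites at least `min_mean_delta`. In both modes the window's supporting
#' (or significant) sites must be direction-homogeneous: a window also
#' containing an opposing supporting site never qualifies.
#'
#' Same-direction qualifying windows merge when their window starts differ
#' by fewer than `window_cpgs + merge_gap_cpgs` CpGs; with the default
#' `merge_gap_cpgs = Inf` all same-direction qualifying windows of the
#' promoter merge (the 2.7 kb promoter is treated as one regulatory unit,
#' so a pair yields at most one hyper- and one hypo-methylated region per
#' promoter), while `merge_gap_cpgs = 0` restricts merging to windows that
#' share a site. Each merged run becomes one DMR spanning its first to
#' last direction-supporting site; opposite directions never merge.
#'
#' @param sites data frame for one promoter, position-ordered: pos,
#'   delta_beta, and m_t/u_t/m_n/u_n counts (`method = "pooled"`) or
#'   q_value (`method = "site_count"`).
#' @param window_cpgs,step_cpgs window size and step, in CpGs.
#' @param min_sig minimum direction-supporting (pooled) or individually
#'   significant (site_count) sites per window.
#' @param min_mean_delta minimum |delta_beta| of the window (pooled) or of
#'   its significant sites (site_count).
#' @param merge_gap_cpgs merge tolerance between qualifying windows, in
#'   window starts (default `Inf`: promoter-wide same-direction merge).
#' @param fdr window-level (pooled) or site-level (site_count) q cutoff.
#' @param site_delta minimum per-site |delta_beta|.
#' @param method `"pooled"` or `"site_count"`.
#' @param window_q optional precomputed q-values for this promoter's
#'   windows (pooled method; supplied by [detect_dmrs()] after pair-wide
#'   BH adjustment).
#' @param delta_conf confidence level at which the pooled window delta
#'   must exceed `min_mean_delta` (pooled method): the lower Wald
#'   confidence bound of the signed difference is compared against the
#'   threshold, which blocks windows whose observed delta is inflated by
#'   selection over many overlapping windows.
#' @return A data frame of calls: start, end (0-based half-open span of
#'   supporting sites), direction, n_cpgs, mean_delta_beta, min_q.
#' @export
sliding_window_dmrs <- function(sites, window_cpgs = 5L, step_cpgs = 1L,
                                min_sig = 3L, min_mean_delta = 0.1,
                                merge_gap_cpgs = Inf, fdr = 0.05,
                                site_delta = 0.05,
                                method = c("pooled", "site_count"),
                                window_q = NULL, delta_conf = 0.95) {
  method <- match.arg(method)
  empty <- data.frame(start = integer(0), end = integer(0),
                      direction = character(0), n_cpgs = integer(0),
                      mean_delta_beta = numeric(0), min_q = numeric(0))
  n <- nrow(sites)
  if (n < window_cpgs) return(empty)
  stopifnot(!is.unsorted(sites$pos))
  starts <- seq.int(1L, n - window_cpgs + 1L, by = step_cpgs)
  ends <- starts + window_cpgs - 1L
  wsum <- function(v) { cv <- cumsum(v); cv[ends] - c(0, cv)[starts] }
  if (method == "pooled") {
    mt <- wsum(sites$m_t); ut <- wsum(sites$u_t)
    mn <- wsum(sites$m_n); un <- wsum(sites$u_n)
    nt <- mt + ut; nn <- mn + un
    bt <- mt / nt; bn <- mn / nn
    wdelta <- bt - bn
    # Wald SE of the pooled beta difference (0.5 continuity guard), used to
    # require the effect to exceed min_mean_delta with confidence -- the
    # observed delta alone is inflated by max-over-windows selection
    wse <- sqrt(((mt + 0.5) * (ut + 0.5) / (nt + 1)^3) +
                ((mn + 0.5) * (un + 0.5) / (nn + 1)^3))
    zconf <- stats::qnorm(1 - (1 - delta_conf) / 2)
    wq <- if (is.null(window_q))
      bh_adjust(fisher_exact_2x2(mt, ut, mn, un)) else window_q
    stopifnot(length(wq) == length(starts))
  }
  calls <- list()
  for (dir in c("hyper", "hypo")) {
    sgn <- if (dir == "hyper") 1 else -1
    support <- sgn * sites$delta_beta >= site_delta
    opposed <- -sgn * sites$delta_beta >= site_delta
    if (method == "site_count") {
      support <- support & sites$q_value < fdr
      opposed <- opposed & sites$q_value < fdr
    }
    if (sum(support) < min_sig) next
    cnt <- wsum(support)
    n_opp <- wsum(opposed)      # direction homogeneity within the window
    dsum <- wsum(ifelse(support, sites$delta_beta, 0))
    ok <- if (method == "pooled") {
      cnt >= min_sig & n_opp == 0 & wq < fdr &
        sgn * wdelta - zconf * wse >= min_mean_delta
    } else {
      cnt >= min_sig & n_opp == 0 &
        abs(dsum / pmax(cnt, 1L)) >= min_mean_delta
    }
    if (!any(ok)) next
    qs <- starts[ok]
    gap <- which(diff(qs) >= window_cpgs + merge_gap_cpgs)
    run_first <- qs[c(1L, gap + 1L)]
    run_last <- qs[c(gap, length(qs))]
    for (r in seq_along(run_first)) {
      idx <- run_first[r]:(run_last[r] + window_cpgs - 1L)
      sidx <- idx[support[idx]]
      min_q <- if (method == "pooled")
        min(wq[ok & starts >= run_first[r] & starts <= run_last[r]])
      else min(sites$q_value[sidx])
      calls[[length(calls) + 1L]] <- data.frame(
        start = sites$pos[min(sidx)], end = sites$pos[max(sidx)] + 2L,
        direction = dir, n_cpgs = length(sidx),
        mean_delta_beta = mean(sites$delta_beta[sidx]),
        min_q = min_q)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect promoter DMRs in every tumor/normal pair of a cohort
#'
#' For each pair: per-CpG exact tests over all promoter CpGs, BH adjustment
#' within the pair, then sliding-window calls within each promoter. With
#' the default `bh_scope = "promoter"` the BH correction is applied across
#' the CpGs of each promoter separately (each promoter is the unit of
#' inference, and at ~23x per-CpG depth a pooled correction across all
#' promoter CpGs of a pair leaves too little per-site power for region
#' calling); `bh_scope = "pair"` pools all of the pair's sites instead.
#'
#' @param profiles named list of per-sample coverage data frames.
#' @param manifest data frame with sample_id, patient_id, tissue ("T"/"N").
#' @param cpg_sites data frame mapping promoter CpGs to genes
#'   (gene_id, chrom, pos).
#' @param min_depth within-pair depth filter.
#' @param bh_scope `"promoter"` or `"pair"`: the site set over which the
#'   site-level BH is applied within each pair (`method = "site_count"`
#'   only; the pooled method adjusts window p-values per promoter).
#' @param method window qualification rule, see [sliding_window_dmrs()].
#' @param ... window parameters passed to [sliding_window_dmrs()].
#' @return A data frame of DMR calls with gene_id and pair_id columns.
#' @export
detect_dmrs <- function(profiles, manifest, cpg_sites, min_depth = 4L,
                        bh_scope = c("promoter", "pair"),
                        method = c("pooled", "site_count"), ...) {
  bh_scope <- match.arg(bh_scope)
  method <- match.arg(method)
  pairs <- split(manifest, manifest$patient_id)
  site_key <- paste(cpg_sites$chrom, cpg_sites$pos)
  out <- list()
  for (pid in names(pairs)) {
    pm <- pairs[[pid]]
    tid <- pm$sample_id[pm$tissue == "T"]
    nid <- pm$sample_id[pm$tissue == "N"]
    stopifnot(length(tid) == 1L, length(nid) == 1L)
    res <- if (method == "pooled")
      site_join(profiles[[tid]], profiles[[nid]], min_depth = min_depth)
    else site_test(profiles[[tid]], profiles[[nid]], min_depth = min_depth)
    if (nrow(res) == 0L) next
    res$gene_id <- cpg_sites$gene_id[match(paste(res$chrom, res$pos),
                                           site_key)]
    res <- res[!is.na(res$gene_id), , drop = FALSE]
    if (method == "site_count")
      res$q_value <- if (bh_scope == "pair") bh_adjust(res$p_value) else
        stats::ave(res$p_value, res$gene_id,
                   FUN = function(p) stats::p.adjust(p, method = "BH"))
    res <- res[order(res$gene_id, res$pos), , drop = FALSE]
    by_gene <- split(seq_len(nrow(res)), res$gene_id)
    window_q <- NULL
    if (method == "pooled") {
      # pair-wide BH over the pooled p-values of every promoter's windows;
      # windows never cross promoters, so all are computed in one pass
      args <- list(...)
      wc <- if (is.null(args$window_cpgs)) 5L else args$window_cpgs
      sc <- if (is.null(args$step_cpgs)) 1L else args$step_cpgs
      n_g <- lengths(by_gene)
      off <- cumsum(c(0L, n_g[-length(n_g)]))
      ok_g <- n_g >= wc
      starts_list <- lapply(which(ok_g), function(i)
        off[i] + seq.int(1L, n_g[i] - wc + 1L, by = sc))
      gs <- unlist(starts_list, use.names = FALSE)
      if (length(gs)) {
        ge <- gs + wc - 1L
        csum <- function(v) { cv <- cumsum(v); cv[ge] - c(0, cv)[gs] }
        wp <- fisher_exact_2x2(csum(res$m_t), csum(res$u_t),
                               csum(res$m_n), csum(res$u_n))
        window_q <- split(bh_adjust(wp),
                          rep(names(by_gene)[ok_g], lengths(starts_list)))
      }
    }
    for (g in names(by_gene)) {
      idx <- by_gene[[g]]
      sub <- structure(lapply(res, `[`, idx), class = "data.frame",
                       row.names = .set_row_names(length(idx)))
      calls <- sliding_window_dmrs(sub, method = method,
                                   window_q = window_q[[g]], ...)
      if (nrow(calls) > 0L) {
        calls$gene_id <- g
        calls$pair_id <- pid
        calls$chrom <- sub$chrom[1L]
        out[[length(out) + 1L]] <- calls
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      pair_id = character(0), direction = character(0),
                      n_cpgs = integer(0), mean_delta_beta = numeric(0),
                      min_q = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "gene_id", "pair_id", "direction",
          "n_cpgs", "mean_delta_beta", "min_q")]
}

#' Summarize DMR recurrence across pairs
#'
#' A gene counts in a pair when it has at least one and at most
#' `max_dmrs_per_pair` DMRs there (the "one or two DMRs" eligibility rule);
#' it is recurrent when it counts in `recurrence_min` or more pairs.
#'
#' @param calls DMR call table from [detect_dmrs()].
#' @param n_pairs number of pairs in the cohort.
#' @param recurrence_min minimum supporting pairs (default 6 of 8).
#' @param max_dmrs_per_pair per-pair DMR count cap for eligibility.
#' @return A data frame: gene_id, n_pairs_with_dmr, dominant_direction,
#'   direction_consistent, frac_hyper, recurrent; sorted by gene_id.
#' @export
summarize_recurrence <- function(calls, n_pairs, recurrence_min = 6L,
                                 max_dmrs_per_pair = 2L) {
  if (recurrence_min > n_pairs)
    abort("recurrence_min exceeds the number of pairs")
  genes <- sort(unique(calls$gene_id))
  rows <- lapply(genes, function(g) {
    sub <- calls[calls$gene_id == g, , drop = FALSE]
    per_pair <- table(sub$pair_id)
    eligible <- names(per_pair)[per_pair >= 1L & per_pair <= max_dmrs_per_pair]
    el <- sub[sub$pair_id %in% eligible, , drop = FALSE]
    n_hyper <- sum(el$direction == "hyper")
    n_hypo <- sum(el$direction == "hypo")
    dom <- if (n_hyper >= n_hypo) "hyper" else "hypo"
    data.frame(gene_id = g, n_pairs_with_dmr = length(eligible),
               dominant_direction = if (nrow(el)) dom else NA_character_,
               direction_consistent = n_hyper == 0L || n_hypo == 0L,
               frac_hyper = if (nrow(el)) n_hyper / (n_hyper + n_hypo)
                            else NA_real_,
               recurrent = length(eligible) >= recurrence_min)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_pairs_with_dmr = integer(0),
                      dominant_direction = character(0),
                      direction_consistent = logical(0),
                      frac_hyper = numeric(0), recurrent = logical(0))
  rownames(out) <- NULL
  out
}
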