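# Cohort-level statistics: bootstrap-supported hierarchical clustering,
# top-variable CpG-island selection, PCA, within-group variance comparison,
# paired validation tests, difference categories, and delta-delta-Ct.

#' Bootstrap-supported hierarchical clustering of samples
#'
#' Average-linkage clustering of sample profiles on 1 - Pearson correlation
#' (or Euclidean) distance, with bootstrap probability (BP) support per
#' internal edge: the fraction of feature-resampled trees that contain the
#' same leaf clade. AU (multiscale) support is deliberately not computed.
#'
#' @param x features x samples numeric matrix, complete cases only.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param n_boot number of bootstrap resamples of the feature rows.
#' @param seed optional seed making the bootstrap deterministic.
#' @return An object of class `cluster_tree`: `hclust`, `phylo` (ape),
#'   `bp` (per internal node, root first), `n_boot`, `distance`.
#' @export
cluster_samples <- function(x, distance = c("correlation", "euclidean"),
                            n_boot = 100L, seed = NULL) {
  distance <- match.arg(distance)
  if (any(is.na(x))) abort("missing values: complete cases required upstream")
  if (ncol(x) < 3L) abort("need at least 3 samples to cluster")
  if (n_boot < 100L) warning("BP support estimated from fewer than 100 resamples")
  dist_fun <- function(m) {
    d <- if (distance == "correlation") stats::as.dist(1 - stats::cor(m))
         else stats::dist(t(m))
    d[is.na(d)] <- 2
    d
  }
  hc <- stats::hclust(dist_fun(x), method = "average")
  phy <- ape::as.phylo(hc)
  run_boot <- function() {
    lapply(seq_len(n_boot), function(b) {
      rows <- sample.int(nrow(x), nrow(x), replace = TRUE)
      ape::as.phylo(stats::hclust(dist_fun(x[rows, , drop = FALSE]),
                                  method = "average"))
    })
  }
  boots <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(phy, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  structure(list(hclust = hc, phylo = phy, bp = counts / n_boot,
                 n_boot = n_boot, distance = distance),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d samples, %s distance, BP from %d resamples\n",
              length(x$phylo$tip.label), x$distance, x$n_boot))
  invisible(x)
}

#' Bootstrap support of the clade containing exactly the given samples
#'
#' @param tree a `cluster_tree`.
#' @param leaves character vector of sample names.
#' @return The clade's BP fraction, or `NA` if no internal node has exactly
#'   this leaf set.
#' @export
clade_support <- function(tree, leaves) {
  stopifnot(inherits(tree, "cluster_tree"))
  pp <- ape::prop.part(tree$phylo)
  labs <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    if (setequal(labs[pp[[i]]], leaves)) return(tree$bp[i])
  }
  NA_real_
}

#' Write a cluster tree as Newick with BP edge labels
#'
#' @param tree a `cluster_tree`.
#' @param path output path.
#' @export
write_cluster_newick <- function(tree, path) {
  phy <- tree$phylo
  phy$node.label <- formatC(tree$bp, format = "f", digits = 3)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Rank CpG islands (or any regions) by cross-sample methylation variability
#'
#' Per region, a chi-square statistic of homogeneity of the methylation
#' proportion across all samples is computed from the 2 x n_samples table of
#' summed methylated/unmethylated counts; regions are ranked by ascending
#' p-value (ties: descending statistic, then region id) and the top `k`
#' returned.
#'
#' @param meth_counts,total_counts regions x samples matrices of methylated
#'   and total read counts (matching dimnames).
#' @param k number of regions to return (default 1000).
#' @return A data frame: region, statistic, df, p_value, rank.
#' @export
top_variable_regions <- function(meth_counts, total_counts, k = 1000L) {
  stopifnot(all(dim(meth_counts) == dim(total_counts)),
            all(meth_counts <= total_counts))
  ids <- rownames(meth_counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(meth_counts)))
  s <- ncol(meth_counts)
  u <- total_counts - meth_counts
  tot <- rowSums(total_counts)
  phat <- ifelse(tot > 0, rowSums(meth_counts) / tot, 0)
  em <- phat * total_counts
  eu <- (1 - phat) * total_counts
  stat <- rowSums(ifelse(em > 0, (meth_counts - em)^2 / em, 0)) +
    rowSums(ifelse(eu > 0, (u - eu)^2 / eu, 0))
  p <- stats::pchisq(stat, df = s - 1L, lower.tail = FALSE)
  if (k > length(ids)) {
    warning("k exceeds the number of regions; returning all")
    k <- length(ids)
  }
  ord <- order(p, -stat, ids)
  out <- data.frame(region = ids[ord], statistic = stat[ord],
                    df = s - 1L, p_value = p[ord])[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Principal component analysis of sample profiles
#'
#' SVD of the feature-centered matrix; sample scores and explained-variance
#' fractions. Sign convention: the largest-magnitude feature loading of each
#' component is made positive.
#'
#' @param x features x samples numeric matrix, complete cases only.
#' @param n_components number of components to return.
#' @return A list: `scores` (samples x components), `explained_variance`
#'   (fractions), `loadings` (features x components).
#' @export
pca_samples <- function(x, n_components = 2L) {
  if (any(is.na(x))) abort("missing values: complete cases required upstream")
  xc <- x - rowMeans(x)
  sv <- svd(t(xc))
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1L])
  if (n_components > rank)
    abort("n_components (", n_components, ") exceeds the matrix rank (",
          rank, ")")
  idx <- seq_len(n_components)
  flip <- vapply(idx, function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx],
                                                     n_components), 2, flip, "*")
  loadings <- sweep(sv$v[, idx, drop = FALSE], 2, flip, "*")
  dimnames(scores) <- list(colnames(x), paste0("PC", idx))
  dimnames(loadings) <- list(rownames(x), paste0("PC", idx))
  list(scores = scores,
       explained_variance = sv$d[idx]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Compare within-group methylation variance between tumors and normals
#'
#' Per feature, the variance of beta within the tumor group and within the
#' normal group; the global summary is the fraction of features with larger
#' tumor variance (constant features excluded) plus a two-sided sign-test
#' p-value on that fraction. When methylated/total count matrices are
#' supplied, the per-feature chi-square homogeneity statistic within each
#' group is reported alongside.
#'
#' @param beta features x samples beta matrix.
#' @param tumor_ids,normal_ids column names of the two groups (>= 2 each).
#' @param meth_counts,total_counts optional count matrices for the
#'   within-group chi-square statistics.
#' @return A list: `per_feature` data frame, `fraction_tumor_greater`,
#'   `sign_test_p`, `n_compared`.
#' @export
group_variance_test <- function(beta, tumor_ids, normal_ids,
                                meth_counts = NULL, total_counts = NULL) {
  if (length(tumor_ids) < 2L || length(normal_ids) < 2L)
    abort("both groups need at least 2 samples")
  vt <- apply(beta[, tumor_ids, drop = FALSE], 1, stats::var)
  vn <- apply(beta[, normal_ids, drop = FALSE], 1, stats::var)
  per <- data.frame(var_tumor = vt, var_normal = vn)
  if (!is.null(meth_counts) && !is.null(total_counts)) {
    chisq_grp <- function(ids) {
      top_variable_regions(meth_counts[, ids, drop = FALSE],
                           total_counts[, ids, drop = FALSE],
                           k = nrow(meth_counts))
    }
    ct <- chisq_grp(tumor_ids); cn <- chisq_grp(normal_ids)
    per$chisq_tumor <- ct$statistic[match(rownames(per), ct$region)]
    per$chisq_normal <- cn$statistic[match(rownames(per), cn$region)]
  }
  informative <- !(vt == 0 & vn == 0) & vt != vn
  n_greater <- sum(vt[informative] > vn[informative])
  n_comp <- sum(informative)
  list(per_feature = per,
       fraction_tumor_greater = if (n_comp > 0) n_greater / n_comp else NA_real_,
       sign_test_p = if (n_comp > 0)
         stats::binom.test(n_greater, n_comp, 0.5)$p.value else NA_real_,
       n_compared = n_comp)
}

#' Student's paired t-test on per-pair beta values
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = beta_T - beta_N` and
#' `df = n - 1`; two-sided p. A zero-variance difference vector yields an
#' undefined-statistic flag rather than an error.
#'
#' @param beta_tumor,beta_normal equal-length paired vectors (n >= 3).
#' @return A list: t_statistic, df, p_value, mean_delta, undefined.
#' @export
paired_t_test <- function(beta_tumor, beta_normal) {
  if (length(beta_tumor) != length(beta_normal))
    abort("paired vectors must have equal length")
  if (length(beta_tumor) < 3L) abort("need at least 3 pairs")
  d <- beta_tumor - beta_normal
  if (stats::sd(d) == 0)
    return(list(t_statistic = NA_real_, df = length(d) - 1L,
                p_value = NA_real_, mean_delta = mean(d), undefined = TRUE))
  tt <- stats::t.test(beta_tumor, beta_normal, paired = TRUE)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_delta = mean(d), undefined = FALSE)
}

#' Bin per-pair absolute methylation differences into categories
#'
#' Right-open bins `[0, 0.05)`, `[0.05, 0.1)`, `[0.1, 0.2)` and the closed
#' top bin `[0.2, 1]` by default; counts sum to the number of pairs.
#'
#' @param values per-pair |delta beta| values in [0, 1].
#' @param cuts interior cut points.
#' @return Named integer vector of category counts.
#' @export
categorize_differences <- function(values, cuts = c(0.05, 0.1, 0.2)) {
  if (any(is.na(values)) || any(values < 0 | values > 1))
    abort("values must lie in [0, 1]")
  bins <- findInterval(values, cuts)
  labels <- c(sprintf("[%g,%g)", c(0, cuts[-length(cuts)]), cuts),
              sprintf("[%g,1]", cuts[length(cuts)]))
  counts <- tabulate(bins + 1L, nbins = length(cuts) + 1L)
  stats::setNames(as.integer(counts), labels)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target_T - Ct_ref_T) - (Ct_target_N - Ct_ref_N)`;
#' ratio = `2^(-ddCt)`. Vectors (e.g. triplicates) are averaged per
#' condition first. The reference gene is typically GAPDH.
#'
#' @param ct_target_t,ct_ref_t,ct_target_n,ct_ref_n positive Ct values
#'   (scalars or replicate vectors).
#' @return A list: delta_delta_ct, ratio.
#' @export
delta_delta_ct <- function(ct_target_t, ct_ref_t, ct_target_n, ct_ref_n) {
  vals <- c(ct_target_t, ct_ref_t, ct_target_n, ct_ref_n)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("Ct values must be positive reals")
  ddct <- (mean(ct_target_t) - mean(ct_ref_t)) -
    (mean(ct_target_n) - mean(ct_ref_n))
  list(delta_delta_ct = ddct, ratio = 2^(-ddct))
}

#' Per-gene paired validation statistics for a large cohort
#'
#' For each gene amplicon: paired t-test of tumor vs normal beta across
#' pairs, the mean within-pair difference, and the difference-category
#' counts of [categorize_differences()].
#'
#' @param beta genes x samples matrix of amplicon mean betas.
#' @param manifest data frame with sample_id, patient_id, tissue.
#' @param cuts category cut points.
#' @return A data frame: gene_id, n_pairs, mean_delta_beta, t_statistic,
#'   p_value, one count column per category.
#' @export
validate_cohort <- function(beta, manifest, cuts = c(0.05, 0.1, 0.2)) {
  tum <- manifest$sample_id[manifest$tissue == "T"]
  nor <- manifest$sample_id[manifest$tissue == "N"]
  stopifnot(length(tum) == length(nor))
  ord <- match(manifest$patient_id[manifest$tissue == "T"],
               manifest$patient_id[manifest$tissue == "N"])
  nor <- nor[ord]
  rows <- lapply(rownames(beta), function(g) {
    bt <- beta[g, tum]; bn <- beta[g, nor]
    tt <- paired_t_test(bt, bn)
    cats <- categorize_differences(pmin(abs(bt - bn), 1), cuts)
    cbind(data.frame(gene_id = g, n_pairs = length(bt),
                     mean_delta_beta = tt$mean_delta,
                     t_statistic = tt$t_statistic, p_value = tt$p_value),
          as.data.frame(as.list(cats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
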