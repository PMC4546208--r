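# Methylation core: bismark-coverage-style IO, beta/M values, depth
# filtering into a cross-sample site matrix, and promoter-level means.
# Internal coordinates are 0-based; the coverage dialect on disk is 1-based
# inclusive.

#' Read a bismark-coverage-style TSV of per-CpG counts
#'
#' Expects six whitespace/tab-separated columns: chrom, start (1-based),
#' end (1-based, equal to start), percent methylation, methylated count,
#' unmethylated count. Positions are converted to 0-based. Strand-split
#' records of one CpG -- the C on the plus strand at position p and the G
#' on the minus strand at p+1 -- are merged into a single record at p by
#' summing counts.
#'
#' @param path file path.
#' @return A data frame: chrom, pos (0-based C position), count_M, count_U.
#' @export
read_coverage_tsv <- function(path) {
  if (!file.exists(path)) abort("coverage file not found: ", path)
  lines <- readLines(path)
  out <- data.frame(chrom = character(0), pos = integer(0),
                    count_M = integer(0), count_U = integer(0))
  if (length(lines) == 0L) return(out)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(bad <- nf != 6L))
    abort("parse error: expected 6 fields at line(s) ",
          paste(which(bad), collapse = ", "), " of ", path)
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  cm <- suppressWarnings(as.numeric(m[, 5L]))
  cu <- suppressWarnings(as.numeric(m[, 6L]))
  bad <- is.na(start) | is.na(end) | is.na(cm) | is.na(cu) |
    cm < 0 | cu < 0 | cm != floor(cm) | cu != floor(cu)
  if (any(bad))
    abort("parse error: non-numeric or negative fields at line(s) ",
          paste(which(bad), collapse = ", "), " of ", path)
  if (any(bad <- end != start))
    abort("parse error: end != start (dialect violation) at line(s) ",
          paste(which(bad), collapse = ", "), " of ", path)
  df <- data.frame(chrom = m[, 1L], pos = as.integer(start) - 1L,
                   count_M = as.integer(cm), count_U = as.integer(cu))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  # merge plus-strand C record at p with minus-strand G record at p+1
  same <- c(df$chrom[-1L] == df$chrom[-nrow(df)], FALSE)
  adj <- c(df$pos[-1L] - df$pos[-nrow(df)] == 1L, FALSE)
  is_g <- rep(FALSE, nrow(df))
  i <- 1L
  while (i < nrow(df)) {                 # greedy left-to-right pairing
    if (same[i] && adj[i] && !is_g[i]) {
      is_g[i + 1L] <- TRUE
      df$count_M[i] <- df$count_M[i] + df$count_M[i + 1L]
      df$count_U[i] <- df$count_U[i] + df$count_U[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  df <- df[!is_g, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write per-CpG counts in the bismark-coverage dialect
#'
#' @param df data frame with chrom, pos (0-based), count_M, count_U.
#' @param path output path.
#' @export
write_coverage_tsv <- function(df, path) {
  depth <- df$count_M + df$count_U
  pct <- ifelse(depth > 0, 100 * df$count_M / depth, 0)
  utils::write.table(
    data.frame(df$chrom, df$pos + 1L, df$pos + 1L,
               formatC(pct, format = "fg", digits = 10), df$count_M,
               df$count_U),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Beta and M values from methylated/unmethylated counts
#'
#' beta = count_M / (count_M + count_U);
#' M = log2((beta + eps) / (1 - beta + eps)) with eps = 0.01 to avoid
#' infinities at fully (un)methylated sites.
#'
#' @param count_M,count_U non-negative count vectors.
#' @param eps M-value stabilizer.
#' @return A data frame with columns beta and m_value.
#' @export
methylation_ratio <- function(count_M, count_U, eps = 0.01) {
  depth <- count_M + count_U
  if (any(depth <= 0))
    abort("undefined methylation value at zero depth; filter such sites first")
  beta <- count_M / depth
  data.frame(beta = beta, m_value = beta_to_m(beta, eps))
}

#' @rdname methylation_ratio
#' @param beta beta values in [0, 1].
#' @export
beta_to_m <- function(beta, eps = 0.01) log2((beta + eps) / (1 - beta + eps))

#' Build a cross-sample site matrix under a depth filter
#'
#' In `all_samples` mode only sites covered at depth >= `min_depth` in every
#' sample are retained (the common-site matrix); in `per_sample` mode sites
#' are dropped independently within each sample (entries become NA) and a
#' site is kept while it survives in at least one sample.
#'
#' @param profiles named list of per-sample coverage data frames
#'   (chrom, pos, count_M, count_U).
#' @param min_depth minimum depth; sites at exactly `min_depth` are kept.
#' @param mode `"all_samples"` or `"per_sample"`.
#' @return An object of class `meth_matrix`: `sites` (chrom, pos),
#'   `samples`, `beta` and `depth` matrices (sites x samples).
#' @export
filter_by_depth <- function(profiles, min_depth = 4L,
                            mode = c("all_samples", "per_sample")) {
  mode <- match.arg(mode)
  stopifnot(min_depth >= 1, length(profiles) >= 1,
            !is.null(names(profiles)), !anyDuplicated(names(profiles)))
  keys <- lapply(profiles, function(p) paste(p$chrom, p$pos))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  ord <- order(sub(" .*", "", all_keys),
               as.integer(sub(".* ", "", all_keys)))
  all_keys <- all_keys[ord]
  ns <- length(profiles)
  depth <- beta <- matrix(NA_real_, length(all_keys), ns,
                          dimnames = list(NULL, names(profiles)))
  for (j in seq_len(ns)) {
    p <- profiles[[j]]
    idx <- match(keys[[j]], all_keys)
    d <- p$count_M + p$count_U
    depth[idx, j] <- d
    beta[idx, j] <- ifelse(d > 0, p$count_M / d, NA_real_)
  }
  pass <- !is.na(depth) & depth >= min_depth
  keep <- if (mode == "all_samples") rowSums(pass) == ns else rowSums(pass) > 0
  if (!any(keep)) {
    warning("no site passes the depth filter; returning an empty matrix")
  }
  beta[!pass] <- NA_real_
  depth[!pass] <- NA_real_
  sites <- data.frame(chrom = sub(" .*", "", all_keys[keep]),
                      pos = as.integer(sub(".* ", "", all_keys[keep])))
  out <- list(sites = sites, samples = names(profiles),
              beta = beta[keep, , drop = FALSE],
              depth = depth[keep, , drop = FALSE])
  attr(out, "n_retained") <- sum(keep)
  attr(out, "min_depth") <- min_depth
  attr(out, "mode") <- mode
  class(out) <- "meth_matrix"
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d sites x %d samples (min_depth %s, %s mode)\n",
              nrow(x$beta), length(x$samples), attr(x, "min_depth"),
              attr(x, "mode")))
  invisible(x)
}

#' Mean promoter methylation per sample
#'
#' Unweighted mean of site-level beta over the retained sites inside the
#' chosen window of each promoter: the full -2200/+500 promoter, or the
#' 500 bp immediately downstream of the TSS (strand-aware). Promoters with
#' no retained site yield NA (propagated, not an error).
#'
#' @param mat a `meth_matrix` from [filter_by_depth()].
#' @param promoters promoter table from [promoter_from_tss()].
#' @param window `"full_promoter"` or `"tss_downstream_500"`.
#' @return Genes x samples matrix of mean betas.
#' @export
promoter_mean_beta <- function(mat, promoters,
                               window = c("full_promoter",
                                          "tss_downstream_500")) {
  window <- match.arg(window)
  stopifnot(inherits(mat, "meth_matrix"))
  if (window == "tss_downstream_500") {
    start <- ifelse(promoters$strand == "+", promoters$tss,
                    promoters$tss - 500L)
    end <- start + 500L
  } else {
    start <- promoters$start
    end <- promoters$end
  }
  out <- matrix(NA_real_, nrow(promoters), length(mat$samples),
                dimnames = list(promoters$gene_id, mat$samples))
  for (i in seq_len(nrow(promoters))) {
    in_win <- mat$sites$chrom == promoters$chrom[i] &
      mat$sites$pos >= start[i] & mat$sites$pos < end[i]
    if (any(in_win))
      out[i, ] <- colMeans(mat$beta[in_win, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}
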