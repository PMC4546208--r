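# Independent oracle implementations used across the test suite. These are
# deliberately written in a different style (explicit loops, closed forms,
# stats::fisher.test) from the package code they check.

# Hypergeometric pmf from log binomial coefficients (no dhyper).
oracle_hyper_pmf <- function(x, white, black, drawn) {
  exp(lchoose(white, x) + lchoose(black, drawn - x) -
        lchoose(white + black, drawn))
}

# Two-sided Fisher p by full enumeration of the table's support.
oracle_fisher_p <- function(a, b, c, d) {
  white <- a + c; black <- b + d; drawn <- a + b
  xs <- max(0, drawn - black):min(drawn, white)
  dens <- oracle_hyper_pmf(xs, white, black, drawn)
  obs <- dens[xs == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Definition-based BH step-up: sort, scale, cumulative minimum from the
# right, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# Vectorized enumeration oracle for the two-sided Fisher test: flattens
# every table's full support and sums log-binomial-coefficient densities
# (no dhyper/phyper, no tail decomposition).
oracle_fisher_enum_vec <- function(a, b, c, d) {
  white <- a + c; black <- b + d; drawn <- a + b
  lo <- pmax(0, drawn - black); hi <- pmin(drawn, white)
  len <- hi - lo + 1
  grp <- rep.int(seq_along(len), len)
  x <- sequence(len, from = lo)
  W <- rep.int(white, len); B <- rep.int(black, len)
  D <- rep.int(drawn, len)
  dens <- exp(lchoose(W, x) + lchoose(B, D - x) - lchoose(W + B, D))
  obs <- exp(lchoose(white, a) + lchoose(black, drawn - a) -
               lchoose(white + black, drawn))
  keep <- dens <= rep.int(obs, len) * (1 + 1e-7)
  pmin(rowsum(dens * keep, grp, reorder = FALSE)[, 1L], 1)
}

# Two-sided exact binomial p by enumeration.
oracle_binom_p <- function(x, n, p0) {
  if (n == 0) return(1)
  dens <- stats::dbinom(0:n, n, p0)
  sum(dens[dens <= dens[x + 1] * (1 + 1e-7)])
}

# Brute-force sliding-window DMR caller mirroring the declared
# qualification and merge rules, with stats::fisher.test for pooled
# window p-values and explicit per-window loops.
oracle_sliding_dmrs <- function(sites, window_cpgs = 5, step_cpgs = 1,
                                min_sig = 3, min_mean_delta = 0.1,
                                merge_gap_cpgs = Inf, fdr = 0.05,
                                site_delta = 0.05, method = "pooled") {
  n <- nrow(sites)
  empty <- data.frame(start = integer(0), end = integer(0),
                      direction = character(0), n_cpgs = integer(0),
                      mean_delta_beta = numeric(0), min_q = numeric(0))
  if (n < window_cpgs) return(empty)
  starts <- seq(1, n - window_cpgs + 1, by = step_cpgs)
  if (method == "pooled") {
    wp <- numeric(length(starts)); wd <- numeric(length(starts))
    wse <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + window_cpgs - 1)
      mt <- sum(sites$m_t[idx]); ut <- sum(sites$u_t[idx])
      mn <- sum(sites$m_n[idx]); un <- sum(sites$u_n[idx])
      wp[k] <- stats::fisher.test(matrix(c(mt, ut, mn, un), 2,
                                         byrow = TRUE))$p.value
      wd[k] <- mt / (mt + ut) - mn / (mn + un)
      wse[k] <- sqrt((mt + .5) * (ut + .5) / (mt + ut + 1)^3 +
                       (mn + .5) * (un + .5) / (mn + un + 1)^3)
    }
    wq <- oracle_bh(wp)
  }
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sgn <- if (dir == "hyper") 1 else -1
    support <- sgn * sites$delta_beta >= site_delta
    opposed <- -sgn * sites$delta_beta >= site_delta
    if (method == "site_count") {
      support <- support & sites$q_value < fdr
      opposed <- opposed & sites$q_value < fdr
    }
    qual <- logical(length(starts))
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + window_cpgs - 1)
      ns <- sum(support[idx])
      if (any(opposed[idx])) next
      if (method == "pooled") {
        qual[k] <- ns >= min_sig && wq[k] < fdr &&
          sgn * wd[k] - stats::qnorm(0.975) * wse[k] >= min_mean_delta
      } else {
        qual[k] <- ns >= min_sig &&
          abs(mean(sites$delta_beta[idx][support[idx]])) >= min_mean_delta
      }
    }
    if (!any(qual)) next
    qs <- starts[qual]
    runs <- list(); cur <- c(qs[1])
    for (q2 in qs[-1]) {
      if (q2 - cur[length(cur)] < window_cpgs + merge_gap_cpgs)
        cur <- c(cur, q2)
      else { runs[[length(runs) + 1]] <- cur; cur <- c(q2) }
    }
    runs[[length(runs) + 1]] <- cur
    for (r in runs) {
      idx <- min(r):(max(r) + window_cpgs - 1)
      sidx <- idx[support[idx]]
      mq <- if (method == "pooled")
        min(wq[qual & starts >= min(r) & starts <= max(r)])
      else min(sites$q_value[sidx])
      out[[length(out) + 1]] <- data.frame(
        start = sites$pos[min(sidx)], end = sites$pos[max(sidx)] + 2L,
        direction = dir, n_cpgs = length(sidx),
        mean_delta_beta = mean(sites$delta_beta[sidx]), min_q = mq)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$direction), ]
  rownames(res) <- NULL
  res
}

# Position-list-based promoter classifier: window counts obtained by
# binary search (findInterval) over sorted base-position vectors, not
# cumulative sums.
oracle_classify <- function(seq, width = 500) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  pc <- which(x == "C"); pg <- which(x == "G"); pn <- which(x == "N")
  pcg <- which(x[-n] == "C" & x[-1] == "G")
  s <- 1:(n - width + 1); e <- s + width - 1
  count_in <- function(pos, a, b)
    findInterval(b, pos) - findInterval(a - 1, pos)
  nN <- count_in(pn, s, e)
  nC <- count_in(pc, s, e); nG <- count_in(pg, s, e)
  nCG <- count_in(pcg, s, e - 1)
  usable <- nN <= 0.1 * width
  if (!any(usable)) stop("all windows N-rich")
  gc <- (nC + nG) / (width - nN)
  expd <- nC * nG / width
  ratio <- ifelse(expd > 0, nCG / expd, 0)
  gc <- gc[usable]; ratio <- ratio[usable]
  if (any(ratio >= 0.75 & gc >= 0.55)) "HCP"
  else if (all(ratio < 0.48)) "LCP"
  else "ICP"
}

# Rank-based AUC of scores against binary labels (Mann-Whitney form).
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}

# Small default config for fast unit-level cohorts.
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_pairs = 4L, n_genes = 40L, recurrence_fraction = 1,
             val_n_pairs = 20L, seed = seed, ...)
}
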