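# Promoter annotation: strand-aware TSS-anchored intervals, CpG-content
# statistics, CpG-island detection, and HCP/ICP/LCP promoter classification.
# All coordinates are 0-based half-open.

#' Build strand-aware promoter intervals around TSS positions
#'
#' A promoter spans -2200 bp to +500 bp around the TSS in the direction of
#' transcription: `[tss - 2200, tss + 500)` on the plus strand and the
#' mirrored `[tss - 500, tss + 2200)` on the minus strand (2700 bp either
#' way). Intervals running off the chromosome start (or past
#' `chrom_length`, if given) are clipped with a warning.
#'
#' @param gene_id,chrom,tss,strand equal-length vectors; `tss` is 0-based,
#'   `strand` one of `"+"`/`"-"`.
#' @param chrom_length optional chromosome length(s) for right clipping.
#' @return A data frame: gene_id, chrom, start, end, strand, tss.
#' @export
promoter_from_tss <- function(gene_id, chrom, tss, strand,
                              chrom_length = NULL) {
  if (any(!strand %in% c("+", "-")))
    abort("unknown strand symbol: ",
          paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  if (any(tss < 0)) abort("tss must be >= 0")
  start <- ifelse(strand == "+", tss - 2200L, tss - 500L)
  end <- start + 2700L
  if (any(start < 0)) {
    warning("clipping ", sum(start < 0), " promoter(s) at chromosome start")
    start <- pmax(start, 0L)
  }
  if (!is.null(chrom_length) && any(end > chrom_length)) {
    warning("clipping ", sum(end > chrom_length),
            " promoter(s) at chromosome end")
    end <- pmin(end, chrom_length)
  }
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, tss = as.integer(tss))
}

# Cumulative per-position indicators for fast sliding-window scans.
# Returns a list of cumsum vectors over the sequence's characters.
.seq_cumsums <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  isC <- x == "C"; isG <- x == "G"; isN <- x == "N"
  cg <- if (n > 1L) isC[-n] & isG[-1L] else logical(0)
  list(n = n, cC = cumsum(isC), cG = cumsum(isG), cN = cumsum(isN),
       cCG = cumsum(cg))
}

# Window stats for all step-1 windows of the given width.
# CG dinucleotides are counted when both bases fall inside the window.
.window_scan <- function(cs, width) {
  n <- cs$n
  if (n < width) return(NULL)
  s <- seq_len(n - width + 1L)          # 1-based window starts
  e <- s + width - 1L
  rng <- function(cum, a, b) cum[b] - c(0, cum)[a]
  nC <- rng(cs$cC, s, e); nG <- rng(cs$cG, s, e); nN <- rng(cs$cN, s, e)
  nCG <- rng(cs$cCG, s, pmin(e - 1L, n - 1L))
  data.frame(start = s - 1L, nC = nC, nG = nG, nN = nN, nCG = nCG)
}

#' CpG-content statistics of a sequence window
#'
#' Counts overlapping `CG` dinucleotides, GC fraction (N bases excluded from
#' both numerator and denominator), the expected CpG count
#' `(#C * #G) / window_length`, and the observed/expected CpG ratio
#' (defined as 0 when the expected count is 0).
#'
#' @param seq DNA string (ACGTN).
#' @param window optional 0-based half-open `c(start, end)`; default the
#'   whole sequence.
#' @return A list: gc_fraction, cpg_obs, cpg_expected, cpg_ratio, window.
#' @export
cpg_content <- function(seq, window = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (is.null(window)) window <- c(0L, n)
  if (window[2L] <= window[1L]) abort("empty window")
  if (window[1L] < 0 || window[2L] > n) abort("window outside sequence")
  sub <- substr(toupper(seq), window[1L] + 1L, window[2L])
  len <- nchar(sub)
  x <- strsplit(sub, "", fixed = TRUE)[[1L]]
  nC <- sum(x == "C"); nG <- sum(x == "G"); nN <- sum(x == "N")
  m <- gregexpr("CG", sub, fixed = TRUE)[[1L]]
  cpg_obs <- if (m[1L] == -1L) 0L else length(m)
  cpg_expected <- nC * nG / len
  list(gc_fraction = if (len > nN) (nC + nG) / (len - nN) else 0,
       cpg_obs = cpg_obs, cpg_expected = cpg_expected,
       cpg_ratio = if (cpg_expected > 0) cpg_obs / cpg_expected else 0,
       window = window)
}

#' Detect CpG islands by sliding-window scan
#'
#' Classical CpG-island criteria: windows of `width` bp (default 200,
#' step 1) qualifying with GC fraction >= `min_gc` and observed/expected
#' CpG ratio >= `min_ratio`; overlapping qualifying windows are merged into
#' maximal intervals.
#'
#' @param seq DNA string of length >= `width`.
#' @param min_gc,min_ratio,width island criteria (defaults 0.5, 0.6, 200).
#' @return A data frame of 0-based half-open intervals (start, end);
#'   zero rows when no island is found.
#' @export
detect_cgis <- function(seq, min_gc = 0.5, min_ratio = 0.6, width = 200L) {
  cs <- .seq_cumsums(seq)
  w <- .window_scan(cs, width)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.null(w)) return(empty)
  denom <- pmax(width - w$nN, 1L)
  gc <- (w$nC + w$nG) / denom
  expd <- w$nC * w$nG / width
  ratio <- ifelse(expd > 0, w$nCG / expd, 0)
  ok <- gc >= min_gc & ratio >= min_ratio
  if (!any(ok)) return(empty)
  starts <- w$start[ok]
  gap <- which(diff(starts) >= width)     # next window no longer overlaps
  first <- starts[c(1L, gap + 1L)]
  last <- starts[c(gap, length(starts))]
  data.frame(start = first, end = last + width)
}

#' Classify a promoter sequence by CpG content (HCP / ICP / LCP)
#'
#' Scans all 500-bp windows (step 1) of the promoter: HCP if any window has
#' CpG observed/expected ratio >= 0.75 and GC fraction >= 0.55; LCP if no
#' window reaches ratio >= 0.48; ICP otherwise. Windows with more than 10%
#' N are skipped.
#'
#' @param seq promoter DNA string (normally 2700 bp; >= 500 required).
#' @param width window size in bp.
#' @param hcp_ratio,hcp_gc,icp_ratio class thresholds.
#' @param max_n_frac maximum tolerated N fraction per window.
#' @return `"HCP"`, `"ICP"` or `"LCP"`.
#' @export
classify_promoter <- function(seq, width = 500L, hcp_ratio = 0.75,
                              hcp_gc = 0.55, icp_ratio = 0.48,
                              max_n_frac = 0.1) {
  if (nchar(seq) < width)
    abort("cannot classify: sequence shorter than ", width, " bp")
  cs <- .seq_cumsums(seq)
  w <- .window_scan(cs, width)
  usable <- w$nN <= max_n_frac * width
  if (!any(usable)) abort("cannot classify: all windows are N-rich")
  w <- w[usable, , drop = FALSE]
  gc <- (w$nC + w$nG) / (width - w$nN)
  expd <- w$nC * w$nG / width
  ratio <- ifelse(expd > 0, w$nCG / expd, 0)
  if (any(ratio >= hcp_ratio & gc >= hcp_gc)) "HCP"
  else if (all(ratio < icp_ratio)) "LCP"
  else "ICP"
}

#' Extract promoter sequences from a genome
#'
#' @param genome_seq named character vector of chromosome sequences.
#' @param promoters promoter table from [promoter_from_tss()].
#' @return Named character vector of promoter sequences (by gene_id).
#' @export
promoter_sequences <- function(genome_seq, promoters) {
  stopifnot(all(promoters$chrom %in% names(genome_seq)))
  out <- vapply(seq_len(nrow(promoters)), function(i)
    substr(genome_seq[[promoters$chrom[i]]],
           promoters$start[i] + 1L, promoters$end[i]), "")
  stats::setNames(out, promoters$gene_id)
}
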