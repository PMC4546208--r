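# Integration of recurrent promoter DMRs with recurrent DEGs into the
# candidate-gene list, classifying the methylation-expression relationship.

#' Match DMR genes to DEGs across pairs
#'
#' A gene is emitted when, in at least `min_pairs` pairs, it simultaneously
#' has a qualifying DMR (at least one and at most `max_dmrs_per_pair` DMRs
#' in the pair) and a significant DEG (`mode = "joint"`). Under
#' `mode = "independent"` the DMR and DEG support are counted separately
#' and both must reach `min_pairs`. The relationship is `negative` when
#' methylation and expression move in opposite directions (hyper & down, or
#' hypo & up), `positive` otherwise.
#'
#' @param dmr_calls per-pair DMR calls from [detect_dmrs()].
#' @param deg_calls per-pair DEG calls from [call_degs()].
#' @param min_pairs minimum supporting pairs (default 5 of 8).
#' @param max_dmrs_per_pair per-pair DMR eligibility cap.
#' @param mode `"joint"` (same-pair support) or `"independent"`.
#' @return A data frame of class `candidate_genes`: gene_id, meth_direction,
#'   expr_direction, relationship, n_pairs_supporting; sorted by decreasing
#'   support, then gene_id.
#' @export
match_dmr_deg <- function(dmr_calls, deg_calls, min_pairs = 5L,
                          max_dmrs_per_pair = 2L,
                          mode = c("joint", "independent")) {
  mode <- match.arg(mode)
  if (anyDuplicated(paste(deg_calls$gene_id, deg_calls$pair_id)))
    abort("duplicated gene ids within a pair in the DEG calls")
  sig_deg <- deg_calls[deg_calls$significant, , drop = FALSE]
  rows <- list()
  for (g in sort(intersect(unique(dmr_calls$gene_id), unique(sig_deg$gene_id)))) {
    dg <- dmr_calls[dmr_calls$gene_id == g, , drop = FALSE]
    per_pair <- table(dg$pair_id)
    dmr_pairs <- names(per_pair)[per_pair >= 1L & per_pair <= max_dmrs_per_pair]
    eg <- sig_deg[sig_deg$gene_id == g, , drop = FALSE]
    deg_pairs <- unique(eg$pair_id)
    support <- if (mode == "joint") intersect(dmr_pairs, deg_pairs)
               else if (length(dmr_pairs) >= min_pairs &&
                        length(deg_pairs) >= min_pairs) deg_pairs
               else character(0)
    n_sup <- if (mode == "joint") length(support)
             else min(length(dmr_pairs), length(deg_pairs))
    if (n_sup < min_pairs) next
    dsub <- dg[dg$pair_id %in% (if (mode == "joint") support else dmr_pairs), ]
    esub <- eg[eg$pair_id %in% (if (mode == "joint") support else deg_pairs), ]
    meth_dir <- if (sum(dsub$direction == "hyper") >=
                    sum(dsub$direction == "hypo")) "hyper" else "hypo"
    expr_dir <- if (sum(esub$direction == "up") >=
                    sum(esub$direction == "down")) "up" else "down"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, meth_direction = meth_dir, expr_direction = expr_dir,
      relationship = if ((meth_dir == "hyper" && expr_dir == "down") ||
                         (meth_dir == "hypo" && expr_dir == "up"))
        "negative" else "positive",
      n_pairs_supporting = as.integer(n_sup))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), meth_direction = character(0),
               expr_direction = character(0), relationship = character(0),
               n_pairs_supporting = integer(0))
  out <- out[order(-out$n_pairs_supporting, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}

#' Retain candidates with an inverse methylation-expression relationship
#'
#' Keeps `relationship == "negative"` candidates only and records the
#' hyper-/hypo-methylated split as attributes.
#'
#' @param candidates output of [match_dmr_deg()].
#' @return The filtered candidate table, with attributes `n_hyper` and
#'   `n_hypo`.
#' @export
filter_negative <- function(candidates) {
  out <- candidates[candidates$relationship == "negative", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hyper") <- sum(out$meth_direction == "hyper")
  attr(out, "n_hypo") <- sum(out$meth_direction == "hypo")
  out
}
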