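# Candidate-gene prioritization: the 3-criterion conjunction (Pol II up in
# the cancer line within 5 kb, H3K27me3 up in the normal line within 5 kb,
# expression up >= 3-fold), and the ddCt qPCR statistics used to validate
# candidates.

min_distance_to_islands <- function(gene, islands) {
  if (nrow(islands) == 0)
    return(list(distance = Inf, idx = NA_integer_))
  d <- interval_distance(gene$chrom, gene$start, gene$end,
                         islands$chrom, islands$start, islands$end)
  i <- which.min(d)
  list(distance = d[i], idx = i)
}

#' Select candidate genes by the 3-criterion epigenome/transcriptome rule
#'
#' A gene qualifies iff (i) its gene body lies within `window_bp` of a
#' Pol II differential island increased in the cancer line with fold >=
#' `fc`, (ii) within `window_bp` of an H3K27me3 differential island
#' increased in the normal line (i.e. decreased in the cancer line with
#' 1/fold >= `fc`), and (iii) it is called up in expression with fold >=
#' `fc` (the DE FDR gate is inherited from the `de_call` when
#' `require_fdr = TRUE`; otherwise only the fold gate applies).
#'
#' Differential islands are expected in the cancer-vs-normal orientation
#' (sample A = cancer), as produced by [differential_islands()].
#'
#' @param de_records output of [call_de()].
#' @param diff_polII,diff_k27 differential islands for Pol II and H3K27me3.
#' @param genes gene models.
#' @param window_bp proximity window (distance 0 means overlap/adjacent).
#' @param fc fold threshold shared by all three criteria.
#' @param require_fdr condition criterion (iii) on the DE call (FDR gate).
#' @return data.frame of candidates sorted by expression fold change
#'   descending: gene_id, expression_fc, polII_distance, polII_fold,
#'   k27_distance, k27_fold, met_polII, met_k27, met_expression; attribute
#'   `all_genes` holds the same columns for every assessed gene.
#' @export
select_candidates <- function(de_records, diff_polII, diff_k27, genes,
                              window_bp = 5000, fc = 3, require_fdr = TRUE) {
  pol_up <- diff_polII[diff_polII$direction == "increased" &
                       diff_polII$fold_change >= fc, , drop = FALSE]
  k27_up_normal <- diff_k27[diff_k27$direction == "decreased" &
                            1 / diff_k27$fold_change >= fc, , drop = FALSE]
  idx <- match(de_records$gene_id, genes$gene_id)
  rows <- lapply(seq_len(nrow(de_records)), function(i) {
    g <- genes[idx[i], ]
    dp <- min_distance_to_islands(g, pol_up)
    dk <- min_distance_to_islands(g, k27_up_normal)
    expr_ok <- de_records$fold_change[i] >= fc &&
      (!require_fdr || de_records$de_call[i] == "up")
    data.frame(gene_id = de_records$gene_id[i],
               expression_fc = de_records$fold_change[i],
               polII_distance = dp$distance,
               polII_fold = if (is.na(dp$idx)) NA_real_ else
                 pol_up$fold_change[dp$idx],
               k27_distance = dk$distance,
               k27_fold = if (is.na(dk$idx)) NA_real_ else
                 k27_up_normal$fold_change[dk$idx],
               met_polII = dp$distance <= window_bp,
               met_k27 = dk$distance <= window_bp,
               met_expression = expr_ok,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  cand <- all[all$met_polII & all$met_k27 & all$met_expression, , drop = FALSE]
  cand <- cand[order(-cand$expression_fc, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "all_genes") <- all
  cand
}

#' Relative expression by the ddCt method
#'
#' Technical replicates are averaged per (sample, assay); dCq = Cq_target -
#' mean(Cq of the two housekeeping assays) (the arithmetic mean of Cq is the
#' geometric mean of the linear quantities); relative expression =
#' `2^-(dCq - mean dCq of the reference group)`, so the reference group
#' averages to 1 on the log scale. Samples missing any required Cq are
#' dropped with a message.
#'
#' @param cq_table long data.frame sample/group/assay/replicate/cq.
#' @param target target assay name.
#' @param housekeeping_pair exactly two housekeeping assay names.
#' @param reference_group group used as the expression baseline.
#' @return data.frame sample/group/rel_expr.
#' @export
ddct <- function(cq_table, target, housekeeping_pair, reference_group) {
  stopifnot(length(housekeeping_pair) == 2)
  need <- c(target, housekeeping_pair)
  x <- cq_table[cq_table$assay %in% need & !is.na(cq_table$cq), , drop = FALSE]
  mean_cq <- stats::aggregate(cq ~ sample + group + assay, data = x, FUN = mean)
  wide <- stats::reshape(mean_cq, idvar = c("sample", "group"),
                         timevar = "assay", direction = "wide")
  cq_cols <- paste0("cq.", need)
  complete <- stats::complete.cases(wide[intersect(cq_cols, names(wide))]) &
    all(cq_cols %in% names(wide))
  if (any(!complete) || !all(cq_cols %in% names(wide))) {
    if (!all(cq_cols %in% names(wide)))
      stop("missing assay(s): ",
           paste(setdiff(need, mean_cq$assay), collapse = ", "))
    message(sum(!complete), " sample(s) dropped for missing Cq")
    wide <- wide[complete, , drop = FALSE]
  }
  if (!reference_group %in% wide$group) stop("reference group has no samples")
  hk <- (wide[[cq_cols[2]]] + wide[[cq_cols[3]]]) / 2
  dcq <- wide[[cq_cols[1]]] - hk
  ref_mean <- mean(dcq[wide$group == reference_group])
  out <- data.frame(sample = wide$sample, group = wide$group,
                    rel_expr = 2^-(dcq - ref_mean),
                    stringsAsFactors = FALSE)
  out[order(out$group, out$sample), , drop = FALSE]
}

#' Compare relative expression between two groups
#'
#' Fold change of arithmetic group means (non-reference over reference) with
#' a two-sided Mann-Whitney p (shared implementation with the
#' copy-number-bias test).
#'
#' @param relative_expressions numeric vector.
#' @param group_labels two-level factor/character vector.
#' @param reference_group denominator group; defaults to the first level.
#' @return list fold_change / U / p_value / groups.
#' @export
compare_groups <- function(relative_expressions, group_labels,
                           reference_group = NULL) {
  groups <- unique(group_labels)
  stopifnot(length(groups) == 2)
  if (is.null(reference_group)) reference_group <- groups[1]
  other <- setdiff(groups, reference_group)
  a <- relative_expressions[group_labels == reference_group]
  b <- relative_expressions[group_labels == other]
  if (min(length(a), length(b)) < 3)
    stop("each group needs at least 3 samples")
  mw <- mann_whitney(b, a)
  list(fold_change = mean(b) / mean(a), U = mw$U, p_value = mw$p_value,
       groups = c(reference = reference_group, test = other))
}
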