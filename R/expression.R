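# Differential expression between two cell lines: RPKM quantification,
# 1-RPKM expression filter, TMM between-library normalization, per-gene
# Fisher exact test on TMM-scaled libraries, BH FDR with a fold-change gate,
# plus miRNA-style chi-square DE and length-bias-aware category enrichment.

#' Reads per kilobase of exon per million mapped reads
#'
#' `count * 1e9 / (exon_length_bp * library_size)`.
#'
#' @param count tag count (vectorized).
#' @param exon_length_bp total exon length of the gene, bp.
#' @param library_size total mapped tags.
#' @return RPKM values.
#' @export
compute_rpkm <- function(count, exon_length_bp, library_size) {
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e9 / (exon_length_bp * library_size)
}

#' Keep genes expressed above a threshold in at least one line
#'
#' @param records data.frame with columns `rpkm_a`, `rpkm_b`.
#' @param threshold_rpkm retention threshold (strictly above).
#' @return the retained rows.
#' @export
filter_expressed <- function(records, threshold_rpkm = 1) {
  records[records$rpkm_a > threshold_rpkm | records$rpkm_b > threshold_rpkm, ,
          drop = FALSE]
}

#' Weighted trimmed mean of M-values scaling factor
#'
#' Doubly trimmed, inverse-variance-weighted mean of per-gene log2 count
#' ratios: genes with a zero in either sample are excluded; the extreme
#' `trim_m` fraction by M (each tail) and `trim_a` fraction by A (each tail)
#' are removed; the factor is `2^(weighted mean of surviving M)`, so it
#' absorbs both sequencing depth and composition differences (a test library
#' that is exactly 2x the reference gives factor 2).
#'
#' @param counts_ref,counts_test equal-length count vectors.
#' @param trim_m trim fraction per tail on M = log2(test/ref).
#' @param trim_a trim fraction per tail on A = mean log2 abundance.
#' @return positive scalar factor.
#' @export
tmm_factor <- function(counts_ref, counts_test, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(length(counts_ref) == length(counts_test))
  keep <- counts_ref > 0 & counts_test > 0
  r <- as.numeric(counts_ref[keep]); t <- as.numeric(counts_test[keep])
  if (length(r) == 0) stop("no genes with nonzero counts in both samples")
  M <- log2(t / r)
  A <- 0.5 * log2(t * r)
  n <- length(M)
  rk_m <- rank(M, ties.method = "first")
  rk_a <- rank(A, ties.method = "first")
  lo_m <- floor(n * trim_m); lo_a <- floor(n * trim_a)
  sel <- rk_m > lo_m & rk_m <= n - lo_m & rk_a > lo_a & rk_a <= n - lo_a
  if (sum(sel) < 10) {
    warning("fewer than 10 genes survive trimming; using untrimmed mean")
    sel <- rep(TRUE, n)
  }
  w <- 1 / (1 / t[sel] + 1 / r[sel])   # delta-method inverse variance
  2^(sum(w * M[sel]) / sum(w))
}

#' Two-sided Fisher exact p for a gene's counts against the two libraries
#'
#' Tests the 2x2 table `[count_a, lib_a - count_a; count_b, lib_b - count_b]`
#' (libraries rounded to integers) by summing hypergeometric probabilities no
#' larger than the observed table's. Computed on the hypergeometric support
#' directly, so library-size margins in the millions are cheap.
#'
#' @param count_a,count_b per-gene counts (vectorized).
#' @param effective_lib_a,effective_lib_b effective library sizes (library
#'   size times TMM factor).
#' @return two-sided p-values.
#' @export
fisher_de <- function(count_a, count_b, effective_lib_a, effective_lib_b) {
  la <- round(effective_lib_a); lb <- round(effective_lib_b)
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  la <- rep_len(la, n); lb <- rep_len(lb, n)
  if (any(count_a > la) || any(count_b > lb))
    stop("count exceeds library size")
  vapply(seq_len(n), function(i) {
    k <- count_a[i] + count_b[i]
    lo <- max(0, k - lb[i]); hi <- min(k, la[i])
    d <- stats::dhyper(lo:hi, la[i], lb[i], k)
    p_obs <- d[count_a[i] - lo + 1]
    min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
  }, 0)
}

#' Assemble an expression record table for two lines
#'
#' Computes RPKM per line, the TMM factor of line B against reference line A,
#' effective libraries, normalized fold change B/A (a 0.5 pseudo-count enters
#' the ratio only, never the test), and the per-gene Fisher exact p.
#'
#' @param counts data.frame gene_id/count_a/count_b.
#' @param genes gene models supplying `exon_length_bp`.
#' @param library_sizes length-2 vector (a, b); defaults to column sums.
#' @param filter apply the `>= 1` RPKM in at least one line filter before
#'   testing.
#' @param threshold_rpkm filter threshold.
#' @return data.frame with gene_id, counts, rpkm_a/b, fold_change, p_value
#'   (fdr/de_call added by [call_de()]); TMM factor in attribute
#'   `"tmm_factor"`.
#' @export
expression_table <- function(counts, genes, library_sizes = NULL,
                             filter = TRUE, threshold_rpkm = 1) {
  idx <- match(counts$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("counts contain unknown gene ids")
  if (is.null(library_sizes))
    library_sizes <- c(sum(counts$count_a), sum(counts$count_b))
  rec <- data.frame(gene_id = counts$gene_id,
                    count_a = counts$count_a, count_b = counts$count_b,
                    exon_length_bp = genes$exon_length_bp[idx],
                    stringsAsFactors = FALSE)
  rec$rpkm_a <- compute_rpkm(rec$count_a, rec$exon_length_bp, library_sizes[1])
  rec$rpkm_b <- compute_rpkm(rec$count_b, rec$exon_length_bp, library_sizes[2])
  if (filter) rec <- filter_expressed(rec, threshold_rpkm)
  f <- tmm_factor(rec$count_a, rec$count_b)
  eff_a <- library_sizes[1]
  eff_b <- library_sizes[1] * f   # depth+composition of B relative to A
  ca <- ifelse(rec$count_a == 0, 0.5, rec$count_a)
  cb <- ifelse(rec$count_b == 0, 0.5, rec$count_b)
  rec$fold_change <- (cb / eff_b) / (ca / eff_a)
  rec$p_value <- fisher_de(rec$count_a, rec$count_b, eff_a, eff_b)
  attr(rec, "tmm_factor") <- f
  attr(rec, "effective_libs") <- c(a = eff_a, b = unname(eff_b))
  rownames(rec) <- NULL
  rec
}

#' Call differential expression with BH FDR and a fold-change gate
#'
#' A gene is called `up`/`down` iff its BH FDR is below `fdr_alpha` AND
#' `max(fc, 1/fc) >= fc_threshold`; direction follows the fold change.
#'
#' @param records output of [expression_table()] (needs `p_value`,
#'   `fold_change`).
#' @param fdr_alpha FDR cutoff.
#' @param fc_threshold fold-change cutoff.
#' @param correction multiple-testing method passed to [stats::p.adjust()].
#' @return `records` with `fdr` and `de_call` columns.
#' @export
call_de <- function(records, fdr_alpha = 0.05, fc_threshold = 3,
                    correction = "BH") {
  records$fdr <- stats::p.adjust(records$p_value, method = correction)
  fc <- records$fold_change
  big <- pmax(fc, 1 / fc) >= fc_threshold
  records$de_call <- ifelse(records$fdr < fdr_alpha & big,
                            ifelse(fc > 1, "up", "down"), "none")
  records
}

#' miRNA-style differential expression: chi-square with Bonferroni
#'
#' Genes at >= 1 RPKM in at least one line are tested with a Pearson
#' chi-square (no continuity correction) on the 2x2 table of the gene's
#' counts against the remaining libraries; genes with any expected cell < 1
#' fall back to the Fisher exact test and are flagged. P-values are
#' Bonferroni-corrected over the tested genes; a gene is called when the
#' corrected p is below `alpha` and the fold change is at least
#' `fc_threshold`.
#'
#' @param records data.frame with count_a/count_b/rpkm_a/rpkm_b/fold_change.
#' @param library_sizes length-2 vector of library sizes.
#' @param alpha corrected-p cutoff.
#' @param fc_threshold fold-change cutoff.
#' @param threshold_rpkm detection filter threshold.
#' @return tested records with `chisq_stat`, `p_value`, `p_bonferroni`,
#'   `fisher_fallback`, `de_call`.
#' @export
mirna_de <- function(records, library_sizes, alpha = 0.05, fc_threshold = 3,
                     threshold_rpkm = 1) {
  rec <- filter_expressed(records, threshold_rpkm)
  la <- library_sizes[1]; lb <- library_sizes[2]
  o11 <- rec$count_a; o12 <- la - o11
  o21 <- rec$count_b; o22 <- lb - o21
  N <- la + lb
  k <- o11 + o21
  e11 <- k * la / N; e12 <- (N - k) * la / N
  e21 <- k * lb / N; e22 <- (N - k) * lb / N
  stat <- (o11 - e11)^2 / e11 + (o12 - e12)^2 / e12 +
    (o21 - e21)^2 / e21 + (o22 - e22)^2 / e22
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  fallback <- pmin(e11, e12, e21, e22) < 1
  if (any(fallback)) {
    p[fallback] <- fisher_de(o11[fallback], o21[fallback], la, lb)
    stat[fallback] <- NA_real_
  }
  rec$chisq_stat <- stat
  rec$p_value <- p
  rec$p_bonferroni <- stats::p.adjust(p, method = "bonferroni")
  rec$fisher_fallback <- fallback
  fc <- rec$fold_change
  big <- pmax(fc, 1 / fc) >= fc_threshold
  rec$de_call <- ifelse(rec$p_bonferroni < alpha & big,
                        ifelse(fc > 1, "up", "down"), "none")
  rec
}

# ---- Wallenius noncentral hypergeometric -----------------------------------

# pmf via the exact integral representation:
#   P(X = x) = C(m1,x) C(m2,n-x) * Int_0^1 (1-t^(w/d))^x (1-t^(1/d))^(n-x) dt
# with d = w (m1 - x) + (m2 - (n - x)).
dwallenius1 <- function(x, m1, m2, n, odds) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  d <- odds * (m1 - x) + (m2 - (n - x))
  if (d <= 0) return(1)   # the urn is emptied; the outcome is forced
  f <- function(t) {
    a <- if (x > 0) x * log1p(-t^(odds / d)) else 0
    b <- if (n - x > 0) (n - x) * log1p(-t^(1 / d)) else 0
    exp(a + b)
  }
  I <- stats::integrate(Vectorize(f), 0, 1, rel.tol = 1e-10,
                        subdivisions = 500L)$value
  exp(lchoose(m1, x) + lchoose(m2, n - x)) * I
}

#' Upper-tail Wallenius noncentral hypergeometric probability
#'
#' P(X >= x) for the biased urn with `m1` white balls of odds `odds`, `m2`
#' black balls of odds 1, and `n` sequential draws without replacement.
#' `odds = 1` reduces exactly to the central hypergeometric. The pmf over the
#' support is renormalized to absorb quadrature error.
#'
#' @param x observed white count.
#' @param m1,m2 category / complement sizes.
#' @param n number of draws.
#' @param odds odds ratio of white vs black.
#' @return upper-tail probability.
#' @export
pwallenius_upper <- function(x, m1, m2, n, odds) {
  lo <- max(0, n - m2); hi <- min(n, m1)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  if (odds == 1)
    return(stats::phyper(x - 1, m1, m2, n, lower.tail = FALSE))
  pmf <- vapply(lo:hi, dwallenius1, 0, m1 = m1, m2 = m2, n = n, odds = odds)
  sum(pmf[(lo:hi) >= x]) / sum(pmf)
}

#' Length-bias-aware category enrichment (biased-urn test)
#'
#' Tests each category for enrichment among DE genes while correcting for
#' the over-detection of long genes. A probability-weighting function is
#' estimated by isotonic regression of the DE indicator on gene length over
#' equal-occupancy length bins (direction chosen by the sign of the
#' bin-level Spearman correlation); each category's odds is the ratio of
#' mean weights inside vs outside; the upper-tail p comes from the Wallenius
#' noncentral hypergeometric with those odds, and BH controls the FDR across
#' categories.
#'
#' @param de_flags logical vector, one per gene.
#' @param gene_lengths numeric vector, same order.
#' @param category_map data.frame gene_id/category; `gene_ids` links it to
#'   the flag/length vectors.
#' @param gene_ids gene ids matching `de_flags`.
#' @param n_bins equal-occupancy bins for the weighting function.
#' @param fdr_alpha significance threshold on the BH FDR.
#' @return data.frame category, n_genes, n_de, odds, p_value, fdr,
#'   significant; empty categories are dropped with a message.
#' @export
length_bias_enrichment <- function(de_flags, gene_lengths, category_map,
                                   gene_ids, n_bins = 40, fdr_alpha = 0.05) {
  stopifnot(length(de_flags) == length(gene_lengths),
            length(gene_ids) == length(de_flags))
  n <- length(de_flags)
  n_bins <- min(n_bins, max(2, floor(n / 5)))
  ord <- order(gene_lengths)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin_de <- tapply(as.numeric(de_flags), bin, mean)
  bin_len <- tapply(gene_lengths, bin, mean)
  incr <- is.na(rho <- suppressWarnings(
    stats::cor(bin_len, bin_de, method = "spearman"))) || rho >= 0
  iso <- if (incr) stats::isoreg(bin_len, bin_de)
         else stats::isoreg(bin_len, -bin_de)
  fit <- if (incr) iso$yf else -iso$yf
  w <- pmax(fit[bin], 1e-4)
  cats <- split(category_map$gene_id, category_map$category)
  keep <- lengths(lapply(cats, intersect, gene_ids)) > 0
  if (any(!keep))
    message("dropping empty categories: ",
            paste(names(cats)[!keep], collapse = ", "))
  cats <- cats[keep]
  n_de_total <- sum(de_flags)
  rows <- lapply(names(cats), function(cn) {
    inside <- gene_ids %in% cats[[cn]]
    m1 <- sum(inside); m2 <- n - m1
    x <- sum(de_flags & inside)
    odds <- if (m2 == 0) 1 else mean(w[inside]) / mean(w[!inside])
    p <- pwallenius_upper(x, m1, m2, n_de_total, odds)
    data.frame(category = cn, n_genes = m1, n_de = x, odds = odds,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_alpha
  out[order(out$p_value, out$category), , drop = FALSE]
}
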