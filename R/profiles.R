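# Expression-quartile TSS metagene profiles: genes are split into quartiles
# by RPKM, tags are binned into 25-bp strand-oriented bins over +/-5 kb
# around each TSS, per-bin counts are Poisson-trimmed, and the mean over
# genes gives the profile.

QUARTILE_LEVELS <- c("high", "medium", "low", "very low")

#' Assign expression quartiles
#'
#' Four groups of equal size (+/-1) by descending RPKM; ties broken by
#' gene_id order so membership is deterministic.
#'
#' @param rpkm numeric vector.
#' @param gene_ids matching gene ids.
#' @return named character vector gene_id -> quartile label
#'   (high/medium/low/very low).
#' @export
assign_quartiles <- function(rpkm, gene_ids) {
  n <- length(rpkm)
  if (n < 4) stop("need at least 4 genes to form quartiles")
  ord <- order(-rpkm, gene_ids)
  q <- character(n)
  q[ord] <- QUARTILE_LEVELS[ceiling(seq_len(n) / (n / 4))]
  stats::setNames(q, gene_ids)
}

#' Cap bin counts at a Poisson upper-tail threshold
#'
#' The cap is the smallest k with upper-tail P(X >= k) < `alpha` under
#' Poisson(`lambda`); counts above the cap are set to the cap. With the
#' default global lambda (the mean bin count of the mark/sample) this
#' removes tower artifacts without reshaping the profile.
#'
#' @param bin_counts numeric vector or matrix of counts.
#' @param alpha upper-tail mass defining the cap.
#' @param lambda Poisson mean; defaults to `mean(bin_counts)`.
#' @return counts with values above the cap replaced by the cap; the cap is
#'   in attribute `"cap"`.
#' @export
poisson_trim <- function(bin_counts, alpha = 1e-5, lambda = NULL) {
  if (is.null(lambda)) lambda <- mean(bin_counts)
  cap <- poisson_tail_threshold(lambda, alpha)
  out <- pmin(bin_counts, cap)
  attributes(out) <- attributes(bin_counts)
  attr(out, "cap") <- cap
  out
}

#' TSS metagene profile for one gene set
#'
#' For each gene, tags are counted in `bin_bp` bins over
#' `[TSS - flank_bp, TSS + flank_bp)`; offsets are strand-oriented, so
#' upstream is always negative (for a minus-strand gene a tag downstream in
#' genomic coordinates maps to a negative offset). Genes whose flank
#' extends past a chromosome edge are skipped with a message. Per-bin,
#' per-gene counts are Poisson-trimmed with a global lambda, and the
#' profile is the mean over genes, so quartiles of slightly unequal size
#' remain comparable.
#'
#' @param tags a `tag_set`.
#' @param genes gene models of one quartile (or any gene set).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param flank_bp half-width of the window around the TSS.
#' @param bin_bp bin width.
#' @param trim apply [poisson_trim()].
#' @param trim_alpha trimming tail mass.
#' @return data.frame bin_offset (left edges, -flank .. flank - bin) and
#'   density (mean trimmed count per gene per bin); attributes `n_genes`,
#'   `n_skipped`, `total_tags` (untrimmed tag total in all flanks).
#' @export
tss_profile <- function(tags, genes, chrom_lengths, flank_bp = 5000,
                        bin_bp = 25, trim = TRUE, trim_alpha = 1e-5) {
  stopifnot(inherits(tags, "tag_set"))
  n_bins <- 2 * flank_bp / bin_bp
  offsets <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  ok <- genes$tss - flank_bp >= 0 &
    genes$tss + flank_bp <= chrom_lengths[genes$chrom]
  if (any(!ok))
    message(sum(!ok), " gene(s) skipped: TSS within ", flank_bp,
            " bp of a chromosome edge")
  g <- genes[ok, , drop = FALSE]
  counts <- matrix(0, nrow = nrow(g), ncol = n_bins)
  by_chrom <- split(tags$tags$pos, tags$tags$chrom)
  for (i in seq_len(nrow(g))) {
    p <- by_chrom[[g$chrom[i]]]
    if (is.null(p)) next
    off <- if (g$strand[i] == "+") p - g$tss[i] else g$tss[i] - p
    off <- off[off >= -flank_bp & off < flank_bp]
    if (length(off) == 0) next
    counts[i, ] <- tabulate((off + flank_bp) %/% bin_bp + 1L, nbins = n_bins)
  }
  total_tags <- sum(counts)
  if (trim && nrow(counts) > 0) counts <- poisson_trim(counts, trim_alpha)
  density <- if (nrow(counts)) colMeans(counts) else rep(0, n_bins)
  out <- data.frame(bin_offset = offsets, density = density)
  attr(out, "n_genes") <- nrow(g)
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "total_tags") <- total_tags
  out
}

#' Metagene profiles for all quartiles of one mark/sample
#'
#' @inheritParams tss_profile
#' @param quartiles named vector gene_id -> quartile (see
#'   [assign_quartiles()]).
#' @return long data.frame mark/sample/quartile/bin_offset/density.
#' @export
metagene_profiles <- function(tags, genes, quartiles, chrom_lengths,
                              flank_bp = 5000, bin_bp = 25, trim = TRUE,
                              trim_alpha = 1e-5) {
  rows <- lapply(QUARTILE_LEVELS, function(q) {
    gset <- genes[quartiles[genes$gene_id] == q, , drop = FALSE]
    prof <- tss_profile(tags, gset, chrom_lengths, flank_bp, bin_bp,
                        trim, trim_alpha)
    data.frame(mark = tags$mark, sample = tags$sample, quartile = q,
               prof, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
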