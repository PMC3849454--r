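# Small in-code fixtures shared across test files.

# a minimal gene_models data.frame built by hand
make_genes <- function(df, exon_starts = NULL, exon_ends = NULL) {
  g <- df
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  if (is.null(exon_starts)) {
    exon_starts <- lapply(seq_len(nrow(g)), function(i) g$start[i])
    exon_ends <- lapply(seq_len(nrow(g)), function(i) g$end[i])
  }
  g$exon_length_bp <- vapply(seq_len(nrow(g)), function(i)
    sum(exon_ends[[i]] - exon_starts[[i]]), 0)
  if (is.null(g$thick_start)) g$thick_start <- g$start
  if (is.null(g$thick_end)) g$thick_end <- g$end
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  class(g) <- c("gene_models", "data.frame")
  g
}

# a tag_set from bare positions on one chromosome
make_tags <- function(pos, mark = "PolII", sample = "s", chrom = "chr1") {
  tag_set(data.frame(chrom = chrom, pos = pos,
                     strand = rep("+", length(pos)),
                     stringsAsFactors = FALSE), mark, sample)
}

# uniform background tag positions over [0, len)
uniform_tags <- function(n, len, mark = "PolII", sample = "s",
                         chrom = "chr1") {
  make_tags(floor(runif(n) * len), mark, sample, chrom)
}

# brute-force two-sided Fisher p by explicit table enumeration with choose()
fisher_enum <- function(ca, cb, la, lb) {
  k <- ca + cb
  lo <- max(0, k - lb); hi <- min(k, la)
  xs <- lo:hi
  logp <- lchoose(la, xs) + lchoose(lb, k - xs) - lchoose(la + lb, k)
  p <- exp(logp)
  obs <- p[ca - lo + 1]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}
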