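# Window/gap island calling against input DNA, differential islands between
# two samples on a shared (pooled) region set, per-mark direction summaries,
# and promoter/UTR/exon/intron annotation of islands.

#' Island-calling parameters
#'
#' Defaults follow the broad-domain caller convention: 200-bp windows, a
#' 200-bp gap for punctate marks (H3K4me1, H3K4me3, Pol II) or 600 bp for
#' the broad H3K27me3 mark, 81% effective genome, island FDR <= 0.001,
#' differential fold >= 3 at FDR < 0.05.
#'
#' @param mark mark name; sets the default gap.
#' @param window_bp consolidating window size.
#' @param gap_bp maximum run of ineligible sequence bridged when merging
#'   eligible windows; must be a multiple of `window_bp`.
#' @param effective_genome_fraction mappable fraction of the genome.
#' @param island_fdr FDR threshold for retained islands.
#' @param eligible_tail Poisson upper-tail mass defining window eligibility.
#' @param diff_fold,diff_fdr differential-island thresholds.
#' @return list of class `island_params`.
#' @export
island_params <- function(mark = "H3K4me3", window_bp = 200, gap_bp = NULL,
                          effective_genome_fraction = 0.81,
                          island_fdr = 0.001, eligible_tail = 0.20,
                          diff_fold = 3, diff_fdr = 0.05) {
  if (is.null(gap_bp)) gap_bp <- if (mark == "H3K27me3") 600 else 200
  if (gap_bp %% window_bp != 0) stop("gap_bp must be a multiple of window_bp")
  stopifnot(effective_genome_fraction > 0, effective_genome_fraction <= 1)
  structure(list(mark = mark, window_bp = window_bp, gap_bp = gap_bp,
                 effective_genome_fraction = effective_genome_fraction,
                 island_fdr = island_fdr, eligible_tail = eligible_tail,
                 diff_fold = diff_fold, diff_fdr = diff_fdr),
            class = "island_params")
}

# smallest k with P(Pois(lambda) >= k) < tail
poisson_tail_threshold <- function(lambda, tail) {
  k <- stats::qpois(1 - tail, lambda)
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) >= tail) k <- k + 1
  k
}

window_counts <- function(positions, n_windows, window_bp) {
  tabulate(pmin(positions %/% window_bp + 1L, n_windows), nbins = n_windows)
}

#' Call enriched islands against input DNA
#'
#' Each chromosome is tiled with `window_bp` windows; a window is eligible
#' when its ChIP count exceeds the upper `eligible_tail` threshold of the
#' genome-wide background Poisson rate (library size scaled to the effective
#' genome). Eligible windows separated by at most `gap_bp` of ineligible
#' sequence merge into islands. Each island is tested by an upper-tail
#' Poisson p of its total ChIP count against the input-derived expectation
#' (input count scaled by the library ratio, floored at the background
#' expectation for the island length); islands are retained at BH FDR
#' `island_fdr`. Without input (`input = NULL` or an empty library) the
#' background expectation alone is used and the result is flagged
#' `background_only`.
#'
#' @param chip `tag_set` of the immunoprecipitated sample.
#' @param input matched input `tag_set`, or NULL.
#' @param params an [island_params()] object.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame chrom/start/end/chip_count/input_count/expected/
#'   normalized_enrichment/p_value/fdr; attribute `background_only`.
#' @export
call_islands <- function(chip, input, params, chrom_lengths) {
  stopifnot(inherits(chip, "tag_set"), inherits(params, "island_params"))
  w <- params$window_bp
  background_only <- is.null(input) || input$library_size == 0
  lambda <- chip$library_size * w /
    (sum(chrom_lengths) * params$effective_genome_fraction)
  k0 <- poisson_tail_threshold(lambda, params$eligible_tail)
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    nw <- ceiling(chrom_lengths[[chrom]] / w)
    cc <- window_counts(chip$tags$pos[chip$tags$chrom == chrom], nw, w)
    elig <- which(cc >= k0)
    if (length(elig) == 0) next
    grp <- cumsum(c(1, diff(elig) > params$gap_bp / w + 1))
    for (g in split(elig, grp)) {
      s <- (min(g) - 1) * w
      e <- max(g) * w
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = s, end = e,
        chip_count = sum(cc[min(g):max(g)]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      chip_count = numeric(), input_count = numeric(),
                      expected = numeric(), normalized_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric())
    attr(out, "background_only") <- background_only
    return(out)
  }
  isl <- do.call(rbind, rows)
  isl$input_count <- 0
  if (!background_only) {
    for (chrom in unique(isl$chrom)) {
      ip <- sort(input$tags$pos[input$tags$chrom == chrom])
      sel <- isl$chrom == chrom
      isl$input_count[sel] <-
        findInterval(isl$end[sel] - 0.5, ip) -
        findInterval(isl$start[sel] - 0.5, ip)
    }
  }
  bg_expect <- lambda * (isl$end - isl$start) / w
  isl$expected <- if (background_only) bg_expect else
    pmax(isl$input_count * chip$library_size / input$library_size, bg_expect)
  isl$normalized_enrichment <- isl$chip_count / isl$expected
  isl$p_value <- stats::ppois(isl$chip_count - 1, isl$expected,
                              lower.tail = FALSE)
  isl$fdr <- stats::p.adjust(isl$p_value, method = "BH")
  isl <- isl[isl$fdr <= params$island_fdr, , drop = FALSE]
  isl <- isl[order(isl$chrom, isl$start), , drop = FALSE]
  rownames(isl) <- NULL
  attr(isl, "background_only") <- background_only
  isl
}

count_in_regions <- function(positions, chroms, regions) {
  out <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    p <- sort(positions[chroms == chrom])
    sel <- regions$chrom == chrom
    out[sel] <- findInterval(regions$end[sel] - 0.5, p) -
      findInterval(regions$start[sel] - 0.5, p)
  }
  out
}

#' Differentially enriched islands between two samples
#'
#' Candidate regions are islands called on the pooled tags of both samples
#' (pooled inputs when given), so one symmetric region set serves both
#' directions. Per region, the library-normalized readcounts (tags per
#' million) give the fold change A/B (0.5 pseudo-count when one side is
#' zero; regions empty in both samples are skipped), and an exact binomial
#' test of the A count against the library-size split gives the p-value.
#' Regions with `max(fc, 1/fc) >= diff_fold` at BH FDR < `diff_fdr` are
#' emitted, direction `increased` when sample A is higher.
#'
#' @param tags_a,tags_b `tag_set`s of the two samples (A is conventionally
#'   the cancer-like line, matching the reporting direction).
#' @param params an [island_params()] object.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param input_a,input_b optional matched inputs, pooled for region calling.
#' @return data.frame chrom/start/end/count_a/count_b/readcount_a/
#'   readcount_b/fold_change/p_value/fdr/direction (passing regions only);
#'   attribute `n_tested` gives the number of candidate regions tested.
#' @export
differential_islands <- function(tags_a, tags_b, params, chrom_lengths,
                                 input_a = NULL, input_b = NULL) {
  pooled <- tag_set(rbind(tags_a$tags, tags_b$tags), tags_a$mark, "pooled")
  pooled_input <- if (!is.null(input_a) && !is.null(input_b))
    tag_set(rbind(input_a$tags, input_b$tags), "input", "pooled") else NULL
  regions <- call_islands(pooled, pooled_input, params, chrom_lengths)
  if (nrow(regions) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      count_a = numeric(), count_b = numeric(),
                      readcount_a = numeric(), readcount_b = numeric(),
                      fold_change = numeric(), p_value = numeric(),
                      fdr = numeric(), direction = character())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  reg <- regions[c("chrom", "start", "end")]
  reg$count_a <- count_in_regions(tags_a$tags$pos, tags_a$tags$chrom, reg)
  reg$count_b <- count_in_regions(tags_b$tags$pos, tags_b$tags$chrom, reg)
  reg <- reg[reg$count_a + reg$count_b > 0, , drop = FALSE]
  la <- tags_a$library_size; lb <- tags_b$library_size
  reg$readcount_a <- reg$count_a / la * 1e6
  reg$readcount_b <- reg$count_b / lb * 1e6
  ca <- ifelse(reg$count_a == 0, 0.5, reg$count_a)
  cb <- ifelse(reg$count_b == 0, 0.5, reg$count_b)
  reg$fold_change <- (ca / la) / (cb / lb)
  p_null <- la / (la + lb)
  reg$p_value <- vapply(seq_len(nrow(reg)), function(i)
    stats::binom.test(reg$count_a[i], reg$count_a[i] + reg$count_b[i],
                      p = p_null)$p.value, 0)
  reg$fdr <- stats::p.adjust(reg$p_value, method = "BH")
  n_tested <- nrow(reg)
  pass <- pmax(reg$fold_change, 1 / reg$fold_change) >= params$diff_fold &
    reg$fdr < params$diff_fdr
  out <- reg[pass, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > 1, "increased", "decreased")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' Per-mark counts and percentages of increased vs decreased islands
#'
#' @param islands either a differential-island data.frame (with `direction`)
#'   or a named list of them, one per mark.
#' @return data.frame mark/n_increased/pct_increased/n_decreased/
#'   pct_decreased (percentages to 1 decimal; NA when a mark has no
#'   islands).
#' @export
summarize_differential <- function(islands) {
  if (is.data.frame(islands)) islands <- list(all = islands)
  rows <- lapply(names(islands), function(mk) {
    d <- islands[[mk]]
    n_inc <- sum(d$direction == "increased")
    n_dec <- sum(d$direction == "decreased")
    tot <- n_inc + n_dec
    data.frame(mark = mk, n_increased = n_inc,
               pct_increased = if (tot) round(100 * n_inc / tot, 1) else NA,
               n_decreased = n_dec,
               pct_decreased = if (tot) round(100 * n_dec / tot, 1) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# feature intervals of one gene, in annotation precedence order
gene_feature_intervals <- function(g, promoter_bp, downstream_bp) {
  plus <- g$strand == "+"
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  feats <- list()
  add <- function(cat, s, e) {
    keep <- e > s
    if (any(keep))
      feats[[length(feats) + 1]] <<- data.frame(category = cat,
                                                start = s[keep], end = e[keep])
  }
  if (plus) add("promoter", max(0, g$tss - promoter_bp), g$tss)
  else add("promoter", g$tss + 1, g$tss + 1 + promoter_bp)
  # exon pieces split by CDS bounds
  utr_left_s <- pmax(es, 0); utr_left_e <- pmin(ee, g$thick_start)
  cds_s <- pmax(es, g$thick_start); cds_e <- pmin(ee, g$thick_end)
  utr_right_s <- pmax(es, g$thick_end); utr_right_e <- ee
  if (plus) {
    add("utr5", utr_left_s, utr_left_e)
    add("utr3", utr_right_s, utr_right_e)
  } else {
    add("utr3", utr_left_s, utr_left_e)
    add("utr5", utr_right_s, utr_right_e)
  }
  add("coding_exon", cds_s, cds_e)
  if (length(es) > 1) add("intron", ee[-length(ee)], es[-1])
  if (plus) add("downstream", g$end, g$end + downstream_bp)
  else add("downstream", max(0, g$start - downstream_bp), g$start)
  if (length(feats)) do.call(rbind, feats) else
    data.frame(category = character(), start = numeric(), end = numeric())
}

#' Annotate islands by genomic context
#'
#' Each island is assigned one category from its midpoint, with precedence
#' promoter (up to `promoter_bp` upstream of a TSS) > 5' UTR > 3' UTR >
#' coding exon > intron > downstream (within `promoter_bp` past the gene
#' end) > distal intergenic, resolved across all genes.
#'
#' @param islands data.frame with chrom/start/end.
#' @param genes gene models.
#' @param promoter_bp promoter (and downstream) window size.
#' @return `islands` with `category` and `gene_id` columns (gene_id NA for
#'   distal intergenic).
#' @export
annotate_islands <- function(islands, genes, promoter_bp = 3000) {
  prec <- c("promoter", "utr5", "utr3", "coding_exon", "intron",
            "downstream")
  mid <- interval_midpoint(islands$start, islands$end)
  cat_out <- rep("distal_intergenic", nrow(islands))
  gene_out <- rep(NA_character_, nrow(islands))
  rank_out <- rep(length(prec) + 1L, nrow(islands))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    on_chrom <- which(islands$chrom == g$chrom)
    if (length(on_chrom) == 0) next
    feats <- gene_feature_intervals(g, promoter_bp, promoter_bp)
    feats$rank <- match(feats$category, prec)
    feats <- feats[order(feats$rank), , drop = FALSE]
    for (fi in seq_len(nrow(feats))) {
      hit <- on_chrom[mid[on_chrom] >= feats$start[fi] &
                      mid[on_chrom] < feats$end[fi]]
      better <- hit[feats$rank[fi] < rank_out[hit]]
      if (length(better)) {
        rank_out[better] <- feats$rank[fi]
        cat_out[better] <- feats$category[fi]
        gene_out[better] <- g$gene_id
      }
    }
  }
  islands$category <- cat_out
  islands$gene_id <- gene_out
  islands
}

#' Category percentage summary of annotated islands
#' @param annotated output of [annotate_islands()].
#' @return data.frame category/n/pct.
#' @export
summarize_annotation <- function(annotated) {
  cats <- c("promoter", "utr5", "utr3", "coding_exon", "intron",
            "downstream", "distal_intergenic")
  n <- vapply(cats, function(cc) sum(annotated$category == cc), 0)
  data.frame(category = cats, n = n,
             pct = round(100 * n / max(1, nrow(annotated)), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
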