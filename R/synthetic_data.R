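# Synthetic toy-study generators. Every generator is a pure function of its
# arguments and seed: it calls set.seed() on entry and touches no other state,
# so the same call always returns byte-identical output.

#' Generate a toy genome annotation
#'
#' Places non-overlapping stranded genes with 1-10 exons on one or more
#' chromosomes. Genes are laid out in per-gene slots with jittered starts so
#' TSS flanks (used by metagene profiles) rarely hit chromosome edges. CDS
#' bounds are set inside the first/last exon so every gene has 5' and 3' UTR
#' sequence.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome.
#' @param n_genes total genes (>= 8).
#' @param seed RNG seed.
#' @return a `gene_models` data.frame (see [read_gene_models()]).
#' @export
generate_genome <- function(n_chrom = 2, chrom_length_bp = 3e6,
                            n_genes = 200, seed = 1) {
  stopifnot(n_genes >= 8, chrom_length_bp >= 1e5)
  set.seed(seed)
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  edge_margin <- 6000
  rows <- list()
  for (ci in seq_len(n_chrom)) {
    ng <- per_chrom[ci]
    if (ng == 0) next
    usable <- chrom_length_bp - 2 * edge_margin
    slot <- floor(usable / ng)
    if (slot < 4000)
      stop("capacity error: ", ng, " genes do not fit in ",
           chrom_length_bp, " bp")
    max_len <- min(12000, slot - 1000)
    for (gi in seq_len(ng)) {
      len <- sample(2000:max_len, 1)
      slack <- slot - len
      s0 <- edge_margin + (gi - 1) * slot + sample.int(slack, 1) - 1
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(1:10, 1)
      # exon/intron lengths: 2*n_ex-1 parts, each >= 100 bp, summing to len
      parts <- 2 * n_ex - 1
      min_part <- min(100, floor(len / (2 * parts)))
      extra <- len - parts * min_part
      lens <- as.vector(stats::rmultinom(1, extra, rep(1, parts))) + min_part
      bounds <- c(0, cumsum(lens))
      ex_idx <- seq(1, parts, by = 2)
      es <- s0 + bounds[ex_idx]
      ee <- s0 + bounds[ex_idx + 1]
      # CDS: from mid first exon to mid last exon (guarantees UTRs)
      thick_start <- es[1] + floor((ee[1] - es[1]) / 2)
      thick_end <- es[n_ex] + ceiling((ee[n_ex] - es[n_ex]) / 2)
      rows[[length(rows) + 1]] <- list(
        gene_id = sprintf("gene_%03d", length(rows) + 1),
        chrom = sprintf("chr%d", ci), start = s0, end = s0 + len,
        strand = strand,
        tss = if (strand == "+") s0 else s0 + len - 1,
        exon_length_bp = sum(ee - es),
        thick_start = thick_start, thick_end = thick_end,
        exon_starts = list(es), exon_ends = list(ee))
    }
  }
  g <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[1:9], stringsAsFactors = FALSE)))
  g$exon_starts <- lapply(rows, function(r) r$exon_starts[[1]])
  g$exon_ends <- lapply(rows, function(r) r$exon_ends[[1]])
  g <- g[order(g$chrom, g$start, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Generate expression counts for two cell lines with planted DE genes
#'
#' Counts are negative-binomial around gene-specific means shared between
#' lines (up to library scaling); a chosen set of genes gets a planted fold
#' change in line B (the "cancer-like" line) relative to line A. A small
#' fraction of genes is made near-silent to exercise the 1-RPKM filter.
#' Overdispersed counts (rather than Poisson) reflect what exact-test DE
#' pipelines see in practice; `dispersion = 0` switches to Poisson.
#'
#' @param genes gene models.
#' @param n_de number of planted DE genes (ignored when `de_gene_ids` given).
#' @param fc_range range the planted fold change is drawn from (min >= 3).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_sizes length-2 vector of total counts, lines A and B.
#' @param seed RNG seed.
#' @param frac_up fraction of planted DE genes that go up in line B.
#' @param de_gene_ids optional explicit DE gene ids (all up when
#'   `de_fold` given as scalar).
#' @param de_fold optional explicit fold change(s) for `de_gene_ids` (> 1 for
#'   up in line B).
#' @return list with `counts` (data.frame gene_id, count_a, count_b),
#'   `truth` (gene_id, fc meaning B/A, log2fc), and `library_sizes`.
#' @export
generate_expression <- function(genes, n_de = 40, fc_range = c(4, 9),
                                dispersion = 0.02,
                                library_sizes = c(a = 2e6, b = 2e6),
                                seed = 1, frac_up = 0.5,
                                de_gene_ids = NULL, de_fold = NULL) {
  stopifnot(fc_range[1] >= 3 || !is.null(de_fold))
  set.seed(seed)
  n <- nrow(genes)
  rel <- exp(stats::rnorm(n, 0, 1.2))
  low <- order(rel)[seq_len(max(1, floor(0.05 * n)))]
  rel[low] <- rel[low] * 1e-4        # near-silent genes, below 1 RPKM
  rel <- rel / sum(rel)
  fc <- rep(1, n)
  if (is.null(de_gene_ids)) {
    stopifnot(n_de <= n)
    de_idx <- sample(setdiff(seq_len(n), low), n_de)
    n_up <- round(frac_up * n_de)
    updown <- c(rep(TRUE, n_up), rep(FALSE, n_de - n_up))
    f <- stats::runif(n_de, fc_range[1], fc_range[2])
    fc[de_idx] <- ifelse(updown, f, 1 / f)
  } else {
    de_idx <- match(de_gene_ids, genes$gene_id)
    stopifnot(!anyNA(de_idx))
    if (is.null(de_fold)) de_fold <- stats::runif(length(de_idx),
                                                  fc_range[1], fc_range[2])
    fc[de_idx] <- rep_len(de_fold, length(de_idx))
  }
  mu_a <- rel * library_sizes[[1]]
  mu_b <- rel * fc * library_sizes[[2]]
  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
  counts <- data.frame(gene_id = genes$gene_id,
                       count_a = draw(mu_a), count_b = draw(mu_b),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes$gene_id[de_idx],
                      fc = fc[de_idx], log2fc = log2(fc[de_idx]),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(counts = counts, truth = truth,
       library_sizes = c(a = sum(counts$count_a), b = sum(counts$count_b)))
}

# Per-mark offset models (strand-oriented bp relative to TSS), matching the
# promoter geometry of the four marks: H3K4me3 bimodal ~+/-350 bp, H3K4me1
# bimodal ~-700/+1300 bp, Pol II at the TSS, H3K27me3 broad over the body of
# weakly expressed genes with a small peak ~250 bp downstream.
default_mark_models <- function() {
  list(
    H3K4me3 = list(kind = "bimodal", centers = c(-350, 350), sd = 70,
                   quartile_weight = c(high = 8, medium = 4, low = 1.5,
                                       `very low` = 0.5)),
    H3K4me1 = list(kind = "bimodal", centers = c(-700, 1300), sd = 140,
                   quartile_weight = c(high = 5, medium = 3, low = 1.5,
                                       `very low` = 0.8)),
    PolII = list(kind = "tss", sd = 80,
                 quartile_weight = c(high = 8, medium = 3, low = 1,
                                     `very low` = 0.3)),
    H3K27me3 = list(kind = "broad", body_flank = 2000, peak = 250,
                    peak_sd = 150, peak_frac = 0.3,
                    quartile_weight = c(high = 1.5, medium = 2, low = 4,
                                        `very low` = 6))
  )
}

draw_offsets <- function(model, n, gene_len, dip = FALSE) {
  if (n == 0) return(numeric(0))
  off <- switch(model$kind,
    bimodal = stats::rnorm(n, sample(model$centers, n, replace = TRUE), model$sd),
    tss = stats::rnorm(n, 0, model$sd),
    broad = {
      pk <- stats::runif(n) < model$peak_frac
      o <- stats::runif(n, -model$body_flank, gene_len + model$body_flank)
      o[pk] <- stats::rnorm(sum(pk), model$peak, model$peak_sd)
      o
    })
  if (dip) {
    # carve a depletion zone at the TSS: resample offsets landing within it
    for (i in 1:8) {
      inside <- abs(off) <= 250
      if (!any(inside)) break
      off[inside] <- stats::runif(sum(inside), 250, 1500)
    }
  }
  off
}

#' Generate ChIP tag sets with planted promoter geometry
#'
#' For each of four marks and two samples ("normal" and "cancer"), draws
#' signal tags around gene TSSs with mark-specific offset distributions and
#' expression-quartile-dependent intensities, plus uniform background tags
#' and uniform matched input libraries. The cancer sample carries (i) a TSS
#' depletion ("dip") of H3K27me3 over top-quartile genes, (ii) a global
#' H3K27me3 deflation, and (iii) a planted Pol II boost at candidate genes;
#' the normal sample carries a planted H3K27me3 boost over candidate gene
#' bodies. These planted islands are recorded in the returned truth.
#'
#' @param genes gene models.
#' @param quartiles named character vector gene_id -> quartile label
#'   ("high", "medium", "low", "very low"), from the normal-like line.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed RNG seed.
#' @param n_signal promoter/gene-associated tag budget per sample; a named
#'   per-mark vector (scalars recycle). Defaults give the sparse per-gene
#'   bin coverage real libraries show: sharp marks concentrate tags in few
#'   bins, so their budget is smaller than the broad H3K27me3 budget.
#' @param n_background,n_input uniform background / input tag budget per
#'   sample.
#' @param candidate_genes gene ids to receive the planted differential
#'   Pol II (cancer) and H3K27me3 (normal) islands.
#' @param candidate_boost planted enrichment factor at candidate genes.
#' @param mark_models per-mark offset models; see `default_mark_models`.
#' @param k27_cancer_scale global H3K27me3 deflation in the cancer sample.
#' @return list with `tags` (nested list `tags[[mark]][[sample]]` of
#'   `tag_set`s, marks incl. "input") and `island_truth` (data.frame of the
#'   planted differential islands: chrom, start, end, mark, sample, factor,
#'   gene_id).
#' @export
generate_chip_tags <- function(genes, quartiles, chrom_lengths, seed = 1,
                               n_signal = c(H3K4me3 = 7000, H3K4me1 = 15000,
                                            PolII = 20000, H3K27me3 = 40000),
                               n_background = 60000,
                               n_input = 100000,
                               candidate_genes = character(),
                               candidate_boost = 6,
                               mark_models = default_mark_models(),
                               k27_cancer_scale = 0.85) {
  set.seed(seed)
  stopifnot(all(genes$gene_id %in% names(quartiles)))
  if (is.null(names(n_signal)))
    n_signal <- stats::setNames(rep_len(n_signal, length(mark_models)),
                                names(mark_models))
  qt <- quartiles[genes$gene_id]
  gene_len <- genes$end - genes$start
  samples <- c("normal", "cancer")
  tags <- list()
  truth <- list()
  for (mark in names(mark_models)) {
    model <- mark_models[[mark]]
    tags[[mark]] <- list()
    for (smp in samples) {
      w <- unname(model$quartile_weight[qt])
      scale <- if (mark == "H3K27me3" && smp == "cancer") k27_cancer_scale else 1
      n_gene_tags <- as.vector(stats::rmultinom(
        1, round(n_signal[[mark]] * scale), w / sum(w)))
      chroms <- character(0); poss <- numeric(0)
      for (gi in seq_len(nrow(genes))) {
        ni <- n_gene_tags[gi]
        if (ni == 0) next
        dip <- mark == "H3K27me3" && smp == "cancer" && qt[gi] == "high"
        off <- draw_offsets(model, ni, gene_len[gi], dip = dip)
        pos <- if (genes$strand[gi] == "+") genes$tss[gi] + off
               else genes$tss[gi] - off
        chroms <- c(chroms, rep(genes$chrom[gi], ni))
        poss <- c(poss, pos)
      }
      pos <- round(poss)
      keep <- pos >= 0 & pos < chrom_lengths[chroms]
      chroms <- chroms[keep]; pos <- pos[keep]
      # uniform background
      nb <- round(n_background * scale)
      bg_chrom <- sample(names(chrom_lengths), nb, replace = TRUE,
                         prob = chrom_lengths / sum(chrom_lengths))
      bg_pos <- floor(stats::runif(nb) * chrom_lengths[bg_chrom])
      # planted candidate islands: add tags in the favored sample until the
      # expected library-normalized region fold equals candidate_boost
      extra_chrom <- character(0); extra_pos <- numeric(0)
      plant <- (mark == "PolII" && smp == "cancer") ||
        (mark == "H3K27me3" && smp == "normal")
      if (plant && length(candidate_genes)) {
        G <- sum(chrom_lengths)
        n_sig <- n_signal[[mark]]
        other_scale <- if (mark == "H3K27me3") k27_cancer_scale else 1
        for (gid in candidate_genes) {
          gi <- which(genes$gene_id == gid)
          if (mark == "PolII") {
            r0 <- max(0, genes$tss[gi] - 1000); r1 <- genes$tss[gi] + 1000
          } else {
            r0 <- max(0, genes$start[gi] - 1000); r1 <- genes$end[gi] + 1000
          }
          L <- r1 - r0
          sig_here <- n_sig * w[gi] / sum(w)
          bg_here <- n_background * L / G
          other_content <- other_scale * (sig_here + bg_here)
          lib_ratio <- scale / other_scale   # this sample over the other
          target <- candidate_boost * other_content * lib_ratio
          n_extra <- max(0, round(target - scale * (sig_here + bg_here)))
          if (n_extra > 0) {
            p_extra <- if (mark == "PolII")
              pmin(pmax(round(stats::rnorm(n_extra, genes$tss[gi], 300)),
                        r0), r1 - 1)
            else floor(stats::runif(n_extra, r0, r1))
            extra_chrom <- c(extra_chrom, rep(genes$chrom[gi], n_extra))
            extra_pos <- c(extra_pos, p_extra)
          }
        }
      }
      df <- data.frame(chrom = c(chroms, bg_chrom, extra_chrom),
                       pos = c(pos, bg_pos, extra_pos),
                       strand = sample(c("+", "-"),
                                       length(pos) + nb + length(extra_pos),
                                       replace = TRUE),
                       stringsAsFactors = FALSE)
      tags[[mark]][[smp]] <- tag_set(df, mark, smp)
    }
  }
  tags$input <- list()
  for (smp in samples) {
    bg_chrom <- sample(names(chrom_lengths), n_input, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
    bg_pos <- floor(stats::runif(n_input) * chrom_lengths[bg_chrom])
    tags$input[[smp]] <- tag_set(
      data.frame(chrom = bg_chrom, pos = bg_pos,
                 strand = sample(c("+", "-"), n_input, replace = TRUE),
                 stringsAsFactors = FALSE), "input", smp)
  }
  for (gid in candidate_genes) {
    g <- genes[genes$gene_id == gid, ]
    truth[[length(truth) + 1]] <- data.frame(
      chrom = g$chrom, start = max(0, g$tss - 1000), end = g$tss + 1000,
      mark = "PolII", sample = "cancer", factor = candidate_boost,
      gene_id = gid, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      chrom = g$chrom, start = max(0, g$start - 1000), end = g$end + 1000,
      mark = "H3K27me3", sample = "normal", factor = candidate_boost,
      gene_id = gid, stringsAsFactors = FALSE)
  }
  island_truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mark = character(), sample = character(), factor = numeric(),
               gene_id = character())
  list(tags = tags, island_truth = island_truth)
}

#' Generate copy-number segments for the cancer-like line
#'
#' Lays out non-overlapping gain / loss / CNLOH segments over the toy genome,
#' including a pair of same-state segments about 0.5 Mb apart (exercising the
#' <1 Mb merge rule) and a loss segment (exercising island exclusion). The
#' remainder of the genome is copy-neutral.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed RNG seed.
#' @return data.frame chrom/start/end/state, sorted, non-overlapping.
#' @export
generate_cna <- function(chrom_lengths, seed = 1) {
  set.seed(seed)
  segs <- list()
  jit <- function(x, s = 2e4) max(0, round(x + stats::runif(1, -s, s)))
  c1 <- names(chrom_lengths)[1]
  L1 <- chrom_lengths[[1]]
  u <- L1 / 3e6   # scale layout to chromosome size
  add <- function(chrom, s, e, st)
    segs[[length(segs) + 1]] <<- data.frame(chrom = chrom, start = s, end = e,
                                            state = st,
                                            stringsAsFactors = FALSE)
  # same-state pair 0.5 Mb apart -> merge target
  a1 <- jit(0.10e6 * u); a2 <- a1 + round(0.35e6 * u)
  b1 <- a2 + 5e5; b2 <- b1 + round(0.30e6 * u)
  add(c1, a1, a2, "gain"); add(c1, b1, b2, "gain")
  add(c1, jit(1.60e6 * u), jit(2.00e6 * u), "CNLOH")
  add(c1, jit(2.30e6 * u), jit(2.60e6 * u), "loss")
  if (length(chrom_lengths) > 1) {
    c2 <- names(chrom_lengths)[2]
    u2 <- chrom_lengths[[2]] / 3e6
    add(c2, jit(0.40e6 * u2), jit(0.90e6 * u2), "gain")
    add(c2, jit(1.50e6 * u2), jit(1.90e6 * u2), "CNLOH")
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a qPCR Cq plate with a planted group effect
#'
#' Cq = baseline - log2(expression) + sample shift + noise; housekeeping
#' assays have constant expression across groups, so the ddCt chain
#' (housekeeping normalization then reference-group normalization) recovers
#' the planted ratio exactly when `noise_sd = 0`.
#'
#' @param genes_assayed character vector of target assay names.
#' @param effect named (or recycled) ratio of group-2 to group-1 expression
#'   per target.
#' @param n_per_group samples per group.
#' @param groups two group labels; the first is the reference group.
#' @param housekeeping exactly two housekeeping assay names.
#' @param noise_sd Gaussian Cq noise, cycles.
#' @param n_rep technical replicates per (sample, assay).
#' @param seed RNG seed.
#' @return list with `cq` (long data.frame sample/group/assay/replicate/cq)
#'   and `truth` (assay -> planted ratio).
#' @export
generate_qpcr <- function(genes_assayed, effect = 2, n_per_group = 10,
                          groups = c("normal", "tumor"),
                          housekeeping = c("HK1", "HK2"),
                          noise_sd = 0.25, n_rep = 3, seed = 1) {
  stopifnot(length(housekeeping) == 2, length(groups) == 2)
  set.seed(seed)
  effect <- rep_len(effect, length(genes_assayed))
  names(effect) <- genes_assayed
  assays <- c(genes_assayed, housekeeping)
  baseline <- stats::setNames(stats::runif(length(assays), 18, 26), assays)
  samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
               paste0(groups[2], "_", seq_len(n_per_group)))
  grp <- rep(groups, each = n_per_group)
  shift <- stats::rnorm(length(samples), 0, 0.3)   # plate/loading shift
  rows <- list()
  for (si in seq_along(samples)) {
    for (a in assays) {
      expr <- if (a %in% housekeeping) 1
              else if (grp[si] == groups[2]) effect[[a]] else 1
      for (r in seq_len(n_rep)) {
        cq <- baseline[[a]] - log2(expr) + shift[si] +
          stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample = samples[si], group = grp[si], assay = a, replicate = r,
          cq = cq, stringsAsFactors = FALSE)
      }
    }
  }
  list(cq = do.call(rbind, rows),
       truth = as.list(effect))
}
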