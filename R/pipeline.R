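# End-to-end orchestration: make_demo() writes a complete synthetic study
# (annotation, tags, counts, CNA, qPCR, truth, config); run_pipeline() runs
# expression -> islands -> profiles -> cna_bias -> prioritize from a config
# and writes per-stage TSV/BED outputs plus a JSON manifest.

CHIP_MARK_SET <- c("H3K4me1", "H3K4me3", "H3K27me3", "PolII")

default_config <- function(outdir, seed) {
  list(
    seed = seed,
    outdir = outdir,
    chrom_lengths = NULL,            # named list, filled by make_demo
    paths = list(),                  # annotation/tags/counts/cna/cq
    de = list(fdr_alpha = 0.05, fc_threshold = 3, threshold_rpkm = 1),
    islands = list(window_bp = 200, gap_default = 200, gap_broad = 600,
                   effective_genome_fraction = 0.81, island_fdr = 0.001,
                   eligible_tail = 0.20, diff_fold = 3, diff_fdr = 0.05),
    profiles = list(flank_bp = 5000, bin_bp = 25, trim_alpha = 1e-5),
    candidates = list(window_bp = 5000, fc = 3, require_fdr = TRUE),
    qpcr = list(housekeeping = c("HK1", "HK2"), reference_group = "normal")
  )
}

params_for_mark <- function(cfg, mark) {
  ic <- cfg$islands
  island_params(mark = mark, window_bp = ic$window_bp,
                gap_bp = if (mark == "H3K27me3") ic$gap_broad else
                  ic$gap_default,
                effective_genome_fraction = ic$effective_genome_fraction,
                island_fdr = ic$island_fdr, eligible_tail = ic$eligible_tail,
                diff_fold = ic$diff_fold, diff_fdr = ic$diff_fdr)
}

#' Write a complete synthetic demo study to disk
#'
#' Generates a toy genome, expression counts with planted DE genes,
#' ChIP/input tag sets with planted differential islands at a set of
#' candidate genes chosen to satisfy all three selection criteria by
#' construction, CNA segments, and a qPCR plate for the candidates; writes
#' everything in the interchange formats the readers consume, a
#' `truth.json` recording all planted parameters, and a `config.yaml`
#' ready for [run_pipeline()].
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; per-generator seeds are derived from it.
#' @param n_genes,n_chrom,chrom_length_bp genome scale.
#' @param n_de planted DE genes.
#' @param n_candidates planted candidate genes.
#' @return the config (invisibly written to `config.yaml`).
#' @export
make_demo <- function(outdir, seed = 1, n_genes = 200, n_chrom = 2,
                      chrom_length_bp = 3e6, n_de = 40, n_candidates = 4) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sub_seed <- function(k) (seed * 101 + k) %% .Machine$integer.max
  genes <- generate_genome(n_chrom, chrom_length_bp, n_genes, sub_seed(1))
  chrom_lengths <- stats::setNames(rep(chrom_length_bp, n_chrom),
                                   unique(genes$chrom))
  cna <- generate_cna(chrom_lengths, sub_seed(2))

  expr <- generate_expression(genes, n_de = n_de, seed = sub_seed(3))
  # candidates: strongly up-regulated planted DE genes outside loss segments
  up <- expr$truth[expr$truth$fc >= 6, , drop = FALSE]
  loss <- cna[cna$state == "loss", , drop = FALSE]
  gidx <- match(up$gene_id, genes$gene_id)
  mid <- interval_midpoint(genes$start[gidx], genes$end[gidx])
  in_loss <- rep(FALSE, nrow(up))
  for (i in seq_len(nrow(loss)))
    in_loss <- in_loss | (genes$chrom[gidx] == loss$chrom[i] &
                          mid >= loss$start[i] & mid < loss$end[i])
  pool <- up$gene_id[!in_loss]
  if (length(pool) < n_candidates)
    stop("not enough strongly up-regulated genes to plant candidates")
  set.seed(sub_seed(4))
  candidates <- sort(sample(pool, n_candidates))

  rpkm_a <- compute_rpkm(expr$counts$count_a, genes$exon_length_bp,
                         sum(expr$counts$count_a))
  quartiles <- assign_quartiles(rpkm_a, genes$gene_id)
  chip <- generate_chip_tags(genes, quartiles, chrom_lengths,
                             seed = sub_seed(5),
                             candidate_genes = candidates)
  qpcr <- generate_qpcr(candidates, effect = 2, seed = sub_seed(6))

  paths <- list(annotation = file.path(outdir, "genes.bed"),
                counts = file.path(outdir, "counts.tsv"),
                cna = file.path(outdir, "cna.tsv"),
                cq = file.path(outdir, "qpcr.tsv"),
                tags = list())
  write_gene_models(genes, paths$annotation)
  write_tsv(expr$counts, paths$counts)
  write_cna_segments(cna, paths$cna)
  write_tsv(qpcr$cq, paths$cq)
  for (mark in c(CHIP_MARK_SET, "input")) {
    paths$tags[[mark]] <- list()
    for (smp in c("normal", "cancer")) {
      p <- file.path(outdir, sprintf("tags_%s_%s.bed", mark, smp))
      write_tags(chip$tags[[mark]][[smp]], p)
      paths$tags[[mark]][[smp]] <- p
    }
  }
  truth <- list(seed = seed,
                de_genes = stats::setNames(as.list(expr$truth$log2fc),
                                           expr$truth$gene_id),
                candidate_genes = candidates,
                island_truth = chip$island_truth,
                cna_truth = cna,
                qpcr_truth = qpcr$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- default_config(outdir, seed)
  cfg$chrom_lengths <- as.list(chrom_lengths)
  cfg$paths <- paths
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(cfg)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Run the full pipeline from a config
#'
#' Stages run in dependency order: expression (RPKM, filter, TMM, Fisher,
#' DE calls) -> differential islands per mark -> quartile TSS metagene
#' profiles -> CNA merge / loss exclusion / mapping-bias test (skipped with
#' a warning when no CNA file is configured) -> 3-criterion candidate
#' selection -> ddCt on the qPCR plate (skipped when absent). All outputs
#' are written under `<outdir>/results` and a `manifest.json` records
#' parameters, input hashes and per-stage row counts.
#'
#' @param config path to a YAML config or the config list itself (see
#'   [make_demo()]).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  outdir <- file.path(cfg$outdir, "results")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  chrom_lengths <- unlist(cfg$chrom_lengths)
  manifest <- list(parameters = cfg[c("de", "islands", "profiles",
                                      "candidates", "qpcr")],
                   seed = cfg$seed,
                   inputs = lapply(
                     Filter(is.character, unlist(cfg$paths)),
                     function(p) unname(tools::md5sum(p))),
                   stages = list())
  res <- list()

  # --- expression ---
  genes <- read_gene_models(cfg$paths$annotation)
  counts <- read_count_table(cfg$paths$counts)
  names(counts)[2:3] <- c("count_a", "count_b")
  rec <- expression_table(counts, genes,
                          threshold_rpkm = cfg$de$threshold_rpkm)
  rec <- call_de(rec, cfg$de$fdr_alpha, cfg$de$fc_threshold)
  write_tsv(rec, file.path(outdir, "expression.tsv"))
  res$expression <- rec
  manifest$stages$expression <- list(
    n_tested = nrow(rec), n_up = sum(rec$de_call == "up"),
    n_down = sum(rec$de_call == "down"),
    tmm_factor = attr(rec, "tmm_factor"))

  # --- islands (differential, cancer vs normal, per mark) ---
  tagset <- function(mark, smp) read_tags(cfg$paths$tags[[mark]][[smp]],
                                          mark, smp)
  diff <- list()
  for (mark in CHIP_MARK_SET) {
    pars <- params_for_mark(cfg, mark)
    diff[[mark]] <- differential_islands(
      tagset(mark, "cancer"), tagset(mark, "normal"), pars, chrom_lengths,
      input_a = tagset("input", "cancer"), input_b = tagset("input", "normal"))
    write_islands(diff[[mark]],
                  file.path(outdir, sprintf("diff_islands_%s.bed", mark)))
  }
  res$differential_islands <- diff
  summ <- summarize_differential(diff)
  write_tsv(summ, file.path(outdir, "differential_summary.tsv"))
  res$differential_summary <- summ
  manifest$stages$islands <- stats::setNames(
    lapply(diff, nrow), names(diff))

  # --- profiles ---
  rpkm_a <- res$expression
  quart <- assign_quartiles(
    compute_rpkm(counts$count_a, genes$exon_length_bp, sum(counts$count_a)),
    genes$gene_id)
  profs <- list()
  for (mark in CHIP_MARK_SET) {
    for (smp in c("normal", "cancer")) {
      profs[[paste(mark, smp, sep = "_")]] <-
        metagene_profiles(tagset(mark, smp), genes, quart, chrom_lengths,
                          flank_bp = cfg$profiles$flank_bp,
                          bin_bp = cfg$profiles$bin_bp,
                          trim_alpha = cfg$profiles$trim_alpha)
    }
  }
  prof_all <- do.call(rbind, profs)
  rownames(prof_all) <- NULL
  write_tsv(prof_all, file.path(outdir, "profiles.tsv"))
  res$profiles <- prof_all
  manifest$stages$profiles <- list(n_rows = nrow(prof_all))

  # --- cna_bias ---
  if (!is.null(cfg$paths$cna) && file.exists(cfg$paths$cna)) {
    cna <- merge_cna(read_cna_segments(cfg$paths$cna))
    excl_pol <- exclude_lost(diff$PolII, cna)
    excl_k27 <- exclude_lost(diff$H3K27me3, cna)
    diff$PolII <- excl_pol$retained
    diff$H3K27me3 <- excl_k27$retained
    bias <- list(PolII = cna_bias_report(diff$PolII, cna, chrom_lengths),
                 H3K27me3 = cna_bias_report(diff$H3K27me3, cna,
                                            chrom_lengths))
    for (mark in names(bias)) {
      write_tsv(bias[[mark]]$densities,
                file.path(outdir, sprintf("cna_density_%s.tsv", mark)))
      write_tsv(bias[[mark]]$tests,
                file.path(outdir, sprintf("cna_tests_%s.tsv", mark)))
    }
    res$cna <- list(segments = cna, bias = bias,
                    excluded = list(PolII = excl_pol[-1],
                                    H3K27me3 = excl_k27[-1]))
    manifest$stages$cna_bias <- list(
      n_segments = nrow(cna),
      excluded_polII = excl_pol$excluded_count,
      excluded_k27 = excl_k27$excluded_count)
  } else {
    warning("no CNA segment file configured; cna_bias stage skipped")
    manifest$stages$cna_bias <- "skipped"
  }

  # --- prioritize ---
  cand <- select_candidates(res$expression, diff$PolII, diff$H3K27me3,
                            genes, window_bp = cfg$candidates$window_bp,
                            fc = cfg$candidates$fc,
                            require_fdr = cfg$candidates$require_fdr)
  write_tsv(cand, file.path(outdir, "candidates.tsv"))
  res$candidates <- cand
  manifest$stages$prioritize <- list(n_candidates = nrow(cand))

  if (!is.null(cfg$paths$cq) && file.exists(cfg$paths$cq)) {
    cq <- read_cq_table(cfg$paths$cq)
    targets <- setdiff(unique(cq$assay), cfg$qpcr$housekeeping)
    qres <- lapply(stats::setNames(targets, targets), function(tg) {
      rel <- ddct(cq, tg, cfg$qpcr$housekeeping, cfg$qpcr$reference_group)
      cmp <- compare_groups(rel$rel_expr, rel$group,
                            cfg$qpcr$reference_group)
      list(relative = rel, fold_change = cmp$fold_change,
           p_value = cmp$p_value)
    })
    qtab <- data.frame(assay = names(qres),
                       fold_change = vapply(qres, `[[`, 0, "fold_change"),
                       p_value = vapply(qres, `[[`, 0, "p_value"))
    write_tsv(qtab, file.path(outdir, "qpcr_results.tsv"))
    res$qpcr <- qres
    manifest$stages$qpcr <- list(n_targets = length(qres))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
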