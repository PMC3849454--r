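chrom1 <- c(chr1 = 1e6)

test_that("eligible windows separated by at most the gap merge into one island", {
  # two hot windows [0,200) and [400,600) plus diffuse background
  set.seed(1)
  pos <- c(sample(0:199, 60, replace = TRUE),
           sample(400:599, 60, replace = TRUE),
           floor(5000 + runif(3000) * (1e6 - 5000)))  # background clear of the pair
  chip <- make_tags(pos)
  pars <- island_params("PolII", gap_bp = 200, island_fdr = 1)
  isl <- call_islands(chip, NULL, pars, chrom1)
  hit <- isl[isl$start < 600 & isl$end > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(0, 600))
  # with gap 0 the same windows stay separate
  pars0 <- island_params("PolII", gap_bp = 0, island_fdr = 1)
  isl0 <- call_islands(chip, NULL, pars0, chrom1)
  expect_equal(nrow(isl0[isl0$start < 600 & isl0$end > 0, ]), 2)
})

test_that("islands tile whole windows and never overlap", {
  set.seed(2)
  chip <- make_tags(c(floor(runif(20000) * 1e6),
                      round(rnorm(2000, 5e5, 2000))))
  inp <- make_tags(floor(runif(20000) * 1e6), mark = "input")
  pars <- island_params("H3K4me3")
  isl <- call_islands(chip, inp, pars, chrom1)
  expect_true(all((isl$end - isl$start) %% pars$window_bp == 0))
  if (nrow(isl) > 1) {
    o <- order(isl$start)
    expect_true(all(isl$start[o][-1] >= isl$end[o][-nrow(isl)]))
  }
})

test_that("a planted 10x 2-kb region is recovered as one island covering >=80%", {
  set.seed(3)
  lambda_bg <- 20000 / 1e6 * 200      # background tags per window
  planted <- c(60e4, 60e4 + 2000)
  n_plant <- round(10 * lambda_bg * 10)  # 10x background over 10 windows
  chip <- make_tags(c(floor(runif(20000) * 1e6),
                      sample(planted[1]:(planted[2] - 1), n_plant,
                             replace = TRUE)))
  inp <- make_tags(floor(runif(20000) * 1e6), mark = "input")
  isl <- call_islands(chip, inp, island_params("PolII"), chrom1)
  hits <- isl[isl$end > planted[1] & isl$start < planted[2], ]
  expect_equal(nrow(hits), 1)
  covered <- min(hits$end, planted[2]) - max(hits$start, planted[1])
  expect_gte(covered / 2000, 0.8)
})

test_that("pure background yields no islands at the default FDR", {
  set.seed(4)
  n_false <- vapply(1:10, function(i) {
    chip <- make_tags(floor(runif(50000) * 1e6))
    inp <- make_tags(floor(runif(50000) * 1e6), mark = "input")
    nrow(call_islands(chip, inp, island_params("H3K4me3"), chrom1))
  }, 0)
  expect_gte(mean(n_false == 0), 0.9)
})

test_that("differential islands are antisymmetric and silent under equality", {
  set.seed(5)
  base <- c(floor(runif(30000) * 1e6), round(rnorm(3000, 3e5, 1000)))
  a <- make_tags(c(base, round(rnorm(2500, 7e5, 800))), sample = "a")
  b <- make_tags(base, sample = "b")
  pars <- island_params("PolII")
  ab <- differential_islands(a, b, pars, chrom1)
  ba <- differential_islands(b, a, pars, chrom1)
  expect_equal(nrow(ab), nrow(ba))
  if (nrow(ab) > 0) {
    expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_true(all(ab$direction != ba$direction))
  }
  # identical samples: nothing passes the 3-fold gate
  aa <- differential_islands(a, make_tags(a$tags$pos, sample = "b"),
                             pars, chrom1)
  expect_equal(nrow(aa), 0)
})

test_that("a planted 5x asymmetric region is emitted with a sane fold estimate", {
  set.seed(6)
  bg_a <- floor(runif(30000) * 1e6)
  bg_b <- floor(runif(30000) * 1e6)
  region <- 50e4:(50e4 + 1999)
  a <- make_tags(c(bg_a, sample(region, 600, replace = TRUE)), sample = "a")
  b <- make_tags(c(bg_b, sample(region, 120, replace = TRUE)), sample = "b")
  d <- differential_islands(a, b, island_params("PolII"), chrom1)
  hit <- d[d$end > 50e4 & d$start < 50e4 + 2000, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "increased")
  expect_gte(hit$fold_change, 3.5)
  expect_lte(hit$fold_change, 7)
})

test_that("direction summaries give percentages to one decimal, NA when empty", {
  mk <- function(n_inc, n_dec)
    data.frame(direction = rep(c("increased", "decreased"), c(n_inc, n_dec)))
  s <- summarize_differential(list(PolII = mk(42809, 16841),
                                   H3K27me3 = mk(2474, 10521),
                                   empty = mk(0, 0),
                                   one = mk(1, 0)))
  expect_equal(s$pct_increased, c(71.8, 19.0, NA, 100.0))
  expect_equal(s$pct_decreased, c(28.2, 81.0, NA, 0.0))
  ok <- !is.na(s$pct_increased)
  expect_true(all(abs(s$pct_increased[ok] + s$pct_decreased[ok] - 100) <= 0.1))
})

test_that("island annotation follows the precedence rules", {
  genes <- make_genes(
    data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
               start = c(10000, 40000), end = c(16000, 46000),
               strand = c("+", "-"),
               thick_start = c(11000, 41000), thick_end = c(15000, 45000)),
    exon_starts = list(c(10000, 12000, 14000), c(40000, 44000)),
    exon_ends = list(c(10500, 12500, 15800), c(40500, 46000)))
  isl <- data.frame(chrom = "chr1",
                    start = c(8900, 10100, 12100, 13000, 15300, 16500,
                              30000, 46500, 39000),
                    end = c(9100, 10300, 12300, 13200, 15500, 16700,
                            30200, 46700, 39200))
  ann <- annotate_islands(isl, genes)
  expect_equal(ann$category,
               c("promoter",        # 1 kb upstream of + TSS
                 "utr5",            # exonic before CDS on + strand
                 "coding_exon",
                 "intron",          # between exons, inside the gene
                 "utr3",            # exonic after CDS on + strand
                 "downstream",      # just past + gene end
                 "distal_intergenic",
                 "promoter",        # upstream of the - gene (right side)
                 "downstream"))     # past the - gene end (left side)
})

test_that("annotation of random islands equals a brute-force per-feature scan", {
  g <- generate_genome(1, 2e6, 30, seed = 9)
  set.seed(9)
  isl <- data.frame(chrom = "chr1", start = sort(sample(0:(2e6 - 300), 200)))
  isl$end <- isl$start + 200
  ann <- annotate_islands(isl, g, promoter_bp = 3000)
  # naive oracle: loop genes/features per island, track best precedence
  prec <- c(promoter = 1, utr5 = 2, utr3 = 3, coding_exon = 4, intron = 5,
            downstream = 6, distal_intergenic = 7)
  oracle <- character(nrow(isl))
  for (ii in seq_len(nrow(isl))) {
    mid <- floor((isl$start[ii] + isl$end[ii]) / 2)
    best <- "distal_intergenic"
    for (gi in seq_len(nrow(g))) {
      gg <- g[gi, ]
      if (gg$chrom != isl$chrom[ii]) next
      cand <- character(0)
      if (gg$strand == "+" && mid >= gg$tss - 3000 && mid < gg$tss)
        cand <- c(cand, "promoter")
      if (gg$strand == "-" && mid > gg$tss && mid <= gg$tss + 3000)
        cand <- c(cand, "promoter")
      es <- gg$exon_starts[[1]]; ee <- gg$exon_ends[[1]]
      in_ex <- any(mid >= es & mid < ee)
      if (in_ex) {
        if (mid < gg$thick_start)
          cand <- c(cand, if (gg$strand == "+") "utr5" else "utr3")
        else if (mid >= gg$thick_end)
          cand <- c(cand, if (gg$strand == "+") "utr3" else "utr5")
        else cand <- c(cand, "coding_exon")
      } else if (mid >= gg$start && mid < gg$end) {
        cand <- c(cand, "intron")
      }
      if (gg$strand == "+" && mid >= gg$end && mid < gg$end + 3000)
        cand <- c(cand, "downstream")
      if (gg$strand == "-" && mid >= gg$start - 3000 && mid < gg$start)
        cand <- c(cand, "downstream")
      for (cc in cand) if (prec[cc] < prec[best]) best <- cc
    }
    oracle[ii] <- best
  }
  expect_equal(ann$category, oracle)
})
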