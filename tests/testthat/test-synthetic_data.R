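test_that("genome generation is deterministic and respects conventions", {
  g1 <- generate_genome(1, 1e6, 20, seed = 7)
  g2 <- generate_genome(1, 1e6, 20, seed = 7)
  expect_identical(g1, g2)
  plus <- g1$strand == "+"
  expect_equal(g1$tss[plus], g1$start[plus])
  expect_equal(g1$tss[!plus], g1$end[!plus] - 1)
  # exon length equals brute-force sum over the exon list
  for (i in seq_len(nrow(g1)))
    expect_equal(g1$exon_length_bp[i],
                 sum(g1$exon_ends[[i]] - g1$exon_starts[[i]]))
  # genes do not overlap and exons stay inside their gene
  ord <- order(g1$chrom, g1$start)
  expect_true(all(diff(g1$start[ord]) > 0))
  same <- g1$chrom[ord][-1] == g1$chrom[ord][-20]
  expect_true(all(g1$end[ord][-20][same] <= g1$start[ord][-1][same]))
  expect_error(generate_genome(1, 1e5, 100, seed = 1), "capacity")
})

test_that("expression generator plants recoverable fold changes", {
  g <- generate_genome(1, 2e6, 60, seed = 2)
  # dispersion -> 0, one planted gene at FC 4, large counts: ratio within 10%
  e <- generate_expression(g, dispersion = 0, seed = 5,
                           library_sizes = c(a = 3e6, b = 3e6),
                           de_gene_ids = g$gene_id[1], de_fold = 4)
  i <- match(g$gene_id[1], e$counts$gene_id)
  expect_gt(e$counts$count_a[i], 500)
  ratio <- e$counts$count_b[i] / e$counts$count_a[i]
  expect_lt(abs(ratio - 4) / 4, 0.1)
  # no planted DE -> empty truth; same seed -> identical tables
  e0 <- generate_expression(g, n_de = 0, seed = 9)
  expect_equal(nrow(e0$truth), 0)
  expect_identical(generate_expression(g, seed = 3),
                   generate_expression(g, seed = 3))
})

test_that("ChIP generator reproduces the planted promoter geometry", {
  g <- generate_genome(1, 3e6, 80, seed = 4)
  rpkm <- seq_len(nrow(g))  # deterministic expression ranking
  qt <- assign_quartiles(rpkm, g$gene_id)
  cl <- c(chr1 = 3e6)
  chip <- generate_chip_tags(g, qt, cl, seed = 8, n_signal = 60000,
                             n_background = 20000, n_input = 50000)
  expect_identical(
    generate_chip_tags(g, qt, cl, seed = 8, n_signal = 60000,
                       n_background = 20000, n_input = 50000)$tags$PolII$normal,
    chip$tags$PolII$normal)
  # Pol II: modal 25-bp binned offset of top-quartile genes within 200 bp of TSS
  top <- g[qt[g$gene_id] == "high", ]
  pol <- chip$tags$PolII$normal$tags
  offs <- unlist(lapply(seq_len(nrow(top)), function(i) {
    p <- pol$pos[pol$chrom == top$chrom[i]]
    o <- if (top$strand[i] == "+") p - top$tss[i] else top$tss[i] - p
    o[abs(o) <= 5000]
  }))
  bins <- floor(offs / 25) * 25
  mode_bin <- as.numeric(names(which.max(table(bins))))
  expect_lte(abs(mode_bin), 200)
  # H3K27me3: higher density over bottom- than top-quartile gene bodies (normal)
  k27 <- chip$tags$H3K27me3$normal$tags
  body_density <- function(gs) {
    n <- sum(vapply(seq_len(nrow(gs)), function(i)
      sum(k27$pos >= gs$start[i] & k27$pos < gs$end[i] &
            k27$chrom == gs$chrom[i]), 0))
    n / sum(gs$end - gs$start)
  }
  expect_gt(body_density(g[qt[g$gene_id] == "very low", ]),
            body_density(g[qt[g$gene_id] == "high", ]))
})

test_that("input libraries are uniform: window counts match Poisson within 3 sigma", {
  g <- generate_genome(1, 2e6, 40, seed = 4)
  qt <- assign_quartiles(seq_len(nrow(g)), g$gene_id)
  chip <- generate_chip_tags(g, qt, c(chr1 = 2e6), seed = 10,
                             n_signal = 10000, n_background = 10000,
                             n_input = 80000)
  inp <- chip$tags$input$normal
  lambda <- inp$library_size * 10000 / 2e6
  cnt <- sum(inp$tags$pos >= 1.2e6 & inp$tags$pos < 1.21e6)
  expect_lt(abs(cnt - lambda), 3 * sqrt(lambda))
})

test_that("CNA generator lays out the states the merge/exclusion rules need", {
  cna <- generate_cna(c(chr1 = 3e6, chr2 = 3e6), seed = 6)
  expect_identical(generate_cna(c(chr1 = 3e6, chr2 = 3e6), seed = 6), cna)
  expect_true(all(c("gain", "loss", "CNLOH") %in% cna$state))
  # a same-state pair strictly under 1 Mb apart exists
  gaps <- sapply(split(cna, cna$chrom), function(s) {
    s <- s[order(s$start), ]
    if (nrow(s) < 2) return(FALSE)
    any(s$state[-1] == s$state[-nrow(s)] &
          s$start[-1] - s$end[-nrow(s)] < 1e6)
  })
  expect_true(any(gaps))
  # pairwise overlap scan: segments never overlap
  for (ch in unique(cna$chrom)) {
    s <- cna[cna$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("qPCR generator has the stated closed form", {
  # no effect, no noise: every ddCt ratio is 1
  q0 <- generate_qpcr("GENE1", effect = 1, noise_sd = 0, seed = 2)
  rel <- ddct(q0$cq, "GENE1", c("HK1", "HK2"), "normal")
  expect_equal(rel$rel_expr, rep(1, nrow(rel)))
  # effect 2, no noise: ratio of group geometric means is exactly 2
  q2 <- generate_qpcr("GENE1", effect = 2, noise_sd = 0, seed = 2)
  rel2 <- ddct(q2$cq, "GENE1", c("HK1", "HK2"), "normal")
  gm <- function(x) exp(mean(log(x)))
  expect_equal(gm(rel2$rel_expr[rel2$group == "tumor"]) /
                 gm(rel2$rel_expr[rel2$group == "normal"]), 2)
  expect_identical(generate_qpcr("G", seed = 4), generate_qpcr("G", seed = 4))
})
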