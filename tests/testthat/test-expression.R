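test_that("RPKM matches its formula, unit case and linearity", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 5000, 1e6), 0)
  set.seed(1)
  cnt <- rpois(50, 100); len <- sample(500:5000, 50); lib <- 2e6
  expect_equal(compute_rpkm(cnt, len, lib),
               vapply(1:50, function(i) cnt[i] * 1e9 / (len[i] * lib), 0))
  expect_equal(compute_rpkm(3 * cnt, len, lib), 3 * compute_rpkm(cnt, len, lib))
  expect_equal(compute_rpkm(cnt, 2 * len, lib), compute_rpkm(cnt, len, lib) / 2)
  expect_error(compute_rpkm(1, 0, 1e6), "exon_length")
})

test_that("the 1-RPKM filter keeps a gene expressed in at least one line", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    rpkm_a = c(0.5, 0.9, 3), rpkm_b = c(2.0, 0.9, 0))
  kept <- filter_expressed(rec)
  expect_setequal(kept$gene_id, c("a", "c"))
  set.seed(2)
  r <- data.frame(rpkm_a = runif(500, 0, 3), rpkm_b = runif(500, 0, 3))
  expect_equal(nrow(filter_expressed(r)),
               sum(sapply(1:500, function(i) r$rpkm_a[i] > 1 || r$rpkm_b[i] > 1)))
})

test_that("TMM factor identities hold and match a sort-and-average oracle", {
  set.seed(3)
  x <- rpois(200, 500) + 1
  expect_equal(tmm_factor(x, x), 1.0)
  expect_equal(tmm_factor(x, 2 * x), 2.0)
  y <- rpois(200, 500) + 1
  # independent oracle: explicit sorts of M and A, average the kept set
  M <- log2(y / x); A <- 0.5 * log2(as.numeric(y) * x)
  n <- length(M)
  keep_m <- order(M)[(floor(0.3 * n) + 1):(n - floor(0.3 * n))]
  keep_a <- order(A)[(floor(0.05 * n) + 1):(n - floor(0.05 * n))]
  sel <- intersect(keep_m, keep_a)
  w <- 1 / (1 / y[sel] + 1 / x[sel])
  expect_equal(tmm_factor(x, y), 2^(sum(w * M[sel]) / sum(w)))
})

test_that("TMM factor agrees with edgeR after removing the depth component", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  x <- rpois(500, 300) + 1
  y <- as.integer(rpois(500, 300) * exp(rnorm(500, 0, 0.1))) + 1
  f_edger <- unname(edgeR::calcNormFactors(cbind(x, y), refColumn = 1,
                                           method = "TMM")[2])
  depth <- sum(y) / sum(x)
  expect_equal(tmm_factor(x, y) / depth, f_edger, tolerance = 0.05)
})

test_that("Fisher exact DE matches enumeration and fisher.test, with monotone power", {
  expect_equal(fisher_de(5, 5, 100, 100), 1.0)
  expect_equal(fisher_de(10, 5, 110, 105), fisher_enum(10, 5, 110, 105))
  # cross-check against stats::fisher.test on a grid
  set.seed(5)
  for (i in 1:25) {
    la <- sample(50:300, 1); lb <- sample(50:300, 1)
    ca <- sample(0:min(40, la), 1); cb <- sample(0:min(40, lb), 1)
    ft <- fisher.test(matrix(c(ca, la - ca, cb, lb - cb), 2, byrow = TRUE))
    expect_equal(fisher_de(ca, cb, la, lb), ft$p.value, tolerance = 1e-9)
  }
  # scaling counts and libraries together increases power (grid check)
  for (mult in c(1, 2, 4, 8)) {
    p <- fisher_de(10 * mult, 5 * mult, 100 * mult, 100 * mult)
    if (mult > 1) expect_lt(p, p_prev)
    p_prev <- p
  }
  expect_error(fisher_de(200, 5, 100, 100), "exceeds")
})

test_that("DE calls apply the FDR and fold-change gates conjunctively", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    fold_change = c(2.9, 4, 4, 0.25),
                    p_value = c(1e-6, 0.06, 1e-6, 1e-6))
  out <- call_de(rec, fdr_alpha = 0.05, fc_threshold = 3)
  expect_equal(out$de_call, c("none", "none", "up", "down"))
  # BH equals brute-force step-up on sorted p-values
  set.seed(6)
  p <- runif(100)^2
  m <- length(p); o <- order(p)
  stepup <- numeric(m)
  stepup[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(p.adjust(p, "BH"), pmin(1, stepup))
})

test_that("expression_table wires counts, RPKM, fold change and p together", {
  g <- generate_genome(1, 2e6, 40, seed = 7)
  e <- generate_expression(g, n_de = 6, seed = 7)
  rec <- expression_table(e$counts, g)
  expect_true(all(rec$rpkm_a > 1 | rec$rpkm_b > 1))
  expect_true(all(rec$fold_change > 0))
  expect_gt(attr(rec, "tmm_factor"), 0)
  called <- call_de(rec)
  recovered <- called$gene_id[called$de_call != "none"]
  expect_gte(mean(e$truth$gene_id %in% recovered), 0.9)
})

test_that("miRNA chi-square DE matches the hand formula, Bonferroni and fallback", {
  rec <- data.frame(gene_id = c("m1", "m2", "m3"),
                    count_a = c(50, 100, 0), count_b = c(50, 10, 1),
                    rpkm_a = c(5, 5, 0.2), rpkm_b = c(5, 1, 2),
                    fold_change = c(1, 0.1, 8))
  out <- mirna_de(rec, library_sizes = c(1e4, 1e4))
  expect_equal(out$p_value[1], 1)             # identical proportions
  expect_equal(out$de_call[1], "none")
  # hand Pearson formula on gene m2's 2x2
  o <- c(100, 1e4 - 100, 10, 1e4 - 10)
  k <- 110; N <- 2e4
  e <- c(k * 1e4 / N, (N - k) * 1e4 / N, k * 1e4 / N, (N - k) * 1e4 / N)
  expect_equal(out$chisq_stat[2], sum((o - e)^2 / e))
  expect_true(out$fisher_fallback[3])         # expected cell < 1
  expect_equal(out$p_bonferroni, pmin(1, 3 * out$p_value))
})

test_that("Wallenius tail reduces to hypergeometric at odds 1 and degenerates sanely", {
  expect_equal(pwallenius_upper(4, 5, 15, 6, 1),
               phyper(3, 5, 15, 6, lower.tail = FALSE))
  expect_equal(pwallenius_upper(0, 5, 15, 6, 2), 1)
  expect_equal(pwallenius_upper(7, 5, 15, 6, 2), 0)
  # category containing every gene: p = 1 at any observed count
  enr <- length_bias_enrichment(
    de_flags = c(rep(TRUE, 6), rep(FALSE, 14)),
    gene_lengths = seq(500, 10000, length.out = 20),
    category_map = data.frame(gene_id = sprintf("g%02d", 1:20),
                              category = "all"),
    gene_ids = sprintf("g%02d", 1:20))
  expect_equal(enr$p_value, 1)
})

test_that("Wallenius tail matches Monte-Carlo urn sampling on a fixed scenario", {
  # N = 20 genes, category of 5, 6 DE draws, odds 2
  m1 <- 5; m2 <- 15; n <- 6; odds <- 2; x_obs <- 3
  p <- pwallenius_upper(x_obs, m1, m2, n, odds)
  set.seed(99)
  w <- c(rep(odds, m1), rep(1, m2))
  nrep <- 2e5
  hits <- vapply(seq_len(nrep), function(i)
    sum(sample.int(m1 + m2, n, prob = w) <= m1) >= x_obs, NA)
  mc <- mean(hits)
  se <- sqrt(mc * (1 - mc) / nrep)
  expect_lt(abs(p - mc), 3 * se)
})

test_that("length-biased enrichment flags a planted long-gene category", {
  set.seed(8)
  n <- 400
  len <- exp(runif(n, log(500), log(2e4)))
  p_de <- pmin(0.9, 0.05 + len / 4e4)        # DE probability grows with length
  de <- runif(n) < p_de
  ids <- sprintf("g%03d", 1:n)
  # category A: random 40 genes enriched among DE beyond the length effect
  de_ids <- ids[de]
  catA <- c(sample(de_ids, 25), sample(setdiff(ids, de_ids), 15))
  catB <- sample(ids, 40)
  cmap <- rbind(data.frame(gene_id = catA, category = "A"),
                data.frame(gene_id = catB, category = "B"),
                data.frame(gene_id = character(), category = character()))
  enr <- length_bias_enrichment(de, len, cmap, ids)
  expect_lt(enr$p_value[enr$category == "A"], 0.01)
  expect_gt(enr$p_value[enr$category == "B"], 0.01)
})
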