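test_that("pileup counts bases, excludes clipped tails, handles zero coverage", {
  fx <- tiny_fixture()
  f <- fx$gene$feature
  reads <- data.frame(read_id = paste0("r", 1:10),
                      sequence = rep(fx$gene_seq, 10))
  aln <- map_reads(reads, fx$genome)
  pf <- pileup(aln, fx$genome, list(fx$gene), flank = 15L)
  body <- pf[pf$position >= 0 & pf$position < 72, ]
  expect_equal(nrow(pf), 72L + 30L)
  expect_true(all(body$depth == 10))
  expect_true(all(body$mismatch_fraction == 0))
  flank <- pf[pf$position < 0, ]
  expect_true(all(flank$depth == 0))
  expect_true(all(is.na(flank$mismatch_fraction)))
})

test_that("a 1-in-10 substitution gives mismatch fraction 0.1", {
  fx <- tiny_fixture()
  ref_base <- substr(fx$gene_seq, 21, 21)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  variant <- fx$gene_seq
  substr(variant, 21, 21) <- alt
  reads <- data.frame(read_id = paste0("r", 1:10),
                      sequence = c(rep(fx$gene_seq, 9), variant))
  aln <- map_reads(reads, fx$genome)
  pf <- pileup(aln, fx$genome, list(fx$gene))
  site <- pf[pf$position == 20, ]
  expect_equal(site$depth, 10)
  expect_equal(site$mismatch_fraction, 0.1)
  expect_equal(site[[paste0("count_", alt)]], 1)
})

test_that("pileup conserves fractional read counts at covered sites", {
  set.seed(31)
  core <- random_dna(60)
  seq <- paste0(random_dna(40), core, random_dna(60), core, random_dna(40))
  f <- feature(c("t1", "t2"), c("tRNA", "tRNA"), c(40L, 160L), c(100L, 220L),
               c("+", "+"))
  g <- genome("dup", seq, annotations = f)
  genes <- list(trna_gene(f[1, ], "Gly", substr(core, 35, 37), 34L, genome = g),
                trna_gene(f[2, ], "Gly", substr(core, 35, 37), 34L, genome = g))
  aln <- map_reads(data.frame(read_id = "m1", sequence = core), g)
  expect_equal(aln$mapq_class, c("multi", "multi"))
  pf <- pileup(aln, g, genes)
  site <- pf[pf$gene_id == "t1" & pf$position == 10, ]
  expect_equal(site$depth, 0.5)   # 1/k fractional count
  total <- sum(pf$depth[pf$position >= 0 & pf$position < 60])
  expect_equal(total, 60)         # one read's worth of bases over both loci
})

test_that("minus-strand genes are piled up in gene orientation", {
  s <- shared_toy_sim()
  phe <- s$toy$trna_genes[[2]]
  expect_equal(phe$feature$strand, "-")
  pf <- pileup(s$aln, s$toy$genome, list(phe))
  site <- pf[pf$position == 26, ]   # planted site, gene-oriented coordinates
  expect_gt(site$mismatch_fraction, 0.02)
  other <- pf[pf$position %in% c(5, 12, 45) , ]
  expect_true(all(other$mismatch_fraction < 0.01))
})

test_that("modification calling applies both thresholds strictly", {
  prof <- data.frame(gene_id = "g", position = 0:3, ref_base = "A",
                     count_A = c(4.5, 98, 97, 50), count_C = c(4.5, 2, 3, 0),
                     count_G = 0, count_T = 0,
                     depth = c(9, 100, 100, 50),
                     mismatch_fraction = c(0.5, 0.02, 0.03, 0))
  calls <- call_modifications(prof)
  expect_equal(calls$position, 2L)       # depth 9 skipped; exactly 2% skipped
  expect_equal(calls$alt_base, "C")
  expect_equal(nrow(call_modifications(prof, min_depth = 200)), 0L)
})

test_that("calls are monotone in both thresholds", {
  set.seed(32)
  prof <- data.frame(gene_id = "g", position = 0:199, ref_base = "A",
                     count_C = 0, count_G = 0, count_T = 0)
  prof$depth <- sample(0:60, 200, replace = TRUE)
  mism <- pmin(prof$depth, rpois(200, 1))
  prof$count_A <- prof$depth - mism
  prof$count_C <- mism
  prof$mismatch_fraction <- ifelse(prof$depth > 0, mism / prof$depth, NA)
  base <- nrow(call_modifications(prof, min_depth = 5, min_freq = 0.01))
  for (d in c(10, 20, 40)) {
    for (f in c(0.02, 0.05, 0.2)) {
      expect_lte(nrow(call_modifications(prof, min_depth = d, min_freq = f)),
                 base)
    }
  }
  # min_freq = 0 returns every covered site with any mismatch
  all_calls <- call_modifications(prof, min_depth = 1, min_freq = 0)
  expect_equal(nrow(all_calls), sum(prof$depth > 0 & mism > 0))
})

test_that("relative_abundance normalizes and rejects empty totals", {
  expect_equal(relative_abundance(c(a = 3, b = 1)), c(a = 0.75, b = 0.25))
  expect_equal(unname(relative_abundance(c(x = 7))), 1)
  expect_equal(unname(relative_abundance(c(a = 2, b = 2, c = 2))),
               rep(1 / 3, 3))
  expect_error(relative_abundance(c(a = 0, b = 0)), "zero")
  expect_error(relative_abundance(c(a = -1, b = 2)))
})

test_that("spearman matches closed-form and handles degenerate input", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 2, 4, 3))$rho, 0.8)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rho))
  expect_error(spearman(1:2, 1:2))
})

test_that("spearman rho agrees with the midrank oracle and cor.test", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    a <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01 * (i %% 2))
    b <- sample(1:8, n, replace = TRUE)
    sp <- spearman(a, b)
    if (is.na(sp$rho)) next
    expect_equal(sp$rho, oracle_spearman_rho(a, b), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("exact permutation p-values behave sensibly at small n", {
  sp <- spearman(1:6, 1:6)
  expect_equal(sp$p_value, 2 / factorial(6))  # only the two perfect orderings
  sp2 <- spearman(c(3, 1, 2, 5, 4), c(2, 3, 1, 4, 5))
  expect_gte(sp2$p_value, 0)
  expect_lte(sp2$p_value, 1)
  # large-n approximation is small for strongly monotone data
  expect_lt(spearman(1:20, (1:20)^2)$p_value, 1e-10)
})

test_that("signed_ratio is a symmetric fold change", {
  expect_equal(signed_ratio(0.2, 0.2), 1)
  expect_equal(signed_ratio(0.4, 0.2), 2)
  expect_equal(signed_ratio(0.2, 0.4), -2)
  expect_warning(out <- signed_ratio(c(1, 2), c(0, 1)), "zero")
  expect_true(is.na(out[1]))
  set.seed(34)
  a <- runif(50, 0.01, 1); b <- runif(50, 0.01, 1)
  expect_equal(signed_ratio(a, b), -signed_ratio(b, a))
  expect_true(all(abs(signed_ratio(a, b)) >= 1))
})

test_that("compare_libraries ties the pieces together", {
  ca <- c(g1 = 100, g2 = 50, g3 = 25)
  cb <- c(g1 = 90, g2 = 60, g3 = 30)
  cmp <- compare_libraries(ca, cb)
  expect_equal(sum(cmp$per_gene$rel_a), 1)
  expect_equal(sum(cmp$per_gene$rel_b), 1)
  expect_equal(cmp$spearman_rho, 1)
  expect_true(all(abs(cmp$per_gene$signed_ratio) >= 1))
})
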