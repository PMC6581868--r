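mk_aln <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(read_id = r$id, sequence = r$seq, reference_id = r$ref,
               ref_start = r$start, strand = r$strand %||% "+",
               aligned_length = r$alen %||% nchar(r$seq),
               n_mismatch = 0L, mismatch_positions = "",
               soft_clip_3 = r$clip %||% "", mapq_class = "unique",
               n_best = 1L, weight = r$w %||% 1, stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("coverage increments the right length class over the aligned span", {
  g <- genome("g", strrep("A", 100))
  aln <- mk_aln(list(id = "r1", seq = strrep("A", 20), ref = "g", start = 0L))
  trk <- coverage(aln, g)
  expect_equal(trk$depth[[1]][1:20], rep(1, 20))
  expect_equal(sum(trk$depth[[1]]), 20)
  expect_equal(sum(trk$depth[[2]]), 0)
  expect_equal(sum(trk$depth[[3]]), 0)
})

test_that("empty alignments give all-zero coverage", {
  g <- genome("g", strrep("A", 50))
  none <- mk_aln(list(id = "x", seq = strrep("A", 20), ref = "g", start = 0L))
  trk <- coverage(none[0, ], g)
  expect_true(all(vapply(trk$depth, sum, 0) == 0))
})

test_that("overlapping reads stack and clipped bases do not count", {
  g <- genome("g", strrep("A", 100))
  aln <- mk_aln(list(id = "r1", seq = strrep("A", 50), ref = "g", start = 0L),
                list(id = "r2", seq = strrep("A", 50), ref = "g", start = 30L),
                list(id = "r3", seq = paste0(strrep("A", 47), "CCA"), ref = "g",
                     start = 0L, alen = 47L, clip = "CCA"))
  trk <- coverage(aln, g)
  expect_equal(trk$depth[[2]][31:47], rep(3, 17))   # both 50-mers + clipped read
  expect_equal(trk$depth[[2]][48], 2)               # clipped tail absent
  # class-wise depths sum to all-read depth at every base
  all_depth <- pooled_depth <- Reduce(`+`, trk$depth)
  aln$weight <- 1
  expect_equal(sum(all_depth), 50 + 50 + 47)
})

test_that("background_level is the median over pooled CDS positions", {
  g <- genome("g", strrep("A", 100),
              annotations = feature(c("CDS_a", "CDS_b"), c("CDS", "CDS"),
                                    c(0L, 50L), c(10L, 60L), c("+", "+")))
  trk <- coverage(mk_aln(list(id = "r", seq = strrep("A", 20), ref = "g",
                              start = 0L, w = 5)), g)
  # positions 0-9 at depth 5, positions 50-59 at 0 -> median 2.5
  expect_equal(unname(background_level(trk, g$annotations)["pooled"]), 2.5)
  g2 <- genome("g2", strrep("A", 3),
               annotations = feature("CDS_c", "CDS", 0L, 3L, "+"))
  trk2 <- coverage(mk_aln(list(id = "r", seq = strrep("A", 18), ref = "g2",
                               start = 2L, alen = 1L, w = 10)), g2)
  expect_equal(unname(background_level(trk2, g2$annotations)["pooled"]), 0)
  expect_error(background_level(trk, feature("x", "tRNA", 0L, 5L, "+")),
               "background")
})

test_that("two equal-length CDSs at uniform depths 2 and 4 give median 3", {
  g <- genome("g", strrep("A", 200),
              annotations = feature(c("CDS_a", "CDS_b"), c("CDS", "CDS"),
                                    c(0L, 100L), c(50L, 150L), c("+", "+")))
  aln <- rbind(mk_aln(list(id = "a", seq = strrep("A", 50), ref = "g",
                           start = 0L, w = 2)),
               mk_aln(list(id = "b", seq = strrep("A", 50), ref = "g",
                           start = 100L, w = 4)))
  trk <- coverage(aln, g)
  expect_equal(unname(background_level(trk, g$annotations)["pooled"]), 3)
})

test_that("subtract_background floors at zero", {
  g <- genome("g", strrep("A", 30))
  trk <- coverage(mk_aln(list(id = "r", seq = strrep("A", 20), ref = "g",
                              start = 0L, w = 7)), g)
  sub <- subtract_background(trk, 5)
  expect_equal(sub$depth[[1]][1], 2)
  sub2 <- subtract_background(trk, c(25, 0, 0))
  expect_equal(sum(sub2$depth[[1]]), 0)
  expect_equal(subtract_background(trk, 0)$depth, trk$depth)
  expect_error(subtract_background(trk, -1))
})

test_that("flat coverage yields no spikes; a high block is intergenic", {
  ann <- feature("CDS_a", "CDS", 0L, 100L, "+")
  g <- genome("g", strrep("A", 300), annotations = ann)
  flat <- coverage(mk_aln(list(id = "r", seq = strrep("A", 100), ref = "g",
                               start = 0L, alen = 300L, w = 5)), g)
  expect_equal(nrow(detect_spikes(flat, ann)), 0L)

  aln <- rbind(mk_aln(list(id = "bg", seq = strrep("A", 30), ref = "g",
                           start = 0L, alen = 100L, w = 2)),
               mk_aln(list(id = "hot", seq = strrep("A", 40), ref = "g",
                           start = 199L, alen = 40L, w = 100)))
  trk <- coverage(aln, g)
  sp <- detect_spikes(trk, ann)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$annotation, "intergenic")
  expect_equal(sp$end - sp$start, 40L)
  expect_equal(sp$start, 199L)
})

test_that("a highly expressed unannotated locus is recovered as an intergenic spike", {
  toy <- build_toy_genome(seed = 77L, n_trna = 2L, n_hidden = 1L)
  hidden <- toy$hidden_genes[[1]]
  genes <- c(toy$trna_genes, toy$hidden_genes)
  w <- setNames(c(1, 1, 8), vapply(genes, `[[`, "", "gene_id"))
  cfg <- sim_config(seed = 8L, n_reads = 4000L, trna_weights = w,
                    background_rate = 0.3)
  sim <- simulate_reads(cfg, toy$genome, genes)
  aln <- map_reads(sim$reads, toy$genome, map_params())
  trk <- coverage(aln, toy$genome)
  sp <- detect_spikes(trk, toy$genome$annotations)
  inter <- sp[sp$annotation == "intergenic", ]
  expect_gte(nrow(inter), 1L)
  expect_true(any(inter$start < hidden$feature$end &
                    inter$end > hidden$feature$start))
})

test_that("no intergenic spikes are called when no hidden locus is simulated", {
  for (seed in c(5L, 6L)) {
    toy <- build_toy_genome(seed = 101L + seed, n_trna = 2L)
    cfg <- sim_config(seed = seed, n_reads = 3000L, background_rate = 0.3)
    sim <- simulate_reads(cfg, toy$genome, toy$trna_genes)
    aln <- map_reads(sim$reads, toy$genome, map_params())
    trk <- coverage(aln, toy$genome)
    sp <- detect_spikes(trk, toy$genome$annotations)
    expect_equal(sum(sp$annotation == "intergenic"), 0L, label = paste("seed", seed))
  }
})

test_that("classify_read reproduces the canonical end-state examples", {
  fx <- tiny_fixture()
  g <- fx$gene; f <- g$feature
  # exact gene + soft-clipped CCA
  a1 <- mk_aln(list(id = "r1", seq = paste0(fx$gene_seq, "CCA"), ref = "tiny",
                    start = f$start, alen = 72L, clip = "CCA"))
  c1 <- classify_read(a1, g)
  expect_equal(c1$state, "plus_CCA")
  expect_equal(c1$half, "full")
  # 5 genomic bases upstream + full gene, no tail
  seq2 <- substr(fx$genome$sequence, f$start - 4, f$end)
  a2 <- mk_aln(list(id = "r2", seq = seq2, ref = "tiny", start = f$start - 5L))
  c2 <- classify_read(a2, g)
  expect_equal(c2$state, "leader_only")
  expect_equal(c2$half, "full")
  # gene bases [0 .. anticodon_offset + 1]
  seq3 <- substr(fx$gene_seq, 1, g$anticodon_offset + 1)
  a3 <- mk_aln(list(id = "r3", seq = seq3, ref = "tiny", start = f$start))
  c3 <- classify_read(a3, g)
  expect_equal(c3$state, "trimmed")
  expect_equal(c3$half, "half5")
  # non-overlapping read is rejected with a reason
  a4 <- mk_aln(list(id = "r4", seq = strrep("A", 20), ref = "tiny", start = 0L))
  c4 <- classify_read(a4, g)
  expect_null(c4)
  # genomic trailer extension
  seq5 <- substr(fx$genome$sequence, f$start + 1, f$end + 6)
  a5 <- mk_aln(list(id = "r5", seq = seq5, ref = "tiny", start = f$start))
  c5 <- classify_read(a5, g)
  expect_equal(c5$state, "trailer_only")
})

test_that("a genome-encoded CCA is classified as plus_CCA", {
  fx <- tiny_fixture()
  g_cca <- fx$gene
  g_cca$encodes_cca <- TRUE
  a <- mk_aln(list(id = "r", seq = fx$gene_seq, ref = "tiny",
                   start = fx$gene$feature$start))
  expect_equal(classify_read(a, g_cca)$state, "plus_CCA")
})

test_that("every sense-overlapping read gets exactly one state and half label", {
  s <- shared_toy_sim()
  cl <- classify_reads(s$aln, s$toy$trna_genes)
  expect_true(all(cl$state %in% c("precursor_both", "leader_only",
                                  "trailer_only", "trimmed", "plus_C",
                                  "plus_CC", "plus_CCA")))
  expect_true(all(cl$half %in% c("full", "half5", "half3", "fragment")))
  expect_equal(anyDuplicated(paste(cl$read_id, cl$gene_id)), 0L)
})

test_that("summaries count states, halves, fractions and ranks", {
  fx <- tiny_fixture()
  cl <- data.frame(read_id = paste0("r", 1:10), gene_id = "AlaT",
                   state = c(rep("trimmed", 7), rep("plus_CCA", 3)),
                   half = c(rep("half5", 7), rep("full", 3)),
                   five_prime_call = "start", three_prime_call = "trimmed",
                   g5 = 0L, g3 = c(rep(36L, 7), rep(72L, 3)), weight = 1)
  summ <- summarize_gene(cl, fx$gene)
  expect_equal(summ$full_length_fraction, 0.3)
  expect_equal(summ$total, 10)
  expect_equal(summ$half5, 7)
  expect_equal(summ$modal_g3, 36L)
  # zero-read gene
  z <- summarize_gene(cl[0, ], fx$gene)
  expect_equal(z$total, 0)
  expect_equal(z$full_length_fraction, 0)
  # ranks: two genes with counts 10 and 5
  toy <- build_toy_genome(seed = 1, n_trna = 2)
  cl2 <- rbind(transform(cl, gene_id = "Ala001"),
               transform(cl[1:5, ], gene_id = "Phe002"))
  summ2 <- summarize_genes(cl2, toy$trna_genes)
  expect_equal(summ2$expression_rank[summ2$gene_id == "Ala001"], 1L)
  expect_equal(summ2$expression_rank[summ2$gene_id == "Phe002"], 2L)
})
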