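# Shared fixtures, built in code.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Tiny handcrafted genome: 10 nt margin + one 72 nt plus-strand tRNA gene
# whose anticodon (TGC) sits at offset 34, + margin.
tiny_fixture <- function(seed = 7L) {
  set.seed(seed)
  gene_seq <- random_dna(72)
  substr(gene_seq, 35, 37) <- "TGC"
  left <- random_dna(150)       # first 120 nt annotated as CDS (background)
  right <- random_dna(30)
  if (substr(right, 1, 1) == "C") substr(right, 1, 1) <- "T"
  seq <- paste0(left, gene_seq, right)
  f <- rbind(feature("CDS_1", "CDS", 0L, 120L, "+"),
             feature("AlaT", "tRNA", 150L, 222L, "+"))
  g <- genome("tiny", seq, annotations = f)
  trna <- trna_gene(f[f$kind == "tRNA", ], "Ala", "TGC", 34L, genome = g)
  list(genome = g, gene = trna, gene_seq = gene_seq)
}

# Moderate simulated library shared by several test files (memoized).
.sim_cache <- new.env(parent = emptyenv())
shared_toy_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  toy <- build_toy_genome(seed = 42L, n_trna = 2L)
  mods <- data.frame(gene_id = c("Ala001", "Ala001", "Phe002"),
                     position = c(20L, 58L, 26L),
                     rate = c(0.25, 0.10, 0.05))
  cfg <- sim_config(seed = 11L, n_reads = 6000L, mod_sites = mods)
  sim <- simulate_reads(cfg, toy$genome, toy$trna_genes)
  aln <- map_reads(sim$reads, toy$genome, map_params())
  .sim_cache$sim <- list(toy = toy, cfg = cfg, sim = sim, aln = aln)
  .sim_cache$sim
}
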