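#!/usr/bin/env Rscript
# Stage 1: build the annotated toy genome and simulate the small-RNA
# library with known ground truth.
#
# The library emulates the structure of an endosymbiont bacteriome small
# RNA pool: a mixture of tRNA maturation states (precursors with genomic
# leaders/trailers, trimmed ends, stepwise non-genomic C/CC/CCA), heavy
# anticodon-loop cleavage into halves, per-site misincorporation at
# planted "modification" positions, and uniform CDS background.

suppressPackageStartupMessages(library(trnaproc))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

toy <- build_toy_genome(seed = 42L, n_trna = 2L)
write_fasta(toy$genome, "results/data/genome.fa")
write_annotations(toy$genome$annotations, "results/data/annotations.gff3",
                  "GFF3", seqname = toy$genome$id)
write_trna_inventory(toy$trna_genes, "results/data/trna_inventory.tsv")

mods <- data.frame(gene_id = c("Ala001", "Ala001", "Phe002", "Phe002"),
                   position = c(20L, 58L, 9L, 26L),
                   rate = c(0.25, 0.10, 0.05, 0.10))
write.table(mods, "results/data/planted_mod_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cfg <- sim_config(seed = 1L, n_reads = 20000L, mod_sites = mods,
                  background_rate = 0.1)
sim <- simulate_reads(cfg, toy$genome, toy$trna_genes)
write_fastq(sim$reads, "results/data/reads.fastq")
write_truth(sim$truth, "results/data/truth.tsv")

cat(sprintf("simulated %d reads (%d molecules drawn, %d discarded)\n",
            nrow(sim$reads), cfg$n_reads, sim$n_discarded))
cat("observable per-read states:\n")
print(table(sim$truth$state))
cat("half labels:\n")
print(table(sim$truth$half))
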