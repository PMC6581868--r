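#!/usr/bin/env Rscript
# Stage 6: translational capacity accounting -- codon usage, wobble
# decodability, 4-box redundancy, and aaRS completeness for the packaged
# Hodgkinia/Sulcia presence rows.

suppressPackageStartupMessages(library(trnaproc))

gnm <- read_fasta("results/data/genome.fa")[[1]]
ann <- read_annotations("results/data/annotations.gff3", "GFF3")
gnm <- genome(gnm$id, gnm$sequence, annotations = ann)
genes <- read_trna_inventory("results/data/trna_inventory.tsv",
                             features = ann, genome = gnm)

cds <- ann[ann$kind == "CDS", , drop = FALSE]
cu <- codon_usage(vapply(seq_len(nrow(cds)), function(i) {
  gene_sequence(gnm, cds[i, , drop = FALSE])
}, ""))
cat(sprintf("codon usage over %d CDSs: %d sense codons counted\n",
            nrow(cds), cu$total))

inv <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                  anticodon = vapply(genes, `[[`, "", "anticodon"))
tab <- decodability(inv, wobble_rules(), cu)
write.table(tab, "results/decoding_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("decoding status of the 61 sense codons under the toy tRNA set:\n")
print(table(tab$status))
cat("amino acids with no decodable codon:\n")
print(attr(tab, "undecodable_amino_acids"))
cat(sprintf("4-box redundancy of the toy set: %.3f\n", redundancy(inv)))

for (org in c("Hodgkinia", "Sulcia")) {
  res <- aars_completeness(read_aars_presence(organism = org))
  cat(sprintf("%s aaRS families present: %d of 20; missing: %s\n", org,
              res$n_present, paste(res$missing, collapse = ", ")))
}
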