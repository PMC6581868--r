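#!/usr/bin/env Rscript
# Stage 2: length-filter the reads and place them on the genome with the
# Hamming mapper (3' soft clipping on, up to 3 mismatches).

suppressPackageStartupMessages(library(trnaproc))

gnm <- read_fasta("results/data/genome.fa")[[1]]
gnm <- genome(gnm$id, gnm$sequence,
              annotations = read_annotations("results/data/annotations.gff3",
                                             "GFF3"))
reads <- filter_reads(read_fastq("results/data/reads.fastq"))
cat(sprintf("reads after 18-100 nt filter: %d (discarded short %d, long %d)\n",
            nrow(reads), attr(reads, "n_short"), attr(reads, "n_long")))

aln <- map_reads(reads, gnm, map_params())
write_sam(aln, gnm, "results/alignments.sam")

per_read <- aln[!duplicated(aln$read_id), ]
cat("mapping classes:\n")
print(table(per_read$mapq_class))
cat(sprintf("soft-clipped 3' tails: %d reads (C/CC/CCA tails: %d)\n",
            sum(nzchar(per_read$soft_clip_3)),
            sum(per_read$soft_clip_3 %in% c("C", "CC", "CCA"))))
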