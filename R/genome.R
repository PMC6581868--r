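#' @importFrom stats median cor pt sd setNames
#' @importFrom utils read.table write.table head tail
NULL

VALID_KINDS <- c("CDS", "tRNA", "rRNA", "tmRNA", "other")

#' Construct a genome object
#'
#' A genome is a named nucleotide sequence plus its feature annotations.
#' Coordinates throughout the package are 0-based half-open; circular
#' genomes allow features to wrap the origin (wrapped intervals are
#' materialized by concatenating the two arcs).
#'
#' @param id character scalar, genome identifier.
#' @param sequence nucleotide string over A/C/G/T (N tolerated but flagged).
#' @param circular logical, whether the molecule is circular.
#' @param annotations data.frame of features as returned by [feature()] /
#'   [read_annotations()], or NULL.
#' @return an object of class `genome`.
#' @export
genome <- function(id, sequence, circular = FALSE, annotations = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome '", id, "': empty sequence")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("genome '", id, "': non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  g <- structure(list(
    id = id,
    sequence = sequence,
    length = nchar(sequence),
    circular = isTRUE(circular),
    has_n = grepl("N", sequence, fixed = TRUE),
    annotations = annotations
  ), class = "genome")
  if (!is.null(annotations)) validate_features(annotations, g)
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp%s, %d features\n", x$id, x$length,
              if (x$circular) " (circular)" else "",
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' Construct a feature table row
#'
#' @param id feature identifier(s).
#' @param kind one of CDS, tRNA, rRNA, tmRNA, other.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @return data.frame with one row per feature.
#' @export
feature <- function(id, kind, start, end, strand = "+") {
  df <- data.frame(id = as.character(id), kind = as.character(kind),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  validate_features(df)
  df
}

validate_features <- function(df, genome = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("id", "kind", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing columns: ", paste(miss, collapse = ","))
  if (nrow(df) == 0L) return(invisible(df))
  if (!all(df$kind %in% VALID_KINDS)) {
    stop("unknown feature kind(s): ",
         paste(unique(setdiff(df$kind, VALID_KINDS)), collapse = ","))
  }
  if (any(df$start < 0L)) stop("negative feature start")
  if (any(df$end <= df$start)) {
    stop("feature end <= start for: ",
         paste(df$id[df$end <= df$start], collapse = ","))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("unknown strand symbol")
  if (!is.null(genome) && !genome$circular && any(df$end > genome$length)) {
    stop("feature extends past end of non-circular genome '", genome$id, "'")
  }
  invisible(df)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (multi-record allowed).
#' @param circular logical, recycled over records.
#' @return list of `genome` objects in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  circular <- rep_len(circular, length(ss))
  ids <- sub("\\s.*$", "", names(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    seq <- toupper(as.character(ss[[i]]))
    bad <- gsub("[ACGTN]", "", seq)
    if (nzchar(bad)) {
      stop("FASTA record '", ids[i], "': non-nucleotide characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
    }
    out[[i]] <- genome(ids[i], seq, circular = circular[i])
  }
  names(out) <- ids
  out
}

#' Write genomes to FASTA
#'
#' @param genomes list of `genome` objects.
#' @param path output path.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read feature annotations (GFF3 or BED)
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) are both converted
#' to the package's internal 0-based half-open convention. The feature kind
#' is taken from the GFF3 `type` column / BED name prefix when it matches
#' one of CDS, tRNA, rRNA, tmRNA; anything else becomes "other".
#'
#' @param path annotation file.
#' @param dialect "GFF3" or "BED".
#' @return feature data.frame (id, kind, start, end, strand).
#' @export
read_annotations <- function(path, dialect = c("GFF3", "BED")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "GFF3") "gff3" else "bed")
  n <- length(gr)
  if (n == 0L) return(feature(character(), character(), integer(), integer(), character()))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("unknown strand symbol in ", path)
  if (dialect == "GFF3") {
    kind <- as.character(gr$type)
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) id <- paste0("feat", seq_len(n))
    id <- ifelse(is.na(id), paste0("feat", seq_len(n)), id)
  } else {
    id <- gr$name
    if (is.null(id)) id <- paste0("feat", seq_len(n))
    kind <- sub("[_.:-].*$", "", id)
  }
  kind[!kind %in% VALID_KINDS] <- "other"
  # GRanges is 1-based inclusive for both dialects after import
  feature(id = id, kind = kind,
          start = BiocGenerics::start(gr) - 1L,
          end = BiocGenerics::end(gr),
          strand = strand)
}

#' Write feature annotations (GFF3 or BED)
#'
#' @param features feature data.frame.
#' @param path output path.
#' @param dialect "GFF3" or "BED".
#' @param seqname reference name to write (single genome).
#' @export
write_annotations <- function(features, path, dialect = c("GFF3", "BED"),
                              seqname = "genome") {
  dialect <- match.arg(dialect)
  validate_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  if (dialect == "GFF3") {
    gr$type <- features$kind
    gr$ID <- features$id
    gr$phase <- ifelse(features$kind == "CDS", 0L, NA_integer_)
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- features$id
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

#' Extract a feature's gene-oriented sequence
#'
#' Minus-strand features are reverse complemented so the result reads
#' 5' to 3' in gene orientation. On circular genomes intervals may wrap:
#' coordinates past the sequence end are taken modulo the genome length.
#'
#' @param genome a `genome`.
#' @param feature single-row feature data.frame (or list with start/end/strand).
#' @return nucleotide string.
#' @export
gene_sequence <- function(genome, feature) {
  start <- feature$start[1]; end <- feature$end[1]; strand <- feature$strand[1]
  s <- genome_subseq(genome, start, end)
  if (strand == "-") revcomp(s) else s
}

# 0-based half-open subsequence with circular wrap-around.
genome_subseq <- function(genome, start, end) {
  L <- genome$length
  if (start < 0L || end <= start) stop("invalid interval [", start, ",", end, ")")
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular) {
    stop("interval [", start, ",", end, ") out of bounds on non-circular genome '",
         genome$id, "'")
  }
  if (end - start > L) stop("interval longer than circular genome")
  paste0(substr(genome$sequence, start + 1L, L),
         substr(genome$sequence, 1L, end - L))
}

#' Construct a tRNA gene record
#'
#' @param feature single-row feature data.frame of kind "tRNA".
#' @param amino_acid 3-letter amino-acid code (e.g. "Ala").
#' @param anticodon 3-nt anticodon, 5' to 3' in gene orientation (DNA alphabet).
#' @param anticodon_offset 0-based index of the anticodon start within the
#'   gene-oriented sequence.
#' @param encodes_cca logical: terminal CCA encoded in the genome.
#' @param genome optional `genome`; when given, the anticodon is checked
#'   against the gene sequence.
#' @return an object of class `trna_gene`.
#' @export
trna_gene <- function(feature, amino_acid, anticodon, anticodon_offset,
                      encodes_cca = FALSE, genome = NULL) {
  stopifnot(nrow(feature) == 1L, feature$kind == "tRNA")
  len <- feature$end - feature$start
  if (len < 48L || len > 100L) {
    stop("tRNA gene '", feature$id, "' length ", len, " outside [48, 100]")
  }
  anticodon <- toupper(anticodon)
  if (nchar(anticodon) != 3L || grepl("[^ACGT]", anticodon)) {
    stop("anticodon must be a 3-nt ACGT string")
  }
  anticodon_offset <- as.integer(anticodon_offset)
  if (anticodon_offset < 0L || anticodon_offset + 3L > len) {
    stop("anticodon offset outside gene body")
  }
  if (!is.null(genome)) {
    gs <- gene_sequence(genome, feature)
    found <- substr(gs, anticodon_offset + 1L, anticodon_offset + 3L)
    if (found != anticodon) {
      stop("gene '", feature$id, "': sequence at anticodon offset is ", found,
           ", expected ", anticodon)
    }
  }
  structure(list(feature = feature, gene_id = feature$id,
                 amino_acid = amino_acid, anticodon = anticodon,
                 anticodon_offset = anticodon_offset,
                 encodes_cca = isTRUE(encodes_cca),
                 length = len),
            class = "trna_gene")
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s %s(%s) [%d,%d)%s ac@%d%s\n", x$gene_id,
              x$amino_acid, x$anticodon, x$feature$start, x$feature$end,
              x$feature$strand, x$anticodon_offset,
              if (x$encodes_cca) " +CCA" else ""))
  invisible(x)
}

#' Read a tRNA inventory TSV
#'
#' Expected columns: gene_id, amino_acid, anticodon, anticodon_offset,
#' encodes_cca. Coordinates come from the matching features (by id) in
#' `features`; when `features` is NULL only the decoding-related fields are
#' used and dummy coordinates are synthesized (decode module use-case).
#'
#' @param path TSV path.
#' @param features optional feature data.frame for coordinates.
#' @param genome optional genome for anticodon verification.
#' @return list of `trna_gene`.
#' @export
read_trna_inventory <- function(path, features = NULL, genome = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "amino_acid", "anticodon", "anticodon_offset", "encodes_cca")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tRNA inventory missing columns: ", paste(miss, collapse = ","))
  lapply(seq_len(nrow(df)), function(i) {
    if (!is.null(features)) {
      f <- features[features$id == df$gene_id[i], , drop = FALSE]
      if (nrow(f) != 1L) stop("inventory gene '", df$gene_id[i], "' not found once in features")
    } else {
      f <- feature(df$gene_id[i], "tRNA", 0L, 72L, "+")
    }
    trna_gene(f, df$amino_acid[i], df$anticodon[i], df$anticodon_offset[i],
              as.logical(df$encodes_cca[i]),
              genome = if (is.null(features)) NULL else genome)
  })
}

#' Write a tRNA inventory TSV
#'
#' @param trna_genes list of `trna_gene`.
#' @param path output TSV.
#' @export
write_trna_inventory <- function(trna_genes, path) {
  df <- data.frame(
    gene_id = vapply(trna_genes, `[[`, "", "gene_id"),
    amino_acid = vapply(trna_genes, `[[`, "", "amino_acid"),
    anticodon = vapply(trna_genes, `[[`, "", "anticodon"),
    anticodon_offset = vapply(trna_genes, `[[`, 0L, "anticodon_offset"),
    encodes_cca = vapply(trna_genes, `[[`, FALSE, "encodes_cca"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate codon usage over a CDS set
#'
#' Counts every codon of every in-frame CDS, excluding the three stop
#' codons. CDSs whose length is not a multiple of 3 are skipped with a
#' warning.
#'
#' @param cds_sequences character vector of gene-oriented CDS sequences.
#' @return list with `counts` (named integer vector over the 61 sense
#'   codons) and `total`.
#' @export
codon_usage <- function(cds_sequences) {
  sense <- sense_codons()
  counts <- setNames(integer(length(sense)), sense)
  for (i in seq_along(cds_sequences)) {
    s <- toupper(cds_sequences[[i]])
    if (nchar(s) %% 3L != 0L) {
      warning("CDS ", i, " length not divisible by 3; skipped")
      next
    }
    if (!nzchar(s)) next
    cods <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
    cods <- cods[cods %in% sense]           # drops stops (and any N-containing)
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  list(counts = counts, total = sum(counts))
}
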