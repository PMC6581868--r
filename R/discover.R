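#' Collapse identical reads
#'
#' Exact-sequence grouping of reads whose length lies in the given window
#' (the window targets molecules long enough to be functional tRNAs).
#' Total count is conserved: the counts sum to the number of in-window
#' input reads.
#'
#' @param reads data.frame(read_id, sequence).
#' @param min_len,max_len inclusive length window (default 48-90).
#' @return data.frame(sequence, count) sorted by count descending, ties by
#'   sequence.
#' @export
collapse_reads <- function(reads, min_len = 48L, max_len = 90L) {
  len <- nchar(reads$sequence)
  s <- reads$sequence[len >= min_len & len <= max_len]
  if (length(s) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(s)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exact full matches of pattern against named reference sequences (both
# strands); returns data.frame(reference_id, start0, strand)
exact_matches <- function(pattern, ref_seqs, ref_subjects, rc_subjects) {
  rows <- list()
  for (ri in seq_along(ref_seqs)) {
    L <- nchar(ref_seqs[ri])
    mp <- Biostrings::matchPattern(pattern, ref_subjects[[ri]], max.mismatch = 0)
    if (length(mp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        reference_id = names(ref_seqs)[ri],
        start0 = BiocGenerics::start(mp) - 1L, strand = "+")
    }
    mm <- Biostrings::matchPattern(pattern, rc_subjects[[ri]], max.mismatch = 0)
    if (length(mm)) {
      # convert positions on the reverse-complemented sequence back
      st_rc <- BiocGenerics::start(mm) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        reference_id = names(ref_seqs)[ri],
        start0 = L - (st_rc + nchar(pattern)), strand = "-")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(reference_id = character(), start0 = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

make_subjects <- function(ref_seqs) {
  list(fwd = lapply(ref_seqs, Biostrings::DNAString),
       rc = lapply(ref_seqs, function(s) Biostrings::DNAString(revcomp(s))))
}

# cheap existence test (no views/data.frame construction)
any_exact_match <- function(pattern, subj) {
  for (x in subj$fwd) {
    if (Biostrings::countPattern(pattern, x) > 0L) return(TRUE)
  }
  for (x in subj$rc) {
    if (Biostrings::countPattern(pattern, x) > 0L) return(TRUE)
  }
  FALSE
}

# longest prefix (or suffix) of `seq` that matches some reference exactly,
# found by binary search on matchable length (matchability is monotone).
longest_exact_end <- function(seq, ref_seqs, subj, from = c("start", "end"),
                              lo_len = 1L) {
  from <- match.arg(from)
  n <- nchar(seq)
  piece <- function(l) if (from == "start") substr(seq, 1L, l) else
    substr(seq, n - l + 1L, n)
  matches <- function(l) any_exact_match(piece(l), subj)
  if (!matches(lo_len)) return(0L)
  lo <- lo_len; hi <- n
  if (matches(n)) return(n)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (matches(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' tRNA locus table for chimera annotation
#'
#' @param genome a `genome`.
#' @param trna_genes list of [trna_gene()] on that genome.
#' @return data.frame(reference_id, gene_id, start, end, strand,
#'   anticodon_offset).
#' @export
trna_loci <- function(genome, trna_genes) {
  do.call(rbind, lapply(trna_genes, function(g) {
    data.frame(reference_id = genome$id, gene_id = g$gene_id,
               start = g$feature$start, end = g$feature$end,
               strand = g$feature$strand,
               anticodon_offset = g$anticodon_offset,
               gene_length = g$length, stringsAsFactors = FALSE)
  }))
}

#' Detect a chimeric ligation artifact in one sequence
#'
#' Searches breakpoints b in [min_segment, len - min_segment] such that
#' the prefix [0, b) and suffix [b, len) each match some reference strand
#' exactly and the two matched loci differ (different reference, different
#' strand, or a same-strand gap larger than the read length). The
#' breakpoint maximizing min(prefix, suffix) length is reported. When a
#' tRNA locus table is supplied, the call is flagged when the junction
#' falls inside a tRNA gene's anticodon window (offset -2 .. +4).
#'
#' @param sequence read sequence (length >= 2 * min_segment).
#' @param references named character vector of reference sequences (or
#'   genome list).
#' @param min_segment minimum segment length (default 16, the scale at
#'   which identical matches arise by chance between tRNA genes).
#' @param loci optional [trna_loci()] table.
#' @param .subj prebuilt subjects (internal; used by [screen_chimeras()]
#'   to avoid rebuilding per sequence).
#' @return one-row data.frame (sequence, breakpoint, segment A/B locus
#'   columns, junction_near_anticodon) or NULL when no breakpoint
#'   qualifies.
#' @export
detect_chimera <- function(sequence, references, min_segment = 16L,
                           loci = NULL, .subj = NULL) {
  ref_seqs <- as_reference_seqs(references)
  subj <- if (is.null(.subj)) make_subjects(ref_seqs) else .subj
  n <- nchar(sequence)
  if (n < 2L * min_segment) return(NULL)
  # a sequence matching contiguously in full is by definition not a chimera
  if (any_exact_match(sequence, subj)) return(NULL)

  P <- longest_exact_end(sequence, ref_seqs, subj, "start", lo_len = min_segment)
  S <- longest_exact_end(sequence, ref_seqs, subj, "end", lo_len = min_segment)
  lo <- max(min_segment, n - S)
  hi <- min(P, n - min_segment)
  if (lo > hi) return(NULL)
  bs <- lo:hi
  bs <- bs[order(-pmin(bs, n - bs), bs)]     # best-balanced breakpoint first
  for (b in bs) {
    pm <- exact_matches(substr(sequence, 1L, b), ref_seqs, subj$fwd, subj$rc)
    sm <- exact_matches(substr(sequence, b + 1L, n), ref_seqs, subj$fwd, subj$rc)
    if (nrow(pm) == 0L || nrow(sm) == 0L) next
    for (i in seq_len(nrow(pm))) {
      for (j in seq_len(nrow(sm))) {
        differs <- pm$reference_id[i] != sm$reference_id[j] ||
          pm$strand[i] != sm$strand[j]
        if (!differs) {
          gap <- if (pm$strand[i] == "+") {
            abs(sm$start0[j] - (pm$start0[i] + b))
          } else {
            abs(pm$start0[i] - (sm$start0[j] + (n - b)))
          }
          differs <- gap > n
        }
        if (!differs) next
        near_ac <- FALSE
        if (!is.null(loci) && nrow(loci)) {
          near_ac <- junction_near_anticodon(pm[i, ], b, TRUE, loci) ||
            junction_near_anticodon(sm[j, ], n - b, FALSE, loci)
        }
        return(data.frame(
          sequence = sequence, breakpoint = b,
          ref_a = pm$reference_id[i], start_a = pm$start0[i], strand_a = pm$strand[i],
          ref_b = sm$reference_id[j], start_b = sm$start0[j], strand_b = sm$strand[j],
          junction_near_anticodon = near_ac, stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

# does the junction end of a matched segment fall inside a tRNA anticodon
# window? `is_prefix`: segment is the read prefix (junction at its 3' end).
junction_near_anticodon <- function(seg, seg_len, is_prefix, loci) {
  # junction position in reference coordinates
  jpos <- if (seg$strand == "+") {
    if (is_prefix) seg$start0 + seg_len else seg$start0
  } else {
    if (is_prefix) seg$start0 else seg$start0 + seg_len
  }
  for (r in seq_len(nrow(loci))) {
    lr <- loci[r, ]
    if (lr$reference_id != seg$reference_id) next
    if (jpos < lr$start || jpos > lr$end) next
    gpos <- if (lr$strand == "+") jpos - lr$start else lr$end - jpos
    if (gpos >= lr$anticodon_offset - 2L && gpos <= lr$anticodon_offset + 4L) {
      return(TRUE)
    }
  }
  FALSE
}

#' Classify collapsed reads
#'
#' Records below `min_count` are dropped; the rest are classified in
#' priority order: full-length match (<= 2 mismatches, optionally plus a
#' terminal C/CC/CCA) to a known tRNA reference => known_tRNA; a local
#' genome match covering >= 80% of the sequence with <= 2 mismatches =>
#' genome_partial; a sequence ending in CCA => cca_unknown; a positive
#' chimera screen => chimera_candidate; else unassigned.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param trna_references named character vector of mature tRNA sequences.
#' @param genomes named character vector / genome list (full genomes).
#' @param min_count minimum coverage cutoff (default 100).
#' @param min_segment chimera segment length (default 16).
#' @param loci optional [trna_loci()] table for the chimera screen.
#' @return collapsed data.frame with a `classification` column.
#' @export
classify_collapsed <- function(collapsed, trna_references, genomes,
                               min_count = 100L, min_segment = 16L,
                               loci = NULL) {
  if (length(trna_references) == 0L) stop("no tRNA references supplied")
  gseqs <- as_reference_seqs(genomes)
  out <- collapsed[collapsed$count >= min_count, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$classification <- character(0)
    return(out)
  }
  # allow an un-encoded terminal C/CC/CCA on top of each reference
  variants <- unlist(lapply(seq_along(trna_references), function(i) {
    v <- paste0(trna_references[i], c("", "C", "CC", "CCA"))
    names(v) <- rep(names(trna_references)[i], 4L)
    v
  }))
  cls <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- out$sequence[i]
    if (any(vapply(variants, function(v) hamming_dist(s, v) <= 2, FALSE))) {
      cls[i] <- "known_tRNA"
      next
    }
    if (has_local_genome_match(s, gseqs, min_cov = 0.8, max_mm = 2L)) {
      cls[i] <- "genome_partial"
      next
    }
    if (endsWith(s, "CCA")) {
      cls[i] <- "cca_unknown"
      next
    }
    ch <- detect_chimera(s, gseqs, min_segment = min_segment, loci = loci)
    cls[i] <- if (!is.null(ch)) "chimera_candidate" else "unassigned"
  }
  out$classification <- cls
  rownames(out) <- NULL
  out
}

# does any substring covering >= min_cov of the sequence place on a genome
# with <= max_mm mismatches? checked at full length and at the minimum
# covering length anchored at either end (degradation-style partials).
has_local_genome_match <- function(s, gseqs, min_cov = 0.8, max_mm = 2L) {
  n <- nchar(s)
  need <- as.integer(ceiling(min_cov * n))
  subj <- make_subjects(gseqs)
  cand <- unique(c(s, substr(s, 1L, need), substr(s, n - need + 1L, n)))
  for (p in cand) {
    for (ri in seq_along(gseqs)) {
      if (length(Biostrings::matchPattern(p, subj$fwd[[ri]], max.mismatch = max_mm,
                                          with.indels = FALSE)) > 0L ||
          length(Biostrings::matchPattern(p, subj$rc[[ri]], max.mismatch = max_mm,
                                          with.indels = FALSE)) > 0L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Single-linkage clustering of collapsed reads
#'
#' Groups collapsed sequences of equal length within `max_mismatch`
#' Hamming distance (single linkage). Rows whose `anticodon`, `leader` or
#' `trailer` metadata differ are never merged, mirroring the rule that
#' near-identical sequences with different anticodons or ends are distinct
#' transcripts.
#'
#' @param collapsed data.frame with `sequence` (and optionally metadata
#'   columns anticodon, leader, trailer).
#' @param max_mismatch linkage threshold (default 2).
#' @return integer cluster id per row.
#' @export
cluster_collapsed <- function(collapsed, max_mismatch = 2L) {
  n <- nrow(collapsed)
  if (n == 0L) return(integer())
  meta_cols <- intersect(c("anticodon", "leader", "trailer"), names(collapsed))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (hamming_dist(collapsed$sequence[i], collapsed$sequence[j]) > max_mismatch) next
      if (length(meta_cols) &&
          any(collapsed[i, meta_cols] != collapsed[j, meta_cols])) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Screen many sequences for chimeric ligation artifacts
#'
#' Vector wrapper around [detect_chimera()] that builds the reference
#' index once.
#'
#' @param sequences character vector (deduplicated internally).
#' @param references named character vector / genome list.
#' @param min_segment minimum segment length (default 16).
#' @param loci optional [trna_loci()] table.
#' @return data.frame of chimera calls (zero rows when none).
#' @export
screen_chimeras <- function(sequences, references, min_segment = 16L,
                            loci = NULL) {
  ref_seqs <- as_reference_seqs(references)
  subj <- make_subjects(ref_seqs)
  calls <- list()
  for (s in unique(sequences)) {
    ch <- detect_chimera(s, ref_seqs, min_segment = min_segment, loci = loci,
                         .subj = subj)
    if (!is.null(ch)) calls[[length(calls) + 1L]] <- ch
  }
  if (length(calls) == 0L) {
    return(data.frame(sequence = character(), breakpoint = integer(),
                      ref_a = character(), start_a = integer(),
                      strand_a = character(), ref_b = character(),
                      start_b = integer(), strand_b = character(),
                      junction_near_anticodon = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}
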