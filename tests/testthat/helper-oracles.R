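# Independent brute-force oracles. These deliberately avoid the package's
# search code paths: plain integer scans over every offset.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Hamming mismatch count of `pat` at every offset of `ref` (0-based starts),
# fully vectorized via an index matrix.
oracle_scan <- function(pat_chars, ref_chars) {
  lp <- length(pat_chars); lr <- length(ref_chars)
  if (lp > lr) return(integer(0))
  noff <- lr - lp + 1L
  idx <- outer(seq_len(lp) - 1L, seq_len(noff), `+`)
  colSums(matrix(ref_chars[idx], nrow = lp) != pat_chars)
}

# Exhaustive mapper: every reference, strand, clip (0..max_clip) and offset,
# under the objective (mismatches, clip, reference order, leftmost, "+" < "-").
# Returns NULL (unmapped) or a data.frame of all equal-best placements.
oracle_map <- function(read, ref_seqs, max_mm = 3L, max_clip = 3L,
                       min_len = 18L) {
  len <- nchar(read)
  if (len < min_len) return(NULL)
  ref_chars <- lapply(ref_seqs, function(r) strsplit(r, "")[[1]])
  rc <- oracle_revcomp(read)
  rows <- list()
  for (clip in 0:min(max_clip, len - min_len)) {
    pat_p <- strsplit(substr(read, 1L, len - clip), "")[[1]]
    pat_m <- strsplit(substr(rc, clip + 1L, len), "")[[1]]
    for (ri in seq_along(ref_seqs)) {
      mm_p <- oracle_scan(pat_p, ref_chars[[ri]])
      hit <- which(mm_p <= max_mm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_idx = ri, strand = "+", start0 = hit - 1L, mm = mm_p[hit],
          clip = clip, five_prime = hit - 1L)
      }
      mm_m <- oracle_scan(pat_m, ref_chars[[ri]])
      hit <- which(mm_m <= max_mm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_idx = ri, strand = "-", start0 = hit - 1L, mm = mm_m[hit],
          clip = clip, five_prime = hit - 1L + length(pat_m) - 1L)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  key <- paste(cand$ref_idx, cand$strand, cand$five_prime)
  ord <- order(cand$mm, cand$clip)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(key[ord]), , drop = FALSE]
  cand <- cand[cand$mm == min(cand$mm), , drop = FALSE]
  cand <- cand[cand$clip == min(cand$clip), , drop = FALSE]
  cand[order(cand$ref_idx, cand$start0, cand$strand == "-"), , drop = FALSE]
}

# Midrank-then-Pearson Spearman oracle with explicit formulas.
oracle_spearman_rho <- function(a, b) {
  midrank <- function(x) {
    n <- length(x)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    }
    r
  }
  ra <- midrank(a); rb <- midrank(b)
  n <- length(a)
  num <- sum(ra * rb) - n * mean(ra) * mean(rb)
  den <- sqrt((sum(ra^2) - n * mean(ra)^2) * (sum(rb^2) - n * mean(rb)^2))
  num / den
}

# Decodability oracle: per codon, loop over tRNAs and test pairing base by
# base with explicit complement lookups (no reverse complement reuse).
oracle_decodability <- function(trna_df, rules) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  codons <- sense_codons()
  status <- setNames(rep("undecodable", length(codons)), codons)
  rank <- c(undecodable = 0, modified_wobble = 1, wobble = 2, perfect = 3)
  for (cod in codons) {
    c1 <- substr(cod, 1, 1); c2 <- substr(cod, 2, 2); c3 <- substr(cod, 3, 3)
    for (i in seq_len(nrow(trna_df))) {
      ac <- trna_df$anticodon[i]
      a34 <- substr(ac, 1, 1); a35 <- substr(ac, 2, 2); a36 <- substr(ac, 3, 3)
      # positions 35/36 must be Watson-Crick with codon positions 2/1
      if (comp[[a36]] != c1 || comp[[a35]] != c2) next
      st <- NULL
      if (comp[[a34]] == c3) {
        st <- "perfect"
      } else {
        mod <- trna_df$modification[i]
        rule <- rules[rules$anticodon34 == a34 & rules$modification == mod, ]
        if (nrow(rule) == 1L &&
            c3 %in% strsplit(rule$reads, ",")[[1]]) {
          st <- if (mod == "none") "wobble" else "modified_wobble"
        }
      }
      if (!is.null(st) && rank[[st]] > rank[[status[[cod]]]]) status[[cod]] <- st
    }
  }
  status
}
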