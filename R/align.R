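#' Mapping parameters
#'
#' @param seed_length minimum mappable read length (default 18).
#' @param max_mismatch maximum Hamming mismatches for a placement
#'   (default 3; raise to 5-8 to tolerate heavily modified reads).
#' @param allow_soft_clip_3 permit clipping up to `max_clip` non-genomic
#'   3' bases when clipping strictly reduces mismatches (default TRUE).
#' @param max_clip maximum clipped 3' bases (default 3, enough for CCA).
#' @param min_read_len reads shorter than this are unmapped (default 18).
#' @return object of class `map_params`.
#' @export
map_params <- function(seed_length = 18L, max_mismatch = 3L,
                       allow_soft_clip_3 = TRUE, max_clip = 3L,
                       min_read_len = 18L) {
  if (seed_length > min_read_len) stop("seed_length must be <= min_read_len")
  structure(list(seed_length = as.integer(seed_length),
                 max_mismatch = as.integer(max_mismatch),
                 allow_soft_clip_3 = isTRUE(allow_soft_clip_3),
                 max_clip = as.integer(max_clip),
                 min_read_len = as.integer(min_read_len)),
            class = "map_params")
}

#' Length-filter trimmed reads
#'
#' @param reads data.frame(read_id, sequence).
#' @param min_len,max_len inclusive length window (default 18-100).
#' @return filtered data.frame with attributes `n_short` and `n_long`
#'   (discard counts).
#' @export
filter_reads <- function(reads, min_len = 18L, max_len = 100L) {
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_short") <- sum(len < min_len)
  attr(out, "n_long") <- sum(len > max_len)
  out
}

as_reference_seqs <- function(references) {
  if (inherits(references, "genome")) references <- list(references)
  if (is.list(references)) {
    seqs <- vapply(references, function(r) {
      if (inherits(r, "genome")) r$sequence else as.character(r)
    }, "")
    ids <- vapply(references, function(r) {
      if (inherits(r, "genome")) r$id else NA_character_
    }, "")
    if (anyNA(ids)) ids <- names(references)
    names(seqs) <- ids
  } else {
    seqs <- references
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("references must be named")
  }
  seqs
}

empty_alignments <- function() {
  data.frame(read_id = character(), sequence = character(),
             reference_id = character(), ref_start = integer(),
             strand = character(), aligned_length = integer(),
             n_mismatch = integer(), mismatch_positions = character(),
             soft_clip_3 = character(), mapq_class = character(),
             n_best = integer(), weight = numeric(),
             stringsAsFactors = FALSE)
}

# All placements of `pattern` (already oriented to the reference forward
# strand) with <= max_mm Hamming mismatches. Returns ref-relative 0-based
# starts and mismatch counts as a two-element list.
hamming_hits <- function(pattern, subject, max_mm) {
  if (nchar(pattern) > length(subject)) return(NULL)
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                with.indels = FALSE)
  if (length(m) == 0L) return(NULL)
  st <- BiocGenerics::start(m)
  st <- st[st >= 1L & (st + nchar(pattern) - 1L) <= length(subject)]
  if (length(st) == 0L) return(NULL)
  mm <- if (max_mm == 0L) integer(length(st)) else
    as.integer(Biostrings::neditStartingAt(Biostrings::DNAString(pattern),
                                           subject, starting.at = st,
                                           with.indels = FALSE))
  list(start0 = st - 1L, mm = mm)
}

# fast reverse complement for plain ACGTN strings
revcomp1 <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

#' Map small reads onto reference sequences
#'
#' Hamming-only (no indel) placement of each read on both strands of every
#' reference. When 3' soft clipping is enabled, up to `max_clip` trailing
#' read bases may be clipped if clipping strictly reduces the mismatch
#' count; the clipped tail is recorded (CCA detection). Among candidate
#' placements the objective minimized is (mismatches, clip length,
#' reference order, leftmost coordinate, "+" before "-"). Equal-best
#' placements at more than one locus are all reported with
#' `mapq_class = "multi"` and fractional weight 1/k.
#'
#' @param reads data.frame(read_id, sequence).
#' @param references named character vector of reference sequences, a
#'   `genome`, or a list of `genome` objects.
#' @param params a [map_params()].
#' @return alignment data.frame, one row per reported placement (unmapped
#'   reads get one row with `mapq_class = "unmapped"`). Columns: read_id,
#'   sequence, reference_id, ref_start (0-based), strand, aligned_length,
#'   n_mismatch, mismatch_positions (comma list of 0-based reference
#'   offsets), soft_clip_3, mapq_class, n_best, weight.
#' @export
map_reads <- function(reads, references, params = map_params()) {
  seqs <- as_reference_seqs(references)
  subjects <- lapply(seqs, Biostrings::DNAString)
  ref_ids <- names(seqs)
  if (nrow(reads) == 0L) return(empty_alignments())

  max_clip <- if (params$allow_soft_clip_3) params$max_clip else 0L
  useq <- unique(reads$sequence)
  per_seq <- vector("list", length(useq))
  names(per_seq) <- useq

  for (s in useq) {
    len <- nchar(s)
    if (len < params$seed_length || len < params$min_read_len) {
      per_seq[[s]] <- "too_short"
      next
    }
    rc <- revcomp1(s)
    c_ref <- integer(0); c_str <- character(0); c_st <- integer(0)
    c_mm <- integer(0); c_clip <- integer(0); c_fp <- integer(0)
    best_mm <- params$max_mismatch + 1L
    # under the (mismatches, clip) objective a longer clip can only win by
    # strictly reducing mismatches, so later clip rounds search with a
    # tightened mismatch budget and stop once 0 is reached
    for (clip in 0:min(max_clip, len - params$seed_length)) {
      allowed <- min(params$max_mismatch, best_mm - 1L)
      if (allowed < 0L) break
      pat_p <- substr(s, 1L, len - clip)
      pat_m <- substr(rc, clip + 1L, len)
      plen <- len - clip
      for (ri in seq_along(ref_ids)) {
        hp <- hamming_hits(pat_p, subjects[[ri]], allowed)
        if (!is.null(hp)) {
          n <- length(hp$start0)
          best_mm <- min(best_mm, hp$mm)
          c_ref <- c(c_ref, rep.int(ri, n)); c_str <- c(c_str, rep.int("+", n))
          c_st <- c(c_st, hp$start0); c_mm <- c(c_mm, hp$mm)
          c_clip <- c(c_clip, rep.int(clip, n)); c_fp <- c(c_fp, hp$start0)
        }
        hm <- hamming_hits(pat_m, subjects[[ri]], allowed)
        if (!is.null(hm)) {
          n <- length(hm$start0)
          best_mm <- min(best_mm, hm$mm)
          c_ref <- c(c_ref, rep.int(ri, n)); c_str <- c(c_str, rep.int("-", n))
          c_st <- c(c_st, hm$start0); c_mm <- c(c_mm, hm$mm)
          c_clip <- c(c_clip, rep.int(clip, n))
          c_fp <- c(c_fp, hm$start0 + plen - 1L)
        }
      }
      if (best_mm == 0L) break
    }
    if (length(c_st) == 0L) { per_seq[[s]] <- "unmapped"; next }
    # per locus (ref, strand, read 5' position) keep the best (mm, clip)
    key <- paste(c_ref, c_str, c_fp)
    ord <- order(c_mm, c_clip)
    keep <- ord[!duplicated(key[ord])]
    sel <- keep[c_mm[keep] == min(c_mm[keep])]
    sel <- sel[c_clip[sel] == min(c_clip[sel])]
    sel <- sel[order(c_ref[sel], c_st[sel], c_str[sel] == "-")]
    per_seq[[s]] <- list(ref_idx = c_ref[sel], strand = c_str[sel],
                         start0 = c_st[sel], mm = c_mm[sel],
                         clip = c_clip[sel][1])
  }

  # assemble output columns (chunk per read, one combine at the end)
  ref_chars <- lapply(seqs, function(x) strsplit(x, "")[[1]])
  n <- nrow(reads)
  L_read <- vector("list", n); L_seq <- vector("list", n)
  L_ref <- vector("list", n); L_st <- vector("list", n)
  L_str <- vector("list", n); L_alen <- vector("list", n)
  L_mm <- vector("list", n); L_mmpos <- vector("list", n)
  L_clip3 <- vector("list", n); L_cls <- vector("list", n)
  L_k <- vector("list", n); L_w <- vector("list", n)

  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    res <- per_seq[[s]]
    len <- nchar(s)
    if (is.character(res)) {
      L_read[[i]] <- reads$read_id[i]; L_seq[[i]] <- s
      L_ref[[i]] <- NA_character_; L_st[[i]] <- NA_integer_
      L_str[[i]] <- NA_character_; L_alen[[i]] <- NA_integer_
      L_mm[[i]] <- NA_integer_; L_mmpos[[i]] <- ""
      L_clip3[[i]] <- ""; L_cls[[i]] <- "unmapped"
      L_k[[i]] <- 0L; L_w[[i]] <- 0
      next
    }
    k <- length(res$start0)
    clip <- res$clip
    alen <- len - clip
    tail3 <- if (clip > 0L) substr(s, len - clip + 1L, len) else ""
    mm_pos <- character(k)
    for (j in seq_len(k)) {
      if (res$mm[j] == 0L) next
      pat <- if (res$strand[j] == "+") substr(s, 1L, alen) else
        substr(revcomp1(s), clip + 1L, len)
      rch <- ref_chars[[res$ref_idx[j]]]
      d <- which(strsplit(pat, "")[[1]] !=
                   rch[(res$start0[j] + 1L):(res$start0[j] + alen)])
      mm_pos[j] <- paste(res$start0[j] + d - 1L, collapse = ",")
    }
    L_read[[i]] <- rep.int(reads$read_id[i], k)
    L_seq[[i]] <- rep.int(s, k)
    L_ref[[i]] <- ref_ids[res$ref_idx]; L_st[[i]] <- res$start0
    L_str[[i]] <- res$strand; L_alen[[i]] <- rep.int(alen, k)
    L_mm[[i]] <- res$mm; L_mmpos[[i]] <- mm_pos
    L_clip3[[i]] <- rep.int(tail3, k)
    L_cls[[i]] <- rep.int(if (k > 1L) "multi" else "unique", k)
    L_k[[i]] <- rep.int(k, k); L_w[[i]] <- rep.int(1 / k, k)
  }
  o_read <- unlist(L_read); o_seq <- unlist(L_seq); o_ref <- unlist(L_ref)
  o_st <- unlist(L_st); o_str <- unlist(L_str); o_alen <- unlist(L_alen)
  o_mm <- unlist(L_mm); o_mmpos <- unlist(L_mmpos); o_clip3 <- unlist(L_clip3)
  o_cls <- unlist(L_cls); o_k <- unlist(L_k); o_w <- unlist(L_w)
  data.frame(read_id = o_read, sequence = o_seq, reference_id = o_ref,
             ref_start = o_st, strand = o_str, aligned_length = o_alen,
             n_mismatch = o_mm, mismatch_positions = o_mmpos,
             soft_clip_3 = o_clip3, mapq_class = o_cls, n_best = o_k,
             weight = o_w, stringsAsFactors = FALSE)
}

#' Write alignments as SAM (text, version 1.6)
#'
#' Minus-strand reads are stored reverse complemented with flag 16; a 3'
#' soft clip appears as trailing S on "+" records and leading S on "-"
#' records. Unmapped reads are written with flag 4.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param references named character vector / genome(s) (for @SQ lines).
#' @param path output path.
#' @export
write_sam <- function(alignments, references, path) {
  seqs <- as_reference_seqs(references)
  mapped <- alignments[alignments$mapq_class != "unmapped", , drop = FALSE]
  if (nrow(mapped) && any(!mapped$reference_id %in% names(seqs))) {
    stop("alignment references unknown sequence: ",
         paste(setdiff(mapped$reference_id, names(seqs)), collapse = ","))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  recs <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    if (a$mapq_class == "unmapped") {
      recs[i] <- paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       a$sequence, strrep("I", nchar(a$sequence)), sep = "\t")
      next
    }
    clip <- nchar(a$soft_clip_3)
    if (a$strand == "+") {
      flag <- 0L
      seq_out <- a$sequence
      cigar <- if (clip > 0L) sprintf("%dM%dS", a$aligned_length, clip) else
        sprintf("%dM", a$aligned_length)
    } else {
      flag <- 16L
      seq_out <- revcomp(a$sequence)
      cigar <- if (clip > 0L) sprintf("%dS%dM", clip, a$aligned_length) else
        sprintf("%dM", a$aligned_length)
    }
    mapq <- if (a$mapq_class == "unique") 42L else 1L
    recs[i] <- paste(a$read_id, flag, a$reference_id, a$ref_start + 1L, mapq,
                     cigar, "*", 0L, 0L, seq_out, strrep("I", nchar(seq_out)),
                     sprintf("NM:i:%d", a$n_mismatch), sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a SAM file back into an alignment data.frame
#'
#' Supports the subset written by [write_sam()] (xM, xMyS, ySxM CIGARs).
#' Mismatch positions are recomputed when `references` are supplied.
#'
#' @param path SAM path.
#' @param references optional references for mismatch recomputation.
#' @return alignment data.frame.
#' @export
read_sam <- function(path, references = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) return(empty_alignments())
  seqs <- if (!is.null(references)) as_reference_seqs(references) else NULL
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) {
      rows[[i]] <- data.frame(
        read_id = f[1], sequence = f[10], reference_id = NA_character_,
        ref_start = NA_integer_, strand = NA_character_,
        aligned_length = NA_integer_, n_mismatch = NA_integer_,
        mismatch_positions = "", soft_clip_3 = "", mapq_class = "unmapped",
        n_best = 0L, weight = 0, stringsAsFactors = FALSE)
      next
    }
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MS]", cigar))[[1]]
    lens <- as.integer(sub("[MS]$", "", ops))
    kinds <- sub("^\\d+", "", ops)
    alen <- sum(lens[kinds == "M"])
    clip <- sum(lens[kinds == "S"])
    seq_stored <- f[10]
    read_seq <- if (strand == "-") revcomp(seq_stored) else seq_stored
    tail3 <- if (clip > 0L) substr(read_seq, nchar(read_seq) - clip + 1L,
                                   nchar(read_seq)) else ""
    start0 <- as.integer(f[4]) - 1L
    nm_field <- grep("^NM:i:", f, value = TRUE)
    nm <- if (length(nm_field)) as.integer(sub("NM:i:", "", nm_field[1])) else NA_integer_
    mm_pos <- ""
    if (!is.null(seqs) && !is.na(nm) && nm > 0L) {
      pat <- if (strand == "+") substr(read_seq, 1L, alen) else
        substr(revcomp(read_seq), clip + 1L, nchar(read_seq))
      ref_piece <- substr(seqs[[f[3]]], start0 + 1L, start0 + alen)
      d <- which(strsplit(pat, "")[[1]] != strsplit(ref_piece, "")[[1]])
      mm_pos <- paste(start0 + d - 1L, collapse = ",")
    }
    rows[[i]] <- data.frame(
      read_id = f[1], sequence = read_seq, reference_id = f[3],
      ref_start = start0, strand = strand, aligned_length = alen,
      n_mismatch = nm, mismatch_positions = mm_pos, soft_clip_3 = tail3,
      mapq_class = "unique", n_best = 1L, weight = 1,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # restore multi-mapper bookkeeping from duplicated read ids
  tab <- table(out$read_id[out$mapq_class != "unmapped"])
  multi <- names(tab)[tab > 1L]
  sel <- out$read_id %in% multi & out$mapq_class != "unmapped"
  out$mapq_class[sel] <- "multi"
  out$n_best[sel] <- as.integer(tab[out$read_id[sel]])
  out$weight[sel] <- 1 / out$n_best[sel]
  rownames(out) <- NULL
  out
}
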