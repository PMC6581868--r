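DEFAULT_LENGTH_CLASSES <- list(c(18L, 47L), c(48L, 89L), c(90L, 100L))

END_STATES <- c("precursor_both", "leader_only", "trailer_only", "trimmed",
                "plus_C", "plus_CC", "plus_CCA")
HALF_LABELS <- c("full", "half5", "half3", "fragment")

#' Per-base coverage by read-length class
#'
#' Each aligned base adds the alignment's fractional weight (1/k for a
#' k-fold multi-mapper) to the depth array of the read's length class;
#' soft-clipped tail bases do not contribute.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param genome the reference `genome` the alignments are on.
#' @param length_classes list of inclusive c(lo, hi) read-length ranges;
#'   default 18-47, 48-89, 90-100.
#' @return object of class `coverage_track`: list(reference_id, length,
#'   length_classes, depth = list of numeric vectors).
#' @export
coverage <- function(alignments, genome, length_classes = DEFAULT_LENGTH_CLASSES) {
  L <- genome$length
  depth <- lapply(length_classes, function(x) numeric(L))
  a <- alignments[which(!is.na(alignments$reference_id) &
                          alignments$reference_id == genome$id), , drop = FALSE]
  if (!is.null(a) && nrow(a) > 0L) {
    if (any(a$ref_start < 0L | a$ref_start + a$aligned_length > L)) {
      stop("alignment outside reference bounds on '", genome$id, "'")
    }
    rlen <- nchar(a$sequence)
    for (ci in seq_along(length_classes)) {
      rng <- length_classes[[ci]]
      sel <- which(rlen >= rng[1] & rlen <= rng[2])
      d <- depth[[ci]]
      for (i in sel) {
        span <- (a$ref_start[i] + 1L):(a$ref_start[i] + a$aligned_length[i])
        d[span] <- d[span] + a$weight[i]
      }
      depth[[ci]] <- d
    }
  }
  structure(list(reference_id = genome$id, length = L,
                 length_classes = length_classes, depth = depth),
            class = "coverage_track")
}

pooled_depth <- function(track) Reduce(`+`, track$depth)

#' Background (median genic) coverage level
#'
#' The median per-base depth over all CDS positions, per length class
#' (plus the pooled track).
#'
#' @param track a [coverage()] track.
#' @param annotations feature data.frame containing at least one CDS.
#' @return numeric vector, one value per length class plus "pooled".
#' @export
background_level <- function(track, annotations) {
  cds <- annotations[annotations$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    stop("no CDS features: supply an explicit background level instead")
  }
  idx <- unlist(lapply(seq_len(nrow(cds)), function(i) {
    (cds$start[i] + 1L):cds$end[i]
  }))
  lv <- vapply(track$depth, function(d) median(d[idx]), 0)
  names(lv) <- vapply(track$length_classes, function(x) paste(x, collapse = "-"), "")
  c(lv, pooled = median(pooled_depth(track)[idx]))
}

#' Subtract a background level from a coverage track
#'
#' Per-base `max(depth - level, 0)`. `level` is recycled over length
#' classes.
#'
#' @param track a [coverage()] track.
#' @param level non-negative background level(s).
#' @return a new coverage_track.
#' @export
subtract_background <- function(track, level) {
  if (any(level < 0)) stop("background level must be >= 0")
  level <- rep_len(as.numeric(level), length(track$depth))
  track$depth <- lapply(seq_along(track$depth), function(i) {
    pmax(track$depth[[i]] - level[i], 0)
  })
  track
}

#' Detect coverage spikes
#'
#' Finds maximal runs of at least `min_run` consecutive positions whose
#' pooled background-subtracted depth is at least `fold` times the pooled
#' background level (when the background is zero, any strictly positive
#' depth qualifies). Each run is labeled with the kind of an overlapping
#' annotation, or "intergenic".
#'
#' @param track a [coverage()] track (raw, not background-subtracted).
#' @param annotations feature data.frame (CDS rows define the background).
#' @param fold fold-over-background threshold (default 10).
#' @param min_run minimum run length in bp (default 20).
#' @param background optional explicit pooled background level (otherwise
#'   computed via [background_level()]).
#' @return data.frame: reference_id, start, end (0-based half-open), peak
#'   depth, fold_over_background, annotation ("intergenic" or feature kind).
#' @export
detect_spikes <- function(track, annotations, fold = 10, min_run = 20L,
                          background = NULL) {
  bg <- if (is.null(background)) unname(background_level(track, annotations)["pooled"]) else background
  d <- pooled_depth(track)
  hot <- if (bg > 0) (d - bg) >= fold * bg else d > 0
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0L) {
    return(data.frame(reference_id = character(), start = integer(),
                      end = integer(), peak_depth = numeric(),
                      fold_over_background = numeric(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(keep, function(i) {
    s0 <- starts[i] - 1L; e0 <- ends[i]      # 0-based half-open
    peak <- max(d[starts[i]:ends[i]])
    ov <- annotations[annotations$start < e0 & annotations$end > s0, , drop = FALSE]
    lab <- if (nrow(ov) == 0L) "intergenic" else ov$kind[which.max(
      pmin(ov$end, e0) - pmax(ov$start, s0))]
    data.frame(reference_id = track$reference_id, start = s0, end = e0,
               peak_depth = peak,
               fold_over_background = if (bg > 0) peak / bg else Inf,
               annotation = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Gene-oriented span of an alignment: 0-based half-open [g5, g3) relative
# to the gene 5' end. NULL when the alignment is antisense to the gene or
# does not overlap it.
gene_span <- function(alignment, gene) {
  f <- gene$feature
  if (is.na(alignment$strand) || alignment$strand != f$strand) return(NULL)
  if (f$strand == "+") {
    g5 <- alignment$ref_start - f$start
    g3 <- alignment$ref_start + alignment$aligned_length - f$start
  } else {
    g5 <- f$end - (alignment$ref_start + alignment$aligned_length)
    g3 <- f$end - alignment$ref_start
  }
  if (g3 <= 0L || g5 >= gene$length) return(NULL)
  c(g5 = g5, g3 = g3)
}

#' Classify one read's maturation state and half label
#'
#' Works in gene orientation. The 5' call is "leader" iff the read starts
#' upstream of the gene; the 3' call is "trailer" iff the alignment extends
#' genomically past the gene end, else, if the read ends within `tol` of
#' the gene 3' end, the non-genomic soft-clipped tail determines
#' plus_C/plus_CC/plus_CCA ("" = trimmed; a gene with a genome-encoded CCA
#' is reported plus_CCA). Leader and trailer together give precursor_both.
#' Half label: "full" covers the gene within `tol` at both ends; "half5"
#' starts within `tol` of the gene 5' end and ends inside the anticodon
#' window (anticodon offset -2 .. +4); "half3" symmetrically; anything
#' else is "fragment".
#'
#' @param alignment single alignment row (sense strand of the gene).
#' @param gene a [trna_gene()].
#' @param tol end tolerance in nt (default 2).
#' @return list(state, half, five_prime_call, three_prime_call) or NULL
#'   with a "reason" attribute when the read does not overlap the gene
#'   sense strand.
#' @export
classify_read <- function(alignment, gene, tol = 2L) {
  sp <- gene_span(alignment, gene)
  if (is.null(sp)) return(NULL)   # no sense-strand overlap with the gene
  g5 <- sp[["g5"]]; g3 <- sp[["g3"]]; L <- gene$length
  ac <- gene$anticodon_offset
  window <- c(ac - 2L, ac + 4L)

  five_call <- if (g5 < 0L) "leader" else "start"
  tail <- alignment$soft_clip_3
  if (g3 > L) {
    three_call <- "trailer"
  } else if (L - g3 <= tol) {
    three_call <- if (gene$encodes_cca) "plus_CCA"
    else switch(tail, "C" = "plus_C", "CC" = "plus_CC", "CCA" = "plus_CCA",
                "trimmed")
  } else {
    three_call <- "internal"
  }

  state <- if (five_call == "leader" && three_call == "trailer") "precursor_both"
  else if (five_call == "leader") "leader_only"
  else if (three_call == "trailer") "trailer_only"
  else if (three_call %in% c("plus_C", "plus_CC", "plus_CCA")) three_call
  else "trimmed"

  covers5 <- g5 <= tol
  covers3 <- g3 >= L - tol
  in_window <- function(p) p >= window[1] && p <= window[2]
  half <- if (covers5 && covers3) "full"
  else if (abs(g5) <= tol && in_window(g3)) "half5"
  else if (covers3 && in_window(g5)) "half3"
  else "fragment"

  list(state = state, half = half,
       five_prime_call = five_call, three_prime_call = three_call,
       g5 = unname(g5), g3 = unname(g3))
}

#' Classify all reads over a set of tRNA genes
#'
#' Applies [classify_read()] to every alignment against every gene it
#' sense-overlaps (fractional multi-mapper weights are carried through).
#'
#' @param alignments alignment data.frame.
#' @param trna_genes list of [trna_gene()].
#' @param tol end tolerance (default 2).
#' @return data.frame: read_id, gene_id, state, half, five_prime_call,
#'   three_prime_call, g5, g3, weight.
#' @export
classify_reads <- function(alignments, trna_genes, tol = 2L) {
  rows <- list()
  a <- alignments[!is.na(alignments$reference_id), , drop = FALSE]
  for (g in trna_genes) {
    f <- g$feature
    # cheap prefilter on reference coordinates
    sel <- a$strand == f$strand &
      a$ref_start < f$end & (a$ref_start + a$aligned_length) > f$start
    sub <- a[which(sel), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      cl <- classify_read(sub[i, ], g, tol = tol)
      if (is.null(cl)) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sub$read_id[i], gene_id = g$gene_id, state = cl$state,
        half = cl$half, five_prime_call = cl$five_prime_call,
        three_prime_call = cl$three_prime_call, g5 = cl$g5, g3 = cl$g3,
        weight = sub$weight[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(), gene_id = character(),
                      state = character(), half = character(),
                      five_prime_call = character(),
                      three_prime_call = character(), g5 = integer(),
                      g3 = integer(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarize end states and half labels for one gene
#'
#' @param classified data.frame from [classify_reads()] (any genes; the
#'   gene's rows are selected by id).
#' @param gene a [trna_gene()].
#' @return one-row data.frame: gene_id, one count column per end state and
#'   half label (fractional weights summed), total, full_length_fraction,
#'   modal_g5, modal_g3 (modal read termini in gene coordinates).
#' @export
summarize_gene <- function(classified, gene) {
  cl <- classified[classified$gene_id == gene$gene_id, , drop = FALSE]
  state_counts <- vapply(END_STATES, function(s) sum(cl$weight[cl$state == s]), 0)
  half_counts <- vapply(HALF_LABELS, function(h) sum(cl$weight[cl$half == h]), 0)
  total <- sum(cl$weight)
  modal <- function(v, w) {
    if (length(v) == 0L) return(NA_integer_)
    t <- tapply(w, v, sum)
    as.integer(names(t)[which.max(t)])
  }
  out <- data.frame(gene_id = gene$gene_id, t(state_counts), t(half_counts),
                    total = total,
                    full_length_fraction = if (total > 0) half_counts[["full"]] / total else 0,
                    modal_g5 = modal(cl$g5, cl$weight),
                    modal_g3 = modal(cl$g3, cl$weight),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize all genes and assign expression ranks
#'
#' Ranks are assigned by total (fractional) read count descending, ties
#' broken alphabetically by gene id; genes with no reads rank last.
#'
#' @param classified data.frame from [classify_reads()].
#' @param trna_genes list of [trna_gene()].
#' @return data.frame, one row per gene, with `expression_rank`.
#' @export
summarize_genes <- function(classified, trna_genes) {
  out <- do.call(rbind, lapply(trna_genes, summarize_gene, classified = classified))
  ord <- order(-out$total, out$gene_id)
  out$expression_rank <- NA_integer_
  out$expression_rank[ord] <- seq_len(nrow(out))
  out
}
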