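#' Per-position pileup over tRNA loci
#'
#' Builds one profile row per position of each gene plus `flank` nt on
#' each side, in gene orientation. Only sense-strand alignments contribute
#' (antisense transcription is reported separately); soft-clipped tail
#' bases are excluded; multi-mapped reads contribute their fractional
#' weight 1/k.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param genome the reference `genome`.
#' @param trna_genes list of [trna_gene()].
#' @param flank flank width in nt (default 15); truncated with a warning
#'   at the ends of a non-circular genome.
#' @return data.frame: gene_id, position (gene-oriented, -flank ..
#'   length+flank-1, 0 = first gene base), ref_base, count_A, count_C,
#'   count_G, count_T, depth, mismatch_fraction (NA at depth 0).
#' @export
pileup <- function(alignments, genome, trna_genes, flank = 15L) {
  a <- alignments[!is.na(alignments$reference_id) &
                    alignments$reference_id == genome$id, , drop = FALSE]
  # aggregate identical placements (duplicate reads) once
  if (nrow(a)) {
    key <- paste(a$sequence, a$ref_start, a$strand, a$aligned_length)
    agg <- tapply(a$weight, key, sum)
    first <- a[!duplicated(key), , drop = FALSE]
    first$weight <- as.numeric(agg[paste(first$sequence, first$ref_start,
                                         first$strand, first$aligned_length)])
    a <- first
  }
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (g in trna_genes) {
    f <- g$feature
    lo <- f$start - flank; hi <- f$end + flank
    if ((lo < 0L || hi > genome$length) && !genome$circular) {
      warning("flank truncated at genome end for gene '", g$gene_id, "'")
      lo <- max(lo, 0L); hi <- min(hi, genome$length)
    }
    # gene-oriented positions covered by the (possibly truncated) window
    if (f$strand == "+") {
      gpos_lo <- lo - f$start; gpos_hi <- hi - f$start - 1L
    } else {
      gpos_lo <- f$end - hi; gpos_hi <- f$end - lo - 1L
    }
    win_seq <- gene_sequence(genome, data.frame(start = lo, end = hi,
                                                strand = f$strand))
    npos <- hi - lo
    counts <- matrix(0, nrow = 4L, ncol = npos, dimnames = list(bases, NULL))
    sel <- which(a$strand == f$strand & a$ref_start < hi &
                   (a$ref_start + a$aligned_length) > lo)
    for (i in sel) {
      sp <- gene_span(a[i, ], g)
      if (is.null(sp)) {
        # overlaps the flank window but not the gene body: still count
        if (f$strand == "+") {
          g5 <- a$ref_start[i] - f$start
        } else {
          g5 <- f$end - (a$ref_start[i] + a$aligned_length[i])
        }
      } else g5 <- sp[["g5"]]
      aseq <- substr(a$sequence[i], 1L, a$aligned_length[i])
      rb <- strsplit(aseq, "")[[1]]
      gp <- g5 + seq_along(rb) - 1L           # gene-oriented positions
      keep <- gp >= gpos_lo & gp <= gpos_hi
      if (!any(keep)) next
      col <- gp[keep] - gpos_lo + 1L
      idx <- cbind(match(rb[keep], bases), col)
      ok <- !is.na(idx[, 1])
      counts[idx[ok, , drop = FALSE]] <- counts[idx[ok, , drop = FALSE]] + a$weight[i]
    }
    depth <- colSums(counts)
    ref_b <- strsplit(win_seq, "")[[1]]
    ref_count <- counts[cbind(match(ref_b, bases), seq_len(npos))]
    mf <- ifelse(depth > 0, 1 - ref_count / depth, NA_real_)
    out[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, position = gpos_lo:gpos_hi, ref_base = ref_b,
      count_A = counts["A", ], count_C = counts["C", ],
      count_G = counts["G", ], count_T = counts["T", ],
      depth = depth, mismatch_fraction = mf, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call candidate modification sites from pileup mismatch fractions
#'
#' A site is called iff depth >= `min_depth` AND mismatch fraction is
#' strictly greater than `min_freq` (a site at exactly the threshold is
#' not called). Calls are sorted by gene then position.
#'
#' @param profiles data.frame from [pileup()].
#' @param min_depth minimum read depth (default 10).
#' @param min_freq polymorphism threshold, exclusive (default 0.02).
#' @return data.frame: gene_id, position, ref_base, mismatch_fraction,
#'   depth, alt_base (dominant non-reference base).
#' @export
call_modifications <- function(profiles, min_depth = 10, min_freq = 0.02) {
  sel <- !is.na(profiles$mismatch_fraction) &
    profiles$depth >= min_depth & profiles$mismatch_fraction > min_freq
  p <- profiles[sel, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(gene_id = character(), position = integer(),
                      ref_base = character(), mismatch_fraction = numeric(),
                      depth = numeric(), alt_base = character(),
                      stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(p[, paste0("count_", bases)])
  cnt[cbind(seq_len(nrow(p)), match(p$ref_base, bases))] <- -Inf
  alt <- bases[max.col(cnt, ties.method = "first")]
  out <- data.frame(gene_id = p$gene_id, position = p$position,
                    ref_base = p$ref_base,
                    mismatch_fraction = p$mismatch_fraction, depth = p$depth,
                    alt_base = alt, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative tRNA abundance within a library
#'
#' Each gene's (fractional) read count over the total count assigned to
#' all tRNAs in the sample.
#'
#' @param per_gene_counts named non-negative numeric vector.
#' @return named vector of fractions summing to 1.
#' @export
relative_abundance <- function(per_gene_counts) {
  if (any(per_gene_counts < 0)) stop("counts must be >= 0")
  total <- sum(per_gene_counts)
  if (total == 0) stop("total tRNA-assigned count is zero")
  per_gene_counts / total
}

# all permutations of 1..n as a matrix (n! rows)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with midrank ties
#'
#' rho is the Pearson correlation of average (midrank) ranks. The p-value
#' is exact (full permutation enumeration of one margin, two-sided) for
#' n <= 8, and a t approximation with n-2 degrees of freedom otherwise.
#'
#' @param a,b paired numeric vectors, length >= 3.
#' @return list(rho, p_value, n); rho is NA for a constant vector.
#' @export
spearman <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("need paired vectors of length >= 3")
  ra <- rank(a); rb <- rank(b)
  if (sd(ra) == 0 || sd(rb) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- cor(ra, rb)
  if (n <= 8L) {
    perms <- permutations(n)
    rho_perm <- apply(perms, 1L, function(p) cor(ra, rb[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Symmetric signed abundance ratio
#'
#' r = a/b; ratios below 1 are reported as -1/r, so a two-fold drop is -2
#' and magnitude is always >= 1.
#'
#' @param a,b paired positive normalized abundances.
#' @return numeric vector; NA (with a warning) where b is zero.
#' @export
signed_ratio <- function(a, b) {
  out <- rep(NA_real_, length(a))
  zero <- b == 0
  if (any(zero)) warning("zero denominator: NA returned for ", sum(zero), " gene(s)")
  r <- a[!zero] / b[!zero]
  out[!zero] <- ifelse(r < 1, -1 / r, r)
  out
}

#' Compare per-gene tRNA abundances between two libraries
#'
#' @param counts_a,counts_b named per-gene (fractional) counts; names must
#'   agree.
#' @return list with rel_a, rel_b (relative abundances), spearman_rho,
#'   p_value, and a per-gene data.frame with the signed ratio.
#' @export
compare_libraries <- function(counts_a, counts_b) {
  genes <- union(names(counts_a), names(counts_b))
  ca <- setNames(rep(0, length(genes)), genes); ca[names(counts_a)] <- counts_a
  cb <- setNames(rep(0, length(genes)), genes); cb[names(counts_b)] <- counts_b
  ra <- relative_abundance(ca); rb <- relative_abundance(cb)
  sp <- spearman(ra, rb)
  per_gene <- data.frame(gene_id = genes, rel_a = unname(ra), rel_b = unname(rb),
                         signed_ratio = suppressWarnings(signed_ratio(unname(ra), unname(rb))),
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene, spearman_rho = sp$rho, p_value = sp$p_value)
}
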