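SIM_STATES <- c("precursor_both", "leader_only", "trailer_only", "trimmed",
                "plus_C", "plus_CC", "plus_CCA")

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic small-RNA library over
#' annotated tRNA genes: the maturation-state mixture (precursor with
#' genomic leader/trailer, trimmed, stepwise +C/+CC/+CCA), anticodon-loop
#' half cleavage, per-site misincorporation mimicking base modifications,
#' uniform background reads from CDS regions, optional chimeric ligation
#' artifacts, and an emitted length window.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param n_reads number of molecules drawn (emitted read count can differ:
#'   a cleaved molecule emits each half independently with probability 0.5,
#'   and reads outside `len_window` are discarded).
#' @param trna_weights named numeric vector, relative expression weight per
#'   gene_id.
#' @param state_probs named probability vector over the seven maturation
#'   states; must sum to 1.
#' @param half_prob probability a molecule is cleaved into halves.
#' @param cleavage_window integer c(lo, hi), inclusive cut window relative
#'   to the anticodon offset (default -2..+4).
#' @param leader_len,trailer_len integer c(min, max) genomic leader/trailer
#'   lengths for precursor states (default 3..10 nt, strictly longer than
#'   the classifier's end tolerance so leaders are never mistaken for
#'   end-trimming jitter).
#' @param mod_sites data.frame(gene_id, position, rate) of per-site
#'   misincorporation rates; `position` is 0-based in gene orientation.
#'   Optional column `truncation`: probability reverse transcription stops
#'   at the site (default 0), emitting only the 3' part of the molecule.
#' @param background_rate fraction of molecules drawn uniformly from CDS
#'   regions.
#' @param chimera_rate fraction of molecules that are ligation chimeras
#'   (5' half of one gene joined to the 3' half of another at the
#'   anticodon).
#' @param len_window inclusive emitted read length window, default c(18, 100).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 10000L, trna_weights = NULL,
                       state_probs = c(precursor_both = 0.10, leader_only = 0.10,
                                       trailer_only = 0.10, trimmed = 0.20,
                                       plus_C = 0.10, plus_CC = 0.10,
                                       plus_CCA = 0.30),
                       half_prob = 0.5, cleavage_window = c(-2L, 4L),
                       leader_len = c(3L, 10L), trailer_len = c(3L, 10L),
                       mod_sites = NULL, background_rate = 0.1,
                       chimera_rate = 0, len_window = c(18L, 100L)) {
  state_probs <- state_probs[SIM_STATES]
  if (anyNA(state_probs)) stop("state_probs must be named over: ",
                               paste(SIM_STATES, collapse = ","))
  if (abs(sum(state_probs) - 1) > 1e-9) stop("state_probs must sum to 1")
  rates <- c(half_prob, background_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  if (background_rate + chimera_rate > 1) stop("background_rate + chimera_rate > 1")
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (!is.null(mod_sites)) {
    stopifnot(all(c("gene_id", "position", "rate") %in% names(mod_sites)))
    if (any(mod_sites$rate < 0 | mod_sites$rate > 1)) stop("mod rates must lie in [0,1]")
    if (is.null(mod_sites$truncation)) mod_sites$truncation <- 0
  }
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 trna_weights = trna_weights, state_probs = state_probs,
                 half_prob = half_prob, cleavage_window = as.integer(cleavage_window),
                 leader_len = as.integer(leader_len),
                 trailer_len = as.integer(trailer_len),
                 mod_sites = mod_sites, background_rate = background_rate,
                 chimera_rate = chimera_rate, len_window = as.integer(len_window)),
            class = "sim_config")
}

# Gene-oriented sequence context: body plus up to `pad` nt of genomic
# flank on each side, in gene orientation.
gene_context <- function(genome, gene, pad = 12L) {
  f <- gene$feature
  if (f$strand == "+") {
    up <- if (f$start >= pad) genome_subseq(genome, f$start - pad, f$start) else
      substr(genome$sequence, 1L, f$start)
    dn_end <- min(genome$length, f$end + pad)
    dn <- if (dn_end > f$end) genome_subseq(genome, f$end, dn_end) else ""
  } else {
    dn0 <- if (f$start >= pad) genome_subseq(genome, f$start - pad, f$start) else
      substr(genome$sequence, 1L, f$start)
    up0_end <- min(genome$length, f$end + pad)
    up0 <- if (up0_end > f$end) genome_subseq(genome, f$end, up0_end) else ""
    up <- revcomp(up0); dn <- revcomp(dn0)
  }
  list(body = gene_sequence(genome, f), upstream = up, downstream = dn)
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

# sample() treats a scalar as 1:n; pick() never does.
pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)

#' Simulate a small-RNA library with per-read ground truth
#'
#' Each tRNA molecule is built by drawing a gene by weight, a maturation
#' state (precursor states carry genomic leader/trailer; plus_C/CC/CCA an
#' equally long non-genomic 3' suffix), optional cleavage into 5'/3'
#' halves at a uniform position in the anticodon window (each half emitted
#' independently with probability 0.5), and per-site misincorporation.
#' Reads outside the length window are discarded and counted. Background
#' molecules are uniform CDS substrings; chimera molecules join two tRNA
#' halves from different genes.
#'
#' @param config a [sim_config()].
#' @param genome a [genome()] whose annotations include the CDS features
#'   used for background reads.
#' @param trna_genes list of [trna_gene()] within the genome.
#' @return list with `reads` (data.frame read_id, sequence), `truth`
#'   (data.frame, one row per emitted read) and `n_discarded`.
#' @export
simulate_reads <- function(config, genome, trna_genes) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- vapply(trna_genes, `[[`, "", "gene_id")
  names(trna_genes) <- gene_ids
  w <- config$trna_weights
  if (is.null(w)) w <- setNames(rep(1, length(gene_ids)), gene_ids)
  w <- w[gene_ids]
  if (anyNA(w) || any(w < 0)) stop("trna_weights must be named, non-negative, covering all genes")
  trna_frac <- 1 - config$background_rate - config$chimera_rate
  if (length(gene_ids) == 0L && trna_frac > 0) stop("empty gene list with tRNA fraction > 0")
  if (length(gene_ids) > 0L && sum(w) == 0 && trna_frac > 0) stop("all-zero weight vector")
  if (config$chimera_rate > 0 && length(gene_ids) < 2L) {
    stop("chimera_rate > 0 requires at least two tRNA genes")
  }

  cds <- NULL
  if (!is.null(genome$annotations)) {
    cds <- genome$annotations[genome$annotations$kind == "CDS", , drop = FALSE]
  }
  if (config$background_rate > 0 && (is.null(cds) || nrow(cds) == 0L)) {
    stop("background_rate > 0 requires CDS annotations")
  }

  ctx <- lapply(trna_genes, gene_context, genome = genome,
                pad = max(config$leader_len[2], config$trailer_len[2]))
  mods_by_gene <- list()
  if (!is.null(config$mod_sites)) {
    mods_by_gene <- split(config$mod_sites, config$mod_sites$gene_id)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  seqs <- character(0); truth_rows <- list(); n_disc <- 0L; k <- 0L
  lw <- config$len_window
  emit <- function(seq, gene_id, state, molecule_state, half, cleavage, mods) {
    len <- nchar(seq)
    if (len < lw[1] || len > lw[2]) { n_disc <<- n_disc + 1L; return(invisible()) }
    k <<- k + 1L
    seqs[[k]] <<- seq
    truth_rows[[k]] <<- data.frame(
      read_id = sprintf("read%07d", k), gene_id = gene_id, state = state,
      molecule_state = molecule_state, half = half,
      cleavage_pos = if (is.null(cleavage)) NA_integer_ else cleavage,
      mod_positions = if (length(mods)) paste(mods, collapse = ",") else "",
      stringsAsFactors = FALSE)
  }

  draw_half_molecule <- function(gene, ctx1) {
    # returns (5' half string up to cut, cut position in gene coords)
    cut <- pick(seq(gene$anticodon_offset + config$cleavage_window[1],
                    gene$anticodon_offset + config$cleavage_window[2]))
    list(cut = cut)
  }

  for (m in seq_len(config$n_reads)) {
    u <- runif(1)
    if (u < config$background_rate) {
      ci <- if (nrow(cds) == 1L) 1L else
        sample(seq_len(nrow(cds)), 1L, prob = cds$end - cds$start)
      clen <- cds$end[ci] - cds$start[ci]
      rlen <- pick(seq(lw[1], min(lw[2], clen)))
      off <- pick(seq(0L, clen - rlen))
      cseq <- gene_sequence(genome, cds[ci, , drop = FALSE])
      emit(substr(cseq, off + 1L, off + rlen), "background", "background",
           "background", "fragment", NULL, integer())
      next
    }
    if (u < config$background_rate + config$chimera_rate) {
      gi <- sample(gene_ids, 2L, replace = FALSE, prob = w)
      gA <- trna_genes[[gi[1]]]; gB <- trna_genes[[gi[2]]]
      cutA <- draw_half_molecule(gA)$cut
      cutB <- draw_half_molecule(gB)$cut
      seqA <- substr(ctx[[gi[1]]]$body, 1L, cutA)
      seqB <- substr(ctx[[gi[2]]]$body, cutB + 1L, gB$length)
      emit(paste0(seqA, seqB), paste0("chimera:", gi[1], "+", gi[2]),
           "chimera", "chimera", "fragment", cutA, integer())
      next
    }
    gid <- if (length(gene_ids) == 1L) gene_ids else sample(gene_ids, 1L, prob = w)
    gene <- trna_genes[[gid]]
    cx <- ctx[[gid]]
    state <- sample(SIM_STATES, 1L, prob = config$state_probs)
    leader <- ""
    trailer <- ""
    tail <- ""
    if (state %in% c("precursor_both", "leader_only")) {
      ll <- pick(seq(config$leader_len[1], config$leader_len[2]))
      ll <- min(ll, nchar(cx$upstream))
      leader <- substr(cx$upstream, nchar(cx$upstream) - ll + 1L, nchar(cx$upstream))
    }
    if (state %in% c("precursor_both", "trailer_only")) {
      tl <- pick(seq(config$trailer_len[1], config$trailer_len[2]))
      tl <- min(tl, nchar(cx$downstream))
      trailer <- substr(cx$downstream, 1L, tl)
    }
    if (state %in% c("plus_C", "plus_CC", "plus_CCA")) {
      tail <- switch(state, plus_C = "C", plus_CC = "CC", plus_CCA = "CCA")
    }
    body <- cx$body
    mod_hits <- integer()
    ms <- mods_by_gene[[gid]]
    if (!is.null(ms)) {
      truncated_at <- NA_integer_
      for (r in seq_len(nrow(ms))) {
        pos <- ms$position[r]
        if (pos < 0L || pos >= gene$length) next
        if (ms$truncation[r] > 0 && runif(1) < ms$truncation[r]) {
          truncated_at <- if (is.na(truncated_at)) pos else max(truncated_at, pos)
        } else if (runif(1) < ms$rate[r]) {
          substr(body, pos + 1L, pos + 1L) <- substitute_base(substr(body, pos + 1L, pos + 1L))
          mod_hits <- c(mod_hits, pos)
        }
      }
      if (!is.na(truncated_at)) {
        # RT stops at the modified base: only the 3' part survives
        body <- substr(body, truncated_at + 2L, gene$length)
        emit(paste0(body, tail, trailer), gid, "truncated", state, "fragment",
             NULL, sort(mod_hits[mod_hits > truncated_at]))
        next
      }
    }
    read <- paste0(leader, body, tail, trailer)
    if (runif(1) < config$half_prob) {
      # a 5' product only shows its 5' state; a 3' product only its 3' state
      cut <- draw_half_molecule(gene)$cut
      cut_in_read <- nchar(leader) + cut
      state5 <- if (nzchar(leader)) "leader_only" else "trimmed"
      state3 <- switch(state,
                       precursor_both = "trailer_only",
                       trailer_only = "trailer_only",
                       leader_only = "trimmed",
                       state)
      half5_lab <- if (nzchar(leader)) "fragment" else "half5"
      if (runif(1) < 0.5) {
        emit(substr(read, 1L, cut_in_read), gid, state5, state, half5_lab,
             cut, sort(mod_hits[mod_hits < cut]))
      }
      if (runif(1) < 0.5) {
        emit(substr(read, cut_in_read + 1L, nchar(read)), gid, state3, state,
             "half3", cut, sort(mod_hits[mod_hits >= cut]))
      }
    } else {
      emit(read, gid, state, state, "full", NULL, sort(mod_hits))
    }
  }
  truth <- if (k > 0L) do.call(rbind, truth_rows) else
    data.frame(read_id = character(), gene_id = character(), state = character(),
               half = character(), cleavage_pos = integer(),
               mod_positions = character(), stringsAsFactors = FALSE)
  reads <- data.frame(read_id = truth$read_id, sequence = unlist(seqs, use.names = FALSE) %||% character(),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, n_discarded = n_disc)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write reads as FASTQ
#'
#' Quality strings are constant "I"; quality is never used downstream.
#'
#' @param reads data.frame(read_id, sequence).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) { writeLines(character(), path); return(invisible(path)) }
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path (4-line records).
#' @return data.frame(read_id, sequence).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[idx]))
  data.frame(read_id = ids, sequence = toupper(lines[idx + 1L]),
             stringsAsFactors = FALSE)
}

TRUTH_COLS <- c("read_id", "gene_id", "state", "molecule_state", "half",
                "cleavage_pos", "mod_positions")

#' Write / read the simulation truth table
#'
#' Lossless TSV round trip of the per-read ground truth emitted by
#' [simulate_reads()].
#'
#' @param truth truth data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(TRUTH_COLS %in% names(truth)))
  write.table(truth[TRUTH_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L ||
      (length(lines) == 1L && !nzchar(trimws(lines)))) {
    return(data.frame(read_id = character(), gene_id = character(),
                      state = character(), molecule_state = character(),
                      half = character(), cleavage_pos = integer(),
                      mod_positions = character(), stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(TRUTH_COLS, header)
  if (length(miss)) stop("truth file missing column(s): ", paste(miss, collapse = ","))
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < length(header) - 1L | nf > length(header))
  if (length(bad)) stop("malformed truth row at line ", bad[1] + 1L)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", colClasses = c(
                     read_id = "character", gene_id = "character",
                     state = "character", molecule_state = "character",
                     half = "character", cleavage_pos = "integer",
                     mod_positions = "character"))
  df$mod_positions[is.na(df$mod_positions)] <- ""
  df[TRUTH_COLS]
}

#' Build an annotated toy genome for simulation
#'
#' Constructs a linear genome containing CDS features (background read
#' source) and randomly sequenced tRNA genes of length 72 with the
#' anticodon at offset 34. The base immediately 3' of every gene (gene
#' orientation) is forced to A/G/T so a non-genomic C/CC/CCA tail is never
#' confounded with a genomic trailer; real genomes do not grant this, see
#' the methods vignette. Optional hidden tRNA genes are placed in
#' intergenic space but left out of the annotation table (spike-detection
#' scenario).
#'
#' @param seed RNG seed.
#' @param n_trna number of annotated tRNA genes (alternating strands).
#' @param n_hidden number of unannotated tRNA-like loci.
#' @param gene_len tRNA gene length (default 72).
#' @param anticodon_offset anticodon start within the gene (default 34).
#' @param n_cds number of CDS features (default 2, 450 nt each).
#' @return list with `genome`, `trna_genes` (annotated), `hidden_genes`.
#' @export
build_toy_genome <- function(seed = 42L, n_trna = 2L, n_hidden = 0L,
                             gene_len = 72L, anticodon_offset = 34L,
                             n_cds = 2L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anticodons <- c("TGC", "GAA", "CAT", "TGG", "GCC", "TCC", "GTT", "GTG")
  aas <- c("Ala", "Phe", "Met", "Pro", "Gly", "Gly", "Asn", "His")
  n_total <- n_trna + n_hidden
  stopifnot(n_total <= length(anticodons))
  margin <- 60L
  cds_len <- 450L
  spacer <- 80L
  pieces <- character(0)
  feats <- list(); genes <- list(); hidden <- list()
  pos <- 0L
  add_seq <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  add_seq(paste(sample(bases, margin, replace = TRUE), collapse = ""))
  for (i in seq_len(n_cds)) {
    start <- pos
    add_seq(paste(sample(bases, cds_len, replace = TRUE), collapse = ""))
    feats[[length(feats) + 1L]] <- feature(sprintf("CDS_%02d", i), "CDS",
                                           start, pos, "+")
    add_seq(paste(sample(bases, spacer, replace = TRUE), collapse = ""))
  }
  for (i in seq_len(n_total)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    gseq <- paste(sample(bases, gene_len, replace = TRUE), collapse = "")
    substr(gseq, anticodon_offset + 1L, anticodon_offset + 3L) <- anticodons[i]
    # avoid an accidental genome-encoded CCA end
    if (substr(gseq, gene_len - 2L, gene_len) == "CCA") {
      substr(gseq, gene_len, gene_len) <- "G"
    }
    genomic <- if (strand == "+") gseq else revcomp(gseq)
    start <- pos
    add_seq(genomic)
    # gene-oriented downstream flank: first base must not be C
    flank <- paste(sample(bases, spacer, replace = TRUE), collapse = "")
    if (strand == "+") {
      if (substr(flank, 1L, 1L) == "C") substr(flank, 1L, 1L) <- "T"
      add_seq(flank)
    } else {
      # for a minus gene the downstream flank is upstream in genome coords:
      # patch the last base of the previously appended spacer region
      prev <- pieces[[length(pieces) - 1L]]
      if (substr(prev, nchar(prev), nchar(prev)) == "G") {
        substr(prev, nchar(prev), nchar(prev)) <- "A"
      }
      pieces[[length(pieces) - 1L]] <- prev
      add_seq(flank)
    }
    id <- sprintf("%s%03d", aas[i], i)
    f <- feature(id, "tRNA", start, pos - spacer, strand)
    g <- NULL  # construct after genome assembly for verification
    if (i <= n_trna) {
      feats[[length(feats) + 1L]] <- f
      genes[[length(genes) + 1L]] <- list(f = f, anticodon = anticodons[i], aa = aas[i])
    } else {
      hidden[[length(hidden) + 1L]] <- list(f = f, anticodon = anticodons[i], aa = aas[i])
    }
  }
  add_seq(paste(sample(bases, margin, replace = TRUE), collapse = ""))
  ann <- do.call(rbind, feats)
  gnm <- genome("toy", paste(pieces, collapse = ""), circular = FALSE,
                annotations = ann)
  mk <- function(x) trna_gene(x$f, x$aa, x$anticodon, anticodon_offset,
                              encodes_cca = FALSE, genome = gnm)
  list(genome = gnm, trna_genes = lapply(genes, mk),
       hidden_genes = lapply(hidden, mk))
}
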