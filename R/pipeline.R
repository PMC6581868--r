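#' Write a coverage track as bedGraph
#'
#' One file per call; `class` selects a length class (index) or, when
#' NULL, the pooled track.
#'
#' @param track a [coverage()] track.
#' @param path output path.
#' @param class length-class index or NULL for pooled depth.
#' @export
write_bedgraph <- function(track, path, class = NULL) {
  d <- if (is.null(class)) pooled_depth(track) else track$depth[[class]]
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = track$reference_id, start = starts[keep],
                   end = ends[keep], value = r$values[keep])
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%g", df$chrom, df$start, df$end, df$value)),
             path)
  invisible(path)
}

#' Write spike regions as BED6
#' @param spikes data.frame from [detect_spikes()].
#' @param path output path.
#' @export
write_spikes_bed <- function(spikes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", spikes$reference_id, spikes$start,
                   spikes$end, spikes$annotation,
                   pmin(1000L, as.integer(spikes$peak_depth)), ".")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Required fields: genome_fasta, annotations (path), annotation_dialect
#' (GFF3/BED), trna_inventory, reads_fastq (or alignments_sam), out_dir,
#' seed. Optional parameter blocks: map (seed_length, max_mismatch, ...),
#' profile (tol, fold, min_run), modcall (min_depth, min_freq, flank),
#' discover (min_count, min_segment), decode (wobble_rules path).
#'
#' @param path YAML file.
#' @return named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

stage_defaults <- list(
  map = list(seed_length = 18L, max_mismatch = 3L, allow_soft_clip_3 = TRUE),
  profile = list(tol = 2L, fold = 10, min_run = 20L),
  modcall = list(min_depth = 10, min_freq = 0.02, flank = 15L),
  discover = list(min_count = 100L, min_segment = 16L,
                  collapse_min_len = 48L, collapse_max_len = 90L)
)

merge_params <- function(user, stage) {
  p <- stage_defaults[[stage]]
  if (!is.null(user)) p[names(user)] <- user
  p
}

#' Run the full analysis pipeline
#'
#' Orchestrates map -> profile -> modcall -> discover -> decode over one
#' genome and writes per-stage TSVs plus a JSON summary to the output
#' directory. Deterministic given the config (and its seed). On a stage
#' failure the error names the stage and partial outputs are retained with
#' a MANIFEST marking incompleteness.
#'
#' @param config a `pipeline_config` (or list with the same fields).
#' @return invisibly, a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")

  # ---- validate inputs before any compute or output ----
  for (p in c("genome_fasta", "annotations", "trna_inventory")) {
    if (is.null(config[[p]])) stop("config missing required field: ", p)
    if (!file.exists(config[[p]])) stop("input path does not exist: ", config[[p]])
  }
  if (is.null(config$reads_fastq) && is.null(config$alignments_sam)) {
    stop("config must name reads_fastq or alignments_sam")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines("status: INCOMPLETE", manifest)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("trnaproc %s", as.character(utils::packageVersion("trnaproc"))),
                 sprintf("seed: %s", config$seed %||% "none"))
  logi <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  gnm <- stage("load", {
    g <- read_fasta(config$genome_fasta, circular = isTRUE(config$circular))[[1]]
    ann <- read_annotations(config$annotations,
                            dialect = config$annotation_dialect %||% "GFF3")
    genome(g$id, g$sequence, circular = g$circular, annotations = ann)
  })
  genes <- stage("load", {
    read_trna_inventory(config$trna_inventory, features = gnm$annotations,
                        genome = gnm)
  })

  # ---- map ----
  mp <- merge_params(config$map, "map")
  aln <- stage("map", {
    if (!is.null(config$alignments_sam)) {
      read_sam(config$alignments_sam, references = gnm)
    } else {
      reads <- filter_reads(read_fastq(config$reads_fastq))
      logi("reads kept after length filter: %d (short %d, long %d)",
           nrow(reads), attr(reads, "n_short"), attr(reads, "n_long"))
      map_reads(reads, gnm, do.call(map_params, mp))
    }
  })
  stage("map", write_sam(aln, gnm, file.path(out_dir, "alignments.sam")))
  n_mapped <- sum(aln$mapq_class != "unmapped" & !duplicated(aln$read_id))
  logi("reads mapped: %d of %d", n_mapped, length(unique(aln$read_id)))

  # ---- profile ----
  pp <- merge_params(config$profile, "profile")
  prof <- stage("profile", {
    trk <- coverage(aln, gnm)
    bg <- background_level(trk, gnm$annotations)
    spikes <- detect_spikes(trk, gnm$annotations, fold = pp$fold,
                            min_run = pp$min_run)
    cl <- classify_reads(aln, genes, tol = pp$tol)
    summ <- summarize_genes(cl, genes)
    write_bedgraph(trk, file.path(out_dir, "coverage_pooled.bedgraph"))
    write_spikes_bed(spikes, file.path(out_dir, "spikes.bed"))
    write.table(summ, file.path(out_dir, "gene_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(track = trk, background = bg, spikes = spikes, classified = cl,
         summary = summ)
  })
  logi("background (pooled median genic): %g", prof$background[["pooled"]])

  # ---- modcall ----
  mc <- merge_params(config$modcall, "modcall")
  mods <- stage("modcall", {
    profs <- pileup(aln, gnm, genes, flank = mc$flank)
    calls <- call_modifications(profs, min_depth = mc$min_depth,
                                min_freq = mc$min_freq)
    write.table(calls, file.path(out_dir, "modification_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(profiles = profs, calls = calls)
  })
  logi("modification calls: %d", nrow(mods$calls))

  # ---- discover ----
  dc <- merge_params(config$discover, "discover")
  disc <- stage("discover", {
    reads <- if (!is.null(config$reads_fastq)) read_fastq(config$reads_fastq) else
      unique(aln[, c("read_id", "sequence")])
    coll <- collapse_reads(reads, dc$collapse_min_len, dc$collapse_max_len)
    trna_refs <- setNames(vapply(genes, function(g) gene_sequence(gnm, g$feature), ""),
                          vapply(genes, `[[`, "", "gene_id"))
    loci <- trna_loci(gnm, genes)
    cls <- classify_collapsed(coll, trna_refs, gnm, min_count = dc$min_count,
                              min_segment = dc$min_segment, loci = loci)
    chim <- cls[cls$classification == "chimera_candidate", , drop = FALSE]
    write.table(cls, file.path(out_dir, "collapsed.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(chim, file.path(out_dir, "chimeras.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(collapsed = cls, chimeras = chim)
  })
  logi("collapsed records >= min_count: %d", nrow(disc$collapsed))

  # ---- decode ----
  dec <- stage("decode", {
    inv <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                      anticodon = vapply(genes, `[[`, "", "anticodon"))
    rules <- if (!is.null(config$decode$wobble_rules)) {
      wobble_rules(config$decode$wobble_rules)
    } else wobble_rules()
    cds <- gnm$annotations[gnm$annotations$kind == "CDS", , drop = FALSE]
    cu <- codon_usage(vapply(seq_len(nrow(cds)), function(i) {
      gene_sequence(gnm, cds[i, , drop = FALSE])
    }, ""))
    tab <- decodability(inv, rules, cu)
    write.table(tab, file.path(out_dir, "decoding_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(table = tab, redundancy = redundancy(inv))
  })
  logi("redundancy: %g", dec$redundancy)

  summary <- list(
    genome = gnm$id,
    n_reads_mapped = n_mapped,
    background = as.list(prof$background),
    gene_summary = prof$summary,
    spikes = prof$spikes,
    modification_calls = mods$calls,
    chimeras = disc$chimeras,
    decoding = list(
      n_undecodable = sum(dec$table$status == "undecodable"),
      undecodable_amino_acids = attr(dec$table, "undecodable_amino_acids"),
      redundancy = dec$redundancy))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  writeLines("status: COMPLETE", manifest)
  invisible(list(alignments = aln, profile = prof, modcall = mods,
                 discover = disc, decode = dec, summary = summary))
}
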