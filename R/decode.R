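#' The 61 sense codons of the standard genetic code
#'
#' @return character vector of 61 DNA codons in alphabetical order
#'   (stops TAA/TAG/TGA excluded).
#' @export
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  sort(names(code)[code != "*"])
}

#' Translate a DNA codon under the standard code
#' @param codon 3-nt DNA string(s).
#' @return one-letter amino acid code(s), "*" for stops.
#' @export
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' The eight 4-box codon families
#'
#' A 4-box family is a codon box (fixed first two bases) whose four codons
#' all encode the same amino acid: Leu-CTN, Val-GTN, Ser-TCN, Pro-CCN,
#' Thr-ACN, Ala-GCN, Arg-CGN, Gly-GGN.
#'
#' @return data.frame with columns prefix, amino_acid, codons (comma list).
#' @export
four_box_families <- function() {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  prefixes <- sort(as.vector(outer(bases, bases, paste0)))
  rows <- lapply(prefixes, function(p) {
    cods <- paste0(p, bases)
    aas <- unname(code[cods])
    if (length(unique(aas)) == 1L && aas[1] != "*") {
      data.frame(prefix = p, amino_acid = aas[1],
                 codons = paste(cods, collapse = ","))
    } else NULL
  })
  do.call(rbind, rows)
}

# Normalize the various tRNA-set representations (list of trna_gene, data
# frame, character vector of anticodons) to a data.frame with gene_id,
# anticodon, modification.
as_trna_table <- function(trna_set) {
  if (is.data.frame(trna_set)) {
    df <- trna_set
    if (!"anticodon" %in% names(df)) stop("tRNA set needs an 'anticodon' column")
    if (!"gene_id" %in% names(df)) df$gene_id <- paste0("trna", seq_len(nrow(df)))
    if (!"modification" %in% names(df)) df$modification <- "none"
  } else if (is.character(trna_set)) {
    df <- data.frame(gene_id = paste0("trna", seq_along(trna_set)),
                     anticodon = trna_set, modification = "none")
  } else {
    df <- data.frame(
      gene_id = vapply(trna_set, `[[`, "", "gene_id"),
      anticodon = vapply(trna_set, `[[`, "", "anticodon"),
      modification = vapply(trna_set, function(g) {
        m <- g$modification; if (is.null(m)) "none" else m
      }, ""))
  }
  df$anticodon <- chartr("Uu", "Tt", toupper(df$anticodon))
  df$modification[is.na(df$modification) | df$modification == ""] <- "none"
  if (any(nchar(df$anticodon) != 3L) || any(grepl("[^ACGT]", df$anticodon))) {
    stop("anticodons must be 3-nt ACGT/U strings")
  }
  df
}

#' Four-box tRNA redundancy statistic
#'
#' The number of tRNA genes whose cognate codon (the exact reverse
#' complement of the anticodon) lies in a 4-box family, divided by the
#' fixed number of 4-box families (8). A value of 1 means one gene per
#' family; 4 means one gene per codon of every family. Genes of 6-box
#' amino acids count only through their 4-box sub-box (e.g. Leu-CTN but
#' not Leu-TTR).
#'
#' @param trna_set anticodon inventory (see [decodability()] for accepted
#'   forms).
#' @return numeric scalar.
#' @export
redundancy <- function(trna_set) {
  fam <- four_box_families()
  fam_codons <- unlist(strsplit(fam$codons, ","))
  if (is.data.frame(trna_set) && nrow(trna_set) == 0L) return(0)
  if (!is.data.frame(trna_set) && length(trna_set) == 0L) return(0)
  df <- as_trna_table(trna_set)
  cognate <- revcomp(df$anticodon)
  sum(cognate %in% fam_codons) / nrow(fam)
}

#' Default N34 wobble pairing rules
#'
#' Reads the packaged rule table (editable TSV) mapping the anticodon
#' wobble base (position 34), with an optional modification tag, to the
#' set of codon third-position bases it can read. Unmodified rules yield
#' status "wobble"; modification-tagged rules yield "modified_wobble".
#'
#' @param path optional alternative rule TSV (columns anticodon34,
#'   modification, reads).
#' @return data.frame(anticodon34, modification, reads).
#' @export
wobble_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wobble_rules.tsv", package = "trnaproc")
  }
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("anticodon34", "modification", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("wobble rule table missing columns: ", paste(miss, collapse = ","))
  df$anticodon34 <- chartr("U", "T", toupper(df$anticodon34))
  df$reads <- chartr("Uu", "Tt", toupper(df$reads))
  df
}

#' Codon decodability under a tRNA set and wobble rules
#'
#' For every sense codon the strongest available status is reported:
#' `perfect` (some anticodon is the exact reverse complement) >
#' `wobble` (positions 35/36 Watson-Crick, position 34 readable under an
#' unmodified rule) > `modified_wobble` (readable only via a
#' modification-tagged rule) > `undecodable`.
#'
#' @param trna_set a data.frame with columns gene_id, anticodon and
#'   optionally modification (tag matching the rule table; "none" default),
#'   a list of [trna_gene()] objects, or a character vector of anticodons.
#' @param rules wobble rule table, default [wobble_rules()].
#' @param codon_usage optional [codon_usage()] table; when given, per-codon
#'   usage counts are attached.
#' @return data.frame with one row per sense codon: codon, amino_acid,
#'   status, trna_gene_id (NA when undecodable), usage (if supplied).
#'   Attribute "undecodable_amino_acids" lists amino acids none of whose
#'   codons are decodable.
#' @export
decodability <- function(trna_set, rules = wobble_rules(), codon_usage = NULL) {
  df <- if ((is.data.frame(trna_set) && nrow(trna_set) == 0L) ||
            (!is.data.frame(trna_set) && length(trna_set) == 0L)) {
    data.frame(gene_id = character(), anticodon = character(),
               modification = character())
  } else as_trna_table(trna_set)
  known_tags <- unique(rules$modification)
  bad <- setdiff(df$modification, known_tags)
  if (length(bad)) {
    stop("unknown modification tag(s): ", paste(bad, collapse = ","),
         "; known tags: ", paste(known_tags, collapse = ","))
  }
  codons <- sense_codons()
  status <- rep("undecodable", length(codons))
  decoder <- rep(NA_character_, length(codons))
  rank <- c(perfect = 3L, wobble = 2L, modified_wobble = 1L, undecodable = 0L)
  for (i in seq_len(nrow(df))) {
    ac <- df$anticodon[i]
    cognate <- revcomp(ac)                    # exact Watson-Crick partner
    base34 <- substr(ac, 1L, 1L)
    rule <- rules[rules$anticodon34 == base34 & rules$modification == df$modification[i], ]
    readable3 <- if (nrow(rule)) strsplit(rule$reads[1], ",")[[1]] else character()
    rule_status <- if (df$modification[i] == "none") "wobble" else "modified_wobble"
    for (j in seq_along(codons)) {
      cod <- codons[j]
      st <- NULL
      if (cod == cognate) {
        st <- "perfect"
      } else if (substr(cod, 1L, 2L) == substr(cognate, 1L, 2L) &&
                 substr(cod, 3L, 3L) %in% readable3) {
        st <- rule_status
      }
      if (!is.null(st) && rank[[st]] > rank[[status[j]]]) {
        status[j] <- st
        decoder[j] <- df$gene_id[i]
      }
    }
  }
  out <- data.frame(codon = codons, amino_acid = translate_codon(codons),
                    status = status, trna_gene_id = decoder,
                    stringsAsFactors = FALSE)
  if (!is.null(codon_usage)) out$usage <- unname(codon_usage$counts[out$codon])
  dead <- tapply(out$status == "undecodable", out$amino_acid, all)
  attr(out, "undecodable_amino_acids") <- sort(names(dead)[dead])
  out
}

#' The 20 canonical aminoacyl-tRNA synthetase families
#' @return character vector of 20 gene names (alaS ... valS).
#' @export
aars_families <- function() {
  c("alaS", "argS", "asnS", "aspS", "cysS", "glnS", "gltX", "glyS", "hisS",
    "ileS", "leuS", "lysS", "metG", "pheS", "proS", "serS", "thrS", "trpS",
    "tyrS", "valS")
}

#' Aminoacyl-tRNA synthetase completeness
#'
#' @param inventory named logical vector (or data.frame with columns
#'   family, present) covering exactly the 20 canonical aaRS families.
#' @return list with `n_present` and sorted `missing` character vector.
#' @export
aars_completeness <- function(inventory) {
  if (is.data.frame(inventory)) {
    inventory <- setNames(as.logical(inventory$present), inventory$family)
  }
  fams <- aars_families()
  if (!setequal(names(inventory), fams) || length(inventory) != 20L) {
    stop("inventory must cover exactly the 20 canonical aaRS families")
  }
  inventory <- inventory[fams]
  list(n_present = sum(inventory), missing = sort(names(inventory)[!inventory]))
}

#' Read an aaRS presence TSV
#'
#' Format: one row per organism, column `organism` then one 0/1 (or
#' TRUE/FALSE or X/blank) column per aaRS family.
#'
#' @param path TSV path; default the packaged table.
#' @param organism row to extract.
#' @return named logical vector over the 20 families.
#' @export
read_aars_presence <- function(path = NULL, organism) {
  if (is.null(path)) {
    path <- system.file("extdata", "aars_presence.tsv", package = "trnaproc")
  }
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  row <- df[df$organism == organism, , drop = FALSE]
  if (nrow(row) != 1L) stop("organism '", organism, "' not found once in ", path)
  vals <- row[, setdiff(names(df), "organism"), drop = TRUE]
  setNames(vapply(vals, function(v) {
    if (is.logical(v)) return(isTRUE(v))
    if (is.numeric(v)) return(v != 0)
    toupper(trimws(as.character(v))) %in% c("X", "1", "TRUE")
  }, FALSE), setdiff(names(df), "organism"))
}
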