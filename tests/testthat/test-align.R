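test_that("filter_reads applies the inclusive length window", {
  reads <- data.frame(read_id = paste0("r", 1:4),
                      sequence = vapply(c(10, 18, 50, 101), random_dna, ""))
  out <- filter_reads(reads)
  expect_equal(out$read_id, c("r2", "r3"))
  expect_equal(attr(out, "n_short"), 1L)
  expect_equal(attr(out, "n_long"), 1L)
  empty <- filter_reads(reads[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_short"), 0L)
})

test_that("exact reads map uniquely with zero mismatches", {
  set.seed(21)
  ref <- c(chr = random_dna(600))
  read <- substr(ref, 101, 140)
  aln <- map_reads(data.frame(read_id = "r1", sequence = read), ref)
  expect_equal(aln$ref_start, 100L)
  expect_equal(aln$n_mismatch, 0L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mapq_class, "unique")
})

test_that("reverse-complement reads map to the minus strand", {
  set.seed(22)
  ref <- c(chr = random_dna(600))
  read <- oracle_revcomp(substr(ref, 201, 260))
  aln <- map_reads(data.frame(read_id = "r1", sequence = read), ref)
  expect_equal(aln$strand, "-")
  expect_equal(aln$ref_start, 200L)
  expect_equal(aln$n_mismatch, 0L)
})

test_that("non-genomic CCA tails are soft clipped", {
  set.seed(23)
  ref <- random_dna(400)
  # make sure the genomic continuation is not C
  if (substr(ref, 241, 241) == "C") substr(ref, 241, 241) <- "G"
  names(ref) <- "chr"
  read <- paste0(substr(ref, 171, 240), "CCA")
  aln <- map_reads(data.frame(read_id = "r1", sequence = read), ref)
  expect_equal(aln$soft_clip_3, "CCA")
  expect_equal(aln$aligned_length, 70L)
  expect_equal(aln$n_mismatch, 0L)
})

test_that("soft clipping never increases the reported mismatch count", {
  set.seed(24)
  ref <- c(chr = random_dna(800))
  for (i in 1:40) {
    st <- sample(1:700, 1)
    read <- substr(ref, st, st + sample(25:60, 1))
    tail <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1), replace = TRUE),
                  collapse = "")
    read <- paste0(read, tail)
    a_clip <- map_reads(data.frame(read_id = "r", sequence = read), ref,
                        map_params(allow_soft_clip_3 = TRUE))
    a_noclip <- map_reads(data.frame(read_id = "r", sequence = read), ref,
                          map_params(allow_soft_clip_3 = FALSE))
    if (a_clip$mapq_class[1] != "unmapped" && a_noclip$mapq_class[1] != "unmapped") {
      expect_lte(a_clip$n_mismatch[1], a_noclip$n_mismatch[1])
    }
  }
})

test_that("reads shorter than the seed length are unmapped with reason", {
  ref <- c(chr = random_dna(200))
  aln <- map_reads(data.frame(read_id = "r1", sequence = "ACGTACGTACGT"), ref)
  expect_equal(aln$mapq_class, "unmapped")
  expect_equal(aln$n_best, 0L)
})

test_that("duplicated loci give fractional multi-mappers", {
  set.seed(25)
  core <- random_dna(60)
  ref <- c(chr = paste0(random_dna(50), core, random_dna(80), core, random_dna(50)))
  aln <- map_reads(data.frame(read_id = "r1", sequence = core), ref)
  expect_equal(nrow(aln), 2L)
  expect_true(all(aln$mapq_class == "multi"))
  expect_equal(aln$n_best, c(2L, 2L))
  expect_equal(aln$weight, c(0.5, 0.5))
  expect_equal(aln$ref_start, sort(aln$ref_start))
})

test_that("mapper matches the exhaustive brute-force oracle on random cases", {
  set.seed(26)
  refs <- c(rA = random_dna(900), rB = random_dna(500))
  params <- map_params()
  for (i in 1:60) {
    ri <- sample(1:2, 1)
    L <- sample(18:80, 1)
    st <- sample(1:(nchar(refs[ri]) - L), 1)
    read <- substr(refs[ri], st, st + L - 1)
    nmm <- sample(0:3, 1)
    for (p in sample(L, nmm)) {
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
    if (runif(1) < 0.5) read <- oracle_revcomp(read)
    got <- map_reads(data.frame(read_id = "r", sequence = read), refs, params)
    want <- oracle_map(read, refs, params$max_mismatch, params$max_clip)
    if (is.null(want)) {
      expect_equal(got$mapq_class, "unmapped", info = paste("case", i))
    } else {
      expect_equal(nrow(got), nrow(want), info = paste("case", i))
      expect_equal(got$ref_start, want$start0, info = paste("case", i))
      expect_equal(got$reference_id, names(refs)[want$ref_idx],
                   info = paste("case", i))
      expect_equal(got$strand, want$strand, info = paste("case", i))
      expect_equal(got$n_mismatch, want$mm, info = paste("case", i))
    }
  }
})

test_that("SAM round trip preserves alignment fields", {
  set.seed(27)
  ref <- random_dna(500)
  if (substr(ref, 161, 161) == "C") substr(ref, 161, 161) <- "G"
  refs <- c(chr = ref)
  reads <- data.frame(
    read_id = c("plus", "minus", "cca", "lost"),
    sequence = c(substr(ref, 51, 110),
                 oracle_revcomp(substr(ref, 301, 360)),
                 paste0(substr(ref, 101, 160), "CCA"),
                 paste(rep("ACGT", 10), collapse = "")))
  aln <- map_reads(reads, refs)
  p <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, refs, p)
  lines <- readLines(p)
  expect_true(any(grepl("^@SQ\tSN:chr\tLN:500$", lines)))
  expect_true(any(grepl("60M3S", lines)))          # + strand soft clip
  expect_true(any(grepl("\t4\t\\*", lines)))       # unmapped flag
  back <- read_sam(p, references = refs)
  for (col in c("read_id", "sequence", "reference_id", "ref_start", "strand",
                "aligned_length", "n_mismatch", "soft_clip_3", "mapq_class")) {
    expect_equal(back[[col]], aln[[col]], label = col)
  }
  expect_equal(nchar(back$soft_clip_3[back$read_id == "cca"]), 3L)
  expect_error(write_sam(aln, c(other = "ACGT"), p), "unknown")
})

test_that("mapping order and output are deterministic", {
  set.seed(28)
  ref <- c(chr = random_dna(400))
  reads <- data.frame(read_id = paste0("r", 1:30),
                      sequence = vapply(1:30, function(i) {
                        st <- sample(1:350, 1)
                        substr(ref, st, st + sample(20:45, 1))
                      }, ""))
  expect_identical(map_reads(reads, ref), map_reads(reads, ref))
})
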