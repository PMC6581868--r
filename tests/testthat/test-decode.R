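test_that("the sense codon set is the standard code minus stops", {
  sc <- sense_codons()
  expect_length(sc, 61L)
  expect_false(any(c("TAA", "TAG", "TGA") %in% sc))
  expect_true("ATG" %in% sc)
  expect_equal(anyDuplicated(sc), 0L)
})

test_that("exactly eight 4-box families exist", {
  fam <- four_box_families()
  expect_equal(nrow(fam), 8L)
  expect_true("GG" %in% fam$prefix)                  # Gly
  expect_false("AT" %in% fam$prefix)                 # Ile/Met mixed box
  expect_setequal(fam$amino_acid, c("L", "V", "S", "P", "T", "A", "R", "G"))
})

test_that("redundancy fixed points and linearity hold", {
  fam <- four_box_families()
  one_per_family <- vapply(strsplit(fam$codons, ","), function(x) {
    revcomp(x[1])
  }, "")
  expect_equal(redundancy(one_per_family), 1.0)
  all_codons <- unlist(strsplit(fam$codons, ","))
  expect_equal(redundancy(revcomp(all_codons)), 4.0)
  expect_equal(redundancy(character()), 0.0)
  expect_equal(redundancy(c("CAT", "GAA")), 0.0)     # Met, Phe: no 4-box
  # doubling every gene doubles the statistic
  expect_equal(redundancy(rep(one_per_family, 2)), 2.0)
  # 6-box amino acids count only via their 4-box sub-box
  expect_equal(redundancy("TAA"), 0.0)               # Leu TTA codon (2-box side)
  expect_equal(redundancy("GAG")                     # Leu CTC codon (4-box side)
               , 1 / 8)
})

test_that("decodability ranks perfect over wobble and flags dead codons", {
  tab <- decodability(data.frame(gene_id = "ala", anticodon = "TGC"))
  expect_equal(tab$status[tab$codon == "GCA"], "perfect")
  expect_equal(tab$status[tab$codon == "GCG"], "wobble")    # U34 reads G
  expect_equal(tab$status[tab$codon == "GCC"], "undecodable")
  expect_equal(nrow(tab), 61L)
  empty <- decodability(data.frame(gene_id = character(),
                                   anticodon = character()))
  expect_true(all(empty$status == "undecodable"))
  expect_true("A" %in% attr(empty, "undecodable_amino_acids"))
})

test_that("superwobble U34 covers whole 4-box families", {
  fam <- four_box_families()
  # one U34 gene per family, superwobble-modified
  acs <- vapply(fam$prefix, function(p) revcomp(paste0(p, "A")), "")
  inv <- data.frame(gene_id = paste0("g", seq_len(8)), anticodon = acs,
                    modification = "superwobble")
  tab <- decodability(inv)
  fam_codons <- unlist(strsplit(fam$codons, ","))
  expect_true(all(tab$status[tab$codon %in% fam_codons] != "undecodable"))
  expect_true(all(tab$status[tab$codon %in% setdiff(tab$codon, fam_codons)]
                  == "undecodable"))
})

test_that("lysidine-modified C34 reads A only, as modified wobble", {
  inv <- data.frame(gene_id = "ileX", anticodon = "CAT",
                    modification = "lysidine")
  tab <- decodability(inv)
  expect_equal(tab$status[tab$codon == "ATA"], "modified_wobble")
  expect_equal(tab$status[tab$codon == "ATG"], "perfect")
  # unmodified C34 reads only G3 codons
  tab0 <- decodability(data.frame(gene_id = "met", anticodon = "CAT"))
  expect_equal(tab0$status[tab0$codon == "ATA"], "undecodable")
})

test_that("unknown modification tags are rejected with the known list", {
  expect_error(decodability(data.frame(gene_id = "x", anticodon = "TGC",
                                       modification = "m1A")),
               "known tags")
})

test_that("adding a tRNA never demotes a codon (monotonicity)", {
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  rank <- c(undecodable = 0, modified_wobble = 1, wobble = 2, perfect = 3)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    inv <- data.frame(gene_id = paste0("g", 1:n),
                      anticodon = vapply(1:n, function(j)
                        paste(sample(bases, 3, replace = TRUE), collapse = ""), ""))
    extra <- rbind(inv, data.frame(gene_id = "new",
                                   anticodon = paste(sample(bases, 3,
                                                            replace = TRUE),
                                                     collapse = "")))
    t1 <- decodability(inv); t2 <- decodability(extra)
    expect_true(all(rank[t2$status] >= rank[t1$status]))
  }
})

test_that("decodability agrees with the brute-force reader oracle", {
  set.seed(62)
  bases <- c("A", "C", "G", "T")
  rules <- wobble_rules()
  tags <- c("none", "none", "none", "xm5s2U", "lysidine", "superwobble")
  for (i in 1:25) {
    n <- sample(2:12, 1)
    inv <- data.frame(
      gene_id = paste0("g", 1:n),
      anticodon = vapply(1:n, function(j)
        paste(sample(bases, 3, replace = TRUE), collapse = ""), ""),
      modification = sample(tags, n, replace = TRUE))
    # lysidine only applies to C34, xm5s2U/superwobble to U34; fix tags up
    a34 <- substr(inv$anticodon, 1, 1)
    inv$modification[inv$modification == "lysidine" & a34 != "C"] <- "none"
    inv$modification[inv$modification %in% c("xm5s2U", "superwobble") &
                       a34 != "T"] <- "none"
    got <- decodability(inv, rules)
    want <- oracle_decodability(inv, rules)
    expect_equal(setNames(got$status, got$codon), want, info = paste("set", i))
  }
})

test_that("aars_completeness counts the canonical families", {
  hodg <- read_aars_presence(organism = "Hodgkinia")
  res <- aars_completeness(hodg)
  expect_equal(res$n_present, 10L)
  expect_true(all(c("argS", "asnS", "aspS", "cysS", "glnS") %in% res$missing))
  all_present <- setNames(rep(TRUE, 20), aars_families())
  expect_equal(aars_completeness(all_present)$n_present, 20L)
  expect_length(aars_completeness(all_present)$missing, 0L)
  none <- setNames(rep(FALSE, 20), aars_families())
  expect_equal(aars_completeness(none)$n_present, 0L)
  expect_length(aars_completeness(none)$missing, 20L)
  expect_error(aars_completeness(all_present[1:19]), "20")
})

test_that("codon usage can be attached to the decoding table", {
  cu <- codon_usage(c("GCAGCGGCA"))
  tab <- decodability(data.frame(gene_id = "ala", anticodon = "TGC"),
                      codon_usage = cu)
  expect_equal(tab$usage[tab$codon == "GCA"], 2L)
  expect_equal(tab$usage[tab$codon == "GCG"], 1L)
})
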