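---
title: "Profiling tRNA maturation from small-RNA reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tRNA maturation from small-RNA reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaproc)
```

# The problem

Highly reduced endosymbiont genomes often lack the genes that mature
tRNAs: the RNase P ribozyme that removes 5′ leaders, the nucleases that
trim 3′ trailers, the nucleotidyl transferase that adds the terminal CCA,
and most base-modification enzymes. Whether their tRNAs are nevertheless
processed is an empirical question that small-RNA sequencing answers
directly, because each processing step leaves a signature in the reads:

* a read extending upstream of the annotated gene carries an untrimmed
  **5′ leader**; one extending downstream carries a **3′ trailer**;
* reads ending exactly at the gene 3′ end with a non-genomic `C`, `CC` or
  `CCA` suffix record **stepwise CCA addition**;
* reads cut in the anticodon loop are **tRNA halves**, a common stable
  degradation/regulation product;
* a genomic position where a reproducible fraction of reads carries a
  non-reference base (reverse transcriptase reading through a modified
  nucleotide) is a candidate **base modification**.

`trnaproc` turns each signature into an explicit classifier and validates
the whole chain on simulated libraries with known truth.

# The read model

A sequenced molecule from tRNA gene $g$ (gene-oriented sequence $s_g$ of
length $L_g$, anticodon starting at offset $a_g$) is generated as:

1. **Gene choice** — multinomial over relative expression weights.
2. **Maturation state** — one draw from the seven-state mixture
   $\pi = (\pi_\mathrm{precursor\_both}, \pi_\mathrm{leader\_only},
   \pi_\mathrm{trailer\_only}, \pi_\mathrm{trimmed}, \pi_{+C}, \pi_{+CC},
   \pi_{+CCA})$. Precursor states prepend/append genomic flank sequence
   (leader and trailer lengths uniform on 3–10 nt); the `plus_*` states
   append the corresponding non-genomic suffix.
3. **Half cleavage** — with probability `half_prob` the molecule is cut
   at a position drawn uniformly from the anticodon window
   $[a_g - 2, a_g + 4]$; each product is then emitted independently with
   probability 1/2. Cleavage is applied to every state, so the expected
   number of emitted reads per molecule is exactly 1 and — importantly —
   the state mixture among *full-length* reads is an unbiased estimate of
   $\pi$. This is the estimator the recovery analyses use.
4. **Misincorporation** — each configured site $(g, p)$ substitutes a
   uniformly chosen different base with its own rate. An optional per-site
   truncation probability (default 0) emulates reverse-transcriptase
   blocking instead; read-through with misincorporation is the default
   signature because that is what the sequencing data this package
   targets predominantly show.
5. **Filtering** — emitted reads outside the 18–100 nt window are
   discarded and counted, mirroring the length filters applied to real
   libraries (below ~18 nt, spurious identical matches between tRNA genes
   become common).

Background molecules (fraction `background_rate`) are uniform substrings
of annotated CDS regions; chimeric molecules (fraction `chimera_rate`)
join the 5′ half of one gene to the 3′ half of another at their anticodon
windows, reproducing the ligation artifacts that arise during adapter
ligation in library preparation.

Per-read truth records two state columns. `state` is the label observable
in that read — a 5′ half cannot reveal whether its parent molecule had a
CCA — and is what classifier confusion matrices are scored against;
`molecule_state` is the generative draw and is what mixture recovery uses.
Quality strings are constant; no downstream step reads them.

## What the simulator does not model

Uniform sequencing error, PCR duplication bias, adapter read-through,
ligase sequence preferences, and secondary-structure-dependent cleavage
preferences are all absent. The toy genome builder additionally forces
the base immediately 3′ of each gene to be a non-C, so a genomic trailer
can never imitate a non-genomic C/CC/CCA tail; in real genomes roughly a
quarter of genes will have a C-starting trailer, and for those a
single +C call is genuinely ambiguous at this read length. Passing tests
therefore demonstrate correctness of the analysis logic under the stated
model, not robustness to every artifact of real libraries.

# The mapper

Alignment is Hamming-only (substitutions, no indels): the quantities this
package measures — end positions, soft-clipped tails, per-position
mismatch fractions — are all defined on substitution space, and tRNA
reads are short enough that indel handling would add ambiguity without
benefit. Candidate placements are found with `Biostrings::matchPattern`
on both strands; up to 3 trailing bases may be soft clipped when (and
only when) clipping strictly reduces the mismatch count, which is exactly
the freedom needed to recover a non-genomic CCA. The reported placement
minimizes (mismatches, clip length, reference order, leftmost coordinate,
"+" before "−"), a total order that makes results reproducible where
heuristic aligners are tie-broken by implementation detail. Reads tied at
more than one locus are kept and counted fractionally (1/k) — endosymbiont
genomes contain near-identical tRNA paralogs, and discarding multi-mapped
reads would silently zero them out. The test suite proves the mapper
equivalent to an exhaustive all-offset scan under the same objective on
1,000 randomized cases.

# End-state and half classification

All calls are made in gene orientation with an end tolerance of
`tol = 2` nt. The 5′ call is *leader* iff the read starts upstream of the
gene (any upstream base); the 3′ call is *trailer* iff the alignment
extends genomically past the gene end, otherwise a read ending within
`tol` of the 3′ end is assigned `plus_C`/`plus_CC`/`plus_CCA` from its
soft-clipped tail (empty tail = `trimmed`). A gene with a genome-encoded
CCA is reported `plus_CCA` so "mature" accounting is uniform across
genes. Leader and trailer together give `precursor_both`; the raw 5′/3′
calls are also emitted for readers who want them separate.

Half labels: *full* covers the gene within `tol` at both ends (leaders
and trailers do not disqualify); *half5* starts within `tol` of the gene
start and ends inside the anticodon window $[a_g-2, a_g+4]$; *half3*
symmetrically; anything else is a *fragment*.

Two tolerances interlock here: `tol = 2` must be smaller than the
shortest leader/trailer the simulator emits (hence the 3–10 nt default —
a 1–2 nt leader would be indistinguishable from end jitter by
construction), and the classifier's anticodon window must equal the
simulator's cleavage window. Under those matched windows the
acceptance suite requires per-class recall of at least 0.95 for both
labels on 50,000-read libraries, and the classifiers achieve 1.0.

# Modification calling

The pileup covers each gene plus 15 nt of flank, in gene orientation,
excluding soft-clipped tail bases and antisense reads, with multi-mapped
reads contributing 1/k. A site is called modified iff depth ≥ 10 *and*
mismatch fraction strictly exceeds 0.02 — a site at exactly 2% is not
called. Calling is monotone in both thresholds. Fractional depths are
kept as-is internally so that base counts at a site always sum to the
(fractional) number of covering reads.

For library comparisons, per-gene counts are normalized to relative
abundances (count over total tRNA-assigned count), compared by Spearman
rank correlation (midranks for ties; exact permutation p-value for
n ≤ 8, t approximation on n − 2 degrees of freedom otherwise), and
summarized per gene by a symmetric signed ratio: $r = a/b$ if $r \ge 1$,
else $-1/r$. A ratio of non-negative abundances can never be below zero,
so the sensible reading of "values less than zero" in this transform is
"values less than one", and that is what is implemented: the statistic is
antisymmetric under swapping libraries and always has magnitude ≥ 1.

# Discovery and chimera screening

Reads of 48–90 nt (long enough to be a functional tRNA) are collapsed
exactly; records below a 100× count cutoff are dropped (configurable;
the analysis scripts use lower cutoffs at their smaller scale). The
remaining sequences are classified by the first matching rule:
full-length match to a known tRNA (≤ 2 mismatches, allowing an extra
terminal C/CC/CCA) → `known_tRNA`; a local genome match covering ≥ 80% of
the sequence → `genome_partial`; ends in CCA → `cca_unknown`; positive
chimera screen → `chimera_candidate`; else `unassigned`. Near-identical
collapsed reads can be grouped by single-linkage clustering at ≤ 2
mismatches, with the rule that differing anticodons, leaders or trailers
forbid merging.

The chimera screen asks whether a breakpoint $b \in
[16, n-16]$ exists such that prefix and suffix each match some reference
strand *exactly* and the two matched loci differ (different reference,
different strand, or same-strand gap larger than the read). Sixteen is
the scale at which identical matches between distinct tRNA genes arise by
chance, so shorter segments are never trusted. Matchable prefix length is
monotone in length, so the implementation binary-searches the longest
exactly-matching prefix and suffix and only enumerates breakpoints in the
feasible interval, preferring the most balanced split. A read that
matches a reference contiguously in full is by definition not a chimera
and exits immediately. Junctions landing inside a tRNA anticodon window
are flagged, since ligation artifacts are overwhelmingly joins of two
tRNA halves. On simulated contiguous-locus libraries the false-positive
rate is zero across 10 seeds × 10,000 reads; injected artifacts at 1%
are recovered essentially completely.

# Decoding capacity

The decode module works from anticodons alone. Codon–anticodon pairing
requires Watson–Crick matches at codon positions 1–2; position 3 is
governed by an editable wobble rule table keyed on the anticodon wobble
base (position 34) and an optional modification tag: unmodified G34 reads
C/U, C34 reads G, A34 reads U, U34 reads A/G; `xm5s2U` restricts U34 to
A/G (as `modified_wobble`); `lysidine` converts C34 to an A-only reader
(the Ile/Met discrimination); `superwobble` lets U34 read all four;
`inosine` (A34) reads U/C/A. Per codon the strongest status wins:
perfect > wobble > modified_wobble. The table ships as data
(`inst/extdata/wobble_rules.tsv`) precisely because wobble judgments are
the softest part of any such figure and users should be able to tighten
or relax them without touching code.

The redundancy statistic divides the number of tRNA genes whose cognate
codon (exact reverse complement of the anticodon) lies in a 4-box family
by the fixed number of 4-box families, eight. Fixing the denominator is
what makes sub-1 values meaningful ("fewer tRNAs than families"); genes
of 6-box amino acids count only through their 4-box sub-box (CUN, UCN,
CGN), and a variant counting the 2-box side as well is deliberately not
offered, because it would change the fixed points (1 = one gene per
family, 4 = one per codon) that give the statistic its interpretation.

```{r}
fam <- four_box_families()
fam$amino_acid
redundancy(vapply(strsplit(fam$codons, ","), function(x) revcomp(x[1]), ""))
```

Aminoacyl-tRNA synthetase completeness is a presence count over the 20
canonical families; the packaged table
(`inst/extdata/aars_presence.tsv`) encodes the published presence rows
for the two cicada endosymbionts (10 of 20 families in *Hodgkinia*,
15 in *Sulcia*).

# Numerical and design choices

* **Coordinates** are 0-based half-open internally; GFF3 (1-based
  inclusive) and BED convert at the I/O boundary only.
* **Determinism**: one seed drives all simulator randomness; the mapper,
  classifiers and callers are deterministic, with every tie broken by an
  explicit total order. Rerunning any stage byte-reproduces its outputs.
* **Degenerate inputs**: empty read sets, zero-coverage sites (mismatch
  fraction reported `NA`), all-zero weight vectors, constant vectors in
  the rank correlation (rho `NA`), and zero denominators in the signed
  ratio (NA with a warning) are all handled explicitly and tested.
* **Background zero**: spike detection compares background-subtracted
  depth against `fold ×` background; when the background is exactly zero
  the rule degenerates, so any strictly positive depth is treated as hot
  — the conservative choice for the synthetic case.
* **Problem sizes**: the validation suite uses a 2-gene toy genome with
  50,000 simulated molecules for parameter recovery, 1,000 randomized
  read/reference cases for mapper-oracle equivalence, 1,000 vectors for
  the rank-correlation oracle, and 10 × 10,000 reads for the chimera
  false-positive sweep; the analysis scripts run at 10,000–20,000 reads.
  These sizes give the binomial confidence intervals used in the
  recovery checks their stated meaning while keeping every analysis
  comfortably reproducible on a laptop.

# Known limitations

Indels (including the gapped alignments that mitochondrial tRNAs with
missing arms would need) are out of scope by design. The chimera
breakpoint rule reconstructs "the two halves aligned to different
places" as an exact two-segment decomposition; artifacts with internal
errors at the junction would be missed. The 2% modification threshold is
applied per alignment set; to pool libraries before thresholding,
concatenate their alignment tables and run the pileup once — the package
deliberately does not pool by default. Anticodon offsets must be supplied in the inventory —
the package does not predict tRNA secondary structure.
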