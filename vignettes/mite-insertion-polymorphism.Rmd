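---
title: "Calling and analysing MITE insertion polymorphisms at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing MITE insertion polymorphisms at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Miniature inverted-repeat transposable elements (MITEs) are short
(< 800 bp), non-coding class II transposons bounded by terminal inverted
repeats (TIRs) and mobilised in trans by related autonomous elements.
*Stowaway*-like MITEs, derived from the *mariner* superfamily, insert into
TA dinucleotides and duplicate them, so an occupied allele reads
`...TA + element + TA...`. Because they transpose recently and frequently,
their presence/absence patterns across resequenced genomes carry a strong
population signal: which sites are unique to one genome, which are shared,
which genomic positions are hit repeatedly by different families, and how
family copy numbers separate host populations.

`mitepop` implements this whole analysis as a reusable pipeline that runs
at desk scale against a synthetic population with known ground truth:

1. a **simulator** of reference genomes, gene annotations, MITE families,
   insertion-bearing accessions and paired short reads;
2. a **structural miner** for TIR/TSD-bounded elements with ORF and
   DD39D-motif triage of autonomous candidates;
3. a **junction-read insertion caller** (consensus matching, trimming,
   unique flank mapping);
4. **population statistics** on the binary presence/absence matrix:
   unique insertion sites (UIS), parallel insertion sites (PIS),
   proliferation coefficients (PrC), Monte-Carlo chi-squared contingency
   analysis, Jaccard distances with PCoA, and PIS co-occurrence
   correlations;
5. a **genic-context classifier** against GFF3-style annotations;
6. **family phylogenetics** (p-distance, neighbour joining, bootstrap);
7. a **concordance summariser** against PCR genotyping calls.

The numbered scripts under `analysis/` run these steps in order; every
computation they narrate lives in the package and is unit-tested.

# The simulator defines the study conditions

`sim_config()` fixes the synthetic study: 10 accessions over two 200 kb
chromosomes at 62% AT, 30 genes, three MITE families (150–450 bp elements,
31-nt TIRs), a mean of 15 insertions per accession per family, 30% unique
sites, five parallel loci, and error-free 20× paired 100 bp reads with
300 ± 30 bp inserts. These sizes keep a full run around two minutes on one
CPU while leaving every statistic well away from small-sample degeneracy
(about 100 site rows, about 450 insertions).

Design points worth knowing:

* **Site planning.** For one accession the number of distinct sites is
  drawn Poisson(λ) directly. For larger populations, per-family total
  presences are drawn Poisson(λN) and converted into site rows such that
  exactly `round(fraction_unique × rows)` rows (parallel-locus rows
  included) are single-accession; shared rows get a uniform 2..N
  occupancy. The unique fraction and the number of parallel loci are
  therefore exact by construction, while per-accession counts follow the
  rate in expectation — the property the recovery analyses need.
* **Spacing.** Insertion sites sit on TA dinucleotides at least
  2 × read-length apart, away from chromosome ends and from the planted
  two-copy repeat block. Real MITE insertions can cluster more tightly;
  the spacing isolates the caller's junction logic from overlapping-flank
  edge cases that the study design does not probe.
* **TSDs and excision.** Insertion always duplicates the TA; excision
  footprints are not simulated (they appear in genotyping assays as
  variant-size alleles, which the concordance vocabulary carries
  explicitly).
* **Diploids.** Under `ploidy_model = "diploid"` each accession has two
  haplotypes, "heterozygous" means the insertion sits on exactly one, and
  reads pool equally from both — the simplest read model consistent with
  PCR-style zygosity calls. The default population is haploid, which makes
  every truth record homozygous.
* **Element orientation** is random per insertion event; the caller's
  strand-aware flank mapping makes orientation invisible downstream, so it
  is not recorded in the truth table.
* **Mate pairs** are generated (FR orientation) but the caller does not
  consume mate identity: flank strand mapping already orients every
  junction, so mates would add information only for ambiguous repeats that
  the uniqueness filter discards anyway.
* **What the simulator does not emulate:** genic insertion preference
  (sites are uniform over eligible TA positions), population structure
  among accessions (memberships are exchangeable), indels and quality
  decay in reads, nested or truncated element copies, and excision.
  Passing recovery tests therefore show the *calling and statistics*
  machinery is correct, not that real carrot libraries would yield 100%
  sensitivity.

# The miner

`find_tir_elements()` reports every span whose termini match an IUPAC TIR
mask (forward at the 5' end, reverse-complemented at the 3' end), whose own
TIRs are mutually reverse-complementary within `tir_seq_mismatches`
(default 1), and which is framed by duplicated TA target sites. Matching is
conservative: a subject `N` matches nothing. All overlapping candidates are
reported; `dedupe = "longest"` applies greedy longest-first non-overlap
selection. Because published TIR lengths can exceed the 13-nt mask, an
optional `extend_tirs` flag grows the reported TIR inward to the maximal
mutually reverse-complementary stretch; coordinates are unaffected.

Triage: an element with an ORF of ≥ 100 codons (configurable; the
literature gives no threshold, and 100 codons is far above chance ORFs in
AT-rich sequence yet far below any real transposase) whose protein carries
a complete DD39D motif is an `autonomous_candidate`; below 800 bp with no
such ORF it is `mite_like`; anything else is `truncated`. The DD39D scan
requires aspartates at i < j < k with k = j + 40 (39 intervening residues)
and a configurable 1–150 residue first spacer — only the second spacer is
fixed by the motif definition.

# The caller

The calling strategy follows the RelocaTE family of junction callers; this
package re-interprets those parameters for a from-scratch matcher rather
than emulating any external tool: minimum terminal overlap 12 bp (`-bm`), exact seed
11 bp (`-bt`), mismatch fraction cap 0.2 (`-m`), minimum support 1 read
(`-r`). A read qualifies when one of its ends overlaps a consensus
terminus; the TE portion is trimmed and the remaining flank placed on the
reference by an exact junction-adjacent 20-mer seed extended over the full
flank on both strands. Flanks with more than one best placement are
discarded — this uniqueness filter is the package's surrogate for
repetitive-region read filtering. Reads qualifying for several families
are assigned to the longest terminal match; equal-length ties are dropped
(TIR-similar families make such ties common for short overlaps, which is
exactly why the tie rule is safe: longer junction reads are unambiguous).

Coordinates follow the TA convention throughout: a call's position is the
A of the reference TA target site; a junction on the element's left maps
to the flank's right end, one on the right to the base after the flank's
left start; every emitted call re-validates `(position-1, position) ==
(T, A)` against the reference and is suppressed otherwise.

# Population statistics

The binary matrix is keyed by exact `(chromosome, position, family)` with
zero positional tolerance — exactness is what makes parallel insertion
sites meaningful. UIS have row sum 1, fixed sites row sum N, and PIS are
positions shared by ≥ 2 family rows. PrC = distinct sites / mean
per-accession count (zero-count accessions included), which is 1 for fully
fixed families and N for fully unique ones; N is always the column count,
never a constant.

The contingency analysis is Pearson's X² with a 2000-replicate Monte-Carlo
p-value over fixed-margin tables and the add-one estimator
`(1 + #{X²_sim ≥ X²_obs})/(B + 1)` (so p never reaches 0), with
`(O−E)/√E` residuals — `stats::chisq.test(simulate.p.value = TRUE)`
provides exactly this null. Jaccard distances come from
`vegan::vegdist(binary = TRUE)`: shared absences never contribute. PCoA is
written out explicitly (double-centre −½D², eigendecompose, scale
eigenvectors by √eigenvalue) because the variance-explained convention —
positive eigenvalues only, no Cailliez correction — needs to be pinned
down; negative eigenvalues are reported but excluded.

# Genic context

Seven labels partition the genome: gene bodies resolve to
5'UTR/CDS/3'UTR/intron (CDS wins where features overlap; the union of
exonic sub-features is used, intron = transcript span minus exons), flank
windows give strand-aware `upstream_2kb`/`downstream_2kb` with the nearest
gene boundary winning overlaps and exact ties going to the following gene
(deterministic and documented — conventional interval-tool recipes leave
this precedence unstated), and everything else is intergenic. A gene
body always beats a neighbour's flank. `segment_lengths()` computes class
lengths by classifying breakpoint-delimited intervals under the same rules,
so the partition property (lengths sum to genome length) holds by
construction and is cross-checked per-base in tests. Distance histograms
use half-open 20 bp bins `[k·20, (k+1)·20)` over a 2 kb span per side; the
boundary insertion at exactly 2000 bp is genic and falls in the last bin.

# Phylogenetics

Terminal sequences are compared without gapped alignment: each element
contributes its first n bases concatenated with the reverse complement of
its last n. TIR/terminal regions are near-fixed-length, so this trades a
multiple-alignment dependency for determinism. The window is a parameter
(50 and 100 are the two conventional choices for this analysis; both are
exposed, and the analysis script uses 60 because the shortest simulated
family is 150 bp). p-distances use pairwise deletion of non-ACGT symbols.
Neighbour joining runs on label-sorted input for deterministic tie-breaks;
negative branch lengths are clamped to zero with the deficit recorded.
Bootstrap support resamples alignment columns, rebuilds the
p-distance/NJ tree per replicate, and reports the percentage of replicates
containing each internal bipartition of the point tree.

# Concordance vocabulary

The genotyping comparison uses a closed vocabulary of seven assay outcomes
against two in silico states. Heterozygous empty+occupied genotypes are
*concordant* with an occupied call — the read pipeline detects presence
regardless of zygosity — and variant-size alleles are "empty" for the
assayed element. Three combinations never occur in the published
verification table but are reachable in the cross-product
(occupied/variant-only and empty/occupied+variant); they are classified
discordant under the same "variant = empty" logic so that classification
is a total function. Percentages are computed on the grand total including
no-amplification combinations, rounded half-up to one decimal.

# Numerical choices and degenerate inputs

* Seeds: one master seed drives everything; per-accession read sets use
  `seed + 1000 + i`. Re-running any `simulate_*` with the same seed is
  byte-identical.
* Zero-coverage read sets, empty annotations, empty matrices and
  header-only GFF3 outputs are all defined, not errors.
* Two accessions with empty presence sets are at Jaccard distance 0
  (identical emptiness), logged.
* A constant vector makes rank correlation undefined — an error, not NA.
* Zero-margin contingency rows/columns are dropped with a warning.
* `eigen()` tolerance for "positive" PCoA eigenvalues is
  `max(|λ|) × 1e-9`.

# Problem sizes

The test suite simulates the default 10-accession population once
(~90 s), runs 200 randomised miner-vs-oracle trials (sequences up to
20 kb), 200 DD39D oracle trials, 100 NJ recovery trials on trees of up to
12 taxa, and 500 Monte-Carlo calibration replicates at B = 2000. The same
sizes are recomputed by `scripts/acceptance.R`. These are the package's
own desk-scale choices: large enough that every stochastic check is stable
across seeds, small enough to run on a laptop.

# Known limitations

* The caller is junction-read-driven and ungapped; split reads with
  indels near the junction, nested insertions, and non-TE structural
  variants are out of scope.
* Sensitivity claims transfer to real data only as far as the simulator's
  assumptions (uniform coverage, substitution-only errors, consensus-exact
  copies, spaced sites) hold; diverged or truncated copies in repetitive
  context will be under-called, which the uniqueness filter makes
  deliberate rather than accidental.
* The genic classifier assigns one gene per insertion; an insertion inside
  overlapping flanks of two genes is counted for the nearer one only.
* PIS co-occurrence correlations on three families rest on three pairs —
  the analysis is shown for its mechanics; population-scale inference
  needs the full family complement.
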