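# mitepop

Population analysis of *Stowaway*-like MITE insertion polymorphisms from
short reads, at desk scale.

Miniature inverted-repeat transposable elements (MITEs) are short
(< 800 bp) non-coding DNA transposons bounded by terminal inverted repeats
(TIRs). *Stowaway*-like MITEs insert into TA dinucleotides and duplicate
them (target-site duplication, TSD), so an occupied allele reads
`...TA + element + TA...`. Their presence/absence patterns across
resequenced plant genomes are a sensitive record of recent transposition:
which insertion sites are unique to one genome (UIS), which genomic
positions carry different families in different genomes (parallel
insertion sites, PIS — insertional hotspots), and how family copy numbers
structure a population.

`mitepop` is aimed at researchers studying transposon insertional
polymorphism who want the full pipeline — structural element mining,
read-based insertion calling, population statistics, genic context,
phylogenetics, genotyping concordance — as tested, reusable functions
driven by a synthetic-data generator with known ground truth.

## The statistics at the core

For a binary sites × accessions matrix **M** (presence = 1):

- **UIS**: rows with `rowSums(M) == 1`; **fixed** sites have
  `rowSums(M) == N`.
- **PIS**: positions where ≥ 2 rows share (chromosome, position) with
  distinct families.
- **Proliferation coefficient** of a family with S distinct sites and T
  total presences over N accessions: `PrC = S·N / T`, i.e. sites over the
  mean per-genome count; PrC = 1 when every site is fixed, N when every
  site is unique — an index of recent family expansion.
- **Contingency analysis**: Pearson `X² = Σ(O−E)²/E` with a Monte-Carlo
  p-value over B = 2000 fixed-margin tables,
  `p = (1 + #{X²_sim ≥ X²_obs})/(B+1)`, and Pearson residuals `(O−E)/√E`.
- **Diversity structure**: Jaccard distance
  `d(a,b) = 1 − |Sa∩Sb|/|Sa∪Sb|` over presence sets (shared absences are
  uninformative), then classical PCoA (eigendecomposition of the
  double-centred `−½D²`).
- **Caller**: reads overlapping a family consensus terminus by ≥ 12 bp
  (11 bp exact seed, ≤ 0.2 mismatch fraction) are trimmed; flanks are
  placed uniquely on the reference, and each call's position is the A of
  the reference TA target site.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
simulated population (10 accessions, 2 × 200 kb chromosomes, 3 MITE
families, λ = 15 insertions/accession/family, 30% unique sites, 5 parallel
loci, error-free 20× reads):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_call_insertions.R
Rscript analysis/04_population_stats.R
```

prints (abridged):

```
Simulated 461 insertions over 109 sites in 10 accessions
  unique sites: 33 (30.3%)
  parallel insertion loci: 5

Called 461 insertions across 10 accessions
  sensitivity at exact positions: 100.0% (461/461)
  false calls: 0

Matrix: 109 sites x 10 accessions
  UIS: 33  fixed: 7  PIS: 5
  PrC by family:
  family total_sites uis_count      prc
1  MITE1          39        15 2.932331
2  MITE2          37        11 2.327044
3  MITE3          33         7 1.952663
Coverage vs sites: Spearman rho = 0.99, p = 0.00
PIS co-occurrence by family pair:
  family_a family_b cooccurrence cumulative_sites tir_distance
1    MITE1    MITE2            2               76   0.06451613
2    MITE1    MITE3            3               72   0.70967742
3    MITE2    MITE3            0               70   0.67741935
```

Reading this: the caller recovered every simulated insertion at its exact
TA coordinate with no false positives; the 30% unique-site design and the
five planted hotspots come back exactly; PrC close to 1 reflects the many
shared sites in this small population (it rises towards N = 10 as sites
become private); and the uniform 20× coverage design yields site counts
that simply track genome size — the Spearman check is the diagnostic one
runs on real libraries, where a correlation would flag coverage bias.
Family pair MITE1/MITE2 shares near-identical TIRs (p-distance 0.065),
the structure the PIS co-occurrence analysis probes.

Steps 2 and 5–7 mine the reference for TIR/TSD elements and triage an
autonomous candidate by its DD39D transposase motif, classify sites into
genic segments with per-100-kb densities and 20-bp distance histograms,
build the bootstrapped neighbour-joining tree of terminal sequences, and
summarise genotyping concordance.

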