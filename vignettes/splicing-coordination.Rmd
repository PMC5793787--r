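---
title: "Detecting splicing coordination from droplet-barcoded read clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting splicing coordination from droplet-barcoded read clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceclouds)
```

## The problem and the data model

A gene with two alternative exons can express four isoform classes. Bulk
short-read sequencing measures each exon's inclusion level (Ψ) but not their
joint distribution across molecules: whether the exons are included in the
same molecules (coordination) or combined at random. Droplet-based linked-read
sequencing restores that information statistically. cDNA is diluted into a
large number of droplets (here modelled as ~200,000), each droplet's content
is amplified linearly with random priming and sequenced as barcoded short
reads. When a gene occurs at most once in a droplet, the reads sharing that
droplet's barcode and mapping to the gene — its *read cloud* — describe a
single RNA molecule, including splice junctions far apart on the mRNA.

`spliceclouds` works from spliced alignments (or a pre-digested
intron-by-barcode evidence table) and an annotation, and never attempts
assembly: a molecule's splicing status at an exon is inferred solely from
junction-spanning reads.

## Per-molecule splicing calls

**Junction evidence.** A junction is accepted from an alignment only when at
least 6 aligned bases flank it on both sides (`min_anchor`), suppressing
false-positive spliced mappings; it is then matched exactly (both
coordinates) against the annotated introns and kept only when it identifies a
unique gene. Both choices are deliberately stringent: mismapped junctions
masquerade as conflicting splicing patterns and would inflate both collision
estimates and contingency tables.

**Molecules.** A molecule of gene *g* is called for barcode *b* when at least
`k` spliced reads of *b* span introns of *g* (default `k = 1`; the call count
is non-increasing in `k`, which `call_molecules()` exposes for threshold
sweeps). Gene expression is reported as molecules per million (MPM), which
sums to 10⁶ by construction.

**Collisions.** Two non-identical molecules of one gene in the same droplet
produce conflicting junction evidence. The default detector flags a
gene–barcode pair when any skippable exon shows evidence for an inclusion
intron *and* its skipping intron; a stricter mode flags any two overlapping
non-identical introns. Flagged pairs are excluded from Ψ and from
coordination tables. Under uniform droplet assignment, per-droplet gene
occupancy is approximately Poisson(λ = molecules/droplets), so the expected
collision fraction among detecting droplets is
`(1 − e^{−λ} − λe^{−λ})/(1 − e^{−λ})` (~λ/2 for small λ), which the simulator
reproduces (see calibration below).

**Exon status and Ψ.** A barcode is *included* for an exon when it shows at
least one inclusion intron and no skipping intron, *skipped* in the converse
case, and uninformative otherwise. Ψ is the included fraction of informative,
non-collision barcodes.

## Event classification from the annotation

A *pure exon-skipping event* is an internal exon that is either included or
skipped in every overlapping transcript: its boundaries are identical
wherever it appears, its two flanking (inclusion) introns are unique, some
transcript splices directly from the upstream flank to the downstream flank
(the skipping intron), no transcript retains either flanking intron, and no
transcript starts or ends strictly inside the skipped region. The last rule
is the annotation-level proxy for alternative transcription start and
poly(A)-site interference — with annotation only, a transcript boundary
inside the region is the observable footprint of such events.

Pairs of pure skipping events are tested only when *separated*: at least one
constitutive exon lies strictly between them. We define a constitutive exon
operationally as an exon contained, with identical boundaries, in every
transcript whose span covers it; the definition is otherwise not pinned down
by common usage. Pair coding status is `entirely_coding` only when every base
of both exons is CDS in every transcript containing them; genes without CDS
records (lincRNAs) are `contains_noncoding`. An exon is frame-preserving when
its length is divisible by three.

For terminal analyses, alternative donor events (≥2 donors sharing an
acceptor) and acceptor events (≥2 acceptors sharing a donor) are built per
gene; the most upstream donor event and the most downstream acceptor event
are retained when the donor event lies upstream and a constitutive exon is
guaranteed between the two sites, so the two sites arise from distinct
splicing reactions. Donors of annotated first exons mark the event class
`first` (a proxy for TSS choice), acceptors of last exons mark `last`
(poly(A) proxy). Events with more than two forms are dichotomised to the two
best-supported forms — the 2×2 test needs binary outcomes, and the
dichotomisation rule (top two by molecule support, falling back to
transcript support) was a genuinely open design choice; alternatives such as
one-vs-rest collapse would conflate distinct splice sites.

## The coordination test

For each pair, informative molecules are counted into the 2×2 table
(*a* both included, *b* first only, *c* second only, *d* both skipped).
Molecules (barcode-level calls), not raw reads, are the informative unit:
read counts per molecule are amplification-dependent and would pseudo-
replicate. Pairs with `n_t ≥ 25` are tested (below 25 informative molecules
only near-perfect coordination is detectable, and the floor matches the
package's intended operating point); the two-sided Fisher's exact test is
computed from the hypergeometric likelihood with the conventional tie rule
(tables with probability ≤ observed × (1 + 10⁻⁷) are summed — the relative
tolerance makes the definition floating-point stable). All tested pairs form
one genome-wide family corrected with Benjamini–Yekutieli: tables of one
gene share molecules and are arbitrarily dependent, which BY tolerates.
Terminal site pairs yield one test per gene and form their own
Benjamini–Hochberg family, with category enrichment assessed by Fisher's
exact test of category membership against significance.

Effect size is the log₂-odds-ratio with a 0.5 pseudocount in every cell,
finite for any table. The comparison of coordination frequency between
entirely-coding and noncoding-containing pairs matches the two groups on
`n_t` (greedy nearest-neighbour, without replacement, seeded) because power
is a steep function of the informative count and the two groups differ in
depth.

## Extent estimation and the down-sampling control

To estimate how much of the transcriptome is coordinated, genes are swept
over informative-count cutoffs; at each cutoff the fraction of genes with at
least one pair satisfying the stringent criterion `P ≤ 5×10⁻⁷` and
`|LOR| ≥ 0.5` is reported (the P cutoff equals a Bonferroni correction of
0.05 for 100,000 tests, an upper bound on separated alternative exon pairs
genome-wide). Confidence intervals are Wilson score intervals — the method
behaves well at small counts and extreme fractions; a normal-approximation
alternative is available via `ci_method = "normal"`. To avoid genes with
many testable pairs dominating, only each gene's largest table can be kept
(`per_gene = TRUE`, default in the down-sampling control).

Deeply covered pairs pass the criterion far more often. The down-sampling
experiment asks whether that is a power artefact: for every table in the
low-cutoff list *L* (`n_t ≥ 25`), a donor is drawn uniformly from the
high-cutoff list *H* (`n_t ≥ 500`) among tables at least as large and
down-sampled to the target's size by drawing without replacement from its
four cells (multivariate hypergeometric — the exact conditional law of
subsampling reads). The resulting list has the identical `n_t` multiset as
*L*; 50 replicates give a distribution of pass fractions. Note the cutoff
definitions imply *H* ⊆ *L*, and the implementation follows the definitions.

## The simulator

`simulate_dataset()` generates data with known truth: per gene, a configured
number of molecules with the first two skippable exons jointly distributed
according to marginals (ψ₁, ψ₂) and an odds ratio (the unique feasible root
of the quadratic linking the joint cell to the marginals; `joint_probs()`),
additional exons included independently; uniform droplet assignment (so
occupancy is Poisson and collisions arise naturally, never injected); a
configurable unspliced fraction (default 1/3, molecules that exist but emit
no junctions); linear amplification modelled as Poisson(mean 20) independent
junction-spanning reads per molecule falling uniformly on the molecule's
junctions — no full-length pass is required, matching random-primed linear
amplification; an anchor-failure probability of
`2(min_anchor − 1)/(read_length − 1)` per junction read (the junction offset
within a 98-bp read is uniform); and a per-read barcode misassignment rate
(default 0.001) that swaps reads to random droplets.

What the generator does **not** emulate: base-level sequencing error,
insert-length structure, mappability differences (pseudogenes), non-uniform
read starts, cell-type mixtures in bulk tissue, and NMD acting on frame-
disrupting isoforms. Passing calibration therefore demonstrates correctness
of the statistical machinery under the stated sampling model, not robustness
to alignment artefacts in real data — on real data the collision and anchor
filters carry that burden.

## Numerical and design notes

* Coordinates are 0-based half-open throughout; GTF is converted on read.
  Strand matters only for 5′→3′ ordering; interval arithmetic is genomic.
* Output ordering is deterministic (p-adjusted, then gene id; ties in
  per-gene table selection break to the upstream pair), and every stochastic
  step takes a seed, so identical configuration and seed give byte-identical
  outputs.
* Degenerate inputs: empty annotation or evidence produce empty results, not
  errors; an all-zero table has `LOR = 0` (pseudocount) and is never tested
  (below the informative floor); `Ψ` is absent when no informative barcode
  exists; MPM requires at least one call.
* The barcode misidentification rate uses molecule calls as denominator —
  molecule calls are what downstream analysis consumes; barcodes or raw
  reads would be equally defensible denominators and are recoverable from
  `barcode_qc()`'s inputs.

## Calibration results computed by the test suite

The package's tests (not this vignette) verify, at the sizes given: exact
agreement of `fisher_two_sided()` with an exhaustive enumeration oracle (500
random tables, `n_t ≤ 30`); raw null p ≤ 0.05 fraction within [0.03, 0.06]
and zero BY discoveries on 1000 null tables of `n_t = 200`; mean estimated
LOR within 1.8–2.2 for 100 tables of `n_t = 1000` at true log₂ OR = 2;
collision fractions within three Monte-Carlo standard errors of the Poisson
closed form for λ ∈ {0.01, 0.1, 1, 5} (single-gene runs of 2,000–25,000
molecules over 5,000–200,000 droplets, all molecules spliced and deeply
covered so that co-encapsulated molecules are almost surely distinguishable);
down-sampling consistency on 300 + 300 tables from one OR mixture; and
molecule-count monotonicity with ΣMPM = 10⁶ on every simulated dataset.
These problem sizes keep each check to seconds-to-minutes on a single CPU
while leaving Monte-Carlo error well below the asserted tolerances.

## Limitations

Gene assignment requires exact annotated junctions; novel splice sites are
invisible. The method needs tens of informative molecules per pair, so lowly
expressed genes are out of reach at moderate depth — the extent sweep makes
that dependence explicit rather than hiding it. Collision detection can only
see conflicts at annotated skippable exons (or overlapping introns), so a
residual rate of undetected collisions dilutes tables slightly toward
independence; and with bulk input, apparent coordination may reflect
cell-type mixtures rather than per-cell splicing dependence.
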