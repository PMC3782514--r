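---
title: "Methods: conserved synteny, substitution rates and divergence dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved synteny, substitution rates and divergence dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntevol)
```

# Scope and model

`syntevol` analyses homologous genomic regions — the classic setting being
the A, B and D subgenomes of hexaploid wheat and their diploid/tetraploid
progenitors around a shared locus — and quantifies their conservation and
divergence at three levels:

1. **Structure**: pairwise conserved blocks, summarized by the conserved
   sequence ratio (CSR, the percentage of the homologous overlap covered by
   conserved blocks) and the average conserved fragment size (CFS, total
   conserved length / number of blocks); inter-block gaps are classified
   into transposable-element insertions, deletions and unknown indels.
2. **Fine conservation**: conserved non-coding sequences (CNS) shared by
   two or more regions, plus cis-regulatory motifs and microsatellites.
3. **Time**: Kimura two-parameter (K2P) distances, Nei–Gojobori (NG86)
   Ka/Ks, LTR-retrotransposon insertion ages via `T = K/2r`, and
   calibrated molecular-clock divergence times.

Every estimator can be exercised against the synthetic-data generator,
which produces region pairs and trios with fully known ground truth.

# Conserved blocks (CSR / CFS)

Classically these comparisons are read off dot plots by eye with a printed
criterion — a 40-bp window at 60% identity. That criterion fixes what counts
as conserved but not an algorithm, so this package defines one explicitly:

* **Seed**: shared exact k-mers with `k = word_size/2` (20 bp by default);
  k-mers occurring more than `max_kmer_hits` times in either sequence are
  skipped as repeats.
* **Chain**: seeds on the same diagonal within `merge_distance` (200 bp) are
  chained.
* **Extend**: each chain grows along its diagonal to the maximal run of
  positions covered by a `word_size` window at `min_identity`; this
  reproduces the printed 40-bp / 60% criterion exactly on the diagonal.
* **Merge and filter**: chains within `merge_distance` on both sequences are
  merged (this bridges short indels, which shift the diagonal); merged
  blocks shorter than `min_block_length` (200 bp) are dropped.

Only the forward strand is compared by default (`include_reverse = TRUE`
enables reverse-complement seeding); the homologous wheat regions show no
inversions, and keeping the default narrow makes the statistic easier to
reason about.

CSR is computed at full precision and rounded once to one decimal for
display; CFS is truncated to integer bp (`floor(total/n)`), which is the
arithmetic that reproduces the published tables (e.g. 82,563 bp in 9 blocks
gives CFS 9,173). The "overlap length" entering CSR is, unless supplied
explicitly, the mean of the first-to-last block anchor spans on the two
sequences: the published definition of the homologous region size is not
stated, so the package makes its definition explicit and overridable —
published overlap sizes can be passed directly to reproduce table rows.

Block-boundary resolution is limited by the window: both endpoints of a
detected block can overshoot a true homology boundary by up to about half a
window into random sequence. Tests therefore compare boundaries at
`word_size` tolerance.

Gap classification between adjacent blocks uses annotation first (an
interval at least half covered by TE features is a TE insertion on that
side), then simple-sequence content (mostly-SSR intervals are
low-complexity), then an optional outgroup (an interval that aligns to the
outgroup is ancestral, hence a deletion on the other side); anything else is
an unknown indel.

# Conserved non-coding sequences

CNS detection follows the VISTA-style criterion: a 100-bp sliding window at
≥ 80% identity. Intergenic stretches between consecutive shared anchor genes
are globally aligned per region pair (Needleman–Wunsch, affine gaps; gap and
N columns count as mismatches — the conservative convention matching
percent-identity plots). Columns covered by a passing window form runs;
runs of at least `min_length` (100 bp — a floor the published analysis never
states; the shortest CNS reported there is ≈ 525 bp, so the default is
permissive and configurable) are intersected across **all** region pairs
and mapped back to every region's coordinates. Intervals are then trimmed
so they start and end on conserved columns (terminal mismatches and edge
mini-windows below the identity threshold are shaved; without this, a
detected CNS drags up to ~40 alignment columns of flanking divergence at
each end). Any interval overlapping a genic feature in any region is
discarded.

The identity attached to a CNS is by default the **pairwise minimum**
across region pairs (`identity_mode = "mean"` is available): whether the
published ≥ 80% refers to the minimum or the mean across subgenomes is not
stated, and the minimum is the stricter reading.

Motif scanning matches IUPAC consensi exactly on both strands; palindromic
consensi (e.g. the G-box CACGTG) are reported once per site on the plus
strand to avoid double counting. SSR detection reports maximal perfect
tandem runs of 1–6-bp units at the usual per-unit-length copy minima
(10/6/5/5/5/5), under the lexicographically smallest rotation of the unit,
with non-primitive units suppressed (a (CTCT)n run is (CT)2n).

# Distances, Ka/Ks and dating

**K2P.** With transition proportion `P` and transversion proportion `Q`
over ungapped non-N columns, `K = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`.
Saturated inputs (`1-2P-Q ≤ 0` or `1-2Q ≤ 0`) are a hard error naming `P`
and `Q` rather than a silent `NaN`.

**NG86.** Synonymous sites are counted from the standard genetic code as
the fraction of the three alternatives per position that are synonymous;
alternatives creating a stop codon count as nonsynonymous. Differences in
codons hit more than once are averaged over all substitution pathways with
equal weights, excluding pathways through stop codons (all pathways are
used only if every one is blocked). Proportions are Jukes–Cantor corrected.
This is the classic deterministic counting method: exactly testable against
brute-force pathway enumeration, and the published quantities this package
reproduces (rate ratios and calibrated times) depend only on printed rate
values, not on the likelihood machinery of codon models. ML codon models
(F3×4 frequencies, gamma rates) are deliberately out of scope.

**Dating.** `T = K/(2r)`. Two rate presets ship: `clock_rate("ltr")` =
1.3e-8 substitutions/site/year and `clock_rate("synonymous")` = 6.5e-9 (the
grass adh synonymous rate). The LTR preset is the default for element
dating: it is the standard doubled rate conventionally applied to LTR
regions, and it is the only rate consistent with the published element ages
the package reproduces (0.0178 → 0.68 MYA requires r = 1.3e-8; the halved
rate would double every age). Both presets are first-class so either
convention can be used explicitly.

**Calibration.** `calibrate(K_cal, T_cal)` gives `r = K_cal/(2 T_cal)` and
`calibrated_time(K) = K·T_cal/K_cal`; the calibration pair always dates to
exactly `T_cal`. The bundled presets anchor on the rice–sorghum row of the
reference clock table (K = 1.6802 for the averaged coding+intron rate of
the slowly evolving gene, Ks = 0.8707 for the GA-signalling gene, both at
60 MY) — the anchor that reproduces the published divergence times
self-consistently. In two-gene dating rows the gene-internal average of
coding and intron rates is taken at full precision *before* any rounding
(0.0031 and 0.0000 average to 0.00155 and date to 0.0554 MY, not the
0.0016-based 0.0571); times are displayed at 4 decimals (2 for element
ages) but carried at full precision.

# Neighbor joining

`nj_tree()` is a from-scratch Saitou–Nei implementation with two choices
that matter for reproducibility: ties in the Q-criterion are broken by the
lexicographically lowest label pair (a cluster is labelled by its smallest
leaf), and negative branch lengths are clamped to zero with the count
recorded in `attr(tree, "clamped")`. On additive matrices NJ is exact, which
the tests exploit (random additive trees of 4–8 taxa are recovered with
topology and branch lengths); `ape::nj` serves as an independent
cross-check on noisy matrices, never as the implementation. Bootstrap
support resamples alignment columns with replacement, rebuilds the tree per
replicate, and reports the percentage of replicates containing each
original bipartition.

# The synthetic-data generator

The generator is the package's instrument for validating estimators, and
its defaults are the study conditions it emulates:

* **Ancestor**: 50 kb of uniform random sequence (desk-scale stand-in for
  the 100–200-kb BAC regions), with embedded two-exon genes, a promoter
  motif pair (TATA-box, G-box) upstream of each gene, and a (CT)₂₃
  microsatellite.
* **Substitutions**: per-site sampling from the exact K2P marginal at the
  target branch length (`κ = 2` by default, the common genomic default) —
  no time stepping, so the marginal distribution is exact and the cost is
  linear. The pairwise target `K = 0.05` sits between the observed
  diploid–tetraploid (≈ 0.03) and inter-subgenome (≈ 0.12) coding
  divergences.
* **Selection**: inside CDS, substitution proposals arrive at the neutral
  rate; synonymous proposals are always accepted, nonsynonymous ones with
  probability ω (default 0.05, matching the strong purifying selection
  observed at this locus), proposals creating stops never. NG86 site
  definitions make this scheme recover ω in expectation.
* **Indels**: Poisson events (2×10⁻⁵/site) with geometric lengths (mean
  10 bp); insertions copy random sequence. Indels and TE insertions avoid
  annotated features, so embedded genes stay frame-intact.
* **TE insertions**: lineage-specific LTR retroelements (1.5-kb LTRs, 3-kb
  body) whose twin LTRs start identical and then diverge to expected
  `2·r·age` (1 MY at 1.3e-8 by default, inside the 0–2.15-MY range of the
  dated wheat elements).
* **Truth**: conserved ancestral intervals surviving in both lineages
  (split at insertion boundaries and mapped to each region's coordinates),
  per-element LTR divergence, and all feature coordinates.

The trio generator shares two anchor genes and `n_cns` intergenic segments
across three regions; the shared segments carry the ancestral state in
regions 2 and 3 and are mutated only on region 1's lineage, so the
**minimum** pairwise identity equals the configured value (independent
mutation in all three copies would push the 2–3 pair below the 80%
detection floor already at 85% configured identity). All other intergenic
sequence is independent random sequence, i.e. diverged beyond any
detection threshold.

What the generator does **not** emulate: GC heterogeneity and rate
variation along the sequence, nested/fragmented TE insertions, tandem
duplications, inversions, sequencing gaps, and selection beyond a constant
ω. Passing recovery tests therefore demonstrates estimator correctness
under the stated model, not robustness to every feature of real BAC
sequence.

# Numerical and procedural choices

* Coordinates are 0-based half-open everywhere inside the package; GFF3
  (1-based closed) and BED convert exactly at the I/O boundary, and
  conversion round-trips are tested. BED has no feature-type column, so the
  package encodes `kind|name` in the BED name field.
* Ambiguity codes collapse to `N` on input (with a warning count) rather
  than erroring; `N` and gap columns are excluded from distance estimation
  and count as mismatches in identity computations.
* Alignment scoring: match +1, mismatch −1, gap open −5, gap extend −1 (a
  length-L gap costs 5 + (L−1)); protein-guided codon alignment uses
  BLOSUM62. Alignments are deterministic.
* `simulate_*` functions take explicit seeds and restore the RNG state
  (`withr::with_seed`); a fixed seed gives byte-identical FASTA/GFF3
  output.
* Monte-Carlo recovery tests use 60–150 replicates at 10–20-kb region
  scale and assert agreement within 3 standard errors; these sizes keep the
  default suite under a minute of simulation time while leaving standard
  errors an order of magnitude below the effects being checked.

# Pipeline

`run_pipeline()` drives simulate → blocks → rates → clock → LTR ages → CNS
→ tree from a validated YAML config (unknown keys rejected, all thresholds
surfaced, defaults: word 40 at 60%, CNS window 100 at 80%, LTR clock). It
writes the four report tables, per-region CNS BED files, a Newick tree with
bootstrap supports, and a manifest with parameters and output checksums;
runs are deterministic given the seed, and the manifest makes stage
isolation checkable (changing the block identity threshold perturbs only
the conservation table). The pipeline functions are the package's
orchestration surface; `scripts/acceptance.R` is a thin Rscript over them
for batch reproduction of the headline numbers.

# Known limitations

* The block finder is seed-based: homology with no shared 20-mer on a
  consistent diagonal (e.g. extreme divergence or dense short indels) is
  invisible to it, although it would pass a brute-force window scan.
* CNS detection requires two shared anchor genes to delimit intergenic
  stretches and assumes collinearity between anchors.
* NG86 saturates earlier than ML codon methods (`ps` or `pn ≥ 3/4` is an
  error); deep grass–grass comparisons near Ks ≈ 1 are at the edge of its
  validity, which is why published rate values are consumed as inputs for
  the dating arithmetic rather than re-estimated from deep alignments.
* Bootstrap support uses the K2P/NJ pipeline only; no ML or Bayesian
  inference is provided.
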