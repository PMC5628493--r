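---
title: "Mapping a recessive locus by autozygosity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by autozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

# The mapping model

A rare recessive phenotype appearing in the offspring of related parents
is, with overwhelming probability, autozygous at the causal locus: both
copies of the mutation are identical by descent (IBD) from one ancestral
carrier. The affected individuals therefore share a chromosomal segment
on which they are homozygous for one haplotype *H*; their unaffected dams
(obligate carriers) carry exactly one copy of *H*; and no unaffected
animal can be homozygous for it. These three statements are the entire
mapping model — no allele-frequency model, no likelihood, no phasing.

`scan_autozygosity()` evaluates them in sliding windows of
`window_size = 40` SNPs (step 1 SNP by default) on **unphased**
genotypes. This reformulation is exact for the three criteria:

* "homozygous for *H*" is a phase-free statement (genotype equals the
  haplotype's homozygote at every window SNP);
* "not homozygous for *H*" likewise;
* "heterozygous for *H*" for an obligate carrier maps to
  *carrier-compatible but not homozygous*: the genotype is consistent
  with at least one copy of *H* everywhere in the window, and differs
  from *H/H* somewhere.

A window is consistent when a shared case haplotype exists and every
role's condition holds; overlapping or bookended consistent windows are
merged into maximal runs. A region's bounds are the outermost SNP
positions of the run (1-based, inclusive) and its length is
`round((end - start) / 1e6, 2)` Mb, matching the usual tabulation of
such scans. The fixed 40-SNP window at ~50K array density (about 17
markers/Mb here) corresponds to roughly 2–3 Mb — long enough that
chance homozygosity-by-state across a whole window is vanishingly rare
for outbred controls, short enough to catch segments eroded by a few
generations of recombination.

## Missing genotypes

The scan takes a `missing_policy`:

* `compatible` (default): a missing call is consistent with any class —
  it is simply ignored in both the case-haplotype inference and the
  classification. This mirrors analyses in which missing array calls
  are imputed before scanning; a sample with no informative call in a
  window is given the benefit of the doubt (classified `carrier`, which
  satisfies every role's requirement).
* `incompatible`: a missing call counts as a mismatch — maximally
  conservative, windows touching missingness in scored samples tend to
  fail.
* `fail_window`: any missing call among scored samples voids the window.

## Sensitivity to genotyping error

The criteria are absolute: a single miscalled case genotype (a
homozygote read as a heterozygote) voids every window containing that
marker, because no imputation/phasing smoothing step is in scope here.
With the generator's default miscall rate of 10⁻³ this occasionally
truncates or splits the reported region. The package's recovery
guarantees — "a reported region contains the causal position in every
replicate where the truth-level consistency condition holds" — are
therefore stated and tested at error rate 0, which is also the regime a
practitioner reaches after imputation. At default error rates the scan
still recovers the causal region in the large majority of replicates,
but this is a typical outcome, not a guarantee, and the tests do not
pretend otherwise.

# The synthetic-data generator

The generator exists so that every downstream stage is testable against
known truth. Its defaults encode the study conditions it emulates:

* **Pedigree** (`build_default_pedigree()`): one ancestral carrier bull
  `B1` (whose own sire is a known non-carrier), B1's son `S1` who sired
  both affected calves out of two of B1's daughters — i.e. half-sib
  matings — the two dams and six further relatives on the carrier path,
  four unaffected close relatives, and 30 unrelated population controls
  standing in for the breed sample used to reject chance homozygosity.
* **Markers**: 1200 SNPs on one 72-Mb chromosome ("20"), ~17/Mb, the
  density of a 50K array; founder alternative-allele frequencies drawn
  Uniform(0.1, 0.9) to mimic array ascertainment toward common SNPs.
* **Meiosis**: Haldane model — crossover count Poisson with mean equal
  to the chromosome's genetic length in Morgans, positions uniform on
  the cM scale, no interference — consistent with the 1 cM = 1 Mb rate
  used throughout the distance arithmetic.
* **Causal allele** (`seed_causal_allele()`): placed on one haplotype
  of the carrier founder; transmissions are then re-sampled by
  rejection until every case carries 2 copies, every obligate carrier
  exactly 1 and every control at most 1, *at both linked variant
  positions*. Rejection is applied per individual in topological order
  (each constrained individual's own two meioses are re-drawn until its
  copy number is right), which is valid here because every individual
  on the carrier path carries its own copy-number constraint, and is
  orders of magnitude cheaper than whole-pedigree rejection; a cap
  aborts with a diagnostic when the pedigree cannot satisfy the roles
  (e.g. a case with no carrier path to the founder). Constraining both
  linked sites makes the emitted case table deterministic — two
  homozygous-alternative private variants in perfect LD — rather than
  true with probability ≈ 0.99 per replicate (one recombination per
  2941 gametes, ~26 informative meioses).
* **Array error model**: independent per-call missingness (default
  0.02, giving >95 % call rates) and symmetric single-step miscalls
  (default 10⁻³): heterozygotes to either homozygote with equal
  probability, homozygotes to the heterozygote. A designated subset of
  8 markers is corrupted at a much higher rate (default 0.8) with
  *random* genotypes rather than single-step miscalls: single-step
  errors can almost never produce the opposing-homozygote
  parent/offspring conflicts that the QC rule looks for, whereas a
  failed assay produces effectively random calls — which is what makes
  a marker "frequently show paternity conflicts".
* **Map flaws**: 5 markers lose their positions and one pair shares a
  position, exercising the third QC rule.
* **Variant tables**: ~150 background variants shared with controls
  and panel (every one present in the panel with ≥ 1 allele copy), 10
  private variants on another chromosome (region-filter fodder), and
  the two seeded variants: G>A in codon 45 (CGG→CAG, R45Q — the G>A
  also destroys an MspI CCGG site, so the two alleles are
  RFLP-distinguishable) and C>T in codon 444 (ACC→ATC, T444I),
  34,342 bp apart in a two-exon plus-strand transcript embedded in
  random reference sequence. An optional synonymous decoy (GCT→GCC in
  codon 445) exercises the protein-changing filter stage. The panel is
  emitted as allele counts over 2 × 1682 chromosomes.
* **Protein alignment**: 12 simulated ortholog sequences substituting
  residues at 0.15 per site, but 0.01 at residue 45 and 0.7 at residue
  444 — reproducing the qualitative contrast between a conserved and a
  non-conserved candidate residue as a computable identity score.

What the generator does **not** emulate: linkage disequilibrium beyond
pedigree transmission (founder haplotypes are drawn marker-wise
independent), population history or selection, read-level sequencing
artifacts, and genotype-likelihood uncertainty. Passing tests therefore
demonstrate the correctness of the mapping logic under the stated
transmission model, not robustness to population LD structure or
low-coverage calling noise.

# Quality control

Three marker rules, in order, with attribution by first failing rule;
samples are never removed:

1. **Call rate** (default 0.95): a marker genotyped in strictly less
   than 95 % of samples is removed; exactly 95 % survives.
2. **Mendelian conflicts**: a conflict is an opposing-homozygote
   parent/offspring pair — of the nine genotype combinations only
   (0,2) and (2,0) are impossible at a biallelic autosomal marker.
   Pairs with a missing call are excluded from the denominator. The
   threshold is a conflict *rate* over tested pairs (default > 0.10
   removes), a deliberately conservative, documented guess since
   "frequently" is not quantifiable; it is exposed as a parameter.
3. **Positions**: markers with unknown chromosome/position, and *all*
   members of any set sharing a position (ambiguity is mutual).

The three filters commute whenever their failure sets are disjoint, and
the surviving set is order-independent unconditionally (each rule is a
property of the marker, not of the other rules' outcomes).

# Variant prioritization

Four intersective filters: candidate region (1-based inclusive bounds on
both sides), case homozygous-alternative with no control carrying the
allele, zero copies in the population panel ("not present" is absolute —
frequency 0.001 fails), and protein-changing. Because they are
intersections, the final set is invariant under filter order; the trace
records one first-fail reason per dropped variant.

Two documented choice points the data cannot decide:

* **Missing control genotypes** default to *not masking* (the variant
  stays private), with a `strict` mode; and a `control_mode =
  "allele_presence"` treats any control record carrying the alternative
  allele as masking regardless of genotype, for pipelines where control
  calls are allele lists rather than genotypes.
* **Consequence classes** are fixed to intergenic / intronic /
  synonymous / missense / stop_gained / stop_lost. Exonic positions
  outside the CDS are reported `intronic` (read: non-coding within the
  transcript span); splice-region annotation is deliberately out of
  scope. Only SNVs are supported; the standard nuclear code is used. A
  mismatch between a variant's reference allele and the genome base is
  a hard error, because it indicates a coordinate bug rather than data
  noise.

The annotator is validated two ways: strand symmetry (a gene re-encoded
on the minus strand of the reverse-complemented contig must annotate
identically) and a full-CDS re-translation oracle (translate the mutated
spliced CDS and diff the proteins) on 1000 random multi-exon genes.

# Conservation scoring

For a reference residue, the score is the fraction of aligned non-gap
residues in its column identical to the reference residue; gaps are
excluded from numerator and denominator (a `mismatch` gap policy is
available). Shannon entropy over the column's residue frequencies (gaps
excluded) is reported as secondary evidence; no substitution-matrix
weighting is applied because the claim being computed is identity-level
conservation. The conserved/not-conserved call uses a default identity
threshold of 0.9 — a configurable convention, since the underlying
contrast (identity 1.0 vs ~0.2 in the simulated alignment) is far from
the threshold either way. A column in which every non-reference sequence
is gapped is scored over the reference alone and flagged.

# Assay statistics

* `insilico_digest()` performs idealized complete digestion: every
  (possibly overlapping) occurrence of the recognition sequence is cut
  at the marked offset; star activity and partial digestion are not
  modeled. Fragment lengths always sum to the amplicon length.
* `ld_r2()` is the *composite* r² — squared Pearson correlation of
  genotype dosages — because phase is unknown in targeted genotyping
  data; it is computed as cov²/(var·var) so that identical vectors give
  exactly 1.0, and is clamped to [0, 1].
* `bp_to_cM()` / `gametes_per_recombination()` implement the
  small-distance accounting (recombination fraction = cM/100, 1 cM/Mb
  by default) with no mapping-function correction: 34,342 bp → 0.034 cM
  → one recombination per 2941 gametes.

# Pipeline

`run_pipeline()` chains simulate → qc → scan → prioritize → conserve →
verify with plain-file hand-off (TSV/VCF/FASTA) so each stage is
independently inspectable and re-runnable from its serialized inputs;
stages can be toggled and externally-produced regions substituted. The
JSON report excludes timings, so identical configuration and seed give
byte-identical payloads. The package's function surface (plus YAML
configuration) is the intended interface; no shell wrapper is shipped.

# Problem sizes and numerical conventions

The validation suite runs, by choice, at sizes where exhaustive oracles
are exact and fast: 50 random fixtures of up to 300 SNPs × 20 samples
for scan-vs-oracle equivalence, 100 error-free replicates of the default
56-individual / 1200-marker study for causal recovery, 1000 random genes
for the annotator, 10,000 random amplicons for the digest property.
Coordinates are 1-based inclusive throughout, except BED export
(0-based half-open, documented); chromosome sorting is numeric where
possible; all simulations are bit-reproducible functions of a single
integer seed, with stage seeds derived by fixed offsets.

# Known limitations

* No phasing or imputation: genotype errors void windows (see above).
* Founder haplotypes carry no background LD, so the simulated scan's
  false-positive region count is lower than on real breed data.
* The carrier founder must be ancestral to every case and obligate
  carrier; pedigrees violating this are rejected rather than partially
  satisfied.
* Indels, multi-nucleotide variants, splice-region and UTR consequence
  classes are out of scope by design.
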