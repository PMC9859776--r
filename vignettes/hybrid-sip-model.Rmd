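---
title: "The hybrid SIP model: assumptions, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid SIP model: assumptions, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hybridsip simulates and analyses a DNA stable-isotope-probing (SIP)
metagenomics experiment in which the genomes of interest — autotrophic,
ammonia-oxidising archaea (AOA) and their viruses — are low-GC minorities in
soils dominated by high-GC, unlabeled background DNA. This vignette is the
package's own account of the model: what is simulated, why each default is
what it is, and what passing tests do and do not establish.

## The buoyant-density model

Isopycnic CsCl centrifugation bands DNA at its buoyant density (BD). The
package uses a linear model in GC fraction and excess ¹³C atom fraction:

$$ \mathrm{BD} = a + b\,\mathrm{GC} + s\,\frac{x - x_0}{1 - x_0} $$

with intercept $a = 1.660$ g/ml, GC slope $b = 0.098$ g/ml (the classic
linear BD–GC relation for double-stranded DNA), full-labeling shift
$s = 0.036$ g/ml, and natural ¹³C abundance $x_0 = 0.011$. All four are
config fields (`gradient$bd_*`). The model is deliberately minimal: it is
strictly increasing in both arguments, which is the property every
downstream conclusion rests on. Fragment-length effects, gradient-formation
dynamics and rotor physics are out of scope.

Two consequences define the experiment's structure:

* a fully labeled GC 0.38 genome bands at 1.7332 g/ml — *above* the HBD cut
  (1.719 g/ml) and inside the band of unlabeled GC ≥ 0.60 background DNA
  (1.7188+ g/ml): **co-migration**, the problem;
* the same genome unlabeled bands at 1.6972 g/ml, below the LBD cut
  (1.699 g/ml), where essentially no background DNA reaches:
  **separability**, the solution.

Bands are Gaussian with half-width `sigma = 0.003` g/ml (diffusion
broadening), and each replicate gradient jitters every band centre by
N(0, 5·10⁻⁴ g/ml) to emulate inter-gradient variation. Binned masses are
renormalized over the fractionated span so each population's mass is
conserved exactly; this is what makes mass-conservation assertable to
1 part in 10⁹.

### Fraction scheme and pooling

Pooling uses fraction midpoints: HBD = midpoint > 1.719 g/ml, LBD =
midpoint < 1.699 g/ml. The default scheme is 40 equal bins (0.003 g/ml
wide) over 1.66–1.78 g/ml. The width was chosen so that 1.699 g/ml falls on
a bin edge: midpoint pooling then reproduces the continuous LBD cut
exactly, and an unlabeled GC 0.38 band (centre 1.6972, σ 0.003) pools 73 %
of its mass into LBD, as the continuous Gaussian arithmetic says it should.
With coarser bins (e.g. 0.006 g/ml) the effective LBD cut slides to the
nearest edge below (1.696) and that fraction collapses to 35 % — an
artefact of discretisation, not of the physics. The effective HBD cut under
the default scheme is the 1.720 edge, which changes no HBD-side property.

## The synthetic community

`build_scenario()` generates the ground truth the pipeline is judged
against. Per soil (pH 4.5 and pH 7.5, disjoint populations):

| block | populations | GC | abundance | active |
|---|---|---|---|---|
| AOA hosts | 4 (pH 4.5) / 3 (pH 7.5) | 0.370–0.390 | 0.12 total | yes |
| inactive AOA | 1 | 0.380 | 0.02 | no |
| high-GC nitrifier | 1 (NOB at 0.60 / AOB at 0.55) | | 0.03 | yes |
| background | 6 | 0.57–0.70 | 0.75 total | no |
| AOA viruses | 6 | host GC − 0.017 ± 0.01 | 0.08 total | follows host |

Choices and why:

* **Abundances** are free parameters (no field estimates exist for them);
  the structure that matters is that the background holds most DNA and that
  active AOA are a low-GC minority. 12 % active AOA after 30 days of
  urea-fuelled growth is a generous but plausible bloom.
* **Labeling** (`scenario$atom13c_active`, default 1.0) applies to active
  populations under the ¹³C treatment; everything else sits at natural
  abundance, 0.011. Autotrophs replicating entirely on ¹³CO₂-derived carbon
  approach full labeling; partial labeling only moves the labeled band
  part-way and can be explored through the config.
* **Virus GC coupling**: virus GC = host GC + N(−0.017, 0.01), clamped to
  [0.2, 0.8], so 0.38-GC hosts yield ≈ 0.363-GC viruses — the empirical
  host–virus GC correlation for these systems.
* **Virus genome lengths** span 8–40 kb so the ≥ 10 kb vOTU filter is
  exercised in both directions; one virus per soil (8 kb) is recoverable
  but never callable. Four of six viruses per soil are temperate (carry an
  integrase cassette), one is virulent, one infects the inactive host (so
  enrichment must *not* be called for it); one carries an mco1
  multicopper-oxidase AMG cassette.
* **Provirus remnants**: every AOA host genome carries an integrase
  cassette. This is what makes "integrase alone is not a virus call" a
  testable rule rather than a convention.
* **Hallmark cassettes** are back-translated copies of the packaged query
  fixtures (below), one distinct query per population, disjoint between
  soils — virus populations in the two soils are distinct, as they are in
  nitrifying soils generally. Shared queries across soils would make
  homologous cassette reads cross-map between soils and manufacture
  enrichment signal where none exists; the test suite's false-positive
  checks depend on this separation, and real shared genes across
  communities would genuinely produce such calls (a known caveat of
  read-recruitment activity inference).
* **Genome lengths** default to 100 kb (hosts) and 150 kb (background) —
  scaled far below real 1.5–4 Mb genomes. Only relative coverage structure
  matters to any stage, and this keeps a full 24-library replicate design
  fast enough to re-run dozens of times in the test suite.
* Base composition outside cassettes is i.i.d. with an exact G+C count
  (the composition is drawn as a shuffled multiset, with the non-cassette
  count adjusted for the cassettes' achievable codon GC), so realized GC
  equals the target to rounding and the ±0.01 genome invariant holds by
  construction rather than probabilistically.

### The hallmark fixture set

`inst/extdata/hallmark_proteins_synthetic.faa` holds 82 fixed synthetic
proteins (150–400 aa): capsid, terminase, portal, integrase (AOA, AOB and
NOB guild annotations) and the AOA-specific mco1 AMG. They are *synthetic*
stand-ins for a curated provirus-derived query database: random sequences
with proteome-like residue frequencies, fixed once and shipped as data.
That is sufficient because every conclusion the pipeline draws depends only
on detectable homology between a contig's cassette and a query — not on
what the proteins fold into. What this surrogate cannot test is remote
homology detection against diverged real virus proteins; scores here are
either near self-alignment (a planted cassette) or near the random-ORF null
(~30–60 bits), with nothing in between. The default score threshold (100)
sits in that gap and was calibrated once against the empirical null
(100 random 200-aa ORFs against the full set: ≥ 99 % produce no hit).

## Sequencing, recovery and mapping

* **Reads**: 50,000 single-end 150 bp reads per library, substitution rate
  0.001, no indels or quality scores. Source populations are drawn
  multinomially ∝ pooled DNA *mass* (deliberately conflating mass and
  genome copy number, as sequencers sample mass), start positions uniform.
* **Recovery surrogate**: real assembly is out of scope. A population is
  recoverable iff its pooled mean depth across the supplied ¹²C LBD
  libraries reaches `min_depth` (5×), and recoverable genomes are emitted
  as contigs cut at uniform random points, every piece ≥ 5 kb, with the
  fragment count scaling as genome length / 20 kb (+0–1, clamped to 1–8).
  The scaling matters: a fixed 2–8 fragment count would shred 15–40 kb
  virus genomes below the 10 kb vOTU filter and leave nothing callable,
  whereas real high-coverage assemblies of small virus genomes come back in
  one or few pieces. The surrogate consults read ground truth (which an
  assembler would not); what it preserves is the design-critical property
  that *only LBD-banding populations yield reference sequences* — including
  the blind spot that an active high-GC nitrifier (labeled, HBD-banding,
  negligible LBD mass) is never recovered and therefore never testable.
* **Mapping** is alignment-free: a read is assigned to the contig sharing
  the most canonical 21-mers, ties to the lexicographically smallest
  contig id, placed at its modal seed diagonal; depth = aligned (clipped)
  bases / contig length, breadth = covered fraction. At 0.1 % error, a
  150 bp read retains ≈ 87 % of its 21-mers intact, so k-mer identity is
  ample. The C++ backend indexes contigs once per mapping batch; the test
  suite pins the assignment against a brute-force oracle.

## Statistics

Per feature and soil, the ¹³C-enrichment test compares HBD read proportions
(count / library depth) across the 3 ¹²C vs 3 ¹³C replicates: Student's
pooled-variance t-test when a two-sided F-test at α = 0.05 accepts variance
homogeneity, Welch's otherwise; two-sided p with a directional call
(`enriched` requires p < 0.05 *and* a greater ¹³C mean). Choices made where
the procedure was open:

* the homogeneity test is an F-test (no test is canonical here; Levene
  would also do and the switch is config-exposed in spirit via
  `var_alpha`);
* two-sided + direction rather than one-sided: the directional requirement
  halves the effective null rate (≈ 0.025 observed under the label-free
  null) and makes "significantly greater" literal; a one-sided option
  exists on `enrichment_test()`;
* proportions are tested untransformed; with n = 3 and proportions ≪ 0.5
  the normal approximation is as defensible as any transform;
* no multiple-testing correction by default (each feature is reported as
  its own replicate-wise test); Benjamini–Hochberg is available via
  `stats$p_adjust = "BH"`;
* degenerate inputs are decided, not errored: both groups constant and
  equal → p = 1; constant and different → p = 0; one group zero-variance →
  maximally inhomogeneous (Welch). ln(0) never enters the reads-per-kb
  heatmap: entries with zero counts or failing the ≥ 1× / ≥ 75 % detection
  filters are masked, never imputed.

The soil-differential comparison applies the same machinery to ¹²C LBD
proportions between soils; `variance_check`'s zero-variance rule is what
lets "present only in soil A" resolve to a Welch test rather than an error.

## Problem sizes used by the tests and acceptance script

Scenario regeneration, fractionation and screening are exercised at full
default size. The type-I-error check runs 200 (tests) / 100 (acceptance
script) label-free replicates at 8,000 reads/library — the null behaviour
of a t-test on multinomial proportions does not depend on depth, and this
keeps hundreds of replicates affordable; parameter recovery runs the
default experiment at full depth (50,000-read libraries) across 20 (tests)
/ 6 (script) master seeds, sequencing and mapping the 18 of 24 libraries
that the inference consumes (the ¹³C LBD libraries feed no statistic).
These sizes are the package's choices for routine verification; all of
them are plain config fields.

## What passing does and does not show

The simulation establishes internal correctness: the gradient model's
monotonic physics, exact mass bookkeeping, faithful pooling and sampling,
oracle-verified mapping and statistics, and recovery of planted ground
truth (sensitivity, false-positive control, soil specificity) under the
stated community. It does *not* establish performance on real soil
metagenomes: no assembler is run (recovery is a thresholded surrogate),
hallmark homology is exact-by-construction rather than remote, genome
lengths and abundances are stylised, reads are single-end and indel-free,
and populations are soil-disjoint. Those simplifications are the price of a
ground truth; the package's claims end where they begin.
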