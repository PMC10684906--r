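---
title: "Detecting uniparental genome elimination in cenh3 progeny screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uniparental genome elimination in cenh3 progeny screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscreen)
```

## The screening problem

Plants carrying a mutated centromeric histone gene (*CENH3*) can, when
crossed to a wild-type partner, occasionally eliminate the entire
chromosome set they contributed to the zygote.  The surviving progeny
then carries only the wild-type parent's genome — the raw material for
doubled-haploid ("instant inbred") breeding.  Such events are rare and
masquerade, at a single genotyped locus, as several other outcomes:
ordinary self-pollination of the mutant parent, a normal F1, or an
aneuploid that lost just the one chromosome carrying the assayed locus.
hapscreen implements the full decision chain that separates these
hypotheses:

1. **Edited-locus genotyping** (`classify_pace`, `classify_sanger`) —
   a first pass over hundreds of seedlings that flags the rare
   homozygous-wild-type *candidates*.
2. **Read-depth dosage analysis** (`dosage_pipeline`) — detects which,
   if any, chromosomes of a candidate are in an abnormal copy state
   relative to euploid controls.
3. **Heterozygosity scanning** (`het_pipeline`) — distinguishes loss of
   one chromosome (heterozygosity collapses only there) from loss of a
   whole parental genome (heterozygosity collapses everywhere).
4. **Marker-based lineage assignment** (`lineage_pipeline`,
   `infer_maternal_parent`) — confirms with a panel of diagnostic loci
   (two per chromosome, 18 in total) that the nuclear genome derives
   from a single parent, and with an organellar marker that the mutant
   plant really was the seed parent.
5. **Flow-cytometry ploidy estimation** (`find_peaks`,
   `estimate_ploidy`) — determines whether the eliminated genome was
   restored by doubling (a tetraploid readout relative to the diploid
   standard, when the surviving set was itself diploid-derived).

A cross simulator (`simulate_cross` and its writers) generates every
raw input — SAM alignments, VCF variant calls, fluorescence tables,
marker genotypes — from a specified karyotype ground truth, so the
entire chain is testable at desk scale.

## Dosage model

Reads are filtered to proper, uniquely mapped pairs with both mates on
one contig (FLAG ∈ {83, 99, 147, 163}, RNEXT `=`, MAPQ exactly 60),
assigned to 250-kb bins by their mid position, and converted to percent
depth $p_{ib} = n_{ib} / \sum_b n_{ib}$ for sample $i$ and bin $b$.
The copy-number estimate is

$$d_{ib} = 2\,\frac{p_{ib}}{\bar{p}^{\,\mathrm{ctl}}_b},$$

where $\bar{p}^{\,\mathrm{ctl}}_b$ is the mean percent depth of the
(at least two, typically four) euploid controls in bin $b$.  A diploid
bin reads out at 2, a monosomic chromosome near 1, a trisomic segment
near 3.  Two consequences of this construction are worth keeping in
mind:

* **The method is relative.**  A tetraploid in which every chromosome
  was doubled is indistinguishable from a diploid — all values remain
  at 2.  Absolute DNA content is the flow-cytometry module's job, and
  the package's tests assert this blindness rather than hiding it.
* **The denominator is the whole sample.**  Percent-of-total
  normalization slightly inflates values genome-wide when part of the
  genome is missing: with one of nine equal chromosomes monosomic, the
  sample spans 17 copy-units instead of 18, so the lost chromosome's
  expectation is $18/17 \approx 1.06$ rather than exactly 1, and the
  disomic chromosomes sit near $2.12$.  This is inherent to the
  procedure (a per-chromosome denominator would erase the
  whole-chromosome signal entirely; that variant is retained as
  `per_chromosome = TRUE` for audit) and is far inside the
  state-calling bands.

States are called from per-chromosome medians with fixed, configurable
thresholds (monosomic < 1.5 ≤ disomic < 2.5 ≤ trisomic < 3.5), and
segmental anomalies as maximal runs of at least 8 consecutive bins
(2 Mb) deviating from the chromosome's state value by more than 0.4.
The source data for these calls are typically inspected as plots; fixed
thresholds make the procedure reproducible and testable, and both
values are arguments of `call_dosage`.  At low coverage (tens of pairs
per bin) single noisy bins can break a deviation run, so segmental
detection is less sensitive than whole-chromosome calling at equal
depth; the run length trades sensitivity against false segments.

## Heterozygosity model

Variant records are post-filtered by the exclusion expression
`QUAL <= 140 || DP > 50 || SCBZ > 0` (i.e. retained when QUAL > 140,
DP ≤ 50 and SCBZ ≤ 0), homozygous calls are dropped, and the surviving
heterozygous SNPs are counted in the same 250-kb bins used for dosage.
The QUAL clause is deliberately taken from the executable filter
expression: it operates on site quality, even though a prose reading
might suggest mapping quality.  Records lacking the SCBZ annotation —
not every caller emits a soft-clip bias score — pass that clause with a
warning tally by default (`strict_scbz = TRUE` reverses this), so the
scan still runs on third-party VCFs.

A chromosome is *reduced* when its median per-bin heterozygous count
falls below 10% of the pooled control median for that chromosome;
genome-wide reduction (the genome-elimination signature) requires every
chromosome to be reduced.  The 10% default leaves ample head-room on
both sides at realistic SNP densities: an outbred control fluctuates a
few percent around its own median, while a uniparental genome's
residual heterozygosity is bounded by the genotyping error floor, which
scales linearly with the error rate.

## Progeny classification and screen summaries

PACE endpoint genotyping reads the edited locus through two
allele-specific primers labelled FAM (wild-type allele) and HEX (edited
allele).  The classifier works on the allele fraction
$r = \mathrm{FAM}/(\mathrm{FAM}+\mathrm{HEX})$ with symmetric bands:
$r \le 0.15$ self, $r \in [0.30, 0.70]$ F1, $r \ge 0.85$ candidate,
anything else (including zero signal in both channels) a no-call.
"Only" and "approximately equal" fluorescence are not quantified in
endpoint assays; explicit no-call gaps between the bands make
borderline wells visible instead of silently forcing them into a
class.  Sanger calls map directly (hom-edited → self, het → F1,
hom-wild-type → candidate), and both assays agree exactly on noise-free
simulations.

`summarize_cross` computes the self-pollination rate as
$100 \times \mathrm{self} / (\mathrm{surveyed} - \mathrm{no\_calls})$,
rounded half-up to one decimal — the convention that exactly reproduces
published per-cross rates from their printed counts; no-call exclusion
is the minimal rule for plates with unclassifiable wells.

## Lineage rules

Marker origin calls are presence-based: a PCR assay cannot distinguish
four identical alleles from two, so a tetraploid of uniparental origin
and a diploid of uniparental origin give the same call.  A uniparental
verdict requires *every* informative locus to be assigned exclusively
to one parent — a single discordant or inconsistent locus withholds the
verdict, because the scientific claim rests on full panel concordance,
not a majority vote.  Organellar inheritance is treated as strictly
maternal, so the mitochondrial haplotype identifies the seed parent
independently of any nuclear karyotype.

## Flow-cytometry model

Per-nucleus fluorescence of a stoichiometric DNA stain scales linearly
with DNA content.  `find_peaks` histograms events on 64 log-spaced bins
(instrument intensities span decades), smooths with a 3-bin moving
average, drops debris below 10% of the global mode, and extracts the
requested number of modes, requiring candidate modes to differ by at
least a factor 1.25 in position so that histogram noise on one peak's
flank is never reported as a second population (distinct ploidy classes
differ by at least 4/3).  Peak medians are taken over events within
±20% of the mode.  The ploidy call is the sample/reference median ratio
times the reference ploidy, rounded; in mixed-preparation mode both
genotypes are stained in one tube and the lower peak is the reference,
which cancels preparation-dependent staining effects.  G2/S-phase
nuclei and debris structure beyond the simple gate are not modelled.

## What the simulator does and does not emulate

The generator's defaults define the conditions under which the package
validates itself:

| parameter | default | meaning |
|---|---|---|
| genome | 9 chromosomes × 5 Mb | 20 bins of 250 kb each; full runs in seconds |
| `depth_per_copy` | 30 | expected retained read pairs per bin per copy |
| `read_length` | 150 bp | typical short-read length |
| `variant_density` | 0.2 / kb | ~50 informative SNPs per bin |
| `error_rate` | 0 | genotyping error (het↔hom flips) |
| `decoy_fraction` | 0.05 | SAM records planted to fail each read filter |
| `filter_fail_fraction` | 0.05 | VCF records planted to fail each post-filter clause |
| `fluor_cv` | 0.05 | multiplicative noise CV, PACE and flow |
| `n_nuclei` | 5000 | events per flow sample |

Per-bin read-pair counts are Poisson with mean copy-number ×
`depth_per_copy` — the minimal read-sampling model — with uniform read
placement inside bins.  Parents are modelled as inbred lines homozygous
for opposite alleles at every simulated SNP and marker site, which
makes every site informative and class signatures exact at zero error
(an F1 is heterozygous everywhere; an eliminated genome nowhere).  Real
outbred parents are polymorphic at only a subset of sites and are
themselves heterozygous at many, so real heterozygosity tracks are
noisier and less uniform than simulated ones.  Decoy records are
planted per failure category rather than produced by a mis-mapping
model: the filters, not an aligner, are under test.  Read sequences are
not simulated (no base errors, no reference sequence), indels and
structural variants other than whole-chromosome or whole-segment copy
changes are absent, and SCBZ is synthesized directly (negative for
clean sites, positive for planted failures) since the pipeline uses it
only as a filter field.  Passing tests therefore demonstrate the
correctness of the decision chain under its stated statistical
assumptions, not robustness to alignment artefacts, GC bias or
mappability structure in real sequencing data.

Each output stream (alignments, variants, fluorescence, per offspring)
derives a child seed deterministically from the master seed, so
identical configurations reproduce byte-identical files and
regenerating one stream never perturbs another.

## Worked example

```{r example, eval = FALSE}
lay <- genome_layout()
cfg <- sim_config(seed = 1)
cr  <- simulate_cross(lay, cfg, c(f1 = 4, aneuploid_mono7 = 1))

dir <- tempfile(); dir.create(dir)
ctl <- file.path(dir, sprintf("ctl%d.sam", 1:4))
for (i in 1:4) write_alignments(cr$offspring[[i]], lay, cfg, ctl[i])
smp <- file.path(dir, "mono7.sam")
write_alignments(cr$offspring[[5]], lay, cfg, smp)

res <- dosage_pipeline(smp, ctl, lay)
res$call
#> <dosage_call>
#>   chr1   disomic    (median 2.16)
#>   chr2   disomic    (median 2.20)
#>   chr3   disomic    (median 2.05)
#>   chr4   disomic    (median 1.98)
#>   chr5   disomic    (median 2.13)
#>   chr6   disomic    (median 2.04)
#>   chr7   monosomic  (median 1.12)
#>   chr8   disomic    (median 2.07)
#>   chr9   disomic    (median 2.13)
#>   no segmental anomalies
```

## Numerical and design choices

* Bins are half-open, `floor(pos / 250000)`: position 125,000 is
  interior to bin 0; position 250,000 opens bin 1.  One shared
  `bin_grid` object serves both dosage and heterozygosity so the
  boundary arithmetic cannot drift between modules.
* A read's mid position is its leftmost position plus half its aligned
  (CIGAR reference-consuming) length.  Each mate counts as one read;
  using the template midpoint instead would double-weight pairs.
* MAPQ is matched exactly to 60 — the unique-mapping value — rather
  than thresholded; a `>=` rule would admit differently calibrated
  records.
* Zero-control bins are masked (NA), never dropped, so bin indices stay
  aligned across samples; all-masked chromosomes are called `other`
  with an explicit flag rather than guessed.
* Rounding of reported rates is half-up to one decimal, matching how
  screen tables are conventionally printed (base R's `round` is
  half-even).
* Chromosome-9-style partial anomalies are simulated as clean
  segment-level copy-number overrides (`set_segment_copy`); chromosome
  shattering is not modelled, and the simulator makes no claim about
  mechanism or timing.

## Problem sizes

The test suite and the acceptance script run entirely on the 9 × 5 Mb
toy genome: dosage and heterozygosity recovery on 20-seeded replicates
of 5-sample families (~10,000 read pairs and ~9,000 variant records per
sample), flow recovery on 20 replicates of 5,000-nuclei samples per
ploidy, and the dosage acceptance run at `depth_per_copy = 120` to hold
the Monte-Carlo standard error of a 20-bin chromosome mean near 0.02.
These sizes were chosen so a complete validation runs in a few minutes
on one core while every statistical margin (Poisson bin noise, binomial
error floors, peak-position jitter) remains comfortably resolvable.

## Known limitations

* Dosage and heterozygosity calls are threshold-based, not model-based:
  no segmentation HMM, no GC/mappability correction, no confidence
  intervals on copy states.
* Absolute ploidy is out of the sequencing modules' reach by
  construction; conclusions about genome doubling rest on the flow
  module.
* The heterozygosity scan assumes one sample per VCF and uses GT
  zygosity only; allele identities and phasing are ignored.
* The simulator's inbred-parent abstraction means marker panels are
  always fully informative; real panels need informativeness screening
  first (uninformative loci are handled, but never generated).
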