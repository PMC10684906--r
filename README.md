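# hapscreen

Screening progeny of *cenh3* mutant × wild-type crosses for uniparental
genome elimination, aneuploidy and ploidy change.

## What it is for

Mutating the centromeric histone gene *CENH3* can turn a plant into a
haploid inducer: in crosses to a wild-type partner, the mutant's entire
chromosome set is occasionally eliminated from the zygote, leaving
progeny that carry only the wild-type parent's genome — the starting
point for doubled-haploid breeding.  Such events are rare, and at a
single genotyped locus they look identical to an aneuploid that merely
lost the one chromosome carrying that locus.  `hapscreen` implements
the complete evidence chain a screening lab uses to tell these
hypotheses apart, plus a simulator that generates every raw input from
a known karyotype so the whole chain is testable without sequencing a
single plant:

| stage | functions | question answered |
|---|---|---|
| endpoint genotyping | `classify_pace`, `classify_sanger`, `summarize_cross` | which seedlings are selfs, F1s or elimination candidates? |
| dosage analysis | `dosage_pipeline` (`filter_reads` → `bin_reads` → `normalize_dosage` → `call_dosage`) | which chromosomes are in abnormal copy state? |
| heterozygosity scan | `het_pipeline` (`filter_variants` → `bin_het_snps` → `detect_het_loss`) | did one chromosome or the whole genome lose heterozygosity? |
| lineage assignment | `call_marker_origin`, `infer_nuclear_lineage`, `infer_maternal_parent` | does the nuclear genome come from a single parent, and who was the mother? |
| flow cytometry | `find_peaks`, `estimate_ploidy` | what is the DNA content relative to a diploid standard? |
| simulation | `simulate_cross`, `write_alignments`, `write_variant_calls`, `write_fluorescence_tables`, `marker_genotypes` | ground-truthed SAM/VCF/CSV inputs for all of the above |

The core dosage statistic for sample *i* and 250-kb bin *b* is

    d_ib = 2 * p_ib / mean(p_b over euploid controls),
    p_ib = reads_ib / total reads_i,

computed from properly paired, uniquely mapped reads (FLAG ∈
{83, 99, 147, 163}, RNEXT `=`, MAPQ 60): a diploid bin reads out at 2,
a monosomic chromosome near 1.  Heterozygosity is counted per bin after
the variant post-filter `QUAL > 140 & DP <= 50 & SCBZ <= 0`, keeping
heterozygous calls only.  The methods vignette
(`vignettes/progeny-screening.Rmd`) derives every rule, default and
known limitation.

## Worked example

Simulate a cross that produced four normal F1 seedlings (used as the
euploid controls) and one monosomic-chromosome-7 aneuploid, then run
the dosage pipeline on the aneuploid:

```r
library(hapscreen)
lay <- genome_layout()                 # 9 chromosomes x 5 Mb, 250-kb bins
cfg <- sim_config(seed = 1)            # 30 read pairs per bin per copy
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

Chromosome 7's bins oscillate around 1 — half the diploid value — while
every other chromosome sits near 2: the single-copy state is recovered,
and the per-bin table in `res$profile` is the substrate for the usual
karyotype plot.  The same family's VCFs, marker tables and fluorescence
CSVs feed the other modules; see the vignette for the full decision
chain, including how a genome-eliminated tetraploid (all 18 diagnostic
markers from the wild-type parent, genome-wide heterozygosity loss,
flow ratio ≈ 2) is distinguished from this aneuploid.

A thin command-line front end over the same functions is included:

```sh
Rscript inst/cli/hapscreen.R simulate --seed 1 \
    --classes f1=4,aneuploid_mono7=1 --out-dir sim
Rscript inst/cli/hapscreen.R dosage --sample sim/sim05_aneuploid_mono7.sam \
    --controls sim/sim01_f1.sam,sim/sim02_f1.sam,sim/sim03_f1.sam,sim/sim04_f1.sam
```

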