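Package: hapscreen
Title: Screening Progeny for Uniparental Genome Elimination, Aneuploidy
    and Ploidy Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A workflow for detecting uniparental genome elimination,
    aneuploidy and ploidy change in progeny of centromeric-histone
    (CENH3) mutant by wild-type crosses.  Classifies seedlings at the
    edited locus from endpoint-fluorescence (PACE/KASP) or Sanger
    genotype calls; estimates relative chromosome copy number from
    binned read depth in aligned reads normalized against euploid
    controls; scans variant calls for chromosome- or genome-wide loss
    of heterozygosity in 250-kb windows; assigns parental lineage from
    diagnostic nuclear and organellar markers; and estimates relative
    nuclear DNA content from flow-cytometry fluorescence peaks.  A
    cross/karyotype simulator generates parental genomes, offspring of
    specified karyotype classes and all downstream raw inputs (SAM,
    VCF, fluorescence tables) so every stage is verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
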