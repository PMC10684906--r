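#' Simulation configuration
#'
#' Collects every tunable of the cross simulator.  Identical
#' (seed, config, layout) triples reproduce identical outputs.
#'
#' @param seed Master random seed (integer).  Every output stream
#'   derives its own child seed deterministically from this value, so
#'   e.g. regenerating a VCF does not perturb the SAM stream.
#' @param depth_per_copy Expected retained read pairs per bin per
#'   chromosome copy (default 30; a diploid bin then averages 60 pairs).
#' @param read_length Read length in bp (default 150).
#' @param variant_density Informative SNP sites per kb (default 0.2,
#'   i.e. ~50 sites per 250-kb bin).
#' @param error_rate Genotyping error probability per variant site
#'   (default 0): a heterozygous truth is miscalled homozygous and vice
#'   versa with this probability.
#' @param decoy_fraction Fraction of SAM records, relative to the
#'   retained set, planted to fail the read filters (default 0.05),
#'   split evenly across the three failure categories (improper flag,
#'   MAPQ != 60, mate on another contig).
#' @param filter_fail_fraction Fraction of VCF records planted to fail
#'   each variant post-filter clause (QUAL <= 140, DP > 50, SCBZ > 0;
#'   default 0.05 per clause, disjoint site sets).
#' @param fluor_cv Coefficient of variation of multiplicative
#'   fluorescence noise for PACE signals and flow-cytometry nuclei
#'   (default 0.05).
#' @param n_nuclei Nuclei per flow-cytometry sample (default 5000).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       depth_per_copy = 30,
                       read_length = 150L,
                       variant_density = 0.2,
                       error_rate = 0,
                       decoy_fraction = 0.05,
                       filter_fail_fraction = 0.05,
                       fluor_cv = 0.05,
                       n_nuclei = 5000L) {
  stopifnot(depth_per_copy > 0, read_length > 0, variant_density > 0,
            error_rate >= 0, error_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            filter_fail_fraction >= 0, filter_fail_fraction <= 1,
            fluor_cv >= 0, n_nuclei > 0)
  structure(list(seed = as.integer(seed),
                 depth_per_copy = depth_per_copy,
                 read_length = as.integer(read_length),
                 variant_density = variant_density,
                 error_rate = error_rate,
                 decoy_fraction = decoy_fraction,
                 filter_fail_fraction = filter_fail_fraction,
                 fluor_cv = fluor_cv,
                 n_nuclei = as.integer(n_nuclei)),
            class = "sim_config")
}

# Deterministic child seed for a named output stream.  Keeps independent
# streams (SAM vs VCF vs fluorescence, per offspring) decoupled while
# remaining reproducible from the single master seed.
derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483587) + 1L
}

#' Offspring karyotype classes
#'
#' The four progeny classes a cenh3-mutant (parent A, female) x
#' wild-type (parent B, male) cross can yield in this workflow:
#' \describe{
#'   \item{self}{self-pollination of the mutant parent: both genome
#'     copies from parent A, homozygous edited at the CENH3 locus.}
#'   \item{f1}{true cross: one copy from each parent, heterozygous at
#'     the edited locus.}
#'   \item{aneuploid_mono7}{F1 background that lost the maternal copy
#'     of chromosome 7: chromosome 7 in single copy (the wild-type
#'     parent's), all others disomic; homozygous wild type at the
#'     edited locus (which resides on chromosome 7).}
#'   \item{eliminated_tetraploid}{maternal genome eliminated, then the
#'     paternal set quadrupled: all chromosomes in four identical
#'     copies from the wild-type parent; zero heterozygous sites.}
#' }
#' @export
OFFSPRING_CLASSES <- c("self", "f1", "aneuploid_mono7",
                       "eliminated_tetraploid")

#' Simulate a cenh3-mutant x wild-type cross
#'
#' Generates the two parental genomes (inbred-line abstraction:
#' homozygous for opposite alleles at every simulated SNP and marker
#' site) and a set of offspring ground-truth specifications of the
#' requested classes.  Downstream writers
#' (\code{\link{write_alignments}}, \code{\link{write_variant_calls}},
#' \code{\link{write_fluorescence_tables}},
#' \code{\link{marker_genotypes}}) turn each offspring spec into the
#' raw inputs the analysis modules consume.
#'
#' @param layout A \code{\link{genome_layout}}.
#' @param config A \code{\link{sim_config}}.
#' @param class_mix Named integer vector of offspring counts per class,
#'   e.g. \code{c(f1 = 3, self = 2)}.  Names must come from
#'   \code{\link{OFFSPRING_CLASSES}}.
#' @return A list with elements \code{parents} (list of two
#'   \code{parental_genome} objects, \code{A} the cenh3 mutant and
#'   maternal parent, \code{B} the wild type) and \code{offspring}
#'   (list of \code{offspring_spec} objects, in class_mix order).
#' @examples
#' cross <- simulate_cross(genome_layout(), sim_config(seed = 1),
#'                         c(f1 = 2, eliminated_tetraploid = 1))
#' sapply(cross$offspring, `[[`, "class")
#' @export
simulate_cross <- function(layout, config, class_mix) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(config, "sim_config"))
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stop("class_mix must be a named vector of counts")
  bad <- setdiff(names(class_mix), OFFSPRING_CLASSES)
  if (length(bad))
    stop("unknown offspring class: ", paste(bad, collapse = ", "))
  if (any(class_mix < 0)) stop("class_mix counts must be >= 0")

  parents <- make_parents(layout, config)
  offspring <- list()
  i <- 0L
  for (cls in names(class_mix)) {
    for (k in seq_len(class_mix[[cls]])) {
      i <- i + 1L
      offspring[[i]] <- make_offspring(sprintf("sim%02d_%s", i, cls),
                                       cls, layout)
    }
  }
  list(parents = parents, offspring = offspring)
}

# Two inbred-line parents: A (cenh3 mutant, maternal) carries the
# reference allele at every informative site, B (wild type) the
# alternate.  SNP positions are drawn once, deterministically from the
# master seed, and shared by every sample of the cross.
make_parents <- function(layout, config) {
  withr::with_seed(derive_seed(config$seed, "parents"), {
    sites <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
      len <- layout$chrom_lengths[[ch]]
      n <- max(1L, round(config$variant_density * len / 1000))
      data.frame(chrom = ch,
                 pos = sort(sample.int(len, n)),
                 ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    alt_of <- c(A = "T", C = "G", G = "C", T = "A")
    sites$alt <- unname(alt_of[sites$ref])
    # two diagnostic marker loci per chromosome, at 1/3 and 2/3 span
    markers <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
      len <- layout$chrom_lengths[[ch]]
      data.frame(locus_id = paste0(ch, c("_m1", "_m2")),
                 chrom = ch,
                 pos = round(c(len / 3, 2 * len / 3)),
                 stringsAsFactors = FALSE)
    }))
    markers$allele_A <- sample(c("A", "C", "G", "T"), nrow(markers),
                               replace = TRUE)
    markers$allele_B <- unname(alt_of[markers$allele_A])
    mito <- list(A = "ATCGGATT", B = "ATCGAATT")
  })
  mk <- function(id, role, allele_col, hap) {
    structure(list(parent_id = id, role = role,
                   sites = sites,       # shared site table; gt below
                   gt = if (allele_col == "ref") "0/0" else "1/1",
                   markers = markers, marker_allele = allele_col,
                   mito_haplotype = hap),
              class = "parental_genome")
  }
  list(A = mk("mutA", "cenh3_mutant", "ref", mito$A),
       B = mk("wtB", "wild_type", "alt", mito$B))
}

make_offspring <- function(id, cls, layout) {
  chroms <- layout$chrom_names
  two <- stats::setNames(rep(2L, length(chroms)), chroms)
  spec <- switch(cls,
    self = list(copy_number = two,
                origin = lapply(two, function(n) rep("A", n)),
                edited_genotype = "hom_edited"),
    f1 = list(copy_number = two,
              origin = lapply(two, function(n) c("A", "B")),
              edited_genotype = "het"),
    aneuploid_mono7 = {
      cn <- two
      if (!"chr7" %in% chroms)
        stop("aneuploid_mono7 requires a chromosome named chr7")
      cn["chr7"] <- 1L
      org <- lapply(chroms, function(ch)
        if (ch == "chr7") "B" else c("A", "B"))
      names(org) <- chroms
      list(copy_number = cn, origin = org,
           edited_genotype = "hom_wildtype")
    },
    eliminated_tetraploid = {
      cn <- stats::setNames(rep(4L, length(chroms)), chroms)
      list(copy_number = cn,
           origin = lapply(cn, function(n) rep("B", n)),
           edited_genotype = "hom_wildtype")
    },
    stop("unknown offspring class: ", cls))
  structure(c(list(id = id, class = cls,
                   segment_overrides = NULL), spec),
            class = "offspring_spec")
}

#' Override copy number on a chromosome segment
#'
#' Adds a segmental copy-number override to an offspring specification,
#' e.g. a partial duplication confined to part of one chromosome.  Read
#' simulation uses the override for bins whose start falls inside
#' \code{[start, end)}; whole-chromosome truth labels are unchanged.
#'
#' @param offspring An \code{offspring_spec}.
#' @param chrom Chromosome name.
#' @param start,end Segment bounds (0-based half-open, bp).
#' @param copy_number Integer copy number for the segment.
#' @return The modified \code{offspring_spec}.
#' @export
set_segment_copy <- function(offspring, chrom, start, end, copy_number) {
  stopifnot(inherits(offspring, "offspring_spec"),
            chrom %in% names(offspring$copy_number),
            start >= 0, end > start, copy_number >= 0)
  ov <- data.frame(chrom = chrom, start = start, end = end,
                   copy_number = as.integer(copy_number),
                   stringsAsFactors = FALSE)
  offspring$segment_overrides <- rbind(offspring$segment_overrides, ov)
  offspring
}

# per-bin copy number vector for one chromosome, with overrides applied
bin_copy_numbers <- function(offspring, chrom, grid) {
  g <- grid[grid$chrom == chrom, ]
  cn <- rep(offspring$copy_number[[chrom]], nrow(g))
  ov <- offspring$segment_overrides
  if (!is.null(ov)) {
    ov <- ov[ov$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(ov)))
      cn[g$start >= ov$start[j] & g$start < ov$end[j]] <- ov$copy_number[j]
  }
  cn
}

#' Write simulated paired-end alignments (SAM)
#'
#' Emits a headered, coordinate-sorted SAM file for one offspring.  For
#' every 250-kb bin the number of retained (filter-passing) read pairs
#' is Poisson with mean \code{copy_number * depth_per_copy}; both mates
#' of a pair are placed uniformly so that their mid positions fall in
#' the bin.  Retained records carry proper-pair FLAGs from
#' \{83, 99, 147, 163\}, RNEXT \code{"="} and MAPQ 60.  A configurable
#' fraction of decoy records is planted to exercise each read-filter
#' criterion: improper FLAG, MAPQ != 60, and mate mapped to another
#' contig.
#'
#' @param offspring An \code{offspring_spec}.
#' @param layout A \code{genome_layout}.
#' @param config A \code{sim_config}.
#' @param path Output SAM path.
#' @return Invisibly, the number of retained records written.
#' @export
write_alignments <- function(offspring, layout, config, path) {
  stopifnot(inherits(offspring, "offspring_spec"))
  grid <- bin_grid(layout)
  L <- config$read_length
  half <- L %/% 2

  withr::with_seed(derive_seed(config$seed, paste0("sam:", offspring$id)), {
    recs <- list()
    for (ch in layout$chrom_names) {
      g <- grid[grid$chrom == ch, ]
      cn <- bin_copy_numbers(offspring, ch, grid)
      npairs <- stats::rpois(nrow(g), cn * config$depth_per_copy)
      tot <- sum(npairs)
      if (tot == 0) next
      binrow <- rep(seq_len(nrow(g)), npairs)
      # mid positions uniform within the half-open bin, per mate
      mid1 <- g$start[binrow] +
        floor(stats::runif(tot) * (g$end[binrow] - g$start[binrow]))
      mid2 <- g$start[binrow] +
        floor(stats::runif(tot) * (g$end[binrow] - g$start[binrow]))
      pos1 <- pmax(1L, as.integer(mid1 - half))
      pos2 <- pmax(1L, as.integer(mid2 - half))
      fr <- stats::runif(tot) < 0.5   # pair orientation
      f1 <- ifelse(fr, 99L, 83L)
      f2 <- ifelse(fr, 147L, 163L)
      qn <- sprintf("%s_%s_p%06d", offspring$id, ch, seq_len(tot))
      recs[[ch]] <- data.frame(
        qname = c(qn, qn), flag = c(f1, f2), chrom = ch,
        pos = c(pos1, pos2), mapq = 60L, rnext = "=",
        pnext = c(pos2, pos1), stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, recs)
    n_retained <- if (is.null(reads)) 0L else nrow(reads)

    # decoys: one third per failure category, uniform genome-wide
    n_decoy <- round(config$decoy_fraction * n_retained)
    if (n_decoy > 0) {
      dch <- sample(layout$chrom_names, n_decoy, replace = TRUE)
      dpos <- as.integer(ceiling(stats::runif(n_decoy) *
                                   (layout$chrom_lengths[dch] - L)))
      cat3 <- rep_len(c("bad_flag", "bad_mapq", "bad_mate"), n_decoy)
      dflag <- ifelse(cat3 == "bad_flag", 97L,
                      sample(c(83L, 99L, 147L, 163L), n_decoy,
                             replace = TRUE))
      dmapq <- ifelse(cat3 == "bad_mapq",
                      sample(c(0L, 27L, 40L), n_decoy, replace = TRUE), 60L)
      other <- vapply(dch, function(c0)
        sample(setdiff(layout$chrom_names, c0), 1L), character(1))
      drnext <- ifelse(cat3 == "bad_mate", other, "=")
      decoys <- data.frame(
        qname = sprintf("%s_decoy%06d", offspring$id, seq_len(n_decoy)),
        flag = dflag, chrom = dch, pos = dpos, mapq = dmapq,
        rnext = drnext, pnext = dpos, stringsAsFactors = FALSE)
      reads <- rbind(reads, decoys)
    }
  })

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom_names,
                      layout$chrom_lengths),
              "@PG\tID:hapscreen\tPN:hapscreen")
  if (!is.null(reads)) {
    reads <- reads[order(match(reads$chrom, layout$chrom_names),
                         reads$pos), ]
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*",
                    reads$qname, reads$flag, reads$chrom, reads$pos,
                    reads$mapq, L, reads$rnext, reads$pnext)
  } else body <- character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(n_retained)
}

#' Write simulated variant calls (VCF 4.2)
#'
#' Emits a single-sample VCF for one offspring over the cross's shared
#' SNP site table.  The genotype at each site follows from which
#' parental copies the offspring carries on that chromosome (parent A
#' contributes the reference allele, parent B the alternate), perturbed
#' by the genotyping error rate (heterozygous truths miscalled
#' homozygous, and vice versa).  Clean records are guaranteed to pass
#' the downstream post-filters (QUAL > 140, DP <= 50, SCBZ <= 0); a
#' configurable fraction of records per clause is planted to fail it.
#'
#' @param offspring An \code{offspring_spec}.
#' @param parents Parent list as returned by \code{simulate_cross}.
#' @param layout A \code{genome_layout}.
#' @param config A \code{sim_config}.
#' @param path Output VCF path.
#' @return Invisibly, the number of records written.
#' @export
write_variant_calls <- function(offspring, parents, layout, config, path) {
  stopifnot(inherits(offspring, "offspring_spec"))
  sites <- parents$A$sites
  n <- nrow(sites)

  withr::with_seed(derive_seed(config$seed, paste0("vcf:", offspring$id)), {
    alleles <- lapply(offspring$origin[sites$chrom], unique)
    gt <- vapply(alleles, function(a) {
      if (length(a) == 2L) "0/1" else if (a == "A") "0/0" else "1/1"
    }, character(1))
    # genotyping error: het <-> hom flips
    err <- stats::runif(n) < config$error_rate
    if (any(err)) {
      flip_to <- ifelse(gt[err] == "0/1",
                        ifelse(stats::runif(sum(err)) < 0.5, "0/0", "1/1"),
                        "0/1")
      gt[err] <- flip_to
    }
    qual <- round(stats::runif(n, 150, 228), 1)
    dp <- pmin(50L, pmax(1L, stats::rpois(n, 30)))
    scbz <- round(-abs(stats::rnorm(n, 1, 0.7)), 3)
    # planted filter failures, disjoint site sets per clause
    ff <- config$filter_fail_fraction
    n_fail <- round(ff * n)
    if (3 * n_fail > n) stop("filter_fail_fraction too large for site count")
    if (n_fail > 0) {
      idx <- sample.int(n, 3 * n_fail)
      i_q <- idx[seq_len(n_fail)]
      i_d <- idx[n_fail + seq_len(n_fail)]
      i_s <- idx[2 * n_fail + seq_len(n_fail)]
      qual[i_q] <- round(stats::runif(n_fail, 30, 140), 1)
      dp[i_d] <- as.integer(51 + stats::rpois(n_fail, 20))
      scbz[i_s] <- round(abs(stats::rnorm(n_fail, 1, 0.5)), 3)
    }
  })

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapscreen-simulator",
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom_names,
            layout$chrom_lengths),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    paste0("##INFO=<ID=SCBZ,Number=1,Type=Float,",
           "Description=\"Soft-clip length bias z-score\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", offspring$id, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\tDP=%d;SCBZ=%.3f\tGT\t%s",
                  sites$chrom, sites$pos, sites$ref, sites$alt,
                  qual, dp, scbz, gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(n)
}

#' Write simulated fluorescence tables (PACE and flow cytometry)
#'
#' PACE endpoint signals: each seedling's FAM/HEX pair is centered on
#' its class archetype at the edited locus — homozygous edited (self)
#' is HEX-only, heterozygous (F1) has equal FAM and HEX, homozygous
#' wild type (elimination candidate) is FAM-only — with multiplicative
#' log-normal noise of coefficient of variation \code{fluor_cv}.
#'
#' Flow cytometry: one sample of \code{n_nuclei} per offspring, each
#' nucleus's fluorescence log-normal around a location that scales
#' linearly with nominal ploidy (100 units per diploid genome
#' equivalent; a tetraploid peaks at 200).
#'
#' @param offspring_list List of \code{offspring_spec} objects.
#' @param config A \code{sim_config}.
#' @param pace_path Output CSV path for PACE signals
#'   (\code{seedling_id,fam,hex}); \code{NULL} to skip.
#' @param flow_path Output CSV path for flow events
#'   (\code{sample_id,fluorescence}); \code{NULL} to skip.
#' @return Invisibly, a list with the two data.frames written.
#' @export
write_fluorescence_tables <- function(offspring_list, config,
                                      pace_path = NULL, flow_path = NULL) {
  if (!length(offspring_list)) stop("offspring list is empty")
  cv <- config$fluor_cv
  sdlog <- sqrt(log(1 + cv^2))
  # mean-1 multiplicative log-normal noise
  noise <- function(n) {
    if (cv == 0) return(rep(1, n))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }

  arch <- list(hom_edited = c(fam = 0, hex = 1),
               het = c(fam = 0.5, hex = 0.5),
               hom_wildtype = c(fam = 1, hex = 0))
  pace <- do.call(rbind, lapply(offspring_list, function(o) {
    a <- arch[[o$edited_genotype]]
    data.frame(seedling_id = o$id, fam = a[["fam"]], hex = a[["hex"]],
               stringsAsFactors = FALSE)
  }))
  flow <- do.call(rbind, lapply(offspring_list, function(o) {
    ploidy <- round(stats::median(o$copy_number))
    data.frame(sample_id = o$id,
               location = 50 * ploidy,   # 100 units at ploidy 2
               stringsAsFactors = FALSE)
  }))

  withr::with_seed(derive_seed(config$seed, "fluor"), {
    pace$fam <- pace$fam * noise(nrow(pace))
    pace$hex <- pace$hex * noise(nrow(pace))
    n <- config$n_nuclei
    flow <- do.call(rbind, lapply(seq_len(nrow(flow)), function(i) {
      data.frame(sample_id = flow$sample_id[i],
                 fluorescence = flow$location[i] * noise(n),
                 stringsAsFactors = FALSE)
    }))
  })

  if (!is.null(pace_path))
    utils::write.csv(pace, pace_path, row.names = FALSE, quote = FALSE)
  if (!is.null(flow_path))
    utils::write.csv(flow, flow_path, row.names = FALSE, quote = FALSE)
  invisible(list(pace = pace, flow = flow))
}

#' Diagnostic marker genotypes for lineage assignment
#'
#' Builds the nuclear marker genotype table (two diagnostic loci per
#' chromosome, 18 for the default nine-chromosome layout) for one
#' offspring, in the format consumed by
#' \code{\link{call_marker_origin}}: each parent homozygous for its
#' allele, the progeny genotype given by the union of alleles on the
#' parental copies it carries (presence-based, as in a PCR assay —
#' tetraploid dosage is not visible).
#'
#' @param offspring An \code{offspring_spec}.
#' @param parents Parent list from \code{simulate_cross}.
#' @param path Optional CSV output path.
#' @return Data.frame with columns \code{locus_id, chrom, parentA_gt,
#'   parentB_gt, progeny_gt}.
#' @export
marker_genotypes <- function(offspring, parents, path = NULL) {
  m <- parents$A$markers
  gt2 <- function(a) paste(a, a, sep = "/")
  prog <- vapply(seq_len(nrow(m)), function(i) {
    who <- unique(offspring$origin[[m$chrom[i]]])
    al <- sort(ifelse(who == "A", m$allele_A[i], m$allele_B[i]))
    paste(if (length(al) == 1L) c(al, al) else al, collapse = "/")
  }, character(1))
  out <- data.frame(locus_id = m$locus_id, chrom = m$chrom,
                    parentA_gt = gt2(m$allele_A),
                    parentB_gt = gt2(m$allele_B),
                    progeny_gt = prog, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Organellar (mitochondrial) haplotypes of a simulated family
#'
#' Every simulated cross uses the cenh3 mutant (parent A) as the female
#' parent, so each offspring inherits parent A's mitochondrial
#' haplotype regardless of its nuclear karyotype.
#'
#' @param offspring An \code{offspring_spec}.
#' @param parents Parent list from \code{simulate_cross}.
#' @return List with \code{progeny} haplotype string and named
#'   \code{parents} haplotype vector.
#' @export
mito_haplotypes <- function(offspring, parents) {
  list(progeny = parents$A$mito_haplotype,
       parents = c(mutA = parents$A$mito_haplotype,
                   wtB = parents$B$mito_haplotype))
}

# Counts-level coverage simulation: per-bin retained-pair counts drawn
# directly as Poisson(copy * depth), bypassing SAM emission.  Used for
# normalization-only property checks where read placement is not under
# test; the SAM writer and reader are exercised elsewhere.
simulate_bin_counts <- function(offspring, layout, depth_per_copy, seed) {
  grid <- bin_grid(layout)
  withr::with_seed(seed, {
    cn <- unlist(lapply(layout$chrom_names, function(ch)
      bin_copy_numbers(offspring, ch, grid)), use.names = FALSE)
    grid$count <- stats::rpois(nrow(grid), 2 * cn * depth_per_copy)
  })
  grid
}
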