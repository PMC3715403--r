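# Synthetic fixture generator.
#
# Emits standard-format VCF/PED/BED/GFF files with known ground truth so
# every other module is testable without downloads. All randomness is
# driven by one seed through R's default Mersenne-Twister generator; the
# same seed reproduces byte-identical files. The truth tables are computed
# by straightforward standalone code in this file, deliberately separate
# from the statistics module they are later compared against.
#
# What the generator emulates: per-site allele frequencies from a
# Beta(0.5, 5) distribution (a rare-variant-heavy site-frequency spectrum),
# Hardy-Weinberg genotype sampling within a cohort, Mendelian transmission
# within families, uniform genotype missingness, and Poisson read depths.
# What it does not emulate: linkage disequilibrium, recombination,
# sequencing error, or relatedness beyond the declared pedigrees.

#' Simulate a population cohort VCF with ground truth
#'
#' Per site: an allele frequency p is drawn from `Beta(af_shape)`, sample
#' genotypes are drawn i.i.d. from Hardy-Weinberg proportions at p, and
#' genotypes are masked uniformly at `missing_rate`. REF/ALT letters are
#' drawn uniformly from {A,C,G,T} without replacement.
#'
#' @param n_samples,n_variants Cohort dimensions.
#' @param af_shape Beta shape parameters of the allele-frequency
#'   distribution.
#' @param missing_rate Per-genotype probability of being uncalled.
#' @param seed Integer seed fixing all randomness.
#' @param dir Output directory (created).
#' @return List: `vcf` and `truth_path` (files), `samples`, `truth`
#'   (per-site data.frame with the drawn p, genotype counts and every
#'   stored statistic, independently computed), and the simulated
#'   `gt_types`, `gts`, `depths` matrices (variants x samples).
#' @export
simulate_cohort <- function(n_samples, n_variants, af_shape = c(0.5, 5),
                            missing_rate = 0, seed = 1L,
                            dir = tempfile("vardb_cohort_")) {
  if (missing_rate < 0 || missing_rate > 1) {
    vardb_stop("missing_rate must be in [0, 1]", "vardb_spec_error")
  }
  if (n_samples == 0 && missing_rate > 0) {
    vardb_stop("missingness is undefined for an empty cohort", "vardb_spec_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- if (n_samples > 0) sprintf("s%03d", seq_len(n_samples)) else character(0)
  with_seed(seed, {
    p <- rbeta(n_variants, af_shape[1], af_shape[2])
    alleles <- t(vapply(seq_len(n_variants), function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2)))
    n_alt_mat <- matrix(0L, n_variants, max(n_samples, 1L))
    miss_mat <- matrix(FALSE, n_variants, max(n_samples, 1L))
    depth_mat <- matrix(-1L, n_variants, max(n_samples, 1L))
    if (n_samples > 0) {
      for (i in seq_len(n_variants)) {
        n_alt_mat[i, ] <- rbinom(n_samples, 2L, p[i])
        miss_mat[i, ] <- runif(n_samples) < missing_rate
        depth_mat[i, ] <- rpois(n_samples, 30L) + 1L
      }
    }
  })
  gts <- matrix("./.", n_variants, max(n_samples, 1L))
  gt_types <- matrix(gt_type_codes[["UNKNOWN"]], n_variants, max(n_samples, 1L))
  depths <- depth_mat
  if (n_samples > 0) {
    for (i in seq_len(n_variants)) {
      ref <- alleles[i, 1]; alt <- alleles[i, 2]
      g <- n_alt_mat[i, ]
      called <- !miss_mat[i, ]
      gts[i, called] <- c(paste0(ref, "/", ref), paste0(ref, "/", alt),
                          paste0(alt, "/", alt))[g[called] + 1L]
      gt_types[i, called] <- c(0L, 1L, 3L)[g[called] + 1L]
      depths[i, !called] <- -1L
    }
  }
  truth <- cohort_truth(p, gt_types, n_samples)
  pos <- 100L + 10L * (seq_len(n_variants) - 1L)
  fields <- if (n_samples > 0) {
    vapply(seq_len(n_variants), function(i) {
      paste(paste0(vcf_gt_token(gt_types[i, ], alleles[i, 1], alleles[i, 2]), ":",
                   ifelse(depths[i, ] < 0L, ".", depths[i, ])),
            collapse = "\t")
    }, character(1))
  } else NULL
  vcf_path <- file.path(dir, "cohort.vcf")
  write_fixture_vcf(vcf_path, samples,
                    chrom = "chr1", pos = pos,
                    ref = alleles[, 1], alt = alleles[, 2],
                    info = rep(".", n_variants),
                    sample_fields = fields)
  truth_path <- file.path(dir, "cohort_truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (n_samples == 0) {
    gts <- gts[, 0, drop = FALSE]; gt_types <- gt_types[, 0, drop = FALSE]
    depths <- depths[, 0, drop = FALSE]
  }
  list(vcf = vcf_path, truth_path = truth_path, samples = samples, truth = truth,
       gts = gts, gt_types = gt_types, depths = depths)
}

# independent straightforward implementations of the stored statistics
cohort_truth <- function(p, gt_types, n_samples) {
  n_variants <- nrow(gt_types)
  out <- data.frame(site = seq_len(n_variants), p_drawn = p)
  stat <- matrix(NA_real_, n_variants, 10)
  for (i in seq_len(n_variants)) {
    g <- if (n_samples > 0) gt_types[i, ] else integer(0)
    nrr <- sum(g == 0L); nra <- sum(g == 1L); naa <- sum(g == 3L); nu <- sum(g == 2L)
    s <- length(g); n <- nrr + nra + naa
    aaf <- if (n > 0) (nra + 2 * naa) / (2 * n) else NA_real_
    chi2 <- p_hwe <- f <- pi_ <- NA_real_
    if (n > 0) {
      ph <- (2 * nrr + nra) / (2 * n)
      if (ph == 0 || ph == 1) { chi2 <- 0; p_hwe <- 1 } else {
        e <- n * c(ph^2, 2 * ph * (1 - ph), (1 - ph)^2)
        o <- c(nrr, nra, naa)
        chi2 <- sum((o - e)^2 / e)
        p_hwe <- pchisq(chi2, 1, lower.tail = FALSE)
      }
      he <- if (n > 0) 2 * ((2 * nrr + nra) / (2 * n)) * (1 - (2 * nrr + nra) / (2 * n)) else 0
      f <- if (he > 0) 1 - (nra / n) / he else NA_real_
      m <- 2 * n; j <- nra + 2 * naa
      pi_ <- if (m >= 2) 2 * j * (m - j) / (m * (m - 1)) else NA_real_
    }
    stat[i, ] <- c(nrr, nra, naa, nu, if (s > 0) n / s else NA_real_, aaf,
                   chi2, p_hwe, f, pi_)
  }
  colnames(stat) <- c("num_hom_ref", "num_het", "num_hom_alt", "num_unknown",
                      "call_rate", "aaf", "hwe_chi2", "hwe", "inbreeding_coeff", "pi")
  cbind(out, as.data.frame(stat))
}

vcf_gt_token <- function(gt_types_row, ref, alt) {
  c("0/0", "0/1", "./.", "1/1")[gt_types_row + 1L]
}

write_fixture_vcf <- function(path, samples, chrom, pos, ref, alt, info,
                              sample_fields = NULL, extra_header = character(0),
                              qual = "100", filter = "PASS") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vardb_fixtures",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  n <- length(pos)
  body <- vapply(seq_len(n), function(i) {
    paste(c(if (length(chrom) == 1L) chrom else chrom[i], pos[i], ".", ref[i], alt[i],
            qual, filter, info[i],
            if (length(samples)) c("GT:DP", sample_fields[i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

#' Simulate a family study VCF + PED with planted inheritance events
#'
#' Two trio families are emitted: `fam1` (affected child `kid1`, unaffected
#' parents) and `fam2` (affected father `dad2` and child `kid2`, unaffected
#' mother). Background variants are transmitted by Mendelian sampling from
#' Hardy-Weinberg founder genotypes and are rejection-sampled so that no
#' background site matches any screened pattern; planted events are
#' constructed to satisfy exactly one pattern each:
#'
#' * `de_novo` (fam1): parents HOM_REF, child HET;
#' * `recessive` (fam1): parents HET, affected child HOM_ALT;
#' * `dominant` (fam2): affected father and child HET, unaffected mother
#'   HOM_REF;
#' * `comp_het_trans` (fam1): per event, two MED-impact HETs in one gene,
#'   one inherited from each parent (unphased);
#' * `comp_het_cis` decoys (fam1): two phased HETs in one gene on the same
#'   haplotype (also phased in the transmitting mother).
#'
#' Every variant carries an `ANN` annotation; background variants get
#' unique genes with a LOW consequence so only planted candidates can form
#' gene pairs.
#'
#' @param n_variants Total variant count (background + planted).
#' @param events Named list of planted-event counts.
#' @param af_shape Background allele-frequency Beta shape.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List: `vcf`, `ped`, `samples`, and `truth` — a list with the
#'   planted variant indices per pattern (`de_novo`, `recessive`,
#'   `dominant` integer vectors; `comp_het_trans`, `comp_het_cis`
#'   data.frames with `variant_a`, `variant_b`, `gene`).
#' @export
simulate_families <- function(n_variants = 1000L,
                              events = list(de_novo = 7L, recessive = 5L,
                                            dominant = 5L, comp_het_trans = 4L,
                                            comp_het_cis = 4L),
                              af_shape = c(0.5, 5), seed = 1L,
                              dir = tempfile("vardb_family_")) {
  n_event_sites <- events$de_novo + events$recessive + events$dominant +
    2L * events$comp_het_trans + 2L * events$comp_het_cis
  if (n_event_sites > n_variants) {
    vardb_stop("requested planted events exceed n_variants", "vardb_spec_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- c("dad1", "mom1", "kid1", "dad2", "mom2", "kid2")
  # genotype matrix in allele-count terms; -1 = placeholder
  gt <- matrix("0/0", n_variants, 6L, dimnames = list(NULL, samples))

  with_seed(seed, {
    site_ids <- sample(n_variants, n_event_sites)
    take <- function(k) {
      ids <- site_ids[seq_len(k)]
      site_ids <<- site_ids[-seq_len(k)]
      ids
    }
    dn_ids <- sort(take(events$de_novo))
    rec_ids <- sort(take(events$recessive))
    dom_ids <- sort(take(events$dominant))
    cht <- matrix(take(2L * events$comp_het_trans), ncol = 2L, byrow = TRUE)
    chc <- matrix(take(2L * events$comp_het_cis), ncol = 2L, byrow = TRUE)
    planted <- c(dn_ids, rec_ids, dom_ids, as.vector(cht), as.vector(chc))

    # background: Mendelian trios, rejection-sampled away from screened patterns
    for (i in setdiff(seq_len(n_variants), planted)) {
      p <- rbeta(1, af_shape[1], af_shape[2])
      gt[i, 1:3] <- draw_trio(p, reject = reject_recessive)
      gt[i, 4:6] <- draw_trio(p, reject = reject_dominant)
    }
    # planted configurations (the other family is fixed HOM_REF)
    gt[dn_ids, 1:3] <- matrix(c("0/0", "0/0", "0/1"), length(dn_ids), 3L, byrow = TRUE)
    gt[rec_ids, 1:3] <- matrix(c("0/1", "0/1", "1/1"), length(rec_ids), 3L, byrow = TRUE)
    gt[dom_ids, 4:6] <- matrix(c("0/1", "0/0", "0/1"), length(dom_ids), 3L, byrow = TRUE)
    for (r in seq_len(nrow(cht))) {
      gt[cht[r, 1], 1:3] <- c("0/0", "0/1", "0/1") # from mom
      gt[cht[r, 2], 1:3] <- c("0/1", "0/0", "0/1") # from dad
    }
    for (r in seq_len(nrow(chc))) {
      # phased, both child ALTs on the maternal haplotype (cis)
      gt[chc[r, 1], 1:3] <- c("0|0", "1|0", "0|1")
      gt[chc[r, 2], 1:3] <- c("0|0", "1|0", "0|1")
    }
    ref_alt <- t(vapply(seq_len(n_variants), function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2)))
    depths <- matrix(rpois(n_variants * 6L, 40L) + 5L, n_variants, 6L)
  })

  genes <- sprintf("BG%05d", seq_len(n_variants))
  cons <- rep("intron_variant", n_variants)
  impact <- rep("MODIFIER", n_variants)
  med_ids <- c(dn_ids, rec_ids, dom_ids)
  genes[med_ids] <- sprintf("EV%05d", med_ids)
  cons[med_ids] <- "missense_variant"; impact[med_ids] <- "MODERATE"
  cht_genes <- sprintf("GENE_CHT%d", seq_len(nrow(cht)))
  chc_genes <- sprintf("GENE_CHC%d", seq_len(nrow(chc)))
  for (r in seq_len(nrow(cht))) {
    genes[cht[r, ]] <- cht_genes[r]; cons[cht[r, ]] <- "missense_variant"
    impact[cht[r, ]] <- "MODERATE"
  }
  for (r in seq_len(nrow(chc))) {
    genes[chc[r, ]] <- chc_genes[r]; cons[chc[r, ]] <- "missense_variant"
    impact[chc[r, ]] <- "MODERATE"
  }
  info <- sprintf("ANN=%s|%s|%s|%s|%s|transcript|TX%05d|protein_coding|1/1|c.1A>G|p.K1E",
                  ref_alt[, 2], cons, impact, genes, genes, seq_len(n_variants))

  pos <- 1000L + 10L * (seq_len(n_variants) - 1L)
  fields <- vapply(seq_len(n_variants), function(i) {
    paste(paste0(gt[i, ], ":", depths[i, ]), collapse = "\t")
  }, character(1))
  vcf_path <- write_fixture_vcf(file.path(dir, "families.vcf"), samples,
                                chrom = "chr1", pos = pos,
                                ref = ref_alt[, 1], alt = ref_alt[, 2], info = info,
                                sample_fields = fields)
  ped_path <- file.path(dir, "families.ped")
  writeLines(c("fam1 dad1 0 0 1 1",
               "fam1 mom1 0 0 2 1",
               "fam1 kid1 dad1 mom1 1 2",
               "fam2 dad2 0 0 1 2",
               "fam2 mom2 0 0 2 1",
               "fam2 kid2 dad2 mom2 1 2"), ped_path)
  truth <- list(
    de_novo = dn_ids, recessive = rec_ids, dominant = dom_ids,
    comp_het_trans = data.frame(variant_a = pmin(cht[, 1], cht[, 2]),
                                variant_b = pmax(cht[, 1], cht[, 2]),
                                gene = cht_genes, stringsAsFactors = FALSE),
    comp_het_cis = data.frame(variant_a = pmin(chc[, 1], chc[, 2]),
                              variant_b = pmax(chc[, 1], chc[, 2]),
                              gene = chc_genes, stringsAsFactors = FALSE)
  )
  truth_path <- file.path(dir, "families_truth.tsv")
  truth_rows <- rbind(
    data.frame(pattern = "de_novo", variant_a = dn_ids, variant_b = NA_integer_,
               gene = genes[dn_ids]),
    data.frame(pattern = "recessive", variant_a = rec_ids, variant_b = NA_integer_,
               gene = genes[rec_ids]),
    data.frame(pattern = "dominant", variant_a = dom_ids, variant_b = NA_integer_,
               gene = genes[dom_ids]),
    data.frame(pattern = "comp_het_trans", variant_a = truth$comp_het_trans$variant_a,
               variant_b = truth$comp_het_trans$variant_b, gene = cht_genes),
    data.frame(pattern = "comp_het_cis", variant_a = truth$comp_het_cis$variant_a,
               variant_b = truth$comp_het_cis$variant_b, gene = chc_genes)
  )
  write.table(truth_rows, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = vcf_path, ped = ped_path, truth_path = truth_path,
       samples = samples, truth = truth, genes = genes, gt = gt)
}

# draw (dad, mom, kid) allele-count genotypes Mendelian-consistently at
# HWE(p); re-draw while the rejection predicate matches a screened pattern
draw_trio <- function(p, reject) {
  repeat {
    dad <- rbinom(1L, 2L, p); mom <- rbinom(1L, 2L, p)
    kid <- sample_allele(dad) + sample_allele(mom)
    cfg <- c(dad, mom, kid)
    if (!reject(cfg)) {
      return(c("0/0", "0/1", "1/1")[cfg + 1L])
    }
  }
}

sample_allele <- function(g) {
  if (g == 0L) 0L else if (g == 2L) 1L else sample(0:1, 1L)
}

reject_recessive <- function(cfg) cfg[1] == 1L && cfg[2] == 1L && cfg[3] == 2L
reject_dominant <- function(cfg) cfg[1] == 1L && cfg[2] == 0L && cfg[3] == 1L

gt_letters <- function(gt_row, ref, alt) {
  vapply(gt_row, function(g) {
    sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
    al <- strsplit(g, "[/|]")[[1]]
    paste(ifelse(al == "1", alt, ref), collapse = sep)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate annotation tracks with known overlaps
#'
#' Emits a BED track (boolean semantics), a GFF3 track (extract semantics,
#' `Name` attribute) and a sites-only VCF track covering a random subset of
#' the given variants, plus decoy intervals overlapping nothing.
#'
#' @param variants data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. built from a simulated VCF.
#' @param overlap_fraction Probability that each variant is covered.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List: `bed`, `gff`, `vcf` (paths) and `truth` — data.frame with
#'   `variant` (row index), `in_bed` (0/1), `gff_value` (the Name of the
#'   covering interval or NA), `in_vcf` (0/1).
#' @export
make_tracks <- function(variants, overlap_fraction, seed = 1L,
                        dir = tempfile("vardb_tracks_")) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    vardb_stop("overlap_fraction must be in [0, 1]", "vardb_spec_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(variants)
  with_seed(seed, {
    covered <- runif(n) < overlap_fraction
  })
  idx <- which(covered)
  bed_path <- file.path(dir, "track.bed")
  gff_path <- file.path(dir, "track.gff")
  vcf_path <- file.path(dir, "sites.vcf")
  # covering intervals hug each chosen variant; decoys sit in the gaps
  bed_lines <- c(
    sprintf("%s\t%d\t%d\tiv%d\t%d", variants$chrom[idx],
            pmax(variants$start[idx] - 1L, 0L), variants$end[idx] + 1L,
            idx, idx),
    sprintf("%s\t%d\t%d\tdecoy%d\t0", variants$chrom, variants$end + 4L,
            variants$end + 6L, seq_len(n))
  )
  writeLines(bed_lines, bed_path)
  gff_lines <- c("##gff-version 3",
                 sprintf("%s\tvardb\tregion\t%d\t%d\t.\t+\t.\tID=region%d;Name=VAL_%d",
                         variants$chrom[idx], pmax(variants$start[idx], 0L) + 1L,
                         variants$end[idx], idx, idx))
  writeLines(gff_lines, gff_path)
  site_ref <- if ("ref" %in% names(variants)) variants$ref[idx] else rep("A", length(idx))
  site_alt <- if ("alt" %in% names(variants)) variants$alt[idx] else rep("G", length(idx))
  write_fixture_vcf(vcf_path, character(0), chrom = variants$chrom[idx],
                    pos = variants$start[idx] + 1L, ref = site_ref, alt = site_alt,
                    info = rep("DB", length(idx)))
  truth <- data.frame(variant = seq_len(n),
                      in_bed = as.integer(covered),
                      gff_value = ifelse(covered, sprintf("VAL_%d", seq_len(n)), NA_character_),
                      in_vcf = as.integer(covered),
                      stringsAsFactors = FALSE)
  list(bed = bed_path, gff = gff_path, vcf = vcf_path, truth = truth)
}
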