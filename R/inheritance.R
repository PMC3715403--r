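# Family-based screens: de novo, autosomal recessive, autosomal dominant,
# compound heterozygotes.
#
# Shared rules: X/Y chromosomes are excluded from all screens; any variant
# with an uncalled genotype among the family members being tested is
# skipped, never guessed. Every hit records the supporting genotypes so
# the pattern can be re-derived.

AUTOSOME_EXCLUDE <- c("X", "Y", "chrX", "chrY")

# complete trios: child rows whose two parental ids resolve to loaded samples
find_trios <- function(session) {
  s <- session$samples
  kids <- which(!is.na(s$paternal_id) & !is.na(s$maternal_id) &
                  s$paternal_id %in% s$name & s$maternal_id %in% s$name)
  lapply(kids, function(i) {
    list(family_id = s$family_id[i],
         child = s$name[i],
         father = s$paternal_id[i],
         mother = s$maternal_id[i],
         child_affected = identical(s$phenotype[i], "affected"),
         father_affected = identical(s$phenotype[match(s$paternal_id[i], s$name)], "affected"),
         mother_affected = identical(s$phenotype[match(s$maternal_id[i], s$name)], "affected"))
  })
}

autosomal_rows <- function(session) {
  rows <- fetch_variants(session)
  rows[!rows$chrom %in% AUTOSOME_EXCLUDE, , drop = FALSE]
}

hit_frame <- function() {
  data.frame(variant_id = integer(0), family_id = character(0), chrom = character(0),
             start = integer(0), ref = character(0), alt = character(0),
             gene = character(0), sample = character(0),
             gt_child = character(0), gt_father = character(0), gt_mother = character(0),
             stringsAsFactors = FALSE)
}

trio_hit <- function(row, trio, idx) {
  data.frame(variant_id = row$variant_id, family_id = trio$family_id,
             chrom = row$chrom, start = row$start, ref = row$ref, alt = row$alt,
             gene = if (is.na(row$gene)) NA_character_ else row$gene,
             sample = trio$child,
             gt_child = row$gts[[1]][idx["child"]],
             gt_father = row$gts[[1]][idx["father"]],
             gt_mother = row$gts[[1]][idx["mother"]],
             stringsAsFactors = FALSE)
}

require_trios <- function(session, predicate = function(t) TRUE, what = "complete trio") {
  trios <- Filter(predicate, find_trios(session))
  if (length(trios) == 0L) {
    vardb_stop(sprintf("no %s found in the samples table; load a PED describing the family structure",
                       what), "vardb_no_trios_error")
  }
  trios
}

#' Find candidate de novo mutations
#'
#' A hit is a variant where, within one complete trio, both parents are
#' HOM_REF, the child is HET, and all three genotypes are called. With
#' `min_depth > 0` all three sequencing depths must also reach `min_depth`
#' (missing depth, stored as -1, never qualifies); `min_depth = 0` applies
#' no depth requirement. By default the reversion configuration (parents
#' HOM_ALT, child HET) is excluded; `include_reversions = TRUE` admits it.
#'
#' @param session A `vardb_session` (or database path).
#' @param min_depth Minimum depth for all three family members.
#' @param include_reversions Also report parents-HOM_ALT/child-HET sites.
#' @return data.frame of hits, one row per (variant, trio).
#' @export
find_de_novo <- function(session, min_depth = 0L, include_reversions = FALSE) {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  trios <- require_trios(session)
  rows <- autosomal_rows(session)
  hits <- list()
  code <- gt_type_codes
  for (trio in trios) {
    idx <- c(child = session$sample_index[[trio$child]],
             father = session$sample_index[[trio$father]],
             mother = session$sample_index[[trio$mother]])
    for (i in seq_len(nrow(rows))) {
      gt <- rows$gt_types[[i]][idx]
      if (any(gt == code[["UNKNOWN"]])) next
      child_het <- gt[1] == code[["HET"]]
      denovo <- child_het && gt[2] == code[["HOM_REF"]] && gt[3] == code[["HOM_REF"]]
      reversion <- child_het && gt[2] == code[["HOM_ALT"]] && gt[3] == code[["HOM_ALT"]]
      if (!(denovo || (include_reversions && reversion))) next
      if (min_depth > 0L) {
        dp <- rows$gt_depths[[i]][idx]
        if (any(dp < min_depth)) next
      }
      hits[[length(hits) + 1L]] <- trio_hit(rows[i, ], trio, idx)
    }
  }
  if (length(hits) == 0L) return(hit_frame())
  do.call(rbind, hits)
}

#' Find variants matching autosomal recessive inheritance
#'
#' Within trios having an affected child and two unaffected parents: the
#' child is HOM_ALT and both parents are HET (all called).
#'
#' @inheritParams find_de_novo
#' @export
find_autosomal_recessive <- function(session) {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  trios <- require_trios(session,
                         function(t) t$child_affected && !t$father_affected && !t$mother_affected,
                         "trio with an affected child and unaffected parents")
  rows <- autosomal_rows(session)
  code <- gt_type_codes
  hits <- list()
  for (trio in trios) {
    idx <- c(child = session$sample_index[[trio$child]],
             father = session$sample_index[[trio$father]],
             mother = session$sample_index[[trio$mother]])
    for (i in seq_len(nrow(rows))) {
      gt <- rows$gt_types[[i]][idx]
      if (any(gt == code[["UNKNOWN"]])) next
      if (gt[1] == code[["HOM_ALT"]] && gt[2] == code[["HET"]] && gt[3] == code[["HET"]]) {
        hits[[length(hits) + 1L]] <- trio_hit(rows[i, ], trio, idx)
      }
    }
  }
  if (length(hits) == 0L) return(hit_frame())
  do.call(rbind, hits)
}

#' Find variants matching autosomal dominant inheritance
#'
#' Per family with at least one affected and one unaffected genotyped
#' member: every affected member is HET, every unaffected member is
#' HOM_REF (unless `allow_unaffected_carriers`), and every affected member
#' whose parents are genotyped has at least one affected parent (the
#' transmission requirement; founders are exempt). Variants with any
#' uncalled genotype among the family are skipped.
#'
#' @inheritParams find_de_novo
#' @param allow_unaffected_carriers Do not disqualify a variant when an
#'   unaffected member carries it (reduced-penetrance screening).
#' @return data.frame of hits, one row per (variant, family), with the
#'   affected carriers listed in `sample`.
#' @export
find_autosomal_dominant <- function(session, allow_unaffected_carriers = FALSE) {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  s <- session$samples
  fams <- split(seq_len(nrow(s)), s$family_id)
  fams <- Filter(function(ix) {
    any(s$phenotype[ix] == "affected", na.rm = TRUE) &&
      any(s$phenotype[ix] == "unaffected", na.rm = TRUE)
  }, fams)
  if (length(fams) == 0L) {
    vardb_stop("no family with both affected and unaffected genotyped members",
               "vardb_no_trios_error")
  }
  rows <- autosomal_rows(session)
  code <- gt_type_codes
  hits <- list()
  for (fam_name in names(fams)) {
    ix <- fams[[fam_name]]
    aff <- ix[s$phenotype[ix] == "affected"]
    unaff <- ix[s$phenotype[ix] == "unaffected"]
    arr <- stats::setNames(s$sample_idx[ix], s$name[ix])
    for (i in seq_len(nrow(rows))) {
      gt <- rows$gt_types[[i]]
      fam_gt <- gt[s$sample_idx[ix]]
      if (any(fam_gt == code[["UNKNOWN"]])) next
      if (!all(gt[s$sample_idx[aff]] == code[["HET"]])) next
      if (!allow_unaffected_carriers &&
          !all(gt[s$sample_idx[unaff]] == code[["HOM_REF"]])) next
      # transmission: each affected with genotyped parents needs an affected parent
      ok <- TRUE
      for (a in aff) {
        parents <- c(s$paternal_id[a], s$maternal_id[a])
        parents <- parents[!is.na(parents) & parents %in% s$name[ix]]
        if (length(parents) == 0L) next
        if (!any(s$phenotype[match(parents, s$name)] == "affected")) { ok <- FALSE; break }
      }
      if (!ok) next
      row <- rows[i, ]
      hits[[length(hits) + 1L]] <- data.frame(
        variant_id = row$variant_id, family_id = fam_name,
        chrom = row$chrom, start = row$start, ref = row$ref, alt = row$alt,
        gene = if (is.na(row$gene)) NA_character_ else row$gene,
        sample = paste(s$name[aff], collapse = ","),
        gt_child = NA_character_, gt_father = NA_character_, gt_mother = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(hit_frame())
  do.call(rbind, hits)
}

#' Find putative compound-heterozygote variant pairs
#'
#' For each sample and gene: pairs of distinct variants at which the
#' sample is HET. Candidate variants default to primary impact severity
#' HIGH or MED. Evidence is used in this order:
#' * both genotypes phased: require the alternate alleles on opposite
#'   haplotypes (pairs in cis are dropped);
#' * both parents genotyped and called at both sites: require opposite
#'   parental origin — at each site exactly one parent is HET, and the two
#'   sites implicate different parents;
#' * otherwise the pair is reported with `priority = "unphased"` as a
#'   putative candidate.
#'
#' @inheritParams find_de_novo
#' @param min_severity `"HIGH"`, `"MED"` or `"LOW"`: minimum primary-impact
#'   severity for candidate variants.
#' @return data.frame with one row per (sample, gene, variant pair).
#' @export
find_comp_hets <- function(session, min_severity = "MED") {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  n_imp <- DBI::dbGetQuery(session$con, "SELECT count(*) AS n FROM variant_impacts")$n
  if (n_imp == 0L) {
    vardb_stop(paste("no transcript impacts in this database; compound-heterozygote",
                     "screening needs gene assignments (load a VCF with snpEff/VEP annotations)"),
               "vardb_no_impacts_error")
  }
  min_rank <- severity_rank(min_severity)
  rows <- autosomal_rows(session)
  rows <- rows[which(!is.na(rows$gene) & !is.na(rows$impact_severity) &
                       severity_rank(rows$impact_severity) >= min_rank), , drop = FALSE]
  s <- session$samples
  code <- gt_type_codes
  out <- list()
  for (si in seq_len(nrow(s))) {
    me <- s$sample_idx[si]
    dad <- if (!is.na(s$paternal_id[si])) s$sample_idx[match(s$paternal_id[si], s$name)] else NA
    mom <- if (!is.na(s$maternal_id[si])) s$sample_idx[match(s$maternal_id[si], s$name)] else NA
    het_rows <- which(vapply(rows$gt_types, function(g) g[me] == code[["HET"]], logical(1)))
    if (length(het_rows) < 2L) next
    for (g in unique(rows$gene[het_rows])) {
      in_gene <- het_rows[rows$gene[het_rows] == g]
      if (length(in_gene) < 2L) next
      prs <- combn(in_gene, 2L)
      for (pi_ in seq_len(ncol(prs))) {
        ia <- prs[1, pi_]; ib <- prs[2, pi_]
        cls <- classify_pair(rows, ia, ib, me, dad, mom, code)
        if (is.null(cls)) next
        out[[length(out) + 1L]] <- data.frame(
          sample = s$name[si], family_id = s$family_id[si] %||% NA_character_,
          gene = g,
          variant_id_a = rows$variant_id[ia], variant_id_b = rows$variant_id[ib],
          gt_a = rows$gts[[ia]][me], gt_b = rows$gts[[ib]][me],
          priority = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(0), family_id = character(0), gene = character(0),
                      variant_id_a = integer(0), variant_id_b = integer(0),
                      gt_a = character(0), gt_b = character(0), priority = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# NULL = rejected; otherwise a priority label
classify_pair <- function(rows, ia, ib, me, dad, mom, code) {
  phased_a <- rows$gt_phases[[ia]][me]
  phased_b <- rows$gt_phases[[ib]][me]
  if (phased_a && phased_b) {
    side_a <- alt_haplotype_side(rows$gts[[ia]][me], rows$alt[ia])
    side_b <- alt_haplotype_side(rows$gts[[ib]][me], rows$alt[ib])
    if (!is.na(side_a) && !is.na(side_b)) {
      return(if (side_a != side_b) "phased_trans" else NULL)
    }
  }
  if (!is.na(dad) && !is.na(mom)) {
    pa <- parental_origin(rows$gt_types[[ia]], dad, mom, code)
    pb <- parental_origin(rows$gt_types[[ib]], dad, mom, code)
    if (!is.na(pa) && !is.na(pb)) {
      return(if (pa != pb) "parental_trans" else NULL)
    }
    return(NULL) # parents available but origin ambiguous/uncalled
  }
  "unphased"
}

# which haplotype (1 or 2) carries the alternate allele of a phased HET
alt_haplotype_side <- function(gts, alt) {
  al <- strsplit(gts, "|", fixed = TRUE)[[1]]
  if (length(al) != 2L) return(NA_integer_)
  if (al[1] == alt && al[2] != alt) return(1L)
  if (al[2] == alt && al[1] != alt) return(2L)
  NA_integer_
}

# "father"/"mother" when exactly one parent is HET (and the other HOM_REF),
# NA otherwise
parental_origin <- function(gt_types, dad, mom, code) {
  gd <- gt_types[dad]; gm <- gt_types[mom]
  if (gd == code[["UNKNOWN"]] || gm == code[["UNKNOWN"]]) return(NA_character_)
  dad_het <- gd == code[["HET"]]
  mom_het <- gm == code[["HET"]]
  if (dad_het && !mom_het) return("father")
  if (mom_het && !dad_het) return("mother")
  NA_character_
}
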