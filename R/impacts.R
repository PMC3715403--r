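# Standardization of transcript-consequence annotations produced upstream
# by snpEff (ANN or legacy EFF) or VEP (CSQ).
#
# All three encodings are mapped to one controlled vocabulary (Sequence
# Ontology terms) and one fixed three-level severity scale. Severity is
# assigned from the term itself via the tables below, never copied from the
# annotator's own impact field, so snpEff- and VEP-annotated loads are
# directly comparable.

#' Consequence severity vocabulary
#'
#' Fixed term sets defining the `impact_severity` scale and the `is_lof`
#' flag. `HIGH` and `MED` are explicit sets; every other term is `LOW`.
#' `is_lof` terms are the classic loss-of-function classes (stop gain,
#' frameshift, essential splice); `is_lof` implies `HIGH`.
#'
#' @format Named list of character vectors: `HIGH`, `MED`, `LOF`.
#' @export
severity_terms <- list(
  HIGH = c("stop_gained", "stop_lost", "start_lost", "frameshift_variant",
           "splice_acceptor_variant", "splice_donor_variant", "transcript_ablation"),
  MED = c("missense_variant", "inframe_insertion", "inframe_deletion",
          "splice_region_variant", "protein_altering_variant"),
  LOF = c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
          "splice_donor_variant")
)

# snpEff legacy EFF effect names -> Sequence Ontology terms
eff_synonyms <- c(
  STOP_GAINED = "stop_gained", STOP_LOST = "stop_lost", START_LOST = "start_lost",
  FRAME_SHIFT = "frameshift_variant",
  SPLICE_SITE_ACCEPTOR = "splice_acceptor_variant",
  SPLICE_SITE_DONOR = "splice_donor_variant",
  SPLICE_SITE_REGION = "splice_region_variant",
  NON_SYNONYMOUS_CODING = "missense_variant",
  SYNONYMOUS_CODING = "synonymous_variant",
  CODON_INSERTION = "inframe_insertion",
  CODON_DELETION = "inframe_deletion",
  CODON_CHANGE_PLUS_CODON_INSERTION = "inframe_insertion",
  CODON_CHANGE_PLUS_CODON_DELETION = "inframe_deletion",
  START_GAINED = "5_prime_UTR_premature_start_codon_gain_variant",
  UTR_5_PRIME = "5_prime_UTR_variant", UTR_3_PRIME = "3_prime_UTR_variant",
  INTRON = "intron_variant", INTERGENIC = "intergenic_variant",
  INTRAGENIC = "intragenic_variant",
  UPSTREAM = "upstream_gene_variant", DOWNSTREAM = "downstream_gene_variant",
  EXON = "non_coding_transcript_exon_variant",
  TRANSCRIPT = "transcript_variant", GENE = "gene_variant"
)

normalize_consequence <- function(term) {
  term <- trimws(term)
  mapped <- unname(eff_synonyms[term])
  unname(ifelse(is.na(mapped), tolower(term), mapped))
}

consequence_severity <- function(term) {
  ifelse(term %in% severity_terms$HIGH, "HIGH",
         ifelse(term %in% severity_terms$MED, "MED", "LOW"))
}

severity_rank <- function(sev) c(LOW = 1L, MED = 2L, HIGH = 3L)[sev]

#' Parse transcript-consequence annotations from a variant's INFO field
#'
#' Reads whichever of the snpEff `ANN`, legacy snpEff `EFF`, or VEP `CSQ`
#' keys is present (or the one named by `source`) and returns one row per
#' transcript block, with the consequence term normalized to the shared
#' vocabulary and severity assigned from [severity_terms]. Malformed blocks
#' are skipped with a warning naming the variant; parsing never aborts a
#' load. Exactly one row is flagged `is_primary` (see
#' [pick_primary_impact()]).
#'
#' @param site A variant record from [read_vcf()].
#' @param source `"auto"` (default), `"ANN"`, `"EFF"` or `"CSQ"`.
#' @param csq_fields CSQ field names from the VCF header (required for CSQ).
#' @return data.frame with columns `variant_id`, `gene`, `transcript`,
#'   `consequence`, `impact_severity`, `is_lof`, `aa_change`, `is_primary`;
#'   zero rows when no consequence field is present.
#' @export
parse_impacts <- function(site, source = "auto", csq_fields = NULL) {
  keys <- intersect(c("ANN", "EFF", "CSQ"), names(site$info))
  if (source == "auto") {
    if (length(keys) > 1L) {
      vardb_stop(sprintf(
        "variant %d carries multiple consequence sources (%s); pass impact_source to choose one",
        site$variant_id, paste(keys, collapse = ", ")), "vardb_validation_error")
    }
    source <- if (length(keys)) keys else return(empty_impacts())
  }
  raw <- site$info[[source]]
  if (is.null(raw) || isTRUE(raw)) return(empty_impacts())
  blocks <- strsplit(raw, ",", fixed = TRUE)[[1]]
  rows <- lapply(blocks, function(b) {
    tryCatch(
      switch(source,
             ANN = parse_ann_block(b),
             EFF = parse_eff_block(b),
             CSQ = parse_csq_block(b, csq_fields)),
      error = function(e) {
        vardb_warn(sprintf("variant %d: skipping malformed %s block '%s'",
                           site$variant_id, source, b))
        NULL
      })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_impacts())
  out <- do.call(rbind, rows)
  out$variant_id <- site$variant_id
  out$impact_severity <- consequence_severity(out$consequence)
  out$is_lof <- out$consequence %in% severity_terms$LOF
  out$is_primary <- FALSE
  out <- out[, c("variant_id", "gene", "transcript", "consequence",
                 "impact_severity", "is_lof", "aa_change", "is_primary")]
  primary <- pick_primary_impact(out, mark_only = TRUE)
  primary
}

empty_impacts <- function() {
  data.frame(variant_id = integer(0), gene = character(0), transcript = character(0),
             consequence = character(0), impact_severity = character(0),
             is_lof = logical(0), aa_change = character(0), is_primary = logical(0),
             stringsAsFactors = FALSE)
}

# ANN: Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|
#      Biotype|Rank|HGVS.c|HGVS.p|...
parse_ann_block <- function(b) {
  f <- strsplit(b, "|", fixed = TRUE)[[1]]
  if (length(f) < 4L || !nzchar(f[2])) stop("too few ANN fields")
  term <- normalize_consequence(strsplit(f[2], "&", fixed = TRUE)[[1]])
  term <- term[which.max(severity_rank(consequence_severity(term)))]
  data.frame(gene = f[4], transcript = if (length(f) >= 7L && nzchar(f[7])) f[7] else "",
             consequence = term,
             aa_change = if (length(f) >= 11L && nzchar(f[11])) f[11] else NA_character_,
             stringsAsFactors = FALSE)
}

# EFF: Effect(Impact|Functional_Class|Codon_Change|AA_Change|AA_len|Gene|
#      Biotype|Coding|Transcript|...)
parse_eff_block <- function(b) {
  m <- regmatches(b, regexec("^([^()]+)\\((.*)\\)$", b))[[1]]
  if (length(m) != 3L) stop("EFF block not Effect(...)")
  f <- strsplit(m[3], "|", fixed = TRUE)[[1]]
  if (length(f) < 6L) stop("too few EFF fields")
  data.frame(gene = f[6],
             transcript = if (length(f) >= 9L && nzchar(f[9])) f[9] else "",
             consequence = normalize_consequence(m[2]),
             aa_change = if (nzchar(f[4])) f[4] else NA_character_,
             stringsAsFactors = FALSE)
}

parse_csq_block <- function(b, csq_fields) {
  if (is.null(csq_fields)) stop("CSQ field order unknown (no header description)")
  f <- strsplit(b, "|", fixed = TRUE)[[1]]
  val <- function(key) {
    i <- match(key, csq_fields)
    if (is.na(i) || i > length(f) || !nzchar(f[i])) NA_character_ else f[i]
  }
  cons <- val("Consequence")
  if (is.na(cons)) stop("CSQ block lacks Consequence")
  term <- normalize_consequence(strsplit(cons, "&", fixed = TRUE)[[1]])
  term <- term[which.max(severity_rank(consequence_severity(term)))]
  gene <- val("SYMBOL") %||% NA_character_
  if (is.na(gene)) gene <- val("Gene")
  data.frame(gene = if (is.na(gene)) "" else gene,
             transcript = if (is.na(val("Feature"))) "" else val("Feature"),
             consequence = term,
             aa_change = val("Amino_acids"),
             stringsAsFactors = FALSE)
}

#' Pick the primary impact among a variant's transcript impacts
#'
#' The primary impact is the one with the highest severity; ties are broken
#' by the lexicographically smallest transcript id, then by input order.
#'
#' @param impacts data.frame as returned by [parse_impacts()] (one variant).
#' @param mark_only If TRUE return the full data.frame with `is_primary`
#'   set on exactly one row; otherwise return just the primary row.
#' @export
pick_primary_impact <- function(impacts, mark_only = FALSE) {
  if (is.null(impacts) || nrow(impacts) == 0L) {
    vardb_stop("cannot pick a primary impact from an empty impact list",
               "vardb_not_found_error")
  }
  if (length(unique(impacts$variant_id)) > 1L) {
    vardb_stop("impacts spanning multiple variants", "vardb_validation_error")
  }
  ord <- order(-severity_rank(impacts$impact_severity), impacts$transcript,
               seq_len(nrow(impacts)))
  impacts$is_primary <- FALSE
  impacts$is_primary[ord[1]] <- TRUE
  if (mark_only) impacts else impacts[ord[1], , drop = FALSE]
}
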