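# VCF reading.
#
# Coordinates are converted from the 1-based inclusive POS of VCF to the
# 0-based half-open [start, end) convention used throughout the package
# (end = start + nchar(ref)). Multi-allelic sites are split at read time
# into one record per ALT allele; sample genotypes are recoded relative to
# that allele and any genotype carrying a different ALT becomes uncalled
# for the split record, which keeps the one-row-per-variant data model
# well defined.

#' Read a VCF file
#'
#' Parses a VCF v4.x file (plain or gzip/bgzip-compressed) into a list of
#' biallelic variant records plus the raw per-sample genotype fields. One
#' record is produced per (line, ALT allele) pair; `variant_id` is assigned
#' sequentially in post-split file order.
#'
#' @param path Path to the VCF file.
#' @return List with:
#'   * `samples`: sample names in header order;
#'   * `records`: list of records, each a list with `variant_id`, `chrom`,
#'     `start` (0-based), `end` (exclusive), `ref`, `alt`, `quality`,
#'     `filter`, `type` (`snp`/`indel`/`sv`), `sub_type`, `info` (named
#'     list), `gt` (recoded per-sample genotype: `letters`, `types`,
#'     `phases`, `depths`), and `line` (source line number);
#'   * `csq_fields`: VEP CSQ field names from the header, or NULL.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    vardb_stop(sprintf("VCF file not found: %s", path), "vardb_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (length(header_idx) == 0L) {
    vardb_stop(sprintf("%s: no #CHROM header line; not a VCF", path),
               "vardb_format_error")
  }
  header_idx <- header_idx[1]
  meta <- lines[seq_len(header_idx - 1L)]
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  if (length(header) < 8L) {
    vardb_stop(sprintf("%s: #CHROM header has %d columns; at least 8 required",
                       path, length(header)), "vardb_format_error")
  }
  samples <- if (length(header) > 9L) header[10:length(header)] else character(0)
  csq_fields <- parse_csq_header(meta)

  body <- lines[-seq_len(header_idx)]
  body_lineno <- header_idx + seq_along(body)
  keep <- nzchar(body) & !startsWith(body, "#")
  body <- body[keep]; body_lineno <- body_lineno[keep]

  n_cols_expected <- if (length(samples)) 9L + length(samples) else length(header)
  records <- vector("list", 2L * length(body))
  n_rec <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || length(f) != n_cols_expected) {
      vardb_stop(sprintf("%s line %d: expected %d tab-separated fields, found %d",
                         path, body_lineno[i], n_cols_expected, length(f)),
                 "vardb_parse_error")
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      vardb_stop(sprintf("%s line %d: POS '%s' is not a positive integer",
                         path, body_lineno[i], f[2]), "vardb_parse_error")
    }
    ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    if (!nzchar(ref) || length(alts) == 0L || !all(nzchar(alts))) {
      vardb_stop(sprintf("%s line %d: empty REF or ALT", path, body_lineno[i]),
                 "vardb_parse_error")
    }
    info <- parse_info(f[8])
    qual <- if (f[6] %in% c(".", "")) NA_real_ else suppressWarnings(as.numeric(f[6]))
    filt <- if (f[7] %in% c(".", "")) NA_character_ else f[7]
    fmt <- if (length(f) >= 9L) strsplit(f[9], ":", fixed = TRUE)[[1]] else character(0)
    sample_fields <- if (length(samples)) f[10:length(f)] else character(0)
    gt_raw <- extract_format_field(sample_fields, fmt, "GT", ".")
    dp_raw <- extract_format_field(sample_fields, fmt, "DP", ".")

    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (identical(alt, ref)) {
        vardb_stop(sprintf("%s line %d: ALT equals REF", path, body_lineno[i]),
                   "vardb_parse_error")
      }
      ty <- classify_variant(ref, alt)
      n_rec <- n_rec + 1L
      records[[n_rec]] <- list(
        variant_id = n_rec,
        chrom = f[1], start = pos - 1L, end = pos - 1L + nchar(ref),
        ref = ref, alt = alt,
        quality = qual, filter = filt,
        type = ty$type, sub_type = ty$sub_type,
        info = info,
        gt = recode_genotypes(gt_raw, dp_raw, ref, alt, k, length(alts)),
        line = body_lineno[i]
      )
    }
  }
  list(samples = samples, records = records[seq_len(n_rec)],
       csq_fields = csq_fields)
}

parse_csq_header <- function(meta) {
  csq <- grep("^##INFO=<ID=CSQ[,>]", meta, value = TRUE)
  if (length(csq) == 0L) return(NULL)
  m <- regmatches(csq[1], regexpr("Format: [^\">]+", csq[1]))
  if (length(m) == 0L) return(NULL)
  strsplit(sub("^Format: ", "", m), "|", fixed = TRUE)[[1]]
}

parse_info <- function(info_field) {
  if (info_field %in% c(".", "")) return(list())
  parts <- strsplit(info_field, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) out[[p]] <- TRUE else {
      out[[substr(p, 1L, eq - 1L)]] <- substr(p, eq + 1L, nchar(p))
    }
  }
  out
}

extract_format_field <- function(sample_fields, fmt, key, missing) {
  idx <- match(key, fmt)
  if (is.na(idx) || length(sample_fields) == 0L) {
    return(rep(missing, length(sample_fields)))
  }
  vapply(strsplit(sample_fields, ":", fixed = TRUE), function(p) {
    if (length(p) >= idx) p[idx] else missing
  }, character(1))
}

classify_variant <- function(ref, alt) {
  if (grepl("^<.*>$", alt) || grepl("\\[|\\]", alt)) {
    return(list(type = "sv", sub_type = gsub("[<>]", "", alt)))
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    transitions <- c(A = "G", G = "A", C = "T", T = "C")
    sub <- if (!is.na(transitions[ref]) && transitions[ref] == alt) "ts" else "tv"
    return(list(type = "snp", sub_type = sub))
  }
  if (nr == na) return(list(type = "snp", sub_type = "mnp"))
  list(type = "indel", sub_type = if (na > nr) "ins" else "del")
}

# Recode raw GT strings relative to ALT allele k of a site with n_alt ALTs.
# Alleles: 0 stays REF, k becomes the (single) ALT; any other called allele
# makes the genotype uncalled for this split record.
recode_genotypes <- function(gt_raw, dp_raw, ref, alt, k, n_alt) {
  s <- length(gt_raw)
  letters <- character(s); types <- integer(s)
  phases <- logical(s)
  depths <- suppressWarnings(as.integer(dp_raw))
  depths[is.na(depths)] <- -1L
  for (i in seq_len(s)) {
    p <- parse_gt_alleles(gt_raw[i], n_alt = n_alt)
    al <- p$alleles
    if (anyNA(al) || any(!al %in% c(0L, k))) {
      letters[i] <- "./."
      types[i] <- gt_type_codes[["UNKNOWN"]]
      phases[i] <- FALSE
      next
    }
    al01 <- as.integer(al == k)
    base <- c(ref, alt)[al01 + 1L]
    sep <- if (p$phased) "|" else "/"
    letters[i] <- paste(base, collapse = sep)
    types[i] <- if (all(al01 == 0L)) gt_type_codes[["HOM_REF"]]
      else if (all(al01 == 1L)) gt_type_codes[["HOM_ALT"]]
      else gt_type_codes[["HET"]]
    phases[i] <- p$phased
  }
  list(letters = letters, types = types, phases = phases, depths = depths)
}
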