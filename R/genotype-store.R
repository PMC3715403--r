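# Packed per-variant genotype arrays.
#
# For each variant the four sample-wise arrays (genotype string, genotype
# type code, phase flag, read depth) are serialized into a fixed
# little-endian binary layout, compressed with zlib, and stored as one BLOB
# column each. Blob layout:
#
#   byte 1      codec tag (currently 1)
#   byte 2      kind tag: 1 = integer, 2 = character, 3 = logical
#   bytes 3-6   element count, int32 LE
#   bytes 7-10  Adler-style checksum word s1, int32 LE
#   bytes 11-14 checksum word s2, int32 LE
#   rest        zlib-compressed payload
#
# The header stays uncompressed so unpack() can reject unknown codec
# versions before touching the payload; the checksum over the uncompressed
# payload catches corrupted bytes that still inflate cleanly.

VARDB_CODEC_TAG <- 1L
.KIND_INT <- 1L
.KIND_CHR <- 2L
.KIND_LGL <- 3L
.CHR_SEP <- "\x1f" # unit separator; never occurs in genotype strings

#' Genotype type codes
#'
#' Integer codes used in the `gt_types` array and accepted (by name) in the
#' genotype-filter language: `HOM_REF = 0`, `HET = 1`, `UNKNOWN = 2`,
#' `HOM_ALT = 3`. `UNKNOWN` marks an uncalled genotype (`"./."`), not a
#' genotype with zero depth.
#'
#' @format Named integer vector of length 4.
#' @export
gt_type_codes <- c(HOM_REF = 0L, HET = 1L, UNKNOWN = 2L, HOM_ALT = 3L)

#' Encode a raw VCF GT field as a genotype type code
#'
#' Maps a diploid (or haploid) GT string to the fixed integer codes of
#' [gt_type_codes]. Any uncalled allele makes the whole genotype `UNKNOWN`;
#' two distinct called alleles are `HET` regardless of which alleles they
#' are.
#'
#' @param gt Character vector of raw GT fields (e.g. `"0/1"`, `"1|1"`, `"."`).
#' @param n_alt Number of ALT alleles at the site; allele indices above it
#'   raise a validation error.
#' @return Integer vector of codes.
#' @examples
#' encode_gt_type(c("0/1", "./.", "1|1"))
#' @export
encode_gt_type <- function(gt, n_alt = 1L) {
  vapply(gt, function(g) {
    al <- parse_gt_alleles(g, n_alt)$alleles
    if (anyNA(al)) return(gt_type_codes[["UNKNOWN"]])
    if (all(al == 0L)) return(gt_type_codes[["HOM_REF"]])
    if (length(unique(al)) == 1L) return(gt_type_codes[["HOM_ALT"]])
    gt_type_codes[["HET"]]
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname encode_gt_type
#' @return `gt_is_phased()`: logical vector, `TRUE` where the separator is
#'   `|` and the genotype is called.
#' @export
gt_is_phased <- function(gt) {
  vapply(gt, function(g) {
    p <- parse_gt_alleles(g, n_alt = Inf)
    p$phased && !anyNA(p$alleles)
  }, logical(1), USE.NAMES = FALSE)
}

# -> list(alleles = integer (NA = uncalled), phased = logical)
parse_gt_alleles <- function(g, n_alt = 1L) {
  if (is.na(g) || g == "" || g == ".") {
    return(list(alleles = NA_integer_, phased = FALSE))
  }
  phased <- grepl("|", g, fixed = TRUE)
  parts <- strsplit(g, "[/|]")[[1]]
  al <- suppressWarnings(ifelse(parts == ".", NA_integer_, as.integer(parts)))
  bad <- !is.na(al) & (al < 0L | al > n_alt)
  if (any(bad)) {
    vardb_stop(
      sprintf("genotype '%s' references allele index %d but the site has %s ALT allele(s)",
              g, max(al[bad]), format(n_alt)),
      "vardb_validation_error"
    )
  }
  list(alleles = al, phased = phased)
}

#' Pack and unpack genotype arrays
#'
#' `pack()` serializes an integer, character or logical array into a
#' compressed blob; `unpack()` restores it exactly. `pack_genotype_row()`
#' packs the four arrays of one variant row at once. Packing is
#' deterministic: identical arrays give byte-identical blobs.
#'
#' @param x Integer, character (no NA) or logical vector.
#' @return `pack()`: a raw vector (the blob).
#' @examples
#' blob <- pack(c(0L, 1L, 3L))
#' unpack(blob)
#' @export
pack <- function(x) {
  if (is.integer(x) || (is.numeric(x) && all(x == as.integer(x)))) {
    kind <- .KIND_INT
    payload <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  } else if (is.character(x)) {
    if (anyNA(x)) vardb_stop("NA strings cannot be packed", "vardb_validation_error")
    if (any(grepl(.CHR_SEP, x, fixed = TRUE))) {
      vardb_stop("genotype strings may not contain the reserved separator byte 0x1f",
                 "vardb_validation_error")
    }
    kind <- .KIND_CHR
    payload <- if (length(x) == 0L) raw(0) else charToRaw(paste(x, collapse = .CHR_SEP))
  } else if (is.logical(x)) {
    if (anyNA(x)) vardb_stop("NA flags cannot be packed", "vardb_validation_error")
    kind <- .KIND_LGL
    payload <- as.raw(as.integer(x))
  } else {
    vardb_stop(sprintf("cannot pack objects of class '%s'", class(x)[1]),
               "vardb_validation_error")
  }
  ck <- payload_checksum(payload)
  c(as.raw(VARDB_CODEC_TAG), as.raw(kind),
    writeBin(c(length(x), ck), raw(), size = 4L, endian = "little"),
    memCompress(payload, type = "gzip"))
}

# Adler-32-style checksum, returned as two int32 words (fits writeBin)
payload_checksum <- function(payload) {
  if (length(payload) == 0L) return(c(1L, 0L))
  v <- as.integer(payload)
  s1 <- (1 + sum(as.numeric(v))) %% 65521
  s2 <- (length(v) + sum(cumsum(as.numeric(v)))) %% 65521
  as.integer(c(s1, s2))
}

#' @rdname pack
#' @param blob A raw vector produced by `pack()`.
#' @return `unpack()`: the original vector.
#' @export
unpack <- function(blob) {
  if (!is.raw(blob) || length(blob) < 14L) {
    vardb_stop("blob is not a vardb genotype blob", "vardb_integrity_error")
  }
  tag <- as.integer(blob[1])
  if (tag != VARDB_CODEC_TAG) {
    vardb_stop(sprintf("unknown genotype codec tag %d (this build reads tag %d)",
                       tag, VARDB_CODEC_TAG), "vardb_version_error")
  }
  kind <- as.integer(blob[2])
  hdr <- readBin(blob[3:14], integer(), n = 3L, size = 4L, endian = "little")
  n <- hdr[1]
  payload <- tryCatch(
    memDecompress(blob[-(1:14)], type = "gzip"),
    error = function(e) vardb_stop("corrupted genotype blob: decompression failed",
                                   "vardb_integrity_error")
  )
  if (!identical(payload_checksum(payload), hdr[2:3])) {
    vardb_stop("corrupted genotype blob: checksum mismatch", "vardb_integrity_error")
  }
  out <- switch(as.character(kind),
    "1" = readBin(payload, integer(), n = n, size = 4L, endian = "little"),
    "2" = if (n == 0L) character(0) else strsplit(rawToChar(payload), .CHR_SEP, fixed = TRUE)[[1]],
    "3" = as.logical(as.integer(payload)),
    vardb_stop("corrupted genotype blob: unknown kind tag", "vardb_integrity_error")
  )
  if (length(out) != n) {
    vardb_stop("corrupted genotype blob: element count mismatch", "vardb_integrity_error")
  }
  out
}

#' @rdname pack
#' @param row A list with elements `gts` (character), `gt_types` (integer),
#'   `gt_phases` (logical) and `gt_depths` (integer), all the same length.
#' @return `pack_genotype_row()`: a named list of four blobs.
#' @export
pack_genotype_row <- function(row) {
  s <- length(row$gts)
  if (length(row$gt_types) != s || length(row$gt_phases) != s || length(row$gt_depths) != s) {
    vardb_stop("genotype row arrays must all have the same length", "vardb_validation_error")
  }
  list(
    gts = pack(row$gts),
    gt_types = pack(as.integer(row$gt_types)),
    gt_phases = pack(as.logical(row$gt_phases)),
    gt_depths = pack(as.integer(row$gt_depths))
  )
}

#' Random access into a packed genotype array
#'
#' Returns the value for one sample without exposing the rest of the array;
#' equivalent to `unpack(blob)[sample_index]`.
#'
#' @param blob A blob from [pack()].
#' @param sample_index 1-based sample position.
#' @export
sample_value <- function(blob, sample_index) {
  x <- unpack(blob)
  if (!is.numeric(sample_index) || length(sample_index) != 1L ||
      is.na(sample_index) || sample_index < 1L || sample_index > length(x)) {
    vardb_stop(sprintf("sample index %s out of range 1..%d",
                       format(sample_index), length(x)), "vardb_bounds_error")
  }
  x[[as.integer(sample_index)]]
}
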