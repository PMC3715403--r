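# Interval annotation tracks.
#
# A track is any BED, GFF/GTF, or sites-only VCF file. Intervals are stored
# 0-based half-open regardless of source convention and indexed per
# chromosome with IRanges; chromosome names are matched with and without a
# "chr" prefix (dual-key normalization shared with the loader). A variant's
# annotation region is its [start, end) span: SNPs are width 1, deletions
# span the deleted bases. Strand is ignored.

#' Build an annotation track from a file
#'
#' @param name Column-safe identifier; becomes the database column name.
#' @param path File path.
#' @param format `"bed"` (0-based half-open), `"gff"` (1-based inclusive;
#'   values extracted from attribute keys), or `"vcf"` (sites-only VCF;
#'   values extracted from INFO keys).
#' @param mode `"boolean"` (1 if any overlap), `"count"` (number of
#'   overlapping intervals), or `"extract"` (values from overlapping
#'   records: unique, lexicographically sorted, comma-joined; or the
#'   maximum when `numeric = TRUE`).
#' @param extract For extract mode: a BED column number (e.g. 4 for name,
#'   5 for score), a GFF attribute key, or a VCF INFO key.
#' @param numeric Extract mode only: coerce values to numeric and report
#'   the maximum across overlaps.
#' @param require_allele VCF tracks only: require REF and ALT identity in
#'   addition to positional overlap (default FALSE: position-only, the
#'   dbSNP-style membership test).
#' @return An `annotation_track` object usable with [annotate_variant()]
#'   and during [vardb_load()].
#' @export
annotation_track <- function(name, path, format = c("bed", "gff", "vcf"),
                             mode = c("boolean", "count", "extract"),
                             extract = NULL, numeric = FALSE,
                             require_allele = FALSE) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    vardb_stop(sprintf("track name '%s' is not a valid column identifier", name),
               "vardb_config_error")
  }
  if (mode == "extract" && is.null(extract)) {
    vardb_stop("extract mode needs an 'extract' column/attribute/key",
               "vardb_config_error")
  }
  iv <- switch(format,
               bed = read_bed_intervals(path),
               gff = read_gff_intervals(path),
               vcf = read_vcf_intervals(path))
  structure(
    list(name = name, path = path, format = format, mode = mode,
         extract = extract, numeric = numeric, require_allele = require_allele,
         index = build_interval_index(iv), intervals = iv),
    class = "annotation_track")
}

norm_chrom <- function(x) sub("^chr", "", x)

# intervals: data.frame(chrom, start (0-based), end (exclusive), plus
# source-specific value columns). The index maps normalized chrom ->
# IRanges (1-based inclusive) + the source row indices.
build_interval_index <- function(iv) {
  if (nrow(iv) == 0L) return(list())
  key <- norm_chrom(iv$chrom)
  lapply(split(seq_len(nrow(iv)), key), function(idx) {
    list(ranges = IRanges::IRanges(start = iv$start[idx] + 1L, end = iv$end[idx]),
         rows = idx)
  })
}

read_bed_intervals <- function(path) {
  if (!file.exists(path)) vardb_stop(sprintf("track file not found: %s", path), "vardb_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]; lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  rows <- strsplit(lines, "[ \t]+")
  ncol_min <- min(lengths(rows))
  if (ncol_min < 3L) {
    bad <- which(lengths(rows) < 3L)[1]
    vardb_stop(sprintf("%s line %d: BED needs at least 3 columns", path, lineno[bad]),
               "vardb_parse_error")
  }
  start <- suppressWarnings(as.integer(vapply(rows, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(rows, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad)) {
    vardb_stop(sprintf("%s line %d: malformed BED coordinates", path, lineno[bad[1]]),
               "vardb_parse_error")
  }
  out <- data.frame(chrom = vapply(rows, `[`, "", 1L), start = start, end = end,
                    stringsAsFactors = FALSE)
  extra <- max(lengths(rows))
  for (j in seq_len(extra)[-(1:3)]) {
    out[[paste0("col", j)]] <- vapply(rows, function(r) if (length(r) >= j) r[j] else NA_character_, "")
  }
  out
}

read_gff_intervals <- function(path) {
  if (!file.exists(path)) vardb_stop(sprintf("track file not found: %s", path), "vardb_io_error")
  g <- tryCatch(rtracklayer::readGFF(path),
                error = function(e) vardb_stop(
                  sprintf("failed to parse GFF %s: %s", path, conditionMessage(e)),
                  "vardb_parse_error"))
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,  # 1-based incl -> 0-based half-open
                    end = as.integer(g$end),
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(g), c("seqid", "start", "end", "strand", "score",
                                  "phase", "frame"))) {
    v <- g[[col]]
    if (is.list(v)) v <- vapply(v, function(x) paste(unlist(x), collapse = ","), "")
    out[[col]] <- as.character(v)
  }
  out
}

read_vcf_intervals <- function(path) {
  v <- read_vcf(path)
  recs <- v$records
  data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    ref = vapply(recs, `[[`, "", "ref"),
    alt = vapply(recs, `[[`, "", "alt"),
    info = I(lapply(recs, `[[`, "info")),
    stringsAsFactors = FALSE
  )
}

# rows of track$intervals overlapping [start, end) on chrom (0-based half-open)
overlapping_rows <- function(track, chrom, start, end, ref = NULL, alt = NULL) {
  node <- track$index[[norm_chrom(chrom)]]
  if (is.null(node) || end <= start) return(integer(0))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, node$ranges)
  rows <- node$rows[S4Vectors::subjectHits(hits)]
  if (track$format == "vcf" && track$require_allele) {
    rows <- rows[track$intervals$ref[rows] == ref & track$intervals$alt[rows] == alt]
  }
  rows
}

#' Annotate one variant against one track
#'
#' @param site A variant record from [read_vcf()] (or any list with
#'   `chrom`, `start`, `end`, and for allele-aware VCF tracks `ref`/`alt`).
#' @param track An [annotation_track()].
#' @return Boolean mode: 0/1. Count mode: integer. Extract mode: character
#'   (sorted unique values comma-joined) or numeric maximum; NA when no
#'   overlap or no usable value.
#' @export
annotate_variant <- function(site, track) {
  rows <- overlapping_rows(track, site$chrom, site$start, site$end,
                           ref = site$ref, alt = site$alt)
  if (track$mode == "boolean") return(as.integer(length(rows) > 0L))
  if (track$mode == "count") return(length(rows))
  if (length(rows) == 0L) return(if (track$numeric) NA_real_ else NA_character_)
  vals <- extract_values(track, rows)
  vals <- vals[!is.na(vals) & nzchar(vals)]
  if (length(vals) == 0L) {
    vardb_warn(sprintf("track '%s': no usable '%s' value among %d overlapping record(s)",
                       track$name, as.character(track$extract), length(rows)))
    return(if (track$numeric) NA_real_ else NA_character_)
  }
  if (track$numeric) {
    num <- suppressWarnings(as.numeric(vals))
    num <- num[!is.na(num)]
    if (length(num) == 0L) return(NA_real_)
    return(max(num))
  }
  paste(sort(unique(vals)), collapse = ",")
}

extract_values <- function(track, rows) {
  iv <- track$intervals
  if (track$format == "bed") {
    col <- track$extract
    colname <- if (is.numeric(col)) paste0("col", as.integer(col)) else col
    if (!colname %in% names(iv)) return(rep(NA_character_, length(rows)))
    return(as.character(iv[[colname]][rows]))
  }
  if (track$format == "gff") {
    if (!track$extract %in% names(iv)) return(rep(NA_character_, length(rows)))
    return(as.character(iv[[track$extract]][rows]))
  }
  vapply(iv$info[rows], function(info) {
    v <- info[[track$extract]]
    if (is.null(v)) NA_character_ else if (isTRUE(v)) "1" else as.character(v)
  }, character(1))
}

#' Annotate a set of variants with all tracks
#'
#' @param sites List of variant records from [read_vcf()].
#' @param tracks List of [annotation_track()] objects with distinct names.
#' @param reserved Column names the track names may not collide with.
#' @return data.frame with one column per track, rows parallel to `sites`;
#'   zero columns when no tracks are given.
#' @export
annotate_all <- function(sites, tracks, reserved = character(0)) {
  names_ <- vapply(tracks, `[[`, "", "name")
  if (anyDuplicated(names_)) {
    vardb_stop("duplicate annotation track names", "vardb_config_error")
  }
  clash <- intersect(names_, reserved)
  if (length(clash)) {
    vardb_stop(sprintf("track name(s) collide with core schema columns: %s",
                       paste(clash, collapse = ", ")), "vardb_config_error")
  }
  out <- data.frame(row.names = seq_along(sites))
  for (tr in tracks) {
    vals <- lapply(sites, annotate_variant, track = tr)
    out[[tr$name]] <- unlist(vals, use.names = FALSE)
  }
  out
}

#' Read a track configuration file
#'
#' Plain-text `key=value` blocks, one track per line:
#' `name=cpg;path=cpg.bed;format=bed;mode=boolean` (fields separated by
#' `;`, `extract=` and `numeric=true` optional).
#'
#' @param path Configuration file path.
#' @param base_dir Directory against which relative track paths resolve.
#' @return List of [annotation_track()] objects.
#' @export
read_track_config <- function(path, base_dir = dirname(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(ln) {
    kv <- strsplit(strsplit(ln, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, function(p) trimws(p[2]), ""),
                            vapply(kv, function(p) trimws(p[1]), ""))
    p <- vals[["path"]]
    if (!file.exists(p) && file.exists(file.path(base_dir, p))) p <- file.path(base_dir, p)
    ex <- vals["extract"]
    ex <- if (is.na(ex)) NULL else if (grepl("^[0-9]+$", ex)) as.integer(ex) else unname(ex)
    annotation_track(name = vals[["name"]], path = p,
                     format = if (is.na(vals["format"])) "bed" else vals[["format"]],
                     mode = if (is.na(vals["mode"])) "boolean" else vals[["mode"]],
                     extract = ex,
                     numeric = isTRUE(tolower(vals["numeric"]) == "true"))
  })
}
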