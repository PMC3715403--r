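# Database schema and loader.
#
# A vardb database is one SQLite file with four user-facing tables —
# variants, variant_impacts, samples, resources — plus a small db_meta
# key/value table holding the schema version and sample count. Genotype
# information lives in four BLOB columns of the variants table (gts,
# gt_types, gt_phases, gt_depths), one compressed array per column per
# variant (see genotype-store.R). Loading may be chunked across cores;
# variant ids are assigned in post-split file order *before* chunking, and
# chunks are written back in order, so the database content is identical
# for any core count, chunk size, or transaction batch size.

VARDB_SCHEMA_VERSION <- 1L

# core variants-table columns, in storage order (annotation columns are
# appended per track at load)
variants_core_columns <- function() {
  c(variant_id = "INTEGER PRIMARY KEY", chrom = "TEXT", start = "INTEGER",
    end = "INTEGER", ref = "TEXT", alt = "TEXT", quality = "REAL",
    filter = "TEXT", type = "TEXT", sub_type = "TEXT",
    gene = "TEXT", transcript = "TEXT", consequence = "TEXT",
    impact_severity = "TEXT", is_lof = "INTEGER",
    num_hom_ref = "INTEGER", num_het = "INTEGER", num_hom_alt = "INTEGER",
    num_unknown = "INTEGER", call_rate = "REAL", aaf = "REAL",
    hwe = "REAL", inbreeding_coeff = "REAL", pi = "REAL",
    gts = "BLOB", gt_types = "BLOB", gt_phases = "BLOB", gt_depths = "BLOB")
}

#' Create an empty vardb database
#'
#' Creates the four tables (`variants`, `variant_impacts`, `samples`,
#' `resources`) and their indexes in a fresh SQLite file. Refuses to touch
#' an existing file unless `overwrite = TRUE`.
#'
#' @param path Database file path.
#' @param overwrite Replace an existing file.
#' @return The path, invisibly.
#' @export
vardb_create <- function(path, overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite) {
      vardb_stop(sprintf("database %s already exists (use overwrite = TRUE)", path),
                 "vardb_exists_error")
    }
    unlink(path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  cols <- variants_core_columns()
  DBI::dbExecute(con, sprintf("CREATE TABLE variants (%s)",
                              paste(names(cols), cols, collapse = ", ")))
  DBI::dbExecute(con, "CREATE TABLE variant_impacts (
      variant_id INTEGER, gene TEXT, transcript TEXT, consequence TEXT,
      impact_severity TEXT, is_lof INTEGER, aa_change TEXT, is_primary INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE samples (
      sample_idx INTEGER PRIMARY KEY, name TEXT UNIQUE, family_id TEXT,
      paternal_id TEXT, maternal_id TEXT, sex TEXT, phenotype TEXT)")
  DBI::dbExecute(con, "CREATE TABLE resources (
      name TEXT, source_path TEXT, version_or_checksum TEXT)")
  DBI::dbExecute(con, "CREATE TABLE db_meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO db_meta VALUES ('schema_version', :v)",
                 params = list(v = as.character(VARDB_SCHEMA_VERSION)))
  DBI::dbExecute(con, "CREATE INDEX idx_variants_pos ON variants (chrom, start, end)")
  DBI::dbExecute(con, "CREATE INDEX idx_variants_gene ON variants (gene)")
  DBI::dbExecute(con, "CREATE INDEX idx_variants_islof ON variants (is_lof)")
  DBI::dbExecute(con, "CREATE INDEX idx_variants_aaf ON variants (aaf)")
  DBI::dbExecute(con, "CREATE INDEX idx_impacts_variant ON variant_impacts (variant_id)")
  invisible(path)
}

#' Load a VCF (and optional PED and annotation tracks) into a database
#'
#' The full load pipeline: parse and split the VCF, encode and pack the
#' per-sample genotype arrays, compute the per-site statistics, parse
#' transcript impacts, annotate against every track, and write everything
#' to SQLite. With `cores > 1` the per-variant work is distributed over
#' forked workers in chunks of `chunk_size` records; results are merged in
#' variant-id order so the database content does not depend on `cores`,
#' `chunk_size`, or `batch_size`.
#'
#' @param db_path Output database file.
#' @param vcf Input VCF path.
#' @param ped Optional PED path. Samples present in the PED but absent from
#'   the VCF are an error; VCF samples missing from the PED are loaded with
#'   null pedigree fields (with a warning).
#' @param tracks List of [annotation_track()] objects (or a config-file
#'   path for [read_track_config()]).
#' @param cores Number of worker processes for chunked loading.
#' @param chunk_size VCF records per chunk.
#' @param batch_size Rows per insert transaction.
#' @param impact_source `"auto"`, `"ANN"`, `"EFF"` or `"CSQ"`.
#' @param overwrite Replace an existing database file.
#' @return The database path, invisibly.
#' @export
vardb_load <- function(db_path, vcf, ped = NULL, tracks = list(), cores = 1L,
                       chunk_size = 10000L, batch_size = 5000L,
                       impact_source = "auto", overwrite = FALSE) {
  if (cores < 1L) vardb_stop("cores must be >= 1", "vardb_config_error")
  if (is.character(tracks) && length(tracks) == 1L) tracks <- read_track_config(tracks)
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)

  parsed <- read_vcf(vcf)
  samples_df <- build_samples_table(parsed$samples, ped)
  vardb_create(db_path, overwrite = overwrite)

  track_names <- vapply(tracks, `[[`, "", "name")
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  for (i in seq_along(tracks)) {
    if (track_names[i] %in% names(variants_core_columns())) {
      vardb_stop(sprintf("track name '%s' collides with a core column", track_names[i]),
                 "vardb_config_error")
    }
    sqltype <- if (tracks[[i]]$mode == "extract" && !tracks[[i]]$numeric) "TEXT" else "REAL"
    DBI::dbExecute(con, sprintf("ALTER TABLE variants ADD COLUMN %s %s",
                                track_names[i], sqltype))
  }

  recs <- parsed$records
  chunk_results <- process_in_chunks(recs, tracks, impact_source, parsed$csq_fields,
                                     cores = cores, chunk_size = chunk_size)
  merged <- merge_chunks(chunk_results)
  write_load_results(con, merged, batch_size = batch_size)

  DBI::dbExecute(con, "DELETE FROM samples")
  if (nrow(samples_df)) {
    DBI::dbWriteTable(con, "samples", samples_df, append = TRUE)
  }
  DBI::dbExecute(con, "INSERT OR REPLACE INTO db_meta VALUES ('n_samples', :v)",
                 params = list(v = as.character(length(parsed$samples))))

  res <- data.frame(name = "vcf", source_path = normalizePath(vcf),
                    version_or_checksum = unname(tools::md5sum(vcf)),
                    stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    res <- rbind(res, data.frame(name = "ped", source_path = normalizePath(ped),
                                 version_or_checksum = unname(tools::md5sum(ped))))
  }
  for (tr in tracks) {
    res <- rbind(res, data.frame(name = tr$name, source_path = normalizePath(tr$path),
                                 version_or_checksum = unname(tools::md5sum(tr$path))))
  }
  DBI::dbWriteTable(con, "resources", res, append = TRUE)
  invisible(db_path)
}

build_samples_table <- function(vcf_samples, ped) {
  nas <- rep(NA_character_, length(vcf_samples))
  base <- data.frame(sample_idx = seq_along(vcf_samples), name = vcf_samples,
                     family_id = nas, paternal_id = nas, maternal_id = nas,
                     sex = nas, phenotype = nas, stringsAsFactors = FALSE)
  if (is.null(ped)) return(base)
  ped_df <- if (is.data.frame(ped)) ped else read_ped(ped)
  missing_in_vcf <- setdiff(ped_df$sample_id, vcf_samples)
  if (length(missing_in_vcf)) {
    vardb_stop(sprintf("PED sample(s) not present in the VCF: %s",
                       paste(missing_in_vcf, collapse = ", ")),
               "vardb_validation_error")
  }
  unped <- setdiff(vcf_samples, ped_df$sample_id)
  if (length(unped)) {
    vardb_warn(sprintf("VCF sample(s) absent from the PED, loaded with null pedigree fields: %s",
                       paste(unped, collapse = ", ")))
  }
  m <- match(base$name, ped_df$sample_id)
  hit <- !is.na(m)
  base$family_id[hit] <- ped_df$family_id[m[hit]]
  base$paternal_id[hit] <- ped_df$paternal_id[m[hit]]
  base$maternal_id[hit] <- ped_df$maternal_id[m[hit]]
  base$sex[hit] <- ped_df$sex[m[hit]]
  base$phenotype[hit] <- ped_df$phenotype[m[hit]]
  base
}

# split records into contiguous chunks, process (possibly forked), return
# per-chunk results tagged with their variant-id range
process_in_chunks <- function(recs, tracks, impact_source, csq_fields,
                              cores = 1L, chunk_size = 10000L) {
  n <- length(recs)
  if (n == 0L) {
    return(list(list(range = c(1L, 0L), variants = NULL, impacts = empty_impacts())))
  }
  starts <- seq(1L, n, by = chunk_size)
  chunks <- lapply(starts, function(s) recs[s:min(s + chunk_size - 1L, n)])
  worker <- function(chunk) process_chunk(chunk, tracks, impact_source, csq_fields)
  results <- if (cores > 1L && length(chunks) > 1L &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, worker, mc.cores = cores)
  } else {
    lapply(chunks, worker)
  }
  for (r in results) {
    if (inherits(r, "try-error") || is.null(r$range)) {
      vardb_stop("chunk processing failed", "vardb_load_error")
    }
  }
  results
}

process_chunk <- function(chunk, tracks, impact_source, csq_fields) {
  ids <- vapply(chunk, `[[`, 0L, "variant_id")
  rows <- vector("list", length(chunk))
  impacts <- vector("list", length(chunk))
  for (i in seq_along(chunk)) {
    rec <- chunk[[i]]
    st <- site_stats(rec$gt$types)
    blobs <- pack_genotype_row(list(gts = rec$gt$letters, gt_types = rec$gt$types,
                                    gt_phases = rec$gt$phases, gt_depths = rec$gt$depths))
    imp <- parse_impacts(rec, source = impact_source, csq_fields = csq_fields)
    impacts[[i]] <- imp
    prim <- if (nrow(imp)) imp[imp$is_primary, , drop = FALSE] else NULL
    rows[[i]] <- c(
      list(variant_id = rec$variant_id, chrom = rec$chrom, start = rec$start,
           end = rec$end, ref = rec$ref, alt = rec$alt, quality = rec$quality,
           filter = rec$filter, type = rec$type, sub_type = rec$sub_type,
           gene = if (is.null(prim)) NA_character_ else prim$gene,
           transcript = if (is.null(prim)) NA_character_ else prim$transcript,
           consequence = if (is.null(prim)) NA_character_ else prim$consequence,
           impact_severity = if (is.null(prim)) NA_character_ else prim$impact_severity,
           is_lof = if (is.null(prim)) NA_integer_ else as.integer(prim$is_lof)),
      st[c("num_hom_ref", "num_het", "num_hom_alt", "num_unknown",
           "call_rate", "aaf", "hwe", "inbreeding_coeff", "pi")],
      list(gts = blobs$gts, gt_types = blobs$gt_types,
           gt_phases = blobs$gt_phases, gt_depths = blobs$gt_depths),
      lapply(tracks, function(tr) annotate_variant(rec, tr)) |>
        stats::setNames(vapply(tracks, `[[`, "", "name"))
    )
  }
  list(range = c(min(ids), max(ids)), variants = rows,
       impacts = do.call(rbind, c(impacts, list(empty_impacts()))))
}

#' Merge chunked load results
#'
#' Chunks must cover disjoint, contiguous variant-id ranges; the merge
#' restores global file order. Exposed mainly so chunked loading can be
#' verified directly.
#'
#' @param chunk_results List of results from internal chunk processing.
#' @return A single merged result (variants in variant_id order).
#' @export
merge_chunks <- function(chunk_results) {
  chunk_results <- chunk_results[vapply(chunk_results, function(r) !is.null(r$variants),
                                        logical(1))]
  if (length(chunk_results) == 0L) {
    return(list(variants = list(), impacts = empty_impacts()))
  }
  ranges <- t(vapply(chunk_results, `[[`, integer(2), "range"))
  ord <- order(ranges[, 1])
  ranges <- ranges[ord, , drop = FALSE]
  chunk_results <- chunk_results[ord]
  if (nrow(ranges) > 1L) {
    gaps <- ranges[-1, 1] - ranges[-nrow(ranges), 2]
    if (any(gaps < 1L)) {
      vardb_stop("chunk variant-id ranges overlap", "vardb_integrity_error")
    }
    if (any(gaps > 1L)) {
      vardb_stop("chunk variant-id ranges are not contiguous", "vardb_integrity_error")
    }
  }
  list(variants = do.call(c, lapply(chunk_results, `[[`, "variants")),
       impacts = do.call(rbind, lapply(chunk_results, `[[`, "impacts")))
}

write_load_results <- function(con, merged, batch_size = 5000L) {
  rows <- merged$variants
  if (length(rows)) {
    colnames_ <- names(rows[[1]])
    placeholders <- paste0(":", colnames_, collapse = ", ")
    sql <- sprintf("INSERT INTO variants (%s) VALUES (%s)",
                   paste(colnames_, collapse = ", "), placeholders)
    blob_cols <- c("gts", "gt_types", "gt_phases", "gt_depths")
    for (s in seq(1L, length(rows), by = batch_size)) {
      batch <- rows[s:min(s + batch_size - 1L, length(rows))]
      params <- lapply(stats::setNames(colnames_, colnames_), function(cn) {
        if (cn %in% blob_cols) {
          lapply(batch, `[[`, cn)
        } else {
          unlist(lapply(batch, function(r) {
            v <- r[[cn]]
            if (is.null(v) || length(v) == 0L) NA else v
          }), use.names = FALSE)
        }
      })
      DBI::dbWithTransaction(con, DBI::dbExecute(con, sql, params = params))
    }
  }
  imp <- merged$impacts
  if (nrow(imp)) {
    imp$is_lof <- as.integer(imp$is_lof)
    imp$is_primary <- as.integer(imp$is_primary)
    DBI::dbWriteTable(con, "variant_impacts", imp, append = TRUE)
  }
}

#' Canonical dump of a database's content
#'
#' Every table as a data.frame, rows in canonical order (variants and
#' impacts by variant_id, samples by sample_idx), with genotype blobs
#' rendered as deterministic hex strings. Two databases loaded from the
#' same inputs compare identical regardless of core count or batch size.
#'
#' @param path Database file.
#' @return Named list of data.frames.
#' @export
vardb_dump <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path, flags = RSQLite::SQLITE_RO)
  on.exit(DBI::dbDisconnect(con))
  v <- DBI::dbGetQuery(con, "SELECT * FROM variants ORDER BY variant_id")
  for (cn in c("gts", "gt_types", "gt_phases", "gt_depths")) {
    v[[cn]] <- vapply(v[[cn]], function(b) paste(as.character(b), collapse = ""), "")
  }
  list(
    variants = v,
    variant_impacts = DBI::dbGetQuery(
      con, "SELECT * FROM variant_impacts ORDER BY variant_id, transcript, consequence"),
    samples = DBI::dbGetQuery(con, "SELECT * FROM samples ORDER BY sample_idx"),
    resources = DBI::dbGetQuery(con, "SELECT * FROM resources ORDER BY name")
  )
}

#' Add an annotation column to an existing database
#'
#' Mirrors the loader's track annotation for databases that already exist:
#' adds one column named after the track and fills it by interval overlap.
#'
#' @param db_path Database file.
#' @param track An [annotation_track()].
#' @return The database path, invisibly.
#' @export
add_annotation <- function(db_path, track) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  existing <- DBI::dbListFields(con, "variants")
  if (track$name %in% existing) {
    vardb_stop(sprintf("column '%s' already exists in variants", track$name),
               "vardb_config_error")
  }
  sqltype <- if (track$mode == "extract" && !track$numeric) "TEXT" else "REAL"
  DBI::dbExecute(con, sprintf("ALTER TABLE variants ADD COLUMN %s %s", track$name, sqltype))
  sites <- DBI::dbGetQuery(con, "SELECT variant_id, chrom, start, end, ref, alt FROM variants")
  if (nrow(sites)) {
    vals <- lapply(seq_len(nrow(sites)), function(i) {
      annotate_variant(as.list(sites[i, , drop = FALSE]), track)
    })
    DBI::dbExecute(con,
      sprintf("UPDATE variants SET %s = :val WHERE variant_id = :id", track$name),
      params = list(val = unlist(vals, use.names = FALSE), id = sites$variant_id))
  }
  DBI::dbExecute(con, "INSERT INTO resources VALUES (:n, :p, :c)",
                 params = list(n = track$name, p = normalizePath(track$path),
                               c = unname(tools::md5sum(track$path))))
  invisible(db_path)
}
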