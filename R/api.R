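# Programmatic session interface: open a database, iterate rows with
# transparently unpacked genotype arrays, look up per-sample values.

#' Open a session on a vardb database
#'
#' Sessions are read-only unless `writable = TRUE` (databases are meant to
#' be shared as single files). The schema version recorded in the file must
#' match this build's.
#'
#' @param path Database file (must exist; nothing is created).
#' @param writable Open read-write.
#' @return A `vardb_session`: connection, samples table, and a named
#'   sample-index map (`sample name -> array position`).
#' @export
open_session <- function(path, writable = FALSE) {
  if (!file.exists(path)) {
    vardb_stop(sprintf("database file not found: %s", path), "vardb_io_error")
  }
  flags <- if (writable) RSQLite::SQLITE_RW else RSQLite::SQLITE_RO
  con <- DBI::dbConnect(RSQLite::SQLite(), path, flags = flags)
  meta <- tryCatch(DBI::dbGetQuery(con, "SELECT key, value FROM db_meta"),
                   error = function(e) {
                     DBI::dbDisconnect(con)
                     vardb_stop(sprintf("%s is not a vardb database (no db_meta table)", path),
                                "vardb_format_error")
                   })
  ver <- as.integer(meta$value[meta$key == "schema_version"])
  if (length(ver) != 1L || is.na(ver) || ver != VARDB_SCHEMA_VERSION) {
    DBI::dbDisconnect(con)
    vardb_stop(sprintf("schema version %s not supported (this build reads version %d)",
                       paste(ver, collapse = ","), VARDB_SCHEMA_VERSION),
               "vardb_version_error")
  }
  samples <- DBI::dbGetQuery(con, "SELECT * FROM samples ORDER BY sample_idx")
  structure(
    list(con = con, path = path,
         samples = samples,
         sample_index = stats::setNames(samples$sample_idx, samples$name),
         schema_version = ver),
    class = "vardb_session")
}

as_session <- function(x) {
  if (inherits(x, "vardb_session")) {
    x$owned <- FALSE # whoever opened it closes it, not a nested callee
    return(x)
  }
  if (is_scalar_string(x)) {
    s <- open_session(x)
    s$owned <- TRUE # opened here: the calling function must close it
    return(s)
  }
  vardb_stop("expected a vardb_session or a database path", "vardb_validation_error")
}

# close a session that as_session() opened from a bare path
release_session <- function(session) {
  if (isTRUE(session$owned)) close_session(session)
}

#' @rdname open_session
#' @param session A `vardb_session`.
#' @export
close_session <- function(session) {
  DBI::dbDisconnect(session$con)
  invisible(NULL)
}

#' @export
print.vardb_session <- function(x, ...) {
  nvar <- DBI::dbGetQuery(x$con, "SELECT count(*) AS n FROM variants")$n
  cat(sprintf("<vardb session> %s\n  %d variants, %d samples, schema v%d\n",
              x$path, nvar, nrow(x$samples), x$schema_version))
  invisible(x)
}

#' Run a query through a session
#'
#' Thin wrapper around [execute_query()]; see there for pseudo-column and
#' genotype-filter semantics.
#'
#' @inheritParams execute_query
#' @export
run_query <- function(session, sql, gt_filter = NULL, strict_missing = FALSE) {
  execute_query(session, sql, gt_filter = gt_filter, strict_missing = strict_missing)
}

#' Fetch variant rows with unpacked genotype arrays
#'
#' Returns the variants table (optionally restricted by a WHERE fragment)
#' with the four genotype blob columns replaced by list-columns of
#' unpacked arrays, ready for [row_genotypes()].
#'
#' @param session A `vardb_session` (or database path).
#' @param where Optional SQL WHERE fragment (without the keyword).
#' @param columns Core columns to include beside the genotype arrays.
#' @return data.frame; `gts`, `gt_types`, `gt_phases`, `gt_depths` are
#'   list-columns of per-sample vectors.
#' @export
fetch_variants <- function(session, where = NULL,
                           columns = c("variant_id", "chrom", "start", "end",
                                       "ref", "alt", "gene", "impact_severity")) {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  sql <- sprintf("SELECT %s, gts, gt_types, gt_phases, gt_depths FROM variants%s ORDER BY variant_id",
                 paste(columns, collapse = ", "),
                 if (is.null(where)) "" else paste0(" WHERE ", where))
  res <- DBI::dbGetQuery(session$con, sql)
  for (cn in GT_FILTER_COLUMNS) res[[cn]] <- lapply(res[[cn]], unpack)
  res
}

#' Genotype information for one sample at one fetched row
#'
#' @param session A `vardb_session`.
#' @param row One row of [fetch_variants()] output (a list or 1-row
#'   data.frame with the unpacked list-columns).
#' @param sample_id Sample name.
#' @return List with `gts`, `gt_type`, `phased`, `depth`.
#' @export
row_genotypes <- function(session, row, sample_id) {
  idx <- session$sample_index[sample_id]
  if (is.na(idx)) {
    vardb_stop(sprintf("unknown sample '%s' (known: %s)", sample_id,
                       paste(names(session$sample_index), collapse = ", ")),
               "vardb_sample_error")
  }
  pick <- function(col) {
    v <- row[[col]]
    if (is.list(v)) v <- v[[1]]
    v[[idx]]
  }
  list(gts = pick("gts"), gt_type = pick("gt_types"),
       phased = pick("gt_phases"), depth = pick("gt_depths"))
}
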