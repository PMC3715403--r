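# PED pedigree reading (PLINK 6-column convention).

#' Read a PED pedigree file
#'
#' Whitespace-delimited, at least six columns per row:
#' `family_id sample_id paternal_id maternal_id sex phenotype`. Integer
#' codes follow PLINK: sex 1 = male, 2 = female, anything else unknown;
#' phenotype 1 = unaffected, 2 = affected, `0`/`-9`/other = unknown.
#' A parental id of `"0"` (or `"."` / `"-9"`) marks a founder and is stored
#' as NA.
#'
#' @param path Path to the PED file.
#' @return data.frame with columns `family_id`, `sample_id`, `paternal_id`,
#'   `maternal_id`, `sex`, `phenotype`, in file order.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) {
    vardb_stop(sprintf("PED file not found: %s", path), "vardb_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(rows) < 6L)
  if (length(bad)) {
    vardb_stop(sprintf("%s line %d: PED rows need at least 6 columns, found %d",
                       path, bad[1], lengths(rows)[bad[1]]), "vardb_format_error")
  }
  missing_parent <- function(x) ifelse(x %in% c("0", ".", "-9"), NA_character_, x)
  out <- data.frame(
    family_id = vapply(rows, `[`, "", 1L),
    sample_id = vapply(rows, `[`, "", 2L),
    paternal_id = missing_parent(vapply(rows, `[`, "", 3L)),
    maternal_id = missing_parent(vapply(rows, `[`, "", 4L)),
    sex = unname(c("1" = "male", "2" = "female")[vapply(rows, `[`, "", 5L)]),
    phenotype = unname(c("1" = "unaffected", "2" = "affected")[vapply(rows, `[`, "", 6L)]),
    stringsAsFactors = FALSE
  )
  out$sex[is.na(out$sex)] <- "unknown"
  out$phenotype[is.na(out$phenotype)] <- "unknown"
  if (any(!nzchar(out$sample_id))) {
    vardb_stop(sprintf("%s: empty sample_id", path), "vardb_validation_error")
  }
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup)) {
    vardb_stop(sprintf("%s: duplicate sample_id(s): %s", path,
                       paste(unique(dup), collapse = ", ")),
               "vardb_validation_error")
  }
  rownames(out) <- NULL
  out
}
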