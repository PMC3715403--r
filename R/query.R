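# SQL query interface with the COLUMN.SAMPLE genotype extension.
#
# Grammar of the genotype-filter language (per-sample conditions on the
# packed arrays):
#
#   expr  := or
#   or    := and ("or" and)*
#   and   := unary ("and" unary)*
#   unary := "not" unary | "(" expr ")" | cmp
#   cmp   := COLUMN "." SAMPLE OP literal
#   OP    := "==" | "!=" | "<" | "<=" | ">" | ">="
#
# COLUMN is one of gts, gt_types, gt_phases, gt_depths. Genotype-type
# names (HOM_REF, HET, HOM_ALT, UNKNOWN) are case-insensitive keywords;
# the spaced "=  =" spelling of equality is accepted. Because the genotype
# arrays are opaque blobs to SQLite, the filter is applied after the SQL
# runs, by decompressing each candidate row's arrays.
#
# Missing-data semantics (defaults): an uncalled genotype compares FALSE
# under == and != against any called literal; comparing explicitly against
# UNKNOWN / "./." uses ordinary equality. Missing depth is -1 and follows
# plain numeric semantics, so "gt_depths.s < 10" is true for a missing
# depth. With strict_missing = TRUE any comparison touching missing data
# (uncalled genotype, or depth of an uncalled genotype) is FALSE.

GT_FILTER_COLUMNS <- c("gts", "gt_types", "gt_phases", "gt_depths")

#' Parse a genotype-filter expression
#'
#' @param text Filter source text, e.g.
#'   `"gt_types.mom == HET and gt_types.dad == HET"`.
#' @param samples Optional character vector of known sample names; when
#'   given, unknown samples are rejected at parse time.
#' @return An AST: nested lists with `node` in `and`/`or`/`not`/`cmp`;
#'   `cmp` leaves carry `column`, `sample`, `op`, `literal` (genotype-type
#'   names already resolved to integer codes).
#' @export
parse_gt_filter <- function(text, samples = NULL) {
  if (!is_scalar_string(text) || !nzchar(trimws(text))) {
    vardb_stop("empty genotype filter expression", "vardb_syntax_error")
  }
  toks <- tokenize_gt_filter(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text; st$samples <- samples
  ast <- parse_or(st)
  if (st$pos <= length(st$toks)) {
    tk <- st$toks[[st$pos]]
    vardb_stop(sprintf("genotype filter: unexpected '%s' at position %d", tk$value, tk$at),
               "vardb_syntax_error")
  }
  ast
}

tokenize_gt_filter <- function(text) {
  # normalize the spaced "=  =" equality spelling seen in the wild
  text <- gsub("=[[:space:]]+=", "==", text)
  n <- nchar(text)
  toks <- list(); i <- 1L
  push <- function(type, value, at) toks[[length(toks) + 1L]] <<- list(type = type, value = value, at = at)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (ch %in% c("(", ")")) { push("paren", ch, i); i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^(==|!=|<=|>=|<|>)", rest))
    if (length(m)) { push("op", m, i); i <- i + nchar(m); next }
    if (ch %in% c("'", '"')) {
      close <- regexpr(ch, substr(text, i + 1L, n), fixed = TRUE)
      if (close == -1L) {
        vardb_stop(sprintf("genotype filter: unterminated string at position %d", i),
                   "vardb_syntax_error")
      }
      push("string", substr(text, i + 1L, i + close - 1L), i)
      i <- i + close + 1L
      next
    }
    m <- regmatches(rest, regexpr("^[.0-9A-Za-z_/|-]+", rest))
    if (length(m) && nzchar(m)) {
      low <- tolower(m)
      if (low %in% c("and", "or", "not")) push("keyword", low, i)
      else push("word", m, i)
      i <- i + nchar(m)
      next
    }
    vardb_stop(sprintf("genotype filter: unexpected character '%s' at position %d", ch, i),
               "vardb_syntax_error")
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { tk <- peek(st); st$pos <- st$pos + 1L; tk }

parse_or <- function(st) {
  left <- parse_and(st)
  args <- list(left)
  while (!is.null(tk <- peek(st)) && tk$type == "keyword" && tk$value == "or") {
    advance(st)
    args[[length(args) + 1L]] <- parse_and(st)
  }
  if (length(args) == 1L) left else list(node = "or", args = args)
}

parse_and <- function(st) {
  left <- parse_unary(st)
  args <- list(left)
  while (!is.null(tk <- peek(st)) && tk$type == "keyword" && tk$value == "and") {
    advance(st)
    args[[length(args) + 1L]] <- parse_unary(st)
  }
  if (length(args) == 1L) left else list(node = "and", args = args)
}

parse_unary <- function(st) {
  tk <- peek(st)
  if (is.null(tk)) {
    vardb_stop("genotype filter: unexpected end of expression", "vardb_syntax_error")
  }
  if (tk$type == "keyword" && tk$value == "not") {
    advance(st)
    return(list(node = "not", args = list(parse_unary(st))))
  }
  if (tk$type == "paren" && tk$value == "(") {
    advance(st)
    inner <- parse_or(st)
    closing <- advance(st)
    if (is.null(closing) || closing$value != ")") {
      vardb_stop(sprintf("genotype filter: missing ')' near position %d", tk$at),
                 "vardb_syntax_error")
    }
    return(inner)
  }
  parse_cmp(st)
}

parse_cmp <- function(st) {
  tk <- advance(st)
  if (is.null(tk) || tk$type != "word") {
    vardb_stop(sprintf("genotype filter: expected COLUMN.SAMPLE at position %d",
                       if (is.null(tk)) nchar(st$text) else tk$at), "vardb_syntax_error")
  }
  dot <- regexpr(".", tk$value, fixed = TRUE)
  if (dot == -1L) {
    vardb_stop(sprintf("genotype filter: '%s' at position %d is not COLUMN.SAMPLE",
                       tk$value, tk$at), "vardb_syntax_error")
  }
  column <- substr(tk$value, 1L, dot - 1L)
  sample <- substr(tk$value, dot + 1L, nchar(tk$value))
  if (!column %in% GT_FILTER_COLUMNS) {
    vardb_stop(sprintf("genotype filter: unknown column '%s' (valid: %s)", column,
                       paste(GT_FILTER_COLUMNS, collapse = ", ")), "vardb_column_error")
  }
  if (!nzchar(sample)) {
    vardb_stop(sprintf("genotype filter: missing sample name after '%s.'", column),
               "vardb_syntax_error")
  }
  if (!is.null(st$samples) && !sample %in% st$samples) {
    vardb_stop(sprintf("genotype filter: unknown sample '%s' (known: %s)", sample,
                       paste(st$samples, collapse = ", ")), "vardb_sample_error")
  }
  op_tk <- advance(st)
  if (is.null(op_tk) || op_tk$type != "op") {
    vardb_stop(sprintf("genotype filter: expected an operator after '%s'", tk$value),
               "vardb_syntax_error")
  }
  lit_tk <- advance(st)
  if (is.null(lit_tk) || !lit_tk$type %in% c("word", "string")) {
    vardb_stop(sprintf("genotype filter: expected a literal after '%s %s'",
                       tk$value, op_tk$value), "vardb_syntax_error")
  }
  literal <- resolve_literal(column, lit_tk)
  list(node = "cmp", column = column, sample = sample, op = op_tk$value,
       literal = literal)
}

resolve_literal <- function(column, lit_tk) {
  v <- lit_tk$value
  if (column == "gt_types") {
    up <- toupper(v)
    if (up %in% names(gt_type_codes)) return(unname(gt_type_codes[up]))
    num <- suppressWarnings(as.integer(v))
    if (is.na(num)) {
      vardb_stop(sprintf("genotype filter: '%s' is not a genotype type (use %s or a code 0-3)",
                         v, paste(names(gt_type_codes), collapse = "/")),
                 "vardb_syntax_error")
    }
    return(num)
  }
  if (column == "gt_depths") {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) {
      vardb_stop(sprintf("genotype filter: gt_depths needs a numeric literal, got '%s'", v),
                 "vardb_syntax_error")
    }
    return(num)
  }
  if (column == "gt_phases") {
    lv <- tolower(v)
    if (lv %in% c("true", "1")) return(TRUE)
    if (lv %in% c("false", "0")) return(FALSE)
    vardb_stop(sprintf("genotype filter: gt_phases needs true/false, got '%s'", v),
               "vardb_syntax_error")
  }
  v # gts: genotype string literal
}

#' Evaluate a genotype-filter AST against one genotype row
#'
#' @param ast From [parse_gt_filter()].
#' @param row List with unpacked `gts`, `gt_types`, `gt_phases`,
#'   `gt_depths` arrays.
#' @param sample_index Named integer vector mapping sample name to array
#'   position.
#' @param strict_missing Make any comparison on missing data FALSE.
#' @return Logical scalar.
#' @export
evaluate_filter <- function(ast, row, sample_index, strict_missing = FALSE) {
  switch(ast$node,
    and = all(vapply(ast$args, evaluate_filter, logical(1), row = row,
                     sample_index = sample_index, strict_missing = strict_missing)),
    or = any(vapply(ast$args, evaluate_filter, logical(1), row = row,
                    sample_index = sample_index, strict_missing = strict_missing)),
    not = !evaluate_filter(ast$args[[1]], row, sample_index, strict_missing),
    cmp = evaluate_cmp(ast, row, sample_index, strict_missing),
    vardb_stop("corrupt genotype-filter AST", "vardb_internal_error")
  )
}

evaluate_cmp <- function(ast, row, sample_index, strict_missing) {
  idx <- sample_index[ast$sample]
  if (is.na(idx)) {
    vardb_stop(sprintf("unknown sample '%s' in genotype filter", ast$sample),
               "vardb_sample_error")
  }
  value <- row[[ast$column]][[idx]]
  uncalled <- row$gt_types[[idx]] == gt_type_codes[["UNKNOWN"]]
  if (strict_missing &&
      ((ast$column %in% c("gts", "gt_types", "gt_phases") && uncalled) ||
       (ast$column == "gt_depths" && row$gt_depths[[idx]] < 0L))) {
    return(FALSE)
  }
  if (ast$column %in% c("gts", "gt_types") && uncalled) {
    literal_is_unknown <- (ast$column == "gt_types" &&
                             ast$literal == gt_type_codes[["UNKNOWN"]]) ||
                          (ast$column == "gts" && ast$literal == "./.")
    if (!literal_is_unknown) return(FALSE)
  }
  switch(ast$op,
    "==" = isTRUE(value == ast$literal),
    "!=" = isTRUE(value != ast$literal),
    "<" = isTRUE(value < ast$literal),
    "<=" = isTRUE(value <= ast$literal),
    ">" = isTRUE(value > ast$literal),
    ">=" = isTRUE(value >= ast$literal)
  )
}

#' Execute SQL with optional pseudo-columns and a genotype filter
#'
#' Runs the SQL statement, then (when requested) decompresses each
#' returned row's genotype blobs to expand `COLUMN.SAMPLE` pseudo-columns
#' in the select list and to apply the genotype filter. Rows returned are
#' exactly those satisfying both the SQL and the filter.
#'
#' @param session A [open_session()] session (or a database path).
#' @param sql SQL text; the select list may contain pseudo-columns such as
#'   `gts.NA12878`.
#' @param gt_filter Optional genotype-filter text or parsed AST.
#' @param strict_missing See [evaluate_filter()].
#' @return data.frame of results (pseudo-columns expanded; blob columns
#'   only present when selected explicitly or via `*`).
#' @export
execute_query <- function(session, sql, gt_filter = NULL, strict_missing = FALSE) {
  session <- as_session(session)
  on.exit(release_session(session), add = TRUE)
  parts <- split_select(sql)
  pseudo <- find_pseudo_columns(parts$select_items)
  for (ps in pseudo) {
    if (!is.null(ps) && !ps$sample %in% names(session$sample_index)) {
      vardb_stop(sprintf("unknown sample '%s' in select list (known: %s)", ps$sample,
                         paste(names(session$sample_index), collapse = ", ")),
                 "vardb_sample_error")
    }
  }
  ast <- if (is.null(gt_filter)) NULL
         else if (is.character(gt_filter)) parse_gt_filter(gt_filter, names(session$sample_index))
         else gt_filter
  needs_blobs <- length(Filter(Negate(is.null), pseudo)) > 0L || !is.null(ast)
  if (needs_blobs && is.null(parts$select_items)) {
    vardb_stop("genotype filters and COLUMN.SAMPLE columns require a SELECT ... FROM statement",
               "vardb_sql_error")
  }

  run_sql <- sql
  hidden <- character(0)
  if (needs_blobs && !is.null(parts$select_items)) {
    keep <- parts$select_items[vapply(pseudo, is.null, logical(1))]
    has_star <- any(trimws2(keep) == "*")
    add <- if (has_star) character(0) else
      paste0(GT_FILTER_COLUMNS, " AS \"..", GT_FILTER_COLUMNS, "\"")
    hidden <- if (has_star) GT_FILTER_COLUMNS else paste0("..", GT_FILTER_COLUMNS)
    run_sql <- paste0("SELECT ", paste(c(keep, add), collapse = ", "),
                      " FROM ", parts$rest)
  }
  res <- tryCatch(DBI::dbGetQuery(session$con, run_sql),
                  error = function(e) vardb_stop(
                    sprintf("SQL error in statement:\n  %s\n%s", sql, conditionMessage(e)),
                    "vardb_sql_error"))
  if (!needs_blobs) return(res)

  n <- nrow(res)
  rows_gt <- if (n) lapply(seq_len(n), function(i) {
    list(gts = unpack(res[[hidden[1]]][[i]]),
         gt_types = unpack(res[[hidden[2]]][[i]]),
         gt_phases = unpack(res[[hidden[3]]][[i]]),
         gt_depths = unpack(res[[hidden[4]]][[i]]))
  }) else list()

  keep_row <- if (is.null(ast)) rep(TRUE, n) else
    vapply(rows_gt, function(r) evaluate_filter(ast, r, session$sample_index,
                                                strict_missing), logical(1))
  res <- res[keep_row, , drop = FALSE]
  rows_gt <- rows_gt[keep_row]

  out <- expand_sample_columns(parts$select_items, pseudo, res, rows_gt,
                               session$sample_index, hidden)
  rownames(out) <- NULL
  out
}

# split "select <items> from <rest>" at the first top-level FROM
split_select <- function(sql) {
  m <- regexpr("^\\s*select\\s+", sql, ignore.case = TRUE)
  if (m == -1L) return(list(select_items = NULL, rest = NULL))
  body <- substr(sql, attr(m, "match.length") + 1L, nchar(sql))
  from <- regexpr("\\bfrom\\b", body, ignore.case = TRUE)
  if (from == -1L) return(list(select_items = NULL, rest = NULL))
  items <- split_top_level(substr(body, 1L, from - 1L))
  list(select_items = items,
       rest = substr(body, from + attr(from, "match.length"), nchar(body)))
}

split_top_level <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; buf <- character(0); items <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      items <- c(items, paste(buf, collapse = "")); buf <- character(0)
    } else buf <- c(buf, ch)
  }
  trimws2(c(items, paste(buf, collapse = "")))
}

find_pseudo_columns <- function(select_items) {
  lapply(select_items, function(it) {
    m <- regmatches(it, regexec("^(gts|gt_types|gt_phases|gt_depths)\\.([A-Za-z0-9_-]+)$",
                                trimws2(it)))[[1]]
    if (length(m) == 3L) list(column = m[2], sample = m[3]) else NULL
  })
}

#' @rdname execute_query
#' @param select_items Character vector of select-list items.
#' @param pseudo,res,rows_gt,sample_index,hidden Internal expansion state.
#' @keywords internal
#' @export
expand_sample_columns <- function(select_items, pseudo, res, rows_gt,
                                  sample_index, hidden) {
  out <- list()
  res_names <- setdiff(names(res), paste0("..", GT_FILTER_COLUMNS))
  star_cols <- setdiff(res_names, character(0))
  plain_i <- 0L
  plain_names <- setdiff(names(res), c(paste0("..", GT_FILTER_COLUMNS)))
  for (j in seq_along(select_items)) {
    ps <- pseudo[[j]]
    it <- select_items[[j]]
    if (is.null(ps)) {
      if (trimws2(it) == "*") {
        for (cn in star_cols) out[[cn]] <- res[[cn]]
      } else {
        plain_i <- plain_i + 1L
        cn <- infer_output_name(it, plain_names, length(out))
        out[[cn]] <- res[[cn]] %||% res[[plain_i]]
      }
    } else {
      idx <- sample_index[[ps$sample]]
      vals <- vapply(rows_gt, function(r) r[[ps$column]][[idx]],
                     switch(ps$column, gts = character(1), gt_phases = logical(1),
                            numeric(1)))
      out[[paste0(ps$column, ".", ps$sample)]] <- vals
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE,
                optional = TRUE)
}

infer_output_name <- function(item, available, n_so_far) {
  alias <- regmatches(item, regexec("\\bas\\s+[\"`]?([A-Za-z0-9_.]+)[\"`]?\\s*$",
                                    item, ignore.case = TRUE))[[1]]
  if (length(alias) == 2L && alias[2] %in% available) return(alias[2])
  it <- trimws2(item)
  if (it %in% available) return(it)
  # fall back to positional match
  available[n_so_far + 1L]
}
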