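# Independent oracles used across the suite. These deliberately do not
# call the implementation paths they check.

# --- naive recursive genotype-filter interpreter -------------------------
# Re-states the filter semantics from first principles: walk the AST,
# look the sample up in the arrays, apply the missing-data rules.
naive_filter_eval <- function(ast, row, sample_index, strict_missing = FALSE) {
  if (ast$node == "and") {
    for (a in ast$args) if (!naive_filter_eval(a, row, sample_index, strict_missing)) return(FALSE)
    return(TRUE)
  }
  if (ast$node == "or") {
    for (a in ast$args) if (naive_filter_eval(a, row, sample_index, strict_missing)) return(TRUE)
    return(FALSE)
  }
  if (ast$node == "not") {
    return(!naive_filter_eval(ast$args[[1]], row, sample_index, strict_missing))
  }
  i <- sample_index[[ast$sample]]
  x <- row[[ast$column]][[i]]
  uncalled <- row$gt_types[[i]] == 2L
  if (strict_missing) {
    if (ast$column == "gt_depths") { if (row$gt_depths[[i]] < 0) return(FALSE) }
    else if (uncalled) return(FALSE)
  }
  if (ast$column %in% c("gts", "gt_types") && uncalled) {
    asks_unknown <- (ast$column == "gt_types" && identical(ast$literal, 2L)) ||
      (ast$column == "gts" && identical(ast$literal, "./."))
    if (!asks_unknown) return(FALSE)
  }
  res <- switch(ast$op,
                "==" = x == ast$literal, "!=" = x != ast$literal,
                "<" = x < ast$literal, "<=" = x <= ast$literal,
                ">" = x > ast$literal, ">=" = x >= ast$literal)
  isTRUE(res)
}

# --- random AST / genotype-row generators --------------------------------
random_cmp <- function(samples) {
  column <- sample(c("gts", "gt_types", "gt_phases", "gt_depths"), 1)
  op <- if (column %in% c("gts", "gt_phases")) sample(c("==", "!="), 1)
        else sample(c("==", "!=", "<", "<=", ">", ">="), 1)
  literal <- switch(column,
    gts = sample(c("A/G", "G/G", "A/A", "./."), 1),
    gt_types = sample(0:3, 1),
    gt_phases = sample(c(TRUE, FALSE), 1),
    gt_depths = sample(c(-1, 0, 5, 10, 30), 1))
  list(node = "cmp", column = column, sample = sample(samples, 1), op = op,
       literal = literal)
}

random_ast <- function(samples, depth = 2) {
  if (depth == 0 || runif(1) < 0.4) return(random_cmp(samples))
  node <- sample(c("and", "or", "not"), 1)
  if (node == "not") return(list(node = "not", args = list(random_ast(samples, depth - 1))))
  k <- sample(2:3, 1)
  list(node = node, args = lapply(seq_len(k), function(i) random_ast(samples, depth - 1)))
}

random_gt_row <- function(n_samples) {
  types <- sample(0:3, n_samples, replace = TRUE)
  gts <- c("A/A", "A/G", "./.", "G/G")[types + 1]
  list(gts = gts, gt_types = types,
       gt_phases = ifelse(types == 2L, FALSE, runif(n_samples) < 0.3),
       gt_depths = ifelse(runif(n_samples) < 0.1, -1L, sample(0:60, n_samples, replace = TRUE)))
}

# --- brute-force interval overlap ----------------------------------------
# all-pairs scan over 0-based half-open intervals
brute_force_overlaps <- function(var_df, iv_df) {
  hits <- list()
  strip <- function(x) sub("^chr", "", x)
  for (i in seq_len(nrow(var_df))) for (j in seq_len(nrow(iv_df))) {
    if (strip(var_df$chrom[i]) != strip(iv_df$chrom[j])) next
    if (var_df$start[i] < iv_df$end[j] && iv_df$start[j] < var_df$end[i]) {
      hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# per-variant overlap counts by all-pairs comparison, vectorized over the
# interval set for each variant (same exhaustive semantics, larger n)
brute_force_overlap_counts <- function(var_df, iv_df) {
  strip <- function(x) sub("^chr", "", x)
  vc <- strip(var_df$chrom); ic <- strip(iv_df$chrom)
  vapply(seq_len(nrow(var_df)), function(i) {
    sum(ic == vc[i] & var_df$start[i] < iv_df$end & iv_df$start < var_df$end[i])
  }, integer(1))
}

# --- breadth-first search distances (geneset oracle) ---------------------
bfs_distances <- function(edges, from) {
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  dist <- c(stats::setNames(0L, from))
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# --- misc ----------------------------------------------------------------
write_lines_tmp <- function(lines, ext = "") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

minimal_vcf <- function(body_lines, samples = character(0),
                        extra_header = character(0)) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"),
    body_lines), ext = ".vcf")
}

trio_ped <- function() {
  write_lines_tmp(c("fam1 dad 0 0 1 1",
                    "fam1 mom 0 0 2 1",
                    "fam1 kid dad mom 1 2"), ext = ".ped")
}

# build, load and open a tiny trio database from explicit genotype rows:
# rows = list(list(pos=, ref=, alt=, gts=c(dad, mom, kid), info=, dps=))
trio_db <- function(rows, ped = trio_ped(), chrom = "chr1") {
  body <- vapply(rows, function(r) {
    dps <- r$dps %||% rep(50L, length(r$gts))
    paste(c(r$chrom %||% chrom, r$pos, ".", r$ref %||% "A", r$alt %||% "G", "100", "PASS",
            r$info %||% ".", "GT:DP", paste0(r$gts, ":", dps)), collapse = "\t")
  }, character(1))
  vcf <- minimal_vcf(body, samples = c("dad", "mom", "kid"))
  db <- tempfile(fileext = ".db")
  vardb_load(db, vcf, ped = ped, overwrite = TRUE)
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a
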