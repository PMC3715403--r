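test_that("the filter grammar parses the published query idioms", {
  ast <- parse_gt_filter("gt_types.NA12878 == HET")
  expect_equal(ast$node, "cmp")
  expect_equal(ast[c("column", "sample", "op", "literal")],
               list(column = "gt_types", sample = "NA12878", op = "==", literal = 1L))
  # whitespace-tolerant equality spelling
  ast2 <- parse_gt_filter("gt_types.NA12878 =  = HET")
  expect_equal(ast2, ast)
  trio <- parse_gt_filter(
    "gt_types.mom == HET and gt_types.dad == HET and gt_types.proband == HOM_ALT")
  expect_equal(trio$node, "and")
  expect_length(trio$args, 3)
  expect_equal(trio$args[[3]]$literal, 3L)
  neg <- parse_gt_filter("not (gt_depths.kid >= 10)")
  expect_equal(neg$node, "not")
  expect_equal(neg$args[[1]]$op, ">=")
  # genotype-type names are case-insensitive; codes accepted directly
  expect_equal(parse_gt_filter("gt_types.s == hom_ref")$literal, 0L)
  expect_equal(parse_gt_filter("gt_types.s == 3")$literal, 3L)
  expect_equal(parse_gt_filter("gts.kid == 'A/G'")$literal, "A/G")
  expect_equal(parse_gt_filter("gts.kid == A/G")$literal, "A/G")
})

test_that("filter parse errors name the offending element", {
  expect_error(parse_gt_filter(""), class = "vardb_syntax_error")
  expect_error(parse_gt_filter("gt_bogus.kid == HET"), class = "vardb_column_error")
  err <- tryCatch(parse_gt_filter("gt_types.ghost == HET", samples = c("mom", "dad")),
                  error = identity)
  expect_s3_class(err, "vardb_sample_error")
  expect_match(conditionMessage(err), "ghost")
  expect_error(parse_gt_filter("gt_types.kid == "), class = "vardb_syntax_error")
  expect_error(parse_gt_filter("gt_types.kid == HET extra"), class = "vardb_syntax_error")
  expect_error(parse_gt_filter("gt_types.kid == NOTATYPE"), class = "vardb_syntax_error")
})

test_that("uncalled genotypes follow the documented comparison rules", {
  idx <- c(kid = 1L)
  called <- list(gts = "A/G", gt_types = 1L, gt_phases = FALSE, gt_depths = 20L)
  uncalled <- list(gts = "./.", gt_types = 2L, gt_phases = FALSE, gt_depths = -1L)
  het <- parse_gt_filter("gt_types.kid == HET")
  expect_true(evaluate_filter(het, called, idx))
  expect_false(evaluate_filter(het, uncalled, idx))
  # != is true only against called values
  ne <- parse_gt_filter("gt_types.kid != HOM_ALT")
  expect_true(evaluate_filter(ne, called, idx))
  expect_false(evaluate_filter(ne, uncalled, idx))
  # explicitly asking for unknowns works
  unk <- parse_gt_filter("gt_types.kid == UNKNOWN")
  expect_true(evaluate_filter(unk, uncalled, idx))
  expect_false(evaluate_filter(unk, called, idx))
  # missing depth (-1) follows numeric semantics by default ...
  lowdp <- parse_gt_filter("gt_depths.kid < 10")
  expect_true(evaluate_filter(lowdp, uncalled, idx))
  # ... and fails everything under strict_missing
  expect_false(evaluate_filter(lowdp, uncalled, idx, strict_missing = TRUE))
  expect_false(evaluate_filter(het, uncalled, idx, strict_missing = TRUE))
})

test_that("the evaluator agrees with an independent naive interpreter", {
  samples <- c("mom", "dad", "kid", "s4")
  idx <- stats::setNames(1:4, samples)
  set.seed(77)
  for (rep in 1:400) {
    ast <- random_ast(samples, depth = 2)
    row <- random_gt_row(4)
    strict <- runif(1) < 0.3
    expect_equal(evaluate_filter(ast, row, idx, strict_missing = strict),
                 naive_filter_eval(ast, row, idx, strict_missing = strict))
  }
})

test_that("pseudo-columns expand to per-sample values from the blobs", {
  rows <- list(
    list(pos = 100, gts = c("0/1", "0/0", "0/1")),
    list(pos = 110, gts = c("0/0", "1|1", "0/1")),
    list(pos = 120, gts = c("./.", "0/0", "1/1")))
  db <- trio_db(rows)
  s <- open_session(db)
  on.exit(close_session(s))
  out <- execute_query(s, "select chrom, gts.kid, gt_types.dad from variants")
  expect_equal(names(out), c("chrom", "gts.kid", "gt_types.dad"))
  expect_equal(out$`gts.kid`, c("A/G", "A/G", "G/G"))
  expect_equal(out$`gt_types.dad`, c(1, 0, 2))
  # selecting every sample equals the full unpacked arrays
  all_cols <- execute_query(s, "select gts.dad, gts.mom, gts.kid from variants")
  raw <- fetch_variants(s)
  for (i in 1:3) {
    expect_equal(unlist(all_cols[i, ], use.names = FALSE), raw$gts[[i]])
  }
  # no pseudo-columns: rows pass through the SQL engine untouched
  plain <- execute_query(s, "select variant_id, start from variants where start >= 109")
  expect_equal(plain$variant_id, c(2L, 3L))
  expect_error(execute_query(s, "select gts.nosuch from variants"),
               class = "vardb_sample_error")
})

test_that("queries combine SQL, annotations and genotype filters", {
  # three LoF variants planted, one of them rare
  ann <- function(gene, cons, imp) sprintf("ANN=G|%s|%s|%s|%s|t|TX_%s|pc|||", cons, imp, gene, gene, gene)
  rows <- list(
    list(pos = 100, gts = c("0/1", "0/0", "0/1"), info = ann("G1", "stop_gained", "HIGH")),
    list(pos = 110, gts = c("0/1", "0/1", "1/1"), info = ann("G2", "missense_variant", "MODERATE")),
    list(pos = 120, gts = c("0/0", "0/1", "0/0"), info = ann("G3", "frameshift_variant", "HIGH")),
    list(pos = 130, gts = c("0/0", "0/0", "0/1"), info = ann("G4", "intron_variant", "MODIFIER")))
  db <- trio_db(rows)
  s <- open_session(db)
  on.exit(close_session(s))
  lof <- execute_query(s, "select variant_id, gene from variants where is_lof = 1")
  expect_equal(lof$gene, c("G1", "G3"))
  rare_lof <- execute_query(s,
    "select variant_id from variants where is_lof = 1 and aaf < 0.2")
  expect_equal(rare_lof$variant_id, 3L) # aaf: v1 = 2/6, v3 = 1/6
  # genotype filter on top of SQL
  hits <- execute_query(s, "select variant_id from variants where is_lof = 1",
                        gt_filter = "gt_types.dad == HET")
  expect_equal(hits$variant_id, 1L)
  none <- execute_query(s, "select variant_id from variants",
                        gt_filter = "gt_types.kid == HOM_ALT and gt_types.mom == HOM_ALT")
  expect_equal(nrow(none), 0L)
  # select * keeps working under a filter
  star <- execute_query(s, "select * from variants", gt_filter = "gt_types.kid == HET")
  expect_equal(star$variant_id, c(1L, 4L))
  expect_error(execute_query(s, "select nope from variants"), class = "vardb_sql_error")
})

test_that("randomized queries agree with a brute-force scan", {
  fx <- simulate_cohort(8, 400, missing_rate = 0.08, seed = 15)
  db <- tempfile(fileext = ".db")
  vardb_load(db, fx$vcf, overwrite = TRUE)
  s <- open_session(db)
  on.exit(close_session(s))
  truth <- fx$truth
  samples <- fx$samples
  idx <- stats::setNames(seq_along(samples), samples)
  set.seed(16)
  for (rep in 1:25) {
    thr <- runif(1)
    cond <- sample(c("aaf", "call_rate", "num_het"), 1)
    sql_where <- switch(cond,
      aaf = sprintf("aaf < %f", thr),
      call_rate = sprintf("call_rate >= %f", thr),
      num_het = sprintf("num_het > %d", sample(0:4, 1)))
    keep_sql <- switch(cond,
      aaf = !is.na(truth$aaf) & truth$aaf < thr,
      call_rate = truth$call_rate >= thr,
      num_het = truth$num_het > as.integer(sub(".*> ", "", sql_where)))
    ast <- random_ast(samples, depth = 1)
    got <- execute_query(s, sprintf("select variant_id from variants where %s", sql_where),
                         gt_filter = ast)
    keep_flt <- vapply(seq_len(400), function(i) {
      row <- list(gts = fx$gts[i, ], gt_types = fx$gt_types[i, ],
                  gt_phases = rep(FALSE, 8), gt_depths = fx$depths[i, ])
      naive_filter_eval(ast, row, idx)
    }, logical(1))
    expect_equal(sort(got$variant_id), which(keep_sql & keep_flt))
    # monotonicity: the filtered set never exceeds the SQL-only set
    sql_only <- execute_query(s, sprintf("select variant_id from variants where %s", sql_where))
    expect_true(all(got$variant_id %in% sql_only$variant_id))
  }
})
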