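documented_variant_columns <- c(
  "variant_id", "chrom", "start", "end", "ref", "alt", "quality", "filter",
  "type", "sub_type", "gene", "transcript", "consequence", "impact_severity",
  "is_lof", "num_hom_ref", "num_het", "num_hom_alt", "num_unknown",
  "call_rate", "aaf", "hwe", "inbreeding_coeff", "pi",
  "gts", "gt_types", "gt_phases", "gt_depths")

test_that("schema creation builds the four documented tables with indexes", {
  db <- tempfile(fileext = ".db")
  vardb_create(db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  tables <- DBI::dbListTables(con)
  expect_true(all(c("variants", "variant_impacts", "samples", "resources") %in% tables))
  for (tb in c("variants", "variant_impacts", "samples", "resources")) {
    expect_equal(DBI::dbGetQuery(con, sprintf("SELECT count(*) n FROM %s", tb))$n, 0L)
  }
  # the full documented column inventory, including every stored statistic
  expect_equal(DBI::dbListFields(con, "variants"), documented_variant_columns)
  idx <- DBI::dbGetQuery(con, "SELECT name FROM sqlite_master WHERE type = 'index'")$name
  expect_true(all(c("idx_variants_pos", "idx_variants_gene", "idx_variants_islof",
                    "idx_variants_aaf") %in% idx))
  # refusal without overwrite; clean slate with it
  expect_error(vardb_create(db), class = "vardb_exists_error")
  expect_silent(vardb_create(db, overwrite = TRUE))
})

test_that("a trio VCF + PED loads with correct row accounting", {
  fx <- simulate_families(n_variants = 100, seed = 2)
  db <- tempfile(fileext = ".db")
  vardb_load(db, fx$vcf, ped = fx$ped, overwrite = TRUE)
  s <- open_session(db)
  on.exit(close_session(s))
  expect_equal(DBI::dbGetQuery(s$con, "SELECT count(*) n FROM variants")$n, 100L)
  expect_equal(nrow(s$samples), 6L)
  expect_equal(s$samples$name, fx$samples) # VCF header order preserved
  # one impact row per ANN block (fixture writes exactly one per variant)
  expect_equal(DBI::dbGetQuery(s$con, "SELECT count(*) n FROM variant_impacts")$n, 100L)
  expect_equal(DBI::dbGetQuery(s$con,
    "SELECT count(*) n FROM variant_impacts WHERE is_primary = 1")$n, 100L)
  res <- DBI::dbGetQuery(s$con, "SELECT name FROM resources")$name
  expect_true(all(c("vcf", "ped") %in% res))
  # pedigree fields came through
  kid <- s$samples[s$samples$name == "kid1", ]
  expect_equal(kid$paternal_id, "dad1")
  expect_equal(kid$phenotype, "affected")
})

test_that("load content is identical for any core count and batch size", {
  fx <- simulate_cohort(6, 300, missing_rate = 0.1, seed = 8)
  dumps <- lapply(list(list(cores = 1, chunk = 300, batch = 5000),
                       list(cores = 2, chunk = 50, batch = 64),
                       list(cores = 4, chunk = 77, batch = 10)),
                  function(cfg) {
    db <- tempfile(fileext = ".db")
    vardb_load(db, fx$vcf, cores = cfg$cores, chunk_size = cfg$chunk,
               batch_size = cfg$batch, overwrite = TRUE)
    vardb_dump(db)
  })
  expect_identical(dumps[[1]], dumps[[2]])
  expect_identical(dumps[[1]], dumps[[3]])
})

test_that("merge_chunks restores file order and rejects bad ranges", {
  fx <- simulate_cohort(3, 60, seed = 4)
  parsed <- read_vcf(fx$vcf)
  recs <- parsed$records
  single <- vardb:::process_in_chunks(recs, list(), "auto", NULL, chunk_size = 60L)
  merged_single <- merge_chunks(single)
  set.seed(5)
  for (rep in 1:3) {
    sizes <- diff(c(0, sort(sample(1:59, sample(2:5, 1))), 60))
    starts <- cumsum(c(1, head(sizes, -1)))
    chunks <- lapply(seq_along(sizes), function(i) {
      vardb:::process_chunk(recs[starts[i]:(starts[i] + sizes[i] - 1)], list(), "auto", NULL)
    })
    merged <- merge_chunks(chunks[sample(seq_along(chunks))]) # shuffled input
    expect_equal(vapply(merged$variants, `[[`, 0L, "variant_id"), 1:60)
    expect_identical(merged$variants, merged_single$variants)
  }
  # overlapping ranges are an integrity error
  c1 <- vardb:::process_chunk(recs[1:30], list(), "auto", NULL)
  c2 <- vardb:::process_chunk(recs[25:60], list(), "auto", NULL)
  expect_error(merge_chunks(list(c1, c2)), class = "vardb_integrity_error")
})

test_that("a zero-sample VCF loads with null statistics and empty blobs", {
  vcf <- minimal_vcf(c("chr1\t100\t.\tA\tG\t50\tPASS\t.",
                       "chr1\t200\t.\tC\tT\t50\tPASS\t."))
  db <- tempfile(fileext = ".db")
  vardb_load(db, vcf, overwrite = TRUE)
  s <- open_session(db)
  on.exit(close_session(s))
  v <- DBI::dbGetQuery(s$con, "SELECT aaf, call_rate, hwe, gts FROM variants")
  expect_true(all(is.na(v$aaf)) && all(is.na(v$hwe)))
  expect_equal(length(unpack(v$gts[[1]])), 0L)
  expect_equal(nrow(s$samples), 0L)
})

test_that("PED/VCF sample mismatches follow the declared contract", {
  vcf <- minimal_vcf("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:10\t0/0:12",
                     samples = c("alice", "bob"))
  stray <- write_lines_tmp(c("f alice 0 0 2 1", "f ghost 0 0 1 1"), ext = ".ped")
  expect_error(vardb_load(tempfile(fileext = ".db"), vcf, ped = stray, overwrite = TRUE),
               class = "vardb_validation_error")
  partial <- write_lines_tmp("f alice 0 0 2 1", ext = ".ped")
  db <- tempfile(fileext = ".db")
  expect_warning(vardb_load(db, vcf, ped = partial, overwrite = TRUE),
                 class = "vardb_warning")
  s <- open_session(db)
  on.exit(close_session(s))
  expect_true(is.na(s$samples$family_id[s$samples$name == "bob"]))
})

test_that("the database undercuts the uncompressed genotype serialization", {
  # 200 samples x 1000 variants of low-entropy genotypes (rare-variant AF
  # spectrum: most genotypes identical hom-ref)
  fx <- simulate_cohort(200, 1000, seed = 6)
  db <- tempfile(fileext = ".db")
  vardb_load(db, fx$vcf, overwrite = TRUE)
  tab_serialized <- sum(vapply(seq_len(1000), function(i) {
    sum(nchar(c(fx$gts[i, ], as.character(fx$gt_types[i, ]),
                as.character(fx$depths[i, ])))) + 3 * 200
  }, numeric(1)))
  expect_lt(file.size(db), tab_serialized)
})
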