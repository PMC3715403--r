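test_that("interval overlap respects half-open boundaries", {
  bed <- write_lines_tmp("chr1\t10\t20\tcpg1", ext = ".bed")
  tr <- annotation_track("cpg", bed, "bed", "boolean")
  inside <- list(chrom = "chr1", start = 15L, end = 16L)
  at_end <- list(chrom = "chr1", start = 20L, end = 21L)
  at_start <- list(chrom = "chr1", start = 9L, end = 10L)
  touching_start <- list(chrom = "chr1", start = 9L, end = 11L)
  expect_equal(annotate_variant(inside, tr), 1L)
  expect_equal(annotate_variant(at_end, tr), 0L)   # end is exclusive
  expect_equal(annotate_variant(at_start, tr), 0L) # variant ends before interval
  expect_equal(annotate_variant(touching_start, tr), 1L)
})

test_that("count and extract modes aggregate overlapping records", {
  bed <- write_lines_tmp(c("chr1\t5\t50\ttfbsB",
                           "chr1\t10\t20\ttfbsA",
                           "chr1\t15\t30\ttfbsA",
                           "chr2\t10\t20\ttfbsC"), ext = ".bed")
  counts <- annotation_track("tfbs_n", bed, "bed", "count")
  vals <- annotation_track("tfbs", bed, "bed", "extract", extract = 4)
  v <- list(chrom = "chr1", start = 16L, end = 17L)
  expect_equal(annotate_variant(v, counts), 3L)
  # unique values, lexicographically sorted, comma-joined
  expect_equal(annotate_variant(v, vals), "tfbsA,tfbsB")
  none <- list(chrom = "chr1", start = 60L, end = 61L)
  expect_equal(annotate_variant(none, counts), 0L)
  expect_true(is.na(annotate_variant(none, vals)))
  # numeric extraction takes the maximum
  bed2 <- write_lines_tmp(c("chr1\t0\t100\tx\t7", "chr1\t0\t100\ty\t12"), ext = ".bed")
  mx <- annotation_track("score", bed2, "bed", "extract", extract = 5, numeric = TRUE)
  expect_equal(annotate_variant(v, mx), 12)
})

test_that("chr prefix differences between variants and tracks are bridged", {
  bed <- write_lines_tmp("1\t10\t20", ext = ".bed")
  tr <- annotation_track("t", bed, "bed", "boolean")
  expect_equal(annotate_variant(list(chrom = "chr1", start = 12L, end = 13L), tr), 1L)
  bed2 <- write_lines_tmp("chr1\t10\t20", ext = ".bed")
  tr2 <- annotation_track("t", bed2, "bed", "boolean")
  expect_equal(annotate_variant(list(chrom = "1", start = 12L, end = 13L), tr2), 1L)
})

test_that("GFF tracks convert coordinates and expose attribute values", {
  gff <- write_lines_tmp(c("##gff-version 3",
                           "chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1;Name=GENE1"),
                         ext = ".gff")
  tr <- annotation_track("gname", gff, "gff", "extract", extract = "Name")
  # GFF 11..20 inclusive == 0-based [10, 20)
  expect_equal(annotate_variant(list(chrom = "chr1", start = 10L, end = 11L), tr), "GENE1")
  expect_true(is.na(annotate_variant(list(chrom = "chr1", start = 20L, end = 21L), tr)))
})

test_that("sites-VCF tracks reproduce dbSNP-style membership semantics", {
  sites <- minimal_vcf(c("chr1\t100\t.\tA\tG\t50\tPASS\t.",
                         "chr1\t200\t.\tC\tT\t50\tPASS\t."))
  tr <- annotation_track("in_dbsnp", sites, "vcf", "boolean")
  expect_equal(annotate_variant(list(chrom = "chr1", start = 99L, end = 100L,
                                     ref = "A", alt = "G"), tr), 1L)
  expect_equal(annotate_variant(list(chrom = "chr1", start = 150L, end = 151L,
                                     ref = "A", alt = "G"), tr), 0L)
  # position-only by default: allele mismatch still matches ...
  expect_equal(annotate_variant(list(chrom = "chr1", start = 99L, end = 100L,
                                     ref = "A", alt = "T"), tr), 1L)
  # ... but not with require_allele
  tr_strict <- annotation_track("in_dbsnp2", sites, "vcf", "boolean", require_allele = TRUE)
  expect_equal(annotate_variant(list(chrom = "chr1", start = 99L, end = 100L,
                                     ref = "A", alt = "T"), tr_strict), 0L)
})

test_that("randomized annotation equals brute-force all-pairs overlap", {
  for (seed in 1:5) {
    set.seed(seed)
    n_iv <- 200; n_var <- 200
    iv <- data.frame(chrom = sample(c("chr1", "chr2", "3"), n_iv, replace = TRUE),
                     start = sample(0:500, n_iv, replace = TRUE))
    iv$end <- iv$start + sample(1:30, n_iv, replace = TRUE)
    vars <- data.frame(chrom = sample(c("chr1", "2", "chr3"), n_var, replace = TRUE),
                       start = sample(0:520, n_var, replace = TRUE))
    vars$end <- vars$start + sample(1:3, n_var, replace = TRUE)
    bed <- write_lines_tmp(sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end), ext = ".bed")
    tr <- annotation_track("t", bed, "bed", "count")
    got <- vapply(seq_len(n_var), function(i) {
      annotate_variant(as.list(vars[i, ]), tr)
    }, integer(1))
    oracle <- brute_force_overlaps(vars, iv)
    expect_equal(got, tabulate(oracle[, 1], nbins = n_var))
  }
})

test_that("annotation is invariant to track file line order", {
  set.seed(99)
  iv <- data.frame(chrom = "chr1", start = sample(0:300, 80))
  iv$end <- iv$start + sample(1:20, 80, replace = TRUE)
  lines <- sprintf("chr1\t%d\t%d", iv$start, iv$end)
  tr1 <- annotation_track("t", write_lines_tmp(lines, ext = ".bed"), "bed", "count")
  tr2 <- annotation_track("t", write_lines_tmp(sample(lines), ext = ".bed"), "bed", "count")
  vars <- lapply(0:320, function(s) list(chrom = "chr1", start = s, end = s + 1L))
  expect_equal(vapply(vars, annotate_variant, 0L, track = tr1),
               vapply(vars, annotate_variant, 0L, track = tr2))
})

test_that("annotate_all enforces distinct, non-clashing column names", {
  bed <- write_lines_tmp("chr1\t0\t10", ext = ".bed")
  t1 <- annotation_track("dup", bed, "bed", "boolean")
  expect_error(annotate_all(list(), list(t1, t1)), class = "vardb_config_error")
  expect_error(annotate_all(list(), list(annotation_track("aaf", bed, "bed", "boolean")),
                            reserved = "aaf"),
               class = "vardb_config_error")
  expect_error(annotation_track("bad name!", bed, "bed", "boolean"),
               class = "vardb_config_error")
  # zero tracks -> zero added columns
  expect_equal(ncol(annotate_all(list(list(chrom = "chr1", start = 1L, end = 2L)),
                                 list())), 0L)
})

test_that("track config files round-trip into working tracks", {
  bed <- write_lines_tmp("chr1\t10\t20\tname1", ext = ".bed")
  cfg <- write_lines_tmp(c(
    sprintf("name=cpg;path=%s;format=bed;mode=boolean", bed),
    sprintf("name=lbl;path=%s;format=bed;mode=extract;extract=4", bed)))
  tracks <- read_track_config(cfg)
  expect_length(tracks, 2)
  v <- list(chrom = "chr1", start = 15L, end = 16L)
  expect_equal(annotate_variant(v, tracks[[1]]), 1L)
  expect_equal(annotate_variant(v, tracks[[2]]), "name1")
})
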