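# hand-built trio cases; sample order in trio_db is (dad, mom, kid)
test_that("de novo screening applies the defining genotype rules", {
  db <- trio_db(list(
    list(pos = 100, gts = c("0/0", "0/0", "0/1")),             # de novo
    list(pos = 110, gts = c("0/0", "0/1", "0/1")),             # inherited
    list(pos = 120, gts = c("0/0", "0/0", "0/1"), dps = c(50, 4, 50)), # low-depth parent
    list(pos = 130, gts = c("0/0", "./.", "0/1")),             # uncalled parent
    list(pos = 140, gts = c("1/1", "1/1", "0/1")),             # reversion
    list(pos = 150, gts = c("0/0", "0/0", "0/1"), chrom = "chrX"))) # sex chromosome
  hits <- find_de_novo(db)
  expect_equal(sort(hits$variant_id), c(1L, 3L))
  # depth gating excludes the low-depth site; monotone in min_depth
  expect_equal(find_de_novo(db, min_depth = 10)$variant_id, 1L)
  expect_length(find_de_novo(db, min_depth = 100)$variant_id, 0L)
  for (d in c(0, 5, 20, 60)) {
    expect_true(all(find_de_novo(db, min_depth = d)$variant_id %in%
                      find_de_novo(db)$variant_id))
  }
  # reversion case only behind the flag
  rev <- find_de_novo(db, include_reversions = TRUE)
  expect_true(5L %in% rev$variant_id)
})

test_that("recessive and dominant screens honor affection status", {
  db <- trio_db(list(
    list(pos = 100, gts = c("0/1", "0/1", "1/1")),  # recessive hit
    list(pos = 110, gts = c("0/1", "0/1", "0/1")),  # kid only HET
    list(pos = 120, gts = c("0/1", "0/0", "1/1")),  # parent not HET
    list(pos = 130, gts = c("0/1", "0/1", "./.")))) # uncalled kid
  hits <- find_autosomal_recessive(db)
  expect_equal(hits$variant_id, 1L)
  expect_equal(hits[, c("gt_child", "gt_father", "gt_mother")],
               data.frame(gt_child = "G/G", gt_father = "A/G", gt_mother = "A/G"),
               ignore_attr = TRUE)

  # dominant family: affected dad + kid, unaffected mom
  ped <- write_lines_tmp(c("fam1 dad 0 0 1 2",
                           "fam1 mom 0 0 2 1",
                           "fam1 kid dad mom 1 2"), ext = ".ped")
  db2 <- trio_db(list(
    list(pos = 100, gts = c("0/1", "0/0", "0/1")),  # hit: transmitted from affected dad
    list(pos = 110, gts = c("0/0", "0/0", "0/1")),  # kid-only: no affected parent carries
    list(pos = 120, gts = c("0/1", "0/1", "0/1")),  # unaffected mom carries
    list(pos = 130, gts = c("0/1", "0/0", "0/0"))), # affected kid not HET
    ped = ped)
  hits2 <- find_autosomal_dominant(db2)
  expect_equal(hits2$variant_id, 1L)
  expect_equal(hits2$sample, "dad,kid")
  # reduced-penetrance flag admits the unaffected carrier site
  relaxed <- find_autosomal_dominant(db2, allow_unaffected_carriers = TRUE)
  expect_equal(sort(relaxed$variant_id), c(1L, 3L))
})

test_that("screens demand usable family structure", {
  vcf <- minimal_vcf("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:10", samples = "solo")
  db <- tempfile(fileext = ".db")
  vardb_load(db, vcf, overwrite = TRUE)
  expect_error(find_de_novo(db), class = "vardb_no_trios_error")
  expect_error(find_autosomal_dominant(db), class = "vardb_no_trios_error")
  expect_error(find_comp_hets(db), class = "vardb_no_impacts_error")
})

test_that("compound heterozygotes require trans configuration", {
  ann <- function(gene) sprintf("ANN=G|missense_variant|MODERATE|%s|%s|t|TX|pc|||", gene, gene)
  db <- trio_db(list(
    # trans pair in GENE1: site 1 from mom, site 2 from dad
    list(pos = 100, gts = c("0/0", "0/1", "0/1"), info = ann("GENE1")),
    list(pos = 110, gts = c("0/1", "0/0", "0/1"), info = ann("GENE1")),
    # cis pair in GENE2: both from mom
    list(pos = 120, gts = c("0/0", "0/1", "0/1"), info = ann("GENE2")),
    list(pos = 130, gts = c("0/0", "0/1", "0/1"), info = ann("GENE2")),
    # phased trans pair in GENE3
    list(pos = 140, gts = c("0|0", "1|0", "1|0"), info = ann("GENE3")),
    list(pos = 150, gts = c("0|0", "0|1", "0|1"), info = ann("GENE3")),
    # phased cis pair in GENE4
    list(pos = 160, gts = c("0|0", "1|0", "0|1"), info = ann("GENE4")),
    list(pos = 170, gts = c("0|0", "1|0", "0|1"), info = ann("GENE4")),
    # HET pair across different genes: not a candidate pair
    list(pos = 180, gts = c("0/0", "0/1", "0/1"), info = ann("GENE5")),
    list(pos = 190, gts = c("0/1", "0/0", "0/1"), info = ann("GENE6"))))
  hits <- find_comp_hets(db)
  kid_hits <- hits[hits$sample == "kid", ]
  expect_setequal(kid_hits$gene, c("GENE1", "GENE3"))
  expect_equal(kid_hits$priority[kid_hits$gene == "GENE1"], "parental_trans")
  expect_equal(kid_hits$priority[kid_hits$gene == "GENE3"], "phased_trans")
})

test_that("severity floor gates comp-het candidates monotonically", {
  ann <- function(gene, cons, imp) sprintf("ANN=G|%s|%s|%s|%s|t|TX|pc|||", cons, imp, gene, gene)
  db <- trio_db(list(
    list(pos = 100, gts = c("0/0", "0/1", "0/1"), info = ann("G1", "stop_gained", "HIGH")),
    list(pos = 110, gts = c("0/1", "0/0", "0/1"), info = ann("G1", "intron_variant", "MODIFIER")),
    list(pos = 120, gts = c("0/0", "0/1", "0/1"), info = ann("G2", "missense_variant", "MODERATE")),
    list(pos = 130, gts = c("0/1", "0/0", "0/1"), info = ann("G2", "missense_variant", "MODERATE"))))
  expect_equal(find_comp_hets(db)$gene, "G2") # default MED floor drops the intron partner
  low <- find_comp_hets(db, min_severity = "LOW")
  expect_setequal(low$gene, c("G1", "G2"))
  expect_equal(nrow(find_comp_hets(db, min_severity = "HIGH")), 0L)
})

test_that("planted fixture events are recovered exactly across seeds", {
  for (seed in c(101, 202)) {
    fx <- simulate_families(n_variants = 300, seed = seed)
    db <- tempfile(fileext = ".db")
    vardb_load(db, fx$vcf, ped = fx$ped, overwrite = TRUE)
    s <- open_session(db)
    expect_identical(sort(find_de_novo(s)$variant_id), sort(fx$truth$de_novo))
    expect_identical(sort(find_autosomal_recessive(s)$variant_id), sort(fx$truth$recessive))
    expect_identical(sort(find_autosomal_dominant(s)$variant_id), sort(fx$truth$dominant))
    ch <- find_comp_hets(s)
    got_pairs <- unique(data.frame(variant_a = pmin(ch$variant_id_a, ch$variant_id_b),
                                   variant_b = pmax(ch$variant_id_a, ch$variant_id_b)))
    want <- fx$truth$comp_het_trans[, c("variant_a", "variant_b")]
    expect_identical(got_pairs[order(got_pairs$variant_a), ],
                     want[order(want$variant_a), ], ignore_attr = TRUE)
    close_session(s)
  }
})

test_that("every recessive hit is reproduced by the equivalent DSL query", {
  fx <- simulate_families(n_variants = 300, seed = 55)
  db <- tempfile(fileext = ".db")
  vardb_load(db, fx$vcf, ped = fx$ped, overwrite = TRUE)
  s <- open_session(db)
  on.exit(close_session(s))
  hits <- find_autosomal_recessive(s)
  # the published filter idiom for the recessive pattern, restricted to the
  # affected-child trio of the fixture (kid1, parents unaffected)
  dsl <- execute_query(s, "select variant_id, chrom from variants",
    gt_filter = "gt_types.mom1 == HET and gt_types.dad1 == HET and gt_types.kid1 == HOM_ALT")
  dsl <- dsl[!dsl$chrom %in% c("X", "Y", "chrX", "chrY"), ]
  expect_true(all(hits$variant_id %in% dsl$variant_id))
  expect_identical(sort(hits$variant_id), sort(dsl$variant_id))
})

test_that("recorded hit genotypes re-derive their pattern", {
  fx <- simulate_families(n_variants = 200, seed = 77)
  db <- tempfile(fileext = ".db")
  vardb_load(db, fx$vcf, ped = fx$ped, overwrite = TRUE)
  s <- open_session(db)
  on.exit(close_session(s))
  dn <- find_de_novo(s)
  expect_true(all(dn$gt_father == dn$gt_mother)) # both parents hom-ref
  expect_true(all(substr(dn$gt_child, 1, 1) != substr(dn$gt_child, 3, 3))) # child het
  ar <- find_autosomal_recessive(s)
  expect_true(all(substr(ar$gt_child, 1, 1) == substr(ar$gt_child, 3, 3)))
})
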