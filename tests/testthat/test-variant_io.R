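test_that("VCF insertion extraction follows the ALT-longer-than-REF rule", {
  path <- write_toy_vcf(c(
    "chr1\t100\tr1\tA\tACGT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\tr2\tAT\tA\t.\tPASS\t.\tGT\t0/1",            # deletion
    "chr1\t300\tr3\tC\tG\t.\tPASS\t.\tGT\t1/1",             # SNV
    "chr1\t400\tr4\tG\t<INS>\t.\tPASS\tSVTYPE=INS\tGT\t0/1",
    "chr2\t500\tr5\tT\tTACGTACGT\t.\tPASS\t.\tGT\t1/1"))
  cs <- read_vcf_insertions(path, "generic")
  expect_equal(nrow(cs$records), 3)
  expect_equal(sum(cs$records$resolved), 2)
  r1 <- cs$records[cs$records$record_id == "r1", ]
  expect_equal(r1$pos, 100L)
  expect_equal(r1$inserted_seq, "CGT")
  expect_equal(r1$size, 3L)
  sym <- cs$records[!cs$records$resolved, ]
  expect_equal(sym$record_id, "r4")
  expect_equal(sym$inserted_seq, "")
})

test_that("empty VCF bodies and multi-allelic records are handled", {
  cs <- read_vcf_insertions(write_toy_vcf(character(0)), "generic")
  expect_equal(nrow(cs$records), 0)
  cs2 <- read_vcf_insertions(write_toy_vcf(
    "chr1\t100\tm1\tA\tACGT,AGGAGG\t.\tPASS\t.\tGT\t1/2"))
  expect_equal(nrow(cs2$records), 2)
  expect_setequal(cs2$records$inserted_seq, c("CGT", "GGAGG"))
})

test_that("REF/ALT prefix disagreement is a record-level error, not fatal", {
  cs <- read_vcf_insertions(write_toy_vcf(c(
    "chr1\t100\tok\tA\tACGTACGT\t.\tPASS\t.\tGT\t1/1",
    "chr1\t200\tbad\tA\tCGGGGG\t.\tPASS\t.\tGT\t1/1")))
  expect_equal(nrow(cs$records), 1)
  expect_match(attr(cs, "record_errors"), "bad")
})

test_that("gold-standard filters remove by size, resolution and LongHomRef with counts", {
  toy <- callset(rbind(rec_row("a", 100, 40),
                       rec_row("b", 200, 60),
                       rec_row("c", 300, 60, filter = "LongHomRef"),
                       rec_row("d", 400, 60, resolved = FALSE)),
                 convention = "giab")
  out <- apply_goldstandard_filters(toy, filter_config())
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$record_id, "b")
  rc <- attr(out, "removal_counts")
  expect_equal(rc[["size"]], 1L)
  expect_equal(rc[["longhomref"]], 1L)
  expect_equal(rc[["unresolved"]], 1L)
})

test_that("filtering is idempotent and permissive configs are the identity", {
  toy <- callset(rbind(rec_row("a", 100, 40), rec_row("b", 200, 60),
                       rec_row("c", 300, 55, filter = "LowQual")))
  once <- apply_goldstandard_filters(toy, filter_config())
  twice <- apply_goldstandard_filters(once, filter_config())
  expect_identical(once$records, twice$records)
  all_off <- apply_goldstandard_filters(
    toy, filter_config(min_size = 0, require_sequence_resolved = FALSE,
                       drop_longhomref = FALSE))
  expect_identical(all_off$records, toy$records)
})

test_that("core-genome restriction uses the chromosome allow-list", {
  toy <- callset(rbind(rec_row("a", 100, 60, chrom = "chr3"),
                       rec_row("b", 200, 60, chrom = "chr3"),
                       rec_row("c", 300, 60, chrom = "chr3_alt"),
                       rec_row("d", 400, 60, chrom = "chrUn_KI270302v1")))
  out <- apply_goldstandard_filters(toy, filter_config(chrom_allowlist = "chr3"))
  expect_equal(nrow(out$records), 2)
  expect_equal(attr(out, "removal_counts")[["core_genome"]], 2L)
})

test_that("discovery technology parsing partitions records into two classes", {
  ch <- callset(rbind(rec_row("x", 100, 60, info = "UNION=Illumina"),
                      rec_row("y", 200, 60, info = "UNION=Pacbio"),
                      rec_row("z", 300, 60, info = "UNION=Bionano")),
                convention = "chaisson")
  d <- parse_discovery_technology(ch)
  expect_equal(as.character(d), c("short_read", "other", "other"))
  expect_true(all(levels(d) == c("short_read", "other")))
  expect_equal(sum(d == "short_read") + sum(d == "other"), 3)

  gi <- callset(rbind(
    rec_row("x", 100, 60, info = "ExactMatchID=HG2_Ill_svaba_1,HG2_PB_pbsv_2"),
    rec_row("y", 200, 60, info = "ExactMatchID=HG2_PB_pbsv_3,HG2_Ill_refine_4"),
    rec_row("z", 300, 60, info = "ExactMatchID=HG2_PB_pbsv_9"),
    rec_row("w", 400, 60, info = ".")),
    convention = "giab")
  d2 <- parse_discovery_technology(gi)
  expect_equal(as.character(d2), c("short_read", "other", "other", "other"))
  expect_equal(attr(d2, "n_missing_tag"), 1L)
})

test_that("write/read round-trip preserves retained fields and is byte-stable", {
  set.seed(31)
  g <- c(chr1 = rand_seq(5000))
  recs <- do.call(rbind, lapply(1:30, function(i) {
    rec_row(sprintf("r%02d", i), pos = 50 + i * 100, len = 0,
            filter = sample(c("PASS", "LowQual"), 1),
            geno = sample(c("0/1", "1/1"), 1), seq = rand_seq(sample(51:120, 1)))
  }))
  cs <- callset(recs)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(cs, f1, genome = g)
  back <- read_vcf_insertions(f1)
  expect_identical(back$records$pos, cs$records$pos)
  expect_identical(back$records$inserted_seq, cs$records$inserted_seq)
  expect_identical(back$records$filter, cs$records$filter)
  expect_identical(back$records$genotype, cs$records$genotype)
  write_vcf(cs, f2, genome = g)
  expect_identical(readLines(f1), readLines(f2))
  # empty callset: header only
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(callset(), f3)
  expect_false(any(!startsWith(readLines(f3), "#")))
})
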