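test_that("the default suite enumerates 22 datasets and subsets restrict it", {
  suite <- build_scenario_suite()
  expect_equal(nrow(suite), 22)
  expect_true(all(suite$n_insertions == 200))
  expect_equal(sum(suite$scenario == "baseline"), 1)
  expect_equal(nrow(build_scenario_suite(scenarios = "size")), 3)
  expect_equal(sum(build_scenario_suite()$scenario == "homology"), 5)
})

test_that("baseline insertions are novel 250 bp exonic with zero junctional homology", {
  gen <- fx_genome()
  tb <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 15, seed = 3)
  expect_equal(nrow(tb), 15)
  expect_true(all(tb$size == 250))
  ctx <- classify_site(tb$chrom, tb$pos, gen$tracks)
  expect_true(all(ctx$genic_context == "exonic"))
  hom <- vapply(seq_len(nrow(tb)), function(i)
    junctional_homology_size(tb$chrom[i], tb$pos[i], tb$inserted_seq[i], gen$genome)$total_size,
    integer(1))
  expect_true(all(hom == 0))
})

test_that("size scenarios keep the baseline locations with resized donors", {
  gen <- fx_genome()
  tb <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 10, seed = 3)
  for (s in c(50, 1000)) {
    ts <- generate_insertions("size", s, gen, fx_donors(), n = 10, seed = 3)
    expect_equal(ts$pos, tb$pos)
    expect_true(all(ts$size == s))
  }
})

test_that("type scenarios build sequences matching their designed class", {
  gen <- fx_genome()
  tt <- generate_insertions("type", "tr_seed6", gen, fx_donors(), n = 5, seed = 3)
  for (i in 1:5) {
    tr <- find_tandem_structure(tt$inserted_seq[i])
    expect_equal(tr$seed_size[1], 6L)
    expect_gte(tr$coverage[1], 0.95)
  }
  td <- generate_insertions("type", "tandem_dup", gen, fx_donors(), n = 5, seed = 3)
  g <- gen$genome[["chr1"]]
  for (i in 1:5) {
    expect_equal(td$inserted_seq[i], substr(g, td$pos[i] + 1, td$pos[i] + 250))
  }
  tm <- generate_insertions("type", "mobile_element", gen, fx_donors(), n = 5, seed = 3)
  expect_true(all(tm$size >= 200 & tm$size <= 300))
})

test_that("homology scenarios carry exactly X bases of right-junction homology", {
  gen <- fx_genome()
  for (X in c(10, 50, 150)) {
    th <- generate_insertions("homology", X, gen, fx_donors(), n = 6, seed = 3)
    h <- lapply(seq_len(nrow(th)), function(i)
      junctional_homology_size(th$chrom[i], th$pos[i], th$inserted_seq[i], gen$genome))
    expect_true(all(vapply(h, `[[`, 0L, "right_size") == X))
    expect_true(all(vapply(h, `[[`, 0L, "total_size") == X))
  }
})

test_that("context scenarios place sites in the requested class; proximal pairs are close", {
  gen <- fx_genome()
  tc <- generate_insertions("context", "sine", gen, fx_donors(), n = 8, seed = 3)
  ctx <- classify_site(tc$chrom, tc$pos, gen$tracks)
  expect_true(all(as.character(ctx$repeat_context) %in% c("sine", "simple_repeat")))
  tp <- generate_insertions("context", "proximal", gen, fx_donors(), n = 10, seed = 3)
  d <- diff(tp$pos)
  # each pair is separated by a 5-150 bp gap
  expect_true(all(sort(d)[seq_len(nrow(tp) %/% 2)] <= 150))
})

test_that("applying insertions conserves length and matches a naive rebuild", {
  g <- c(chrA = strrep("ACGT", 250))
  truth <- data.frame(chrom = "chrA", pos = c(100L, 400L),
                      inserted_seq = c("TTTTT", "GGGGGGG"), stringsAsFactors = FALSE)
  mut <- apply_insertions(g, truth)
  expect_equal(nchar(mut[["chrA"]]), 1000 + 5 + 7)
  naive <- paste0(substr(g, 1, 100), "TTTTT", substr(g, 101, 400), "GGGGGGG",
                  substr(g, 401, 1000))
  expect_equal(unname(mut["chrA"]), naive)
  expect_identical(apply_insertions(g, truth[0, ]), g)
  dup <- truth; dup$pos <- c(100L, 100L)
  expect_error(apply_insertions(g, dup), "collision")
})

test_that("truth VCFs are homozygous, label-carrying and round-trip exactly", {
  gen <- fx_genome()
  tb <- generate_insertions("homology", 20, gen, fx_donors(), n = 8, seed = 3)
  f <- tempfile(fileext = ".vcf")
  write_truth_vcf(tb, gen$genome, f)
  back <- read_vcf_insertions(f)
  expect_equal(back$records$pos, tb$pos)
  expect_equal(back$records$inserted_seq, tb$inserted_seq)
  expect_true(all(back$records$genotype == "1/1"))
  expect_equal(unname(inschar:::.info_tag(back$records$info, "EXPHOM")),
               rep("20", 8))
  expect_equal(unname(inschar:::.info_tag(back$records$info, "TYPE")),
               rep("novel_sequence", 8))
})

test_that("identical scenario and seed give byte-identical truth VCFs", {
  gen <- fx_genome()
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  t1 <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 10, seed = 8)
  t2 <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 10, seed = 8)
  write_truth_vcf(t1, gen$genome, f1)
  write_truth_vcf(t2, gen$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})
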