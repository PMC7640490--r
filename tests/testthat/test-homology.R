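test_that("strict scan counts identical bases outward from the insertion site", {
  # left side: flank ...TTACGT vs insertion ...NNACGT -> 4 identical then mismatch
  left <- paste0("GGGG", "TTACGT")
  ins <- paste0(strrep("G", 244), "NNACGT")
  sm <- small_homology(left, "CCCCCCCCCC", ins)
  expect_equal(sm$left, 4L)
  # first compared base differs on both sides
  sm0 <- small_homology("AAAAAAAAAA", "AAAAAAAAAA", "CGGGGGGGGC")
  expect_equal(sm0$left, 0L)
  expect_equal(sm0$right, 0L)
  # right side saturates at the 10 bp cap
  rf <- "ACGTACGTAC"
  smr <- small_homology("GGGGGGGGGG", rf, paste0(rf, strrep("T", 240)))
  expect_equal(smr$right, 10L)
  # shorter insertions cap the comparison at the insertion length
  sms <- small_homology("GGGGGGGGGG", "ACGTAAAAAA", "ACGT")
  expect_equal(smr$left, 0L)
  expect_equal(sms$right, 4L)
})

test_that("alignment-based homology applies the distance rules and overlap removal", {
  set.seed(51)
  # force mismatches at positions `at` of `s` relative to reference `ref_seq`
  # (several in a row, so score-positive chance extensions cannot bridge them)
  guard <- function(s, at, ref_seq) {
    for (a in at) {
      r <- substr(ref_seq, a, a)
      if (substr(s, a, a) == r) substr(s, a, a) <- setdiff(c("A", "C", "G", "T"), r)[1]
    }
    s
  }
  # no overlap: left copy covers ins[201,250], right covers ins[1,60] -> 110
  ins <- rand_seq(250)
  left_w <- paste0(rand_seq(200), substr(ins, 201, 250))
  left_w <- guard(left_w, 196:200, ins)
  right_w <- paste0(substr(ins, 1, 60), rand_seq(190))
  right_w <- guard(right_w, 61:65, ins)
  h <- large_homology(left_w, right_w, ins)
  expect_equal(h$left_size, 50L)
  expect_equal(h$right_size, 60L)
  expect_equal(h$total_size, 110L)
  # overlap on the inserted sequence: 60 + 70 - 30 = 100, capped by ins length
  ins2 <- rand_seq(100)
  left_w2 <- paste0(rand_seq(40), substr(ins2, 41, 100))
  left_w2 <- guard(left_w2, 36:40, ins2)
  right_w2 <- paste0(substr(ins2, 1, 70), rand_seq(30))
  right_w2 <- guard(right_w2, 71:75, ins2)
  h2 <- large_homology(left_w2, right_w2, ins2)
  expect_equal(h2$total_size, 100L)
  expect_equal(h2$left_size + h2$right_size - 30L, h2$total_size)
  # total never exceeds the per-side sum
  expect_lte(h$total_size, h$left_size + h$right_size)
  expect_lte(h2$total_size, h2$left_size + h2$right_size)
})

test_that("two-tier homology measures designed junction constructions exactly", {
  set.seed(52)
  g <- c(chr1 = rand_seq(60000))
  pos <- 30000L
  gs <- g[["chr1"]]
  # left = 3, right = 5 exact junction copies, mismatches beyond
  ins <- rand_seq(250)
  substr(ins, 1, 5) <- substr(gs, pos + 1, pos + 5)
  substr(ins, 248, 250) <- substr(gs, pos - 2, pos)
  fix_at <- function(ins, at, ref) {
    if (substr(ins, at, at) == ref) substr(ins, at, at) <- setdiff(c("A", "C", "G", "T"), ref)[1]
    ins
  }
  ins <- fix_at(ins, 6, substr(gs, pos + 6, pos + 6))
  ins <- fix_at(ins, 247, substr(gs, pos - 3, pos - 3))
  h <- junctional_homology_size("chr1", pos, ins, g)
  expect_equal(h$left_size, 3L)
  expect_equal(h$right_size, 5L)
  expect_equal(h$total_size, 8L)
  expect_equal(h$method, "strict_scan")
  # a simulated tandem duplication reaches at least the insertion size
  dup <- substr(gs, pos + 1, pos + 250)
  hd <- junctional_homology_size("chr1", pos, dup, g)
  expect_gte(hd$total_size, 250L)
  expect_equal(hd$method, "alignment")
})

test_that("random insertions at random sites show only chance-level homology", {
  set.seed(53)
  g <- c(chr1 = rand_seq(100000))
  tot <- vapply(1:30, function(i) {
    junctional_homology_size("chr1", sample(2000:98000, 1), rand_seq(250), g)$total_size
  }, integer(1))
  expect_lte(max(tot), 12L)    # pairs of >6 bp chance matches are ~1e-8 events
  expect_gt(mean(tot <= 3), 0.8)
})

test_that("the alignment tier refines a capped strict scan (lower-bound property)", {
  set.seed(54)
  g <- c(chr1 = rand_seq(60000))
  pos <- 20000L
  gs <- g[["chr1"]]
  for (X in c(15L, 40L)) {
    ins <- rand_seq(250)
    substr(ins, 1, X) <- substr(gs, pos + 1, pos + X)
    if (substr(ins, X + 1, X + 1) == substr(gs, pos + X + 1, pos + X + 1)) {
      substr(ins, X + 1, X + 1) <- setdiff(c("A", "C", "G", "T"),
                                           substr(gs, pos + X + 1, pos + X + 1))[1]
    }
    strict <- small_homology(substr(gs, pos - 9, pos), substr(gs, pos + 1, pos + 10), ins)
    h <- junctional_homology_size("chr1", pos, ins, g)
    expect_equal(strict$right, 10L)      # capped
    expect_gte(h$right_size, strict$right)
    # the 90%-identity alignment may legitimately extend a little past the
    # planted copy; it can never report less than the planted size
    expect_gte(h$right_size, X)
    expect_lte(h$right_size, X + 10L)
  }
})

test_that("the random-insertion null is seed-deterministic and edge cases hold", {
  set.seed(55)
  g <- c(chr1 = rand_seq(200000))
  expect_equal(random_null_homology(g, n = 0)$max, 0L)
  a <- random_null_homology(g, n = 150, seed = 7)
  b <- random_null_homology(g, n = 150, seed = 7)
  expect_identical(a$sizes, b$sizes)
  expect_equal(length(a$sizes), 150)
  # null maxima stay in the chance regime regardless of seed
  c2 <- random_null_homology(g, n = 150, seed = 8)
  expect_lte(max(a$max, c2$max), 10L)
})
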