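test_that("global identity counts matches over alignment columns and is symmetric", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(global_identity("AAAA", "AAAT"), 0.75)
  set.seed(41)
  a <- rand_seq(250)
  ch <- strsplit(a, "")[[1]]
  idx <- sample(250, 25)
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  b <- paste(ch, collapse = "")
  # known edit script: 25 substitutions in 250 columns
  expect_equal(global_identity(a, b), 0.90)
  expect_equal(global_identity(a, b), global_identity(b, a))
  expect_error(global_identity("", "ACGT"), "nonempty")
})

test_that("local alignment recovers planted segments on both strands", {
  set.seed(42)
  tgt <- rand_seq(5000)
  q <- substr(tgt, 2001, 2100)
  al <- local_align(q, tgt)
  expect_equal(nrow(al), 1)
  expect_equal(al$identity, 1)
  expect_equal(c(al$query_start, al$query_end), c(1L, 100L))
  expect_equal(c(al$target_start, al$target_end), c(2001L, 2100L))
  # 5 substitutions -> identity 0.95
  ch <- strsplit(q, "")[[1]]
  for (i in c(10, 30, 50, 70, 90)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  al5 <- local_align(paste(ch, collapse = ""), tgt)
  expect_equal(al5$identity[1], 0.95)
  # reverse complement -> minus strand
  alrc <- local_align(inschar:::.revcomp(q), tgt)
  expect_equal(alrc$strand, "-")
  expect_equal(c(alrc$target_start, alrc$target_end), c(2001L, 2100L))
  # preconditions
  expect_error(local_align("ACGTACGTACGT", tgt), "20")
  expect_error(local_align(paste0(strrep("N", 15), "ACGTA"), tgt), "N")
})

test_that("seeded alignment agrees with the full dynamic-programming oracle", {
  set.seed(43)
  for (case in 1:6) {
    qlen <- sample(60:200, 1)
    q <- rand_seq(qlen)
    mut <- inschar:::.mutate_seq(q, 0.05)
    tgt <- paste0(rand_seq(100), mut, rand_seq(100))
    # oracle: one full Smith-Waterman over the entire pair, no seeding
    or <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(tgt), type = "local",
      substitutionMatrix = inschar:::.sub_mat(), gapOpening = 5, gapExtension = 2)
    op <- as.character(Biostrings::alignedPattern(or))
    os <- as.character(Biostrings::alignedSubject(or))
    oid <- inschar:::.aln_identity(op, os)$identity
    al <- local_align(q, tgt, min_identity = 0.8)
    expect_gt(nrow(al), 0)
    expect_lt(abs(al$identity[1] - oid), 0.02 + 1e-9)
    # the oracle's region is recovered
    expect_lt(abs(al$target_start[1] - IRanges::start(Biostrings::subject(or))), 10)
  }
})

test_that("tandem structure detection reports seed, copy number and coverage", {
  tr <- find_tandem_structure(strrep("ACG", 50))
  expect_equal(tr$seed_size[1], 3L)
  expect_equal(tr$copy_number[1], 50)
  expect_equal(tr$coverage[1], 1)
  # 6 bp seed, 42 copies, one substitution every 10 copies
  set.seed(44)
  seedm <- "ACGGTT"
  arr <- strsplit(strrep(seedm, 42), "")[[1]]
  for (p in seq(30, length(arr), by = 60)) arr[p] <- setdiff(c("A", "C", "G", "T"), arr[p])[1]
  tr2 <- find_tandem_structure(paste(arr, collapse = ""))
  expect_equal(tr2$seed_size[1], 6L)
  expect_gte(tr2$coverage[1], 0.9)
})

test_that("tandem detection agrees with a brute-force period scan on random sequence", {
  set.seed(45)
  s <- rand_seq(250)
  # oracle: exhaustive scan over all periods, longest low-divergence run
  ch <- strsplit(s, "")[[1]]
  brute_best <- 0
  for (p in 1:125) {
    mism <- as.integer(ch[1:(250 - p)] != ch[(p + 1):250])
    run <- inschar:::.longest_low_div_run(mism, 0.10)
    if (!is.null(run) && run[2] >= p) brute_best <- max(brute_best, (run[2] + p) / 250)
  }
  tr <- find_tandem_structure(s, min_coverage = 0.1)
  got <- if (nrow(tr)) tr$coverage[1] else 0
  expect_lt(brute_best, 0.8)
  expect_lt(got, 0.8)
})

test_that("tandem detection is invariant to cyclic rotation of the seed", {
  motif <- "ACGGTC"
  rots <- vapply(0:5, function(r) {
    m <- paste0(substr(motif, r + 1, 6), substr(motif, 1, r))
    tr <- find_tandem_structure(strtrim(strrep(m, 45), 250))
    paste(tr$seed_size[1], tr$coverage[1])
  }, character(1))
  expect_equal(length(unique(rots)), 1)
})

test_that("genomic copy counting finds planted loci and honours thresholds", {
  set.seed(46)
  piece <- rand_seq(120)
  bgs <- replicate(31, rand_seq(900))
  g <- c(chr1 = paste(c(rbind(bgs[1:30], piece), bgs[31]), collapse = ""))
  expect_equal(count_genomic_copies(piece, g), 30)
  expect_equal(count_genomic_copies(rand_seq(100), g), 0)
  # monotone non-increasing in min_identity and min_query_cov
  gmut <- c(chr1 = paste(c(rbind(vapply(bgs[1:30], function(b)
    inschar:::.mutate_seq(piece, 0.06), character(1)), bgs[1:30]), bgs[31]), collapse = ""))
  # loci at 6% divergence: present at 0.90 identity, absent at 0.99
  c90 <- count_genomic_copies(piece, gmut, min_identity = 0.90)
  c99 <- count_genomic_copies(piece, gmut, min_identity = 0.99)
  expect_lte(c99, c90)
  c_cov50 <- count_genomic_copies(piece, g, min_query_cov = 0.5)
  c_cov99 <- count_genomic_copies(piece, g, min_query_cov = 0.99)
  expect_lte(c_cov99, c_cov50)
})
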