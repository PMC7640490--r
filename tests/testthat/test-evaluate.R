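test_that("call filtering keeps PASS calls above the size floor", {
  toy <- callset(rbind(rec_row("a", 100, 60, filter = "PASS"),
                       rec_row("b", 200, 40, filter = "PASS"),
                       rec_row("c", 300, 60, filter = "LowQual")))
  expect_equal(nrow(filter_calls(toy)$records), 1)
  expect_equal(nrow(filter_calls(toy, match_config(pass_only = FALSE))$records), 2)
  expect_equal(nrow(filter_calls(callset())$records), 0)
})

test_that("symbolic duplication calls resolve from reference coordinates", {
  set.seed(81)
  g <- c(chr1 = rand_seq(5000))
  rec <- rbind(
    rec_row("s1", 3000, 0, info = "SVTYPE=DUP;DUPCOORDS=chr1:101-350", resolved = FALSE),
    rec_row("s2", 3500, 0, info = "SVTYPE=DUP;DUPCOORDS=garbage", resolved = FALSE))
  rs <- resolve_symbolic(callset(rec), g)
  r <- rs$records[order(rs$records$record_id), ]
  expect_true(r$resolved[1])
  expect_equal(r$size[1], 250L)
  expect_equal(r$inserted_seq[1], unname(substr(g, 101, 350)))
  expect_false(r$resolved[2])
  # a resolved copy identical to the truth counts as a sequence TP downstream
  truth <- data.frame(chrom = "chr1", pos = 3000L,
                      inserted_seq = substr(g, 101, 350), stringsAsFactors = FALSE)
  rep <- match_and_score(truth, rs)
  expect_equal(rep$n_tp_seq, 1)
})

test_that("site margin, size tolerance and identity thresholds are exact boundaries", {
  set.seed(82)
  truth_seq <- rand_seq(250)
  truth <- data.frame(chrom = "chr1", pos = 1000L, inserted_seq = truth_seq,
                      stringsAsFactors = FALSE)
  call_at <- function(pos, seq = truth_seq, id = "c1")
    callset(rec_row(id, pos, 0, seq = seq))
  expect_equal(match_and_score(truth, call_at(1010L))$n_tp_site, 1)
  r11 <- match_and_score(truth, call_at(1011L))
  expect_equal(r11$n_tp_site, 0)
  expect_equal(r11$n_fp, 1)
  # size boundary: +10% of 250 is 275
  pad <- function(n) paste0(truth_seq, strrep("A", n))
  expect_equal(match_and_score(truth, call_at(1000L, pad(25)))$n_tp_seq, 1)
  expect_equal(match_and_score(truth, call_at(1000L, pad(26)))$n_tp_seq, 0)
  # identity boundary: 25 substitutions in 250 columns = 0.90 passes, 26 fail
  mut_n <- function(n) {
    ch <- strsplit(truth_seq, "")[[1]]
    for (i in seq_len(n)) ch[i * 9] <- setdiff(c("A", "C", "G", "T"), ch[i * 9])[1]
    paste(ch, collapse = "")
  }
  expect_equal(match_and_score(truth, call_at(1000L, mut_n(25)))$n_tp_seq, 1)
  expect_equal(match_and_score(truth, call_at(1000L, mut_n(26)))$n_tp_seq, 0)
})

test_that("matching is one-to-one, order-stable, and self-match is perfect", {
  gen <- fx_genome()
  tb <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 12, seed = 4)
  rep <- match_and_score(tb, truth_as_callset(tb))
  expect_equal(rep$recall_site, 1)
  expect_equal(rep$recall_seq, 1)
  expect_equal(rep$n_fp, 0)
  # one call cannot validate two truths
  truth2 <- data.frame(chrom = "chr1", pos = c(1000L, 1008L),
                       inserted_seq = c(rand_seq(100), rand_seq(100)),
                       stringsAsFactors = FALSE)
  one_call <- callset(rec_row("c1", 1004, 0, seq = rand_seq(100)))
  expect_equal(match_and_score(truth2, one_call)$n_tp_site, 1)
  # permutation of call order does not change the result
  calls <- truth_as_callset(tb)
  set.seed(83)
  shuf <- callset(calls$records[sample(nrow(calls$records)), ])
  r1 <- match_and_score(tb, calls); r2 <- match_and_score(tb, shuf)
  expect_equal(sort(r1$tp_truth_ids), sort(r2$tp_truth_ids))
  # disjoint chromosome naming is an error
  bad <- callset(rec_row("c1", 1000, 60, chrom = "3"))
  expect_error(match_and_score(tb, bad), "chromosome")
})

test_that("recall monotonicity invariants hold on randomized inputs", {
  gen <- fx_genome()
  tb <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 15, seed = 5)
  set.seed(84)
  r <- truth_as_callset(tb)$records
  r$pos <- r$pos + sample(-15:15, nrow(r), replace = TRUE)
  r$filter <- sample(c("PASS", "LowQual"), nrow(r), replace = TRUE)
  noisy <- callset(r)
  rep <- match_and_score(tb, noisy)
  expect_lte(rep$recall_seq, rep$recall_site)
  # widening the margin never decreases site recall
  r5 <- match_and_score(tb, noisy, match_config(site_margin = 5))
  r20 <- match_and_score(tb, noisy, match_config(site_margin = 20))
  expect_lte(r5$recall_site, r20$recall_site)
  # disabling pass_only never decreases recall
  rall <- match_and_score(tb, noisy, match_config(pass_only = FALSE))
  expect_gte(rall$recall_site, rep$recall_site)
  expect_gte(rall$recall_seq, rep$recall_seq)
  # tightening identity never increases sequence recall
  tight <- match_and_score(tb, noisy, match_config(min_identity = 0.99))
  expect_lte(tight$recall_seq, rep$recall_seq)
})

test_that("caller combination reports union, intersection and k-of-n counts", {
  gen <- fx_genome()
  tb <- generate_insertions("baseline", "baseline", gen, fx_donors(), n = 9, seed = 6)
  full <- truth_as_callset(tb)
  sub <- function(idx, tag) {
    r <- full$records[idx, ]; r$record_id <- paste0(tag, seq_along(idx)); callset(r)
  }
  # identical callsets: union == intersection
  same <- combine_callsets(list(A = full, B = full, C = full), tb)
  expect_equal(same$union_count, same$intersection_count)
  # disjoint TP sets
  dis <- combine_callsets(list(A = sub(1:3, "a"), B = sub(4:6, "b"), C = sub(7:9, "c")), tb)
  expect_equal(dis$intersection_count, 0)
  expect_equal(dis$union_count, 9)
  expect_equal(unname(dis$k_of_n[["1"]]), 9L)
  # nested callsets: union equals the larger TP set
  nest <- combine_callsets(list(A = sub(1:4, "a"), B = full), tb)
  expect_equal(nest$union_count, 9)
  expect_equal(nest$intersection_count, 4)
})
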