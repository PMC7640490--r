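# Sequence comparison primitives: seed-and-extend local alignment, global
# identity, tandem-period detection and genomic copy counting. Dynamic
# programming is delegated to Biostrings::pairwiseAlignment; seeding, locus
# clustering, identity accounting and period verification are implemented
# here.

.SUB_MAT <- NULL

.sub_mat <- function() {
  if (is.null(.SUB_MAT)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
    # N never matches anything, including itself
    m["N", ] <- -1; m[, "N"] <- -1
    utils::assignInMyNamespace(".SUB_MAT", m)
  }
  .SUB_MAT
}

# Identity bookkeeping on a pair of aligned strings: matches / alignment
# columns, gaps count as columns, N matches nothing.
.aln_identity <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  matches <- sum(pc == sc & pc %in% DNA_BASES)
  list(identity = matches / length(pc), n_matches = matches, columns = length(pc))
}

# Trim the longest zero-sum (or negative) prefix/suffix off an aligned pair
# (match +1, mismatch/gap -1) so that among equal-scoring alignments the
# shortest, highest-identity one is reported. Returns trimmed column range.
.trim_zero_tails <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  sc_col <- ifelse(pc == sc & pc %in% DNA_BASES, 1L, -1L)
  n <- length(sc_col)
  cs <- cumsum(sc_col)
  lead <- which(cs <= 0)
  from <- if (length(lead)) max(lead) + 1L else 1L
  cs_r <- rev(cumsum(rev(sc_col)))
  tail_idx <- which(cs_r <= 0)
  to <- if (length(tail_idx)) min(tail_idx) - 1L else n
  if (from > to) return(NULL)
  c(from, to)
}

# Count query/subject positions consumed by columns [from, to] of an aligned
# string pair; used to convert trimmed column ranges back to coordinates.
.consumed <- function(chars, from, to) {
  sum(chars[seq.int(from, to)] != "-")
}

# ---- target k-mer index -----------------------------------------------------
# Seeds are located by exact k-mer lookup against a per-target index: k-mers
# are 2-bit encoded into integers, positions radix-sorted by code, and query
# codes resolved by binary search. The index is cached per target (keyed by
# length plus sequence excerpts) because classification sweeps hundreds of
# queries over the same genome and consensus library.

.idx_cache <- new.env(parent = emptyenv())

.kmer_codes <- function(seq, k) {
  b <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(b))
  code[b == 65L] <- 0L; code[b == 67L] <- 1L  # A C
  code[b == 71L] <- 2L; code[b == 84L] <- 3L  # G T
  n <- length(code) - k + 1L
  if (n < 1L) return(integer(0))
  val <- integer(n)
  for (j in seq_len(k)) {
    val <- val * 4L + code[j:(j + n - 1L)]
  }
  val
}

.target_index <- function(target, k) {
  lt <- nchar(target)
  cacheable <- lt >= 50000L   # small targets are cheap to index on the fly
  key <- NULL
  if (cacheable) {
    key <- paste(k, lt, substr(target, 1L, 24L), substr(target, lt - 23L, lt),
                 substr(target, lt %/% 2L, lt %/% 2L + 23L), sep = "|")
    hit <- get0(key, envir = .idx_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  val <- .kmer_codes(target, k)
  pos <- which(!is.na(val))
  val <- val[pos]
  o <- order(val, method = "radix")
  idx <- list(sval = val[o], spos = pos[o])
  if (cacheable) {
    if (length(ls(.idx_cache)) > 16L) rm(list = ls(.idx_cache), envir = .idx_cache)
    assign(key, idx, envir = .idx_cache)
  }
  idx
}

.empty_alignments <- function() {
  data.frame(query_start = integer(0), query_end = integer(0),
             target_start = integer(0), target_end = integer(0),
             strand = character(0), identity = numeric(0),
             n_matches = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Local alignment by exact k-mer seeding and Smith-Waterman refinement
#'
#' BLAT-like local alignment discovery at desk scale: exact k-mer seeds
#' (default k = 11) are located on both strands of the target, clustered into
#' candidate loci by implied target start, and each locus is refined with a
#' full Smith-Waterman alignment of the query against a local target window.
#' Alignments are trimmed to their shortest maximal-scoring form and emitted
#' when identity (matches / alignment columns, gaps counted, N never matches)
#' reaches `min_identity`. Equal-identity alignments are ordered leftmost
#' target coordinate first.
#'
#' @param query query sequence (character); must be at least 20 bp and at
#'   most 50 percent N.
#' @param target target sequence (character), e.g. a chromosome.
#' @param min_identity minimum identity of emitted alignments, in (0, 1].
#' @param k seed k-mer size.
#' @param both_strands also search the reverse complement of the query;
#'   minus-strand hits report query coordinates on the original orientation.
#' @param max_kmer_hits seeds occurring more often than this in the target
#'   are masked (overused-tile rule).
#' @param max_loci refine at most this many seed clusters (strongest first).
#' @param min_score minimum alignment score (matches minus mismatch/gap
#'   penalties) of emitted alignments; filters the chance short alignments a
#'   single seed hit would otherwise produce (default 30).
#' @param min_cluster_seeds minimum number of seed hits a cluster needs
#'   before Smith-Waterman refinement (default 2; genuine alignments of the
#'   emitted score carry several seeds).
#' @return data.frame with columns `query_start`, `query_end`,
#'   `target_start`, `target_end` (1-based, closed), `strand`, `identity`,
#'   `n_matches`, `score`.
#' @export
local_align <- function(query, target, min_identity = 0.9, k = 11,
                        both_strands = TRUE, max_kmer_hits = 400, max_loci = 400,
                        min_score = 30, min_cluster_seeds = 2) {
  query <- toupper(query); target <- toupper(target)
  lq <- nchar(query)
  if (lq < 20) stop("query shorter than 20 bp")
  if (sum(strsplit(query, "")[[1]] == "N") > lq / 2) {
    stop("low-complexity/ambiguous query: more than 50% N")
  }
  stopifnot(min_identity > 0, min_identity <= 1)
  tgt <- Biostrings::DNAString(target)
  lt <- nchar(target)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  idx <- .target_index(target, k)
  for (strand in strands) {
    q <- if (strand == "+") query else .revcomp(query)
    qval <- .kmer_codes(q, k)
    qpos <- which(!is.na(qval))
    if (!length(qpos) || !length(idx$sval)) next
    qv <- qval[qpos]
    hi <- findInterval(qv, idx$sval)
    lo <- findInterval(qv - 0.5, idx$sval)
    cnt <- hi - lo
    keep_k <- cnt > 0L & cnt <= max_kmer_hits
    if (!any(keep_k)) next
    # implied target start of the full query for each (query-pos, target-pos)
    take <- sequence(nvec = cnt[keep_k], from = lo[keep_k] + 1L)
    imp <- idx$spos[take] - rep(qpos[keep_k], cnt[keep_k]) + 1L
    imp <- sort(imp)
    # cluster implied starts: same locus when within half a query length
    brk <- c(TRUE, diff(imp) > max(20L, lq %/% 2L))
    cl_id <- cumsum(brk)
    cl_start <- tapply(imp, cl_id, stats::median)
    cl_n <- tabulate(cl_id)
    elig <- which(cl_n >= min_cluster_seeds)
    o <- elig[order(-cl_n[elig], cl_start[elig])]
    if (length(o) > max_loci) o <- o[seq_len(max_loci)]
    qds <- Biostrings::DNAString(q)
    for (ci in o) {
      anchor <- as.integer(cl_start[ci])
      ws <- max(1L, anchor - max(20L, lq %/% 4L))
      we <- min(lt, anchor + lq + max(20L, lq %/% 4L))
      if (we - ws + 1L < k) next
      win <- Biostrings::subseq(tgt, ws, we)
      al <- Biostrings::pairwiseAlignment(qds, win, type = "local",
                                          substitutionMatrix = .sub_mat(),
                                          gapOpening = 5, gapExtension = 2)
      p <- as.character(Biostrings::alignedPattern(al))
      s <- as.character(Biostrings::alignedSubject(al))
      rng <- .trim_zero_tails(p, s)
      if (is.null(rng)) next
      pc <- strsplit(p, "", fixed = TRUE)[[1]]
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      q0 <- IRanges::start(Biostrings::pattern(al))
      t0 <- IRanges::start(Biostrings::subject(al))
      q_from <- q0 + (if (rng[1] > 1) .consumed(pc, 1L, rng[1] - 1L) else 0L)
      t_from <- ws - 1L + t0 + (if (rng[1] > 1) .consumed(sc, 1L, rng[1] - 1L) else 0L)
      q_to <- q_from + .consumed(pc, rng[1], rng[2]) - 1L
      t_to <- t_from + .consumed(sc, rng[1], rng[2]) - 1L
      idn <- .aln_identity(paste(pc[rng[1]:rng[2]], collapse = ""),
                           paste(sc[rng[1]:rng[2]], collapse = ""))
      if (idn$identity < min_identity) next
      if (2L * idn$n_matches - idn$columns < min_score) next
      if (strand == "-") {
        tmp <- q_from
        q_from <- lq - q_to + 1L
        q_to <- lq - tmp + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        query_start = q_from, query_end = q_to,
        target_start = t_from, target_end = t_to,
        strand = strand, identity = idn$identity,
        n_matches = idn$n_matches, score = Biostrings::score(al),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_alignments())
  res <- do.call(rbind, out)
  # deduplicate: alignments whose target intervals overlap by more than half
  # of the shorter one are the same locus; keep best identity then leftmost
  res <- res[order(-res$identity, res$target_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i == nrow(res)) break
    for (j in seq.int(i + 1L, nrow(res))) {
      if (!keep[j]) next
      ov <- min(res$target_end[i], res$target_end[j]) -
        max(res$target_start[i], res$target_start[j]) + 1L
      if (ov <= 0) next
      shorter <- min(res$target_end[i] - res$target_start[i],
                     res$target_end[j] - res$target_start[j]) + 1L
      if (ov > shorter / 2) keep[j] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$identity, res$target_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' End-to-end identity between two sequences
#'
#' Needleman-Wunsch global alignment identity: matches divided by alignment
#' columns, gap columns included, N matching nothing. Symmetric in its
#' arguments.
#'
#' @param a,b nonempty sequences (character).
#' @return identity fraction in \[0, 1\].
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity requires nonempty sequences")
  a <- toupper(a); b <- toupper(b)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = .sub_mat(),
                                      gapOpening = 5, gapExtension = 2)
  idn <- .aln_identity(as.character(Biostrings::alignedPattern(al)),
                       as.character(Biostrings::alignedSubject(al)))
  idn$identity
}

# Candidate tandem periods from the distances between repeated k-mer
# occurrences, plus all small periods.
.candidate_periods <- function(ch, max_period) {
  n <- length(ch)
  cand <- seq_len(min(max_period, 30L))
  if (n >= 24) {
    k <- 6L
    starts <- seq_len(n - k + 1L)
    kmers <- substring(paste(ch, collapse = ""), starts, starts + k - 1L)
    pos_by_kmer <- split(starts, kmers)
    d <- unlist(lapply(pos_by_kmer, function(p) if (length(p) > 1) diff(p) else NULL),
                use.names = FALSE)
    d <- d[d <= max_period]
    if (length(d)) {
      tb <- table(d)
      cand <- c(cand, as.integer(names(tb)[tb >= 2L]))
    }
  }
  sort(unique(cand[cand >= 1L & cand <= max_period]))
}

# Longest run of shift-p self-matches with mean mismatch <= max_div, i.e. the
# longest subarray of (max_div - mism) with nonnegative sum. O(m) via strict
# prefix minima scanned against descending right endpoints.
# Returns c(start, length) of the run in the shifted-match vector, or NULL.
.longest_low_div_run <- function(mism, max_div) {
  m <- length(mism)
  x <- max_div - mism
  P <- c(0, cumsum(x))                      # length m + 1; interval (i..j] = P[j+1] - P[i+1]
  pm <- which(P <= cummin(P))               # strictly decreasing prefix minima (indices into P)
  best_len <- 0L; best_start <- NA_integer_
  ptr <- length(pm)
  for (j in seq.int(m + 1L, 2L)) {
    while (ptr >= 1L && pm[ptr] < j && P[pm[ptr]] <= P[j]) {
      len <- j - pm[ptr]
      if (len > best_len) { best_len <- len; best_start <- pm[ptr] }
      ptr <- ptr - 1L
    }
    if (ptr < 1L) break
  }
  if (best_len == 0L) return(NULL)
  c(best_start, best_len)                   # run covers mism[best_start .. best_start+len-1]
}

#' Detect tandem-repeat structure in a sequence
#'
#' Reports tandem arrays as (seed size, copy number, covered span, coverage).
#' Candidate periods are proposed from the distance histogram of repeated
#' 6-mers (plus all periods up to 30 bp) and each candidate p is verified by
#' shift-p self-comparison: the array is the longest run of positions where
#' `seq[i] == seq[i+p]` with at most `max_divergence` mean mismatch, and must
#' contain at least two full copies. The smallest verified period is reported
#' first among equal-coverage annotations.
#'
#' @param seq sequence of length >= 2.
#' @param max_divergence tolerated mismatch fraction within the array
#'   (default 0.10).
#' @param min_coverage drop annotations covering less than this fraction of
#'   the sequence (default 0.5).
#' @return data.frame with columns `seed_size`, `copy_number`, `span_start`,
#'   `span_end`, `coverage`, ordered by decreasing coverage then increasing
#'   seed size. Zero rows when no array is found.
#' @export
find_tandem_structure <- function(seq, max_divergence = 0.10, min_coverage = 0.5) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2) stop("sequence must be at least 2 bp")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  max_period <- n %/% 2L
  if (max_period < 1L) return(.empty_tandem())
  cands <- .candidate_periods(ch, max_period)
  rows <- list()
  for (p in cands) {
    a <- ch[seq_len(n - p)]
    b <- ch[seq.int(p + 1L, n)]
    mism <- as.integer(a != b | !(a %in% DNA_BASES))
    run <- .longest_low_div_run(mism, max_divergence)
    if (is.null(run)) next
    if (run[2] < p) next          # require at least two full copies
    span_start <- run[1]
    span_len <- run[2] + p
    coverage <- span_len / n
    if (coverage < min_coverage) next
    rows[[length(rows) + 1L]] <- data.frame(
      seed_size = p, copy_number = span_len / p,
      span_start = span_start, span_end = span_start + span_len - 1L,
      coverage = coverage, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_tandem())
  res <- do.call(rbind, rows)
  res <- res[order(-res$coverage, res$seed_size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_tandem <- function() {
  data.frame(seed_size = integer(0), copy_number = numeric(0),
             span_start = integer(0), span_end = integer(0),
             coverage = numeric(0), stringsAsFactors = FALSE)
}

#' Count genomic copies of a sequence
#'
#' Counts disjoint genomic loci carrying an alignment of the query with
#' identity at least `min_identity` that covers at least `min_query_cov` of
#' the query. Loci on the same chromosome whose alignments overlap by more
#' than half of the shorter one are merged (handled inside [local_align()]'s
#' deduplication plus a cross-strand merge here).
#'
#' @param seq query sequence, >= 20 bp.
#' @param genome a `DNAStringSet` (or coercible) genome.
#' @param min_identity minimum alignment identity.
#' @param min_query_cov minimum fraction of the query covered.
#' @param ... passed to [local_align()].
#' @return integer copy count.
#' @export
count_genomic_copies <- function(seq, genome, min_identity = 0.9, min_query_cov = 0.8, ...) {
  genome <- .as_genome(genome)
  lq <- nchar(seq)
  total <- 0L
  for (chrom in names(genome)) {
    al <- local_align(seq, as.character(genome[[chrom]]), min_identity = min_identity, ...)
    if (!nrow(al)) next
    qcov <- (al$query_end - al$query_start + 1L) / lq
    al <- al[qcov >= min_query_cov, , drop = FALSE]
    if (!nrow(al)) next
    # merge loci overlapping > 50% of the shorter interval (strand-agnostic)
    al <- al[order(al$target_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(al))
    for (i in seq_len(nrow(al))) {
      if (!keep[i] || i == nrow(al)) next
      for (j in seq.int(i + 1L, nrow(al))) {
        if (!keep[j]) next
        ov <- min(al$target_end[i], al$target_end[j]) -
          max(al$target_start[i], al$target_start[j]) + 1L
        if (ov <= 0) next
        shorter <- min(al$target_end[i] - al$target_start[i],
                       al$target_end[j] - al$target_start[j]) + 1L
        if (ov > shorter / 2) keep[j] <- FALSE
      }
    }
    total <- total + sum(keep)
  }
  total
}
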