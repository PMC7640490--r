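# Junctional homology: near-identical sequence shared between a flank of the
# insertion site and the corresponding end of the inserted sequence. Two-tier
# detection: a strict base-by-base scan for small homologies (< 10 bp per
# side), refined by 90%-identity local alignments for larger ones.

#' Strict small-scale junctional homology scan
#'
#' Compares outward from the insertion site: on the left side, the last bases
#' of the left flank against the last bases of the inserted sequence; on the
#' right side, the first bases of the right flank against the first bases of
#' the inserted sequence. Each side counts identical nucleotides until the
#' first mismatch, capped at `cap` (10 bp) and at the insertion length. N
#' never matches.
#'
#' @param left_flank sequence immediately left of the insertion site (at
#'   least `cap` bp when available).
#' @param right_flank sequence immediately right of the insertion site.
#' @param ins inserted sequence.
#' @param cap per-side scan cap in bp (default 10).
#' @return list with integer elements `left` and `right`.
#' @export
small_homology <- function(left_flank, right_flank, ins, cap = 10L) {
  ins <- toupper(ins); left_flank <- toupper(left_flank); right_flank <- toupper(right_flank)
  li <- nchar(ins)
  # left: flank suffix vs insertion suffix
  left <- 0L
  kmax <- min(cap, li, nchar(left_flank))
  while (left < kmax) {
    a <- substr(left_flank, nchar(left_flank) - left, nchar(left_flank) - left)
    b <- substr(ins, li - left, li - left)
    if (a != b || !(a %in% DNA_BASES)) break
    left <- left + 1L
  }
  # right: flank prefix vs insertion prefix
  right <- 0L
  kmax <- min(cap, li, nchar(right_flank))
  while (right < kmax) {
    a <- substr(right_flank, right + 1L, right + 1L)
    b <- substr(ins, right + 1L, right + 1L)
    if (a != b || !(a %in% DNA_BASES)) break
    right <- right + 1L
  }
  list(left = left, right = right)
}

# One side of the alignment-based search. side = "left" or "right".
# Returns list(size, ins_start, ins_end) or NULL when no candidate passes the
# two <= max_dist constraints.
.align_homology_side <- function(window, ins, side, min_identity = 0.9, max_dist = 10L) {
  lw <- nchar(window); li <- nchar(ins)
  if (li < 20 || lw < 20) return(NULL)
  # homologies start at 11 bp, so the usual score/cluster floors are relaxed;
  # the two distance constraints below do the false-positive control here
  al <- tryCatch(local_align(ins, window, min_identity = min_identity, both_strands = FALSE,
                             min_score = 11, min_cluster_seeds = 1),
                 error = function(e) NULL)
  if (is.null(al) || !nrow(al)) return(NULL)
  if (side == "left") {
    # homologous copy must end within max_dist of the insertion site (window
    # right end) and within max_dist of the insertion's end
    ok <- (lw - al$target_end) <= max_dist & (li - al$query_end) <= max_dist
    dist <- (lw - al$target_end) + (li - al$query_end)
  } else {
    ok <- (al$target_start - 1L) <= max_dist & (al$query_start - 1L) <= max_dist
    dist <- (al$target_start - 1L) + (al$query_start - 1L)
  }
  al <- al[ok, , drop = FALSE]; dist <- dist[ok]
  if (!nrow(al)) return(NULL)
  size <- al$query_end - al$query_start + 1L
  # closest to the extremities wins; ties keep the larger homology
  o <- order(dist, -size)
  i <- o[1]
  list(size = size[i], ins_start = al$query_start[i], ins_end = al$query_end[i])
}

# Sum two per-side homologies after removing their overlap on the inserted
# sequence. Sides are given as ins-coordinate intervals (NULL when size 0).
.total_homology <- function(left_int, right_int) {
  l <- if (is.null(left_int)) 0L else left_int[2] - left_int[1] + 1L
  r <- if (is.null(right_int)) 0L else right_int[2] - right_int[1] + 1L
  if (l == 0L || r == 0L) return(l + r)
  ov <- max(0L, min(left_int[2], right_int[2]) - max(left_int[1], right_int[1]) + 1L)
  l + r - ov
}

#' Alignment-based junctional homology
#'
#' Searches the junction windows flanking the insertion site for copies of
#' the inserted-sequence extremities with at least `min_identity` identity,
#' requiring the copy to lie within `max_dist` bp of the insertion site and
#' within `max_dist` bp of the corresponding insertion extremity. When
#' several candidates pass on one side, the one closest to the extremities is
#' kept (ties: the larger homology). The total size sums both sides after
#' removing their overlap on the inserted sequence.
#'
#' @param left_window,right_window reference sequence immediately left/right
#'   of the insertion site (typically the same length as the insertion,
#'   capped at 10 kb).
#' @param ins inserted sequence.
#' @param min_identity minimum alignment identity (default 0.90).
#' @param max_dist distance constraint in bp (default 10).
#' @return list with `left_size`, `right_size`, `total_size`, `method`.
#' @export
large_homology <- function(left_window, right_window, ins, min_identity = 0.9,
                           max_dist = 10L) {
  li <- nchar(ins)
  lh <- .align_homology_side(left_window, ins, "left", min_identity, max_dist)
  rh <- .align_homology_side(right_window, ins, "right", min_identity, max_dist)
  left_int <- if (!is.null(lh)) c(lh$ins_start, lh$ins_end) else NULL
  right_int <- if (!is.null(rh)) c(rh$ins_start, rh$ins_end) else NULL
  total <- .total_homology(left_int, right_int)
  list(left_size = if (is.null(lh)) 0L else lh$size,
       right_size = if (is.null(rh)) 0L else rh$size,
       total_size = total,
       method = if (is.null(lh) && is.null(rh)) "none" else "alignment")
}

#' Junctional homology of one insertion
#'
#' Two-tier measurement: the strict scan runs first on the 10 bp junctions;
#' when either side reaches the scan cap the alignment-based search refines
#' that side using junction windows of the same length as the insertion
#' (capped at `max_window`). The reported total is the maximum of the strict
#' and alignment-based totals, both computed with overlap removal on the
#' inserted sequence.
#'
#' @param chrom,pos insertion site: `pos` is the 1-based anchor base; the
#'   sequence is inserted between `pos` and `pos + 1`.
#' @param ins inserted sequence.
#' @param genome genome (`DNAStringSet` or coercible).
#' @param cap strict-scan per-side cap (default 10).
#' @param min_identity alignment identity threshold (default 0.90).
#' @param max_window junction window cap in bp (default 10000).
#' @return list with `left_size`, `right_size`, `total_size`, `method`
#'   (`"strict_scan"`, `"alignment"` or `"none"`) and `at_edge` flag set when
#'   a contig edge truncated a flank.
#' @export
junctional_homology_size <- function(chrom, pos, ins, genome, cap = 10L,
                                     min_identity = 0.9, max_window = 10000L) {
  g <- .chrom_seq(genome, chrom)
  lg <- nchar(g)
  li <- nchar(ins)
  stopifnot(pos >= 1, pos <= lg)
  at_edge <- (pos < cap) || (pos + cap > lg)
  lf10 <- substr(g, max(1L, pos - cap + 1L), pos)
  rf10 <- substr(g, pos + 1L, min(lg, pos + cap))
  sm <- small_homology(lf10, rf10, ins, cap = cap)
  eff_cap_l <- min(cap, li, nchar(lf10))
  eff_cap_r <- min(cap, li, nchar(rf10))
  left_int <- if (sm$left > 0L) c(li - sm$left + 1L, li) else NULL
  right_int <- if (sm$right > 0L) c(1L, sm$right) else NULL
  total_strict <- .total_homology(left_int, right_int)
  best <- list(left_size = sm$left, right_size = sm$right, total_size = total_strict,
               method = if (total_strict > 0L) "strict_scan" else "none",
               at_edge = at_edge)
  need_l <- sm$left >= eff_cap_l && eff_cap_l > 0L
  need_r <- sm$right >= eff_cap_r && eff_cap_r > 0L
  if (!need_l && !need_r) return(best)
  w <- min(li, max_window)
  a_left_int <- left_int; a_right_int <- right_int
  a_left <- sm$left; a_right <- sm$right
  if (need_l) {
    lw <- substr(g, max(1L, pos - w + 1L), pos)
    lh <- .align_homology_side(lw, ins, "left", min_identity, cap)
    if (!is.null(lh)) { a_left_int <- c(lh$ins_start, lh$ins_end); a_left <- lh$size }
  }
  if (need_r) {
    rw <- substr(g, pos + 1L, min(lg, pos + w))
    rh <- .align_homology_side(rw, ins, "right", min_identity, cap)
    if (!is.null(rh)) { a_right_int <- c(rh$ins_start, rh$ins_end); a_right <- rh$size }
  }
  total_aln <- .total_homology(a_left_int, a_right_int)
  if (total_aln > total_strict) {
    return(list(left_size = a_left, right_size = a_right, total_size = total_aln,
                method = "alignment", at_edge = at_edge))
  }
  best
}

#' Junctional homology for every record of a callset
#'
#' @param cs an `inschar_callset` with resolved records.
#' @param genome genome.
#' @param ... passed to [junctional_homology_size()].
#' @return data.frame with `record_id`, `left_size`, `right_size`,
#'   `total_size`, `method`.
#' @export
callset_homology <- function(cs, genome, ...) {
  stopifnot(inherits(cs, "inschar_callset"))
  genome <- .genome_chars(genome)
  r <- cs$records
  out <- lapply(seq_len(nrow(r)), function(i) {
    h <- junctional_homology_size(r$chrom[i], r$pos[i], r$inserted_seq[i], genome, ...)
    data.frame(record_id = r$record_id[i], left_size = h$left_size,
               right_size = h$right_size, total_size = h$total_size,
               method = h$method, stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(record_id = character(0), left_size = integer(0),
                      right_size = integer(0), total_size = integer(0),
                      method = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Null distribution of junctional homology under random insertions
#'
#' Places `n` insertions of `ins_len` i.i.d. uniform A/C/G/T bases at sites
#' sampled uniformly along the genome and measures each with the same
#' two-tier detector used for real insertions. The maximum of this null
#' distribution calibrates how much junctional homology arises by chance.
#'
#' @param genome genome (`DNAStringSet` or coercible).
#' @param n number of random insertions (default 2000).
#' @param ins_len inserted-sequence length (default 250).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `sizes` (integer vector of length `n`) and `max`
#'   (0 when `n == 0`).
#' @export
random_null_homology <- function(genome, n = 2000, ins_len = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- .genome_chars(genome)
  lens <- nchar(genome)
  if (n == 0) return(list(sizes = integer(0), max = 0L))
  chroms <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
  sizes <- integer(n)
  for (i in seq_len(n)) {
    lg <- lens[[chroms[i]]]
    pos <- sample.int(lg - 1L, 1)
    ins <- .rand_dna(ins_len)
    sizes[i] <- junctional_homology_size(chroms[i], pos, ins, genome)$total_size
  }
  list(sizes = sizes, max = max(sizes))
}
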